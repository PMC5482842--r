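---
title: "Modelling foliar d15N isoscapes from terrain and invader proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling foliar d15N isoscapes from terrain and invader proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In nutrient-poor coastal dunes invaded by an N~2~-fixing acacia, the foliar
nitrogen isotope ratio (d15N, in per mil) of a non-fixing native shrub is a
functional tracer of nitrogen input: symbiotically fixed N carries a
signature near 0‰, while the native background is strongly depleted, so
enrichment toward 0‰ near invader canopies indicates uptake of
invader-derived N. The observed variation, however, mixes this invader
signal with the native system's own heterogeneity — topographically
controlled moisture, landform, and vegetation cover all shift d15N.
`nitroscape` implements the full analysis that disentangles these
components: six spatially explicit predictor rasters, an additive mixed
model, AICc model selection, split-sample validation, spatial residual
diagnostics, and continuous predicted isoscapes.

## The model

For plant $i$ on transect $t$ nested in plot $p$:

$$
\delta^{15}N_{i} = \beta_0 + f_1(\mathrm{dist}_i) + f_2(\mathrm{elev}_i)
 + f_3(\log \mathrm{area}_i) + f_4(\log(\mathrm{cover}_i + 1))
 + f_5(\mathrm{TWI}_i) + \gamma_{\mathrm{landform}(i)}
 + b_p + b_{t(p)} + \varepsilon_i
$$

with Gaussian errors and identity link, thin-plate regression spline
smooths $f_j$ (basis dimension $k = 10$ by default, sum-to-zero
constrained), a five-level landform factor, and random intercepts for plot
and for transect-within-plot (transect labels are globally unique, so a
plain transect intercept realizes the nesting). Fitting uses
`mgcv::gam(..., method = "ML")`: penalized splines in their mixed-model
representation, smoothing parameters and variance components by maximum
likelihood — ML rather than REML because candidate models with different
fixed-effect structures are compared by AICc.

The parameter count used for AICc is the number of estimated parameters in
the mixed-model representation: intercept, landform contrasts and one
unpenalized linear term per smooth, plus one smoothing parameter per
smooth, the two random-intercept variances and the residual variance. For
the full model this gives 18, dropping one smooth removes 2 — the same
accounting that reproduces the df column of the published selection table,
which is why it was adopted.

## Predictors

* `dist_ac` — Euclidean distance (m) from each 1-m cell center to the
  nearest footprint cell of an invader canopy larger than 6 m² (strict
  inequality; the threshold and the boundary rule are arguments).
  Distances are computed cell-center to cell-center, so the sub-cell error
  is at most $\sqrt{2}/2$ m; equidistant ties go to the lowest canopy id.
* `area_ac`, `elev_ac` — area (m², log-transformed for modelling) and
  relative elevation of that nearest canopy. The canopy reference elevation
  is the mean DEM over its footprint (centroid-cell and minimum variants
  are selectable); negative `elev_ac` means the cell lies below the canopy.
* `twi` — topographic wetness index $\ln(a/\tan\beta)$, with contributing
  area $a$ from multiple-flow-direction routing (each cell passes its
  accumulated area to all strictly lower 8-neighbours with weights
  proportional to $(\text{drop}/\text{distance})^{1.1}$; cells processed in
  descending elevation order, ties by cell index; flats and pits retain
  their accumulation). Slope is Zevenbergen–Thorne central differences;
  $\tan\beta$ is floored at 0.001 so flat cells stay finite; the index is
  smoothed with a four-cell circular mean filter.
* `landform` — five classes (ridge, slope, plain, drainage, valley) from
  the topographic position index: DEM smoothed with a five-cell mean
  filter, TPI as cell elevation minus the mean over a 10–100 m annulus,
  standardized to z-scores, then ridge $z \ge 1$, valley $z \le -1$,
  drainage $-1 < z \le -0.5$, upper mid-slope $0.5 \le z < 1$ mapped to
  slope, and $|z| < 0.5$ split into plain vs slope at a 5° slope threshold.
  All thresholds are arguments. The 10-class Weiss-style scheme is collapsed
  to these five because thin classes merge at this spatial extent.
* `cover` — percent vegetation cover. From classified returns, the bounded
  convention $100 \cdot n_{\text{nonground}} / n_{\text{total}}$ is the
  default (the literal nonground/ground ratio is unbounded and inconsistent
  with a 0–92 % observed range; it remains available), smoothed with a
  six-cell mean filter; modelling uses $\log(\text{cover}+1)$.

Two readings of the TPI window are defensible ("minimum radius ...
maximum radius"); the annulus reading is implemented and the filled-window
variant is `inner_radius_m = 0`. No depression filling is applied by
default — the target landscapes are well-drained dunes.

## The synthetic world

`simulate_scenario()` generates a complete study landscape so that every
stage is testable without field data. Its defaults *are* the study design
being emulated: a 600 × 600 m raster at 1 m; eight plots, each centered on
one invader canopy, four ~20 m transects per plot in the cardinal
directions with on average 13 ± 3 plants each (≈ 420–450 plants); 20
canopies with areas log-uniform in 8.3–564.7 m² (the eight plot canopies
stratified over that range so it is always represented); residual noise
1.8‰ around an overall level of −5.84‰. The DEM superposes two
anisotropic sinusoidal ridge systems (primary wavelength 120 m, amplitude
3 m; secondary 45 m / 1.2 m) with a correlated random field (0.8 m,
25 m correlation length) — dune ridges and swales, not a calibrated
reproduction of any real site. Cover is a smooth random field mapped to
percent and clamped, leaving bare-sand patches at exactly 0 and dense
patches above 90 %, with 100 % under canopies.

The generative truth mirrors the reported effect magnitudes: a cosine
taper giving +3‰ at the canopy edge and exactly 0 beyond 8 m; a sigmoid
elevation effect (span 2‰) enriching plants below the canopy; a sigmoid
canopy-area effect reaching +1‰ for the largest canopies; a linear
log-cover effect spanning 5‰; a linear TWI effect spanning −4‰; and
landform offsets with valleys and drainages highest and plains lowest
(span ≈ 1.2‰). The cover and TWI components are defined by their span
over the *realized* covariate range, so `calibrate_truth()` fixes their
slopes per scenario — this calibration is part of the stated world, not a
tuning knob. All components are mean-centered over the sample so the
intercept carries the level; component values, random intercepts
(SD 0.8‰ plot, 0.6‰ transect — invented, chosen so the marginal SD stays
in the observed 2–4‰ range) and noise draws are stored in the output
table for recovery testing. One master seed expands deterministically into
per-stage child seeds.

What the generator does *not* emulate: LiDAR sensor physics and point
clouds (rasters are emitted directly), GPS error, multi-species structure,
spatially correlated residuals (the motivating analysis confirmed their
absence), and multiple disjoint sites — the eight plots share one
landscape. A green recovery test therefore establishes that the estimation
machinery recovers a world with the stated structure; it cannot establish
anything about field data.

## Validation and diagnostics

`split_validate()` repeats (default 100×): fit on a random 75 % of rows,
predict the held-out 25 % — random intercepts included for groups present
in training, fixed effects only otherwise — and score RMSE and R².
R² is the squared Pearson correlation of predicted vs measured by default
(the published headline statistic comes from a predicted–observed
comparison); the $1 - \mathrm{SSE}/\mathrm{SST}$ convention is a flag.
Splits that leave fewer than two training plots, an unseen test landform
class, or a constant test response are redrawn and logged. On the default
synthetic world the test suite asserts median R² in [0.45, 0.75] and
median RMSE in [1.6, 2.1]‰ — the bands implied by the generative variance
bookkeeping, which bracket the published field values.

Residual spatial structure is checked with binary-weight Moran's I
correlograms (expectation $-1/(n-1)$, envelope from 199 permutations by
default) and experimental semivariograms, both over 10 equal-width
distance bins to half the maximum pair distance.

## Selection and isoscapes

`dredge_gamm()` fits all $2^6 = 64$ subsets of the six fixed terms (each
smooth in or out whole, landform as a block; random structure and ML kept
throughout), ranks by $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ and
attaches Akaike weights. Non-converging candidates are flagged and
excluded from the weights.

`predict_isoscape()` maps fixed-effects-only predictions cell by cell
(random intercepts are transect-local and undefined on the raster), masked
beyond the maximum training distance to a canopy. `scenario_isoscape()`
holds any subset of predictors at their training mean (or modal class)
while others keep their raster variation; because the linear predictor is
additive, single-predictor maps decompose exactly:
scenario(A) + scenario(B) − baseline = scenario(A, B), which the tests
assert to 1e−8.

## Numerical choices

* Focal means (disk and annulus windows) are FFT convolutions with
  edge-clipped normalization; nodata cells are excluded from windows and
  stay nodata. Equality with direct window enumeration is tested to 1e−8.
* The nearest-canopy search runs on the integer cell lattice (squared
  distances are exact integers), so ties are exact and resolve to the
  lowest id; a bucketed expanding-ring search keeps it fast while matching
  the all-pairs oracle exactly.
* Fit serialization writes spec + training table + fitted quantities as
  JSON; since fitting is deterministic, reloading refits and verifies the
  stored log-likelihood, which guarantees exact re-prediction without
  serializing basis internals.
* Smooth bases reduce $k$ with a warning when a covariate has fewer
  distinct values (the canopy-area predictor is piecewise constant over
  plots, so this fires routinely in small worlds).
* Raster exchange uses plain-text ESRI ASCII grids and GeoJSON rather than
  GeoTIFF: the toolchain is self-contained and the files are diffable;
  swap in a GDAL-backed reader/writer if binary rasters are needed.

## Known limitations

Single-site rasters (no per-site masking across disjoint study sites); no
model-averaged predictions; no variogram model fitting or kriging; no
prediction-uncertainty rasters; Gaussian identity-link responses only. The
df convention, while consistent with the published table, is one of
several defensible accountings of penalized/mixed parameters — comparisons
across software should use the same convention throughout.
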