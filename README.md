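# nitroscape

Community-scale **foliar δ¹⁵N isoscapes** from terrain and invader
proximity.

In nutrient-poor dune systems invaded by an N₂-fixing acacia, the nitrogen
isotope ratio (δ¹⁵N, ‰) of a non-fixing native shrub traces nitrogen input
by the invader: fixed N arrives with a signature near 0‰ while the native
background is strongly depleted, so foliage near invader canopies is
measurably enriched. But δ¹⁵N also responds to the native system's own
heterogeneity — soil moisture, landform, vegetation cover. `nitroscape` is
for ecologists who want to separate those components and map them: it
builds six spatially explicit predictor rasters from a DEM, a cover raster
and canopy polygons, fits an additive mixed model of δ¹⁵N, selects among
all term subsets by AICc, validates by repeated random splits and spatial
residual diagnostics, and predicts continuous δ¹⁵N isoscapes with
scenario decompositions. A synthetic dune-landscape generator with a known
generative truth makes the entire chain testable end to end.

## The model

For plant *i* on transect *t* nested in plot *p*:

```
δ¹⁵N_i = β₀ + f₁(dist.Ac) + f₂(elev.Ac) + f₃(log area.Ac)
       + f₄(log(cover+1)) + f₅(TWI) + γ_landform + b_p + b_t(p) + ε_i
```

Gaussian errors, thin-plate regression spline smooths `f_j`, a five-level
landform factor and nested random intercepts, all fitted by maximum
likelihood (via mgcv). Candidates are ranked by
`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)` with Akaike weights
`w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`. Terrain predictors: topographic wetness
index `ln(a/tanβ)` with multiple-flow-direction contributing area, and a
five-class landform map (ridge/slope/plain/drainage/valley) from an
annulus topographic position index.

## Worked example

```r
library(nitroscape)

scen <- simulate_scenario(sim_config(seed = 1))
scen
#> <scenario> 600x600 m, 20 canopies, 410 plants, d15N [-13.9, 1.3]

fit <- fit_gamm(scen$plants, gamm_spec())
fit
#> <nitro_gamm> n = 410, logLik = -784.59, df = 18, sigma = 1.708
#>   edf: dist_ac 4.09, elev_ac 1.00, log_area_ac 1.00, log_cover 1.64, ...
```

The residual SD (1.71‰) recovers the generative noise (1.8‰), and the
distance smooth is clearly nonlinear (edf 4.1):

```r
pe <- partial_effect(fit, "dist_ac")
#> distance effect: 3.07 permil at 0 m vs -0.55 at 10 m
```

— a ~3‰ enrichment at the canopy edge decaying to nothing beyond ~8 m,
which is exactly the structure the generator planted. All-subsets
selection over the six fixed terms (64 candidates):

```r
sel <- dredge_gamm(scen$plants, gamm_spec(k = 5))
head(as.data.frame(sel), 3)
#>   dist_ac elev_ac log_area_ac log_cover   twi landform df logLik AICc delta weight
#> 1    TRUE   FALSE       FALSE      TRUE  TRUE     TRUE 14 -779.0 1587 0.000  0.859
#> 2    TRUE   FALSE        TRUE      TRUE  TRUE     TRUE 16 -779.1 1592 4.461  0.092
#> 3    TRUE   FALSE       FALSE      TRUE FALSE     TRUE 12 -785.1 1595 7.886  0.017
```

The best model keeps distance, cover, TWI and landform and drops the weak
canopy-area term. Predictive skill by 100 random 75/25 splits
(`split_validate`) and the final isoscape:

```r
v <- split_validate(scen$plants, gamm_spec(), n_runs = 20, seed = 1)
v
#> <validation_summary> 20 runs (train 75%)
#>   median R2 0.482 (IQR 0.429-0.511), median RMSE 1.840 (IQR 1.788-1.916) permil

iso <- predict_isoscape(fit, scen$stack, scen$plants)
iso
#> <raster_grid> 600 x 600 cells, 1 m resolution
#>   values: [-11.15, 0.7639], 320902 nodata cells
```

Predictions are fixed-effects only and masked beyond the maximum training
distance to a canopy (hence the nodata cells far from invader stands).
`scenario_isoscape(fit, scen$stack, scen$plants, vary = "dist_ac")` maps a
single predictor's contribution with all others held at their training
means; such maps add up exactly to the joint map.

A complete run with all intermediate files (ASCII grids, GeoJSON, CSV,
JSON manifest with checksums) is one call —
`run_pipeline(sim_config(seed = 1), "out/")` — or from the shell:
`exec/nitroscape-pipeline --out out/ --seed 1`.

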