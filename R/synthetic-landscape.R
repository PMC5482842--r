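#' Simulation configuration for a synthetic dune scenario
#'
#' Bundles every tunable of the synthetic landscape generator. Defaults
#' reproduce the sampling design of the motivating field study: eight plots,
#' each centered on one invader canopy with four ~20 m transects in the
#' cardinal directions and on average 13 +/- 3 sampled plants per transect
#' (~450 plants in total); canopy areas spanning 8.3-564.7 m^2; residual
#' noise of 1.8 permil around an overall level of -5.84 permil.
#'
#' @param extent_m numeric length-2, landscape width and height (m).
#' @param cell_size_m raster resolution (m).
#' @param n_plots number of sampling plots (each centered on a canopy).
#' @param transects_per_plot transects per plot (laid N/E/S/W; at most 4).
#' @param transect_length_m transect length from the canopy edge (m).
#' @param plants_per_transect_mean,plants_per_transect_sd Gaussian count
#'   model for plants per transect.
#' @param n_canopies total invader canopies on the landscape.
#' @param canopy_area_range_m2 min and max canopy area (m^2), sampled
#'   log-uniformly.
#' @param noise_sd_permil residual SD of observed d15N (permil).
#' @param intercept_permil overall d15N level (permil).
#' @param plot_re_sd_permil,transect_re_sd_permil SDs of the nested random
#'   intercepts (permil).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param dem_params list of DEM shape parameters (ridge amplitude,
#'   wavelength and orientation for two superposed dune ridge systems, plus
#'   amplitude and correlation length of a smooth random field).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(extent_m = c(600, 600), cell_size_m = 1,
                       n_plots = 8, transects_per_plot = 4,
                       transect_length_m = 20,
                       plants_per_transect_mean = 13,
                       plants_per_transect_sd = 3,
                       n_canopies = 20,
                       canopy_area_range_m2 = c(8.3, 564.7),
                       noise_sd_permil = 1.8,
                       intercept_permil = -5.84,
                       plot_re_sd_permil = 0.8,
                       transect_re_sd_permil = 0.6,
                       seed = 1,
                       dem_params = list(base = 10,
                                         ridge_amp = 3, ridge_wavelength = 120,
                                         ridge_angle_deg = 20,
                                         ridge2_amp = 1.2, ridge2_wavelength = 45,
                                         ridge2_angle_deg = 75,
                                         noise_amp = 0.8, noise_corr_m = 25)) {
  if (any(!is.finite(extent_m)) || any(extent_m <= 0) || cell_size_m <= 0)
    stop("configuration error: extent and cell size must be positive")
  if (canopy_area_range_m2[1] <= 6)
    stop("configuration error: minimum canopy area must exceed 6 m^2")
  sds <- c(plants_per_transect_sd, noise_sd_permil, plot_re_sd_permil,
           transect_re_sd_permil)
  if (any(sds < 0)) stop("configuration error: SDs must be >= 0")
  cfg <- list(extent_m = extent_m, cell_size_m = cell_size_m,
              n_plots = n_plots, transects_per_plot = transects_per_plot,
              transect_length_m = transect_length_m,
              plants_per_transect_mean = plants_per_transect_mean,
              plants_per_transect_sd = plants_per_transect_sd,
              n_canopies = n_canopies,
              canopy_area_range_m2 = canopy_area_range_m2,
              noise_sd_permil = noise_sd_permil,
              intercept_permil = intercept_permil,
              plot_re_sd_permil = plot_re_sd_permil,
              transect_re_sd_permil = transect_re_sd_permil,
              seed = as.integer(seed), dem_params = dem_params)
  class(cfg) <- "sim_config"
  ## plots sit on a jittered grid with a 130 m margin (plants must stay
  ## >= 100 m from the raster edge) and >= 50 m separation
  pg <- plot_grid(cfg)
  if (is.null(pg))
    stop("configuration error: extent too small to hold all plots with a 100 m margin")
  cfg
}

## plot-center grid; NULL when the extent cannot host it
plot_grid <- function(config) {
  margin <- 130
  g <- ceiling(sqrt(config$n_plots))
  interior <- config$extent_m - 2 * margin
  if (any(interior < 0)) return(NULL)
  if (g > 1 && any(interior / (g - 1) < 50)) return(NULL)
  xs <- if (g == 1) margin + interior[1] / 2 else seq(margin, config$extent_m[1] - margin, length.out = g)
  ys <- if (g == 1) margin + interior[2] / 2 else seq(margin, config$extent_m[2] - margin, length.out = g)
  centers <- expand.grid(x = xs, y = ys)
  centers[seq_len(config$n_plots), , drop = FALSE]
}

## deterministic per-stage child seeds (kept below 2^31)
stage_seed <- function(config, stage) {
  stages <- c(dem = 1L, canopies = 2L, cover = 3L, sampling = 4L,
              response = 5L, validate = 6L)
  i <- stages[[stage]]
  as.integer((as.numeric(config$seed) * 48271 + i * 1299709) %% 2147483629 + 1)
}

## smooth, unit-variance Gaussian random field via FFT convolution of white
## noise with a Gaussian kernel (correlation length in cells)
gaussian_field <- function(nr, nc, corr_cells) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_cells < 1) return(w)
  s <- corr_cells / 2
  r <- ceiling(3 * s)
  off <- seq.int(-r, r)
  k <- exp(-outer(off^2, off^2, `+`) / (2 * s^2))
  f <- conv2d_same(w, k / sum(k))
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic dune DEM
#'
#' Superposes two anisotropic sinusoidal ridge systems (primary dune ridges
#' plus a secondary oblique system) and a low-frequency correlated random
#' field on a constant base level. Purely deterministic given the config
#' seed; produces no nodata cells.
#'
#' @param config a [sim_config].
#' @return A [raster_grid] of elevations (m).
#' @export
generate_dem <- function(config) {
  p <- config$dem_params
  cs <- config$cell_size_m
  nc <- as.integer(round(config$extent_m[1] / cs))
  nr <- as.integer(round(config$extent_m[2] / cs))
  if (nr < 1 || nc < 1) stop("configuration error: non-positive extent")
  set.seed(stage_seed(config, "dem"))
  x <- (seq_len(nc) - 0.5) * cs
  y <- ((nr - seq_len(nr)) + 0.5) * cs
  z <- matrix(p$base, nr, nc)
  add_ridges <- function(z, amp, wl, ang_deg) {
    if (amp == 0) return(z)
    th <- ang_deg * pi / 180
    ph <- stats::runif(1, 0, 2 * pi)
    proj <- outer(y * sin(th), x * cos(th), `+`)
    z + amp * sin(2 * pi * proj / wl + ph)
  }
  z <- add_ridges(z, p$ridge_amp, p$ridge_wavelength, p$ridge_angle_deg)
  z <- add_ridges(z, p$ridge2_amp, p$ridge2_wavelength, p$ridge2_angle_deg)
  if (p$noise_amp > 0)
    z <- z + p$noise_amp * gaussian_field(nr, nc, p$noise_corr_m / cs)
  raster_grid(z, cs, 0, 0)
}

## build one elliptical canopy polygon of exact target area
make_ellipse_canopy <- function(id, cx, cy, area, aspect, angle, n_vert = 48L) {
  a <- sqrt(area / (pi * aspect))
  b <- a * aspect
  ## regular n-gon inscribed in the ellipse underestimates the area; rescale
  shape_factor <- (n_vert / (2 * pi)) * sin(2 * pi / n_vert)
  sc <- 1 / sqrt(shape_factor)
  a <- a * sc; b <- b * sc
  t <- seq(0, 2 * pi, length.out = n_vert + 1L)[-(n_vert + 1L)]
  ex <- a * cos(t); ey <- b * sin(t)
  xy <- cbind(cx + ex * cos(angle) - ey * sin(angle),
              cy + ex * sin(angle) + ey * cos(angle))
  list(id = id, area_m2 = area, center = c(cx, cy),
       a = a, b = b, angle = angle, xy = xy)
}

#' Generate invader canopy polygons
#'
#' The first `n_plots` canopies ("central" canopies, one per plot) sit on the
#' plot grid with areas drawn by stratified log-uniform sampling so the full
#' area range is represented; remaining canopies are placed uniformly at
#' random with log-uniform areas. Polygons are 48-vertex ellipses whose
#' shoelace area equals the sampled area.
#'
#' @param config a [sim_config].
#' @param dem DEM raster (used only to check the extent).
#' @return A list of class `canopy_set`.
#' @export
generate_canopies <- function(config, dem) {
  n <- config$n_canopies
  if (n < 1) stop("n_canopies must be >= 1")
  rng <- config$canopy_area_range_m2
  if (prod(config$extent_m) < 4 * n * mean(rng))
    stop("generation error: extent too small to place canopies without overlap")
  set.seed(stage_seed(config, "canopies"))
  la <- log(rng)
  n_central <- min(config$n_plots, n)
  areas <- numeric(n)
  if (diff(la) < 1e-12) {
    areas[] <- rng[1]
  } else {
    strata <- seq(la[1], la[2], length.out = n_central + 1L)
    areas[seq_len(n_central)] <- exp(strata[-length(strata)] +
                                       stats::runif(n_central) * diff(strata))
    if (n > n_central)
      areas[(n_central + 1L):n] <- exp(stats::runif(n - n_central, la[1], la[2]))
  }
  centers <- plot_grid(config)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= n_central) {
      cx <- centers$x[i] + stats::runif(1, -15, 15)
      cy <- centers$y[i] + stats::runif(1, -15, 15)
    } else {
      cx <- stats::runif(1, 40, config$extent_m[1] - 40)
      cy <- stats::runif(1, 40, config$extent_m[2] - 40)
    }
    out[[i]] <- make_ellipse_canopy(i, cx, cy, areas[i],
                                    aspect = stats::runif(1, 0.5, 0.95),
                                    angle = stats::runif(1, 0, pi))
  }
  structure(list(canopies = out), class = "canopy_set")
}

#' @export
print.canopy_set <- function(x, ...) {
  ar <- canopy_areas(x)
  cat(sprintf("<canopy_set> %d canopies, areas %.1f-%.1f m^2\n",
              length(x$canopies), min(ar), max(ar)))
  invisible(x)
}

#' Canopy areas
#' @param canopies a `canopy_set`.
#' @return Numeric vector of polygon areas (m^2), named by canopy id.
#' @export
canopy_areas <- function(canopies) {
  vapply(canopies$canopies, function(k) k$area_m2, 0,
         USE.NAMES = FALSE) -> a
  names(a) <- vapply(canopies$canopies, function(k) as.character(k$id), "")
  a
}

#' Generate a vegetation cover raster
#'
#' A spatially autocorrelated percent-cover field: a smooth Gaussian random
#' field mapped linearly to percent and clamped to [0, 100], which leaves
#' bare-sand patches (exact 0) and occasional very dense patches (>= 90
#' percent), as observed in coastal dune mosaics. Cells under canopy
#' footprints are forced to 100 percent.
#'
#' @param config a [sim_config].
#' @param canopies a `canopy_set`.
#' @param template raster geometry to generate on (usually the DEM).
#' @return A [raster_grid] of cover in percent.
#' @export
generate_cover <- function(config, canopies, template) {
  set.seed(stage_seed(config, "cover"))
  nr <- nrow(template$values); nc <- ncol(template$values)
  f <- gaussian_field(nr, nc, 15 / template$cell_size)
  cover <- pmin(pmax(30 + 28 * f, 0), 100)
  lab <- canopy_label_matrix(canopies, template)
  cover[lab > 0L] <- 100
  grid_like(template, cover)
}

## ellipse radius from the center along direction `phi` (radians)
ellipse_radius <- function(canopy, phi) {
  rel <- phi - canopy$angle
  1 / sqrt((cos(rel) / canopy$a)^2 + (sin(rel) / canopy$b)^2)
}

#' Lay out plots, transects and plant locations
#'
#' Each plot is centered on one central canopy; four transects run from the
#' canopy edge outward in the cardinal directions (N/E/S/W) for
#' `transect_length_m`, with plants at jittered regular spacing. Transects
#' that would leave the landscape are truncated with a warning.
#'
#' @param config a [sim_config].
#' @param canopies a `canopy_set` (first `n_plots` canopies are the plot
#'   centers; all must exceed 6 m^2).
#' @return A data.frame with columns `plant_id, plot_id, transect_id, x, y,
#'   azimuth_deg, dist_along_m`.
#' @export
layout_sampling <- function(config, canopies) {
  ks <- canopies$canopies
  if (length(ks) < config$n_plots)
    stop("need at least n_plots canopies")
  central <- ks[seq_len(config$n_plots)]
  if (any(vapply(central, function(k) k$area_m2, 0) <= 6))
    stop("plot-center canopies must be larger than 6 m^2")
  set.seed(stage_seed(config, "sampling"))
  dirs <- c(N = 90, E = 0, S = 270, W = 180)[seq_len(config$transects_per_plot)]
  ext <- config$extent_m
  rows <- list()
  n_trunc <- 0L
  pid <- 0L
  for (p in seq_along(central)) {
    k <- central[[p]]
    for (d in seq_along(dirs)) {
      az <- dirs[d] * pi / 180
      dvec <- c(cos(az), sin(az))
      r0 <- ellipse_radius(k, az)
      start <- k$center + r0 * dvec
      n_pl <- max(3L, as.integer(round(stats::rnorm(
        1, config$plants_per_transect_mean, config$plants_per_transect_sd))))
      L <- config$transect_length_m
      spacing <- L / n_pl
      dd <- (seq_len(n_pl) - 0.5) * spacing +
        stats::runif(n_pl, -0.3, 0.3) * spacing
      dd <- pmin(pmax(dd, 0), L)
      px <- start[1] + dd * dvec[1]
      py <- start[2] + dd * dvec[2]
      keep <- px > 1 & px < ext[1] - 1 & py > 1 & py < ext[2] - 1
      if (!all(keep)) n_trunc <- n_trunc + 1L
      if (!any(keep)) next
      idx <- which(keep)
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = pid + seq_along(idx),
        plot_id = sprintf("p%02d", p),
        transect_id = sprintf("p%02d_%s", p, names(dirs)[d]),
        x = px[idx], y = py[idx],
        azimuth_deg = dirs[[d]], dist_along_m = dd[idx])
      pid <- pid + length(idx)
    }
  }
  if (n_trunc > 0L)
    warning(sprintf("%d transect(s) truncated at the landscape edge", n_trunc))
  do.call(rbind, rows)
}

#' Truth model for the synthetic d15N response
#'
#' Defines the component effect shapes and magnitudes used to simulate
#' foliar d15N: a ~3 permil enrichment next to the canopy decaying to zero
#' by `dist_range` (8 m); a ~2 permil enrichment for plants downslope of the
#' canopy; up to ~1 permil near the largest canopies; a monotone cover
#' effect spanning ~5 permil; a linear TWI decrease spanning ~4 permil; and
#' landform offsets with valleys/drainages highest and plains lowest. Cover
#' and TWI components are expressed relative to the realized covariate range
#' and are instantiated by [calibrate_truth].
#'
#' @param dist_span,elev_span,area_span,cover_span,twi_span component spans
#'   in permil (max minus min over the relevant covariate range).
#' @param dist_range distance (m) beyond which the canopy effect is exactly 0.
#' @param landform_offsets named numeric offsets (permil) per landform class.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(dist_span = 3, elev_span = 2, area_span = 1,
                        cover_span = 5, twi_span = 4, dist_range = 8,
                        landform_offsets = c(ridge = -0.2, slope = 0,
                                             plain = -0.4, drainage = 0.6,
                                             valley = 0.8)) {
  tr <- list(
    dist_span = dist_span, elev_span = elev_span, area_span = area_span,
    cover_span = cover_span, twi_span = twi_span, dist_range = dist_range,
    landform_offsets = landform_offsets,
    f_dist = function(d) ifelse(d < dist_range,
                                dist_span * (1 + cos(pi * d / dist_range)) / 2,
                                0),
    f_elev = function(e) elev_span * stats::plogis(-(e + 0.3) / 0.4),
    f_logarea = function(la) area_span * stats::plogis((la - 5.5) / 0.4),
    f_logcover = NULL, f_twi = NULL, calibrated = FALSE)
  class(tr) <- "truth_model"
  tr
}

#' Instantiate range-relative truth components
#'
#' The cover and TWI components are defined by their span over the realized
#' covariate distribution; this fixes their slopes from the sampled plants'
#' covariate ranges.
#'
#' @param truth a [truth_model].
#' @param table model table with `log_cover` and `twi` columns.
#' @return The truth model with `f_logcover` and `f_twi` closures set.
#' @export
calibrate_truth <- function(truth, table) {
  lc_r <- range(table$log_cover, na.rm = TRUE)
  tw_r <- range(table$twi, na.rm = TRUE)
  lc_slope <- if (diff(lc_r) > 1e-9) truth$cover_span / diff(lc_r) else 0
  tw_slope <- if (diff(tw_r) > 1e-9) -truth$twi_span / diff(tw_r) else 0
  lc_mid <- mean(lc_r); tw_mid <- mean(tw_r)
  truth$f_logcover <- function(lc) lc_slope * (lc - lc_mid)
  truth$f_twi <- function(t) tw_slope * (t - tw_mid)
  truth$calibrated <- TRUE
  truth
}

## raw (uncentered) component matrix at the rows of a model table
truth_components <- function(truth, table) {
  if (!truth$calibrated) stop("truth model not calibrated; see calibrate_truth()")
  off <- truth$landform_offsets[as.character(table$landform)]
  off[is.na(off)] <- 0
  cbind(dist = truth$f_dist(table$dist_ac),
        elev = truth$f_elev(table$elev_ac),
        area = truth$f_logarea(table$log_area_ac),
        cover = truth$f_logcover(table$log_cover),
        twi = truth$f_twi(table$twi),
        landform = unname(off))
}

#' Simulate observed d15N for sampled plants
#'
#' Observed d15N = intercept + sum of mean-centered truth components +
#' plot random intercept + transect random intercept + iid Gaussian noise.
#' Each component is centered over the sampled covariate distribution so
#' the intercept carries the overall level. Realized random effects and all
#' component values are stored for recovery testing.
#'
#' @param table model table (see [extract_at_points]) with predictor values
#'   for every plant.
#' @param truth a calibrated [truth_model].
#' @param config a [sim_config].
#' @return The table with columns `comp_*`, `b_plot`, `b_transect`, `eps`,
#'   `d15n_true` (fixed part) and `d15n_obs` added.
#' @export
generate_delta15n <- function(table, truth, config) {
  pred_cols <- c("dist_ac", "elev_ac", "log_area_ac", "log_cover", "twi",
                 "landform")
  miss <- !stats::complete.cases(table[pred_cols])
  if (any(miss))
    stop(sprintf("missing predictor values for plant(s): %s",
                 paste(table$plant_id[miss], collapse = ", ")))
  set.seed(stage_seed(config, "response"))
  comp <- truth_components(truth, table)
  comp <- sweep(comp, 2, colMeans(comp))
  plots <- unique(table$plot_id)
  transects <- unique(table$transect_id)
  b_p <- stats::rnorm(length(plots), 0, config$plot_re_sd_permil)
  b_t <- stats::rnorm(length(transects), 0, config$transect_re_sd_permil)
  names(b_p) <- plots; names(b_t) <- transects
  eps <- stats::rnorm(nrow(table), 0, config$noise_sd_permil)
  fixed <- config$intercept_permil + rowSums(comp)
  out <- table
  colnames(comp) <- paste0("comp_", colnames(comp))
  out <- cbind(out, as.data.frame(comp))
  out$b_plot <- unname(b_p[out$plot_id])
  out$b_transect <- unname(b_t[out$transect_id])
  out$eps <- eps
  out$d15n_true <- fixed
  out$d15n_obs <- fixed + out$b_plot + out$b_transect + eps
  out
}

#' Simulate a complete scenario
#'
#' Runs the full generative chain: DEM, terrain layers, canopies, cover,
#' sampling layout, predictor stack, extraction at plants, truth calibration
#' and the d15N response. Every stage derives its own seed from
#' `config$seed`, so the result is a pure function of `(config, truth)`.
#'
#' @param config a [sim_config].
#' @param truth a [truth_model] (calibrated internally).
#' @return A list of class `scenario` with elements `dem`, `cover`,
#'   `canopies`, `terrain`, `stack`, `plants` (the model table with truth
#'   columns), `truth`, `config`.
#' @export
simulate_scenario <- function(config = sim_config(), truth = truth_model()) {
  dem <- generate_dem(config)
  terr <- terrain_stack(dem)
  canopies <- generate_canopies(config, dem)
  cover <- generate_cover(config, canopies, dem)
  plants <- layout_sampling(config, canopies)
  stack <- build_predictor_stack(dem, cover, canopies, terrain = terr)
  table <- extract_at_points(stack, plants)
  truth <- calibrate_truth(truth, table)
  table <- generate_delta15n(table, truth, config)
  structure(list(dem = dem, cover = cover, canopies = canopies,
                 terrain = terr, stack = stack, plants = table,
                 truth = truth, config = config),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %dx%d m, %d canopies, %d plants, d15N [%.1f, %.1f]\n",
              x$config$extent_m[1], x$config$extent_m[2],
              length(x$canopies$canopies), nrow(x$plants),
              min(x$plants$d15n_obs), max(x$plants$d15n_obs)))
  invisible(x)
}

#' Write a scenario to plain-text files
#'
#' DEM and cover as ESRI ASCII grids, canopies as GeoJSON polygons with
#' `id` and `area_m2` properties, plants as CSV and GeoJSON points.
#'
#' @param scenario a `scenario`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ascii_grid(scenario$dem, file.path(dir, "dem.asc"))
  write_ascii_grid(scenario$cover, file.path(dir, "cover.asc"))
  write_canopies_geojson(scenario$canopies, file.path(dir, "canopies.geojson"))
  pl <- scenario$plants
  utils::write.csv(pl, file.path(dir, "plants.csv"), row.names = FALSE)
  feats <- lapply(seq_len(nrow(pl)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(pl$x[i], pl$y[i])),
    properties = list(plant_id = pl$plant_id[i], plot_id = pl$plot_id[i],
                      transect_id = pl$transect_id[i],
                      d15n_obs = pl$d15n_obs[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "plants.geojson"), auto_unbox = TRUE,
                       digits = 8)
  invisible(dir)
}

#' Write canopies as GeoJSON
#' @param canopies a `canopy_set`.
#' @param path output file.
#' @export
write_canopies_geojson <- function(canopies, path) {
  feats <- lapply(canopies$canopies, function(k) {
    ring <- rbind(k$xy, k$xy[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(id = k$id, area_m2 = k$area_m2))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Read canopies from GeoJSON
#' @param path GeoJSON file written by [write_canopies_geojson] (or any
#'   FeatureCollection of polygons with `id` and `area_m2` properties).
#' @return A `canopy_set`.
#' @export
read_canopies_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  ks <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    xy <- xy[-nrow(xy), , drop = FALSE]
    list(id = f$properties$id, area_m2 = f$properties$area_m2,
         center = colMeans(xy), a = NA_real_, b = NA_real_,
         angle = NA_real_, xy = xy)
  })
  structure(list(canopies = ks), class = "canopy_set")
}
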