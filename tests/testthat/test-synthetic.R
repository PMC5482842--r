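test_that("config invariants are enforced", {
  expect_error(sim_config(extent_m = c(-1, 100)), "configuration error")
  expect_error(sim_config(canopy_area_range_m2 = c(5, 100)), "6 m")
  expect_error(sim_config(noise_sd_permil = -1), "SDs")
  expect_error(sim_config(extent_m = c(250, 250)), "margin")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config(seed = 9)
  d1 <- generate_dem(cfg); d2 <- generate_dem(cfg)
  expect_identical(d1$values, d2$values)
  k1 <- generate_canopies(cfg, d1); k2 <- generate_canopies(cfg, d1)
  expect_identical(canopy_areas(k1), canopy_areas(k2))
  c1 <- generate_cover(cfg, k1, d1); c2 <- generate_cover(cfg, k1, d1)
  expect_identical(c1$values, c2$values)
  p1 <- layout_sampling(cfg, k1); p2 <- layout_sampling(cfg, k1)
  expect_identical(p1, p2)
  ## different seed changes the landscape
  expect_false(identical(generate_dem(small_config(seed = 10))$values,
                         d1$values))
})

test_that("DEM has dune structure; zero amplitudes give a constant plane", {
  cfg <- small_config(seed = 3)
  dem <- generate_dem(cfg)
  expect_false(anyNA(dem$values))
  sl <- terrain_slope(dem)$values
  interior <- sl[2:(nrow(sl) - 1), 2:(ncol(sl) - 1)]
  expect_gt(mean(interior > 1e-6), 0.5)

  flat_cfg <- small_config(seed = 3)
  flat_cfg$dem_params[c("ridge_amp", "ridge2_amp", "noise_amp")] <- 0
  flat <- generate_dem(flat_cfg)
  expect_equal(max(flat$values) - min(flat$values), 0)
})

test_that("canopy areas respect the configured range and the polygon", {
  cfg <- small_config(seed = 4)
  dem <- generate_dem(cfg)
  ks <- generate_canopies(cfg, dem)
  ar <- canopy_areas(ks)
  expect_true(all(ar >= 8.3 - 1e-9 & ar <= 564.7 + 1e-9))
  ## stated area equals shoelace polygon area within 1%
  for (k in ks$canopies) {
    poly_area <- nitroscape:::polygon_area(k$xy)
    expect_lt(abs(poly_area - k$area_m2) / k$area_m2, 0.01)
  }
  ## degenerate range
  deg <- small_config(seed = 4)
  deg$canopy_area_range_m2 <- c(10, 10)
  kd <- generate_canopies(deg, dem)
  expect_true(all(abs(canopy_areas(kd) - 10) <= 0.1))
})

test_that("rasterized footprints approximate polygon areas", {
  cfg <- small_config(seed = 5)
  dem <- generate_dem(cfg)
  ks <- generate_canopies(cfg, dem)
  lab <- nitroscape:::canopy_label_matrix(ks, dem)
  for (k in ks$canopies) {
    if (k$area_m2 < 25) next
    ncells <- sum(lab == k$id)
    expect_lt(abs(ncells * dem$cell_size^2 - k$area_m2) / k$area_m2, 0.15)
  }
})

test_that("cover is patchy, bounded and forced to 100 under canopies", {
  cfg <- small_config(seed = 6)
  dem <- generate_dem(cfg)
  ks <- generate_canopies(cfg, dem)
  cov <- generate_cover(cfg, ks, dem)
  v <- cov$values
  expect_equal(min(v), 0)
  expect_gte(max(v), 90)
  expect_gt(mean(v == 0), 0.01)
  lab <- nitroscape:::canopy_label_matrix(ks, dem)
  expect_true(all(v[lab > 0] == 100))
})

test_that("sampling layout follows the plot/transect design", {
  cfg <- sim_config(seed = 11)  # default: 8 plots x 4 transects x ~13
  dem <- generate_dem(cfg)
  ks <- generate_canopies(cfg, dem)
  pl <- layout_sampling(cfg, ks)
  expect_gte(nrow(pl), 400)
  expect_lte(nrow(pl), 500)
  expect_true(all(pl$azimuth_deg %in% c(0, 90, 180, 270)))
  ## strict nesting: each transect id belongs to exactly one plot
  nest <- unique(pl[, c("plot_id", "transect_id")])
  expect_false(any(duplicated(nest$transect_id)))
  expect_equal(length(unique(pl$plot_id)), 8)
  ## plants stay inside the landscape
  expect_true(all(pl$x > 0 & pl$x < cfg$extent_m[1] &
                    pl$y > 0 & pl$y < cfg$extent_m[2]))
})

test_that("zero-length transects put all plants at the canopy edge", {
  cfg <- small_config(seed = 7)
  cfg$transect_length_m <- 0
  dem <- generate_dem(cfg)
  ks <- generate_canopies(cfg, dem)
  pl <- layout_sampling(cfg, ks)
  expect_true(all(pl$dist_along_m == 0))
})

test_that("d15N composition: pure intercept under a null truth", {
  tab <- data.frame(plant_id = 1:6, plot_id = rep(c("p1", "p2"), each = 3),
                    transect_id = rep(c("p1_N", "p2_N"), each = 3),
                    dist_ac = c(0, 3, 10, 1, 2, 6), elev_ac = 0,
                    log_area_ac = 3, log_cover = c(0, 1, 2, 3, 2, 1),
                    twi = c(4, 5, 6, 7, 5, 4),
                    landform = factor("slope",
                                      levels = names(landform_legend())))
  cfg <- small_config(seed = 2)
  cfg$noise_sd_permil <- 0
  cfg$plot_re_sd_permil <- 0
  cfg$transect_re_sd_permil <- 0
  null_truth <- truth_model(dist_span = 0, elev_span = 0, area_span = 0,
                            cover_span = 0, twi_span = 0,
                            landform_offsets = c(ridge = 0, slope = 0,
                                                 plain = 0, drainage = 0,
                                                 valley = 0))
  null_truth <- calibrate_truth(null_truth, tab)
  out <- generate_delta15n(tab, null_truth, cfg)
  expect_equal(out$d15n_obs, rep(-5.84, 6), tolerance = 1e-12)
})

test_that("random intercepts are shared within groups", {
  scen <- default_scenario()
  tab <- scen$plants
  by_tr <- tapply(tab$b_transect, tab$transect_id, function(v)
    length(unique(v)))
  expect_true(all(by_tr == 1))
  by_pl <- tapply(tab$b_plot, tab$plot_id, function(v) length(unique(v)))
  expect_true(all(by_pl == 1))
})

test_that("missing predictors are an explicit error", {
  scen <- default_scenario()
  tab <- scen$plants[1:10, ]
  tab$twi[3] <- NA
  expect_error(generate_delta15n(tab, scen$truth, scen$config),
               "missing predictor")
})

test_that("default scenario matches the stated statistical world", {
  scen <- default_scenario()
  tab <- scen$plants
  ## marginal spread of the response
  expect_gt(sd(tab$d15n_obs), 2)
  expect_lt(sd(tab$d15n_obs), 4)
  ## >= 95% of values inside the observed field range plus a 2 permil guard
  expect_gte(mean(tab$d15n_obs >= -15.2 & tab$d15n_obs <= 3.1), 0.95)
  ## component spans within 30% of their nominal magnitudes (3, 1, 5, 4)
  spans <- c(dist = 3, area = 1, cover = 5, twi = 4)
  for (nm in names(spans)) {
    realized <- diff(range(tab[[paste0("comp_", nm)]]))
    expect_gt(realized, 0.7 * spans[[nm]])
    expect_lt(realized, 1.3 * spans[[nm]])
  }
  ## distance component vanishes beyond 8 m
  far <- tab$dist_ac >= 8
  expect_true(any(far))
  expect_equal(var(tab$comp_dist[far]), 0, tolerance = 1e-12)
})

test_that("scenario files round-trip through plain-text formats", {
  scen <- default_scenario()
  dir <- withr::local_tempdir()
  write_scenario(scen, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "dem.asc", "cover.asc", "canopies.geojson", "plants.csv",
    "plants.geojson")))))
  ks <- read_canopies_geojson(file.path(dir, "canopies.geojson"))
  expect_equal(length(ks$canopies), length(scen$canopies$canopies))
  expect_equal(canopy_areas(ks), canopy_areas(scen$canopies),
               tolerance = 1e-6)
  dem2 <- read_ascii_grid(file.path(dir, "dem.asc"))
  expect_equal(dem2$values, scen$dem$values, tolerance = 1e-5)
})
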