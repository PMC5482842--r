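test_that("canopy filtering is strictly greater-than by default", {
  k6 <- square_canopy(2, 30, 10, sqrt(6))
  k6$area_m2 <- 6                                       # exactly on boundary
  ks <- canopy_set_of(square_canopy(1, 10, 10, 2),      # 4 m^2
                      k6,
                      square_canopy(3, 50, 10, sqrt(8.3)))
  kept <- filter_canopies(ks)
  expect_equal(vapply(kept$canopies, function(k) k$id, 0L), 3L)
  ## inclusive variant keeps the boundary canopy
  expect_equal(length(filter_canopies(ks, strict = FALSE)$canopies), 2L)
  big <- canopy_set_of(square_canopy(1, 10, 10, 4), square_canopy(2, 30, 30, 5))
  expect_equal(length(filter_canopies(big)$canopies), 2L)
  expect_error(filter_canopies(canopy_set_of()), "empty")
  expect_error(filter_canopies(canopy_set_of(square_canopy(1, 5, 5, 1))),
               "no qualifying")
})

test_that("distance raster: trivial geometry", {
  tpl <- raster_grid(matrix(0, 9, 9))
  ## single cell footprint at cell center (4.5, 4.5)
  ks <- canopy_set_of(square_canopy(1, 4.5, 4.5, 1))
  d <- distance_to_canopy(ks, tpl)
  rc <- nitroscape:::point_to_cell(tpl, 4.5, 4.5)
  expect_equal(d$values[rc$row, rc$col], 0)
  expect_equal(d$values[rc$row, rc$col + 3L], 3)
  expect_equal(d$values[rc$row + 1L, rc$col + 1L], sqrt(2))
})

test_that("distance raster equals the all-pairs oracle exactly", {
  tpl <- raster_grid(matrix(0, 50, 50))
  set.seed(12)
  ks <- canopy_set_of(square_canopy(1, 8.3, 11.2, 4.1),
                      square_canopy(2, 31.5, 7.9, 6.4),
                      square_canopy(3, 24.8, 38.2, 9.7),
                      square_canopy(4, 44.1, 44.6, 3.3))
  d <- distance_to_canopy(ks, tpl)
  lab <- nitroscape:::canopy_label_matrix(ks, tpl)
  expect_identical(d$values, oracle_distance(lab))
  ## 1-Lipschitz: neighbouring cells differ by at most the cell distance
  expect_true(all(abs(diff(d$values)) <= 1 + 1e-12))
  expect_true(all(abs(t(diff(t(d$values)))) <= 1 + 1e-12))
})

test_that("nearest-canopy attributes: self-assignment, flat DEM, tie rule", {
  tpl <- raster_grid(matrix(0, 20, 21))
  set.seed(2)
  z <- matrix(rnorm(20 * 21, 10), 20, 21)
  dem <- raster_grid(z)
  ks <- canopy_set_of(square_canopy(1, 4.5, 10.5, 3),
                      square_canopy(2, 16.5, 10.5, 3))
  att <- nearest_canopy_attributes(ks, tpl, dem)
  lab <- nitroscape:::canopy_label_matrix(ks, tpl)
  ## inside canopy 2: its own area and elevation reference
  inside2 <- which(lab == 2L, arr.ind = TRUE)
  expect_true(all(att$area_ac$values[inside2] == 9))
  ref2 <- mean(z[lab == 2L])
  expect_equal(att$elev_ac$values[inside2], z[inside2] - ref2,
               tolerance = 1e-12)
  ## flat DEM: relative elevation is zero everywhere
  att0 <- nearest_canopy_attributes(ks, tpl, raster_grid(matrix(5, 20, 21)))
  expect_true(all(abs(att0$elev_ac$values) < 1e-12))
  ## exact midpoint column is equidistant: lowest id wins
  mid <- nitroscape:::point_to_cell(tpl, 10.5, 10.5)
  expect_equal(att$id$values[mid$row, mid$col], 1)
})

test_that("cover from classified points follows both conventions", {
  tpl <- raster_grid(matrix(0, 4, 4))
  pts <- data.frame(
    x = c(rep(0.5, 10), rep(1.5, 3), rep(2.5, 4)),
    y = c(rep(3.5, 10), rep(3.5, 3), rep(3.5, 4)),
    class = c(rep("ground", 7), rep("nonground", 3),
              rep("ground", 3), rep("nonground", 4)))
  cov <- cover_from_classified_points(pts, tpl, smooth_radius_cells = 0)
  expect_equal(cov$values[1, 1], 30)        # 3 nonground / 10 total
  expect_equal(cov$values[1, 2], 0)         # ground only
  expect_equal(cov$values[1, 3], 100)       # nonground only
  expect_true(is.na(cov$values[4, 4]))      # no returns
  raw <- cover_from_classified_points(pts, tpl, convention = "ratio",
                                      smooth_radius_cells = 0)
  expect_equal(raw$values[1, 1], 100 * 3 / 7)
  expect_true(is.na(raw$values[1, 3]))      # unbounded ratio undefined
  expect_error(cover_from_classified_points(
    data.frame(x = 1, y = 1, class = "canopy"), tpl), "class")
})

test_that("extraction returns cell values verbatim with log transforms", {
  scen <- default_scenario()
  stack <- scen$stack
  ## a plant exactly at a cell center
  cc <- cell_centers(stack$dist_ac)
  p <- data.frame(plant_id = 1L, plot_id = "p01", transect_id = "p01_N",
                  x = cc$x[120], y = cc$y[80])
  tab <- extract_at_points(stack, p)
  expect_equal(tab$dist_ac, stack$dist_ac$values[80, 120])
  expect_equal(tab$twi, stack$twi$values[80, 120])
  expect_equal(tab$log_cover, log(stack$cover$values[80, 120] + 1))
  expect_equal(tab$log_area_ac, log(stack$area_ac$values[80, 120]))
  ## zero cover maps to log_cover 0
  zc <- which(stack$cover$values == 0, arr.ind = TRUE)[1, ]
  p0 <- data.frame(plant_id = 2L, plot_id = "p01", transect_id = "p01_N",
                   x = cc$x[zc[2]], y = cc$y[zc[1]])
  expect_equal(extract_at_points(stack, p0)$log_cover, 0)
  ## outside plants raise a named error
  pbad <- data.frame(plant_id = 99L, plot_id = "p01", transect_id = "p01_N",
                     x = -5, y = 10)
  expect_error(extract_at_points(stack, pbad), "99")
})

test_that("extraction is idempotent and order-independent", {
  scen <- default_scenario()
  pl <- scen$plants[1:30, c("plant_id", "plot_id", "transect_id", "x", "y")]
  a <- extract_at_points(scen$stack, pl)
  b <- extract_at_points(scen$stack, pl[30:1, ])
  b <- b[order(b$plant_id), ]
  rownames(b) <- NULL
  expect_equal(a[order(a$plant_id), "twi"], b$twi)
  expect_equal(extract_at_points(scen$stack, pl)$dist_ac, a$dist_ac)
})

test_that("full scenario yields a complete 400+ row model table", {
  scen <- default_scenario()
  tab <- scen$plants
  need <- c("dist_ac", "log_area_ac", "elev_ac", "log_cover", "twi",
            "landform")
  expect_gte(nrow(tab), 400)
  expect_false(any(is.na(tab[need])))
  ## dist_ac is 0 exactly on footprint cells, positive elsewhere
  expect_true(all(tab$dist_ac >= 0))
})
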