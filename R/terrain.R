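#' Circular mean filter
#'
#' Replaces each cell by the mean of all cells whose center lies within
#' `radius_cells` cell widths of it (the cell itself included). Windows are
#' clipped at the grid edge; nodata cells are excluded from the mean and
#' remain nodata.
#'
#' @param grid a [raster_grid].
#' @param radius_cells non-negative filter radius, in cells.
#' @return A smoothed `raster_grid`.
#' @export
mean_filter_circular <- function(grid, radius_cells) {
  if (!is.finite(radius_cells) || radius_cells < 0)
    stop("radius_cells must be >= 0")
  if (radius_cells < 1) return(grid)
  focal_mean_kernel(grid, disk_kernel(radius_cells))
}

#' Local slope (tan beta)
#'
#' Dimensionless slope from central finite differences on cell-center
#' elevations (the Zevenbergen-Thorne stencil); border rows/columns use
#' one-sided differences. Cells with nodata anywhere in their stencil are
#' nodata.
#'
#' @param dem a [raster_grid] of elevations (m).
#' @return A `raster_grid` of tan(beta) >= 0.
#' @export
terrain_slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must have at least 3 x 3 cells")
  cs <- dem$cell_size
  zx <- matrix(NA_real_, nr, nc)
  zy <- matrix(NA_real_, nr, nc)
  zx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * cs)
  zx[, 1] <- (z[, 2] - z[, 1]) / cs
  zx[, nc] <- (z[, nc] - z[, nc - 1]) / cs
  ## row index grows southward, so z decreasing with row = positive dz/dy
  zy[2:(nr - 1), ] <- (z[1:(nr - 2), ] - z[3:nr, ]) / (2 * cs)
  zy[1, ] <- (z[1, ] - z[2, ]) / cs
  zy[nr, ] <- (z[nr - 1, ] - z[nr, ]) / cs
  grid_like(dem, sqrt(zx^2 + zy^2))
}

#' Multiple-flow-direction flow accumulation
#'
#' Contributing area (m^2) per cell. Each cell starts with its own area;
#' cells are visited in order of decreasing elevation and pass their total
#' accumulated area to all strictly lower 8-neighbours, with weights
#' proportional to (elevation drop / distance)^exponent. Flats and pits keep
#' their accumulation (no routing out). Ties in elevation are broken by cell
#' index, making the result deterministic.
#'
#' @param dem a [raster_grid]; must be free of nodata holes in the region of
#'   interest.
#' @param exponent flow-partition convergence exponent (default 1.1).
#' @return A `raster_grid` of contributing area in m^2.
#' @export
mfd_flow_accumulation <- function(dem, exponent = 1.1) {
  z <- dem$values
  if (anyNA(z)) stop("DEM contains nodata cells; fill or crop before routing")
  ## descending elevation, ties by linear cell index
  ord <- order(-as.vector(z), seq_along(z)) - 1L
  acc <- mfd_accum_cpp(z, dem$cell_size, exponent, ord)
  grid_like(dem, acc)
}

#' Topographic wetness index
#'
#' TWI = ln(a / tan(beta)) where a is the contributing area per unit contour
#' length (accumulation / cell size). Zero slopes are floored at
#' `slope_epsilon` so flat cells stay finite. The raw index is then smoothed
#' with a circular mean filter (default four-cell radius).
#'
#' @param accum flow accumulation raster (m^2), e.g. from
#'   [mfd_flow_accumulation].
#' @param slope slope raster (tan beta), e.g. from [terrain_slope].
#' @param slope_epsilon floor for tan(beta) (default 0.001).
#' @param smooth_radius_cells radius of the post-hoc mean filter (default 4;
#'   0 disables smoothing).
#' @return A `raster_grid` of TWI values.
#' @export
twi <- function(accum, slope, slope_epsilon = 0.001, smooth_radius_cells = 4) {
  stopifnot_aligned(accum, slope)
  a <- accum$values / accum$cell_size
  if (any(a <= 0, na.rm = TRUE))
    stop("non-positive flow accumulation: conservation violated")
  raw <- log(a / pmax(slope$values, slope_epsilon))
  out <- grid_like(accum, raw)
  if (smooth_radius_cells >= 1) out <- mean_filter_circular(out, smooth_radius_cells)
  out
}

#' Topographic position index
#'
#' Elevation of each cell minus the mean elevation over an annular
#' neighbourhood (inner_radius < distance <= outer_radius, in meters).
#' Positive values are locally high positions, negative locally low. The
#' window is clipped at grid edges. Supply a pre-smoothed DEM (five-cell
#' mean filter is the conventional choice). Set `inner_radius_m = 0` for the
#' filled-window variant.
#'
#' @param dem a [raster_grid] of (smoothed) elevations.
#' @param inner_radius_m,outer_radius_m annulus radii in meters (outer >
#'   inner).
#' @return A `raster_grid` of TPI values (m).
#' @export
tpi <- function(dem, inner_radius_m = 10, outer_radius_m = 100) {
  if (outer_radius_m <= inner_radius_m)
    stop("outer_radius_m must exceed inner_radius_m")
  cs <- dem$cell_size
  k <- annulus_kernel(inner_radius_m / cs, outer_radius_m / cs)
  ann_mean <- focal_mean_kernel(dem, k)
  grid_like(dem, dem$values - ann_mean$values)
}

#' Landform legend
#'
#' @return Named integer vector mapping class names to the codes used by
#'   [classify_landforms].
#' @export
landform_legend <- function() {
  c(ridge = 1L, slope = 2L, plain = 3L, drainage = 4L, valley = 5L)
}

#' Landform classification from TPI and slope
#'
#' TPI is standardized to z-scores over the non-nodata cells, then cells are
#' classed: ridge (z >= 1), valley (z <= -1), drainage (-1 < z <= -0.5),
#' upper mid-slope (0.5 <= z < 1 -> slope class), and for |z| < 0.5 plain or
#' slope depending on whether the local slope is below `slope_threshold_deg`.
#' This collapses the classical ten-class topographic-position scheme to the
#' five classes ridges, slopes, plains, drainages and valleys.
#'
#' @param tpi_grid TPI raster from [tpi].
#' @param slope_grid slope raster (tan beta) co-registered with `tpi_grid`.
#' @param slope_threshold_deg slope (degrees) separating plains from
#'   mid-slopes (default 5).
#' @return A `raster_grid` of integer class codes (see [landform_legend]),
#'   with a `legend` attribute.
#' @export
classify_landforms <- function(tpi_grid, slope_grid, slope_threshold_deg = 5) {
  stopifnot_aligned(tpi_grid, slope_grid)
  leg <- landform_legend()
  t_v <- tpi_grid$values
  s_v <- slope_grid$values
  ok <- !is.na(t_v) & !is.na(s_v)
  thr <- tan(slope_threshold_deg * pi / 180)
  out <- matrix(NA_real_, nrow(t_v), ncol(t_v))
  sd_t <- stats::sd(t_v[ok])
  if (!is.finite(sd_t) || sd_t < 1e-12) {
    warning("TPI has zero variance; classifying by slope only")
    out[ok] <- ifelse(s_v[ok] < thr, leg[["plain"]], leg[["slope"]])
  } else {
    zz <- (t_v - mean(t_v[ok])) / sd_t
    cls <- matrix(NA_real_, nrow(t_v), ncol(t_v))
    steep <- s_v >= thr
    cls[ok & zz >= 1] <- leg[["ridge"]]
    cls[ok & zz <= -1] <- leg[["valley"]]
    cls[ok & zz > -1 & zz <= -0.5] <- leg[["drainage"]]
    cls[ok & zz >= 0.5 & zz < 1] <- leg[["slope"]]
    mid <- ok & abs(zz) < 0.5
    cls[mid & steep] <- leg[["slope"]]
    cls[mid & !steep] <- leg[["plain"]]
    out <- cls
  }
  g <- grid_like(tpi_grid, out)
  attr(g, "legend") <- leg
  g
}

#' All terrain layers from a DEM
#'
#' Convenience wrapper running the standard chain: slope on the raw DEM, MFD
#' accumulation, smoothed TWI, TPI on a five-cell mean-filtered DEM, and the
#' five-class landform map.
#'
#' @param dem a [raster_grid].
#' @param mfd_exponent MFD convergence exponent.
#' @param twi_smooth_radius mean-filter radius (cells) applied to TWI.
#' @param tpi_smooth_radius mean-filter radius (cells) applied to the DEM
#'   before TPI.
#' @param tpi_inner_m,tpi_outer_m TPI annulus radii (m).
#' @param slope_threshold_deg plain/slope threshold for landforms.
#' @return List with `slope`, `accum`, `twi`, `tpi`, `landform` rasters.
#' @export
terrain_stack <- function(dem, mfd_exponent = 1.1, twi_smooth_radius = 4,
                          tpi_smooth_radius = 5, tpi_inner_m = 10,
                          tpi_outer_m = 100, slope_threshold_deg = 5) {
  sl <- terrain_slope(dem)
  acc <- mfd_flow_accumulation(dem, exponent = mfd_exponent)
  wet <- twi(acc, sl, smooth_radius_cells = twi_smooth_radius)
  dem_s <- mean_filter_circular(dem, tpi_smooth_radius)
  tp <- tpi(dem_s, tpi_inner_m, tpi_outer_m)
  lf <- classify_landforms(tp, sl, slope_threshold_deg)
  list(slope = sl, accum = acc, twi = wet, tpi = tp, landform = lf)
}
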