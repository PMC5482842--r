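#' Filter canopies by minimum area
#'
#' Retains canopies strictly larger than `min_area_m2` (default 6 m^2),
#' mirroring the rule that only invader canopies above that size are assumed
#' to influence their neighbourhood.
#'
#' @param canopies a `canopy_set`.
#' @param min_area_m2 area threshold (m^2).
#' @param strict if `TRUE` (default) keep area > threshold, else >=.
#' @return The filtered `canopy_set`.
#' @export
filter_canopies <- function(canopies, min_area_m2 = 6, strict = TRUE) {
  if (length(canopies$canopies) == 0L)
    stop("no qualifying canopies: empty canopy set")
  keep <- vapply(canopies$canopies, function(k)
    if (strict) k$area_m2 > min_area_m2 else k$area_m2 >= min_area_m2, TRUE)
  if (!any(keep)) stop("no qualifying canopies after area filter")
  structure(list(canopies = canopies$canopies[keep]), class = "canopy_set")
}

## integer matrix of canopy ids per cell (0 = no canopy); on overlap the
## lowest id wins
canopy_label_matrix <- function(canopies, template) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  cc <- cell_centers(template)
  lab <- matrix(0L, nr, nc)
  for (k in canopies$canopies) {
    bb_c <- which(cc$x >= min(k$xy[, 1]) - 1 & cc$x <= max(k$xy[, 1]) + 1)
    bb_r <- which(cc$y >= min(k$xy[, 2]) - 1 & cc$y <= max(k$xy[, 2]) + 1)
    if (!length(bb_c) || !length(bb_r)) next
    g <- expand.grid(r = bb_r, c = bb_c)
    inside <- points_in_polygon(cc$x[g$c], cc$y[g$r], k$xy)
    hit <- g[inside & lab[cbind(g$r, g$c)] == 0L, , drop = FALSE]
    lab[cbind(hit$r, hit$c)] <- as.integer(k$id)
  }
  lab
}

#' Rasterized canopy footprints
#'
#' @param canopies a `canopy_set`.
#' @param template raster geometry.
#' @return A [raster_grid] of integer canopy ids (`NA` outside footprints).
#' @export
canopy_footprints <- function(canopies, template) {
  lab <- canopy_label_matrix(canopies, template)
  v <- matrix(NA_real_, nrow(lab), ncol(lab))
  v[lab > 0L] <- lab[lab > 0L]
  grid_like(template, v)
}

## nearest-footprint-cell distance (m) and canopy id per cell; exact on the
## cell lattice, equidistant ties go to the lowest canopy id
nearest_canopy_map <- function(canopies, template) {
  lab <- canopy_label_matrix(canopies, template)
  if (!any(lab > 0L))
    stop("no canopy footprint cells inside the raster extent")
  nr <- nrow(lab); nc <- ncol(lab)
  ## candidate set: footprint cells on the footprint boundary (the nearest
  ## footprint cell of any outside cell is a boundary cell)
  occ <- lab > 0L
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- occ
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  boundary <- occ & !interior
  idx <- which(boundary)
  fr <- (idx - 1L) %% nr
  fc <- (idx - 1L) %/% nr
  fid <- lab[idx]
  o <- order(fid, idx)
  res <- nearest_footprint_cpp(nr, nc, fr[o], fc[o], fid[o])
  dist <- sqrt(res$d2) * template$cell_size
  id <- res$id
  ## cells inside a footprint: distance 0, own canopy
  dist[occ] <- 0
  id[occ] <- lab[occ]
  list(dist = grid_like(template, dist),
       id = grid_like(template, id + 0))
}

#' Distance to the nearest canopy
#'
#' Euclidean distance (m) from each cell center to the nearest canopy
#' footprint cell center; exactly 0 on footprint cells. Apply
#' [filter_canopies] first to restrict to qualifying canopies.
#'
#' @param canopies a (filtered) `canopy_set`.
#' @param grid_template raster geometry.
#' @return A [raster_grid] of distances (m).
#' @export
distance_to_canopy <- function(canopies, grid_template) {
  nearest_canopy_map(canopies, grid_template)$dist
}

#' Area and relative elevation of the nearest canopy
#'
#' For each cell, the nearest canopy is the one owning the nearest footprint
#' cell (ties to the lowest id). `area_ac` is that canopy's polygon area;
#' `elev_ac` is the cell's DEM elevation minus the reference elevation of
#' that canopy (negative: the cell lies below the canopy).
#'
#' @param canopies a (filtered) `canopy_set`.
#' @param grid_template raster geometry.
#' @param dem DEM raster co-registered with the template.
#' @param reference canopy reference elevation rule: mean DEM over the
#'   footprint (default), the footprint's center cell, or its minimum.
#' @return List with `area_ac` and `elev_ac` rasters.
#' @export
nearest_canopy_attributes <- function(canopies, grid_template, dem,
                                      reference = c("mean", "centroid", "min")) {
  reference <- match.arg(reference)
  stopifnot_aligned(grid_template, dem)
  nm <- nearest_canopy_map(canopies, grid_template)
  lab <- canopy_label_matrix(canopies, grid_template)
  ids <- vapply(canopies$canopies, function(k) k$id, 0L)
  areas <- vapply(canopies$canopies, function(k) k$area_m2, 0)
  refz <- vapply(canopies$canopies, function(k) {
    cells <- which(lab == k$id)
    if (!length(cells)) {
      rc <- point_to_cell(grid_template, k$center[1], k$center[2])
      cells <- (rc$col - 1L) * nrow(lab) + rc$row
    }
    z <- dem$values[cells]
    switch(reference, mean = mean(z, na.rm = TRUE),
           centroid = {
             rc <- point_to_cell(grid_template, k$center[1], k$center[2])
             dem$values[rc$row, rc$col]
           },
           min = min(z, na.rm = TRUE))
  }, 0)
  pos <- match(nm$id$values, ids)
  area_ac <- matrix(areas[pos], nrow(lab), ncol(lab))
  elev_ac <- dem$values - matrix(refz[pos], nrow(lab), ncol(lab))
  list(area_ac = grid_like(grid_template, area_ac),
       elev_ac = grid_like(grid_template, elev_ac),
       id = nm$id, dist = nm$dist)
}

#' Vegetation cover from classified points
#'
#' Grids ground / non-ground classified returns and computes percent cover
#' per cell. The bounded convention (default) is 100 * non-ground / total,
#' which stays in [0, 100]; the literal ratio non-ground / ground is
#' available as `convention = "ratio"` (unbounded). Cells with no points are
#' nodata. The result is smoothed with a circular mean filter (six-cell
#' radius by default).
#'
#' @param points data.frame with `x`, `y` and `class` in
#'   `c("ground", "nonground")`.
#' @param grid_template raster geometry.
#' @param convention `"fraction"` (bounded, default) or `"ratio"`.
#' @param smooth_radius_cells mean-filter radius (0 disables).
#' @return A [raster_grid] of percent cover.
#' @export
cover_from_classified_points <- function(points, grid_template,
                                         convention = c("fraction", "ratio"),
                                         smooth_radius_cells = 6) {
  convention <- match.arg(convention)
  if (!all(points$class %in% c("ground", "nonground")))
    stop("point class must be 'ground' or 'nonground'")
  rc <- point_to_cell(grid_template, points$x, points$y)
  if (any(!rc$inside)) stop("classified points fall outside the raster extent")
  nr <- nrow(grid_template$values); nc <- ncol(grid_template$values)
  lin <- (rc$col - 1L) * nr + rc$row
  ng <- tabulate(lin[points$class == "nonground"], nbins = nr * nc)
  gr <- tabulate(lin[points$class == "ground"], nbins = nr * nc)
  tot <- ng + gr
  v <- if (convention == "fraction") 100 * ng / tot else 100 * ng / gr
  v[tot == 0L] <- NA_real_
  v[is.infinite(v)] <- NA_real_
  out <- grid_like(grid_template, matrix(v, nr, nc))
  if (smooth_radius_cells >= 1)
    out <- mean_filter_circular(out, smooth_radius_cells)
  out
}

#' Build the six-layer predictor stack
#'
#' Filters canopies (> `min_area_m2`), computes the three invader-proximity
#' layers, and assembles them with the terrain layers (TWI, landform) and
#' the cover raster into one co-registered stack.
#'
#' @param dem DEM raster.
#' @param cover percent-cover raster.
#' @param canopies a `canopy_set` (filtered internally).
#' @param terrain optional precomputed [terrain_stack] output; computed from
#'   the DEM when `NULL`.
#' @param min_area_m2 canopy area threshold.
#' @return A list of class `predictor_stack` with rasters `dist_ac`,
#'   `area_ac`, `elev_ac`, `twi`, `cover`, `landform`.
#' @export
build_predictor_stack <- function(dem, cover, canopies, terrain = NULL,
                                  min_area_m2 = 6) {
  stopifnot_aligned(dem, cover)
  if (is.null(terrain)) terrain <- terrain_stack(dem)
  ksub <- filter_canopies(canopies, min_area_m2)
  att <- nearest_canopy_attributes(ksub, dem, dem)
  structure(list(dist_ac = att$dist, area_ac = att$area_ac,
                 elev_ac = att$elev_ac, twi = terrain$twi, cover = cover,
                 landform = terrain$landform, canopy_id = att$id),
            class = "predictor_stack")
}

#' Extract predictor values at plant locations
#'
#' Nearest-cell extraction of every stack layer at each plant, with the log
#' transforms used for modelling: `log_area_ac = log(area_ac)` and
#' `log_cover = log(cover + 1)`. Plants outside the raster extent are an
#' error; rows with any nodata predictor are dropped with a warning.
#'
#' @param stack a `predictor_stack`.
#' @param plants data.frame with at least `plant_id`, `plot_id`,
#'   `transect_id`, `x`, `y`.
#' @return The model table: input columns plus `dist_ac`, `area_ac`,
#'   `log_area_ac`, `elev_ac`, `cover`, `log_cover`, `twi`, `landform`
#'   (factor over the landform legend).
#' @export
extract_at_points <- function(stack, plants) {
  rc <- point_to_cell(stack$dist_ac, plants$x, plants$y)
  if (any(!rc$inside))
    stop(sprintf("plant(s) outside raster extent: %s",
                 paste(plants$plant_id[!rc$inside], collapse = ", ")))
  cells <- cbind(rc$row, rc$col)
  out <- plants
  out$dist_ac <- stack$dist_ac$values[cells]
  out$area_ac <- stack$area_ac$values[cells]
  out$log_area_ac <- log(out$area_ac)
  out$elev_ac <- stack$elev_ac$values[cells]
  out$cover <- stack$cover$values[cells]
  out$log_cover <- log(out$cover + 1)
  out$twi <- stack$twi$values[cells]
  leg <- landform_legend()
  code <- stack$landform$values[cells]
  out$landform <- factor(names(leg)[match(code, leg)], levels = names(leg))
  need <- c("dist_ac", "log_area_ac", "elev_ac", "log_cover", "twi", "landform")
  keep <- stats::complete.cases(out[need])
  if (!all(keep)) {
    warning(sprintf("dropping %d plant(s) with nodata predictor values",
                    sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
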