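#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix (row 1 = northernmost row)
#' plus a square cell size and the coordinates of the lower-left corner of a
#' projected CRS. Nodata cells are `NA`. This is the carrier for the DEM,
#' vegetation cover, all terrain layers, the predictor stack and predicted
#' isoscapes.
#'
#' @param values numeric matrix; row 1 is the top (north) row.
#' @param cell_size cell edge length in meters (> 0).
#' @param xll,yll x and y coordinate of the lower-left corner (meters).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1, xll = 0, yll = 0) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %.3g m resolution\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  extent: x [%.1f, %.1f], y [%.1f, %.1f]\n",
              x$xll, x$xll + ncol(v) * x$cell_size,
              x$yll, x$yll + nrow(v) * x$cell_size))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' Is an object a raster_grid?
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

## new grid sharing geometry with `template`
grid_like <- function(template, values) {
  raster_grid(values, template$cell_size, template$xll, template$yll)
}

## check that two grids share shape, cell size and origin
stopifnot_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        abs(g$cell_size - ref$cell_size) > 1e-9 ||
        abs(g$xll - ref$xll) > 1e-6 || abs(g$yll - ref$yll) > 1e-6)
      stop("raster grids are not co-registered")
  }
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param grid a `raster_grid`.
#' @return List with matrices-free numeric vectors `x` (per column) and `y`
#'   (per row, top row first).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(x = grid$xll + (seq_len(nc) - 0.5) * grid$cell_size,
       y = grid$yll + (nr - seq_len(nr) + 0.5) * grid$cell_size)
}

## row/col of the cell whose center is nearest to (x, y); NA when outside
point_to_cell <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  col <- floor((x - grid$xll) / cs) + 1L
  row <- nr - floor((y - grid$yll) / cs)
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  col[!inside] <- NA_integer_; row[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Extract raster values at point locations (nearest cell)
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates (meters, same CRS as the grid).
#' @return Numeric vector of cell values; `NA` for nodata cells. Points
#'   outside the grid extent are an error.
#' @export
extract_cells <- function(grid, x, y) {
  rc <- point_to_cell(grid, x, y)
  if (any(!rc$inside))
    stop(sprintf("%d point(s) fall outside the raster extent", sum(!rc$inside)))
  grid$values[cbind(rc$row, rc$col)]
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header followed by rows north to south).
#'
#' @param grid a `raster_grid`.
#' @param path file path.
#' @param nodata value written for `NA` cells (default -9999).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `raster_grid`.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.6f", grid$xll),
           sprintf("yllcorner %.6f", grid$yll),
           sprintf("cellsize %.6f", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  dat <- scan(path, skip = 6L, quiet = TRUE)
  if (length(dat) != nr * nc) stop("ASCII grid payload does not match header")
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  raster_grid(m, val[["cellsize"]], val[["xllcorner"]], val[["yllcorner"]])
}
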