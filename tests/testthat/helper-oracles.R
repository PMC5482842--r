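## Independent brute-force oracles. These deliberately avoid the package's
## own algorithms (FFT focal windows, ordered MFD routing, bucketed nearest
## search) so that each comparison is a genuine dual-route check.

## focal mean by direct window enumeration; nodata excluded from means and
## nodata cells stay nodata
oracle_mean_filter <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(m[i, j])) next
      vals <- c()
      for (u in -floor(radius):floor(radius)) {
        for (v in -floor(radius):floor(radius)) {
          if (u^2 + v^2 > radius^2) next
          r <- i + u; s <- j + v
          if (r < 1 || r > nr || s < 1 || s > nc) next
          vals <- c(vals, m[r, s])
        }
      }
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[i, j] <- mean(vals)
    }
  }
  out
}

## MFD accumulation by fixed-point propagation: build the full flow-fraction
## matrix under the same weight rule, then iterate a = area + t(F) %*% a
## until convergence
oracle_mfd <- function(z, cell_size = 1, exponent = 1.1) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  Fm <- matrix(0, n, n)
  lin <- function(r, c) (c - 1L) * nr + r
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      w <- c(); tgt <- c()
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (z[rr, cc] < z[r, c]) {
            dist <- cell_size * sqrt(dr^2 + dc^2)
            w <- c(w, ((z[r, c] - z[rr, cc]) / dist)^exponent)
            tgt <- c(tgt, lin(rr, cc))
          }
        }
      }
      if (length(w)) Fm[lin(r, c), tgt] <- w / sum(w)
    }
  }
  area <- rep(cell_size^2, n)
  a <- area
  for (it in 1:10000) {
    a_new <- area + as.vector(t(Fm) %*% a)
    if (max(abs(a_new - a)) < 1e-14) break
    a <- a_new
  }
  matrix(a, nr, nc)
}

## all-pairs nearest footprint-cell distance (integer lattice arithmetic)
oracle_distance <- function(label, cell_size = 1) {
  nr <- nrow(label); nc <- ncol(label)
  idx <- which(label > 0)
  fr <- (idx - 1L) %% nr
  fc <- (idx - 1L) %/% nr
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- sqrt(min(((r - 1L) - fr)^2 + ((c - 1L) - fc)^2)) * cell_size
    }
  }
  out
}

## annulus TPI by direct enumeration
oracle_tpi <- function(m, inner, outer, cell_size = 1) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rmax <- ceiling(outer / cell_size)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (u in -rmax:rmax) {
        for (v in -rmax:rmax) {
          d <- sqrt(u^2 + v^2) * cell_size
          if (d <= inner || d > outer) next
          r <- i + u; s <- j + v
          if (r < 1 || r > nr || s < 1 || s > nc) next
          vals <- c(vals, m[r, s])
        }
      }
      out[i, j] <- m[i, j] - mean(vals)
    }
  }
  out
}

## Moran's I for one binary weight matrix, straight from the formula
oracle_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

## square canopy polygon fixture (axis-aligned, exact area side^2)
square_canopy <- function(id, cx, cy, side) {
  h <- side / 2
  xy <- cbind(c(cx - h, cx + h, cx + h, cx - h),
              c(cy - h, cy - h, cy + h, cy + h))
  list(id = as.integer(id), area_m2 = side^2, center = c(cx, cy),
       a = h, b = h, angle = 0, xy = xy)
}

canopy_set_of <- function(...) {
  structure(list(canopies = list(...)), class = "canopy_set")
}
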