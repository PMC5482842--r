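## FFT-backed 2-D "same" convolution for symmetric focal kernels.
## Kernels here (disks, annuli) are symmetric, so convolution equals
## correlation and no flip is needed. Kernel dims must be odd.
conv2d_same <- function(a, k) {
  nr <- nrow(a); nc <- ncol(a)
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- stats::nextn(nr + kr - 1L, c(2L, 3L, 5L))
  pc <- stats::nextn(nc + kc - 1L, c(2L, 3L, 5L))
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- a
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- k
  C <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r <- (kr - 1L) %/% 2L; cshift <- (kc - 1L) %/% 2L
  C[seq_len(nr) + r, seq_len(nc) + cshift, drop = FALSE]
}

## 0/1 kernel of cells whose center lies within `radius_cells` of the center
disk_kernel <- function(radius_cells) {
  r <- as.integer(floor(radius_cells))
  off <- seq.int(-r, r)
  d2 <- outer(off^2, off^2, `+`)
  k <- (d2 <= radius_cells^2) * 1
  k
}

## 0/1 kernel for inner < distance <= outer (distances in cells)
annulus_kernel <- function(inner_cells, outer_cells) {
  r <- as.integer(ceiling(outer_cells))
  off <- seq.int(-r, r)
  d <- sqrt(outer(off^2, off^2, `+`))
  (d > inner_cells & d <= outer_cells) * 1
}

## Focal mean with an arbitrary 0/1 kernel; nodata cells are excluded from
## the mean and stay nodata in the output; windows are clipped at the edges.
focal_mean_kernel <- function(grid, kernel) {
  v <- grid$values
  na <- is.na(v)
  v0 <- v; v0[na] <- 0
  num <- conv2d_same(v0, kernel)
  den <- conv2d_same((!na) * 1, kernel)
  out <- num / pmax(den, 1e-12)
  out[na | den < 0.5] <- NA_real_
  grid_like(grid, out)
}
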