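#' Repeated random-split predictive validation
#'
#' Repeats `n_runs` times: assign `train_frac` of the rows to a training
#' set, fit the model on it, predict the held-out test rows (random
#' intercepts are used for groups present in training; unseen groups get
#' fixed effects only), and score test R-squared and RMSE. Splits that
#' leave fewer than two training plots, a test landform class unseen in
#' training, or a constant test response are redrawn (logged via message).
#'
#' @param table model table.
#' @param spec a [gamm_spec].
#' @param n_runs number of random splits (default 100).
#' @param train_frac training fraction (default 0.75).
#' @param seed RNG seed; the whole summary is reproducible from it.
#' @param r2 convention: `"cor"` (squared Pearson correlation of predicted
#'   vs measured, default) or `"ssr"` (1 - SSE/SST).
#' @return A list of class `validation_summary`: per-run data.frame `runs`
#'   and medians / interquartile ranges of R-squared and RMSE.
#' @export
split_validate <- function(table, spec = gamm_spec(), n_runs = 100,
                           train_frac = 0.75, seed = 1,
                           r2 = c("cor", "ssr")) {
  r2 <- match.arg(r2)
  n <- nrow(table)
  n_train <- round(train_frac * n)
  if (n_train < 10 || n_train >= n)
    stop("train fraction leaves too few training or test rows")
  set.seed(seed)
  runs <- data.frame(run = seq_len(n_runs), r2 = NA_real_, rmse = NA_real_)
  for (run in seq_len(n_runs)) {
    for (try in 1:25) {
      idx <- sample.int(n, n_train)
      tr <- table[idx, , drop = FALSE]
      te <- table[-idx, , drop = FALSE]
      ok <- length(unique(tr$plot_id)) >= 2 &&
        stats::sd(te[[spec$response]]) > 0 &&
        (!spec$landform ||
           all(unique(as.character(te$landform)) %in%
                 unique(as.character(tr$landform))))
      if (ok) break
      message(sprintf("run %d: redrawing degenerate split (attempt %d)",
                      run, try))
      if (try == 25) stop("could not draw a valid split in 25 attempts")
    }
    fit <- fit_gamm(tr, spec)
    pred <- predict(fit, te, include_random = TRUE)
    obs <- te[[spec$response]]
    runs$rmse[run] <- sqrt(mean((pred - obs)^2))
    runs$r2[run] <- if (r2 == "cor") {
      if (stats::sd(pred) < 1e-12) 0 else stats::cor(pred, obs)^2
    } else {
      1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    }
  }
  structure(list(runs = runs,
                 median_r2 = stats::median(runs$r2),
                 iqr_r2 = unname(stats::quantile(runs$r2, c(0.25, 0.75))),
                 median_rmse = stats::median(runs$rmse),
                 iqr_rmse = unname(stats::quantile(runs$rmse, c(0.25, 0.75))),
                 n_runs = n_runs, train_frac = train_frac, seed = seed,
                 r2_convention = r2),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf(
    "<validation_summary> %d runs (train %.0f%%)\n  median R2 %.3f (IQR %.3f-%.3f), median RMSE %.3f (IQR %.3f-%.3f) permil\n",
    x$n_runs, 100 * x$train_frac, x$median_r2, x$iqr_r2[1], x$iqr_r2[2],
    x$median_rmse, x$iqr_rmse[1], x$iqr_rmse[2]))
  invisible(x)
}

## default distance bins: 10 equal-width bins to half the max pair distance
default_bins <- function(coords, n_bins = 10) {
  dmax <- sqrt(max((outer(coords[, 1], coords[, 1], `-`))^2 +
                     (outer(coords[, 2], coords[, 2], `-`))^2))
  seq(0, dmax / 2, length.out = n_bins + 1L)
}

#' Moran's I correlogram
#'
#' Binary-weight Moran's I per distance bin: with z the centered values and
#' w_ij = 1 when the pair distance falls in the bin,
#' I = (n / S0) * sum w_ij z_i z_j / sum z_i^2. A permutation envelope
#' (default 199 permutations, 2.5/97.5 percent quantiles) and the
#' independence expectation -1/(n-1) are attached.
#'
#' @param values numeric vector (e.g. model residuals).
#' @param coords two-column matrix of point coordinates (m).
#' @param bin_edges distance bin edges; default 10 equal bins to half the
#'   maximum pairwise distance.
#' @param n_perm number of permutations for the envelope.
#' @param seed RNG seed for the permutations.
#' @return A list of class `correlogram` with data.frame `bins`
#'   (`lo, hi, n_pairs, moran_i, env_lo, env_hi`) and `expected`.
#' @export
morans_i <- function(values, coords, bin_edges = NULL, n_perm = 199,
                     seed = 1) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (n < 10) stop("need at least 10 points")
  if (stats::sd(values) < 1e-12)
    stop("Moran's I undefined for zero-variance values")
  if (is.null(bin_edges)) bin_edges <- default_bins(coords)
  D <- as.matrix(stats::dist(coords))
  z <- values - mean(values)
  zz <- sum(z^2)
  nb <- length(bin_edges) - 1L
  Ws <- vector("list", nb)
  out <- data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
                    n_pairs = NA_real_, moran_i = NA_real_,
                    env_lo = NA_real_, env_hi = NA_real_)
  moran_stat <- function(W, S0, zv) (n / S0) * as.numeric(zv %*% W %*% zv) / sum(zv^2)
  for (b in seq_len(nb)) {
    W <- (D > out$lo[b] & D <= out$hi[b]) * 1
    diag(W) <- 0
    S0 <- sum(W)
    out$n_pairs[b] <- S0 / 2
    if (S0 > 0) {
      Ws[[b]] <- W
      out$moran_i[b] <- moran_stat(W, S0, z)
    }
  }
  if (any(out$n_pairs == 0))
    warning("empty distance bin(s): ",
            paste(which(out$n_pairs == 0), collapse = ", "))
  if (n_perm > 0) {
    set.seed(seed)
    perm <- matrix(NA_real_, n_perm, nb)
    for (p in seq_len(n_perm)) {
      zp <- z[sample.int(n)]
      for (b in seq_len(nb)) {
        if (!is.null(Ws[[b]]))
          perm[p, b] <- moran_stat(Ws[[b]], 2 * out$n_pairs[b], zp)
      }
    }
    out$env_lo <- apply(perm, 2, stats::quantile, 0.025, na.rm = TRUE)
    out$env_hi <- apply(perm, 2, stats::quantile, 0.975, na.rm = TRUE)
  }
  structure(list(bins = out, expected = -1 / (n - 1), n = n,
                 n_perm = n_perm),
            class = "correlogram")
}

#' Experimental semivariogram
#'
#' gamma(b) = (1 / 2 N_b) * sum over pairs in bin b of (v_i - v_j)^2.
#'
#' @inheritParams morans_i
#' @return A list of class `semivariogram` with data.frame `bins`
#'   (`lo, hi, n_pairs, gamma`).
#' @export
semivariogram <- function(values, coords, bin_edges = NULL) {
  coords <- as.matrix(coords)
  n <- length(values)
  if (is.null(bin_edges)) bin_edges <- default_bins(coords)
  D <- as.matrix(stats::dist(coords))
  S <- outer(values, values, `-`)^2
  ut <- upper.tri(D)
  d <- D[ut]; s <- S[ut]
  nb <- length(bin_edges) - 1L
  out <- data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
                    n_pairs = NA_real_, gamma = NA_real_)
  for (b in seq_len(nb)) {
    inb <- d > out$lo[b] & d <= out$hi[b]
    out$n_pairs[b] <- sum(inb)
    out$gamma[b] <- if (any(inb)) mean(s[inb]) / 2 else NA_real_
  }
  structure(list(bins = out, n = n), class = "semivariogram")
}
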