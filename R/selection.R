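#' Akaike Information Criterion with finite-sample correction
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1).
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed k + 1.
#' @return The AICc value.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: need n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2) with Delta_i the AICc
#' difference to the best model; interpretable as relative model support.
#'
#' @param aiccs vector of AICc values (or, equivalently, deltas).
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aiccs) {
  if (!length(aiccs) || any(!is.finite(aiccs)))
    stop("need at least one finite AICc value")
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' All-subsets model selection by AICc
#'
#' Fits every subset of the fixed terms of `full_spec` (each smooth in or
#' out as a whole, landform as a block; the random-intercept structure and
#' ML estimation are kept throughout, 2^m candidates including the
#' intercept-only model), ranks candidates by AICc and attaches deltas and
#' Akaike weights. Candidates that fail to fit are flagged and excluded
#' from the weights.
#'
#' @param table model table.
#' @param full_spec the most complex candidate, a [gamm_spec].
#' @param max_candidates guard against oversized term sets.
#' @return A data.frame of class `selection_table`, sorted by AICc, with
#'   one indicator column per term plus `df`, `logLik`, `AICc`, `delta`,
#'   `weight`, `converged`; attribute `n` is the sample size used for the
#'   correction and `specs` the per-candidate specs.
#' @export
dredge_gamm <- function(table, full_spec = gamm_spec(), max_candidates = 128) {
  terms <- c(full_spec$smooths, if (full_spec$landform) "landform")
  m <- length(terms)
  n_cand <- 2^m
  if (n_cand > max_candidates)
    stop(sprintf("%d candidates exceed max_candidates = %d", n_cand,
                 max_candidates))
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  colnames(grid) <- terms
  specs <- vector("list", n_cand)
  rows <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    inc <- terms[grid[i, ]]
    sp <- gamm_spec(smooths = intersect(inc, full_spec$smooths),
                    landform = "landform" %in% inc,
                    random = full_spec$random, k = full_spec$k,
                    response = full_spec$response)
    specs[[i]] <- sp
    fit <- tryCatch(suppressWarnings(fit_gamm(table, sp)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message(sprintf("candidate %d failed: %s", i, conditionMessage(fit)))
      rows[[i]] <- data.frame(df = NA_integer_, logLik = NA_real_,
                              AICc = NA_real_, converged = FALSE)
    } else {
      rows[[i]] <- data.frame(df = fit$df, logLik = fit$logLik,
                              AICc = aicc(fit$logLik, fit$df, fit$n),
                              converged = TRUE)
    }
  }
  res <- cbind(as.data.frame(grid), do.call(rbind, rows))
  res$delta <- NA_real_
  res$weight <- NA_real_
  ok <- res$converged
  res$delta[ok] <- res$AICc[ok] - min(res$AICc[ok])
  res$weight[ok] <- akaike_weights(res$AICc[ok])
  ord <- order(res$AICc)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n") <- nrow(table)
  attr(res, "specs") <- specs[ord]
  class(res) <- c("selection_table", "data.frame")
  res
}

#' Write a selection table as CSV
#' @param sel a `selection_table`.
#' @param path output file.
#' @export
write_selection_csv <- function(sel, path) {
  utils::write.csv(as.data.frame(sel), path, row.names = FALSE)
  invisible(path)
}

#' Terms of the best-supported candidate
#' @param sel a `selection_table`.
#' @return Character vector of the included terms of the AICc-best model.
#' @export
best_terms <- function(sel) {
  ind_cols <- setdiff(names(sel),
                      c("df", "logLik", "AICc", "delta", "weight", "converged"))
  best <- sel[which(sel$converged)[1], , drop = FALSE]
  ind_cols[as.logical(best[1, ind_cols])]
}
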