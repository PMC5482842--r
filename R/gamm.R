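SMOOTH_TERMS <- c("dist_ac", "elev_ac", "log_area_ac", "log_cover", "twi")

#' Specify an additive mixed model of d15N
#'
#' The model family is Gaussian with identity link: thin-plate regression
#' spline smooths for any subset of the five continuous predictors, an
#' optional parametric landform factor, and random intercepts for plot and
#' for transect nested in plot (transect ids are globally unique, so a plain
#' transect intercept realizes the nesting).
#'
#' @param smooths character subset of
#'   `c("dist_ac","elev_ac","log_area_ac","log_cover","twi")` (may be empty).
#' @param landform include the landform factor?
#' @param random include the nested random intercepts?
#' @param k basis dimension per smooth (default 10).
#' @param response response column name.
#' @return An object of class `gamm_spec`.
#' @export
gamm_spec <- function(smooths = SMOOTH_TERMS, landform = TRUE, random = TRUE,
                      k = 10, response = "d15n_obs") {
  smooths <- as.character(smooths)
  bad <- setdiff(smooths, SMOOTH_TERMS)
  if (length(bad))
    stop("unknown smooth term(s): ", paste(bad, collapse = ", "))
  structure(list(smooths = smooths, landform = isTRUE(landform),
                 random = isTRUE(random), k = k, response = response),
            class = "gamm_spec")
}

#' @export
print.gamm_spec <- function(x, ...) {
  cat("<gamm_spec>", x$response, "~",
      paste(c(if (x$landform) "landform",
              if (length(x$smooths)) paste0("s(", x$smooths, ")"),
              if (x$random) c("(1|plot)", "(1|plot:transect)")),
            collapse = " + "), "\n")
  invisible(x)
}

#' Thin-plate regression spline basis with its penalty
#'
#' Low-rank thin-plate spline basis of dimension `k` for one covariate, with
#' the sum-to-zero (centering) constraint absorbed so the columns are
#' identifiable next to an intercept. The penalty is symmetric positive
#' semi-definite and its null space contains the linear trend in `x`.
#'
#' @param x covariate values.
#' @param k requested basis dimension; reduced with a warning when `x` has
#'   fewer distinct values.
#' @return List with design matrix `X` (k-1 columns), penalty `S`, and the
#'   underlying mgcv smooth object `smooth`.
#' @export
build_smooth_basis <- function(x, k = 10) {
  nd <- length(unique(x))
  if (nd < 2L) stop("need at least 2 distinct covariate values")
  if (nd < k) {
    warning(sprintf("only %d distinct values; reducing basis dimension from %d",
                    nd, k))
    k <- nd
  }
  dat <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = k), data = dat,
                        absorb.cons = TRUE)[[1]]
  list(X = sm$X, S = sm$S[[1]], smooth = sm)
}

re_terms_of <- function(spec) {
  if (spec$random) c("s(plot_id)", "s(transect_id)") else character()
}

gamm_formula <- function(spec, k_use) {
  rhs <- c(if (spec$landform) "landform",
           if (length(spec$smooths))
             sprintf('s(%s, bs = "tp", k = %d)', spec$smooths,
                     k_use[spec$smooths]),
           if (spec$random) c('s(plot_id, bs = "re")',
                              's(transect_id, bs = "re")'))
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit the additive mixed model
#'
#' Penalized splines are handled in their mixed-model representation jointly
#' with the random intercepts; smoothing parameters and variance components
#' are estimated by maximum likelihood (`mgcv::gam(..., method = "ML")`),
#' matching the use of ML fits for AICc-based model selection. The fit is
#' deterministic given the table and spec.
#'
#' @param table model table (see [extract_at_points]); must be complete for
#'   all terms in the spec.
#' @param spec a [gamm_spec].
#' @return An object of class `nitro_gamm` wrapping the mgcv fit, with the
#'   log-likelihood, the parameter count used for AICc, per-smooth effective
#'   degrees of freedom, variance components and training summaries.
#' @export
fit_gamm <- function(table, spec = gamm_spec()) {
  stopifnot(inherits(spec, "gamm_spec"))
  need <- c(spec$response, spec$smooths, if (spec$landform) "landform",
            if (spec$random) c("plot_id", "transect_id"))
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[need]), , drop = FALSE]
  if (!nrow(dat)) stop("no complete rows for the requested terms")
  y <- dat[[spec$response]]
  if (any(!is.finite(y))) stop("non-finite response values")
  if (stats::sd(y) < 1e-8)
    stop("degenerate fit: response is constant, residual variance is zero")
  dat$plot_id <- factor(dat$plot_id)
  dat$transect_id <- factor(dat$transect_id)
  if (spec$random && nlevels(dat$plot_id) < 2L)
    stop("random intercepts require at least 2 plots")
  if (spec$landform) {
    dat$landform <- droplevels(factor(dat$landform))
    if (nlevels(dat$landform) < 2L)
      stop("singular design: landform has a single observed level")
    ## reference level: plain when observed, else first level
    if ("plain" %in% levels(dat$landform))
      dat$landform <- stats::relevel(dat$landform, "plain")
  }
  k_use <- integer(0)
  if (length(spec$smooths)) {
    k_use <- vapply(spec$smooths, function(tm) {
      nd <- length(unique(dat[[tm]]))
      if (nd < spec$k)
        warning(sprintf("term %s: only %d distinct values; k reduced", tm, nd))
      as.integer(min(spec$k, nd))
    }, 0L)
  }
  fml <- gamm_formula(spec, k_use)
  g <- mgcv::gam(fml, data = dat, method = "ML")
  if (g$sig2 < 1e-10)
    stop("degenerate fit: residual variance is (numerically) zero")
  edf <- smooth_edfs(g, spec)
  vc <- variance_components(g, spec)
  fit <- structure(list(
    gam = g, spec = spec, k_use = k_use, n = nrow(dat),
    logLik = as.numeric(stats::logLik(g)),
    df = count_parameters(spec,
                          n_landform_levels = if (spec$landform)
                            nlevels(dat$landform) else 0L),
    edf = edf, vcomp = vc, sigma = sqrt(g$sig2),
    fitted = as.numeric(stats::fitted(g)),
    residuals = as.numeric(stats::residuals(g, type = "response")),
    train = list(
      means = vapply(spec$smooths, function(tm) mean(dat[[tm]]), 0),
      ranges = lapply(stats::setNames(spec$smooths, spec$smooths),
                      function(tm) range(dat[[tm]])),
      landform_levels = if (spec$landform) levels(dat$landform) else NULL,
      landform_modal = if (spec$landform)
        names(which.max(base::table(dat$landform))) else NULL,
      plot_levels = levels(dat$plot_id),
      transect_levels = levels(dat$transect_id),
      data = dat)),
    class = "nitro_gamm")
  fit
}

## total estimated-parameter count, the AICc df convention: fixed
## coefficients in the mixed-model representation (intercept, landform
## contrasts, one linear null-space term per smooth) plus one smoothing
## parameter per smooth, the two random-intercept variances and the
## residual variance
count_parameters <- function(spec, n_landform_levels = 5L) {
  n_sm <- length(spec$smooths)
  fixed <- 1L + (if (spec$landform) n_landform_levels - 1L else 0L) + n_sm
  varpar <- n_sm + (if (spec$random) 2L else 0L) + 1L
  fixed + varpar
}

#' Parameter count used for AICc
#' @param fit a `nitro_gamm`.
#' @return Integer parameter count (see [fit_gamm] details).
#' @export
param_count <- function(fit) fit$df

#' Maximum-likelihood log-likelihood of a fit
#' @param fit a `nitro_gamm`.
#' @export
log_likelihood <- function(fit) fit$logLik

smooth_edfs <- function(g, spec) {
  if (!length(g$smooth)) return(stats::setNames(numeric(0), character(0)))
  labs <- vapply(g$smooth, function(s) s$term[1], "")
  edf <- vapply(seq_along(g$smooth), function(j) {
    s <- g$smooth[[j]]
    sum(g$edf[s$first.para:s$last.para])
  }, 0)
  stats::setNames(edf, labs)
}

variance_components <- function(g, spec) {
  out <- c(resid = unname(g$sig2))
  if (spec$random) {
    labs <- vapply(g$smooth, function(s) s$label, "")
    sp <- g$sp
    ## for bs = "re", variance = sig2 / sp
    for (tm in c("plot_id", "transect_id")) {
      lab <- paste0("s(", tm, ")")
      j <- match(lab, labs)
      if (!is.na(j)) {
        spj <- sp[[paste0(lab)]]
        if (is.null(spj) || is.na(spj)) spj <- sp[j]
        out[tm] <- unname(g$sig2 / max(spj, 1e-12))
      }
    }
  }
  out
}

#' Effective degrees of freedom of one smooth
#' @param fit a `nitro_gamm`.
#' @param term smooth term name (e.g. `"dist_ac"`).
#' @return The trace of the term's hat-matrix block.
#' @export
edf_term <- function(fit, term) {
  if (!term %in% names(fit$edf)) stop("term not in the fitted model: ", term)
  unname(fit$edf[term])
}

#' Estimated random intercepts
#' @param fit a `nitro_gamm`.
#' @return List of named numeric vectors `plot` and `transect` (empty when
#'   the spec has no random terms).
#' @export
ranef_gamm <- function(fit) {
  if (!fit$spec$random) return(list(plot = numeric(0), transect = numeric(0)))
  cf <- stats::coef(fit$gam)
  pl <- cf[grep("^s\\(plot_id\\)", names(cf))]
  tr <- cf[grep("^s\\(transect_id\\)", names(cf))]
  list(plot = stats::setNames(as.numeric(pl), fit$train$plot_levels),
       transect = stats::setNames(as.numeric(tr), fit$train$transect_levels))
}

#' Predict from a fitted additive mixed model
#'
#' Fixed-effects prediction is intercept + landform effect + sum of smooth
#' effects. With `include_random = TRUE`, the estimated random intercepts
#' are added for groups seen in training; unseen groups contribute 0.
#'
#' @param object a `nitro_gamm`.
#' @param newdata data.frame with the model's covariates.
#' @param include_random add estimated group intercepts?
#' @param ... unused.
#' @return Numeric vector of predicted d15N (permil).
#' @export
predict.nitro_gamm <- function(object, newdata, include_random = TRUE, ...) {
  spec <- object$spec
  if (spec$landform) {
    lv <- object$train$landform_levels
    cls <- as.character(newdata$landform)
    if (any(!cls %in% lv))
      stop("unknown landform class in newdata: ",
           paste(unique(setdiff(cls, lv)), collapse = ", "))
    newdata$landform <- factor(cls, levels = lv)
  }
  nd <- newdata
  if (spec$random) {
    ## placeholder levels so the design matrix can be built; the random
    ## columns are excluded from the linear predictor below
    nd$plot_id <- factor(object$train$plot_levels[1],
                         levels = object$train$plot_levels)
    nd$transect_id <- factor(object$train$transect_levels[1],
                             levels = object$train$transect_levels)
  }
  p <- as.numeric(mgcv::predict.gam(object$gam, newdata = nd,
                                    exclude = re_terms_of(spec),
                                    newdata.guaranteed = FALSE))
  if (include_random && spec$random) {
    re <- ranef_gamm(object)
    if (!is.null(newdata$plot_id)) {
      b <- re$plot[as.character(newdata$plot_id)]
      b[is.na(b)] <- 0
      p <- p + b
    }
    if (!is.null(newdata$transect_id)) {
      b <- re$transect[as.character(newdata$transect_id)]
      b[is.na(b)] <- 0
      p <- p + b
    }
  }
  unname(p)
}

#' Partial effect of one model term
#'
#' Centered effect of a single smooth (or the landform factor) on an evenly
#' spaced covariate grid, with 95 percent credible intervals from the
#' Bayesian posterior covariance of the coefficients, plus partial
#' residuals: model residuals with the term's own contribution added, all
#' other predictors at their training means / most frequent class.
#'
#' @param fit a `nitro_gamm`.
#' @param term a smooth term name or `"landform"`.
#' @param n_grid grid size for continuous terms.
#' @return A list of class `partial_effect` with `x`, `effect`, `se`,
#'   `lower`, `upper` and data.frame `partial_residuals`.
#' @export
partial_effect <- function(fit, term, n_grid = 100) {
  spec <- fit$spec
  is_land <- identical(term, "landform")
  if (!is_land && !term %in% spec$smooths)
    stop("term not in the fitted model: ", term)
  if (is_land && !spec$landform)
    stop("landform is not in the fitted model")
  dat <- fit$train$data
  if (is_land) {
    xg <- factor(fit$train$landform_levels, levels = fit$train$landform_levels)
    nd <- data.frame(landform = xg)
  } else {
    r <- fit$train$ranges[[term]]
    xg <- seq(r[1], r[2], length.out = n_grid)
    nd <- stats::setNames(data.frame(xg), term)
  }
  for (tm in setdiff(spec$smooths, term))
    nd[[tm]] <- fit$train$means[[tm]]
  if (spec$landform && !is_land)
    nd$landform <- factor(fit$train$landform_modal,
                          levels = fit$train$landform_levels)
  if (spec$random) {
    nd$plot_id <- factor(fit$train$plot_levels[1],
                         levels = fit$train$plot_levels)
    nd$transect_id <- factor(fit$train$transect_levels[1],
                             levels = fit$train$transect_levels)
  }
  tlab <- if (is_land) "landform" else paste0("s(", term, ")")
  pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "terms",
                          se.fit = TRUE, terms = tlab)
  eff <- as.numeric(pr$fit[, tlab])
  se <- as.numeric(pr$se.fit[, tlab])
  ## own-term contribution at the training rows, for partial residuals
  tr_terms <- mgcv::predict.gam(fit$gam, type = "terms", terms = tlab)
  own <- as.numeric(tr_terms[, tlab])
  if (is_land) {
    ## center the factor effect over the training rows
    ctr <- mean(own)
    eff <- eff - ctr
    own <- own - ctr
  }
  prs <- data.frame(x = if (is_land) dat$landform else dat[[term]],
                    partial_residual = fit$residuals + own)
  structure(list(term = term, x = xg, effect = eff, se = se,
                 lower = eff - 1.96 * se, upper = eff + 1.96 * se,
                 partial_residuals = prs),
            class = "partial_effect")
}

#' @export
print.partial_effect <- function(x, ...) {
  cat(sprintf("<partial_effect> %s: effect range [%.2f, %.2f] permil\n",
              x$term, min(x$effect), max(x$effect)))
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes the model spec, the training table, coefficients, smoothing
#' parameters, variance components and likelihood quantities. Because
#' fitting is deterministic, the stored spec + table are sufficient for
#' exact re-prediction: [read_gamm_json] refits and verifies the stored
#' log-likelihood.
#'
#' @param fit a `nitro_gamm`.
#' @param path output file.
#' @export
write_gamm_json <- function(fit, path) {
  obj <- list(
    spec = unclass(fit$spec),
    n = fit$n, logLik = fit$logLik, df = fit$df,
    coefficients = as.list(stats::coef(fit$gam)),
    smoothing_parameters = as.list(fit$gam$sp),
    variance_components = as.list(fit$vcomp),
    edf = as.list(fit$edf),
    table = fit$train$data[, !vapply(fit$train$data, is.factor, TRUE) |
                             names(fit$train$data) %in%
                             c("plot_id", "transect_id", "landform"),
                           drop = FALSE])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       factor = "string")
  invisible(path)
}

#' @rdname write_gamm_json
#' @param tol tolerance for the log-likelihood consistency check.
#' @export
read_gamm_json <- function(path, tol = 1e-4) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(gamm_spec, obj$spec[c("smooths", "landform", "random", "k",
                                        "response")])
  tab <- as.data.frame(obj$table)
  if ("landform" %in% names(tab))
    tab$landform <- factor(tab$landform, levels = names(landform_legend()))
  fit <- fit_gamm(tab, spec)
  if (abs(fit$logLik - obj$logLik) > tol * (1 + abs(obj$logLik)))
    warning("refit log-likelihood deviates from the stored value")
  fit
}

#' @export
print.nitro_gamm <- function(x, ...) {
  cat(sprintf("<nitro_gamm> n = %d, logLik = %.2f, df = %d, sigma = %.3f\n",
              x$n, x$logLik, x$df, x$sigma))
  if (length(x$edf)) {
    cat("  edf:", paste(sprintf("%s %.2f", names(x$edf), x$edf),
                        collapse = ", "), "\n")
  }
  invisible(x)
}
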