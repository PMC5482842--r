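## assemble a per-cell newdata frame from stack layers; `constants` is a
## named list used instead of the raster for non-varied predictors
stack_newdata <- function(fit, stack, vary = NULL, constants = NULL) {
  spec <- fit$spec
  terms <- c(spec$smooths, if (spec$landform) "landform")
  if (is.null(vary)) vary <- terms
  layer_of <- function(tm) switch(tm,
    dist_ac = stack$dist_ac$values,
    log_area_ac = log(stack$area_ac$values),
    elev_ac = stack$elev_ac$values,
    log_cover = log(stack$cover$values + 1),
    twi = stack$twi$values,
    landform = stack$landform$values)
  nr <- nrow(stack$dist_ac$values); ncell <- length(stack$dist_ac$values)
  nd <- list()
  valid <- rep(TRUE, ncell)
  for (tm in terms) {
    if (tm %in% vary) {
      v <- as.vector(layer_of(tm))
      if (is.null(v)) stop("predictor stack lacks the layer for term: ", tm)
      valid <- valid & !is.na(v)
      if (tm == "landform") {
        leg <- landform_legend()
        cls <- names(leg)[match(v, leg)]
        known <- cls %in% fit$train$landform_levels
        valid <- valid & (known | is.na(cls))
        cls[!known] <- fit$train$landform_levels[1]
        nd$landform <- factor(cls, levels = fit$train$landform_levels)
      } else nd[[tm]] <- v
    } else {
      nd[[tm]] <- if (tm == "landform")
        factor(rep(constants$landform, ncell),
               levels = fit$train$landform_levels)
      else rep(constants[[tm]], ncell)
    }
  }
  list(newdata = as.data.frame(nd), valid = valid)
}

training_constants <- function(fit) {
  cn <- as.list(fit$train$means)
  if (fit$spec$landform) cn$landform <- fit$train$landform_modal
  cn
}

#' Predict a continuous d15N isoscape
#'
#' Fixed-effects-only prediction of d15N for every raster cell from the
#' predictor stack (random intercepts are transect-local and not defined on
#' the raster). Cells farther from the nearest canopy than the maximum
#' distance observed in the training table are masked as nodata, as are
#' cells with nodata in any required layer.
#'
#' @param fit a `nitro_gamm`.
#' @param stack a `predictor_stack` co-registered with the training data's
#'   rasters.
#' @param table the training model table (source of the distance limit).
#' @return A [raster_grid] of predicted d15N (permil).
#' @export
predict_isoscape <- function(fit, stack, table) {
  scenario_isoscape(fit, stack, table, vary = NULL)
}

#' Scenario decomposition isoscapes
#'
#' Like [predict_isoscape], but only the predictors named in `vary` keep
#' their raster values; all others are held constant at their training mean
#' (continuous) or most frequent class (landform). Because the model is
#' additive, scenario maps decompose: scenario(A) + scenario(B) - baseline
#' equals scenario(A, B) cellwise.
#'
#' @param fit a `nitro_gamm`.
#' @param stack a `predictor_stack`.
#' @param table the training model table.
#' @param vary character vector of model terms to vary (`NULL` = all,
#'   `character(0)` = constant baseline map).
#' @return A [raster_grid] of predicted d15N (permil).
#' @export
scenario_isoscape <- function(fit, stack, table, vary = NULL) {
  spec <- fit$spec
  terms <- c(spec$smooths, if (spec$landform) "landform")
  if (!is.null(vary)) {
    bad <- setdiff(vary, terms)
    if (length(bad))
      stop("vary includes term(s) not in the model: ",
           paste(bad, collapse = ", "))
  }
  sn <- stack_newdata(fit, stack, vary = vary,
                      constants = training_constants(fit))
  p <- rep(NA_real_, length(sn$valid))
  if (any(sn$valid))
    p[sn$valid] <- predict(fit, sn$newdata[sn$valid, , drop = FALSE],
                           include_random = FALSE)
  ## domain-of-validity mask: beyond the training distance maximum
  dmax <- max(table$dist_ac, na.rm = TRUE)
  dv <- as.vector(stack$dist_ac$values)
  p[is.na(dv) | dv > dmax] <- NA_real_
  grid_like(stack$dist_ac, matrix(p, nrow(stack$dist_ac$values)))
}
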