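test_that("thin-plate basis: penalty PSD, centered columns, linear null space", {
  set.seed(5)
  x <- runif(80)
  bs <- build_smooth_basis(x, k = 8)
  expect_equal(ncol(bs$X), 7)          # one column absorbed by centering
  expect_lt(max(abs(colSums(bs$X))), 1e-8)
  expect_equal(bs$S, t(bs$S), tolerance = 1e-10)
  ev <- eigen(bs$S, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(sum(ev < 1e-8), 1)      # linear trend unpenalized

  ## lambda -> infinity collapses the smooth onto the least-squares line
  y <- 2 * x + rnorm(80, 0, 0.1)
  yc <- y - mean(y)
  beta <- solve(crossprod(bs$X) + 1e8 * bs$S, crossprod(bs$X, yc))
  fitted <- as.vector(bs$X %*% beta)
  ols <- lm(yc ~ x)
  expect_equal(fitted, unname(fitted(ols)), tolerance = 1e-3)
  slope <- coef(lm(fitted ~ x))[["x"]]
  expect_equal(slope, 2, tolerance = 0.1)

  expect_warning(build_smooth_basis(rep(1:5, 10), k = 8), "distinct")
})

test_that("degenerate constant response is a reported error", {
  tab <- default_scenario()$plants[1:60, ]
  tab$d15n_obs <- -5.84
  expect_error(fit_gamm(tab, gamm_spec(smooths = character(),
                                       landform = FALSE)),
               "degenerate")
})

test_that("random-intercept-only fit shrinks group means", {
  set.seed(21)
  tab <- data.frame(
    plot_id = rep(c("a", "b", "c", "d"), each = 12),
    transect_id = rep(sprintf("t%d", 1:8), each = 6),
    d15n_obs = rep(c(-2, 2, -1, 1), each = 12) + rnorm(48, 0, 1.5))
  fit <- fit_gamm(tab, gamm_spec(smooths = character(), landform = FALSE))
  re <- ranef_gamm(fit)
  raw <- tapply(tab$d15n_obs, tab$plot_id, mean) - mean(tab$d15n_obs)
  expect_true(all(abs(re$plot) < abs(raw) + 1e-8))
  expect_gt(cor(re$plot, raw), 0.9)
})

test_that("with no smooths and no random terms the fit is the landform OLS", {
  tab <- default_scenario()$plants
  fit <- fit_gamm(tab, gamm_spec(smooths = character(), random = FALSE))
  ols <- lm(d15n_obs ~ landform, data = droplevels(tab))
  p_gamm <- predict(fit, tab, include_random = FALSE)
  expect_equal(p_gamm, unname(predict(ols, droplevels(tab))),
               tolerance = 1e-6)
  ## gam reports the unbiased residual variance RSS / (n - p)
  expect_equal(fit$sigma^2, summary(ols)$sigma^2, tolerance = 1e-6)
})

test_that("prediction identities hold on the training data", {
  fit <- default_fit()
  tab <- default_scenario()$plants
  ## self-consistency with the fitted values
  expect_equal(predict(fit, tab, include_random = TRUE), fit$fitted,
               tolerance = 1e-8)
  ## additive decomposition: intercept + sum of term contributions
  tt <- mgcv::predict.gam(fit$gam, type = "terms")
  keep <- !grepl("plot_id|transect_id", colnames(tt))
  intercept <- attr(tt, "constant")
  full <- predict(fit, tab, include_random = FALSE)
  expect_equal(full, unname(intercept + rowSums(tt[, keep, drop = FALSE])),
               tolerance = 1e-8)
  ## all covariates at training means, modal landform, no random effects
  nd <- data.frame(as.list(fit$train$means))
  nd$landform <- factor(fit$train$landform_modal,
                        levels = fit$train$landform_levels)
  p_mean <- predict(fit, nd, include_random = FALSE)
  nd_full <- transform(nd, plot_id = fit$train$plot_levels[1],
                       transect_id = fit$train$transect_levels[1])
  tt_mean <- mgcv::predict.gam(fit$gam, newdata = nd_full, type = "terms")
  keep_mean <- !grepl("plot_id|transect_id", colnames(tt_mean))
  expect_equal(p_mean,
               unname(intercept + sum(tt_mean[, keep_mean])),
               tolerance = 1e-8)
  ## unknown landform class is an error
  bad <- nd; bad$landform <- "plain"
  if (!"plain" %in% fit$train$landform_levels)
    expect_error(predict(fit, bad), "unknown landform")
})

test_that("unseen groups fall back to fixed-effects-only predictions", {
  fit <- default_fit()
  tab <- default_scenario()$plants[1:5, ]
  tab$plot_id <- "p99"
  tab$transect_id <- "p99_N"
  p_new <- predict(fit, tab, include_random = TRUE)
  p_fix <- predict(fit, tab, include_random = FALSE)
  expect_equal(p_new, p_fix, tolerance = 1e-12)
})

test_that("partial effects are centered with positive uncertainty", {
  fit <- default_fit()
  tab <- default_scenario()$plants
  for (tm in c("dist_ac", "twi")) {
    pe <- partial_effect(fit, tm)
    ## centering over the training covariate values
    own <- mgcv::predict.gam(fit$gam, type = "terms",
                             terms = paste0("s(", tm, ")"))
    expect_lt(abs(mean(own)), 1e-6)
    expect_true(all(pe$se > 0))
    expect_true(all(pe$upper > pe$lower))
    expect_equal(nrow(pe$partial_residuals), nrow(tab))
  }
  pe_land <- partial_effect(fit, "landform")
  expect_equal(length(pe_land$effect),
               length(fit$train$landform_levels))
  expect_error(partial_effect(fit, "bogus"), "not in the fitted model")
})

test_that("edf and the parameter-count convention behave", {
  fit <- default_fit()
  for (tm in fit$spec$smooths) {
    e <- edf_term(fit, tm)
    expect_gte(e, 1 - 1e-6)
    expect_lte(e, fit$spec$k - 1 + 1e-6)
  }
  ## df convention: full model with 5 smooths + 5-level landform + 2 RE
  ## variances + residual = 18; each dropped smooth removes 2
  full <- gamm_spec()
  expect_equal(nitroscape:::count_parameters(full, 5L), 18L)
  expect_equal(nitroscape:::count_parameters(
    gamm_spec(smooths = setdiff(full$smooths, "log_area_ac")), 5L), 16L)
  expect_equal(nitroscape:::count_parameters(
    gamm_spec(smooths = setdiff(full$smooths, c("log_area_ac", "elev_ac")),
              landform = TRUE), 5L), 14L)
  expect_equal(param_count(fit), fit$df)
})

test_that("fits are permutation invariant and likelihood-monotone", {
  tab <- default_scenario()$plants
  spec <- gamm_spec(smooths = c("dist_ac", "log_cover", "twi"), k = 5)
  f1 <- fit_gamm(tab, spec)
  set.seed(4)
  f2 <- fit_gamm(tab[sample(nrow(tab)), ], spec)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  ## nested models: ML log-likelihood cannot decrease with an added term
  sub <- fit_gamm(tab, gamm_spec(smooths = c("dist_ac", "twi"), k = 5))
  expect_gte(f1$logLik, sub$logLik - 1e-4)
  sub2 <- fit_gamm(tab, gamm_spec(smooths = c("dist_ac", "log_cover", "twi"),
                                  k = 5, landform = FALSE))
  expect_gte(f1$logLik, sub2$logLik - 1e-4)
})

test_that("fit serialization round-trips through JSON", {
  fit <- default_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_gamm_json(fit, path)
  fit2 <- read_gamm_json(path)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-6)
  tab <- default_scenario()$plants[1:20, ]
  expect_equal(predict(fit2, tab), predict(fit, tab), tolerance = 1e-6)
})
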