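test_that("determination coefficient matches hand arithmetic", {
  o <- c(1, 2, 3)
  expect_equal(r_squared(o, o), 1)
  expect_equal(r_squared(o, rep(mean(o), 3)), 0)
  expect_equal(r_squared(o, c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)),
               class = "leafallom_domain_error")
})

test_that("concordance correlation penalises shift and never exceeds |r|", {
  o <- c(1, 2, 3)
  expect_equal(concordance_correlation(o, o), 1)
  expect_equal(concordance_correlation(o, c(2, 3, 4)), 4 / 7)
  shifted <- o + 5
  expect_lt(abs(concordance_correlation(o, shifted)),
            abs(cor(o, shifted)))
  set.seed(17)
  for (i in 1:200) {
    x <- rnorm(20); y <- rnorm(20, mean = runif(1, -2, 2))
    expect_lte(abs(concordance_correlation(x, y)),
               abs(cor(x, y)) + 1e-12)
  }
  # the n-1 variant differs only through the mean-shift term
  x <- rnorm(10); y <- x + 1
  expect_gt(concordance_correlation(x, y, denominator = "n-1"),
            concordance_correlation(x, y))
  expect_error(concordance_correlation(c(1, 1), c(2, 2)),
               class = "leafallom_domain_error")
})

test_that("Gaussian AIC follows n log(rss/n) + 2K", {
  expect_equal(aic_ls(rss = 10, n = 10, n_params = 2), 6)
  # same rss, one parameter fewer: AIC smaller by 2
  expect_equal(aic_ls(rss = 5, n = 20, n_params = 1),
               aic_ls(rss = 5, n = 20, n_params = 2) - 2)
  expect_error(aic_ls(rss = 0, n = 10, n_params = 1),
               class = "leafallom_perfect_fit")
})

test_that("lack-of-fit test recognises pure-error structure", {
  # predictions equal to group means: no lack of fit at all
  l <- rep(c(100, 200, 300), each = 4)
  set.seed(3)
  w <- 0.001 * l + rnorm(12, 0, 0.005)
  gm <- ave(w, l)
  r0 <- lack_of_fit_test(l, w, gm, n_params = 1)
  expect_true(r0$applicable)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$df_pe, 12 - 3)
  expect_equal(r0$df_lof, 3 - 1)

  # no replicates after rounding: not applicable, not an error
  r1 <- lack_of_fit_test(c(10, 20, 30, 40), rnorm(4), rnorm(4), n_params = 1)
  expect_false(r1$applicable)
})

test_that("lack-of-fit test is calibrated under the true model and powerful against curvature", {
  # type-I error at alpha = 0.05 under a correct isometric model
  set.seed(55)
  l <- rep(seq(100, 340, by = 10), each = 4)   # 25 groups x 4 replicates
  reps <- 400
  rej <- 0
  for (i in seq_len(reps)) {
    w <- pmax(1e-4 * l + rnorm(length(l), 0, 0.0015), 1e-9)
    fit <- fit_scaling(leaf_records(l, w), "isometric")
    lt <- lack_of_fit_test(l, w, fitted(fit), n_params = 1)
    if (lt$p.value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / reps - 0.05), 0.03)

  # strong power against a b = 1.4 power law fitted isometrically
  set.seed(56)
  l2 <- rep(seq(30, 620, length.out = 60), each = 5)   # n = 300
  miss <- 0
  for (i in 1:50) {
    w2 <- 1e-5 * l2^1.4 * exp(rnorm(length(l2), 0, 0.2) - 0.02)
    fit2 <- fit_scaling(leaf_records(l2, w2), "isometric")
    lt2 <- lack_of_fit_test(l2, w2, fitted(fit2), n_params = 1)
    if (lt2$p.value >= 0.05) miss <- miss + 1
  }
  expect_lte(miss, 2)
})

test_that("paired means test handles exact and degenerate cases", {
  o <- rnorm(100)
  expect_equal(mean_difference_test(o, o)$p.value, 1)
  big <- mean_difference_test(o, o + 10)
  expect_lt(big$p.value, 1e-6)
  sym <- mean_difference_test(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  degen <- mean_difference_test(c(1, 2, 3), c(0, 1, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p.value, 0)
})

test_that("residual diagnostics are calibrated and detect funnel-shaped spread", {
  set.seed(91)
  # homoscedastic normal residuals: both p-values uniform-ish
  n_ok_norm <- 0; n_ok_bp <- 0
  for (i in 1:100) {
    f <- runif(300, 0.01, 0.1)
    fake <- list(residuals = rnorm(300, 0, 0.01), fitted = f)
    rd <- residual_diagnostics(fake)
    if (rd$normality_p > 0.05) n_ok_norm <- n_ok_norm + 1
    if (rd$homoscedasticity_p > 0.05) n_ok_bp <- n_ok_bp + 1
  }
  expect_gte(n_ok_norm, 85); expect_gte(n_ok_bp, 85)

  # variance growing with the square of the fitted value: detected
  det <- 0
  for (i in 1:50) {
    f <- runif(500, 0.01, 0.1)
    fake <- list(residuals = rnorm(500, 0, f), fitted = f)
    if (residual_diagnostics(fake)$homoscedasticity_p < 0.05) det <- det + 1
  }
  expect_gte(det / 50, 0.9)

  expect_false(residual_diagnostics(
    list(residuals = rnorm(7), fitted = runif(7)))$applicable)
})

test_that("D'Agostino omnibus test broadly agrees with Shapiro-Wilk", {
  set.seed(40)
  x <- rnorm(2000)
  expect_gt(leafallom:::dagostino_k2(x), 0.05)
  y <- rexp(2000)
  expect_lt(leafallom:::dagostino_k2(y), 1e-6)
})

test_that("compare_models selects allometry on curved data and stays honest on straight data", {
  cfg <- sim_config(b_true = 1.4, n_leaves = 1000, seed = 6021)
  cmp <- compare_models(simulate_leaves(cfg))
  expect_equal(cmp$verdict, "strong")
  expect_equal(cmp$favored, "allometric")
  expect_lt(cmp$allometric$aic, cmp$isometric$aic)
  expect_s3_class(cmp$thresholds, "threshold_diagnostics")
  expect_s3_class(cmp$bias, "bias_profile")

  # b = 1 truth: the two families describe the same data
  cfg1 <- sim_config(b_true = 1, n_leaves = 400, seed = 6022)
  cmp1 <- compare_models(simulate_leaves(cfg1))
  expect_lt(abs(cmp1$delta_aic), 10)

  expect_error(compare_models(leaf_records(c(10, 20), c(0.1, 0.2))),
               class = "leafallom_data_error")
})

test_that("comparison reports are deterministic and serialize to JSON", {
  d <- simulate_leaves(sim_config(n_leaves = 300, seed = 8))
  c1 <- compare_models(d); c2 <- compare_models(d)
  c1$allometric$fit$call <- c2$allometric$fit$call <- NULL
  c1$isometric$fit$call <- c2$isometric$fit$call <- NULL
  expect_identical(c1[c("delta_aic", "verdict", "favored")],
                   c2[c("delta_aic", "verdict", "favored")])
  json <- write_report_json(c2)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$schema, "leafallom-report/1")
  expect_equal(parsed$delta_aic, c2$delta_aic)
  expect_true(!is.null(parsed$display$l_star_mm))
})
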