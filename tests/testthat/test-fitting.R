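test_that("log-log starting values are exact on noiseless power-law data", {
  l <- c(20, 50, 120, 260, 500)
  s1 <- loglog_start(power_law_leaves(l, a = 1e-5, b = 1.41))
  expect_equal(unname(s1), c(1e-5, 1.41), tolerance = 1e-10)
  s2 <- loglog_start(power_law_leaves(l, a = 2, b = 1))
  expect_equal(unname(s2), c(2, 1), tolerance = 1e-10)
})

test_that("log-log starting values cope with noise and bad records", {
  set.seed(12)
  l <- rlnorm(10000, log(150), 0.5)
  w <- 1e-5 * l^1.41 * exp(rnorm(10000, 0, 0.1))
  s <- loglog_start(leaf_records(l, w))
  expect_lt(abs(s[["b"]] - 1.41), 0.02)

  r <- leaf_records(c(10, 20, 30, 40), c(0, 0.1, 0.2, 0.3))
  expect_warning(loglog_start(r), class = "leafallom_dropped_records")
  expect_error(
    suppressWarnings(loglog_start(leaf_records(c(10, 20, 30),
                                               c(0, 0, 0.1)))),
    class = "leafallom_data_error")
})

test_that("allometric leaf fit recovers exact and interpolating data", {
  l <- c(30, 80, 150, 320, 610)
  fit <- fit_scaling(power_law_leaves(l, a = 1e-5, b = 1.41), "allometric")
  expect_equal(coef(fit)[["a"]], 1e-5, tolerance = 1e-6)
  expect_equal(coef(fit)[["b"]], 1.41, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)

  fit2 <- fit_scaling(leaf_records(c(1, 2, 5), 3 * c(1, 2, 5)^2),
                      "allometric")
  expect_equal(coef(fit2)[["a"]], 3, tolerance = 1e-6)
  expect_equal(coef(fit2)[["b"]], 2, tolerance = 1e-6)
})

test_that("allometric leaf fit recovers b from heteroscedastic noisy data", {
  set.seed(77)
  b_hat <- replicate(8, {
    l <- rlnorm(1000, log(150), 0.5)
    w <- 1e-5 * l^1.41 * exp(rnorm(1000, 0, 0.2) - 0.02)
    coef(fit_scaling(leaf_records(l, w), "allometric"))[["b"]]
  })
  expect_lt(abs(mean(b_hat) - 1.41), 0.05)
  expect_true(all(abs(b_hat - 1.41) < 0.15))

  set.seed(78)
  l <- rlnorm(500, log(150), 0.5)
  w <- 1e-5 * l^1.41 * exp(rnorm(500, 0, 0.2) - 0.02)
  fit <- fit_scaling(leaf_records(l, w), "allometric")
  expect_true(all(fit$se > 0))
  expect_equal(length(fitted(fit)), 500)
  expect_equal(fit$sigma, sqrt(fit$rss / (fit$n - 2)))
})

test_that("isometric leaf fit is the closed-form origin regression", {
  l <- c(10, 40, 90, 200)
  fit <- fit_scaling(leaf_records(l, 1e-4 * l), "isometric")
  expect_equal(coef(fit)[["c"]], 1e-4, tolerance = 1e-12)
  expect_equal(fit$rss, 0)

  # hand-computed sum(w*l)/sum(l^2) = 3/5
  fit2 <- fit_scaling(leaf_records(c(1, 2), c(1, 1)), "isometric")
  expect_equal(coef(fit2)[["c"]], 3 / 5, tolerance = 1e-12)

  expect_error(fit_scaling(leaf_records(5, 0.5), "isometric"),
               class = "leafallom_data_error")
})

test_that("shoot fits agree with leaf fits and hand calculations", {
  set.seed(21)
  lens <- lapply(1:30, function(i) runif(sample(3:6, 1), 20, 500))
  w <- shoot_weight_allometric(lens, a = 1e-5, b = 1.41)
  sh <- shoot_records(lens, w)
  fit <- fit_scaling(sh, "allometric")
  expect_equal(coef(fit)[["a"]], 1e-5, tolerance = 1e-5)
  expect_equal(coef(fit)[["b"]], 1.41, tolerance = 1e-6)

  # single-leaf shoots reduce to the leaf-level fit
  l <- c(30, 80, 150, 320, 610)
  wl <- 1e-5 * l^1.41 * c(1.1, 0.9, 1.05, 0.97, 1.02)
  leaf_fit <- fit_scaling(leaf_records(l, wl), "allometric")
  shoot_fit <- fit_scaling(shoot_records(as.list(l), wl), "allometric")
  expect_equal(coef(shoot_fit), coef(leaf_fit), tolerance = 1e-8)
  iso_leaf <- fit_scaling(leaf_records(l, wl), "isometric")
  iso_shoot <- fit_scaling(shoot_records(as.list(l), wl), "isometric")
  expect_equal(coef(iso_shoot), coef(iso_leaf), tolerance = 1e-12)

  # two shoots with totals (10, 1) and (20, 1): c = 30/500
  sh2 <- shoot_records(list(c(4, 6), c(12, 8)), c(1, 1))
  expect_equal(coef(fit_scaling(sh2, "isometric"))[["c"]], 0.06,
               tolerance = 1e-12)
})

test_that("noisy shoot aggregates still recover the exponent", {
  cfg <- sim_config(noise = list("multiplicative", sigma = 0.1),
                    n_shoots = 500, seed = 404)
  sh <- simulate_shoots(cfg)
  fit <- fit_scaling(sh, "allometric")
  expect_lt(abs(coef(fit)[["b"]] - cfg$b_true), 0.05)
})

test_that("profile optimum matches a dense grid search", {
  set.seed(5)
  l <- runif(18, 20, 500)
  w <- 1.3e-5 * l^1.38 * exp(rnorm(18, 0, 0.15))
  fit <- fit_scaling(leaf_records(l, w), "allometric")
  oracle <- grid_allometric(as.list(l), w, seq(1.0, 1.8, by = 1e-4))
  expect_lt(abs(coef(fit)[["b"]] - oracle$b), 1e-4)
  expect_lte(fit$rss, oracle$rss + 1e-12)
})

test_that("the allometric family never fits worse than the isometric slice", {
  set.seed(8)
  for (i in 1:5) {
    l <- runif(40, 10, 600)
    w <- 10^runif(1, -5, -4) * l^runif(1, 0.8, 1.6) *
      exp(rnorm(40, 0, 0.3))
    r <- leaf_records(l, w)
    allo <- fit_scaling(r, "allometric")
    iso <- fit_scaling(r, "isometric")
    expect_lte(allo$rss, iso$rss * (1 + 1e-10))
  }
})

test_that("degenerate and undersized data are rejected; missing weights are excluded with a message", {
  expect_error(fit_scaling(leaf_records(c(100, 100, 100), c(1, 2, 3))),
               class = "leafallom_data_error")
  expect_error(fit_scaling(leaf_records(c(100, 200), c(1, 2)), "allometric"),
               class = "leafallom_data_error")
  r <- leaf_records(c(30, 80, 150, 320), c(0.01, 0.03, NA, 0.1))
  expect_message(fit_scaling(r, "isometric"), "1 record")
})

test_that("log-scale fitting matches the log-log regression", {
  set.seed(99)
  l <- rlnorm(300, log(150), 0.5)
  w <- 1e-5 * l^1.41 * exp(rnorm(300, 0, 0.2))
  fit <- fit_scaling(leaf_records(l, w), "allometric", scale = "log")
  ref <- lm(log(w) ~ log(l))
  expect_equal(coef(fit)[["b"]], unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(coef(fit)[["a"]], exp(unname(coef(ref)[1])), tolerance = 1e-12)
  expect_equal(fit$sigma, summary(ref)$sigma, tolerance = 1e-12)
})
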