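sq <- list(a = 1e-5, b = 1.410012, c = 1e-4)   # San Quintin printed fits

test_that("deviation function matches its closed form and b = 1 convention", {
  expect_equal(theta_deviation(123, a = 2e-5, b = 1, c = 3e-4), 0)
  expect_equal(theta_deviation(100, sq$a, sq$b, sq$c),
               0.00339270039714316, tolerance = 1e-12)
  l_star <- threshold_length(sq$a, sq$b, sq$c)
  expect_equal(theta_deviation(l_star, sq$a, sq$b, sq$c), 0,
               tolerance = 1e-15)
})

test_that("threshold length reproduces printed and hand-derived values", {
  expect_equal(threshold_length(sq$a, sq$b, sq$c), 274.8, tolerance = 5e-4)
  expect_equal(threshold_length(a = 0.3, b = 2, c = 0.3), 1)
  # printed mesocosm parameters imply ~996 mm (not the printed threshold,
  # which is extremely sensitive to rounding of b)
  expect_equal(threshold_length(0.000104, 1.1628, 0.00032),
               996.000263790924, tolerance = 1e-9)
  expect_error(threshold_length(1e-5, 1, 1e-4),
               class = "leafallom_undefined_threshold")
})

test_that("maximum-deviation length sits between 0 and the threshold", {
  expect_equal(max_deviation_length(sq$a, sq$b, sq$c), 118.851752041093,
               tolerance = 1e-9)
  expect_equal(max_deviation_length(1, 2, 1), 0.5)
  tr <- random_triples(40, seed = 61)
  for (i in seq_len(nrow(tr))) {
    ltm <- max_deviation_length(tr$a[i], tr$b[i], tr$c[i])
    ls <- threshold_length(tr$a[i], tr$b[i], tr$c[i])
    expect_gt(ltm, 0)
    expect_lt(ltm, ls)
    # the deviation's derivative vanishes there
    expect_equal(tr$c[i] - tr$a[i] * tr$b[i] * ltm^(tr$b[i] - 1), 0,
                 tolerance = 1e-12 * tr$c[i])
  }
  expect_error(max_deviation_length(1e-5, 1, 1e-4),
               class = "leafallom_undefined_threshold")
})

test_that("maximum absolute deviation: closed form, identity and sign structure", {
  expect_equal(max_abs_deviation(sq$a, sq$b, sq$c), 0.0035, tolerance = 2e-2)
  expect_equal(max_abs_deviation(1e-5, 1, 1e-4), 0)
  tr <- random_triples(40, seed = 62)
  for (i in seq_len(nrow(tr))) {
    a <- tr$a[i]; b <- tr$b[i]; cc <- tr$c[i]
    tm <- max_abs_deviation(a, b, cc)
    ltm <- max_deviation_length(a, b, cc)
    ls <- threshold_length(a, b, cc)
    expect_equal(tm, abs(theta_deviation(ltm, a, b, cc)),
                 tolerance = 1e-12)
    # sign flips across the threshold; direction reverses for b < 1
    th_in <- theta_deviation(0.5 * ls, a, b, cc)
    th_out <- theta_deviation(1.5 * ls, a, b, cc)
    if (b > 1) {
      expect_gt(th_in, 0); expect_lt(th_out, 0)
    } else {
      expect_lt(th_in, 0); expect_gt(th_out, 0)
    }
  }
})

test_that("closed-form maximum deviation agrees with grid maximization", {
  tr <- random_triples(25, seed = 63)
  for (i in seq_len(nrow(tr))) {
    expect_equal(max_abs_deviation(tr$a[i], tr$b[i], tr$c[i]),
                 grid_theta_max(tr$a[i], tr$b[i], tr$c[i], n_grid = 2e5),
                 tolerance = 1e-6)
  }
})

test_that("threshold partition counts strictly, with ties below", {
  expect_equal(threshold_partition(c(50, 100, 300), 274.8),
               c(pct_below = 200 / 3, pct_above = 100 / 3))
  expect_equal(threshold_partition(c(10, 20), 100),
               c(pct_below = 100, pct_above = 0))
  expect_equal(unname(threshold_partition(c(50, 100), 100)["pct_below"]),
               100)  # tie counted below
  expect_error(threshold_partition(numeric(0), 100),
               class = "leafallom_domain_error")
})

test_that("preset populations hit their configured below-threshold share", {
  cfg <- sim_preset("san-quintin", n_leaves = 2000, seed = 314)
  d <- simulate_leaves(cfg)
  l_star <- threshold_length(cfg$a_true, cfg$b_true, cfg$c_ref)
  part <- threshold_partition(d$length_mm, l_star)
  expect_lt(abs(part[["pct_below"]] - cfg$target_pct_below), 3)

  cfg2 <- sim_preset("mesocosm", n_leaves = 2000, seed = 315)
  d2 <- simulate_leaves(cfg2)
  part2 <- threshold_partition(
    d2$length_mm, threshold_length(cfg2$a_true, cfg2$b_true, cfg2$c_ref))
  expect_lt(abs(part2[["pct_below"]] - cfg2$target_pct_below), 3)
})

test_that("threshold diagnostics bundle fitted parameter pairs", {
  d <- threshold_diagnostics(c(a = sq$a, b = sq$b), c(c = sq$c),
                             lengths = c(120, 180, 250, 320))
  expect_s3_class(d, "threshold_diagnostics")
  expect_equal(d$l_star, 274.8, tolerance = 5e-4)
  expect_lt(d$l_theta_max, d$l_star)
  expect_equal(d$pct_below + d$pct_above, 100)
  expect_equal(d$pct_below, 75)
})

test_that("bias profile captures proxy underestimation beyond the threshold", {
  # noiseless allometric data, b > 1: beyond l*, c l < a l^b = w always
  l <- seq(20, 700, by = 10)
  r <- power_law_leaves(l, a = sq$a, b = sq$b)
  iso <- fit_scaling(r, "isometric")
  bp <- bias_profile(r, c(a = sq$a, b = sq$b), iso)
  expect_equal(bp$fraction_underestimated_above_threshold, 1)
  expect_true(all(bp$per_leaf$rel_error[l > bp$l_star] < 0))

  # b = 1 with c = a: the proxy is exact
  r2 <- leaf_records(l, 2e-4 * l)
  bp2 <- bias_profile(r2, c(a = 2e-4, b = 1), c(c = 2e-4))
  expect_equal(bp2$per_leaf$rel_error, rep(0, length(l)))
  expect_equal(bp2$mean_abs_rel_error, 0)

  # zero-weight records are excluded with a warning
  r3 <- leaf_records(c(l, 50), c(sq$a * l^sq$b, 0))
  expect_warning(bias_profile(r3, c(a = sq$a, b = sq$b), c(c = sq$c)),
                 class = "leafallom_dropped_records")
})

test_that("mesocosm-like data are predominantly underestimated beyond the threshold", {
  # evaluated at the population's published parameters: beyond l* the proxy
  # line lies below the conditional mean, so most observations there exceed
  # it; below l* the opposite holds
  cfg <- sim_preset("mesocosm", n_leaves = 1000, seed = 2024)
  d <- simulate_leaves(cfg)
  bp <- bias_profile(d, c(a = cfg$a_true, b = cfg$b_true), c(c = cfg$c_ref))
  expect_gt(bp$fraction_underestimated_above_threshold, 0.5)
  below <- bp$per_leaf$length_mm <= bp$l_star
  frac_below <- mean(bp$per_leaf$rel_error[below] < 0)
  expect_gt(bp$fraction_underestimated_above_threshold, frac_below)
  expect_gt(bp$fraction_underestimated, 0.5)
})
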