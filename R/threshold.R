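#' Deviation between isometric and allometric weight predictions
#'
#' The deviation function \eqn{\theta(l) = c l - a l^b} (for \eqn{b \neq 1})
#' measures, at leaf length \eqn{l}, how far the isometric proxy's predicted
#' weight lies from the allometric prediction. It is defined to be
#' identically zero at \eqn{b = 1}, where the two model families coincide up
#' to the value of the constant. For \eqn{b > 1}, \eqn{\theta > 0} below the
#' threshold length and \eqn{\theta < 0} beyond it (the proxy underestimates
#' long leaves); for \eqn{b < 1} the signs reverse.
#'
#' @param l leaf length(s), mm, >= 0.
#' @param a,b allometric parameters (a > 0, b > 0).
#' @param c isometric weight-to-length ratio (> 0), g/mm.
#' @return deviation(s) in g.
#' @examples
#' theta_deviation(100, a = 1e-5, b = 1.410012, c = 1e-4)
#' @export
theta_deviation <- function(l, a, b, c) {
  check_scaling_params(a = a, b = b, c = c)
  check_lengths(l)
  if (b == 1) return(rep(0, length(l)))
  l * (c - a * l^(b - 1))
}

#' Threshold leaf length where the two models intersect
#'
#' For \eqn{b \neq 1} the isometric line \eqn{c l} crosses the allometric
#' curve \eqn{a l^b} at the origin and at one nonvanishing threshold
#' \eqn{l_* = (c/a)^{1/(b-1)}}; beyond \eqn{l_*} the two models' predictions
#' diverge with opposite sign. At \eqn{b = 1} the models are proportional and
#' no finite threshold exists: a `leafallom_undefined_threshold` error is
#' raised so callers must branch on that case explicitly.
#'
#' @inheritParams theta_deviation
#' @return threshold length \eqn{l_*} in mm.
#' @examples
#' threshold_length(a = 1e-5, b = 1.410012, c = 1e-4)  # 274.8 mm
#' @export
threshold_length <- function(a, b, c) {
  check_scaling_params(a = a, b = b, c = c)
  if (b == 1) {
    stop_leafallom("leafallom_undefined_threshold",
                   "threshold length is undefined at b = 1 (models are proportional)")
  }
  (c / a)^(1 / (b - 1))
}

#' Length of maximum deviation
#'
#' The absolute deviation \eqn{|\theta(l)|} on \eqn{(0, l_*)} peaks where
#' \eqn{d\theta/dl = c - a b l^{b-1}} vanishes, at
#' \eqn{l_{\theta m} = l_* b^{-1/(b-1)} = (c/(a b))^{1/(b-1)}}, which always
#' satisfies \eqn{0 < l_{\theta m} < l_*}.
#'
#' @inheritParams theta_deviation
#' @return \eqn{l_{\theta m}} in mm.
#' @export
max_deviation_length <- function(a, b, c) {
  threshold_length(a, b, c) * b^(-1 / (b - 1))
}

#' Maximum absolute deviation between the models
#'
#' Closed-form maximum of \eqn{|\theta(l)|} over \eqn{(0, l_*)}:
#' \eqn{\theta_{max} = (c/(a b))^{b/(b-1)} \, a \, |b - 1|}, attained at
#' [max_deviation_length()]. When \eqn{\theta_{max}} is small relative to
#' the residual standard errors of the fits, the two models are practically
#' indistinguishable below the threshold. Returns 0 at \eqn{b = 1} (the
#' deviation function is identically zero there).
#'
#' @inheritParams theta_deviation
#' @return \eqn{\theta_{max}} in g.
#' @examples
#' max_abs_deviation(a = 1e-5, b = 1.410012, c = 1e-4)   # ~0.0035 g
#' max_abs_deviation(a = 0.000104, b = 1.1628, c = 0.00032)  # ~0.018 g
#' @export
max_abs_deviation <- function(a, b, c) {
  check_scaling_params(a = a, b = b, c = c)
  if (b == 1) return(0)
  (c / (a * b))^(b / (b - 1)) * a * abs(b - 1)
}

#' Partition a length sample at the threshold
#'
#' Percentages of a leaf-length sample lying below and above the threshold
#' length. Ties (lengths exactly at `l_star`) are counted as "below";
#' percentages are returned unrounded (round only at presentation).
#'
#' @param lengths numeric vector of leaf lengths (mm), nonempty.
#' @param l_star threshold length (mm), > 0.
#' @return named numeric `c(pct_below = ..., pct_above = ...)`, summing
#'   to 100.
#' @examples
#' threshold_partition(c(50, 100, 300), 274.8)
#' @export
threshold_partition <- function(lengths, l_star) {
  check_lengths(lengths)
  if (!is.finite(l_star) || l_star <= 0) {
    stop_leafallom("leafallom_domain_error", "l_star must be positive")
  }
  below <- mean(lengths <= l_star) * 100
  c(pct_below = below, pct_above = 100 - below)
}

#' Threshold diagnostics for a fitted model pair
#'
#' Bundles the closed-form deviation analysis for fitted allometric
#' \eqn{(a, b)} and isometric \eqn{(c)} parameters with an observed length
#' sample: the threshold length \eqn{l_*}, the location \eqn{l_{\theta m}}
#' and size \eqn{\theta_{max}} of the maximum deviation, and the
#' below/above-threshold partition of the sample.
#'
#' @param allometric a `scaling_fit` with `model = "allometric"`, or a named
#'   vector/list with `a` and `b`.
#' @param isometric a `scaling_fit` with `model = "isometric"`, or a named
#'   vector/list with `c`.
#' @param lengths leaf lengths (mm) to partition; defaults to the lengths
#'   stored in the allometric fit when available.
#' @return object of class `"threshold_diagnostics"`: list with `a`, `b`,
#'   `c`, `l_star`, `l_theta_max`, `theta_max`, `pct_below`, `pct_above`, `n`.
#' @examples
#' threshold_diagnostics(c(a = 1e-5, b = 1.410012), c(c = 1e-4),
#'                       lengths = c(120, 180, 250, 320))
#' @export
threshold_diagnostics <- function(allometric, isometric, lengths = NULL) {
  ab <- extract_params(allometric, c("a", "b"))
  cc <- extract_params(isometric, "c")
  if (is.null(lengths) && inherits(allometric, "scaling_fit")) {
    lengths <- unlist(allometric$lengths)
  }
  if (is.null(lengths)) {
    stop_leafallom("leafallom_data_error",
                   "a length sample is required for the threshold partition")
  }
  l_star <- threshold_length(ab[["a"]], ab[["b"]], cc[["c"]])
  part <- threshold_partition(lengths, l_star)
  structure(list(
    a = ab[["a"]], b = ab[["b"]], c = cc[["c"]],
    l_star = l_star,
    l_theta_max = max_deviation_length(ab[["a"]], ab[["b"]], cc[["c"]]),
    theta_max = max_abs_deviation(ab[["a"]], ab[["b"]], cc[["c"]]),
    pct_below = unname(part["pct_below"]),
    pct_above = unname(part["pct_above"]),
    n = length(lengths)
  ), class = "threshold_diagnostics")
}

#' @export
print.threshold_diagnostics <- function(x, ...) {
  cat("Threshold diagnostics (isometric vs allometric)\n")
  cat(sprintf("  a = %s, b = %s, c = %s\n",
              signif(x$a, 6), signif(x$b, 7), signif(x$c, 6)))
  cat(sprintf("  threshold length l*        : %.1f mm\n", x$l_star))
  cat(sprintf("  max-deviation length l_tm  : %.1f mm\n", x$l_theta_max))
  cat(sprintf("  max |deviation| theta_max  : %s g\n", signif(x$theta_max, 2)))
  cat(sprintf("  lengths below / above l*   : %.0f%% / %.0f%%  (n = %d)\n",
              x$pct_below, x$pct_above, x$n))
  invisible(x)
}

#' Bias profile of the isometric weight-to-length proxy
#'
#' Per-leaf comparison of the isometric proxy against observed weights:
#' deviation \eqn{\theta(l)} against the allometric fit, relative error
#' \eqn{(c l - w)/w} against the observation, the fraction of observed
#' weights underestimated by the proxy (overall and restricted to leaves
#' beyond the threshold), and the mean absolute relative miscalculation.
#' Records with zero observed weight are excluded with a warning (relative
#' error undefined).
#'
#' @param records [leaf_records()] with weights.
#' @param allometric,isometric fitted parameters as in
#'   [threshold_diagnostics()].
#' @return object of class `"bias_profile"`: list with `per_leaf`
#'   (data.frame: `length_mm`, `theta_g`, `rel_error`),
#'   `fraction_underestimated`, `fraction_underestimated_above_threshold`
#'   (`NA` if no leaf lies beyond `l_star`), `mean_abs_rel_error`, `l_star`.
#' @export
bias_profile <- function(records, allometric, isometric) {
  records <- as_leaf_records(records)
  ab <- extract_params(allometric, c("a", "b"))
  cc <- extract_params(isometric, "c")
  keep <- !is.na(records$weight_g)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop_leafallom("leafallom_data_error", "no records with weights")
  }
  zero_w <- records$weight_g == 0
  if (any(zero_w)) {
    warn_leafallom("leafallom_dropped_records", sprintf(
      "%d record(s) with zero observed weight excluded from the bias profile",
      sum(zero_w)))
    records <- records[!zero_w, , drop = FALSE]
  }
  l <- records$length_mm
  w <- records$weight_g
  iso_pred <- cc[["c"]] * l
  theta <- theta_deviation(l, ab[["a"]], ab[["b"]], cc[["c"]])
  rel <- (iso_pred - w) / w
  l_star <- if (ab[["b"]] == 1) NA_real_ else
    threshold_length(ab[["a"]], ab[["b"]], cc[["c"]])
  above <- if (is.na(l_star)) rep(FALSE, length(l)) else l > l_star
  structure(list(
    per_leaf = data.frame(length_mm = l, theta_g = theta, rel_error = rel),
    fraction_underestimated = mean(iso_pred < w),
    fraction_underestimated_above_threshold =
      if (any(above)) mean(iso_pred[above] < w[above]) else NA_real_,
    mean_abs_rel_error = mean(abs(rel)),
    l_star = l_star, n = length(l)
  ), class = "bias_profile")
}

#' @export
print.bias_profile <- function(x, ...) {
  cat("Bias profile of the isometric weight-to-length proxy\n")
  cat(sprintf("  n = %d leaves; threshold l* = %s mm\n", x$n,
              if (is.na(x$l_star)) "undefined (b = 1)" else
                sprintf("%.1f", x$l_star)))
  cat(sprintf("  fraction underestimated (all leaves)  : %.2f\n",
              x$fraction_underestimated))
  if (!is.na(x$fraction_underestimated_above_threshold)) {
    cat(sprintf("  fraction underestimated (l > l*)      : %.2f\n",
                x$fraction_underestimated_above_threshold))
  }
  cat(sprintf("  mean |relative miscalculation|        : %.1f%%\n",
              100 * x$mean_abs_rel_error))
  invisible(x)
}

# pull named parameters out of a scaling_fit / named vector / list
extract_params <- function(x, wanted) {
  src <- if (inherits(x, "scaling_fit")) x$coefficients else unlist(x)
  if (!all(wanted %in% names(src))) {
    stop_leafallom("leafallom_domain_error", sprintf(
      "expected parameter(s) %s", paste(wanted, collapse = ", ")))
  }
  as.list(src[wanted])
}
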