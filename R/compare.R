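#' Side-by-side comparison of the allometric and isometric models
#'
#' Runs the full selection battery on one dataset: both least-squares fits,
#' fit-quality statistics (R^2, Lin's CCC, residual standard error), the
#' Gaussian AIC of each model and their difference, a lack-of-fit F test and
#' paired observed-vs-predicted means test per model, residual normality and
#' homoscedasticity checks, the closed-form threshold diagnostics computed
#' from the fitted \eqn{(a, b, c)}, and the bias profile of the isometric
#' proxy against the observed weights.
#'
#' The AIC verdict follows the conventional evidence bands for AIC
#' differences: `"strong"` when \eqn{|\Delta AIC| > 10}, `"positive"` when
#' \eqn{4 < |\Delta AIC| \le 10}, `"indistinguishable"` otherwise, with
#' `delta_aic = AIC_isometric - AIC_allometric` (positive favours the
#' allometric model). The diagnostic p-values are reported raw, without
#' multiplicity adjustment.
#'
#' Deterministic given the data and settings.
#'
#' @param data [leaf_records()] (with weights) or [shoot_records()].
#' @param resolution replicate-grouping resolution (mm) for the lack-of-fit
#'   test, see [lack_of_fit_test()].
#' @param scale fitting scale passed to [fit_scaling()].
#' @param ccc_denominator passed to [concordance_correlation()].
#' @return object of class `"model_comparison"`: list with `allometric` and
#'   `isometric` blocks (each: `fit`, `r_squared`, `ccc`, `aic`,
#'   `lack_of_fit`, `mean_test`, `residual_diagnostics`), `delta_aic`,
#'   `favored`, `verdict`, `thresholds` ([threshold_diagnostics()]; `NULL`
#'   if the fitted b is exactly 1), and `bias` ([bias_profile()]; leaf data
#'   only).
#' @examples
#' cfg <- sim_config(n_leaves = 300, seed = 42)
#' cmp <- compare_models(simulate_leaves(cfg))
#' cmp$verdict
#' @export
compare_models <- function(data, resolution = 1, scale = "raw",
                           ccc_denominator = "n") {
  allo <- fit_scaling(data, model = "allometric", scale = scale)
  iso <- fit_scaling(data, model = "isometric", scale = scale)

  stage <- function(expr, what) {
    tryCatch(expr, leafallom_error = function(e) {
      e$message <- sprintf("[%s] %s", what, e$message)
      stop(e)
    })
  }

  block <- function(fit) {
    obs <- if (fit$scale == "log") log(fit$observed) else fit$observed
    L <- if (fit$level == "leaf") fit$lengths else
      vapply(fit$lengths, sum, numeric(1))
    list(
      fit = fit,
      r_squared = stage(r_squared(obs, fit$fitted), "r_squared"),
      ccc = stage(concordance_correlation(obs, fit$fitted,
                                          denominator = ccc_denominator),
                  "ccc"),
      aic = stage(aic_ls(fit), "aic"),
      lack_of_fit = stage(
        lack_of_fit_test(L, obs, fit$fitted,
                         n_params = length(fit$coefficients),
                         resolution = resolution), "lack_of_fit"),
      mean_test = stage(mean_difference_test(obs, fit$fitted), "mean_test"),
      residual_diagnostics = stage(residual_diagnostics(fit),
                                   "residual_diagnostics")
    )
  }

  ba <- block(allo)
  bi <- block(iso)
  delta <- bi$aic - ba$aic
  verdict <- if (abs(delta) > 10) "strong"
             else if (abs(delta) > 4) "positive"
             else "indistinguishable"

  b_hat <- allo$coefficients[["b"]]
  thresholds <- if (b_hat == 1) NULL else stage(
    threshold_diagnostics(allo, iso, lengths = unlist(allo$lengths)),
    "thresholds")
  bias <- if (allo$level == "leaf") stage(
    bias_profile(allo$data, allo, iso), "bias") else NULL

  structure(list(
    allometric = ba, isometric = bi,
    delta_aic = delta,
    favored = if (delta > 0) "allometric" else if (delta < 0) "isometric"
              else "neither",
    verdict = verdict,
    thresholds = thresholds, bias = bias,
    settings = list(resolution = resolution, scale = scale,
                    ccc_denominator = ccc_denominator)
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  fmt_p <- function(p) if (is.null(p)) "NA" else format.pval(p, digits = 3)
  row <- function(b) {
    cf <- b$fit$coefficients; se <- b$fit$se
    pars <- paste(sprintf("%s = %s +/- %s", names(cf), signif(cf, 6),
                          signif(se, 3)), collapse = ", ")
    lof <- if (isTRUE(b$lack_of_fit$applicable)) {
      sprintf("F(%d,%d) = %.3g, p = %s", b$lack_of_fit$df_lof,
              b$lack_of_fit$df_pe, b$lack_of_fit$statistic,
              fmt_p(b$lack_of_fit$p.value))
    } else "n/a"
    rd <- b$residual_diagnostics
    cat(sprintf("  parameters     : %s\n", pars))
    cat(sprintf("  R^2 = %.4f   CCC = %.4f   se_fit = %s   AIC = %.2f\n",
                b$r_squared, b$ccc, signif(b$fit$sigma, 3), b$aic))
    cat(sprintf("  lack of fit    : %s\n", lof))
    cat(sprintf("  means test p   : %s\n", fmt_p(b$mean_test$p.value)))
    if (isTRUE(rd$applicable)) {
      cat(sprintf("  residuals      : normality p = %s (%s), homoscedasticity p = %s\n",
                  fmt_p(rd$normality_p), rd$normality_method,
                  fmt_p(rd$homoscedasticity_p)))
    } else {
      cat("  residuals      : diagnostics n/a\n")
    }
  }
  cat("Model comparison: allometric (w = a l^b) vs isometric (w = c l)\n")
  cat("----------------------------------------------------------------\n")
  cat("Allometric model\n"); row(x$allometric)
  cat("Isometric model\n"); row(x$isometric)
  cat("----------------------------------------------------------------\n")
  cat(sprintf("delta AIC (iso - allo) = %.2f  ->  %s (favours %s)\n",
              x$delta_aic, x$verdict, x$favored))
  if (!is.null(x$thresholds)) {
    cat("\n"); print(x$thresholds)
  }
  if (!is.null(x$bias)) {
    cat("\n"); print(x$bias)
  }
  cat("\n(p-values are reported raw; no multiplicity adjustment)\n")
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Writes a versioned JSON document with full-precision values plus a
#' `display` block rounded to the precision conventionally used in printed
#' tables (threshold length to 1 decimal mm, theta_max to 2 significant
#' figures).
#'
#' @param x a [compare_models()] result.
#' @param path file path to write; `NULL` returns the JSON string.
#' @return invisibly, the JSON string.
#' @export
write_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "model_comparison"))
  blk <- function(b) list(
    coefficients = as.list(b$fit$coefficients),
    se = as.list(b$fit$se),
    n = b$fit$n, rss = b$fit$rss, se_fit = b$fit$sigma,
    r_squared = b$r_squared, ccc = b$ccc, aic = b$aic,
    lack_of_fit = unclass(b$lack_of_fit),
    mean_test = b$mean_test,
    residual_diagnostics = b$residual_diagnostics)
  doc <- list(
    schema = "leafallom-report/1",
    allometric = blk(x$allometric),
    isometric = blk(x$isometric),
    delta_aic = x$delta_aic, favored = x$favored, verdict = x$verdict,
    thresholds = if (!is.null(x$thresholds)) unclass(x$thresholds),
    bias = if (!is.null(x$bias)) {
      b <- unclass(x$bias); b$per_leaf <- NULL; b
    },
    settings = x$settings)
  if (!is.null(x$thresholds)) {
    doc$display <- list(
      l_star_mm = round(x$thresholds$l_star, 1),
      l_theta_max_mm = round(x$thresholds$l_theta_max, 1),
      theta_max_g = signif(x$thresholds$theta_max, 2),
      pct_below = round(x$thresholds$pct_below),
      pct_above = round(x$thresholds$pct_above))
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(json)
}
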