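#' @export
print.scaling_fit <- function(x, digits = 6, ...) {
  cat(sprintf("%s scaling fit (%s-level, %s scale)\n",
              capitalize(x$model), x$level, x$scale))
  cf <- format(signif(x$coefficients, digits))
  se <- format(signif(x$se, digits))
  for (i in seq_along(cf)) {
    cat(sprintf("  %s = %s +/- %s\n", names(x$coefficients)[i], cf[i], se[i]))
  }
  cat(sprintf("  n = %d, rss = %s, se_fit = %s\n",
              x$n, format(signif(x$rss, digits)),
              format(signif(x$sigma, digits))))
  invisible(x)
}

#' Summarise a scaling fit
#'
#' Augments the fit with the agreement statistics conventionally reported
#' for leaf scaling fits: the determination coefficient R^2 of observed
#' against model-predicted weights and Lin's concordance correlation
#' coefficient (rho-hat), plus parameter standard errors and the residual
#' standard error of the fit.
#'
#' @param object a [fit_scaling()] result.
#' @param robust use the HC3 heteroscedasticity-consistent standard errors
#'   instead of the classical Gauss-Newton ones.
#' @param ... unused.
#' @export
summary.scaling_fit <- function(object, robust = FALSE, ...) {
  se <- if (robust) sqrt(diag(object$vcov_robust)) else object$se
  obs <- if (object$scale == "log") log(object$observed) else object$observed
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  out <- list(model = object$model, level = object$level, scale = object$scale,
              coefficients = tab, n = object$n, rss = object$rss,
              sigma = object$sigma,
              r_squared = r_squared(obs, object$fitted),
              ccc = concordance_correlation(obs, object$fitted),
              robust = robust)
  class(out) <- "summary.scaling_fit"
  out
}

capitalize <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))

#' @export
print.summary.scaling_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s scaling fit (%s-level, %s scale)\n\n",
              capitalize(x$model), x$level, x$scale))
  printCoefmat(signif(x$coefficients, digits + 2))
  cat(sprintf("\nn = %d   R^2 = %.*f   CCC (rho-hat) = %.*f   se_fit = %s\n",
              x$n, digits, x$r_squared, digits, x$ccc,
              format(signif(x$sigma, digits))))
  if (x$robust) cat("(standard errors: HC3 heteroscedasticity-consistent)\n")
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) object$coefficients

#' @export
#' @rdname summary.scaling_fit
#' @param x,object a `scaling_fit`.
vcov.scaling_fit <- function(object, robust = FALSE, ...) {
  if (robust) object$vcov_robust else object$vcov
}

#' @export
fitted.scaling_fit <- function(object, ...) object$fitted

#' @export
residuals.scaling_fit <- function(object, ...) object$residuals

#' @export
nobs.scaling_fit <- function(object, ...) object$n

#' Predict weights from a fitted scaling model
#'
#' @param object a [fit_scaling()] result.
#' @param newdata lengths to predict at: a numeric vector of leaf lengths
#'   (mm), a [leaf_records()] table, a list of per-shoot length vectors, or a
#'   [shoot_records()] table. Omitted: the fitted values' inputs.
#' @param ... unused.
#' @return predicted weights (g), one per leaf or per shoot.
#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$lengths
  cf <- object$coefficients
  shootish <- inherits(newdata, "shoot_records") ||
    (is.list(newdata) && !is.data.frame(newdata))
  if (inherits(newdata, "leaf_records") || is.data.frame(newdata)) {
    newdata <- as_leaf_records(newdata)$length_mm
  }
  if (object$model == "allometric") {
    if (shootish) shoot_weight_allometric(newdata, cf[["a"]], cf[["b"]])
    else allometric_weight(newdata, cf[["a"]], cf[["b"]])
  } else {
    if (shootish) shoot_weight_isometric(newdata, cf[["c"]])
    else isometric_weight(newdata, cf[["c"]])
  }
}

#' @export
confint.scaling_fit <- function(object, parm, level = 0.95, robust = FALSE,
                                ...) {
  cf <- object$coefficients
  se <- if (robust) sqrt(diag(object$vcov_robust)) else object$se
  if (missing(parm)) parm <- names(cf)
  q <- stats::qt(1 - (1 - level) / 2, df = object$df.residual)
  out <- cbind(cf[parm] - q * se[parm], cf[parm] + q * se[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
logLik.scaling_fit <- function(object, ...) {
  n <- object$n
  p <- length(object$coefficients)
  val <- -n / 2 * (log(2 * pi) + log(object$rss / n) + 1)
  structure(val, df = p + 1L, nobs = n, class = "logLik")
}

#' Simulate responses from a fitted scaling model
#'
#' Parametric simulation at the fit's observed lengths: Gaussian additive
#' noise with the fitted residual standard error for raw-scale fits, and
#' multiplicative lognormal noise (log-scale residual sd) for log-scale
#' fits.
#'
#' @param object a [fit_scaling()] result.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param ... unused.
#' @return `data.frame` with `nsim` columns of simulated weights (g).
#' @export
simulate.scaling_fit <- function(object, nsim = 1, seed = NULL, ...) {
  expr <- function() {
    n <- object$n
    mu <- if (object$scale == "log") exp(object$fitted) else object$fitted
    sims <- replicate(nsim, {
      if (object$scale == "log") {
        mu * exp(stats::rnorm(n, 0, object$sigma))
      } else {
        object$fitted + stats::rnorm(n, 0, object$sigma)
      }
    })
    as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  }
  if (is.null(seed)) expr() else with_seed(seed, expr())
}

#' Diagnostic plots for a scaling fit
#'
#' Two base-graphics panels: observed versus predicted weights with the
#' identity line, and residuals against fitted values.
#'
#' @param x a [fit_scaling()] result.
#' @param which subset of `1:2` selecting the panels.
#' @param ... passed to [plot()].
#' @export
plot.scaling_fit <- function(x, which = 1:2, ...) {
  obs <- if (x$scale == "log") log(x$observed) else x$observed
  lab <- if (x$scale == "log") "log weight" else "weight (g)"
  if (1 %in% which) {
    plot(x$fitted, obs, xlab = paste("predicted", lab),
         ylab = paste("observed", lab),
         main = sprintf("%s fit: observed vs predicted", x$model), ...)
    abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    plot(x$fitted, x$residuals, xlab = paste("fitted", lab),
         ylab = "residual", main = "Residuals vs fitted", ...)
    abline(h = 0, lty = 2)
  }
  invisible(x)
}
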