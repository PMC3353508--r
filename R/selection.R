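#' Determination coefficient of observed vs predicted values
#'
#' \eqn{R^2 = 1 - \sum (o_i - p_i)^2 / \sum (o_i - \bar o)^2}. For a model
#' without a fitted intercept (regression through the origin, nonlinear
#' power law) this can be negative; it is at most 1.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return dimensionless scalar in \eqn{(-\infty, 1]}.
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop_leafallom("leafallom_domain_error",
                   "observed values have zero variance; R^2 undefined")
  }
  1 - sum((observed - predicted)^2) / sst
}

#' Lin's concordance correlation coefficient
#'
#' Agreement statistic
#' \eqn{\hat\rho = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' penalising both imprecision (scatter about the best line) and
#' location/scale shift away from the identity line. Unlike Pearson's r it
#' only reaches 1 when predictions reproduce observations exactly; always
#' \eqn{|\hat\rho| \le |r|}.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2), not
#'   both constant.
#' @param denominator moment estimators with `"n"` (Lin's original, the
#'   default) or `"n-1"` denominators; the choice only rescales all three
#'   moments and therefore matters only through the squared mean difference
#'   term.
#' @return \eqn{\hat\rho \in [-1, 1]}.
#' @examples
#' concordance_correlation(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
concordance_correlation <- function(observed, predicted,
                                    denominator = c("n", "n-1")) {
  check_paired(observed, predicted)
  denominator <- match.arg(denominator)
  n <- length(observed)
  mx <- mean(observed); my <- mean(predicted)
  d <- if (denominator == "n") n else n - 1L
  sx2 <- sum((observed - mx)^2) / d
  sy2 <- sum((predicted - my)^2) / d
  sxy <- sum((observed - mx) * (predicted - my)) / d
  if (sx2 == 0 && sy2 == 0) {
    stop_leafallom("leafallom_domain_error",
                   "both vectors constant; concordance undefined")
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Gaussian least-squares AIC
#'
#' \eqn{AIC = n \ln(rss/n) + 2K} with \eqn{K} = number of mean parameters
#' plus one for the error variance. Only differences in AIC between models
#' fitted to the same data are meaningful under this convention (additive
#' constants from the Gaussian likelihood are dropped).
#'
#' @param rss residual sum of squares (g^2), or a `scaling_fit` (in which
#'   case `n` and `n_params` are taken from the fit).
#' @param n sample size.
#' @param n_params number of mean parameters (2 allometric, 1 isometric).
#' @return dimensionless AIC value.
#' @examples
#' aic_ls(rss = 10, n = 10, n_params = 2)  # 6
#' @export
aic_ls <- function(rss, n = NULL, n_params = NULL) {
  if (inherits(rss, "scaling_fit")) {
    fit <- rss
    rss <- fit$rss; n <- fit$n; n_params <- length(fit$coefficients)
  }
  if (rss <= 0) {
    stop_leafallom("leafallom_perfect_fit",
                   "rss is zero: the Gaussian AIC diverges to -Inf (perfect fit)")
  }
  k <- n_params + 1L
  if (n <= k) {
    stop_leafallom("leafallom_domain_error", "need n > n_params + 1 for AIC")
  }
  n * log(rss / n) + 2 * k
}

#' Lack-of-fit F test against pure error
#'
#' Partitions the residual sum of squares of a fitted curve into pure error
#' (variation among replicate observations at the same length) and lack of
#' fit. Measured lengths are effectively discrete, so replicate groups are
#' formed by rounding lengths to `resolution` mm (default 1 mm). With
#' \eqn{m} groups, \eqn{p} model parameters and \eqn{n} observations,
#' \eqn{F = [SS_{lof}/(m-p)] / [SS_{pe}/(n-m)]} is compared to the upper
#' tail of \eqn{F_{m-p,\, n-m}}.
#'
#' If no length group contains replicates, pure error is undefined and a
#' not-applicable result (`applicable = FALSE`) is returned rather than an
#' error.
#'
#' @param lengths numeric vector of lengths (mm).
#' @param observed observed weights (g).
#' @param predicted model-predicted weights (g).
#' @param n_params number of model mean parameters.
#' @param resolution length-rounding resolution in mm for replicate
#'   grouping.
#' @return object of class `"lof_test"`: list with `statistic` (F),
#'   `df_lof` (m - p), `df_pe` (n - m), `p.value`, `ss_lof`, `ss_pe`,
#'   `n_groups`, `applicable`.
#' @export
lack_of_fit_test <- function(lengths, observed, predicted, n_params,
                             resolution = 1) {
  check_paired(observed, predicted)
  if (length(lengths) != length(observed)) {
    stop_leafallom("leafallom_domain_error",
                   "lengths and observed must have equal length")
  }
  grp <- factor(round(lengths / resolution) * resolution)
  m <- nlevels(grp)
  n <- length(observed)
  if (m == n || m <= n_params) {
    return(structure(list(applicable = FALSE, n_groups = m, n = n,
                          reason = if (m == n) "no replicate groups"
                                   else "fewer groups than parameters"),
                     class = "lof_test"))
  }
  gm <- stats::ave(observed, grp)                # group means, per observation
  ss_pe <- sum((observed - gm)^2)
  rss <- sum((observed - predicted)^2)
  ss_lof <- max(rss - ss_pe, 0)
  df_lof <- m - n_params
  df_pe <- n - m
  f <- (ss_lof / df_lof) / (ss_pe / df_pe)
  structure(list(statistic = f, df_lof = df_lof, df_pe = df_pe,
                 p.value = stats::pf(f, df_lof, df_pe, lower.tail = FALSE),
                 ss_lof = ss_lof, ss_pe = ss_pe, n_groups = m, n = n,
                 applicable = TRUE),
            class = "lof_test")
}

#' @export
print.lof_test <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("Lack-of-fit test: not applicable (%s)\n", x$reason))
  } else {
    cat(sprintf(
      "Lack-of-fit F = %.4g on (%d, %d) df, p = %.4g  [%d length groups]\n",
      x$statistic, x$df_lof, x$df_pe, x$p.value, x$n_groups))
  }
  invisible(x)
}

#' Paired test of observed vs predicted means
#'
#' Two-sided paired t test on the differences observed - predicted. Two
#' degenerate cases are handled explicitly: all differences zero returns
#' p = 1, and constant nonzero differences (zero variance, nonzero mean)
#' return p = 0 with `degenerate = TRUE`.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return list with `statistic` (t), `df`, `p.value`, `mean_difference`,
#'   `degenerate`.
#' @export
mean_difference_test <- function(observed, predicted) {
  check_paired(observed, predicted)
  d <- observed - predicted
  if (all(d == 0)) {
    return(list(statistic = 0, df = length(d) - 1L, p.value = 1,
                mean_difference = 0, degenerate = TRUE))
  }
  if (stats::sd(d) == 0) {
    return(list(statistic = Inf, df = length(d) - 1L, p.value = 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

#' Residual diagnostics: normality and homoscedasticity
#'
#' Normality of residuals by Shapiro-Wilk for n <= 5000, and by the
#' D'Agostino K^2 omnibus test (combining transformed skewness and kurtosis)
#' for larger samples where Shapiro-Wilk is unavailable. Homoscedasticity by
#' the studentized Breusch-Pagan (Koenker) test: the \eqn{n R^2} statistic
#' of the auxiliary regression of squared residuals on fitted values,
#' referred to \eqn{\chi^2_1}.
#'
#' Requires at least 8 residuals; with fewer, or with constant residuals,
#' returns `applicable = FALSE` rather than failing.
#'
#' @param fit a `scaling_fit`, or a list with `residuals` and `fitted`.
#' @return list with `normality_p`, `homoscedasticity_p`,
#'   `normality_method`, `applicable`.
#' @export
residual_diagnostics <- function(fit) {
  r <- fit$residuals
  f <- fit$fitted
  n <- length(r)
  if (n < 8L || stats::sd(r) == 0) {
    return(list(applicable = FALSE,
                reason = if (n < 8L) "fewer than 8 residuals"
                         else "constant residuals"))
  }
  if (n <= 5000L) {
    norm_p <- stats::shapiro.test(r)$p.value
    norm_method <- "shapiro-wilk"
  } else {
    norm_p <- dagostino_k2(r)
    norm_method <- "dagostino-k2"
  }
  aux <- stats::lm(I(r^2) ~ f)
  bp_stat <- n * summary(aux)$r.squared
  list(normality_p = norm_p,
       homoscedasticity_p = stats::pchisq(bp_stat, 1, lower.tail = FALSE),
       bp_statistic = bp_stat,
       normality_method = norm_method,
       applicable = TRUE)
}

# D'Agostino K^2 omnibus normality test (p-value).
# Standard normalizing transforms of sample skewness (D'Agostino 1970) and
# kurtosis (Anscombe & Glynn 1983); K^2 = Zs^2 + Zk^2 ~ chi^2_2 under
# normality.
dagostino_k2 <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness transform
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis transform
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- Zs^2 + Zk^2
  stats::pchisq(k2, df = 2, lower.tail = FALSE)
}

check_paired <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop_leafallom("leafallom_domain_error",
                   "observed and predicted must have equal length")
  }
  if (length(observed) < 2L) {
    stop_leafallom("leafallom_domain_error", "need at least 2 paired values")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop_leafallom("leafallom_domain_error", "missing values not allowed")
  }
  invisible(NULL)
}
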