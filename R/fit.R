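#' Log-log starting values for the allometric fit
#'
#' Ordinary least squares of \eqn{\ln w} on \eqn{\ln l} gives
#' \eqn{(a_0, b_0) = (e^{intercept}, slope)}, the classical starting point for
#' the nonlinear power-law fit. Records with missing or non-positive weight
#' cannot enter the log regression and are excluded with a warning.
#'
#' @param records a [leaf_records()] table with weights.
#' @return named numeric vector `c(a = ..., b = ...)`.
#' @examples
#' r <- leaf_records(length_mm = c(50, 100, 200, 400),
#'                   weight_g = 1e-5 * c(50, 100, 200, 400)^1.41)
#' loglog_start(r)
#' @export
loglog_start <- function(records) {
  records <- as_leaf_records(records)
  l <- records$length_mm
  w <- records$weight_g
  usable <- !is.na(w) & w > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    warn_leafallom("leafallom_dropped_records", sprintf(
      "%d record(s) without strictly positive weight excluded from the log-log regression",
      n_dropped))
  }
  if (sum(usable) < 3L) {
    stop_leafallom("leafallom_data_error",
                   "need >= 3 records with positive weights for log-log starting values")
  }
  fit <- stats::lm(log(w[usable]) ~ log(l[usable]))
  cf <- unname(stats::coef(fit))
  c(a = exp(cf[1]), b = cf[2])
}

#' Fit a scaling model to leaf or shoot morphometry data
#'
#' Least-squares estimation of the allometric power law \eqn{w = a l^b} or
#' the isometric proportionality \eqn{w = c l} from individual-leaf records
#' (per-leaf weights) or shoot records (aggregate weight per shoot with
#' per-leaf lengths, fitted through the aggregated models
#' \eqn{w_s = \sum_k a l_k^b} and \eqn{w_s = c \sum_k l_k}).
#'
#' @details
#' With `scale = "raw"` (the default, matching how scaling parameters are
#' conventionally reported for these data) the objective is additive least
#' squares on the original gram scale. The isometric fit is the closed-form
#' regression through the origin \eqn{\hat c = \sum w_i L_i / \sum L_i^2}.
#' The allometric fit exploits that, for fixed \eqn{b}, the optimal
#' \eqn{a(b) = \sum w_i S_i(b) / \sum S_i(b)^2} (with \eqn{S_i(b)} the unit's
#' summed \eqn{l^b}) is closed-form, reducing the problem to a 1-D profile
#' minimisation over \eqn{b > 0}: a coarse grid bracket centred on the
#' log-log starting value followed by golden-section/parabolic refinement
#' ([stats::optimize()], tolerance 1e-9 on \eqn{b}). Positivity of `a` is
#' automatic (weights are positive), `b` is kept positive by the search
#' bracket. If the profile minimum runs into the bracket edge even after
#' expansion, a convergence error carrying the last iterate is raised.
#'
#' Standard errors come from the Gauss-Newton covariance approximation
#' \eqn{\hat\sigma^2 (J'J)^{-1}} with \eqn{\hat\sigma^2 = rss/(n-p)}; a
#' heteroscedasticity-consistent (HC3) covariance is also stored and
#' available via `vcov(fit, robust = TRUE)`, relevant because leaf-weight
#' spread typically grows with the mean.
#'
#' With `scale = "log"` the allometric model is fitted as OLS of
#' \eqn{\ln w} on \eqn{\ln l} (the maximum-likelihood fit under
#' multiplicative lognormal errors); fitted values, residuals, `rss` and
#' `sigma` are then on the log scale, while `coef()` still reports
#' \eqn{(a, b)} with \eqn{a = e^{intercept}}. For shoot data the log-scale
#' fit regresses \eqn{\ln w_s} on \eqn{\ln L_s} (total shoot leaf length) and
#' is an approximation to the aggregated model, intended for sensitivity
#' analysis.
#'
#' Leaf records with missing weight are excluded (a message reports the
#' count).
#'
#' @param data a [leaf_records()] or [shoot_records()] table (a plain
#'   `data.frame` with the `leaf_records` columns is accepted).
#' @param model `"allometric"` (two parameters a, b) or `"isometric"`
#'   (single ratio c).
#' @param scale `"raw"` for least squares on grams (default), `"log"` for
#'   the log-scale fit.
#' @return An object of class `"scaling_fit"`; see [summary.scaling_fit()],
#'   [coef.scaling_fit()], [predict.scaling_fit()].
#' @examples
#' set.seed(7)
#' l <- rlnorm(200, log(150), 0.5)
#' w <- 1e-5 * l^1.41 * exp(rnorm(200, 0, 0.2) - 0.02)
#' fit <- fit_scaling(leaf_records(l, w))
#' coef(fit)
#' summary(fit)
#' @export
fit_scaling <- function(data, model = c("allometric", "isometric"),
                        scale = c("raw", "log")) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  cl <- match.call()

  if (inherits(data, "shoot_records")) {
    level <- "shoot"
    lens <- data$leaf_lengths_mm
    w <- data$shoot_weight_g
    n_excluded <- 0L
  } else {
    data <- as_leaf_records(data)
    level <- "leaf"
    keep <- !is.na(data$weight_g)
    n_excluded <- sum(!keep)
    if (n_excluded > 0L) {
      message(sprintf("fit_scaling: %d record(s) without weight excluded",
                      n_excluded))
    }
    data <- data[keep, , drop = FALSE]
    lens <- as.list(data$length_mm)
    w <- data$weight_g
  }

  n <- length(w)
  p <- if (model == "allometric") 2L else 1L
  min_n <- p + 1L
  if (n < min_n) {
    stop_leafallom("leafallom_data_error", sprintf(
      "need >= %d units with weights to fit the %s model (got %d)",
      min_n, model, n))
  }
  L <- vapply(lens, sum, numeric(1))   # total length per unit
  if (all(L == L[1])) {
    stop_leafallom("leafallom_data_error",
                   "degenerate data: all (total) lengths identical")
  }

  fit <- if (scale == "log") {
    fit_scaling_log(model, lens, L, w)
  } else if (model == "isometric") {
    fit_isometric_raw(L, w)
  } else {
    fit_allometric_raw(lens, L, w, level)
  }

  structure(c(fit, list(
    model = model, level = level, scale = scale,
    n = n, n_excluded = n_excluded,
    observed = w, lengths = if (level == "leaf") unlist(lens) else lens,
    data = data, call = cl
  )), class = "scaling_fit")
}

# -- raw-scale fits -----------------------------------------------------------

fit_isometric_raw <- function(L, w) {
  sL2 <- sum(L^2)
  c_hat <- sum(w * L) / sL2
  fitted <- c_hat * L
  res <- w - fitted
  rss <- sum(res^2)
  n <- length(w)
  sigma2 <- rss / (n - 1L)
  vc <- matrix(sigma2 / sL2, 1, 1, dimnames = list("c", "c"))
  J <- matrix(L, ncol = 1L)
  list(coefficients = c(c = c_hat), se = c(c = sqrt(vc[1, 1])),
       vcov = vc, vcov_robust = hc3_vcov(J, res),
       rss = rss, fitted = fitted, residuals = res,
       sigma = sqrt(sigma2), df.residual = n - 1L,
       convergence = list(converged = TRUE, method = "closed-form"))
}

fit_allometric_raw <- function(lens, L, w, level) {
  sw2 <- sum(w^2)
  S <- function(b) vapply(lens, function(l) sum(l^b), numeric(1))
  prof_rss <- function(b) {
    Sb <- S(b)
    sS2 <- sum(Sb^2)
    if (!is.finite(sS2) || sS2 <= 0) return(Inf)
    sw2 - sum(w * Sb)^2 / sS2
  }

  # bracket around the log-log starting value (pseudo-leaf totals for shoots)
  start <- tryCatch(
    suppressWarnings(loglog_start(leaf_records(length_mm = L, weight_g = w))),
    leafallom_error = function(e) c(a = NA_real_, b = 1)
  )
  b0 <- if (is.finite(start["b"]) && start["b"] > 0) unname(start["b"]) else 1
  lo <- max(1e-3, b0 - 2); hi <- b0 + 2
  for (trial in 1:3) {
    grid <- seq(lo, hi, by = 0.02)
    vals <- vapply(grid, prof_rss, numeric(1))
    i <- which.min(vals)
    at_edge <- i == 1L || i == length(grid)
    if (!at_edge) break
    # expand toward the offending edge, up to a hard positivity floor / cap
    if (i == 1L) { hi <- grid[2]; lo <- max(1e-6, lo - 4) }
    else { lo <- grid[length(grid) - 1L]; hi <- hi + 4 }
    if (lo <= 1e-6 && hi >= 20) { lo <- 1e-6; hi <- 20 }
  }
  if (at_edge) {
    stop_leafallom("leafallom_convergence_error",
                   "allometric profile minimum at the search boundary for b",
                   last_iterate = list(b = grid[i], rss = vals[i],
                                       bracket = c(lo, hi)))
  }
  opt <- stats::optimize(prof_rss, lower = grid[i - 1L], upper = grid[i + 1L],
                         tol = 1e-9)
  b_hat <- opt$minimum
  Sb <- S(b_hat)
  a_hat <- sum(w * Sb) / sum(Sb^2)
  if (!is.finite(a_hat) || a_hat <= 0) {
    stop_leafallom("leafallom_convergence_error",
                   "allometric fit produced a non-positive normalization constant",
                   last_iterate = list(a = a_hat, b = b_hat))
  }
  fitted <- a_hat * Sb
  res <- w - fitted
  rss <- sum(res^2)
  n <- length(w)
  sigma2 <- rss / (n - 2L)

  # Gauss-Newton covariance: J = [dfit/da, dfit/db]
  dSdb <- vapply(lens, function(l) sum(l^b_hat * log(l)), numeric(1))
  J <- cbind(a = Sb, b = a_hat * dSdb)
  JtJ <- crossprod(J)
  vc <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    stop_leafallom("leafallom_convergence_error",
                   "singular Gauss-Newton information matrix",
                   last_iterate = list(a = a_hat, b = b_hat))
  })
  dimnames(vc) <- list(c("a", "b"), c("a", "b"))
  list(coefficients = c(a = a_hat, b = b_hat),
       se = c(a = sqrt(vc[1, 1]), b = sqrt(vc[2, 2])),
       vcov = vc, vcov_robust = hc3_vcov(J, res),
       rss = rss, fitted = fitted, residuals = res,
       sigma = sqrt(sigma2), df.residual = n - 2L,
       convergence = list(converged = TRUE, method = "profile-1d",
                          objective = opt$objective, bracket = c(lo, hi)))
}

# -- log-scale fits -----------------------------------------------------------

fit_scaling_log <- function(model, lens, L, w) {
  if (any(w <= 0)) {
    stop_leafallom("leafallom_data_error",
                   "log-scale fitting requires strictly positive weights")
  }
  n <- length(w)
  if (model == "allometric") {
    lf <- stats::lm(log(w) ~ log(L))
    cf <- unname(stats::coef(lf))
    vc_log <- stats::vcov(lf)
    a_hat <- exp(cf[1]); b_hat <- cf[2]
    # delta method for a = exp(intercept)
    se_a <- a_hat * sqrt(vc_log[1, 1])
    vc <- diag(c(se_a^2, vc_log[2, 2]))
    dimnames(vc) <- list(c("a", "b"), c("a", "b"))
    res <- stats::residuals(lf)
    list(coefficients = c(a = a_hat, b = b_hat),
         se = c(a = se_a, b = unname(sqrt(vc_log[2, 2]))),
         vcov = vc, vcov_log = vc_log,
         vcov_robust = vc,
         rss = sum(res^2), fitted = unname(stats::fitted(lf)),
         residuals = unname(res),
         sigma = summary(lf)$sigma, df.residual = n - 2L,
         lm = lf,
         convergence = list(converged = TRUE, method = "log-ols"))
  } else {
    z <- log(w) - log(L)
    int <- mean(z)
    res <- z - int
    rss <- sum(res^2)
    sigma2 <- rss / (n - 1L)
    c_hat <- exp(int)
    se_int <- sqrt(sigma2 / n)
    vc <- matrix((c_hat * se_int)^2, 1, 1, dimnames = list("c", "c"))
    list(coefficients = c(c = c_hat), se = c(c = c_hat * se_int),
         vcov = vc, vcov_robust = vc,
         rss = rss, fitted = int + log(L), residuals = res,
         sigma = sqrt(sigma2), df.residual = n - 1L,
         convergence = list(converged = TRUE, method = "log-closed-form"))
  }
}

# -- shared helpers -----------------------------------------------------------

# HC3 sandwich covariance from a Jacobian and raw residuals
hc3_vcov <- function(J, res) {
  JtJi <- solve(crossprod(J))
  h <- pmin(rowSums((J %*% JtJi) * J), 1 - 1e-8)
  meat <- crossprod(J * (res / (1 - h)))
  V <- JtJi %*% meat %*% JtJi
  dimnames(V) <- dimnames(crossprod(J))
  V
}

as_leaf_records <- function(data) {
  if (inherits(data, "leaf_records")) return(data)
  if (is.data.frame(data) && all(c("length_mm", "weight_g") %in% names(data))) {
    return(leaf_records(
      length_mm = data$length_mm, weight_g = data$weight_g,
      site = if ("site" %in% names(data)) data$site else "site1",
      shoot_id = if ("shoot_id" %in% names(data)) data$shoot_id else NA,
      leaf_rank = if ("leaf_rank" %in% names(data)) data$leaf_rank else NA))
  }
  stop_leafallom("leafallom_data_error",
                 "expected leaf_records (or a data.frame with length_mm and weight_g)")
}
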