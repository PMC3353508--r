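#' Scaling-law weight predictions
#'
#' Predicted leaf dry weight under the two competing scaling models. The
#' allometric model is the power law \eqn{w = a l^b} with normalization
#' constant \eqn{a} (g mm^-b) and dimensionless allometric exponent \eqn{b};
#' the isometric model is the proportional special case \eqn{w = c l}, the
#' scaling that underlies the leaf weight-to-length ratio used by the
#' plastochrone method. Lengths are in mm and weights in g throughout.
#'
#' `l = 0` is allowed in prediction (both models return 0 g there); negative
#' lengths are a domain error.
#'
#' @param l numeric vector of leaf lengths (mm), all >= 0.
#' @param a normalization constant, > 0 (g mm^-b).
#' @param b allometric exponent, > 0 (dimensionless). Not restricted to
#'   b > 1: sub-linear scaling (0 < b < 1) is handled throughout.
#' @param c weight-to-length ratio, > 0 (g/mm).
#' @return numeric vector of predicted weights (g).
#' @examples
#' allometric_weight(100, a = 1e-5, b = 1.410012)
#' isometric_weight(274.8, c = 1e-4)
#' @seealso [shoot_weight_allometric()] for shoot aggregates,
#'   [fit_scaling()] to estimate the parameters from data.
#' @export
allometric_weight <- function(l, a, b) {
  check_scaling_params(a = a, b = b)
  check_lengths(l)
  a * l^b
}

#' @rdname allometric_weight
#' @export
isometric_weight <- function(l, c) {
  check_scaling_params(c = c)
  check_lengths(l)
  c * l
}

#' Shoot-aggregated weight predictions
#'
#' Predicted aggregate dry weight of a shoot from the lengths of its leaves:
#' the sum of per-leaf model predictions, \eqn{w_s = \sum_k a l_k^b}
#' (allometric) or \eqn{w_s = c \sum_k l_k} (isometric). Both are exactly
#' additive in the per-leaf predictions.
#'
#' @param lengths either a numeric vector of leaf lengths (mm) for a single
#'   shoot, or a list of such vectors (one per shoot).
#' @inheritParams allometric_weight
#' @return numeric: one predicted shoot weight (g) per shoot.
#' @examples
#' shoot_weight_allometric(c(100, 100), a = 1e-5, b = 1.410012)
#' shoot_weight_isometric(list(c(100, 200, 300), 150), c = 1e-4)
#' @export
shoot_weight_allometric <- function(lengths, a, b) {
  check_scaling_params(a = a, b = b)
  lens <- as_length_list(lengths)
  vapply(lens, function(l) sum(a * l^b), numeric(1))
}

#' @rdname shoot_weight_allometric
#' @export
shoot_weight_isometric <- function(lengths, c) {
  check_scaling_params(c = c)
  lens <- as_length_list(lengths)
  vapply(lens, function(l) c * sum(l), numeric(1))
}

# -- internal validation helpers ---------------------------------------------

check_scaling_params <- function(a = NULL, b = NULL, c = NULL) {
  if (!is.null(a) && (!is.finite(a) || a <= 0)) {
    stop_leafallom("leafallom_domain_error",
                   "normalization constant 'a' must be a positive number")
  }
  if (!is.null(b) && (!is.finite(b) || b <= 0)) {
    stop_leafallom("leafallom_domain_error",
                   "allometric exponent 'b' must be a positive number")
  }
  if (!is.null(c) && (!is.finite(c) || c <= 0)) {
    stop_leafallom("leafallom_domain_error",
                   "weight-to-length ratio 'c' must be a positive number")
  }
  invisible(NULL)
}

check_lengths <- function(l, allow_zero = TRUE) {
  if (length(l) == 0L) {
    stop_leafallom("leafallom_domain_error", "no lengths supplied")
  }
  if (anyNA(l) || any(l < 0) || (!allow_zero && any(l == 0))) {
    stop_leafallom("leafallom_domain_error",
                   "leaf lengths must be non-negative and non-missing")
  }
  invisible(NULL)
}

# Coerce shoot length input (vector = one shoot, list, or shoot_records)
# to a list of numeric vectors, one per shoot.
as_length_list <- function(lengths) {
  if (inherits(lengths, "shoot_records")) {
    lens <- lengths$leaf_lengths_mm
  } else if (is.list(lengths)) {
    lens <- lapply(lengths, as.numeric)
  } else {
    lens <- list(as.numeric(lengths))
  }
  if (length(lens) == 0L) {
    stop_leafallom("leafallom_domain_error", "no shoots supplied")
  }
  for (l in lens) check_lengths(l)
  lens
}
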