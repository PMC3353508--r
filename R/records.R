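#' Leaf morphometry records
#'
#' Construct a validated table of individual eelgrass leaves. Units are fixed
#' package-wide: lengths in millimetres, dry weights in grams. Lengths must be
#' strictly positive (an observed leaf has positive length); weights may be
#' missing (`NA`) for leaves measured for length only, but must be
#' non-negative when present.
#'
#' @param length_mm numeric vector of leaf lengths (mm), all > 0.
#' @param weight_g numeric vector of leaf dry weights (g), `NA` allowed;
#'   recycled `NA` by default when omitted.
#' @param site character site labels (recycled).
#' @param shoot_id character shoot labels (recycled), `NA` allowed.
#' @param leaf_rank integer leaf rank within the shoot (1 = youngest visible
#'   leaf; e.g. 3 for a fully developed "leaf-3"), `NA` allowed.
#'
#' @return A `data.frame` of class `"leaf_records"` with columns `site`,
#'   `shoot_id`, `leaf_rank`, `length_mm`, `weight_g`.
#' @examples
#' leaf_records(length_mm = c(120, 250, 410),
#'              weight_g  = c(0.011, 0.027, 0.051))
#' @export
leaf_records <- function(length_mm, weight_g = NA_real_, site = "site1",
                         shoot_id = NA_character_, leaf_rank = NA_integer_) {
  length_mm <- as.numeric(length_mm)
  n <- length(length_mm)
  if (n == 0L) {
    stop_leafallom("leafallom_data_error", "no leaf records supplied")
  }
  weight_g <- rep_len(as.numeric(weight_g), n)
  site <- rep_len(as.character(site), n)
  shoot_id <- rep_len(as.character(shoot_id), n)
  leaf_rank <- rep_len(as.integer(leaf_rank), n)
  if (anyNA(length_mm) || any(length_mm <= 0)) {
    bad <- which(is.na(length_mm) | length_mm <= 0)
    stop_leafallom("leafallom_domain_error", sprintf(
      "leaf lengths must be positive and non-missing (offending rows: %s)",
      paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (any(weight_g < 0, na.rm = TRUE)) {
    bad <- which(weight_g < 0)
    stop_leafallom("leafallom_domain_error", sprintf(
      "leaf weights must be non-negative (offending rows: %s)",
      paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (any(!nzchar(site) | is.na(site))) {
    stop_leafallom("leafallom_data_error", "site labels must be nonempty")
  }
  if (any(!is.na(leaf_rank) & leaf_rank < 1L)) {
    stop_leafallom("leafallom_domain_error", "leaf_rank must be >= 1")
  }
  out <- data.frame(site = site, shoot_id = shoot_id, leaf_rank = leaf_rank,
                    length_mm = length_mm, weight_g = weight_g,
                    stringsAsFactors = FALSE)
  class(out) <- c("leaf_records", "data.frame")
  out
}

#' Shoot-aggregated morphometry records
#'
#' Construct validated shoot records: for each shoot, the lengths (mm) of all
#' its leaves plus a single aggregate dry weight (g). This is the data shape
#' arising when leaves are weighed together per shoot while lengths are
#' recorded per leaf.
#'
#' @param leaf_lengths_mm list with one numeric vector of leaf lengths (mm)
#'   per shoot; every vector nonempty, all entries > 0.
#' @param shoot_weight_g numeric vector of aggregate shoot dry weights (g),
#'   one per shoot, all > 0.
#' @param site,shoot_id character labels (recycled / defaulted).
#'
#' @return A `data.frame` of class `"shoot_records"` with columns `site`,
#'   `shoot_id`, `n_leaves`, `shoot_weight_g` and a list column
#'   `leaf_lengths_mm`.
#' @examples
#' shoot_records(leaf_lengths_mm = list(c(100, 180, 240), c(90, 150)),
#'               shoot_weight_g = c(0.055, 0.024))
#' @export
shoot_records <- function(leaf_lengths_mm, shoot_weight_g,
                          site = "site1", shoot_id = NULL) {
  if (!is.list(leaf_lengths_mm) || length(leaf_lengths_mm) == 0L) {
    stop_leafallom("leafallom_data_error",
                   "leaf_lengths_mm must be a nonempty list of length vectors")
  }
  n <- length(leaf_lengths_mm)
  shoot_weight_g <- as.numeric(shoot_weight_g)
  if (length(shoot_weight_g) != n) {
    stop_leafallom("leafallom_data_error",
                   "one shoot weight is required per shoot")
  }
  lens <- lapply(leaf_lengths_mm, as.numeric)
  ok <- vapply(lens, function(l) length(l) >= 1L && !anyNA(l) && all(l > 0),
               logical(1))
  if (!all(ok)) {
    stop_leafallom("leafallom_domain_error", sprintf(
      "every shoot needs >= 1 leaf with positive lengths (offending shoots: %s)",
      paste(utils::head(which(!ok), 5L), collapse = ", ")))
  }
  if (anyNA(shoot_weight_g) || any(shoot_weight_g <= 0)) {
    stop_leafallom("leafallom_domain_error",
                   "shoot weights must be positive and non-missing")
  }
  site <- rep_len(as.character(site), n)
  if (any(!nzchar(site) | is.na(site))) {
    stop_leafallom("leafallom_data_error", "site labels must be nonempty")
  }
  if (is.null(shoot_id)) shoot_id <- sprintf("shoot%d", seq_len(n))
  shoot_id <- rep_len(as.character(shoot_id), n)
  out <- data.frame(site = site, shoot_id = shoot_id,
                    n_leaves = vapply(lens, length, integer(1)),
                    shoot_weight_g = shoot_weight_g,
                    stringsAsFactors = FALSE)
  out$leaf_lengths_mm <- lens
  class(out) <- c("shoot_records", "data.frame")
  out
}

#' @export
print.leaf_records <- function(x, ...) {
  cat(sprintf("Leaf records: %d leaves, %d with weights, %d site(s)\n",
              nrow(x), sum(!is.na(x$weight_g)), length(unique(x$site))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
print.shoot_records <- function(x, ...) {
  cat(sprintf("Shoot records: %d shoots, %d leaves total, %d site(s)\n",
              nrow(x), sum(x$n_leaves), length(unique(x$site))))
  df <- as.data.frame(x)
  df$leaf_lengths_mm <- vapply(df$leaf_lengths_mm, function(l)
    paste(signif(utils::head(l, 4L), 4), collapse = ","), character(1))
  print.data.frame(utils::head(df, 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# keep the class (and list column) through [ subsetting
#' @export
`[.leaf_records` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("leaf_records", "data.frame")
  out
}

#' @export
`[.shoot_records` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("shoot_records", "data.frame")
  out
}
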