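#' Read and write leaf morphometry CSV files
#'
#' The leaf dialect is a headed delimited file (UTF-8, dot decimal
#' separator) with mandatory columns `site`, `shoot_id`, `leaf_rank`,
#' `length_mm`, `weight_g`. Units are fixed by the column names; there is no
#' unit autodetection. `weight_g` may be empty for length-only records
#' (empty field, never 0); `shoot_id` and `leaf_rank` may be empty.
#' Non-positive or unparseable lengths are rejected with the offending data
#' row number (row 1 = first row after the header).
#'
#' @param path file path.
#' @param sep field separator: `","` (default), `";"` or `"\t"`.
#' @return `read_leaf_csv()`: a [leaf_records()] table with a `provenance`
#'   attribute naming the source file.
#' @export
read_leaf_csv <- function(path, sep = ",") {
  df <- read_table_checked(path, sep,
                           c("site", "shoot_id", "leaf_rank", "length_mm",
                             "weight_g"))
  len <- parse_num(df$length_mm, "length_mm", path)
  wt <- parse_num(df$weight_g, "weight_g", path, allow_empty = TRUE)
  rank <- parse_num(df$leaf_rank, "leaf_rank", path, allow_empty = TRUE)
  bad <- which(is.na(len) | len <= 0)
  if (length(bad) > 0L) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: non-positive or missing length_mm on data row(s) %s",
      path, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  out <- leaf_records(length_mm = len, weight_g = wt,
                      site = df$site,
                      shoot_id = ifelse(nzchar(df$shoot_id), df$shoot_id, NA),
                      leaf_rank = rank)
  attr(out, "provenance") <- normalizePath(path)
  out
}

#' @rdname read_leaf_csv
#' @param records a [leaf_records()] table.
#' @return `write_leaf_csv()`: the path, invisibly. Missing weights are
#'   written as empty fields.
#' @export
write_leaf_csv <- function(records, path, sep = ",") {
  records <- as_leaf_records(records)
  df <- as.data.frame(records)
  df$weight_g <- ifelse(is.na(df$weight_g), "",
                        format(df$weight_g, digits = 15, trim = TRUE,
                               scientific = FALSE))
  df$shoot_id[is.na(df$shoot_id)] <- ""
  df$leaf_rank <- ifelse(is.na(df$leaf_rank), "", df$leaf_rank)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write shoot-aggregated CSV files
#'
#' The shoot dialect uses two files: a long-format leaf table with columns
#' `site`, `shoot_id`, `length_mm` (one row per leaf) and a shoot table
#' with columns `site`, `shoot_id`, `shoot_weight_g` (one row per shoot).
#' They are joined on (`site`, `shoot_id`). A duplicated shoot in the
#' weight table, a leaf whose shoot has no weight row (orphan), and a
#' weighed shoot with no leaves are all errors.
#'
#' @param leaves_path path to the leaf-length table.
#' @param shoots_path path to the shoot-weight table.
#' @param sep field separator as in [read_leaf_csv()].
#' @return `read_shoot_csv()`: a [shoot_records()] table with a
#'   `provenance` attribute.
#' @export
read_shoot_csv <- function(leaves_path, shoots_path, sep = ",") {
  lf <- read_table_checked(leaves_path, sep, c("site", "shoot_id", "length_mm"))
  sf <- read_table_checked(shoots_path, sep,
                           c("site", "shoot_id", "shoot_weight_g"))
  len <- parse_num(lf$length_mm, "length_mm", leaves_path)
  wt <- parse_num(sf$shoot_weight_g, "shoot_weight_g", shoots_path)
  bad <- which(is.na(len) | len <= 0)
  if (length(bad) > 0L) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: non-positive or missing length_mm on data row(s) %s",
      leaves_path, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  skey <- paste(sf$site, sf$shoot_id, sep = "\r")
  if (anyDuplicated(skey)) {
    dup <- sf$shoot_id[duplicated(skey)]
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: duplicate shoot weight row(s) for shoot_id %s",
      shoots_path, paste(unique(dup), collapse = ", ")))
  }
  lkey <- paste(lf$site, lf$shoot_id, sep = "\r")
  orphan <- !(lkey %in% skey)
  if (any(orphan)) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: leaf row(s) reference shoot_id %s with no shoot weight",
      leaves_path,
      paste(unique(lf$shoot_id[orphan]), collapse = ", ")))
  }
  empty <- !(skey %in% lkey)
  if (any(empty)) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: shoot_id %s has a weight but no leaves",
      shoots_path, paste(sf$shoot_id[empty], collapse = ", ")))
  }
  lens <- split(len, factor(lkey, levels = skey))
  names(lens) <- NULL
  out <- shoot_records(leaf_lengths_mm = lens, shoot_weight_g = wt,
                       site = sf$site, shoot_id = sf$shoot_id)
  attr(out, "provenance") <- c(normalizePath(leaves_path),
                               normalizePath(shoots_path))
  out
}

#' @rdname read_shoot_csv
#' @param shoots a [shoot_records()] table.
#' @return `write_shoot_csv()`: character vector of the two paths,
#'   invisibly.
#' @export
write_shoot_csv <- function(shoots, leaves_path, shoots_path, sep = ",") {
  stopifnot(inherits(shoots, "shoot_records"))
  lf <- data.frame(
    site = rep(shoots$site, shoots$n_leaves),
    shoot_id = rep(shoots$shoot_id, shoots$n_leaves),
    length_mm = format(unlist(shoots$leaf_lengths_mm), digits = 15,
                       trim = TRUE, scientific = FALSE))
  sf <- data.frame(site = shoots$site, shoot_id = shoots$shoot_id,
                   shoot_weight_g = format(shoots$shoot_weight_g, digits = 15,
                                           trim = TRUE, scientific = FALSE))
  utils::write.table(lf, leaves_path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(sf, shoots_path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(leaves_path, shoots_path))
}

# -- internal -----------------------------------------------------------------

read_table_checked <- function(path, sep, required) {
  if (!file.exists(path)) {
    stop_leafallom("leafallom_data_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = TRUE,
                          quote = "\"", comment.char = "",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: missing mandatory column(s): %s", path,
      paste(missing_cols, collapse = ", ")))
  }
  df
}

parse_num <- function(x, column, path, allow_empty = FALSE) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  empty <- !nzchar(x)
  bad <- which(is.na(out) & !empty)
  if (length(bad) > 0L) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: unparseable %s on data row(s) %s", path, column,
      paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!allow_empty && any(empty)) {
    stop_leafallom("leafallom_data_error", sprintf(
      "%s: empty %s on data row(s) %s", path, column,
      paste(utils::head(which(empty), 5L), collapse = ", ")))
  }
  out
}
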