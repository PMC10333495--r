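# Reading and writing the tabular interchange formats. Long format is a
# delimited file with header `participant,day,item,score`; wide format has
# header `participant,<item>@d<day>,...`; metadata is
# `participant,delirium_dsm5,<covariate>...`. The delimiter defaults to
# TAB for .tsv paths and comma otherwise.

guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read long-format scores
#'
#' @param path delimited text file with header columns `participant`,
#'   `day`, `item`, `score`. Malformed rows, unknown items, out-of-range
#'   scores and duplicate cells are errors that name the offending line.
#' @param catalog an [item_catalog].
#' @param n_days number of days.
#' @param sep field delimiter; default inferred from the file extension.
#' @return A [longitudinal_scores] object.
#' @seealso [write_long()]
#' @export
read_long <- function(path, catalog = item_catalog(), n_days = 5L,
                      sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant", "day", "item", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  records <- validate_records(df, catalog, n_days,
                              lines = seq_len(nrow(df)) + 1L)
  structure(list(records = records, catalog = catalog,
                 n_days = as.integer(n_days)),
            class = "longitudinal_scores")
}

#' Write long-format scores
#'
#' Rows are emitted in the canonical order (participant, day, catalogue
#' item order) so output is deterministic and round-trips through
#' [read_long()].
#'
#' @param scores a [longitudinal_scores] object.
#' @param path output file.
#' @param sep field delimiter; default inferred from the file extension.
#' @export
write_long <- function(scores, path, sep = NULL) {
  stopifnot(inherits(scores, "longitudinal_scores"))
  sep <- guess_sep(path, sep)
  write.table(scores$records, path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a wide participants-by-features matrix
#'
#' @param path delimited text file with header `participant` followed by
#'   the `item@day` feature labels.
#' @inheritParams read_long
#' @return Numeric matrix as produced by [to_wide()].
#' @export
read_wide <- function(path, catalog = item_catalog(), n_days = 5L,
                      sep = NULL) {
  sep <- guess_sep(path, sep)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"participant" %in% names(df))
    stop(path, ": missing `participant` column", call. = FALSE)
  X <- as.matrix(df[setdiff(names(df), "participant")])
  rownames(X) <- as.character(df$participant)
  storage.mode(X) <- "double"
  # route through the record validator: bounds, labels, duplicates
  to_wide(wide_to_long(X, catalog, n_days))
}

#' Write a wide matrix
#'
#' @param X matrix from [to_wide()].
#' @param path output file.
#' @param sep field delimiter; default inferred from the file extension.
#' @export
write_wide <- function(X, path, sep = NULL) {
  check_matrix(X)
  sep <- guess_sep(path, sep)
  df <- data.frame(participant = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read participant metadata
#'
#' @param path delimited file with header `participant`, optionally
#'   `delirium_dsm5` (logical or 0/1) and further numeric covariates.
#' @param sep field delimiter; default inferred from the file extension.
#' @return Data frame with unique `participant` ids and, when present, a
#'   logical `delirium_dsm5` column.
#' @export
read_meta <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop("metadata file not found: ", path, call. = FALSE)
  sep <- guess_sep(path, sep)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"participant" %in% names(df))
    stop(path, ": missing `participant` column", call. = FALSE)
  df$participant <- as.character(df$participant)
  if (anyDuplicated(df$participant))
    stop(path, ": duplicate participant ids", call. = FALSE)
  if ("delirium_dsm5" %in% names(df))
    df$delirium_dsm5 <- as.logical(df$delirium_dsm5)
  df
}

#' Write a JSON results manifest
#'
#' @param results named list (seeds, selected K values, AIC tables, ...).
#' @param path output `.json` file.
#' @export
write_json_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
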