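#' Wide participants-by-features score matrix
#'
#' Pivots a complete [longitudinal_scores] object into a numeric matrix
#' with one row per participant and one column per `item@day` cell. For
#' 13 items over 5 days this is the 65-column matrix on which feature
#' grouping operates. Column order is day-major ([feature_labels()]);
#' row order is lexicographic in participant id.
#'
#' @param scores a [longitudinal_scores] object; every participant must be
#'   complete (no imputation is performed -- missing cells are an error
#'   that names the offending cells).
#' @return Numeric matrix with participant rownames and `item@day`
#'   colnames.
#' @seealso [wide_to_long()] for the inverse, [group_features()]
#' @export
#' @examples
#' coh <- simulate_cohort(default_design(), seed = 1)
#' X <- to_wide(coh$scores)
#' dim(X)  # 286 x 65
to_wide <- function(scores) {
  stopifnot(inherits(scores, "longitudinal_scores"))
  labels <- feature_labels(scores$catalog, scores$n_days)
  ids <- sort(unique(scores$records$participant))
  rec <- scores$records
  ridx <- match(rec$participant, ids)
  cidx <- match(paste0(rec$item, "@d", rec$day), labels)
  X <- matrix(NA_real_, nrow = length(ids), ncol = length(labels),
              dimnames = list(ids, labels))
  X[cbind(ridx, cidx)] <- rec$score
  if (anyNA(X)) {
    holes <- which(is.na(X), arr.ind = TRUE)
    cells <- paste0(ids[holes[, 1L]], ":", labels[holes[, 2L]])
    stop("incomplete participants; missing cell(s): ",
         abbreviate_list(cells), call. = FALSE)
  }
  X
}

#' Unpivot a wide matrix back to longitudinal records
#'
#' @param X numeric matrix with participant rownames and `item@day`
#'   colnames covering exactly `items x days`.
#' @param catalog an [item_catalog].
#' @param n_days number of days.
#' @return A [longitudinal_scores] object.
#' @export
wide_to_long <- function(X, catalog = item_catalog(), n_days = 5L) {
  check_matrix(X)
  labels <- feature_labels(catalog, n_days)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("`X` must have participant rownames and feature colnames",
         call. = FALSE)
  if (!setequal(colnames(X), labels) || anyDuplicated(colnames(X)))
    stop(sprintf("`X` must have exactly the %d `item@day` columns",
                 length(labels)), call. = FALSE)
  parsed <- parse_feature_labels(colnames(X), catalog)
  records <- data.frame(
    participant = rep(rownames(X), times = ncol(X)),
    day = rep(parsed$day, each = nrow(X)),
    item = rep(parsed$item, each = nrow(X)),
    score = as.vector(X),
    stringsAsFactors = FALSE)
  longitudinal_scores(records, catalog, n_days)
}
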