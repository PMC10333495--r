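#' Stage 1: cluster item@day feature columns into groups
#'
#' Treats each column of the wide matrix (a length-`n` vector of the
#' feature over participants) as one point and applies [select_k()] to
#' the transposed matrix, so the features themselves are partitioned in a
#' hypothesis-free way. Columns are clustered on the raw ordinal scores by
#' default: all features share the same bounded scale, so raw Euclidean
#' distance is already commensurable. Set `standardize = TRUE` to z-score
#' each feature first (sensitivity analysis).
#'
#' @param X wide matrix from [to_wide()] (participants x features, no
#'   missing entries, at least 2 rows).
#' @param k_range,restarts,master_seed,aic_method,... passed to
#'   [select_k()].
#' @param standardize z-score each feature column before clustering
#'   (default `FALSE`).
#' @return An object of class `feature_grouping`: list with `group_of`
#'   (named integer vector, column label -> group index `1..G`), `G`,
#'   `group_names` (defaults to `"group1"..`), and `report` (the full
#'   `kselect` selection report).
#' @seealso [reduce_features()], [suggest_group_names()]
#' @export
#' @examples
#' coh <- simulate_cohort(default_design(), seed = 17)
#' g <- group_features(to_wide(coh$scores), restarts = 50, master_seed = 1)
#' g$G
group_features <- function(X, k_range = 1:10, restarts = 1000L,
                           master_seed = 1L, standardize = FALSE,
                           aic_method = c("fixed", "profile"), ...) {
  check_matrix(X)
  if (nrow(X) < 2L)
    stop("`X` must have at least 2 participants", call. = FALSE)
  if (is.null(colnames(X)))
    stop("`X` must have feature column labels", call. = FALSE)
  pts <- if (standardize) scale_columns(X) else X
  report <- select_k(t(pts), k_range = k_range, restarts = restarts,
                     master_seed = master_seed,
                     aic_method = match.arg(aic_method), ...)
  feature_grouping(structure(report$solution$cluster, names = colnames(X)),
                   report = report)
}

# z-score columns; zero-variance columns are centered only
scale_columns <- function(X) {
  s <- apply(X, 2L, sd)
  s[s == 0] <- 1
  scale(X, center = TRUE, scale = s)
}

#' Construct a feature grouping
#'
#' @param group_of named integer vector mapping every column label to a
#'   group index; indices must cover `1..G` with no empty group.
#' @param group_names optional character vector of length `G` with human
#'   labels (cosmetic only).
#' @param report optional `kselect` report the grouping came from.
#' @return A `feature_grouping` object.
#' @export
feature_grouping <- function(group_of, group_names = NULL, report = NULL) {
  if (is.null(names(group_of)) || anyDuplicated(names(group_of)))
    stop("`group_of` must have unique column-label names", call. = FALSE)
  group_of <- structure(as.integer(group_of), names = names(group_of))
  G <- max(group_of)
  if (anyNA(group_of) || min(group_of) < 1L ||
      !all(seq_len(G) %in% group_of))
    stop("group indices must cover 1..G with every group non-empty",
         call. = FALSE)
  if (is.null(group_names)) {
    group_names <- paste0("group", seq_len(G))
  } else if (length(group_names) != G || anyDuplicated(group_names)) {
    stop("`group_names` must be ", G, " unique labels", call. = FALSE)
  }
  structure(list(group_of = group_of, G = G,
                 group_names = as.character(group_names), report = report),
            class = "feature_grouping")
}

#' @export
print.feature_grouping <- function(x, ...) {
  cat(sprintf("Feature grouping: %d columns -> %d group(s)\n",
              length(x$group_of), x$G))
  for (g in seq_len(x$G)) {
    members <- names(x$group_of)[x$group_of == g]
    cat(sprintf("  %s (%d): %s\n", x$group_names[g], length(members),
                abbreviate_list(members, 4L)))
  }
  invisible(x)
}

#' Collapse a wide matrix to per-group composite means
#'
#' Each grouped feature of the reduced matrix is, per participant, the
#' arithmetic mean of the member columns of that group, yielding the
#' low-dimensional composite matrix participants x G on which participant
#' clustering operates.
#'
#' @param X wide matrix whose columns are exactly the labels covered by
#'   `grouping`.
#' @param grouping a [feature_grouping].
#' @return Numeric matrix participants x G with group-name colnames.
#' @export
reduce_features <- function(X, grouping) {
  check_matrix(X)
  stopifnot(inherits(grouping, "feature_grouping"))
  if (is.null(colnames(X)) ||
      !setequal(colnames(X), names(grouping$group_of)) ||
      anyDuplicated(colnames(X)))
    stop("`grouping` must cover exactly the columns of `X`", call. = FALSE)
  out <- vapply(seq_len(grouping$G), function(g) {
    members <- names(grouping$group_of)[grouping$group_of == g]
    rowMeans(X[, members, drop = FALSE])
  }, numeric(nrow(X)))
  matrix(as.numeric(out), nrow = nrow(X),
         dimnames = list(rownames(X), grouping$group_names))
}

#' Suggest descriptive group names
#'
#' Purely cosmetic convenience: a group in which at least `threshold` of
#' the member cells come from a single item is named `"<item>-dominant"`;
#' otherwise the generic name is kept.
#'
#' @param grouping a [feature_grouping].
#' @param catalog the [item_catalog] the labels parse under.
#' @param threshold dominance fraction (default 0.8).
#' @return Character vector of length `G`.
#' @export
suggest_group_names <- function(grouping, catalog = item_catalog(),
                                threshold = 0.8) {
  stopifnot(inherits(grouping, "feature_grouping"))
  parsed <- parse_feature_labels(names(grouping$group_of), catalog)
  vapply(seq_len(grouping$G), function(g) {
    items <- parsed$item[grouping$group_of == g]
    tab <- sort(table(items), decreasing = TRUE)
    if (tab[1L] / length(items) >= threshold)
      paste0(names(tab)[1L], "-dominant")
    else grouping$group_names[g]
  }, character(1))
}

#' Write a feature grouping as TSV
#'
#' Two columns, `col_label` and `group`, one row per feature column --
#' the tabular analogue of a checkmark grid of group assignments.
#'
#' @param grouping a [feature_grouping].
#' @param path output file.
#' @export
write_feature_grouping <- function(grouping, path) {
  stopifnot(inherits(grouping, "feature_grouping"))
  df <- data.frame(col_label = names(grouping$group_of),
                   group = grouping$group_of,
                   group_name = grouping$group_names[grouping$group_of],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
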