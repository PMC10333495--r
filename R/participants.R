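#' Stage 2: cluster participants on the composite matrix
#'
#' Applies [select_k()] to the rows of the reduced matrix (participants in
#' composite-feature space). The same selection protocol is used as for
#' feature grouping; its defaults may be overridden independently.
#'
#' @param Xr reduced matrix from [reduce_features()] (at least 2 rows).
#' @param k_range,restarts,master_seed,aic_method,... passed to
#'   [select_k()].
#' @param standardize z-score each composite before clustering (default
#'   `FALSE`; composites inherit the shared ordinal scale, so raw values
#'   are the default here too).
#' @return A `kselect` report; its `$solution` is the minimum-AIC
#'   clustering of the participants.
#' @seealso [participant_clusters()]
#' @export
cluster_participants <- function(Xr, k_range = 1:10, restarts = 1000L,
                                 master_seed = 1L, standardize = FALSE,
                                 aic_method = c("fixed", "profile"), ...) {
  check_matrix(Xr)
  if (nrow(Xr) < 2L)
    stop("`Xr` must have at least 2 participants", call. = FALSE)
  pts <- if (standardize) scale_columns(Xr) else Xr
  select_k(pts, k_range = k_range, restarts = restarts,
           master_seed = master_seed, aic_method = match.arg(aic_method),
           ...)
}

#' Order clusters by within-cluster mean severity
#'
#' Rank 1 is the cluster whose members have the highest mean peak daily
#' total severity ([max_total_severity()]); ties are broken toward the
#' smaller raw cluster index.
#'
#' @param solution a `kmeans_solution` over participants.
#' @param severities numeric vector of per-participant severities, in the
#'   row order the solution was fitted on.
#' @return Integer vector of length `K`: `severity_rank[k]` is the rank of
#'   raw cluster `k` (1 = most severe).
#' @export
rank_by_severity <- function(solution, severities) {
  stopifnot(inherits(solution, "kmeans_solution"))
  if (length(severities) != length(solution$cluster))
    stop("`severities` must have one value per clustered participant",
         call. = FALSE)
  if (!is.numeric(severities) || anyNA(severities))
    stop("`severities` must be numeric and complete", call. = FALSE)
  means <- vapply(seq_len(solution$K),
                  function(k) mean(severities[solution$cluster == k]),
                  numeric(1))
  ord <- order(-means, seq_len(solution$K))
  rank <- integer(solution$K)
  rank[ord] <- seq_len(solution$K)
  rank
}

#' Majority-rule diagnosis label per cluster
#'
#' A cluster is labelled `"delirium"` when its members with a known
#' diagnosis include at least as many delirium as non-delirium
#' participants (an exact tie resolves toward `"delirium"`, the clinically
#' conservative side), and `"non-delirium"` otherwise. Missing diagnoses
#' are excluded from the counts.
#'
#' @param solution a `kmeans_solution` over participants.
#' @param dsm5 logical vector of per-participant diagnoses (`NA` allowed),
#'   in the row order the solution was fitted on.
#' @return Character vector of length `K` with values `"delirium"` /
#'   `"non-delirium"`.
#' @export
#' @examples
#' label_from_counts(c(27, 12), c(1, 68))  # "delirium", "non-delirium"
label_delirium <- function(solution, dsm5) {
  stopifnot(inherits(solution, "kmeans_solution"))
  if (length(dsm5) != length(solution$cluster))
    stop("`dsm5` must have one value per clustered participant",
         call. = FALSE)
  dsm5 <- as.logical(dsm5)
  if (all(is.na(dsm5)))
    stop("no diagnosis labels available", call. = FALSE)
  n_del <- vapply(seq_len(solution$K), function(k)
    sum(dsm5[solution$cluster == k], na.rm = TRUE), numeric(1))
  n_non <- vapply(seq_len(solution$K), function(k)
    sum(!dsm5[solution$cluster == k], na.rm = TRUE), numeric(1))
  label_from_counts(n_del, n_non)
}

#' Majority-rule label from per-cluster counts
#'
#' The counting rule behind [label_delirium()], usable directly on a
#' printed table of per-cluster delirium / non-delirium counts.
#'
#' @param n_delirium,n_non_delirium numeric vectors of per-cluster counts.
#' @return Character vector of labels.
#' @export
label_from_counts <- function(n_delirium, n_non_delirium) {
  if (length(n_delirium) != length(n_non_delirium))
    stop("count vectors must have equal length", call. = FALSE)
  ifelse(n_delirium >= n_non_delirium, "delirium", "non-delirium")
}

#' Bundle a participant clustering with severity ranks and labels
#'
#' @param solution a `kmeans_solution` over participants (typically
#'   `cluster_participants(...)$solution`).
#' @param severities per-participant severities for [rank_by_severity()].
#' @param dsm5 optional per-participant logical diagnoses for
#'   [label_delirium()]; when absent all labels are `NA`.
#' @return An object of class `participant_clusters`: list with
#'   `solution`, `severity_rank`, `delirium_label`, `participant_ids`.
#' @export
participant_clusters <- function(solution, severities, dsm5 = NULL) {
  stopifnot(inherits(solution, "kmeans_solution"))
  rank <- rank_by_severity(solution, severities)
  label <- if (is.null(dsm5)) rep(NA_character_, solution$K)
           else label_delirium(solution, dsm5)
  structure(list(solution = solution, severity_rank = rank,
                 delirium_label = label,
                 participant_ids = names(severities)),
            class = "participant_clusters")
}

#' @export
print.participant_clusters <- function(x, ...) {
  cat(sprintf("Participant clustering: K = %d\n", x$solution$K))
  ord <- order(x$severity_rank)
  sizes <- tabulate(x$solution$cluster, x$solution$K)
  for (k in ord)
    cat(sprintf("  rank %d (raw %d): n = %d%s\n", x$severity_rank[k], k,
                sizes[k],
                if (is.na(x$delirium_label[k])) ""
                else paste0(", ", x$delirium_label[k])))
  invisible(x)
}

#' Per-cluster summary table
#'
#' One row per cluster in severity order: sizes, diagnosis counts, mean
#' +/- standard error of peak severity, and the mean of any numeric
#' covariates supplied.
#'
#' @param clusters a [participant_clusters] object.
#' @param severities per-participant severities (same order as fitted).
#' @param meta optional data frame with `participant` plus covariates;
#'   matched to `clusters$participant_ids`.
#' @return Data frame, rows ordered by `severity_rank`.
#' @export
cluster_summary <- function(clusters, severities, meta = NULL) {
  stopifnot(inherits(clusters, "participant_clusters"))
  sol <- clusters$solution
  se <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  rows <- lapply(seq_len(sol$K), function(k) {
    in_k <- sol$cluster == k
    data.frame(severity_rank = clusters$severity_rank[k], raw_cluster = k,
               n = sum(in_k), label = clusters$delirium_label[k],
               severity_mean = mean(severities[in_k]),
               severity_se = se(severities[in_k]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    idx <- match(clusters$participant_ids, meta$participant)
    if ("delirium_dsm5" %in% names(meta)) {
      lab <- as.logical(meta$delirium_dsm5)[idx]
      out$n_delirium <- vapply(seq_len(sol$K), function(k)
        sum(lab[sol$cluster == k], na.rm = TRUE), numeric(1))
      out$n_non_delirium <- vapply(seq_len(sol$K), function(k)
        sum(!lab[sol$cluster == k], na.rm = TRUE), numeric(1))
    }
    for (cov in setdiff(names(meta), c("participant", "delirium_dsm5"))) {
      v <- meta[[cov]][idx]
      if (is.numeric(v))
        out[[paste0(cov, "_mean")]] <- vapply(seq_len(sol$K), function(k)
          mean(v[sol$cluster == k], na.rm = TRUE), numeric(1))
    }
  }
  out[order(out$severity_rank), , drop = FALSE]
}

#' Per-participant assignment table
#'
#' @param clusters a [participant_clusters] object.
#' @return Data frame `participant`, `raw_cluster`, `severity_rank`,
#'   `cluster_label`.
#' @export
participant_assignments <- function(clusters) {
  stopifnot(inherits(clusters, "participant_clusters"))
  k <- clusters$solution$cluster
  data.frame(participant = clusters$participant_ids, raw_cluster = k,
             severity_rank = clusters$severity_rank[k],
             cluster_label = clusters$delirium_label[k],
             stringsAsFactors = FALSE)
}
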