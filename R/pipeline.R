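#' Run the full two-stage phenotyping pipeline
#'
#' Orchestrates: wide-matrix construction, stage-1 feature grouping,
#' dimension reduction, stage-2 participant clustering, severity ranking,
#' majority diagnosis labelling, post-hoc profiling, covariate ANOVA, and
#' the two PCA views. Stage 1 consumes per-run seeds
#' `master_seed + 1, master_seed + 2, ...`; stage 2 continues the counter
#' where stage 1 stopped, so the whole run is reproducible from
#' `master_seed` alone and every single K-means run can be replayed from
#' the manifest.
#'
#' @param scores a [longitudinal_scores] object (all participants
#'   complete).
#' @param meta optional data frame with `participant`, optional logical
#'   `delirium_dsm5`, and numeric covariates for the ANOVA.
#' @param k_range candidate K values for both stages (default `1:10`).
#' @param restarts restarts per K for both stages (default 1000; can be a
#'   length-2 vector `c(stage1, stage2)`).
#' @param master_seed integer seed driving both stages.
#' @param alpha_fwer family-wise error rate of the post-hoc battery.
#' @param standardize z-score points before clustering (length-2 logical
#'   recycled over the stages; default `FALSE`).
#' @param aic_method AIC variant for [kmeans_aic()].
#' @param out_dir optional directory; when given, all result tables plus a
#'   `manifest.json` are written there (see [report_results()]).
#' @param verbose print stage progress to stderr.
#' @return An object of class `delphen_result`: list with `X`, `grouping`,
#'   `Xr`, `stage1`/`stage2` (`kselect` reports), `clusters`
#'   ([participant_clusters]), `severities`, `profile`, `labels`, `anova`,
#'   `embedding_features`, `embedding_participants`, `manifest`.
#' @export
#' @examples
#' coh <- simulate_cohort(default_design(), seed = 17)
#' res <- run_pipeline(coh$scores, coh$meta, restarts = 50, master_seed = 1)
#' res$stage1$selected_k
run_pipeline <- function(scores, meta = NULL, k_range = 1:10,
                         restarts = 1000L, master_seed = 1L,
                         alpha_fwer = 0.05, standardize = FALSE,
                         aic_method = c("fixed", "profile"),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(scores, "longitudinal_scores"))
  aic_method <- match.arg(aic_method)
  restarts <- rep_len(as.integer(restarts), 2L)
  standardize <- rep_len(as.logical(standardize), 2L)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 0: building wide matrix")
  X <- to_wide(scores)

  say("stage 1: feature grouping (%d restarts / K)", restarts[1L])
  grouping <- group_features(X, k_range = k_range, restarts = restarts[1L],
                             master_seed = master_seed,
                             standardize = standardize[1L],
                             aic_method = aic_method)
  say("stage 1: selected G = %d", grouping$G)
  Xr <- reduce_features(X, grouping)

  # continue the run counter so the two stages never share a seed
  stage2_seed <- derive_seed(master_seed,
                             length(grouping$report$k_range) * restarts[1L])
  say("stage 2: participant clustering (%d restarts / K)", restarts[2L])
  stage2 <- cluster_participants(Xr, k_range = k_range,
                                 restarts = restarts[2L],
                                 master_seed = stage2_seed,
                                 standardize = standardize[2L],
                                 aic_method = aic_method)
  say("stage 2: selected K = %d", stage2$selected_k)

  severities <- max_total_severity(scores)
  severities <- severities[rownames(X)]
  dsm5 <- NULL
  if (!is.null(meta) && "delirium_dsm5" %in% names(meta))
    dsm5 <- as.logical(meta$delirium_dsm5)[match(rownames(X),
                                                 meta$participant)]
  clusters <- participant_clusters(stage2$solution, severities, dsm5)

  profile <- NULL
  labels <- NULL
  if (stage2$selected_k >= 2L) {
    profile <- posthoc_profile(Xr, clusters,
                               characterization_config(alpha_fwer))
    labels <- interpret_labels(profile,
                               domains = guess_domains(grouping, Xr))
  } else {
    say("stage 3: K = 1, skipping post-hoc profile")
  }

  anova <- list()
  if (!is.null(meta)) {
    idx <- match(rownames(X), meta$participant)
    for (cov in setdiff(names(meta), c("participant", "delirium_dsm5"))) {
      v <- meta[[cov]][idx]
      if (is.numeric(v) && stage2$selected_k >= 2L)
        anova[[cov]] <- tryCatch(anova_across_clusters(v, clusters),
                                 error = function(e) NULL)
    }
  }

  embedding_features <- pca_2d(t(X))
  embedding_participants <- pca_2d(Xr)

  manifest <- list(
    package = "delphen",
    version = as.character(packageVersion("delphen")),
    master_seed = as.integer(master_seed),
    stage2_seed = stage2_seed,
    k_range = as.integer(k_range),
    restarts = restarts,
    aic_method = aic_method,
    standardize = standardize,
    alpha_fwer = alpha_fwer,
    selected_G = grouping$G,
    selected_K = stage2$selected_k,
    stage1_aic = aic_summary(grouping$report),
    stage2_aic = aic_summary(stage2),
    stage1_winning_seed = grouping$report$solution$seed,
    stage2_winning_seed = stage2$solution$seed)

  result <- structure(list(
    X = X, grouping = grouping, Xr = Xr, stage1 = grouping$report,
    stage2 = stage2, clusters = clusters, severities = severities,
    profile = profile, labels = labels, anova = anova,
    embedding_features = embedding_features,
    embedding_participants = embedding_participants,
    meta = meta, manifest = manifest), class = "delphen_result")

  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

# map grouped features to the four canonical clinical domains when the
# grouping looks like the standard 4-group structure; cosmetic only
guess_domains <- function(grouping, Xr) {
  if (grouping$G != 4L) return(rep("other", grouping$G))
  parsed <- tryCatch(parse_feature_labels(names(grouping$group_of)),
                     error = function(e) NULL)
  if (is.null(parsed)) return(rep("other", grouping$G))
  motor_items <- c("affective_lability", "motor_agitation",
                   "motor_retardation")
  vapply(seq_len(4L), function(g) {
    item <- parsed$item[grouping$group_of == g]
    day <- parsed$day[grouping$group_of == g]
    if (mean(item == "sleep_wake_cycle") >= 0.8) return("sleep")
    if (mean(day == 1L) >= 0.8) return("acute")
    if (mean(item %in% motor_items) >= 0.6) return("motor")
    "cognitive"
  }, character(1))
}

#' @export
print.delphen_result <- function(x, ...) {
  cat("Two-stage K-means phenotyping result\n")
  cat(sprintf("  %d participants x %d features -> %d grouped features -> %d clusters\n",
              nrow(x$X), ncol(x$X), x$grouping$G, x$stage2$selected_k))
  print(x$clusters)
  if (!is.null(x$labels)) {
    ord <- order(x$clusters$severity_rank)
    for (k in ord)
      cat(sprintf("  cluster rank %d: %s\n", x$clusters$severity_rank[k],
                  x$labels[k]))
  }
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Artifacts: `feature_grouping.tsv`, `participants.tsv`,
#' `cluster_summary.tsv`, `profile.tsv`, `anova.tsv`,
#' `embedding_features.tsv`, `embedding_participants.tsv`,
#' `manifest.json`. The manifest carries every seed, range and selected K
#' needed to replay the analysis (and any single K-means run); it contains
#' no timestamp, so identical configurations yield byte-identical
#' manifests.
#'
#' @param result a `delphen_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "delphen_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_feature_grouping(result$grouping, p("feature_grouping.tsv"))
  write.table(participant_assignments(result$clusters), p("participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cluster_summary(result$clusters, result$severities,
                              result$meta),
              p("cluster_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(result$profile))
    write_profile(result$profile, p("profile.tsv"), labels = result$labels)
  if (length(result$anova)) {
    adf <- do.call(rbind, lapply(names(result$anova), function(cov) {
      a <- result$anova[[cov]]
      data.frame(covariate = cov, F = a$F, df_between = a$df_between,
                 df_within = a$df_within, p = a$p,
                 stringsAsFactors = FALSE)
    }))
    write.table(adf, p("anova.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  dsm5 <- if (!is.null(result$meta) &&
              "delirium_dsm5" %in% names(result$meta))
    as.logical(result$meta$delirium_dsm5)[match(rownames(result$X),
                                                result$meta$participant)]
  write_projection(result$embedding_features,
                   group = result$grouping$group_of[colnames(result$X)],
                   path = p("embedding_features.tsv"))
  write_projection(result$embedding_participants,
                   group = result$clusters$solution$cluster,
                   diagnosis = dsm5,
                   path = p("embedding_participants.tsv"))
  write_json_results(result$manifest, p("manifest.json"))
  invisible(out_dir)
}

#' Render a text report from written pipeline artifacts
#'
#' Reads a [write_results()] directory (no recomputation) and renders a
#' human-readable summary: the selection outcome, a cluster-summary table
#' in severity order, and the symbolic post-hoc profile grid.
#'
#' @param results_dir directory written by [write_results()] /
#'   [run_pipeline()].
#' @return The report lines, invisibly; they are also printed.
#' @export
report_results <- function(results_dir) {
  need <- c("manifest.json", "cluster_summary.tsv", "feature_grouping.tsv",
            "participants.tsv")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing))
    stop("incomplete results bundle; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  manifest <- jsonlite::read_json(file.path(results_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  summ <- read.table(file.path(results_dir, "cluster_summary.tsv"),
                     header = TRUE, sep = "\t", check.names = FALSE)
  out <- c(
    sprintf("delphen pipeline report (seed %s)", manifest$master_seed),
    sprintf("feature groups: G = %s; participant clusters: K = %s",
            manifest$selected_G, manifest$selected_K),
    "", "cluster summary (severity order):",
    utils::capture.output(print(summ, row.names = FALSE)))
  prof_path <- file.path(results_dir, "profile.tsv")
  if (file.exists(prof_path)) {
    prof <- read.table(prof_path, header = TRUE, sep = "\t",
                       check.names = FALSE)
    out <- c(out, "", "post-hoc profile (vs cohort baseline):",
             utils::capture.output(print(prof, row.names = FALSE)))
  }
  cat(out, sep = "\n")
  invisible(out)
}
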