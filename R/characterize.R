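#' Configuration for post-hoc cluster characterization
#'
#' @param alpha_fwer family-wise error rate controlled by Bonferroni
#'   division over the full battery (default 0.05).
#' @param grading_cutoffs strictly decreasing corrected-p cutoffs that
#'   grade significant effects as `+` / `++` / `+++` (default 0.05, 0.01,
#'   0.001). The grades are a reporting convention of this package, not a
#'   property of the test.
#' @return A `characterization_config` object.
#' @export
characterization_config <- function(alpha_fwer = 0.05,
                                    grading_cutoffs = c(0.05, 0.01, 0.001)) {
  if (!is.numeric(alpha_fwer) || length(alpha_fwer) != 1L ||
      alpha_fwer <= 0 || alpha_fwer >= 1)
    stop("`alpha_fwer` must be in (0, 1)", call. = FALSE)
  if (length(grading_cutoffs) < 1L || any(diff(grading_cutoffs) >= 0) ||
      any(grading_cutoffs <= 0 | grading_cutoffs >= 1))
    stop("`grading_cutoffs` must be strictly decreasing values in (0, 1)",
         call. = FALSE)
  structure(list(alpha_fwer = alpha_fwer,
                 grading_cutoffs = as.numeric(grading_cutoffs)),
            class = "characterization_config")
}

#' One-sample t-test
#'
#' Two-sided Student t-test of `mean(values) = mu0` with `n - 1` degrees
#' of freedom. A degenerate (zero-variance) sample is reported as
#' `(t = 0, p = 1)` when its mean equals `mu0` and as an infinite
#' statistic with `p = 0` otherwise, flagged via `degenerate`.
#'
#' @param values numeric sample of size at least 2.
#' @param mu0 null-hypothesis mean.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3), 0)  # t = 2 sqrt(3), df = 2
one_sample_t <- function(values, mu0) {
  if (!is.numeric(values) || anyNA(values) || length(values) < 2L)
    stop("`values` must be a complete numeric sample of size >= 2",
         call. = FALSE)
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0))
    stop("`mu0` must be a single finite number", call. = FALSE)
  if (sd(values) == 0) {
    if (mean(values) == mu0)
      return(list(t = 0, p = 1, df = length(values) - 1L,
                  degenerate = TRUE))
    return(list(t = sign(mean(values) - mu0) * Inf, p = 0,
                df = length(values) - 1L, degenerate = TRUE))
  }
  ht <- t.test(values, mu = mu0)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Post-hoc profile of clusters against the cohort baseline
#'
#' For every (cluster, grouped feature) pair, tests with [one_sample_t()]
#' whether the cluster's mean composite equals the overall mean of that
#' composite across *all* participants (the baseline deliberately includes
#' the tested cluster's own members, which makes the battery mildly
#' conservative under the null). The family for Bonferroni correction is
#' the full battery of `m = K * G` tests: a pair is significant iff its
#' raw p-value is at most `alpha_fwer / m`. Significant pairs are graded
#' by where the corrected p-value (`min(1, m p)`) falls among
#' `grading_cutoffs`, and signed by the direction of the difference.
#'
#' Clusters with fewer than 2 members cannot be tested and are reported as
#' `N.S.` with `NA` statistics.
#'
#' @param Xr reduced matrix (participants x grouped features).
#' @param clustering cluster assignments: an integer vector, a
#'   `kmeans_solution`, or a [participant_clusters] object; must cover the
#'   rows of `Xr` with `K >= 2`.
#' @param config a [characterization_config].
#' @return An object of class `cluster_profile`: list with `table` (one
#'   row per test: `cluster`, `feature`, `n`, `mean`, `baseline`, `t`,
#'   `df`, `p`, `p_adj`, `significant`, `direction`, `grade`),
#'   `direction` and `grade` (`K x G` matrices), `K`, `G`, `m`, `config`.
#' @seealso [interpret_labels()], [format_profile()]
#' @export
posthoc_profile <- function(Xr, clustering,
                            config = characterization_config()) {
  check_matrix(Xr)
  stopifnot(inherits(config, "characterization_config"))
  assign <- cluster_assignments(clustering)
  if (length(assign) != nrow(Xr))
    stop("`clustering` must cover the rows of `Xr`", call. = FALSE)
  K <- max(assign)
  if (K < 2L) stop("post-hoc profiling needs K >= 2", call. = FALSE)
  if (!all(seq_len(K) %in% assign))
    stop("empty cluster in `clustering`", call. = FALSE)
  G <- ncol(Xr)
  features <- colnames(Xr)
  if (is.null(features)) features <- paste0("feature", seq_len(G))
  m <- K * G
  alpha <- config$alpha_fwer

  rows <- vector("list", m)
  i <- 0L
  for (k in seq_len(K)) {
    for (g in seq_len(G)) {
      i <- i + 1L
      vals <- Xr[assign == k, g]
      mu0 <- mean(Xr[, g])
      if (length(vals) < 2L) {
        tt <- list(t = NA_real_, p = NA_real_, df = NA_real_,
                   degenerate = TRUE)
      } else {
        tt <- one_sample_t(vals, mu0)
      }
      p_adj <- if (is.na(tt$p)) NA_real_ else min(1, tt$p * m)
      sig <- !is.na(tt$p) && tt$p <= alpha / m
      dir <- if (!sig) "N.S."
             else if (mean(vals) > mu0) "elevated" else "depressed"
      grade <- if (!sig) 0L else sum(p_adj <= config$grading_cutoffs)
      rows[[i]] <- data.frame(
        cluster = k, feature = features[g], n = length(vals),
        mean = mean(vals), baseline = mu0, t = tt$t, df = tt$df,
        p = tt$p, p_adj = p_adj, significant = sig, direction = dir,
        grade = grade, stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  direction <- matrix(table$direction, nrow = K, ncol = G, byrow = TRUE,
                      dimnames = list(paste0("cluster", seq_len(K)),
                                      features))
  grade <- matrix(table$grade, nrow = K, ncol = G, byrow = TRUE,
                  dimnames = dimnames(direction))
  structure(list(table = table, direction = direction, grade = grade,
                 K = K, G = G, m = m, config = config),
            class = "cluster_profile")
}

cluster_assignments <- function(clustering) {
  if (inherits(clustering, "participant_clusters"))
    return(clustering$solution$cluster)
  if (inherits(clustering, "kmeans_solution"))
    return(clustering$cluster)
  if (is.numeric(clustering) && all(clustering == round(clustering)))
    return(as.integer(clustering))
  stop("`clustering` must be assignments, a kmeans_solution, or a ",
       "participant_clusters object", call. = FALSE)
}

#' Symbolic profile grid
#'
#' Renders a [posthoc_profile()] as a `K x G` character grid with cells
#' `+`, `+ +`, `+ + +` (elevated), `-`, `- -`, `- - -` (depressed) or
#' `N.S.`.
#'
#' @param profile a `cluster_profile`.
#' @return Character matrix.
#' @export
format_profile <- function(profile) {
  stopifnot(inherits(profile, "cluster_profile"))
  out <- profile$direction
  for (i in seq_along(out)) {
    out[i] <- switch(profile$direction[i],
      elevated = paste(rep("+", profile$grade[i]), collapse = " "),
      depressed = paste(rep("-", profile$grade[i]), collapse = " "),
      "N.S.")
  }
  out
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf(
    "Post-hoc profile: %d cluster(s) x %d feature(s), %d tests,\n",
    x$K, x$G, x$m))
  cat(sprintf("  FWER alpha = %g (per-test threshold %.3g)\n",
              x$config$alpha_fwer, x$config$alpha_fwer / x$m))
  print(format_profile(x), quote = FALSE)
  invisible(x)
}

#' Write the symbolic profile grid as TSV
#'
#' @param profile a `cluster_profile`.
#' @param path output file.
#' @param labels optional per-cluster interpretation strings appended as a
#'   final column.
#' @export
write_profile <- function(profile, path, labels = NULL) {
  grid <- format_profile(profile)
  df <- data.frame(cluster = seq_len(nrow(grid)), grid,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(labels)) df$interpretation <- labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-way ANOVA of a covariate across clusters
#'
#' Fixed-effects one-way analysis of variance of a per-participant
#' covariate over cluster membership. Missing covariate values are dropped
#' (complete-case); clusters left with fewer than 2 complete members are
#' excluded with a warning.
#'
#' @param covariate numeric per-participant vector (`NA` allowed).
#' @param clustering assignments as in [posthoc_profile()].
#' @return List with `F`, `df_between`, `df_within`, `p`,
#'   `excluded_clusters`.
#' @export
#' @examples
#' anova_across_clusters(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))  # F = 13.5
anova_across_clusters <- function(covariate, clustering) {
  assign <- cluster_assignments(clustering)
  if (length(covariate) != length(assign))
    stop("`covariate` must have one value per clustered participant",
         call. = FALSE)
  keep <- !is.na(covariate)
  covariate <- covariate[keep]
  assign <- assign[keep]
  sizes <- table(assign)
  small <- as.integer(names(sizes)[sizes < 2L])
  if (length(small)) {
    warning("excluding cluster(s) with < 2 complete members: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(assign %in% small)
    covariate <- covariate[keep]
    assign <- assign[keep]
  }
  if (length(unique(assign)) < 2L)
    stop("ANOVA needs at least 2 clusters with >= 2 members each",
         call. = FALSE)
  if (var(covariate) == 0)
    stop("zero total variance in `covariate`", call. = FALSE)
  ht <- oneway.test(covariate ~ factor(assign), var.equal = TRUE)
  list(F = unname(ht$statistic), df_between = unname(ht$parameter[1L]),
       df_within = unname(ht$parameter[2L]), p = ht$p.value,
       excluded_clusters = small)
}

#' Clinical-style interpretation of direction patterns
#'
#' Maps each cluster's per-domain direction pattern to one of the seven
#' archetypal phenotype labels; patterns matching none of the rules fall
#' back to `"unclassified pattern"`. The rules operate on the four
#' canonical symptom domains; `domains` states which profile column plays
#' which role. With a feature count other than four, or domains outside
#' the canonical set, every cluster is `"unclassified pattern"`.
#'
#' Rules (`+` elevated, `-` depressed, `0` not significant), in the
#' order (motor, cognitive, acute, sleep):
#' `0 + 0 0` cognitive and higher-order thinking domain dominant
#' delirium; `+ + + 0` prolonged delirium; `0 0 + 0` acute and brief
#' delirium; `+ + 0 0` subsyndromal delirium-enriched; `0 + 0 +`
#' subsyndromal delirium-enriched with insomnia; `- - - +` insomnia;
#' `- - - -` fit.
#'
#' @param profile a `cluster_profile`.
#' @param domains character vector of length `G` assigning each profile
#'   feature one of `"motor"`, `"cognitive"`, `"acute"`, `"sleep"`.
#' @return Character vector of per-cluster labels.
#' @export
interpret_labels <- function(profile,
                             domains = c("motor", "cognitive", "acute",
                                         "sleep")) {
  stopifnot(inherits(profile, "cluster_profile"))
  canonical <- c("motor", "cognitive", "acute", "sleep")
  if (length(domains) != profile$G || !setequal(domains, canonical) ||
      anyDuplicated(domains))
    return(rep("unclassified pattern", profile$K))
  sym <- c(elevated = "+", depressed = "-", N.S. = "0")
  pat <- matrix(sym[profile$direction], nrow = profile$K)
  colnames(pat) <- domains
  pat <- pat[, canonical, drop = FALSE]
  rules <- c(
    "0+00" = "cognitive and higher-order thinking domain dominant delirium",
    "+++0" = "prolonged delirium",
    "00+0" = "acute and brief delirium",
    "++00" = "subsyndromal delirium-enriched",
    "0+0+" = "subsyndromal delirium-enriched with insomnia",
    "---+" = "insomnia",
    "----" = "fit")
  keys <- apply(pat, 1L, paste, collapse = "")
  out <- unname(rules[keys])
  out[is.na(out)] <- "unclassified pattern"
  out
}
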