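#' Default planted cohort design
#'
#' A synthetic stand-in for a 286-participant postoperative cohort
#' assessed on the 13 DRS-R-98 severity items over 5 days. The design
#' plants both structures the pipeline is meant to recover:
#'
#' *Feature partition* (4 groups over the 65 `item@day` cells):
#' * `sleep` -- the sleep--wake cycle item on all 5 days;
#' * `acute` -- every non-sleep item on day 1 (the acute/temporal block);
#' * `motor` -- affective lability and the two motor items on days 2--5;
#' * `cognitive` -- the cognitive/higher-order items plus perceptual
#'   disturbance and delusion on days 2--5.
#'
#' This partition is an explicit approximation of the qualitative
#' description of the four recovered symptom groups (sleep-only, day-1
#' acute, cognitive/higher-order, mixed motor); it is configuration, not
#' code, and can be edited freely.
#'
#' *Participant archetypes* (7, sizes summing to 286): group-mean severity
#' profiles realize the archetypal elevated/neutral/depressed patterns
#' (elevated = 2.0 mean item score, neutral = 0.5, depressed = 0.2), with
#' per-archetype delirium-diagnosis probabilities equal to the published
#' per-cluster count ratios (6/6, 8/8, 13/13, 27/28, 20/26, 12/80,
#' 5/125).
#'
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   applied per cell before rounding and clipping (default 0.4, the
#'   reference noise level).
#' @return An object of class `planted_design`.
#' @seealso [simulate_cohort()], [planted_design()]
#' @export
#' @examples
#' d <- default_design()
#' sum(d$archetypes$size)  # 286
default_design <- function(noise_sd = 0.4) {
  catalog <- item_catalog()
  n_days <- 5L
  labels <- feature_labels(catalog, n_days)
  parsed <- parse_feature_labels(labels, catalog)
  motor_items <- c("affective_lability", "motor_agitation",
                   "motor_retardation")
  part <- ifelse(parsed$item == "sleep_wake_cycle", "sleep",
          ifelse(parsed$day == 1L, "acute",
          ifelse(parsed$item %in% motor_items, "motor", "cognitive")))
  names(part) <- labels

  archetypes <- data.frame(
    name = c("cognitive_dominant", "prolonged", "acute_brief",
             "subsyndromal", "subsyndromal_insomnia", "insomnia", "fit"),
    size = c(6L, 8L, 13L, 28L, 26L, 80L, 125L),
    delirium_prob = c(6 / 6, 8 / 8, 13 / 13, 27 / 28, 20 / 26, 12 / 80,
                      5 / 125),
    stringsAsFactors = FALSE)

  hi <- 2.0; mid <- 0.5; lo <- 0.2
  profiles <- rbind(
    cognitive_dominant    = c(mid, hi,  mid, mid),
    prolonged             = c(hi,  hi,  hi,  mid),
    acute_brief           = c(mid, mid, hi,  mid),
    subsyndromal          = c(hi,  hi,  mid, mid),
    subsyndromal_insomnia = c(mid, hi,  mid, hi),
    insomnia              = c(lo,  lo,  lo,  hi),
    fit                   = c(lo,  lo,  lo,  lo))
  colnames(profiles) <- c("motor", "cognitive", "acute", "sleep")

  planted_design(part, archetypes, profiles, noise_sd = noise_sd,
                 catalog = catalog, n_days = n_days)
}

#' Construct and validate a planted design
#'
#' @param feature_partition named character vector assigning every
#'   `item@day` label to a planted group; every group must be non-empty.
#' @param archetypes data frame with columns `name`, `size` (>= 1),
#'   `delirium_prob` (in `[0, 1]`).
#' @param profiles numeric archetype x group matrix of mean item scores;
#'   rows match `archetypes$name`, columns the group names. Means are
#'   constant across days within a group (day structure enters through the
#'   partition itself).
#' @param noise_sd non-negative noise standard deviation.
#' @param catalog an [item_catalog].
#' @param n_days number of days.
#' @return A `planted_design` object.
#' @export
planted_design <- function(feature_partition, archetypes, profiles,
                           noise_sd = 0.4, catalog = item_catalog(),
                           n_days = 5L) {
  labels <- feature_labels(catalog, n_days)
  if (is.null(names(feature_partition)) ||
      !setequal(names(feature_partition), labels) ||
      anyDuplicated(names(feature_partition)))
    stop("`feature_partition` must cover every item@day cell exactly once",
         call. = FALSE)
  groups <- colnames(profiles)
  if (is.null(groups) || anyDuplicated(groups))
    stop("`profiles` must have unique group colnames", call. = FALSE)
  if (!setequal(unique(feature_partition), groups))
    stop("partition groups and profile columns must agree", call. = FALSE)
  if (!is.data.frame(archetypes) ||
      !all(c("name", "size", "delirium_prob") %in% names(archetypes)))
    stop("`archetypes` needs columns name, size, delirium_prob",
         call. = FALSE)
  if (any(archetypes$size < 1L) ||
      any(archetypes$size != round(archetypes$size)))
    stop("archetype sizes must be positive integers", call. = FALSE)
  if (any(archetypes$delirium_prob < 0 | archetypes$delirium_prob > 1))
    stop("`delirium_prob` must lie in [0, 1]", call. = FALSE)
  if (!is.matrix(profiles) || nrow(profiles) != nrow(archetypes))
    stop("`profiles` must have one row per archetype", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  structure(list(feature_partition = feature_partition[labels],
                 groups = groups, archetypes = archetypes,
                 profiles = profiles, noise_sd = noise_sd,
                 catalog = catalog, n_days = as.integer(n_days)),
            class = "planted_design")
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf(
    "Planted design: %d participants, %d archetypes, %d feature groups, noise sd %g\n",
    sum(x$archetypes$size), nrow(x$archetypes), length(x$groups),
    x$noise_sd))
  cat("  group sizes:",
      paste(sprintf("%s=%d", x$groups,
                    as.vector(table(x$feature_partition)[x$groups])),
            collapse = ", "), "\n")
  invisible(x)
}

# Table-2-like per-archetype mean ages and baseline cognition used for the
# optional covariate draws (independent normals; no attempt at the joint
# covariate distribution of a real cohort).
archetype_age_means <- c(70.8, 75.6, 68.5, 73.1, 70.3, 63.4, 63.9)
archetype_mmse_means <- c(26.8, 27.1, 27.6, 27.8, 28.4, 28.8, 28.7)

#' Simulate a synthetic cohort from a planted design
#'
#' Participants are assigned to archetypes in design order (sizes are
#' exact, not multinomial). Each cell score is
#' `round(clip(mean(archetype, group(cell)) + N(0, noise_sd)))` into the
#' catalogue's score range; the DSM-5 diagnosis label is a Bernoulli draw
#' with the archetype's probability. With `covariates = TRUE` (default for
#' the 7-archetype design), age and a baseline cognition score are drawn
#' as independent archetype-shifted normals for exercising the
#' across-cluster ANOVA. Everything is reproducible from `seed`; the
#' caller's RNG state is untouched.
#'
#' @param design a [planted_design].
#' @param seed integer seed.
#' @param covariates draw age / baseline cognition covariates? Only
#'   available for 7-archetype designs.
#' @return An object of class `synthetic_cohort`: list with `scores`
#'   ([longitudinal_scores]), `meta` (data frame `participant`,
#'   `delirium_dsm5`, covariates), `truth` (list: `archetype` named
#'   integer vector, `archetype_names`, `feature_partition`, `seed`).
#' @export
#' @examples
#' coh <- simulate_cohort(default_design(), seed = 17)
#' table(coh$truth$archetype)
simulate_cohort <- function(design, seed = 1L,
                            covariates = nrow(design$archetypes) == 7L) {
  stopifnot(inherits(design, "planted_design"))
  n <- sum(design$archetypes$size)
  arch <- rep(seq_len(nrow(design$archetypes)), design$archetypes$size)
  ids <- sprintf(paste0("P%0", nchar(n), "d"), seq_len(n))
  labels <- names(design$feature_partition)
  lo <- design$catalog$score_min
  hi <- design$catalog$score_max

  mu <- design$profiles[arch, design$feature_partition, drop = FALSE]
  cohort <- with_seed(seed, {
    X <- matrix(round(pmin(hi, pmax(lo, mu + rnorm(length(mu), 0,
                                                   design$noise_sd)))),
                nrow = n, dimnames = list(ids, labels))
    dsm5 <- runif(n) < design$archetypes$delirium_prob[arch]
    meta <- data.frame(participant = ids, delirium_dsm5 = dsm5,
                       stringsAsFactors = FALSE)
    if (covariates) {
      if (nrow(design$archetypes) != 7L)
        stop("covariate draws are defined for 7-archetype designs only",
             call. = FALSE)
      meta$age <- round(rnorm(n, archetype_age_means[arch], 8), 1)
      meta$baseline_cognition <-
        pmin(30, round(rnorm(n, archetype_mmse_means[arch], 1.5), 1))
    }
    list(X = X, meta = meta)
  })

  scores <- wide_to_long(cohort$X, design$catalog, design$n_days)
  structure(list(
    scores = scores, meta = cohort$meta,
    truth = list(archetype = structure(arch, names = ids),
                 archetype_names = design$archetypes$name,
                 feature_partition = design$feature_partition,
                 seed = as.integer(seed)),
    design = design), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(x$truth$archetype)
  cat(sprintf(
    "Synthetic cohort: %d participants (seed %d), %d with delirium label\n",
    n, x$truth$seed, sum(x$meta$delirium_dsm5)))
  print(table(archetype = x$truth$archetype_names[x$truth$archetype])[
    x$truth$archetype_names])
  invisible(x)
}

#' Write a cohort to disk
#'
#' Long-format scores CSV, metadata CSV, and a truth JSON holding the
#' planted partition, per-participant archetypes and the seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_long(cohort$scores, file.path(dir, "scores.csv"))
  write.table(cohort$meta, file.path(dir, "meta.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write_json_results(list(
    seed = cohort$truth$seed,
    archetype = as.list(cohort$truth$archetype),
    archetype_names = cohort$truth$archetype_names,
    feature_partition = as.list(cohort$truth$feature_partition)),
    file.path(dir, "truth.json"))
  invisible(dir)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of the
#' same objects; 1 means identical up to relabeling, 0 is the expectation
#' under independent random partitions. Used as the planted-structure
#' recovery metric.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length", call. = FALSE)
  if (length(labels_a) == 0L)
    stop("labelings must be non-empty", call. = FALSE)
  mclust::adjustedRandIndex(labels_a, labels_b)
}
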