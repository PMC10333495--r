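test_that("one-sample t matches textbook closed forms", {
  r <- one_sample_t(c(1, 2, 3), 2)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  for (case in 1:10) {
    set.seed(case)
    x <- rnorm(sample(3:20, 1))
    mu0 <- rnorm(1)
    got <- one_sample_t(x, mu0)
    ref <- textbook_t(x, mu0)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("degenerate samples are flagged, not mis-tested", {
  r <- one_sample_t(c(2, 2, 2), 2)
  expect_true(r$degenerate)
  expect_equal(c(r$t, r$p), c(0, 1))
  r <- one_sample_t(c(2, 2, 2), 0)
  expect_true(r$degenerate && is.infinite(r$t) && r$p == 0)
  expect_error(one_sample_t(3, 0), "size >= 2")
})

test_that("across-cluster ANOVA matches hand-computed sums of squares", {
  a <- anova_across_clusters(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(a$F, 13.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 4)

  for (case in 1:10) {
    set.seed(case + 50)
    groups <- rep(1:3, c(5, 7, 6))
    v <- rnorm(length(groups), mean = groups)
    got <- anova_across_clusters(v, groups)
    ref <- textbook_anova(v, groups)
    expect_equal(got$F, ref$F, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("ANOVA guards degenerate inputs", {
  expect_error(anova_across_clusters(rep(1, 6), rep(1:2, each = 3)),
               "zero total variance")
  expect_warning(
    a <- anova_across_clusters(c(1, 2, 3, 4, 9), c(1, 1, 2, 2, 3)),
    "excluding cluster")
  expect_equal(a$excluded_clusters, 3L)
  expect_error(
    suppressWarnings(anova_across_clusters(c(1, 2, 9), c(1, 1, 2))),
    "at least 2 clusters")
})

test_that("ANOVA p-values are calibrated under the null", {
  set.seed(99)
  p <- replicate(400, {
    v <- rnorm(40)
    anova_across_clusters(v, rep(1:2, each = 20))$p
  })
  expect_gt(mean(p), 0.4)
  expect_lt(mean(p), 0.6)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("the Bonferroni contract holds in both directions", {
  set.seed(7)
  Xr <- matrix(rnorm(60 * 3), 60, 3,
               dimnames = list(NULL, paste0("f", 1:3)))
  assign <- rep(1:4, each = 15)
  prof <- posthoc_profile(Xr, assign)
  m <- prof$m
  expect_equal(m, 12L)
  with(prof$table, {
    expect_identical(significant, p <= 0.05 / m)
    expect_identical(direction == "N.S.", !significant)
    # sign of direction equals sign of (cluster mean - baseline)
    expect_true(all(direction[significant] ==
      ifelse(mean[significant] > baseline[significant],
             "elevated", "depressed")))
  })
})

test_that("an extreme shifted cluster is elevated at the maximum grade", {
  set.seed(8)
  Xr <- matrix(rnorm(400 * 2), 400, 2,
               dimnames = list(NULL, c("f1", "f2")))
  assign <- rep(1:2, each = 200)
  Xr[assign == 2, 1] <- Xr[assign == 2, 1] + 10
  prof <- posthoc_profile(Xr, assign)
  expect_identical(prof$direction[2, "f1"], "elevated")
  expect_equal(prof$grade[2, "f1"], 3L)
  expect_identical(format_profile(prof)[2, "f1"], "+ + +")
})

test_that("the insomnia archetype profiles as sleep-elevated only", {
  coh <- simulate_cohort(default_design(), seed = 17)
  X <- to_wide(coh$scores)
  g <- feature_grouping(structure(
    match(coh$truth$feature_partition, colnames(coh$design$profiles)),
    names = names(coh$truth$feature_partition)))
  Xr <- reduce_features(X, g)  # columns group1..group4 = motor, cognitive, acute, sleep
  prof <- posthoc_profile(Xr, unname(coh$truth$archetype))
  expect_identical(unname(prof$direction[6, ]),
                   c("depressed", "depressed", "depressed", "elevated"))
  expect_identical(unname(prof$direction[7, ]), rep("depressed", 4))
})

test_that("direction patterns map to the archetypal interpretations", {
  fake <- function(pattern) {
    structure(list(direction = matrix(pattern, nrow = 1), K = 1L, G = 4L),
              class = "cluster_profile")
  }
  expect_identical(
    interpret_labels(fake(c("N.S.", "elevated", "N.S.", "N.S."))),
    "cognitive and higher-order thinking domain dominant delirium")
  expect_identical(
    interpret_labels(fake(rep("depressed", 4))), "fit")
  expect_identical(
    interpret_labels(fake(c("depressed", "depressed", "depressed",
                            "elevated"))), "insomnia")
  expect_identical(
    interpret_labels(fake(c("elevated", "N.S.", "N.S.", "elevated"))),
    "unclassified pattern")
  # domains other than the canonical four fall back to unclassified
  expect_identical(
    interpret_labels(fake(rep("depressed", 4)), domains = rep("x", 4)),
    "unclassified pattern")
})

test_that("configuration invariants are enforced", {
  expect_error(characterization_config(alpha_fwer = 0), "alpha")
  expect_error(characterization_config(grading_cutoffs = c(0.01, 0.05)),
               "decreasing")
  expect_error(posthoc_profile(matrix(rnorm(20), 10, 2), rep(1L, 10)),
               "K >= 2")
  expect_error(posthoc_profile(matrix(rnorm(20), 10, 2),
                               c(rep(1L, 9), 3L)), "empty cluster")
})
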