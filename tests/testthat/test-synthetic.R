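test_that("the default design encodes the planted study structure", {
  d <- default_design()
  expect_equal(sum(d$archetypes$size), 286L)
  expect_equal(as.vector(table(d$feature_partition)[
    c("sleep", "acute", "motor", "cognitive")]), c(5L, 12L, 12L, 36L))
  expect_equal(d$archetypes$delirium_prob[7], 0.04)
  # insomnia archetype is elevated on the sleep group only
  ins <- d$profiles["insomnia", ]
  expect_equal(unname(which(ins == max(ins))),
               unname(which(colnames(d$profiles) == "sleep")))
  expect_true(all(ins[colnames(d$profiles) != "sleep"] < 0.5))
})

test_that("design validation rejects malformed inputs", {
  d <- default_design()
  bad <- d$feature_partition[-1]
  expect_error(planted_design(bad, d$archetypes, d$profiles),
               "exactly once")
  arch <- d$archetypes; arch$delirium_prob[1] <- 1.5
  expect_error(planted_design(d$feature_partition, arch, d$profiles),
               "\\[0, 1\\]")
  expect_error(planted_design(d$feature_partition, d$archetypes,
                              d$profiles, noise_sd = -1), "non-negative")
})

test_that("simulated cohorts are bounded, complete and reproducible", {
  coh <- simulate_cohort(default_design(), seed = 4)
  expect_true(all(coh$scores$records$score %in% 0:3))
  expect_true(all(complete_participants(coh$scores)))
  expect_equal(length(unique(coh$scores$records$participant)), 286L)

  again <- simulate_cohort(default_design(), seed = 4)
  expect_identical(coh$scores$records, again$scores$records)
  expect_identical(coh$meta, again$meta)
  other <- simulate_cohort(default_design(), seed = 5)
  expect_false(identical(coh$scores$records, other$scores$records))
})

test_that("zero noise with integer means reproduces the means exactly", {
  d <- default_design(noise_sd = 0)
  d$profiles[] <- ifelse(d$profiles >= 1, 2, 0)
  coh <- simulate_cohort(d, seed = 1)
  X <- to_wide(coh$scores)
  mu <- d$profiles[coh$truth$archetype, d$feature_partition[colnames(X)]]
  expect_equal(unname(X), unname(mu))
})

test_that("the adjusted Rand index matches pair-counting enumeration", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c("x", "x", "y"), c(1, 1, 2)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               brute_force_ari(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  for (case in 1:5) {
    set.seed(case)
    a <- sample(1:3, 12, TRUE)
    b <- sample(1:3, 12, TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_force_ari(a, b),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("a noiseless cohort is recovered perfectly by both stages", {
  coh <- simulate_cohort(default_design(noise_sd = 0), seed = 2)
  X <- to_wide(coh$scores)
  g <- group_features(X, restarts = 60, master_seed = 3)
  expect_equal(g$G, 4L)
  expect_equal(adjusted_rand_index(
    g$group_of, coh$truth$feature_partition[names(g$group_of)]), 1)
  rep2 <- cluster_participants(reduce_features(X, g), restarts = 60,
                               master_seed = 4)
  expect_equal(rep2$selected_k, 7L)
  expect_equal(adjusted_rand_index(rep2$solution$cluster,
                                   coh$truth$archetype), 1)
})

test_that("recovery degrades monotonically with the noise level", {
  # grid starts at the reference noise: below ~0.3 the rounding threshold
  # sitting exactly at the neutral mean makes effective cell noise
  # non-monotone in noise_sd (see the methods vignette)
  noise_grid <- c(0.4, 0.8, 1.2)
  mean_ari <- vapply(noise_grid, function(ns) {
    ari <- vapply(1:5, function(s) {
      coh <- simulate_cohort(default_design(noise_sd = ns), seed = s)
      X <- to_wide(coh$scores)
      g <- group_features(X, restarts = 30, master_seed = s)
      f_ari <- adjusted_rand_index(
        g$group_of, coh$truth$feature_partition[names(g$group_of)])
      rep2 <- cluster_participants(reduce_features(X, g), restarts = 30,
                                   master_seed = s + 100)
      p_ari <- adjusted_rand_index(rep2$solution$cluster,
                                   coh$truth$archetype)
      (f_ari + p_ari) / 2
    }, numeric(1))
    mean(ari)
  }, numeric(1))
  expect_true(all(diff(mean_ari) <= 1e-9))
})

test_that("cohorts round-trip to disk with their truth", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(default_design(), seed = 11)
  write_cohort(coh, dir)
  back <- read_long(file.path(dir, "scores.csv"))
  expect_identical(back$records, coh$scores$records)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 11L)
  expect_equal(unlist(truth$archetype[["P001"]]), 1L, ignore_attr = TRUE)
})
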