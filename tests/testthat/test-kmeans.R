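test_that("lloyd matches closed forms at the extremes", {
  set.seed(42)
  pts <- matrix(rnorm(30), 10, 3)

  one <- lloyd(pts, K = 1, seed = 5)
  expect_equal(one$centers[1, ], colMeans(pts), ignore_attr = TRUE)
  expect_equal(one$wcss, sum(scale(pts, scale = FALSE)^2))

  all_k <- lloyd(pts, K = 10, seed = 5)
  expect_equal(all_k$wcss, 0)
  expect_setequal(all_k$cluster, 1:10)
})

test_that("lloyd finds the global optimum of the two-pair configuration", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  fit <- select_k(pts, k_range = 2, restarts = 10, master_seed = 1)$solution
  expect_equal(fit$wcss, 1.0)
  expect_identical(fit$cluster[1], fit$cluster[2])
  expect_identical(fit$cluster[3], fit$cluster[4])
  # exhaustive enumeration confirms 1.0 is the global optimum
  expect_equal(brute_force_wcss(pts, 2), 1.0)
})

test_that("lloyd validates its arguments", {
  pts <- matrix(rnorm(10), 5, 2)
  expect_error(lloyd(pts, K = 6, seed = 1), "K")
  expect_error(lloyd(pts, K = 0, seed = 1), "K")
  pts[1, 1] <- NA
  expect_error(lloyd(pts, K = 2, seed = 1), "non-finite")
})

test_that("the objective is non-increasing across lloyd iterations", {
  for (case in 1:20) {
    set.seed(case)
    pts <- matrix(rnorm(40 * 3), 40, 3)
    fit <- lloyd(pts, K = sample(2:6, 1), seed = case + 100)
    expect_true(all(diff(fit$wcss_trace) <= 1e-9))
    # reported wcss is the objective of the returned partition
    expect_equal(fit$wcss, partition_wcss(pts, fit$cluster))
  }
})

test_that("multi-restart selection attains the brute-force optimum", {
  for (case in 1:5) {
    set.seed(case)
    n <- sample(6:8, 1)
    K <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    opt <- brute_force_wcss(pts, K)
    rep <- select_k(pts, k_range = K, restarts = 200, master_seed = case)
    expect_gte(rep$solution$wcss, opt - 1e-9)
    expect_lt(rep$solution$wcss, opt + 1e-9)
  }
})

test_that("lloyd agrees with stats::kmeans on well-separated blobs", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 5, 0.3), 20))
  ours <- select_k(pts, k_range = 2, restarts = 30, master_seed = 1)
  ref <- kmeans(pts, centers = 2, nstart = 30, algorithm = "Lloyd")
  expect_equal(ours$solution$wcss, ref$tot.withinss, tolerance = 1e-10)
})

test_that("kmeans_aic implements both variants and their contracts", {
  # spherical-Gaussian profile-likelihood value, direct evaluation
  expect_equal(kmeans_aic(1, K = 2, n = 4, d = 2, method = "profile"),
               8 * log(1 / 8) + 8)
  for (method in c("fixed", "profile")) {
    # monotone in wcss at fixed K
    expect_lt(kmeans_aic(1, K = 3, n = 50, d = 4, method = method),
              kmeans_aic(2, K = 3, n = 50, d = 4, method = method))
    # +2d penalty per extra cluster at equal wcss
    expect_equal(kmeans_aic(5, K = 4, n = 50, d = 4, method = method) -
                 kmeans_aic(5, K = 3, n = 50, d = 4, method = method),
                 2 * 4)
  }
  # the floor guards perfect fits
  expect_true(is.finite(kmeans_aic(0, K = 2, n = 10, d = 2,
                                   method = "profile")))
  expect_error(kmeans_aic(1, K = 2, n = 0, d = 2), "positive integers")
})

test_that("select_k selects the argmin of the full recorded AIC table", {
  set.seed(21)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 8, 0.3), 20))
  rep <- select_k(pts, k_range = 1:5, restarts = 25, master_seed = 9)
  expect_equal(nrow(rep$table), 5 * 25)
  expect_equal(rep$solution$aic, min(rep$table$aic))
  expect_equal(rep$selected_k,
               rep$table$K[which.min(rep$table$aic)])
  expect_equal(rep$selected_k, 2L)
  # every recorded run is replayable in isolation from its seed
  row <- rep$table[17, ]
  replay <- lloyd(pts, row$K, row$seed)
  expect_equal(replay$wcss, row$wcss)
})

test_that("selection is deterministic and honours singleton ranges", {
  set.seed(2)
  pts <- matrix(rnorm(60), 30, 2)
  a <- select_k(pts, k_range = 1:4, restarts = 15, master_seed = 77)
  b <- select_k(pts, k_range = 1:4, restarts = 15, master_seed = 77)
  expect_identical(a$table, b$table)
  expect_identical(a$solution$cluster, b$solution$cluster)

  only3 <- select_k(pts, k_range = 3, restarts = 10, master_seed = 1)
  expect_equal(only3$selected_k, 3L)
})

test_that("wcss and AIC are invariant under cluster relabeling", {
  set.seed(33)
  pts <- matrix(rnorm(50), 25, 2)
  fit <- lloyd(pts, K = 3, seed = 8)
  perm <- c(3L, 1L, 2L)
  relabeled <- perm[fit$cluster]
  expect_equal(partition_wcss(pts, relabeled), fit$wcss)
  expect_equal(kmeans_aic(partition_wcss(pts, relabeled), K = 3,
                          n = 25, d = 2),
               kmeans_aic(fit$wcss, K = 3, n = 25, d = 2))
})
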