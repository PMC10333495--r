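# Independent oracles and small fixture builders used across the suite.

# exhaustive minimum-WCSS partition of n points into exactly K non-empty
# clusters (feasible for n <= 8, K <= 3)
brute_force_wcss <- function(points, K) {
  n <- nrow(points)
  stopifnot(n <= 10, K <= 4)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) != K) next
    w <- partition_wcss(points, a)
    if (w < best) best <- w
  }
  best
}

# WCSS of an assignment about its cluster means
partition_wcss <- function(points, assign) {
  sum(vapply(unique(assign), function(k) {
    sub <- points[assign == k, , drop = FALSE]
    sum(scale(sub, center = TRUE, scale = FALSE)^2)
  }, numeric(1)))
}

# adjusted Rand index by direct enumeration of all object pairs
brute_force_ari <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pairs <- pairs + 1
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      s_a <- s_a + same_a
      s_b <- s_b + same_b
      s_both <- s_both + (same_a && same_b)
    }
  }
  expected <- s_a * s_b / pairs
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_both - expected) / (max_index - expected)
}

# textbook one-sample t
textbook_t <- function(x, mu0) {
  t <- (mean(x) - mu0) / (sd(x) / sqrt(length(x)))
  list(t = t, p = 2 * pt(-abs(t), df = length(x) - 1))
}

# textbook one-way fixed-effects ANOVA
textbook_anova <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, df_between = dfb, df_within = dfw,
       p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# complete toy longitudinal record set with random in-range scores
toy_records <- function(ids, catalog = item_catalog(), n_days = 5L,
                        seed = 1) {
  set.seed(seed)
  rec <- expand.grid(participant = ids, day = seq_len(n_days),
                     item = catalog$items, stringsAsFactors = FALSE)
  rec$score <- sample(catalog$score_min:catalog$score_max, nrow(rec),
                      replace = TRUE)
  rec
}

# minimal kmeans_solution stub for rank/label unit tests
stub_solution <- function(cluster) {
  structure(list(K = max(cluster), cluster = as.integer(cluster)),
            class = "kmeans_solution")
}
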