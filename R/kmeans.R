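#' Lloyd's K-means with deterministic tie-breaking
#'
#' One K-means fit from one seeded initialization. Initial centroids are
#' `K` distinct data points sampled uniformly without replacement.
#' Iterations alternate nearest-centroid assignment (squared Euclidean
#' distance, ties broken toward the lowest cluster index) and mean
#' updates, until the assignment stabilizes, the largest centroid shift
#' falls below `tol`, or `max_iter` is reached. A cluster left empty by an
#' assignment step is reseeded at the point currently farthest from its
#' own centroid, so every cluster index `1..K` always appears.
#'
#' @param points numeric `n x d` matrix (rows are points).
#' @param K number of clusters, `1 <= K <= n`.
#' @param seed integer seed for the initialization (the caller's RNG state
#'   is left untouched).
#' @param max_iter maximum number of Lloyd iterations (default 300).
#' @param tol convergence threshold on the largest Euclidean centroid
#'   shift (default 1e-6).
#' @return An object of class `kmeans_solution`: list with `K`, `cluster`
#'   (assignments in `1..K`), `centers` (`K x d`), `wcss` (within-cluster
#'   sum of squared distances of the returned partition), `wcss_trace`
#'   (objective after each iteration; non-increasing), `aic` (`NA` until
#'   scored), `n_iter`, `seed`, `converged`.
#' @seealso [select_k()], [kmeans_aic()]
#' @export
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' lloyd(pts, K = 2, seed = 1)$wcss  # 1: each pair contributes 2 * 0.5^2
lloyd <- function(points, K, seed, max_iter = 300L, tol = 1e-6) {
  check_matrix(points, "points")
  n <- nrow(points)
  d <- ncol(points)
  if (!is_count(K) || K > n)
    stop(sprintf("`K` must be an integer in [1, %d]", n), call. = FALSE)
  if (!is_count(max_iter)) stop("`max_iter` must be >= 1", call. = FALSE)
  if (!is.numeric(tol) || tol < 0) stop("`tol` must be >= 0", call. = FALSE)
  K <- as.integer(K)

  centers <- with_seed(seed,
    points[sample.int(n, K), , drop = FALSE])
  xsq <- rowSums(points^2)
  total_sq <- sum(xsq)
  assign_prev <- integer(n)
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # n x K squared distances; max.col(-D, "first") gives the lowest index
    # among tied nearest centroids
    D <- outer(xsq, rowSums(centers^2), "+") - 2 * (points %*% t(centers))
    assign <- max.col(-D, ties.method = "first")
    dmin <- D[cbind(seq_len(n), assign)]
    for (k in seq_len(K)) {
      if (!any(assign == k)) {
        far <- which.max(dmin)
        assign[far] <- k
        dmin[far] <- -Inf
      }
    }
    counts <- tabulate(assign, K)
    new_centers <- rowsum(points, assign) / counts
    # objective of the current partition about its means:
    # sum ||x||^2 - sum_k n_k ||mu_k||^2
    trace <- c(trace, max(total_sq - sum(counts * rowSums(new_centers^2)), 0))
    shift2 <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    same <- identical(assign, assign_prev)
    assign_prev <- assign
    if (same || shift2 < tol^2) {
      converged <- TRUE
      break
    }
  }

  dimnames(centers) <- list(NULL, colnames(points))
  structure(list(K = K, cluster = assign, centers = centers,
                 wcss = trace[length(trace)], wcss_trace = trace,
                 aic = NA_real_, n_iter = length(trace),
                 seed = as.integer(seed), converged = converged),
            class = "kmeans_solution")
}

#' @export
print.kmeans_solution <- function(x, ...) {
  cat(sprintf(
    "K-means solution: K = %d, wcss = %.6g, %d iteration(s), seed %d\n",
    x$K, x$wcss, x$n_iter, x$seed))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$K), collapse = ", "),
      "\n")
  if (!is.na(x$aic)) cat(sprintf("  AIC = %.6g\n", x$aic))
  invisible(x)
}

#' AIC score of a K-means solution
#'
#' Penalized-fit score used to compare solutions across `K`, under a
#' spherical Gaussian reading of K-means with `K * d` mean parameters.
#' Two variants of handling the noise variance are provided:
#'
#' * `"fixed"` (default): the variance is fixed at `sigma0^2` score
#'   units, giving `AIC = wcss / sigma0^2 + 2 K d`. Natural when all
#'   features share one bounded ordinal scale, and the package default
#'   (see the methods vignette for why the profiled variant is unsuitable
#'   for low-dimensional point sets).
#' * `"profile"`: the shared variance is profiled out at its maximum
#'   likelihood estimate `wcss / (n d)`, giving
#'   `AIC = n d log(max(wcss / (n d), eps)) + 2 K d`, with `eps` a floor
#'   guarding perfect fits (`wcss = 0`).
#'
#' Both variants are strictly increasing in `wcss` at fixed `K` and add a
#' `2 d` penalty per extra cluster.
#'
#' @param wcss within-cluster sum of squares, or a `kmeans_solution`
#'   (whose `wcss` and `K` are then used).
#' @param K number of clusters (ignored when `wcss` is a solution).
#' @param n,d number of points and their dimension; `n * d > 0`.
#' @param method `"fixed"` or `"profile"`.
#' @param sigma0 fixed noise standard deviation for `method = "fixed"`
#'   (default 1 score unit).
#' @param eps variance floor for `method = "profile"` (default 1e-12).
#' @return The AIC value (numeric scalar).
#' @export
#' @examples
#' kmeans_aic(1, K = 2, n = 4, d = 2, method = "profile")  # 8 log(1/8) + 8
kmeans_aic <- function(wcss, K = NULL, n, d,
                       method = c("fixed", "profile"),
                       sigma0 = 1, eps = 1e-12) {
  if (inherits(wcss, "kmeans_solution")) {
    K <- wcss$K
    wcss <- wcss$wcss
  }
  method <- match.arg(method)
  if (!is_count(n) || !is_count(d))
    stop("`n` and `d` must be positive integers", call. = FALSE)
  if (!is.numeric(wcss) || length(wcss) != 1L || !is.finite(wcss) || wcss < 0)
    stop("`wcss` must be a single non-negative number", call. = FALSE)
  if (!is_count(K)) stop("`K` must be a positive integer", call. = FALSE)
  switch(method,
    fixed = wcss / sigma0^2 + 2 * K * d,
    profile = n * d * log(max(wcss / (n * d), eps)) + 2 * K * d)
}

#' Multi-restart K-means with AIC selection of K
#'
#' Runs [lloyd()] for every `(K, restart)` pair over `k_range`, scores
#' every run with [kmeans_aic()], and returns the solution attaining the
#' global minimum AIC over the full table (ties broken toward smaller `K`,
#' then lower run seed). Run `i` (counting restarts within `K`, in
#' `k_range` order) uses seed `(master_seed + i) mod (2^31 - 1)`, so the
#' report is fully reproducible and any single run can be replayed with
#' [lloyd()] from its recorded seed.
#'
#' @param points numeric `n x d` matrix of points to cluster.
#' @param k_range candidate numbers of clusters (default `1:10`).
#' @param restarts independent initializations per `K` (default 1000).
#' @param master_seed integer seed the per-run seeds derive from.
#' @param aic_method,sigma0,eps passed to [kmeans_aic()].
#' @param max_iter,tol passed to [lloyd()].
#' @return An object of class `kselect`: list with `table` (data frame of
#'   `K`, `restart`, `seed`, `wcss`, `aic` for every run), `selected_k`,
#'   `solution` (the winning [lloyd()] fit, AIC filled in), `k_range`,
#'   `restarts`, `master_seed`, `aic_method`.
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
#' select_k(pts, k_range = 1:4, restarts = 20, master_seed = 7)$selected_k
select_k <- function(points, k_range = 1:10, restarts = 1000L,
                     master_seed = 1L,
                     aic_method = c("fixed", "profile"),
                     sigma0 = 1, eps = 1e-12,
                     max_iter = 300L, tol = 1e-6) {
  check_matrix(points, "points")
  aic_method <- match.arg(aic_method)
  if (length(k_range) == 0L || !all(vapply(k_range, is_count, TRUE)))
    stop("`k_range` must be a non-empty set of positive integers",
         call. = FALSE)
  if (!is_count(restarts)) stop("`restarts` must be >= 1", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(points)
  d <- ncol(points)
  if (any(k_range > n))
    stop(sprintf("`k_range` exceeds the number of points (%d)", n),
         call. = FALSE)

  runs <- expand.grid(restart = seq_len(restarts), K = k_range)
  runs <- runs[c("K", "restart")]
  runs$seed <- derive_seed(master_seed, seq_len(nrow(runs)))
  runs$wcss <- NA_real_
  runs$aic <- NA_real_

  best <- NULL
  for (i in seq_len(nrow(runs))) {
    fit <- lloyd(points, runs$K[i], runs$seed[i], max_iter = max_iter,
                 tol = tol)
    fit$aic <- kmeans_aic(fit$wcss, fit$K, n, d, method = aic_method,
                          sigma0 = sigma0, eps = eps)
    runs$wcss[i] <- fit$wcss
    runs$aic[i] <- fit$aic
    if (is.null(best) ||
        fit$aic < best$aic ||
        (fit$aic == best$aic && (fit$K < best$K ||
          (fit$K == best$K && fit$seed < best$seed))))
      best <- fit
  }

  structure(list(table = runs, selected_k = best$K, solution = best,
                 k_range = k_range, restarts = as.integer(restarts),
                 master_seed = as.integer(master_seed),
                 aic_method = aic_method),
            class = "kselect")
}

#' @export
print.kselect <- function(x, ...) {
  cat(sprintf(
    "AIC selection over K in {%s}, %d restart(s) each (seed %d, %s AIC)\n",
    paste(x$k_range, collapse = ", "), x$restarts, x$master_seed,
    x$aic_method))
  best <- vapply(split(x$table$aic, x$table$K), min, numeric(1))
  tab <- data.frame(K = as.integer(names(best)), best_aic = best)
  print(tab, row.names = FALSE)
  cat(sprintf("selected K = %d (AIC = %.6g, run seed %d)\n",
              x$selected_k, x$solution$aic, x$solution$seed))
  invisible(x)
}

#' Per-K best-AIC summary of a selection report
#'
#' @param report a `kselect` object from [select_k()].
#' @return Data frame with one row per `K`: best `wcss` and best `aic`.
#' @export
aic_summary <- function(report) {
  stopifnot(inherits(report, "kselect"))
  tab <- report$table
  data.frame(K = sort(unique(tab$K)),
             wcss = vapply(split(tab$wcss, tab$K), min, numeric(1)),
             aic = vapply(split(tab$aic, tab$K), min, numeric(1)),
             row.names = NULL)
}
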