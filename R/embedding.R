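#' Two-dimensional principal-component projection
#'
#' Covariance PCA (columns centered, not scaled) of a point set, returning
#' the first two principal-component scores. Used for the two standard
#' views of the pipeline: the feature columns of the wide matrix coloured
#' by feature group, and the participants of the reduced matrix coloured
#' by cluster. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible.
#'
#' @param points numeric `m x d` matrix, `m >= 2`, `d >= 2`. Rank-0 input
#'   (all rows identical) is an error. For rank-1 input the second score
#'   column is zero.
#' @return An object of class `projection_2d`: list with `scores`
#'   (`m x 2`, zero column means), `explained_variance_fraction` (length
#'   2, non-increasing), `loadings` (`d x 2`), `axis_labels`.
#' @export
#' @examples
#' pr <- pca_2d(matrix(rnorm(40), 10, 4))
#' colMeans(pr$scores)  # ~ 0
pca_2d <- function(points) {
  check_matrix(points, "points")
  m <- nrow(points)
  d <- ncol(points)
  if (m < 2L || d < 2L)
    stop("`points` must be at least 2 x 2", call. = FALSE)
  centered <- scale(points, center = TRUE, scale = FALSE)
  if (all(abs(centered) < .Machine$double.eps * 100))
    stop("rank-0 input: all points are identical", call. = FALSE)
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  n_pc <- ncol(pc$rotation)
  scores <- matrix(0, nrow = m, ncol = 2L,
                   dimnames = list(rownames(points), c("PC1", "PC2")))
  loadings <- matrix(0, nrow = d, ncol = 2L,
                     dimnames = list(colnames(points), c("PC1", "PC2")))
  for (j in seq_len(min(2L, n_pc))) {
    v <- pc$rotation[, j]
    flip <- if (v[which.max(abs(v))] < 0) -1 else 1
    scores[, j] <- pc$x[, j] * flip
    loadings[, j] <- v * flip
  }
  ev <- pc$sdev^2
  evf <- c(ev, 0, 0)[1:2] / sum(ev)
  structure(list(scores = scores, explained_variance_fraction = evf,
                 loadings = loadings, axis_labels = c("PC1", "PC2")),
            class = "projection_2d")
}

#' @export
print.projection_2d <- function(x, ...) {
  cat(sprintf("2-D PCA projection of %d points (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), 100 * x$explained_variance_fraction[1L],
              100 * x$explained_variance_fraction[2L]))
  invisible(x)
}

#' Write a projection as a scatter TSV (and optionally plot it)
#'
#' The numeric TSV (`id, pc1, pc2, group_or_cluster, diagnosis`) is the
#' artifact of record; the optional image is a convenience.
#'
#' @param projection a [pca_2d()] result.
#' @param group per-point group or cluster labels (required, non-empty).
#' @param path output TSV file.
#' @param diagnosis optional per-point diagnosis (e.g. logical DSM-5
#'   flag), written as-is and used to vary plotting symbols.
#' @param image optional path to a PNG rendering of the scatter.
#' @return `path`, invisibly.
#' @export
write_projection <- function(projection, group, path, diagnosis = NULL,
                             image = NULL) {
  stopifnot(inherits(projection, "projection_2d"))
  m <- nrow(projection$scores)
  if (length(group) == 0L)
    stop("`group` must be non-empty", call. = FALSE)
  if (length(group) != m)
    stop("`group` must have one label per projected point", call. = FALSE)
  if (!is.null(diagnosis) && length(diagnosis) != m)
    stop("`diagnosis` must have one value per projected point",
         call. = FALSE)
  ids <- rownames(projection$scores)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  df <- data.frame(id = ids,
                   pc1 = projection$scores[, 1L],
                   pc2 = projection$scores[, 2L],
                   group_or_cluster = group,
                   diagnosis = if (is.null(diagnosis)) NA else diagnosis,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image)) {
    grDevices::png(image, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    gi <- as.integer(factor(group))
    pchs <- if (is.null(diagnosis)) 19 else
      ifelse(diagnosis %in% c(TRUE, "TRUE", "delirium"), 4, 19)
    graphics::plot(df$pc1, df$pc2, col = gi, pch = pchs,
                   xlab = sprintf("PC1 (%.1f%%)",
                     100 * projection$explained_variance_fraction[1L]),
                   ylab = sprintf("PC2 (%.1f%%)",
                     100 * projection$explained_variance_fraction[2L]))
  }
  invisible(path)
}
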