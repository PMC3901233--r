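## Classical MDS of fingerprint distances, per-metabolite max-standardization,
## K-means / hierarchical clustering and the adjusted Rand recovery metric.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities and eigendecomposes (via
#' [stats::cmdscale()]); coordinates are ordered by descending eigenvalue.
#' Axes with non-positive eigenvalues are dropped and all eigenvalues are
#' reported, so non-Euclidean input is visible to the caller. The embedded
#' configuration is the best `dims`-dimensional least-squares approximation
#' of the (double-centered) dissimilarity structure.
#'
#' @param d an `mfp_dist`, [stats::dist] or symmetric matrix without missing
#'   values.
#' @param dims target dimensionality (default 2).
#' @return object of class `mfp_mds`: list with `points` (samples x <= dims
#'   coordinate matrix), `eig` (all eigenvalues), `gof` (goodness-of-fit as
#'   in `cmdscale`).
#' @export
classical_mds <- function(d, dims = 2L) {
  m <- if (inherits(d, "dist")) as.matrix(d) else unclass(as.matrix(d))
  if (anyNA(m)) {
    mfp_stop("mfp_missing_distance",
             "distance matrix contains missing entries; impute or subset first")
  }
  if (dims < 1L || dims > nrow(m) - 1L) {
    mfp_stop("mfp_bad_input", "dims must lie in [1, n_samples - 1]")
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = dims, eig = TRUE)
  pts <- fit$points
  ## cmdscale may return fewer columns than requested when eigenvalues are
  ## non-positive; keep whatever carries positive eigenvalue
  keep <- seq_len(min(ncol(pts), sum(fit$eig > 1e-12)))
  pts <- pts[, keep, drop = FALSE]
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  structure(list(points = pts, eig = fit$eig, gof = fit$GOF),
            class = "mfp_mds")
}

#' @export
print.mfp_mds <- function(x, ...) {
  cat(sprintf("<mfp_mds> %d samples in %d dimensions (GOF %.3f)\n",
              nrow(x$points), ncol(x$points), x$gof[1L]))
  neg <- sum(x$eig < -1e-12)
  if (neg > 0L) {
    cat(sprintf("  %d negative eigenvalues (non-Euclidean input)\n", neg))
  }
  invisible(x)
}

#' Max-standardize abundances per metabolite
#'
#' Divides each metabolite's values by its maximum over the selected samples,
#' mapping every retained metabolite onto `[0, 1]` with max exactly 1, so
#' that clustering is not dominated by high-abundance metabolites.
#' Metabolites with no positive value are dropped with a warning. Idempotent.
#'
#' @param x an [mfp_dataset] or a features x samples matrix.
#' @return standardized features x samples matrix; dropped feature ids in
#'   attribute `dropped`.
#' @export
standardize_max <- function(x) {
  m <- if (inherits(x, "mfp_dataset")) x$abund else as.matrix(x)
  maxima <- apply(m, 1L, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  drop <- !is.finite(maxima) | maxima <= 0
  if (any(drop)) {
    warning(sprintf("%d feature(s) without positive values dropped", sum(drop)),
            call. = FALSE)
  }
  out <- m[!drop, , drop = FALSE] / maxima[!drop]
  attr(out, "dropped") <- rownames(m)[drop] %||% character(0)
  out
}

#' K-means clustering of samples
#'
#' Clusters the columns (samples) of a standardized matrix with
#' [stats::kmeans()], taking the best of `n_init` seeded initializations.
#' The same seed always yields the same assignments.
#'
#' @param m features x samples matrix (typically from [standardize_max()]);
#'   missing values are not allowed.
#' @param k number of clusters (`<=` number of samples).
#' @param n_init random initializations.
#' @param seed integer seed.
#' @return object of class `mfp_kmeans`: list with `assignments` (named
#'   integer vector over samples), `wcss` (within-cluster sum of squares),
#'   `total_ss`, `centers`.
#' @export
kmeans_cluster <- function(m, k, n_init = 10L, seed = 1L) {
  y <- t(as.matrix(m))
  if (anyNA(y)) mfp_stop("mfp_missing_value", "matrix contains missing values")
  if (k < 1L || k > nrow(y)) {
    mfp_stop("mfp_bad_input", "k must lie in [1, n_samples]")
  }
  fit <- with_seed(seed, stats::kmeans(y, centers = k, nstart = n_init,
                                       iter.max = 100L))
  structure(list(assignments = stats::setNames(fit$cluster, rownames(y)),
                 wcss = fit$tot.withinss, total_ss = fit$totss,
                 centers = fit$centers, k = k),
            class = "mfp_kmeans")
}

#' @export
print.mfp_kmeans <- function(x, ...) {
  cat(sprintf("<mfp_kmeans> k = %d, %d samples, WCSS/TSS = %.3f\n",
              x$k, length(x$assignments), x$wcss / x$total_ss))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Builds the merge tree with [stats::hclust()] and cuts it into `k` groups.
#' A standardized features x samples matrix is clustered on Euclidean
#' distances between sample columns; an `mfp_dist` / `dist` input is used
#' directly.
#'
#' @param x features x samples matrix, `mfp_dist`, or `dist`.
#' @param linkage one of `"average"`, `"complete"`, `"single"`.
#' @param k number of groups to cut into (default 3).
#' @return object of class `mfp_hclust`: list with `assignments`, `tree`
#'   (the `hclust` object), `linkage`, `k`.
#' @export
hierarchical_cluster <- function(x, linkage = c("average", "complete", "single"),
                                 k = 3L) {
  linkage <- tryCatch(match.arg(linkage), error = function(e)
    mfp_stop("mfp_bad_input",
             "linkage must be one of 'average', 'complete', 'single'"))
  d <- if (inherits(x, "mfp_dist")) {
    stats::as.dist(unclass(x))
  } else if (inherits(x, "dist")) {
    x
  } else {
    stats::dist(t(as.matrix(x)))
  }
  n <- attr(d, "Size")
  if (n < 2L) mfp_stop("mfp_insufficient_data", "need >= 2 samples")
  if (anyNA(d)) mfp_stop("mfp_missing_distance", "distances contain NA")
  if (k < 1L || k > n) mfp_stop("mfp_bad_input", "k must lie in [1, n_samples]")
  tree <- stats::hclust(d, method = linkage)
  structure(list(assignments = stats::cutree(tree, k = k), tree = tree,
                 linkage = linkage, k = k),
            class = "mfp_hclust")
}

#' @export
print.mfp_hclust <- function(x, ...) {
  cat(sprintf("<mfp_hclust> %s linkage, cut at k = %d\n", x$linkage, x$k))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' permutation), approximately 0 for independent ones. Computed from the
#' contingency table via the permutation-model closed form.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    mfp_stop("mfp_length_mismatch", "label vectors must have equal length")
  }
  n <- length(labels_a)
  if (n < 2L) mfp_stop("mfp_insufficient_data", "need >= 2 observations")
  tab <- table(labels_a, labels_b)
  sum_nij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    ## both partitions trivial (all-singletons or single cluster): identical
    ## partitions score 1 by convention, anything else 0
    return(as.numeric(sum_nij == maximum && sum_a == sum_b))
  }
  (sum_nij - expected) / (maximum - expected)
}
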