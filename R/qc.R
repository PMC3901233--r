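## Replicate quality control: pairwise Spearman rank correlation among the
## replicates of each accession x organ x stage cell, plus outlier flagging.

#' Spearman rank correlation of two abundance vectors
#'
#' Average ranks are used for ties and missing entries are removed pairwise
#' (zeros are kept: a non-detect is informative for replicate agreement).
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`.
#' @section Errors: fewer than 3 complete pairs raises an
#'   `mfp_insufficient_data` error; zero rank variance in either vector (all
#'   values tied) raises `mfp_undefined_correlation`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    mfp_stop("mfp_length_mismatch", "x and y must have equal length")
  }
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3L) {
    mfp_stop("mfp_insufficient_data",
             sprintf("only %d complete pairs; need >= 3", sum(keep)))
  }
  rx <- rank(x[keep])
  ry <- rank(y[keep])
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    mfp_stop("mfp_undefined_correlation",
             "zero rank variance: correlation undefined")
  }
  ## Pearson on average ranks == tie-corrected Spearman
  stats::cor(rx, ry)
}

#' Per-group replicate correlation matrices
#'
#' Splits samples into replicate groups (by default accession x organ x
#' stage) and returns, for each group with at least two replicates, the
#' symmetric unit-diagonal matrix of pairwise Spearman correlations among its
#' replicate samples. Singleton groups are skipped with a warning and listed
#' in the result. Pairs whose correlation is undefined (constant ranks, too
#' few complete pairs) yield `NA` in the matrix.
#'
#' @param x an [mfp_dataset].
#' @param group_by character vector of sample-table columns defining
#'   replicate groups.
#' @return object of class `mfp_qc`: list with `matrices` (named list of
#'   correlation matrices keyed by group label), `pairs` (long data.frame of
#'   group, sample_i, sample_j, rho) and `skipped` (singleton group labels).
#' @export
replicate_correlations <- function(x, group_by = c("accession", "organ", "stage")) {
  bad <- setdiff(group_by, names(x$samples))
  if (length(bad)) {
    mfp_stop("mfp_bad_selector",
             sprintf("unknown grouping columns: %s", paste(bad, collapse = ", ")))
  }
  key <- do.call(paste, c(x$samples[group_by], sep = " / "))
  mats <- list()
  skipped <- character(0)
  pair_rows <- list()
  for (g in unique(key)) {
    ids <- x$samples$sample_id[key == g]
    if (length(ids) < 2L) {
      warning(sprintf("group '%s' has a single replicate; skipped", g),
              call. = FALSE)
      skipped <- c(skipped, g)
      next
    }
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (a in seq_len(length(ids) - 1L)) {
      for (b in seq.int(a + 1L, length(ids))) {
        rho <- tryCatch(
          spearman_rho(x$abund[, ids[a]], x$abund[, ids[b]]),
          mfp_error = function(e) NA_real_)
        m[a, b] <- m[b, a] <- rho
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          group = g, sample_i = ids[a], sample_j = ids[b], rho = rho,
          stringsAsFactors = FALSE)
      }
    }
    mats[[g]] <- m
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(group = character(), sample_i = character(),
               sample_j = character(), rho = numeric(),
               stringsAsFactors = FALSE)
  structure(list(matrices = mats, pairs = pairs, skipped = skipped),
            class = "mfp_qc")
}

#' @export
print.mfp_qc <- function(x, ...) {
  cat(sprintf("<mfp_qc> %d replicate groups, %d pairwise correlations\n",
              length(x$matrices), nrow(x$pairs)))
  if (nrow(x$pairs)) {
    cat(sprintf("  rho: min %.3f, median %.3f, max %.3f\n",
                min(x$pairs$rho, na.rm = TRUE),
                stats::median(x$pairs$rho, na.rm = TRUE),
                max(x$pairs$rho, na.rm = TRUE)))
  }
  if (length(x$skipped)) {
    cat("  skipped singleton groups:", length(x$skipped), "\n")
  }
  invisible(x)
}

#' Flag replicates that disagree with their co-replicates
#'
#' A replicate is flagged when the median of its Spearman correlations to the
#' other replicates of its group falls below `threshold`. The 0.7 default is
#' a configurable convention of this package, not a published cutoff.
#'
#' @param qc result of [replicate_correlations()].
#' @param threshold flagging threshold on the median correlation.
#' @return data.frame with columns `group`, `sample_id`, `median_rho`.
#' @export
flag_outlier_replicates <- function(qc, threshold = 0.7) {
  if (!inherits(qc, "mfp_qc")) {
    mfp_stop("mfp_bad_input", "`qc` must come from replicate_correlations()")
  }
  rows <- list()
  for (g in names(qc$matrices)) {
    m <- qc$matrices[[g]]
    for (id in rownames(m)) {
      others <- m[id, setdiff(colnames(m), id)]
      med <- stats::median(others, na.rm = TRUE)
      if (!is.na(med) && med < threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, sample_id = id, median_rho = med,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), sample_id = character(),
               median_rho = numeric(), stringsAsFactors = FALSE)
}

#' Paired abundances of two samples for scatter plotting
#'
#' @param x an [mfp_dataset].
#' @param sample_i,sample_j sample ids.
#' @return data.frame `feature_id`, `x`, `y` restricted to features measured
#'   in both samples, in feature order.
#' @export
scatter_pairs <- function(x, sample_i, sample_j) {
  for (id in c(sample_i, sample_j)) {
    if (!id %in% colnames(x$abund)) {
      mfp_stop("mfp_unknown_sample", sprintf("unknown sample id '%s'", id))
    }
  }
  xi <- x$abund[, sample_i]
  xj <- x$abund[, sample_j]
  keep <- !is.na(xi) & !is.na(xj)
  data.frame(feature_id = rownames(x$abund)[keep], x = unname(xi[keep]),
             y = unname(xj[keep]), stringsAsFactors = FALSE)
}
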