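## Weighted Manhattan sample dissimilarity.
##
## For non-negative abundance profiles y_i, y_j over K metabolites,
##
##   D_ij = (1 / K*) * sum_k |Y_ki - Y_kj| / sqrt(Y_ki^2 + Y_kj^2)
##
## where the sum runs over metabolites with Y_ki + Y_kj > 0 and K* counts
## them. sqrt(Y_ki^2 + Y_kj^2) estimates the standard deviation of the
## abundance difference, so each metabolite contributes a term in [0, 1]
## regardless of its magnitude, D is invariant to common multiplicative
## rescaling of both profiles, D = 0 iff the profiles are identical and
## D = 1 iff the two samples share no constituents. Excluding both-zero
## metabolites from K* is what makes the D = 1 boundary exact; `strict =
## TRUE` instead divides by all pairwise-complete metabolites (diluting D
## toward 0 when many metabolites are absent from both samples).

#' Weighted Manhattan dissimilarity between two abundance profiles
#'
#' @param y_i,y_j non-negative numeric vectors of equal length (one abundance
#'   per metabolite). `NA` entries (unmeasured) are removed pairwise;
#'   measured zeros participate.
#' @param strict if `TRUE`, normalize by the number of pairwise-complete
#'   metabolites instead of only those present in at least one sample.
#' @return dissimilarity in `[0, 1]`.
#' @section Errors: negative input raises `mfp_negative_value`; profiles with
#'   no metabolite present in either sample raise `mfp_undefined_distance`.
#' @examples
#' weighted_manhattan(c(1, 0), c(0, 1))  # disjoint constituents -> 1
#' weighted_manhattan(c(2, 2), c(1, 1))  # 1/sqrt(5)
#' @export
weighted_manhattan <- function(y_i, y_j, strict = FALSE) {
  if (length(y_i) != length(y_j)) {
    mfp_stop("mfp_length_mismatch", "profiles must have equal length")
  }
  if (any(y_i < 0, na.rm = TRUE) || any(y_j < 0, na.rm = TRUE)) {
    mfp_stop("mfp_negative_value", "abundances must be non-negative")
  }
  keep <- !is.na(y_i) & !is.na(y_j)
  a <- y_i[keep]
  b <- y_j[keep]
  pos <- (a + b) > 0
  if (!any(pos)) {
    mfp_stop("mfp_undefined_distance",
             "no metabolite present in either sample: distance undefined")
  }
  terms <- abs(a[pos] - b[pos]) / sqrt(a[pos]^2 + b[pos]^2)
  sum(terms) / (if (strict) length(a) else sum(pos))
}

#' Pairwise weighted Manhattan distance matrix
#'
#' Computes the dissimilarity of every sample pair of a dataset (optionally
#' restricted by a sample selector). Pairs with an undefined distance (no
#' shared constituents measured) are set to `NA` with a warning.
#'
#' @param x an [mfp_dataset].
#' @param keep,... optional sample selection, as in [select_samples()].
#' @param strict see [weighted_manhattan()].
#' @return symmetric matrix of class `mfp_dist` with zero diagonal, sample
#'   ids as dimnames, and attributes `mode` (`"present"` or `"strict"`).
#' @export
fingerprint_dist <- function(x, keep = NULL, ..., strict = FALSE) {
  if (!is.null(keep) || length(list(...))) x <- select_samples(x, keep, ...)
  if (ncol(x$abund) < 2L) {
    mfp_stop("mfp_insufficient_data", "need >= 2 samples for a distance matrix")
  }
  if (any(x$abund < 0, na.rm = TRUE)) {
    mfp_stop("mfp_negative_value", "abundances must be non-negative")
  }
  ids <- colnames(x$abund)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  undefined <- 0L
  for (i in seq_len(n - 1L)) {
    yi <- x$abund[, i]
    for (j in seq.int(i + 1L, n)) {
      dij <- tryCatch(weighted_manhattan(yi, x$abund[, j], strict = strict),
                      mfp_undefined_distance = function(e) NA_real_)
      if (is.na(dij)) undefined <- undefined + 1L
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (undefined > 0L) {
    warning(sprintf("%d sample pair(s) had undefined distance (set to NA)",
                    undefined), call. = FALSE)
  }
  structure(d, class = c("mfp_dist", "matrix", "array"),
            mode = if (strict) "strict" else "present")
}

#' @export
print.mfp_dist <- function(x, ...) {
  vals <- x[upper.tri(x)]
  cat(sprintf("<mfp_dist> %d samples, mode '%s'\n", nrow(x), attr(x, "mode")))
  cat(sprintf("  D: min %.4f, median %.4f, max %.4f%s\n",
              min(vals, na.rm = TRUE), stats::median(vals, na.rm = TRUE),
              max(vals, na.rm = TRUE),
              if (anyNA(vals)) sprintf(" (%d NA)", sum(is.na(vals))) else ""))
  invisible(x)
}

#' @export
as.dist.mfp_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass(m), diag = diag, upper = upper)
}

#' Write a distance matrix as CSV with a JSON provenance block
#'
#' @param d an `mfp_dist`.
#' @param path CSV output path; a sibling `<path>.json` records the mode and
#'   sample count.
#' @return `path`, invisibly.
#' @export
write_dist <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_len(ncol(d))) df[[colnames(d)[j]]] <- format_num(d[, j])
  write_csv_utf8(df, path, quote = 1L)
  jsonlite::write_json(list(mode = attr(d, "mode"), n_samples = nrow(d)),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
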