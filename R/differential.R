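## Differential abundance: volcano coordinates (log2 ratio of group means +
## Welch t-test), BH adjustment, aligned organ-contrast ratio panels and
## all-pairs accession fingerprints with one shared metabolite ordering.

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (via [stats::t.test()]). Two conventions cover the
#' degenerate cases the generic test refuses: when both groups are constant
#' with equal means the result is `t = 0, p = 1`; when both are constant with
#' unequal means the difference is real but has no estimable variance, and an
#' `mfp_degenerate_variance` error is raised.
#'
#' @param x,y numeric vectors (>= 2 values each) of replicate abundances.
#' @return list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    mfp_stop("mfp_insufficient_data", "need >= 2 values per group")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    mfp_stop("mfp_degenerate_variance",
             "both groups constant with unequal means: variance inestimable")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' @param p vector of raw p-values in `(0, 1]`.
#' @return step-up q-values, monotone in `p` and elementwise `>= p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    mfp_stop("mfp_bad_pvalue", "p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## pseudocount: half the smallest positive abundance in the dataset, so log
## ratios stay finite and rescaling the data rescales the pseudocount with it
default_pseudocount <- function(mat) {
  pos <- mat[!is.na(mat) & mat > 0]
  if (!length(pos)) return(1e-9)
  min(pos) / 2
}

#' Volcano-plot coordinates for a two-group contrast
#'
#' For every feature, the log2 ratio of group means (with pseudocount) is the
#' x coordinate and the Welch t-test p-value the y coordinate. Features with
#' fewer than two measured replicates in either group are reported with
#' status `"skipped"`; features where both groups are constant at different
#' levels get status `"degenerate"` (`t`, `p` missing).
#'
#' @param x an [mfp_dataset].
#' @param group_a,group_b character vectors of sample ids (see
#'   [samples_where()]); must not overlap.
#' @param pseudocount additive constant `c` in
#'   `log2((mean_a + c) / (mean_b + c))`; default half the smallest positive
#'   value in the dataset.
#' @param adjust if `TRUE`, append BH q-values (computed over features with
#'   status `"ok"`). Off by default: raw p-values are the conventional
#'   volcano y axis.
#' @return data.frame of class `mfp_volcano` with columns `feature_id`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `ratio`, `log2_ratio`, `t`, `df`,
#'   `p_value`, `neg_log10_p`, `status` (+ `q_value`). Attributes
#'   `pseudocount`, `group_a`, `group_b`.
#' @export
volcano <- function(x, group_a, group_b, pseudocount = NULL, adjust = FALSE) {
  unknown <- setdiff(c(group_a, group_b), colnames(x$abund))
  if (length(unknown)) {
    mfp_stop("mfp_unknown_sample",
             sprintf("unknown sample ids: %s", paste(unknown, collapse = ", ")))
  }
  if (!length(group_a) || !length(group_b)) {
    mfp_stop("mfp_empty_selection", "both contrast groups must be non-empty")
  }
  overlap <- intersect(group_a, group_b)
  if (length(overlap)) {
    mfp_stop("mfp_overlapping_groups",
             sprintf("groups overlap: %s", paste(overlap, collapse = ", ")))
  }
  pc <- pseudocount %||% default_pseudocount(x$abund)

  ma <- x$abund[, group_a, drop = FALSE]
  mb <- x$abund[, group_b, drop = FALSE]
  n_a <- rowSums(!is.na(ma))
  n_b <- rowSums(!is.na(mb))
  mean_a <- rowMeans(ma, na.rm = TRUE)
  mean_b <- rowMeans(mb, na.rm = TRUE)

  k <- nrow(x$abund)
  t_stat <- df <- p <- rep(NA_real_, k)
  status <- rep("ok", k)
  for (i in seq_len(k)) {
    if (n_a[i] < 2L || n_b[i] < 2L) {
      status[i] <- "skipped"
      next
    }
    res <- tryCatch(welch_t(ma[i, ], mb[i, ]),
                    mfp_degenerate_variance = function(e) NULL)
    if (is.null(res)) {
      status[i] <- "degenerate"
    } else {
      t_stat[i] <- res$t
      df[i] <- res$df
      p[i] <- res$p
    }
  }

  ratio <- (mean_a + pc) / (mean_b + pc)
  out <- data.frame(
    feature_id = rownames(x$abund),
    mean_a = ifelse(is.nan(mean_a), NA_real_, mean_a),
    mean_b = ifelse(is.nan(mean_b), NA_real_, mean_b),
    n_a = n_a, n_b = n_b,
    ratio = ratio,
    log2_ratio = log2(ratio),
    t = t_stat, df = df, p_value = p,
    neg_log10_p = -log10(p),
    status = status,
    stringsAsFactors = FALSE)
  if (adjust) {
    out$q_value <- NA_real_
    ok <- out$status == "ok" & !is.na(out$p_value)
    out$q_value[ok] <- bh_adjust(out$p_value[ok])
  }
  rownames(out) <- NULL
  structure(out, class = c("mfp_volcano", "data.frame"),
            pseudocount = pc, group_a = group_a, group_b = group_b)
}

#' @export
print.mfp_volcano <- function(x, alpha = 0.05, ...) {
  ok <- x$status == "ok"
  cat(sprintf("<mfp_volcano> %d features (%d tested, %d skipped/degenerate)\n",
              nrow(x), sum(ok), sum(!ok)))
  cat(sprintf("  pseudocount: %g\n", attr(x, "pseudocount")))
  cat(sprintf("  p < %g: %d features; |log2 ratio| > 1: %d features\n",
              alpha, sum(x$p_value < alpha, na.rm = TRUE),
              sum(abs(x$log2_ratio) > 1 & ok, na.rm = TRUE)))
  invisible(x)
}

## Shared metabolite ordering for panel figures: platform, then chemical
## class (NA last), then mean log-ratio across panels, ties by feature_id.
## Emitted with every panel object so figures are reproducible.
shared_feature_order <- function(features, ratio_mat) {
  cls <- features$chemical_class
  cls[is.na(cls)] <- "~~unclassified"
  mean_lr <- rowMeans(ratio_mat, na.rm = TRUE)
  mean_lr[is.nan(mean_lr)] <- 0
  order(features$platform, cls, mean_lr, features$feature_id)
}

#' Organ-contrast log-ratio panels across accessions
#'
#' For each accession (panel), the per-feature log2 ratio of mean abundance
#' between two organs is computed; all panels share one metabolite ordering
#' (platform, chemical class, mean log-ratio) which is recorded in the
#' result, so the panels are directly comparable row by row. An accession
#' missing one of the organs yields an all-`NA` column with a warning.
#'
#' @param x an [mfp_dataset].
#' @param organ_a,organ_b the contrast organs (numerator / denominator).
#' @param pseudocount as in [volcano()].
#' @return object of class `mfp_ratio_panels`: list with `log2_ratio`
#'   (ordered features x accessions matrix), `feature_order` (feature ids in
#'   display order), `organ_a`, `organ_b`, `pseudocount`.
#' @export
ratio_panels <- function(x, organ_a, organ_b, pseudocount = NULL) {
  for (o in c(organ_a, organ_b)) {
    if (!o %in% x$samples$organ) {
      mfp_stop("mfp_empty_selection", sprintf("no samples with organ '%s'", o))
    }
  }
  pc <- pseudocount %||% default_pseudocount(x$abund)
  ## sorted accession/sample order makes the result exactly invariant to the
  ## input sample ordering (column order and floating-point summation order)
  accs <- sort(unique(x$samples$accession))
  lr <- matrix(NA_real_, nrow(x$abund), length(accs),
               dimnames = list(rownames(x$abund), accs))
  for (a in accs) {
    ids_a <- sort(x$samples$sample_id[x$samples$accession == a &
                                        x$samples$organ == organ_a])
    ids_b <- sort(x$samples$sample_id[x$samples$accession == a &
                                        x$samples$organ == organ_b])
    if (!length(ids_a) || !length(ids_b)) {
      warning(sprintf("accession '%s' lacks organ '%s'; panel left missing",
                      a, if (length(ids_a)) organ_b else organ_a), call. = FALSE)
      next
    }
    mean_a <- rowMeans(x$abund[, ids_a, drop = FALSE], na.rm = TRUE)
    mean_b <- rowMeans(x$abund[, ids_b, drop = FALSE], na.rm = TRUE)
    lr[, a] <- log2((mean_a + pc) / (mean_b + pc))
  }
  ord <- shared_feature_order(x$features, lr)
  structure(list(log2_ratio = lr[ord, , drop = FALSE],
                 feature_order = rownames(x$abund)[ord],
                 organ_a = organ_a, organ_b = organ_b, pseudocount = pc),
            class = "mfp_ratio_panels")
}

#' @export
print.mfp_ratio_panels <- function(x, ...) {
  cat(sprintf("<mfp_ratio_panels> %s vs %s: %d features x %d accession panels\n",
              x$organ_a, x$organ_b, nrow(x$log2_ratio), ncol(x$log2_ratio)))
  invisible(x)
}

#' All-pairs accession fingerprint profiles
#'
#' Pools all organs, averages each feature within accession, and emits the
#' log2 abundance ratio for every ordered accession pair (the second
#' accession of the pair is the denominator). All profiles share one feature
#' ordering, and profiles are antisymmetric:
#' `log-ratio(a, b) == -log-ratio(b, a)` exactly.
#'
#' @param x an [mfp_dataset] with >= 2 accessions.
#' @param pseudocount as in [volcano()].
#' @return object of class `mfp_fingerprints`: list with `log2_ratio`
#'   (ordered features x ordered-pairs matrix, columns named
#'   `"A vs B"`), `feature_order`, `pairs` (data.frame `numerator`,
#'   `denominator`), `pseudocount`.
#' @export
pairwise_accession_fingerprints <- function(x, pseudocount = NULL) {
  accs <- sort(unique(x$samples$accession))
  n_samp <- vapply(accs, function(a) sum(x$samples$accession == a), integer(1))
  if (any(n_samp == 0L)) {
    warning(sprintf("accessions without samples excluded: %s",
                    paste(accs[n_samp == 0L], collapse = ", ")), call. = FALSE)
    accs <- accs[n_samp > 0L]
  }
  if (length(accs) < 2L) {
    mfp_stop("mfp_insufficient_data", "need >= 2 accessions with samples")
  }
  pc <- pseudocount %||% default_pseudocount(x$abund)
  means <- vapply(accs, function(a) {
    ids <- sort(x$samples$sample_id[x$samples$accession == a])
    rowMeans(x$abund[, ids, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x$abund)))
  log_means <- log2(means + pc)

  pairs <- expand.grid(denominator = accs, numerator = accs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, c("numerator", "denominator")]
  rownames(pairs) <- NULL
  lr <- log_means[, pairs$numerator, drop = FALSE] -
    log_means[, pairs$denominator, drop = FALSE]
  colnames(lr) <- paste(pairs$numerator, "vs", pairs$denominator)

  ord <- shared_feature_order(x$features, lr)
  structure(list(log2_ratio = lr[ord, , drop = FALSE],
                 feature_order = rownames(x$abund)[ord],
                 pairs = pairs, pseudocount = pc),
            class = "mfp_fingerprints")
}

#' @export
print.mfp_fingerprints <- function(x, ...) {
  cat(sprintf(
    "<mfp_fingerprints> %d features x %d ordered accession pairs (%d comparisons)\n",
    nrow(x$log2_ratio), ncol(x$log2_ratio), ncol(x$log2_ratio) / 2L))
  invisible(x)
}
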