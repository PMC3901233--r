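## Base-graphics plot methods for the main result objects.

#' Volcano plot
#'
#' @param x an `mfp_volcano`.
#' @param alpha horizontal significance guide (raw p).
#' @param lfc vertical fold-change guides at `+/- lfc` on the log2 axis.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mfp_volcano <- function(x, alpha = 0.05, lfc = 1, ...) {
  ok <- x$status == "ok" & !is.na(x$p_value)
  sig <- ok & x$p_value < alpha & abs(x$log2_ratio) > lfc
  graphics::plot(x$log2_ratio[ok], x$neg_log10_p[ok],
                 xlab = "log2 abundance ratio (A / B)",
                 ylab = expression(-log[10] ~ p),
                 pch = 16, cex = 0.6,
                 col = ifelse(sig[ok], "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(alpha), lty = 2, col = "grey60")
  graphics::abline(v = c(-lfc, lfc), lty = 2, col = "grey60")
  invisible(x)
}

#' MDS ordination plot
#'
#' @param x an `mfp_mds`.
#' @param groups optional factor over samples used for colors (e.g.
#'   accession); recycled against rownames of the coordinates.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mfp_mds <- function(x, groups = NULL, ...) {
  pts <- x$points
  if (ncol(pts) < 2L) mfp_stop("mfp_bad_input", "need >= 2 embedded dimensions")
  col <- if (is.null(groups)) "grey30" else as.integer(factor(groups)) + 1L
  graphics::plot(pts[, 1L], pts[, 2L], xlab = "MDS 1", ylab = "MDS 2",
                 pch = 16, col = col, asp = 1, ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))) + 1L, pch = 16,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Replicate scatter plot
#'
#' @param x an [mfp_dataset].
#' @param sample_i,sample_j sample ids to compare.
#' @param log if `TRUE` (default) plot on log-log axes (zeros dropped).
#' @param ... passed to [graphics::plot()].
#' @return the [scatter_pairs()] data.frame, invisibly.
#' @export
plot_replicate_scatter <- function(x, sample_i, sample_j, log = TRUE, ...) {
  sp <- scatter_pairs(x, sample_i, sample_j)
  rho <- tryCatch(spearman_rho(sp$x, sp$y), mfp_error = function(e) NA_real_)
  if (log) sp <- sp[sp$x > 0 & sp$y > 0, ]
  graphics::plot(sp$x, sp$y, log = if (log) "xy" else "",
                 xlab = sample_i, ylab = sample_j, pch = 16, cex = 0.6,
                 col = "grey30",
                 main = sprintf("Spearman rho = %.3f", rho), ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2, col = "grey60")
  invisible(sp)
}
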