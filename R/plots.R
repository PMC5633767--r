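#' Plot a coverage track with optional classified segments
#'
#' Per-chromosome bin coverage with segment means overlaid; deletions in
#' red, duplications in blue.
#'
#' @param x a [coverage_track()].
#' @param segments optional classified segments for the same chromosome.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coverage_track <- function(x, segments = NULL, ...) {
  pos <- (seq_along(x$values) - 0.5) * x$bin_size / 1e6
  graphics::plot(pos, x$values, pch = ".", col = "grey40",
                 xlab = sprintf("%s position (Mb)", x$chrom),
                 ylab = "reads / bin", ...)
  if (!is.null(segments) && nrow(segments)) {
    segments <- segments[segments$chrom == x$chrom, , drop = FALSE]
    cols <- c(deletion = "red3", normal = "black", duplication = "blue3")
    graphics::segments(segments$start / 1e6, segments$mean_cov,
                       segments$end / 1e6, segments$mean_cov,
                       col = cols[segments$class], lwd = 2)
  }
  invisible(x)
}

#' Plot LOD profiles per linkage group
#'
#' @param x a [scan_qtl()] result.
#' @param threshold horizontal reference line (default 5).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lod_profiles <- function(x, threshold = 5, ...) {
  groups <- unique(x$group)
  old <- graphics::par(mfrow = c(1, length(groups)), mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(old))
  for (g in groups) {
    pg <- x[x$group == g, ]
    graphics::plot(pg$cM, pg$LOD, type = "l", xlab = "cM", ylab = "LOD",
                   main = g, ...)
    graphics::abline(h = threshold, lty = 2, col = "red3")
  }
  invisible(x)
}
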