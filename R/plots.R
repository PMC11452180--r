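#' Plot one TF's frequency profile with its cluster bar
#'
#' Raw per-rank frequencies as gray bars, the smoothed profile as a
#' line, detected peaks as points, and each called cluster as a
#' horizontal bar at its cut level (borders dashed to the coverage
#' index).  Purely illustrative: all quantitative output lives in the
#' tables and JSON reports.
#'
#' @param result a [PCCDResult-class].
#' @param tf TF name present in the result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotProfile <- function(result, tf, ...) {
  stopifnot(is(result, "PCCDResult"))
  prof <- result@profiles[[tf]]
  if (is.null(prof)) stop("no profile for TF '", tf, "' in this result")
  L <- length(prof@f)
  graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, 1.05),
                 xlab = "rank (1 = furthest from NB, oldest)",
                 ylab = "frequency", main = tf, ...)
  graphics::rect(seq_len(L) - 0.4, 0, seq_len(L) + 0.4, prof@f,
                 col = "gray85", border = "gray70")
  graphics::lines(seq_len(L), prof@fSmooth, lwd = 2, col = "steelblue4")
  pk <- result@peaks[[tf]]
  if (nrow(pk)) {
    graphics::points(pk$position, pk$height, pch = 19, col = "firebrick")
  }
  for (cl in result@clusters[[tf]]) {
    if (!length(cl@bounds)) next
    y <- min(cl@peak$height, 1) * 0.5
    graphics::segments(cl@bounds[1L], y, cl@bounds[2L], y, lwd = 3,
                       col = "darkgreen")
    if (length(cl@coreSpan)) {
      graphics::segments(cl@coreSpan[1L] - 0.5, y, cl@coreSpan[2L] + 0.5, y,
                         lwd = 5, col = "darkgreen")
    }
  }
  invisible(NULL)
}
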