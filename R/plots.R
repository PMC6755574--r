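# Base-graphics rendering.  The plotted objects (curve groups, the MCS
# category matrix, the control-chart result) are plain data structures that
# are computed and tested headlessly; these functions only draw them.

#' Plot one accumulation-curve group
#'
#' Model curves are drawn as solid colored lines, the ideal curve as a black
#' dashed line and the random curve as a grey dotted line.
#'
#' @param group one element of \code{\link{curveSeries}} output.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotAccumulation <- function(group, main = "", ...) {
  ymax <- max(vapply(group, function(cv) max(cv$accumulated), numeric(1)))
  xmax <- max(group[[1]]$tests)
  graphics::plot(NA, xlim = c(1, xmax), ylim = c(0, ymax),
                 xlab = "tests", ylab = "accumulated response",
                 main = main, ...)
  models <- group[!names(group) %in% c("ideal", "random")]
  cols <- grDevices::hcl.colors(max(3, length(models)), "Dark 3")
  for (i in seq_along(models))
    graphics::lines(models[[i]]$tests, models[[i]]$accumulated,
                    col = cols[i], lwd = 1.5)
  graphics::lines(group$ideal$tests, group$ideal$accumulated, lty = 2)
  graphics::lines(group$random$tests, group$random$accumulated,
                  lty = 3, col = "grey40")
  graphics::legend("bottomright",
                   legend = c(names(models), "ideal", "random"),
                   col = c(cols[seq_along(models)], "black", "grey40"),
                   lty = c(rep(1, length(models)), 2, 3), cex = 0.7, bty = "n")
  invisible(NULL)
}

#' Plot the multiple-comparisons-similarity matrix
#'
#' Heatmap-style matrix of the pairwise significance categories, with both
#' axes ordered best to worst by mean performance measure.
#'
#' @param comp a \linkS4class{ComparisonResult}.
#' @param main plot title (defaults to the measure name).
#' @return invisibly, the category matrix.
#' @export
plotMCS <- function(comp, main = NULL) {
  m <- mcsMatrix(comp)
  cats <- c(sprintf("p<=%g", comp@bands[1]),
            sprintf("%g<p<=%g", comp@bands[1], comp@bands[2]),
            sprintf("p>%g", comp@bands[2]))
  pal <- c("firebrick3", "goldenrod2", "springgreen3")
  z <- matrix(match(m, cats), nrow(m), ncol(m))
  z[is.na(z)] <- 4L  # diagonal ("self")
  cc <- ncol(m)
  op <- graphics::par(mar = c(1, 8, 8, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(cc), seq_len(cc), t(z[rev(seq_len(cc)), ]),
                  col = c(pal, "grey85"), zlim = c(1, 4), axes = FALSE,
                  xlab = "", ylab = "",
                  main = if (is.null(main)) paste("MCS:", comp@measure) else main)
  graphics::axis(3, at = seq_len(cc), labels = colnames(m), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::axis(2, at = seq_len(cc), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::legend("bottomleft", legend = cats, fill = pal, cex = 0.7,
                   bg = "white")
  invisible(m)
}

#' Plot a Hotelling T2 control chart
#'
#' T2 per external observation with the horizontal upper control limit;
#' observations above the line are outside the applicability domain.
#'
#' @param chart a \linkS4class{ControlChartResult}.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotControlChart <- function(chart, main = "Hotelling T2 control chart") {
  t2 <- chart@t2
  graphics::plot(seq_along(t2), t2, type = "b", pch = 20,
                 xlab = "external observation", ylab = expression(T^2),
                 ylim = c(0, max(t2, chart@ucl) * 1.05), main = main)
  graphics::abline(h = chart@ucl, col = "firebrick3", lty = 2)
  if (length(chart@outliers))
    graphics::points(chart@outliers, t2[chart@outliers], col = "firebrick3",
                     pch = 19)
  graphics::mtext(sprintf("UCL = %.3g (alpha = %g)", chart@ucl, chart@alpha),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(NULL)
}
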