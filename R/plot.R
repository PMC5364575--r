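#' Diagnostic plot of a threshold selection
#'
#' Replicates the standard threshold-selection diagnostic: the raw and
#' smoothed normalized histograms, the slope difference distribution
#' (rescaled to the panel), its peaks (crosses) and valleys (circles), and
#' the selected threshold (asterisk).
#'
#' @param x an `"sdd_threshold"` object from [sdd_threshold()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.sdd_threshold <- function(x, ...) {
  graphics::plot(0:255, x$raw_histogram, type = "h", col = "grey75",
                 xlab = "gray level", ylab = "normalized frequency",
                 ylim = c(-1, 1.05), ...)
  graphics::lines(0:255, x$smoothed, col = "cyan4", lwd = 2)
  sdd <- x$sdd
  sc <- max(abs(sdd$s))
  graphics::lines(sdd$position, sdd$s / sc, col = "grey40")
  graphics::points(sdd$peaks$position, sdd$peaks$magnitude / sc,
                   pch = 4, col = "blue")
  graphics::points(sdd$valleys$position, sdd$valleys$magnitude / sc,
                   pch = 1, col = "red")
  graphics::points(x$threshold, x$valley$magnitude / sc, pch = 8,
                   col = "red3", cex = 1.6)
  graphics::abline(v = x$threshold, lty = 3, col = "red3")
  invisible(x)
}

#' Overlay quantified cell centers on an image
#'
#' @param result an `"sdd_pipeline"` object.
#' @param image the image quantified (numeric matrix); defaults to the
#'   filtered mask if omitted.
#' @export
plot_quantification <- function(result, image = NULL) {
  stopifnot(inherits(result, "sdd_pipeline"))
  if (is.null(image)) image <- result$masks$filtered * 255
  graphics::image(t(image[nrow(image):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(image) / ncol(image))
  ct <- result$centroids
  if (nrow(ct)) {
    graphics::points((ct$col + 0.5) / ncol(image),
                     1 - (ct$row + 0.5) / nrow(image),
                     pch = 19, col = "green3")
  }
  invisible(result)
}
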