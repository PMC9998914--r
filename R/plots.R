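# Base-graphics views of the two report objects.

#' Plot detection metrics across IoU thresholds
#'
#' F1, precision and recall against the evaluation threshold tau — the
#' standard picture of how detection quality degrades as the overlap
#' requirement tightens.
#'
#' @param x a `metrics_report` from [evaluate_over_taus()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.metrics_report <- function(x, ...) {
  graphics::plot(x$tau, x$f1, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = expression(tau), ylab = "score", ...)
  graphics::lines(x$tau, x$precision, type = "b", pch = 1, lty = 2)
  graphics::lines(x$tau, x$recall, type = "b", pch = 2, lty = 3)
  graphics::legend("bottomleft", c("F1", "precision", "recall"),
                   pch = c(16, 1, 2), lty = 1:3, bty = "n")
  invisible(x)
}

#' Plot a phantom pod's long-axis cross-section
#'
#' The Z-X mid-slice (through the pod axis) of the intensity volume with the
#' ground-truth seed centroids overlaid, coloured by valve — the view in
#' which valve sorting operates.
#'
#' @param x a `pod_phantom` from [generate_pod()].
#' @param ... further arguments passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.pod_phantom <- function(x, ...) {
  img <- vol_data(x$image)
  ymid <- round(dim(img)[2] / 2)
  sl <- img[, ymid, ]
  graphics::image(seq_len(nrow(sl)) - 1, seq_len(ncol(sl)) - 1, sl,
                  col = grDevices::gray.colors(64, 0, 1), xlab = "Z (slice)",
                  ylab = "X", useRaster = TRUE, ...)
  graphics::points(x$truth$z_centroid, x$truth$x_centroid, pch = 16,
                   col = ifelse(x$truth$valve == 1L, "dodgerblue", "firebrick"))
  invisible(x)
}
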