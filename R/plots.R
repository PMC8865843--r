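# Base-graphics views of the main result objects.

#' Heatmap of a distance matrix
#'
#' @param x a [DistanceMatrix-class].
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @importFrom graphics image axis text par matplot legend points
#' @importFrom grDevices hcl.colors
#' @export
plotDistanceMatrix <- function(x, main = paste(x@flavor, "distances"), ...) {
  v <- distanceValues(x)
  n <- nrow(v)
  image(seq_len(n), seq_len(n), t(v[n:1, ]), axes = FALSE,
        xlab = "", ylab = "", main = main,
        col = hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  axis(1, seq_len(n), colnames(v), las = 2, cex.axis = 0.8)
  axis(2, seq_len(n), rev(rownames(v)), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Tuning curves coloured by cluster
#'
#' @param x a [TuningCurveSet-class] (clustered or not).
#' @param reference optional data.frame from [afferentReference()]; its
#'   curves are over-plotted dashed.
#' @param ... passed to [graphics::matplot()].
#' @export
plotTuningCurves <- function(x, reference = NULL, ...) {
  cols <- if (length(x@cluster))
    c(low = "firebrick", high = "forestgreen")[as.character(x@cluster)]
  else rep("grey30", nrow(x@sensitivity))
  matplot(x@frequencies, t(x@sensitivity), type = "l", lty = 1,
          col = cols, xlab = "frequency (Hz)", ylab = "sensitivity", ...)
  if (!is.null(reference))
    for (cv in split(reference, reference$curve))
      graphics::lines(cv$frequency_hz, cv$sensitivity, lty = 2, lwd = 2,
                      col = if (cv$curve[1] == "RA") "firebrick"
                            else "forestgreen")
  invisible(x)
}

#' t-SNE scatter of materials coloured by category
#'
#' @param coords output of [tsneEmbed()].
#' @param ... passed to [graphics::plot()].
#' @export
plotTsne <- function(coords, ...) {
  cats <- attr(coords, "categories")
  col <- seq_along(MATERIAL_CATEGORIES)[cats + 1L]
  plot(coords, col = col, pch = 19, xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  legend("topright", legend = MATERIAL_CATEGORIES[sort(unique(cats)) + 1L],
         col = sort(unique(cats)) + 1L, pch = 19, cex = 0.7)
  invisible(coords)
}
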