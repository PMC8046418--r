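#' QIBC-style scatter of a per-cell metric along the DNA-content axis
#'
#' The field-standard view: total DAPI (DNA content) on x, a damage or
#' marker metric on y, one dot per cell, optionally colored by phase and
#' with the 2N/4N anchors marked.
#'
#' @param cells cell table.
#' @param y metric column for the y axis.
#' @param anchors optional `dapi_anchors`; drawn as vertical lines.
#' @param log_y log-scale the y axis.
#' @param col_by optional column for point colors (e.g. `"phase"`).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL; draws on the active device.
#' @export
plot_qibc_scatter <- function(cells, y, anchors = NULL, log_y = FALSE,
                              col_by = "phase", ...) {
  if (is.null(cells[[y]])) stopf("metric '%s' missing", y)
  cols <- "grey30"
  if (!is.null(col_by) && !is.null(cells[[col_by]])) {
    f <- factor(cells[[col_by]])
    pal <- grDevices::hcl.colors(max(3, nlevels(f)), "Dark 3")
    cols <- pal[as.integer(f)]
  }
  graphics::plot(cells$total_dna, cells[[y]],
                 log = if (log_y) "y" else "",
                 pch = 16, cex = 0.4, col = cols,
                 xlab = "total DAPI (a.u., DNA content)", ylab = y, ...)
  if (!is.null(anchors))
    graphics::abline(v = c(anchors$anchor_2n, anchors$anchor_4n),
                     lty = 2, col = "grey50")
  invisible(NULL)
}
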