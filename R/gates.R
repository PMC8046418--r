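#' Declare a 2-D (or 1-D) cytometry-style gate
#'
#' Replaces by-eye gating with a declared, logged region. A gate is a
#' rectangle or polygon over one or two cell-table features, each on a
#' linear or log axis. Rectangle boundaries are lower-inclusive /
#' upper-exclusive so that counts are additive across adjacent gates.
#'
#' @param gate_name name recorded in reports.
#' @param x_feature,y_feature cell-table column names (`y_feature` may be
#'   NULL for a 1-D gate).
#' @param region for rectangles, a list with `xlim` (and `ylim`); for
#'   polygons, a `data.frame` with columns `x`, `y` in transformed
#'   coordinates.
#' @param x_transform,y_transform `"linear"` or `"log"`.
#' @return a `gate_spec` object.
#' @export
gate_spec <- function(gate_name, x_feature, y_feature = NULL,
                      region, x_transform = "linear",
                      y_transform = "linear") {
  if (is.data.frame(region)) {
    if (nrow(region) < 3 || is.null(region$x) || is.null(region$y))
      stopf("a polygon region needs >= 3 (x, y) vertices")
    type <- "polygon"
  } else {
    if (is.null(region$xlim) || diff(region$xlim) <= 0)
      stopf("a rectangle region needs a non-degenerate 'xlim'")
    if (!is.null(y_feature) &&
        (is.null(region$ylim) || diff(region$ylim) <= 0))
      stopf("a 2-D rectangle needs a non-degenerate 'ylim'")
    type <- "rectangle"
  }
  structure(list(gate_name = gate_name, x_feature = x_feature,
                 y_feature = y_feature, region = region, type = type,
                 x_transform = match.arg(x_transform, c("linear", "log")),
                 y_transform = match.arg(y_transform, c("linear", "log"))),
            class = "gate_spec")
}

gate_axis <- function(values, transform) {
  if (transform == "log") log(pmax(values, .Machine$double.eps)) else values
}

# even-odd ray casting; boundary points resolve by the crossing rule
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Apply a gate to a cell table
#'
#' @param cells cell table containing the gate's features.
#' @param gate a [gate_spec()].
#' @return a list with `cells` (the subset inside the gate, with a
#'   `gate` column) and `report` (gate name, counts, fraction). An empty
#'   result warns rather than errors.
#' @export
apply_gate <- function(cells, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  if (is.null(cells[[gate$x_feature]]))
    stopf("feature '%s' missing from the cell table", gate$x_feature)
  x <- gate_axis(cells[[gate$x_feature]], gate$x_transform)
  if (gate$type == "rectangle") {
    inside <- x >= gate$region$xlim[1] & x < gate$region$xlim[2]
    if (!is.null(gate$y_feature)) {
      if (is.null(cells[[gate$y_feature]]))
        stopf("feature '%s' missing from the cell table", gate$y_feature)
      y <- gate_axis(cells[[gate$y_feature]], gate$y_transform)
      inside <- inside & y >= gate$region$ylim[1] & y < gate$region$ylim[2]
    }
  } else {
    if (is.null(cells[[gate$y_feature]]))
      stopf("feature '%s' missing from the cell table", gate$y_feature)
    y <- gate_axis(cells[[gate$y_feature]], gate$y_transform)
    inside <- point_in_polygon(x, y, gate$region$x, gate$region$y)
  }
  inside[is.na(inside)] <- FALSE
  sub <- cells[inside, , drop = FALSE]
  if (!nrow(sub)) warnf("gate '%s' selected no cells", gate$gate_name)
  sub$gate <- rep(gate$gate_name, nrow(sub))
  list(cells = sub,
       report = list(gate_name = gate$gate_name,
                     n_in = nrow(sub), n_total = nrow(cells),
                     fraction = if (nrow(cells)) nrow(sub) / nrow(cells)
                     else NA_real_))
}

#' Default anchor-relative DNA-content gates
#'
#' The 2N and 4N windows used for binned comparisons: total DAPI within
#' +/-10% of the respective anchor.
#'
#' @param anchors a `dapi_anchors` object.
#' @param half_width relative half-width (default 0.1).
#' @return named list of two [gate_spec()] objects, `gate_2n`, `gate_4n`.
#' @export
dna_content_gates <- function(anchors, half_width = 0.1) {
  list(gate_2n = gate_spec("2N", "total_dna",
                           region = list(xlim = anchors$anchor_2n *
                                           c(1 - half_width, 1 + half_width))),
       gate_4n = gate_spec("4N", "total_dna",
                           region = list(xlim = anchors$anchor_4n *
                                           c(1 - half_width, 1 + half_width))))
}
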