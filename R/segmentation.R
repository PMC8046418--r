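#' Dynamic background correction of one channel
#'
#' Estimates a smooth background and subtracts it, clipping at zero, so
#' that intensities are comparable across the field. Three estimators are
#' available; the scale must be chosen per channel role (larger than a
#' nucleus for whole-field correction of nuclear channels; between focus
#' and nucleus size when preparing a focus channel).
#'
#' \describe{
#'   \item{tophat}{white top-hat: input minus its grayscale opening with a
#'     disc of radius `scale`. Removes everything wider than the disc.}
#'   \item{rolling_ball}{grayscale opening with a disc of radius `scale`
#'     followed by Gaussian smoothing of the background estimate.}
#'   \item{plane_fit}{least-squares plane fitted to the dim (background)
#'     half of the pixels, then subtracted; suits flat or tilted-
#'     illumination backgrounds.}
#' }
#'
#' @param channel numeric matrix of intensities.
#' @param method one of `"tophat"`, `"rolling_ball"`, `"plane_fit"`.
#' @param scale structuring-element radius in px (ignored by plane_fit).
#' @return background-corrected matrix, non-negative.
#' @export
correct_background <- function(channel,
                               method = c("tophat", "rolling_ball",
                                          "plane_fit"),
                               scale = 25) {
  method <- match.arg(method)
  if (!is.matrix(channel) || !is.numeric(channel))
    stopf("'channel' must be a numeric matrix")
  if (method != "plane_fit") assert_scalar_number(scale, "scale",
                                                  positive = TRUE)
  if (method == "plane_fit") {
    nr <- nrow(channel); nc <- ncol(channel)
    # fit on a pixel subsample of the dim (background) half of the field
    step <- max(1L, floor(sqrt(length(channel) / 40000)))
    ri <- seq(1L, nr, by = step); ci <- seq(1L, nc, by = step)
    sub <- channel[ri, ci]
    dim_idx <- sub <= median(sub)
    rr <- ri[row(sub)[dim_idx]]; cc <- ci[col(sub)[dim_idx]]
    fit <- lm.fit(cbind(1, rr, cc), sub[dim_idx])
    b <- fit$coefficients
    bg <- b[1] + outer(b[2] * seq_len(nr), b[3] * seq_len(nc), "+")
    return(pmax(channel - bg, 0))
  }
  if (method == "tophat") return(white_tophat(channel, scale))
  # rolling_ball: grayscale opening as the background, lightly smoothed
  # (normalized convolution keeps the estimate unbiased at the borders)
  bg <- grey_opening(channel, scale)
  s <- max(1, scale / 4)
  bg <- gaussian_blur(bg, s) /
    gaussian_blur(matrix(1, nrow(bg), ncol(bg)), s)
  pmax(channel - bg, 0)
}

#' Segment interphase nuclei from the DNA-stain channel
#'
#' Intensity-based detection on the background-corrected DNA channel:
#' light Gaussian smoothing, Otsu threshold, hole filling, optional
#' distance-transform watershed to split touching nuclei, then size and
#' border filtering. Returns a label mask with contiguous labels `1..K` in
#' raster order.
#'
#' @param dna_channel background-corrected numeric matrix.
#' @param params list of segmentation parameters: `threshold_method`
#'   (`"otsu"` or a fixed numeric threshold), `threshold_factor`
#'   (default 0.3; the Otsu threshold is scaled down by this factor so the
#'   mask captures the dim shoulder of each nucleus — with integrated
#'   intensity as the DNA-content proxy, truncating the object loses
#'   signal), `smooth_sigma` (default 1), `min_area` / `max_area` in px^2
#'   (defaults 1500 / 16000), `split_touching` (default TRUE),
#'   `watershed_tolerance` (distance-map units), `border_policy`
#'   (`"exclude"` drops nuclei touching the field edge, `"flag"` keeps
#'   them; truncated intensities make them unusable for DNA-content work
#'   either way).
#' @return integer label matrix; 0 is background. An empty field yields an
#'   all-zero mask, not an error.
#' @export
segment_nuclei <- function(dna_channel, params = list()) {
  p <- utils::modifyList(
    list(threshold_method = "otsu", threshold_factor = 0.3,
         smooth_sigma = 1, min_area = 1500, max_area = 16000,
         split_touching = TRUE, watershed_tolerance = NULL,
         border_policy = "exclude"),
    params)
  if (!is.matrix(dna_channel)) stopf("'dna_channel' must be a matrix")
  x <- dna_channel
  if (p$smooth_sigma > 0) x <- gaussian_blur(x, p$smooth_sigma)
  rng <- range(x)
  if (diff(rng) <= 0)
    return(matrix(0L, nrow(x), ncol(x)))
  if (identical(p$threshold_method, "otsu")) {
    xn <- (x - rng[1]) / diff(rng)
    th <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256L) *
      p$threshold_factor
  } else {
    th <- as.numeric(p$threshold_method)
  }
  mask <- x > th
  if (!any(mask)) return(matrix(0L, nrow(x), ncol(x)))
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  labels <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(mask))),
                   nrow(x), ncol(x))
  if (isTRUE(p$split_touching) && max(labels) > 0L) {
    # watershed each connected component on its own padded crop: same
    # result as a whole-field distance-transform watershed, much cheaper
    tol <- p$watershed_tolerance %||% max(1, 0.25 * sqrt(p$min_area / pi))
    out <- matrix(0L, nrow(x), ncol(x))
    next_lab <- 0L
    idx <- which(labels > 0L)
    lab_v <- labels[idx]
    prow <- ((idx - 1L) %% nrow(x)) + 1L
    pcol <- ((idx - 1L) %/% nrow(x)) + 1L
    rmin <- tapply(prow, lab_v, min); rmax <- tapply(prow, lab_v, max)
    cmin <- tapply(pcol, lab_v, min); cmax <- tapply(pcol, lab_v, max)
    for (li in seq_along(rmin)) {
      l <- as.integer(names(rmin)[li])
      r0 <- max(1L, rmin[[li]] - 1L); r1 <- min(nrow(x), rmax[[li]] + 1L)
      c0 <- max(1L, cmin[[li]] - 1L); c1 <- min(ncol(x), cmax[[li]] + 1L)
      sub <- (labels[r0:r1, c0:c1] == l) * 1
      ws <- EBImage::imageData(EBImage::watershed(EBImage::distmap(sub),
                                                  tolerance = tol, ext = 1L))
      ws <- matrix(as.integer(ws), nrow(sub), ncol(sub))
      pos <- ws > 0L
      out[r0:r1, c0:c1][pos] <- ws[pos] + next_lab
      next_lab <- next_lab + max(ws)
    }
    labels <- out
  }

  areas <- tabulate(labels[labels > 0L])
  drop <- which(areas < p$min_area | areas > p$max_area)
  if (identical(p$border_policy, "exclude")) {
    border_labs <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border_labs[border_labs > 0L])
  }
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_raster_order(labels)
}

# contiguous labels 1..K ordered by first pixel in column-major raster order
relabel_raster_order <- function(labels) {
  pos <- labels > 0L
  if (!any(pos)) return(labels)
  old <- labels[pos]
  first <- vapply(split(which(pos), old), min, numeric(1))
  ord <- names(sort(first))
  map <- integer(max(labels))
  map[as.integer(ord)] <- seq_along(ord)
  labels[pos] <- map[old]
  labels
}

#' Extract per-nucleus geometry and intensity features
#'
#' One record per label: centroid, area, bounding box, border flag, and
#' per-channel total and mean intensity summed over the exact mask. The
#' channels supplied here are expected to be background-corrected; totals
#' on the DNA channel are the per-cell DNA-content proxy used everywhere
#' downstream.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param field a `qibc_field` or a named list of channel matrices.
#' @param field_id identifier to stamp on the records (defaults to the
#'   field's own).
#' @return a `data.frame` with one row per nucleus, ordered by label:
#'   `nucleus_label`, `field_id`, `centroid_row`, `centroid_col`, `area`,
#'   `bbox_*`, `touches_border`, and `total_<role>` / `mean_<role>` per
#'   channel.
#' @export
extract_features <- function(labels, field, field_id = NULL) {
  channels <- if (inherits(field, "qibc_field")) field$channels else field
  if (is.null(field_id))
    field_id <- if (inherits(field, "qibc_field")) field$field_id else "field"
  if (!all(vapply(channels, function(ch)
    identical(dim(ch), dim(labels)), logical(1))))
    stopf("all channels must share the label mask's shape")
  idx <- which(labels > 0L)
  if (!length(idx)) {
    out <- data.frame(nucleus_label = integer(0), field_id = character(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      area = numeric(0), bbox_row_min = integer(0),
                      bbox_row_max = integer(0), bbox_col_min = integer(0),
                      bbox_col_max = integer(0), touches_border = logical(0))
    for (ch in names(channels)) {
      out[[paste0("total_", ch)]] <- numeric(0)
      out[[paste0("mean_", ch)]] <- numeric(0)
    }
    return(out)
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  labs <- sort(unique(lab))
  f <- factor(lab, levels = labs)
  area <- as.vector(table(f))
  cen_r <- rowsum(rows, f)[, 1] / area
  cen_c <- rowsum(cols, f)[, 1] / area
  rmin <- vapply(split(rows, f), min, numeric(1))
  rmax <- vapply(split(rows, f), max, numeric(1))
  cmin <- vapply(split(cols, f), min, numeric(1))
  cmax <- vapply(split(cols, f), max, numeric(1))
  touches <- rmin == 1L | cmin == 1L | rmax == nr | cmax == ncol(labels)
  out <- data.frame(nucleus_label = labs, field_id = field_id,
                    centroid_row = cen_r, centroid_col = cen_c,
                    area = area,
                    bbox_row_min = rmin, bbox_row_max = rmax,
                    bbox_col_min = cmin, bbox_col_max = cmax,
                    touches_border = touches,
                    row.names = NULL)
  for (ch in names(channels)) {
    tot <- rowsum(channels[[ch]][idx], f)[, 1]
    out[[paste0("total_", ch)]] <- tot
    out[[paste0("mean_", ch)]] <- tot / area
  }
  out
}
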