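#' Rendering parameters for synthetic fields
#'
#' Fixed optical/staining constants of the generator. Intensities are
#' photon-count-like arbitrary units on a 16-bit scale.
#'
#' @param dna_gain integrated DNA-channel intensity per genome equivalent
#'   (default 2e5 counts, so a 2N nucleus integrates ~4e5 a.u. and its
#'   interior sits well above the read noise).
#' @param marker_gain mean nuclear counts per arbitrary marker-level unit
#'   (default 300).
#' @param nucleus_area_g1 mean G1 nucleus area in px^2 (default 4000, a
#'   U-2 OS-like nucleus at a 40x objective); areas scale as
#'   `dna_content^(2/3)` with 10% jitter. This default keeps the focus
#'   load sparse relative to the nuclear area even at ~20 foci per
#'   nucleus.
#' @param area_jitter relative uniform jitter on nucleus area.
#' @param focus_amplitude peak counts of a rendered focus (default 3000).
#' @param focus_sigma Gaussian radius of a focus in px (default 1.0).
#' @param focus_amplitude_multiplier global multiplier on focus amplitude
#'   (per-focus intensity is held constant by default).
#' @param focus_min_spacing minimum pairwise distance between planted foci
#'   in px (default 9); foci are modeled as resolvable discrete damage
#'   sites.
#' @param nuclear_focus_level pan-nuclear (non-focal) signal on the focus
#'   channel, in marker-level units.
#' @param pixel_depth bit depth of the rendered images.
#' @return a named list of rendering constants.
#' @export
render_params <- function(dna_gain = 2e5, marker_gain = 300,
                          nucleus_area_g1 = 4000, area_jitter = 0.1,
                          focus_amplitude = 3000, focus_sigma = 1.0,
                          focus_amplitude_multiplier = 1,
                          focus_min_spacing = 9,
                          nuclear_focus_level = 0.5,
                          pixel_depth = 16) {
  list(dna_gain = dna_gain, marker_gain = marker_gain,
       nucleus_area_g1 = nucleus_area_g1, area_jitter = area_jitter,
       focus_amplitude = focus_amplitude, focus_sigma = focus_sigma,
       focus_amplitude_multiplier = focus_amplitude_multiplier,
       focus_min_spacing = focus_min_spacing,
       nuclear_focus_level = nuclear_focus_level,
       pixel_depth = pixel_depth)
}

# sequential rejection placement of nucleus centroids with a minimum
# pairwise distance; errors naming the limit when the field is too crowded
place_centroids <- function(n, image_shape, margin, min_spacing,
                            max_tries = 400L * n) {
  nr <- image_shape[1]; nc <- image_shape[2]
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
    stopf("image shape %dx%d too small for nuclei of margin %d px",
          nr, nc, margin)
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf(paste0("cannot place %d nuclei at minimum spacing %.1f px in a ",
                   "%dx%d field (placed %d); reduce cell count or spacing"),
            n, min_spacing, nr, nc, placed)
    r <- runif(1, margin + 1, nr - margin)
    c_ <- runif(1, margin + 1, nc - margin)
    if (placed == 0L ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c_)^2) >=
          min_spacing^2) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c_
    }
  }
  cbind(row = rows, col = cols)
}

# uniform points inside the (scaled) ellipse with a minimum pairwise spacing
place_foci <- function(k, ctr, semi_r, semi_c, min_spacing,
                       shrink = 0.65, max_tries = 300L) {
  if (k == 0L) return(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("row", "col"))))
  rows <- numeric(k); cols <- numeric(k); placed <- 0L
  for (i in seq_len(k)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      rad <- sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      r <- ctr[1] + shrink * semi_r * rad * sin(th)
      c_ <- ctr[2] + shrink * semi_c * rad * cos(th)
      if (placed == 0L ||
          min((rows[seq_len(placed)] - r)^2 +
              (cols[seq_len(placed)] - c_)^2) >= min_spacing^2) {
        placed <- placed + 1L
        rows[placed] <- r; cols[placed] <- c_
        ok <- TRUE
        break
      }
    }
    if (!ok) break  # nucleus saturated; truth records the planted count
  }
  cbind(row = rows[seq_len(placed)], col = cols[seq_len(placed)])
}

#' Render one synthetic microscope field with ground truth
#'
#' Renders a multi-channel 2-D field from sampled cell states: nuclei as
#' smooth elliptical intensity domes on the DNA channel (integrated
#' intensity proportional to DNA content, area growing as
#' `dna_content^(2/3)`), uniform nuclear marker signal on the EdU /
#' Cyclin A / H4K20me2 channels, and Gaussian focus spots on the focus
#' channel with per-cell counts drawn Poisson from the focus-rate model.
#' A Gaussian PSF blur, constant background and Gaussian read noise are
#' applied; everything is seeded.
#'
#' @param states a population `data.frame` from [sample_population()].
#' @param image_shape `c(rows, cols)`, at least 128x128.
#' @param focus_params a [focus_model_params()] object; its condition
#'   should match the population's.
#' @param channels roles to render; `"dna"` is mandatory.
#' @param psf_sigma Gaussian PSF sigma in px (default 1).
#' @param noise list with `gaussian_sd` (read noise SD, counts) and
#'   `background_level` (constant offset, counts).
#' @param params rendering constants from [render_params()].
#' @param min_spacing minimum centroid spacing in px; default ensures
#'   non-overlapping nuclei.
#' @param field_id identifier recorded in the outputs.
#' @param seed integer seed for this field.
#' @return a list with `image` (a `qibc_field`: named channel matrices,
#'   channel roles, pixel depth, field id), `truth` (per-cell ground-truth
#'   `data.frame`) and `foci` (planted focus positions).
#' @export
render_field <- function(states,
                         image_shape = c(512, 512),
                         focus_params = focus_model_params(
                           condition = states$condition[1]),
                         channels = c("dna", "edu", "cyclinA", "focus",
                                      "h4k20me2"),
                         psf_sigma = 1,
                         noise = list(gaussian_sd = 10, background_level = 100),
                         params = render_params(),
                         min_spacing = NULL,
                         field_id = "field_001",
                         seed = 1L) {
  stopifnot(is.data.frame(states), nrow(states) >= 1)
  if (length(image_shape) != 2L || any(image_shape < 128))
    stopf("'image_shape' must be at least 128x128")
  channels <- match.arg(channels, several.ok = TRUE)
  if (!"dna" %in% channels) stopf("a 'dna' channel is mandatory")
  set.seed(as.integer(seed))
  n <- nrow(states)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])

  lambda <- expected_focus_count(states, focus_params)

  area <- params$nucleus_area_g1 * (states$dna_content / 2)^(2 / 3) *
    runif(n, 1 - params$area_jitter, 1 + params$area_jitter)
  ecc <- runif(n, 0.9, 1.1)
  semi_c <- sqrt(area / pi) * ecc   # column (x) semi-axis
  semi_r <- sqrt(area / pi) / ecc   # row (y) semi-axis
  max_semi <- max(semi_r, semi_c)
  margin <- ceiling(max_semi) + 4L
  if (is.null(min_spacing)) min_spacing <- 2 * max_semi + 2
  ctr <- place_centroids(n, c(nr, nc), margin, min_spacing)

  scene <- setNames(lapply(channels, function(x) matrix(0, nr, nc)), channels)

  area_px <- integer(n)
  true_tot <- matrix(0, n, length(channels),
                     dimnames = list(NULL, channels))
  n_foci <- integer(n)
  foci_list <- vector("list", n)
  amp <- params$focus_amplitude * params$focus_amplitude_multiplier
  fsig <- params$focus_sigma

  for (i in seq_len(n)) {
    cy <- ctr[i, "row"]; cx <- ctr[i, "col"]
    br <- semi_r[i]; bc <- semi_c[i]
    rr <- max(1L, floor(cy - br)):min(nr, ceiling(cy + br))
    cc <- max(1L, floor(cx - bc)):min(nc, ceiling(cx + bc))
    q <- outer(((rr - cy) / br)^2, ((cc - cx) / bc)^2, "+")
    inside <- q < 1
    area_px[i] <- sum(inside)
    # paraboloid dome integrating (continuously) to dna_gain * dna_content
    tgt <- params$dna_gain * states$dna_content[i]
    peak <- 2 * tgt / (pi * br * bc)
    dome <- peak * pmax(1 - q, 0)
    scene$dna[rr, cc] <- scene$dna[rr, cc] + dome
    true_tot[i, "dna"] <- sum(dome)

    for (ch in intersect(channels, c("edu", "cyclinA", "h4k20me2"))) {
      lev <- switch(ch, edu = states$edu_level[i],
                    cyclinA = states$cyclinA_level[i],
                    h4k20me2 = states$h4k20me2_level[i])
      val <- lev * params$marker_gain
      scene[[ch]][rr, cc][inside] <- scene[[ch]][rr, cc][inside] + val
      true_tot[i, ch] <- val * area_px[i]
    }

    if ("focus" %in% channels) {
      pan <- params$nuclear_focus_level * params$marker_gain
      scene$focus[rr, cc][inside] <- scene$focus[rr, cc][inside] + pan
      k <- rpois(1, lambda[i])
      pos <- place_foci(k, c(cy, cx), br, bc, params$focus_min_spacing)
      n_foci[i] <- nrow(pos)
      if (nrow(pos) > 0) {
        box <- ceiling(4 * fsig)
        for (j in seq_len(nrow(pos))) {
          fr <- pos[j, "row"]; fc <- pos[j, "col"]
          r2 <- max(1L, floor(fr - box)):min(nr, ceiling(fr + box))
          c2 <- max(1L, floor(fc - box)):min(nc, ceiling(fc + box))
          g <- amp * outer(exp(-(r2 - fr)^2 / (2 * fsig^2)),
                           exp(-(c2 - fc)^2 / (2 * fsig^2)))
          scene$focus[r2, c2] <- scene$focus[r2, c2] + g
          true_tot[i, "focus"] <- true_tot[i, "focus"] + sum(g)
        }
        foci_list[[i]] <- data.frame(cell_id = states$cell_id[i],
                                     row = pos[, "row"], col = pos[, "col"],
                                     amplitude = amp, sigma = fsig)
      }
    }
  }

  max_val <- 2^params$pixel_depth - 1
  for (ch in channels) {
    x <- scene[[ch]]
    if (psf_sigma > 0)
      x <- gaussian_blur(x, psf_sigma)
    x <- x + (noise$background_level %||% 0)
    sd_ <- noise$gaussian_sd %||% 0
    if (sd_ > 0) x <- x + rnorm(length(x), sd = sd_)
    scene[[ch]] <- matrix(pmin(pmax(round(x), 0), max_val), nr, nc)
  }

  truth <- cbind(states,
                 data.frame(field_id = field_id,
                            centroid_row = ctr[, "row"],
                            centroid_col = ctr[, "col"],
                            semiaxis_row = semi_r,
                            semiaxis_col = semi_c,
                            nucleus_area_px = area_px,
                            expected_foci = lambda,
                            true_focus_count = n_foci))
  for (ch in channels)
    truth[[paste0("true_total_", ch)]] <- true_tot[, ch]

  foci <- do.call(rbind, foci_list[!vapply(foci_list, is.null, logical(1))])
  if (is.null(foci))
    foci <- data.frame(cell_id = integer(0), row = numeric(0),
                       col = numeric(0), amplitude = numeric(0),
                       sigma = numeric(0))
  foci$field_id <- rep(field_id, nrow(foci))

  image <- structure(list(channels = scene,
                          channel_roles = setNames(channels, channels),
                          pixel_depth = params$pixel_depth,
                          field_id = field_id),
                     class = "qibc_field")
  list(image = image, truth = truth, foci = foci)
}
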