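`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage- or field-local seed from a master seed
#'
#' One master seed governs a whole run; every field, bootstrap or stage
#' derives its own seed deterministically so that work units are
#' reproducible independently of execution order.
#'
#' @param master integer master seed.
#' @param index integer index of the work unit (field number, stage id...).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  # multiplicative-congruential mix; doubles stay exact (< 2^53)
  m <- (abs(as.numeric(master)) %% 2147483647)
  i <- abs(as.numeric(index)) %% 2147483647
  as.integer(((m * 48271 + i * 16807 + 12345) %% 2147483647))
}

# Otsu threshold on a numeric vector (two-class variance maximisation on a
# 256-bin histogram). Used for 1-D marker gating in log space; EBImage's
# otsu() serves the image-raster case.
otsu_vector <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_mu <- mu[n_bins]
  w0 <- w[-n_bins]
  w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-n_bins] / w0
  m1 <- (tot_mu - mu[-n_bins]) / w1
  between <- w0 * w1 * (m0 - m1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  (breaks[k + 1L])
}

# lognormal multiplicative noise with unit mean and given coefficient of
# variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}

# separable Gaussian blur via two 1-D convolutions (stats::filter is a
# compiled loop); zero-padded boundaries. Much faster than an FFT on the
# field sizes used here and exactly sum-preserving away from the border.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m) rbind(matrix(0, half, ncol(m)), m,
                           matrix(0, half, ncol(m)))
  conv_cols <- function(m) {
    y <- stats::filter(pad(m), k, sides = 2)
    matrix(y[(half + 1):(half + nrow(m)), ], nrow(m), ncol(m))
  }
  t(conv_cols(t(conv_cols(x))))
}

# --- flat grayscale morphology with a disc structuring element ---------
# Disc erosion/dilation decomposed into horizontal chords: for each row
# offset dy the disc contributes a centered 1-D min/max of half-width
# w(dy) = floor(sqrt(R^2 - dy^2)). 1-D running extrema are built from
# O(log w) vectorized pmin/pmax of shifted copies. Outside the image the
# erosion sees +Inf and the dilation -Inf (standard border handling), so
# a constant field is a fixed point of opening.

shift_rows_fill <- function(m, d, fill) {
  nr <- nrow(m)
  out <- matrix(fill, nr, ncol(m))
  if (d >= 0) {
    if (d < nr) out[seq_len(nr - d), ] <- m[(d + 1):nr, , drop = FALSE]
  } else {
    if (-d < nr) out[(-d + 1):nr, ] <- m[seq_len(nr + d), , drop = FALSE]
  }
  out
}

# y[i,] = extremum of x[i .. i+k-1, ] (start-anchored window of k rows)
run_ext_rows <- function(x, k, op, fill) {
  y <- x
  s <- 1L
  while (s < k) {
    t <- min(s, k - s)
    y <- op(y, shift_rows_fill(y, t, fill))
    s <- s + t
  }
  y
}

# centered running extremum over rows with half-width w
centered_ext_rows <- function(x, w, op, fill) {
  if (w == 0L) return(x)
  shift_rows_fill(run_ext_rows(x, 2L * w + 1L, op, fill), -w, fill)
}

disc_morph <- function(x, radius, op, fill) {
  r <- as.integer(ceiling(radius))
  dys <- 0:r
  ws <- floor(sqrt(pmax(radius^2 - dys^2, 0)))
  # horizontal chords: centered extrema along columns (transpose trick)
  chord <- lapply(unique(ws), function(w)
    t(centered_ext_rows(t(x), w, op, fill)))
  names(chord) <- as.character(unique(ws))
  out <- matrix(fill, nrow(x), ncol(x))
  for (i in seq_along(dys)) {
    h <- chord[[as.character(ws[i])]]
    out <- op(out, shift_rows_fill(h, dys[i], fill))
    if (dys[i] > 0)
      out <- op(out, shift_rows_fill(h, -dys[i], fill))
  }
  out
}

grey_erode <- function(x, radius) disc_morph(x, radius, pmin, Inf)
grey_dilate <- function(x, radius) disc_morph(x, radius, pmax, -Inf)
grey_opening <- function(x, radius) grey_dilate(grey_erode(x, radius),
                                                radius)
white_tophat <- function(x, radius) pmax(x - grey_opening(x, radius), 0)

# local maxima of a density object, returned as (x, y) of each mode
density_modes <- function(d) {
  y <- d$y
  n <- length(y)
  i <- which(y[-c(1, n)] > y[-c(n - 1, n)] & y[-c(1, n)] >= y[-c(1, 2)]) + 1L
  list(x = d$x[i], y = d$y[i])
}
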