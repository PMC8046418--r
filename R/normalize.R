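#' Normalize a per-cell damage metric to DNA content
#'
#' The central normalization: each cell's readout (focus count,
#' accumulated focus intensity, or a nuclear mean intensity) is divided by
#' that same cell's DNA content measured as total DAPI, then rescaled by a
#' power of ten so the numbers sit on a convenient linear scale. Because
#' IR-induced damage scales with the amount of DNA, this division flattens
#' the DNA-content dependence of a proportional signal and exposes genuine
#' per-chromatin changes in recruitment.
#'
#' @param cells interphase-filtered cell table; `total_dna` must be
#'   positive.
#' @param source_metric column to normalize (e.g. `"focus_count"`,
#'   `"foci_total_intensity"`).
#' @param scale_exponent integer power of 10, or `"auto"`: the smallest
#'   integer that puts the G1 median of the normalized values into
#'   `[1, 100]` (falls back to the whole-table median when no phase
#'   column is present).
#' @return the cell table with a `norm_<source_metric>` column; the
#'   exponent used is attached as attribute
#'   `scale_exponent_<source_metric>`.
#' @export
normalize_to_dna <- function(cells, source_metric = "focus_count",
                             scale_exponent = "auto") {
  if (is.null(cells[[source_metric]]))
    stopf("metric '%s' missing from the cell table", source_metric)
  if (is.null(cells$total_dna)) stopf("cell table lacks 'total_dna'")
  bad <- !is.finite(cells$total_dna) | cells$total_dna <= 0
  if (any(bad)) {
    warnf("%d rows excluded from normalization: non-positive total DAPI",
          sum(bad))
    cells <- cells[!bad, , drop = FALSE]
  }
  raw <- cells[[source_metric]] / cells$total_dna
  if (identical(scale_exponent, "auto")) {
    ref <- if (!is.null(cells$phase) && any(cells$phase == "G1"))
      raw[cells$phase == "G1"] else raw
    m <- median(ref, na.rm = TRUE)
    scale_exponent <- if (is.finite(m) && m > 0) ceiling(-log10(m)) else 0L
  }
  assert_scalar_number(scale_exponent, "scale_exponent")
  col <- paste0("norm_", source_metric)
  cells[[col]] <- raw * 10^scale_exponent
  attr(cells, paste0("scale_exponent_", source_metric)) <-
    as.integer(scale_exponent)
  cells
}

#' Summarize a metric per group, box-plot style
#'
#' Per group: n, median, mean, quartiles, and Tukey whiskers (most extreme
#' values within 1.5 IQR of the box). Medians and means are both always
#' reported.
#'
#' @param cells cell table.
#' @param grouping a column name (e.g. `"phase"`, `"gate"`, `"condition"`)
#'   or a vector of group labels of the table's length.
#' @param metric column to summarize.
#' @return a `data.frame` with one row per non-empty group.
#' @export
summarize_groups <- function(cells, grouping, metric) {
  if (is.null(cells[[metric]])) stopf("metric '%s' missing", metric)
  g <- if (length(grouping) == 1L && is.character(grouping)) {
    if (is.null(cells[[grouping]])) stopf("grouping column '%s' missing",
                                          grouping)
    cells[[grouping]]
  } else grouping
  if (length(g) != nrow(cells))
    stopf("grouping length does not match the cell table")
  keep <- !is.na(g) & is.finite(cells[[metric]])
  dropped <- setdiff(unique(g), unique(g[keep]))
  if (length(dropped))
    warnf("empty group(s) omitted: %s", paste(dropped, collapse = ", "))
  vals <- split(cells[[metric]][keep], g[keep])
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(group_name = nm, n_cells = length(v),
               median = q[2], mean = mean(v), q1 = q[1], q3 = q[3],
               whisker_lo = lo, whisker_hi = hi)
  })
  do.call(rbind, rows)
}

#' Ratio of a damage metric between two groups
#'
#' Default statistic is the ratio of medians (robust to the skew of focus
#' counts); means are available behind a flag. When raw per-cell values
#' are supplied a seeded bootstrap 95% CI accompanies the point estimate
#' (the CI is a descriptive convenience, seeded for reproducibility).
#'
#' @param a,b numeric vectors of per-cell values (numerator a, denominator
#'   b), or single-row group summaries from [summarize_groups()] (then no
#'   CI is computed).
#' @param stat `"median"` or `"mean"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @param conf confidence level.
#' @return a list with `ratio`, `stat`, and (when computable) `ci_lo`,
#'   `ci_hi`.
#' @export
recruitment_ratio <- function(a, b, stat = c("median", "mean"),
                              n_boot = 1000L, seed = 1L, conf = 0.95) {
  stat <- match.arg(stat)
  f <- if (stat == "median") median else mean
  if (is.data.frame(a) && is.data.frame(b)) {
    if (nrow(a) != 1L || nrow(b) != 1L)
      stopf("group-summary input must be single rows")
    den <- b[[stat]]
    if (!is.finite(den) || den == 0)
      stopf("undefined ratio: denominator group %s is zero", stat)
    return(list(ratio = a[[stat]] / den, stat = stat,
                ci_lo = NA_real_, ci_hi = NA_real_))
  }
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  den <- f(b)
  if (den == 0) stopf("undefined ratio: denominator group %s is zero", stat)
  est <- f(a) / den
  set.seed(as.integer(seed))
  bs <- vapply(seq_len(n_boot), function(i) {
    d <- f(sample(b, replace = TRUE))
    if (d == 0) return(NA_real_)
    f(sample(a, replace = TRUE)) / d
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(ratio = est, stat = stat, ci_lo = ci[1], ci_hi = ci[2],
       n_boot = n_boot)
}

#' Damage-metric profile along the DNA-content axis
#'
#' Bins cells into equal-count bins of total DAPI between the 2N and 4N
#' anchors (or over the observed range) and reports the per-bin median of
#' the chosen metric together with a Spearman correlation of bin center
#' versus median — the monotonicity statistic behind "recruitment declines
#' through S phase".
#'
#' @param cells cell table.
#' @param metric column to profile.
#' @param n_bins number of equal-count bins (default 8); at least
#'   `20 * n_bins` cells are required.
#' @param anchors optional `dapi_anchors`; when given, only cells between
#'   the anchors are profiled.
#' @return a `data.frame` (`bin`, `dapi_center`, `median_metric`, `n`)
#'   with attributes `spearman_rho` and `rho_defined` (FALSE when the
#'   metric is constant across bins, in which case rho is reported as 0).
#' @export
decline_profile <- function(cells, metric, n_bins = 8L, anchors = NULL) {
  if (is.null(cells[[metric]])) stopf("metric '%s' missing", metric)
  if (is.null(cells$total_dna)) stopf("cell table lacks 'total_dna'")
  d <- cells[is.finite(cells$total_dna) & is.finite(cells[[metric]]), ,
             drop = FALSE]
  if (!is.null(anchors))
    d <- d[d$total_dna >= anchors$anchor_2n &
             d$total_dna <= anchors$anchor_4n, , drop = FALSE]
  need <- 20L * n_bins
  if (nrow(d) < need)
    stopf("decline_profile needs at least %d cells (%d bins x 20); got %d",
          need, n_bins, nrow(d))
  qs <- quantile(d$total_dna, probs = seq(0, 1, length.out = n_bins + 1L),
                 names = FALSE)
  qs[1] <- qs[1] - 1e-9
  bin <- cut(d$total_dna, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  centers <- tapply(d$total_dna, bin, median)
  meds <- tapply(d[[metric]], bin, median)
  ns <- tapply(d$total_dna, bin, length)
  out <- data.frame(bin = as.integer(names(centers)),
                    dapi_center = as.numeric(centers),
                    median_metric = as.numeric(meds),
                    n = as.integer(ns))
  rho_defined <- length(unique(out$median_metric)) > 1L
  rho <- if (rho_defined)
    suppressWarnings(cor(out$dapi_center, out$median_metric,
                         method = "spearman")) else 0
  attr(out, "spearman_rho") <- rho
  attr(out, "rho_defined") <- rho_defined
  out
}
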