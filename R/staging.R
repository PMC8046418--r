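#' Fit 2N/4N DAPI anchors from an asynchronous population
#'
#' Locates the G1 (2N) and G2 (4N) modes of the total-DAPI distribution by
#' kernel density estimation on log-transformed totals (Silverman
#' bandwidth). The 2N anchor is the lowest substantial mode; the 4N anchor
#' is the dominant mode between 1.6x and 2.4x of it, falling back to
#' exactly `2 * anchor_2n` (with a warning) when the population contains
#' no resolvable 4N peak. On a well-formed cycling population the anchor
#' ratio is ~2: total DAPI doubles as the genome replicates.
#'
#' @param total_dapi numeric vector of per-nucleus total DAPI intensities
#'   (a.u.); at least ~200 cells spanning the cycle are recommended.
#' @param mode_height_frac a mode is "substantial" when its density is at
#'   least this fraction of the tallest mode (default 0.25).
#' @return a `dapi_anchors` object: `anchor_2n`, `anchor_4n`,
#'   `valid_range` (`[0.75 * anchor_2n, 1.25 * anchor_4n]`, the interphase
#'   2N-4N filter window), and `fallback_4n`.
#' @export
fit_dapi_anchors <- function(total_dapi, mode_height_frac = 0.25) {
  x <- total_dapi[is.finite(total_dapi) & total_dapi > 0]
  if (length(x) < 10)
    stopf("too few cells (%d) to fit DAPI anchors", length(x))
  if (length(x) < 200)
    warnf("only %d cells; DAPI anchors may be unstable", length(x))
  d <- density(log(x), bw = "nrd0")
  m <- density_modes(d)
  if (!length(m$x))
    stopf(paste0("no resolvable mode in the total-DAPI distribution; ",
                 "supply anchors manually"))
  keep <- m$y >= mode_height_frac * max(m$y)
  a2 <- exp(min(m$x[keep]))
  cand <- which(exp(m$x) / a2 > 1.6 & exp(m$x) / a2 < 2.4)
  fallback <- length(cand) == 0L
  if (fallback) {
    warnf("no 4N mode found between 1.6x and 2.4x the 2N anchor; %s",
          "falling back to anchor_4n = 2 * anchor_2n")
    a4 <- 2 * a2
  } else {
    a4 <- exp(m$x[cand[which.max(m$y[cand])]])
  }
  structure(list(anchor_2n = a2, anchor_4n = a4,
                 valid_range = c(0.75 * a2, 1.25 * a4),
                 fallback_4n = fallback),
            class = "dapi_anchors")
}

#' @export
print.dapi_anchors <- function(x, ...) {
  cat(sprintf("DAPI anchors: 2N = %.4g, 4N = %.4g (ratio %.3f)%s\n",
              x$anchor_2n, x$anchor_4n, x$anchor_4n / x$anchor_2n,
              if (x$fallback_4n) " [4N by fallback]" else ""))
  cat(sprintf("interphase window: [%.4g, %.4g]\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Interphase 2N-4N filter
#'
#' Keeps nuclei whose total DAPI lies inside the anchors' valid range,
#' removing debris, doublets and mis-segmented objects; downstream
#' analyses operate on properly detected interphase nuclei only.
#'
#' @param cells cell table with a `total_dna` column.
#' @param anchors a `dapi_anchors` object (or list with `valid_range`).
#' @param audit when TRUE, rows are retained and an `excluded` flag is
#'   added instead of dropping them.
#' @return the filtered (or flagged) cell table; an `excluded` column is
#'   present either way.
#' @export
filter_interphase <- function(cells, anchors, audit = FALSE) {
  if (is.null(cells$total_dna)) stopf("cell table lacks 'total_dna'")
  vr <- anchors$valid_range
  out <- !(cells$total_dna >= vr[1] & cells$total_dna <= vr[2])
  cells$excluded <- out
  if (audit) cells else cells[!out, , drop = FALSE]
}

#' Classify cells as EdU-positive (S phase) or negative
#'
#' Thresholds log mean-EdU at the antimode between the EdU-negative and
#' EdU-positive populations (two-class Otsu in log space, so the call is
#' invariant to global intensity rescaling). If the two classes are not
#' separated by at least a factor `min_separation`, the population is
#' treated as having no S-phase arc: all cells are called negative with a
#' warning.
#'
#' @param cells cell table with a `mean_edu` column.
#' @param min_separation minimum fold-separation between class means for
#'   the threshold to be trusted (default 3).
#' @return the cell table with an `edu_positive` logical column; the log
#'   threshold is attached as attribute `edu_log_threshold`.
#' @export
classify_edu <- function(cells, min_separation = 3) {
  if (is.null(cells$mean_edu)) stopf("cell table lacks 'mean_edu'")
  lx <- log(pmax(cells$mean_edu, .Machine$double.eps))
  th <- otsu_vector(lx)
  lo <- lx[lx <= th]; hi <- lx[lx > th]
  if (!length(hi) || !length(lo) ||
      (mean(hi) - mean(lo)) < log(min_separation)) {
    warnf("EdU distribution looks unimodal; calling all cells EdU-negative")
    cells$edu_positive <- FALSE
    attr(cells, "edu_log_threshold") <- NA_real_
    return(cells)
  }
  cells$edu_positive <- lx > th
  attr(cells, "edu_log_threshold") <- th
  cells
}

#' Call cell-cycle phase per nucleus
#'
#' Combines the markers: S is EdU-positive; among EdU-negative cells, G1
#' is below the DAPI midpoint of the anchors (and Cyclin A low, when that
#' channel is present), G2 above it (and Cyclin A high). EdU-negative
#' cells whose DAPI and Cyclin A calls disagree are marked `excluded`
#' rather than guessed. A `late_S_early_G2` subphase is flagged for
#' EdU-positive cells in the upper DAPI tertile between the anchors, and
#' for EdU-negative near-4N cells with intermediate-high Cyclin A.
#' Without an EdU channel the call degrades to DAPI (+ Cyclin A) only and
#' is flagged `coarse`.
#'
#' All thresholds are anchor- or antimode-relative, so phase calls are
#' invariant to multiplying every intensity by a constant.
#'
#' @param cells cell table after [classify_edu()] (needs `total_dna`,
#'   `edu_positive`; `mean_cyclinA` optional).
#' @param anchors a `dapi_anchors` object.
#' @param config optional overrides: `use_cyclinA`, `near_4n`
#'   (relative half-width of the "near 4N" window, default 0.1),
#'   `late_s_tertile` (default 2/3).
#' @return the cell table with `phase` (`G1`, `S`, `G2` or `excluded`),
#'   `subphase`, and `staging` (`"full"` or `"coarse"`) columns.
#' @export
call_phase <- function(cells, anchors, config = list()) {
  cfg <- utils::modifyList(list(use_cyclinA = TRUE, near_4n = 0.1,
                                late_s_tertile = 2 / 3), config)
  if (is.null(cells$total_dna)) stopf("cell table lacks 'total_dna'")
  a2 <- anchors$anchor_2n; a4 <- anchors$anchor_4n
  mid <- (a2 + a4) / 2
  n <- nrow(cells)
  has_edu <- !is.null(cells$edu_positive)
  has_cyc <- cfg$use_cyclinA && !is.null(cells$mean_cyclinA)

  cyc_high <- rep(NA, n)
  cyc_th <- NA_real_
  if (has_cyc) {
    ref <- if (has_edu) !cells$edu_positive else rep(TRUE, n)
    lx <- log(pmax(cells$mean_cyclinA, .Machine$double.eps))
    cyc_th <- otsu_vector(lx[ref])
    cyc_high <- lx > cyc_th
  }

  phase <- rep("excluded", n)
  if (has_edu) {
    s <- cells$edu_positive
    lowd <- cells$total_dna <= mid
    if (has_cyc) {
      phase[!s & lowd & !cyc_high] <- "G1"
      phase[!s & !lowd & cyc_high] <- "G2"
    } else {
      phase[!s & lowd] <- "G1"
      phase[!s & !lowd] <- "G2"
    }
    phase[s] <- "S"
  } else {
    lowd <- cells$total_dna <= mid
    if (has_cyc) {
      phase[lowd & !cyc_high] <- "G1"
      phase[!lowd | cyc_high] <- ifelse(
        cells$total_dna[!lowd | cyc_high] > mid, "G2", "S")
    } else {
      phase[lowd] <- "G1"
      phase[!lowd] <- "G2"
    }
  }

  subphase <- rep("none", n)
  late_s_cut <- a2 + cfg$late_s_tertile * (a4 - a2)
  if (has_edu) {
    subphase[cells$edu_positive & cells$total_dna >= late_s_cut] <-
      "late_S_early_G2"
    third <- (a4 - a2) / 3
    subphase[cells$edu_positive & cells$total_dna < a2 + third] <- "early_S"
    subphase[cells$edu_positive & cells$total_dna >= a2 + third &
               cells$total_dna < late_s_cut] <- "mid_S"
  }
  if (has_cyc && any(phase == "G2")) {
    near4 <- abs(cells$total_dna - a4) <= cfg$near_4n * a4
    g2_med <- median(log(pmax(cells$mean_cyclinA[phase == "G2"],
                              .Machine$double.eps)))
    inter <- log(pmax(cells$mean_cyclinA, .Machine$double.eps)) > cyc_th &
      log(pmax(cells$mean_cyclinA, .Machine$double.eps)) <= g2_med
    flag <- (if (has_edu) !cells$edu_positive else rep(TRUE, n)) &
      near4 & inter & subphase == "none"
    subphase[flag] <- "late_S_early_G2"
  }

  cells$phase <- phase
  cells$subphase <- subphase
  cells$staging <- if (has_edu) "full" else "coarse"
  if (!has_edu)
    warnf("no EdU feature: coarse staging from DAPI%s only",
          if (has_cyc) " + Cyclin A" else "")
  attr(cells, "cyclinA_log_threshold") <- cyc_th
  attr(cells, "dapi_midpoint") <- mid
  cells
}
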