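#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end run with its default. The
#' configuration round-trips losslessly through YAML/JSON (see
#' [read_run_config()]).
#'
#' @param image_dir directory of TIFF fields plus sidecars; NULL when
#'   `simulate` is given.
#' @param simulate optional [generate_experiment()] config; the images are
#'   generated under `out_dir/images` before analysis.
#' @param out_dir output directory for CSVs and the run report (NULL: keep
#'   results in memory only).
#' @param seed master seed governing simulation and bootstraps.
#' @param background list: `method` (default `"plane_fit"` for whole-field
#'   correction of nuclear channels) and `scale`.
#' @param segmentation parameter list for [segment_nuclei()].
#' @param focus parameter list for focus detection: `spot_scale`,
#'   `method`, `threshold_policy`, `k`, `min_focus_area`.
#' @param staging parameter list for [call_phase()].
#' @param metrics per-cell metrics to normalize to DNA content.
#' @param n_bins bins for the DNA-axis decline profiles.
#' @param audit keep interphase-excluded rows (flagged) in the cell table.
#' @return a `qibc_config` list.
#' @export
qibc_config <- function(image_dir = NULL, simulate = NULL, out_dir = NULL,
                        seed = 1L,
                        background = list(method = "plane_fit", scale = 50),
                        segmentation = list(),
                        focus = list(spot_scale = 1.5, method = "tophat",
                                     threshold_policy = "k_sigma", k = 5,
                                     min_focus_area = 4),
                        staging = list(),
                        metrics = c("focus_count", "foci_total_intensity"),
                        n_bins = 8L,
                        audit = FALSE) {
  structure(list(image_dir = image_dir, simulate = simulate,
                 out_dir = out_dir, seed = as.integer(seed),
                 background = background, segmentation = segmentation,
                 focus = focus, staging = staging, metrics = metrics,
                 n_bins = n_bins, audit = audit),
            class = "qibc_config")
}

#' Read / write a run configuration (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a `qibc_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(qibc_config, cfg)
}

#' @rdname read_run_config
#' @param config a `qibc_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate an image directory before analysis
#'
#' Checks every TIFF field: sidecar present, file readable, page count
#' matching the declared channel order, consistent page shapes, and
#' exactly one channel with the `dna` role. Reporting only — never throws.
#'
#' @param image_dir directory containing `*.tif` plus `*.json` sidecars.
#' @return a `data.frame` with `file`, `pass`, `reason`.
#' @export
validate_inputs <- function(image_dir) {
  tifs <- sort(list.files(image_dir, pattern = "\\.tiff?$",
                          full.names = TRUE))
  if (!length(tifs))
    return(data.frame(file = character(0), pass = logical(0),
                      reason = character(0)))
  rows <- lapply(tifs, function(f) {
    reason <- ""
    ok <- TRUE
    sidecar <- paste0(tools::file_path_sans_ext(f), ".json")
    if (!file.exists(sidecar)) {
      ok <- FALSE; reason <- "missing sidecar"
    } else {
      fld <- tryCatch(read_field_tiff(f), error = function(e) e)
      if (inherits(fld, "error")) {
        ok <- FALSE; reason <- conditionMessage(fld)
      } else {
        shapes <- vapply(fld$channels,
                         function(m) paste(dim(m), collapse = "x"),
                         character(1))
        if (length(unique(shapes)) != 1L) {
          ok <- FALSE
          reason <- sprintf("mixed page shapes: %s",
                            paste(unique(shapes), collapse = " vs "))
        } else if (sum(fld$channel_roles == "dna") != 1L) {
          ok <- FALSE; reason <- "missing dna channel"
        }
      }
    }
    data.frame(file = basename(f), pass = ok, reason = reason)
  })
  do.call(rbind, rows)
}

# condition of a field: ground truth when present, else the field-id stem
field_condition <- function(field_id, truth = NULL) {
  if (!is.null(truth)) {
    hit <- truth$condition[truth$field_id == field_id]
    if (length(hit)) return(hit[1])
  }
  sub("_f[0-9]+$", "", field_id)
}

#' Run the full QIBC pipeline
#'
#' Simulate (optionally) then segment, quantify foci, stage and analyze:
#' per field, background-correct every channel, segment nuclei on the DNA
#' channel, extract per-nucleus features, detect and aggregate foci; then
#' pool all fields, fit DAPI anchors, apply the interphase 2N-4N filter,
#' classify EdU and call phases, normalize the damage metrics to DNA
#' content, and produce 2N/4N group summaries, recruitment ratios and
#' DNA-axis decline profiles per condition. Every table row is traceable
#' to its `(field_id, nucleus_label)`; a rerun with the same configuration
#' and seed reproduces all outputs bit-identically.
#'
#' @param config a [qibc_config()].
#' @return a list: `cells` (the cell table), `foci`, `anchors`,
#'   `summaries`, `ratios`, `profiles`, `report` (stage timings, counts,
#'   thresholds, anchors, seeds, versions). When `config$out_dir` is set,
#'   CSVs and `report.json` are written there too.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qibc_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  image_dir <- config$image_dir
  if (!is.null(config$simulate)) {
    image_dir <- file.path(config$out_dir %||% tempdir(), "images")
    generate_experiment(config$simulate, image_dir, seed = config$seed)
    tick("simulate")
  }
  if (is.null(image_dir)) stopf("config needs 'image_dir' or 'simulate'")
  truth_path <- file.path(image_dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL

  validation <- validate_inputs(image_dir)
  bad <- validation$file[!validation$pass]
  if (length(bad))
    stopf("stage validate failed for: %s", paste(bad, collapse = ", "))
  tick("validate")

  tifs <- sort(list.files(image_dir, pattern = "\\.tiff?$",
                          full.names = TRUE))
  fp <- config$focus
  cells_list <- list(); foci_list <- list()
  for (f in tifs) {
    fld <- read_field_tiff(f)
    roles <- fld$channel_roles
    corrected <- lapply(fld$channels, function(ch)
      correct_background(ch, method = config$background$method %||%
                           "plane_fit",
                         scale = config$background$scale %||% 50))
    names(corrected) <- names(fld$channels)
    dna_name <- names(roles)[roles == "dna"]
    labels <- segment_nuclei(corrected[[dna_name]], config$segmentation)
    if (!is.null(config$out_dir)) {
      mask_dir <- file.path(config$out_dir, "masks")
      dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
      tiff::writeTIFF(labels / 65535,
                      file.path(mask_dir,
                                paste0(fld$field_id, "_labels.tif")),
                      bits.per.sample = 16L)
    }
    nuc <- extract_features(labels, corrected, field_id = fld$field_id)
    names(nuc) <- sub(paste0("_", dna_name, "$"), "_dna", names(nuc))
    if ("focus" %in% roles && nrow(nuc)) {
      focus_name <- names(roles)[roles == "focus"][1]
      resp <- enhance_foci(fld$channels[[focus_name]], labels,
                           spot_scale = fp$spot_scale %||% 1.5,
                           method = fp$method %||% "tophat")
      fr <- detect_foci(resp, labels,
                        threshold_policy = fp$threshold_policy %||%
                          "k_sigma",
                        k = fp$k %||% 5,
                        min_focus_area = fp$min_focus_area %||% 4,
                        field_id = fld$field_id)
      nuc <- aggregate_foci(fr, nuc)
      foci_list[[fld$field_id]] <- fr
    } else if (nrow(nuc)) {
      nuc$focus_count <- NA_integer_
      nuc$foci_total_intensity <- NA_real_
    }
    if (nrow(nuc)) nuc$condition <- field_condition(fld$field_id, truth)
    cells_list[[fld$field_id]] <- nuc
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  foci <- if (length(foci_list)) do.call(rbind, foci_list) else NULL
  if (!is.null(foci)) rownames(foci) <- NULL
  has_foci <- !is.null(foci)
  if (!has_foci)
    warnf("no focus channel: analysis restricted to nuclear intensities")
  tick("segment_quantify")

  anchors <- fit_dapi_anchors(cells$total_dna)
  cells <- filter_interphase(cells, anchors, audit = config$audit)
  analysed <- cells[!cells$excluded, , drop = FALSE]
  has_edu <- "mean_edu" %in% names(analysed)
  if (has_edu) analysed <- classify_edu(analysed)
  analysed <- call_phase(analysed, anchors, config$staging)
  tick("stage")

  metrics <- intersect(config$metrics,
                       names(analysed)[colSums(!is.na(analysed)) > 0])
  exponents <- list()
  for (m in metrics) {
    analysed <- normalize_to_dna(analysed, m)
    exponents[[m]] <- attr(analysed, paste0("scale_exponent_", m))
  }
  gates <- dna_content_gates(anchors)
  conds <- unique(analysed$condition)
  summaries <- list(); ratios <- list(); profiles <- list()
  boot_i <- 0L
  for (cond in conds) {
    sub <- analysed[analysed$condition == cond, , drop = FALSE]
    g2n <- apply_gate(sub, gates$gate_2n)$cells
    g4n <- apply_gate(sub, gates$gate_4n)$cells
    for (m in metrics) {
      nm <- paste0("norm_", m)
      key <- paste(cond, m, sep = ".")
      summaries[[key]] <- cbind(condition = cond, metric = m,
                                summarize_groups(rbind(g2n, g4n), "gate", m))
      boot_i <- boot_i + 1L
      rr_raw <- recruitment_ratio(g4n[[m]], g2n[[m]],
                                  seed = derive_seed(config$seed,
                                                     1000L + boot_i))
      boot_i <- boot_i + 1L
      rr_norm <- recruitment_ratio(g4n[[nm]], g2n[[nm]],
                                   seed = derive_seed(config$seed,
                                                      1000L + boot_i))
      ratios[[key]] <- data.frame(condition = cond, metric = m,
                                  raw_4n_over_2n = rr_raw$ratio,
                                  raw_ci_lo = rr_raw$ci_lo,
                                  raw_ci_hi = rr_raw$ci_hi,
                                  norm_4n_over_2n = rr_norm$ratio,
                                  norm_ci_lo = rr_norm$ci_lo,
                                  norm_ci_hi = rr_norm$ci_hi)
      pr <- tryCatch(decline_profile(sub, nm, n_bins = config$n_bins,
                                     anchors = anchors),
                     error = function(e) {
                       warnf("decline profile skipped for %s/%s: %s",
                             cond, m, conditionMessage(e))
                       NULL
                     })
      if (!is.null(pr))
        profiles[[key]] <- cbind(condition = cond, metric = m, pr,
                                 spearman_rho = attr(pr, "spearman_rho"))
    }
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else NULL
  ratios <- if (length(ratios)) do.call(rbind, ratios) else NULL
  profiles <- if (length(profiles)) do.call(rbind, profiles) else NULL
  if (!is.null(summaries)) rownames(summaries) <- NULL
  if (!is.null(ratios)) rownames(ratios) <- NULL
  if (!is.null(profiles)) rownames(profiles) <- NULL
  tick("analyze")

  report <- list(seed = config$seed,
                 n_fields = length(tifs),
                 n_cells_segmented = nrow(cells),
                 n_cells_interphase = nrow(analysed),
                 anchors = list(anchor_2n = anchors$anchor_2n,
                                anchor_4n = anchors$anchor_4n,
                                ratio = anchors$anchor_4n /
                                  anchors$anchor_2n,
                                valid_range = anchors$valid_range),
                 edu_log_threshold = attr(analysed, "edu_log_threshold"),
                 scale_exponents = exponents,
                 timings_s = as.list(timings),
                 r_version = as.character(getRversion()),
                 package_version = as.character(
                   utils::packageVersion("qibcr")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(analysed, file.path(config$out_dir, "cells.csv"),
              row.names = FALSE)
    if (has_foci)
      write.csv(foci, file.path(config$out_dir, "foci.csv"),
                row.names = FALSE)
    if (!is.null(summaries))
      write.csv(summaries, file.path(config$out_dir, "group_summary.csv"),
                row.names = FALSE)
    if (!is.null(profiles))
      write.csv(profiles, file.path(config$out_dir,
                                    "decline_profiles.csv"),
                row.names = FALSE)
    if (!is.null(ratios))
      write.csv(ratios, file.path(config$out_dir,
                                  "recruitment_ratios.csv"),
                row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cells = analysed, all_cells = cells, foci = foci, anchors = anchors,
       summaries = summaries, ratios = ratios, profiles = profiles,
       validation = validation, report = report)
}
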