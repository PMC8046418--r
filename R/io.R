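#' Write a multi-channel field as TIFF plus JSON sidecar
#'
#' One TIFF page per channel, 16-bit (or the field's depth); channel roles,
#' page order, pixel depth and field id go to `<path>.json`.
#'
#' @param field a `qibc_field` object.
#' @param path output TIFF path (sidecar written next to it).
#' @return invisibly, the sidecar path.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "qibc_field"))
  max_val <- 2^field$pixel_depth - 1
  pages <- lapply(field$channels, function(m) m / max_val)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(field_id = field$field_id,
         pixel_depth = field$pixel_depth,
         channel_roles = as.list(field$channel_roles),
         page_order = names(field$channels)),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Read a multi-channel field written by [write_field_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return a `qibc_field` object with counts on the original scale.
#' @export
read_field_tiff <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stopf("missing channel-role sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  max_val <- 2^meta$pixel_depth - 1
  ch <- lapply(pages, function(p) round(p * max_val))
  names(ch) <- meta$page_order
  structure(list(channels = ch,
                 channel_roles = unlist(meta$channel_roles),
                 pixel_depth = meta$pixel_depth,
                 field_id = meta$field_id),
            class = "qibc_field")
}

#' Generate a complete synthetic QIBC experiment on disk
#'
#' Samples per-condition populations, renders every field, and writes the
#' TIFF images with sidecars, a single ground-truth CSV and a JSON manifest
#' echoing the configuration and master seed. Per-field seeds are derived
#' deterministically from the master seed so identical configurations
#' reproduce identical datasets.
#'
#' @param config list with elements `conditions` (character vector),
#'   `n_fields` (fields per condition), `cells_per_field`,
#'   `phase_fractions`, `image_shape`, `marker` (focus marker),
#'   `channels` (roles to render, default all five),
#'   `min_cells_per_condition` (default 1000, mirroring large-cohort
#'   acquisition), plus optional `render`, `noise`, `psf_sigma`,
#'   `focus` overrides.
#' @param out_dir output directory, created if needed.
#' @param seed master seed.
#' @return the manifest, invisibly; side effect: files under `out_dir`.
#' @export
generate_experiment <- function(config, out_dir, seed = 1L) {
  conds <- config$conditions %||% "control"
  n_fields <- config$n_fields %||% 5L
  cpf <- config$cells_per_field %||% 200L
  if (length(conds) < 1 || n_fields < 1)
    stopf("config must name at least one condition and one field")
  min_cells <- config$min_cells_per_condition %||% 1000L
  if (n_fields * cpf < min_cells)
    stopf("%d fields x %d cells = %d cells/condition, below the configured minimum of %d",
          n_fields, cpf, n_fields * cpf, min_cells)
  fractions <- config$phase_fractions %||% c(G1 = 0.5, S = 0.3, G2 = 0.2)
  shape <- config$image_shape %||% c(1024, 1024)
  marker <- config$marker %||% "53BP1"
  channels <- config$channels %||% c("dna", "edu", "cyclinA", "focus",
                                     "h4k20me2")
  rp <- do.call(render_params, config$render %||% list())
  noise <- config$noise %||% list(gaussian_sd = 10, background_level = 100)
  psf <- config$psf_sigma %||% 1
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)

  files <- character(0)
  truth_all <- list()
  idx <- 0L
  for (cond in conds) {
    fp <- do.call(focus_model_params,
                  c(list(marker = marker, condition = cond),
                    config$focus %||% list()))
    for (f in seq_len(n_fields)) {
      idx <- idx + 1L
      fid <- sprintf("%s_f%03d", cond, f)
      pop <- sample_population(cpf, fractions, cond,
                               seed = derive_seed(seed, 2L * idx))
      fld <- render_field(pop, image_shape = shape, focus_params = fp,
                          channels = channels,
                          psf_sigma = psf, noise = noise, params = rp,
                          field_id = fid,
                          seed = derive_seed(seed, 2L * idx + 1L))
      fname <- file.path(out_dir, paste0(fid, ".tif"))
      write_field_tiff(fld$image, fname)
      files <- c(files, fname)
      truth_all[[idx]] <- fld$truth
    }
  }
  truth <- do.call(rbind, truth_all)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  write.csv(truth, truth_path, row.names = FALSE)
  manifest <- list(master_seed = as.integer(seed),
                   config = config,
                   files = basename(files),
                   ground_truth = basename(truth_path),
                   n_cells_total = nrow(truth),
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("qibcr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
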