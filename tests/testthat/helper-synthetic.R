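# shared fixture builders; everything is generated in code, seeded

# cache for expensive simulated runs shared across test files
.qibc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.qibc_cache[[key]])) .qibc_cache[[key]] <- force(expr)
  .qibc_cache[[key]]
}

# a moderate full-channel pipeline run (control + siBRCA1, 53BP1) reused by
# staging/normalization tests; ~400 cells per condition
test_run_full <- function() {
  cached("run_full", {
    out <- file.path(tempdir(), "qibcr_test_run_full")
    unlink(out, recursive = TRUE)
    cfg <- qibc_config(
      simulate = list(conditions = c("control", "siBRCA1"), n_fields = 5,
                      cells_per_field = 50, image_shape = c(1024, 1024),
                      marker = "53BP1", min_cells_per_condition = 250),
      out_dir = out, seed = 42)
    res <- suppressWarnings(run_pipeline(cfg))
    res$truth <- utils::read.csv(file.path(out, "images",
                                           "ground_truth.csv"))
    res$out_dir <- out
    res
  })
}

# match pipeline cells to ground-truth rows by field and nearest centroid
match_truth <- function(cells, truth, max_dist = Inf) {
  idx <- integer(nrow(cells))
  dist <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tt <- which(truth$field_id == cells$field_id[i])
    d2 <- (truth$centroid_row[tt] - cells$centroid_row[i])^2 +
      (truth$centroid_col[tt] - cells$centroid_col[i])^2
    j <- which.min(d2)
    idx[i] <- tt[j]
    dist[i] <- sqrt(d2[j])
  }
  idx[dist > max_dist] <- NA_integer_
  list(idx = idx, dist = dist)
}

# one rendered field with defaults, cached
test_field <- function(n = 20, seed = 7, shape = c(768, 768), ...) {
  key <- paste0("field_", n, "_", seed, "_", paste(shape, collapse = "x"))
  cached(key, {
    st <- sample_population(n, seed = seed)
    render_field(st, image_shape = shape, seed = seed + 1000L, ...)
  })
}

# a synthetic label mask: one elliptical nucleus per entry of `centers`
make_label_mask <- function(shape, centers, radius) {
  m <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    rr <- pmax(1, floor(centers[i, 1] - radius)):
      pmin(shape[1], ceiling(centers[i, 1] + radius))
    cc <- pmax(1, floor(centers[i, 2] - radius)):
      pmin(shape[2], ceiling(centers[i, 2] + radius))
    q <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
    blk <- m[rr, cc]
    blk[q < radius^2] <- i
    m[rr, cc] <- blk
  }
  m
}

# render a Gaussian spot into a matrix (analytic integral = 2*pi*sigma^2*A)
add_spot <- function(m, row, col, amplitude, sigma) {
  rr <- seq_len(nrow(m)); cc <- seq_len(ncol(m))
  m + amplitude * outer(exp(-(rr - row)^2 / (2 * sigma^2)),
                        exp(-(cc - col)^2 / (2 * sigma^2)))
}
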