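# brute-force pixel-loop oracle for per-label features
oracle_features <- function(labels, channels) {
  labs <- sort(unique(labels[labels > 0]))
  out <- list()
  for (l in labs) {
    area <- 0; sr <- 0; sc <- 0
    tot <- setNames(numeric(length(channels)), names(channels))
    for (r in seq_len(nrow(labels))) for (c_ in seq_len(ncol(labels))) {
      if (labels[r, c_] == l) {
        area <- area + 1; sr <- sr + r; sc <- sc + c_
        for (ch in names(channels))
          tot[[ch]] <- tot[[ch]] + channels[[ch]][r, c_]
      }
    }
    out[[as.character(l)]] <- list(label = l, area = area,
                                   centroid = c(sr, sc) / area,
                                   totals = tot)
  }
  out
}

test_that("planted non-touching nuclei are recovered one-to-one", {
  fld <- test_field(20, seed = 7)
  corr <- correct_background(fld$image$channels$dna, "plane_fit")
  labels <- segment_nuclei(corr)
  expect_equal(max(labels), 20L)
  feats <- extract_features(labels, fld$image)
  m <- match_truth(feats, fld$truth)
  expect_true(all(m$dist <= 3))
  expect_equal(sort(unique(m$idx)), seq_len(20))
  # area within 15% of the planted footprint
  expect_true(all(abs(feats$area / fld$truth$nucleus_area_px[m$idx] - 1)
                  <= 0.15))
})

test_that("an empty raster yields an empty labeling, not an error", {
  expect_equal(max(segment_nuclei(matrix(0, 200, 200))), 0)
  expect_equal(nrow(extract_features(matrix(0L, 50, 50),
                                     list(dna = matrix(0, 50, 50)))), 0L)
})

test_that("touching nuclei split under the watershed flag", {
  m <- matrix(0, 200, 200)
  rr <- row(m); cc <- col(m)
  dumb <- (sqrt((rr - 100)^2 + (cc - 80)^2) < 28) |
    (sqrt((rr - 100)^2 + (cc - 130)^2) < 28)
  m[dumb] <- 1000
  p <- list(min_area = 500, max_area = 10000)
  expect_equal(max(segment_nuclei(m, c(p, split_touching = TRUE))), 2L)
  expect_equal(max(segment_nuclei(m, c(p, split_touching = FALSE))), 1L)
})

test_that("size and border filters drop out-of-range and truncated objects", {
  m <- matrix(0, 300, 300)
  rr <- row(m); cc <- col(m)
  m[sqrt((rr - 150)^2 + (cc - 150)^2) < 40] <- 1000  # good nucleus
  m[sqrt((rr - 60)^2 + (cc - 60)^2) < 8] <- 1000     # debris, too small
  m[sqrt((rr - 2)^2 + (cc - 250)^2) < 40] <- 1000    # border-touching
  lab <- segment_nuclei(m, list(min_area = 1000, max_area = 10000,
                                border_policy = "exclude"))
  expect_equal(max(lab), 1L)
  lab2 <- segment_nuclei(m, list(min_area = 1000, max_area = 10000,
                                 border_policy = "flag"))
  expect_equal(max(lab2), 2L)
  feats <- extract_features(lab2, list(dna = m))
  expect_equal(sum(feats$touches_border), 1L)
})

test_that("labels are disjoint and contiguous after filtering", {
  fld <- test_field(20, seed = 7)
  corr <- correct_background(fld$image$channels$dna, "plane_fit")
  labels <- segment_nuclei(corr)
  present <- sort(unique(labels[labels > 0]))
  expect_equal(present, seq_len(max(labels)))
})

test_that("feature extraction matches a constant-region hand computation", {
  lab <- make_label_mask(c(100, 100), cbind(50, 50), 20)
  ch <- list(dna = matrix(7.5, 100, 100))
  f <- extract_features(lab, ch)
  expect_equal(f$total_dna, sum(lab > 0) * 7.5)
  expect_equal(f$mean_dna, 7.5)
})

test_that("feature extraction equals the brute-force pixel loop", {
  set.seed(11)
  lab <- make_label_mask(c(120, 120),
                         cbind(c(30, 80, 60), c(30, 40, 95)), 14)
  channels <- list(dna = matrix(runif(120 * 120, 0, 1000), 120, 120),
                   focus = matrix(runif(120 * 120, 0, 50), 120, 120))
  f <- extract_features(lab, channels)
  oo <- oracle_features(lab, channels)
  for (i in seq_len(nrow(f))) {
    o <- oo[[as.character(f$nucleus_label[i])]]
    expect_equal(f$area[i], o$area)
    expect_equal(c(f$centroid_row[i], f$centroid_col[i]), o$centroid)
    expect_equal(f$total_dna[i], o$totals[["dna"]])
    expect_equal(f$total_focus[i], o$totals[["focus"]])
  }
  # total = mean * area identity
  expect_equal(f$total_dna, f$mean_dna * f$area)
})

test_that("a noiseless G2 nucleus carries twice the G1 DNA signal", {
  st <- rbind(sample_population(1, c(G1 = 1, S = 0, G2 = 0), seed = 5,
                                dna_cv = 0),
              sample_population(1, c(G1 = 0, S = 0, G2 = 1), seed = 6,
                                dna_cv = 0))
  st$cell_id <- 1:2
  fld <- render_field(st, image_shape = c(384, 384), channels = "dna",
                      noise = list(gaussian_sd = 0, background_level = 0),
                      seed = 4)
  lab <- segment_nuclei(fld$image$channels$dna)
  f <- extract_features(lab, fld$image)
  expect_equal(nrow(f), 2L)
  expect_equal(max(f$total_dna) / min(f$total_dna), 2, tolerance = 0.02)
})

test_that("measured total DAPI tracks true DNA content tightly", {
  fld <- test_field(20, seed = 7)
  corr <- correct_background(fld$image$channels$dna, "plane_fit")
  labels <- segment_nuclei(corr)
  feats <- extract_features(labels, list(dna = corr),
                            field_id = fld$image$field_id)
  m <- match_truth(feats, fld$truth)
  expect_gt(cor(feats$total_dna, fld$truth$dna_content[m$idx]), 0.98)
})

test_that("shape mismatches are rejected", {
  expect_error(extract_features(matrix(0L, 10, 10),
                                list(dna = matrix(0, 20, 20))),
               "shape")
})
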