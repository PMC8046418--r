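test_that("flat nuclear signal produces no foci", {
  lab <- make_label_mask(c(128, 128), cbind(64, 64), 30)
  ch <- matrix(100, 128, 128)
  ch[lab > 0] <- 400  # uniform pan-nuclear signal, no spots
  resp <- enhance_foci(ch, lab, spot_scale = 1.5)
  foci <- detect_foci(resp, lab)
  expect_equal(nrow(foci), 0L)
})

test_that("a single planted spot is found at its true position", {
  set.seed(1)
  lab <- make_label_mask(c(128, 128), cbind(64, 64), 30)
  ch <- matrix(100 + rnorm(128 * 128, 0, 5), 128, 128)
  ch[lab > 0] <- ch[lab > 0] + 150
  ch <- add_spot(ch, 60.2, 70.4, amplitude = 2000, sigma = 1.2)
  ch <- qibcr:::gaussian_blur(ch, 1)  # optical blur, as any real image
  for (method in c("tophat", "log")) {
    resp <- enhance_foci(ch, lab, spot_scale = 1.5, method = method)
    peak <- which(resp == max(resp), arr.ind = TRUE)[1, ]
    expect_lt(sqrt((peak[1] - 60.2)^2 + (peak[2] - 70.4)^2), 1.5)
    foci <- detect_foci(resp, lab)
    expect_equal(nrow(foci), 1L)
    expect_equal(foci$nucleus_label, 1L)
  }
})

test_that("spot intensity survives enhancement on a sloped background", {
  set.seed(2)
  lab <- make_label_mask(c(128, 128), cbind(64, 64), 34)
  slope <- outer(seq_len(128) * 0.5, seq_len(128) * 0.2, "+")
  ch <- matrix(100 + rnorm(128 * 128, 0, 3), 128, 128) + slope
  ch <- add_spot(ch, 64, 64, amplitude = 2000, sigma = 1.2)
  ch <- qibcr:::gaussian_blur(ch, 1)
  # structuring radius comfortably above the blurred spot core so the
  # opening removes only background, not spot mass
  resp <- enhance_foci(ch, lab, spot_scale = 3)
  foci <- detect_foci(resp, lab)
  expect_equal(nrow(foci), 1L)
  analytic <- 2000 * 2 * pi * 1.2^2
  expect_equal(foci$total_intensity, analytic, tolerance = 0.1)
})

test_that("planted per-nucleus counts {0,3,7} are recovered exactly", {
  set.seed(3)
  lab <- make_label_mask(c(200, 200),
                         cbind(c(50, 100, 150), c(50, 120, 60)), 24)
  ch <- matrix(100 + rnorm(200 * 200, 0, 5), 200, 200)
  ch[lab > 0] <- ch[lab > 0] + 150
  # resolvable spots: pairwise separations comfortably above one blurred
  # spot diameter
  spots2 <- list(c(100, 129), c(100, 111), c(109, 120))
  th6 <- seq(0, 2 * pi, length.out = 7)[-7]
  spots3 <- c(list(c(150, 60)),
              lapply(th6, function(a) c(150 + 11.5 * cos(a),
                                        60 + 11.5 * sin(a))))
  for (s in spots2) ch <- add_spot(ch, s[1], s[2], 2000, 1.2)
  for (s in spots3) ch <- add_spot(ch, s[1], s[2], 2000, 1.2)
  ch <- qibcr:::gaussian_blur(ch, 1)
  resp <- enhance_foci(ch, lab, spot_scale = 1.5)
  foci <- detect_foci(resp, lab)
  agg <- aggregate_foci(foci, extract_features(lab, list(dna = ch)))
  expect_equal(agg$focus_count[order(agg$nucleus_label)], c(0L, 3L, 7L))
})

test_that("an all-zero response yields no records", {
  lab <- make_label_mask(c(64, 64), cbind(32, 32), 15)
  foci <- detect_foci(matrix(0, 64, 64), lab)
  expect_equal(nrow(foci), 0L)
})

test_that("two sub-resolution spots merge into one focus (documented rule)", {
  set.seed(4)
  lab <- make_label_mask(c(128, 128), cbind(64, 64), 30)
  ch <- matrix(100 + rnorm(128 * 128, 0, 5), 128, 128)
  ch[lab > 0] <- ch[lab > 0] + 150
  # separation < 1 spot radius: the merge rule keeps them as one focus
  ch <- add_spot(ch, 64, 64, 2000, 1.5)
  ch <- add_spot(ch, 64, 65.2, 2000, 1.5)
  ch <- qibcr:::gaussian_blur(ch, 1)
  resp <- enhance_foci(ch, lab, spot_scale = 1.5)
  foci <- detect_foci(resp, lab)
  expect_equal(nrow(foci), 1L)
})

test_that("aggregation is additive and conserves counts", {
  nuclei <- data.frame(nucleus_label = 1:2, field_id = "f",
                       area = c(100, 100))
  foci <- data.frame(focus_id = 1:3, nucleus_label = 1L, field_id = "f",
                     centroid_row = 1:3, centroid_col = 1:3,
                     area = 5, total_intensity = c(10, 20, 30))
  agg <- aggregate_foci(foci, nuclei)
  expect_equal(agg$focus_count, c(3L, 0L))
  expect_equal(agg$foci_total_intensity, c(60, 0))
  expect_equal(sum(agg$focus_count), nrow(foci))
})

test_that("an empty focus list zero-fills every nucleus", {
  nuclei <- data.frame(nucleus_label = 1:4, field_id = "f")
  agg <- aggregate_foci(detect_foci(matrix(0, 32, 32),
                                    matrix(0L, 32, 32)), nuclei)
  expect_true(all(agg$focus_count == 0L))
  expect_true(all(agg$foci_total_intensity == 0))
})

test_that("foci referencing unknown nuclei raise a consistency error", {
  nuclei <- data.frame(nucleus_label = 1:2, field_id = "f")
  foci <- data.frame(focus_id = 1L, nucleus_label = 9L, field_id = "f",
                     centroid_row = 1, centroid_col = 1, area = 5,
                     total_intensity = 10)
  expect_error(aggregate_foci(foci, nuclei), "unknown nuclei")
})

test_that("focus centroids lie inside their parent nucleus mask", {
  fld <- test_field(20, seed = 7)
  corr <- correct_background(fld$image$channels$dna, "plane_fit")
  lab <- segment_nuclei(corr)
  resp <- enhance_foci(fld$image$channels$focus, lab, 1.5)
  foci <- detect_foci(resp, lab)
  expect_gt(nrow(foci), 0)
  inside <- vapply(seq_len(nrow(foci)), function(i)
    lab[round(foci$centroid_row[i]), round(foci$centroid_col[i])],
    integer(1))
  expect_equal(inside, foci$nucleus_label)
})

test_that("doubling planted amplitudes doubles accumulated intensity", {
  st <- sample_population(6, seed = 21)
  base <- render_field(st, image_shape = c(512, 512), seed = 31)
  dbl <- render_field(st, image_shape = c(512, 512), seed = 31,
                      params = render_params(
                        focus_amplitude_multiplier = 2))
  get_totals <- function(fld) {
    corr <- correct_background(fld$image$channels$dna, "plane_fit")
    lab <- segment_nuclei(corr)
    resp <- enhance_foci(fld$image$channels$focus, lab, 1.5)
    agg <- aggregate_foci(
      detect_foci(resp, lab, field_id = fld$image$field_id),
      extract_features(lab, fld$image))
    sum(agg$foci_total_intensity)
  }
  expect_equal(get_totals(dbl) / get_totals(base), 2, tolerance = 0.02)
})

test_that("invalid spot scale is rejected", {
  lab <- make_label_mask(c(64, 64), cbind(32, 32), 15)
  expect_error(enhance_foci(matrix(0, 64, 64), lab, spot_scale = 0), "> 0")
})
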