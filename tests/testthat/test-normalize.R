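test_that("proportional damage flattens under DNA-content division", {
  cells <- data.frame(total_dna = c(2, 4), focus_count = c(6, 12))
  out <- normalize_to_dna(cells, "focus_count", scale_exponent = 0)
  expect_equal(out$norm_focus_count, c(3, 3))
})

test_that("zero counts normalize to zero", {
  cells <- data.frame(total_dna = runif(50, 1e5, 2e5),
                      focus_count = 0)
  out <- normalize_to_dna(cells, "focus_count", scale_exponent = 0)
  expect_true(all(out$norm_focus_count == 0))
})

test_that("normalization is homogeneous in the DNA denominator", {
  set.seed(4)
  cells <- data.frame(total_dna = runif(200, 1e5, 4e5),
                      focus_count = rpois(200, 8))
  a <- normalize_to_dna(cells, "focus_count", scale_exponent = 6)
  cells2 <- cells
  cells2$total_dna <- cells2$total_dna * 5
  b <- normalize_to_dna(cells2, "focus_count", scale_exponent = 6)
  expect_equal(b$norm_focus_count, a$norm_focus_count / 5)
})

test_that("the automatic exponent puts the G1 median on a 1-100 scale", {
  set.seed(5)
  cells <- data.frame(total_dna = runif(300, 1e5, 4e5),
                      focus_count = rpois(300, 8),
                      phase = sample(c("G1", "S", "G2"), 300, TRUE))
  out <- normalize_to_dna(cells, "focus_count")
  k <- attr(out, "scale_exponent_focus_count")
  expect_true(is.integer(k))
  g1_med <- median(out$norm_focus_count[out$phase == "G1"])
  expect_gte(g1_med, 1)
  expect_lte(g1_med, 100)
  # smallest such integer: one less undershoots
  expect_lt(g1_med / 10, 1)
})

test_that("non-positive DNA rows are excluded with a warning", {
  cells <- data.frame(total_dna = c(1e5, 0, -2), focus_count = c(5, 5, 5))
  expect_warning(out <- normalize_to_dna(cells, "focus_count", 0),
                 "excluded")
  expect_equal(nrow(out), 1L)
})

test_that("group summaries match hand-computed box statistics", {
  cells <- data.frame(v = c(1, 2, 3, 4, 5), g = "a")
  s <- summarize_groups(cells, "g", "v")
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n_cells, 5L)
  expect_equal(s$whisker_lo, 1)
  expect_equal(s$whisker_hi, 5)
})

test_that("Tukey whiskers stop at 1.5 IQR", {
  cells <- data.frame(v = c(1:10, 100), g = "a")
  s <- summarize_groups(cells, "g", "v")
  expect_lt(s$whisker_hi, 100)
})

test_that("identical groups have recruitment ratio 1", {
  v <- rpois(500, 10)
  r <- recruitment_ratio(v, v, seed = 3)
  expect_equal(r$ratio, 1)
  expect_true(r$ci_lo <= 1 && r$ci_hi >= 1)
})

test_that("bootstrap CIs are reproducible under a fixed seed", {
  set.seed(10)
  a <- rpois(300, 12); b <- rpois(300, 6)
  r1 <- recruitment_ratio(a, b, seed = 77)
  r2 <- recruitment_ratio(a, b, seed = 77)
  expect_identical(r1, r2)
  expect_gt(r1$ratio, 1.5)
})

test_that("a zero denominator is an explicit error", {
  expect_error(recruitment_ratio(rpois(50, 5), rep(0, 50)),
               "undefined ratio")
})

test_that("median and mean ratios agree in direction across conditions", {
  res <- test_run_full()
  g <- dna_content_gates(res$anchors)
  for (cond in unique(res$cells$condition)) {
    sub <- res$cells[res$cells$condition == cond, ]
    v4 <- apply_gate(sub, g$gate_4n)$cells$norm_focus_count
    v2 <- apply_gate(sub, g$gate_2n)$cells$norm_focus_count
    med <- recruitment_ratio(v4, v2, "median", n_boot = 50, seed = 1)
    mn <- recruitment_ratio(v4, v2, "mean", n_boot = 50, seed = 1)
    expect_equal(sign(log(med$ratio)), sign(log(mn$ratio)))
  }
})

test_that("decline profiles detect monotone trends and flag flat ones", {
  set.seed(6)
  n <- 400
  cells <- data.frame(total_dna = runif(n, 1e5, 2e5))
  cells$metric <- 10 - 4e-5 * cells$total_dna + rnorm(n, 0, 0.1)
  pr <- decline_profile(cells, "metric", n_bins = 8)
  expect_lt(attr(pr, "spearman_rho"), -0.8)
  expect_true(attr(pr, "rho_defined"))

  cells$metric <- 5
  pr2 <- decline_profile(cells, "metric", n_bins = 8)
  expect_equal(attr(pr2, "spearman_rho"), 0)
  expect_false(attr(pr2, "rho_defined"))
  expect_true(all(pr2$median_metric == 5))
})

test_that("too few cells for binning errors naming the minimum", {
  cells <- data.frame(total_dna = runif(50), metric = 1)
  expect_error(decline_profile(cells, "metric", n_bins = 8), "160")
})

test_that("equal-count bins have near-equal occupancy", {
  set.seed(8)
  cells <- data.frame(total_dna = rlnorm(800, 12, 0.3),
                      metric = runif(800))
  pr <- decline_profile(cells, "metric", n_bins = 8)
  expect_equal(nrow(pr), 8L)
  expect_lt(diff(range(pr$n)), 3)
  expect_equal(sum(pr$n), 800L)
})
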