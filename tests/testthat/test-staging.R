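make_dapi_mixture <- function(n = 4000, a2 = 1e5, seed = 1) {
  set.seed(seed)
  g1 <- a2 * rlnorm(round(0.5 * n), 0, 0.05)
  g2 <- 2 * a2 * rlnorm(round(0.2 * n), 0, 0.05)
  s <- runif(n - length(g1) - length(g2), a2, 2 * a2)
  c(g1, s, g2)
}

test_that("anchors land on the 2N and 4N modes of a mixed population", {
  x <- make_dapi_mixture(4000, a2 = 1e5)
  a <- fit_dapi_anchors(x)
  expect_equal(a$anchor_2n, 1e5, tolerance = 0.05)
  expect_equal(a$anchor_4n, 2e5, tolerance = 0.05)
  expect_false(a$fallback_4n)
})

test_that("a pure-G1 population falls back to anchor_4n = 2 x anchor_2n", {
  set.seed(2)
  x <- 1e5 * rlnorm(2000, 0, 0.05)
  expect_warning(a <- fit_dapi_anchors(x), "falling back")
  expect_equal(a$anchor_4n, 2 * a$anchor_2n)
  expect_true(a$fallback_4n)
})

test_that("anchors are exactly scale-equivariant", {
  x <- make_dapi_mixture(3000)
  a1 <- fit_dapi_anchors(x)
  a3 <- fit_dapi_anchors(3 * x)
  expect_equal(a3$anchor_2n, 3 * a1$anchor_2n, tolerance = 1e-10)
  expect_equal(a3$anchor_4n, 3 * a1$anchor_4n, tolerance = 1e-10)
})

test_that("degenerate input errors with guidance", {
  expect_error(fit_dapi_anchors(rep(1, 5)), "too few")
})

test_that("the interphase filter removes debris and keeps interior cells", {
  x <- make_dapi_mixture(2000)
  a <- fit_dapi_anchors(x)
  cells <- data.frame(total_dna = c(0.5 * a$anchor_2n,  # debris
                                    a$anchor_2n,        # exactly at 2N
                                    3 * a$anchor_4n))   # doublet
  out <- filter_interphase(cells, a, audit = TRUE)
  expect_equal(out$excluded, c(TRUE, FALSE, TRUE))
  kept <- filter_interphase(cells, a)
  expect_equal(nrow(kept), 1L)
})

test_that("planted out-of-range outliers are recovered by the filter", {
  x <- make_dapi_mixture(4000)
  a <- fit_dapi_anchors(x)
  set.seed(7)
  n_out <- 200
  flag <- rep(FALSE, length(x))
  flag[sample(length(x), n_out)] <- TRUE
  x[flag] <- x[flag] * sample(c(0.3, 3.5), n_out, replace = TRUE)
  out <- filter_interphase(data.frame(total_dna = x), a, audit = TRUE)
  expect_gte(mean(out$excluded[flag]), 0.95)
})

test_that("EdU classification separates a bimodal population", {
  p <- sample_population(5000, seed = 9)
  cells <- data.frame(mean_edu = p$edu_level * 300)
  out <- classify_edu(cells)
  expect_lt(mean(out$edu_positive != (p$phase == "S")), 0.01)
  # scale equivariance: flags unchanged under a global gain change
  out7 <- classify_edu(data.frame(mean_edu = cells$mean_edu * 7))
  expect_identical(out$edu_positive, out7$edu_positive)
})

test_that("a unimodal EdU distribution yields all-negative with warning", {
  set.seed(3)
  cells <- data.frame(mean_edu = 300 * rlnorm(1000, 0, 0.15))
  expect_warning(out <- classify_edu(cells), "unimodal")
  expect_false(any(out$edu_positive))
})

test_that("prototypical cells are staged correctly", {
  x <- make_dapi_mixture(2000)
  a <- fit_dapi_anchors(x)
  cells <- data.frame(
    total_dna = c(a$anchor_2n, a$anchor_4n, 1.5 * a$anchor_2n),
    mean_edu = c(300, 310, 3000),
    mean_cyclinA = c(300, 1800, 900),
    edu_positive = c(FALSE, FALSE, TRUE))
  out <- call_phase(cells, a)
  expect_equal(out$phase, c("G1", "G2", "S"))
  expect_equal(out$staging, rep("full", 3))
})

test_that("phase calls on a rendered population beat 90% accuracy", {
  res <- test_run_full()
  m <- match_truth(res$cells, res$truth)
  expect_gt(mean(res$cells$phase == res$truth$phase[m$idx]), 0.9)
})

test_that("every retained cell receives exactly one phase", {
  res <- test_run_full()
  expect_true(all(res$cells$phase %in% c("G1", "S", "G2", "excluded")))
  expect_equal(sum(table(res$cells$phase)), nrow(res$cells))
})

test_that("late-S cells carry the late_S_early_G2 subphase", {
  res <- test_run_full()
  m <- match_truth(res$cells, res$truth)
  late <- res$truth$phase[m$idx] == "S" & res$truth$s_progress[m$idx] > 2 / 3
  expect_gte(mean(res$cells$subphase[late] == "late_S_early_G2"), 0.8)
})

test_that("phase calls are invariant to a global intensity rescaling", {
  res <- test_run_full()
  cells <- res$cells
  sc <- cells
  for (col in grep("^(total|mean)_", names(cells), value = TRUE))
    sc[[col]] <- sc[[col]] * 5
  a <- fit_dapi_anchors(cells$total_dna)
  a5 <- fit_dapi_anchors(sc$total_dna)
  p1 <- call_phase(classify_edu(cells), a)
  p5 <- call_phase(classify_edu(sc), a5)
  expect_identical(p1$phase, p5$phase)
})

test_that("missing EdU degrades to a flagged coarse staging", {
  x <- make_dapi_mixture(2000)
  a <- fit_dapi_anchors(x)
  cells <- data.frame(total_dna = c(a$anchor_2n, a$anchor_4n))
  expect_warning(out <- call_phase(cells, a), "coarse")
  expect_equal(out$staging, rep("coarse", 2))
  expect_equal(out$phase, c("G1", "G2"))
})
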