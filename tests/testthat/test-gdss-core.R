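make_p <- function(values, mask = NULL) {
  p_value_volume(values, mask, "one")
}

test_that("histogram bins are half-open, conserving, and calibrated", {
  v <- array(0.995, c(10, 10, 1))
  h <- build_histogram(make_p(v))
  expect_equal(h$counts[100], 100)
  expect_equal(sum(h$counts[-100]), 0)
  # boundary values fall in the right-hand bin; p = 1 joins the last bin
  v2 <- array(c(0, 0.01, 0.5, 1), c(2, 2, 1))
  h2 <- build_histogram(make_p(v2))
  expect_equal(which(h2$counts > 0), c(1, 2, 51, 100))
  expect_error(build_histogram(make_p(v), bin_width = 0.03), "divide")
  expect_error(p_value_volume(array(1.2, c(2, 2, 1))), "\\[0, 1\\]")
  # uniform p at N = 1e6: every bin within 5 binomial SDs of 1e4
  set.seed(71)
  u <- array(runif(1e6), c(100, 100, 100))
  hu <- build_histogram(make_p(u))
  expect_equal(sum(hu$counts), 1e6)
  expect_true(all(abs(hu$counts - 1e4) < 5 * sqrt(1e6 * 0.01 * 0.99)))
})

test_that("n0 is the mean count over bins with left edge in [lo, hi)", {
  v <- array(c(rep(0.355, 80), rep(0.365, 100), rep(0.375, 120)),
             c(300, 1, 1))
  h <- build_histogram(make_p(v))
  expect_equal(estimate_n0(h, 0.35, 0.38), 100)
  # default window covers the 15 bins 0.35 .. 0.49
  expect_equal(sum(h$left_edges >= 0.35 - 1e-9 &
                     h$left_edges < 0.5 - 1e-9), 15)
  hu <- build_histogram(make_p(array(runif(4000), c(20, 20, 10))))
  expect_equal(estimate_n0(hu), mean(hu$counts[36:50]))
  expect_error(estimate_n0(h, 0.351, 0.355), "no histogram bin")
})

test_that("initial assignment keeps the n0 most null-like voxels per bin", {
  dims <- c(150, 1, 1)
  pv <- array(0.005, dims)       # all 150 voxels in bin 1
  g <- structure(list(values = array(as.numeric(1:150), dims),
                      mask = array(TRUE, dims), grid = threshold_grid()),
                 class = "geometric_probability_volume")
  p <- make_p(pv)
  h <- build_histogram(p)
  lab <- initial_assignment(h, p, g, n0 = 100)
  expect_equal(n_rejected(lab), 50)
  # the 50 smallest-pH0 voxels (values 1..50) are the rejected ones
  expect_true(all(lab$labels[1:50, 1, 1] == 1L))
  expect_true(all(lab$labels[51:150, 1, 1] == 0L))
  # bins at or under quota reject nothing
  expect_equal(n_rejected(initial_assignment(h, p, g, n0 = 150)), 0)
  # monotonicity: larger n0 never rejects more
  rej <- vapply(c(40, 80, 120, 160), function(n0)
    n_rejected(initial_assignment(h, p, g, n0 = n0)), numeric(1))
  expect_true(all(diff(rej) <= 0))
  # sentinel Inf sorts first (most null-like)
  g$values[1, 1, 1] <- Inf
  lab2 <- initial_assignment(h, p, g, n0 = 100)
  expect_equal(lab2$labels[1, 1, 1], 0L)
})

test_that("bin likelihood statistics use the sample-SD convention", {
  dims <- c(6, 1, 1)
  pv <- array(c(0.011, 0.012, 0.013, 0.01, 0.02, 0.03) / 2, dims)
  pv[] <- c(0.011, 0.012, 0.013, 0.015, 0.016, 0.017)
  p <- make_p(pv)
  h <- build_histogram(p)
  lab <- significance_labeling(array(c(0L, 0L, 0L, 1L, 1L, 1L), dims),
                               array(TRUE, dims), "initial")
  st <- bin_likelihood_stats(lab, p, h)
  expect_equal(st$mu[2, 1], 0.012)
  expect_equal(st$sigma[2, 1], sd(c(0.011, 0.012, 0.013)))
  expect_equal(st$mu[2, 2], 0.016)
  # {0.01, 0.02, 0.03}-style spacing: mean 0.016, sample sd 0.001
  expect_equal(st$sigma[2, 2], 0.001)
  # untouched bins fall back to the midpoint with floored sigma and are
  # flagged empty
  expect_equal(st$mu[50, 1], 0.495)
  expect_equal(st$sigma[50, 1], 1e-6)
  expect_equal(st$empty[50, ], c(1L, 1L))
  expect_equal(st$empty[2, ], c(0L, 0L))
  # single-member group: mu is that p, sigma floored
  lab$labels[5, 1, 1] <- 0L
  lab$labels[6, 1, 1] <- 0L
  st2 <- bin_likelihood_stats(lab, p, h)
  expect_equal(st2$mu[2, 2], 0.015)
  expect_equal(st2$sigma[2, 2], 1e-6)
})

test_that("ICM with gamma = 0 is the per-voxel ML labeling, idempotent", {
  set.seed(4)
  dims <- c(8, 8, 4)
  pv <- array(runif(prod(dims), 0, 0.01), dims)   # all in bin 1
  p <- make_p(pv)
  h <- build_histogram(p)
  lab0 <- significance_labeling(
    array(as.integer(runif(prod(dims)) < 0.4), dims),
    array(TRUE, dims), "initial")
  st <- bin_likelihood_stats(lab0, p, h)
  cfg <- mrf_config(gamma = 0)
  ref <- mrf_refine(lab0, p, st, cfg, h)
  # decoupled limit: label = argmin of the Gaussian negative log-likelihood
  e <- function(y, m, s) (y - m)^2 / (2 * s^2) + 0.5 * log(2 * pi * s^2)
  ml <- ifelse(e(pv, st$mu[1, 2], st$sigma[1, 2]) <
                 e(pv, st$mu[1, 1], st$sigma[1, 1]), 1L, 0L)
  expect_equal(as.vector(ref$labels), as.vector(ml))
  ref2 <- mrf_refine(ref, p, st, cfg, h)
  expect_equal(ref2$labels, ref$labels)
  expect_lte(attr(ref2, "sweeps"), 1 + 1)  # one confirming sweep
})

test_that("an isolated dissenting voxel is flipped by its neighborhood", {
  dims <- c(5, 5, 3)
  pv <- array(0.002, dims)
  p <- make_p(pv)
  h <- build_histogram(p)
  labels <- array(1L, dims)
  labels[3, 3, 2] <- 0L          # lone null voxel, 10 neighbors rejected
  lab0 <- significance_labeling(labels, array(TRUE, dims), "initial")
  st <- bin_likelihood_stats(lab0, p, h)
  ref <- mrf_refine(lab0, p, st, mrf_config(gamma = 0.5), h)
  expect_equal(ref$labels[3, 3, 2], 1L)
  # and symmetrically: a lone rejected voxel in a null sea is removed
  labels2 <- array(0L, dims)
  labels2[3, 3, 2] <- 1L
  lab1 <- significance_labeling(labels2, array(TRUE, dims), "initial")
  st1 <- bin_likelihood_stats(lab1, p, h)
  ref1 <- mrf_refine(lab1, p, st1, mrf_config(gamma = 0.5), h)
  expect_equal(ref1$labels[3, 3, 2], 0L)
})

test_that("ICM energy is non-increasing on random instances", {
  set.seed(12)
  for (rep in 1:20) {
    dims <- c(6, 6, 4)
    pv <- array(runif(prod(dims)), dims)
    p <- make_p(pv)
    h <- build_histogram(p)
    lab0 <- significance_labeling(
      array(as.integer(runif(prod(dims)) < 0.5), dims),
      array(TRUE, dims), "initial")
    st <- bin_likelihood_stats(lab0, p, h)
    ref <- mrf_refine(lab0, p, st, mrf_config(gamma = runif(1, 0, 2)), h)
    en <- attr(ref, "energy")
    expect_true(all(diff(en) <= 1e-6))
  }
})

test_that("labels stay conserved on the mask through every stage", {
  ds <- tiny_cohort(beta1 = 0.1, grid = 20L, radius = 3, fwhm = 2, seed = 6)
  stat <- fit_voxelwise_glm(ds)
  res <- gdss(stat)
  for (lab in list(res$initial, res$labeling)) {
    expect_true(all(lab$labels[lab$mask] %in% c(0L, 1L)))
    expect_true(all(is.na(lab$labels[!lab$mask])))
  }
  expect_equal(sum(res$histogram$counts), sum(stat$mask))
})

test_that("an exactly uniform histogram rejects nothing", {
  dims <- c(10, 10, 10)
  # 10 voxels in every bin, exactly uniform
  pv <- array(rep(seq(0.0005, 0.9995, length.out = 100), each = 10), dims)
  p <- make_p(pv)
  g <- structure(list(values = array(Inf, dims), mask = array(TRUE, dims),
                      grid = threshold_grid()),
                 class = "geometric_probability_volume")
  h <- build_histogram(p)
  n0 <- estimate_n0(h)
  expect_equal(n0, 10)
  lab <- initial_assignment(h, p, g, n0)
  expect_equal(n_rejected(lab), 0)
  st <- bin_likelihood_stats(lab, p, h)
  ref <- mrf_refine(lab, p, st, mrf_config(), h)
  expect_equal(n_rejected(ref), 0)
})

test_that("gdss end-to-end: strong signal is recovered, reports cohere", {
  ds <- tiny_cohort(beta1 = 0.055, grid = 40L, radius = 5, fwhm = 4,
                    seed = 9)
  stat <- fit_voxelwise_glm(ds)
  res <- gdss(stat)
  sc <- score_labeling(res$labeling, ds$truth_mask)
  expect_gt(sc$tpr, 0.99)
  expect_equal(res$report$rejected_refined, n_rejected(res$labeling))
  expect_equal(res$report$n_masked, 40^3)
  expect_true(all(diff(res$report$mrf_energy) <= 1e-6))
})
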