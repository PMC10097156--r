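test_that("single-covariate t matches the closed-form simple-regression t", {
  # hand-computable 5-subject table, one voxel replicated over a tiny grid
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 2.9, 4.2, 4.8, 6.3)
  data <- array(rep(y, each = 8), c(2, 2, 2, 5))
  stat <- fit_voxelwise_glm(data, data.frame(x = x), "x")
  # textbook formula: b1 = Sxy/Sxx, t = b1 / sqrt(MSE/Sxx)
  xc <- x - mean(x); yc <- y - mean(y)
  b1 <- sum(xc * yc) / sum(xc^2)
  res <- y - mean(y) - b1 * xc
  t_oracle <- b1 / sqrt(sum(res^2) / 3 / sum(xc^2))
  expect_equal(stat$values[1, 1, 1], t_oracle, tolerance = 1e-12)
  expect_equal(stat$df, 3)
  # cross-check against lm()
  expect_equal(t_oracle, summary(lm(y ~ x))$coefficients[2, 3],
               tolerance = 1e-12)
})

test_that("noise-free data gives numerically infinite statistics", {
  ds <- local({
    cfg <- synthetic_config(grid_dims = rep(7L, 3), n_subjects = 10,
                            beta1 = 0.05, noise_sd = 0,
                            regions = list(list(center = c(4, 4, 4),
                                                radius = 2)),
                            fwhm = 0, seed = 5)
    simulate_cohort(cfg)
  })
  expect_warning(stat <- fit_voxelwise_glm(ds), "zero-variance")
  expect_gt(abs(stat$values[4, 4, 4]), 1e6)
  # voxels constant across subjects (outside the sphere) are dropped
  expect_false(stat$mask[1, 1, 1])
  expect_equal(stat$values[1, 1, 1], 0)
})

test_that("rank-deficient designs and bad shapes error", {
  expect_error(design_matrix(data.frame(a = 1:4, b = 2 * (1:4)), "a"),
               "rank deficient")
  expect_error(design_matrix(data.frame(a = 1:4), "missing"), "not found")
  data <- array(rnorm(8 * 5), c(2, 2, 2, 5))
  expect_error(fit_voxelwise_glm(data, data.frame(x = 1:4), "x"), "5 subjects")
})

test_that("null data yields central-t statistics and calibrated p-values", {
  ds <- local({
    cfg <- synthetic_config(grid_dims = rep(16L, 3), n_subjects = 50,
                            fwhm = 0, seed = 31)
    simulate_cohort(cfg)
  })
  stat <- fit_voxelwise_glm(ds)
  expect_equal(stat$df, 48)
  ks <- ks.test(as.vector(stat$values), pt, df = 48)
  expect_gt(ks$p.value, 0.01)
  p <- one_sided_p(stat)
  frac <- mean(p$values < 0.05)
  nvox <- length(p$values)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nvox) + 0.005)
})

test_that("one_sided_p is the upper tail and is strictly decreasing", {
  tv <- array(c(-2, 0, 1.68, 5, 30, -30, 2, 3), c(2, 2, 2))
  stat <- statistic_volume(tv, df = 48, kind = "t")
  p <- one_sided_p(stat)
  expect_equal(p$values[2, 1, 1], 0.5)
  expect_equal(p$values[1, 2, 1], 0.0497, tolerance = 1e-3)  # t = 1.68
  expect_lt(p$values[1, 1, 2], 1e-6)                          # t = 30
  ord <- order(tv)
  expect_true(all(diff(p$values[ord]) < 0))
  zstat <- statistic_volume(tv, kind = "z")
  expect_equal(one_sided_p(zstat)$values, pnorm(tv, lower.tail = FALSE))
})

test_that("t_to_z preserves the one-sided p-value", {
  tv <- array(seq(-6, 8, length.out = 27), c(3, 3, 3))
  stat <- statistic_volume(tv, df = 48, kind = "t")
  z <- t_to_z(stat)
  expect_equal(z$kind, "z")
  expect_equal(one_sided_p(z)$values, one_sided_p(stat)$values,
               tolerance = 1e-12)
  expect_equal(t_to_z(statistic_volume(array(0, c(1, 1, 2)), df = 10,
                                       kind = "t"))$values[1],
               0, tolerance = 1e-12)
  # asymptotic identity at large df
  big <- statistic_volume(array(2, c(1, 1, 2)), df = 1000, kind = "t")
  expect_lt(abs(t_to_z(big)$values[1] - 2), 0.01)
  # monotone in t
  expect_true(all(diff(z$values[order(tv)]) > 0))
})

test_that("analytic power has the textbook limits and monotonicities", {
  expect_equal(analytic_power(0, n = 50, alpha = 0.05), 0.05,
               tolerance = 1e-6)
  pw <- vapply(seq(0.005, 0.055, by = 0.01), analytic_power, numeric(1))
  expect_true(all(diff(pw) > 0))
  pn <- vapply(c(10, 30, 50, 200), function(n)
    analytic_power(0.05, n = n), numeric(1))
  expect_true(all(diff(pn) > 0))
})

test_that("cohens_d matches the pooled-SD two-group definition", {
  # D = 2t/sqrt(df) equals (m1 - m2) / s_pooled with the population (N)
  # denominator for equal-n groups
  set.seed(8)
  n <- 10
  g <- rep(c(0, 1), each = n)
  data <- array(rnorm(8 * 2 * n), c(2, 2, 2, 2 * n))
  data[, , , g == 1] <- data[, , , g == 1] + 0.8
  stat <- fit_voxelwise_glm(data, data.frame(grp = g), "grp")
  d <- cohens_d(stat)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    y <- data[i, j, k, ]
    m1 <- mean(y[g == 1]); m0 <- mean(y[g == 0])
    ss <- sum((y[g == 1] - m1)^2) + sum((y[g == 0] - m0)^2)
    d_oracle <- (m1 - m0) / sqrt(ss / (2 * n))
    expect_equal(d[i, j, k], d_oracle, tolerance = 1e-6)
  }
  expect_equal(cohens_d(statistic_volume(array(0, c(1, 1, 2)), df = 9,
                                         kind = "t"))[1], 0)
  # strictly increasing in t at fixed df
  tv <- array(seq(-3, 3, length.out = 8), c(2, 2, 2))
  dd <- cohens_d(statistic_volume(tv, df = 20, kind = "t"))
  expect_true(all(diff(dd[order(tv)]) > 0))
})
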