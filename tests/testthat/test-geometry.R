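test_that("smoothness estimation recovers iid derivative variance", {
  set.seed(17)
  v <- array(rnorm(40^3), rep(40L, 3))
  s <- estimate_smoothness(statistic_volume(v, kind = "z"))
  # difference of two iid unit normals has variance 2
  expect_equal(unname(diag(s$deriv_cov)), rep(2, 3), tolerance = 0.05 * 2)
  # shared-minuend differences covary with variance of the common voxel (~1)
  off <- s$deriv_cov[upper.tri(s$deriv_cov)]
  expect_equal(unname(off), rep(1, 3), tolerance = 0.1)
  expect_equal(s$sigma, 1, tolerance = 0.05)
  expect_equal(s$lebesgue_L, 40^3)
  expect_error(estimate_smoothness(array(1, rep(8L, 3))), "constant")
})

test_that("smoothing shrinks lambda_det; scaling is degree-6 homogeneous", {
  set.seed(23)
  noise <- array(rnorm(40^3), rep(40L, 3))
  s2 <- estimate_smoothness(gaussian_smooth(noise, 2))
  s4 <- estimate_smoothness(gaussian_smooth(noise, 4))
  expect_lt(s4$lambda_det, s2$lambda_det)
  s1 <- estimate_smoothness(noise)
  s3 <- estimate_smoothness(3 * noise)
  expect_equal(s3$lambda_det, 3^6 * s1$lambda_det, tolerance = 1e-8)
})

test_that("expected Euler characteristic has its closed-form structure", {
  s <- fixed_smoothness(L = 1e5, lambda_det = 4)
  expect_equal(expected_euler(1, s), 0)
  # closed-form ratio: H2(2) e^{-2} / H2(3) e^{-4.5} = 3 e^{-2} / (8 e^{-4.5})
  expect_equal(expected_euler(2, s) / expected_euler(3, s),
               (3 * exp(-2)) / (8 * exp(-4.5)), tolerance = 1e-12)
  u <- seq(sqrt(3) + 0.01, 7, by = 0.05)
  expect_true(all(diff(expected_euler(u, s)) < 0))
})

test_that("cluster-extent density normalizes and matches its survival", {
  for (beta in c(0.3, 1, 4)) {
    total <- integrate(cluster_size_pmf, 0, Inf, beta = beta, D = 3,
                       rel.tol = 1e-9)
    expect_equal(total$value, 1, tolerance = 1e-6)
    for (k in c(0.5, 2, 10)) {
      cdf <- integrate(cluster_size_pmf, 0, k, beta = beta, D = 3,
                       rel.tol = 1e-9)$value
      expect_equal(exp(-beta * k^(2 / 3)), 1 - cdf, tolerance = 1e-6)
    }
  }
  expect_error(cluster_size_pmf(-1, 1), "positive")
  expect_error(cluster_size_pmf(1, 0), "positive")
  # Gamma(D/2 + 1) = 3 sqrt(pi) / 4 enters beta for D = 3 (exact value)
  expect_equal(beta_param(1, 1, 3), (3 * sqrt(pi) / 4)^(2 / 3),
               tolerance = 1e-12)
})

test_that("conditional exceedance evaluates its closed form", {
  expect_equal(conditional_exceedance(2, 2), 1)
  expect_equal(conditional_exceedance(3, 2), (8 / 3) * exp(-2.5),
               tolerance = 1e-12)
  x <- seq(2, 8, by = 0.05)
  expect_true(all(diff(conditional_exceedance(x, 2)) < 0))
  expect_error(conditional_exceedance(1.5, 2), ">=")
  expect_error(conditional_exceedance(1.2, 1), "exceed 1")
})

test_that("threshold grid validates its prior", {
  g <- threshold_grid()
  expect_length(g$u_values, 46)
  expect_equal(sum(g$prior), 1)
  expect_error(threshold_grid(c(2, 2, 3)), "ascending")
  expect_error(threshold_grid(c(2, 3), prior = c(0.4, 0.4)), "sum to 1")
})

test_that("geometric probability: sentinel, per-threshold ordering, signal", {
  dims <- rep(11L, 3)
  s <- fixed_smoothness(L = prod(dims))
  # nothing above the lowest threshold: all sentinel
  low <- statistic_volume(array(0.5, dims), kind = "z")
  g0 <- geometric_null_probability(low, threshold_grid(), s)
  expect_true(all(is.infinite(g0$values)))
  # two isolated single-voxel spikes at one threshold: the higher peak is
  # less probable under the null
  v <- array(0, dims)
  v[3, 3, 3] <- 3
  v[9, 9, 9] <- 5
  f <- statistic_volume(v, kind = "z")
  one_u <- threshold_grid(u_values = 2.5, prior = 1)
  g1 <- geometric_null_probability(f, one_u, s)
  expect_lt(g1$values[9, 9, 9], g1$values[3, 3, 3])
  expect_true(is.infinite(g1$values[1, 1, 1]))
  # raising a voxel without changing its threshold memberships can only
  # lower its pH0 (every p(x|u) term is decreasing in x)
  va <- v; va[9, 9, 9] <- 5.01   # memberships: u <= 5.0 on the 0.1 ladder
  vb <- v; vb[9, 9, 9] <- 5.09   # same memberships, higher value
  ga <- geometric_null_probability(statistic_volume(va, kind = "z"),
                                   threshold_grid(), s)
  gb <- geometric_null_probability(statistic_volume(vb, kind = "z"),
                                   threshold_grid(), s)
  expect_lt(gb$values[9, 9, 9], ga$values[9, 9, 9])
  # larger clusters are less probable than singletons at the same height
  v3 <- array(0, dims)
  v3[3, 3, 3] <- 3
  v3[7:9, 7:9, 7:9] <- 3
  g3 <- geometric_null_probability(statistic_volume(v3, kind = "z"),
                                   one_u, s)
  expect_lt(g3$values[8, 8, 8], g3$values[3, 3, 3])
  expect_error(geometric_null_probability(
    statistic_volume(v, array(FALSE, dims), kind = "z"),
    threshold_grid(), s), "empty")
})

test_that("pH0 is invariant to cluster relabeling order", {
  set.seed(3)
  v <- array(rnorm(15^3, sd = 1.4), rep(15L, 3))
  s <- fixed_smoothness(L = 15^3)
  f <- statistic_volume(v, kind = "z")
  g1 <- geometric_null_probability(f, threshold_grid(), s)
  # reverse the lattice: clusters are discovered in opposite order, but each
  # voxel must keep its pH0
  vr <- v[15:1, 15:1, 15:1]
  g2 <- geometric_null_probability(statistic_volume(vr, kind = "z"),
                                   threshold_grid(), s)
  expect_equal(g2$values[15:1, 15:1, 15:1], g1$values)
})
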