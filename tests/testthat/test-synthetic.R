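test_that("sphere masks match brute-force lattice enumeration", {
  g <- c(25L, 25L, 25L)
  ctr <- c(13, 13, 13)
  expect_equal(sum(make_sphere_mask(ctr, 0, g)), 1)
  expect_equal(sum(make_sphere_mask(ctr, 1, g)), 7)
  for (r in c(2, 5, 10)) {
    gg <- rep(2L * r + 5L, 3)
    cc <- rep(r + 3, 3)
    expect_equal(sum(make_sphere_mask(cc, r, gg)), oracle_sphere_count(r))
  }
  expect_error(make_sphere_mask(c(2, 13, 13), 5, g), "exceeds")
  expect_error(synthetic_config(grid_dims = g, regions = list(
    list(center = c(24, 13, 13), radius = 5))), "exceeds")
})

test_that("sphere layouts are centered and just touching", {
  g <- c(100L, 100L, 100L)
  one <- sphere_layout("1sphere5", g)
  expect_equal(one[[1]]$center, c(51, 51, 51))
  two <- sphere_layout("2sphere5", g)
  expect_equal(two[[2]]$center[1] - two[[1]]$center[1], 10)
  three <- sphere_layout("3sphere5", g)
  expect_equal(vapply(three, function(r) r$center[1], numeric(1)),
               c(41, 51, 61))
  expect_length(sphere_layout("null", g), 0)
  # just-touching closed balls with centers 2r apart share the tangent voxel
  m1 <- make_sphere_mask(two[[1]]$center, 5, g)
  m2 <- make_sphere_mask(two[[2]]$center, 5, g)
  expect_equal(sum(m1 & m2), 1)
})

test_that("noise-free cohort equals the linear model exactly", {
  gd <- rep(15L, 3)
  cfg <- synthetic_config(grid_dims = gd, n_subjects = 4, beta0 = 0.2,
                          beta1 = 0.01, noise_sd = 0,
                          regions = list(list(center = c(8, 8, 8),
                                              radius = 3)),
                          fwhm = 0, seed = 3)
  ds <- simulate_cohort(cfg)
  tm <- ds$truth_mask
  for (s in seq_len(4)) {
    vol <- ds$data[, , , s]
    expect_equal(unique(vol[!tm]), 0)
    expect_equal(vol[8, 8, 8], 0.2 + 0.01 * ds$ages[s])
  }
})

test_that("null cohorts have the configured noise moments", {
  cfg <- synthetic_config(grid_dims = rep(14L, 3), n_subjects = 50,
                          fwhm = 0, seed = 11)
  ds <- simulate_cohort(cfg)
  expect_equal(dim(ds$data), c(14, 14, 14, 50))
  expect_false(any(ds$truth_mask))
  # across-subject mean ~ 0 everywhere (|mean| < 4 sd/sqrt(n))
  m <- apply(ds$data, 1:3, mean)
  expect_lt(max(abs(m)), 4 / sqrt(50))
  # voxelwise SD ~ 1 within Monte-Carlo error at n = 50
  sds <- apply(ds$data, 1:3, sd)
  expect_equal(mean(sds), 1, tolerance = 0.02)
  expect_gt(min(sds), 0.5)
  expect_lt(max(sds), 1.6)
  # pooled intensities consistent with Normal(0, 1)
  ks <- ks.test(as.vector(ds$data[, , 1:3, ]), "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("gaussian smoothing is a unit-sum, mass-conserving kernel", {
  # unit-sum kernel: a constant field is unchanged wherever the kernel
  # support stays inside the grid (zero padding attenuates the boundary)
  const <- array(2.5, rep(24L, 3))
  sm_const <- gaussian_smooth(const, 4)
  expect_equal(sm_const[9:16, 9:16, 9:16], const[9:16, 9:16, 9:16],
               tolerance = 1e-12)
  expect_lt(sm_const[1, 12, 12], 2.5)
  delta <- array(0, rep(21L, 3))
  delta[11, 11, 11] <- 1
  sm <- gaussian_smooth(delta, 4)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # interior finite-support input: total intensity preserved to truncation
  blob <- array(0, rep(31L, 3))
  blob[14:18, 14:18, 14:18] <- runif(125)
  expect_equal(sum(gaussian_smooth(blob, 4)), sum(blob), tolerance = 1e-6)
  expect_error(gaussian_smooth(const, 0), "positive")
  expect_error(gaussian_smooth(const, -1), "positive")
})

test_that("smoothed white-noise SD equals the discrete kernel sum of squares", {
  w <- oracle_kernel(4)
  expect_equal(smoothed_noise_sd(4), sqrt(sum(w^2)^3), tolerance = 1e-12)
  # the discrete value at FWHM = 4 is about 0.0677 (the published 0.070711
  # corresponds to 1/sqrt(200), not the discrete kernel)
  expect_equal(smoothed_noise_sd(4), 0.06768, tolerance = 1e-4)
  set.seed(21)
  noise <- array(rnorm(40^3), rep(40L, 3))
  sm <- gaussian_smooth(noise, 4)
  core <- sm[11:30, 11:30, 11:30]  # interior, away from zero-padded edges
  expect_equal(sd(core), smoothed_noise_sd(4), tolerance = 0.05)
})

test_that("simulation is deterministic under the seed", {
  cfg <- synthetic_config(grid_dims = rep(10L, 3), n_subjects = 5,
                          beta1 = 0.02,
                          regions = list(list(center = c(5, 5, 5),
                                              radius = 2)),
                          fwhm = 2, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("null batches derive per-dataset seeds and stay signal-free", {
  cfg <- synthetic_config(grid_dims = rep(8L, 3), n_subjects = 4, seed = 7,
                          fwhm = 0)
  b <- simulate_null_batch(3, cfg)
  expect_length(b, 3)
  for (ds in b) expect_false(any(ds$truth_mask))
  expect_identical(b, simulate_null_batch(3, cfg))
  expect_false(identical(b[[1]]$data, b[[2]]$data))
  # member i is regenerable alone from seed + i
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 2L
  expect_identical(simulate_cohort(cfg2), b[[2]])
  cfg_sig <- synthetic_config(grid_dims = rep(8L, 3), n_subjects = 4,
                              regions = list(list(center = c(4, 4, 4),
                                                  radius = 1)))
  expect_error(simulate_null_batch(2, cfg_sig), "no signal regions")
})

test_that("regression slope at sphere centers converges to beta1", {
  gd <- rep(9L, 3)
  cfg <- synthetic_config(grid_dims = gd, n_subjects = 500, beta1 = 0.05,
                          regions = list(list(center = c(5, 5, 5),
                                              radius = 2)),
                          fwhm = 0, seed = 13)
  ds <- simulate_cohort(cfg)
  y <- ds$data[5, 5, 5, ]
  fit <- summary(lm(y ~ ds$ages))
  b1 <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(b1 - 0.05), 3 * se)
})
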