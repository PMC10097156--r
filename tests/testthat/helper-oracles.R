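# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force / enumeration, not by calling the code they check.

# brute-force sphere: triple loop over the bounding cube
oracle_sphere_count <- function(radius) {
  n <- 0L
  for (x in -radius:radius)
    for (y in -radius:radius)
      for (z in -radius:radius)
        if (x^2 + y^2 + z^2 <= radius^2) n <- n + 1L
  n
}

# discrete truncated Gaussian kernel and its sum of squares (per axis)
oracle_kernel <- function(fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  r <- ceiling(4 * sigma)
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w / sum(w)
}

# brute-force step-up FDR: test the inequality at every k explicitly
oracle_fdr <- function(p, q, c_n) {
  n <- length(p)
  ps <- sort(p)
  k <- 0L
  for (i in seq_len(n))
    if (ps[i] <= i * q / (n * c_n)) k <- i
  if (k == 0) rep(FALSE, n) else p <= ps[k]
}

# naive per-rung TFCE (same {v >= h} excursion convention as the transform)
oracle_tfce <- function(v, E = 0.5, H = 2, dh, conn = 26) {
  out <- array(0, dim(v))
  nst <- floor(max(v) / dh)
  for (i in seq_len(nst)) {
    h <- i * dh
    lab <- label_clusters(v, h - 1e-12, conn)
    if (attr(lab, "n_clusters") == 0) next
    sizes <- tabulate(lab[lab > 0])
    sel <- lab > 0
    out[sel] <- out[sel] + sizes[lab[sel]]^E * h^H * dh
  }
  out
}

# small signal cohort used by several end-to-end tests
tiny_cohort <- function(beta1, grid = 32L, radius = 5, fwhm = 4,
                        n_subjects = 50L, seed = 1L) {
  gd <- rep(as.integer(grid), 3)
  ctr <- floor(gd / 2) + 1L
  cfg <- synthetic_config(
    grid_dims = gd, n_subjects = n_subjects, beta1 = beta1,
    regions = list(list(center = ctr, radius = radius)),
    fwhm = fwhm, seed = seed)
  simulate_cohort(cfg)
}

# uniform-width constant smoothness stand-in for geometry tests that need a
# deterministic SmoothnessEstimate
fixed_smoothness <- function(L, lambda_det = 1, sigma = 1) {
  structure(list(lebesgue_L = L, sigma = sigma, lambda_det = lambda_det,
                 deriv_cov = diag(3), D = 3L),
            class = "smoothness_estimate")
}
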