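# Random-field geometry under the null hypothesis.  For a unit-variance
# Gaussian field on a 3D lattice, the expected Euler characteristic of the
# excursion set above u, the cluster-extent distribution, and the peak-height
# conditional exceedance probability combine -- over a ladder of
# cluster-defining thresholds -- into a per-voxel probability pH0 that the
# observed local configuration (cluster extent and voxel height) arose in a
# null field.

#' Threshold grid for the geometric probability
#'
#' Ascending z-score cluster-defining thresholds with a prior over them.  The
#' default is u = 2.0, 2.1, ..., 6.5 (46 values) with a uniform prior.
#'
#' @param u_values ascending thresholds (z-scores).
#' @param prior per-threshold prior probabilities; must be non-negative and
#'   sum to 1.  Default: uniform.
#' @return An object of class `threshold_grid`.
#' @export
threshold_grid <- function(u_values = seq(2.0, 6.5, by = 0.1),
                           prior = NULL) {
  if (is.unsorted(u_values, strictly = TRUE))
    stop("u_values must be strictly ascending")
  if (is.null(prior)) prior <- rep(1 / length(u_values), length(u_values))
  if (length(prior) != length(u_values))
    stop("prior length must match u_values")
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-8)
    stop("prior must be non-negative and sum to 1")
  structure(list(u_values = u_values, prior = prior),
            class = "threshold_grid")
}

#' Estimate field smoothness from first differences
#'
#' Computes, inside the mask, the 3x3 covariance matrix of the three
#' first-order forward differences of the field (the discrete gradient), its
#' determinant `lambda_det`, the field SD `sigma`, and the Lebesgue measure
#' `lebesgue_L` (masked voxel count, unit voxel volume).
#'
#' @param field a `statistic_volume` (z-scaled fields expected downstream) or
#'   a bare 3D array.
#' @param mask optional mask when `field` is a bare array.
#' @return An object of class `smoothness_estimate` with elements
#'   `lebesgue_L`, `sigma`, `lambda_det`, `deriv_cov`, `D`.
#' @export
estimate_smoothness <- function(field, mask = NULL) {
  if (inherits(field, "statistic_volume")) {
    v <- field$values
    mask <- field$mask
  } else {
    v <- field
    if (is.null(mask)) mask <- array(TRUE, dim(v))
  }
  d <- dim(v)
  if (any(d < 2)) stop("mask must span at least 2 voxels along each axis")
  # forward differences; valid where both endpoints are inside the mask
  ix <- seq_len(d[1] - 1); iy <- seq_len(d[2] - 1); iz <- seq_len(d[3] - 1)
  common <- mask[ix, iy, iz, drop = FALSE] &
    mask[ix + 1, iy, iz, drop = FALSE] &
    mask[ix, iy + 1, iz, drop = FALSE] &
    mask[ix, iy, iz + 1, drop = FALSE]
  if (sum(common) < 10) stop("too few interior mask voxels to estimate smoothness")
  base <- v[ix, iy, iz, drop = FALSE]
  G <- cbind(
    (v[ix + 1, iy, iz, drop = FALSE] - base)[common],
    (v[ix, iy + 1, iz, drop = FALSE] - base)[common],
    (v[ix, iy, iz + 1, drop = FALSE] - base)[common])
  dcov <- stats::cov(G)
  ldet <- det(dcov)
  sigma <- sd(v[mask])
  if (!is.finite(ldet) || ldet <= 0 || sigma == 0)
    stop("field is (numerically) constant: derivative covariance is singular")
  structure(list(lebesgue_L = sum(mask), sigma = sigma, lambda_det = ldet,
                 deriv_cov = dcov, D = 3L),
            class = "smoothness_estimate")
}

#' Expected Euler characteristic of the excursion set above u
#'
#' For a smooth Gaussian field of SD `sigma` over a 3D volume:
#' `E(chi_u) = L * (2 pi)^-2 * sigma^-5 * sqrt(|A|) * H2(u / sigma) *
#' exp(-u^2 / (2 sigma^2))` with the probabilists' Hermite polynomial
#' `H2(v) = v^2 - 1`.  At high thresholds this approximates the expected
#' number of suprathreshold clusters.
#'
#' @param u threshold (same scale as the field).
#' @param s a `smoothness_estimate`.
#' @return Expected Euler characteristic (vectorized over `u`).
#' @export
expected_euler <- function(u, s) {
  stopifnot(inherits(s, "smoothness_estimate"))
  if (s$D != 3L) stop("only 3-dimensional fields are supported")
  v <- u / s$sigma
  s$lebesgue_L * (2 * pi)^(-2) * s$sigma^(-5) * sqrt(s$lambda_det) *
    (v^2 - 1) * exp(-u^2 / (2 * s$sigma^2))
}

#' Cluster-extent density in a null field
#'
#' Density of the suprathreshold cluster extent `k` (voxels):
#' `p(k) = (2 beta / D) * k^(2/D - 1) * exp(-beta * k^(2/D))`, which
#' integrates to 1 over k > 0 for any `beta > 0`.
#'
#' @param k cluster extent(s), > 0.
#' @param beta scale parameter, > 0 (see [beta_param()]).
#' @param D field dimensionality (3).
#' @return Density values.
#' @export
cluster_size_pmf <- function(k, beta, D = 3) {
  if (any(k <= 0)) stop("cluster size k must be positive")
  if (beta <= 0) stop("beta must be positive")
  (2 * beta / D) * k^(2 / D - 1) * exp(-beta * k^(2 / D))
}

#' Scale parameter of the cluster-extent density
#'
#' `beta = (Gamma(D/2 + 1) * E(chi_u) / E(N))^(2/D)`, where `E(chi_u)` is the
#' expected Euler characteristic (expected cluster count) and `E(N)` the
#' expected number of suprathreshold voxels.
#'
#' @param e_chi expected Euler characteristic at the threshold.
#' @param e_n expected suprathreshold voxel count at the threshold.
#' @param D field dimensionality (3).
#' @return beta.
#' @export
beta_param <- function(e_chi, e_n, D = 3) {
  if (e_chi <= 0 || e_n <= 0)
    stop("expected cluster and voxel counts must be positive")
  (gamma(D / 2 + 1) * e_chi / e_n)^(2 / D)
}

#' Expected suprathreshold voxel count in a null field
#'
#' Analytic expectation `E(N) = L * (1 - Phi(u / sigma))` for a Gaussian
#' field of SD sigma over L voxels.
#'
#' @param u threshold.
#' @param s a `smoothness_estimate`.
#' @return Expected count (vectorized over `u`).
#' @export
expected_suprathreshold <- function(u, s) {
  stopifnot(inherits(s, "smoothness_estimate"))
  s$lebesgue_L * pnorm(u / s$sigma, lower.tail = FALSE)
}

#' Conditional exceedance probability of a peak height
#'
#' Probability that a unit-variance Gaussian field exceeds `x` given that it
#' exceeds the threshold `u`:
#' `p(x | u) = ((x^2 - 1) / (u^2 - 1)) * exp(-(x^2 - u^2) / 2)`, clipped to
#' `[0, 1]`; equals 1 at `x = u`.
#'
#' @param x observed value(s), `x >= u`.
#' @param u threshold, `u > 1`.
#' @return Probabilities in `[0, 1]`.
#' @export
conditional_exceedance <- function(x, u) {
  if (u <= 1) stop("threshold u must exceed 1")
  if (any(x < u)) stop("x must be >= u")
  p <- ((x^2 - 1) / (u^2 - 1)) * exp(-(x^2 - u^2) / 2)
  pmin(pmax(p, 0), 1)
}

#' Geometric probability of the null hypothesis per voxel
#'
#' For each threshold u in the grid, labels the connected components of the
#' excursion set `{z > u}`; every voxel v inside a component of extent k and
#' with value x contributes `p(C = k | x, u) * p(x | u) * p(u)` to its
#' aggregate pH0.  Voxels never exceeding the lowest threshold exhibit no
#' suprathreshold geometry and receive the sentinel `Inf`, sorting as most
#' null-like downstream.
#'
#' @param field a `statistic_volume` of kind `"z"`.
#' @param grid a `threshold_grid`.
#' @param s a `smoothness_estimate`; its `sigma` is used as the field SD (the
#'   GDSS pipeline fixes it at 1 after z-scaling).
#' @param connectivity cluster connectivity (default 26).
#' @param use_observed_n if `TRUE`, E(N) is the observed suprathreshold count
#'   instead of the analytic null expectation (the default).
#' @return An object of class `geometric_probability_volume` with elements
#'   `values` (3D array; `Inf` sentinel, NA outside the mask), `mask`,
#'   `grid`.
#' @export
geometric_null_probability <- function(field, grid = threshold_grid(),
                                       s = NULL, connectivity = 26L,
                                       use_observed_n = FALSE) {
  stopifnot(inherits(field, "statistic_volume"))
  if (field$kind != "z")
    stop("field must be z-scaled (see t_to_z())")
  stopifnot(inherits(grid, "threshold_grid"))
  if (!any(field$mask)) stop("mask is empty")
  if (is.null(s)) s <- estimate_smoothness(field)
  connectivity <- check_connectivity(connectivity)

  z <- field$values
  z[!field$mask] <- -Inf
  dims <- dim(z)
  acc <- numeric(length(z))
  seen <- logical(length(z))

  for (i in seq_along(grid$u_values)) {
    u <- grid$u_values[i]
    pu <- grid$prior[i]
    labels <- .cc_label(as.double(z), as.integer(dims), as.double(u),
                        connectivity)
    sup <- which(labels > 0L)
    if (length(sup) == 0) next
    sizes <- tabulate(labels[sup])
    e_chi <- expected_euler(u, s)
    if (e_chi <= 0) next
    e_n <- if (use_observed_n) length(sup) else expected_suprathreshold(u, s)
    beta <- beta_param(e_chi, e_n, 3)
    k <- sizes[labels[sup]]
    x <- pmax(z[sup], u)
    contrib <- cluster_size_pmf(k, beta, 3) * conditional_exceedance(x, u) * pu
    acc[sup] <- acc[sup] + contrib
    seen[sup] <- TRUE
  }

  values <- array(Inf, dims)
  values[seen] <- acc[seen]
  values[!field$mask] <- NA_real_
  structure(list(values = values, mask = field$mask, grid = grid,
                 smoothness = s),
            class = "geometric_probability_volume")
}

#' @export
print.geometric_probability_volume <- function(x, ...) {
  nsup <- sum(is.finite(x$values[x$mask]))
  cat(sprintf(
    "geometric_probability_volume: %d of %d masked voxels suprathreshold\n",
    nsup, sum(x$mask)))
  invisible(x)
}
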