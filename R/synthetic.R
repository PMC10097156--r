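# Synthetic-cohort simulator: spherical signal regions whose intensity grows
# linearly with a participant-level covariate (age), iid Gaussian noise, and
# separable Gaussian smoothing.  Every downstream stage of the package is
# testable against these cohorts without any external data.

#' Synthetic cohort configuration
#'
#' Describes one simulated imaging cohort: grid size, number of participants,
#' the age covariate distribution, the linear signal model
#' `y_i = beta0 + beta1 * age_i + eps_i` inside the signal regions, the noise
#' distribution, the spherical signal regions, and the smoothing kernel.
#'
#' Defaults reproduce the simulation regime used throughout the package's
#' benchmarks: ages ~ Normal(20, 2) years, unit-variance Gaussian noise,
#' 50 participants, FWHM 4 voxels.
#'
#' @param grid_dims integer vector of 3 positive lattice dimensions (voxels).
#' @param n_subjects number of participants.
#' @param age_mean,age_sd mean and SD of the age covariate (years); `age_sd`
#'   must be positive.
#' @param beta0 intercept of the signal model (intensity units).
#' @param beta1 intensity change per year of age inside signal regions.
#' @param noise_mean,noise_sd Gaussian noise mean and SD; `noise_sd >= 0`.
#' @param regions list of signal regions, each `list(center = c(x, y, z),
#'   radius = r)` in voxel units; empty list = pure-null cohort.
#' @param fwhm Gaussian smoothing kernel FWHM in voxels; 0 disables smoothing.
#' @param seed integer seed controlling ages and noise.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_dims = c(100L, 100L, 100L),
                             n_subjects = 50L,
                             age_mean = 20, age_sd = 2,
                             beta0 = 0, beta1 = 0,
                             noise_mean = 0, noise_sd = 1,
                             regions = list(),
                             fwhm = 4, seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("grid_dims must be 3 positive integers")
  if (n_subjects < 1L) stop("n_subjects must be positive")
  if (age_sd <= 0) stop("age_sd must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (fwhm < 0) stop("fwhm must be non-negative")
  for (r in regions) {
    if (!is.list(r) || is.null(r$center) || is.null(r$radius))
      stop("each region must be list(center = c(x, y, z), radius = r)")
    if (r$radius < 0) stop("region radius must be non-negative")
    check_region_in_grid(r$center, r$radius, grid_dims)
  }
  structure(list(grid_dims = grid_dims, n_subjects = as.integer(n_subjects),
                 age_mean = age_mean, age_sd = age_sd,
                 beta0 = beta0, beta1 = beta1,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 regions = regions, fwhm = fwhm, seed = as.integer(seed)),
            class = "synthetic_config")
}

check_region_in_grid <- function(center, radius, grid_dims) {
  if (any(center - radius < 1) || any(center + radius > grid_dims))
    stop(sprintf(
      "region at center (%s) with radius %g exceeds the %s grid",
      paste(center, collapse = ","), radius,
      paste(grid_dims, collapse = "x")))
  invisible(TRUE)
}

#' Standard sphere layouts
#'
#' Presets for the benchmark region configurations: one sphere of radius 5,
#' two or three just-touching spheres of radius 5 placed along the first axis
#' (centers 2*radius apart), one sphere of radius 10, or no signal.  All
#' layouts are centered in the grid so that smoothing does not interact with
#' the volume boundary.
#'
#' @param layout one of `"1sphere5"`, `"2sphere5"`, `"3sphere5"`,
#'   `"1sphere10"`, `"null"`.
#' @param grid_dims grid dimensions the spheres are centered in.
#' @return A list of regions suitable for [synthetic_config()].
#' @export
sphere_layout <- function(layout = c("1sphere5", "2sphere5", "3sphere5",
                                     "1sphere10", "null"),
                          grid_dims = c(100L, 100L, 100L)) {
  layout <- match.arg(layout)
  ctr <- floor(grid_dims / 2) + 1L
  mk <- function(offsets, radius)
    lapply(offsets, function(o) list(center = c(ctr[1] + o, ctr[2], ctr[3]),
                                     radius = radius))
  switch(layout,
         "1sphere5"  = mk(0, 5),
         "2sphere5"  = mk(c(-5, 5), 5),
         "3sphere5"  = mk(c(-10, 0, 10), 5),
         "1sphere10" = mk(0, 10),
         "null"      = list())
}

#' Spherical voxel mask
#'
#' All lattice points with squared Euclidean distance to `center` at most
#' `radius^2`.
#'
#' @param center voxel triple (1-based).
#' @param radius sphere radius in voxels (`0` gives the single center voxel).
#' @param grid_dims grid dimensions.
#' @return Logical 3D array.
#' @export
make_sphere_mask <- function(center, radius, grid_dims) {
  grid_dims <- as.integer(grid_dims)
  check_region_in_grid(center, radius, grid_dims)
  dx2 <- (seq_len(grid_dims[1]) - center[1])^2
  dy2 <- (seq_len(grid_dims[2]) - center[2])^2
  dz2 <- (seq_len(grid_dims[3]) - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  d2 <= radius^2
}

#' Ground-truth signal mask for a configuration
#' @param config a `synthetic_config`.
#' @return Logical 3D array, the union of all region spheres.
#' @export
truth_mask <- function(config) {
  m <- array(FALSE, config$grid_dims)
  for (r in config$regions)
    m <- m | make_sphere_mask(r$center, r$radius, config$grid_dims)
  m
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian convolution with kernel SD
#' `sigma = fwhm / sqrt(8 * log(2))`, truncated at 4 sigma and renormalized to
#' unit sum.  The grid is zero-padded: mass leaving the volume is lost, which
#' matches the simulation protocol of centering all signal in the volume.
#'
#' @param volume 3D numeric array.
#' @param fwhm_voxels kernel full width at half maximum, in voxels (> 0).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm_voxels) {
  if (length(dim(volume)) != 3L) stop("`volume` must be a 3D array")
  if (fwhm_voxels <= 0) stop("fwhm_voxels must be positive")
  out <- volume + 0  # force a copy: the C++ routine smooths in place
  .smooth_stack_inplace(out, as.integer(dim(volume)), 1L,
                        as.double(fwhm_voxels))
  out
}

#' Standard deviation of smoothed unit-variance white noise
#'
#' The exact discrete-kernel value `sqrt(sum(w^2))` of the truncated,
#' renormalized 3D kernel: smoothing iid Normal(0, 1) noise yields voxelwise
#' SD equal to this number (about 0.0677 at FWHM = 4 voxels).
#'
#' @param fwhm_voxels kernel FWHM in voxels.
#' @return The voxelwise SD of smoothed unit-variance white noise.
#' @export
smoothed_noise_sd <- function(fwhm_voxels) {
  if (fwhm_voxels <= 0) stop("fwhm_voxels must be positive")
  sigma <- fwhm_voxels / sqrt(8 * log(2))
  r <- ceiling(4 * sigma)
  w <- dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  sqrt(sum(w^2)^3)
}

#' Simulate one synthetic cohort
#'
#' Draws participant ages from Normal(age_mean, age_sd), builds per-subject
#' volumes equal to `beta0 + beta1 * age` inside the signal regions and 0
#' outside, adds iid Normal(noise_mean, noise_sd) noise everywhere, and
#' smooths each volume at the configured FWHM.  The random draws consume one
#' seeded stream in a fixed order (ages first, then noise subject-by-subject),
#' so identical configurations are bitwise reproducible.
#'
#' @param config a `synthetic_config`.
#' @return An object of class `synthetic_dataset` with elements `data` (4D
#'   array, x-y-z-subject), `ages`, `truth_mask`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dims <- config$grid_dims
  n <- config$n_subjects
  nvox <- prod(dims)

  set.seed(config$seed)
  ages <- rnorm(n, config$age_mean, config$age_sd)
  data <- array(rnorm(nvox * n, config$noise_mean, config$noise_sd),
                dim = c(dims, n))
  tm <- truth_mask(config)
  if (any(tm)) {
    sig_idx <- which(tm)  # linear indices within one volume
    for (s in seq_len(n)) {
      data[sig_idx + (s - 1) * nvox] <-
        data[sig_idx + (s - 1) * nvox] +
        config$beta0 + config$beta1 * ages[s]
    }
  }
  if (config$fwhm > 0)
    .smooth_stack_inplace(data, dims, n, as.double(config$fwhm))

  structure(list(data = data, ages = ages, truth_mask = tm, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %s grid, %d subjects, %d signal voxels, fwhm = %g\n",
    paste(x$config$grid_dims, collapse = "x"), x$config$n_subjects,
    sum(x$truth_mask), x$config$fwhm))
  invisible(x)
}

#' Simulate a batch of pure-null cohorts
#'
#' Generates `n_datasets` independent cohorts with no signal regions; the seed
#' of dataset `i` is `config$seed + i`, so any single member can be
#' regenerated without the rest.
#'
#' @param n_datasets number of cohorts.
#' @param config a `synthetic_config` with an empty `regions` list.
#' @return A list of `synthetic_dataset` objects, all with empty truth masks.
#' @export
simulate_null_batch <- function(n_datasets, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$regions) > 0)
    stop("simulate_null_batch requires a configuration with no signal regions")
  lapply(seq_len(n_datasets), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    simulate_cohort(cfg)
  })
}
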