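# The GDSS decision procedure.  The p-value histogram estimates, from its
# flat central region, how many voxels per bin the null hypothesis should
# contribute (n0); in each bin the n0 voxels whose local random-field
# geometry looks most null-like keep the null label and the remainder are
# rejected; a Potts-prior MRF solved by iterated conditional modes then
# removes isolated dissenting voxels to leave contiguous significant regions.

#' P-value histogram
#'
#' Counts of masked p-values over half-open bins `[l, l + w)` (the last bin is
#' closed at 1).
#'
#' @param p a `p_value_volume`.
#' @param bin_width bin width; must divide 1 evenly (default 0.01).
#' @return An object of class `p_value_histogram` with elements `counts`,
#'   `bin_width`, `left_edges`, `bin_index` (3D array of 1-based bin per
#'   voxel, 0 outside the mask), `n_masked`.
#' @export
build_histogram <- function(p, bin_width = 0.01) {
  stopifnot(inherits(p, "p_value_volume"))
  nbins <- round(1 / bin_width)
  if (abs(nbins * bin_width - 1) > 1e-9)
    stop("bin_width must divide 1 evenly")
  idx <- array(0L, dim(p$values))
  pm <- p$values[p$mask]
  idx[p$mask] <- pmin(as.integer(floor(pm / bin_width)), nbins - 1L) + 1L
  counts <- tabulate(idx[p$mask], nbins)
  structure(list(counts = counts, bin_width = bin_width,
                 left_edges = (seq_len(nbins) - 1L) * bin_width,
                 bin_index = idx, n_masked = sum(p$mask)),
            class = "p_value_histogram")
}

#' Estimate the per-bin null count n0
#'
#' Arithmetic mean of the counts of all bins whose left edge lies in
#' `[lo, hi)`.  The default window `[0.35, 0.5)` covers the flat central
#' region of the p-value histogram, where the statistics are expected to
#' follow the (possibly slightly off-center) empirical null.
#'
#' @param hist a `p_value_histogram`.
#' @param lo,hi averaging window over bin left edges.
#' @return The estimated null count per bin (possibly fractional).
#' @export
estimate_n0 <- function(hist, lo = 0.35, hi = 0.5) {
  stopifnot(inherits(hist, "p_value_histogram"))
  sel <- hist$left_edges >= lo - 1e-9 & hist$left_edges < hi - 1e-9
  if (!any(sel)) stop("the [lo, hi) window covers no histogram bin")
  mean(hist$counts[sel])
}

#' Initial null/rejected assignment from the histogram and geometry
#'
#' Per histogram bin: if the bin holds at most n0 voxels they all keep the
#' null label; otherwise the n0 voxels with the largest geometric null
#' probability (the sentinel `Inf` sorting first) stay null and the remainder
#' are rejected.  Ties are broken by linear voxel index, so the assignment is
#' reproducible.  The fractional n0 is rounded to the nearest integer for the
#' per-bin quota.
#'
#' @param hist a `p_value_histogram` built from `p`.
#' @param p the `p_value_volume`.
#' @param g a `geometric_probability_volume` on the same mask.
#' @param n0 the per-bin null count; defaults to [estimate_n0()] of `hist`.
#' @return A `significance_labeling` with `stage = "initial"`.
#' @export
initial_assignment <- function(hist, p, g, n0 = NULL) {
  stopifnot(inherits(hist, "p_value_histogram"),
            inherits(p, "p_value_volume"),
            inherits(g, "geometric_probability_volume"))
  if (!identical(dim(p$values), dim(g$values)) || !identical(p$mask, g$mask))
    stop("p-value and geometric-probability volumes are on different masks")
  if (is.null(n0)) n0 <- estimate_n0(hist)
  quota <- as.integer(round(n0))

  labels <- array(NA_integer_, dim(p$values))
  labels[p$mask] <- 0L
  midx <- which(p$mask)
  bins <- hist$bin_index[midx]
  ph0 <- g$values[midx]
  ord <- split(seq_along(midx), bins)
  for (vox in ord) {
    if (length(vox) <= quota) next
    # order by descending pH0, ties by ascending voxel index
    o <- vox[order(-ph0[vox], vox)]
    rej <- o[-seq_len(quota)]
    labels[midx[rej]] <- 1L
  }
  significance_labeling(labels, p$mask, "initial")
}

#' Per-bin Gaussian likelihood statistics
#'
#' Mean and SD of the p-values of the null-labeled and rejected voxels in
#' each histogram bin (sample SD, n - 1 denominator).  Groups with fewer than
#' two members fall back to the bin midpoint with SD `sigma_floor`; all SDs
#' are floored at `sigma_floor`.
#'
#' @param labeling a `significance_labeling` from [initial_assignment()].
#' @param p the `p_value_volume`.
#' @param hist the `p_value_histogram`.
#' @param sigma_floor lower bound on group SDs (default 1e-6).
#' @return An object of class `bin_likelihood_stats`: matrices `mu`, `sigma`
#'   and `empty` of shape nbins x 2 (columns: null, rejected).  A group
#'   flagged `empty` had no members at initialization; MRF refinement never
#'   moves a voxel into an empty group.
#' @export
bin_likelihood_stats <- function(labeling, p, hist, sigma_floor = 1e-6) {
  stopifnot(inherits(labeling, "significance_labeling"),
            inherits(p, "p_value_volume"),
            inherits(hist, "p_value_histogram"))
  nbins <- length(hist$counts)
  mid <- hist$left_edges + hist$bin_width / 2
  mu <- matrix(rep(mid, 2), ncol = 2)
  sigma <- matrix(sigma_floor, nbins, 2)
  empty <- matrix(1L, nbins, 2)   # no observed members at initialization
  midx <- which(p$mask)
  bins <- hist$bin_index[midx]
  pv <- p$values[midx]
  lab <- labeling$labels[midx]
  for (grp in 0:1) {
    sel <- lab == grp
    if (!any(sel)) next
    bs <- bins[sel]
    m <- tapply(pv[sel], bs, mean)
    s <- tapply(pv[sel], bs, sd)
    bi <- as.integer(names(m))
    mu[bi, grp + 1] <- m
    sg <- ifelse(is.na(s), sigma_floor, pmax(s, sigma_floor))
    sigma[bi, grp + 1] <- sg
    empty[bi, grp + 1] <- 0L
  }
  structure(list(mu = mu, sigma = sigma, empty = empty,
                 sigma_floor = sigma_floor, bin_width = hist$bin_width),
            class = "bin_likelihood_stats")
}

#' MRF configuration
#'
#' Parameters of the Potts-prior MRF used to regularize the initial
#' assignment: the clique potential `gamma` charged per disagreeing neighbor
#' pair, the 10-voxel neighborhood (8 in-slice neighbors plus the co-located
#' voxel in each adjacent slice -- fixed), the maximum number of ICM sweeps,
#' the SD floor of the bin likelihoods, and whether the group statistics are
#' recomputed after each sweep (default: fixed at initialization).
#'
#' @param gamma clique potential per disagreeing pair (>= 0; default 0.5).
#' @param max_sweeps maximum ICM sweeps (>= 1; default 100).
#' @param sigma_floor SD floor for the bin likelihoods.
#' @param recompute_stats recompute group statistics after every sweep.
#' @return An object of class `mrf_config`.
#' @export
mrf_config <- function(gamma = 0.5, max_sweeps = 100L, sigma_floor = 1e-6,
                       recompute_stats = FALSE) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  structure(list(gamma = gamma, max_sweeps = as.integer(max_sweeps),
                 sigma_floor = sigma_floor,
                 recompute_stats = recompute_stats),
            class = "mrf_config")
}

#' MRF/MAP refinement of a significance labeling
#'
#' Iterated conditional modes: each voxel in raster order takes the label
#' minimizing the Gaussian negative log-likelihood of its p-value under its
#' bin's group statistics plus `gamma` times the number of neighbors (10-voxel
#' neighborhood) carrying the opposite label, until a sweep makes no flips or
#' `max_sweeps` is reached.  The total posterior energy is non-increasing
#' across sweeps and is returned as an attribute.
#'
#' @param labeling the initial `significance_labeling`.
#' @param p the `p_value_volume`.
#' @param stats `bin_likelihood_stats` (or `NULL` to compute from `labeling`).
#' @param cfg an `mrf_config`.
#' @param hist the histogram (needed for bin indices; required when `stats`
#'   is `NULL` or `cfg$recompute_stats`).
#' @return A `significance_labeling` with `stage = "mrf_refined"` and
#'   attributes `sweeps` and `energy` (per-sweep total energy trace).
#' @export
mrf_refine <- function(labeling, p, stats = NULL, cfg = mrf_config(),
                       hist = NULL) {
  stopifnot(inherits(labeling, "significance_labeling"),
            inherits(p, "p_value_volume"))
  if (is.null(hist)) hist <- build_histogram(p)
  if (is.null(stats))
    stats <- bin_likelihood_stats(labeling, p, hist, cfg$sigma_floor)

  labels <- labeling$labels
  labels[!labeling$mask] <- 0L
  dims <- dim(labels)

  run_icm <- function(lab, st, sweeps) {
    .icm_refine(as.integer(lab), as.double(p$values),
                as.integer(hist$bin_index), as.logical(labeling$mask),
                as.integer(dims), st$mu, st$sigma, st$empty,
                as.double(cfg$gamma), as.integer(sweeps))
  }

  if (!cfg$recompute_stats) {
    res <- run_icm(labels, stats, cfg$max_sweeps)
    out_labels <- res$labels
    sweeps <- res$sweeps
    energy <- res$energy
  } else {
    out_labels <- labels
    energy <- numeric(0)
    sweeps <- 0L
    cur <- stats
    repeat {
      res <- run_icm(out_labels, cur, 1L)
      sweeps <- sweeps + 1L
      energy <- c(energy, res$energy[length(res$energy)])
      changed <- !identical(res$labels, out_labels)
      out_labels <- res$labels
      if (!changed || sweeps >= cfg$max_sweeps) break
      tmp <- array(out_labels, dims)
      tmp[!labeling$mask] <- NA_integer_
      cur <- bin_likelihood_stats(
        significance_labeling(tmp, labeling$mask, "initial"),
        p, hist, cfg$sigma_floor)
    }
  }

  out <- array(out_labels, dims)
  out[!labeling$mask] <- NA_integer_
  res <- significance_labeling(out, labeling$mask, "mrf_refined")
  attr(res, "sweeps") <- sweeps
  attr(res, "energy") <- energy
  res
}

#' Run the full GDSS procedure
#'
#' Composes the pipeline: t-to-z conversion, smoothness estimation, the
#' geometric null probability aggregated over the threshold grid, the p-value
#' histogram with its n0 estimate, the initial per-bin assignment, and MRF
#' refinement.
#'
#' @param field a `statistic_volume` (t or z).
#' @param p optional `p_value_volume`; computed from `field` when `NULL`.
#' @param grid a `threshold_grid`.
#' @param mrf an `mrf_config`.
#' @param bin_width histogram bin width.
#' @param n0_range length-2 vector, the n0 averaging window.
#' @param connectivity cluster connectivity for the geometry (default 26).
#' @param fix_sigma fix the field SD at 1 for the geometry (the default; the
#'   thresholds are z-scores).
#' @return An object of class `gdss_result`: the refined `labeling`, the
#'   `initial` labeling, `n0`, `histogram`, `geometry`, and a machine-readable
#'   `report` (n0, bin table, rejection counts, MRF sweeps and energy trace).
#' @export
gdss <- function(field, p = NULL, grid = threshold_grid(),
                 mrf = mrf_config(), bin_width = 0.01,
                 n0_range = c(0.35, 0.5), connectivity = 26L,
                 fix_sigma = TRUE) {
  stopifnot(inherits(field, "statistic_volume"))
  if (is.null(p)) p <- one_sided_p(field)
  if (!identical(dim(p$values), dim(field$values)))
    stop("p-value volume and field have different shapes")
  z <- t_to_z(field)
  s <- estimate_smoothness(z)
  if (fix_sigma) s$sigma <- 1
  g <- geometric_null_probability(z, grid, s, connectivity)
  hist <- build_histogram(p, bin_width)
  n0 <- estimate_n0(hist, n0_range[1], n0_range[2])
  initial <- initial_assignment(hist, p, g, n0)
  stats <- bin_likelihood_stats(initial, p, hist, mrf$sigma_floor)
  refined <- mrf_refine(initial, p, stats, mrf, hist)

  report <- list(
    n0 = n0,
    n_masked = hist$n_masked,
    bin_counts = hist$counts,
    rejected_initial = n_rejected(initial),
    rejected_refined = n_rejected(refined),
    mrf_sweeps = attr(refined, "sweeps"),
    mrf_energy = attr(refined, "energy"),
    smoothness = list(lebesgue_L = s$lebesgue_L, sigma = s$sigma,
                      lambda_det = s$lambda_det))
  structure(list(labeling = refined, initial = initial, n0 = n0,
                 histogram = hist, geometry = g, stats = stats,
                 report = report),
            class = "gdss_result")
}

#' @export
print.gdss_result <- function(x, ...) {
  cat(sprintf(
    "gdss_result: n0 = %.1f, rejected %d (initial) -> %d (refined) of %d voxels, %d ICM sweeps\n",
    x$n0, x$report$rejected_initial, x$report$rejected_refined,
    x$report$n_masked, x$report$mrf_sweeps))
  invisible(x)
}
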