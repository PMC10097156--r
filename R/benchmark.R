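# Replication harnesses for the simulation benchmarks: the pure-null FWER
# protocol (many replicate cohorts, every procedure, per-dataset rejection
# counts) and the single-cohort signal-recovery protocol (TPR per procedure
# against the known sphere).

#' Run all procedures on one cohort
#'
#' Fits the voxelwise model, then applies the uncorrected one-sided test and
#' the requested correction procedures, returning one labeling per procedure.
#'
#' @param dataset a `synthetic_dataset` (or 4D array with `covariate`).
#' @param procedures subset of `c("uncorrected", "fdr", "topofdr", "gdss",
#'   "tfce")`.
#' @param alpha uncorrected / TFCE significance level.
#' @param q FDR rate.
#' @param cdt topological-FDR cluster-defining threshold.
#' @param n_perm TFCE permutations.
#' @param seed seed for the TFCE permutation stream.
#' @param covariate per-subject covariate when `dataset` is a bare array.
#' @param mrf GDSS MRF configuration.
#' @param fdr_c_form FDR variant for the voxelwise FDR comparator.  The
#'   benchmarks default to `"bh"`: the reference results this harness
#'   replicates show FDR familywise error near the nominal q under the
#'   global null, which is classical BH behavior (the arbitrary-dependency
#'   BY correction drives it to ~q/log(N)).  Set `"by"` for the
#'   dependency-robust variant.
#' @return Named list of `significance_labeling` objects; the fitted
#'   `statistic_volume` is attached as attribute `stat`.
#' @export
run_procedures <- function(dataset,
                           procedures = c("uncorrected", "fdr", "topofdr",
                                          "gdss", "tfce"),
                           alpha = 0.05, q = 0.05, cdt = 3.0,
                           n_perm = 100L, seed = 1L, covariate = NULL,
                           mrf = mrf_config(), fdr_c_form = "bh") {
  procedures <- match.arg(procedures, several.ok = TRUE)
  stat <- fit_voxelwise_glm(dataset)
  p <- one_sided_p(stat)
  out <- list()
  if ("uncorrected" %in% procedures)
    out$uncorrected <- labeling_from_mask(
      p$values < alpha & p$mask, p$mask)
  if ("fdr" %in% procedures)
    out$fdr <- fdr_labeling(p, q = q, c_form = fdr_c_form)
  if ("topofdr" %in% procedures)
    out$topofdr <- topological_fdr(stat, cdt = cdt, q = q)
  if ("gdss" %in% procedures)
    out$gdss <- gdss(stat, p, mrf = mrf)$labeling
  if ("tfce" %in% procedures)
    out$tfce <- tfce_permutation_test(dataset, n_perm = n_perm,
                                      alpha = alpha, seed = seed,
                                      covariate = covariate)
  attr(out, "stat") <- stat
  out
}

#' Pure-null FWER benchmark
#'
#' Generates `n_datasets` signal-free cohorts (dataset i uses seed
#' `config$seed + i`), applies the requested procedures to each, and records
#' the per-dataset rejection counts.  Datasets are processed one at a time
#' and discarded, so memory stays bounded.
#'
#' @param n_datasets number of replicate null cohorts.
#' @param config a `synthetic_config` with no regions.
#' @param procedures,alpha,q,cdt,n_perm see [run_procedures()].
#' @param max_region_width if not `NULL`, also collect the GDSS rejected
#'   region widths per dataset (see [region_widths()]).
#' @param progress print one line per dataset.
#' @return A list: `counts` (n_datasets x procedures matrix of rejection
#'   counts), `fwer` and `avg_significant` per procedure, and
#'   `gdss_region_widths` (vector) when requested.
#' @export
null_benchmark <- function(n_datasets, config,
                           procedures = c("uncorrected", "fdr", "gdss",
                                          "tfce"),
                           alpha = 0.05, q = 0.05, cdt = 3.0,
                           n_perm = 100L, max_region_width = TRUE,
                           progress = FALSE, fdr_c_form = "bh") {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$regions) > 0)
    stop("null_benchmark requires a signal-free configuration")
  counts <- matrix(NA_real_, n_datasets, length(procedures),
                   dimnames = list(NULL, procedures))
  widths <- integer(0)
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- config$seed + i
    ds <- simulate_cohort(cfg)
    labs <- run_procedures(ds, procedures, alpha = alpha, q = q, cdt = cdt,
                           n_perm = n_perm, seed = cfg$seed + 1000L,
                           fdr_c_form = fdr_c_form)
    counts[i, ] <- vapply(labs[procedures], n_rejected, numeric(1))
    if (isTRUE(max_region_width) && "gdss" %in% procedures)
      widths <- c(widths, region_widths(labs$gdss))
    if (progress)
      message(sprintf("null dataset %d/%d: %s", i, n_datasets,
                      paste(procedures, counts[i, ], collapse = ", ")))
  }
  out <- list(
    counts = counts,
    fwer = apply(counts, 2, fwer_estimate),
    avg_significant = apply(counts, 2, avg_significant))
  if (isTRUE(max_region_width) && "gdss" %in% procedures)
    out$gdss_region_widths <- widths
  out
}

#' Signal-recovery benchmark on one cohort
#'
#' Simulates a cohort with the given sphere layout and slope, runs the
#' requested procedures, and scores each against the ground-truth sphere.
#'
#' @param beta1 covariate slope inside the signal regions.
#' @param layout sphere layout preset (see [sphere_layout()]).
#' @param grid_dims grid dimensions.
#' @param fwhm smoothing kernel FWHM (voxels).
#' @param n_subjects cohort size.
#' @param seed simulation seed.
#' @param procedures,alpha,q,cdt,n_perm see [run_procedures()].
#' @return A list: `tpr` (named vector per procedure), `scores` (full
#'   `evaluation_result` per procedure), `labelings`, `dataset`.
#' @export
signal_benchmark <- function(beta1, layout = "1sphere5",
                             grid_dims = c(100L, 100L, 100L), fwhm = 4,
                             n_subjects = 50L, seed = 1L,
                             procedures = c("uncorrected", "fdr", "topofdr",
                                            "gdss", "tfce"),
                             alpha = 0.05, q = 0.05, cdt = 3.0,
                             n_perm = 100L, fdr_c_form = "bh") {
  cfg <- synthetic_config(grid_dims = grid_dims, n_subjects = n_subjects,
                          beta1 = beta1,
                          regions = sphere_layout(layout, grid_dims),
                          fwhm = fwhm, seed = seed)
  ds <- simulate_cohort(cfg)
  labs <- run_procedures(ds, procedures, alpha = alpha, q = q, cdt = cdt,
                         n_perm = n_perm, seed = seed + 1000L,
                         fdr_c_form = fdr_c_form)
  unc <- labs$uncorrected
  scores <- lapply(labs, score_labeling, truth = ds$truth_mask,
                   uncorrected = unc)
  list(tpr = vapply(scores, function(s) s$tpr, numeric(1)),
       scores = scores, labelings = labs, dataset = ds)
}
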