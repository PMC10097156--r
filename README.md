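# gdss

Multiple-comparisons correction for voxelwise statistical maps on 3D
brain-image lattices.

A mass-univariate analysis fits the same regression at every voxel of an
imaging volume and then has to decide, across ~10⁵–10⁶ correlated tests,
where the null hypothesis is rejected. This package implements the
**geometry-derived statistical significance (GDSS)** procedure, which
augments each voxel's p-value with a probability that its local
random-field geometry — the extent k of the suprathreshold cluster holding
it and its own height x — would arise under the null:

    pH0(x) = Σ_u Σ_C  p(C = k | x, u) · p(x | u) · p(u)

aggregated over cluster-defining thresholds u = 2.0 … 6.5 (z-scores) with a
uniform prior. The p-value histogram's flat central region ([0.35, 0.5))
estimates the per-bin null count n₀; within each bin the n₀ voxels with the
largest pH0 stay null and the rest are rejected; a Potts-prior Markov
random field solved by iterated conditional modes (ICM) then yields
contiguous significant regions. The cluster-extent law
p(k) = (2β/3)·k^(−1/3)·exp(−β k^(2/3)), the expected Euler characteristic
E(χᵤ) = L·(2π)⁻²·√|A|·(u²−1)·e^(−u²/2), and the peak conditional
exceedance p(x|u) = ((x²−1)/(u²−1))·e^(−(x²−u²)/2) are the standard
Gaussian-random-field results for a unit-variance field.

Also included, because GDSS is meaningful only against its competitors:

* `fdr_by()` / `fdr_labeling()` — step-up FDR (Benjamini–Yekutieli c(N) or
  classical BH),
* `topological_fdr()` — FDR over cluster-peak conditional p-values at a
  fixed cluster-defining threshold (default z = 3),
* `tfce_transform()` / `tfce_permutation_test()` — threshold-free cluster
  enhancement (E = 0.5, H = 2) with max-statistic permutation,
* a voxelwise GLM engine (`fit_voxelwise_glm`, `one_sided_p`, `t_to_z`,
  `cohens_d`, `analytic_power`),
* a synthetic-cohort simulator (`synthetic_config`, `simulate_cohort`,
  `simulate_null_batch`, `gaussian_smooth`) generating the benchmark worlds
  (spherical signal regions, age covariate, Gaussian noise, FWHM 2–10
  smoothing),
* an evaluation harness (`score_labeling`, `fwer_estimate`,
  `fit_two_gaussian_mixture`, `estimated_power`, `null_benchmark`,
  `signal_benchmark`),
* minimal NIfTI-1 I/O (`read_volume`/`write_volume`) and a CLI
  (`exec/gdss`, subcommands `simulate glm gdss fdr topofdr tfce evaluate
  benchmark pipeline`).

## Worked example

```r
library(gdss)

# a 50-subject cohort on a 48^3 grid: intensity rises with age by
# beta1 = 0.04 per year inside a radius-5 sphere, FWHM-4 smoothing
cfg <- synthetic_config(grid_dims = rep(48L, 3), n_subjects = 50,
                        beta1 = 0.04,
                        regions = sphere_layout("1sphere5", rep(48L, 3)),
                        fwhm = 4, seed = 7)
ds   <- simulate_cohort(cfg)
stat <- fit_voxelwise_glm(ds)          # t-map, df = 48
res  <- gdss(stat)                     # full GDSS pipeline
res
#> gdss_result: n0 = 1102.2, rejected 4496 (initial) -> 770 (refined) of 110592 voxels, 19 ICM sweeps

score_labeling(res$labeling, ds$truth_mask)$tpr
#> [1] 0.9067961

fdr <- fdr_labeling(one_sided_p(stat), q = 0.05, c_form = "bh")
score_labeling(fdr, ds$truth_mask)$tpr
#> [1] 0.6621359
```

Read: the histogram holds ≈1102 null voxels per 0.01-wide p-value bin; the
initial geometric assignment rejects 4496 voxels and MRF refinement
consolidates them into 770 contiguous ones. At this moderate effect size
GDSS recovers 91% of the 515 true signal voxels while classical FDR — which
sees only the p-values, not the cluster geometry — recovers 66%.

## Layout

* `R/` — simulator, GLM, random-field geometry, GDSS core, comparators,
  evaluation, NIfTI I/O, pipeline/CLI
* `src/gdss_ops.cpp` — smoothing, connected components, TFCE, ICM
* `vignettes/gdss-methods.Rmd` — model assumptions, parameter choices,
  numerical conventions, known limitations
* `tests/testthat/` — unit, property, and acceptance suites
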