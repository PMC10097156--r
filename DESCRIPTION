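Package: gdss
Title: Geometry-Derived Statistical Significance for Voxelwise Statistical Maps
Version: 0.1.0
Authors@R:
    person("GDSS", "Maintainers", email = "gdss@example.org", role = c("aut", "cre"))
Description: Multiple-comparisons correction for voxelwise statistical maps on
    3D brain-image lattices. Implements the geometry-derived statistical
    significance (GDSS) procedure, which combines the empirical p-value
    histogram with a random-field geometric probability that each voxel's
    suprathreshold cluster configuration arose under the null hypothesis, and
    refines the resulting null/rejected labeling into contiguous regions with
    a Markov random field prior solved by iterated conditional modes.
    Also provides the comparator procedures used to benchmark GDSS
    (Benjamini-Yekutieli FDR, topological FDR over cluster peaks, and
    threshold-free cluster enhancement with max-statistic permutation), a
    voxelwise linear-model engine with analytic power calculations, a
    synthetic-cohort simulator (spherical signal regions, Gaussian noise,
    Gaussian smoothing), an evaluation harness (TPR, relative FPR, FWER,
    effect-size mixture modeling), minimal NIfTI-1 input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
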