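# Reference multiple-comparisons procedures used to benchmark GDSS:
# step-up FDR with the Benjamini-Yekutieli dependency factor, topological FDR
# over cluster-peak conditional p-values, and threshold-free cluster
# enhancement assessed by max-statistic permutation.

#' Step-up false discovery rate (Benjamini-Yekutieli / Benjamini-Hochberg)
#'
#' Sorts the p-values ascending and finds the largest k with
#' `P(k) <= k * q / (N * c(N))`, where `c(N) = sum_{i=1..N} 1/i` under the
#' arbitrary-dependency (BY) correction or `c(N) = 1` for the classical BH
#' procedure.  All p-values at most `P(k)` are rejected.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @param c_form `"by"` (default) or `"bh"`.
#' @return An object of class `fdr_result`: `q`, `k` (0 if nothing passes),
#'   `p_threshold` (`-Inf` if nothing passes), `rejected` (logical vector in
#'   input order), `c_n`.
#' @export
fdr_by <- function(pvals, q = 0.05, c_form = c("by", "bh")) {
  c_form <- match.arg(c_form)
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  c_n <- if (c_form == "by") sum(1 / seq_len(n)) else 1
  ps <- sort(pvals)
  ok <- ps <= seq_len(n) * q / (n * c_n)
  k <- if (any(ok)) max(which(ok)) else 0L
  p_threshold <- if (k > 0) ps[k] else -Inf
  structure(list(q = q, k = k, p_threshold = p_threshold,
                 rejected = pvals <= p_threshold, c_n = c_n,
                 c_form = c_form),
            class = "fdr_result")
}

#' Voxelwise FDR labeling of a p-value volume
#'
#' Applies [fdr_by()] to all masked p-values and returns the rejection set as
#' a labeling.
#'
#' @param p a `p_value_volume`.
#' @param q target FDR.
#' @param c_form `"by"` or `"bh"`.
#' @return A `significance_labeling`; the `fdr_result` is attached as
#'   attribute `fdr`.
#' @export
fdr_labeling <- function(p, q = 0.05, c_form = "by") {
  stopifnot(inherits(p, "p_value_volume"))
  res <- fdr_by(p$values[p$mask], q, c_form)
  rejected <- array(FALSE, dim(p$values))
  rejected[p$mask] <- res$rejected
  out <- labeling_from_mask(rejected, p$mask)
  attr(out, "fdr") <- res
  out
}

#' Topological FDR over cluster peaks
#'
#' Thresholds the z-field at the cluster-defining threshold `cdt`, computes
#' each cluster's peak conditional exceedance probability
#' [conditional_exceedance()], applies step-up FDR to the peak p-values, and
#' rejects every voxel of each surviving cluster.
#'
#' @param field a `statistic_volume` of kind `"z"` (t-volumes are converted).
#' @param cdt cluster-defining threshold (z-score; default 3.0).
#' @param q target FDR over the cluster peaks.
#' @param connectivity cluster connectivity (default 26).
#' @param c_form FDR variant over the peaks: `"bh"` (default) or `"by"`.
#' @return A `significance_labeling` with attribute `clusters`, a data.frame
#'   (cluster id, size, peak value, conditional p, significant flag).
#' @export
topological_fdr <- function(field, cdt = 3.0, q = 0.05, connectivity = 26L,
                            c_form = "bh") {
  stopifnot(inherits(field, "statistic_volume"))
  if (field$kind == "t") field <- t_to_z(field)
  labels <- label_clusters(field$values, cdt, connectivity, field$mask)
  ncl <- attr(labels, "n_clusters")
  rejected <- array(FALSE, dim(field$values))
  if (ncl == 0) {
    out <- labeling_from_mask(rejected, field$mask)
    attr(out, "clusters") <- data.frame(
      cluster = integer(0), size = integer(0), peak = numeric(0),
      p_conditional = numeric(0), significant = logical(0))
    return(out)
  }
  sup <- which(labels > 0L)
  sizes <- tabulate(labels[sup], ncl)
  peaks <- vapply(split(field$values[sup], labels[sup]), max, numeric(1))
  peaks <- peaks[order(as.integer(names(peaks)))]
  pcond <- conditional_exceedance(pmax(peaks, cdt), cdt)
  fdr <- fdr_by(pcond, q, c_form)
  sig <- fdr$rejected
  if (any(sig))
    rejected[sup[labels[sup] %in% which(sig)]] <- TRUE
  out <- labeling_from_mask(rejected, field$mask)
  attr(out, "clusters") <- data.frame(
    cluster = seq_len(ncl), size = sizes, peak = as.numeric(peaks),
    p_conditional = pcond, significant = sig)
  attr(out, "fdr") <- fdr
  out
}

#' Threshold-free cluster enhancement transform
#'
#' Per voxel, the Riemann sum over thresholds `h = dh, 2dh, ... <= value` of
#' `extent(cluster at h)^E * h^H * dh`, with clusters formed at each rung
#' under the chosen connectivity.  Negative statistics map to 0.
#'
#' @param field a `statistic_volume` or a bare 3D array.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step; default `max(field) / 100`.
#' @param connectivity cluster connectivity (default 26).
#' @return An object of class `tfce_map`: `values` (3D array), `E`, `H`,
#'   `dh`.
#' @export
tfce_transform <- function(field, E = 0.5, H = 2.0, dh = NULL,
                           connectivity = 26L) {
  mask <- NULL
  if (inherits(field, "statistic_volume")) {
    mask <- field$mask
    field <- field$values
  }
  connectivity <- check_connectivity(connectivity)
  v <- field
  if (!is.null(mask)) v[!mask] <- 0
  if (is.null(dh)) {
    vmax <- max(v)
    dh <- if (vmax > 0) vmax / 100 else 1
  }
  if (dh <= 0) stop("dh must be positive")
  out <- .tfce_transform(as.double(v), as.integer(dim(v)), as.double(E),
                         as.double(H), as.double(dh), connectivity)
  dim(out) <- dim(v)
  structure(list(values = out, E = E, H = H, dh = dh, mask = mask),
            class = "tfce_map")
}

#' TFCE max-statistic permutation test
#'
#' Computes the observed TFCE map of the contrast t-field, then permutes the
#' covariate of interest across subjects `n_perm` times; each permutation's
#' maximum TFCE statistic forms the max-null distribution.  A voxel is
#' rejected when its corrected p-value
#' `(1 + #\{perm maxima >= observed\}) / (1 + n_perm)` is at most `alpha`
#' (the standard max-statistic convention, guaranteeing familywise error at
#' most `alpha` under exchangeability).  Deterministic under `seed`.
#'
#' @param data 4D array (x, y, z, subject) or `synthetic_dataset`.
#' @param covariate per-subject covariate of interest (defaults to the ages
#'   of a `synthetic_dataset`).
#' @param nuisance optional data.frame of nuisance regressors (kept fixed
#'   under permutation; the intercept is implicit).
#' @param n_perm number of permutations (>= 100 and >= 1/alpha).
#' @param alpha familywise significance level.
#' @param seed integer seed for the permutation stream.
#' @param E,H,connectivity TFCE parameters, see [tfce_transform()].
#' @param mask optional analysis mask.
#' @return A `significance_labeling` with attributes `max_null` (the
#'   permutation null maxima), `threshold`, and `tfce` (the observed map).
#' @export
tfce_permutation_test <- function(data, covariate = NULL, nuisance = NULL,
                                  n_perm = 100L, alpha = 0.05, seed = 1L,
                                  E = 0.5, H = 2.0, connectivity = 26L,
                                  mask = NULL) {
  if (inherits(data, "synthetic_dataset")) {
    if (is.null(covariate)) covariate <- data$ages
    data <- data$data
  }
  if (is.null(covariate)) stop("`covariate` is required")
  if (n_perm < 100) stop("need at least 100 permutations")
  if (n_perm < 1 / alpha)
    stop("n_perm is too small to resolve the requested alpha")
  dims <- dim(data)[1:3]
  n <- dim(data)[4]
  if (length(covariate) != n)
    stop("covariate length must match the number of subjects")
  if (is.null(mask)) mask <- array(TRUE, dims)

  Y <- matrix(data, ncol = n)
  simple <- is.null(nuisance)
  if (simple) {
    # simple regression fast path: t from the correlation with the centered
    # covariate, using precomputed per-voxel sums
    S1 <- rowSums(Y)
    S2 <- rowSums(Y^2)
    df <- n - 2
    syy <- pmax(S2 - S1^2 / n, 0)
    tmap_for <- function(x) {
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      num <- as.vector(Y %*% xc)
      denom2 <- pmax(syy * sxx - num^2, 0)
      tv <- num * sqrt(df) / sqrt(pmax(denom2, .Machine$double.eps))
      tv[denom2 == 0] <- 0
      tv
    }
  } else {
    nuisance <- as.data.frame(nuisance)
    df <- n - (ncol(nuisance) + 2L)
    tmap_for <- function(x) {
      dm <- design_matrix(cbind(data.frame(.coi = x), nuisance), ".coi")
      X <- dm$X
      XtXinv <- chol2inv(chol(crossprod(X)))
      wc <- X %*% (XtXinv %*% dm$contrast)
      bc <- as.vector(Y %*% wc)
      Q <- qr.Q(qr(X))
      rss <- pmax(0, rowSums(Y^2) - rowSums((Y %*% Q)^2))
      vcb <- (rss / df) * drop(t(dm$contrast) %*% XtXinv %*% dm$contrast)
      tv <- numeric(length(bc))
      ok <- vcb > 0
      tv[ok] <- bc[ok] / sqrt(vcb[ok])
      tv
    }
  }

  tfce_of <- function(x) {
    tv <- array(tmap_for(x), dims)
    tv[!mask] <- 0
    tfce_transform(tv, E = E, H = H, connectivity = connectivity)$values
  }

  obs <- tfce_of(covariate)
  set.seed(seed)
  max_null <- vapply(seq_len(n_perm), function(i) {
    max(tfce_of(sample(covariate)))
  }, numeric(1))
  # standard max-statistic convention: corrected p = (1 + #{perm >= obs}) /
  # (1 + n_perm), reject p <= alpha; equivalently obs must exceed all but
  # the top floor(alpha * (n_perm + 1)) - 1 permutation maxima
  k <- floor(alpha * (n_perm + 1))       # allowed #{perm >= obs}, plus obs
  threshold <- sort(max_null, decreasing = TRUE)[k]
  rejected <- obs > threshold & mask
  out <- labeling_from_mask(rejected, mask)
  attr(out, "max_null") <- max_null
  attr(out, "threshold") <- threshold
  attr(out, "tfce") <- obs
  out
}
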