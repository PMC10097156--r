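# Scoring of labelings against ground truth (TPR, relative FPR, FWER,
# average significant voxels) and the effect-size two-Gaussian mixture /
# power estimation machinery.

#' Score a labeling against ground truth
#'
#' TPR is the fraction of truth voxels rejected.  The relative FPR divides
#' the procedure's false-positive rate over non-truth voxels by the
#' false-positive rate of the uncorrected voxelwise test on the same
#' background, so procedures are compared on a common scale.
#'
#' @param labeling a `significance_labeling`.
#' @param truth logical 3D array of true-signal voxels.
#' @param uncorrected the uncorrected-test `significance_labeling` used as
#'   the FPR normalizer (optional; without it `fpr_rel` is `NA`).
#' @return An object of class `evaluation_result`: `tpr`, `fpr`, `fpr_rel`,
#'   and the raw counts `tp`, `fp`, `fn`, `tn`.  Undefined ratios are `NA`
#'   with the `undefined` flag set.
#' @export
score_labeling <- function(labeling, truth, uncorrected = NULL) {
  stopifnot(inherits(labeling, "significance_labeling"))
  check_same_dims(labeling$labels, truth)
  mask <- labeling$mask
  rej <- labeling$labels == 1L & mask
  tr <- truth & mask
  tp <- sum(rej & tr); fp <- sum(rej & !tr)
  fn <- sum(!rej & tr & mask); tn <- sum(!rej & !tr & mask)
  undefined <- FALSE
  tpr <- if (sum(tr) > 0) tp / sum(tr) else { undefined <- TRUE; NA_real_ }
  nneg <- sum(mask & !tr)
  fpr <- if (nneg > 0) fp / nneg else NA_real_
  fpr_rel <- NA_real_
  if (!is.null(uncorrected)) {
    stopifnot(inherits(uncorrected, "significance_labeling"))
    fp_unc <- sum(uncorrected$labels == 1L & uncorrected$mask & !tr)
    if (fp_unc > 0 && nneg > 0) {
      fpr_rel <- fp / fp_unc
    } else {
      undefined <- TRUE
    }
  }
  structure(list(tpr = tpr, fpr = fpr, fpr_rel = fpr_rel,
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 undefined = undefined),
            class = "evaluation_result")
}

rejection_counts <- function(labelings) {
  if (is.numeric(labelings)) return(as.numeric(labelings))
  vapply(labelings, function(l) {
    if (inherits(l, "significance_labeling")) as.numeric(n_rejected(l))
    else as.numeric(l)
  }, numeric(1))
}

#' Familywise error rate over replicate null datasets
#'
#' Fraction of labelings with at least one rejected voxel.
#'
#' @param labelings list of `significance_labeling` objects, or a numeric
#'   vector of per-dataset rejection counts.
#' @return The FWER estimate.
#' @export
fwer_estimate <- function(labelings) {
  counts <- rejection_counts(labelings)
  if (length(counts) == 0) stop("need at least one labeling")
  mean(counts >= 1)
}

#' Average number of significant voxels (floor convention)
#'
#' Mean rejection count over the labelings with at least one rejection,
#' rounded down to the closest integer.  `NA` (flagged) when no labeling has
#' any rejection.
#'
#' @inheritParams fwer_estimate
#' @return Integer average, or `NA` if undefined.
#' @export
avg_significant <- function(labelings) {
  counts <- rejection_counts(labelings)
  if (length(counts) == 0) stop("need at least one labeling")
  pos <- counts[counts >= 1]
  if (length(pos) == 0) {
    out <- NA_integer_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  as.integer(floor(mean(pos)))
}

#' Two-component Gaussian mixture of effect sizes
#'
#' Expectation-maximization fit of a two-Gaussian mixture, with k-quantile
#' initialization and random restarts.  The component whose mean is nearest 0
#' is labeled the null component and reported first.
#'
#' @param values numeric vector (>= 100 values).
#' @param restarts number of EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the log-likelihood.
#' @param seed optional seed for the restart perturbations.
#' @return An object of class `effect_size_mixture`: `weights`, `means`,
#'   `sds` (null component first), `loglik`, `converged`, `n`.
#' @export
fit_two_gaussian_mixture <- function(values, restarts = 10L, max_iter = 500L,
                                     tol = 1e-8, seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need at least 100 finite values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)

  em_once <- function(mu, sg, w) {
    ll_old <- -Inf
    converged <- FALSE
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(values, mu[1], sg[1])
      d2 <- w[2] * dnorm(values, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r2 <- d2 / tot
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      n2 <- sum(r2); n1 <- n - n2
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum((1 - r2) * values) / n1, sum(r2 * values) / n2)
      sg <- sqrt(c(sum((1 - r2) * (values - mu[1])^2) / n1,
                   sum(r2 * (values - mu[2])^2) / n2))
      sg <- pmax(sg, 1e-6)
      w <- c(n1, n2) / n
    }
    list(mu = mu, sg = sg, w = w, loglik = ll_old, converged = converged,
         trace = trace)
  }

  qs <- quantile(values, c(0.25, 0.75), names = FALSE)
  s0 <- sd(values)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- if (r == 1) qs else sort(qs + rnorm(2, 0, s0 / 2))
    fit <- em_once(mu0, c(s0, s0) / sqrt(2), c(0.5, 0.5))
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik))
      best <- fit
  }

  # null component = mean nearest 0, reported first
  ord <- order(abs(best$mu))
  structure(list(weights = best$w[ord], means = best$mu[ord],
                 sds = best$sg[ord], loglik = best$loglik,
                 loglik_trace = best$trace,
                 converged = best$converged, n = n),
            class = "effect_size_mixture")
}

#' @export
print.effect_size_mixture <- function(x, ...) {
  cat(sprintf(
    "effect_size_mixture: null %.3f*N(%.3f, %.3f), alt %.3f*N(%.3f, %.3f)%s\n",
    x$weights[1], x$means[1], x$sds[1],
    x$weights[2], x$means[2], x$sds[2],
    if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Statistical power estimated from the mixture fit
#'
#' The mixture's alternate-component weight estimates the fraction of voxels
#' truly under the alternative; power is the rejection count divided by that
#' estimated alternate voxel count, clipped to `[0, 1]`.
#'
#' @param mix an `effect_size_mixture` fitted on the map's effect sizes.
#' @param labeling a `significance_labeling` (or a rejection count).
#' @param mask_size number of voxels the mixture was fitted over.
#' @return Estimated power, or flagged `NA` if the alternate weight is 0.
#' @export
estimated_power <- function(mix, labeling, mask_size) {
  stopifnot(inherits(mix, "effect_size_mixture"))
  nrej <- if (inherits(labeling, "significance_labeling"))
    n_rejected(labeling) else as.numeric(labeling)
  w_alt <- mix$weights[2]
  if (w_alt <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  min(1, max(0, nrej / (w_alt * mask_size)))
}

#' Widths of rejected regions
#'
#' For each connected component of the rejection set, the smallest
#' bounding-box edge ("width"); used to check that null-data rejections stay
#' sparse and narrow.
#'
#' @param labeling a `significance_labeling`.
#' @param connectivity component connectivity (default 26).
#' @return Integer vector of component widths (empty if nothing rejected).
#' @export
region_widths <- function(labeling, connectivity = 26L) {
  stopifnot(inherits(labeling, "significance_labeling"))
  rej <- array(0, dim(labeling$labels))
  rej[labeling$labels == 1L & labeling$mask] <- 1
  labels <- label_clusters(rej, 0.5, connectivity)
  ncl <- attr(labels, "n_clusters")
  if (ncl == 0) return(integer(0))
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  vapply(seq_len(ncl), function(cl) {
    sub <- idx[lab == cl, , drop = FALSE]
    min(apply(sub, 2, function(cc) diff(range(cc)) + 1L))
  }, numeric(1))
}
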