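# Voxelwise ordinary least squares: a mass-univariate linear model fitted at
# every voxel of a 4D stack, the one-sided p-value and z-score transforms,
# Cohen's D effect sizes, and the closed-form power of the slope test under a
# noncentral t alternative.

#' Design matrix with a contrast
#'
#' @param covariates data.frame of per-subject regressors.  An intercept
#'   column is prepended automatically unless one is already present (a
#'   constant column).
#' @param contrast either the name of a column of `covariates` (tests that
#'   coefficient against 0) or a numeric weight vector over the design
#'   columns.
#' @return An object of class `design_matrix` with elements `X` (model
#'   matrix) and `contrast` (numeric weights).
#' @export
design_matrix <- function(covariates, contrast) {
  covariates <- as.data.frame(covariates)
  has_const <- any(vapply(covariates, function(col)
    is.numeric(col) && length(unique(col)) == 1L, logical(1)))
  X <- as.matrix(covariates[vapply(covariates, is.numeric, logical(1))])
  if (!has_const)
    X <- cbind("(Intercept)" = 1, X)
  if (is.character(contrast)) {
    if (!contrast %in% colnames(X))
      stop(sprintf("contrast column '%s' not found in the design", contrast))
    cvec <- as.numeric(colnames(X) == contrast)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != ncol(X))
      stop("contrast length must equal the number of design columns")
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, contrast = cvec), class = "design_matrix")
}

#' Fit the voxelwise linear model
#'
#' Ordinary least squares at every masked voxel of a 4D stack, returning the
#' t statistic of the requested contrast with `df = n - rank(X)`.  Voxels
#' whose intensities are identical across subjects carry no information about
#' the contrast; they receive statistic 0 and are dropped from the returned
#' mask with a warning.
#'
#' @param data 4D numeric array (x, y, z, subject) or a `synthetic_dataset`.
#' @param design a `design_matrix`, or a data.frame together with `contrast`.
#' @param contrast used when `design` is a data.frame; see [design_matrix()].
#' @param mask optional logical 3D array restricting the fit.
#' @return A `statistic_volume` of kind `"t"`.  The attribute `flagged` holds
#'   the logical array of zero-variance voxels.
#' @export
fit_voxelwise_glm <- function(data, design = NULL, contrast = NULL,
                              mask = NULL) {
  if (inherits(data, "synthetic_dataset")) {
    if (is.null(design)) {
      design <- data.frame(age = data$ages)
      contrast <- "age"
    }
    data <- data$data
  }
  if (is.null(design)) stop("`design` is required")
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array")
  dims <- dim(data)[1:3]
  n <- dim(data)[4]
  if (!inherits(design, "design_matrix"))
    design <- design_matrix(design, contrast)
  X <- design$X
  cvec <- design$contrast
  if (nrow(X) != n)
    stop(sprintf("design has %d rows but the stack has %d subjects",
                 nrow(X), n))
  p <- ncol(X)
  if (n <= p) stop("need more subjects than design columns")
  if (is.null(mask)) mask <- array(TRUE, dims)

  Y <- matrix(data, ncol = n)       # voxels x subjects, no copy of layout
  XtXinv <- chol2inv(chol(crossprod(X)))
  # contrast estimate c'b per voxel: one matrix-vector product
  wc <- X %*% (XtXinv %*% cvec)
  bc <- as.vector(Y %*% wc)
  # residual sum of squares via the orthonormal column basis of X
  Q <- qr.Q(qr(X))
  fit2 <- (Y %*% Q)^2
  rss <- pmax(0, rowSums(Y^2) - rowSums(fit2))
  df <- n - p
  var_cb <- (rss / df) * drop(t(cvec) %*% XtXinv %*% cvec)

  tval <- rep(0, length(bc))
  ok <- var_cb > 0
  tval[ok] <- bc[ok] / sqrt(var_cb[ok])
  # zero residual variance with a nonzero estimate: numerically infinite
  degen <- !ok & abs(bc) > 0
  tval[degen] <- sign(bc[degen]) * .Machine$double.xmax^0.5

  flagged <- array(!ok & !degen, dims)   # constant across subjects
  flagged <- flagged & mask
  if (any(flagged)) {
    warning(sprintf("%d zero-variance voxels flagged and removed from mask",
                    sum(flagged)))
    mask <- mask & !flagged
  }
  stat <- array(tval, dims)
  out <- statistic_volume(stat, mask, df = df, kind = "t")
  attr(out, "flagged") <- flagged
  out
}

#' One-sided p-values of a statistic volume
#'
#' Upper-tail probability of each masked statistic under its null
#' distribution (central t with the volume's df, or standard normal).
#'
#' @param stat a `statistic_volume`.
#' @return A `p_value_volume` with `sidedness = "one"`.
#' @export
one_sided_p <- function(stat) {
  stopifnot(inherits(stat, "statistic_volume"))
  p <- if (stat$kind == "t")
    pt(stat$values, df = stat$df, lower.tail = FALSE)
  else
    pnorm(stat$values, lower.tail = FALSE)
  p_value_volume(p, stat$mask, "one")
}

#' Convert a t-statistic volume to z-scores
#'
#' Probability-integral transform preserving the one-sided p-value:
#' `z = qnorm(pt(t, df))`, evaluated on the log scale in the relevant tail so
#' extreme statistics survive the round trip.
#'
#' @param stat a `statistic_volume` of kind `"t"`.
#' @return A `statistic_volume` of kind `"z"`.
#' @export
t_to_z <- function(stat) {
  stopifnot(inherits(stat, "statistic_volume"))
  if (stat$kind == "z") return(stat)
  tv <- stat$values
  z <- tv
  up <- !is.na(tv) & tv >= 0
  z[up] <- qnorm(pt(tv[up], stat$df, lower.tail = FALSE, log.p = TRUE),
                 lower.tail = FALSE, log.p = TRUE)
  z[!up] <- qnorm(pt(tv[!up], stat$df, lower.tail = TRUE, log.p = TRUE),
                  lower.tail = TRUE, log.p = TRUE)
  statistic_volume(z, stat$mask, df = NULL, kind = "z")
}

#' Cohen's D effect size from a t-statistic volume
#'
#' Standard conversion `D = 2 t / sqrt(df)`, sign preserved.
#'
#' @param stat a `statistic_volume` of kind `"t"`.
#' @return 3D numeric array of effect sizes (NA outside the mask).
#' @export
cohens_d <- function(stat) {
  stopifnot(inherits(stat, "statistic_volume"), stat$kind == "t")
  d <- 2 * stat$values / sqrt(stat$df)
  d[!stat$mask] <- NA_real_
  d
}

#' Standard error of the simple-regression slope
#'
#' `s(b1) = sigma_eps / sqrt((n - 1) * sigma_x^2)` for a single covariate
#' with population SD `sigma_x`.
#'
#' @param n number of subjects.
#' @param sigma_x covariate SD.
#' @param sigma_eps residual (noise) SD.
#' @return The slope standard error.
#' @export
slope_se <- function(n, sigma_x, sigma_eps) {
  if (n < 3) stop("n must be >= 3")
  if (sigma_x <= 0 || sigma_eps <= 0) stop("SDs must be positive")
  sigma_eps / sqrt((n - 1) * sigma_x^2)
}

#' Analytic power of the voxelwise slope test
#'
#' Power of the one-sided level-`alpha` test of `beta1 = 0` when the true
#' slope is `beta1`: the upper-tail probability, beyond the central-t critical
#' value `qt(1 - alpha, n - 2)`, of the noncentral t distribution with
#' `df = n - 2` and noncentrality `delta = |beta1| / s(b1)`.
#'
#' `smoothed_sigma_eps` substitutes the post-smoothing noise SD for
#' `sigma_eps`, giving the power at the center of a smoothed signal region.
#' `s_b1` overrides the slope standard error entirely (e.g. to reproduce a
#' published table that rounds `s^2(b1)` before use).
#'
#' @param beta1 true slope under the alternative.
#' @param n number of subjects (>= 3).
#' @param sigma_x covariate SD.
#' @param sigma_eps noise SD.
#' @param alpha one-sided significance level.
#' @param smoothed_sigma_eps optional replacement noise SD after smoothing.
#' @param s_b1 optional explicit slope standard error.
#' @return The rejection probability (equals `alpha` when `beta1 = 0`).
#' @export
analytic_power <- function(beta1, n = 50, sigma_x = 2, sigma_eps = 1,
                           alpha = 0.05, smoothed_sigma_eps = NULL,
                           s_b1 = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(smoothed_sigma_eps)) sigma_eps <- smoothed_sigma_eps
  se <- if (!is.null(s_b1)) s_b1 else slope_se(n, sigma_x, sigma_eps)
  delta <- abs(beta1) / se
  crit <- qt(1 - alpha, df = n - 2)
  pt(crit, df = n - 2, ncp = delta, lower.tail = FALSE)
}
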