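# Core containers for lattice-indexed statistics.  All volumes are plain 3D
# arrays in column-major order; masks are logical arrays of the same shape.

#' Statistic volume
#'
#' A 3D lattice of voxelwise test statistics together with its analysis mask,
#' degrees of freedom, and the statistic family (Student t or standard normal
#' z).  This is the common currency passed between the voxelwise linear model,
#' the random-field geometry, and the comparator procedures.
#'
#' @param values 3D numeric array of test statistics.
#' @param mask logical 3D array of the same shape; `NULL` means all voxels.
#' @param df degrees of freedom (required when `kind = "t"`).
#' @param kind `"t"` or `"z"`.
#' @return An object of class `statistic_volume` with elements `values`,
#'   `mask`, `df` and `kind`.
#' @export
statistic_volume <- function(values, mask = NULL, df = NULL,
                             kind = c("t", "z")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  check_same_dims(values, mask)
  if (kind == "t") {
    if (is.null(df)) stop("`df` is required for a t-statistic volume")
    if (df < 1) stop("`df` must be >= 1")
  }
  if (any(!is.finite(values[mask]) & !is.infinite(values[mask])))
    stop("statistic values must not be NA/NaN inside the mask")
  structure(list(values = values, mask = mask, df = df, kind = kind),
            class = "statistic_volume")
}

#' P-value volume
#'
#' @param values 3D numeric array of p-values in `[0, 1]`.
#' @param mask logical 3D array (`NULL` = all voxels).
#' @param sidedness `"one"` or `"two"`.
#' @return An object of class `p_value_volume`.
#' @export
p_value_volume <- function(values, mask = NULL, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  check_same_dims(values, mask)
  pv <- values[mask]
  if (any(is.na(pv)) || any(pv < 0 | pv > 1))
    stop("p-values must lie in [0, 1] inside the mask")
  structure(list(values = values, mask = mask, sidedness = sidedness),
            class = "p_value_volume")
}

#' Significance labeling
#'
#' Binary null/rejected label per masked voxel, produced by the initial
#' histogram assignment (`stage = "initial"`) or by MRF refinement
#' (`stage = "mrf_refined"`).
#'
#' @param labels integer 3D array with 1 = rejected, 0 = null (NA outside the
#'   mask is permitted).
#' @param mask logical 3D array.
#' @param stage labeling stage.
#' @return An object of class `significance_labeling`.
#' @export
significance_labeling <- function(labels, mask,
                                  stage = c("initial", "mrf_refined",
                                            "external")) {
  stage <- match.arg(stage)
  check_same_dims(labels, mask)
  lm <- labels[mask]
  if (any(is.na(lm)) || !all(lm %in% c(0L, 1L)))
    stop("labels inside the mask must be 0 (null) or 1 (rejected)")
  structure(list(labels = labels, mask = mask, stage = stage),
            class = "significance_labeling")
}

#' Number of rejected voxels in a labeling
#' @param labeling a `significance_labeling`.
#' @return Integer count of rejected voxels.
#' @export
n_rejected <- function(labeling) {
  sum(labeling$labels[labeling$mask] == 1L)
}

#' Build a labeling from a logical rejection mask
#' @param rejected logical 3D array (TRUE = rejected).
#' @param mask analysis mask.
#' @param stage labeling stage tag.
#' @return A `significance_labeling`.
#' @export
labeling_from_mask <- function(rejected, mask = NULL, stage = "external") {
  if (is.null(mask)) mask <- array(TRUE, dim(rejected))
  lab <- array(0L, dim(rejected))
  lab[rejected] <- 1L
  significance_labeling(lab, mask, stage)
}

#' @export
print.statistic_volume <- function(x, ...) {
  cat(sprintf("statistic_volume [%s]: %s voxels, %s masked%s\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              sum(x$mask),
              if (!is.null(x$df)) sprintf(", df = %g", x$df) else ""))
  invisible(x)
}

#' @export
print.significance_labeling <- function(x, ...) {
  cat(sprintf("significance_labeling [%s]: %d of %d voxels rejected\n",
              x$stage, n_rejected(x), sum(x$mask)))
  invisible(x)
}

check_same_dims <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("array dimensions differ: (%s) vs (%s)",
                 paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")))
  invisible(TRUE)
}

# connectivity validation shared by the cluster-based procedures
check_connectivity <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  as.integer(connectivity)
}

#' Label connected components of an excursion set
#'
#' Connected components of `{values > threshold}` under 6-, 18- or
#' 26-connectivity.  Voxels outside the excursion set (or outside the mask)
#' get label 0.
#'
#' @param values 3D numeric array.
#' @param threshold scalar threshold defining the excursion set.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask optional logical array; out-of-mask voxels never enter a
#'   component.
#' @return Integer 3D array of component labels (0 = background), with
#'   attribute `n_clusters`.
#' @export
label_clusters <- function(values, threshold, connectivity = 26L,
                           mask = NULL) {
  connectivity <- check_connectivity(connectivity)
  v <- values
  if (!is.null(mask)) {
    check_same_dims(values, mask)
    v[!mask] <- -Inf
  }
  lab <- .cc_label(as.double(v), as.integer(dim(values)),
                   as.double(threshold), connectivity)
  ncl <- attr(lab, "n_clusters")
  dim(lab) <- dim(values)
  attr(lab, "n_clusters") <- ncl
  lab
}
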