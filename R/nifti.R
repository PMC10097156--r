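# Minimal NIfTI-1 input/output.  Supports 3D/4D volumes, the common scalar
# datatypes, gzip-compressed files, both endiannesses on read, and carries
# the sform affine through a read-write round trip bit-exactly (data are
# written as float64).  This is deliberately a small, self-contained codec:
# the analysis environment provides no NIfTI package.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8, signed = TRUE))   # float64

open_maybe_gz <- function(path, mode) {
  # gzfile reads plain files transparently; for writing choose by extension
  if (grepl("\\.gz$", path) || mode == "rb") gzfile(path, mode)
  else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return A numeric array (3D or 4D) with attributes `affine` (4x4 voxel-to-
#'   world matrix) and `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  if (length(hdr_raw) < 348) stop("truncated NIfTI header")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size,
            endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  if (!ndim %in% c(3L, 4L)) stop(sprintf("unsupported dimensionality: %d", ndim))
  dims <- dim0[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1, 2)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d", datatype))
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE)
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1))
  else diag(c(pixdim[2:4], 1))

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(data) < n) stop("truncated NIfTI data section")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- array(as.double(data), dims)
  attr(arr, "affine") <- affine
  attr(arr, "pixdim") <- pixdim[2:(1 + ndim)]
  arr
}

#' Write a NIfTI-1 volume
#'
#' Writes `array` as float64 with an sform affine; `.gz` paths are
#' gzip-compressed.  A read-write round trip preserves data and affine
#' bit-exactly.
#'
#' @param array 3D or 4D numeric array.
#' @param path output `.nii` or `.nii.gz` path.
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @return The path, invisibly.
#' @export
write_volume <- function(array, path, affine = diag(4)) {
  dims <- dim(array)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L))
    stop("`array` must be a 3D or 4D array")
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  ndim <- length(dims)
  pixdim <- c(0, sqrt(colSums(affine[1:3, 1:3]^2)), rep(1, 4))
  if (ndim == 4L) pixdim[5] <- 1

  hdr <- raw(348)
  wr <- function(off, value, what, size) {
    b <- writeBin(value, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  wr(0, 348L, "integer", 4)
  wr(40, as.integer(c(ndim, dims, rep(1L, 7 - length(dims)))), "integer", 2)
  wr(70, 64L, "integer", 2)            # datatype float64
  wr(72, 64L, "integer", 2)            # bitpix
  wr(76, pixdim, "double", 4)
  wr(108, 352, "double", 4)            # vox_offset
  wr(112, 1, "double", 4)              # scl_slope
  wr(116, 0, "double", 4)              # scl_inter
  wr(252, 0L, "integer", 2)            # qform_code
  wr(254, 1L, "integer", 2)            # sform_code
  wr(280, as.double(t(affine[1:3, ])), "double", 4)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                # no extensions
  writeBin(as.double(array), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a cohort design table
#'
#' CSV with `subject_id` as the first column and numeric covariates after it.
#'
#' @param path CSV path.
#' @param n_subjects optional expected row count (validated when given).
#' @return data.frame of covariates (without `subject_id`), with the ids as
#'   attribute `subject_id`.
#' @export
read_design <- function(path, n_subjects = NULL) {
  d <- read.csv(path)
  if (names(d)[1] != "subject_id")
    stop("design CSV must have `subject_id` as its first column")
  if (!is.null(n_subjects) && nrow(d) != n_subjects)
    stop(sprintf("design has %d rows but the data stack has %d subjects",
                 nrow(d), n_subjects))
  out <- d[-1]
  attr(out, "subject_id") <- d$subject_id
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes the 4D subject stack and 3D truth mask as NIfTI, the design as a
#' `subject_id,age` CSV, and the generating configuration as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(dataset$data, file.path(dir, "data.nii.gz"))
  write_volume(dataset$truth_mask + 0, file.path(dir, "truth_mask.nii.gz"))
  write.csv(data.frame(subject_id = seq_along(dataset$ages),
                       age = dataset$ages),
            file.path(dir, "design.csv"), row.names = FALSE)
  cfg <- dataset$config
  cfg$grid_dims <- as.integer(cfg$grid_dims)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
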