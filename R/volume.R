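#' @useDynLib radrobust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median mad quantile var aggregate
#'   binomial fft glm predict qt pchisq optim setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
"_PACKAGE"

# ---- core containers --------------------------------------------------------
#
# The pipeline moves three light S3 objects around:
#   image_volume : 3-D numeric array in Hounsfield units + per-axis spacing (mm)
#   roi_mask     : logical array aligned voxel-for-voxel with a volume
#   lesion_sample: (volume, mask, subject_id, replicate, label)
# Axis convention: dims are (x, y, z); z is the axial (slice) axis.

#' Construct an image volume
#'
#' A 3-D scalar grid in Hounsfield units with per-axis voxel spacing in mm.
#' Dimension order is (x, y, z) with z the axial/slice axis.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite lengths (mm)")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Construct an ROI mask
#'
#' @param data logical (or coercible) 3-D array; TRUE marks lesion voxels.
#' @param spacing numeric length-3 spacing in mm.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  data <- array(as.logical(data), dim = dim(data))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive lengths (mm)")
  structure(list(data = data, spacing = spacing), class = "roi_mask")
}

#' Bundle a volume, mask and metadata into a lesion sample
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] of identical shape.
#' @param subject_id character scalar.
#' @param replicate replicate tag: `"baseline"`, `"retest"` or a
#'   perturbation label such as `"S:2"`.
#' @param label binary response label (0 = unresponsive, 1 = responsive),
#'   or `NA` for unlabeled samples.
#' @return A `lesion_sample` object.
#' @export
lesion_sample <- function(volume, mask, subject_id,
                          replicate = "baseline", label = NA_integer_) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("mask shape must equal volume shape")
  if (!any(mask$data)) stop("mask must contain at least one voxel")
  structure(list(volume = volume, mask = mask,
                 subject_id = as.character(subject_id),
                 replicate = as.character(replicate),
                 label = if (is.na(label)) NA_integer_ else as.integer(label)),
            class = "lesion_sample")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s, spacing %s mm, range [%.1f, %.1f] HU\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.lesion_sample <- function(x, ...) {
  cat(sprintf("lesion_sample %s [%s] label=%s, %d mask voxels, grid %s\n",
              x$subject_id, x$replicate,
              ifelse(is.na(x$label), "NA", x$label),
              sum(x$mask$data), paste(dim(x$volume$data), collapse = "x")))
  invisible(x)
}

# ---- minimal NIfTI-1 I/O ----------------------------------------------------
# Single-file .nii / .nii.gz, float32 data, identity orientation. Enough to
# round-trip the synthetic cohorts; not a general-purpose NIfTI implementation.

#' Write a volume or mask as NIfTI-1
#'
#' Writes a single-file uncompressed `.nii` or gzipped `.nii.gz` (float32,
#' identity orientation, spacing stored in `pixdim`).
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path; gzip compression is used iff it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  dat <- x$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim = dim(dat))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(dat)
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused
  writeBin(as.integer(c(3, d, 1, 1, 1, 1)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                             # intent params etc.
  writeBin(16L, con, size = 2)                       # datatype float32
  writeBin(32L, con, size = 2)                       # bitpix
  writeBin(0L, con, size = 2)                        # slice_start
  writeBin(c(1, x$spacing, 1, 1, 1, 1), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                       # vox_offset (float!)
  writeBin(c(1, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(raw(4), con)                              # slice_end/code/units
  writeBin(c(0, 0), con, size = 4)                   # cal_max, cal_min
  writeBin(raw(16), con)                             # slice_dur..glmin
  writeBin(charToRaw(sprintf("%-80s", "radrobust synthetic volume")), con)
  writeBin(raw(24), con)                             # aux_file
  writeBin(c(0L, 1L), con, size = 2)                 # qform=0, sform=1
  writeBin(rep(0, 6), con, size = 4)                 # quaternions
  # identity sform scaled by spacing
  writeBin(c(x$spacing[1], 0, 0, 0), con, size = 4)
  writeBin(c(0, x$spacing[2], 0, 0), con, size = 4)
  writeBin(c(0, 0, x$spacing[3], 0), con, size = 4)
  writeBin(raw(16), con)                             # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)
  writeBin(raw(4), con)                              # extension flag
  writeBin(as.numeric(dat), con, size = 4)
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as_mask logical; return an [roi_mask()] (data > 0.5) instead of an
#'   [image_volume()].
#' @return An `image_volume` or `roi_mask`.
#' @export
read_nifti <- function(path, as_mask = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_sz <- readBin(con, "integer", 1, size = 4)
  if (!identical(hdr_sz, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dims <- readBin(con, "integer", 8, size = 2)
  if (dims[1] != 3L) stop("expected a 3-D NIfTI volume")
  d <- dims[2:4]
  invisible(readBin(con, "raw", 14))
  dtype <- readBin(con, "integer", 1, size = 2)
  if (dtype != 16L) stop("only float32 NIfTI supported")
  invisible(readBin(con, "raw", 2 + 2))
  pixdim <- readBin(con, "numeric", 8, size = 4)
  vox_off <- readBin(con, "numeric", 1, size = 4)
  # skip the rest of the header up to vox_offset (we are at byte 112)
  invisible(readBin(con, "raw", as.integer(vox_off) - 112L))
  vals <- readBin(con, "numeric", prod(d), size = 4)
  arr <- array(vals, dim = d)
  sp <- pixdim[2:4]
  if (as_mask) roi_mask(arr > 0.5, sp) else image_volume(arr, sp)
}
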