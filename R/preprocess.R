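# Image normalization and slab selection. Fixed stage order:
# window -> histogram equalization -> Gaussian denoise -> max-area slab.

#' Preprocessing configuration
#'
#' @param window_mode `"fixed"` (default) or `"adaptive"`. Adaptive sets
#'   centre = in-ROI mean and width = 6 x in-ROI SD (mean +/- 3 SD); it is
#'   kept for display/CNN-style inputs, but because it re-derives the
#'   intensity mapping from each (possibly perturbed) ROI it erases the
#'   absolute intensity scale that perturbation ICCs measure agreement on,
#'   so the radiomics path defaults to the fixed lung window.
#' @param window_center_hu,window_width_hu fixed window (default lung window,
#'   centre -600 HU, width 1500 HU).
#' @param equalize logical; apply histogram equalization. Off by default on
#'   the radiomics path: global equalization compresses in-ROI intensities
#'   to the lesion's volume fraction of the CDF, collapsing fixed-bin-width
#'   discretization to one or two gray levels. Turn on for display or
#'   CNN-style inputs.
#' @param equalize_bins histogram bin count (default 256).
#' @param gauss_sigma_mm Gaussian denoising sigma in mm (default 0.75, one
#'   in-plane voxel); 0 disables.
#' @param n_slices axial slab thickness in slices (default 3).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(window_mode = c("fixed", "adaptive"),
                              window_center_hu = -600, window_width_hu = 1500,
                              equalize = FALSE, equalize_bins = 256,
                              gauss_sigma_mm = 0.75, n_slices = 3) {
  window_mode <- match.arg(window_mode)
  if (window_width_hu <= 0) stop("window_width_hu must be > 0")
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (equalize_bins < 2) stop("equalize_bins must be >= 2")
  structure(list(window_mode = window_mode,
                 window_center_hu = window_center_hu,
                 window_width_hu = window_width_hu,
                 equalize = equalize, equalize_bins = equalize_bins,
                 gauss_sigma_mm = gauss_sigma_mm, n_slices = n_slices),
            class = "preprocess_config")
}

#' Window/level intensity normalization
#'
#' Clips intensities to `[centre - width/2, centre + width/2]` and rescales
#' affinely to `[0, 1]`. In adaptive mode the window is derived from the ROI:
#' centre = in-ROI mean, width = 6 x in-ROI SD; a zero-variance ROI falls
#' back to the fixed lung window with a warning.
#'
#' @param volume an [image_volume()].
#' @param config a [preprocess_config()].
#' @param mask an [roi_mask()]; required for adaptive mode.
#' @return A windowed [image_volume()] with values in `[0, 1]`.
#' @export
window_level <- function(volume, config = preprocess_config(), mask = NULL) {
  ctr <- config$window_center_hu; wid <- config$window_width_hu
  if (config$window_mode == "adaptive") {
    if (is.null(mask)) stop("adaptive windowing needs an ROI mask")
    v <- volume$data[mask$data]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance ROI; falling back to fixed lung window")
    } else {
      ctr <- mean(v); wid <- 6 * s
    }
  }
  lo <- ctr - wid / 2; hi <- ctr + wid / 2
  out <- pmin(pmax(volume$data, lo), hi)
  image_volume(array((out - lo) / (hi - lo), dim = dim(out)), volume$spacing)
}

#' Histogram equalization
#'
#' Classic CDF-mapping equalization over `bins` equal-width bins spanning the
#' volume's intensity range: each voxel is mapped to the empirical CDF of its
#' bin. The mapping is monotone non-decreasing, so voxel rank order is
#' preserved; output lies in `(0, 1]`. Constant volumes are returned as-is.
#'
#' @param volume an [image_volume()].
#' @param bins number of histogram bins.
#' @return An equalized [image_volume()].
#' @export
equalize_histogram <- function(volume, bins = 256) {
  v <- volume$data
  rng <- range(v)
  if (!all(is.finite(rng))) stop("volume must be finite")
  if (rng[1] == rng[2]) return(volume)
  idx <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  cdf <- cumsum(counts) / length(v)
  image_volume(array(cdf[idx], dim = dim(v)), volume$spacing)
}

# separable Gaussian convolution with reflective boundaries, sigma in voxels
gauss_smooth_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(-r:r)^2 / (2 * sigma_vox^2)); k <- k / sum(k)
  d <- dim(arr)
  n <- d[axis]
  # half-sample symmetric ("reflect") boundary: conserves total mass for
  # symmetric kernels; modular fold handles radii larger than the axis
  refl <- function(i) {
    j <- (i - 1) %% (2 * n)
    j[j >= n] <- 2 * n - 1 - j[j >= n]
    j + 1
  }
  out <- array(0, dim = d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- refl(seq_len(n) + off)
    sl <- switch(axis, arr[idx, , , drop = FALSE],
                 arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    out <- out + k[j] * sl
  }
  out
}

#' Gaussian denoising
#'
#' Separable Gaussian convolution; the physical `sigma_mm` is converted to
#' voxels through the spacing, so anisotropic grids are smoothed isotropically
#' in physical space. Reflective boundary handling preserves the global mean.
#' `sigma_mm = 0` is the identity.
#'
#' @param volume an [image_volume()].
#' @param sigma_mm Gaussian sigma in mm.
#' @return A smoothed [image_volume()].
#' @export
gaussian_denoise <- function(volume, sigma_mm) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(volume)
  out <- volume$data
  for (ax in 1:3) out <- gauss_smooth_axis(out, sigma_mm / volume$spacing[ax], ax)
  image_volume(out, volume$spacing)
}

#' Select the consecutive axial slices with maximal tumour area
#'
#' Finds the window of `n_slices` consecutive axial (z) slices whose summed
#' in-mask voxel count is maximal; ties go to the smallest starting index.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param n_slices slab thickness (default 3).
#' @return List with `volume` and `mask` slabs (z-extent `n_slices`), plus
#'   `start`, the first selected slice index.
#' @export
select_max_area_slices <- function(volume, mask, n_slices = 3) {
  if (!any(mask$data)) stop("mask is empty")
  nz <- dim(mask$data)[3]
  if (nz < n_slices) {
    warning(sprintf("volume has %d slices < n_slices = %d; using all", nz, n_slices))
    n_slices <- nz
  }
  areas <- apply(mask$data, 3, sum)
  wins <- vapply(seq_len(nz - n_slices + 1),
                 function(s) sum(areas[s:(s + n_slices - 1)]), numeric(1))
  s <- which.max(wins)          # which.max takes the first maximum: smallest start
  zz <- s:(s + n_slices - 1)
  list(volume = image_volume(volume$data[, , zz, drop = FALSE], volume$spacing),
       mask = roi_mask(mask$data[, , zz, drop = FALSE], mask$spacing),
       start = s)
}

# 1-D linear interpolation resample of an array along one axis onto physical
# positions pos_mm (source grid at (0:(n-1))*sp_mm); clamped at the ends
resample_axis_linear <- function(arr, axis, sp_mm, pos_mm) {
  n <- dim(arr)[axis]
  x <- pos_mm / sp_mm
  x <- pmin(pmax(x, 0), n - 1)
  i0 <- pmin(floor(x), n - 2); w <- x - i0
  if (n == 1) { i0 <- rep(0, length(x)); w <- rep(0, length(x)) }
  take <- function(idx) switch(axis, arr[idx + 1, , , drop = FALSE],
                               arr[, idx + 1, , drop = FALSE],
                               arr[, , idx + 1, drop = FALSE])
  a0 <- take(i0); a1 <- take(pmin(i0 + 1, n - 1))
  # weight array broadcast along the other axes
  warr <- aperm(array(w, dim = c(length(x), dim(a0)[-axis])),
                order(c(axis, seq_len(3)[-axis])))
  a0 * (1 - warr) + a1 * warr
}

# box-average resample along one axis: each output voxel is the mean of the
# source voxels whose centres fall inside its physical extent (models the
# partial-volume averaging of thick-slice reconstruction)
resample_axis_box <- function(arr, axis, sp_mm, pos_mm, width_mm) {
  n <- dim(arr)[axis]
  src <- (seq_len(n) - 1) * sp_mm
  slices <- lapply(pos_mm, function(p) {
    idx <- which(src >= p - width_mm / 2 & src < p + width_mm / 2)
    if (!length(idx)) idx <- which.min(abs(src - p))
    sl <- switch(axis, arr[idx, , , drop = FALSE],
                 arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    apply(sl, setdiff(1:3, axis), mean)
  })
  out <- array(0, dim = replace(dim(arr), axis, length(pos_mm)))
  for (i in seq_along(slices)) {
    switch(axis,
           out[i, , ] <- slices[[i]],
           out[, i, ] <- slices[[i]],
           out[, , i] <- slices[[i]])
  }
  out
}

#' Resample a volume/mask pair to a target spacing
#'
#' The image is linearly interpolated. The mask uses nearest-neighbour when
#' upsampling and box occupancy (>= 50 % of covered source voxels inside)
#' when downsampling — plain nearest-neighbour on a coarse grid quantizes
#' the lesion by whole slices and can change its volume by far more than
#' thick-slice partial-volume reconstruction does. The new grid covers the
#' old physical extent; voxel centres sit at `(0:(n-1)) * spacing`.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] or `NULL`.
#' @param target_spacing numeric length-3 (mm).
#' @return List with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target_spacing) {
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(target_spacing <= 0)) stop("target_spacing must be > 0")
  if (isTRUE(all.equal(target_spacing, volume$spacing)))
    return(list(volume = volume, mask = mask))
  d <- dim(volume$data)
  out_img <- volume$data
  out_msk <- if (!is.null(mask)) array(as.numeric(mask$data), dim = d) else NULL
  for (ax in 1:3) {
    if (target_spacing[ax] == volume$spacing[ax]) next
    extent <- (d[ax] - 1) * volume$spacing[ax]
    n_new <- max(1L, floor(extent / target_spacing[ax]) + 1L)
    pos <- (seq_len(n_new) - 1) * target_spacing[ax]
    out_img <- resample_axis_linear(out_img, ax, volume$spacing[ax], pos)
    if (!is.null(out_msk)) {
      if (target_spacing[ax] > volume$spacing[ax]) {
        out_msk <- resample_axis_box(out_msk, ax, volume$spacing[ax], pos,
                                     target_spacing[ax])
      } else {
        # nearest neighbour: snap positions to the closest source voxel
        nn_pos <- round(pos / volume$spacing[ax]) * volume$spacing[ax]
        out_msk <- resample_axis_linear(out_msk, ax, volume$spacing[ax],
                                        nn_pos)
      }
    }
  }
  list(volume = image_volume(out_img, target_spacing),
       mask = if (!is.null(out_msk))
         roi_mask(out_msk >= 0.5, target_spacing) else NULL)
}

#' Run the full preprocessing chain on a lesion sample
#'
#' Fixed order: window/level, histogram equalization, Gaussian denoising,
#' maximum-area slab selection. Spacing metadata is carried through
#' unchanged (no resampling happens here).
#'
#' @param sample a [lesion_sample()].
#' @param config a [preprocess_config()].
#' @return A preprocessed [lesion_sample()] whose volume holds normalized
#'   intensities in `[0, 1]` on the selected slab.
#' @export
preprocess_sample <- function(sample, config = preprocess_config()) {
  v <- window_level(sample$volume, config, sample$mask)
  if (config$equalize) v <- equalize_histogram(v, config$equalize_bins)
  if (config$gauss_sigma_mm > 0) v <- gaussian_denoise(v, config$gauss_sigma_mm)
  slab <- select_max_area_slices(v, sample$mask, config$n_slices)
  out <- lesion_sample(slab$volume, slab$mask, sample$subject_id,
                       sample$replicate, sample$label)
  attr(out, "meta") <- attr(sample, "meta")
  out
}
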