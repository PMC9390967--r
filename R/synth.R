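# Synthetic CT-lesion cohorts: ellipsoidal lesions carved into a homogeneous
# lung-like background, with class-dependent Gaussian-random-field texture,
# additive acquisition ("quantum") noise, and same-day test-retest replicates.
# All randomness flows from one seed through derive_subseed().

#' Derive a reproducible sub-seed
#'
#' Lehmer-style mixing of a parent seed and an index; used so that every
#' subject / replicate in a cohort gets an independent, reproducible stream.
#' Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed integer parent seed.
#' @param index non-negative integer (subject number, replicate slot, ...).
#' @return integer sub-seed.
#' @export
derive_subseed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (k in c(index + 1, 7919)) {
    s <- (s * 48271 + k) %% m
  }
  as.integer(s)
}

#' Lesion generator parameters
#'
#' @param semiaxes_mm positive length-3: ellipsoid semi-axes (mm).
#' @param center_mm length-3 lesion centre in physical coordinates (mm);
#'   `NULL` centres the lesion in the grid.
#' @param mean_hu mean in-lesion intensity (HU).
#' @param texture_corr_mm correlation length (FWHM, mm) of the Gaussian
#'   random field that models intra-tumour texture.
#' @param texture_sd_hu standard deviation of the texture field (HU).
#' @param noise_sd_hu SD of additive i.i.d. Gaussian acquisition noise (HU).
#' @param background_hu intensity outside the lesion (default -800, aerated
#'   lung parenchyma).
#' @param rim_mm width of the peritumoral rim beyond the ROI surface over
#'   which intensities stay tumour-like (default 3). Models infiltrative
#'   margins, partial-volume and respiratory blur: the drawn contour does
#'   not step off a cliff into pure air.
#' @param rim_decay_mm width of the smooth (raised-cosine) transition from
#'   rim intensity down to background (default 3).
#' @return A `lesion_params` list.
#' @export
lesion_params <- function(semiaxes_mm = c(9, 8, 7), center_mm = NULL,
                          mean_hu = 40, texture_corr_mm = 3,
                          texture_sd_hu = 40, noise_sd_hu = 10,
                          background_hu = -800, rim_mm = 3,
                          rim_decay_mm = 3) {
  semiaxes_mm <- as.numeric(semiaxes_mm)
  if (length(semiaxes_mm) != 3L || any(semiaxes_mm <= 0))
    stop("semiaxes_mm must be 3 positive lengths")
  if (texture_sd_hu < 0) stop("texture_sd_hu must be >= 0")
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0")
  structure(list(semiaxes_mm = semiaxes_mm, center_mm = center_mm,
                 mean_hu = mean_hu, texture_corr_mm = texture_corr_mm,
                 texture_sd_hu = texture_sd_hu, noise_sd_hu = noise_sd_hu,
                 background_hu = background_hu, rim_mm = rim_mm,
                 rim_decay_mm = rim_decay_mm),
            class = "lesion_params")
}

#' Cohort specification
#'
#' Defaults mirror an imbalanced immunotherapy-response cohort of 157
#' subjects (124 responsive / 33 unresponsive) scanned at 0.75 mm in-plane
#' resolution. The two classes differ in texture correlation length, the
#' handle the rest of the pipeline is asked to recover.
#'
#' @param n_responsive,n_unresponsive class sizes.
#' @param params_responsive,params_unresponsive [lesion_params()] per class.
#' @param spacing_mm voxel spacing (mm); default `c(0.75, 0.75, 3)` with the
#'   slice axis last: 3 mm sits mid-range of the 1-5 mm acquisition
#'   protocol, so slice-spacing perturbations move both up and down.
#' @param shape grid dimensions (voxels).
#' @param jitter_size SD of the per-subject lognormal jitter on semi-axes
#'   (default 0.35: lesion volumes span roughly a decade, as RECIST
#'   target-lesion cohorts do). Semi-axes are clamped so lesion + retest
#'   shift + ROI dilation stay inside the grid.
#' @param jitter_hu SD (HU) of the per-subject additive jitter on `mean_hu`
#'   (default 40, emulating variable contrast enhancement).
#' @param jitter_texture SD of the per-subject lognormal jitter on
#'   `texture_sd_hu` (default 0.3).
#' @param seed integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_responsive = 124, n_unresponsive = 33,
                        params_responsive = lesion_params(texture_corr_mm = 4.5),
                        params_unresponsive = lesion_params(texture_corr_mm = 1.5),
                        spacing_mm = c(0.75, 0.75, 3),
                        shape = c(40, 40, 12),
                        jitter_size = 0.35, jitter_hu = 40,
                        jitter_texture = 0.3, seed = 1L) {
  if (n_responsive < 0 || n_unresponsive < 0) stop("class counts must be >= 0")
  structure(list(n_responsive = as.integer(n_responsive),
                 n_unresponsive = as.integer(n_unresponsive),
                 params_responsive = params_responsive,
                 params_unresponsive = params_unresponsive,
                 spacing_mm = as.numeric(spacing_mm),
                 shape = as.integer(shape),
                 jitter_size = jitter_size, jitter_hu = jitter_hu,
                 jitter_texture = jitter_texture, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Gaussian random field: white noise smoothed with a Gaussian kernel of
# FWHM = corr_mm, renormalized so the marginal SD equals sd_hu exactly in
# expectation. Circular (FFT) convolution; fine for fields much smaller than
# the grid period.
grf_field <- function(shape, spacing, corr_mm, sd_hu) {
  w <- array(rnorm(prod(shape)), dim = shape)
  if (sd_hu == 0) return(array(0, dim = shape))
  if (corr_mm <= 0) return(w * sd_hu)
  sigma_vox <- (corr_mm / 2.35482) / spacing
  ks <- lapply(1:3, function(ax) {
    n <- shape[ax]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))   # circular offsets
    k <- exp(-x^2 / (2 * sigma_vox[ax]^2))
    k / sum(k)
  })
  k3 <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  sm <- Re(fft(fft(w) * fft(k3), inverse = TRUE)) / prod(shape)
  sm * (sd_hu / sqrt(sum(k3^2)))
}

# physical voxel-centre coordinates along one axis (0-based, mm)
axis_coords <- function(n, sp) (seq_len(n) - 1) * sp

#' Generate one synthetic lesion
#'
#' Carves an ellipsoidal ROI into a homogeneous background and fills it with
#' `mean_hu` plus a Gaussian-random-field texture; i.i.d. Gaussian
#' acquisition noise is added everywhere. Deterministic given `seed`.
#'
#' @param params a [lesion_params()].
#' @param spacing voxel spacing (mm).
#' @param shape grid dimensions.
#' @param seed integer seed.
#' @param subject_id,label,replicate metadata passed to [lesion_sample()].
#' @return A [lesion_sample()]; generator provenance is kept in
#'   `attr(, "meta")` so test-retest replicates can re-realize the same
#'   underlying lesion.
#' @export
generate_lesion <- function(params, spacing = c(0.75, 0.75, 3),
                            shape = c(40, 40, 12), seed = 1L,
                            subject_id = "synthetic", label = NA_integer_,
                            replicate = "baseline") {
  stopifnot(inherits(params, "lesion_params"))
  spacing <- as.numeric(spacing); shape <- as.integer(shape)
  extent <- (shape - 1) * spacing
  ctr <- if (is.null(params$center_mm)) extent / 2 else as.numeric(params$center_mm)
  for (ax in 1:3) {
    if (ctr[ax] - params$semiaxes_mm[ax] < 0 ||
        ctr[ax] + params$semiaxes_mm[ax] > extent[ax])
      stop(sprintf("ellipsoid exceeds the grid along axis %d (%s)",
                   ax, c("x", "y", "z")[ax]))
  }
  cx <- axis_coords(shape[1], spacing[1])
  cy <- axis_coords(shape[2], spacing[2])
  cz <- axis_coords(shape[3], spacing[3])
  q <- outer(outer(((cx - ctr[1]) / params$semiaxes_mm[1])^2,
                   ((cy - ctr[2]) / params$semiaxes_mm[2])^2, "+"),
             ((cz - ctr[3]) / params$semiaxes_mm[3])^2, "+")
  mask <- q <= 1

  # lesion-intensity weight: 1 inside the ROI and through the peritumoral
  # rim, then raised-cosine decay to background. d = physical distance
  # beyond the ellipsoid surface along the ray from the centre.
  rho <- sqrt(outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, "+"),
                    (cz - ctr[3])^2, "+"))
  d_out <- ifelse(q > 1, rho * (1 - 1 / sqrt(pmax(q, 1))), 0)
  w <- ifelse(d_out <= params$rim_mm, 1,
              0.5 * (1 + cos(pi * pmin((d_out - params$rim_mm) /
                                         max(params$rim_decay_mm, 1e-9), 1))))

  field_seed <- derive_subseed(seed, 0L)
  noise_seed <- derive_subseed(seed, 1L)
  set.seed(field_seed)
  tex <- grf_field(shape, spacing, params$texture_corr_mm, params$texture_sd_hu)
  img <- params$background_hu + (params$mean_hu + tex - params$background_hu) * w
  set.seed(noise_seed)
  if (params$noise_sd_hu > 0)
    img <- img + array(rnorm(prod(shape), sd = params$noise_sd_hu), dim = shape)

  s <- lesion_sample(image_volume(img, spacing), roi_mask(mask, spacing),
                     subject_id = subject_id, replicate = replicate,
                     label = label)
  attr(s, "meta") <- list(params = params, spacing = spacing, shape = shape,
                          seed = seed)
  s
}

#' Generate a synthetic cohort
#'
#' One lesion per subject; per-subject geometry (semi-axes, mean HU) is
#' jittered around the class parameters, all driven by per-subject sub-seeds
#' of `spec$seed`. Responsive subjects (label 1) come first.
#'
#' @param spec a [cohort_spec()].
#' @return A list of [lesion_sample()]s of length
#'   `n_responsive + n_unresponsive`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_responsive + spec$n_unresponsive
  if (n == 0) return(list())
  labels <- c(rep(1L, spec$n_responsive), rep(0L, spec$n_unresponsive))
  # largest semi-axis that still leaves room for a 2 mm ROI dilation and a
  # 1-voxel retest shift inside the grid
  extent <- (spec$shape - 1) * spec$spacing_mm
  cap <- extent / 2 - 3 - spec$spacing_mm
  out <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (labels[i] == 1L) spec$params_responsive else spec$params_unresponsive
    sseed <- derive_subseed(spec$seed, i)
    set.seed(derive_subseed(sseed, 999L))
    p <- base
    # one common size factor + mild per-axis anisotropy jitter
    size_f <- exp(rnorm(1, sd = spec$jitter_size))
    p$semiaxes_mm <- pmin(pmax(base$semiaxes_mm * size_f *
                                 exp(rnorm(3, sd = 0.08)), 2.5), cap)
    p$mean_hu <- base$mean_hu + rnorm(1, sd = spec$jitter_hu)
    p$texture_sd_hu <- base$texture_sd_hu * exp(rnorm(1, sd = spec$jitter_texture))
    out[[i]] <- generate_lesion(p, spacing = spec$spacing_mm,
                                shape = spec$shape, seed = sseed,
                                subject_id = sprintf("subj%03d", i),
                                label = labels[i])
  }
  out
}

# trilinear shift of an array by a (sub-voxel) offset, constant fill outside
shift_trilinear <- function(arr, shift_vox, fill) {
  d <- dim(arr)
  lo <- floor(shift_vox); fr <- shift_vox - lo
  pad <- function(a, off) {
    # integer shift by off with constant fill
    idx <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]) - off[ax]
      i[i < 1 | i > d[ax]] <- NA
      i
    })
    out <- array(fill, dim = d)
    ok <- lapply(idx, function(i) which(!is.na(i)))
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      a[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]]]
    out
  }
  acc <- array(0, dim = d)
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    w <- prod(ifelse(c(bx, by, bz) == 1, fr, 1 - fr))
    if (w > 0) acc <- acc + w * pad(arr, lo + c(bx, by, bz))
  }
  acc
}

#' Generate a test-retest replicate pair
#'
#' Re-realizes the same underlying lesion (identical texture field), applies
#' a small random rigid shift (uniform in `[-1, 1]` voxel per axis, trilinear
#' interpolation) to model repositioning between scans taken minutes apart,
#' and draws fresh acquisition noise.
#'
#' @param sample a baseline [lesion_sample()] produced by [generate_lesion()].
#' @param seed integer seed for the retest realization.
#' @param max_shift_vox maximum |shift| per axis in voxels (0 disables).
#' @return List of two samples: the baseline (tag `"baseline"`) and the
#'   retest replicate (tag `"retest"`).
#' @export
generate_test_retest_pair <- function(sample, seed = 1L, max_shift_vox = 1) {
  meta <- attr(sample, "meta")
  if (is.null(meta)) stop("sample carries no generator metadata")
  p <- meta$params
  set.seed(derive_subseed(seed, 2L))
  shift <- if (max_shift_vox > 0) runif(3, -max_shift_vox, max_shift_vox) else c(0, 0, 0)

  # clean (noiseless) baseline field, from the same field seed
  clean_p <- p; clean_p$noise_sd_hu <- 0
  clean <- generate_lesion(clean_p, meta$spacing, meta$shape, meta$seed,
                           sample$subject_id, sample$label)
  img <- shift_trilinear(clean$volume$data, shift, fill = p$background_hu)
  mvox <- array(as.numeric(clean$mask$data), dim = meta$shape)
  mask <- shift_trilinear(mvox, shift, fill = 0) >= 0.5
  if (!any(mask)) mask <- clean$mask$data   # degenerate tiny-mask guard
  set.seed(derive_subseed(seed, 3L))
  if (p$noise_sd_hu > 0)
    img <- img + array(rnorm(prod(meta$shape), sd = p$noise_sd_hu),
                       dim = meta$shape)
  retest <- lesion_sample(image_volume(img, meta$spacing),
                          roi_mask(mask, meta$spacing),
                          subject_id = sample$subject_id,
                          replicate = "retest", label = sample$label)
  base <- sample; base$replicate <- "baseline"
  list(baseline = base, retest = retest)
}

#' Write a cohort to disk as NIfTI pairs plus a manifest CSV
#'
#' @param cohort list of [lesion_sample()]s.
#' @param dir output directory (created if needed).
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, compress = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- lapply(cohort, function(s) {
    stem <- sprintf("%s_%s", s$subject_id, gsub("[^A-Za-z0-9._-]", "-", s$replicate))
    vp <- file.path(dir, paste0(stem, "_image", ext))
    mp <- file.path(dir, paste0(stem, "_mask", ext))
    write_nifti(s$volume, vp)
    write_nifti(s$mask, mp)
    data.frame(subject_id = s$subject_id, replicate = s$replicate,
               label = s$label, image = vp, mask = mp,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "cohort_manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to `cohort_manifest.csv`.
#' @return List of [lesion_sample()]s.
#' @export
read_cohort <- function(manifest_path) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    lesion_sample(read_nifti(man$image[i]),
                  read_nifti(man$mask[i], as_mask = TRUE),
                  subject_id = man$subject_id[i],
                  replicate = man$replicate[i],
                  label = if (is.na(man$label[i])) NA_integer_ else man$label[i])
  })
}
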