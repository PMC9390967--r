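# Perturbation families used for robustness testing, emulating multicentre
# variability: S (axial slice thickness), R (in-plane rotation), Seg (ROI
# contour variation). None of them ever touches the subject id or label.

#' Default perturbation grids
#'
#' S: slice thicknesses 1, 2, 3, 5 mm. R: rotations -30, -15, 15, 30 degrees.
#' Seg: ROI enlargement and shrinking with a 2 mm ball (approximate
#' inter-observer contouring variability).
#'
#' @param spacing_mm thicknesses for S.
#' @param angles_deg angles for R.
#' @param seg_radius_mm morphology radius for Seg.
#' @return Named list of family parameter vectors/specs.
#' @export
perturbation_defaults <- function(spacing_mm = c(1, 2, 3, 5),
                                  angles_deg = c(-30, -15, 15, 30),
                                  seg_radius_mm = 2) {
  list(S = spacing_mm, R = angles_deg,
       Seg = list(modes = c("enlarge", "shrink"), radius_mm = seg_radius_mm))
}

#' Slice-spacing perturbation (family S)
#'
#' Resamples volume and mask along the axial axis to the target slice
#' thickness (linear / nearest-neighbour interpolation); in-plane spacing is
#' untouched. Replicate tag becomes `"S:<mm>"`.
#'
#' @param sample a [lesion_sample()].
#' @param thickness_mm target slice thickness (mm).
#' @return Perturbed [lesion_sample()].
#' @export
perturb_spacing <- function(sample, thickness_mm) {
  if (thickness_mm <= 0) stop("thickness_mm must be > 0")
  sp <- sample$volume$spacing
  extent <- (dim(sample$volume$data)[3] - 1) * sp[3]
  if (extent < thickness_mm)
    stop(sprintf("slab z-extent %.1f mm thinner than one %.1f mm slice",
                 extent, thickness_mm))
  tgt <- c(sp[1], sp[2], thickness_mm)
  res <- resample_isotropic(sample$volume, sample$mask, tgt)
  if (!any(res$mask$data)) stop("spacing perturbation annihilated the mask for ",
                                sample$subject_id)
  out <- lesion_sample(res$volume, res$mask, sample$subject_id,
                       sprintf("S:%g", thickness_mm), sample$label)
  attr(out, "meta") <- attr(sample, "meta")
  out
}

# bilinear in-plane rotation of one 2-D matrix about physical point ctr (mm)
rotate_plane <- function(M, sp_xy, ctr, theta_deg, fill, nearest = FALSE) {
  th <- theta_deg * pi / 180
  d <- dim(M)
  gx <- (seq_len(d[1]) - 1) * sp_xy[1]
  gy <- (seq_len(d[2]) - 1) * sp_xy[2]
  X <- matrix(gx, d[1], d[2]) - ctr[1]
  Y <- matrix(gy, d[1], d[2], byrow = TRUE) - ctr[2]
  # inverse mapping: source = R(-theta) (target - c) + c
  sx <- (cos(th) * X + sin(th) * Y + ctr[1]) / sp_xy[1]
  sy <- (-sin(th) * X + cos(th) * Y + ctr[2]) / sp_xy[2]
  if (nearest) {
    i <- round(sx) + 1; j <- round(sy) + 1
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    out <- matrix(fill, d[1], d[2])
    out[ok] <- M[cbind(i[ok], j[ok])]
    return(out)
  }
  i0 <- floor(sx); j0 <- floor(sy)
  fi <- sx - i0; fj <- sy - j0
  out <- matrix(0, d[1], d[2]); wsum <- matrix(0, d[1], d[2])
  for (bi in 0:1) for (bj in 0:1) {
    ii <- i0 + bi + 1; jj <- j0 + bj + 1
    w <- (bi * fi + (1 - bi) * (1 - fi)) * (bj * fj + (1 - bj) * (1 - fj))
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    idx <- cbind(ii[ok], jj[ok])
    out[ok] <- out[ok] + w[ok] * M[idx]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  miss <- wsum < 0.999
  out[miss] <- fill
  out[!miss] <- out[!miss] / wsum[!miss]
  out
}

#' In-plane rotation perturbation (family R)
#'
#' Rotates image (bilinear) and mask (nearest-neighbour) in the axial plane
#' about the mask centroid; out-of-grid regions are filled with the
#' background intensity (the in-plane minimum by default) rather than zero
#' to avoid fake edges. Grid shape is unchanged.
#'
#' @param sample a [lesion_sample()].
#' @param theta_deg rotation angle in degrees.
#' @param fill background fill value; `NULL` uses the volume minimum.
#' @return Perturbed [lesion_sample()] tagged `"R:<deg>"`.
#' @export
perturb_rotation <- function(sample, theta_deg, fill = NULL) {
  if (theta_deg == 0) {
    out <- lesion_sample(sample$volume, sample$mask, sample$subject_id,
                         "R:0", sample$label)
    attr(out, "meta") <- attr(sample, "meta")
    return(out)
  }
  sp <- sample$volume$spacing
  if (is.null(fill)) {
    meta <- attr(sample, "meta")
    fill <- if (!is.null(meta)) meta$params$background_hu else min(sample$volume$data)
  }
  idx <- which(sample$mask$data, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1) * sp[1:2]
  d <- dim(sample$volume$data)
  img <- sample$volume$data; msk <- sample$mask$data
  for (z in seq_len(d[3])) {
    img[, , z] <- rotate_plane(img[, , z], sp[1:2], ctr, theta_deg, fill)
    msk[, , z] <- rotate_plane(msk[, , z], sp[1:2], ctr, theta_deg, FALSE,
                               nearest = TRUE)
  }
  out <- lesion_sample(image_volume(img, sp), roi_mask(msk, sp),
                       sample$subject_id, sprintf("R:%g", theta_deg),
                       sample$label)
  attr(out, "meta") <- attr(sample, "meta")
  out
}

# offsets (voxels) of a ball of physical radius r_mm under spacing sp
ball_offsets <- function(r_mm, sp) {
  rv <- floor(r_mm / sp)
  off <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  keep <- (off$dx * sp[1])^2 + (off$dy * sp[2])^2 + (off$dz * sp[3])^2 <= r_mm^2
  as.matrix(off[keep, , drop = FALSE])
}

# shift a logical array by integer offset, FALSE outside
shift_logical <- function(m, off) {
  d <- dim(m)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(array(FALSE, dim = d))
    src[[ax]] <- if (o >= 0) 1:(d[ax] - o) else (1 - o):d[ax]
    dst[[ax]] <- if (o >= 0) (1 + o):d[ax] else 1:(d[ax] + o)
  }
  out <- array(FALSE, dim = d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Morphological ROI perturbation (family Seg)
#'
#' Dilates (`"enlarge"`) or erodes (`"shrink"`) the mask with a ball
#' structuring element of physical radius `radius_mm`; the image is
#' untouched. Models inter-observer contouring variability.
#'
#' @param sample a [lesion_sample()].
#' @param mode `"enlarge"` or `"shrink"`.
#' @param radius_mm ball radius in mm.
#' @return Perturbed [lesion_sample()] tagged `"Seg:<mode><mm>"`.
#' @export
perturb_roi <- function(sample, mode = c("enlarge", "shrink"), radius_mm = 2) {
  mode <- match.arg(mode)
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  sp <- sample$mask$spacing
  offs <- ball_offsets(radius_mm, sp)
  m <- sample$mask$data
  if (mode == "enlarge") {
    out <- array(FALSE, dim = dim(m))
    for (r in seq_len(nrow(offs))) out <- out | shift_logical(m, offs[r, ])
  } else {
    out <- array(TRUE, dim = dim(m))
    for (r in seq_len(nrow(offs))) out <- out & shift_logical(m, offs[r, ])
    if (!any(out))
      stop("erosion annihilated the mask of sample ", sample$subject_id)
  }
  res <- lesion_sample(sample$volume, roi_mask(out, sp), sample$subject_id,
                       sprintf("Seg:%s%g", mode, radius_mm), sample$label)
  attr(res, "meta") <- attr(sample, "meta")
  res
}

#' Build the full perturbation set for one sample
#'
#' For each requested family, returns the original sample plus every
#' perturbed version; defaults give 4 (S) / 4 (R) / 2 (Seg) perturbed
#' versions per family.
#'
#' @param sample a [lesion_sample()].
#' @param specs list as returned by [perturbation_defaults()]; families may
#'   be omitted or have empty parameter sets.
#' @return Named list: family -> list of [lesion_sample()]s (original first).
#' @export
build_perturbation_set <- function(sample, specs = perturbation_defaults()) {
  out <- list()
  for (fam in names(specs)) {
    versions <- list(sample)
    if (fam == "S") {
      for (th in specs$S) versions <- c(versions, list(perturb_spacing(sample, th)))
    } else if (fam == "R") {
      for (a in specs$R) versions <- c(versions, list(perturb_rotation(sample, a)))
    } else if (fam == "Seg") {
      for (md in specs$Seg$modes)
        versions <- c(versions, list(perturb_roi(sample, md, specs$Seg$radius_mm)))
    } else stop("unknown perturbation family: ", fam)
    out[[fam]] <- versions
  }
  out
}
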