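# Discretization and first-order / shape feature classes. All texture
# classes consume the integer gray-level map produced by discretize().

#' Discretization configuration
#'
#' @param mode `"fixed_bin_width"` (default) or `"fixed_bin_count"`.
#' @param bin_width intensity bin width (default 25, the common radiomics
#'   default on a 0-255 display-scaled image).
#' @param bin_count number of bins for fixed-count mode.
#' @return A `discretization_config` list.
#' @export
discretization_config <- function(mode = c("fixed_bin_width", "fixed_bin_count"),
                                  bin_width = 25, bin_count = 32) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_width" && bin_width <= 0) stop("bin_width must be > 0")
  if (mode == "fixed_bin_count" && bin_count < 2) stop("bin_count must be >= 2")
  structure(list(mode = mode, bin_width = bin_width, bin_count = bin_count),
            class = "discretization_config")
}

#' Discretize in-mask intensities to integer gray levels
#'
#' Fixed-bin-width mode maps voxel `v` to `floor((v - min) / width) + 1`
#' with `min` the in-mask minimum; fixed-bin-count divides the in-mask range
#' into `bin_count` equal bins (top edge inclusive). Out-of-mask voxels get
#' level 0. A constant ROI yields a single level (`ng = 1`).
#'
#' @param data 3-D numeric array.
#' @param mask logical array of the same shape.
#' @param config a [discretization_config()].
#' @return List with `levels` (integer array, 0 outside mask) and `ng`.
#' @export
discretize <- function(data, mask, config = discretization_config()) {
  if (!any(mask)) stop("mask is empty")
  v <- data[mask]
  lv <- array(0L, dim = dim(data))
  if (config$mode == "fixed_bin_width") {
    l <- floor((v - min(v)) / config$bin_width) + 1
  } else {
    rng <- max(v) - min(v)
    if (rng == 0) l <- rep(1, length(v))
    else l <- pmin(floor((v - min(v)) / (rng / config$bin_count)) + 1,
                   config$bin_count)
  }
  lv[mask] <- as.integer(l)
  list(levels = lv, ng = max(1L, as.integer(max(l))))
}

# quantile convention: type 7 (linear interpolation, the numpy default)
q7 <- function(x, p) as.numeric(quantile(x, p, type = 7, names = FALSE))

#' First-order (intensity histogram) features
#'
#' 18 features on the raw in-mask intensities. Entropy and Uniformity use
#' the discretized histogram; percentiles use linear interpolation;
#' Skewness / Kurtosis / Variance are population moments (Kurtosis is not
#' excess-corrected). A zero-variance ROI gives Skewness = Kurtosis = 0.
#'
#' @param data,mask numeric/logical arrays.
#' @param spacing voxel spacing (mm) for Total Energy.
#' @param disc a [discretization_config()].
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(data, mask, spacing,
                                disc = discretization_config()) {
  x <- data[mask]
  n <- length(x)
  vv <- prod(spacing)
  dd <- discretize(data, mask, disc)
  p <- tabulate(dd$levels[mask], nbins = dd$ng) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  p10 <- q7(x, 0.10); p90 <- q7(x, 0.90)
  sub <- x[x >= p10 & x <= p90]
  c(Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = p10,
    `90Percentile` = p90,
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = q7(x, 0.75) - q7(x, 0.25),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' Shape features (3-D)
#'
#' 14 features from the binary ROI only. Mesh area/volume come from a
#' marching-tetrahedra iso-surface at level 0.5 (vertices at voxel-edge
#' midpoints); maximum diameters use boundary-voxel centres; axis lengths
#' come from the eigenvalues `l1 >= l2 >= l3` of the sample covariance of
#' physical voxel-centre coordinates (`axis = 4 * sqrt(l)`).
#'
#' @param mask logical array.
#' @param spacing voxel spacing (mm).
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  mv <- cpp_mesh_area_volume(as.logical(mask), as.integer(d),
                             as.numeric(spacing))
  dia <- cpp_max_diameters(as.logical(mask), as.integer(d),
                           as.numeric(spacing))
  n <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, spacing, `*`)
  ev <- if (n >= 2) {
    sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                    only.values = TRUE)$values, 0), decreasing = TRUE)
  } else c(0, 0, 0)
  A <- mv$area; V <- mv$volume
  c(MeshVolume = V,
    VoxelVolume = n * prod(spacing),
    SurfaceArea = A,
    SurfaceVolumeRatio = if (V > 0) A / V else 0,
    Sphericity = if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0,
    Maximum3DDiameter = dia[1],
    Maximum2DDiameterSlice = dia[2],
    Maximum2DDiameterColumn = dia[3],
    Maximum2DDiameterRow = dia[4],
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}
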