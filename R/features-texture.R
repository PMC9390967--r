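# Texture feature classes. Gray-level matrices are built in C++ over the 13
# unique 3-D directions (distance 1); GLCM and GLRLM features are computed
# per direction and averaged over non-empty directions, GLSZM/GLDM/NGTDM use
# a single aggregated matrix. Degenerate inputs (single gray level) follow
# documented conventions and never yield NA.

#' Gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence counts at distance 1 over the 13 unique 3-D
#' directions.
#'
#' @param levels integer gray-level array (0 outside the ROI).
#' @param ng number of gray levels.
#' @return `ng x ng x 13` array of counts.
#' @export
glcm_matrix <- function(levels, ng) {
  cpp_glcm(as.integer(levels), as.integer(dim(levels)), as.integer(ng))
}

#' Build the GLRLM, GLSZM, GLDM and NGTDM raw matrices
#'
#' GLRLM: run lengths over 13 directions. GLSZM: 26-connected equal-level
#' zones. GLDM: dependence counts (26-neighbourhood, `|level diff| <= alpha`,
#' dependence size = 1 + dependent neighbours). NGTDM: neighbourhood
#' gray-tone difference sums over the 26-neighbourhood.
#'
#' @param levels integer gray-level array (0 outside the ROI).
#' @param ng number of gray levels.
#' @param gldm_alpha GLDM dependence tolerance (default 0).
#' @return List with elements `glrlm`, `glszm`, `gldm`, `ngtdm`.
#' @export
texture_matrices <- function(levels, ng, gldm_alpha = 0) {
  lv <- as.integer(levels); dm <- as.integer(dim(levels)); ng <- as.integer(ng)
  list(glrlm = cpp_glrlm(lv, dm, ng),
       glszm = cpp_glszm(lv, dm, ng),
       gldm = cpp_gldm(lv, dm, ng, as.integer(gldm_alpha)),
       ngtdm = cpp_ngtdm(lv, dm, ng))
}

# entropy helper, log base 2, 0 log 0 = 0
h2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

# ---- GLCM -------------------------------------------------------------------

glcm_features_one <- function(P) {
  # P: normalized symmetric ng x ng matrix for one direction
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(px * seq_len(ng)); muy <- sum(py * seq_len(ng))
  sx <- sqrt(sum(px * (seq_len(ng) - mux)^2))
  sy <- sqrt(sum(py * (seq_len(ng) - muy)^2))
  # difference and sum distributions
  k_d <- 0:(ng - 1)
  pd <- vapply(k_d, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * ng)
  ps <- vapply(k_s, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(pd * k_d)
  # information measures
  hxy <- h2(P)
  hx <- h2(px); hy <- h2(py)
  pxpy <- outer(px, py)
  ok <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[ok] * log2(pxpy[ok]))
  hxy2 <- h2(pxpy)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  # MCC: second largest eigenvalue of Q
  mcc <- 1
  if (ng > 1) {
    nzx <- px > 0
    if (sum(nzx) > 1) {
      Q <- matrix(0, ng, ng)
      for (ii in which(nzx)) {
        Q[ii, ] <- colSums(t(P) * P[ii, ] / pmax(py, .Machine$double.xmin)) / px[ii]
      }
      evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      mcc <- if (length(evq) >= 2) sqrt(max(evq[2], 0)) else 1
    }
  }
  offd <- abs(i - j) > 0
  c(Autocorrelation = sum(P * i * j),
    ClusterProminence = sum(P * (i + j - mux - muy)^4),
    ClusterShade = sum(P * (i + j - mux - muy)^3),
    ClusterTendency = sum(P * (i + j - mux - muy)^2),
    Contrast = sum(P * (i - j)^2),
    Correlation = if (sx * sy > 0) (sum(P * i * j) - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = h2(pd),
    DifferenceVariance = sum(pd * (k_d - da)^2),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (any(offd)) sum(P[offd] / (i - j)[offd]^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ps * k_s),
    SumEntropy = h2(ps),
    SumSquares = sum(P * (i - mux)^2))
}

#' GLCM features (24), averaged over directions
#'
#' Each of the 13 direction matrices is normalized and scored separately;
#' the feature value is the mean over directions with at least one
#' co-occurring pair.
#'
#' @param counts `ng x ng x 13` count array from [glcm_matrix()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(counts) {
  ng <- dim(counts)[1]
  vals <- NULL
  for (d in seq_len(dim(counts)[3])) {
    M <- counts[, , d, drop = FALSE]
    dim(M) <- c(ng, ng)
    tot <- sum(M)
    if (tot == 0) next
    vals <- rbind(vals, glcm_features_one(M / tot))
  }
  if (is.null(vals)) {   # single isolated voxel: no co-occurrences at all
    vals <- rbind(glcm_features_one(matrix(1, 1, 1)))
  }
  colMeans(vals)
}

# ---- GLRLM ------------------------------------------------------------------

glrlm_features_one <- function(P, np) {
  ng <- nrow(P); nl <- ncol(P)
  nr <- sum(P)
  i <- matrix(seq_len(ng), ng, nl); j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  pr <- P / nr
  mu_i <- sum(pr * i); mu_j <- sum(pr * j)
  gl <- rowSums(P); rl <- colSums(P)
  c(ShortRunEmphasis = sum(P / j^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(gl^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gl^2) / nr^2,
    RunLengthNonUniformity = sum(rl^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(pr * (i - mu_i)^2),
    RunVariance = sum(pr * (j - mu_j)^2),
    RunEntropy = h2(pr),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

#' GLRLM features (16), averaged over the 13 directions
#'
#' @param counts `ng x maxlen x 13` run-length count array.
#' @param np number of in-mask voxels.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(counts, np) {
  ng <- dim(counts)[1]; nl <- dim(counts)[2]
  vals <- NULL
  for (d in seq_len(dim(counts)[3])) {
    M <- counts[, , d, drop = FALSE]
    dim(M) <- c(ng, nl)
    if (sum(M) == 0) next
    vals <- rbind(vals, glrlm_features_one(M, np))
  }
  colMeans(vals)
}

# ---- GLSZM ------------------------------------------------------------------

#' GLSZM features (16)
#'
#' Same functional forms as the run-length class with zones in place of
#' runs (single aggregated matrix, no direction averaging).
#'
#' @param P `ng x maxsize` zone-count matrix.
#' @param np number of in-mask voxels.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(P, np) {
  ng <- nrow(P); ns <- ncol(P)
  nz <- sum(P)
  i <- matrix(seq_len(ng), ng, ns); j <- matrix(seq_len(ns), ng, ns, byrow = TRUE)
  pz <- P / nz
  mu_i <- sum(pz * i); mu_j <- sum(pz * j)
  gl <- rowSums(P); sz <- colSums(P)
  c(SmallAreaEmphasis = sum(P / j^2) / nz,
    LargeAreaEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(gl^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gl^2) / nz^2,
    SizeZoneNonUniformity = sum(sz^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sz^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(pz * (i - mu_i)^2),
    ZoneVariance = sum(pz * (j - mu_j)^2),
    ZoneEntropy = h2(pz),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}

# ---- GLDM -------------------------------------------------------------------

#' GLDM features (14)
#'
#' @param P `ng x 27` dependence-count matrix (column = dependence size).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(P) {
  ng <- nrow(P); nd <- ncol(P)
  nz <- sum(P)
  i <- matrix(seq_len(ng), ng, nd); j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  pd <- P / nz
  mu_i <- sum(pd * i); mu_j <- sum(pd * j)
  gl <- rowSums(P); dp <- colSums(P)
  c(SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(gl^2) / nz,
    DependenceNonUniformity = sum(dp^2) / nz,
    DependenceNonUniformityNormalized = sum(dp^2) / nz^2,
    GrayLevelVariance = sum(pd * (i - mu_i)^2),
    DependenceVariance = sum(pd * (j - mu_j)^2),
    DependenceEntropy = h2(pd),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}

# ---- NGTDM ------------------------------------------------------------------

#' NGTDM features (5)
#'
#' Conventions for degenerate inputs: Coarseness returns 1e6 when
#' `sum(p*s) = 0`; Contrast is 0 with a single occupied gray level;
#' Busyness and Strength return 0 on zero denominators.
#'
#' @param mats list with `n` (per-level voxel counts) and `s` (per-level
#'   absolute gray-tone difference sums), as built by [texture_matrices()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(mats) {
  n <- mats$n; s <- mats$s
  np <- sum(n)
  lev <- which(n > 0)
  p <- n / np
  ngp <- length(lev)
  ps_sum <- sum(p[lev] * s[lev])
  coarse <- if (ps_sum > 0) 1 / ps_sum else 1e6
  contrast <- 0
  if (ngp > 1) {
    cc <- 0
    for (a in lev) for (b in lev) cc <- cc + p[a] * p[b] * (a - b)^2
    contrast <- cc / (ngp * (ngp - 1)) * sum(s) / np
  }
  busy_den <- 0; complexity <- 0; strength_num <- 0
  for (a in lev) for (b in lev) {
    busy_den <- busy_den + abs(a * p[a] - b * p[b])
    complexity <- complexity +
      abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    strength_num <- strength_num + (p[a] + p[b]) * (a - b)^2
  }
  c(Coarseness = coarse,
    Contrast = contrast,
    Busyness = if (busy_den > 0) ps_sum / busy_den else 0,
    Complexity = complexity / np,
    Strength = if (sum(s) > 0) strength_num / sum(s) else 0)
}
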