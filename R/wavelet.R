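# One-level 3-D stationary (undecimated) wavelet transform with the coif1
# basis and circular boundary handling. Sub-bands keep the input shape, so
# the ROI mask stays aligned and texture matrices can be recomputed on each
# sub-band.

# coif1 analysis low-pass filter (6 taps); high-pass by quadrature mirror
coif1_dec_lo <- function() {
  c(-0.015655728135465137, -0.07273261951285112, 0.3848648468642029,
    0.8525720202122554, 0.3378976624578092, -0.07273261951285112)
}

coif1_dec_hi <- function() {
  lo <- coif1_dec_lo()
  L <- length(lo)
  ((-1)^(0:(L - 1))) * rev(lo)
}

# circular 1-D filtering along one axis of a 3-D array:
# y[n] = sum_k h[k] * x[(n + k - offset) mod N], offset = floor(L/2)
swt_filter_axis <- function(arr, h, axis) {
  d <- dim(arr)
  n <- d[axis]
  off <- length(h) %/% 2
  out <- array(0, dim = d)
  for (k in seq_along(h)) {
    idx <- ((seq_len(n) - 1 + (k - 1) - off) %% n) + 1
    sl <- switch(axis, arr[idx, , , drop = FALSE],
                 arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    out <- out + h[k] * sl
  }
  out
}

#' One-level 3-D stationary wavelet decomposition
#'
#' Applies the coif1 analysis filter pair along x, y and z (circular
#' boundaries, no decimation), yielding the 8 low/high-pass combinations.
#' Sub-band names are three letters, first letter = x axis; `L` = low-pass,
#' `H` = high-pass. Order: LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#'
#' @param volume an [image_volume()] (or plain 3-D array).
#' @return Named list of 8 sub-band arrays, each the shape of the input.
#' @export
wavelet_decompose <- function(volume) {
  arr <- if (inherits(volume, "image_volume")) volume$data else volume
  lo <- coif1_dec_lo(); hi <- coif1_dec_hi()
  bands <- list()
  for (bx in c("L", "H")) {
    ax <- swt_filter_axis(arr, if (bx == "L") lo else hi, 1)
    for (by in c("L", "H")) {
      axy <- swt_filter_axis(ax, if (by == "L") lo else hi, 2)
      for (bz in c("L", "H")) {
        bands[[paste0(bx, by, bz)]] <-
          swt_filter_axis(axy, if (bz == "L") lo else hi, 3)
      }
    }
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
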