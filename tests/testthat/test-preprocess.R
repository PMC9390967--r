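# preprocessing: windowing, equalization, denoising, slab selection,
# resampling

test_that("window_level clips and rescales affinely", {
  v <- image_volume(array(c(-1000, 0, 1000, 0, 0, 0, 0, 0),
                          dim = c(2, 2, 2)), c(1, 1, 1))
  cfg <- preprocess_config(window_mode = "fixed", window_center_hu = 0,
                           window_width_hu = 1000)
  out <- window_level(v, cfg)
  expect_equal(out$data[1, 1, 1], 0)     # clipped at -500 -> 0
  expect_equal(out$data[2, 1, 1], 0.5)
  expect_equal(out$data[1, 2, 1], 1)     # clipped at +500 -> 1
  # constant volume inside a window containing it stays constant
  cv <- image_volume(array(100, dim = c(3, 3, 3)), c(1, 1, 1))
  outc <- window_level(cv, preprocess_config("fixed", 0, 1000))
  expect_true(all(outc$data == outc$data[1]))
})

test_that("adaptive windowing uses ROI stats and falls back on zero variance", {
  set.seed(1)
  arr <- array(rnorm(1000, 50, 30), dim = c(10, 10, 10))
  v <- image_volume(arr, c(1, 1, 1))
  m <- roi_mask(array(TRUE, dim = dim(arr)), c(1, 1, 1))
  out <- window_level(v, preprocess_config("adaptive"), m)
  # oracle: direct clip-scale with mean +/- 3 SD
  lo <- mean(arr) - 3 * sd(arr); hi <- mean(arr) + 3 * sd(arr)
  oracle <- (pmin(pmax(arr, lo), hi) - lo) / (hi - lo)
  expect_equal(out$data, oracle)
  expect_true(all(out$data >= 0 & out$data <= 1))
  cv <- image_volume(array(7, dim = c(4, 4, 4)), c(1, 1, 1))
  cm <- roi_mask(array(TRUE, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_warning(window_level(cv, preprocess_config("adaptive"), cm),
                 "zero-variance")
})

test_that("histogram equalization maps through the empirical CDF", {
  # constant volume is returned unchanged
  cv <- image_volume(array(3, dim = c(2, 2, 2)), c(1, 1, 1))
  expect_equal(equalize_histogram(cv)$data, cv$data)
  # two-valued volume {a,a,a,b}: mapped values are the empirical CDF
  v <- image_volume(array(c(1, 1, 1, 5), dim = c(4, 1, 1)), c(1, 1, 1))
  out <- equalize_histogram(v, bins = 4)
  expect_equal(as.numeric(out$data), c(0.75, 0.75, 0.75, 1))
  # rank order is preserved on arbitrary input
  set.seed(2)
  r <- array(rnorm(240), dim = c(8, 6, 5))
  eq <- equalize_histogram(image_volume(r, c(1, 1, 1)))$data
  expect_true(all(diff(eq[order(r)]) >= -1e-12))
})

test_that("gaussian_denoise matches a direct convolution oracle", {
  expect_identical(gaussian_denoise(image_volume(array(rnorm(27), dim = c(3, 3, 3)),
                                                 c(1, 1, 1)), 0)$data |> dim(),
                   c(3L, 3L, 3L))
  v0 <- image_volume(array(rnorm(27), dim = c(3, 3, 3)), c(1, 1, 1))
  expect_equal(gaussian_denoise(v0, 0)$data, v0$data)

  # delta impulse on a 9x9x1 grid: centre slice values equal the separable
  # discrete kernel (oracle computed directly here)
  arr <- array(0, dim = c(9, 9, 1))
  arr[5, 5, 1] <- 1
  out <- gaussian_denoise(image_volume(arr, c(1, 1, 1)), 1)$data
  r <- ceiling(3)
  k <- exp(-(-r:r)^2 / 2); k <- k / sum(k)
  oracle <- outer(k, k)   # z axis: single slice, reflective smoothing is identity
  expect_equal(out[(5 - r):(5 + r), (5 - r):(5 + r), 1], oracle,
               tolerance = 1e-12)

  # reflective boundaries preserve the global mean
  set.seed(3)
  v <- image_volume(array(rnorm(8 * 7 * 6), dim = c(8, 7, 6)), c(1, 1, 2))
  sm <- gaussian_denoise(v, 1.5)
  expect_lt(abs(mean(sm$data) - mean(v$data)), 1e-6)
})

test_that("select_max_area_slices maximizes summed area with low tie-break", {
  mk <- function(areas) {
    nz <- length(areas)
    m <- array(FALSE, dim = c(10, 10, nz))
    for (z in seq_len(nz)) if (areas[z] > 0) m[seq_len(areas[z]), 1, z] <- TRUE
    roi_mask(m, c(1, 1, 1))
  }
  v <- image_volume(array(0, dim = c(10, 10, 5)), c(1, 1, 1))
  m <- mk(c(0, 5, 9, 5, 0))
  out <- select_max_area_slices(v, m, 3)
  # brute-force oracle over all windows
  areas <- c(0, 5, 9, 5, 0)
  wins <- vapply(1:3, function(s) sum(areas[s:(s + 2)]), numeric(1))
  expect_equal(out$start, which.max(wins))
  expect_equal(dim(out$volume$data)[3], 3)
  # single-slice mask: the first window containing it
  out2 <- select_max_area_slices(v, mk(c(0, 0, 1, 0, 0)), 3)
  expect_equal(out2$start, 1)
  # uniform areas: lowest start index
  out3 <- select_max_area_slices(v, mk(c(2, 2, 2, 2, 2)), 3)
  expect_equal(out3$start, 1)
  # fewer slices than requested: use all, warn
  v2 <- image_volume(array(0, dim = c(10, 10, 2)), c(1, 1, 1))
  expect_warning(o4 <- select_max_area_slices(v2, mk(c(1, 1)), 3), "using all")
  expect_equal(dim(o4$volume$data)[3], 2)
})

test_that("resample_isotropic is exact on identity and 1-D ramps", {
  v <- image_volume(array(rnorm(60), dim = c(5, 4, 3)), c(1, 2, 3))
  m <- roi_mask(array(TRUE, dim = c(5, 4, 3)), c(1, 2, 3))
  same <- resample_isotropic(v, m, c(1, 2, 3))
  expect_identical(same$volume$data, v$data)
  # ramp along x resampled 2x finer: linear interpolation oracle
  ramp <- array(rep(0:4, times = 12), dim = c(5, 4, 3))
  rv <- image_volume(ramp, c(2, 2, 2))
  fine <- resample_isotropic(rv, NULL, c(1, 2, 2))
  expect_equal(fine$volume$data[, 1, 1], seq(0, 4, by = 0.5))
  # mask stays binary through resampling
  set.seed(4)
  mm <- roi_mask(array(runif(60) > 0.5, dim = c(5, 4, 3)), c(1, 2, 3))
  out <- resample_isotropic(v, mm, c(0.7, 1.1, 2.9))
  expect_type(out$mask$data, "logical")
})

test_that("preprocess_sample is deterministic and keeps spacing metadata", {
  s <- quick_lesion(1)
  a <- preprocess_sample(s)
  b <- preprocess_sample(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$volume$spacing, s$volume$spacing)
  expect_equal(dim(a$volume$data)[3], 3)
  expect_true(all(a$volume$data >= 0 & a$volume$data <= 1))
})
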