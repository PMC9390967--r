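# radiomics feature extraction: discretization, texture matrices, wavelet,
# cardinalities, and oracle equivalence on the frozen fixtures

test_that("discretize follows the fixed-bin-width formula", {
  arr <- array(c(0, 24, 25, 51, -99, -99), dim = c(6, 1, 1))
  msk <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), dim = c(6, 1, 1))
  dd <- discretize(arr, msk, discretization_config(bin_width = 25))
  expect_equal(dd$levels[msk], c(1L, 1L, 2L, 3L))
  expect_equal(dd$ng, 3L)
  expect_true(all(dd$levels[!msk] == 0L))

  cst <- discretize(array(7, dim = c(2, 2, 2)),
                    array(TRUE, dim = c(2, 2, 2)))
  expect_equal(cst$ng, 1L)

  set.seed(5)
  v <- array(rnorm(200, 0, 60), dim = c(10, 10, 2))
  m <- array(runif(200) > 0.3, dim = c(10, 10, 2))
  dd2 <- discretize(v, m, discretization_config(bin_width = 10))
  expect_equal(dd2$levels[m],
               as.integer(floor((v[m] - min(v[m])) / 10) + 1))
})

test_that("GLCM counts match brute-force pair enumeration", {
  # single-slice 2x2 checkerboard of levels {1,2}
  lv <- array(0L, dim = c(2, 2, 1))
  lv[, , 1] <- c(1L, 2L, 2L, 1L)
  counts <- glcm_matrix(lv, 2)
  # brute force over all in-mask ordered pairs per direction
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0), c(1,0,1),
                c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1), c(1,1,-1),
                c(1,-1,1), c(1,-1,-1))
  for (d in seq_len(13)) {
    oracle <- matrix(0, 2, 2)
    for (x in 1:2) for (y in 1:2) {
      x2 <- x + dirs[d, 1]; y2 <- y + dirs[d, 2]; z2 <- 1 + dirs[d, 3]
      if (x2 %in% 1:2 && y2 %in% 1:2 && z2 == 1) {
        a <- lv[x, y, 1]; b <- lv[x2, y2, 1]
        oracle[a, b] <- oracle[a, b] + 1
        oracle[b, a] <- oracle[b, a] + 1
      }
    }
    expect_equal(counts[, , d], oracle)
  }
  # constant ROI: all mass at (1,1)
  cl <- array(1L, dim = c(3, 3, 1))
  cc <- glcm_matrix(cl, 1)
  expect_true(all(cc >= 0) && sum(cc) > 0)
  expect_equal(dim(cc), c(1L, 1L, 13L))
})

test_that("GLRLM, GLSZM and NGTDM behave on hand-enumerable inputs", {
  # 1-D strip [1,1,2] along x
  lv <- array(c(1L, 1L, 2L), dim = c(3, 1, 1))
  tm <- texture_matrices(lv, 2)
  xdir <- tm$glrlm[, , 1]   # first direction is (1,0,0)
  expect_equal(xdir[1, 2], 1)  # one run of length 2 at level 1
  expect_equal(xdir[2, 1], 1)  # one run of length 1 at level 2
  expect_equal(sum(xdir), 2)

  # constant ROI: GLSZM is a single zone of size |mask|
  cl <- array(1L, dim = c(3, 3, 2))
  tmc <- texture_matrices(cl, 1)
  expect_equal(sum(tmc$glszm), 1)
  expect_equal(which(tmc$glszm[1, ] > 0), 18)
  # NGTDM difference sums are all zero on a constant ROI
  expect_true(all(tmc$ngtdm$s == 0))
  expect_equal(sum(tmc$ngtdm$n), 18)
})

test_that("first-order mean and energy on {1,2,3} are 2 and 14", {
  arr <- array(c(1, 2, 3), dim = c(3, 1, 1))
  msk <- array(TRUE, dim = c(3, 1, 1))
  fo <- firstorder_features(arr, msk, c(1, 1, 1))
  expect_equal(unname(fo["Mean"]), 2)
  expect_equal(unname(fo["Energy"]), 14)
  expect_equal(unname(fo["TotalEnergy"]), 14)
  expect_equal(unname(fo["Variance"]), 2 / 3)
})

test_that("wavelet decomposition: 8 sub-bands, low/high-pass behaviour,
           1-D coif1 filter-bank oracle", {
  arr <- array(rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  bands <- wavelet_decompose(arr)
  expect_length(bands, 8)
  expect_named(bands, c("LLL", "LLH", "LHL", "LHH",
                        "HLL", "HLH", "HHL", "HHH"))
  expect_true(all(vapply(bands, function(b) identical(dim(b), dim(arr)),
                         logical(1))))
  # constant volume: LLL proportional (x 2^(3/2)), details ~ 0
  cst <- array(3, dim = c(4, 4, 4))
  bc <- wavelet_decompose(cst)
  expect_equal(bc$LLL, array(3 * 2^1.5, dim = c(4, 4, 4)), tolerance = 1e-10)
  for (nm in names(bc)[-1]) expect_lt(max(abs(bc[[nm]])), 1e-10)

  # 1-D circular filter-bank oracle: direct convolution sum computed here
  lo <- radrobust:::coif1_dec_lo()
  n <- 11
  set.seed(6)
  x <- rnorm(n)
  arr1 <- array(x, dim = c(n, 1, 1))
  got <- radrobust:::swt_filter_axis(arr1, lo, 1)[, 1, 1]
  off <- length(lo) %/% 2
  oracle <- vapply(seq_len(n), function(i)
    sum(vapply(seq_along(lo), function(k)
      lo[k] * x[((i - 1 + (k - 1) - off) %% n) + 1], numeric(1))),
    numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  # quadrature mirror: high-pass of a constant is 0, filters orthogonal
  expect_lt(abs(sum(radrobust:::coif1_dec_hi())), 1e-12)
  expect_equal(sum(lo), sqrt(2), tolerance = 1e-12)
})

test_that("feature inventory: 851 columns with the printed per-class counts", {
  s <- preprocess_sample(quick_lesion(7))
  fv <- extract_all(s)
  expect_length(fv, 851)
  pr <- feature_provenance(names(fv))
  counts <- table(pr$class)
  expect_equal(unname(counts[c("shape", "firstorder", "glcm", "glrlm",
                               "glszm", "gldm", "ngtdm")]),
               c(14L, 162L, 216L, 144L, 144L, 126L, 45L),
               ignore_attr = TRUE)
  expect_equal(sum(pr$filter == "original"), 107L)
  expect_equal(sum(pr$filter != "original"), 744L)
  # shape only ever pairs with the original filter
  expect_true(all(pr$filter[pr$class == "shape"] == "original"))
  # wavelet off: the 107 original features
  expect_length(extract_all(s, extraction_config(wavelet = FALSE)), 107)
  # determinism
  expect_identical(fv, extract_all(s))
})

test_that("every original feature matches the independent reference
           extractor on the three fixture lesions", {
  for (stem in c("lesion1", "lesion2", "lesion3")) {
    s <- read_fixture_sample(stem)
    fv <- extract_all(s, extraction_config(wavelet = FALSE,
                                           intensity_scale = 1))
    exp <- read.csv(test_path("fixtures", paste0(stem, "_expected.csv")),
                    stringsAsFactors = FALSE)
    expect_length(fv, nrow(exp))
    got <- fv[exp$feature]
    expect_false(any(is.na(got)))
    rel <- abs(got - exp$value) / pmax(abs(exp$value), 1e-12)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("degenerate constant ROI yields defined (never missing) features", {
  arr <- array(5, dim = c(4, 4, 3))
  s <- array_sample(arr)
  fv <- extract_all(s, extraction_config(wavelet = FALSE, intensity_scale = 1))
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["original_firstorder_Variance"]), 0)
  expect_equal(unname(fv["original_glcm_MaximumProbability"]), 1)
})

test_that("first-order mean moves < 1 % under rotation perturbations", {
  s <- quick_lesion(8)
  m0 <- mean(s$volume$data[s$mask$data])
  for (a in c(-30, -15, 15, 30)) {
    r <- perturb_rotation(s, a)
    expect_lt(abs(mean(r$volume$data[r$mask$data]) - m0) / abs(m0), 0.01)
  }
})
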