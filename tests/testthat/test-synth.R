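# synthetic cohort generator

test_that("noiseless lesion is exactly mean_hu inside the mask", {
  p <- lesion_params(texture_sd_hu = 0, noise_sd_hu = 0)
  s <- generate_lesion(p, seed = 1)
  expect_true(all(s$volume$data[s$mask$data] == p$mean_hu))
  # outside, far from the rim, it is exactly background
  expect_equal(s$volume$data[1, 1, 1], p$background_hu)
})

test_that("generation is deterministic given the seed", {
  s1 <- generate_lesion(lesion_params(), seed = 42)
  s2 <- generate_lesion(lesion_params(), seed = 42)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$mask$data, s2$mask$data)
  s3 <- generate_lesion(lesion_params(), seed = 43)
  expect_false(identical(s1$volume$data, s3$volume$data))
})

test_that("acquisition noise has the stated SD (Monte-Carlo)", {
  p <- lesion_params(semiaxes_mm = c(13, 12, 11), texture_sd_hu = 0,
                     noise_sd_hu = 20, rim_mm = 0, rim_decay_mm = 1e-6)
  s <- generate_lesion(p, spacing = c(0.75, 0.75, 1), shape = c(48, 48, 32),
                       seed = 7)
  x <- s$volume$data[s$mask$data] - p$mean_hu
  expect_gt(length(x), 1e4)
  expect_lt(abs(sd(x) - 20), 1)
})

test_that("ellipsoid exceeding the grid errors naming the axis", {
  p <- lesion_params(semiaxes_mm = c(50, 8, 7))
  expect_error(generate_lesion(p), "axis 1")
  p2 <- lesion_params(semiaxes_mm = c(8, 8, 30))
  expect_error(generate_lesion(p2), "axis 3")
})

test_that("cohort honours the Table-1 class counts and stays reproducible", {
  spec <- cohort_spec(seed = 1)   # defaults: 124 responsive / 33 unresponsive
  cohort <- generate_cohort(spec)
  expect_length(cohort, 157)
  labels <- vapply(cohort, function(s) s$label, integer(1))
  expect_equal(sum(labels == 1), 124)
  expect_equal(sum(labels == 0), 33)
  # reproducibility: regenerating one subject gives identical data
  again <- generate_cohort(spec)
  expect_identical(cohort[[17]]$volume$data, again[[17]]$volume$data)
})

test_that("empty cohort and differing seeds behave per contract", {
  expect_length(generate_cohort(cohort_spec(0, 0)), 0)
  s1 <- generate_cohort(cohort_spec(3, 2, shape = c(30, 30, 10), seed = 1))
  s2 <- generate_cohort(cohort_spec(3, 2, shape = c(30, 30, 10), seed = 2))
  expect_false(identical(s1[[1]]$volume$data, s2[[1]]$volume$data))
  expect_identical(vapply(s1, function(s) s$label, integer(1)),
                   vapply(s2, function(s) s$label, integer(1)))
  expect_error(cohort_spec(-1, 5), "counts")
})

test_that("test-retest pair: degenerate case reproduces the baseline", {
  p <- lesion_params(noise_sd_hu = 0)
  s <- generate_lesion(p, seed = 11)
  pair <- generate_test_retest_pair(s, seed = 1, max_shift_vox = 0)
  expect_equal(pair$retest$volume$data, pair$baseline$volume$data)
  expect_identical(pair$retest$mask$data, pair$baseline$mask$data)
  expect_identical(pair$retest$replicate, "retest")
})

test_that("test-retest ICC of first-order mean is high at low noise and
           degrades when noise dominates texture", {
  icc_at_noise <- function(noise_sd, n = 30) {
    m <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      p <- lesion_params(noise_sd_hu = noise_sd,
                         mean_hu = 40 + 30 * sin(i),   # subject heterogeneity
                         semiaxes_mm = c(8, 7, 6) * (0.8 + 0.02 * i))
      s <- generate_lesion(p, spacing = c(0.75, 0.75, 3),
                           shape = c(36, 36, 10), seed = 100 + i)
      pr <- generate_test_retest_pair(s, seed = 200 + i)
      m[i, 1] <- mean(pr$baseline$volume$data[pr$baseline$mask$data])
      m[i, 2] <- mean(pr$retest$volume$data[pr$retest$mask$data])
    }
    icc_2_1(m)
  }
  lo <- icc_at_noise(5)
  hi <- icc_at_noise(150)
  expect_gt(lo, 0.9)
  expect_lt(hi, lo)
})

test_that("NIfTI round trip preserves volumes, masks and the manifest", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(2, 1, shape = c(24, 24, 8), seed = 3))
  man <- write_cohort(cohort, dir)
  expect_true(file.exists(man))
  back <- read_cohort(man)
  expect_length(back, 3)
  expect_equal(back[[1]]$volume$data, cohort[[1]]$volume$data,
               tolerance = 1e-6)   # float32 storage
  expect_identical(back[[2]]$mask$data, cohort[[2]]$mask$data)
  expect_identical(back[[3]]$label, cohort[[3]]$label)
  expect_equal(back[[1]]$volume$spacing, cohort[[1]]$volume$spacing,
               tolerance = 1e-6)
})
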