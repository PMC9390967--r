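# ICC(2,1), family reports, the robustness gate, zero-MAD removal,
# standardization

# independent ICC oracle: mean squares from a two-way fixed-effects fit via
# lm/anova, then the Shrout-Fleiss (2,1) formula
icc_oracle <- function(m) {
  df <- data.frame(v = as.numeric(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  a <- anova(lm(v ~ subj + rater, data = df))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("icc_2_1 matches the two-way-ANOVA oracle", {
  m <- matrix(c(1, 3, 5, 7, 2, 5, 8, 11), ncol = 2)
  expect_equal(icc_2_1(m), icc_oracle(m), tolerance = 1e-12)
  # 20 random matrices of varying shape
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:12, 1); k <- sample(2:5, 1)
    mm <- matrix(rnorm(n * k, sd = sample(1:10, 1)), n, k) +
      rnorm(n)                       # add subject effects
    expect_equal(icc_2_1(mm), icc_oracle(mm), tolerance = 1e-10)
  }
})

test_that("icc_2_1 edge behaviour: perfect agreement, shuffling, degeneracy,
           affine invariance", {
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_2_1(m), 1)
  # independently shuffled columns destroy agreement
  set.seed(12)
  iccs <- replicate(30, {
    base <- rnorm(10)
    icc_2_1(cbind(sample(base), sample(base), sample(base)))
  })
  expect_lt(mean(iccs), 0.3)
  expect_error(icc_2_1(matrix(5, 4, 3)), "degenerate")
  expect_error(icc_2_1(matrix(rnorm(4), 2, 2)), "3 subjects")
  # common affine rescaling leaves ICC unchanged
  mm <- matrix(rnorm(15), 5, 3) + 2 * rnorm(5)
  expect_equal(icc_2_1(mm), icc_2_1(3.7 * mm - 11), tolerance = 1e-10)
})

test_that("family_icc: identity perturbation gives ICC 1; bookkeeping and
           row checks hold", {
  set.seed(13)
  base <- data.frame(f1 = rnorm(8), f2 = runif(8) * 10)
  rownames(base) <- paste0("s", 1:8)
  rep1 <- family_icc(base, list(base), "ident")
  expect_equal(nrow(rep1), 2)
  expect_true(all(rep1$icc == 1))
  expect_true(all(rep1$k_versions == 2))
  # report count = n_features x n_families
  rep2 <- rbind(family_icc(base, list(base), "A"),
                family_icc(base, list(base + rnorm(16)), "B"))
  expect_equal(nrow(rep2), 2 * 2)
  bad <- base; rownames(bad) <- paste0("x", 1:8)
  expect_error(family_icc(base, list(bad), "A"), "mismatch")
})

test_that("mask-sensitive voxel count is less Seg-robust than first-order
           mean on a synthetic cohort", {
  set.seed(14)
  cohort <- generate_cohort(cohort_spec(8, 4, seed = 21))
  feat <- function(s) c(mean_hu = mean(s$volume$data[s$mask$data]),
                        nvox = sum(s$mask$data))
  base <- as.data.frame(t(vapply(cohort, feat, numeric(2))))
  enl <- as.data.frame(t(vapply(lapply(cohort, perturb_roi, mode = "enlarge",
                                       radius_mm = 2), feat, numeric(2))))
  shr <- as.data.frame(t(vapply(lapply(cohort, perturb_roi, mode = "shrink",
                                       radius_mm = 2), feat, numeric(2))))
  rownames(enl) <- rownames(shr) <- rownames(base)
  rep <- family_icc(base, list(enl, shr), "Seg")
  expect_gt(rep$icc[rep$feature == "mean_hu"],
            rep$icc[rep$feature == "nvox"])
})

test_that("filter_robust applies a strict cutoff and nests under thresholds", {
  rep <- data.frame(
    feature = rep(c("a", "b", "c"), each = 3),
    family = rep(c("S", "R", "Seg"), 3),
    icc = c(0.9, 0.8, 0.76,    # a: min 0.76 -> retained at 0.75
            0.9, 0.9, 0.75,    # b: min 0.75 -> dropped (strict >)
            0.99, 0.98, 0.97), # c: retained
    n_subjects = 10, k_versions = 3)
  keep <- filter_robust(rep, robust_filter_config(0.75))
  expect_setequal(keep, c("a", "c"))
  # retained sets shrink monotonically (nesting) as the threshold rises
  prev <- filter_robust(rep, robust_filter_config(0))
  for (thr in c(0.5, 0.76, 0.9, 0.98)) {
    cur <- filter_robust(rep, robust_filter_config(thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # pooled (mean) mode
  keep_mean <- filter_robust(rep, robust_filter_config(0.75, FALSE))
  expect_true("b" %in% keep_mean)
})

test_that("remove_zero_mad drops exactly the zero-MAD columns", {
  tab <- data.frame(const = rep(4, 4),
                    spike = c(1, 1, 1, 9),     # MAD 0
                    keep = c(1, 2, 3, 4))
  out <- remove_zero_mad(tab)
  expect_identical(colnames(out), "keep")
  expect_error(remove_zero_mad(tab[, 1:2]), "zero MAD")
})

test_that("standardize centres/scales by train statistics only", {
  set.seed(15)
  tr <- data.frame(a = rnorm(20, 5, 2), b = runif(20))
  held <- data.frame(a = rnorm(10, 50, 2), b = runif(10) + 10)
  st <- standardize(tr, list(held))
  expect_lt(max(abs(colMeans(st$train))), 1e-10)
  psd <- vapply(st$train, function(c) sqrt(mean((c - mean(c))^2)), numeric(1))
  expect_equal(unname(psd), c(1, 1), tolerance = 1e-10)
  # population-SD convention: {0, 10} -> {-1, 1}
  st2 <- standardize(data.frame(x = c(0, 10)))
  expect_equal(st2$train$x, c(-1, 1))
  # held-out transform uses train statistics, not its own
  expect_gt(abs(mean(st$applied[[1]]$a)), 5)
  expect_error(standardize(data.frame(z = rep(1, 5))), "zero train SD")
})
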