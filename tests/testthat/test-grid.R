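# SMOTE, stratified CV, AUC, RSD, the model grid, best-row selection and
# confusion metrics

test_that("smote_oversample balances classes and stays convex", {
  set.seed(31)
  # already balanced: unchanged
  Xb <- matrix(rnorm(20), 10, 2)
  yb <- rep(c(0, 1), each = 5)
  out <- smote_oversample(Xb, yb, seed = 1)
  expect_identical(out$X, Xb)
  # 1-D minority {0, 1}: all synthetic values inside [0, 1]
  X <- matrix(c(0, 1, rnorm(8, 10)), ncol = 1)
  y <- c(1, 1, rep(0, 8))
  out2 <- smote_oversample(X, y, seed = 2)
  expect_equal(sum(out2$y == 1), sum(out2$y == 0))
  synth <- out2$X[-(1:10), 1]
  expect_true(all(synth >= 0 & synth <= 1))
  # balance across random imbalances and seeds; originals preserved
  for (i in 1:5) {
    n1 <- sample(3:10, 1); n0 <- sample(12:25, 1)
    XX <- matrix(rnorm((n1 + n0) * 3), ncol = 3)
    yy <- c(rep(1, n1), rep(0, n0))
    oo <- smote_oversample(XX, yy, seed = i)
    expect_equal(sum(oo$y == 1), sum(oo$y == 0))
    expect_identical(oo$X[seq_len(n1 + n0), ], XX)
  }
  expect_error(smote_oversample(matrix(rnorm(6), 3), c(1, 0, 0), seed = 1),
               "at least 2")
})

test_that("stratified_kfold keeps per-fold class counts within 1 of
           proportionality", {
  y <- c(rep(1, 124), rep(0, 33))
  f <- stratified_kfold(y, k = 10, seed = 1)
  expect_setequal(unique(f), 1:10)
  for (k in 1:10) {
    expect_true(sum(y[f == k] == 1) %in% c(12, 13))
    expect_true(sum(y[f == k] == 0) %in% c(3, 4))
  }
  # partition is exact and disjoint by construction; determinism
  expect_identical(f, stratified_kfold(y, k = 10, seed = 1))
  expect_false(identical(f, stratified_kfold(y, k = 10, seed = 2)))
  expect_error(stratified_kfold(c(1, 1, 0), k = 2), "smaller k")
})

test_that("auc matches pair counting, including ties", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # 4-sample toy with one tie: hand-enumerated pairs
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.5, 0.5, 0.1)
  expect_equal(auc(y, s), (1 + 1 + 0.5 + 1) / 4)
  # label-independent scores: ~0.5 at large n
  set.seed(32)
  yy <- rep(c(0, 1), 2000)
  expect_lt(abs(auc(yy, rnorm(4000)) - 0.5), 0.03)
  # oracle: explicit pair counting on random score vectors with ties
  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  for (i in 1:10) {
    yy <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(yy)) < 2) next
    ss <- sample(seq(0, 1, 0.1), 30, replace = TRUE)  # forces ties
    expect_equal(auc(yy, ss), pair_auc(yy, ss), tolerance = 1e-12)
  }
  expect_error(auc(c(1, 1), c(0.5, 0.3)), "both classes")
})

test_that("rsd follows the two-point arithmetic and scale invariance", {
  expect_equal(rsd(rep(0.77, 10)), 0)
  expect_equal(rsd(c(0.8, 1.0)), 100 * (0.2 / sqrt(2)) / 0.9)
  f <- c(0.6, 0.7, 0.9, 0.85)
  expect_equal(rsd(f), rsd(3 * f), tolerance = 1e-12)
  expect_error(rsd(c(0, 0)), "mean")
})

test_that("run_grid produces consistent rows and select_best applies the
           AUC-then-RSD tie-break", {
  set.seed(33)
  n <- 40
  y <- rep(c(1, 0), c(26, 14))
  tab <- data.frame(sig = y + rnorm(n, sd = 0.6),
                    n1 = rnorm(n), n2 = rnorm(n), n3 = runif(n))
  rows <- run_grid(list(tab1 = tab), y, selectors = "MIM",
                   classifiers = classifier_registry()["logistic"],
                   cv = cv_config(k = 3, seed = 1), n_select = 2)
  expect_equal(nrow(rows), 1)
  expect_identical(rows$model, "tab1_MIM_logistic")
  # rsd field consistent with its folds
  fa <- rows$fold_aucs[[1]]
  expect_length(fa, 3)
  expect_equal(rows$rsd, 100 * sd(fa) / mean(fa), tolerance = 1e-10)
  expect_equal(rows$mean_auc, mean(fa), tolerance = 1e-12)

  mkrow <- function(model, auc_, rsd_) data.frame(
    model = model, mean_auc = auc_, rsd = rsd_, failed = FALSE)
  rows2 <- rbind(mkrow("a", 0.90, 2), mkrow("b", 0.96, 5))
  expect_identical(select_best(rows2)$model, "b")      # AUC primary
  rows3 <- rbind(mkrow("radA", 0.96, 0.61), mkrow("radB", 0.96, 0.50))
  expect_identical(select_best(rows3)$model, "radB")   # RSD tie-break
  expect_identical(select_best(rows3[2, ])$model, "radB")
  rows4 <- rbind(mkrow("x", NA, NA)); rows4$failed <- TRUE
  expect_error(select_best(rows4), "failed")
})

test_that("confusion_metrics matches hand arithmetic and symmetry", {
  y <- c(rep(1, 4), rep(0, 4))
  expect_equal(unname(confusion_metrics(y, y)),
               c(1, 1, 1, 1, 1), ignore_attr = TRUE)
  # TP=9 FN=1 FP=2 TN=8
  yy <- c(rep(1, 10), rep(0, 10))
  pp <- c(rep(1, 9), 0, 1, 1, rep(0, 8))
  cm <- confusion_metrics(yy, pp)
  expect_equal(unname(cm["acc"]), 0.85)
  expect_equal(unname(cm["sensitivity"]), 0.9)
  expect_equal(unname(cm["specificity"]), 0.8)
  expect_equal(unname(cm["precision"]), 9 / 11)
  expect_equal(unname(cm["f1"]), 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  # swapping the positive-class convention swaps sens/spec
  cs <- confusion_metrics(1 - yy, 1 - pp)
  expect_equal(unname(cs["sensitivity"]), unname(cm["specificity"]))
  expect_equal(unname(cs["specificity"]), unname(cm["sensitivity"]))
})

test_that("all 12 classifiers learn a separable toy and score sensibly", {
  set.seed(34)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(y * 2 + rnorm(n, sd = 0.5), rnorm(n))
  Xte <- cbind(c(-0.5, 2.5), c(0, 0))
  for (spec in classifier_registry(seed = 7)) {
    fit <- classifier_fit(spec, X, y)
    sc <- classifier_predict(fit, Xte)
    expect_length(sc, 2)
    expect_true(all(is.finite(sc)))
    expect_gt(sc[2], sc[1])   # the class-1-like point scores higher
    # training AUC is high on a cleanly separable problem
    expect_gt(auc(y, classifier_predict(fit, X)), 0.9)
  }
})

test_that("in-fold fitting shows no optimism on label-permuted data with a
           globally-selectable noise table", {
  set.seed(35)
  n <- 40
  tab <- as.data.frame(matrix(rnorm(n * 120), n, 120))
  colnames(tab) <- sprintf("f%03d", 1:120)
  y <- sample(rep(c(0, 1), c(26, 14)))
  rows <- run_grid(list(noise = tab), y, selectors = c("MIM", "FSCR"),
                   classifiers = classifier_registry()["logistic"],
                   cv = cv_config(k = 5, seed = 2), n_select = 5)
  expect_true(all(rows$mean_auc > 0.25 & rows$mean_auc < 0.75))
  # the leak: selecting on ALL data then cross-validating is optimistic
  sc <- score_features(standardize(tab)$train, y, "FSCR")
  leak_feats <- names(sort(sc, decreasing = TRUE))[1:5]
  folds <- stratified_kfold(y, 5, seed = 2)
  leak_auc <- mean(vapply(1:5, function(fi) {
    tr <- folds != fi
    fit <- classifier_fit(classifier_registry()$logistic,
                          as.matrix(tab[tr, leak_feats]), y[tr])
    auc(y[!tr], classifier_predict(fit, as.matrix(tab[!tr, leak_feats])))
  }, numeric(1)))
  expect_gt(leak_auc, max(rows$mean_auc))
})
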