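# the 13 feature selectors and the recursive-feature-addition wrapper

test_that("mutual information: independence, closed form, joint-table oracle", {
  set.seed(21)
  x <- sample(1:3, 4000, replace = TRUE)
  y <- sample(0:1, 4000, replace = TRUE)
  expect_lt(mutual_information(x, y), 0.005)
  # y = x with L equiprobable levels -> ln L
  z <- rep(1:4, each = 25)
  expect_equal(mutual_information(z, z), log(4), tolerance = 1e-12)
  # 3-level toy joint table vs the direct-sum oracle
  xt <- c(1, 1, 2, 2, 3, 3, 1, 2, 3, 3, 3, 1)
  yt <- c(0, 1, 0, 0, 1, 1, 0, 1, 0, 1, 1, 0)
  expect_equal(mutual_information(xt, yt), mi_oracle(xt, yt),
               tolerance = 1e-12)
  expect_gte(mutual_information(xt, yt), 0)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("the chain identity I(X,Xs;Y) = I(Xs;Y) + I(X;Y|Xs) holds", {
  set.seed(22)
  for (i in 1:5) {
    x <- sample(1:3, 60, replace = TRUE)
    xs <- sample(1:2, 60, replace = TRUE)
    y <- as.integer(runif(60) < (0.2 + 0.2 * (x == 1) + 0.3 * (xs == 2)))
    lhs <- mutual_information(interaction(x, xs, drop = TRUE), y)
    rhs <- mutual_information(xs, y) +
      conditional_mutual_information(x, y, xs)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("a feature equal to the label ranks first under every method", {
  set.seed(23)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  tab <- data.frame(noise1 = rnorm(n), perfect = y + rnorm(n, sd = 1e-3),
                    noise2 = runif(n), noise3 = rnorm(n))
  for (m in selector_names()) {
    sel <- select_features(tab, y, selector_config(m, n_select = 1))
    expect_identical(sel, "perfect")
  }
})

test_that("Fisher score matches the formula oracle on constructed data", {
  # class 0: {-0.5, 0.5} (mean 0, pop var .25); class 1: {0.5, 1.5}
  tab <- data.frame(f = c(-0.5, 0.5, 0.5, 1.5))
  y <- c(0, 0, 1, 1)
  sc <- score_features(tab, y, "FSCR")
  # oracle: sum n_c (mu_c - mu)^2 / sum n_c var_c = (2*.25+2*.25)/(2*.25+2*.25)
  expect_equal(unname(sc["f"]), 1)
  # Welch t oracle
  sct <- score_features(tab, y, "TSCR")
  se <- sqrt(var(c(-0.5, 0.5)) / 2 + var(c(0.5, 1.5)) / 2)
  expect_equal(unname(sct["f"]), 1 / se, tolerance = 1e-12)
})

test_that("ReliefF gives ~0 weight to label-independent noise", {
  set.seed(24)
  ws <- replicate(8, {
    n <- 40
    y <- rep(c(0, 1), n / 2)
    tab <- data.frame(sig = y + rnorm(n, sd = 0.2), noise = rnorm(n))
    sc <- score_features(tab, y, "RELF", selector_config("RELF"))
    sc["noise"]
  })
  expect_lt(abs(mean(ws)), 0.05)
  # and the informative feature outranks it
  set.seed(25)
  y <- rep(c(0, 1), 20)
  tab <- data.frame(sig = y + rnorm(40, sd = 0.2), noise = rnorm(40))
  sc <- score_features(tab, y, "RELF", selector_config("RELF"))
  expect_gt(sc["sig"], sc["noise"])
})

test_that("duplicated top feature: MIM re-picks it, MRMR/MIFS never do", {
  set.seed(26)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  top <- y + rnorm(n, sd = 0.3)
  tab <- data.frame(a_top = top, b_dup = top, weak = y + rnorm(n, sd = 2),
                    noise = rnorm(n))
  mim <- greedy_select(tab, y, "MIM", 2)
  expect_setequal(mim, c("a_top", "b_dup"))
  for (m in c("MRMR", "MIFS")) {
    sel <- greedy_select(tab, y, m, 2)
    expect_identical(sel[1], "a_top")
    expect_false("b_dup" %in% sel)
  }
})

test_that("greedy selection matches step-wise brute-force criterion
           evaluation (MRMR, JMI, CMIM) on 8-feature toys", {
  bin5 <- function(x) radrobust:::equal_freq_bin(x, 5)
  cmi_oracle <- function(x, y, z) {
    s <- 0
    for (zz in unique(z)) {
      sel <- z == zz
      s <- s + mean(sel) * mi_oracle(x[sel], y[sel])
    }
    s
  }
  brute_step <- function(D, y, selected, avail, method) {
    J <- vapply(avail, function(f) {
      if (!length(selected)) return(mi_oracle(D[[f]], y))
      switch(method,
             MRMR = mi_oracle(D[[f]], y) -
               mean(vapply(selected, function(s)
                 mi_oracle(D[[f]], D[[s]]), numeric(1))),
             JMI = sum(vapply(selected, function(s)
               mi_oracle(interaction(D[[f]], D[[s]], drop = TRUE), y),
               numeric(1))),
             CMIM = min(vapply(selected, function(s)
               cmi_oracle(D[[f]], y, D[[s]]), numeric(1))))
    }, numeric(1))
    avail[which.max(J)]   # avail kept name-sorted
  }
  set.seed(27)
  for (rep_ in 1:3) {
    n <- 50
    y <- rep(c(0, 1), each = n / 2)
    tab <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    colnames(tab) <- paste0("f", 1:8)
    tab$f1 <- tab$f1 + y          # relevance structure
    tab$f2 <- tab$f1 + rnorm(n, sd = 0.2)
    tab$f3 <- tab$f3 + 0.5 * y
    for (method in c("MRMR", "JMI", "CMIM")) {
      got <- greedy_select(tab, y, method, 4)
      D <- lapply(tab, bin5)
      selected <- character(0)
      avail <- sort(colnames(tab))
      for (step in 1:4) {
        pick <- brute_step(D, y, selected, avail, method)
        selected <- c(selected, pick)
        avail <- setdiff(avail, pick)
      }
      expect_identical(got, selected)
    }
  }
})

test_that("recursive feature addition recovers the informative feature and
           respects its contract", {
  set.seed(28)
  hits <- 0
  for (i in 1:5) {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    tab <- as.data.frame(matrix(rnorm(n * 9), n, 9))
    colnames(tab) <- paste0("n", 1:9)
    tab$info <- y + rnorm(n, sd = 0.4)
    ranked <- select_features(tab, y, selector_config("MIM", n_select = 10))
    final <- recursive_feature_addition(ranked, tab, y, seed = i)
    if ("info" %in% final) hits <- hits + 1
    # output is a subsequence of the ranking
    expect_identical(final, ranked[ranked %in% final])
  }
  expect_gte(hits, 4)
  # tol = Inf: exactly the first ranked feature survives
  y <- rep(c(0, 1), 10)
  tab <- data.frame(a = y + rnorm(20, sd = 0.1), b = rnorm(20))
  expect_identical(recursive_feature_addition(c("a", "b"), tab, y, tol = Inf),
                   "a")
})

test_that("scores are invariant to sample permutation", {
  set.seed(29)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  tab <- data.frame(a = y + rnorm(n), b = rnorm(n), c = runif(n))
  perm <- sample(n)
  for (m in c("CHSQ", "FSCR", "TSCR", "GINI", "MIM")) {
    s1 <- score_features(tab, y, m)
    s2 <- score_features(tab[perm, , drop = FALSE], y[perm], m)
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})
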