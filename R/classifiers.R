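# The 12-classifier registry. Every classifier implements the
# fit / predict-score contract: classifier_fit(spec, X, y) -> model,
# classifier_predict(model, X) -> numeric score (monotone in P(y = 1)).
# Only base R + MASS are available in the target image, so trees (CART in
# C++), kNN, naive Bayes, SVMs, the MLP and the GP classifier are
# implemented here; hyperparameters follow common library defaults and are
# echoed into run manifests.

#' The 12-classifier registry
#'
#' logistic regression; k-nearest neighbours (k = 5); QDA (pooled-covariance
#' fallback for deficient classes); linear and RBF-kernel SVC (squared-hinge,
#' C = 1, RBF gamma = 1/(p Var)); gradient-boosted trees (100 rounds, depth
#' 3, learning rate 0.1); multilayer perceptron (one hidden layer of 100,
#' BFGS, L2 1e-4); Gaussian process (RBF kernel regression on +/-1 labels,
#' noise 0.1); decision tree (depth 5); Gaussian naive Bayes; random forest
#' (100 trees, random-subspace sqrt(p)); AdaBoost (SAMME, 50 stumps).
#'
#' @param seed integer seed used by the stochastic members.
#' @return Named list of classifier specs.
#' @export
classifier_registry <- function(seed = 1L) {
  mk <- function(name, ...) {
    structure(list(name = name, seed = seed, hyper = list(...)),
              class = "classifier_spec")
  }
  list(
    logistic = mk("logistic"),
    knn = mk("knn", k = 5),
    qda = mk("qda", reg = 1e-6),
    svm_linear = mk("svm_linear", C = 1),
    svm_rbf = mk("svm_rbf", C = 1, gamma = NULL),
    gboost = mk("gboost", n_rounds = 100, depth = 3, learning_rate = 0.1),
    mlp = mk("mlp", hidden = 100, maxit = 200, decay = 1e-4),
    gaussian_process = mk("gaussian_process", noise = 0.1, length_scale = NULL),
    decision_tree = mk("decision_tree", depth = 5, min_leaf = 2),
    naive_bayes = mk("naive_bayes", var_smoothing = 1e-9),
    random_forest = mk("random_forest", n_trees = 100, depth = 8, min_leaf = 1),
    adaboost = mk("adaboost", n_rounds = 50)
  )
}

fit_cart <- function(X, y, w = NULL, rows = NULL, feats = NULL,
                     depth = 5, min_leaf = 1) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(rows)) rows <- seq_len(n) - 1L
  if (is.null(feats)) feats <- seq_len(ncol(X)) - 1L
  cpp_cart_fit(X, as.numeric(y), as.numeric(w), as.integer(rows),
               as.integer(feats), as.integer(depth), as.integer(min_leaf),
               TRUE)
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# squared-hinge SVM in the primal via BFGS; returns decision function
svm_primal <- function(X, y, C) {
  ypm <- ifelse(y == 1, 1, -1)
  p <- ncol(X)
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- 1 - ypm * (X %*% w + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1]
    m <- as.numeric(1 - ypm * (X %*% w + b))
    act <- m > 0
    gw <- w - 2 * C * t(X[act, , drop = FALSE]) %*% (ypm[act] * m[act])
    gb <- -2 * C * sum(ypm[act] * m[act])
    c(gw, gb)
  }
  th <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
              control = list(maxit = 200))$par
  list(w = th[1:p], b = th[p + 1])
}

# kernelized squared-hinge SVM on the alpha-expansion f(x) = K alpha + b
svm_kernel <- function(K, ypm, C, reg = 1e-8) {
  n <- nrow(K)
  obj <- function(th) {
    a <- th[1:n]; b <- th[n + 1]
    f <- K %*% a + b
    m <- 1 - ypm * f
    0.5 * sum(a * (K %*% a)) + C * sum(pmax(m, 0)^2) + reg * sum(a^2)
  }
  grad <- function(th) {
    a <- th[1:n]; b <- th[n + 1]
    f <- as.numeric(K %*% a + b)
    m <- 1 - ypm * f
    act <- m > 0
    ga <- K %*% a - 2 * C * K[, act, drop = FALSE] %*% (ypm[act] * m[act]) +
      2 * reg * a
    gb <- -2 * C * sum(ypm[act] * m[act])
    c(ga, gb)
  }
  th <- optim(rep(0, n + 1), obj, grad, method = "BFGS",
              control = list(maxit = 150))$par
  list(alpha = th[1:n], b = th[n + 1])
}

mlp_fit <- function(X, y, hidden, decay, maxit, seed) {
  p <- ncol(X); n <- nrow(X)
  h <- hidden
  nw <- (p + 1) * h + (h + 1)
  set.seed(seed)
  th0 <- rnorm(nw, sd = 0.5 / sqrt(p + 1))
  unpack <- function(th) {
    W1 <- matrix(th[1:((p + 1) * h)], p + 1, h)
    w2 <- th[((p + 1) * h + 1):nw]
    list(W1 = W1, w2 = w2)
  }
  fwd <- function(th, XX) {
    pa <- unpack(th)
    A <- tanh(cbind(1, XX) %*% pa$W1)
    as.numeric(cbind(1, A) %*% pa$w2)
  }
  obj <- function(th) {
    z <- fwd(th, X)
    pr <- 1 / (1 + exp(-z))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(y * log(pr) + (1 - y) * log(1 - pr)) + decay * sum(th^2)
  }
  grad <- function(th) {
    pa <- unpack(th)
    Z1 <- cbind(1, X) %*% pa$W1
    A <- tanh(Z1)
    z <- as.numeric(cbind(1, A) %*% pa$w2)
    pr <- 1 / (1 + exp(-z))
    dz <- pr - y
    gw2 <- as.numeric(t(cbind(1, A)) %*% dz)
    dA <- outer(dz, pa$w2[-1]) * (1 - A^2)
    gW1 <- t(cbind(1, X)) %*% dA
    c(as.numeric(gW1), gw2) + 2 * decay * th
  }
  th <- optim(th0, obj, grad, method = "BFGS",
              control = list(maxit = maxit))$par
  list(theta = th, fwd = fwd)
}

#' Fit a classifier from the registry
#'
#' @param spec a `classifier_spec` from [classifier_registry()].
#' @param X numeric matrix (rows = samples).
#' @param y binary labels (0/1).
#' @return A fitted `classifier_model`.
#' @export
classifier_fit <- function(spec, X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  hp <- spec$hyper
  model <- switch(
    spec$name,
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = binomial())$coefficients),
    knn = list(X = X, y = y, k = hp$k),
    qda = {
      ok <- tryCatch(list(type = "qda", fit = MASS::qda(X, grouping = factor(y))),
                     error = function(e) NULL)
      if (is.null(ok))  # pooled-covariance fallback for deficient classes
        ok <- tryCatch(list(type = "lda", fit = MASS::lda(X, grouping = factor(y))),
                       error = function(e) NULL)
      if (is.null(ok))  # last resort: diagonal Gaussian discriminant
        ok <- list(type = "diag",
                   fit = classifier_fit(classifier_registry(spec$seed)$naive_bayes,
                                        X, y))
      ok
    },
    svm_linear = svm_primal(X, y, hp$C),
    svm_rbf = {
      gamma <- hp$gamma
      if (is.null(gamma)) {
        v <- mean(apply(X, 2, var)) * ncol(X)
        gamma <- if (v > 0) 1 / v else 1
      }
      K <- rbf_kernel(X, X, gamma)
      fit <- svm_kernel(K, ifelse(y == 1, 1, -1), hp$C)
      list(Xtr = X, gamma = gamma, alpha = fit$alpha, b = fit$b)
    },
    gboost = {
      # gradient boosting with logistic loss; depth-limited CART on the
      # negative gradient (residuals), constant learning rate
      f <- rep(0, nrow(X))
      trees <- vector("list", hp$n_rounds)
      for (m in seq_len(hp$n_rounds)) {
        pr <- 1 / (1 + exp(-f))
        res <- y - pr
        tr <- fit_cart(X, res, depth = hp$depth, min_leaf = 2)
        trees[[m]] <- tr
        f <- f + hp$learning_rate * cpp_cart_predict(tr, X)
      }
      list(trees = trees, lr = hp$learning_rate)
    },
    mlp = mlp_fit(X, y, hp$hidden, hp$decay, hp$maxit, spec$seed),
    gaussian_process = {
      ls <- hp$length_scale
      if (is.null(ls)) {
        ls2 <- mean(apply(X, 2, var)) * ncol(X)
        ls <- if (ls2 > 0) sqrt(ls2) else 1
      }
      gamma <- 1 / (2 * ls^2)
      K <- rbf_kernel(X, X, gamma)
      a <- solve(K + hp$noise^2 * diag(nrow(X)), ifelse(y == 1, 1, -1))
      list(Xtr = X, gamma = gamma, alpha = a)
    },
    decision_tree = fit_cart(X, y, depth = hp$depth, min_leaf = hp$min_leaf),
    naive_bayes = {
      stats_by <- lapply(c(0, 1), function(c_) {
        Xc <- X[y == c_, , drop = FALSE]
        list(mu = colMeans(Xc),
             v = apply(Xc, 2, function(col) mean((col - mean(col))^2)) +
               hp$var_smoothing * max(apply(X, 2, var), 1),
             prior = mean(y == c_))
      })
      stats_by
    },
    random_forest = {
      set.seed(spec$seed)
      n <- nrow(X); p <- ncol(X)
      mtry <- max(1L, floor(sqrt(p)))
      trees <- lapply(seq_len(hp$n_trees), function(m) {
        rows <- sample.int(n, n, replace = TRUE) - 1L
        feats <- sample.int(p, mtry) - 1L
        fit_cart(X, y, rows = rows, feats = feats, depth = hp$depth,
                 min_leaf = hp$min_leaf)
      })
      trees
    },
    adaboost = {
      # SAMME with decision stumps
      n <- nrow(X)
      w <- rep(1 / n, n)
      stumps <- list(); alphas <- numeric(0)
      for (m in seq_len(hp$n_rounds)) {
        st <- fit_cart(X, y, w = w, depth = 1, min_leaf = 1)
        pred <- as.integer(cpp_cart_predict(st, X) >= 0.5)
        err <- sum(w[pred != y]) / sum(w)
        if (err >= 0.5 - 1e-10) break
        err <- max(err, 1e-10)
        a <- 0.5 * log((1 - err) / err)
        w <- w * exp(ifelse(pred != y, a, -a))
        w <- w / sum(w)
        stumps[[length(stumps) + 1]] <- st
        alphas <- c(alphas, a)
        if (err < 1e-9) break
      }
      if (!length(stumps)) {   # unlearnable: fall back to the prior
        stumps <- list(fit_cart(X, y, depth = 0)); alphas <- 1
      }
      list(stumps = stumps, alphas = alphas)
    },
    stop("unknown classifier: ", spec$name)
  )
  structure(list(name = spec$name, model = model, hyper = hp,
                 seed = spec$seed),
            class = "classifier_model")
}

#' Score samples with a fitted classifier
#'
#' Returns a numeric score monotone in P(y = 1): a probability where the
#' model provides one, otherwise the decision-function value.
#'
#' @param fit a `classifier_model`.
#' @param X numeric matrix.
#' @return Numeric score vector.
#' @export
classifier_predict <- function(fit, X) {
  X <- as.matrix(X)
  hp <- fit$hyper
  m <- fit$model
  switch(
    fit$name,
    logistic = {
      co <- m; co[!is.finite(co)] <- 0
      as.numeric(1 / (1 + exp(-(cbind(1, X) %*% co))))
    },
    knn = {
      D <- as.matrix(dist(rbind(m$X, X)))[seq_len(nrow(m$X)),
                                          -seq_len(nrow(m$X)), drop = FALSE]
      apply(D, 2, function(d) {
        nn <- order(d)[seq_len(min(m$k, length(d)))]
        mean(m$y[nn])
      })
    },
    qda = {
      if (m$type == "diag") classifier_predict(m$fit, X)
      else as.numeric(predict(m$fit, X)$posterior[, "1"])
    },
    svm_linear = as.numeric(X %*% m$w + m$b),
    svm_rbf = as.numeric(rbf_kernel(X, m$Xtr, m$gamma) %*% m$alpha + m$b),
    gboost = {
      f <- rep(0, nrow(X))
      for (tr in m$trees) f <- f + m$lr * cpp_cart_predict(tr, X)
      1 / (1 + exp(-f))
    },
    mlp = as.numeric(1 / (1 + exp(-m$fwd(m$theta, X)))),
    gaussian_process = as.numeric(rbf_kernel(X, m$Xtr, m$gamma) %*% m$alpha),
    decision_tree = as.numeric(cpp_cart_predict(m, X)),
    naive_bayes = {
      loglik <- function(s) {
        Z <- sweep(X, 2, s$mu)
        rowSums(sweep(Z^2, 2, -0.5 / s$v, `*`)) -
          0.5 * sum(log(2 * pi * s$v)) + log(max(s$prior, 1e-12))
      }
      l0 <- loglik(m[[1]]); l1 <- loglik(m[[2]])
      1 / (1 + exp(l0 - l1))
    },
    random_forest = {
      preds <- vapply(m, function(tr) cpp_cart_predict(tr, X),
                      numeric(nrow(X)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
      rowMeans(preds)
    },
    adaboost = {
      f <- rep(0, nrow(X))
      for (i in seq_along(m$stumps)) {
        pm <- ifelse(cpp_cart_predict(m$stumps[[i]], X) >= 0.5, 1, -1)
        f <- f + m$alphas[i] * pm
      }
      f / sum(m$alphas)
    },
    stop("unknown classifier: ", fit$name)
  )
}
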