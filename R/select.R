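# Thirteen feature-scoring/selection methods and the recursive-feature-
# addition wrapper. Information-theoretic criteria share one plug-in mutual
# information estimator on equal-frequency discretized features (5 bins by
# default); ties always break by feature-name order for reproducibility.

#' Selector configuration
#'
#' @param method one of CHSQ, RELF, MIM, FSCR, MIFS, GINI, ICAP, JMI, CIFE,
#'   CMIM, DISR, MRMR, TSCR.
#' @param n_select number of features to select.
#' @param mi_bins equal-frequency bins for MI discretization (default 5).
#' @param mifs_beta redundancy weight of MIFS (default 1).
#' @param relieff_k neighbours per class for ReliefF (default 10).
#' @return A `selector_config` list.
#' @export
selector_config <- function(method, n_select = 10, mi_bins = 5,
                            mifs_beta = 1, relieff_k = 10) {
  method <- match.arg(method, selector_names())
  if (n_select < 1) stop("n_select must be >= 1")
  if (mi_bins < 2) stop("mi_bins must be >= 2")
  structure(list(method = method, n_select = as.integer(n_select),
                 mi_bins = as.integer(mi_bins), mifs_beta = mifs_beta,
                 relieff_k = as.integer(relieff_k)),
            class = "selector_config")
}

#' The 13 selector names
#' @return Character vector.
#' @export
selector_names <- function() {
  c("CHSQ", "RELF", "MIM", "FSCR", "MIFS", "GINI", "ICAP",
    "JMI", "CIFE", "CMIM", "DISR", "MRMR", "TSCR")
}

# equal-frequency discretization into <= bins levels (integer codes)
equal_freq_bin <- function(x, bins = 5) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), type = 7))
  if (length(qs) <= 2) return(as.integer(x > qs[1]) + 1L)
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

#' Plug-in mutual information of two discrete vectors
#'
#' `I(X;Y) = sum p(x,y) log(p(x,y) / (p(x) p(y)))`, natural log, from the
#' empirical joint table. Non-negative up to floating-point error.
#'
#' @param x,y integer/factor vectors of equal length.
#' @return MI in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  jt <- table(x, y) / length(x)
  px <- rowSums(jt); py <- colSums(jt)
  pp <- outer(px, py)
  nz <- jt > 0
  max(sum(jt[nz] * log(jt[nz] / pp[nz])), 0)
}

#' Conditional mutual information I(X;Y|Z)
#'
#' @param x,y,z discrete vectors of equal length.
#' @return CMI in nats (>= 0).
#' @export
conditional_mutual_information <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) stop("length mismatch")
  tot <- 0
  n <- length(x)
  for (zz in unique(z)) {
    sel <- z == zz
    tot <- tot + sum(sel) / n * mutual_information(x[sel], y[sel])
  }
  max(tot, 0)
}

# joint entropy of up to three discrete vectors (nats)
joint_entropy <- function(...) {
  jt <- table(...) / length(..1)
  p <- jt[jt > 0]
  -sum(p * log(p))
}

# ---- univariate scores ------------------------------------------------------

relieff_weights <- function(X, y, k = 10) {
  # ReliefF with all samples as "hits"; distances on [0,1]-rescaled features
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(c) diff(range(c)))
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, `/`)
  D <- as.matrix(dist(Xs, method = "manhattan"))
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    same <- which(y == y[i]); same <- same[same != i]
    diff_ <- which(y != y[i])
    kh <- min(k, length(same)); km <- min(k, length(diff_))
    if (kh == 0 || km == 0) next
    hits <- same[order(d[same])][seq_len(kh)]
    miss <- diff_[order(d[diff_])][seq_len(km)]
    for (j in seq_len(p)) {
      w[j] <- w[j] - sum(abs(Xs[i, j] - Xs[hits, j])) / (kh * n) +
        sum(abs(Xs[i, j] - Xs[miss, j])) / (km * n)
    }
  }
  w
}

#' Univariate relevance scores for all 13 methods
#'
#' Larger is always more relevant. CHSQ: chi-square statistic on the
#' discretized feature x class table. FSCR: Fisher score
#' `sum n_c (mu_c - mu)^2 / sum n_c var_c`. TSCR: |Welch t|. GINI: impurity
#' decrease of the best single split. RELF: ReliefF weights. MIM and the
#' other MI criteria reduce to I(X;Y) univariately.
#'
#' @param table feature data.frame.
#' @param labels binary labels (0/1), two classes present.
#' @param method selector name.
#' @param config a [selector_config()] (bins, k).
#' @return Named numeric score vector, one per feature.
#' @export
score_features <- function(table, labels, method,
                           config = selector_config(method)) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("labels must contain two classes")
  X <- as.matrix(table)
  p <- ncol(X)
  scores <- switch(
    method,
    CHSQ = vapply(seq_len(p), function(j) {
      tb <- table(equal_freq_bin(X[, j], config$mi_bins), y)
      e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
      sum((tb - e)^2 / pmax(e, .Machine$double.eps))
    }, numeric(1)),
    RELF = relieff_weights(X, y, config$relieff_k),
    FSCR = vapply(seq_len(p), function(j) {
      x <- X[, j]; mu <- mean(x)
      num <- den <- 0
      for (c_ in unique(y)) {
        xc <- x[y == c_]
        num <- num + length(xc) * (mean(xc) - mu)^2
        den <- den + length(xc) * mean((xc - mean(xc))^2)
      }
      if (den > 0) num / den else 0
    }, numeric(1)),
    TSCR = vapply(seq_len(p), function(j) {
      x0 <- X[y == 0, j]; x1 <- X[y == 1, j]
      se <- sqrt(var(x0) / length(x0) + var(x1) / length(x1))
      if (se > 0) abs(mean(x1) - mean(x0)) / se else 0
    }, numeric(1)),
    GINI = vapply(seq_len(p), function(j) {
      x <- X[, j]
      n <- length(x)
      gini <- function(yy) { pr <- mean(yy); 2 * pr * (1 - pr) }
      parent <- gini(y)
      cand <- sort(unique(x))
      if (length(cand) < 2) return(0)
      thr <- (head(cand, -1) + tail(cand, -1)) / 2
      best <- 0
      for (t_ in thr) {
        l <- y[x <= t_]; r <- y[x > t_]
        dec <- parent - (length(l) * gini(l) + length(r) * gini(r)) / n
        if (dec > best) best <- dec
      }
      best
    }, numeric(1)),
    # all MI-based criteria share univariate relevance I(X;Y)
    vapply(seq_len(p), function(j)
      mutual_information(equal_freq_bin(X[, j], config$mi_bins), y),
      numeric(1))
  )
  names(scores) <- colnames(table)
  scores
}

# ---- greedy information-theoretic selection ---------------------------------

greedy_criteria <- c("MIM", "MIFS", "MRMR", "JMI", "CMIM", "CIFE", "ICAP", "DISR")

#' Sequential forward selection under an information-theoretic criterion
#'
#' At each step the candidate X maximizing the criterion J(X | selected S)
#' is added: MIM `I(X;Y)`; MIFS `I(X;Y) - beta sum_S I(X;Xs)`; MRMR
#' `I(X;Y) - mean_S I(X;Xs)`; JMI `sum_S I(X,Xs;Y)`; CMIM
#' `min_S I(X;Y|Xs)`; CIFE `I(X;Y) - sum_S (I(X;Xs) - I(X;Xs|Y))`; ICAP
#' `I(X;Y) - sum_S max(0, I(X;Xs) - I(X;Xs|Y))`; DISR
#' `sum_S I(X,Xs;Y) / H(X,Xs,Y)`. Ties break by feature-name order.
#'
#' @param table feature data.frame.
#' @param labels binary labels.
#' @param method one of MIM, MIFS, MRMR, JMI, CMIM, CIFE, ICAP, DISR.
#' @param n_select number of features.
#' @param config a [selector_config()].
#' @return Character vector of selected names, in selection order.
#' @export
greedy_select <- function(table, labels, method, n_select,
                          config = selector_config(method, n_select)) {
  method <- match.arg(method, greedy_criteria)
  y <- as.integer(labels)
  feats <- colnames(table)
  if (n_select > length(feats)) {
    warning("n_select exceeds feature count; selecting all")
    n_select <- length(feats)
  }
  # order candidates by name for deterministic tie-breaks
  ford <- order(feats)
  D <- lapply(table, equal_freq_bin, bins = config$mi_bins)
  rel <- vapply(D, mutual_information, numeric(1), y = y)
  sel <- character(0)
  avail <- feats[ford]
  # caches of pairwise statistics against selected features
  red <- list()     # I(X;Xs)
  redc <- list()    # I(X;Xs|Y)
  jmi_ <- list()    # I(X,Xs;Y)
  disr_ <- list()   # I(X,Xs;Y)/H(X,Xs,Y)
  cmim_ <- stats::setNames(rep(Inf, length(feats)), feats)  # running min I(X;Y|Xs)
  for (step in seq_len(n_select)) {
    if (length(sel)) {
      s_new <- sel[length(sel)]
      for (f in avail) {
        if (method %in% c("MIFS", "MRMR", "CIFE", "ICAP"))
          red[[f]] <- c(red[[f]], mutual_information(D[[f]], D[[s_new]]))
        if (method %in% c("CIFE", "ICAP"))
          redc[[f]] <- c(redc[[f]],
                         conditional_mutual_information(D[[f]], D[[s_new]], y))
        if (method == "JMI")
          jmi_[[f]] <- c(jmi_[[f]],
                         mutual_information(interaction(D[[f]], D[[s_new]],
                                                        drop = TRUE), y))
        if (method == "DISR") {
          jxy <- mutual_information(interaction(D[[f]], D[[s_new]],
                                                drop = TRUE), y)
          hh <- joint_entropy(D[[f]], D[[s_new]], y)
          disr_[[f]] <- c(disr_[[f]], if (hh > 0) jxy / hh else 0)
        }
        if (method == "CMIM")
          cmim_[f] <- min(cmim_[f],
                          conditional_mutual_information(D[[f]], y, D[[s_new]]))
      }
    }
    J <- vapply(avail, function(f) {
      if (!length(sel)) return(rel[f])
      switch(method,
             MIM = rel[f],
             MIFS = rel[f] - config$mifs_beta * sum(red[[f]]),
             MRMR = rel[f] - mean(red[[f]]),
             JMI = sum(jmi_[[f]]),
             CMIM = cmim_[f],
             CIFE = rel[f] - sum(red[[f]] - redc[[f]]),
             ICAP = rel[f] - sum(pmax(0, red[[f]] - redc[[f]])),
             DISR = sum(disr_[[f]]))
    }, numeric(1))
    pick <- avail[which.max(J)]   # avail is name-sorted: first max wins ties
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
    if (!length(avail)) break
  }
  sel
}

#' Select features with any of the 13 methods
#'
#' Greedy criteria use [greedy_select()]; pure scoring methods rank by
#' [score_features()] and take the top `n_select` (name order on ties).
#'
#' @param table feature data.frame.
#' @param labels binary labels.
#' @param config a [selector_config()].
#' @return Character vector of selected feature names.
#' @export
select_features <- function(table, labels, config) {
  if (config$method %in% greedy_criteria)
    return(greedy_select(table, labels, config$method, config$n_select, config))
  sc <- score_features(table, labels, config$method, config)
  ord <- order(-sc, names(sc))
  head(names(sc)[ord], min(config$n_select, length(sc)))
}

#' Recursive feature addition wrapper
#'
#' Walks a ranked feature list; a feature is kept iff adding it improves the
#' mean cross-validated AUC of `estimator` by more than `tol`.
#'
#' @param ranked_features character vector (most relevant first).
#' @param table feature data.frame.
#' @param labels binary labels.
#' @param estimator a classifier spec from [classifier_registry()] (default
#'   logistic regression).
#' @param k CV folds.
#' @param seed fold seed.
#' @param tol minimum AUC improvement (default 1e-4).
#' @param max_features hard cap (default 20).
#' @return Character vector: the retained subset (a subsequence of the
#'   input ranking).
#' @export
recursive_feature_addition <- function(ranked_features, table, labels,
                                       estimator = NULL, k = 5, seed = 1L,
                                       tol = 1e-4, max_features = 20) {
  if (is.null(estimator)) estimator <- classifier_registry()[["logistic"]]
  y <- as.integer(labels)
  folds <- stratified_kfold(y, k = k, seed = seed)
  cv_auc <- function(feats) {
    aucs <- vapply(seq_len(k), function(fi) {
      tr <- folds != fi; te <- !tr
      fit <- classifier_fit(estimator, as.matrix(table[tr, feats, drop = FALSE]),
                            y[tr])
      sc <- classifier_predict(fit, as.matrix(table[te, feats, drop = FALSE]))
      auc(y[te], sc)
    }, numeric(1))
    mean(aucs)
  }
  current <- character(0)
  best <- 0.5        # chance-level baseline for the empty model
  for (f in ranked_features) {
    if (length(current) >= max_features) break
    a <- cv_auc(c(current, f))
    if (isTRUE(a > best + tol)) {
      current <- c(current, f)
      best <- a
    }
  }
  if (!length(current)) current <- ranked_features[1]
  current
}
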