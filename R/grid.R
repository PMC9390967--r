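# Model grid: SMOTE rebalancing, stratified k-fold CV, Mann-Whitney AUC,
# the RSD stability criterion, the extractor x selector x classifier grid
# and confusion-matrix metrics. Standardization, SMOTE and feature
# selection are all fit strictly inside training folds.

#' SMOTE minority oversampling
#'
#' Synthetic minority samples `x_new = x_i + u (x_nn - x_i)`, `u ~ U(0,1)`,
#' with `x_nn` one of the `k_neighbors` nearest minority neighbours, until
#' the classes balance. Originals are preserved.
#'
#' @param X numeric matrix.
#' @param y binary labels (0/1).
#' @param k_neighbors neighbour pool size (default 5).
#' @param seed integer seed.
#' @return List with balanced `X` and `y`.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1L else 0L
  Xm <- X[y == minority, , drop = FALSE]
  nm <- nrow(Xm)
  if (nm < 2) stop("minority class needs at least 2 samples for SMOTE")
  need <- abs(n1 - n0)
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  set.seed(seed)
  idx <- sample.int(nm, need, replace = TRUE)
  new_rows <- matrix(0, need, ncol(X))
  for (r in seq_len(need)) {
    i <- idx[r]
    nb <- order(D[i, ])[seq_len(min(k_neighbors, nm - 1))]
    j <- nb[sample.int(length(nb), 1)]
    u <- runif(1)
    new_rows[r, ] <- Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
  }
  list(X = rbind(X, new_rows), y = c(y, rep(minority, need)))
}

#' Stratified k-fold assignments
#'
#' Shuffles within class, then deals class members round-robin so per-fold
#' class counts differ from exact proportionality by at most 1.
#'
#' @param labels binary label vector.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return Integer fold id (1..k) per sample.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L) {
  y <- as.integer(labels)
  for (cls in unique(y)) {
    if (sum(y == cls) < k)
      stop(sprintf("class %d has %d < k = %d members; use a smaller k",
                   cls, sum(y == cls), k))
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    ids <- which(y == cls)
    ids <- ids[sample.int(length(ids))]
    folds[ids] <- rep(seq_len(k), length.out = length(ids))
  }
  folds
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' `AUC = P(score+ > score-) + 0.5 P(tie)` over all positive/negative
#' pairs.
#'
#' @param labels binary labels (both classes present).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  y <- as.integer(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (!length(pos) || !length(neg))
    stop("AUC needs both classes present")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Relative standard deviation of fold AUCs
#'
#' `RSD = 100 * sd(fold_aucs) / mean(fold_aucs)` with the sample SD.
#'
#' @param fold_aucs numeric vector of per-fold AUCs.
#' @return RSD in percent.
#' @export
rsd <- function(fold_aucs) {
  m <- mean(fold_aucs)
  if (m <= 0) stop("mean fold AUC must be > 0")
  100 * sd(fold_aucs) / m
}

#' Cross-validation configuration
#'
#' @param k folds (default 10).
#' @param seed fold/SMOTE seed.
#' @param smote apply SMOTE inside training folds.
#' @param smote_k SMOTE neighbour count.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 10, seed = 1L, smote = TRUE, smote_k = 5) {
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 smote = smote, smote_k = as.integer(smote_k)),
            class = "cv_config")
}

# one (table, selector) fold-wise selection + per-classifier AUCs.
# Selection and standardization are fit on the training fold only; SMOTE is
# applied after selection, before the classifier fit.
grid_cell <- function(table, labels, sel_cfg, classifiers, cv) {
  y <- as.integer(labels)
  folds <- stratified_kfold(y, k = cv$k, seed = cv$seed)
  cell <- lapply(classifiers, function(cl)
    list(fold_aucs = numeric(0), scores = numeric(length(y)),
         preds = integer(length(y)), features = NULL, failed = FALSE,
         message = NA_character_))
  for (fi in seq_len(cv$k)) {
    tr <- folds != fi; te <- !tr
    res <- tryCatch({
      st <- standardize(table[tr, , drop = FALSE],
                        list(table[te, , drop = FALSE]))
      feats <- select_features(st$train, y[tr], sel_cfg)
      Xtr <- as.matrix(st$train[, feats, drop = FALSE])
      Xte <- as.matrix(st$applied[[1]][, feats, drop = FALSE])
      ytr <- y[tr]
      if (cv$smote) {
        sm <- smote_oversample(Xtr, ytr, cv$smote_k,
                               seed = cv$seed + fi)
        Xtr <- sm$X; ytr <- sm$y
      }
      list(Xtr = Xtr, Xte = Xte, ytr = ytr, feats = feats)
    }, error = function(e) e)
    for (ci in seq_along(classifiers)) {
      if (inherits(res, "error")) {
        cell[[ci]]$failed <- TRUE
        cell[[ci]]$message <- conditionMessage(res)
        next
      }
      out <- tryCatch({
        fit <- classifier_fit(classifiers[[ci]], res$Xtr, res$ytr)
        sc <- classifier_predict(fit, res$Xte)
        list(auc = auc(y[te], sc), sc = sc)
      }, error = function(e) e)
      if (inherits(out, "error")) {
        cell[[ci]]$failed <- TRUE
        cell[[ci]]$message <- conditionMessage(out)
      } else {
        cell[[ci]]$fold_aucs <- c(cell[[ci]]$fold_aucs, out$auc)
        cell[[ci]]$scores[te] <- out$sc
        cell[[ci]]$preds[te] <- as.integer(out$sc >= stats::median(out$sc))
        cell[[ci]]$features <- res$feats
      }
    }
  }
  cell
}

#' Run the extractor x selector x classifier model grid
#'
#' For every combination: inside each training fold the features are
#' standardized, selected, SMOTE-rebalanced and a classifier is fitted,
#' then the untouched test fold is scored. Rows are named
#' `<extractor>_<selector>_<classifier>`.
#'
#' @param feature_tables named list of feature `data.frame`s (one per
#'   extractor), all row-aligned with `labels`.
#' @param labels binary labels.
#' @param selectors character vector of selector names (default all 13).
#' @param classifiers named list from [classifier_registry()].
#' @param cv a [cv_config()].
#' @param n_select features per selector (default 10).
#' @return data.frame of grid rows: extractor, selector, classifier, one
#'   column per fold AUC, mean_auc, sd_auc, rsd, failed, selected features
#'   (attribute `selected`), plus pooled out-of-fold scores (attribute
#'   `scores`).
#' @export
run_grid <- function(feature_tables, labels, selectors = selector_names(),
                     classifiers = classifier_registry(),
                     cv = cv_config(), n_select = 10) {
  stopifnot(length(names(feature_tables)) == length(feature_tables))
  rows <- list(); selected <- list(); scores <- list()
  for (ex in names(feature_tables)) {
    tab <- feature_tables[[ex]]
    if (nrow(tab) != length(labels)) stop("table rows must align with labels")
    for (sel in selectors) {
      sel_cfg <- selector_config(sel, n_select = n_select)
      cell <- grid_cell(tab, labels, sel_cfg, classifiers, cv)
      for (ci in seq_along(classifiers)) {
        cl <- names(classifiers)[ci]
        nm <- paste(ex, sel, cl, sep = "_")
        cc <- cell[[ci]]
        if (cc$failed || length(cc$fold_aucs) < cv$k) {
          rows[[nm]] <- data.frame(
            extractor = ex, selector = sel, classifier = cl,
            mean_auc = NA_real_, sd_auc = NA_real_, rsd = NA_real_,
            failed = TRUE, message = cc$message, stringsAsFactors = FALSE)
        } else {
          rows[[nm]] <- data.frame(
            extractor = ex, selector = sel, classifier = cl,
            mean_auc = mean(cc$fold_aucs), sd_auc = sd(cc$fold_aucs),
            rsd = rsd(cc$fold_aucs), failed = FALSE,
            message = NA_character_, stringsAsFactors = FALSE)
          selected[[nm]] <- cc$features
          scores[[nm]] <- cc$scores
        }
        rows[[nm]]$fold_aucs <- I(list(cc$fold_aucs))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$model <- rownames(out)
  attr(out, "selected") <- selected
  attr(out, "scores") <- scores
  attr(out, "labels") <- as.integer(labels)
  out
}

#' Select the best grid row
#'
#' Highest mean AUC; ties broken by lowest RSD, then by model name.
#'
#' @param rows grid data.frame from [run_grid()].
#' @return The single best row (data.frame of one row).
#' @export
select_best <- function(rows) {
  ok <- rows[!rows$failed & !is.na(rows$mean_auc), , drop = FALSE]
  if (!nrow(ok)) stop("all grid rows failed")
  ord <- order(-ok$mean_auc, ok$rsd, ok$model)
  ok[ord[1], , drop = FALSE]
}

#' Confusion-matrix metrics
#'
#' ACC, sensitivity, specificity, precision and F1 for binary predictions;
#' zero-denominator cases return 0 (flagged via attribute
#' `degenerate = TRUE`).
#'
#' @param labels true binary labels.
#' @param predictions predicted binary labels.
#' @return Named numeric vector (acc, sensitivity, specificity, precision,
#'   f1).
#' @export
confusion_metrics <- function(labels, predictions) {
  y <- as.integer(labels); p <- as.integer(predictions)
  tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
  safe <- function(num, den) if (den > 0) num / den else 0
  sens <- safe(tp, tp + fn); spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  out <- c(acc = (tp + tn) / length(y), sensitivity = sens,
           specificity = spec, precision = prec, f1 = f1)
  attr(out, "degenerate") <- (tp + fn == 0) || (tn + fp == 0) || (tp + fp == 0)
  out
}
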