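# Feature-stability scoring: ICC(2,1) across perturbation families and
# test-retest pairs, the ICC > 0.75 gate, zero-MAD removal and
# train-statistics standardization.

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement
#' (Shrout-Fleiss). From the two-way ANOVA mean squares (rows = subjects,
#' columns = versions/raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#'
#' @param m numeric matrix, `n_subjects x k_versions` (n >= 3, k >= 2).
#' @return ICC value in `(-Inf, 1]`; may be negative.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("ICC(2,1) needs at least 3 subjects")
  if (k < 2) stop("ICC(2,1) needs at least 2 versions")
  if (any(!is.finite(m))) stop("measurement matrix must be finite")
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den <= 0) {
    if (msr == 0 && msc == 0 && mse == 0)
      stop("degenerate measurement matrix (zero total variance)")
    return(0)
  }
  (msr - mse) / den
}

#' Per-family ICC reports for every feature
#'
#' For each feature, stacks the baseline column with the family's perturbed
#' versions into an `n_subjects x k` measurement matrix and computes
#' ICC(2,1). Features with zero total variance are reported with `icc = NA`
#' (they are dropped later by the zero-MAD filter anyway).
#'
#' @param baseline_table feature `data.frame` (rows = subjects).
#' @param perturbed_tables list of feature tables, same rows and columns.
#' @param family family label recorded in the report.
#' @return data.frame with columns `feature`, `family`, `icc`,
#'   `n_subjects`, `k_versions`.
#' @export
family_icc <- function(baseline_table, perturbed_tables, family) {
  for (pt in perturbed_tables) {
    if (!identical(dim(pt), dim(baseline_table)) ||
        !identical(colnames(pt), colnames(baseline_table)))
      stop("perturbed tables must share rows and columns with the baseline")
    bad <- rownames(pt) != rownames(baseline_table)
    if (any(bad))
      stop("subject rows mismatch: ",
           paste(head(rownames(baseline_table)[bad], 5), collapse = ", "))
  }
  k <- length(perturbed_tables) + 1L
  n <- nrow(baseline_table)
  iccs <- vapply(seq_along(baseline_table), function(jc) {
    m <- cbind(baseline_table[[jc]],
               do.call(cbind, lapply(perturbed_tables, `[[`, jc)))
    tryCatch(icc_2_1(m), error = function(e) NA_real_)
  }, numeric(1))
  data.frame(feature = colnames(baseline_table), family = family,
             icc = iccs, n_subjects = n, k_versions = k,
             stringsAsFactors = FALSE)
}

#' Compute ICC reports across all perturbation families
#'
#' Convenience wrapper: extracts features for the baseline cohort and every
#' perturbed version, then scores each family.
#'
#' @param cohort list of baseline [lesion_sample()]s.
#' @param specs perturbation grids ([perturbation_defaults()]).
#' @param config an [extraction_config()].
#' @param preprocess a [preprocess_config()].
#' @return List with `reports` (rbind of per-family reports) and
#'   `baseline_table`.
#' @export
cohort_perturbation_icc <- function(cohort, specs = perturbation_defaults(),
                                    config = extraction_config(wavelet = FALSE),
                                    preprocess = preprocess_config()) {
  psets <- lapply(cohort, build_perturbation_set, specs = specs)
  fams <- names(specs)
  baseline <- extract_cohort(cohort, config, preprocess)
  reports <- NULL
  for (fam in fams) {
    nv <- length(psets[[1]][[fam]]) - 1L
    if (nv < 1) next
    ptabs <- lapply(seq_len(nv) + 1L, function(vi) {
      vs <- lapply(psets, function(ps) ps[[fam]][[vi]])
      tt <- extract_cohort(vs, config, preprocess)
      rownames(tt) <- rownames(baseline)   # replicate tag differs by design
      tt
    })
    reports <- rbind(reports, family_icc(baseline, ptabs, fam))
  }
  list(reports = reports, baseline_table = baseline)
}

#' Robustness filter configuration
#'
#' @param icc_threshold retention cutoff (strict `>`; default 0.75).
#' @param require_all_families if `TRUE` (default) the minimum ICC over
#'   families is gated; otherwise families are pooled by mean.
#' @return A `robust_filter_config` list.
#' @export
robust_filter_config <- function(icc_threshold = 0.75,
                                 require_all_families = TRUE) {
  if (icc_threshold < 0 || icc_threshold > 1) stop("threshold must be in [0,1]")
  structure(list(icc_threshold = icc_threshold,
                 require_all_families = require_all_families),
            class = "robust_filter_config")
}

#' Filter features by ICC robustness
#'
#' A feature is retained iff its minimum ICC over families is strictly
#' greater than the threshold (`require_all_families = TRUE`), or its mean
#' ICC is when pooling. `NA` ICCs (degenerate features) never pass.
#'
#' @param reports ICC report data.frame from [family_icc()].
#' @param config a [robust_filter_config()].
#' @return Character vector of retained feature names (original column
#'   order of the reports).
#' @export
filter_robust <- function(reports, config = robust_filter_config()) {
  agg <- if (config$require_all_families) {
    tapply(reports$icc, reports$feature, function(v) min(v))
  } else {
    tapply(reports$icc, reports$feature, function(v) mean(v))
  }
  keep <- names(agg)[!is.na(agg) & agg > config$icc_threshold]
  # restore first-appearance order
  ord <- unique(reports$feature)
  ord[ord %in% keep]
}

#' Remove zero-MAD (nonpredictive) feature columns
#'
#' Drops every column whose median absolute deviation about the column
#' median is exactly zero.
#'
#' @param table feature data.frame.
#' @return The table without zero-MAD columns.
#' @export
remove_zero_mad <- function(table) {
  if (ncol(table) == 0) stop("empty feature table")
  mads <- vapply(table, function(col)
    median(abs(col - median(col))), numeric(1))
  keep <- mads > 0
  if (!any(keep)) stop("all columns have zero MAD")
  out <- table[, keep, drop = FALSE]
  attr(out, "labels") <- attr(table, "labels")
  out
}

#' Standardize feature tables with train-derived statistics
#'
#' Centers to the training mean and scales to unit training SD (population
#' SD, divisor `n`, the scikit-learn StandardScaler convention); the
#' identical transform is applied to any held-out tables, guarding against
#' information leakage.
#'
#' @param train_table training feature data.frame.
#' @param apply_tables optional list of held-out tables with the same
#'   columns.
#' @return List with `train` and `applied` (list), plus `center`/`scale`.
#' @export
standardize <- function(train_table, apply_tables = list()) {
  ctr <- vapply(train_table, mean, numeric(1))
  scl <- vapply(train_table, function(col)
    sqrt(mean((col - mean(col))^2)), numeric(1))
  zero <- !is.finite(scl) | scl == 0
  if (any(zero))
    stop("zero train SD in column(s): ",
         paste(head(colnames(train_table)[zero], 5), collapse = ", "))
  tf <- function(tab) {
    out <- as.data.frame(sweep(sweep(as.matrix(tab), 2, ctr), 2, scl, `/`))
    rownames(out) <- rownames(tab)
    attr(out, "labels") <- attr(tab, "labels")
    out
  }
  list(train = tf(train_table), applied = lapply(apply_tables, tf),
       center = ctr, scale = scl)
}
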