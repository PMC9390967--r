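# Feature extraction front-end: 107 original features (14 shape +
# 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM) and
# optionally the 93 non-shape features on each of the 8 stationary-wavelet
# sub-bands (744), i.e. 851 features in total. Column names follow
# `<filter>_<class>_<name>` with filters `original` and `wavelet-LLL` ...
# `wavelet-HHH`.

#' Extraction configuration
#'
#' @param wavelet logical; add the 8 wavelet sub-band feature sets.
#' @param disc a [discretization_config()]; texture matrices are
#'   re-discretized per image filter (each sub-band gets its own in-mask
#'   minimum).
#' @param intensity_scale factor applied to the (normalized, `[0,1]`)
#'   preprocessed volume before extraction; the default 255 puts
#'   intensities on the 8-bit display scale the default 25-wide bins
#'   assume. Use 1 when feeding raw-HU volumes.
#' @param gldm_alpha GLDM dependence tolerance.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(wavelet = TRUE, disc = discretization_config(),
                              intensity_scale = 255, gldm_alpha = 0) {
  structure(list(wavelet = wavelet, disc = disc,
                 intensity_scale = intensity_scale, gldm_alpha = gldm_alpha),
            class = "extraction_config")
}

# 93 intensity/texture features of one image filter (no shape)
filter_features <- function(data, mask, spacing, config) {
  fo <- firstorder_features(data, mask, spacing, config$disc)
  dd <- discretize(data, mask, config$disc)
  gl <- glcm_features(glcm_matrix(dd$levels, dd$ng))
  tm <- texture_matrices(dd$levels, dd$ng, config$gldm_alpha)
  np <- sum(mask)
  rl <- glrlm_features(tm$glrlm, np)
  sz <- glszm_features(tm$glszm, np)
  dmf <- gldm_features(tm$gldm)
  ng <- ngtdm_features(tm$ngtdm)
  c(stats::setNames(fo, paste0("firstorder_", names(fo))),
    stats::setNames(gl, paste0("glcm_", names(gl))),
    stats::setNames(rl, paste0("glrlm_", names(rl))),
    stats::setNames(sz, paste0("glszm_", names(sz))),
    stats::setNames(dmf, paste0("gldm_", names(dmf))),
    stats::setNames(ng, paste0("ngtdm_", names(ng))))
}

#' Extract all radiomics features from one (preprocessed) lesion sample
#'
#' Shape features are computed once on the original mask; first-order and
#' the five texture classes are computed on the original image and, when
#' `config$wavelet` is on, on each of the 8 coif1 stationary-wavelet
#' sub-bands (re-discretized per sub-band). Any non-finite feature value is
#' an error, never silently dropped.
#'
#' @param sample a [lesion_sample()], normally from [preprocess_sample()].
#' @param config an [extraction_config()].
#' @return Named numeric vector of 851 (wavelet on) or 107 (off) features.
#' @export
extract_all <- function(sample, config = extraction_config()) {
  data <- sample$volume$data * config$intensity_scale
  mask <- sample$mask$data
  spacing <- sample$volume$spacing
  sh <- shape_features(mask, spacing)
  orig <- filter_features(data, mask, spacing, config)
  out <- c(stats::setNames(sh, paste0("original_shape_", names(sh))),
           stats::setNames(orig, paste0("original_", names(orig))))
  if (config$wavelet) {
    bands <- wavelet_decompose(data)
    for (bn in names(bands)) {
      fv <- filter_features(bands[[bn]], mask, spacing, config)
      out <- c(out, stats::setNames(fv, paste0("wavelet-", bn, "_", names(fv))))
    }
  }
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(head(names(out)[bad], 5), collapse = ", "))
  out
}

#' Parse feature names into provenance (filter, class, name)
#'
#' @param feature_names character vector of `<filter>_<class>_<name>` names.
#' @return data.frame with columns `filter`, `class`, `name`.
#' @export
feature_provenance <- function(feature_names) {
  parts <- regmatches(feature_names,
                      regexec("^([^_]+)_([^_]+)_(.+)$", feature_names))
  data.frame(filter = vapply(parts, `[`, "", 2),
             class = vapply(parts, `[`, "", 3),
             name = vapply(parts, `[`, "", 4),
             stringsAsFactors = FALSE)
}

#' Extract a feature table for a cohort
#'
#' @param cohort list of [lesion_sample()]s.
#' @param config an [extraction_config()].
#' @param preprocess a [preprocess_config()] applied to every sample first,
#'   or `NULL` if samples are already preprocessed.
#' @return A `data.frame`: one row per sample (rownames
#'   `<subject>:<replicate>`), one column per feature, plus the attribute
#'   `labels` (integer vector aligned with rows).
#' @export
extract_cohort <- function(cohort, config = extraction_config(),
                           preprocess = preprocess_config()) {
  rows <- lapply(cohort, function(s) {
    if (!is.null(preprocess)) s <- preprocess_sample(s, preprocess)
    extract_all(s, config)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- vapply(cohort, function(s)
    paste0(s$subject_id, ":", s$replicate), "")
  attr(tab, "labels") <- vapply(cohort, function(s) s$label, integer(1))
  tab
}

#' Default seven-slot extractor registry
#'
#' With CNN-based extraction out of scope, the seven extractor slots are
#' filled by radiomics variants that differ in discretization, wavelet use
#' and preprocessing — enough to make every slot a genuinely different view
#' of the same lesions. Each entry holds an `extraction_config` and a
#' `preprocess_config`.
#'
#' @param wavelet logical; allow wavelet-using slots (turn off for speed in
#'   large grid runs).
#' @return Named list of extractor specs.
#' @export
extractor_registry <- function(wavelet = TRUE) {
  pp <- preprocess_config()
  list(
    radiomics = list(extract = extraction_config(wavelet = wavelet), preprocess = pp),
    radiomics_bw10 = list(
      extract = extraction_config(wavelet = FALSE,
                                  disc = discretization_config(bin_width = 10)),
      preprocess = pp),
    radiomics_bw50 = list(
      extract = extraction_config(wavelet = FALSE,
                                  disc = discretization_config(bin_width = 50)),
      preprocess = pp),
    radiomics_bc16 = list(
      extract = extraction_config(wavelet = FALSE,
                                  disc = discretization_config("fixed_bin_count",
                                                               bin_count = 16)),
      preprocess = pp),
    radiomics_eq = list(
      extract = extraction_config(wavelet = FALSE),
      preprocess = preprocess_config(equalize = TRUE)),
    radiomics_smooth = list(
      extract = extraction_config(wavelet = FALSE),
      preprocess = preprocess_config(gauss_sigma_mm = 1.5)),
    radiomics_sharp = list(
      extract = extraction_config(wavelet = FALSE),
      preprocess = preprocess_config(gauss_sigma_mm = 0))
  )
}
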