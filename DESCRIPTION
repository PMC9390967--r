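Package: radrobust
Title: Robustness-Aware CT Radiomics Modelling for Treatment-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for building perturbation-robust CT
    radiomics classifiers of binary treatment response. Provides a synthetic
    CT-lesion cohort generator (ellipsoidal lesions with Gaussian-random-field
    texture, acquisition noise and test-retest replicates), image
    preprocessing (windowing, histogram equalization, Gaussian denoising,
    maximum-area slab selection, resampling), three perturbation families
    (slice spacing, in-plane rotation, ROI dilation/erosion), a from-scratch
    radiomics feature extractor (shape, first-order, GLCM, GLRLM, GLSZM,
    GLDM, NGTDM, with stationary-wavelet sub-band variants; 851 features),
    ICC(2,1) feature-robustness filtering, thirteen univariate and
    information-theoretic feature selectors with a recursive-feature-addition
    wrapper, SMOTE rebalancing, and a stratified cross-validated
    extractor x selector x classifier model grid selected by mean AUC and
    relative standard deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
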