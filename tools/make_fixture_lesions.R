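# Generates the three fixture lesions used by the oracle-equivalence tests.
# Each fixture is the *preprocessed* slab (windowed, denoised, 3 axial
# slices, scaled to 0-255) written as plain text, so the Python reference
# implementation and the R extractor consume byte-identical inputs.
# Run from the repository root:  Rscript tools/make_fixture_lesions.R

library(radrobust)

outdir <- "tests/testthat/fixtures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  lesion1 = list(p = lesion_params(semiaxes_mm = c(7, 6, 5), texture_corr_mm = 3,
                                   texture_sd_hu = 40, noise_sd_hu = 10),
                 spacing = c(0.75, 0.75, 1), shape = c(28, 28, 20), seed = 101L),
  lesion2 = list(p = lesion_params(semiaxes_mm = c(6, 6, 6), texture_corr_mm = 1.5,
                                   texture_sd_hu = 60, noise_sd_hu = 20),
                 spacing = c(0.75, 0.75, 1), shape = c(28, 28, 20), seed = 202L),
  lesion3 = list(p = lesion_params(semiaxes_mm = c(8, 5, 5), texture_corr_mm = 5,
                                   texture_sd_hu = 30, noise_sd_hu = 5),
                 spacing = c(0.75, 0.75, 2), shape = c(28, 28, 12), seed = 303L)
)

for (nm in names(specs)) {
  sp <- specs[[nm]]
  s <- generate_lesion(sp$p, spacing = sp$spacing, shape = sp$shape,
                       seed = sp$seed, subject_id = nm)
  pp <- preprocess_sample(s, preprocess_config())
  img <- pp$volume$data * 255
  d <- dim(img)
  hdr <- sprintf("# dims %d %d %d spacing %g %g %g", d[1], d[2], d[3],
                 pp$volume$spacing[1], pp$volume$spacing[2], pp$volume$spacing[3])
  writeLines(c(hdr, sprintf("%.8g", as.numeric(img))),
             file.path(outdir, paste0(nm, "_volume.txt")))
  writeLines(c(hdr, sprintf("%d", as.integer(pp$mask$data))),
             file.path(outdir, paste0(nm, "_mask.txt")))
  cat(nm, ": ", sum(pp$mask$data), "mask voxels\n")
}
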