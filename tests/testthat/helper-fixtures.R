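# shared helpers: fixture readers and tiny deterministic inputs

read_fixture_array <- function(stem, what) {
  path <- test_path("fixtures", sprintf("%s_%s.txt", stem, what))
  hdr <- strsplit(readLines(path, n = 1), " +")[[1]]
  list(arr = array(as.numeric(readLines(path)[-1]),
                   dim = as.integer(hdr[3:5])),
       spacing = as.numeric(hdr[7:9]))
}

read_fixture_sample <- function(stem) {
  v <- read_fixture_array(stem, "volume")
  m <- read_fixture_array(stem, "mask")
  lesion_sample(image_volume(v$arr, v$spacing),
                roi_mask(m$arr > 0.5, m$spacing), stem)
}

# small all-TRUE-mask sample around an arbitrary array (unit spacing)
array_sample <- function(arr, spacing = c(1, 1, 1), mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(arr))
  lesion_sample(image_volume(arr, spacing), roi_mask(mask, spacing), "toy")
}

# a quick small default lesion for perturbation tests
quick_lesion <- function(seed = 5L, noise = 10, corr = 3) {
  generate_lesion(lesion_params(semiaxes_mm = c(8, 7, 6), noise_sd_hu = noise,
                                texture_corr_mm = corr),
                  spacing = c(0.75, 0.75, 3), shape = c(36, 36, 10),
                  seed = seed, subject_id = sprintf("quick%d", seed))
}

# plug-in mutual information computed independently (direct double sum over
# the joint table) - oracle for the package estimator
mi_oracle <- function(x, y) {
  vx <- unique(x); vy <- unique(y)
  n <- length(x)
  s <- 0
  for (a in vx) for (b in vy) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) s <- s + pab * log(pab / (sum(x == a) / n * sum(y == b) / n))
  }
  s
}
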