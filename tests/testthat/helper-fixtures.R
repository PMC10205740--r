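# Shared fixtures: all datasets are generated in code at test time.

# small, fast generator geometry (64 px =~ 41 um field of view)
tiny_config <- function(seed = 1L, ...) {
  generator_config(height_px = 64, width_px = 64,
                   band_thickness_um = c(10, 16),
                   undulation_amplitude_um = 3, undulation_period_um = 30,
                   nuclei_density_per_um2 = 0.02, noise_sigma = 4,
                   seed = seed, ...)
}

# write a tiny on-disk dataset and return its manifest
tiny_dataset <- function(n, seed = 42L, seg_share = 1, annotate = FALSE) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  strata <- strata_epidermis_cohort()
  strata$has_segmentation <- seg_share
  generate_dataset(n, dir, strata = strata, config_template = tiny_config(),
                   seed = seed, annotate = annotate)
}

# manifest emulating the 804-sample cohort composition, without image files
cohort_manifest <- function(path) {
  strata <- strata_epidermis_cohort()
  n <- 804
  tissue <- rep(names(strata$tissue), round(n * strata$tissue))
  staining <- rep(names(strata$staining), round(n * strata$staining))
  set.seed(7)
  staining <- sample(staining)
  has_seg <- sample(rep(c(TRUE, FALSE), c(202, n - 202)))
  df <- data.frame(
    sample_id = sprintf("C%04d", seq_len(n)),
    image_path = sprintf("images/C%04d.png", seq_len(n)),
    tissue = tissue, staining = staining,
    s_nuclei = round(runif(n), 4),
    mask_path = ifelse(has_seg, sprintf("masks/C%04d_mask.png", seq_len(n)), ""),
    resolution_um_per_px = 0.645,
    image_height_px = 1040L, image_width_px = 1384L)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# random 3-class label matrix
random_mask <- function(h = 16, w = 16) {
  matrix(sample(0:2, h * w, replace = TRUE), h, w)
}
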