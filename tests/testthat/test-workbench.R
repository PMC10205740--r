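test_that("inconsistent experiments fail before any training", {
  d <- withr::local_tempdir()
  strata <- strata_epidermis_cohort()
  strata$has_segmentation <- 0
  man <- generate_dataset(6, d, strata, tiny_config(), seed = 61)
  cfg <- experiment_config(dataset = file.path(d, "manifest.csv"),
                           task = "segmentation", k_folds = 2,
                           output_dir = withr::local_tempdir())
  expect_error(run_experiment(cfg), class = "epiderm_config_error")
})

test_that("a small experiment runs end to end and reruns byte-identically", {
  d <- withr::local_tempdir()
  strata <- strata_epidermis_cohort(); strata$has_segmentation <- 1
  man <- generate_dataset(10, d, strata, tiny_config(), seed = 62)
  ucfg <- unet_config(base_width = 16L, patch_px = 32L, epochs = 1L,
                      steps_per_epoch = 4L, batch_size = 2L)
  run1 <- withr::local_tempdir(); run2 <- withr::local_tempdir()
  cfg1 <- experiment_config(dataset = file.path(d, "manifest.csv"),
                            task = "segmentation", k_folds = 2, seed = 1L,
                            output_dir = run1, model_config = ucfg)
  rep1 <- run_experiment(cfg1)
  expect_true(all(file.exists(file.path(run1, c("config.json", "seeds.json",
                                                "report.csv")))))
  expect_true(all(c("mae_s_nuclei", "mae_s_area", "iou_macro", "pixel_acc")
                  %in% names(rep1)))
  cfg2 <- cfg1; cfg2$output_dir <- run2
  run_experiment(cfg2)
  expect_identical(unname(tools::md5sum(file.path(run1, "report.csv"))),
                   unname(tools::md5sum(file.path(run2, "report.csv"))))
})

test_that("deposit statistics recompute S_area consistently from masks", {
  d <- withr::local_tempdir()
  strata <- strata_epidermis_cohort()
  strata$has_segmentation <- 0.5
  man <- generate_dataset(12, d, strata, tiny_config(), seed = 63,
                          annotate = TRUE)
  stats <- deposit_statistics(d)
  expect_equal(stats$counts$n, 12L)
  expect_equal(stats$n_masked, 6L)
  # recomputed S_area equals the manifest's ground truth exactly
  df <- as.data.frame(man)
  truth <- df$s_area[match(stats$s_area$sample_id, df$sample_id)]
  expect_equal(stats$s_area$s_area, truth)
  # with a second annotator present the pathologist pair statistic appears
  expect_false(is.null(stats$pathologist_vs_pathologist))
  expect_gte(stats$pathologist_vs_pathologist$mean, 0)
})

test_that("the critical-subset filter keeps exactly the mid-range scores", {
  d <- withr::local_tempdir()
  strata <- strata_epidermis_cohort(); strata$has_segmentation <- 1
  man <- generate_dataset(3, d, strata, tiny_config(), seed = 64)
  df <- as.data.frame(man)
  df$s_nuclei <- c(0.05, 0.5, 0.95)
  man2 <- epiderm:::new_manifest(df, 0.645, 64, 64, base_dir = d)
  write_manifest(man2, file.path(d, "manifest.csv"))
  stats <- deposit_statistics(d)
  expect_equal(stats$n_critical, 1L)
  expect_error(deposit_statistics(withr::local_tempdir()),
               class = "epiderm_io_error")
})
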