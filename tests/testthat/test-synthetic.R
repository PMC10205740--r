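test_that("degenerate damage targets are honored exactly", {
  s0 <- generate_sample(tiny_config(seed = 1, target_damage_fraction = 0))
  expect_equal(sum(s0$mask == 2L), 0)
  expect_equal(s0$true_scores$s_area, 0)
  expect_equal(s0$true_scores$s_nuclei, 0)

  s1 <- generate_sample(tiny_config(seed = 1, target_damage_fraction = 1))
  expect_equal(s1$true_scores$s_area, 1)
  expect_equal(sum(s1$mask == 1L), 0)
})

test_that("ground truth is internally consistent for every sample", {
  for (seed in 1:8) {
    s <- generate_sample(tiny_config(seed = seed,
                                     target_damage_fraction = runif(1),
                                     heterogeneity = runif(1)))
    # damaged pixels lie inside the epidermis band (classes partition it)
    expect_true(all(s$mask %in% 0:2))
    # nuclei lie inside the band
    cls_at_nuclei <- s$mask[cbind(s$nuclei$y_px, s$nuclei$x_px)]
    expect_true(all(cls_at_nuclei >= 1L))
    # scores recompute bit-exactly
    expect_identical(s$true_scores$s_nuclei, mean(s$nuclei$damaged))
    expect_identical(s$true_scores$s_area, s_area_from_mask(s$mask)$s_area)
  }
})

test_that("fixed seed reproduces identical samples and identical files", {
  a <- generate_sample(tiny_config(seed = 77))
  b <- generate_sample(tiny_config(seed = 77))
  expect_identical(a, b)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  strata <- strata_epidermis_cohort()
  generate_dataset(6, d1, strata, tiny_config(), seed = 9)
  generate_dataset(6, d2, strata, tiny_config(), seed = 9)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("dataset stratum allocation matches requested shares within one", {
  strata <- strata_epidermis_cohort()
  expect_identical(epiderm:::allocate_counts(804, strata$tissue),
                   c(487L, 269L, 48L))
  expect_identical(epiderm:::allocate_counts(804, strata$staining),
                   c(415L, 317L, 36L, 36L))
  # n = 8 at segmentation share 0.25 -> exactly 2 carry masks
  strata$has_segmentation <- 0.25
  man <- tiny_dataset(8, seed = 21, seg_share = 0.25)
  expect_equal(sum(man$has_segmentation), 2)
  expect_equal(sum(!is.na(man$s_area)), 2)
})

test_that("heterogeneity index separates uniform from concentrated damage", {
  band <- matrix(1L, 128, 128)
  set.seed(31)
  speckle <- band
  speckle[matrix(runif(128 * 128) < 0.5, 128, 128)] <- 2L
  expect_lt(heterogeneity_index(speckle, 32), 0.15)

  half <- band
  half[, 1:64] <- 2L
  expect_gte(heterogeneity_index(half, 32), 0.8)

  # symmetric under 180-degree rotation
  m <- generate_sample(tiny_config(seed = 3, heterogeneity = 0.7))$mask
  rot <- m[nrow(m):1, ncol(m):1]
  expect_equal(heterogeneity_index(rot, 32), heterogeneity_index(m, 32))

  expect_error(heterogeneity_index(matrix(0L, 16, 16)),
               class = "epiderm_undefined_score")
})

test_that("annotator noise is truncated, seedable and zero at zero config", {
  cfg0 <- annotator_config(base_noise_sd = 0, heterogeneity_coupling = 0)
  s <- runif(20)
  expect_identical(simulate_annotator(s, 0.5, cfg0), s)

  cfg <- annotator_config(base_noise_sd = 0.5, heterogeneity_coupling = 0.5,
                          seed = 4)
  out <- simulate_annotator(rep(0.98, 500), 1, cfg)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, simulate_annotator(rep(0.98, 500), 1, cfg))
})

test_that("annotator error grows with heterogeneity and calibrates to the
           pathologist regime", {
  set.seed(5)
  truth <- runif(500)
  maes <- sapply(c(0, 0.5, 1), function(h) {
    c2 <- annotator_config(seed = 12 + h * 100)
    mean(abs(simulate_annotator(truth, h, c2) - truth))
  })
  expect_true(all(diff(maes) >= 0))

  coupling <- calibrate_annotator(target_mae = 0.2)
  a1 <- simulate_annotator(truth, 1, annotator_config(
    heterogeneity_coupling = coupling, seed = 1))
  a2 <- simulate_annotator(truth, 1, annotator_config(
    heterogeneity_coupling = coupling, seed = 2))
  expect_lt(abs(mean(abs(a1 - a2)) - 0.2), 0.025)
})
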