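test_that("mae_stats returns mean and population sd of absolute errors", {
  v <- c(0.1, 0.4, 0.8)
  expect_equal(mae_stats(v, v), list(mean = 0, sd = 0))
  expect_equal(mae_stats(v + 0.1, v), list(mean = 0.1, sd = 0))
  out <- mae_stats(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.6))
  expect_equal(out$mean, 0.16667, tolerance = 1e-4)
  expect_equal(out$sd, 0.09428, tolerance = 1e-4)
  expect_error(mae_stats(1:3 / 10, 1:4 / 10), class = "epiderm_shape_error")
})

test_that("macro IoU follows the three-class convention", {
  m <- random_mask(8, 8)
  expect_equal(macro_iou(m, m), 1)
  truth <- matrix(c(0L, 1L, 1L, 2L), 1)
  pred <- matrix(c(0L, 1L, 2L, 2L), 1)
  expect_equal(macro_iou(pred, truth), mean(c(1, 0.5, 0.5)), tolerance = 1e-5)
  # classes absent from both masks count as 1.0
  ones <- matrix(1L, 2, 2)
  expect_equal(macro_iou(ones, ones), 1)
  # a spurious prediction of an absent class drags the macro down
  spur <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  expect_lt(macro_iou(spur, ones), 0.9)
  expect_error(macro_iou(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               class = "epiderm_shape_error")
})

test_that("metrics agree with brute-force set and tally oracles", {
  set.seed(90)
  for (i in 1:200) {
    pred <- random_mask(); truth <- random_mask()
    # set-based oracle for IoU
    oracle <- mean(vapply(0:2, function(k) {
      P <- which(pred == k); T <- which(truth == k)
      u <- union(P, T)
      if (length(u) == 0) 1.0 else length(intersect(P, T)) / length(u)
    }, numeric(1)))
    expect_equal(macro_iou(pred, truth), oracle)
    # tally oracle for accuracy
    expect_equal(pixel_accuracy(pred, truth),
                 sum(pred == truth) / length(pred))
  }
})

test_that("pixel accuracy hits its boundary cases", {
  a <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  expect_equal(pixel_accuracy(a, a), 1)
  expect_equal(pixel_accuracy(a, 2L - a), 0.5)  # only the value 1 maps to itself
  b <- a; b[1, 1] <- 2L
  expect_equal(pixel_accuracy(b, a), 0.75)
})

test_that("stratified folds balance every stratum to within one", {
  # 2 strata x 10 samples, k = 10 -> exactly one of each per fold
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   image_path = "x.png",
                   tissue = rep(c("human_skin", "porcine_skin"), each = 10),
                   staining = "CPD", s_nuclei = 0.5)
  utils::write.csv(df, p, row.names = FALSE)
  man <- load_manifest(p)
  fa <- stratified_folds(man, k = 10, seed = 1)
  tab <- table(fa$fold_of, as.data.frame(man)$tissue)
  expect_true(all(tab == 1))

  # partition: every sample in exactly one fold
  expect_setequal(names(fa$fold_of), df$sample_id)
  expect_true(all(fa$fold_of %in% 1:10))

  # tiny stratum of 3 spreads over exactly 3 folds
  df3 <- df
  df3$tissue[1:3] <- "human_skin_model"
  utils::write.csv(df3, p, row.names = FALSE)
  fa3 <- stratified_folds(load_manifest(p), k = 10, seed = 2)
  counts <- table(fa3$fold_of[df3$tissue == "human_skin_model"])
  expect_equal(sum(counts == 1), 3)

  expect_error(stratified_folds(man, k = 1), class = "epiderm_config_error")
  expect_error(stratified_folds(man, k = 25), class = "epiderm_config_error")
})

test_that("cohort-scale folds stay balanced per stratum and overall", {
  p <- withr::local_tempfile(fileext = ".csv")
  cohort_manifest(p)
  man <- load_manifest(p)
  fa <- stratified_folds(man, k = 10, seed = 3)
  sizes <- table(fa$fold_of)
  expect_true(all(sizes %in% c(80, 81)))
  df <- as.data.frame(man)
  key <- paste(df$staining, df$tissue, df$has_segmentation)
  for (s in unique(key)) {
    per_fold <- table(factor(fa$fold_of[key == s], levels = 1:10))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("bootstrap agreement has the right degenerate behaviour", {
  s <- runif(20)
  ba <- bootstrap_agreement(s, s, n_boot = 200, seed = 4)
  expect_true(all(ba$mae_samples == 0))
  ba2 <- bootstrap_agreement(s + 0.1, s, n_boot = 200, seed = 4)
  expect_true(all(abs(ba2$mae_samples - 0.1) < 1e-12))
  expect_lt(max(ba2$sd_samples), 1e-12)
  ba3 <- bootstrap_agreement(s + 0.1, s, n_boot = 200, seed = 4)
  expect_identical(ba2$mae_samples, ba3$mae_samples)
  expect_error(bootstrap_agreement(1, 1), class = "epiderm_shape_error")
})

test_that("bootstrap mean converges to the plug-in MAE", {
  set.seed(91)
  a <- runif(40); b <- runif(40)
  ms <- mae_stats(a, b)
  ba <- bootstrap_agreement(a, b, n_boot = 2000, seed = 5)
  se <- stats::sd(ba$mae_samples) / sqrt(2000)
  expect_lt(abs(mean(ba$mae_samples) - ms$mean), 3 * se + 1e-3)
})

test_that("cross-validation report aggregates folds and repeats", {
  man <- tiny_dataset(12, seed = 51, seg_share = 1)
  folds <- stratified_folds(man, k = 3, seed = 6)
  const_trainer <- list(
    fit = function(manifest, train_ids, seed) list(),
    predict = function(model, image) list(scores = score_pair(s_nuclei = 0.5)))
  rep <- cross_validate_report(man, folds, const_trainer, repeats = 2, seed = 9)
  runs <- rep[!is.na(rep$fold), ]
  expect_equal(nrow(runs), 6)  # 3 folds x 2 repeats
  agg <- rep[!is.na(rep$aggregate), ]
  expect_setequal(agg$aggregate, c("mean", "sd_folds", "sd_runs"))
  expect_true(all(c("mae_s_nuclei", "mae_s_area", "iou_macro", "pixel_acc")
                  %in% names(rep)))
  # constant predictor on varying truth: per-fold MAEs present, IoU absent
  expect_true(all(is.finite(runs$mae_s_nuclei)))
  expect_true(all(is.na(runs$iou_macro)))
})
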