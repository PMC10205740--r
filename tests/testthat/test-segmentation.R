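test_that("U-Net variants have ordered capacity and valid widths", {
  n16 <- n_parameters(build_unet(unet_config(base_width = 16L)))
  n32 <- n_parameters(build_unet(unet_config(base_width = 32L)))
  n64 <- n_parameters(build_unet(unet_config(base_width = 64L)))
  expect_lt(n16, n32)
  expect_lt(n32, n64)
  expect_error(unet_config(base_width = 24L), class = "epiderm_config_error")
  expect_s3_class(unet_config(base_width = 8L, allow_any_width = TRUE),
                  "epiderm_unet_config")
  expect_error(unet_config(patch_px = 100L), class = "epiderm_config_error")
})

test_that("segmenter probabilities sum to one and preserve input dims", {
  model <- build_unet(unet_config(base_width = 16L, patch_px = 64L, seed = 9L))
  img <- array(runif(128 * 96 * 3) * 255, c(128, 96, 3))
  pm <- predict_mask(model, img)
  expect_equal(dim(pm$mask), c(128, 96))
  expect_true(all(pm$mask %in% 0:2))
  s <- pm$probs[, , 1] + pm$probs[, , 2] + pm$probs[, , 3]
  expect_lt(max(abs(s - 1)), 1e-6)
})

test_that("uniform logits argmax to background via the low-class tie-break", {
  model <- build_unet(unet_config(base_width = 16L, patch_px = 64L, seed = 9L))
  w <- model_weights(model)
  k <- length(w$conv)
  w$conv[[k]]$W[] <- 0; w$conv[[k]]$b[] <- 0
  epiderm:::nn_unet_set_weights(model$ptr, w)
  img <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  pm <- predict_mask(model, img)
  expect_true(all(pm$mask == 0L))
  # and the undefined score is flagged, never silently 0
  expect_error(score_from_prediction(model, img),
               class = "epiderm_undefined_score")
})

test_that("repeat training yields one model and history per repeat with
           consecutive seeds", {
  man <- tiny_dataset(6, seed = 41, seg_share = 1)
  cfg <- unet_config(base_width = 16L, patch_px = 32L, epochs = 2L,
                     steps_per_epoch = 3L, batch_size = 2L, seed = 100L)
  models <- train_segmenter(man, config = cfg, repeats = 2L)
  expect_length(models, 2)
  expect_equal(vapply(models, function(m) m$config$seed, numeric(1)),
               c(100, 101))
  for (m in models) {
    expect_equal(nrow(m$history), 2)
    expect_true(all(is.finite(m$history$loss)))
  }
})

test_that("short training reduces the mean loss on synthetic data", {
  man <- tiny_dataset(8, seed = 42, seg_share = 1)
  cfg <- unet_config(base_width = 16L, patch_px = 32L, epochs = 3L,
                     steps_per_epoch = 8L, batch_size = 4L, seed = 7L)
  m <- train_segmenter(man, config = cfg, repeats = 1L)[[1]]
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
})

test_that("training requires masks on every training sample", {
  man <- tiny_dataset(6, seed = 43, seg_share = 0.5)
  expect_error(train_segmenter(man, man$sample_id,
                               unet_config(epochs = 1L)),
               class = "epiderm_validation_error")
  man0 <- tiny_dataset(4, seed = 44, seg_share = 0)
  expect_error(train_segmenter(man0, config = unet_config(epochs = 1L)),
               class = "epiderm_validation_error")
})

test_that("scoring the ground-truth mask recovers the generator's S_area", {
  s <- generate_sample(tiny_config(seed = 45, target_damage_fraction = 0.4))
  expect_identical(s_area_from_mask(s$mask)$s_area, s$true_scores$s_area)
})
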