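test_that("regressor head width and output range match the architecture", {
  model <- build_regressor(regressor_config(seed = 2L))
  # concatenated global max+mean pooling of the 512-channel feature map
  expect_equal(epiderm:::nn_vgg_feature_width(model$ptr), 1024L)
  x <- array(runif(64 * 64 * 3) - 0.5, c(64, 64, 3))
  y <- epiderm:::nn_vgg_predict(model$ptr, x)
  expect_gt(y, 0); expect_lt(y, 1)

  # zeroed output layer pins the sigmoid at exactly 0.5
  w <- model_weights(model)
  w$fc2$W[] <- 0; w$fc2$b[] <- 0
  epiderm:::nn_vgg_set_weights(model$ptr, w)
  expect_identical(epiderm:::nn_vgg_predict(model$ptr, x), 0.5)
})

test_that("pretrained flag without weights is rejected", {
  expect_error(build_regressor(regressor_config(pretrained = TRUE)),
               class = "epiderm_config_error")
})

test_that("regression training reduces loss and is seed-reproducible", {
  man <- tiny_dataset(12, seed = 31, seg_share = 0.5)
  cfg <- regressor_config(train_scope = "head", dropout_rate = 0,
                          learning_rate = 0.003, epochs = 5L,
                          steps_per_epoch = 40L, batch_size = 8L,
                          downsample_factor = 2L, seed = 4L)
  m1 <- train_regressor(man, target = "s_nuclei", config = cfg)
  expect_lt(m1$history$loss[5], m1$history$loss[1])
  m2 <- train_regressor(man, target = "s_nuclei", config = cfg)
  expect_identical(m1$history, m2$history)
})

test_that("full fine-tuning also reduces the training loss", {
  man <- tiny_dataset(8, seed = 32, seg_share = 0)
  cfg <- regressor_config(train_scope = "full", epochs = 3L,
                          steps_per_epoch = 4L, batch_size = 4L,
                          downsample_factor = 2L, seed = 4L)
  m <- train_regressor(man, target = "s_nuclei", config = cfg)
  expect_lt(m$history$loss[3], m$history$loss[1])
})

test_that("s_area target requires annotated samples", {
  man <- tiny_dataset(6, seed = 33, seg_share = 0.5)
  unmasked <- man$sample_id[!man$has_segmentation]
  expect_error(
    train_regressor(man, unmasked, "s_area", regressor_config(epochs = 1L)),
    class = "epiderm_validation_error")
  expect_error(train_regressor(man, character(0), "s_nuclei"),
               class = "epiderm_validation_error")
})

test_that("image masking zeroes exactly the background support", {
  img <- array(runif(8 * 8 * 3) * 255 + 1, c(8, 8, 3))
  ones <- matrix(1L, 8, 8)
  expect_identical(mask_image(img, ones), img)
  zeros <- matrix(0L, 8, 8)
  expect_true(all(mask_image(img, zeros) == 0))
  checker <- matrix(rep_len(c(0L, 1L), 64), 8, 8)
  out <- mask_image(img, checker)
  for (ch in 1:3) {
    expect_true(all(out[, , ch][checker == 0] == 0))
    expect_identical(out[, , ch][checker == 1], img[, , ch][checker == 1])
  }
  expect_error(mask_image(img, matrix(1L, 4, 4)), class = "epiderm_shape_error")
})

test_that("a briefly trained masker recovers the epidermis on held-out data", {
  man <- tiny_dataset(24, seed = 5, seg_share = 1)
  cfg <- masker_config(epochs = 10L, batches_per_epoch = 5L, batch_size = 4L,
                       patch_px = 32L, seed = 1L)
  mk <- build_and_train_masker(man, man$sample_id[1:20], cfg)
  expect_lt(tail(mk$history$loss, 1), mk$history$loss[1])
  ious <- vapply(21:24, function(i) {
    smp <- load_sample(man[i, , drop = FALSE])
    pred <- predict_epidermis_mask(mk, smp$image)
    expect_true(all(pred %in% 0:1))
    expect_equal(dim(pred), dim(smp$mask))
    truthb <- (smp$mask >= 1L) + 0L
    sum(pred & truthb) / sum(pred | truthb)
  }, numeric(1))
  expect_gte(mean(ious), 0.6)
})

test_that("masker needs at least one annotated sample", {
  man <- tiny_dataset(4, seed = 6, seg_share = 0)
  expect_error(build_and_train_masker(man), class = "epiderm_validation_error")
})
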