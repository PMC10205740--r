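# Three-class semantic segmentation (background / healthy epidermis /
# damaged epidermis) and the derivation of S_area from predictions.
#
# The U-Net family is parameterized by its base feature width N (U-Net/N,
# N in {16, 32, 64}): encoder widths (N, 2N, 4N) with three pooling steps
# and an 8N bottleneck, mirrored decoder with skip connections, two
# convolutions with batch normalization per block, per-pixel 3-way softmax.

#' Segmentation U-Net configuration
#'
#' Defaults follow the reference training recipe: 50 epochs of 100 steps
#' with batch size 32, Adamax with learning rate 0.001 and
#' `beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7`, categorical cross-entropy,
#' 256 x 256 patches from 2x downsampled images, with flips, brightness in
#' `[0.75, 1.25]` and rotations within +/-15 degrees.
#'
#' @param base_width Base feature width, one of 16, 32, 64 (other values
#'   only behind `allow_any_width = TRUE`).
#' @param pool_count Number of pooling steps (fixed architecture uses 3).
#' @param patch_px Training patch size; must be divisible by
#'   `2^pool_count`.
#' @param downsample_factor Image downsampling before patching.
#' @param epochs,steps_per_epoch,batch_size Training recipe.
#' @param learning_rate,beta1,beta2,epsilon Adamax hyperparameters.
#' @param seed Integer base seed.
#' @param allow_any_width Permit base widths outside {16, 32, 64}.
#' @return A list of class `epiderm_unet_config`.
#' @export
unet_config <- function(base_width = 64L, pool_count = 3L, patch_px = 256L,
                        downsample_factor = 2L, epochs = 50L,
                        steps_per_epoch = 100L, batch_size = 32L,
                        learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-7, seed = 42L, allow_any_width = FALSE) {
  if (!base_width %in% c(16L, 32L, 64L) && !allow_any_width)
    ep_stop("base_width must be one of 16, 32, 64 (or set allow_any_width)",
            "epiderm_config_error")
  if (patch_px %% 2^pool_count != 0)
    ep_stop("patch_px must be divisible by 2^pool_count", "epiderm_config_error")
  stopifnot(base_width >= 1, pool_count >= 1, epochs >= 1,
            steps_per_epoch >= 1, batch_size >= 1, downsample_factor >= 1)
  structure(as.list(environment()), class = "epiderm_unet_config")
}

#' Build a segmentation U-Net
#'
#' @param config An [unet_config()].
#' @return An `epiderm_model` of kind `"segmenter"` mapping 3-channel
#'   patches to per-pixel 3-class probabilities.
#' @export
build_unet <- function(config = unet_config()) {
  widths <- as.integer(config$base_width * 2^(seq_len(config$pool_count) - 1))
  ptr <- nn_unet_create(widths, 3L, 3L, as.integer(config$seed))
  structure(list(ptr = ptr, config = config, kind = "segmenter", history = NULL),
            class = "epiderm_model")
}

#' Train segmentation U-Nets (repeated runs)
#'
#' Trains `repeats` independent models on the same fold, each with seed
#' `config$seed + repeat index - 1`, by random patch sampling on
#' downsampled images with flip/brightness/rotation augmentation.
#'
#' @param manifest An `epiderm_manifest`.
#' @param train_ids Training sample ids; all must carry masks.
#' @param config An [unet_config()].
#' @param repeats Number of independent trainings (default 5).
#' @return A list of trained `epiderm_model`s, each with its history.
#' @export
train_segmenter <- function(manifest, train_ids = NULL, config = unet_config(),
                            repeats = 5L) {
  df <- as.data.frame(manifest)
  if (is.null(train_ids)) train_ids <- df$sample_id[df$has_segmentation]
  if (length(train_ids) < 1)
    ep_stop("segmentation training needs at least one masked sample",
            "epiderm_validation_error")
  has <- df$has_segmentation[match(train_ids, df$sample_id)]
  if (!all(has))
    ep_stop("all segmentation training samples must carry masks",
            "epiderm_validation_error")
  data <- load_training_set(manifest, train_ids, config$downsample_factor,
                            need_mask = TRUE)
  policy <- augment_policy(flips = TRUE, brightness_range = c(0.75, 1.25),
                           rotation_deg = c(-15, 15))
  lapply(seq_len(repeats), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    model <- build_unet(cfg)
    model$history <- train_unet_patches(
      model$ptr, data, cfg$epochs, cfg$steps_per_epoch, cfg$batch_size,
      cfg$patch_px, cfg$learning_rate, policy, binary = FALSE,
      beta1 = cfg$beta1, beta2 = cfg$beta2, eps = cfg$epsilon, seed = cfg$seed)
    model
  })
}

#' Predict a full-image label mask
#'
#' Downsamples the image by the model's factor, stitches sliding-window
#' softmax predictions, takes the per-pixel argmax (ties toward the lower
#' class index) and upsamples the labels back to the original resolution
#' with nearest-neighbour so the class set is preserved.
#'
#' @param model A trained segmenter (`epiderm_model`), or a list of them
#'   (probabilities are averaged across models).
#' @param image H x W x 3 array at acquisition resolution.
#' @return A list with `mask` (integer H x W, classes 0/1/2) and `probs`
#'   (class-probability array at working resolution).
#' @export
predict_mask <- function(model, image) {
  models <- if (inherits(model, "epiderm_model")) list(model) else model
  cfg <- models[[1]]$config
  work <- downsample(image, cfg$downsample_factor, "image")
  size <- min(cfg$patch_px, dim(work)[1], dim(work)[2])
  size <- max(2^cfg$pool_count, (size %/% 2^cfg$pool_count) * 2^cfg$pool_count)
  probs <- NULL
  for (m in models) {
    pfun <- function(patch) nn_unet_predict(m$ptr, prep_input(patch))
    p <- sliding_window_predict(work, pfun, size_px = size)
    probs <- if (is.null(probs)) p else probs + p
  }
  probs <- probs / length(models)
  cls <- prob_argmax(probs)
  mask <- upsample_nearest(cls, dim(image)[1], dim(image)[2])
  storage.mode(mask) <- "integer"
  list(mask = mask, probs = probs)
}

#' Estimate S_area from a segmentation prediction
#'
#' Applies [s_area_from_mask()] to [predict_mask()]'s output. When the
#' model predicts no epidermis at all the undefined-score error
#' propagates — the failure is flagged, never silently scored as 0.
#'
#' @param model A trained segmenter (or list of repeats).
#' @param image H x W x 3 array.
#' @return An [score_pair()] with `s_area` set, plus `areas` attribute
#'   with the pixel counts.
#' @export
score_from_prediction <- function(model, image) {
  pm <- predict_mask(model, image)
  area <- s_area_from_mask(pm$mask)
  out <- score_pair(s_area = area$s_area)
  attr(out, "areas") <- area[c("a_dmg", "a_epi")]
  out
}
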