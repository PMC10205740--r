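# Score regression from downsampled whole images, plus the binary
# epidermis masker that feeds the masked-regression variant.
#
# The backbone is a VGG16-style stack (thirteen 3x3 convolutions in five
# blocks, widths 64..512) whose final 512-channel feature map is reduced by
# concatenated global max and mean pooling (1024 = 512 + 512 features),
# followed by dropout, a 128-unit ReLU layer, dropout, and a single sigmoid
# output neuron. Inputs are scaled to [-0.5, 0.5] before entering the
# network.

VGG16_PLAN <- c(64, 64, 0, 128, 128, 0, 256, 256, 256, 0,
                512, 512, 512, 0, 512, 512, 512, 0)

prep_input <- function(image) image / 255 - 0.5

#' Regression model configuration
#'
#' @param backbone Only `"vgg16_style"` is available.
#' @param pretrained If `TRUE`, initial backbone weights must be supplied
#'   via `weights`; the package does not bundle any.
#' @param head_hidden Width of the hidden ReLU layer (default 128).
#' @param dropout_rate Dropout applied before and after the hidden layer.
#' @param downsample_factor Input downsampling factor (default 4).
#' @param loss `"mse"` (default) or `"mae"`.
#' @param learning_rate,epochs,steps_per_epoch,batch_size Adamax training
#'   recipe.
#' @param train_scope `"full"` fine-tunes the whole network; `"head"`
#'   freezes the convolutional backbone and trains the pooled head only.
#' @param seed Integer seed (weight init, dropout, batch sampling).
#' @return A list of class `epiderm_regressor_config`.
#' @export
regressor_config <- function(backbone = "vgg16_style", pretrained = FALSE,
                             head_hidden = 128L, dropout_rate = 0.5,
                             downsample_factor = 4L, loss = c("mse", "mae"),
                             learning_rate = 0.001, epochs = 50L,
                             steps_per_epoch = 100L, batch_size = 32L,
                             train_scope = c("full", "head"), seed = 42L) {
  loss <- match.arg(loss)
  train_scope <- match.arg(train_scope)
  if (backbone != "vgg16_style") ep_stop("unknown backbone", "epiderm_config_error")
  stopifnot(dropout_rate >= 0, dropout_rate < 1, downsample_factor >= 1,
            head_hidden >= 1, epochs >= 1, steps_per_epoch >= 1, batch_size >= 1)
  structure(as.list(environment()), class = "epiderm_regressor_config")
}

#' Build the score regressor
#'
#' @param config An [regressor_config()].
#' @param weights Optional weight list (as returned by [model_weights()])
#'   to initialize from; required when `config$pretrained` is `TRUE`.
#' @return A model handle of class `epiderm_model`.
#' @export
build_regressor <- function(config = regressor_config(), weights = NULL) {
  if (isTRUE(config$pretrained) && is.null(weights))
    ep_stop("pretrained = TRUE requires a `weights` list; none are bundled",
            "epiderm_config_error")
  ptr <- nn_vgg_create(as.integer(VGG16_PLAN), 3L, as.integer(config$head_hidden),
                       as.integer(config$seed))
  if (!is.null(weights)) nn_vgg_set_weights(ptr, weights)
  structure(list(ptr = ptr, config = config, kind = "regressor", history = NULL),
            class = "epiderm_model")
}

#' @export
print.epiderm_model <- function(x, ...) {
  np <- switch(x$kind,
               regressor = nn_vgg_nparams(x$ptr),
               nn_unet_nparams(x$ptr))
  cat(sprintf("<epiderm %s model: %s parameters>\n", x$kind,
              format(np, big.mark = ",")))
  invisible(x)
}

#' Extract model weights
#' @param model An `epiderm_model`.
#' @return A nested list of weight matrices.
#' @export
model_weights <- function(model) {
  if (model$kind == "regressor") nn_vgg_get_weights(model$ptr)
  else nn_unet_get_weights(model$ptr)
}

#' Number of trainable parameters
#' @param model An `epiderm_model`.
#' @return Parameter count.
#' @export
n_parameters <- function(model) {
  if (model$kind == "regressor") nn_vgg_nparams(model$ptr)
  else nn_unet_nparams(model$ptr)
}

# load and downsample the training images once; returns list(image, mask,
# target) per id
load_training_set <- function(manifest, ids, factor, target = NULL,
                              need_mask = FALSE) {
  df <- as.data.frame(manifest)
  rows <- match(ids, df$sample_id)
  if (anyNA(rows)) ep_stop("unknown sample ids in training set", "epiderm_validation_error")
  lapply(rows, function(r) {
    smp <- load_sample(df[r, , drop = FALSE], base_dir = attr(manifest, "base_dir"))
    if (need_mask && is.null(smp$mask))
      ep_stop(paste0("sample ", df$sample_id[r], " has no mask"),
              "epiderm_validation_error")
    out <- list(image = downsample(smp$image, factor, "image"),
                mask = if (!is.null(smp$mask)) downsample(smp$mask, factor, "mask"))
    if (!is.null(target)) {
      y <- df[[target]][r]
      if (is.null(y) || is.na(y))
        ep_stop(paste0("sample ", df$sample_id[r], " lacks target ", target),
                "epiderm_validation_error")
      out$target <- y
    }
    out
  })
}

#' Train the score regressor
#'
#' Trains on downsampled whole images (factor `config$downsample_factor`)
#' with random flips and brightness augmentation, minimizing the configured
#' loss with Adamax. With `train_scope = "head"` only the pooled head is
#' updated and the (fixed) backbone acts as a feature extractor. Runs are
#' deterministic for a fixed seed on a single-threaded BLAS.
#'
#' @param manifest An `epiderm_manifest`.
#' @param train_ids Sample ids to train on (default: all samples).
#' @param target `"s_nuclei"` or `"s_area"`; every training sample must
#'   carry the target score.
#' @param config An [regressor_config()].
#' @param masker Optional masker model (see [build_and_train_masker()]);
#'   when given, training images are epidermis-masked first
#'   (masked-regression variant).
#' @return An `epiderm_model` with a `history` data.frame of per-epoch
#'   mean training loss.
#' @export
train_regressor <- function(manifest, train_ids = NULL,
                            target = c("s_nuclei", "s_area"),
                            config = regressor_config(), masker = NULL) {
  target <- match.arg(target)
  df <- as.data.frame(manifest)
  if (is.null(train_ids)) train_ids <- df$sample_id
  if (length(train_ids) == 0) ep_stop("empty training fold", "epiderm_validation_error")
  if (target == "s_area") {
    rows <- match(train_ids, df$sample_id)
    if (any(is.na(df$s_area[rows])))
      ep_stop("target s_area requires annotated (masked) training samples",
              "epiderm_validation_error")
  }
  data <- load_training_set(manifest, train_ids, config$downsample_factor,
                            target = target)
  if (any(dim(data[[1]]$image)[1:2] < 32))
    ep_stop("downsampled input smaller than 32 px cannot pass the five pooling stages",
            "epiderm_config_error")
  if (!is.null(masker)) {
    rows <- match(train_ids, df$sample_id)
    for (j in seq_along(data)) {
      full <- load_sample(df[rows[j], , drop = FALSE],
                          base_dir = attr(manifest, "base_dir"))$image
      emask <- predict_epidermis_mask(masker, full)
      emask <- upsample_nearest(emask, dim(data[[j]]$image)[1],
                                dim(data[[j]]$image)[2])
      data[[j]]$image <- mask_image(data[[j]]$image, emask)
    }
  }
  model <- build_regressor(config)
  policy <- augment_policy(flips = TRUE, brightness_range = c(0.75, 1.25))
  n <- length(data)
  hist <- numeric(config$epochs)
  loss_kind <- if (config$loss == "mse") 0L else 1L
  targets <- vapply(data, `[[`, numeric(1), "target")
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      losses <- numeric(config$steps_per_epoch)
      if (config$train_scope == "head") {
        # frozen backbone: re-augment the set once per epoch, extract the
        # pooled features in a single forward pass each, then run the head
        # updates on feature minibatches
        feats <- t(vapply(data, function(d) {
          a <- augment(d$image, policy = policy)
          nn_vgg_features(model$ptr, prep_input(a$image))
        }, numeric(nn_vgg_feature_width(model$ptr))))
        for (st in seq_len(config$steps_per_epoch)) {
          idx <- sample.int(n, config$batch_size, replace = TRUE)
          losses[st] <- nn_vgg_train_head(
            model$ptr, feats[idx, , drop = FALSE], targets[idx],
            config$learning_rate, 0.9, 0.999, 1e-7, loss_kind,
            config$dropout_rate)
        }
      } else {
        for (st in seq_len(config$steps_per_epoch)) {
          idx <- sample.int(n, config$batch_size, replace = TRUE)
          xs <- vector("list", length(idx))
          for (j in seq_along(idx)) {
            a <- augment(data[[idx[j]]]$image, policy = policy)
            xs[[j]] <- prep_input(a$image)
          }
          losses[st] <- nn_vgg_train_batch(
            model$ptr, xs, targets[idx], config$learning_rate, 0.9, 0.999,
            1e-7, loss_kind, FALSE, config$dropout_rate)
        }
      }
      hist[ep] <- mean(losses)
    }
  })
  model$history <- data.frame(epoch = seq_len(config$epochs), loss = hist)
  model$target <- target
  model
}

#' Epidermis-masker configuration
#'
#' A binary (epidermis vs rest) encoder-decoder with four encoder blocks
#' of 32/64/128/256 filters, each two convolutions with batch
#' normalization followed by max pooling, mirrored in the decoder with
#' skip connections; optimized with Adamax (learning rate 0.001) under
#' per-pixel binary cross-entropy on 256 x 256 patches from 2x downsampled
#' images.
#'
#' @param encoder_widths Encoder block widths.
#' @param epochs,batches_per_epoch,batch_size Training recipe (defaults
#'   150 epochs of 50 batches of 32).
#' @param patch_px Patch size.
#' @param downsample_factor Image downsampling before patching.
#' @param learning_rate Adamax learning rate.
#' @param threshold Probability threshold for the binary mask.
#' @param seed Integer seed.
#' @return A list of class `epiderm_masker_config`.
#' @export
masker_config <- function(encoder_widths = c(32L, 64L, 128L, 256L),
                          epochs = 150L, batches_per_epoch = 50L,
                          batch_size = 32L, patch_px = 256L,
                          downsample_factor = 2L, learning_rate = 0.001,
                          threshold = 0.5, seed = 42L) {
  if (any(diff(encoder_widths) <= 0))
    ep_stop("encoder widths must be strictly increasing", "epiderm_config_error")
  stopifnot(threshold > 0, threshold < 1,
            patch_px %% 2^length(encoder_widths) == 0)
  structure(as.list(environment()), class = "epiderm_masker_config")
}

# shared patch-based U-Net training loop (masker: binary; segmenter: 3-class)
train_unet_patches <- function(ptr, data, epochs, steps, batch_size, patch_px,
                               lr, policy, binary, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-7, seed = 42L) {
  n <- length(data)
  hist <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      losses <- numeric(steps)
      for (st in seq_len(steps)) {
        idx <- sample.int(n, batch_size, replace = TRUE)
        xs <- vector("list", batch_size)
        ys <- vector("list", batch_size)
        for (j in seq_len(batch_size)) {
          d <- data[[idx[j]]]
          a <- augment(d$image, d$mask, policy = policy)
          pt <- sample_patches(a$image, a$mask, patch_spec(size_px = patch_px,
                                                           count = 1))[[1]]
          xs[[j]] <- prep_input(pt$image)
          m <- pt$mask
          if (binary) m <- matrix(as.integer(m >= 1L), nrow(m), ncol(m))
          ys[[j]] <- m
        }
        losses[st] <- nn_unet_train_batch(ptr, xs, ys, lr, beta1, beta2, eps)
      }
      hist[ep] <- mean(losses)
    }
  })
  data.frame(epoch = seq_len(epochs), loss = hist)
}

#' Train the binary epidermis masker
#'
#' @param manifest An `epiderm_manifest`.
#' @param train_ids Training sample ids (must all carry masks; epidermis =
#'   classes 1 and 2 collapsed to foreground).
#' @param config An [masker_config()].
#' @return An `epiderm_model` of kind `"masker"` with a training history.
#' @export
build_and_train_masker <- function(manifest, train_ids = NULL,
                                   config = masker_config()) {
  df <- as.data.frame(manifest)
  if (is.null(train_ids)) train_ids <- df$sample_id[df$has_segmentation]
  if (length(train_ids) == 0)
    ep_stop("no masked samples available for masker training",
            "epiderm_validation_error")
  data <- load_training_set(manifest, train_ids, config$downsample_factor,
                            need_mask = TRUE)
  ptr <- nn_unet_create(as.integer(config$encoder_widths), 3L, 1L,
                        as.integer(config$seed))
  policy <- augment_policy(flips = TRUE, brightness_range = c(0.75, 1.25))
  hist <- train_unet_patches(ptr, data, config$epochs, config$batches_per_epoch,
                             config$batch_size, config$patch_px,
                             config$learning_rate, policy, binary = TRUE,
                             seed = config$seed)
  structure(list(ptr = ptr, config = config, kind = "masker", history = hist),
            class = "epiderm_model")
}

#' Predict a binary epidermis mask
#'
#' Runs the masker over the image (downsampled by the masker's factor)
#' with sliding-window inference and thresholds the stitched foreground
#' probability.
#'
#' @param masker An `epiderm_model` of kind `"masker"`.
#' @param image H x W x 3 array; set `native_scale = TRUE` when the image
#'   is already at the masker's working resolution.
#' @param native_scale Skip the masker's own downsampling step.
#' @return An integer 0/1 matrix at the input image's resolution.
#' @export
predict_epidermis_mask <- function(masker, image, native_scale = FALSE) {
  stopifnot(masker$kind == "masker")
  work <- if (native_scale) image
          else downsample(image, masker$config$downsample_factor, "image")
  pfun <- function(patch) nn_unet_predict(masker$ptr, prep_input(patch))
  size <- min(masker$config$patch_px, dim(work)[1], dim(work)[2])
  size <- max(2^length(masker$config$encoder_widths),
              (size %/% 2^length(masker$config$encoder_widths)) *
                2^length(masker$config$encoder_widths))
  probs <- sliding_window_predict(work, pfun, size_px = size)
  bin <- matrix(as.integer(probs[, , 1] >= masker$config$threshold),
                dim(work)[1], dim(work)[2])
  upsample_nearest(bin, dim(image)[1], dim(image)[2])
}

#' Zero out non-epidermis pixels
#'
#' @param image H x W x 3 array.
#' @param epidermis_mask Binary H x W matrix (1 = epidermis).
#' @return The image with all background pixels set to 0 in every channel.
#' @export
mask_image <- function(image, epidermis_mask) {
  if (!all(dim(epidermis_mask) == dim(image)[1:2]))
    ep_stop("mask dimensions must match image", "epiderm_shape_error")
  out <- image
  for (ch in 1:3) out[, , ch] <- out[, , ch] * (epidermis_mask != 0)
  out
}

#' Predict a damage score with the regression model
#'
#' The image is downsampled by the model's configured factor; with a
#' masker given, non-epidermis pixels are zeroed first (masked
#' regression). The output is the sigmoid activation, strictly in (0, 1).
#'
#' @param model A trained regressor (`epiderm_model`).
#' @param image H x W x 3 array at acquisition resolution.
#' @param masker Optional masker model.
#' @return A scalar score in `(0, 1)`.
#' @export
predict_score <- function(model, image, masker = NULL) {
  stopifnot(model$kind == "regressor")
  work <- downsample(image, model$config$downsample_factor, "image")
  if (!is.null(masker)) {
    emask <- predict_epidermis_mask(masker, image)
    work <- mask_image(work, upsample_nearest(emask, dim(work)[1], dim(work)[2]))
  }
  nn_vgg_predict(model$ptr, prep_input(work))
}
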