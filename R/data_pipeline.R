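# Image transforms shared by both model families. Images are H x W x 3
# arrays on the 0-255 scale; masks are integer H x W matrices with classes
# {0, 1, 2}. Geometric transforms are always applied identically to image
# and mask; photometric transforms touch the image only.

#' Downsample an image or a label mask
#'
#' Images are resized with bilinear interpolation; masks with
#' nearest-neighbour so the label set is preserved. Output dimensions are
#' `ceiling(input / factor)`.
#'
#' @param x H x W x 3 image array or integer label matrix.
#' @param factor Integer downsampling factor (`>= 1`).
#' @param kind `"image"` or `"mask"`.
#' @return The resized array or matrix.
#' @export
downsample <- function(x, factor, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (length(factor) != 1 || !is.finite(factor) || factor < 1)
    ep_stop("downsampling factor must be >= 1", "epiderm_config_error")
  if (factor == 1) return(x)
  h2 <- ceiling(dim(x)[1] / factor)
  w2 <- ceiling(dim(x)[2] / factor)
  if (kind == "image") {
    out <- EBImage::imageData(EBImage::resize(x, w = h2, h = w2))
    clip(out, 0, 255)
  } else {
    out <- EBImage::imageData(EBImage::resize(x, w = h2, h = w2, filter = "none"))
    storage.mode(out) <- "integer"
    out
  }
}

#' Augmentation policy
#'
#' @param flips Enable random horizontal/vertical flips.
#' @param brightness_range Multiplicative brightness factor range (uniform;
#'   `c(1, 1)` disables).
#' @param rotation_deg Rotation range in degrees (uniform; `c(0, 0)`
#'   disables). Rotation is used by the segmentation recipe only.
#' @return A list of class `epiderm_augment_policy`.
#' @export
augment_policy <- function(flips = TRUE, brightness_range = c(0.75, 1.25),
                           rotation_deg = c(0, 0)) {
  stopifnot(length(brightness_range) == 2, length(rotation_deg) == 2)
  structure(list(flips = flips, brightness_range = brightness_range,
                 rotation_deg = rotation_deg),
            class = "epiderm_augment_policy")
}

#' Randomly augment an image (and its mask)
#'
#' Draws one transform from the policy and applies the identical geometric
#' part (rotation, flips) to image and mask; the brightness factor (a
#' multiplicative factor on RGB, clipped to 0-255) is applied to the image
#' only. With all knobs neutral (`flips = FALSE`, brightness `c(1, 1)`,
#' rotation `c(0, 0)`) the function is the identity.
#'
#' @param image H x W x 3 array (0-255).
#' @param mask Optional integer label matrix of the same H x W.
#' @param policy An [augment_policy()].
#' @param seed Optional seed for a deterministic draw.
#' @return A list with `image`, `mask` (or `NULL`) and the drawn `params`.
#' @export
augment <- function(image, mask = NULL, policy = augment_policy(), seed = NULL) {
  if (!is.null(mask) && !all(dim(mask) == dim(image)[1:2]))
    ep_stop("mask dimensions must match image", "epiderm_shape_error")
  with_seed(seed, {
    angle <- if (any(policy$rotation_deg != 0))
      stats::runif(1, policy$rotation_deg[1], policy$rotation_deg[2]) else 0
    flip_h <- policy$flips && stats::runif(1) < 0.5
    flip_v <- policy$flips && stats::runif(1) < 0.5
    bright <- if (any(policy$brightness_range != 1))
      stats::runif(1, policy$brightness_range[1], policy$brightness_range[2]) else 1

    if (angle != 0) {
      dm <- dim(image)[1:2]
      image <- EBImage::imageData(EBImage::rotate(image, angle, output.dim = dm))
      image <- clip(image, 0, 255)
      if (!is.null(mask)) {
        mask <- EBImage::imageData(EBImage::rotate(mask, angle, filter = "none",
                                                   output.dim = dm))
        storage.mode(mask) <- "integer"
      }
    }
    if (flip_h) {  # reverse columns
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if (flip_v) {  # reverse rows
      image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
      if (!is.null(mask)) mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    }
    if (bright != 1) image <- clip(image * bright, 0, 255)
    list(image = image, mask = mask,
         params = list(angle = angle, flip_h = flip_h, flip_v = flip_v,
                       brightness = bright))
  })
}

#' Patch-sampling specification
#'
#' @param size_px Patch edge in pixels.
#' @param stride_px Stride for sliding-window inference; defaults to half
#'   the patch size.
#' @param count Number of random patches to draw.
#' @param seed Optional seed.
#' @return A list of class `epiderm_patch_spec`.
#' @export
patch_spec <- function(size_px = 256, stride_px = size_px / 2, count = 1,
                       seed = NULL) {
  stopifnot(size_px >= 1, stride_px >= 1, stride_px <= size_px, count >= 1)
  structure(list(size_px = as.integer(size_px), stride_px = as.integer(stride_px),
                 count = as.integer(count), seed = seed),
            class = "epiderm_patch_spec")
}

#' Sample random in-bounds patches
#'
#' Draws `spec$count` patches at uniformly random origins; the mask patch,
#' when a mask is given, is pixel-aligned with the image patch.
#'
#' @param image H x W x 3 array.
#' @param mask Optional label matrix.
#' @param spec An [patch_spec()].
#' @return A list of lists with `image`, `mask` and `origin` (1-based
#'   `c(row, col)`).
#' @export
sample_patches <- function(image, mask = NULL, spec = patch_spec()) {
  H <- dim(image)[1]; W <- dim(image)[2]; s <- spec$size_px
  if (H < s || W < s)
    ep_stop(sprintf("image %dx%d smaller than patch size %d", H, W, s),
            "epiderm_shape_error")
  with_seed(spec$seed, {
    y0 <- sample.int(H - s + 1, spec$count, replace = TRUE)
    x0 <- sample.int(W - s + 1, spec$count, replace = TRUE)
    lapply(seq_len(spec$count), function(i) {
      ys <- y0[i]:(y0[i] + s - 1); xs <- x0[i]:(x0[i] + s - 1)
      list(image = image[ys, xs, , drop = FALSE],
           mask = if (!is.null(mask)) mask[ys, xs, drop = FALSE],
           origin = c(y0[i], x0[i]))
    })
  })
}

# reflect-pad an image (rows/cols) up to at least (h, w)
pad_reflect <- function(image, h, w) {
  ri <- seq_len(max(h, dim(image)[1]))
  ci <- seq_len(max(w, dim(image)[2]))
  fold <- function(i, n) {
    # reflect indices beyond n back into 1..n
    i <- (i - 1) %% (2 * n)
    ifelse(i < n, i + 1, 2 * n - i)
  }
  image[fold(ri, dim(image)[1]), fold(ci, dim(image)[2]), , drop = FALSE]
}

#' Sliding-window prediction with stitching
#'
#' Tiles the image with `size_px` windows on a `stride_px` grid, snapping
#' the final row/column of windows to the image edge so every pixel is
#' covered; per-pixel class probabilities from overlapping windows are
#' averaged. Images smaller than a window are reflect-padded and the
#' result cropped back.
#'
#' @param image H x W x 3 array.
#' @param per_patch_fn Function mapping a `size_px` x `size_px` x 3 patch
#'   to a `size_px` x `size_px` x K probability array.
#' @param size_px Window size.
#' @param stride_px Stride (`<= size_px`).
#' @return An H x W x K probability array (per-pixel probabilities sum
#'   to 1 when the per-patch maps do).
#' @export
sliding_window_predict <- function(image, per_patch_fn, size_px,
                                   stride_px = size_px / 2) {
  stopifnot(stride_px >= 1, stride_px <= size_px)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < size_px || W < size_px) {
    padded <- pad_reflect(image, size_px, size_px)
    out <- sliding_window_predict(padded, per_patch_fn, size_px, stride_px)
    return(out[seq_len(H), seq_len(W), , drop = FALSE])
  }
  starts <- function(n) {
    s <- seq(1, n - size_px + 1, by = stride_px)
    if (s[length(s)] != n - size_px + 1) s <- c(s, n - size_px + 1)
    s
  }
  ys <- starts(H); xs <- starts(W)
  acc <- NULL
  cnt <- matrix(0, H, W)
  for (y0 in ys) for (x0 in xs) {
    yr <- y0:(y0 + size_px - 1); xr <- x0:(x0 + size_px - 1)
    p <- per_patch_fn(image[yr, xr, , drop = FALSE])
    if (is.null(acc)) acc <- array(0, c(H, W, dim(p)[3]))
    acc[yr, xr, ] <- acc[yr, xr, , drop = FALSE] + p
    cnt[yr, xr] <- cnt[yr, xr] + 1
  }
  for (k in seq_len(dim(acc)[3])) acc[, , k] <- acc[, , k] / cnt
  acc
}

# argmax over the 3rd dim with ties broken toward the lower class index
prob_argmax <- function(probs) {
  K <- dim(probs)[3]
  best <- probs[, , 1]
  cls <- matrix(0L, dim(probs)[1], dim(probs)[2])
  for (k in seq_len(K - 1)) {
    better <- probs[, , k + 1] > best
    best[better] <- probs[, , k + 1][better]
    cls[better] <- k
  }
  cls
}
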