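# The network engine is validated against finite differences: analytic
# backprop gradients must match central-difference derivatives of the
# batch loss for every layer type (convolution, batch normalization,
# pooling path, skip concatenation, pooled head, dense layers).

fd_grad <- function(loss_fn, set_fn, w, path, idx, eps = 1e-5) {
  w2 <- w
  w2[[path]][[1]][idx] <- w2[[path]][[1]][idx] + eps
  set_fn(w2); lp <- loss_fn()
  w2[[path]][[1]][idx] <- w2[[path]][[1]][idx] - 2 * eps
  set_fn(w2); lm <- loss_fn()
  set_fn(w)
  (lp - lm) / (2 * eps)
}

test_that("U-Net backprop matches finite differences for all layers", {
  set.seed(71)
  p <- epiderm:::nn_unet_create(c(2L, 3L), 3L, 3L, 7L)
  xs <- lapply(1:2, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  ys <- lapply(1:2, function(i) matrix(sample(0:2, 64, TRUE), 8, 8))
  g <- epiderm:::nn_unet_grads(p, xs, ys)
  w <- epiderm:::nn_unet_get_weights(p)
  loss_fn <- function() epiderm:::nn_unet_batch_loss(p, xs, ys)
  set_fn <- function(w2) epiderm:::nn_unet_set_weights(p, w2)
  eps <- 1e-5
  for (k in seq_along(w$conv)) {
    for (r in 1:2) {
      idx <- sample(length(w$conv[[k]]$W), 1)
      w2 <- w
      w2$conv[[k]]$W[idx] <- w2$conv[[k]]$W[idx] + eps
      set_fn(w2); lp <- loss_fn()
      w2$conv[[k]]$W[idx] <- w2$conv[[k]]$W[idx] - 2 * eps
      set_fn(w2); lm <- loss_fn()
      set_fn(w)
      fd <- (lp - lm) / (2 * eps)
      an <- g$conv[[k]]$W[idx]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-5)
    }
  }
  # batchnorm parameters
  for (k in c(1, 4, 7)) {
    for (nm in c("g", "b")) {
      w2 <- w
      w2$bn[[k]][[nm]][1] <- w2$bn[[k]][[nm]][1] + eps
      set_fn(w2); lp <- loss_fn()
      w2$bn[[k]][[nm]][1] <- w2$bn[[k]][[nm]][1] - 2 * eps
      set_fn(w2); lm <- loss_fn()
      set_fn(w)
      fd <- (lp - lm) / (2 * eps)
      an <- epiderm:::nn_unet_grads(p, xs, ys)$bn[[k]][[nm]][1]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-5)
    }
  }
})

test_that("binary (sigmoid) U-Net head also passes the gradient check", {
  set.seed(72)
  p <- epiderm:::nn_unet_create(c(2L, 2L), 3L, 1L, 3L)
  xs <- lapply(1:2, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  ys <- lapply(1:2, function(i) matrix(sample(0:1, 64, TRUE), 8, 8))
  g <- epiderm:::nn_unet_grads(p, xs, ys)
  w <- epiderm:::nn_unet_get_weights(p)
  eps <- 1e-5
  for (k in seq_along(w$conv)) {
    idx <- sample(length(w$conv[[k]]$W), 1)
    w2 <- w
    w2$conv[[k]]$W[idx] <- w2$conv[[k]]$W[idx] + eps
    epiderm:::nn_unet_set_weights(p, w2)
    lp <- epiderm:::nn_unet_batch_loss(p, xs, ys)
    w2$conv[[k]]$W[idx] <- w2$conv[[k]]$W[idx] - 2 * eps
    epiderm:::nn_unet_set_weights(p, w2)
    lm <- epiderm:::nn_unet_batch_loss(p, xs, ys)
    epiderm:::nn_unet_set_weights(p, w)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g$conv[[k]]$W[idx]) /
                max(1e-8, abs(fd) + abs(g$conv[[k]]$W[idx])), 1e-5)
  }
})

test_that("VGG-style regressor backprop matches finite differences", {
  set.seed(73)
  p <- epiderm:::nn_vgg_create(c(4L, 0L, 6L, 0L), 3L, 5L, 3L)
  xs <- lapply(1:2, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  ys <- runif(2)
  g <- epiderm:::nn_vgg_grads(p, xs, ys, 0L, FALSE)
  w <- epiderm:::nn_vgg_get_weights(p)
  eps <- 1e-5
  check_one <- function(path, k, idx, an) {
    w2 <- w
    if (path == "conv") w2$conv[[k]]$W[idx] <- w2$conv[[k]]$W[idx] + eps
    else w2[[path]]$W[idx] <- w2[[path]]$W[idx] + eps
    epiderm:::nn_vgg_set_weights(p, w2)
    lp <- epiderm:::nn_vgg_batch_loss(p, xs, ys, 0L)
    if (path == "conv") w2$conv[[k]]$W[idx] <- w2$conv[[k]]$W[idx] - 2 * eps
    else w2[[path]]$W[idx] <- w2[[path]]$W[idx] - 2 * eps
    epiderm:::nn_vgg_set_weights(p, w2)
    lm <- epiderm:::nn_vgg_batch_loss(p, xs, ys, 0L)
    epiderm:::nn_vgg_set_weights(p, w)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-5)
  }
  for (k in seq_along(w$conv)) {
    idx <- sample(length(w$conv[[k]]$W), 1)
    check_one("conv", k, idx, g$conv[[k]]$W[idx])
  }
  check_one("fc1", NA, 3, g$fc1$W[3])
  check_one("fc2", NA, 2, g$fc2$W[2])
})

test_that("network outputs are well-formed probability maps", {
  p <- epiderm:::nn_unet_create(c(4L, 8L, 16L), 3L, 3L, 1L)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  out <- epiderm:::nn_unet_predict(p, x)
  expect_equal(dim(out), c(32, 32, 3))
  expect_lt(max(abs(out[, , 1] + out[, , 2] + out[, , 3] - 1)), 1e-6)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("identical seeds give identical weights and training traces", {
  a <- epiderm:::nn_unet_get_weights(epiderm:::nn_unet_create(c(4L, 8L), 3L, 3L, 5L))
  b <- epiderm:::nn_unet_get_weights(epiderm:::nn_unet_create(c(4L, 8L), 3L, 3L, 5L))
  expect_identical(a, b)
})
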