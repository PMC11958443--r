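# A compact convolutional network implemented from first principles:
# 3x3 same-padding convolutions via im2col + BLAS matmul, ReLU, 2x2 max
# pooling, dense layers, MSE/MAE losses and an Adam optimizer. Sized for
# desk-scale training of sub-pixel center regressors on streamed synthetic
# images; the full-scale architectures are carried as declarative specs.

#' Declarative model specifications
#'
#' `model_spec()` describes a conv-stack + dense regression architecture:
#' 3x3 kernels, ReLU activations, optional 2x2 max pooling after selected
#' conv layers, a dense stack, and a linear output of `n_out` values.
#' Presets: `demo_regressor_spec()` is the desk-scale center regressor
#' (4 conv layers of widths 16/32/64/64 with pooling after the first three,
#' one dense layer of 64, 2 outputs, 64-px input); `cr_cnn_spec()` and
#' `pupil_cnn_spec()` carry the full-scale seven-conv architectures
#' (documented configuration; training them is a compute decision left to
#' the user); `heatmap_unet_spec()` documents the residual heatmap model
#' (six residual modules in encoder and decoder at 256 channels, one output
#' map per feature).
#'
#' @param input_size Input side length, pixels (square grayscale input).
#' @param conv_widths Integer vector of conv channel widths.
#' @param pool_after Logical vector (same length) marking layers followed
#'   by 2x2 max pooling.
#' @param dense_widths Integer vector of hidden dense widths.
#' @param n_out Number of linear outputs.
#' @return Object of class `eyeforge_model_spec` (serializable to YAML).
#' @export
model_spec <- function(input_size, conv_widths, pool_after,
                       dense_widths, n_out = 2) {
  stopifnot(length(pool_after) == length(conv_widths))
  sz <- input_size
  for (p in pool_after) {
    if (p) {
      sz <- sz %/% 2  # odd trailing row/column is dropped by the pool
      if (sz < 1) rlang::abort("input too small for the pooling stack")
    }
  }
  structure(list(input_size = as.integer(input_size),
                 conv_widths = as.integer(conv_widths),
                 pool_after = as.logical(pool_after),
                 dense_widths = as.integer(dense_widths),
                 n_out = as.integer(n_out),
                 kernel = 3L, final_size = as.integer(sz)),
            class = "eyeforge_model_spec")
}

#' @rdname model_spec
#' @export
demo_regressor_spec <- function(input_size = 64) {
  model_spec(input_size, conv_widths = c(16, 32, 64, 64),
             pool_after = c(TRUE, TRUE, TRUE, FALSE),
             dense_widths = 64, n_out = 2)
}

#' @rdname model_spec
#' @param rate `"500"` or `"1000"` (the 1000-Hz pupil model is wider).
#' @export
cr_cnn_spec <- function(input_size = 180) {
  model_spec(input_size, conv_widths = c(64, 64, 128, 128, 256, 256, 512),
             pool_after = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
             dense_widths = c(64, 32), n_out = 2)
}

#' @rdname model_spec
#' @export
pupil_cnn_spec <- function(input_size = 180, rate = c("500", "1000")) {
  rate <- match.arg(rate)
  widths <- if (rate == "500") c(64, 64, 128, 128, 256, 256, 512) else
    c(128, 128, 256, 256, 512, 512, 768)
  model_spec(input_size, conv_widths = widths,
             pool_after = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
             dense_widths = c(64, 64), n_out = 2)
}

#' @rdname model_spec
#' @param n_features Number of output heatmaps (pupil + CRs).
#' @export
heatmap_unet_spec <- function(input_size = 128, n_features = 6) {
  structure(list(kind = "residual_unet", input_size = as.integer(input_size),
                 residual_modules = 6L, channels = 256L,
                 n_features = as.integer(n_features)),
            class = c("eyeforge_unet_spec", "eyeforge_model_spec"))
}

#' Initialize network parameters from a spec
#'
#' He-normal initialization for conv and dense weights, zero biases.
#'
#' @param spec An [model_spec()].
#' @param seed Integer seed for the initialization draw.
#' @return Object of class `eyeforge_cnn`.
#' @export
init_model <- function(spec, seed = 1L) {
  stopifnot(!inherits(spec, "eyeforge_unet_spec"))
  withr::with_seed(seed, {
    conv <- list()
    c_in <- 1L
    sz <- spec$input_size
    for (i in seq_along(spec$conv_widths)) {
      f <- spec$conv_widths[i]
      fan_in <- 9L * c_in
      conv[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f),
        b = rep(0, f), pool = spec$pool_after[i]
      )
      c_in <- f
      if (spec$pool_after[i]) sz <- sz %/% 2
    }
    dense <- list()
    d_in <- sz * sz * c_in
    widths <- c(spec$dense_widths, spec$n_out)
    for (i in seq_along(widths)) {
      d_out <- widths[i]
      dense[[i]] <- list(
        W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
        b = rep(0, d_out),
        act = if (i < length(widths)) "relu" else "linear"
      )
      d_in <- d_out
    }
  })
  structure(list(spec = spec, conv = conv, dense = dense),
            class = "eyeforge_cnn")
}

#' Number of trainable parameters
#'
#' @param model An `eyeforge_cnn`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(purrr::map_dbl(c(model$conv, model$dense),
                     ~ length(.x$W) + length(.x$b)))
}

# forward pass; X is an (H, W, 1, N) array, returns N x n_out predictions
# plus caches for backprop
nn_forward <- function(model, X, keep_cache = TRUE) {
  N <- dim(X)[4]
  cache <- list(conv = list(), dense = list())
  a <- X
  for (i in seq_along(model$conv)) {
    ly <- model$conv[[i]]
    d <- dim(a)
    cols <- im2col3(a, d[1], d[2], d[3], d[4])
    Z <- sweep(cols %*% ly$W, 2, ly$b, "+")
    A <- pmax(Z, 0)
    f <- ncol(ly$W)
    arr <- aperm(array(A, c(d[1], d[2], N, f)), c(1, 2, 4, 3))
    st <- list(cols = if (keep_cache) cols else NULL, Z = if (keep_cache) Z else NULL,
               dim_in = d)
    if (ly$pool) {
      mp <- maxpool2(arr, d[1], d[2], f, N)
      st$pool_idx <- mp$idx
      st$dim_pre <- dim(arr)
      arr <- mp$y
    }
    cache$conv[[i]] <- st
    a <- arr
  }
  d <- dim(a)
  flat_dim <- d[1] * d[2] * d[3]
  Xf <- t(matrix(a, flat_dim, N))
  cache$flat_dim <- d
  for (i in seq_along(model$dense)) {
    ly <- model$dense[[i]]
    Z <- sweep(Xf %*% ly$W, 2, ly$b, "+")
    cache$dense[[i]] <- list(X = if (keep_cache) Xf else NULL, Z = Z)
    Xf <- if (ly$act == "relu") pmax(Z, 0) else Z
  }
  list(out = Xf, cache = cache)
}

# backward pass; dout is N x n_out gradient of the loss wrt predictions
nn_backward <- function(model, cache, dout) {
  grads <- list(conv = vector("list", length(model$conv)),
                dense = vector("list", length(model$dense)))
  g <- dout
  for (i in rev(seq_along(model$dense))) {
    ly <- model$dense[[i]]
    st <- cache$dense[[i]]
    if (ly$act == "relu") g <- g * (st$Z > 0)
    grads$dense[[i]] <- list(W = crossprod(st$X, g), b = colSums(g))
    g <- g %*% t(ly$W)
  }
  d <- cache$flat_dim
  N <- d[4]
  g <- array(t(g), c(d[1], d[2], d[3], N))
  for (i in rev(seq_along(model$conv))) {
    ly <- model$conv[[i]]
    st <- cache$conv[[i]]
    if (ly$pool) {
      g <- maxpool2_backward(g, st$pool_idx, st$dim_pre[1], st$dim_pre[2],
                             st$dim_pre[3], st$dim_pre[4])
    }
    din <- st$dim_in
    f <- ncol(ly$W)
    dZ <- matrix(aperm(g, c(1, 2, 4, 3)), din[1] * din[2] * N, f)
    dZ <- dZ * (st$Z > 0)
    grads$conv[[i]] <- list(W = crossprod(st$cols, dZ), b = colSums(dZ))
    if (i > 1) {
      dcols <- dZ %*% t(ly$W)
      g <- col2im3(dcols, din[1], din[2], din[3], din[4])
    }
  }
  grads
}

#' Predict feature centers with a trained regressor
#'
#' @param object An `eyeforge_cnn`.
#' @param images A list of image matrices or an (H, W, 1, N) array.
#' @param ... Unused.
#' @return N x 2 matrix of predicted offsets from the image center, px.
#' @export
predict.eyeforge_cnn <- function(object, images, ...) {
  X <- stack_images(images, object$spec$input_size)
  nn_predict(object, X)
}

stack_images <- function(images, size) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.matrix(images)) images <- list(images)
  arr <- array(0, c(size, size, 1, length(images)))
  for (i in seq_along(images)) arr[, , 1, i] <- images[[i]]
  arr
}

# Adam optimizer state and update
adam_init <- function(model) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(t = 0,
       m = list(conv = purrr::map(model$conv, zero_like),
                dense = purrr::map(model$dense, zero_like)),
       v = list(conv = purrr::map(model$conv, zero_like),
                dense = purrr::map(model$dense, zero_like)))
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, frozen_conv = integer()) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m$W <- beta1 * m$W + (1 - beta1) * g$W
    m$b <- beta1 * m$b + (1 - beta1) * g$b
    v$W <- beta2 * v$W + (1 - beta2) * g$W^2
    v$b <- beta2 * v$b + (1 - beta2) * g$b^2
    p$W <- p$W - lr * (m$W / bc1) / (sqrt(v$W / bc2) + eps)
    p$b <- p$b - lr * (m$b / bc1) / (sqrt(v$b / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(model$conv)) {
    if (i %in% frozen_conv) next
    r <- upd(model$conv[[i]], grads$conv[[i]], state$m$conv[[i]],
             state$v$conv[[i]])
    model$conv[[i]][c("W", "b")] <- r$p[c("W", "b")]
    state$m$conv[[i]] <- r$m
    state$v$conv[[i]] <- r$v
  }
  for (i in seq_along(model$dense)) {
    r <- upd(model$dense[[i]], grads$dense[[i]], state$m$dense[[i]],
             state$v$dense[[i]])
    model$dense[[i]][c("W", "b")] <- r$p[c("W", "b")]
    state$m$dense[[i]] <- r$m
    state$v$dense[[i]] <- r$v
  }
  list(model = model, state = state)
}

#' Segmentation and heatmap losses
#'
#' Pixelwise losses used for the heatmap models, defined on probability
#' maps `p` and binary (or soft) targets `t` in `[0, 1]`: binary
#' cross-entropy, Dice loss `1 - 2*sum(p*t)/(sum(p)+sum(t))`, focal loss
#' with exponent `gamma`, and their weighted combination
#' `bce_weight * BCE + Dice + Focal`.
#'
#' @param p,t Numeric arrays of equal shape, values in `[0, 1]`.
#' @param eps Clamping constant for the logarithms.
#' @param gamma Focal exponent.
#' @param bce_weight Weight on the BCE term in the combination.
#' @return Scalar loss.
#' @name heatmap_losses
NULL

#' @rdname heatmap_losses
#' @export
bce_loss <- function(p, t, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' @rdname heatmap_losses
#' @export
dice_loss <- function(p, t, eps = 1e-7) {
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' @rdname heatmap_losses
#' @export
focal_loss <- function(p, t, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * (1 - p)^gamma * log(p) + (1 - t) * p^gamma * log(1 - p))
}

#' @rdname heatmap_losses
#' @export
combined_heatmap_loss <- function(p, t, bce_weight = 1, gamma = 2) {
  bce_weight * bce_loss(p, t) + dice_loss(p, t) + focal_loss(p, t, gamma)
}
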