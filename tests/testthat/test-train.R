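test_that("im2col convolution matches a direct nested-loop oracle", {
  withr::with_seed(1, {
    H <- 6; W <- 5; C <- 2; N <- 2; f <- 3
    x <- array(rnorm(H * W * C * N), c(H, W, C, N))
    Wt <- matrix(rnorm(9 * C * f), 9 * C, f)
  })
  cols <- eyeforge:::im2col3(x, H, W, C, N)
  out <- cols %*% Wt
  # direct evaluation: zero-padded 3x3 correlation
  oracle <- function(n, h, w, k) {
    acc <- 0
    for (c in 1:C) for (kw in 1:3) for (kh in 1:3) {
      hs <- h + kh - 2; ws <- w + kw - 2
      v <- if (hs >= 1 && hs <= H && ws >= 1 && ws <= W) x[hs, ws, c, n] else 0
      acc <- acc + v * Wt[(c - 1) * 9 + (kw - 1) * 3 + kh, k]
    }
    acc
  }
  for (pick in list(c(1, 1, 1, 1), c(2, 3, 4, 2), c(1, 6, 5, 3),
                    c(2, 1, 5, 1))) {
    n <- pick[1]; h <- pick[2]; w <- pick[3]; k <- pick[4]
    row <- h + H * (w - 1) + H * W * (n - 1)
    expect_equal(out[row, k], oracle(n, h, w, k), tolerance = 1e-12)
  }
})

test_that("max pooling and its backward pass route values correctly", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  mp <- eyeforge:::maxpool2(x, 4, 4, 1, 1)
  expect_equal(as.vector(mp$y), c(6, 8, 14, 16))
  dy <- array(c(10, 20, 30, 40), c(2, 2, 1, 1))
  dx <- eyeforge:::maxpool2_backward(dy, mp$idx, 4, 4, 1, 1)
  expect_equal(sum(dx), 100)
  expect_equal(dx[2, 2, 1, 1], 10)
  expect_equal(dx[4, 4, 1, 1], 40)
})

test_that("analytic gradients agree with finite differences", {
  spec <- model_spec(8, conv_widths = c(3, 4), pool_after = c(TRUE, TRUE),
                     dense_widths = 5, n_out = 2)
  model <- init_model(spec, seed = 2)
  withr::with_seed(3, {
    X <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
    Y <- matrix(rnorm(4), 2, 2)
  })
  lf <- eyeforge:::loss_fn("mse")
  fw <- nn_forward_internal <- eyeforge:::nn_forward(model, X)
  grads <- eyeforge:::nn_backward(model, fw$cache, lf$grad(fw$out, Y))
  eps <- 1e-6
  num_grad <- function(set, get) {
    m2 <- model
    v <- get(m2)
    out <- v
    for (i in seq_along(v)[1:min(6, length(v))]) {
      vp <- v; vp[i] <- vp[i] + eps
      m2 <- set(model, vp)
      lp <- lf$value(eyeforge:::nn_forward(m2, X)$out, Y)
      vm <- v; vm[i] <- vm[i] - eps
      m2 <- set(model, vm)
      lm <- lf$value(eyeforge:::nn_forward(m2, X)$out, Y)
      out[i] <- (lp - lm) / (2 * eps)
    }
    out[1:min(6, length(v))]
  }
  g_conv1 <- num_grad(function(m, v) { m$conv[[1]]$W[] <- v; m },
                      function(m) as.vector(m$conv[[1]]$W))
  expect_equal(as.vector(grads$conv[[1]]$W)[1:6], g_conv1, tolerance = 1e-5)
  g_dense2 <- num_grad(function(m, v) { m$dense[[2]]$W[] <- v; m },
                       function(m) as.vector(m$dense[[2]]$W))
  expect_equal(as.vector(grads$dense[[2]]$W)[1:6], g_dense2,
               tolerance = 1e-5)
  g_bias <- num_grad(function(m, v) { m$conv[[2]]$b <- v; m },
                     function(m) m$conv[[2]]$b)
  expect_equal(grads$conv[[2]]$b[1:4], g_bias[1:4], tolerance = 1e-5)
})

test_that("heatmap losses match hand-computed values on 2x2 toy maps", {
  p <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2)
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  bce_hand <- -mean(log(c(0.9, 0.9, 0.8, 0.8)))
  expect_equal(bce_loss(p, t), bce_hand, tolerance = 1e-6)
  dice_hand <- 1 - (2 * (0.9 + 0.8) + 1e-7) / (2 + 2 + 1e-7)
  expect_equal(dice_loss(p, t), dice_hand, tolerance = 1e-6)
  focal_hand <- -mean(c(0.1^2 * log(0.9), 0.1^2 * log(0.9),
                        0.2^2 * log(0.8), 0.2^2 * log(0.8)))
  expect_equal(focal_loss(p, t), focal_hand, tolerance = 1e-6)
  expect_equal(combined_heatmap_loss(p, t, bce_weight = 100),
               100 * bce_hand + dice_hand + focal_hand, tolerance = 1e-4)
})

test_that("heatmap targets put unit bumps at rounded centers", {
  li <- labeled_image(NULL, pupil = c(10.4, 20.6),
                      crs = tibble::tibble(id = 0:1, x = c(5, 30),
                                           y = c(6, 31),
                                           absent = c(FALSE, TRUE)),
                      width = 48, height = 48)
  maps <- make_heatmap_targets(li, size = 48)
  expect_named(maps, c("pupil", "cr0", "cr1"))
  expect_equal(max(maps$pupil), 1)
  pk <- extract_peaks(maps["pupil"])
  expect_equal(c(pk$x, pk$y), c(10, 21))
  expect_true(all(maps$cr1 == 0))
  # bump mass matches the closed-form Gaussian integral within 1%
  expect_lt(abs(sum(maps$cr0) / (2 * pi * 1^2) - 1), 0.01)
})

test_that("streamed batches are reproducible and never reuse images", {
  spec <- stream_spec(highres_cr_config(stage = 2, size = 32), 16, 4)
  s1 <- stream_batches(spec, seed = 5)
  s2 <- stream_batches(spec, seed = 5)
  b1 <- s1(); b2 <- s2()
  expect_identical(b1$x, b2$x)
  expect_identical(b1$y, b2$y)
  hashes <- character()
  s3 <- stream_batches(spec, seed = 6)
  for (i in 1:12) {
    b <- s3()
    for (k in 1:4) {
      hashes <- c(hashes, paste(head(b$x[, , 1, k], 40), collapse = ","))
    }
  }
  expect_equal(anyDuplicated(hashes), 0)
})

test_that("early stopping halts after patience non-improving epochs", {
  # zero learning rate: validation loss is constant, never improving on the
  # first epoch's value, so training stops after patience + 1 epochs
  cfg <- train_config(
    stages = list(list(cfg = highres_cr_config(stage = 2, size = 16),
                       lr = 0, max_epochs = 10, patience = 3,
                       frozen_conv = integer(), batch_size = 4,
                       images_per_epoch = 8, lr_decay = 1)),
    val_size = 4, loss = "mse"
  )
  spec <- model_spec(16, c(4, 4), c(TRUE, TRUE), 8, 2)
  res <- train_two_stage(init_model(spec, seed = 1), cfg, seed = 2)
  expect_equal(nrow(res$history), 4)
  expect_equal(length(unique(res$history$val_loss)), 1)
})

test_that("frozen conv layers keep identical weights through a stage", {
  spec <- model_spec(16, c(4, 4), c(TRUE, TRUE), 8, 2)
  model <- init_model(spec, seed = 3)
  cfg <- train_config(
    stages = list(list(cfg = highres_cr_config(stage = 2, size = 16),
                       lr = 1e-3, max_epochs = 2, patience = 5,
                       frozen_conv = 1L, batch_size = 4,
                       images_per_epoch = 8, lr_decay = 0.95)),
    val_size = 4, loss = "mse"
  )
  res <- train_two_stage(model, cfg, seed = 4)
  expect_identical(res$model$conv[[1]]$W, model$conv[[1]]$W)
  expect_false(identical(res$model$conv[[2]]$W, model$conv[[2]]$W))
  # learning-rate schedule decays exponentially per epoch
  expect_equal(res$history$lr, 1e-3 * 0.95^(res$history$epoch - 1))
  # stage learning rates must not increase
  expect_error(train_config(stages = list(list(lr = 1e-4), list(lr = 1e-3))))
})

test_that("synthetic evaluation reports errors against generator labels", {
  spec <- model_spec(32, c(4, 4), c(TRUE, TRUE), 8, 2)
  model <- init_model(spec, seed = 11)
  ev <- evaluate_synthetic(model, highres_cr_config(stage = 2, size = 32),
                           n = 20, seed = 12)
  expect_equal(nrow(ev$errors), 20)
  expect_true(all(ev$errors$error_px >= 0))
  expect_equal(ev$median_error, median(ev$errors$error_px))
  expect_true(all(diff(ev$detection$rate) >= 0))
  # a zero-weight network predicts the image center; its error must equal
  # the label's distance from the center (analytic oracle)
  zero <- model
  for (i in seq_along(zero$dense)) zero$dense[[i]]$W[] <- 0
  zero$dense[[length(zero$dense)]]$b[] <- 0
  ev0 <- evaluate_synthetic(zero, highres_cr_config(stage = 2, size = 32),
                            n = 10, seed = 13)
  scenes <- generate_scenes(highres_cr_config(stage = 2, size = 32), 10,
                            seed = 13)
  mid <- (32 - 1) / 2
  d <- purrr::map_dbl(scenes, ~ sqrt(sum((c(.x$crs$x, .x$crs$y) - mid)^2)))
  expect_equal(ev0$errors$error_px, d, tolerance = 1e-9)
})

test_that("full-scale architecture specs construct and handle odd pooling", {
  cr <- cr_cnn_spec()
  expect_equal(cr$conv_widths, c(64, 64, 128, 128, 256, 256, 512))
  expect_equal(cr$dense_widths, c(64, 32))
  pu <- pupil_cnn_spec(rate = "1000")
  expect_equal(pu$conv_widths, c(128, 128, 256, 256, 512, 512, 768))
  un <- heatmap_unet_spec(n_features = 6)
  expect_equal(un$residual_modules, 6L)
  expect_equal(un$channels, 256L)
  # odd intermediate sizes: the pool drops the trailing row/column
  spec <- model_spec(9, c(2, 2), c(TRUE, TRUE), 4, 2)
  expect_equal(spec$final_size, 2L)
  m <- init_model(spec, seed = 5)
  out <- eyeforge:::nn_forward(m, array(rnorm(81 * 2), c(9, 9, 1, 2)))$out
  expect_equal(dim(out), c(2, 2))
  expect_gt(count_params(m), 0)
})
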