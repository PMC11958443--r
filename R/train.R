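# Training on streamed synthetic data: every batch is freshly generated,
# shown to the network once, and discarded, so the model never sees the
# same image twice. A two-stage curriculum trains first on a broad, hard
# distribution and then narrows to scenes close to the target setup, with
# a reduced learning rate and frozen early layers.

#' Stream specification
#'
#' @param cfg A pipeline configuration (the generator to stream from).
#' @param images_per_epoch Unique images per epoch.
#' @param batch_size Images per gradient step.
#' @return Object of class `eyeforge_stream`.
#' @export
stream_spec <- function(cfg, images_per_epoch = 1000, batch_size = 32) {
  structure(list(cfg = cfg, images_per_epoch = as.integer(images_per_epoch),
                 batch_size = as.integer(batch_size)),
            class = "eyeforge_stream")
}

#' Iterator over freshly generated training batches
#'
#' Returns a closure that yields `list(x, y, index)` on each call: `x` an
#' `(H, W, 1, B)` image array, `y` a `B x 2` matrix of center offsets from
#' the image center in pixels (the regression target). Batches are
#' deterministic given the root seed and independent of batching layout;
#' each image comes from its own child stream indexed by a global counter.
#' Generator placement failures skip to the next substream (counted in the
#' `failures` attribute of the batch).
#'
#' @param spec An [stream_spec()].
#' @param seed Root seed.
#' @return A function yielding batches.
#' @export
stream_batches <- function(spec, seed = 1L) {
  counter <- 0L
  size <- spec$cfg$size
  function() {
    b <- spec$batch_size
    x <- array(0, c(size, size, 1, b))
    y <- matrix(0, b, 2)
    failures <- 0L
    i <- 1L
    while (i <= b) {
      counter <<- counter + 1L
      li <- tryCatch(
        withr::with_seed(child_seed(seed, counter), gen_scene(spec$cfg)),
        eyeforge_error_placement = function(e) NULL
      )
      if (is.null(li)) { failures <- failures + 1L; next }
      x[, , 1, i] <- li$image
      ctr <- scene_center_label(li)
      mid <- (size - 1) / 2
      y[i, ] <- ctr - mid
      i <- i + 1L
    }
    structure(list(x = x, y = y, index = counter), failures = failures)
  }
}

# the regression target of a labeled image: the pupil center when present,
# otherwise the (single) CR center
scene_center_label <- function(li) {
  if (!is.null(li$pupil)) return(li$pupil)
  c(li$crs$x[1], li$crs$y[1])
}

#' Gaussian heatmap training targets
#'
#' One target map per feature: an isotropic Gaussian bump with peak value 1
#' at the rounded feature center and SD 1 px; absent features get an
#' all-zero map. The unit peak fixes the logit scale that the validity rule
#' (max value >= 1) presupposes.
#'
#' @param li An `eyeforge_labeled`.
#' @param size Map side length, pixels.
#' @param sd Bump standard deviation, px.
#' @return Named list of matrices (`pupil` if present, then `cr0`,
#'   `cr1`, ...).
#' @export
make_heatmap_targets <- function(li, size = li$width, sd = 1) {
  bump <- function(cx, cy) {
    g <- grid_xy(size, size)
    exp(-((g$x - round(cx))^2 + (g$y - round(cy))^2) / (2 * sd^2))
  }
  maps <- list()
  if (!is.null(li$pupil)) maps$pupil <- bump(li$pupil[1], li$pupil[2])
  if (nrow(li$crs) > 0) {
    for (i in seq_len(nrow(li$crs))) {
      nm <- paste0("cr", li$crs$id[i])
      maps[[nm]] <- if (li$crs$absent[i]) {
        matrix(0, size, size)
      } else {
        bump(li$crs$x[i], li$crs$y[i])
      }
    }
  }
  maps
}

#' Training configuration
#'
#' @param stages List of stage descriptions, each a list with elements
#'   `cfg` (generator configuration), `lr` (initial learning rate),
#'   `max_epochs`, `patience` (early-stopping patience, epochs),
#'   `frozen_conv` (indices of conv layers frozen in this stage),
#'   `batch_size`, `images_per_epoch`, `lr_decay` (per-epoch exponential
#'   decay factor).
#' @param val_size Pre-generated validation set size per stage.
#' @param loss `"mse"` or `"mae"`.
#' @return Object of class `eyeforge_train_config`.
#' @export
train_config <- function(stages, val_size = 300, loss = c("mse", "mae")) {
  loss <- match.arg(loss)
  lrs <- purrr::map_dbl(stages, "lr")
  if (length(lrs) > 1 && any(diff(lrs) > 0)) {
    rlang::abort("stage learning rates must be non-increasing")
  }
  structure(list(stages = stages, val_size = as.integer(val_size),
                 loss = loss),
            class = "eyeforge_train_config")
}

#' Default two-stage regime for the demo CR center regressor
#'
#' Stage 1 trains on the broad CR distribution, stage 2 narrows to scenes
#' with the CR near the image center at a reduced learning rate with the
#' first conv layer frozen.
#'
#' @param size Canvas/input side, pixels.
#' @param rate `"500"` or `"1000"` pipeline variant.
#' @param epochs1,epochs2 Per-stage epoch caps.
#' @param images_per_epoch Streamed images per epoch.
#' @return An [train_config()].
#' @export
demo_train_config <- function(size = 64, rate = "500", epochs1 = 4,
                              epochs2 = 8, images_per_epoch = 1000) {
  train_config(
    stages = list(
      list(cfg = highres_cr_config(rate = rate, stage = 1, size = size),
           lr = 1e-3, max_epochs = epochs1, patience = 3,
           frozen_conv = integer(), batch_size = 32,
           images_per_epoch = images_per_epoch, lr_decay = 0.95),
      list(cfg = highres_cr_config(rate = rate, stage = 2, size = size),
           lr = 2e-4, max_epochs = epochs2, patience = 3,
           frozen_conv = 1L, batch_size = 32,
           images_per_epoch = images_per_epoch, lr_decay = 0.95)
    ),
    val_size = 300, loss = "mse"
  )
}

# forward in chunks to bound the transient im2col allocations
nn_predict <- function(model, X, chunk = 64L) {
  N <- dim(X)[4]
  out <- NULL
  for (i in seq(1, N, by = chunk)) {
    j <- min(i + chunk - 1, N)
    p <- nn_forward(model, X[, , , i:j, drop = FALSE], keep_cache = FALSE)$out
    out <- rbind(out, p)
  }
  out
}

loss_fn <- function(kind) {
  if (kind == "mse") {
    list(value = function(p, y) mean((p - y)^2),
         grad = function(p, y) 2 * (p - y) / length(p))
  } else {
    list(value = function(p, y) mean(abs(p - y)),
         grad = function(p, y) sign(p - y) / length(p))
  }
}

#' Train a center-regression CNN with the two-stage regime
#'
#' Per stage: stream freshly generated batches (each image shown once),
#' optimize with Adam under a per-epoch exponential learning-rate decay,
#' validate each epoch on a pre-generated fixed synthetic set, stop early
#' when the validation loss has not improved for `patience` epochs, and
#' restore the best weights. Between stages the stage's frozen conv layers
#' are excluded from updates.
#'
#' @param model An `eyeforge_cnn` from [init_model()].
#' @param cfg An [train_config()].
#' @param seed Root seed for streaming, validation sets and batching.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained), `history` (tibble: stage, epoch,
#'   train_loss, val_loss, lr).
#' @export
train_two_stage <- function(model, cfg, seed = 1L, verbose = FALSE) {
  lf <- loss_fn(cfg$loss)
  history <- list()
  for (s in seq_along(cfg$stages)) {
    st <- cfg$stages[[s]]
    val <- generate_scenes(st$cfg, cfg$val_size, seed = child_seed(seed, 7e6 + s))
    size <- st$cfg$size
    mid <- (size - 1) / 2
    val_x <- stack_images(purrr::map(val, "image"), size)
    val_y <- do.call(rbind, purrr::map(val, ~ scene_center_label(.x) - mid))
    stream <- stream_batches(stream_spec(st$cfg, st$images_per_epoch,
                                         st$batch_size),
                             seed = child_seed(seed, 31L * s))
    opt <- adam_init(model)
    best_loss <- Inf
    best_model <- model
    since_best <- 0L
    steps <- ceiling(st$images_per_epoch / st$batch_size)
    for (epoch in seq_len(st$max_epochs)) {
      lr <- st$lr * st$lr_decay^(epoch - 1)
      tr_loss <- 0
      for (step in seq_len(steps)) {
        batch <- stream()
        fw <- nn_forward(model, batch$x)
        l <- lf$value(fw$out, batch$y)
        if (!is.finite(l)) {
          rlang::abort(sprintf("non-finite loss at stage %d epoch %d", s, epoch),
                       class = "eyeforge_error_training")
        }
        grads <- nn_backward(model, fw$cache, lf$grad(fw$out, batch$y))
        r <- adam_step(model, grads, opt, lr, frozen_conv = st$frozen_conv)
        model <- r$model
        opt <- r$state
        tr_loss <- tr_loss + l
      }
      val_pred <- nn_predict(model, val_x)
      vl <- lf$value(val_pred, val_y)
      history[[length(history) + 1]] <- tibble::tibble(
        stage = s, epoch = epoch, train_loss = tr_loss / steps,
        val_loss = vl, lr = lr
      )
      if (verbose) {
        message(sprintf("stage %d epoch %d train %.4f val %.4f",
                        s, epoch, tr_loss / steps, vl))
      }
      if (vl < best_loss) {
        best_loss <- vl
        best_model <- model
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= st$patience) break
      }
    }
    model <- best_model
  }
  history <- dplyr::bind_rows(history)
  structure(list(model = model, history = history,
                 loss = cfg$loss, seed = seed),
            class = "eyeforge_trained")
}

#' @export
print.eyeforge_trained <- function(x, ...) {
  cat(sprintf("trained center regressor (%d parameters), %d epochs\n",
              count_params(x$model), nrow(x$history)))
  invisible(x)
}

#' @method tidy eyeforge_trained
#' @export
tidy.eyeforge_trained <- function(x, ...) x$history

#' @method glance eyeforge_trained
#' @export
glance.eyeforge_trained <- function(x, ...) {
  tibble::tibble(
    n_params = count_params(x$model),
    epochs = nrow(x$history),
    final_val_loss = x$history$val_loss[nrow(x$history)],
    best_val_loss = min(x$history$val_loss)
  )
}

#' Evaluate a trained regressor on held-out synthetic images
#'
#' Generates `n` fresh labeled images, runs the model, and reports
#' localization errors of the predicted centers against the generator
#' labels.
#'
#' @param trained An [train_two_stage()] result (or `eyeforge_cnn`).
#' @param cfg Pipeline configuration for the held-out images.
#' @param n Number of images.
#' @param seed Seed for the held-out set.
#' @param thresholds Detection-rate thresholds, px.
#' @return List with `errors` (tibble: index, error_px), `median_error`,
#'   `mean_error`, and `detection` (cumulative detection rates).
#' @export
evaluate_synthetic <- function(trained, cfg, n = 500, seed = 99L,
                               thresholds = c(0.5, 1, 2, 5)) {
  model <- if (inherits(trained, "eyeforge_trained")) trained$model else trained
  scenes <- generate_scenes(cfg, n, seed = seed)
  size <- cfg$size
  mid <- (size - 1) / 2
  X <- stack_images(purrr::map(scenes, "image"), size)
  pred <- nn_predict(model, X) + mid
  truth <- do.call(rbind, purrr::map(scenes, scene_center_label))
  err <- sqrt(rowSums((pred - truth)^2))
  list(errors = tibble::tibble(index = seq_len(n), error_px = err),
       median_error = stats::median(err), mean_error = mean(err),
       detection = cumulative_detection_rate(err, thresholds))
}
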