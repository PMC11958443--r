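# Eye-tracking data-quality metrics and P-CR gaze calibration. Signals are
# tibbles of timestamped 2D positions; precision metrics use a sliding
# window (200 ms by convention) with stride one sample and report the
# median over windows.

#' Timed 2D position signal
#'
#' @param t Timestamps in seconds, strictly increasing. Generated from
#'   `fs` when omitted.
#' @param x,y Positions (px or deg); `NA` marks missing samples.
#' @param valid Optional logical; invalid samples are treated as missing.
#' @param fs Sampling rate in Hz.
#' @param unit Unit tag (`"px"` or `"deg"`).
#' @return Tibble of class `eyeforge_signal` with columns `t`, `x`, `y`,
#'   `valid` and attributes `fs`, `unit`.
#' @export
timed_signal <- function(x, y, t = NULL, valid = NULL, fs, unit = "px") {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  stopifnot(all(diff(t) > 0))
  if (is.null(valid)) valid <- !(is.na(x) | is.na(y))
  out <- tibble::tibble(t = t, x = x, y = y, valid = valid & !is.na(x) & !is.na(y))
  attr(out, "fs") <- fs
  attr(out, "unit") <- unit
  class(out) <- c("eyeforge_signal", class(out))
  out
}

signal_fs <- function(signal) attr(signal, "fs")

# number of samples in a window of `window` seconds at the signal's rate
window_samples <- function(signal, window) {
  n <- round(window * signal_fs(signal))
  max(n, 2L)
}

#' Windowed RMS sample-to-sample precision
#'
#' RMS-S2S precision: in each window (stride one sample) the root mean
#' square of Euclidean displacements between consecutive valid samples is
#' computed; the median over windows is returned. Missing samples are
#' excluded pairwise; windows with fewer than two valid samples are
#' skipped.
#'
#' @param signal A [timed_signal()].
#' @param window Window duration in seconds (default 200 ms).
#' @return Median windowed RMS-S2S (same unit as the signal).
#' @export
rms_s2s <- function(signal, window = 0.2) {
  win_stat(signal, window, function(x, y) {
    d2 <- diff(x)^2 + diff(y)^2
    if (length(d2) == 0) return(NA_real_)
    sqrt(mean(d2))
  })
}

#' Windowed STD precision
#'
#' In each window the combined positional standard deviation
#' `sqrt(var(x) + var(y))` over valid samples is computed; the median over
#' windows is returned.
#'
#' @inheritParams rms_s2s
#' @return Median windowed STD.
#' @export
std_precision <- function(signal, window = 0.2) {
  win_stat(signal, window, function(x, y) {
    sqrt(stats::var(x) + stats::var(y))
  })
}

win_stat <- function(signal, window, stat) {
  k <- window_samples(signal, window)
  n <- nrow(signal)
  if (sum(signal$valid) < 2) {
    rlang::abort("need at least two valid samples",
                 class = "eyeforge_error_metric")
  }
  vals <- vapply(seq_len(max(n - k + 1, 1)), function(i) {
    idx <- i:min(i + k - 1, n)
    ok <- signal$valid[idx]
    if (sum(ok) < 2) return(NA_real_)
    stat(signal$x[idx][ok], signal$y[idx][ok])
  }, numeric(1))
  stats::median(vals, na.rm = TRUE)
}

#' Pupil minus CR vector
#'
#' The P-CR gaze vector: the CR center location subtracted elementwise from
#' the pupil center location. A sample is missing when either input is.
#'
#' @param pupil,cr [timed_signal()] objects on aligned timestamps.
#' @return A [timed_signal()] of the difference vector.
#' @export
pcr_vector <- function(pupil, cr) {
  if (nrow(pupil) != nrow(cr) ||
      max(abs(pupil$t - cr$t)) > .Machine$double.eps^0.5) {
    rlang::abort("pupil and CR signals must share timestamps",
                 class = "eyeforge_error_alignment")
  }
  ok <- pupil$valid & cr$valid
  timed_signal(x = ifelse(ok, pupil$x - cr$x, NA_real_),
               y = ifelse(ok, pupil$y - cr$y, NA_real_),
               t = pupil$t, valid = ok, fs = signal_fs(pupil),
               unit = attr(pupil, "unit"))
}

poly_terms <- function(x, y) {
  cbind(1, x, y, x^2, y^2, x * y)
}

#' Fit a second-order polynomial P-CR calibration
#'
#' Least-squares fit, per screen axis, of a second-order polynomial with
#' first-order interaction (terms 1, x, y, x^2, y^2, xy) mapping the P-CR
#' vector to gaze angles in degrees. Nine fixation targets on a 3x3 grid
#' are sufficient (six terms per axis).
#'
#' @param pcr Data frame with columns `x`, `y`: P-CR vectors at the
#'   calibration fixations.
#' @param targets Data frame with columns `x`, `y`: target positions, deg.
#' @return Object of class `eyeforge_calibration` holding a 6 x 2
#'   coefficient matrix.
#' @export
fit_calibration <- function(pcr, targets) {
  stopifnot(nrow(pcr) == nrow(targets))
  if (nrow(pcr) < 6) {
    rlang::abort("need at least 6 calibration points",
                 class = "eyeforge_error_fit")
  }
  X <- poly_terms(pcr$x, pcr$y)
  if (qr(X)$rank < 6) {
    rlang::abort("calibration design is rank deficient (collinear points)",
                 class = "eyeforge_error_fit")
  }
  fit <- stats::lm.fit(X, cbind(targets$x, targets$y))
  coefs <- fit$coefficients
  rownames(coefs) <- c("1", "x", "y", "x^2", "y^2", "xy")
  colnames(coefs) <- c("deg_x", "deg_y")
  structure(list(coefficients = coefs,
                 residuals = fit$residuals, n = nrow(pcr)),
            class = "eyeforge_calibration")
}

#' Apply a fitted calibration to a P-CR signal
#'
#' @param model An [fit_calibration()] result.
#' @param pcr A [timed_signal()] of P-CR vectors (or a data frame with
#'   `x`, `y`).
#' @return A [timed_signal()] of gaze positions in degrees (missing samples
#'   pass through as missing), or a tibble when `pcr` is a plain data
#'   frame.
#' @export
apply_calibration <- function(model, pcr) {
  g <- poly_terms(pcr$x, pcr$y) %*% model$coefficients
  if (inherits(pcr, "eyeforge_signal")) {
    timed_signal(x = ifelse(pcr$valid, g[, 1], NA_real_),
                 y = ifelse(pcr$valid, g[, 2], NA_real_),
                 t = pcr$t, valid = pcr$valid, fs = signal_fs(pcr),
                 unit = "deg")
  } else {
    tibble::tibble(x = g[, 1], y = g[, 2])
  }
}

#' @export
print.eyeforge_calibration <- function(x, ...) {
  cat("P-CR polynomial calibration (6 terms per axis)\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy eyeforge_calibration
#' @export
tidy.eyeforge_calibration <- function(x, ...) {
  tibble::tibble(
    term = rep(rownames(x$coefficients), 2),
    axis = rep(colnames(x$coefficients), each = 6),
    estimate = c(x$coefficients[, 1], x$coefficients[, 2])
  )
}

#' @method glance eyeforge_calibration
#' @export
glance.eyeforge_calibration <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    rmse_x = sqrt(mean(x$residuals[, 1]^2)),
    rmse_y = sqrt(mean(x$residuals[, 2]^2))
  )
}

#' Gaze accuracy as mean fixation offset
#'
#' For each fixation window, the Euclidean distance between the median gaze
#' position in the window and the target is computed; the mean over
#' fixations is returned.
#'
#' @param gaze A [timed_signal()] in degrees.
#' @param targets Data frame with columns `x`, `y` (one row per fixation).
#' @param windows Data frame with columns `t_start`, `t_end` (seconds, one
#'   row per fixation).
#' @return List with `accuracy` (mean offset, deg), `offsets` (per
#'   fixation) and `n_skipped` (empty windows).
#' @export
accuracy_offset <- function(gaze, targets, windows) {
  stopifnot(nrow(targets) == nrow(windows))
  offs <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    idx <- gaze$t >= windows$t_start[i] & gaze$t <= windows$t_end[i] &
      gaze$valid
    if (!any(idx)) next
    mx <- stats::median(gaze$x[idx])
    my <- stats::median(gaze$y[idx])
    offs[i] <- sqrt((mx - targets$x[i])^2 + (my - targets$y[i])^2)
  }
  n_skipped <- sum(is.na(offs))
  if (n_skipped > 0) {
    rlang::warn(sprintf("%d empty fixation window(s) skipped", n_skipped))
  }
  list(accuracy = mean(offs, na.rm = TRUE), offsets = offs,
       n_skipped = n_skipped)
}

#' Cumulative detection rate
#'
#' Fraction of localization errors within (less than or equal to) each
#' threshold distance.
#'
#' @param errors Non-negative localization errors, px.
#' @param thresholds Threshold distances, px.
#' @return Tibble with columns `threshold`, `rate`.
#' @export
cumulative_detection_rate <- function(errors, thresholds = c(2, 5)) {
  if (length(errors) == 0) {
    rlang::abort("no errors supplied", class = "eyeforge_error_metric")
  }
  stopifnot(all(errors >= 0))
  tibble::tibble(
    threshold = thresholds,
    rate = vapply(thresholds, function(t) mean(errors <= t), numeric(1))
  )
}

#' Mean pixel error between predicted and true centers
#'
#' Predictions made on downscaled images are multiplied by `scale` to undo
#' the downscaling before the Euclidean distance is computed.
#'
#' @param pred,truth Data frames with columns `x`, `y` (matched rows).
#' @param scale Upscaling factor applied to predictions.
#' @return Mean Euclidean error in full-resolution pixels.
#' @export
mean_pixel_error <- function(pred, truth, scale = 1) {
  stopifnot(nrow(pred) == nrow(truth))
  ok <- stats::complete.cases(pred[, c("x", "y")]) &
    stats::complete.cases(truth[, c("x", "y")])
  if (!any(ok)) {
    rlang::abort("no valid prediction/truth pairs",
                 class = "eyeforge_error_metric")
  }
  mean(sqrt((pred$x[ok] * scale - truth$x[ok])^2 +
              (pred$y[ok] * scale - truth$y[ok])^2))
}
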