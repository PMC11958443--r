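# ggplot2 visualizations for rendered images, labeled scenes, detection
# rate curves and training history.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rendered image
#'
#' @param object An `eyeforge_image` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eyeforge_image
#' @export
autoplot.eyeforge_image <- function(object, ...) {
  df <- image_df(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

image_df <- function(image) {
  tibble::tibble(
    x = rep(seq_len(ncol(image)) - 1, each = nrow(image)),
    y = rep(seq_len(nrow(image)) - 1, times = ncol(image)),
    value = as.vector(unclass(image))
  )
}

#' Plot a labeled synthetic scene with its ground-truth centers
#'
#' @param object An `eyeforge_labeled`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eyeforge_labeled
#' @export
autoplot.eyeforge_labeled <- function(object, ...) {
  p <- autoplot.eyeforge_image(object$image)
  lbl <- labels_tibble(object)
  lbl <- lbl[!lbl$absent, ]
  if (nrow(lbl) > 0) {
    p <- p + ggplot2::geom_point(
      data = lbl,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$feature),
      inherit.aes = FALSE, shape = 3, size = 2
    )
  }
  p
}

#' Plot cumulative detection rate curves
#'
#' @param errors Numeric localization errors, px, or a named list of such
#'   vectors to compare methods.
#' @param max_px Largest threshold shown.
#' @return A ggplot of the cumulative detection rate against the error
#'   threshold.
#' @export
plot_detection_rate <- function(errors, max_px = 5) {
  if (!is.list(errors)) errors <- list(method = errors)
  ths <- seq(0, max_px, by = 0.1)
  df <- purrr::imap_dfr(errors, function(e, nm) {
    dplyr::mutate(cumulative_detection_rate(e, ths), method = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$rate,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "error threshold (px)",
                  y = "cumulative detection rate") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object An `eyeforge_trained` result.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch, faceted by stage.
#' @method autoplot eyeforge_trained
#' @export
autoplot.eyeforge_trained <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~stage, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}
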