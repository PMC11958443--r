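#' Labeled synthetic image
#'
#' Container pairing a rendered image with its ground truth: the continuous
#' (sub-pixel) pupil center, a tibble of CR centers with identity indices
#' and absence flags, and optional binary masks. Coordinates are 0-based
#' pixel centers in the full-resolution image frame.
#'
#' @param image Rendered image matrix (values in `[0, 1]`), or `NULL` when
#'   only labels were generated.
#' @param pupil Numeric `c(x, y)` or `NULL`.
#' @param crs Tibble with columns `id` (0-based identity), `x`, `y`,
#'   `absent` (logical); may have zero rows.
#' @param masks Named list of logical matrices.
#' @param scene The [scene_spec()] the image was rendered from (optional).
#' @param width,height Canvas size (required when `image` is `NULL`).
#' @return Object of class `eyeforge_labeled`.
#' @export
labeled_image <- function(image, pupil = NULL, crs = empty_crs(),
                          masks = list(), scene = NULL,
                          width = if (!is.null(image)) ncol(image) else NULL,
                          height = if (!is.null(image)) nrow(image) else NULL) {
  stopifnot(!is.null(width), !is.null(height))
  if (!is.null(pupil)) {
    stopifnot(pupil[1] >= 0, pupil[1] <= width - 1,
              pupil[2] >= 0, pupil[2] <= height - 1)
  }
  present <- !crs$absent
  if (any(present)) {
    stopifnot(all(crs$x[present] >= 0), all(crs$x[present] <= width - 1),
              all(crs$y[present] >= 0), all(crs$y[present] <= height - 1))
  }
  stopifnot(!anyDuplicated(crs$id))
  structure(
    list(image = image, pupil = pupil, crs = crs, masks = masks,
         scene = scene, width = width, height = height, valid = TRUE),
    class = "eyeforge_labeled"
  )
}

empty_crs <- function() {
  tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                 absent = logical())
}

#' Flatten labels of one or many labeled images to a tibble
#'
#' One row per labeled feature, in the format written to `labels.csv`:
#' `filename` (or index), `feature` (`"pupil"`/`"cr"`), `id`, `x`, `y`,
#' `absent`.
#'
#' @param x An `eyeforge_labeled` or a list of them.
#' @param filenames Optional character vector of file names.
#' @return A tibble.
#' @export
labels_tibble <- function(x, filenames = NULL) {
  if (inherits(x, "eyeforge_labeled")) x <- list(x)
  if (is.null(filenames)) {
    filenames <- sprintf("img_%06d.png", seq_along(x) - 1L)
  }
  purrr::map2_dfr(x, filenames, function(li, fn) {
    rows <- list()
    if (!is.null(li$pupil)) {
      rows$pupil <- tibble::tibble(filename = fn, feature = "pupil",
                                   id = 0L, x = li$pupil[1], y = li$pupil[2],
                                   absent = FALSE)
    }
    if (nrow(li$crs) > 0) {
      rows$cr <- tibble::tibble(filename = fn, feature = "cr",
                                id = li$crs$id, x = li$crs$x, y = li$crs$y,
                                absent = li$crs$absent)
    }
    dplyr::bind_rows(rows)
  })
}

# derive a bounded per-image seed from a root seed and an image index so
# generation order and parallel workers do not change content
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 2654435761) %% 2147483647)
}

#' Generate a batch of labeled scenes from any pipeline configuration
#'
#' Dispatches on the configuration class (see [highres_cr_config()],
#' [highres_pupil_config()], [eds2019_config()], [chugh_config()],
#' [eds2020_config()]). Each image draws from an independent child stream
#' indexed by its counter, so the same `seed` reproduces the same images
#' regardless of batch splits.
#'
#' @param cfg A pipeline configuration object.
#' @param n Number of images.
#' @param seed Root seed (integer).
#' @param offset Index of the first image in the stream (for batching).
#' @param render If `FALSE`, skip rasterization and return label-only
#'   `eyeforge_labeled` objects (fast path for distribution checks).
#' @return List of `eyeforge_labeled`.
#' @export
generate_scenes <- function(cfg, n, seed = 1L, offset = 0L, render = TRUE) {
  purrr::map(seq_len(n), function(i) {
    withr::with_seed(child_seed(seed, offset + i), gen_scene(cfg, render = render))
  })
}

#' @keywords internal
gen_scene <- function(cfg, render = TRUE) UseMethod("gen_scene")
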