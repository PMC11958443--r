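# Classical thresholding baseline: binarize at fixed pupil and CR
# thresholds, fill holes, select blobs by size/shape/relative-location
# criteria, and return binary centers of mass. Also prepares the masked
# cutouts used as CNN input on high-resolution images.

#' Thresholding-baseline configuration
#'
#' @param pupil_threshold 8-bit intensity below which pixels count as pupil.
#' @param cr_threshold 8-bit intensity above which pixels count as CR.
#' @param pupil_area,cr_area Admissible blob areas, px^2.
#' @param max_axis_ratio Maximum moment-ellipse axis ratio for the pupil.
#' @param cr_location_factor A CR blob is accepted only if its center lies
#'   within `cr_location_factor` times the pupil blob's bounding radius of
#'   the pupil center.
#' @param cutout_size Side of the CNN input cutouts, pixels.
#' @param cr_mask_radius Radius of the black circular mask on CR cutouts.
#' @param pupil_mask_scale Scale of the grey elliptical mask on pupil
#'   cutouts relative to the fitted pupil ellipse.
#' @return Object of class `eyeforge_threshold_config`.
#' @export
threshold_config <- function(pupil_threshold, cr_threshold,
                             pupil_area = c(50, 1e5), cr_area = c(2, 5000),
                             max_axis_ratio = 3, cr_location_factor = 1.5,
                             cutout_size = 180, cr_mask_radius = 32,
                             pupil_mask_scale = 1.4) {
  stopifnot(pupil_threshold >= 0, pupil_threshold <= 255,
            cr_threshold >= 0, cr_threshold <= 255)
  structure(as.list(environment()),
            class = "eyeforge_threshold_config")
}

blob_bounding_radius <- function(mask, center) {
  idx <- which(mask)
  y <- (idx - 1L) %% nrow(mask)
  x <- (idx - 1L) %/% nrow(mask)
  sqrt(max((x - center[1])^2 + (y - center[2])^2))
}

#' Detect pupil and CR centers by fixed-threshold binarization
#'
#' Binarizes the image at the pupil threshold (dark blobs) and the CR
#' threshold (bright blobs), fills holes, and selects candidates: the pupil
#' is the largest dark blob passing the size and shape criteria; the CR is
#' the largest bright blob whose center lies within
#' `cr_location_factor` times the pupil's bounding radius of the pupil
#' center. Centers are binary centers of mass.
#'
#' @param image Image matrix with values in `[0, 1]`.
#' @param cfg A [threshold_config()].
#' @return Tibble with one row per feature (`"pupil"`, `"cr"`): `x`, `y`,
#'   `found`, `area`. Coordinates are `NA` when the feature is missing.
#' @export
threshold_detect <- function(image, cfg) {
  img255 <- image * 255
  res <- tibble::tibble(feature = c("pupil", "cr"),
                        x = NA_real_, y = NA_real_,
                        found = FALSE, area = NA_real_)
  pupil_mask <- NULL
  bw_p <- img255 < cfg$pupil_threshold
  if (any(bw_p)) {
    bw_p <- fill_holes(bw_p)
    lab <- matrix(as.integer(EBImage::bwlabel(bw_p)), nrow = nrow(bw_p))
    best <- select_blob(lab, cfg$pupil_area, cfg$max_axis_ratio)
    if (!is.null(best)) {
      pupil_mask <- lab == best
      ctr <- blob_centroid(pupil_mask)
      res[1, c("x", "y")] <- as.list(ctr)
      res$found[1] <- TRUE
      res$area[1] <- sum(pupil_mask)
    }
  }
  if (!is.null(pupil_mask)) {
    p_ctr <- c(res$x[1], res$y[1])
    p_rad <- blob_bounding_radius(pupil_mask, p_ctr)
    bw_c <- img255 > cfg$cr_threshold
    if (any(bw_c)) {
      bw_c <- fill_holes(bw_c)
      lab_c <- matrix(as.integer(EBImage::bwlabel(bw_c)), nrow = nrow(bw_c))
      ids <- setdiff(unique(as.vector(lab_c)), 0L)
      best_area <- -Inf
      for (id in ids) {
        m <- lab_c == id
        a <- sum(m)
        if (a < cfg$cr_area[1] || a > cfg$cr_area[2]) next
        ctr <- blob_centroid(m)
        if (sqrt(sum((ctr - p_ctr)^2)) > cfg$cr_location_factor * p_rad) next
        if (a > best_area) {
          best_area <- a
          res[2, c("x", "y")] <- as.list(ctr)
          res$found[2] <- TRUE
          res$area[2] <- a
        }
      }
    }
  }
  attr(res, "pupil_mask") <- pupil_mask
  res
}

disk_mask <- function(size, center, radius) {
  g <- grid_xy(size, size)
  (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
}

#' Masked CR cutout
#'
#' Takes a `size x size` cutout centered on the integer-rounded CR center
#' (edges replicated at image borders) and applies a black circular mask:
#' pixels farther than `mask_radius` from the cutout center (inclusive
#' boundary) are set to 0.
#'
#' @param image Image matrix in `[0, 1]`.
#' @param cr_center Numeric `c(x, y)`.
#' @param size Cutout side.
#' @param mask_radius Disk radius, pixels.
#' @return The masked cutout matrix.
#' @export
make_cr_cutout <- function(image, cr_center, size = 180, mask_radius = 32) {
  origin <- centered_origin(cr_center, size)
  cut <- crop_replicate(image, origin, size)
  local_center <- round(cr_center) - origin
  cut[!disk_mask(size, local_center, mask_radius)] <- 0
  cut
}

#' Masked pupil cutout
#'
#' Fits an ellipse to the binarized pupil blob, takes a `size x size` cutout
#' centered on the blob's center of mass, and sets pixels outside the
#' ellipse scaled by `mask_scale` to middle grey (128/255).
#'
#' @param image Image matrix in `[0, 1]`.
#' @param pupil_mask Logical matrix of the binarized pupil blob.
#' @param size Cutout side.
#' @param mask_scale Ellipse scale factor.
#' @return List with `cutout` (masked matrix), `center` (`c(x, y)` in the
#'   full image), and `ellipse` (the unscaled fit).
#' @export
make_pupil_cutout <- function(image, pupil_mask, size = 180,
                              mask_scale = 1.4) {
  boundary <- blob_boundary(pupil_mask)
  if (nrow(boundary) < 5) {
    rlang::abort("pupil blob too small for ellipse fit",
                 class = "eyeforge_error_fit")
  }
  ell <- fit_ellipse(boundary)
  center <- blob_centroid(pupil_mask)
  origin <- centered_origin(center, size)
  cut <- crop_replicate(image, origin, size)
  local_center <- ell$center - origin
  # soft_ellipse orients its *minor* axis along theta
  mask_ell <- soft_ellipse(local_center[1], local_center[2],
                           r_minor = mask_scale * ell$r_minor,
                           r_major = mask_scale * ell$r_major,
                           theta = ell$theta + pi / 2, L = 0, edge_width = 0)
  inside <- render_soft_ellipse(mask_ell, size, size) >= 0.5
  cut[!inside] <- 128 / 255
  list(cutout = cut, center = center, ellipse = ell)
}
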