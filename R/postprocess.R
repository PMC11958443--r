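# Inference-side post-processing: turning per-feature logit heatmaps into
# feature centers, selecting the two most confident CRs, flagging frames
# unsuitable for tracking, and the adaptive pupil-prior cutout strategy.

#' Locate the peak of each heatmap
#'
#' For each map the position of the global maximum and its logit value are
#' returned. Ties are broken by the smallest row (y) then smallest column
#' (x) index.
#'
#' @param heatmaps A matrix or list of matrices (optionally named by
#'   feature identity; unnamed maps are numbered `0, 1, ...`).
#' @return Tibble with columns `id`, `x`, `y`, `logit` (0-based pixel
#'   coordinates of the peak).
#' @export
extract_peaks <- function(heatmaps) {
  if (is.matrix(heatmaps)) heatmaps <- list(heatmaps)
  if (length(heatmaps) == 0) {
    rlang::abort("at least one heatmap required", class = "eyeforge_error_input")
  }
  ids <- names(heatmaps) %||% as.character(seq_along(heatmaps) - 1L)
  purrr::map2_dfr(heatmaps, ids, function(m, id) {
    if (length(m) == 0) {
      rlang::abort("empty heatmap", class = "eyeforge_error_input")
    }
    mx <- max(m)
    idx <- which(m == mx)
    rows <- (idx - 1L) %% nrow(m)
    cols <- (idx - 1L) %/% nrow(m)
    k <- order(rows, cols)[1]
    tibble::tibble(id = id, x = as.numeric(cols[k]), y = as.numeric(rows[k]),
                   logit = mx)
  })
}

#' Select the two most confident corneal reflections
#'
#' Chooses the two CR identities with the highest peak logit values across
#' the output heatmaps; selection is independent per frame. Ties are broken
#' by the lower identity index (row order of `peaks`).
#'
#' @param peaks Tibble from [extract_peaks()] restricted to CR maps.
#' @return The two selected rows of `peaks`, highest logit first.
#' @export
select_best_two <- function(peaks) {
  if (nrow(peaks) < 2) {
    rlang::abort("need at least two CR maps", class = "eyeforge_error_input")
  }
  ord <- order(-peaks$logit, seq_len(nrow(peaks)))
  peaks[ord[1:2], ]
}

#' Frame validity from CR peak logits
#'
#' A frame is excluded (e.g., blinks, cutouts that missed the pupil) when
#' fewer than two CR heatmaps have a maximum value greater than or equal to
#' one.
#'
#' @param peaks Tibble from [extract_peaks()] restricted to CR maps.
#' @return `TRUE` when the frame is usable.
#' @export
check_validity <- function(peaks) {
  sum(peaks$logit >= 1) >= 2
}

#' Pupil-prior detection
#'
#' Wraps an external pupil detector's output: a center estimate plus a
#' confidence in `[0, 1]` (0 indicating a poor ellipse outline).
#'
#' @param x,y Center, full-resolution pixels.
#' @param confidence Confidence in `[0, 1]`.
#' @return Object of class `eyeforge_pupil_prior`.
#' @export
pupil_prior <- function(x, y, confidence) {
  stopifnot(confidence >= 0, confidence <= 1)
  structure(list(center = c(x, y), confidence = confidence),
            class = "eyeforge_pupil_prior")
}

#' Read pupil-prior detections from a CSV file
#'
#' Adapter for detectors run offline; expects columns `filename`, `x`, `y`,
#' `confidence`.
#'
#' @param path CSV path.
#' @return Tibble of detections.
#' @export
read_pupil_priors <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Cutout geometry
#'
#' A fixed-size crop of the (downscaled) image: integer origin in the
#' downscaled frame, side length, and the downscale factor that maps
#' full-resolution coordinates into the downscaled frame.
#'
#' @param origin Integer `c(x, y)` of the cutout's top-left pixel in the
#'   downscaled frame.
#' @param size Side length, pixels.
#' @param factor Downscale factor (full-res coordinate = downscaled * factor).
#' @return Object of class `eyeforge_cutout`.
#' @export
cutout_spec <- function(origin, size, factor = 2) {
  structure(list(origin = as.integer(round(origin)), size = as.integer(size),
                 factor = factor),
            class = "eyeforge_cutout")
}

#' Map coordinates between the full-resolution and cutout-local frames
#'
#' @param spec An [cutout_spec()].
#' @param xy Numeric `c(x, y)`.
#' @return Transformed `c(x, y)`.
#' @export
cutout_to_local <- function(spec, xy) {
  xy / spec$factor - spec$origin
}

#' @rdname cutout_to_local
#' @export
cutout_to_global <- function(spec, xy) {
  (xy + spec$origin) * spec$factor
}

#' Downscale an image by an integer factor (block mean)
#'
#' @param image Numeric matrix.
#' @param factor Integer factor >= 1; edges are replicated to a multiple of
#'   the factor first.
#' @return The downscaled matrix.
#' @export
downscale_image <- function(image, factor = 2) {
  if (factor == 1) return(image)
  h <- nrow(image); w <- ncol(image)
  H <- ceiling(h / factor) * factor
  W <- ceiling(w / factor) * factor
  img <- image[pmin(seq_len(H), h), pmin(seq_len(W), w), drop = FALSE]
  blk <- matrix(0, H / factor, W / factor)
  for (dy in seq_len(factor)) {
    for (dx in seq_len(factor)) {
      blk <- blk + img[seq(dy, H, by = factor), seq(dx, W, by = factor)]
    }
  }
  blk / factor^2
}

# crop with edge-replication padding; origin is the 0-based (x, y) of the
# top-left pixel, which may lie outside the image
crop_replicate <- function(image, origin, size) {
  rows <- pmin(pmax(origin[2] + seq_len(size), 1), nrow(image))
  cols <- pmin(pmax(origin[1] + seq_len(size), 1), ncol(image))
  image[rows, cols, drop = FALSE]
}

centered_origin <- function(center, size) {
  as.integer(round(center) - floor(size / 2))
}

#' Adaptive pupil-prior cutout
#'
#' The image is downscaled by `factor` and a `size x size` cutout is taken
#' as model input. If the pupil prior's confidence is at least `threshold`,
#' the cutout is centered on the prior's center estimate; otherwise a naive
#' centered cutout is taken, `fallback_locator` (a first inference pass;
#' a function of the cutout matrix returning `list(pupil = c(x, y))` in
#' cutout-local coordinates, or `NULL` on failure) is run, and a second
#' cutout is centered on its pupil estimate.
#'
#' @param image Full-resolution image matrix.
#' @param prior An [pupil_prior()].
#' @param threshold Confidence gate in `[0, 1]`.
#' @param size Cutout side length in downscaled pixels.
#' @param fallback_locator Locator used on the fallback path.
#' @param factor Downscale factor.
#' @return List with `spec` ([cutout_spec()]), `image` (the cutout matrix),
#'   `path` (`"prior"` or `"fallback"`), and `valid` (`FALSE` when the
#'   fallback locator failed).
#' @export
adaptive_cutout <- function(image, prior, threshold, size,
                            fallback_locator = NULL, factor = 2) {
  stopifnot(threshold >= 0, threshold <= 1)
  ds <- downscale_image(image, factor)
  if (prior$confidence >= threshold) {
    spec <- cutout_spec(centered_origin(prior$center / factor, size), size,
                        factor)
    return(list(spec = spec, image = crop_replicate(ds, spec$origin, size),
                path = "prior", valid = TRUE))
  }
  naive_center <- c(ncol(ds) - 1, nrow(ds) - 1) / 2
  spec0 <- cutout_spec(centered_origin(naive_center, size), size, factor)
  cut0 <- crop_replicate(ds, spec0$origin, size)
  loc <- if (is.null(fallback_locator)) NULL else fallback_locator(cut0)
  if (is.null(loc) || is.null(loc$pupil)) {
    return(list(spec = spec0, image = cut0, path = "fallback", valid = FALSE))
  }
  center_ds <- loc$pupil + spec0$origin
  spec <- cutout_spec(centered_origin(center_ds, size), size, factor)
  list(spec = spec, image = crop_replicate(ds, spec$origin, size),
       path = "fallback", valid = TRUE)
}

#' Pupil center and ellipse from a segmentation probability map
#'
#' Binarizes the probability map at `threshold`, fills holes, labels
#' connected components, keeps blobs passing the shape and size criteria
#' (area within `area`, moment-ellipse axis ratio at most `max_axis_ratio`),
#' selects the largest qualifying blob, and returns its binary center of
#' mass together with a least-squares ellipse fit to the blob boundary.
#'
#' @param prob_map Matrix with values in `[0, 1]`.
#' @param threshold Binarization threshold.
#' @param area Length-2 numeric, admissible blob area in px^2.
#' @param max_axis_ratio Maximum major/minor moment-axis ratio.
#' @return `NULL` when no blob survives; otherwise a list with `center`
#'   (`c(x, y)`, 0-based), `ellipse` (see [fit_ellipse()]), and `mask`
#'   (logical matrix of the selected blob).
#' @export
prob_map_to_pupil <- function(prob_map, threshold = 0.99,
                              area = c(25, 10000), max_axis_ratio = 3) {
  bw <- prob_map >= threshold
  if (!any(bw)) return(NULL)
  bw <- fill_holes(bw)
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(lab), nrow = nrow(bw))
  best <- select_blob(lab, area, max_axis_ratio)
  if (is.null(best)) return(NULL)
  mask <- lab == best
  list(center = blob_centroid(mask), ellipse = fit_ellipse(blob_boundary(mask)),
       mask = mask)
}

fill_holes <- function(bw) {
  out <- EBImage::fillHull(EBImage::Image(bw * 1))
  matrix(as.numeric(out), nrow = nrow(bw)) > 0.5
}

# largest blob whose area and moment axis ratio pass the criteria
select_blob <- function(lab, area, max_axis_ratio) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0) return(NULL)
  best <- NULL
  best_area <- -Inf
  for (id in ids) {
    mask <- lab == id
    a <- sum(mask)
    if (a < area[1] || a > area[2]) next
    if (a >= 3) {
      ratio <- moment_axis_ratio(mask)
      if (is.finite(ratio) && ratio > max_axis_ratio) next
    }
    if (a > best_area) { best <- id; best_area <- a }
  }
  best
}

blob_centroid <- function(mask) {
  idx <- which(mask)
  y <- (idx - 1L) %% nrow(mask)
  x <- (idx - 1L) %/% nrow(mask)
  c(mean(x), mean(y))
}

moment_axis_ratio <- function(mask) {
  idx <- which(mask)
  y <- (idx - 1L) %% nrow(mask)
  x <- (idx - 1L) %/% nrow(mask)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) return(Inf)
  sqrt(ev[1] / ev[2])
}

# boundary pixels: blob pixels with at least one 4-neighbor outside
blob_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  idx <- which(mask & !inner)
  tibble::tibble(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

#' Least-squares ellipse fit
#'
#' Direct least-squares fit of a conic constrained to an ellipse
#' (Fitzgibbon's method) to a set of boundary points.
#'
#' @param pts Tibble or data frame with columns `x`, `y` (>= 5 points).
#' @return List with `center` (`c(x, y)`), `r_major`, `r_minor`, `theta`
#'   (major-axis angle, radians).
#' @export
fit_ellipse <- function(pts) {
  if (nrow(pts) < 5) {
    rlang::abort("ellipse fit needs at least 5 boundary points",
                 class = "eyeforge_error_fit")
  }
  x <- pts$x - mean(pts$x)
  y <- pts$y - mean(pts$y)
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # pick the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  k <- which(cond > 0)[1]
  if (is.na(k)) {
    rlang::abort("degenerate boundary: no ellipse solution",
                 class = "eyeforge_error_fit")
  }
  a1 <- Re(ev$vectors[, k])
  coefs <- c(a1, Tm %*% a1)  # A B C D E F on centered coords
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C  # negative for an ellipse
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # centered conic: A u^2 + B uv + C v^2 = -G0; principal axes from the
  # eigendecomposition of the quadratic form
  G0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  radii <- sqrt(-G0 / eq$values)
  k <- which.max(radii)  # conic scale sign is arbitrary; pick by radius
  list(center = c(cx + mean(pts$x), cy + mean(pts$y)),
       r_major = max(radii), r_minor = min(radii),
       theta = atan2(eq$vectors[2, k], eq$vectors[1, k]))
}

#' Re-center a cutout whose pupil sits too close to the edge
#'
#' When the estimated pupil center lies strictly closer than the fitted
#' ellipse's major-axis radius to any edge of the cutout, the cutout is
#' re-centered on the estimate (a single pass); otherwise it is returned
#' unchanged.
#'
#' @param cutout An [cutout_spec()].
#' @param center Pupil center in cutout-local coordinates.
#' @param ellipse Ellipse fit (list with `r_major`).
#' @return A (possibly re-centered) [cutout_spec()].
#' @export
recenter_if_near_edge <- function(cutout, center, ellipse) {
  edge_dist <- min(center[1], cutout$size - 1 - center[1],
                   center[2], cutout$size - 1 - center[2])
  if (edge_dist < ellipse$r_major) {
    cutout_spec(centered_origin(center + cutout$origin, cutout$size),
                cutout$size, cutout$factor)
  } else {
    cutout
  }
}
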