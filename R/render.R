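# Rendering primitives. Images are height x width numeric matrices; row i,
# col j holds the pixel with 0-based coordinates (x = j - 1, y = i - 1).
# Intermediate fields live on the 8-bit scale [0, 255]; the final rendered
# image is scaled to [0, 1] and discretized to the 256 levels k/255.

grid_xy <- function(width, height) {
  list(
    x = matrix(rep(seq_len(width) - 1, each = height), nrow = height),
    y = matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  )
}

#' Evaluate the unclipped Gaussian field of a feature
#'
#' Computes `A * exp(-a dx^2 - b dx dy - c dy^2)` over the canvas, with the
#' quadratic-form coefficients derived from the orientation and the spreads
#' along the minor and major axes (themselves derived from the plateau radii
#' via [plateau_sigma()]). No clipping is applied; the value exceeds 1
#' inside the plateau and equals exactly 1 on the plateau ellipse.
#'
#' @param feature A [gaussian_feature()].
#' @param width,height Canvas extent in pixels.
#' @param x,y Optional explicit evaluation points (vectors or matrices);
#'   when supplied the canvas extent is ignored.
#' @return Matrix (or vector matching `x`) of unclipped field values.
#' @export
eval_gaussian_field <- function(feature, width = NULL, height = NULL,
                                x = NULL, y = NULL) {
  if (is.null(x)) {
    g <- grid_xy(width, height)
    x <- g$x
    y <- g$y
  }
  s_a <- plateau_sigma(feature$r_minor, feature$A)
  s_b <- plateau_sigma(feature$r_major, feature$A)
  th <- feature$theta
  a <- cos(th)^2 / (2 * s_a^2) + sin(th)^2 / (2 * s_b^2)
  b <- sin(2 * th) / (4 * s_a^2) - sin(2 * th) / (4 * s_b^2)
  cc <- sin(th)^2 / (2 * s_a^2) + cos(th)^2 / (2 * s_b^2)
  dx <- x - feature$x
  dy <- y - feature$y
  # quadratic form a dx^2 + 2b dx dy + c dy^2: the factor 2 on the cross
  # term makes the form an exact rotation of the axis-aligned Gaussian, so
  # the plateau identity holds along the principal axes at any orientation
  feature$A * exp(-a * dx^2 - 2 * b * dx * dy - cc * dy^2)
}

#' Raised-cosine blend field of a soft-edged ellipse
#'
#' The coefficient is 1 strictly inside the ellipse and 0 outside the
#' ellipse grown by `edge_width`. Across the band the coefficient follows
#' `(1 + cos(pi * t)) / 2` where `t` in `[0, 1]` parameterizes the radial
#' position between the inner and outer ellipse along each ray from the
#' center, so it decreases monotonically outward.
#'
#' @param e A [soft_ellipse()].
#' @inheritParams eval_gaussian_field
#' @return Matrix of blend coefficients in `[0, 1]`.
#' @export
render_soft_ellipse <- function(e, width = NULL, height = NULL,
                                x = NULL, y = NULL) {
  if (is.null(x)) {
    g <- grid_xy(width, height)
    x <- g$x
    y <- g$y
  }
  dx <- x - e$x
  dy <- y - e$y
  # canonical frame: minor axis along x' (consistent with eval_gaussian_field)
  xp <- cos(e$theta) * dx + sin(e$theta) * dy
  yp <- -sin(e$theta) * dx + cos(e$theta) * dy
  rho <- sqrt(xp^2 + yp^2)
  psi <- atan2(yp, xp)
  r_in <- ray_radius(psi, e$r_minor, e$r_major)
  if (e$edge_width == 0) {
    coef <- ifelse(rho <= r_in, 1, 0)
  } else {
    r_out <- ray_radius(psi, e$r_minor + e$edge_width,
                        e$r_major + e$edge_width)
    t <- (rho - r_in) / (r_out - r_in)
    t <- pmin(pmax(t, 0), 1)
    coef <- (1 + cos(pi * t)) / 2
  }
  coef
}

# radius of the ellipse with semi-axes (a along x', b along y') in direction psi
ray_radius <- function(psi, a, b) {
  1 / sqrt((cos(psi) / a)^2 + (sin(psi) / b)^2)
}

#' Sample a concrete collarette outline
#'
#' Places the base vertices at equal angles (with a random phase) around the
#' center at distance `r_col` plus a per-vertex radial offset whose magnitude
#' is drawn uniformly from `[jitter_lo, jitter_hi] * r_col` with random sign,
#' then upsamples the closed polygon to five times the number of vertices
#' with periodic cubic spline interpolation.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param poly A [collarette_polygon()].
#' @return Object of class `eyeforge_collarette_outline`: the polygon with a
#'   realized `outline` tibble (`x`, `y`; `5 * n_vertices` points, first and
#'   last coinciding).
#' @export
realize_collarette <- function(poly) {
  n <- poly$n_vertices
  phase <- stats::runif(1, 0, 2 * pi)
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  mag <- stats::runif(n, poly$jitter_lo, poly$jitter_hi) * poly$r_col
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  r <- poly$r_col + sgn * mag
  vx <- poly$x + r * cos(ang)
  vy <- poly$y + r * sin(ang)
  # closed periodic spline through the vertices, sampled at 5n points
  # (endpoints coincide: the curve closes on itself)
  t0 <- seq_len(n + 1) - 1
  ts <- seq(0, n, length.out = 5L * n)
  sx <- stats::spline(t0, c(vx, vx[1]), method = "periodic", xout = ts)$y
  sy <- stats::spline(t0, c(vy, vy[1]), method = "periodic", xout = ts)$y
  out <- poly
  out$vertices <- tibble::tibble(x = vx, y = vy)
  out$outline <- tibble::tibble(x = sx, y = sy)
  class(out) <- c("eyeforge_collarette_outline", class(poly))
  out
}

#' Blend field of a realized collarette
#'
#' Fills the interior of the spline outline at coefficient 1 with a
#' raised-cosine edge of width `edge_width` extending outward. The outline
#' is star-shaped about its center (vertex jitter is at most a fraction of
#' `r_col`), so the boundary radius is interpolated as a periodic function
#' of the polar angle.
#'
#' @param outline A realized collarette from [realize_collarette()].
#' @inheritParams eval_gaussian_field
#' @return Matrix of blend coefficients in `[0, 1]`.
#' @export
render_collarette <- function(outline, width = NULL, height = NULL,
                              x = NULL, y = NULL) {
  stopifnot(inherits(outline, "eyeforge_collarette_outline"))
  if (is.null(x)) {
    g <- grid_xy(width, height)
    x <- g$x
    y <- g$y
  }
  ox <- outline$outline$x - outline$x
  oy <- outline$outline$y - outline$y
  oang <- atan2(oy, ox)
  orad <- sqrt(ox^2 + oy^2)
  ord <- order(oang)
  oang <- oang[ord]
  orad <- orad[ord]
  # periodic extension for interpolation across the -pi/pi wrap
  ang_ext <- c(oang[length(oang)] - 2 * pi, oang, oang[1] + 2 * pi)
  rad_ext <- c(orad[length(orad)], orad, orad[1])
  dx <- x - outline$x
  dy <- y - outline$y
  rho <- sqrt(dx^2 + dy^2)
  psi <- atan2(dy, dx)
  r_b <- stats::approx(ang_ext, rad_ext, xout = as.vector(psi),
                       ties = mean)$y
  r_b <- matrix(r_b, nrow = nrow(rho))
  if (outline$edge_width == 0) {
    coef <- ifelse(rho <= r_b, 1, 0)
  } else {
    t <- (rho - r_b) / outline$edge_width
    t <- pmin(pmax(t, 0), 1)
    coef <- (1 + cos(pi * t)) / 2
  }
  coef
}

#' Evaluate a background model over the canvas
#'
#' @param bg A background object (see [backgrounds]).
#' @param width,height Canvas extent.
#' @return Luminance field matrix on the 8-bit scale.
#' @export
eval_background <- function(bg, width, height) {
  g <- grid_xy(width, height)
  switch(bg$kind,
    uniform = matrix(bg$L, nrow = height, ncol = width),
    split_line = {
      # signed distance to the line through (x, y) with direction `angle`;
      # the positive side (left of the direction) is the light side
      s <- -sin(bg$angle) * (g$x - bg$x) + cos(bg$angle) * (g$y - bg$y)
      ifelse(s < 0, bg$L_dark, bg$L_light)
    },
    gradient = {
      p <- cos(bg$angle) * g$x + sin(bg$angle) * g$y
      t <- (p - min(p)) / max(max(p) - min(p), .Machine$double.eps)
      bg$L_from + t * (bg$L_to - bg$L_from)
    },
    rlang::abort(paste0("unknown background kind: ", bg$kind))
  )
}

#' Add i.i.d. Gaussian pixel noise
#'
#' Adds a value drawn independently per pixel from `N(0, sigma_n^2)` on the
#' 8-bit scale. Deterministic given `seed`.
#'
#' @param image Numeric matrix on the 8-bit scale.
#' @param sigma_n Noise standard deviation, >= 0.
#' @param seed Optional integer seed for the noise draw.
#' @return The perturbed image (unclipped).
#' @export
add_pixel_noise <- function(image, sigma_n, seed = NULL) {
  if (sigma_n < 0) {
    rlang::abort("`sigma_n` must be >= 0", class = "eyeforge_error_noise")
  }
  if (sigma_n == 0) return(image)
  draw <- function() {
    image + matrix(stats::rnorm(length(image), 0, sigma_n),
                   nrow = nrow(image))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# round half away from zero to the nearest of the 256 levels k/255;
# input on the 8-bit scale, already clipped to [0, 255]
quantize_255 <- function(image) {
  floor(image + 0.5) / 255
}

#' Render a scene to an 8-bit image
#'
#' Evaluates the background, composites each layer in order, adds pixel
#' noise, clips to `[0, 255]`, scales to `[0, 1]` and discretizes to 256
#' levels. Dark Gaussian features blend the running image toward their
#' plateau luminance by the clipped field `c = min(field, 1)`
#' (`image <- image - (image - L) * c`), so the plateau luminance equals `L`
#' regardless of background; bright features apply
#' `image <- max(image, L * c)`. Soft ellipses and collarettes blend toward
#' their luminance by their raised-cosine coefficient.
#'
#' @param spec A [scene_spec()].
#' @param seed Optional integer seed for the pixel noise; with a fixed seed
#'   rendering is bit-identical across calls.
#' @return Matrix of class `eyeforge_image` with values restricted to the
#'   256 levels `k/255`.
#' @export
compose_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "eyeforge_scene"))
  if (spec$width < 1 || spec$height < 1) {
    rlang::abort("empty canvas", class = "eyeforge_error_canvas")
  }
  img <- eval_background(spec$background, spec$width, spec$height)
  for (layer in spec$layers) {
    if (inherits(layer, "eyeforge_gaussian")) {
      cf <- pmin(eval_gaussian_field(layer, spec$width, spec$height), 1)
      if (layer$polarity == "dark") {
        img <- img - (img - layer$L) * cf
      } else {
        img <- pmax(img, layer$L * cf)
      }
    } else if (inherits(layer, "eyeforge_collarette_outline")) {
      cf <- render_collarette(layer, spec$width, spec$height)
      img <- img - (img - layer$L) * cf
    } else if (inherits(layer, "eyeforge_ellipse")) {
      cf <- render_soft_ellipse(layer, spec$width, spec$height)
      img <- img - (img - layer$L) * cf
    } else if (inherits(layer, "eyeforge_collarette")) {
      rlang::abort("collarette layer must be realized with realize_collarette() before rendering")
    } else {
      rlang::abort("unknown layer type")
    }
  }
  img <- add_pixel_noise(img, spec$sigma_n, seed = seed)
  img <- pmin(pmax(img, 0), 255)
  out <- quantize_255(img)
  class(out) <- c("eyeforge_image", class(out))
  out
}
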