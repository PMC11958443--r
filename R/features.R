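#' Blob-like eye features as 2D Gaussians
#'
#' A pupil or corneal reflection (CR) is modelled as an anisotropic 2D
#' Gaussian with a luminance plateau: the amplitude `A` controls how steep
#' the edge of the feature is, while the plateau radii `r_minor`, `r_major`
#' stay fixed because the spreads are parameterized as
#' `sigma = r / sqrt(2 * log(A))`. The continuous field therefore equals
#' exactly 1 at distance `r_minor` (resp. `r_major`) from the center along
#' the principal axes, and values above 1 are clipped to form the plateau.
#'
#' Coordinates are 0-based pixel indices: a pixel's sample point is its
#' center at integer coordinates, `x` grows rightward (columns), `y` grows
#' downward (rows). `theta` is measured from the +x axis toward +y and is
#' the orientation of the minor axis (at `theta = 0` the minor axis lies
#' along x).
#'
#' @param x,y Feature center in pixels (continuous, 0-based).
#' @param r_minor,r_major Plateau radii in pixels; `r_major >= r_minor > 0`.
#' @param A Gaussian amplitude, strictly greater than 1.
#' @param theta Orientation in radians.
#' @param L Plateau luminance on the 8-bit scale, in `[0, 255]`.
#' @param polarity `"bright"` features are max-composited onto the image;
#'   `"dark"` features blend the image toward `L`.
#' @return An object of class `eyeforge_gaussian`.
#' @examples
#' cr <- gaussian_feature(32, 32, r_minor = 4, A = 100, L = 255,
#'                        polarity = "bright")
#' @export
gaussian_feature <- function(x, y, r_minor, r_major = r_minor, A,
                             theta = 0, L, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!is.finite(A) || A <= 1) {
    rlang::abort("amplitude `A` must be > 1 (plateau undefined otherwise)",
                 class = "eyeforge_error_amplitude")
  }
  stopifnot(r_minor > 0, r_major >= r_minor, L >= 0, L <= 255)
  structure(
    list(x = x, y = y, r_minor = r_minor, r_major = r_major, A = A,
         theta = theta, L = L, polarity = polarity),
    class = "eyeforge_gaussian"
  )
}

#' Gaussian spread from plateau radius and amplitude
#'
#' Inverts the plateau construction: the spread for which a Gaussian of
#' amplitude `A` passes through 1 at distance `r` from its center,
#' `sigma = r / sqrt(-2 * log(1 / A)) = r / sqrt(2 * log(A))`.
#'
#' @param r Plateau radius in pixels, `> 0`.
#' @param A Amplitude, `> 1`.
#' @return Spread in pixels.
#' @examples
#' plateau_sigma(4, exp(2))  # 2
#' @export
plateau_sigma <- function(r, A) {
  if (any(!is.finite(A)) || any(A <= 1)) {
    rlang::abort("amplitude `A` must be > 1", class = "eyeforge_error_amplitude")
  }
  stopifnot(all(r > 0))
  r / sqrt(2 * log(A))
}

#' Soft-edged ellipse layer
#'
#' An elliptical region of uniform luminance whose edge is modulated by a
#' raised cosine: the blend coefficient is 1 strictly inside the ellipse,
#' 0 outside the ellipse grown by `edge_width`, and follows
#' `(1 + cos(pi * t)) / 2` across the band, with `t` the position along the
#' outward direction parameterized by elliptical radius. Used for the iris.
#'
#' @inheritParams gaussian_feature
#' @param edge_width Width of the raised-cosine transition band, pixels >= 0.
#' @return An object of class `eyeforge_ellipse`.
#' @export
soft_ellipse <- function(x, y, r_minor, r_major = r_minor, theta = 0, L,
                         edge_width = 0) {
  stopifnot(r_minor > 0, r_major >= r_minor, edge_width >= 0)
  structure(
    list(x = x, y = y, r_minor = r_minor, r_major = r_major, theta = theta,
         L = L, edge_width = edge_width),
    class = "eyeforge_ellipse"
  )
}

#' Irregular collarette polygon
#'
#' The collarette is modelled as a jittered polygon around a center: base
#' vertices at mean distance `r_col`, each radially displaced by a fraction
#' of `r_col` drawn from `[jitter_lo, jitter_hi]` (random sign), joined by a
#' closed periodic cubic spline upsampled to five times the number of
#' vertices, and filled at luminance `L` with a raised-cosine edge.
#'
#' Vertex jitter is random: call [realize_collarette()] to sample a concrete
#' outline before rendering.
#'
#' @inheritParams soft_ellipse
#' @param n_vertices Number of base vertices, >= 3.
#' @param r_col Mean vertex distance from the center, pixels > 0.
#' @param jitter_lo,jitter_hi Per-vertex radial jitter fractions of `r_col`.
#' @return An object of class `eyeforge_collarette`.
#' @export
collarette_polygon <- function(x, y, n_vertices, r_col,
                               jitter_lo = 0.05, jitter_hi = 0.2,
                               L, edge_width = 0) {
  if (r_col <= 0) rlang::abort("`r_col` must be > 0", class = "eyeforge_error_geometry")
  stopifnot(n_vertices >= 3, jitter_hi >= jitter_lo, jitter_lo >= 0)
  structure(
    list(x = x, y = y, n_vertices = as.integer(n_vertices), r_col = r_col,
         jitter_lo = jitter_lo, jitter_hi = jitter_hi, L = L,
         edge_width = edge_width),
    class = "eyeforge_collarette"
  )
}

#' Background luminance models
#'
#' Backgrounds evaluate to a full-canvas luminance field on the 8-bit scale.
#' `bg_uniform` is a flat field; `bg_split_line` divides the canvas by a
#' straight line (the pupil-iris border) into a dark and a light side;
#' `bg_gradient` varies luminance linearly between two values along a
#' random axis across the canvas extent.
#'
#' @param L,L_dark,L_light,L_from,L_to Luminances on the 8-bit scale.
#' @param x,y A point on the dividing line (0-based pixels).
#' @param angle Orientation of the dividing line / gradient axis, radians.
#' @return A background object.
#' @name backgrounds
NULL

#' @rdname backgrounds
#' @export
bg_uniform <- function(L) {
  structure(list(kind = "uniform", L = L), class = "eyeforge_background")
}

#' @rdname backgrounds
#' @export
bg_split_line <- function(x, y, angle, L_dark, L_light) {
  structure(list(kind = "split_line", x = x, y = y, angle = angle,
                 L_dark = L_dark, L_light = L_light),
            class = "eyeforge_background")
}

#' @rdname backgrounds
#' @export
bg_gradient <- function(L_from, L_to, angle) {
  structure(list(kind = "gradient", L_from = L_from, L_to = L_to,
                 angle = angle),
            class = "eyeforge_background")
}

#' Scene description
#'
#' A full synthetic image: a background model, an ordered list of feature
#' layers (composited first to last), and the pixel-noise level. Rendering a
#' scene with [compose_scene()] is a pure function of the scene and an
#' explicit noise seed.
#'
#' @param width,height Canvas size in pixels.
#' @param background A background object (see [backgrounds]).
#' @param layers List of features ([gaussian_feature()], [soft_ellipse()],
#'   realized collarettes).
#' @param sigma_n Standard deviation of i.i.d. per-pixel Gaussian noise on
#'   the 8-bit scale, >= 0.
#' @return An object of class `eyeforge_scene`.
#' @export
scene_spec <- function(width, height, background, layers = list(),
                       sigma_n = 0) {
  stopifnot(width >= 1, height >= 1, sigma_n >= 0,
            inherits(background, "eyeforge_background"))
  structure(
    list(width = as.integer(width), height = as.integer(height),
         background = background, layers = layers, sigma_n = sigma_n),
    class = "eyeforge_scene"
  )
}
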