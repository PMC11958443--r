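# Generators emulating eye images from VR headsets: full-eye segmentation
# scenes (sclera, iris, collarette, pupil, CRs), and two illuminator
# constellations whose CRs must be localized *and* identified — a five-light
# house-shaped polygon and an eight-light octagon — with per-CR dropout and
# spurious reflections.

rnorm_clip <- function(mean, sd, lo = 0, hi = 255) {
  min(max(stats::rnorm(1, mean, sd), lo), hi)
}

#' Configuration for the full-eye segmentation pipeline
#'
#' Scenes are composed sclera -> iris (raised-cosine edge) -> collarette ->
#' pupil -> CRs. The pupil plateau is constrained to lie fully inside the
#' iris interior so scenes stay coherent. Labels include the pupil center, a
#' binary pupil mask (pixels where the pupil blend coefficient is at least
#' 0.5) and CR centers.
#'
#' @param size Canvas side, pixels (defaults to the 192-pixel inference
#'   cutout).
#' @param L_s_mean,L_s_sd Sclera luminance, Normal.
#' @param r_i Iris minor plateau-radius range; major is minor times a factor
#'   in `major_factor_i`; `L_i_mean`, `L_i_sd` give its Normal luminance and
#'   `iris_edge` its raised-cosine edge-width range.
#' @param n_vert_col Collarette vertex-count range (integers); `r_col_frac`
#'   scales the iris major radius to the mean vertex distance; `L_col_frac`
#'   scales the iris luminance; `col_edge` is the edge-width range.
#' @param r_p,major_factor_p,A_p,L_p_mean,L_p_sd Pupil shape and luminance.
#' @param n_cr,r_c,major_factor_c,A_c CR count and shape ranges.
#' @param sigma_n Pixel-noise SD range.
#' @return Object of class `eyeforge_cfg_eds2019`.
#' @export
eds2019_config <- function(size = 192,
                           L_s_mean = 217, L_s_sd = 26,
                           r_i = c(30, 42.5), major_factor_i = c(1, 1.3),
                           L_i_mean = 77, L_i_sd = 16, iris_edge = c(8, 20),
                           n_vert_col = c(13, 24), r_col_frac = c(0.3, 0.6),
                           L_col_frac = c(1.25, 1.6), col_edge = c(1, 4),
                           r_p = c(10, 30), major_factor_p = c(1, 1.3),
                           A_p = c(2, 2000), L_p_mean = 34, L_p_sd = 15,
                           n_cr = c(1, 8), r_c = c(0.8, 4),
                           major_factor_c = c(1, 1.4), A_c = c(2, 20000),
                           sigma_n = c(0, 15)) {
  structure(as.list(environment()),
            class = c("eyeforge_cfg_eds2019", "eyeforge_cfg"))
}

#' @export
gen_scene.eyeforge_cfg_eds2019 <- function(cfg, render = TRUE) {
  size <- cfg$size
  # iris: randomly positioned/oriented, kept fully in-canvas (incl. edge)
  a_i <- runif_range(cfg$r_i)
  b_i <- a_i * runif_range(cfg$major_factor_i)
  edge_i <- runif_range(cfg$iris_edge)
  margin <- b_i + edge_i
  if (size - 1 < 2 * margin) {
    rlang::abort("canvas too small to contain the iris and its edge band",
                 class = "eyeforge_error_usage")
  }
  icx <- stats::runif(1, margin, size - 1 - margin)
  icy <- stats::runif(1, margin, size - 1 - margin)
  L_i <- rnorm_clip(cfg$L_i_mean, cfg$L_i_sd)
  iris <- soft_ellipse(icx, icy, r_minor = a_i, r_major = b_i,
                       theta = stats::runif(1, 0, 2 * pi), L = L_i,
                       edge_width = edge_i)
  # collarette on the iris, centered on the iris center
  r_col <- runif_range(cfg$r_col_frac) * b_i
  col <- collarette_polygon(icx, icy,
                            n_vertices = sample(cfg$n_vert_col[1]:cfg$n_vert_col[2], 1),
                            r_col = r_col, L = runif_range(cfg$L_col_frac) * L_i,
                            edge_width = runif_range(cfg$col_edge))
  col <- realize_collarette(col)
  # pupil: plateau fully inside the iris interior (rejection on offset+shape)
  pupil <- NULL
  for (attempt in 1:1000) {
    a_p <- runif_range(cfg$r_p)
    b_p <- a_p * runif_range(cfg$major_factor_p)
    off_r <- stats::runif(1, 0, a_i)
    off_a <- stats::runif(1, 0, 2 * pi)
    pcx <- icx + off_r * cos(off_a)
    pcy <- icy + off_r * sin(off_a)
    if (off_r + b_p <= a_i) {
      pupil <- gaussian_feature(pcx, pcy, r_minor = a_p, r_major = b_p,
                                A = rlogunif_range(cfg$A_p),
                                L = rnorm_clip(cfg$L_p_mean, cfg$L_p_sd),
                                theta = stats::runif(1, 0, 2 * pi),
                                polarity = "dark")
      break
    }
  }
  if (is.null(pupil)) {
    rlang::abort("could not place pupil inside iris",
                 class = "eyeforge_error_placement")
  }
  n_cr <- sample(cfg$n_cr[1]:cfg$n_cr[2], 1)
  crs <- sample_nonoverlapping_crs(n_cr, cfg$r_c, cfg$major_factor_c,
                                   cfg$A_c, size, size)
  L_s <- rnorm_clip(cfg$L_s_mean, cfg$L_s_sd)
  sigma_n <- runif_range(cfg$sigma_n)
  spec <- scene_spec(size, size, bg_uniform(L_s),
                     c(list(iris, col, pupil), crs), sigma_n)
  img <- if (render) compose_scene(spec) else NULL
  mask <- eval_gaussian_field(pupil, size, size) >= 0.5
  li <- labeled_image(
    img, pupil = c(pupil$x, pupil$y),
    crs = tibble::tibble(id = seq_along(crs) - 1L,
                         x = purrr::map_dbl(crs, "x"),
                         y = purrr::map_dbl(crs, "y"),
                         absent = FALSE),
    masks = list(pupil = mask), scene = spec, width = size, height = size
  )
  li$info <- list(L_s = L_s, L_i = L_i, iris = iris, collarette = col,
                  pupil = pupil, sigma_n = sigma_n, r_col = r_col)
  li
}

#' Five-light house constellation
#'
#' The five IR lights project to a house-shaped polygon: a rectangle of
#' width `w` and height `h` with an additional roof vertex a height `h_r`
#' above the middle of its top edge; the separation of the two bottom
#' vertices is scaled by `f_b`. Vertices are ordered starting from the
#' topmost position and moving clockwise (apex, top-right, bottom-right,
#' bottom-left, top-left), rotated by `phi` about the vertex centroid and
#' translated so the centroid sits at `center`. Remember y grows downward.
#'
#' @param w Rectangle width, pixels.
#' @param f_b Bottom-width scaling factor.
#' @param h Rectangle height, pixels.
#' @param h_r Roof height above the top edge, pixels.
#' @param phi Rotation, degrees.
#' @param center Numeric `c(x, y)` centroid position.
#' @return Tibble with columns `id` (0-4), `x`, `y`.
#' @export
build_house_constellation <- function(w, f_b, h, h_r, phi = 0,
                                      center = c(0, 0)) {
  if (w <= 0 || h <= 0 || h_r <= 0 || f_b <= 0 || f_b > 1) {
    rlang::abort("invalid house dimensions", class = "eyeforge_error_geometry")
  }
  vx <- c(0, w / 2, f_b * w / 2, -f_b * w / 2, -w / 2)
  vy <- c(-h / 2 - h_r, -h / 2, h / 2, h / 2, -h / 2)
  rotate_to(vx, vy, phi, center)
}

#' Eight-light octagon constellation
#'
#' Regular octagon of circumradius `m`, first vertex in the bottom-right
#' octant, clockwise order (y grows downward, so clockwise on screen means
#' increasing polar angle), rotated by `phi` about the center.
#'
#' @param m Circumradius, pixels > 0.
#' @param phi Rotation, degrees.
#' @param center Numeric `c(x, y)`.
#' @return Tibble with columns `id` (0-7), `x`, `y`.
#' @export
build_octagon_constellation <- function(m, phi = 0, center = c(0, 0)) {
  if (m <= 0) rlang::abort("`m` must be > 0", class = "eyeforge_error_geometry")
  ang <- (67.5 + 45 * (0:7)) * pi / 180
  rotate_to(m * cos(ang), m * sin(ang), phi, center)
}

# rotate about the vertex centroid, then translate the layout origin to
# `center` (the unrotated layout is expressed relative to that origin)
rotate_to <- function(vx, vy, phi_deg, center) {
  cx <- mean(vx); cy <- mean(vy)
  phi <- phi_deg * pi / 180
  dx <- vx - cx; dy <- vy - cy
  tibble::tibble(
    id = seq_along(vx) - 1L,
    x = center[1] + cx + cos(phi) * dx - sin(phi) * dy,
    y = center[2] + cy + sin(phi) * dx + cos(phi) * dy
  )
}

#' Sample spurious (non-illuminator) reflections
#'
#' Draws a count uniformly from `n_range` and places each reflection by
#' rejection sampling with the inverted pupil Gaussian: a uniform candidate
#' position is accepted with probability `1 - min(G_pupil(x, y), 1)`, so
#' spurious reflections rarely appear near the pupil center (never inside
#' its plateau).
#'
#' @param n_range Integer range of counts (inclusive).
#' @param pupil The pupil [gaussian_feature()].
#' @param width,height Canvas size.
#' @param r_minor Minor radius range; major is minor times a factor in
#'   `major_factor`; `A` is the amplitude range (log-uniform).
#' @param major_factor,A Shape ranges.
#' @param max_attempts Rejection cap per reflection.
#' @return List of bright [gaussian_feature()].
#' @export
sample_spurious <- function(n_range, pupil, width, height,
                            r_minor = c(1, 2.5), major_factor = c(1, 2.5),
                            A = c(200, 100000), max_attempts = 1000) {
  n <- sample(n_range[1]:n_range[2], 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      x <- stats::runif(1, 0, width - 1)
      y <- stats::runif(1, 0, height - 1)
      g <- min(eval_gaussian_field(pupil, x = x, y = y), 1)
      if (stats::runif(1) < 1 - g) {
        rm <- runif_range(r_minor)
        out[[i]] <- gaussian_feature(x, y, r_minor = rm,
                                     r_major = rm * runif_range(major_factor),
                                     A = rlogunif_range(A), L = 255,
                                     theta = stats::runif(1, 0, 2 * pi),
                                     polarity = "bright")
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort("could not place spurious reflection",
                   class = "eyeforge_error_placement")
    }
  }
  out
}

#' Configurations for the constellation pipelines
#'
#' Both pipelines render 128 x 128 scenes with a linear-gradient background
#' (two luminances drawn from `[63, 178]`, random axis), a dark pupil, a CR
#' constellation close to the pupil with independent per-CR dropout, and
#' spurious reflections. The house pipeline uses a five-light constellation
#' (dropout 16%, rotation up to +/-45 degrees in stage 1; 10% and +/-35
#' degrees with at most 3 spurious reflections in stage 2). The octagon
#' pipeline uses eight lights, dropout 20%, rotation up to +/-0.57 degrees,
#' and a Weibull pupil luminance (shape 2, scale 25, offset 18).
#'
#' @param stage Training stage, 1 or 2.
#' @param size Canvas side `d`, pixels.
#' @param n_vertices Octagon vertex count (exposed because the source
#'   datasets differ in how many lights are visible).
#' @return A configuration object.
#' @name constellation_configs
NULL

#' @rdname constellation_configs
#' @export
chugh_config <- function(stage = 1, size = 128) {
  stopifnot(stage %in% c(1, 2))
  d <- size
  structure(
    list(stage = stage, size = as.integer(size),
         r_p = c(6, 22.5), major_factor_p = c(1, 1.3), A_p = c(200, 100000),
         w_frac = c(0.1, 0.45), f_b = c(0.05, 0.2), h_frac = c(0.5, 0.6),
         h_r_frac = c(0.2, 0.5),
         phi_max = if (stage == 2) 35 else 45,
         dropout = if (stage == 2) 0.10 else 0.16,
         n_spur = if (stage == 2) c(1, 3) else c(1, 5),
         r_c = c(1, 2.5), major_factor_c = c(1, 1.1), A_c = c(200, 100000),
         L_i = c(63, 178), sigma_n = c(0, 30),
         center_sd = 0.05 * d, pupil_frac = c(0.3, 0.7),
         constellation = "house"),
    class = c("eyeforge_cfg_chugh", "eyeforge_cfg_constellation",
              "eyeforge_cfg")
  )
}

#' @rdname constellation_configs
#' @export
eds2020_config <- function(stage = 1, size = 128, n_vertices = 8) {
  cfg <- chugh_config(stage = stage, size = size)
  cfg$constellation <- "octagon"
  cfg$n_vertices <- as.integer(n_vertices)
  cfg$m_frac <- c(0.15, 0.4)
  cfg$phi_max <- 0.57
  cfg$dropout <- 0.20
  cfg$pupil_luminance <- "weibull"  # 18 + Weibull(shape 2, scale 25)
  class(cfg) <- c("eyeforge_cfg_eds2020", "eyeforge_cfg_constellation",
                  "eyeforge_cfg")
  cfg
}

r_weibull_luminance <- function(offset = 18, scale = 25, shape = 2,
                                max = 255) {
  repeat {
    v <- offset + stats::rweibull(1, shape = shape, scale = scale)
    if (v <= max) return(v)
  }
}

#' @export
gen_scene.eyeforge_cfg_constellation <- function(cfg, render = TRUE) {
  d <- cfg$size
  a_p <- runif_range(cfg$r_p)
  L_p <- if (identical(cfg$pupil_luminance, "weibull")) {
    r_weibull_luminance()
  } else {
    r_pupil_luminance()
  }
  pupil <- gaussian_feature(
    stats::runif(1, cfg$pupil_frac[1] * d, cfg$pupil_frac[2] * d),
    stats::runif(1, cfg$pupil_frac[1] * d, cfg$pupil_frac[2] * d),
    r_minor = a_p, r_major = a_p * runif_range(cfg$major_factor_p),
    A = rlogunif_range(cfg$A_p), L = L_p,
    theta = stats::runif(1, 0, 2 * pi), polarity = "dark"
  )
  # constellation centroid close to the pupil; resample until fully in-canvas
  verts <- NULL
  for (attempt in 1:1000) {
    phi <- sample(c(-1, 1), 1) * stats::runif(1, 0, cfg$phi_max)
    center <- c(pupil$x + stats::rnorm(1, 0, cfg$center_sd),
                pupil$y + stats::rnorm(1, 0, cfg$center_sd))
    cand <- if (cfg$constellation == "house") {
      w <- runif_range(cfg$w_frac) * d
      build_house_constellation(w, f_b = runif_range(cfg$f_b),
                                h = runif_range(cfg$h_frac) * w,
                                h_r = runif_range(cfg$h_r_frac) * w,
                                phi = phi, center = center)
    } else {
      build_octagon_constellation(runif_range(cfg$m_frac) * d, phi = phi,
                                  center = center)
    }
    if (all(cand$x >= 0) && all(cand$x <= d - 1) &&
        all(cand$y >= 0) && all(cand$y <= d - 1)) {
      verts <- cand
      break
    }
  }
  if (is.null(verts)) {
    rlang::abort("could not place constellation in canvas",
                 class = "eyeforge_error_placement")
  }
  verts$absent <- stats::runif(nrow(verts)) < cfg$dropout
  cr_features <- purrr::pmap(verts[!verts$absent, c("x", "y")], function(x, y) {
    rm <- runif_range(cfg$r_c)
    gaussian_feature(x, y, r_minor = rm,
                     r_major = rm * runif_range(cfg$major_factor_c),
                     A = rlogunif_range(cfg$A_c), L = 255,
                     theta = stats::runif(1, 0, 2 * pi), polarity = "bright")
  })
  spur <- sample_spurious(cfg$n_spur, pupil, d, d)
  bg <- bg_gradient(runif_range(cfg$L_i), runif_range(cfg$L_i),
                    stats::runif(1, 0, 2 * pi))
  sigma_n <- runif_range(cfg$sigma_n)
  spec <- scene_spec(d, d, bg, c(list(pupil), cr_features, spur), sigma_n)
  img <- if (render) compose_scene(spec) else NULL
  li <- labeled_image(
    img, pupil = c(pupil$x, pupil$y),
    crs = tibble::tibble(id = verts$id, x = verts$x, y = verts$y,
                         absent = verts$absent),
    scene = spec, width = d, height = d
  )
  li$info <- list(pupil = pupil, phi = phi, L_p = L_p, sigma_n = sigma_n,
                  spurious = spur, constellation_center = center)
  li
}
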