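# Generators for the high-resolution desk-mounted setups: one pipeline pair
# for corneal-reflection (CR) images and one for pupil images, each with a
# 500-Hz and a 1000-Hz variant and a narrowed second-stage regime used late
# in training. All interval parameters are sampled uniformly except the
# Gaussian amplitude A, which spans four orders of magnitude and is sampled
# log-uniformly.

runif_range <- function(range) stats::runif(1, range[1], range[2])

rlogunif_range <- function(range) exp(stats::runif(1, log(range[1]), log(range[2])))

# pupil luminance: exponential with scale 10, offset 1, truncated at 255
r_pupil_luminance <- function(scale = 10, offset = 1, max = 255) {
  repeat {
    v <- offset + stats::rexp(1, rate = 1 / scale)
    if (v <= max) return(v)
  }
}

#' Configuration for the high-resolution CR pipeline
#'
#' Images contain one circular CR at full white on a background divided by a
#' randomly oriented straight line (the pupil-iris border) passing close to
#' the CR; one side is dark at an exponentially distributed pupil luminance,
#' the other is iris grey. In the second training stage the CR center is
#' constrained to a span of 1.5 pixels around the image center.
#'
#' @param rate `"500"` (iris side fixed at 128) or `"1000"` (iris side
#'   uniform in `[32, 153]`).
#' @param stage Training stage, 1 or 2.
#' @param size Canvas side in pixels (square). Training images default to
#'   the 180-pixel inference cutout size.
#' @param r_cr Plateau radius range of the circular CR, pixels.
#' @param A Amplitude range (log-uniformly sampled).
#' @param sigma_n Pixel-noise SD range.
#' @param line_dist_factor The line's closest approach to the CR center is
#'   uniform in `[0, line_dist_factor * r_cr]`.
#' @return Object of class `eyeforge_cfg_hr_cr`.
#' @export
highres_cr_config <- function(rate = c("500", "1000"), stage = 1, size = 180,
                              r_cr = c(1, 30), A = c(2, 20000),
                              sigma_n = c(0, 30), line_dist_factor = 2) {
  rate <- match.arg(rate)
  stopifnot(stage %in% c(1, 2))
  structure(
    list(rate = rate, stage = stage, size = as.integer(size), r_cr = r_cr,
         A = A, L_cr = 255, L_i = if (rate == "500") c(128, 128) else c(32, 153),
         sigma_n = sigma_n, line_dist_factor = line_dist_factor),
    class = c("eyeforge_cfg_hr_cr", "eyeforge_cfg")
  )
}

#' Configuration for the high-resolution pupil pipeline
#'
#' Images contain one dark elliptical pupil Gaussian on a uniform iris-grey
#' background plus one to four bright CRs positioned anywhere (they may
#' overlap the pupil) subject to a pairwise separation of at least 1.25
#' times the sum of major-axis radii. In the second stage the pupil center
#' is constrained to a 1.5-pixel span around the image center and exactly
#' one CR is generated.
#'
#' @inheritParams highres_cr_config
#' @param r_p Pupil plateau minor-radius range, pixels; the major radius is
#'   the minor radius times a factor in `major_factor_p`.
#' @param major_factor_p,major_factor_c Axis-ratio ranges.
#' @param A_p,A_c Amplitude ranges (log-uniform).
#' @param n_cr Range of CR counts (integer endpoints, inclusive).
#' @param r_c CR plateau minor-radius range.
#' @param crs_clear_of_pupil If `TRUE`, CRs are additionally kept clear of
#'   the pupil by the separation rule with factor `cr_clear_factor`, and at
#'   least `cr_margin` px from the canvas border (used to build
#'   well-separated scenes for the thresholding baseline).
#' @param cr_clear_factor,cr_margin Separation factor and border margin for
#'   `crs_clear_of_pupil`.
#' @param cr_inside_pupil If `TRUE` (stage 2), the single CR is placed well
#'   inside the pupil plateau (center within `inside_frac` of the pupil
#'   major radius), the configuration typical of on-axis illumination where
#'   the reflection sits on the cornea in front of the pupil.
#' @param inside_frac Fraction of the pupil major radius bounding the CR
#'   offset when `cr_inside_pupil` is set.
#' @return Object of class `eyeforge_cfg_hr_pupil`.
#' @export
highres_pupil_config <- function(rate = c("500", "1000"), stage = 1,
                                 size = 180,
                                 r_p = c(20, 60), major_factor_p = c(1, 1.3),
                                 A_p = c(2, 20000), n_cr = c(1, 4),
                                 r_c = c(4, 12), major_factor_c = c(1, 1.1),
                                 A_c = c(2, 20000), sigma_n = c(0, 30),
                                 crs_clear_of_pupil = FALSE,
                                 cr_clear_factor = 1.25, cr_margin = 0,
                                 cr_inside_pupil = FALSE,
                                 inside_frac = 0.4) {
  rate <- match.arg(rate)
  stopifnot(stage %in% c(1, 2))
  structure(
    list(rate = rate, stage = stage, size = as.integer(size), r_p = r_p,
         major_factor_p = major_factor_p, A_p = A_p, n_cr = n_cr, r_c = r_c,
         major_factor_c = major_factor_c, A_c = A_c, L_cr = 255,
         L_i = if (rate == "500") c(64, 179) else c(32, 153),
         sigma_n = sigma_n, crs_clear_of_pupil = crs_clear_of_pupil,
         cr_clear_factor = cr_clear_factor, cr_margin = cr_margin,
         cr_inside_pupil = cr_inside_pupil, inside_frac = inside_frac),
    class = c("eyeforge_cfg_hr_pupil", "eyeforge_cfg")
  )
}

# uniform center; stage 2 constrains to a 1.5-px span around the image center
sample_center <- function(size, stage) {
  mid <- (size - 1) / 2
  if (stage == 2) {
    c(mid + stats::runif(1, -0.75, 0.75), mid + stats::runif(1, -0.75, 0.75))
  } else {
    c(stats::runif(1, 0, size - 1), stats::runif(1, 0, size - 1))
  }
}

#' Sample non-overlapping corneal reflections
#'
#' Draws `n` randomly positioned and oriented CRs, resampling any CR whose
#' center lies closer to another CR than 1.25 times the sum of the two
#' major-axis radii. Positions are uniform over the canvas.
#'
#' @param n Number of CRs.
#' @param r_minor Minor plateau-radius range.
#' @param major_factor Axis-ratio range.
#' @param A Amplitude range (log-uniform).
#' @param width,height Canvas size.
#' @param keep_clear Optional list of `list(x =, y =, r =)` discs whose
#'   centers CRs must stay clear of by the same rule (with `r` playing the
#'   role of the other major radius; an optional `factor` element overrides
#'   the 1.25 separation factor per disc).
#' @param margin Keep CR centers at least this many pixels from the canvas
#'   border (0 = anywhere in-canvas).
#' @param max_attempts Resampling cap per CR before a placement-failure
#'   error is raised.
#' @return List of [gaussian_feature()] with polarity `"bright"`, `L = 255`.
#' @export
sample_nonoverlapping_crs <- function(n, r_minor, major_factor, A,
                                      width, height, keep_clear = list(),
                                      margin = 0, max_attempts = 1000) {
  stopifnot(n >= 1)
  crs <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      rm <- runif_range(r_minor)
      rM <- rm * runif_range(major_factor)
      cand <- gaussian_feature(stats::runif(1, margin, width - 1 - margin),
                               stats::runif(1, margin, height - 1 - margin),
                               r_minor = rm, r_major = rM,
                               A = rlogunif_range(A), L = 255,
                               theta = stats::runif(1, 0, 2 * pi),
                               polarity = "bright")
      ok <- TRUE
      for (other in crs) {
        d <- sqrt((cand$x - other$x)^2 + (cand$y - other$y)^2)
        if (d < 1.25 * (cand$r_major + other$r_major)) { ok <- FALSE; break }
      }
      if (ok) for (kc in keep_clear) {
        d <- sqrt((cand$x - kc$x)^2 + (cand$y - kc$y)^2)
        fac <- kc$factor %||% 1.25
        if (d < fac * (cand$r_major + kc$r)) { ok <- FALSE; break }
      }
      if (ok) { crs[[i]] <- cand; placed <- TRUE; break }
    }
    if (!placed) {
      rlang::abort("could not place corneal reflection without overlap",
                   class = "eyeforge_error_placement")
    }
  }
  crs
}

#' @export
gen_scene.eyeforge_cfg_hr_cr <- function(cfg, render = TRUE) {
  size <- cfg$size
  center <- sample_center(size, cfg$stage)
  r <- runif_range(cfg$r_cr)
  cr <- gaussian_feature(center[1], center[2], r_minor = r, r_major = r,
                         A = rlogunif_range(cfg$A), L = cfg$L_cr,
                         polarity = "bright")
  # pupil-iris border: a random orientation, closest approach to the CR
  # center uniform in [0, line_dist_factor * r]
  ang <- stats::runif(1, 0, 2 * pi)
  u <- stats::runif(1, 0, cfg$line_dist_factor * r)
  px <- center[1] + u * -sin(ang)
  py <- center[2] + u * cos(ang)
  L_p <- r_pupil_luminance()
  L_i <- runif_range(cfg$L_i)
  bg <- bg_split_line(px, py, ang, L_dark = L_p, L_light = L_i)
  sigma_n <- runif_range(cfg$sigma_n)
  spec <- scene_spec(size, size, bg, list(cr), sigma_n)
  img <- if (render) compose_scene(spec) else NULL
  li <- labeled_image(img, pupil = NULL,
                      crs = tibble::tibble(id = 0L, x = center[1],
                                           y = center[2], absent = FALSE),
                      scene = spec, width = size, height = size)
  li$info <- list(L_p = L_p, L_i = L_i, sigma_n = sigma_n, r_cr = r)
  li
}

#' @export
gen_scene.eyeforge_cfg_hr_pupil <- function(cfg, render = TRUE) {
  size <- cfg$size
  center <- sample_center(size, cfg$stage)
  r_p <- runif_range(cfg$r_p)
  pupil <- gaussian_feature(center[1], center[2], r_minor = r_p,
                            r_major = r_p * runif_range(cfg$major_factor_p),
                            A = rlogunif_range(cfg$A_p),
                            L = r_pupil_luminance(),
                            theta = stats::runif(1, 0, 2 * pi),
                            polarity = "dark")
  n_cr <- if (cfg$stage == 2) 1L else sample(cfg$n_cr[1]:cfg$n_cr[2], 1)
  if (cfg$cr_inside_pupil) {
    rm <- runif_range(cfg$r_c)
    d <- stats::runif(1, 0, cfg$inside_frac * pupil$r_major)
    a <- stats::runif(1, 0, 2 * pi)
    crs <- list(gaussian_feature(pupil$x + d * cos(a), pupil$y + d * sin(a),
                                 r_minor = rm,
                                 r_major = rm * runif_range(cfg$major_factor_c),
                                 A = rlogunif_range(cfg$A_c), L = 255,
                                 theta = stats::runif(1, 0, 2 * pi),
                                 polarity = "bright"))
    L_i <- runif_range(cfg$L_i)
    sigma_n <- runif_range(cfg$sigma_n)
    spec <- scene_spec(size, size, bg_uniform(L_i), c(list(pupil), crs),
                       sigma_n)
    img <- if (render) compose_scene(spec) else NULL
    li <- labeled_image(
      img, pupil = center,
      crs = tibble::tibble(id = 0L, x = crs[[1]]$x, y = crs[[1]]$y,
                           absent = FALSE),
      scene = spec, width = size, height = size
    )
    li$info <- list(L_p = pupil$L, L_i = L_i, sigma_n = sigma_n,
                    pupil = pupil, cr_features = crs)
    return(li)
  }
  keep_clear <- if (cfg$crs_clear_of_pupil) {
    list(list(x = pupil$x, y = pupil$y, r = pupil$r_major,
              factor = cfg$cr_clear_factor))
  } else list()
  crs <- sample_nonoverlapping_crs(n_cr, cfg$r_c, cfg$major_factor_c,
                                   cfg$A_c, size, size,
                                   keep_clear = keep_clear,
                                   margin = if (cfg$crs_clear_of_pupil) cfg$cr_margin else 0)
  L_i <- runif_range(cfg$L_i)
  sigma_n <- runif_range(cfg$sigma_n)
  spec <- scene_spec(size, size, bg_uniform(L_i), c(list(pupil), crs),
                     sigma_n)
  img <- if (render) compose_scene(spec) else NULL
  li <- labeled_image(
    img, pupil = center,
    crs = tibble::tibble(id = seq_along(crs) - 1L,
                         x = purrr::map_dbl(crs, "x"),
                         y = purrr::map_dbl(crs, "y"),
                         absent = FALSE),
    scene = spec, width = size, height = size
  )
  li$info <- list(L_p = pupil$L, L_i = L_i, sigma_n = sigma_n,
                  pupil = pupil, cr_features = crs)
  li
}
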