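test_that("plateau sigma inverts the plateau construction", {
  expect_equal(plateau_sigma(4, exp(2)), 2)
  expect_equal(plateau_sigma(5, exp(0.5)), 5)
  # high-precision scalar evaluation as oracle at the amplitude range maximum
  expect_equal(plateau_sigma(10, 20000), 10 / sqrt(2 * log(20000)),
               tolerance = 1e-12)
  expect_error(plateau_sigma(4, 1), class = "eyeforge_error_amplitude")
  expect_error(gaussian_feature(0, 0, 3, A = 0.5, L = 10),
               class = "eyeforge_error_amplitude")
})

test_that("gaussian field hits amplitude at center and 1 on the plateau ellipse", {
  f <- gaussian_feature(10.4, 7.3, r_minor = 3, r_major = 5, A = 37,
                        theta = 0.9, L = 255, polarity = "bright")
  expect_equal(eval_gaussian_field(f, x = f$x, y = f$y), 37)
  th <- f$theta
  expect_equal(eval_gaussian_field(f, x = f$x + 3 * cos(th),
                                   y = f$y + 3 * sin(th)), 1,
               tolerance = 1e-12)
  expect_equal(eval_gaussian_field(f, x = f$x + 5 * cos(th + pi / 2),
                                   y = f$y + 5 * sin(th + pi / 2)), 1,
               tolerance = 1e-12)
  f0 <- gaussian_feature(0, 0, r_minor = 2, A = 10, L = 255)
  expect_equal(eval_gaussian_field(f0, x = 2, y = 0), 1, tolerance = 1e-12)
})

test_that("plateau identity holds for 1000 random radius/amplitude pairs", {
  withr::with_seed(101, {
    r <- runif(1000, 0.5, 30)
    A <- exp(runif(1000, log(2), log(20000)))
    th <- runif(1000, 0, 2 * pi)
  })
  worst <- 0
  for (i in seq_len(1000)) {
    f <- gaussian_feature(0, 0, r_minor = r[i], r_major = r[i] * 1.2,
                          A = A[i], theta = th[i], L = 255)
    v1 <- eval_gaussian_field(f, x = r[i] * cos(th[i]), y = r[i] * sin(th[i]))
    v2 <- eval_gaussian_field(f, x = 1.2 * r[i] * cos(th[i] + pi / 2),
                              y = 1.2 * r[i] * sin(th[i] + pi / 2))
    worst <- max(worst, abs(v1 - 1), abs(v2 - 1))
  }
  expect_lt(worst, 1e-9)
})

test_that("field is equivariant under rotation and symmetric under theta + pi", {
  f0 <- gaussian_feature(0, 0, 3, 7, A = 50, theta = 0, L = 255)
  f45 <- gaussian_feature(0, 0, 3, 7, A = 50, theta = pi / 4, L = 255)
  withr::with_seed(7, {
    xs <- runif(200, -10, 10)
    ys <- runif(200, -10, 10)
  })
  rx <- cos(pi / 4) * xs - sin(pi / 4) * ys
  ry <- sin(pi / 4) * xs + cos(pi / 4) * ys
  expect_lt(max(abs(eval_gaussian_field(f45, x = rx, y = ry) -
                      eval_gaussian_field(f0, x = xs, y = ys))), 1e-9)
  fpi <- gaussian_feature(5, 5, 2, 4, A = 9, theta = 0.6 + pi, L = 255)
  fref <- gaussian_feature(5, 5, 2, 4, A = 9, theta = 0.6, L = 255)
  expect_lt(max(abs(eval_gaussian_field(fpi, 32, 32) -
                      eval_gaussian_field(fref, 32, 32))), 1e-9)
})

test_that("compositing gives exact plateau luminances and identity background", {
  flat <- compose_scene(scene_spec(16, 16, bg_uniform(128)))
  expect_true(all(flat == 128 / 255))
  # bright CR at full white: plateau pixels saturate exactly
  cr <- gaussian_feature(32, 32, r_minor = 5, A = 4, L = 255,
                         polarity = "bright")
  img <- compose_scene(scene_spec(64, 64, bg_uniform(128), list(cr)))
  expect_equal(img[33, 33], 1)
  inside <- eval_gaussian_field(cr, 64, 64) >= 1
  expect_true(all(img[inside] == 1))
  # dark pupil blends to its luminance regardless of background
  pu <- gaussian_feature(32, 32, r_minor = 5, A = 4, L = 1, polarity = "dark")
  img2 <- compose_scene(scene_spec(64, 64, bg_uniform(128), list(pu)))
  expect_equal(img2[33, 33] * 255, 1)
  expect_error(compose_scene(scene_spec(0, 5, bg_uniform(1))))
})

test_that("rendered pixels are 8-bit levels and renders are seed-reproducible", {
  cr <- gaussian_feature(20, 25, r_minor = 4, A = 100, L = 255,
                         polarity = "bright")
  spec <- scene_spec(48, 48, bg_uniform(77.3), list(cr), sigma_n = 12)
  a <- compose_scene(spec, seed = 5)
  b <- compose_scene(spec, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(abs(a * 255 - round(a * 255)) < 1e-12))
  expect_true(all(a >= 0 & a <= 1))
  c2 <- compose_scene(spec, seed = 6)
  expect_false(identical(unclass(a), unclass(c2)))
})

test_that("noiseless symmetric CR centroid matches the feature center", {
  # large CRs: the centroid discretization error of a pixel-sampled disc
  # scales as 1/r, so the sub-pixel rendering check uses the upper part of
  # the pipeline's radius range where the 8-bit staircase is negligible
  withr::with_seed(33, {
    for (i in 1:20) {
      x <- runif(1, 80, 100)
      y <- runif(1, 80, 100)
      r <- runif(1, 20, 30)
      A <- exp(runif(1, log(2), log(20000)))
      img <- compose_scene(centered_cr_scene(x, y, r, A, size = 180))
      ctr <- intensity_centroid(img, 100 / 255)
      expect_lt(sqrt(sum((ctr - c(x, y))^2)), 0.02)
    }
  })
})

test_that("soft ellipse blend is 1 inside, 0 outside, raised-cosine across", {
  e <- soft_ellipse(32, 32, 8, 12, theta = 0, L = 50, edge_width = 4)
  cf <- render_soft_ellipse(e, 64, 64)
  expect_equal(cf[33, 33], 1)       # center
  expect_equal(cf[33, 33 + 7], 1)   # just inside along x (minor)
  expect_equal(cf[33, 33 + 13], 0)  # outside grown ellipse along x
  # band midpoint along the minor axis: t = 0.5 -> coefficient 0.5
  mid <- render_soft_ellipse(e, x = 32 + 10, y = 32)
  expect_equal(mid, 0.5, tolerance = 1e-12)
  # edge_width = 0 gives a binary mask
  b <- render_soft_ellipse(soft_ellipse(32, 32, 8, 12, L = 1), 64, 64)
  expect_true(all(b %in% c(0, 1)))
  # monotone decrease along outward rays through the band
  withr::with_seed(4, angs <- runif(100, 0, 2 * pi))
  for (a in angs) {
    rr <- seq(6, 18, by = 0.25)
    v <- render_soft_ellipse(e, x = 32 + rr * cos(a), y = 32 + rr * sin(a))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("collarette outline is a closed 5n-point spline near radius r_col", {
  poly <- collarette_polygon(50, 50, n_vertices = 13, r_col = 20,
                             jitter_lo = 0, jitter_hi = 0, L = 100,
                             edge_width = 0)
  out <- withr::with_seed(10, realize_collarette(poly))
  expect_equal(nrow(out$outline), 65)
  expect_lt(max(abs(out$outline[1, ] - out$outline[nrow(out$outline), ])),
            1e-9)
  rad <- sqrt((out$outline$x - 50)^2 + (out$outline$y - 50)^2)
  expect_lt(max(abs(rad - 20)), 0.02 * 20)
  expect_error(collarette_polygon(0, 0, 13, r_col = -1, L = 1),
               class = "eyeforge_error_geometry")
})

test_that("pixel noise has the requested SD and is deterministic given seed", {
  flat <- matrix(100, 256, 256)
  expect_identical(add_pixel_noise(flat, 0), flat)
  n1 <- add_pixel_noise(flat, 10, seed = 3)
  expect_gt(sd(n1 - flat), 9.5)
  expect_lt(sd(n1 - flat), 10.5)
  expect_identical(n1, add_pixel_noise(flat, 10, seed = 3))
  expect_error(add_pixel_noise(flat, -1), class = "eyeforge_error_noise")
})
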