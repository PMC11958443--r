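test_that("house constellation geometry matches the construction", {
  h <- build_house_constellation(40, f_b = 1, h = 22, h_r = 10)
  expect_equal(h$x, c(0, 20, 20, -20, -20))
  expect_equal(h$y, c(-21, -11, 11, 11, -11))
  # mirror symmetry about the vertical axis at phi = 0
  h2 <- build_house_constellation(30, f_b = 0.12, h = 16, h_r = 9)
  expect_equal(h2$x, -h2$x[c(1, 5, 4, 3, 2)])
  expect_equal(h2$y, h2$y[c(1, 5, 4, 3, 2)])
  expect_error(build_house_constellation(-1, 0.1, 10, 5),
               class = "eyeforge_error_geometry")
})

test_that("octagon constellation is regular, bottom-right-first, clockwise", {
  o <- build_octagon_constellation(10)
  expect_equal(sqrt(o$x^2 + o$y^2), rep(10, 8), tolerance = 1e-9)
  ang <- atan2(o$y, o$x)
  expect_equal(diff(ang) %% (2 * pi), rep(pi / 4, 7), tolerance = 1e-9)
  # first vertex in the bottom-right octant (x > 0, y > 0 with y downward)
  expect_gt(o$x[1], 0)
  expect_gt(o$y[1], 0)
  expect_error(build_octagon_constellation(0),
               class = "eyeforge_error_geometry")
})

test_that("constellation identities run clockwise from their anchors", {
  withr::with_seed(31, {
    for (i in 1:200) {
      w <- runif(1, 12.8, 57.6)
      h <- build_house_constellation(w, f_b = runif(1, 0.05, 0.2),
                                     h = runif(1, 0.5, 0.6) * w,
                                     h_r = runif(1, 0.2, 0.5) * w,
                                     phi = runif(1, -45, 45),
                                     center = c(64, 64))
      expect_true(all(w / 2 >= 6.4 & w / 2 <= 28.8))
      ang <- atan2(h$y - mean(h$y), h$x - mean(h$x))
      # increasing polar angle (y down) = clockwise on screen, mod start
      expect_lte(sum(diff(ang) < 0), 1)
      o <- build_octagon_constellation(runif(1, 19.2, 51.2),
                                       phi = runif(1, -0.57, 0.57),
                                       center = c(64, 64))
      ango <- atan2(o$y - 64, o$x - 64)
      expect_lte(sum(diff(ango) < 0), 1)
    }
  })
})

test_that("spurious reflections avoid the pupil plateau", {
  pupil <- gaussian_feature(64, 64, r_minor = 15, r_major = 18, A = 1000,
                            L = 10, polarity = "dark")
  pos <- withr::with_seed(41, purrr::map_dfr(1:2000, function(i) {
    s <- sample_spurious(c(1, 1), pupil, 128, 128)[[1]]
    tibble::tibble(x = s$x, y = s$y)
  }))
  d <- sqrt((pos$x - 64)^2 + (pos$y - 64)^2)
  # plateau disc vs a far annulus of equal area (r in [50, sqrt(50^2+15^2)])
  inside <- mean(d <= 15)
  annulus <- mean(d > 50 & d <= sqrt(50^2 + 15^2))
  expect_lt(inside, 0.1 * annulus)
})

test_that("house pipeline: dropout, rotation and identity anchoring", {
  s1 <- generate_scenes(chugh_config(stage = 1), 3000, seed = 51,
                        render = FALSE)
  presence <- purrr::map_dfr(s1, ~ .x$crs)
  rate <- 1 - mean(presence$absent)
  ci <- qnorm(0.995) * sqrt(0.84 * 0.16 / nrow(presence))
  expect_lt(abs(rate - 0.84), ci + 0.01)
  # stage 2 narrows rotation and spurious count
  s2 <- generate_scenes(chugh_config(stage = 2), 300, seed = 52,
                        render = FALSE)
  expect_true(all(abs(purrr::map_dbl(s2, ~ .x$info$phi)) <= 35))
  expect_true(all(purrr::map_int(s2, ~ length(.x$info$spurious)) <= 3))
  # identity 0 is the roof apex: topmost vertex at small rotations
  small_rot <- purrr::keep(s1, ~ abs(.x$info$phi) < 20)
  for (li in small_rot[1:50]) {
    expect_equal(which.min(li$crs$y), 1L)
  }
  # canvases are exactly 128 x 128 and labels in-canvas
  expect_true(all(purrr::map_int(s1, "width") == 128L))
  expect_true(all(presence$x >= 0 & presence$x <= 127 &
                    presence$y >= 0 & presence$y <= 127))
})

test_that("octagon pipeline: Weibull pupil luminance and tiny rotations", {
  s <- generate_scenes(eds2020_config(), 3000, seed = 61, render = FALSE)
  L_p <- purrr::map_dbl(s, ~ .x$info$L_p)
  expect_gte(min(L_p), 18)
  expect_lt(abs(mean(L_p) - (18 + 25 * gamma(1.5))) / (18 + 25 * gamma(1.5)),
            0.02)
  expect_true(all(abs(purrr::map_dbl(s, ~ .x$info$phi)) <= 0.57))
  presence <- purrr::map_dfr(s, ~ .x$crs)
  rate <- 1 - mean(presence$absent)
  ci <- qnorm(0.995) * sqrt(0.8 * 0.2 / nrow(presence))
  expect_lt(abs(rate - 0.80), ci + 0.01)
})

test_that("dropout is independent across constellation identities", {
  s <- generate_scenes(chugh_config(), 4000, seed = 71, render = FALSE)
  pres <- do.call(rbind, purrr::map(s, ~ as.integer(!.x$crs$absent)))
  for (a in 1:4) for (b in (a + 1):5) {
    p <- suppressWarnings(chisq.test(table(pres[, a], pres[, b]))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("segmentation scenes stack sclera, iris, collarette, pupil, CRs", {
  cfg <- eds2019_config(sigma_n = c(0, 0))
  scenes <- generate_scenes(cfg, 10, seed = 81)
  for (li in scenes) {
    info <- li$info
    # collarette mean radius within the sampled fraction of the iris major
    expect_gte(info$r_col, 0.3 * info$iris$r_major)
    expect_lte(info$r_col, 0.6 * info$iris$r_major)
    # pupil center inside the iris
    d <- sqrt((li$pupil[1] - info$iris$x)^2 + (li$pupil[2] - info$iris$y)^2)
    expect_lt(d, info$iris$r_minor)
    # mask centroid agrees with the labeled center for symmetric pupils
    ctr <- colMeans(which(li$masks$pupil, arr.ind = TRUE))
    mask_xy <- c(ctr[2] - 1, ctr[1] - 1)
    expect_lt(sqrt(sum((mask_xy - li$pupil)^2)), 0.5)
  }
  # background far from all features equals the quantized sclera luminance
  checked <- 0
  for (li in scenes) {
    info <- li$info
    corners <- rbind(c(0, 0), c(191, 0), c(0, 191), c(191, 191))
    d_iris <- sqrt((corners[, 1] - info$iris$x)^2 +
                     (corners[, 2] - info$iris$y)^2)
    clear <- d_iris > info$iris$r_major + 25
    for (cr in li$scene$layers[-(1:3)]) {
      clear <- clear & sqrt((corners[, 1] - cr$x)^2 +
                              (corners[, 2] - cr$y)^2) > 20 * cr$r_major
    }
    k <- which(clear)[1]
    if (is.na(k)) next
    val <- li$image[corners[k, 2] + 1, corners[k, 1] + 1]
    expect_equal(val, floor(min(max(info$L_s, 0), 255) + 0.5) / 255)
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})
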