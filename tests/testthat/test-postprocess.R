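test_that("peak extraction locates maxima with row-then-column tie-breaks", {
  m <- matrix(0, 30, 40)
  m[21, 11] <- 7  # (x = 10, y = 20)
  pk <- extract_peaks(m)
  expect_equal(c(pk$x, pk$y, pk$logit), c(10, 20, 7))
  # constant map resolves to the origin
  pk0 <- extract_peaks(matrix(1, 5, 5))
  expect_equal(c(pk0$x, pk0$y), c(0, 0))
  # two equal maxima: the smaller row (y) wins
  m2 <- matrix(0, 10, 10)
  m2[4, 10] <- 3  # y = 3, x = 9
  m2[6, 2] <- 3   # y = 5, x = 1
  pk2 <- extract_peaks(m2)
  expect_equal(c(pk2$x, pk2$y), c(9, 3))
  expect_error(extract_peaks(list()), class = "eyeforge_error_input")
})

test_that("best-two selection takes the largest logits, lower id on ties", {
  pk <- tibble::tibble(id = paste0("cr", 0:4), x = 0, y = 0,
                       logit = c(5, 3, 0.5, 7, 2))
  expect_equal(select_best_two(pk)$id, c("cr3", "cr0"))
  pk_eq <- tibble::tibble(id = paste0("cr", 0:2), x = 0, y = 0, logit = 1)
  expect_equal(select_best_two(pk_eq)$id, c("cr0", "cr1"))
  pk_tie <- tibble::tibble(id = paste0("cr", 0:2), x = 0, y = 0,
                           logit = c(9, 9, 1))
  expect_equal(select_best_two(pk_tie)$id, c("cr0", "cr1"))
  expect_error(select_best_two(pk_eq[1, ]), class = "eyeforge_error_input")
})

test_that("validity requires two CR maps with max logit of at least one", {
  pk <- function(l) tibble::tibble(id = seq_along(l), x = 0, y = 0, logit = l)
  expect_true(check_validity(pk(c(1.0, 1.0, 0.2))))
  expect_false(check_validity(pk(c(0.99, 5.0))))
  expect_false(check_validity(pk(numeric())))
  # monotone: raising any logit never invalidates
  base <- c(0.5, 1.2, 1.0)
  expect_true(check_validity(pk(base)))
  expect_true(check_validity(pk(base + c(10, 0, 0))))
})

test_that("best-two on exact delta-bump heatmaps recovers labels exactly", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(3:6, 1)
      amps <- runif(n, 1, 10)
      xs <- sample(0:63, n)
      ys <- sample(0:63, n)
      maps <- purrr::map(seq_len(n), function(i) {
        m <- matrix(0, 64, 64)
        m[ys[i] + 1, xs[i] + 1] <- amps[i]
        m
      })
      names(maps) <- paste0("cr", seq_len(n) - 1)
      sel <- select_best_two(extract_peaks(maps))
      top2 <- order(-amps)[1:2]
      expect_setequal(sel$id, paste0("cr", top2 - 1))
      expect_equal(sel$x[order(sel$id)], xs[sort(top2)])
      expect_equal(sel$y[order(sel$id)], ys[sort(top2)])
    }
  })
})

test_that("adaptive cutout gates on the prior confidence", {
  img <- matrix(runif(360 * 360), 360, 360)
  # confident prior: cutout centered on the prior (downscaled by 2)
  res <- adaptive_cutout(img, pupil_prior(200, 150, 0.95), threshold = 0.90,
                         size = 64)
  expect_equal(res$path, "prior")
  expect_equal(res$spec$origin, c(100 - 32, 75 - 32))
  expect_equal(dim(res$image), c(64, 64))
  # low confidence: two-pass naive path through the fallback locator
  called <- FALSE
  locator <- function(cut) {
    called <<- TRUE
    list(pupil = c(40, 20))
  }
  res2 <- adaptive_cutout(img, pupil_prior(200, 150, 0.69), threshold = 0.70,
                          size = 64, fallback_locator = locator)
  expect_true(called)
  expect_equal(res2$path, "fallback")
  expect_true(res2$valid)
  # locator failure flags the frame invalid
  res3 <- adaptive_cutout(img, pupil_prior(0, 0, 0), threshold = 0.5,
                          size = 64, fallback_locator = function(cut) NULL)
  expect_false(res3$valid)
  # a prior exactly at the image center reproduces the naive cutout
  ctr <- c((360 - 1) / 2, (360 - 1) / 2)
  res4 <- adaptive_cutout(img, pupil_prior(ctr[1], ctr[2], 1), threshold = 0.9,
                          size = 64)
  res5 <- adaptive_cutout(img, pupil_prior(ctr[1], ctr[2], 0), threshold = 0.9,
                          size = 64, fallback_locator = function(cut)
                            list(pupil = c(31.5, 31.5)))
  expect_equal(res4$spec$origin, res5$spec$origin)
})

test_that("cutout coordinates round-trip within the downscale quantization", {
  spec <- cutout_spec(c(17, 23), 64, factor = 2)
  withr::with_seed(9, pts <- matrix(runif(40, 0, 300), ncol = 2))
  for (i in seq_len(nrow(pts))) {
    back <- cutout_to_global(spec, cutout_to_local(spec, pts[i, ]))
    expect_lt(max(abs(back - pts[i, ])), 2 + 1e-9)
    expect_equal(back, pts[i, ], tolerance = 1e-9)
  }
})

test_that("probability maps yield pupil centers via mask morphology", {
  pm <- matrix(0, 64, 64)
  pm[disk_px(64, c(30, 25), 10)] <- 1
  res <- prob_map_to_pupil(pm)
  expect_lt(max(abs(res$center - c(30, 25))), 0.01)
  # interior holes are filled before the center of mass
  pm_hole <- pm
  pm_hole[disk_px(64, c(30, 25), 3)] <- 0
  res2 <- prob_map_to_pupil(pm_hole)
  expect_lt(max(abs(res2$center - c(30, 25))), 0.01)
  # a tiny blob below the area criterion loses to the large one
  pm2 <- pm
  pm2[disk_px(64, c(55, 55), 1)] <- 1
  res3 <- prob_map_to_pupil(pm2)
  expect_lt(max(abs(res3$center - c(30, 25))), 0.01)
  # sub-threshold values never form a blob
  expect_null(prob_map_to_pupil(matrix(0.9, 32, 32)))
})

test_that("ellipse fitting recovers parametric ellipses", {
  t <- seq(0, 2 * pi, length.out = 60)
  fit <- fit_ellipse(tibble::tibble(
    x = 30 + 12 * cos(t) * cos(0.7) - 7 * sin(t) * sin(0.7),
    y = 40 + 12 * cos(t) * sin(0.7) + 7 * sin(t) * cos(0.7)
  ))
  expect_equal(fit$center, c(30, 40), tolerance = 1e-6)
  expect_equal(fit$r_major, 12, tolerance = 1e-6)
  expect_equal(fit$r_minor, 7, tolerance = 1e-6)
  expect_equal(fit$theta %% pi, 0.7, tolerance = 1e-6)
  expect_error(fit_ellipse(tibble::tibble(x = 1:4, y = 1:4)),
               class = "eyeforge_error_fit")
})

test_that("cutouts re-center only when the pupil crowds the edge", {
  cut <- cutout_spec(c(0, 0), 100, factor = 2)
  ell_small <- list(r_major = 5)
  expect_identical(recenter_if_near_edge(cut, c(50, 50), ell_small), cut)
  # 10 px from the edge with a 15 px major radius triggers re-centering
  moved <- recenter_if_near_edge(cut, c(89, 50), list(r_major = 15))
  expect_false(identical(moved$origin, cut$origin))
  expect_equal(moved$origin, c(89 - 50, 50 - 50))
  # exactly at the major radius stays (strict "closer than")
  expect_identical(recenter_if_near_edge(cut, c(84, 50), list(r_major = 15)),
                   cut)
})
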