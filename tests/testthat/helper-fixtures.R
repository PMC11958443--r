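# Shared fixture builders; everything is generated in code at test time.

# a bright circular CR on a uniform background, fully inside the canvas
centered_cr_scene <- function(x, y, r, A, size = 64, bg = 100, L = 255) {
  cr <- gaussian_feature(x, y, r_minor = r, A = A, L = L,
                         polarity = "bright")
  scene_spec(size, size, bg_uniform(bg), list(cr), sigma_n = 0)
}

# intensity-weighted centroid of (image - background), 0-based coords
intensity_centroid <- function(image, bg01) {
  d <- unclass(image) - bg01
  x <- rep(seq_len(ncol(image)) - 1, each = nrow(image))
  y <- rep(seq_len(nrow(image)) - 1, times = ncol(image))
  c(sum(x * d), sum(y * d)) / sum(d)
}

# logical disk mask on a square canvas (0-based center coordinates)
disk_px <- function(size, center, radius) {
  x <- matrix(rep(seq_len(size) - 1, each = size), nrow = size)
  y <- matrix(rep(seq_len(size) - 1, times = size), nrow = size)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

# exact quadratic gaze map used by calibration-recovery tests
quadratic_map <- function(px, py) {
  tibble::tibble(
    x = 1.5 + 0.8 * px - 0.1 * py + 0.02 * px^2 - 0.015 * py^2 + 0.03 * px * py,
    y = -0.7 + 0.05 * px + 0.9 * py - 0.01 * px^2 + 0.025 * py^2 - 0.02 * px * py
  )
}
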