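test_that("candidate grid follows the scan formula and the published defaults", {
  cfg <- correction_config(k_min = 1e-9, k_max = 1e-6, n_steps = 20L)
  expect_equal(candidate_k(0, cfg), 1e-9)
  expect_equal(candidate_k(20, cfg), 1e-6)
  expect_equal(candidate_k(5, cfg), 1e-9 + 5 * (1e-6 - 1e-9) / 20)
  expect_error(candidate_k(21, cfg), "out of range")
  gb <- correction_config_groupB()
  expect_equal(gb$k_min, 1e-9)                       # start coefficient
  expect_equal((gb$k_max - gb$k_min) / gb$n_steps, 5e-8)  # first-round step
  expect_equal(gb$rounds, 15L)
})

test_that("edge detection: constant, step edge and square perimeter", {
  cfg <- correction_config()
  flat <- array(128, c(64, 64, 3))
  expect_false(any(detect_edges(flat, cfg)))

  step <- matrix(40, 64, 64)
  step[, 33:64] <- 220
  e <- detect_edges(array(rep(step, 3), c(64, 64, 3)), cfg)
  hit <- which(e, arr.ind = TRUE)
  expect_gt(nrow(hit), 32)
  expect_true(all(abs(hit[, 2] - 32.5) <= 1))   # only around the step column

  sq <- matrix(20, 128, 128)
  sq[33:96, 33:96] <- 230
  e2 <- detect_edges(array(rep(sq, 3), c(128, 128, 3)), cfg)
  perimeter <- 4 * 64
  expect_lt(abs(sum(e2) - perimeter) / perimeter, 0.10)
})

test_that("restricted Hough accumulator votes where lines are", {
  cfg <- correction_config(n_rho = 363L)
  empty <- hough_space(matrix(FALSE, 64, 64), cfg)
  expect_true(all(empty$accumulator == 0))

  # vertical line at a known offset from the center
  e <- matrix(FALSE, 128, 128)
  e[11:118, 96] <- TRUE                      # x = 95 (0-based), 31.5 off-center
  ht <- hough_space(e, cfg)
  i <- which.max(ht$accumulator)
  rho0 <- ht$rho[(i - 1) %% nrow(ht$accumulator) + 1]
  theta0 <- ht$theta[(i - 1) %/% nrow(ht$accumulator) + 1]
  expect_equal(theta0, 0)
  step <- ht$rho[2] - ht$rho[1]
  expect_lt(abs(rho0 - 31.5), step)
  # one split vote per edge pixel at theta = 0
  th0 <- which(ht$theta == 0)
  expect_equal(sum(ht$accumulator[, th0]), 108)
  expect_gte(max(ht$accumulator[, th0]), 108 / 2)

  # two parallel vertical lines -> two local maxima in the same theta column
  e[11:118, 40] <- TRUE
  ht2 <- hough_space(e, cfg)
  col <- ht2$accumulator[, th0]
  locmax <- which(col >= c(-1, col[-length(col)]) & col > c(col[-1], -1) & col > 20)
  expect_equal(length(locmax), 2L)
})

test_that("HT smoothing preserves interior mass and composes as a semigroup", {
  cfg <- correction_config(gaussian_sigma = 1.2)
  z <- list(accumulator = matrix(0, 41, 21), rho = seq(-20, 20), theta = seq(0, 20) / 40)
  class(z) <- "ht_space"
  expect_true(all(smooth_ht(z, cfg)$accumulator == 0))

  z$accumulator[21, 11] <- 7   # interior impulse
  sm <- smooth_ht(z, cfg)
  expect_lt(abs(sum(sm$accumulator) - 7) / 7, 1e-3)
  expect_true(all(sm$accumulator >= 0))

  # two passes with sigma equal one pass with sigma * sqrt(2)
  cfg2 <- correction_config(gaussian_sigma = 1.2 * sqrt(2))
  twice <- smooth_ht(smooth_ht(z, cfg), cfg)$accumulator
  once <- smooth_ht(z, cfg2)$accumulator
  expect_lt(max(abs(twice - once)), 0.02 * max(once))
})

test_that("undistortion is exact at k = 0 and relocates points by the radius formula", {
  img <- generate_texture_image(4, c(128, 128), 0.6)
  expect_identical(undistort(img, 0), img)

  dot <- array(0, c(256, 256, 3))
  dot[128, 200, ] <- 255                  # bright dot at radius 72.5 (x offset)
  k <- 2e-6
  und <- undistort(dot, k)
  hit <- which(und[, , 1] == max(und[, , 1]), arr.ind = TRUE)[1, ]
  # intensity centroid around the peak: bilinear splitting is sub-pixel
  win_i <- (hit[1] - 2):(hit[1] + 2)
  win_j <- (hit[2] - 2):(hit[2] + 2)
  patch <- und[win_i, win_j, 1]
  ci <- sum((win_i - 1) * rowSums(patch)) / sum(patch)
  cj <- sum((win_j - 1) * colSums(patch)) / sum(patch)
  # the dot sits at distorted radius r_d; it must appear at r_u = r_d/(1+k r_d^2)
  r_d <- 200 - 127.5
  r_u <- r_d / (1 + k * r_d^2)
  expect_lt(abs(cj - (127.5 + r_u)), 1)
  expect_lt(abs(ci - 127.5), 1)

  expect_error(undistort(dot, 1e-3), "invertible|monotone")
})

test_that("degenerate featureless images yield k = 0 with a warning", {
  flat <- array(128, c(128, 128, 3))
  expect_warning(m <- estimate_k(flat), "no edges")
  expect_equal(m$k, 0)
  expect_true(m$degenerate)
})

test_that("straightness score is invariant to quarter-turn rotation", {
  grid <- generate_line_grid(c(256, 256), spacing = 32, width = 3,
                             center_gap = 48)
  dist <- apply_radial_distortion(grid, 5e-7)
  rot90 <- function(img) {
    out <- array(0, c(dim(img)[2], dim(img)[1], 3))
    for (c in 1:3) out[, , c] <- t(img[, , c])[, dim(img)[1]:1]
    out
  }
  cfg <- correction_config(n_rho = 363L)
  s1 <- straightness_score(dist, 3e-7, cfg)$score
  s2 <- straightness_score(rot90(dist), 3e-7, cfg)$score
  expect_lt(abs(s1 - s2) / max(s1, s2), 0.05)
})

test_that("distortion model text round trip", {
  m <- structure(list(k = 2.71e-7, center = c(255.5, 255.5), score = 1,
                      rho0 = 0, theta0 = 0, degenerate = FALSE),
                 class = "distortion_model")
  f <- withr::local_tempfile()
  write_distortion_model(m, f)
  m2 <- read_distortion_model(f)
  expect_equal(m2$k, m$k)
  expect_equal(m2$center, m$center)
})
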