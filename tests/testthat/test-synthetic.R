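test_that("texture generator honors its contracts", {
  # determinism
  a <- generate_texture_image(7, c(64, 64), 0.6)
  b <- generate_texture_image(7, c(64, 64), 0.6)
  expect_identical(a, b)
  # zero texture level -> per-channel constant image
  flat <- generate_texture_image(3, c(64, 64), 0)
  for (c in 1:3) expect_equal(stats::sd(flat[, , c]), 0)
  # strong-light class forces mean intensity above 200
  strong <- generate_texture_image(7, c(64, 64), 0.5, "strong")
  expect_gt(mean(strong), 200)
  # intensity range
  expect_true(all(a >= 0 & a <= 255))
  # undersized images are rejected
  expect_error(generate_texture_image(1, c(32, 64)), "at least 64")
})

test_that("quadruples: identity case, determinism, overlap accounting", {
  src <- generate_texture_image(42, c(192, 192), 0.7)
  q0 <- make_stitch_quadruple(src, c(64, 64), 1, 0, 5)
  expect_identical(q0$I_A, q0$I_B)
  expect_identical(q0$label, q0$I_A)
  expect_equal(max(abs(q0$gt_offsets)), 0)

  q1 <- make_stitch_quadruple(src, c(64, 64), 0.7, 6, 9)
  q2 <- make_stitch_quadruple(src, c(64, 64), 0.7, 6, 9)
  expect_identical(q1, q2)
  expect_identical(q1$overlap_class, "high")

  for (seed in 1:5) {
    req <- 0.45 + 0.08 * seed
    q <- make_stitch_quadruple(src, c(64, 64), req, 3, seed)
    expect_lt(abs(q$overlap_rate - req), 0.05)
    expect_identical(q$overlap_class, if (q$overlap_rate > 0.6) "high" else "low")
  }
  expect_error(make_stitch_quadruple(src, c(64, 64), 0.99, 20, 1), "not reachable")
})

test_that("stored offsets agree with an independent corner solve and warp oracle", {
  src <- generate_texture_image(42, c(192, 192), 0.7)
  corners <- oracle_corners(64, 64)
  for (seed in 1:4) {
    q <- make_stitch_quadruple(src, c(64, 64), 0.75, 6, seed)
    # independent SVD-based solve through the 4 corner correspondences
    Ho <- oracle_dlt(corners, corners + q$gt_offsets)
    rec <- t(apply(cbind(corners, 1) %*% t(Ho), 1, function(p) p[1:2] / p[3])) - corners
    expect_lt(max(abs(rec - q$gt_offsets)), 1e-6)
    # warping I_B by the implied homography reproduces I_A on the overlap
    Hm <- solve_homography(q$gt_offsets, q$size)
    cv <- warp_to_canvas(q$I_A, q$I_B, Hm)
    ov <- cv$M_AC > 0.999 & cv$M_BC > 0.999
    d <- abs(cv$I_AW - cv$I_BW)
    expect_lt(mean(d[array(ov, dim(d))]), 2)
  }
})

test_that("radial distortion follows the closed-form division model", {
  src <- generate_texture_image(11, c(64, 64), 0.5)
  expect_identical(apply_radial_distortion(src, 0), src)

  # a vertical line lands where the model says it must
  img <- array(235, c(512, 512, 3))
  img[, 456, ] <- 30                      # x = 455 (0-based), 199.5 px off-center
  k <- 3e-7
  dist <- apply_radial_distortion(img, k)
  row <- dist[256, , 1]                   # mid-height: radius ~ horizontal offset
  p <- which.min(row)
  win <- (p - 4):(p + 4)
  xhat <- sum((win - 1) * (235 - row[win])) / sum(235 - row[win])  # ink centroid
  r_u <- 455 - 255.5
  r_d <- (1 - sqrt(1 - 4 * k * r_u^2)) / (2 * k * r_u)
  expect_lt(abs(xhat - (255.5 + r_d)), 0.5)

  # monotonicity guard
  expect_error(apply_radial_distortion(img, 1e-4), "monotone")

  # round trip on smooth texture, central 50% crop
  tex <- generate_texture_image(12, c(256, 256), 0.7)
  rt <- undistort(apply_radial_distortion(tex, 5e-6 / 4), 5e-6 / 4)
  cr <- function(x) x[65:192, 65:192, , drop = FALSE]
  mse <- mean((cr(rt) - cr(tex))^2)
  expect_gt(10 * log10(255^2 / mse), 35)
})

test_that("dataset writing and reading round-trips", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, dir = dir, seed = 2, size = c(160, 160),
                         patch = c(64, 64))
  expect_length(readLines(file.path(dir, "index.txt")), 3)
  back <- read_dataset(dir)
  expect_length(back, 3)
  # PNG quantizes to 8 bits; offsets and overlap survive exactly
  expect_equal(back[[2]]$gt_offsets, ds[[2]]$gt_offsets, tolerance = 1e-6)
  expect_equal(back[[2]]$overlap_rate, ds[[2]]$overlap_rate, tolerance = 1e-6)
  expect_lt(max(abs(back[[2]]$I_B - ds[[2]]$I_B)), 0.51)
})
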