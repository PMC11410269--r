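test_that("warped vertices are plain corner sums", {
  z <- matrix(0, 4, 2)
  expect_equal(unname(warped_vertices(z, c(50, 100))), oracle_corners(50, 100))
  off <- matrix(c(5, 0, 5, 0, 5, 0, 5, 0), 4, 2, byrow = TRUE)
  v <- warped_vertices(off, c(50, 100))
  expect_equal(unname(v[, 1]), c(5, 104, 104, 5))
  set.seed(3)
  for (i in 1:5) {
    off <- matrix(runif(8, -9, 9), 4, 2)
    expect_equal(unname(warped_vertices(off, c(32, 40))),
                 oracle_corners(32, 40) + off)
  }
})

test_that("canvas is the minimal integer bounding rectangle", {
  sz <- c(40, 60)
  v0 <- warped_vertices(matrix(0, 4, 2), sz)
  c0 <- canvas_size(v0, sz)
  expect_equal(c(c0$h, c0$w), c(40, 60))
  expect_equal(c0$translation, c(0, 0))

  off_t <- matrix(rep(c(7, 3), 4), 4, 2, byrow = TRUE)  # pure translation
  ct <- canvas_size(warped_vertices(off_t, sz), sz)
  expect_equal(c(ct$h, ct$w), c(40 + 3, 60 + 7))

  set.seed(8)
  for (i in 1:10) {
    off <- matrix(runif(8, -10, 10), 4, 2)
    v <- warped_vertices(off, sz)
    cc <- canvas_size(v, sz)
    xs <- c(v[, 1], oracle_corners(sz[1], sz[2])[, 1])
    ys <- c(v[, 2], oracle_corners(sz[1], sz[2])[, 2])
    expect_equal(cc$w, as.integer(ceiling(max(xs)) - floor(min(xs)) + 1))
    expect_equal(cc$h, as.integer(ceiling(max(ys)) - floor(min(ys)) + 1))
    # minimality: shrinking by one pixel would exclude a corner
    expect_lt(max(xs) + cc$translation[1], cc$w - 1 + 1)
    expect_gt(max(xs) + cc$translation[1], cc$w - 2)
    expect_lt(max(ys) + cc$translation[2], cc$h)
    expect_gt(max(ys) + cc$translation[2], cc$h - 2)
  }
})

test_that("identity warp places the inputs bit-exactly and masks are binary", {
  src <- generate_texture_image(21, c(64, 72), 0.6)
  cv <- warp_to_canvas(src, src, diag(3))
  expect_equal(c(cv$h, cv$w), c(64, 72))
  expect_equal(cv$I_AW, src, ignore_attr = TRUE)
  expect_equal(cv$I_BW, src, ignore_attr = TRUE)
  expect_true(all(cv$M_AC %in% c(0, 1)))
  expect_true(all(cv$M_AC == 1))
})

test_that("sub-pixel translation reproduces hand-computed bilinear weights", {
  ramp <- array(0, c(4, 4, 3))
  for (c in 1:3) ramp[, , c] <- matrix(rep(seq(0, 30, by = 10), each = 4), 4, 4)
  off <- matrix(rep(c(1.5, 0), 4), 4, 2, byrow = TRUE)
  Hm <- solve_homography(off, c(4, 4))
  cv <- warp_to_canvas(ramp, ramp, Hm)
  # canvas column 4 (0-based) samples the target at u = 4 - 1.5 = 2.5:
  # the mean of ramp columns 2 and 3 (values 20 and 30)
  expect_equal(cv$translation, c(0, 0))
  expect_equal(cv$I_BW[2, 5, 1], (20 + 30) / 2)
})

test_that("canvas warping matches the per-pixel oracle and conserves area", {
  big1 <- generate_texture_image(22, c(64, 64), 0.8)
  big2 <- generate_texture_image(23, c(64, 64), 0.8)
  src <- big1[1:32, 1:32, , drop = FALSE]
  tgt <- big2[1:32, 1:32, , drop = FALSE]
  set.seed(9)
  for (i in 1:3) {
    off <- matrix(runif(8, -6, 6), 4, 2)
    Hm <- solve_homography(off, c(32, 32))
    cv <- warp_to_canvas(src, tgt, Hm)
    orc <- oracle_warp(tgt, Hm, cv$h, cv$w, cv$translation[1], cv$translation[2])
    expect_lt(max(abs(cv$I_BW - orc)), 1e-6)
    # reference mask keeps the input area exactly; the target mask covers the
    # warped quadrilateral, whose shoelace area it must match
    expect_equal(sum(cv$M_AC), 32 * 32)
    verts <- warped_vertices(off, c(32, 32))
    shoelace <- abs(sum(verts[, 1] * verts[c(2:4, 1), 2] -
                          verts[c(2:4, 1), 1] * verts[, 2])) / 2
    perim <- sum(sqrt(rowSums((verts - verts[c(2:4, 1), ])^2)))
    # corner coordinates are pixel centers; the sampled support extends half a
    # pixel beyond them (exact for the identity: 31^2 + 124/2 + 1 = 32^2)
    expected_area <- shoelace + perim / 2 + 1
    expect_lt(abs(sum(cv$M_BC) - expected_area) / expected_area, 0.02)
    expect_true(all(cv$M_BC >= 0 & cv$M_BC <= 1))
  }
})

test_that("composition: identity canvas crop recovers the input exactly", {
  src <- generate_texture_image(25, c(64, 64), 0.5)[1:40, 1:40, , drop = FALSE]
  off <- matrix(rep(c(6, -4), 4), 4, 2, byrow = TRUE)    # integer translation
  Hm <- solve_homography(off, c(40, 40))
  cv <- warp_to_canvas(src, src, Hm)
  tx <- cv$translation[1]; ty <- cv$translation[2]
  back <- cv$I_AW[(ty + 1):(ty + 40), (tx + 1):(tx + 40), , drop = FALSE]
  expect_equal(back, src, ignore_attr = TRUE)
})
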