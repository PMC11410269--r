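test_that("seam masks match an independent scalar implementation", {
  M_AC <- matrix(0, 8, 8); M_AC[, 1:5] <- 1
  M_BC <- matrix(0, 8, 8); M_BC[, 4:8] <- 1
  got <- seam_masks(M_AC, M_BC)
  want <- oracle_seam_masks(M_AC, M_BC)
  expect_equal(got$M_AS, want$M_AS)
  expect_equal(got$M_BS, want$M_BS)

  # constant all-ones masks: gradients vanish in the interior
  ones <- matrix(1, 12, 12)
  sm <- seam_masks(ones, ones)
  expect_true(all(sm$M_AS[5:8, 5:8] == 0))

  # disjoint supports far apart: both seam masks vanish
  L <- matrix(0, 24, 24); L[, 1:6] <- 1
  R <- matrix(0, 24, 24); R[, 18:24] <- 1
  smd <- seam_masks(L, R)
  expect_true(all(smd$M_AS == 0))
  expect_true(all(smd$M_BS == 0))

  expect_error(seam_masks(ones, matrix(1, 8, 8)), "differ")
})

test_that("seam masks are clipped and dominated by the content masks", {
  set.seed(19)
  for (i in 1:25) {
    M1 <- matrix(runif(100) < 0.5, 10, 10) * runif(1, 0.5, 1)
    M2 <- matrix(runif(100) < 0.5, 10, 10) * runif(1, 0.5, 1)
    sm <- seam_masks(M1, M2)
    expect_true(all(sm$M_AS >= 0 & sm$M_AS <= 1))
    expect_true(all(sm$M_BS >= 0 & sm$M_BS <= 1))
    expect_true(all(sm$M_AS <= M1 + 1e-12))
    expect_true(all(sm$M_BS <= M2 + 1e-12))
  }
})

test_that("low-res branch parameter count equals the published filter plan", {
  # independent layer-by-layer arithmetic for the printed plan
  # 64,64,128,128,256,256,512,512,256,256,128,128,64,64,3 with 3x3 kernels,
  # U-Net skip concatenations and three channel-preserving 2x2 deconvolutions
  ins <- c(6, 64, 64, 128, 128, 256, 256, 512, 512 + 256, 256, 256 + 128,
           128, 128 + 64, 64, 64)
  outs <- c(64, 64, 128, 128, 256, 256, 512, 512, 256, 256, 128, 128, 64, 64, 3)
  conv_expect <- sum(3 * 3 * ins * outs + outs)
  deconv_expect <- sum(2 * 2 * c(512, 256, 128)^2 + c(512, 256, 128))
  pc <- lowres_parameter_count(recon_config(base = 64L))
  expect_equal(unname(pc["conv"]), conv_expect)
  expect_equal(unname(pc["deconv"]), deconv_expect)
  expect_equal(unname(pc["total"]), conv_expect + deconv_expect)

  # the instantiated weights carry exactly that many parameters
  cfg4 <- recon_config(base = 4L, highres_channels = 8L, lowres_size = 32L)
  w <- init_recon_weights(cfg4, 1)
  n_lr <- sum(vapply(grep("^lr_", names(w$w), value = TRUE),
                     function(nm) length(w$w[[nm]]), numeric(1)))
  expect_equal(n_lr, unname(lowres_parameter_count(cfg4)["total"]))
})

test_that("branches produce correctly shaped, initialized outputs", {
  cfg <- test_rcfg()
  w <- init_recon_weights(cfg, 3)
  q <- fix_quadruple(seed = 8L)
  Hm <- solve_homography(q$gt_offsets, q$size)
  cv <- warp_to_canvas(q$I_A, q$I_B, Hm)
  S_LR <- lowres_branch(cv, w)
  expect_equal(dim(S_LR), c(32, 32, 3))
  expect_true(all(S_LR >= 0 & S_LR <= 255))
  S_HR <- highres_branch(S_LR, cv, w)
  expect_equal(dim(S_HR), c(cv$h, cv$w, 3L))
  # zero-initialized output convolution: exactly mid-grey everywhere
  expect_true(all(abs(S_HR - 127.5) < 1e-9))
})

test_that("C2f block preserves shape, widens as specified, and feeds every branch", {
  cfg <- test_rcfg()   # 8 channels, 2 bottlenecks
  w <- init_recon_weights(cfg, 4)
  f <- array(rnorm(12 * 10 * 8), c(12, 10, 8))
  out <- c2f_block(f, w)
  expect_equal(dim(out), dim(f))
  # concatenation width before fusion: (2 + n) * C / 2
  expect_equal(nrow(w$w[["c2f_out_w"]]), (2 + 2) * 8 / 2)
  expect_error(c2f_block(array(0, c(4, 4, 7)), w), "even")

  # every branch receives gradient: backward through the block reaches the
  # 1x1 input conv, both bottlenecks and the fusion conv
  tp <- endostitch:::nn_tape()
  xn <- endostitch:::nn_const(tp, f)
  y <- endostitch:::c2f_forward(tp, w, xn, cfg)
  loss <- endostitch:::nn_l1(tp, y, array(0, dim(f)))
  endostitch:::nn_backward(tp, loss)
  g <- endostitch:::collect_grads(tp)
  for (nm in c("c2f_in_w", "c2f_bn1_w1", "c2f_bn2_w1", "c2f_out_w")) {
    expect_gt(max(abs(g[[nm]])), 0)
  }
  # one gradient verified against finite differences
  fd <- function(delta) {
    w2 <- init_recon_weights(cfg, 4)
    w2$w[["c2f_bn1_w1"]][1] <- w2$w[["c2f_bn1_w1"]][1] + delta
    tp2 <- endostitch:::nn_tape()
    endostitch:::nn_l1(tp2, endostitch:::c2f_forward(tp2, w2, endostitch:::nn_const(tp2, f), cfg),
                       array(0, dim(f)))$val
  }
  num <- (fd(1e-5) - fd(-1e-5)) / 2e-5
  expect_equal(num, g[["c2f_bn1_w1"]][1], tolerance = 1e-4)
})

test_that("loss fixed points and exact decomposition", {
  cfg <- test_rcfg()
  w <- init_recon_weights(cfg, 5)
  src <- generate_texture_image(9, c(96, 96), 0.7)
  cv <- warp_to_canvas(src, src, diag(3))   # identical warps, full overlap
  masks <- seam_masks(cv$M_AC, cv$M_BC)
  S <- cfg$lowres_size
  S_LR <- resize_image(src, S, S, "area")
  ls <- reconstruction_loss(S_LR, src, cv, masks, w)
  # consistency term: S_LR equals the downsampled S_HR by construction
  expect_lt(ls$consistency, 1e-10)
  # identical content, all-ones masks: content and seam terms vanish
  expect_lt(ls$content_l, 1e-6)
  expect_lt(ls$content_h, 1e-6)
  expect_equal(ls$seam_l, 0)
  expect_equal(ls$seam_h, 0)

  # decomposition at the default weights
  q <- fix_quadruple(seed = 13L)
  Hm <- solve_homography(q$gt_offsets, q$size)
  cv2 <- warp_to_canvas(q$I_A, q$I_B, Hm)
  m2 <- seam_masks(cv2$M_AC, cv2$M_BC)
  S_LR2 <- lowres_branch(cv2, w)
  S_HR2 <- highres_branch(S_LR2, cv2, w)
  lw <- loss_weights()
  expect_equal(lw$lambda_s, 2)
  expect_equal(lw$lambda_c, 1e-6)
  ls2 <- reconstruction_loss(S_LR2, S_HR2, cv2, m2, w, lw)
  expect_equal(ls2$l_lr, lw$lambda_c * ls2$content_l + lw$lambda_s * ls2$seam_l,
               tolerance = 1e-9)
  expect_equal(ls2$total,
               lw$w_lr * ls2$l_lr + lw$w_hr * ls2$l_hr + lw$w_cs * ls2$consistency,
               tolerance = 1e-6)
})

test_that("a short optimization run reduces the reconstruction objective", {
  cfg <- test_rcfg()
  hcfg <- test_hcfg()
  hw <- init_homography_weights(hcfg, 1)   # identity predictions suffice here
  ds <- lapply(1:2, function(i) fix_quadruple(seed = 70L + i, patch = c(48L, 48L),
                                              overlap = 0.85, shift = 3,
                                              src_size = c(160L, 160L)))
  w <- train_reconstruction(ds, hw, cfg = cfg, epochs = 3L, lr = 3e-3, seed = 2)
  log <- attr(w, "loss_log")
  expect_length(log, 3L)
  expect_lt(log[3], log[1])
})

test_that("stitching failures surface with the stage name", {
  cfg <- test_rcfg()
  hcfg <- test_hcfg()
  hw <- init_homography_weights(hcfg, 1)
  rw <- init_recon_weights(cfg, 1)
  q <- fix_quadruple(seed = 90L)
  bad_B <- q$I_B[1:32, 1:32, , drop = FALSE]
  expect_error(stitch(q$I_A, bad_B, hw, rw), "predict_offsets")
  res <- stitch(q$I_A, q$I_B, hw, rw)
  expect_s3_class(res, "stitch_result")
  expect_true(all(is.finite(res$S_HR)))
})
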