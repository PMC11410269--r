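# ---- unsupervised feature-to-pixel reconstruction --------------------------
# Two branches resolve the ghosting a single homography leaves behind: a
# low-resolution encoder-decoder learns the deformation rules of the stitch at
# a fixed working resolution, and a fully convolutional high-resolution branch
# (three convolutions, eight residual blocks and a C2f feature-mixing block)
# refines the result at canvas resolution. Training needs no ground truth:
# content terms pull each branch output toward the warped inputs on their
# content masks, seam terms enforce photometric continuity in the seam bands,
# and a consistency term ties the two branches together.

#' Configuration of the reconstruction networks
#'
#' @param base filter count of the first low-res encoder stage; the printed
#'   encoder-decoder plan uses
#'   `base * c(1, 1, 2, 2, 4, 4, 8, 8, 4, 4, 2, 2, 1, 1)` followed by a
#'   3-channel output convolution (default `base = 64` gives the plan
#'   64, 64, 128, 128, 256, 256, 512, 512, 256, 256, 128, 128, 64, 64, 3).
#' @param highres_channels working width of the high-resolution branch.
#' @param lowres_size working resolution of the low-res branch (multiple
#'   of 8).
#' @param c2f_bottlenecks residual bottlenecks inside the C2f block.
#' @param perceptual_channels channel plan of the frozen feature extractor
#'   behind the perceptual loss.
#' @param perceptual_seed seed of the frozen extractor weights.
#' @return list of class `"recon_config"`.
#' @export
recon_config <- function(base = 64L, highres_channels = 64L, lowres_size = 256L,
                         c2f_bottlenecks = 2L, perceptual_channels = c(16L, 32L, 48L),
                         perceptual_seed = 909L) {
  stopifnot(lowres_size %% 8L == 0L, highres_channels %% 2L == 0L)
  structure(list(base = as.integer(base),
                 highres_channels = as.integer(highres_channels),
                 lowres_size = as.integer(lowres_size),
                 c2f_bottlenecks = as.integer(c2f_bottlenecks),
                 perceptual_channels = as.integer(perceptual_channels),
                 perceptual_seed = as.integer(perceptual_seed)),
            class = "recon_config")
}

#' Loss weights of the reconstruction objective
#'
#' Defaults follow the published schedule: content coefficient `1e-6` (the
#' perceptual distance is an unnormalized feature sum, which this coefficient
#' rescales), seam coefficient 2, and stage weights 100 / 1 / 1 for the
#' low-resolution, high-resolution and consistency terms.
#' @param lambda_c,lambda_s content / seam coefficients.
#' @param w_lr,w_hr,w_cs stage weights.
#' @return list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_c = 1e-6, lambda_s = 2, w_lr = 100, w_hr = 1,
                         w_cs = 1) {
  stopifnot(lambda_c >= 0, lambda_s >= 0, w_lr >= 0, w_hr >= 0, w_cs >= 0)
  structure(list(lambda_c = lambda_c, lambda_s = lambda_s,
                 w_lr = w_lr, w_hr = w_hr, w_cs = w_cs),
            class = "loss_weights")
}

# Channel plan of the low-res encoder-decoder for a given base width:
# list of (in, out) per 3x3 convolution, plus deconv widths.
lowres_plan <- function(base) {
  w <- base
  list(conv_in = c(6, w, w, 2 * w, 2 * w, 4 * w, 4 * w,       # conv1..7 input
                   8 * w, 12 * w, 4 * w, 6 * w, 2 * w, 3 * w, w, w),
       conv_out = c(w, w, 2 * w, 2 * w, 4 * w, 4 * w, 8 * w,
                    8 * w, 4 * w, 4 * w, 2 * w, 2 * w, w, w, 3),
       deconv = c(8 * w, 4 * w, 2 * w))
}

#' Initialize reconstruction-network weights
#'
#' He initialization throughout except the two output convolutions, which are
#' zero-initialized so both branches start from a neutral 0.5 grey (the
#' bounded output activation is centered there).
#' @param cfg a `"recon_config"`.
#' @param seed integer seed.
#' @return a parameter store with attribute `cfg`.
#' @export
init_recon_weights <- function(cfg = recon_config(), seed = 1L) {
  plan <- lowres_plan(cfg$base)
  w <- with_seed(seed, {
    w <- list()
    for (i in seq_along(plan$conv_out)) {
      ci <- plan$conv_in[i]; co <- plan$conv_out[i]
      w[[sprintf("lr_w%d", i)]] <-
        if (i == length(plan$conv_out)) array(0, c(9 * ci, co))
        else he_init(9 * ci, 9 * ci * co, c(9 * ci, co))
      w[[sprintf("lr_b%d", i)]] <- numeric(co)
    }
    for (i in seq_along(plan$deconv)) {
      cd <- plan$deconv[i]
      w[[sprintf("lr_dw%d", i)]] <- he_init(4 * cd, 4 * cd * cd, c(2, 2, cd, cd))
      w[[sprintf("lr_db%d", i)]] <- numeric(cd)
    }
    ch <- cfg$highres_channels
    hin <- c(9, ch, ch)
    for (i in 1:3) {
      w[[sprintf("hr_w%d", i)]] <- he_init(9 * hin[i], 9 * hin[i] * ch, c(9 * hin[i], ch))
      w[[sprintf("hr_b%d", i)]] <- numeric(ch)
    }
    for (r in 1:8) for (j in 1:2) {
      w[[sprintf("hr_res%d_w%d", r, j)]] <- he_init(9 * ch, 9 * ch * ch, c(9 * ch, ch))
      w[[sprintf("hr_res%d_b%d", r, j)]] <- numeric(ch)
    }
    c2 <- ch %/% 2L
    w[["c2f_in_w"]] <- he_init(ch, ch * ch, c(ch, ch))
    w[["c2f_in_b"]] <- numeric(ch)
    for (n in seq_len(cfg$c2f_bottlenecks)) for (j in 1:2) {
      w[[sprintf("c2f_bn%d_w%d", n, j)]] <- he_init(9 * c2, 9 * c2 * c2, c(9 * c2, c2))
      w[[sprintf("c2f_bn%d_b%d", n, j)]] <- numeric(c2)
    }
    cc <- (2L + cfg$c2f_bottlenecks) * c2
    w[["c2f_out_w"]] <- he_init(cc, cc * ch, c(cc, ch))
    w[["c2f_out_b"]] <- numeric(ch)
    w[["hr_out_w"]] <- array(0, c(9 * ch, 3))
    w[["hr_out_b"]] <- numeric(3)
    w
  })
  pc <- cfg$perceptual_channels
  w <- c(w, with_seed(cfg$perceptual_seed, {
    p <- list()
    cin <- 3L
    for (i in seq_along(pc)) {
      p[[sprintf("perc_w%d", i)]] <- he_init(9 * cin, 9 * cin * pc[i], c(9 * cin, pc[i]))
      p[[sprintf("perc_b%d", i)]] <- numeric(pc[i])
      cin <- pc[i]
    }
    p
  }))
  st <- param_store(w)
  attr(st, "cfg") <- cfg
  st
}

#' Parameter count of the low-resolution branch
#'
#' Counts the weights and biases of the 15 convolutions and 3 transposed
#' convolutions implied by the filter plan.
#' @param cfg a `"recon_config"`.
#' @return named integer vector with `conv`, `deconv` and `total`.
#' @export
lowres_parameter_count <- function(cfg = recon_config()) {
  plan <- lowres_plan(cfg$base)
  conv <- sum(9 * plan$conv_in * plan$conv_out + plan$conv_out)
  deconv <- sum(4 * plan$deconv^2 + plan$deconv)
  c(conv = conv, deconv = deconv, total = conv + deconv)
}

# ---- seam masks -------------------------------------------------------------

# forward-difference gradient magnitude with zero-padded border
mask_grad <- function(M) {
  H <- nrow(M); W <- ncol(M)
  up <- rbind(0, M[-H, , drop = FALSE])
  left <- cbind(0, M[, -W, drop = FALSE])
  abs(M - up) + abs(M - left)
}

# zero-padded convolution with the all-ones 3x3 kernel
box3 <- function(M) {
  H <- nrow(M); W <- ncol(M)
  mp <- matrix(0, H + 2, W + 2)
  mp[2:(H + 1), 2:(W + 1)] <- M
  mp[1:H, 1:W] + mp[1:H, 2:(W + 1)] + mp[1:H, 3:(W + 2)] +
    mp[2:(H + 1), 1:W] + mp[2:(H + 1), 2:(W + 1)] + mp[2:(H + 1), 3:(W + 2)] +
    mp[3:(H + 2), 1:W] + mp[3:(H + 2), 2:(W + 1)] + mp[3:(H + 2), 3:(W + 2)]
}

#' Seam masks from the content masks
#'
#' The seam band of one image is where the *other* image's content boundary
#' crosses its own content: the content-mask gradient
#' `|M[i,j] - M[i-1,j]| + |M[i,j] - M[i,j-1]|` (zero-padded border) is dilated
#' by three all-ones 3x3 convolutions, clipped to `[0, 1]`, and multiplied by
#' this image's content mask.
#' @param M_AC,M_BC content masks (H* x W*, values in `[0, 1]`).
#' @return list with `M_AS` and `M_BS`.
#' @export
seam_masks <- function(M_AC, M_BC) {
  if (!all(dim(M_AC) == dim(M_BC))) stop("mask sizes differ", call. = FALSE)
  M_AS <- clamp(box3(box3(box3(mask_grad(M_BC)))), 0, 1) * M_AC
  M_BS <- clamp(box3(box3(box3(mask_grad(M_AC)))), 0, 1) * M_BC
  list(M_AS = M_AS, M_BS = M_BS)
}

# ---- network branches -------------------------------------------------------

conv_block <- function(tape, x, store, wname, bname, act = "relu") {
  y <- nn_conv3(tape, x, nn_param(tape, store, wname), nn_param(tape, store, bname))
  switch(act, relu = nn_relu(tape, y), sigmoid = nn_sigmoid(tape, y), none = y)
}

forward_lowres <- function(tape, store, inp, cfg) {
  x <- nn_const(tape, inp)
  skips <- list()
  i <- 0L
  conv <- function(x, act = "relu") {
    force(x)  # nested calls must consume layer indices inside-out
    i <<- i + 1L
    conv_block(tape, x, store, sprintf("lr_w%d", i), sprintf("lr_b%d", i), act)
  }
  x <- conv(conv(x))                        # conv1-2 @ S
  skips[[1]] <- x
  x <- conv(conv(nn_pool2(tape, x)))        # conv3-4 @ S/2
  skips[[2]] <- x
  x <- conv(conv(nn_pool2(tape, x)))        # conv5-6 @ S/4
  skips[[3]] <- x
  x <- conv(conv(nn_pool2(tape, x)))        # conv7-8 @ S/8
  for (d in 1:3) {
    x <- nn_deconv2(tape, x, nn_param(tape, store, sprintf("lr_dw%d", d)),
                    nn_param(tape, store, sprintf("lr_db%d", d)))
    x <- nn_concat(tape, list(x, skips[[4L - d]]))
    x <- conv(conv(x))                      # conv9-10 / 11-12 / 13-14
  }
  conv(x, act = "sigmoid")                  # conv15 -> S_LR in [0, 1]
}

c2f_forward <- function(tape, store, x, cfg) {
  ch <- dim(x$val)[3]
  c2 <- ch %/% 2L
  y <- nn_conv1(tape, x, nn_param(tape, store, "c2f_in_w"),
                nn_param(tape, store, "c2f_in_b"))
  split_node <- function(y, from, to) {
    d <- dim(y$val)
    nn_node(tape, y$val[, , from:to, drop = FALSE], parents = list(y),
            backfn = function(g) {
              gy <- array(0, d)
              gy[, , from:to] <- g
              list(gy)
            })
  }
  h1 <- split_node(y, 1L, c2)
  h2 <- split_node(y, c2 + 1L, ch)
  retained <- list(h1, h2)
  z <- h2
  for (n in seq_len(cfg$c2f_bottlenecks)) {
    b <- nn_relu(tape, nn_conv3(tape, z,
                                nn_param(tape, store, sprintf("c2f_bn%d_w1", n)),
                                nn_param(tape, store, sprintf("c2f_bn%d_b1", n))))
    b <- nn_conv3(tape, b, nn_param(tape, store, sprintf("c2f_bn%d_w2", n)),
                  nn_param(tape, store, sprintf("c2f_bn%d_b2", n)))
    z <- nn_add(tape, z, b)
    retained[[length(retained) + 1L]] <- z
  }
  cat_node <- nn_concat(tape, retained)
  nn_conv1(tape, cat_node, nn_param(tape, store, "c2f_out_w"),
           nn_param(tape, store, "c2f_out_b"))
}

forward_highres <- function(tape, store, S_LR, canvas, cfg, upw = NULL) {
  if (is.null(upw))
    upw <- list(Rw = resize_weights(dim(S_LR$val)[1], canvas$h, "bilinear"),
                Cw = resize_weights(dim(S_LR$val)[2], canvas$w, "bilinear"))
  up <- nn_resize(tape, S_LR, upw$Rw, upw$Cw)
  x <- nn_concat(tape, list(up, nn_const(tape, canvas$I_AW / 255),
                            nn_const(tape, canvas$I_BW / 255)))
  for (i in 1:3)
    x <- conv_block(tape, x, store, sprintf("hr_w%d", i), sprintf("hr_b%d", i))
  for (r in 1:8) {
    b <- conv_block(tape, x, store, sprintf("hr_res%d_w1", r), sprintf("hr_res%d_b1", r))
    b <- conv_block(tape, b, store, sprintf("hr_res%d_w2", r), sprintf("hr_res%d_b2", r), "none")
    x <- nn_add(tape, x, b)
  }
  x <- c2f_forward(tape, store, x, cfg)
  conv_block(tape, x, store, "hr_out_w", "hr_out_b", act = "sigmoid")
}

#' Run the low-resolution deformation branch
#'
#' Downsamples the two warped images to the working resolution, concatenates
#' them (6 channels) and reconstructs the stitched image with the
#' encoder-decoder (3 poolings, 3 transposed convolutions, skip connections at
#' equal resolutions).
#' @param canvas a `"stitch_canvas"`.
#' @param weights reconstruction parameter store.
#' @param cfg a `"recon_config"` (defaults to the store's).
#' @return S_LR, `lowres_size^2 x 3` array in `[0, 255]`.
#' @export
lowres_branch <- function(canvas, weights, cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(weights, "cfg")
  S <- cfg$lowres_size
  inp <- array(0, c(S, S, 6L))
  inp[, , 1:3] <- resize_image(canvas$I_AW / 255, S, S, "area")
  inp[, , 4:6] <- resize_image(canvas$I_BW / 255, S, S, "area")
  tp <- nn_tape()
  forward_lowres(tp, weights, inp, cfg)$val * 255
}

#' Run the high-resolution refinement branch
#'
#' Upsamples `S_LR` to canvas resolution, concatenates it with both warped
#' images (9 channels) and refines through 3 convolutions, 8 residual blocks
#' and the C2f block.
#' @param S_LR low-resolution stitch in `[0, 255]`.
#' @param canvas a `"stitch_canvas"`.
#' @param weights reconstruction parameter store.
#' @param cfg a `"recon_config"`.
#' @return S_HR, `H* x W* x 3` array in `[0, 255]`.
#' @export
highres_branch <- function(S_LR, canvas, weights, cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(weights, "cfg")
  tp <- nn_tape()
  forward_highres(tp, weights, nn_const(tp, S_LR / 255), canvas, cfg)$val * 255
}

#' Apply a C2f feature-mixing block
#'
#' 1x1 convolution, channel split into halves, one half threaded through
#' `n` residual bottlenecks with every intermediate retained, concatenation of
#' all retained tensors and a fusing 1x1 convolution back to the input width.
#' @param features H x W x C array (C even, matching the stored widths).
#' @param weights reconstruction parameter store.
#' @param cfg a `"recon_config"`.
#' @return H x W x C array.
#' @export
c2f_block <- function(features, weights, cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(weights, "cfg")
  if (dim(features)[3] %% 2L != 0L) stop("channel count must be even", call. = FALSE)
  tp <- nn_tape()
  c2f_forward(tp, weights, nn_const(tp, features), cfg)$val
}

# ---- losses -----------------------------------------------------------------

# Frozen-extractor feature pyramid of a node; features kept at 1/4 and 1/8
# resolution.
perc_feat_nodes <- function(tape, store, f) {
  keep <- list()
  for (i in seq_along(grep("^perc_w", names(store$w)))) {
    wn <- nn_const(tape, store$w[[sprintf("perc_w%d", i)]])
    bn <- nn_const(tape, store$w[[sprintf("perc_b%d", i)]])
    f <- nn_pool2(tape, nn_relu(tape, nn_conv3(tape, f, wn, bn)))
    if (i >= 2L) keep[[length(keep) + 1L]] <- f
  }
  keep
}

# Features of a constant image (plain arrays, reusable across steps).
perc_feats_const <- function(store, x) {
  tp <- nn_tape()
  lapply(perc_feat_nodes(tp, store, nn_const(tp, x)), function(nd) nd$val)
}

# Perceptual distance of a node against precomputed constant features:
# sum of absolute feature differences over both scales.
perceptual_l1 <- function(tape, store, a, fb) {
  fa <- perc_feat_nodes(tape, store, a)
  terms <- lapply(seq_along(fa), function(i) nn_l1(tape, fa[[i]], fb[[i]], reduce = "sum"))
  nn_add_scalar_nodes(tape, terms)
}

as3 <- function(m) array(rep(m, 3L), c(dim(m), 3L))

# Constant tensors of the loss for one sample; computed once per sample.
recon_loss_consts <- function(canvas, masks, store, cfg) {
  S <- cfg$lowres_size
  dn <- function(x) resize_image(x, S, S, "area")
  I_AW <- canvas$I_AW / 255; I_BW <- canvas$I_BW / 255
  MAC_lr <- dn(canvas$M_AC); MBC_lr <- dn(canvas$M_BC)
  sm_lr <- seam_masks(MAC_lr, MBC_lr)
  A_lr <- dn(I_AW); B_lr <- dn(I_BW)
  hp <- as.integer(ceiling(canvas$h / 8) * 8)
  wp <- as.integer(ceiling(canvas$w / 8) * 8)
  inp <- array(0, c(S, S, 6L))
  inp[, , 1:3] <- A_lr
  inp[, , 4:6] <- B_lr
  list(inp = inp, hp = hp, wp = wp,
       I_AW = I_AW, I_BW = I_BW,
       fA_lr = perc_feats_const(store, A_lr),
       fB_lr = perc_feats_const(store, B_lr),
       fA_h = perc_feats_const(store, pad_pool(I_AW)),
       fB_h = perc_feats_const(store, pad_pool(I_BW)),
       MAC_lr3 = as3(MAC_lr), MBC_lr3 = as3(MBC_lr),
       MAS_lr3 = as3(sm_lr$M_AS), MBS_lr3 = as3(sm_lr$M_BS),
       MAC3 = as3(canvas$M_AC), MBC3 = as3(canvas$M_BC),
       MAS3 = as3(masks$M_AS), MBS3 = as3(masks$M_BS),
       Rw = resize_weights(canvas$h, S, "area"),
       Cw = resize_weights(canvas$w, S, "area"),
       upw = list(Rw = resize_weights(S, canvas$h, "bilinear"),
                  Cw = resize_weights(S, canvas$w, "bilinear")))
}

# Build the full loss graph from the cached constants.
recon_loss_nodes <- function(tape, store, S_LR, S_HR, cc, lw) {
  content_l <- nn_add_scalar_nodes(tape, list(
    perceptual_l1(tape, store, nn_mul_const(tape, S_LR, cc$MAC_lr3), cc$fA_lr),
    perceptual_l1(tape, store, nn_mul_const(tape, S_LR, cc$MBC_lr3), cc$fB_lr)))
  A_lr <- cc$inp[, , 1:3, drop = FALSE]
  B_lr <- cc$inp[, , 4:6, drop = FALSE]
  seam_l <- nn_add_scalar_nodes(tape, list(
    nn_l1(tape, nn_mul_const(tape, S_LR, cc$MAS_lr3), A_lr * cc$MAS_lr3),
    nn_l1(tape, nn_mul_const(tape, S_LR, cc$MBS_lr3), B_lr * cc$MBS_lr3)))
  content_h <- nn_add_scalar_nodes(tape, list(
    perceptual_l1(tape, store,
                  nn_pad(tape, nn_mul_const(tape, S_HR, cc$MAC3), cc$hp, cc$wp),
                  cc$fA_h),
    perceptual_l1(tape, store,
                  nn_pad(tape, nn_mul_const(tape, S_HR, cc$MBC3), cc$hp, cc$wp),
                  cc$fB_h)))
  seam_h <- nn_add_scalar_nodes(tape, list(
    nn_l1(tape, nn_mul_const(tape, S_HR, cc$MAS3), cc$I_AW * cc$MAS3),
    nn_l1(tape, nn_mul_const(tape, S_HR, cc$MBS3), cc$I_BW * cc$MBS3)))
  cs <- nn_l1(tape, nn_sub(tape, nn_resize(tape, S_HR, cc$Rw, cc$Cw), S_LR), 0)
  l_lr <- nn_add_scalar_nodes(tape, list(content_l, seam_l), c(lw$lambda_c, lw$lambda_s))
  l_hr <- nn_add_scalar_nodes(tape, list(content_h, seam_h), c(lw$lambda_c, lw$lambda_s))
  total <- nn_add_scalar_nodes(tape, list(l_lr, l_hr, cs), c(lw$w_lr, lw$w_hr, lw$w_cs))
  list(content_l = content_l, seam_l = seam_l, content_h = content_h,
       seam_h = seam_h, consistency = cs, l_lr = l_lr, l_hr = l_hr, total = total)
}

# images fed to the perceptual extractor must pool twice; pad odd sizes
pad_pool <- function(x) {
  d <- dim(x)
  H <- ceiling(d[1] / 8) * 8
  W <- ceiling(d[2] / 8) * 8
  if (H == d[1] && W == d[2]) return(x)
  out <- array(0, c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  out
}

#' Reconstruction objective breakdown
#'
#' Evaluates the composite objective: perceptual content terms (each branch
#' output, masked by the content masks, against the corresponding warped
#' image), L1 seam terms on the seam bands, the scale-consistency L1 between
#' the downsampled high-res output and the low-res output, the per-stage
#' weighted sums and the total.
#' @param S_LR,S_HR branch outputs in `[0, 255]`.
#' @param canvas a `"stitch_canvas"`.
#' @param masks seam masks from [seam_masks()] at canvas resolution.
#' @param weights reconstruction parameter store (frozen perceptual
#'   extractor).
#' @param lw a `"loss_weights"`.
#' @return named list of numeric loss components.
#' @export
reconstruction_loss <- function(S_LR, S_HR, canvas, masks, weights,
                                lw = loss_weights()) {
  cfg <- attr(weights, "cfg")
  cc <- recon_loss_consts(canvas, masks, weights, cfg)
  tp <- nn_tape()
  nodes <- recon_loss_nodes(tp, weights, nn_const(tp, S_LR / 255),
                            nn_const(tp, S_HR / 255), cc, lw)
  out <- lapply(nodes, function(nd) nd$val)
  for (nm in names(out))
    if (!is.finite(out[[nm]])) stop("non-finite loss term: ", nm, call. = FALSE)
  out
}

# ---- training and inference -------------------------------------------------

# Precompute the per-sample stitching geometry and loss constants under
# frozen homography weights.
prepare_canvases <- function(dataset, hweights, rweights = NULL, cfg = NULL) {
  lapply(dataset, function(q) {
    off <- predict_offsets(q$I_A, q$I_B, hweights)
    Hm <- solve_homography(off, dim(q$I_A)[1:2])
    canvas <- warp_to_canvas(q$I_A, q$I_B, Hm)
    masks <- seam_masks(canvas$M_AC, canvas$M_BC)
    out <- list(canvas = canvas, masks = masks, off = off)
    if (!is.null(rweights))
      out$cc <- recon_loss_consts(canvas, masks, rweights, cfg)
    out
  })
}

#' Train the reconstruction networks
#'
#' Freezes the homography weights, warps every sample into its stitching
#' canvas once, then minimizes the composite objective with Adam, one sample
#' per step.
#' @param dataset list of `"quadruple"` samples or a dataset directory.
#' @param hweights trained homography parameter store (frozen).
#' @param weights reconstruction store to continue from; fresh when `NULL`.
#' @param cfg a `"recon_config"` (ignored when `weights` given).
#' @param lw a `"loss_weights"`.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @param verbose print per-epoch mean loss.
#' @return trained parameter store; per-epoch mean losses in attribute
#'   `loss_log`.
#' @export
train_reconstruction <- function(dataset, hweights, weights = NULL,
                                 cfg = recon_config(), lw = loss_weights(),
                                 epochs = 20L, lr = 1e-4, seed = 1L,
                                 verbose = FALSE) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (is.null(weights)) weights <- init_recon_weights(cfg, seed)
  cfg <- attr(weights, "cfg")
  geom <- prepare_canvases(dataset, hweights, weights, cfg)
  n <- length(dataset)
  log <- numeric(0)
  orders <- with_seed(seed, replicate(epochs, sample.int(n), simplify = FALSE))
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (i in orders[[ep]]) {
      g <- geom[[i]]
      tp <- nn_tape()
      S_LR <- forward_lowres(tp, weights, g$cc$inp, cfg)
      S_HR <- forward_highres(tp, weights, S_LR, g$canvas, cfg, upw = g$cc$upw)
      nodes <- recon_loss_nodes(tp, weights, S_LR, S_HR, g$cc, lw)
      if (!is.finite(nodes$total$val))
        stop("reconstruction training diverged (non-finite loss)", call. = FALSE)
      nn_backward(tp, nodes$total)
      adam_step(weights, collect_grads(tp), lr = lr)
      tot <- tot + nodes$total$val
    }
    log <- c(log, tot / n)
    if (verbose) message(sprintf("epoch %d/%d: mean loss %.5f", ep, epochs, tot / n))
  }
  attr(weights, "loss_log") <- log
  weights
}

#' Stitch two images
#'
#' The full inference path: optional radial-distortion correction, four-point
#' homography prediction, stitching-domain warping, seam-mask computation and
#' the two reconstruction branches. Any stage failure is reported with the
#' stage name.
#' @param I_A,I_B images (H x W x 3, same size).
#' @param hweights,rweights trained homography / reconstruction stores.
#' @param lw a `"loss_weights"` for the reported loss breakdown.
#' @param distortion a `"distortion_model"` applied to both inputs first, or
#'   `NULL`.
#' @return object of class `"stitch_result"`: `S_LR`, `S_HR` (in `[0, 255]`),
#'   `offsets`, `canvas`, `masks` and `losses`.
#' @export
stitch <- function(I_A, I_B, hweights, rweights, lw = loss_weights(),
                   distortion = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stitching failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(distortion)) {
    I_A <- stage("undistort", undistort(I_A, distortion))
    I_B <- stage("undistort", undistort(I_B, distortion))
    attr(I_A, "valid") <- NULL
    attr(I_B, "valid") <- NULL
  }
  off <- stage("predict_offsets", predict_offsets(I_A, I_B, hweights))
  Hm <- stage("solve_homography", solve_homography(off, dim(I_A)[1:2]))
  canvas <- stage("warp_to_canvas", warp_to_canvas(I_A, I_B, Hm))
  masks <- stage("seam_masks", seam_masks(canvas$M_AC, canvas$M_BC))
  cfg <- attr(rweights, "cfg")
  S_LR <- stage("lowres_branch", lowres_branch(canvas, rweights, cfg))
  S_HR <- stage("highres_branch", highres_branch(S_LR, canvas, rweights, cfg))
  losses <- stage("loss", reconstruction_loss(S_LR, S_HR, canvas, masks, rweights, lw))
  if (any(!is.finite(S_HR))) stop("stitching failed at stage 'highres_branch': non-finite output", call. = FALSE)
  structure(list(S_LR = S_LR, S_HR = S_HR, offsets = off, canvas = canvas,
                 masks = masks, losses = losses),
            class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat("stitch result: canvas ", dim(x$S_HR)[1], " x ", dim(x$S_HR)[2],
      ", total loss ", format(x$losses$total, digits = 4), "\n", sep = "")
  cat("  offsets (px):", paste(sprintf("%.1f", x$offsets), collapse = " "), "\n")
  invisible(x)
}
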