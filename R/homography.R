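# ---- unsupervised multi-scale homography estimation ------------------------
# A shared-weight convolutional pyramid encodes both views; from the coarsest
# level down, a local correlation volume between the reference features and
# the (pre-aligned) target features feeds a small regression head that
# predicts a residual four-point offset, added to the upscaled running
# estimate. Training minimizes the ablation-masked photometric objective: the
# reference is multiplied by the warped all-ones validity mask so pixels the
# warped target cannot cover contribute nothing.

#' Configuration of the homography network
#'
#' @param levels pyramid levels (>= 2); level `l` works at scale `1 / 2^l`.
#' @param channels feature channels per level (coarse entries last).
#' @param corr_radius local correlation radius per level, in level pixels.
#' @param head_channels channels of the two regression-head convolutions.
#' @param max_offset bound (px) on the predicted corner motion, applied as a
#'   smooth `max_offset * tanh(x / max_offset)` clamp.
#' @return list of class `"homography_config"`.
#' @export
homography_config <- function(levels = 3L, channels = c(32L, 64L, 96L),
                              corr_radius = c(4L, 4L, 2L),
                              head_channels = c(48L, 32L), max_offset = 16) {
  levels <- as.integer(levels)
  stopifnot(levels >= 2L, length(channels) == levels, length(corr_radius) == levels)
  structure(list(levels = levels, channels = as.integer(channels),
                 corr_radius = as.integer(corr_radius),
                 head_channels = as.integer(head_channels),
                 max_offset = max_offset),
            class = "homography_config")
}

#' Initialize homography-network weights
#'
#' Convolutions are He-initialized; the per-level regression heads' final
#' fully connected layers are zero-initialized, so an untrained network
#' predicts exactly zero offsets (residual parameterization).
#' @param cfg a `"homography_config"`.
#' @param seed integer seed.
#' @return a parameter store (environment) with attribute `cfg`.
#' @export
init_homography_weights <- function(cfg = homography_config(), seed = 1L) {
  w <- with_seed(seed, {
    w <- list()
    cin <- 3L
    for (l in seq_len(cfg$levels)) {
      cl <- cfg$channels[l]
      w[[sprintf("enc%d_w1", l)]] <- he_init(9 * cin, 9 * cin * cl, c(9 * cin, cl))
      w[[sprintf("enc%d_b1", l)]] <- numeric(cl)
      w[[sprintf("enc%d_w2", l)]] <- he_init(9 * cl, 9 * cl * cl, c(9 * cl, cl))
      w[[sprintf("enc%d_b2", l)]] <- numeric(cl)
      cin <- cl
    }
    for (l in seq_len(cfg$levels)) {
      nc <- (2L * cfg$corr_radius[l] + 1L)^2
      h1 <- cfg$head_channels[1]; h2 <- cfg$head_channels[2]
      w[[sprintf("head%d_w1", l)]] <- he_init(9 * nc, 9 * nc * h1, c(9 * nc, h1))
      w[[sprintf("head%d_b1", l)]] <- numeric(h1)
      w[[sprintf("head%d_w2", l)]] <- he_init(9 * h1, 9 * h1 * h2, c(9 * h1, h2))
      w[[sprintf("head%d_b2", l)]] <- numeric(h2)
      w[[sprintf("head%d_wfc", l)]] <- matrix(0, h2, 8L)
      w[[sprintf("head%d_bfc", l)]] <- numeric(8L)
    }
    w
  })
  st <- param_store(w)
  attr(st, "cfg") <- cfg
  st
}

# Shared encoder: returns list of per-level feature nodes (scale 1/2^l).
hnet_encode <- function(tape, store, img, cfg) {
  x <- nn_const(tape, img)
  feats <- vector("list", cfg$levels)
  for (l in seq_len(cfg$levels)) {
    x <- nn_relu(tape, nn_conv3(tape, x,
                                nn_param(tape, store, sprintf("enc%d_w1", l)),
                                nn_param(tape, store, sprintf("enc%d_b1", l))))
    x <- nn_relu(tape, nn_conv3(tape, x,
                                nn_param(tape, store, sprintf("enc%d_w2", l)),
                                nn_param(tape, store, sprintf("enc%d_b2", l))))
    x <- nn_pool2(tape, x)
    feats[[l]] <- x
  }
  feats
}

# Pad an image (H, W, C) with zeros so both sides divide 2^levels.
pad_to_multiple <- function(img, mult) {
  d <- dim(img)
  H2 <- as.integer(ceiling(d[1] / mult) * mult)
  W2 <- as.integer(ceiling(d[2] / mult) * mult)
  if (H2 == d[1] && W2 == d[2]) return(img)
  out <- array(0, c(H2, W2, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- img
  out
}

# Normalize and pad one sample once; downsampled image pyramids feed the
# per-level photometric losses.
hnet_prepare <- function(I_A, I_B, cfg) {
  mult <- 2^cfg$levels
  A <- pad_to_multiple(I_A / 255, mult)
  B <- pad_to_multiple(I_B / 255, mult)
  H <- dim(A)[1]; W <- dim(A)[2]
  list(A = A, B = B,
       Al = lapply(seq_len(cfg$levels), function(l) resize_image(A, H / 2^l, W / 2^l, "area")),
       Bl = lapply(seq_len(cfg$levels), function(l) resize_image(B, H / 2^l, W / 2^l, "area")))
}

# Core forward pass. Returns the (bounded) offsets node plus per-level
# photometric loss nodes when with_loss = TRUE.
hnet_forward <- function(tape, store, I_A, I_B, cfg, with_loss = FALSE,
                         prep = NULL) {
  if (is.null(prep)) prep <- hnet_prepare(I_A, I_B, cfg)
  A <- prep$A
  B <- prep$B
  H <- dim(A)[1]; W <- dim(A)[2]
  fA <- hnet_encode(tape, store, A, cfg)
  fB <- hnet_encode(tape, store, B, cfg)
  Al <- prep$Al
  Bl <- prep$Bl
  off <- nn_const(tape, numeric(8L))  # running estimate, full-res px
  losses <- list()
  for (l in seq.int(cfg$levels, 1L)) {
    sc <- 2^l
    hl <- H / sc; wl <- W / sc
    # pre-align target features by the running estimate (detached)
    fBl <- fB[[l]]
    if (max(abs(off$val)) > 1e-9) {
      off_l <- matrix(off$val, 4L, 2L, byrow = TRUE) / sc
      hv <- h_to_vec(solve_homography_inv(off_l, c(hl, wl)))
      fBl <- nn_warp(tape, fBl, hv, hl, wl)  # consts in, node out? fBl is node
    }
    cv <- nn_correlation(tape, fA[[l]], fBl, cfg$corr_radius[l])
    h1 <- nn_relu(tape, nn_conv3(tape, cv,
                                 nn_param(tape, store, sprintf("head%d_w1", l)),
                                 nn_param(tape, store, sprintf("head%d_b1", l))))
    h2 <- nn_relu(tape, nn_conv3(tape, h1,
                                 nn_param(tape, store, sprintf("head%d_w2", l)),
                                 nn_param(tape, store, sprintf("head%d_b2", l))))
    gp <- nn_gap(tape, h2)
    res <- nn_fc(tape, gp,
                 nn_param(tape, store, sprintf("head%d_wfc", l)),
                 nn_param(tape, store, sprintf("head%d_bfc", l)))
    off <- nn_add(tape, off, nn_scale(tape, res, sc))
    if (with_loss) {
      off_b <- if (l == 1L) nn_tanh_bound(tape, off, cfg$max_offset) else off
      losses[[length(losses) + 1L]] <-
        ablation_loss_node(tape, Al[[l]], Bl[[l]], nn_scale(tape, off_b, 1 / sc))
    }
  }
  off <- nn_tanh_bound(tape, off, cfg$max_offset)
  list(off = off, losses = losses, pad_size = c(H, W))
}

# Differentiable ablation photometric loss at a given offsets node.
# Images are plain arrays in [0, 1]; the validity mask and its pixel count are
# held fixed within the step (threshold subgradient is zero a.e.).
ablation_loss_node <- function(tape, A, B, off_node) {
  h <- dim(A)[1]; w <- dim(A)[2]
  off_m <- matrix(off_node$val, 4L, 2L, byrow = TRUE)
  hv_val <- tryCatch(h_to_vec(solve_homography_inv(off_m, c(h, w))),
                     error = function(e) NULL)
  if (is.null(hv_val)) return(nn_const(tape, 0))
  tpv <- nn_tape()
  maskw <- nn_warp(tpv, matrix(1, h, w), hv_val, h, w)$val
  mask <- (maskw >= 0.999) * 1
  npix <- max(1, sum(mask))
  hv <- nn_dlt_inv(tape, off_node, c(h, w))
  Bw <- nn_warp(tape, B, hv, h, w)
  mask3 <- array(rep(mask, dim(A)[3]), dim(A))
  Amask <- nn_mul_const(tape, nn_const(tape, A), mask3)
  nn_l1(tape, nn_sub(tape, Bw, Amask), 0, mask = mask3, reduce = "sum",
        denom = npix * dim(A)[3])
}

# Offsets (8-vector node) -> inverse-homography 8-vector node; the Jacobian of
# the linear solve is taken by central finite differences (smooth rational
# map).
nn_dlt_inv <- function(tape, off, size, eps = 1e-4) {
  f <- function(o) h_to_vec(solve_homography_inv(matrix(o, 4L, 2L, byrow = TRUE), size))
  val <- f(off$val)
  nn_node(tape, val, parents = list(off),
          backfn = function(g) {
            J <- matrix(0, 8L, 8L)  # J[i, j] = d hv_i / d off_j
            for (j in 1:8) {
              op <- off$val; op[j] <- op[j] + eps
              om <- off$val; om[j] <- om[j] - eps
              J[, j] <- (f(op) - f(om)) / (2 * eps)
            }
            list(as.vector(crossprod(J, g)))
          })
}

#' Ablation-masked photometric loss of a homography
#'
#' `L = || W(E, H) * I_A - W(I_B, H) ||_1` averaged over valid pixels, where
#' `W` warps into the reference frame, `E` is the all-ones image (its warp is
#' the validity mask, thresholded at 0.999) and `*` is pixel-wise
#' multiplication. Zero when the images agree under `H` on the valid region,
#' and zero when `H` pushes the target fully out of frame (everything is
#' ablated).
#' @param I_A,I_B images (H x W x 3, `[0, 255]`).
#' @param H 3 x 3 homography (target to reference frame).
#' @return non-negative scalar.
#' @export
ablation_loss <- function(I_A, I_B, H) {
  check_image(I_A, "I_A"); check_image(I_B, "I_B")
  h <- dim(I_A)[1]; w <- dim(I_A)[2]
  Hinv <- solve(H)
  Hinv <- Hinv / Hinv[3, 3]
  tp <- nn_tape()
  maskw <- nn_warp(tp, matrix(1, h, w), h_to_vec(Hinv), h, w)$val
  mask <- (maskw >= 0.999) * 1
  npix <- sum(mask)
  if (npix == 0) return(0)
  Bw <- nn_warp(tp, I_B / 255, h_to_vec(Hinv), h, w)$val
  mask3 <- array(rep(mask, dim(I_A)[3]), dim(I_A))
  sum(abs(mask3 * ((I_A / 255) - Bw))) / (npix * dim(I_A)[3])
}

#' Predict four-point corner offsets
#'
#' Runs the multi-scale correlation network coarse-to-fine. Images whose sides
#' do not divide `2^levels` are zero-padded internally; the returned offsets
#' are converted back to the original corners.
#' @param I_A,I_B reference and target image (same size, H x W x 3).
#' @param weights parameter store from [init_homography_weights()] or
#'   [train_homography()].
#' @param cfg a `"homography_config"`; defaults to the config stored in
#'   `weights`.
#' @return 4 x 2 offset matrix (TL, TR, BR, BL).
#' @export
predict_offsets <- function(I_A, I_B, weights, cfg = NULL) {
  check_image(I_A, "I_A"); check_image(I_B, "I_B")
  if (!all(dim(I_A) == dim(I_B))) stop("images must have identical size", call. = FALSE)
  if (is.null(cfg)) cfg <- attr(weights, "cfg")
  tp <- nn_tape()
  fw <- hnet_forward(tp, weights, I_A, I_B, cfg, with_loss = FALSE)
  off <- matrix(fw$off$val, 4L, 2L, byrow = TRUE,
                dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")))
  if (!all(fw$pad_size == dim(I_A)[1:2])) {
    # express the same projective map through the original corners
    Hm <- solve_homography(off, fw$pad_size)
    corners <- image_corners(dim(I_A)[1], dim(I_A)[2])
    off <- apply_h(Hm, corners) - corners
    dimnames(off) <- list(c("TL", "TR", "BR", "BL"), c("x", "y"))
  }
  off
}

#' Train the homography network
#'
#' Minimizes the mean ablation-masked photometric loss (summed over pyramid
#' levels) with Adam, one sample per step.
#' @param dataset list of `"quadruple"` samples or a dataset directory.
#' @param weights parameter store to start from; a fresh
#'   [init_homography_weights()] when `NULL`.
#' @param cfg a `"homography_config"` (ignored when `weights` given).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed (sample order; and fresh-weight init).
#' @param verbose print per-epoch mean loss.
#' @return the trained parameter store; per-epoch mean losses in attribute
#'   `loss_log`.
#' @export
train_homography <- function(dataset, weights = NULL, cfg = homography_config(),
                             epochs = 150L, lr = 1e-4, seed = 1L, verbose = FALSE) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (is.null(weights)) weights <- init_homography_weights(cfg, seed)
  cfg <- attr(weights, "cfg")
  n <- length(dataset)
  log <- numeric(0)
  orders <- with_seed(seed, replicate(epochs, sample.int(n), simplify = FALSE))
  preps <- lapply(dataset, function(q) hnet_prepare(q$I_A, q$I_B, cfg))
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (i in orders[[ep]]) {
      q <- dataset[[i]]
      tp <- nn_tape()
      fw <- hnet_forward(tp, weights, q$I_A, q$I_B, cfg, with_loss = TRUE,
                         prep = preps[[i]])
      loss <- nn_add_scalar_nodes(tp, fw$losses, rep(1 / length(fw$losses), length(fw$losses)))
      if (!is.finite(loss$val)) stop("homography training diverged (non-finite loss)", call. = FALSE)
      nn_backward(tp, loss)
      adam_step(weights, collect_grads(tp), lr = lr)
      tot <- tot + loss$val
    }
    log <- c(log, tot / n)
    if (verbose) message(sprintf("epoch %d/%d: mean ablation loss %.5f", ep, epochs, tot / n))
  }
  attr(weights, "loss_log") <- log
  weights
}
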