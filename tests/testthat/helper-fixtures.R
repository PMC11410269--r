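# Shared fixtures and small independent oracles used across the test files.

# small deterministic texture + quadruple
fix_quadruple <- function(seed = 5L, patch = c(64L, 64L), overlap = 0.8,
                          shift = 5, src_size = c(192L, 192L), texture = 0.7) {
  src <- generate_texture_image(seed, src_size, texture)
  make_stitch_quadruple(src, patch, overlap, shift, seed + 100L)
}

# independent homography solve: full 9-parameter SVD null-space DLT, a
# different construction from the package's 8x8 linear solve
oracle_dlt <- function(src, dst) {
  A <- matrix(0, 8L, 9L)
  for (k in 1:4) {
    x <- src[k, 1]; y <- src[k, 2]; u <- dst[k, 1]; v <- dst[k, 2]
    A[2 * k - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * k, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nv = 9)$v[, 9]
  matrix(h, 3, 3, byrow = TRUE) / h[9]
}

oracle_corners <- function(h, w) {
  matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1), 4, 2, byrow = TRUE)
}

# per-pixel scalar warp oracle: backward map through Hinv, manual bilinear
oracle_warp <- function(img, Hm, out_h, out_w, tx, ty) {
  Hinv <- solve(Hm)
  C <- dim(img)[3]
  out <- array(0, c(out_h, out_w, C))
  for (yy in 0:(out_h - 1)) for (xx in 0:(out_w - 1)) {
    p <- Hinv %*% c(xx - tx, yy - ty, 1)
    u <- p[1] / p[3]; v <- p[2] / p[3]
    u0 <- floor(u); v0 <- floor(v)
    fu <- u - u0; fv <- v - v0
    g <- function(xi, yi, c) {
      if (xi < 0 || xi > dim(img)[2] - 1 || yi < 0 || yi > dim(img)[1] - 1) return(0)
      img[yi + 1, xi + 1, c]
    }
    for (c in seq_len(C))
      out[yy + 1, xx + 1, c] <- (1 - fu) * (1 - fv) * g(u0, v0, c) +
        fu * (1 - fv) * g(u0 + 1, v0, c) +
        (1 - fu) * fv * g(u0, v0 + 1, c) +
        fu * fv * g(u0 + 1, v0 + 1, c)
  }
  out
}

# scalar reimplementation of the seam-mask equations (loops, no vectorization)
oracle_seam_masks <- function(M_AC, M_BC) {
  H <- nrow(M_AC); W <- ncol(M_AC)
  grad <- function(M) {
    G <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      up <- if (i > 1) M[i - 1, j] else 0
      left <- if (j > 1) M[i, j - 1] else 0
      G[i, j] <- abs(M[i, j] - up) + abs(M[i, j] - left)
    }
    G
  }
  conv3 <- function(M) {
    G <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      s <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) s <- s + M[ii, jj]
      }
      G[i, j] <- s
    }
    G
  }
  clip <- function(M) pmin(pmax(M, 0), 1)
  list(M_AS = clip(conv3(conv3(conv3(grad(M_BC))))) * M_AC,
       M_BS = clip(conv3(conv3(conv3(grad(M_AC))))) * M_BC)
}

# straight-from-formula SSIM oracle (loops over fully supported windows)
oracle_ssim <- function(a, b) {
  k <- exp(-(seq(-5, 5))^2 / (2 * 1.5^2)); k <- k / sum(k)
  wmat <- outer(k, k)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  H <- dim(a)[1]; W <- dim(a)[2]
  vals <- numeric(dim(a)[3])
  for (c in seq_len(dim(a)[3])) {
    s <- c()
    for (i in 6:(H - 5)) for (j in 6:(W - 5)) {
      x <- a[(i - 5):(i + 5), (j - 5):(j + 5), c]
      y <- b[(i - 5):(i + 5), (j - 5):(j + 5), c]
      mx <- sum(wmat * x); my <- sum(wmat * y)
      sxx <- sum(wmat * x * x) - mx^2
      syy <- sum(wmat * y * y) - my^2
      sxy <- sum(wmat * x * y) - mx * my
      s <- c(s, ((2 * mx * my + C1) * (2 * sxy + C2)) /
               ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
    }
    vals[c] <- mean(s)
  }
  mean(vals)
}

mean_corner_error <- function(off, gt) mean(sqrt(rowSums((off - gt)^2)))

# reduced-width configs used by the fast tests
test_hcfg <- function(max_offset = 16)
  homography_config(levels = 2L, channels = c(8L, 16L), corr_radius = c(4L, 2L),
                    head_channels = c(24L, 16L), max_offset = max_offset)

test_rcfg <- function() recon_config(base = 4L, highres_channels = 8L, lowres_size = 32L)

clip255 <- function(x) pmin(pmax(x, 0), 255)
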