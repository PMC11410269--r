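# ---- minimal reverse-mode autodiff over dense arrays -----------------------
# Feature maps are arrays dim c(H, W, C); vectors are plain numerics.
# A tape records nodes in creation order; reverse iteration is a valid
# topological order, so backward() is a single backwards sweep.
# Convolutions run as im2col + GEMM so the heavy lifting stays in BLAS.

nn_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

nn_node <- function(tape, val, parents = list(), backfn = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$name <- name
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

nn_const <- function(tape, val) nn_node(tape, val)

is_node <- function(x) is.environment(x)
node_val <- function(x) if (is_node(x)) x$val else x

#' @keywords internal
nn_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      gk <- gs[[k]]
      if (is.null(gk)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) gk else p$grad + gk
    }
  }
  invisible(NULL)
}

# ---- parameter store + Adam ------------------------------------------------

#' Create a parameter store
#' @keywords internal
param_store <- function(params) {
  st <- new.env(parent = emptyenv())
  st$w <- params
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

nn_param <- function(tape, store, name) {
  nn_node(tape, store$w[[name]], name = name)
}

# Collect parameter gradients accumulated on a tape, summed per name.
collect_grads <- function(tape) {
  gs <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$name) || is.null(nd$grad)) next
    gs[[nd$name]] <- if (is.null(gs[[nd$name]])) nd$grad else gs[[nd$name]] + nd$grad
  }
  gs
}

#' One Adam update over a parameter store
#' @param store parameter store.
#' @param grads named list of gradients (missing names are skipped).
#' @param lr learning rate; beta1/beta2/eps standard Adam constants.
#' @keywords internal
adam_step <- function(store, grads, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  store$t <- store$t + 1L
  bc1 <- 1 - beta1^store$t
  bc2 <- 1 - beta2^store$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (anyNA(g) || any(!is.finite(g))) stop("non-finite gradient for ", nm, call. = FALSE)
    store$m[[nm]] <- beta1 * store$m[[nm]] + (1 - beta1) * g
    store$v[[nm]] <- beta2 * store$v[[nm]] + (1 - beta2) * g * g
    store$w[[nm]] <- store$w[[nm]] -
      lr * (store$m[[nm]] / bc1) / (sqrt(store$v[[nm]] / bc2) + eps)
  }
  invisible(store)
}

# He-scaled initialization for a fan_in x fan_out weight matrix
he_init <- function(fan_in, n, dim) {
  array(stats::rnorm(n, sd = sqrt(2 / fan_in)), dim)
}

# ---- im2col for 3x3 stride-1 pad-1 convolution -----------------------------
# The 9 shifted views are materialized by a single indexed gather per shift;
# out-of-frame neighbors point at a sacrificial zero row (index H*W + 1).
# Index maps are cached per image geometry.

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W) {
  key <- paste0(H, "x", W)
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  trash <- H * W + 1L
  idx <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    ii <- i + di; jj <- j + dj
    p <- ii + (jj - 1L) * H
    p[ii < 1L | ii > H | jj < 1L | jj > W] <- trash
    idx[[k]] <- p
  }
  .im2col_cache[[key]] <- idx
  idx
}

# x as (H*W + 1) x C matrix with a trailing zero row
with_zero_row <- function(x, n, C) {
  xm <- matrix(0, n + 1L, C)
  xm[seq_len(n), ] <- x
  xm
}

# 3x3 convolution, stride 1, zero padding 1. W: (9*Cin) x Cout, b: Cout.
# Evaluated as nine shifted GEMM accumulations: y[p] = sum_k x[p + d_k] W_k,
# with the shifts realized by indexed gathers against a zero-row sentinel.
nn_conv3 <- function(tape, x, w, b) {
  d <- dim(x$val)
  H <- d[1]; Wd <- d[2]; C <- d[3]
  n <- H * Wd
  Cout <- ncol(w$val)
  idx <- im2col_idx(H, Wd)
  xm <- with_zero_row(x$val, n, C)
  y <- matrix(rep(b$val, each = n), n, Cout)
  for (k in 1:9) {
    z <- xm %*% w$val[((k - 1L) * C + 1L):(k * C), , drop = FALSE]
    y <- y + z[idx[[k]], , drop = FALSE]
  }
  nn_node(tape, array(y, c(H, Wd, Cout)), parents = list(x, w, b),
          backfn = function(g) {
            gm <- with_zero_row(g, n, Cout)
            gw <- array(0, dim(w$val))
            gx <- matrix(0, n, C)
            xt <- xm[seq_len(n), , drop = FALSE]
            for (k in 1:9) {
              rows <- ((k - 1L) * C + 1L):(k * C)
              gys <- gm[idx[[10L - k]], , drop = FALSE]  # reverse shift
              gx <- gx + gys %*% t(w$val[rows, , drop = FALSE])
              gw[rows, ] <- crossprod(xt, gys)
            }
            list(array(gx, d), gw, colSums(matrix(g, n, Cout)))
          })
}

# 1x1 convolution. W: Cin x Cout, b: Cout.
nn_conv1 <- function(tape, x, w, b) {
  d <- dim(x$val)
  xm <- matrix(x$val, d[1] * d[2], d[3])
  Cout <- ncol(w$val)
  y <- sweep(xm %*% w$val, 2L, b$val, "+")
  nn_node(tape, array(y, c(d[1], d[2], Cout)), parents = list(x, w, b),
          backfn = function(g) {
            gm <- matrix(g, d[1] * d[2], Cout)
            list(array(gm %*% t(w$val), d), crossprod(xm, gm), colSums(gm))
          })
}

nn_relu <- function(tape, x) {
  y <- x$val
  y[y < 0] <- 0
  nn_node(tape, y, parents = list(x),
          backfn = function(g) list(g * (x$val > 0)))
}

nn_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$val))
  nn_node(tape, y, parents = list(x),
          backfn = function(g) list(g * y * (1 - y)))
}

# Smooth bound: y = s * tanh(x / s); identity-like near 0, |y| < s.
nn_tanh_bound <- function(tape, x, s) {
  t <- tanh(x$val / s)
  nn_node(tape, s * t, parents = list(x),
          backfn = function(g) list(g * (1 - t^2)))
}

# 2x2 max pooling, stride 2 (H, W must be even).
nn_pool2 <- function(tape, x) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  m <- list(
    x$val[io, jo, , drop = FALSE], x$val[io + 1L, jo, , drop = FALSE],
    x$val[io, jo + 1L, , drop = FALSE], x$val[io + 1L, jo + 1L, , drop = FALSE]
  )
  y <- pmax(m[[1]], m[[2]], m[[3]], m[[4]])
  nn_node(tape, y, parents = list(x),
          backfn = function(g) {
            gx <- array(0, d)
            left <- array(TRUE, dim(y))
            sub <- list(cbind(0L, 0L), cbind(1L, 0L), cbind(0L, 1L), cbind(1L, 1L))
            for (k in 1:4) {
              sel <- (m[[k]] == y) & left
              left <- left & !sel
              gi <- g * sel
              di <- sub[[k]][1]; dj <- sub[[k]][2]
              gx[io + di, jo + dj, ] <- gx[io + di, jo + dj, ] + gi
            }
            list(gx)
          })
}

# Global average pooling -> length-C vector.
nn_gap <- function(tape, x) {
  d <- dim(x$val)
  y <- colMeans(matrix(x$val, d[1] * d[2], d[3]))
  nn_node(tape, y, parents = list(x),
          backfn = function(g) {
            list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d))
          })
}

# Fully connected: x vector (Cin), W Cin x Cout, b Cout.
nn_fc <- function(tape, x, w, b) {
  y <- as.vector(x$val %*% w$val) + b$val
  nn_node(tape, y, parents = list(x, w, b),
          backfn = function(g) {
            list(as.vector(w$val %*% g), outer(x$val, g), g)
          })
}

# Transposed convolution 2x2, stride 2 (channel plan Cin -> Cout, size x2).
# W: array c(2, 2, Cin, Cout), b: Cout.
nn_deconv2 <- function(tape, x, w, b) {
  d <- dim(x$val)
  H <- d[1]; Wd <- d[2]; Cin <- d[3]
  Cout <- dim(w$val)[4]
  xm <- matrix(x$val, H * Wd, Cin)
  y <- array(0, c(2L * H, 2L * Wd, Cout))
  io <- seq(1L, 2L * H, 2L); jo <- seq(1L, 2L * Wd, 2L)
  for (a in 1:2) for (bb in 1:2) {
    Wa <- matrix(w$val[a, bb, , ], Cin, Cout)
    y[io + (a - 1L), jo + (bb - 1L), ] <- array(xm %*% Wa, c(H, Wd, Cout))
  }
  y <- sweep(y, 3L, b$val, "+")
  nn_node(tape, y, parents = list(x, w, b),
          backfn = function(g) {
            gw <- array(0, dim(w$val))
            gx <- matrix(0, H * Wd, Cin)
            gb <- numeric(Cout)
            for (a in 1:2) for (bb in 1:2) {
              gs <- matrix(g[io + (a - 1L), jo + (bb - 1L), ], H * Wd, Cout)
              Wa <- matrix(w$val[a, bb, , ], Cin, Cout)
              gw[a, bb, , ] <- crossprod(xm, gs)
              gx <- gx + gs %*% t(Wa)
              gb <- gb + colSums(gs)
            }
            list(array(gx, d), gw, gb)
          })
}

# Channel concatenation.
nn_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$val))
  H <- ds[[1]][1]; W <- ds[[1]][2]
  cs <- vapply(ds, function(d) d[3], numeric(1))
  y <- array(0, c(H, W, sum(cs)))
  at <- 0L
  for (k in seq_along(xs)) {
    y[, , (at + 1L):(at + cs[k])] <- xs[[k]]$val
    at <- at + cs[k]
  }
  nn_node(tape, y, parents = xs,
          backfn = function(g) {
            out <- vector("list", length(xs))
            at <- 0L
            for (k in seq_along(xs)) {
              out[[k]] <- g[, , (at + 1L):(at + cs[k]), drop = FALSE]
              at <- at + cs[k]
            }
            out
          })
}

nn_add <- function(tape, a, b) {
  nn_node(tape, a$val + b$val, parents = list(a, b),
          backfn = function(g) list(g, g))
}

nn_sub <- function(tape, a, b) {
  nn_node(tape, a$val - b$val, parents = list(a, b),
          backfn = function(g) list(g, -g))
}

# Multiply by a constant array/scalar (e.g. a mask).
nn_mul_const <- function(tape, x, m) {
  nn_node(tape, x$val * m, parents = list(x),
          backfn = function(g) list(g * m))
}

nn_scale <- function(tape, x, s) nn_mul_const(tape, x, s)

nn_add_scalar_nodes <- function(tape, xs, w = NULL) {
  if (is.null(w)) w <- rep(1, length(xs))
  v <- 0
  for (k in seq_along(xs)) v <- v + w[k] * xs[[k]]$val
  nn_node(tape, v, parents = xs,
          backfn = function(g) lapply(seq_along(xs), function(k) g * w[k]))
}

# L1 distance with optional constant weighting mask; reduce = mean | sum.
nn_l1 <- function(tape, a, b, mask = NULL, reduce = "mean", denom = NULL) {
  dv <- a$val - node_val(b)
  if (!is.null(mask)) dv <- dv * mask
  n <- if (!is.null(denom)) denom else if (reduce == "mean") length(dv) else 1
  val <- sum(abs(dv)) / n
  parents <- if (is_node(b)) list(a, b) else list(a)
  nn_node(tape, val, parents = parents,
          backfn = function(g) {
            gd <- g * sign(dv) / n
            if (!is.null(mask)) gd <- gd * mask
            if (is_node(b)) list(gd, -gd) else list(gd)
          })
}

# Zero-pad bottom/right to (H2, W2).
nn_pad <- function(tape, x, H2, W2) {
  d <- dim(x$val)
  if (d[1] == H2 && d[2] == W2) return(x)
  y <- array(0, c(H2, W2, d[3]))
  y[seq_len(d[1]), seq_len(d[2]), ] <- x$val
  nn_node(tape, y, parents = list(x),
          backfn = function(g) list(g[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]))
}

# Separable resize by constant weight matrices (differentiable in x).
nn_resize <- function(tape, x, Rw, Cw) {
  d <- dim(x$val)
  C <- d[3]
  y <- array(0, c(nrow(Rw), nrow(Cw), C))
  for (c in seq_len(C)) y[, , c] <- Rw %*% x$val[, , c] %*% t(Cw)
  nn_node(tape, y, parents = list(x),
          backfn = function(g) {
            gx <- array(0, d)
            for (c in seq_len(C)) gx[, , c] <- t(Rw) %*% g[, , c] %*% Cw
            list(gx)
          })
}

# ---- local correlation volume ----------------------------------------------
# out[, , k] = <a[i, j, ], b[i + dy, j + dx, ]> / C for (dy, dx) in [-r, r]^2.
nn_correlation <- function(tape, a, b, r) {
  d <- dim(a$val)
  H <- d[1]; W <- d[2]; C <- d[3]
  n <- (2L * r + 1L)^2
  bp <- array(0, c(H + 2L * r, W + 2L * r, C))
  bp[(r + 1L):(r + H), (r + 1L):(r + W), ] <- b$val
  y <- array(0, c(H, W, n))
  k <- 0L
  shifts <- matrix(0L, n, 2L)
  for (dx in -r:r) for (dy in -r:r) {
    k <- k + 1L
    shifts[k, ] <- c(dy, dx)
    bs <- bp[(r + 1L + dy):(r + H + dy), (r + 1L + dx):(r + W + dx), , drop = FALSE]
    y[, , k] <- rowSums(matrix(a$val * bs, H * W, C)) / C
  }
  nn_node(tape, y, parents = list(a, b),
          backfn = function(g) {
            ga <- array(0, d)
            gbp <- array(0, dim(bp))
            for (k in seq_len(n)) {
              dy <- shifts[k, 1]; dx <- shifts[k, 2]
              bs <- bp[(r + 1L + dy):(r + H + dy), (r + 1L + dx):(r + W + dx), , drop = FALSE]
              gk <- array(rep(g[, , k] / C, C), d)
              ga <- ga + gk * bs
              gbp[(r + 1L + dy):(r + H + dy), (r + 1L + dx):(r + W + dx), ] <-
                gbp[(r + 1L + dy):(r + H + dy), (r + 1L + dx):(r + W + dx), ] + gk * a$val
            }
            list(ga, gbp[(r + 1L):(r + H), (r + 1L):(r + W), , drop = FALSE])
          })
}

# Sum w into a zero vector of length n at (possibly repeated) indices idx.
scatter_add <- function(n, idx, w) {
  out <- numeric(n)
  if (!length(idx)) return(out)
  o <- order(idx)
  si <- idx[o]
  cs <- cumsum(w[o])
  ends <- c(which(si[-1L] != si[-length(si)]), length(si))
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  out[si[ends]] <- sums
  out
}

# ---- homography-parameterized warp -----------------------------------------
# hv is the 8-vector (h11, h12, h13, h21, h22, h23, h31, h32) of the backward
# map (h33 = 1): output pixel (x, y) on a canvas with translation (tx, ty)
# samples the source at (u, v) = Hinv . (x - tx, y - ty, 1).

warp_coords <- function(hv, out_h, out_w, tx = 0, ty = 0) {
  x <- matrix(rep(0:(out_w - 1L), each = out_h), out_h, out_w) - tx
  y <- matrix(rep(0:(out_h - 1L), out_w), out_h, out_w) - ty
  D <- hv[7] * x + hv[8] * y + 1
  list(u = (hv[1] * x + hv[2] * y + hv[3]) / D,
       v = (hv[4] * x + hv[5] * y + hv[6]) / D,
       x = x, y = y, D = D)
}

# Differentiable warp. img: node or plain array; hv: node or plain 8-vector.
# Gradients flow to whichever inputs are nodes.
nn_warp <- function(tape, img, hv, out_h, out_w, tx = 0, ty = 0) {
  imv <- node_val(img)
  ismat <- is.matrix(imv)
  if (ismat) imv <- array(imv, c(dim(imv), 1L))
  hvv <- node_val(hv)
  H <- dim(imv)[1]; W <- dim(imv)[2]; C <- dim(imv)[3]
  cc <- warp_coords(hvv, out_h, out_w, tx, ty)
  u <- as.vector(cc$u); v <- as.vector(cc$v)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  gather_idx <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1)
    idx <- ifelse(ok, yi + 1 + xi * H, NA_real_)
    list(ok = ok, idx = idx)
  }
  i00 <- gather_idx(u0, v0); i10 <- gather_idx(u0 + 1, v0)
  i01 <- gather_idx(u0, v0 + 1); i11 <- gather_idx(u0 + 1, v0 + 1)
  gv <- function(ch, gi) {
    out <- numeric(length(u))
    out[gi$ok] <- ch[gi$idx[gi$ok]]
    out
  }
  w00 <- (1 - fu) * (1 - fv); w10 <- fu * (1 - fv)
  w01 <- (1 - fu) * fv; w11 <- fu * fv
  y <- array(0, c(out_h, out_w, C))
  vals <- vector("list", C)
  for (c in seq_len(C)) {
    ch <- imv[, , c]
    vals[[c]] <- list(gv(ch, i00), gv(ch, i10), gv(ch, i01), gv(ch, i11))
    y[, , c] <- w00 * vals[[c]][[1]] + w10 * vals[[c]][[2]] +
      w01 * vals[[c]][[3]] + w11 * vals[[c]][[4]]
  }
  if (ismat) y <- y[, , 1]
  parents <- list()
  if (is_node(img)) parents <- c(parents, list(img))
  if (is_node(hv)) parents <- c(parents, list(hv))
  if (!length(parents)) return(nn_node(tape, y))
  nn_node(tape, y, parents = parents,
          backfn = function(g) {
            if (ismat) g <- array(g, c(out_h, out_w, 1L))
            out <- list()
            gu_tot <- numeric(length(u))
            gv_tot <- numeric(length(u))
            gimg <- if (is_node(img)) array(0, dim(imv)) else NULL
            for (c in seq_len(C)) {
              gc <- as.vector(g[, , c])
              vc <- vals[[c]]
              if (is_node(hv)) {
                dval_du <- (1 - fv) * (vc[[2]] - vc[[1]]) + fv * (vc[[4]] - vc[[3]])
                dval_dv <- (1 - fu) * (vc[[3]] - vc[[1]]) + fu * (vc[[4]] - vc[[2]])
                gu_tot <- gu_tot + gc * dval_du
                gv_tot <- gv_tot + gc * dval_dv
              }
              if (is_node(img)) {
                sel <- c(i00$ok, i10$ok, i01$ok, i11$ok)
                idx4 <- c(i00$idx, i10$idx, i01$idx, i11$idx)[sel]
                w4 <- (c(gc, gc, gc, gc) * c(w00, w10, w01, w11))[sel]
                gimg[, , c] <- gimg[, , c] + scatter_add(H * W, idx4, w4)
              }
            }
            if (is_node(img)) out <- c(out, list(if (ismat) gimg[, , 1] else gimg))
            if (is_node(hv)) {
              X <- as.vector(cc$x); Y <- as.vector(cc$y); D <- as.vector(cc$D)
              ghv <- c(
                sum(gu_tot * X / D), sum(gu_tot * Y / D), sum(gu_tot / D),
                sum(gv_tot * X / D), sum(gv_tot * Y / D), sum(gv_tot / D),
                -sum((gu_tot * u + gv_tot * v) * X / D),
                -sum((gu_tot * u + gv_tot * v) * Y / D)
              )
              out <- c(out, list(ghv))
            }
            out
          })
}

# ---- finite-difference gradient check helper (used by tests) ---------------

#' Numerical gradient of a scalar function of one array
#' @keywords internal
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
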