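# ---- radial distortion estimation by line straightness ---------------------
# A distorted frame bends straight scene lines; undistorting with the right
# division-model coefficient k makes them straight again, which concentrates
# Hough-transform votes into sharp peaks. k is found by scanning a candidate
# grid, scoring each candidate by the peak of the product of smoothed,
# angle-restricted HT accumulators computed at several scales, and refining
# the interval around the best candidate over a number of rounds.

#' Configuration for distortion estimation
#'
#' @param k_min,k_max initial candidate interval for the division-model
#'   coefficient (px^-2).
#' @param n_steps grid subdivisions per round (grid has `n_steps + 1` points).
#' @param rounds interval-refinement rounds; each round re-centers the
#'   interval on the best candidate and shrinks it by `1 / n_steps`.
#' @param k_tol refinement stops early once the grid step falls below this.
#' @param tau_theta half-width (radians) of the quasi-horizontal /
#'   quasi-vertical angle bands searched in Hough space.
#' @param ht_rho_res,ht_theta_res Hough bin resolutions (px fraction of the
#'   half-diagonal is fixed by `n_rho`; `ht_theta_res` in radians).
#' @param n_rho number of rho bins (odd, so the bins are symmetric about 0 and
#'   the score is invariant to quarter-turn rotations).
#' @param gaussian_sigma HT-space smoothing, in bins.
#' @param canny_low,canny_high hysteresis thresholds on the gradient
#'   magnitude (8-bit scale).
#' @param canny_sigma pre-smoothing for edge detection, in px.
#' @param scales multi-resolution factors the straightness score combines.
#' @param n_peaks number of product-space peaks summed by the straightness
#'   score.
#' @return list of class `"correction_config"`.
#' @export
correction_config <- function(k_min = 0, k_max = 1e-6, n_steps = 20L, rounds = 15L,
                              k_tol = 1e-11, tau_theta = 10 * pi / 180,
                              ht_theta_res = 0.5 * pi / 180, n_rho = 725L,
                              gaussian_sigma = 1.0, canny_low = 50, canny_high = 150,
                              canny_sigma = 1.4, scales = c(1, 0.5, 0.25),
                              n_peaks = 20L) {
  stopifnot(k_min < k_max, n_steps >= 2L, rounds >= 1L, n_rho %% 2L == 1L)
  structure(list(k_min = k_min, k_max = k_max, n_steps = as.integer(n_steps),
                 rounds = as.integer(rounds), k_tol = k_tol,
                 tau_theta = tau_theta, ht_theta_res = ht_theta_res,
                 n_rho = as.integer(n_rho), gaussian_sigma = gaussian_sigma,
                 canny_low = canny_low, canny_high = canny_high,
                 canny_sigma = canny_sigma, scales = scales,
                 n_peaks = as.integer(n_peaks)),
            class = "correction_config")
}

#' Defaults matching the published group-B calibration
#'
#' Start coefficient 1e-9, first-round increment 5e-8 over 20 steps, 15
#' refinement rounds.
#' @return a `"correction_config"`.
#' @export
correction_config_groupB <- function() {
  correction_config(k_min = 1e-9, k_max = 1e-9 + 20L * 5e-8, n_steps = 20L,
                    rounds = 15L)
}

#' Candidate distortion coefficient on the scan grid
#'
#' `k_i = k_min + i * (k_max - k_min) / n_steps`.
#' @param i grid index, `0 <= i <= n_steps`.
#' @param cfg a `"correction_config"`.
#' @return candidate k.
#' @export
candidate_k <- function(i, cfg) {
  if (any(i < 0 | i > cfg$n_steps)) stop("i out of range [0, n_steps]", call. = FALSE)
  cfg$k_min + i * (cfg$k_max - cfg$k_min) / cfg$n_steps
}

# ---- Canny edge detection ---------------------------------------------------

#' Detect edges (Canny)
#'
#' Grayscale (luma) conversion, Gaussian pre-smoothing, Sobel gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' double-threshold hysteresis.
#' @param img H x W x 3 array or H x W matrix in `[0, 255]`.
#' @param cfg a `"correction_config"` (thresholds, smoothing).
#' @return H x W logical matrix of edge pixels.
#' @export
detect_edges <- function(img, cfg = correction_config()) {
  g <- if (is.matrix(img)) img else luma(img)
  g <- gaussian_blur(g, cfg$canny_sigma, pad = "replicate")
  H <- nrow(g); W <- ncol(g)
  sx <- matrix(0, H, W); sy <- matrix(0, H, W)
  # Sobel via shifted sums (replicate padding)
  gp <- rbind(g[1, ], g, g[H, ])
  gp <- cbind(gp[, 1], gp, gp[, W])
  sub <- function(di, dj) gp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  sx <- (sub(-1, 1) + 2 * sub(0, 1) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(0, -1) + sub(1, -1))
  sy <- (sub(1, -1) + 2 * sub(1, 0) + sub(1, 1)) -
    (sub(-1, -1) + 2 * sub(-1, 0) + sub(-1, 1))
  mag <- sqrt(sx^2 + sy^2)
  # non-maximum suppression in 4 quantized directions
  ang <- atan2(sy, sx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4L
  mp <- matrix(0, H + 2, W + 2)
  mp[2:(H + 1), 2:(W + 1)] <- mag
  msub <- function(di, dj) mp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  pick <- function(s, a, b) {
    sel <- sector == s
    n1[sel] <<- a[sel]; n2[sel] <<- b[sel]
  }
  pick(0L, msub(0, 1), msub(0, -1))    # horizontal gradient -> vertical edge
  pick(1L, msub(1, 1), msub(-1, -1))
  pick(2L, msub(1, 0), msub(-1, 0))
  pick(3L, msub(1, -1), msub(-1, 1))
  keep <- mag >= n1 & mag > n2
  strong <- keep & mag >= cfg$canny_high
  weak <- keep & mag >= cfg$canny_low & !strong
  # hysteresis: grow strong set through 8-connected weak pixels
  sp <- matrix(FALSE, H + 2, W + 2)
  sp[2:(H + 1), 2:(W + 1)] <- strong
  repeat {
    dil <- sp[1:H, 1:W] | sp[1:H, 2:(W + 1)] | sp[1:H, 3:(W + 2)] |
      sp[2:(H + 1), 1:W] | sp[2:(H + 1), 3:(W + 2)] |
      sp[3:(H + 2), 1:W] | sp[3:(H + 2), 2:(W + 1)] | sp[3:(H + 2), 3:(W + 2)]
    add <- dil & weak & !sp[2:(H + 1), 2:(W + 1)]
    if (!any(add)) break
    sp[2:(H + 1), 2:(W + 1)] <- sp[2:(H + 1), 2:(W + 1)] | add
  }
  sp[2:(H + 1), 2:(W + 1)]
}

# ---- restricted Hough transform --------------------------------------------

ht_thetas <- function(cfg) {
  band1 <- seq(-cfg$tau_theta, cfg$tau_theta, by = cfg$ht_theta_res)
  band2 <- seq(pi / 2 - cfg$tau_theta, pi / 2 + cfg$tau_theta, by = cfg$ht_theta_res)
  c(band1, band2)
}

#' Line accumulator over the quasi-axial angle bands
#'
#' Standard `(rho, theta)` voting with a center-origin rho convention
#' (`rho = (x - cx) cos(theta) + (y - cy) sin(theta)`), restricted to
#' `theta` in `[-tau, tau]` (quasi-vertical lines) and
#' `[pi/2 - tau, pi/2 + tau]` (quasi-horizontal); one vote per edge pixel and
#' theta bin.
#' @param edges H x W logical matrix.
#' @param cfg a `"correction_config"`.
#' @return object of class `"ht_space"`: list with `accumulator`
#'   (`n_rho x n_theta`), `rho` and `theta` bin centers.
#' @export
hough_space <- function(edges, cfg = correction_config()) {
  H <- nrow(edges); W <- ncol(edges)
  thetas <- ht_thetas(cfg)
  rmax <- sqrt((H / 2)^2 + (W / 2)^2)
  rho_bins <- seq(-rmax, rmax, length.out = cfg$n_rho)
  acc <- matrix(0, cfg$n_rho, length(thetas))
  idx <- which(edges)
  if (length(idx)) {
    y <- ((idx - 1L) %% H) - (H - 1) / 2
    x <- ((idx - 1L) %/% H) - (W - 1) / 2
    step <- rho_bins[2] - rho_bins[1]
    wcount <- function(b, w) {
      ok <- b >= 1L & b <= cfg$n_rho & w > 0
      out <- numeric(cfg$n_rho)
      if (any(ok)) {
        agg <- rowsum(w[ok], b[ok])
        out[as.integer(rownames(agg))] <- agg[, 1]
      }
      out
    }
    for (t in seq_along(thetas)) {
      rho <- x * cos(thetas[t]) + y * sin(thetas[t])
      # one vote per edge pixel, split linearly between the two nearest rho
      # bins so sub-bin line positions do not alias
      pos <- (rho + rmax) / step
      b0 <- floor(pos)
      fr <- pos - b0
      acc[, t] <- wcount(b0 + 1L, 1 - fr) + wcount(b0 + 2L, fr)
    }
  }
  structure(list(accumulator = acc, rho = rho_bins, theta = thetas),
            class = "ht_space")
}

#' Smooth a Hough accumulator
#'
#' Separable Gaussian blur with a normalized, zero-padded kernel, damping the
#' oscillations that bin quantization produces; interior vote mass is
#' preserved.
#' @param space an `"ht_space"`.
#' @param cfg a `"correction_config"` (uses `gaussian_sigma`).
#' @return smoothed `"ht_space"`.
#' @export
smooth_ht <- function(space, cfg = correction_config()) {
  stopifnot(cfg$gaussian_sigma > 0)
  space$accumulator <- gaussian_blur(space$accumulator, cfg$gaussian_sigma,
                                     pad = "zero")
  space
}

# ---- undistortion -----------------------------------------------------------

#' Correct division-model radial distortion
#'
#' Backward mapping: every output (undistorted) pixel at radius `r_u` from the
#' center samples the distorted image at
#' `r_d = (1 - sqrt(1 - 4 k r_u^2)) / (2 k r_u)`, the inverse of
#' `r_u = r_d / (1 + k r_d^2)`; bilinear interpolation, unmapped pixels black.
#' @param img H x W x 3 array (or H x W matrix).
#' @param model a `"distortion_model"` (from [estimate_k()]) or a bare numeric
#'   k.
#' @return corrected image, same size.
#' @export
undistort <- function(img, model) {
  k <- if (inherits(model, "distortion_model")) model$k else model
  center <- if (inherits(model, "distortion_model")) model$center else NULL
  ismat <- is.matrix(img)
  H <- if (ismat) nrow(img) else dim(img)[1]
  W <- if (ismat) ncol(img) else dim(img)[2]
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)
  if (k == 0) return(img)
  x <- matrix(rep(0:(W - 1), each = H), H, W) - center[1]
  y <- matrix(rep(0:(H - 1), W), H, W) - center[2]
  ru2 <- x^2 + y^2
  disc <- 1 - 4 * k * ru2
  if (any(disc < 0))
    stop("k = ", k, " is outside the invertible range for this image size",
         call. = FALSE)
  # r_d / r_u, with the k -> 0 limit handled explicitly
  scale <- ifelse(ru2 > 0, (1 - sqrt(disc)) / (2 * k * ru2), 1)
  # monotonicity of the forward map requires k * r_d^2 < 1
  if (k * max(ru2 * scale^2) >= 1)
    stop("k = ", k, " is not monotone over the image radius range", call. = FALSE)
  u <- x * scale + center[1]
  v <- y * scale + center[2]
  out <- warp_backward(img, u, v)
  # pixels whose source sample fell outside the frame: black, not content
  attr(out, "valid") <- u >= 0 & u <= W - 1 & v >= 0 & v <= H - 1
  out
}

# Binary erosion by r iterations of a 3x3 minimum.
erode_mask <- function(mask, r) {
  H <- nrow(mask); W <- ncol(mask)
  for (it in seq_len(r)) {
    mp <- matrix(FALSE, H + 2, W + 2)
    mp[2:(H + 1), 2:(W + 1)] <- mask
    mask <- mp[1:H, 1:W] & mp[1:H, 2:(W + 1)] & mp[1:H, 3:(W + 2)] &
      mp[2:(H + 1), 1:W] & mp[2:(H + 1), 2:(W + 1)] & mp[2:(H + 1), 3:(W + 2)] &
      mp[3:(H + 2), 1:W] & mp[3:(H + 2), 2:(W + 1)] & mp[3:(H + 2), 3:(W + 2)]
  }
  mask
}

# ---- straightness score and iterative estimation ---------------------------

#' Line-straightness score of a candidate coefficient
#'
#' Undistorts the image with `k`, then at each scale in `cfg$scales` detects
#' edges (restricted to the eroded valid region, so the unmapped black rim
#' cannot vote), accumulates the angle-restricted Hough space, normalizes it
#' by the vote count (removing the k-dependent magnification of line lengths)
#' and smooths it; the accumulators (shared bin geometry across scales) are
#' multiplied elementwise and the score sums the `n_peaks` largest rho-local
#' maxima of the product space. Straight lines concentrate their votes at
#' every scale, so the score peaks at the true coefficient; summing over
#' several peaks averages the per-line quantization noise that a single
#' maximum is dominated by.
#' @param img H x W x 3 array.
#' @param k candidate coefficient.
#' @param cfg a `"correction_config"`.
#' @return list with `score` (non-negative), `rho0`, `theta0` (bin maximizing
#'   the product space).
#' @export
straightness_score <- function(img, k, cfg = correction_config()) {
  und <- undistort(img, k)
  g <- if (is.matrix(und)) und else luma(und)
  valid <- attr(und, "valid")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(g), ncol(g))
  # drop the unmapped rim plus the edge-detector's support around it, so the
  # content/black boundary (straight along the frame for any k) cannot vote
  valid <- erode_mask(valid, ceiling(3 * cfg$canny_sigma) + 2L)
  prod_acc <- NULL
  thetas <- NULL; rhos <- NULL
  for (s in cfg$scales) {
    gs <- if (s == 1) g else resize_image(g, round(nrow(g) * s), round(ncol(g) * s), "area")
    vs <- if (s == 1) valid else
      resize_image(valid * 1, round(nrow(g) * s), round(ncol(g) * s), "area") > 0.999
    cfg_s <- cfg
    # area downsampling already antialiases; shrink the detector's
    # pre-smoothing with the scale so thin structures keep their gradients
    cfg_s$canny_sigma <- max(0.8, cfg$canny_sigma * s)
    e <- detect_edges(gs, cfg_s) & vs
    ht <- smooth_ht(hough_space(e, cfg_s), cfg_s)
    acc <- ht$accumulator / max(1, sum(e))
    prod_acc <- if (is.null(prod_acc)) acc else prod_acc * acc
    thetas <- ht$theta; rhos <- ht$rho
  }
  i <- which.max(prod_acc)
  up <- rbind(-Inf, prod_acc[-nrow(prod_acc), , drop = FALSE])
  dn <- rbind(prod_acc[-1, , drop = FALSE], -Inf)
  peaks <- prod_acc[prod_acc >= up & prod_acc > dn]
  peaks <- sort(peaks, decreasing = TRUE)
  list(score = sum(peaks[seq_len(min(cfg$n_peaks, length(peaks)))]),
       rho0 = rhos[(i - 1L) %% nrow(prod_acc) + 1L],
       theta0 = thetas[(i - 1L) %/% nrow(prod_acc) + 1L])
}

#' Estimate the radial distortion coefficient of a single image
#'
#' Scans `n_steps + 1` candidates over `[k_min, k_max]`, keeps the
#' straightness-score maximizer, then re-centers and shrinks the interval by
#' `1 / n_steps` and repeats for up to `cfg$rounds` rounds (stopping early
#' once the grid step falls below `cfg$k_tol`). The distortion center is fixed
#' at the image center.
#' @param img H x W x 3 array, at least 128 x 128.
#' @param cfg a `"correction_config"`.
#' @param verbose print per-round progress.
#' @return object of class `"distortion_model"`: `k`, `center`, `score`,
#'   `rho0`, `theta0`, `degenerate` (TRUE when the image has no edges, in
#'   which case `k = 0`).
#' @export
estimate_k <- function(img, cfg = correction_config(), verbose = FALSE) {
  check_image(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H < 128L || W < 128L) stop("image must be at least 128 x 128", call. = FALSE)
  center <- c((W - 1) / 2, (H - 1) / 2)
  if (!any(detect_edges(img, cfg))) {
    warning("no edges detected; returning k = 0")
    return(structure(list(k = 0, center = center, score = 0, rho0 = NA_real_,
                          theta0 = NA_real_, degenerate = TRUE),
                     class = "distortion_model"))
  }
  lo <- cfg$k_min; hi <- cfg$k_max
  best <- list(k = lo, score = -Inf, rho0 = NA_real_, theta0 = NA_real_)
  for (round in seq_len(cfg$rounds)) {
    step <- (hi - lo) / cfg$n_steps
    if (step < cfg$k_tol) break
    ks <- lo + (0:cfg$n_steps) * step
    best_round <- NULL
    for (k in ks) {
      sc <- tryCatch(straightness_score(img, k, cfg), error = function(e) NULL)
      if (is.null(sc)) next
      if (is.null(best_round) || sc$score > best_round$score)
        best_round <- list(k = k, score = sc$score, rho0 = sc$rho0, theta0 = sc$theta0)
    }
    if (is.null(best_round)) break
    best <- best_round
    if (verbose)
      message(sprintf("round %d: k = %.4g (score %.4g, step %.2g)",
                      round, best$k, best$score, step))
    half <- (hi - lo) / (2 * cfg$n_steps)
    lo <- max(cfg$k_min, best$k - half)
    hi <- min(cfg$k_max, best$k + half)
  }
  structure(list(k = best$k, center = center, score = best$score,
                 rho0 = best$rho0, theta0 = best$theta0, degenerate = FALSE),
            class = "distortion_model")
}

#' @export
print.distortion_model <- function(x, ...) {
  cat("division-model radial distortion: k = ", format(x$k, digits = 4),
      " px^-2, center (", x$center[1], ", ", x$center[2], ")\n", sep = "")
  if (isTRUE(x$degenerate)) cat("  (degenerate: no edges found)\n")
  else cat("  peak (rho0, theta0) = (", format(x$rho0, digits = 4), ", ",
           format(x$theta0, digits = 4), "), score ",
           format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write / read a distortion model as plain text
#' @param model a `"distortion_model"`.
#' @param path file path.
#' @export
write_distortion_model <- function(model, path) {
  writeLines(c(format(model$k, digits = 17),
               paste(format(model$center, digits = 17), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_distortion_model
#' @export
read_distortion_model <- function(path) {
  ln <- readLines(path)
  structure(list(k = as.numeric(ln[1]),
                 center = as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]]),
                 score = NA_real_, rho0 = NA_real_, theta0 = NA_real_,
                 degenerate = FALSE),
            class = "distortion_model")
}

# ---- line curvature diagnostic ---------------------------------------------

#' Mean curvature of detected edge chains
#'
#' Labels 8-connected edge chains and, for every chain of at least `min_len`
#' pixels, measures the maximum perpendicular deviation of its pixels from the
#' chord joining its two most distant points. The mean over chains is a
#' straightness diagnostic: it shrinks when radial distortion is corrected.
#' @param img H x W x 3 array (or logical edge matrix).
#' @param cfg a `"correction_config"` for edge detection.
#' @param min_len minimum chain length in pixels.
#' @return mean max-deviation in pixels (NA when no chain is long enough).
#' @export
line_curvature <- function(img, cfg = correction_config(), min_len = 30L) {
  edges <- if (is.logical(img) && is.matrix(img)) img else detect_edges(img, cfg)
  valid <- attr(img, "valid")
  if (!is.null(valid)) edges <- edges & erode_mask(valid, ceiling(3 * cfg$canny_sigma) + 2L)
  H <- nrow(edges); W <- ncol(edges)
  lab <- matrix(0L, H, W)
  cur <- 0L
  nbr_di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  devs <- numeric(0)
  todo <- which(edges)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    members <- integer(0)
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, p)
      i <- (p - 1L) %% H + 1L
      j <- (p - 1L) %/% H + 1L
      for (t in 1:8) {
        ii <- i + nbr_di[t]; jj <- j + nbr_dj[t]
        if (ii < 1L || ii > H || jj < 1L || jj > W) next
        q <- ii + (jj - 1L) * H
        if (edges[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
    if (length(members) < min_len) next
    yy <- (members - 1L) %% H
    xx <- (members - 1L) %/% H
    # chord endpoints: extremes along the principal direction
    cx <- xx - mean(xx); cy <- yy - mean(yy)
    cov <- cbind(c(sum(cx * cx), sum(cx * cy)), c(sum(cx * cy), sum(cy * cy)))
    ev <- eigen(cov, symmetric = TRUE)$vectors[, 1]
    proj <- cx * ev[1] + cy * ev[2]
    a <- which.min(proj); b <- which.max(proj)
    dx <- xx[b] - xx[a]; dy <- yy[b] - yy[a]
    len <- sqrt(dx^2 + dy^2)
    if (len < 1) next
    dev <- abs(dx * (yy - yy[a]) - dy * (xx - xx[a])) / len
    devs <- c(devs, max(dev))
  }
  if (!length(devs)) return(NA_real_)
  mean(devs)
}
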