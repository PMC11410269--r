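# ---- image container conventions -------------------------------------------
# Images are numeric arrays dim c(H, W, 3) with intensities in [0, 255].
# Pixel coordinates are 0-based pixel centers: x (column index) rightward,
# y (row index) downward, so array element [y + 1, x + 1, c] is pixel (x, y).
# Masks and single-channel maps are H x W matrices.

#' Clamp values to a range
#' @param x numeric vector/array.
#' @param lo,hi range bounds.
#' @return `x` with values clipped to `[lo, hi]`, shape preserved.
#' @keywords internal
clamp <- function(x, lo = 0, hi = 255) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

#' Run an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' session RNG.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Validate an RGB image array
#' @keywords internal
check_image <- function(img, name = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(name, " must be an H x W x 3 array", call. = FALSE)
  if (anyNA(img)) stop(name, " contains NA", call. = FALSE)
  invisible(img)
}

#' Convert RGB to luma
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`.
#' @param img H x W x 3 array in \[0, 255\].
#' @return H x W matrix.
#' @export
luma <- function(img) {
  check_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read an RGB image from a PNG file
#' @param path file path.
#' @return H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] == 2L) px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  px * 255
}

#' Write an RGB image to a PNG file
#' @param img H x W x 3 array in \[0, 255\].
#' @param path file path.
#' @export
write_image <- function(img, path) {
  check_image(img)
  png::writePNG(clamp(img) / 255, path)
  invisible(path)
}

# ---- separable resize ------------------------------------------------------

#' Row/column weight matrix for 1-D resampling
#'
#' Returns the dense `n_out x n_in` matrix `A` such that `y = A %*% x`
#' resamples a length-`n_in` signal to length `n_out`. `"bilinear"` uses
#' pixel-center linear interpolation (border-clamped); `"area"` uses exact
#' box-overlap averaging, the antialiasing choice for downsampling. Rows sum
#' to one in both modes.
#' @param n_in,n_out input/output lengths.
#' @param method `"bilinear"` or `"area"`.
#' @keywords internal
resize_weights <- function(n_in, n_out, method = c("bilinear", "area")) {
  method <- match.arg(method)
  A <- matrix(0, n_out, n_in)
  if (n_in == n_out) {
    diag(A) <- 1
    return(A)
  }
  if (method == "bilinear") {
    u <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    u <- pmin(pmax(u, 0), n_in - 1)
    j0 <- floor(u)
    f <- u - j0
    j1 <- pmin(j0 + 1, n_in - 1)
    for (i in seq_len(n_out)) {
      A[i, j0[i] + 1] <- A[i, j0[i] + 1] + (1 - f[i])
      A[i, j1[i] + 1] <- A[i, j1[i] + 1] + f[i]
    }
  } else {
    s <- n_in / n_out
    for (i in seq_len(n_out)) {
      a <- (i - 1) * s
      b <- i * s
      j <- floor(a)
      while (j < b && j < n_in) {
        ov <- min(b, j + 1) - max(a, j)
        if (ov > 0) A[i, j + 1] <- ov / s
        j <- j + 1
      }
      A[i, ] <- A[i, ] / sum(A[i, ])
    }
  }
  A
}

#' Resize an image or mask
#'
#' Separable resampling: bilinear for upsampling, box/area averaging for
#' antialiased downsampling.
#' @param img H x W x C array or H x W matrix.
#' @param h,w output size.
#' @param method `"bilinear"` or `"area"`.
#' @return resized array/matrix.
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "area")) {
  method <- match.arg(method)
  ismat <- is.matrix(img)
  if (ismat) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  R <- resize_weights(d[1], h, method)
  Cw <- resize_weights(d[2], w, method)
  out <- array(0, c(h, w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- R %*% img[, , c] %*% t(Cw)
  if (ismat) out[, , 1] else out
}

# ---- separable Gaussian blur -----------------------------------------------

#' Normalized 1-D Gaussian kernel
#' @keywords internal
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of matrix rows/cols with kernel k, zero or replicate padding
conv_sep1 <- function(m, k, dim = 1L, pad = "zero") {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(m)[dim]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    off <- t - r - 1L
    src <- seq_len(n) + off
    if (pad == "replicate") src <- pmin(pmax(src, 1L), n)
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    if (dim == 1L) out[ok, ] <- out[ok, ] + k[t] * m[src[ok], , drop = FALSE]
    else out[, ok] <- out[, ok] + k[t] * m[, src[ok], drop = FALSE]
  }
  out
}

#' Separable Gaussian blur
#'
#' @param img H x W matrix or H x W x C array.
#' @param sigma standard deviation in pixels/bins.
#' @param pad `"replicate"` (images) or `"zero"` (accumulators; preserves the
#'   vote mass of interior impulses).
#' @return blurred array, same shape.
#' @export
gaussian_blur <- function(img, sigma, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  f <- function(m) conv_sep1(conv_sep1(m, k, 1L, pad), k, 2L, pad)
  if (is.matrix(img)) return(f(img))
  out <- img
  for (c in seq_len(dim(img)[3])) out[, , c] <- f(img[, , c])
  out
}

# ---- bilinear sampling (plain, non-differentiable path) --------------------

#' Bilinear gather at fractional coordinates with zero padding
#'
#' @param ch H x W matrix (one channel).
#' @param u,v vectors of 0-based sample coordinates (x, y).
#' @return vector of sampled values; samples fully outside return 0, border
#'   samples blend with 0 (this is what yields fractional content masks).
#' @keywords internal
bilinear_gather <- function(ch, u, v) {
  H <- nrow(ch); W <- ncol(ch)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  g <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1)
    out <- numeric(length(xi))
    out[ok] <- ch[cbind(yi[ok] + 1, xi[ok] + 1)]
    out
  }
  (1 - fu) * (1 - fv) * g(u0, v0) +
    fu * (1 - fv) * g(u0 + 1, v0) +
    (1 - fu) * fv * g(u0, v0 + 1) +
    fu * fv * g(u0 + 1, v0 + 1)
}

#' Warp an image by a backward coordinate mapping
#'
#' For every output pixel `(x, y)` the source location is given by `u`/`v`;
#' values are gathered bilinearly, out-of-range samples are black.
#' @param img H x W x C array (or matrix).
#' @param u,v matrices (out_h x out_w) of 0-based source coordinates.
#' @return warped array of shape out_h x out_w x C.
#' @keywords internal
warp_backward <- function(img, u, v) {
  ismat <- is.matrix(img)
  if (ismat) img <- array(img, c(dim(img), 1L))
  C <- dim(img)[3]
  out <- array(0, c(nrow(u), ncol(u), C))
  uu <- as.vector(u); vv <- as.vector(v)
  for (c in seq_len(C)) out[, , c] <- bilinear_gather(img[, , c], uu, vv)
  if (ismat) out[, , 1] else out
}

#' Mean squared error between two equally sized arrays (8-bit scale)
#' @keywords internal
mse_arrays <- function(a, b) mean((a - b)^2)

#' Peak signal-to-noise ratio at 8-bit peak
#' @param mse mean squared error on the \[0, 255\] scale.
#' @return PSNR in dB; `Inf` when `mse == 0`.
#' @keywords internal
psnr_from_mse <- function(mse) {
  if (mse <= 0) return(Inf)
  10 * log10(255^2 / mse)
}
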