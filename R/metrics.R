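# ---- evaluation battery -----------------------------------------------------
# MSE / RMSE / PSNR / SSIM / sliding-window RMSE between a stitched output and
# the ground-truth label, under "crop" (centered crop of the larger to the
# smaller) or "resize" (output resized to the label) normalization. All
# metrics are computed on the 8-bit [0, 255] scale.

#' Structural similarity index
#'
#' Standard single-scale SSIM with an 11 x 11 Gaussian window (sigma 1.5),
#' stabilizers `K1 = 0.01`, `K2 = 0.03` at dynamic range 255, averaged over
#' channels.
#' @param a,b H x W x 3 arrays (or matrices) in `[0, 255]`.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim_index <- function(a, b) {
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  if (is.matrix(b)) b <- array(b, c(dim(b), 1L))
  stopifnot(all(dim(a) == dim(b)))
  if (min(dim(a)[1:2]) < 11L) stop("images smaller than the 11x11 SSIM window", call. = FALSE)
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  k <- gauss_kernel_11()
  win <- function(m) conv_sep1(conv_sep1(m, k, 1L, pad = "zero"), k, 2L, pad = "zero")
  # restrict to fully supported window positions
  r <- 5L
  H <- dim(a)[1]; W <- dim(a)[2]
  ii <- (r + 1L):(H - r); jj <- (r + 1L):(W - r)
  vals <- numeric(dim(a)[3])
  for (c in seq_len(dim(a)[3])) {
    x <- a[, , c]; y <- b[, , c]
    mx <- win(x); my <- win(y)
    sxx <- win(x * x) - mx * mx
    syy <- win(y * y) - my * my
    sxy <- win(x * y) - mx * my
    s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
      ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    vals[c] <- mean(s[ii, jj])
  }
  mean(vals)
}

# 11-tap Gaussian window, sigma 1.5, normalized
gauss_kernel_11 <- function() {
  k <- exp(-(seq(-5, 5))^2 / (2 * 1.5^2))
  k / sum(k)
}

#' Sliding-window RMSE
#'
#' Mean over all 32 x 32 windows (stride 16) of the per-window RMSE, using
#' only windows where at least half of the pixels are valid. This
#' locality-sensitive aggregate is a package convention (the windowed RMSE is
#' not standardized); window size, stride and the validity rule are fixed
#' here and reported with the metric.
#' @param a,b equally sized H x W x 3 arrays in `[0, 255]`.
#' @param valid optional H x W logical matrix of valid (label-covered)
#'   pixels; all-valid when `NULL`.
#' @param win,stride window size and stride in px.
#' @return RMSE aggregate (NA when no window qualifies).
#' @export
rmse_sw <- function(a, b, valid = NULL, win = 32L, stride = 16L) {
  stopifnot(all(dim(a) == dim(b)))
  H <- dim(a)[1]; W <- dim(a)[2]
  if (H < win || W < win) stop("images smaller than the sliding window", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  vals <- numeric(0)
  for (i0 in seq(1L, H - win + 1L, by = stride)) {
    for (j0 in seq(1L, W - win + 1L, by = stride)) {
      vsub <- valid[i0:(i0 + win - 1L), j0:(j0 + win - 1L)]
      if (mean(vsub) < 0.5) next
      d <- a[i0:(i0 + win - 1L), j0:(j0 + win - 1L), , drop = FALSE] -
        b[i0:(i0 + win - 1L), j0:(j0 + win - 1L), , drop = FALSE]
      vals <- c(vals, sqrt(mean(d^2)))
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Pairwise image-quality metrics
#'
#' @param output stitched image (H x W x 3, `[0, 255]`).
#' @param label ground-truth stitched image.
#' @param mode `"resize"` (output resampled to the label size) or `"crop"`
#'   (centered crop of the larger image to the common size).
#' @return object of class `"metric_report"`: list with `mse`, `rmse`,
#'   `psnr` (dB; `Inf` for identical images), `ssim`, `rmse_sw` and `mode`.
#' @export
pair_metrics <- function(output, label, mode = c("resize", "crop")) {
  mode <- match.arg(mode)
  check_image(output, "output"); check_image(label, "label")
  if (mode == "resize") {
    if (!all(dim(output) == dim(label)))
      output <- resize_image(output, dim(label)[1], dim(label)[2],
                             if (prod(dim(output)[1:2]) > prod(dim(label)[1:2])) "area" else "bilinear")
  } else {
    h <- min(dim(output)[1], dim(label)[1])
    w <- min(dim(output)[2], dim(label)[2])
    cc <- function(img) {
      i0 <- (dim(img)[1] - h) %/% 2L
      j0 <- (dim(img)[2] - w) %/% 2L
      img[(i0 + 1L):(i0 + h), (j0 + 1L):(j0 + w), , drop = FALSE]
    }
    output <- cc(output); label <- cc(label)
  }
  if (min(dim(label)[1:2]) < 32L)
    stop("images too small for the metric battery (need >= 32 px)", call. = FALSE)
  mse <- mse_arrays(output, label)
  rep <- structure(list(mse = mse, rmse = sqrt(mse), psnr = psnr_from_mse(mse),
                        ssim = ssim_index(output, label),
                        rmse_sw = rmse_sw(output, label), mode = mode),
                   class = "metric_report")
  stopifnot(abs(rep$rmse - sqrt(rep$mse)) < 1e-9)
  if (is.finite(rep$psnr))
    stopifnot(abs(rep$psnr - 10 * log10(255^2 / rep$mse)) < 1e-9)
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metrics (%s): MSE %.2f  RMSE %.2f  PSNR %s dB  SSIM %.4f  RMSE_SW %.2f\n",
              x$mode, x$mse, x$rmse,
              if (is.finite(x$psnr)) sprintf("%.2f", x$psnr) else "Inf",
              x$ssim, x$rmse_sw))
  invisible(x)
}

#' Evaluate trained weights over a dataset
#'
#' Stitches every sample and compares against its label. Samples whose
#' stitching raises an error are counted separately and excluded from the
#' means (infinite PSNR values are likewise excluded from the PSNR mean).
#' @param dataset list of `"quadruple"` samples or a dataset directory.
#' @param hweights,rweights trained parameter stores.
#' @param mode `"resize"` or `"crop"`.
#' @return list with `aggregate` (mean metrics), `per_sample` (data frame),
#'   and `errors` (failure count).
#' @export
batch_report <- function(dataset, hweights, rweights, mode = c("resize", "crop")) {
  mode <- match.arg(mode)
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  rows <- list()
  errors <- 0L
  for (i in seq_along(dataset)) {
    q <- dataset[[i]]
    res <- tryCatch({
      st <- stitch(q$I_A, q$I_B, hweights, rweights)
      m <- pair_metrics(st$S_HR, q$label, mode)
      data.frame(sample = i, mse = m$mse, rmse = m$rmse, psnr = m$psnr,
                 ssim = m$ssim, rmse_sw = m$rmse_sw)
    }, error = function(e) NULL)
    if (is.null(res)) errors <- errors + 1L else rows[[length(rows) + 1L]] <- res
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = integer(), mse = numeric(), rmse = numeric(),
               psnr = numeric(), ssim = numeric(), rmse_sw = numeric())
  agg <- if (nrow(per)) {
    list(mse = mean(per$mse), rmse = mean(per$rmse),
         psnr = mean(per$psnr[is.finite(per$psnr)]),
         ssim = mean(per$ssim), rmse_sw = mean(per$rmse_sw, na.rm = TRUE))
  } else list(mse = NA_real_, rmse = NA_real_, psnr = NA_real_,
              ssim = NA_real_, rmse_sw = NA_real_)
  list(aggregate = agg, per_sample = per, errors = errors, mode = mode)
}
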