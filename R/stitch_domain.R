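# ---- stitching-domain transformer layer ------------------------------------
# Computes the warped target corners, the minimal bounding canvas that holds
# the reference image and the warped target, and warps both images (plus
# all-ones masks) into that canvas by backward bilinear sampling.

#' Warped target-corner coordinates
#'
#' Each target corner `(x_k, y_k)` moves to `(x_k + dx_k, y_k + dy_k)`;
#' corners are at 0-based pixel centers `(0,0)`, `(W-1,0)`, `(W-1,H-1)`,
#' `(0,H-1)`.
#' @param off 4 x 2 offsets (TL, TR, BR, BL).
#' @param size `c(H, W)`.
#' @return 4 x 2 matrix of warped corner coordinates.
#' @export
warped_vertices <- function(off, size) {
  off <- as.matrix(off)
  stopifnot(all(is.finite(off)))
  image_corners(size[1], size[2]) + off
}

#' Minimal bounding canvas of reference and warped target
#'
#' The canvas spans from the floor of the smallest to the ceiling of the
#' largest coordinate over the four reference corners (identical to the
#' undisplaced target corners) and the four warped corners, so no content is
#' ever cropped. The translation maps reference-frame coordinates into canvas
#' coordinates.
#' @param vertsW 4 x 2 warped corner coordinates.
#' @param size reference image size `c(H, W)`.
#' @return list with `h`, `w` (canvas size `H*`, `W*`) and
#'   `translation = c(tx, ty)`.
#' @export
canvas_size <- function(vertsW, size) {
  stopifnot(all(is.finite(vertsW)))
  ref <- image_corners(size[1], size[2])
  xs <- c(vertsW[, 1], ref[, 1])
  ys <- c(vertsW[, 2], ref[, 2])
  x0 <- floor(min(xs)); x1 <- ceiling(max(xs))
  y0 <- floor(min(ys)); y1 <- ceiling(max(ys))
  w <- as.integer(x1 - x0 + 1L)
  h <- as.integer(y1 - y0 + 1L)
  if (w <= 0L || h <= 0L) stop("degenerate (zero-area) canvas", call. = FALSE)
  list(h = h, w = w, translation = c(-x0, -y0))
}

#' Warp both images into the stitching domain
#'
#' Places the reference image into the canvas by the (translated) identity
#' warp and the target image by the homography `H`; content masks are the same
#' warps applied to all-ones images. Sampling is backward bilinear with zero
#' fill, so masks are exactly 1 in the warped interiors and fall off to 0
#' across a sub-pixel border band.
#' @param I_A,I_B reference and target images (H x W x 3).
#' @param H 3 x 3 homography mapping target coordinates to reference
#'   coordinates (from [solve_homography()]).
#' @param canvas optional canvas from [canvas_size()]; computed from the
#'   corner images of `H` when missing.
#' @return object of class `"stitch_canvas"`: list with `h`, `w`,
#'   `translation`, warped images `I_AW`, `I_BW` and content masks `M_AC`,
#'   `M_BC` (H* x W* matrices in `[0, 1]`).
#' @export
warp_to_canvas <- function(I_A, I_B, H, canvas = NULL) {
  check_image(I_A, "I_A"); check_image(I_B, "I_B")
  hB <- dim(I_B)[1]; wB <- dim(I_B)[2]
  corners <- image_corners(hB, wB)
  vertsW <- apply_h(H, corners)
  if (is.null(canvas)) canvas <- canvas_size(vertsW, dim(I_A)[1:2])
  tx <- canvas$translation[1]; ty <- canvas$translation[2]
  all_in <- function(p) all(p[, 1] + tx >= -1e-6 & p[, 1] + tx <= canvas$w - 1 + 1e-6 &
                            p[, 2] + ty >= -1e-6 & p[, 2] + ty <= canvas$h - 1 + 1e-6)
  if (!all_in(vertsW) || !all_in(image_corners(dim(I_A)[1], dim(I_A)[2])))
    stop("canvas does not contain all warped corners", call. = FALSE)
  Hinv <- solve(H)
  Hinv <- Hinv / Hinv[3, 3]
  id8 <- c(1, 0, 0, 0, 1, 0, 0, 0)
  ones_A <- matrix(1, dim(I_A)[1], dim(I_A)[2])
  ones_B <- matrix(1, hB, wB)
  tp <- nn_tape()  # non-differentiable use of the shared warp kernel
  I_AW <- nn_warp(tp, I_A, id8, canvas$h, canvas$w, tx, ty)$val
  I_BW <- nn_warp(tp, I_B, h_to_vec(Hinv), canvas$h, canvas$w, tx, ty)$val
  M_AC <- nn_warp(tp, ones_A, id8, canvas$h, canvas$w, tx, ty)$val
  M_BC <- nn_warp(tp, ones_B, h_to_vec(Hinv), canvas$h, canvas$w, tx, ty)$val
  structure(list(h = canvas$h, w = canvas$w, translation = canvas$translation,
                 I_AW = I_AW, I_BW = I_BW,
                 M_AC = clamp(M_AC, 0, 1), M_BC = clamp(M_BC, 0, 1), H = H),
            class = "stitch_canvas")
}

#' @export
print.stitch_canvas <- function(x, ...) {
  cat("stitch canvas ", x$h, " x ", x$w,
      ", translation (", x$translation[1], ", ", x$translation[2], ")\n",
      "  content coverage: A ", sprintf("%.1f%%", 100 * mean(x$M_AC > 0.5)),
      ", B ", sprintf("%.1f%%", 100 * mean(x$M_BC > 0.5)), "\n", sep = "")
  invisible(x)
}

#' Dump the warped images and masks of a canvas as PNG files
#' @param canvas a `"stitch_canvas"`.
#' @param dir output directory.
#' @export
dump_warps <- function(canvas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(canvas$I_AW, file.path(dir, "I_AW.png"))
  write_image(canvas$I_BW, file.path(dir, "I_BW.png"))
  png::writePNG(clamp(canvas$M_AC, 0, 1), file.path(dir, "M_AC.png"))
  png::writePNG(clamp(canvas$M_BC, 0, 1), file.path(dir, "M_BC.png"))
  invisible(dir)
}
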