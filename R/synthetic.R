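# ---- synthetic endoscopy-like scenes and stitching quadruples --------------
# Real gastroenteroscopy frames show low-texture mucosa under strongly varying
# illumination. The generator emulates that with a pinkish base color, a
# low-frequency illumination gradient and several octaves of band-limited
# value noise; the stitching quadruples follow the standard synthetic-warp
# recipe: crop a reference patch, crop a projectively perturbed patch with a
# controlled overlap, and keep the exact corner motions as ground truth.

#' Generate a textured endoscopy-like source image
#'
#' @param seed integer seed; the output is bit-identical for identical inputs.
#' @param size `c(H, W)`, both at least 64.
#' @param texture_level amplitude of the band-limited texture and of the
#'   illumination gradient, in `[0, 1]`; 0 gives a per-channel constant image.
#' @param brightness_class `"normal"` or `"strong"`; strong-light frames are
#'   rescaled until their mean intensity exceeds 200 (the usual strong-light
#'   cutoff for endoscopy frames).
#' @param blur_px motion-blur extent in pixels; values above 1 apply a linear
#'   blur kernel longer than one pixel.
#' @return H x W x 3 array in `[0, 255]` with a `meta` attribute recording
#'   `texture_level`, `brightness_class` and `blur_px`.
#' @export
generate_texture_image <- function(seed, size = c(256L, 256L), texture_level = 0.6,
                                   brightness_class = c("normal", "strong"),
                                   blur_px = 0) {
  brightness_class <- match.arg(brightness_class)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 64L || W < 64L) stop("size must be at least 64 x 64", call. = FALSE)
  if (texture_level < 0 || texture_level > 1) stop("texture_level must be in [0, 1]", call. = FALSE)
  img <- with_seed(seed, {
    base <- c(185, 125, 115) + stats::runif(3, -12, 12)  # mucosa palette
    # low-frequency illumination: bilinear ramp between 4 random corner gains
    corner <- matrix(stats::runif(4, -1, 1), 2, 2)
    ry <- seq(0, 1, length.out = H)
    rx <- seq(0, 1, length.out = W)
    illum <- outer(1 - ry, 1 - rx) * corner[1, 1] + outer(1 - ry, rx) * corner[1, 2] +
      outer(ry, 1 - rx) * corner[2, 1] + outer(ry, rx) * corner[2, 2]
    # band-limited value noise: coarse white noise upsampled, three octaves
    tex <- matrix(0, H, W)
    amp <- 1
    for (cell in c(8L, 16L, 32L)) {
      hh <- max(2L, ceiling(H / cell)); ww <- max(2L, ceiling(W / cell))
      coarse <- matrix(stats::rnorm(hh * ww), hh, ww)
      tex <- tex + amp * resize_image(coarse, H, W, "bilinear")
      amp <- amp * 0.6
    }
    tex <- tex / stats::sd(tex)
    lum <- texture_level * (28 * tex + 35 * illum)
    chroma <- texture_level * 6 * resize_image(matrix(stats::rnorm(64), 8, 8), H, W, "bilinear")
    img <- array(0, c(H, W, 3))
    img[, , 1] <- base[1] + lum + chroma
    img[, , 2] <- base[2] + lum - 0.5 * chroma
    img[, , 3] <- base[3] + lum - 0.5 * chroma
    img
  })
  if (blur_px > 0) {
    len <- as.integer(round(blur_px)) + 1L
    if (len > 1L) {
      k <- rep(1 / len, len)
      for (c in 1:3) img[, , c] <- conv_sep1(img[, , c], k, 2L, pad = "replicate")
    }
  }
  img <- clamp(img)
  if (brightness_class == "strong") {
    img <- img + (215 - mean(img))
    img <- clamp(img)
    while (mean(img) <= 200) img <- clamp(img + 5)
  }
  attr(img, "meta") <- list(texture_level = texture_level,
                            brightness_class = brightness_class,
                            blur_px = blur_px)
  img
}

#' Generate a straight-line grid fixture
#'
#' A light background crossed by dark quasi-vertical and quasi-horizontal
#' lines, rendered analytically from their distance fields with a 1 px
#' antialiasing ramp; the canonical target for line-straightness based
#' distortion estimation. Lines passing close to the distortion center stay
#' straight under radial distortion and carry no calibration signal, so a
#' `center_gap` keeps the fixture's lines at informative radii, and a small
#' `angle` tilt avoids the degenerate case of exactly pixel-aligned lines.
#' @param size `c(H, W)`.
#' @param spacing line spacing in pixels.
#' @param width line width in pixels.
#' @param margin border kept free of lines.
#' @param center_gap half-width of the central band (around the image center)
#'   kept free of lines, per orientation.
#' @param angle line tilt in radians (within the quasi-axial Hough bands).
#' @param orientation draw `"both"` families or only `"vertical"` /
#'   `"horizontal"` lines (crossing-free fixtures for edge-chain
#'   diagnostics).
#' @return H x W x 3 array in `[0, 255]`.
#' @export
generate_line_grid <- function(size = c(512L, 512L), spacing = 48L, width = 5L,
                               margin = 16L, center_gap = 0L, angle = 0.03,
                               orientation = c("both", "vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  x <- matrix(rep(0:(W - 1), each = H), H, W) - (W - 1) / 2
  y <- matrix(rep(0:(H - 1), W), H, W) - (H - 1) / 2
  ink <- matrix(0, H, W)
  rots <- switch(orientation, both = c(0, pi / 2), vertical = 0,
                 horizontal = pi / 2)
  draw <- function(r) {
    # quasi-vertical: x cos(a) + y sin(a) = r; quasi-horizontal rotated 90deg
    for (rot in rots) {
      d <- abs(x * cos(angle + rot) + y * sin(angle + rot) - r)
      ink <<- pmax(ink, clamp(width / 2 + 0.5 - d, 0, 1))
    }
  }
  half <- (min(H, W) - 1) / 2
  offs <- seq(center_gap, half - margin, by = spacing)
  offs <- offs[offs >= center_gap]
  for (r in c(-rev(offs), offs[if (center_gap > 0) TRUE else -1])) draw(r)
  img <- 235 - 205 * ink
  array(rep(img, 3L), c(H, W, 3L))
}

# ---- four-point offsets and the direct linear solve ------------------------

# 0-based corner coordinates (pixel centers), order TL, TR, BR, BL.
image_corners <- function(h, w) {
  matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1), 4L, 2L, byrow = TRUE,
         dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")))
}

# Solve the 3x3 projective transform mapping src points to dst points
# (both 4 x 2), normalized so H[3, 3] = 1.
dlt_solve <- function(src, dst) {
  A <- matrix(0, 8L, 8L)
  bvec <- numeric(8L)
  for (k in 1:4) {
    x <- src[k, 1]; y <- src[k, 2]
    xp <- dst[k, 1]; yp <- dst[k, 2]
    A[2 * k - 1, ] <- c(x, y, 1, 0, 0, 0, -x * xp, -y * xp)
    A[2 * k, ] <- c(0, 0, 0, x, y, 1, -x * yp, -y * yp)
    bvec[2 * k - 1] <- xp
    bvec[2 * k] <- yp
  }
  h <- tryCatch(solve(A, bvec),
                error = function(e) stop("degenerate corner configuration", call. = FALSE))
  matrix(c(h, 1), 3L, 3L, byrow = TRUE)
}

#' Homography from four-point corner offsets
#'
#' Builds the 3x3 projective matrix that maps the target image corners
#' (TL, TR, BR, BL at 0-based pixel centers) onto the displaced corners
#' `corner + offset`, by a direct linear solve; normalized so the bottom-right
#' entry is 1.
#' @param off 4 x 2 matrix of corner displacements `(dx, dy)`, rows ordered
#'   TL, TR, BR, BL.
#' @param size image size `c(H, W)`.
#' @return 3 x 3 homography matrix (target frame to reference frame).
#' @export
solve_homography <- function(off, size) {
  off <- as.matrix(off)
  stopifnot(nrow(off) == 4L, ncol(off) == 2L)
  if (any(!is.finite(off))) stop("offsets must be finite", call. = FALSE)
  corners <- image_corners(size[1], size[2])
  dlt_solve(corners, corners + off)
}

# Inverse map (reference frame -> target frame) solved directly so corners
# interpolate exactly; used by the warping layers.
solve_homography_inv <- function(off, size) {
  corners <- image_corners(size[1], size[2])
  dlt_solve(corners + off, corners)
}

# Flatten a homography matrix (with [3,3] == 1) to its 8-vector.
h_to_vec <- function(H) c(t(H))[1:8]

apply_h <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2] / p[, 3]
}

# ---- stitching quadruples ---------------------------------------------------

#' Build a synthetic stitching quadruple
#'
#' Crops a reference patch `I_A` from `source`, then crops a target patch
#' `I_B` from a projectively perturbed copy: the target window is displaced
#' laterally to achieve the requested overlap and each of its four corners is
#' shifted independently by up to `max_corner_shift` pixels. The exact corner
#' motions are stored as ground truth, and the ground-truth stitched `label`
#' is the source crop covering the union region (computed with the same
#' minimal-bounding-canvas rule used at inference).
#'
#' @param source H x W x 3 source image.
#' @param patch patch size `c(h, w)`.
#' @param overlap_rate requested overlap fraction in `(0, 1]`.
#' @param max_corner_shift per-axis bound on the uniform corner perturbation
#'   (pixels).
#' @param seed integer seed.
#' @return an object of class `"quadruple"`: list with `I_A`, `I_B`,
#'   `gt_offsets` (4 x 2, TL/TR/BR/BL), `label`, `overlap_rate` (measured),
#'   `overlap_class` (`"high"` above 0.6), and `size`.
#' @export
make_stitch_quadruple <- function(source, patch = c(128L, 128L), overlap_rate = 0.7,
                                  max_corner_shift = 10, seed = 1L) {
  check_image(source, "source")
  h <- as.integer(patch[1]); w <- as.integer(patch[2])
  if (overlap_rate <= 0 || overlap_rate > 1) stop("overlap_rate must be in (0, 1]", call. = FALSE)
  H <- dim(source)[1]; W <- dim(source)[2]
  m <- ceiling(max_corner_shift)
  d_hi <- ceiling(w * (1 - overlap_rate)) + 2L * m  # upper bound on displacement
  if (w + d_hi + 2 * m + 2 > W || h + 2 * m + 2 > H)
    stop("requested overlap/shift needs a source of at least ",
         w + d_hi + 2 * m + 2, " x ", h + 2 * m + 2, " px; got ", W, " x ", H,
         call. = FALSE)
  with_seed(seed, {
    x0 <- sample.int(W - w - d_hi - 2 * m - 1L, 1L) + m  # A window origin (0-based)
    y0 <- sample.int(H - h - 2 * m - 1L, 1L) + m
    pert <- matrix(stats::runif(8, -max_corner_shift, max_corner_shift), 4L, 2L)
    a0 <- c(x0, y0)
    corners <- image_corners(h, w)
    # Pixel-overlap fraction of the A window with the perturbed target quad
    # displaced laterally by d; the displacement is solved by bisection so the
    # measured overlap matches the request despite the corner perturbation.
    gx <- rep(0:(w - 1), each = h) + a0[1]
    gy <- rep(0:(h - 1), w) + a0[2]
    quad_at <- function(d) sweep(corners, 2L, a0 + c(d, 0), "+") + pert
    ov_at <- function(d) mean(point_in_quad(gx, gy, quad_at(d)))
    if (ov_at(0) < overlap_rate - 0.05)
      stop("overlap_rate = ", overlap_rate, " is not reachable: the corner-",
           "shift budget (", max_corner_shift, " px) caps the overlap at ",
           sprintf("%.3f", ov_at(0)), call. = FALSE)
    d <- 0
    if (ov_at(0) > overlap_rate) {
      lo <- 0; hi <- d_hi
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        if (ov_at(mid) >= overlap_rate) lo <- mid else hi <- mid
      }
      d <- lo
    }
    if (abs(d - round(d)) < 1e-6) d <- round(d)
    quad_src <- quad_at(d)
    I_A <- source[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
    if (max(abs(pert)) == 0 && d == round(d)) {
      # pure integer translation: crop directly so the identity case is exact
      I_B <- source[(y0 + 1):(y0 + h), (x0 + d + 1):(x0 + d + w), , drop = FALSE]
    } else {
      # I_B: backward-warp the source quad onto the h x w target rectangle
      Hq <- dlt_solve(corners, quad_src)        # target rect -> source quad
      cc <- warp_coords(h_to_vec(Hq), h, w)
      I_B <- warp_backward(source, cc$u, cc$v)
    }
    # ground-truth motion of the target corners expressed in the A frame
    gt_offsets <- sweep(quad_src, 2L, a0, "-") - corners
    dimnames(gt_offsets) <- dimnames(corners)
    verts <- warped_vertices(gt_offsets, c(h, w))
    cv <- canvas_size(verts, c(h, w))
    lx <- a0[1] - cv$translation[1]
    ly <- a0[2] - cv$translation[2]
    label <- source[(ly + 1):(ly + cv$h), (lx + 1):(lx + cv$w), , drop = FALSE]
    ov <- ov_at(d)  # measured pixel overlap of the A window with the B quad
    structure(list(I_A = I_A, I_B = I_B, gt_offsets = gt_offsets, label = label,
                   overlap_rate = ov,
                   overlap_class = if (ov > 0.6) "high" else "low",
                   size = c(h, w)),
              class = "quadruple")
  })
}

# Point-in-convex-quadrilateral test (vertices in TL, TR, BR, BL order).
point_in_quad <- function(px, py, quad) {
  inside <- rep(TRUE, length(px))
  for (k in 1:4) {
    a <- quad[k, ]; b <- quad[if (k == 4L) 1L else k + 1L, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & cross >= -1e-9
  }
  inside
}

#' @export
print.quadruple <- function(x, ...) {
  cat("stitching quadruple: ", x$size[1], "x", x$size[2],
      ", overlap ", sprintf("%.3f", x$overlap_rate), " (", x$overlap_class, ")\n",
      "  max |gt offset| = ", sprintf("%.2f", max(abs(x$gt_offsets))), " px",
      ", label ", dim(x$label)[1], "x", dim(x$label)[2], "\n", sep = "")
  invisible(x)
}

# ---- radial distortion forward model ---------------------------------------

#' Apply single-parameter division-model radial distortion
#'
#' Forward model of the radial lens aberration: a distorted pixel at radius
#' `r_d` from the center shows the scene point at undistorted radius
#' `r_u = r_d / (1 + k * r_d^2)`. Resampling is bilinear; samples falling
#' outside the source are black.
#' @param img H x W x 3 array.
#' @param k division-model coefficient (px^-2); `k = 0` is the identity. The
#'   mapping must be monotone over the image radius range (`k * r_max^2 < 1`).
#' @param center distortion center `c(cx, cy)` in 0-based pixel coordinates;
#'   defaults to the image center.
#' @return distorted image, same size.
#' @export
apply_radial_distortion <- function(img, k, center = NULL) {
  check_image(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)
  if (k == 0) return(img)
  rmax2 <- max((c(0, W - 1) - center[1])^2) + max((c(0, H - 1) - center[2])^2)
  if (k * rmax2 >= 1)
    stop("k = ", k, " is not monotone over the image radius range", call. = FALSE)
  x <- matrix(rep(0:(W - 1), each = H), H, W) - center[1]
  y <- matrix(rep(0:(H - 1), W), H, W) - center[2]
  r2 <- x^2 + y^2
  s <- 1 / (1 + k * r2)   # r_u / r_d
  u <- x * s + center[1]
  v <- y * s + center[2]
  out <- warp_backward(img, u, v)
  attr(out, "meta") <- attr(img, "meta")
  out
}

# ---- dataset I/O ------------------------------------------------------------

#' Write a quadruple sample to a directory
#'
#' Writes `I_A.png`, `I_B.png`, `label.png` and a `meta.yaml` sidecar with the
#' ground-truth offsets and the measured overlap rate.
#' @param q a `"quadruple"`.
#' @param dir output directory (created if needed).
#' @export
write_quadruple <- function(q, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(q$I_A, file.path(dir, "I_A.png"))
  write_image(q$I_B, file.path(dir, "I_B.png"))
  write_image(q$label, file.path(dir, "label.png"))
  yaml::write_yaml(list(gt_offsets = as.vector(t(q$gt_offsets)),
                        overlap_rate = q$overlap_rate,
                        overlap_class = q$overlap_class,
                        size = as.integer(q$size)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a quadruple sample written by [write_quadruple()]
#' @param dir sample directory.
#' @return a `"quadruple"` object.
#' @export
read_quadruple <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  off <- matrix(unlist(meta$gt_offsets), 4L, 2L, byrow = TRUE,
                dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")))
  structure(list(I_A = read_image(file.path(dir, "I_A.png")),
                 I_B = read_image(file.path(dir, "I_B.png")),
                 gt_offsets = off,
                 label = read_image(file.path(dir, "label.png")),
                 overlap_rate = meta$overlap_rate,
                 overlap_class = meta$overlap_class,
                 size = as.integer(unlist(meta$size))),
            class = "quadruple")
}

#' Generate a dataset of stitching quadruples
#'
#' Draws textured sources and quadruples across the scene strata observed in
#' endoscopy recordings: high/low overlap split at the 60% boundary, a share
#' of strong-light frames (mean intensity above 200) and of motion-blurred
#' frames (shift above 1 px).
#' @param n number of samples.
#' @param dir optional output directory; when given, samples are written as
#'   `sample_0001`, ... plus an `index.txt`, and the directory path is
#'   returned invisibly alongside the in-memory list.
#' @param seed integer seed.
#' @param size source image size; `patch` patch size.
#' @param overlap_range range the per-sample requested overlap is drawn from.
#' @param max_corner_shift corner perturbation bound (px).
#' @param strong_frac,blur_frac fraction of strong-light / motion-blur frames.
#' @param texture_range range of per-sample texture levels.
#' @return list of `"quadruple"` objects (attribute `dir` if written).
#' @export
generate_dataset <- function(n, dir = NULL, seed = 1L, size = c(256L, 256L),
                             patch = c(128L, 128L), overlap_range = c(0.5, 0.9),
                             max_corner_shift = 10, strong_frac = 0.15,
                             blur_frac = 0.15, texture_range = c(0.5, 0.9)) {
  params <- with_seed(seed, {
    list(overlap = stats::runif(n, overlap_range[1], overlap_range[2]),
         texture = stats::runif(n, texture_range[1], texture_range[2]),
         strong = stats::runif(n) < strong_frac,
         blur = stats::runif(n) < blur_frac,
         seeds = sample.int(2^30, 2 * n))
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    src <- generate_texture_image(params$seeds[i], size,
                                  texture_level = params$texture[i],
                                  brightness_class = if (params$strong[i]) "strong" else "normal",
                                  blur_px = if (params$blur[i]) 2 else 0)
    # a drawn corner perturbation can make large overlaps unreachable; back
    # off the requested rate deterministically until the sample is feasible
    ov <- params$overlap[i]
    q <- NULL
    while (is.null(q)) {
      q <- tryCatch(make_stitch_quadruple(src, patch, ov, max_corner_shift,
                                          params$seeds[n + i]),
                    error = function(e) {
                      if (!grepl("not reachable", conditionMessage(e))) stop(e)
                      NULL
                    })
      if (is.null(q)) ov <- ov - 0.05
    }
    out[[i]] <- q
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    nm <- sprintf("sample_%04d", seq_len(n))
    for (i in seq_len(n)) write_quadruple(out[[i]], file.path(dir, nm[i]))
    writeLines(nm, file.path(dir, "index.txt"))
    attr(out, "dir") <- dir
  }
  out
}

#' Read a dataset directory written by [generate_dataset()]
#' @param dir dataset directory containing `index.txt`.
#' @return list of `"quadruple"` objects.
#' @export
read_dataset <- function(dir) {
  nm <- readLines(file.path(dir, "index.txt"))
  lapply(nm, function(s) read_quadruple(file.path(dir, s)))
}
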