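---
title: "Unsupervised endoscopic image stitching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised endoscopic image stitching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Gastroenteroscopy delivers a narrow, distorted, low-texture view of a large
organ. Stitching overlapping frames into a panorama widens the effective
field of view and lowers the chance of missed lesions, but the classical
feature-matching pipeline (SIFT-like keypoints, RANSAC, blending) fails
exactly where endoscopy needs it: smooth mucosa offers few distinctive
keypoints, illumination varies strongly, and the lens introduces marked
radial distortion. `endostitch` implements an alternative pipeline in which
every learned component is trained **without ground-truth alignment labels**:

1. **Radial distortion correction** by a Hough-transform line-straightness
   search over a single-parameter division model.
2. **Coarse alignment** by a multi-scale correlation network that regresses a
   four-point homography, trained with an ablation-masked photometric loss.
3. **Stitching-domain warping** onto the minimal bounding canvas.
4. **Feature-to-pixel reconstruction** by a two-branch network (with a C2f
   feature-mixing block) that suppresses the ghosting a single homography
   cannot explain.

Because clinical recordings cannot be redistributed, the package also ships a
synthetic scene generator that emulates the relevant statistics of
endoscopic frames; every claim the test suite makes is made on that
generator's output.

## Synthetic scenes and stitching quadruples

`generate_texture_image()` emulates mucosa-like frames: a pinkish base
color, a bilinear illumination ramp between four random corner gains, and
three octaves of band-limited value noise whose amplitude is the
`texture_level`. Two strata mirror what an endoscopy archive contains:
strong-light frames are affinely rescaled until the mean intensity exceeds
200 (the usual strong-light cutoff on 8-bit frames), and motion-blurred
frames are convolved with a linear kernel longer than one pixel. What the
generator deliberately does **not** emulate: specular highlights, fluid,
peristaltic non-rigidity, vignetting, and sensor noise correlations. Tests
passing on these scenes therefore demonstrate the correctness of the
machinery and the trainability of the objectives, not clinical performance.

`make_stitch_quadruple()` builds one training record `(I_A, I_B,
gt_offsets, label)` by the standard synthetic-warp recipe: `I_A` is an
axis-aligned crop; the target window is displaced laterally and its four
corners perturbed independently (uniform per axis, bounded by
`max_corner_shift`); `I_B` is the backward-warped crop of that perturbed
quadrilateral. The displacement is solved by bisection so that the
**measured** pixel overlap between the A window and the target quadrilateral
matches the requested rate (the corner perturbation would otherwise bias it);
samples are classified high/low overlap at the 60% boundary. The exact
corner motions are stored as ground truth, and `label` is the source crop
over the union region, computed with the same minimal-canvas rule used at
inference, so label and canvas geometry agree by construction. The original
description of such quadruples leaves the third element's encoding
unspecified; this package stores the four exact corner offsets, which
determine the homography uniquely.

## Division-model distortion and its estimation

A distorted pixel at radius $r_d$ from the image center observes the scene
point at undistorted radius

$$ r_u = \frac{r_d}{1 + k\, r_d^2}, $$

the one-parameter division model; endoscope distortion is dominantly radial
and published calibrations report a single coefficient, so no decentering or
higher-order terms are modeled, and the center is fixed at the image center.
`undistort()` inverts the model in closed form
($r_d = (1 - \sqrt{1 - 4 k r_u^2}) / (2 k r_u)$) with bilinear backward
sampling; monotonicity ($k\,r_d^2 < 1$ over the frame) is checked.

`estimate_k()` scans candidates $k_i = k_{\min} + i\,(k_{\max} -
k_{\min})/n$ and keeps the straightness-score maximizer; the interval is
then re-centered on the best candidate, shrunk by $1/n$, and rescanned for a
configurable number of rounds (default 15, matching published calibration
settings of start coefficient $10^{-9}$, first-round increment $5\times
10^{-8}$ over 20 steps; refinement stops early when the grid step falls
below `k_tol` since candidates closer than $10^{-11}$ px$^{-2}$ produce
numerically identical undistortions). Refinement has a noise floor: below
roughly $10^{-9}$ px$^{-2}$ a candidate's effect on the frame is a
sub-pixel resampling perturbation whose influence on the score exceeds the
straightness signal, so the package's own recovery checks run two
refinement rounds (grid resolution $2.5\times10^{-9}$), which reach that
floor.

The score itself works on the principle that correcting with the right $k$
makes scene lines straight, which concentrates Hough votes. Per scale in
$\{1, 1/2, 1/4\}$ the undistorted frame is edge-detected (Canny: luma,
Gaussian pre-smoothing, Sobel, non-maximum suppression, hysteresis),
restricted to the quasi-axial angle bands $[-\tau_\theta, \tau_\theta] \cup
[\pi/2 - \tau_\theta, \pi/2 + \tau_\theta]$ ($\tau_\theta = 10^\circ$), and
voted into a $(\rho, \theta)$ accumulator; accumulators are smoothed and
multiplied elementwise across scales. Several numerical choices here were
driven by failure analysis during development and differ from the most naive
reading of the procedure:

* **Valid-region restriction.** Undistortion leaves an unmapped black rim;
  its content boundary runs parallel to the frame and is straight for
  *every* candidate $k$, so it would dominate the score. Edges are
  restricted to the valid-sample region eroded by the edge detector's
  support.
* **Vote normalization.** Undistortion with larger $k$ minifies content and
  shortens lines in pixels; accumulators are normalized by their vote count
  so the score measures *concentration*, not raw line length.
* **Sub-bin voting.** Each edge pixel's vote is split linearly between the
  two nearest $\rho$ bins (still one vote per pixel and $\theta$ bin),
  suppressing the quantization alias that otherwise produces a spurious dip
  at exactly the true coefficient.
* **Top-peak sum.** The score sums the `n_peaks` (default 20) largest
  $\rho$-local maxima of the product space rather than taking the single
  maximum: a single peak is dominated by per-line resampling noise, while
  the sum averages it over many lines. (Whether to use the maximum or a sum
  over peaks was genuinely open; the maximum was tried first and proved
  noise-dominated at desk scale.)
* **Scale-proportional pre-smoothing.** The downsampled pyramid levels are
  already antialiased, so the Canny pre-smoothing shrinks with the scale —
  otherwise thin lines lose their gradients entirely at quarter scale.
* Bin geometry defaults: 725 $\rho$ bins (about 1 px at $512^2$), $\theta$
  resolution $0.5^\circ$, accumulator smoothing $\sigma = 1$ bin.

The test fixture (`generate_line_grid()`) renders antialiased lines
analytically from their distance fields, tilted by a small angle so no line
is exactly pixel-aligned, and keeps lines away from the distortion center
(`center_gap`), where radial distortion cannot bend them and no calibration
signal exists. `line_curvature()` — mean over 8-connected edge chains of the
maximum deviation from the chord through the chain's extreme points — is the
independent straightness diagnostic; it is measured on crossing-free
(single-orientation) fixtures because chains merge at line crossings.

## Unsupervised homography estimation

The motion between frames is parameterized by the displacements
$(\Delta x_k, \Delta y_k)$ of the four target-image corners; the
corresponding $3\times3$ projective matrix is recovered by a direct linear
solve (8 equations, 8 unknowns) that interpolates the corners exactly.

The network is a shared-weight convolutional pyramid (defaults: 3 levels,
channels 32/64/96, two 3×3 convolutions and a max-pool per level). From the
coarsest level down, a local correlation volume (radius 4/4/2 level-pixels)
between the reference features and the target features — pre-aligned by the
running estimate — feeds a small convolutional head ending in a
zero-initialized fully connected layer that predicts a *residual* corner
offset, added to the upscaled running estimate. Zero initialization makes
the untrained network predict exactly zero motion, and the final estimate is
bounded by a smooth clamp $m \tanh(x/m)$ (`max_offset`). The pre-alignment
warp treats the running estimate as a constant (no gradient through the
feature warp); gradients reach the coarse levels through their own
photometric losses instead, which is the standard arrangement in
coarse-to-fine motion networks and keeps the graph well-conditioned.

Training minimizes the ablation-masked photometric objective

$$ L = \lVert \mathcal{W}(E, H) \odot I_A - \mathcal{W}(I_B, H)
\rVert_1, $$

where $\mathcal{W}$ warps into the reference frame and $E$ is the all-ones
image, so the warped validity mask ablates reference pixels the target
cannot cover. Numerical choices: the mask is thresholded at 0.999 (binary
ablation, as the strategy is described), the loss is divided by the valid
pixel count (with a floor of one) so that pushing the target out of frame is
not rewarded at intermediate mask values, the mask and its count are held
constant within each gradient step (the threshold's subgradient is zero
almost everywhere), and the loss is evaluated at every pyramid level on
area-downsampled images with equal weights. The gradient of the warp with
respect to the homography entries is analytic through the bilinear sampler;
the Jacobian of the corner-to-matrix linear solve is taken by central finite
differences (a smooth rational map; step $10^{-4}$ px).

Optimization is Adam at learning rate $10^{-4}$ with the published schedule
of 150 pretraining epochs on a synthetic-warp corpus and 50 fine-tuning
epochs (`train_homography()`); the pretraining corpus is built from the
package's own texture generator by the same quadruple recipe, since the
natural-image corpus used originally is immaterial to the mechanism.

## Stitching-domain transformer

Warped target corners are the corner-plus-offset sums; the canvas spans from
the floor of the smallest to the ceiling of the largest coordinate over the
eight reference/warped corners (never cropping content), with the
translation mapping reference coordinates into the canvas. Both images and
two all-ones masks are backward-warped bilinearly (zero fill) into the
canvas; the coordinate convention everywhere is 0-based pixel centers, x
rightward, y downward. Content masks are exactly 1 in warped interiors and
fall to 0 across a sub-pixel antialiased border.

## Two-branch reconstruction

Seam masks follow the mask-gradient construction: the boundary gradient of
one image's content mask ($|M_{i,j}-M_{i-1,j}| + |M_{i,j}-M_{i,j-1}|$,
zero-padded border, so the canvas border itself counts as a boundary) is
dilated by three all-ones 3×3 convolutions, clipped to $[0,1]$, and
multiplied by the *other* image's content mask — a band of width ~7 px where
one image's edge crosses the other's content.

The **low-resolution branch** downsamples both warped images to a fixed
working resolution (256×256 at full scale), concatenates them, and runs an
encoder–decoder with exactly the published filter plan 64, 64, 128, 128,
256, 256, 512, 512, 256, 256, 128, 128, 64, 64, 3 (three max-pools, three
channel-preserving 2×2 transposed convolutions, skip concatenations at equal
resolutions, sigmoid output). The **high-resolution branch** upsamples the
low-res stitch to canvas size, concatenates it with both warped images
(9 channels), and refines through three convolutions, eight residual blocks
and one C2f block, placed after the residual stack (its position is not
pinned down by the originating description; one block after the stack is the
minimal choice and easy to ablate). The C2f block applies a 1×1 convolution,
splits channels in half, threads one half through $n = 2$ residual
bottlenecks retaining every intermediate, concatenates all $2 + n$ tensors
and fuses them back with a 1×1 convolution. Both output convolutions are
zero-initialized so each branch starts from mid-grey (sigmoid-centered).

The objective combines, per branch, a perceptual content term (branch output
masked by each content mask against the corresponding warped image — the
mask is applied to the branch output only, reading the loss exactly as
written) and an L1 seam term on the seam bands, plus an L1 consistency term
between the downsampled high-res output and the low-res output:

$$ L = \omega_{LR} (\lambda_c L^l_{content} + \lambda_s L^l_{seam})
     + \omega_{HR} (\lambda_c L^h_{content} + \lambda_s L^h_{seam})
     + \omega_{CS} \lVert S_{HR}{\downarrow} - S_{LR} \rVert_1 $$

with defaults $\lambda_c = 10^{-6}$, $\lambda_s = 2$, $\omega = (100, 1,
1)$. A coefficient of $10^{-6}$ only balances the objective if the
perceptual distance is an **unnormalized sum** over feature elements (the
scale of summed deep-feature maps); the package therefore defines $L_P$ as
the sum of absolute feature differences, while the L1 seam and consistency
terms are means. The note accompanying the published coefficients reverses
the roles of the two symbols relative to the equation they annotate; this
package follows the equation.

The perceptual features come from a frozen random-weight convolutional
pyramid (three conv/ReLU/pool stages; features compared at 1/4 and 1/8
resolution) with a fixed seed. No pretrained classifier is required or
downloaded; a fixed random projection preserves the loss's structure —
multi-scale, receptive-field-weighted photometric agreement — and keeps
every result reproducible offline. Reconstruction training
(`train_reconstruction()`) freezes the homography weights, precomputes each
sample's canvas, masks and constant-side features once, and runs Adam
(20 epochs, $10^{-4}$ by default).

## Evaluation battery

`pair_metrics()` reports MSE, RMSE, PSNR (8-bit peak; identical images give
an infinite PSNR sentinel that batch means exclude) and single-scale SSIM
(11×11 Gaussian window, $\sigma = 1.5$, $K = (0.01, 0.03)$, channel
average) under `resize` or centered-`crop` normalization. The
sliding-window RMSE has no standard definition, so the package fixes one and
labels it a convention: the mean over 32×32 windows at stride 16 of the
per-window RMSE, using only windows with at least half their pixels valid.
`batch_report()` excludes failed stitches from the means and reports their
count separately.

## Problem sizes and degenerate inputs

The package's own test and demonstration runs use desk-scale sizes, chosen
once: homography-recovery checks use 48×48 patches with corner shifts up to
10 px and a reduced-width configuration (2 levels, 8/16 channels); the
end-to-end demonstration (`demo_end_to_end()`) uses 64 training and 16 test
quadruples of 128×128 patches, the 2/1/2-epoch schedule, learning rate
$10^{-3}$, and reduced widths (homography 8/16; reconstruction base 8,
high-res width 6, 64×64 low-res working resolution). The full-width
architectures are instantiated and verified structurally (parameter counts,
shapes, gradient flow) rather than trained. Degenerate inputs are defined
behaviors: featureless frames return $k = 0$ with a warning from
`estimate_k()`; zero-texture quadruples produce a constant photometric loss
(no gradient); out-of-frame homographies ablate everything and score zero
loss; stitching failures surface with their stage name and are counted, not
averaged, by the evaluator.

## Known limitations

A single homography cannot explain parallax; the reconstruction stage
suppresses the resulting ghosting but cannot re-align large depth
discontinuities (mesh or multi-homography warps are out of scope). The
distortion model omits decentering and assumes the distortion center at the
image center. The synthetic generator's realism limits are listed above; in
particular, success of the demonstration pipeline on synthetic mucosa does
not certify clinical image quality.
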