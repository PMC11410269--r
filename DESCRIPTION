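Package: endostitch
Title: Unsupervised Endoscopic Image Stitching with Radial Distortion
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An unsupervised panorama-stitching toolkit for gastrointestinal
    endoscopy frames. Provides Hough-transform based estimation and correction
    of single-parameter (division model) radial lens distortion, a multi-scale
    correlation network that regresses a four-point homography trained with an
    ablation-masked photometric objective, a stitching-domain transformer that
    warps both views onto the minimal bounding canvas, and a two-branch
    feature-to-pixel reconstruction network (with a split/concat C2f feature
    mixing block) trained with content, seam and scale-consistency losses.
    Includes a synthetic quadruple generator that emulates endoscopy-like
    scenes so the whole framework can be trained and evaluated without
    clinical data, plus an evaluation battery (MSE, RMSE, PSNR, SSIM,
    sliding-window RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
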