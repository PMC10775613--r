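# corneaseg

Unsupervised corneal contour extraction from dynamic corneal deformation
videos.

Air-puff tonometry (ultra-high-speed Scheimpflug recording, e.g. Corvis ST)
captures the cornea flattening and rebounding as a short video — natively
139 frames of 576 x 150 pixels — in which the cornea appears as a bright
crescent-shaped band on a dark, noisy background. Corneal biomechanical
indices are computed from the corneal contour in every frame, but manual
annotation is impractical and classical thresholding/edge detection breaks
down on noisy frames. `corneaseg` is for researchers who need per-frame
corneal contours without any labelled training data.

## Method

Each frame is processed by an unsupervised segmentation pipeline:

1. **SLIC superpixels** pre-group pixels with the combined metric
   D' = sqrt((d_c/m)^2 + (d_s/S)^2), with d_c the CIELAB colour distance,
   d_s the pixel distance, m = 10 and S = sqrt(N/K).
2. A **six-layer stride-1 fully convolutional network** (128/64/32/16/8/4
   maps, BatchNorm everywhere, ReLU on the odd layers, softmax output)
   is trained on the frame itself by alternating per-pixel argmax
   labelling, superpixel majority refinement, and SGD on the loss

   L = L_ce + alpha * L_fs,   L_fs = |Fs - C|,   Fs = L^2 / (4 pi S),

   i.e. cross-entropy against the refined labels plus a shape-factor prior
   (alpha = 0.1, C = 10) expressing that the cornea is an elongated band.
   Training stops when L < 0.1.
3. The corneal region is the connected component whose shape factor is
   closest to C (background suppressed), and its closed boundary is traced
   with the Moore neighbourhood.
4. The **shared model**: every frame after the first starts from the
   previous frame's trained parameters, which cuts training to a few
   epochs per frame and makes the extraction robust to per-frame noise.

Accuracy is measured as the overlap error E = 1 - IoU between extracted
and true corneal masks.

Because no public corneal deformation videos exist, the package ships a
synthetic generator (`synthetic_config()`, `generate_video()`) producing
deformation-like videos — a bright parabolic band whose apex dips and
recovers, Gaussian noise, bright blob artifacts — with exact per-frame
ground-truth masks and contours.

## Worked example

```r
library(corneaseg)

cfg <- synthetic_config(n_frames = 5, noise_sigma = 0.05,
                        n_blob_artifacts = 5, seed = 1)
gv  <- generate_video(cfg)

res <- process_video(gv$video, cfg = train_config(seed = 1001),
                     truth = gv$truth)
res$frames[, c("frame", "loss", "epochs_used", "epochs_to_threshold", "E")]
res
```

```
  frame       loss epochs_used epochs_to_threshold           E
1     1 0.09084584          15                  15 0.015829694
2     2 0.09981311          12                  12 0.009782439
3     3 0.09447098           1                   1 0.010322984
4     4 0.06878899           1                   1 0.012035011
5     5 0.06981788           1                   1 0.011437524
<video_result> 5 frames, 0 failed, shared model
  mean E = 0.0119 (sd 0.0024), mean IoU = 0.9881
```

Reading the output: the first (cold-started) frame needed 15 training
epochs to bring the loss below the 0.1 stopping threshold; once the shared
model kicks in, frames converge in one or a few epochs. Every frame's
overlap error E is about 0.01-0.016, i.e. the extracted corneal mask
overlaps the true mask to an IoU of roughly 0.99. `res$contours[[t]]`
holds the ordered (row, col) boundary pixels of frame `t`, and
`plot_contour_overlay(gv$video, res, 3)` displays a contour over its
frame. `run_baselines(gv$video, gv$truth)` scores classical Otsu /
Roberts / Sobel extraction on the same video for comparison.

A thin command-line front end is installed with the package
(`inst/cli/corneaseg`) with `simulate`, `extract`, `evaluate` and
`benchmark` subcommands.

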