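# uwvdetect

Underwater video object detection in R: contrast enhancement, a
coordinate-attention anchor-free detector, a video-aware composite loss,
and frame-level tubelet optimization, with Pascal VOC I/O, mAP@0.5
evaluation, and seeded synthetic fixtures so everything is testable
without external data.

## The problem

Underwater footage is blurry and low-contrast, and frame-by-frame
detectors produce temporally unstable results: the boxes for one physical
object jitter between adjacent frames and its confidence can dip suddenly.
`uwvdetect` is for researchers analysing benthic survey video (five
classes: *echinus*, *holothurian*, *starfish*, *fish*, *jellyfish*) who
want a detection pipeline that treats the video as a video rather than as
independent images.

## What it implements

- **CLAHE enhancement** (`enhance_video`) — per-RGB-channel contrast
  limited adaptive histogram equalization: per-tile histograms clipped at
  `clip_limit` times the uniform bin height, excess redistributed, levels
  remapped through `T(g) = round((cdf(g) − cdf_min)/(1 − cdf_min)·255)`,
  pixels reconstructed by bilinear interpolation between tile mappings.
- **Detector** (`build_detector`, `detect_frames`) — CSPDarknet backbone +
  PAFPN neck + decoupled head at strides 8/16/32, anchor-free decode
  `c = (grid + offset)·s`, `w,h = eᵗ·s`, per-class NMS at 0.5, test size
  576. With `use_ca = TRUE` the backbone's CSP blocks become CSP_CA1
  (residual units kept, coordinate-attention gate inserted after the trunk
  1×1 conv) and CSP_CA2 (units replaced by the gate). Coordinate attention
  pools rows and columns separately and multiplies the feature map by
  direction-aware sigmoid gates. `count_parameters()` counts trainable
  scalars exactly: 99.00 M baseline, 82.66 M with coordinate attention
  (5 classes, X scale).
- **Composite loss** (`total_loss` and friends) —
  `L = λcls·Lcls + λreg·Lreg + λconf·Lconf + λjitter·Ljitter` with BCE
  classification/confidence terms, regression
  `Lreg = 1 − CIOUlog` where
  `CIOUlog = IOUlog − ρ²/c² − αv` is computed on logarithms of
  λ-padded box areas (`iou_log`, `ciou_log`), and a jitter term
  (`jitter_loss`): the mean absolute difference between predicted and
  ground-truth box *accelerations* (second differences of coordinates over
  consecutive frames), weighted `λjitter = 0.05`.
- **Frame-level optimization** (`optimize_detections`) — adjacent-frame,
  same-class detections paired by
  `X(iou, dcenter, ratio_w, ratio_h)·scoreA·scoreB` (logistic `X`), greedy
  matrix matching, chained into frame-contiguous tubelets, then re-scored
  (tubelet-mean confidence) and re-coordinated (renormalized truncated
  Gaussian smoothing of the four coordinate time series, σ = 1 frame).
- **Evaluation** (`evaluate_detections`) — VOC-style: greedy one-to-one
  matching at IOU ≥ 0.5, monotone precision envelope, AP as the exact area
  under the step curve, mAP as the mean over defined classes.
- **Synthetic fixtures** (`generate_scene`, `corrupt_detections`) — seeded
  low-contrast, blurred clips with moving objects and exact tracks, plus
  detector-like corruption (coordinate jitter, confidence dips, misses,
  false positives).
- **Smoke training** (`smoke_train`) — SGD (momentum 0.9, lr 0.005) on the
  composite loss with a simplified center-radius assigner, for verifying
  the training graph at desk scale. The network forward/backward passes run
  on a small reverse-mode autodiff engine included in the package; no deep
  learning framework is required.

## Worked example

```r
library(uwvdetect)

# a 20-frame synthetic underwater clip with 3 tracked objects
scene <- generate_scene(scene_config(width = 128, height = 128,
                                     n_frames = 20, n_objects = 3), seed = 42)
scene$clip
#> <video_clip: 20 frames, 128x128 px, fps=NA>

# contrast enhancement widens the compressed intensity range
range(scene$clip$frames[[1]])
#> [1]  87 176
enhanced <- enhance_video(scene$clip, clahe_params(tile_grid = c(8, 8),
                                                   clip_limit = 2))
range(enhanced$frames[[1]])
#> [1]  71 192

# detector-like noisy detections (3 px jitter, confidence dips)
noisy <- corrupt_detections(scene$annotations,
                            noise_config(box_sigma = 3, p_dip = 0.2),
                            image_size = c(128, 128), seed = 43)
nrow(noisy)
#> [1] 60

# frame-level optimization: tubelet linking + re-scoring + re-coordinating
opt <- optimize_detections(noisy, image_size = c(128, 128))
evaluate_detections(noisy, scene$annotations)$map
#> [1] 0.9733333
evaluate_detections(opt, scene$annotations)$map
#> [1] 1

# model sizes
count_parameters(build_detector(detector_config(use_ca = FALSE))) / 1e6
#> [1] 98.99923
count_parameters(build_detector(detector_config(use_ca = TRUE))) / 1e6
#> [1] 82.66129
```

The enhancement expands the degraded clip's intensity range; the
optimizer lifts mAP@0.5 on this fixture from 0.973 to 1.0 by smoothing
jittered boxes back over the matching threshold and filling in dipped
confidences; and the two parameter counts are the exact model sizes of the
baseline and coordinate-attention configurations.

## Command line

A thin CLI over the same functions ships at `inst/cli/uwv.R`:

```sh
Rscript inst/cli/uwv.R synth    --out fixtures --seed 7 --frames 20 --size 128x128
Rscript inst/cli/uwv.R enhance  --in fixtures/frames --out enhanced --tiles 8x8 --clip 2.0
Rscript inst/cli/uwv.R detect   --in enhanced --out det.jsonl --size 576 --nms 0.5
Rscript inst/cli/uwv.R optimize --in det.jsonl --out det_opt.jsonl --sigma 1.0 --tau 0.3 --image-size 128x128
Rscript inst/cli/uwv.R eval     --det det_opt.jsonl --gt fixtures/annotations --iou 0.5
Rscript inst/cli/uwv.R params   --ca
```

Detections are interchanged as JSON lines, one object per line with keys
`frame` (0-based), `class_id` (0-based), `score`, `x1`, `y1`, `x2`, `y2`
(0-based half-open pixel corners). Pascal VOC XML (1-based inclusive
boxes, optional ImageNet-VID-style `<trackid>`) is converted at the
reader/writer boundary only.

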