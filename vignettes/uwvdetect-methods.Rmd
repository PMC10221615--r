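---
title: "Underwater video object detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Underwater video object detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uwvdetect)
```

## The problem

Underwater footage is blurry and low-contrast: light absorption compresses
the intensity range and scatter smears object boundaries, so benthic
animals (sea urchins, sea cucumbers, starfish, fish, jellyfish) are easy to
miss or misclassify, and frame-by-frame detectors produce temporally
unstable output — box coordinates jitter between adjacent frames and the
confidence for one physical object can drop suddenly in single frames.
`uwvdetect` implements a detection pipeline that attacks both problems:

1. **Contrast enhancement** — per-channel CLAHE on every frame;
2. **A coordinate-attention detector** — an anchor-free one-stage detector
   whose backbone CSP blocks carry coordinate-attention gates;
3. **A video-aware training loss** — log-area CIoU box regression plus an
   inter-frame jitter (acceleration) penalty;
4. **Frame-level post-processing** — detections linked into tubelets
   across adjacent frames, then re-scored and re-coordinated.

Every stage is testable without external data through the seeded synthetic
scene generator.

## Contrast enhancement (CLAHE)

Plain histogram equalization remaps gray level $g$ through the normalized
cumulative histogram $f_x(g)$.  We use the standard remap

$$T(g) = \mathrm{round}\!\left(\frac{f_x(g) - f_{\min}}{1 - f_{\min}}\,(L-1)\right),$$

with $f_{\min}$ the smallest nonzero cumulative value and $L = 256$.
Presentations of the final rescaling step vary and are sometimes
ambiguous; this remap is the textbook transformation that the
cumulative-histogram construction describes, and it maps the darkest
occupied level to 0 and the brightest to 255.  A single-level tile is left
unchanged — equalizing it is undefined, and this keeps constant images
fixed points of the whole pipeline.

CLAHE computes this mapping per image tile on a *clipped* histogram: counts
above `clip_limit` times the uniform bin height are cut and the excess is
spread evenly over all bins, which bounds the slope of the mapping and
stops noise amplification in flat regions.  Because spreading can push bins
back over the ceiling, the clip-and-spread pass iterates
(`redistribute_iters`, default 5); the residual excess after the last pass
is spread and accepted, so histogram mass is conserved exactly.  Each
output pixel interpolates bilinearly between the four nearest tile-center
mappings (constant extrapolation outside the outer centers), the canonical
reconstruction that avoids tile seams.

Tunables: `tile_grid` (default 8×8 tiles) and `clip_limit` (default 2.0,
relative to the uniform bin height).  These are the common CLAHE defaults
and both are exposed.  Color frames are enhanced independently per R, G, B
channel — deliberately so; no LAB/HSV variant is provided.

## The detector

The detector is the familiar anchor-free one-stage layout: a CSPDarknet
backbone (space-to-depth stem, four downsampling stages, spatial-pyramid
pooling), a PAFPN neck, and a decoupled classification/regression/
objectness head at strides 8, 16 and 32.  Boxes decode as
$c = (\mathrm{grid} + \mathrm{offset})\cdot s$ and
$w,h = e^{t}\cdot s$; inference letterboxes each frame (padding value
114), thresholds $\mathrm{obj}\times\mathrm{cls}$ scores and applies
per-class NMS (default threshold 0.5, test size 576).

**Model scale.** The default multipliers are depth 1.33 / width 1.25 — the
X scale.  This is inferred, not copied: at 5 classes it is the only
standard scale whose trainable-parameter count matches the published
99.00 M baseline, which `count_parameters()` reproduces exactly
(98,999,230 parameters).

**Coordinate attention.** The CA module pools a $C\times H\times W$ map
along rows and along columns separately, concatenates the two directional
descriptors, passes them through a shared 1×1 convolution (to
$\max(\texttt{mid\_min}, C/r)$ channels, batch norm, hard-swish), splits
them back, and maps each to $C$ channels with a 1×1 convolution and a
sigmoid.  The two gates multiply the input elementwise, so each output
position is modulated by row- and column-specific attention — positional
information that plain channel attention discards, and which helps locate
blurry objects.

**CSP_CA placement.** Two CA-augmented CSP variants exist: CSP_CA1 keeps
the residual units and inserts a CA module between the trunk's 1×1
convolution and the units; CSP_CA2 removes the units entirely and replaces
them with one CA module.  Which network stages to convert is a genuinely
open choice, so the published parameter count of the CA variant (82.66 M)
adjudicates:
converting the three residual-type backbone stages to CSP_CA1 and the last
(non-residual) backbone stage to CSP_CA2, with $r = 32$ and
$\texttt{mid\_min} = 8$, yields 82,661,288 parameters = 82.66 M exactly.
Extending the conversion into the neck removes a further ~22 M parameters
and is inconsistent with that count, which also agrees with the variant's
published backbone name (a CA-augmented CSPDarknet, neck unchanged).  The
placement is exposed as `ca_placement` should a user want the wider
variant.

**No tensor framework.**  No deep-learning runtime is part of this
package's dependency set; the forward and backward passes are implemented
in `R/autodiff.R` as a small reverse-mode tape over numeric arrays
(im2col convolutions, train-mode batch normalization, SiLU/hard-swish/
sigmoid, stride-1 max pooling, nearest upsampling, the CA pooling/gating
ops).  Every operation is verified against central finite differences in
the test suite, including end-to-end through the assembled detector.
Parameter counting walks the architecture description without
materializing weights, so full-scale (~10^8 parameter) models are counted
in milliseconds while only desk-scale configurations are actually run.

## The composite loss

$$\mathcal{L} = \lambda_{cls} L_{cls} + \lambda_{reg} L_{reg} +
\lambda_{conf} L_{conf} + \lambda_{jitter} L_{jitter}$$

Classification and confidence use binary cross-entropy (probabilities
clamped at $10^{-7}$).  The jitter weight defaults to
$\lambda_{jitter} = 0.05$, which compensates for the jitter term's raw
magnitude being much larger than the other terms;
$\lambda_{cls} = \lambda_{conf} = 1, \lambda_{reg} = 5$ follow the
baseline detector convention.

**Log-area IOU.** Underwater object sizes span a wide range, which makes
plain IOU volatile.  The overlap term is therefore computed on logarithms
of $\lambda$-padded side products:

$$\mathrm{IOU}_{\log} = \frac{\log\,(w_i+\lambda)(h_i+\lambda)}
{\log\,(w_1+\lambda)(h_1+\lambda) + \log\,(w_2+\lambda)(h_2+\lambda) -
\log\,(w_i+\lambda)(h_i+\lambda)}$$

With $\lambda = 1$, disjoint boxes give numerator $\log 1 = 0$, identical
boxes give 1, and the value is invariant to the logarithm base (a ratio of
logs; tested to $10^{-12}$).  The complete form adds a center-distance
penalty $\rho^2/c^2$ ($\rho$ the center distance, $c$ the enclosing-box
diagonal) and a shape term $\alpha v$ with
$v = \tfrac{4}{\pi^2}(\arctan\frac{w_1}{h_1} - \arctan\frac{w_2}{h_2})^2$
and $\alpha = v/(1 - \mathrm{IOU}_{\log} + v)$.  The shape term enters
with sign $-1$ by default: a $+\alpha v$ term would *reward* aspect-ratio
mismatch and make the loss $1-\mathrm{CIOU}_{\log}$ non-monotone in shape
agreement, contrary to the CIoU family it extends; the sign is exposed as
`shape_sign` for comparisons with the positive-sign form.  Degenerate geometry is guarded: a vanishing denominator
returns 1 for identical boxes and 0 otherwise, coincident point-boxes drop
the $\rho^2/c^2$ term, and $0/0$ aspect ratios are stabilized with a
$10^{-12}$ additive guard that perturbs non-degenerate values below
testing tolerance.

**Jitter loss.** Box coordinates of one object over $T$ consecutive
frames form four time series $Y$; velocity $V_i = Y_i - Y_{i-1}$ and
acceleration $A_i = V_i - V_{i-1}$ are first and second differences.  The
loss is the mean absolute difference between predicted and ground-truth
accelerations, averaged over the four coordinates, summed over the $T-2$
defined acceleration indices, divided by $T-2$, and averaged over objects.
Second differences annihilate linear motion, so a prediction offset by a
constant velocity from the truth incurs no penalty — the term punishes
only *irregularity*.  Objects missing from a frame contribute only their
complete triplets, with the $T-2$ divisor unchanged; sequences shorter
than 3 frames contribute 0.  The mean (rather than sum) over the four
coordinates keeps $\lambda_{jitter} = 0.05$ scale-compatible regardless of
box parameterization.  Coordinates are corner-format, matching how box
coordinates are stored throughout.

**Assignment (a stand-in).** Full-scale training machinery
(optimal-transport assignment, mosaic/mixup augmentation, EMA) is not a
contribution of this method and is out of scope.  `smoke_train()` uses a
simplified center-radius assigner — an anchor is positive for a box when
its cell center falls inside the box and within 2.5 strides of the box
center, ties to the nearest center — with plain SGD (momentum 0.9,
learning rate 0.005, weight decay 5e-4, the published settings).  Its
purpose is verifying that the composite loss trains the full graph, not
producing usable weights.  Per track and frame, the positive prediction
with the highest objectness feeds the jitter term.

## Frame-level optimization

Adjacent-frame detections of the same class are paired by the similarity

$$\mathrm{score} = X(\mathrm{IOU}, d_{center}, \mathrm{ratio}_w,
\mathrm{ratio}_h)\times \mathrm{score}_A \times \mathrm{score}_B,$$

where $X$ is a logistic function of the overlap, the center distance
normalized by the image diagonal, and the absolute log side-ratios.
There is no canonical choice for $X$'s weights; the default
$X = \sigma(4\,\mathrm{iou} - 8\,d - 2|\log r_w| - 2|\log r_h| + 1)$ is
hand-set so that perfectly aligned pairs score near the ceiling and
far-apart pairs fall below any sensible link threshold, and the weights
are configurable.  Matching is class-restricted: re-scoring averages class
confidences within a tubelet, which presumes one class per tubelet.

Pairs are selected greedily from the score matrix — repeatedly take the
global maximum at or above $\tau_{link}$ (default 0.3) and zero its row
and column; ties break toward the lowest (row, col) index.  This is the
specified procedure, *not* an optimal assignment, and the tests include a
matrix where the two differ.  A matched pair extends the tubelet ending at
the earlier detection or starts a new one; unmatched detections become
singletons.  Tubelets are therefore a partition: frame-contiguous (no gap
bridging, by design) and class-pure.

Each tubelet is then **re-scored** — every member receives the tubelet's
mean confidence, so isolated confidence dips are filled in by neighboring
frames — and **re-coordinated**: each of the four coordinate series is
convolved with a truncated Gaussian ($\sigma = 1$ frame, radius
$\lceil 3\sigma\rceil$) whose window is intersected with the tubelet
extent and renormalized to sum to one.  Without the renormalization,
boundary coordinates would shrink toward zero, contradicting the smoothing
intent; with it, constant series and singleton tubelets are exact no-ops.

## VOC-style evaluation

A detection is a true positive when it matches, one-to-one and greedily by
descending score, an unmatched same-class ground-truth box at
IOU ≥ 0.5.  Per class, precision is made monotone from the high-recall
side and AP is the exact area under the step curve — the integral form of
the definition; the classic 11-point interpolation is available for
comparison (`interpolation = "11point"`).
Classes with neither ground truth nor detections have undefined AP and are
excluded from the mean; a class with detections but no ground truth scores
0.  mAP is the arithmetic mean over defined classes.

## The synthetic scene generator

`generate_scene()` emulates exactly the properties the pipeline targets:
a noisy mid-gray background, a few filled ellipses/rectangles with
class-keyed colors moving on linear or sinusoidal trajectories (reflecting
at frame edges so objects stay in view), then *contrast compression*
(intensities pulled toward mid-gray by a factor `gamma`, default 0.45, so
the range is about `gamma`·255) and Gaussian blur (`blur_sigma`, default
1 px).  Ground-truth boxes are tight to the rendered shapes before
degradation, and track identities are exact.  `corrupt_detections()`
emulates a detector's failure modes on top: i.i.d. corner jitter
(`box_sigma`), score noise with occasional dips (`p_dip`, `dip_depth`),
misses (`p_miss`) and Poisson false positives (`fp_rate`) whose areas are
drawn from the ground-truth size range so they occasionally confuse the
linker.  Everything is deterministic under a fixed seed.

What the generator does **not** model: wavelength-dependent color
attenuation, refraction and caustics, occlusion between objects,
deformable animals, camera motion.  Passing tests therefore demonstrate
the algorithmic properties of the stages (mass conservation, contraction
of jitter statistics, mAP arithmetic, trainability of the graph), not
field performance on real footage.

## Problem sizes and numerical choices

The standard corrupted-track fixture is 3 objects over 20 frames of
128×128 px with 3 px box jitter — large enough that tubelet statistics are
meaningful, small enough that the whole suite runs in well under a minute.
Smoke training runs 50 SGD steps on two synthetic 64×64 frames with a
width-0.125 / depth-0.33 detector (about 0.5 M parameters); the acceptance
check asserts a strictly decreasing 10-step-windowed total loss.  These
sizes are the package's chosen desk-scale study conditions.

Other numerical conventions, in one place: boxes are corner-format,
0-based, half-open (`w = x2 − x1`), with the ±1 VOC conversion owned
solely by the annotation reader/writer; detection interchange is JSONL
(streamable per-frame, unlike one monolithic COCO JSON); probabilities are
clamped at $10^{-7}$ in cross-entropies; NMS discards boxes at IOU
strictly greater than the threshold; greedy-matching ties break
lexicographically; full training to the published mAP values requires the
original video dataset (not publicly deposited) and GPU-scale compute, and
is explicitly out of scope.
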