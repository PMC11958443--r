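---
title: "Abstract synthetic eye images for gaze-feature localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abstract synthetic eye images for gaze-feature localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
```

eyeforge generates abstract, parametric training images for pupil and
corneal-reflection (CR) localization models. The premise is that a network
can learn sub-pixel feature localization from images that only reproduce
the *light distributions* of the relevant features — blob-like bright and
dark regions, their edges, and their spatial relations — without any
photorealism. This vignette documents the rendering model, the synthetic
pipelines, the inference-side post-processing, the data-quality metrics,
the training harness, and the numerical decisions behind them.

## The rendering model

### Blob features with luminance plateaus

A pupil or CR is an anisotropic 2D Gaussian

$$G(x, y) = A \exp\!\big(-(a\,\Delta x^2 + 2b\,\Delta x \Delta y + c\,\Delta y^2)\big),$$

with the quadratic form the rotation by $\theta$ of an axis-aligned
Gaussian with spreads $\sigma_\alpha$ (minor) and $\sigma_\beta$ (major):

$$a = \frac{\cos^2\theta}{2\sigma_\alpha^2} + \frac{\sin^2\theta}{2\sigma_\beta^2},
\qquad
b = \frac{\sin 2\theta}{4\sigma_\alpha^2} - \frac{\sin 2\theta}{4\sigma_\beta^2},
\qquad
c = \frac{\sin^2\theta}{2\sigma_\alpha^2} + \frac{\cos^2\theta}{2\sigma_\beta^2}.$$

The amplitude $A > 1$ controls how steep the feature's edge is. So that
varying $A$ does not change the feature's size, the spreads are
parameterized by the plateau radii $r$:

$$\sigma_r = \frac{r}{\sqrt{-2\log(1/A)}} = \frac{r}{\sqrt{2\ln A}},
\qquad r \in \{\alpha, \beta\},$$

which makes the continuous field exactly 1 at distance $r$ from the center
along each principal axis, for every $A$. Values above 1 are clipped; the
clipped region is the *luminance plateau* — the uniformly bright part of a
CR or the uniformly dark part of a pupil. With this convention the
factor 2 on the cross term is required: without it the exponent is not a
rotation of the axis-aligned form and the plateau identity fails at oblique
orientations. Note that at $\theta = 0$ this form puts the minor axis along
$x$; `theta` in `gaussian_feature()` is therefore documented as the
minor-axis angle.

### Coordinates

Pixel indices are 0-based; a pixel's sample point is its center at integer
coordinates; $x$ grows rightward (columns), $y$ downward (rows); angles are
measured from $+x$ toward $+y$, so increasing polar angle is clockwise on
screen. Labels use this frame everywhere, including `labels.csv`.

### Compositing, noise and quantization

A scene is a background plus an ordered list of feature layers:

* **dark features** blend the running image toward their plateau luminance
  $L$ by the clipped field $c = \min(G, 1)$:
  $\text{img} \leftarrow \text{img} - (\text{img} - L)\,c$. The blend (rather
  than a literal subtraction) makes the plateau luminance exactly $L$
  regardless of what lies underneath, which is the property that makes
  pupil luminance a meaningful, dataset-matched parameter;
* **bright features** apply $\text{img} \leftarrow \max(\text{img}, L\,c)$,
  so a CR saturates to full white inside its plateau and never darkens the
  image;
* **soft-edged ellipses** (iris) and **collarette polygons** blend toward
  their luminance by a raised-cosine coefficient, 1 inside the shape and 0
  outside the shape grown by `edge_width`, following
  $(1 + \cos \pi t)/2$ across the band. The band extends *outward*; the
  interior is always at full value.

After compositing, i.i.d. Gaussian pixel noise $\mathcal N(0, \sigma_n^2)$
is added on the 8-bit scale, then the image is clipped to $[0, 255]$,
scaled to $[0, 1]$ and discretized to the 256 levels $k/255$ with
round-half-away-from-zero (an explicit rule so renders are bit-exact and
reproducible). Noise is added before clipping, mirroring a sensor that
saturates after adding read noise.

The collarette outline places $N$ base vertices at equal angles (random
phase) at distance $r_{col}$ plus a per-vertex radial offset of magnitude
uniform in $[0.05, 0.2]\,r_{col}$ with random sign, then upsamples the
closed polygon to $5N$ points by periodic cubic spline interpolation. The
filled region is rasterized in polar form (the jittered outline is
star-shaped about its center).

## Synthetic pipelines

Five pipelines emulate the light distributions of distinct recording
setups. Every interval parameter is sampled uniformly, with one exception:
the amplitude $A$ spans up to five orders of magnitude, and a uniform draw
would almost never produce a soft-edged feature, so $A$ is sampled
log-uniformly. Luminances follow the stated distributions (exponential,
Normal, or Weibull); unbounded luminance draws are resampled above 255 so
they remain valid 8-bit values.

* **High-resolution CR** (500/1000 Hz): one circular CR (plateau radius
  $[1, 30]$ px, $A \in [2, 20000]$, full white) on a background split by a
  randomly oriented straight line — the pupil-iris border — whose closest
  approach to the CR center is uniform in $[0, 2 r]$ px (the closest-approach law is a package decision;
  the border passing near the CR creates the hard luminance step beside it). The dark side has
  exponential luminance (scale 10, offset 1), the other side is middle grey
  (128) at 500 Hz or uniform $[32, 153]$ at 1000 Hz; $\sigma_n \in [0,30]$.
  Stage 2 confines the CR center to a 1.5-px span around the image center.
* **High-resolution pupil**: one dark elliptical pupil (minor radius
  $[20, 60]$ px, axis ratio $[1, 1.3]$, exponential luminance) on a uniform
  iris-grey field ($[64, 179]$ or $[32, 153]$), with one to four bright CRs
  (minor radius $[4, 12]$, ratio $[1, 1.1]$) positioned anywhere — they may
  overlap the pupil — subject to pairwise center separation of at least
  1.25 times the sum of major radii, violators being resampled (capped at
  1000 attempts, then a placement-failure error). Stage 2: pupil centered
  within 1.5 px, exactly one CR.
* **Full-eye segmentation scenes**: sclera $\mathcal N(217, 26)$; iris
  ellipse (minor radius $[30, 42.5]$ px, ratio $[1, 1.3]$,
  $\mathcal N(77, 16)$, raised-cosine edge $[8, 20]$ px); collarette
  ($13$–$24$ vertices, mean radius $[0.3, 0.6]$ of the iris major radius,
  luminance $[1.25, 1.6] L_i$, edge $[1, 4]$ px); pupil (minor radius
  $[10, 30]$, $A \in [2, 2000]$, $\mathcal N(34, 15)$); one to eight CRs
  (minor radius $[0.8, 4]$, ratio $[1, 1.4]$); $\sigma_n \in [0, 15]$.
  Labels add a binary pupil mask (pixels with blend coefficient
  $\ge 0.5$). The pupil's axis ratio follows the
  same $[1, 1.3]$ convention as every other pipeline. The pupil plateau is
  constrained to lie fully inside the iris interior — required for a
  coherent eye — by resampling the pupil's shape and offset; this skews
  pupil sizes slightly small within large-pupil/small-iris draws. The iris
  (plus edge band) is kept fully in-canvas for the same reason. This
  pipeline has a single training regime (no narrowed second stage is
  defined for it).
* **House constellation** (128 px canvas): five CRs at the vertices of a
  house-shaped polygon (rectangle of width $w \in [0.1, 0.45]d$, height
  $[0.5, 0.6]w$, roof $[0.2, 0.5]w$, bottom separation scaled by
  $[0.05, 0.2]$), identity 0 at the roof apex and identities running
  clockwise; rotation $\pm[0, 45]^\circ$; per-CR independent dropout 16%;
  one to five spurious reflections; dark pupil (minor radius $[6, 22.5]$,
  $A \in [200, 100000]$, exponential luminance); linear-gradient background
  between two luminances from $[63, 178]$ along a random axis. Stage 2:
  dropout 10%, rotation $\pm[0, 35]^\circ$, at most 3 spurious reflections.
* **Octagon constellation**: as the house pipeline but eight CRs on a
  regular octagon (circumradius $[0.15, 0.4]d$), first identity at the
  bottom-right vertex, clockwise; rotation $\pm[0, 0.57]^\circ$; dropout
  20%; pupil luminance $18 + \mathrm{Weibull}(k{=}2, \lambda{=}25)$. Setups differ in how many
  lights are actually visible, so the builder exposes the vertex count as
  configuration.

Constellation centroids sit close to the pupil: centroid = pupil center
plus an isotropic Gaussian offset with SD $0.05 d$ (a package decision reflecting that the
illuminator constellation projects onto the cornea near the pupil), resampled
until all vertices are in-canvas so that labels remain valid. The pupil
center itself is uniform in the central $[0.3, 0.7]d$ square. Dropped CRs
contribute nothing to the image and carry an `absent` flag; their heatmap
target is all zeros. Spurious reflections are placed by rejection sampling
against the inverted pupil Gaussian — a candidate is accepted with
probability $1 - \min(G_{\text{pupil}}, 1)$ — so they never land inside the
pupil plateau and rarely near it.

### Randomness and reproducibility

Each image draws from its own child RNG stream, derived from the root seed
and the image counter (a multiplicative-hash seed below $2^{31}$), so
generation order, batch splits and parallel workers do not change content;
`run_generate()` is byte-stable given a seed. Rendering itself is a pure
function of the scene and an explicit noise seed.

## Post-processing

Heatmap models emit one logit map per feature. The peak of each map is its
integer argmax (ties: smallest row, then column; no sub-pixel refinement —
pixel-level output matches how heatmap models are scored, while sub-pixel
output is the regression CNN's job). The two CRs with the highest peak
logits are selected independently per frame; a frame is invalid when fewer
than two CR maps peak at or above 1. The logit-1 rule presupposes the
training-target scale, which the harness fixes: targets are isotropic
Gaussian bumps with peak exactly 1 (SD 1 px) at the rounded feature center.

Segmentation outputs are binarized at 0.99, holes are filled (flood-fill
morphology only; no opening or closing), blobs are filtered by area
($[25, 10000]$ px$^2$) and moment axis ratio ($\le 3$) — the size and shape
criteria are configurable package defaults — and the largest survivor yields a binary center
of mass plus a direct least-squares ellipse fit to its boundary. If the
center lies strictly closer than the fitted major radius to a cutout edge,
the cutout is re-centered once and inference is meant to be re-run.

The adaptive cutout gates on an external pupil prior (e.g., an
ellipse-fitting detector run offline, supplied as a callable or CSV): with
confidence at or above the threshold (0.70 or 0.90 depending on setup) the
cutout centers on the prior; otherwise a naive centered cutout feeds a
first inference pass whose pupil estimate centers a second cutout. Images
are downscaled by a factor of two (block mean) before cropping; centers
estimated on downscaled images are multiplied back by the factor before
any metric. Cutouts at borders replicate edge pixels.

## Thresholding baseline

The classical method binarizes at fixed pupil (dark) and CR (bright)
thresholds, fills holes, and selects blobs by size, shape and relative
location — the CR must lie within 1.5 times the pupil blob's bounding
radius of the pupil center (a configurable package default).
Centers are binary centers of mass. For CNN input preparation, 180-px
cutouts are taken around the detected centers; CR cutouts get a black
radius-32 disk mask (inclusive boundary), pupil cutouts a middle-grey mask
outside 1.4 times the fitted pupil ellipse. Per-recording threshold search
is deliberately outside the library: it is a small grid search over this
function.

## Data-quality metrics and calibration

Precision metrics slide a 200-ms window (stride one sample; a window holds
`round(0.2 * fs)` samples) and report the median over windows:

* **RMS-S2S**: root mean square of Euclidean displacements between
  consecutive valid samples. Axes are combined per step (Euclidean-step
  convention; combining per-axis RMS afterwards would be an alternative
  reading, and for i.i.d. noise the two coincide). For i.i.d. positional
  noise of SD $\sigma$ per axis the expectation is $2\sigma$.
* **STD precision**: $\sqrt{\mathrm{var}(x) + \mathrm{var}(y)}$ per window;
  $\sigma\sqrt 2$ for the same noise.

Missing samples are deleted pairwise inside windows; windows with fewer
than two valid samples are skipped before the median.

Gaze is calibrated from the P-CR vector (pupil center minus CR center) by
per-axis least squares on the six terms $1, x, y, x^2, y^2, xy$; a
typical 3×3 fixation grid ($h \in \{-7, 0, 7\}^\circ$,
$v \in \{-5, 0, 5\}^\circ$) gives nine points for six coefficients, and any
map inside the model class is recovered with zero residual. Accuracy is the
mean over fixations of the distance between the median in-window gaze and
the target. The cumulative detection rate is the inclusive fraction of
errors within a threshold ("within" is read as $\le$); mean pixel error
upscales predictions by the downscale factor first.

## Training harness

Training streams freshly generated images: every batch is built on the
fly, shown once, and discarded, so the model never revisits an image and
the effective training set is the generator's distribution itself. The
two-stage regime trains first on the broad, hard distribution, then on the
narrowed stage-2 distribution with a reduced learning rate and the first
conv layer(s) frozen. Early stopping monitors a pre-generated, fixed
validation set (making stopping deterministic given seeds) and restores the
best weights after `patience` non-improving epochs. The learning rate
decays exponentially per epoch (factor 0.95 by default).

Because no deep-learning framework is a dependency, the package implements
its convolutional stack directly: 3×3 same-padding convolutions as im2col
gathers (C++) followed by BLAS matrix products, ReLU, 2×2 max pooling,
dense layers, MSE/MAE losses, and Adam. Gradients are verified against
finite differences in the tests. The full-scale seven-conv architectures
and the residual heatmap U-Net are carried as declarative `model_spec()`
configurations (kernel sizes, pooling placement and activations are
package defaults: 3×3, pooling every second layer, ReLU; parameter counts
are reported by `count_params()`). The BCE/Dice/Focal losses used by heatmap training, including
the weight-100 BCE variant, are implemented and unit-tested against
hand-computed values.

The desk-scale demonstration trains a small center regressor (conv widths
16/32/64/64 with pooling after the first three, one dense layer of 64, two
linear outputs) on 64×64 stage-2 CR images: 4 epochs of stage 1 plus up to
8 of stage 2, 1000 fresh images per epoch, batch 32, lr $10^{-3}$ then
$2\times10^{-4}$ with the first conv layer frozen. The target is the CR
center offset from the image center in px (center-relative targets are the natural
choice given the stage-2 centering constraint). On 500 held-out stage-2 images
this reaches a median localization error of about half a pixel on one CPU
in a few minutes — the package's scaled-down demonstration that sub-pixel
accuracy is learnable from these abstract images. Problem sizes (canvas
64 px, 12 epochs, 300 validation images) were chosen so the demonstration
runs on a desk machine; the full-scale regimes remain available as
configuration.

## Numerical choices and degenerate inputs

* Quantization rounds half away from zero; all rendered values are exactly
  $k/255$.
* Placement loops (CR separation, constellation in-canvas, pupil-in-iris,
  spurious rejection) are capped at 1000 attempts and raise a typed
  placement-failure error; the batch streamer skips to the next child
  stream and counts the failure.
* The centroid oracle for sub-pixel rendering uses CRs with plateau radius
  $[20, 30]$ px: the centroid of a pixel-sampled hard-edged disc has
  discretization error $O(1/r)$, and below roughly $r = 15$ the 8-bit
  staircase dominates, so the 0.02-px bound is checked in the regime where
  discretization is negligible (measured errors reach 0.4 px at
  $r \approx 1$ — a property of pixel sampling, not of the renderer).
* The "well-separated" scenes for the baseline check are stage-2 pupil
  scenes, noiseless, with a larger pupil ($[35, 60]$ px), a single small CR
  ($[4, 8]$ px, $A \ge 20$) placed well inside the pupil plateau — the
  configuration of on-axis illumination, where hole-filling makes the
  center of mass exact — and thresholds midway between the scene's known
  luminances. Center-of-mass discretization then stays under half a pixel.
* Ellipse fits use Fitzgibbon's direct least-squares conic with the axes
  and orientation extracted by eigendecomposition (robust to the conic's
  arbitrary scale sign); degenerate boundaries (under 5 points, or no
  ellipse solution) raise a typed fit error.
* Ties in heatmap argmax break to the smallest row then column; equal
  best-two logits break to the lower identity.

## What the synthetic tests do and do not show

The generators emulate luminance plateaus, soft edges, noise, constellation
geometry, dropout and spurious reflections. They do not model eyelids,
eyelashes, skin texture, motion blur, interlacing, off-axis distortion or
real sensor artifacts. Tests passing on synthetic data therefore validate
the *machinery* — rendering correctness, label fidelity, the selection and
validity logic, metric closed forms, and that sub-pixel localization is
learnable from streamed abstract images — but say nothing about accuracy on
real recordings, which depends on how well the parameter distributions
bracket a given camera and illuminator setup. Real-data evaluation
additionally requires the external pupil prior and per-dataset pre- and
post-processing parameters.
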