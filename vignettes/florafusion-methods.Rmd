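---
title: "Two-view flower classification: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-view flower classification: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

florafusion classifies flower specimens from paired front/back photographs.
This vignette explains the model and its assumptions, the parameters that
matter, what the synthetic data generator does and does not emulate, the
numerical choices baked into the implementation, and the known limits.

## The model and its assumptions

The core assumption is *complementarity of views*: two cultivars may be
indistinguishable from the front yet differ on the back (calyx, bracts,
receptacle), or the reverse. A single-stream classifier on either view is
then bounded away from perfect accuracy no matter how well it is trained,
while a classifier that fuses both views is not.

Each view runs through a 17-convolution residual backbone: a 7×7 stride-2
stem, a 3×3 stride-2 max pool, four stages of two basic blocks (stage
widths 64, 64, 128, 256, 512 at canonical scale), global average pooling.
Blocks are *pre-activation* basic blocks (BN → ReLU → 3×3 conv → BN → ReLU
→ 3×3 conv, added to the shortcut, with no post-addition ReLU), so every
block output satisfies the purely additive update
`x[l+1] = h(x[l]) + F(x[l], W[l])` exactly. This matters because the
cross-stream connection is defined additively: in the final stage, stream
`p` receives the other stream's identity term,
`x[l+1]^p = h(x[l]^p) + h(x[l]^q) + F(x[l]^p, W[p])`, both streams updated
from the pre-update inputs. With the conventional post-addition ReLU these
identities would hold only approximately; with pre-activation blocks the
package can (and does) assert them to machine precision.

The head runs 512 → 128 → 32 per stream with ReLU on the hidden layers.
The inputs of both FC layers are fused by `u^p = y^p + α·y^q` — an
*asymmetric* weighted sum: each stream keeps unit weight on itself and
weight `α` (default 1/3, i.e. own:other = 3:1 in relative terms) on the
other stream, preserving stream identity while mixing evidence. The two
32-d outputs are concatenated and classified by a single linear layer.
Streams share no weights; batch-norm statistics are per stream.

Tunable parameters, with defaults:

* `fusionAlpha` (1/3): cross-stream weight in the FC fusion. 0 disables the
  fusion; the ablation grid sweeps {0, 1/4, 1/3, 1/2, 1}.
* `crossResidualStage` (4): which stage carries cross-stream residuals;
  the default is the final 512-channel stage, i.e. the last four
  convolutions per stream.
* `stageChannels`, `fcDims`, `inputSize`: canonical (64,64,128,256,512),
  (128,32), 224 px; desk-scale profile (8,8,16,32,64), (32,16), 32 px.
* `mode`: `two_stream_full`, `front_only`, `back_only`, `concat_only`
  (two streams, no cross terms anywhere), `conv_cross_only` (cross-stream
  conv residuals, no FC fusion).

## Preprocessing

Five steps, applied independently per view: Canny edge detection (on the
ITU-R 601 luminance, hysteresis thresholds 50/150 on the Sobel magnitude of
the 8-bit intensity, replicate border padding), a minimal square crop
around the bounding box of all edges (centred on the box, clipped inside
the image by shifting, minimum side 8 px against speckle; empty masks leave
the image untouched), bilinear resize to the square input size, optional
random rotation up to ±15° (training only, black fill, drawn after the
resize, independent angles per view with a `lockAngles` option), and
normalisation `(x/255 − mean)/std` with ImageNet channel statistics by
default — chosen because the staged training is designed around
ImageNet-transferred shallow weights.

## Training

Stage one freezes the first 13 convolutional layers per stream (stem +
stages 1–3, together with their batch norms, which also stop updating
running statistics) and trains the rest; stage two unfreezes everything.
Canonical schedule: 20 epochs at learning rate 1e-3, then 30 at 1e-4,
batch 24, Adam (SGD-momentum, RMSprop and NAdam are available behind the
`optimizer` field), cross-entropy loss, no within-stage schedulers. After
every epoch the model is evaluated on the validation split and the best
checkpoint (weights + running statistics) is what the run returns.
Experiments repeat the whole split/init/train/test cycle with per-repeat
seeds `seed + r − 1`, re-randomising all three splits each repeat.

The desk-scale ("fast") profile used by the tests and the acceptance
script is 32×32 inputs, reduced widths, 5 + 10 epochs — and learning rate
1e-3 in *both* stages. The 1e-4 fine-tuning rate of the canonical schedule
presumes pretrained shallow weights; the fast profile initialises randomly
(no weight file is bundled), and at 1e-4 its ~45 optimizer steps underfit
badly. This is a deliberate property of the fast profile, not of the
canonical schedule. Rotation augmentation is drawn once per repeat on the
training split, which keeps the preprocessing cacheable; per-epoch
re-augmentation would be the natural extension at photographic scale.

Problem sizes: the test suite and `scripts/acceptance.R` use 6 classes ×
20 pairs at 64-px renders, 32-px inputs, 3 repeats — sizes at which a full
repeated experiment trains in well under a minute per mode on one CPU.

## The synthetic generator

`generateDataset()` draws flower-like images whose class identity is split
across views: the front is a rosette of k disjoint petal wedges around a
centre disk (cues: petal count, petal hue, centre radius), the back is a
set of concentric calyx rings with darker bract spokes (cues: ring count,
ring hue, spoke count), on a dark background emulating high-contrast studio
imaging, with per-image rotation, jitter, scale and Gaussian noise.
Cue assignment pairs classes so that a chosen fraction share identical
front cues (resolvable only from the back) and an offset set of pairs share
back cues, while the joint cue vector stays unique — so
`bayesSeparability()` can *enumerate* the best achievable single-view
accuracies (2/3 front, 2/3 back at the defaults) and the joint bound (1).
Ground truth (bounding boxes, petal masks, cue vectors) is exact by
construction, which is the reason for procedural rather than photorealistic
rendering.

What passing tests on this data do show: the implementation's fusion
machinery extracts complementary information that single streams provably
cannot. What they do not show: robustness to photographic nuisance —
lighting, pose, occlusion, intra-cultivar biological variation, background
clutter — none of which the generator emulates. Results at desk scale are
not evidence about accuracy on real cultivar photographs.

## Numerical choices

* Convolutions carry no bias (each is followed by batch norm); projection
  shortcuts are plain 1×1 stride-2 convolutions without batch norm, so the
  identity path stays a pure linear map and the cross-stream sum
  `h(x^p) + h(x^q)` can be projected as `proj(x^p + x^q)` per stream.
* Batch norm: momentum 0.1, eps 1e-5; batch statistics in training, running
  statistics in evaluation; frozen layers run in evaluation mode.
* Initialisation: He for conv and FC weights, unit/zero batch-norm scale
  and shift, all drawn from R's RNG so a seed reproduces a model exactly.
* Argmax ties in classification break towards the lowest class index.
* The gradient of every layer is hand-derived and checked against central
  finite differences in the test suite (relative error below 1e-4).
* Degenerate inputs: an empty edge mask leaves the image uncropped; a crop
  smaller than 8 px is widened; a minimal square larger than the short side
  of an oblong image is capped at that side (containment is then
  impossible by construction); non-finite training loss aborts with a
  diagnostic rather than continuing.
* Class activation maps are gradient-weighted (plain CAM is undefined here
  because three FC layers separate the conv features from the logits) and
  are computed by default at the deepest stage with at least 4×4 spatial
  extent — the final 7×7 stage at canonical scale, an earlier stage for
  small inputs whose final stage is 1×1. Maps are ReLU-rectified, min-max
  normalised, bilinearly upsampled.
* The t-SNE used for feature embeddings is an exact O(n²) implementation
  (perplexity calibration by bisection, early exaggeration, momentum
  gradient descent), embedded from the fused 64-d vectors by default.

## Known limitations

* The two-stream model at canonical scale counts ≈22.5 M trainable
  parameters (two unshared 17-conv backbones plus the head); no
  weight-sharing scheme between the streams is implemented.
* Desk-scale accuracy figures are properties of the synthetic study, not
  of any photographic dataset; the canonical 224-px schedule is provided
  but takes CPU-hours per repeat at realistic dataset sizes.
* Average inference time is hardware-dependent and reported for context
  only.
* The single-view Bayes bounds assume the noiseless cue model; pixel noise
  can only lower achievable accuracy, so trained single-view models may sit
  below, never meaningfully above, the enumerated bound.
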