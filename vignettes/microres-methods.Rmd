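---
title: "Residual-sum micro-expression recognition: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-sum micro-expression recognition: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microres)
```

Micro-expressions (MEs) are involuntary facial movements lasting roughly
1/25–1/3 of a second. Clips containing them are short, heavily redundant, and
the motion is subtle enough that frame-by-frame appearance is dominated by
identity and lighting rather than by the expression. `microres` implements a
recognition pipeline built around that observation: collapse the informative
part of a clip into a single *pixel residual-sum* image, tile it at two
scales with overlapping crops, extract per-tile CNN features, and classify
the fused, position-embedded feature vector. This vignette explains each
stage, the tunable parameters and their defaults, the numerical choices, and
what the bundled synthetic data generator does and does not establish.

## Window and key-frame selection

Annotations give each clip an onset, apex and offset frame. Only the
onset-to-apex stretch is analyzed: the relaxation tail after the apex mostly
repeats information. The window is

* `start = onset`;
* `end = min(apex, offset)`, unless the apex is fewer than 10 frames past
  the onset, in which case `end = min(onset + 10, offset)` so that very tight
  annotations still produce a usable window.

Clips without an apex label (SMIC-HS style) fall back to the floor midpoint
of `[onset, offset]`; we apply the same rule to any apex-less clip rather
than special-casing one dataset.

From the window, `n_key` key frames (default 5) are sampled at interval
`gap = ceiling((end - start) / (n_key + 1))` as
`min(start + k * gap, end)` for `k = 1 .. n_key - 1`, plus `end` itself. Two
deliberate details:

* The set always terminates in `end`, so the apex-adjacent frame — the
  highest-intensity one — is always included.
* The result is a *list*, not a set: on windows shorter than `n_key + 1`
  frames the clamping produces duplicates, and we keep them so the residual
  sum below always pools exactly `n_key` terms. The magnitude scale of the
  residual image is then independent of clip length, which matters because
  the ARS modulus is scale-sensitive.

## Residual-sum images

Let `Q_f(x, y, z)` be the 8-bit value of channel `z` at pixel `(x, y)` of
frame `f`, and let `F` be the key-frame list. The accumulated motion map is

```
diff(x, y, z) = sum over f in F of | Q_f(x, y, z) - Q_start(x, y, z) |
```

computed in ordinary double arithmetic (no 8-bit overflow; with `n_key = 5`
the values can reach 1275). Two reductions to an 8-bit image are provided:

* **ARS** (absolute residual sum): `diff mod 256`. The modulus is applied
  once to the final sum — not per term. Regions of large accumulated motion
  wrap around, which compresses their dynamic range while leaving subtle
  motion untouched; saturation at 255 would be the obvious alternative, but
  we implement the modulus as specified and note that the wraparound is
  exactly what makes ARS insensitive to gross head motion.
* **RRS** (relative residual sum): min–max rescaling of `diff` to
  `[gmin, gmax]` (defaults 0 and 255). The minimum and maximum are taken
  globally over all pixels *and* channels: the defining formula has no
  channel subscript, and a global range preserves inter-channel contrast. A
  per-channel variant is available behind `per_channel = TRUE` for ablation.

Numerical corner cases, all covered by tests: rescaled values are rounded
half-to-even (R's `round()`), the convention we fixed since none is stated
for this step anywhere; a constant `diff` map (a truly static clip) has zero
range and maps to all-`gmin`; RRS is invariant to adding a constant to every
`diff` value while ARS is not.

Both methods share every step before the reduction, so the package computes
`diff` once per clip. A third `method = "apex"` simply takes the cropped apex
frame — it is the natural ablation baseline, containing the same face at peak
expression but none of the temporal pooling.

## Face cropping

Faces are cropped from 68-point landmarks. The box is the tight bounding box
of the points expanded by `margin * max(width, height)` per side (default
`margin = 0.1`, configurable — no canonical value exists) and clamped to the
frame. Two design choices:

* **The detector is an interface.** Any `frame -> 68 points` function can be
  used; all bundled code and tests inject landmarks from files or from the
  synthetic generator, so the package needs no model download.
* **One box per clip**, computed from the onset frame and applied to every
  frame. Per-frame boxes would jitter, and box jitter is indistinguishable
  from motion once the residual sum is taken; a fixed box guarantees the
  residual image reflects facial motion only.

Resampling is bilinear with replicate borders, arranged so that cropping a
full frame to its own size is exactly the identity (output pixel centers map
affinely onto the box). The output is 320 × 320, the tiling module's input.

## CGPO tiling

The Cropped Gaussian Pyramid with Overlapping turns the 320 × 320 image into
10 tiles of 160 × 160:

* tile 0 — the full image downsampled once with a Gaussian pyramid step
  (5 × 5 binomial kernel 1,4,6,4,1 normalized, separable, symmetric
  reflection at borders, then decimation by 2);
* tiles 1–9 — a 3 × 3 grid of overlapping full-resolution crops at offsets
  `{0, 112, 160}` in each axis, ordered row-major (y outer).

The grid rule is `stride = round(tile_size * (1 - alpha))` with the final
offset clamped to `image_size - tile_size` and duplicates dropped. At the
default overlap factor `alpha = 0.3` the stride is 112, adjacent tiles share
48 of 160 pixels (exactly 30%), and the clamped last tile overlaps more. We
note openly that this rule is a reconstruction: the published description of
the module fixes only the overlap factor and the total of 10 overlapping
subplots, and one downsampled tile plus a clamped 3 × 3 grid is the unique
simple geometry that produces that count. Only the full-resolution level is
multi-cropped; the downsampled level contributes its single global view,
consistent with that tile receiving no position embedding later. Tile order
is fixed and documented because the position embeddings are ordinal: a
permutation of tiles between runs would silently re-associate embeddings.

## Feature extraction, fusion, classification

One shared-weight extractor maps every tile to a feature vector
`z_i` of dimension 24: a strided 3 × 3 stem convolution, a chain of MB6
inverted-bottleneck blocks (1 × 1 expansion by 6, depthwise 3 × 3 stride 2,
1 × 1 projection, batch norm throughout — the standard mobile-CNN block),
then a 1 × 1 convolution, batch norm, global average pooling and a fully
connected layer. The channel schedule must be strictly increasing — the
"progressively increasing channels" constraint — and is configurable;
`backbone_spec()` defaults to `[16, 32, 64, 96]`, and `tiny_backbone()`
(`[8, 16, 24]` with 8 × mean-pooled input) is the desk-scale configuration
used throughout the tests and the bundled study. The full-scale published
extractor (a ReXNet schedule at ~7.6 M parameters with ImageNet transfer) is
deliberately out of scope: nothing in this package depends on its exact
widths, and no pretrained weights are shipped.

Because no deep-learning framework is part of the package's dependency
footprint, the layers — convolution via im2col gather + BLAS products,
depthwise convolution, batch normalization, global pooling, fully connected —
and their backward passes are implemented in base R, with Adam as the default
optimizer (the optimizer is pluggable by design; projection-corrected
variants of Adam are not reimplemented). The backward pass is verified
against central finite differences in the test suite, which is the strongest
correctness evidence a hand-rolled engine can offer.

Fusion: tiles 1–9 receive trainable position embeddings `p_i` of the same
dimension, initialized i.i.d. normal with mean 0 and variance 0.2, and

```
z'_i = z_i + p_i   (i = 1..9),    feature = [z_0, z'_1, ..., z'_9]
```

a 240-dimensional vector fed to a single linear classifier (no hidden layer
is specified anywhere, so we use none). The combination operator is
elementwise addition, not concatenation: the embeddings are stated to have
the *same* dimension as the features, and the concatenation ("splicing") is
described as a separate, final step. `z_0` is excluded from embedding — the
global view needs no location code.

Training minimizes the label-smoothing cross-entropy
`-sum_k q_k log softmax(logits)_k`, `q_k = (1 - eps) 1[k = true] + eps / C`.
The smoothing mass `eps` defaults to 0.1 (the customary value; no published
value exists for this model). At `eps = 0` the loss is ordinary
cross-entropy, and under uniform logits it equals `log C` — both are frozen
test assertions.

## Augmentation

Training-time augmentation applies, in order: brightness/contrast/saturation
each scaled by an independent uniform draw from [0.2, 1.8] and hue shifted
uniformly within ±0.5 of the [0, 1] hue wheel; grayscale conversion with
probability 0.2; horizontal flip with probability 0.5; rotation uniform in
±15° (bilinear, replicate borders). Draw order is fixed, so a seeded run is
exactly reproducible. Two interpretation choices are documented rather than
hidden: the jitter factors are drawn independently per property, and the hue
range is read on the conventional [0, 1] wheel. Augmentation is applied to
the residual image *before* tiling, so all 10 tiles of a sample see one
consistent transform — the only placement that keeps the tile set coherent.
For the small synthetic study below the default is no augmentation: with 30
training clips per fold and a tiny backbone, the photometric jitter mostly
slows convergence without changing the outcome, and the study is meant to be
cheap and deterministic.

## Evaluation protocol

Evaluation is leave-one-subject-out (LOSO): one fold per subject, testing on
all of that subject's clips. Predictions are pooled across folds before
computing the metrics once — the composite-benchmark convention — rather than
averaging per-fold scores; the two agree only in degenerate cases, and
pooling is what makes small per-subject test sets usable. The metrics are

* `UF1 = (1/C) sum_i 2 TP_i / (2 TP_i + FP_i + FN_i)` (macro F1),
* `UAR = (1/C) sum_i TP_i / N_i` (balanced accuracy),
* `Accuracy = sum_i TP_i / N`.

A class absent from both truth and predictions has a 0/0 F1 term; we define
it as 0 and flag the class, while UAR refuses zero-support classes outright.
For composite-dataset work, `merge_to_three_classes()` maps disgust,
contempt, fear, sadness and anger to `negative`, happiness to `positive`,
and keeps `surprise`; labels outside the nine mappable classes (e.g.
"others", "repression") are rejected rather than guessed, and 5-class
single-dataset work uses raw labels unmerged.

## The synthetic study

Real ME corpora are access-restricted, so the package ships a generator
whose output has the statistical structure the method exploits, and the
bundled study runs on it end to end. Each subject gets a deterministic
schematic face (ellipse, eyes, brows, nose, mouth) with per-subject geometry
and intensity jitter plus ten low-amplitude blotches — static appearance
clutter that makes subject identity a genuine confound. Each clip plants a
Gaussian intensity bump (sd 4.5% of the frame) in a class-specific region —
mouth corner, brow, or nose wing — ramping linearly from 0 at the onset to
`motion_amplitude` at the apex (a linear ramp is the simplest monotone
profile consistent with motion growing toward the apex) and relaxing to a
quarter of the peak at the offset, under i.i.d. Gaussian pixel noise and
per-frame multiplicative illumination drift.

Defaults, chosen once as a plausible miniature of a spontaneous-ME corpus
and then left alone: 6 subjects × 6 clips × 3 balanced classes, 320 × 320
frames, 24-frame clips, peak amplitude 40 of 255 (MEs are subtle; the bump
must be visible in a single frame yet small against facial structure), noise
sd 3, illumination drift ±2%. With five key frames the planted signal
accumulates to roughly 120 of 255 in the residual map against a noise floor
around 17, while in any single raw frame the bump competes with identity
clutter of comparable amplitude — precisely the regime in which temporal
pooling should pay off, and the mechanism behind the ablation comparison.

The study itself (also what `scripts/acceptance.R` reruns): RRS, ARS and the
raw-apex baseline on the identical clips, `tiny_backbone()`, 25 epochs of
Adam at 3e-3 with batch size 12, LOSO with pooled scoring; plus a
zero-amplitude control, which must score at chance (its pooled accuracy is
compared to 1/3 with a binomial test). Problem sizes were picked so the full
study completes in minutes on a single CPU core. Generation is streaming —
each clip's frames are preprocessed and discarded — so memory stays flat.

What passing this study shows: the full pipeline — window, key frames,
single-box cropping, residual reduction, tiling, shared extractor,
embedding fusion, LOSO bookkeeping, pooled metrics — is wired correctly, the
planted class signal survives every stage, subject-level generalization
works, and the residual methods beat a same-architecture apex-frame baseline
in the regime built to reward temporal pooling. What it does not show:
performance on real faces. The generator has no geometric warping (motion is
additive intensity change), no FACS action-unit structure, no head pose, no
texture, and its class regions are cleanly disjoint; numbers obtained on it
say nothing about the published benchmarks on CASME II, SMIC-HS or SAMM,
which additionally require the full-scale pretrained backbone.

## Known limitations

* The CGPO grid rule is a documented reconstruction (see above); any other
  geometry yielding 10 tiles would need its own stride rule.
* The CNN engine is CPU-only, double precision and deliberately small;
  training the full-size schedule on real data is out of its intended range.
* JPEG frame input requires the optional `jpeg` package; PNG is native.
* Whether ARS's modulus should instead saturate is untestable from the
  method's definition alone; the modulus is implemented, and the RRS path is
  the saturation-free alternative.
* The rotation/resampling conventions (replicate borders, bilinear) are
  fixed choices where the augmentation recipe states none.
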