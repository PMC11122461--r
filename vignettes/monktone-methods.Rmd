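---
title: "Methods: continuous Monk skin-tone estimation under varied illumination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous Monk skin-tone estimation under varied illumination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(monktone)
```

## The estimation problem

Perceived skin colour confounds two physical quantities: the skin's
pigmentation and the illuminant under which it was photographed. A light
source tints every observed colour multiplicatively (to first order, the
von Kries / diagonal model), so the same person photographed under
warm-white halogen and cool-white fluorescent light produces markedly
different pixel values. `monktone` implements a pipeline for estimating a
*continuous* skin-tone index on the 10-point Monk Skin Tone (MST) Scale
from RGB face images, designed to be trainable and evaluable across
heterogeneous lighting.

The tone model is deliberately simple: the ten MST anchor colours
$C_1, \dots, C_{10}$ run light to dark, and a continuous index
$x \in [1, 10]$ maps to sRGB by linear interpolation between adjacent
anchors,

$$\hat C = C_n + (C_{n+1} - C_n)\,(x - \lfloor x \rfloor),
  \qquad n = \lfloor x \rfloor,$$

with the boundary case $x = 10$ returning $C_{10}$ and out-of-range
estimates clamped to $[1, 10]$. The anchor RGB distances are non-uniform
(the packaged anchors average about 41.1 units between neighbours), which
is why evaluation also happens in CIELAB space, where Euclidean distance
approximates perceived colour difference.

Regression rather than classification is the primary head: skin tone is a
continuous perceptual quantity, and the package's own benchmark (and the
evaluation framework below) consistently favours the regression model.

## The synthetic studio

The capture protocol being emulated is a controlled studio: each identity
is photographed under 15 lighting conditions (5 light types x 3 intensity
levels) in 5 head rotations, i.e. 75 images per identity; 285 identities
give 21,375 images, 4,275 of them front-facing. Because the original
image corpus is private, `build_dataset()` synthesises a stand-in with
the same structure and the same confound:

* A face is a shaded ellipse whose un-shaded core carries exactly the
  interpolated tone colour; eyes and mouth patches and a radial shading
  gradient provide spatial structure outside the core. Geometry (centre,
  axes) is jittered per identity.
* The illuminant is a diagonal gain: warm types are red-heavy, cool types
  blue-heavy, and the three intensity levels apply exposures 0.7 / 1.0 /
  1.3. The grey backdrop is tinted too, so the colour cast is scene-wide.
  Observed pixels are `clip(exposure * gain * colour + noise)` with
  Gaussian 8-bit noise (default sd 2).
* Tone labels are drawn from a scaled Beta(2.2, 2.2) on [1, 10]: peaked
  mid-scale with thin tails, emulating the recruitment difficulty at the
  extremes of the pigmentation spectrum. The published distribution is
  only available as a figure, so this is a stand-in shape, not a
  reproduction.
* `complexion_sigma` (default 0) adds a per-identity gap between the
  assigned label and the rendered complexion. The MST labelling process
  carries a stated margin of error of about half a unit, and label
  inaccuracy is one of the error sources discussed for mid-range tones;
  setting `complexion_sigma = 0.5` reproduces that property. It is off by
  default so that the renderer's colour contract (face core mean equals
  the interpolated label colour) holds exactly.

Everything is seeded: identities carry hash-derived RNG substreams, so
adding identities never perturbs earlier ones, and a manifest plus seed
reproduces every pixel. What the simulator does *not* model: real facial
texture and structure, spectral (non-diagonal) illuminant effects,
detector noise beyond additive Gaussian, or camera processing. Passing
tests on this world therefore demonstrates that the pipeline's machinery
is correct and that the method can separate tone from illuminant in a
diagonal-gain world — not that the learned weights transfer to real
photographs.

## Preprocessing

All operators are deterministic given their seeds and composable:

* `crop_and_resize()` crops the ground-truth face box expanded by a 10%
  margin ("slight background allowance"; the margin is a package choice)
  and resizes bilinearly. Coordinates are 0-based, half-open boxes.
* `split_identities()` partitions 65:35 either by identity (`non_mixed`,
  the realistic regime: nobody appears in both sides) or by image
  (`mixed`, which leaks identities across the split). Counts follow the
  floor rule.
* `augment_flips()` quadruples records with horizontal/vertical flips. It
  is applied to the training split only, after splitting — the safe order
  that cannot leak augmented copies into validation.
* `grey_world_balance()` rescales channels to a common mean (the Grey
  World Assumption); it is idempotent pre-clipping.
* `shuffle_pixels()` applies one uniform permutation per image to whole
  RGB triples, destroying spatial structure while preserving every
  channel histogram and the mean colour — the property that makes it a
  clean ablation of "does the model need facial structure?".
* `to_input_tensor()` produces LAB (default), RGB, or the 9-channel
  R,G,B,H,S,V,L,a,b concatenation. Fixed scalings: RGB and HSV in
  [0, 1], L/100, (a+128)/255, (b+128)/255.

LAB input is the default because the space is approximately perceptually
uniform, matching how the MST scale itself was designed.

## Colour conversion conventions

`rgb_to_lab()` is a closed-form sRGB (D65) → XYZ → L\*a\*b\* conversion in
the float convention: L in [0, 100], a and b signed. Under this
convention the largest possible Euclidean LAB distance is the box
diagonal $\sqrt{100^2 + 255^2 + 255^2} \approx 374.23$
(`max_lab_distance()`), consistent with the worst-case average error of
374.17 quoted for this metric elsewhere; the 8-bit scaled convention is
exposed as a non-default option for comparison with 8-bit library
output. The conversion is pinned by tests against an independent
closed-form oracle to 0.05 per channel.

## Models and training

The estimator is a VGG-style CNN: 3x3 convolutions with batch
normalisation and ReLU, 2x2 max pooling between stages, then fully
connected layers with sigmoid activation and dropout, ending in one real
output (regression, MSE loss) or ten softmax probabilities
(classification, cross-entropy, class $k$ = tone $k+1$; continuous
labels round half-up to integer tones for classification training).

Three profiles share this structure. `vgg16_like` and `vgg11_like`
mirror the 13- and 8-convolution VGG layouts with 4096-unit FC layers;
`tiny` (8/16/32 filters, one 64-unit FC layer, plus a fixed 2x2
average-pool stem for inputs above 32 px) exists so the full pipeline
trains in minutes on one CPU. The compute backend is a compact CNN
engine written in vectorised R — im2col convolutions through BLAS matrix
multiplies, with analytic gradients verified against finite differences.

Training is plain SGD with momentum. The protocol defaults follow the
tuned values for the full-scale model: learning rate 1e-5, momentum 0.9,
batch size 32, dropout 0.5. Epoch count is configurable (default 50;
the source protocol does not state one). For the `tiny` profile the
desk-scale experiments use learning rate 1e-3 and 15 epochs: a standard
regime for a three-block network regressing targets in [1, 10], where
1e-5 (tuned for a 138M-parameter model on a far larger corpus) would
barely move the weights in a desk-scale budget. All randomness — weight
initialisation, batch shuffling, dropout — is governed by one seed, and
identical configurations reproduce identical histories.

`freeze_layers(model, n)` excludes the first `n` convolutional layers
(counting weight-bearing feature-extractor layers in forward order, each
with its attached batch norm) from updates; the head always trains. This
supports the transfer-learning grid 0/4/8/12 on the 13-conv profile.
`fine_tune()` freezes the whole feature extractor and continues training
the head on a single light type at a tenfold-reduced learning rate
(1e-5 → 1e-6 under protocol defaults).

## Evaluation framework

For estimates $\hat x$ and targets $x$:

* **Distances** $d_i = |\hat x_i - x_i|$. (The defining equations write
  signed differences, but thresholding is only meaningful on magnitudes;
  the absolute value is used and documented.)
* **Threshold accuracy** $A_n$ = percentage of samples with
  $d_i \le n \cdot 0.1$; the **accuracy distribution** collects $A_n$
  over the grid $n = 0..n_{max}$. The tie rule is $\le$ (ties are
  measure-zero for continuous model outputs); headline thresholds are
  0.5, 1 and 2.
* **LAB error**: map $\hat x_i$ and $x_i$ through the scale to CIELAB,
  take Euclidean distances, report mean $\mu$ and *population* standard
  deviation $\sigma$ (divide by $N$, no Bessel correction).
* **Classification accuracy** is batch-wise argmax accuracy averaged
  unweighted over batches (a sample-weighted variant is also exposed).
* `eval_report()` breaks all of this down overall, per light type, and
  per skin-tone group — Group 1 (tones 1-3), Group 2 (4-7), Group 3
  (8-10), assigning non-integer targets by rounding half-up.

All metric implementations are pinned against naive loop-based oracles
to 1e-9.

## Experiment orchestration and ablations

`run_experiment()` chains simulate → split → augment → preprocess →
build → train → evaluate, derives every stage seed from one master seed,
and persists config snapshot, manifest, training log and report.
`run_ablation()` crosses the two dataset permutations of interest:

* **Pixel shuffling** removes spatial structure. On the synthetic
  benchmark this reliably lowers threshold-0.5 validation accuracy: the
  network loses the clean un-shaded face core and has to regress from a
  scrambled mixture of face, feature and backdrop pixels.
* **Identity mixing** (mixed vs identity-disjoint splits) tests leakage.
  Leakage can only help when identities carry label-relevant information
  beyond their rendered colour; with `complexion_sigma = 0.5` (the label
  margin of error) and an epoch budget long enough to overfit (30), the
  mixed split's memorisation advantage appears, mirroring the real-data
  ordering. With exact labels the two splits genuinely tie on synthetic
  data — an instructive difference between the simulator and real faces,
  where identity appearance is far richer.

## Scaled-down acceptance experiments

The desk-scale benchmark sizes (used by the test suite and
`scripts/acceptance.R`) are: 60 identities x 15 conditions x front
rotation at 64 px for held-out tone recovery (tiny profile, 15 epochs),
and 40 identities at 32 px for the ablation and head-comparison arms.
These sizes keep a full run in minutes while leaving the phenomena of
interest measurable. Typical results: threshold-2 accuracy 100% and
threshold-0.5 accuracy around 60-75% on held-out identities (chance at
threshold 0.5 is roughly 10%), with LAB error near 4 ± 3 — far below
the full-scale error ceiling, as expected for a simulator whose only
nuisance factors are illuminant gain, shading and Gaussian noise.

## Numerical choices and degenerate inputs

* Indices clamp to [1, 10]; `floor(10)` is special-cased to anchor 10.
* Batch norm uses eps 1e-5 and running-stat momentum 0.1; evaluation
  mode uses running statistics, and dropout is inverted (masks scale by
  1/(1-p)) and disabled at evaluation.
* Non-finite training loss aborts with the epoch index rather than
  continuing silently.
* Grey-world balancing errors on zero-mean channels; splits that would
  empty one side error as degenerate; unknown config keys are rejected
  by name.
* `classification_accuracy()`'s unweighted batch mean makes the final
  figure depend on batching; both rules are implemented, the unweighted
  one being the default for comparability.

## Known limitations

The simulator's faces are geometric, not photometric: no texture, no
specular highlights, no spectral rendering (the Appendix-level spectral
characterisation of real lamps is out of scope), and no real face
detector (ground-truth boxes stand in; a pluggable detector interface
would slot in at `crop_and_resize()`). Absolute accuracies on this world
exceed those reported on real data and should not be compared to them —
the package's claims are structural (counts, metric identities,
determinism, orderings between experimental arms), not photometric.
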