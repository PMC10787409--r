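---
title: "Methods: attention-gated encoder-decoder segmentation of musculoskeletal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-gated encoder-decoder segmentation of musculoskeletal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Segmenting the supraspinatus on oblique-coronal, PD fat-suppressed shoulder
MRI is hard for classical methods because the muscle is a thin, elongated,
crescent-shaped structure whose grey levels are close to those of adjacent
muscles (trapezius, deltoid) and periarticular tissue. `museg` implements a
deep encoder-decoder segmentation network for this setting together with the
full experimental scaffolding around it: a synthetic phantom generator, the
subject-level data split, threefold augmentation, the training recipe,
pooled pixel-count evaluation, and a five-variant ablation harness.

The clinical images this design targets are 8-bit 512x512x3 PNG exports of
MRI slices with hand-traced binary masks, grouped 3-5 slices per subject.
Such data are typically private; every stage of this package is therefore
exercisable end-to-end on synthetic phantoms that reproduce the geometry of
the task without any patient data.

## The model

The architecture follows the LinkNet encoder-decoder family with two
additions at the points where thin-structure segmentation tends to fail.

**Encoder.** A residual encoder (depth 18 or 34; block counts (2,2,2,2) or
(3,4,6,3)) with a 7x7 stride-2 stem and 3x3 stride-2 max pooling. For an
input of side $S$ the four stages emit features at $S/4, S/8, S/16, S/32$
with 64, 128, 256, 512 channels; a 512x512 input reaches a 16x16x512
bottleneck (total stride 32, which is why input sides must be divisible
by 32).

**Channel attention on the skips.** Each skip feature is passed through a
squeeze-excitation gate before fusion: global average pooling to a
per-channel descriptor, an affine reduction to $C/r$ ($r = 16$ by default),
ReLU, an affine expansion back to $C$, and a logistic squashing; the skip is
rescaled channel-wise by the resulting gate in $(0,1)^C$. The gate can
suppress channels that carry mostly background texture before they are added
into the decoder.

**DenseASPP bridge.** Between encoder and decoder, dilated 3x3 convolutions
with ascending rates $d \in \{3, 6, 12, 18, 24\}$ are applied in a densely
connected cascade: branch $i$ consumes the concatenation of the bottleneck
with the outputs of branches $1..i\!-\!1$ (each branch first reduces to 128
channels 1x1, then emits 64 channels at its dilation, padding = dilation so
geometry is preserved). A final 1x1 projection restores 512 channels and is
added residually to the bottleneck. This widens the receptive field without
losing resolution.

**Decoder and head.** Four decoder blocks (1x1 reduce to $C/4$, 3x3
transposed convolution with stride 2, 1x1 expand to the next stage's
channel count), with the gated skip added elementwise after blocks 1-3
(LinkNet-style additive fusion, not concatenation). The head is a stride-2
transposed convolution to 32 channels, a 3x3 convolution, and a 1x1
convolution to a single logistic output, so the network emits a probability
map at input resolution.

Batch normalization follows every convolution, as is conventional in this
encoder family. Weights are He-initialized from a caller-supplied seed; a
pretrained encoder is deliberately not required, so everything runs offline.

### Ablation variants

`build_variant()` exposes the five-model grid used to attribute performance:
`baseline` (depth-18, no additions), `scheme1` (depth-34), `scheme2`
(depth-34 + attention), `scheme3` (depth-34 + DenseASPP), and `full` (both
additions). Parameter counts are strictly ordered
(baseline < scheme1 < {scheme2, scheme3} < full), and toggling a flag
changes only the named parameter subtree - both properties are asserted in
the test suite.

## Training recipe

Binary cross-entropy on the probability map (predictions clamped by
$\varepsilon = 10^{-7}$ before the logarithms), the Adam optimizer
(framework-default moments $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, recorded in run provenance), batch size 2, learning
rate $10^{-4}$, 30 epochs by default, seeded shuffling each epoch. There is
no learning-rate schedule, weight decay, or early stopping in the recipe;
the best-validation-Dice checkpoint and the last checkpoint are both kept.
Predictions are binarized at probability 0.5 (the loss implies a
single-channel logistic output, for which 0.5 is the natural cut).

The gradient passed to the optimizer is computed analytically layer by
layer; convolution, transposed convolution, batch normalization and pooling
kernels are compiled (Armadillo, single-precision im2col + GEMM), and every
kernel's gradient is verified against numerical differentiation in the test
suite.

## Evaluation

Pixel tallies TP, FP, FN, TN feed the three reported metrics, on the
percent scale:

$$\mathrm{Pre} = \frac{TP}{TP+FP},\qquad
  \mathrm{IoU} = \frac{TP}{TP+FP+FN},\qquad
  \mathrm{Dice} = \frac{2TP}{(TP+FP)+(TP+FN)}.$$

Counts are **pooled** over all pixels of all evaluated images before the
ratios are taken (micro averaging). Pooling is a deliberate design choice:
under shared counts Dice and IoU satisfy the identity
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ exactly, and the
transcribed reference tables bundled with the package satisfy it row by row
at their printed precision - which pins down pooled rather than per-image
averaging as the convention in use. Per-image metrics remain available via
`evaluate(..., per_image = TRUE)`.

Zero denominators return 0 with a warning, except the doubly-empty case
(no target and no prediction), which returns 100; the sources are silent
here, so the convention is ours and is documented at the function.

## The phantom generator

`generate_dataset()` emulates the study's data geometry, not its physics:

* **Target.** One connected, elongated crescent per slice - the difference
  of two offset ellipses, rotated to lie roughly horizontal - with mask area
  constrained to a configurable fraction interval (default [0.02, 0.10]; the
  real mask-area statistics are not published, so this interval is a
  plumbing choice). Masks are guaranteed to be a single 4-connected
  component by rejection sampling.
* **Subjects.** Each subject draws a base shape and intensity profile; its
  3-5 slices are shift/scale/intensity perturbations of that base, so
  slices within a subject are correlated and subject-level splitting is the
  only leak-free protocol.
* **Distractors.** Elliptical structures whose mean intensity sits
  `contrast` grey levels from the target's (default 25 on the 8-bit scale,
  emulating the near-isointense neighboring muscles); the first distractor
  abuts the target boundary to exercise the blurred-boundary failure mode.
* **Noise and channels.** Additive Gaussian noise (default sigma 8, clipped
  to [0, 255]); three near-identical channels with per-channel intensity
  jitter of at most 2 grey levels, matching a grayscale-to-RGB export.

What the phantom does **not** emulate: coil bias fields, PD fat-suppression
contrast behavior, anatomy-specific texture, partial-volume effects, or
annotation noise. Passing the phantom-based tests therefore demonstrates
that the pipeline's mechanics (shapes, gradients, splits, metrics,
reproducibility) are correct, not that clinical-grade accuracy would be
reached on real MRI.

Two calibration points anchor the generator: with `noise_sigma = 0`,
`contrast = 255` and no distractors, midpoint thresholding recovers the
mask exactly (Dice 100%); and lowering `contrast` can only degrade a fixed
global-threshold segmenter, giving a monotone difficulty dial.

## Data handling

* Threefold augmentation: each image contributes itself, one rotated copy
  (90 degrees by default - exact on masks; arbitrary angles use
  nearest-neighbor resampling) and one flipped copy, with the flip axis
  alternating by sample index so both horizontal and vertical flips occur.
  The listed transforms and the 3x total pin down the
  {original, rotation, flip} reading; each output carries an `$augment` tag.
* Subject-level split: subjects are shuffled under the spec seed and
  apportioned by largest-remainder rounding (default 0.70/0.15/0.15, which
  sends 42/9/9 of a 60-subject cohort); ties go to train, then validation.
* Masks are binarized at grey level 128 on load, tolerating anti-aliased
  annotations.

## Numerical choices and degenerate inputs

* Single-precision conv kernels; batch normalization in double precision
  (eps $10^{-5}$, momentum 0.1, biased batch variance for normalization and
  unbiased for the running estimate).
* Input sides must be divisible by 32; violations raise an error naming the
  stride law rather than silently padding.
* Non-finite training losses abort with the epoch and batch index.
* The generator retries shape draws (up to 200) before admitting the
  configured area interval is unsatisfiable.

## Problem sizes in the shipped tests

The test suite exercises the architecture at 64-512 px and trains at
64-128 px: the learning-sanity check trains the full variant on 40
noiseless high-contrast 128 px phantoms for up to 15 epochs over three
seeds, and the ablation harness runs all five variants for one epoch on a
tiny 64 px corpus. These sizes were chosen so a laptop-class single CPU
reproduces everything in minutes while the network still crosses all the
stride stages that the 512 px clinical input would.

## Known limitations

* No pretrained encoder weights, mixed precision, or multi-device support.
* The comparison baselines from the segmentation literature (FCN, SegNet,
  UNet, DenseNet) are not implemented; the bundled table of reported
  metrics is used only for the internal-consistency audit.
* Boundary-distance metrics (Hausdorff, ASSD) and significance testing are
  out of scope.
* DICOM/NIfTI ingestion is out of scope; the package reads the PNG export
  format.
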