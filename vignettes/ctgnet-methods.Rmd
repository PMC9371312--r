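---
title: "Cross-task guided breast-ultrasound analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-task guided breast-ultrasound analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Breast-ultrasound (BUS) reading couples two judgements that are usually
modelled separately: *where* a lesion is (segmentation) and *what* the
image shows (classification). `ctgnet` implements a cross-task guided
multi-task network in which the two tasks exchange attention soft masks
rather than just sharing an encoder.

A single grayscale image passes through four units:

1. **Feature extraction.** A convolutional encoder (a lightweight
   4-stage stack by default; a VGG16-style stack is selectable) followed
   by atrous spatial pyramid pooling (ASPP) produces the shared features
   `F'` (D channels at 1/8 resolution). ASPP runs a 1x1 branch plus one
   dilated 3x3 branch per configured rate and fuses them with a 1x1
   projection; its multi-rate receptive fields help with the wide range
   of lesion sizes.
2. **Coarse segmentation.** A decoder with four x2 bilinear upsampling
   stages, each followed by two convolutions, emits a 3-channel
   per-pixel softmax `M = (M_l, M_m, M_b)`: coarse lesion, mammary
   gland, background. These are *soft* masks; they are passed on as
   probabilities, never thresholded.
3. **Lesion classification.** The lesion attention module (LAM) gates
   the shared features with the two soft masks,
   `F_LAM = F' + F' * M_m + F' * M_l`, so gland- and lesion-consistent
   activations are emphasised. Global average pooling and an affine map
   yield the per-class feature matrix `G_global` (D1 x C); a second
   affine map gives the class scores `H_score = softmax(logits)`.
4. **Fine segmentation.** Two attention streams are fused by channel
   concatenation and decoded to the final binary lesion mask:
   * the category selection module (CSM) re-weights a 1x1 transform of
     `G_global` by the class scores and multiplies it with a C-channel
     projection of `F'`, injecting "what the classifier believes" into
     the segmentation;
   * the anatomical knowledge guidance module (AKGM) is a non-local
     self-attention block whose query and key are gated by the gland
     mask `M_m`, with output `alpha * (V S^T) + F'` and the scalar
     `alpha` learned from an initial value of exactly zero, so attention
     switches on gradually and the module is the identity at
     initialisation.

The attention masks stay inside the computation graph: gradients of the
classification loss reach the coarse decoder through LAM, and gradients
of the fine Dice loss reach the classifier through CSM. This cross-task
gradient flow is the point of the design, and the package's tests assert
it explicitly.

### Loss and task balancing

The joint objective is

```
L_total = lambda_1 * L_cls + lambda_2 * (L_cseg + L_fseg)
```

with cross-entropy for classification and soft Dice (smoothing
`eps = 1` in numerator and denominator) for both segmentation heads; the
two Dice terms share one task weight, so the scheme has K = 2 tasks.
Dynamic weight averaging (DWA) sets the weights each epoch from the
ratio of the last two epoch-mean task losses,
`lambda_k = K exp(w_k/T) / sum_i exp(w_i/T)` with temperature `T = 2`;
the first two epochs use unit weights, and the weights always sum to 2.
Optimisation is Adam (`beta1 = 0.9`, `beta2 = 0.99`, `eps = 1e-8`) with
early stopping on the weighted validation loss after 10 epochs without
improvement.

## Implementation notes and numerical choices

The network, including all backward passes, is implemented in this
package: convolutions, pooling and bilinear resampling run through
compiled kernels, the attention and head algebra through ordinary matrix
products. Every analytic gradient is checked against central finite
differences in the test suite at a generic (jittered) parameter point;
the check uses a step of 1e-6 because the ReLU kinks make coarser steps
noisy, and the exact-zero bias point at initialisation is itself a
non-differentiable point of the loss.

Choices the architecture description leaves open were resolved as
follows.

* **Decoder resolution.** A stride-8 backbone with four x2 upsamplings
  overshoots the input resolution; the decoder keeps the stated four
  stages and bilinearly resizes the logits to the exact image size
  before the softmax, which guarantees a resolution match for any input
  size.
* **Decoder block composition: instance normalisation.** The soft-Dice
  objective rewards ever more confident softmax outputs. With plain
  conv+ReLU blocks the decoder activations grow without bound (observed
  to exceed 1e3 within 50 Adam steps at learning rate 1e-3) until the
  per-pixel softmax saturates and all segmentation gradients vanish —
  training then freezes with the lesion channel collapsed. Each decoder
  convolution is therefore followed by instance normalisation (each
  channel standardised over the spatial positions of its own image, with
  a learned per-channel affine map) before the ReLU, the standard block
  composition in modern medical-segmentation decoders. Instance
  normalisation has no batch coupling and no running statistics, so
  inference stays deterministic and batch-size independent. The encoder
  is left normalisation-free, which keeps the shared features exactly
  translation-equivariant in whole-stride steps.
* **Batch-pooled training Dice.** The training loss computes one soft
  Dice per class over the concatenated pixels of the whole batch rather
  than averaging per-image Dice. With per-image averaging and `eps = 1`,
  a lesion-free image reaches a perfect lesion-channel Dice by
  predicting nothing, and the gradient pulling its pixels toward
  "empty" is two orders of magnitude stronger than the gradient pulling
  lesion pixels toward "lesion" on the images that have one; in every
  trial the lesion channel collapsed to the empty prediction. Pooling
  equalises the two signals. *Evaluation* metrics are still averaged
  per image, matching how Dice is reported for cases.
* **Attention conventions.** Query/key depth is `D' = max(1, D/8)`; the
  similarity matrix is the row softmax of `t(Q') K'` over the key axis,
  so each output position is a convex combination of value vectors;
  `alpha` is a single scalar. Soft masks are resized between image and
  feature resolution by bilinear interpolation, which preserves their
  probabilistic range (and per-pixel sums, by linearity).
* **Classification head.** `G_global` is produced from the pooled
  vector by one affine map reshaped to D1 x C — the minimal realisation
  of "transformed into" — and the logits by a weight vector shared
  across class columns plus a per-class bias, which makes class
  permutation act consistently on scores and features. No dropout or
  normalisation is used in the head.
* **Channel order** of the coarse mask is (lesion, gland, background)
  everywhere, and `hard_mask()` breaks argmax ties toward the lower
  channel index.
* **Empty-mask metric conventions.** Both masks empty: DSC = JI = TPR
  = 1, FPR = tFPR = 0. Ground truth empty but prediction non-empty:
  DSC = JI = TPR = 0, FPR = 1, and tFPR undefined for that image — it is
  excluded from tFPR averages and counted in the `n_tfpr_excluded`
  column.

## The phantom generator

Real BUS data cannot ship with the package, so every stage is exercised
on seeded synthetic phantoms that reproduce the features the method
actually uses:

* a layered anatomy — bright skin/fat band, mid-grey mammary-gland band,
  darker muscle with periodic bright rib-like blobs;
* at most one hypoechoic lesion per image, placed entirely inside the
  gland band (the anatomical prior that AKGM exploits);
* lesion morphology encodes the class: benign lesions are smooth
  ellipses (axis ratio 0.6-1.0), malignant ones star polygons with 7-12
  jittered spikes — a learnable shape signal analogous to clinical
  morphology;
* Gaussian smoothing followed by multiplicative unit-mean Gamma speckle,
  so expected layer contrast is preserved;
* binary labels (normal/lesion) by default, three-class
  (normal/benign/malignant) by configuration.

The lesion radius parameter is the geometric-mean semi-axis, so the
pixel area tracks `pi r^2` regardless of eccentricity; shapes are
rescaled, area-preserving, whenever a draw would not fit inside the
gland band. Defaults (64x64 images, skin fraction 0.12, gland fraction
0.35, lesion probability 0.5, radius 5-10 px, contrast offset -0.25,
speckle strength 0.15) were chosen once as a plausibly difficult
low-contrast setting and define the study conditions for all tests.

What the phantoms do **not** emulate: acoustic shadowing and
enhancement, probe markings and annotations, posterior features,
heterogeneous parenchyma, multiple lesions, or operator variability.
Passing the phantom experiments therefore demonstrates that the
implementation is correct and that the architecture can learn this
class of layered, speckled, low-contrast images — not that it reaches
any particular performance on clinical data.

## Problem sizes and profiles

The full profile mirrors the published recipe (256x256 inputs, D = 64,
batch 16, learning rate 1e-4, up to 100 epochs, patience 10). The
*desk profile* used by the examples, tests and the acceptance script is
the package's own choice of a configuration a single CPU trains in
minutes: 64x64 phantoms, a narrow encoder (base width 8, D = 32,
D1 = 16), batch 8, 20 epochs, Adam at 3e-3. The larger step size is
deliberate: a small normalised network trained from scratch for a few
hundred steps, rather than a pretrained VGG16 being fine-tuned for tens
of thousands, sits in the regime where normalised segmentation networks
are routinely trained with step sizes of 1e-3 to 1e-2. The end-to-end
experiments train 200 images for 20 epochs (500 Adam steps) and
evaluate on 50 held-out phantoms; the capacity check overfits a single
batch of 8 phantoms for 300 steps.

## Known limitations

* The N x N attention matrix is materialised, so AKGM is quadratic in
  the number of feature cells; at stride 8 a 256x256 input gives
  N = 1024, which is the intended operating range. Larger inputs need a
  larger stride.
* VGG16 is available as an encoder topology, but pretrained weights are
  not bundled; `pretrained = TRUE` is refused rather than silently
  random.
* The per-epoch DWA update uses epoch-mean losses; with very few batches
  per epoch the loss ratios are noisy and the weights move accordingly.
* `cls_metrics()` assumes binary labels; in three-class mode the
  evaluation treats "any lesion" as the positive class, with the
  positive score defined as one minus the normal-class score.
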