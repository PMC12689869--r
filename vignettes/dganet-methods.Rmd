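---
title: "DGA-Net in R: model, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DGA-Net in R: model, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: the model and its assumptions, the parameters that matter, what the
synthetic phantom generator does and does not emulate, and the places where
the design was genuinely open and we had to decide.

## 1. Problem and model

Liver and tumor segmentation in abdominal CT is a dense three-class labelling
problem (background / liver / tumor, with the liver mask conventionally
including tumor voxels). DGA-Net addresses two recurring difficulties —
long-range pixel dependencies and parameter cost — with a dual-branch
encoder and a cross-attention decoder:

* the **FSMF branch** learns filters in the Fourier domain. The 2D DFT of a
  feature map is split into real and imaginary parts; each passes through a
  `1x1 conv -> LeakyReLU (slope 0.01) -> 1x1 conv` branch before the inverse
  transform, a 3x3 convolution and a residual connection. Because every
  frequency bin mixes information from the whole image, one such unit has a
  global receptive field at the cost of a few 1x1 convolutions. A multi-scale
  fusion unit (native + 2x-downsampled paths + residual) follows each
  spectral pass to restore local detail.
* the **MAHA branch** replaces quadratic self-attention with Hadamard-product
  attention applied per channel group along one axis pair each (height–width,
  channel–height, channel–width). The attention weights are
  `softmax((q + Pq) ⊙ (k + Pk) + Rb)` over the attended axis pair, with the
  softmax normalizing to 1 along that pair at every position of the remaining
  axes; the output is the weight map times `v`, element-wise. Nothing of size
  `L × L` is ever materialized, so the multiply count grows linearly in the
  pixel count (an invariant the test suite checks by operation counting).
* the **GMCA decoder** fuses, at each of five stages, the upsampled decoder
  state with the two encoder skips: channel-grouped concatenation + layer
  normalization feeds a four-branch dilated-convolution block (dilations
  1/2/5/7, padding = dilation so sizes are preserved), while the ungrouped
  maps feed two multi-head cross-attention arms (decoder queries against
  FSMF keys/values and against MAHA keys/values, scale `sqrt(D/H)`); the two
  arm outputs are added element-wise, and the two branch outputs are each
  projected by a 1x1 convolution and summed.

The training loss is `L = L_CE + L_DC`: mean pixel-wise cross-entropy plus
one minus the mean soft Dice over the two foreground classes. Dice is
computed on probabilities (differentiable), with smoothing 1e-5; background
is excluded from the Dice term, which is what makes the term useful against
the extreme class imbalance of tumor pixels.

## 2. Tunable parameters

| parameter | default | meaning |
| --- | --- | --- |
| `stage_widths` | 20, 40, 80, 172, 336 | channels per encoder stage (decoder mirrors them) |
| `miaf_heads` | 4 | heads in the decoder cross-attention |
| `token_budget` | 4096 | max tokens before attention; larger grids are average-pooled 2x repeatedly, attended, and bilinearly restored |
| `input_size` | 512 x 512 | reference size of the MAHA positional tables (bilinearly rescaled at other sizes) |
| `lr0`, `poly_exponent` | 0.01, 0.9 | SGD schedule `lr0 (1 - e/e_max)^0.9` |
| `momentum`, `clip_norm` | 0.99 (Nesterov), 12 | optimizer stability pair |
| `batch_size`, `max_epochs` | 4, 1000 | published recipe; desk runs cap `max_steps` |
| HU window, z-norm | [-17, 201], (99.04, 39.36) | CT preprocessing constants |
| `spacing` | 0.7676 mm/px | target in-plane resolution |

The stage widths were calibrated once — a one-dimensional sweep of the base
width followed by a small grid over the two deepest widths — so that the
default network carries 13.90M trainable parameters (the published budget is
13.91M; the printed per-stage channel counts of the reference pipeline are
not reconcilable with that budget, so the budget itself was taken as the
binding constraint). They are frozen; nothing else was tuned against a
reported number.

## 3. Architecture bookkeeping

Both branches produce skips at relative resolutions 1, 1/2, 1/4, 1/8, 1/16.
Stage 1 keeps full resolution (the published data flow downsamples at every
stage *except* the first): the FSMF stem is conFFT + conOp, and the MAHA
stem is the DConv double convolution *without* its trailing max-pool — the
literal reading "three DConv stages" would desynchronize the two branches'
resolutions and break the per-stage skip pairing. Stages 2–4 are DConv
blocks (two `3x3 conv + BN + ReLU`, then 2x2 max-pool); stage 5 max-pools
and applies the branch's specialty units (a 1x1 projection and two stacked
FSMF units; one MAHA unit per stage at stages 4–5). The decoder starts from
a 1x1 fusion of the two deepest skips and walks back up through five GMCA
stages; the final head is a 1x1 convolution to three classes with a softmax
over channels.

Two practical consequences:

* inputs must be divisible by 32 when the FSMF units are active (four
  halvings plus the down/up pass inside the deepest multi-scale fusion);
  `predict_volume()` pads slices reflectively and crops afterwards.
* the MAHA positional tables have a build-time spatial extent; at other
  run-time sizes they are bilinearly rescaled (differentiably), the standard
  treatment for resolution-dependent positional parameters.

## 4. Numerical choices

* **Frequency-domain gradients.** The DFT is treated as a real linear map to
  (real, imaginary) pairs; the backward passes are the exact adjoints
  (`Re(F^H g)` and `-Im(F^H g)`), verified against finite differences.
* **Cross-entropy.** The public `cross_entropy_loss()` follows the stated
  definition on probabilities with a 1e-7 clamp before the logarithm.
  Training, however, uses a fused log-sum-exp cross-entropy on the logits
  whose gradient is exactly `(softmax - onehot)/N`: the clamped probability
  form has a vanishing gradient once a pixel saturates to the wrong class
  (the product `p * 1/max(p, eps)` collapses for `p << eps`), which we
  observed as an unrecoverable all-background collapse in early experiments.
* **Optimizer stability.** Nesterov momentum 0.99 at lr 0.01 amplifies
  gradients by up to `1/(1-m) = 100`; the reference framework survives this
  with a global gradient-norm clip of 12, which we adopt
  (`train_config(clip_norm = 12)`).
* **Batch/layer normalization.** BN uses batch statistics in training and
  running statistics (momentum 0.1, eps 1e-5) in evaluation; LN normalizes
  the concatenated channel dimension per spatial position, eps 1e-5.
* **Down/up sampling.** The down path in multi-scale fusion is 2x2 average
  pooling; all upsampling is half-pixel-centre bilinear interpolation
  (corner alignment disabled), which preserves constants exactly and the
  spatial mean to numerical precision.
* **Attention degeneracies.** A zero pre-activation map softmaxes to uniform
  weights; zero-magnitude spectrum bins get phase 0 by convention
  (`atan2(0, 0) = 0`).
* **Surface metrics.** Boundaries are foreground pixels with a background
  face-neighbour (4-connectivity in 2D, 6 in 3D; the array border counts as
  background). Directed distances are exact Euclidean distances in physical
  units via a Felzenszwalb distance transform with anisotropic spacing.
  HD95 is the 95th percentile (linear interpolation between order
  statistics) of the *merged* set of both directed distance lists, which
  makes it symmetric. Empty masks make surface distances undefined: the
  functions return `NA` with a warning and aggregation skips them. RAVD is
  unsigned; Dice of two empty masks is 1, VOE 0.
* **Dice-loss reading.** The printed overlap formula defines the Dice
  *coefficient*; as a loss to be minimized it is implemented as
  `1 - soft Dice`, the only reading under which training reduces it.

## 5. The phantom generator

`generate_case()` emulates the geometry and intensity statistics of
LiTS-style liver CT at desk scale: a smoothly deformed ellipse ("liver",
100 ± 15 HU) on a darker background (-50 ± 20 HU), containing star-shaped
"tumor" blobs (60 ± 12 HU) whose caliper (maximum Feret) diameter is
controlled in the three clinical strata (< 2 cm, 2–5 cm, > 5 cm at a
configurable mm/px spacing, default 0.7676). Intensities (not labels) get a
1-pixel Gaussian blur to imitate partial-volume edges, and optional i.i.d.
Gaussian HU noise. Generation is bit-identical under a fixed seed.

Choices a user should know about:

* the default HU statistics were chosen so both tissues survive the
  [-17, 201] HU window and the published z-normalization constants remain
  plausible; contrast between liver and tumor is then ~40 HU against ~12-15
  HU texture noise, i.e. an *easy* but not trivial discrimination problem.
* only the first (largest) tumor must belong to the declared stratum —
  stratification is by the case's maximum diameter, so secondary lesions
  sample smaller diameters and are dropped when the liver is too crowded;
  a stratum whose minimum diameter cannot fit the liver raises an error
  suggesting a larger image or smaller stratum.
* tumors are extruded through the slice stack and the liver shrinks slightly
  toward the stack ends; there is no 3D shape prior, no vessels, ribs,
  breathing artifacts, or scanner-specific noise texture.

A green training test on phantoms therefore establishes that the
architecture, loss, optimizer and pipeline can jointly learn a
medium-contrast segmentation task end-to-end on CPU — it says nothing about
clinical LiTS performance, which requires the real data and GPU-scale
training and is explicitly out of scope here.

## 6. Open-design decisions

Several points were under-determined and decided once:

* **Spectrum components.** The spectral learning unit operates on the real
  and imaginary parts of the DFT (matching the superscripts of the defining
  equations); the alternative amplitude/phase reading is implementable but
  not the default.
* **One axis per group.** MAHA groups 1–3 attend along exactly one axis pair
  each rather than summing all three axes per group; this keeps the
  parameter count at the stated low-cost level. The q/k/v "MLPs" are single
  linear (1x1 convolution) maps.
* **Hadamard attention algebra.** The printed attention formula has index
  collisions; it is implemented as
  `softmax_axis((q + Pq) ⊙ (k + Pk) + Rb) ⊙ v` — positional embeddings fold
  additively into q and k, plus a positional bias — which is the reading
  consistent with "weights computed by the Hadamard product, augmented by
  relative position embeddings".
* **FFAB/MIAF merge.** The source is silent on how the two decoder branches
  combine; each is 1x1-projected to the stage width and the two are summed,
  consistent with the stated element-wise-addition gloss for combining the
  attention arms.
* **Token budget.** Cross-attention materializes an `L x L` matrix per head;
  above the budget (default 4096 tokens) the maps are average-pooled before
  attending and bilinearly restored after. The desk configuration uses 256
  tokens: a 4096-token score matrix (~134 MB per head per arm) is
  incompatible with the single-CPU training budget. This knob trades
  attention resolution for compute and was fixed before any acceptance
  measurement.
* **Frequency-domain 1x1 convolutions carry no bias** (a bias added to every
  frequency bin is not a meaningful spatial operation); the spatial 3x3
  convolutions keep biases.
* **Checkpoint format.** A single RDS file holding the config as JSON text,
  all named parameter arrays, BN running statistics and an integer checksum
  of the config; the loader rebuilds the architecture and validates the
  checksum.

## 7. Known limitations

* 2D only: slices are segmented independently; no cross-slice context.
* The engine is CPU-bound, double-precision R; it is built for correctness
  and desk-scale experiments (seconds per training step at width 8, 96x96),
  not for full-scale 512x512 training at width 336.
* The public cross-entropy on probabilities is for evaluation and testing;
  training always goes through the fused logits path (see section 4).
* Replicate confidence intervals use the t-based formula
  `mean ± t(0.975, n-1) sd/sqrt(n)`; published bracketed intervals in this
  literature are not always internally consistent, so only the formula and
  the critical value (4.303 at df = 2) are contract-tested.
* The NIfTI codec covers the single-file NIfTI-1 subset this package writes
  (float32/64, int16/32, uint8, little-endian, slope/intercept honoured on
  read); it is cross-checked against nibabel in the test suite but is not a
  general-purpose reader.
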