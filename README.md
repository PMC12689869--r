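# dganet

Slicewise liver and tumor segmentation of abdominal CT with **DGA-Net**, a
dual-branch encoder–decoder network, implemented entirely in R. The package
is aimed at methods researchers who want to study, test and retrain this
architecture at desk scale — on synthetic CT phantoms, on a single CPU,
without any deep-learning runtime or dataset download.

## The model

DGA-Net segments each CT slice into background (0), liver (1) and tumor (2)
with two parallel five-stage encoders and a five-stage decoder:

* **FSMF branch** (Fourier spectral-learning multi-scale fusion). A stem
  applies `FFT -> 1x1 conv -> IFFT` (conFFT) plus a `3x3 conv + ReLU`
  (conOp); three double-convolution (DConv) stages halve the resolution; the
  deepest stage stacks two FSMF units. Each FSMF unit learns separate
  `1x1 conv -> LeakyReLU -> 1x1 conv` filters on the real and imaginary parts
  of the 2D DFT of its input,

      F_re, F_im = FFT2(x);   y = conv3x3(IFFT2(f(F_re), g(F_im))) + x,

  then fuses three scales: `ReLU(BN(conv3x3(x))) + UP(ReLU(BN(conv3x3(DN(x))))) + x`.

* **MAHA branch** (multi-axis aggregation Hadamard attention). Feature maps
  are chunked into four channel groups. Groups 1–3 receive Hadamard-product
  attention along one axis pair each — height–width, channel–height,
  channel–width:

      w = softmax_axis((q + Pq) (*) (k + Pk) + Rb);   out = w (*) v + x,

  where `q,k,v` are 1x1 projections, `Pq, Pk, Rb` learned positional tables
  on the attended plane, and `(*)` the element-wise (Hadamard) product. No
  token-by-token score matrix is formed, so cost is linear in the pixel
  count. Group 4 is a residual 3x3 convolution; the groups are merged by a
  3x3 convolution with GELU.

* **GMCA decoder** (group multi-head cross-attention aggregation). Each stage
  upsamples the previous decoder state bilinearly, chunks it and the two
  encoder skips into four groups, concatenates matching groups and layer
  normalizes them. The fused groups feed four parallel dilated 3x3
  convolutions (d = 1, 2, 5, 7; FFAB) while the ungrouped maps feed two
  cross-attention arms (MIAF): queries from the decoder state, keys/values
  from the FSMF skip (arm 1) and the MAHA skip (arm 2),
  `softmax(Q K^T / sqrt(D/H)) V` per head, arms combined by element-wise
  addition. Both branch outputs are projected by 1x1 convolutions and summed.

Training minimizes `L = L_CE + L_DC` (pixel-wise cross-entropy plus soft Dice
over the foreground classes) with SGD (lr 0.01, Nesterov momentum 0.99,
polynomial decay `(1 - epoch/epoch_max)^0.9`, batch 4, gradient-norm clip 12).
The default configuration (stage widths 20/40/80/172/336) carries
**13.90 million trainable parameters**, matching the published 13.91M budget
within 0.1%.

Evaluation implements the field's six metrics — Dice, Dice per case (DPC),
global Dice (DG), volumetric overlap error (VOE), relative absolute volume
difference (RAVD), average symmetric surface distance (ASSD) and HD95 —
with spacing-aware exact Euclidean distance transforms, plus replicate
statistics (mean, SD, 95% CI, paired two-tailed t-test with critical |t| =
4.303 at df = 2).

Everything runs on a package-internal reverse-mode autodiff engine (plain R
arrays + Rcpp kernels for convolution and the distance transform); no torch
or tensorflow is required.

## Worked example

```r
library(dganet)

# 1. synthesize LiTS-like phantom cases (bright liver, darker tumor blobs)
cases <- generate_dataset(20, phantom_spec(image_size = 96, slices = 4, seed = 42))

# 2. train a desk-scale (width-8) DGA-Net for 200 steps
fit <- train_dganet(cases[1:16], dganet_desk_config(),
                    train_config(max_epochs = 13, max_steps = 200, seed = 42))
tail(fit$history[, c("epoch", "lr", "loss", "ce", "dice")], 1)
#>  epoch           lr       loss         ce       dice
#>     12 0.0009941479 0.03698193 0.02104601 0.01593592

# 3. evaluate on held-out phantoms
rep <- evaluate_model(fit$net, cases[17:20], train_config())
rep
#> Aggregate metrics:
#>  class    dpc     dg      voe     ravd     assd   hd95
#>  liver 0.9986 0.9986 0.002889 0.001061 0.003085 0.0000
#>  tumor 0.9833 0.9837 0.032831 0.014428 0.032687 0.1919
#> (8 case rows; see $per_case)
```

Reading the output: after 200 CPU training steps (about 5 minutes) the
held-out Dice-per-case is 0.999 for liver and 0.983 for tumor; the surface
distances (ASSD, HD95) are in millimetres at the 0.7676 mm/px default
spacing, so the average boundary error is a small fraction of a pixel.
Phantoms are an easy task by design -- see the methods vignette for what
these numbers do and do not establish.

The same loop is available from the command line via the launcher at
`system.file("cli", "dganet", package = "dganet")` (symlink it onto your
PATH, or call `dganet_main()` from R):

```sh
dganet synth    --config cfg.json --cases 20 --out phantoms/
dganet train    --config cfg.json --data phantoms/ --out model.dgk
dganet predict  --config cfg.json --checkpoint model.dgk --image phantoms/case_001_image.nii.gz
dganet evaluate --config cfg.json --checkpoint model.dgk --data phantoms/ --out report
dganet ablate   --config cfg.json --variant no_gmca --data phantoms/
```

Configs are JSON with `phantom`, `net` and `train` sections mirroring
`phantom_spec()`, `dganet_config()` and `train_config()`. Volumes are read
and written as NIfTI-1 (`.nii` / `.nii.gz`).

## Package layout

| Area | Files |
| --- | --- |
| autodiff engine | `R/tensor.R`, `R/ops.R`, `src/kernels.cpp` |
| Fourier blocks | `R/fourier.R` |
| Hadamard attention | `R/maha.R` |
| decoder | `R/gmca.R` |
| assembly, counting, checkpoints | `R/network.R` |
| losses / metrics / statistics | `R/losses.R`, `R/metrics.R`, `R/replicate_stats.R` |
| phantoms, pipeline, NIfTI, CLI | `R/phantoms.R`, `R/pipeline.R`, `R/nifti.R`, `R/cli.R` |

See `vignettes/dganet-methods.Rmd` for the modelling choices, parameter
meanings and known limitations.
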