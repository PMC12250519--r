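# octdamage

Quantification of laser-induced skin damage from swept-source OCT B-scans.

Laser safety and laser-therapy studies need a number: how large is the
damaged skin volume, and how does it change with irradiation dose and
recovery time? OCT delivers stacks of cross-sectional B-scans of the injury
site noninvasively, but speckle noise obscures the lesion boundary and
manual delineation does not scale to hundreds of slices per scan.
`octdamage` is an R toolkit for the whole measurement chain, aimed at
image-analysis researchers and methods developers working with OCT-like
cross-sectional data:

* **BM3D-style speckle suppression** — block matching, a separable
  orthonormal 3-D transform (2-D DCT per 8×8 block, 1-D Haar across the
  similarity group), hard thresholding and weighted aggregation, iterated
  twice — plus frequency-domain (`log_spectrum()`, `hf_band_energy()`) and
  fidelity (`psnr()`) diagnostics.
* **Attention-UNet segmentation** of the damaged region. The decoder can
  carry SimAM (a parameter-free energy attention: a pixel with value $x$ in
  a channel with spatial mean $\mu$ and variance $\sigma^2$ is reweighted by
  $\mathrm{sigmoid}\!\big(\frac{(x-\mu)^2+2\sigma^2+2\lambda}{4(\sigma^2+\lambda)}\big)$)
  and PSA (pyramid squeeze attention: channels split into multi-scale
  convolution branches rescaled by softmax-normalised squeeze descriptors),
  combined in **tandem**, **parallel** or **nested** topologies. Training
  uses weighted cross-entropy (damage 1.5 / background 1.0), Adam with
  weight decay, cosine learning-rate cycles and gradient clipping. There is
  no deep-learning framework underneath: the package implements a small
  reverse-mode autodiff tape over compiled (RcppArmadillo) convolution
  kernels, verified against finite differences.
* **Segmentation metrics** from a pixel confusion matrix: Dice
  $2|X\cap Y|/(|X|+|Y|)$, accuracy, mean pixel accuracy (mPA) and mean IoU.
* **Voxel volumetry**: $V = V_P \sum_k F(s_k)$ — the damage-pixel count
  summed over slices times the per-voxel volume ($10 \times 22 \times 50\ \mu
  m = 11{,}000\ \mu m^3$ by default) — with dose/timepoint healing tables.
* **A seeded phantom generator** emulating layered skin-like B-scans with
  elliptical lesions, exact truth masks and analytic lesion volumes, so the
  entire pipeline is testable without any acquired data.

## Worked example

Forty 64×64 phantom B-scans with jittered lesions are generated, a
ParallelAT-UNet (depth 3, base width 16) is trained for 30 epochs (about two
minutes on one CPU core), and the held-out test images are evaluated and
measured:

```r
library(octdamage)

pairs  <- phantom_benchmark(40, seed = 1)
images <- lapply(pairs, function(p) p$images$slices[[1]])
masks  <- lapply(pairs, function(p) p$truth$slices[[1]])

fit <- train_segmenter(
  build_unet("parallel", base_width = 16, depth = 3, seed = 1),
  list(images = images, masks = masks),
  train_config(epochs = 30, lr = 3e-4, lr_period = 30, seed = 1))
print(fit)

idx <- fit$split$test
ev <- evaluate_segmenter(fit, images[idx], masks[idx])
print(ev$pooled)

pred <- mask_stack(ev$predictions)
print(damage_volume(pred, voxel_geometry()))
```

```
<oct_unet> variant=parallel depth=3 base_width=16 classes=2
  parameters: 120,458  attention: parallel @ decoder level(s) 1,2
  trained: 30 epoch(s), best val Dice 0.9478
Dice 0.9287 | mIoU 92.89% | mPA 98.74% | accuracy 99.14%
<damage_volume> V = 1.147e+07 um^3 over 4 slice(s), V_P = 11000 um^3
```

The report reads: a Dice of 0.93 against the true lesions, and the four test
B-scans carry about $1.15 \times 10^7\ \mu m^3$ of segmented damage
(four slices of a 64×64 grid at $11{,}000\ \mu m^3$ per voxel).
`healing_table()` then collates such volumes across dose and recovery-time
groups, and `run_pipeline()` (or the `inst/cli/octdamage` script) drives the
same chain — denoise, train or load, segment, evaluate, volumetrise — from a
single YAML configuration.

## Package layout

| Area | Entry points |
| --- | --- |
| Image I/O & geometry | `read_image_stack()`, `write_mask_stack()`, `preprocess_geometry()`, `restore_geometry()` |
| Denoising | `bm3d_config()`, `bm3d_denoise()`, `match_blocks()`, `collaborative_filter()`, `psnr()`, `log_spectrum()` |
| Attention | `attention_config()`, `attention_block()`, `simam()`, `apply_attention()`, `psa_softmax_weights()` |
| Segmenter | `build_unet()`, `train_segmenter()`, `predict()`/`predict_stack()`, `evaluate_segmenter()` |
| Metrics | `confusion()`, `dice()`, `accuracy()`, `mpa()`, `miou()`, `metrics_report()` |
| Volumetry | `voxel_geometry()`, `damage_pixel_count()`, `damage_volume()`, `healing_table()` |
| Phantoms | `phantom_spec()`, `generate_phantom()`, `phantom_benchmark()` |
| Pipeline / CLI | `pipeline_config()`, `run_pipeline()`, `cli_main()`, `inst/cli/octdamage` |

The methods vignette (`vignettes/damage-quantification.Rmd`) documents the
model, its assumptions, the tunable parameters and the design decisions in
detail.
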