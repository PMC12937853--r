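# wmcanet

Segmentation of the femoral **intercondylar notch** — the narrow (5–8 mm)
concave groove at the distal femur that houses the cruciate ligaments — is a
prerequisite for ACL-reconstruction planning, but the notch is tiny relative
to the ~50 mm femoral structure around it, its boundaries are blurred, and
nearby scar tissue can sit within a few percent of its MRI signal.
`wmcanet` is a tested, CPU-only R implementation of a **wavelet multi-scale
contextual attention network (WMCA-Net)** for this task, aimed at
researchers who want to study, extend, or ablate the architecture without
GPUs or access to clinical MRI data.

The network is a U-shaped encoder–decoder (residual-CNN or
windowed-transformer backbone) with four cooperating blocks:

* **SHFDEB** — dense separable-convolution extraction of high-frequency
  detail at the shallowest stage;
* **WSFB** — per-stage single-level orthonormal **Haar** split
  (LL/LH/HL/HH), soft-threshold denoising of the detail bands
  (`sign(v)·max(|v|−t, 0)`, `t = 0.05`), learnable high-frequency and
  low-frequency pathways, and 1×1 fusion;
* **MDCB** — parallel (kernels 3/5/7) and serial large-kernel (7, 9)
  depth-wise convolution blocks for multi-scale context;
* **CWAM** — decomposition of a saliency map `F_m` at threshold 0.5 into
  `m_f = max(F_m − 0.5, 0)`, `m_b = max(0.5 − F_m, 0)`,
  `m_u = 0.5 − |F_m − 0.5|`, uncertainty injection, and single-head scaled
  dot-product attention (row-softmax of `QᵀK/√d`) over spatial tokens.

Training uses the hybrid loss `α·Dice + β·Focal` (focal term
`−α_k (1−P)^γ log(P+ε)`, `γ = 2`, `ε = 1e−5`) with deep supervision, AdamW,
cosine annealing and early stopping on validation DSC; evaluation reports
DSC, IoU, HD95 (mm) and ASSD (mm). Because no deep-learning runtime is
assumed, gradients come from a compact reverse-mode autograd engine on
dense arrays with C++ convolution kernels — every building block is unit
tested against closed forms, finite differences, or brute-force oracles.

A seeded **phantom generator** produces synthetic knee slices (bright
femur disc, concave 5–8 mm notch with a/u/w-style contour templates,
osteophyte-like deformations in ~30% of samples, near-isointense
distractor tissue, boundary blur, noise) so the entire pipeline is
exercisable end to end from a fresh checkout.

## Worked example

```r
library(wmcanet)

cfg <- phantom_config()                      # 112 px at 0.5 mm/px, 50 mm femur
s   <- generate_notch_phantom(cfg, seed = 42)
g   <- measure_phantom(s)
# notch width: 6.0 mm | area fraction: 0.0651 | femur diameter: 50.0 mm | osteophyte: TRUE
```

The sample's notch is 6.0 mm wide (inside the 5–8 mm anatomical range),
covers 6.5% of the frame pixels (inside the 5–8% band clinical slices
show), the femur spans 50 mm, and this seed drew an osteophyte.

```r
b <- haar_decompose(matrix(c(1, 3, 2, 4), 2, 2))   # the block [[1,2],[3,4]]
c(b$ll, b$lh, b$hl, b$hh)
#  5 -2 -1  0
```

The orthonormal Haar convention is pinned by this worked example:
`haar_reconstruct(b)` inverts it exactly and energy is preserved.

```r
pred <- s$mask; pred[, 1:56] <- 0L           # degrade the left half
metric_report(pred, s$mask, spacing_mm = s$pixel_spacing_mm)
#  class       dsc       iou hd95_mm   assd_mm
#      1 0.8193642 0.6940024       2 0.7868409
```

Erasing the left half of the notch costs ~18 DSC points and moves the
95th-percentile boundary error to 2 mm — the boundary metrics are in
physical millimetres via the sample's pixel spacing.

Training end to end (the same call the test suite uses to overfit eight
64×64 phantoms to DSC > 0.95 in a few minutes on one CPU):

```r
pcfg    <- phantom_config(image_size_px = 64, pixel_spacing_mm = 1)
samples <- lapply(1:8, function(i) generate_notch_phantom(pcfg, i))
tcfg    <- train_config(network = network_config(input_size_px = 64),
                        lr_initial = 1e-3, batch_size = 4, max_epochs = 200,
                        seed = 1, augmentation = augment_config(enabled = FALSE),
                        target_val_dsc = 0.95)
fit <- train(tcfg, samples, samples)
predict_mask(fit$net, samples[[1]]$image)
```

`ablation_grid(network_config())` enumerates the six incremental module
configurations per backbone (baseline, +SHFDEB, +WSFB, +SHFDEB+WSFB,
+MDCB, +CWAM) for ablation studies. A thin CLI with `make-phantoms`,
`train`, `crossval`, `predict` and `evaluate` subcommands lives at
`inst/cli/wmca.R`.

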