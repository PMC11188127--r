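---
title: "faunet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{faunet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fluorescence microscopy trades signal for damage: raising laser power or
dwell time improves SNR but bleaches fluorophores and perturbs live
samples, so practitioners routinely acquire fast, photon-starved images.
Supervised denoisers learn the mapping from low-SNR to high-SNR
acquisitions from registered pairs, but classical CNN pipelines retrain
one model per experiment, which costs hours and tens of pairs each time.

faunet implements a convolutional transformer U-net whose attention
operates across the *frame* axis (Z depth or T time — the package treats
them identically), together with the two-stage scheme that makes it
practical: pretrain one backbone on pooled data, then fine-tune it on
5–10 pairs from a new experiment in minutes.

## The model

A batch tensor has axes `[B, C, F, H, W]`. The network is:

1. a pre-convolution lifting `C` to `base_channels` (default 32);
2. `n_down_levels` (default 2) encoder stages, each `cells_per_level`
   (default 4) transformer cells followed by a stride-2 convolution that
   halves H, W and doubles channels;
3. matching decoder stages: 2× nearest-neighbour upsample + conv halving
   channels, concatenation with the corresponding encoder output, a merge
   convolution, then `cells_per_level` cells;
4. a post-convolution back to `C`, and a long skip connection adding the
   network input to the output.

Each **cell** is a pre-norm transformer block built from convolutions:

- an input-projection conv sets the channel width `c`;
- attention sublayer: instance norm → three independent per-frame 2D
  convolutions produce K, Q, V → multi-head frame attention → an output
  projection conv → residual add;
- mixer sublayer: instance norm → conv (`c` → `mixer_expansion * c`) →
  GELU → conv back to `c` → residual add.

**Frame attention (pooled mode, the default).** For head `h` with
per-head width `d_h`, the score between frames `t` and `s` is

    score[t, s] = sum_{c in h, x, y} Q[c, t, x, y] K[c, s, x, y] / sqrt(d_h H W)

softmaxed over `s`; frame `t` of the output is the attention-weighted sum
of V frames. Each head keeps a single F × F matrix, so memory and compute
are linear in pixel count and quadratic only in the (short) frame axis —
this is the property that makes the architecture viable on
100 × 1200 × 1200-scale stacks, and it is asserted structurally in the
tests (the score tensor is F × F, never pixels × pixels). A `pixelwise`
mode (an F × F softmax at every pixel) is provided for study; it was not
selected as the default because its cost profile contradicts the
linear-in-pixels motivation.

### Design choices the source architecture leaves open

- **Score pooling.** How attention coefficients aggregate over a
  `[C, F, H, W]` tensor is not specified anywhere; we pool over channels
  and pixels per head (see above), with the pixelwise alternative behind
  `attention_mode`.
- **No positional encoding** across frames. The resulting
  frame-permutation equivariance of the whole network is elevated to a
  test (it also implies the model cannot exploit frame *order*, only
  cross-frame redundancy — the right prior for jittering/drifting
  structures).
- **Pre-norm residual layout.** "CNN attention, instance norm and CNN
  mixer" fixes the ingredients but not the order; we use the standard
  pre-norm transformer layout with residuals around both sublayers.
  Instance norm is computed per (sample, channel) jointly over (F, H, W).
- **Resampling.** Stride-2 conv down; nearest-neighbour ×2 + conv up with
  concat-and-merge. H, W not divisible by `2^n_down_levels` are
  reflect-padded internally and cropped back; frames are never resampled.
- **Identity initialization.** The post-conv is zero-initialized, so the
  untrained network is exactly the identity through the long skip. This
  stabilizes fine-tuning (the model can only improve on the input) and
  gives the test suite an exact fixed point to assert.

## Training

Both stages run the same loop: Adam (β = 0.9/0.999), global
gradient-norm clipping at 1.0, random aligned patch pairs (default
`(8, 128, 128)`; the desk-scale suite uses `(4, 32, 32)`), loss
`1.0 · MSE + 0.1 · (1 − SSIM3D)`. The source work discloses neither its
loss nor its optimizer; MSE anchors intensity fidelity and the SSIM term
rewards the structural restoration that evaluation measures.
Fine-tuning starts from the backbone weights, keeps *all* layers
trainable, and only reduces the learning rate (`lr_finetune`).

Normalization is per-stack percentile scaling (0.5 / 99.8, robust to hot
pixels), always fitted on the **low**-SNR member and applied to both, so
input statistics at inference — where no high-SNR image exists — match
training. At inference the map is applied without clipping so that it is
exactly invertible (an identity-initialized model therefore returns the
input bit-for-bit, which the tests assert through arbitrary tilings);
during training patches are clipped to [0, 1].

Learning rates: the `full-scale` preset keeps 1e-4 (backbone) and
2.5e-5 (fine-tune). The `smoke` preset — a ~70k-parameter model trained
for a few hundred steps, used throughout the test suite — uses 3e-3 and
1e-3: small models on short budgets need proportionally larger steps, and
these values were fixed from that reasoning, not tuned against the
acceptance thresholds.

Reproducibility: one master seed derives per-epoch/per-batch/per-phantom
sub-seeds through a 31-bit LCG fold (`derive_seed`), so runs are exactly
repeatable and extending a schedule never reshuffles earlier batches.

Inference tiles large stacks with overlapping spatial tiles (disjoint
frame chunks), feather-blends overlaps with linear ramps and divides by
the accumulated weight map, so blend weights sum to exactly 1 at every
voxel.

## The synthetic world

No real acquisitions ship with the package; the simulator generates what
the training scheme needs and nothing more:

- **Structure families.** `filaments` (smoothed random-walk curves,
  anti-aliased, drifting ~0.5 px/frame) stand in for the cytoskeletal
  structures of backbone datasets; `blobs` (Gaussian spots with per-frame
  jitter) for the islet/vesicle-like fine-tune domains; `tubes`
  (branching static networks) for tissue. Cross-domain transfer
  experiments train on filaments and fine-tune on blobs.
- **Noise.** Poisson shot noise at photon level α plus Gaussian read
  noise σ_r, averaged over `n_average` repeats — the standard
  fluorescence camera model. Defaults α = 15, σ_r = 1 give a measured
  single-shot input PSNR of ≈ 18–19 dB against the clean phantom — a
  realistic photon-starved operating point; the high-SNR member uses
  a 32-repeat average (the line-average analog). Real photon counts for
  the source datasets are not published; these values are configuration,
  not a claim.
- **Average series.** `make_average_series` draws N (conventionally 64)
  independent single-shot repeats of one field and returns running means,
  exactly the repeated-acquisition protocol used to probe robustness
  across input SNR. Member N doubles as the acquisition-style ground
  truth; the clean phantom is retained as an oracle reference that real
  data does not have.

What a green test does **not** establish: phantoms are piecewise-smooth,
single-channel, drift-registered and noise is spatially white — real
tissue autofluorescence, sCMOS fixed-pattern noise, optical PSF structure
and registration error are all absent. Results transfer as evidence that
the mechanism works, not as performance predictions for any instrument.

## Numerical choices

- SSIM3D uses a separable 3D Gaussian window (11 points, σ = 1.5,
  k1 = 0.01, k2 = 0.03, symmetric edge padding), clipped per axis to the
  largest odd size not exceeding that axis so short frame axes are legal;
  the training loss uses a 7-point window on patch-sized volumes. Both
  the metric and its analytic gradient are verified against brute-force
  voxel loops / central differences.
- PSNR returns an `Inf` sentinel at zero MSE. Metrics default to
  `data_range = 1` on the stacks' stored scale.
- Instance norm uses ε = 1e-5; GELU is exact (`x Φ(x)`).
- Degenerate inputs: constant stacks cannot be percentile-normalized and
  raise a classed error; uint16 TIFF export refuses out-of-range values
  rather than clipping silently.
- All backward passes are hand-derived and checked against central
  differences to ~1e-6 relative error (both attention modes), which is
  what makes the from-scratch R training engine trustworthy.

## Fast adaptation and robustness experiments

The package's central empirical claims, at desk scale:

- **Fast adaptation**: fine-tuning a filament-trained backbone on 5 blob
  pairs for 30 epochs matches or beats an identically budgeted model
  trained from scratch (mean over 3 seeds), and the fine-tuned validation
  loss does not exceed the backbone's zero-shot loss on the new domain.
- **Robustness across SNR**: following the repeated-acquisition protocol
  (training pairs are (Avg-n, Avg-64) members of one series, n spanning
  1..63), one fine-tuned model applied to Avg-n inputs for
  n ∈ {1,4,8,16,32,64} yields clean-referenced output PSNR that is
  non-decreasing in n (0.5 dB tolerance) and above the input PSNR for all
  n ≤ 32. Fine-tuning only at single-shot SNR would not (and should not)
  satisfy the Avg-32 bound — the protocol is part of the claim.

Both are asserted in `tests/testthat/test-acceptance.R` with the exact
budgets stated there.

## Known limitations

- **Tiled inference is only approximately consistent with whole-stack
  inference.** Instance norm and pooled frame attention both aggregate
  over the entire inference window, so the network is not shift-local:
  with a trained smoke-scale model, 32×32-tiled and full-stack passes
  differ by roughly 1e-2 mean absolute on the [0, 1] scale, uniformly
  across the field rather than at seams (feather blending makes the
  stitching itself exact, as the identity-model tests show). Users who
  need strict consistency should tile at the deployment size used
  during validation. The test suite keeps a deliberately failing
  assertion documenting the stricter 1e-3 aspiration.
- Pure-R training is ~3 orders of magnitude slower than a GPU stack; the
  defaults in the `full-scale` preset are faithful but impractical on a
  laptop CPU — the `smoke` preset is the supported desk-scale entry
  point.
- Only baseline uncompressed TIFF is read/written; proprietary formats
  (CZI, ND2, LIF) and OME-XML metadata are out of scope.
- Pairs are assumed pixel-registered; there is no registration step.
- Multi-channel models are supported in the architecture but the
  simulator emits single-channel phantoms; multi-stain stacks are
  processed channel-by-channel at inference.
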