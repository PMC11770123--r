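---
title: "Methods: cross-modal alignment and conditional diffusion for virtual H&E staining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal alignment and conditional diffusion for virtual H&E staining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intraoperative assessment of deep surgical margins in tongue squamous cell
carcinoma (TSCC) relies on frozen fresh sectioning and H&E staining — slow,
destructive, and error-prone. Raman hyperspectral imaging records a
vibrational "molecular fingerprint" spectrum at every spatial position of an
unstained cryosection in minutes, but its grayscale band images are not
readable by pathologists. `ramanstain` implements a pipeline that converts a
Raman cube into an H&E-style sub-image a pathologist could read: a
cross-modal alignment network ties Raman and H&E patch representations to a
shared latent vocabulary, and a conditional denoising-diffusion model
synthesizes H&E sub-images from conditioning vectors computed out of that
vocabulary.

## Data model and tiling

Inputs are RGB H&E images `[3, H, W]` with known micrometers per pixel and
Raman cubes `[bands, X, Y]` (full scale: 1340 bands over 600–3100 cm⁻¹ at
1 µm sampling, regions of 400 × 50 µm). H&E images are first brought to the
common physical sampling of 1 pixel per µm² by explicit per-axis bilinear
resizing (`resize_to_physical()`); the per-axis targets are explicit because
source scans need not share a single scale factor per axis.

Sub-images are extracted with an unfold-style sliding window
(`extract_subimages()`): 0-based half-open windows, row-major enumeration,
and floor semantics `floor((extent - window)/stride) + 1` per axis — the
remainder at the far edge is dropped. At full scale a `[3, 602, 490]` image
yields 11 × 8 = 88 sub-images with a 256-px window at stride 32, and
15 × 12 = 180 with a 128-px window. A Raman region maps to exactly one
sub-cube; only its last spatial axis is cropped (50 → 48 lines). The crop is
centered — dropping the first and last line — because any fixed choice is
equally consistent with the extraction counts; the offset is configurable.

## Encoders and the frozen H&E stack

Both modalities are encoded by an initial 3×3 convolution followed by two
downsampling blocks; each block is two residual units (groupNorm → SiLU →
conv, twice, with an additive shortcut) and a stride-2 convolution, so the
spatial extents halve twice: `[3,256,256] → [64,64,64]` and
`[1340,400,48] → [64,100,12]` at full scale. Group normalization uses 8
groups (the largest divisor of the channel width not exceeding 8 at toy
widths); the group count is a free choice as only the normalization family
is fixed by the architecture.

The H&E encoder is pretrained inside a mirror-image autoencoder
(`pretrain_autoencoder()`, MSE objective) and then frozen
(`freeze_encoder()`): during alignment training its parameters are treated
as constants, which the implementation guarantees structurally — frozen
subgraphs carry no backward closures, so no gradient exists that could move
them, and the test suite asserts bit-identical weights by fingerprint. The
Raman encoder is deliberately *not* pretrained or frozen; it trains end to
end with the alignment objective (pretraining it was found to hurt
classification at full scale). The pretraining duration is configuration
(`ae_steps`), as no stopping rule is fixed by the architecture.

## The alignment network

The encoded feature map is split ViT-style into non-overlapping `4×4`
patches (256 H&E / 75 Raman patches at full scale), flattened
(`d = 64·4·4 = 1024`) and linearly projected to 128 dimensions — one shared
projection per modality. A bank of seed vectors `seed[cls, k]` (dimension
64, independent-normal initialized) generates per-class targets in each
modality's latent space through a per-modality stack of three fully
connected layers (64 → 128) with layerNorm + SiLU between them:

    Target[M][cls, k] = FCs_M(seed[cls, k])

Because both stacks consume the *same* seed tensor, target index `(cls, k)`
names the same latent concept in both modalities — this is the whole
cross-modal alignment mechanism, and it is asserted structurally in the
tests. Classification is a similarity vote:

    dist[cls, i, k] = cos(Patch_i, Target[cls, k])
    logits[cls]     = sum_k w[cls, k] * sum_i exp(lambda * (1 + dist[cls, i, k]))

with `w` and `lambda` trainable nonnegative scalars — nonnegativity is
enforced by softplus reparameterization so the optimizer stays
unconstrained. `lambda` starts at `log 2 ≈ 0.6931` (softplus of 0). The
temperature maps similarities from `[-1, 1]` to `[0, 2·lambda]` and the
exponential amplifies the largest similarities along the patch axis before
the weighted sum over targets. The loss is cross-entropy against a
label-smoothed one-hot target, `(1 - s)·onehot + s/n_classes` with
`s = 0.15` — the standard smoothing convention, since only the mechanism and
value are fixed.

Open choices resolved here: `K` (targets per class) is not architecturally
fixed; the default is 16, and the desk-scale configurations use 4 — enough
vocabulary for separable toy problems. The weights `w` are per-modality (the
superscript-M notation suggests separate banks); `lambda` is one shared
scalar. Cosine norms are guarded at `1e-8`, so zero vectors never produce
NaN. Multi-task batching alternates H&E and Raman items within each epoch
and accumulates gradients across both, which realizes equal-weight loss
summation without a mixing hyperparameter; one AdamW update is applied per
`accum` samples (64 at full scale), so the update count is
`ceiling(samples_seen / accum)` regardless of batch geometry — the same
contract as distributed training with gradient accumulation. Early stopping
monitors validation loss with a patience threshold (300 epochs at full
scale) and the best-validation checkpoint is kept.

## Conditioning

At training time the diffusion model is conditioned on the K H&E targets of
the tile's own class, in order (`conditioning_for_training()`). At inference
the conditioning is computed from a Raman sub-image: its distance tensor is
sparsified by a two-step top-K rule (`compute_mask()`) — per (class, target)
fiber keep the `k_patch` largest entries along the patch axis, then per
patch keep the `k_clstarget` largest surviving entries along the combined
class/target axis — and each target index k receives a softmax-weighted
convex combination of the aligned H&E targets
(`synthesize_conditioning()`):

    cond[k] = sum_{cls,i} softmax_{cls,i}(score[cls, i, k]) * Target_HE[cls, k]

Three choices deserve note. First, the mask enters *additively*: surviving
entries keep their distance as the softmax score and masked entries score
`-Inf` (weight exactly 0). A literal product of `-Inf` with a negative
distance would flip its sign and promote the very entries the mask is meant
to remove; only the additive reading "filters out smaller values". Second,
the two k values are not architecturally fixed; the defaults are
`k_patch = 8` and `k_clstarget = K`, so for a two-class bank the weaker
class's targets are filtered out of the conditioning — with
`k_clstarget = n_classes·K` the conditioning would be a near-uniform blend
of both classes (cosine similarities live in a narrow numeric range, so an
unfiltered softmax is flat) and class identity would barely steer
generation. Third, the softmax uses the raw distances by default; an
optional temperature flag reproduces the temperature-modified reading, off
by default. Ties at the kth value resolve to the lowest index,
deterministically. A target index left with no survivors is an error naming
that index, not a silent NaN.

## Diffusion model

The generator is a conditional UNet trained as a standard DDPM: linear
variance schedule (`1e-4` to `0.02`), noise prediction, MSE loss, ancestral
sampling. None of schedule, step count, or sampler are fixed by the
architecture description, so the defaults follow the original DDPM
formulation as the least-surprising reading; `T = 1000` at full scale. The
desk-scale runs use a short, strong schedule (`T = 20`, variance ramp up to
0.45): with tiny images the class- and content-ambiguous high-noise regime
is exactly where the denoiser must rely on memory and conditioning, and a
short schedule concentrates training there instead of spending most draws
on timesteps whose prediction is trivial. Sampling uses the posterior-mean
parameterization with the implied clean-image estimate clamped to `[-1, 1]`
at every step (the standard stabilization for epsilon-parameterized
samplers; switchable off), and on a timestep subsequence the
alpha-bar-ratio generalization of the ancestral update, which reduces
exactly to DDPM when every step is used. The reverse chain is verified in
the tests against the closed-form oracle denoiser of a point-mass data
distribution, which it must (and does) invert exactly.

The UNet halves the extent at each of its levels (5 at full scale on
`[3,128,128]`, reaching 4×4 at the bottleneck) and mirrors them with
nearest-neighbour-upsample + convolution blocks joined by skip
concatenation. Self- and cross-attention run only where the extent is at
most 16 pixels — at full scale that is the 16- and 8-px levels plus the
bottleneck — and the conditioning enters as the K×128 context of every
cross-attention layer. Attention output projections are zero-initialized,
so every attention block starts as the identity and its contribution is
learned from zero — without this, randomly-initialized cross-attention
injects context noise that slows conditioning learning badly at desk scale.
Timestep information enters as a sinusoidal embedding passed through a
two-layer MLP and applied scale-shift style (AdaGN) at the second group
normalization of each residual block: `h * (1 + scale(t)) + shift(t)`, with
zero-initialized modulation projections. The multiplicative path matters —
epsilon prediction requires timestep-dependent *gains* (the optimal
denoiser rescales its input by schedule-dependent factors), which a
shift-only injection cannot express and which dominated the remaining error
in desk-scale memorization runs. Images are scaled to `[-1, 1]` internally;
PNG export rescales to 8 bits.

Training draws one uniform timestep per tile per epoch, accumulates
gradients over `accum` tiles per AdamW update, writes periodic checkpoints
every 25 epochs (full scale: 1000 epochs), and keeps the best-validation
parameters when a validation set is supplied (validation MSE at a fixed
spread of timesteps and fixed noise seeds, so the monitor is deterministic
given the parameters).

## The synthetic phantom generator

Real paired data are patient material and are not redistributable, so the
package ships a generator of co-registered phantoms
(`generate_sample()`, `generate_dataset()`) that emulates exactly the
structure the pipeline needs: one latent element placement drawn per sample
and rendered into *both* modalities — class-dependent RGB texture (irregular
high-chroma blobs and ring structures for the carcinoma class, echoing
pleomorphic cells and keratin pearls; parallel striations with peripheral
dots for normal muscle) and a class-dependent spectral signature in the cube
(smooth Gaussian-bump band profiles peaking in disjoint regions, amplified
1.45× under planted elements). Additive Gaussian noise, clipped to [0, 1],
is the only noise model. Defaults: 64 bands (1340 reproduces full-scale
shapes but adds nothing to the mathematics), 32 µm canvas at 1 µm/px, 6
elements, noise SD 0.02 — values chosen once as a plausible desk-scale
miniature of the real geometry.

What the phantoms do *not* emulate: Raman physics (peak broadening,
autofluorescence baselines), stain variability, histological morphology
beyond the planted vocabulary, or inter-patient heterogeneity. Tests passing
on phantoms therefore demonstrate that the *mechanisms* — alignment,
masking, conditioning, generation — work as specified, not that the trained
toy models would transfer to tissue.

Splits are assigned at the sample (patient) level, mirroring the
train/validation versus later-registered-patient test design, and the split
allocator errors out rather than silently producing an empty requested
split.

## Desk-scale study conditions

The test suite and the acceptance script run the full stack at reduced
geometry chosen once: 16×16 px phantoms with 6 bands, encoder width 8,
K = 4, patch 4 (one patch per image — the smallest geometry that exercises
every code path); alignment training 10 epochs at learning rate 2e-3 with
accumulation 8. The diffusion memorization run uses 8×8 px images, one UNet
level, base width 12, T = 20 (variance ramp to 0.45) and 3500 steps at
2e-3; the class-conditional closure run uses 4×4 px tiles, base width 16
and 500 epochs — at that size the per-channel noise mean is large enough
that the noised image alone does not betray the class, so the training
gradient genuinely rewards reading the cross-attention context. The
full-scale optimizer settings (AdamW, lr 1e-5, decay 1e-5, effective batch
64) remain the configuration defaults; the toy runs override the rate
because a desk-scale problem trained for minutes needs a proportionally
larger step size, not because the defaults are wrong at full scale.

In the conditional-closure study the two phantom classes carry orthogonal
spectral signatures (disjoint band blocks) and class-constant H&E colors.
With the default mask sizes (`k_patch = 8`, `k_clstarget = K`) the
surviving conditioning entries then concentrate their softmax mass entirely
on the true class, so the inference-time conditioning coincides with the
training-time class targets — the property the planted-color statistic
measures. When an alignment model is too weak to rank targets
class-coherently, some target index can be left without surviving entries;
that raises the documented error, and the closure runs score such a failed
generation as a miss rather than widening the mask.

## Known limitations

* Pure-R execution: the autodiff engine is exact (finite-difference-checked)
  but not fast; full-scale geometry is supported by the shape arithmetic and
  the code paths, not by desk-scale compute budgets.
* Single-head attention; multi-head adds capacity, not new structure.
* The diffusion sampler is ancestral only; no DDIM-style deterministic
  sampler beyond the subsequence generalization.
* The region-majority diagnosis rule scores "uncertain" calls as
  non-agreement; the alternative (excluding them) is configurable but not
  the default.
* Whole-slide stitching of generated sub-images is out of scope.
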