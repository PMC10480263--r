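---
title: "Repairing partial CBCT: simulation, model and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repairing partial CBCT: simulation, model and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiotherapy patients are positioned for each treatment fraction by
registering an on-couch cone-beam CT (CBCT) to the planning CT. Setup
CBCT has two weaknesses: the kV imager's limited field of view truncates
the patient cross-section whenever the target is lateralised, and
scatter in the cone-beam geometry produces streak artifacts. Both
degrade registration accuracy. `cbctrepair` implements a complete,
desk-scale experimental pipeline around a learned remedy: conditional
adversarial image translation that removes streaks and imputes the
anatomy missing outside the field of view, refined per patient by
transfer learning.

Two study designs are supported. The *synthetic study* manufactures
partial, streaked CBCT slices from CT and trains a two-model cascade
(streak removal, then anatomy imputation). The *clinical-style study*
trains a single base model on preprocessed CT/CBCT pairs from a cohort
and then produces patient-specific variants by retraining only the
final generator layers.

## Synthetic CBCT simulation

`simulate_scbct_slice()` composes five stages, each separately exposed
and separately tested:

1. **Elastic deformation.** Random displacements, uniform in
   `[-deform_max_disp, +deform_max_disp]` px, are drawn on a coarse
   grid (`deform_grid_spacing` px apart), interpolated bilinearly to
   pixel resolution and used to warp the slice. The deformed image is a
   plausible "inconsistent" version of the anatomy.
2. **Forward projection.** Both the original and the deformed slice are
   radon-transformed (parallel beam, `n_angles` angles over
   `[0°, 180°)`, unit detector spacing, bilinear sampling along rays).
   Intensities are shifted by `attenuation_offset` (+1024 HU) first so
   that air contributes approximately zero attenuation — line integrals
   of negative HU values have no physical meaning.
3. **Partial sinogram replacement.** A fraction
   `f ~ Uniform(0, max_replace_fraction)` is drawn per image
   (`max_replace_fraction` defaults to 0.10), and `round(f * N)` entry
   positions are chosen uniformly without replacement and copied from
   the deformed sinogram into the original. The projection data are now
   mutually inconsistent, which is precisely what produces streaks
   after reconstruction. Replacement is entry-wise; a view-wise variant
   can be emulated by mixing rows manually. Note that the *measured*
   fraction of entries whose value changed is at most the drawn
   fraction, because rays that miss the deformed region carry identical
   values in both sinograms.
4. **Filtered back-projection.** Ram-Lak (ramp) filtering in the
   frequency domain, linear interpolation during backprojection, the
   attenuation offset removed and the result clamped to
   `[-1024, 3071]` HU. On a 128 px phantom with 90 angles the
   round-trip error of this reconstruction is about 36 HU (mean
   absolute error over the body interior); the test suite asserts a
   calibrated 60 HU tolerance.
5. **Field-of-view truncation.** An isocentre is rejection-sampled
   uniformly over the body mask (pixels above -500 HU, largest
   connected component) until at least `min_outside_fraction` (5%) of
   body pixels lie farther than `fov_radius` from it — i.e. until the
   simulated acquisition genuinely truncates the patient. All pixels
   beyond `fov_radius` are then assigned stored intensity 0, with no
   recentring and no cropping, emulating a partial acquisition already
   registered to the CT grid.

The streak-removal ground truth is the original CT under the *same*
FOV mask; the imputation ground truth is the original CT in full.

**Masked value semantics.** The FOV exterior is stored as 0, not
-1024 HU. Through the intensity normalisation (below), stored 0 maps to
about -0.5 on the network's `[-1, 1]` scale — a flat level distinct
from air — so the network can distinguish "outside the field of view"
from "air". This follows the printed convention of assigning zero; the
alternative (treating masked pixels as air) is a one-line change at the
call site of `apply_fov_mask()`.

Key parameters (defaults at the clinical 512 px scale, scaled
proportionally by `desk_sim_params()`):

| parameter | default | unit | note |
|---|---|---|---|
| `max_replace_fraction` | 0.10 | — | upper bound of the per-image uniform draw |
| `fov_radius` | 128 | px | 512 px scale; a quarter of the grid at desk scale |
| `n_angles` | 180 | — | 90 at desk scale; reconstruction quality, not fidelity, limits this |
| `deform_grid_spacing` | 64 | px | coarse field = smooth, large-scale distortion |
| `deform_max_disp` | 15 | px | visible but anatomically plausible warp |
| `min_outside_fraction` | 0.05 | — | isocentre acceptance rule |
| `attenuation_offset` | 1024 | HU | air maps to ~0 before projection |

The projection-angle count, filter, deformation magnitude and the
entry-wise reading of "random replacement of sinogram values" are
choices this package makes explicitly (all configurable); the headline
constants — the 10% bound and the 128 px radius — are fixed by the
methodology being implemented.

## The thorax phantom

`make_thorax_phantom()` rasterises analytic structures: an outer body
ellipse with a fat rim, a soft-tissue interior, two lung ellipses, bone
sites (spine, sternum, eight ribs) and a full-width couch slab 10 px
thick (at 512 px scale) whose top edge sits at `couch_row`. HU levels
are exact (air -1000, lung -750, fat -90, soft tissue +40, couch +100,
bone +700), with no edge anti-aliasing by default, so analytic masks
are usable as exact test oracles. `make_cohort()` draws one set of
per-structure jitter factors per patient (uniform within ±5% of each
size/position parameter by default) plus a bounded per-slice random
drift (steps of a fifth of the jitter), giving distinct patients and
smooth intra-patient variation. Interior structures move and scale with
the body so jitter cannot break containment.

What the phantom does *not* emulate: CT noise, beam hardening, scatter
physics, true 3-D cone-beam geometry (everything is slice-wise
parallel-beam), realistic organ texture, or clothing and immobilisation
devices visible in real planning CTs. Passing tests therefore
demonstrate that the pipeline's mechanics are correct and that the
models learn the intended mapping on controlled anatomy — not that the
clinical image quality figures of any particular dataset are
reproduced. The clinical headline numbers (e.g. volume SSIM near unity
against real NSCLC data) depend on that data and are out of scope here.

## Clinical-style preprocessing

`build_training_pairs()` applies, per slice: zero padding of the CBCT
onto the target grid (`pad_to_grid()`), rigid registration of the CT
onto the padded CBCT, and couch removal from the target.

- **Registration** (`register_ct_to_cbct()`) optimises rotation,
  translation and isotropic scale (the "resize") by Nelder-Mead over a
  Pearson-correlation metric computed *only* on the nonzero
  (field-of-view) region of the CBCT, with multi-resolution refinement
  (4x, 2x, 1x). Restricting the metric to the FOV prevents the zero
  padding from biasing the alignment. On phantom fixtures, 20 random
  perturbations up to ±5° and ±10 px are recovered with sub-half-pixel
  median error. A 2-D slice-wise model was chosen because pairing is
  index-aligned after the slice-thickness equality check; full 6-DOF
  volumetric registration is out of scope.
- **Couch removal** assigns -1024 HU to every pixel *below* the couch
  surface row, where "below" means larger row index (posterior in
  supine, head-first display orientation). `detect_couch_surface()`
  finds the first row below the body whose above-air run spans at least
  60% of the width, with a configurable fallback. Couch removal happens
  after registration, following the preprocessing flow this package
  mirrors; removing it from the target keeps the model from
  hallucinating a couch.
- For pairs constructed programmatically on a shared grid (the phantom
  studies), registration can be switched off (`register = FALSE`); it
  is still exercised and acceptance-tested on known perturbations.

## The conditional adversarial model

`pix2pix()` trains a U-shaped generator against a patch discriminator.
The generator is built as an explicit flattened layer sequence: image
input; eight encoder stages of 4x4 stride-2 convolution, batch
normalisation (from stage 2) and leaky ReLU (slope 0.2); eight decoder
stages of 4x4 stride-2 transposed convolution, batch normalisation,
dropout (rate 0.5, first four stages), leaky ReLU and a depth
concatenation with the mirrored encoder activation; and a terminal 3x3
convolution. At full depth this listing has exactly 61 entries, and
`generator_layer_kinds()` exposes it for conformance checking. Every
decoder stage ends in a concatenation; the outermost stage, whose
output is at full resolution, concatenates the network input itself —
the only shape-consistent reading, and a useful one, since it hands the
final convolution direct access to the input image.

Choices the architecture description leaves open, and what this package
does:

- **Loss and optimiser.** Generator loss = conditional adversarial
  (binary cross-entropy against a sigmoid patch discriminator) plus
  `l1_weight = 100` times the mean absolute error on the normalised
  scale; Adam with learning rate 2e-4, momentum 0.5; batch size 1.
  These are the canonical translation-network defaults and the only
  defensible reconstruction.
- **Output activation.** `tanh`, matching the `[-1, 1]` intensity
  normalisation (`normalize_hu()` maps `[-1024, 3071]` HU affinely onto
  `[-1, 1]`). A linear-output switch exists on `generator_spec()`.
- **Batch-1 normalisation.** With batch size 1, batch normalisation
  reduces to per-channel normalisation over the spatial dimensions. The
  same statistics are used in training and inference (no running
  averages), the convention of the reference translation network; it
  also makes inference deterministic.
- **Discriminator.** 4x4 convolutions of stride 2, 2, 2, 1, 1 on the
  channel-concatenated (condition, candidate) pair, batch normalisation
  and leaky ReLU between, yielding a grid of patch logits with a 70 px
  receptive field per output unit.
- **Scale profiles.** The clinical profile is 512 px input, 64 base
  filters, depth 8 (bottleneck 2x2). `desk_generator_spec()` reduces
  this to 32-128 px inputs with 16 base filters and a depth that keeps
  the bottleneck at 2x2 — a 1x1 bottleneck would zero the normalised
  activation and stall the gradient through the innermost stage.

All stochastic elements — initialisation (N(0, 0.02)), data order,
dropout — consume the R random stream seeded from the training
configuration, so runs are bit-reproducible single-threaded
(`layer_checksums()` verifies this in the tests).

The backward passes of every layer are hand-verified against central
finite differences in the test suite; this is the load-bearing
correctness evidence for the training loop.

## Patient-specific transfer learning

`transfer_learn()` clones the base model, freezes all generator
parameters except the last `n_trainable_param_layers` *parameterised*
layers in topological order, and continues adversarial training on the
target patient's pairs with a fresh optimiser. "Final two layers" is
interpreted as the final two weight-bearing layers — the last decoder
batch normalisation and the terminal convolution — because activation
and concatenation layers carry no weights that could be retrained. The
patch discriminator continues to adapt during the transfer run (the
freeze applies to the generator network); the base model object is
never modified, and the frozen layers come out bit-identical, which
the acceptance tests assert checksum by checksum.

One CBCT set yields "patient-specific model 1", two sets "model 2";
`make_patient_specific()` wires this to the preprocessing chain and
guards the base cohort against patient leakage.

## Evaluation

`ssim_slice()` implements SSIM with a Gaussian window (11x11, sigma
1.5), constants K1 = 0.01, K2 = 0.03, and a *fixed* `data_range` of
4095 — the full HU span — rather than per-image ranges, which would
make values incomparable across slices. The SSIM map is averaged over
fully valid windows. By default metrics are computed over the full
frame including any shared zero exterior (which inflates similarity
when input and truth share large padded backgrounds — the reason
volume-level SSIM against clinical data can sit near unity even for
visibly incomplete images); a `mask` argument computes body-only
variants instead. `mae_slice()` is the mean absolute error in HU.
`evaluate_volume()` aggregates per-slice values into the mean and
sample standard deviation (n - 1) across the testing volume, and
`compare_reports()` renders the comparison table (volume label, SSIM,
SD, MAE, SD). `difference_map()` is truth minus output, rendered on a
symmetric diverging scale about 0 HU.

## Problem sizes used by the tests

The package's own desk profile, chosen once: 32 px slices for training
runs (3-4 patients x 2-4 slices, 10-60 epochs; the transfer-trend
check uses 50 base epochs and 40 transfer epochs over three seeds) and
128 px slices with 90 projection angles for simulator geometry,
reconstruction and registration checks. At these sizes the full suite
runs in a few minutes on one CPU while every mechanism — including a
complete base + transfer + evaluation study — is exercised end to end.
The same code paths scale to the 512 px clinical profile unchanged.

## Known limitations

- Streak structure from entry-wise sinogram replacement is statistically
  plausible but not a physical scatter model; no beam hardening, metal
  or motion artifacts.
- Training-mode generator L1 retains a floor (active dropout plus the
  adversarial term), so "near-zero" overfitting is asserted as an
  order-of-magnitude drop and a small inference-mode error, not as an
  exact zero.
- Registration is 2-D rigid + isotropic scale; out-of-plane motion and
  deformation are not modelled.
- DICOM series I/O is not provided; volumes move through NIfTI.
- CPU-only: the clinical 512 px / 500-epoch regime is supported by the
  code but is a multi-day computation, as adversarial training at that
  scale always is.
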