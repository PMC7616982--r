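---
title: "Pseudo-CT synthesis and transcranial ultrasound evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-CT synthesis and transcranial ultrasound evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Treatment-planning simulations for transcranial ultrasound stimulation
(TUS) need a map of the skull's acoustic properties, conventionally
derived from an x-ray CT of the head. For healthy-volunteer
neuroscience studies a CT is hard to justify, so a *pseudo-CT* (pCT) in
Hounsfield units (HU) is synthesised from MR images instead. `skullpct`
implements three pCT routes and the downstream acoustic evaluation
chain:

* **cCT** — a classical conversion from a zero-echo-time (ZTE) bone
  image: soft-tissue-peak normalisation, skull segmentation by a fixed
  intensity band, and a calibrated linear map to HU;
* **zCT** — a slice-stack U-Net regression from ZTE to HU;
* **tCT** — the same network from a T1-weighted image, in which bone is
  signal-poor.

The evaluation chain converts a (p)CT into medium property maps,
simulates the continuous-wave field of a 4-element annular array at
500 kHz, and compares image-space errors (MAE/RMSE) and focal metrics
(peak pressure, peak position, −6 dB focal volume) against the
ground-truth CT pipeline.

Because no clinical paired MR/CT cohort is distributed with the
package, a synthetic head-phantom generator provides paired
CT/ZTE/T1w volumes with known masks, so every stage is runnable and
testable at desk scale.

## Classical ZTE conversion

A bias-corrected ZTE volume is divided by the mode of its masked
intensity histogram (a kernel-density argmax over the head), putting
soft tissue at intensity 1. The skull mask is the largest 26-connected
component of voxels in the bone band $[0.2, 0.75]$, with enclosed
intra-bone holes filled and a radius-1 closing. Within the mask,

$$\mathrm{CT} = -2085\,\mathrm{ZTE} + 2329 \quad [\mathrm{HU}],$$

with soft tissue at 42 HU inside the head and air at −1000 HU outside;
values driven below −1000 HU are clamped to the physical floor of the
HU scale. The calibration line is fitted by total least squares — the
first principal component of the joint (ZTE, CT) density within the
skull — so it is symmetric in the two modalities, unlike ordinary
regression (`calibrate_linear_pca()`); pooled calibration is the
default and per-subject calibration is available via
`classical_pct(..., calibrate_with = )`.

One deliberate deviation from a convention sometimes used here:
slice-wise 2D hole filling is *not* applied to the skull mask. Every
transverse slice through the cranial vault shows the skull as a closed
ring whose in-plane "hole" is the brain, so 2D filling would absorb
the cranial cavity into bone. Filling is therefore restricted to
enclosed 3D cavities smaller than a quarter of the bone-mask volume
(intra-bone holes), followed by the closing.

## The learned mapping

The network is a 5-level U-Net over stacks of `n = 11` consecutive
transverse MR slices; the output is the single centre slice in HU.
Encoder levels use two (levels 1–2) or three (levels 3–5) 3×3
zero-padded convolutions, each followed by ReLU then batch
normalisation (in that written order), 2×2/stride-2 max pooling
between levels, and skip connections on levels 1–4. The decoder
mirrors the encoder with 2×2/stride-2 transposed convolutions followed
by dropout (probability 0.1 for T1w, 0 for ZTE; decoder side only). A
final 1×1 convolution maps 64 features to HU. Channel widths double
per encoder level except the deepest (64, 128, 256, 512, 512).

Training minimises the masked L1 loss
$$L(\theta) = \frac{1}{|\Omega_T|}\sum_{i\in\Omega_T}
  \frac{1}{N_i}\,\lVert m_i \odot (y_i - f_\theta(x_i))\rVert_1,$$
where $N_i$ is the number of pixels in the image (not the mask
cardinality — implemented literally), with Adam, mini-batches of 32,
reduce-on-plateau scheduling (patience 5, factor 0.2) from $10^{-4}$
down to $10^{-6}$, and per-sample affine augmentation (rotations
±10°, translations ±5 % of the image size, x-parallel shears ±2.5°,
bilinear resampling, masks re-binarised). Edge stacks replicate the
nearest valid slice. Validation loss is masked, computed per epoch.

All layers (convolution via per-sample im2col with BLAS matrix
products in C++, max-pool, transposed convolution, batch
normalisation, dropout, Adam) are implemented in the package; forward
and backward passes are verified against finite differences in the
test suite.

**Miniature schedule.** The tested default is a 2-level, 8-channel
network on 64² slices with a 3-slice stack. A few choices differ from
the full schedule and exist because the full one is tuned for roughly
$10^5$ optimisation steps while the miniature budget is a few hundred:
the learning rate is $10^{-2}$, batches of 16, augmentation off, and
the final convolution carries a fixed output scale of 1000 so the HU
dynamic range is reachable from unit-scale batch-normalised features.
None of this changes the model class, only the optimisation scale.

**Batch-norm recalibration.** Batches of heterogeneous transverse
slices have strongly batch-dependent feature statistics, so running
averages accumulated during training misrepresent evaluation-time
normalisation (the classic small-batch train/eval gap). After the last
epoch, `train_unet()` makes one pass over the training set and resets
each layer's running mean/variance to the exact average of the
per-batch statistics, which closes most of that gap.

## Acoustic property maps

CT-like volumes are segmented into background, skin, brain and skull:
skull is HU > 300 within the head (the threshold is configurable),
closed with radius 1; brain is the soft tissue enclosed by the skull
(flood fill from the grid border); skin is the remaining head tissue.
Within the skull, mass density follows a monotone piecewise-linear
HU→density curve through standard tissue anchors — air 1.2 kg/m³ at
−1000 HU, fat ≈ 930 at −98, soft tissue ≈ 1030 at 14, ≈ 1119 at 120,
cranial bone ≈ 1975 at 1600 and 2800 at 3000 HU — and sound speed
follows the linear skull relationship $c = 1.33\rho + 167$ (m/s,
kg/m³). Skull attenuation is a single constant, 8 dB/MHz/cm by
default; soft tissue and background default to water-like reference
values ($c = 1500$ m/s, $\rho = 1000$ kg/m³, lossless). All reference
values are explicit, configurable assumptions (`medium_reference()`).

## Wave solvers

Three field predictors are provided:

* `oneil_axial_bowl()` — the closed-form on-axis solution for a solid
  spherical-cap source, used as the analytic oracle; the removable
  singularity at the geometric focus is evaluated by its limit.
* `rayleigh_pressure()` / `free_field_focus()` — a Rayleigh–Sommerfeld
  summation over a deterministic ring sampling of the curved annular
  array (grid-free source description; ≥ 6 surface points per
  wavelength; rings use an even azimuthal count so the sampling is
  mirror-symmetric). Element outer apertures are the nominal 32.8, 46,
  55.9 and 64 mm on a 63.2 mm radius of curvature; only outer
  apertures are printed for the device, so the inner edge of each
  element sits a configurable 0.5 mm kerf beyond its inner
  neighbour. All elements are driven in phase (the device focus is the
  centre of curvature; no steering is modelled).
* `cw_steady_state_2d()` — the internal heterogeneous solver: the
  first-order acoustic equations on a 2D slice, advanced by a k-space
  pseudospectral time-domain scheme (Fourier derivatives on staggered
  grids with the $\mathrm{sinc}(c_{\mathrm{ref}}k\Delta t/2)$ temporal
  correction), split-field PML on all sides, driven by a ramped
  sinusoid until the per-point amplitude changes by less than
  $10^{-3}$ between successive cycles, then demodulated at the drive
  frequency. Defaults are 6 points per wavelength in water and 60
  points per period; time steps violating the k-space stability limit
  raise an error. Injected sources are band-limited by an isotropic
  radial cosine roll-off in k-space (grid-delta sources would otherwise
  pump a spatial-Nyquist checkerboard response). A second-order
  finite-difference scheme at 6 PPW
  would accumulate several percent of anisotropic phase error over the
  ~21 wavelengths from the transducer to the focus; the k-space scheme
  is dispersion-free in the reference medium, which the tests verify
  against a 2D Green's-function summation (≤ 2 % amplitude error).

The full 3D heterogeneous solve is deliberately out of scope: the
mapping claims, not the solver, are the scientific content, and the 2D
slice through the beam axis supports the relative CT-vs-pCT
comparisons. For 3D work, `run_simulation(backend = "external")`
writes an exchange bundle (medium maps as NIfTI, source point samples
as CSV with positions/normals/phases/weights, grid spec as JSON) and
re-imports an externally computed field; a missing backend is an
explicit error, never a silent fallback.

Simulation windows are cropped to the beam path (aperture plus a
12 mm lateral margin, bowl apex to 30 mm beyond the focus) so each 2D
solve stays around 200×200 cells at the 0.5 mm simulation spacing.

## Focal metrics

The focal peak is the arg-max amplitude cell within the brain mask
(optional quadratic sub-cell refinement, off by default); the −6 dB
focal volume is the measure of in-mask cells with amplitude at least
half the peak — a threshold on pressure amplitude, not intensity. On
2D slices the same definitions yield an area; comparisons are always
like-for-like. Comparison records report
$|\mathrm{test}-\mathrm{ref}|/\mathrm{ref}\times 100$ for pressure and
volume and the Euclidean shift in mm for position; summaries use the
sample (n−1) standard deviation.

## The phantom generator

Phantoms are concentric ellipsoids: skin surface (default semi-axes
70×90×80 mm), outer skull table 5 mm deeper, and an inner table a
further 6 mm (±2 mm smooth directional modulation peaking
posteriorly, emulating the occipital protuberance that makes visual
targets harder than motor ones). The through-thickness HU profile
peaks at the cortical tables (1700 HU) and dips to the diploe
(900 HU); a smooth seeded modulation (±12 %) adds subject-specific
mineral-density structure. Those numbers are modelling choices with
two constraints: the full modulated range must stay inside
[765, 1912] HU, the interval the classical conversion's fixed
[0.2, 0.75] ZTE band maps to under the printed line (a real subject
outside that band is exactly the failure mode that excluded one
cohort subject from the classical route), and the modulation must be
information that ZTE carries and T1w does not — without it, bone HU
would be a deterministic function of geometry and a T1w-trained
network could recover it from shape alone, which real T1w cannot.

The ZTE image is synthesised by inverting the printed linear mapping
in bone (so the classical round trip is exact at zero noise), soft
tissue near 1, air near 0; the T1w image has structured soft tissue
and dark bone uncorrelated with HU. Additive Gaussian noise per
modality (defaults: 20 HU CT, 0.015 ZTE, 0.03 T1w) supports
SD-recovery tests; an optional multiplicative low-order bias field
(mean exactly 1 over the head, bounded peak deviation) emulates the
artefact that bias-field correction removes in real data.

What the phantoms do *not* emulate: real anatomy (facial bones,
foramina, sinuses), CT beam-hardening and dental artefacts,
registration error between modalities, and MR sequence-specific
contrast. Passing phantom tests therefore demonstrates correctness of
the implementations and the internal consistency of the chain, not
clinical performance.

## Problem sizes and numerical choices

Tests and experiments run at deliberate desk scales, chosen once:
2 mm phantom grids (~100 voxels per axis) for cohort experiments, 3 mm
64×64×56 phantoms for network training, a 0.5 mm simulation grid
(6 PPW at 500 kHz in water) for the acceptance-level acoustic
comparisons and 1 mm (3 PPW) for coarse cohort smoke tests.
Midway histogram equalisation uses 1024 uniform quantiles with linear
interpolation. Head masks use a global Otsu threshold (separating air
from head) followed by enclosed-cavity filling, largest component,
radius-2 closing and a final fill. Connectivity is 26-neighbour for
bone components and 6-neighbour for flood fills. Seeds parameterise
every stochastic step; identical seeds give bit-identical phantoms,
training runs and fields.

## Known limitations

* The internal solver is 2D; out-of-plane focusing and aberration are
  not captured, so absolute focal metrics differ from 3D values even
  though paired CT-vs-pCT differences are meaningful.
* The HU→density curve is a published-anchor reconstruction of the
  conventional piecewise-linear conversion; its exact breakpoints are
  locked by regression tests but are an assumption, as are the
  soft-tissue reference properties and the constant skull attenuation.
* The learned route is demonstrated at miniature scale; the full
  11-slice, 64-channel configuration is implemented and
  parameter-count-verified but not trained in the test suite.
* Phantom soft tissue is homogeneous (42 HU); image metrics over the
  head are therefore easier than on real data.
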