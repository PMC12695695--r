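---
title: "Dual-input synthetic CT for adaptive proton therapy: models, phantom and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-input synthetic CT for adaptive proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adaptive proton therapy (APT) for head tumors needs an up-to-date CT-quality
volume at every fraction: proton dose deposition is governed by the stopping
power ratio (SPR) of tissue, conventionally derived from CT Hounsfield units
(HU), and small anatomical changes shift the Bragg peak. The in-room
cone-beam CT (CBCT) acquired for patient setup is available daily but its HU
are inaccurate (shading/cupping, scatter, reduced field of view, lower
effective resolution), so it cannot feed dose calculation directly. A
conditional GAN can translate CBCT into a synthetic CT (sCT); the hypothesis
this package operationalizes is that adding the planning T1-weighted MRI as
a second input channel recovers the soft-tissue detail (ventricles, eyes,
optic nerves) that CBCT lacks, and that this improves both HU fidelity and
proton-range accuracy.

`dualsct` implements the full chain — multimodal head-phantom simulation,
NIfTI preprocessing, ResUnet/SwinUnet generators with a patch critic,
Pix2Pix and CycleGAN training regimes, masked image/delineation metrics,
HU-to-SPR conversion and a straight-ray proton range engine — sized so the
whole study runs on one CPU.

## The synthetic phantom: what it emulates, and what it does not

No clinical data ship with the package. `generateLabelVolume()` paints a
head ellipsoid with a skull shell, brain, paired lateral ventricles, eyes
with lenses, optic nerves and a nasal air cavity — exactly the structures
whose recovery the evaluation probes. `renderCT()` assigns mean HU per
tissue (air −1000, soft tissue 40, bone 1000, brain 35, CSF 10, eye 30,
lens 80, optic nerve 40 — configurable package defaults, not measured
calibrations) plus Gaussian noise (default 5 HU, a realistic head-protocol
level), clipped to the working HU range [−1024, 3072].

`simulateCBCT()` degrades the CT with the failure modes that make CBCT
dose calculation unreliable: per-tissue affine HU corruption whose defaults
collapse the 25 HU brain/ventricle contrast (both near 20 HU), a radially
increasing cupping field, noise (15 HU), a resolution blur applied *after*
the noise (CBCT texture is smoother than CT — this ordering is what an MAE
training target preserves and an adversarial critic can detect), and a
cylindrical field-of-view truncation to −1024. The bone bias default is
deliberately small (−20 HU): T1-MRI is nearly signal-free in bone, so bone
correction must come from the CBCT values themselves, and the package keeps
the MRI's role where the underlying hypothesis places it — soft tissue.

`simulateT1Mri()` renders T1 contrast (bone and air near zero, CSF darker
than brain parenchyma) with a smooth multiplicative bias field (max/min
ratio bounded by `(1+a)/(1-a)`) and noise. The decisive property, asserted
by tests, is that the MRI's brain/ventricle contrast-to-noise far exceeds
the CBCT's.

`simulateCohort()` and `makeDataset()` emulate a fractionated course: one
planning MRI per patient, reused across that patient's weekly CT/CBCT
triplets, which receive small per-triplet anatomical jitter. Inter-patient
variability is larger, and deliberately largest for the ventricles (size
jitter ×3, position spread of several mm): ventricular geometry is the most
variable brain feature across subjects and the one that changes during
treatment. Without that variability a CBCT-only network could localize
ventricles from position priors alone, which would void the premise that
imaging evidence is required. The per-triplet jitter leaves the ventricle
boost off so the planning MRI stays anatomically faithful within a patient.

What the phantom does **not** model: projection-domain physics (scatter,
beam hardening, FDK artifacts), realistic MRI sequences, anatomy beyond
ellipsoids/capsules, and pediatric/adult differences. Passing tests
therefore demonstrate that the algorithms behave as designed under
controlled conditions, not that clinical-grade image quality is achieved.

## Preprocessing

Following standard practice, CT and CBCT are clipped to [−1024, 3072] HU
and min-max normalized to [−1, 1] against those fixed bounds
(`clipHU()`, `normalizeMinMax()`); the MRI is normalized per volume (T1
intensities have no fixed window). `resampleRigid()` maps CBCT/MRI into CT
space through a rigid transform with trilinear or nearest sampling
(fill −1024 for HU, 0 otherwise). `splitPatients()` partitions at the
patient level — never slices or triplets — with validation/test sizes
floored and the remainder assigned to training, so 27 patients at
(0.75, 0.10, 0.15) give 21/2/4. Training consumes axial slices in batches
of 3 with the channel order fixed as CBCT first, MRI second.

## Networks and training

Both generators map `(H, W, inChannels)` slices in [−1, 1] to a CT slice
bounded by a saturating tanh output. The ResUnet is an encoder–decoder with
residual blocks and skip concatenation; the SwinUnet replaces them with
windowed multi-head self-attention blocks (alternating plain and shifted
windows, pre-norm MLPs) on top of convolutional patch embedding/merging.
Published block internals for the reference architectures are not available,
so standard pre-activation residual blocks and standard Swin blocks (without
relative position bias or the shifted-window attention mask — at desk-scale
window counts the cyclic-shift leakage is negligible) are used, with depths
and widths configurable; `clinicalScaleConfig()` reproduces the full-scale
widths `[64,128,256,512,1024]` (ResUnet) and `[128,256,512,1024,2048]` with
heads `[8,16,32,32,32]` (SwinUnet). Exact parameter-count equality with the
full-scale models is a reporting goal, not an assertion.

Two architecture choices matter at desk scale and are this package's own:

* **Global residual.** The output is
  `tanh(atanh(clip(cbct)) + correction)`, with a zero-initialized output
  convolution, so an untrained generator reproduces the CBCT exactly and
  training learns corrections. Without it, the few hundred optimization
  steps of a CPU run are spent recovering from random-init output.
  `generatorConfig(residual = FALSE)` restores the plain behavior.
* **Desk learning rates.** The clinical protocol (Adam, generator 1e-4,
  discriminator 1e-6, batch 3, 100 epochs, generator pre-training) is the
  `trainConfig()` default. The desk-scale experiment harness uses
  generator 1e-3 while preserving the protocol's 100× generator/critic
  asymmetry (critic 1e-5): 1e-4 is matched to ~1e5-step training runs,
  whereas the desk runs last a few hundred steps.

Losses: the autoencoder regime minimizes MAE (`pretrainGenerator()`, also
the warm-up for adversarial training); Pix2Pix adds a sigmoid
binary-cross-entropy adversarial term against a patch critic on
(condition, candidate) stacks, weighted 1 : λ_L1 with λ_L1 = 100; CycleGAN
(CBCT↔CT, no MRI, unpaired shuffling) uses adversarial terms both ways plus
λ_cycle = 10 cycle-consistency. The λ defaults follow the canonical
formulations the architectures derive from and are exposed in
`lossWeights()`. Model selection keeps the checkpoint with the best
validation masked MAE (last epoch when no validation set exists).
Everything runs on a small reverse-mode autodiff tape with compiled
convolution kernels; training is bit-deterministic given the seed.

### The collapse demonstration

Adversarial training without the protocol's fix — a randomly initialized
plain generator and the critic trained at the generator's rate — lets the
critic separate real from fake almost immediately (fakes start as garbage)
and its loss races toward zero, while the generator's adversarial loss
explodes; `collapseExperiment()` reproduces this and shows the fix
(pre-training, i.e. starting from the CBCT baseline, plus the 1e-6 critic
rate) keeps the critic loss near ln 2. Note that the global-residual
architecture is itself a form of built-in pre-training, which is why the
no-fix arm uses the plain variant.

## Evaluation

Image metrics are computed strictly inside masks (never background):
`maskedMAE()` (HU), `maskedPSNR()` (dB, data range 4096 HU, the clipped
dynamic range), and `maskedSSIM()` (3D, uniform 7³ window, k₁ = 0.01,
k₂ = 0.03 — the dimensionality/window are package conventions since none is
universal, all configurable). Delineation overlap uses `diceCoefficient()`
(both-empty defined as 1) and `hausdorffDistance()` (exact surface-to-surface
maximum by default, HD95 selectable; distances in mm via the voxel spacing).
`pairedModelComparison()` is a two-sided paired Wilcoxon signed-rank test
with the exact permutation distribution for n ≤ 25 (midranks for ties,
zeros discarded). HU error maps and fixed-bin difference histograms
(50 HU bins over ±1000, clamped into the outer bins so counts are
conserved) cover region-wise analyses such as skull and nasal cavities.

## Proton range engine

The package deliberately replaces a clinical dose engine with an analytic
model: `huToSpr()` applies a piecewise-linear HU→SPR calibration (the
shipped default is a small synthetic table anchored at air ≈ 0.001,
water = 1.0 at 0 HU, dense bone ≈ 1.6; any two-column CSV can be
substituted), `weplProfile()` accumulates water-equivalent path length by
midpoint sampling along straight rays, and `braggCurve()` is an
asymmetric-Gaussian depth-dose whose distal 80% crossing sits exactly at
the configured water range, with all widths proportional to it (so range
scales exactly with energy, and uniform SPR scaling by s rescales range by
1/s). Beam energy is specified directly as R80-in-water because no beam
data library is available. There is no scatter, no lateral spread, no
nuclear halo: distal-R80 *geometry* is faithful under straight-ray physics,
absolute dose is not, and DVHs produced by `doseVolumeFromBeam()` are
mechanism demonstrations.

A beam (`beamSpec()`) is a lateral monoenergetic field of 80–100 mm sampled
by 1×1 mm beamlets on a 1 mm dose grid with 2.5 mm delivery spot spacing.
`computeR80Map()` extracts per-beamlet distal R80 as the *last* downward
80% crossing beyond the peak, linearly interpolated between samples —
robust to local noise; beamlets whose falloff leaves the volume are masked,
never silently zeroed. `r80DifferenceHistogram()` normalizes R80
differences to the water range (1 mm at 100 mm water = 1%) with 0.1%-wide
bins over ±5% and reports mean, SD and the fraction within ±1%.

## Desk-scale study conditions and what the experiments show

`mriBenefitExperiment()` fixes one cohort (3 patients × 2 triplets,
64×64×16 voxels at 4 mm, anatomy seed 42), holds the last patient out
entirely, and for each of five fixed training seeds trains a CBCT-only and
a CBCT+MRI Pix2Pix model (2 MAE warm-up epochs + 3 adversarial epochs,
batch 3, ~100k-parameter ResUnets) plus an equal-budget MAE autoencoder.
It reports held-out ventricle-mask MAE for both Pix2Pix models and the
mean absolute Laplacian (a sharpness surrogate) of autoencoder versus
Pix2Pix sCTs. The directional claims — MRI lowers ventricle error;
adversarial training yields sharper output than pure MAE — are asserted in
4 or more of the 5 replicates. These are scaled-down analogues: clinical
effect sizes are not reproducible from phantoms, and the experiments show
mechanism, not clinical performance. Problem sizes were chosen so the full
suite runs in minutes on one CPU.

## Numerical conventions and degenerate inputs

* Voxel indexing is 0-based in world-coordinate math; world axes are RAS;
  `world = origin + orientation %*% (index * spacing)`, all mm.
* Normalization uses fixed HU bounds for CT/CBCT and per-volume bounds for
  MRI; `hi == lo` is a degenerate-range error.
* `maskedPSNR()` returns `Inf` for identical inputs; empty masks are
  errors everywhere rather than silent zeros.
* Histogram values outside the configured range are clamped into the outer
  bins so totals equal mask counts.
* The signed-rank test discards zero differences and reports a degenerate
  result when all differences are zero.
* Dose lines that never drop below 80% of their peak inside the volume are
  invalid; `computeR80Map()` errors only when *no* beamlet is valid.
* Training aborts on non-finite losses, restoring the last good checkpoint.

## Known limitations

The phantom's geometric anatomy and intensity tables are stylized; CBCT
degradation is image-domain, not projection-domain; the SwinUnet omits
relative position bias and attention masks; the range engine ignores
lateral transport; and the desk-scale GAN runs are far from convergence, so
quantitative metrics from `mriBenefitExperiment()` measure relative model
behavior under identical budgets, nothing more. In particular, while the
MRI-benefit direction replicates across independent seed panels, the
sharpness contrast between the adversarial and MAE arms is small (fractions
of a percent of the Laplacian magnitude) and sensitive to the training
seed; at clinical training scale the MAE arm smooths far more visibly.
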