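---
title: "Quantitative T2* reconstruction of the moving fetal body: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T2* reconstruction of the moving fetal body: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fetalt2star` reconstructs quantitative T2* maps of the fetal body from
low-field (0.55T) multi-echo dynamic gradient-echo MRI. This vignette is the
package's account of its science: the signal and acquisition models, the
estimation procedures and their assumptions, the tunable parameters, and
what the synthetic validation does and does not establish.

## The signal model

Magnitude gradient-echo signal decays mono-exponentially with echo time,

S(TE) = S0 · exp(−TE / T2*),

with S0 the proton-density-weighted amplitude and T2* the effective
transverse relaxation time, an indirect marker of blood oxygenation. At
0.55T, fetal body T2* values are long (lungs of the order of 200–300 ms),
so three echoes at 46/120/194 ms sample the decay well. Each *dynamic* is
one complete whole-uterus stack (3.125 × 3.125 × 3 mm voxels), repeated
15–30 times; the fetus moves freely between (and sometimes within)
dynamics.

## Pipeline

1. **Motion QC** (`motion_qc`): each dynamic's first-echo stack is scored by
   normalized cross-correlation (NCC) against the voxelwise median stack;
   dynamics below a threshold (default 0.8) are excluded, and the
   best-scoring dynamic is always retained. This is an automated surrogate
   for a visual review of motion-corrupted dynamics; it is a documented
   stand-in, not a reconstruction of an expert's judgement, and the
   threshold is exposed.
2. **MP-PCA denoising** (`mppca_denoise`): sliding 5×5×5 patches are
   decomposed as voxels × measurements matrices (measurements = flattened
   dynamic × echo pairs); eigenvalues within the Marchenko–Pastur noise bulk
   are nulled. The bulk is identified by the crossing of two noise-level
   estimators (the mean of the candidate bulk vs. the MP-edge-implied level
   `(λ_max − λ_min)/(4√γ)`), ties resolved by discarding. Patches are
   uncentered; overlapping reconstructions are averaged uniformly. The
   per-patch noise level and retained component count are returned as maps.
3. **Voxel-wise T2* fitting** (`fit_t2star_map`): a log-linear least-squares
   fit weighted by the squared signal (the standard variance stabilization
   for log-transformed magnitude data) initializes a damped Gauss–Newton
   refinement of (log S0, 1/T2*). Fits are classified failed when any input
   signal is non-positive (code 1), the estimate leaves (0, 1000] ms
   (code 2; fits are never clamped), or the refinement stalls without
   converging (code 3). The 1000 ms cap sits far above the fetal range at
   this field strength. With two echoes the fit is the closed form and the
   goodness-of-fit is defined as 1.
4. **Slice-to-volume reconstruction** (`reconstruct`): the second echo (the
   best organ contrast) is reconstructed into a 1.2 mm isotropic volume;
   see below.
5. **Quantitative propagation** (`propagate_channel`): the recovered slice
   transforms and deformable fields are frozen and applied to the
   per-dynamic T2* maps, which are combined by the same super-resolution
   inversion without re-estimating anything. Failed-fit voxels carry zero
   weight in the data term. Per-dynamic T2* maps are computed *before*
   reconstruction and propagated, never re-fit from reconstructed echoes.
6. **Organ statistics and growth curves** (`organ_stats`, `growth_curve`,
   `cohort_curves`): per-organ means, medians, SDs and volumes over valid
   voxels, the two-standard-deviation reconstruction-equivalence check, and
   ordinary least-squares T2*-against-GA fits summarized by the signed
   coefficient of determination `sign(slope)·R²`.

## The slice acquisition model and its inversion

An acquired slice sample at in-plane position p of slice k is modeled as

y = ∫ PSF(u) · V(T(p + u)) du,

with V the high-resolution volume, T the slice's rigid world transform and
PSF an anisotropic Gaussian whose through-plane FWHM equals the slice
thickness (3 mm) and whose in-plane FWHM is 1.2× the in-plane voxel size —
the standard slice-profile assumption of the super-resolution
reconstruction literature. The integral is evaluated by tensor-product
Gauss–Hermite quadrature (3 nodes per axis in reconstruction, 5 in the
simulator so that recovery experiments do not invert the exact quadrature
they were generated with), with trilinear interpolation of V under the
quadrature. Weights are normalized per sample, so a constant volume maps to
a constant slice and samples with less than half their PSF mass in support
are flagged rather than attenuated. Linear interpolation (not cubic) is
used throughout: the Gaussian quadrature already low-passes beyond the
cubic-vs-linear difference, and it keeps the innermost loop affordable on
one CPU.

**Rigid stage.** Registration maximizes NCC between simulated and observed
slices by Nelder–Mead with deterministic seeded multi-starts and incumbent
restarts (6-dimensional simplexes collapse prematurely without them). Two
engineering choices matter:

- The first registration target is built from a *single reference dynamic*
  (the one closest to the voxelwise median stack). A consensus volume of
  still-unaligned stacks is geometrically inconsistent and was measured (on
  phantom ground truth) to bias the first round by several degrees; a
  single stack is rigid-consistent by construction.
- The second round re-registers each dynamic's stack to the
  *leave-one-out* volume rebuilt from the other dynamics: registering a
  stack to a volume containing its own data reinforces that stack's current
  (possibly wrong) transform, and the leave-one-out target removes this
  self-consistency bias (measured to cut the worst per-dynamic rotation
  errors by more than half). Rounds beyond the second refine per slice.
- Per-slice refinement is tethered to the dynamic's stack-level transform
  by a small quadratic prior (`slice_prior`, default 5e-4 per squared
  degree/mm). Out-of-plane rotation of a single 2D slice is weakly
  determined; the tether encodes that within-dynamic motion is close to
  rigid while still letting well-supported slices deviate.

Registration itself uses a delta PSF on a stride-2 sample grid — the
target volume is already smooth, so the quadrature only costs time there —
while the super-resolution steps use the full PSF. Slices with too little
support are flagged excluded; after the final round, slices with NCC below
`exclude_ncc` (default 0.5) are excluded from the data term (never emptying
the slice set).

**Super-resolution stage.** The volume solves a regularized least-squares
problem: data term from all non-excluded slices through the PSF forward
model, plus an edge-preserving first-difference penalty with Huber-type
IRLS weights `1/sqrt(1 + (d/δ)²)` (δ = 0.05 of the robust intensity
scale). The normal equations are solved by conjugate gradient with a fixed
small budget (8 steps × 3 outer IRLS iterations): the inversion is
semi-convergent, and early stopping is part of the regularization. The
final volume is produced by a cold-start solve with exactly the budget used
by `propagate_channel`, which makes propagating the registration channel
reproduce the primary reconstruction identically — the intended
self-consistency of multi-channel propagation. The regularization weight is
0.02 for intermediate iterations and 0.015 for the final one, expressed
relative to a unit-normalized data term; intensity matching (per-slice
scale) and robust slice-outlier statistics exist but are off by default,
matching the intended protocol (slice scale fixed at 1). An optional
damping toward the PSF-weighted interpolation estimate (`sr_damping`) is
available but defaults to 0 — on the phantom it blurred small-organ
quantitative accuracy more than it suppressed ringing.

**Deformable stage.** Rather than a variational free-form-deformation
optimizer, the refinement estimates a smooth per-dynamic displacement field
by coarse-to-fine local block matching between each observed stack and its
resimulation, at control-point spacings of 12 then 5 mm. Matches require
real block structure (SD ≥ 10% of the body-signal SD), raw NCC ≥ 0.6, and
survive a median ± 4·MAD outlier rejection; a small shift penalty prefers
the zero displacement, and lattice nodes without genuine block support stay
at the identity. Displacements are smoothed onto the control-point lattice
by confidence-weighted normalized convolution and capped (default 10 mm).
Each dynamic's field is accepted only if it reduces that dynamic's
resimulation residual by at least 2%; purely rigid dynamics therefore keep
the identity field. This design satisfies the operational contracts of a
deformable stage (near-zero fields on rigid data, residual reduction under
true smooth bending, two pyramid levels) at a cost compatible with a single
CPU.

## The digital phantom

`make_phantom` builds a piecewise-constant digital fetus: a uniform body
envelope (T2* 60 ms) containing ten non-overlapping ellipsoidal organs
(lungs, thymus, gall bladder, kidney pelvis, kidney parenchyma, spleen,
adrenal gland, stomach, bladder, liver), with all sizes scaling
monotonically with gestational age (GA 17–40 weeks) and organ T2* drawn
from a per-organ linear GA model plus seeded subject-level noise. The
default model places lung T2* near 180 ms at 17 weeks rising by 5 ms/week
— consistent with the low-field regime — with increasing trends in lungs
and liver, decreasing trends in the kidney compartments, and weak trends
elsewhere; these numbers are configuration with the right orders of
magnitude and directions, not fitted normative curves. The default grid is
64³ voxels of 2 mm, i.e. a 128 mm field of view: organs must stay several
acquisition voxels wide for interior statistics to exist at 3 mm
resolution, which bounds how far the simulation can be scaled down.

`simulate_acquisition` applies per-dynamic rigid motion (a seeded random
walk capped at 10°/10 mm by default, the first dynamic at the identity),
evaluates the mono-exponential signal, integrates it through the
acquisition PSF onto the 3.125 × 3.125 × 3 mm grid, and applies Rician
noise (magnitude data; Rayleigh in the background). The phantom
deliberately omits texture, B0/B1 inhomogeneity, flow, and maternal
anatomy beyond the envelope: passing its recovery tests demonstrates the
correctness and stability of the estimation machinery, not performance on
clinical data.

## Validation design and what the numbers mean

- *Transform recovery* is measured modulo the global gauge freedom of
  slice-to-volume reconstruction: per-dynamic gauge estimates
  `G_d = T_d⁻¹ M_d⁻¹` are averaged and the spread around the mean gauge is
  the error. On the default 64³/8-dynamic noiseless phantom the median
  error is ≈ 0.5° and ≈ 0.3 mm.
- *In-organ error* means pooled relative residuals over organ interiors
  (masks eroded by ~3 recon voxels, the PSF depth); boundary voxels are
  partial-volume mixtures for any method at this organ-to-voxel ratio.
- *Mean preservation* mirrors a reconstruction-validation design in which
  the organ mean from the reconstructed volume must lie within two sample
  standard deviations (n−1 denominator; closed interval) of the
  per-dynamic organ means. The reconstruction-side mean is computed
  symmetrically with the per-dynamic means: the propagated T2* volume is
  PSF-projected back into each dynamic's frame through the recovered
  transforms and sampled with the identical eroded lung masks. Direct
  interior sampling on the 1.2 mm grid instead measures the (real, scale-
  dependent) partial-volume bias of small phantom organs on top of the
  question actually being asked — whether reconstruction *alters* the mean.
- *Relaxometry accuracy*: the Gauss–Newton fitter is exact on noiseless
  decays and attains the Cramér–Rao bound under noise. That bound is worth
  stating: for three echoes at 46/120/194 ms and first-echo SNR 20, the
  best possible median relative T2* error is ≈ 8% at T2* 74–150 ms, rising
  to ≈ 13% at 300 ms. Median errors below 5% require first-echo SNR ≈ 35
  or more echoes; no estimator can beat this at SNR 20.
- *Growth curves*: ordinary least squares per organ; the signed R²
  reproduces the convention of quoting decreasing organs with negative
  values (an alternative reading of such negative values as Pearson r is
  possible; signed R² is the shipped definition). Slope recovery is tested
  across 20 seeded cohorts of 30 subjects against the generative model.

Problem sizes in the test-suite and acceptance runs are chosen for a
single-CPU desk-scale budget: the reconstruction oracle uses one 64³
subject with 8 dynamics; the mean-preservation cohort uses ten 48³
subjects with 5 dynamics, stack-level registration (the simulated motion is
per-dynamic rigid) and stride-2 denoising. The interpretation of the
external reconstruction parameters is documented and isolated behind
`recon_config`: the final-iteration value 0.015 is read as the
super-resolution regularization weight of the last iteration, and the
control-point pair [12, 5] as millimetre spacings of the two coarse-to-fine
deformable levels.

## Known limitations

- The phantom is piecewise constant and rigid-by-dynamic; per-slice jitter
  is supported but textureless anatomy makes slice-level refinement easier
  than in vivo.
- Quantitative propagation combines T2* values that were themselves fitted
  from PSF-blurred signals; near boundaries the mono-exponential fit of a
  partial-volume mixture is not the mixture of the fits, so sub-voxel
  accuracy at organ boundaries is not claimed anywhere.
- No atlas-space reorientation is shipped (no fetal atlas is distributed);
  reconstructions live in a frame defined by the data, with the gauge
  handled explicitly in validation.
- Rician bias correction after denoising, multi-compartment decay models,
  and B0-inhomogeneity correction are out of scope.

## Worked example

```{r example}
library(fetalt2star)

ph <- make_phantom(ga = 30, seed = 2)
series <- simulate_acquisition(ph, acquisition_protocol(n_dynamics = 6),
                               random_motion_trace(6, seed = 2),
                               noise_sigma = 4, seed = 2)
cfg <- pipeline_config(protocol = series$protocol,
                       recon = recon_config(rounds = 2))
res <- run_pipeline(cfg, series, labels = ph$labels, out_dir = "run01")
res$organ_stats
```
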