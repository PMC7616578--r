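# fetalt2star

Quantitative T2* mapping of the fetal body from low-field (0.55T)
multi-echo dynamic MRI, with motion-robust 3D reconstruction.

## The problem

Fetal body T2* is an indirect marker of blood oxygenation, and many organs
(lungs, liver, kidneys, spleen) change T2* over gestation. Low-field
scanners make fetal T2* mapping attractive — longer T2*, fewer
susceptibility artefacts, wider bore — but the acquisitions that tolerate
fetal motion are stacks of thick 2D slices (3.125 × 3.125 × 3 mm), repeated
as 15–30 *dynamics* while the fetus moves. Turning those into organ-wise
quantitative numbers requires denoising, voxel-wise relaxometry, motion
correction, and a resolution-recovering 3D reconstruction, plus statistics
that exclude failed fits.

`fetalt2star` is an R implementation of that pipeline for researchers in
quantitative fetal MRI:

- **Motion QC**: automated exclusion of motion-corrupted dynamics by
  normalized cross-correlation against the median stack.
- **MP-PCA denoising**: patch-wise PCA with the noise bulk identified by
  the Marchenko–Pastur eigenvalue distribution.
- **Relaxometry**: voxel-wise mono-exponential fitting
  `S(TE) = S0 · exp(−TE/T2*)` (log-linear initialization, Gauss–Newton
  refinement, explicit failure taxonomy, 1000 ms cap).
- **Deformable slice-to-volume reconstruction**: per-slice rigid
  registration by NCC, PSF-based super-resolution onto a 1.2 mm isotropic
  grid (edge-preserving regularization, final-iteration weight 0.015,
  intensity matching and robust slice statistics off by default,
  deformable refinement with 12/5 mm control-point spacings), and
  propagation of the frozen transforms to the per-dynamic T2* maps to form
  a 3D quantitative volume.
- **Analysis**: organ statistics with failed-voxel exclusion, the
  two-standard-deviation reconstruction equivalence check, Dice overlap,
  and gestational-age growth curves summarized by signed R².
- **A digital moving-fetus phantom**: ten GA-scaled ellipsoidal organs with
  GA-linear T2*, rigid motion traces and Rician noise, so every stage can
  be validated against exact ground truth without scan data.

## Worked example

```r
library(fetalt2star)

# a digital fetus at 30 weeks and its dynamic multi-echo acquisition
ph <- make_phantom(ga = 30, seed = 2)
series <- simulate_acquisition(ph, acquisition_protocol(n_dynamics = 3),
                               noise_sigma = 4, seed = 2)

# voxel-wise mono-exponential T2* fit of the first dynamic
map <- fit_t2star_map(series, dynamic = 1)

# organ statistics against the phantom's own labels (interior sampling)
st <- organ_stats(map, ph$labels, erode = 1)
print(st[st$organ %in% c("lungs", "liver", "stomach"),
         c("organ", "mean_t2s", "sd_t2s", "valid_voxels", "volume_mm3")],
      row.names = FALSE, digits = 4)
#>    organ mean_t2s sd_t2s valid_voxels volume_mm3
#>    lungs    246.8  41.87          136      10078
#>  stomach    190.0  44.96            6       1260
#>    liver    151.5  21.56           67       5977
cat("ground truth:", round(ph$organ_t2s[c("lungs", "liver", "stomach")], 1))
#> ground truth: 243.8 151.6 200.8

# the two-standard-deviation reconstruction equivalence check
eq <- equivalence_check(c(196.9, 191.7, 194.2, 197.5, 190.3, 196.1,
                          193.0, 195.8, 191.1, 193.9), 189.07)
print(eq)
#> mean 194.05, 2-sigma range 189.0 - 199.1, reconstruction 189.07: equal (within 2 SD)
```

The per-organ means track the phantom's ground truth where organ interiors
outsize the acquisition voxels (lungs, liver); the small stomach is
partial-volume limited at 3 mm resolution, which is exactly why the
pipeline reconstructs before quantifying. The full pipeline — QC, denoise,
fit, reconstruct, propagate, statistics — runs via `run_pipeline()` (or
`fetalt2s run-all`), and `run_simulation_suite()` repeats it over a
synthetic cohort, producing an equivalence table and growth curves.

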