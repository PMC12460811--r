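# strain4d

4-D myocardial strain mapping for embryonic zebrafish hearts.

## The problem

A beating embryonic zebrafish heart (2–3 beats/s) is imaged by
spinning-disk microscopy one z-plane at a time: the raw data are one 2-D
fluorescence movie per z position, each starting at an arbitrary cardiac
phase. `strain4d` turns such nongated acquisitions into quantitative maps
of myocardial deformation:

1. **Retrospective synchronization** — per-slice heart-period estimation
   (autocorrelation of the integrated intensity, refined to sub-frame
   precision) and binning into K = 10 cardiac phases from systole to
   diastole, producing a 3-D volume per phase.
2. **Segmentation & meshing** — rolling-ball background removal, Otsu +
   morphology segmentation of the myocardial shell at the minimum-volume
   (systolic) reference phase, iso-surface triangulation, and
   connectivity-based separation of the epicardial and endocardial
   surfaces.
3. **Cyclic registration** — a deformable motion model, cubic B-splines
   in space × a truncated Fourier basis in cardiac phase, fitted to all
   phase volumes at once; the displacement field is exactly periodic and
   vanishes at the reference phase by construction.
4. **Strain mapping** — per-element area strain
   `ε_area,j(t) = sqrt(A_j(t) / A_j(0))` on the morphed surface meshes,
   with regional mean-strain and strain-variation (population SD) curves,
   plus trabecular-ridge metrics: radial/circumferential ridge
   shortening, transmural thickening, and compact-layer circumferential
   strain.

Because raw acquisitions of this kind are rarely shareable, the package
includes a **synthetic beating-heart phantom** — a contracting
quasi-spherical myocardial shell with radial and circumferential
trabecular ridges, a closed-form periodic deformation field, material
fluorescence texture and Poisson–Gaussian camera noise — whose analytic
ground truth (displacements, per-element strain, ridge lengths, labels,
periods, phase offsets) validates every pipeline stage.

## Worked example

```r
library(strain4d)

# a phantom beating at 90 bpm imaged at 30 Hz, SNR ~ 10,
# homogeneous peak strain 1.10
spec <- phantom_spec(seed = 12, radial_ampl_epi = 0.10,
                     radial_ampl_endo = 0.10, ridge_shortening = NA,
                     ridge_thickening = 0)
ph <- build_phantom(spec)

# full pipeline: synchronize -> segment -> mesh -> register -> strain
rep <- run_pipeline(pipeline_config(movie = ph$movie, seed = 12))
print(rep$cycle)
subset(rep$summary, phase == 5)
```

```
cardiac_cycle_set: K = 10 phases, 40 slices (33 gated), period 0.667 s
excluded from gating:
  z003: aperiodic
  z037: aperiodic
  ...
 phase surface     n mean_strain   sd_strain
     5     epi 30312    1.092411 0.008971804
     5    endo 12760    1.093103 0.004527053
```

The endocardial mean area strain at end-diastole (phase 5) comes out as
1.093 against an analytic truth of 1.095 for this phantom — the strain at
the diastolic phase-bin centre relative to the systolic reference bin,
recovered with a bias of -0.002. The strain variation (SD across
elements) is small because the prescribed deformation is spatially
homogeneous. Slices outside the heart carry no periodic signal and are
excluded from gating automatically.

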