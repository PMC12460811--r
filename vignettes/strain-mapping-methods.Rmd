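---
title: "4-D myocardial strain mapping: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{4-D myocardial strain mapping: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strain4d)
```

## The problem

The embryonic zebrafish ventricle beats several times per second while a
spinning-disk microscope can only image one z-plane at a time. An
acquisition therefore consists of one 2-D movie per z position, each
starting at an arbitrary, unknown cardiac phase. To measure myocardial
deformation in 4-D, the pipeline must (i) reconstruct a 3-D + phase
dataset retrospectively, (ii) segment and mesh the myocardial wall at a
reference phase, (iii) track the wall through the cycle with a motion
model, and (iv) convert the tracked surfaces into strain measures at the
whole-ventricle and trabecular-ridge scales. `strain4d` implements that
chain, and ships a synthetic beating-heart phantom whose deformation is
known in closed form, so that every stage can be validated quantitatively
without any raw microscopy data.

## Retrospective synchronization

Each slice movie's cardiac period is the first autocorrelation peak of
its spatially integrated intensity, corrected for the finite-length taper
of the autocorrelation estimate and refined to sub-frame precision by
parabolic interpolation (`estimate_period()`). Frames are then assigned
to `K` phase bins (default `K = 10`, systole to diastole) by
`floor(K * ((t - t0) mod T) / T)`. The anchor `t0` marks phase 0 at the
minimum of the kernel-smoothed folded intensity profile — the systole
proxy, since a smaller heart presents less fluorescent wall area in every
plane. An explicit `t0` can be supplied where an automated anchor is not
wanted. `reconstruct_4d()` averages the frames of each bin (averaging is
the maximum-likelihood combination under Poisson noise), stacks slices
along z, and refines the relative phase of adjacent slices by cyclic
correlation, chaining outward from the most strongly modulated slice.
Slices that are aperiodic or whose period deviates more than 10% from the
median are excluded from gating and filled with their time average, and
are reported in the reconstruction log.

Accuracy at the study's acquisition protocol (300 frames per slice at
30 Hz): the period is recovered to well under half a frame at
shell signal-to-noise ratio (SNR) near 10, at least 95% of frames land in
their true phase bin, and the noise-free reconstruction differs from
directly rendered in-phase volumes by less than 1% of the dynamic range.
These are asserted by the test suite and recomputed by
`scripts/acceptance.R`.

## Segmentation and meshing

Background is removed per z-plane with the classic rolling-ball
background (grayscale opening with a disc; the radius must exceed the
largest genuine structure — the default of 40 px clears the polar caps of
the ventricle, which are wide discs in en-face planes). The myocardium at
the reference (minimum-volume) phase is segmented by a global Otsu
threshold, 3-D morphological closing, largest connected component, and
filling of internal cavities smaller than 2% of the foreground — the
ventricular lumen, a much larger cavity, is deliberately left open so the
wall remains a shell. A threshold-separability check rejects volumes
whose histogram carries no foreground/background structure. Manually
edited label volumes can be supplied in place of the automatic result
(`label_volume()`).

The labelled shell is converted to a triangulated surface by marching
tetrahedra on the Gaussian-smoothed label field at iso-level 0.5 (six
tetrahedra per cell with consistent face diagonals, giving a watertight
mesh), with vertices in physical micrometres. The two connected
components of a closed shell are separated by graph connectivity; the
component with the larger bounding-box diagonal is the epicardium.
Sampling regions mimic a clipping-plane selection: epicardial elements
are selected by a half-space, and endocardial elements within a distance
band of the selected epicardial elements, so the two surfaces' regions
overlap spatially.

## The cyclic motion model

Deformable registration uses a displacement field

    u(x, k) = sum_g B_g(x) * sum_h [ c_g,h^cos (cos(2 pi h (k - r)/K) - 1)
                                   + c_g,h^sin  sin(2 pi h (k - r)/K) ]

— a tensor-product cubic B-spline control lattice in space multiplied by
a truncated Fourier basis over cardiac phase. Every temporal basis
function vanishes at the reference phase `r`, so `u(x, r) = 0`
identically, and the field is exactly periodic over the cycle by
construction; no drift term exists because single-cycle phase-binned data
have no drift axis. Fitting minimises an image-dissimilarity metric
between each phase volume warped by `u` and the reference volume
(the forward direction: `u` maps reference positions to phase positions,
so the reference mesh can be displaced directly), plus a bending-energy
penalty `lambda` on second differences of the control lattice.

Defaults and rationale:

* metric: normalized cross-correlation (`"ncc"`); `"ssd"` is available
  and preferred for same-modality phantom data. Both use analytic
  gradients (the exact gradient of the trilinear interpolant — a numerical
  gradient over ~10^4 coefficients would be both inexact and infeasible);
* harmonics `H = 2`: cardiac motion is low-harmonic, and `K = 10` phase
  samples support at most `H = 4` (Nyquist);
* control spacing 8 voxels, two coarse-to-fine levels, `lambda = 0.01`,
  L-BFGS with a fixed iteration cap for determinism;
* reference phase: the minimum-foreground (systolic) volume, selected
  automatically; a config override accepts an explicit index;
* a fold-over check (positivity of det(I + grad u)) is evaluated on
  tissue voxels only — the field is pure extrapolation in background and
  lumen — and triggers a single refit with `lambda` escalated tenfold.

For trabecular (ridge-level) analysis, `trabecular_motion_spec()`
substitutes a 2-voxel final control spacing over four levels with the SSD
metric: ridge-scale displacement differentials live at the width of the
ridges themselves and are invisible to an 8-voxel lattice.

## Area strain and summaries

For each triangular element j the area strain at phase t is
`sqrt(A_j(t) / A_j(0))`, the square root of the ratio of the deformed to
the reference element area, computed by the cross-product formula on the
morphed meshes; 1 means undeformed, values above 1 stretching. Elements
degenerate at any phase are excluded at all phases so that the regional
summaries keep phase-constant element counts. Regional curves report, per
phase and per surface within the sampling region, the mean strain and the
strain variation — the standard deviation across elements with
denominator n, because the elements tessellate the region exhaustively
rather than sampling it. Scalar metrics follow their printed definitions:
ejection fraction `(diastolic area - systolic area)/diastolic area x 100%`
from mid-slice lumen areas, heart rate from the dominant period, and cell
cross-sectional area ratios (shoelace formula) as a deformation estimate
for incompressible cardiomyocytes.

## Trabecular ridge metrics

Ridge centrelines are polyline annotations (JSON, or generated by the
phantom). `measure_ridge_shortening()` densifies a trace by arc-length
resampling, displaces it through the motion model to the measurement
phase — the phase of maximal endocardial displacement, the antipode of
the systolic reference — and reports the fractional length change.
`measure_transmural_strain()` works on a 2-D cross-section plane like a
caliper: the transmural extent at the ridge is the distance from the
ridge crest (deepest endocardial contour point in an angular window) to
the epicardial contour in the same window; this crest-to-epicardium
definition is deliberately robust to tangential registration error,
because only the fitted surface shape enters. Compact-layer
circumferential strain is the fractional perimeter change of the
epicardial contour in the cutting plane.

## The phantom: what it emulates and what it does not

`phantom_spec()` builds a quasi-spherical myocardial shell (default outer
radius 14 um, wall 5 um — a geometrically scaled-down ventricle that fits
the desk-scale 128 x 128 x 40 voxel grid at the acquisition's 1-um
z-step) carrying four radial (meridional) and two circumferential
(equatorial) trabecular ridges on its endocardial surface. The periodic
deformation is prescribed in closed form in spherical shell coordinates:

* independent epicardial and endocardial radial expansion amplitudes,
  blended linearly across the wall (systolic reference, peak mid-cycle
  through a truncated-Fourier waveform, default a raised cosine);
* a transmurally weighted compression of the polar angle, normalised so
  the net meridional shortening of radial-ridge crest arcs equals the
  prescribed `ridge_shortening` fraction exactly at peak (`NA` makes
  ridges passive — required for spatially homogeneous strain phantoms);
* an extra inward displacement proportional to the radial ridges'
  envelope, thickening them transmurally as tissue blocks;
* an optional equatorial-band circumferential contraction.

Because the map and its inverse are closed-form, the generator provides
analytic ground truth for every downstream quantity: displacement fields,
per-element area strain (cross-checked internally against the
finite-difference surface Jacobian), ridge arc lengths by dense numerical
integration, label volumes, per-slice periods and phase offsets.
Intensities are rendered per slice with a soft (Gaussian-integrated)
boundary, a smooth multiplicative texture tied to the tissue's material
coordinates (emulating cell-to-cell reporter variability — and providing
the tangential image structure without which registration could not
observe in-plane sliding at all), Poisson shot noise and Gaussian read
noise with defaults giving SNR near 10 at the shell, and 16-bit
digitisation. Each slice starts at an independent uniform-random phase
offset, as in slice-sequential acquisition.

The phantom does not emulate photorealistic optics (no PSF beyond the
soft edge), blood cells, valves, photobleaching, or drift; passing tests
demonstrate correctness of the computational chain under known smooth
periodic motion, not robustness to every artefact of real microscopy.

The trabecular configuration (`trabecular_spec()`) mirrors the study's
separate higher-resolution acquisition for ridge analysis: a larger
ventricle (outer radius 18 um, wall 6 um), finer z-sampling (0.9 um over
56 planes), taller and wider ridges that run from the poles toward the
outer curvature and stop short of the equator (so their thickening field
cannot leak into the equatorial circumferential ridges), and noise-free
rendering — gating and noise robustness are validated separately, and the
ridge-scale differentials sit at the resolution limit. Its control
deformation (ridge shortening 0.15, thickening 0.20) is physiological in
scale, and the isoproterenol-like state raises them to 0.20 / 0.45 — a
roughly one-third increase in prescribed ridge shortening and a more than
doubled thickening amplitude, the direction and approximate proportion of
the reported beta-adrenergic effects on trabecular strain.

## Numerical choices and known limitations

* Phase bins are left-closed; a 1e-9-cycle guard absorbs floating-point
  representation at bin boundaries. All reconstruction comparisons are
  made at bin centres, including the reference (so recovered strain is
  relative to the bin-0 centre, not to the exact systolic instant; the
  difference is second order in the bin width).
* Marching tetrahedra can emit slivers; zero-area triangles are dropped
  and watertightness is checked by edge-sharing counts.
* The epi/endo split uses bounding-box size, not normal orientation,
  because iso-surfacing does not guarantee consistent winding.
* Ridge-level absolute recovery carries a systematic bias: the crest
  displacement profile is a peak of roughly the ridge's own width, and
  any smooth B-spline field attenuates a peak narrower than its control
  spacing (verified by projecting the analytic truth field onto the model
  class). The bias is common mode between conditions, so condition
  contrasts — the quantities of biological interest — are recovered
  accurately; both absolute values and contrasts are reported.
* Runtime scales with the number of voxels times control points. The
  shipped problem sizes (128 x 128 x 40 whole-ventricle runs, 10 phases;
  64 x 64 x 56 trabecular registrations) were chosen so a full validation
  sweep completes on a single CPU in tens of minutes; the phantom
  generator and pipeline accept full 512 x 512 acquisition-scale
  configurations unchanged.

## Reproducing the study-style analysis

The `analysis/` scripts run the whole workflow as a narrative: phantom
generation and export (`01`), synchronization (`02`), whole-ventricle
strain mapping with control vs ISO-like comparison (`03`), trabecular
ridge metrics (`04`), and scalar functional metrics (`05`). Tables land
in `results/`, raw stacks in `scratch/`. `scripts/acceptance.R` condenses
the validation into one run that recomputes every headline quantity from
scratch against the phantom truth.
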