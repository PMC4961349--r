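---
title: "Detecting the mid-cortical hypo-intense band in laminar T1-w profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the mid-cortical hypo-intense band in laminar T1-w profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminaband)
```

## The problem

Heavily myelinated intracortical fibre bands — the stria of Gennari in
primary visual cortex and, more generally, the lines of Baillarger — appear
in high-resolution (0.5 mm) T1-weighted MRI as a *hypo-intense band* near
mid cortical depth: a local dip in image intensity between the bright white
matter and the bright CSF. `laminaband` implements the full chain from a
T1-w volume plus binary WM and CSF segmentations to a per-location
statistical statement about that band:

1. **Bias correction** — the T1-w volume is divided by a heavily blurred
   proton-density (PD) volume acquired with the same receive coil, removing
   the multiplicative receive-field inhomogeneity the two scans share.
2. **Surface extraction** — the binary masks are smoothed with a Gaussian
   (SD 0.8 voxels), the WM/GM and GM/CSF boundary meshes are extracted as
   isosurfaces at level 0.5, and outward unit vertex normals are computed.
3. **Profile extraction** — each WM vertex normal is grown as a straight ray
   until it intersects the CSF mesh; only intersecting ("valid") normals are
   kept. Along each valid normal the volume is sampled by nearest-neighbour
   interpolation at 100 equally spaced steps; relative depth is Euclidean
   distance from the GM/WM border (the *equi-distance* convention, adequate
   at 0.5 mm resolution).
4. **Band detection** — profiles of a location are averaged; the mean
   profile is smoothed with a cubic smoothing spline (`spar = 0.55`); the
   band minimum is the *first* negative-to-positive zero crossing of the
   spline's first derivative, and the band start is the first
   positive-to-negative crossing preceding it, if any. A bootstrap over
   profiles (2000 resamples with replacement, re-averaging, re-smoothing and
   re-detecting each time) yields the proportion of replicates in which a
   band was found, the median and 95% percentile CI of the band-minimum
   depth, and a one-sided test of whether the detection proportion exceeds
   75% (`stats::prop.test`, Yates-corrected, Bonferroni-corrected across
   locations). The band amplitude is the smoothed intensity at the band
   start minus the intensity at the minimum.

The headline quantity reported downstream is the band-location CI, not the
proportion-test p-value: the p-value is computed on bootstrap counts, whose
effective sample size is chosen by the analyst (see *Limitations*).

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `blur_fwhm_mm` | 12 | mm | FWHM of the PD blur before division |
| `mask_smooth_sd_vox` | 0.8 | voxels | mask smoothing before isosurfacing |
| `iso_level` | 0.5 | — | isosurface level on the smoothed mask |
| `n_steps` | 100 | — | samples per profile |
| `max_ray_mm` | 10 | mm | cap on normal growth (≈3× maximal cortical thickness) |
| `spar` | 0.55 | — | `smooth.spline` smoothing parameter |
| `n_boot` | 2000 | — | bootstrap repetitions |
| `null_prop` | 0.75 | — | null detection proportion |
| `ci_level` | 0.95 | — | percentile CI coverage |

The FWHM→sigma conversion is the standard Gaussian relation
`sigma = fwhm / (2 * sqrt(2 * log(2)))`, stated here to rule out a silent
factor-of-2.355 discrepancy. Because the profile smoothing step was
originally performed with R's own `smooth.spline`, this package calls that
routine directly with `spar = 0.55`; no re-derivation of the spar→lambda
mapping is needed, `stats::smooth.spline` *is* the reference
implementation. On 100 points, `spar = 0.55` corresponds to roughly 15
equivalent degrees of freedom — a mildly smoothed fit, a point that matters
below.

## The synthetic phantom

No raw MRI accompanies the analysis, so validation rests on a phantom with
known laminar structure. Two geometries are provided: concentric spheres
(WM core of radius 9 mm, GM shell to 12 mm, CSF outside), which exercise
curvature and normal divergence, and a flat slab, which gives exact planar
oracles. Intensities are arbitrary units with WM (150) and CSF (180)
brighter than GM (100), on a 0.5 mm isotropic grid — at least five voxels
across the 3 mm ribbon.

GM intensity at relative depth $d$ is

$$ I(d) = I_\mathrm{gm} + s\,(0.5 - d)
        - A\,\exp\!\left(-\frac{(d - d_0)^2}{2 w^2}\right), $$

a linear descent of `gm_slope` $s$ (default 15) across the ribbon — the
intracortical myelin gradient, which makes real no-band profiles fall
monotonically toward the pial surface — plus a Gaussian dip of amplitude
$A$ (default 10), centre $d_0$ (default 0.5) and width $w$ (default 0.08)
when the band is present. A smooth unimodal dip is the minimal shape
producing the two derivative zero crossings the detector is defined on.
The noiseless volume is blurred with a small Gaussian (`pv_blur_mm`, the
*sigma* in mm, default 0.25 — partial volume at 0.5 mm voxels), multiplied
by a linear or polynomial receive-field (default 30% peak-to-peak when
enabled), and Gaussian noise is added. The PD volume is flat anatomy
(value 1) on its own coarser 1 mm grid times the *same* bias field — flat
because real PD anatomy is irrelevant to the division step's contract,
while sharing the bias isolates exactly what PD division must remove.
Masks are exact pre-noise region indicators: segmentation was manual in the
original workflow and segmentation error is out of scope.

What the phantom does *not* emulate: Rician noise statistics, motion and
Gibbs ringing, anatomical curvature variation, thin sulcal CSF, or
segmentation error. Passing tests therefore demonstrate the correctness and
calibration of the pipeline's machinery, not its robustness to those
real-data effects.

### Locations and profile counts

A location is a sphere of interest on the WM mesh (seed point + radius,
default 4 mm) thinned to 30 vertices by deterministic farthest-point
sampling. The thinning is not cosmetic: an isosurface mesh at 0.5 mm voxels
is far denser than the 25–45 profiles a location is expected to yield, and
a tight bundle of adjacent, near-parallel normals samples the *same* voxel
columns, so their nearest-neighbour staircases average coherently into a
staircase mean profile that destabilises the spline derivative. Spreading
the origins across the patch decorrelates the staircases and recovers a
smooth mean profile.

## Numerical choices

- **Nearest-neighbour convention.** Sample points map to voxels through the
  NIfTI affine with 0-based voxel-centre coordinates; exact half-coordinate
  ties break toward the lower index.
- **Zero-crossing localisation.** Crossings are placed by linear
  interpolation of the derivative between the two bracketing samples
  (sub-step precision); the derivative itself is the analytic first
  derivative of the fitted spline, which agrees with finite differences of
  the fitted values to $O(\Delta^2)$.
- **Plateaus.** Exact-zero derivative samples inherit the preceding sign
  regime, so a flat stretch cannot create duplicate crossings.
- **Interior rule.** A crossing counts only if both bracketing samples lie
  strictly inside (0, 1), excluding the first and last sampling interval.
- **Band start absent.** If no positive-to-negative crossing precedes the
  minimum, the profile value at depth 0 is the amplitude reference and the
  result is flagged `start_absent`.
- **Division floor.** The blurred PD is floored at `1e-6` times its median
  before division, avoiding infinities at volume edges; edge replication is
  used for both resampling and blurring so that edge profiles are not
  darkened by zero padding.
- **Isosurface.** Marching tetrahedra on a consistent 6-tetrahedron cube
  decomposition (shared face diagonals between neighbouring cubes), so
  closed level sets give watertight meshes; any isosurface algorithm
  meeting the watertightness and accuracy contracts would be conformant.
  The largest connected component is kept, since mask smoothing can create
  specks. Normal orientation is fixed globally by an interior reference
  point (the mask centroid), making it independent of face winding.

## Known biases and limitations

**Depth bias under the myelin gradient.** The smoothing spline interacts
with the linear gradient: smoothing widens and attenuates the dip, and the
gradient then displaces the fitted minimum downslope. On noiseless
gradient-free phantoms the recovered minima are within 0.01–0.02 of the
injected depths (0.3/0.5/0.7); with the default gradient of 15 the
systematic displacement grows to ≈ +0.04–0.05. Users comparing band depths
across regions with different myelin gradients should expect this
interaction.

**The detector has no type-I control.** The operational definition — first
interior negative-to-positive derivative crossing of a ~15-df spline fit —
finds *some* crossing in essentially every noisy profile set: a smoothed
pure-noise profile is non-monotone with probability ≈ 1 (and the
probability is scale-free, independent of the noise amplitude), and any
profile sampled border-to-border between bright WM and bright CSF is
U-shaped, guaranteeing a crossing regardless of noise. Measured on no-band
phantoms at the default conditions, the bootstrap detection proportion is
≈ 1.0 and the 75% proportion test rejects for every null location. The
proportion test should therefore be read as a *stability screen* for the
bootstrap, not a calibrated hypothesis test — which is precisely why the CI
of the band location, not the p-value, is the reported quantity. The
acceptance suite states the idealised false-positive bound and reports the
measured count, so the failure is visible rather than papered over.

**Scale of the validation runs.** The test and acceptance phantoms use
64³ voxels at 0.5 mm, one 30-profile location per phantom, 2000 bootstrap
replicates, 5 noise seeds for recovery and 20 independent nulls — sizes
chosen so each stage is verifiable at desk scale while using the reference
analysis settings throughout.

## A minimal run

```{r example, eval = FALSE}
spec <- phantom_spec(noise_sd = 5, bias_field = "linear", seed = 7)
report <- run_pipeline(run_config(
  phantom = spec,
  band = band_config(n_tests = 12),
  n_locations = 1, seed = 7))
report

# or stage by stage:
ph <- generate_phantom(spec)
corrected <- pd_correct(ph$t1w, ph$pd)
wm <- mask_to_mesh(ph$wm_mask)
csf <- mask_to_mesh(ph$csf_mask, invert = TRUE)
filt <- select_location_vertices(
  wm, wm$vertices[which.max(wm$vertices[, 1]), ], 4, n_max = 30)
ps <- extract_location(corrected, wm, csf, profile_config(), filt, "V1-like")
res <- analyze_location(ps, band_config(n_tests = 12, rng_seed = 11))
res
ggplot2::autoplot(res, profile_set = ps)
```
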