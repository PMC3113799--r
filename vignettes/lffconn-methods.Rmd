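---
title: "Methods: low-frequency fluctuation seed connectivity in task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-frequency fluctuation seed connectivity in task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lffconn)
```

## The analysis in one paragraph

Low-frequency fluctuations (LFF) of the BOLD signal — here the band from
0.0166 Hz to 0.1 Hz — carry intrinsic functional-connectivity information
that persists underneath task-evoked activity.  `lffconn` maps this
connectivity from task fMRI in five stages.  Each subject's 4D run is
spatially smoothed (Gaussian, FWHM 4 mm) and residualized against a general
linear model `Y = X b + e` whose design `X` encodes the stimulation
convolved with a Gamma hemodynamic kernel, so stimulus-locked variance is
projected out and the residuals `e` retain the fluctuations of interest.
The residuals are band-pass filtered to the LFF band.  A seed — a 7-voxel
sphere (189 mm^3 on the 3 mm grid): the voxel containing the seed
coordinate plus its six face neighbors — is averaged into a single time
course, and its Pearson correlation with every voxel of a volume of
interest (VOI) yields a per-subject correlation map, stabilized by the
Fisher transform z = 0.5 log((1+r)/(1−r)).  Group maps average z voxelwise
and invert the transform; two groups are contrasted by voxelwise t-tests
mapped to z values, with family-wise error controlled by Monte Carlo
cluster-size thresholds simulated inside the VOI (small-volume correction).
Surviving clusters are reported in a table of region label, contrast
direction, peak Talairach location, maximum z and size in mm^3, keeping
only clusters above a 300 mm^3 report floor.

The package also ships a synthetic 4D generator that plants group-specific
coupling topologies with analytically controlled target correlations, so
the entire chain is falsifiable against a known ground truth at desk scale.

## The generative model

`simulate_subject()` composes each voxel time course from four parts:

* **Task component.**  A four-condition event schedule (auditory sentence
  trials in the motivating design) is convolved with a Gamma hemodynamic
  kernel and added with per-voxel random gains (uniform on 0.5–1.5 times
  the condition amplitude).  The kernel is a Gamma density parameterized by
  time-to-peak (default 6 s) and shape (default 6), sampled on the TR grid
  and normalized to unit sum.  The published experiment does not fix
  per-trial timing, so the generator uses a deterministic schedule (one
  4 s trial every 12 s, conditions interleaved) as its convention.
* **Baseline drift.**  A random per-voxel mixture of low-order Legendre
  polynomials and slow sinusoids, all with spectral mass below 0.0166 Hz.
  This emulates "scanner drift" without committing to a scanner model.
* **Regional LFF signal.**  Every phantom region carries a unit-variance
  band-limited (0.0166–0.1 Hz) signal.  A coupling edge (A, B, r) gives
  both regions a shared latent with weight sqrt(r) plus a private latent
  carrying the remaining variance, so the model correlation of the two
  regions' noiseless band components is exactly r.  This construction makes
  the target analytically controllable; its price is that the couplings
  incident to one region must sum to at most 1, which the scenario
  validator enforces.
* **White noise** (per voxel and time step) and a constant baseline of 100.

Default scenario parameters are the study conditions of the motivating
design: TR 2 s, 540 time steps, 16 adults and 15 children, 3 mm isotropic
grid.  The coupling topologies are: adults, left frontal seeds coupled to
the left posterior temporal region (r = 0.5 and 0.4); children,
interhemispheric temporal (0.5), homotopic inferior frontal (0.4) and
bilateral precentral (0.5) couplings.  The strengths are scenario
parameters chosen to produce group-average correlations in the range the
display threshold (r = 0.45) makes visible; they are not empirical claims.
`noise_sd` defaults to 0.5 relative to the unit band signal — an
LFF-dominated regime chosen so that region-mean series retain the planted
correlation after filtering; the recovery experiments verify this.

What the generator does **not** emulate: head motion, registration error,
susceptibility artifacts, slice timing, physiological noise spectra, and
the 20-slice slab geometry of the original acquisition.  Passing tests
therefore certify the statistical machinery, not robustness to those
real-data nuisances.

## Numerical choices

* **Coordinates.**  Talairach mm map to voxel indices by nearest-center
  rounding with half-voxel ties toward −Inf; `index_to_mm()` returns voxel
  centers, so round trips from centers are exact.  Axes follow RAS.
* **Sphere membership** in `make_phantom_voi()` counts a voxel when the
  sphere intersects its cube, which reproduces the canonical 7-voxel /
  189 mm^3 seed at radius 1.5 mm on a 3 mm grid and degenerates to the
  single center voxel at radius 0.
* **Smoothing** is separable Gaussian convolution with sigma =
  FWHM/(2 sqrt(2 log 2)) per axis, half-sample reflective boundaries
  (which preserve each volume's spatial mean), kernel truncated at 4
  sigma.  The smoothing operator `K` of the GLM formulation is read as
  spatial smoothing of the data: its FWHM is stated in mm, which forces
  the spatial interpretation, and smoothing the spatially constant design
  columns would be a no-op.  Estimation is ordinary least squares without
  prewhitening — inference is on correlations of the residuals, not on the
  regression coefficients, so residual autocorrelation enters only through
  the effective degrees of freedom of r, which the group-level t-test
  absorbs empirically.
* **Band-pass.**  Each series is detrended (mean + linear trend) and then
  masked in the frequency domain: gain 1 inside [0.0166, 0.1] Hz, raised
  cosine roll-off over 0.002 Hz outside each edge, DC removed.  The
  detrending step prevents the spectral leakage a slow ramp would smear
  into the band; the filter is linear and exactly zero-phase.  The band
  edges are configurable: the methods description of the original analysis
  mentions both a band-pass (0.0166–0.1 Hz) and a low-pass (below
  0.0166 Hz) reading, which are one configuration change apart here; the
  band-pass reading is the default because it is the one attached to the
  statement of what is analyzed for correlations.
* **Group test.**  Pooled-variance t by default (group sizes 16/15 are
  nearly equal; Welch by flag), converted to z by two-sided probability
  matching on the log scale, so extreme t values stay finite.
* **Smoothness estimation** (an input the Monte Carlo null needs that the
  original description leaves unstated) inverts the Gaussian
  autocorrelation model rho = exp(−d^2/(4 sigma^2)) from the correlation
  of face-adjacent in-mask voxels, after centering the maps voxelwise
  across subjects so shared mean structure (e.g. the seed's own
  neighborhood) does not inflate the estimate.  Estimates are floored at
  the voxel size, the effective resolution of an unsmoothed map.
* **Monte Carlo correction.**  Null iterations draw white noise on the
  full grid, smooth to the estimated FWHM, restandardize within the VOI,
  threshold |z| >= 2.576 (two-sided p < 0.01, configurable — the original
  analysis states only the corrected level p < 0.05), and record the
  maximum cluster size.  The cutoff is the ceiling of the (1−alpha)
  quantile of that null, floored at one voxel.  Clusters are
  26-connected by default (configurable to 6; the original rule is
  unstated).  A cluster survives on size alone by default; the simulated
  max-z quantile is available as an alternative "peak" accept rule because
  the original size/peak combination rule is also unstated.
* **Undefined voxels** (zero temporal variance) propagate as NA and are
  excluded from group statistics rather than fabricated as r = 0.

## Validation experiments and problem sizes

Three experiment drivers make the pipeline's statistical claims testable:

* `fwe_null_experiment()` repeats the full null pipeline (two groups of 8
  drawn from the same uncoupled scenario on a two-region phantom,
  20x18x16 grid, 128 time steps, 500 Monte Carlo iterations) and reports
  the fraction of studies with any surviving cluster; at alpha = 0.05 the
  acceptance suite requires 0.05 ± 0.03 over 300 repetitions.
* `coupling_recovery_experiment()` plants a single edge (r = 0.3 or 0.6)
  on the desk-scale six-region phantom, runs 100 subjects (256 time steps)
  through smoothing, GLM residualization, band filtering and seed mapping,
  and requires the subject-mean correlation over the coupled region to be
  within ±0.05 of the target.
* `topology_recovery_experiment()` simulates the default adult/child
  topologies (16 + 15 subjects, 128 time steps) on the desk-scale phantom,
  seeds the left temporal region, and requires the corrected contrast to
  contain an adults > children cluster over the planted left frontal
  region and a children > adults cluster over the planted right temporal
  region in >= 90% of 20 replicates.

The reduced run lengths and grids are the package's own desk-scale choices:
they preserve the band's frequency resolution (>= 10 Fourier bins in band)
and the FWHM-to-voxel ratio of the full design while keeping each
experiment in the minutes range on one CPU.  `scripts/acceptance.R` reruns
the same drivers at further reduced repetition counts.

## Known limitations

* The Monte Carlo null assumes Gaussian spatial autocorrelation; heavy
  non-Gaussian smoothness structure (real data) would need a permutation
  or heavier-tailed null.
* The t-to-z probability matching makes the thresholded map voxelwise
  Gaussian but cluster extents of a t field differ slightly from a
  Gaussian field's at equal height; the calibration experiment bounds the
  practical effect.
* Motion, registration and atlas labeling are out of scope: region labels
  come from the phantom's label map or a user-supplied lookup.
* Only the VOI is analyzed; the pipeline makes no statement about
  connectivity outside it.
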