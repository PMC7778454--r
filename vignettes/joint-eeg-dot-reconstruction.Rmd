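---
title: "Joint EEG-DOT source reconstruction: model, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint EEG-DOT source reconstruction: model, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

EEG measures scalp potentials generated by neuronal currents at millisecond
resolution, but the skull acts as a spatial low-pass filter and the inverse
problem is severely ill-posed: reconstructed sources spread over centimeters.
Diffuse optical tomography (DOT) reconstructs hemoglobin concentration
changes at millimeter scale, but hemodynamics evolve over seconds. Two
sources a few centimeters and a few tens of milliseconds apart are therefore
unresolvable by either modality alone. Because neurovascular coupling
co-localizes evoked electrical and hemodynamic activity, a DOT reconstruction
can constrain *where* EEG activity is allowed to be large, while EEG retains
*when* it happens.

Both inverse problems share the linear form

$$Y = H\beta + \epsilon,$$

with $Y$ the measurements (scalp potentials, or optical density changes
$\Delta OD$), $H$ the forward operator (leadfield, or Jacobian), $\beta$ the
sources (dipole moments, or $[\Delta HbO; \Delta Hb]$), and $\epsilon$ sensor
noise. Under zero-mean Gaussian assumptions $\beta \sim N(0, C_P)$,
$\epsilon \sim N(0, C_N)$, the maximum a posteriori estimate is the posterior
mean

$$\hat\beta = C_P H^\top (H C_P H^\top + C_N)^{-1} Y,$$

and the covariances are expressed as nonnegative combinations of fixed
components,

$$C_N = \sum_i \Lambda_{N,i} Q_{N,i}, \qquad
  C_P = \sum_i \Lambda_{P,i} Q_{P,i},$$

whose coefficients are estimated by restricted maximum likelihood (ReML):
maximize the likelihood of $Y$ under the marginal model
$\mathrm{cov}(Y) = H C_P H^\top + C_N$. With single identity components on
both sides and fixed coefficients this reduces to Tikhonov regularization
with ridge weight $\Lambda_N / \Lambda_P$ — a useful oracle that the test
suite exploits.

The three reconstruction schemes are:

* **EEG only** — $C_N = \Lambda_N I$, $C_P = \Lambda_P I$, applied
  independently to every timestep of the trial-averaged EEG.
* **DOT only** — two noise components (one per wavelength, each i.i.d.
  within its wavelength block) and two prior components (one per chromophore),
  applied to the block-averaged $\Delta OD$.
* **EEG with DOT prior** — the max-normalized HbO reconstruction $v$ is
  thresholded, $\beta'_i = v_i \cdot 1\{v_i > k\}$, and mapped to per-voxel
  prior variances

  $$Q_P\{i,i\} = 1 - \exp\!\left(-\frac{\beta'_i + a}{b}\right),$$

  so every voxel keeps a baseline variance $1 - e^{-a/b}$ and hemodynamically
  active voxels receive up to $1 - e^{-(1+a)/b}$. Defaults $k = 0.1$,
  $a = 0.1$, $b = 1$ ($a = 0.25$ with the 64-channel montage). Smaller $a$
  biases the solution harder toward the prior; smaller $b$ widens the dynamic
  range between the most and least trusted voxels.

Localization accuracy is scored with the bias-spread metric (BSM): the valid
voxels are those with at least half the maximum absolute amplitude;
$\mathrm{bias}$ is the distance (mm) from their unweighted center of mass to
the true center, $\mathrm{spread}$ the mean square distance (mm²) of the
valid voxels to that center of mass, and
$\mathrm{BSM} = \sqrt{\mathrm{bias}^2 + \mathrm{spread}}$. With two active
spots the valid voxels are normally partitioned by the nearer true center;
if all of them are nearer one center the other spot is *undetected*, and if
they form a single lattice-contiguous blob straddling both centers the whole
blob scores both spots. Contiguity is single-linkage at 1.5x the source
lattice spacing (voxel adjacency).

## The phantom

The anatomical head and finite-element forward solvers that a study on real
anatomy would use are replaced by analytic models, which keep the physics the
method exploits while making every number reproducible from code:

* **Geometry** — four concentric shells (brain/CSF/skull/scalp, outer radii
  80/82/87/92 mm), relative conductivities 1 : 5 : 1/80 : 1. Sources are a
  Fibonacci lattice on the brain shell with radial orientations (default
  2500 voxels, ~5.7 mm spacing).
* **EEG leadfield** — the classical Legendre-series solution for a radial
  dipole in concentric conducting spheres, solved per degree by a small
  radially-scaled linear system (so the series is numerically stable at high
  degree); truncation at 60 terms by default, the resistive skull damping
  making the neglected tail ~1e-4 of the largest coefficient. Dipoles are
  retracted 2 mm below the source shell because the interior expansion is
  singular exactly on the brain/CSF interface; columns are
  average-referenced. In the homogeneous limit the series matches the
  closed-form single-sphere potential to machine precision (tested at
  truncation 400, where the undamped tail bound $(2n+1)f^{n-1}$ is < 1e-10).
* **DOT Jacobian** — continuous-wave Rytov sensitivity built from
  diffusion-approximation Green's functions of a semi-infinite homogeneous
  medium (optodes buried one transport mean free path below their scalp
  point, mirrored across an extrapolated boundary with $z_b = 2AD$,
  $A = 2.95$). The per-voxel kernel
  $G(s\!\to\!r)\,G(r\!\to\!d)/G(s\!\to\!d)$ reproduces the "banana"
  sensitivity profile and exact source-detector reciprocity. Chromophore
  columns are scaled by $\ln 10$ times molar extinction coefficients
  (packaged literature-typical table, overridable); optical properties
  default to brain-like $\mu_a$/$\mu_s'$ at 750/850 nm.
* **Sensor layouts** — 10-20 / 10-10 montages with 32 or 64 electrodes
  (angular scheme mapped radially to the scalp); DOT grids are
  source/detector checkerboards in the tangent plane of a right-lateral
  patch at 45° elevation: 4x4 at 22 mm spacing (24 channels, source-detector
  distances 17-27 mm), optionally one extra detector past the lateral edge
  (two extra channels), and a 6x6 high-density grid at 13 mm spacing
  (60 channels, distances within 7.5-29 mm). The published grids are only
  constrained by channel counts and distance ranges, so the layouts here are
  parametric rather than replicas.

## What the simulator emulates

Each activation spot (voxels within 4 mm of a center; at the default lattice
resolution that is 1-2 voxels — the 8 mm physical spot size is kept, the
voxel multiplicity of a dense anatomical mesh is not) carries one impulse
train: 100 trials in the first 20 s of a 30 s block, 200 ms apart, with spot
B stimulated 50 ms after spot A. The train is convolved with

* a unit-peak Gaussian **neural kernel** (peak 50 ms, FWHM 40 ms — the
  source text specifies only "a simple bell shape"; these values make the two
  per-trial responses cross at ~75 ms with equal amplitudes, matching the
  three canonical readout times 50/75/100 ms), sampled at 1000 Hz;
* a unit-peak **canonical double-gamma HRF** (peak 6 s, undershoot 16 s,
  undershoot ratio 1/6), sampled at 10 Hz; $\Delta Hb = -\Delta HbO / 3$.

I.i.d. Gaussian background activity is added to *every* voxel at every
sample, with standard deviations 1/20 (electrical), 4x (HbO) and 2x (Hb) of
the **single-stimulus** evoked maximum of the respective signal. The
single-stimulus reference matters: at 200 ms spacing ~45 hemodynamic
responses superpose into a plateau ~45x the single-trial peak, and a
background at 4x *that* would bury the evoked activity entirely, which is
inconsistent with the hemodynamic localization accuracy this class of
methods demonstrably achieves (and which the DOT-only scheme reproduces here:
spot BSMs of ~4-7 mm).

Recordings are the forward projections plus white sensor noise scaled so
that (max |pre-noise signal|)² / noise variance equals the configured SNR:
10 (EEG), 10 (750 nm), 20 (850 nm).

What the generator does **not** emulate: structured physiological noise
(cardiac/respiratory oscillations), nonlinear or delayed neurovascular
coupling, scalp/skull optical layering, extended or non-radial sources, and
electrode/optode coregistration error. Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms under the stated
generative model, not performance on real recordings.

## Numerical and design choices

* **Hyperparameter updates** — Fisher scoring on log-coefficients
  (positivity by construction) with Levenberg-Marquardt damping and step
  rejection; tolerance 1e-6 relative objective change, at most 128 accepted
  iterations; coefficients initialized by splitting the empirical data
  variance equally across components; 1e-10 x mean-diagonal jitter before
  factorization. Multiple timepoints enter as i.i.d. columns through their
  second-moment matrix. The objective trace is non-decreasing up to the
  rejection tolerance 1e-9 and is checked in the tests.
* **Per-timestep reconstruction** — hyperparameters are re-estimated
  independently at every timestep of the averaged trial; timesteps are not
  coupled.
* **Preprocessing** — EEG: plain epoch averaging over the 200 ms trials.
  DOT: zero-phase (forward-backward) order-2 Butterworth low-pass at 1 Hz —
  zero-phase so the hemodynamic peak latency is not shifted — followed by a
  time average over a 2-25 s response window (the averaging window for the
  block mean is not specified by the source description; a post-onset window
  covering the plateau of the superposed responses is used and is
  configurable).
* **Thresholding scale** — the prior threshold $k$ applies to the
  max-normalized HbO map (with $k = 0.1$ a threshold on raw amplitudes would
  be meaningless, since the solver's output scale is arbitrary).
* **Smoothness kernel** — the optional spatial prior kernel is
  $G_{ij} = \exp(-\|r_i - r_j\|^2 / \sigma^2)$ with a *negative* exponent;
  the positive sign that appears in some descriptions diverges and cannot be
  a covariance.
* **MBLL pathlength factors** — differential pathlength factors 6.0 (750 nm)
  and 5.0 (850 nm), overridable; the projection baseline interpolates
  channel-wise HbO onto the cortex with a 15 mm Gaussian kernel placed at
  source-detector midpoints projected radially to the source shell.
* **Two-spot rule ties** — voxels equidistant from both centers are assigned
  to spot A, deterministically.
* **Peak-lag readout** — the recovered stimulus offset is measured on the
  joint full-series reconstruction as the difference of peak latencies of
  the spatially pooled (10 mm radius), lightly smoothed (5 ms moving
  average) time courses at the two true centers; pooling suppresses
  voxel-level noise jitter while preserving the two distinct peaks.
* **Assessment shortcut** — for large random-location sweeps the i.i.d.
  source background is drawn directly in sensor space as
  $N(0, \sigma^2 L L^\top)$ via a Cholesky factor; this is the exact
  distribution of the mapped source background (verified against the
  faithful path in the tests), not an approximation. Scenario runs use the
  faithful source-space path.

## Problem sizes and known limitations

Scenario runs use the default 2500-voxel shell; unit tests use a 600-voxel
shell. The random-location assessment samples locations uniformly over the
DOT grid's tangent footprint plus a 10 mm margin (100 runs per grid in the
acceptance checks), which preserves the mix of well-covered and marginal
locations that drives the improvement statistics. The parameter sweep over
$(a, b)$ shares one simulated dataset across the grid.

Limitations worth keeping in mind: the spherical phantom has no sulci, so
cortical projection and DOT coverage are more benign than on real anatomy;
BSM values are quantized by the ~5.7 mm lattice; spots contain only 1-2
voxels at this resolution, so the *spread* of the true activation is
essentially zero; and with 32 electrodes the EEG-only point spread is large
enough that at particular noise draws the joint reconstruction can still
fail to separate the two sources (the random assessments quantify how
often). Improvement percentages measured on this phantom characterize the
phantom, not any anatomical dataset.
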