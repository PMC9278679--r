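---
title: "Characterizing patient-positioning uncertainty in CT-MRI radiotherapy workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing patient-positioning uncertainty in CT-MRI radiotherapy workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regqa)
```

## The problem

When radiotherapy planning combines CT and MRI (or PET/CT and MRI), the two
acquisitions happen on different machines, so the patient's position on each
scanner differs by a small rigid displacement. Two clinical workflows are
compared throughout this package: **C1**, in which the patient is moved
between scanners on an air-cushion transfer table without getting up, and
**C2**, in which the patient is repositioned on each scanner using
thermoformed-mask markings and room lasers. The displacement between the two
acquisitions is estimated by rigidly registering the MRI onto the CT; the
transform read off the registration is the *positioning shift* for that
session.

Two error sources combine in any such measurement:

* the **registration error** (mRE): the bias of the registration algorithm
  itself, measured by injecting *known* transforms into one volume and
  comparing what the algorithm recovers against what was injected;
* the **positioning error** (mPE): the mean observed shift for a setup.

The package's summary statistic is the quadrature total error per axis,

$$\mathrm{TE} = \sqrt{\mathrm{mRE}^2 + \mathrm{mPE}^2},$$

computed for the three translations (mm) and the three rotations (degrees),
with the in-plane translations x and y sharing one mRE, z its own, and the
three rotations a pooled one.

## Rigid transforms and Euler angles

Rotations use the extrinsic x-then-y-then-z convention
$R = R_x(\phi)\,R_y(\theta)\,R_z(\alpha)$ where $\phi$ is pitch (about the
left-right axis), $\theta$ roll (anterior-posterior) and $\alpha$ yaw
(superior-inferior). `compose_rotation_matrix()` builds the matrix from its
closed-form entries; `decompose_rotation_matrix()` solves it back via
$\theta = \arcsin R_{13}$, $\alpha = \operatorname{atan2}(-R_{12}, R_{11})$,
$\phi = \operatorname{atan2}(-R_{23}, R_{33})$. Angles are degrees at every
interface, radians internally, because clinical reports are in degrees.

Numerical choices worth stating:

* decomposition round-trips composition to below $10^{-9}$ degrees for
  $|\theta| < 90^\circ$; the clinical operating range here is $\pm 5^\circ$;
* at gimbal lock ($|\theta| = 90^\circ$) only $\phi \pm \alpha$ is
  determined; the convention is $\alpha = 0$ with $\phi$ absorbing the
  remainder, and the result is flagged. This never occurs in the operating
  range and any fixed convention would do;
* a transform maps $p \mapsto R\,(p - c) + c + t$ about a rotation center
  $c$. The center defaults to the fixed volume's geometric center, recorded
  in all outputs, since commercial systems rarely publish their convention;
* differences between an induced transform and its estimate are computed by
  matrix composition (estimate composed with the inverse of the induced
  transform), reported per component as estimate minus expected.

## The registration engine

`register_rigid()` is a standard mutual-information rigid registration:
joint-histogram MI (64 bins at full resolution), a 3-level block-mean
pyramid (downsampling 4, 2, 1; coarser levels use proportionally fewer
bins because they hold fewer samples), and derivative-free Nelder-Mead
optimization over the six parameters with 1 mm and 1 degree treated as
commensurate steps. It is fully deterministic: a frozen jitter pattern, a
fixed evaluation order and no stochastic optimizer components, so identical
inputs reproduce identical results bit for bit.

Three design details matter for accuracy and are easy to get wrong:

* **Parzen-windowed binning in the objective.** A hard-binned joint
  histogram is piecewise constant in the transform parameters at fine
  scales, which stalls a simplex optimizer; linear (Parzen) binning makes
  the metric smooth. The exported `mutual_information()` keeps hard binning
  so that its values have the textbook interpretation (e.g.
  $MI(A, A) = H(A)$ exactly for discrete images).
* **Jittered sample positions.** If the fixed image is sampled exactly on
  its own voxel grid, its noise enters the histogram unsmoothed while every
  off-grid candidate transform interpolation-smooths the moving image's
  noise. That asymmetry biases rotation optima by a few tenths of a degree.
  The objective therefore samples both images at voxel centers plus a
  frozen sub-voxel jitter, so both are interpolated comparably at every
  candidate. The jitter is a fixed pattern, not a random process: results
  stay deterministic.
* **Simplex restarts.** Nelder-Mead in six dimensions collapses readily; at
  each pyramid level the optimizer is restarted with a fresh simplex at
  shrinking scales (1, 1/4, 1/16 of the level's step), keeping the
  incumbent whenever a restart fails to improve it.

A deterministic coarse grid search over translations ($\pm 12$ mm, 4 mm
step) seeds the coarsest level so that offsets up to the clinical capture
range need no manual initialization. Intensities are binned between each
volume's 1st and 99th percentiles (robust to CT tails), and out-of-field
voxels get the moving volume's minimum so signed CT intensities do not pile
up at zero.

A fourth detail is the **body-contour mask** (default: sample points are
kept where the fixed image clears its 1st percentile by 10% of the robust
intensity range). Air fills roughly four fifths of a head field of view,
and its noise otherwise dominates both marginal histograms: a small pure
rotation displaces most voxels by sub-voxel amounts, so its misalignment
penalty on MI is weak, while every resampling interpolation-smooths the
moving image's noise, which raises MI irrespective of alignment. Unmasked,
that reward stalled the recovery of a 2-degree single-axis rotation more
than a degree short; restricting the metric to the head region removes
most of it (and cuts the per-evaluation cost about five-fold). A light
per-level Gaussian pre-smoothing (default 0.3 voxels) damps what remains;
sigmas approaching a voxel blur the few-voxel-thick shell that localizes
rotations and degrade accuracy again, so the default is deliberately
small.

One residual limitation survives all of this, because it lives in the
metric rather than the optimizer: for a *pure roll* (rotation about the
anterior-posterior axis) the phantom's x-z cross-section is nearly
circular (50 vs 55 mm semi-axes), and the classic interpolation artifact
of histogram-based MI — present even on noise-free volumes, as profiling
the metric along roll confirms — can displace the optimum by up to about
half a degree. Roll components of combined transforms, where the other
components supply gradient, recover to better than 0.15 degrees, and the
protocol's regression test freezes the pure-roll bound at 0.55 degrees.
Reference clinical engines report rotation errors of the same order (up to
0.6 degrees).

Registration direction is fixed = CT, moving = MRI; the returned transform
maximizes $MI(\mathrm{CT}, \mathrm{MRI} \circ T)$, so when the MRI was
displaced by $t$ the output estimates $t^{-1}$, and the accuracy protocol
inverts it before differencing.

## The synthetic phantom and what it does (not) emulate

`generate_skull_phantom()` builds a desk-scale digital analogue of a
gelatin-filled skull phantom: a 64^3 grid at 2.5 mm isotropic spacing (the
slice thickness typical of radiotherapy head protocols), an ellipsoidal
bony shell (outer semi-axes 50 x 65 x 55 mm, nominal thickness 6 mm)
around a homogeneous gelatin-like interior. The inner ellipsoid is offset
by (3, -4, 2) mm so the shell thickness varies across the surface, the way
a skull is thicker at its base: a perfectly concentric shell is
rotationally near-symmetric and would make small rotations unidentifiable
for *any* intensity-based algorithm — a degenerate test object rather than
a hard one. The offset leaves the analytic shell volume unchanged, so the
voxelization is still validated against the closed-form ellipsoid-shell
volume.

The two modalities share one grid and one geometry — the ground-truth
inter-modality transform is exactly the identity — but map tissues
differently: CT-like intensities are HU-flavored (air -1000, gelatin 40,
bone 700), MRI-like intensities are T1-flavored (background 5, gelatin 900,
bone 150), i.e. contrast is inverted and registration is genuinely
multimodal. Additive Gaussian noise (SD 15 CT / 25 MRI, chosen as visually
realistic for head protocols relative to the ~1000-unit tissue contrasts)
and a 10% low-frequency multiplicative bias field on the MRI complete the
picture. Everything is a pure function of the configuration, seed included.

What the phantom does **not** emulate: MRI geometric distortion (gradient
nonlinearity, susceptibility), sequence physics, anatomy beyond the
three-compartment geometry, and the transfer hardware itself. Passing the
recovery tests therefore demonstrates the *algorithmic* accuracy of the
engine on well-posed multimodal volumes, not the full clinical error budget
of any scanner pair.

The cohort simulator, `simulate_cohort_shifts()`, draws each of the six
shift components independently from $\mathcal N(\text{offset}_k,
\text{spread}_k)$, with per-setup defaults taken from the bundled
patient-study reference means and spreads from the reference interquartile
ranges via $\mathrm{IQR}/1.349$. Independence across components is a
modeling choice — couplings such as pitch with anterior-posterior shift are
plausible but unreported — and Gaussianity is the simplest model that
exercises every downstream statistic.

## The accuracy protocol

`run_accuracy_protocol()` reproduces the known-transform validation stage:
one nonzero component at a time, translations 0.5–19.5 mm in 1 mm steps
(20 values per axis) and rotations 0.2–5.0 degrees in 0.2-degree steps
(25 values per axis), 10 repeats each, all overridable. A `figure_n` preset
(10 translation values per axis: 0.5, 2.5, ..., 18.5) matches the sparser
per-figure sample counts reported in some summaries of this protocol; both
readings of the grid are supported rather than silently choosing one.
Repeats of a deterministic engine are identical; the repeat index stays in
the schema for parity with operator-driven protocols and stochastic engine
variants. Registration failures are flagged per record, never dropped, and
`summarize_accuracy()` pools differences the way the reference analysis
does: x,y translations together, z separately, rotations together, each
summarized by Bland-Altman mean, SD and limits mean ± k·SD.

## Statistics

* `descriptive_stats()`: mean, median, type-7 (linear interpolation)
  quantiles for the IQR — the most common convention; the choice is
  configurable because reference tables rarely state theirs.
* `bland_altman()`: mean, sample SD (n-1), limits mean ± k·SD. The default
  k is 1.96; k = 2 is available because the reference registration-accuracy
  row is consistent with ±2 SD rather than ±1.96 SD. The package keeps both
  rather than silently reconciling.
* `one_sample_ttest()`: two-sided Student t-test against zero via
  `stats::t.test()`; a zero-variance sample is a degenerate-sample error,
  not a silent p-value.
* `total_error()` and `build_error_report()`: signed mean shifts enter the
  quadrature (the square removes sign); report cells are rounded half away
  from zero to 2 decimals, the printed precision of the reference tables.
  No multiple-testing correction is applied across the six components,
  matching the reference analysis.

`reproduce_error_tables()` recomputes every total-error cell from the
bundled reference means. The phantom table reproduces 12 of 12 cells at
2-decimal precision; the patient table reproduces 11 of 12, with the
left-right C2 cell published as 1.39 where quadrature of the printed means
gives 1.395... → 1.40 — evidently computed from unrounded inputs upstream.
The report flags this cell in its `note` column instead of passing it
silently.

## Problem sizes and test design

The test suite exercises the engine at the phantom's native 64^3 size: a
20-transform recovery study (translations up to ±10 mm, rotations up to
±5°, acceptance at 95% of components within 0.5 voxel / 0.3°), plus
single-case self-registration and known-transform checks. The full
1350-registration accuracy protocol is exercised end-to-end with an oracle
registrar (exact bookkeeping, zero residuals) and with the real engine on a
reduced grid; running the complete protocol with the real engine is a
matter of minutes per hundred registrations and is left to the CLI.
Statistical calibration uses 10^4 null simulations for the t-test's type-I
error and replicate-cohort coverage checks for the simulator's
2·spread/√n offset-recovery claim, which is a per-component 95% statement
and is tested as such (coverage across replicates) rather than as a joint
all-components bound that a correct simulator would fail on half of all
seeds.

## Worked example

```{r example, eval = FALSE}
# phantom pair and a known displacement
ph <- generate_skull_phantom(phantom_config(seed = 7))
ctr <- volume_center(ph$ct)
t <- rigid_transform(translation = c(5, -2, 1), angles = c(1, 0.5, -2),
                     center = ctr)
displaced <- inject_transform(ph$mri, t)

# register back and compare
res <- register_rigid(ph$ct, displaced)
estimate <- invert_transform(res$transform)
transform_difference(t, estimate)

# cohort statistics and the total-error report
shifts <- simulate_cohort_shifts(cohort_config(seed = 7))
summarize_shifts(shifts)
build_error_report(shifts, list(xy_mm = -0.48, z_mm = -0.19,
                                rot_deg = 0.04))

# the reference tables, recomputed
reproduce_error_tables("phantom")
reproduce_error_tables("patient")
```

## Known limitations

* The engine is a standard Maes/Viola-class MI registration, not a
  reimplementation of any commercial algorithm; absolute agreement with a
  specific vendor's output is out of scope.
* Trilinear interpolation leaves O(contrast) pointwise residuals at sharp
  boundaries under repeated resampling; interior means stay small but
  voxel-level round-trip equality only holds for integer-voxel shifts.
* The cohort model is independent Gaussians; correlated or heavy-tailed
  patient motion is not simulated.
* Only axis-aligned NIfTI volumes are read; oblique orientations are
  rejected rather than silently re-sliced.
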