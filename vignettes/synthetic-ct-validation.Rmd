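---
title: "Validating synthetic CT for MRI-only brain radiotherapy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating synthetic CT for MRI-only brain radiotherapy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`sctval` implements the quantitative core of a clinical validation of
synthetic CT (sCT) for MRI-only brain radiotherapy planning: image-domain
accuracy of the sCT against a reference CT, geometric-distortion
quantification, dose-domain agreement of plans recalculated on the sCT,
and verification that the sCT can replace the CT as the reference image
for setup imaging. Because clinical images cannot ship with a package,
`sctval` also contains a seeded digital-cohort generator so every
analysis can be exercised, and its estimators verified, end to end.

This vignette documents the models and the numerical choices. Function
reference documentation lives in the roxygen help pages; a worked
example is in the README.

# Image model

Volumes are dense 3-D arrays with isotropic or anisotropic voxel
spacing and a physical origin; coordinates refer to **voxel centres**,
so voxel `(i, j, k)` (1-based) sits at `origin + (i-1, j-1, k-1) *
spacing` mm. Masks share the geometry and carry logical values. NIfTI
import/export is delegated to `RNifti`; the round trip through float32
is exact to single precision.

# HU accuracy metrics

For a region mask $R$ the package reports

* $\mathrm{MAE} = \frac{1}{|R|}\sum_{v \in R} |sCT_v - CT_v|$,
* $\mathrm{ME} = \frac{1}{|R|}\sum_{v \in R} (sCT_v - CT_v)$
  (positive = sCT overestimates HU),

over body, brain and bone regions, where bone is defined by the fixed
threshold $\mathrm{HU} \ge 250$ on the reference CT and restricted to
the body. Geometric agreement of bone is the Dice similarity
coefficient (DSC) between the 250-HU bone masks of CT and sCT. A
post-surgical sub-analysis restricts the same metrics to a
volume-of-interest: the resection cavity dilated by 10 mm, limited to
the axial slices the cavity occupies — the region where sCT conversion
models are most likely to fail because post-surgical anatomy is
under-represented in training data.

# Geometric distortion

Patient-induced distortion is computed from a B0 field map via the
standard readout-displacement relation

$$d\ [\mathrm{mm}] = \frac{\Delta B_0\ [\mathrm{Hz}]}{\mathrm{BW}\
[\mathrm{Hz/px}]} \times \text{pixel size}\ [\mathrm{mm}],$$

with defaults of 744 Hz/px bandwidth and 1.1 mm pixels, so a 744 Hz
off-resonance displaces exactly one pixel (1.1 mm). Statistics
(mean, SD, max, 99th percentile of $|d|$; quantile type 7) are
reported for brain, bone ($\ge 250$ HU) and intra-body air
($< -900$ HU) — air interfaces are where susceptibility gradients
concentrate. System-level (gradient-nonlinearity) distortion is
assessed on a marker phantom: marker blobs are detected by local
thresholding and connected components, centroids are matched to the
known template lattice by nearest neighbour, and displacement
statistics are summarised in radial bins from isocentre.

# Dose comparison

DVHs are accumulated on a fixed 0.01 Gy bin grid; $D_{x\%}$ is the
largest bin edge whose cumulative volume is still $\ge x\,\%$ — the
order-statistic definition at bin resolution — and endpoint
differences are reported in percent of prescription,
$(D^{sCT} - D^{CT})/\text{prescription} \times 100$. Agreement of full
distributions uses the global 3-D gamma index with a 15 % lower dose
cut-off applied to the reference distribution and dose differences
normalised to the prescription. Criteria 3 %/3 mm, 2 %/2 mm and
1 %/1 mm are evaluated. The gamma search samples a subgrid of step
DTA/10 within a radius of 3 × DTA, interpolating the evaluated dose
trilinearly; offsets are visited in order of increasing distance with
early termination once no closer offset can improve the minimum.
Positions falling outside the evaluated grid are skipped. The
implementation is in C++ (via Rcpp) and is verified in the test suite
against an exhaustive R re-implementation with no sorting and no early
exit.

# Setup-image replacement (registration deltas)

Whether sCT can replace CT as the setup reference is tested by
registering a simulated setup CBCT rigidly to the CT and to the sCT and
comparing the two 6-DoF results parameter-wise (three translations,
three Euler angles). Both registrations must share the same rotation
centre for the parameter deltas to be meaningful; the package uses the
intensity centroid of the bone window (200–1700 HU) of the fixed
image, and `registration_delta()` refuses to compare transforms with
different centres. Registration itself is multi-resolution pattern
search over normalised cross-correlation of the bone-windowed images
inside a head bounding box, followed by a Nelder–Mead polish.

A note on resolution: with 3 mm voxels, trilinear resampling of a
2-voxel-thick skull shell produces a partial-volume interference
pattern that can bias recovered rotations by up to ~0.5° even when the
optimiser finds the global optimum of the sampled objective. This is a
property of the discretisation, not of the optimiser; at 1.5 mm voxels
the same experiment recovers all parameters an order of magnitude
inside tolerance. The registration-QA experiments therefore run at
1.5 mm, while the cohort pipeline's setup-verification deltas — which
compare two registrations of the *same* moving image and share the
lattice artefact — remain valid at 3 mm.

Couch localisation emulates finding the treatment-couch top in a
low-SNR ZTE-like image by row-wise intensity projection and edge
detection; it reports the couch-top height and a found/not-found flag.

# The digital cohort

The generator is an emulation for verification, not a patient model. A
20-case cohort table mirrors a realistic clinical mix: prescriptions
24–60 Gy, PTV volumes 2–448 cc, 14 of 20 post-resection cases (cavity
diameters 10–30 mm), and a "complex geometry" flag on 7 cases. Each
case derives its own seed from the cohort seed, so any case is
reproducible in isolation.

A head phantom is an ellipsoidal head with skin, skull shell, brain,
an air cavity (sinus), and optionally carved spherical resection
defects; class HU means are water-like soft tissue, ~800 HU cortical
bone-shell, ~40 HU brain and −1000 HU air, with smooth intra-class
texture. The sCT is the CT plus class-conditional perturbations: a
configurable mean bone bias (default −40 HU, emulating systematic bone
underestimation by MR-to-HU conversion), per-class noise, and optional
bone *thickening* near resection sites (default 2 mm), emulating the
known failure mode of conversion models that hallucinate bone across
surgical defects. The B0 field is a smooth background polynomial
(amplitude 60 Hz over the body) plus a dipole-like term capped at
600 Hz around the air cavity. Dose is an analytic multi-beam model:
exponential depth attenuation through the density image (bilinear
HU-to-density ramp: $1 + \mathrm{HU}/1000$ below 0 HU, clamped at 0;
$1 + \mathrm{HU}/1950$ above), Gaussian lateral profiles, normalised to
the prescription as the target mean. The CBCT is the CT moved by a
known rigid offset plus noise.

What the generator does **not** emulate: MR acquisition physics, real
conversion-model residuals (spatially correlated errors, streaks),
scatter/beam-hardening in CBCT, heterogeneity-corrected dose transport.
The point is that every estimator in the package can be run against
inputs whose ground truth is known exactly — biases are recovered,
identical inputs give exactly null differences, and known rigid motions
are recovered to sub-voxel accuracy.

Grid sizes are package choices balancing fidelity against runtime: the
default phantom is 64 × 80 × 64 at 3 mm (a full head in ~1 s), the
registration-QA phantom 128 × 160 × 128 at 1.5 mm, and gamma oracle
grids 9 × 9 × 9 at 3 mm.

# Statistics

Cohort metrics are summarised as mean, SD, and range. Group
comparisons (resected vs not, complex vs not) use the Wilcoxon
rank-sum test: exact by complete enumeration when $n_1 + n_2 \le 12$
and tie-free (two-sided $p$ = twice the smaller tail, capped at 1),
otherwise the normal approximation with continuity correction. The
exact path reproduces textbook values (e.g. $p = 0.1$ for
$\{1,2,3\}$ vs $\{4,5,6\}$) and the approximate path matches
`stats::wilcox.test(correct = TRUE, exact = FALSE)`.

# Limitations

* The dose model is analytic; gamma and DVH agreement between CT and
  sCT doses reflects the injected HU perturbations only.
* Rigid registration only; no deformable component.
* The phantom's resection geometry is spherical; real cavities are not.
* Distortion analysis assumes the readout-direction model of Eq. 1
  (bandwidth-dominated EPI-free sequences).
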