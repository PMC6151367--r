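---
title: "Digital phantoms for radiomic stability analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phantoms for radiomic stability analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models: what each
stage computes, which assumptions it makes, which parameters matter, and
where the design was genuinely open.

## 1. Lesion shape model

Lesion shells are star-shaped solids defined in a stretched coordinate
frame:

\[ x \in \text{lesion} \iff \lVert Mx \rVert < R_0\,\bigl(1 + a\,f(u)\bigr), \qquad u = \frac{Mx}{\lVert Mx \rVert} \]

where \(R_0\) is the base radius (mm), \(a \in [0,1)\) the deformation
amplitude, \(f\) a seeded random field on the unit sphere, and \(M\) a
seeded rotation combined with a volume-preserving `diag(e, 1, 1/e)`
stretch, \(e = 1 + 0.9a\). The field \(f\) is a sum of 20 Fisher-kernel
lobes (concentrations 15–50), normalized by the 55th percentile of its
absolute value and clamped to \([-1, 1]\): the clamping matters, because
it puts sizeable surface patches at the extreme radii, which is what
drives sphericity down into the 0.5–0.75 range typical of segmented
patient lesions. Pure max-normalized smooth fields plateau near
sphericity 0.8 regardless of amplitude.

Properties guaranteed by construction: the shape is star-shaped about
the origin (single connected component, since \(a < 1\) keeps
\(R > 0\)); identical seeds give bit-identical rasterizations; volume
scales exactly as \(R_0^3\), which `shell_for_sphericity()` exploits to
hit a target volume with one rescaling after bisecting the amplitude
against the target sphericity (amplitude–sphericity is empirically
monotone for fixed seed, which the test suite asserts over a sweep).
Because the deformation floor varies with the seed, the fitter tries a
few derived seeds when the target sphericity is below the reachable
range of the first.

Ground truth is computed on a dedicated rasterization grid
(`resolution`, default 1.5 mm): volume from a sub-voxel occupancy field
(linearized signed radial distance), surface from a marching-tetrahedra
mesh of the continuous radial field (see section 6), sphericity from
\(\pi^{1/3}(6V)^{2/3}/S\).

## 2. Uptake model and heterogeneity ground truth

Compartments use nominal concentrations \(C_1\) (base, defaults drawn in
0.03–0.16 MBq/cc across the cohort), \(C_2 = 5C_1\) (high uptake) and
\(C_0 = 0\) (necrosis). The seven layouts `a`–`g` carve compartments as
quantile regions of the radial depth (concentric cores), of the
distance to seeded interior anchors (eccentric blobs and foci), or of a
projection (polar caps), so realized voxel fractions match the request
exactly up to rounding and sub-regions stay connected.

The heterogeneity ground truth uses the *nominal* concentrations and
realized voxel fractions — not image values — mirroring assay-based
ground truth rather than image measurements:

* `COV_GS`: population standard deviation over mean, volume-fraction
  weighted, ×100. Necrotic voxels participate; an all-necrotic lesion
  (zero mean) is an error.
* `I_G-GS` (Gini): with modality frequencies \(p_i\) over the distinct
  concentrations, \((1-\sum p_i^2)\cdot k/(k-1)\) for \(k\ge 2\), else 0.
  The normalization is a deliberate choice: the index must reach 1 at
  maximal heterogeneity, which the unnormalized \(1-\sum p_i^2\) cannot
  do for \(k = 2\). It is permutation-invariant and maximal at uniform
  frequencies.
* `H_GS = COV_GS × I_G-GS`, 0 for homogeneous lesions, ≤ 100 over
  two-level \(C/5C\) configurations.
* Necrosis is included in the COV/Gini modality set but excluded from
  the *active* volume `v_gs_active`, which is the denominator of the
  segmentation volume error.

## 3. The default cohort

`build_study()` reproduces the study template: five shells A–E with
volumes 6.8/10.5/8.5/12.5/32.3 cc and sphericity targets
0.57/0.62/0.49/0.74/0.73; nine acquisitions totalling 38 lesions, 20
homogeneous; lesion-to-background ratios 4–27; heterogeneous lesions
with printed total-heterogeneity values 12.7–62.2. For each
heterogeneous lesion the necrosis fraction follows from the printed
active volume, and the \(C_2\) fraction is solved numerically (grid
search over 500 candidates) so the generated `H_GS` matches the printed
value; generated and printed values agree to ~0.1. A consequence of
this choice is that necrotic template lesions also carry a small
\(C_2\) focus (layouts `f`/`g`): with the Gini normalization above, a
two-modality necrosis-only configuration constrained to the printed
active volume cannot reach the printed `H_GS`, so the third modality
absorbs the difference. The `a`–`e` layouts remain available through
`uptake_config()`.

## 4. Acquisition and reconstruction emulation

Scanner reconstruction is emulated in the image domain; sinogram-level
OSEM/PSF/TOF is out of scope. The chain is: rasterize the nominal
concentration field onto the reconstruction grid (in-plane voxel =
`fov_mm / matrix_size`, default 700/256 ≈ 2.73 mm; slice 3.27 mm) with
2×2×2 sub-voxel supersampling (conserves the activity integral across
matrix sizes to well under 1%); convolve with the system PSF; add
seeded Gaussian noise with variance proportional to the local signal
(`sd = noise_scale · sqrt(0.01 · x)`, a Poisson-like surrogate); apply
the post-reconstruction Gaussian filter.

The protocol grid maps onto surrogates:

| knob | emulation |
|---|---|
| matrix size 128/192/256 | voxel size 5.47/3.65/2.73 mm |
| PSF modelling on/off | effective blur FWHM 4.5 / 6.3 mm |
| TOF on/off | noise scale × 0.75 / 1 |
| iterations × subsets | noise scale × sqrt(it·sub / 54) |
| filter FWHM 5/7 mm | post-filter width |

`noise_scale = 0.25` is the package's default acquisition condition: it
was chosen once so that a uniform liver-like region (0.013 MBq/cc) at
the standard protocol shows a region-of-interest COV of about 4–5%,
comfortably inside the < 8% noise QA bound that the emulated protocol
is meant to satisfy; the suite checks the bound, not the design value.
Test-retest pairs reuse the same signal chain with two derived noise
seeds.

What the emulator deliberately does *not* model: scatter, attenuation,
randoms, dead time, reconstruction nonlinearity (OSEM noise is not
Gaussian, and its bias interacts with iteration count), patient motion,
and inter-scanner differences. Two consequences matter when reading
results. First, the image is *linear* in the nominal concentrations:
lesion contrast enters only through the lesion-to-background ratio, so
in noiseless calibrations the optimal adaptive-threshold coefficient is
exactly independent of L/B (the shipped table shows this: ε varies with
diameter, not L/B; the L/B axis is kept for interface fidelity and for
recalibration on noisy data, where the degeneracy breaks). Second,
passing stability tests here demonstrates correctness of the pipeline
under the modeled degradations, not robustness to everything a real
scanner does.

## 5. Segmentation

*Fixed threshold*: voxels ≥ 60% of the within-region maximum, inclusive
comparison (the maximum voxel always belongs to the MTV), largest
26-connected component kept.

*Adaptive threshold*: iterative background-corrected rule
\(T_k = \varepsilon(\hat V_k, \widehat{L/B}_k)\,(\bar u_k - B) + B\)
with \(\bar u_k\) the mean uptake of the current mask and \(B\) the
background estimate (border-shell median when not supplied).
Convergence: relative volume change ≤ 0.5%, max 50 iterations;
non-convergence raises an error carrying the last iterate. The ε table
is calibrated by golden-section search on noiseless PSF-blurred
simulated spheres (diameters 12–36 mm × L/B 3–30); lookups interpolate
over measured L/B within each diameter row, then across volumes, both
on log scales, clamped at the borders. The shipped table
(`inst/extdata/adaptive_calibration.csv`) is regenerated by
`tools/make_calibration.R` and by `calibrate_adaptive()` (deterministic
given its seed). Spheres near the resolution limit (≲ 8 voxels across)
remain partial-volume dominated; the table's own 12 mm row carries a
~17% training error, and the held-out validation in the test suite
therefore uses well-resolved sizes.

Volume error convention: `mtv_percent_error()` returns
\(100\,(V^{active}_{GS} - MTV)/V^{active}_{GS}\) — positive =
under-segmentation. Published tables in this literature are not
consistent about this sign; the convention here is fixed, documented,
and switchable (`sign = "mtv_minus_gt"`), and the test suite pins both
directions.

## 6. Surface meshes

No iso-surface extractor is assumed from the environment; the package
implements marching tetrahedra (six-tetrahedra cube decomposition
around a consistent diagonal, linear edge interpolation), which yields
a closed triangulation for any level set away from the array border.
Voxel-face counting was rejected: it overestimates surface area by
~50% on spheres and would bias every sphericity down.

For *binary masks* (the morphological features), the occupancy field is
smoothed with a 1-voxel Gaussian before extracting the 0.5 level — this
anti-aliases the staircase — and the known first-order curvature bias of
level-set smoothing (the surface moves inward by ≈ σ²·mean curvature)
is corrected with the volume-equivalent-radius factor
\(1/(1 - 2\sigma^2/r_{\mathrm{eff}}^2)\), exact for spheres. The suite
checks digital spheres (2% tolerance at radius 20 voxels) and a 4:1:1
prolate spheroid against its closed-form area. The correction is least
accurate for shapes whose local curvature differs strongly from
\(1/r_{\mathrm{eff}}\) (thin lobes, plates) and for masks only a few
voxels across.

## 7. Feature definitions and numerical choices

Preprocessing: tri-linear isotropic resampling to the in-plane pixel
size (nearest-neighbour for the mask; already-isotropic inputs pass
through bitwise unchanged), then fixed-bin-count discretization of the
within-mask range onto 64 levels (min → 1, max → 64). Mask-relative
bounds are used because the discretization is applied to the MTV
content; "axial size" is read as the in-plane *pixel* size, the other
reading (matrix size) being dimensionally unusable as a target spacing.

Texture matrices use 26-connectivity via its 13 unique direction
vectors. Directional GLCM/GLRLM matrices are *merged* (summed) before
feature computation, not averaged per direction — with the alternative
exposed through the per-direction matrix API. Formulas follow the
standard Vallières/IBSI lineage and are documented at each function.
Conventions worth making explicit:

* GLCM: symmetric normalized matrix; SumAverage is the mean of the
  \(i+j\) marginal; Variance and Correlation use the marginal mean.
* GLRLM: run percentage divides by voxels × directions, so a fully
  fragmented region reaches RP = 1; GLV/RLV are run-probability
  weighted variances.
* GLSZM: zones are 26-connected equal-level components (orientation
  free, single matrix); ZP = zones / voxels.
* NGTDM: neighbourhood means are restricted to in-mask neighbours;
  denominators are ε-guarded (ε = 1e-12); Coarseness is capped at 1e6
  on constant regions.
* Degenerate inputs (constant region, single voxel) produce documented
  sentinel values plus a per-group flag, never missing entries, so
  cohort tables stay rectangular: histogram Skewness/Kurtosis 0,
  Entropy 0, Uniformity 1; GLCM sentinel of the one-cell matrix;
  morphological surface of a single voxel falls back to the voxel
  cuboid.

Feature vectors carry group-qualified names (`GLCM_Energy`,
`HIST_Energy`, ...) because the display names recur across groups; the
registry (`feature_registry()`) maps them to the display name and group
and is frozen by a golden test (58 = 5 + 13 + 9 + 13 + 13 + 5).

## 8. Statistical battery

* **Friedman vs segmentation**: with exactly two methods the Friedman
  statistic is a function of the sign of per-lesion differences only,
  so the exact two-sided sign-test p-value is used (ties dropped);
  three or more methods use the chi-square Friedman test. Stability ⇔
  p ≥ 0.05. The suite verifies the empirical type-I error at n = 38
  lies in [0.03, 0.07] over 1000 null replicates.
* **COV vs reconstruction**: per one-factor settings family, the COV of
  each feature across the family's settings is computed per lesion and
  averaged over lesions ("average of all lesions"); the representative
  COV is the worst family value; classes cut at 5/10/20% (right-closed
  boundaries, unit-tested exactly); the headline flag is representative
  COV ≤ 10%. Near-zero feature means use |mean| with a flag rather than
  dropping the feature.
* **Test-retest ICC**: one-way random single-measure ICC(1,1) by
  default — sensitive to systematic shifts, which is what "pairwise
  agreement" should penalize; two-way consistency ICC(3,1) behind a
  flag. Reproducible ⇔ ICC > 0.6 in both of the two test-retest pairs.
  Zero between-lesion variance flags the feature non-reproducible.
* **Mann–Whitney** homogeneous vs heterogeneous, two-sided, normal
  approximation with tie correction; discriminative ⇔ p < 0.05.
* **Correlation with H_GS**: Spearman by default (texture–heterogeneity
  relations are monotone but rarely linear); Pearson by flag.
* **Sphericity agreement**: two-sided paired t-test against `S_GS`,
  necrotic lesions excluded upstream (their active surface is
  undefined); degenerate all-equal differences short-circuit to p = 1
  (no shift) or p = 0 (constant shift).
* No multiple-testing correction in the headline flags (per-feature
  p < 0.05 readout); Benjamini–Hochberg columns are emitted alongside
  for transparency.

`build_report()` joins everything into one row per feature, emits the
summary fractions and the reproducible → discriminative → correlated
funnel counts, and is a pure function (identical inputs ⇒ identical
CSV).

## 9. Determinism and orchestration

Every stochastic operation is a pure function of an integer seed. A
master seed fans out through a counter-based Lehmer step
(`child_seed()`), so stages can be re-run independently and the whole
`run_study()` output — ground truth, features, report, summary — is
byte-identical across runs with the same configuration. Configurations
are validated (`study_config()`), reject unknown YAML keys, and
round-trip losslessly; each run writes a manifest with the package
version, config hash and seeds.

## 10. Problem sizes in the shipped tests

The test and acceptance suites run the same code paths as a full study
at reduced scale, a deliberate sizing choice: texture oracles
brute-force volumes up to 6×6×6; statistical calibration uses 1000 null
replicates at the cohort's 38/20/18 sample sizes; segmentation-bias
checks use six noiseless lesions of 5–10 cc; the end-to-end determinism
check runs a 6-lesion cohort on the matrix-size settings family twice.
The full 38-lesion, 14-setting study is what `run_study()` executes by
default from a single seed.

## 11. Known limitations

* The emulator's linearity and Gaussian noise understate
  reconstruction-driven feature variability, especially for
  iteration/subset effects that are bias-driven in real OSEM.
* Shape ground truth is star-shaped by construction: no concavities
  that break star-shapedness, no disconnected or toroidal lesions.
* Mesh-based surfaces are least reliable below ~4 voxels radius;
  morphological features of very small MTVs inherit that bias.
* The adaptive method is one representative of the background-corrected
  iterative threshold family; it is calibrated on spheres, and its
  small-lesion behaviour is partial-volume limited by design.
* The Gini index is the normalized categorical form; Lorenz-based
  concentration variants would differ for k ≥ 3, and the normalization
  choice is recorded in the ground-truth output (`gini_gs` column) and
  here.
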