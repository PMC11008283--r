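---
title: "Models, phantoms and design choices in petlong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, phantoms and design choices in petlong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

petlong evaluates partial-volume-correction (PVC) methods for longitudinal
tau-PET SUVR and estimates change with linear mixed-effects models (LMEM).
This vignette documents the models, the synthetic worlds the package tests
itself on, and the design decisions that were genuinely open.

## 1. The measurement model

A PET image is treated as the true piecewise-constant activity convolved
with an isotropic Gaussian point spread function (PSF) of full width at
half maximum `fwhm_mm`, plus multiplicative noise. Two FWHM operating
points matter in practice: ~5 mm for a single-site study after post-hoc
filtering, and 8 mm as the harmonized multisite target resolution; the
package exposes one `fwhm_mm` knob rather than compounding intrinsic and
filter resolutions, because only the total is identifiable from either
setting's description.

Convolution uses zero padding. The phantom builder therefore enforces a
background margin of at least 3×FWHM around the head, which makes
in-volume mass conservation hold to better than 1e-6 and removes the
boundary-dialect ambiguity. Two independent convolution implementations
(separable banded-matrix, and zero-padded FFT) realize the same discrete
operator and are required by the tests to agree to 1e-8; neither is
derived from the other, so their agreement is a genuine cross-check.

## 2. PVC methods and their numerical choices

* **Meltzer (2-compartment)**: `pet / (brain ⊗ h)` where the smoothed mask
  is at least `mask_threshold`. The threshold is unstated in the source
  material; the default is 0.5, excluded voxels are counted and reported.
* **Müller-Gärtner (3-compartment)**: white matter is the mean of the
  *uncorrected* image over an eroded WM mask (default 2 shells of
  6-connected erosion ≈ 4 mm at 2 mm voxels), CSF is assumed 0; corrected
  values exist where the smoothed GM mask is at least `gm_threshold`
  (default 0.3); negative voxels are floored at 0 and counted.
* **van Cittert**: the classical iteration with a nonnegativity clamp,
  f₀ = g, f_{k+1} = max(f_k + α(g − h⊗f_k), 0). The source citation does
  not pin down the reblurred vs classical dialect; classical-with-clamp is
  implemented and the choice is visible in the diagnostics (residual norms
  per iteration). Default: at most 30 iterations, stopping early when the
  residual norm changes by less than 1e-4 relative.
* **GTM**: W[i,j] = mean over region i of the blurred indicator of region
  j, over *all* non-background compartments (cortical ROIs, WM, CSF,
  skull, meninges when present), so extra-cortical signal is modelled
  rather than assumed zero. The system is solved by least squares; the
  condition number is reported and a configurable cap (default 1e6)
  converts ill-conditioning into an actionable error. Note a normalization
  subtlety: because W entries are region means, mass conservation is the
  count-weighted statement Σᵢ|Rᵢ|·W[i,j] ≤ |Rⱼ|, not a plain column sum.
* **RBV**: `pet · s / (s ⊗ h)` with s the painted GTM solution; voxels
  where the denominator falls below 1% of its maximum are left
  uncorrected, and the run errors if more than half the brain is invalid.

Regional means of corrected images are taken over each method's validity
mask; composites (e.g. whole cortical gray) with no valid voxels under a
method — white matter under the GM-only 3-compartment correction — are
dropped rather than silently filled with zeros.

## 3. The digital phantom

The default phantom is a nested-sphere head on a 64³ grid of 2 mm voxels:
skull and meningeal shells, a CSF envelope, a cerebral gray-matter shell
divided into six azimuthal sectors (frontal, parietal, occipital, rest
temporal, lateral temporal, mesial temporal — the mesial sector smallest,
matching its role as the noisiest composite), a white-matter core with a
ventricular cavity, and a separate cerebellar-gray reference blob. True
activities are SUVR-like (reference = 1): cortical 1.15–1.55, white matter
1.10 (off-target binding), meninges 0.30, CSF 0.10.

Two geometry choices matter and were revised during development:

* **Cortical thickness 6 mm**, i.e. thinner than the 8 mm PSF. With a
  thick shell, an ROI that tracks atrophy exactly shows almost no signal
  decline (removing the most-diluted boundary voxels compensates the extra
  dilution of the rest), and the atrophy confound the phantom must exhibit
  disappears. With the ribbon under one FWHM every GM voxel is partial-
  volume diluted, and 5%/yr atrophy produces the expected ~ −1%/yr drift
  in uncorrected whole-cortical-gray SUVR while GTM-corrected values stay
  flat.
* **Atrophy = erosion ordered by geodesic distance from the CSF front.**
  Plain morphological erosion of the GM mask consumes the ribbon from both
  its CSF and WM faces, creating a nonphysical CSF moat at the GM/WM
  interface. Ordering removal by distance from CSF (ties broken by array
  index, so series are deterministic and monotone) models sulcal widening:
  voxels are reassigned to CSF at the anatomically correct surface. The
  cumulative fraction removed at time t is `annual_atrophy_fraction · t`
  of the baseline GM voxel count, exact to rounding.

The cerebellar reference is placed 6 mm clear of the cerebrum: when it was
adjacent, cortical atrophy changed the spill-in to the reference and
corrupted every SUVR trend (a realistic failure mode, but not the one
under test).

What a green phantom test does **not** establish: real anatomy (convoluted
sulci, sub-voxel thickness variation), non-Gaussian or spatially varying
PSFs, scanner reconstruction effects, motion, or registration error. The
phantom validates the algorithms' mathematics, not their clinical
performance.

## 4. The cohort simulator

Long-format lnSUVR tables follow exactly the generative model the LMEM
assumes:

lnSUVR_ij = μ_{g,roi} + β'x_i + u_i + (b_{g,roi} + v_i)·t_ij + ε_ij,

u_i ~ N(0, σ_u²(g)), v_i ~ N(0, σ_v²(g)), ε ~ N(0, σ²) iid. Defaults are
the published cohort structure: the natural-history preset has groups of
10/24/15/14 (CU/prodromal/mild/moderate), visits at 0/26/52/78 weeks with
jitter SDs 2.5/3.23/3.6 weeks and retention 1/0.889/0.810 (the realized
56/63 and 51/63 follow-up counts); the multisite preset has 122/212
(prodromal/mild), visits 0/49/73 weeks, jitter 3.35/3.8, retention
0.940/0.862. Baseline lnSUVR means are ln of the printed group-mean SUVRs
(a matched-CV lognormal approximation, since the tables print SUVR-scale
means); slopes are ln(1 + pct/100) of the printed annualized percent
changes; σ = 0.03 (single-site, the printed ~3% within-subject
variability) and 0.04 (multisite, the upper end of the printed 3–4%
range). Random-intercept SDs come from each group's baseline TMP
coefficient of variation; random-slope SDs from the whole-cortical-gray
effect sizes (SD = |mean|/ES on the percent scale), giving ~0.009–0.024
per year. Covariate effects (APOE4, age, sex, centiloid) default to zero:
the source model treats them as nuisance intercept adjustments and prints
no coefficients, and zero defaults keep parameter-recovery tests sharp;
hooks exist to set them. Weeks convert to years at 52.1775 weeks/year
(365.25-day year), fixed for reproducibility.

Tau levels are assigned from the generated baseline temporal-meta-ROI
(TMP) SUVR quartiles of the AD subjects, with linear-interpolation
quantiles (R type 7) — the convention is configurable because printed cut
points depend on it — and the closed/open pattern low ≤ Q1 < mid ≤ Q3 <
high; the published fixed pair (1.30, 1.75) is available as an override.
Dropout is independent per visit (monotone dropout is available but off);
a rise-then-fall trajectory option exists for robustness experiments and
is off by default.

## 5. Mixed-model estimation and derived statistics

`fit_lmem` fits by REML (ML optional) through lme4 with independent random
intercept and slope, `(1|subject) + (0 + time|subject)`. Degrees-of-
freedom ambiguity is resolved by using the normal approximation
throughout: a contrast is significant when its t-score exceeds 1.96,
matching the evaluation criterion the package implements. Group slopes
are the reference slope plus interaction coefficients; per-subject slopes
add the random-slope BLUP (covariates affect intercepts only in both model
presets, so subject slopes are covariate-free by construction). The
three-way multisite grouping (diagnostic × tau level) is reparameterized
as a single cell-means factor crossed with time, which spans the same
slope space as the factorial expansion and keeps every contrast readable.
Subjects with unknown APOE4 status are retained via an explicit factor
level rather than dropped.

"Bootstrap from posterior simulations" is read as parametric draws of the
fixed effects from N(β̂, V̂); a subject-resampling bootstrap is provided as
the alternative and is used for statistics that are functionals of the
per-subject values (effect sizes, Spearman correlations). Percentile 95%
intervals; draws where a statistic is undefined (degenerate resamples)
are dropped.

Two honest findings from the synthetic world are worth recording:

* At the literal natural-history sample size (63 subjects, ≤4 visits),
  the random-slope SD σ_v ≈ 0.01 is weakly identified against σ = 0.03
  and REML estimates pile up at zero in a nontrivial fraction of
  replicates; recovery bias measurements are therefore run at the ~500-
  subject operating point (group proportions ×8), where all components
  recover within a few percent and Wald CIs cover at ~95%.
* With the balanced four-visit schedule and iid lognormal noise, the
  endpoint per-visit change estimator is nearly as efficient as the LMEM
  slope (slope information concentrates at the endpoints), so the LMEM's
  bootstrap CI is narrower only ~60% of the time, although its effect
  size is essentially always larger (BLUP shrinkage). The clearly
  narrower CIs reported on real data must therefore also reflect
  irregularities — nonlinear rise-then-fall trajectories (observed in
  ~36% of trial participants), variable intervals, site effects — that
  the default generator deliberately omits. The corresponding acceptance
  clause is asserted at its stated level and is expected red; this is a
  property of the stated synthetic world, not of the estimator code.

## 6. The RBV overcorrection mechanism

The package reproduces, by construction, the mechanism by which RBV can
overcorrect high-tau cortex: CSF is modelled as one homogeneous GTM
region, but its true signal is heterogeneous — stable near the cortex,
declining elsewhere (ventricles, deep CSF). The merged-CSF GTM estimate
then declines over time, the painted synthetic image declines next to the
cortex, and the RBV denominator s ⊗ h shrinks at cortical voxels whose
actual signal is stable — amplifying them. The 3-compartment method, which
assumes CSF = 0 at all times, is immune. In the test phantom the CSF
envelope within 3 shells (~6 mm) of the cortex is held constant while the
remainder declines at −0.5/yr on the log scale; RBV then shows ~ +1%/yr
spurious cortical change while Müller-Gärtner stays within ±0.15%/yr.

## 7. Degenerate inputs and numerical guards

Empty masks, erosion to emptiness, atrophy that consumes an entire ROI,
non-positive reference means, SUVR ≤ 0 under the log transform, singular
interaction cells (a group with fewer than two distinct visit times),
all-identical stratification values, and GTM condition-number overflow
are explicit errors that name the offending object. Reported estimates
are written to CSV with 9 significant digits so pipeline reruns at a
fixed seed are byte-identical.

## 8. Known limitations

Isotropic voxels and PSFs only; no registration or MRI segmentation (the
segmentation is taken as given, on the PET grid); no nonlinear trajectory
models (the linearity assumption is itself only defensible over ~1.5
years); no treatment-arm structure; the phantom's geometry is schematic.
The NIfTI reader/writer covers the single-frame little-endian subset the
package emits (validated against nibabel) and is not a general NIfTI
implementation.
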