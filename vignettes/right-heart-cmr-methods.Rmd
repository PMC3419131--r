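---
title: "Right-heart CMR measurement and diagnostic accuracy: methods"
author: "rhcmr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Right-heart CMR measurement and diagnostic accuracy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhcmr)
```

`rhcmr` quantifies right-heart cardiovascular magnetic resonance (CMR)
measurements from segmented inputs and evaluates their diagnostic
accuracy for pulmonary hypertension (PH), defined as catheter mPAP ≥ 25
mmHg.  This vignette is the package's account of its models, conventions,
numerical choices and limitations.

## Volumetry by slice summation

Cavity volumes come from Simpson's method on a contiguous short-axis
stack: the shoelace area of each traced endocardial polygon times the
effective inter-slice distance, summed base to apex.  The inter-slice
distance is carried explicitly by the contour format; its default of
10 mm corresponds to the common acquisition of 8 mm slices with a 2 mm
gap.  Slices without a contour contribute zero volume — no apical or
basal extrapolation — matching manual workstation practice, where the
observer simply does not trace slices without discernible cavity.

End-diastole is fixed at cine phase 0 (the first phase of an R-wave
triggered acquisition).  End-systole is the phase minimising the *summed*
endocardial volume, with ties broken toward the earliest phase.  A
per-slice minimum would compose a non-physical phase from different time
points, so it is not offered.  Whether the LV end-systolic phase should
be selected independently of the RV is genuinely open; the fitting
function exposes `es_mode = "per_structure"` (default) and `"shared"`,
which only matters for LV cavity metrics since masses are end-diastolic
in either mode.

Myocardial mass is the epicardial-minus-endocardial volume times the
myocardial density 1.05 g/cm³.  The inter-ventricular septum counts with
the left ventricle: an RV epicardial contour traces the free wall only,
and the package enforces on every slice that an epicardial contour
encloses at least its endocardial partner's area.  The ventricular mass
index (VMI) is RV mass over LV mass.  Units are centralised: contours in
mm, volumes in mL, masses in g.

Body surface area uses the Du Bois formula
$0.007184\,h^{0.725}\,w^{0.425}$ (h in cm, w in kg) when no measured BSA
accompanies the data; cohort tables may carry BSA directly and bypass it.

**Numerical behaviour.** A regular $n$-gon underestimates its circle by a
factor $\frac{n}{2\pi}\sin\frac{2\pi}{n}$; at the default 64 vertices
this is 0.16%, and the test suite asserts convergence of cylinder and
half-ellipsoid phantoms to their closed forms within 1% at 64 vertices
and 1 mm slice spacing.  The half-ellipsoid phantom samples areas at
slice midpoints, so the summation is a midpoint rule with $O(d^2)$ error.
Mass equals 1.05 × the wall volume from the very same summation, so the
identity `mass = (V_epi − V_endo) × 1.05` holds to machine precision, not
approximately.

## Functional indices

From paired end-diastolic/end-systolic 4-chamber landmark frames:

- **TAPSE** — change of the tricuspid annulus–apex distance (cm).  Any
  annulus point the annotator provides is accepted; the package does not
  restrict to the lateral annulus.
- **fractional TAAD** — TAPSE over the end-diastolic annulus–apex
  distance, in percent (scale-free).
- **SFD excursion / fractional SFD** — change of the septum–free-wall
  perpendicular distance at mid-ventricle.  The midpoint is defined as
  50% of the apex–annulus axis; the annotator supplies the septal and
  free-wall points, and the package takes their distance.
- **RVRAC** — 100·(A_ED − A_ES)/A_ED from planimetered 4-chamber areas.
  Note the *diastolic* denominator.
- **eccentricity index** — D2/D1 of two perpendicular LV minor-axis
  diameters on the mid-chamber short-axis image (D2 parallel to the
  septum); the systolic frame gives sEI, the diastolic frame dEI, with
  values above 1.2 read as septal flattening.

Negative excursions (paradoxical motion) are returned signed, never
clamped, so threshold rules operate on the physiologic scale.  All
metrics are invariant under rigid motion of the landmark coordinates, and
the fractional metrics under uniform scaling; both properties are
asserted over hundreds of randomly parameterised synthetic landmark sets.

## Phase-contrast flow

Velocity-encoded frames are bin averages from retrospective gating, so
each of the $n$ frames represents $RR/n$ seconds and per-beat volumes are
frame sums, not trapezoids.  Per-frame flow is $\sum v\,\Delta A$ over
the PA mask (cm/s × cm² = mL/s) with antegrade flow positive.  The
retrograde volume per beat integrates only negative-velocity pixels; the
retrograde flow index converts to L/min and divides by BSA.  The
retrograde percentage divides by the *antegrade* volume per beat (a
convention the package documents because alternatives exist); when no
antegrade flow is present the percentage is undefined (`NA` with a
warning) while the index is still returned.  PA areas are mask pixel
counts times pixel area; pulsatility is 100·(max − min)/min over the
cycle — the minimum-area denominator, deliberately different from RVRAC.
Velocity aliasing is out of scope: inputs are assumed unwrapped (venc
well above peak velocities).

## Echo pressure chain

TG = 4·TRJV² (modified Bernoulli), PASP = TG + estimated RAP, and
mPAP = 0.61·PASP + 2 mmHg for comparison with catheter mean pressure.
TRJV is in m/s throughout: clinical tables occasionally label jet
velocities "cm/s", but Bernoulli inputs at that scale would be absurd, so
the package standardises on m/s.  The composition is strictly increasing
in TRJV, asserted in tests.

## Diagnostic statistics

Threshold rules are boundary-inclusive with a declared direction
(`GE_POSITIVE` for e.g. VMI ≥ 0.4, `LE_POSITIVE` for e.g. TAPSE ≤ 2 cm).
Records missing a metric are dropped from that rule's analysis, so each
rule reports its own denominator — reproducing the familiar pattern of
per-modality subsets (late-enhancement and phase-contrast imaging being
available in only part of a cohort).

- **Fisher's exact test**: two-sided as the sum of hypergeometric
  probabilities not exceeding the observed table's (with a 1e-7 relative
  tolerance, the same convention as `stats::fisher.test`).  The
  implementation is checked against an exhaustive binomial-coefficient
  enumeration for *every* 2×2 table with total count ≤ 30, and against
  `stats::fisher.test` on random tables.
- **ROC/AUC**: rank-based (Mann–Whitney) with midrank ties.  The
  direction is declared per metric, never inferred from the data, so a
  degenerate sample cannot silently flip a rule.  A dichotomous marker's
  AUC equals (sensitivity + specificity)/2 exactly; the identity is
  asserted, as is invariance under strictly monotone transforms, and
  agreement with `pROC` on continuous data.
- **Group comparisons**: pooled-variance Student t by default (Welch by
  flag), chi-square for categorical data, one-way ANOVA with
  Bonferroni-adjusted pairwise t-tests beyond two groups.  These call
  `t.test`, `chisq.test`, `aov` and `pairwise.t.test`.
- **Bland–Altman**: bias ± 1.96·SD of paired differences.
- **Reporting precision**: percentages round half-up to integers, AUC to
  two decimals, correlations to two decimals — applied only at the
  reporting layer; all internal values keep full precision.

`predictive_values()` reconstructs PPV/NPV from a published operating
point (sensitivity, specificity) and group sizes via the Bayes identity
$PPV = sp/(sp + (1-c)(1-p))$; the same identity is asserted against
`confusion_metrics()` on random tables.

## Synthetic data

**Phantoms.** Ventricle phantoms polygonize cylinders, half-ellipsoids
and concentric shells whose volumes and masses are closed-form;
contraction scales every cavity area by a smooth factor reaching the
programmed systolic fraction at a declared phase, so EDV, ESV, EF and the
ES phase index are exact ground truth.  Velocity phantoms lay a parabolic
antegrade profile over systolic frames and a uniform retrograde patch
over diastolic frames, then rescale so per-beat volumes match the request
exactly; mask radius can pulse to program area pulsatility.

**Cohort generator.** Each group draws catheter mPAP from a truncated
normal (no-PH below 25 mmHg, PH at or above), and every metric through a
Gaussian copula: the latent correlation is $2\sin(\pi\rho_s/6)$ for a
target Spearman $\rho_s$, and the marginal is a truncated normal whose
*underlying* parameters are solved (Nelder–Mead on the closed-form
truncated moments) so the requested mean/SD are recovered *after*
truncation.  Pulmonary vascular resistance is the one exception: its
no-PH dispersion exceeds its mean, which no zero-floored truncated normal
can produce, so PVR uses a moment-matched lognormal — the classical model
for a strongly right-skewed resistance.  Correlation signs follow group
physiology (retrograde flow rises with pressure); published correlation
tables occasionally carry sign inconsistencies, and the generator treats
the magnitude as the specification.  Because mPAP is drawn within group
relative to the 25 mmHg boundary, the group-label invariant holds by
construction.

Clinical subgroups are allocated to PH patients by largest-remainder
proportional scaling of the configured mix (the published subgroup counts
sum to 192 against a stated 194, so exact counts cannot be preserved
under any allocation); late-gadolinium-enhancement status is Bernoulli at
the group rate within a per-group measured subset, and phase-contrast and
echo metrics exist only in their measurement subsets (106, 195 of 233 by
default).  Records can be appended with a `non_diagnostic` flag to
emulate quality-failure exclusions; the pipeline drops them before any
analysis.  The whole specification ships as versioned YAML
(`inst/extdata/cohort_defaults.yaml`); identical seeds give byte-identical
cohorts.

Where the defaults are not dictated by the cohort structure above they
are single, documented choices: BSA 1.85 ± 0.20 m² (groups reported as
not significantly different, no values printed), PVR–mPAP rank
correlation 0.8 (tightly coupled haemodynamically but not printed), RAP
estimates on the clinical {5, 10, 15} mmHg grid with group-dependent
weights, and an mRAP/CO/CI correlation magnitude of 0.4–0.5.

**What the generator does and does not emulate.** It reproduces group
marginals, within-group metric–pressure coupling, subset structure and
annotation rates — enough to exercise every statistical path at realistic
operating points.  It does not model real ventricular shape, regional
wall motion, papillary muscles, segmentation error, velocity noise or
aliasing, inter-metric correlations beyond the shared mPAP factor, or
longitudinal change.  Passing tests therefore validate the *computation*,
not clinical performance on real images.

## Test problem sizes

The suite validates phantom convergence at 64 vertices and 1 mm spacing
(cylinder and 90-slice half-ellipsoid), functional-metric recovery over
200 random rigid-motion parameterisations, the Fisher implementation over
all 46,375 non-empty 2×2 tables with n ≤ 30, correlation sampling
behaviour over 100 replicate draws at n = 233, and generator recovery at
n = 10,000 per group — marginal means/SDs within the spec's absolute
bands (e.g. VMI mean and SD within 0.01) or 3.5σ Monte-Carlo bands, and
rank correlations within ±0.02.  The default suite runs in well under a
minute.

## Known limitations

- Volumetry assumes contours live on a contiguous equal-spacing stack;
  variable spacing per slice is not supported.
- The simple-polygon check is O(n²) per contour — fine for manual
  contours (≤ ~100 vertices), not meant for dense automated masks.
- No confidence intervals for AUC; none are reported by the reporting
  layer, keeping parity with integer-percent accuracy tables.
- The copula couples each metric to mPAP only; conditional on mPAP,
  metrics are independent, which understates real inter-metric
  correlation (e.g. VMI with RV mass index).
- Echo RAP estimation from IVC imaging is not modelled; RAP is an input.
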