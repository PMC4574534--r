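---
title: "Methods: whole-body atheroma scoring, LV volumetry and cohort statistics"
author: "wbcvmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body atheroma scoring, LV volumetry and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcvmr)
```

# The quantification problem

Whole-body cardiovascular MR combines contrast-enhanced angiography of the
arterial tree from the carotids to the calves with a cine cardiac MR study of
the left ventricle. In cohort studies of type 2 diabetes and cardiovascular
disease the two readouts of interest are (i) a single standardised measure of
systemic stenotic atheroma burden, and (ii) left-ventricular mass, volumes and
function. This package implements both quantification chains and the
statistical battery used to compare them across the four design strata
(diabetes with CVD, diabetes alone, CVD alone, healthy controls), together
with a synthetic cohort generator so that the full pipeline can be exercised
and validated without patient data.

# Standardised atheroma score

## Taxonomy and grading

The arterial tree is read as 31 vessel segments in five anatomical
territories — head and neck (9 segments), aorta (3), abdominal branches (5),
ilio-femoral (6), and popliteal/infrageniculate run-off (8) — acquired over
four imaging stations. The territory structure is fixed; the per-segment
*names* shipped by `wbmra_taxonomy()` are a packaged convention (reading
schemes of this family enumerate territories, not individual labels), and a
custom taxonomy of the same shape can be supplied everywhere.

Each diagnostic segment receives a categorical grade for its worst luminal
narrowing: 0 none, 1 below 50 %, 2 from 50 to below 70 %, 3 from 70 to below
100 %, 4 occlusion. Published grade descriptions in this family are slightly
inconsistent about whether 50 % itself is grade 1 or grade 2; we adopt
half-open bins with 50 % and 70 % belonging to the higher grade, which keeps
the bins disjoint and exhaustive over (0, 100]. Where a segment carries
several lesions the most severe one grades the vessel (`score_vessel()`);
no vessel-specific or multi-lesion weighting is applied.

## The score

For one participant the whole-body score is

$$SAS = \left[\left(\frac{\sum \text{grade}}{n}\right) \div 4\right] \times 100,$$

where the sum runs over the $n$ diagnostic segments and 4 is the maximum
grade; territory scores apply the same formula within a territory. Two
consequences are deliberate design choices:

* **Non-diagnostic segments** leave both numerator and denominator, so image
  quality degrades precision, not the score's scale.
* **A participant with $n = 0$ has an undefined score**, signalled as `NA`
  with a warning — never coerced to 0, which would bias group medians
  downwards. Undefined scores are excluded from group statistics.

An algebraic identity links the two levels: the whole-body SAS equals the
diagnostic-count-weighted mean of the territory SAS values. The test suite
verifies this, plus permutation invariance and the $[0, 100]$ bounds, against
an independent brute-force evaluation on a thousand random profiles.

Percentages in summary tables are computed exactly and only rounded for
display (one decimal place). Where published figures in this literature
occasionally disagree with their own denominators, we report the exact value.

# Left-ventricular volumetry

## Disc summation

Volumes come from short-axis contour stacks by disc summation (the "Simpson
rule" of clinical CMR): each slice's contour area (shoelace formula,
orientation-independent) times the effective slab span, summed base to apex.
The slab span is slice thickness **plus** inter-slice gap — each contour
represents its slab out to the half-gaps — the common convention for gapped
cine stacks (the default geometry is 6 mm slices with a 4 mm gap).
Endocardial contours are blood-pool boundaries by contract: papillary muscle
area belongs to the pool, which is a tracing-convention statement rather than
anything this package can enforce from coordinates.

Accuracy was characterised on discretised prolate spheroids with known
analytic volume: at 2 mm effective spacing the error is well below 1 %, and
it decreases monotonically under slice refinement once the (separately
controllable) polygon-resolution error is accounted for. The package's
acceptance checks require 3 % at 2 mm spacing.

## Derived metrics

With end-diastolic volume $EDV$, end-systolic $ESV$, mass $LVM$ (epicardial
minus endocardial disc volume at end-diastole times myocardial density
$\rho = 1.05$ g/ml — the standard CMR value; a density is required because
the global function index needs a myocardial *volume*):

* $SV = EDV - ESV$, $EF = 100 \cdot SV / EDV$;
* mass-to-volume ratio: reported as $LVM/LVEDV$ in g/ml by default. The
  opposite direction ($LVEDV/LVM$) also circulates in the literature under
  the same name; because the printed unit of the ratio as a concentricity
  index is g/ml, mass-over-volume is the default and
  `derive_metrics(..., lvmvr = "volume_over_mass")` emits the literal
  reciprocal;
* global function index: $LVGFI = SV / \left[(EDV + ESV)/2 + LVM/\rho\right]$,
  reported as a unitless fraction (typical healthy values around 0.45–0.50).
  It is scale-invariant, so it can equally be evaluated on BSA-indexed
  summary values;
* indexing: volumes and mass are divided by DuBois body surface area,
  $BSA = 0.007184 \, W^{0.425} H^{0.725}$ (kg, cm). $EF$ and $LVGFI$ are
  index-free by construction.

Degenerate inputs are contracts, not silent conversions: $ESV > EDV$ and
epicardial volume below endocardial volume are validation errors; $EDV = 0$
yields an undefined $EF$ signal.

# Cohort statistics

## Descriptives and the normality gate

Variables are summarised as mean ± SD when a Shapiro–Wilk test (α = 0.05,
the small-cohort standard; the specific test is our choice) does not reject
normality, otherwise as median with dispersion. Both dispersion conventions
— interquartile range and min–max range — are always computed; the range is
the default display. Constant vectors and $n < 3$ make the gate undecidable;
both summaries remain valid and the parametric label is used.

When normality fails, `normalize_transform()` walks a fixed ladder —
identity, square root, logarithm, reciprocal — skipping steps undefined for
the data's sign, and keeps the first transform that passes the gate. The
ladder order is a convention (recorded here and in every report); it matters
only when several transforms would pass.

## Group comparisons

`compare_groups()` picks one-way ANOVA (on the transformed scale) when the
ladder succeeds, otherwise Kruskal–Wallis, with Bonferroni-corrected pairwise
t or rank-sum contrasts. The Bonferroni family is **all six pairwise
contrasts** among the four groups; reports additionally mark the
reference-group contrasts the field's tables footnote (significant vs the
diabetes-only group, vs healthy controls, or both). The nonparametric post
hoc (rank-sum with Bonferroni) is our convention. Under a null simulation
with a skewed common distribution the full auto path holds its type-I error
near the nominal 5 % (the acceptance bound allows 7.5 % Monte-Carlo slack
over 1,000 replicates).

## Covariate adjustment

`ancova_adjust()` fits `dependent ~ group + age + sex + BMI + hypertension +
smoking` by least squares with group categorical against the healthy-control
reference and the binaries as 0/1 indicators. The adjusted group effect is a
partial F test of the full against the covariates-only model; pairwise
adjusted contrasts come from `emmeans` with Bonferroni correction. Constant
covariates are dropped (with a warning) so the nesting identity with one-way
ANOVA holds; genuinely collinear designs raise an error naming the column.
Parameter-recovery simulations (a 1-residual-SD adjusted group effect) show
the 95 % CI covering the truth at its nominal rate.

## Agreement

Intra-observer reliability uses ICC(2,1): two-way random effects, absolute
agreement, single measure, computed in closed form from the two-way mean
squares, with the standard F-based confidence interval (Satterthwaite
degrees of freedom) and a p-value testing ICC = 0. The implementation is
cross-checked against an independent variance-component composition from
`aov()` mean squares to $10^{-10}$. Identical reads with between-subject
variance give exactly 1; an all-constant matrix is an error (agreement is
undefined without variance).

# The synthetic cohort generator

`generate_cohort()` emulates the study conditions the analysis assumes:

* **Design**: four groups of 34/55/30/29 participants; demographics
  (age, sex, BMI, hypertension, smoking, HbA1c, prior-event flags, LGE
  prevalence) drawn per group with the case-control contrasts typical of
  such cohorts.
* **Stenosis**: a per-territory zero-inflated categorical model. Per-group
  abnormal-segment prevalence (26.4/15.7/32.7/13.3 %) and the grade split
  given abnormality are taken from the aggregate segment-count rows of the
  reference design. A participant-level lognormal frailty (mean 1, per-group
  `sdlog` 1.3/0.8/0.7/1.0) supplies the strong right skew of per-subject
  burden — a handful of participants carry most lesions — which is what
  makes group *medians* sit far below means. The frailty scale was
  calibrated once so that large-cohort median SAS values reproduce the
  reference ordering (CVD-only > diabetes+CVD > diabetes-only > controls,
  approximately 10 / 4 / 3.2 / 2.4) in at least 95 % of replicates at
  n = 500 per group; territory multipliers vary mildly around 1.
  Ground-truth stenosis percents are drawn within each grade's band, so the
  grading path can be exercised from percentages.
* **Non-diagnostic segments**: independent per segment at rate 24/4588.
* **Observer noise**: a rescore shifts each diagnostic grade by ±1 with a
  configurable probability (clipped to 0–4, non-diagnostic flags preserved).
  The default 0.15 sits where 20-subject rescoring experiments average an
  SAS ICC(2,1) near 0.93; `calibrate_rescore_noise()` re-derives the value
  by bisection.
* **Ventricles**: prolate spheroids (long axis 1.7 × short axis) whose
  semi-axes are solved so cavity and wall volumes realise per-group draws of
  indexed EDV, EF and mass; indexed mass additionally carries age, BMI and
  sex slopes applied to centred covariates, so a known adjusted group effect
  exists for recovery tests. Analytic volumes are stored as truth.
* **Determinism**: one master seed spawns fixed substreams (demographics,
  stenosis, geometry, noise); a fixed seed reproduces byte-identical output.

What the generator deliberately does **not** emulate: spatial correlation of
disease along the arterial tree (segments are conditionally independent
given the frailty), reader drift or grade-dependent error structure, real
contour irregularity or papillary anatomy, image artefacts clustering
non-diagnostic segments within examinations, and any MR signal physics.
Passing tests therefore demonstrate the correctness and statistical
behaviour of the *quantification chain* under a plausible data-generating
process, not claims about real patient populations.

# Numerical choices and problem sizes

* Polygon areas use the shoelace formula; polygon simplicity is checked in
  `validate_inputs()` (vectorised proper-crossing test), not on every area
  evaluation.
* Shapiro–Wilk is capped at 5,000 values by deterministic thinning.
* ICC confidence bounds are clamped to $(-1, 1]$ and to bracket the
  estimate; the identical-read case short-circuits the degenerate F
  construction.
* Wall thickness for the synthetic ventricle is solved by `uniroot` to
  $10^{-10}$ mm on a bracket of 0–60 mm.
* Test and acceptance problem sizes are the package's own choices: 1,000
  random profiles for the SAS brute-force check, 100 replicates of n = 2,000
  cohorts for the median-ordering property, 200 replicates for noise
  calibration and ANCOVA recovery, 1,000 null replicates for type-I error.

# Known limitations

* The SAS weights all segments equally; neither lesion length, multi-site
  disease within a segment, nor vessel importance is modelled — a
  recognised limitation of stenosis-count scores.
* Coronary arteries are outside the 31-segment taxonomy.
* LGE enters as a per-subject boolean (with an attributable-history flag);
  scar pattern analysis from images is out of scope, as is all image
  processing — the package starts from grades/percentages and contours.
* The LVMVR naming ambiguity is handled by a switch, not resolved: both
  directions are computed, mass-over-volume (g/ml) is the default.
* Group-level results of any real cohort are not desk-reproducible from
  summary statistics; the acceptance suite therefore validates arithmetic
  identities, analytic-geometry recovery, and statistical operating
  characteristics rather than re-deriving cohort tables.
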