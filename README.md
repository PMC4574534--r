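# wbcvmr

Quantification tools for whole-body cardiovascular MR (WB-CVMR) cohort
studies: systemic atherosclerotic burden from whole-body MR angiography, and
left-ventricular structure and function from cine cardiac MR — together with
the statistical battery used to compare both across case-control strata of
type 2 diabetes and cardiovascular disease.

The package is aimed at imaging researchers who have per-segment stenosis
readings and short-axis LV contours (from any reading workstation) and need
reproducible scores, metrics, group comparisons and agreement statistics —
plus a seeded synthetic cohort generator so every stage of the pipeline can
be exercised and validated without patient data.

## What it computes

**Standardised atheroma score (SAS).** The arterial tree is read as 31
vessel segments in five territories (head/neck, aorta, abdominal,
ilio-femoral, run-off). Each diagnostic segment carries a categorical grade
for its worst stenosis (0 none; 1 <50 %; 2 50–<70 %; 3 70–<100 %; 4
occlusion), and

```
SAS = [ (Σ grade / n) ÷ 4 ] × 100,
```

summed over the n diagnostic segments — a 0–100 whole-body burden score,
with territory scores by the same formula. Non-diagnostic segments leave
numerator and denominator; a participant with no diagnostic segments has an
*undefined* (never zero) score.

**LV volumetry.** Disc-summation ("Simpson rule") volumes from short-axis
endo/epicardial contour stacks (slice area × [thickness + gap], base to
apex), myocardial mass at density 1.05 g/ml, DuBois body-surface-area
indexing, ejection fraction, mass-to-volume ratio (g/ml), and the global
function index `LVGFI = SV / [(EDV+ESV)/2 + LVM/1.05]`.

**Cohort statistics.** Normality-gated descriptives (Shapiro–Wilk with a
transform ladder), one-way ANOVA or Kruskal–Wallis with Bonferroni pairwise
contrasts, ANCOVA adjusting for age, sex, BMI, hypertension and smoking
(pairwise adjusted contrasts via `emmeans`), and intra-observer agreement by
ICC(2,1) — two-way random effects, absolute agreement, single measure —
with F-based confidence intervals.

**Synthetic cohorts.** `generate_cohort()` draws a four-group cohort
(34/55/30/29 by default) with realistic demographics, a frailty-driven
zero-inflated stenosis model calibrated so group median SAS reproduces the
characteristic ordering (CVD-only > diabetes+CVD > diabetes-only >
controls), observer-noise rescoring calibrated to an SAS ICC near 0.93, and
ellipsoidal ventricles with analytic ground-truth volumes.

## Worked example

```r
library(wbcvmr)

# One participant's score sheet: grades 4,3,2,1 on four segments, rest normal
scores <- data.frame(participant_id = "P001", segment_id = 1:31,
                     diagnostic = TRUE, grade = c(4, 3, 2, 1, rep(0, 27)))
atheroma_profile(scores)
#> Atheroma profile: P001
#>   diagnostic segments: 31 / 31
#>   whole-body SAS: 8.1
#>   territory SAS: head_neck=27.8, aorta=0.0, abdominal=0.0, iliofemoral=0.0, runoff=0.0
```

The whole-body SAS is (10/31)/4 × 100 = 8.1: a tenth of the worst possible
burden, concentrated in the head/neck territory (whose 9 segments alone
score 27.8).

```r
# A synthetic ventricle with EDV 150 ml, ESV 50 ml, mass 120 g,
# discretised at the 6 mm/4 mm cine geometry and quantified back:
geo <- wbcvmr:::lv_ellipsoid_geometry(150, 50, 120)
ed <- discretise_lv_ellipsoid(geo$a_ed, geo$c_ed, a_epi = geo$a_epi,
                              c_epi = geo$c_epi, slice_thickness = 6, gap = 4)
es <- discretise_lv_ellipsoid(geo$a_es, geo$c_es, slice_thickness = 6,
                              gap = 4, phase = "ES")
derive_metrics(ed, es, height_cm = 178, weight_kg = 82)
#> Left-ventricular metrics
#>   EDV 149.7 ml (74.8 ml/m2)   ESV 50.0 ml (25.0 ml/m2)
#>   SV  99.7 ml (49.8 ml/m2)   EF  66.6 %
#>   LVM 119.1 g (59.5 g/m2)    MVR 0.80 (g/ml)   GFI 0.47
#>   BSA 2.001 m2
```

Disc summation recovers the analytic volumes to well under 1 % at this slice
spacing; EF and LVGFI land in the healthy range.

```r
# Full pipeline on a synthetic cohort: tables, box-plot data, agreement
run_pipeline(out_dir = "wbcvmr_out", seed = 1)
```

writes `table1_demographics.csv/.md`, `table2_mri_metrics.csv/.md` (group
summaries with Bonferroni significance markers), `sas_boxplot_data.csv`,
`ancova.csv`, `agreement.csv`, all intermediate per-participant files and a
`manifest.json`; re-running with the same seed reproduces the numeric
outputs byte-identically. A thin CLI wrapper lives at `inst/cli/wbcvmr.R`
(subcommands `simulate`, `score`, `volumetry`, `stats`, `report`, `run-all`,
`validate`).

## Documentation

The methods vignette (`vignettes/wbcvmr-methods.Rmd`) documents the scoring
and volumetry conventions, the statistical gates, every tunable of the
synthetic generator and its calibration, numerical choices, and what passing
tests do and do not establish about real data.
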