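Package: wbcvmr
Title: Whole-Body Cardiovascular MR Atheroma Scoring and Left-Ventricular Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for whole-body cardiovascular magnetic
    resonance studies of atherosclerotic burden. Implements the standardised
    atheroma score (SAS) over a 31-segment arterial taxonomy with five
    anatomical territories, disc-summation (Simpson rule) left-ventricular
    volumetry from short-axis contour stacks with DuBois body-surface-area
    indexing, and the accompanying cohort statistics: normality-gated group
    comparisons (one-way ANOVA or Kruskal-Wallis with Bonferroni post hoc),
    ANCOVA adjustment for cardiovascular risk factors, and intra-observer
    agreement via the two-way random-effects absolute-agreement single-measure
    intraclass correlation ICC(2,1). A seeded synthetic cohort generator
    emulates a four-group case-control design (type 2 diabetes and
    cardiovascular disease strata) so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
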