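Package: credmeta
Title: Credibility Assessment for Candidate-Gene Association Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A field-synopsis pipeline for candidate-gene case-control
    association studies. From per-study genotype counts it builds the four
    classical genetic-model 2x2 contrasts (dominant, recessive, and the two
    genotype-restricted additive comparisons), pools per-study odds ratios by
    inverse-variance fixed-effect or DerSimonian-Laird random-effects
    meta-analysis with Cochran's Q and I-squared heterogeneity (test-based
    confidence intervals), tests funnel-plot asymmetry with Egger's
    regression, checks Hardy-Weinberg equilibrium in controls (chi-square or
    exact conditional test), estimates statistical power for the pooled
    contrast, computes Wakefield's Bayesian false-discovery probability, and
    grades each association with the Venice credibility criteria before
    assigning a three-tier highly/less/not-credible verdict. A synthetic
    multi-study genotype-count generator and sensitivity re-analysis
    (Hardy-Weinberg and ethnicity exclusions) make every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
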