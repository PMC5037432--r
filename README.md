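# credmeta

Credibility assessment for candidate-gene case-control association
meta-analyses — a field-synopsis pipeline in R.

Candidate-gene literatures accumulate dozens of small case-control studies
per variant. Pooling them answers "is there an association?"; a field
synopsis also has to answer "how much should we believe it?". credmeta
implements the whole chain for biallelic SNPs, calibrated against a
published synopsis of paediatric inflammatory bowel disease (Crohn's
disease and ulcerative colitis) whose printed summary tables ship as
fixtures:

* **Genetic-model contrasts** — each study's genotype counts become four
  2×2 tables: dominant (wt/var & var/var vs wt/wt), recessive (var/var vs
  the rest), additive 1 (var/wt vs wt/wt) and additive 2 (var/var vs
  wt/wt), the additive pair genotype-restricted.
* **Pooling** — per-study crude log odds ratios (Haldane–Anscombe 0.5
  correction for zero cells), inverse-variance fixed-effect or
  DerSimonian–Laird random-effects pooling, switched by Cochran's Q at
  p < 0.05; I² = max(0, (Q − df)/Q)·100 with a test-based ln H confidence
  interval; Egger's regression (standardized effect on precision,
  intercept t-test on k − 2 df) for small-study effects.
* **Quality** — Hardy–Weinberg equilibrium in controls (chi-square when
  all expected counts ≥ 5, exact conditional test otherwise) and
  two-proportion normal-approximation power at the pooled OR, with
  exposure prevalence derived from the control reference-allele frequency
  under HWE.
* **Credibility** — Wakefield's Bayesian false-discovery probability
  BFDP = ABF·PO / (1 + ABF·PO) with
  ABF = √((V+W)/V)·exp(−θ²W / 2V(V+W)), prior π = 0.05,
  W = (ln 3 / z₀.₉₇₅)²; Venice A/B/C grades for amount of evidence
  (power), replication (I²) and protection from bias (Egger); and a
  three-tier highly / less / not credible classification.
* **Sensitivity** — re-analysis after excluding HWE-violating and/or
  non-white-population studies, with a delta report.
* **Synthetic data** — a generator for multi-study genotype-count datasets
  with configurable true OR, effect model, heterogeneity τ, small-study
  bias and HWE distortion, so every stage is testable without external
  data.

## Worked example

Re-score the packaged printed Crohn's-disease summary table (20 variants,
per-model OR/CI/p/I²/power) through the credibility layer:

```r
library(credmeta)

cd <- load_printed_summaries("CD")
scored <- score_reported(cd, pipeline_config())
table(scored$verdicts$tier)
#> highly_credible   less_credible    not_credible
#>               9               2               9
subset(scored$verdicts, tier == "less_credible")$variant_id
#> [1] "rs11739135" "rs1050152"
```

Nine variants (in *NOD2*, *IL23R*, *IBD5*, *ATG16L1* and *TNF-α*) come out
highly credible — significant in at least two genetic models with a
qualifying model that also has BFDP < 0.20, power ≥ 0.80 and I² ≤ 50 — and
two more are significant in two models but lack such a witness.

The same layer works piecewise:

```r
bfdp_from_or_ci(4.75, 2.43, 9.26)$bfdp      # TNF-α rs1800629, additive-2
#> [1] 0.01789709
power_two_proportions(1158, 4766, p0 = exposure_prevalence(0.923, "dominant"),
                      or_alt = 0.32)        # IL23R rs11209026, dominant
#> [1] 1
venice_grade(1.00, 46, FALSE)$as_string     # NOD2 rs2066844, dominant
#> [1] "ABB"
```

And from raw counts, end to end, on synthetic data:

```r
ds  <- simulate_meta_dataset(simulation_design(true_or = 2, seed = 42))
res <- run_pipeline(ds)
res$models[1, c("model", "method", "or", "ci_low", "ci_high", "p")]
#>      model method       or   ci_low  ci_high            p
#> 1 dominant  fixed 1.935322 1.766046 2.120823 2.195951e-45
res$verdicts$tier
#> [1] "highly_credible"
```

The numbered scripts under `analysis/` are thin drivers over these
functions: `01_score_printed_tables.R` re-scores the printed CD and UC
tables and writes verdict tables under `results/`,
`02_simulation_recovery.R` measures bias, CI coverage and type-I error of
the pooled analysis under the reference simulation conditions, and
`03_sensitivity.R` demonstrates the exclusion re-analysis on a constructed
dataset with one HWE-violating and one non-white study.

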