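---
title: "Grading the credibility of candidate-gene meta-analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading the credibility of candidate-gene meta-analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credmeta)
```

## The problem

A field synopsis takes every candidate-gene case-control study of one
disease, pools the per-study evidence variant by variant, and then asks a
harder question than "is p < 0.05?": *how credible is each pooled
association?* credmeta implements that full chain for biallelic SNPs in
case-control data — here calibrated against a synopsis of paediatric
inflammatory bowel disease (Crohn's disease, CD, and ulcerative colitis,
UC), whose printed summary tables are packaged as fixtures — but every
stage is generic.

The pipeline has two entry points because the two natural inputs differ:

* `run_pipeline()` starts from **per-study genotype counts** (wild-type
  homozygote / heterozygote / variant homozygote in cases and controls) and
  computes everything;
* `score_reported()` starts from **already-pooled per-model summary rows**
  (OR, 95% CI, p, I², power) — the situation when reassessing a published
  synopsis whose per-study counts are unavailable — and recomputes only the
  downstream credibility layer.

## Genetic-model contrasts

Each study's genotype counts are recoded into four 2×2 exposure tables:
dominant (carriers vs wild-type homozygotes), recessive (variant
homozygotes vs everyone else), and two genotype-restricted comparisons,
additive 1 (heterozygote vs wild-type homozygote) and additive 2 (variant
homozygote vs wild-type homozygote). The additive contrasts *drop* the
excluded genotype class rather than recoding it: the comparison named
"var/var vs wt/wt" is between those two genotype groups only. Studies that
report only carrier vs non-carrier counts are analysable under the
dominant model alone; the other three models are flagged inapplicable, and
no allele frequency can be derived from them.

## Pooling and heterogeneity

Per-study effects are crude log odds ratios with the large-sample standard
error $\sqrt{1/a + 1/b + 1/c + 1/d}$. When any cell is zero, 0.5 is added
to all four cells (Haldane–Anscombe); tables with zero exposed (or zero
unexposed) in *both* arms carry no information about the odds ratio and
are dropped with a logged reason rather than corrected.

Pooling is inverse-variance. Cochran's $Q = \sum w_i(\theta_i -
\hat\theta)^2$ with $w_i = 1/se_i^2$ is tested against $\chi^2_{k-1}$; if
$p_Q < 0.05$ (strict) the DerSimonian–Laird random-effects model is used,
with the method-of-moments between-study variance

$$\hat\tau^2 = \max\!\left(0,\ \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right)$$

and re-weighting by $1/(se_i^2 + \hat\tau^2)$; otherwise the fixed-effect
model. $I^2 = \max(0, (Q - df)/Q) \cdot 100$, with a 95% CI from the
test-based standard error of $\ln H$ ($H = \sqrt{Q/df}$), truncated to
[0, 100] — the canonical closed form, chosen because the source tables
print I² CIs without naming a method. Pooled p-values are two-sided normal
z-tests on the pooled log-OR. We chose inverse-variance rather than
Mantel–Haenszel fixed-effect pooling because it pairs naturally with the
DerSimonian–Laird estimator and the difference is negligible at these
sample sizes.

Small-study effects are tested with Egger's regression — OLS of the
standardized effect $\theta_i/se_i$ on precision $1/se_i$, the intercept
tested two-sided on $t_{k-2}$ — at the conventional 0.10 threshold
(configurable). With fewer than three studies the test is not evaluable
and is treated downstream as "no small-study effect detected", with a
flag. When all studies share one precision the regression is
unidentifiable; the line through the origin fits exactly, so the intercept
is reported as 0 (no asymmetry information), flagged degenerate.

## Quality layer: Hardy–Weinberg and power

Control genotype counts are tested for Hardy–Weinberg equilibrium (HWE):
the 1-df chi-square goodness-of-fit test when all HWE-expected counts are
at least 5, otherwise the exact conditional test (probability ordering
over heterozygote counts given the allele counts). The two branches order
the sample space differently, so their p-values can differ by a few
hundredths even in large samples; what the dispatch guarantees — and what
the tests check — is that the *violation verdict* at $\alpha = 0.05$
almost never depends on the branch.

Statistical power uses only quantities a synopsis table prints: the pooled
case/control totals, the pooled OR as the alternative, and an exposure
prevalence derived from the control reference-allele frequency $f$ under
HWE (dominant $1-f^2$; recessive $q^2$; additive 1 $2fq/(f^2+2fq)$;
additive 2 $q^2/(f^2+q^2)$, the latter two conditional on the restricted
genotype set). Power itself is the normal-approximation two-proportion
z-test with unequal group sizes, pooled-proportion null standard deviation
and no continuity correction, so power equals the nominal level exactly at
OR = 1. This uncorrected form is fully specified and reproduces the
printed boundary values (1.00 and 0.05); mid-range printed powers from
other software may deviate by a few hundredths and are not relied on.

## Credibility layer

**BFDP.** Wakefield's Bayesian false-discovery probability is computed
from the pooled OR and CI alone: $\theta = \ln \mathrm{OR}$, $V = ((\ln
hi - \ln lo)/2z_{0.975})^2$, and

$$\mathrm{ABF} = \sqrt{\frac{V+W}{V}}\,
  \exp\!\left(-\frac{\theta^2 W}{2V(V+W)}\right), \qquad
  \mathrm{BFDP} = \frac{\mathrm{ABF} \cdot PO}{1 + \mathrm{ABF}\cdot PO},$$

with prior odds of no association $PO = (1-\pi)/\pi$ at $\pi = 0.05$ and
noteworthiness threshold 0.20. The prior variance default $W = (\ln
3/z_{0.975})^2$ — a prior 97.5% point at OR 3 — was identified because it
reproduces three independent printed BFDP values (0.465, 0.017, 0.963)
from their printed OR/CI inputs; it is configurable. $V$ is recovered from
the CI rather than the p-value because the CI is always printed and the
two give near-identical values here.

**Venice grades.** Amount of evidence: A/B/C at power ≥ 0.80 / 0.50–0.79 /
< 0.50. Replication: A at I² ≤ 25, B below 50, C at I² ≥ 50. Bias: B when
no small-study effect is detected, otherwise C; A is never assigned
because complete protection from bias cannot be established. Boundary
conventions (power exactly 0.80 → A; I² exactly 25 → A; I² exactly 50 → C)
are fixed and documented since the published ranges leave them open.

**Three tiers.** A variant is *highly credible* when (i) its pooled effect
is significant (p < 0.05, strict) in at least two eligible genetic models
and (ii) at least one significant model also has BFDP < 0.20, power
≥ 0.80 and I² ≤ 50 — a "qualifying" witness model. Significant in ≥ 2
models without a witness is *less credible*; everything else *not
credible*. Two design points deserve explanation:

* *The witness rule is existential, not conjunctive.* Requiring the BFDP /
  power / I² criteria of every model (or of the whole variant at once)
  fails to reproduce the published tier assignments; requiring them of a
  single significant model reproduces the printed set of nine
  highly-credible CD variants and both less-credible CD variants exactly.
  For the same reason "less credible" is implemented as
  significant-but-not-highly rather than by a literal power window
  (50–79%), which the published assignments themselves contradict (one
  less-credible variant prints power 0.93).
* *The I² witness cut is inclusive at 50.* Printed I² values are integers.
  One published highly-credible variant's only candidate witness row
  prints I² = 50 — and is graded "B" (i.e. < 50) in the same printed row —
  so the printed 50 is a rounded 49.x. Treating the classification cut as
  I² ≤ 50 resolves the rounding boundary; the Venice replication *grade*
  keeps the strict convention (50 → C).

Only models meeting the minimum-study rule (default: three independent
studies) contribute to either count. The packaged UC fixture illustrates
rule-driven behaviour: the source narrative says four UC variants are
significant in ≥ 2 models, but its own printed values yield five; the
classifier reports five and the discrepancy is visible rather than
special-cased. Similarly, one printed CD row (rs2241880, recessive)
carries a replication grade inconsistent with its own printed I²; the
recomputed grade differs there by construction.

## Sensitivity analysis

`apply_exclusions()` drops studies whose controls violate HWE at 0.05
and/or studies of non-white populations (a configurable, case-insensitive
allow-list — "white", "european", "caucasian" — since source ethnicity
labels are coarse). Carrier-format records are never dropped for HWE
because the test is not evaluable on them. `sensitivity_compare()` reports
per-model changes in the pooled log-OR, OR ratios, significance flips and
tier flips; both effect-size deltas and re-assessed tiers are emitted
because published sensitivity narratives are ambiguous about which was
re-checked.

## The synthetic-data generator

Per-study counts behind published synopses are often unavailable, so the
generator emulates the assumed data structure directly: control genotypes
are multinomial draws from HWE proportions, optionally distorted by an
inbreeding-like coefficient F (heterozygosity scaled by 1 − F); the
study-level log odds ratio is $\ln \mathrm{OR} + N(0, \tau^2) + b \cdot
se_i$, where the last term is the canonical small-study-bias mechanism the
Egger intercept targets; and case genotypes are drawn so that the study OR
acts on the designated model's exposure dichotomy, with genotype classes
outside the dichotomy keeping their control proportions and classes within
a side keeping their control conditional split. Induced (smaller) effects
on the other three contrasts follow automatically, as they would for a
single causal dichotomy.

The generator's defaults are the reference study conditions used by the
test battery: k = 6 studies of 500 cases / 1000 controls, control
variant-allele frequency 0.3, dominant model, true OR 2, τ = 0. What it
does **not** emulate: linkage disequilibrium between variants, covariate
confounding, population stratification, genotyping error, or shared
controls across phenotypes. Passing recovery tests therefore show the
estimator chain is correct under its own assumptions, not that those
assumptions hold in any given literature.

## Numerical choices and problem sizes

Ties in the exact HWE test are included with a 1e-9 relative tolerance;
pooled totals for power use full study arms (matching how synopsis tables
report sample sizes) even for restricted contrasts; eligibility ordering
is by gene then variant id so runs are deterministic; all simulation-based
checks fix their seeds. The simulation battery uses 200 replicates for
recovery/coverage (Monte-Carlo SE of the mean pooled log-OR about 0.003)
and 1000 for type-I error — large enough for the ±0.02 band checked, small
enough to run comfortably on a laptop. Oracle-equivalence checks (pooling
vs metafor, Egger vs lm, exact HWE vs brute-force enumeration, ABF vs
direct normal-density ratio) run on 100 random instances each at 1e-10 /
1e-12.

## Known limitations

Peto odds ratios, Hartung–Knapp adjustment, trim-and-fill, allele-level
(per-chromosome) contrasts, multi-allelic and X-linked variants are out of
scope. The power formula is one specific normal approximation; other
programs' mid-range powers can differ. BFDP depends on the prior variance
W; the default is calibrated to one published synopsis and should be
revisited for other priors. The classification boundary conventions are
exactly those stated above; data falling on a boundary are decided by
them, not re-examined.
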