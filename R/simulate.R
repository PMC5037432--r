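#' Design of a synthetic multi-study case-control dataset
#'
#' Describes the generative model used to emulate the data structure of a
#' candidate-gene meta-analysis: `k` independent case-control studies of a
#' biallelic SNP, controls drawn from (possibly distorted) Hardy-Weinberg
#' proportions, and a true odds ratio imposed on one genetic model's
#' exposure dichotomy. The defaults are the reference study conditions used
#' throughout the test battery: 6 studies of 500 cases / 1000 controls,
#' control variant-allele frequency 0.3 (`f_ref = 0.7`), a dominant-model
#' odds ratio of 2, and no heterogeneity, bias, or equilibrium violation.
#'
#' @param k Number of studies.
#' @param n_cases,n_controls Per-study arm sizes (scalars or length-`k`
#'   vectors).
#' @param f_ref Control reference (wild-type) allele frequency in (0, 1).
#' @param model Genetic model carrying the effect.
#' @param true_or True odds ratio on that model's exposure (> 0).
#' @param tau Between-study SD of the log odds ratio (0 = homogeneous).
#' @param small_study_bias Coefficient linking a study's approximate
#'   standard error to an added log odds ratio (0 = none); the generative
#'   mechanism the Egger intercept targets.
#' @param hwe_F Inbreeding-like distortion of control genotypes: the
#'   heterozygote proportion is scaled by `(1 - F)`, the excess split
#'   between the homozygotes (0 = Hardy-Weinberg).
#' @param seed Integer seed; the simulated dataset is byte-reproducible
#'   under it.
#' @param variant_id,gene,phenotype,ethnicity Labels for the generated
#'   records (`ethnicity` may be a length-`k` vector).
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(k = 6, n_cases = 500, n_controls = 1000,
                              f_ref = 0.7, model = "dominant", true_or = 2,
                              tau = 0, small_study_bias = 0, hwe_F = 0,
                              seed = 1, variant_id = "rs_sim", gene = "SIM",
                              phenotype = "CD", ethnicity = "white") {
  model <- match.arg(model, MODEL_LEVELS)
  stopifnot(k >= 1, f_ref > 0, f_ref < 1, true_or > 0, tau >= 0,
            hwe_F >= 0, hwe_F < 1)
  structure(
    list(k = as.integer(k),
         n_cases = rep_len(as.integer(n_cases), k),
         n_controls = rep_len(as.integer(n_controls), k),
         f_ref = f_ref, model = model, true_or = true_or, tau = tau,
         small_study_bias = small_study_bias, hwe_F = hwe_F,
         seed = as.integer(seed), variant_id = variant_id, gene = gene,
         phenotype = phenotype, ethnicity = rep_len(ethnicity, k)),
    class = "simulation_design"
  )
}

control_genotype_probs <- function(f, F) {
  q <- 1 - f
  p <- c(f^2 + F * f * q, 2 * f * q * (1 - F), q^2 + F * f * q)
  if (any(p < 0) || any(p > 1)) stop("distorted genotype probabilities outside (0, 1)")
  p
}

# Case genotype probabilities when a study odds ratio `or` acts on the
# exposure dichotomy of `model`. The effect moves probability mass across
# the model's dichotomy; genotype classes outside the dichotomy keep their
# control probability, and classes within a side keep their control
# conditional split.
case_genotype_probs <- function(pc, model, or) {
  shift <- function(p0) or * p0 / (1 - p0 + or * p0)
  switch(model,
    dominant = {
      p0 <- pc[2] + pc[3]
      p1 <- shift(p0)
      c(1 - p1, p1 * pc[2] / p0, p1 * pc[3] / p0)
    },
    recessive = {
      p0 <- pc[3]
      p1 <- shift(p0)
      rest <- pc[1] + pc[2]
      c((1 - p1) * pc[1] / rest, (1 - p1) * pc[2] / rest, p1)
    },
    additive1 = {
      p0 <- pc[2] / (pc[1] + pc[2])
      p1 <- shift(p0)
      inside <- 1 - pc[3]
      c(inside * (1 - p1), inside * p1, pc[3])
    },
    additive2 = {
      p0 <- pc[3] / (pc[1] + pc[3])
      p1 <- shift(p0)
      inside <- 1 - pc[2]
      c(inside * (1 - p1), pc[2], inside * p1)
    }
  )
}

# Approximate standard error of the study's model contrast at the design
# odds ratio, used to scale the small-study bias term.
approx_study_se <- function(design, i) {
  pc <- control_genotype_probs(design$f_ref, design$hwe_F)
  p0 <- switch(design$model,
    dominant = pc[2] + pc[3], recessive = pc[3],
    additive1 = pc[2] / (pc[1] + pc[2]), additive2 = pc[3] / (pc[1] + pc[3]))
  p1 <- design$true_or * p0 / (1 - p0 + design$true_or * p0)
  n1 <- design$n_cases[i]; n2 <- design$n_controls[i]
  # restricted models only use part of each arm
  frac1 <- switch(design$model, dominant = 1, recessive = 1,
                  additive1 = 1 - case_genotype_probs(pc, design$model, design$true_or)[3],
                  additive2 = 1 - pc[2])
  frac2 <- switch(design$model, dominant = 1, recessive = 1,
                  additive1 = pc[1] + pc[2], additive2 = pc[1] + pc[3])
  sqrt(1 / (n1 * frac1 * p1) + 1 / (n1 * frac1 * (1 - p1)) +
       1 / (n2 * frac2 * p0) + 1 / (n2 * frac2 * (1 - p0)))
}

#' Simulate one study's genotype counts
#'
#' Draws control genotypes multinomially from the (possibly distorted)
#' Hardy-Weinberg proportions, perturbs the design log odds ratio by the
#' between-study normal deviate and the small-study bias term, and draws
#' case genotypes consistent with that study-level effect on the designated
#' model's exposure dichotomy. Uses the current R random number stream;
#' [simulate_meta_dataset()] seeds it from the design.
#'
#' @param design A [simulation_design()].
#' @param study_index Which study (1..k) to generate.
#' @return A one-row data frame shaped like an `assoc_dataset` record.
#' @export
simulate_study_counts <- function(design, study_index) {
  stopifnot(study_index >= 1, study_index <= design$k)
  i <- study_index
  pc <- control_genotype_probs(design$f_ref, design$hwe_F)
  theta <- log(design$true_or) + rnorm(1, 0, design$tau) +
    design$small_study_bias * approx_study_se(design, i)
  pa <- case_genotype_probs(pc, design$model, exp(theta))
  gc <- as.vector(rmultinom(1, design$n_controls[i], pc))
  ga <- as.vector(rmultinom(1, design$n_cases[i], pa))
  data.frame(
    variant_id = design$variant_id, gene = design$gene,
    phenotype = design$phenotype,
    study_id = sprintf("study_%02d", i), ethnicity = design$ethnicity[i],
    case_wtwt = ga[1], case_wtvar = ga[2], case_varvar = ga[3],
    control_wtwt = gc[1], control_wtvar = gc[2], control_varvar = gc[3],
    carrier_only = FALSE, stringsAsFactors = FALSE
  )
}

#' Simulate a complete multi-study dataset
#'
#' Generates `k` study records for one (variant, phenotype) pair,
#' deterministic under the design seed.
#'
#' @param design A [simulation_design()].
#' @return An `assoc_dataset` with a `variants` table carrying the design's
#'   control reference-allele frequency.
#' @export
simulate_meta_dataset <- function(design) {
  set.seed(design$seed)
  records <- do.call(rbind, lapply(seq_len(design$k), function(i)
    simulate_study_counts(design, i)))
  variants <- data.frame(
    variant_id = design$variant_id, gene = design$gene,
    phenotype = design$phenotype, ref_allele = "A",
    ref_freq_controls = design$f_ref, stringsAsFactors = FALSE
  )
  new_dataset(records, variants,
              provenance = sprintf("synthetic (seed %d)", design$seed))
}
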