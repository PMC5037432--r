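# Shared builders for in-code fixtures. No files are stored: everything is
# generated here or drawn from the packaged printed-summary tables.

make_record <- function(case = c(50, 30, 20), control = c(70, 20, 10),
                        variant_id = "rs_test", gene = "GENE",
                        phenotype = "CD", study_id = "s1",
                        ethnicity = "white", carrier_only = FALSE) {
  if (carrier_only) {
    data.frame(variant_id = variant_id, gene = gene, phenotype = phenotype,
               study_id = study_id, ethnicity = ethnicity,
               case_wtwt = case[1], case_wtvar = case[2], case_varvar = NA,
               control_wtwt = control[1], control_wtvar = control[2],
               control_varvar = NA, carrier_only = TRUE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = variant_id, gene = gene, phenotype = phenotype,
               study_id = study_id, ethnicity = ethnicity,
               case_wtwt = case[1], case_wtvar = case[2], case_varvar = case[3],
               control_wtwt = control[1], control_wtvar = control[2],
               control_varvar = control[3], carrier_only = FALSE,
               stringsAsFactors = FALSE)
  }
}

make_effect <- function(log_or, se, study_id = "s") {
  z <- qnorm(0.975)
  structure(
    list(study_id = study_id, log_or = log_or, se = se, or = exp(log_or),
         ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
         corrected = FALSE, n_cases = NA_real_, n_controls = NA_real_),
    class = "study_effect"
  )
}

# k random study effects with spread-out standard errors
random_effects <- function(k, theta = 0.5, tau = 0.3) {
  se <- exp(runif(k, log(0.08), log(0.8)))
  th <- rnorm(k, theta, sqrt(tau^2 + se^2))
  mapply(make_effect, th, se, sprintf("s%d", seq_len(k)), SIMPLIFY = FALSE)
}

# random genotype counts conditioned to small totals, for exact HWE checks
random_genotypes <- function(n_max = 30) {
  n <- sample(2:n_max, 1)
  repeat {
    g <- as.vector(rmultinom(1, n, prob = runif(3, 0.05, 1)))
    if (sum(g) == n) return(g)
  }
}

hwe_exact_p_wrapper <- function(g) credmeta:::hwe_exact_p(g)

# brute-force conditional HWE p-value: direct factorial weights over all
# heterozygote counts compatible with the observed allele counts
hwe_brute_force_p <- function(g) {
  n <- sum(g)
  n_rare <- min(2 * g[1] + g[2], 2 * g[3] + g[2])
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  w <- vapply(hs, function(h) {
    n_rr <- (n_rare - h) / 2
    n_cc <- n - h - n_rr
    2^h * factorial(n) / (factorial(n_rr) * factorial(h) * factorial(n_cc))
  }, numeric(1))
  probs <- w / sum(w)
  p_obs <- probs[hs == g[2]]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}
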