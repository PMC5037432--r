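#' Hardy-Weinberg equilibrium test on control genotype counts
#'
#' Dispatches between the chi-square goodness-of-fit test (1 df, no
#' continuity correction) when all Hardy-Weinberg expected genotype counts
#' are at least 5, and the exact conditional test otherwise. The exact test
#' conditions on the observed allele counts and sums the probabilities of
#' all heterozygote counts whose conditional probability does not exceed
#' that of the observed configuration.
#'
#' Carrier-format data (heterozygotes and variant homozygotes merged) do not
#' determine the genotype distribution, so the test is not evaluable.
#'
#' @param counts Numeric vector `c(wtwt, wtvar, varvar)` of control genotype
#'   counts; an `NA` variant-homozygote slot marks carrier-format data.
#' @param alpha Violation threshold (default 0.05).
#' @return An `hwe_result`: `method` (`"chi_square"` or `"exact"`),
#'   `p_value`, `violated`, `evaluable`.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25)) # perfect proportions: p = 1
#' hwe_test(c(10, 10, 10))
hwe_test <- function(counts, alpha = 0.05) {
  not_evaluable <- structure(
    list(method = NA_character_, p_value = NA_real_, violated = FALSE,
         evaluable = FALSE),
    class = "hwe_result"
  )
  if (length(counts) != 3 || anyNA(counts)) return(not_evaluable)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) return(not_evaluable)
  n_wt <- 2 * counts[1] + counts[2]
  p <- n_wt / (2 * n)
  if (p == 0 || p == 1) {
    # monomorphic sample: trivially consistent with equilibrium
    return(structure(list(method = "exact", p_value = 1, violated = FALSE,
                          evaluable = TRUE), class = "hwe_result"))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (all(expected >= 5)) {
    stat <- sum((counts - expected)^2 / expected)
    pval <- pchisq(stat, df = 1, lower.tail = FALSE)
    return(structure(
      list(method = "chi_square", statistic = stat,
           p_value = max(pval, .Machine$double.xmin), violated = pval < alpha,
           evaluable = TRUE),
      class = "hwe_result"
    ))
  }
  pval <- hwe_exact_p(counts)
  structure(
    list(method = "exact", p_value = pval, violated = pval < alpha,
         evaluable = TRUE),
    class = "hwe_result"
  )
}

# Conditional distribution of the heterozygote count given allele counts:
# P(h) proportional to 2^h * n! / (n_AA! h! n_aa!). The p-value sums P(h')
# over all h' with P(h') <= P(h_obs) (ties included up to rounding).
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_rare <- min(2 * counts[1] + counts[2], 2 * counts[3] + counts[2])
  h_obs <- counts[2]
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  log_w <- vapply(hs, function(h) {
    n_rr <- (n_rare - h) / 2
    n_cc <- n - h - n_rr
    h * log(2) + lgamma(n + 1) - lgamma(n_rr + 1) - lgamma(h + 1) - lgamma(n_cc + 1)
  }, numeric(1))
  w <- exp(log_w - max(log_w))
  probs <- w / sum(w)
  p_obs <- probs[hs == h_obs]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

#' Exposure prevalence implied by a control reference-allele frequency
#'
#' Converts the wild-type (reference) allele frequency `f` in controls into
#' the control prevalence of the exposed genotype class of each genetic
#' model, assuming Hardy-Weinberg proportions (`q = 1 - f` is the variant
#' allele frequency). The additive comparisons are restricted to the two
#' genotype classes they compare, so their prevalence is conditional on
#' membership of that restricted set:
#' dominant `1 - f^2`; recessive `q^2`;
#' additive1 `2fq / (f^2 + 2fq)`; additive2 `q^2 / (f^2 + q^2)`.
#'
#' @param f_ref Reference (wild-type) allele frequency in controls, strictly
#'   inside (0, 1).
#' @param model Genetic model label.
#' @return Exposure prevalence in (0, 1).
#' @export
exposure_prevalence <- function(f_ref, model) {
  model <- match.arg(model, MODEL_LEVELS)
  if (is.na(f_ref) || f_ref <= 0 || f_ref >= 1) {
    stop("f_ref must be strictly between 0 and 1")
  }
  q <- 1 - f_ref
  switch(model,
    dominant  = 1 - f_ref^2,
    recessive = q^2,
    additive1 = 2 * f_ref * q / (f_ref^2 + 2 * f_ref * q),
    additive2 = q^2 / (f_ref^2 + q^2)
  )
}

#' Power of the two-sided two-proportion z-test
#'
#' Normal-approximation power, with unequal group sizes and no continuity
#' correction, for detecting the alternative odds ratio `or_alt` on a
#' control exposure prevalence `p0`. The case prevalence is
#' `p1 = or_alt * p0 / (1 - p0 + or_alt * p0)`. The null standard deviation
#' uses the pooled proportion, so at `or_alt = 1` the power equals the
#' nominal level exactly.
#'
#' @param n_cases,n_controls Group sizes.
#' @param p0 Exposure prevalence in controls, strictly inside (0, 1).
#' @param or_alt Alternative odds ratio (> 0).
#' @param alpha Two-sided level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_two_proportions(1158, 4766, p0 = 1 - 0.923^2, or_alt = 0.32)
power_two_proportions <- function(n_cases, n_controls, p0, or_alt,
                                  alpha = 0.05) {
  stopifnot(n_cases >= 1, n_controls >= 1, or_alt > 0,
            alpha > 0, alpha < 1)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly between 0 and 1")
  p1 <- or_alt * p0 / (1 - p0 + or_alt * p0)
  if (p1 <= 0 || p1 >= 1) stop("implied case prevalence outside (0, 1)")
  d <- p1 - p0
  pbar <- (n_cases * p1 + n_controls * p0) / (n_cases + n_controls)
  s0 <- sqrt(pbar * (1 - pbar) * (1 / n_cases + 1 / n_controls))
  s1 <- sqrt(p1 * (1 - p1) / n_cases + p0 * (1 - p0) / n_controls)
  z <- qnorm(1 - alpha / 2)
  pnorm((d - z * s0) / s1) + pnorm((-d - z * s0) / s1)
}
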