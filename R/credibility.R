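#' BFDP prior parameters
#'
#' @param prior_pi Prior probability of a true association (default 0.05).
#' @param prior_w Prior variance of the log odds ratio under the
#'   alternative. The default `(log(3)/qnorm(0.975))^2` puts the prior 97.5%
#'   point at an odds ratio of 3.
#' @param noteworthy BFDP threshold below which an association is
#'   noteworthy (default 0.20, i.e. a false discovery is costed four times
#'   a false non-discovery).
#' @return A `bfdp_params` list.
#' @export
bfdp_params <- function(prior_pi = 0.05,
                        prior_w = (log(3) / qnorm(0.975))^2,
                        noteworthy = 0.20) {
  stopifnot(prior_pi > 0, prior_pi < 1, prior_w > 0,
            noteworthy > 0, noteworthy < 1)
  structure(list(prior_pi = prior_pi, prior_w = prior_w,
                 noteworthy = noteworthy),
            class = "bfdp_params")
}

#' Bayesian false-discovery probability from a pooled OR and CI
#'
#' Wakefield's approximate-Bayes-factor calculation. The squared standard
#' error is recovered from the confidence interval,
#' `V = ((log(hi) - log(lo)) / (2 z))^2` with `z = qnorm(0.975)`; the
#' approximate Bayes factor (null over alternative) is
#' `ABF = sqrt((V + W)/V) * exp(-theta^2 W / (2 V (V + W)))`, equivalently
#' the ratio of the two normal marginal densities
#' `N(theta; 0, V) / N(theta; 0, V + W)`; and with prior odds of no
#' association `PO = (1 - pi)/pi`,
#' `BFDP = ABF * PO / (1 + ABF * PO)`.
#'
#' @param or_ Pooled odds ratio (> 0).
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low < ci_high`.
#' @param params A [bfdp_params()].
#' @return A `bfdp_result`: `theta`, `V`, `ABF`, `PO`, `bfdp`, `noteworthy`.
#' @export
#' @examples
#' bfdp_from_or_ci(4.75, 2.43, 9.26)$bfdp # about 0.018
bfdp_from_or_ci <- function(or_, ci_low, ci_high, params = bfdp_params()) {
  if (or_ <= 0 || ci_low <= 0 || ci_high <= 0) {
    stop("odds ratio and confidence bounds must be positive")
  }
  if (ci_low >= ci_high) stop("ci_low must be below ci_high")
  z <- qnorm(0.975)
  theta <- log(or_)
  V <- ((log(ci_high) - log(ci_low)) / (2 * z))^2
  W <- params$prior_w
  ABF <- sqrt((V + W) / V) * exp(-theta^2 * W / (2 * V * (V + W)))
  PO <- (1 - params$prior_pi) / params$prior_pi
  bfdp <- ABF * PO / (1 + ABF * PO)
  structure(
    list(theta = theta, V = V, ABF = ABF, PO = PO, bfdp = bfdp,
         noteworthy = bfdp < params$noteworthy),
    class = "bfdp_result"
  )
}

#' Venice credibility grade
#'
#' Three-letter A/B/C grade: amount of evidence from statistical power
#' (A at `power >= 0.80`, B at `0.50 <= power < 0.80`, C below),
#' replication consistency from I-squared (A at `I2 <= 25`, B at
#' `25 < I2 < 50`, C at `I2 >= 50`), and protection from bias from the
#' small-study test (B when none detected, C otherwise; complete bias
#' assessment being impossible, A is never assigned).
#'
#' @param power Statistical power in `[0, 1]`.
#' @param i2 I-squared in `[0, 100]`.
#' @param bias_detected Logical, or an `egger_result` whose `detected`
#'   field is used (not-evaluable results count as not detected).
#' @return A `venice_grade`: `amount`, `replication`, `bias`, `as_string`.
#' @export
#' @examples
#' venice_grade(1.00, 46, FALSE)$as_string # "ABB"
venice_grade <- function(power, i2, bias_detected = FALSE) {
  stopifnot(power >= 0, power <= 1, i2 >= 0, i2 <= 100)
  if (inherits(bias_detected, "egger_result")) {
    bias_detected <- isTRUE(bias_detected$detected)
  }
  amount <- if (power >= 0.80) "A" else if (power >= 0.50) "B" else "C"
  replication <- if (i2 <= 25) "A" else if (i2 < 50) "B" else "C"
  bias <- if (bias_detected) "C" else "B"
  structure(
    list(amount = amount, replication = replication, bias = bias,
         as_string = paste0(amount, replication, bias)),
    class = "venice_grade"
  )
}

#' Three-tier credibility classification of one variant
#'
#' A variant is **highly credible** when its pooled effect is statistically
#' significant (p < 0.05) in at least two eligible genetic models AND at
#' least one significant model additionally has BFDP < 0.20, power >= 0.80
#' and I-squared not above 50 (the "qualifying" or witness model; the
#' criteria are existential over models, not conjunctive across all of
#' them). A variant significant in at least two eligible models that has no
#' witness is **less credible**; everything else is **not credible**. Only
#' models meeting the minimum-study rule contribute.
#'
#' Boundary conventions: p exactly at `alpha` is not significant; power
#' exactly 0.80 qualifies; I-squared exactly 50 qualifies (printed
#' I-squared values are integers, so the boundary is taken inclusively).
#'
#' @param per_model Data frame with one row per genetic model and columns
#'   `model`, `p`, `bfdp`, `power`, `i2`, and logical `eligible`.
#' @param alpha Significance threshold (default 0.05).
#' @param noteworthy BFDP threshold (default 0.20).
#' @return A `credibility_verdict`: `tier` (one of `"highly_credible"`,
#'   `"less_credible"`, `"not_credible"`), `n_significant_models`,
#'   `qualifying_model` (`NA` if none), `rationale` (per-model logical
#'   columns `significant`, `witness`).
#' @export
classify_variant <- function(per_model, alpha = 0.05, noteworthy = 0.20) {
  pm <- as.data.frame(per_model, stringsAsFactors = FALSE)
  needed <- c("model", "p", "bfdp", "power", "i2", "eligible")
  missing_cols <- setdiff(needed, names(pm))
  if (length(missing_cols)) {
    stop("per_model is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  pm <- pm[pm$eligible & !is.na(pm$p), , drop = FALSE]
  # canonical model order so the qualifying model is deterministic
  pm <- pm[order(match(pm$model, MODEL_LEVELS)), , drop = FALSE]
  if (nrow(pm) == 0) {
    return(structure(
      list(tier = "not_credible", n_significant_models = 0L,
           qualifying_model = NA_character_,
           rationale = data.frame(model = character(), significant = logical(),
                                  witness = logical(), stringsAsFactors = FALSE),
           no_eligible_models = TRUE),
      class = "credibility_verdict"
    ))
  }
  sig <- pm$p < alpha
  witness <- sig & !is.na(pm$bfdp) & pm$bfdp < noteworthy &
    !is.na(pm$power) & pm$power >= 0.80 &
    !is.na(pm$i2) & pm$i2 <= 50
  n_sig <- sum(sig)
  tier <- if (n_sig >= 2 && any(witness)) {
    "highly_credible"
  } else if (n_sig >= 2) {
    "less_credible"
  } else {
    "not_credible"
  }
  structure(
    list(tier = tier, n_significant_models = as.integer(n_sig),
         qualifying_model = if (any(witness)) pm$model[which(witness)[1]]
                            else NA_character_,
         rationale = data.frame(model = pm$model, significant = sig,
                                witness = witness, stringsAsFactors = FALSE),
         no_eligible_models = FALSE),
    class = "credibility_verdict"
  )
}
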