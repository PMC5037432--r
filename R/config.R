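#' Pipeline configuration
#'
#' Bundles every threshold used by the synopsis pipeline. All thresholds are
#' probabilities in (0, 1); `min_studies` is the minimum number of
#' independent studies a (variant, phenotype) pair needs before it is
#' meta-analysed.
#'
#' @param min_studies Minimum number of independent studies per variant
#'   (default 3).
#' @param alpha Two-sided significance level for pooled effects (default
#'   0.05).
#' @param alpha_het Significance level of Cochran's Q used to switch from the
#'   fixed-effect to the random-effects model (default 0.05).
#' @param egger_alpha Significance level of the Egger intercept test used to
#'   flag a small-study effect (default 0.10).
#' @param hwe_alpha Significance level for Hardy-Weinberg violation in
#'   controls (default 0.05).
#' @param prior_pi Prior probability of a true association used by the BFDP
#'   (default 0.05).
#' @param prior_w Prior variance of the log odds ratio under the alternative;
#'   the default `(log(3)/qnorm(0.975))^2` places the prior 97.5% point at an
#'   odds ratio of 3.
#' @param noteworthy BFDP noteworthiness threshold (default 0.20).
#' @param ethnicity_allow Case-insensitive ethnicity labels counted as
#'   "white" by the sensitivity layer.
#'
#' @return An object of class `credmeta_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$prior_w
pipeline_config <- function(min_studies = 3,
                            alpha = 0.05,
                            alpha_het = 0.05,
                            egger_alpha = 0.10,
                            hwe_alpha = 0.05,
                            prior_pi = 0.05,
                            prior_w = (log(3) / qnorm(0.975))^2,
                            noteworthy = 0.20,
                            ethnicity_allow = c("white", "european", "caucasian")) {
  stopifnot(
    min_studies >= 1,
    alpha > 0, alpha < 1,
    alpha_het > 0, alpha_het < 1,
    egger_alpha > 0, egger_alpha < 1,
    hwe_alpha > 0, hwe_alpha < 1,
    prior_pi > 0, prior_pi < 1,
    prior_w > 0,
    noteworthy > 0, noteworthy < 1
  )
  structure(
    list(
      min_studies = as.integer(min_studies), alpha = alpha,
      alpha_het = alpha_het, egger_alpha = egger_alpha,
      hwe_alpha = hwe_alpha, prior_pi = prior_pi, prior_w = prior_w,
      noteworthy = noteworthy,
      ethnicity_allow = tolower(ethnicity_allow)
    ),
    class = "credmeta_config"
  )
}

#' @export
print.credmeta_config <- function(x, ...) {
  cat("credmeta pipeline configuration\n")
  for (nm in setdiff(names(x), "ethnicity_allow")) {
    cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-12s %s\n", "ethnicity",
              paste(x$ethnicity_allow, collapse = ", ")))
  invisible(x)
}
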