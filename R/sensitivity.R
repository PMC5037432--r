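#' Exclusion criteria for sensitivity re-analysis
#'
#' @param drop_hwe_violating Drop studies whose control genotype counts
#'   violate Hardy-Weinberg equilibrium at `hwe_alpha`.
#' @param drop_non_white Drop studies whose ethnicity label is not on the
#'   allow-list (case-insensitive).
#' @param hwe_alpha Hardy-Weinberg violation threshold (default 0.05).
#' @param ethnicity_allow Labels counted as white populations.
#' @return An `exclusion_criteria` list.
#' @export
exclusion_criteria <- function(drop_hwe_violating = FALSE,
                               drop_non_white = FALSE,
                               hwe_alpha = 0.05,
                               ethnicity_allow = c("white", "european", "caucasian")) {
  structure(
    list(drop_hwe_violating = isTRUE(drop_hwe_violating),
         drop_non_white = isTRUE(drop_non_white),
         hwe_alpha = hwe_alpha,
         ethnicity_allow = tolower(ethnicity_allow)),
    class = "exclusion_criteria"
  )
}

#' Apply sensitivity exclusions to a dataset
#'
#' Removes records violating Hardy-Weinberg equilibrium in controls and/or
#' records from non-white populations, and logs every drop with its reason.
#' Carrier-format records are never dropped for Hardy-Weinberg (the test is
#' not evaluable on them). With both flags off the dataset is returned
#' unchanged, so a sensitivity run with no exclusions reproduces the
#' primary analysis exactly. The operation is idempotent.
#'
#' @param ds An `assoc_dataset`.
#' @param crit An [exclusion_criteria()].
#' @return List with `dataset` (filtered `assoc_dataset`) and `log` (data
#'   frame `study_id`, `variant_id`, `phenotype`, `reason`).
#' @export
apply_exclusions <- function(ds, crit = exclusion_criteria()) {
  rec <- ds$records
  keep <- rep(TRUE, nrow(rec))
  log <- list()
  note <- function(i, reason) {
    log[[length(log) + 1]] <<- data.frame(
      study_id = rec$study_id[i], variant_id = rec$variant_id[i],
      phenotype = rec$phenotype[i], reason = reason, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rec))) {
    if (crit$drop_non_white &&
        !(tolower(rec$ethnicity[i]) %in% crit$ethnicity_allow)) {
      keep[i] <- FALSE
      note(i, sprintf("non-white population (%s)", rec$ethnicity[i]))
      next
    }
    if (crit$drop_hwe_violating && !isTRUE(rec$carrier_only[i])) {
      h <- hwe_test(c(rec$control_wtwt[i], rec$control_wtvar[i],
                      rec$control_varvar[i]), alpha = crit$hwe_alpha)
      if (h$evaluable && h$violated) {
        keep[i] <- FALSE
        note(i, sprintf("controls violate HWE (p = %.3g)", h$p_value))
      }
    }
  }
  out <- ds
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  list(
    dataset = out,
    log = if (length(log)) do.call(rbind, log) else
      data.frame(study_id = character(), variant_id = character(),
                 phenotype = character(), reason = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Compare a full analysis with a sensitivity re-analysis
#'
#' Joins the per-model summary rows of two pipeline runs on
#' (variant, phenotype, model) and reports the change in pooled log odds
#' ratio, the ratio of odds ratios, significance flips, and (when verdicts
#' are present) credibility-tier flips.
#'
#' @param full,reduced Results from [run_pipeline()] (lists with `$models`
#'   and `$verdicts`).
#' @param alpha Significance threshold for flip detection.
#' @return List with `models` (per-model delta report) and `verdicts`
#'   (per-variant tier comparison).
#' @export
sensitivity_compare <- function(full, reduced, alpha = 0.05) {
  keys <- c("variant_id", "phenotype", "model")
  fm <- full$models; rm_ <- reduced$models
  merged <- merge(fm[, c(keys, "or", "p", "n_studies")],
                  rm_[, c(keys, "or", "p", "n_studies")],
                  by = keys, suffixes = c("_full", "_reduced"))
  if (nrow(merged) == 0) stop("no shared (variant, phenotype, model) keys")
  merged$delta_log_or <- log(merged$or_reduced) - log(merged$or_full)
  merged$or_ratio <- merged$or_reduced / merged$or_full
  merged$sig_full <- merged$p_full < alpha
  merged$sig_reduced <- merged$p_reduced < alpha
  merged$sig_flip <- !is.na(merged$sig_full) & !is.na(merged$sig_reduced) &
    merged$sig_full != merged$sig_reduced

  verdicts <- NULL
  if (!is.null(full$verdicts) && !is.null(reduced$verdicts)) {
    vk <- c("variant_id", "phenotype")
    verdicts <- merge(full$verdicts[, c(vk, "tier")],
                      reduced$verdicts[, c(vk, "tier")],
                      by = vk, suffixes = c("_full", "_reduced"))
    verdicts$tier_flip <- verdicts$tier_full != verdicts$tier_reduced
  }
  list(models = merged, verdicts = verdicts)
}
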