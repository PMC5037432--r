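model_row_template <- function(gene, variant_id, phenotype, model) {
  data.frame(
    gene = gene, variant_id = variant_id, phenotype = phenotype,
    model = model, n_studies = NA_integer_, n_cases = NA_integer_,
    n_controls = NA_integer_, method = NA_character_, or = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_, Q = NA_real_,
    Q_p = NA_real_, i2 = NA_real_, i2_low = NA_real_, i2_high = NA_real_,
    tau2 = NA_real_, egger_p = NA_real_, egger_detected = NA,
    power = NA_real_, bfdp = NA_real_, venice = NA_character_,
    eligible = FALSE, status = "no_data", stringsAsFactors = FALSE
  )
}

variant_f_ref <- function(ds, variant_id, phenotype) {
  if (!is.null(ds$variants) && "ref_freq_controls" %in% names(ds$variants)) {
    v <- ds$variants[ds$variants$variant_id == variant_id &
                       ds$variants$phenotype == phenotype, , drop = FALSE]
    if (nrow(v) >= 1 && !is.na(v$ref_freq_controls[1])) {
      return(v$ref_freq_controls[1])
    }
  }
  # fall back to the pooled control genotype counts of full-genotype records
  rec <- ds$records
  rec <- rec[rec$variant_id == variant_id & rec$phenotype == phenotype &
               !rec$carrier_only, , drop = FALSE]
  if (nrow(rec) == 0) return(NA_real_)
  n_wt <- sum(2 * rec$control_wtwt + rec$control_wtvar)
  n_all <- 2 * sum(rec$control_wtwt + rec$control_wtvar + rec$control_varvar)
  if (n_all == 0) NA_real_ else n_wt / n_all
}

#' Run the full synopsis pipeline on raw genotype counts
#'
#' For every eligible (variant, phenotype) pair: builds all four genetic
#' model meta-analyses (per-study odds ratios, heterogeneity, fixed/random
#' switch, pooling, Egger test), checks Hardy-Weinberg equilibrium in each
#' study's controls, estimates power at the pooled odds ratio (exposure
#' prevalence derived from the control reference-allele frequency under
#' Hardy-Weinberg), computes the BFDP from the pooled OR and CI, grades
#' each model with the Venice criteria, and classifies the variant into
#' the three credibility tiers.
#'
#' @param ds An `assoc_dataset`.
#' @param config A [pipeline_config()].
#' @return A `synopsis_results` list: `models` (one row per variant x
#'   model), `verdicts` (one row per variant), `hwe` (per-study control
#'   Hardy-Weinberg results), `log` (per-study drops and corrections),
#'   `config`.
#' @export
run_pipeline <- function(ds, config = pipeline_config()) {
  elig <- eligible_variants(ds, config$min_studies)
  if (nrow(elig) == 0) {
    warning("no (variant, phenotype) pair reaches min_studies; empty summary")
  }
  model_rows <- list()
  verdict_rows <- list()
  hwe_rows <- list()
  log_rows <- list()

  for (vi in seq_len(nrow(elig))) {
    variant_id <- elig$variant_id[vi]
    phenotype <- elig$phenotype[vi]
    gene <- elig$gene[vi]
    f_ref <- variant_f_ref(ds, variant_id, phenotype)

    rec <- ds$records[ds$records$variant_id == variant_id &
                        ds$records$phenotype == phenotype, , drop = FALSE]
    for (j in seq_len(nrow(rec))) {
      h <- if (rec$carrier_only[j]) hwe_test(c(0, NA, 0)) else
        hwe_test(c(rec$control_wtwt[j], rec$control_wtvar[j],
                   rec$control_varvar[j]), alpha = config$hwe_alpha)
      hwe_rows[[length(hwe_rows) + 1]] <- data.frame(
        variant_id = variant_id, phenotype = phenotype,
        study_id = rec$study_id[j], method = h$method, p = h$p_value,
        violated = h$violated, evaluable = h$evaluable,
        stringsAsFactors = FALSE)
    }

    for (m in MODEL_LEVELS) {
      row <- model_row_template(gene, variant_id, phenotype, m)
      res <- meta_analyse(ds, variant_id, phenotype, m, config)
      if (nrow(res$dropped) > 0) {
        log_rows[[length(log_rows) + 1]] <- cbind(
          data.frame(variant_id = variant_id, phenotype = phenotype,
                     model = m, stringsAsFactors = FALSE),
          res$dropped)
      }
      if (any(res$effects$corrected)) {
        log_rows[[length(log_rows) + 1]] <- data.frame(
          variant_id = variant_id, phenotype = phenotype, model = m,
          study_id = res$effects$study_id[res$effects$corrected],
          reason = "continuity correction (+0.5 to all cells)",
          stringsAsFactors = FALSE)
      }
      row$n_studies <- res$k
      row$status <- res$status
      if (!is.null(res$pooled)) {
        p <- res$pooled
        row$n_cases <- res$n_cases
        row$n_controls <- res$n_controls
        row$method <- p$method
        row$or <- p$or; row$ci_low <- p$ci_low; row$ci_high <- p$ci_high
        row$p <- p$p_value; row$Q <- p$Q; row$Q_p <- p$Q_p
        row$i2 <- p$I2; row$i2_low <- p$I2_ci95[1]; row$i2_high <- p$I2_ci95[2]
        row$tau2 <- p$tau2
        row$egger_p <- res$egger$p_value
        row$egger_detected <- isTRUE(res$egger$detected)
        if (!is.na(f_ref) && f_ref > 0 && f_ref < 1) {
          p0 <- exposure_prevalence(f_ref, m)
          row$power <- power_two_proportions(res$n_cases, res$n_controls,
                                             p0, p$or, alpha = config$alpha)
        }
        row$bfdp <- bfdp_from_or_ci(
          p$or, p$ci_low, p$ci_high,
          bfdp_params(config$prior_pi, config$prior_w, config$noteworthy))$bfdp
        if (!is.na(row$power)) {
          row$venice <- venice_grade(row$power, p$I2, res$egger)$as_string
        }
        row$eligible <- res$status == "ok"
      }
      model_rows[[length(model_rows) + 1]] <- row
    }
  }

  models <- if (length(model_rows)) do.call(rbind, model_rows) else
    model_row_template("", "", "", "dominant")[0, , drop = FALSE]
  rownames(models) <- NULL

  for (vi in seq_len(nrow(elig))) {
    vm <- models[models$variant_id == elig$variant_id[vi] &
                   models$phenotype == elig$phenotype[vi], , drop = FALSE]
    verdict <- classify_variant(
      data.frame(model = vm$model, p = vm$p, bfdp = vm$bfdp,
                 power = vm$power, i2 = vm$i2, eligible = vm$eligible,
                 stringsAsFactors = FALSE),
      alpha = config$alpha, noteworthy = config$noteworthy)
    verdict_rows[[length(verdict_rows) + 1]] <- data.frame(
      gene = elig$gene[vi], variant_id = elig$variant_id[vi],
      phenotype = elig$phenotype[vi], tier = verdict$tier,
      n_significant_models = verdict$n_significant_models,
      qualifying_model = verdict$qualifying_model, stringsAsFactors = FALSE)
  }
  verdicts <- if (length(verdict_rows)) do.call(rbind, verdict_rows) else
    data.frame(gene = character(), variant_id = character(),
               phenotype = character(), tier = character(),
               n_significant_models = integer(),
               qualifying_model = character(), stringsAsFactors = FALSE)
  structure(
    list(
      models = models, verdicts = verdicts,
      hwe = if (length(hwe_rows)) do.call(rbind, hwe_rows) else NULL,
      log = if (length(log_rows)) do.call(rbind, log_rows) else
        data.frame(variant_id = character(), phenotype = character(),
                   model = character(), study_id = character(),
                   reason = character(), stringsAsFactors = FALSE),
      config = config
    ),
    class = "synopsis_results"
  )
}

#' @export
print.synopsis_results <- function(x, ...) {
  cat(sprintf("synopsis_results: %d model row(s), %d variant verdict(s)\n",
              nrow(x$models), nrow(x$verdicts)))
  if (nrow(x$verdicts)) print(table(x$verdicts$tier))
  invisible(x)
}

#' Score already-pooled per-model summary rows
#'
#' The credibility layer alone: starting from per-model summary statistics
#' (pooled odds ratio, 95% CI, p-value, I-squared, power) rather than raw
#' counts, recomputes the BFDP from the OR and CI (unless a `bfdp` column
#' is already present), the Venice grade, and the three-tier classification.
#' This is the entry point for re-scoring a published synopsis table whose
#' per-study counts are not available.
#'
#' @param rows Data frame with columns `variant_id`, `phenotype`, `model`,
#'   `n_studies`, `or`, `ci_low`, `ci_high`, `p`, and optionally `gene`,
#'   `i2`, `power`, `bfdp`, `bias_detected`. Missing `bfdp` values are
#'   recomputed; `bias_detected` defaults to `FALSE`.
#' @param config A [pipeline_config()].
#' @param recompute_bfdp Force recomputation of the BFDP from the OR and CI
#'   even when a `bfdp` column is supplied.
#' @return List with `models` (input rows augmented with `bfdp`, `venice`,
#'   `eligible`) and `verdicts` (per-variant tiers).
#' @export
score_reported <- function(rows, config = pipeline_config(),
                           recompute_bfdp = FALSE) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  needed <- c("variant_id", "phenotype", "model", "n_studies",
              "or", "ci_low", "ci_high", "p")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols)) {
    stop("rows is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"gene" %in% names(rows)) rows$gene <- NA_character_
  if (!"i2" %in% names(rows)) rows$i2 <- NA_real_
  if (!"power" %in% names(rows)) rows$power <- NA_real_
  if (!"bias_detected" %in% names(rows)) rows$bias_detected <- FALSE
  if (!"bfdp" %in% names(rows)) rows$bfdp <- NA_real_
  bad <- !is.na(rows$or) & (rows$or <= 0 | rows$ci_low <= 0 |
                              rows$ci_high <= rows$ci_low)
  if (any(bad)) stop("malformed OR/CI in row(s): ",
                     paste(which(bad), collapse = ", "))

  params <- bfdp_params(config$prior_pi, config$prior_w, config$noteworthy)
  for (i in seq_len(nrow(rows))) {
    if (is.na(rows$or[i])) next
    if (recompute_bfdp || is.na(rows$bfdp[i])) {
      rows$bfdp[i] <- bfdp_from_or_ci(rows$or[i], rows$ci_low[i],
                                      rows$ci_high[i], params)$bfdp
    }
  }
  rows$venice <- NA_character_
  has_grade <- !is.na(rows$power) & !is.na(rows$i2)
  for (i in which(has_grade)) {
    rows$venice[i] <- venice_grade(rows$power[i], rows$i2[i],
                                   isTRUE(rows$bias_detected[i]))$as_string
  }
  rows$eligible <- !is.na(rows$p) & rows$n_studies >= config$min_studies

  keys <- unique(rows[, c("gene", "variant_id", "phenotype")])
  verdict_rows <- lapply(seq_len(nrow(keys)), function(i) {
    vm <- rows[rows$variant_id == keys$variant_id[i] &
                 rows$phenotype == keys$phenotype[i], , drop = FALSE]
    v <- classify_variant(
      vm[, c("model", "p", "bfdp", "power", "i2", "eligible")],
      alpha = config$alpha, noteworthy = config$noteworthy)
    data.frame(gene = keys$gene[i], variant_id = keys$variant_id[i],
               phenotype = keys$phenotype[i], tier = v$tier,
               n_significant_models = v$n_significant_models,
               qualifying_model = v$qualifying_model, stringsAsFactors = FALSE)
  })
  list(models = rows, verdicts = do.call(rbind, verdict_rows))
}

#' Packaged published synopsis summary tables
#'
#' Loads the per-model summary rows (pooled OR, 95% CI, p, I-squared with
#' CI, power, BFDP, Venice string, study count) transcribed from the
#' published paediatric IBD field-synopsis tables for Crohn's disease (CD)
#' or ulcerative colitis (UC). Rows the synopsis marked "n/a" (carrier-only
#' variants outside the dominant model, models with no informative studies)
#' are absent. A logical `bias_detected` column is derived from the third
#' letter of the printed Venice string.
#'
#' @param phenotype `"CD"` or `"UC"`.
#' @return Data frame ready for [score_reported()].
#' @export
load_printed_summaries <- function(phenotype = c("CD", "UC")) {
  phenotype <- match.arg(phenotype)
  path <- system.file("extdata",
                      sprintf("%s_printed_summaries.tsv", tolower(phenotype)),
                      package = "credmeta", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$bias_detected <- substr(df$venice, 3, 3) == "C"
  df
}

#' Packaged variant metadata from the published synopsis
#'
#' Gene, pooled sample sizes, reference allele and control reference-allele
#' frequency per variant and phenotype, as printed in the synopsis'
#' variant-selection table. Carrier-format variants have no allele
#' frequency (`NA`).
#'
#' @return Data frame with one row per (variant, phenotype).
#' @export
load_variant_info <- function() {
  path <- system.file("extdata", "variant_info.tsv", package = "credmeta",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "n/a", ""))
}
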