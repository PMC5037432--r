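#' Per-study log odds ratio from a fourfold table
#'
#' Computes the crude log odds ratio `log(ad/bc)` and its large-sample
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell is zero, 0.5
#' is added to all four cells first (Haldane-Anscombe correction) and the
#' effect is flagged `corrected`. Tables with zero exposed in both arms, or
#' zero unexposed in both arms, carry no information about the odds ratio
#' and return `NULL` (the study is dropped for that contrast; callers log
#' the drop rather than abort).
#'
#' @param t A `fourfold` table from [build_contrast()].
#' @return A `study_effect` (fields `study_id`, `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high`, `corrected`) or `NULL` for an uninformative table.
#' @export
study_log_or <- function(t) {
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  if ((a + b) == 0 || (cc + d) == 0) return(NULL)
  if ((a == 0 && cc == 0) || (b == 0 && d == 0)) return(NULL)
  corrected <- FALSE
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  log_or <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- qnorm(0.975)
  structure(
    list(study_id = t$study_id %||% NA_character_,
         log_or = log_or, se = se, or = exp(log_or),
         ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
         corrected = corrected,
         n_cases = t$a + t$b, n_controls = t$c + t$d),
    class = "study_effect"
  )
}

effects_matrix <- function(effects) {
  th <- vapply(effects, function(e) e$log_or, numeric(1))
  se <- vapply(effects, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("standard errors must be positive")
  list(th = th, se = se, k = length(th))
}

pooled_result <- function(method, th_pool, se_pool, k, Q, tau2, effects) {
  z <- qnorm(0.975)
  het <- heterogeneity_from_Q(Q, k)
  structure(
    list(
      k = k,
      n_cases = sum(vapply(effects, function(e) e$n_cases %||% NA_real_, numeric(1))),
      n_controls = sum(vapply(effects, function(e) e$n_controls %||% NA_real_, numeric(1))),
      method = method, log_or = th_pool, se = se_pool,
      or = exp(th_pool),
      ci_low = exp(th_pool - z * se_pool), ci_high = exp(th_pool + z * se_pool),
      p_value = 2 * pnorm(-abs(th_pool / se_pool)),
      Q = Q, Q_p = het$Q_p, I2 = het$I2, I2_ci95 = het$I2_ci95,
      tau2 = tau2
    ),
    class = "pooled_effect"
  )
}

#' Inverse-variance fixed-effect pooling
#'
#' Pools study log odds ratios with weights `1/se^2`. Cochran's Q is
#' computed from the same weights; a single study pools to itself with
#' `Q = 0`.
#'
#' @param effects List of `study_effect` objects.
#' @return A `pooled_effect` with `method = "fixed"`, `tau2 = 0`.
#' @export
pool_fixed <- function(effects) {
  if (length(effects) < 1) stop("at least one study effect required")
  m <- effects_matrix(effects)
  w <- 1 / m$se^2
  th_pool <- sum(w * m$th) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  Q <- sum(w * (m$th - th_pool)^2)
  pooled_result("fixed", th_pool, se_pool, m$k, Q, 0, effects)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/se^2`, then re-pooling with weights
#' `1/(se^2 + tau2)`. Q and I-squared are reported from the fixed-effect
#' weights, as is conventional.
#'
#' @param effects List of at least two `study_effect` objects.
#' @return A `pooled_effect` with `method = "random"`.
#' @export
pool_random_dl <- function(effects) {
  if (length(effects) < 2) stop("at least two study effects required")
  m <- effects_matrix(effects)
  w <- 1 / m$se^2
  th_fix <- sum(w * m$th) / sum(w)
  Q <- sum(w * (m$th - th_fix)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (m$k - 1)) / denom)
  wr <- 1 / (m$se^2 + tau2)
  th_pool <- sum(wr * m$th) / sum(wr)
  se_pool <- sqrt(1 / sum(wr))
  pooled_result("random", th_pool, se_pool, m$k, Q, tau2, effects)
}

heterogeneity_from_Q <- function(Q, k) {
  df <- k - 1
  if (df < 1) {
    return(list(Q_p = NA_real_, I2 = 0, I2_ci95 = c(NA_real_, NA_real_),
                evaluable = FALSE))
  }
  Q_p <- pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  # test-based CI on ln(H), H = sqrt(Q/df) (Higgins & Thompson)
  se_lnH <- if (Q > k) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (df - 1)) * (1 - 1 / (3 * (df - 1)^2)))
  } else {
    NA_real_
  }
  if (is.na(se_lnH)) {
    ci <- c(0, 100)
  } else {
    lnH <- log(max(sqrt(Q / df), 1))
    z <- qnorm(0.975)
    H_lo <- max(1, exp(lnH - z * se_lnH))
    H_hi <- max(1, exp(lnH + z * se_lnH))
    i2_of_H <- function(H) max(0, min(100, (H^2 - 1) / H^2 * 100))
    ci <- c(i2_of_H(H_lo), i2_of_H(H_hi))
  }
  list(Q_p = Q_p, I2 = min(100, I2), I2_ci95 = ci, evaluable = TRUE)
}

#' Heterogeneity of a set of study effects
#'
#' Cochran's Q against chi-square on k - 1 degrees of freedom,
#' `I2 = max(0, (Q - df)/Q) * 100` truncated to `[0, 100]`, and a
#' test-based 95% CI for I-squared via the log of Higgins' H statistic.
#' With fewer than two studies heterogeneity is undefined; I-squared is
#' reported as 0 with `evaluable = FALSE`.
#'
#' @param effects List of `study_effect` objects.
#' @return List with `Q`, `Q_p`, `I2`, `I2_ci95`, `evaluable`.
#' @export
heterogeneity <- function(effects) {
  m <- effects_matrix(effects)
  if (m$k < 2) {
    return(c(list(Q = 0), heterogeneity_from_Q(0, m$k)))
  }
  w <- 1 / m$se^2
  th_fix <- sum(w * m$th) / sum(w)
  Q <- sum(w * (m$th - th_fix)^2)
  c(list(Q = Q), heterogeneity_from_Q(Q, m$k))
}

#' Fixed- vs random-effects model choice
#'
#' The random-effects model is selected exactly when the heterogeneity test
#' is significant: `Q_p < alpha_het` (strict; `Q_p` equal to the threshold
#' keeps the fixed-effect model). An undefined `Q_p` (single study) keeps
#' the fixed-effect model.
#'
#' @param Q_p P-value of Cochran's Q.
#' @param alpha_het Heterogeneity significance threshold (default 0.05).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(Q_p, alpha_het = 0.05) {
  stopifnot(alpha_het > 0, alpha_het < 1)
  if (is.na(Q_p)) return("fixed")
  if (Q_p < alpha_het) "random" else "fixed"
}

#' Egger regression for small-study effects
#'
#' Ordinary least squares of the standardized effect `log_or/se` on the
#' precision `1/se`; the intercept estimates funnel-plot asymmetry and is
#' tested two-sided against t on k - 2 degrees of freedom. Needs at least
#' three studies; below that the result is flagged not evaluable and is
#' treated downstream as "no small-study effect detected".
#'
#' @param effects List of `study_effect` objects.
#' @param alpha Detection threshold on the intercept p-value (default 0.10).
#' @return An `egger_result`: `intercept`, `intercept_se`, `p_value`,
#'   `detected`, `k_used`, `evaluable`.
#' @export
egger_test <- function(effects, alpha = 0.10) {
  m <- effects_matrix(effects)
  if (m$k < 3) {
    return(structure(
      list(intercept = NA_real_, intercept_se = NA_real_,
           p_value = NA_real_, detected = FALSE, k_used = m$k,
           evaluable = FALSE),
      class = "egger_result"
    ))
  }
  y <- m$th / m$se
  x <- 1 / m$se
  xbar <- mean(x); ybar <- mean(y)
  Sxx <- sum((x - xbar)^2)
  if (Sxx == 0) {
    # identical precisions: the funnel carries no asymmetry information;
    # the line through the origin fits with intercept 0
    return(structure(
      list(intercept = 0, intercept_se = NA_real_, p_value = 1,
           detected = FALSE, k_used = m$k, evaluable = TRUE,
           degenerate = TRUE),
      class = "egger_result"
    ))
  }
  slope <- sum((x - xbar) * (y - ybar)) / Sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (m$k - 2)
  intercept_se <- sqrt(s2 * (1 / m$k + xbar^2 / Sxx))
  p <- if (intercept_se == 0) {
    if (abs(intercept) < 1e-12) 1 else 0
  } else {
    2 * pt(-abs(intercept / intercept_se), df = m$k - 2)
  }
  structure(
    list(intercept = intercept, intercept_se = intercept_se, p_value = p,
         detected = p < alpha, k_used = m$k, evaluable = TRUE),
    class = "egger_result"
  )
}

#' Meta-analyse one variant under one genetic model
#'
#' Drives the per-variant chain: contrast construction, per-study log odds
#' ratios (with continuity handling and drops), heterogeneity, the
#' fixed/random model switch, pooling, and the Egger test. Per-study
#' failures are logged, not fatal.
#'
#' @param ds An `assoc_dataset`.
#' @param variant_id,phenotype Which association to analyse.
#' @param model Genetic model label.
#' @param config A [pipeline_config()].
#' @return A `meta_result` list: `variant_id`, `phenotype`, `model`,
#'   `status` (`"ok"` or `"insufficient_studies"`), `effects` (data frame of
#'   per-study results), `pooled` (`pooled_effect` or `NULL`), `egger`,
#'   `dropped` (data frame of per-study drop reasons), `n_cases`,
#'   `n_controls` (pooled full-genotype totals of contributing studies).
#' @export
meta_analyse <- function(ds, variant_id, phenotype, model,
                         config = pipeline_config()) {
  rec <- ds$records
  rec <- rec[rec$variant_id == variant_id & rec$phenotype == phenotype, ,
             drop = FALSE]
  effects <- list()
  dropped <- list()
  n_cases <- 0L; n_controls <- 0L
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, , drop = FALSE]
    if (!record_analysable(r)) {
      dropped[[length(dropped) + 1]] <- data.frame(
        study_id = r$study_id, reason = "empty case or control arm",
        stringsAsFactors = FALSE)
      next
    }
    t <- build_contrast(r, model)
    if (is.null(t)) {
      dropped[[length(dropped) + 1]] <- data.frame(
        study_id = r$study_id, reason = "model inapplicable to record",
        stringsAsFactors = FALSE)
      next
    }
    e <- study_log_or(t)
    if (is.null(e)) {
      dropped[[length(dropped) + 1]] <- data.frame(
        study_id = r$study_id, reason = "uninformative table (double-zero margin)",
        stringsAsFactors = FALSE)
      next
    }
    # pooled totals use full study arms, matching how published synopsis
    # tables report sample sizes at the variant level
    if (isTRUE(r$carrier_only)) {
      n_cases <- n_cases + r$case_wtwt + r$case_wtvar
      n_controls <- n_controls + r$control_wtwt + r$control_wtvar
    } else {
      n_cases <- n_cases + r$case_wtwt + r$case_wtvar + r$case_varvar
      n_controls <- n_controls + r$control_wtwt + r$control_wtvar + r$control_varvar
    }
    effects[[length(effects) + 1]] <- e
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(study_id = character(), reason = character(),
               stringsAsFactors = FALSE)

  k <- length(effects)
  status <- if (k >= config$min_studies) "ok" else "insufficient_studies"
  pooled <- NULL
  egger <- NULL
  if (k >= 1) {
    het <- heterogeneity(effects)
    method <- select_model(het$Q_p, config$alpha_het)
    pooled <- if (method == "random" && k >= 2) pool_random_dl(effects)
              else pool_fixed(effects)
    egger <- egger_test(effects, alpha = config$egger_alpha)
  }
  eff_df <- if (k > 0) {
    do.call(rbind, lapply(effects, function(e)
      data.frame(study_id = e$study_id, log_or = e$log_or, se = e$se,
                 or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
                 corrected = e$corrected, stringsAsFactors = FALSE)))
  } else {
    data.frame(study_id = character(), log_or = numeric(), se = numeric(),
               or = numeric(), ci_low = numeric(), ci_high = numeric(),
               corrected = logical(), stringsAsFactors = FALSE)
  }
  structure(
    list(variant_id = variant_id, phenotype = phenotype, model = model,
         status = status, k = k, n_cases = n_cases, n_controls = n_controls,
         effects = eff_df, pooled = pooled, egger = egger, dropped = dropped),
    class = "meta_result"
  )
}

#' Forest-plot data for a meta-analysis result
#'
#' @param res A `meta_result` from [meta_analyse()].
#' @return Data frame with one row per study (label, OR, CI, normalized
#'   inverse-variance weight) plus a final `pooled` row.
#' @export
forest_data <- function(res) {
  eff <- res$effects
  if (nrow(eff) == 0) stop("no analysable studies")
  w <- 1 / eff$se^2
  out <- data.frame(
    label = eff$study_id, or = eff$or, ci_low = eff$ci_low,
    ci_high = eff$ci_high, weight = w / sum(w), stringsAsFactors = FALSE
  )
  if (!is.null(res$pooled)) {
    p <- res$pooled
    out <- rbind(out, data.frame(
      label = sprintf("pooled (%s)", p$method), or = p$or,
      ci_low = p$ci_low, ci_high = p$ci_high, weight = NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}

#' Funnel-plot data for a meta-analysis result
#'
#' @param res A `meta_result`.
#' @return Data frame of per-study `log_or` and `se`.
#' @export
funnel_data <- function(res) {
  res$effects[, c("study_id", "log_or", "se")]
}
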