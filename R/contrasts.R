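#' Build the 2x2 exposure table for one genetic model
#'
#' Recodes one study's genotype counts into the case-control fourfold table
#' of the requested genetic model:
#' \describe{
#'   \item{dominant}{carriers (het + variant homozygote) vs wild-type
#'     homozygotes;}
#'   \item{recessive}{variant homozygotes vs everyone else;}
#'   \item{additive1}{heterozygotes vs wild-type homozygotes, variant
#'     homozygotes excluded;}
#'   \item{additive2}{variant homozygotes vs wild-type homozygotes,
#'     heterozygotes excluded.}
#' }
#' The additive comparisons are genotype-restricted: the third genotype
#' class is dropped, not recoded. Carrier-format records (only carrier vs
#' non-carrier counts reported) are analysable under the dominant model
#' only; any other model returns `NULL` ("inapplicable").
#'
#' @param rec One record (single row of an `assoc_dataset`'s `records`, or a
#'   named list with the same fields).
#' @param model One of `"dominant"`, `"recessive"`, `"additive1"`,
#'   `"additive2"`.
#' @return A `fourfold` object (fields `a` exposed cases, `b` unexposed
#'   cases, `c` exposed controls, `d` unexposed controls, `model`,
#'   `corrected = FALSE`), or `NULL` when the model is inapplicable to the
#'   record.
#' @export
#' @examples
#' rec <- list(case_wtwt = 50, case_wtvar = 30, case_varvar = 20,
#'             control_wtwt = 70, control_wtvar = 20, control_varvar = 10,
#'             carrier_only = FALSE)
#' t <- build_contrast(rec, "dominant")
#' t$a * t$d / (t$b * t$c) # crude odds ratio
build_contrast <- function(rec, model) {
  model <- match.arg(model, MODEL_LEVELS)
  carrier <- isTRUE(rec$carrier_only)
  if (carrier && model != "dominant") return(NULL)

  cells <- switch(model,
    dominant = {
      cv <- if (carrier) 0 else rec$case_varvar
      gv <- if (carrier) 0 else rec$control_varvar
      c(a = rec$case_wtvar + cv, b = rec$case_wtwt,
        c = rec$control_wtvar + gv, d = rec$control_wtwt)
    },
    recessive = c(a = rec$case_varvar, b = rec$case_wtwt + rec$case_wtvar,
                  c = rec$control_varvar, d = rec$control_wtwt + rec$control_wtvar),
    additive1 = c(a = rec$case_wtvar, b = rec$case_wtwt,
                  c = rec$control_wtvar, d = rec$control_wtwt),
    additive2 = c(a = rec$case_varvar, b = rec$case_wtwt,
                  c = rec$control_varvar, d = rec$control_wtwt)
  )
  if (anyNA(cells)) return(NULL)
  structure(
    list(a = unname(cells["a"]), b = unname(cells["b"]),
         c = unname(cells["c"]), d = unname(cells["d"]),
         model = model, corrected = FALSE,
         study_id = rec$study_id %||% NA_character_),
    class = "fourfold"
  )
}

#' Variant-allele frequency in one study arm
#'
#' Computes (het + 2 x variant homozygotes) / (2 x arm size) from full
#' genotype counts. Carrier-format records do not resolve the heterozygote /
#' homozygote split, so the frequency cannot be calculated and an error is
#' raised.
#'
#' @param rec One genotype-count record.
#' @param arm `"cases"` or `"controls"`.
#' @return Variant-allele frequency in `[0, 1]`.
#' @export
variant_allele_freq <- function(rec, arm = c("cases", "controls")) {
  arm <- match.arg(arm)
  if (isTRUE(rec$carrier_only)) {
    stop("variant-allele frequency cannot be calculated for carrier-format records")
  }
  g <- if (arm == "cases") {
    c(rec$case_wtwt, rec$case_wtvar, rec$case_varvar)
  } else {
    c(rec$control_wtwt, rec$control_wtvar, rec$control_varvar)
  }
  if (anyNA(g)) stop("full genotype counts required")
  n <- sum(g)
  if (n == 0) stop("empty arm")
  (g[2] + 2 * g[3]) / (2 * n)
}
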