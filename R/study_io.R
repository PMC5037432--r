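#' @section Data model:
#' A dataset is a list with three components:
#' \describe{
#'   \item{records}{one row per (variant, phenotype, study): genotype counts
#'     `case_wtwt`, `case_wtvar`, `case_varvar`, `control_wtwt`,
#'     `control_wtvar`, `control_varvar`, plus `variant_id`, `gene`,
#'     `phenotype`, `study_id`, `ethnicity` and the logical `carrier_only`.
#'     In carrier-format rows the carrier count (het + variant homozygote)
#'     is stored in the `*_wtvar` slot and `*_varvar` is `NA`.}
#'   \item{variants}{one row per (variant, phenotype): `gene`, `ref_allele`,
#'     `ref_freq_controls` (wild-type allele frequency in controls), optional
#'     `maf`.}
#'   \item{provenance}{free-text source tag.}
#' }
#' @name dataset-model
NULL

RECORD_COUNT_COLS <- c(
  "case_wtwt", "case_wtvar", "case_varvar",
  "control_wtwt", "control_wtvar", "control_varvar"
)
RECORD_META_COLS <- c("variant_id", "gene", "phenotype", "study_id", "ethnicity")

#' Construct a genotype-count dataset
#'
#' @param records Data frame of per-study genotype counts (see
#'   [dataset-model]). A missing `carrier_only` column is inferred: rows with
#'   both `*_varvar` counts absent but carrier counts present are treated as
#'   carrier-format.
#' @param variants Optional data frame of per-variant metadata with columns
#'   `variant_id`, `phenotype`, `gene`, and `ref_freq_controls`.
#' @param provenance Free-text source tag.
#'
#' @return An object of class `assoc_dataset`.
#' @export
new_dataset <- function(records, variants = NULL, provenance = "unspecified") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_META_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in RECORD_COUNT_COLS) {
    if (!cc %in% names(records)) records[[cc]] <- NA_integer_
    v <- records[[cc]]
    if (any(!is.na(v) & (v < 0 | v != round(v)))) {
      stop("column ", cc, " contains negative or non-integer counts")
    }
    records[[cc]] <- as.integer(records[[cc]])
  }
  if (!"carrier_only" %in% names(records)) {
    records$carrier_only <- is.na(records$case_varvar) &
      is.na(records$control_varvar) &
      !is.na(records$case_wtvar) & !is.na(records$control_wtvar)
  }
  records$carrier_only <- as.logical(records$carrier_only)

  key <- paste(records$variant_id, records$phenotype, records$study_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), c("variant_id", "phenotype", "study_id")]
    stop("duplicate (variant, phenotype, study) triple(s): ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = "; "))
  }

  if (!is.null(variants)) {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
    if (!all(c("variant_id", "phenotype") %in% names(variants))) {
      stop("variants must have columns variant_id and phenotype")
    }
    if ("ref_freq_controls" %in% names(variants)) {
      bad <- !is.na(variants$ref_freq_controls) &
        (variants$ref_freq_controls < 0 | variants$ref_freq_controls > 1)
      if (any(bad)) stop("ref_freq_controls outside [0, 1]")
    }
  }

  structure(
    list(records = records, variants = variants, provenance = provenance),
    class = "assoc_dataset"
  )
}

#' @export
print.assoc_dataset <- function(x, ...) {
  nv <- length(unique(paste(x$records$variant_id, x$records$phenotype)))
  cat(sprintf(
    "assoc_dataset: %d record(s), %d (variant, phenotype) pair(s) [%s]\n",
    nrow(x$records), nv, x$provenance
  ))
  invisible(x)
}

validate_record_row <- function(row, i) {
  problems <- list()
  add <- function(field, msg) {
    problems[[length(problems) + 1]] <<- data.frame(
      row = i, field = field, message = msg, stringsAsFactors = FALSE
    )
  }
  carrier <- isTRUE(row$carrier_only)
  needed <- if (carrier) {
    c("case_wtwt", "case_wtvar", "control_wtwt", "control_wtvar")
  } else {
    RECORD_COUNT_COLS
  }
  for (cc in needed) {
    v <- row[[cc]]
    if (is.na(v)) {
      add(cc, "count is missing")
    } else if (v < 0 || v != round(v)) {
      add(cc, sprintf("count '%s' is not a non-negative integer", format(v)))
    }
  }
  if (carrier && (!is.na(row$case_varvar) || !is.na(row$control_varvar))) {
    add("carrier_only", "carrier-format row must leave varvar counts empty")
  }
  if (length(problems) == 0) NULL else do.call(rbind, problems)
}

#' Read a genotype-count dataset from a delimited file
#'
#' Rows violating the record invariants (missing or negative counts,
#' non-integer counts) are rejected, not fatal: they are dropped from the
#' returned dataset and reported row-by-row in the `rejected` attribute.
#' Structural problems (missing file, missing mandatory column, duplicate
#' (variant, phenotype, study) triples) are errors.
#'
#' @param path Path to the records table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param variants_path Optional path to a per-variant metadata table.
#' @param col_map Optional named character vector mapping file headers to the
#'   canonical snake_case column names, e.g.
#'   `c(SNP = "variant_id", AA_cases = "case_wtwt")`.
#' @param provenance Source tag stored on the dataset (defaults to `path`).
#'
#' @return An `assoc_dataset`; rejected rows (if any) are in
#'   `attr(ds, "rejected")` with columns `row`, `field`, `message`.
#' @export
read_dataset <- function(path, dialect = c("tsv", "csv"), variants_path = NULL,
                         col_map = NULL, provenance = path) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  missing_cols <- setdiff(RECORD_META_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cc in RECORD_COUNT_COLS) {
    if (!cc %in% names(raw)) raw[[cc]] <- NA_real_
    raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  }
  if (!"carrier_only" %in% names(raw)) {
    raw$carrier_only <- is.na(raw$case_varvar) & is.na(raw$control_varvar) &
      !is.na(raw$case_wtvar) & !is.na(raw$control_wtvar)
  } else {
    raw$carrier_only <- as.logical(raw$carrier_only)
  }

  rejected <- list()
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    probs <- validate_record_row(raw[i, , drop = FALSE], i)
    if (!is.null(probs)) {
      keep[i] <- FALSE
      rejected[[length(rejected) + 1]] <- probs
    }
  }
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)

  records <- raw[keep, , drop = FALSE]
  rownames(records) <- NULL
  for (cc in RECORD_COUNT_COLS) records[[cc]] <- as.integer(records[[cc]])

  variants <- NULL
  if (!is.null(variants_path)) {
    if (!file.exists(variants_path)) stop("file not found: ", variants_path)
    variants <- read.delim(variants_path, sep = sep, stringsAsFactors = FALSE,
                           na.strings = c("NA", "n/a", ""))
  }

  ds <- new_dataset(records, variants, provenance = provenance)
  attr(ds, "rejected") <- rejected
  if (nrow(rejected) > 0) {
    warning(sprintf("rejected %d row(s); see attr(., 'rejected')",
                    length(unique(rejected$row))))
  }
  ds
}

#' Write a dataset back to delimited text
#'
#' Counts and metadata round-trip exactly: `read_dataset()` on the written
#' files reproduces the in-memory dataset.
#'
#' @param ds An `assoc_dataset`.
#' @param path Output path for the records table.
#' @param dialect `"tsv"` or `"csv"`.
#' @param variants_path Optional output path for the variants table.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path, dialect = c("tsv", "csv"),
                          variants_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  cols <- c(RECORD_META_COLS, RECORD_COUNT_COLS, "carrier_only")
  write.table(ds$records[, cols], path, sep = sep, row.names = FALSE,
              quote = FALSE, na = "")
  if (!is.null(variants_path) && !is.null(ds$variants)) {
    write.table(ds$variants, variants_path, sep = sep, row.names = FALSE,
                quote = FALSE, na = "")
  }
  invisible(path)
}

record_analysable <- function(rec) {
  if (isTRUE(rec$carrier_only)) {
    ct <- rec$case_wtwt + rec$case_wtvar
    nt <- rec$control_wtwt + rec$control_wtvar
  } else {
    ct <- rec$case_wtwt + rec$case_wtvar + rec$case_varvar
    nt <- rec$control_wtwt + rec$control_wtvar + rec$control_varvar
  }
  !is.na(ct) && !is.na(nt) && ct >= 1 && nt >= 1
}

#' List (variant, phenotype) pairs with enough independent studies
#'
#' A pair is eligible when at least `min_studies` distinct studies contribute
#' an analysable record (case and control totals both at least 1). Output is
#' ordered by gene, then variant id, so repeated runs are deterministic.
#'
#' @param ds An `assoc_dataset`.
#' @param min_studies Minimum distinct study count (default 3).
#' @return Data frame with columns `gene`, `variant_id`, `phenotype`,
#'   `n_studies`.
#' @export
eligible_variants <- function(ds, min_studies = 3) {
  stopifnot(min_studies >= 1)
  rec <- ds$records
  ok <- vapply(seq_len(nrow(rec)), function(i)
    record_analysable(rec[i, , drop = FALSE]), logical(1))
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(data.frame(gene = character(), variant_id = character(),
                      phenotype = character(), n_studies = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    study_id ~ gene + variant_id + phenotype, data = rec,
    FUN = function(s) length(unique(s))
  )
  names(agg)[names(agg) == "study_id"] <- "n_studies"
  agg <- agg[agg$n_studies >= min_studies, , drop = FALSE]
  agg <- agg[order(agg$gene, agg$variant_id, agg$phenotype), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "n/a", formatC(x, digits = digits, format = "fg"))
}

#' Write the per-variant summary table
#'
#' Lays the per-model results out one row per (variant, phenotype) with a
#' block of columns per genetic model in the fixed order dominant,
#' recessive, additive1, additive2 (mirroring a published synopsis table:
#' OR (95% CI), p, I-squared (CI), power, BFDP, Venice string). A
#' machine-readable JSON file with full numeric precision is written next to
#' it; [read_summary_results()] restores it exactly.
#'
#' @param results Per-model results data frame as produced by
#'   [run_pipeline()] (`$models`) or [score_reported()] (`$models`).
#' @param path Output TSV path; the JSON twin replaces the extension with
#'   `.json`.
#' @param digits Significant digits for the human-readable table.
#' @return Invisibly, the JSON path.
#' @export
write_summary_table <- function(results, path, digits = 3) {
  if (nrow(results) == 0) stop("results is empty")
  keys <- unique(results[, c("gene", "variant_id", "phenotype")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    out <- keys[i, ]
    for (m in MODEL_LEVELS) {
      r <- results[results$variant_id == out$variant_id &
                     results$phenotype == out$phenotype &
                     results$model == m, , drop = FALSE]
      blk <- if (nrow(r) == 1 && !is.na(r$or)) {
        data.frame(
          n = r$n_studies,
          or_ci = sprintf("%s (%s, %s)", fmt_num(r$or, digits),
                          fmt_num(r$ci_low, digits), fmt_num(r$ci_high, digits)),
          p = fmt_num(r$p, digits),
          i2_ci = sprintf("%s (%s, %s)", fmt_num(r$i2, 2),
                          fmt_num(r$i2_low, 2), fmt_num(r$i2_high, 2)),
          power = fmt_num(r$power, 2),
          bfdp = fmt_num(r$bfdp, 3),
          venice = if (is.na(r$venice)) "n/a" else r$venice,
          stringsAsFactors = FALSE
        )
      } else {
        data.frame(n = NA_integer_, or_ci = "n/a", p = "n/a", i2_ci = "n/a",
                   power = "n/a", bfdp = "n/a", venice = "n/a",
                   stringsAsFactors = FALSE)
      }
      names(blk) <- paste(m, names(blk), sep = "_")
      out <- cbind(out, blk)
    }
    out
  })
  wide <- do.call(rbind, rows)
  write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "n/a")
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(results, json_path, digits = NA, na = "null")
  invisible(json_path)
}

#' Read back full-precision summary results
#'
#' @param json_path Path written by [write_summary_table()].
#' @return The per-model results data frame, numerically identical to the
#'   one that was written.
#' @export
read_summary_results <- function(json_path) {
  df <- jsonlite::fromJSON(json_path)
  as.data.frame(df, stringsAsFactors = FALSE)
}
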