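test_that("a dataset round-trips through write and read bit-identically", {
  records <- rbind(
    make_record(c(50, 30, 20), c(70, 20, 10), study_id = "s1"),
    make_record(c(40, 35, 25), c(65, 25, 10), study_id = "s2"),
    make_record(c(80, 20), c(90, 10), study_id = "s3", carrier_only = TRUE)
  )
  variants <- data.frame(variant_id = "rs_test", phenotype = "CD",
                         gene = "GENE", ref_allele = "A",
                         ref_freq_controls = 0.8, stringsAsFactors = FALSE)
  ds <- new_dataset(records, variants, provenance = "unit test")

  rec_path <- withr::local_tempfile(fileext = ".tsv")
  var_path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, rec_path, variants_path = var_path)
  ds2 <- read_dataset(rec_path, variants_path = var_path)

  cols <- c("variant_id", "gene", "phenotype", "study_id", "ethnicity",
            "case_wtwt", "case_wtvar", "case_varvar",
            "control_wtwt", "control_wtvar", "control_varvar", "carrier_only")
  expect_identical(ds2$records[, cols], ds$records[, cols])
  expect_equal(ds2$variants$ref_freq_controls, 0.8)
  expect_true(ds2$records$carrier_only[3])
  expect_true(is.na(ds2$records$case_varvar[3]))
})

test_that("invalid rows are rejected with row-level diagnostics, not errors", {
  records <- rbind(
    make_record(study_id = "s1"),
    make_record(study_id = "s2"),
    make_record(study_id = "s3")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  txt <- readLines(path)
  txt[3] <- sub("^(\\S+\t\\S+\t\\S+\t\\S+\t\\S+\t)50", "\\1-1", txt[3])
  writeLines(txt, path)

  expect_warning(ds <- read_dataset(path), "rejected 1 row")
  expect_equal(nrow(ds$records), 2)
  rej <- attr(ds, "rejected")
  expect_equal(rej$row, 2)
  expect_equal(rej$field, "case_wtwt")
  expect_match(rej$message, "-1")
})

test_that("structural problems are fatal", {
  records <- make_record()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(records[, setdiff(names(records), "study_id")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(path), "study_id")
  expect_error(read_dataset(file.path(tempdir(), "no_such_file.tsv")),
               "not found")
  expect_error(
    new_dataset(rbind(make_record(study_id = "s1"),
                      make_record(study_id = "s1"))),
    "duplicate"
  )
})

test_that("carrier-format rows are inferred from empty varvar columns", {
  rec <- make_record(c(80, 20), c(90, 10), carrier_only = TRUE)
  rec$carrier_only <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  ds <- read_dataset(path)
  expect_true(ds$records$carrier_only[1])
})

test_that("eligibility counts distinct studies and is monotone in the threshold", {
  records <- rbind(
    make_record(study_id = "s1", variant_id = "rsA"),
    make_record(study_id = "s2", variant_id = "rsA"),
    make_record(study_id = "s3", variant_id = "rsA"),
    make_record(study_id = "s1", variant_id = "rsB"),
    make_record(study_id = "s2", variant_id = "rsB"),
    make_record(case = c(0, 0, 0), study_id = "s1", variant_id = "rsC")
  )
  ds <- new_dataset(records)

  e3 <- eligible_variants(ds, min_studies = 3)
  expect_equal(e3$variant_id, "rsA")
  e1 <- eligible_variants(ds, min_studies = 1)
  expect_setequal(e1$variant_id, c("rsA", "rsB")) # rsC has an empty case arm

  for (m in 1:4) {
    high <- eligible_variants(ds, m)
    if (m < 4) {
      low <- eligible_variants(ds, m + 1)
      expect_true(all(paste(low$variant_id, low$phenotype) %in%
                        paste(high$variant_id, high$phenotype)))
    }
  }
})

test_that("summary table writes model blocks in fixed order and round-trips JSON", {
  cd <- load_printed_summaries("CD")
  sc <- score_reported(cd)
  path <- withr::local_tempfile(fileext = ".tsv")
  json_path <- write_summary_table(sc$models, path)

  wide <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(wide), 20)
  carrier_row <- wide[wide$variant_id == "rs5743289", ]
  expect_false(carrier_row$dominant_or_ci == "n/a")
  expect_equal(carrier_row$recessive_or_ci, "n/a")
  expect_equal(carrier_row$additive2_venice, "n/a")

  back <- read_summary_results(json_path)
  expect_equal(back$or, sc$models$or, tolerance = 0)
  expect_equal(back$bfdp, sc$models$bfdp, tolerance = 0)
})
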