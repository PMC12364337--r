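test_that("a small quarter joins DEMO, DRUG and REAC rows on primaryid", {
  dir <- withr::local_tempdir()
  b <- write_raw_quarter(
    dir, "2015Q1",
    demo_lines = c("primaryid$caseid$caseversion$fda_dt",
                   "1001$C1$1$20150302",
                   "1002$C2$1$20150415",
                   "1003$C3$2$20150601"),
    drug_lines = c("primaryid$drug_seq$role_cod$drugname$prod_ai",
                   "1001$1$PS$XALKORI$CRIZOTINIB",
                   "1001$2$C$ASPIRIN$",
                   "1002$1$PS$IMATINIB$IMATINIB"),
    reac_lines = c("primaryid$pt",
                   "1001$Pleural effusion",
                   "1001$Nausea",
                   "1002$Rash")
  )
  res <- read_quarter(b)
  s <- res$series
  expect_equal(nrow(s$reports), 3)
  expect_setequal(s$reports$primary_id, c("1001", "1002", "1003"))
  expect_equal(nrow(s$drugs), 3)
  expect_equal(sum(s$drugs$primary_id == "1001"), 2)
  expect_equal(nrow(s$reactions), 3)
  expect_equal(s$reports$receipt_date[s$reports$primary_id == "1001"],
               as.Date("2015-03-02"))
  # report 1003 has no drug and no reaction rows: retained but flagged
  r3 <- s$reports[s$reports$primary_id == "1003", ]
  expect_false(r3$has_drug)
  expect_false(r3$has_reaction)
  expect_true(all(s$reports$has_drug[s$reports$primary_id != "1003"]))
  # active_ingredient empty -> NA
  expect_true(is.na(s$drugs$active_ingredient[s$drugs$verbatim_name ==
                                                "ASPIRIN"]))
  # parse stats: all rows kept, conservation holds
  st <- res$bundle$parse_stats
  expect_equal(st$rows_read, c(3, 3, 3))
  expect_true(all(st$rows_read == st$rows_kept + st$rows_rejected))
})

test_that("empty DEMO body with a valid header yields an empty series", {
  dir <- withr::local_tempdir()
  b <- write_raw_quarter(
    dir, "E",
    c("primaryid$caseid$caseversion$fda_dt"),
    c("primaryid$drug_seq$role_cod$drugname$prod_ai"),
    c("primaryid$pt"))
  res <- read_quarter(b)
  expect_equal(nrow(res$series$reports), 0)
  expect_equal(res$bundle$parse_stats$rows_read, c(0, 0, 0))
})

test_that("a missing required header column is a hard error naming it", {
  dir <- withr::local_tempdir()
  b <- write_raw_quarter(
    dir, "X",
    c("primaryid$caseid$caseversion$fda_dt", "1$C$1$20150101"),
    c("primaryid$drug_seq$drugname$prod_ai", "1$1$ASPIRIN$"),  # no role_cod
    c("primaryid$pt", "1$Nausea"))
  expect_error(read_quarter(b), "role_cod")
})

test_that("malformed rows are rejected, counted by reason, never silently dropped", {
  dir <- withr::local_tempdir()
  b <- write_raw_quarter(
    dir, "R",
    c("primaryid$caseid$caseversion$fda_dt",
      "1001$C1$1$20150302",
      "1001$C1$1$20150302",      # duplicate primaryid
      "$C9$1$20150101",          # missing primaryid
      "too$few"),                # field count mismatch
    c("primaryid$drug_seq$role_cod$drugname$prod_ai",
      "1001$1$PS$XALKORI$CRIZOTINIB",
      "1001$2$XX$ASPIRIN$",      # invalid role code
      "1001$zz$PS$ASPIRIN$"),    # bad drug_seq
    c("primaryid$pt",
      "1001$Pleural effusion",
      "1001$PLEURAL EFFUSION",   # duplicate PT (case-insensitive)
      "1001$"))                  # missing pt
  res <- read_quarter(b)
  st <- res$bundle$parse_stats
  expect_equal(st$rows_read, c(4, 3, 3))
  expect_equal(st$rows_kept, c(1, 1, 1))
  expect_true(all(st$rows_read == st$rows_kept + st$rows_rejected))
  lg <- res$bundle$reject_log
  reason_n <- function(f, r) sum(lg$n[lg$file == f & lg$reason == r])
  expect_equal(reason_n("DEMO", "duplicate_primaryid"), 1)
  expect_equal(reason_n("DEMO", "missing_primaryid"), 1)
  expect_equal(reason_n("DEMO", "field_count_mismatch"), 1)
  expect_equal(reason_n("DRUG", "invalid_role_code"), 1)
  expect_equal(reason_n("DRUG", "bad_drug_seq"), 1)
  expect_equal(reason_n("REAC", "duplicate_pt"), 1)
  expect_equal(reason_n("REAC", "missing_pt"), 1)
})

test_that("FAERS dates parse with truncated forms resolving to period start", {
  expect_equal(parse_faers_date(c("20150321", "201503", "2015", "", "banana")),
               as.Date(c("2015-03-21", "2015-03-01", "2015-01-01", NA, NA)))
})

test_that("write then read round-trips a synthetic quarter exactly", {
  dir <- withr::local_tempdir()
  s <- generate_reports(synthetic_config(n_reports = 100, seed = 42))
  b <- write_quarter(s, dir, "RT")
  res <- read_quarter(b)
  got <- res$series
  expect_equal(sum(res$bundle$parse_stats$rows_rejected), 0)
  # same reports, same drug/reaction multisets
  ord <- function(df) df[do.call(order, as.list(df)), , drop = FALSE]
  expect_equal(
    ord(got$reports[, c("primary_id", "case_id", "case_version",
                        "receipt_date")]),
    ord(s$reports[, c("primary_id", "case_id", "case_version",
                      "receipt_date")]),
    ignore_attr = TRUE)
  expect_equal(ord(got$drugs), ord(s$drugs), ignore_attr = TRUE)
  expect_equal(ord(got$reactions), ord(s$reactions), ignore_attr = TRUE)
})

test_that("the field delimiter is stripped from values on write", {
  dir <- withr::local_tempdir()
  s <- series_from_specs(list(report_spec(
    "1", "C1", 1, "2015-06-01",
    drugs = list(c("BRAND$NAME 10$MG", "PS")),
    reactions = "Nausea")))
  b <- write_quarter(s, dir, "D")
  got <- read_quarter(b)$series
  expect_equal(nrow(got$reports), 1)
  expect_equal(got$drugs$verbatim_name, "BRANDNAME 10MG")
  # and the round-trip of the sanitized form is stable
  b2 <- write_quarter(got, dir, "D2")
  expect_equal(read_quarter(b2)$series$drugs$verbatim_name,
               "BRANDNAME 10MG")
})

test_that("empty series writes valid header-only files", {
  dir <- withr::local_tempdir()
  s <- generate_reports(synthetic_config(n_reports = 5, seed = 1))
  empty <- filter_reports(s, character(0))
  empty$provenance <- empty$provenance[0, ]
  b <- write_quarter(empty, dir, "E")
  expect_equal(readLines(b$demo_path), "primaryid$caseid$caseversion$fda_dt")
  res <- read_quarter(b)
  expect_equal(nrow(res$series$reports), 0)
})

test_that("merging quarters keeps the later version of a resubmitted primaryid", {
  dir <- withr::local_tempdir()
  b1 <- write_raw_quarter(
    dir, "Q1",
    c("primaryid$caseid$caseversion$fda_dt", "1001$C1$1$20150302"),
    c("primaryid$drug_seq$role_cod$drugname$prod_ai", "1001$1$PS$ASPIRIN$"),
    c("primaryid$pt", "1001$Nausea"))
  b2 <- write_raw_quarter(
    dir, "Q2",
    c("primaryid$caseid$caseversion$fda_dt", "1001$C1$1$20150901",
      "2001$C2$1$20150905"),
    c("primaryid$drug_seq$role_cod$drugname$prod_ai", "2001$1$PS$IMATINIB$"),
    c("primaryid$pt", "2001$Rash"))
  res <- read_quarters(find_quarters(dir))
  s <- res$series
  expect_equal(nrow(s$reports), 2)
  expect_equal(s$reports$receipt_date[s$reports$primary_id == "1001"],
               as.Date("2015-09-01"))
  stages <- s$provenance$stage
  expect_equal(stages[(length(stages) - 1):length(stages)],
               c("read", "merge"))
  expect_equal(s$provenance$reports_out[length(stages)], 2)
})
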