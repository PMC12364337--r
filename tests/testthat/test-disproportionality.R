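crizotinib_map <- function() drug_synonym_map("CRIZOTINIB", "XALKORI")

test_that("an 8-report hand-built series partitions into the expected cells", {
  s <- series_from_specs(list(
    # 2 drug + event
    report_spec("1", "C1", 1, "2015-01-01",
                drugs = list(c("CRIZOTINIB", "PS")),
                reactions = "Pleural effusion"),
    report_spec("2", "C2", 1, "2015-01-01",
                drugs = list(c("XALKORI", "PS")),
                reactions = c("Pleural effusion", "Nausea")),
    # 1 drug only
    report_spec("3", "C3", 1, "2015-01-01",
                drugs = list(c("CRIZOTINIB", "PS")), reactions = "Rash"),
    # 2 event only
    report_spec("4", "C4", 1, "2015-01-01",
                drugs = list(c("IMATINIB", "PS")),
                reactions = "Pleural effusion"),
    report_spec("5", "C5", 1, "2015-01-01",
                reactions = "Pleural effusion"),
    # 3 neither
    report_spec("6", "C6", 1, "2015-01-01",
                drugs = list(c("ASPIRIN", "C")), reactions = "Nausea"),
    report_spec("7", "C7", 1, "2015-01-01"),
    # SS-role crizotinib + event: background under the PS restriction
    report_spec("8", "C8", 1, "2015-01-01",
                drugs = list(c("CRIZOTINIB", "SS")),
                reactions = "Pleural effusion")
  ))
  tab <- build_contingency(s, crizotinib_map(), "Pleural effusion",
                           require_primary_suspect = TRUE)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 3, 2))
  expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(s$reports))
  # lifting the PS restriction moves the SS report from c to a
  tab2 <- build_contingency(s, crizotinib_map(), "Pleural effusion",
                            require_primary_suspect = FALSE)
  expect_equal(tab2$a, tab$a + 1)
  expect_equal(tab2$c, tab$c - 1)
})

test_that("a series with no drug matches puts everything in the background", {
  s <- random_series(40, seed = 2)
  tab <- build_contingency(s, drug_synonym_map("NONEXISTENTDRUG"),
                           "Pleural effusion")
  expect_equal(tab$a, 0)
  expect_equal(tab$b, 0)
  expect_equal(tab$c + tab$d, nrow(s$reports))
})

test_that("contingency construction matches brute-force enumeration on random series", {
  maps <- list(crizotinib_map(), drug_synonym_map("ALECTINIB", "ALECENSA"))
  for (seed in 1:12) {
    s <- random_series(80, seed = 1000 + seed)
    map <- maps[[1 + seed %% 2]]
    flag <- seed %% 3 != 0
    tab <- build_contingency(s, map, c("Pleural effusion"), flag)
    oracle <- oracle_contingency(s, map$synonyms, "Pleural effusion", flag)
    expect_equal(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), oracle)
  }
})

test_that("the balanced table gives ROR 1 with a CI straddling 1", {
  r <- compute_ror(contingency_table(10, 10, 10, 10))
  expect_equal(r$ror, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  expect_false(r$is_signal)
})

test_that("ROR and Woolf CI reproduce the frozen reference values", {
  # reference computed beforehand with an independent odds-ratio oracle
  r <- compute_ror(contingency_table(20, 80, 100, 9800))
  expect_equal(r$ror, 24.5)
  expect_equal(r$se_log, sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 9800),
               tolerance = 1e-12)
  expect_equal(r$ci_low, 14.448136, tolerance = 1e-6)
  expect_equal(r$ci_high, 41.545152, tolerance = 1e-6)
  expect_false(r$corrected)
  expect_equal(r$n_reports, 20)
  expect_true(r$is_signal)
})

test_that("zero cells trigger the Haldane-Anscombe correction and flag", {
  r <- compute_ror(contingency_table(0, 10, 10, 100))
  expect_true(r$corrected)
  expect_equal(r$ror, (0.5 * 100.5) / (10.5 * 10.5), tolerance = 1e-12)
  expect_equal(r$n_reports, 0)
  expect_error(compute_ror(contingency_table(0, 0, 0, 0)), "undefined")
})

test_that("swapping exposure rows inverts the estimate and its interval", {
  set.seed(9)
  for (i in 1:20) {
    cells <- sample(1:500, 4, replace = TRUE)
    r <- compute_ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    inv <- compute_ror(contingency_table(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(inv$ror, 1 / r$ror, tolerance = 1e-12)
    expect_equal(inv$ci_low, 1 / r$ci_high, tolerance = 1e-12)
    expect_equal(inv$ci_high, 1 / r$ci_low, tolerance = 1e-12)
  }
})

test_that("the point estimate is the geometric mean of its CI bounds", {
  set.seed(10)
  for (i in 1:30) {
    cells <- sample(1:2000, 4, replace = TRUE)
    r <- compute_ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(sqrt(r$ci_low * r$ci_high), r$ror, tolerance = 1e-9)
    expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
  }
})

test_that("implied_ror_from_ci inverts log-symmetric intervals", {
  expect_equal(round(implied_ror_from_ci(6.60, 9.12), 2), 7.76)
  expect_equal(round(implied_ror_from_ci(7.10, 11.41), 2), 9.00)
  expect_equal(implied_ror_from_ci(1, 1), 1)
  expect_error(implied_ror_from_ci(-1, 2), "positive")
  expect_error(implied_ror_from_ci(3, 2), "exceed")
})

test_that("the tri-criteria signal rule applies strict thresholds", {
  crit <- signal_criteria()
  mk <- function(ror, lo, n) list(ror = ror, ci_low = lo, n_reports = n)
  expect_true(classify_signal(mk(4.76, 3.80, 76), crit))
  expect_false(classify_signal(mk(1.0, 0.8, 1000), crit))
  expect_false(classify_signal(mk(2.5, 0.95, 50), crit))   # CI bound fails
  expect_false(classify_signal(mk(2.5, 1.5, 9), crit))     # n fails
  expect_false(classify_signal(mk(2.0, 1.5, 50), crit))    # ROR not > 2.00
  expect_false(classify_signal(mk(2.5, 1.0, 50), crit))    # bound not > 1.00
  expect_true(classify_signal(mk(2.01, 1.01, 10), crit))   # minimal pass
})

test_that("run_analysis yields one row per (drug, event) pair and isolates errors", {
  s <- random_series(120, seed = 77)
  res <- run_analysis(s)
  expect_equal(nrow(res), 10)
  expect_equal(unique(res$drug), names(default_synonym_maps()))
  # rows with zero a+b and zero c never abort the run; all-zero impossible here
  expect_true(all(!is.na(res$ror) | !is.na(res$error)))
  # empty drug list -> empty table
  expect_equal(nrow(run_analysis(s, drugs = list())), 0)
})

test_that("run_analysis reports an error row for an all-zero table without aborting", {
  s <- series_from_specs(list())
  expect_equal(nrow(s$reports), 0)
  res <- run_analysis(s, drugs = list(crizotinib_map()),
                      event_term_sets = list("Pleural effusion" =
                                               "Pleural effusion"))
  expect_equal(nrow(res), 1)
  expect_true(is.na(res$ror))
  expect_match(res$error, "zero")
})

test_that("the shipped reference table is internally Woolf-consistent", {
  ref <- alk_effusion_reference()
  expect_equal(nrow(ref), 10)
  implied <- implied_ror_from_ci(ref$ci_low, ref$ci_high)
  expect_true(all(abs(implied - ref$ror) <= 0.02))
  expect_gte(sum(round(implied, 2) == ref$ror), 6)
})
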