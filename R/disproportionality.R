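#' A 2x2 contingency table of report counts
#'
#' Cross-classifies a cleaned report series by exposure to a target drug
#' and presence of a target adverse event:
#' `a` = drug and event, `b` = drug only, `c` = event only,
#' `d` = neither. Cells are report counts; every report contributes to
#' exactly one cell, so `a + b + c + d` is the series size.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>  (reports)\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for one (drug, event) pair
#'
#' The background (cells `c` and `d`) comprises every cleaned report not
#' matching the target drug — all other drugs, kinase inhibitors
#' included.
#'
#' @param series A deduplicated `case_series`.
#' @param drug A `drug_synonym_map` for the target drug.
#' @param event_terms Character vector of target preferred terms.
#' @param require_primary_suspect Restrict drug matches to primary-suspect
#'   entries (default `TRUE`).
#' @return A `contingency_table`.
#' @export
build_contingency <- function(series, drug, event_terms,
                              require_primary_suspect = TRUE) {
  dm <- match_drug(series, drug, require_primary_suspect)
  em <- match_event(series, event_terms)
  contingency_table(a = sum(dm & em), b = sum(dm & !em),
                    c = sum(!dm & em), d = sum(!dm & !em))
}

#' Signal classification thresholds
#'
#' The tri-criteria rule: a (drug, event) pair is a signal when the ROR
#' exceeds `min_ror`, the lower 95% confidence bound exceeds
#' `min_ci_low`, and at least `min_reports` drug-and-event reports exist.
#' ROR and bound comparisons are strict; the report-count comparison is
#' `>=`.
#'
#' @param min_ror ROR threshold (default 2.00).
#' @param min_ci_low Lower-CI threshold (default 1.00).
#' @param min_reports Minimum number of drug-and-event reports
#'   (default 10).
#' @param z_quantile Normal quantile for the CI (default 1.959964,
#'   two-sided 95%).
#' @return An object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_ror = 2.00, min_ci_low = 1.00,
                            min_reports = 10L, z_quantile = 1.959964) {
  if (any(c(min_ror, min_ci_low, min_reports, z_quantile) <= 0)) {
    stop("all thresholds must be strictly positive", call. = FALSE)
  }
  structure(list(min_ror = min_ror, min_ci_low = min_ci_low,
                 min_reports = as.integer(min_reports),
                 z_quantile = z_quantile),
            class = "signal_criteria")
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' Computes `ROR = (a*d)/(b*c)` with the Woolf log-scale interval:
#' `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)` and
#' `CI = exp(ln ROR +- z * SE)`. The interval is symmetric in log space,
#' so the point estimate is the geometric mean of its bounds. If any cell
#' is zero the Haldane-Anscombe correction adds 0.5 to all four cells
#' before computing, and the result is flagged `corrected`. `n_reports`
#' is always the uncorrected cell `a`.
#'
#' @param table A `contingency_table`.
#' @param criteria A `signal_criteria` (supplies the z quantile and the
#'   signal classification thresholds).
#' @return An object of class `disprop_result` with fields `ror`,
#'   `se_log`, `ci_low`, `ci_high`, `n_reports`, `corrected`,
#'   `is_signal`.
#' @export
compute_ror <- function(table, criteria = signal_criteria()) {
  stopifnot(inherits(table, "contingency_table"),
            inherits(criteria, "signal_criteria"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (all(cells == 0)) {
    stop("all four cells are zero: ROR undefined", call. = FALSE)
  }
  corrected <- any(cells == 0)
  work <- as.numeric(cells) + if (corrected) 0.5 else 0
  ror <- (work[1] * work[4]) / (work[2] * work[3])
  se_log <- sqrt(sum(1 / work))
  half <- criteria$z_quantile * se_log
  result <- structure(
    list(ror = ror, se_log = se_log,
         ci_low = exp(log(ror) - half), ci_high = exp(log(ror) + half),
         n_reports = table$a, corrected = corrected, is_signal = NA),
    class = "disprop_result"
  )
  result$is_signal <- classify_signal(result, criteria)
  result
}

#' @export
print.disprop_result <- function(x, ...) {
  cat(sprintf("<disprop_result> ROR %.2f (95%% CI %.2f-%.2f), n = %d%s%s\n",
              x$ror, x$ci_low, x$ci_high, x$n_reports,
              if (x$corrected) ", zero-cell corrected" else "",
              if (isTRUE(x$is_signal)) ", SIGNAL" else ""))
  invisible(x)
}

#' Point estimate implied by a log-symmetric confidence interval
#'
#' Inverts the Woolf construction: a log-symmetric interval has its point
#' estimate at the geometric mean of its bounds,
#' `exp((ln lo + ln hi)/2) = sqrt(lo*hi)`. Useful for auditing published
#' ROR tables that print only rounded bounds.
#'
#' @param ci_low,ci_high Positive CI bounds, `ci_low <= ci_high`.
#' @return The implied point estimate.
#' @export
#' @examples
#' implied_ror_from_ci(6.60, 9.12) # ~7.76
implied_ror_from_ci <- function(ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) {
    stop("confidence bounds must be positive", call. = FALSE)
  }
  if (any(ci_low > ci_high)) {
    stop("ci_low must not exceed ci_high", call. = FALSE)
  }
  sqrt(ci_low * ci_high)
}

#' Apply the tri-criteria signal rule
#'
#' @param result A `disprop_result` (or any list with `ror`, `ci_low`,
#'   `n_reports`).
#' @param criteria A `signal_criteria`.
#' @return `TRUE` when `ror > min_ror`, `ci_low > min_ci_low` and
#'   `n_reports >= min_reports`.
#' @export
classify_signal <- function(result, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  isTRUE(result$ror > criteria$min_ror) &&
    isTRUE(result$ci_low > criteria$min_ci_low) &&
    isTRUE(result$n_reports >= criteria$min_reports)
}

#' Disproportionality analysis over a drug/event grid
#'
#' One result row per (drug, event set) pair, against the all-other-drugs
#' background of the same cleaned series. Statistical errors in one pair
#' (e.g. an all-zero table) are captured in the `error` column without
#' aborting the remaining pairs.
#'
#' @param series A cleaned (deduplicated) `case_series`.
#' @param drugs List of `drug_synonym_map`s (row order follows this
#'   list).
#' @param event_term_sets Named list of character vectors of preferred
#'   terms (column order follows this list).
#' @param criteria A `signal_criteria`.
#' @param require_primary_suspect Restrict drug matches to primary-suspect
#'   entries (default `TRUE`).
#' @return Tibble with columns `drug`, `event`, `a`, `b`, `c`, `d`,
#'   `ror`, `ci_low`, `ci_high`, `n_reports`, `corrected`, `is_signal`,
#'   `error`.
#' @export
run_analysis <- function(series, drugs = default_synonym_maps(),
                         event_term_sets = default_event_terms(),
                         criteria = signal_criteria(),
                         require_primary_suspect = TRUE) {
  stopifnot(inherits(series, "case_series"))
  if (length(drugs) == 0 || length(event_term_sets) == 0) {
    return(tibble::tibble(
      drug = character(), event = character(), a = integer(),
      b = integer(), c = integer(), d = integer(), ror = double(),
      ci_low = double(), ci_high = double(), n_reports = integer(),
      corrected = logical(), is_signal = logical(), error = character()))
  }
  if (is.null(names(event_term_sets))) {
    names(event_term_sets) <- vapply(event_term_sets, `[[`, "", 1)
  }
  rows <- list()
  for (map in drugs) {
    dm <- match_drug(series, map, require_primary_suspect)
    for (ev in names(event_term_sets)) {
      em <- match_event(series, event_term_sets[[ev]])
      tab <- contingency_table(sum(dm & em), sum(dm & !em),
                               sum(!dm & em), sum(!dm & !em))
      res <- tryCatch(compute_ror(tab, criteria), error = function(e) e)
      if (inherits(res, "error")) {
        row <- tibble::tibble(
          drug = map$canonical_name, event = ev,
          a = tab$a, b = tab$b, c = tab$c, d = tab$d,
          ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n_reports = tab$a, corrected = NA, is_signal = NA,
          error = conditionMessage(res))
      } else {
        row <- tibble::tibble(
          drug = map$canonical_name, event = ev,
          a = tab$a, b = tab$b, c = tab$c, d = tab$d,
          ror = res$ror, ci_low = res$ci_low, ci_high = res$ci_high,
          n_reports = res$n_reports, corrected = res$corrected,
          is_signal = res$is_signal, error = NA_character_)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Published ALK-inhibitor effusion disproportionality estimates
#'
#' Reporting odds ratios, 95% confidence bounds and report counts for
#' pleural and pericardial effusion under the five ALK inhibitors, as
#' published from an 11-year FAERS extract (2013-2023). Shipped as a
#' reference table for internal-consistency auditing: a Woolf interval is
#' log-symmetric, so [implied_ror_from_ci()] applied to each row's bounds
#' must reproduce its printed ROR up to rounding of the bounds.
#'
#' @return Tibble with columns `drug`, `event`, `ror`, `ci_low`,
#'   `ci_high`, `n_reports`.
#' @export
alk_effusion_reference <- function() {
  path <- system.file("extdata", "alk-effusion-reference.csv",
                      package = "faersignal", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
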