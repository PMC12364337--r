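#' Spontaneous-report case series
#'
#' A `case_series` is the relational container the whole pipeline operates
#' on: one row per safety report (a report version), plus child tables of
#' drug entries and reaction preferred terms keyed by `primary_id`, plus an
#' ordered provenance table recording how many reports entered and left
#' every processing stage.
#'
#' @param reports Tibble with columns `primary_id` (character, unique),
#'   `case_id` (character), `case_version` (integer), `receipt_date`
#'   (`Date`, `NA` when missing), `has_drug` and `has_reaction` (logical
#'   flags set at parse time).
#' @param drugs Tibble with columns `primary_id`, `seq` (integer, unique
#'   within a report), `role_code` (one of `"PS"`, `"SS"`, `"C"`, `"I"`),
#'   `verbatim_name`, `active_ingredient` (character, may be `NA`).
#' @param reactions Tibble with columns `primary_id`, `pt` (MedDRA
#'   preferred term as plain text; no duplicates within a report).
#' @param provenance Tibble with columns `stage`, `reports_in`,
#'   `reports_out`; consecutive stages must telescope
#'   (`reports_out` of stage k equals `reports_in` of stage k + 1).
#'
#' @return An object of class `case_series`.
#' @export
case_series <- function(reports, drugs = NULL, reactions = NULL,
                        provenance = NULL) {
  reports <- tibble::as_tibble(reports)
  need <- c("primary_id", "case_id", "case_version", "receipt_date")
  missing_cols <- setdiff(need, names(reports))
  if (length(missing_cols) > 0) {
    stop("reports table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reports$primary_id)) {
    stop("primary_id values must be unique within a case series", call. = FALSE)
  }
  if (any(is.na(reports$primary_id)) || any(!nzchar(reports$primary_id))) {
    stop("primary_id values must be non-empty", call. = FALSE)
  }
  if (is.null(drugs)) drugs <- empty_drug_table()
  if (is.null(reactions)) reactions <- empty_reaction_table()
  drugs <- tibble::as_tibble(drugs)
  reactions <- tibble::as_tibble(reactions)
  bad_role <- setdiff(unique(drugs$role_code), c(ROLE_CODES, NA_character_))
  if (length(bad_role) > 0) {
    stop("invalid role_code value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(provenance)) provenance <- empty_provenance()
  provenance <- tibble::as_tibble(provenance)
  validate_provenance(provenance, nrow(reports))
  if (!"has_drug" %in% names(reports)) {
    reports$has_drug <- reports$primary_id %in% drugs$primary_id
  }
  if (!"has_reaction" %in% names(reports)) {
    reports$has_reaction <- reports$primary_id %in% reactions$primary_id
  }
  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         provenance = provenance),
    class = "case_series"
  )
}

ROLE_CODES <- c("PS", "SS", "C", "I")

empty_drug_table <- function() {
  tibble::tibble(primary_id = character(), seq = integer(),
                 role_code = character(), verbatim_name = character(),
                 active_ingredient = character())
}

empty_reaction_table <- function() {
  tibble::tibble(primary_id = character(), pt = character())
}

empty_provenance <- function() {
  tibble::tibble(stage = character(), reports_in = integer(),
                 reports_out = integer())
}

validate_provenance <- function(prov, n_now) {
  if (nrow(prov) == 0) return(invisible(TRUE))
  if (any(prov$reports_out > prov$reports_in)) {
    stop("provenance stage gained reports (reports_out > reports_in)",
         call. = FALSE)
  }
  if (nrow(prov) > 1 &&
      any(prov$reports_out[-nrow(prov)] != prov$reports_in[-1])) {
    stop("provenance chain does not telescope", call. = FALSE)
  }
  if (prov$reports_out[nrow(prov)] != n_now) {
    stop("final provenance reports_out (", prov$reports_out[nrow(prov)],
         ") does not match series size (", n_now, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Number of reports in a case series
#' @param series A `case_series`.
#' @return Integer count of report rows.
#' @export
n_reports <- function(series) {
  stopifnot(inherits(series, "case_series"))
  nrow(series$reports)
}

#' Append a provenance stage
#'
#' Records a processing stage and returns the series with the updated
#' provenance chain. `reports_in` defaults to the previous stage's
#' `reports_out` (or the current size for the first stage).
#'
#' @param series A `case_series`.
#' @param stage Stage name.
#' @param reports_in,reports_out Report counts entering/leaving the stage.
#' @return The series with one more provenance row.
#' @export
add_stage <- function(series, stage, reports_in, reports_out) {
  stopifnot(inherits(series, "case_series"))
  series$provenance <- dplyr::bind_rows(
    series$provenance,
    tibble::tibble(stage = stage, reports_in = as.integer(reports_in),
                   reports_out = as.integer(reports_out))
  )
  validate_provenance(series$provenance, nrow(series$reports))
  series
}

#' Restrict a case series to a set of report ids
#'
#' Keeps the given `primary_id`s in the reports table and drops child
#' drug/reaction rows of removed reports. Does not touch provenance; callers
#' record their own stage.
#'
#' @param series A `case_series`.
#' @param keep_ids Character vector of `primary_id`s to retain.
#' @return The filtered series (no provenance row added).
#' @export
filter_reports <- function(series, keep_ids) {
  stopifnot(inherits(series, "case_series"))
  series$reports <- dplyr::filter(series$reports, .data$primary_id %in% keep_ids)
  series$drugs <- dplyr::filter(series$drugs, .data$primary_id %in% keep_ids)
  series$reactions <- dplyr::filter(series$reactions,
                                    .data$primary_id %in% keep_ids)
  series
}

#' @export
print.case_series <- function(x, ...) {
  cat("<case_series> ", nrow(x$reports), " reports, ",
      nrow(x$drugs), " drug entries, ", nrow(x$reactions),
      " reaction terms\n", sep = "")
  if (nrow(x$provenance) > 0) {
    cat("provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("  %-18s %8d -> %8d\n", x$provenance$stage[i],
                  x$provenance$reports_in[i], x$provenance$reports_out[i]))
    }
  }
  invisible(x)
}

#' Write a cleaned case series to plain CSV files
#'
#' Serializes the three relational tables and the provenance chain as CSVs
#' (`series_reports.csv`, `series_drugs.csv`, `series_reactions.csv`,
#' `provenance.csv`) with fixed column order, for interchange between
#' pipeline stages. Dates are written ISO-8601.
#'
#' @param series A `case_series`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_case_series <- function(series, dir) {
  stopifnot(inherits(series, "case_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep_out <- series$reports
  rep_out$receipt_date <- format(rep_out$receipt_date, "%Y-%m-%d")
  utils::write.csv(
    rep_out[, c("primary_id", "case_id", "case_version", "receipt_date",
                "has_drug", "has_reaction")],
    file.path(dir, "series_reports.csv"), row.names = FALSE, na = "")
  utils::write.csv(
    series$drugs[, c("primary_id", "seq", "role_code", "verbatim_name",
                     "active_ingredient")],
    file.path(dir, "series_drugs.csv"), row.names = FALSE, na = "")
  utils::write.csv(series$reactions[, c("primary_id", "pt")],
                   file.path(dir, "series_reactions.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(series$provenance, file.path(dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a case series written by [write_case_series()]
#'
#' @param dir Directory containing the series CSVs.
#' @return A `case_series`.
#' @export
read_case_series <- function(dir) {
  pth <- function(f) file.path(dir, f)
  if (!file.exists(pth("series_reports.csv"))) {
    stop("no series_reports.csv under ", dir, call. = FALSE)
  }
  rd <- function(f) tibble::as_tibble(
    utils::read.csv(pth(f), colClasses = "character"))
  reports <- rd("series_reports.csv")
  reports$case_version <- as.integer(reports$case_version)
  rdt <- reports$receipt_date
  rdt[!nzchar(rdt) | is.na(rdt)] <- NA_character_
  reports$receipt_date <- as.Date(rdt)
  reports$has_drug <- reports$has_drug == "TRUE"
  reports$has_reaction <- reports$has_reaction == "TRUE"
  drugs <- rd("series_drugs.csv")
  drugs$seq <- as.integer(drugs$seq)
  drugs$active_ingredient[!nzchar(drugs$active_ingredient)] <- NA_character_
  reactions <- rd("series_reactions.csv")
  prov <- empty_provenance()
  if (file.exists(pth("provenance.csv"))) {
    prov <- tibble::as_tibble(utils::read.csv(pth("provenance.csv")))
    prov$reports_in <- as.integer(prov$reports_in)
    prov$reports_out <- as.integer(prov$reports_out)
  }
  case_series(reports, drugs, reactions, prov)
}
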