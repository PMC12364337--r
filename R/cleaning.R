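#' Normalize a verbatim drug name
#'
#' Uppercases, trims, collapses internal whitespace, and removes
#' punctuation except hyphens. Deterministic, idempotent and
#' case-insensitive, so FAERS verbatim names that differ only in
#' formatting ("  Xalkori (crizotinib) 250mg", "XALKORI CRIZOTINIB 250MG")
#' map to the same string.
#'
#' @param verbatim Character vector of raw drug names.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_drug_name("  Xalkori (crizotinib) 250mg")
normalize_drug_name <- function(verbatim) {
  x <- toupper(as.character(verbatim))
  x <- gsub("[^A-Z0-9 -]", " ", x)
  x <- gsub("[ ]+", " ", x)
  trimws(x)
}

#' A drug synonym map
#'
#' Groups the name variants (generic, brand, salt, formatting variants)
#' under which one drug appears in FAERS verbatim fields. All entries are
#' stored normalized via [normalize_drug_name()].
#'
#' @param canonical_name Canonical drug name, e.g. `"CRIZOTINIB"`.
#' @param synonyms Character vector of additional name variants; the
#'   canonical name is always included.
#' @return An object of class `drug_synonym_map`.
#' @export
drug_synonym_map <- function(canonical_name, synonyms = character()) {
  canonical <- normalize_drug_name(canonical_name)
  if (!nzchar(canonical)) stop("canonical name is empty", call. = FALSE)
  syn <- unique(c(canonical, normalize_drug_name(synonyms)))
  syn <- syn[nzchar(syn)]
  structure(list(canonical_name = canonical, synonyms = syn),
            class = "drug_synonym_map")
}

#' @export
print.drug_synonym_map <- function(x, ...) {
  cat("<drug_synonym_map>", x$canonical_name, "=",
      paste(x$synonyms, collapse = " | "), "\n")
  invisible(x)
}

#' Default ALK-inhibitor synonym maps
#'
#' Seed maps for the five ALK inhibitors analyzed by the package's shipped
#' configuration: generic names plus US/EU brand names. User-extensible via
#' the run configuration.
#'
#' @return Named list of `drug_synonym_map`s.
#' @export
default_synonym_maps <- function() {
  maps <- list(
    drug_synonym_map("CRIZOTINIB", "XALKORI"),
    drug_synonym_map("CERITINIB", "ZYKADIA"),
    drug_synonym_map("ALECTINIB", "ALECENSA"),
    drug_synonym_map("BRIGATINIB", "ALUNBRIG"),
    drug_synonym_map("LORLATINIB", c("LORBRENA", "LORVIQUA"))
  )
  stats::setNames(maps, vapply(maps, `[[`, "", "canonical_name"))
}

#' Default target event preferred terms
#'
#' The two MedDRA preferred terms the shipped configuration analyzes.
#' Terms are compared case-insensitively as plain strings (no MedDRA
#' hierarchy traversal).
#'
#' @return Named list of character vectors (one event set per outcome).
#' @export
default_event_terms <- function() {
  list("Pleural effusion" = "Pleural effusion",
       "Pericardial effusion" = "Pericardial effusion")
}

# TRUE for each name that contains some synonym as a whole token run
# (so "XALKORI CRIZOTINIB 250MG" matches CRIZOTINIB, but "NIB" does not).
name_has_synonym <- function(norm_names, synonyms) {
  padded <- paste0(" ", norm_names, " ")
  hit <- rep(FALSE, length(norm_names))
  for (syn in synonyms) {
    hit <- hit | grepl(paste0(" ", syn, " "), padded, fixed = TRUE)
  }
  hit
}

#' Match reports against a drug synonym map
#'
#' A report matches when some drug entry's normalized verbatim name or
#' active ingredient contains a synonym of the map as a whole token; with
#' `require_primary_suspect` the matching entry must additionally carry
#' role code `"PS"`. A report counts once no matter how many of its drug
#' entries match.
#'
#' @param series A `case_series`.
#' @param map A `drug_synonym_map`.
#' @param require_primary_suspect Restrict to primary-suspect entries
#'   (default `TRUE`, the usual attribution-strengthening choice).
#' @return Logical vector aligned with `series$reports` rows.
#' @export
match_drug <- function(series, map, require_primary_suspect = TRUE) {
  stopifnot(inherits(series, "case_series"),
            inherits(map, "drug_synonym_map"))
  drugs <- series$drugs
  if (require_primary_suspect) {
    drugs <- drugs[drugs$role_code == "PS", , drop = FALSE]
  }
  if (nrow(drugs) == 0) {
    return(rep(FALSE, nrow(series$reports)))
  }
  # normalize each distinct raw name once; synthetic and real quarters
  # repeat the same verbatim strings many times
  raw <- c(drugs$verbatim_name, drugs$active_ingredient)
  raw[is.na(raw)] <- ""
  uraw <- unique(raw)
  uhit <- name_has_synonym(normalize_drug_name(uraw), map$synonyms)
  hit <- uhit[match(raw, uraw)]
  n <- nrow(drugs)
  entry_hit <- hit[seq_len(n)] | hit[n + seq_len(n)]
  hit_ids <- unique(drugs$primary_id[entry_hit])
  series$reports$primary_id %in% hit_ids
}

#' Match reports against a set of event preferred terms
#'
#' A report matches when any of its reaction terms, compared
#' case-insensitively after trimming, equals one of the target preferred
#' terms.
#'
#' @param series A `case_series`.
#' @param preferred_terms Character vector of target MedDRA preferred
#'   terms, e.g. `c("Pleural effusion")`.
#' @return Logical vector aligned with `series$reports` rows.
#' @export
match_event <- function(series, preferred_terms) {
  stopifnot(inherits(series, "case_series"))
  targets <- tolower(trimws(preferred_terms))
  hits <- series$reactions$primary_id[
    tolower(trimws(series$reactions$pt)) %in% targets]
  series$reports$primary_id %in% unique(hits)
}

#' Deduplicate report versions down to one report per case
#'
#' FAERS cases accumulate versions as follow-up reports arrive; counting a
#' case more than once inflates disproportionality. For every `case_id`
#' exactly one report survives: the one with the highest `case_version`,
#' ties broken by latest `receipt_date` (missing dates sort last), then by
#' lexicographically greatest `primary_id`. Idempotent.
#'
#' @param series A `case_series`.
#' @return The deduplicated series with a `deduplicate` provenance stage.
#' @export
deduplicate <- function(series) {
  stopifnot(inherits(series, "case_series"))
  n_in <- nrow(series$reports)
  ranked <- dplyr::arrange(series$reports,
                           .data$case_id,
                           dplyr::desc(.data$case_version),
                           dplyr::desc(.data$receipt_date),
                           dplyr::desc(.data$primary_id))
  keep <- ranked$primary_id[!duplicated(ranked$case_id)]
  out <- filter_reports(series, keep)
  add_stage(out, "deduplicate", n_in, nrow(out$reports))
}

#' An inclusive receipt-date analysis window
#'
#' @param start_date,end_date Dates (or strings coercible via
#'   [as.Date()]); both bounds inclusive.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) {
    stop("window bounds must be valid dates", call. = FALSE)
  }
  if (start_date > end_date) {
    stop("window start must not be after its end", call. = FALSE)
  }
  structure(list(start_date = start_date, end_date = end_date),
            class = "analysis_window")
}

#' Default analysis window
#'
#' January 1 2013 through December 31 2023, the eleven-year window the
#' shipped example configuration uses.
#'
#' @return An `analysis_window`.
#' @export
default_analysis_window <- function() {
  analysis_window("2013-01-01", "2023-12-31")
}

#' Restrict a case series to an analysis window
#'
#' Retains reports whose FDA receipt date lies in
#' `[start_date, end_date]`. Reports with missing receipt dates cannot be
#' windowed and are dropped; the drop is visible in the `window`
#' provenance stage (and the missing-date share of it in the
#' `missing_dates` attribute of the result).
#'
#' @param series A `case_series`.
#' @param window An `analysis_window`.
#' @return The windowed series with a `window` provenance stage.
#' @export
apply_window <- function(series, window = default_analysis_window()) {
  stopifnot(inherits(series, "case_series"),
            inherits(window, "analysis_window"))
  n_in <- nrow(series$reports)
  d <- series$reports$receipt_date
  keep_mask <- !is.na(d) & d >= window$start_date & d <= window$end_date
  out <- filter_reports(series, series$reports$primary_id[keep_mask])
  out <- add_stage(out, "window", n_in, nrow(out$reports))
  attr(out, "missing_dates") <- sum(is.na(d))
  out
}

#' Run the full cleaning chain
#'
#' Deduplication followed by date windowing, the cleaning order used by
#' the pipeline's ingest command.
#'
#' @param series A `case_series` (fresh from [read_quarters()]).
#' @param window An `analysis_window`.
#' @return The cleaned series with complete provenance.
#' @export
clean_series <- function(series, window = default_analysis_window()) {
  apply_window(deduplicate(series), window)
}
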