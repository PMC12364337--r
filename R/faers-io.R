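#' A FAERS quarter bundle
#'
#' Locates the three quarterly ASCII files (DEMO, DRUG, REAC) that together
#' describe one quarter of spontaneous reports. Files are "$"-delimited
#' text with a single header line; the primaryid-era schema (2012Q4
#' onward) is assumed.
#'
#' @param demo_path,drug_path,reac_path Paths to the three files.
#' @param quarter_label Label such as `"2015Q3"`.
#' @return An object of class `quarter_bundle`. `parse_stats` and
#'   `reject_log` are `NULL` until the bundle has been read.
#' @export
quarter_bundle <- function(demo_path, drug_path, reac_path, quarter_label) {
  for (p in c(demo_path, drug_path, reac_path)) {
    if (!file.exists(p)) stop("file does not exist: ", p, call. = FALSE)
  }
  structure(
    list(demo_path = demo_path, drug_path = drug_path, reac_path = reac_path,
         quarter_label = quarter_label, parse_stats = NULL, reject_log = NULL),
    class = "quarter_bundle"
  )
}

#' Discover quarter bundles in a directory
#'
#' Matches files named `DEMO<label>.txt` and pairs them with
#' `DRUG<label>.txt` / `REAC<label>.txt`.
#'
#' @param dir Directory to scan.
#' @return List of `quarter_bundle`s, ordered by label.
#' @export
find_quarters <- function(dir) {
  demos <- sort(list.files(dir, pattern = "^DEMO.*\\.txt$", full.names = TRUE))
  lapply(demos, function(d) {
    label <- sub("\\.txt$", "", sub("^DEMO", "", basename(d)))
    quarter_bundle(d,
                   file.path(dir, paste0("DRUG", label, ".txt")),
                   file.path(dir, paste0("REAC", label, ".txt")),
                   quarter_label = label)
  })
}

FAERS_DELIM <- "$"

# Required header columns per file kind (lowercased).
FAERS_COLUMNS <- list(
  DEMO = c("primaryid", "caseid", "caseversion", "fda_dt"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  REAC = c("primaryid", "pt")
)

# Split a "$"-delimited file into a character matrix, counting rejects.
# FAERS files carry Latin-1 bytes; lines are decoded to UTF-8 up front.
parse_dollar_file <- function(path, kind) {
  con <- file(path, open = "r", encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- enc2utf8(lines)
  if (length(lines) == 0) {
    stop("file is empty (no header line): ", path, call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[1], FAERS_DELIM, fixed = TRUE)[[1]]))
  required <- FAERS_COLUMNS[[kind]]
  miss <- setdiff(required, header)
  if (length(miss) > 0) {
    stop(kind, " file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, FAERS_DELIM, fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty field is dropped by strsplit; tolerate one short field
  ok <- nf == length(header) | nf == length(header) - 1L
  rejected <- tibble::tibble(reason = character(), n = integer())
  if (any(!ok)) {
    rejected <- tibble::tibble(reason = "field_count_mismatch",
                               n = sum(!ok))
  }
  fields <- fields[ok]
  dat <- if (length(fields) == 0) {
    stats::setNames(as.data.frame(matrix(character(), 0, length(header))),
                    header)
  } else {
    m <- t(vapply(fields, function(f) {
      length(f) <- length(header)
      f
    }, character(length(header))))
    stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), header)
  }
  dat[is.na(dat)] <- ""
  list(data = tibble::as_tibble(dat), rows_read = length(body),
       rejects = rejected)
}

count_reject <- function(rejects, reason, n) {
  if (n == 0) return(rejects)
  dplyr::bind_rows(rejects, tibble::tibble(reason = reason, n = as.integer(n)))
}

#' Parse FAERS receipt dates
#'
#' FAERS dates are `YYYYMMDD`; truncated forms resolve to the first day of
#' the period (`YYYYMM` to day 1, `YYYY` to January 1). Anything else is
#' `NA` (missing), which excludes the report from date-filtered stages.
#'
#' @param x Character vector of raw date fields.
#' @return A `Date` vector with `NA` for unparseable values.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(x)
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^[0-9]{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  ym <- grepl("^[0-9]{6}$", x)
  out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
  yr <- grepl("^[0-9]{4}$", x)
  out[yr] <- as.Date(paste0(x[yr], "0101"), format = "%Y%m%d")
  out
}

#' Read one FAERS quarter into a case series
#'
#' Joins DEMO, DRUG and REAC rows on `primaryid` into one safety report per
#' kept DEMO row. Reports lacking any drug or any reaction row are retained
#' but flagged (`has_drug` / `has_reaction`). Unparseable rows are
#' rejected, counted by reason, and reported in the returned bundle's
#' `parse_stats` / `reject_log` — never silently dropped.
#'
#' Row-level reject reasons: `field_count_mismatch` (wrong number of "$"
#' fields), `missing_primaryid`, `duplicate_primaryid` (later DEMO
#' duplicates), `missing_caseid`, `invalid_role_code`, `bad_drug_seq`,
#' `duplicate_drug_seq`, `missing_pt`, `duplicate_pt` (repeat of a
#' preferred term within one report).
#'
#' @param bundle A `quarter_bundle`.
#' @return A list with elements `series` (a `case_series` whose provenance
#'   opens with the read stage) and `bundle` (the input bundle with
#'   `parse_stats` and `reject_log` populated; `parse_stats` satisfies
#'   `rows_read == rows_kept + rows_rejected` for every file).
#' @export
read_quarter <- function(bundle) {
  stopifnot(inherits(bundle, "quarter_bundle"))

  demo_p <- parse_dollar_file(bundle$demo_path, "DEMO")
  drug_p <- parse_dollar_file(bundle$drug_path, "DRUG")
  reac_p <- parse_dollar_file(bundle$reac_path, "REAC")

  # --- DEMO ---
  demo <- demo_p$data
  demo_rej <- demo_p$rejects
  demo$primaryid <- trimws(demo$primaryid)
  bad <- !nzchar(demo$primaryid)
  demo_rej <- count_reject(demo_rej, "missing_primaryid", sum(bad))
  demo <- demo[!bad, , drop = FALSE]
  dup <- duplicated(demo$primaryid)
  demo_rej <- count_reject(demo_rej, "duplicate_primaryid", sum(dup))
  demo <- demo[!dup, , drop = FALSE]
  demo$caseid <- trimws(demo$caseid)
  bad <- !nzchar(demo$caseid)
  demo_rej <- count_reject(demo_rej, "missing_caseid", sum(bad))
  demo <- demo[!bad, , drop = FALSE]
  reports <- tibble::tibble(
    primary_id = demo$primaryid,
    case_id = demo$caseid,
    case_version = suppressWarnings(as.integer(trimws(demo$caseversion))),
    receipt_date = parse_faers_date(demo$fda_dt)
  )
  reports$case_version[is.na(reports$case_version)] <- 0L

  # --- DRUG ---
  drug <- drug_p$data
  drug_rej <- drug_p$rejects
  drug$primaryid <- trimws(drug$primaryid)
  bad <- !nzchar(drug$primaryid)
  drug_rej <- count_reject(drug_rej, "missing_primaryid", sum(bad))
  drug <- drug[!bad, , drop = FALSE]
  drug$role_cod <- toupper(trimws(drug$role_cod))
  bad <- !drug$role_cod %in% ROLE_CODES
  drug_rej <- count_reject(drug_rej, "invalid_role_code", sum(bad))
  drug <- drug[!bad, , drop = FALSE]
  seqs <- suppressWarnings(as.integer(trimws(drug$drug_seq)))
  bad <- is.na(seqs) | seqs < 1L
  drug_rej <- count_reject(drug_rej, "bad_drug_seq", sum(bad))
  drug <- drug[!bad, , drop = FALSE]
  seqs <- seqs[!bad]
  dup <- duplicated(paste(drug$primaryid, seqs, sep = "\r"))
  drug_rej <- count_reject(drug_rej, "duplicate_drug_seq", sum(dup))
  drug <- drug[!dup, , drop = FALSE]
  seqs <- seqs[!dup]
  drugs <- tibble::tibble(
    primary_id = drug$primaryid,
    seq = seqs,
    role_code = drug$role_cod,
    verbatim_name = trimws(drug$drugname),
    active_ingredient = {
      ai <- trimws(drug$prod_ai)
      ai[!nzchar(ai)] <- NA_character_
      ai
    }
  )

  # --- REAC ---
  reac <- reac_p$data
  reac_rej <- reac_p$rejects
  reac$primaryid <- trimws(reac$primaryid)
  bad <- !nzchar(reac$primaryid)
  reac_rej <- count_reject(reac_rej, "missing_primaryid", sum(bad))
  reac <- reac[!bad, , drop = FALSE]
  reac$pt <- trimws(reac$pt)
  bad <- !nzchar(reac$pt)
  reac_rej <- count_reject(reac_rej, "missing_pt", sum(bad))
  reac <- reac[!bad, , drop = FALSE]
  dup <- duplicated(paste(reac$primaryid, tolower(reac$pt), sep = "\r"))
  reac_rej <- count_reject(reac_rej, "duplicate_pt", sum(dup))
  reac <- reac[!dup, , drop = FALSE]
  reactions <- tibble::tibble(primary_id = reac$primaryid, pt = reac$pt)

  stats <- tibble::tibble(
    file = c("DEMO", "DRUG", "REAC"),
    rows_read = c(demo_p$rows_read, drug_p$rows_read, reac_p$rows_read),
    rows_kept = c(nrow(reports), nrow(drugs), nrow(reactions)),
    rows_rejected = c(sum(demo_rej$n), sum(drug_rej$n), sum(reac_rej$n))
  )
  stopifnot(all(stats$rows_read == stats$rows_kept + stats$rows_rejected))
  reject_log <- dplyr::bind_rows(
    dplyr::mutate(demo_rej, file = "DEMO", .before = 1),
    dplyr::mutate(drug_rej, file = "DRUG", .before = 1),
    dplyr::mutate(reac_rej, file = "REAC", .before = 1)
  )
  bundle$parse_stats <- stats
  bundle$reject_log <- reject_log

  series <- case_series(reports, drugs, reactions)
  series <- add_stage(series, paste0("read:", bundle$quarter_label),
                      demo_p$rows_read, nrow(reports))
  list(series = series, bundle = bundle)
}

#' Read and merge several quarters
#'
#' Concatenates the quarters' reports. A `primary_id` resubmitted in a
#' later quarter supersedes the earlier occurrence (the later quarter's
#' row is kept); the drop is recorded in the `merge` provenance stage.
#'
#' @param bundles List of `quarter_bundle`s (chronological order).
#' @return A list with `series` (merged `case_series`) and `bundles` (the
#'   input bundles with parse statistics filled in).
#' @export
read_quarters <- function(bundles) {
  if (length(bundles) == 0) {
    return(list(series = add_stage(case_series(tibble::tibble(
      primary_id = character(), case_id = character(),
      case_version = integer(), receipt_date = as.Date(character()))),
      "read", 0L, 0L), bundles = list()))
  }
  parsed <- lapply(bundles, read_quarter)
  all_series <- lapply(parsed, `[[`, "series")
  reports <- dplyr::bind_rows(lapply(all_series, `[[`, "reports"))
  drugs <- dplyr::bind_rows(lapply(all_series, `[[`, "drugs"))
  reactions <- dplyr::bind_rows(lapply(all_series, `[[`, "reactions"))
  n_in <- nrow(reports)
  # keep the LAST occurrence of a primary_id (later quarter supersedes)
  keep <- !duplicated(reports$primary_id, fromLast = TRUE)
  dropped_ids <- reports$primary_id[!keep]
  reports <- reports[keep, , drop = FALSE]
  if (length(dropped_ids) > 0) {
    drugs <- drugs[!duplicated(paste(drugs$primary_id, drugs$seq)), ,
                   drop = FALSE]
    reactions <- reactions[!duplicated(paste(reactions$primary_id,
                                             tolower(reactions$pt))), ,
                           drop = FALSE]
  }
  prov <- dplyr::bind_rows(lapply(all_series, `[[`, "provenance"))
  total_read <- sum(prov$reports_in)
  series <- case_series(
    reports, drugs, reactions,
    provenance = tibble::tibble(
      stage = c("read", "merge"),
      reports_in = as.integer(c(total_read, n_in)),
      reports_out = as.integer(c(n_in, nrow(reports)))))
  list(series = series, bundles = lapply(parsed, `[[`, "bundle"))
}

# "$" is the field delimiter and the dialect has no quoting convention:
# strip it from every value on write.
sanitize_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  gsub("$", "", x, fixed = TRUE)
}

write_dollar_file <- function(df, path) {
  header <- paste(names(df), collapse = FAERS_DELIM)
  if (nrow(df) == 0) {
    body <- character()
  } else {
    cols <- lapply(df, sanitize_field)
    body <- do.call(paste, c(cols, sep = FAERS_DELIM))
  }
  con <- file(path, open = "w", encoding = "latin1")
  on.exit(close(con))
  writeLines(c(header, body), con)
}

#' Write a case series as one FAERS quarter
#'
#' Emits `DEMO<label>.txt`, `DRUG<label>.txt` and `REAC<label>.txt` in the
#' "$"-delimited dialect so that [read_quarter()] reproduces the series
#' (same ids, same drug and reaction multisets). "$" characters inside
#' values are stripped, since the dialect cannot escape its delimiter.
#'
#' @param series A `case_series`.
#' @param out_dir Output directory (created if absent).
#' @param quarter_label Label embedded in the file names.
#' @return The `quarter_bundle` pointing at the written files.
#' @export
write_quarter <- function(series, out_dir, quarter_label) {
  stopifnot(inherits(series, "case_series"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  demo <- data.frame(
    primaryid = series$reports$primary_id,
    caseid = series$reports$case_id,
    caseversion = series$reports$case_version,
    fda_dt = ifelse(is.na(series$reports$receipt_date), "",
                    format(series$reports$receipt_date, "%Y%m%d")),
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    primaryid = series$drugs$primary_id,
    drug_seq = series$drugs$seq,
    role_cod = series$drugs$role_code,
    drugname = series$drugs$verbatim_name,
    prod_ai = series$drugs$active_ingredient,
    stringsAsFactors = FALSE
  )
  reac <- data.frame(primaryid = series$reactions$primary_id,
                     pt = series$reactions$pt, stringsAsFactors = FALSE)
  paths <- file.path(out_dir, paste0(c("DEMO", "DRUG", "REAC"),
                                     quarter_label, ".txt"))
  write_dollar_file(demo, paths[1])
  write_dollar_file(drug, paths[2])
  write_dollar_file(reac, paths[3])
  quarter_bundle(paths[1], paths[2], paths[3], quarter_label)
}
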