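# Fixture builders and independent oracle predicates shared by the suite.

# Build a case_series from compact per-report specs:
#   report("1001", "C1", 1, "2015-03-02",
#          drugs = list(c("CRIZOTINIB", "PS")), reactions = "Pleural effusion")
report_spec <- function(pid, case, version, date, drugs = list(),
                        reactions = character()) {
  list(pid = pid, case = case, version = version, date = date,
       drugs = drugs, reactions = reactions)
}

series_from_specs <- function(specs) {
  demo <- tibble::tibble(
    primary_id = vapply(specs, `[[`, "", "pid"),
    case_id = vapply(specs, `[[`, "", "case"),
    case_version = vapply(specs, function(s) as.integer(s$version), 1L),
    receipt_date = as.Date(vapply(specs, function(s) {
      if (is.na(s$date)) NA_character_ else as.character(s$date)
    }, ""))
  )
  drugs <- dplyr::bind_rows(lapply(specs, function(s) {
    if (length(s$drugs) == 0) return(NULL)
    tibble::tibble(
      primary_id = s$pid,
      seq = seq_along(s$drugs),
      role_code = vapply(s$drugs, `[`, "", 2),
      verbatim_name = vapply(s$drugs, `[`, "", 1),
      active_ingredient = NA_character_
    )
  }))
  reactions <- dplyr::bind_rows(lapply(specs, function(s) {
    if (length(s$reactions) == 0) return(NULL)
    tibble::tibble(primary_id = s$pid, pt = s$reactions)
  }))
  if (is.null(drugs) || ncol(drugs) == 0) drugs <- NULL
  if (is.null(reactions) || ncol(reactions) == 0) reactions <- NULL
  case_series(demo, drugs, reactions)
}

# Write raw "$"-delimited quarter files from character line vectors.
write_raw_quarter <- function(dir, label, demo_lines, drug_lines, reac_lines) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(c("DEMO", "DRUG", "REAC"), label, ".txt"))
  writeLines(demo_lines, paths[1])
  writeLines(drug_lines, paths[2])
  writeLines(reac_lines, paths[3])
  quarter_bundle(paths[1], paths[2], paths[3], label)
}

# ---- Independent oracle predicates (deliberately naive, loop-based) ----

oracle_normalize <- function(x) {
  x <- toupper(x)
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "")[[1]]
    keep <- vapply(chars, function(ch) {
      grepl("[A-Z0-9-]", ch) || ch == " "
    }, TRUE)
    chars[!keep] <- " "
    s <- paste(chars, collapse = "")
    s <- gsub(" +", " ", s)
    out[i] <- trimws(s)
  }
  out
}

# Per-report drug match by explicit loops over entries and synonyms.
oracle_match_drug <- function(series, pid, synonyms, require_ps) {
  rows <- series$drugs[series$drugs$primary_id == pid, , drop = FALSE]
  syn <- oracle_normalize(synonyms)
  for (i in seq_len(nrow(rows))) {
    if (require_ps && rows$role_code[i] != "PS") next
    for (fld in c(rows$verbatim_name[i], rows$active_ingredient[i])) {
      if (is.na(fld)) next
      tokens <- strsplit(oracle_normalize(fld), " ")[[1]]
      for (s in syn) {
        stoks <- strsplit(s, " ")[[1]]
        k <- length(stoks)
        if (k == 0 || k > length(tokens)) next
        for (start in seq_len(length(tokens) - k + 1)) {
          if (all(tokens[start:(start + k - 1)] == stoks)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

oracle_match_event <- function(series, pid, terms) {
  pts <- series$reactions$pt[series$reactions$primary_id == pid]
  any(tolower(trimws(pts)) %in% tolower(trimws(terms)))
}

# Brute-force 2x2 cell counts by a double loop over reports.
oracle_contingency <- function(series, synonyms, terms, require_ps) {
  a <- b <- c_ <- d <- 0L
  for (pid in series$reports$primary_id) {
    dm <- oracle_match_drug(series, pid, synonyms, require_ps)
    em <- oracle_match_event(series, pid, terms)
    if (dm && em) a <- a + 1L
    else if (dm) b <- b + 1L
    else if (em) c_ <- c_ + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c_, d = d)
}

# Random small series over a mixed vocabulary, for randomized fixtures.
random_series <- function(n, seed) {
  set.seed(seed)
  drugs_pool <- c("CRIZOTINIB", "Xalkori (crizotinib) 250mg", "ALECTINIB",
                  "alectinib.", "IMATINIB", "ASPIRIN", "LORBRENA")
  events_pool <- c("Pleural effusion", "PLEURAL EFFUSION",
                   "Pericardial effusion", "Nausea", "Rash")
  roles <- c("PS", "SS", "C", "I")
  specs <- lapply(seq_len(n), function(i) {
    nd <- sample(0:3, 1)
    report_spec(
      pid = sprintf("R%05d", i), case = sprintf("K%05d", i), version = 1,
      date = as.Date("2015-01-01") + sample(0:3000, 1),
      drugs = if (nd == 0) list() else lapply(seq_len(nd), function(j) {
        c(sample(drugs_pool, 1), sample(roles, 1))
      }),
      reactions = sample(events_pool, sample(0:2, 1))
    )
  })
  series_from_specs(specs)
}

# Direct Woolf interval from cell counts (shared by calibration checks).
woolf_ci <- function(a, b, c, d, z = 1.959964) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(ror = ror, lo = exp(log(ror) - z * se), hi = exp(log(ror) + z * se))
}
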