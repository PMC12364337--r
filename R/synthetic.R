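#' Event probability among exposed reports implied by a target odds ratio
#'
#' Inverse-odds construction: given a background event probability `p0`
#' and a target odds ratio, returns the exposed-arm probability
#' `p1 = (or * p0) / (1 - p0 + or * p0)`, so that
#' `odds(p1) / odds(p0)` equals the target exactly. This is how the
#' generator injects drug-event associations with known ground truth.
#'
#' @param target_or Target odds ratio (> 0).
#' @param p0 Background event probability, strictly inside (0, 1).
#' @return The exposed-arm event probability.
#' @export
#' @examples
#' event_prob_given_exposure(9, 0.1) # odds 1/9 -> odds 1, i.e. 0.5
event_prob_given_exposure <- function(target_or, p0) {
  if (any(p0 <= 0 | p0 >= 1)) {
    stop("background probability must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (any(target_or <= 0)) {
    stop("target odds ratio must be positive", call. = FALSE)
  }
  (target_or * p0) / (1 - p0 + target_or * p0)
}

# Non-target vocabulary: filler concomitant drugs and background reaction
# preferred terms, so every generated report has at least one drug entry
# and one reaction (as real FAERS reports do).
background_drug_names <- function(n = 25) sprintf("BACKGROUND DRUG %02d", seq_len(n))

background_reaction_terms <- function() {
  c("Nausea", "Headache", "Fatigue", "Dizziness", "Vomiting", "Rash",
    "Diarrhoea", "Pyrexia", "Anaemia", "Insomnia")
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defaults emulate the regime of an ALK-inhibitor effusion analysis over
#' an 11-year FAERS window: five target drugs at ~1% marginal exposure
#' each, pleural effusion at 1% and pericardial effusion at 0.5%
#' background reporting probability, and one injected association
#' (crizotinib - pleural effusion at odds ratio 8). At the default
#' population size this yields drug-and-event cell counts of the same
#' order as published effusion signal tables (tens to ~150 reports).
#'
#' @param n_reports Number of distinct cases to generate.
#' @param drug_vocab Named numeric vector: canonical target drug name ->
#'   marginal exposure probability.
#' @param event_vocab Named numeric vector: target preferred term ->
#'   background reporting probability.
#' @param injected_signals Data frame with columns `drug`, `event`, `or`:
#'   drug-event pairs whose population odds ratio is forced to `or` via
#'   [event_prob_given_exposure()]. `NULL` for a fully null population.
#' @param duplicate_rate Fraction of cases emitted with a second, earlier
#'   report version (exercises deduplication).
#' @param secondary_role_rate Fraction of target-drug mentions demoted
#'   from primary suspect to a secondary-suspect/concomitant role.
#' @param date_range An [analysis_window()]; receipt dates are uniform
#'   over it.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 100000L,
                             drug_vocab = c(CRIZOTINIB = 0.01,
                                            CERITINIB = 0.01,
                                            ALECTINIB = 0.01,
                                            BRIGATINIB = 0.01,
                                            LORLATINIB = 0.01),
                             event_vocab = c("Pleural effusion" = 0.010,
                                             "Pericardial effusion" = 0.005),
                             injected_signals = data.frame(
                               drug = "CRIZOTINIB",
                               event = "Pleural effusion",
                               or = 8),
                             duplicate_rate = 0.10,
                             secondary_role_rate = 0.10,
                             date_range = default_analysis_window(),
                             seed = 1L) {
  if (n_reports < 1) stop("n_reports must be positive", call. = FALSE)
  if (any(drug_vocab <= 0 | drug_vocab >= 1) ||
      any(event_vocab <= 0 | event_vocab >= 1)) {
    stop("vocabulary probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1 ||
      secondary_role_rate < 0 || secondary_role_rate >= 1) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(date_range, "analysis_window"))
  if (!is.null(injected_signals)) {
    injected_signals <- as.data.frame(injected_signals)
    stopifnot(all(c("drug", "event", "or") %in% names(injected_signals)))
    if (any(injected_signals$or <= 0)) {
      stop("injected odds ratios must be positive", call. = FALSE)
    }
    bad <- !injected_signals$drug %in% names(drug_vocab) |
      !injected_signals$event %in% names(event_vocab)
    if (any(bad)) {
      stop("injected signals must reference drugs/events in the vocabularies",
           call. = FALSE)
    }
  }
  structure(
    list(n_reports = as.integer(n_reports), drug_vocab = drug_vocab,
         event_vocab = event_vocab, injected_signals = injected_signals,
         duplicate_rate = duplicate_rate,
         secondary_role_rate = secondary_role_rate,
         date_range = date_range, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Verbatim-name styles exercising the cleaning module's normalization:
# canonical, lower case with trailing dot, and brand-style decoration.
decorate_drug_name <- function(canonical, style) {
  ifelse(style == 1L, canonical,
         ifelse(style == 2L, paste0(tolower(canonical), "."),
                paste0(canonical, " (", tolower(canonical), ") 250MG")))
}

#' Generate a synthetic spontaneous-report population
#'
#' Each case draws target-drug exposures independently from the marginal
#' probabilities, then event occurrences from the background
#' probabilities, overridden by [event_prob_given_exposure()] for
#' injected (drug, event) pairs (a case exposed to several injected drugs
#' for the same event takes the largest implied probability). Target-drug
#' mentions carry role `PS`, demoted to `SS`/`C` at
#' `secondary_role_rate`; every case additionally carries one background
#' concomitant drug and one background reaction term. Receipt dates are
#' uniform over `date_range`. A `duplicate_rate` fraction of cases is
#' emitted twice: an earlier version 1 and a later version 2 that differ
#' only in `case_version`, `primary_id` and `receipt_date`, so
#' deduplication must recover exactly one report per case.
#'
#' @param config A `synthetic_config`.
#' @return A `case_series` (provenance opens with a `generate` stage).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drug_names <- names(config$drug_vocab)
  event_names <- names(config$event_vocab)

  case_id <- sprintf("C%08d", seq_len(n))

  exposure <- matrix(FALSE, n, length(drug_names),
                     dimnames = list(NULL, drug_names))
  for (j in seq_along(drug_names)) {
    exposure[, j] <- stats::runif(n) < config$drug_vocab[j]
  }

  event_prob <- matrix(rep(config$event_vocab, each = n), n,
                       length(event_names),
                       dimnames = list(NULL, event_names))
  if (!is.null(config$injected_signals)) {
    for (k in seq_len(nrow(config$injected_signals))) {
      dg <- config$injected_signals$drug[k]
      ev <- config$injected_signals$event[k]
      p1 <- event_prob_given_exposure(config$injected_signals$or[k],
                                      config$event_vocab[[ev]])
      rows <- exposure[, dg]
      event_prob[rows, ev] <- pmax(event_prob[rows, ev], p1)
    }
  }
  occurred <- matrix(stats::runif(n * length(event_names)), n,
                     length(event_names)) < event_prob

  span <- as.integer(config$date_range$end_date -
                       config$date_range$start_date)
  dates <- config$date_range$start_date +
    sample.int(span + 1L, n, replace = TRUE) - 1L

  # duplicate versions: chosen cases get version 1 (earlier) + version 2
  is_dup <- stats::runif(n) < config$duplicate_rate
  version <- ifelse(is_dup, 2L, 1L)
  final_pid <- paste0(case_id, sprintf("%02d", version))
  demo <- tibble::tibble(primary_id = final_pid, case_id = case_id,
                         case_version = version, receipt_date = dates)
  if (any(is_dup)) {
    early_dates <- pmax(dates[is_dup] - (sample.int(180L, sum(is_dup),
                                                    replace = TRUE)),
                        config$date_range$start_date)
    demo <- dplyr::bind_rows(demo, tibble::tibble(
      primary_id = paste0(case_id[is_dup], "01"),
      case_id = case_id[is_dup], case_version = 1L,
      receipt_date = early_dates))
  }

  # drug entries per case: exposed target drugs, then one background drug
  case_idx <- which(exposure, arr.ind = TRUE)
  tgt_case <- case_idx[, 1]
  tgt_drug <- drug_names[case_idx[, 2]]
  n_tgt <- length(tgt_case)
  if (n_tgt > 0) {
    demoted <- stats::runif(n_tgt) < config$secondary_role_rate
    alt_role <- c("SS", "C")[1L + (stats::runif(n_tgt) < 0.5)]
    role <- ifelse(demoted, alt_role, rep("PS", n_tgt))
    style <- sample.int(3L, n_tgt, replace = TRUE)
    ord <- order(tgt_case)
    tgt_case <- tgt_case[ord]; tgt_drug <- tgt_drug[ord]
    role <- role[ord]; style <- style[ord]
    seq_within <- stats::ave(seq_along(tgt_case), tgt_case,
                             FUN = seq_along)
    case_drugs <- tibble::tibble(
      case_id = case_id[tgt_case],
      seq = as.integer(seq_within),
      role_code = role,
      verbatim_name = decorate_drug_name(tgt_drug, style),
      active_ingredient = tgt_drug
    )
  } else {
    case_drugs <- tibble::tibble(
      case_id = character(), seq = integer(), role_code = character(),
      verbatim_name = character(), active_ingredient = character())
  }
  n_target_per_case <- tabulate(tgt_case, nbins = n)
  bg <- tibble::tibble(
    case_id = case_id,
    seq = n_target_per_case + 1L,
    role_code = "C",
    verbatim_name = sample(background_drug_names(), n, replace = TRUE),
    active_ingredient = NA_character_
  )
  case_drugs <- dplyr::arrange(dplyr::bind_rows(case_drugs, bg),
                               .data$case_id, .data$seq)

  # reactions per case: occurred target events plus one background term
  ev_idx <- which(occurred, arr.ind = TRUE)
  case_reactions <- dplyr::bind_rows(
    tibble::tibble(case_id = case_id[ev_idx[, 1]],
                   pt = event_names[ev_idx[, 2]]),
    tibble::tibble(case_id = case_id,
                   pt = sample(background_reaction_terms(), n,
                               replace = TRUE))
  )
  case_reactions <- dplyr::arrange(case_reactions, .data$case_id, .data$pt)

  # attach children to every emitted version of each case
  version_map <- demo[, c("primary_id", "case_id")]
  drugs <- dplyr::inner_join(version_map, case_drugs, by = "case_id",
                             relationship = "many-to-many")
  drugs <- drugs[, c("primary_id", "seq", "role_code", "verbatim_name",
                     "active_ingredient")]
  reactions <- dplyr::inner_join(version_map, case_reactions,
                                 by = "case_id",
                                 relationship = "many-to-many")
  reactions <- reactions[, c("primary_id", "pt")]

  series <- case_series(demo, drugs, reactions)
  add_stage(series, "generate", nrow(demo), nrow(demo))
}

#' Write a generated series as FAERS quarter bundles
#'
#' Partitions the reports by receipt date into `n_quarters` contiguous,
#' equal-width date intervals and writes each as one FAERS-dialect bundle
#' via [write_quarter()]. The union of the bundles re-read with
#' [read_quarters()] equals the input series.
#'
#' @param series A `case_series`.
#' @param out_dir Output directory.
#' @param n_quarters Number of bundles (>= 1).
#' @return List of `quarter_bundle`s.
#' @export
emit_quarters <- function(series, out_dir, n_quarters = 1L) {
  stopifnot(inherits(series, "case_series"), n_quarters >= 1)
  d <- series$reports$receipt_date
  if (all(is.na(d))) stop("series has no receipt dates to partition on",
                          call. = FALSE)
  lo <- min(d, na.rm = TRUE)
  hi <- max(d, na.rm = TRUE)
  breaks <- lo + as.numeric(hi - lo + 1) * (seq_len(n_quarters - 1L) /
                                              n_quarters)
  part <- findInterval(as.numeric(d), as.numeric(breaks)) + 1L
  part[is.na(part)] <- 1L  # undated reports land in the first bundle
  lapply(seq_len(n_quarters), function(i) {
    sub <- filter_reports(series, series$reports$primary_id[part == i])
    sub$provenance <- empty_provenance()
    write_quarter(sub, out_dir, sprintf("SIM%02d", i))
  })
}
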