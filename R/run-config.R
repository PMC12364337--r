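#' Read a pipeline run configuration
#'
#' The run configuration is a YAML file naming the inputs, the target
#' drugs (with synonym lists), the target event preferred terms, the
#' analysis window, the signal thresholds, and — when simulation is
#' requested — the generator parameters. A complete example reproducing a
#' five-drug, two-event effusion design ships at
#' `system.file("extdata", "example-config.yaml", package = "faersignal")`.
#'
#' Recognized keys (all optional unless noted):
#' \describe{
#'   \item{input_dir}{Directory holding `DEMO*/DRUG*/REAC*.txt` quarter
#'     files (required by ingest; simulate writes into it).}
#'   \item{output_dir}{Directory for cleaned series, provenance and
#'     results (required).}
#'   \item{drugs}{Mapping canonical name -> list of synonyms.}
#'   \item{events}{Mapping event label -> list of preferred terms.}
#'   \item{window}{`start` / `end` dates (ISO), default 2013-01-01 /
#'     2023-12-31.}
#'   \item{criteria}{`min_ror`, `min_ci_low`, `min_reports`,
#'     `z_quantile`.}
#'   \item{require_primary_suspect}{Logical, default `TRUE`.}
#'   \item{simulate}{Generator block: `n_reports`, `drug_probs`,
#'     `event_probs`, `injected` (list of `drug`/`event`/`or`),
#'     `duplicate_rate`, `secondary_role_rate`, `n_quarters`, `seed`.}
#' }
#'
#' @param path Path to the YAML file.
#' @param seed Optional integer overriding the configured seed.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  build_run_config(raw, seed = seed, base_dir = dirname(path))
}

build_run_config <- function(raw, seed = NULL, base_dir = ".") {
  if (is.null(raw$output_dir)) {
    stop("config must name an output_dir", call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  drugs <- if (is.null(raw$drugs)) {
    default_synonym_maps()
  } else {
    maps <- lapply(names(raw$drugs), function(nm) {
      drug_synonym_map(nm, unlist(raw$drugs[[nm]]))
    })
    stats::setNames(maps, vapply(maps, `[[`, "", "canonical_name"))
  }
  events <- if (is.null(raw$events)) {
    default_event_terms()
  } else {
    lapply(raw$events, function(x) as.character(unlist(x)))
  }
  if (length(drugs) == 0 || length(events) == 0) {
    stop("config must name at least one drug and one event set",
         call. = FALSE)
  }
  window <- if (is.null(raw$window)) {
    default_analysis_window()
  } else {
    analysis_window(raw$window$start, raw$window$end)
  }
  crit_args <- raw$criteria[names(raw$criteria) %in%
                              c("min_ror", "min_ci_low", "min_reports",
                                "z_quantile")]
  criteria <- do.call(signal_criteria, as.list(crit_args))
  sim <- NULL
  if (!is.null(raw$simulate)) {
    s <- raw$simulate
    inj <- NULL
    if (!is.null(s$injected) && length(s$injected) > 0) {
      inj <- do.call(rbind, lapply(s$injected, function(x) {
        data.frame(drug = x$drug, event = x$event, or = as.numeric(x$or))
      }))
    }
    sim_seed <- if (!is.null(seed)) seed else
      if (!is.null(s$seed)) s$seed else 1L
    args <- list(date_range = window, seed = sim_seed,
                 injected_signals = inj)
    if (!is.null(s$n_reports)) args$n_reports <- s$n_reports
    if (!is.null(s$drug_probs)) args$drug_vocab <- unlist(s$drug_probs)
    if (!is.null(s$event_probs)) args$event_vocab <- unlist(s$event_probs)
    if (!is.null(s$duplicate_rate)) args$duplicate_rate <- s$duplicate_rate
    if (!is.null(s$secondary_role_rate)) {
      args$secondary_role_rate <- s$secondary_role_rate
    }
    if (is.null(s$injected)) args$injected_signals <- NULL
    sim <- list(config = do.call(synthetic_config, args),
                n_quarters = if (is.null(s$n_quarters)) 1L else
                  as.integer(s$n_quarters))
  }
  structure(
    list(input_dir = resolve(raw$input_dir),
         output_dir = resolve(raw$output_dir),
         drugs = drugs, events = events, window = window,
         criteria = criteria,
         require_primary_suspect =
           if (is.null(raw$require_primary_suspect)) TRUE else
             isTRUE(raw$require_primary_suspect),
         simulate = sim),
    class = "run_config"
  )
}
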