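# End-to-end orchestration: ingest -> dedup -> cohort -> 2x2 tables ->
# four statistics -> classification -> report bundle, from one YAML config.

#' Build a pipeline configuration
#'
#' All analysis choices that are conventions rather than data (counting
#' unit, chi-square variant, zero-cell policy, the positivity thresholds,
#' the time-to-onset bin edges) surface here with their defaults.
#'
#' @param input_dir directory with the quarterly ASCII tables.
#' @param output_dir directory for the report bundle.
#' @param target canonical target drug label.
#' @param synonym_file two-column synonym list (`NULL`: bundled
#'   temozolomide list).
#' @param pt_soc_map_file two-column PT-to-SOC map (`NULL`: bundled
#'   synthetic map).
#' @param counting_unit `"event"` or `"case"` (see
#'   [build_contingency_tables()]).
#' @param criteria a [signal_criteria()].
#' @param yates logical, Yates-corrected chi-square.
#' @param zero_cell `"undefined"` or `"haldane"`.
#' @param tto_breaks time-to-onset bin edges in days.
#' @param indication_merge_file optional two-column indication merge map.
#' @param seed integer seed recorded with the run.
#' @return object of class `dpa_config`.
#' @export
dpa_config <- function(input_dir, output_dir, target = "TEMOZOLOMIDE",
                       synonym_file = NULL, pt_soc_map_file = NULL,
                       counting_unit = "event",
                       criteria = signal_criteria(), yates = TRUE,
                       zero_cell = "undefined",
                       tto_breaks = c(0, 30, 60, 90, 180, 365, 730, Inf),
                       indication_merge_file = NULL, seed = 1L) {
  structure(list(
    input_dir = input_dir, output_dir = output_dir, target = target,
    synonym_file = synonym_file %||%
      system.file("extdata", "temozolomide_synonyms.tsv",
                  package = "faersdpa"),
    pt_soc_map_file = pt_soc_map_file %||%
      system.file("extdata", "synthetic_pt_soc_map.tsv",
                  package = "faersdpa"),
    counting_unit = counting_unit, criteria = criteria, yates = yates,
    zero_cell = zero_cell, tto_breaks = tto_breaks,
    indication_merge_file = indication_merge_file,
    seed = as.integer(seed)), class = "dpa_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [dpa_config()]; criteria thresholds live
#' under a `criteria:` block (`ror_min`, `prr_min`, `ebgm05_min`,
#' `ic025_min`, `a_min`, `require_all`).
#'
#' @param path YAML file path.
#' @return a `dpa_config`.
#' @export
read_dpa_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(signal_criteria, y$criteria %||% list())
  dpa_config(
    input_dir = y$input_dir, output_dir = y$output_dir,
    target = y$target %||% "TEMOZOLOMIDE",
    synonym_file = y$synonym_file, pt_soc_map_file = y$pt_soc_map_file,
    counting_unit = y$counting_unit %||% "event", criteria = crit,
    yates = y$yates %||% TRUE, zero_cell = y$zero_cell %||% "undefined",
    tto_breaks = if (!is.null(y$tto_breaks))
      c(as.numeric(y$tto_breaks), Inf) else c(0, 30, 60, 90, 180, 365, 730,
                                              Inf),
    indication_merge_file = y$indication_merge_file,
    seed = y$seed %||% 1L)
}

#' Validate a pipeline configuration without running it
#'
#' @param config a `dpa_config`.
#' @return character vector of problems; empty when [run_dpa_pipeline()]
#'   would pass its preconditions. Never mutates state.
#' @export
validate_dpa_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$input_dir) || !dir.exists(config$input_dir))
    add(paste0("input_dir does not exist: ",
               config$input_dir %||% "<missing>"))
  for (f in c("synonym_file", "pt_soc_map_file", "indication_merge_file")) {
    p <- config[[f]]
    if (!is.null(p) && nzchar(p) && !file.exists(p))
      add(paste0(f, " not found: ", p))
  }
  if (!config$counting_unit %in% c("event", "case"))
    add("counting_unit must be 'event' or 'case'")
  if (!config$zero_cell %in% c("undefined", "haldane"))
    add("zero_cell must be 'undefined' or 'haldane'")
  crit <- config$criteria
  for (f in c("ror_min", "prr_min", "ebgm05_min", "ic025_min", "a_min"))
    if (!is.na(crit[[f]]) && crit[[f]] < 0)
      add(paste0("criteria threshold ", f, " must be non-negative"))
  if (!is.null(config$tto_breaks) &&
      (config$tto_breaks[1] != 0 || is.finite(utils::tail(config$tto_breaks,
                                                          1))))
    add("tto_breaks must start at 0 and end at Inf")
  problems
}

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, eol = "\n",
                     na = "NA")
}

#' Run the full disproportionality pipeline
#'
#' Ingests the quarterly tables, links and deduplicates reports, selects
#' the target primary-suspect cohort, builds PT- and SOC-level 2x2 tables,
#' computes all four statistics, classifies signals, and writes the report
#' bundle to `config$output_dir`:
#' `table1_demographics.tsv`, `soc_signals.tsv`, `pt_signals_all.tsv`,
#' `pt_signals_positive.tsv`, `annual_counts.tsv`, `time_to_onset.tsv`,
#' `indications.tsv`, `run_log.txt` and `config.yaml` (the configuration,
#' serialized verbatim). Re-running with the same config and inputs is
#' bit-identical.
#'
#' @param config a `dpa_config`.
#' @return invisibly, a list with the in-memory results (`cases`, `cohort`,
#'   `soc_stats`, `pt_stats`, `descriptives`, `log`).
#' @export
run_dpa_pipeline <- function(config) {
  problems <- validate_dpa_config(config)
  if (length(problems))
    stop("stage config: ", paste(problems, collapse = "; "), call. = FALSE)
  set.seed(config$seed)

  raw <- read_faers_quarter(config$input_dir)
  cases <- deduplicate_cases(link_cases(raw))
  log <- attr(cases, "log")
  log$raw_rows <- attr(raw, "log")

  synonyms <- read_mapping(config$synonym_file)
  pt_soc_map <- read_mapping(config$pt_soc_map_file)
  names(pt_soc_map) <- c("pt", "soc")
  cohort <- select_target_cohort(cases, config$target, synonyms)
  log$target_cases <- length(cohort$target_ids)
  log$background_cases <- length(cohort$background_ids)

  pt_tab <- build_contingency_tables(cases, cohort, "PT",
                                     counting_unit = config$counting_unit)
  # SOC tables only cover mapped PTs; unmapped PTs would be an error, so
  # restrict the SOC analysis to the mapped subset and log the rest
  mapped <- cases$events$pt %in% pt_soc_map$pt
  log$unmapped_pt_rows <- sum(!mapped)
  soc_cases <- cases
  soc_cases$events <- cases$events[mapped, , drop = FALSE]
  soc_tab <- build_contingency_tables(soc_cases, cohort, "SOC", pt_soc_map,
                                      counting_unit = config$counting_unit)

  pt_stats <- compute_signal_stats(pt_tab, criteria = config$criteria,
                                   yates = config$yates,
                                   zero_cell = config$zero_cell)
  soc_stats <- compute_signal_stats(soc_tab, criteria = config$criteria,
                                    yates = config$yates,
                                    zero_cell = config$zero_cell)
  log$positive_pts <- sum(pt_stats$signal == "positive")
  log$positive_socs <- sum(soc_stats$signal == "positive")

  tgt <- cohort$target_ids
  desc <- list(
    table1 = do.call(rbind, lapply(
      c("sex", "age_bucket", "reporter", "country", "route", "outcome"),
      function(v) {
        s <- summarize_categorical(cases, v, case_ids = tgt)
        cbind(variable = v, s)
      })),
    annual = annual_counts(cases, case_ids = tgt),
    tto = time_to_onset(cases, target = config$target, synonyms = synonyms,
                        case_ids = tgt, breaks = config$tto_breaks),
    indications = summarize_indications(
      cases,
      merge_map = if (!is.null(config$indication_merge_file))
        read_mapping(config$indication_merge_file),
      case_ids = tgt))
  log$tto <- desc$tto$log

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(desc$table1, file.path(out, "table1_demographics.tsv"))
  .write_tsv(.round_stats(soc_stats), file.path(out, "soc_signals.tsv"))
  .write_tsv(.round_stats(pt_stats), file.path(out, "pt_signals_all.tsv"))
  .write_tsv(.round_stats(pt_stats[pt_stats$signal == "positive", ,
                                   drop = FALSE]),
             file.path(out, "pt_signals_positive.tsv"))
  .write_tsv(desc$annual, file.path(out, "annual_counts.tsv"))
  tto_out <- rbind(
    data.frame(bin = c("median", "q1", "q3"),
               count = NA_integer_,
               percentage = c(desc$tto$median, desc$tto$q1, desc$tto$q3)),
    desc$tto$bins)
  .write_tsv(tto_out, file.path(out, "time_to_onset.tsv"))
  .write_tsv(desc$indications, file.path(out, "indications.tsv"))

  cfg_out <- config
  cfg_out$criteria <- unclass(cfg_out$criteria)
  cfg_out$tto_breaks <- as.character(cfg_out$tto_breaks)
  yaml::write_yaml(unclass(cfg_out), file.path(out, "config.yaml"))
  writeLines(c("faersdpa run log",
               paste0(.flatten_log(log), collapse = "\n")),
             file.path(out, "run_log.txt"))
  invisible(list(cases = cases, cohort = cohort, soc_stats = soc_stats,
                 pt_stats = pt_stats, descriptives = desc, log = log))
}

# fixed-precision numeric formatting so report bytes are deterministic
.round_stats <- function(s) {
  num <- vapply(s, is.numeric, TRUE)
  s[num] <- lapply(s[num], function(x) round(x, 6))
  s
}

.flatten_log <- function(log, prefix = "") {
  unlist(lapply(names(log), function(nm) {
    v <- log[[nm]]
    if (is.list(v)) .flatten_log(v, paste0(prefix, nm, "."))
    else paste0(prefix, nm, ": ", paste(v, collapse = ", "))
  }))
}

#' Disproportionality statistics for a pre-built a/b/c/d table file
#'
#' Reads a delimited text file with columns `label, a, b, c, d`, computes
#' the four statistics and classification, and returns (and optionally
#' writes) the signal table. This is the `stats` verb of the command-line
#' interface.
#'
#' @param path input table file (tab, comma or `$` delimited).
#' @param out optional output TSV path.
#' @param ... passed to [compute_signal_stats()].
#' @return the signal-statistics data.frame.
#' @export
stats_from_table_file <- function(path, out = NULL, ...) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl("\\$", first)) "$" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("label", "a", "b", "c", "d")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("table file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- compute_signal_stats(tab, ...)
  if (!is.null(out)) .write_tsv(.round_stats(res), out)
  res
}
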