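# FAERS quarterly ASCII ingestion: $-delimited tables DEMO, DRUG, REAC,
# THER, OUTC, INDI -> linked case model -> deduplicated reports.

.faers_required_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod", "wt",
           "occr_country", "occp_cod"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "route"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"))

#' Read one quarter of FAERS-style ASCII tables
#'
#' Each table is plain text, `$`-delimited, with one header line. Readers
#' tolerate column supersets but insist on the FAERS-standard mandatory
#' columns; a missing mandatory column is a format error naming the table
#' and column. All fields are read as character; nothing is coerced here.
#'
#' @param paths either a directory containing `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt`, `THER.txt`, `OUTC.txt`, `INDI.txt` (case-insensitive stem
#'   match), or a named list/vector of file paths with names among
#'   `demo, drug, reac, ther, outc, indi`.
#' @return named list of character data.frames with attribute `log`, a list
#'   of per-table row counts.
#' @export
read_faers_quarter <- function(paths) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    files <- list.files(paths, full.names = TRUE)
    stems <- toupper(sub("\\..*$", "", basename(files)))
    paths <- stats::setNames(
      files[match(c("DEMO", "DRUG", "REAC", "THER", "OUTC", "INDI"), stems)],
      c("demo", "drug", "reac", "ther", "outc", "indi"))
    paths <- paths[!is.na(paths)]
  }
  paths <- as.list(paths)
  names(paths) <- tolower(names(paths))
  out <- list()
  counts <- list()
  for (tb in names(.faers_required_cols)) {
    if (is.null(paths[[tb]])) next
    if (!file.exists(paths[[tb]]))
      stop(sprintf("table '%s': file not found: %s", tb, paths[[tb]]),
           call. = FALSE)
    dt <- data.table::fread(paths[[tb]], sep = "$", colClasses = "character",
                            quote = "", header = TRUE, data.table = FALSE,
                            keepLeadingZeros = TRUE, strip.white = FALSE)
    miss <- setdiff(.faers_required_cols[[tb]], names(dt))
    if (length(miss))
      stop(sprintf("table '%s': missing mandatory column(s): %s",
                   tb, paste(miss, collapse = ", ")), call. = FALSE)
    out[[tb]] <- dt
    counts[[tb]] <- nrow(dt)
  }
  if (is.null(out$demo))
    stop("table 'demo': no DEMO table supplied", call. = FALSE)
  attr(out, "log") <- counts
  out
}

#' Convert a FAERS age + unit code to years
#'
#' Unit codes: `DEC` decades (x10), `YR` years, `MON` months (/12), `WK`
#' weeks (/52.14), `DY` days (/365.25), `HR` hours (treated as missing).
#' Results outside (0, 120] are set missing: FAERS ages above 120 years are
#' data-entry artifacts.
#'
#' @param age character or numeric age values.
#' @param age_cod character unit codes (empty/unknown codes give `NA`).
#' @return numeric vector of ages in years.
#' @export
harmonize_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  f <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.14, DY = 1 / 365.25)
  mult <- f[cod]
  mult[cod == "HR"] <- NA_real_
  mult[is.na(mult) & cod == ""] <- NA_real_
  out <- v * unname(mult)
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

.sex_map <- c(F = "female", M = "male")
.occp_map <- c(MD = "physician", PH = "pharmacist",
               OT = "other health-professional", CN = "consumer",
               RN = "registered nurse")
.outc_map <- c(HO = "hospitalization", DE = "death", LT = "life-threatening",
               DS = "disability", CA = "congenital anomaly",
               RI = "required intervention", OT = "other serious")

map_code <- function(x, map, default = "unknown") {
  out <- unname(map[toupper(trimws(x))])
  out[is.na(out)] <- default
  out
}

#' Link raw quarterly tables into the case model
#'
#' Produces a `faers_cases` object: one report per DEMO row, with drugs,
#' events, outcomes, therapy dates and indications attached by report key
#' (`primaryid`). Reports with zero reaction rows are dropped; DRUG/REAC/
#' OUTC/THER/INDI rows whose key matches no DEMO row are dropped; both
#' counts are logged. Dates are parsed from the FAERS 8/6/4-digit styles
#' (partial dates resolve to the first day of the period; malformed dates
#' become missing and are counted). The report country is taken from
#' `reporter_country` when present, falling back to `occr_country`.
#'
#' @param raw named list of raw tables from [read_faers_quarter()] or
#'   [generate_faers()].
#' @return a `faers_cases` object: list of data.frames `reports` (one row
#'   per report), `drugs`, `events`, `outcomes`; attribute `log` carries
#'   dropped-row and bad-date counts.
#' @export
link_cases <- function(raw) {
  demo <- raw$demo
  log <- list()
  bad_dates <- 0L

  pdate <- function(x) {
    d <- parse_faers_date(x)
    bad_dates <<- bad_dates + attr(d, "n_bad")
    as.Date(as.vector(d))
  }

  reports <- data.frame(
    caseid = trimws(demo$caseid),
    primaryid = suppressWarnings(as.numeric(trimws(demo$primaryid))),
    fda_dt = pdate(demo$fda_dt),
    event_dt = if ("event_dt" %in% names(demo)) pdate(demo$event_dt)
               else as.Date(rep(NA, nrow(demo))),
    sex = map_code(demo$sex, .sex_map),
    age_years = harmonize_age(demo$age, demo$age_cod),
    weight_kg = suppressWarnings(as.numeric(demo$wt)),
    country = {
      ctry <- if ("reporter_country" %in% names(demo) &&
                  any(nzchar(trimws(demo$reporter_country))))
        demo$reporter_country else demo$occr_country
      ctry <- trimws(ctry)
      ifelse(nzchar(ctry), ctry, NA_character_)
    },
    reporter = map_code(demo$occp_cod, .occp_map),
    stringsAsFactors = FALSE)
  reports$weight_kg[!is.na(reports$weight_kg) & reports$weight_kg <= 0] <-
    NA_real_

  keep_tab <- function(tab, name) {
    if (is.null(tab)) return(NULL)
    tab$primaryid <- suppressWarnings(as.numeric(trimws(tab$primaryid)))
    orphan <- !(tab$primaryid %in% reports$primaryid)
    log[[paste0("orphan_", name, "_rows")]] <<- sum(orphan)
    tab[!orphan, , drop = FALSE]
  }
  drug <- keep_tab(raw$drug, "drug")
  reac <- keep_tab(raw$reac, "reac")
  ther <- keep_tab(raw$ther, "ther")
  outc <- keep_tab(raw$outc, "outc")
  indi <- keep_tab(raw$indi, "indi")

  drugs <- if (!is.null(drug) && nrow(drug)) {
    d <- data.frame(
      caseid = trimws(drug$caseid),
      primaryid = drug$primaryid,
      drug_seq = trimws(drug$drug_seq),
      role = toupper(trimws(drug$role_cod)),
      drugname_raw = drug$drugname,
      route = {
        r <- trimws(drug$route)
        ifelse(nzchar(r), r, NA_character_)
      },
      stringsAsFactors = FALSE)
    # therapy start and indication attach to (report, drug sequence)
    if (!is.null(ther) && nrow(ther)) {
      key <- paste(d$primaryid, d$drug_seq)
      tkey <- paste(ther$primaryid, trimws(ther$dsg_drug_seq))
      d$therapy_start <- pdate(ther$start_dt)[match(key, tkey)]
    } else d$therapy_start <- as.Date(rep(NA, nrow(d)))
    if (!is.null(indi) && nrow(indi)) {
      key <- paste(d$primaryid, d$drug_seq)
      ikey <- paste(indi$primaryid, trimws(indi$indi_drug_seq))
      ind <- indi$indi_pt[match(key, ikey)]
      d$indication_pt <- ifelse(!is.na(ind) & nzchar(trimws(ind)),
                                trimws(ind), NA_character_)
    } else d$indication_pt <- NA_character_
    d
  } else data.frame(caseid = character(), primaryid = numeric(),
                    drug_seq = character(), role = character(),
                    drugname_raw = character(), route = character(),
                    therapy_start = as.Date(character()),
                    indication_pt = character(), stringsAsFactors = FALSE)

  events <- if (!is.null(reac) && nrow(reac)) {
    data.frame(caseid = trimws(reac$caseid), primaryid = reac$primaryid,
               pt = trimws(reac$pt), stringsAsFactors = FALSE)
  } else data.frame(caseid = character(), primaryid = numeric(),
                    pt = character(), stringsAsFactors = FALSE)

  outcomes <- if (!is.null(outc) && nrow(outc)) {
    data.frame(caseid = trimws(outc$caseid), primaryid = outc$primaryid,
               outcome = map_code(outc$outc_cod, .outc_map),
               stringsAsFactors = FALSE)
  } else data.frame(caseid = character(), primaryid = numeric(),
                    outcome = character(), stringsAsFactors = FALSE)

  # a report with no reaction rows is not an adverse-event report: drop it
  has_event <- reports$primaryid %in% events$primaryid
  log$dropped_no_event_reports <- sum(!has_event)
  reports <- reports[has_event, , drop = FALSE]
  for (nm in c("drugs", "events", "outcomes")) {
    tab <- get(nm)
    assign(nm, tab[tab$primaryid %in% reports$primaryid, , drop = FALSE])
  }
  log$bad_dates <- bad_dates
  log$reports <- nrow(reports)

  out <- list(reports = `rownames<-`(reports, NULL),
              drugs = `rownames<-`(drugs, NULL),
              events = `rownames<-`(events, NULL),
              outcomes = `rownames<-`(outcomes, NULL))
  attr(out, "log") <- log
  class(out) <- "faers_cases"
  out
}

#' Deduplicate reports: one surviving report per case
#'
#' FAERS carries multiple report versions per case. For each `caseid` the
#' report with the latest receipt date (`fda_dt`) survives, ties broken by
#' the largest `primaryid` (the FAERS "latest case version" convention).
#' Field values are never altered: whole reports are removed. Idempotent.
#'
#' @param cases a `faers_cases` object from [link_cases()].
#' @return a `faers_cases` object with one report per case; attribute
#'   `log$duplicates_removed` counts removed reports.
#' @export
deduplicate_cases <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  rep <- cases$reports
  # order: case, then receipt date (NA first), then primaryid; keep last
  ord <- order(rep$caseid,
               ifelse(is.na(rep$fda_dt), -Inf, as.numeric(rep$fda_dt)),
               rep$primaryid)
  rep_ord <- rep[ord, , drop = FALSE]
  keep_last <- !duplicated(rep_ord$caseid, fromLast = TRUE)
  survivors <- rep_ord$primaryid[keep_last]
  n_removed <- nrow(rep) - length(survivors)

  out <- list(
    reports = rep[rep$primaryid %in% survivors, , drop = FALSE],
    drugs = cases$drugs[cases$drugs$primaryid %in% survivors, , drop = FALSE],
    events = cases$events[cases$events$primaryid %in% survivors, ,
                          drop = FALSE],
    outcomes = cases$outcomes[cases$outcomes$primaryid %in% survivors, ,
                              drop = FALSE])
  out <- lapply(out, `rownames<-`, NULL)
  log <- attr(cases, "log") %||% list()
  log$duplicates_removed <- n_removed
  attr(out, "log") <- log
  class(out) <- "faers_cases"
  out
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf(
    "<faers_cases> %d reports (%d cases), %d drug rows, %d event rows\n",
    nrow(x$reports), length(unique(x$reports$caseid)), nrow(x$drugs),
    nrow(x$events)))
  invisible(x)
}
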