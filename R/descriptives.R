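# Descriptive summaries of a report cohort: baseline characteristics,
# annual report counts, time to onset, and indication tallies.

#' Cut ages into the reporting buckets
#'
#' Buckets are `<20`, `20~40`, `40~60`, `>=60`, `unknown`; interior buckets
#' are left-closed (`[20,40)`, `[40,60)`), so an age of exactly 60 falls in
#' `>=60`.
#'
#' @param age_years numeric ages in years (`NA` allowed).
#' @return character vector of bucket labels.
#' @export
age_bucket <- function(age_years) {
  out <- ifelse(is.na(age_years), "unknown",
         ifelse(age_years < 20, "<20",
         ifelse(age_years < 40, "20~40",
         ifelse(age_years < 60, "40~60", ">=60"))))
  out
}

#' Summarize a categorical baseline variable with percentages
#'
#' Counts per category with `percentage = 100 * count / denominator`,
#' rounded half-up to 2 decimals. Supported variables: `sex`, `age_bucket`,
#' `reporter`, `country`, `route`, `outcome`. For case-level variables each
#' case counts once; `route` uses each case's primary-suspect drug route;
#' `outcome` counts outcome codes, where one case may carry several codes
#' (its natural denominator is therefore the outcome-code total, the
#' `"all-rows"` rule). The denominator rule is `"known-only"` (non-missing
#' rows; default for most variables) or `"all-rows"`.
#'
#' @param cases deduplicated `faers_cases`.
#' @param variable one of the supported variable names.
#' @param denominator `"known-only"` or `"all-rows"`. Default:
#'   `"all-rows"` for `age_bucket`, `reporter` and `outcome` (where
#'   "unknown" is itself a reported category), `"known-only"` otherwise.
#' @param case_ids optional character vector restricting to a cohort.
#' @return data.frame `category`, `count`, `percentage`, ordered by
#'   decreasing count; attribute `denominator` holds the value used.
#' @export
summarize_categorical <- function(cases, variable,
                                  denominator = NULL, case_ids = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  supported <- c("sex", "age_bucket", "reporter", "country", "route",
                 "outcome")
  if (!variable %in% supported)
    stop("unsupported variable '", variable, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  rep <- cases$reports
  if (!is.null(case_ids)) rep <- rep[rep$caseid %in% case_ids, , drop = FALSE]

  vals <- switch(variable,
    sex = ifelse(rep$sex == "unknown", NA_character_, rep$sex),
    age_bucket = age_bucket(rep$age_years),
    reporter = rep$reporter,
    country = rep$country,
    route = {
      d <- cases$drugs[cases$drugs$role == "PS", , drop = FALSE]
      d <- d[!duplicated(d$caseid), , drop = FALSE]
      r <- d$route[match(rep$caseid, d$caseid)]
      toupper(r)
    },
    outcome = {
      o <- cases$outcomes[cases$outcomes$caseid %in% rep$caseid, ,
                          drop = FALSE]
      unique(o[, c("caseid", "outcome")])$outcome
    })

  if (is.null(denominator))
    denominator <- if (variable %in% c("age_bucket", "reporter", "outcome"))
      "all-rows" else "known-only"
  denominator <- match.arg(denominator, c("known-only", "all-rows"))
  if (denominator == "known-only") vals <- vals[!is.na(vals)]
  n_known <- sum(!is.na(vals))
  denom <- if (denominator == "known-only") n_known else length(vals)
  vals[is.na(vals)] <- "unknown"

  tab <- table(vals)
  out <- data.frame(category = names(tab), count = as.vector(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- round_half_up(100 * out$count / max(denom, 1), 2)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  out
}

#' Annual report counts
#'
#' Counts surviving reports by calendar year of the receipt date; reports
#' with a missing receipt date are excluded and counted in the log.
#'
#' @param cases deduplicated `faers_cases`.
#' @param case_ids optional cohort restriction.
#' @return data.frame `year`, `count`, ascending by year; attribute
#'   `n_missing_date` counts excluded reports.
#' @export
annual_counts <- function(cases, case_ids = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  rep <- cases$reports
  if (!is.null(case_ids)) rep <- rep[rep$caseid %in% case_ids, , drop = FALSE]
  ok <- !is.na(rep$fda_dt)
  yr <- as.integer(format(rep$fda_dt[ok], "%Y"))
  tab <- table(yr)
  out <- data.frame(year = as.integer(names(tab)), count = as.vector(tab))
  attr(out, "n_missing_date") <- sum(!ok)
  out
}

#' Time to onset of events after therapy start
#'
#' Per case, the lag in days from the earliest therapy start of the target
#' drug (all drugs if `target` is `NULL`) to the event onset date. Negative
#' or missing lags are excluded from the median/quartiles and counted.
#' Binned counts use right-closed bins over the default edges
#' `0, 30, 60, 90, 180, 365, 730, Inf` (days); following reporting practice
#' for spontaneous-report onset tables, bin percentages are taken over all
#' included reports (`denominator = "included"`, so reports with missing
#' onset are part of the denominator), or over known lags only with
#' `denominator = "known"`.
#'
#' @param cases deduplicated `faers_cases`.
#' @param target canonical target drug label (with `synonyms` as in
#'   [normalize_drug_name()]); `NULL` uses the earliest start date of any
#'   drug per case.
#' @param synonyms synonym mapping for `target`.
#' @param case_ids optional cohort restriction.
#' @param breaks bin edges in days (first edge 0, last `Inf`).
#' @param denominator `"included"` (default) or `"known"`.
#' @return list with `lags` (named numeric, known lags in days), `median`,
#'   `q1`, `q3`, `bins` (data.frame `bin`, `count`, `percentage`), and
#'   `log` (counts of included, known, missing, negative).
#' @export
time_to_onset <- function(cases, target = NULL, synonyms = NULL,
                          case_ids = NULL,
                          breaks = c(0, 30, 60, 90, 180, 365, 730, Inf),
                          denominator = c("included", "known")) {
  stopifnot(inherits(cases, "faers_cases"))
  denominator <- match.arg(denominator)
  rep <- cases$reports
  if (!is.null(case_ids)) rep <- rep[rep$caseid %in% case_ids, , drop = FALSE]
  d <- cases$drugs[cases$drugs$caseid %in% rep$caseid, , drop = FALSE]
  if (!is.null(target)) {
    tgt <- normalize_drug_name(target, synonyms)
    d <- d[normalize_drug_name(d$drugname_raw, synonyms) == tgt, ,
           drop = FALSE]
  }
  d <- d[!is.na(d$therapy_start), , drop = FALSE]
  start <- if (nrow(d)) {
    agg <- stats::aggregate(therapy_start ~ caseid, data = d, FUN = min)
    agg$therapy_start[match(rep$caseid, agg$caseid)]
  } else as.Date(rep(NA, nrow(rep)))
  lag <- as.numeric(rep$event_dt - as.Date(start, origin = "1970-01-01"))
  neg <- !is.na(lag) & lag < 0
  known <- !is.na(lag) & lag >= 0
  lags <- stats::setNames(lag[known], rep$caseid[known])

  qs <- if (length(lags)) stats::quantile(lags, c(0.25, 0.5, 0.75), type = 7)
        else c(NA_real_, NA_real_, NA_real_)
  bin_lab <- paste0(ifelse(breaks[-length(breaks)] == 0, "0",
                           paste0(">", breaks[-length(breaks)])),
                    ifelse(is.finite(breaks[-1]),
                           paste0("-", breaks[-1]), "+"), " days")
  cutv <- cut(lags, breaks = breaks, include.lowest = TRUE, right = TRUE,
              labels = bin_lab)
  denom <- if (denominator == "included") nrow(rep) else length(lags)
  bins <- data.frame(bin = bin_lab, count = as.vector(table(cutv)),
                     stringsAsFactors = FALSE)
  bins$percentage <- round_half_up(100 * bins$count / max(denom, 1), 2)

  list(lags = lags, median = unname(qs[2]), q1 = unname(qs[1]),
       q3 = unname(qs[3]), bins = bins,
       log = list(included = nrow(rep), known = length(lags),
                  missing = sum(is.na(lag)), negative = sum(neg)))
}

#' Tally indications, merging synonymous labels
#'
#' Counts distinct (case, indication) assignments of the primary-suspect
#' drug, after sending raw indication PTs through a merge map (e.g. all
#' glioma variants to "glioma"); unmapped labels pass through unchanged.
#'
#' @param cases deduplicated `faers_cases`.
#' @param merge_map named character vector or two-column data.frame sending
#'   raw indication labels to group labels; `NULL` for raw tallies.
#' @param case_ids optional cohort restriction.
#' @return data.frame `indication`, `count`, descending.
#' @export
summarize_indications <- function(cases, merge_map = NULL, case_ids = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  d <- cases$drugs[cases$drugs$role == "PS" & !is.na(cases$drugs$indication_pt),
                   , drop = FALSE]
  if (!is.null(case_ids)) d <- d[d$caseid %in% case_ids, , drop = FALSE]
  d <- unique(d[, c("caseid", "indication_pt")])
  lab <- d$indication_pt
  if (!is.null(merge_map)) {
    if (is.data.frame(merge_map))
      merge_map <- stats::setNames(merge_map[[2]], merge_map[[1]])
    hit <- lab %in% names(merge_map)
    lab[hit] <- unname(merge_map[lab[hit]])
  }
  tab <- table(lab)
  out <- data.frame(indication = names(tab), count = as.vector(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$indication), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentages from a vector of category counts
#'
#' Recomputes a report-style percentage column (half-up, 2 decimals) from
#' counts, e.g. to check a published baseline-characteristics table.
#'
#' @param counts named numeric vector of category counts.
#' @param denominator total to divide by; defaults to `sum(counts)`.
#' @return data.frame `category`, `count`, `percentage`.
#' @export
percentage_table <- function(counts, denominator = sum(counts)) {
  data.frame(category = names(counts) %||% as.character(seq_along(counts)),
             count = as.vector(counts),
             percentage = round_half_up(100 * as.vector(counts) / denominator,
                                        2),
             stringsAsFactors = FALSE)
}
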