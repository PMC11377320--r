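# Synthetic spontaneous-report generator.
#
# Emits DEMO/DRUG/REAC/THER/OUTC/INDI tables in the FAERS quarterly ASCII
# dialect with known ground truth: planted drug-event associations with a
# specified relative reporting rate lambda, injected duplicate reports, and
# controlled missingness, so that every downstream stage (ingestion, dedup,
# cohorting, disproportionality, descriptives) can be tested without a
# database download.

#' Drug / PT label universes used by the generator
#'
#' Stable label builders so planted signals can reference the universes.
#'
#' @param n number of labels.
#' @return character vector of labels.
#' @export
sim_drug_labels <- function(n) sprintf("DRUG%02d", seq_len(n))

#' @rdname sim_drug_labels
#' @export
sim_pt_labels <- function(n) sprintf("PT%03d", seq_len(n))

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defaults describe the simulated study conditions used throughout the test
#' suite: a modest database (2,000 cases, 6 drugs, 25 PTs over 5 SOCs) with a
#' per-PT baseline reporting probability of 0.05 (so cases carry a little over
#' one event on average), 5\% duplicate reports, and missingness rates for age
#' (21\%) and time-to-onset (45\%) matching what spontaneous-report databases
#' typically show for an oncology drug.
#'
#' @param n_cases number of unique cases (before duplicate injection).
#' @param n_drugs,n_pts sizes of the drug and PT universes (labels from
#'   [sim_drug_labels()] / [sim_pt_labels()]).
#' @param pt_soc_map data.frame with columns `pt`, `soc` mapping every PT to
#'   exactly one primary SOC; `NULL` assigns PTs round-robin to 5 synthetic
#'   SOC labels.
#' @param background_rate per-PT baseline reporting probability in (0,1).
#' @param planted_signals data.frame with columns `drug`, `pt`, `lambda`:
#'   for cases whose primary-suspect drug is `drug`, PT `pt` occurs with
#'   probability `min(1, lambda * background_rate)`; all other pairs have
#'   lambda = 1.
#' @param duplicate_fraction fraction of cases re-emitted as a duplicate
#'   report (new report id, later receipt date, all other fields identical),
#'   in [0,1).
#' @param missing_age_fraction,missing_tto_fraction fractions in [0,1) of
#'   cases with missing age, and with a missing therapy-start or onset date.
#' @param seed integer random seed; generation is bit-reproducible.
#' @return an object of class `faers_sim_config`.
#' @export
faers_sim_config <- function(n_cases = 2000,
                             n_drugs = 6,
                             n_pts = 25,
                             pt_soc_map = NULL,
                             background_rate = 0.05,
                             planted_signals = NULL,
                             duplicate_fraction = 0.05,
                             missing_age_fraction = 0.21,
                             missing_tto_fraction = 0.45,
                             seed = 1L) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
      stop_config(field, "must be a positive integer")
  }
  chk_count(n_cases, "n_cases")
  chk_count(n_drugs, "n_drugs")
  chk_count(n_pts, "n_pts")
  if (!is.numeric(background_rate) || length(background_rate) != 1 ||
      is.na(background_rate) || background_rate <= 0 || background_rate >= 1)
    stop_config("background_rate", "must lie in (0,1)")
  for (f in c("duplicate_fraction", "missing_age_fraction",
              "missing_tto_fraction")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v >= 1)
      stop_config(f, "must lie in [0,1)")
  }
  chk_count(abs(seed) + 1, "seed")

  drugs <- sim_drug_labels(n_drugs)
  pts <- sim_pt_labels(n_pts)

  if (is.null(pt_soc_map)) {
    n_soc <- min(5L, n_pts)
    pt_soc_map <- data.frame(
      pt = pts,
      soc = sprintf("SOC%02d", ((seq_len(n_pts) - 1L) %% n_soc) + 1L),
      stringsAsFactors = FALSE)
  }
  if (!all(pts %in% pt_soc_map$pt))
    stop_config("pt_soc_map", "must cover every PT in the universe")

  if (is.null(planted_signals)) {
    planted_signals <- data.frame(drug = character(), pt = character(),
                                  lambda = numeric(), stringsAsFactors = FALSE)
  }
  planted_signals <- as.data.frame(planted_signals)
  if (nrow(planted_signals)) {
    if (!all(c("drug", "pt", "lambda") %in% names(planted_signals)))
      stop_config("planted_signals", "needs columns drug, pt, lambda")
    if (!all(planted_signals$drug %in% drugs))
      stop_config("planted_signals", "references drugs outside the universe")
    if (!all(planted_signals$pt %in% pts))
      stop_config("planted_signals", "references PTs outside the universe")
    if (any(planted_signals$lambda < 0))
      stop_config("planted_signals", "lambda must be >= 0")
  }

  structure(list(
    n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
    n_pts = as.integer(n_pts), drugs = drugs, pts = pts,
    pt_soc_map = pt_soc_map, background_rate = background_rate,
    planted_signals = planted_signals,
    duplicate_fraction = duplicate_fraction,
    missing_age_fraction = missing_age_fraction,
    missing_tto_fraction = missing_tto_fraction,
    seed = as.integer(seed)), class = "faers_sim_config")
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Produces the six FAERS-style raw tables plus the ground truth. Each case
#' has exactly one primary-suspect (PS) drug, possibly secondary/concomitant
#' drugs, and at least one PT event. Events arise per PT as independent
#' Bernoulli draws with probability `background_rate`, inflated to
#' `min(1, lambda * background_rate)` for a planted (drug, PT) pair when the
#' case's PS drug matches; a case that draws no event receives one PT
#' uniformly at random so the "every report lists an event" invariant of real
#' spontaneous-report data holds. Case ids are sequential integers and report
#' ids are `caseid * 100 + version`, so "latest report per case" is well
#' defined; injected duplicates differ only in report id and receipt date.
#' Therapy start precedes event onset by an exponential lag (mean 60 days)
#' to exercise time-to-onset analysis.
#'
#' @param config a [faers_sim_config()].
#' @return list with elements `tables` (named list of character data.frames:
#'   `demo`, `drug`, `reac`, `ther`, `outc`, `indi`, in the same dialect the
#'   ingestion readers accept) and `truth` (list with `planted_pairs`, the
#'   planted data.frame including lambda, and `case_events`, the in-memory
#'   per-case event assignments used for round-trip checks).
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  drugs <- config$drugs
  pts <- config$pts

  caseid <- seq_len(n)
  primaryid <- caseid * 100L + 1L

  # receipt dates 2004-2023 with a linearly increasing annual trend
  yr_w <- seq(1, 3, length.out = 20)
  year <- sample(2004:2023, n, replace = TRUE, prob = yr_w / sum(yr_w))
  fda_dt <- as.Date(sprintf("%d-%02d-%02d", year,
                            sample(1:12, n, TRUE), sample(1:28, n, TRUE)))

  sex <- sample(c("F", "M", "UNK"), n, TRUE, prob = c(0.46, 0.53, 0.01))
  age <- round(pmin(95, pmax(1, stats::rnorm(n, 58, 18))))
  age_cod <- rep("YR", n)
  age_missing <- stats::runif(n) < config$missing_age_fraction
  wt <- round(pmin(150, pmax(35, stats::rnorm(n, 73, 15))), 1)
  wt_missing <- stats::runif(n) < 0.3
  country <- sample(c("US", "JP", "CA", "FR", "DE", "GB", "IT", "CN", "ES"),
                    n, TRUE,
                    prob = c(0.50, 0.07, 0.07, 0.07, 0.06, 0.06, 0.06,
                             0.055, 0.055))
  occp <- sample(c("MD", "PH", "OT", "CN", "RN", ""), n, TRUE,
                 prob = c(0.30, 0.28, 0.14, 0.12, 0.01, 0.15))

  ps_drug <- sample(drugs, n, TRUE)

  # event matrix: per-PT Bernoulli, planted pairs inflated for matching PS
  prob <- matrix(config$background_rate, nrow = n, ncol = config$n_pts,
                 dimnames = list(NULL, pts))
  if (nrow(config$planted_signals)) {
    for (i in seq_len(nrow(config$planted_signals))) {
      g <- config$planted_signals$drug[i]
      e <- config$planted_signals$pt[i]
      lam <- config$planted_signals$lambda[i]
      prob[ps_drug == g, e] <- min(1, lam * config$background_rate)
    }
  }
  ev <- matrix(stats::runif(n * config$n_pts), n) < prob
  none <- !rowSums(ev)
  if (any(none)) { # guarantee >= 1 event per case
    fill <- sample.int(config$n_pts, sum(none), TRUE)
    ev[cbind(which(none), fill)] <- TRUE
  }

  # therapy start / event onset: onset lags start by Exp(mean 60) days and
  # the report is received a short delay after onset
  tto <- round(stats::rexp(n, 1 / 60))
  event_dt <- fda_dt - sample(0:60, n, TRUE)
  start_dt <- event_dt - tto
  tto_missing <- stats::runif(n) < config$missing_tto_fraction
  drop_start <- tto_missing & stats::runif(n) < 0.5 # half lose start, half onset

  demo <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    fda_dt = format_faers_date(fda_dt),
    event_dt = ifelse(tto_missing & !drop_start, "",
                      format_faers_date(event_dt)),
    sex = sex,
    age = ifelse(age_missing, "", as.character(age)),
    age_cod = ifelse(age_missing, "", age_cod),
    wt = ifelse(wt_missing, "", as.character(wt)),
    wt_cod = ifelse(wt_missing, "", "KG"),
    occr_country = country,
    reporter_country = country,
    occp_cod = occp,
    stringsAsFactors = FALSE)

  # drugs: PS always first (drug_seq 1), then 0-2 extra SS/C/I drugs
  n_extra <- sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2))
  extra_case <- rep(caseid, n_extra)
  extra_drug <- sample(drugs, length(extra_case), TRUE)
  routes <- c("ORAL", "INTRAVENOUS", "INTRAVENOUS DRIP", "TRANSPLACENTAL",
              "UNKNOWN")
  drug <- data.frame(
    primaryid = as.character(c(primaryid, extra_case * 100L + 1L)),
    caseid = as.character(c(caseid, extra_case)),
    drug_seq = as.character(c(rep(1L, n),
                              sequence(n_extra[n_extra > 0]) + 1L)),
    role_cod = c(rep("PS", n),
                 sample(c("SS", "C", "I"), length(extra_case), TRUE,
                        prob = c(0.4, 0.5, 0.1))),
    drugname = c(ps_drug, extra_drug),
    route = c(sample(routes, n, TRUE, prob = c(0.63, 0.01, 0.01, 0.001, 0.349)),
              sample(routes, length(extra_case), TRUE,
                     prob = c(0.5, 0.05, 0.05, 0.001, 0.399))),
    stringsAsFactors = FALSE)
  drug <- drug[order(as.integer(drug$caseid), as.integer(drug$drug_seq)), ]

  idx <- which(ev, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  reac <- data.frame(
    primaryid = as.character(idx[, 1] * 100L + 1L),
    caseid = as.character(idx[, 1]),
    pt = pts[idx[, 2]],
    stringsAsFactors = FALSE)

  ther <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    dsg_drug_seq = "1",
    start_dt = ifelse(tto_missing & drop_start, "",
                      format_faers_date(start_dt)),
    stringsAsFactors = FALSE)

  outc_codes <- c("HO", "OT", "DE", "LT", "DS", "RI", "CA")
  outc_prob <- c(0.36, 0.34, 0.23, 0.05, 0.016, 0.003, 0.001)
  om <- matrix(stats::runif(n * 7), n) < rep(outc_prob, each = n)
  oidx <- which(om, arr.ind = TRUE)
  oidx <- oidx[order(oidx[, 1], oidx[, 2]), , drop = FALSE]
  outc <- data.frame(
    primaryid = as.character(oidx[, 1] * 100L + 1L),
    caseid = as.character(oidx[, 1]),
    outc_cod = outc_codes[oidx[, 2]],
    stringsAsFactors = FALSE)

  indications <- c("Glioma", "Glioblastoma multiforme", "Astrocytoma",
                   "Brain neoplasm", "Malignant melanoma",
                   "Neuroendocrine tumour", "Pituitary tumour")
  indi <- data.frame(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    indi_drug_seq = "1",
    indi_pt = sample(indications, n, TRUE,
                     prob = c(0.45, 0.18, 0.08, 0.12, 0.08, 0.05, 0.04)),
    stringsAsFactors = FALSE)

  tables <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, indi = indi)

  # duplicate injection: same case, new report id (version 2), later receipt
  n_dup <- floor(config$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_cases <- sort(sample(caseid, n_dup))
    delay <- sample(30:400, n_dup, TRUE)
    for (tb in names(tables)) {
      rows <- tables[[tb]][tables[[tb]]$caseid %in% as.character(dup_cases), ,
                           drop = FALSE]
      if (!nrow(rows)) next
      rows$primaryid <- as.character(as.integer(rows$caseid) * 100L + 2L)
      if (tb == "demo") {
        old <- parse_faers_date(rows$fda_dt)
        rows$fda_dt <- format_faers_date(
          old + delay[match(rows$caseid, as.character(dup_cases))])
      }
      tables[[tb]] <- rbind(tables[[tb]], rows)
    }
  }
  for (tb in names(tables)) {
    tables[[tb]] <- tables[[tb]][order(as.integer(tables[[tb]]$caseid),
                                       as.integer(tables[[tb]]$primaryid)), ,
                                 drop = FALSE]
    rownames(tables[[tb]]) <- NULL
  }

  truth <- list(
    planted_pairs = config$planted_signals,
    ps_drug = stats::setNames(ps_drug, caseid),
    case_events = lapply(seq_len(n), function(i) pts[ev[i, ]]))
  names(truth$case_events) <- caseid

  list(tables = tables, truth = truth)
}

#' Write raw tables (and optional ground-truth manifest) to a directory
#'
#' Tables are written in the FAERS quarterly ASCII dialect: plain text,
#' `$`-delimited, one header line, one record per line, as `DEMO.txt`,
#' `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt`, `INDI.txt`.
#'
#' @param tables named list of raw tables as returned by [generate_faers()].
#' @param dir output directory (created if needed).
#' @param truth optional ground truth; planted pairs are written to
#'   `ground_truth.txt`.
#' @return invisibly, the named vector of file paths written.
#' @export
write_faers <- function(tables, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in names(tables)) {
    p <- file.path(dir, paste0(toupper(tb), ".txt"))
    data.table::fwrite(tables[[tb]], p, sep = "$", quote = FALSE, eol = "\n")
    paths[tb] <- p
  }
  if (!is.null(truth) && nrow(truth$planted_pairs)) {
    p <- file.path(dir, "ground_truth.txt")
    data.table::fwrite(truth$planted_pairs, p, sep = "$", quote = FALSE,
                       eol = "\n")
    paths["ground_truth"] <- p
  }
  invisible(paths)
}

#' A hand-written 20-row fixture with documented expected counts
#'
#' Twenty raw DEMO rows covering 18 distinct cases: cases 2 and 5 each carry
#' a duplicate report (version 2, later receipt date, otherwise identical),
#' case 7 has a missing age, and the pair (TEMOZOLOMIDE, Thrombocytopenia)
#' is planted. Expected values, all hand-counted:
#'
#' * raw DEMO rows: 20; cases after deduplication: 18 (reports 202 and 502
#'   survive for cases 2 and 5).
#' * target-PS cohort under the bundled temozolomide synonym list: cases
#'   1-8 (case 3 spelled "TEMODAR", case 4 "temodal ", case 6
#'   "Temozolomide."); case 9 lists TEMOZOLOMIDE as SS only and stays in
#'   the background.
#' * event-level PT margins after within-case PT deduplication (case 6
#'   lists Thrombocytopenia twice): target 11, background 12.
#' * Thrombocytopenia 2x2 at PT level: a = 6 (cases 1,2,3,5,6,8), b = 5,
#'   c = 1 (case 12), d = 11, N = 23.
#' * SOC "Blood and lymphatic system disorders" under the fixture map
#'   (Thrombocytopenia, Anaemia): a = 7 (six Thrombocytopenia cases plus
#'   case 3's Anaemia), c = 2.
#' * time to onset, target cohort: case 4 has no therapy start date; the
#'   seven known lags are 10, 20, 30, 45, 60, 100, 150 days (median 45).
#'
#' @return list with `tables` (raw table list, same shape as
#'   [generate_faers()]) and `pt_soc_map` (the fixture's PT to SOC map).
#' @export
fixture_small <- function() {
  demo_txt <- c(
    # primaryid caseid fda_dt event_dt sex age age_cod wt wt_cod occr rep occp
    "101$1$20200115$20200110$M$55$YR$80$KG$US$US$MD",
    "201$2$20200110$20200105$F$61$YR$66$KG$US$US$PH",
    "202$2$20200601$20200105$F$61$YR$66$KG$US$US$PH",
    "301$3$20200320$20200318$M$47$YR$90$KG$JP$JP$MD",
    "401$4$20200405$20200401$F$35$YR$58$KG$FR$FR$OT",
    "501$5$20210301$20210225$M$68$YR$82$KG$US$US$CN",
    "502$5$20210915$20210225$M$68$YR$82$KG$US$US$CN",
    "601$6$20210510$20210505$F$72$YR$70$KG$DE$DE$MD",
    "701$7$20210620$20210615$M$$$75$KG$US$US$PH",
    "801$8$20220130$20220125$F$29$YR$61$KG$CA$CA$MD",
    "901$9$20220215$20220210$M$6$DEC$77$KG$US$US$MD",
    "1001$10$20220301$20220227$F$44$YR$64$KG$GB$GB$CN",
    "1101$11$20220412$20220410$M$51$YR$85$KG$US$US$OT",
    "1201$12$20220505$20220501$F$63$YR$59$KG$IT$IT$MD",
    "1301$13$20220618$20220615$M$38$YR$92$KG$US$US$PH",
    "1401$14$20220722$20220720$F$57$YR$67$KG$ES$ES$MD",
    "1501$15$20220830$20220828$M$49$YR$88$KG$US$US$UNK",
    "1601$16$20220911$20220909$F$66$YR$62$KG$JP$JP$MD",
    "1701$17$20221015$20221012$M$53$YR$79$KG$US$US$PH",
    "1801$18$20221120$20221118$F$60$YR$65$KG$CN$CN$MD")
  drug_txt <- c(
    "101$1$1$PS$TEMOZOLOMIDE$ORAL",
    "201$2$1$PS$TEMOZOLOMIDE$ORAL",
    "202$2$1$PS$TEMOZOLOMIDE$ORAL",
    "301$3$1$PS$TEMODAR$ORAL",
    "401$4$1$PS$temodal $ORAL",
    "501$5$1$PS$TEMOZOLOMIDE$ORAL",
    "502$5$1$PS$TEMOZOLOMIDE$ORAL",
    "601$6$1$PS$Temozolomide.$ORAL",
    "701$7$1$PS$TEMOZOLOMIDE$ORAL",
    "801$8$1$PS$TEMOZOLOMIDE$ORAL",
    "801$8$2$C$DEXAMETHASONE$ORAL",
    "901$9$1$PS$ASPIRIN$ORAL",
    "901$9$2$SS$TEMOZOLOMIDE$ORAL",
    "1001$10$1$PS$IBUPROFEN$ORAL",
    "1101$11$1$PS$ASPIRIN$ORAL",
    "1201$12$1$PS$HEPARIN$INTRAVENOUS",
    "1301$13$1$PS$IBUPROFEN$ORAL",
    "1401$14$1$PS$METFORMIN$ORAL",
    "1501$15$1$PS$ASPIRIN$ORAL",
    "1601$16$1$PS$METFORMIN$ORAL",
    "1701$17$1$PS$IBUPROFEN$ORAL",
    "1801$18$1$PS$ASPIRIN$ORAL")
  reac_txt <- c(
    "101$1$Thrombocytopenia", "101$1$Nausea",
    "201$2$Thrombocytopenia", "202$2$Thrombocytopenia",
    "301$3$Thrombocytopenia", "301$3$Anaemia",
    "401$4$Nausea",
    "501$5$Thrombocytopenia", "502$5$Thrombocytopenia",
    "601$6$Thrombocytopenia", "601$6$Thrombocytopenia",
    "701$7$Headache",
    "801$8$Thrombocytopenia", "801$8$Rash",
    "901$9$Headache",
    "1001$10$Nausea",
    "1101$11$Rash",
    "1201$12$Thrombocytopenia",
    "1301$13$Headache", "1301$13$Nausea",
    "1401$14$Anaemia",
    "1501$15$Nausea",
    "1601$16$Headache",
    "1701$17$Rash", "1701$17$Nausea",
    "1801$18$Headache")
  ther_txt <- c(
    "101$1$1$20191231",  # lag  10 against DEMO event_dt 20200110
    "201$2$1$20191216", "202$2$1$20191216",   # lag  20
    "301$3$1$20200217",                        # lag  30
    "401$4$1$",                                # missing start date
    "501$5$1$20210111", "502$5$1$20210111",   # lag  45
    "601$6$1$20210306",                        # lag  60
    "701$7$1$20210307",                        # lag 100
    "801$8$1$20210828",                        # lag 150
    "901$9$1$20220201",
    "1201$12$1$20220420")
  outc_txt <- c(
    "101$1$HO", "201$2$HO", "202$2$HO", "301$3$DE", "501$5$HO", "502$5$HO",
    "501$5$LT", "502$5$LT", "601$6$OT", "801$8$HO", "1201$12$HO",
    "1301$13$OT")
  indi_txt <- c(
    "101$1$1$Glioma", "201$2$1$Glioma", "202$2$1$Glioma",
    "301$3$1$Glioblastoma multiforme", "401$4$1$Astrocytoma",
    "501$5$1$Glioma", "502$5$1$Glioma",
    "601$6$1$Glioblastoma multiforme",
    "701$7$1$Brain neoplasm", "801$8$1$Malignant melanoma",
    "901$9$1$Headache", "1201$12$1$Thrombosis")
  parse <- function(lines, header) {
    con <- textConnection(c(header, lines))
    on.exit(close(con))
    utils::read.table(con, sep = "$", header = TRUE, colClasses = "character",
                      quote = "", comment.char = "")
  }
  tables <- list(
    demo = parse(demo_txt, paste(
      "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod",
      "occr_country$reporter_country$occp_cod", sep = "$")),
    drug = parse(drug_txt, "primaryid$caseid$drug_seq$role_cod$drugname$route"),
    reac = parse(reac_txt, "primaryid$caseid$pt"),
    ther = parse(ther_txt, "primaryid$caseid$dsg_drug_seq$start_dt"),
    outc = parse(outc_txt, "primaryid$caseid$outc_cod"),
    indi = parse(indi_txt, "primaryid$caseid$indi_drug_seq$indi_pt"))
  pt_soc_map <- data.frame(
    pt = c("Thrombocytopenia", "Anaemia", "Nausea", "Headache", "Rash"),
    soc = c("Blood and lymphatic system disorders",
            "Blood and lymphatic system disorders",
            "Gastrointestinal disorders", "Nervous system disorders",
            "Skin and subcutaneous tissue disorders"),
    stringsAsFactors = FALSE)
  list(tables = tables, pt_soc_map = pt_soc_map)
}
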