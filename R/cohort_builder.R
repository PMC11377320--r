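# Target-drug cohorting and 2x2 contingency-table construction.
#
# A case belongs to the target cohort iff at least one of its drugs with
# role PS (primary suspect) normalizes to the target label; everything else
# is background, including cases where the target appears only as SS/C/I.

#' Normalize a drug name and map it through a synonym list
#'
#' Uppercases, trims, strips punctuation/registered-mark characters and
#' collapses whitespace, then maps through the synonym table. Unmapped names
#' are returned normalized but unmapped. Normalization is idempotent.
#'
#' @param raw character vector of raw drug names.
#' @param synonyms named character vector or two-column data.frame
#'   (`synonym`, `canonical`) mapping normalized synonyms to a canonical
#'   label; `NULL` for no mapping.
#' @return character vector of canonical (or normalized) names.
#' @export
normalize_drug_name <- function(raw, synonyms = NULL) {
  x <- toupper(trimws(raw))
  x <- gsub("[^A-Z0-9 ]+", "", x)
  x <- trimws(gsub(" +", " ", x))
  if (is.null(synonyms)) return(x)
  if (is.data.frame(synonyms))
    synonyms <- stats::setNames(synonyms[[2]], synonyms[[1]])
  names(synonyms) <- normalize_drug_name(names(synonyms))
  mapped <- unname(synonyms[x])
  ifelse(is.na(mapped), x, toupper(mapped))
}

#' Read a two-column delimited mapping file
#'
#' Used for both drug synonym lists (`synonym`, `canonical`) and PT-to-SOC
#' maps (`pt`, `soc`). Delimiter is auto-detected among tab, `$` and comma.
#'
#' @param path file path.
#' @return data.frame with the file's two columns.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl("\\$", first)) "$" else ","
  utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                    quote = "\"", comment.char = "", stringsAsFactors = FALSE)
}

#' Bundled temozolomide synonym list
#' @return data.frame (`synonym`, `canonical`).
#' @export
temozolomide_synonyms <- function() {
  read_mapping(system.file("extdata", "temozolomide_synonyms.tsv",
                           package = "faersdpa"))
}

#' Split cases into target-PS cohort and background
#'
#' A case is in the target cohort iff it has at least one drug with role
#' `PS` whose normalized name equals `target`. The partition is exhaustive
#' and disjoint on case ids.
#'
#' @param cases deduplicated `faers_cases`.
#' @param target canonical target drug label.
#' @param synonyms synonym mapping passed to [normalize_drug_name()].
#' @return list with `target_ids` and `background_ids` (character case ids)
#'   and `is_target`, a named logical over all case ids.
#' @export
select_target_cohort <- function(cases, target, synonyms = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  target <- normalize_drug_name(target, synonyms)
  d <- cases$drugs
  hit <- d$role == "PS" &
    normalize_drug_name(d$drugname_raw, synonyms) == target
  target_ids <- unique(d$caseid[hit])
  all_ids <- unique(cases$reports$caseid)
  target_ids <- intersect(all_ids, target_ids)
  list(target_ids = target_ids,
       background_ids = setdiff(all_ids, target_ids),
       is_target = stats::setNames(all_ids %in% target_ids, all_ids))
}

#' Build drug-event 2x2 contingency tables at PT or SOC level
#'
#' For every observed event label, counts the classic a/b/c/d cells against
#' the rest of the database. With `counting_unit = "event"` (default) the
#' unit is the distinct (case, label) pair: a case reporting the same PT
#' twice contributes once to that PT, and the margins a+b (target) and c+d
#' (background) are the total distinct case-label pairs at the chosen
#' level, identical across labels. With `counting_unit = "case"` the margins
#' are the case totals of each cohort. At SOC level each PT maps to its one
#' primary SOC; by default a case contributing two PTs of one SOC counts
#' twice (pure aggregation, so SOC cells are exact sums of PT cells), or
#' once per case with `soc_within_case_dedup = TRUE`.
#'
#' @param cases deduplicated `faers_cases`.
#' @param cohort partition from [select_target_cohort()].
#' @param level `"PT"` or `"SOC"`.
#' @param pt_soc_map data.frame (`pt`, `soc`); required for SOC level, and
#'   must cover every observed PT.
#' @param counting_unit `"event"` (distinct case-label pairs; default) or
#'   `"case"`.
#' @param soc_within_case_dedup logical; see above.
#' @return data.frame with columns `label`, `a`, `b`, `c`, `d`, `N`,
#'   ordered by decreasing `a`.
#' @export
build_contingency_tables <- function(cases, cohort,
                                     level = c("PT", "SOC"),
                                     pt_soc_map = NULL,
                                     counting_unit = c("event", "case"),
                                     soc_within_case_dedup = FALSE) {
  stopifnot(inherits(cases, "faers_cases"))
  level <- match.arg(level)
  counting_unit <- match.arg(counting_unit)
  ev <- unique(cases$events[, c("caseid", "pt")])

  if (level == "SOC") {
    if (is.null(pt_soc_map))
      stop("pt_soc_map is required at SOC level", call. = FALSE)
    soc <- pt_soc_map$soc[match(ev$pt, pt_soc_map$pt)]
    if (anyNA(soc))
      stop("unmapped PTs for SOC level: ",
           paste(sort(unique(ev$pt[is.na(soc)])), collapse = ", "),
           call. = FALSE)
    ev$label <- soc
    if (soc_within_case_dedup) ev <- unique(ev[, c("caseid", "label")])
  } else {
    ev$label <- ev$pt
  }

  is_target <- ev$caseid %in% cohort$target_ids
  if (counting_unit == "event") {
    margin_t <- sum(is_target)
    margin_b <- sum(!is_target)
  } else {
    margin_t <- length(cohort$target_ids)
    margin_b <- length(cohort$background_ids)
    ev <- unique(ev[, c("caseid", "label")])
    is_target <- ev$caseid %in% cohort$target_ids
  }

  labels <- sort(unique(ev$label))
  a <- as.vector(table(factor(ev$label[is_target], levels = labels)))
  c_ <- as.vector(table(factor(ev$label[!is_target], levels = labels)))
  out <- data.frame(label = labels, a = a, b = margin_t - a, c = c_,
                    d = margin_b - c_, stringsAsFactors = FALSE)
  out$N <- out$a + out$b + out$c + out$d
  out <- out[order(-out$a, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
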