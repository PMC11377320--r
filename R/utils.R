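#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for printed report percentages (base [round()] rounds half-to-even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2) # 0.13 0.14
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon absorbs binary representation error of values like 53.645
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Parse FAERS-style dates
#'
#' FAERS date fields carry 8-digit (yyyymmdd), 6-digit (yyyymm) or 4-digit
#' (yyyy) values. Partial dates resolve to the first day of the period;
#' anything else becomes `NA` and is counted.
#'
#' @param x character vector of raw date strings.
#' @return a `Date` vector with attribute `n_bad`, the number of non-empty
#'   values that failed to parse.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  nc <- nchar(x)
  full <- ifelse(!is.na(x) & nc == 6, paste0(x, "01"),
          ifelse(!is.na(x) & nc == 4, paste0(x, "0101"), x))
  full[!is.na(nc) & !(nc %in% c(4, 6, 8))] <- NA_character_
  out <- as.Date(full, format = "%Y%m%d")
  n_bad <- sum(!is.na(x) & is.na(out))
  attr(out, "n_bad") <- n_bad
  out
}

#' Format a Date as an 8-digit FAERS date string
#' @param d Date vector.
#' @return character vector, `""` for `NA`.
#' @keywords internal
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

# simple named-counter helper used for run logs
new_counter <- function() {
  env <- new.env(parent = emptyenv())
  list(
    add = function(name, n = 1) {
      cur <- if (exists(name, envir = env)) get(name, envir = env) else 0
      assign(name, cur + n, envir = env)
    },
    as_list = function() {
      nm <- sort(ls(env))
      stats::setNames(lapply(nm, get, envir = env), nm)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
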