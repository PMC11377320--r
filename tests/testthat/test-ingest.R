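test_that("fixture DEMO parses to 20 rows with all declared fields", {
  dir <- withr::local_tempdir()
  write_faers(fx$tables, dir)
  raw <- read_faers_quarter(dir)
  expect_equal(nrow(raw$demo), 20)
  expect_true(all(c("primaryid", "caseid", "fda_dt", "sex", "age", "age_cod",
                    "wt", "occr_country", "occp_cod") %in% names(raw$demo)))
  expect_equal(attr(raw, "log")$demo, 20)
})

test_that("a header-only file yields zero rows without error", {
  dir <- withr::local_tempdir()
  write_faers(fx$tables, dir)
  writeLines("primaryid$caseid$pt", file.path(dir, "REAC.txt"))
  raw <- read_faers_quarter(dir)
  expect_equal(nrow(raw$reac), 0)
})

test_that("a missing mandatory column is a format error naming it", {
  dir <- withr::local_tempdir()
  write_faers(fx$tables, dir)
  writeLines(c("primaryid$caseid", "101$1"), file.path(dir, "REAC.txt"))
  expect_error(read_faers_quarter(dir), "reac.*pt")
})

test_that("malformed dates degrade to missing and are counted", {
  tabs <- fx$tables
  tabs$demo$fda_dt[1] <- "2023131" # 7 digits: not a FAERS date style
  cases <- link_cases(tabs)
  expect_equal(sum(cases$reports$caseid == "1"), 1) # row kept
  expect_true(is.na(cases$reports$fda_dt[cases$reports$caseid == "1"]))
  expect_gte(attr(cases, "log")$bad_dates, 1)
  # partial dates resolve to the first day of the period
  d <- parse_faers_date(c("202003", "2020", "20200315"))
  expect_equal(as.Date(as.vector(d)),
               as.Date(c("2020-03-01", "2020-01-01", "2020-03-15")))
})

test_that("deduplication keeps the latest receipt date, ties to largest id", {
  demo <- fx$tables$demo[0, ]
  mk <- function(pid, cid, dt) {
    r <- fx$tables$demo[1, ]
    r$primaryid <- pid; r$caseid <- cid; r$fda_dt <- dt
    r
  }
  tabs <- list(
    demo = rbind(mk("101", "1", "20200101"), mk("102", "1", "20200601"),
                 mk("201", "2", "20200301"), mk("203", "2", "20200301"),
                 mk("202", "2", "20200301")),
    reac = data.frame(primaryid = c("101", "102", "201", "202", "203"),
                      caseid = c("1", "1", "2", "2", "2"),
                      pt = "Nausea", stringsAsFactors = FALSE))
  dd <- deduplicate_cases(link_cases(tabs))
  expect_setequal(dd$reports$primaryid, c(102, 203))
  expect_equal(attr(dd, "log")$duplicates_removed, 3)
})

test_that("deduplication is idempotent and identity on distinct cases", {
  dd1 <- dedup_fixture()
  dd2 <- deduplicate_cases(dd1)
  expect_equal(dd2$reports, dd1$reports)
  expect_equal(dd2$events, dd1$events)
  expect_equal(attr(dd2, "log")$duplicates_removed, 0)
  expect_equal(nrow(dd1$reports), 18)
  expect_equal(attr(dd1, "log")$duplicates_removed, 2)
  # dedup only removes whole reports, never edits fields
  raw <- linked_fixture()
  expect_equal(dd1$reports,
               raw$reports[raw$reports$primaryid %in% dd1$reports$primaryid, ],
               ignore_attr = TRUE)
})

test_that("linking attaches the documented fixture event lists", {
  dd <- dedup_fixture()
  ev <- split(dd$events$pt, dd$events$caseid)
  expect_setequal(ev[["1"]], c("Thrombocytopenia", "Nausea"))
  expect_setequal(ev[["3"]], c("Thrombocytopenia", "Anaemia"))
  expect_equal(ev[["6"]], c("Thrombocytopenia", "Thrombocytopenia"))
  expect_equal(ev[["12"]], "Thrombocytopenia")
  # therapy start and indication land on the PS drug record
  ps <- dd$drugs[dd$drugs$role == "PS" & dd$drugs$caseid == "1", ]
  expect_equal(ps$therapy_start, as.Date("2019-12-31"))
  expect_equal(ps$indication_pt, "Glioma")
})

test_that("reports without reaction rows are dropped with a logged count", {
  tabs <- list(demo = fx$tables$demo)
  cases <- link_cases(tabs)
  expect_equal(nrow(cases$reports), 0)
  expect_equal(attr(cases, "log")$dropped_no_event_reports, 20)
})

test_that("orphan drug/reaction rows (no DEMO key) are dropped and logged", {
  tabs <- fx$tables
  tabs$reac <- rbind(tabs$reac,
                     data.frame(primaryid = "99901", caseid = "999",
                                pt = "Nausea"))
  cases <- link_cases(tabs)
  expect_false("999" %in% cases$events$caseid)
  expect_equal(attr(cases, "log")$orphan_reac_rows, 1)
})

test_that("generate -> write -> read -> link reproduces generator state", {
  cfg <- faers_sim_config(n_cases = 1000, duplicate_fraction = 0.08,
                          seed = 21)
  sim <- generate_faers(cfg)
  dir <- withr::local_tempdir()
  write_faers(sim$tables, dir)
  cases <- deduplicate_cases(link_cases(read_faers_quarter(dir)))
  expect_equal(nrow(cases$reports), 1000)
  got <- lapply(split(cases$events$pt, cases$events$caseid), sort)
  want <- lapply(sim$truth$case_events, sort)
  expect_identical(got[order(as.integer(names(got)))],
                   want[order(as.integer(names(want)))])
})

test_that("age unit codes convert to years as documented", {
  expect_equal(harmonize_age(c("6", "55", "18", "104.28", "730.5", "5", ""),
                             c("DEC", "YR", "MON", "WK", "DY", "HR", "YR")),
               c(60, 55, 1.5, 2, 2, NA, NA))
  expect_true(is.na(harmonize_age("130", "YR"))) # out of range
  expect_true(is.na(harmonize_age("13", "DEC")))
})
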