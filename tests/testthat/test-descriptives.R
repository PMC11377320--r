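test_that("percentages recompute half-up to two decimals", {
  sex <- percentage_table(c(female = 6305, male = 7297))
  expect_equal(sex$percentage, c(46.35, 53.65))
  expect_equal(percentage_table(c(only = 42))$percentage, 100.00)
  expect_equal(round_half_up(c(0.125, 0.135, 28.3047, 1.985), 2),
               c(0.13, 0.14, 28.30, 1.99))
})

test_that("age buckets are left-closed with 60 in the oldest bucket", {
  expect_equal(age_bucket(c(19.9, 20, 39.9, 40, 59.9, 60, 85, NA)),
               c("<20", "20~40", "20~40", "40~60", "40~60", ">=60", ">=60",
                 "unknown"))
})

test_that("categorical summaries count each case once with the right rule", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  sex <- summarize_categorical(dd, "sex", case_ids = coh$target_ids)
  expect_setequal(sex$count, c(4, 4)) # target cases 1-8 split 4 F / 4 M
  expect_equal(sex$percentage, c(50, 50))
  expect_equal(attr(sex, "denominator"), 8)
  age <- summarize_categorical(dd, "age_bucket", case_ids = coh$target_ids)
  expect_equal(age$count[age$category == "unknown"], 1) # case 7
  expect_equal(sum(age$count), 8)
  # outcome counts use the outcome-code total as denominator: case 5
  # carries HO and LT, cases 4 and 7 carry none, so 7 codes over 8 cases
  out <- summarize_categorical(dd, "outcome", case_ids = coh$target_ids)
  expect_equal(sum(out$count), 7)
  expect_equal(attr(out, "denominator"), 7)
  expect_equal(out$count[out$category == "hospitalization"], 4)
  expect_error(summarize_categorical(dd, "shoe_size"), "sex")
})

test_that("annual counts cover the receipt years and log missing dates", {
  dd <- dedup_fixture()
  ann <- annual_counts(dd)
  expect_equal(sum(ann$count), 18)
  # duplicate survivors carry the later receipt dates (cases 2 and 5)
  expect_equal(ann$count[ann$year == 2020], 4)
  expect_equal(ann$count[ann$year == 2021], 3)
  expect_equal(ann$count[ann$year == 2022], 11)
  empty <- annual_counts(dd, case_ids = character(0))
  expect_equal(nrow(empty), 0)
})

test_that("time to onset reproduces the documented fixture lags", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  tto <- time_to_onset(dd, target = "TEMOZOLOMIDE",
                       synonyms = temozolomide_synonyms(),
                       case_ids = coh$target_ids)
  expect_setequal(tto$lags, c(10, 20, 30, 45, 60, 100, 150))
  expect_equal(tto$median, 45)
  expect_equal(tto$q1, 25)
  expect_equal(tto$q3, 80)
  expect_equal(tto$log$included, 8)
  expect_equal(tto$log$known, 7)
  expect_equal(tto$log$missing, 1) # case 4 has no therapy start date
  # percentages over all included reports (8), not only known lags
  b <- tto$bins
  expect_equal(b$count[1:4], c(3, 2, 0, 2))
  expect_equal(b$percentage[1:4], c(37.5, 25, 0, 25))
  k <- time_to_onset(dd, target = "TEMOZOLOMIDE",
                     synonyms = temozolomide_synonyms(),
                     case_ids = coh$target_ids, denominator = "known")
  expect_equal(k$bins$percentage[1], round_half_up(300 / 7, 2))
})

test_that("identical lags collapse median and quartiles", {
  dd <- dedup_fixture()
  dd$reports$event_dt <- dd$reports$fda_dt
  dd$drugs$therapy_start <- dd$reports$fda_dt[
    match(dd$drugs$caseid, dd$reports$caseid)] - 7
  tto <- time_to_onset(dd)
  expect_equal(unique(tto$lags), 7)
  expect_equal(c(tto$q1, tto$median, tto$q3), c(7, 7, 7))
})

test_that("events dated before therapy start are excluded and logged", {
  dd <- dedup_fixture()
  dd$drugs$therapy_start[dd$drugs$caseid == "1"] <- as.Date("2020-06-01")
  tto <- time_to_onset(dd, target = "TEMOZOLOMIDE",
                       synonyms = temozolomide_synonyms(),
                       case_ids = fixture_cohort(dd)$target_ids)
  expect_equal(tto$log$negative, 1)
  expect_false(10 %in% tto$lags)
})

test_that("indication tallies merge synonymous labels", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  merge_map <- c("Glioma" = "glioma", "Glioblastoma multiforme" = "glioma",
                 "Astrocytoma" = "glioma")
  got <- summarize_indications(dd, merge_map, case_ids = coh$target_ids)
  expect_equal(got$count[got$indication == "glioma"], 6)
  expect_equal(got$count[got$indication == "Brain neoplasm"], 1)
  raw <- summarize_indications(dd, NULL, case_ids = coh$target_ids)
  expect_equal(raw$count[raw$indication == "Glioma"], 3)
  expect_equal(sum(raw$count), sum(got$count)) # merging conserves counts
})
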