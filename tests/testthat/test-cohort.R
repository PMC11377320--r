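syn <- temozolomide_synonyms()

test_that("drug-name normalization maps synonyms and is idempotent", {
  expect_equal(normalize_drug_name(" Temodar®", syn), "TEMOZOLOMIDE")
  expect_equal(normalize_drug_name("TEMOZOLOMIDE", syn), "TEMOZOLOMIDE")
  expect_equal(normalize_drug_name("temodal ", syn), "TEMOZOLOMIDE")
  expect_equal(normalize_drug_name("ASPIRIN", syn), "ASPIRIN")
  x <- c(" Temodar®", "ibu-profen", "ASPIRIN")
  expect_equal(normalize_drug_name(normalize_drug_name(x, syn), syn),
               normalize_drug_name(x, syn))
})

test_that("cohort selection follows the primary-suspect role rule", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  expect_setequal(coh$target_ids, as.character(1:8))
  # case 9 lists the target as SS only: background
  expect_true("9" %in% coh$background_ids)
  expect_setequal(c(coh$target_ids, coh$background_ids),
                  unique(dd$reports$caseid))
  expect_length(intersect(coh$target_ids, coh$background_ids), 0)
})

test_that("empty case collections give two empty partitions", {
  dd <- dedup_fixture()
  dd$reports <- dd$reports[0, ]
  dd$drugs <- dd$drugs[0, ]
  coh <- select_target_cohort(dd, "TEMOZOLOMIDE", syn)
  expect_length(coh$target_ids, 0)
  expect_length(coh$background_ids, 0)
})

test_that("fixture contingency tables match the hand counts", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  tab <- build_contingency_tables(dd, coh, "PT")
  thr <- tab[tab$label == "Thrombocytopenia", ]
  expect_equal(thr$a, 6)
  expect_equal(thr$b, 5)
  expect_equal(thr$c, 1)
  expect_equal(thr$d, 11)
  expect_equal(thr$N, 23)
  # margins are identical across labels at a fixed level
  expect_equal(unique(tab$a + tab$b), 11)
  expect_equal(unique(tab$c + tab$d), 12)
})

test_that("within-case duplicate PT rows count once", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  # case 6 lists Thrombocytopenia twice; margin counts it once (6 of a = 6)
  tab <- build_contingency_tables(dd, coh, "PT")
  expect_equal(tab$a[tab$label == "Thrombocytopenia"], 6)
  expect_equal(sum(tab$a), 11) # 12 raw target event rows, 11 distinct pairs
})

test_that("SOC tables are exact aggregations of PT tables", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  pt <- build_contingency_tables(dd, coh, "PT")
  soc <- build_contingency_tables(dd, coh, "SOC", fx$pt_soc_map)
  map <- stats::setNames(fx$pt_soc_map$soc, fx$pt_soc_map$pt)
  for (s in soc$label) {
    members <- names(map)[map == s]
    expect_equal(soc$a[soc$label == s],
                 sum(pt$a[pt$label %in% members]), label = s)
    expect_equal(soc$c[soc$label == s],
                 sum(pt$c[pt$label %in% members]), label = s)
  }
  expect_equal(sum(soc$a), sum(pt$a))
  # within-case SOC dedup collapses case 3's two blood PTs to one
  soc2 <- build_contingency_tables(dd, coh, "SOC", fx$pt_soc_map,
                                   soc_within_case_dedup = TRUE)
  blood <- "Blood and lymphatic system disorders"
  expect_equal(soc$a[soc$label == blood], 7)
  expect_equal(soc2$a[soc2$label == blood], 6)
})

test_that("SOC level with unmapped PTs errors and lists them", {
  dd <- dedup_fixture()
  coh <- fixture_cohort(dd)
  bad_map <- fx$pt_soc_map[fx$pt_soc_map$pt != "Rash", ]
  expect_error(build_contingency_tables(dd, coh, "SOC", bad_map), "Rash")
})

test_that("case- and event-level counting agree for one event per case", {
  cfg <- faers_sim_config(n_cases = 300, background_rate = 0.001,
                          duplicate_fraction = 0, seed = 13)
  sim <- generate_faers(cfg) # nearly every case gets the single fallback PT
  cases <- deduplicate_cases(link_cases(sim$tables))
  one_ev <- names(which(table(unique(cases$events)[, "caseid"]) == 1))
  cases$events <- cases$events[cases$events$caseid %in% one_ev, ]
  cases$reports <- cases$reports[cases$reports$caseid %in% one_ev, ]
  coh <- select_target_cohort(cases, "DRUG01")
  ev <- build_contingency_tables(cases, coh, "PT", counting_unit = "event")
  ca <- build_contingency_tables(cases, coh, "PT", counting_unit = "case")
  expect_equal(ev, ca)
})
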