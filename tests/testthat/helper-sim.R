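# shared fixtures built in code

fx <- fixture_small()

linked_fixture <- function() link_cases(fx$tables)
dedup_fixture <- function() deduplicate_cases(link_cases(fx$tables))

fixture_cohort <- function(cases = dedup_fixture()) {
  select_target_cohort(cases, "TEMOZOLOMIDE", temozolomide_synonyms())
}

# random 2x2 tables with all-positive cells, reproducible
random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, TRUE),
             b = sample.int(10 * max_cell, n, TRUE),
             c = sample.int(10 * max_cell, n, TRUE),
             d = sample.int(100 * max_cell, n, TRUE))
}
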