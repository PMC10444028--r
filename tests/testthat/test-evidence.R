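test_that("screening strings map to verdicts by whole-string match", {
  expect_equal(interpret_screening_value("Reactive"), "positive")
  expect_equal(interpret_screening_value("HIV-1 positive"), "positive")
  expect_equal(interpret_screening_value("  DETECTED "), "positive")
  expect_equal(interpret_screening_value("Not detected"), "negative")
  expect_equal(interpret_screening_value("Nonreactive"), "negative")
  expect_equal(interpret_screening_value(""), "unknown")
  expect_equal(interpret_screening_value("indeterminate"), "unknown")
})

test_that("no string in the negative set ever reads positive, including superstring traps", {
  neg <- default_run_config()$screening$negative
  traps <- c(neg, toupper(neg), paste0("  ", neg, " "))
  expect_true(all(interpret_screening_value(traps) == "negative"))
})

test_that("viral-load scale comes from unit metadata first, then the bounded heuristic", {
  expect_equal(infer_vl_scale(350, "copies/mL"),
               tibble::tibble(scale = "linear", source = "unit_metadata"))
  expect_equal(infer_vl_scale(2.5, "log10 copies/mL")$scale, "log10")
  expect_equal(infer_vl_scale(5.2, "ln copies/mL")$scale, "ln")
  expect_equal(infer_vl_scale(2.5, ""),
               tibble::tibble(scale = "log10", source = "heuristic"))
  expect_equal(infer_vl_scale(350, ""),
               tibble::tibble(scale = "linear", source = "heuristic"))
  expect_equal(infer_vl_scale(-5, "copies/mL"),
               tibble::tibble(scale = "unknown", source = "error"))
  expect_equal(infer_vl_scale(350, "copies/mL", force_scale = "log10")$source,
               "config_override")
})

test_that("detectability is strict > 200 copies/mL on the value's own scale", {
  expect_equal(interpret_viral_load(1000, "linear"), "detectable")
  expect_equal(interpret_viral_load(200, "linear"), "undetectable")
  # oracle: exponentiate, then compare on the linear scale
  expect_equal(10^2.5 > 200, interpret_viral_load(2.5, "log10") == "detectable")
  expect_equal(exp(5.2) > 200, interpret_viral_load(5.2, "ln") == "detectable")
  expect_equal(interpret_viral_load(2.5, "log10"), "detectable")
  expect_equal(interpret_viral_load(5.2, "ln"), "undetectable")
  expect_equal(interpret_viral_load(NA_real_, "linear"), "unknown")
  expect_equal(interpret_viral_load(100, "unknown"), "unknown")
})

test_that("linear and log-transformed values yield the same verdict", {
  withr::with_seed(42, {
    v <- 10^stats::runif(500, -2, 7)
    expect_identical(interpret_viral_load(v, "linear"),
                     interpret_viral_load(log10(v), "log10"))
    expect_identical(interpret_viral_load(v, "linear"),
                     interpret_viral_load(log(v), "ln"))
  })
})

test_that("same-day drug records union into one combo; separate days stay separate", {
  reg <- demo_registry()
  drugs <- dplyr::bind_rows(
    drug_row("A", "emtricitabine", "2020-01-01"),
    drug_row("A", "tenofovir_disoproxil", "2020-01-01"),
    drug_row("B", "emtricitabine", "2020-01-01"),
    drug_row("B", "tenofovir_disoproxil", "2020-01-02"))
  combos <- group_drug_combos(drugs, reg)
  a <- combos[combos$person_id == "A", ]
  expect_equal(nrow(a), 1)
  expect_true(a$is_prep_pair)
  expect_equal(nrow(combos[combos$person_id == "B", ]), 2)
  expect_false(any(combos$is_prep_pair[combos$person_id == "B"]))
})

test_that("fixed-dose products and a tolerance window both form combinations", {
  reg <- demo_registry()
  combos <- group_drug_combos(drug_row("A", "truvada"), reg)
  expect_true(combos$is_prep_pair)
  split <- dplyr::bind_rows(drug_row("A", "emtricitabine", "2020-01-01"),
                            drug_row("A", "tenofovir_disoproxil", "2020-01-03"))
  expect_equal(nrow(group_drug_combos(split, reg, tolerance_days = 0)), 2)
  merged <- group_drug_combos(split, reg, tolerance_days = 3)
  expect_equal(nrow(merged), 1)
  expect_true(merged$is_prep_pair)
})

test_that("drug pattern classification matches the PrEP definition exactly", {
  reg <- demo_registry()
  pattern_of <- function(drugs) {
    classify_drug_pattern(group_drug_combos(drugs, reg))$drug_pattern
  }
  # repeated FTC+TDF pairs are PrEP
  expect_equal(pattern_of(dplyr::bind_rows(
    drug_row("A", "truvada", "2020-01-01"),
    drug_row("A", "truvada", "2020-05-01"))), "PREP_ONLY")
  # a single agent is never PrEP
  expect_equal(pattern_of(drug_row("A", "emtricitabine")), "ART")
  # three ingredients are never PrEP
  expect_equal(pattern_of(drug_row("A", "biktarvy")), "ART")
  # any additional combination disqualifies
  expect_equal(pattern_of(dplyr::bind_rows(
    drug_row("A", "truvada", "2020-01-01"),
    drug_row("A", "darunavir", "2020-02-01"))), "ART")
  # HCV-only regimens are excluded from drug evidence
  expect_equal(pattern_of(drug_row("A", "sofosbuvir")), "HCV_ONLY")
  expect_equal(pattern_of(drug_row("A", "harvoni")), "HCV_ONLY")
  # role-less drugs neither create nor break a pattern
  expect_equal(pattern_of(dplyr::bind_rows(
    drug_row("A", "truvada", "2020-01-01"),
    drug_row("A", "aspirin", "2020-02-01"))), "PREP_ONLY")
})

test_that("pattern classification is order-invariant and PrEP/ART mutually exclusive", {
  reg <- demo_registry()
  withr::with_seed(7, {
    for (i in 1:20) {
      lb <- generate_cohort(cohort_spec(n_persons = 30, seed = i))
      drugs <- lb$bundle$drugs
      p1 <- classify_drug_pattern(group_drug_combos(drugs, reg))
      p2 <- classify_drug_pattern(group_drug_combos(
        drugs[sample(nrow(drugs)), ], reg))
      expect_equal(dplyr::arrange(p1, person_id), dplyr::arrange(p2, person_id))
      expect_lte(max(table(p1$person_id)), 1) # one label per person
    }
  })
})

test_that("suppression requires ART plus undetectable loads on two distinct dates", {
  two_dates <- tibble::tibble(verdict = c("undetectable", "undetectable"),
                              date = as.Date(c("2020-01-01", "2020-06-01")))
  same_date <- tibble::tibble(verdict = c("undetectable", "undetectable"),
                              date = as.Date(c("2020-01-01", "2020-01-01")))
  one <- two_dates[1, ]
  expect_true(detect_suppressed_on_art(two_dates, "ART"))
  expect_false(detect_suppressed_on_art(same_date, "ART"))
  expect_false(detect_suppressed_on_art(one, "ART"))
  expect_false(detect_suppressed_on_art(two_dates, "PREP_ONLY"))
})
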