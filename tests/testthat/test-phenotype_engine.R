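reg <- demo_registry()

profile_of <- function(bundle, pid = "A") {
  p <- build_evidence_profiles(bundle, reg)
  p[p$person_id == pid, ]
}

test_that("evidence profiles summarize each domain correctly", {
  b <- make_bundle("A", conditions = cond_row("A", "86406008"))
  p <- profile_of(b)
  expect_true(p$condition_pos)
  expect_equal(p$survey_status, "missing")
  expect_equal(p$drug_pattern, "NONE")

  b <- make_bundle("A", surveys = survey_row("A", "Infectious Disease Condition: HIV/AIDS"))
  expect_equal(profile_of(b)$survey_status, "positive")

  b <- make_bundle("A",
    drugs = drug_row("A", "biktarvy"),
    measurements = dplyr::bind_rows(
      meas_row("A", "20447-9", vn = 50, unit = "copies/mL", date = "2020-01-01"),
      meas_row("A", "20447-9", vn = 80, unit = "copies/mL", date = "2020-06-01")))
  p <- profile_of(b)
  expect_true(p$suppressed_on_art)
  expect_equal(p$vl_undetectable_count, 2)

  # empty slices give an all-missing profile
  p <- profile_of(make_bundle("A"))
  expect_false(p$condition_pos)
  expect_equal(p$screening_status, "missing")
  expect_false(p$suppressed_on_art)
})

test_that("tier assignment follows the documented examples", {
  prof <- function(...) {
    defaults <- list(person_id = "A", condition_pos = FALSE,
                     survey_status = "missing", screening_status = "missing",
                     vl_detectable_count = 0L, vl_undetectable_count = 0L,
                     drug_pattern = "NONE", suppressed_on_art = FALSE)
    args <- utils::modifyList(defaults, list(...))
    tibble::as_tibble(args)
  }
  a <- assign_phenotype(prof(survey_status = "positive"))
  expect_equal(a$label, "CONFIRMED_PWH")
  expect_equal(a$confirm_basis, "survey")
  expect_equal(a$evidence_sources, "survey")

  a <- assign_phenotype(prof(condition_pos = TRUE))
  expect_equal(a$label, "PROBABLE_PWH")
  expect_equal(a$evidence_sources, "condition")

  a <- assign_phenotype(prof(condition_pos = TRUE, drug_pattern = "ART"))
  expect_equal(a$label, "CONFIRMED_PWH")
  expect_equal(a$confirm_basis, "condition_and_drug")
  expect_equal(a$evidence_sources, "condition+drug")

  a <- assign_phenotype(prof(drug_pattern = "ART"))
  expect_equal(a$label, "PROBABLE_PWH")
  expect_equal(a$evidence_sources, "drug")

  a <- assign_phenotype(prof(drug_pattern = "PREP_ONLY", screening_status = "negative"))
  expect_equal(a$label, "PREP_USER")
  expect_equal(a$evidence_sources, "drug+lab")

  a <- assign_phenotype(prof(drug_pattern = "PREP_ONLY", screening_status = "negative",
                             condition_pos = TRUE))
  expect_equal(a$label, "PROBABLE_PWH")

  expect_equal(assign_phenotype(prof())$label, "NONE")
  expect_equal(assign_phenotype(prof())$evidence_sources, "")
})

test_that("every satisfied confirming clause is recorded in confirm_basis", {
  p <- tibble::tibble(person_id = "A", condition_pos = TRUE,
                      survey_status = "positive", screening_status = "positive",
                      vl_detectable_count = 1L, vl_undetectable_count = 0L,
                      drug_pattern = "ART", suppressed_on_art = FALSE)
  a <- assign_phenotype(p)
  expect_equal(a$confirm_basis, "survey+lab+condition_and_drug")
  expect_equal(a$evidence_sources, "condition+drug+lab+survey")
})

test_that("adding confirming evidence never demotes a confirmed person", {
  profiles <- enumerate_profiles()
  base <- assign_phenotype(profiles)
  upgraded <- profiles
  upgraded$survey_status <- "positive"
  up <- assign_phenotype(upgraded)
  confirmed <- base$label == "CONFIRMED_PWH"
  expect_true(all(up$label[confirmed] == "CONFIRMED_PWH"))
})

test_that("PrEP users never coexist with a positive HIV evidence atom", {
  profiles <- enumerate_profiles()
  a <- assign_phenotype(profiles)
  prep <- a$label == "PREP_USER"
  expect_false(any(profiles$condition_pos[prep]))
  expect_false(any(profiles$survey_status[prep] == "positive"))
  expect_false(any(profiles$screening_status[prep] == "positive"))
  expect_false(any(profiles$vl_detectable_count[prep] > 0))
})

test_that("the HBV flag marks PrEP users with chronic-HBV codes and never relabels", {
  b <- make_bundle(c("A", "B", "C"),
    conditions = dplyr::bind_rows(cond_row("A", "B18.1"),
                                  cond_row("C", "B180"), cond_row("C", "B20")),
    drugs = dplyr::bind_rows(drug_row("A", "truvada"), drug_row("B", "descovy"),
                             drug_row("C", "biktarvy")),
    measurements = dplyr::bind_rows(
      meas_row("A", "75622-1", vs = "Nonreactive"),
      meas_row("B", "75622-1", vs = "Nonreactive")))
  res <- run_cohort(b, reg)
  a <- res$assignments
  expect_equal(a$label[a$person_id == "A"], "PREP_USER")
  expect_true(a$hbv_flag[a$person_id == "A"])
  expect_equal(a$label[a$person_id == "B"], "PREP_USER")
  expect_false(a$hbv_flag[a$person_id == "B"])
  # flag is scoped to PrEP users: the confirmed person with an HBV code is unflagged
  expect_equal(a$label[a$person_id == "C"], "CONFIRMED_PWH")
  expect_false(a$hbv_flag[a$person_id == "C"])
})

test_that("run_cohort is deterministic and invariant to record order", {
  lb <- generate_cohort(cohort_spec(n_persons = 120, seed = 21))
  res1 <- run_cohort(lb$bundle, reg, alias_map = lb$alias_map)
  shuffled <- lb$bundle
  withr::with_seed(1, {
    for (tbl in c("conditions", "drugs", "measurements", "surveys")) {
      shuffled[[tbl]] <- shuffled[[tbl]][sample(nrow(shuffled[[tbl]])), ]
    }
  })
  res2 <- run_cohort(shuffled, reg, alias_map = lb$alias_map)
  expect_identical(res1$assignments, res2$assignments)
  expect_identical(res1$tier_counts, res2$tier_counts)
})

test_that("every person gets exactly one label and tiers partition the PWH total", {
  lb <- generate_cohort(cohort_spec(n_persons = 400, seed = 13))
  res <- run_cohort(lb$bundle, reg, alias_map = lb$alias_map)
  expect_equal(nrow(res$assignments), length(unique(res$assignments$person_id)))
  expect_equal(sum(res$tier_counts), nrow(res$assignments))
  pwh <- sum(res$assignments$label %in% c("CONFIRMED_PWH", "PROBABLE_PWH"))
  expect_equal(pwh, unname(res$tier_counts["CONFIRMED_PWH"] +
                             res$tier_counts["PROBABLE_PWH"]))
})

test_that("edge-case bundle labels, sources and flags are recovered exactly", {
  ec <- generate_edge_cases()
  res <- run_cohort(ec$bundle, reg, alias_map = ec$alias_map)
  cmp <- dplyr::inner_join(ec$truth, res$assignments, by = "person_id",
                           suffix = c(".planted", ".engine"))
  expect_equal(nrow(cmp), nrow(ec$truth))
  expect_equal(cmp$label.engine, cmp$label.planted, info = cmp$note)
  expect_equal(cmp$evidence_sources.engine, cmp$evidence_sources.planted,
               info = cmp$note)
  expect_equal(cmp$hbv_flag.engine, cmp$hbv_flag.planted, info = cmp$note)
})
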