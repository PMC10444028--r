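test_that("the Venn decomposition partitions PWH by exact source subset", {
  a <- tibble::tibble(
    person_id = c("A", "B", "C", "D", "E"),
    label = c("CONFIRMED_PWH", "PROBABLE_PWH", "PROBABLE_PWH", "PREP_USER", "NONE"),
    confirm_basis = c("condition_and_drug", "", "", "", ""),
    evidence_sources = c("condition+drug", "drug", "drug", "drug+lab", ""),
    hbv_flag = FALSE)
  v <- venn_decomposition(a)
  expect_equal(v$n[v$sources == "condition+drug"], 1)
  expect_equal(v$n[v$sources == "drug"], 2)
  expect_equal(sum(v$n), 3) # PrEP and NONE excluded
  expect_equal(nrow(v), 15) # all non-empty subsets reported

  only_survey <- tibble::tibble(person_id = "X", label = "CONFIRMED_PWH",
                                confirm_basis = "survey",
                                evidence_sources = "survey", hbv_flag = FALSE)
  v <- venn_decomposition(only_survey)
  expect_equal(v$n[v$sources == "survey"], 1)
  expect_equal(sum(v$n), 1)

  bad <- only_survey
  bad$evidence_sources <- ""
  expect_error(venn_decomposition(bad), "empty evidence_sources")
})

test_that("small-cell masking suppresses 1..19 and leaves 0 and 20 alone", {
  expect_equal(mask_small_cells(c(0, 1, 19, 20, 500)),
               c("0", "<20", "<20", "20", "500"))
  expect_equal(mask_small_cells(4, threshold = 5), "<5")
  expect_error(mask_small_cells(-1), "non-negative")
})

test_that("category shares reproduce printed cohort percentages with half-up rounding", {
  expect_equal(category_share(3324, 7667), 43.4)
  expect_equal(category_share(2191, 7667), 28.6)
  expect_equal(category_share(608, 7667), 7.9)
  expect_equal(category_share(81, 7667), 1.1)
  expect_equal(category_share(0, 7667), 0)
  # exact .x5 ties round up (banker's rounding would give 2.2 here)
  expect_equal(category_share(9, 400), 2.3)
  expect_error(category_share(1, 0), "positive")
  expect_error(category_share(5, 4), "count must lie")
  # complement property within rounding tolerance
  withr::with_seed(3, {
    t <- sample(50:5000, 50)
    c <- vapply(t, function(tt) sample(0:tt, 1), integer(1))
    s <- category_share(c, t) + category_share(t - c, t)
    expect_true(all(s >= 99.9 & s <= 100.1))
  })
})

test_that("the demographic table matches a hand-computed fixture", {
  persons <- tibble::tibble(
    person_id = sprintf("P%d", 1:10), birth_year = 1980L,
    gender = c(rep("Female", 4), rep("Male", 6)),
    race = "Unknown", ethnicity = "Unknown", marital_status = "Unknown",
    sexual_orientation = "Unknown", education = "Unknown",
    income_band = "Unknown", insurance = "Unknown", disability = "No",
    chronic_conditions = "0")
  assignments <- tibble::tibble(
    person_id = persons$person_id,
    label = c(rep("CONFIRMED_PWH", 5), rep("PROBABLE_PWH", 3), "PREP_USER", "NONE"),
    confirm_basis = "", evidence_sources = "", hbv_flag = FALSE)
  d <- demographic_table(assignments, persons)
  g <- d[d$characteristic == "gender", ]
  # hand computation: PWH total 8 = 5 confirmed (4 F, 1 M) + 3 probable (all M)
  expect_equal(g$n_total[g$level == "Female"], 4)
  expect_equal(g$pct_total[g$level == "Female"], category_share(4, 8))
  expect_equal(g$n_confirmed[g$level == "Male"], 1)
  expect_equal(g$pct_confirmed[g$level == "Male"], 20.0)
  expect_equal(g$n_prep[g$level == "Male"], 1)
  expect_equal(g$pct_prep[g$level == "Male"], 100.0)
  # a tier with a single observed level sits at 100%
  inc <- d[d$characteristic == "income_band", ]
  expect_equal(inc$pct_total, 100.0)
  expect_error(demographic_table(assignments, persons[-1, ]), "missing from persons")
})

test_that("tier comparison matches the closed-form 2x2 chi-square", {
  d <- tibble::tibble(
    characteristic = "gender", level = c("F", "M"),
    n_total = c(40, 40), pct_total = c(50, 50),
    n_confirmed = c(30, 10), pct_confirmed = c(75, 25),
    n_probable = c(10, 30), pct_probable = c(25, 75),
    n_prep = c(0, 0), pct_prep = c(0, 0))
  ct <- compare_tiers(d)
  # closed form: n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 80 * 800^2 / 40^4
  expect_equal(ct$statistic, 80 * (30 * 30 - 10 * 10)^2 / (40 * 40 * 40 * 40))
  expect_equal(ct$df, 1L)
  # identical distributions carry no association
  d2 <- d
  d2$n_probable <- d2$n_confirmed
  expect_equal(compare_tiers(d2)$p_value, 1)
  # degenerate single-level characteristic is skipped, not an error
  d3 <- d[1, ]
  expect_equal(compare_tiers(d3)$note, "skipped: degenerate table")
  expect_true(is.na(compare_tiers(d3)$p_value))
})

test_that("masking is render-only: internal counts reconcile while cells are suppressed", {
  lb <- generate_cohort(cohort_spec(n_persons = 600, seed = 31))
  res <- run_cohort(lb$bundle, demo_registry(), alias_map = lb$alias_map)
  rep <- build_cohort_report(res)
  # internal: every tier's level counts sum to the tier total, unmasked
  for (ch in unique(rep$demographics$characteristic)) {
    d <- rep$demographics[rep$demographics$characteristic == ch, ]
    expect_equal(sum(d$n_confirmed), unname(res$tier_counts["CONFIRMED_PWH"]))
    expect_equal(sum(d$n_prep), unname(res$tier_counts["PREP_USER"]))
  }
  expect_equal(sum(rep$venn$total$n),
               unname(res$tier_counts["CONFIRMED_PWH"] + res$tier_counts["PROBABLE_PWH"]))
  # rendered: no unmasked small cell anywhere
  dir <- withr::local_tempdir()
  write_cohort_report(rep, dir)
  for (f in list.files(dir, full.names = TRUE)) {
    tokens <- unlist(strsplit(paste(readLines(f), collapse = "\t"),
                              "[^0-9A-Za-z.<>+-]+"))
    ints <- suppressWarnings(as.integer(tokens[grepl("^[0-9]+$", tokens)]))
    expect_false(any(ints >= 1 & ints <= 19, na.rm = TRUE), info = f)
  }
})
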