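# Synthetic labeled cohorts ----------------------------------------------------
#
# Generates OMOP-shaped bundles in which every person's records are planted
# to satisfy an intended phenotype label *by construction*: the generator
# realizes classification rules, it does not simulate disease. That choice is
# deliberate — the artifact under test is the classification logic, so ground
# truth must be exact, and any disagreement between planted and recovered
# labels indicts either the engine or the generator, never sampling noise.
# Configurable "messiness" (log-scale viral loads, missing units, duplicate
# ids, HCV/HBV decoys, out-of-window records, sloppy result strings) adds the
# artifacts real extracts carry, designed to be non-confounding.

.tier_names <- c("CONFIRMED_PWH", "PROBABLE_PWH", "PREP_USER", "NONE")

.default_confirmed_composition <- c(
  "condition+drug" = 0.40,
  "condition+drug+lab" = 0.10,
  "condition+drug+survey" = 0.10,
  "condition+drug+lab+survey" = 0.08,
  "survey" = 0.13,
  "lab" = 0.02,
  "drug+lab" = 0.07,
  "lab+survey" = 0.04,
  "condition+lab" = 0.03,
  "condition+survey" = 0.03)

# probable = unconfirmed EHR evidence; roughly 1:2 condition-only to
# drug-only, the split seen in real tiered HIV cohorts
.default_probable_composition <- c("condition" = 0.312, "drug" = 0.688)

.subset_confirms <- function(key) {
  s <- strsplit(key, "+", fixed = TRUE)[[1]]
  ("survey" %in% s) || ("lab" %in% s) ||
    (all(c("condition", "drug") %in% s))
}

#' Specify a synthetic cohort
#'
#' @param n_persons Cohort size.
#' @param tier_mix Named proportions over the four labels (must sum to 1).
#'   The default is an enriched test cohort: PWH split roughly 60/40
#'   confirmed/probable, PrEP users about 7% of the PWH count, remainder
#'   unaffected.
#' @param confirmed_composition Named proportions over evidence-source
#'   subsets for confirmed persons; every subset must contain a confirming
#'   clause (survey, lab, or condition+drug).
#' @param probable_composition Proportions over `"condition"` / `"drug"`
#'   (the only subsets that are probable-consistent).
#' @param messiness Named rates in `[0, 1]`: `log_scale_vl` (viral loads
#'   recorded on the log10 scale), `missing_units` (unit text absent, scale
#'   left to the heuristic), `messy_strings` (case/whitespace noise in
#'   result strings), `duplicate_ids` (persons split across two ids),
#'   `hcv_decoys` (HCV-only regimens added to ART persons),
#'   `hbv_decoys` (chronic-HBV codes added to PrEP/none persons),
#'   `out_of_window` (HIV evidence dated outside the study windows).
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_persons = 1000,
                        tier_mix = c(CONFIRMED_PWH = 0.25, PROBABLE_PWH = 0.17,
                                     PREP_USER = 0.03, NONE = 0.55),
                        confirmed_composition = .default_confirmed_composition,
                        probable_composition = .default_probable_composition,
                        messiness = list(log_scale_vl = 0.3, missing_units = 0.2,
                                         messy_strings = 0.3, duplicate_ids = 0.02,
                                         hcv_decoys = 0.05, hbv_decoys = 0.03,
                                         out_of_window = 0.05),
                        seed = 1L) {
  stopifnot(n_persons >= 0, is.numeric(tier_mix))
  if (!setequal(names(tier_mix), .tier_names)) {
    stop("tier_mix must name exactly the four labels", call. = FALSE)
  }
  if (abs(sum(tier_mix) - 1) > 1e-8 || any(tier_mix < 0)) {
    stop("tier_mix proportions must be non-negative and sum to 1", call. = FALSE)
  }
  bad <- names(confirmed_composition)[!vapply(names(confirmed_composition),
                                              .subset_confirms, logical(1))]
  if (length(bad) > 0) {
    stop("infeasible confirmed evidence subset(s) (no confirming clause): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(names(probable_composition) %in% c("condition", "drug"))) {
    stop("probable subsets must be 'condition' or 'drug' alone; anything more is confirming or impossible",
         call. = FALSE)
  }
  rates <- unlist(messiness)
  if (any(rates < 0 | rates > 1)) stop("messiness rates must lie in [0, 1]", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons),
                 tier_mix = tier_mix[.tier_names],
                 confirmed_composition = confirmed_composition / sum(confirmed_composition),
                 probable_composition = probable_composition / sum(probable_composition),
                 messiness = messiness, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Largest-remainder apportionment: integer counts per tier, summing to n.
.apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.samp1 <- function(x) x[[sample.int(length(x), 1)]]

.rand_date <- function(start, end) {
  s <- as.Date(start)
  s + (sample.int(as.integer(as.Date(end) - s) + 1L, 1L) - 1L)
}

.messy <- function(s, rate) {
  if (stats::runif(1) >= rate) return(s)
  switch(sample.int(3, 1),
         paste0("  ", s, " "),
         toupper(s),
         tolower(s))
}

# Demographic margins loosely shaped like a US HIV-enriched research cohort;
# they exist only to exercise the reporting layer.
.sample_demographics <- function(n) {
  pick <- function(levels, probs) sample(levels, n, replace = TRUE, prob = probs)
  tibble::tibble(
    birth_year = sample(1935:2003, n, replace = TRUE),
    gender = pick(c("Female", "Male", "Other/skipped"), c(0.35, 0.60, 0.05)),
    race = pick(c("Black or African American", "White", "Asian/other/unknown"),
                c(0.41, 0.38, 0.21)),
    ethnicity = pick(c("Hispanic or Latino", "Not Hispanic or Latino", "Unknown"),
                     c(0.15, 0.81, 0.04)),
    marital_status = pick(c("Divorced/separated/widowed", "Married/living with partner",
                            "Never married", "Unknown"), c(0.23, 0.32, 0.40, 0.05)),
    sexual_orientation = pick(c("Straight", "Gay", "Bisexual", "Lesbian", "None",
                                "Prefer not to answer or skipped"),
                              c(0.56, 0.29, 0.07, 0.01, 0.02, 0.05)),
    education = pick(c("High school degree or more", "Less than a high school degree",
                       "Unknown"), c(0.92, 0.035, 0.045)),
    income_band = pick(c("Greater than 35 000 US dollars", "Less than 35 000 US dollars",
                         "Unknown"), c(0.30, 0.50, 0.20)),
    insurance = pick(c("Yes", "No", "Unknown"), c(0.91, 0.05, 0.04)),
    disability = pick(c("Yes", "No"), c(0.125, 0.875)),
    # digit-free level labels so rendered tables stay scannable for
    # unmasked small integers
    chronic_conditions = pick(c("None", "One", "Two or more"), c(0.62, 0.21, 0.17))
  )
}

#' Generate a labeled synthetic cohort
#'
#' Produces an [omop_bundle()] whose records realize each person's intended
#' label and evidence-source subset exactly, plus the ground-truth table and
#' (when duplicate-id messiness is on) the alias map the pipeline needs to
#' consolidate them.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `labeled_bundle`: list with `bundle`
#'   (`omop_bundle`), `truth` (tibble `person_id, label, evidence_sources`,
#'   keyed by canonical id), `alias_map`, and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(spec) {
  n <- spec$n_persons
  m <- spec$messiness
  cfg <- default_run_config()
  ehr_lo <- "2000-01-01"; ehr_hi <- "2022-06-30"
  svy_lo <- "2018-10-01"; svy_hi <- "2022-06-30"

  counts <- .apportion(n, spec$tier_mix)
  labels <- rep(.tier_names, counts)
  ids <- sprintf("P%06d", seq_len(n))

  conditions <- list(); drugs <- list(); measurements <- list(); surveys <- list()
  add_condition <- function(pid, code, date) {
    conditions[[length(conditions) + 1]] <<- list(person_id = pid, concept_id = code,
                                                  source_code = code, date = date)
  }
  add_drug <- function(pid, code, date) {
    drugs[[length(drugs) + 1]] <<- list(person_id = pid, drug_code = code, date = date)
  }
  add_meas <- function(pid, concept, vs, vn, unit, date) {
    measurements[[length(measurements) + 1]] <<- list(
      person_id = pid, concept_id = concept, value_string = vs,
      value_number = vn, unit = unit, date = date)
  }
  add_survey <- function(pid, answer, date) {
    surveys[[length(surveys) + 1]] <<- list(person_id = pid,
                                            question_concept_id = "1384391",
                                            answer_value = answer, date = date)
  }

  hiv_codes <- c("B20", "Z21", "86406008")
  screen_concepts <- c("75622-1", "7918-6")
  vl_concepts <- c("20447-9", "10351-5")
  pos_strings <- c("Detected", "HIV-1 positive", "Positive", "Reactive",
                   "Abnormal", "High")
  neg_strings <- c("Not detected", "Nonreactive", "Negative")
  art_products <- c("dolutegravir", "darunavir", "biktarvy", "atripla")
  prep_products <- c("truvada", "descovy")
  hcv_products <- c("sofosbuvir", "harvoni", "mavyret")

  plant_condition <- function(pid) {
    for (k in seq_len(.samp1(1:2))) {
      add_condition(pid, .samp1(hiv_codes), .rand_date(ehr_lo, ehr_hi))
    }
  }
  plant_art <- function(pid) {
    for (k in seq_len(.samp1(1:3))) {
      d <- .rand_date(ehr_lo, ehr_hi)
      if (stats::runif(1) < 0.3) { # split prescription, same-day two agents
        add_drug(pid, "emtricitabine", d)
        add_drug(pid, "dolutegravir", d)
      } else {
        add_drug(pid, .samp1(art_products), d)
      }
    }
  }
  plant_prep <- function(pid) {
    prod <- .samp1(prep_products)
    for (k in seq_len(.samp1(1:2))) {
      d <- .rand_date(ehr_lo, ehr_hi)
      if (stats::runif(1) < 0.3) { # split FTC + tenofovir rows, same day
        add_drug(pid, "emtricitabine", d)
        add_drug(pid, if (prod == "truvada") "tenofovir_disoproxil"
                 else "tenofovir_alafenamide", d)
      } else {
        add_drug(pid, prod, d)
      }
    }
  }
  plant_vl <- function(pid, detectable, date = .rand_date(ehr_lo, ehr_hi)) {
    log_scale <- stats::runif(1) < m$log_scale_vl
    no_unit <- stats::runif(1) < m$missing_units
    if (log_scale) {
      v <- round(if (detectable) stats::runif(1, 2.40, 6.0)
                 else stats::runif(1, 0.7, 2.25), 2)
      unit <- if (no_unit) "" else "log10 copies/mL"
    } else {
      v <- if (detectable) round(10^stats::runif(1, log10(250), 6))
           else .samp1(21:195) # >= 21 so a missing unit still reads linear
      unit <- if (no_unit) "" else "copies/mL"
    }
    add_meas(pid, .samp1(vl_concepts), "", v, unit, date)
  }
  plant_screen <- function(pid, positive) {
    s <- .messy(.samp1(if (positive) pos_strings else neg_strings), m$messy_strings)
    add_meas(pid, .samp1(screen_concepts), s, NA_real_, "",
             .rand_date(ehr_lo, ehr_hi))
  }
  plant_lab_positive <- function(pid, with_art) {
    mode <- if (with_art) .samp1(c("vl", "screen", "suppression")) else
      .samp1(c("vl", "screen"))
    if (mode == "suppression") {
      # suppression needs undetectable loads on distinct dates: sample the
      # dates without replacement so duplicate draws can never collapse them
      k <- .samp1(2:3)
      offsets <- sample.int(as.integer(as.Date(ehr_hi) - as.Date(ehr_lo)) + 1L, k)
      for (d in as.Date(ehr_lo) + offsets - 1L) {
        plant_vl(pid, detectable = FALSE, date = as.Date(d, origin = "1970-01-01"))
      }
    } else if (mode == "vl") {
      plant_vl(pid, detectable = TRUE)
    } else {
      plant_screen(pid, positive = TRUE)
    }
  }
  plant_survey_positive <- function(pid) {
    add_survey(pid, .messy("Infectious Disease Condition: HIV/AIDS", m$messy_strings),
               .rand_date(svy_lo, svy_hi))
  }

  truth_sources <- character(n)
  conf_keys <- names(spec$confirmed_composition)
  prob_keys <- names(spec$probable_composition)

  for (i in seq_len(n)) {
    pid <- ids[i]
    lab <- labels[i]
    if (lab == "CONFIRMED_PWH") {
      key <- sample(conf_keys, 1, prob = spec$confirmed_composition)
      s <- strsplit(key, "+", fixed = TRUE)[[1]]
      if ("condition" %in% s) plant_condition(pid)
      if ("drug" %in% s) plant_art(pid)
      if ("lab" %in% s) plant_lab_positive(pid, with_art = "drug" %in% s)
      if ("survey" %in% s) plant_survey_positive(pid)
      truth_sources[i] <- key
    } else if (lab == "PROBABLE_PWH") {
      key <- sample(prob_keys, 1, prob = spec$probable_composition)
      if (key == "condition") plant_condition(pid) else plant_art(pid)
      truth_sources[i] <- key
    } else if (lab == "PREP_USER") {
      plant_prep(pid)
      plant_screen(pid, positive = FALSE)
      truth_sources[i] <- "drug+lab"
    } else {
      truth_sources[i] <- ""
      # some unaffected persons carry decoy evidence that must not classify
      if (stats::runif(1) < m$hcv_decoys) {
        add_drug(pid, .samp1(hcv_products), .rand_date(ehr_lo, ehr_hi))
      }
      if (stats::runif(1) < m$hbv_decoys) {
        add_condition(pid, .samp1(c("B180", "B181", "B191")),
                      .rand_date(ehr_lo, ehr_hi))
      }
      if (stats::runif(1) < 0.2) add_survey(pid, "None of these",
                                            .rand_date(svy_lo, svy_hi))
    }
    # decoys that are label-invariant for affected persons
    if (lab %in% c("CONFIRMED_PWH", "PROBABLE_PWH") &&
        grepl("drug", truth_sources[i]) && stats::runif(1) < m$hcv_decoys) {
      add_drug(pid, .samp1(hcv_products), .rand_date(ehr_lo, ehr_hi))
    }
    if (lab == "PREP_USER" && stats::runif(1) < m$hbv_decoys) {
      add_condition(pid, .samp1(c("B180", "B181", "B191")),
                    .rand_date(ehr_lo, ehr_hi))
    }
    if (stats::runif(1) < m$out_of_window) {
      # HIV evidence dated outside the windows: filtered before classification
      if (stats::runif(1) < 0.5) {
        add_condition(pid, "B20", as.Date("1980-06-15"))
      } else {
        add_survey(pid, "Infectious Disease Condition: HIV/AIDS",
                   as.Date("2018-09-15"))
      }
    }
  }

  to_tibble <- function(rows) {
    if (length(rows) == 0) return(NULL)
    dplyr::bind_rows(rows)
  }
  empty <- list(
    conditions = tibble::tibble(person_id = character(0), concept_id = character(0),
                                source_code = character(0), date = as.Date(character(0))),
    drugs = tibble::tibble(person_id = character(0), drug_code = character(0),
                           date = as.Date(character(0))),
    measurements = tibble::tibble(person_id = character(0), concept_id = character(0),
                                  value_string = character(0), value_number = numeric(0),
                                  unit = character(0), date = as.Date(character(0))),
    surveys = tibble::tibble(person_id = character(0), question_concept_id = character(0),
                             answer_value = character(0), date = as.Date(character(0))))
  cond_tbl <- to_tibble(conditions) %||% empty$conditions
  drug_tbl <- to_tibble(drugs) %||% empty$drugs
  meas_tbl <- to_tibble(measurements) %||% empty$measurements
  svy_tbl <- to_tibble(surveys) %||% empty$surveys

  persons <- dplyr::bind_cols(tibble::tibble(person_id = ids),
                              .sample_demographics(n))

  # duplicate-id messiness: split a person's records across two ids
  alias_map <- character(0)
  dup_ids <- ids[stats::runif(n) < m$duplicate_ids]
  if (length(dup_ids) > 0) {
    alias_ids <- paste0(dup_ids, "D")
    alias_map <- stats::setNames(dup_ids, alias_ids)
    alias_rows <- persons[match(dup_ids, persons$person_id), ]
    alias_rows$person_id <- alias_ids
    persons <- dplyr::bind_rows(persons, alias_rows)
    reassign <- function(tbl) {
      idx <- which(tbl$person_id %in% dup_ids)
      if (length(idx) == 0) return(tbl)
      move <- idx[stats::runif(length(idx)) < 0.5]
      tbl$person_id[move] <- paste0(tbl$person_id[move], "D")
      tbl
    }
    cond_tbl <- reassign(cond_tbl); drug_tbl <- reassign(drug_tbl)
    meas_tbl <- reassign(meas_tbl); svy_tbl <- reassign(svy_tbl)
  }

  bundle <- omop_bundle(persons, cond_tbl, drug_tbl, meas_tbl, svy_tbl,
                        provenance = list(source = "synthetic"))
  structure(list(
    bundle = bundle,
    truth = tibble::tibble(person_id = ids, label = labels,
                           evidence_sources = truth_sources),
    alias_map = alias_map,
    spec = spec), class = "labeled_bundle")
}

#' @export
print.labeled_bundle <- function(x, ...) {
  cat("<labeled_bundle>", nrow(x$truth), "persons,",
      length(x$alias_map), "aliased ids\n")
  print(table(x$truth$label))
  invisible(x)
}

#' Deterministic edge-case bundle
#'
#' One hand-built person per boundary of the classification rules: the
#' viral-load threshold hit exactly on the linear and log10 scales, a barely
#' detectable load, single-drug and three-drug regimens, a PrEP pair broken
#' by an extra combination, a survey-positive PrEP candidate, a PrEP pair
#' with no negative screen, virologic suppression with one vs two
#' undetectable loads, an HCV-only regimen, an HBV-coded PrEP user, a
#' "Not detected" screening trap, a duplicate-id pair, and an
#' out-of-window diagnosis. No randomness.
#'
#' @return A `labeled_bundle` whose `truth` also carries `note` and
#'   `hbv_flag` columns.
#' @export
generate_edge_cases <- function() {
  d0 <- as.Date("2020-06-01"); d1 <- as.Date("2021-03-15")
  sv <- as.Date("2020-11-01")
  rows <- list()
  truth <- list()
  conditions <- list(); drugs <- list(); measurements <- list(); surveys <- list()
  cnd <- function(pid, code, date = d0) conditions[[length(conditions) + 1]] <<-
    tibble::tibble(person_id = pid, concept_id = code, source_code = code, date = date)
  drg <- function(pid, code, date = d0) drugs[[length(drugs) + 1]] <<-
    tibble::tibble(person_id = pid, drug_code = code, date = date)
  mea <- function(pid, vs, vn, unit, concept = "20447-9", date = d0)
    measurements[[length(measurements) + 1]] <<-
      tibble::tibble(person_id = pid, concept_id = concept, value_string = vs,
                     value_number = vn, unit = unit, date = date)
  svy <- function(pid, ans, date = sv) surveys[[length(surveys) + 1]] <<-
    tibble::tibble(person_id = pid, question_concept_id = "1384391",
                   answer_value = ans, date = date)
  tru <- function(pid, label, sources, note, hbv = FALSE) truth[[length(truth) + 1]] <<-
    tibble::tibble(person_id = pid, label = label, evidence_sources = sources,
                   note = note, hbv_flag = hbv)

  # viral-load boundaries
  mea("E01", "", 200, "copies/mL")
  tru("E01", "NONE", "", "VL exactly 200 copies/mL is undetectable (strict >)")
  mea("E02", "", round(log10(200), 4), "log10 copies/mL")
  tru("E02", "NONE", "", "VL exactly log10(200) is undetectable")
  mea("E03", "", 201, "copies/mL")
  tru("E03", "CONFIRMED_PWH", "lab", "VL 201 copies/mL just over threshold")
  mea("E04", "", 2.5, "") # unit-less low value -> log10 heuristic, 10^2.5 > 200
  tru("E04", "CONFIRMED_PWH", "lab", "unit-less 2.5 read as log10 via heuristic")
  # drug-pattern boundaries
  drg("E05", "emtricitabine")
  tru("E05", "PROBABLE_PWH", "drug", "single agent is ART evidence, never PrEP")
  drg("E06", "biktarvy")
  tru("E06", "PROBABLE_PWH", "drug", "three-ingredient regimen is ART, not PrEP")
  drg("E07", "truvada"); drg("E07", "darunavir", d1)
  tru("E07", "PROBABLE_PWH", "drug", "PrEP pair plus another combination is ART")
  drg("E08", "truvada"); mea("E08", "Nonreactive", NA_real_, "", "75622-1")
  tru("E08", "PREP_USER", "drug+lab", "FTC+TDF only with negative screen")
  drg("E09", "descovy"); mea("E09", "Not detected", NA_real_, "", "75622-1")
  tru("E09", "PREP_USER", "drug+lab",
      "'Not detected' must match the negative set, not the 'detected' rule")
  drg("E10", "truvada"); mea("E10", "Nonreactive", NA_real_, "", "75622-1")
  svy("E10", "Infectious Disease Condition: HIV/AIDS")
  tru("E10", "CONFIRMED_PWH", "survey",
      "positive self-report vetoes PrEP (PrEP drugs and a negative screen are not positive evidence)")
  drg("E11", "truvada"); cnd("E11", "B20")
  mea("E11", "Nonreactive", NA_real_, "", "75622-1")
  tru("E11", "PROBABLE_PWH", "condition",
      "diagnosis code routes a PrEP candidate to probable")
  drg("E12", "truvada")
  tru("E12", "NONE", "", "PrEP pair without a negative screen is unlabeled")
  # suppression rule
  drg("E13", "biktarvy")
  mea("E13", "", 50, "copies/mL", date = d0); mea("E13", "", 60, "copies/mL", date = d1)
  tru("E13", "CONFIRMED_PWH", "drug+lab",
      "ART with undetectable loads on two distinct dates")
  drg("E14", "biktarvy"); mea("E14", "", 50, "copies/mL")
  tru("E14", "PROBABLE_PWH", "drug", "one undetectable load does not confirm")
  # exclusions and flags
  drg("E15", "sofosbuvir"); drg("E15", "harvoni", d1)
  tru("E15", "NONE", "", "HCV-only regimens are excluded from drug evidence")
  drg("E16", "truvada"); mea("E16", "Nonreactive", NA_real_, "", "75622-1")
  cnd("E16", "B181")
  tru("E16", "PREP_USER", "drug+lab",
      "chronic-HBV code flags but does not relabel a PrEP user", hbv = TRUE)
  cnd("E17", "B20"); cnd("E17", "B180"); drg("E17", "biktarvy")
  tru("E17", "CONFIRMED_PWH", "condition+drug",
      "HBV flag applies to PrEP users only")
  # cross-domain basics
  svy("E18", "Infectious Disease Condition: HIV/AIDS")
  tru("E18", "CONFIRMED_PWH", "survey", "survey-only confirmation")
  cnd("E19", "Z21")
  tru("E19", "PROBABLE_PWH", "condition", "condition-only is probable")
  cnd("E20", "B20", as.Date("1980-12-31"))
  tru("E20", "NONE", "", "diagnosis outside the EHR window is filtered")
  # duplicate-id pair: condition under canonical id, ART under alias
  cnd("E21", "B20"); drg("E21D", "biktarvy")
  tru("E21", "CONFIRMED_PWH", "condition+drug",
      "alias records merge before classification")

  truth_tbl <- dplyr::bind_rows(truth)
  ids <- c(truth_tbl$person_id, "E21D")
  persons <- dplyr::bind_cols(
    tibble::tibble(person_id = ids),
    .with_seed(99L, .sample_demographics(length(ids))))
  bundle <- omop_bundle(persons,
                        dplyr::bind_rows(conditions),
                        dplyr::bind_rows(drugs),
                        dplyr::bind_rows(measurements),
                        dplyr::bind_rows(surveys),
                        provenance = list(source = "edge-cases"))
  structure(list(bundle = bundle, truth = truth_tbl,
                 alias_map = c(E21D = "E21"), spec = NULL),
            class = "labeled_bundle")
}

#' Write a labeled bundle to an OMOP-shaped directory
#'
#' Emits the five OMOP CSVs plus `truth.csv` and (when duplicate ids were
#' generated) `aliases.csv`. The directory round-trips through
#' [read_omop_dir()].
#'
#' @param labeled A `labeled_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_labeled_bundle <- function(labeled, dir) {
  stopifnot(inherits(labeled, "labeled_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- default_schema()$files
  b <- labeled$bundle
  readr::write_csv(b$persons, file.path(dir, files[["persons"]]))
  readr::write_csv(b$conditions, file.path(dir, files[["conditions"]]))
  readr::write_csv(b$drugs, file.path(dir, files[["drugs"]]))
  readr::write_csv(b$measurements, file.path(dir, files[["measurements"]]))
  readr::write_csv(b$surveys, file.path(dir, files[["surveys"]]))
  readr::write_csv(labeled$truth, file.path(dir, "truth.csv"))
  if (length(labeled$alias_map) > 0) {
    readr::write_csv(tibble::tibble(alias = names(labeled$alias_map),
                                    canonical = unname(labeled$alias_map)),
                     file.path(dir, "aliases.csv"))
  }
  invisible(dir)
}
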