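# Phenotype assignment ---------------------------------------------------------
#
# Per-person evidence from the four domains (conditions, drugs, labs, survey)
# is aggregated into an evidence profile and mapped to one of four labels:
#
#   CONFIRMED_PWH  — a positive self-report, a confirming lab result
#                    (positive screen, detectable viral load, or virologic
#                    suppression on ART), or an HIV diagnosis code together
#                    with non-PrEP antiretroviral exposure;
#   PROBABLE_PWH   — unconfirmed EHR evidence: a diagnosis code or ART
#                    exposure alone;
#   PREP_USER      — exclusively FTC+TDF / FTC+TAF two-drug exposure with a
#                    negative HIV screen and no HIV evidence anywhere else;
#   NONE           — no HIV-relevant evidence.
#
# Precedence is fixed: CONFIRMED > PROBABLE > PREP_USER > NONE.

#' Build per-person evidence profiles
#'
#' Scans a filtered, consolidated bundle once per domain and summarises, for
#' every person in the persons table:
#' * `condition_pos` — any condition whose source code or concept id holds
#'   the `hiv_condition` role;
#' * `screening_status` — `"positive"` if any screening row is positive,
#'   else `"negative"` if any explicit negative exists, else `"missing"`;
#' * `vl_detectable_count` / `vl_undetectable_count` — distinct result dates
#'   by viral-load verdict;
#' * `survey_status` — response to the HIV survey item (`"positive"`,
#'   `"negative"`, `"missing"`);
#' * `drug_pattern` — [classify_drug_pattern()] over same-day ingredient
#'   combos;
#' * `suppressed_on_art` — on ART with undetectable viral loads on >= 2
#'   distinct dates.
#'
#' Persons with no records in a domain get the neutral value for it; the
#' function is total over empty bundles.
#'
#' @param bundle A filtered, consolidated `omop_bundle`.
#' @param registry A `concept_registry`.
#' @param config Run config, see [default_run_config()].
#' @return Tibble with one row per person.
#' @export
build_evidence_profiles <- function(bundle, registry, config = default_run_config()) {
  stopifnot(inherits(bundle, "omop_bundle"))
  persons <- bundle$persons["person_id"]

  hiv_cond_ids <- unique(bundle$conditions$person_id[
    codes_in_role(bundle$conditions$source_code, registry, "hiv_condition") |
      codes_in_role(bundle$conditions$concept_id, registry, "hiv_condition")])

  labs <- interpret_measurements(bundle$measurements, registry, config)
  screen <- labs[labs$kind == "screening", ] %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::summarise(
      screening_status = dplyr::case_when(
        any(.data$verdict == "positive") ~ "positive",
        any(.data$verdict == "negative") ~ "negative",
        TRUE ~ "missing"),
      .groups = "drop")
  vl <- labs[labs$kind == "viral_load", ] %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::summarise(
      vl_detectable_count = dplyr::n_distinct(.data$date[.data$verdict == "detectable"]),
      vl_undetectable_count = dplyr::n_distinct(.data$date[.data$verdict == "undetectable"]),
      .groups = "drop")

  svy_rows <- bundle$surveys[
    codes_in_role(bundle$surveys$question_concept_id, registry, "survey_hiv_question"), ]
  ans <- normalize_text(svy_rows$answer_value)
  svy_rows$.pos <- ans %in% registry$roles$survey_hiv_positive_answers
  svy_rows$.neg <- ans %in% registry$roles$survey_hiv_negative_answers
  survey <- svy_rows %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::summarise(
      survey_status = dplyr::case_when(
        any(.data$.pos) ~ "positive",
        any(.data$.neg) ~ "negative",
        TRUE ~ "missing"),
      .groups = "drop")

  combos <- group_drug_combos(bundle$drugs, registry, config$combo_tolerance_days)
  patterns <- classify_drug_pattern(combos)

  persons %>%
    dplyr::mutate(condition_pos = .data$person_id %in% hiv_cond_ids) %>%
    dplyr::left_join(survey, by = "person_id") %>%
    dplyr::left_join(screen, by = "person_id") %>%
    dplyr::left_join(vl, by = "person_id") %>%
    dplyr::left_join(patterns, by = "person_id") %>%
    dplyr::mutate(
      survey_status = dplyr::coalesce(.data$survey_status, "missing"),
      screening_status = dplyr::coalesce(.data$screening_status, "missing"),
      vl_detectable_count = dplyr::coalesce(.data$vl_detectable_count, 0L),
      vl_undetectable_count = dplyr::coalesce(.data$vl_undetectable_count, 0L),
      drug_pattern = dplyr::coalesce(.data$drug_pattern, "NONE"),
      suppressed_on_art = .data$drug_pattern == "ART" &
        .data$vl_undetectable_count >= 2
    )
}

#' Assign phenotype labels from evidence profiles
#'
#' Pure, total, vectorized tier assignment:
#'
#' 1. **CONFIRMED_PWH** if any confirming clause holds —
#'    `survey`: positive self-report; `lab`: positive screen, detectable
#'    viral load, or suppression on ART; `condition_and_drug`: diagnosis
#'    code plus non-PrEP ART exposure. Every satisfied clause is recorded in
#'    `confirm_basis`.
#' 2. else **PROBABLE_PWH** if a diagnosis code or ART exposure exists
#'    (EHR evidence without confirmation).
#' 3. else **PREP_USER** if the drug pattern is exclusively the PrEP pairs,
#'    the screening status is explicitly negative, and neither diagnosis
#'    codes nor a positive self-report exist (a positive survey answer
#'    vetoes PrEP).
#' 4. else **NONE**.
#'
#' `evidence_sources` records the domains contributing to the assignment
#' (for PWH: each domain with positive evidence; for PrEP users: the drug
#' pattern plus the negative lab), as a sorted `+`-joined key such as
#' `"condition+drug"`.
#'
#' @param profiles Tibble from [build_evidence_profiles()] (any number of
#'   rows, including one).
#' @return Tibble `person_id, label, confirm_basis, evidence_sources,
#'   hbv_flag` (the flag is initialized `FALSE`; see
#'   [hbv_flag_prep_users()]).
#' @export
assign_phenotype <- function(profiles) {
  p <- tibble::as_tibble(profiles)
  basis_survey <- p$survey_status == "positive"
  basis_lab <- p$screening_status == "positive" |
    p$vl_detectable_count >= 1 |
    p$suppressed_on_art
  basis_cond_drug <- p$condition_pos & p$drug_pattern == "ART"

  confirmed <- basis_survey | basis_lab | basis_cond_drug
  probable <- !confirmed & (p$condition_pos | p$drug_pattern == "ART")
  prep <- !confirmed & !probable &
    p$drug_pattern == "PREP_ONLY" &
    p$screening_status == "negative" &
    !p$condition_pos &
    p$survey_status != "positive"

  label <- dplyr::case_when(
    confirmed ~ "CONFIRMED_PWH",
    probable ~ "PROBABLE_PWH",
    prep ~ "PREP_USER",
    TRUE ~ "NONE"
  )

  n <- nrow(p)
  basis <- character(n)
  sources <- character(n)
  for (i in seq_len(n)) {
    b <- c("survey", "lab", "condition_and_drug")[
      c(basis_survey[i], basis_lab[i], basis_cond_drug[i])]
    basis[i] <- if (confirmed[i]) paste(b, collapse = "+") else ""
    src <- switch(label[i],
      CONFIRMED_PWH = ,
      PROBABLE_PWH = c("condition", "drug", "lab", "survey")[
        c(p$condition_pos[i], p$drug_pattern[i] == "ART",
          basis_lab[i], basis_survey[i])],
      PREP_USER = c("drug", "lab"),
      character(0))
    sources[i] <- sources_key(src)
  }
  tibble::tibble(person_id = p$person_id, label = label,
                 confirm_basis = basis, evidence_sources = sources,
                 hbv_flag = FALSE)
}

#' Flag PrEP users carrying chronic hepatitis B codes
#'
#' Diagnostic check for PrEP misclassification: FTC/TDF regimens also treat
#' HBV, so PrEP users with a chronic-HBV diagnosis code may be HBV patients
#' rather than PrEP users. The flag is informational — labels are never
#' changed — and applies only to persons labelled `PREP_USER`.
#'
#' @param assignments Tibble from [assign_phenotype()].
#' @param conditions Condition tibble from the (filtered, consolidated)
#'   bundle.
#' @param registry A `concept_registry`.
#' @return `assignments` with `hbv_flag` set.
#' @export
hbv_flag_prep_users <- function(assignments, conditions, registry) {
  hbv_ids <- unique(conditions$person_id[
    codes_in_role(conditions$source_code, registry, "hbv_condition") |
      codes_in_role(conditions$concept_id, registry, "hbv_condition")])
  assignments$hbv_flag <- assignments$label == "PREP_USER" &
    assignments$person_id %in% hbv_ids
  assignments
}

#' Run the full cohort pipeline
#'
#' Date-filters the bundle, consolidates duplicate ids, builds evidence
#' profiles, assigns phenotype labels, and applies the HBV diagnostic flag.
#' Deterministic: output is sorted by person id and invariant to input
#' record order.
#'
#' @param bundle An `omop_bundle` (raw; windows are applied here).
#' @param registry A `concept_registry`.
#' @param config Run config, see [default_run_config()].
#' @param alias_map Optional duplicate-id map for
#'   [consolidate_person_ids()].
#' @return An object of class `cohort_result`: a list with `assignments`,
#'   `profiles`, `persons` (post-consolidation demographics), `tier_counts`,
#'   and `meta` (registry version, window settings).
#' @export
run_cohort <- function(bundle, registry, config = default_run_config(),
                       alias_map = NULL) {
  bundle <- filter_by_date_window(bundle, config$windows$ehr, config$windows$survey)
  bundle <- consolidate_person_ids(bundle, alias_map)
  profiles <- build_evidence_profiles(bundle, registry, config) %>%
    dplyr::arrange(.data$person_id)
  assignments <- assign_phenotype(profiles)
  assignments <- hbv_flag_prep_users(assignments, bundle$conditions, registry)
  tiers <- c("CONFIRMED_PWH", "PROBABLE_PWH", "PREP_USER", "NONE")
  tier_counts <- vapply(tiers, function(t) sum(assignments$label == t), integer(1))
  structure(
    list(assignments = assignments, profiles = profiles,
         persons = bundle$persons, tier_counts = tier_counts,
         meta = list(registry_version = registry$metadata$version,
                     windows = config$windows,
                     masking_threshold = config$masking_threshold)),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>", nrow(x$assignments), "persons\n")
  tc <- x$tier_counts
  for (t in names(tc)) cat(sprintf("  %-14s %d\n", t, tc[[t]]))
  invisible(x)
}
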