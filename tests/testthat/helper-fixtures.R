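# Shared fixtures and the independent tier-assignment oracle.

# Build a small omop_bundle from partial tables; demographics default to
# "Unknown" and birth_year to 1980 so only the evidence of interest varies.
make_bundle <- function(person_ids,
                        conditions = NULL, drugs = NULL,
                        measurements = NULL, surveys = NULL,
                        strict = TRUE) {
  persons <- tibble::tibble(
    person_id = person_ids, birth_year = 1980L,
    gender = "Unknown", race = "Unknown", ethnicity = "Unknown",
    marital_status = "Unknown", sexual_orientation = "Unknown",
    education = "Unknown", income_band = "Unknown", insurance = "Unknown",
    disability = "Unknown", chronic_conditions = "0")
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
  omop_bundle(persons,
              conditions %||% empty$conditions,
              drugs %||% empty$drugs,
              measurements %||% empty$measurements,
              surveys %||% empty$surveys,
              provenance = list(source = "test"), strict = strict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cond_row <- function(pid, code, date = "2020-06-01") {
  tibble::tibble(person_id = pid, concept_id = code, source_code = code,
                 date = as.Date(date))
}
drug_row <- function(pid, code, date = "2020-06-01") {
  tibble::tibble(person_id = pid, drug_code = code, date = as.Date(date))
}
meas_row <- function(pid, concept, vs = "", vn = NA_real_, unit = "",
                     date = "2020-06-01") {
  tibble::tibble(person_id = pid, concept_id = concept, value_string = vs,
                 value_number = vn, unit = unit, date = as.Date(date))
}
survey_row <- function(pid, answer, date = "2020-11-01") {
  tibble::tibble(person_id = pid, question_concept_id = "1384391",
                 answer_value = answer, date = as.Date(date))
}

# Independent brute-force tier oracle: a literal transcription of the
# clinical tier definitions, evaluated clause by clause for a single
# profile. Deliberately written as a flat rule list, not shared with the
# vectorized implementation.
oracle_label <- function(survey_status, screening_status, vl_detectable_count,
                         vl_undetectable_count, drug_pattern, condition_pos,
                         suppressed_on_art) {
  # confirmed: any of the three confirmation routes
  if (survey_status == "positive") return("CONFIRMED_PWH")
  if (screening_status == "positive") return("CONFIRMED_PWH")
  if (vl_detectable_count >= 1) return("CONFIRMED_PWH")
  if (suppressed_on_art) return("CONFIRMED_PWH")
  if (condition_pos && drug_pattern == "ART") return("CONFIRMED_PWH")
  # probable: unconfirmed EHR evidence
  if (condition_pos) return("PROBABLE_PWH")
  if (drug_pattern == "ART") return("PROBABLE_PWH")
  # PrEP: exclusively the two-drug pairs, negative screen, nothing positive
  if (drug_pattern == "PREP_ONLY" && screening_status == "negative" &&
      !condition_pos && survey_status != "positive") {
    return("PREP_USER")
  }
  "NONE"
}

# Enumerate the full finite profile space (viral-load counts capped at 2,
# the suppression flag only where consistent with ART + >= 2 undetectable).
enumerate_profiles <- function() {
  grid <- expand.grid(
    survey_status = c("positive", "negative", "missing"),
    screening_status = c("positive", "negative", "missing"),
    vl_detectable_count = 0:2,
    vl_undetectable_count = 0:2,
    drug_pattern = c("PREP_ONLY", "ART", "HCV_ONLY", "NONE"),
    condition_pos = c(TRUE, FALSE),
    suppressed_on_art = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  ok <- !grid$suppressed_on_art |
    (grid$drug_pattern == "ART" & grid$vl_undetectable_count >= 2)
  grid <- grid[ok, ]
  grid$person_id <- sprintf("T%04d", seq_len(nrow(grid)))
  tibble::as_tibble(grid)
}
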