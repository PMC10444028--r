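# Evidence interpretation ------------------------------------------------------
#
# Raw measurement rows and drug exposure histories are turned here into the
# atoms the classifier consumes: screening verdicts, viral-load
# detectability on the correct scale, per-day drug combinations, and the
# per-person drug pattern class.

#' Interpret an HIV screening result string
#'
#' Whole-string match (after trimming, case-folding and whitespace collapse)
#' against the configured positive and negative vocabularies. Substrings
#' never match: "Not detected" cannot fire on "detected". Anything outside
#' both sets — including empty input — is `"unknown"`. Total and vectorized.
#'
#' @param value_string Character vector of raw result strings.
#' @param positive,negative Character vectors of result strings counted as a
#'   positive / an explicit negative screen (defaults from
#'   [default_run_config()]).
#' @return Character vector in `{"positive", "negative", "unknown"}`.
#' @export
#' @examples
#' interpret_screening_value(c("Reactive", "Not detected", ""))
interpret_screening_value <- function(value_string,
                                      positive = default_run_config()$screening$positive,
                                      negative = default_run_config()$screening$negative) {
  v <- normalize_text(value_string)
  out <- rep("unknown", length(v))
  out[v %in% normalize_text(negative)] <- "negative"
  out[v %in% normalize_text(positive)] <- "positive"
  out
}

#' Infer the scale of a numeric viral-load value
#'
#' Unit metadata wins when present: units mentioning "log10" map to `log10`,
#' "ln" (or bare "log") to natural log, "copies" without a log marker to
#' `linear`. A config-level `force_scale` overrides everything. With no unit
#' and no override, a bounded-value heuristic applies: values at or below
#' `log_bound` are taken as log10 (no plausible linear viral load is that
#' small a number while log values above 8 would exceed 10^8 copies/mL),
#' larger values as linear. Negative values are unresolvable.
#'
#' @param value_number Numeric vector of measurement values.
#' @param unit_string Character vector of raw unit text ("" when absent).
#' @param log_bound Heuristic cutoff (log10 copies/mL).
#' @param force_scale Optional scale name applied to all rows
#'   (`"linear"`, `"log10"`, `"ln"`).
#' @return A tibble with columns `scale` in
#'   `{"linear","log10","ln","unknown"}` and `source` in
#'   `{"unit_metadata","config_override","heuristic","error"}`.
#' @export
infer_vl_scale <- function(value_number, unit_string = "",
                           log_bound = default_run_config()$viral_load$log_bound,
                           force_scale = NULL) {
  n <- max(length(value_number), length(unit_string))
  value_number <- rep_len(as.numeric(value_number), n)
  unit <- normalize_text(rep_len(unit_string, n))

  scale <- rep("unknown", n)
  source <- rep("heuristic", n)

  if (!is.null(force_scale)) {
    stopifnot(force_scale %in% c("linear", "log10", "ln"))
    scale[] <- force_scale
    source[] <- "config_override"
  } else {
    is_log10 <- grepl("log\\s*10", unit)
    is_ln <- !is_log10 & grepl("(^|[^a-z])(ln|log)([^a-z0-9]|$)", unit)
    is_linear <- !is_log10 & !is_ln & grepl("copies|cp/ml|c/ml", unit)
    scale[is_log10] <- "log10"
    scale[is_ln] <- "ln"
    scale[is_linear] <- "linear"
    source[is_log10 | is_ln | is_linear] <- "unit_metadata"
    open <- scale == "unknown"
    scale[open] <- ifelse(value_number[open] <= log_bound, "log10", "linear")
  }
  bad <- is.na(value_number) | value_number < 0
  scale[bad] <- "unknown"
  source[bad] <- "error"
  tibble::tibble(scale = scale, source = source)
}

#' Interpret a viral-load value against the detectability threshold
#'
#' Detectable iff the value strictly exceeds the threshold expressed on the
#' value's own scale: linear `v > t`, log10 `v > log10(t)`, natural log
#' `v > ln(t)`. Exactly the threshold (200 copies/mL by default) is
#' undetectable — the detectable and suppressed rules are the strict pair
#' "> t" / "< t", and the boundary is resolved to undetectable. Missing
#' values or unresolved scales give `"unknown"`.
#'
#' @param value_number Numeric vector.
#' @param scale Character vector of scales (recycled), as from
#'   [infer_vl_scale()].
#' @param threshold_copies Detectability threshold in copies/mL.
#' @return Character vector in `{"detectable", "undetectable", "unknown"}`.
#' @export
#' @examples
#' interpret_viral_load(c(1000, 200, 2.5), c("linear", "linear", "log10"))
interpret_viral_load <- function(value_number, scale,
                                 threshold_copies = default_run_config()$viral_load$threshold_copies) {
  n <- max(length(value_number), length(scale))
  v <- rep_len(as.numeric(value_number), n)
  s <- rep_len(as.character(scale), n)
  cut <- c(linear = threshold_copies,
           log10 = log10(threshold_copies),
           ln = log(threshold_copies))
  out <- rep("unknown", n)
  ok <- !is.na(v) & s %in% names(cut)
  out[ok] <- ifelse(v[ok] > cut[s[ok]], "detectable", "undetectable")
  out
}

#' Interpret the HIV-relevant measurement rows of a bundle
#'
#' Routes each measurement through the screening or viral-load interpreter
#' according to its lab concept's registry role. Rows whose concept carries
#' neither role are dropped.
#'
#' @param measurements Measurement tibble from an `omop_bundle`.
#' @param registry A `concept_registry`.
#' @param config Run config (screening vocabularies, threshold, log bound).
#' @return Tibble `person_id, kind, verdict, date, raw_value` with `kind` in
#'   `{"screening", "viral_load"}`.
#' @export
interpret_measurements <- function(measurements, registry,
                                   config = default_run_config()) {
  is_screen <- codes_in_role(measurements$concept_id, registry, "hiv_screen_lab")
  is_vl <- codes_in_role(measurements$concept_id, registry, "hiv_vl_lab")

  screen <- measurements[is_screen, ]
  screen_out <- tibble::tibble(
    person_id = screen$person_id,
    kind = "screening",
    verdict = interpret_screening_value(screen$value_string,
                                        config$screening$positive,
                                        config$screening$negative),
    date = screen$date,
    raw_value = screen$value_string
  )

  vl <- measurements[is_vl & !is_screen, ]
  scale <- infer_vl_scale(vl$value_number, vl$unit,
                          log_bound = config$viral_load$log_bound,
                          force_scale = config$viral_load$force_scale)
  vl_out <- tibble::tibble(
    person_id = vl$person_id,
    kind = "viral_load",
    verdict = interpret_viral_load(vl$value_number, scale$scale,
                                   config$viral_load$threshold_copies),
    date = vl$date,
    raw_value = as.character(ifelse(is.na(vl$value_number), vl$value_string,
                                    as.character(vl$value_number)))
  )
  dplyr::bind_rows(screen_out, vl_out)
}

# Cluster sorted dates so that dates within `tol` days of the running anchor
# share a group; tol = 0 reduces to identity on calendar days.
.cluster_dates <- function(dates, tol) {
  if (tol <= 0 || length(dates) <= 1) return(dates)
  o <- order(dates)
  d <- dates[o]
  anchor <- d[1]
  grp <- d
  for (i in seq_along(d)) {
    if (as.numeric(d[i] - anchor) > tol) anchor <- d[i]
    grp[i] <- anchor
  }
  grp[order(o)]
}

#' Group drug exposures into per-day ingredient combinations
#'
#' Resolves each drug record to ingredient-level codes (fixed-dose products
#' expand through the registry's ingredient map), then unions all ingredients
#' a person was started on the same day (or within `tolerance_days`, for
#' split prescriptions) into one combination. Each combo carries the derived
#' flags the pattern classifier needs.
#'
#' @param drugs Drug tibble from an `omop_bundle` (`person_id, drug_code,
#'   date`).
#' @param registry A `concept_registry`.
#' @param tolerance_days Days two records may differ and still form one combo.
#' @return Tibble `person_id, date, ingredients` (list-column) plus logical
#'   flags `relevant` (any ART/PrEP-component/HCV-role ingredient; role-less
#'   ingredients count only as generic other drugs), `is_prep_pair` (exactly
#'   FTC+TDF or FTC+TAF), `has_art`, `hcv_only` (every ingredient is an
#'   HCV-role agent).
#' @export
group_drug_combos <- function(drugs, registry, tolerance_days = 0) {
  if (nrow(drugs) == 0) {
    return(tibble::tibble(person_id = character(0), date = as.Date(character(0)),
                          ingredients = list(), relevant = logical(0),
                          is_prep_pair = logical(0), has_art = logical(0),
                          hcv_only = logical(0)))
  }
  expanded <- tibble::tibble(
    person_id = drugs$person_id,
    date = drugs$date,
    ingredients = resolve_ingredients(drugs$drug_code, registry)
  ) %>%
    tidyr::unnest(ingredients) %>%
    dplyr::distinct()

  expanded <- expanded %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::mutate(date = .cluster_dates(.data$date, tolerance_days)) %>%
    dplyr::ungroup() %>%
    dplyr::distinct()

  combos <- expanded %>%
    dplyr::group_by(.data$person_id, .data$date) %>%
    dplyr::summarise(ingredients = list(sort(unique(.data$ingredients))),
                     .groups = "drop")

  ftc <- registry$roles$prep_component_ftc
  tdf <- registry$roles$prep_component_tdf
  taf <- registry$roles$prep_component_taf
  art <- registry$roles$art_drug
  hcv <- registry$roles$hcv_drug
  roleful <- unique(c(art, hcv, ftc, tdf, taf))

  flag <- function(f) vapply(combos$ingredients, f, logical(1))
  combos$relevant <- flag(function(i) any(i %in% roleful))
  combos$is_prep_pair <- flag(function(i) setequal(i, c(ftc, tdf)) || setequal(i, c(ftc, taf)))
  combos$hcv_only <- flag(function(i) length(i) > 0 && all(i %in% hcv))
  combos$has_art <- flag(function(i) any(i %in% art)) & !combos$hcv_only
  combos
}

#' Classify a person's overall drug pattern
#'
#' Per-person label over the HIV-relevant combinations (combos containing no
#' ART/PrEP/HCV-role ingredient — routine non-HIV medication — are ignored):
#'
#' * `PREP_ONLY`: at least one relevant combo, and every relevant combo is
#'   exactly the FTC+TDF or FTC+TAF pair (any dose, any form). A single
#'   agent, a three-ingredient regimen, or any additional relevant
#'   combination disqualifies.
#' * `ART`: some combo carries an antiretroviral-role ingredient, the person
#'   is not PrEP-only, and their relevant combos are not exclusively
#'   HCV-treatment regimens.
#' * `HCV_ONLY`: every relevant combo is composed solely of HCV-role agents
#'   (these never count as HIV drug evidence).
#' * `NONE`: no relevant combos (or residual cases carrying no ART evidence).
#'
#' @param combos Output of [group_drug_combos()] (may cover many persons).
#' @return Tibble `person_id, drug_pattern`.
#' @export
classify_drug_pattern <- function(combos) {
  if (nrow(combos) == 0) {
    return(tibble::tibble(person_id = character(0), drug_pattern = character(0)))
  }
  combos %>%
    dplyr::filter(.data$relevant) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::summarise(
      n_combos = dplyr::n(),
      all_prep = all(.data$is_prep_pair),
      any_art = any(.data$has_art),
      all_hcv = all(.data$hcv_only),
      .groups = "drop"
    ) %>%
    dplyr::mutate(drug_pattern = dplyr::case_when(
      .data$n_combos > 0 & .data$all_prep ~ "PREP_ONLY",
      .data$any_art ~ "ART",
      .data$all_hcv ~ "HCV_ONLY",
      TRUE ~ "NONE"
    )) %>%
    dplyr::select("person_id", "drug_pattern")
}

#' Virologic suppression on ART
#'
#' True iff the person's drug pattern is `ART` and their viral-load history
#' contains undetectable results on at least two distinct dates (distinct
#' dates, not rows, so duplicated result rows cannot inflate the count).
#'
#' @param vl_history Tibble of viral-load interpretations for one person
#'   (`verdict`, `date`; rows of other kinds are ignored).
#' @param drug_pattern The person's pattern from [classify_drug_pattern()].
#' @return Logical scalar.
#' @export
detect_suppressed_on_art <- function(vl_history, drug_pattern) {
  if (!identical(drug_pattern, "ART")) return(FALSE)
  und <- vl_history$date[vl_history$verdict == "undetectable"]
  length(unique(und)) >= 2
}
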