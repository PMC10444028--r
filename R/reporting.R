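# Cohort reporting -------------------------------------------------------------
#
# Summary outputs: the evidence-source (Venn) decomposition of the identified
# cohort, the demographic table with within-tier percentages, chi-square
# comparisons of the confirmed vs probable tiers, and disclosure-control
# masking of small rendered cells. Masking is strictly a render-layer
# operation — internal counts stay exact so totals always reconcile.

.pwh_labels <- c("CONFIRMED_PWH", "PROBABLE_PWH")

# All 15 non-empty subsets of the four evidence sources, as canonical keys.
.venn_subsets <- function() {
  src <- c("condition", "drug", "lab", "survey")
  keys <- character(0)
  for (k in 1:4) {
    keys <- c(keys, apply(utils::combn(src, k), 2, paste, collapse = "+"))
  }
  sort(keys)
}

#' Evidence-source (Venn) decomposition
#'
#' Partitions the identified PWH (confirmed + probable) by the exact subset
#' of evidence sources that flagged each person. The 15 non-empty subsets of
#' \{condition, drug, lab, survey\} are all reported (zeros included); the
#' counts are pairwise disjoint and sum to the PWH total.
#'
#' @param assignments Tibble from [assign_phenotype()] /
#'   [run_cohort()]`$assignments`.
#' @param labels Which labels to decompose (default: both PWH tiers; pass
#'   `"CONFIRMED_PWH"` for the confirmed-only panel).
#' @return Tibble `sources, n` with one row per subset.
#' @export
venn_decomposition <- function(assignments, labels = .pwh_labels) {
  x <- assignments[assignments$label %in% labels, ]
  if (any(x$evidence_sources == "")) {
    stop("internal consistency failure: PWH with empty evidence_sources: ",
         paste(utils::head(x$person_id[x$evidence_sources == ""], 5),
               collapse = ", "), call. = FALSE)
  }
  keys <- .venn_subsets()
  counts <- table(factor(x$evidence_sources, levels = keys))
  tibble::tibble(sources = keys, n = as.integer(counts))
}

#' Mask small counts for disclosure control
#'
#' Renders counts as strings with cells in `[1, threshold - 1]` replaced by
#' the mask token `"<threshold"`. Zero is rendered as `"0"` — an empty cell
#' discloses no individual — and counts at or above the threshold pass
#' through unchanged.
#'
#' @param n Integer vector of counts (non-negative).
#' @param threshold Masking threshold (default 20).
#' @return Character vector of rendered cells.
#' @export
#' @examples
#' mask_small_cells(c(0, 5, 19, 20, 250))
mask_small_cells <- function(n, threshold = 20) {
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  ifelse(n > 0 & n < threshold, paste0("<", threshold), as.character(n))
}

#' Percentage share of a category
#'
#' `100 * count / total`, rounded half-up to one decimal (the convention for
#' all printed percentages in this package).
#'
#' @param count,total Non-negative counts with `count <= total`, `total > 0`.
#' @return Numeric percentage with one decimal.
#' @export
#' @examples
#' category_share(3324, 7667)
category_share <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive to form a share", call. = FALSE)
  if (any(count < 0) || any(count > total)) {
    stop("count must lie in [0, total]", call. = FALSE)
  }
  round_half_up(100 * count / total, 1)
}

.age_group <- function(birth_year, anchor_date) {
  age <- as.integer(format(as.Date(anchor_date), "%Y")) - birth_year
  cut(age, breaks = c(17, 29, 39, 49, 64, Inf),
      labels = c("18-29", "30-39", "40-49", "50-64", "65+"))
}

.demographic_characteristics <- c(
  "gender", "age_group", "race", "ethnicity", "marital_status",
  "sexual_orientation", "education", "income_band", "insurance",
  "disability", "chronic_conditions")

#' Demographic summary table by phenotype tier
#'
#' For each characteristic (gender, age group, race, ethnicity, marital
#' status, sexual orientation, education, income, insurance, disability,
#' chronic-condition count): level counts and within-tier percentages for
#' the total PWH cohort, the confirmed and probable tiers, and PrEP users.
#' Unknown/skip responses are preserved as levels. Percentages are computed
#' on exact counts; masking happens only at render time
#' ([render_demographics()]).
#'
#' @param assignments Assignment tibble.
#' @param persons Persons tibble (every assigned person must appear).
#' @param anchor_date Date at which age is computed (default: the EHR window
#'   end from [default_run_config()]).
#' @return Tibble `characteristic, level, n_total, pct_total, n_confirmed,
#'   pct_confirmed, n_probable, pct_probable, n_prep, pct_prep`.
#' @export
demographic_table <- function(assignments, persons,
                              anchor_date = default_run_config()$windows$ehr[2]) {
  missing_ids <- setdiff(assignments$person_id, persons$person_id)
  if (length(missing_ids) > 0) {
    stop("person(s) missing from persons table: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::inner_join(assignments, persons, by = "person_id") %>%
    dplyr::mutate(age_group = as.character(.age_group(.data$birth_year, anchor_date)))

  tiers <- list(
    total = df$label %in% .pwh_labels,
    confirmed = df$label == "CONFIRMED_PWH",
    probable = df$label == "PROBABLE_PWH",
    prep = df$label == "PREP_USER")
  totals <- vapply(tiers, sum, integer(1))

  rows <- lapply(.demographic_characteristics, function(ch) {
    levels_all <- sort(unique(df[[ch]]))
    out <- tibble::tibble(characteristic = ch, level = levels_all)
    for (tn in names(tiers)) {
      cnt <- unname(vapply(levels_all,
                           function(lv) sum(df[[ch]][tiers[[tn]]] == lv),
                           integer(1)))
      out[[paste0("n_", tn)]] <- cnt
      out[[paste0("pct_", tn)]] <-
        if (totals[[tn]] > 0) category_share(cnt, totals[[tn]]) else NA_real_
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Chi-square comparison of the confirmed and probable tiers
#'
#' For each characteristic, the standard chi-square test of independence
#' (no continuity correction) on the confirmed-vs-probable level-count
#' contingency table. Levels with zero counts in both tiers are dropped
#' (noted in `note`); characteristics left with a single level are skipped.
#'
#' @param demographics Output of [demographic_table()].
#' @return Tibble `characteristic, statistic, df, p_value, note`.
#' @export
compare_tiers <- function(demographics) {
  out <- lapply(split(demographics, demographics$characteristic), function(d) {
    m <- cbind(confirmed = d$n_confirmed, probable = d$n_probable)
    keep <- rowSums(m) > 0
    note <- if (all(keep)) "" else
      paste0("dropped zero-marginal level(s): ",
             paste(d$level[!keep], collapse = ", "))
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2 || any(colSums(m) == 0)) {
      return(tibble::tibble(characteristic = d$characteristic[1],
                            statistic = NA_real_, df = NA_integer_,
                            p_value = NA_real_,
                            note = "skipped: degenerate table"))
    }
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    tibble::tibble(characteristic = d$characteristic[1],
                   statistic = unname(ct$statistic),
                   df = as.integer(unname(ct$parameter)),
                   p_value = unname(ct$p.value), note = note)
  })
  dplyr::bind_rows(out) %>% dplyr::arrange(.data$characteristic)
}

#' Assemble the full cohort report
#'
#' @param result A `cohort_result` from [run_cohort()].
#' @return Object of class `cohort_report`: list with `tier_counts`, `venn`
#'   (total-PWH and confirmed-only decompositions), `demographics`,
#'   `comparisons`, and `meta`.
#' @export
build_cohort_report <- function(result) {
  stopifnot(inherits(result, "cohort_result"))
  demo <- demographic_table(result$assignments, result$persons)
  structure(
    list(
      tier_counts = result$tier_counts,
      venn = list(total = venn_decomposition(result$assignments),
                  confirmed = venn_decomposition(result$assignments,
                                                 "CONFIRMED_PWH")),
      demographics = demo,
      comparisons = compare_tiers(demo),
      meta = c(result$meta, list(test = "chi-square, no continuity correction"))),
    class = "cohort_report")
}

#' Render the demographic table with masking applied
#'
#' Count cells below the threshold are suppressed together with their
#' percentage (a masked count with a visible percentage would be
#' recoverable).
#'
#' @param demographics Output of [demographic_table()].
#' @param threshold Masking threshold.
#' @return Tibble of rendered string cells, one `"n (pct)"` column per tier.
#' @export
render_demographics <- function(demographics, threshold = 20) {
  out <- demographics[, c("characteristic", "level")]
  for (tn in c("total", "confirmed", "probable", "prep")) {
    n <- demographics[[paste0("n_", tn)]]
    pct <- demographics[[paste0("pct_", tn)]]
    masked <- mask_small_cells(n, threshold)
    out[[tn]] <- ifelse(masked == as.character(n) & !is.na(pct),
                        sprintf("%s (%.1f)", masked, pct), masked)
  }
  out
}

.render_p <- function(p) {
  ifelse(is.na(p), "skipped", ifelse(p < 0.001, "<.001", sprintf("%.3f", p)))
}

#' Write report files (TSV + JSON) with masking applied
#'
#' Emits `venn.tsv`, `demographics.tsv`, `comparisons.tsv`, and
#' `report.json` under `dir`. Every rendered count cell passes through
#' [mask_small_cells()]; no integer between 1 and `threshold - 1` appears in
#' any output file.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @param threshold Masking threshold (default: the run config value carried
#'   in the report metadata).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir,
                                threshold = report$meta$masking_threshold %||% 20) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  venn_tab <- dplyr::bind_rows(
    dplyr::mutate(report$venn$total, panel = "total_pwh"),
    dplyr::mutate(report$venn$confirmed, panel = "confirmed"))
  venn_tab <- tibble::tibble(panel = venn_tab$panel, sources = venn_tab$sources,
                             n = mask_small_cells(venn_tab$n, threshold))
  readr::write_tsv(venn_tab, file.path(dir, "venn.tsv"))

  readr::write_tsv(render_demographics(report$demographics, threshold),
                   file.path(dir, "demographics.tsv"))

  comp <- tibble::tibble(
    characteristic = report$comparisons$characteristic,
    chi_square = ifelse(is.na(report$comparisons$statistic), "skipped",
                        sprintf("%.2f", report$comparisons$statistic)),
    p_value = .render_p(report$comparisons$p_value),
    note = report$comparisons$note)
  readr::write_tsv(comp, file.path(dir, "comparisons.tsv"))

  json <- list(
    tier_counts = as.list(stats::setNames(
      mask_small_cells(report$tier_counts, threshold),
      names(report$tier_counts))),
    venn_total = stats::setNames(as.list(mask_small_cells(report$venn$total$n, threshold)),
                                 report$venn$total$sources),
    venn_confirmed = stats::setNames(
      as.list(mask_small_cells(report$venn$confirmed$n, threshold)),
      report$venn$confirmed$sources),
    meta = list(registry_version = report$meta$registry_version,
                masking_threshold = threshold,
                comparison_test = report$meta$test))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
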