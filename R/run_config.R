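# Run configuration ------------------------------------------------------------
#
# All tunables that are policy rather than algorithm live here: the study
# date windows, the screening result vocabularies, the viral-load threshold
# and log-scale heuristic bound, the same-day combo tolerance, and the
# disclosure-control masking threshold.

#' Default run configuration
#'
#' * `windows$ehr`: EHR records (conditions, drugs, measurements) are kept
#'   from 1981-01-01 to 2022-07-01 inclusive — the clinical era of HIV
#'   through the data cut.
#' * `windows$survey`: survey responses kept from 2018-10-01 to 2022-06-30
#'   inclusive (the collection period of the self-report instrument).
#' * `screening$positive`: result strings treated as a positive HIV screen;
#'   `screening$negative`: strings treated as an explicit negative. Matching
#'   is whole-string after trimming/case-folding, so "not detected" can never
#'   fire the "detected" rule.
#' * `viral_load$threshold_copies`: detectability threshold, copies/mL;
#'   strictly greater-than (exactly 200 is undetectable).
#' * `viral_load$log_bound`: unit-less values at or below this are assumed
#'   log10-scaled when unit metadata is absent (8 log10 copies/mL = 1e8,
#'   above any physiologic linear-scale ambiguity).
#' * `combo_tolerance_days`: how far apart two drug records may start and
#'   still count as one combination regimen (0 = same calendar day).
#' * `masking_threshold`: rendered counts below this are suppressed.
#' * `strict`: orphan-record handling for [read_omop_dir()].
#'
#' @return A named list of settings.
#' @export
default_run_config <- function() {
  list(
    windows = list(
      ehr = c("1981-01-01", "2022-07-01"),
      survey = c("2018-10-01", "2022-06-30")
    ),
    screening = list(
      positive = c("detected", "hiv-1 positive", "hiv-positive", "positive",
                   "reactive", "abnormal", "high"),
      negative = c("negative", "nonreactive", "non-reactive", "not detected",
                   "undetected", "normal")
    ),
    viral_load = list(
      threshold_copies = 200,
      log_bound = 8,
      force_scale = NULL
    ),
    combo_tolerance_days = 0,
    masking_threshold = 20,
    strict = TRUE
  )
}

#' Load a run configuration file
#'
#' Reads YAML and overlays it on [default_run_config()]; unspecified settings
#' keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A run-config list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_into(cfg, user)
}
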