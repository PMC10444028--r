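#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Normalize a clinical code string
#'
#' Codes are compared after trimming whitespace, case-folding to upper case,
#' and stripping the decimal point used in dotted ICD-10 forms, so that
#' `"B18.1"` and `"b181"` match the same registry entry.
#'
#' @param code Character vector of codes (ICD-10, SNOMED, LOINC, ingredient
#'   identifiers, OMOP concept ids). Coerced to character.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("B18.1", " b20 ", "86406008"))
normalize_code <- function(code) {
  code <- toupper(trimws(as.character(code)))
  gsub(".", "", code, fixed = TRUE)
}

# Free-text normalizer for lab result strings and survey answers: trim,
# lower-case, collapse internal whitespace. Dots are kept (they carry meaning
# in phrases, unlike in ICD codes).
normalize_text <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

#' Round half up
#'
#' Deterministic decimal rounding where ties at 5 always round away from
#' zero-ward ambiguity (0.05 -> 0.1), unlike base R's banker's rounding.
#' Used for all reported percentages.
#'
#' @param x Numeric vector (non-negative in this package's usage).
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against representation error just under .5 ulps
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Parse ISO-8601 dates strictly; anything that does not match returns NA.
parse_iso_date <- function(x) {
  as.Date(as.character(x), format = "%Y-%m-%d")
}

# Sort + join an evidence-source character vector into a canonical key such
# as "condition+drug". Empty input gives "".
sources_key <- function(sources) {
  paste(sort(unique(sources)), collapse = "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
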