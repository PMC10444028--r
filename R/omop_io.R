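# OMOP CDM table intake -------------------------------------------------------
#
# The phenotype consumes five OMOP-CDM-shaped tables, read from delimited
# text: person, condition_occurrence, drug_exposure, measurement, and
# observation (survey rows). This module reads and type-checks them into an
# in-memory bundle, applies the study date windows, and consolidates
# duplicate person identifiers.

.bundle_tables <- c("persons", "conditions", "drugs", "measurements", "surveys")

.canonical_columns <- list(
  persons = c("person_id", "birth_year", "gender", "race", "ethnicity",
              "marital_status", "sexual_orientation", "education",
              "income_band", "insurance", "disability", "chronic_conditions"),
  conditions = c("person_id", "concept_id", "source_code", "date"),
  drugs = c("person_id", "drug_code", "date"),
  measurements = c("person_id", "concept_id", "value_string", "value_number",
                   "unit", "date"),
  surveys = c("person_id", "question_concept_id", "answer_value", "date")
)

#' Default file/column schema for an OMOP directory
#'
#' Maps bundle tables to file names and canonical column names to the column
#' names found in the files. Override entries to adapt to local extracts,
#' e.g. `default_schema(files = c(surveys = "survey.csv"))`.
#'
#' @param files Named character vector overriding file names per table.
#' @param columns Named list of named character vectors,
#'   `canonical_name = file_column_name`, overriding column mappings per table.
#' @return A schema list with elements `files` and `columns`.
#' @export
default_schema <- function(files = character(0), columns = list()) {
  f <- c(persons = "person.csv", conditions = "condition_occurrence.csv",
         drugs = "drug_exposure.csv", measurements = "measurement.csv",
         surveys = "observation.csv")
  f[names(files)] <- files
  cols <- lapply(.canonical_columns, function(cc) stats::setNames(cc, cc))
  for (tbl in names(columns)) {
    cols[[tbl]][names(columns[[tbl]])] <- columns[[tbl]]
  }
  list(files = f, columns = cols)
}

#' Construct an OMOP bundle
#'
#' Low-level constructor from already-typed tibbles; most users call
#' [read_omop_dir()] instead. Performs column checks and the orphan-record
#' check (child rows whose `person_id` is absent from `persons`).
#'
#' @param persons,conditions,drugs,measurements,surveys Tibbles with the
#'   canonical columns (see the package vignette).
#' @param provenance List carrying source path, row counts and rejection log.
#' @param strict If `TRUE` (default) orphan child records are an error; if
#'   `FALSE` they are dropped and counted in provenance.
#' @return An object of class `omop_bundle`.
#' @export
omop_bundle <- function(persons, conditions, drugs, measurements, surveys,
                        provenance = list(), strict = TRUE) {
  tabs <- list(persons = persons, conditions = conditions, drugs = drugs,
               measurements = measurements, surveys = surveys)
  for (nm in names(tabs)) {
    missing_cols <- setdiff(.canonical_columns[[nm]], names(tabs[[nm]]))
    if (length(missing_cols) > 0) {
      stop("table '", nm, "' lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    tabs[[nm]] <- tibble::as_tibble(tabs[[nm]])[, .canonical_columns[[nm]]]
  }
  if (nrow(tabs$persons) == 0) stop("persons table is empty", call. = FALSE)
  if (anyDuplicated(tabs$persons$person_id)) {
    stop("persons table has duplicate person_id rows; consolidate aliases first",
         call. = FALSE)
  }
  known <- tabs$persons$person_id
  dropped_orphans <- integer(0)
  for (nm in setdiff(names(tabs), "persons")) {
    orphan <- !(tabs[[nm]]$person_id %in% known)
    if (any(orphan)) {
      ids <- unique(tabs[[nm]]$person_id[orphan])
      if (strict) {
        stop("orphan person_id(s) in table '", nm, "': ",
             paste(ids, collapse = ", "), call. = FALSE)
      }
      dropped_orphans[nm] <- sum(orphan)
      tabs[[nm]] <- tabs[[nm]][!orphan, ]
    }
  }
  provenance$row_counts <- vapply(tabs, nrow, integer(1))
  if (length(dropped_orphans) > 0) provenance$dropped_orphans <- dropped_orphans
  structure(c(tabs, list(provenance = provenance)), class = "omop_bundle")
}

#' @export
print.omop_bundle <- function(x, ...) {
  cat("<omop_bundle>\n")
  for (nm in .bundle_tables) cat(sprintf("  %-13s %6d rows\n", nm, nrow(x[[nm]])))
  rej <- x$provenance$rejected
  if (!is.null(rej) && nrow(rej) > 0) cat("  rejected rows:", nrow(rej), "\n")
  invisible(x)
}

# Read one delimited table as all-character columns, rename per schema,
# and fail clearly when expected columns are absent.
.read_raw_table <- function(dir, tbl, schema) {
  path <- file.path(dir, schema$files[[tbl]])
  if (!file.exists(path)) {
    stop("missing OMOP table file: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  colmap <- schema$columns[[tbl]]
  absent <- setdiff(unname(colmap), names(raw))
  if (length(absent) > 0) {
    stop("file ", schema$files[[tbl]], " lacks column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- raw[, unname(colmap)]
  names(out) <- names(colmap)
  out
}

#' Read an OMOP CDM directory into a typed bundle
#'
#' Expects five comma-separated, UTF-8, headered files (names configurable via
#' `schema`), with ISO-8601 dates. Malformed rows (unparseable date, missing
#' person_id, measurement rows with neither a string nor a numeric value) are
#' rejected individually, with the reason logged in
#' `bundle$provenance$rejected`; structural problems (missing file, empty
#' persons table) are fatal.
#'
#' @param dir Directory containing the five files.
#' @param schema Schema from [default_schema()].
#' @param strict Orphan handling, see [omop_bundle()].
#' @return An `omop_bundle`.
#' @export
read_omop_dir <- function(dir, schema = default_schema(), strict = TRUE) {
  if (!dir.exists(dir)) stop("OMOP directory not found: ", dir, call. = FALSE)
  rejects <- list()
  note_reject <- function(tbl, keep, reason) {
    if (all(keep)) return(invisible(NULL))
    rejects[[length(rejects) + 1]] <<- tibble::tibble(
      table = tbl, row = which(!keep), reason = reason)
  }

  tabs <- lapply(stats::setNames(.bundle_tables, .bundle_tables),
                 function(tbl) .read_raw_table(dir, tbl, schema))

  # persons: typed demographics, birth_year integer
  p <- tabs$persons
  keep <- !is.na(p$person_id) & p$person_id != ""
  note_reject("persons", keep, "missing person_id")
  p <- p[keep, ]
  p$birth_year <- suppressWarnings(as.integer(p$birth_year))
  keep <- !is.na(p$birth_year)
  note_reject("persons", keep, "unparseable birth_year")
  p <- p[keep, ]
  demo_cols <- setdiff(.canonical_columns$persons, c("person_id", "birth_year"))
  for (cc in demo_cols) {
    p[[cc]] <- ifelse(is.na(p[[cc]]) | p[[cc]] == "", "Unknown", p[[cc]])
  }
  tabs$persons <- p

  for (tbl in setdiff(.bundle_tables, "persons")) {
    x <- tabs[[tbl]]
    keep <- !is.na(x$person_id) & x$person_id != ""
    note_reject(tbl, keep, "missing person_id")
    x <- x[keep, ]
    d <- parse_iso_date(x$date)
    keep <- !is.na(d)
    note_reject(tbl, keep, "unparseable date")
    x <- x[keep, ]
    x$date <- parse_iso_date(x$date)
    tabs[[tbl]] <- x
  }

  m <- tabs$measurements
  m$value_number <- suppressWarnings(as.numeric(m$value_number))
  m$value_string <- ifelse(is.na(m$value_string), "", m$value_string)
  m$unit <- ifelse(is.na(m$unit), "", m$unit)
  keep <- !(m$value_string == "" & is.na(m$value_number))
  note_reject("measurements", keep, "no value (neither string nor numeric)")
  tabs$measurements <- m[keep, ]

  rejected <- if (length(rejects) == 0) {
    tibble::tibble(table = character(0), row = integer(0), reason = character(0))
  } else {
    dplyr::bind_rows(rejects)
  }
  omop_bundle(tabs$persons, tabs$conditions, tabs$drugs, tabs$measurements,
              tabs$surveys,
              provenance = list(source = normalizePath(dir), rejected = rejected),
              strict = strict)
}

.as_window <- function(w, what) {
  w <- as.Date(unlist(w, use.names = FALSE))
  if (length(w) != 2 || any(is.na(w))) {
    stop(what, " window must be two valid dates", call. = FALSE)
  }
  if (w[1] > w[2]) {
    stop(what, " window is inverted: start ", w[1], " > end ", w[2], call. = FALSE)
  }
  w
}

#' Restrict a bundle to the study date windows
#'
#' Conditions, drug exposures and measurements are kept when dated inside the
#' EHR window; survey responses when inside the survey window. Both intervals
#' are closed (`[start, end]` inclusive). The persons table is untouched.
#' Filtering is idempotent.
#'
#' @param bundle An `omop_bundle`.
#' @param ehr_window,survey_window Length-2 date vectors (or anything
#'   `as.Date` accepts), `c(start, end)` with `start <= end`.
#' @return The filtered `omop_bundle`.
#' @export
filter_by_date_window <- function(bundle, ehr_window, survey_window) {
  stopifnot(inherits(bundle, "omop_bundle"))
  ehr <- .as_window(ehr_window, "EHR")
  svy <- .as_window(survey_window, "survey")
  inside <- function(d, w) d >= w[1] & d <= w[2]
  for (tbl in c("conditions", "drugs", "measurements")) {
    bundle[[tbl]] <- bundle[[tbl]][inside(bundle[[tbl]]$date, ehr), ]
  }
  bundle$surveys <- bundle$surveys[inside(bundle$surveys$date, svy), ]
  bundle$provenance$row_counts <- vapply(bundle[.bundle_tables], nrow, integer(1))
  bundle
}

# Resolve an alias map alias -> canonical to its fixed point, detecting
# cycles. Returns a named character vector mapping every alias to its final
# canonical id.
.resolve_aliases <- function(alias_map) {
  out <- alias_map
  for (a in names(alias_map)) {
    seen <- a
    target <- alias_map[[a]]
    while (target %in% names(alias_map)) {
      if (target %in% seen) {
        stop("alias cycle involving id '", a, "'", call. = FALSE)
      }
      seen <- c(seen, target)
      target <- alias_map[[target]]
    }
    out[[a]] <- target
  }
  out
}

#' Consolidate duplicate person identifiers
#'
#' Applies an alias map (duplicate id -> canonical id, resolved transitively)
#' to every table: child records are re-keyed to the canonical id and alias
#' rows are removed from the persons table. The canonical id must itself have
#' a persons row (its demographics are retained).
#'
#' @param bundle An `omop_bundle`.
#' @param alias_map Named character vector `c(alias = canonical)`, or `NULL` /
#'   empty for a no-op.
#' @return The consolidated `omop_bundle`.
#' @export
consolidate_person_ids <- function(bundle, alias_map = NULL) {
  stopifnot(inherits(bundle, "omop_bundle"))
  if (is.null(alias_map) || length(alias_map) == 0) return(bundle)
  amap <- .resolve_aliases(alias_map)
  canon <- function(ids) {
    as.character(ifelse(ids %in% names(amap), unname(amap[ids]), ids))
  }
  targets <- unique(unname(amap))
  persons <- bundle$persons[!(bundle$persons$person_id %in% names(amap)), ]
  missing_canon <- setdiff(targets, persons$person_id)
  if (length(missing_canon) > 0) {
    stop("canonical id(s) lack a persons row (demographics missing): ",
         paste(missing_canon, collapse = ", "), call. = FALSE)
  }
  bundle$persons <- persons
  for (tbl in setdiff(.bundle_tables, "persons")) {
    bundle[[tbl]]$person_id <- canon(bundle[[tbl]]$person_id)
  }
  bundle$provenance$row_counts <- vapply(bundle[.bundle_tables], nrow, integer(1))
  bundle$provenance$consolidated_aliases <- length(amap)
  bundle
}
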