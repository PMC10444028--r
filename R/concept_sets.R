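# Role-tagged concept sets ----------------------------------------------------
#
# Every piece of evidence the classifier consumes is driven by membership of a
# code in a role: what counts as an HIV diagnosis, an antiretroviral
# ingredient, a PrEP component, an HCV-only agent, an HBV diagnosis, an HIV
# lab test, or the self-report survey item. The registry is plain data loaded
# from a YAML/JSON config so deployments can swap in their own pre-expanded
# code lists without touching the algorithm.

# Closed role vocabulary. Roles in .optional_roles may be empty (or absent,
# in which case they materialize as empty sets).
.code_roles <- c(
  "hiv_condition", "art_drug",
  "prep_component_ftc", "prep_component_tdf", "prep_component_taf",
  "hcv_drug", "hbv_condition",
  "hiv_screen_lab", "hiv_vl_lab",
  "survey_hiv_question"
)
.answer_roles <- c("survey_hiv_positive_answers", "survey_hiv_negative_answers")
.all_roles <- c(.code_roles, .answer_roles)
.optional_roles <- c("hcv_drug", "hbv_condition", "survey_hiv_negative_answers")

#' Construct a concept-set registry
#'
#' A registry maps each phenotyping role to the set of codes (or, for the two
#' survey-answer roles, response strings) that realize it, plus an optional
#' drug-product-to-ingredient mapping used to resolve fixed-dose combination
#' products. Codes are stored normalized (see [normalize_code()]); answer
#' strings are stored case/whitespace-normalized.
#'
#' @param roles Named list, role name -> character vector of codes/answers.
#'   Role names must belong to the closed role vocabulary; mandatory roles
#'   must be non-empty.
#' @param ingredients Named list mapping a drug product code to the character
#'   vector of ingredient codes it resolves to. Codes absent from this map are
#'   treated as already ingredient-level.
#' @param metadata List with at least `version` (character); free-form
#'   provenance note allowed under `source`.
#' @return An object of class `concept_registry`.
#' @export
concept_registry <- function(roles, ingredients = list(), metadata = list(version = "unversioned")) {
  stopifnot(is.list(roles), is.list(ingredients))
  unknown <- setdiff(names(roles), .all_roles)
  if (length(unknown) > 0) {
    stop("unknown role name(s) in concept config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_roles <- setdiff(setdiff(.all_roles, .optional_roles), names(roles))
  if (length(missing_roles) > 0) {
    stop("role ", paste(missing_roles, collapse = ", "), " absent from concept config",
         call. = FALSE)
  }
  out <- stats::setNames(vector("list", length(.all_roles)), .all_roles)
  for (role in .all_roles) {
    vals <- as.character(roles[[role]] %||% character(0))
    vals <- if (role %in% .answer_roles) normalize_text(vals) else normalize_code(vals)
    if (anyDuplicated(vals)) {
      warning("duplicate entries in role '", role, "' deduplicated", call. = FALSE)
      vals <- unique(vals)
    }
    if (role %in% setdiff(.all_roles, .optional_roles) && length(vals) == 0) {
      stop("role ", role, " absent from concept config", call. = FALSE)
    }
    out[[role]] <- vals
  }
  ing <- lapply(ingredients, function(v) unique(normalize_code(v)))
  names(ing) <- normalize_code(names(ingredients) %||% character(0))
  if (any(lengths(ing) == 0)) {
    stop("ingredient mapping entries must resolve to at least one ingredient",
         call. = FALSE)
  }
  structure(
    list(roles = out, ingredients = ing,
         metadata = list(version = as.character(metadata$version %||% "unversioned"),
                         source = as.character(metadata$source %||% ""))),
    class = "concept_registry"
  )
}

#' @export
print.concept_registry <- function(x, ...) {
  cat("<concept_registry> version", x$metadata$version, "\n")
  sizes <- vapply(x$roles, length, integer(1))
  for (r in names(sizes)) cat(sprintf("  %-28s %d entries\n", r, sizes[[r]]))
  cat("  ingredient map:", length(x$ingredients), "products\n")
  invisible(x)
}

#' Load a concept-set configuration file
#'
#' Reads a YAML (or JSON) file with a top-level `roles` mapping, optional
#' `ingredients` mapping, and optional `metadata`, and returns a validated
#' [concept_registry()].
#'
#' @param path Path to the config file.
#' @return A `concept_registry`.
#' @export
load_concept_config <- function(path) {
  if (!file.exists(path)) stop("concept config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$roles)) stop("concept config has no 'roles' section", call. = FALSE)
  concept_registry(roles = cfg$roles,
                   ingredients = cfg$ingredients %||% list(),
                   metadata = cfg$metadata %||% list(version = "unversioned"))
}

#' Save a registry back to YAML
#'
#' Inverse of [load_concept_config()]: `load -> save -> load` yields an equal
#' registry (codes already normalized).
#'
#' @param registry A `concept_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_concept_registry <- function(registry, path) {
  stopifnot(inherits(registry, "concept_registry"))
  yaml::write_yaml(
    list(metadata = registry$metadata,
         roles = lapply(registry$roles, as.list),
         ingredients = lapply(registry$ingredients, as.list)),
    path
  )
  invisible(path)
}

#' The bundled demonstration registry
#'
#' A small, documented subset of representative ICD-10 / SNOMED / LOINC /
#' ingredient codes per role, sufficient to exercise every rule branch.
#' Production deployments are expected to supply their own pre-expanded
#' concept lists via [load_concept_config()]; the algorithm, not the list, is
#' what this package fixes.
#'
#' @return A `concept_registry`.
#' @export
demo_registry <- function() {
  load_concept_config(system.file("extdata", "demo_concepts.yaml",
                                  package = "hivphenotype", mustWork = TRUE))
}

#' Classify a code against the registry
#'
#' Returns every role whose code set contains the normalized code. Unknown
#' codes yield an empty character vector; the function is total and pure.
#' Only code-bearing roles participate (survey answer strings are matched by
#' the evidence layer, not here).
#'
#' @param code A single code string or concept id.
#' @param registry A `concept_registry`.
#' @return Character vector of role names (possibly empty).
#' @export
#' @examples
#' classify_code("B18.1", demo_registry())
classify_code <- function(code, registry) {
  stopifnot(inherits(registry, "concept_registry"), length(code) == 1)
  nc <- normalize_code(code)
  roles <- .code_roles
  roles[vapply(roles, function(r) nc %in% registry$roles[[r]], logical(1))]
}

# Vectorized membership helper used by the evidence layer.
codes_in_role <- function(codes, registry, role) {
  normalize_code(codes) %in% registry$roles[[role]]
}

#' Resolve drug product codes to ingredient codes
#'
#' Fixed-dose combination products resolve through the registry's ingredient
#' map; codes not in the map pass through unchanged (assumed ingredient-level).
#'
#' @param codes Character vector of drug codes.
#' @param registry A `concept_registry`.
#' @return List of character vectors, one per input code.
#' @export
resolve_ingredients <- function(codes, registry) {
  nc <- normalize_code(codes)
  lapply(nc, function(code) registry$ingredients[[code]] %||% code)
}

#' Validate registry content
#'
#' Cross-role consistency checks beyond structural loading:
#' * `forbidden_overlap`: codes in both `hiv_condition` and `hbv_condition`
#'   (would make an HBV diagnosis count as HIV evidence) — fatal in strict
#'   mode;
#' * `flagged_overlap`: `hcv_drug` codes also holding `art_drug` role —
#'   allowed (dual-use agents) but reported, since HCV-only regimens are the
#'   exclusion set for drug evidence;
#' * `hcv_only`: informational listing of agents carrying only the
#'   `hcv_drug` role;
#' * `non_singleton_prep`: `prep_component_*` roles are expected to hold a
#'   single ingredient each;
#' * `multi_question`: more than one survey question concept.
#'
#' @param registry A `concept_registry`.
#' @param strict If `TRUE`, forbidden findings raise an error.
#' @return A tibble with columns `category`, `detail`, `severity`
#'   (`"fatal"`, `"warning"`, `"info"`); zero rows for a clean registry.
#' @export
validate_registry <- function(registry, strict = FALSE) {
  stopifnot(inherits(registry, "concept_registry"))
  rows <- list()
  add <- function(category, detail, severity) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      category = category, detail = detail, severity = severity)
  }
  bad <- intersect(registry$roles$hiv_condition, registry$roles$hbv_condition)
  if (length(bad) > 0) {
    add("forbidden_overlap",
        paste0("codes in both hiv_condition and hbv_condition: ",
               paste(bad, collapse = ", ")), "fatal")
  }
  dual <- intersect(registry$roles$hcv_drug, registry$roles$art_drug)
  if (length(dual) > 0) {
    add("flagged_overlap",
        paste0("hcv_drug codes also tagged art_drug (dual-use agents): ",
               paste(dual, collapse = ", ")), "warning")
  }
  hcv_only <- setdiff(registry$roles$hcv_drug, registry$roles$art_drug)
  if (length(hcv_only) > 0) {
    add("hcv_only",
        paste0("hcv_drug-only agents (excluded from drug evidence): ",
               paste(hcv_only, collapse = ", ")), "info")
  }
  for (r in c("prep_component_ftc", "prep_component_tdf", "prep_component_taf")) {
    if (length(registry$roles[[r]]) != 1) {
      add("non_singleton_prep", paste0(r, " holds ", length(registry$roles[[r]]),
                                       " ingredients; expected exactly 1"), "fatal")
    }
  }
  if (length(registry$roles$survey_hiv_question) != 1) {
    add("multi_question",
        paste0(length(registry$roles$survey_hiv_question),
               " survey question concepts registered; default design expects 1"),
        "warning")
  }
  report <- if (length(rows) == 0) {
    tibble::tibble(category = character(0), detail = character(0),
                   severity = character(0))
  } else {
    dplyr::bind_rows(rows)
  }
  if (strict && any(report$severity == "fatal")) {
    stop("registry validation failed:\n  ",
         paste(report$detail[report$severity == "fatal"], collapse = "\n  "),
         call. = FALSE)
  }
  report
}
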