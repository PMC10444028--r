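Package: hivphenotype
Title: Rule-Based Computable Phenotyping of HIV Status and PrEP Use from
    OMOP CDM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies people with HIV (confirmed and probable tiers) and
    pre-exposure prophylaxis (PrEP) users from OMOP Common Data Model shaped
    electronic health record and survey extracts. Implements a rule-based
    computable phenotype that combines diagnosis codes, antiretroviral drug
    exposure patterns, HIV laboratory results (screening strings and viral
    loads with log-scale handling), and a self-reported survey item; produces
    evidence-source (Venn) decompositions, demographic summaries with
    small-cell suppression, and tier comparisons. Ships a role-tagged concept
    set registry, a synthetic OMOP cohort generator with per-person ground
    truth for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
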