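---
title: "Methods: rule-based HIV/PrEP phenotyping from OMOP CDM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based HIV/PrEP phenotyping from OMOP CDM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hivphenotype)
```

# The problem

Large research programs that pool electronic health records (EHR) and
self-reported survey data under the OMOP Common Data Model need executable,
auditable definitions — computable phenotypes — to find the patients a study
is about. `hivphenotype` implements such a phenotype for HIV: it identifies
people with HIV (PWH), tiered into **confirmed** and **probable** cases by
the strength of their evidence, and separately identifies **PrEP users** —
HIV-negative people taking the two-drug pre-exposure prophylaxis
combinations — who must not be mistaken for cases merely because they take
antiretrovirals.

The input is five OMOP-shaped tables (`person`, `condition_occurrence`,
`drug_exposure`, `measurement`, `observation` with survey rows) read from
CSV. The output is one label per person, with the clauses that produced it,
the set of evidence domains that contributed, and disclosure-safe summary
tables.

# The classification rules

Four evidence domains feed the classifier:

1. **Conditions** — any diagnosis code holding the `hiv_condition` registry
   role (ICD-10 `B20`–`B24`, `Z21`; SNOMED HIV/AIDS concepts).
2. **Drugs** — exposures resolved to ingredient level and grouped into
   same-day combinations, then classified per person as `PREP_ONLY`
   (exclusively FTC+TDF or FTC+TAF pairs), `ART` (any antiretroviral
   evidence beyond that), `HCV_ONLY` (regimens made solely of
   hepatitis-C agents, which never count as HIV evidence), or `NONE`.
3. **Labs** — screening result strings interpreted against configurable
   positive/negative vocabularies, and viral loads compared against the
   detectability threshold on the correct scale.
4. **Survey** — the personal-medical-history HIV item (OMOP concept
   `1384391`); the configured affirmative answer is a confirmation on its
   own.

Tier assignment evaluates in fixed precedence:

* **CONFIRMED_PWH** — positive survey response, **or** a confirming lab
  result (positive screen, viral load > 200 copies/mL, or virologic
  suppression on ART), **or** an HIV diagnosis code together with non-PrEP
  ART exposure.
* **PROBABLE_PWH** — otherwise, any unconfirmed EHR evidence: a diagnosis
  code alone or ART exposure alone.
* **PREP_USER** — otherwise, exclusively PrEP-pair drug exposure *plus* an
  explicitly negative HIV screen, with no diagnosis codes and no positive
  survey answer.
* **NONE** — otherwise.

Every satisfied confirming clause is recorded (`confirm_basis`), and
`evidence_sources` keeps the exact domain subset for the Venn
decomposition.

## Design choices in the tier rules

Several points were genuinely open; the package resolves them as follows
and tests pin the behaviour:

* **Probable includes drug-only persons.** A narrow reading would restrict
  the probable tier to diagnosis-code-only persons, but tiered HIV cohorts
  built this way report substantial probable counts identified through drug
  exposure; we define probable as *any* unconfirmed EHR evidence
  (condition **or** non-PrEP ART). This is the single most consequential
  interpretation in the package and is deliberately prominent here.
* **A positive survey answer vetoes PrEP.** A self-reported PWH taking
  FTC/TDF is a confirmed case, not a PrEP user; allowing both would create
  contradictory labels.
* **A lone undetectable viral load confers nothing.** Undetectable results
  only matter through the suppression rule (ART + undetectable loads on at
  least two *distinct dates* — distinct dates, not rows, so duplicated
  records cannot fake suppression). Low numeric values such as 26 or 1.95
  are treated as evidence *considered*, never as confirmation by
  themselves.
* **Explicit survey "no" and missing are distinguished** in the evidence
  profile but currently treated identically by the tier rules; the
  distinction is kept for reporting.

# Laboratory interpretation

**Screening strings.** Matching is whole-string after trimming,
case-folding and whitespace collapse. The default positive vocabulary is
*detected, HIV-1 positive, HIV-positive, positive, reactive, abnormal,
high*; the default negative vocabulary is *negative, nonreactive,
non-reactive, not detected, undetected, normal*. Whole-string matching is
what makes "Not detected" safe: substring logic would light it up on
"detected". Both sets are run-config entries because local result
vocabularies vary.

**Viral-load scales.** Results arrive linear ("350 copies/mL"), as log10,
or occasionally as natural log, and unit text is often missing. Scale
resolution is layered: a config-level `force_scale` override wins, then
unit metadata (`log10` markers, `ln`/bare `log`, `copies`), then a bounded
heuristic for unit-less rows — values at or below `log_bound = 8` are read
as log10. The bound is the physiologic argument: 8 log10 copies/mL is
10^8 copies/mL, above any plausible ambiguity, while no meaningful *linear*
viral load is ≤ 8 copies in a reporting context that drops units. Each
interpretation records which path fired (`unit_metadata`,
`config_override`, `heuristic`), so provenance is auditable.

**The threshold.** Detectable means strictly greater than 200 copies/mL on
the value's own scale (`v > 200`, `log10(v) > log10(200)`,
`ln(v) > ln(200)`). The detectable/suppressed pair is printed as the strict
pair "> 200" / "< 200", which leaves exactly 200 undefined; the package
resolves the boundary to *undetectable* — the conservative direction, since
detectability confirms a case. Scale equivariance
(`verdict(v, linear) == verdict(log10(v), log10)`) is property-tested over
random values and is exact because the thresholds are transformed, not the
values.

# Drug combinations and the PrEP definition

Drug records resolve to ingredient codes through an explicit product map in
the registry (e.g. a fixed-dose FTC/TDF product expands to both
ingredients), so the package runs offline with no vocabulary service.
"Combination" means ingredients started on the same calendar day — for
fixed-dose products and same-day split prescriptions the start dates
coincide — with a configurable `combo_tolerance_days` (default 0) to absorb
split prescriptions filled days apart.

`PREP_ONLY` requires that *every* HIV-relevant combination a person has is
exactly the FTC+TDF or FTC+TAF pair (any dose, any form): a single agent is
not PrEP, three ingredients are not PrEP, and any additional relevant
combination disqualifies. Combinations containing no ART/PrEP/HCV-role
ingredient (routine non-HIV medication) are ignored by the pattern
classifier: the source platforms extract the drug-exposure table through
HIV-specific concept sets, so "all drug records" in the PrEP rule means all
*HIV-relevant* records, and an aspirin prescription should not strip
someone of PrEP status. Regimens composed entirely of HCV-role agents are
excluded from drug evidence (`HCV_ONLY`); dual-use agents count as ART
whenever any ingredient holds the ART role and the regimen is not
HCV-only.

Because FTC/TDF also treats chronic hepatitis B and is used for
post-exposure prophylaxis, PrEP identification can misclassify; the package
reproduces the diagnostic check of flagging identified PrEP users who carry
chronic-HBV ICD codes (`B180`, `B181`, `B191`). The flag never relabels —
it quantifies the risk.

# Intake, windows, consolidation

Dates are ISO-8601; intervals are closed on both ends. Defaults keep EHR
records in [1981-01-01, 2022-07-01] (the clinical era of HIV through the
data cut) and survey responses in [2018-10-01, 2022-06-30] (the
instrument's collection period). Inclusive bounds are the conservative
reading of "from X to Y". Malformed rows are rejected individually with
logged reasons; orphan child records (person absent from `person`) are
fatal by default because silently dropping them changes cohort counts —
a lenient drop-and-log mode is available. Duplicate person ids consolidate
through an explicit alias map resolved transitively with cycle detection;
filtering and consolidation commute, and filtering is idempotent (both
property-tested).

# Reporting and disclosure control

* **Venn decomposition** partitions PWH by their exact evidence-source
  subset (15 subsets of condition/drug/lab/survey), reported for all PWH
  and for the confirmed tier.
* **Percentages** use round-half-up at one decimal — the convention of the
  printed tables this mirrors; banker's rounding would diverge on `.x5`
  ties (the package returns 2.3% for 9/400, not 2.2%).
* **Masking** renders any count in [1, 19] as `<20`. Zero renders as 0: an
  empty cell discloses no individual, while small nonzero cells do.
  Masking is render-layer only — internal counts stay exact so totals
  always reconcile — and a masked count suppresses its percentage too,
  since a visible percentage would let a reader invert the mask.
* **Tier comparison** uses the standard chi-square test of independence
  without continuity correction on the confirmed-vs-probable contingency
  table per characteristic, with unknown/skip levels kept as categories;
  the choice of test is recorded in the report metadata. Degrees of
  freedom are kept in the R object but not rendered, so report files
  contain no small unmasked integers at all.

# The synthetic cohort generator

There is no public data this phenotype can run on, so the package ships a
generator that is itself first-class, tested code. It plants records that
**satisfy the rules by construction** rather than sampling a disease model:
a person intended as confirmed-by-lab receives, say, a viral load drawn
above the threshold or a "Reactive" screen; a person intended as a PrEP
user receives only PrEP-pair combinations plus a negative screen. Ground
truth is therefore exact, and any planted-vs-recovered disagreement is a
bug, not noise.

Defaults: 25% confirmed / 17% probable (the roughly 60/40 split seen in
tiered HIV cohorts), 3% PrEP users (about 7% of the PWH count), 55%
unaffected — an enriched test cohort, not a prevalence model. Confirmed
evidence subsets are weighted toward condition+drug and drug-alone
compositions, again shaped like published Venn decompositions. Messiness
rates (30% log-scale viral loads, 20% missing units, 30% sloppy result
strings, 2% duplicated ids, 5%/3% HCV/HBV decoys, 5% out-of-window records)
were chosen once as plausible for a multi-site EHR extract. Decoys are
designed non-confounding: HCV-only regimens go to persons whose pattern
they cannot change, HBV codes never carry the HIV-condition role, and
out-of-window evidence exists precisely to be removed by the window filter.

What the generator does **not** emulate — and therefore what passing tests
do *not* show about real data: production-scale concept lists (the bundled
registry is a documented demo subset; deployments supply their own),
free-text notes, longitudinal care trajectories, correlated demographics,
coding-practice drift across sites, and true PEP courses (short FTC/TDF
exposure is structurally identical to PrEP here, as it is for the real
algorithm). Demographics are sampled independently per person purely to
exercise the reporting layer.

`generate_edge_cases()` complements the sampler with a fixed, seedless
bundle: one person per rule boundary (200 copies/mL exactly, log10(200)
exactly, the heuristic path, each PrEP disqualifier, suppression with one
vs two dates, the survey veto, the HBV flag scope, an alias pair, an
out-of-window diagnosis).

# Problem sizes and numerical notes

The test suite enumerates the full finite profile space (~700 profiles
after consistency constraints) and checks the vectorized classifier against
an independently coded brute-force rule table; recovery tests run the full
pipeline on synthetic cohorts of up to 5,000 persons with all messiness
enabled; scale equivariance is checked over 10,000 random viral loads —
sizes chosen to exercise every branch many times over while the whole suite
stays fast enough to run on every change. Rounding uses an epsilon guard
(`sqrt(.Machine$double.eps)`) so values representing exact `.x5` ties in
binary floating point still round up. All randomness is seed-scoped:
`generate_cohort()` restores the caller's RNG state.

# Known limitations

* The tier rules are only as good as the supplied concept sets; count
  differences against any production deployment are attributable to
  registry content, not logic.
* PEP users and some HBV patients on dual-use regimens can satisfy the PrEP
  definition; the HBV flag measures, but cannot eliminate, this.
* No NLP over clinical notes; diagnosis mentions that exist only in
  narrative text are invisible.
* EHR records dated after a person's survey response receive no special
  handling; all in-window records count equally.
* The chi-square comparisons assume independent persons and moderately
  sized cells; with heavy masking-scale sparsity the p-values are
  indicative only.
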