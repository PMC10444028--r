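# Demonstration concept-set registry.
#
# A deliberately small, representative subset of codes per role, enough to
# drive every branch of the phenotyping rules. Real deployments replace this
# file with their platform's full pre-expanded concept lists (no vocabulary
# traversal is performed — lists must arrive pre-expanded).
metadata:
  version: demo-1
  source: >
    Representative demonstration subset assembled for testing and examples;
    not a clinically complete code list.
roles:
  # ICD-10 (undotted) and SNOMED codes for HIV diagnosis
  hiv_condition: ["B20", "B21", "B22", "B23", "B24", "Z21", "86406008", "62479008"]
  # antiretroviral ingredients (ingredient-level codes)
  art_drug:
    - emtricitabine
    - tenofovir_disoproxil
    - tenofovir_alafenamide
    - dolutegravir
    - darunavir
    - lamivudine
    - abacavir
    - efavirenz
    - raltegravir
    - bictegravir
    - ritonavir
  # the two-ingredient PrEP pairings: FTC + TDF, or FTC + TAF
  prep_component_ftc: [emtricitabine]
  prep_component_tdf: [tenofovir_disoproxil]
  prep_component_taf: [tenofovir_alafenamide]
  # direct-acting HCV antivirals: regimens made only of these are excluded
  hcv_drug: [sofosbuvir, ledipasvir, glecaprevir, pibrentasvir, ribavirin]
  # chronic hepatitis B ICD codes used for the PrEP misclassification check
  hbv_condition: ["B180", "B181", "B191"]
  # LOINC: HIV antigen/antibody screening panels
  hiv_screen_lab: ["75622-1", "7918-6", "29893-5", "56888-1"]
  # LOINC: HIV-1 RNA viral load
  hiv_vl_lab: ["20447-9", "10351-5", "25836-8"]
  # OMOP concept id of the personal-medical-history infectious disease item
  survey_hiv_question: ["1384391"]
  survey_hiv_positive_answers:
    - "Infectious Disease Condition: HIV/AIDS"
  survey_hiv_negative_answers:
    - "None of these"
    - "No"
# fixed-dose combination products -> ingredient-level codes
ingredients:
  truvada: [emtricitabine, tenofovir_disoproxil]
  descovy: [emtricitabine, tenofovir_alafenamide]
  biktarvy: [bictegravir, emtricitabine, tenofovir_alafenamide]
  atripla: [efavirenz, emtricitabine, tenofovir_disoproxil]
  harvoni: [ledipasvir, sofosbuvir]
  mavyret: [glecaprevir, pibrentasvir]
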