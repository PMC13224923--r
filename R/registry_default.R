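# Content of the shipped FY2026 registry, fully explicit per the
# framework's convention that descendant inclusion is never inferred from
# hyphen shorthand: families are used only where the whole family is
# stage-defining (e.g. I25), and named children ship as literals/ranges
# (e.g. N18.30-N18.32 rather than N18.3).
#
# The authoritative artifact is inst/extdata/ckm_registry_fy2026.json;
# this builder exists so the shipped document can be regenerated and so
# the test suite can assert that document and builder agree.

lit <- function(v) code_pattern("literal", v)
fam <- function(v) code_pattern("family", v)
rng <- function(v) code_pattern("range", v)

build_default_registry <- function() {
  sets <- list(
    # ---- stage 1: excess or dysfunctional adiposity -------------------
    code_set("overweight_obesity", "stage_core",
             list(lit("E66.3"), lit("E66.8"), lit("E66.9"),
                  rng("E66.811-E66.813")),
             "chronic"),
    code_set("prediabetes", "stage_core", list(lit("R73.03")), "chronic"),
    # adult BMI codes: optional supporting documentation only, never
    # stage-defining
    code_set("bmi_adult", "supplementary",
             list(rng("Z68.25-Z68.45")), "chronic"),
    code_set("adiposity_supplementary", "supplementary",
             list(lit("R63.5")), "chronic"),

    # ---- stage 2: metabolic risk factors / moderate-high CKD ----------
    code_set("hypertension", "stage_core",
             list(lit("I10"), lit("I11.9"), fam("I12"), lit("I13.10")),
             "chronic"),
    code_set("hypertriglyceridemia", "stage_core",
             list(lit("E78.1")), "chronic"),
    # expanded claims-based proxy; consulted only when the staging config
    # enables it
    code_set("hypertriglyceridemia_expanded", "stage_core",
             list(lit("E78.2")), "chronic"),
    code_set("metabolic_syndrome", "stage_core",
             list(lit("E88.810")), "chronic"),
    code_set("diabetes", "stage_core",
             list(fam("E11"), fam("E10"), fam("E13")), "chronic"),
    # CKD stage 3 (moderate-high risk proxy); N18.4-N18.6 route to
    # stages 3/4B and must never match here
    code_set("ckd_moderate_risk", "stage_core",
             list(rng("N18.30-N18.32")), "chronic"),
    # CKD stage 1-2; qualifies for stage 2 only together with
    # albuminuria/proteinuria codes in the window
    code_set("ckd_mild", "stage_core",
             list(lit("N18.1"), lit("N18.2")), "chronic"),
    code_set("albuminuria_proteinuria", "supplementary",
             list(fam("R80")), "chronic"),
    code_set("nafld_nash", "supplementary",
             list(lit("K76.0"), lit("K75.81")), "chronic"),
    code_set("sleep_apnea", "supplementary",
             list(lit("G47.30"), lit("G47.31"), lit("G47.33"),
                  lit("G47.39")),
             "chronic"),
    code_set("pcos", "supplementary", list(lit("E28.2")), "chronic"),

    # ---- stage 3: claims-only risk equivalents ------------------------
    code_set("ckd_very_high_risk", "stage_core",
             list(lit("N18.4"), lit("N18.5")), "chronic"),
    code_set("ckd_shpt", "supplementary", list(lit("N25.81")), "chronic"),

    # ---- stage 4: clinical CVD ----------------------------------------
    code_set("coronary_heart_disease", "stage_core",
             list(fam("I25"), fam("I20")), "chronic"),
    code_set("ami", "stage_core", list(fam("I21"), fam("I22")), "acute"),
    code_set("heart_failure", "stage_core",
             list(lit("I50.1"), fam("I50.2"), fam("I50.3"), fam("I50.4"),
                  lit("I50.9"), lit("I11.0"), lit("I13.0"), lit("I13.2")),
             "chronic"),
    code_set("atrial_fibrillation", "stage_core",
             list(lit("I48.0"), lit("I48.19"), lit("I48.20"),
                  lit("I48.21")),
             "chronic"),
    code_set("peripheral_artery_disease", "stage_core",
             list(fam("I70.2"), lit("I73.9")), "chronic"),
    code_set("stroke_acute", "stage_core", list(rng("I60-I64")), "acute"),
    code_set("stroke_history", "stage_core",
             list(fam("I69"), lit("Z86.73")), "chronic"),
    # window-level CKD presence, used by the stage-3/4 co-occurrence
    # clauses ("... and/or CKD")
    code_set("ckd_any", "supplementary", list(fam("N18")), "chronic"),
    code_set("kidney_failure", "substage_marker",
             list(lit("N18.6")), "chronic"),
    code_set("dialysis_dependence", "substage_marker",
             list(lit("Z99.2")), "chronic"),
    code_set("kidney_transplant", "substage_marker",
             list(lit("Z94.0")), "chronic")
  )

  stages <- list(
    stage_definition(0L, character(), character(), character(),
                     "absence_of_stage_1_to_4"),
    stage_definition(1L,
                     c("overweight_obesity", "prediabetes"),
                     c("bmi_adult", "adiposity_supplementary"),
                     character(),
                     "adiposity_without_higher_stage_core"),
    stage_definition(2L,
                     c("hypertension", "hypertriglyceridemia",
                       "hypertriglyceridemia_expanded",
                       "metabolic_syndrome", "diabetes",
                       "ckd_moderate_risk", "ckd_mild"),
                     c("albuminuria_proteinuria", "nafld_nash",
                       "sleep_apnea", "pcos"),
                     character(),
                     "any_metabolic_or_moderate_high_ckd"),
    stage_definition(3L,
                     "ckd_very_high_risk",
                     "ckd_shpt",
                     character(),
                     "risk_equivalent_in_ckm_context"),
    stage_definition(4L,
                     c("coronary_heart_disease", "ami", "heart_failure",
                       "atrial_fibrillation", "peripheral_artery_disease",
                       "stroke_acute", "stroke_history"),
                     c("ckd_any", "kidney_failure", "dialysis_dependence",
                       "kidney_transplant"),
                     character(),
                     "clinical_cvd_with_ckm_cooccurrence")
  )

  new_registry("ckm-aha-stages-0-4/ICD-10-CM-FY2026", sets, stages)
}
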