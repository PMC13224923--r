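# ckmstage

Claims-based staging of cardiovascular-kidney-metabolic (CKM) syndrome
with ICD-10-CM diagnosis codes.

CKM syndrome is the American Heart Association's construct for the
intertwined progression of metabolic risk factors, chronic kidney
disease (CKD), and cardiovascular disease (CVD), graded as stages 0-4
(stage 4 split into 4A/4B by kidney failure). There is no single
ICD-10-CM code for the syndrome, so identifying CKM stages in claims or
EHR data requires machine-actionable code sets plus explicit
operational rules. `ckmstage` provides both, for epidemiologists and
health-services researchers building CKM cohorts from administrative
data:

- a **code-set registry** (JSON authoritative, flattened CSV companion)
  mapping stages 0-4 to FY2026 ICD-10-CM codes with explicit literal /
  family / range pattern semantics and subtractive exclusions;
- **encounter-confirmation rules**: a chronic condition is confirmed by
  ≥2 outpatient claims on different dates (≥30 days apart by default)
  or ≥1 inpatient claim; an acute event (MI, stroke) by a single
  inpatient claim;
- **lookback windowing** around an index date (default 24 months,
  half-open, excluding the index day);
- the **hierarchical staging engine**: each stage's eligibility
  predicate is evaluated with its co-occurrence rule and the highest
  qualifying stage is assigned (4 > 3 > 2 > 1 > 0; stage 0 is defined
  by the absence of qualifying codes);
- an **EHR-enhanced mode** for stage 3 (subclinical disease), using
  cardiac biomarkers (NT-proBNP ≥125 pg/mL; sex-specific hs-troponin
  cutoffs), imaging flags (coronary calcification, CT/catheterization
  atherosclerosis), and lab-based KDIGO eGFR-albuminuria risk
  categories;
- a **synthetic cohort generator** producing claims histories with
  known ground-truth stages and deliberate boundary cases, so the whole
  pipeline is testable without any data access.

## Worked example

A patient indexed on 2026-01-01 with a 24-month lookback: two
outpatient essential-hypertension claims (I10) 45 days apart, two
outpatient type-2-diabetes claims (E11.9) 60 days apart, one outpatient
obesity class 3 claim (E66.813) with a BMI support code (Z68.41), and
one inpatient acute-MI claim (I21.3); no kidney-failure codes.

```r
library(ckmstage)

h <- patient_history("case1", list(
  claim_record("case1", "2025-03-01", "outpatient", "I10", "c1"),
  claim_record("case1", "2025-04-15", "outpatient", "I10", "c2"),
  claim_record("case1", "2025-02-01", "outpatient", "E11.9", "c3"),
  claim_record("case1", "2025-04-02", "outpatient", "E11.9", "c4"),
  claim_record("case1", "2025-06-20", "outpatient",
               c("E66.813", "Z68.41"), "c5"),
  claim_record("case1", "2025-09-10", "inpatient", "I21.3", "c6")))

cfg <- staging_config(index = index_spec("2026-01-01", 24))
assign_stage(h, ckm_registry(), cfg)
#> <ckm_assignment> patient case1: stage 4A (claims_only)
#>   qualifying: ami
```

The confirmed hypertension and diabetes qualify the patient for stage 2
(established metabolic disease); the inpatient MI is a clinical CVD
event co-occurring with them, which meets stage 4; with no ESRD (N18.6)
or dialysis-dependence (Z99.2) markers the substage is A. By contrast,
a patient with only confirmed overweight/obesity codes (e.g. E66.9) and
no stage 2-4 core codes in the window is assigned stage 1.

The same run is available from a shell via the thin CLI:

```sh
Rscript inst/cli/ckmstage stage --claims claims.csv --out stages.csv
Rscript inst/cli/ckmstage simulate --n 60 --seed 1 --out-dir cohort/
Rscript inst/cli/ckmstage validate-codesets
Rscript inst/cli/ckmstage export --format csv --out registry.csv
```

## Package layout

- `R/` — registry and pattern matching, claims model, confirmation
  rules, staging engine, measurement criteria, cohort simulator, CLI.
- `inst/extdata/` — the shipped FY2026 registry (JSON + schema) and the
  KDIGO 2012 risk grid.
- `vignettes/ckm-staging.Rmd` — the methods vignette: model,
  assumptions, parameters, and design decisions.
- `tests/testthat/` — unit, property, and end-to-end suites.
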