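---
title: "Staging cardiovascular-kidney-metabolic syndrome from claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging cardiovascular-kidney-metabolic syndrome from claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckmstage)
```

## The staging construct

Cardiovascular-kidney-metabolic (CKM) syndrome describes the mutually
reinforcing progression of metabolic risk factors, chronic kidney
disease (CKD), and cardiovascular disease (CVD). The American Heart
Association grades it on a 0-4 continuum:

* **Stage 0** — no CKM risk factors (defined, in claims, by the absence
  of any stage 1-4 qualifying codes in the lookback window);
* **Stage 1** — excess or dysfunctional adiposity (overweight/obesity,
  abdominal obesity, or prediabetes) *without* other metabolic risk
  factors or CKD;
* **Stage 2** — established metabolic risk factors
  (hypertriglyceridemia, hypertension, metabolic syndrome, diabetes) or
  moderate- to high-risk CKD;
* **Stage 3** — subclinical CVD (subclinical atherosclerosis or
  subclinical heart failure), or risk equivalents (very high-risk CKD,
  high predicted 10-year CVD risk), in a CKM context;
* **Stage 4** — clinical CVD (coronary disease, MI, heart failure,
  atrial fibrillation, peripheral artery disease, stroke) co-occurring
  with any stage 1-3 condition or CKD; **4A** without and **4B** with
  kidney failure (ESRD N18.6 and/or dialysis dependence Z99.2).

Because no single ICD-10-CM code represents the syndrome, `ckmstage`
operationalizes each stage as machine-actionable code sets plus
explicit timing, confirmation, and co-occurrence rules, and assigns
each patient the **highest qualifying stage** (4 > 3 > 2 > 1 > 0).

## The code-set registry

The registry (JSON authoritative, CSV companion for review) maps each
stage to named code sets with a *role* and an *acuity*:

* `stage_core` sets are stage-defining;
* `supplementary` sets (NAFLD/NASH, sleep apnea, PCOS, BMI Z-codes,
  abnormal weight gain, renal secondary hyperparathyroidism) refine
  phenotyping but never define a stage;
* `substage_marker` sets (N18.6, Z99.2, Z94.0) drive the 4A/4B split;
* acuity selects the confirmation rule (chronic vs acute event).

Codes are held dotless and uppercase internally (`E66.813` →
`E66813`); the dotted form is regenerated for display by inserting a
dot after the third character. Patterns come in three kinds:

* `literal` — exact equality;
* `family` — a stem plus all descendants (`I25` matches `I25`,
  `I2510`, ...);
* `range` — same-length bounds under lexicographic comparison with the
  code truncated to the upper bound's length, so `I60-I64` captures
  `I639` and `Z6825-Z6845` captures `Z6841` but not `Z684` (codes
  shorter than the lower bound never match a range).

Every kind can carry subtractive exclusion patterns which always
override a positive match. Hyphen shorthand in clinical documentation
("I25.-") is *never* expanded automatically: where only specific
children are stage-defining (e.g. CKD stage 3 as N18.30-N18.32 rather
than all of N18.3), the shipped registry lists them explicitly as
ranges or literals. The test suite checks the matcher against an
independent explicit-expansion oracle over every registry pattern plus
randomly generated well-formed codes.

The shipped registry is pinned to FY2026 ICD-10-CM conventions and
includes codes new in recent fiscal years (E11.A diabetes in remission,
adult obesity class codes E66.811-E66.813); datasets predating those
codes simply never match them. `validate_registry()` audits structural
findings rather than raising: empty sets, duplicate names, malformed
values, acute acuity outside the MI/stroke event sets, and — the one
content rule with clinical teeth — any stage-2 CKD proxy pattern that
would reach very high-risk CKD (N18.4-N18.5) or kidney failure
(N18.6), which must route to stages 3 and 4B instead.

## Claims model and windowing

Claims arrive in a long CSV (one row per claim-code) and group into
claim records by (patient, claim id, service date, setting). Codes are
de-duplicated within a record, and duplicate rows collapse, so
administrative duplicates cannot fabricate a second confirming claim on
the same date. Only `inpatient` and `outpatient` settings are accepted;
local vocabularies should be mapped before ingestion.

The lookback window is **half-open**: `[index − lookback_months,
index)`. The index day itself is excluded by default so that index-day
events cannot contaminate baseline staging; `include_index_date = TRUE`
closes the bound for sensitivity analyses. Month subtraction is
calendar-based with day-of-month clamping (one month before March 31 is
February 28), which keeps a "24-month lookback" meaning calendar months
rather than 720 days. The default is 24 months with an index date of
2026-01-01; both are ordinary parameters of `index_spec()`.

## Encounter confirmation

A chronic condition is confirmed by ≥2 outpatient claims on different
dates or ≥1 inpatient claim; an acute event (MI, acute stroke) by a
single inpatient claim. Tunables in `confirmation_policy()`:

| parameter | default | meaning |
|---|---|---|
| `min_outpatient_claims` | 2 | distinct outpatient claim dates required |
| `min_day_separation` | 30 days | minimum gap between at least one pair of matching dates |
| `inpatient_sufficient` | `TRUE` | one inpatient claim confirms a chronic set |
| `acute_single_inpatient` | `TRUE` | one inpatient claim confirms an acute set |

Three choices were genuinely open and are resolved as follows. The
30-day gap is treated as a **mandatory minimum** (the alternative
reading — merely illustrative — is recovered by setting
`min_day_separation = 0`); the gap is **inclusive** (exactly 30 days
apart confirms); and it must hold for at least one pair of matching
dates, not all pairs. When a condition is documented both inpatient and
outpatient, the inpatient path takes precedence for the reported
evidence basis, keeping the audit trail deterministic.

## Stage eligibility and the hierarchy

All code sets are evaluated once per patient (confirmation plus raw
presence), then the four predicates run:

* **Stage 2** fires on any confirmed metabolic core condition
  (hypertension I10/I11.9/I12.-/I13.10; pure hypertriglyceridemia
  E78.1; metabolic syndrome E88.810; diabetes E11.-/E10.-/E13.-) or on
  *moderate- to high-risk CKD*: confirmed N18.30-N18.32, or confirmed
  N18.1-N18.2 together with albuminuria/proteinuria codes (R80.-)
  present in the window. Mixed hyperlipidemia (E78.2) participates only
  when `enable_expanded_tg_proxy = TRUE`, reflecting its status as an
  expanded administrative proxy rather than a core definition. R80
  corroboration defaults to raw presence (laboratory findings are
  rarely re-documented across visits); `require_confirmed_albuminuria`
  tightens it.
* **Stage 3** (claims-only) fires on confirmed very high-risk CKD
  (N18.4-N18.5). Kidney-failure markers (confirmed N18.6, or Z99.2
  presence) also satisfy this clause when no clinical CVD is present:
  ESRD and dialysis dependence are KDIGO G5 states, squarely inside the
  "G4-G5 or very high KDIGO risk" risk-equivalent definition, and
  without this routing an ESRD patient with no CVD codes would
  paradoxically land at stage 0 and stage assignment would not be
  monotone in the claims history. Claims-only stage 3 remains a
  conservative proxy — subclinical atherosclerosis and subclinical HF
  are essentially invisible in diagnosis codes — and should be labeled
  as such in analyses.
* **Stage 3** (EHR-enhanced) additionally fires when a subclinical
  criterion is met — positive coronary calcification or CT/cath
  atherosclerosis; NT-proBNP ≥125 pg/mL; hs-troponin T ≥14 (women) /
  ≥22 (men) ng/L; hs-troponin I ≥10 / ≥12 ng/L; an abnormal-echo flag;
  a lab-based KDIGO G4/G5 or very-high category; or an externally
  supplied high 10-year-predicted-risk flag — **and** the patient has
  CKM context (any confirmed stage-1/2 core condition or any CKD code
  present). The 10-year risk construct enters only as a boolean input:
  no risk equation is part of this framework.
* **Stage 4** fires when a clinical CVD set is confirmed (acute MI
  I21.-/I22.- and acute stroke I60-I64 via single inpatient claim;
  chronic coronary disease, HF, AF, PAD, and stroke history via the
  chronic rule) **and** co-occurrence holds: any confirmed stage 1-3
  core condition or any N18.- presence in the window. Stroke
  history/sequelae codes (I69.-, Z86.73) count by default and can be
  switched off for incident-event studies. Hypertensive combination
  codes (I11.0, I13.0, I13.2) are treated as independent set members —
  window-level co-presence — because claims data cannot guarantee
  same-claim pairing of their components.
* **Stage 1** fires on confirmed overweight/obesity or prediabetes
  (R73.03) with the exclusion clause clear. By default the exclusion
  uses *confirmed-condition* semantics: the patient is demoted from
  stage 1 only when some stage 2-4 predicate actually fires. The
  literal code-presence reading is available as
  `strict_raw_exclusion = TRUE`, under which a single uncorroborated
  higher-stage code (e.g. one stray E11.9 claim) pushes an otherwise
  stage-1 patient to stage 0 — the one documented exception to
  monotonicity. BMI Z-codes (Z68.25-Z68.45) are supporting
  documentation only and never define stage 1 on their own.

Substage 4B requires a kidney-failure marker: confirmed N18.6, Z99.2
presence, or — when `transplant_as_kidney_failure = TRUE` — transplant
status Z94.0 together with any N18.- presence. The transplant route is
off by default because transplant recipients' effective risk stratum
depends on graft function, which claims cannot see.

Mode consistency is structural: claims-only staging never consults
measurement panels, and the two modes can differ only through stage-3
eligibility (and through stage 1's exclusion clause, which consumes
it).

## Measurement criteria

All printed thresholds are inclusive, and units are fixed (no unit
inference — silent conversion is a misclassification hazard; uACR is
mg/g). Missing fields always mean "criterion not met", never an error,
so sparse EHR panels degrade gracefully to claims-only behavior; the
one exception is that troponin thresholds cannot be evaluated without
`sex`, which is an error rather than a silent skip. The prediabetes
glucose band is implemented exactly as the staging construct prints it
(100-124 mg/dL) even though 100-125 is a common laboratory convention;
users who want the wider band can pre-round. Metabolic-syndrome
counting follows the classic ≥3-of-5 rule (waist, low HDL-C, TG ≥150,
BP ≥130/≥80 or antihypertensives, fasting glucose ≥100), with
sex- and ancestry-adjusted waist cutoffs.

The KDIGO eGFR-albuminuria grid ships as an editable CSV
(`inst/extdata/kdigo_2012_risk_grid.csv`, transcribed from the KDIGO
2012 classification) rather than being hard-coded, for transparency and
because the grid is referenced, not redefined, by the CKM construct.
`kdigo_category()` returns an explicit not-computable result when
either input is missing.

## The synthetic cohort generator

`generate_cohort()` produces claims histories with known ground-truth
stages. Non-boundary patients are constructed to satisfy their target
stage's predicates under the *default* policy and to fail every higher
stage: stage-2 patients draw a confirmed metabolic condition (or a CKD
proxy with albuminuria), stage-4A patients add a CVD event (inpatient
acute or confirmed chronic) to a confirmed stage-2 condition, and
stage-4B patients add ESRD or dialysis codes. Boundary patients violate
exactly one rule each — a 29-day gap, a single outpatient chronic
claim, an event on the index date, or E78.2 with the proxy off — so the
windowing and confirmation edges are exercised in the direction the
violated rule dictates. A companion generator emits stage-3 measurement
panels sitting exactly on the printed biomarker thresholds. Dates are
drawn uniformly within the lookback window and then adjusted to meet or
violate gap constraints; all randomness derives deterministically from
the cohort seed, so outputs are byte-identical across re-runs.

The generator emulates code placement and claim timing only. It does
**not** model utilization intensity, coding error, under-documentation,
comorbidity correlation, or demographic structure beyond the sex and
ancestry flags the thresholds need. Perfect ground-truth recovery on
synthetic cohorts therefore demonstrates that the engine implements its
stated rules exactly — not that those rules recover clinical truth in
real data, which requires empirical validation against chart review or
registries.

## Numerical and testing choices

Everything in the pipeline is deterministic given inputs and
configuration; there is no unseeded randomness anywhere in staging.
Degenerate inputs have defined behavior: empty histories stage 0,
header-only CSVs yield empty cohorts, and an empty measurement panel
meets no criterion. The test suite sizes were chosen to exercise the
space at desk scale: a 600-patient uniform cohort (100 per label) for
ground-truth recovery, 500 seeded random-augmentation trials for the
monotonicity property (appending claims never lowers the assigned
stage under the default configuration), and the full registry × (all
registry codes + 200 random codes) cross for matcher-oracle
equivalence.

## Known limitations

* Claims-only stage 3 under-ascertains subclinical disease by
  construction; treat it as a conservative very-high-risk-CKD proxy.
* Code position (primary vs secondary diagnosis), provider specialty,
  and pharmacy claims are not used.
* Staging is cross-sectional at one index date; current-versus-worst-
  ever and time-updated staging are study-level designs outside this
  package's scope.
* The registry carries the stage-defining and supplementary codes of
  the framework, not the complete ICD-10-CM tabular list; it is
  schema-extensible for local additions (e.g. locally used insulin-
  resistance codes, which the framework names but does not enumerate).
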