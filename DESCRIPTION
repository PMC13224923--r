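Package: ckmstage
Title: Claims-Based Staging of Cardiovascular-Kidney-Metabolic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Machine-actionable ICD-10-CM code sets and a hierarchical
    staging engine for cardiovascular-kidney-metabolic (CKM) syndrome
    stages 0-4, following the American Heart Association staging
    construct. Provides a JSON code-set registry with explicit
    descendant and exclusion semantics, encounter-confirmation rules for
    chronic and acute conditions in administrative claims (two
    outpatient claims on different dates or one inpatient claim),
    lookback windowing around an index date, claims-only and
    EHR-enhanced staging modes (structured labs, cardiac biomarkers,
    imaging flags, and KDIGO eGFR-albuminuria risk categories), and a
    synthetic-cohort generator with known ground-truth stages for
    end-to-end testing and sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
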