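test_that("adiposity thresholds are inclusive and ancestry-adjusted", {
  p <- function(...) measurement_panel("p", ...)
  expect_true(adiposity_met(p(sex = "male", bmi = 25)))
  expect_false(adiposity_met(p(sex = "male", bmi = 24.9)))
  expect_true(adiposity_met(p(sex = "male", asian_ancestry = TRUE,
                              bmi = 23)))
  expect_false(adiposity_met(p(sex = "male", asian_ancestry = TRUE,
                               bmi = 22.9)))
  expect_true(adiposity_met(p(sex = "female", waist_cm = 88)))
  expect_false(adiposity_met(p(sex = "female", waist_cm = 80)))
  expect_true(adiposity_met(p(sex = "female", asian_ancestry = TRUE,
                              waist_cm = 80)))
  expect_true(adiposity_met(p(sex = "male", waist_cm = 102)))
  expect_true(adiposity_met(p(sex = "male", asian_ancestry = TRUE,
                              waist_cm = 90)))
  expect_false(adiposity_met(p(sex = "female", bmi = 24, waist_cm = 80)))
  expect_false(adiposity_met(p()))
})

test_that("the prediabetes bands are closed exactly as printed", {
  g <- function(v) dysfunctional_adiposity_met(
    measurement_panel("p", fasting_glucose_mg_dl = v))
  expect_false(g(99)); expect_true(g(100)); expect_true(g(124))
  expect_false(g(125))
  a <- function(v) dysfunctional_adiposity_met(
    measurement_panel("p", hba1c_percent = v))
  expect_false(a(5.6)); expect_true(a(5.7)); expect_true(a(6.4))
  expect_false(a(6.5))
})

test_that("subclinical HF thresholds are sex-specific and inclusive", {
  p <- function(...) measurement_panel("p", ...)
  expect_true(subclinical_hf_met(p(sex = "male", ntprobnp_pg_ml = 125)))
  expect_false(subclinical_hf_met(p(sex = "male",
                                    ntprobnp_pg_ml = 124.9)))
  expect_true(subclinical_hf_met(p(sex = "female", hs_tnt_ng_l = 14)))
  expect_false(subclinical_hf_met(p(sex = "male", hs_tnt_ng_l = 14)))
  expect_true(subclinical_hf_met(p(sex = "male", hs_tnt_ng_l = 22)))
  expect_true(subclinical_hf_met(p(sex = "female", hs_tni_ng_l = 10)))
  expect_false(subclinical_hf_met(p(sex = "male", hs_tni_ng_l = 10)))
  expect_true(subclinical_hf_met(p(sex = "male", hs_tni_ng_l = 12)))
  expect_true(subclinical_hf_met(p(echo_abnormal = TRUE)))
  expect_false(subclinical_hf_met(p()))
  expect_error(subclinical_hf_met(p(hs_tnt_ng_l = 20)), "sex")
})

test_that("subclinical ASCVD needs an imaging flag", {
  expect_true(subclinical_ascvd_met(
    measurement_panel("p", cac_positive = TRUE)))
  expect_true(subclinical_ascvd_met(
    measurement_panel("p", ct_or_cath_atherosclerosis = TRUE)))
  expect_false(subclinical_ascvd_met(measurement_panel("p")))
})

test_that("metabolic-syndrome counting matches its five components", {
  p <- measurement_panel("p", sex = "male", triglycerides_mg_dl = 150,
                         fasting_glucose_mg_dl = 100, sbp_mmhg = 130)
  expect_identical(mets_component_count(p), 3L)
  expect_true(mets_met(p))
  expect_identical(mets_component_count(
    measurement_panel("p", sex = "male", hdl_mg_dl = 39)), 1L)
  expect_identical(mets_component_count(
    measurement_panel("p", sex = "male", hdl_mg_dl = 40)), 0L)
  expect_identical(mets_component_count(
    measurement_panel("p", sex = "female", hdl_mg_dl = 49)), 1L)
  expect_identical(mets_component_count(
    measurement_panel("p", on_antihypertensives = TRUE)), 1L)
  expect_identical(mets_component_count(
    measurement_panel("p", dbp_mmhg = 80)), 1L)
  expect_identical(mets_component_count(measurement_panel("p")), 0L)
  expect_false(mets_met(measurement_panel("p")))
  # decomposition: the count equals the sum of component predicates
  panel <- measurement_panel("p", sex = "female", asian_ancestry = TRUE,
                             waist_cm = 80, hdl_mg_dl = 45,
                             triglycerides_mg_dl = 200, sbp_mmhg = 120,
                             dbp_mmhg = 70, fasting_glucose_mg_dl = 101)
  parts <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_identical(mets_component_count(panel), sum(parts))
})

test_that("KDIGO bands and the risk grid classify as published", {
  k <- kdigo_category(95, 10)
  expect_identical(c(k$g_stage, k$a_stage, k$risk), c("G1", "A1", "low"))
  k2 <- kdigo_category(25, 10)
  expect_identical(k2$g_stage, "G4")
  expect_identical(k2$risk, "very_high")
  expect_identical(kdigo_category(14, 10)$g_stage, "G5")
  expect_identical(kdigo_category(15, 10)$g_stage, "G4")
  expect_identical(kdigo_category(29, 10)$g_stage, "G4")
  expect_identical(kdigo_category(30, 10)$g_stage, "G3b")
  expect_identical(kdigo_category(45, 10)$g_stage, "G3a")
  expect_identical(kdigo_category(60, 29.9)$a_stage, "A1")
  expect_identical(kdigo_category(60, 30)$a_stage, "A2")
  expect_identical(kdigo_category(60, 300)$a_stage, "A2")
  expect_identical(kdigo_category(60, 301)$a_stage, "A3")
  expect_identical(kdigo_category(75, 50)$risk, "moderate")
  expect_identical(kdigo_category(50, 400)$risk, "very_high")
})

test_that("missing KDIGO inputs are explicitly not computable", {
  k <- kdigo_category(NA, 10)
  expect_false(k$computable)
  expect_true(is.na(k$risk))
  expect_false(kdigo_stage3_equivalent(measurement_panel("p")))
})

test_that("KDIGO risk is monotone in eGFR and uACR", {
  risk_rank <- c(low = 1, moderate = 2, high = 3, very_high = 4)
  egfrs <- c(95, 75, 50, 35, 20, 10)
  uacrs <- c(10, 100, 500)
  for (i in seq_along(egfrs)) {
    for (j in seq_along(uacrs)) {
      r <- risk_rank[kdigo_category(egfrs[i], uacrs[j])$risk]
      if (i > 1) {
        expect_gte(r, risk_rank[kdigo_category(egfrs[i - 1],
                                               uacrs[j])$risk])
      }
      if (j > 1) {
        expect_gte(r, risk_rank[kdigo_category(egfrs[i],
                                               uacrs[j - 1])$risk])
      }
    }
  }
})

test_that("an empty panel meets no criterion", {
  p <- measurement_panel("p")
  expect_false(adiposity_met(p))
  expect_false(dysfunctional_adiposity_met(p))
  expect_false(subclinical_hf_met(p))
  expect_false(subclinical_ascvd_met(p))
  expect_identical(mets_component_count(p), 0L)
})

test_that("panels reject unknown fields and negative values", {
  expect_error(measurement_panel("p", glucose = 100), "unknown")
  expect_error(measurement_panel("p", bmi = -1), "non-negative")
})

test_that("measurement CSVs parse into panels", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c(
    "patient_id,sex,asian_ancestry,field,value,date",
    "p1,female,false,ntprobnp_pg_ml,125,2025-11-01",
    "p1,female,false,cac_positive,true,2025-10-01",
    "p2,male,true,bmi,23,2025-09-01"), path)
  panels <- read_measurements(path)
  expect_identical(names(panels), c("p1", "p2"))
  expect_true(subclinical_hf_met(panels$p1))
  expect_true(subclinical_ascvd_met(panels$p1))
  expect_true(adiposity_met(panels$p2))
})
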