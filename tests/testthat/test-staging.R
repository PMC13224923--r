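reg <- ckm_registry()
cfg <- staging_config(index = default_index())

test_that("the claims-only use case is assigned stage 4A", {
  a <- assign_stage(worked_example_history(), reg, cfg)
  expect_identical(a$stage, 4L)
  expect_identical(a$substage, "A")
  expect_true(a$eligibilities[["2"]])   # confirmed I10 / E11.9
  expect_true(a$eligibilities[["4"]])   # inpatient MI with co-occurrence
  expect_true("ami" %in% a$qualifying_sets)
})

test_that("adiposity without higher-stage codes is stage 1", {
  for (code in c("E66.9", "E66.3", "E66.8", "R73.03")) {
    a <- assign_stage(contrast_history(code = code), reg, cfg)
    expect_identical(a$stage, 1L)
    expect_identical(a$substage, "none")
  }
})

test_that("BMI support codes alone never define stage 1", {
  h <- history_of("p",
    cl("2025-02-01", "outpatient", "Z68.27"),
    cl("2025-04-01", "outpatient", "Z68.27"))
  expect_identical(assign_stage(h, reg, cfg)$stage, 0L)
})

test_that("an empty or unrelated history is stage 0", {
  expect_identical(assign_stage(patient_history("p"), reg, cfg)$stage, 0L)
  h <- history_of("p", cl("2025-02-01", "outpatient", "J06.9"))
  expect_identical(assign_stage(h, reg, cfg)$stage, 0L)
})

test_that("confirmed metabolic conditions give stage 2", {
  for (code in c("I10", "I11.9", "I13.10", "E78.1", "E88.810", "E11.9",
                 "E11.A", "N18.31")) {
    h <- history_of("p",
      cl("2025-01-05", "outpatient", code),
      cl("2025-03-05", "outpatient", code))
    expect_identical(assign_stage(h, reg, cfg)$stage, 2L,
                     label = paste("code", code))
  }
})

test_that("mild CKD qualifies for stage 2 only with albuminuria codes", {
  base <- list(cl("2025-01-05", "outpatient", "N18.2"),
               cl("2025-03-05", "outpatient", "N18.2"))
  h_no <- do.call(history_of, c("p", base))
  expect_identical(assign_stage(h_no, reg, cfg)$stage, 0L)
  h_yes <- do.call(history_of,
                   c("p", base,
                     list(cl("2025-05-01", "outpatient", "R80.9"))))
  expect_identical(assign_stage(h_yes, reg, cfg)$stage, 2L)
  # configurable: R80 itself must be confirmed
  strict <- staging_config(index = default_index(),
                           require_confirmed_albuminuria = TRUE)
  expect_identical(assign_stage(h_yes, reg, strict)$stage, 0L)
})

test_that("the expanded triglyceride proxy is off by default", {
  h <- history_of("p",
    cl("2025-01-05", "outpatient", "E78.2"),
    cl("2025-03-05", "outpatient", "E78.2"))
  expect_identical(assign_stage(h, reg, cfg)$stage, 0L)
  on <- staging_config(index = default_index(),
                       enable_expanded_tg_proxy = TRUE)
  expect_identical(assign_stage(h, reg, on)$stage, 2L)
})

test_that("supplementary risk-enhancers are never stage-defining", {
  for (code in c("K76.0", "K75.81", "G47.33", "E28.2", "R63.5")) {
    h <- history_of("p",
      cl("2025-01-05", "outpatient", code),
      cl("2025-03-05", "outpatient", code))
    expect_identical(assign_stage(h, reg, cfg)$stage, 0L,
                     label = paste("code", code))
  }
})

test_that("very high-risk CKD is stage 3 in claims-only mode", {
  for (code in c("N18.4", "N18.5")) {
    h <- history_of("p",
      cl("2025-01-05", "outpatient", code),
      cl("2025-03-05", "outpatient", code))
    a <- assign_stage(h, reg, cfg)
    expect_identical(a$stage, 3L, label = code)
    expect_identical(a$substage, "none")
  }
  # kidney failure without clinical CVD routes to stage 3, not 0
  h6 <- history_of("p", cl("2025-01-05", "inpatient", "N18.6"))
  expect_identical(assign_stage(h6, reg, cfg)$stage, 3L)
})

test_that("stage 4 needs clinical CVD plus CKM co-occurrence", {
  # inpatient MI alone: no adiposity/metabolic/CKD context
  lone <- history_of("p", cl("2025-09-10", "inpatient", "I21.3"))
  expect_identical(assign_stage(lone, reg, cfg)$stage, 0L)
  # chronic HF confirmed + moderate CKD confirmed
  h <- history_of("p",
    cl("2025-01-05", "outpatient", "I50.9"),
    cl("2025-03-05", "outpatient", "I50.9"),
    cl("2025-02-05", "outpatient", "N18.30"),
    cl("2025-04-05", "outpatient", "N18.30"))
  expect_identical(assign_stage(h, reg, cfg)$stage, 4L)
  # raw CKD presence (single N18 claim) satisfies the clause too
  h2 <- history_of("p",
    cl("2025-09-10", "inpatient", "I21.3"),
    cl("2025-05-05", "outpatient", "N18.2"))
  expect_identical(assign_stage(h2, reg, cfg)$stage, 4L)
  # a single outpatient CVD claim is not a confirmed chronic condition
  h3 <- history_of("p",
    cl("2025-01-05", "outpatient", "I50.9"),
    cl("2025-02-05", "outpatient", "E66.9"),
    cl("2025-04-05", "outpatient", "E66.9"))
  expect_identical(assign_stage(h3, reg, cfg)$stage, 1L)
})

test_that("substage separates kidney failure from its absence", {
  base <- list(cl("2025-01-05", "outpatient", "I10"),
               cl("2025-03-05", "outpatient", "I10"),
               cl("2025-09-10", "inpatient", "I21.3"))
  a4a <- assign_stage(do.call(history_of, c("p", base)), reg, cfg)
  expect_identical(a4a$substage, "A")
  expect_false(any(c("kidney_failure", "dialysis_dependence") %in%
                     a4a$qualifying_sets))

  withkf <- c(base, list(cl("2025-06-01", "inpatient", "N18.6")))
  a4b <- assign_stage(do.call(history_of, c("p", withkf)), reg, cfg)
  expect_identical(a4b$substage, "B")
  expect_true("kidney_failure" %in% a4b$qualifying_sets)

  # Z99.2 presence alone marks kidney failure
  withdial <- c(base, list(cl("2025-06-01", "outpatient", "Z99.2")))
  a4b2 <- assign_stage(do.call(history_of, c("p", withdial)), reg, cfg)
  expect_identical(a4b2$substage, "B")

  # transplant status counts only when configured
  withtx <- c(base, list(cl("2025-06-01", "outpatient",
                            c("Z94.0", "N18.3"))))
  expect_identical(assign_stage(do.call(history_of, c("p", withtx)),
                                reg, cfg)$substage, "A")
  txcfg <- staging_config(index = default_index(),
                          transplant_as_kidney_failure = TRUE)
  expect_identical(assign_stage(do.call(history_of, c("p", withtx)),
                                reg, txcfg)$substage, "B")
})

test_that("stroke history counts as chronic CVD unless disabled", {
  h <- history_of("p",
    cl("2025-01-05", "outpatient", "Z86.73"),
    cl("2025-03-05", "outpatient", "Z86.73"),
    cl("2025-02-05", "outpatient", "I10"),
    cl("2025-04-05", "outpatient", "I10"))
  expect_identical(assign_stage(h, reg, cfg)$stage, 4L)
  incident <- staging_config(index = default_index(),
                             count_stroke_history = FALSE)
  expect_identical(assign_stage(h, reg, incident)$stage, 2L)
})

test_that("the reported stage equals the maximum eligible stage", {
  set.seed(55)
  for (trial in 1:40) {
    lab <- sample(c("0", "1", "2", "3", "4A", "4B"), 1L)
    p <- generate_patient(lab, seed = 10000 + trial)
    a <- assign_stage(p$history, reg, cfg)
    expected <- if (any(a$eligibilities)) {
      max(as.integer(names(a$eligibilities))[a$eligibilities])
    } else 0L
    expect_identical(a$stage, expected)
    expect_identical(a$substage != "none", a$stage == 4L)
  }
})

test_that("strict raw exclusion demotes adiposity with a stray core code", {
  h <- history_of("p",
    cl("2025-01-05", "outpatient", "E66.9"),
    cl("2025-03-05", "outpatient", "E66.9"),
    cl("2025-05-01", "outpatient", "E11.9"))   # single, unconfirmed
  expect_identical(assign_stage(h, reg, cfg)$stage, 1L)
  strict <- staging_config(index = default_index(),
                           strict_raw_exclusion = TRUE)
  expect_identical(assign_stage(h, reg, strict)$stage, 0L)
})

test_that("claims-only mode never consults the measurement panel", {
  panel <- measurement_panel("p", sex = "female", ntprobnp_pg_ml = 5000,
                             cac_positive = TRUE)
  h <- contrast_history("p")
  h$panel <- panel
  a_claims <- assign_stage(h, reg, cfg)
  expect_identical(a_claims$stage, 1L)
  ecfg <- staging_config("ehr_enhanced", index = default_index())
  a_ehr <- assign_stage(h, reg, ecfg)
  expect_identical(a_ehr$stage, 3L)
  # the two modes may differ only through stage-3 eligibility (and the
  # stage-1 exclusion clause that consumes it)
  expect_identical(a_claims$eligibilities[c("2", "4")],
                   a_ehr$eligibilities[c("2", "4")])
  expect_true(a_ehr$eligibilities[["3"]])
  expect_false(a_claims$eligibilities[["3"]])
})

test_that("subclinical findings require CKM context in EHR mode", {
  ecfg <- staging_config("ehr_enhanced", index = default_index())
  panel <- measurement_panel("p", sex = "male", cac_positive = TRUE)
  no_context <- patient_history("p")
  expect_identical(assign_stage(no_context, reg, ecfg, panel = panel)$stage,
                   0L)
  with_context <- contrast_history("p")
  expect_identical(assign_stage(with_context, reg, ecfg,
                                panel = panel)$stage, 3L)
})

test_that("stage_patients returns one ordered row per patient", {
  hs <- list(worked_example_history("b"), contrast_history("a"))
  df <- stage_patients(hs, reg, cfg)
  expect_identical(df$patient_id, c("a", "b"))
  expect_identical(df$stage, c(1L, 4L))
  expect_identical(df$substage, c("none", "A"))
  expect_match(df$qualifying_sets[2], "ami")
})
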