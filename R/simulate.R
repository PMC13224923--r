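# Synthetic claims cohorts with known ground-truth stages. Non-boundary
# patients are constructed to satisfy their target stage's predicates
# under the default confirmation policy and to fail every higher stage;
# boundary patients violate exactly one rule (day gap, claim count,
# index-date timing, or the expanded-proxy switch) so windowing and
# confirmation edges are exercised end to end.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483587) + 1L
}

stage_labels <- c("0", "1", "2", "3", "4A", "4B")

# concrete code catalogue per stage-defining condition, covering every
# code row of the shipped registry
sim_catalogue <- list(
  stage1 = c("E663", "E668", "E669", "E66811", "E66812", "E66813",
             "R7303"),
  bmi = c("Z6825", "Z6830", "Z6835", "Z6841", "Z6845"),
  stage2_simple = list(
    hypertension = c("I10", "I119", "I120", "I129", "I1310"),
    hypertriglyceridemia = "E781",
    metabolic_syndrome = "E88810",
    diabetes = c("E119", "E11A", "E1165", "E109", "E139")),
  ckd_moderate = c("N1830", "N1831", "N1832"),
  ckd_mild = c("N181", "N182"),
  albuminuria = c("R809", "R801"),
  ckd_very_high = c("N184", "N185"),
  cvd_acute = c("I213", "I214", "I21A1", "I220", "I600", "I610",
                "I639", "I64"),
  cvd_chronic = c("I2510", "I209", "I501", "I5020", "I509", "I480",
                  "I4819", "I702", "I739", "I6930", "Z8673"),
  kidney_failure = c("N186"),
  dialysis = c("Z992"),
  neutral = c("J069", "M545", "K219", "B349", "H6690", "L039", "M7960",
              "R519")
)

sim_dates <- function(index, n, gap = NULL) {
  w <- lookback_window(index)
  span <- as.integer(w$upper - 1L - w$lower)
  if (is.null(gap)) {
    w$lower + sample.int(span + 1L, n, replace = TRUE) - 1L
  } else {
    d1 <- w$lower + sample.int(span + 1L - gap, 1L) - 1L
    c(d1, d1 + gap)
  }
}

sim_chronic_pair <- function(pid, code, index, claim_prefix,
                             gap = NULL, extra_codes = NULL) {
  if (is.null(gap)) gap <- sample(30:180, 1L)
  d <- sim_dates(index, 2L, gap = gap)
  list(
    claim_record(pid, d[1L], "outpatient", c(code, extra_codes),
                 paste0(claim_prefix, "a")),
    claim_record(pid, d[2L], "outpatient", code,
                 paste0(claim_prefix, "b")))
}

sim_inpatient <- function(pid, code, index, claim_id) {
  list(claim_record(pid, sim_dates(index, 1L), "inpatient", code,
                    claim_id))
}

sim_stage2_condition <- function(pid, index, claim_prefix) {
  kind <- sample(c("simple", "ckd_moderate", "ckd_mild_alb"), 1L,
                 prob = c(0.7, 0.15, 0.15))
  if (kind == "simple") {
    set <- sample(names(sim_catalogue$stage2_simple), 1L)
    code <- sample(sim_catalogue$stage2_simple[[set]], 1L)
    sim_chronic_pair(pid, code, index, claim_prefix)
  } else if (kind == "ckd_moderate") {
    code <- sample(sim_catalogue$ckd_moderate, 1L)
    sim_chronic_pair(pid, code, index, claim_prefix)
  } else {
    code <- sample(sim_catalogue$ckd_mild, 1L)
    c(sim_chronic_pair(pid, code, index, claim_prefix),
      list(claim_record(pid, sim_dates(index, 1L), "outpatient",
                        sample(sim_catalogue$albuminuria, 1L),
                        paste0(claim_prefix, "r"))))
  }
}

sim_cvd_event <- function(pid, index, claim_prefix) {
  if (stats::runif(1) < 0.5) {
    sim_inpatient(pid, sample(sim_catalogue$cvd_acute, 1L), index,
                  paste0(claim_prefix, "e"))
  } else {
    sim_chronic_pair(pid, sample(sim_catalogue$cvd_chronic, 1L), index,
                     claim_prefix)
  }
}

boundary_templates <- c("gap29", "single_chronic", "index_date_event",
                        "expanded_tg")

sim_boundary <- function(pid, template, index) {
  switch(template,
    gap29 = list(
      claims = sim_chronic_pair(pid, "I10", index, "b", gap = 29L),
      nominal = "2", expected = "0",
      note = "29-day gap fails the >=30-day chronic rule"),
    single_chronic = list(
      claims = list(claim_record(pid, sim_dates(index, 1L),
                                 "outpatient", "I10", "b1")),
      nominal = "2", expected = "0",
      note = "single outpatient claim fails the 2-claim chronic rule"),
    index_date_event = list(
      claims = c(sim_chronic_pair(pid, "I10", index, "b"),
                 list(claim_record(pid, index$index_date, "inpatient",
                                   "I213", "be"))),
      nominal = "4A", expected = "2",
      note = paste("inpatient MI on the index date is outside the",
                   "half-open lookback window")),
    expanded_tg = list(
      claims = sim_chronic_pair(pid, "E782", index, "b"),
      nominal = "2", expected = "0",
      note = "E78.2 qualifies only under the expanded TG proxy"),
    stop("unknown boundary template '", template, "'", call. = FALSE))
}

#' Measurement panel for an EHR-enhanced stage-3 truth
#'
#' Emits a panel sitting exactly on one printed subclinical threshold
#' (NT-proBNP 125 pg/mL, sex-specific troponin cutoffs, or a positive
#' imaging flag), for boundary testing of the EHR-enhanced pathway.
#'
#' @param patient_id Patient identifier.
#' @param seed Integer seed.
#' @return A `ckm_panel`.
#' @export
generate_stage3_panel <- function(patient_id, seed) {
  with_local_seed(seed, {
    sex <- sample(c("female", "male"), 1L)
    kind <- sample(c("bnp", "tnt", "tni", "cac"), 1L)
    args <- list(patient_id = patient_id, sex = sex)
    args[[switch(kind,
                 bnp = "ntprobnp_pg_ml",
                 tnt = "hs_tnt_ng_l",
                 tni = "hs_tni_ng_l",
                 cac = "cac_positive")]] <- switch(kind,
      bnp = 125,
      tnt = if (sex == "female") 14 else 22,
      tni = if (sex == "female") 10 else 12,
      cac = TRUE)
    do.call(measurement_panel, args)
  })
}

#' Generate one labeled synthetic patient
#'
#' Deterministic given the seed. Non-boundary patients carry confirmed
#' core codes for their target stage (e.g. stage 2: two outpatient
#' hypertension claims >= 30 days apart; stage 4A: an inpatient MI claim
#' plus a confirmed stage-2 condition and no kidney-failure markers;
#' stage 4B adds ESRD or dialysis dependence) and nothing that would
#' qualify a higher stage. Boundary patients violate exactly one rule.
#'
#' @param label Target label: one of `"0","1","2","3","4A","4B"`.
#' @param seed Integer seed.
#' @param index An [index_spec()]; claims are placed inside its window.
#' @param boundary Generate a boundary patient instead (labels are then
#'   taken from the template, not from `label`).
#' @param template Boundary template name (one of `"gap29"`,
#'   `"single_chronic"`, `"index_date_event"`, `"expanded_tg"`);
#'   sampled when `NULL`.
#' @param patient_id Identifier; defaults to a seed-derived id.
#' @param ehr For stage-3 targets, construct an EHR-enhanced truth
#'   (threshold measurement panel plus adiposity context) instead of a
#'   claims-only very-high-risk-CKD truth.
#' @return A `ckm_labeled` list: `history`, optional `panel`,
#'   `truth_stage`, `truth_substage`, `is_boundary`,
#'   `expected_default_stage`, `template`, `note`.
#' @export
generate_patient <- function(label, seed,
                             index = index_spec("2026-01-01", 24L),
                             boundary = FALSE, template = NULL,
                             patient_id = sprintf("S%09d", seed),
                             ehr = FALSE) {
  label <- as.character(label)
  if (!boundary && !label %in% stage_labels)
    stop("unknown stage label '", label, "'", call. = FALSE)
  with_local_seed(seed, {
    pid <- patient_id
    panel <- NULL
    note <- ""
    if (boundary) {
      if (is.null(template)) template <- sample(boundary_templates, 1L)
      b <- sim_boundary(pid, template, index)
      claims <- b$claims
      truth <- b$nominal
      expected <- b$expected
      note <- b$note
    } else {
      template <- NA_character_
      expected <- label
      truth <- label
      claims <- switch(label,
        "0" = {
          d <- sim_dates(index, sample(2:4, 1L))
          lapply(seq_along(d), function(i)
            claim_record(pid, d[i], "outpatient",
                         sample(sim_catalogue$neutral, 1L),
                         paste0("n", i)))
        },
        "1" = {
          code <- sample(sim_catalogue$stage1, 1L)
          extra <- if (stats::runif(1) < 0.3)
            sample(sim_catalogue$bmi, 1L) else NULL
          sim_chronic_pair(pid, code, index, "s1", extra_codes = extra)
        },
        "2" = sim_stage2_condition(pid, index, "s2"),
        "3" = {
          if (ehr) {
            panel <- generate_stage3_panel(pid, derive_seed(seed, 1L))
            sim_chronic_pair(pid, sample(c("E669", "E66813"), 1L),
                             index, "s1")
          } else {
            code <- sample(sim_catalogue$ckd_very_high, 1L)
            base <- if (stats::runif(1) < 0.5)
              sim_inpatient(pid, code, index, "s3i")
            else sim_chronic_pair(pid, code, index, "s3")
            if (stats::runif(1) < 0.3)
              base <- c(base, sim_chronic_pair(pid, "I10", index, "s2"))
            base
          }
        },
        "4A" = c(sim_stage2_condition(pid, index, "s2"),
                 sim_cvd_event(pid, index, "s4")),
        "4B" = {
          kf <- if (stats::runif(1) < 0.5)
            sim_inpatient(pid, "N186", index, "kf")
          else list(claim_record(pid, sim_dates(index, 1L),
                                 "outpatient", "Z992", "kf1"))
          c(sim_chronic_pair(pid, "I10", index, "s2"),
            sim_cvd_event(pid, index, "s4"), kf)
        })
      if (label == "3" && ehr) note <- "EHR-enhanced stage-3 truth"
    }
    truth_stage <- as.integer(substr(truth, 1L, 1L))
    truth_substage <- if (nchar(truth) > 1L) substr(truth, 2L, 2L)
      else "none"
    structure(list(
      history = patient_history(pid, claims, panel),
      panel = panel,
      truth_stage = truth_stage,
      truth_substage = truth_substage,
      is_boundary = boundary,
      expected_default_stage = expected,
      template = template,
      note = note), class = "ckm_labeled")
  })
}

#' Cohort specification
#'
#' @param n_patients Number of patients (>= 1).
#' @param stage_mix Named proportions over labels
#'   `"0","1","2","3","4A","4B"`, summing to 1 (tolerance 1e-9).
#' @param boundary_fraction Share of patients replaced by boundary-case
#'   templates (default 0).
#' @param seed Integer master seed.
#' @param index_date,lookback_months Index specification for the cohort.
#' @return A `ckm_cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        stage_mix = stats::setNames(rep(1 / 6, 6),
                                                    stage_labels),
                        boundary_fraction = 0,
                        seed = 1L,
                        index_date = "2026-01-01",
                        lookback_months = 24L) {
  stopifnot(n_patients >= 1L)
  if (is.null(names(stage_mix)) ||
      !setequal(names(stage_mix), stage_labels))
    stop("stage_mix must be named over labels ",
         paste(stage_labels, collapse = ","), call. = FALSE)
  stage_mix <- stage_mix[stage_labels]
  if (any(stage_mix < 0 | stage_mix > 1) ||
      abs(sum(stage_mix) - 1) > 1e-9)
    stop("stage_mix proportions must lie in [0,1] and sum to 1",
         call. = FALSE)
  stopifnot(boundary_fraction >= 0, boundary_fraction <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 stage_mix = stage_mix,
                 boundary_fraction = boundary_fraction,
                 seed = as.integer(seed),
                 index = index_spec(index_date, lookback_months)),
            class = "ckm_cohort_spec")
}

# largest-remainder rounding of n * proportions to integers summing to n
round_counts <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(prop))
}

#' Generate a labeled synthetic cohort
#'
#' Stage counts follow the specification's proportions under
#' deterministic largest-remainder rounding; boundary patients (if any)
#' cycle through the boundary templates. Byte-identical output for a
#' fixed spec.
#'
#' @param spec A [cohort_spec()].
#' @return A `ckm_cohort`: list with `patients` (list of `ckm_labeled`),
#'   `truth` (data.frame `patient_id,truth_stage,truth_substage,
#'   is_boundary`), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ckm_cohort_spec"))
  counts <- round_counts(spec$n_patients, spec$stage_mix)
  n_boundary <- as.integer(round(spec$boundary_fraction *
                                   spec$n_patients))
  labels <- rep(names(counts), counts)
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%05d", i)
    s <- derive_seed(spec$seed, i)
    if (i <= n_boundary) {
      tmpl <- boundary_templates[((i - 1L) %% length(boundary_templates))
                                 + 1L]
      patients[[i]] <- generate_patient(labels[i], s, spec$index,
                                        boundary = TRUE,
                                        template = tmpl,
                                        patient_id = pid)
    } else {
      patients[[i]] <- generate_patient(labels[i], s, spec$index,
                                        patient_id = pid)
    }
  }
  truth <- data.frame(
    patient_id = vapply(patients, function(p) p$history$patient_id, ""),
    truth_stage = vapply(patients, `[[`, 0L, "truth_stage"),
    truth_substage = vapply(patients, `[[`, "", "truth_substage"),
    is_boundary = vapply(patients, `[[`, TRUE, "is_boundary"),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, truth = truth, spec = spec),
            class = "ckm_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits `claims.csv` (claims dialect), `truth.csv`
#' (`patient_id,truth_stage,truth_substage,is_boundary`),
#' `measurements.csv` when any patient carries a panel, and
#' `provenance.json` (spec and seed).
#'
#' @param cohort A `ckm_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_claims(lapply(cohort$patients, `[[`, "history"),
               file.path(dir, "claims.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  panels <- Filter(Negate(is.null),
                   lapply(cohort$patients, `[[`, "panel"))
  if (length(panels)) {
    rows <- list()
    for (p in panels) {
      flds <- setdiff(names(p), c("patient_id", "sex", "asian_ancestry"))
      for (f in flds) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = p$patient_id, sex = p$sex,
          asian_ancestry = p$asian_ancestry, field = f,
          value = as.character(p[[f]]), date = "2025-12-01",
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "measurements.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  spec <- cohort$spec
  prov <- list(n_patients = spec$n_patients,
               stage_mix = as.list(spec$stage_mix),
               boundary_fraction = spec$boundary_fraction,
               seed = spec$seed,
               index_date = format(spec$index$index_date),
               lookback_months = spec$index$lookback_months)
  writeLines(as.character(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                           pretty = 2)),
             file.path(dir, "provenance.json"))
  invisible(dir)
}
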