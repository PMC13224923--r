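# Structured-measurement criteria for the EHR-enhanced pathway:
# anthropometric/glycemic thresholds, subclinical HF biomarkers,
# subclinical ASCVD imaging flags, metabolic-syndrome component counting,
# and KDIGO eGFR-albuminuria risk categorization.
#
# Missing measurements always mean "criterion not met", never an error:
# EHR panels are sparse and staging must degrade gracefully to
# claims-only behavior. All printed thresholds are inclusive.

panel_fields_numeric <- c(
  "bmi", "waist_cm", "fasting_glucose_mg_dl", "hba1c_percent",
  "ntprobnp_pg_ml", "hs_tnt_ng_l", "hs_tni_ng_l",
  "egfr_ml_min_1.73m2", "uacr_mg_g",
  "hdl_mg_dl", "triglycerides_mg_dl", "sbp_mmhg", "dbp_mmhg")

panel_fields_flag <- c(
  "cac_positive", "ct_or_cath_atherosclerosis", "echo_abnormal",
  "high_10yr_risk", "on_antihypertensives")

#' Construct a measurement panel
#'
#' All measurement fields are optional; `sex` is required whenever a
#' troponin threshold is to be evaluated. Units are fixed (BMI kg/m2,
#' waist cm, glucose mg/dL, HbA1c percent, NT-proBNP pg/mL, troponins
#' ng/L, eGFR mL/min/1.73m2, uACR mg/g, lipids mg/dL, pressures mmHg);
#' no unit inference is performed.
#'
#' @param patient_id Patient identifier.
#' @param sex `"female"`, `"male"`, or `NA`.
#' @param asian_ancestry Logical; lowers the BMI/waist thresholds.
#' @param ... Named numeric measurements or logical flags drawn from the
#'   panel vocabulary (see Details in the package vignette).
#' @return A `ckm_panel` object.
#' @examples
#' measurement_panel("p1", sex = "female", ntprobnp_pg_ml = 125)
#' @export
measurement_panel <- function(patient_id, sex = NA_character_,
                              asian_ancestry = FALSE, ...) {
  vals <- list(...)
  unknown <- setdiff(names(vals),
                     c(panel_fields_numeric, panel_fields_flag))
  if (length(unknown))
    stop("unknown measurement field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.na(sex)) sex <- match.arg(sex, c("female", "male"))
  for (f in intersect(names(vals), panel_fields_numeric)) {
    v <- vals[[f]]
    if (!is.na(v) && (!is.numeric(v) || v < 0))
      stop("measurement '", f, "' must be a non-negative number",
           call. = FALSE)
  }
  structure(c(list(patient_id = as.character(patient_id), sex = sex,
                   asian_ancestry = isTRUE(asian_ancestry)), vals),
            class = "ckm_panel")
}

pv <- function(panel, field) {
  v <- panel[[field]]
  if (is.null(v)) NA else v
}

has <- function(panel, field) {
  v <- panel[[field]]
  !is.null(v) && !is.na(v)
}

#' Excess adiposity criterion
#'
#' BMI >= 25 kg/m2 (>= 23 if Asian ancestry), or waist circumference
#' >= 88 cm in women / >= 102 cm in men (>= 80 / >= 90 cm if Asian
#' ancestry). `FALSE` when the relevant fields are absent.
#'
#' @param panel A `ckm_panel`.
#' @return Logical scalar.
#' @export
adiposity_met <- function(panel) {
  bmi_thr <- if (panel$asian_ancestry) 23 else 25
  if (has(panel, "bmi") && pv(panel, "bmi") >= bmi_thr) return(TRUE)
  if (has(panel, "waist_cm") && !is.na(panel$sex)) {
    thr <- if (panel$asian_ancestry) {
      if (panel$sex == "female") 80 else 90
    } else {
      if (panel$sex == "female") 88 else 102
    }
    if (pv(panel, "waist_cm") >= thr) return(TRUE)
  }
  FALSE
}

#' Dysfunctional adiposity (prediabetes) criterion
#'
#' Fasting glucose in 100-124 mg/dL or HbA1c in 5.7-6.4 percent, both
#' bands closed as printed in the staging construct (values above the
#' band are in the diabetes range and do not meet this criterion).
#'
#' @param panel A `ckm_panel`.
#' @return Logical scalar.
#' @export
dysfunctional_adiposity_met <- function(panel) {
  fg <- pv(panel, "fasting_glucose_mg_dl")
  if (!is.na(fg) && fg >= 100 && fg <= 124) return(TRUE)
  a1c <- pv(panel, "hba1c_percent")
  if (!is.na(a1c) && a1c >= 5.7 && a1c <= 6.4) return(TRUE)
  FALSE
}

#' Subclinical heart-failure criterion
#'
#' NT-proBNP >= 125 pg/mL, hs-troponin T >= 14 (women) / 22 (men) ng/L,
#' hs-troponin I >= 10 (women) / 12 (men) ng/L, or an abnormal
#' echocardiogram flag. Troponin thresholds require `sex`.
#'
#' @param panel A `ckm_panel`.
#' @return Logical scalar.
#' @export
subclinical_hf_met <- function(panel) {
  if ((has(panel, "hs_tnt_ng_l") || has(panel, "hs_tni_ng_l")) &&
      is.na(panel$sex))
    stop("sex is required to evaluate troponin thresholds",
         call. = FALSE)
  bnp <- pv(panel, "ntprobnp_pg_ml")
  if (!is.na(bnp) && bnp >= 125) return(TRUE)
  tnt <- pv(panel, "hs_tnt_ng_l")
  if (!is.na(tnt) && tnt >= (if (panel$sex == "female") 14 else 22))
    return(TRUE)
  tni <- pv(panel, "hs_tni_ng_l")
  if (!is.na(tni) && tni >= (if (panel$sex == "female") 10 else 12))
    return(TRUE)
  isTRUE(pv(panel, "echo_abnormal"))
}

#' Subclinical ASCVD criterion
#'
#' Positive coronary artery calcification, or subclinical atherosclerosis
#' on CT angiography or coronary catheterization.
#'
#' @param panel A `ckm_panel`.
#' @return Logical scalar.
#' @export
subclinical_ascvd_met <- function(panel) {
  isTRUE(pv(panel, "cac_positive")) ||
    isTRUE(pv(panel, "ct_or_cath_atherosclerosis"))
}

#' Metabolic-syndrome component count
#'
#' Counts the five components: (1) waist >= 88/102 cm women/men
#' (>= 80/90 if Asian ancestry); (2) HDL-C < 40 mg/dL in men or
#' < 50 mg/dL in women; (3) triglycerides >= 150 mg/dL; (4) SBP >= 130
#' or DBP >= 80 mmHg or antihypertensive use; (5) fasting glucose
#' >= 100 mg/dL. Absent fields contribute 0.
#'
#' @param panel A `ckm_panel`.
#' @return Integer 0-5.
#' @export
mets_component_count <- function(panel) {
  comp <- logical(5L)
  if (has(panel, "waist_cm") && !is.na(panel$sex)) {
    thr <- if (panel$asian_ancestry) {
      if (panel$sex == "female") 80 else 90
    } else {
      if (panel$sex == "female") 88 else 102
    }
    comp[1L] <- pv(panel, "waist_cm") >= thr
  }
  if (has(panel, "hdl_mg_dl") && !is.na(panel$sex)) {
    comp[2L] <- pv(panel, "hdl_mg_dl") <
      (if (panel$sex == "male") 40 else 50)
  }
  if (has(panel, "triglycerides_mg_dl"))
    comp[3L] <- pv(panel, "triglycerides_mg_dl") >= 150
  comp[4L] <- (has(panel, "sbp_mmhg") && pv(panel, "sbp_mmhg") >= 130) ||
    (has(panel, "dbp_mmhg") && pv(panel, "dbp_mmhg") >= 80) ||
    isTRUE(pv(panel, "on_antihypertensives"))
  if (has(panel, "fasting_glucose_mg_dl"))
    comp[5L] <- pv(panel, "fasting_glucose_mg_dl") >= 100
  sum(comp)
}

#' Metabolic syndrome met (>= 3 of 5 components)
#'
#' @param panel A `ckm_panel`.
#' @return Logical scalar.
#' @export
mets_met <- function(panel) {
  mets_component_count(panel) >= 3L
}

kdigo_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "kdigo_2012_risk_grid.csv",
                          package = "ckmstage", mustWork = TRUE)
      cache <<- utils::read.csv(path, colClasses = "character")
    }
    cache
  }
})

#' KDIGO eGFR-albuminuria risk category
#'
#' G stage by eGFR bands (>=90, 60-89, 45-59, 30-44, 15-29, <15
#' mL/min/1.73m2), A stage by uACR bands (<30, 30-300, >300 mg/g), and
#' the combined risk category from the KDIGO 2012 heat-map grid shipped
#' as an editable data file. Missing input yields an explicit
#' not-computable result rather than a silent default.
#'
#' @param egfr eGFR in mL/min/1.73m2, positive.
#' @param uacr Urine albumin-to-creatinine ratio in mg/g, non-negative.
#' @return A `ckm_kdigo` object with `g_stage`, `a_stage`, `risk`, and
#'   `computable`.
#' @examples
#' kdigo_category(95, 10)   # G1/A1, low
#' kdigo_category(25, 10)   # G4/A1, very high
#' @export
kdigo_category <- function(egfr, uacr) {
  if (missing(egfr) || missing(uacr) || is.na(egfr) || is.na(uacr)) {
    return(structure(list(g_stage = NA_character_,
                          a_stage = NA_character_,
                          risk = NA_character_, computable = FALSE),
                     class = "ckm_kdigo"))
  }
  stopifnot(egfr > 0, uacr >= 0)
  g <- if (egfr >= 90) "G1" else if (egfr >= 60) "G2" else
       if (egfr >= 45) "G3a" else if (egfr >= 30) "G3b" else
       if (egfr >= 15) "G4" else "G5"
  a <- if (uacr < 30) "A1" else if (uacr <= 300) "A2" else "A3"
  grid <- kdigo_grid()
  risk <- grid$risk[grid$g_stage == g & grid$a_stage == a]
  structure(list(g_stage = g, a_stage = a, risk = risk,
                 computable = TRUE),
            class = "ckm_kdigo")
}

#' @export
print.ckm_kdigo <- function(x, ...) {
  if (!x$computable) cat("<ckm_kdigo> not computable\n")
  else cat("<ckm_kdigo> ", x$g_stage, "/", x$a_stage, " - ", x$risk,
           " risk\n", sep = "")
  invisible(x)
}

#' Does a panel satisfy the stage-3 very-high-risk-CKD lab clause?
#'
#' True when the KDIGO category is computable and either the G stage is
#' G4/G5 or the combined risk is very high.
#'
#' @param panel A `ckm_panel`.
#' @return Logical scalar.
#' @export
kdigo_stage3_equivalent <- function(panel) {
  k <- kdigo_category(pv(panel, "egfr_ml_min_1.73m2"),
                      pv(panel, "uacr_mg_g"))
  isTRUE(k$computable) &&
    (k$g_stage %in% c("G4", "G5") || k$risk == "very_high")
}

#' Read measurement panels from CSV
#'
#' Long dialect with header `patient_id,sex,asian_ancestry,field,value,
#' date`; one row per measurement. Numeric fields are parsed as numbers,
#' flag fields as logicals. When a field repeats for a patient, the row
#' with the latest date wins (ties: last row).
#'
#' @param path Path to the measurements CSV.
#' @return Named list of [measurement_panel()] objects.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "sex", "asian_ancestry", "field", "value",
            "date")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("measurements CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- list()
  for (pid in sort(unique(df$patient_id))) {
    rows <- df[df$patient_id == pid, , drop = FALSE]
    rows <- rows[order(as.Date(rows$date)), , drop = FALSE]
    vals <- list()
    for (i in seq_len(nrow(rows))) {
      f <- rows$field[i]
      v <- rows$value[i]
      if (f %in% panel_fields_numeric) {
        vals[[f]] <- as.numeric(v)
      } else if (f %in% panel_fields_flag) {
        vals[[f]] <- toupper(v) %in% c("TRUE", "T", "1", "YES")
      } else {
        stop("unknown measurement field '", f, "' for patient ", pid,
             call. = FALSE)
      }
    }
    sex <- rows$sex[nrow(rows)]
    if (is.na(sex) || !nzchar(sex)) sex <- NA_character_
    out[[pid]] <- do.call(measurement_panel, c(
      list(patient_id = pid, sex = sex,
           asian_ancestry = toupper(rows$asian_ancestry[nrow(rows)]) %in%
             c("TRUE", "T", "1", "YES")),
      vals))
  }
  out
}
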