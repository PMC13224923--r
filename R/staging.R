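# Hierarchical stage assignment: stage-eligibility predicates with
# co-occurrence rules, evaluated bottom-up once per patient, then the
# highest qualifying stage wins (4 > 3 > 2 > 1 > 0).

#' Staging configuration
#'
#' @param mode `"claims_only"` or `"ehr_enhanced"`. The modes differ only
#'   in stage-3 eligibility: EHR-enhanced additionally admits subclinical
#'   ASCVD/HF measurements, lab-based KDIGO categories and an external
#'   high 10-year-risk flag; stages 1, 2 and 4 never consult
#'   measurements.
#' @param policy A [confirmation_policy()].
#' @param index An [index_spec()].
#' @param strict_raw_exclusion When `TRUE`, stage 1 is additionally
#'   blocked by the mere presence of any stage 2-4 core code in the
#'   window (the literal exclusion wording); the default blocks only on
#'   confirmed higher-stage conditions, so a single uncorroborated
#'   higher-stage code cannot demote a genuine stage-1 patient to 0.
#' @param enable_expanded_tg_proxy Consult the expanded
#'   hypertriglyceridemia proxy set (mixed hyperlipidemia E78.2) for
#'   stage 2 (default `FALSE`).
#' @param require_confirmed_albuminuria When `TRUE`, the R80 component of
#'   the mild-CKD stage-2 proxy must itself be confirmed; the default
#'   requires only presence in the window.
#' @param count_stroke_history Count cerebrovascular sequelae/history
#'   codes (I69.-, Z86.73) as chronic clinical CVD for stage 4 (default
#'   `TRUE`); disable for incident-event studies.
#' @param transplant_as_kidney_failure Count kidney-transplant status
#'   (Z94.0 together with any N18.- presence) as a kidney-failure marker
#'   for substage 4B (default `FALSE`).
#' @return A `ckm_config` object.
#' @export
staging_config <- function(mode = c("claims_only", "ehr_enhanced"),
                           policy = confirmation_policy(),
                           index = index_spec("2026-01-01", 24L),
                           strict_raw_exclusion = FALSE,
                           enable_expanded_tg_proxy = FALSE,
                           require_confirmed_albuminuria = FALSE,
                           count_stroke_history = TRUE,
                           transplant_as_kidney_failure = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(policy, "ckm_policy"), inherits(index, "ckm_index"))
  structure(list(mode = mode, policy = policy, index = index,
                 strict_raw_exclusion = isTRUE(strict_raw_exclusion),
                 enable_expanded_tg_proxy =
                   isTRUE(enable_expanded_tg_proxy),
                 require_confirmed_albuminuria =
                   isTRUE(require_confirmed_albuminuria),
                 count_stroke_history = isTRUE(count_stroke_history),
                 transplant_as_kidney_failure =
                   isTRUE(transplant_as_kidney_failure)),
            class = "ckm_config")
}

stage2_metabolic_sets <- function(config) {
  s <- c("hypertension", "hypertriglyceridemia", "metabolic_syndrome",
         "diabetes")
  if (config$enable_expanded_tg_proxy)
    s <- c(s, "hypertriglyceridemia_expanded")
  s
}

stage4_cvd_sets <- function(config) {
  s <- c("coronary_heart_disease", "ami", "heart_failure",
         "atrial_fibrillation", "peripheral_artery_disease",
         "stroke_acute")
  if (config$count_stroke_history) s <- c(s, "stroke_history")
  s
}

# evaluate confirmation + raw presence for every registry set once
compute_statuses <- function(windowed, registry, policy) {
  statuses <- lapply(registry$code_sets, confirm_condition,
                     history = windowed, policy = policy)
  presence <- vapply(registry$code_sets, raw_presence,
                     TRUE, history = windowed)
  list(statuses = statuses, presence = presence)
}

#' Moderate- to high-risk CKD (claims proxy)
#'
#' True when CKD stage 3 (N18.30-N18.32) is confirmed, or CKD stage 1-2
#' (N18.1-N18.2) is confirmed with albuminuria/proteinuria codes (R80.-)
#' in the window. Forced false when very high-risk CKD (N18.4-N18.5) or
#' kidney failure (N18.6) is confirmed: those route to stages 3 and 4B.
#'
#' @param ev Evaluation context from [assign_stage()] internals (list
#'   with `statuses` and `presence`).
#' @param config A `ckm_config`.
#' @return Logical scalar.
#' @keywords internal
ckd_moderate_high <- function(ev, config) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  if (conf("ckd_very_high_risk") || conf("kidney_failure")) return(FALSE)
  alb <- if (config$require_confirmed_albuminuria)
    conf("albuminuria_proteinuria")
  else isTRUE(ev$presence[["albuminuria_proteinuria"]])
  conf("ckd_moderate_risk") || (conf("ckd_mild") && alb)
}

eligible_stage2 <- function(ev, config) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  any(vapply(stage2_metabolic_sets(config), conf, TRUE)) ||
    ckd_moderate_high(ev, config)
}

kidney_failure_marker <- function(ev, config) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  conf("kidney_failure") ||
    isTRUE(ev$presence[["dialysis_dependence"]]) ||
    (config$transplant_as_kidney_failure &&
       isTRUE(ev$presence[["kidney_transplant"]]) &&
       isTRUE(ev$presence[["ckd_any"]]))
}

# adiposity / metabolic / CKD context required by the stage-3 and
# stage-4 co-occurrence clauses
ckm_context <- function(ev, config) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  conf("overweight_obesity") || conf("prediabetes") ||
    any(vapply(stage2_metabolic_sets(config), conf, TRUE)) ||
    conf("ckd_moderate_risk") || conf("ckd_mild") ||
    conf("ckd_very_high_risk") ||
    isTRUE(ev$presence[["ckd_any"]])
}

eligible_stage3 <- function(ev, panel, config) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  claims_clause <- conf("ckd_very_high_risk") ||
    kidney_failure_marker(ev, config)
  if (claims_clause) return(TRUE)
  if (config$mode != "ehr_enhanced" || is.null(panel)) return(FALSE)
  equiv <- subclinical_ascvd_met(panel) || subclinical_hf_met(panel) ||
    kdigo_stage3_equivalent(panel) ||
    isTRUE(panel[["high_10yr_risk"]])
  equiv && ckm_context(ev, config)
}

eligible_stage4 <- function(ev, config) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  cvd <- any(vapply(stage4_cvd_sets(config), conf, TRUE))
  cvd && ckm_context(ev, config)
}

eligible_stage1 <- function(ev, registry, config, higher_eligible) {
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)
  adiposity <- conf("overweight_obesity") || conf("prediabetes")
  if (!adiposity) return(FALSE)
  if (higher_eligible) return(FALSE)
  if (config$strict_raw_exclusion) {
    core_2_4 <- unlist(lapply(registry$stages[3:5], `[[`, "core_sets"))
    if (!config$enable_expanded_tg_proxy)
      core_2_4 <- setdiff(core_2_4, "hypertriglyceridemia_expanded")
    if (any(ev$presence[core_2_4])) return(FALSE)
  }
  TRUE
}

substage_stage4 <- function(ev, config) {
  if (kidney_failure_marker(ev, config)) "B" else "A"
}

#' Assign the CKM stage for one patient
#'
#' Windows the claims history, evaluates every registry code set once
#' under the confirmation policy, applies the stage 1-4 eligibility
#' predicates, and returns the highest qualifying stage with its
#' evidence trail. Stage 0 is assigned when no stage qualifies (defined
#' by absence). Substage A/B applies only at stage 4 and is driven by
#' kidney-failure markers (ESRD N18.6 confirmed, dialysis dependence
#' Z99.2 present, optionally transplant status).
#'
#' @param history A `ckm_history` (claims in any window; windowing is
#'   applied here). An attached measurement panel (or `panel`) is
#'   consulted only in EHR-enhanced mode and only for stage 3.
#' @param registry A `ckm_registry`; default the shipped FY2026 registry.
#' @param config A [staging_config()].
#' @param panel Optional [measurement_panel()] overriding
#'   `history$panel`.
#' @return A `ckm_assignment` with fields `patient_id`, `stage`,
#'   `substage`, `mode`, `eligibilities`, `qualifying_sets`, and
#'   `evidence` (confirmed `ckm_status` objects per qualifying stage).
#' @examples
#' reg <- ckm_registry()
#' cfg <- staging_config(index = index_spec("2026-01-01", 24))
#' h <- patient_history("p1", list(
#'   claim_record("p1", "2025-03-01", "outpatient", "E66.9", "c1"),
#'   claim_record("p1", "2025-05-01", "outpatient", "E66.9", "c2")))
#' assign_stage(h, reg, cfg)$stage  # 1
#' @export
assign_stage <- function(history, registry = ckm_registry(),
                         config = staging_config(), panel = NULL) {
  stopifnot(inherits(history, "ckm_history"),
            inherits(registry, "ckm_registry"),
            inherits(config, "ckm_config"))
  if (is.null(panel)) panel <- history$panel
  windowed <- window_claims(history, config$index)
  ev <- compute_statuses(windowed, registry, config$policy)
  conf <- function(nm) isTRUE(ev$statuses[[nm]]$confirmed)

  e2 <- eligible_stage2(ev, config)
  e3 <- eligible_stage3(ev, panel, config)
  e4 <- eligible_stage4(ev, config)
  e1 <- eligible_stage1(ev, registry, config, e2 || e3 || e4)
  elig <- c(`1` = e1, `2` = e2, `3` = e3, `4` = e4)
  stage <- if (any(elig)) max(which(elig)) else 0L
  substage <- if (stage == 4L) substage_stage4(ev, config) else "none"

  qualifying <- character()
  evidence <- list()
  confirmed_of <- function(sets) {
    sets[vapply(sets, conf, TRUE)]
  }
  if (e1 && stage == 1L) {
    qualifying <- confirmed_of(c("overweight_obesity", "prediabetes"))
  }
  if (e2) {
    q2 <- confirmed_of(stage2_metabolic_sets(config))
    if (ckd_moderate_high(ev, config))
      q2 <- c(q2, confirmed_of(c("ckd_moderate_risk", "ckd_mild")))
    if (stage == 2L) qualifying <- q2
    evidence[["2"]] <- ev$statuses[q2]
  }
  if (e3) {
    q3 <- confirmed_of(c("ckd_very_high_risk", "kidney_failure"))
    if (isTRUE(ev$presence[["dialysis_dependence"]]))
      q3 <- c(q3, "dialysis_dependence")
    if (config$mode == "ehr_enhanced" && !is.null(panel) &&
        length(q3) == 0L)
      q3 <- "ehr_subclinical"
    if (stage == 3L) qualifying <- q3
    evidence[["3"]] <- ev$statuses[intersect(q3, names(ev$statuses))]
  }
  if (e4) {
    q4 <- confirmed_of(stage4_cvd_sets(config))
    if (stage == 4L) {
      qualifying <- q4
      if (substage == "B")
        qualifying <- c(qualifying,
                        confirmed_of("kidney_failure"),
                        if (isTRUE(ev$presence[["dialysis_dependence"]]))
                          "dialysis_dependence")
    }
    evidence[["4"]] <- ev$statuses[q4]
  }
  if (e1) evidence[["1"]] <-
    ev$statuses[confirmed_of(c("overweight_obesity", "prediabetes"))]

  structure(list(patient_id = history$patient_id,
                 stage = as.integer(stage), substage = substage,
                 mode = config$mode, eligibilities = elig,
                 qualifying_sets = unique(qualifying),
                 evidence = evidence,
                 statuses = ev$statuses, presence = ev$presence),
            class = "ckm_assignment")
}

#' @export
print.ckm_assignment <- function(x, ...) {
  cat("<ckm_assignment> patient ", x$patient_id, ": stage ", x$stage,
      if (x$substage != "none") x$substage, " (", x$mode, ")\n",
      sep = "")
  if (length(x$qualifying_sets))
    cat("  qualifying: ", paste(x$qualifying_sets, collapse = "; "),
        "\n", sep = "")
  invisible(x)
}

#' Stage a collection of patients
#'
#' @param histories List of `ckm_history` objects (e.g. from
#'   [read_claims()]).
#' @param registry A `ckm_registry`.
#' @param config A [staging_config()].
#' @param panels Optional named list of measurement panels, matched to
#'   histories by patient id.
#' @return A data.frame with columns
#'   `patient_id,stage,substage,mode,qualifying_sets` (semicolon-joined
#'   set names), one row per patient, ordered by patient id. The full
#'   `ckm_assignment` objects are attached as attribute `assignments`.
#' @export
stage_patients <- function(histories, registry = ckm_registry(),
                           config = staging_config(), panels = NULL) {
  histories <- histories[order(vapply(histories, `[[`, "",
                                      "patient_id"))]
  assignments <- lapply(histories, function(h) {
    p <- if (!is.null(panels)) panels[[h$patient_id]] else NULL
    assign_stage(h, registry, config, panel = p)
  })
  df <- data.frame(
    patient_id = vapply(assignments, `[[`, "", "patient_id"),
    stage = vapply(assignments, `[[`, 0L, "stage"),
    substage = vapply(assignments, `[[`, "", "substage"),
    mode = vapply(assignments, `[[`, "", "mode"),
    qualifying_sets = vapply(assignments, function(a)
      paste(a$qualifying_sets, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "assignments") <- assignments
  df
}
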