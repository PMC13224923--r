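# Encounter-confirmation rules. Chronic conditions: >=2 outpatient claims
# on different dates (with a minimum day gap, >=30 by default, inclusive)
# or >=1 inpatient claim. Acute events: a single inpatient claim.

#' Confirmation policy
#'
#' Tunable claim-count and day-gap thresholds for chronic versus acute
#' condition ascertainment. The day-gap test is inclusive (exactly 30
#' days apart confirms under the default) and applies to at least one
#' pair of matching outpatient dates; set `min_day_separation = 0` for a
#' distinct-dates-only rule.
#'
#' @param min_outpatient_claims Minimum outpatient claims on distinct
#'   dates for a chronic condition (default 2).
#' @param min_day_separation Minimum gap in days between at least one
#'   pair of matching outpatient dates (default 30).
#' @param inpatient_sufficient One inpatient claim confirms a chronic
#'   condition (default `TRUE`).
#' @param acute_single_inpatient One inpatient claim confirms an acute
#'   event set (default `TRUE`); when `FALSE`, acute sets fall back to
#'   the chronic rule.
#' @return A `ckm_policy` object.
#' @export
confirmation_policy <- function(min_outpatient_claims = 2L,
                                min_day_separation = 30L,
                                inpatient_sufficient = TRUE,
                                acute_single_inpatient = TRUE) {
  min_outpatient_claims <- as.integer(min_outpatient_claims)
  min_day_separation <- as.integer(min_day_separation)
  stopifnot(min_outpatient_claims >= 1L, min_day_separation >= 0L)
  structure(list(min_outpatient_claims = min_outpatient_claims,
                 min_day_separation = min_day_separation,
                 inpatient_sufficient = isTRUE(inpatient_sufficient),
                 acute_single_inpatient = isTRUE(acute_single_inpatient)),
            class = "ckm_policy")
}

evidence_frame <- function(claims, set) {
  if (length(claims) == 0L)
    return(data.frame(service_date = as.Date(character()),
                      setting = character(), matched_code = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(claims, function(cl) {
    hit <- cl$codes[codes_match_any(cl$codes, set$patterns)]
    data.frame(service_date = cl$service_date, setting = cl$setting,
               matched_code = hit, stringsAsFactors = FALSE)
  }))
}

#' Is any matching code present in the window?
#'
#' Pure presence: true as soon as any claim carries any code matching the
#' set, with no claim-count or setting requirement.
#'
#' @param history A windowed `ckm_history`.
#' @param set A `ckm_code_set`.
#' @return Logical scalar.
#' @export
raw_presence <- function(history, set) {
  for (cl in history$claims) {
    if (any(codes_match_any(cl$codes, set$patterns))) return(TRUE)
  }
  FALSE
}

#' Confirm a condition under the encounter rules
#'
#' For chronic sets: confirmed if one inpatient claim carries a matching
#' code (when `inpatient_sufficient`), or if at least
#' `min_outpatient_claims` outpatient claims on distinct dates match and
#' at least one pair of those dates is `>= min_day_separation` days
#' apart. For acute sets: confirmed by a single matching inpatient claim
#' (when `acute_single_inpatient`). The inpatient path takes precedence
#' for the reported basis when both apply. Evidence lists the matching
#' claims behind the satisfied rule.
#'
#' @param history A windowed `ckm_history`.
#' @param set A `ckm_code_set` from a valid registry.
#' @param policy A [confirmation_policy()].
#' @return A `ckm_status` object with fields `set_name`, `confirmed`,
#'   `basis` (`"inpatient"`, `"outpatient_pair"`, `"acute_event"` or
#'   `"none"`) and an `evidence` data.frame.
#' @export
confirm_condition <- function(history, set,
                              policy = confirmation_policy()) {
  matching <- Filter(function(cl) any(codes_match_any(cl$codes,
                                                      set$patterns)),
                     history$claims)
  inpt <- Filter(function(cl) cl$setting == "inpatient", matching)
  outp <- Filter(function(cl) cl$setting == "outpatient", matching)
  confirmed <- FALSE
  basis <- "none"
  evidence_claims <- list()

  acute_rule <- set$acuity == "acute" && policy$acute_single_inpatient
  if (acute_rule) {
    if (length(inpt) >= 1L) {
      confirmed <- TRUE
      basis <- "acute_event"
      evidence_claims <- inpt
    }
  } else {
    if (policy$inpatient_sufficient && length(inpt) >= 1L) {
      confirmed <- TRUE
      basis <- "inpatient"
      evidence_claims <- inpt
    } else {
      dates <- unique(as.Date(vapply(outp, function(cl)
        as.character(cl$service_date), "")))
      ok <- length(dates) >= policy$min_outpatient_claims
      if (ok && policy$min_outpatient_claims >= 2L) {
        ok <- as.integer(max(dates) - min(dates)) >=
          policy$min_day_separation
      }
      if (ok) {
        confirmed <- TRUE
        basis <- "outpatient_pair"
        evidence_claims <- outp
      }
    }
  }

  structure(list(set_name = set$name, confirmed = confirmed,
                 basis = basis,
                 evidence = evidence_frame(evidence_claims, set)),
            class = "ckm_status")
}

#' @export
print.ckm_status <- function(x, ...) {
  cat("<ckm_status> ", x$set_name, ": ",
      if (x$confirmed) paste0("confirmed (", x$basis, ")")
      else "not confirmed", "\n", sep = "")
  if (nrow(x$evidence)) {
    apply(x$evidence, 1L, function(r)
      cat("  ", r[["service_date"]], " ", r[["setting"]], " ",
          format_code(r[["matched_code"]]), "\n", sep = ""))
  }
  invisible(x)
}
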