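# Patient claims histories, index dates, lookback windowing.
#
# Claims arrive in long CSV form (one row per claim-code) with header
#   patient_id,claim_id,service_date,setting,icd10cm_code
# and are grouped into claim records by (patient_id, claim_id,
# service_date, setting). Codes are normalized and de-duplicated within a
# record so administrative duplicates cannot fabricate extra confirming
# claims.

#' Construct a claim record
#'
#' @param patient_id Opaque patient identifier.
#' @param service_date Service date (`Date` or ISO-8601 string).
#' @param setting `"inpatient"` or `"outpatient"`.
#' @param codes Non-empty vector of ICD-10-CM codes (normalized on
#'   construction, de-duplicated).
#' @param claim_id Optional claim identifier.
#' @return A `ckm_claim` object.
#' @export
claim_record <- function(patient_id, service_date,
                         setting = c("outpatient", "inpatient"),
                         codes, claim_id = NA_character_) {
  setting <- match.arg(setting)
  service_date <- as.Date(service_date)
  if (is.na(service_date)) stop("invalid service date", call. = FALSE)
  codes <- sort(unique(normalize_code(codes)))
  if (length(codes) == 0L)
    stop("a claim record needs at least one code", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 claim_id = as.character(claim_id),
                 service_date = service_date,
                 setting = setting, codes = codes),
            class = "ckm_claim")
}

#' Construct a patient history
#'
#' Claims are sorted by service date (ties broken by claim id then by
#' setting) so that histories built from permuted inputs are identical.
#'
#' @param patient_id Patient identifier; all claims must carry it.
#' @param claims List of [claim_record()] objects.
#' @param panel Optional [measurement_panel()] for EHR-enhanced staging.
#' @return A `ckm_history` object.
#' @export
patient_history <- function(patient_id, claims = list(), panel = NULL) {
  patient_id <- as.character(patient_id)
  if (length(claims)) {
    ids <- vapply(claims, `[[`, "", "patient_id")
    if (!all(ids == patient_id))
      stop("claims carry a different patient_id than '", patient_id, "'",
           call. = FALSE)
    ord <- order(as.Date(vapply(claims, function(cl)
                   as.character(cl$service_date), "")),
                 vapply(claims, `[[`, "", "claim_id"),
                 vapply(claims, `[[`, "", "setting"))
    claims <- claims[ord]
  }
  structure(list(patient_id = patient_id, claims = claims, panel = panel),
            class = "ckm_history")
}

#' @export
print.ckm_history <- function(x, ...) {
  cat("<ckm_history> patient ", x$patient_id, ": ", length(x$claims),
      " claim(s)", if (!is.null(x$panel)) " + measurement panel", "\n",
      sep = "")
  for (cl in x$claims) {
    cat("  ", format(cl$service_date), " ", cl$setting, " ",
        paste(format_code(cl$codes), collapse = ","), "\n", sep = "")
  }
  invisible(x)
}

#' Index date and lookback specification
#'
#' The lookback window is the half-open interval
#' `[index_date - lookback_months, index_date)`: the index day itself is
#' excluded so index-day events cannot contaminate baseline staging.
#' `include_index_date = TRUE` closes the upper bound for sensitivity
#' analyses. Month subtraction is calendar-based with day-of-month
#' clamping (e.g. one month before 2026-03-31 is 2026-02-28).
#'
#' @param index_date Anchor date for cohort entry.
#' @param lookback_months Positive integer, default 24.
#' @param include_index_date Logical, default `FALSE`.
#' @return A `ckm_index` object.
#' @export
index_spec <- function(index_date, lookback_months = 24L,
                       include_index_date = FALSE) {
  index_date <- as.Date(index_date)
  lookback_months <- as.integer(lookback_months)
  stopifnot(!is.na(index_date), lookback_months >= 1L)
  structure(list(index_date = index_date,
                 lookback_months = lookback_months,
                 include_index_date = isTRUE(include_index_date)),
            class = "ckm_index")
}

# calendar-month shift with day-of-month clamping to month end
add_months <- function(date, months) {
  lt <- as.POSIXlt(date)
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + months
  first <- as.Date(lt)
  nxt <- as.POSIXlt(first)
  nxt$mon <- nxt$mon + 1L
  last_day <- as.integer(as.Date(nxt) - 1L - first) + 1L
  first + (pmin(day, last_day) - 1L)
}

#' Lookback window bounds
#'
#' @param index A `ckm_index`.
#' @return A list with `lower` (inclusive) and `upper` dates plus
#'   `upper_closed` indicating whether the index day itself is included.
#' @export
lookback_window <- function(index) {
  list(lower = add_months(index$index_date, -index$lookback_months),
       upper = index$index_date,
       upper_closed = index$include_index_date)
}

#' Restrict a history to its lookback window
#'
#' Retains exactly the claims with
#' `lower <= service_date < index_date` (or `<=` when the index day is
#' included). Idempotent; the measurement panel is carried through
#' unchanged.
#'
#' @param history A `ckm_history`.
#' @param index A `ckm_index`.
#' @return The windowed `ckm_history`.
#' @export
window_claims <- function(history, index) {
  w <- lookback_window(index)
  keep <- vapply(history$claims, function(cl) {
    d <- cl$service_date
    d >= w$lower && (if (w$upper_closed) d <= w$upper else d < w$upper)
  }, TRUE)
  patient_history(history$patient_id, history$claims[keep], history$panel)
}

#' Read claims histories from CSV
#'
#' Expects the long claims dialect (header
#' `patient_id,claim_id,service_date,setting,icd10cm_code`). Rows are
#' grouped into claim records by (patient_id, claim_id, service_date,
#' setting); codes are normalized; duplicate (patient, date, setting,
#' code) rows collapse. Errors report the offending row number.
#'
#' @param path Path to the claims CSV.
#' @return Named list of [patient_history()] objects, ordered by
#'   patient id.
#' @export
read_claims <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "claim_id", "service_date", "setting",
            "icd10cm_code")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("claims CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  row_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- !df$setting %in% c("inpatient", "outpatient")
  if (any(bad))
    stop("unknown care setting '", df$setting[bad][1L], "' at row ",
         row_no[bad][1L], call. = FALSE)
  dates <- as.Date(df$service_date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable service date '",
         df$service_date[is.na(dates)][1L], "' at row ",
         row_no[is.na(dates)][1L], call. = FALSE)
  codes <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(normalize_code(df$icd10cm_code[i]),
             error = function(e) {
               stop(conditionMessage(e), " at row ", row_no[i],
                    call. = FALSE)
             })
  }, "")
  key <- paste(df$patient_id, df$claim_id, format(dates), df$setting,
               sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  claims_by_patient <- list()
  for (g in groups) {
    cl <- claim_record(df$patient_id[g[1L]], dates[g[1L]],
                       df$setting[g[1L]], codes[g],
                       df$claim_id[g[1L]])
    pid <- cl$patient_id
    claims_by_patient[[pid]] <- c(claims_by_patient[[pid]], list(cl))
  }
  pids <- sort(names(claims_by_patient))
  out <- lapply(pids, function(pid) {
    patient_history(pid, claims_by_patient[[pid]])
  })
  names(out) <- pids
  out
}

#' Write claims histories to CSV
#'
#' Inverse of [read_claims()] up to row ordering: emits one row per
#' claim-code in the long dialect, deterministically ordered.
#'
#' @param histories List of `ckm_history` objects.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_claims <- function(histories, path) {
  rows <- list()
  for (h in histories) {
    for (cl in h$claims) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = h$patient_id,
        claim_id = cl$claim_id,
        service_date = format(cl$service_date),
        setting = cl$setting,
        icd10cm_code = cl$codes,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), claim_id = character(),
               service_date = character(), setting = character(),
               icd10cm_code = character(), stringsAsFactors = FALSE)
  df <- df[order(df$patient_id, df$service_date, df$claim_id,
                 df$icd10cm_code), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
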