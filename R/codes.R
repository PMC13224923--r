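# ICD-10-CM code normalization and pattern matching.
#
# All codes are held internally in a single canonical ("dotless") form:
# uppercase, decimal point removed, 3-7 alphanumeric characters with a
# leading letter. Patterns come in three kinds:
#   literal - one exact code,
#   family  - a code stem; the stem itself and every descendant match,
#   range   - a pair of same-length bounds "LO-HI"; a code matches when it
#             is at least LO and its prefix truncated to the length of HI
#             is at most HI (so descendants of in-range codes match too).
# Every kind may carry subtractive exclusion patterns which override a
# positive match.

#' Normalize an ICD-10-CM code string
#'
#' Converts a raw code to the canonical matching form: whitespace stripped,
#' uppercased, decimal point removed. The canonical form must be 3-7
#' alphanumeric characters starting with a letter; anything else is an
#' error naming the offending string. The function is idempotent.
#'
#' @param raw Character vector of raw code strings (dotted or dotless).
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code(c("I10", "E66.813", "n18.30"))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character())
  x <- toupper(gsub(".", "", trimws(as.character(raw)), fixed = TRUE))
  bad <- is.na(x) | !grepl("^[A-Z][A-Z0-9]{2,6}$", x)
  if (any(bad)) {
    stop("malformed ICD-10-CM code(s): ",
         paste(sprintf("'%s'", raw[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Format a normalized code with its conventional decimal point
#'
#' Inserts a dot after the third character when the code is longer than
#' three characters (the display convention for ICD-10-CM).
#'
#' @param code Character vector of normalized codes.
#' @return Character vector in dotted display form.
#' @export
format_code <- function(code) {
  ifelse(nchar(code) > 3L,
         paste0(substr(code, 1L, 3L), ".", substring(code, 4L)),
         code)
}

#' Construct a code pattern
#'
#' @param kind One of `"literal"`, `"family"`, `"range"`.
#' @param value For `literal` and `family`, a single code (dotted input is
#'   normalized). For `range`, either a string `"LO-HI"` or a length-2
#'   vector of bounds; bounds must be the same length, share a leading
#'   letter, and satisfy `LO <= HI`.
#' @param exclusions Optional list of `code_pattern` objects (or raw code
#'   strings, treated as literals) that subtract from the match.
#' @return An object of class `ckm_pattern`.
#' @examples
#' code_pattern("family", "I25")
#' code_pattern("range", "Z68.25-Z68.45")
#' @export
code_pattern <- function(kind = c("literal", "family", "range"),
                         value, exclusions = list()) {
  kind <- match.arg(kind)
  if (kind == "range") {
    if (length(value) == 1L) value <- strsplit(value, "-", fixed = TRUE)[[1L]]
    if (length(value) != 2L)
      stop("a range pattern needs exactly two bounds", call. = FALSE)
    value <- normalize_code(value)
    lo <- value[1L]; hi <- value[2L]
    if (nchar(lo) != nchar(hi))
      stop("range bounds must have equal length: ", lo, "-", hi, call. = FALSE)
    same_stem <- substr(lo, 1L, 3L) == substr(hi, 1L, 3L)
    same_letter_ordered <- substr(lo, 1L, 1L) == substr(hi, 1L, 1L) &&
      substr(lo, 1L, 3L) <= substr(hi, 1L, 3L)
    if (!(same_stem || same_letter_ordered))
      stop("range bounds must share a 3-character stem or an ordered ",
           "same-letter stem: ", lo, "-", hi, call. = FALSE)
    if (lo > hi)
      stop("range lower bound exceeds upper bound: ", lo, "-", hi,
           call. = FALSE)
  } else {
    if (length(value) != 1L)
      stop(kind, " pattern takes a single value", call. = FALSE)
    value <- normalize_code(value)
  }
  exclusions <- lapply(exclusions, function(e) {
    if (inherits(e, "ckm_pattern")) e else code_pattern("literal", e)
  })
  structure(list(kind = kind, value = value, exclusions = exclusions),
            class = "ckm_pattern")
}

#' @export
format.ckm_pattern <- function(x, ...) {
  body <- switch(x$kind,
    literal = format_code(x$value),
    family  = paste0(format_code(x$value), ".-"),
    range   = paste(format_code(x$value), collapse = "-"))
  if (length(x$exclusions)) {
    body <- paste0(body, " ∖ {",
                   paste(vapply(x$exclusions, format, ""), collapse = ", "),
                   "}")
  }
  body
}

#' @export
print.ckm_pattern <- function(x, ...) {
  cat("<ckm_pattern ", x$kind, "> ", format(x), "\n", sep = "")
  invisible(x)
}

match_one <- function(code, pattern) {
  hit <- switch(pattern$kind,
    literal = code == pattern$value,
    family  = startsWith(code, pattern$value),
    range   = {
      lo <- pattern$value[1L]; hi <- pattern$value[2L]
      nchar(code) >= nchar(lo) &
        code >= lo &
        substr(code, 1L, nchar(hi)) <= hi
    })
  if (any(hit) && length(pattern$exclusions)) {
    for (ex in pattern$exclusions) hit <- hit & !match_one(code, ex)
  }
  hit
}

#' Match normalized codes against a code pattern
#'
#' Literal patterns match by exact equality; family patterns match the stem
#' itself and any descendant; range patterns match codes lying between the
#' bounds under normalized lexicographic comparison, with the code prefix
#' truncated to the upper bound's length so that descendants of in-range
#' codes are captured (e.g. `I63.9` within `I60-I64`). Exclusions override
#' a positive match. Total on valid inputs; vectorized over `code`.
#'
#' @param code Character vector of normalized codes.
#' @param pattern A `ckm_pattern`.
#' @return Logical vector, one element per code.
#' @examples
#' code_matches("I213", code_pattern("family", "I21"))
#' code_matches("Z6841", code_pattern("range", "Z6825-Z6845"))
#' @export
code_matches <- function(code, pattern) {
  stopifnot(inherits(pattern, "ckm_pattern"))
  if (length(code) == 0L) return(logical())
  match_one(code, pattern)
}

#' Match codes against any pattern in a list
#'
#' @param code Character vector of normalized codes.
#' @param patterns List of `ckm_pattern` objects.
#' @return Logical vector, `TRUE` where at least one pattern matches.
#' @export
codes_match_any <- function(code, patterns) {
  if (length(code) == 0L) return(logical())
  hit <- rep(FALSE, length(code))
  for (p in patterns) hit <- hit | code_matches(code, p)
  hit
}
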