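# Shared fixtures: claims histories built in code, an independent
# explicit-expansion oracle for pattern matching, and the published
# stage-to-code mapping used for registry content checks.

default_index <- function(include = FALSE) {
  index_spec("2026-01-01", 24L, include_index_date = include)
}

history_of <- function(pid, ...) {
  specs <- list(...)
  patient_history(pid, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    claim_record(pid, s$date, s$setting, s$codes, paste0("c", i))
  }))
}

cl <- function(date, setting, codes) {
  list(date = date, setting = setting, codes = codes)
}

# the claims-only use case: hypertension and diabetes confirmed by
# outpatient pairs, one obesity claim with a BMI support code, one
# inpatient MI, no kidney-failure codes
worked_example_history <- function(pid = "case1") {
  history_of(pid,
    cl("2025-03-01", "outpatient", "I10"),
    cl("2025-04-15", "outpatient", "I10"),          # 45 days later
    cl("2025-02-01", "outpatient", "E11.9"),
    cl("2025-04-02", "outpatient", "E11.9"),        # 60 days later
    cl("2025-06-20", "outpatient", c("E66.813", "Z68.41")),
    cl("2025-09-10", "inpatient", "I21.3"))
}

# adiposity only, nothing from stages 2-4
contrast_history <- function(pid = "case2", code = "E66.9") {
  history_of(pid,
    cl("2025-02-01", "outpatient", code),
    cl("2025-04-01", "outpatient", code))
}

# ---- explicit-expansion oracle ---------------------------------------
# Independent of code_matches: every pattern is expanded to an explicit
# list of code prefixes by enumerating the numeric suffix sequence
# between the range bounds; membership is then a plain prefix test
# (exact equality for literals). Exclusions recurse.

oracle_expand <- function(pattern) {
  if (pattern$kind == "range") {
    lo <- pattern$value[1L]
    hi <- pattern$value[2L]
    # longest common prefix, then enumerate the numeric tail
    n <- nchar(lo)
    common <- 0L
    for (k in seq_len(n)) {
      if (substr(lo, 1L, k) == substr(hi, 1L, k)) common <- k else break
    }
    tail_lo <- as.integer(substring(lo, common + 1L))
    tail_hi <- as.integer(substring(hi, common + 1L))
    width <- n - common
    paste0(substr(lo, 1L, common),
           formatC(tail_lo:tail_hi, width = width, flag = "0"))
  } else {
    pattern$value
  }
}

oracle_matches <- function(code, pattern) {
  hit <- if (pattern$kind == "literal") {
    code == pattern$value
  } else {
    any(startsWith(code, oracle_expand(pattern)))
  }
  if (hit) {
    for (ex in pattern$exclusions) {
      if (oracle_matches(code, ex)) return(FALSE)
    }
  }
  hit
}

registry_patterns <- function(registry = ckm_registry()) {
  unlist(lapply(registry$code_sets, `[[`, "patterns"),
         recursive = FALSE, use.names = FALSE)
}

# every concrete code mentioned by the shipped registry: literals,
# family stems, and full range enumerations
registry_universe <- function(registry = ckm_registry()) {
  codes <- character()
  for (p in registry_patterns(registry)) {
    codes <- c(codes, oracle_expand(p))
    for (ex in p$exclusions) codes <- c(codes, oracle_expand(ex))
  }
  sort(unique(codes))
}

random_wellformed_codes <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    extra <- sample(0:4, 1L)
    paste0(sample(LETTERS, 1L),
           paste(sample(0:9, 2L, replace = TRUE), collapse = ""),
           paste(sample(c(0:9, LETTERS), extra, replace = TRUE),
                 collapse = ""))
  }, "")
}

# published stage-to-code mapping: every code string printed in the
# staging table, keyed by the stage row it appears in
published_stage_codes <- list(
  `1` = c("E663", "E66811", "E66812", "E66813", "E668", "E669",
          "Z6825", "Z6845", "R7303", "R635"),
  `2` = c("I10", "I119", "I120", "I1310", "E781", "E782", "E88810",
          "E119", "E11A", "E10", "E13", "N1830", "N1831", "N1832",
          "N181", "N182", "R80", "K760", "K7581", "G4730", "G4731",
          "G4733", "G4739", "E282"),
  `3` = c("N184", "N185", "N2581"),
  `4` = c("I25", "I20", "I210", "I211", "I212", "I213", "I214",
          "I21A1", "I22", "I501", "I502", "I503", "I504", "I509",
          "I110", "I130", "I132", "I480", "I4819", "I4820", "I4821",
          "I702", "I739", "I60", "I61", "I62", "I63", "I64", "I69",
          "Z8673", "N186", "Z992", "Z940"))
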