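# Code-set registry: named code sets with roles and acuity, five stage
# definitions, and JSON (authoritative) / CSV (flattened companion)
# serialization. The JSON document is the specification of record; the CSV
# is a review/audit artifact regenerated from it.

#' Construct a code set
#'
#' A named collection of code patterns with a role in the staging
#' algorithm and a condition acuity that selects the encounter-confirmation
#' rule (chronic: two outpatient claims on different dates or one
#' inpatient claim; acute: a single inpatient claim).
#'
#' @param name Identifier, unique within a registry.
#' @param role One of `"stage_core"`, `"supplementary"`, `"exclusion"`,
#'   `"substage_marker"`.
#' @param patterns Non-empty list of [code_pattern()] objects.
#' @param acuity `"chronic"` or `"acute"`. Acute is reserved for
#'   event-type sets (myocardial infarction, stroke).
#' @return An object of class `ckm_code_set`.
#' @export
code_set <- function(name,
                     role = c("stage_core", "supplementary", "exclusion",
                              "substage_marker"),
                     patterns,
                     acuity = c("chronic", "acute")) {
  role <- match.arg(role)
  acuity <- match.arg(acuity)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.list(patterns) || length(patterns) == 0L)
    stop("code set '", name, "' needs a non-empty pattern list",
         call. = FALSE)
  if (!all(vapply(patterns, inherits, TRUE, "ckm_pattern")))
    stop("patterns of '", name, "' must be ckm_pattern objects",
         call. = FALSE)
  structure(list(name = name, role = role, acuity = acuity,
                 patterns = patterns),
            class = "ckm_code_set")
}

#' @export
print.ckm_code_set <- function(x, ...) {
  cat("<ckm_code_set> ", x$name, " [", x$role, ", ", x$acuity, "]\n",
      sep = "")
  cat("  ", paste(vapply(x$patterns, format, ""), collapse = "; "), "\n",
      sep = "")
  invisible(x)
}

#' Construct a stage definition
#'
#' @param stage Integer 0-4.
#' @param core_sets,supplementary_sets,exclusion_sets Character vectors of
#'   code-set names. Stage 0 is defined by absence and has no core sets.
#' @param cooccurrence_rule Identifier of the eligibility rule applied by
#'   the staging engine for this stage.
#' @return An object of class `ckm_stage_def`.
#' @export
stage_definition <- function(stage, core_sets = character(),
                             supplementary_sets = character(),
                             exclusion_sets = character(),
                             cooccurrence_rule) {
  stage <- as.integer(stage)
  stopifnot(length(stage) == 1L, stage %in% 0:4)
  if (stage == 0L && length(core_sets) > 0L)
    stop("stage 0 is defined by absence and takes no core sets",
         call. = FALSE)
  structure(list(stage = stage,
                 core_sets = as.character(core_sets),
                 supplementary_sets = as.character(supplementary_sets),
                 exclusion_sets = as.character(exclusion_sets),
                 cooccurrence_rule = as.character(cooccurrence_rule)),
            class = "ckm_stage_def")
}

new_registry <- function(version, code_sets, stages) {
  names(code_sets) <- vapply(code_sets, `[[`, "", "name")
  if (anyDuplicated(names(code_sets)))
    stop("duplicate code-set name(s): ",
         paste(unique(names(code_sets)[duplicated(names(code_sets))]),
               collapse = ", "), call. = FALSE)
  stages <- stages[order(vapply(stages, `[[`, 0L, "stage"))]
  got <- vapply(stages, `[[`, 0L, "stage")
  if (!identical(got, 0:4))
    stop("a registry needs exactly five stage definitions 0-4; got: ",
         paste(got, collapse = ", "), call. = FALSE)
  for (sd in stages) {
    refs <- c(sd$core_sets, sd$supplementary_sets, sd$exclusion_sets)
    missing <- setdiff(refs, names(code_sets))
    if (length(missing))
      stop("stage ", sd$stage, " references undefined code set(s): ",
           paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  structure(list(version = version, code_sets = code_sets, stages = stages),
            class = "ckm_registry")
}

#' @export
print.ckm_registry <- function(x, ...) {
  cat("<ckm_registry> ", x$version, "\n", sep = "")
  cat("  ", length(x$code_sets), " code sets; stages 0-4\n", sep = "")
  for (sd in x$stages) {
    cat("  stage ", sd$stage, ": ",
        if (length(sd$core_sets)) paste(sd$core_sets, collapse = ", ")
        else "(defined by absence)", "\n", sep = "")
  }
  invisible(x)
}

#' Retrieve one code set from a registry
#'
#' @param registry A `ckm_registry`.
#' @param name Code-set name.
#' @return The `ckm_code_set`; errors if absent.
#' @export
registry_set <- function(registry, name) {
  s <- registry$code_sets[[name]]
  if (is.null(s)) stop("no code set named '", name, "'", call. = FALSE)
  s
}

#' Retrieve a stage definition from a registry
#'
#' @param registry A `ckm_registry`.
#' @param stage Integer 0-4.
#' @return The `ckm_stage_def`.
#' @export
registry_stage <- function(registry, stage) {
  registry$stages[[as.integer(stage) + 1L]]
}

#' Classify a code against every set in a registry
#'
#' Returns every (stage, role, set) whose patterns match the code, ordered
#' by stage then set name. Codes outside all CKM sets yield a zero-row
#' result.
#'
#' @param code A single normalized code.
#' @param registry A `ckm_registry`.
#' @return A data.frame with columns `stage`, `role`, `set_name`.
#' @export
classify_code <- function(code, registry) {
  stopifnot(length(code) == 1L)
  code <- normalize_code(code)
  rows <- list()
  for (sd in registry$stages) {
    refs <- sort(c(sd$core_sets, sd$supplementary_sets, sd$exclusion_sets))
    for (nm in refs) {
      st <- registry$code_sets[[nm]]
      if (codes_match_any(code, st$patterns)) {
        rows[[length(rows) + 1L]] <-
          data.frame(stage = sd$stage, role = st$role, set_name = nm,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(stage = integer(), role = character(),
                      set_name = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# ---- JSON serialization -----------------------------------------------

pattern_to_list <- function(p) {
  list(kind = p$kind,
       value = if (p$kind == "range") paste(p$value, collapse = "-")
               else p$value,
       exclusions = lapply(p$exclusions, pattern_to_list))
}

pattern_from_list <- function(x, path) {
  for (f in c("kind", "value")) {
    if (is.null(x[[f]]))
      stop("registry document invalid at ", path, ": missing '", f, "'",
           call. = FALSE)
  }
  excl <- lapply(seq_along(x$exclusions), function(i) {
    pattern_from_list(x$exclusions[[i]],
                      paste0(path, ".exclusions[", i, "]"))
  })
  tryCatch(code_pattern(x$kind, x$value, excl),
           error = function(e) {
             stop("registry document invalid at ", path, ": ",
                  conditionMessage(e), call. = FALSE)
           })
}

registry_to_list <- function(registry) {
  sets <- registry$code_sets[order(names(registry$code_sets))]
  list(
    version = registry$version,
    code_sets = lapply(unname(sets), function(s) {
      list(name = s$name, role = s$role, acuity = s$acuity,
           patterns = lapply(s$patterns, pattern_to_list))
    }),
    stages = lapply(registry$stages, function(sd) {
      list(stage = sd$stage,
           core_sets = as.list(sd$core_sets),
           supplementary_sets = as.list(sd$supplementary_sets),
           exclusion_sets = as.list(sd$exclusion_sets),
           cooccurrence_rule = sd$cooccurrence_rule)
    })
  )
}

#' Export a registry as canonical JSON
#'
#' The canonical form orders code sets by name and stages 0-4, so
#' `export_registry_json(load_registry(x))` is a fixed point.
#'
#' @param registry A `ckm_registry`.
#' @param path Optional file path; when given, the JSON text is also
#'   written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
export_registry_json <- function(registry, path = NULL) {
  txt <- jsonlite::toJSON(registry_to_list(registry), auto_unbox = TRUE,
                          pretty = 2, digits = NA)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Export a registry as a flattened CSV companion
#'
#' One row per (stage, set, pattern), with columns
#' `stage,set_name,role,acuity,pattern_kind,pattern_value,exclusions`.
#' Exclusion patterns are `|`-joined in `kind:value` form. Intended for
#' human review and audit; the JSON document remains authoritative.
#'
#' @param registry A `ckm_registry`.
#' @param path Optional file path for the CSV.
#' @return The data.frame, invisibly when `path` is given.
#' @export
export_registry_csv <- function(registry, path = NULL) {
  rows <- list()
  for (sd in registry$stages) {
    refs <- c(sd$core_sets, sd$supplementary_sets, sd$exclusion_sets)
    for (nm in sort(refs)) {
      st <- registry$code_sets[[nm]]
      for (p in st$patterns) {
        val <- if (p$kind == "range") paste(p$value, collapse = "-")
               else p$value
        exc <- paste(vapply(p$exclusions, function(e) {
          v <- if (e$kind == "range") paste(e$value, collapse = "-")
               else e$value
          paste0(e$kind, ":", v)
        }, ""), collapse = "|")
        rows[[length(rows) + 1L]] <- data.frame(
          stage = sd$stage, set_name = nm, role = st$role,
          acuity = st$acuity, pattern_kind = p$kind, pattern_value = val,
          exclusions = exc, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    return(invisible(out))
  }
  out
}

#' Load a registry from its JSON document
#'
#' Performs structural validation with JSON-path error messages, checks
#' that all five stage definitions are present and that every referenced
#' code set exists, and rebuilds the typed registry object.
#'
#' @param document JSON text, or a path to a JSON file.
#' @return A `ckm_registry`.
#' @export
load_registry <- function(document) {
  if (length(document) == 1L && !grepl("[{]", document) &&
      file.exists(document)) {
    document <- paste(readLines(document, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  for (f in c("version", "code_sets", "stages")) {
    if (is.null(doc[[f]]))
      stop("registry document invalid at $.", f, ": missing", call. = FALSE)
  }
  sets <- lapply(seq_along(doc$code_sets), function(i) {
    s <- doc$code_sets[[i]]
    path <- paste0("$.code_sets[", i, "]")
    for (f in c("name", "role", "acuity", "patterns")) {
      if (is.null(s[[f]]))
        stop("registry document invalid at ", path, ": missing '", f, "'",
             call. = FALSE)
    }
    pats <- lapply(seq_along(s$patterns), function(j) {
      pattern_from_list(s$patterns[[j]],
                        paste0(path, ".patterns[", j, "]"))
    })
    code_set(s$name, s$role, pats, s$acuity)
  })
  stages <- lapply(seq_along(doc$stages), function(i) {
    sd <- doc$stages[[i]]
    path <- paste0("$.stages[", i, "]")
    if (is.null(sd$stage) || is.null(sd$cooccurrence_rule))
      stop("registry document invalid at ", path,
           ": missing 'stage' or 'cooccurrence_rule'", call. = FALSE)
    stage_definition(sd$stage,
                     unlist(sd$core_sets) %||% character(),
                     unlist(sd$supplementary_sets) %||% character(),
                     unlist(sd$exclusion_sets) %||% character(),
                     sd$cooccurrence_rule)
  })
  new_registry(doc$version, sets, stages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The shipped FY2026 CKM registry
#'
#' Loads the packaged registry document mapping CKM stages 0-4 to
#' ICD-10-CM FY2026 code sets. The result is cached for the session.
#'
#' @return A `ckm_registry`.
#' @examples
#' reg <- ckm_registry()
#' classify_code("E88.810", reg)
#' @export
ckm_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "ckm_registry_fy2026.json",
                          package = "ckmstage", mustWork = TRUE)
      cache <<- load_registry(path)
    }
    cache
  }
})

#' Audit a registry for structural findings
#'
#' Returns findings rather than raising: malformed codes, empty pattern
#' lists, duplicate set names, acute acuity on non-event sets, and
#' stage-2 CKD-proxy sets whose patterns reach into very high-risk CKD
#' (N18.4-N18.5) or kidney failure (N18.6) without an exclusion -- those
#' codes must route to stages 3 and 4B, not stage 2.
#'
#' @param registry A `ckm_registry` (or a structurally similar list, so
#'   that damaged registries can still be audited).
#' @return A data.frame with columns `set_name` and `finding`; zero rows
#'   when clean.
#' @export
validate_registry <- function(registry) {
  findings <- list()
  note <- function(set_name, finding) {
    findings[[length(findings) + 1L]] <<-
      data.frame(set_name = set_name, finding = finding,
                 stringsAsFactors = FALSE)
  }
  nms <- vapply(registry$code_sets, `[[`, "", "name")
  for (d in unique(nms[duplicated(nms)]))
    note(d, "duplicate code-set name")
  event_sets <- c("ami", "stroke_acute")
  for (st in registry$code_sets) {
    if (length(st$patterns) == 0L) {
      note(st$name, "code set has zero patterns")
      next
    }
    for (p in st$patterns) {
      vals <- if (p$kind == "range") p$value else p$value
      ok <- grepl("^[A-Z][A-Z0-9]{2,6}$", vals)
      if (!all(ok))
        note(st$name, paste0("malformed code value '",
                             paste(vals[!ok], collapse = ","), "'"))
    }
    if (st$acuity == "acute" && !st$name %in% event_sets)
      note(st$name,
           "acute acuity is reserved for event-type sets (MI, stroke)")
  }
  # stage-2 CKD proxy must not reach N18.4-N18.6
  s2 <- registry$stages[[3L]]
  ckd_sets <- grep("^ckd", s2$core_sets, value = TRUE)
  for (nm in ckd_sets) {
    st <- registry$code_sets[[nm]]
    hot <- c("N184", "N185", "N186")
    hit <- hot[codes_match_any(hot, st$patterns)]
    if (length(hit))
      note(nm, paste0("stage-2 CKD proxy matches ",
                      paste(format_code(hit), collapse = ", "),
                      "; must exclude very high-risk CKD (N18.4-N18.5) ",
                      "and kidney failure (N18.6)"))
  }
  if (length(findings) == 0L)
    return(data.frame(set_name = character(), finding = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}
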