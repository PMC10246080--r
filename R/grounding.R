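# Parse the model's structured payload (Summary / Mechanism / Enriched
# Terms) and ground each returned term string to the ontology by exact
# normalized match against primary labels, then synonyms. Ungrounded is a
# legitimate outcome, not an error; matches to obsolete terms are kept but
# flagged, so the use of obsoleted vocabulary stays visible downstream.

#' Parse a completion payload
#'
#' Locates the section headers case-insensitively. The term list is split
#' on semicolons (falling back to commas when no semicolon is present),
#' enumeration prefixes and surrounding whitespace are stripped, and empty
#' fragments dropped. The narrative summary and mechanism are carried
#' verbatim; a payload containing what looks like a reported p-value is
#' flagged with a fabricated-statistic warning, since the generator performs
#' no statistical test.
#'
#' @param text Raw completion text.
#' @return An object of class `summary_payload`: list with `summary`,
#'   `mechanism`, `raw_terms`, `groundings` (`NULL` until
#'   [ground_payload()]), `warnings`.
#' @export
parse_payload <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  warnings <- character(0)
  grab_section <- function(header) {
    idx <- grep(paste0("^\\s*", header, "\\s*:"), lines, ignore.case = TRUE)
    if (!length(idx)) return(NULL)
    first <- sub(paste0("^\\s*", header, "\\s*:\\s*"), "",
                 lines[[idx[[1]]]], ignore.case = TRUE)
    rest <- character(0)
    j <- idx[[1]] + 1L
    while (j <= length(lines) &&
           !grepl("^\\s*(summary|mechanism|enriched terms|hypothesis|note)\\s*:",
                  lines[[j]], ignore.case = TRUE)) {
      rest <- c(rest, lines[[j]])
      j <- j + 1L
    }
    squish(paste(c(first, rest), collapse = " "))
  }
  summary <- grab_section("summary")
  mechanism <- grab_section("mechanism")
  terms_blob <- grab_section("enriched terms")
  if (is.null(terms_blob)) {
    cond <- errorCondition("no 'Enriched Terms' section found in payload",
                           class = c("genesum_parse_error", "genesum_error"))
    cond$raw_text <- text
    stop(cond)
  }
  if (is.null(summary)) {
    warnings <- c(warnings, "missing Summary section")
    summary <- ""
  }
  if (is.null(mechanism)) {
    warnings <- c(warnings, "missing Mechanism section")
    mechanism <- ""
  }
  sep <- if (grepl(";", terms_blob, fixed = TRUE)) ";" else ","
  raw <- strsplit(terms_blob, sep, fixed = TRUE)[[1]]
  raw <- vapply(raw, strip_enumeration, character(1), USE.NAMES = FALSE)
  raw <- raw[nzchar(raw)]
  stat_pat <- "\\bp(-| )?value|\\bp\\s*[=<]\\s*[0-9.]"
  if (grepl(stat_pat, paste(summary, mechanism, terms_blob),
            ignore.case = TRUE)) {
    warnings <- c(warnings,
                  "fabricated-statistic: payload reports a p-value that no test produced")
  }
  structure(list(summary = summary, mechanism = mechanism,
                 raw_terms = raw, groundings = NULL, warnings = warnings),
            class = "summary_payload")
}

#' @noRd
strip_enumeration <- function(x) {
  x <- squish(x)
  x <- sub("^\\(?[0-9]+[.)]?\\s+", "", x)
  x <- sub("^[-*]\\s+", "", x)
  squish(x)
}

# Normalization applied to labels, synonyms and raw term strings before
# exact comparison: case-fold, collapse internal whitespace, strip
# surrounding (non-alphanumeric) punctuation.
#' @noRd
normalize_term_string <- function(x) {
  x <- tolower(squish(x))
  gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", x)
}

# Lazily built normalized label/synonym -> term-id indexes on the ontology.
#' @noRd
grounding_index <- function(o, synonym_scopes = NULL) {
  cache <- ontology_cache(o)
  key <- paste0("gindex::", paste(synonym_scopes %||% "all", collapse = ","))
  idx <- cache[[key]]
  if (!is.null(idx)) return(idx)
  labels <- list()
  synonyms <- list()
  for (t in o$terms) {
    if (!is.na(t$label)) {
      k <- normalize_term_string(t$label)
      if (nzchar(k)) labels[[k]] <- c(labels[[k]], t$id)
    }
    for (j in seq_along(t$synonyms)) {
      if (!is.null(synonym_scopes) && !(t$synonym_scopes[[j]] %in% synonym_scopes)) next
      k <- normalize_term_string(t$synonyms[[j]])
      if (nzchar(k)) synonyms[[k]] <- c(synonyms[[k]], t$id)
    }
  }
  idx <- list(labels = labels, synonyms = synonyms)
  cache[[key]] <- idx
  idx
}

#' Ground one term string to the ontology
#'
#' Exact normalized matching only, against primary labels first and then
#' synonyms; no fuzzy matching (so a paraphrase of a label — however close —
#' stays ungrounded, which is exactly the behavior under study). Ambiguous
#' hits are broken by the lexicographically smallest term identifier, with a
#' warning. Strings shaped like numeric identifiers (`prefix:digits`) are
#' never grounded: the prompt deliberately avoids asking for identifiers
#' because generative models fabricate plausible-looking ones.
#'
#' @param raw Raw term string from the payload.
#' @param o An [ontology].
#' @param synonym_scopes Optional character vector restricting which synonym
#'   scopes (`EXACT`, `BROAD`, `NARROW`, `RELATED`) may ground; default all.
#' @return An object of class `grounding_outcome`: list with `raw`, `status`
#'   (`grounded`, `grounded_obsolete`, `ungrounded`), `term`, `matched_via`,
#'   `note`.
#' @export
ground_term <- function(raw, o, synonym_scopes = NULL) {
  out <- list(raw = raw, status = "ungrounded", term = NA_character_,
              matched_via = NA_character_, note = NA_character_)
  if (grepl("^[A-Za-z][A-Za-z0-9_.]*:[0-9]+$", trimws(raw))) {
    out$note <- "identifier-like string refused: identifiers are never accepted as groundings"
    return(structure(out, class = "grounding_outcome"))
  }
  key <- normalize_term_string(raw)
  if (!nzchar(key)) return(structure(out, class = "grounding_outcome"))
  idx <- grounding_index(o, synonym_scopes)
  hit <- idx$labels[[key]]
  via <- "label"
  if (is.null(hit)) {
    hit <- idx$synonyms[[key]]
    via <- "synonym"
  }
  if (is.null(hit)) return(structure(out, class = "grounding_outcome"))
  if (length(hit) > 1L) {
    out$note <- paste0("ambiguous match (", paste(sort(hit), collapse = ", "),
                       "); smallest identifier chosen")
  }
  term <- sort(hit)[[1]]
  out$term <- term
  out$matched_via <- via
  out$status <- if (o$terms[[term]]$obsolete) "grounded_obsolete" else "grounded"
  structure(out, class = "grounding_outcome")
}

#' Ground every term of a payload
#'
#' Applies [ground_term()] elementwise, preserving order. Raw strings that
#' ground to an identifier already produced by an earlier string are marked
#' duplicates (the term set downstream keeps the first occurrence).
#' Idempotent: grounding an already-grounded payload recomputes the same
#' outcomes.
#'
#' @param payload A `summary_payload` from [parse_payload()].
#' @param o An [ontology].
#' @param synonym_scopes Passed to [ground_term()].
#' @return The payload with `groundings` filled (one per raw term) and
#'   warnings accumulated.
#' @export
ground_payload <- function(payload, o, synonym_scopes = NULL) {
  outcomes <- lapply(payload$raw_terms, ground_term, o = o,
                     synonym_scopes = synonym_scopes)
  warnings <- payload$warnings[!grepl("^(duplicate|ambiguous|identifier)",
                                      payload$warnings)]
  seen <- character(0)
  for (i in seq_along(outcomes)) {
    oc <- outcomes[[i]]
    if (!is.na(oc$note)) warnings <- c(warnings, paste0(oc$raw, ": ", oc$note))
    if (oc$status != "ungrounded") {
      if (oc$term %in% seen) {
        outcomes[[i]]$duplicate <- TRUE
        warnings <- c(warnings,
                      paste0("duplicate grounding collapsed: '", oc$raw,
                             "' -> ", oc$term))
      } else {
        outcomes[[i]]$duplicate <- FALSE
        seen <- c(seen, oc$term)
      }
    }
  }
  payload$groundings <- outcomes
  payload$warnings <- unique(warnings)
  payload
}

#' Grounded term set of a payload
#'
#' Unique grounded identifiers in first-occurrence order.
#'
#' @param payload A grounded `summary_payload`.
#' @param include_obsolete Keep `grounded_obsolete` matches? Default `TRUE`.
#' @return Character vector of term identifiers.
#' @export
grounded_terms <- function(payload, include_obsolete = TRUE) {
  if (is.null(payload$groundings)) {
    stop_genesum("payload has not been grounded yet", "genesum_validation_error")
  }
  keep <- c("grounded", if (include_obsolete) "grounded_obsolete")
  ids <- vapply(payload$groundings, function(g) {
    if (g$status %in% keep) g$term else NA_character_
  }, character(1))
  unique(ids[!is.na(ids)])
}

#' Serialize a grounded payload as JSON
#'
#' @param payload A grounded `summary_payload`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_payload_json <- function(payload, path) {
  doc <- list(
    summary = payload$summary,
    mechanism = payload$mechanism,
    terms = lapply(payload$groundings %||% list(), function(g) {
      list(raw = g$raw, status = g$status,
           term_id = if (is.na(g$term)) NULL else g$term,
           matched_via = if (is.na(g$matched_via)) NULL else g$matched_via)
    }),
    warnings = as.list(payload$warnings)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @export
print.summary_payload <- function(x, ...) {
  cat("<summary_payload> ", length(x$raw_terms), " raw terms",
      if (!is.null(x$groundings)) {
        paste0(" (", length(grounded_terms(x)), " grounded)")
      } else " (ungrounded)",
      "\n  summary: ", substr(x$summary, 1, 70), "\n", sep = "")
  invisible(x)
}
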