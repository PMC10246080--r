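# Backend contract for prompt completion. A backend is a list with an `id`
# and a `fun(request) -> response text`. Completions are cached in a
# single-file JSON key-value store keyed by a content hash of
# (backend id, model name, temperature, prompt), so cached completions can
# be shipped as plain-text test fixtures and the whole suite runs offline.

#' Construct a completion request
#'
#' @param prompt The full prompt string.
#' @param model_name Model identifier recorded with the request.
#' @param temperature Sampling temperature; defaults to 0, the minimum
#'   (determinism-maximizing) setting.
#' @param max_output_tokens Output token cap; defaults to the 25% output
#'   reserve of a 4096-token budget.
#' @return An object of class `completion_request`.
#' @export
completion_request <- function(prompt, model_name = "mock", temperature = 0,
                               max_output_tokens = 1024L) {
  if (temperature < 0) {
    stop_genesum("temperature must be nonnegative", "genesum_validation_error")
  }
  structure(list(prompt = prompt, model_name = model_name,
                 temperature = temperature,
                 max_output_tokens = as.integer(max_output_tokens)),
            class = "completion_request")
}

#' Open (or create) a completion cache
#'
#' @param path Path of the JSON cache file; created on first write.
#' @return An object of class `completion_cache`.
#' @export
completion_cache <- function(path) {
  structure(list(path = path), class = "completion_cache")
}

#' @noRd
cache_read_all <- function(cache) {
  if (is.null(cache) || !file.exists(cache$path)) return(list())
  jsonlite::fromJSON(cache$path, simplifyVector = FALSE)
}

#' @noRd
cache_key <- function(backend_id, req) {
  content_hash(backend_id, req$model_name, req$temperature, req$prompt)
}

#' @noRd
cache_get <- function(cache, key) {
  cache_read_all(cache)[[key]]
}

#' @noRd
cache_put <- function(cache, key, response_text) {
  entries <- cache_read_all(cache)
  entries[[key]] <- response_text
  jsonlite::write_json(entries, cache$path, auto_unbox = TRUE, pretty = TRUE)
  invisible(key)
}

#' Complete a prompt through a backend, cache first
#'
#' The cache is consulted before the backend; on a miss the backend is
#' called and the response stored, so a repeated identical request is served
#' byte-identically from cache. Any change to the prompt — including an
#' end-marker toggle — changes the key and forces a fresh completion, which
#' is what makes the run-to-run stability probe work.
#'
#' @param req A [completion_request].
#' @param backend A backend object (see [mock_backend()],
#'   [cached_only_backend()], [openai_compatible_backend()]).
#' @param cache Optional [completion_cache].
#' @return An object of class `completion_record`: list with `request`,
#'   `response_text`, `backend_id`, `cached`, `truncated_output`.
#' @export
complete <- function(req, backend, cache = NULL) {
  key <- cache_key(backend$id, req)
  hit <- cache_get(cache, key)
  cached <- !is.null(hit)
  if (cached) {
    response <- hit
  } else {
    response <- tryCatch(backend$fun(req), error = function(e) {
      stop_genesum(paste0("backend '", backend$id,
                          "' failed with no cache entry (retry possible): ",
                          conditionMessage(e)),
                   "genesum_transport_error")
    })
    if (!is.null(cache)) cache_put(cache, key, response)
  }
  truncated <- count_tokens(response) >= req$max_output_tokens
  if (truncated) {
    warn_genesum("response may have been truncated by the output token limit",
                 "genesum_llm_warning")
  }
  structure(list(request = req, response_text = response,
                 backend_id = backend$id, cached = cached,
                 truncated_output = truncated),
            class = "completion_record")
}

#' Deterministic mock completion
#'
#' A pure function of the prompt, the behavior flag, and the annotation
#' store's label inventory. The mock reads *only* the description lines in
#' the prompt (mirroring the observation that, under swapped descriptions,
#' a model summarizes the in-context text and ignores the gene symbols):
#'
#' * `faithful` — returned terms are the ontology labels occurring in two or
#'   more description lines, most-shared first;
#' * `noisy` — faithful, plus one unrelated ontology label chosen
#'   deterministically from a hash of the whole prompt (so any prompt edit,
#'   even the end marker, can change it);
#' * `ungroundable` — faithful, with the last term replaced by a paraphrase
#'   absent from the ontology's labels and synonyms.
#'
#' @param req A [completion_request].
#' @param store The [annotation_store] whose ontology supplies the label
#'   inventory.
#' @param behavior `"faithful"`, `"noisy"`, or `"ungroundable"`.
#' @return Response text in the `Summary:` / `Mechanism:` /
#'   `Enriched Terms:` payload format.
#' @export
mock_complete <- function(req, store,
                          behavior = c("faithful", "noisy", "ungroundable")) {
  behavior <- match.arg(behavior)
  lines <- extract_description_lines(req$prompt)
  if (!length(lines)) {
    stop_genesum("prompt contains no recognizable description block",
                 "genesum_format_error")
  }
  o <- store$ontology
  labels <- sort(vapply(o$terms, `[[`, character(1), "label"))
  labels <- labels[!is.na(labels) & nzchar(labels)]
  counts <- vapply(labels, function(lb) {
    sum(vapply(lines, function(ln) grepl(lb, ln, fixed = TRUE), logical(1)))
  }, integer(1))
  shared <- labels[counts >= 2L]
  shared <- shared[order(-counts[counts >= 2L], shared)]
  terms <- shared
  if (behavior == "noisy") {
    pool <- labels[counts == 0L]
    if (length(pool)) {
      pick <- pool[(hash_int(req$prompt) %% length(pool)) + 1L]
      terms <- c(terms, pick)
    }
  } else if (behavior == "ungroundable" && length(terms)) {
    known <- c(labels, unlist(lapply(o$terms, `[[`, "synonyms"),
                              use.names = FALSE))
    phony <- paste(terms[length(terms)], "maintenance")
    while (phony %in% known) phony <- paste(phony, "maintenance")
    terms[length(terms)] <- phony
  }
  head_term <- if (length(terms)) terms[[1]] else "no shared function"
  paste0(
    "Summary: These ", length(lines),
    " genes share functions related to ", head_term, ".\n",
    "Mechanism: The genes may act together in processes involving ",
    head_term, ".\n",
    "Enriched Terms: ", paste(terms, collapse = "; "), "\n")
}

# Pull the gene description block back out of a built prompt: the lines
# following the "Here are the gene summaries:" cue, minus end markers and
# blanks.
#' @noRd
extract_description_lines <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  cue <- grep("Here are the gene summaries:", lines, fixed = TRUE)
  if (!length(cue)) return(character(0))
  body <- lines[seq(cue[[1]] + 1L, length.out = max(0L, length(lines) - cue[[1]]))]
  body <- trimws(body)
  body[nzchar(body) & !grepl("^[^A-Za-z0-9]+$", body)]
}

#' Mock backend
#'
#' Wraps [mock_complete()] in the backend contract.
#'
#' @inheritParams mock_complete
#' @return A backend object usable with [complete()].
#' @export
mock_backend <- function(store,
                         behavior = c("faithful", "noisy", "ungroundable")) {
  behavior <- match.arg(behavior)
  list(id = paste0("mock-", behavior),
       fun = function(req) mock_complete(req, store, behavior))
}

#' Cached-only backend
#'
#' Never generates: every cache miss is a transport error. Useful for
#' replaying shipped completion fixtures.
#'
#' @return A backend object.
#' @export
cached_only_backend <- function() {
  list(id = "cached-only",
       fun = function(req) {
         stop("cold cache: no entry for this request and no live backend")
       })
}

#' OpenAI-compatible live backend
#'
#' Thin adapter for a chat-completions-style HTTP endpoint. Endpoint and key
#' are read from the environment variables `GENESUM_API_BASE` and
#' `GENESUM_API_KEY`, never from configuration files. Requires network
#' access and the `curl` binary; everything else in the package runs with
#' the mock or cached backends.
#'
#' @return A backend object.
#' @export
openai_compatible_backend <- function() {
  list(id = "openai-compatible",
       fun = function(req) {
         base <- Sys.getenv("GENESUM_API_BASE")
         key <- Sys.getenv("GENESUM_API_KEY")
         if (!nzchar(base)) {
           stop("GENESUM_API_BASE is not set")
         }
         body <- jsonlite::toJSON(list(
           model = req$model_name,
           temperature = req$temperature,
           max_tokens = req$max_output_tokens,
           prompt = req$prompt), auto_unbox = TRUE)
         tmp <- tempfile(fileext = ".json")
         on.exit(unlink(tmp), add = TRUE)
         writeLines(body, tmp)
         out <- system2("curl",
                        c("-sS", "-X", "POST",
                          paste0(base, "/completions"),
                          "-H", "Content-Type: application/json",
                          "-H", paste0("Authorization: Bearer ", key),
                          "--data", paste0("@", tmp)),
                        stdout = TRUE)
         resp <- jsonlite::fromJSON(paste(out, collapse = ""),
                                    simplifyVector = FALSE)
         resp$choices[[1]]$text %||% resp$choices[[1]]$message$content
       })
}
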