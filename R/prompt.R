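# Token-budgeted prompt construction. The template carries two placeholders,
# {{ taxon }} and {{ gene_descriptions }}; description lines are truncated
# from the end of the string by a single global truncation factor (TF) so
# the filled prompt fits the model's token budget after an output reserve.

#' Count tokens in a string
#'
#' The default tokenizer counts whitespace-delimited words, the usual
#' rough-and-ready gloss of model tokens; any function mapping a string to a
#' nonnegative integer can be plugged in for model-accurate accounting.
#'
#' @param text A string.
#' @param tokenizer `"whitespace"` or a function `(character) -> integer`.
#' @return Nonnegative integer token count.
#' @export
count_tokens <- function(text, tokenizer = "whitespace") {
  if (is.function(tokenizer)) return(as.integer(tokenizer(text)))
  if (!identical(tokenizer, "whitespace")) {
    stop_genesum(paste0("unknown tokenizer: ", tokenizer),
                 "genesum_validation_error")
  }
  if (!nzchar(text)) return(0L)
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  length(toks[nzchar(toks)])
}

#' Global truncation factor for a set of description lengths
#'
#' TF is the fraction of each description's tokens retained so the summed
#' description text fits `available_budget`: `min(1, budget / sum(tokens))`.
#' A TF of 1 means no truncation; a TF of 0.25 means only 25% of the
#' original text could be used.
#'
#' @param description_tokens Integer vector of per-description token counts.
#' @param available_budget Tokens available for description text after the
#'   fixed template, per-line overhead and output reserve are subtracted.
#' @return TF in `(0, 1]`.
#' @export
compute_truncation_factor <- function(description_tokens, available_budget) {
  total <- sum(description_tokens)
  if (total == 0) return(1)
  if (available_budget <= 0) {
    stop_genesum("no token budget left for descriptions (template alone exceeds the limit)",
                 "genesum_budget_error")
  }
  min(1, available_budget / total)
}

#' Read the packaged default prompt template
#'
#' @param path Optional override path; by default the template shipped with
#'   the package.
#' @return Template text as one string.
#' @export
default_template <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("templates", "prompt.txt", package = "genesum")
  }
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Specify a prompt to build
#'
#' @param descriptions List of [gene_description] objects, in order.
#' @param taxon Taxon string substituted for `{{ taxon }}`.
#' @param token_budget Model token limit covering input and output; defaults
#'   to 4096 (the classic completion-model limit; 8192 and 32768 suit larger
#'   models).
#' @param template_text Template with `{{ taxon }}` and
#'   `{{ gene_descriptions }}` placeholders.
#' @param end_marker Marker appended after the description block; the
#'   stability probe toggles this between `"###"` and `"==="`.
#' @param output_reserve Fraction of `token_budget` held back for the
#'   model's output (the limit covers both directions). Default 0.25.
#' @return An object of class `prompt_spec`.
#' @export
prompt_spec <- function(descriptions, taxon = "Homo sapiens",
                        token_budget = 4096L,
                        template_text = default_template(),
                        end_marker = "###",
                        output_reserve = 0.25) {
  if (!nzchar(end_marker)) {
    stop_genesum("end_marker must be nonempty", "genesum_validation_error")
  }
  if (token_budget <= 0) {
    stop_genesum("token_budget must be positive", "genesum_validation_error")
  }
  structure(list(descriptions = descriptions, taxon = taxon,
                 token_budget = as.integer(token_budget),
                 template_text = template_text, end_marker = end_marker,
                 output_reserve = output_reserve),
            class = "prompt_spec")
}

#' @noRd
fill_template <- function(template_text, taxon, block) {
  out <- gsub("{{ taxon }}", taxon, template_text, fixed = TRUE)
  gsub("{{ gene_descriptions }}", block, out, fixed = TRUE)
}

#' Build a prompt under the token budget
#'
#' Fills the template, computes the tokens available for description text
#' (budget minus output reserve, fixed template tokens, per-line symbol
#' overhead and the end marker), derives the global truncation factor, and
#' truncates each description to its first `floor(TF * tokens)` tokens —
#' from the end of the string, on the assumption that the head of a
#' description is the more informative part. Building the same spec twice
#' yields byte-identical text.
#'
#' @param spec A [prompt_spec].
#' @param tokenizer Passed to [count_tokens()].
#' @return An object of class `built_prompt`: list with `text`,
#'   `truncation_factor`, `token_count`.
#' @export
build_prompt <- function(spec, tokenizer = "whitespace") {
  desc <- spec$descriptions
  texts <- vapply(desc, `[[`, character(1), "text")
  lines <- vapply(desc, `[[`, character(1), "line")
  text_tokens <- vapply(texts, count_tokens, integer(1),
                        tokenizer = tokenizer, USE.NAMES = FALSE)
  line_tokens <- vapply(lines, count_tokens, integer(1),
                        tokenizer = tokenizer, USE.NAMES = FALSE)
  overhead <- sum(line_tokens - text_tokens)
  fixed <- fill_template(spec$template_text, spec$taxon, "")
  fixed_tokens <- count_tokens(fixed, tokenizer) +
    count_tokens(spec$end_marker, tokenizer)
  reserve <- ceiling(spec$output_reserve * spec$token_budget)
  available <- spec$token_budget - reserve - fixed_tokens - overhead
  if (available < 0 || (available <= 0 && sum(text_tokens) > 0)) {
    stop_genesum(sprintf(
      "token budget %d cannot accommodate the template and %d description line(s)",
      spec$token_budget, length(desc)), "genesum_budget_error")
  }
  tf <- compute_truncation_factor(text_tokens, available)
  new_lines <- lines
  if (tf < 1) {
    keep <- floor(tf * text_tokens)
    for (i in seq_along(desc)) {
      if (text_tokens[[i]] == 0L || keep[[i]] >= text_tokens[[i]]) next
      toks <- strsplit(texts[[i]], "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      kept <- paste(toks[seq_len(keep[[i]])], collapse = " ")
      new_lines[[i]] <- if (nzchar(kept)) {
        paste0(desc[[i]]$symbol, ": ", kept)
      } else {
        desc[[i]]$symbol
      }
    }
  }
  block <- paste(new_lines, collapse = "\n")
  text <- paste0(fill_template(spec$template_text, spec$taxon, block),
                 "\n", spec$end_marker)
  structure(list(text = text,
                 truncation_factor = tf,
                 token_count = count_tokens(text, tokenizer)),
            class = "built_prompt")
}

#' @export
print.built_prompt <- function(x, ...) {
  cat("<built_prompt> ", x$token_count, " tokens, TF = ",
      format(x$truncation_factor, digits = 4), "\n", sep = "")
  invisible(x)
}
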