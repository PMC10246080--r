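# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state; the caller's .Random.seed is
# untouched, so seeded operations compose without side effects.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Stable content hash used for completion cache keys and the mock
# backend's prompt-sensitive choices.
#' @noRd
content_hash <- function(...) {
  digest::digest(list(...), algo = "sha256")
}

# Small nonnegative integer derived from a hash, for deterministic
# prompt-dependent choices in the mock backend.
#' @noRd
hash_int <- function(...) {
  strtoi(substr(content_hash(...), 1L, 7L), base = 16L)
}

# Collapse runs of whitespace and trim; used for prompt lines and for
# grounding normalization.
#' @noRd
squish <- function(x) {
  trimws(gsub("[[:space:]]+", " ", x))
}

#' @noRd
stop_genesum <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "genesum_error")))
}

#' @noRd
warn_genesum <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "genesum_warning")))
}
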