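# Ontology container: terms with labels, synonyms, obsolescence metadata and
# typed parent edges, plus transitive ancestor/descendant closure over a
# configurable relation set. Identifiers are opaque strings compared exactly.

#' Construct an ontology object
#'
#' Builds the in-memory ontology used throughout the package: a directed
#' acyclic graph of terms connected by typed parent edges (e.g. `is_a`,
#' `part_of`). Only the relations named in `closure_relations` participate in
#' ancestor/descendant closure; obsolete terms are loaded and indexed (so
#' free-text grounding can still recognize them) but contribute no edges to
#' closure traversal.
#'
#' @param terms A list of term records, each a list with elements `id`,
#'   `label`, `synonyms` (character vector), `synonym_scopes` (character
#'   vector parallel to `synonyms`), `obsolete` (logical), `replaced_by`
#'   (identifier or `NA`), and `parents` (data frame with columns `relation`
#'   and `parent`).
#' @param closure_relations Character vector of relation names traversed when
#'   computing closures. Defaults to `is_a` plus `part_of`.
#'
#' @return An object of class `ontology`.
#' @export
ontology <- function(terms, closure_relations = c("is_a", "part_of")) {
  if (length(closure_relations) < 1L) {
    stop_genesum("closure_relations must name at least one relation",
                 "genesum_validation_error")
  }
  terms <- lapply(terms, normalize_term)
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_genesum(paste0("duplicate term identifier: ",
                        ids[duplicated(ids)][1]),
                 "genesum_validation_error")
  }
  names(terms) <- ids
  o <- structure(
    list(terms = terms, closure_relations = closure_relations),
    class = "ontology"
  )
  validate_ontology(o)
  attr(o, "cache") <- new.env(parent = emptyenv())
  o
}

#' @noRd
normalize_term <- function(t) {
  stopifnot(is.character(t$id), nzchar(t$id))
  parents <- t$parents
  if (is.null(parents) || NROW(parents) == 0L) {
    parents <- data.frame(relation = character(0), parent = character(0),
                          stringsAsFactors = FALSE)
  }
  list(
    id = t$id,
    label = t$label %||% NA_character_,
    synonyms = as.character(t$synonyms %||% character(0)),
    synonym_scopes = as.character(t$synonym_scopes %||%
                                    rep("EXACT", length(t$synonyms %||% character(0)))),
    obsolete = isTRUE(t$obsolete),
    replaced_by = t$replaced_by %||% NA_character_,
    parents = `rownames<-`(parents[order(parents$parent, parents$relation), ,
                                   drop = FALSE], NULL)
  )
}

#' @noRd
validate_ontology <- function(o) {
  ids <- names(o$terms)
  for (t in o$terms) {
    unknown <- setdiff(t$parents$parent, ids)
    if (length(unknown)) {
      stop_genesum(paste0("term ", t$id, " has unresolved parent ", unknown[1]),
                   "genesum_validation_error")
    }
    if (!is.na(t$replaced_by)) {
      if (!t$replaced_by %in% ids || o$terms[[t$replaced_by]]$obsolete) {
        stop_genesum(paste0("term ", t$id,
                            " replaced_by must name a non-obsolete term: ",
                            t$replaced_by),
                     "genesum_validation_error")
      }
    }
  }
  cyc <- find_cycle(o)
  if (!is.null(cyc)) {
    stop_genesum(paste0("closure graph contains a cycle: ",
                        paste(cyc, collapse = " -> ")),
                 "genesum_cycle_error")
  }
  invisible(o)
}

# Parents of `id` that participate in closure traversal. Obsolete terms have
# no closure parents by construction.
#' @noRd
closure_parents <- function(o, id) {
  t <- o$terms[[id]]
  if (t$obsolete) return(character(0))
  unique(t$parents$parent[t$parents$relation %in% o$closure_relations])
}

# Depth-first search over closure edges; returns one cycle as a vector of
# identifiers, or NULL when the graph is acyclic.
#' @noRd
find_cycle <- function(o) {
  color <- new.env(parent = emptyenv())   # absent = white, 1 = grey, 2 = black
  for (start in names(o$terms)) {
    if (!is.null(color[[start]])) next
    # iterative DFS with an explicit stack of (node, parent-iterator index)
    stack <- list(list(id = start, i = 0L,
                       kids = closure_parents(o, start)))
    color[[start]] <- 1L
    path <- c(start)
    while (length(stack)) {
      top <- stack[[length(stack)]]
      if (top$i < length(top$kids)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- top$kids[[top$i + 1L]]
        st <- color[[nxt]]
        if (is.null(st)) {
          color[[nxt]] <- 1L
          path <- c(path, nxt)
          stack[[length(stack) + 1L]] <-
            list(id = nxt, i = 0L, kids = closure_parents(o, nxt))
        } else if (st == 1L) {
          return(c(path[seq(match(nxt, path), length(path))], nxt))
        }
      } else {
        color[[top$id]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      }
    }
  }
  NULL
}

#' @noRd
ontology_cache <- function(o) {
  cache <- attr(o, "cache")
  if (is.null(cache)) {
    # objects restored from serialization lose nothing: rebuild lazily
    cache <- new.env(parent = emptyenv())
  }
  cache
}

#' @noRd
check_term <- function(o, id) {
  if (!id %in% names(o$terms)) {
    stop_genesum(paste0("unknown term identifier: ", id),
                 "genesum_lookup_error")
  }
  invisible(id)
}

#' Ancestors of a term
#'
#' Transitive closure over the ontology's configured closure relations.
#'
#' @param o An [ontology] object.
#' @param id Term identifier.
#' @param reflexive Include the term itself?
#' @return Character vector of ancestor identifiers (unordered set).
#' @export
ancestors <- function(o, id, reflexive = FALSE) {
  check_term(o, id)
  cache <- ontology_cache(o)
  key <- paste0("anc::", id)
  res <- cache[[key]]
  if (is.null(res)) {
    seen <- character(0)
    frontier <- closure_parents(o, id)
    while (length(frontier)) {
      new <- setdiff(frontier, seen)
      seen <- c(seen, new)
      frontier <- unique(unlist(lapply(new, closure_parents, o = o),
                                use.names = FALSE))
    }
    res <- sort(unique(seen))
    cache[[key]] <- res
  }
  if (reflexive) sort(unique(c(res, id))) else res
}

# Lazily built child adjacency over closure edges.
#' @noRd
child_index <- function(o) {
  cache <- ontology_cache(o)
  idx <- cache[["children"]]
  if (is.null(idx)) {
    idx <- new.env(parent = emptyenv())
    for (id in names(o$terms)) {
      for (p in closure_parents(o, id)) {
        idx[[p]] <- c(idx[[p]], id)
      }
    }
    cache[["children"]] <- idx
  }
  idx
}

#' Descendants of a term
#'
#' @inheritParams ancestors
#' @return Character vector of descendant identifiers.
#' @export
descendants <- function(o, id, reflexive = FALSE) {
  check_term(o, id)
  cache <- ontology_cache(o)
  key <- paste0("desc::", id)
  res <- cache[[key]]
  if (is.null(res)) {
    kids <- child_index(o)
    seen <- character(0)
    frontier <- kids[[id]] %||% character(0)
    while (length(frontier)) {
      new <- setdiff(frontier, seen)
      seen <- c(seen, new)
      frontier <- unique(unlist(lapply(new, function(x) kids[[x]] %||% character(0)),
                                use.names = FALSE))
    }
    res <- sort(unique(seen))
    cache[[key]] <- res
  }
  if (reflexive) sort(unique(c(res, id))) else res
}

#' Are two terms related through the hierarchy?
#'
#' True when the terms are equal, or one is an ancestor or descendant of the
#' other under the ontology's closure relations. This is the matching rule
#' used by the closure-aware benchmark when crediting a predicted term
#' against a standard-enrichment term.
#'
#' @inheritParams ancestors
#' @param a,b Term identifiers.
#' @return Logical scalar.
#' @export
related_by_hierarchy <- function(o, a, b) {
  check_term(o, a)
  check_term(o, b)
  a == b || a %in% ancestors(o, b) || a %in% descendants(o, b)
}

#' Load an ontology from disk
#'
#' Reads OBO 1.4 flat files or OBO-Graph JSON. All terms are loaded,
#' including obsolete ones (needed so grounding can flag the use of
#' obsoleted vocabulary); obsolete terms never contribute closure edges.
#'
#' @param path Path to the ontology file.
#' @param format `"obo"` or `"obographs-json"`. Defaults by file extension
#'   (`.json` selects OBO-Graph JSON).
#' @param closure_relations Relations traversed by [ancestors()] and
#'   [descendants()].
#' @return An [ontology] object.
#' @export
load_ontology <- function(path,
                          format = c("auto", "obo", "obographs-json"),
                          closure_relations = c("is_a", "part_of")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_genesum(paste0("ontology file not found: ", path), "genesum_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "obographs-json" else "obo"
  }
  terms <- switch(format,
                  "obo" = parse_obo(path),
                  "obographs-json" = parse_obographs(path))
  ontology(terms, closure_relations = closure_relations)
}

#' @noRd
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  cur_line <- 0L
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$id)) {
        stop_genesum(paste0("OBO parse error: [Term] stanza starting at line ",
                            cur_line, " has no id"),
                     "genesum_format_error")
      }
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" ) next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(synonyms = character(0), synonym_scopes = character(0),
                    parents = data.frame(relation = character(0),
                                         parent = character(0),
                                         stringsAsFactors = FALSE))
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop_genesum(paste0("OBO parse error at line ", i, ": ", ln),
                   "genesum_format_error")
    }
    key <- m[2]; val <- m[3]
    if (key == "id") {
      cur$id <- strip_obo_comment(val)
    } else if (key == "name") {
      cur$label <- val
    } else if (key == "synonym") {
      sm <- regmatches(val, regexec('^"(.*)"\\s*([A-Z]*)', val))[[1]]
      if (length(sm) != 3L) {
        stop_genesum(paste0("OBO parse error at line ", i,
                            ": malformed synonym: ", val),
                     "genesum_format_error")
      }
      cur$synonyms <- c(cur$synonyms, sm[2])
      cur$synonym_scopes <- c(cur$synonym_scopes,
                              if (nzchar(sm[3])) sm[3] else "RELATED")
    } else if (key == "is_a") {
      cur$parents <- rbind(cur$parents,
                           data.frame(relation = "is_a",
                                      parent = strip_obo_comment(val),
                                      stringsAsFactors = FALSE))
    } else if (key == "relationship") {
      parts <- strsplit(strip_obo_comment(val), "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop_genesum(paste0("OBO parse error at line ", i,
                            ": malformed relationship: ", val),
                     "genesum_format_error")
      }
      cur$parents <- rbind(cur$parents,
                           data.frame(relation = parts[1], parent = parts[2],
                                      stringsAsFactors = FALSE))
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(strip_obo_comment(val), "true")
    } else if (key == "replaced_by") {
      cur$replaced_by <- strip_obo_comment(val)
    }
    # other tags (def, xref, namespace, ...) are ignored
  }
  flush()
  terms
}

#' @noRd
strip_obo_comment <- function(x) {
  trimws(sub("\\s*!.*$", "", x))
}

#' @noRd
parse_obographs <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_genesum(paste0("OBO-Graph JSON parse error in ", path,
                                        ": ", conditionMessage(e)),
                                 "genesum_format_error")
                  })
  graphs <- doc$graphs
  if (is.null(graphs) || !length(graphs)) {
    stop_genesum("OBO-Graph JSON has no graphs", "genesum_format_error")
  }
  g <- graphs[[1]]
  terms <- list()
  for (nd in g$nodes %||% list()) {
    if (!is.null(nd$type) && !identical(nd$type, "CLASS")) next
    syn <- nd$meta$synonyms %||% list()
    syn_vals <- vapply(syn, function(s) s$val %||% "", character(1))
    syn_scopes <- vapply(syn, function(s) {
      pred <- s$pred %||% "hasRelatedSynonym"
      switch(pred,
             hasExactSynonym = "EXACT", hasBroadSynonym = "BROAD",
             hasNarrowSynonym = "NARROW", hasRelatedSynonym = "RELATED",
             "RELATED")
    }, character(1))
    repl <- NA_character_
    for (bpv in nd$meta$basicPropertyValues %||% list()) {
      if (grepl("IAO_0100001", bpv$pred %||% "")) repl <- bpv$val
    }
    terms[[length(terms) + 1L]] <- list(
      id = nd$id,
      label = nd$lbl %||% NA_character_,
      synonyms = syn_vals[nzchar(syn_vals)],
      synonym_scopes = syn_scopes[nzchar(syn_vals)],
      obsolete = isTRUE(nd$meta$deprecated),
      replaced_by = repl,
      parents = data.frame(relation = character(0), parent = character(0),
                           stringsAsFactors = FALSE)
    )
  }
  idx <- vapply(terms, `[[`, character(1), "id")
  for (e in g$edges %||% list()) {
    pred <- e$pred %||% "is_a"
    rel <- if (identical(pred, "is_a")) "is_a" else shorten_pred(pred)
    j <- match(e$sub, idx)
    if (is.na(j)) next
    terms[[j]]$parents <- rbind(
      terms[[j]]$parents,
      data.frame(relation = rel, parent = e$obj, stringsAsFactors = FALSE))
  }
  terms
}

# Map common relation IRIs onto OBO relation names; anything unrecognized
# keeps its final path segment as an opaque relation name.
#' @noRd
shorten_pred <- function(pred) {
  if (grepl("BFO_0000050", pred)) return("part_of")
  sub("^.*[/#]", "", pred)
}

#' Write an ontology as an OBO 1.4 flat file
#'
#' Stanzas are emitted in identifier order so output is deterministic.
#'
#' @param o An [ontology] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(o, path) {
  out <- c("format-version: 1.4", "")
  for (id in sort(names(o$terms))) {
    t <- o$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", t$id))
    if (!is.na(t$label)) out <- c(out, paste0("name: ", t$label))
    for (j in seq_along(t$synonyms)) {
      out <- c(out, sprintf('synonym: "%s" %s []',
                            t$synonyms[[j]], t$synonym_scopes[[j]]))
    }
    p <- t$parents
    if (NROW(p)) {
      for (j in seq_len(nrow(p))) {
        if (p$relation[[j]] == "is_a") {
          out <- c(out, paste0("is_a: ", p$parent[[j]]))
        } else {
          out <- c(out, paste0("relationship: ", p$relation[[j]], " ",
                               p$parent[[j]]))
        }
      }
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    if (!is.na(t$replaced_by)) out <- c(out, paste0("replaced_by: ", t$replaced_by))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, `[[`, logical(1), "obsolete"))
  cat("<ontology> ", length(x$terms), " terms (", n_obs, " obsolete); ",
      "closure over {", paste(x$closure_relations, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}
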