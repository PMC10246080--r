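# Per-gene description lines placed into the prompt. Three sources: none
# (bare symbol), narrative (curated prose looked up in a table), and
# ontological (controlled natural language rendered from the gene's direct
# annotations).

#' Construct a gene description
#'
#' @param symbol Gene symbol.
#' @param source One of `"none"`, `"narrative"`, `"ontological"`.
#' @param text Description text (empty for `source = "none"`).
#' @return An object of class `gene_description` with fields `symbol`,
#'   `source`, `text`, and the prompt `line` (`"symbol: text"`, or the bare
#'   symbol when there is no text).
#' @export
gene_description <- function(symbol, source, text = "") {
  source <- match.arg(source, c("none", "narrative", "ontological"))
  text <- squish(text)
  line <- if (source == "none" || !nzchar(text)) symbol else paste0(symbol, ": ", text)
  structure(list(symbol = symbol, source = source, text = text, line = line),
            class = "gene_description")
}

#' Read a narrative description table
#'
#' Two-column TSV mapping gene symbol to narrative text.
#'
#' @param path TSV path (no header).
#' @return Named character vector, symbol -> text.
#' @export
load_narrative_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_genesum(paste0("narrative table not found: ", path), "genesum_io_error")
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("symbol", "text"))
  stats::setNames(as.character(df$text), df$symbol)
}

#' Write a narrative description table
#' @param tab Named character vector, symbol -> text.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_narrative_tsv <- function(tab, path) {
  utils::write.table(data.frame(symbol = names(tab), text = unname(tab)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Default mapping from GAF aspect codes to the introductory phrase of the
# rendered sentence fragment.
default_aspect_labels <- c(P = "involved in", F = "enables", C = "located in")

#' Render a controlled-language synopsis from a gene's annotations
#'
#' Deterministic sentence built from the labels of the gene's direct
#' annotations: labels are grouped by GAF aspect (configurable phrasing per
#' aspect), alphabetically ordered within a group, and joined as
#' `"involved in X, Y and Z"`. Stands in for curated automated gene
#' descriptions so the pipeline runs fully offline.
#'
#' @param symbol Gene symbol (must be annotated in `store`).
#' @param store An [annotation_store].
#' @param aspect_labels Named character vector mapping aspect code to
#'   introductory phrase; unknown aspects fall back to `"involved in"`.
#' @return A single string; empty (with a warning) for a gene with no
#'   annotations.
#' @export
render_ontological_synopsis <- function(symbol, store,
                                        aspect_labels = default_aspect_labels) {
  terms <- store$direct[[symbol]]
  if (is.null(terms) || !length(terms)) {
    warn_genesum(paste0("no annotations for gene ", symbol),
                 "genesum_description_warning")
    return("")
  }
  labels <- vapply(terms, function(t) store$ontology$terms[[t]]$label,
                   character(1))
  asp <- rep("P", length(terms))
  ga <- store$aspects[[symbol]]
  if (!is.null(ga)) {
    hit <- match(terms, names(ga))
    asp[!is.na(hit)] <- unname(ga[hit[!is.na(hit)]])
  }
  asp[!asp %in% names(aspect_labels)] <- names(aspect_labels)[1]
  pieces <- character(0)
  for (a in names(aspect_labels)) {
    grp <- sort(unique(labels[asp == a]))
    if (!length(grp)) next
    pieces <- c(pieces, paste(aspect_labels[[a]], oxford_join(grp)))
  }
  paste(pieces, collapse = "; ")
}

#' @noRd
oxford_join <- function(x) {
  if (length(x) == 1L) return(x)
  paste0(paste(x[-length(x)], collapse = ", "), " and ", x[length(x)])
}

#' Produce the description line for one gene
#'
#' @param symbol Gene symbol.
#' @param source `"none"`, `"narrative"`, or `"ontological"`.
#' @param narrative_table Named character vector (required for
#'   `source = "narrative"`).
#' @param store An [annotation_store] (required for
#'   `source = "ontological"`).
#' @param aspect_labels Passed to [render_ontological_synopsis()].
#' @return A [gene_description]. A symbol missing from the requested source
#'   yields an empty-text description with a warning; the gene stays in the
#'   prompt as a bare symbol rather than being dropped.
#' @export
describe_gene <- function(symbol, source = c("none", "narrative", "ontological"),
                          narrative_table = NULL, store = NULL,
                          aspect_labels = default_aspect_labels) {
  source <- match.arg(source)
  if (source == "none") {
    return(gene_description(symbol, "none"))
  }
  if (source == "narrative") {
    if (is.null(narrative_table)) {
      stop_genesum("narrative source requires narrative_table",
                   "genesum_validation_error")
    }
    text <- if (symbol %in% names(narrative_table)) narrative_table[[symbol]] else ""
    if (!nzchar(text)) {
      warn_genesum(paste0("no narrative description for gene ", symbol),
                   "genesum_description_warning")
    }
    return(gene_description(symbol, "narrative", text))
  }
  if (is.null(store)) {
    stop_genesum("ontological source requires an annotation store",
                 "genesum_validation_error")
  }
  text <- if (symbol %in% names(store$direct)) {
    render_ontological_synopsis(symbol, store, aspect_labels)
  } else {
    warn_genesum(paste0("gene ", symbol, " not annotated in store"),
                 "genesum_description_warning")
    ""
  }
  gene_description(symbol, "ontological", text)
}

#' Describe every gene of a set
#'
#' @param gs A [gene_set].
#' @inheritParams describe_gene
#' @return List of [gene_description] objects, in gene-set order.
#' @export
describe_gene_set <- function(gs, source = c("none", "narrative", "ontological"),
                              narrative_table = NULL, store = NULL,
                              aspect_labels = default_aspect_labels) {
  source <- match.arg(source)
  lapply(gs$genes, describe_gene, source = source,
         narrative_table = narrative_table, store = store,
         aspect_labels = aspect_labels)
}
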