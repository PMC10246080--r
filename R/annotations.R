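# Gene -> ontology-term annotations (GAF 2.x) with closure-expanded
# term -> gene lookup, and the background gene universe used by the
# over-representation baseline.

#' Construct a gene annotation store
#'
#' @param direct Named list: gene symbol -> character vector of directly
#'   annotated term identifiers.
#' @param background Character vector of gene symbols forming the background
#'   universe. Every annotated gene must be included.
#' @param ontology The [ontology] the term identifiers live in.
#' @param aspects Optional named list parallel to `direct` giving, per gene,
#'   the GAF aspect (`P`/`F`/`C`) of each annotation.
#' @return An object of class `annotation_store`.
#' @export
annotation_store <- function(direct, background, ontology, aspects = NULL) {
  if (!length(background)) {
    stop_genesum("background gene universe is empty", "genesum_validation_error")
  }
  background <- unique(as.character(background))
  direct <- lapply(direct, function(x) sort(unique(as.character(x))))
  bad_gene <- setdiff(names(direct), background)
  if (length(bad_gene)) {
    stop_genesum(paste0("annotated gene not in background: ", bad_gene[1]),
                 "genesum_validation_error")
  }
  all_terms <- unique(unlist(direct, use.names = FALSE))
  unknown <- setdiff(all_terms, names(ontology$terms))
  if (length(unknown)) {
    stop_genesum(paste0("annotation to term absent from ontology: ", unknown[1]),
                 "genesum_validation_error")
  }
  structure(
    list(direct = direct, background = background, ontology = ontology,
         aspects = aspects),
    class = "annotation_store",
    cache = new.env(parent = emptyenv())
  )
}

#' Read a GAF 2.x gene association file
#'
#' Builds the direct gene-to-term map from the DB Object Symbol (column 3)
#' and GO ID (column 5); the background universe is every distinct symbol in
#' the file, including genes whose only rows were dropped by the qualifier
#' policy.
#'
#' @param path GAF file path (`!`-prefixed comment lines allowed).
#' @param ontology The [ontology] annotations refer to.
#' @param qualifier_policy `"exclude_not"` (default) drops rows whose
#'   qualifier contains `NOT`; `"keep_all"` keeps them.
#' @param evidence_codes Optional character vector; when given, only rows
#'   with one of these evidence codes (column 7) are kept.
#' @return An [annotation_store].
#' @export
load_gaf <- function(path, ontology,
                     qualifier_policy = c("exclude_not", "keep_all"),
                     evidence_codes = NULL) {
  qualifier_policy <- match.arg(qualifier_policy)
  if (!file.exists(path)) {
    stop_genesum(paste0("GAF file not found: ", path), "genesum_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines)) {
    stop_genesum("GAF file contains no annotation rows", "genesum_format_error")
  }
  direct <- list()
  aspects <- list()
  background <- character(0)
  n_skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 15L) {
      n_skipped <- n_skipped + 1L
      next
    }
    sym <- f[[3]]; qual <- f[[4]]; term <- f[[5]]
    evidence <- f[[7]]; aspect <- if (length(f) >= 9L) f[[9]] else ""
    if (!nzchar(sym) || !nzchar(term)) {
      n_skipped <- n_skipped + 1L
      next
    }
    background <- c(background, sym)
    if (qualifier_policy == "exclude_not" && grepl("\\bNOT\\b", qual)) next
    if (evidence == "ND") next  # no-data rows carry the gene, not an annotation
    if (!is.null(evidence_codes) && !(evidence %in% evidence_codes)) next
    if (!term %in% names(ontology$terms)) {
      warn_genesum(paste0("GAF row skipped: term not in ontology: ", term),
                   "genesum_gaf_warning")
      next
    }
    direct[[sym]] <- c(direct[[sym]], term)
    aspects[[sym]] <- c(aspects[[sym]], stats::setNames(aspect, term))
  }
  if (n_skipped > 0L) {
    warn_genesum(paste0(n_skipped, " malformed GAF row(s) skipped"),
                 "genesum_gaf_warning")
  }
  if (!length(background)) {
    stop_genesum("GAF file yielded no usable rows", "genesum_format_error")
  }
  annotation_store(direct, unique(background), ontology, aspects = aspects)
}

#' Genes annotated to a term under annotation closure
#'
#' Annotation to a term implies annotation to all of its ancestors, so a
#' term's gene set is every gene directly annotated to the term or to any of
#' its descendants. Results are memoized per term.
#'
#' @param store An [annotation_store].
#' @param term Term identifier.
#' @param within Restrict the result to this set of gene symbols; defaults
#'   to the full background.
#' @return Character vector of gene symbols.
#' @export
genes_annotated_to <- function(store, term, within = store$background) {
  check_term(store$ontology, term)
  cache <- attr(store, "cache")
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  key <- paste0("tg::", term)
  genes <- cache[[key]]
  if (is.null(genes)) {
    fam <- descendants(store$ontology, term, reflexive = TRUE)
    genes <- names(store$direct)[vapply(store$direct, function(tt) {
      any(tt %in% fam)
    }, logical(1))]
    genes <- sort(genes)
    cache[[key]] <- genes
  }
  intersect(genes, within)
}

#' @export
print.annotation_store <- function(x, ...) {
  cat("<annotation_store> ", length(x$background), " background genes, ",
      length(x$direct), " annotated; ontology of ",
      length(x$ontology$terms), " terms\n", sep = "")
  invisible(x)
}

#' Construct a gene set
#'
#' @param genes Character vector of gene symbols (order preserved).
#' @param name,taxon Metadata carried into prompts and reports.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, name = "gene set", taxon = "Homo sapiens") {
  genes <- as.character(genes)
  genes <- genes[nzchar(trimws(genes))]
  if (!length(genes)) {
    stop_genesum("gene set is empty", "genesum_validation_error")
  }
  dup <- duplicated(toupper(genes))
  if (any(dup)) {
    warn_genesum(paste0("duplicate gene symbols collapsed: ",
                        paste(unique(genes[dup]), collapse = ", ")),
                 "genesum_geneset_warning")
    genes <- genes[!dup]
  }
  if (length(genes) < 3L) {
    warn_genesum("gene set has fewer than 3 genes", "genesum_geneset_warning")
  }
  structure(list(name = name, taxon = taxon, genes = genes),
            class = "gene_set")
}

#' Read a gene set file
#'
#' Accepts either a plain list with one symbol per line, or a YAML mapping
#' with keys `name`, `taxon` and `genes`.
#'
#' @param path File path; `.yaml`/`.yml` extensions select the YAML reader.
#' @return A [gene_set].
#' @export
load_gene_set <- function(path) {
  if (!file.exists(path)) {
    stop_genesum(paste0("gene set file not found: ", path), "genesum_io_error")
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    gene_set(unlist(doc$genes, use.names = FALSE),
             name = doc$name %||% basename(path),
             taxon = doc$taxon %||% "Homo sapiens")
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    gene_set(lines[nzchar(lines) & !startsWith(lines, "#")],
             name = basename(path))
  }
}

#' Write a gene set as YAML
#'
#' @param gs A [gene_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  yaml::write_yaml(list(name = gs$name, taxon = gs$taxon,
                        genes = as.list(gs$genes)), path)
  invisible(path)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, " (", x$taxon, "): ", length(x$genes),
      " genes\n", sep = "")
  invisible(x)
}
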