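# Seeded generators for synthetic ontologies, annotation stores with one
# planted over-represented term, gene sets in the 3-200 size range, and
# narrative description tables, so the entire pipeline runs and is testable
# with no downloads. Labels follow a uniform "<noun> process <NNN>" pattern
# with fixed-width indices, which guarantees no label is a substring of
# another (the mock backend scans description text for label substrings).

fixture_nouns <- c("kinase", "transport", "signaling", "membrane", "repair",
                   "binding", "adhesion", "splicing", "folding", "secretion",
                   "oxidation", "replication", "translation", "assembly",
                   "clearance", "fusion")

#' Specify a synthetic fixture
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: a 3-layer, 20-term DAG over 100 background genes, a
#' 20-gene sample, and one planted term annotated to 80% of the sample but
#' only 10% of the remaining background — a strong over-representation
#' signal a correct hypergeometric baseline should rank first.
#'
#' @param seed Integer seed; the fixture is fully reproducible from it.
#' @param n_terms Total terms, including obsolete ones.
#' @param n_genes Background universe size.
#' @param dag_depth Number of DAG layers (root layer included); at least 2.
#' @param sample_size Emitted gene-set size (3-200, the supported range).
#' @param planted_rate_sample Fraction of sample genes annotated to the
#'   planted term.
#' @param planted_rate_background Fraction of non-sample background genes
#'   annotated to the planted term (must be below the sample rate).
#' @param n_obsolete Obsolete terms; the first carries a live synonym so
#'   grounding probes can hit an obsoleted term.
#' @param synonym_rate Fraction of live terms given a synonym.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_terms = 20L, n_genes = 100L,
                         dag_depth = 3L, sample_size = 20L,
                         planted_rate_sample = 0.8,
                         planted_rate_background = 0.1,
                         n_obsolete = 1L, synonym_rate = 0.3) {
  if (dag_depth < 2L) {
    stop_genesum("dag_depth must be >= 2", "genesum_validation_error")
  }
  if (planted_rate_sample <= planted_rate_background) {
    stop_genesum("planted_rate_sample must exceed planted_rate_background",
                 "genesum_validation_error")
  }
  if (sample_size < 3L || sample_size > 200L) {
    stop_genesum("sample_size must be between 3 and 200",
                 "genesum_validation_error")
  }
  if (sample_size > n_genes) {
    stop_genesum("sample_size cannot exceed n_genes", "genesum_validation_error")
  }
  if (round(planted_rate_sample * sample_size) < 1) {
    stop_genesum("planted_rate_sample * sample_size must reach at least one gene",
                 "genesum_spec_error")
  }
  if (n_terms - n_obsolete < dag_depth + 1L) {
    stop_genesum("not enough live terms for the requested DAG depth",
                 "genesum_spec_error")
  }
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 n_genes = as.integer(n_genes), dag_depth = as.integer(dag_depth),
                 sample_size = as.integer(sample_size),
                 planted_rate_sample = planted_rate_sample,
                 planted_rate_background = planted_rate_background,
                 n_obsolete = as.integer(n_obsolete),
                 synonym_rate = synonym_rate),
            class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Builds a random layered DAG (singly rooted, acyclic by construction:
#' every non-root term's parents sit in strictly earlier layers), annotates
#' genes — every gene gets one to three random live-term annotations, and
#' the planted term is additionally annotated at the specified sample and
#' background rates — and renders a narrative table whose texts embed the
#' genes' annotation labels among distractor words, so the faithful mock
#' backend is solvable from the narrative source as well as the ontological
#' one.
#'
#' @param spec A [fixture_spec].
#' @return List with elements `ontology`, `store`, `gene_set`, `narrative`
#'   (named character vector), and `planted_term` (identifier).
#' @export
make_fixture <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    n_live <- spec$n_terms - spec$n_obsolete
    ids <- sprintf("FX:%07d", seq_len(spec$n_terms))
    nouns <- sample(fixture_nouns, spec$n_terms, replace = TRUE)
    labels <- sprintf("%s process %03d", nouns, seq_len(spec$n_terms))

    # layer assignment: root alone in layer 1, others spread over 2..depth
    layer <- c(1L, sort(sample(2:spec$dag_depth, n_live - 1L, replace = TRUE)))
    terms <- vector("list", spec$n_terms)
    for (i in seq_len(n_live)) {
      parents <- data.frame(relation = character(0), parent = character(0),
                            stringsAsFactors = FALSE)
      if (i > 1L) {
        pool <- which(layer == layer[[i]] - 1L)
        n_par <- min(length(pool), sample(1:2, 1))
        for (p in pool[sample.int(length(pool), n_par)]) {
          parents <- rbind(parents,
                           data.frame(relation = "is_a", parent = ids[[p]],
                                      stringsAsFactors = FALSE))
        }
        earlier <- which(layer < layer[[i]])
        if (length(earlier) && stats::runif(1) < 0.2) {
          p <- earlier[sample.int(length(earlier), 1)]
          if (!ids[[p]] %in% parents$parent) {
            parents <- rbind(parents,
                             data.frame(relation = "part_of", parent = ids[[p]],
                                        stringsAsFactors = FALSE))
          }
        }
      }
      syn <- character(0)
      if (stats::runif(1) < spec$synonym_rate) {
        syn <- paste("syn", labels[[i]])
      }
      terms[[i]] <- list(id = ids[[i]], label = labels[[i]], synonyms = syn,
                         parents = parents)
    }
    for (j in seq_len(spec$n_obsolete)) {
      i <- n_live + j
      terms[[i]] <- list(
        id = ids[[i]], label = labels[[i]],
        synonyms = if (j == 1L) paste("syn", labels[[i]]) else character(0),
        obsolete = TRUE, replaced_by = ids[[2L]],
        parents = data.frame(relation = character(0), parent = character(0),
                             stringsAsFactors = FALSE))
    }
    o <- ontology(terms)

    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    sample_genes <- sort(sample(genes, spec$sample_size))
    others <- setdiff(genes, sample_genes)

    # planted term: a random non-root live term below the top layer
    deep <- which(layer >= 2L)
    planted <- ids[[deep[sample.int(length(deep), 1)]]]

    direct <- stats::setNames(vector("list", spec$n_genes), genes)
    live_ids <- ids[seq_len(n_live)]
    for (g in genes) {
      k <- sample(1:3, 1)
      direct[[g]] <- sample(live_ids, k)
    }
    planted_sample <- sample(sample_genes,
                             round(spec$planted_rate_sample * spec$sample_size))
    n_bg <- round(spec$planted_rate_background * length(others))
    planted_bg <- if (n_bg > 0) sample(others, n_bg) else character(0)
    # ensure non-planted sample genes are not planted-term carriers by chance,
    # keeping the planted contrast at its nominal rates
    for (g in setdiff(genes, c(planted_sample, planted_bg))) {
      direct[[g]] <- setdiff(direct[[g]], planted)
      if (!length(direct[[g]])) direct[[g]] <- setdiff(live_ids, planted)[[1]]
    }
    for (g in c(planted_sample, planted_bg)) {
      direct[[g]] <- unique(c(direct[[g]], planted))
    }
    store <- annotation_store(direct, genes, o)

    gs <- gene_set(sample_genes,
                   name = sprintf("synthetic set (seed %d)", spec$seed),
                   taxon = "Homo sapiens")

    distractors <- c("cell", "tissue", "response", "pathway", "homeostasis",
                     "organelle", "cycle", "matrix")
    narrative <- vapply(genes, function(g) {
      lbls <- sort(vapply(direct[[g]], function(t) o$terms[[t]]$label,
                          character(1)))
      paste0("This gene participates in ", paste(lbls, collapse = " and "),
             " within the ", sample(distractors, 1), ".")
    }, character(1))

    list(ontology = o, store = store, gene_set = gs,
         narrative = narrative, planted_term = planted)
  })
}

#' Write a fixture to disk
#'
#' Emits `ontology.obo`, `annotations.gaf`, `gene_set.yaml` and
#' `narrative.tsv` into `dir`; reloading them reproduces equal objects.
#'
#' @param fx A fixture list from [make_fixture()] (or any compatible
#'   ontology/store/gene-set/narrative bundle).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths (the manifest).
#' @export
write_fixture <- function(fx, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ontology = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    gene_set = file.path(dir, "gene_set.yaml"),
    narrative = file.path(dir, "narrative.tsv")
  )
  write_obo(fx$ontology, paths[["ontology"]])
  write_gaf(fx$store, paths[["gaf"]])
  write_gene_set(fx$gene_set, paths[["gene_set"]])
  write_narrative_tsv(fx$narrative, paths[["narrative"]])
  paths
}

#' Write an annotation store as GAF 2.2
#'
#' One row per direct gene-term annotation; unannotated background genes are
#' carried as rows with a `ND` (no data) annotation to the ontology root so
#' the background universe survives a round trip.
#'
#' @param store An [annotation_store].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(store, path) {
  rows <- character(0)
  roots <- names(store$ontology$terms)[vapply(names(store$ontology$terms),
    function(id) {
      !store$ontology$terms[[id]]$obsolete && !length(ancestors(store$ontology, id))
    }, logical(1))]
  root <- sort(roots)[[1]]
  gaf_row <- function(sym, term, evidence, aspect) {
    paste(c("GSX", sym, sym, "", term, "GSX:0000001", evidence, "", aspect,
            sym, "", "gene", "taxon:9606", "20260101", "GSX", "", ""),
          collapse = "\t")
  }
  for (sym in sort(store$background)) {
    terms <- store$direct[[sym]]
    if (is.null(terms) || !length(terms)) {
      rows <- c(rows, gaf_row(sym, root, "ND", "P"))
      next
    }
    ga <- store$aspects[[sym]]
    for (t in sort(terms)) {
      aspect <- if (!is.null(ga) && t %in% names(ga) && nzchar(ga[[t]])) ga[[t]] else "P"
      rows <- c(rows, gaf_row(sym, t, "IEA", aspect))
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @param closure_relations Passed to [load_ontology()].
#' @return List with `ontology`, `store`, `gene_set`, `narrative`.
#' @export
load_fixture <- function(dir, closure_relations = c("is_a", "part_of")) {
  o <- load_ontology(file.path(dir, "ontology.obo"),
                     closure_relations = closure_relations)
  store <- load_gaf(file.path(dir, "annotations.gaf"), o)
  list(ontology = o,
       store = store,
       gene_set = load_gene_set(file.path(dir, "gene_set.yaml")),
       narrative = load_narrative_tsv(file.path(dir, "narrative.tsv")))
}
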