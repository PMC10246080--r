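# Standard over-representation baseline: hypergeometric upper-tail test per
# candidate term, Bonferroni correction over the terms actually tested, and
# fully deterministic ranking.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of observing at
#' least `k` annotated genes in a sample of `n` drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation. Computed
#' via [stats::phyper()], which works in log space and is numerically stable.
#'
#' @param k Observed count of annotated genes in the sample.
#' @param K Annotated genes in the background universe.
#' @param n Sample size.
#' @param N Background universe size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  ok <- is.numeric(k) && is.numeric(K) && is.numeric(n) && is.numeric(N) &&
    k >= 0 && k <= n && n <= N && K >= 0 && K <= N
  if (!ok) {
    stop_genesum(
      sprintf("invalid hypergeometric arguments: need 0 <= k <= n <= N and 0 <= K <= N, got k=%s K=%s n=%s N=%s",
              k, K, n, N),
      "genesum_domain_error")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set
#'
#' Tests every candidate term (a term annotated, under annotation closure,
#' to at least `min_annotated` genes of the sample) with the hypergeometric
#' upper tail, then applies Bonferroni correction with `m` equal to the
#' number of candidate terms tested. Rows are sorted by adjusted p, then raw
#' p, then term identifier, so ranking is fully deterministic.
#'
#' Gene symbols are matched against the background case-insensitively;
#' sample genes absent from the background are dropped (all of them missing
#' is an error).
#'
#' @param gs A [gene_set].
#' @param store An [annotation_store].
#' @param min_annotated Minimum sample genes annotated for a term to enter
#'   the test set. Default 1.
#' @return A data frame of class `enrichment_result` with columns `term`,
#'   `label`, `rank`, `k`, `n_sample`, `K`, `N`, `p_raw`, `p_adj`, and
#'   attributes `m_tests`, `n_sample`, `missing_genes`.
#' @export
enrich <- function(gs, store, min_annotated = 1L) {
  bg <- store$background
  hit <- match(toupper(gs$genes), toupper(bg))
  missing <- gs$genes[is.na(hit)]
  sample_genes <- unique(bg[hit[!is.na(hit)]])
  if (!length(sample_genes)) {
    stop_genesum(paste0("no gene of the set is in the background universe; ",
                        "missing: ", paste(missing, collapse = ", ")),
                 "genesum_validation_error")
  }
  n <- length(sample_genes)
  N <- length(bg)
  o <- store$ontology
  # candidate terms: closure over everything any sample gene is annotated to
  direct_terms <- unique(unlist(store$direct[sample_genes], use.names = FALSE))
  candidates <- sort(unique(unlist(
    lapply(direct_terms, ancestors, o = o, reflexive = TRUE),
    use.names = FALSE)))
  rows <- lapply(candidates, function(t) {
    in_sample <- genes_annotated_to(store, t, within = sample_genes)
    k <- length(in_sample)
    if (k < min_annotated) return(NULL)
    K <- length(genes_annotated_to(store, t))
    data.frame(term = t, label = o$terms[[t]]$label, k = k, n_sample = n,
               K = K, N = N,
               p_raw = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) {
    warn_genesum("no candidate terms to test", "genesum_enrichment_warning")
    res <- data.frame(term = character(0), label = character(0),
                      rank = integer(0), k = integer(0), n_sample = integer(0),
                      K = integer(0), N = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0))
  } else {
    m <- nrow(rows)
    rows$p_adj <- pmin(1, rows$p_raw * m)
    ord <- order(rows$p_adj, rows$p_raw, rows$term)
    rows <- rows[ord, , drop = FALSE]
    rows$rank <- seq_len(nrow(rows))
    res <- rows[, c("term", "label", "rank", "k", "n_sample", "K", "N",
                    "p_raw", "p_adj")]
    rownames(res) <- NULL
  }
  structure(res,
            class = c("enrichment_result", "data.frame"),
            m_tests = NROW(rows) %||% 0L,
            n_sample = n,
            missing_genes = missing)
}

#' Write enrichment results as TSV
#'
#' @param res An `enrichment_result` from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat("<enrichment_result> ", nrow(x), " terms tested (Bonferroni m = ",
      attr(x, "m_tests"), "), sample n = ", attr(x, "n_sample"), "\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}
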