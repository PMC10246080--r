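# Closure-aware evaluation of predicted term sets against top-n/p-filtered
# standard enrichment, plus the robustness controls (gene-set perturbation,
# description swapping), run-to-run Jaccard stability, and the exact
# Mann-Whitney test used to compare metric distributions.

#' Evaluation configuration
#'
#' @param top_n Keep at most this many standard-enrichment terms (by rank).
#' @param p_cutoff P-value cutoff applied before the top-n cut.
#' @param use_adjusted_p Filter on Bonferroni-adjusted p (default) or raw p.
#' @param closure_matching Credit a predicted term that is an ancestor or
#'   descendant of a standard term (default), or require identity.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(top_n = 10L, p_cutoff = 0.05,
                        use_adjusted_p = TRUE, closure_matching = TRUE) {
  if (top_n < 1L) stop_genesum("top_n must be >= 1", "genesum_validation_error")
  if (p_cutoff <= 0 || p_cutoff > 1) {
    stop_genesum("p_cutoff must be in (0, 1]", "genesum_validation_error")
  }
  structure(list(top_n = as.integer(top_n), p_cutoff = p_cutoff,
                 use_adjusted_p = isTRUE(use_adjusted_p),
                 closure_matching = isTRUE(closure_matching)),
            class = "eval_config")
}

#' Filter standard-enrichment results for comparison
#'
#' Keeps rows passing the p-value cutoff, then the first `top_n` by rank.
#' With `top_n = 1` the filtered list is just the top hit.
#'
#' @param res An `enrichment_result` from [enrich()].
#' @param cfg An [eval_config].
#' @return Ordered character vector of term identifiers (possibly empty).
#' @export
filter_standard <- function(res, cfg) {
  p <- if (cfg$use_adjusted_p) res$p_adj else res$p_raw
  keep <- res[p <= cfg$p_cutoff, , drop = FALSE]
  keep <- keep[order(keep$rank), , drop = FALSE]
  utils::head(keep$term, cfg$top_n)
}

#' Closure-aware confusion counts and summary metrics
#'
#' For each standard-enrichment term, a predicted term equal to it — or,
#' under closure matching, an ancestor or descendant of it — makes it a true
#' positive; unmatched standard terms are false negatives. A predicted term
#' is *accounted* when it matches at least one standard term; unaccounted
#' predicted terms are false positives. Precision uses accounted predicted
#' terms in the numerator (one predicted term may cover several standard
#' terms, and vice versa), recall is `tp / (tp + fn)`, and F1 their harmonic
#' mean; all are 0 when their denominator is 0. `has_hit` records whether
#' any standard term was matched, and `has_top_hit` whether the rank-1
#' standard term was (directly or through ancestry).
#'
#' @param predicted Character vector of predicted term identifiers.
#' @param standard Ordered character vector from [filter_standard()]
#'   (rank-1 first).
#' @param o The [ontology].
#' @param cfg An [eval_config].
#' @return An object of class `evaluation_report`: list with `tp`, `fp`,
#'   `fn`, `accounted`, `precision`, `recall`, `f1`, `has_hit`,
#'   `has_top_hit`, `config`.
#' @export
confusion <- function(predicted, standard, o, cfg = eval_config()) {
  predicted <- unique(as.character(predicted))
  standard <- as.character(standard)
  for (id in c(predicted, standard)) check_term(o, id)
  match_fun <- if (cfg$closure_matching) {
    function(a, b) related_by_hierarchy(o, a, b)
  } else {
    function(a, b) identical(a, b)
  }
  std_matched <- vapply(standard, function(t) {
    any(vapply(predicted, match_fun, logical(1), b = t))
  }, logical(1))
  pred_accounted <- vapply(predicted, function(p) {
    any(vapply(standard, match_fun, logical(1), a = p))
  }, logical(1))
  tp <- sum(std_matched)
  fn <- length(standard) - tp
  accounted <- sum(pred_accounted)
  fp <- length(predicted) - accounted
  precision <- if (accounted + fp > 0) accounted / (accounted + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, accounted = accounted,
                 precision = precision, recall = recall, f1 = f1,
                 has_hit = as.integer(tp >= 1L),
                 has_top_hit = as.integer(length(standard) > 0 && std_matched[[1]]),
                 config = cfg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> tp=%d fp=%d fn=%d  P=%.3f R=%.3f F1=%.3f  has_hit=%d has_top_hit=%d\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$has_hit, x$has_top_hit))
  invisible(x)
}

#' Perturb a gene set by random dropout and replacement
#'
#' Simulates noisy input: `r = max(1, round(fraction * N))` genes are
#' removed uniformly at random and replaced by `r` distinct genes drawn
#' uniformly from `pool` minus the set, so the size is preserved and even a
#' 3-gene set is perturbed at the nominal 10% rate. `fraction = 0` is an
#' explicit no-op.
#'
#' @param gs A [gene_set].
#' @param pool Character vector of candidate replacement genes (typically
#'   the annotated background).
#' @param fraction Fraction of genes to replace; default 0.1.
#' @param seed Integer seed; identical seeds give identical perturbations.
#' @return A perturbed [gene_set] (name suffixed with `" (perturbed)"`).
#' @export
perturb_gene_set <- function(gs, pool, fraction = 0.1, seed = 1L) {
  if (fraction == 0) return(gs)
  if (fraction < 0 || fraction > 1) {
    stop_genesum("fraction must be in [0, 1]", "genesum_validation_error")
  }
  n <- length(gs$genes)
  r <- max(1L, as.integer(round(fraction * n)))
  candidates <- setdiff(pool, gs$genes)
  if (length(candidates) < r) {
    stop_genesum(sprintf(
      "replacement pool too small: need %d genes outside the set, have %d",
      r, length(candidates)), "genesum_validation_error")
  }
  with_seed(seed, {
    drop_idx <- sample.int(n, r)
    replacements <- sample(candidates, r)
    genes <- gs$genes
    genes[drop_idx] <- replacements
    gene_set(genes, name = paste0(gs$name, " (perturbed)"), taxon = gs$taxon)
  })
}

#' Swap descriptions with donors from a foreign gene set
#'
#' Control for latent-knowledge use: each description's text is replaced by
#' a random donor text (symbols unchanged), so a model relying on the
#' in-context text — rather than on what it already knows about the symbols
#' — will summarize the foreign function.
#'
#' @param descriptions List of [gene_description] objects.
#' @param donor_pool Nonempty list of [gene_description] donors.
#' @param seed Integer seed.
#' @return List of [gene_description] objects with swapped texts.
#' @export
swap_descriptions <- function(descriptions, donor_pool, seed = 1L) {
  if (!length(donor_pool)) {
    stop_genesum("donor pool is empty", "genesum_validation_error")
  }
  donor_texts <- vapply(donor_pool, `[[`, character(1), "text")
  with_seed(seed, {
    idx <- sample.int(length(donor_texts), length(descriptions), replace = TRUE)
    lapply(seq_along(descriptions), function(i) {
      d <- descriptions[[i]]
      gene_description(d$symbol, d$source, donor_texts[[idx[[i]]]])
    })
  })
}

#' Jaccard similarity of two term sets
#'
#' Terms are counted directly — no ontology hierarchy — as in the
#' run-to-run stability protocol. Defined as 1 when both sets are empty.
#'
#' @param a,b Character vectors of term identifiers.
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_terms <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}

#' One-sided exact Mann-Whitney (rank-sum) test
#'
#' For small samples (`length(x) + length(y) <= exact_threshold`) the
#' one-sided p-value is computed from the full permutation distribution of
#' the rank-sum statistic, with ties handled by midranks over all
#' distinguishable arrangements. Larger samples fall back to the normal
#' approximation with tie correction ([stats::wilcox.test()]), flagged via
#' the `"exact"` attribute.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative `"greater"` tests whether `x` tends larger than `y`;
#'   `"less"` the reverse.
#' @param exact_threshold Combined sample size up to which exact enumeration
#'   is used. Default 20.
#' @return The one-sided p-value, with attribute `exact` (logical).
#' @export
exact_mann_whitney <- function(x, y, alternative = c("greater", "less"),
                               exact_threshold = 20L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) {
    stop_genesum("both samples must be nonempty", "genesum_domain_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (n > exact_threshold) {
    p <- stats::wilcox.test(x, y, alternative = alternative,
                            exact = FALSE, correct = TRUE)$p.value
    return(structure(p, exact = FALSE))
  }
  r <- rank(c(x, y))        # midranks for ties
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats_all <- colSums(matrix(r[combs], nrow = nx))
  eps <- 1e-9
  p <- if (alternative == "greater") {
    mean(stats_all >= w_obs - eps)
  } else {
    mean(stats_all <= w_obs + eps)
  }
  structure(p, exact = TRUE)
}
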