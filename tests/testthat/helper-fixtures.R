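# Shared fixtures and independent brute-force oracles used across tests.

# Four-term DAG: T0 root; T1 is_a T0; T2 is_a T1; T3 part_of T0.
toy_dag <- function(closure_relations = "is_a") {
  ontology(list(
    list(id = "T0", label = "root process"),
    list(id = "T1", label = "mid process",
         parents = data.frame(relation = "is_a", parent = "T0")),
    list(id = "T2", label = "leaf process",
         parents = data.frame(relation = "is_a", parent = "T1")),
    list(id = "T3", label = "side process",
         parents = data.frame(relation = "part_of", parent = "T0"))
  ), closure_relations = closure_relations)
}

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "genesum")
}

load_toy <- function() {
  o <- load_ontology(toy_path("toy.obo"))
  store <- suppressWarnings(load_gaf(toy_path("toy.gaf"), o))
  gs <- load_gene_set(toy_path("toy_genes.yaml"))
  narrative <- load_narrative_tsv(toy_path("toy_narrative.tsv"))
  list(ontology = o, store = store, gene_set = gs, narrative = narrative)
}

# Independent hypergeometric upper tail: direct combinatorial sum of the
# probability mass function (exact in double precision for N <= 40).
hyper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- seq(k, min(n, K))
  if (!length(j) || k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Literal brute-force transcription of the confusion rule: for each standard
# term, a predicted term equal to it or related through the hierarchy makes
# it a true positive; unaccounted predicted terms are false positives,
# unaccounted standard terms false negatives.
brute_confusion <- function(predicted, standard, o, closure) {
  matches <- function(p, t) {
    if (p == t) return(TRUE)
    if (!closure) return(FALSE)
    p %in% ancestors(o, t) || p %in% descendants(o, t)
  }
  tp <- 0L
  std_hit <- logical(length(standard))
  for (i in seq_along(standard)) {
    for (p in predicted) {
      if (matches(p, standard[[i]])) { std_hit[[i]] <- TRUE; break }
    }
  }
  tp <- sum(std_hit)
  fn <- length(standard) - tp
  accounted <- 0L
  for (p in predicted) {
    hit <- FALSE
    for (t in standard) if (matches(p, t)) { hit <- TRUE; break }
    if (hit) accounted <- accounted + 1L
  }
  fp <- length(predicted) - accounted
  list(tp = tp, fp = fp, fn = fn, accounted = accounted)
}

# Brute-force ancestor closure: repeated one-step parent expansion to the
# fixed point, independent of the package's traversal.
brute_ancestors <- function(o, id) {
  one_step <- function(ids) {
    unique(unlist(lapply(ids, function(x) {
      t <- o$terms[[x]]
      if (t$obsolete) return(character(0))
      t$parents$parent[t$parents$relation %in% o$closure_relations]
    }), use.names = FALSE))
  }
  acc <- character(0)
  frontier <- one_step(id)
  repeat {
    new <- setdiff(frontier, acc)
    if (!length(new)) break
    acc <- union(acc, new)
    frontier <- one_step(acc)
  }
  sort(acc)
}

# Exact one-sided rank-sum p-value by bitmask enumeration of all group
# assignments (independent of the combn-based implementation).
mw_oracle <- function(x, y, alternative) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  stats_all <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != nx) next
    stats_all <- c(stats_all, sum(r[bits == 1L]))
  }
  eps <- 1e-9
  if (alternative == "greater") mean(stats_all >= w_obs - eps)
  else mean(stats_all <= w_obs + eps)
}

# Random small DAG for property tests: terms T1..Tn layered so edges always
# point to earlier indices (acyclic by construction).
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- list(list(id = "R001", label = "term 001"))
  for (i in 2:n_terms) {
    n_par <- sample(1:min(3, i - 1), 1)
    pars <- sample(seq_len(i - 1), n_par)
    rel <- sample(c("is_a", "part_of"), n_par, replace = TRUE)
    terms[[i]] <- list(
      id = sprintf("R%03d", i), label = sprintf("term %03d", i),
      parents = data.frame(relation = rel,
                           parent = sprintf("R%03d", pars)))
  }
  terms
}
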