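test_that("standard results filter by p cutoff then top-n", {
  res <- structure(
    data.frame(term = paste0("S", 1:5), label = letters[1:5], rank = 1:5,
               k = 1, n_sample = 5, K = 2, N = 10,
               p_raw = c(.0005, .005, .1, .3, .5),
               p_adj = c(.001, .01, .2, .6, 1)),
    class = c("enrichment_result", "data.frame"))
  expect_equal(filter_standard(res, eval_config(top_n = 10, p_cutoff = 0.05)),
               c("S1", "S2"))
  expect_equal(filter_standard(res, eval_config(top_n = 1, p_cutoff = 0.05)),
               "S1")
  expect_length(filter_standard(res, eval_config(top_n = 100, p_cutoff = 1)), 5L)
  raw <- filter_standard(res, eval_config(top_n = 10, p_cutoff = 0.05,
                                          use_adjusted_p = FALSE))
  expect_equal(raw, c("S1", "S2"))
})

test_that("confusion handles identity, ancestry and equality-only matching", {
  o <- toy_dag()
  r <- confusion(c("T2", "T3"), c("T2", "T3"), o)
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 0L, 0L))
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  expect_equal(r$has_top_hit, 1L)

  # ancestor match under closure
  r2 <- confusion("T1", "T2", o, eval_config(closure_matching = TRUE))
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(1L, 0L, 0L))
  # same pair, equality-only
  r3 <- confusion("T1", "T2", o, eval_config(closure_matching = FALSE))
  expect_equal(c(r3$tp, r3$fp, r3$fn), c(0L, 1L, 1L))
  expect_equal(c(r3$precision, r3$recall, r3$f1), c(0, 0, 0))
  expect_error(confusion("T9", "T2", o), class = "genesum_lookup_error")
})

test_that("a parent of the top hit counts as top hit only under closure", {
  toy <- load_toy()
  # rank-1 standard term is myelination (FX:0000002); predict its parent
  r_on <- confusion("FX:0000001", c("FX:0000002", "FX:0000003"),
                    toy$ontology, eval_config(closure_matching = TRUE))
  expect_equal(r_on$has_top_hit, 1L)
  r_off <- confusion("FX:0000001", c("FX:0000002", "FX:0000003"),
                     toy$ontology, eval_config(closure_matching = FALSE))
  expect_equal(r_off$has_top_hit, 0L)
})

test_that("confusion agrees with the brute-force rule on exhaustive subsets", {
  toy <- load_toy()
  ids <- names(toy$ontology$terms)
  subsets <- lapply(0:(2^6 - 1), function(m) ids[bitwAnd(m, 2^(0:5)) > 0])
  # sample the predicted x standard grid densely enough to stay fast here;
  # the acceptance suite runs the full 64 x 64 grid
  set.seed(9)
  for (i in sample(length(subsets), 12)) {
    for (j in sample(length(subsets), 12)) {
      for (closure in c(TRUE, FALSE)) {
        got <- confusion(subsets[[i]], subsets[[j]], toy$ontology,
                         eval_config(closure_matching = closure))
        want <- brute_confusion(subsets[[i]], subsets[[j]], toy$ontology,
                                closure)
        expect_equal(got$tp, want$tp)
        expect_equal(got$fp, want$fp)
        expect_equal(got$fn, want$fn)
      }
    }
  }
})

test_that("metric bounds and has_top_hit <= has_hit hold on random evaluations", {
  toy <- load_toy()
  ids <- names(toy$ontology$terms)
  set.seed(33)
  for (i in 1:300) {
    pred <- sample(ids, sample(0:4, 1))
    std <- sample(ids, sample(0:4, 1))
    r <- confusion(pred, std, toy$ontology,
                   eval_config(closure_matching = sample(c(TRUE, FALSE), 1)))
    expect_true(r$precision >= 0 && r$precision <= 1)
    expect_true(r$recall >= 0 && r$recall <= 1)
    expect_true(r$f1 >= 0 && r$f1 <= 1)
    expect_lte(r$has_top_hit, r$has_hit)
  }
})

test_that("perturbation preserves size and replaces the stated count", {
  pool <- sprintf("P%03d", 1:300)
  for (n in c(3L, 20L, 200L)) {
    gs <- suppressWarnings(gene_set(sprintf("G%03d", 1:n), name = "orig"))
    p <- perturb_gene_set(gs, c(gs$genes, pool), fraction = 0.1, seed = 4)
    expect_length(p$genes, n)
    expect_equal(length(setdiff(p$genes, gs$genes)), max(1L, round(0.1 * n)))
    expect_identical(perturb_gene_set(gs, c(gs$genes, pool), 0.1, seed = 4)$genes,
                     p$genes)
  }
  gs <- gene_set(sprintf("G%03d", 1:10))
  expect_identical(perturb_gene_set(gs, pool, fraction = 0), gs)
  expect_error(perturb_gene_set(gs, gs$genes, fraction = 0.5, seed = 1),
               class = "genesum_validation_error")
})

test_that("description swapping keeps symbols and borrows donor texts", {
  desc <- list(gene_description("gA", "narrative", "involved in glycolysis"),
               gene_description("gB", "narrative", "involved in glycolysis"))
  donors <- list(gene_description("zX", "narrative", "involved in endocytosis"),
                 gene_description("zY", "narrative", "involved in endocytosis"))
  sw <- swap_descriptions(desc, donors, seed = 2)
  expect_equal(vapply(sw, `[[`, character(1), "symbol"), c("gA", "gB"))
  expect_true(all(vapply(sw, `[[`, character(1), "text") == "involved in endocytosis"))
  one <- swap_descriptions(desc, donors[1], seed = 2)
  expect_true(all(vapply(one, `[[`, character(1), "text") == donors[[1]]$text))
  expect_identical(swap_descriptions(desc, donors, seed = 2), sw)
  expect_error(swap_descriptions(desc, list(), seed = 1),
               class = "genesum_validation_error")
})

test_that("jaccard similarity follows set arithmetic", {
  expect_equal(jaccard_terms(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(jaccard_terms(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_terms("a", "b"), 0)
  expect_equal(jaccard_terms(character(0), character(0)), 1)
})

test_that("exact Mann-Whitney reproduces worked examples", {
  expect_equal(as.numeric(exact_mann_whitney(c(1, 2), c(3, 4), "less")), 1 / 6)
  expect_equal(as.numeric(exact_mann_whitney(5, 5, "less")), 1)
  expect_equal(as.numeric(exact_mann_whitney(5, 5, "greater")), 1)
  # unique most-extreme arrangement
  expect_equal(as.numeric(exact_mann_whitney(c(100, 101, 102), c(1, 2), "greater")),
               1 / choose(5, 3))
  expect_error(exact_mann_whitney(numeric(0), 1), class = "genesum_domain_error")
})

test_that("exact Mann-Whitney agrees with bitmask enumeration incl. ties", {
  set.seed(77)
  for (i in 1:40) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    vals <- sample(1:4, nx + ny, replace = TRUE)  # many ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    for (alt in c("greater", "less")) {
      expect_equal(as.numeric(exact_mann_whitney(x, y, alt)),
                   mw_oracle(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("large samples fall back to the flagged normal approximation", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(30) - 1
  p <- exact_mann_whitney(x, y, "greater")
  expect_false(attr(p, "exact"))
  expect_equal(as.numeric(p),
               stats::wilcox.test(x, y, alternative = "greater",
                                  exact = FALSE)$p.value)
})
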