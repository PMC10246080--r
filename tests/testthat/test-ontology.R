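test_that("OBO loading captures terms, synonyms, obsolescence and typed edges", {
  o <- load_ontology(toy_path("toy.obo"))
  expect_length(o$terms, 6L)
  expect_equal(o$terms[["FX:0000002"]]$label, "myelination")
  expect_true("myelinogenesis" %in% o$terms[["FX:0000002"]]$synonyms)
  expect_true(o$terms[["FX:0000006"]]$obsolete)
  expect_equal(o$terms[["FX:0000006"]]$replaced_by, "FX:0000002")
  expect_equal(o$terms[["FX:0000005"]]$parents$relation, "part_of")
})

test_that("closure respects the configured relation set", {
  o <- toy_dag(closure_relations = "is_a")
  expect_length(o$terms, 4L)
  expect_setequal(ancestors(o, "T2"), c("T1", "T0"))
  expect_setequal(ancestors(o, "T2", reflexive = TRUE), c("T2", "T1", "T0"))
  expect_equal(ancestors(o, "T0"), character(0))
  # part_of edge not traversed under is_a-only closure
  expect_equal(ancestors(o, "T3"), character(0))
  expect_setequal(descendants(o, "T0"), c("T1", "T2"))
  expect_equal(descendants(o, "T2"), character(0))
  expect_setequal(descendants(o, "T1", reflexive = TRUE), c("T1", "T2"))
})

test_that("empty ontology loads and unknown identifiers error", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines("format-version: 1.4", f)
  o <- load_ontology(f)
  expect_length(o$terms, 0L)
  o4 <- toy_dag()
  expect_error(ancestors(o4, "TX"), class = "genesum_lookup_error")
  expect_error(related_by_hierarchy(o4, "T0", "TX"),
               class = "genesum_lookup_error")
})

test_that("a cyclic closure graph is rejected with the cycle named", {
  terms <- list(
    list(id = "T0", label = "a",
         parents = data.frame(relation = "is_a", parent = "T2")),
    list(id = "T1", label = "b",
         parents = data.frame(relation = "is_a", parent = "T0")),
    list(id = "T2", label = "c",
         parents = data.frame(relation = "is_a", parent = "T1"))
  )
  err <- expect_error(ontology(terms, "is_a"), class = "genesum_cycle_error")
  expect_match(conditionMessage(err), "T0")
})

test_that("hierarchy relatedness covers equality, ancestry, and disjoint branches", {
  o <- toy_dag()
  expect_true(related_by_hierarchy(o, "T1", "T2"))
  expect_true(related_by_hierarchy(o, "T1", "T1"))
  expect_false(related_by_hierarchy(o, "T1", "T3"))
  # symmetry over all pairs
  ids <- names(o$terms)
  for (a in ids) for (b in ids) {
    expect_equal(related_by_hierarchy(o, a, b), related_by_hierarchy(o, b, a))
  }
})

test_that("closure matches brute-force fixed-point expansion on random DAGs", {
  for (seed in 1:3) {
    o <- ontology(random_dag(40, seed), closure_relations = c("is_a", "part_of"))
    for (id in names(o$terms)) {
      expect_equal(ancestors(o, id), brute_ancestors(o, id))
    }
  }
})

test_that("widening the closure relations never shrinks ancestor sets", {
  terms <- random_dag(30, 7)
  narrow <- ontology(terms, closure_relations = "is_a")
  wide <- ontology(terms, closure_relations = c("is_a", "part_of"))
  for (id in names(narrow$terms)) {
    expect_true(all(ancestors(narrow, id) %in% ancestors(wide, id)))
  }
})

test_that("ancestor and descendant closures are mutually consistent", {
  o <- ontology(random_dag(25, 11))
  ids <- names(o$terms)
  for (a in ids) {
    for (b in ancestors(o, a)) {
      expect_true(a %in% descendants(o, b))
    }
  }
})

test_that("obsolete terms contribute no closure edges", {
  o <- ontology(list(
    list(id = "A", label = "a"),
    list(id = "B", label = "b", obsolete = TRUE,
         parents = data.frame(relation = "is_a", parent = "A"))
  ))
  expect_equal(ancestors(o, "B"), character(0))
  expect_equal(descendants(o, "A"), character(0))
})

test_that("OBO-Graph JSON loads nodes, edges, deprecation and synonyms", {
  doc <- list(graphs = list(list(
    nodes = list(
      list(id = "J:1", lbl = "root"),
      list(id = "J:2", lbl = "child",
           meta = list(synonyms = list(list(val = "kid", pred = "hasExactSynonym")))),
      list(id = "J:3", lbl = "old", meta = list(deprecated = TRUE))
    ),
    edges = list(
      list(sub = "J:2", pred = "is_a", obj = "J:1"),
      list(sub = "J:3", pred = "http://purl.obolibrary.org/obo/BFO_0000050",
           obj = "J:1")
    )
  )))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  o <- load_ontology(f, format = "obographs-json")
  expect_length(o$terms, 3L)
  expect_equal(ancestors(o, "J:2"), "J:1")
  expect_true(o$terms[["J:3"]]$obsolete)
  expect_equal(o$terms[["J:2"]]$synonyms, "kid")
  # deprecated node's part_of edge is ignored in closure
  expect_equal(ancestors(o, "J:3"), character(0))
})
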