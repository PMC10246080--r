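test_that("payload sections parse with semicolon-separated terms", {
  p <- parse_payload(paste0(
    "Summary: S\nMechanism: M\n",
    "Enriched Terms: myelination; Schwann cell differentiation\n"))
  expect_equal(p$summary, "S")
  expect_equal(p$mechanism, "M")
  expect_equal(p$raw_terms, c("myelination", "Schwann cell differentiation"))
})

test_that("parsing tolerates sloppy payloads", {
  # empty fragments dropped
  p <- parse_payload("Enriched Terms: a;b;;c")
  expect_equal(p$raw_terms, c("a", "b", "c"))
  expect_true("missing Summary section" %in% p$warnings)
  # comma fallback and enumeration stripping
  p2 <- parse_payload("Summary: s\nMechanism: m\nEnriched Terms: 1. alpha, 2. beta")
  expect_equal(p2$raw_terms, c("alpha", "beta"))
  # case-insensitive headers
  p3 <- parse_payload("SUMMARY: s\nmechanism: m\nENRICHED TERMS: x; y")
  expect_equal(p3$raw_terms, c("x", "y"))
  # no term section at all
  err <- expect_error(parse_payload("Summary: only narrative"),
                      class = "genesum_parse_error")
  expect_match(err$raw_text, "only narrative")
})

test_that("reported p-values are flagged as fabricated statistics", {
  p <- parse_payload(
    "Summary: significant at p = 0.001\nMechanism: m\nEnriched Terms: x")
  expect_true(any(grepl("fabricated-statistic", p$warnings)))
})

test_that("grounding matches labels, then synonyms, normalized", {
  toy <- load_toy()
  o <- toy$ontology
  g1 <- ground_term("Myelination", o)
  expect_equal(g1$status, "grounded")
  expect_equal(g1$term, "FX:0000002")
  expect_equal(g1$matched_via, "label")
  # normalization: case, internal whitespace, surrounding punctuation
  g2 <- ground_term("  MYELINATION.  ", o)
  expect_equal(g2$term, "FX:0000002")
  g3 <- ground_term("myelinogenesis", o)
  expect_equal(g3$matched_via, "synonym")
  expect_equal(g3$term, "FX:0000002")
  # no fuzzy matching: a close paraphrase stays ungrounded
  g4 <- ground_term("myelin sheath maintenance", o)
  expect_equal(g4$status, "ungrounded")
  expect_true(is.na(g4$term))
})

test_that("matches to obsolete terms are kept but flagged", {
  toy <- load_toy()
  g <- ground_term("myelin renewal", toy$ontology)  # synonym of the obsolete term
  expect_equal(g$status, "grounded_obsolete")
  expect_equal(g$term, "FX:0000006")
  g2 <- ground_term("myelin upkeep", toy$ontology)  # its primary label
  expect_equal(g2$status, "grounded_obsolete")
})

test_that("identifier-like strings are never grounded", {
  o <- ontology(list(list(id = "GO:0008150", label = "GO:0008150")))
  for (raw in c("GO:0008150", "FX:0000002", "HP:0010871")) {
    g <- ground_term(raw, o)
    expect_equal(g$status, "ungrounded")
    expect_match(g$note, "identifier")
  }
})

test_that("ambiguous synonym hits resolve to the smallest identifier", {
  o <- ontology(list(
    list(id = "A:2", label = "alpha", synonyms = "shared name"),
    list(id = "A:1", label = "beta", synonyms = "shared name")
  ))
  g <- ground_term("shared name", o)
  expect_equal(g$term, "A:1")
  expect_match(g$note, "ambiguous")
})

test_that("payload grounding preserves order, dedupes, and is idempotent", {
  toy <- load_toy()
  p <- parse_payload(paste0(
    "Summary: s\nMechanism: m\n",
    "Enriched Terms: myelination; glucose metabolism; myelinogenesis; nonsense phrase"))
  g <- ground_payload(p, toy$ontology)
  expect_length(g$groundings, 4L)
  expect_equal(grounded_terms(g), c("FX:0000002", "FX:0000005"))
  expect_true(g$groundings[[3]]$duplicate)  # myelinogenesis -> same id as myelination
  expect_equal(g$groundings[[4]]$status, "ungrounded")
  g2 <- ground_payload(g, toy$ontology)
  expect_equal(grounded_terms(g2), grounded_terms(g))
  expect_equal(lapply(g2$groundings, `[[`, "status"),
               lapply(g$groundings, `[[`, "status"))
})

test_that("fully ungrounded payloads stay valid with an empty predicted set", {
  toy <- load_toy()
  p <- ground_payload(parse_payload("Enriched Terms: gibberish one; gibberish two"),
                      toy$ontology)
  expect_equal(grounded_terms(p), character(0))
  empty <- ground_payload(parse_payload("Summary: s\nMechanism: m\nEnriched Terms:"),
                          toy$ontology)
  expect_length(empty$groundings, 0L)
})

test_that("payload JSON includes statuses and warnings", {
  toy <- load_toy()
  p <- ground_payload(parse_payload(
    "Summary: s\nMechanism: m\nEnriched Terms: myelination; mystery"),
    toy$ontology)
  f <- withr::local_tempfile(fileext = ".json")
  write_payload_json(p, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(doc$terms[[1]]$status, "grounded")
  expect_equal(doc$terms[[1]]$term_id, "FX:0000002")
  expect_equal(doc$terms[[2]]$status, "ungrounded")
})
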