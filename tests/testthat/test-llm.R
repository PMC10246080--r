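toy_prompt <- function(store, gs, source = "ontological", end_marker = "###") {
  desc <- suppressWarnings(describe_gene_set(gs, source, store = store))
  build_prompt(prompt_spec(desc, token_budget = 4096L,
                           end_marker = end_marker))$text
}

test_that("faithful mock returns labels shared by at least two description lines", {
  toy <- load_toy()
  req <- completion_request(toy_prompt(toy$store, toy$gene_set))
  resp <- mock_complete(req, toy$store, "faithful")
  expect_match(resp, "Enriched Terms:")
  payload <- parse_payload(resp)
  expect_true("myelination" %in% payload$raw_terms)
  expect_true("axon ensheathment" %in% payload$raw_terms)
  # labels on a single line only are not returned
  expect_false("Schwann cell differentiation" %in% payload$raw_terms)
})

test_that("the mock reads only in-prompt text, not gene symbols", {
  toy <- load_toy()
  # swap in foreign descriptions: terms follow the foreign text
  desc <- describe_gene_set(toy$gene_set, "ontological", store = toy$store)
  donors <- list(gene_description("ZZZ1", "narrative", "involved in glucose metabolism"),
                 gene_description("ZZZ2", "narrative", "involved in glucose metabolism"))
  swapped <- swap_descriptions(desc, donors, seed = 5)
  prompt <- build_prompt(prompt_spec(swapped, token_budget = 4096L))$text
  resp <- mock_complete(completion_request(prompt), toy$store, "faithful")
  terms <- parse_payload(resp)$raw_terms
  expect_true("glucose metabolism" %in% terms)
  expect_false("myelination" %in% terms)
})

test_that("ungroundable behavior emits a paraphrase absent from the ontology", {
  toy <- load_toy()
  req <- completion_request(toy_prompt(toy$store, toy$gene_set))
  resp <- mock_complete(req, toy$store, "ungroundable")
  terms <- parse_payload(resp)$raw_terms
  labels <- vapply(toy$ontology$terms, `[[`, character(1), "label")
  syns <- unlist(lapply(toy$ontology$terms, `[[`, "synonyms"))
  expect_true(any(!terms %in% c(labels, syns)))
})

test_that("noisy behavior adds one unrelated ontology label", {
  toy <- load_toy()
  req <- completion_request(toy_prompt(toy$store, toy$gene_set))
  faithful <- parse_payload(mock_complete(req, toy$store, "faithful"))$raw_terms
  noisy <- parse_payload(mock_complete(req, toy$store, "noisy"))$raw_terms
  expect_length(noisy, length(faithful) + 1L)
  extra <- setdiff(noisy, faithful)
  labels <- vapply(toy$ontology$terms, `[[`, character(1), "label")
  expect_true(extra %in% labels)
})

test_that("mock completion is a pure function of prompt and behavior", {
  toy <- load_toy()
  req <- completion_request(toy_prompt(toy$store, toy$gene_set))
  expect_identical(mock_complete(req, toy$store, "faithful"),
                   mock_complete(req, toy$store, "faithful"))
})

test_that("a prompt without a description block is a format error", {
  toy <- load_toy()
  req <- completion_request("no gene summaries here")
  expect_error(mock_complete(req, toy$store), class = "genesum_format_error")
  req2 <- completion_request("Here are the gene summaries:\n###")
  expect_error(mock_complete(req2, toy$store), class = "genesum_format_error")
})

# a cached-only backend replaying entries written under another backend id
cached_only_backend_with_id <- function(id) {
  b <- cached_only_backend()
  b$id <- id
  b
}

test_that("completions are cached and replayed byte-identically", {
  toy <- load_toy()
  cache <- completion_cache(withr::local_tempfile(fileext = ".json"))
  backend <- mock_backend(toy$store)
  req <- completion_request(toy_prompt(toy$store, toy$gene_set))
  r1 <- complete(req, backend, cache)
  r2 <- complete(req, backend, cache)
  expect_false(r1$cached)
  expect_true(r2$cached)
  expect_identical(r1$response_text, r2$response_text)
  # cached-only backend can now serve the same request
  r3 <- complete(req, cached_only_backend_with_id(backend$id), cache)
  expect_true(r3$cached)
})

test_that("changing only the end marker misses the cache", {
  toy <- load_toy()
  cache <- completion_cache(withr::local_tempfile(fileext = ".json"))
  backend <- mock_backend(toy$store)
  ra <- complete(completion_request(toy_prompt(toy$store, toy$gene_set, end_marker = "###")),
                 backend, cache)
  rb <- complete(completion_request(toy_prompt(toy$store, toy$gene_set, end_marker = "===")),
                 backend, cache)
  expect_false(rb$cached)
})

test_that("a backend failure with a cold cache is a transport error", {
  req <- completion_request("Here are the gene summaries:\ngA: something")
  expect_error(complete(req, cached_only_backend()),
               class = "genesum_transport_error")
})
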