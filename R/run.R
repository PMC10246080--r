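# Pipeline orchestration: the summarize chain (descriptions -> prompt ->
# completion -> parse -> ground), the evaluation grid, perturbation and the
# end-marker stability probe, each emitting a run manifest sufficient to
# re-execute the run bit-identically with the mock or cached backend.

#' @noRd
build_manifest <- function(command, config, inputs = NULL, outputs = NULL,
                           backend_id = NULL, seeds = NULL,
                           truncation_factor = NULL, warnings = character(0)) {
  hashes <- NULL
  if (!is.null(inputs)) {
    inputs <- inputs[file.exists(unlist(inputs))]
    hashes <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  }
  deterministic <- is.null(backend_id) ||
    grepl("^(mock|cached)", backend_id)
  list(command = command,
       config = config,
       seeds = seeds,
       backend_id = backend_id,
       input_hashes = hashes,
       outputs = as.list(outputs %||% character(0)),
       truncation_factor = truncation_factor,
       warnings = as.list(warnings),
       # wall-clock time is omitted for deterministic backends so reruns
       # reproduce the manifest byte-identically
       timestamp = if (deterministic) NULL else format(Sys.time(), tz = "UTC"))
}

#' @noRd
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Run the full summarization chain
#'
#' Describes each gene from the chosen source, builds the token-budgeted
#' prompt, completes it against the backend (cache first), parses the
#' payload and grounds its terms against the ontology.
#'
#' @param gs A [gene_set].
#' @param store An [annotation_store].
#' @param source Description source: `"none"`, `"narrative"`,
#'   `"ontological"`.
#' @param backend Backend object; defaults to the faithful mock over
#'   `store`.
#' @param narrative_table Named character vector (required for
#'   `source = "narrative"`).
#' @param token_budget,end_marker,template_text,output_reserve Passed to
#'   [prompt_spec()].
#' @param model_name,temperature Passed to [completion_request()].
#' @param cache Optional [completion_cache].
#' @param out_dir When given, `payload.json` and `manifest.json` are written
#'   there.
#' @param input_paths Optional named character vector of input files whose
#'   MD5 hashes go into the manifest.
#' @return List with `payload` (grounded `summary_payload`), `prompt`
#'   (`built_prompt`), `record` (`completion_record`), `manifest`.
#' @export
run_summarize <- function(gs, store,
                          source = c("ontological", "narrative", "none"),
                          backend = mock_backend(store),
                          narrative_table = NULL,
                          token_budget = 4096L, end_marker = "###",
                          template_text = default_template(),
                          output_reserve = 0.25,
                          model_name = "mock", temperature = 0,
                          cache = NULL, out_dir = NULL, input_paths = NULL) {
  source <- match.arg(source)
  warnings <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  desc <- collect(describe_gene_set(gs, source,
                                    narrative_table = narrative_table,
                                    store = store))
  prompt <- collect(build_prompt(prompt_spec(
    desc, taxon = gs$taxon, token_budget = token_budget,
    template_text = template_text, end_marker = end_marker,
    output_reserve = output_reserve)))
  if (prompt$truncation_factor < 1) {
    warnings <- c(warnings, sprintf("descriptions truncated: TF = %.4f",
                                    prompt$truncation_factor))
  }
  req <- completion_request(prompt$text, model_name = model_name,
                            temperature = temperature)
  record <- collect(complete(req, backend, cache))
  payload <- collect(ground_payload(parse_payload(record$response_text),
                                    store$ontology))
  warnings <- unique(c(warnings, payload$warnings))
  manifest <- build_manifest(
    command = "summarize",
    config = list(gene_set = gs$name, taxon = gs$taxon, n_genes = length(gs$genes),
                  source = source, token_budget = token_budget,
                  end_marker = end_marker, output_reserve = output_reserve,
                  model_name = model_name, temperature = temperature,
                  cache = if (is.null(cache)) NULL else cache$path),
    inputs = input_paths,
    backend_id = record$backend_id,
    truncation_factor = prompt$truncation_factor,
    warnings = warnings)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    payload_path <- file.path(out_dir, "payload.json")
    write_payload_json(payload, payload_path)
    manifest$outputs <- list("payload.json")
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(payload = payload, prompt = prompt, record = record,
       manifest = manifest)
}

#' Run standard enrichment and write its table
#'
#' @inheritParams run_summarize
#' @param min_annotated Passed to [enrich()].
#' @param out_dir When given, `enrichment.tsv` and `manifest.json` are
#'   written there.
#' @return List with `result` (the `enrichment_result`) and `manifest`.
#' @export
run_enrich <- function(gs, store, min_annotated = 1L, out_dir = NULL,
                       input_paths = NULL) {
  res <- enrich(gs, store, min_annotated = min_annotated)
  manifest <- build_manifest(
    command = "enrich",
    config = list(gene_set = gs$name, min_annotated = min_annotated,
                  m_tests = attr(res, "m_tests"),
                  n_sample = attr(res, "n_sample")),
    inputs = input_paths)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_enrichment_tsv(res, file.path(out_dir, "enrichment.tsv"))
    manifest$outputs <- list("enrichment.tsv")
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(result = res, manifest = manifest)
}

#' Evaluate the summarization chain over an (n, p) grid
#'
#' For each combination of `top_n` and `p_cutoff`, filters the standard
#' enrichment results and scores the grounded predicted terms with the
#' closure-aware confusion counts. Ungrounded strings are excluded from the
#' false-positive count by default (they are a separate reporting category);
#' set `count_ungrounded_fp = TRUE` to penalize them.
#'
#' @inheritParams run_summarize
#' @param top_n_grid,p_cutoff_grid Numeric vectors spanning the grid.
#' @param closure_matching,use_adjusted_p Passed to [eval_config()].
#' @param count_ungrounded_fp Add each ungrounded raw term to `fp`?
#' @param out_dir When given, `evaluation.tsv` and `manifest.json` are
#'   written there.
#' @return List with `table` (long-format data frame: one row per grid
#'   cell), `summarize_run`, `enrichment`, `manifest`.
#' @export
run_evaluate <- function(gs, store,
                         source = c("ontological", "narrative", "none"),
                         backend = mock_backend(store),
                         narrative_table = NULL,
                         top_n_grid = c(1L, 10L),
                         p_cutoff_grid = c(0.05, 0.01),
                         closure_matching = TRUE, use_adjusted_p = TRUE,
                         count_ungrounded_fp = FALSE,
                         min_annotated = 1L,
                         token_budget = 4096L, end_marker = "###",
                         cache = NULL, out_dir = NULL, input_paths = NULL) {
  source <- match.arg(source)
  run <- run_summarize(gs, store, source = source, backend = backend,
                       narrative_table = narrative_table,
                       token_budget = token_budget, end_marker = end_marker,
                       cache = cache)
  predicted <- grounded_terms(run$payload)
  n_ungrounded <- sum(vapply(run$payload$groundings,
                             function(g) g$status == "ungrounded", logical(1)))
  res <- enrich(gs, store, min_annotated = min_annotated)
  rows <- list()
  for (n in top_n_grid) {
    for (p in p_cutoff_grid) {
      cfg <- eval_config(top_n = n, p_cutoff = p,
                         use_adjusted_p = use_adjusted_p,
                         closure_matching = closure_matching)
      std <- filter_standard(res, cfg)
      rep <- confusion(predicted, std, store$ontology, cfg)
      fp <- rep$fp + if (count_ungrounded_fp) n_ungrounded else 0L
      prec <- if (rep$accounted + fp > 0) rep$accounted / (rep$accounted + fp) else 0
      f1 <- if (prec + rep$recall > 0) 2 * prec * rep$recall / (prec + rep$recall) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene_set = gs$name, source = source, backend = run$record$backend_id,
        n = n, p_cutoff = p, tp = rep$tp, fp = fp, fn = rep$fn,
        precision = prec, recall = rep$recall, f1 = f1,
        has_hit = rep$has_hit, has_top_hit = rep$has_top_hit,
        truncation_factor = run$prompt$truncation_factor,
        n_ungrounded = n_ungrounded,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  manifest <- build_manifest(
    command = "evaluate",
    config = list(gene_set = gs$name, source = source,
                  top_n_grid = top_n_grid, p_cutoff_grid = p_cutoff_grid,
                  closure_matching = closure_matching,
                  use_adjusted_p = use_adjusted_p,
                  count_ungrounded_fp = count_ungrounded_fp,
                  m_tests = attr(res, "m_tests")),
    inputs = input_paths,
    backend_id = run$record$backend_id,
    truncation_factor = run$prompt$truncation_factor,
    warnings = run$manifest$warnings)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "evaluation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$outputs <- list("evaluation.tsv")
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(table = tab, summarize_run = run, enrichment = res,
       manifest = manifest)
}

#' Perturb a gene set and write the result
#'
#' @inheritParams run_summarize
#' @param fraction,seed Passed to [perturb_gene_set()]; the replacement pool
#'   is the store's background.
#' @param out_dir When given, `perturbed.yaml` and `manifest.json` are
#'   written there.
#' @return List with `gene_set` (perturbed) and `manifest`.
#' @export
run_perturb <- function(gs, store, fraction = 0.1, seed = 1L,
                        out_dir = NULL, input_paths = NULL) {
  pgs <- perturb_gene_set(gs, store$background, fraction = fraction,
                          seed = seed)
  manifest <- build_manifest(
    command = "perturb",
    config = list(gene_set = gs$name, fraction = fraction),
    inputs = input_paths, seeds = seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_gene_set(pgs, file.path(out_dir, "perturbed.yaml"))
    manifest$outputs <- list("perturbed.yaml")
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(gene_set = pgs, manifest = manifest)
}

#' Run the end-marker stability probe
#'
#' Re-runs the same summarization with an insignificant syntactic prompt
#' change — the end marker toggled from `"###"` to `"==="` — and reports the
#' Jaccard similarity between the two runs' grounded term sets (terms
#' counted directly, no hierarchy).
#'
#' @inheritParams run_summarize
#' @param markers Length-2 character vector of end markers.
#' @param out_dir When given, `stability.json` and `manifest.json` are
#'   written there.
#' @return List with `jaccard`, `run_a_terms`, `run_b_terms`, the two runs,
#'   and `manifest`.
#' @export
run_stability <- function(gs, store,
                          source = c("ontological", "narrative", "none"),
                          backend = mock_backend(store),
                          narrative_table = NULL,
                          markers = c("###", "==="),
                          token_budget = 4096L, cache = NULL,
                          out_dir = NULL, input_paths = NULL) {
  source <- match.arg(source)
  runs <- lapply(markers, function(mk) {
    run_summarize(gs, store, source = source, backend = backend,
                  narrative_table = narrative_table,
                  token_budget = token_budget, end_marker = mk,
                  cache = cache)
  })
  a <- grounded_terms(runs[[1]]$payload)
  b <- grounded_terms(runs[[2]]$payload)
  jac <- jaccard_terms(a, b)
  manifest <- build_manifest(
    command = "stability",
    config = list(gene_set = gs$name, source = source, markers = markers),
    inputs = input_paths,
    backend_id = runs[[1]]$record$backend_id)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(list(jaccard = jac, run_a_terms = a, run_b_terms = b),
                         file.path(out_dir, "stability.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest$outputs <- list("stability.json")
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(jaccard = jac, run_a_terms = a, run_b_terms = b, runs = runs,
       manifest = manifest)
}
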