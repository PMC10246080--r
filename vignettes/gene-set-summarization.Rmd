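---
title: "Methods: gene set summarization, grounding and the closure-aware benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene set summarization, grounding and the closure-aware benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesum)
```

## Overview

`genesum` treats gene set interpretation two ways and scores one against the
other. The *baseline* is classical over-representation analysis (ORA): a
hypergeometric upper-tail test per ontology term with Bonferroni correction.
The *summarization chain* builds a natural-language prompt from per-gene
descriptions, obtains a completion, parses the structured payload and
grounds the returned term strings in the ontology. The *benchmark* then
counts, with awareness of the ontology hierarchy, how much of the
statistically supported answer the summarizer recovered.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical and design choices made where the design was
genuinely open, and what the synthetic fixtures do and do not establish.

## The ontology layer

An ontology here is a DAG of terms with labels, synonyms (all scopes pooled
into one set by default; a `synonym_scopes` argument restricts grounding to
chosen scopes), obsolescence flags and typed parent edges. Closure —
`ancestors()`, `descendants()`, `related_by_hierarchy()` — traverses only
the relations in `closure_relations`, defaulting to `{is_a, part_of}`:
these are the two hierarchy-bearing relations a GO-style analysis normally
generalizes over, and which relations an evaluation should traverse is a
judgment call we expose as configuration rather than fix. Obsolete terms
are loaded and indexed (so grounding can recognize the use of obsoleted
vocabulary) but contribute no closure edges; their `replaced_by` pointer
must name a live term. Identifiers are opaque strings compared exactly; no
CURIE/IRI expansion is attempted. Acyclicity over the closure relations is
validated at construction, and a violation reports one witness cycle.

## Annotations and the background universe

GAF 2.x rows supply direct gene-to-term annotations (symbol in column 3,
term in column 5). Rows with a `NOT` qualifier are dropped by default
(`qualifier_policy = "keep_all"` retains them); evidence-code filtering is
available but off by default, since requiring particular codes is a
curation policy rather than part of the method. The background universe
defaults to every distinct symbol in the file — for annotated-corpus ORA
the natural choice, though a user-supplied background is accepted because
the right universe depends on what was assayed. Annotation closure
(annotation to a term implies annotation to its ancestors) is computed
lazily per queried term and memoized: closure tables over a full-size
ontology would be large, and typical queries touch few terms. Gene symbols
are stored case-preserving and matched case-insensitively.

## The over-representation baseline

For a sample of `n` background genes, of which `k` are annotated (under
closure) to a term carried by `K` of the `N` background genes, the raw
p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed by
`stats::phyper` in log space. Candidate terms are those annotated to at
least `min_annotated` (default 1) sample genes under closure; the
Bonferroni multiplier `m` is the number of candidates actually tested, not
the ontology size — the conventional ORA choice, and `m` is recorded in the
result's metadata so the correction is auditable. Rows are ordered by
(adjusted p, raw p, term identifier): the identifier tie-break makes
rankings fully deterministic. Only over-representation is tested, the
root term is tested like any other, and no FDR-style procedure is offered —
the benchmark's filtering semantics are defined against Bonferroni.

## Descriptions, prompts and truncation

Each gene contributes one prompt line, `symbol: text` (bare symbol when
there is no text). Three sources: `none` (symbol only — the line contains
nothing but the symbol, guarding controlled comparisons against information
leakage), `narrative` (a curated prose table, TSV `symbol → text`), and
`ontological` (a deterministic controlled-language rendering of the gene's
direct annotation labels, grouped by GAF aspect — "involved in X, Y and Z";
"enables …"; "located in …" — with labels alphabetized within groups). The
rendering deliberately stays minimal: the downstream contract needs
informative, deterministic text, not any particular description grammar.

The prompt template ships as a package resource with `{{ taxon }}` and
`{{ gene_descriptions }}` placeholders and is overridable, since different
models may need adjusted phrasing. Token accounting defaults to whitespace
word counts — the usual rough equivalence — and accepts any
string-to-count function where model-accurate budgets matter. From the
budget (default 4096; 8192/32768 suit larger models) we subtract an output
reserve (default 25% — the limit covers both directions and no principled
split exists, so a round fraction is fixed once), the filled template and
end marker, and the per-line symbol overhead; what remains is available for
description text. A single global truncation factor
`TF = min(1, available / total_description_tokens)` scales every
description: each keeps its first `floor(TF × tokens)` tokens, truncated
from the end on the assumption that openings carry the most information.
Uniform proportionality (rather than per-line schemes) keeps the factor
interpretable: TF = 0.25 means only 25% of the original text could be
used. A budget too small for the template alone is an error, not a silent
empty prompt.

## Completion, caching and the mock backend

A backend is `(id, fun: request → text)`. Requests default to temperature
0 — determinism is the point of the exercise. Completions are cached in a
single JSON file keyed by a SHA-256 hash of (backend id, model name,
temperature, prompt); identical requests replay byte-identically, and any
prompt edit — including the end-marker toggle used by the stability probe —
is a cache miss. The cache format is plain text so completion fixtures can
be committed. A `cached_only` backend errors on every miss (replay mode);
an OpenAI-compatible adapter reads its endpoint and key from environment
variables only, and nothing in the package or tests requires it.

The mock backend is a pure function of (prompt, behavior, label
inventory). It re-extracts the description lines from the prompt and reads
*only* them — mirroring the observation that, under swapped descriptions, a
model summarizes the in-context text and ignores the symbols. `faithful`
returns every ontology label occurring in at least two description lines
(most-shared first, ties alphabetical); `noisy` adds one unrelated label
selected by the prompt hash, so syntactically trivial prompt changes can
change the answer — giving the stability probe something real to measure;
`ungroundable` replaces the last term with a paraphrase verified absent
from all labels and synonyms. The mock is deliberately *easy* to ground:
it exists to exercise the pipeline's contracts, not to model LLM quality.

## Parsing and grounding

Payload parsing finds `Summary:` / `Mechanism:` / `Enriched Terms:`
headers case-insensitively, splits terms on semicolons (comma fallback),
strips enumeration prefixes and drops empty fragments; a payload with no
term section is a parse error carrying the raw text. The narrative summary
is never parsed for content, but any p-value-like string anywhere in the
payload raises a fabricated-statistic warning — no test was run, so any
reported statistic is invented.

Grounding is exact normalized matching only: case-fold, collapse internal
whitespace, strip surrounding punctuation; labels first, then synonyms;
ambiguity broken by smallest identifier with a warning. Whole-string
matching (not longest-substring annotation) keeps outcomes auditable
one-to-one against the raw term list. There is deliberately no fuzzy
matching: that a near-miss paraphrase stays ungrounded is part of the
phenomenon under study, not a defect to engineer away. Matches to obsolete
terms are kept and flagged `grounded_obsolete` rather than auto-replaced,
so obsolete-vocabulary use remains visible. Identifier-shaped strings
(`prefix:digits`) are refused outright — generative models fabricate
plausible identifiers, so the prompt never asks for them and the grounder
never accepts them.

## The benchmark

Standard results are filtered to rows passing the p cutoff (adjusted p by
default — Bonferroni is what the baseline computes; raw-p mode exists),
then cut to the top `n` by rank. Matching uses
`related_by_hierarchy` under closure matching (default) or identity
otherwise. A standard term matched by any predicted term is a true
positive; unmatched standard terms are false negatives; a predicted term
matching no standard term is a false positive. Precision's numerator
counts *accounted* predicted terms rather than `tp`: one predicted term
may cover several standard terms and vice versa, and this choice keeps
precision a property of the predicted list. All ratios are defined as 0
on an empty denominator. `has_hit` is whether any standard term matched;
`has_top_hit` whether the rank-1 term did. Ungrounded raw strings are
excluded from `fp` by default (they are reported as their own category;
a flag counts them against precision).

Perturbation replaces `r = max(1, round(fraction × N))` genes (default
fraction 0.1) with distinct random draws from a stated pool — the `max(1,·)`
ensures even a 3-gene set is actually perturbed; `fraction = 0` is an
explicit no-op. The replacement pool is an explicit parameter (the
annotated background in the shipped workflows). Description swapping
replaces each line's text with a random donor's, symbols unchanged.
Stability re-runs a configuration with the end marker toggled
`###` → `===` and reports the Jaccard similarity of the grounded term
sets, counting terms directly with no hierarchy credit.

Metric distributions are compared with a one-sided exact Mann-Whitney
test: for combined sample sizes up to 20, the p-value comes from full
enumeration of rank-sum assignments with midranks for ties; larger samples
use the tie-corrected normal approximation and the result is flagged
inexact.

## Synthetic fixtures: what they do and do not show

`make_fixture()` generates a layered, singly rooted DAG (edges only point
to earlier layers, so acyclicity holds by construction) with unique
fixed-pattern labels — `"<noun> process <NNN>"` — chosen so no label is a
substring of another, which the mock's substring scan requires. Defaults:
20 terms in 3 layers, 100 background genes, a 20-gene sample, one obsolete
term carrying a live synonym, 30% synonym rate, and a planted term
annotated to 80% of the sample versus 10% of the remaining background —
a strong, unambiguous over-representation signal. Every gene also receives
one to three random annotations so descriptions are informative and other
terms see realistic background counts. Gene-set sizes from 3 to 200 are
supported, matching the range a curated evaluation corpus spans. Narrative
texts embed each gene's annotation labels among distractor words so the
faithful mock is solvable from the narrative source too.

Passing tests on these fixtures establishes the *contracts*: the
statistics agree with enumeration oracles, closure scoring matches a
brute-force transcription of its definition, the chain is byte-deterministic,
truncation respects budgets, grounding distinguishes its three outcomes.
They do not establish anything about real LLM output quality, real GO
topology (fixture DAGs are small and regular), real annotation bias, or
narrative-summary quality — the last is explicitly out of scope throughout.

## Numerical and reproducibility choices

* Hypergeometric tails delegate to `phyper` (log-space); test oracles use
  direct combinatorial sums, exact in double precision for `N ≤ 40`.
* Exact Mann-Whitney enumerates `C(n, n_x)` assignments; the threshold of
  20 keeps that below ~185k arrangements.
* Seeded operations (`perturb_gene_set`, `swap_descriptions`,
  `make_fixture`) save and restore the caller's RNG state, so they compose
  without side effects and identical seeds give identical output.
* Run manifests omit wall-clock timestamps under deterministic backends
  (mock, cached-only): re-running a manifest must reproduce output files
  byte-identically, which a timestamp would break. Live-backend manifests
  carry timestamps.
* Problem sizes in the shipped test and acceptance workflows (100 fixtures
  for recovery rates, 50 for benchmark means, 500 oracle draws) are chosen
  to give stable rates on a single CPU in seconds; all scale up by
  argument.

## Known limitations

* The ontological synopsis is a minimal controlled-language rendering, not
  a reproduction of any curated description service's grammar.
* Grounding is whole-string and exact; a production annotator might prefer
  longest-substring matching, which would ground more but blur the
  accounting.
* The Bonferroni multiplier depends on the candidate-term universe, which
  in turn depends on the annotation corpus; results are only comparable
  across runs that share a background and `min_annotated`.
* No aggregation across repeated stochastic completions is implemented;
  the stability probe quantifies variability but does not average it away.
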