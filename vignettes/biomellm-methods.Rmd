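---
title: "biomellm: methods, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{biomellm: methods, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomellm)
```

## The task

Submitter-provided metadata of environmental sequencing samples is
free-form: the same information may sit in `sample_isolation_source`, a
verbose `study_STUDY_ABSTRACT`, or a user-invented field; values may be
placeholders ("missing", "NaN"); ontology knowledge may be encoded as
numeric CURIEs (`ENVO:00002297`) that a language model cannot interpret
natively. `biomellm` re-annotates each sample into an operational scheme
designed for metadata reuse: a five-way **biome** (*animal*, *plant*,
*water*, *soil*, *other* — controlled source-context labels, not ecological
biomes), a ≤ 3-word **sub-biome**, a country-level **location**, and 5–8
**keywords**. Two curation conventions are baked in throughout, because
they are the classic ambiguous cases: rhizosphere samples are labelled
*plant* and sediment samples *water*.

The pipeline is: clean → translate ontology codes → pack into
token-budgeted requests → prompt an LLM → parse → reconcile IDs and retry →
validate against gold labels → check geographic consistency. Every stage is
exercised offline through a deterministic mock backend, so the package's
claims are about the machinery, not about any particular model.

## Cleaning and ontology translation

`clean_record()` removes (a) empty-valued fields, (b) fields whose whole
trimmed value equals a placeholder, case-insensitively (default set:
missing, NaN, not applicable, unknown, NA, none, null), and (c) fields
whose *name* begins with "experiment" (case-insensitive), which describe
wet-lab procedure rather than sample origin. Placeholder comparison is
deliberately whole-value only: substring removal would destroy informative
text such as "NaN-free soil". Cleaning is idempotent, never increases the
token count, and logs every removal with a reason code, so the reduction is
auditable. Whether the placeholder family should also cover variants like
"n/a" or "-" is genuinely open; the set is a constructor argument so a
curator can widen it.

`translate_ontology()` replaces every word-bounded CURIE whose prefix comes
from the loaded dictionary (ENVO, FOODON, NCBITaxon, PO, UBERON by
convention) with its textual label; unknown CURIEs are left intact and
logged rather than guessed. Word-boundary matching avoids false hits inside
longer identifiers. The field count never changes.

The consolidated-file dialect — an accession-only line starts a record;
`name: value` lines with first-colon splitting follow — is an assumption:
the grammar of real consolidated exports varies, and the reader flags
malformed lines in a warnings attribute instead of dropping them.
`shard_key()` shards by the last three accession digits, zero-padding
shorter tails so the directory fan-out is total and capped at 1000.

## Token budgeting and first-fit decreasing

LLM APIs charge per token and cap request size, so samples are packed into
chunks under a budget `chunksize` that *includes* the system prompt.
`pack_ffd()` implements first-fit decreasing: sort samples by token count
descending (ties broken by accession, ascending, for bit-reproducible
runs), place each into the first chunk it fits, else open a new one. FFD is
the standard near-optimal heuristic with the classical at most
(11/9)·OPT + 1 guarantee; the tests verify partition, budget, determinism
and the guarantee against an exact branch-and-bound oracle on all small
instances. Samples larger than the effective budget become singleton chunks
with an `oversize_flag` rather than errors: dropping records silently would
bias any downstream accuracy estimate. The default tokenizer is the
`ceiling(nchar/4)` byte-pair rule of thumb; any `text -> integer` function
can be plugged in, and the same tokenizer must be used for the prompt and
the samples so the budget accounting is consistent.

## Prompts, backends, parsing and retry

`build_system_prompt()` carries three variants: the standard inline prompt
(five `___`-separated values per sample, keywords in curly brackets), the
"better" variant that appends one clause instructing rhizosphere → plant
and sediment → water, and a JSON variant requesting an array of objects.
The JSON template's exact schema wording is a reconstruction; its content
mirrors the inline fields. The separation is byte-stable so that
`better − standard` is exactly the added clause.

Backends implement a minimal contract (`complete`, `submit_batch`,
`fetch_batch`). Synchronous submission sends one request per chunk;
asynchronous submission is *never* chunked — exactly one request per sample
— mirroring batch APIs. Transport failures are retried 3 times with
exponential backoff and then recorded, separately from content-level
failures: a missing or unparseable sample ID is re-requested individually
(unchunked, even if the original run was chunked, to isolate failures) up
to `max_retries` times (default 2), after which it is reported with
`status = "unresolved"`, never silently dropped. Parsers never raise on
arbitrary bytes; malformed lines, duplicates and unexpected IDs are data in
the parse report, and `parsed ∪ missing` always partitions the expected ID
set. Keyword-count (5–8) and sub-biome-length (≤ 3 words) violations are
flagged, not rejected — discarding them would bias accuracy measurement
against exactly the decoding settings that cause them.

Output filenames embed every run parameter (samples per biome, seed,
chunking, chunk size, model, token cap, temperature, nucleus sampling,
frequency/presence penalties, free-text tag, request count or batch id,
timestamp) and parse back into a `request_config`, so a results file is
self-describing. Decoding defaults are the neutral baseline: temperature 1,
top-p 1, zero penalties.

## Validation statistics

**Exact vs lenient matching.** Exact requires the normalised prediction to
equal the gold label. Lenient accepts a prediction in which exactly one of
the five labels occurs as a complete word followed by clarifying text
("animal (human)"); "animals" fails (not a complete word) and a prediction
containing two distinct biome words fails (ambiguity must not count as
correct). Exact implies lenient, so lenient accuracy can never be below
exact accuracy — a property the tests assert on every run.

**Metrics.** `compute_metrics()` builds the gold × predicted confusion
matrix with a sixth "none" column for unresolved or unmatchable
predictions, which therefore count as wrong — mirroring what a production
consumer experiences. Precision, recall and F1 are macro-averaged over the
five biomes; the benchmark is balanced by construction, which makes macro
and weighted averaging nearly coincide, and macro matches the per-biome
framing. Cohen's κ is computed from the full matrix. All four metrics are
verified against a from-definitions oracle on a thousand random instances.

**Paired tests.** Comparisons between runs over the same sample IDs use
McNemar's test for biome correctness and the paired *t*-test for sub-biome
cosine similarity; disjoint ID sets use Welch's independent *t*. Partially
overlapping sets are an explicit error — silently intersecting or pooling
would change the hypothesis being tested. The McNemar variant is the
uncorrected χ² = (b − c)²/(b + c) for b + c ≥ 25 and the exact two-sided
binomial `min(1, 2·P(X ≤ min(b, c)))` below that, standard practice when
the named variant is unspecified; the exact branch is verified against full
binomial enumeration for every b + c ≤ 24. Degenerate-input conventions are
fixed for determinism: no discordant pairs → p = 1, statistic 0; all paired
differences exactly zero → p = 1; constant non-zero differences → error
(the statistic is undefined). Bonferroni correction multiplies by the
family size and caps at 1.

**Embeddings.** Sub-biome agreement is scored by cosine similarity between
embeddings of the predicted and curator sub-biomes. The offline provider is
a seeded hashing embedder over word tokens and character trigrams: identical
texts map to identical vectors and texts sharing more word tokens score
higher — sufficient to validate the machinery and the monotonicity the
tests assert, but *not* a semantic model (synonyms share no tokens and score
low). Vectors from different providers are never comparable and mixing them
is an error.

## Geolocation consistency

`parse_lat_lon()` recognises combined fields (`lat_lon`, hemisphere-letter
form "37.77 N 122.42 W" where S/W negate, signed decimal pairs) and
separate latitude/longitude fields; out-of-bounds values are rejected with
a warning. Distances use the haversine with mean Earth radius 6371.0 km
(conventional choice) and are bucketed into half-open lower-inclusive
intervals [0,100), [100,500), [500,1000), [1000,4000), [4000,∞) — the
boundary convention is ours, as only the category labels are standard.

Geocoding is a pluggable contract; the bundled offline gazetteer (~50
places + a few research institutions, hand-written) stands in for remote
services so tests run without network. Text matching is word-level
containment in either direction after lowercasing and punctuation
stripping; semantically equivalent but textually disjoint names ("McMurdo
Station" vs "Antarctica") do not match, a limitation inherent to string
matching and one reason real-world mismatch triage exists.

For a mismatch, `triage_mismatch()` tests candidate corrections of the raw
stored pair — swap(lat, lon), longitude sign flip, latitude sign flip — and
returns the corresponding error code when a corrected point lands within
100 km of the predicted location; checks run in that fixed order. Stored
pairs may be out of bounds (a swap artifact), so triage works on raw
numbers, not validated points. Points sitting on a known institution map to
`institution_coords`; an unresolvable prediction yields
`location_not_in_text`; anything else is `metadata_completely_wrong`.
Calling triage on a pair that already matches the prediction raises an
error: that sample should have matched upstream.

The error injector (`inject_coordinate_errors()`) applies exactly one mode
per selected sample and logs a truth table. A corruption whose stored point
stays within 300 km of the truth — the gazetteer's reverse-geocoding
locality radius — is skipped as operationally undetectable: it would still
reverse-geocode to the same locality (e.g. swapping Cairo's 30.0/31.2
coordinates moves it only ~190 km). The relocation mode additionally
re-draws until no triage correction of the random point lands back on the
truth, so it cannot masquerade as a swap or sign flip.

## The synthetic benchmark and what it shows

`generate_benchmark()` emits `5 × n_per_biome` records with `SYN`-prefixed
accessions (honest provenance; no collision with real archives) built from
hand-written per-biome template banks: concise host/isolation-source
fields, an environment field, a scientific-name field, a verbose abstract,
a location name and a `lat_lon` pair from the gazetteer. Placeholder fields
and raw ontology CURIEs are injected at configurable rates; the default
profile is noise-free so that the generator's outputs reload through the
metadata reader without warnings. The benchmark scale used throughout
validation is the curated scale of 200 samples per biome (1,000 records);
unit tests use 5–100 samples per biome to stay fast, and the geolocation
recovery runs use 2,000 records.

The deterministic mock backend draws each sample's predicted biome from a
row-stochastic confusion matrix keyed by `(seed, sample_id)`, so a designed
diagonal (e.g. 0.806) is recovered by the validation module within binomial
sampling error — the parameter-recovery test that ties generator, parser
and metrics together. Omission and malformation apply on first request
only by default, exercising the retry path; `permanent_omit_ids` exercises
the unresolved path.

What passing these tests shows: the pipeline's bookkeeping (ID
reconciliation, retry, flagging), its statistics, and its triage logic are
correct on data with known ground truth. What it does not show: performance
on real SRA metadata. The templates are regular and their vocabulary
overlaps cleanly with the bundled keyword whitelists, so the keyword
baseline scores far higher here than any whitelist classifier would on real
submissions (its synthetic weakness is confined to the deliberately
ambiguous rhizosphere templates, which mention soil). Comparisons between
the mock "LLM" and the baseline on synthetic data characterise the
machinery only; neither number transfers to real corpora, where the
relative ordering of semantic and keyword classifiers must be established
against a hand-curated benchmark.

## Cost model

`estimate_cost()` is the linear token-volume model
`n_tokens · (1 − reduction) · price / 10⁶`; `report_cost()` rounds to the
nearest ten currency units for headline figures. Cleaning empty and
placeholder fields reduces input volume (ontology translation lengthens it
slightly); at a 35% net reduction and $0.5 per million input tokens, a
volume that would cost $522 drops to ≈ $340 — the scale of saving that
motivates the cleaning stage for multi-million-sample runs.

## Defaults at a glance

| Parameter | Default | Why |
|---|---|---|
| placeholders | missing, NaN, not applicable, unknown, NA, none, null | common SRA placeholder spellings; whole-value match |
| tokenizer | ceil(chars/4) | standard BPE rule of thumb; pluggable |
| chunksize | 3000 tokens | mild chunking (a handful of samples per request) |
| temp/topp/freqp/presp | 1 / 1 / 0 / 0 | neutral decoding baseline |
| max_retries | 2 | isolates transient omissions without unbounded cost |
| transport retries | 3, exponential backoff | client hygiene, separate from parse retry |
| Earth radius | 6371.0 km | conventional mean radius |
| triage radius | 100 km | "same locality" scale for corrections |
| reverse-geocode radius | 300 km | gazetteer density; also the injector's detectability bound |
| lenient token length | ≥ 3 chars, stop-words excluded | stops "of"/"in" inflating field matches |
| min lenient count (field report) | 20 | excludes rarely matching fields from the per-biome breakdown |

## Known limitations

* The inline parser assumes the five-field `___` grammar; models that wrap
  answers in prose are handled only via the malformed-line/retry path.
* The mock embedder is lexical; cosine similarities involving paraphrase
  are meaningful only relatively, within one provider.
* The gazetteer is tiny by design; reverse geocoding returns `NA` on open
  ocean and the text-match rate depends on its density.
* Triage attributes a mismatch to the *first* correction that fits; on
  pathological coordinates (|lat| ≈ |lon|) a sign flip can be
  indistinguishable from a swap. The injector avoids generating such
  ambiguous cases rather than pretending triage could resolve them.
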