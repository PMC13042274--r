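Package: biomellm
Title: LLM-Assisted Re-Annotation of Microbiome Sample Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to re-annotate heterogeneous sequencing-sample metadata
    (SRA/BioSample style key:value records) into five operational biomes
    (animal, plant, water, soil, other) plus a concise sub-biome, a sampling
    location, and descriptive keywords, using a prompt-based large language
    model pipeline. Includes metadata cleaning and ontology-code translation,
    token-budgeted request packing by first-fit decreasing bin packing, a
    pluggable LLM backend contract with a deterministic offline mock, inline
    and JSON response parsers with identifier reconciliation and retry, a
    keyword-whitelist baseline classifier, validation statistics (exact and
    lenient label matching, confusion matrices, Cohen's kappa, McNemar and
    t tests with Bonferroni correction, embedding cosine similarity), offline
    geolocation consistency checks with coordinate-error triage, metadata
    field informativeness analysis, and a synthetic gold-labelled benchmark
    generator so that the full pipeline is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
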