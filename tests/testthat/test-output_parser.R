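# Inline and JSON response parsing with strict ID reconciliation.

example_line <- paste0(
  "SRS123456___animal___Los Angeles, USA___",
  "{medical, bone fracture, infection, collagen, hospital, intensive care, ",
  "cast, Staphylococcus epidermidis}___human elbow")

test_that("the documented example response line parses field by field", {
  res <- parse_inline(example_line, expected_ids = "SRS123456")
  ann <- res$annotations
  expect_equal(nrow(ann), 1)
  expect_equal(ann$sample_id, "SRS123456")
  expect_equal(ann$biome_raw, "animal")
  expect_equal(ann$location, "Los Angeles, USA")
  expect_length(strsplit(ann$keywords, "|", fixed = TRUE)[[1]], 8)
  expect_equal(ann$sub_biome, "human elbow")
  expect_false(ann$flagged)
  expect_length(res$report$missing_ids, 0)
})

test_that("NA fields pass through and parsed/missing partition expected IDs", {
  raw <- "SRS1___soil___NA___{a, b, c, d, e}___agricultural"
  res <- parse_inline(raw, expected_ids = c("SRS1", "SRS2"))
  expect_equal(res$annotations$location, NA_character_)
  expect_equal(res$annotations$biome_raw, "soil")
  expect_equal(res$report$parsed_ids, "SRS1")
  expect_equal(res$report$missing_ids, "SRS2")
  expect_setequal(c(res$report$parsed_ids, res$report$missing_ids),
                  c("SRS1", "SRS2"))
})

test_that("wrong field counts and non-accession lines are malformed, ID retried", {
  raw <- paste("SRS10___water___Oslo, Norway___{a, b, c, d, e}",  # 4 fields
               "here is your answer:",                            # chatter
               "not-an-id___soil___NA___{a, b, c, d, e}___field", # bad id
               sep = "\n")
  res <- parse_inline(raw, expected_ids = "SRS10")
  expect_equal(nrow(res$annotations), 0)
  expect_equal(res$report$missing_ids, "SRS10")
  expect_setequal(res$report$malformed_lines$reason,
                  c("field_count", "bad_id"))
})

test_that("duplicates keep the first occurrence; unexpected IDs are reported", {
  raw <- paste("SRS20___soil___NA___{a, b, c, d, e}___field",
               "SRS20___water___NA___{a, b, c, d, e}___lake",
               "SRS99___soil___NA___{a, b, c, d, e}___field",
               sep = "\n")
  res <- parse_inline(raw, expected_ids = "SRS20")
  expect_equal(res$annotations$biome_raw, "soil")
  expect_equal(res$report$duplicate_ids, "SRS20")
  expect_equal(res$report$unexpected_ids, "SRS99")
})

test_that("keyword-count and sub-biome-length violations flag but keep the row", {
  raw <- paste("SRS30___soil___NA___{a, b}___field",
               "SRS31___soil___NA___{a, b, c, d, e}___a very long sub biome phrase",
               sep = "\n")
  res <- parse_inline(raw, expected_ids = c("SRS30", "SRS31"))
  expect_equal(nrow(res$annotations), 2)
  expect_true(all(res$annotations$flagged))
})

test_that("JSON responses parse with key aliases and keyword normalisation", {
  raw <- jsonlite::toJSON(list(
    list(id = "SRS40", biome = "water", location = "Oslo, Norway",
         keywords = "lake, fjord, cold, nordic, water", `sub-biome` = "lake"),
    list(sample_id = "SRS41", category = "soil", geo = "NA",
         keywords = list("a", "b", "c", "d", "e"), sub_biome = "forest soil")
  ), auto_unbox = TRUE)
  res <- parse_json(raw, expected_ids = c("SRS40", "SRS41"))
  expect_equal(nrow(res$annotations), 2)
  expect_equal(res$annotations$keywords[1], "lake|fjord|cold|nordic|water")
  expect_equal(res$annotations$biome_raw[2], "soil")
  expect_equal(res$annotations$location[2], NA_character_)
  # single object (not array) is accepted
  single <- parse_json('{"id": "SRS42", "biome": "soil", "keywords": ["a","b","c","d","e"], "sub_biome": "x"}',
                       "SRS42")
  expect_equal(single$annotations$sample_id, "SRS42")
})

test_that("invalid JSON marks everything missing without raising", {
  res <- parse_json('{"truncated": [', expected_ids = c("SRS50", "SRS51"))
  expect_equal(nrow(res$annotations), 0)
  expect_setequal(res$report$missing_ids, c("SRS50", "SRS51"))
  expect_equal(res$report$malformed_lines$reason, "invalid_json")
  # parser never raises on arbitrary bytes
  expect_silent(parse_inline(rawToChar(as.raw(c(65, 10, 95, 95, 95))), "SRS1"))
})

test_that("mock emissions round-trip through both parsers", {
  bm <- tiny_benchmark(3, seed = 17)
  for (fmt in c("inline", "json")) {
    ma <- mock_annotate(bm$records, bm$gold, seed = 4, format = fmt)
    parser <- if (fmt == "inline") parse_inline else parse_json
    merged <- if (fmt == "inline") paste(ma$responses, collapse = "\n") else
      paste0("[", paste(gsub("^\\[|\\]$", "", ma$responses), collapse = ","), "]")
    res <- parser(merged, bm$gold$sample_id)
    expect_setequal(res$annotations$sample_id, bm$gold$sample_id)
    expect_equal(res$annotations$biome_raw[match(bm$gold$sample_id,
                                                 res$annotations$sample_id)],
                 bm$gold$biome)
    expect_equal(res$annotations$sub_biome[match(bm$gold$sample_id,
                                                 res$annotations$sample_id)],
                 bm$gold$sub_biome)
    expect_length(res$report$missing_ids, 0)
  }
})

test_that("label normalisation lowercases, trims, collapses, keeps parentheticals", {
  expect_equal(normalize_label("Animal "), "animal")
  expect_equal(normalize_label("animal (incl. human)"), "animal (incl. human)")
  expect_equal(normalize_label("  soil\tsample"), "soil sample")
})

test_that("annotation CSV carries the status column", {
  bm <- tiny_benchmark(1, seed = 23)
  ma <- mock_annotate(bm$records, bm$gold, seed = 2)
  res <- parse_inline(paste(ma$responses, collapse = "\n"), bm$gold$sample_id)
  res$annotations$status <- "ok"
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(res$annotations, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("sample_id", "biome", "location", "keywords", "sub_biome", "status"))
  expect_equal(nrow(back), 5)
})
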