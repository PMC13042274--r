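# Benchmark generator, mock annotation behaviour, coordinate-error injection.

test_that("the generator yields the requested shape with balanced biomes", {
  bm <- generate_benchmark(3, seed = 1)
  expect_length(bm$records, 15)
  expect_equal(unname(table(bm$gold$biome)[biome_levels()]),
               rep(3L, 5), ignore_attr = TRUE)
  expect_true(all(grepl("^SYN[0-9]{6}$", bm$gold$sample_id)))
  expect_false(any(duplicated(bm$gold$sample_id)))
  expect_true(all(nzchar(bm$gold$sub_biome)))
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_benchmark(4, seed = 123,
                          noise = noise_profile(placeholder_rate = 0.3,
                                                ontology_code_rate = 0.3))
  b <- generate_benchmark(4, seed = 123,
                          noise = noise_profile(placeholder_rate = 0.3,
                                                ontology_code_rate = 0.3))
  expect_identical(vapply(a$records, serialize_for_prompt, ""),
                   vapply(b$records, serialize_for_prompt, ""))
  expect_identical(a$gold, b$gold)
  c <- generate_benchmark(4, seed = 124)
  expect_false(identical(vapply(a$records, serialize_for_prompt, ""),
                         vapply(c$records, serialize_for_prompt, "")))
})

test_that("zero-noise output reloads through metadata_io without warnings", {
  bm <- generate_benchmark(2, seed = 7, noise = noise_profile())
  path <- withr::local_tempfile(fileext = ".txt")
  write_records(bm$records, path)
  back <- load_records(path)
  expect_length(attr(back, "warnings"), 0)
  expect_length(back, length(bm$records))
  # and cleaning removes nothing
  logs <- lapply(back, function(r) clean_record(r)$log)
  expect_true(all(vapply(logs, nrow, 1L) == 0))
})

test_that("placeholder noise is injected at roughly the requested rate", {
  bm <- generate_benchmark(100, seed = 13,
                           noise = noise_profile(placeholder_rate = 0.3))
  hit <- vapply(bm$records, function(r) nrow(clean_record(r)$log) > 0, logical(1))
  se <- sqrt(0.3 * 0.7 / 500)
  expect_lt(abs(mean(hit) - 0.3), 3 * se)
})

test_that("rhizosphere templates carry plant gold and sediment templates water", {
  bm <- generate_benchmark(60, seed = 17)
  rhizo <- grepl("rhizosphere", bm$gold$sub_biome)
  expect_true(any(rhizo))
  expect_true(all(bm$gold$biome[rhizo] == "plant"))
  sedi <- grepl("sediment", bm$gold$sub_biome)
  expect_true(any(sedi))
  expect_true(all(bm$gold$biome[sedi] == "water"))
})

test_that("identity confusion and zero noise give 100% downstream accuracy", {
  bm <- tiny_benchmark(4, seed = 19)
  ma <- mock_annotate(bm$records, bm$gold, confusion = confusion_spec(1), seed = 1)
  res <- parse_inline(paste(ma$responses, collapse = "\n"), bm$gold$sample_id)
  met <- compute_metrics(res$annotations, bm$gold, "lenient")
  expect_equal(met$accuracy, 1)
})

test_that("a designed diagonal of 0.806 is recovered within 3 standard errors", {
  bm <- generate_benchmark(200, seed = 29)
  ma <- mock_annotate(bm$records, bm$gold, confusion = confusion_spec(0.806),
                      seed = 31)
  res <- parse_inline(paste(ma$responses, collapse = "\n"), bm$gold$sample_id)
  acc <- compute_metrics(res$annotations, bm$gold, "lenient")$accuracy
  se <- sqrt(0.806 * 0.194 / 1000)
  expect_lt(abs(acc - 0.806), 3 * se)
})

test_that("omission and malformation rates are honoured within 3 SE", {
  bm <- generate_benchmark(100, seed = 37)  # 500 samples
  ma <- mock_annotate(bm$records, bm$gold, seed = 41,
                      noise = noise_profile(omission_rate = 0.1))
  res <- parse_inline(paste(ma$responses, collapse = "\n"), bm$gold$sample_id)
  miss_rate <- length(res$report$missing_ids) / nrow(bm$gold)
  se <- sqrt(0.1 * 0.9 / 500)
  expect_lt(abs(miss_rate - 0.1), 3 * se)
})

test_that("confusion specs are row-stochastic and validated", {
  cs <- confusion_spec(0.8)
  expect_equal(unname(rowSums(cs)), rep(1, 5))
  expect_equal(unname(diag(cs)), rep(0.8, 5))
  bad <- matrix(0.3, 5, 5, dimnames = list(biome_levels(), biome_levels()))
  expect_error(mock_backend(data.frame(sample_id = "SYN000001", biome = "soil",
                                       sub_biome = "x"), confusion = bad))
})

test_that("coordinate-error injection logs exactly one mode per sample", {
  bm <- generate_benchmark(60, seed = 43)
  rates <- list(latlon_swapped = 0.1, lon_sign_flip = 0.1, lat_sign_flip = 0.1,
                relocate = 0.05, institution = 0.05)
  inj <- inject_coordinate_errors(bm$records, bm$gold, rates, seed = 47)
  expect_equal(nrow(inj$truth), length(bm$records))
  # swap mode stores the raw reversed pair
  sw <- inj$truth[inj$truth$mode == "latlon_swapped", ][1, ]
  expect_equal(sw$stored_lat, sw$true_lon)
  expect_equal(sw$stored_lon, sw$true_lat)
  rec <- inj$records[[match(sw$sample_id, bm$gold$sample_id)]]
  expect_equal(unname(rec$fields[["lat_lon"]]),
               sprintf("%.4f %.4f", sw$true_lon, sw$true_lat))
  # untouched samples keep their coordinates
  none <- inj$truth[inj$truth$mode == "none", ][1, ]
  rec0 <- inj$records[[match(none$sample_id, bm$gold$sample_id)]]
  expect_equal(unname(rec0$fields[["lat_lon"]]),
               sprintf("%.4f %.4f", none$true_lat, none$true_lon))
  # mode frequencies track the requested rates within 3 SE (n = 300)
  for (m in names(rates)) {
    p <- rates[[m]]
    obs <- mean(inj$truth$mode == m)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / nrow(inj$truth)) + 0.02)
  }
})

test_that("fixture bundles land on disk as plain text", {
  bm <- tiny_benchmark(2, seed = 53)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(bm$records, bm$gold, dir,
                                noise = noise_profile())
  expect_true(all(file.exists(paths)))
  gold <- utils::read.csv(paths[["gold"]])
  expect_equal(names(gold), c("sample_id", "biome", "sub_biome"))
  expect_equal(nrow(gold), 10)
})
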