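# Prompt templates, submission modes, filename round-trip, retry contract.

test_that("prompt variants contain their defining instructions", {
  std <- build_system_prompt("standard_inline")
  expect_true(grepl("Extract strictly 5–8 keywords", std))
  expect_true(grepl('separate all values with 3 underscores', std))
  expect_true(grepl("SRS123456___animal___Los Angeles, USA___", std, fixed = TRUE))

  better <- build_system_prompt("better_inline")
  added <- sub(std, "", better, fixed = TRUE)
  expect_equal(trimws(added),
               "Please note that rhizosphere samples should be categorized as 'plant' and sediment samples as 'water'.")

  js <- build_system_prompt("json")
  expect_true(grepl("JSON", js))
  expect_error(build_system_prompt("fancy"))
  expect_identical(std, build_system_prompt("standard_inline"))  # byte-stable
})

test_that("sync submission sends one request per chunk and retries transport", {
  bm <- tiny_benchmark(2, seed = 31)
  backend <- mock_backend(bm$gold, seed = 1)
  cfg <- request_config(chunksize = 4000)
  prompt <- build_system_prompt("standard_inline")
  chunks <- chunk_records(bm$records, cfg, prompt)
  sub <- submit_sync(chunks, bm$records, cfg, backend, prompt)
  expect_equal(sub$request_count, length(chunks))
  expect_length(sub$responses, length(chunks))

  # chunking disabled: n samples -> n requests
  cfg1 <- request_config(chunking = FALSE)
  chunks1 <- chunk_records(bm$records, cfg1, prompt)
  expect_length(chunks1, length(bm$records))

  # empty chunk list -> zero calls
  empty <- submit_sync(list(), bm$records, cfg, backend, prompt)
  expect_equal(empty$request_count, 0)

  # a flaky backend that fails twice then succeeds is absorbed by transport retry
  calls <- 0L
  flaky <- llm_backend(complete = function(sp, pl, cf) {
    calls <<- calls + 1L
    if (calls < 3L) stop("boom")
    backend$complete(sp, pl, cf)
  })
  sub2 <- submit_sync(chunks[1], bm$records, cfg, flaky, prompt)
  expect_false(is.na(sub2$responses[1]))
  expect_equal(calls, 3L)
})

test_that("async mode is never chunked: one request per sample", {
  bm <- tiny_benchmark(2, seed = 37)
  backend <- mock_backend(bm$gold, seed = 1, format = "json")
  cfg <- request_config(mode = "async", chunking = TRUE)  # forced off
  expect_false(cfg$chunking)
  sub <- submit_async(bm$records, cfg, backend, build_system_prompt("json"))
  expect_equal(sub$request_count, length(bm$records))
  expect_length(sub$responses, length(bm$records))
  expect_match(sub$batch_id, "batch")
})

test_that("omitted IDs are recovered by retry; permanent omissions are reported", {
  bm <- generate_benchmark(20, seed = 43)  # 100 samples
  backend <- mock_backend(bm$gold, seed = 9, omission_rate = 0.1)
  cfg <- request_config(chunksize = 3000, max_retries = 2)
  res <- annotate_records(bm$records, cfg, backend)
  expect_equal(sum(res$annotations$status == "unresolved"), 0)
  expect_setequal(res$annotations$sample_id, bm$gold$sample_id)
  expect_lte(res$backend_calls,
             res$request_count + cfg$max_retries * length(bm$records))

  # a backend that never answers one ID reports exactly that ID unresolved
  drop_id <- bm$gold$sample_id[7]
  stubborn <- mock_backend(bm$gold, seed = 9, permanent_omit_ids = drop_id)
  res2 <- annotate_records(bm$records, cfg, stubborn)
  expect_equal(res2$annotations$sample_id[res2$annotations$status == "unresolved"],
               drop_id)
  expect_equal(res2$retries_used, 2L)
})

test_that("all-parsed first pass triggers zero retry calls", {
  bm <- tiny_benchmark(2, seed = 47)
  backend <- mock_backend(bm$gold, seed = 2)
  res <- annotate_records(bm$records, request_config(), backend)
  expect_equal(res$retry_calls, 0L)
  expect_true(all(res$annotations$status == "ok"))
})

test_that("malformed lines are retried like omissions", {
  bm <- generate_benchmark(10, seed = 53)
  backend <- mock_backend(bm$gold, seed = 3, malformation_rate = 0.2)
  res <- annotate_records(bm$records, request_config(max_retries = 2), backend)
  expect_equal(sum(res$annotations$status == "unresolved"), 0)
  expect_setequal(res$annotations$sample_id, bm$gold$sample_id)
})

test_that("the pipeline is bit-reproducible under the mock backend", {
  run_once <- function() {
    bm <- generate_benchmark(5, seed = 59)
    backend <- mock_backend(bm$gold, seed = 6, omission_rate = 0.1,
                            confusion = confusion_spec(0.9))
    annotate_records(bm$records, request_config(max_retries = 2), backend)$annotations
  }
  expect_identical(run_once(), run_once())
})

test_that("output filenames embed all parameters and round-trip", {
  cfg <- request_config(model = "gpt-3.5-turbo-0125", maxtokens = 512,
                        temp = 0.7, topp = 0.9, freqp = 0.5, presp = -0.5,
                        chunking = TRUE, chunksize = 2000, nspb = 100,
                        rs = 7, opt_text = "pilot-run")
  fn <- output_filename(cfg, timestamp = "20260101T120000", request_count = 12)
  parsed <- parse_output_filename(fn)
  expect_equal(parsed$config[names(parsed$config) != "max_retries"],
               cfg[names(cfg) != "max_retries"])
  expect_equal(parsed$request_count, 12L)
  refn <- output_filename(parsed$config, timestamp = parsed$timestamp,
                          request_count = parsed$request_count)
  expect_identical(refn, fn)

  # async filenames carry the batch designation
  acfg <- request_config(mode = "async")
  afn <- output_filename(acfg, timestamp = "20260101T120000", batch_id = "abc123")
  expect_match(afn, "batch")
  expect_equal(parse_output_filename(afn)$batch_id, "abc123")

  # differing seeds yield distinct filenames
  cfg2 <- request_config(rs = 8)
  expect_false(output_filename(request_config(rs = 7), "20260101T120000", 1) ==
                 output_filename(cfg2, "20260101T120000", 1))
})
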