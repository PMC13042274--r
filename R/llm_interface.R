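# Request configuration, submission, ID reconciliation and retry.

#' Build a request configuration
#'
#' Carries the run parameters that are also embedded in the output filename:
#' samples per biome (`nspb`), random seed (`rs`), chunking switch and chunk
#' size in tokens (total per request, system prompt included), model name,
#' completion token cap, and the four decoding ("creativity") parameters.
#' Defaults are the baseline settings used before any perturbation:
#' temperature 1, nucleus sampling 1, frequency and presence penalty 0.
#' Asynchronous mode never chunks, so `mode = "async"` forces
#' `chunking = FALSE`.
#'
#' @param model Model name string.
#' @param maxtokens Maximum completion tokens.
#' @param temp,topp Temperature in `[0, 2]` and nucleus-sampling mass in
#'   `[0, 1]`.
#' @param freqp,presp Frequency and presence penalties in `[-2, 2]`.
#' @param chunking Whether to pack several samples into one request.
#' @param chunksize Token budget per request (prompt included).
#' @param nspb Samples per biome drawn from the benchmark.
#' @param rs Random seed recorded for reproducibility.
#' @param opt_text Optional free-text run tag (sanitised to
#'   `[A-Za-z0-9.-]` in filenames).
#' @param mode `"sync"` or `"async"`.
#' @param max_retries Parse-level retries for missing or malformed IDs.
#' @return Object of class `request_config`.
#' @export
request_config <- function(model = "gpt-3.5-turbo-0125", maxtokens = 1024L,
                           temp = 1, topp = 1, freqp = 0, presp = 0,
                           chunking = TRUE, chunksize = 3000L,
                           nspb = 200L, rs = 42L, opt_text = "",
                           mode = c("sync", "async"), max_retries = 2L) {
  mode <- match.arg(mode)
  stopifnot(temp >= 0, temp <= 2, topp >= 0, topp <= 1,
            freqp >= -2, freqp <= 2, presp >= -2, presp <= 2,
            maxtokens > 0, chunksize > 0, nspb >= 1, max_retries >= 0)
  if (mode == "async") chunking <- FALSE
  structure(list(model = model, maxtokens = as.integer(maxtokens),
                 temp = temp, topp = topp, freqp = freqp, presp = presp,
                 chunking = isTRUE(chunking), chunksize = as.integer(chunksize),
                 nspb = as.integer(nspb), rs = as.integer(rs),
                 opt_text = as.character(opt_text), mode = mode,
                 max_retries = as.integer(max_retries)),
            class = "request_config")
}

sanitize_token <- function(x) gsub("[^A-Za-z0-9.-]", "-", x)

#' Render the run output filename
#'
#' The filename embeds every run parameter plus either the request count
#' (synchronous) or the word "batch" and the batch id (asynchronous), and a
#' timestamp, so a results file is self-describing and parseable back into
#' its [request_config()].
#'
#' @param config A `request_config`.
#' @param timestamp `POSIXct` or a preformatted `%Y%m%dT%H%M%S` string.
#' @param request_count Number of API requests (sync mode).
#' @param batch_id Opaque batch identifier (async mode).
#' @return Filename string ending in `.out.txt`.
#' @seealso [parse_output_filename()]
#' @export
output_filename <- function(config, timestamp = Sys.time(),
                            request_count = NULL, batch_id = NULL) {
  stopifnot(inherits(config, "request_config"))
  ts <- if (inherits(timestamp, "POSIXt")) format(timestamp, "%Y%m%dT%H%M%S") else timestamp
  tail_part <- if (config$mode == "async") {
    if (is.null(batch_id)) stop("async filenames need a batch_id")
    paste0("batch=", sanitize_token(batch_id))
  } else {
    if (is.null(request_count)) stop("sync filenames need a request_count")
    paste0("req=", request_count)
  }
  paste0(paste(
    paste0("nspb=", config$nspb),
    paste0("rs=", config$rs),
    paste0("chunking=", if (config$chunking) "T" else "F"),
    paste0("chunksize=", config$chunksize),
    paste0("model=", sanitize_token(config$model)),
    paste0("maxtokens=", config$maxtokens),
    paste0("temp=", format(config$temp)),
    paste0("topp=", format(config$topp)),
    paste0("freqp=", format(config$freqp)),
    paste0("presp=", format(config$presp)),
    paste0("opt=", sanitize_token(config$opt_text)),
    tail_part,
    paste0("ts=", ts),
    sep = "_"), ".out.txt")
}

#' Parse a run output filename back into its configuration
#'
#' @param filename A name produced by [output_filename()].
#' @return List with `config` (a `request_config`), `timestamp` string, and
#'   `request_count` or `batch_id`.
#' @export
parse_output_filename <- function(filename) {
  base <- sub("\\.out\\.txt$", "", basename(filename))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
  g <- function(k) vals[match(k, keys)]
  mode <- if ("batch" %in% keys) "async" else "sync"
  cfg <- request_config(
    model = g("model"), maxtokens = as.integer(g("maxtokens")),
    temp = as.numeric(g("temp")), topp = as.numeric(g("topp")),
    freqp = as.numeric(g("freqp")), presp = as.numeric(g("presp")),
    chunking = g("chunking") == "T", chunksize = as.integer(g("chunksize")),
    nspb = as.integer(g("nspb")), rs = as.integer(g("rs")),
    opt_text = g("opt"), mode = mode
  )
  out <- list(config = cfg, timestamp = unname(g("ts")))
  if (mode == "async") out$batch_id <- unname(g("batch")) else
    out$request_count <- as.integer(g("req"))
  out
}

records_by_id <- function(records) {
  stats::setNames(records, vapply(records, `[[`, "", "sample_id"))
}

#' Pack records into request chunks per the configuration
#'
#' With chunking enabled, serialized records are packed first-fit decreasing
#' under `chunksize` minus the measured system-prompt token count; with
#' chunking disabled every sample is its own request.
#'
#' @param records List of [metadata_record].
#' @param config A `request_config`.
#' @param system_prompt The system prompt (its token count is part of the
#'   budget).
#' @param tokenizer Optional tokenizer override for [count_tokens()].
#' @return List of chunks as from [pack_ffd()].
#' @export
chunk_records <- function(records, config, system_prompt, tokenizer = NULL) {
  ids <- vapply(records, `[[`, "", "sample_id")
  if (!config$chunking) {
    return(lapply(seq_along(records), function(i) {
      tok <- count_tokens(serialize_for_prompt(records[[i]]), tokenizer)
      list(members = ids[i], payload_tokens = tok,
           capacity = config$chunksize, oversize_flag = FALSE)
    }))
  }
  toks <- count_tokens(vapply(records, serialize_for_prompt, ""), tokenizer)
  prompt_tokens <- count_tokens(system_prompt, tokenizer)
  pack_ffd(data.frame(sample_id = ids, token_count = toks,
                      stringsAsFactors = FALSE),
           capacity = config$chunksize, prompt_tokens = prompt_tokens)
}

transport_call <- function(backend, system_prompt, payload, config,
                           attempts = 3L, backoff = 0.05) {
  for (k in seq_len(attempts)) {
    res <- tryCatch(backend$complete(system_prompt, payload, config),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (k < attempts) Sys.sleep(backoff * 2^(k - 1L))
  }
  structure(NA_character_, failed = TRUE, message = conditionMessage(res))
}

#' Submit chunks synchronously
#'
#' One backend call per chunk; the payload is the concatenation of the
#' chunk members' serialized records. Transport failures are retried 3
#' times with exponential backoff, then recorded as failed chunks (response
#' `NA`), never raised.
#'
#' @param chunks List of chunks (see [chunk_records()]).
#' @param records List of [metadata_record] covering all chunk members.
#' @param config A `request_config` with `mode = "sync"`.
#' @param backend An `llm_backend`.
#' @param system_prompt System prompt string.
#' @return List with `responses` (character, one per chunk, `NA` on
#'   transport failure) and `request_count`.
#' @export
submit_sync <- function(chunks, records, config, backend, system_prompt) {
  stopifnot(config$mode == "sync")
  index <- records_by_id(records)
  responses <- character(length(chunks))
  for (i in seq_along(chunks)) {
    payload <- paste(vapply(index[chunks[[i]]$members], serialize_for_prompt, ""),
                     collapse = "\n\n")
    responses[i] <- transport_call(backend, system_prompt, payload, config)
  }
  list(responses = responses, request_count = length(chunks))
}

#' Submit records asynchronously (batch mode)
#'
#' Asynchronous requests are never chunked: exactly one request per sample
#' is placed in the batch. The backend's `submit_batch`/`fetch_batch` pair
#' mirrors a submit-then-poll API with an opaque batch id.
#'
#' @inheritParams submit_sync
#' @return List with `responses` (one per record), `batch_id`, and
#'   `request_count` (= number of records).
#' @export
submit_async <- function(records, config, backend, system_prompt) {
  stopifnot(config$mode == "async")
  requests <- lapply(records, function(r) {
    list(system_prompt = system_prompt, payload = serialize_for_prompt(r))
  })
  bid <- backend$submit_batch(requests)
  resp <- backend$fetch_batch(bid)
  list(responses = vapply(resp, identity, ""), batch_id = bid,
       request_count = length(records))
}

#' Reconcile parsed IDs against expectations and retry failures
#'
#' IDs missing from the parsed output, or whose lines failed parsing, are
#' re-requested individually (never chunked, regardless of the original
#' run) up to `config$max_retries` times. IDs still unresolved afterwards
#' are reported with `status = "unresolved"`, never silently dropped.
#'
#' @param annotations Annotation data.frame from the first parse.
#' @param report Parse report from the first parse.
#' @param records List of [metadata_record] (used to rebuild payloads).
#' @param config A `request_config`.
#' @param backend An `llm_backend`.
#' @param system_prompt System prompt string.
#' @param parser `"inline"` or `"json"` - which dialect to parse retries
#'   with.
#' @return List with `annotations` (every expected ID present, `status` in
#'   ok/flagged/unresolved), `report`, `retry_calls` (number of retry
#'   requests sent), `retries_used`.
#' @export
reconcile_and_retry <- function(annotations, report, records, config, backend,
                                system_prompt, parser = c("inline", "json")) {
  parser <- match.arg(parser)
  parse_fun <- if (parser == "inline") parse_inline else parse_json
  index <- records_by_id(records)
  expected <- names(index)
  retry_calls <- 0L
  retries_used <- 0L

  pending <- setdiff(expected, annotations$sample_id)
  while (length(pending) && retries_used < config$max_retries) {
    retries_used <- retries_used + 1L
    got <- list()
    for (id in pending) {
      payload <- serialize_for_prompt(index[[id]])
      raw <- transport_call(backend, system_prompt, payload, config)
      retry_calls <- retry_calls + 1L
      if (is.na(raw)) next
      res <- parse_fun(raw, expected_ids = id)
      if (nrow(res$annotations)) got[[length(got) + 1L]] <- res$annotations
    }
    if (length(got)) {
      annotations <- rbind(annotations, do.call(rbind, got))
      annotations <- annotations[!duplicated(annotations$sample_id), , drop = FALSE]
    }
    pending <- setdiff(expected, annotations$sample_id)
  }

  annotations$status <- ifelse(annotations$flagged, "flagged", "ok")
  if (length(pending)) {
    unresolved <- data.frame(sample_id = pending, biome_raw = NA_character_,
                             location = NA_character_, keywords = NA_character_,
                             sub_biome = NA_character_, flagged = FALSE,
                             status = "unresolved", stringsAsFactors = FALSE)
    annotations <- rbind(annotations, unresolved)
  }
  annotations <- annotations[match(expected, annotations$sample_id), , drop = FALSE]
  rownames(annotations) <- NULL
  report$missing_ids <- pending
  report$parsed_ids <- setdiff(expected, pending)
  list(annotations = annotations, report = report,
       retry_calls = retry_calls, retries_used = retries_used)
}

#' Run the full annotation round-trip for a record set
#'
#' Convenience wrapper: chunk (sync) or batch (async), submit, parse every
#' response, then [reconcile_and_retry()].
#'
#' @param records List of [metadata_record].
#' @param config A `request_config`.
#' @param backend An `llm_backend`.
#' @param variant Prompt variant for [build_system_prompt()]; the `json`
#'   variant implies the JSON parser.
#' @return As [reconcile_and_retry()], plus `request_count` and
#'   `backend_calls` (initial requests + retry calls).
#' @export
annotate_records <- function(records, config, backend,
                             variant = c("standard_inline", "better_inline", "json")) {
  variant <- match.arg(variant)
  parser <- if (variant == "json") "json" else "inline"
  system_prompt <- build_system_prompt(variant)
  expected <- vapply(records, `[[`, "", "sample_id")

  if (config$mode == "sync") {
    chunks <- chunk_records(records, config, system_prompt)
    sub <- submit_sync(chunks, records, config, backend, system_prompt)
    chunk_ids <- lapply(chunks, `[[`, "members")
  } else {
    sub <- submit_async(records, config, backend, system_prompt)
    chunk_ids <- as.list(expected)
  }

  parse_fun <- if (parser == "inline") parse_inline else parse_json
  ann_list <- list(); reports <- list()
  for (i in seq_along(sub$responses)) {
    raw <- sub$responses[i]
    if (is.na(raw)) {
      reports[[i]] <- empty_parse_report(chunk_ids[[i]])
      next
    }
    res <- parse_fun(raw, expected_ids = chunk_ids[[i]])
    ann_list[[length(ann_list) + 1L]] <- res$annotations
    reports[[i]] <- res$report
  }
  annotations <- if (length(ann_list)) do.call(rbind, ann_list) else
    empty_annotations()
  annotations <- annotations[!duplicated(annotations$sample_id), , drop = FALSE]
  report <- merge_parse_reports(reports, expected)

  out <- reconcile_and_retry(annotations, report, records, config, backend,
                             system_prompt, parser = parser)
  out$request_count <- sub$request_count
  out$backend_calls <- sub$request_count + out$retry_calls
  if (config$mode == "async") out$batch_id <- sub$batch_id
  out
}
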