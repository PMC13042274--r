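# LLM backend contract and the deterministic offline mock.

#' The five operational biome labels
#'
#' Broad sample-origin classes used throughout: animal, plant, water, soil,
#' other. These are controlled labels for source context, not ecological or
#' ENVO biomes.
#'
#' @return Character vector of the five labels, in canonical order.
#' @export
biome_levels <- function() c("animal", "plant", "water", "soil", "other")

# deterministic 31-bit seed derived from a string plus a base seed
str_seed <- function(s, seed, salt = 0L) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  as.integer((h + as.numeric(seed) * 7919 + salt * 104729) %% 2147483629)
}

# evaluate code under a temporary RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# small per-biome keyword bank shared by the mock backend and the generator
biome_keyword_bank <- list(
  animal = c("host", "gut", "feces", "mucosa", "mammal", "tissue", "skin", "rumen"),
  plant  = c("leaf", "root", "rhizosphere", "crop", "phyllosphere", "seed", "tree", "stem"),
  water  = c("lake", "river", "marine", "sediment", "estuary", "freshwater", "plankton", "brine"),
  soil   = c("topsoil", "agricultural", "forest", "loam", "tundra", "peatland", "arid", "grassland"),
  other  = c("bioreactor", "laboratory", "urban", "air", "food", "fungus", "sludge", "indoor")
)

extract_payload_ids <- function(payload) {
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines[grepl(accession_regex, lines)]
}

#' Construct an LLM backend object
#'
#' A backend is the pluggable transport contract: `complete(system_prompt,
#' payload, config)` returns raw response text; `submit_batch(requests)`
#' returns an opaque batch id; `fetch_batch(batch_id)` returns the raw texts.
#'
#' @param complete Function `(system_prompt, payload, config) -> character`.
#' @param submit_batch Function `(requests) -> batch_id`; `requests` is a
#'   list of `list(system_prompt=, payload=)`.
#' @param fetch_batch Function `(batch_id) -> list of character`.
#' @param name Backend name for manifests and filenames.
#' @return Object of class `llm_backend`.
#' @export
llm_backend <- function(complete, submit_batch = NULL, fetch_batch = NULL,
                        name = "custom") {
  structure(list(complete = complete, submit_batch = submit_batch,
                 fetch_batch = fetch_batch, name = name),
            class = "llm_backend")
}

#' Deterministic mock LLM backend
#'
#' Generates well-formed inline or JSON responses from a gold-label table,
#' with a configurable biome confusion matrix, ID omission rate, and line
#' malformation rate. Fully deterministic: each sample's behaviour is keyed
#' by a 31-bit seed derived from `(seed, sample_id)`, so a given benchmark
#' and seed always yield byte-identical responses. Omission and malformation
#' are by default "first request only" (the sample is answered correctly
#' when re-requested), which exercises the retry path; IDs listed in
#' `permanent_omit_ids` are never answered.
#'
#' @param gold data.frame with columns `sample_id`, `biome`, `sub_biome`,
#'   and optionally `location`.
#' @param seed Integer seed.
#' @param confusion Optional 5x5 row-stochastic matrix (rows and columns
#'   named by [biome_levels()]): probability that a gold-`b` sample is
#'   annotated as biome `b'`. `NULL` means the identity (perfect) matrix.
#' @param omission_rate Probability that a sample's line is missing from the
#'   response the first time it is requested.
#' @param malformation_rate Probability that a sample's first response line
#'   has only 4 fields (sub-biome dropped), failing the parser.
#' @param format `"inline"` or `"json"`.
#' @param omit_once If `TRUE` (default) omission/malformation apply only to
#'   the first request for an ID; retries succeed.
#' @param permanent_omit_ids IDs the mock never returns.
#' @param paraphrase_rate Probability that the sub-biome is a light
#'   paraphrase of the gold sub-biome rather than verbatim.
#' @return An `llm_backend`.
#' @export
mock_backend <- function(gold, seed = 1L, confusion = NULL,
                         omission_rate = 0, malformation_rate = 0,
                         format = c("inline", "json"), omit_once = TRUE,
                         permanent_omit_ids = character(),
                         paraphrase_rate = 0) {
  format <- match.arg(format)
  stopifnot(all(c("sample_id", "biome", "sub_biome") %in% names(gold)))
  if (is.null(confusion)) {
    confusion <- diag(5)
    dimnames(confusion) <- list(biome_levels(), biome_levels())
  }
  stopifnot(all(abs(rowSums(confusion) - 1) < 1e-9))
  gold_ix <- stats::setNames(seq_len(nrow(gold)), gold$sample_id)
  state <- new.env(parent = emptyenv())
  state$omitted <- character()
  state$malformed <- character()
  state$batches <- list()

  annotate_one <- function(id) {
    row <- gold[gold_ix[[id]], ]
    biome <- local_seed(str_seed(id, seed, 13L), {
      sample(colnames(confusion), 1L, prob = confusion[row$biome, ])
    })
    sub <- row$sub_biome
    if (paraphrase_rate > 0 &&
        local_seed(str_seed(id, seed, 17L), stats::runif(1)) < paraphrase_rate) {
      sub <- paste(sub, "environment")
    }
    loc <- if ("location" %in% names(gold) && !is.na(row$location)) row$location else "NA"
    kw <- local_seed(str_seed(id, seed, 19L), {
      n <- sample(5:8, 1L)
      sample(biome_keyword_bank[[row$biome]], n)
    })
    list(sample_id = id, biome = biome, location = loc, keywords = kw, sub_biome = sub)
  }

  respond <- function(payload) {
    ids <- extract_payload_ids(payload)
    ids <- ids[ids %in% names(gold_ix)]
    out_inline <- character()
    out_json <- list()
    for (id in ids) {
      if (id %in% permanent_omit_ids) next
      u <- local_seed(str_seed(id, seed, 23L), stats::runif(1))
      if (u < omission_rate && !(omit_once && id %in% state$omitted)) {
        state$omitted <- c(state$omitted, id)
        next
      }
      ann <- annotate_one(id)
      v <- local_seed(str_seed(id, seed, 29L), stats::runif(1))
      malform <- v < malformation_rate && !(omit_once && id %in% state$malformed)
      if (malform) state$malformed <- c(state$malformed, id)
      if (format == "inline") {
        line <- if (malform) {
          paste(ann$sample_id, ann$biome, ann$location, sep = "___")
        } else {
          paste(ann$sample_id, ann$biome, ann$location,
                paste0("{", paste(ann$keywords, collapse = ", "), "}"),
                ann$sub_biome, sep = "___")
        }
        out_inline <- c(out_inline, line)
      } else {
        obj <- list(sample_id = ann$sample_id, biome = ann$biome,
                    location = ann$location, keywords = ann$keywords,
                    sub_biome = ann$sub_biome)
        if (malform) obj$sample_id <- NULL
        out_json[[length(out_json) + 1L]] <- obj
      }
    }
    if (format == "inline") {
      paste(out_inline, collapse = "\n")
    } else {
      as.character(jsonlite::toJSON(out_json, auto_unbox = TRUE))
    }
  }

  llm_backend(
    complete = function(system_prompt, payload, config = NULL) respond(payload),
    submit_batch = function(requests) {
      bid <- sprintf("mockbatch%06d", length(state$batches) + 1L)
      state$batches[[bid]] <- requests
      bid
    },
    fetch_batch = function(batch_id) {
      reqs <- state$batches[[batch_id]]
      if (is.null(reqs)) stop("unknown batch id: ", batch_id)
      lapply(reqs, function(r) respond(r$payload))
    },
    name = "mock"
  )
}

#' OpenAI-compatible chat-completions HTTP backend
#'
#' Speaks the chat-completions dialect over HTTP via the system `curl`
#' binary. Requires network access and an API key in the environment
#' variable named by `api_key_env`; intended for production runs only (the
#' test suite uses [mock_backend()] exclusively).
#'
#' @param endpoint Chat-completions URL.
#' @param api_key_env Name of the environment variable holding the API key.
#' @param name Backend label.
#' @return An `llm_backend`.
#' @export
http_backend <- function(endpoint, api_key_env = "LLM_API_KEY", name = "http") {
  llm_backend(
    complete = function(system_prompt, payload, config = NULL) {
      key <- Sys.getenv(api_key_env)
      if (!nzchar(key)) stop("no API key in $", api_key_env)
      body <- jsonlite::toJSON(list(
        model = if (!is.null(config)) config$model else "gpt-3.5-turbo-0125",
        max_tokens = if (!is.null(config)) config$maxtokens else 1024L,
        temperature = if (!is.null(config)) config$temp else 1,
        top_p = if (!is.null(config)) config$topp else 1,
        frequency_penalty = if (!is.null(config)) config$freqp else 0,
        presence_penalty = if (!is.null(config)) config$presp else 0,
        messages = list(list(role = "system", content = system_prompt),
                        list(role = "user", content = payload))
      ), auto_unbox = TRUE)
      tmp <- tempfile(fileext = ".json"); writeLines(as.character(body), tmp)
      out <- system2("curl",
                     c("-sS", "-X", "POST", endpoint,
                       "-H", shQuote(paste0("Authorization: Bearer ", key)),
                       "-H", shQuote("Content-Type: application/json"),
                       "--data", paste0("@", tmp)),
                     stdout = TRUE)
      parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
      parsed$choices[[1]]$message$content
    },
    name = name
  )
}
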