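# Token counting and first-fit-decreasing packing of samples into requests.

#' Approximate token counter
#'
#' Default tokenizer contract: `ceiling(nchar(text) / 4)`, a standard
#' rule-of-thumb for byte-pair-encoding vocabularies on English text. Any
#' function `text -> integer` can be supplied wherever a tokenizer is
#' accepted, so a vendor-exact tokenizer can be plugged in.
#'
#' @param text Character vector.
#' @param tokenizer Optional replacement function; `NULL` uses the default
#'   approximation.
#' @return Integer vector of token counts; 0 only for empty text.
#' @export
count_tokens <- function(text, tokenizer = NULL) {
  if (!is.null(tokenizer)) {
    return(vapply(text, tokenizer, numeric(1), USE.NAMES = FALSE))
  }
  as.integer(ceiling(nchar(text, type = "chars") / 4))
}

#' Pack samples into token-budgeted chunks (first-fit decreasing)
#'
#' Sorts samples by token count in descending order (ties broken by
#' sample_id ascending, for full determinism) and places each into the first
#' existing chunk where it fits under `capacity - prompt_tokens`; otherwise a
#' new chunk is opened. A sample larger than the effective capacity becomes a
#' singleton chunk flagged oversize rather than an error, so no record is
#' ever dropped.
#'
#' @param samples data.frame with columns `sample_id` and `token_count`
#'   (positive integers).
#' @param capacity Total token budget per request, including the system
#'   prompt.
#' @param prompt_tokens Tokens consumed by the system prompt (measured once,
#'   with the same tokenizer as the samples).
#' @return List of chunks; each chunk is a list with `members` (sample_ids in
#'   insertion order), `payload_tokens`, `capacity`, `oversize_flag`.
#' @export
pack_ffd <- function(samples, capacity, prompt_tokens = 0L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "token_count") %in% names(samples)))
  if (capacity <= prompt_tokens) {
    stop("capacity (", capacity, ") must exceed prompt_tokens (", prompt_tokens, ")")
  }
  if (nrow(samples) == 0L) return(list())
  if (any(samples$token_count <= 0)) stop("token counts must be positive")
  eff <- capacity - prompt_tokens

  ord <- order(-samples$token_count, samples$sample_id)
  ids <- samples$sample_id[ord]
  sizes <- samples$token_count[ord]

  members <- list(); loads <- integer(); oversize <- logical()
  for (i in seq_along(ids)) {
    if (sizes[i] > eff) {
      members[[length(members) + 1L]] <- ids[i]
      loads <- c(loads, sizes[i]); oversize <- c(oversize, TRUE)
      next
    }
    placed <- FALSE
    for (b in seq_along(members)) {
      if (!oversize[b] && loads[b] + sizes[i] <= eff) {
        members[[b]] <- c(members[[b]], ids[i])
        loads[b] <- loads[b] + sizes[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      members[[length(members) + 1L]] <- ids[i]
      loads <- c(loads, sizes[i]); oversize <- c(oversize, FALSE)
    }
  }
  lapply(seq_along(members), function(b) {
    list(members = members[[b]], payload_tokens = unname(loads[b]),
         capacity = capacity, oversize_flag = oversize[b])
  })
}

#' Chunk manifest as a data.frame
#'
#' One row per packed sample: `chunk_index`, `sample_id`, `token_count`,
#' `oversize_flag`. Suitable for writing with [utils::write.csv()].
#'
#' @param chunks Result of [pack_ffd()].
#' @param samples The data.frame given to [pack_ffd()].
#' @return data.frame manifest.
#' @export
chunk_manifest <- function(chunks, samples) {
  tok <- stats::setNames(samples$token_count, samples$sample_id)
  do.call(rbind, lapply(seq_along(chunks), function(i) {
    data.frame(chunk_index = i,
               sample_id = chunks[[i]]$members,
               token_count = unname(tok[chunks[[i]]$members]),
               oversize_flag = chunks[[i]]$oversize_flag,
               stringsAsFactors = FALSE)
  }))
}
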