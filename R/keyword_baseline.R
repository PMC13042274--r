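# Keyword-whitelist baseline classifier (MicrobeAtlas style).

#' Load biome term sets
#'
#' Term sets map each biome to a whitelist of lowercase keywords. Accepted
#' formats: 2-column TSV (`biome`, `keyword`) or JSON
#' (`{"plant": ["leaf", ...], ...}`). A keyword may appear in more than one
#' set; that ambiguity is what the multi-match rule detects. A small
#' default fixture ships with the package (`system.file("extdata",
#' "term_sets.tsv", package = "biomellm")`); production whitelists are
#' user-supplied.
#'
#' @param path TSV or JSON file.
#' @return Named list of character vectors, class `term_sets`.
#' @export
load_term_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sets <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    sets <- lapply(sets, function(x) tolower(as.character(x)))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "#")
    if (nrow(df) && tolower(df[[1]][1]) == "biome") df <- df[-1, , drop = FALSE]
    sets <- split(tolower(trimws(df[[2]])), tolower(trimws(df[[1]])))
  }
  bad <- setdiff(names(sets), biome_levels())
  if (length(bad)) stop("unknown biome(s) in term sets: ", paste(bad, collapse = ", "))
  if (any(!lengths(sets))) stop("term sets must be non-empty")
  structure(sets, class = "term_sets")
}

#' Extract normalised keyword tokens from a record
#'
#' Concatenates all field values, lowercases, strips characters other than
#' letters, digits and hyphens, splits on whitespace/punctuation, and
#' deduplicates preserving first occurrence.
#'
#' @param record A [metadata_record] (ideally cleaned first).
#' @return Character vector of unique tokens.
#' @export
extract_keywords <- function(record) {
  text <- tolower(paste(unname(record$fields), collapse = " "))
  text <- gsub("[^a-z0-9-]+", " ", text)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens) & tokens != "-"]
  unique(tokens)
}

#' Classify a token set against biome term sets
#'
#' Returns the unique biome whose term set intersects the tokens. If the
#' tokens hit two or more biomes' sets (ambiguity, e.g. "leaf, banana,
#' tree, insect"), or none at all, the sample is labelled `"unknown"`.
#' For comparison against five-way classifiers, `"unknown"` is customarily
#' aligned with `"other"` (see [align_unknown()]).
#'
#' @param tokens Character vector from [extract_keywords()].
#' @param term_sets A `term_sets` object.
#' @return One of animal/plant/water/soil/other/unknown.
#' @export
classify_keywords <- function(tokens, term_sets) {
  hits <- names(term_sets)[vapply(term_sets, function(s) any(tokens %in% s), logical(1))]
  if (length(hits) == 1L) hits else "unknown"
}

#' Align "unknown" baseline labels with "other"
#'
#' @param labels Character vector of baseline labels.
#' @return Labels with `"unknown"` replaced by `"other"`.
#' @export
align_unknown <- function(labels) {
  ifelse(labels == "unknown", "other", labels)
}

#' Run the keyword baseline over a record collection
#'
#' @param records List of [metadata_record].
#' @param term_sets A `term_sets` object.
#' @param align If `TRUE`, map `"unknown"` to `"other"` for five-way
#'   comparison.
#' @return data.frame with `sample_id` and `biome`.
#' @export
keyword_baseline <- function(records, term_sets, align = FALSE) {
  labels <- vapply(records, function(r) {
    classify_keywords(extract_keywords(r), term_sets)
  }, character(1))
  if (align) labels <- align_unknown(labels)
  data.frame(sample_id = vapply(records, `[[`, "", "sample_id"),
             biome = labels, stringsAsFactors = FALSE)
}
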