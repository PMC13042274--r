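# Parsing LLM responses (inline "___" dialect and JSON) into annotations.

KEYWORD_MIN <- 5L
KEYWORD_MAX <- 8L
SUBBIOME_MAX_WORDS <- 3L

empty_annotations <- function() {
  data.frame(sample_id = character(), biome_raw = character(),
             location = character(), keywords = character(),
             sub_biome = character(), flagged = logical(),
             stringsAsFactors = FALSE)
}

empty_parse_report <- function(expected_ids = character()) {
  list(parsed_ids = character(), missing_ids = as.character(expected_ids),
       malformed_lines = data.frame(text = character(), reason = character(),
                                    stringsAsFactors = FALSE),
       duplicate_ids = character(), unexpected_ids = character())
}

merge_parse_reports <- function(reports, expected_ids) {
  parsed <- unique(unlist(lapply(reports, `[[`, "parsed_ids")))
  list(parsed_ids = intersect(expected_ids, parsed),
       missing_ids = setdiff(expected_ids, parsed),
       malformed_lines = do.call(rbind, c(
         list(empty_parse_report()$malformed_lines),
         lapply(reports, `[[`, "malformed_lines"))),
       duplicate_ids = unique(unlist(lapply(reports, `[[`, "duplicate_ids"))),
       unexpected_ids = unique(unlist(lapply(reports, `[[`, "unexpected_ids"))))
}

#' Normalise a free-text label
#'
#' Lowercases, trims, and collapses internal whitespace. Parentheticals are
#' preserved - distinguishing "animal" from "animal (incl. human)" is the
#' job of lenient matching, not normalisation.
#'
#' @param text Character vector.
#' @return Normalised character vector.
#' @export
normalize_label <- function(text) {
  tolower(trimws(gsub("[[:space:]]+", " ", text)))
}

na_or <- function(x) {
  x <- trimws(x)
  ifelse(!nzchar(x) | toupper(x) == "NA", NA_character_, x)
}

split_keywords <- function(block) {
  block <- trimws(block)
  if (!nzchar(block) || toupper(block) == "NA") return(NULL)
  inner <- sub("^\\{(.*)\\}$", "\\1", block)
  kw <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
  kw <- kw[nzchar(kw)]
  if (!length(kw)) NULL else kw
}

annotation_row <- function(id, biome, location, keywords, sub_biome) {
  n_kw <- length(keywords)
  sub <- na_or(sub_biome)
  flagged <- (!is.null(keywords) && (n_kw < KEYWORD_MIN || n_kw > KEYWORD_MAX)) ||
    (!is.na(sub) && length(strsplit(sub, "[[:space:]]+")[[1]]) > SUBBIOME_MAX_WORDS)
  data.frame(sample_id = id, biome_raw = na_or(biome),
             location = na_or(location),
             keywords = if (is.null(keywords)) NA_character_ else
               paste(keywords, collapse = "|"),
             sub_biome = sub, flagged = flagged, stringsAsFactors = FALSE)
}

finalize_parse <- function(rows, malformed, expected_ids) {
  expected_ids <- as.character(expected_ids)
  duplicate_ids <- character(); unexpected_ids <- character()
  ann <- empty_annotations()
  if (length(rows)) {
    all_rows <- do.call(rbind, rows)
    dup <- duplicated(all_rows$sample_id)
    duplicate_ids <- unique(all_rows$sample_id[dup])
    all_rows <- all_rows[!dup, , drop = FALSE]
    unexpected <- !(all_rows$sample_id %in% expected_ids)
    unexpected_ids <- all_rows$sample_id[unexpected]
    ann <- all_rows[!unexpected, , drop = FALSE]
    rownames(ann) <- NULL
  }
  list(annotations = ann,
       report = list(
         parsed_ids = ann$sample_id,
         missing_ids = setdiff(expected_ids, ann$sample_id),
         malformed_lines = malformed,
         duplicate_ids = duplicate_ids,
         unexpected_ids = unexpected_ids))
}

#' Parse an inline (triple-underscore) LLM response
#'
#' Each non-empty line is split on the literal separator `"___"` into
#' exactly 5 fields: sample id, biome, location, `{keyword, ...}` block,
#' sub-biome. Lines with the wrong field count, or whose first field is not
#' an accession, are collected in `malformed_lines` (their IDs, when
#' extractable, stay in `missing_ids` so they can be retried). `"NA"`
#' values become `NA`. Keyword-count (5-8) and sub-biome-length (3 words)
#' violations are kept but flagged, not rejected - discarding them would
#' bias accuracy measurement. The parser never raises on arbitrary text;
#' every failure is data in the report.
#'
#' @param raw Raw response text.
#' @param expected_ids Character vector of sample IDs that were requested.
#' @return List with `annotations` (data.frame: sample_id, biome_raw,
#'   location, keywords (pipe-joined), sub_biome, flagged) and `report`
#'   (parsed_ids, missing_ids, malformed_lines, duplicate_ids,
#'   unexpected_ids). `parsed` and `missing` always partition `expected`.
#' @export
parse_inline <- function(raw, expected_ids) {
  malformed <- empty_parse_report()$malformed_lines
  rows <- list()
  lines <- trimws(strsplit(paste(raw, collapse = "\n"), "\n", fixed = TRUE)[[1]])
  for (ln in lines[nzchar(lines)]) {
    parts <- strsplit(ln, "___", fixed = TRUE)[[1]]
    if (length(parts) != 5L) {
      malformed <- rbind(malformed, data.frame(
        text = ln, reason = "field_count", stringsAsFactors = FALSE))
      next
    }
    id <- trimws(parts[1])
    if (!grepl(accession_regex, id)) {
      malformed <- rbind(malformed, data.frame(
        text = ln, reason = "bad_id", stringsAsFactors = FALSE))
      next
    }
    rows[[length(rows) + 1L]] <- annotation_row(
      id, parts[2], parts[3], split_keywords(parts[4]), parts[5])
  }
  finalize_parse(rows, malformed, expected_ids)
}

json_alias <- function(obj, aliases) {
  keys <- gsub("[^a-z]", "", tolower(names(obj)))
  for (a in aliases) {
    hit <- match(a, keys)
    if (!is.na(hit)) return(obj[[hit]])
  }
  NULL
}

#' Parse a JSON-dialect LLM response
#'
#' Accepts a single object or an array of objects; key aliases
#' (`sample_id`/`id`/`accession`, `biome`/`category`, `sub_biome`/
#' `subbiome`/`sub-biome`, ...) are normalised. Keywords may be an array or
#' a single comma-joined string. Syntactically invalid JSON marks the whole
#' response malformed and all its expected IDs missing (so they are
#' retried); objects without a valid accession are individually malformed.
#'
#' @inheritParams parse_inline
#' @return Same structure as [parse_inline()].
#' @export
parse_json <- function(raw, expected_ids) {
  malformed <- empty_parse_report()$malformed_lines
  parsed <- tryCatch(
    jsonlite::fromJSON(paste(raw, collapse = "\n"), simplifyVector = FALSE),
    error = function(e) e)
  if (inherits(parsed, "error")) {
    malformed <- rbind(malformed, data.frame(
      text = paste(raw, collapse = "\n"), reason = "invalid_json",
      stringsAsFactors = FALSE))
    return(finalize_parse(list(), malformed, expected_ids))
  }
  if (!is.null(names(parsed))) parsed <- list(parsed)  # single object
  rows <- list()
  for (obj in parsed) {
    if (!is.list(obj)) {
      malformed <- rbind(malformed, data.frame(
        text = paste(deparse(obj), collapse = ""), reason = "not_an_object",
        stringsAsFactors = FALSE))
      next
    }
    id <- json_alias(obj, c("sampleid", "id", "sample", "accession"))
    if (is.null(id) || !grepl(accession_regex, trimws(as.character(id)))) {
      malformed <- rbind(malformed, data.frame(
        text = as.character(jsonlite::toJSON(obj, auto_unbox = TRUE)),
        reason = "bad_id", stringsAsFactors = FALSE))
      next
    }
    biome <- json_alias(obj, c("biome", "biomeraw", "category", "sourcecategory"))
    loc <- json_alias(obj, c("location", "geographiclocation", "geolocation", "geo"))
    kw <- json_alias(obj, c("keywords", "keyterms", "tags"))
    sub <- json_alias(obj, c("subbiome", "specificorigin", "suborigin"))
    kw <- if (is.null(kw)) NULL
      else if (length(kw) > 1L || is.list(kw)) {
        k <- trimws(unlist(kw, use.names = FALSE)); k[nzchar(k)]
      } else split_keywords(as.character(kw))
    rows[[length(rows) + 1L]] <- annotation_row(
      trimws(as.character(id)),
      if (is.null(biome)) "NA" else as.character(biome),
      if (is.null(loc)) "NA" else as.character(loc),
      kw,
      if (is.null(sub)) "NA" else as.character(sub))
  }
  finalize_parse(rows, malformed, expected_ids)
}

#' Write the consolidated annotation CSV
#'
#' Columns: sample_id, biome, location, keywords (pipe-joined), sub_biome,
#' status (`ok`/`flagged`/`unresolved`).
#'
#' @param annotations Annotation data.frame (with `status`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  out <- data.frame(sample_id = annotations$sample_id,
                    biome = annotations$biome_raw,
                    location = annotations$location,
                    keywords = annotations$keywords,
                    sub_biome = annotations$sub_biome,
                    status = if ("status" %in% names(annotations))
                      annotations$status else
                      ifelse(annotations$flagged, "flagged", "ok"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
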