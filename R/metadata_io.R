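# Reading, cleaning and serialising per-sample metadata records.

#' Default placeholder values removed during cleaning
#'
#' Whole-value, case-insensitive matches against these strings (after
#' trimming) mark a field as uninformative. Submitters use them in place of
#' real content ("missing", "NaN", "not applicable", ...).
#'
#' @return Character vector of placeholder strings.
#' @export
default_placeholders <- function() {
  c("missing", "NaN", "not applicable", "unknown", "NA", "none", "null")
}

accession_regex <- "^[A-Z]{2,4}[0-9]+$"

#' Construct a metadata record
#'
#' A `metadata_record` is one sample's ordered field_name -> value mapping
#' plus its accession. Field names are kept verbatim (case-sensitive) and
#' field order is stable across read/clean/write.
#'
#' @param sample_id Accession string (e.g. `"SRS994677"`, `"SYN000001"`).
#' @param fields Named character vector (names = field names, values = text).
#'   Duplicate field names are allowed.
#' @param source_path Optional provenance string.
#' @return An object of class `metadata_record`.
#' @export
metadata_record <- function(sample_id, fields = character(), source_path = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  fields <- as.character(fields) |> stats::setNames(names(fields))
  if (length(fields) && is.null(names(fields))) {
    stop("fields must be named")
  }
  structure(
    list(sample_id = sample_id, fields = fields, source_path = source_path),
    class = "metadata_record"
  )
}

#' @export
print.metadata_record <- function(x, ...) {
  cat("<metadata_record>", x$sample_id, "-", length(x$fields), "fields\n")
  invisible(x)
}

#' Read per-sample metadata records
#'
#' Two dialects are supported. `"consolidated-multirecord"`: a single plain
#' or gzip file in which a line consisting solely of an accession (2-4
#' capital letters followed by digits, at column 0) starts a new record, and
#' subsequent `name: value` lines (first-colon split) are its fields.
#' `"per-sample-file"`: one file is one record; the accession is the first
#' accession-shaped line, or the file's base name if none is present.
#'
#' Malformed lines (non-empty, not a field, not an accession) are reported in
#' the `warnings` attribute, never silently dropped. Field content that
#' precedes any accession header produces a logged warning and no record.
#'
#' @param path Path to the metadata file (optionally `.gz`).
#' @param dialect `"consolidated-multirecord"` (default) or
#'   `"per-sample-file"`.
#' @return A list of [metadata_record] objects with attribute `warnings`
#'   (character vector).
#' @export
load_records <- function(path, dialect = c("consolidated-multirecord", "per-sample-file")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read metadata file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  warnings <- character()
  records <- list()

  if (dialect == "per-sample-file") {
    acc_lines <- grep(accession_regex, trimws(lines))
    sid <- if (length(acc_lines)) trimws(lines[acc_lines[1]]) else
      toupper(tools::file_path_sans_ext(basename(path)))
    if (!grepl(accession_regex, sid)) {
      warnings <- c(warnings, sprintf("no parsable sample_id in %s; file skipped", path))
      return(structure(list(), warnings = warnings))
    }
    body <- if (length(acc_lines)) lines[-acc_lines[1]] else lines
    rec <- parse_record_body(sid, body, path)
    warnings <- c(warnings, attr(rec, "warnings"))
    return(structure(list(rec), warnings = warnings))
  }

  # consolidated: split on accession header lines
  is_header <- grepl(accession_regex, lines)
  if (!any(is_header)) {
    if (any(nzchar(trimws(lines)))) {
      warnings <- c(warnings, "content found but no record header with a parsable sample_id; skipped")
    }
    return(structure(list(), warnings = warnings))
  }
  if (any(nzchar(trimws(lines[seq_len(which(is_header)[1] - 1)])))) {
    warnings <- c(warnings, "lines before first record header ignored (no parsable sample_id)")
  }
  starts <- which(is_header)
  ends <- c(starts[-1] - 1L, length(lines))
  seen <- character()
  for (i in seq_along(starts)) {
    sid <- trimws(lines[starts[i]])
    if (sid %in% seen) {
      warnings <- c(warnings, sprintf("duplicate record %s; later occurrence skipped", sid))
      next
    }
    seen <- c(seen, sid)
    body <- if (starts[i] < ends[i]) lines[(starts[i] + 1L):ends[i]] else character()
    rec <- parse_record_body(sid, body, path)
    warnings <- c(warnings, attr(rec, "warnings"))
    attr(rec, "warnings") <- NULL
    if (length(rec$fields) == 0L) {
      warnings <- c(warnings, sprintf("record %s has no fields; skipped", sid))
      next
    }
    records[[length(records) + 1L]] <- rec
  }
  structure(records, warnings = warnings)
}

parse_record_body <- function(sample_id, body, path) {
  warnings <- character()
  nm <- character(); val <- character()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    if (!grepl(":", ln, fixed = TRUE)) {
      warnings <- c(warnings, sprintf("record %s: malformed line (no colon): %s", sample_id, ln))
      next
    }
    pos <- regexpr(":", ln, fixed = TRUE)
    nm <- c(nm, trimws(substr(ln, 1L, pos - 1L)))
    val <- c(val, trimws(substr(ln, pos + 1L, nchar(ln))))
  }
  rec <- metadata_record(sample_id, stats::setNames(val, nm), source_path = path)
  attr(rec, "warnings") <- warnings
  rec
}

#' Write records in the consolidated plain-text dialect
#'
#' @param records List of [metadata_record].
#' @param path Output file path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (rec in records) {
    writeLines(rec$sample_id, con)
    if (length(rec$fields)) {
      writeLines(paste0(names(rec$fields), ": ", unname(rec$fields)), con)
    }
  }
  invisible(path)
}

#' Clean one metadata record
#'
#' Removes fields with empty values, fields whose whole trimmed value equals
#' a placeholder (case-insensitive; substrings such as "NaN-free soil"
#' survive), and fields whose name begins with "experiment"
#' (case-insensitive) - those describe wet-lab procedure, not sample origin.
#' Cleaning is idempotent and every removal is logged with its reason.
#'
#' @param record A [metadata_record].
#' @param placeholders Character vector of placeholder values;
#'   defaults to [default_placeholders()].
#' @return A list with elements `record` (cleaned [metadata_record]) and
#'   `log` (a `cleaning_log`: data.frame of removals with columns
#'   `field`, `value`, `reason` in
#'   `empty`/`placeholder`/`experiment_prefix`).
#' @export
clean_record <- function(record, placeholders = default_placeholders()) {
  stopifnot(inherits(record, "metadata_record"))
  ph <- tolower(trimws(placeholders))
  nm <- names(record$fields)
  val <- unname(record$fields)
  trimmed <- trimws(val)

  reason <- rep(NA_character_, length(val))
  reason[!nzchar(trimmed)] <- "empty"
  reason[is.na(reason) & tolower(trimmed) %in% ph] <- "placeholder"
  reason[is.na(reason) & grepl("^experiment", nm, ignore.case = TRUE)] <- "experiment_prefix"

  keep <- is.na(reason)
  out <- record
  out$fields <- stats::setNames(val[keep], nm[keep])
  log <- data.frame(
    field = nm[!keep], value = val[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  class(log) <- c("cleaning_log", class(log))
  list(record = out, log = log)
}

#' Load an ontology CURIE dictionary from a 2-column TSV
#'
#' @param path TSV with columns CURIE (e.g. `ENVO:00002297`) and label.
#'   A header row is detected and skipped if its first cell is not a CURIE.
#' @return Named character vector (names = CURIEs, values = labels) of class
#'   `ontology_dictionary`, with attribute `prefixes`.
#' @export
load_ontology_dictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) && !grepl("^[A-Za-z]+:[0-9]+$", df[[1]][1])) df <- df[-1, , drop = FALSE]
  curies <- trimws(df[[1]])
  labels <- trimws(df[[2]])
  ok <- grepl("^[A-Za-z]+:[0-9]+$", curies) & nzchar(labels)
  if (!all(ok)) warning(sum(!ok), " malformed dictionary rows dropped")
  dict <- stats::setNames(labels[ok], curies[ok])
  structure(dict,
            prefixes = unique(sub(":.*$", "", curies[ok])),
            class = "ontology_dictionary")
}

#' Translate ontology codes embedded in field values
#'
#' Every CURIE (`PREFIX:digits`, word-bounded, prefixes taken from the loaded
#' dictionary) occurring in any field value and present in the dictionary is
#' replaced by its textual label; misses are left intact and logged. The
#' number of fields never changes.
#'
#' @param record A [metadata_record].
#' @param dict An `ontology_dictionary` from [load_ontology_dictionary()].
#' @return List with `record` (translated) and `log` (data.frame with columns
#'   `curie`, `label`, `status` in `translated`/`untranslated`).
#' @export
translate_ontology <- function(record, dict) {
  stopifnot(inherits(record, "metadata_record"))
  prefixes <- attr(dict, "prefixes")
  if (is.null(prefixes) || !length(prefixes)) {
    prefixes <- unique(sub(":.*$", "", names(dict)))
  }
  pat <- paste0("\\b(", paste(prefixes, collapse = "|"), "):([0-9]+)\\b")
  curie_log <- character(); status_log <- character(); label_log <- character()
  vals <- unname(record$fields)
  for (i in seq_along(vals)) {
    m <- gregexpr(pat, vals[i])[[1]]
    if (m[1] == -1L) next
    hits <- regmatches(vals[i], gregexpr(pat, vals[i]))[[1]]
    repl <- vapply(hits, function(cu) {
      if (cu %in% names(dict)) {
        curie_log <<- c(curie_log, cu); label_log <<- c(label_log, unname(dict[cu]))
        status_log <<- c(status_log, "translated")
        unname(dict[cu])
      } else {
        curie_log <<- c(curie_log, cu); label_log <<- c(label_log, NA_character_)
        status_log <<- c(status_log, "untranslated")
        cu
      }
    }, character(1))
    regmatches(vals[i], gregexpr(pat, vals[i])) <- list(repl)
  }
  out <- record
  out$fields <- stats::setNames(vals, names(record$fields))
  list(record = out,
       log = data.frame(curie = curie_log, label = label_log, status = status_log,
                        stringsAsFactors = FALSE))
}

#' Directory shard key for a sample accession
#'
#' Records are sharded into directories named after the last 3 digits of the
#' accession; accessions with fewer than 3 trailing digits are zero-padded on
#' the left, keeping the fan-out total and deterministic (at most 1000
#' shards).
#'
#' @param sample_id Accession string ending in at least one digit.
#' @return 3-character digit string.
#' @export
shard_key <- function(sample_id) {
  vapply(sample_id, function(s) {
    digits <- sub("^.*?([0-9]*)$", "\\1", s)
    if (!nzchar(digits)) stop("sample_id has no trailing digits: ", s)
    padded <- paste0("00", digits)
    substr(padded, nchar(padded) - 2L, nchar(padded))
  }, character(1), USE.NAMES = FALSE)
}

#' Serialise a record as a prompt payload block
#'
#' Deterministic one-record text block: the accession on its own line, then
#' `field_name: value` lines in stored order. Newlines inside values are
#' flattened to single spaces so that one line is always one field.
#'
#' @param record A [metadata_record].
#' @return A single string (lines joined with `\n`).
#' @seealso [deserialize_record()] for the inverse.
#' @export
serialize_for_prompt <- function(record) {
  flat <- gsub("[\r\n]+", " ", unname(record$fields))
  paste(c(record$sample_id,
          if (length(flat)) paste0(names(record$fields), ": ", flat)),
        collapse = "\n")
}

#' Inverse of [serialize_for_prompt()]
#'
#' @param text A serialized record block.
#' @return A [metadata_record].
#' @export
deserialize_record <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rec <- parse_record_body(trimws(lines[1]), lines[-1], path = NULL)
  attr(rec, "warnings") <- NULL
  rec
}

#' Write cleaning logs as JSON lines
#'
#' One JSON object per record: `{"sample_id": ..., "removed": [...],
#' "translated": [...]}`.
#'
#' @param logs Named list (by sample_id) of lists with elements `removed`
#'   (cleaning_log data.frame) and `translated` (translation data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_logs <- function(logs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (sid in names(logs)) {
    obj <- list(sample_id = sid,
                removed = logs[[sid]]$removed,
                translated = logs[[sid]]$translated)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows"), con)
  }
  invisible(path)
}
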