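# Which metadata fields carry sample-origin information.

# short function words excluded from lenient sub-biome tokens
STOPWORDS <- c("the", "and", "for", "from", "with", "type", "sample", "its",
               "are", "was", "per")

subbiome_words <- function(sub_biome, min_len = 3L) {
  w <- strsplit(normalize_label(sub_biome), "[^a-z0-9-]+")[[1]]
  w <- setdiff(w[nchar(w) >= min_len], STOPWORDS)
  w
}

#' Match a gold sub-biome against every field of a record
#'
#' Full match: the entire normalised sub-biome string occurs in the field
#' value with word boundaries ("cow rumen" inside "isolated from cow rumen
#' fluid"). Lenient match: any constituent word of the sub-biome (length >=
#' 3 after normalisation, stop-words excluded) occurs as a whole word
#' ("rumen" inside "bovine rumen"). Full implies lenient.
#'
#' @param record A cleaned [metadata_record].
#' @param gold_sub_biome Curator-assigned sub-biome (non-empty).
#' @return List (`field_match_profile`): sample_id, full_match_fields,
#'   lenient_match_fields (character vectors of field names).
#' @export
match_subbiome_fields <- function(record, gold_sub_biome) {
  stopifnot(nzchar(gold_sub_biome))
  sub <- normalize_label(gold_sub_biome)
  words <- subbiome_words(gold_sub_biome)
  vals <- normalize_label(unname(record$fields))
  nm <- names(record$fields)
  full_pat <- paste0("\\b", escape_regex(sub), "\\b")
  full <- nm[grepl(full_pat, vals)]
  lenient <- if (length(words)) {
    pat <- paste0("\\b(", paste(vapply(words, escape_regex, ""), collapse = "|"), ")\\b")
    nm[grepl(pat, vals)]
  } else character()
  lenient <- union(lenient, full)
  structure(list(sample_id = record$sample_id,
                 full_match_fields = unique(full),
                 lenient_match_fields = unique(lenient)),
            class = "field_match_profile")
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Field informativeness report
#'
#' Aggregates [match_subbiome_fields()] profiles: per-field full and
#' lenient match counts, mean/SD of per-sample matching-field counts, mean
#' word count per field, and a per-biome breakdown restricted to fields
#' with at least `min_lenient` lenient matches (rarely matching fields are
#' excluded from the breakdown but kept in the totals).
#'
#' @param profiles List of `field_match_profile`.
#' @param gold Gold data.frame (`sample_id`, `biome`).
#' @param records Optional list of [metadata_record] used for the mean
#'   word count per field.
#' @param min_lenient Minimum lenient-match count for the per-biome table
#'   (default 20).
#' @return List: `fields` (data.frame field_name, full_count,
#'   lenient_count, mean_words), `per_sample` (data.frame with
#'   mean/sd of full and lenient fields per sample), `per_biome`
#'   (field-by-biome lenient-count table), `n_full_fields`,
#'   `n_lenient_fields`.
#' @export
field_frequency_report <- function(profiles, gold, records = NULL,
                                   min_lenient = 20L) {
  if (!length(profiles)) stop("no profiles supplied")
  ids <- vapply(profiles, `[[`, "", "sample_id")
  biome <- gold$biome[match(ids, gold$sample_id)]
  full_list <- lapply(profiles, `[[`, "full_match_fields")
  len_list <- lapply(profiles, `[[`, "lenient_match_fields")

  full_tab <- table(unlist(full_list))
  len_tab <- table(unlist(len_list))
  all_fields <- sort(union(names(full_tab), names(len_tab)))
  fields <- data.frame(
    field_name = all_fields,
    full_count = as.integer(full_tab[all_fields]),
    lenient_count = as.integer(len_tab[all_fields]),
    stringsAsFactors = FALSE)
  fields$full_count[is.na(fields$full_count)] <- 0L
  fields$lenient_count[is.na(fields$lenient_count)] <- 0L

  if (!is.null(records)) {
    wc <- list()
    for (rec in records) {
      for (j in seq_along(rec$fields)) {
        f <- names(rec$fields)[j]
        n <- length(strsplit(trimws(rec$fields[[j]]), "[[:space:]]+")[[1]])
        wc[[f]] <- c(wc[[f]], n)
      }
    }
    fields$mean_words <- vapply(fields$field_name, function(f) {
      if (is.null(wc[[f]])) NA_real_ else mean(wc[[f]])
    }, numeric(1))
  }

  n_full <- lengths(full_list)
  n_len <- lengths(len_list)
  per_sample <- data.frame(
    mean_full_fields = mean(n_full), sd_full_fields = stats::sd(n_full),
    mean_lenient_fields = mean(n_len), sd_lenient_fields = stats::sd(n_len))

  keep <- fields$field_name[fields$lenient_count >= min_lenient]
  per_biome <- NULL
  if (length(keep)) {
    long <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      fl <- intersect(len_list[[i]], keep)
      if (!length(fl)) return(NULL)
      data.frame(field_name = fl, biome = biome[i], stringsAsFactors = FALSE)
    }))
    if (!is.null(long)) {
      per_biome <- as.data.frame.matrix(table(long$field_name, long$biome))
    }
  }
  list(fields = fields, per_sample = per_sample, per_biome = per_biome,
       n_full_fields = sum(fields$full_count > 0),
       n_lenient_fields = sum(fields$lenient_count > 0))
}
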