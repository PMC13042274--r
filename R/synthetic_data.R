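# Synthetic gold-labelled benchmark generator and coordinate-error injection.
# All generated content is synthetic: template snippets, SYN-prefixed
# accessions, and gazetteer-derived coordinates; no repository content is
# reproduced.

#' Noise profile for the synthetic benchmark
#'
#' @param placeholder_rate Probability that a record gains an extra
#'   placeholder-valued field ("missing", "NaN", ...).
#' @param ontology_code_rate Probability that a record's environment field
#'   carries a raw ontology CURIE instead of (or alongside) text.
#' @param verbose_abstract Include a verbose multi-sentence
#'   `study_STUDY_ABSTRACT` field.
#' @param coord_error_rates Named rates for [inject_coordinate_errors()]
#'   modes (`latlon_swapped`, `lon_sign_flip`, `lat_sign_flip`,
#'   `relocate`, `institution`); must sum to at most 1.
#' @param omission_rate,malformation_rate Passed to the mock backend by
#'   [mock_annotate()].
#' @param paraphrase_rate Mock sub-biome paraphrase probability.
#' @return List of class `noise_profile`.
#' @export
noise_profile <- function(placeholder_rate = 0, ontology_code_rate = 0,
                          verbose_abstract = TRUE,
                          coord_error_rates = list(),
                          omission_rate = 0, malformation_rate = 0,
                          paraphrase_rate = 0) {
  rates <- c(placeholder_rate, ontology_code_rate, omission_rate,
             malformation_rate, paraphrase_rate, unlist(coord_error_rates))
  stopifnot(all(rates >= 0 & rates <= 1))
  if (length(coord_error_rates)) {
    stopifnot(sum(unlist(coord_error_rates)) <= 1 + 1e-12)
  }
  structure(list(placeholder_rate = placeholder_rate,
                 ontology_code_rate = ontology_code_rate,
                 verbose_abstract = isTRUE(verbose_abstract),
                 coord_error_rates = coord_error_rates,
                 omission_rate = omission_rate,
                 malformation_rate = malformation_rate,
                 paraphrase_rate = paraphrase_rate),
            class = "noise_profile")
}

#' Row-stochastic biome confusion specification
#'
#' Convenience constructor for the mock backend: diagonal probability
#' `diagonal` for every biome, remaining mass spread evenly over the other
#' four labels.
#'
#' @param diagonal Per-biome probability of the correct label.
#' @return 5x5 row-stochastic matrix with biome dimnames.
#' @export
confusion_spec <- function(diagonal = 1) {
  stopifnot(diagonal >= 0, diagonal <= 1)
  m <- matrix((1 - diagonal) / 4, 5, 5,
              dimnames = list(biome_levels(), biome_levels()))
  diag(m) <- diagonal
  m
}

load_templates <- function() {
  path <- system.file("extdata", "biome_templates.json", package = "biomellm")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Generate a gold-labelled synthetic benchmark
#'
#' Emits `5 * n_per_biome` SRA-like records (`SYN`-prefixed accessions to
#' avoid collision with real ones) with biome-consistent field content
#' drawn from per-biome template banks: host and isolation-source fields,
#' environment fields, a verbose abstract, a scientific-name field, and a
#' `lat_lon` coordinate pair taken from the bundled gazetteer. Sub-biome
#' vocabulary follows the curation conventions (rhizosphere sub-biomes are
#' labelled plant; sediment sub-biomes are labelled water). Placeholder
#' and ontology-code noise are injected at the profile's rates. Output is
#' deterministic given the seed.
#'
#' @param n_per_biome Records per biome (the curated benchmark scale is
#'   200).
#' @param seed Integer seed.
#' @param noise A [noise_profile()].
#' @param gazetteer A [load_gazetteer()] table.
#' @return List with `records` (list of [metadata_record]) and `gold`
#'   (data.frame: sample_id, biome, sub_biome, location, lat, lon).
#' @export
generate_benchmark <- function(n_per_biome, seed = 1L,
                               noise = noise_profile(),
                               gazetteer = load_gazetteer()) {
  stopifnot(n_per_biome >= 1)
  tpl <- load_templates()
  places <- gazetteer[gazetteer$kind == "place", , drop = FALSE]
  dict_path <- system.file("extdata", "ontology_dictionary.tsv",
                           package = "biomellm")
  curies <- names(load_ontology_dictionary(dict_path))

  local_seed(as.integer(seed), {
    biomes <- rep(biome_levels(), each = n_per_biome)
    n <- length(biomes)
    ids <- sprintf("SYN%06d", seq_len(n))
    records <- vector("list", n)
    gold <- data.frame(sample_id = ids, biome = biomes,
                       sub_biome = NA_character_, location = NA_character_,
                       lat = NA_real_, lon = NA_real_,
                       stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      b <- biomes[i]
      bank <- tpl[[b]]
      k <- sample(length(bank$sub_biomes), 1L)
      sub <- bank$sub_biomes[k]
      iso <- bank$isolation_sources[k]
      host <- if (!is.null(bank$hosts)) sample(bank$hosts, 1L) else NA
      p <- places[sample(nrow(places), 1L), ]
      loc_text <- paste0(p$name, ", ", p$country)

      fields <- c(
        sample_SCIENTIFIC_NAME = paste(sample(c("metagenome", "microbial community"), 1L),
                                       "from", iso),
        sample_isolation_source = iso,
        sample_env_biome = bank$env_biome[k],
        sample_geo_loc_name = loc_text,
        lat_lon = sprintf("%.4f %.4f", p$lat, p$lon))
      if (!is.na(host)) fields <- c(fields, sample_host = host)
      if (noise$verbose_abstract) {
        fields <- c(fields, study_STUDY_ABSTRACT = paste0(
          "In this study we collected ", sample(20:400, 1L),
          " microbial samples from ", iso, " near ", p$name,
          " and profiled community composition by 16S rRNA gene sequencing. ",
          "Samples were stored at -80C prior to DNA extraction and library ",
          "preparation, and sequence data were deposited in a public archive."))
      }
      if (stats::runif(1) < noise$placeholder_rate) {
        ph_field <- sample(c("sample_host_disease", "sample_collection_protocol",
                             "sample_depth"), 1L)
        fields <- c(fields, stats::setNames(
          sample(c("missing", "NaN", "not applicable", "unknown"), 1L), ph_field))
      }
      if (stats::runif(1) < noise$ontology_code_rate && length(curies)) {
        fields["sample_env_biome"] <- paste(fields[["sample_env_biome"]],
                                            sample(curies, 1L))
      }
      records[[i]] <- metadata_record(ids[i], fields)
      gold$sub_biome[i] <- sub
      gold$location[i] <- loc_text
      gold$lat[i] <- p$lat
      gold$lon[i] <- p$lon
    }
    list(records = records, gold = gold)
  })
}

#' Mock-annotate a benchmark (raw LLM-style responses)
#'
#' Runs the deterministic [mock_backend()] over the records exactly as the
#' production pipeline would (one payload per chunk of serialized records)
#' and returns the raw responses, so parser, retry, and validation stages
#' can be exercised offline.
#'
#' @param records,gold Output of [generate_benchmark()].
#' @param confusion 5x5 row-stochastic matrix (see [confusion_spec()]).
#' @param seed Integer seed.
#' @param noise A [noise_profile()] (omission/malformation/paraphrase rates
#'   apply).
#' @param format `"inline"` or `"json"`.
#' @return List with `responses` (character vector, one per record) and
#'   `backend` (the stateful mock, reusable for retries).
#' @export
mock_annotate <- function(records, gold, confusion = confusion_spec(1),
                          seed = 1L, noise = noise_profile(),
                          format = c("inline", "json")) {
  format <- match.arg(format)
  backend <- mock_backend(gold, seed = seed, confusion = confusion,
                          omission_rate = noise$omission_rate,
                          malformation_rate = noise$malformation_rate,
                          paraphrase_rate = noise$paraphrase_rate,
                          format = format)
  responses <- vapply(records, function(r) {
    backend$complete("", serialize_for_prompt(r), NULL)
  }, character(1))
  list(responses = responses, backend = backend)
}

#' Inject coordinate error modes into records
#'
#' Per selected sample applies exactly one mutually exclusive mode to the
#' stored `lat_lon` pair and logs it in a truth table: `latlon_swapped`
#' (store "lon lat" - possibly an out-of-bounds raw pair), `lon_sign_flip`
#' / `lat_sign_flip` (negate one coordinate), `relocate` (random distant
#' point; metadata completely wrong), `institution` (coordinates of a
#' gazetteer institution entry). A mode is skipped for a sample when the
#' corrupted pair would still sit within `detect_km` of the truth: such a
#' point reverse-geocodes to the same locality, so the corruption is
#' operationally undetectable and the sample is left intact (mode
#' `"none"`).
#'
#' @param records List of [metadata_record] with a `lat_lon` field.
#' @param gold Gold table from [generate_benchmark()] (supplies true
#'   coordinates).
#' @param rates Named list of per-mode probabilities summing to <= 1.
#' @param seed Integer seed.
#' @param gazetteer For institution coordinates.
#' @param detect_km Detectability radius; defaults to the gazetteer
#'   reverse-geocoding locality radius (see [geocode_reverse()]).
#' @return List with `records` (modified) and `truth` (data.frame:
#'   sample_id, mode, expected_code, true_lat, true_lon, stored_lat,
#'   stored_lon; mode `"none"` for untouched samples).
#' @export
inject_coordinate_errors <- function(records, gold, rates, seed = 1L,
                                     gazetteer = load_gazetteer(),
                                     detect_km = 300) {
  modes <- c("latlon_swapped", "lon_sign_flip", "lat_sign_flip",
             "relocate", "institution")
  rates <- rates[intersect(names(rates), modes)]
  stopifnot(length(rates) > 0, sum(unlist(rates)) <= 1 + 1e-12)
  inst <- gazetteer[gazetteer$kind == "institution", , drop = FALSE]
  cum <- cumsum(unlist(rates))

  local_seed(as.integer(seed), {
    truth <- data.frame(sample_id = character(), mode = character(),
                        expected_code = character(), true_lat = numeric(),
                        true_lon = numeric(), stored_lat = numeric(),
                        stored_lon = numeric(), stringsAsFactors = FALSE)
    for (i in seq_along(records)) {
      rec <- records[[i]]
      gi <- match(rec$sample_id, gold$sample_id)
      if (is.na(gi) || !("lat_lon" %in% names(rec$fields))) next
      lat <- gold$lat[gi]; lon <- gold$lon[gi]
      u <- stats::runif(1)
      mode <- if (any(u < cum)) names(rates)[which(u < cum)[1]] else "none"
      stored <- c(lat, lon); code <- NA_character_
      if (mode == "latlon_swapped") {
        stored <- c(lon, lat); code <- "latlon_swapped"
      } else if (mode == "lon_sign_flip") {
        stored <- c(lat, -lon)
        code <- if (-lon < 0) "lon_sign_neg" else "lon_sign_pos"
      } else if (mode == "lat_sign_flip") {
        stored <- c(-lat, lon)
        code <- if (-lat < 0) "lat_sign_neg" else "lat_wrong"
      } else if (mode == "relocate") {
        for (attempt in 1:20) {
          cand <- c(stats::runif(1, -60, 70), stats::runif(1, -170, 170))
          # no triage correction of the random point may land back on the
          # truth, or the mode would be misdiagnosed as a swap/sign flip
          variants <- list(cand, c(cand[2], cand[1]),
                           c(cand[1], -cand[2]), c(-cand[1], cand[2]))
          ok <- all(vapply(variants, function(v) {
            corruption_detectable(v, lat, lon, detect_km)
          }, logical(1)))
          if (ok) break
        }
        stored <- cand; code <- "metadata_completely_wrong"
      } else if (mode == "institution") {
        if (!nrow(inst)) next
        j <- sample(nrow(inst), 1L)
        stored <- c(inst$lat[j], inst$lon[j]); code <- "institution_coords"
      }
      if (mode != "none" &&
          !corruption_detectable(stored, lat, lon, detect_km)) {
        mode <- "none"; stored <- c(lat, lon); code <- NA_character_
      }
      if (mode != "none") {
        rec$fields[["lat_lon"]] <- sprintf("%.4f %.4f", stored[1], stored[2])
        records[[i]] <- rec
      }
      truth <- rbind(truth, data.frame(
        sample_id = rec$sample_id, mode = mode, expected_code = code,
        true_lat = lat, true_lon = lon,
        stored_lat = stored[1], stored_lon = stored[2],
        stringsAsFactors = FALSE))
    }
    list(records = records, truth = truth)
  })
}

# TRUE when the stored pair is not trivially equal to the truth and no
# *other* correction lands back on the truth before the intended one would.
corruption_detectable <- function(stored, true_lat, true_lon, threshold_km) {
  truep <- list(lat = true_lat, lon = true_lon)
  d <- function(la, lo) {
    if (is.na(la) || is.na(lo) || abs(la) > 90 || abs(lo) > 180) return(Inf)
    haversine_km(list(lat = la, lon = lo), truep)
  }
  d(stored[1], stored[2]) > threshold_km
}

#' Write a benchmark fixture bundle to disk
#'
#' Records in the consolidated metadata dialect, gold labels as CSV
#' (sample_id, biome, sub_biome), the coordinate-error truth table as CSV,
#' and the noise profile as JSON.
#'
#' @param records,gold Benchmark from [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @param truth Optional truth table from [inject_coordinate_errors()].
#' @param noise Optional [noise_profile()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(records, gold, dir, truth = NULL, noise = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.txt"),
             gold = file.path(dir, "gold.csv"))
  write_records(records, paths[["records"]])
  utils::write.csv(gold[, c("sample_id", "biome", "sub_biome")],
                   paths[["gold"]], row.names = FALSE)
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "coordinate_truth.csv")
    utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  }
  if (!is.null(noise)) {
    paths[["noise"]] <- file.path(dir, "noise_profile.json")
    jsonlite::write_json(unclass(noise), paths[["noise"]], auto_unbox = TRUE)
  }
  invisible(paths)
}
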