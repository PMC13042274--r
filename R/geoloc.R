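# Coordinate extraction, great-circle distances, location text matching and
# mismatch triage.

EARTH_RADIUS_KM <- 6371.0

#' Construct a geographic point
#'
#' @param lat Latitude in degrees, `[-90, 90]`.
#' @param lon Longitude in degrees, `[-180, 180]`.
#' @return Object of class `geo_point` (list with `lat`, `lon`).
#' @export
geo_point <- function(lat, lon) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (is.na(lat) || is.na(lon) || abs(lat) > 90 || abs(lon) > 180) {
    stop("coordinates out of bounds: lat=", lat, " lon=", lon)
  }
  structure(list(lat = lat, lon = lon), class = "geo_point")
}

num_re <- "[-+]?[0-9]+(?:\\.[0-9]+)?"

parse_coord_value <- function(value) {
  v <- trimws(value)
  # hemisphere-letter form: "37.7749 N 122.4194 W"
  m <- regmatches(v, regexec(
    paste0("(", num_re, ")\\s*([NSns])[,;]?\\s+(", num_re, ")\\s*([EWew])"),
    v, perl = TRUE))[[1]]
  if (length(m) == 5) {
    lat <- as.numeric(m[2]) * if (toupper(m[3]) == "S") -1 else 1
    lon <- as.numeric(m[4]) * if (toupper(m[5]) == "W") -1 else 1
    return(c(lat = lat, lon = lon))
  }
  # signed decimal pair: "37.7749, -122.4194" / "37.7749 -122.4194"
  m <- regmatches(v, regexec(
    paste0("^(", num_re, ")[,;\\s]+(", num_re, ")$"), v, perl = TRUE))[[1]]
  if (length(m) == 3) {
    return(c(lat = as.numeric(m[2]), lon = as.numeric(m[3])))
  }
  NULL
}

#' Extract sampling coordinates from a metadata record
#'
#' Searches fields whose names look coordinate-bearing: combined fields
#' (`lat_lon`, `lat lon`, `geographic location (latitude and longitude)`)
#' in either the hemisphere-letter form (`"37.7749 N 122.4194 W"`; S and W
#' negate) or a signed decimal pair, and separate latitude/longitude
#' fields. Values outside `[-90, 90] x [-180, 180]` are rejected with a
#' warning and `NULL` is returned.
#'
#' @param record A [metadata_record].
#' @return A [geo_point()], or `NULL` when no parseable in-bounds
#'   coordinates are present.
#' @export
parse_lat_lon <- function(record) {
  nm <- tolower(names(record$fields))
  vals <- unname(record$fields)
  finish <- function(lat, lon) {
    res <- tryCatch(geo_point(lat, lon), error = function(e) {
      warning("record ", record$sample_id, ": ", conditionMessage(e))
      NULL
    })
    res
  }
  combined <- grepl("lat[ _/]?lon|latitude.*longitude", nm)
  for (i in which(combined)) {
    co <- parse_coord_value(vals[i])
    if (!is.null(co)) return(finish(co["lat"], co["lon"]))
  }
  lat_ix <- which(grepl("lat", nm) & !grepl("lon", nm))
  lon_ix <- which(grepl("lon", nm) & !grepl("lat", nm))
  if (length(lat_ix) && length(lon_ix)) {
    lat <- suppressWarnings(as.numeric(trimws(vals[lat_ix[1]])))
    lon <- suppressWarnings(as.numeric(trimws(vals[lon_ix[1]])))
    if (!is.na(lat) && !is.na(lon)) return(finish(lat, lon))
  }
  NULL
}

#' Great-circle distance (haversine)
#'
#' Mean Earth radius 6371.0 km.
#'
#' @param p,q [geo_point()] objects (or lists with `lat`, `lon`).
#' @return Distance in kilometres.
#' @export
haversine_km <- function(p, q) {
  to_rad <- pi / 180
  phi1 <- p$lat * to_rad; phi2 <- q$lat * to_rad
  dphi <- (q$lat - p$lat) * to_rad
  dlam <- (q$lon - p$lon) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Distance category for a location mismatch
#'
#' Half-open, lower-inclusive buckets: `[0, 100)`, `[100, 500)`,
#' `[500, 1000)`, `[1000, 4000)`, `[4000, Inf)`.
#'
#' @param km Non-negative distance(s) in kilometres.
#' @return Factor with levels LT100, KM100_500, KM500_1000, KM1000_4000,
#'   GT4000.
#' @export
categorize_distance <- function(km) {
  stopifnot(all(km >= 0, na.rm = TRUE))
  cut(km, breaks = c(0, 100, 500, 1000, 4000, Inf),
      labels = c("LT100", "KM100_500", "KM500_1000", "KM1000_4000", "GT4000"),
      right = FALSE, include.lowest = TRUE)
}

geo_tokens <- function(text) {
  t <- tolower(gsub("[^a-z0-9 ]+", " ", tolower(text)))
  tok <- strsplit(trimws(t), "[[:space:]]+")[[1]]
  unique(tok[nzchar(tok)])
}

#' Word-level location text match
#'
#' After lowercasing and punctuation stripping, matches when either
#' string's token set contains the other's ("Los Angeles, USA" is contained
#' in a full reverse-geocode string mentioning Los Angeles and USA).
#' Semantically equivalent but textually disjoint names ("McMurdo Station"
#' vs "Antarctica") do not match; that limitation is inherited from string
#' matching itself. An `NA` prediction never matches.
#'
#' @param predicted LLM-predicted location text.
#' @param geocoded Coordinate-derived location text.
#' @return Logical.
#' @export
match_location_text <- function(predicted, geocoded) {
  if (is.na(predicted) || is.na(geocoded)) return(FALSE)
  a <- geo_tokens(predicted); b <- geo_tokens(geocoded)
  if (!length(a) || !length(b)) return(FALSE)
  all(a %in% b) || all(b %in% a)
}

#' Load the offline gazetteer
#'
#' CSV with columns `name`, `country`, `lat`, `lon` and optionally `kind`
#' (`place` or `institution`). A ~50-place gazetteer ships with the package
#' (`system.file("extdata", "gazetteer.csv", package = "biomellm")`) as an
#' offline stand-in for remote forward/reverse geocoding services.
#'
#' @param path CSV path; default the bundled gazetteer.
#' @return data.frame of class `gazetteer`.
#' @export
load_gazetteer <- function(path = system.file("extdata", "gazetteer.csv",
                                              package = "biomellm")) {
  gz <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "country", "lat", "lon") %in% names(gz)))
  if (is.null(gz$kind)) gz$kind <- "place"
  class(gz) <- c("gazetteer", class(gz))
  gz
}

#' Forward geocode a location text against the gazetteer
#'
#' Finds the gazetteer entry whose name tokens are contained in the text
#' (or vice versa); ties are broken towards the longest name match.
#'
#' @param text Location text.
#' @param gazetteer A [load_gazetteer()] table.
#' @return A [geo_point()] with attribute `entry` (the matched row), or
#'   `NULL` when nothing matches.
#' @export
geocode_forward <- function(text, gazetteer) {
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- geo_tokens(text)
  cand <- which(vapply(gazetteer$name, function(nm) {
    nt <- geo_tokens(nm)
    all(nt %in% toks)
  }, logical(1)))
  if (!length(cand)) {
    cand <- which(vapply(seq_len(nrow(gazetteer)), function(i) {
      nt <- geo_tokens(paste(gazetteer$name[i], gazetteer$country[i]))
      all(toks %in% nt)
    }, logical(1)))
  }
  if (!length(cand)) return(NULL)
  best <- cand[which.max(nchar(gazetteer$name[cand]))]
  structure(geo_point(gazetteer$lat[best], gazetteer$lon[best]),
            entry = gazetteer[best, , drop = FALSE])
}

#' Reverse geocode a point against the gazetteer
#'
#' @param point A [geo_point()].
#' @param gazetteer A [load_gazetteer()] table.
#' @param max_km Entries further than this are not considered a hit.
#' @return `"name, country"` string, or `NA` if nothing is within
#'   `max_km`.
#' @export
geocode_reverse <- function(point, gazetteer, max_km = 300) {
  d <- vapply(seq_len(nrow(gazetteer)), function(i) {
    haversine_km(point, list(lat = gazetteer$lat[i], lon = gazetteer$lon[i]))
  }, numeric(1))
  d[gazetteer$kind == "institution"] <- Inf  # institutions are not localities
  i <- which.min(d)
  if (!is.finite(d[i]) || d[i] > max_km) return(NA_character_)
  paste0(gazetteer$name[i], ", ", gazetteer$country[i])
}

#' Triage a location mismatch
#'
#' Given the raw metadata coordinate pair (possibly out of bounds, e.g. a
#' swapped pair) and the point resolved from the LLM-predicted location
#' text, tests candidate corrections of the metadata pair - swap(lat, lon),
#' negate longitude, negate latitude - and returns the matching code when a
#' corrected point lands within `threshold_km` of the predicted point.
#' Codes follow the error taxonomy: `latlon_swapped`; `lon_sign_neg` /
#' `lon_sign_pos` (stored longitude sign wrongly negative / positive);
#' `lat_sign_neg` (stored latitude wrongly negative) or `lat_wrong` (other
#' latitude error); `institution_coords` when the metadata point sits on a
#' known institution; otherwise `metadata_completely_wrong`. A missing
#' predicted point yields `location_not_in_text`. Calling this on a pair
#' that already matches the prediction is a precondition violation (the
#' sample should have matched upstream) and raises an error.
#'
#' @param meta_lat,meta_lon Raw metadata coordinate pair (not validated).
#' @param predicted_point [geo_point()] for the predicted location, or
#'   `NULL`.
#' @param threshold_km Correction acceptance radius (default 100 km).
#' @param institutions Optional data.frame (`lat`, `lon`) of known
#'   institution coordinates.
#' @return A triage code string.
#' @export
triage_mismatch <- function(meta_lat, meta_lon, predicted_point,
                            threshold_km = 100, institutions = NULL) {
  if (is.null(predicted_point)) return("location_not_in_text")
  near <- function(lat, lon) {
    if (is.na(lat) || is.na(lon) || abs(lat) > 90 || abs(lon) > 180) return(FALSE)
    haversine_km(list(lat = lat, lon = lon), predicted_point) <= threshold_km
  }
  if (near(meta_lat, meta_lon)) {
    stop("metadata point already within ", threshold_km,
         " km of prediction; text mismatch should have been resolved upstream")
  }
  if (near(meta_lon, meta_lat)) return("latlon_swapped")
  if (near(meta_lat, -meta_lon)) {
    return(if (meta_lon < 0) "lon_sign_neg" else "lon_sign_pos")
  }
  if (near(-meta_lat, meta_lon)) {
    return(if (meta_lat < 0) "lat_sign_neg" else "lat_wrong")
  }
  if (!is.null(institutions) && nrow(institutions)) {
    d <- vapply(seq_len(nrow(institutions)), function(i) {
      if (is.na(meta_lat) || abs(meta_lat) > 90) return(Inf)
      haversine_km(list(lat = meta_lat, lon = meta_lon),
                   list(lat = institutions$lat[i], lon = institutions$lon[i]))
    }, numeric(1))
    if (any(d <= threshold_km)) return("institution_coords")
  }
  "metadata_completely_wrong"
}

#' Geolocation consistency report
#'
#' For every sample with parseable metadata coordinates: reverse geocode
#' the metadata point, string-match against the predicted location, and for
#' mismatches forward geocode the prediction, measure the great-circle
#' distance, bucket it, and triage the likely cause.
#'
#' @param records List of [metadata_record].
#' @param annotations Annotation data.frame with `sample_id`, `location`.
#' @param gazetteer A [load_gazetteer()] table.
#' @param threshold_km Triage correction radius.
#' @return data.frame: sample_id, meta_lat, meta_lon, predicted_text,
#'   geocoded_text, text_match, distance_km, category, triage.
#' @export
geo_match_report <- function(records, annotations, gazetteer,
                             threshold_km = 100) {
  institutions <- gazetteer[gazetteer$kind == "institution", , drop = FALSE]
  rows <- list()
  loc <- stats::setNames(annotations$location, annotations$sample_id)
  for (rec in records) {
    raw <- raw_lat_lon(rec)
    if (is.null(raw)) next
    predicted <- if (rec$sample_id %in% names(loc)) loc[[rec$sample_id]] else NA_character_
    valid <- abs(raw["lat"]) <= 90 && abs(raw["lon"]) <= 180
    geocoded <- if (valid) {
      geocode_reverse(geo_point(raw["lat"], raw["lon"]), gazetteer)
    } else NA_character_
    tm <- match_location_text(predicted, geocoded)
    dist <- NA_real_; cat_ <- NA_character_; tri <- NA_character_
    if (!tm) {
      pp <- if (!is.na(predicted)) geocode_forward(predicted, gazetteer) else NULL
      if (!is.null(pp) && valid) {
        dist <- haversine_km(geo_point(raw["lat"], raw["lon"]), pp)
        cat_ <- as.character(categorize_distance(dist))
      }
      tri <- tryCatch(
        triage_mismatch(raw["lat"], raw["lon"], pp, threshold_km, institutions),
        error = function(e) "matched_within_threshold")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = rec$sample_id, meta_lat = unname(raw["lat"]),
      meta_lon = unname(raw["lon"]), predicted_text = predicted,
      geocoded_text = geocoded, text_match = tm, distance_km = dist,
      category = cat_, triage = tri, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(sample_id = character(), meta_lat = numeric(),
                      meta_lon = numeric(), predicted_text = character(),
                      geocoded_text = character(), text_match = logical(),
                      distance_km = numeric(), category = character(),
                      triage = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# raw coordinate pair without bounds validation (swap artifacts must survive)
raw_lat_lon <- function(record) {
  nm <- tolower(names(record$fields))
  vals <- unname(record$fields)
  combined <- grepl("lat[ _/]?lon|latitude.*longitude", nm)
  for (i in which(combined)) {
    co <- parse_coord_value(vals[i])
    if (!is.null(co)) return(co)
  }
  lat_ix <- which(grepl("lat", nm) & !grepl("lon", nm))
  lon_ix <- which(grepl("lon", nm) & !grepl("lat", nm))
  if (length(lat_ix) && length(lon_ix)) {
    lat <- suppressWarnings(as.numeric(trimws(vals[lat_ix[1]])))
    lon <- suppressWarnings(as.numeric(trimws(vals[lon_ix[1]])))
    if (!is.na(lat) && !is.na(lon)) return(c(lat = lat, lon = lon))
  }
  NULL
}
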