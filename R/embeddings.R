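# Embedding provider contract, offline mock embedder, cosine similarity.

#' Cosine similarity of two vectors
#'
#' `dot(a, b) / (|a| * |b|)`. Vectors must have the same length and, when
#' tagged, come from the same provider; comparing embeddings produced by
#' different models is meaningless. All-zero vectors are an error.
#'
#' @param a,b Numeric vectors.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  pa <- attr(a, "provider"); pb <- attr(b, "provider")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb)) {
    stop("embeddings come from different providers: ", pa, " vs ", pb)
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("dimension mismatch: ", length(a), " vs ", length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Deterministic offline mock embedding provider
#'
#' A seeded hashing embedder over word tokens and character trigrams: each
#' token is hashed into one of `dim` buckets; word tokens carry more weight
#' than trigrams. Identical texts always map to identical vectors, and
#' texts sharing more word tokens score higher cosine similarity - enough
#' structure to validate the sub-biome similarity machinery offline. It is
#' not a semantic model: synonyms ("bovine"/"cow") share no tokens and
#' score low.
#'
#' @param dim Embedding dimension.
#' @param seed Integer seed mixed into the hash.
#' @param word_weight,trigram_weight Bucket increments for word tokens and
#'   character trigrams.
#' @return Object of class `embedding_provider` with elements `name`,
#'   `dim`, `embed_one(text)`.
#' @export
mock_embedding_provider <- function(dim = 256L, seed = 1L,
                                    word_weight = 4, trigram_weight = 1) {
  dim <- as.integer(dim)
  stopifnot(dim > 0)
  name <- sprintf("mock-hash-%d-s%d", dim, as.integer(seed))
  bucket <- function(tok, salt) (str_seed(tok, seed, salt) %% dim) + 1L
  embed_one <- function(text) {
    norm <- tolower(gsub("[^a-z0-9 ]+", " ", tolower(text)))
    words <- strsplit(trimws(norm), "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    if (!length(words)) stop("cannot embed empty text")
    v <- numeric(dim)
    for (w in words) {
      v[bucket(w, 1L)] <- v[bucket(w, 1L)] + word_weight
      if (nchar(w) >= 3) {
        for (i in seq_len(nchar(w) - 2L)) {
          tri <- substr(w, i, i + 2L)
          v[bucket(tri, 2L)] <- v[bucket(tri, 2L)] + trigram_weight
        }
      }
    }
    structure(v, provider = name)
  }
  structure(list(name = name, dim = dim, embed_one = embed_one),
            class = "embedding_provider")
}

#' Embed a list of texts
#'
#' One vector per text, constant dimension. Per-text failures (empty text,
#' provider errors) are collected as error records, never silently lost.
#'
#' @param texts Character vector.
#' @param provider An `embedding_provider`.
#' @return List with `vectors` (list of numeric vectors, `NULL` where
#'   embedding failed), `errors` (data.frame: index, text, message),
#'   `provider`, `dim`.
#' @export
embed_texts <- function(texts, provider) {
  stopifnot(inherits(provider, "embedding_provider"))
  vectors <- vector("list", length(texts))
  err_ix <- integer(); err_txt <- character(); err_msg <- character()
  for (i in seq_along(texts)) {
    t <- texts[i]
    res <- tryCatch({
      if (is.na(t) || !nzchar(trimws(t))) stop("empty text")
      provider$embed_one(t)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      err_ix <- c(err_ix, i); err_txt <- c(err_txt, as.character(t))
      err_msg <- c(err_msg, conditionMessage(res))
    } else {
      vectors[[i]] <- res
    }
  }
  list(vectors = vectors,
       errors = data.frame(index = err_ix, text = err_txt, message = err_msg,
                           stringsAsFactors = FALSE),
       provider = provider$name, dim = provider$dim)
}

#' Per-sample cosine similarity between predicted and gold sub-biomes
#'
#' Embeds both sub-biome texts with the same provider and returns the
#' cosine similarity per sample; samples where either text cannot be
#' embedded get `NA`.
#'
#' @param annotations Annotation data.frame with `sample_id`, `sub_biome`.
#' @param gold Gold data.frame with `sample_id`, `sub_biome`.
#' @param provider An `embedding_provider`;
#'   defaults to [mock_embedding_provider()].
#' @return data.frame: sample_id, cosine_sim.
#' @export
subbiome_similarity <- function(annotations, gold,
                                provider = mock_embedding_provider()) {
  ids <- intersect(annotations$sample_id, gold$sample_id)
  a <- annotations$sub_biome[match(ids, annotations$sample_id)]
  g <- gold$sub_biome[match(ids, gold$sample_id)]
  ea <- embed_texts(a, provider)
  eg <- embed_texts(g, provider)
  sims <- vapply(seq_along(ids), function(i) {
    va <- ea$vectors[[i]]; vg <- eg$vectors[[i]]
    if (is.null(va) || is.null(vg)) return(NA_real_)
    cosine_similarity(va, vg)
  }, numeric(1))
  data.frame(sample_id = ids, cosine_sim = sims, stringsAsFactors = FALSE)
}
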