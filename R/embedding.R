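#' Embedding backend contract
#'
#' An embedder is any object of class `embedder` with a `dimension` field
#' and an [embed_text()] method returning a finite numeric vector of that
#' dimension for any non-empty string, deterministically for a fixed backend
#' version. The package ships a seeded hash backend that needs no model
#' downloads; a contextual (transformer) backend can be plugged in by
#' providing another method with the same contract.
#'
#' @param backend An `embedder`.
#' @param text A non-empty string.
#' @return Numeric vector of length `backend$dimension`.
#' @export
embed_text <- function(backend, text) {
  UseMethod("embed_text")
}

#' @export
embed_text.default <- function(backend, text) {
  stop("no embed_text method for class ", paste(class(backend), collapse = "/"),
       call. = FALSE)
}

#' Embedding dimension of a backend
#' @param backend An `embedder`.
#' @return Integer dimension.
#' @export
embedding_dimension <- function(backend) {
  as.integer(backend$dimension)
}

# 31-bit polynomial rolling hash over UTF-8 bytes followed by three Lehmer
# mixing rounds so low-order bits avalanche; exact in double precision.
token_hash <- function(token, seed) {
  codes <- utf8ToInt(token)
  h <- (seed %% 104729) * 7919 + 1
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  h <- (h %% 2147483646) + 1
  for (r in 1:3) h <- (h * 48271) %% 2147483647
  as.integer(h)
}

hash_tokenize <- function(text) {
  tokens <- stringr::str_split(tolower(text), "[^a-z0-9']+")[[1]]
  tokens[nzchar(tokens)]
}

#' Deterministic hash embedding backend
#'
#' A feature-hashing embedder: every token maps to a signed one-hot unit
#' vector whose coordinate and sign are drawn from a seeded hash of the
#' token, and a string's embedding is the unweighted mean of its token
#' vectors. Identical strings give bitwise-identical vectors in any
#' process, and strings with disjoint vocabularies are orthogonal up to
#' hash collisions (probability about `1/dimension` per token pair), which
#' makes the backend a faithful, download-free stand-in for a contextual
#' model in tests and simulations. Choose a dimension several times larger
#' than the working vocabulary so that background tokens rarely share a
#' slot with frame terms; the default comfortably exceeds the synthetic
#' generator's default vocabulary.
#'
#' @param dimension Embedding dimension, at least 2. Default 2048.
#' @param seed Integer seed folded into every token hash.
#' @return An `embedder` of class `hash_backend`.
#' @export
hash_backend <- function(dimension = 2048L, seed = 1L) {
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 2L) {
    stop("dimension must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(name = sprintf("hash-d%d-s%d", dimension, as.integer(seed)),
         dimension = dimension, seed = as.integer(seed),
         cache = new.env(parent = emptyenv())),
    class = c("hash_backend", "embedder")
  )
}

#' @export
print.hash_backend <- function(x, ...) {
  cat("<hash_backend> dimension ", x$dimension, ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

hash_token_vector <- function(backend, token) {
  cached <- backend$cache[[token]]
  if (!is.null(cached)) return(cached)
  h <- token_hash(token, backend$seed)
  slot <- (h %% backend$dimension) + 1L
  sign <- if ((h %/% backend$dimension) %% 2L == 0L) 1 else -1
  v <- numeric(backend$dimension)
  v[slot] <- sign
  backend$cache[[token]] <- v
  v
}

#' @export
embed_text.hash_backend <- function(backend, text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- hash_tokenize(text)
  if (length(tokens) == 0L) {
    stop("cannot embed empty text", call. = FALSE)
  }
  mat <- vapply(tokens, function(tk) hash_token_vector(backend, tk),
                numeric(backend$dimension))
  if (length(tokens) == 1L) as.numeric(mat) else rowMeans(mat)
}

sentence_abbreviations <- c(
  "mr", "mrs", "ms", "dr", "prof", "rev", "sr", "jr", "st", "vs", "etc",
  "approx", "dept", "est", "fig", "no", "inc", "co", "corp", "jan", "feb",
  "mar", "apr", "jun", "jul", "aug", "sep", "sept", "oct", "nov", "dec"
)

#' Split text into sentences
#'
#' Rule-based splitter on terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace, with guards for common abbreviations so "Dr. Smith" does not
#' break a sentence. Adequate for news prose; a different splitter can be
#' passed to [embed_article()].
#'
#' @param text A string.
#' @return Character vector of non-empty sentences.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- stringr::str_squish(text)
  if (!nzchar(s)) return(character())
  for (ab in sentence_abbreviations) {
    s <- stringr::str_replace_all(
      s, stringr::regex(paste0("\\b(", ab, ")\\.(?=\\s)"), ignore_case = TRUE),
      "\\1\x01")
  }
  parts <- stringr::str_split(s, "(?<=[.!?])\\s+")[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- stringr::str_squish(parts)
  parts[nzchar(parts)]
}

#' Centroid vector of a frame lexicon
#'
#' The frame vector is the unweighted arithmetic mean of the embeddings of
#' every expanded term (seeds included). No normalisation is applied before
#' averaging; cosine scoring downstream is scale-invariant.
#'
#' @param lexicon A `frame_lexicon`.
#' @param backend An `embedder`.
#' @return Numeric vector of length `embedding_dimension(backend)`.
#' @export
embed_terms <- function(lexicon, backend) {
  stopifnot(inherits(lexicon, "frame_lexicon"))
  terms <- lexicon$expanded_terms
  if (length(terms) == 0L) {
    stop("lexicon '", lexicon$frame, "' has no expanded terms", call. = FALSE)
  }
  mat <- vapply(terms, function(t) embed_text(backend, t),
                numeric(embedding_dimension(backend)))
  if (length(terms) == 1L) as.numeric(mat) else rowMeans(mat)
}

#' Sentence-level article embedding
#'
#' The article is split into sentences, each sentence is embedded, and the
#' article vector is the unweighted mean of the sentence vectors; word
#' embeddings are never pooled across sentence boundaries.
#'
#' @param text Non-empty article text.
#' @param backend An `embedder`.
#' @param splitter Function text -> character vector of sentences.
#' @return Numeric vector of length `embedding_dimension(backend)`.
#' @export
embed_article <- function(text, backend, splitter = split_sentences) {
  stopifnot(is.character(text), length(text) == 1L)
  sentences <- splitter(text)
  if (length(sentences) == 0L) {
    stop("no sentences after splitting; cannot embed", call. = FALSE)
  }
  mat <- vapply(sentences, function(s) embed_text(backend, s),
                numeric(embedding_dimension(backend)))
  if (length(sentences) == 1L) as.numeric(mat) else rowMeans(mat)
}
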