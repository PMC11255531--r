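#' Cosine similarity of two vectors
#'
#' `u . v / (|u| |v|)`, clamped to `[-1, 1]` against floating-point drift so
#' downstream binning never sees an out-of-range score.
#'
#' @param u,v Numeric vectors of equal length; neither may be all-zero.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch: ", length(u), " vs ", length(v), call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  }
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Build frame centroid vectors for a set of lexicons
#'
#' @param lexicons Named list of `frame_lexicon` objects.
#' @param backend An `embedder`.
#' @return Named list of numeric centroid vectors, one per frame.
#' @export
frame_vectors <- function(lexicons, backend) {
  stats::setNames(
    lapply(lexicons, embed_terms, backend = backend),
    vapply(lexicons, function(lx) lx$frame, character(1))
  )
}

#' Score decedent records against frame centroids
#'
#' Each record's text is embedded at sentence level and compared to every
#' frame centroid by cosine similarity, giving a complete victims-by-frames
#' score grid. Scoring is decedent-level, not article-level: mixed-gender
#' articles contribute one scored span per decedent.
#'
#' @param victims Victim tibble (`victim_id`, `gender`, `circumstances`,
#'   `text`) from [resolve_corpus_victims()].
#' @param frames Named list of centroid vectors from [frame_vectors()].
#' @param backend The `embedder` the centroids were built with.
#' @param splitter Sentence splitter passed to [embed_article()].
#' @return Tibble with one row per (victim, frame): `victim_id`, `gender`,
#'   `circumstances` (list-column), `frame`, `score` in `[-1, 1]`.
#' @export
score_corpus <- function(victims, frames, backend,
                         splitter = split_sentences) {
  if (nrow(victims) == 0L) stop("no victim records to score", call. = FALSE)
  if (length(frames) == 0L) stop("no frames to score against", call. = FALSE)
  empty <- !nzchar(trimws(victims$text))
  if (any(empty)) {
    stop("victim record(s) with empty text: ",
         paste(victims$victim_id[empty], collapse = ", "), call. = FALSE)
  }
  article_vecs <- lapply(victims$text, embed_article,
                         backend = backend, splitter = splitter)
  rows <- lapply(seq_len(nrow(victims)), function(i) {
    tibble::tibble(
      victim_id = victims$victim_id[[i]],
      gender = victims$gender[[i]],
      circumstances = victims$circumstances[i],
      frame = names(frames),
      score = vapply(frames, cosine_similarity, numeric(1),
                     u = article_vecs[[i]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a score table to CSV
#'
#' Circumstance sets are serialised semicolon-delimited.
#'
#' @param scores Score tibble from [score_corpus()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(
    victim_id = scores$victim_id,
    gender = scores$gender,
    circumstances = vapply(scores$circumstances, paste, character(1),
                           collapse = ";"),
    frame = scores$frame,
    score = scores$score,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path CSV path.
#' @return Score tibble with a list-column of circumstances.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(victim_id = "character"))
  tibble::tibble(
    victim_id = df$victim_id,
    gender = df$gender,
    circumstances = strsplit(df$circumstances, ";", fixed = TRUE),
    frame = df$frame,
    score = as.numeric(df$score)
  )
}
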