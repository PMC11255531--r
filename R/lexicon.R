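#' Frame names of the stigma-of-suicide attitude scale
#' @export
frame_levels <- function() c("stigma", "glorification", "isolation")

#' Construct a frame lexicon
#'
#' A lexicon pairs a named attitude frame with its seed terms, the expanded
#' term set used for embedding, and the terms removed by coder pruning.
#' Seeds are always retained in the expanded set; the expanded and excluded
#' sets never overlap.
#'
#' @param frame One of [frame_levels()] (other names are allowed for
#'   user-defined frames).
#' @param seed_terms Character vector of lowercase terms.
#' @param expanded_terms Terms retained for embedding (defaults to seeds).
#' @param excluded_terms Terms removed by pruning.
#' @return An object of class `frame_lexicon`.
#' @export
frame_lexicon <- function(frame, seed_terms,
                          expanded_terms = seed_terms,
                          excluded_terms = character()) {
  norm <- function(x) {
    x <- tolower(trimws(x))
    if (any(!nzchar(x))) stop("lexicon terms must be non-empty", call. = FALSE)
    x
  }
  seed_terms <- norm(seed_terms)
  expanded_terms <- unique(c(seed_terms, norm(expanded_terms)))
  excluded_terms <- if (length(excluded_terms)) norm(excluded_terms) else character()
  excluded_terms <- setdiff(excluded_terms, seed_terms)
  if (length(intersect(expanded_terms, excluded_terms)) > 0L) {
    stop("expanded and excluded terms overlap", call. = FALSE)
  }
  structure(
    list(frame = frame, seed_terms = seed_terms,
         expanded_terms = expanded_terms, excluded_terms = excluded_terms),
    class = "frame_lexicon"
  )
}

#' @export
print.frame_lexicon <- function(x, ...) {
  cat("<frame_lexicon> ", x$frame, ": ", length(x$seed_terms), " seed(s), ",
      length(x$expanded_terms), " expanded term(s), ",
      length(x$excluded_terms), " excluded\n", sep = "")
  invisible(x)
}

#' Default seed terms for the three attitude frames
#'
#' The nine one-word descriptors printed as examples of the scale's stigma,
#' glorification and isolation dimensions. The full 80-descriptor inventory
#' belongs to the original scale publication and is supplied by the analyst
#' via [read_lexicons()] when available.
#'
#' @return Named list of character vectors, one per frame.
#' @export
default_seed_terms <- function() {
  list(
    stigma = c("shallow", "pathetic", "immoral"),
    glorification = c("understandable", "brave", "motivated"),
    isolation = c("unhappy", "depressed", "sad")
  )
}

#' Build a synonym source
#'
#' A synonym source answers synset-style lookups: given a word (and
#' optionally a part of speech) it returns the lemmas of all synonym groups
#' containing that word. Two constructors are provided: an in-memory list
#' and a CSV-backed table.
#'
#' @param mapping Named list: word -> character vector of synonyms, or a
#'   data frame with columns `word`, `synonym` and optionally `pos`.
#' @return An object of class `synonym_source`: a function
#'   `(word, pos = NULL) -> character vector`.
#' @export
synonym_source <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("word", "synonym") %in% names(mapping)))
    df <- mapping
    f <- function(word, pos = NULL) {
      hit <- df$word == tolower(word)
      if (!is.null(pos) && "pos" %in% names(df)) {
        hit <- hit & df$pos %in% pos
      }
      unique(tolower(df$synonym[hit]))
    }
  } else {
    stopifnot(is.list(mapping), !is.null(names(mapping)))
    names(mapping) <- tolower(names(mapping))
    f <- function(word, pos = NULL) {
      syn <- mapping[[tolower(word)]]
      if (is.null(syn)) character() else unique(tolower(syn))
    }
  }
  structure(f, class = c("synonym_source", "function"))
}

#' Load the small synonym table bundled with the package
#'
#' A compact hand-authored synonym table covering the default seed terms,
#' for examples and tests. It is a placeholder for a full lexical database
#' (such as WordNet), not a reconstruction of one.
#'
#' @return A `synonym_source`.
#' @export
bundled_synonym_source <- function() {
  path <- system.file("extdata", "synonyms-mini.csv", package = "framescore")
  synonym_source(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Expand seed terms through a synonym source
#'
#' Looks every seed up across the noun, verb, adjective and adverb classes
#' and pools the lemmas. Underscore-joined multiword lemmas are normalised
#' to space-joined phrases. The result is deduplicated and deterministic:
#' seeds first in their given order, then the remaining candidates in
#' lexicographic order. A seed with no synonyms is kept as-is with a
#' warning.
#'
#' @param seeds Character vector of seed terms.
#' @param source A `synonym_source`.
#' @return Character vector of candidate terms.
#' @export
expand_lexicon <- function(seeds, source) {
  stopifnot(length(seeds) > 0L, inherits(source, "synonym_source"))
  seeds <- tolower(trimws(seeds))
  pos_classes <- c("n", "v", "a", "r")
  candidates <- lapply(seeds, function(s) {
    lemmas <- unique(unlist(lapply(pos_classes, function(p) source(s, p))))
    if (length(lemmas) == 0L) {
      warning("no synonyms found for seed '", s, "'; kept as-is",
              call. = FALSE)
    }
    lemmas
  })
  extra <- unique(unlist(candidates))
  extra <- gsub("_", " ", extra, fixed = TRUE)
  extra <- sort(setdiff(extra, seeds), method = "radix")
  c(seeds, extra)
}

#' Record one coder's keep/remove decisions over candidate terms
#'
#' @param coder_id Identifier string.
#' @param decisions Named character vector: term -> `"keep"` or `"remove"`.
#' @return An object of class `coder_decisions`.
#' @export
coder_decisions <- function(coder_id, decisions) {
  stopifnot(is.character(decisions), !is.null(names(decisions)))
  if (!all(decisions %in% c("keep", "remove"))) {
    stop("decisions must be 'keep' or 'remove'", call. = FALSE)
  }
  structure(list(coder_id = coder_id,
                 decisions = stats::setNames(decisions,
                                             tolower(names(decisions)))),
            class = "coder_decisions")
}

#' Read coder decisions from CSV (`coder_id,term,decision`)
#'
#' @param path CSV path.
#' @return List of `coder_decisions`, one per coder in the file.
#' @export
read_coder_decisions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$coder_id), function(d) {
    coder_decisions(d$coder_id[[1L]],
                    stats::setNames(d$decision, d$term))
  })
}

#' Prune candidate terms by coder consensus
#'
#' A candidate is excluded when the coders' remove votes satisfy the policy:
#' `unanimous_remove` (every coder voted remove — the conservative default)
#' or `any_remove` (at least one did). Seeds are never excluded regardless
#' of votes.
#'
#' @param frame Frame name for the resulting lexicon.
#' @param seeds Seed terms (always retained).
#' @param candidates Candidate terms from [expand_lexicon()].
#' @param decisions List of `coder_decisions`; each coder must decide every
#'   non-seed candidate.
#' @param policy `"unanimous_remove"` or `"any_remove"`.
#' @return A `frame_lexicon` with the expanded/excluded partition.
#' @export
apply_pruning <- function(frame, seeds, candidates, decisions,
                          policy = c("unanimous_remove", "any_remove")) {
  policy <- match.arg(policy)
  stopifnot(length(decisions) >= 1L)
  seeds <- tolower(trimws(seeds))
  candidates <- unique(c(seeds, tolower(trimws(candidates))))
  judged <- setdiff(candidates, seeds)
  votes <- vapply(judged, function(term) {
    per_coder <- vapply(decisions, function(cd) {
      d <- unname(cd$decisions[term])
      if (is.na(d)) {
        stop("coder ", cd$coder_id, " has no decision for term '", term, "'",
             call. = FALSE)
      }
      d == "remove"
    }, logical(1))
    switch(policy,
           unanimous_remove = all(per_coder),
           any_remove = any(per_coder))
  }, logical(1))
  excluded <- judged[votes]
  frame_lexicon(frame, seeds,
                expanded_terms = setdiff(candidates, excluded),
                excluded_terms = excluded)
}

#' Read frame lexicons from CSV (`frame,term,role`)
#'
#' `role` is one of `seed`, `expanded`, `excluded`.
#'
#' @param path CSV path.
#' @return Named list of `frame_lexicon` objects.
#' @export
read_lexicons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "term", "role") %in% names(df)))
  lapply(split(df, df$frame), function(d) {
    frame_lexicon(
      d$frame[[1L]],
      seed_terms = d$term[d$role == "seed"],
      expanded_terms = d$term[d$role %in% c("seed", "expanded")],
      excluded_terms = d$term[d$role == "excluded"]
    )
  })
}

#' Write frame lexicons to CSV (`frame,term,role`)
#'
#' @param lexicons Named list of `frame_lexicon` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lexicons <- function(lexicons, path) {
  rows <- lapply(lexicons, function(lx) {
    rbind(
      data.frame(frame = lx$frame, term = lx$seed_terms, role = "seed"),
      if (length(setdiff(lx$expanded_terms, lx$seed_terms)))
        data.frame(frame = lx$frame,
                   term = setdiff(lx$expanded_terms, lx$seed_terms),
                   role = "expanded"),
      if (length(lx$excluded_terms))
        data.frame(frame = lx$frame, term = lx$excluded_terms,
                   role = "excluded")
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Default frame lexicons (seeds only, no expansion)
#'
#' @return Named list of `frame_lexicon` objects for the three frames.
#' @export
default_lexicons <- function() {
  seeds <- default_seed_terms()
  stats::setNames(
    lapply(names(seeds), function(f) frame_lexicon(f, seeds[[f]])),
    names(seeds)
  )
}
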