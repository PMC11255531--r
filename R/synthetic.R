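#' Specification for a synthetic annotated news corpus
#'
#' Defines the study conditions a generated corpus emulates: how many
#' decedents of each gender, how circumstances are distributed within each
#' gender, and at what rate frame-lexicon tokens are injected into the
#' background token stream for each (gender, circumstance, frame) cell.
#' Defaults mirror the observed composition of the annotated study sample:
#' 153 male and 64 female decedents, with circumstance frequencies taken
#' from the per-gender attribution counts of the top seven circumstances.
#'
#' @param n_male,n_female Number of decedents per gender.
#' @param circumstance_distribution Named list `gender -> named numeric
#'   vector` of circumstance probabilities (each summing to 1).
#' @param injection_rates Tibble with columns `gender`, `circumstance`,
#'   `frame`, `rate`; `"*"` is a wildcard for gender or circumstance. A
#'   missing cell means rate 0.
#' @param background_vocab_size Number of distinct synthetic background
#'   tokens (`tok0001`, ...).
#' @param sentences_per_article Length-2 integer range (inclusive).
#' @param tokens_per_sentence Length-2 integer range (inclusive).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_male = 153L, n_female = 64L,
                           circumstance_distribution = NULL,
                           injection_rates = NULL,
                           background_vocab_size = 500L,
                           sentences_per_article = c(6L, 10L),
                           tokens_per_sentence = c(10L, 14L),
                           seed = 1L) {
  if (is.null(circumstance_distribution)) {
    circumstance_distribution <- list(
      cis_male = c(unspecified = 35, legal_problem = 31, mental_health = 29,
                   social_relationship = 21, physical_health = 24,
                   financial_job = 10, preceding_suicidality = 9) / 159,
      cis_female = c(unspecified = 24, legal_problem = 9, mental_health = 8,
                     social_relationship = 13, physical_health = 8,
                     financial_job = 9, preceding_suicidality = 4) / 75
    )
  }
  for (g in names(circumstance_distribution)) {
    p <- circumstance_distribution[[g]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("circumstance distribution for ", g, " must sum to 1",
           call. = FALSE)
    }
  }
  if (is.null(injection_rates)) {
    injection_rates <- tibble::tibble(gender = character(),
                                      circumstance = character(),
                                      frame = character(), rate = numeric())
  }
  if (any(injection_rates$rate < 0 | injection_rates$rate > 1)) {
    stop("injection rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_male >= 1L, n_female >= 1L, background_vocab_size >= 1L,
            length(sentences_per_article) == 2L,
            length(tokens_per_sentence) == 2L,
            sentences_per_article[1] >= 1L,
            sentences_per_article[1] <= sentences_per_article[2],
            tokens_per_sentence[1] >= 1L,
            tokens_per_sentence[1] <= tokens_per_sentence[2])
  structure(
    list(n_male = as.integer(n_male), n_female = as.integer(n_female),
         circumstance_distribution = circumstance_distribution,
         injection_rates = injection_rates,
         background_vocab_size = as.integer(background_vocab_size),
         sentences_per_article = as.integer(sentences_per_article),
         tokens_per_sentence = as.integer(tokens_per_sentence),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_male, " male + ", x$n_female,
      " female decedents, vocab ", x$background_vocab_size,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

lexicon_token_vocabulary <- function(lexicons) {
  unique(unlist(lapply(lexicons, function(lx) {
    unlist(lapply(lx$expanded_terms, hash_tokenize))
  })))
}

lookup_rate <- function(rates, gender, circumstance, frame) {
  hit <- (rates$frame == frame) &
    (rates$gender == gender | rates$gender == "*") &
    (rates$circumstance == circumstance | rates$circumstance == "*")
  if (!any(hit)) 0 else rates$rate[which(hit)[1L]]
}

#' Generate a synthetic annotated corpus with known framing structure
#'
#' Every synthetic decedent receives a gender and a circumstance drawn from
#' the spec, and an article built from background tokens into which terms
#' from each frame lexicon are injected i.i.d. at the (gender,
#' circumstance, frame) rate. The background vocabulary is synthetic token
#' strings, guaranteed disjoint from real-word lexicons, so the hash
#' backend sees near-orthogonal background text. The output is fully
#' deterministic given the spec.
#'
#' @param spec A `synthetic_spec`.
#' @param lexicons Named list of `frame_lexicon` objects whose terms are
#'   injected.
#' @return List with `articles` (corpus tibble), `annotations` (annotation
#'   tibble, one decedent per article), and `ground_truth` (tibble of
#'   realized injected/total token counts per gender, circumstance and
#'   frame).
#' @export
generate_corpus <- function(spec, lexicons = default_lexicons()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- sprintf("tok%04d", seq_len(spec$background_vocab_size))
  lex_vocab <- lexicon_token_vocabulary(lexicons)
  clash <- intersect(vocab, lex_vocab)
  if (length(clash) > 0L) {
    stop("lexicon vocabulary overlaps the background vocabulary (",
         paste(utils::head(clash, 3), collapse = ", "),
         "); frames would be confounded", call. = FALSE)
  }
  frame_names <- vapply(lexicons, function(lx) lx$frame, character(1))

  set.seed(spec$seed)
  genders <- c(rep("cis_male", spec$n_male), rep("cis_female", spec$n_female))
  n <- length(genders)
  circs <- vapply(genders, function(g) {
    p <- spec$circumstance_distribution[[g]]
    if (is.null(p)) stop("no circumstance distribution for gender ", g,
                         call. = FALSE)
    sample(names(p), 1L, prob = p)
  }, character(1))

  texts <- character(n)
  gt <- list()
  for (i in seq_len(n)) {
    n_sent <- sample(seq(spec$sentences_per_article[1],
                         spec$sentences_per_article[2]), 1L)
    sent_lens <- sample(seq(spec$tokens_per_sentence[1],
                            spec$tokens_per_sentence[2]), n_sent,
                        replace = TRUE)
    n_tok <- sum(sent_lens)
    tokens <- sample(vocab, n_tok, replace = TRUE)
    taken <- rep(FALSE, n_tok)
    injected <- stats::setNames(integer(length(frame_names)), frame_names)
    for (f in frame_names) {
      rate <- lookup_rate(spec$injection_rates, genders[[i]], circs[[i]], f)
      if (rate > 0) {
        hit <- !taken & stats::runif(n_tok) < rate
        if (any(hit)) {
          terms <- lexicons[[which(frame_names == f)[1L]]]$expanded_terms
          tokens[hit] <- sample(terms, sum(hit), replace = TRUE)
          taken <- taken | hit
          injected[[f]] <- sum(hit)
        }
      }
    }
    gt[[i]] <- tibble::tibble(
      gender = genders[[i]], circumstance = circs[[i]],
      frame = frame_names, n_injected = as.integer(injected),
      n_tokens = n_tok
    )
    ends <- cumsum(sent_lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    sentences <- vapply(seq_len(n_sent), function(s) {
      paste0(paste(tokens[starts[s]:ends[s]], collapse = " "), ".")
    }, character(1))
    texts[[i]] <- paste(sentences, collapse = " ")
  }

  ground_truth <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(gt), .data$gender, .data$circumstance,
                    .data$frame),
    n_injected = sum(.data$n_injected),
    n_tokens = sum(.data$n_tokens),
    .groups = "drop"
  )
  ground_truth$realized_rate <- ground_truth$n_injected / ground_truth$n_tokens

  ids <- sprintf("art%05d", seq_len(n))
  list(
    articles = tibble::tibble(
      article_id = ids, text = texts, source = "synthetic",
      date = NA_character_
    ),
    annotations = tibble::tibble(
      article_id = ids,
      victim_id = sprintf("vic%05d", seq_len(n)),
      gender = genders,
      circumstances = as.list(circs),
      span_start = NA_integer_,
      span_end = NA_integer_
    ),
    ground_truth = ground_truth
  )
}

#' Generate mixed-gender articles with valid character spans
#'
#' Each article concatenates one male-decedent and one female-decedent text
#' segment and carries two annotations whose 0-based half-open spans slice
#' exactly their segment — the input shape that forces per-decedent span
#' resolution in [resolve_victims()].
#'
#' @param spec A `synthetic_spec` (controls segment sizes and the seed).
#' @param k Number of mixed-gender articles.
#' @return List with `articles` and `annotations` tibbles (2 annotations
#'   per article).
#' @export
generate_mixed_gender_articles <- function(spec, k) {
  stopifnot(inherits(spec, "synthetic_spec"), k >= 1L)
  vocab <- sprintf("tok%04d", seq_len(spec$background_vocab_size))
  set.seed(spec$seed + 1L)
  segment <- function() {
    n_tok <- sample(seq(spec$tokens_per_sentence[1],
                        spec$tokens_per_sentence[2]), 1L)
    paste0(paste(sample(vocab, n_tok, replace = TRUE), collapse = " "), ".")
  }
  arts <- vector("list", k)
  anns <- vector("list", k)
  for (i in seq_len(k)) {
    seg_m <- segment()
    seg_f <- segment()
    text <- paste(seg_m, seg_f)
    id <- sprintf("mix%05d", i)
    arts[[i]] <- tibble::tibble(article_id = id, text = text,
                                source = "synthetic", date = NA_character_)
    anns[[i]] <- tibble::tibble(
      article_id = id,
      victim_id = sprintf("mixvic%05d%s", i, c("m", "f")),
      gender = c("cis_male", "cis_female"),
      circumstances = list("unspecified", "unspecified"),
      span_start = c(0L, nchar(seg_m) + 1L),
      span_end = c(nchar(seg_m), nchar(text))
    )
  }
  list(articles = dplyr::bind_rows(arts), annotations = dplyr::bind_rows(anns))
}
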