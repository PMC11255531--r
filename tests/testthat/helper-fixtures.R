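# Shared fixtures and independent oracles for the test suite.

# Write a small JSONL corpus and return its path.
write_corpus_fixture <- function(texts, ids = sprintf("a%02d", seq_along(texts)),
                                 path = withr::local_tempfile(fileext = ".jsonl",
                                                              .local_envir = parent.frame())) {
  lines <- vapply(seq_along(texts), function(i) {
    jsonlite::toJSON(list(article_id = ids[[i]], text = texts[[i]],
                          source = "fixture"), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  path
}

make_annotations <- function(article_id, victim_id, gender, circumstances,
                             span_start = NA_integer_, span_end = NA_integer_) {
  tibble::tibble(
    article_id = article_id, victim_id = victim_id, gender = gender,
    circumstances = circumstances,
    span_start = as.integer(span_start), span_end = as.integer(span_end)
  )
}

# A lookup-table embedder used where tests need vectors with known values.
stub_backend <- function(vectors) {
  structure(list(name = "stub", dimension = length(vectors[[1L]]),
                 vectors = vectors),
            class = c("stub_backend", "embedder"))
}
embed_text.stub_backend <- function(backend, text) {
  v <- backend$vectors[[text]]
  if (is.null(v)) stop("stub backend has no vector for '", text, "'")
  v
}
registerS3method("embed_text", "stub_backend", embed_text.stub_backend,
                 envir = asNamespace("framescore"))

# Exhaustive two-sided permutation p-value for the Mann-Whitney U statistic:
# enumerates every assignment of the pooled values to the two groups.
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  r <- rank(pooled)
  u_of <- function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  center <- n_a * (n - n_a) / 2
  assignments <- utils::combn(n, n_a)
  us <- apply(assignments, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Victim tibble straight from a generated synthetic corpus.
victims_from_synth <- function(gen) {
  tibble::tibble(
    victim_id = gen$annotations$victim_id,
    gender = gen$annotations$gender,
    circumstances = gen$annotations$circumstances,
    text = gen$articles$text
  )
}

# Study-condition run: gender-differential stigma injection, hash backend.
gender_injection_pvalues <- function(rep_seed, n_per_gender = 100L,
                                     rate_male = 0.15, rate_female = 0.05) {
  backend <- hash_backend(seed = 100L + rep_seed)
  rates <- tibble::tibble(
    gender = c("cis_male", "cis_female"), circumstance = "*",
    frame = "stigma", rate = c(rate_male, rate_female)
  )
  spec <- synthetic_spec(n_male = n_per_gender, n_female = n_per_gender,
                         injection_rates = rates, seed = 1000L + rep_seed)
  gen <- generate_corpus(spec)
  centroids <- frame_vectors(default_lexicons(), backend)
  scores <- score_corpus(victims_from_synth(gen), centroids, backend)
  vapply(c("stigma", "glorification"), function(f) {
    s <- scores[scores$frame == f, ]
    mann_whitney(s$score[s$gender == "cis_male"],
                 s$score[s$gender == "cis_female"])$p
  }, numeric(1))
}

# Which circumstance wins the stigma MI column under targeted injection.
targeted_mi_winner <- function(rep_seed, circumstance = "legal_problem",
                               rate = 0.2) {
  backend <- hash_backend(seed = 200L + rep_seed)
  rates <- tibble::tibble(gender = "cis_male", circumstance = circumstance,
                          frame = "stigma", rate = rate)
  spec <- synthetic_spec(n_male = 100L, n_female = 100L,
                         injection_rates = rates, seed = 2000L + rep_seed)
  gen <- generate_corpus(spec)
  centroids <- frame_vectors(default_lexicons(), backend)
  scores <- score_corpus(victims_from_synth(gen), centroids, backend)
  mi <- suppressWarnings(stratified_mi(scores, frames = "stigma"))
  mi$circumstance[[which.max(mi$mi)]]
}

# Per-gender circumstance attribution counts printed in the study's summary
# table (row order follows top_circumstances()).
table1_counts <- function() {
  list(
    cis_male = c(unspecified = 35L, legal_problem = 31L, mental_health = 29L,
                 social_relationship = 21L, physical_health = 24L,
                 financial_job = 10L, preceding_suicidality = 9L),
    cis_female = c(unspecified = 24L, legal_problem = 9L, mental_health = 8L,
                   social_relationship = 13L, physical_health = 8L,
                   financial_job = 9L, preceding_suicidality = 4L)
  )
}

# Expand printed counts into one single-circumstance annotation per count.
table1_annotations <- function() {
  counts <- table1_counts()
  rows <- list()
  k <- 0L
  for (g in names(counts)) {
    for (circ in names(counts[[g]])) {
      for (i in seq_len(counts[[g]][[circ]])) {
        k <- k + 1L
        rows[[k]] <- make_annotations(sprintf("t1a%03d", k),
                                      sprintf("t1v%03d", k), g, list(circ))
      }
    }
  }
  dplyr::bind_rows(rows)
}
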