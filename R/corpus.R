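#' Read a news corpus from JSONL
#'
#' One JSON object per line with keys `article_id`, `text`, and optionally
#' `source` and `date`. Lines are validated individually so a malformed
#' record is reported with its line number.
#'
#' @param path Path to a UTF-8 JSONL file.
#' @return A tibble with columns `article_id`, `text`, `source`, `date`
#'   (character; `NA` where absent), one row per article in file order.
#' @export
read_corpus <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("corpus file is empty: ", path, call. = FALSE)
    return(tibble::tibble(
      article_id = character(), text = character(),
      source = character(), date = character()
    ))
  }
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("malformed JSON on line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (is.null(obj$article_id) || is.null(obj$text)) {
      stop("line ", i, ": missing required field ",
           if (is.null(obj$article_id)) "'article_id'" else "'text'",
           call. = FALSE)
    }
    if (!nzchar(trimws(obj$text))) {
      stop("line ", i, ": article text is empty", call. = FALSE)
    }
    tibble::tibble(
      article_id = as.character(obj$article_id),
      text = as.character(obj$text),
      source = if (is.null(obj$source)) NA_character_ else as.character(obj$source),
      date = if (is.null(obj$date)) NA_character_ else as.character(obj$date)
    )
  })
  corpus <- dplyr::bind_rows(rows)
  dup <- corpus$article_id[duplicated(corpus$article_id)]
  if (length(dup) > 0L) {
    stop("duplicate article_id in corpus: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  message(nrow(corpus), " articles read from ", path)
  corpus
}

#' Write a corpus to JSONL
#'
#' @param corpus Tibble as returned by [read_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(all(c("article_id", "text") %in% names(corpus)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(
      article_id = corpus$article_id[[i]],
      text = corpus$text[[i]]
    )
    if ("source" %in% names(corpus) && !is.na(corpus$source[[i]])) {
      rec$source <- corpus$source[[i]]
    }
    if ("date" %in% names(corpus) && !is.na(corpus$date[[i]])) {
      rec$date <- corpus$date[[i]]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Gender identity labels recognised by the annotation scheme
#' @export
gender_levels <- function() {
  c("cis_male", "cis_female", "trans_male", "trans_female", "unspecified")
}

#' The seven most frequent circumstance-of-suicide codes
#'
#' The annotation scheme is user-extensible; these named codes cover the
#' circumstances analysed throughout the package.
#' @export
top_circumstances <- function() {
  c("unspecified", "legal_problem", "mental_health", "social_relationship",
    "physical_health", "financial_job", "preceding_suicidality")
}

#' Read victim-level annotations from CSV
#'
#' Expected header: `article_id,victim_id,gender,circumstances,span_start,
#' span_end`. Circumstances are semicolon-delimited; span cells may be empty.
#' Spans are 0-based, half-open character offsets into the article text.
#'
#' @param path CSV path.
#' @return Tibble with columns `article_id`, `victim_id`, `gender`,
#'   `circumstances` (list of character vectors), `span_start`, `span_end`
#'   (integer, `NA` when absent).
#' @export
read_annotations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("article_id", "victim_id", "gender", "circumstances")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("annotation file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(raw$gender), gender_levels())
  if (length(bad) > 0L) {
    stop("unknown gender label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  circ <- lapply(strsplit(raw$circumstances, ";", fixed = TRUE), function(x) {
    x <- trimws(x)
    x <- x[nzchar(x)]
    if (length(x) == 0L) "unspecified" else x
  })
  to_int <- function(x) {
    if (is.null(x)) return(rep(NA_integer_, nrow(raw)))
    suppressWarnings(as.integer(ifelse(nzchar(trimws(x)), x, NA)))
  }
  tibble::tibble(
    article_id = raw$article_id,
    victim_id = raw$victim_id,
    gender = raw$gender,
    circumstances = circ,
    span_start = to_int(raw$span_start),
    span_end = to_int(raw$span_end)
  )
}

#' Write victim-level annotations to CSV
#'
#' @param annotations Tibble as returned by [read_annotations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(
    article_id = annotations$article_id,
    victim_id = annotations$victim_id,
    gender = annotations$gender,
    circumstances = vapply(annotations$circumstances, paste,
                           character(1), collapse = ";"),
    span_start = ifelse(is.na(annotations$span_start), "",
                        as.character(annotations$span_start)),
    span_end = ifelse(is.na(annotations$span_end), "",
                      as.character(annotations$span_end)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Build a keyword filter rule set
#'
#' An article is retained when its lowercased text contains at least one
#' include keyword (matched case-insensitively on word boundaries) and
#' matches none of the exclude patterns. Exclude rules are ordered: an
#' excluded article is attributed to the first rule that matches it.
#'
#' @param include_keywords Character vector of keywords; must be non-empty.
#' @param exclude_rules Named list: reason label -> character vector of
#'   patterns. Conventional labels are `homicide_suicide`, `bombing`,
#'   `attempt`, `euphemism`, `fiction`, `other`.
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(include_keywords, exclude_rules = list()) {
  include_keywords <- tolower(trimws(include_keywords))
  if (length(include_keywords) == 0L || !all(nzchar(include_keywords))) {
    stop("include_keywords must be a non-empty set of non-empty strings",
         call. = FALSE)
  }
  if (length(exclude_rules) > 0L) {
    if (is.null(names(exclude_rules)) || anyDuplicated(names(exclude_rules))) {
      stop("exclude_rules must have unique reason labels", call. = FALSE)
    }
    exclude_rules <- lapply(exclude_rules, function(p) {
      p <- tolower(trimws(p))
      if (any(!nzchar(p))) stop("empty exclude pattern", call. = FALSE)
      p
    })
  }
  structure(
    list(include_keywords = include_keywords, exclude_rules = exclude_rules),
    class = "filter_rules"
  )
}

#' @export
print.filter_rules <- function(x, ...) {
  cat("<filter_rules> ", length(x$include_keywords), " include keyword(s), ",
      length(x$exclude_rules), " exclude rule(s)\n", sep = "")
  invisible(x)
}

#' Read a filter rule set from a YAML config block
#'
#' Layout: `include_keywords:` a list of strings, `exclude_rules:` a list of
#' maps with keys `reason` and `patterns`.
#'
#' @param path YAML path.
#' @return A `filter_rules` object.
#' @export
read_filter_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  ex <- list()
  for (rule in cfg$exclude_rules) {
    ex[[rule$reason]] <- unlist(rule$patterns)
  }
  filter_rules(unlist(cfg$include_keywords), ex)
}

#' Default filter rule set
#'
#' A small keyword list for tests and examples. The keyword inventory used
#' for large-scale screening is domain-curated and should be supplied by the
#' analyst; this default is a placeholder, not a curated inventory.
#' @return A `filter_rules` object.
#' @export
default_filter_rules <- function() {
  filter_rules(
    include_keywords = c("suicide", "killed himself", "killed herself",
                         "took his own life", "took her own life",
                         "died by suicide"),
    exclude_rules = list(
      homicide_suicide = c("murder-suicide", "homicide-suicide",
                           "killed his wife", "killed her husband"),
      bombing = c("suicide bomb", "suicide bomber", "suicide bombing",
                  "suicide attack"),
      attempt = c("suicide attempt", "attempted suicide", "survived"),
      euphemism = c("political suicide", "career suicide", "suicide mission"),
      fiction = c("movie", "film", "novel", "fiction", "episode", "character")
    )
  )
}

word_boundary_regex <- function(keyword) {
  paste0("\\b", stringr::str_replace_all(keyword,
    "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1"), "\\b")
}

#' Filter a corpus with inclusion and exclusion rules
#'
#' @param corpus Article tibble from [read_corpus()].
#' @param rules A `filter_rules` object.
#' @return List with `included` (article tibble) and `exclusion_report`
#'   (named integer vector: reason label -> count; articles with no include
#'   keyword are counted under `no_keyword`). Every input article appears
#'   exactly once, either in `included` or in one exclusion count.
#' @export
filter_corpus <- function(corpus, rules) {
  stopifnot(inherits(rules, "filter_rules"))
  text <- tolower(corpus$text)
  inc_rx <- vapply(rules$include_keywords, word_boundary_regex, character(1))
  has_kw <- Reduce(`|`, lapply(inc_rx, function(rx) {
    stringr::str_detect(text, stringr::regex(rx))
  }), init = rep(FALSE, length(text)))

  reason <- rep(NA_character_, length(text))
  reason[!has_kw] <- "no_keyword"
  for (label in names(rules$exclude_rules)) {
    rxs <- vapply(rules$exclude_rules[[label]], word_boundary_regex,
                  character(1))
    hit <- Reduce(`|`, lapply(rxs, function(rx) {
      stringr::str_detect(text, stringr::regex(rx))
    }), init = rep(FALSE, length(text)))
    assign_now <- is.na(reason) & hit
    reason[assign_now] <- label
  }

  included <- corpus[is.na(reason), , drop = FALSE]
  excluded <- reason[!is.na(reason)]
  report <- if (length(excluded) > 0L) {
    tab <- table(excluded)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  stopifnot(nrow(included) + sum(report) == nrow(corpus))
  list(included = included, exclusion_report = report)
}

#' Resolve one article into decedent-level records
#'
#' When every annotation of the article shares one gender the article is
#' treated as reporting a single death of that gender: one record carrying
#' the union of the annotated circumstances and the full article text. When
#' genders differ, every annotation must carry a character span (0-based,
#' half-open) and one record per annotation is produced with the span slice
#' as its text.
#'
#' @param article One-row article tibble (or list with `article_id`, `text`).
#' @param annotations Annotation tibble; all rows must reference the article.
#' @return Tibble with columns `victim_id`, `gender`, `circumstances`
#'   (list-column), `text`.
#' @export
resolve_victims <- function(article, annotations) {
  if (is.data.frame(article)) {
    stopifnot(nrow(article) == 1L)
    article <- as.list(article)
  }
  if (nrow(annotations) == 0L) {
    stop("no annotations supplied for article ", article$article_id,
         call. = FALSE)
  }
  if (!all(annotations$article_id == article$article_id)) {
    stop("annotations reference a different article_id", call. = FALSE)
  }
  genders <- unique(annotations$gender)
  if (length(genders) == 1L) {
    return(tibble::tibble(
      victim_id = annotations$victim_id[[1L]],
      gender = genders,
      circumstances = list(sort(unique(unlist(annotations$circumstances)))),
      text = article$text
    ))
  }
  n_chr <- nchar(article$text)
  missing_span <- is.na(annotations$span_start) | is.na(annotations$span_end)
  if (any(missing_span)) {
    stop("article ", article$article_id, " mentions victims of different ",
         "genders; every annotation needs a character span (victim ",
         paste(annotations$victim_id[missing_span], collapse = ", "),
         " lacks one). Supply span_start/span_end (0-based, half-open).",
         call. = FALSE)
  }
  ok <- annotations$span_start >= 0L &
    annotations$span_start < annotations$span_end &
    annotations$span_end <= n_chr
  if (!all(ok)) {
    stop("invalid span for victim ",
         paste(annotations$victim_id[!ok], collapse = ", "),
         " (need 0 <= start < end <= ", n_chr, ")", call. = FALSE)
  }
  tibble::tibble(
    victim_id = annotations$victim_id,
    gender = annotations$gender,
    circumstances = annotations$circumstances,
    text = substr(rep(article$text, nrow(annotations)),
                  annotations$span_start + 1L, annotations$span_end)
  )
}

#' Resolve a whole corpus into decedent-level records
#'
#' Applies [resolve_victims()] article by article. Annotations whose article
#' is not present in `corpus` (e.g. dropped by filtering) are discarded with
#' a warning.
#'
#' @param corpus Article tibble.
#' @param annotations Annotation tibble.
#' @return Victim tibble (`victim_id`, `gender`, `circumstances`, `text`).
#' @export
resolve_corpus_victims <- function(corpus, annotations) {
  known <- annotations$article_id %in% corpus$article_id
  if (any(!known)) {
    warning(sum(!known), " annotation(s) reference articles absent from the ",
            "filtered corpus and were dropped", call. = FALSE)
    annotations <- annotations[known, , drop = FALSE]
  }
  ids <- unique(annotations$article_id)
  out <- lapply(ids, function(id) {
    resolve_victims(corpus[corpus$article_id == id, , drop = FALSE],
                    annotations[annotations$article_id == id, , drop = FALSE])
  })
  dplyr::bind_rows(out)
}
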