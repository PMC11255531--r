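test_that("read_corpus ingests articles in file order and validates lines", {
  path <- write_corpus_fixture(c("one text.", "two text.", "three text."))
  suppressMessages(corpus <- read_corpus(path))
  expect_equal(nrow(corpus), 3L)
  expect_equal(corpus$article_id, c("a01", "a02", "a03"))
  expect_equal(corpus$text[[2]], "two text.")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), empty)
  expect_warning(out <- read_corpus(empty), "empty")
  expect_equal(nrow(out), 0L)

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"article_id":"x","text":"ok"}', '{"article_id":"y"}'), bad)
  expect_error(suppressMessages(read_corpus(bad)), "line 2.*text")

  dup <- write_corpus_fixture(c("a.", "b."), ids = c("same", "same"))
  expect_error(suppressMessages(read_corpus(dup)), "duplicate")

  malformed <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"article_id":"x","text":"ok"}', "{not json"), malformed)
  expect_error(suppressMessages(read_corpus(malformed)), "line 2")
})

test_that("filter_corpus includes by keyword, excludes by first matching rule", {
  corpus <- tibble::tibble(
    article_id = sprintf("f%d", 1:5),
    text = c("A suicide was reported in the town.",
             "The suicide bombing killed twelve.",
             "Stock markets fell sharply today.",
             "He died by suicide last week, officials said.",
             "Another suicide occurred on Tuesday."),
    source = "fx", date = NA_character_
  )
  rules <- filter_rules(
    include_keywords = "suicide",
    exclude_rules = list(bombing = c("suicide bombing"),
                         attempt = c("suicide attempt"))
  )
  res <- filter_corpus(corpus, rules)
  expect_equal(nrow(res$included), 3L)
  expect_equal(res$exclusion_report[["bombing"]], 1L)
  expect_equal(res$exclusion_report[["no_keyword"]], 1L)
  expect_equal(nrow(res$included) + sum(res$exclusion_report), nrow(corpus))
})

test_that("an article matching two exclude rules is counted once, first rule wins", {
  corpus <- tibble::tibble(
    article_id = "x1",
    text = "The suicide bombing followed a suicide attempt.",
    source = "fx", date = NA_character_
  )
  rules <- filter_rules("suicide",
                        list(bombing = "suicide bombing",
                             attempt = "suicide attempt"))
  res <- filter_corpus(corpus, rules)
  expect_equal(sum(res$exclusion_report), 1L)
  expect_equal(names(res$exclusion_report), "bombing")

  flipped <- filter_rules("suicide",
                          list(attempt = "suicide attempt",
                               bombing = "suicide bombing"))
  expect_equal(names(filter_corpus(corpus, flipped)$exclusion_report),
               "attempt")
})

test_that("filtering is idempotent and conserves article counts", {
  set.seed(11)
  texts <- c(
    replicate(30, paste("a suicide was reported in sector",
                        sample(1000, 1))),
    replicate(10, paste("a suicide bombing hit sector", sample(1000, 1))),
    replicate(10, paste("quiet day in sector", sample(1000, 1)))
  )
  corpus <- tibble::tibble(article_id = sprintf("c%02d", seq_along(texts)),
                           text = texts, source = "fx", date = NA_character_)
  rules <- filter_rules("suicide", list(bombing = "suicide bombing"))
  first <- filter_corpus(corpus, rules)
  expect_equal(nrow(first$included) + sum(first$exclusion_report), 50L)
  second <- filter_corpus(first$included, rules)
  expect_identical(second$included, first$included)
  expect_equal(sum(second$exclusion_report), 0L)
})

test_that("study-scale screening arithmetic: 800 sampled minus 600 excluded leaves 200", {
  # 800 candidate articles of which 600 carry an exclusion marker
  reasons <- rep(c("bombing", "attempt", "euphemism", "fiction",
                   "homicide_suicide", "included"),
                 c(150, 150, 100, 100, 100, 200))
  marker <- c(bombing = "suicide bombing", attempt = "suicide attempt",
              euphemism = "political suicide", fiction = "a fictional suicide",
              homicide_suicide = "murder-suicide", included = "died by suicide")
  corpus <- tibble::tibble(
    article_id = sprintf("s%03d", seq_along(reasons)),
    text = paste("report mentions", marker[reasons], "in the region"),
    source = "fx", date = NA_character_
  )
  rules <- filter_rules("suicide", list(
    homicide_suicide = "murder-suicide", bombing = "suicide bombing",
    attempt = "suicide attempt", euphemism = "political suicide",
    fiction = "fictional"
  ))
  res <- filter_corpus(corpus, rules)
  expect_equal(nrow(res$included), 200L)
  expect_equal(sum(res$exclusion_report), 600L)
})

test_that("empty include keyword set is rejected", {
  expect_error(filter_rules(character()), "non-empty")
})

test_that("same-gender annotations collapse to one record with the union of circumstances", {
  article <- tibble::tibble(article_id = "m1",
                            text = "Full article text about one man.")
  ann <- make_annotations(
    c("m1", "m1"), c("v1", "v2"), c("cis_male", "cis_male"),
    list("legal_problem", "financial_job")
  )
  rec <- resolve_victims(article, ann)
  expect_equal(nrow(rec), 1L)
  expect_setequal(rec$circumstances[[1]], c("financial_job", "legal_problem"))
  expect_equal(rec$text, article$text)
})

test_that("mixed-gender annotations need spans and yield per-victim slices", {
  text <- "He was remembered fondly. She was remembered too."
  article <- tibble::tibble(article_id = "m2", text = text)
  ann <- make_annotations(
    c("m2", "m2"), c("v1", "v2"), c("cis_male", "cis_female"),
    list("unspecified", "unspecified"),
    span_start = c(0L, 26L), span_end = c(25L, 49L)
  )
  rec <- resolve_victims(article, ann)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$text[[1]], "He was remembered fondly.")
  expect_equal(rec$text[[2]], "She was remembered too.")

  ann$span_start[2] <- NA_integer_
  expect_error(resolve_victims(article, ann), "span")

  ann$span_start[2] <- 26L
  ann$span_end[2] <- 100L
  expect_error(resolve_victims(article, ann), "0 <= start < end")
})

test_that("corpus-level resolution drops orphan annotations with a warning and bounds record count", {
  corpus <- tibble::tibble(article_id = c("k1", "k2"),
                           text = c("First article text.", "Second one."),
                           source = "fx", date = NA_character_)
  ann <- make_annotations(
    c("k1", "k1", "k2", "gone"), sprintf("v%d", 1:4),
    c("cis_male", "cis_male", "cis_female", "cis_male"),
    list("unspecified", "legal_problem", "unspecified", "unspecified")
  )
  expect_warning(rec <- resolve_corpus_victims(corpus, ann), "dropped")
  expect_lte(nrow(rec), nrow(ann))
  expect_equal(nrow(rec), 2L)  # one per same-gender article
})

test_that("annotation CSV round-trips through write and read", {
  ann <- make_annotations(
    c("r1", "r1"), c("v1", "v2"), c("cis_male", "cis_female"),
    list(c("legal_problem", "mental_health"), "unspecified"),
    span_start = c(0L, NA), span_end = c(10L, NA)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$circumstances, ann$circumstances)
  expect_equal(back$span_start, ann$span_start)
  expect_equal(back$gender, ann$gender)
})
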