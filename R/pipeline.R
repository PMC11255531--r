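#' Assemble and validate a pipeline configuration
#'
#' All paths are checked up front so a misconfigured run fails before any
#' computation. Lexicon and filter-rule paths are optional; the bundled
#' defaults are used when they are absent.
#'
#' @param corpus Path to the JSONL corpus.
#' @param annotations Path to the annotation CSV.
#' @param output_dir Directory for all outputs (created if missing).
#' @param lexicons Optional lexicon CSV (`frame,term,role`).
#' @param filter_rules Optional YAML filter rule file.
#' @param backend List: `type` (only `"hash"` is built in), `dimension`,
#'   `seed`.
#' @param bins Number of shared equal-width bins for mutual information.
#' @param genders Length-2 gender pair compared; other identities are
#'   scored but excluded from the comparisons.
#' @param frames Frames to analyse (`NULL` = all lexicon frames).
#' @param circumstances Circumstances for the stratified analysis.
#' @param seed Master seed recorded in the run log.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, annotations, output_dir,
                            lexicons = NULL, filter_rules = NULL,
                            backend = list(type = "hash", dimension = 2048L,
                                           seed = 1L),
                            bins = 10L,
                            genders = c("cis_male", "cis_female"),
                            frames = NULL,
                            circumstances = top_circumstances(),
                            seed = 1L) {
  for (p in c(corpus, annotations, lexicons, filter_rules)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", p, call. = FALSE)
    }
  }
  stopifnot(length(genders) == 2L, bins >= 2L)
  if (!identical(backend$type, "hash")) {
    stop("unknown backend type '", backend$type,
         "'; the built-in backend is 'hash'", call. = FALSE)
  }
  structure(
    list(corpus = corpus, annotations = annotations,
         output_dir = output_dir, lexicons = lexicons,
         filter_rules = filter_rules, backend = backend,
         bins = as.integer(bins), genders = genders, frames = frames,
         circumstances = circumstances, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `paths:` may
#' group `corpus`, `annotations`, `lexicons`, `filter_rules`, `output_dir`.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- cfg$paths %||% cfg
  backend <- cfg$backend %||% list(type = "hash", dimension = 2048L, seed = 1L)
  backend$dimension <- as.integer(backend$dimension %||% 2048L)
  backend$seed <- as.integer(backend$seed %||% 1L)
  backend$type <- backend$type %||% "hash"
  pipeline_config(
    corpus = paths$corpus,
    annotations = paths$annotations,
    output_dir = paths$output_dir %||% ".",
    lexicons = paths$lexicons,
    filter_rules = paths$filter_rules,
    backend = backend,
    bins = cfg$bins %||% 10L,
    genders = unlist(cfg$genders %||% c("cis_male", "cis_female")),
    frames = if (!is.null(cfg$frames)) unlist(cfg$frames),
    circumstances = unlist(cfg$circumstances %||% top_circumstances()),
    seed = cfg$seed %||% 1L
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the framing pipeline end to end
#'
#' Filter the corpus, resolve decedent records, build frame centroids,
#' score every decedent against every frame, compare the gender pair per
#' frame (Mann-Whitney), and stratify between-gender mutual information by
#' circumstance. Writes five artefacts to the output directory:
#' `scores.csv`, `comparisons.json`, `mi_matrix.csv`,
#' `circumstance_table.csv` and `run_log.json`. All outputs are
#' deterministic for a fixed configuration and seed.
#'
#' @param config A `pipeline_config` (or path to its YAML file).
#' @return Invisibly, a list with the in-memory results (`scores`,
#'   `comparisons`, `mi`, `table1`, `exclusion_report`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  corpus <- stage("read_corpus", read_corpus(config$corpus))
  annotations <- stage("read_annotations", read_annotations(config$annotations))
  rules <- stage("filter_rules", {
    if (is.null(config$filter_rules)) default_filter_rules()
    else read_filter_rules(config$filter_rules)
  })
  filtered <- stage("filter_corpus", filter_corpus(corpus, rules))
  victims <- stage("resolve_victims",
                   resolve_corpus_victims(filtered$included, annotations))

  lexicons <- stage("lexicons", {
    if (is.null(config$lexicons)) default_lexicons()
    else read_lexicons(config$lexicons)
  })
  if (!is.null(config$frames)) {
    lexicons <- lexicons[intersect(names(lexicons), config$frames)]
  }
  backend <- stage("backend", hash_backend(config$backend$dimension,
                                           config$backend$seed))
  centroids <- stage("frame_vectors", frame_vectors(lexicons, backend))
  scores <- stage("score_corpus", score_corpus(victims, centroids, backend))

  comparisons <- stage("mann_whitney", {
    lapply(names(centroids), function(f) {
      sub <- scores[scores$frame == f, , drop = FALSE]
      a <- sub$score[sub$gender == config$genders[[1L]]]
      b <- sub$score[sub$gender == config$genders[[2L]]]
      mann_whitney(a, b, labels = config$genders)
    }) |> stats::setNames(names(centroids))
  })
  mi <- stage("stratified_mi",
              stratified_mi(scores, frames = names(centroids),
                            circumstances = config$circumstances,
                            genders = config$genders, bins = config$bins))
  tab1 <- stage("circumstance_table",
                circumstance_table(annotations,
                                   circumstances = config$circumstances))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    scores = file.path(config$output_dir, "scores.csv"),
    comparisons = file.path(config$output_dir, "comparisons.json"),
    mi_matrix = file.path(config$output_dir, "mi_matrix.csv"),
    circumstance_table = file.path(config$output_dir,
                                   "circumstance_table.csv"),
    run_log = file.path(config$output_dir, "run_log.json")
  )
  stage("write_outputs", {
    write_scores(scores, paths$scores)
    jsonlite::write_json(
      lapply(comparisons, function(cm) as.list(cm)),
      paths$comparisons, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_mi_matrix(mi, paths$mi_matrix)
    utils::write.csv(as.data.frame(tab1), paths$circumstance_table,
                     row.names = FALSE)
    log <- list(
      package = "framescore",
      package_version = as.character(utils::packageVersion("framescore")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      backend = backend$name,
      seed = config$seed,
      bins = config$bins,
      genders = config$genders,
      frames = names(centroids),
      circumstances = config$circumstances,
      n_articles_in = nrow(corpus),
      n_articles_included = nrow(filtered$included),
      exclusion_report = as.list(filtered$exclusion_report),
      n_victims = nrow(victims)
    )
    jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(list(scores = scores, comparisons = comparisons, mi = mi,
                 table1 = tab1, exclusion_report = filtered$exclusion_report,
                 paths = paths))
}
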