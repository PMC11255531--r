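#' Mann-Whitney U comparison of two score samples
#'
#' The U statistic for the first sample is computed by rank sum with
#' midranks for ties. The two-sided p-value is exact (full permutation
#' distribution) when `n_a * n_b <= 400` and the pooled sample has no ties,
#' and otherwise uses the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric score vectors, each non-empty.
#' @param labels Length-2 character vector naming the groups.
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `U` (for group a), `p`, `method`.
#' @export
mann_whitney <- function(a, b, labels = c("a", "b")) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  exact <- (n_a * n_b <= 400) && !has_ties
  if (length(unique(pooled)) == 1L) {
    # all observations tied: the samples are indistinguishable
    return(tibble::tibble(
      group_a = labels[[1L]], group_b = labels[[2L]],
      n_a = n_a, n_b = n_b, mean_a = mean(a), mean_b = mean(b),
      U = n_a * n_b / 2, p = 1, method = "degenerate"
    ))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    group_a = labels[[1L]], group_b = labels[[2L]],
    n_a = n_a, n_b = n_b,
    mean_a = mean(a), mean_b = mean(b),
    U = U, p = wt$p.value,
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Shared equal-width binning of a pooled sample
#'
#' @param pooled Numeric vector.
#' @param bins Number of bins, at least 2.
#' @return Integer bin assignment (1..bins), or `NULL` when the pooled
#'   range is zero.
#' @keywords internal
shared_bins <- function(pooled, bins) {
  stopifnot(bins >= 2L)
  lo <- min(pooled)
  hi <- max(pooled)
  if (hi == lo) return(NULL)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  as.integer(cut(pooled, breaks = breaks, include.lowest = TRUE,
                 labels = FALSE))
}

#' Plug-in mutual information between a group label and binned scores
#'
#' Pools the two samples, forms `bins` shared equal-width bins over the
#' pooled range, builds the joint distribution of (group, bin) from plug-in
#' cell frequencies, and returns `I(G;S)` in bits (zero cells skipped under
#' the `0 log 0 = 0` convention). For two groups the result lies in
#' `[0, 1]` bits; larger values mean more divergent gender-conditional
#' score distributions.
#'
#' @param a,b Numeric score vectors, each non-empty.
#' @param bins Number of shared equal-width bins (default 10).
#' @return A one-row tibble: `mi` (bits), `n_a`, `n_b`, `bins`.
#' @export
mi_between_groups <- function(a, b, bins = 10L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(a, b)
  assignment <- shared_bins(pooled, bins)
  if (is.null(assignment)) {
    warning("pooled scores are constant; mutual information is 0",
            call. = FALSE)
    return(tibble::tibble(mi = 0, n_a = length(a), n_b = length(b),
                          bins = as.integer(bins)))
  }
  g <- rep(c(1L, 2L), c(length(a), length(b)))
  joint <- table(g, assignment) / length(pooled)
  pg <- rowSums(joint)
  ps <- colSums(joint)
  mi <- 0
  for (i in seq_along(pg)) {
    for (j in seq_along(ps)) {
      pij <- joint[i, j]
      if (pij > 0) mi <- mi + pij * log2(pij / (pg[[i]] * ps[[j]]))
    }
  }
  tibble::tibble(mi = max(0, mi), n_a = length(a), n_b = length(b),
                 bins = as.integer(bins))
}

#' Circumstance-stratified mutual information matrix
#'
#' For every requested (circumstance, frame) cell, selects the decedents
#' whose circumstance set contains that circumstance — a decedent annotated
#' with several circumstances contributes to every matching stratum — and
#' computes the between-gender mutual information of their frame scores. A
#' cell where either gender group is empty is reported as `NA` rather than
#' raising an error.
#'
#' @param scores Score tibble from [score_corpus()].
#' @param frames Frames to tabulate (default: all present).
#' @param circumstances Circumstances to stratify by (default
#'   [top_circumstances()]).
#' @param genders Length-2 gender pair compared (default cis male vs cis
#'   female; other identities are excluded from the comparison).
#' @param bins Number of shared bins per cell.
#' @return Tibble with columns `circumstance`, `frame`, `mi`, `n_a`, `n_b`.
#' @export
stratified_mi <- function(scores, frames = unique(scores$frame),
                          circumstances = top_circumstances(),
                          genders = c("cis_male", "cis_female"),
                          bins = 10L) {
  stopifnot(length(genders) == 2L)
  grid <- expand.grid(circumstance = circumstances, frame = frames,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    circ <- grid$circumstance[[k]]
    frm <- grid$frame[[k]]
    sel <- scores$frame == frm &
      vapply(scores$circumstances, function(cs) circ %in% cs, logical(1))
    sub <- scores[sel, , drop = FALSE]
    sa <- sub$score[sub$gender == genders[[1L]]]
    sb <- sub$score[sub$gender == genders[[2L]]]
    if (length(sa) == 0L || length(sb) == 0L) {
      return(tibble::tibble(circumstance = circ, frame = frm,
                            mi = NA_real_, n_a = length(sa),
                            n_b = length(sb)))
    }
    res <- mi_between_groups(sa, sb, bins = bins)
    tibble::tibble(circumstance = circ, frame = frm, mi = res$mi,
                   n_a = res$n_a, n_b = res$n_b)
  })
  dplyr::bind_rows(rows)
}

#' Write a stratified MI matrix as CSV (circumstances x frames)
#'
#' @param mi_table Tibble from [stratified_mi()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mi_matrix <- function(mi_table, path) {
  wide <- tidyr::pivot_wider(
    mi_table[, c("circumstance", "frame", "mi")],
    names_from = "frame", values_from = "mi"
  )
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Cohen's kappa for two coders' labels
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the product of the coders' marginal label frequencies.
#' When both coders are constant and identical (`p_e = 1`) agreement is
#' perfect and kappa is defined as 1.
#'
#' @param labels_1,labels_2 Equal-length label vectors.
#' @return A one-row tibble: `n`, `p_o`, `p_e`, `kappa`.
#' @export
cohen_kappa <- function(labels_1, labels_2) {
  if (length(labels_1) != length(labels_2)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (length(labels_1) == 0L) stop("no labels supplied", call. = FALSE)
  labels_1 <- as.character(labels_1)
  labels_2 <- as.character(labels_2)
  n <- length(labels_1)
  alphabet <- union(labels_1, labels_2)
  p_o <- mean(labels_1 == labels_2)
  m1 <- table(factor(labels_1, levels = alphabet)) / n
  m2 <- table(factor(labels_2, levels = alphabet)) / n
  p_e <- sum(as.numeric(m1) * as.numeric(m2))
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  tibble::tibble(n = n, p_o = p_o, p_e = p_e, kappa = kappa)
}

round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  floor(round(x * scale, 8) + 0.5) / scale
}

#' Circumstance-by-gender summary table
#'
#' Counts circumstance attributions per gender: a decedent annotated with
#' `k` circumstances contributes `k` counts. Row totals sum over the listed
#' circumstances and percentages are `100 * count / row_total`, rounded
#' half-up to one decimal.
#'
#' @param annotations Annotation tibble (needs `gender`, `circumstances`).
#' @param circumstances Circumstances to tabulate (default
#'   [top_circumstances()]).
#' @return Tibble with columns `gender`, `circumstance`, `n`, `row_total`,
#'   `pct`.
#' @export
circumstance_table <- function(annotations,
                               circumstances = top_circumstances()) {
  if (nrow(annotations) == 0L) stop("no annotations supplied", call. = FALSE)
  long <- tidyr::unnest(
    tibble::tibble(gender = annotations$gender,
                   circumstance = annotations$circumstances),
    "circumstance"
  )
  long <- long[long$circumstance %in% circumstances, , drop = FALSE]
  counts <- dplyr::count(long, .data$gender, .data$circumstance, name = "n")
  full <- tidyr::complete(
    counts,
    gender = unique(long$gender),
    circumstance = circumstances,
    fill = list(n = 0L)
  )
  full <- dplyr::group_by(full, .data$gender)
  full <- dplyr::mutate(full, row_total = sum(.data$n))
  full <- dplyr::ungroup(full)
  full$pct <- round_half_up(100 * full$n / full$row_total, 1L)
  full$circumstance <- factor(full$circumstance, levels = circumstances)
  full <- dplyr::arrange(full, .data$gender, .data$circumstance)
  full$circumstance <- as.character(full$circumstance)
  full
}
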