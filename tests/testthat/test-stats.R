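test_that("Mann-Whitney U and exact p match hand enumeration on the smallest case", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 6)  # 6 rank arrangements, the two most extreme
  expect_equal(res$method, "exact")
})

test_that("identical samples give the central U with midranks", {
  a <- c(3, 1, 4, 1, 5)
  res <- mann_whitney(a, a)
  expect_equal(res$U, length(a)^2 / 2)
  expect_error(mann_whitney(numeric(), a), "non-empty")
})

test_that("exact p-values agree with the exhaustive permutation oracle", {
  set.seed(19)
  for (i in 1:10) {
    a <- sample(1000L, 4L)
    b <- sample(2000L:3000L, 4L)
    mixed <- sample(c(a, b))
    a <- mixed[1:4]
    b <- mixed[5:8]
    expect_equal(mann_whitney(a, b)$p, perm_mw_p(a, b), tolerance = 1e-12)
  }
  # every unbalanced small split, no ties
  for (n_a in 1:4) {
    vals <- sample(100L, 8L)
    a <- vals[seq_len(n_a)]
    b <- vals[(n_a + 1):8]
    expect_equal(mann_whitney(a, b)$p, perm_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(23)
  a <- rnorm(30)
  b <- rnorm(30)
  res <- mann_whitney(a, b)
  expect_equal(res$method, "normal_approx")
  expect_equal(res$p,
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  tied <- mann_whitney(c(1, 2, 2), c(2, 3, 4))
  expect_equal(tied$method, "normal_approx")
})

test_that("mutual information vanishes for identical samples and is 1 bit for full separation", {
  a <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(mi_between_groups(a, a)$mi, 0, tolerance = 1e-12)

  low <- runif(8, 0, 0.1)
  high <- runif(8, 0.9, 1)
  expect_equal(mi_between_groups(low, high)$mi, 1, tolerance = 1e-12)
})

test_that("plug-in MI equals the hand-summed value on a fixed 2x3 contingency", {
  # binning at 3 shared bins puts group a at counts (2,1,0), group b (0,1,2)
  a <- c(0.1, 0.2, 1.5)
  b <- c(1.5, 2.4, 2.5)
  res <- mi_between_groups(a, b, bins = 3L)
  p <- matrix(c(2, 1, 0, 0, 1, 2) / 6, nrow = 2, byrow = TRUE)
  pg <- rowSums(p)
  ps <- colSums(p)
  hand <- 0
  for (i in 1:2) for (j in 1:3) {
    if (p[i, j] > 0) hand <- hand + p[i, j] * log2(p[i, j] / (pg[i] * ps[j]))
  }
  expect_equal(res$mi, hand, tolerance = 1e-12)
  expect_equal(hand, 2 / 3, tolerance = 1e-12)
})

test_that("MI is non-negative, at most 1 bit for two groups, and binning-invariant under monotone maps", {
  set.seed(29)
  for (i in 1:10) {
    a <- runif(25)
    b <- runif(25, 0.3, 1.3)
    mi <- mi_between_groups(a, b)$mi
    expect_gte(mi, 0)
    expect_lte(mi, 1)
  }
  # affine rescaling preserves equal-width bin assignments exactly
  a <- runif(30)
  b <- runif(30, 0.5, 1.5)
  base <- mi_between_groups(a, b)$mi
  expect_equal(mi_between_groups(10 * a - 3, 10 * b - 3)$mi, base,
               tolerance = 1e-12)
})

test_that("constant pooled scores yield zero MI with a warning", {
  expect_warning(res <- mi_between_groups(rep(0.5, 4), rep(0.5, 6)),
                 "constant")
  expect_equal(res$mi, 0)
})

test_that("stratified MI fills every cell, shares multi-circumstance victims, flags empty cells", {
  scores <- tibble::tibble(
    victim_id = sprintf("v%d", 1:8),
    gender = rep(c("cis_male", "cis_female"), each = 4),
    circumstances = c(
      list(c("legal_problem", "financial_job")),
      rep(list("legal_problem"), 3),
      rep(list("legal_problem"), 3),
      list("mental_health")
    ),
    frame = "stigma",
    score = c(0.9, 0.8, 0.85, 0.7, 0.2, 0.3, 0.1, 0.25)
  )
  mi <- stratified_mi(scores, frames = "stigma",
                      circumstances = c("legal_problem", "financial_job",
                                        "mental_health"))
  expect_equal(nrow(mi), 3L)
  legal <- mi[mi$circumstance == "legal_problem", ]
  expect_equal(legal$n_a + legal$n_b, 7L)  # v1 contributes here too
  fin <- mi[mi$circumstance == "financial_job", ]
  expect_true(is.na(fin$mi))  # no female scores in that stratum
  expect_equal(fin$n_a, 1L)
})

test_that("a victim with several circumstances lands in each matching stratum", {
  scores <- tibble::tibble(
    victim_id = c("v1", "v2"),
    gender = c("cis_male", "cis_female"),
    circumstances = list(c("legal_problem", "financial_job"),
                         c("legal_problem", "financial_job")),
    frame = "stigma", score = c(0.6, 0.2)
  )
  mi <- stratified_mi(scores, frames = "stigma",
                      circumstances = c("legal_problem", "financial_job"))
  expect_equal(mi$n_a, c(1L, 1L))
  expect_equal(mi$n_b, c(1L, 1L))
})

test_that("Cohen kappa matches hand computations and is symmetric", {
  mixed <- c("a", "b", "a", "c", "b")
  expect_equal(cohen_kappa(mixed, mixed)$kappa, 1)

  # 2x2 confusion counts 20/5/10/15: p_o = 0.7, p_e = 0.5
  l1 <- rep(c("A", "A", "B", "B"), c(20, 5, 10, 15))
  l2 <- rep(c("A", "B", "A", "B"), c(20, 5, 10, 15))
  res <- cohen_kappa(l1, l2)
  expect_equal(res$p_o, 0.7)
  expect_equal(res$p_e, 0.5)
  expect_equal(res$kappa, 0.4)
  expect_equal(cohen_kappa(l2, l1)$kappa, res$kappa)

  expect_equal(cohen_kappa(rep("x", 5), rep("x", 5))$kappa, 1)
  expect_error(cohen_kappa(c("a", "b"), "a"), "length")
})

test_that("independent random labels give near-zero kappa", {
  set.seed(31)
  l1 <- sample(c("yes", "no"), 10000, replace = TRUE)
  l2 <- sample(c("yes", "no"), 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(l1, l2)$kappa), 0.05)
})

test_that("circumstance table counts attributions and rounds percentages half-up", {
  ann <- make_annotations(
    sprintf("a%d", 1:3), sprintf("v%d", 1:3),
    c("cis_male", "cis_male", "cis_female"),
    list(c("legal_problem", "financial_job"), "legal_problem", "unspecified")
  )
  tab <- circumstance_table(ann)
  male <- tab[tab$gender == "cis_male", ]
  expect_equal(sum(male$n), male$row_total[[1]])
  expect_equal(male$n[male$circumstance == "legal_problem"], 2L)
  expect_equal(male$pct[male$circumstance == "legal_problem"],
               round(100 * 2 / 3, 1))

  solo <- circumstance_table(make_annotations("a1", "v1", "cis_female",
                                              list("mental_health")))
  expect_equal(solo$pct[solo$gender == "cis_female" &
                          solo$circumstance == "mental_health"], 100.0)
})
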