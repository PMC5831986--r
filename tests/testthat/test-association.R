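test_that("Spearman handles perfect monotone, antitone and degenerate inputs", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_cor(1:4, c(40, 30, 20, 10))$rho, -1)
  expect_equal(spearman_cor(1:5, rep(2, 5))$method_note, "CONSTANT_INPUT")
  expect_equal(spearman_cor(1:2, 2:1)$method_note, "INSUFFICIENT_N")
})

test_that("Spearman rho and exact p match the enumeration oracle", {
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  res <- spearman_cor(x, y)
  expect_equal(res$method_note, "exact_permutation")
  expect_equal(res$rho, oracle_pearson(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(res$rho, 0.8, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_spearman_exact_p(x, y), tolerance = 1e-12)
  # independently frozen: 16 of the 120 permutations reach |rho| >= 0.8
  expect_equal(res$p_value, 16 / 120, tolerance = 1e-12)
})

test_that("Spearman on tied data equals rank-then-Pearson and cor.test", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties, like copy numbers
    y <- round(rlnorm(n, 0, 1), 1)
    res <- spearman_cor(x, y)
    expect_equal(res$rho, oracle_pearson(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(res$rho,
                 suppressWarnings(cor.test(x, y, method = "spearman")$estimate[[1]]),
                 tolerance = 1e-9)
  }
})

test_that("Spearman is invariant under increasing transforms and antisymmetric", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    base <- spearman_cor(x, y)
    expect_equal(spearman_cor(exp(x), y)$rho, base$rho, tolerance = 1e-12)
    expect_equal(spearman_cor(x, y^3)$rho, base$rho, tolerance = 1e-12)
    expect_equal(spearman_cor(x, -y)$rho, -base$rho, tolerance = 1e-12)
  }
})

test_that("exact and approximate Spearman p agree on average for small n", {
  set.seed(41)
  diffs <- replicate(40, {
    n <- sample(5:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    exact <- spearman_cor(x, y, exact_n_max = 9L)$p_value
    approx <- spearman_cor(x, y, exact_n_max = 0L)$p_value
    abs(exact - approx)
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("pairwise matrix emits C(V,2) results and skips degenerate variables", {
  set.seed(8)
  d <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20), d = rnorm(20))
  m <- pairwise_matrix(d, c("a", "b", "c", "d"))
  expect_equal(nrow(m), 6L)
  expect_true(all(abs(m$rho) <= 1))
  expect_true(all(m$n == 20L))
  sc <- attr(m, "scatter_data")
  expect_length(sc, 6L)
  expect_equal(sc[["a~b"]]$x, d$a)

  d$e <- NA_real_
  m2 <- pairwise_matrix(d, c("a", "b", "e"))
  expect_equal(nrow(m2), 1L)
  expect_equal(nrow(attr(m2, "skipped")), 2L)
  expect_error(pairwise_matrix(d, c("a", "zzz")), "zzz")
})

test_that("exclusion rules build nested analysis sets with a complete audit", {
  cohort <- data.frame(
    sample_id = sprintf("P%d", 1:6),
    pre_sampling_progesterone = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    post_sampling_cerclage = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    post_sampling_progesterone = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    outcome = c("term", "term", "term", "miscarriage", "termination", "term"),
    stringsAsFactors = FALSE)
  sets <- apply_exclusions(cohort)
  # pre-sampling progesterone excluded everywhere
  expect_false("P1" %in% sets$all_comers$sample_id)
  expect_false("P1" %in% sets$outcome_set$sample_id)
  # post-sampling treatment and pregnancy loss: kept in all-comers only
  expect_true(all(c("P2", "P3", "P4", "P5") %in% sets$all_comers$sample_id))
  expect_false(any(c("P2", "P3", "P4", "P5") %in% sets$outcome_set$sample_id))
  # unflagged record retained in both
  expect_true("P6" %in% sets$outcome_set$sample_id)
  # arithmetic: |all_comers| + |pre-sampling exclusions| = |input|
  n_pre <- sum(sets$audit$set_removed_from == "all")
  expect_equal(nrow(sets$all_comers) + n_pre, nrow(cohort))
  expect_true(all(sets$outcome_set$sample_id %in% sets$all_comers$sample_id))
  expect_setequal(sets$audit$rule[sets$audit$sample_id == "P1"],
                  "pre_sampling_progesterone")
})

test_that("stratified correlations cover each stratum and mark underpowered ones", {
  set.seed(9)
  n <- 40
  cohort <- data.frame(outcome = rep(c("term", "preterm"), c(30, 10)),
                       a = rnorm(n), b = rnorm(n), c = rnorm(n))
  res <- stratified_correlations(cohort, c("a", "b", "c"))
  expect_equal(nrow(res), 6L)  # 2 strata x C(3,2)
  expect_setequal(unique(res$stratum), c("term", "preterm"))

  tiny <- cohort[c(1, 31, 32), ]  # preterm stratum of n = 2
  res2 <- stratified_correlations(tiny, c("a", "b", "c"))
  pt <- res2[res2$stratum == "preterm", ]
  expect_true(all(pt$method_note == "UNDERPOWERED"))
  expect_true(all(is.na(pt$rho)))
})

test_that("Mann-Whitney exact enumeration matches the assignment oracle", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$method_note, "exact_enumeration")
  expect_equal(res$p_value, oracle_mwu_exact_p(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)  # 2 of C(6,3)=20 splits

  # identical multisets: no separation, p = 1 by the enumeration convention
  same <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$p_value, 1)

  # tied data still handled exactly by enumeration
  set.seed(13)
  x <- sample(1:4, 5, replace = TRUE)
  y <- sample(2:6, 6, replace = TRUE)
  res <- mann_whitney(x, y)
  expect_equal(res$p_value, oracle_mwu_exact_p(x, y), tolerance = 1e-12)

  expect_equal(mann_whitney(numeric(0), 1:3)$method_note, "EMPTY_GROUP")
})

test_that("Mann-Whitney agrees with wilcox.test on both branches", {
  set.seed(17)
  # exact, tie-free small samples
  x <- rnorm(5); y <- rnorm(7) + 0.5
  res <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  # normal approximation with tie correction for larger groups
  x <- sample(1:8, 30, replace = TRUE)
  y <- sample(2:9, 35, replace = TRUE)
  res <- mann_whitney(x, y)
  expect_equal(res$method_note, "normal_approximation_tie_corrected")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("compare_groups summarises the two groups and their test", {
  cohort <- data.frame(outcome = rep(c("term", "preterm"), each = 5),
                       v = c(1:5, 6:10))
  res <- compare_groups(cohort, "v")
  expect_equal(res$n_x, 5L)
  expect_equal(res$median_x, 3)
  expect_equal(res$median_y, 8)
  expect_lt(res$p_value, 0.05)
  empty <- cohort[cohort$outcome == "term", ]
  expect_null(compare_groups(empty, "v"))
})
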