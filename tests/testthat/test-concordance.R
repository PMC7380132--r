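test_that("cross-tabulation counts pairs and excludes unclassified samples", {
  a <- c(S1 = "M", S2 = "M", S3 = "N")
  b <- c(S1 = "M", S2 = "N", S3 = "N")
  tab <- cross_tabulate(a, b)
  expect_equal(tab, matrix(c(1L, 0L, 1L, 1L), 2L,
                           dimnames = list(c("M", "N"), c("M", "N"))))
  # identical vectors give a diagonal table
  tab2 <- cross_tabulate(a, a)
  expect_equal(tab2[1L, 2L] + tab2[2L, 1L], 0L)
  # unclassified excluded with a log line
  a2 <- c(a, S4 = "unclassified"); b2 <- c(b, S4 = "M")
  expect_message(tab3 <- cross_tabulate(a2, b2), "excluded 1")
  expect_equal(sum(tab3), 3L)
  expect_error(cross_tabulate(c(X = "M"), c(Y = "M")), "no shared")
})

test_that("a 456-sample cohort built from published counts has the printed marginals", {
  tab <- confusion_from_counts(95, 104, 314, 352)
  expect_equal(sum(tab), 456L)
  expect_equal(unname(rowSums(tab)), c(104L, 352L))
  expect_equal(unname(colSums(tab)), c(133L, 323L))
  # the same table via label vectors and cross_tabulate
  ref <- rep(c("Mes", "Mes", "non-Mes", "non-Mes"), c(95, 9, 38, 314))
  cmp <- rep(c("Mes", "non-Mes", "Mes", "non-Mes"), c(95, 9, 38, 314))
  names(ref) <- names(cmp) <- sprintf("S%03d", seq_along(ref))
  expect_equal(unname(cross_tabulate(ref, cmp)), unname(tab))
})

test_that("Cohen's kappa handles agreement, independence and degeneracy", {
  expect_equal(cohens_kappa(matrix(c(10, 0, 0, 10), 2L)), 1)
  expect_equal(cohens_kappa(matrix(25, 2L, 2L)), 0)
  expect_equal(cohens_kappa(matrix(c(10, 0, 0, 0), 2L)), 1)  # p_e = 1, p_o = 1
  expect_error(cohens_kappa(matrix(1:6, 2L)), "square")
  # label-level oracle on random vectors; perfect self-agreement
  for (seed in c(51L, 52L)) {
    labs <- withr::with_seed(seed, sample(c("A", "B", "C"), 60, replace = TRUE))
    labs2 <- withr::with_seed(seed + 10L, sample(c("A", "B", "C"), 60, replace = TRUE))
    names(labs) <- names(labs2) <- sprintf("S%02d", 1:60)
    tab <- cross_tabulate(labs, labs2)
    expect_equal(cohens_kappa(tab), kappa_oracle(unname(labs), unname(labs2)))
    expect_equal(cohens_kappa(cross_tabulate(labs, labs)), 1)
    # independent library cross-check
    expect_equal(cohens_kappa(tab), e1071::classAgreement(tab)$kappa)
  }
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  tab <- matrix(c(40, 5, 3, 7, 30, 2, 1, 4, 20), 3L,
                dimnames = list(letters[1:3], letters[1:3]))
  perm <- c(3L, 1L, 2L)
  expect_equal(cohens_kappa(tab[perm, perm]), cohens_kappa(tab))
})

test_that("per-class accuracy is the diagonal fraction per reference row", {
  tab <- confusion_from_counts(95, 104, 314, 352)
  acc <- per_class_accuracy(tab)
  expect_equal(unname(acc), c(95 / 104, 314 / 352))
  expect_equal(unname(per_class_accuracy(matrix(c(7, 0, 0, 9), 2L))), c(1, 1))
  expect_equal(unname(per_class_accuracy(matrix(c(0, 0, 5, 5), 2L))), c(0, 1))
  expect_message(acc0 <- per_class_accuracy(matrix(c(0, 2, 0, 3), 2L)),
                 "undefined")
  expect_true(is.na(acc0[1L]))
})

test_that("two-sided Fisher p matches full enumeration and closed forms", {
  # closed-form extreme table: p = 2 / C(20, 10)
  tab <- matrix(c(10, 0, 0, 10), 2L)
  expect_equal(fisher_exact_2x2(tab), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(5, 2L, 2L)), 1)
  expect_message(p0 <- fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2L)), "zero margin")
  expect_equal(p0, 1)
  # the spec-style stage-II-vs-III table against the 24-table enumeration
  stage_tab <- matrix(c(1, 22, 83, 276), 2L, byrow = TRUE)
  expect_equal(fisher_exact_2x2(stage_tab), fisher_oracle(stage_tab),
               tolerance = 1e-7)
})

test_that("Fisher p equals the enumeration oracle for random tables with n <= 60", {
  tabs <- withr::with_seed(61L, replicate(200L, {
    n <- sample(4:60, 1L)
    cells <- as.vector(stats::rmultinom(1L, n, prob = stats::runif(4, 0.05, 1)))
    matrix(cells, 2L)
  }, simplify = FALSE))
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab), tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant under transposition and row+column swap", {
  tabs <- withr::with_seed(62L, replicate(25L, matrix(sample(0:15, 4, TRUE), 2L),
                                          simplify = FALSE))
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p, tolerance = 1e-9)
  }
})

test_that("subtype-by-group tests tabulate pairs with raw and BH-adjusted p", {
  coh <- small_cohort()
  res <- classify_cohort(coh$matrix, coh$archetypes$signatures$mes15, "all",
                         coh$annotations)
  out <- subtype_by_group_test(res$calls, coh$annotations, "stage_group")
  expect_identical(out$group_a, "I-II")
  expect_identical(out$group_b, "III-IV")
  # generator ground truth: Mes confined to late stage => small p, direction recorded
  expect_lt(out$p, 0.05)
  expect_lt(out$a_mes / (out$a_mes + out$a_nonmes),
            out$b_mes / (out$b_mes + out$b_nonmes))
  expect_equal(out$p_bh, out$p)   # single comparison
  expect_identical(names(attr(out, "tables")), "I-II vs III-IV")
  # equal Mes fractions with equal margins give p = 1
  calls_eq <- data.frame(sample_id = sprintf("E%02d", 1:40),
                         is_mes = rep(c(TRUE, FALSE), 20L))
  ann_eq <- data.frame(sample_id = calls_eq$sample_id,
                       grp = rep(c("x", "y"), each = 20L))
  expect_equal(subtype_by_group_test(calls_eq, ann_eq, "grp")$p, 1)
  # single group: counts only, no test
  one <- subtype_by_group_test(calls_eq, transform(ann_eq, grp = "x"), "grp")
  expect_identical(names(one), c("group", "n_mes", "n_nonmes"))
  expect_error(subtype_by_group_test(calls_eq, ann_eq, "nope"), "unknown")
})
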