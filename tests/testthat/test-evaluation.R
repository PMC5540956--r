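planted6 <- c(1, 1, 1, 2, 2, 2)
retrieved6 <- c(1, 1, 2, 1, 2, 2)

test_that("confusion table counts overlaps with consistent marginals", {
  ct <- confusion_table(planted6, retrieved6)
  expect_equal(ct$counts, matrix(c(2L, 1L, 1L, 2L), 2))
  expect_equal(ct$row_sums, c(3, 3), ignore_attr = TRUE)
  expect_equal(ct$col_sums, c(3, 3), ignore_attr = TRUE)
  expect_equal(ct$total, 6)
  # any partition against the single community gives one column
  ct1 <- confusion_table(planted6, rep(1, 6))
  expect_equal(dim(ct1$counts), c(2L, 1L))
  expect_equal(as.vector(ct1$counts), c(3L, 3L))
  expect_error(confusion_table(planted6, 1:3), "same")
})

test_that("nmi reproduces its defining identities", {
  # identical multi-community partitions
  expect_equal(nmi(planted6, planted6), 1)
  expect_equal(nmi(c(1, 2, 3, 1, 2, 3), c(3, 1, 2, 3, 1, 2)), 1)
  # against the single community: no information
  expect_equal(nmi(planted6, rep(1, 6)), 0)
  # both trivial: defined as identity
  expect_equal(nmi(rep(1, 5), rep(1, 5)), 1)
})

test_that("nmi on the worked fixture matches the contingency oracle", {
  val <- nmi(planted6, retrieved6)
  expect_equal(val, nmi_oracle(planted6, retrieved6), tolerance = 1e-12)
  expect_equal(val, 0.0817, tolerance = 1e-4)
})

test_that("nmi is symmetric, label-invariant and bounded on random pairs", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- sample.int(5, n, replace = TRUE)
    b <- sample.int(5, n, replace = TRUE)
    v <- nmi(a, b)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, nmi(b, a), tolerance = 1e-12)
    expect_equal(v, nmi(c(11, 3, 7, 20, 5)[a], b), tolerance = 1e-12)
    expect_equal(v, nmi_oracle(a, b), tolerance = 1e-12)
    ss <- sensitivity_specificity(a, b)
    expect_true(ss$sensitivity >= 0 && ss$sensitivity <= 1)
    expect_true(ss$specificity >= 0 && ss$specificity <= 1)
  }
})

test_that("biggest-overlap matching counts TP/FP/TN/FN per community", {
  m <- match_communities(planted6, retrieved6)
  expect_equal(m$matched, c(1, 2))
  expect_equal(m$TP, c(2, 2), ignore_attr = TRUE)
  expect_equal(m$FP, c(1, 1), ignore_attr = TRUE)
  expect_equal(m$FN, c(1, 1), ignore_attr = TRUE)
  expect_equal(m$TN, c(2, 2), ignore_attr = TRUE)
  # identity match
  mi <- match_communities(planted6, planted6)
  expect_true(all(mi$FP == 0) && all(mi$FN == 0))
  expect_true(all(mi$TP + mi$FN == 3))
  # forced many-to-one onto a single retrieved community
  m1 <- match_communities(planted6, rep(1, 6))
  expect_equal(m1$matched, c(1, 1))
  expect_equal(m1$FP, c(3, 3), ignore_attr = TRUE)
  expect_equal(m1$TN, c(0, 0), ignore_attr = TRUE)
})

test_that("sensitivity and specificity evaluate the matched communities", {
  expect_equal(sensitivity_specificity(planted6, planted6),
               list(sensitivity = 1, specificity = 1))
  ss <- sensitivity_specificity(planted6, retrieved6)
  expect_equal(ss$sensitivity, 2 / 3)
  expect_equal(ss$specificity, 2 / 3)
  # all-singleton retrieval: each community keeps one node, rest missed
  sss <- sensitivity_specificity(planted6, 1:6)
  expect_equal(sss$sensitivity, 1 / 3)
  expect_equal(sss$specificity, 1)
  # single retrieved community covers everything: specificity collapses
  s1 <- sensitivity_specificity(planted6, rep(1, 6))
  expect_equal(s1$sensitivity, 1)
  expect_equal(s1$specificity, 0)
})
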