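test_that("nearest-PD projection fixes indefinite targets and keeps PD ones", {
  I5 <- diag(5)
  expect_equal(nearest_positive_definite(I5), I5)
  # an already-PD unit-diagonal matrix is a fixed point
  C <- matrix(0.3, 4, 4)
  diag(C) <- 1
  expect_equal(nearest_positive_definite(C), C, tolerance = 1e-8)
  # indefinite 2x2: off-diagonal pulled to ~1, eigenvalues floored
  A <- matrix(c(1, 1.2, 1.2, 1), 2)
  X <- nearest_positive_definite(A, eig_floor = 1e-8)
  ev <- eigen(X, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-8 / 2)
  expect_equal(X[1, 2], 1, tolerance = 1e-6)
  expect_equal(diag(X), c(1, 1))
  expect_error(nearest_positive_definite(matrix(1:6, 2)), "square")
  expect_error(nearest_positive_definite(matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
})

test_that("nearest-PD agrees with the alternating-projection reference", {
  skip_if_not_installed("Matrix")
  set.seed(42)
  for (i in 1:5) {
    A <- matrix(runif(64, -0.8, 0.8), 8)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    mine <- nearest_positive_definite(A)
    ref <- as.matrix(Matrix::nearPD(A, corr = TRUE)$mat)
    dimnames(ref) <- NULL
    expect_equal(mine, ref, tolerance = 1e-5)
  }
})

test_that("Cholesky coloring reproduces the target covariance", {
  net <- rand_network(10, p = 0.4, seed = 9)
  C <- correlation_target(net, unit_diagonal = TRUE)
  L <- cholesky_factor(C)
  expect_equal(L %*% t(L), C, tolerance = 1e-10)
  expect_true(all(diag(L) > 0))
  # empirical correlations converge to the target at large m; the
  # sampling error of a correlation is ~(1 - r^2)/sqrt(m), so a strongly
  # correlated 10-node target (0.9-weight clique) must be recovered with
  # small Frobenius error while a weakly correlated one is bounded by
  # the statistical scale sqrt(2*45)/sqrt(m) ~ 0.03
  idx <- t(utils::combn(10, 2))
  clique <- weighted_network(data.frame(from = idx[, 1], to = idx[, 2],
                                        weight = 0.9), 10)
  C9 <- correlation_target(clique, unit_diagonal = TRUE)
  Y <- correlated_timeseries(C9, n_timepoints = 1e5, baseline = 100,
                             seed = 4)
  expect_lt(norm(stats::cor(t(Y)) - C9, "F"), 0.02)
  expect_lt(abs(mean(Y) - 100), 3 / sqrt(1e5) * 10)
  Yw <- correlated_timeseries(C, n_timepoints = 1e5, seed = 4)
  expect_lt(norm(stats::cor(t(Yw)) - C, "F"), 0.05)
  # independent series under the identity target
  Y0 <- correlated_timeseries(diag(10), n_timepoints = 1e5, seed = 5)
  R0 <- stats::cor(t(Y0))
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.015)
  # a planted pairwise correlation is recovered
  C2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  Y2 <- correlated_timeseries(C2, n_timepoints = 1e5, seed = 6)
  expect_equal(stats::cor(Y2[1, ], Y2[2, ]), 0.8, tolerance = 0.01)
  expect_error(correlated_timeseries(diag(3), n_timepoints = 2), "at least 3")
})

test_that("covariance conditioning of an adjacency admits a Cholesky factor", {
  net <- rand_network(20, p = 0.2, seed = 11)
  C <- correlation_target(net)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-8 / 2)
  expect_silent(chol(C + diag(1e-12, 20)))
  # planted edges keep larger implied correlation than non-edges on average
  A <- adjacency_matrix(net)
  R <- stats::cov2cor(C)
  up <- upper.tri(A)
  expect_gt(mean(R[up & A > 0]), mean(R[up & A == 0]))
})

test_that("Rician noise follows the magnitude construction and SNR scale", {
  x <- matrix(100, 10, 100)
  # vanishing noise: output equals input
  y <- add_rician_noise(x, snr = 1e9, seed = 1)
  expect_lt(max(abs(y - x) / x), 1e-3)
  # sd of the output matches sigma_N = mean|x| / snr at high SNR
  x2 <- matrix(100, 1, 1e5)
  y2 <- add_rician_noise(x2, snr = 35, seed = 2)
  expect_equal(stats::sd(y2), 100 / 35, tolerance = 0.05)
  # zero signal with fixed sigma: Rayleigh law with mean sigma*sqrt(pi/2)
  z <- add_rician_noise(matrix(0, 1, 1e5), snr = 1, sigma = 2, seed = 3)
  expect_equal(mean(z), 2 * sqrt(pi / 2), tolerance = 0.02)
  expect_error(add_rician_noise(x, snr = 0), "positive")
})

test_that("cohorts are reproducible and share the conditioned target", {
  net <- generate_lfr(lfr_params(n_nodes = 60, avg_degree = 6,
                                 max_degree = 12, min_community = 10,
                                 max_community = 25, seed = 5))$network
  p1 <- generate_cohort(net, n_subjects = 3, n_timepoints = 50, snr = 35,
                        seed = 9)
  p2 <- generate_cohort(net, n_subjects = 3, n_timepoints = 50, snr = 35,
                        seed = 9)
  expect_identical(p1$data, p2$data)
  expect_equal(p1$n_timepoints, 50)
  expect_false(identical(p1$data[[1]], p1$data[[2]]))
})

test_that("group averaging beats single subjects and noise degrades fidelity", {
  net <- generate_lfr(lfr_params(n_nodes = 60, avg_degree = 6,
                                 max_degree = 12, min_community = 10,
                                 max_community = 25, seed = 5))$network
  C <- correlation_target(net)
  R <- stats::cov2cor(C)
  frob_to_target <- function(mats) {
    g <- fisher_group_average(mats)
    diag(g) <- 1
    norm(g - R, "F")
  }
  wins <- 0
  for (s in 1:10) {
    panel <- generate_cohort(net, n_subjects = 8, n_timepoints = 150,
                             snr = 35, seed = 100 + s)
    mats <- lapply(panel$data, pearson_matrix)
    group_err <- frob_to_target(mats)
    subj_err <- vapply(mats, function(m) frob_to_target(list(m)),
                       numeric(1))
    if (group_err < min(subj_err)) wins <- wins + 1
  }
  expect_gte(wins, 9)
  # single-subject distance to the target grows as SNR drops
  errs <- vapply(c(1e9, 70, 35), function(snr) {
    mean(vapply(1:5, function(s) {
      panel <- generate_cohort(net, n_subjects = 1, n_timepoints = 150,
                               snr = snr, seed = 200 + s)
      norm(pearson_matrix(panel$data[[1]]) - R, "F")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("cohort CSV round-trip preserves the series", {
  net <- rand_network(6, p = 0.5, seed = 3)
  panel <- generate_cohort(net, n_subjects = 2, n_timepoints = 20,
                           snr = 70, seed = 4)
  dir <- withr::local_tempdir()
  manifest <- write_cohort_csv(panel, dir)
  back <- read_cohort_csv(manifest)
  expect_equal(back, panel$data, tolerance = 1e-12, ignore_attr = TRUE)
})
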