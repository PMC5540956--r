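#' Nearest positive-definite correlation matrix
#'
#' Projects a symmetric matrix onto the set of unit-diagonal matrices whose
#' smallest eigenvalue is at least `eig_floor`, by alternating projections
#' between the positive-semidefinite cone (eigenvalue clipping) and the
#' unit-diagonal affine set. This is the conditioning step required before
#' a Cholesky factorization of an arbitrary (e.g. sparse adjacency-derived)
#' correlation target.
#'
#' @param mat square symmetric numeric matrix; asymmetries up to 1e-12 are
#'   symmetrized, larger ones are an error.
#' @param eig_floor lower bound imposed on the eigenvalues (default 1e-8).
#' @param max_iter iteration cap for the alternating projections.
#' @param tol convergence tolerance on the Frobenius norm of successive
#'   iterate differences.
#' @return The conditioned matrix: symmetric, unit diagonal, minimum
#'   eigenvalue >= `eig_floor` (up to numerical round-off), off-diagonal
#'   entries in (-1, 1).
#' @examples
#' nearest_positive_definite(matrix(c(1, 1.2, 1.2, 1), 2))
#' @export
nearest_positive_definite <- function(mat, eig_floor = 1e-8,
                                      max_iter = 200, tol = 1e-10) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("input must be a square matrix")
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-12) stop("input must be symmetric")
  X <- (mat + t(mat)) / 2
  diag(X) <- 1
  D <- matrix(0, nrow(X), ncol(X)) # Dykstra correction for the PSD step
  for (it in seq_len(max_iter)) {
    R <- X - D
    eg <- eigen(R, symmetric = TRUE)
    Y <- eg$vectors %*% (pmax(eg$values, eig_floor) * t(eg$vectors))
    Y <- (Y + t(Y)) / 2
    D <- Y - R
    Xn <- Y
    diag(Xn) <- 1
    delta <- sqrt(sum((Xn - X)^2))
    X <- Xn
    if (delta < tol) break
  }
  ev <- eigen(X, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eig_floor / 2)
    stop(sprintf("nearest-PD projection did not converge (min eigenvalue %.3g after %d iterations)",
                 min(ev), max_iter))
  X
}

#' Lower Cholesky factor of a conditioned correlation target
#'
#' @param target output of [nearest_positive_definite()].
#' @return Lower-triangular matrix `L` with `L %*% t(L)` equal to `target`.
#' @export
cholesky_factor <- function(target) {
  t(chol(target))
}

#' Correlated node time series via Cholesky coloring
#'
#' Draws standardized white-noise series X (i.i.d. standard Gaussian per
#' node and timepoint) and returns `Y = L X + baseline`, whose population
#' covariance (ignoring the baseline shift) is exactly the target matrix;
#' for a unit-diagonal target the pairwise correlations equal the target
#' entries directly.
#'
#' @param target symmetric positive-definite target matrix (see
#'   [correlation_target()] / [nearest_positive_definite()]).
#' @param n_timepoints series length m (>= 3; default 150).
#' @param baseline additive signal baseline (default 100).
#' @param seed integer RNG seed.
#' @return A `nodes x timepoints` numeric matrix.
#' @export
correlated_timeseries <- function(target, n_timepoints = 150,
                                  baseline = 100, seed = 1) {
  if (n_timepoints < 3)
    stop("n_timepoints must be at least 3 (Pearson correlation needs >= 3 points)")
  L <- cholesky_factor(target)
  n <- nrow(L)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
    L %*% X + baseline
  })
}

#' Add Rician noise at a given signal-to-noise ratio
#'
#' Rician noise is the magnitude of a complex Gaussian perturbation of the
#' signal, the standard noise model of MR magnitude images: each sample `y`
#' becomes `sqrt((y + g1)^2 + g2^2)` with `g1`, `g2` independent Gaussian
#' draws of standard deviation `sigma_N`. The noise scale is set from the
#' input as `sigma_N = mean(|y|) / snr`, following the definition
#' SNR = S_bar / sigma_N with S_bar the average signal magnitude.
#'
#' @param series numeric matrix (nodes x timepoints), predominantly
#'   positive (baseline-shifted).
#' @param snr signal-to-noise ratio (> 0); the simulations use 35 and 70.
#' @param seed integer RNG seed.
#' @param sigma override of the noise standard deviation; when given, `snr`
#'   is ignored.
#' @return Matrix of the same shape as `series`.
#' @export
add_rician_noise <- function(series, snr, seed = 1, sigma = NULL) {
  if (is.null(sigma)) {
    if (snr <= 0) stop("snr must be positive")
    sigma <- mean(abs(series)) / snr
  }
  with_seed(seed, {
    g1 <- stats::rnorm(length(series), sd = sigma)
    g2 <- stats::rnorm(length(series), sd = sigma)
    out <- sqrt((series + g1)^2 + g2^2)
    dim(out) <- dim(series)
    out
  })
}

#' Condition a weighted adjacency into a Cholesky-ready target
#'
#' Turns the (zero-diagonal, arbitrary-scale) adjacency into the closest
#' positive-definite matrix usable as the covariance target of the time
#' series generator. The default is the plain Higham projection onto the
#' positive-semidefinite cone: eigenvalues clipped at `eig_floor`, diagonal
#' left free, so node signal variances inherit the heterogeneous
#' connectivity strengths of the network. With `unit_diagonal = TRUE` the
#' adjacency is instead rescaled into \[0, 1) (dividing by max weight +
#' 0.05 when any weight is >= 1) and projected to the nearest unit-diagonal
#' correlation matrix via [nearest_positive_definite()].
#'
#' @param network a [weighted_network()].
#' @param unit_diagonal normalize to a unit-diagonal correlation matrix
#'   (default `FALSE`: covariance target, diagonal free).
#' @inheritParams nearest_positive_definite
#' @return Conditioned symmetric positive-definite target matrix.
#' @export
correlation_target <- function(network, eig_floor = 1e-8,
                               unit_diagonal = FALSE) {
  A <- adjacency_matrix(network)
  if (unit_diagonal) {
    mx <- if (nrow(network$edges) > 0) max(network$edges$weight) else 0
    if (mx >= 1) A <- A / (mx + 0.05)
    diag(A) <- 1
    return(nearest_positive_definite(A, eig_floor = eig_floor))
  }
  eg <- eigen(A, symmetric = TRUE)
  C <- eg$vectors %*% (pmax(eg$values, eig_floor) * t(eg$vectors))
  (C + t(C)) / 2
}

#' Simulate a multi-subject cohort of synthetic BOLD time series
#'
#' Conditions the network adjacency once into a correlation target, then
#' generates `n_subjects` independent realizations of correlated node time
#' series with Rician noise, mimicking inter-subject variability in a
#' resting-state cohort. Each subject uses a distinct sub-seed derived
#' deterministically from `seed`; the noise scale `sigma_N` is fixed once
#' from the cohort-level mean signal magnitude (`~ baseline`).
#'
#' @param network a [weighted_network()] whose weights define the target
#'   correlation structure.
#' @param n_subjects number of subjects (the simulations use 20/40/60).
#' @param n_timepoints series length per node (default 150).
#' @param snr signal-to-noise ratio of the added Rician noise; `Inf` (or
#'   very large) disables noise in practice.
#' @param baseline additive signal baseline (default 100).
#' @param seed master integer seed; the panel is a pure function of all
#'   arguments.
#' @return An object of class `timeseries_panel`: list with `data` (list of
#'   `nodes x timepoints` matrices, one per subject), `target` (the
#'   conditioned correlation matrix), `n_timepoints`, `baseline`, `snr`,
#'   `seed`.
#' @export
generate_cohort <- function(network, n_subjects, n_timepoints = 150,
                            snr = 35, baseline = 100, seed = 1) {
  stopifnot(inherits(network, "weighted_network"), n_subjects >= 1)
  C <- correlation_target(network)
  sigma <- baseline / snr
  data <- vector("list", n_subjects)
  for (k in seq_len(n_subjects)) {
    y <- correlated_timeseries(C, n_timepoints = n_timepoints,
                               baseline = baseline,
                               seed = derive_seed(seed, 2L * k))
    if (is.finite(snr))
      y <- add_rician_noise(y, snr = snr, sigma = sigma,
                            seed = derive_seed(seed, 2L * k + 1L))
    data[[k]] <- y
  }
  structure(list(data = data, target = C, n_timepoints = n_timepoints,
                 baseline = baseline, snr = snr, seed = seed),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("<timeseries_panel: %d subjects, %d nodes x %d timepoints, snr=%g, baseline=%g>\n",
              length(x$data), nrow(x$data[[1]]), x$n_timepoints, x$snr,
              x$baseline))
  invisible(x)
}

#' Write/read a cohort as per-subject CSV files plus a manifest
#'
#' Each subject file holds one timepoint per row and one node per column
#' (0-based node ids in the header). The manifest is a CSV listing subject
#' file names alongside the panel's snr and seed.
#'
#' @param panel a `timeseries_panel` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param manifest path of a cohort manifest CSV.
#' @return The manifest path (write) or a list of subject matrices (read).
#' @export
write_cohort_csv <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(panel$data))
  for (k in seq_along(panel$data)) {
    files[k] <- file.path(dir, sprintf("subject_%03d.csv", k))
    m <- t(panel$data[[k]])
    colnames(m) <- seq_len(ncol(m)) - 1L
    utils::write.csv(m, files[k], row.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(file = basename(files), snr = panel$snr,
                              seed = panel$seed),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(manifest) {
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  lapply(man$file, function(f) {
    m <- as.matrix(utils::read.csv(file.path(dir, f), check.names = FALSE))
    dimnames(m) <- NULL
    t(m)
  })
}
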