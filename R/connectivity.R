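#' Subject-level Pearson correlation matrix
#'
#' Pairwise Pearson correlations between node time series, the standard
#' functional-connectivity estimate at the single-subject level.
#'
#' @param series numeric matrix, nodes x timepoints (>= 3 timepoints).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 3) stop("at least 3 timepoints are required")
  v <- apply(series, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance series at node(s): %s",
                 paste(which(v == 0), collapse = ", ")))
  M <- stats::cor(t(series))
  dimnames(M) <- NULL
  diag(M) <- 1
  M
}

#' Fisher-averaged group connectivity matrix
#'
#' Averages subject correlation matrices on the variance-stabilized Fisher
#' z scale: correlations are clipped to +/-(1 - 1e-7), transformed with
#' atanh, averaged across subjects, and transformed back with tanh so the
#' group matrix remains on the correlation scale.
#'
#' @param matrices list of equally sized subject correlation matrices.
#' @return Symmetric group matrix with unit diagonal and off-diagonal
#'   entries in (-1, 1).
#' @export
fisher_group_average <- function(matrices) {
  if (length(matrices) == 0) stop("at least one subject matrix is required")
  dims <- vapply(matrices, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[1, 1])) stop("subject matrices must share dimensions")
  clip <- 1 - 1e-7
  zbar <- Reduce(`+`, lapply(matrices, function(m)
    atanh(pmin(pmax(as.matrix(m), -clip), clip)))) / length(matrices)
  G <- tanh(zbar)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  dimnames(G) <- NULL
  G
}

#' Convert a group correlation matrix into a weighted network
#'
#' Drops the diagonal and discards non-positive correlations (percolation
#' and the community detection methods operate on non-negative weights).
#'
#' @param group symmetric correlation-scale matrix.
#' @return A [weighted_network()] whose edge weights are the positive
#'   off-diagonal correlations.
#' @export
group_to_network <- function(group) {
  G <- as.matrix(group)
  diag(G) <- 0
  n_neg <- sum(G[upper.tri(G)] < 0)
  if (n_neg > 0)
    message(sprintf("dropping %d negative-correlation edges", n_neg))
  G[G < 0] <- 0
  network_from_adjacency(G)
}

#' Group network straight from a cohort panel
#'
#' Convenience composition: per-subject Pearson matrices, Fisher group
#' average, conversion to a non-negative weighted network.
#'
#' @param panel a `timeseries_panel` (or plain list of node x time
#'   matrices).
#' @return A [weighted_network()].
#' @export
cohort_group_network <- function(panel) {
  series <- if (inherits(panel, "timeseries_panel")) panel$data else panel
  mats <- lapply(series, pearson_matrix)
  group_to_network(fisher_group_average(mats))
}
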