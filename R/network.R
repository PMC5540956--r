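#' Weighted undirected network
#'
#' The central container of the package: a symmetric, non-negatively
#' weighted, undirected graph over `n_nodes` nodes without self-loops.
#' Nodes are indexed `1..n_nodes` internally; the file readers/writers
#' translate to the 0-based ids used in the on-disk formats.
#'
#' @param edges data frame (or matrix) with columns `from`, `to`, `weight`;
#'   node ids in `1..n_nodes`, one row per undirected edge.
#' @param n_nodes number of nodes (isolated nodes are allowed and kept).
#' @return An object of class `weighted_network`: a list with elements
#'   `n_nodes` and `edges` (data frame with `from < to`, sorted).
#' @examples
#' net <- weighted_network(data.frame(from = c(1, 2), to = c(2, 3),
#'                                    weight = c(0.9, 0.5)), n_nodes = 3)
#' net
#' @export
weighted_network <- function(edges, n_nodes) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    from <- as.integer(edges$from)
    to <- as.integer(edges$to)
    w <- as.numeric(edges$weight)
    if (any(from == to)) stop("self-loops are not allowed")
    if (any(from < 1L | to < 1L | from > n_nodes | to > n_nodes))
      stop("node ids must lie in 1..n_nodes")
    if (any(!is.finite(w)) || any(w < 0))
      stop("edge weights must be finite and non-negative")
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    key <- (lo - 1) * as.double(n_nodes) + hi
    if (anyDuplicated(key)) stop("duplicate edges")
    ord <- order(lo, hi)
    edges <- data.frame(from = lo[ord], to = hi[ord], weight = w[ord])
  } else {
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network: %d nodes, %d edges", x$n_nodes,
              nrow(x$edges)))
  if (nrow(x$edges) > 0)
    cat(sprintf(", weights in [%.4g, %.4g]", min(x$edges$weight),
                max(x$edges$weight)))
  cat(">\n")
  invisible(x)
}

#' Build a network from a dense adjacency matrix
#'
#' Upper triangle is used; the matrix must be symmetric. Zero entries and
#' the diagonal are dropped.
#'
#' @param adj square symmetric numeric matrix with non-negative entries.
#' @return A [weighted_network()].
#' @export
network_from_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square")
  if (max(abs(adj - t(adj))) > 1e-9) stop("adjacency matrix must be symmetric")
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  weighted_network(data.frame(from = idx[, 1], to = idx[, 2],
                              weight = adj[idx]),
                   n_nodes = nrow(adj))
}

#' Dense adjacency matrix of a network
#'
#' @param net a [weighted_network()].
#' @return An `n_nodes x n_nodes` symmetric numeric matrix, zero diagonal.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_nodes
  A <- matrix(0, n, n)
  e <- net$edges
  A[cbind(e$from, e$to)] <- e$weight
  A[cbind(e$to, e$from)] <- e$weight
  A
}

#' Convert to an igraph object
#'
#' @param net a [weighted_network()].
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    igraph::E(g)$weight <- net$edges$weight
  }
  g
}

#' Node degrees and strengths
#'
#' Degree counts incident edges; strength sums their weights.
#'
#' @param net a [weighted_network()].
#' @return Integer (degree) or numeric (strength) vector of length `n_nodes`.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  tabulate(c(net$edges$from, net$edges$to), nbins = net$n_nodes)
}

#' @rdname node_degrees
#' @export
node_strengths <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  s <- numeric(net$n_nodes)
  e <- net$edges
  if (nrow(e) > 0) {
    add <- tapply(c(e$weight, e$weight), c(e$from, e$to), sum)
    s[as.integer(names(add))] <- as.numeric(add)
  }
  s
}

#' Canonicalize a partition
#'
#' Relabels community assignments to consecutive integers `1..K`, labels
#' ordered by decreasing community size (ties broken by the smallest member
#' node id), so that identical groupings always yield identical labels.
#'
#' @param membership integer-like vector, one community label per node.
#' @return Integer vector of the same length with labels `1..K` and an
#'   attribute `n_communities`.
#' @export
as_partition <- function(membership) {
  m <- as.integer(as.factor(membership))
  sizes <- tabulate(m)
  first <- match(seq_along(sizes), m)
  ord <- order(-sizes, first)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  out <- relabel[m]
  attr(out, "n_communities") <- length(sizes)
  out
}

#' Number of communities in a partition
#' @param partition vector of community labels.
#' @export
n_communities <- function(partition) length(unique(as.vector(partition)))

## --- on-disk formats (0-based ids, per the package's file conventions) ---

#' Read/write edge-list TSV
#'
#' Tab-separated columns `node_i`, `node_j`, `weight` with 0-based node ids.
#' `n_nodes` on read defaults to the largest id + 1.
#'
#' @param net a [weighted_network()].
#' @param path file path.
#' @param n_nodes optional node count override on read.
#' @export
write_edgelist_tsv <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  df <- data.frame(node_i = net$edges$from - 1L, node_j = net$edges$to - 1L,
                   weight = net$edges$weight)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_tsv
#' @export
read_edgelist_tsv <- function(path, n_nodes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_nodes))
    n_nodes <- if (nrow(df) > 0) max(df$node_i, df$node_j) + 1L else 0L
  weighted_network(data.frame(from = df$node_i + 1L, to = df$node_j + 1L,
                              weight = df$weight), n_nodes = n_nodes)
}

#' Read/write dense adjacency CSV
#'
#' Comma-separated square matrix with a header row of 0-based node ids.
#'
#' @inheritParams write_edgelist_tsv
#' @export
write_adjacency_csv <- function(net, path) {
  A <- adjacency_matrix(net)
  colnames(A) <- seq_len(ncol(A)) - 1L
  utils::write.csv(A, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path) {
  A <- as.matrix(utils::read.csv(path, header = TRUE, check.names = FALSE))
  dimnames(A) <- NULL
  network_from_adjacency(A)
}

#' Read/write partition TSV
#'
#' Tab-separated columns `node_id`, `community_id`, both 0-based; rows
#' ordered by node id.
#'
#' @param partition vector of community labels (one per node).
#' @param path file path.
#' @export
write_partition_tsv <- function(partition, path) {
  p <- as_partition(partition)
  df <- data.frame(node_id = seq_along(p) - 1L, community_id = p - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  p <- integer(nrow(df))
  p[df$node_id + 1L] <- df$community_id + 1L
  as_partition(p)
}
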