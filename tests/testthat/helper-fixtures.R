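# Fixture graphs used across tests (built in code, never stored on disk).

two_triangles <- function(w_intra = 1, bridge = NULL) {
  e <- data.frame(from = c(1, 1, 2, 4, 4, 5), to = c(2, 3, 3, 5, 6, 6),
                  weight = w_intra)
  if (!is.null(bridge))
    e <- rbind(e, data.frame(from = 3, to = 4, weight = bridge))
  weighted_network(e, 6)
}

two_cliques_bridge <- function() {
  cl <- function(off) {
    idx <- t(utils::combn(4, 2)) + off
    data.frame(from = idx[, 1], to = idx[, 2], weight = 1)
  }
  weighted_network(rbind(cl(0), cl(4),
                         data.frame(from = 4, to = 5, weight = 1)), 8)
}

path3 <- function() {
  weighted_network(data.frame(from = c(1, 2), to = c(2, 3),
                              weight = c(0.9, 0.5)), 3)
}

# Erdos-Renyi-ish random weighted graph with at least one edge.
rand_network <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p
    if (any(keep)) break
  }
  weighted_network(data.frame(from = idx[keep, 1], to = idx[keep, 2],
                              weight = stats::runif(sum(keep), 0.1, 1)), n)
}
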