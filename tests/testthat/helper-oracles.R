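# Independent oracles: deliberately separate code paths from the package
# (union-find instead of BFS, entropy-form NMI instead of the count
# formula, brute-force partition enumeration for Q and AS maxima).

# connected components by union-find
uf_components <- function(net) {
  parent <- seq_len(net$n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  e <- net$edges
  for (r in seq_len(nrow(e))) {
    a <- find(e$from[r])
    b <- find(e$to[r])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(net$n_nodes), find, integer(1))
}

uf_giant_size <- function(net) {
  max(tabulate(as.integer(as.factor(uf_components(net)))))
}

# NMI via the entropy decomposition 2*I(A;B)/(H(A)+H(B)), base-2 logs
# (the base cancels in the ratio).
nmi_oracle <- function(a, b) {
  tab <- table(a, b)
  N <- sum(tab)
  p <- tab / N
  pa <- rowSums(p); pb <- colSums(p)
  h <- function(x) -sum(ifelse(x > 0, x * log2(x), 0))
  mi <- sum(ifelse(p > 0, p * log2(p / outer(pa, pb)), 0))
  den <- h(pa) + h(pb)
  if (den == 0) return(1)
  2 * mi / den
}

# all set partitions of n elements as restricted growth strings
all_partitions <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    rows <- list()
    rec <- function(prefix, k) {
      i <- length(prefix) + 1L
      if (i > n) {
        rows[[length(rows) + 1L]] <<- prefix
        return()
      }
      for (lab in seq_len(k + 1L)) rec(c(prefix, lab), max(k, lab))
    }
    rec(integer(0), 0L)
    out <- do.call(rbind, rows)
    cache[[key]] <<- out
    out
  }
})

# exhaustive maximum modularity over all partitions
max_modularity_oracle <- function(net) {
  P <- all_partitions(net$n_nodes)
  e <- net$edges
  s <- node_strengths(net)
  W <- sum(e$weight)
  same_e <- P[, e$from, drop = FALSE] == P[, e$to, drop = FALSE]
  intra_w <- as.numeric(same_e %*% e$weight)
  pr <- which(upper.tri(diag(net$n_nodes)), arr.ind = TRUE)
  same_p <- P[, pr[, 1], drop = FALSE] == P[, pr[, 2], drop = FALSE]
  ss <- as.numeric(same_p %*% (s[pr[, 1]] * s[pr[, 2]]))
  null_term <- (sum(s^2) + 2 * ss) / (2 * W)^2
  q <- intra_w / W - null_term
  list(max = max(q), argmax = P[which.max(q), ])
}

# exhaustive maximum asymptotical surprise over all partitions
max_surprise_oracle <- function(net) {
  P <- all_partitions(net$n_nodes)
  n <- net$n_nodes
  e <- net$edges
  W <- sum(e$weight)
  same_e <- P[, e$from, drop = FALSE] == P[, e$to, drop = FALSE]
  q <- as.numeric(same_e %*% e$weight) / W
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  same_p <- P[, pr[, 1], drop = FALSE] == P[, pr[, 2], drop = FALSE]
  qe <- rowSums(same_p) / (n * (n - 1) / 2)
  # one-sided (upper-tail) form: densities at or below expectation carry
  # no surprise
  kl <- function(q, p) {
    t1 <- ifelse(q > 0, q * log(pmax(q, 1e-300) / p), 0)
    t2 <- ifelse(q < 1, (1 - q) * log(pmax(1 - q, 1e-300) / (1 - p)), 0)
    t1 + t2
  }
  as_val <- ifelse(q > qe & qe > 0 & qe < 1, W * kl(q, pmax(qe, 1e-300)),
                   0)
  list(max = max(as_val), argmax = P[which.max(as_val), ])
}
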