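#' Weighted Newman modularity of a partition
#'
#' Q = (1/2W) * sum_ij [w_ij - s_i s_j / 2W] delta(c_i, c_j), with W the
#' total edge weight and s_i the node strengths: the intra-community weight
#' in excess of the degree-preserving (configuration) null model.
#'
#' @param network a [weighted_network()] with at least one edge.
#' @param partition community labels, one per node.
#' @return Modularity Q (dimensionless; 0 for the single-community
#'   partition).
#' @export
modularity_score <- function(network, partition) {
  stopifnot(inherits(network, "weighted_network"))
  partition <- as.vector(partition)
  if (length(partition) != network$n_nodes || anyNA(partition))
    stop("partition must assign a community to every network node")
  e <- network$edges
  if (nrow(e) == 0) stop("modularity is undefined for an edgeless network")
  W <- sum(e$weight)
  intra <- partition[e$from] == partition[e$to]
  s <- node_strengths(network)
  S_c <- tapply(s, partition, sum)
  sum(e$weight[intra]) / W - sum(S_c^2) / (2 * W)^2
}

#' Community detection by modularity maximization (Louvain)
#'
#' Runs Louvain local moving + aggregation `n_restarts` times under
#' different node orders (seeded), keeping the partition of highest
#' modularity. Falls back to the single-community partition in the
#' (degenerate) case that no partition of positive modularity is found.
#'
#' @param network a [weighted_network()] with at least one edge.
#' @param seed integer RNG seed.
#' @param n_restarts number of randomized restarts (default 16).
#' @return Partition vector (labels 1..K, see [as_partition()]) with
#'   attribute `score` holding its modularity.
#' @export
louvain_communities <- function(network, seed = 1, n_restarts = 16) {
  stopifnot(inherits(network, "weighted_network"))
  if (nrow(network$edges) == 0) stop("network has no edges")
  g <- as_igraph(network)
  n <- network$n_nodes
  with_seed(seed, {
    best <- rep(1L, n)
    best_q <- -Inf
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
      # vertex i of the original graph is vertex perm[i] of the permuted one
      memb <- as.integer(igraph::membership(cl))[perm]
      q <- modularity_score(network, memb)
      if (q > best_q + 1e-12) { best_q <- q; best <- memb }
    }
    if (best_q < 0) { best <- rep(1L, n); best_q <- 0 }
    out <- as_partition(best)
    attr(out, "score") <- modularity_score(network, out)
    out
  })
}

#' Asymptotical Surprise of a partition
#'
#' AS = W * KL(q || <q>): the total edge weight times the binary
#' Kullback-Leibler divergence between the observed intracluster weight
#' fraction q and the fraction of intracluster node pairs <q> expected
#' under an Erdos-Renyi null,
#' AS = W * \[q ln(q/<q>) + (1-q) ln((1-q)/(1-<q>))\] for q > <q>,
#' with the convention 0 * ln 0 = 0. The statistic is the asymptotic form
#' of minus the log upper-tail probability of the observed intracluster
#' density, so it is one-sided: partitions whose intracluster density does
#' not exceed the null expectation (q <= <q>) carry no surprise and score
#' 0 — in particular the single-community and all-singleton partitions.
#'
#' @param network a [weighted_network()] with positive total weight.
#' @param partition community labels, one per node.
#' @return A list of class `surprise_score` with `value` (AS), `q` and
#'   `q_expected`.
#' @export
asymptotical_surprise <- function(network, partition) {
  stopifnot(inherits(network, "weighted_network"))
  partition <- as.vector(partition)
  if (length(partition) != network$n_nodes || anyNA(partition))
    stop("partition must assign a community to every network node")
  e <- network$edges
  W <- sum(e$weight)
  if (W <= 0) stop("asymptotical surprise needs positive total weight")
  n <- network$n_nodes
  q <- sum(e$weight[partition[e$from] == partition[e$to]]) / W
  sizes <- tabulate(as.integer(as.factor(partition)))
  q_exp <- sum(sizes * (sizes - 1) / 2) / (n * (n - 1) / 2)
  structure(list(value = .surprise_kl(q, q_exp) * W, q = q,
                 q_expected = q_exp), class = "surprise_score")
}

# one-sided binary KL (upper tail): 0 unless q exceeds the expectation p;
# 0*log(0) = 0; degenerate null values of p carry no surprise
.surprise_kl <- function(q, p) {
  q <- min(max(q, 0), 1) # guard round-off just outside [0, 1]
  if (q <= p + 1e-15) return(0)
  if (p <= 0 || p >= 1)
    stop("degenerate expected density with q > <q>")
  term <- function(a, b) if (a <= 0) 0 else a * log(a / b)
  term(q, p) + term(1 - q, 1 - p)
}

#' @export
print.surprise_score <- function(x, ...) {
  cat(sprintf("<surprise: AS=%.6g (q=%.4g, <q>=%.4g)>\n", x$value, x$q,
              x$q_expected))
  invisible(x)
}

#' Community detection by Asymptotical Surprise maximization (PACO)
#'
#' Agglomerative partitioning-cost optimization: starting from singleton
#' communities, edges are visited in decreasing weight order (Kruskal
#' style) and the endpoint communities merged whenever the merge increases
#' Asymptotical Surprise; a local node-move refinement pass then relocates
#' single nodes while AS keeps improving. The whole procedure is repeated
#' `n_trials` times under seeded randomized tie orders and the best-AS
#' partition is returned.
#'
#' @param network a [weighted_network()] with at least one edge.
#' @param seed integer RNG seed.
#' @param n_trials number of randomized trials (default 16).
#' @return Partition vector with attribute `score` holding its AS value.
#' @export
paco_communities <- function(network, seed = 1, n_trials = 16) {
  stopifnot(inherits(network, "weighted_network"))
  e <- network$edges
  if (nrow(e) == 0) stop("network has no edges")
  n <- network$n_nodes
  W <- sum(e$weight)
  pairs_tot <- n * (n - 1) / 2
  # adjacency list for the refinement pass
  adj <- .adjacency_list(e, n)
  with_seed(seed, {
    best <- NULL
    best_as <- -Inf
    for (trial in seq_len(n_trials)) {
      # trial 1 follows the strict decreasing-weight (Kruskal) order;
      # later trials draw weight-biased random orders so restarts explore
      # different agglomeration paths
      ord <- if (trial == 1) order(-e$weight, sample.int(nrow(e)))
             else sample.int(nrow(e), prob = e$weight)
      memb <- .paco_sweep(e, ord, adj, n, W, pairs_tot)
      # alternate randomized local moves and community merges to a fixpoint
      for (round in seq_len(20)) {
        m1 <- .paco_refine(memb, adj, n, W, pairs_tot)
        m2 <- .paco_merge_communities(m1, e, n, W, pairs_tot)
        if (identical(m2, memb)) break
        memb <- m2
      }
      as_val <- asymptotical_surprise(network, memb)$value
      if (as_val > best_as + 1e-12) { best_as <- as_val; best <- memb }
    }
    # never worse than the trivial partitions (both have AS = 0)
    if (best_as < 0) { best <- seq_len(n); best_as <- 0 }
    out <- as_partition(best)
    attr(out, "score") <- asymptotical_surprise(network, out)$value
    out
  })
}

.adjacency_list <- function(e, n) {
  adj <- vector("list", n)
  if (nrow(e) == 0) return(adj)
  idx <- c(e$from, e$to)
  nbr <- c(e$to, e$from)
  w <- c(e$weight, e$weight)
  ord <- order(idx)
  idx <- idx[ord]; nbr <- nbr[ord]; w <- w[ord]
  bounds <- findInterval(0:n, idx)
  for (v in seq_len(n)) {
    if (bounds[v + 1] > bounds[v]) {
      sel <- (bounds[v] + 1):bounds[v + 1]
      adj[[v]] <- cbind(nbr[sel], w[sel])
    } else adj[[v]] <- cbind(integer(0), numeric(0))
  }
  adj
}

# Kruskal-style agglomerative sweep: starting from singletons, edges are
# visited in the given order and for each cross-community edge (u, v) the
# best AS-improving operation among {move v to u's community, move u to
# v's community, merge the two communities} is applied; sweeps repeat
# until no operation improves. Merges are evaluated via the smaller
# community's adjacency and only while one side is small (large-block
# merges are handled by the dedicated merge pass).
.paco_sweep <- function(e, ord, adj, n, W, pairs_tot, max_sweep = 15,
                        merge_cap = 8L) {
  memb <- seq_len(n)
  size <- rep(1L, n)
  intra_w <- 0
  intra_pairs <- 0
  cur <- 0 # all singletons: q = 0, <q> = 0
  w_to_comm <- function(v, comm) {
    a <- adj[[v]]
    if (nrow(a) == 0) return(0)
    sum(a[memb[a[, 1]] == comm, 2])
  }
  as_of <- function(w, p) W * .surprise_kl(w / W, p / pairs_tot)
  for (sweep in seq_len(max_sweep)) {
    changed <- FALSE
    for (r in ord) {
      u <- e$from[r]
      v <- e$to[r]
      cu <- memb[u]
      cv <- memb[v]
      if (cu == cv) next
      # candidate 1: move v into cu; candidate 2: move u into cv
      d_w <- c(w_to_comm(v, cu) - w_to_comm(v, cv),
               w_to_comm(u, cv) - w_to_comm(u, cu))
      d_p <- c(size[cu] - (size[cv] - 1), size[cv] - (size[cu] - 1))
      # candidate 3: merge, while one side is still small
      if (min(size[cu], size[cv]) <= merge_cap) {
        small <- if (size[cu] <= size[cv]) cu else cv
        other <- if (small == cu) cv else cu
        wbet <- sum(vapply(which(memb == small), w_to_comm, numeric(1),
                           comm = other))
        d_w <- c(d_w, wbet)
        d_p <- c(d_p, as.double(size[cu]) * size[cv])
      }
      gains <- vapply(seq_along(d_w), function(i)
        as_of(intra_w + d_w[i], intra_pairs + d_p[i]) - cur, numeric(1))
      k <- which.max(gains)
      if (gains[k] <= 1e-12) next
      if (k == 1) {
        memb[v] <- cu
        size[cv] <- size[cv] - 1L
        size[cu] <- size[cu] + 1L
      } else if (k == 2) {
        memb[u] <- cv
        size[cu] <- size[cu] - 1L
        size[cv] <- size[cv] + 1L
      } else {
        memb[memb == cv] <- cu
        size[cu] <- size[cu] + size[cv]
        size[cv] <- 0L
      }
      intra_w <- intra_w + d_w[k]
      intra_pairs <- intra_pairs + d_p[k]
      cur <- as_of(intra_w, intra_pairs)
      changed <- TRUE
    }
    if (!changed) break
  }
  memb
}

# Local node moves (including moves to singleton) while AS improves.
.paco_refine <- function(memb, adj, n, W, pairs_tot, max_pass = 10) {
  size <- tabulate(memb, nbins = max(memb, n))
  intra_w <- 0
  for (v in seq_len(n)) {
    a <- adj[[v]]
    if (nrow(a) > 0)
      intra_w <- intra_w + sum(a[memb[a[, 1]] == memb[v], 2])
  }
  intra_w <- intra_w / 2
  intra_pairs <- sum(size * (size - 1) / 2)
  cur_as <- W * .surprise_kl(intra_w / W, intra_pairs / pairs_tot)
  free_label <- length(size) + 1L
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (v in sample.int(n)) {
      a <- adj[[v]]
      if (nrow(a) == 0) next
      cv <- memb[v]
      nb_comm <- memb[a[, 1]]
      w_to <- tapply(a[, 2], nb_comm, sum)
      w_own <- if (as.character(cv) %in% names(w_to))
        w_to[[as.character(cv)]] else 0
      cand_comms <- unique(c(as.integer(names(w_to)), 0L)) # 0 = singleton
      best_gain <- 1e-12
      best_c <- NA_integer_
      for (cc in cand_comms) {
        if (cc == cv) next
        w_new <- if (cc == 0L) 0 else w_to[[as.character(cc)]]
        sz_new <- if (cc == 0L) 0L else size[cc]
        d_w <- w_new - w_own
        d_pairs <- sz_new - (size[cv] - 1L)
        as2 <- W * .surprise_kl((intra_w + d_w) / W,
                              (intra_pairs + d_pairs) / pairs_tot)
        if (as2 - cur_as > best_gain) {
          best_gain <- as2 - cur_as
          best_c <- cc
        }
      }
      if (!is.na(best_c)) {
        cc <- best_c
        w_new <- if (cc == 0L) 0 else w_to[[as.character(cc)]]
        sz_new <- if (cc == 0L) 0L else size[cc]
        intra_w <- intra_w + (w_new - w_own)
        intra_pairs <- intra_pairs + (sz_new - (size[cv] - 1L))
        cur_as <- W * .surprise_kl(intra_w / W, intra_pairs / pairs_tot)
        size[cv] <- size[cv] - 1L
        if (cc == 0L) {
          memb[v] <- free_label
          size <- c(size, rep(0L, free_label - length(size)))
          size[free_label] <- 1L
          free_label <- free_label + 1L
        } else {
          memb[v] <- cc
          size[cc] <- size[cc] + 1L
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# Greedy merges of whole communities while AS improves (escapes local
# optima that single-node moves cannot).
.paco_merge_communities <- function(memb, e, n, W, pairs_tot) {
  repeat {
    labs <- as.integer(as.factor(memb))
    k <- max(labs)
    if (k == 1) return(memb)
    size <- tabulate(labs, nbins = k)
    B <- matrix(0, k, k)
    ca <- labs[e$from]
    cb <- labs[e$to]
    for (r in seq_along(ca)) {
      B[ca[r], cb[r]] <- B[ca[r], cb[r]] + e$weight[r]
    }
    B <- B + t(B)
    intra_w <- sum(diag(B)) / 2
    intra_pairs <- sum(size * (size - 1) / 2)
    cur <- W * .surprise_kl(intra_w / W, intra_pairs / pairs_tot)
    best_gain <- 1e-12
    best_pair <- NULL
    for (a in seq_len(k - 1)) for (b in seq.int(a + 1, k)) {
      if (B[a, b] == 0) next
      cand <- W * .surprise_kl((intra_w + B[a, b]) / W,
                             (intra_pairs + as.double(size[a]) * size[b]) /
                               pairs_tot)
      if (cand - cur > best_gain) {
        best_gain <- cand - cur
        best_pair <- c(a, b)
      }
    }
    if (is.null(best_pair)) return(memb)
    memb[labs == best_pair[2]] <- memb[which(labs == best_pair[1])[1]]
    memb <- match(memb, unique(memb))
    # loop again with the merged partition
  }
}

#' Community detection by the map equation (InfoMap adapter)
#'
#' Thin adapter around an InfoMap backend. The default backend is igraph's
#' built-in InfoMap implementation (`igraph::cluster_infomap`), matching
#' the igraph tooling commonly used for this method; alternatively an
#' external `Infomap` command can be invoked via `backend = "command"`,
#' writing the network as a Pajek-style link list, running the command, and
#' parsing the returned module assignments. Nodes missing from a backend's
#' output are assigned to fresh singleton communities with a warning.
#'
#' @param network a [weighted_network()] with at least one edge.
#' @param seed integer RNG seed.
#' @param backend `"igraph"` (default) or `"command"`.
#' @param command external InfoMap executable (for `backend = "command"`).
#' @param n_trials attempts for the igraph backend.
#' @return Partition vector with attribute `score` holding the partition's
#'   modularity (for comparability across methods).
#' @export
infomap_communities <- function(network, seed = 1,
                                backend = c("igraph", "command"),
                                command = "Infomap", n_trials = 10) {
  stopifnot(inherits(network, "weighted_network"))
  if (nrow(network$edges) == 0) stop("network has no edges")
  backend <- match.arg(backend)
  memb <- if (backend == "igraph") {
    if (!"cluster_infomap" %in% getNamespaceExports("igraph"))
      stop("configuration error: igraph InfoMap backend unavailable; install igraph with InfoMap support")
    g <- as_igraph(network)
    with_seed(seed, as.integer(igraph::membership(
      igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight,
                              nb.trials = n_trials))))
  } else {
    .infomap_command(network, command, seed)
  }
  if (length(memb) < network$n_nodes || anyNA(memb)) {
    warning("backend left nodes unassigned; treating them as singletons")
    full <- seq.int(max(memb, na.rm = TRUE) + 1L,
                    length.out = network$n_nodes)
    full[seq_along(memb)][!is.na(memb)] <- memb[!is.na(memb)]
    memb <- full
  }
  out <- as_partition(memb)
  attr(out, "score") <- modularity_score(network, out)
  out
}

.infomap_command <- function(network, command, seed) {
  if (Sys.which(command) == "")
    stop(sprintf("configuration error: InfoMap backend '%s' not found on PATH; install it from mapequation.org or use backend = \"igraph\"",
                 command))
  dir <- tempfile("infomap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  netfile <- file.path(dir, "net.txt")
  df <- data.frame(a = network$edges$from, b = network$edges$to,
                   w = network$edges$weight)
  utils::write.table(df, netfile, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  status <- system2(command, c(netfile, dir, "--clu", "-2", "--silent",
                               "--seed", seed))
  clu <- file.path(dir, "net.clu")
  if (status != 0 || !file.exists(clu))
    stop("format error: InfoMap backend produced no parseable output")
  out <- utils::read.table(clu, comment.char = "#")
  memb <- rep(NA_integer_, network$n_nodes)
  memb[out[, 1]] <- out[, 2]
  memb
}

#' Run a community detection method by name
#'
#' Dispatches the three methods of the analysis pipeline: `"newman"`
#' (modularity/Louvain), `"surprise"` (Asymptotical Surprise/PACO) and
#' `"infomap"`.
#'
#' @param network a [weighted_network()].
#' @param method one of `"newman"`, `"surprise"`, `"infomap"`.
#' @param seed integer RNG seed.
#' @param restarts restarts/trials forwarded to the method.
#' @param ... further arguments forwarded to the method.
#' @return Partition vector with a `score` attribute.
#' @export
detect_communities <- function(network,
                               method = c("newman", "surprise", "infomap"),
                               seed = 1, restarts = 16, ...) {
  method <- match.arg(method)
  switch(method,
         newman = louvain_communities(network, seed = seed,
                                      n_restarts = restarts, ...),
         surprise = paco_communities(network, seed = seed,
                                     n_trials = restarts, ...),
         infomap = infomap_communities(network, seed = seed, ...))
}
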