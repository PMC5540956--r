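#' Parameters for the weighted LFR benchmark
#'
#' Bundles and validates the parameters of the weighted
#' Lancichinetti-Fortunato-Radicchi (LFR) benchmark: networks with power-law
#' degree and community-size distributions, a planted partition, and
#' controlled topological (`mixing_topology`, mu_t) and weight
#' (`mixing_weight`, mu_w) mixing. Defaults are the benchmark configuration
#' used throughout the package's simulations: 600 nodes, degree exponent 2,
#' community-size exponent 1, mean degree 12 capped at 50, community sizes
#' in 5..50, and mu_t = mu_w = 0.2.
#'
#' @param n_nodes number of nodes N.
#' @param degree_exponent power-law exponent of the degree distribution
#'   (tau_d > 1).
#' @param community_exponent power-law exponent of the community-size
#'   distribution (tau_c >= 1).
#' @param avg_degree target mean degree.
#' @param max_degree maximum degree.
#' @param min_community,max_community bounds on planted community sizes.
#' @param mixing_topology fraction mu_t in \[0,1\] of each node's edges that
#'   reach outside its own community.
#' @param mixing_weight fraction mu_w in \[0,1\] of each node's strength
#'   carried by inter-community edges.
#' @param strength_exponent exponent beta of the node strength law
#'   s_i = k_i^beta used for weight generation.
#' @param seed integer RNG seed.
#' @return A validated list of class `lfr_params`.
#' @export
lfr_params <- function(n_nodes = 600, degree_exponent = 2,
                       community_exponent = 1, avg_degree = 12,
                       max_degree = 50, min_community = 5,
                       max_community = 50, mixing_topology = 0.2,
                       mixing_weight = 0.2, strength_exponent = 1.5,
                       seed = 1) {
  p <- list(n_nodes = as.integer(n_nodes),
            degree_exponent = degree_exponent,
            community_exponent = community_exponent,
            avg_degree = avg_degree, max_degree = as.integer(max_degree),
            min_community = as.integer(min_community),
            max_community = as.integer(max_community),
            mixing_topology = mixing_topology,
            mixing_weight = mixing_weight,
            strength_exponent = strength_exponent,
            seed = as.integer(seed))
  if (p$mixing_topology < 0 || p$mixing_topology > 1 ||
      p$mixing_weight < 0 || p$mixing_weight > 1)
    stop("mixing parameters must lie in [0, 1]")
  if (p$min_community > p$max_community || p$max_community > p$n_nodes)
    stop("community-size bounds must satisfy min <= max <= n_nodes")
  if (p$avg_degree > p$max_degree || p$max_degree >= p$n_nodes)
    stop("degrees must satisfy avg_degree <= max_degree < n_nodes")
  if (p$degree_exponent <= 1) stop("degree_exponent must exceed 1")
  if (p$community_exponent < 1) stop("community_exponent must be >= 1")
  class(p) <- "lfr_params"
  p
}

# Mean of the continuous truncated power law p(x) ~ x^(-tau) on [a, b].
.plaw_mean <- function(a, b, tau) {
  num <- if (abs(tau - 2) < 1e-12) log(b / a) else
    (b^(2 - tau) - a^(2 - tau)) / (2 - tau)
  den <- if (abs(tau - 1) < 1e-12) log(b / a) else
    (b^(1 - tau) - a^(1 - tau)) / (1 - tau)
  num / den
}

# Inverse-CDF sampling from the truncated power law on [a, b].
.plaw_sample <- function(n, a, b, tau) {
  u <- stats::runif(n)
  if (abs(tau - 1) < 1e-12) {
    a * (b / a)^u
  } else {
    (a^(1 - tau) + u * (b^(1 - tau) - a^(1 - tau)))^(1 / (1 - tau))
  }
}

# Power-law degree sequence with mean within 2% of the target (resampled up
# to 100 times), values capped at max_k.
.sample_degrees <- function(n, tau, k_avg, k_max) {
  f <- function(a) .plaw_mean(a, k_max, tau) - k_avg
  if (f(1) > 0) stop("avg_degree infeasible: below the minimum of the law")
  a <- stats::uniroot(f, c(1, k_max - 1e-6), tol = 1e-10)$root
  for (attempt in seq_len(100)) {
    k <- pmax(1L, pmin(as.integer(round(.plaw_sample(n, a, k_max, tau))),
                       as.integer(k_max)))
    if (abs(mean(k) - k_avg) <= 0.02 * k_avg) return(k)
  }
  stop(sprintf("could not sample a degree sequence with mean %.3g +/- 2%%",
               k_avg))
}

# Community sizes from a truncated power law, adjusted in unit steps to
# tile exactly n nodes within [min_c, max_c].
.sample_community_sizes <- function(n, tau, min_c, max_c) {
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, as.integer(round(.plaw_sample(1, min_c, max_c, tau))))
  sizes <- pmax(min_c, pmin(sizes, max_c))
  for (it in seq_len(10000)) {
    d <- sum(sizes) - n
    if (d == 0) return(sizes)
    if (d > 0) {
      cand <- which(sizes > min_c)
      if (length(cand) == 0) {
        if (length(sizes) == 1) stop("community sizes cannot tile n_nodes")
        drop <- sample(length(sizes), 1)
        sizes <- sizes[-drop]
      } else {
        i <- if (length(cand) == 1) cand else sample(cand, 1)
        sizes[i] <- sizes[i] - 1L
      }
    } else {
      cand <- which(sizes < max_c)
      if (length(cand) == 0) sizes <- c(sizes, min_c)
      else {
        i <- if (length(cand) == 1) cand else sample(cand, 1)
        sizes[i] <- sizes[i] + 1L
      }
    }
  }
  stop("community sizes cannot tile n_nodes")
}

# Greedy community assignment: nodes in decreasing internal-degree order,
# each placed in a random community with free slots large enough to host
# its internal degree.
.assign_communities <- function(int_deg, sizes) {
  n <- length(int_deg)
  membership <- integer(n)
  slots <- sizes
  ord <- order(-int_deg, stats::runif(n))
  for (v in ord) {
    ok <- which(slots > 0 & sizes - 1L >= int_deg[v])
    if (length(ok) == 0) return(NULL)
    c_id <- if (length(ok) == 1) ok else sample(ok, 1, prob = slots[ok])
    membership[v] <- c_id
    slots[c_id] <- slots[c_id] - 1L
  }
  membership
}

# Random pairing of stubs with local repair: resolve self-loops, duplicate
# edges and (when `groups` is given) forbidden same-group pairs by random
# double-edge swaps; irreparable stubs are dropped.
.pair_stubs <- function(deg, ids = seq_along(deg), groups = NULL,
                        forbid = c("none", "same_group")) {
  forbid <- match.arg(forbid)
  stubs <- rep(ids, deg)
  if (length(stubs) < 2) return(cbind(integer(0), integer(0)))
  if (length(stubs) %% 2 == 1) stubs <- stubs[-sample(length(stubs), 1)]
  stubs <- sample(stubs)
  m <- length(stubs) / 2
  a <- stubs[seq_len(m)]
  b <- stubs[m + seq_len(m)]
  n_max <- max(ids)
  bad_of <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- (lo - 1) * as.double(n_max) + hi
    bad <- a == b | duplicated(key) | duplicated(key, fromLast = TRUE)
    if (forbid == "same_group") bad <- bad | groups[a] == groups[b]
    which(bad)
  }
  for (pass in seq_len(30)) {
    bad <- bad_of(a, b)
    if (length(bad) == 0) break
    for (e in bad) {
      f <- sample(m, 1)
      if (f == e) next
      # propose swap (a_e,b_e),(a_f,b_f) -> (a_e,b_f),(a_f,b_e)
      na <- a; nb <- b
      nb[e] <- b[f]; nb[f] <- b[e]
      if (length(bad_of(na[c(e, f)], nb[c(e, f)])) == 0 &&
          !any(.edge_exists(na, nb, e, f, n_max))) {
        a <- na; b <- nb
      }
    }
  }
  bad <- bad_of(a, b)
  if (length(bad) > 0) { a <- a[-bad]; b <- b[-bad] }
  cbind(pmin(a, b), pmax(a, b))
}

# would swapped pairs e,f duplicate an existing edge?
.edge_exists <- function(a, b, e, f, n_max) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (lo - 1) * as.double(n_max) + hi
  k2 <- key[c(e, f)]
  vapply(k2, function(k) sum(key == k) > 1, logical(1))
}

# Simple graph on `members` with internal degrees `deg` (igraph's
# Viger-Latapy sampler when feasible, stub pairing with repair otherwise).
.intra_edges <- function(members, deg) {
  keep <- deg > 0
  members <- members[keep]; deg <- deg[keep]
  if (length(members) < 2 || sum(deg) < 2)
    return(cbind(integer(0), integer(0)))
  if (sum(deg) %% 2 == 1) {
    i <- sample(length(deg), 1)
    deg[i] <- deg[i] - 1L
    if (deg[i] == 0) { members <- members[-i]; deg <- deg[-i] }
    if (length(members) < 2) return(cbind(integer(0), integer(0)))
  }
  el <- tryCatch(suppressWarnings({
    g <- igraph::sample_degseq(deg, method = "vl")
    igraph::as_edgelist(g)
  }), error = function(e) NULL)
  if (is.null(el)) {
    idx <- .pair_stubs(deg, ids = seq_along(deg))
    el <- idx
  }
  if (nrow(el) == 0) return(cbind(integer(0), integer(0)))
  cbind(members[el[, 1]], members[el[, 2]])
}

#' Generate a weighted LFR benchmark network
#'
#' Builds a weighted undirected network with a planted community partition:
#' degrees and community sizes are drawn from truncated power laws, each
#' node splits its edges between its own community and the rest of the
#' network according to `mixing_topology`, and edge weights are assigned so
#' that node strength follows s_i = k_i^beta with the inter-community
#' strength fraction matching `mixing_weight`. When `mixing_topology > 0`
#' and the realized graph is not connected, the giant component is kept if
#' it covers at least 95% of nodes, otherwise the construction is retried;
#' with `mixing_topology = 0` communities are mutually disconnected by
#' design and the network is returned as built.
#'
#' @param params an [lfr_params()] object.
#' @param mixing_tolerance maximum allowed deviation of the realized mean
#'   mixing from the targets (default 0.05).
#' @return A list with elements `network` (a [weighted_network()]),
#'   `membership` (planted partition, labels 1..K in decreasing community
#'   size) and `params`.
#' @examples
#' b <- generate_lfr(lfr_params(n_nodes = 120, avg_degree = 8,
#'                              max_degree = 20, min_community = 10,
#'                              max_community = 40, seed = 7))
#' empirical_mixing(b$network, b$membership)
#' @export
generate_lfr <- function(params, mixing_tolerance = 0.05) {
  stopifnot(inherits(params, "lfr_params"))
  with_seed(params$seed, {
    last_mix <- c(NA, NA)
    fallback <- NULL
    for (attempt in seq_len(20)) {
      built <- .build_lfr_once(params)
      if (is.null(built)) next
      mix <- empirical_mixing(built$network, built$membership)
      last_mix <- c(mix$mu_t_hat, mix$mu_w_hat)
      if (abs(mix$mu_t_hat - params$mixing_topology) > mixing_tolerance ||
          abs(mix$mu_w_hat - params$mixing_weight) > mixing_tolerance)
        next
      if (built$network$n_nodes == params$n_nodes) return(built)
      # disconnected build trimmed to its giant component: keep as a
      # fallback, but prefer a fully connected realization
      if (is.null(fallback)) fallback <- built
    }
    if (!is.null(fallback)) {
      warning(sprintf("no fully connected realization in 20 attempts; returning a giant component of %d/%d nodes",
                      fallback$network$n_nodes, params$n_nodes))
      return(fallback)
    }
    stop(sprintf(paste0("failed to reach target mixing (mu_t=%.3g, ",
                        "mu_w=%.3g); achieved mu_t=%.3g, mu_w=%.3g"),
                 params$mixing_topology, params$mixing_weight,
                 last_mix[1], last_mix[2]))
  })
}

.build_lfr_once <- function(p) {
  n <- p$n_nodes
  k <- .sample_degrees(n, p$degree_exponent, p$avg_degree, p$max_degree)
  sizes <- .sample_community_sizes(n, p$community_exponent,
                                   p$min_community, p$max_community)
  # stochastic rounding keeps E[ext_i / k_i] exactly mu_t
  ext_exact <- p$mixing_topology * k
  ext <- as.integer(floor(ext_exact)) +
    stats::rbinom(n, 1L, ext_exact - floor(ext_exact))
  int <- k - ext
  over <- int > max(sizes) - 1L
  ext[over] <- ext[over] + (int[over] - (max(sizes) - 1L))
  int[over] <- max(sizes) - 1L
  membership <- NULL
  for (try in seq_len(50)) {
    membership <- .assign_communities(int, sizes)
    if (!is.null(membership)) break
  }
  if (is.null(membership)) return(NULL)

  el <- vector("list", length(sizes) + 1L)
  for (c_id in seq_along(sizes)) {
    mem <- which(membership == c_id)
    el[[c_id]] <- .intra_edges(mem, int[mem])
  }
  if (sum(ext) >= 2 && p$mixing_topology > 0) {
    el[[length(el)]] <- .pair_stubs(ext, ids = seq_len(n),
                                    groups = membership,
                                    forbid = "same_group")
  }
  el <- do.call(rbind, el)
  if (is.null(el) || nrow(el) == 0) return(NULL)
  w <- .assign_weights(el, membership, n, p)
  net <- weighted_network(data.frame(from = el[, 1], to = el[, 2],
                                     weight = w), n_nodes = n)
  if (p$mixing_topology > 0) {
    comp <- igraph::components(as_igraph(net))
    if (max(comp$csize) < 0.95 * n) return(NULL)
    if (max(comp$csize) < n) {
      giant <- which(comp$membership == which.max(comp$csize))
      net <- .induced_network(net, giant)
      membership <- membership[giant]
    }
  }
  list(network = net, membership = as_partition(membership), params = p)
}

# Edge weights: node strength target s_i = k_i^beta split (1-mu_w)/mu_w
# between intra- and inter-community edges; initialized from per-node
# per-edge shares and balanced multiplicatively toward the targets.
.assign_weights <- function(el, membership, n, p) {
  intra <- membership[el[, 1]] == membership[el[, 2]]
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  d_int <- tabulate(c(el[intra, 1], el[intra, 2]), nbins = n)
  d_ext <- deg - d_int
  s <- deg^p$strength_exponent
  t_int <- ifelse(d_ext == 0, s, (1 - p$mixing_weight) * s)
  t_ext <- ifelse(d_int == 0, s, p$mixing_weight * s)
  t_int[d_int == 0] <- 0
  t_ext[d_ext == 0] <- 0
  share_int <- ifelse(d_int > 0, t_int / d_int, 0)
  share_ext <- ifelse(d_ext > 0, t_ext / d_ext, 0)
  w <- ifelse(intra,
              (share_int[el[, 1]] + share_int[el[, 2]]) / 2,
              (share_ext[el[, 1]] + share_ext[el[, 2]]) / 2)
  for (it in seq_len(8)) {
    a_int <- numeric(n); a_ext <- numeric(n)
    wi <- w[intra]; we <- w[!intra]
    if (length(wi) > 0) {
      acc <- tapply(c(wi, wi), c(el[intra, 1], el[intra, 2]), sum)
      a_int[as.integer(names(acc))] <- acc
    }
    if (length(we) > 0) {
      acc <- tapply(c(we, we), c(el[!intra, 1], el[!intra, 2]), sum)
      a_ext[as.integer(names(acc))] <- acc
    }
    f_int <- ifelse(a_int > 0, t_int / a_int, 1)
    f_ext <- ifelse(a_ext > 0, t_ext / a_ext, 1)
    w <- ifelse(intra,
                w * (f_int[el[, 1]] + f_int[el[, 2]]) / 2,
                w * (f_ext[el[, 1]] + f_ext[el[, 2]]) / 2)
  }
  pmax(w, .Machine$double.eps)
}

# Subnetwork induced by `nodes` (ids remapped to 1..length(nodes)).
.induced_network <- function(net, nodes) {
  idmap <- integer(net$n_nodes)
  idmap[nodes] <- seq_along(nodes)
  e <- net$edges
  keep <- idmap[e$from] > 0 & idmap[e$to] > 0
  weighted_network(data.frame(from = idmap[e$from[keep]],
                              to = idmap[e$to[keep]],
                              weight = e$weight[keep]),
                   n_nodes = length(nodes))
}

#' Empirical mixing of a partitioned weighted network
#'
#' Measures the realized topological and weight mixing of a network against
#' a partition: the mean over (non-isolated) nodes of the fraction of
#' incident edges, respectively incident edge weight, that connects to
#' other communities.
#'
#' @param network a [weighted_network()].
#' @param partition community labels, one per node.
#' @return A list with `mu_t_hat` (degree mixing) and `mu_w_hat` (strength
#'   mixing), both in \[0, 1\].
#' @export
empirical_mixing <- function(network, partition) {
  stopifnot(inherits(network, "weighted_network"))
  partition <- as.vector(partition)
  if (length(partition) != network$n_nodes || anyNA(partition))
    stop("partition must assign a community to every network node")
  e <- network$edges
  n <- network$n_nodes
  deg <- tabulate(c(e$from, e$to), nbins = n)
  str <- node_strengths(network)
  inter <- partition[e$from] != partition[e$to]
  deg_ext <- tabulate(c(e$from[inter], e$to[inter]), nbins = n)
  str_ext <- numeric(n)
  if (any(inter)) {
    we <- e$weight[inter]
    acc <- tapply(c(we, we), c(e$from[inter], e$to[inter]), sum)
    str_ext[as.integer(names(acc))] <- acc
  }
  keep <- deg > 0
  list(mu_t_hat = mean(deg_ext[keep] / deg[keep]),
       mu_w_hat = mean(str_ext[keep] / str[keep]))
}
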