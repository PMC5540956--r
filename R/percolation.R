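#' Sparsify a weighted network at an edge-weight threshold
#'
#' Retains exactly the edges with weight >= `t` (closed convention, so
#' every observed edge weight is an attainable threshold). The node set is
#' unchanged: nodes detached by thresholding persist as isolates.
#'
#' @param network a [weighted_network()].
#' @param t threshold, >= 0.
#' @return The thresholded [weighted_network()].
#' @export
sparsify <- function(network, t) {
  stopifnot(inherits(network, "weighted_network"))
  if (t < 0) stop("threshold must be non-negative")
  keep <- network$edges$weight >= t
  weighted_network(network$edges[keep, , drop = FALSE], network$n_nodes)
}

#' Giant connected component
#'
#' Size and membership of the largest connected component (edges with
#' positive weight). An edgeless graph has giant size 1; ties between
#' equally large components are broken toward the component containing the
#' lowest node id.
#'
#' @param network a [weighted_network()].
#' @return List with `size` and `members` (sorted node ids).
#' @export
giant_component <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  comp <- igraph::components(as_igraph(network))
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # lowest-id tie-break: component whose smallest member comes first
    firsts <- vapply(best, function(b) min(which(comp$membership == b)),
                     integer(1))
    best <- best[which.min(firsts)]
  }
  members <- which(comp$membership == best)
  list(size = length(members), members = members)
}

#' Percolation profile of a weighted network
#'
#' Sweeps edge-weight thresholds and records the giant-component size at
#' each, yielding the step-wise percolation curve. The percolation
#' threshold `t_star` is, under the default rule, the highest threshold at
#' which the giant component still contains every node of the original
#' (unthresholded) giant component; above it the network starts breaking
#' apart. The alternative rule `"maxdrop"` returns the threshold at which
#' the largest single drop in giant size occurs.
#'
#' @param network a [weighted_network()] with at least one edge.
#' @param grid `"unique"` (default: all sorted distinct positive edge
#'   weights, exact) or `"quantile:K"` for K evenly spaced weight quantiles
#'   (bounded cost on dense matrices).
#' @param tstar_rule `"preserve"` (default) or `"maxdrop"`, see above.
#' @return An object of class `percolation_profile`: list with
#'   `thresholds`, `giant_sizes`, `t_star`, and `giant0` (node set of the
#'   unthresholded giant component).
#' @examples
#' net <- weighted_network(data.frame(from = c(1, 2), to = c(2, 3),
#'                                    weight = c(0.9, 0.5)), 3)
#' percolation_profile(net)
#' @export
percolation_profile <- function(network, grid = "unique",
                                tstar_rule = c("preserve", "maxdrop")) {
  stopifnot(inherits(network, "weighted_network"))
  tstar_rule <- match.arg(tstar_rule)
  w <- network$edges$weight
  if (length(w) == 0) stop("percolation profile needs at least one edge")
  thresholds <- .threshold_grid(w, grid)
  g0 <- giant_component(network)
  if (g0$size < network$n_nodes)
    warning(sprintf("network is disconnected; t* computed w.r.t. the giant component (%d of %d nodes; excluded: %s)",
                    g0$size, network$n_nodes,
                    paste(utils::head(setdiff(seq_len(network$n_nodes),
                                              g0$members), 10),
                          collapse = ", ")))
  sizes <- integer(length(thresholds))
  preserved <- logical(length(thresholds))
  for (i in seq_along(thresholds)) {
    g <- giant_component(sparsify(network, thresholds[i]))
    sizes[i] <- g$size
    # same size inside the original giant implies the same node set
    preserved[i] <- g$size == g0$size
  }
  t_star <- if (tstar_rule == "preserve") {
    if (!any(preserved)) thresholds[1] else max(thresholds[preserved])
  } else {
    drops <- c(g0$size, sizes[-length(sizes)]) - sizes
    thresholds[which.max(drops)]
  }
  structure(list(thresholds = thresholds, giant_sizes = sizes,
                 t_star = t_star, giant0 = g0$members),
            class = "percolation_profile")
}

.threshold_grid <- function(w, grid) {
  w <- w[w > 0]
  if (identical(grid, "unique")) return(sort(unique(w)))
  if (is.character(grid) && grepl("^quantile:[0-9]+$", grid)) {
    k <- as.integer(sub("^quantile:", "", grid))
    return(sort(unique(stats::quantile(w, probs = seq(0, 1, length.out = k),
                                       names = FALSE, type = 1))))
  }
  if (is.numeric(grid)) return(sort(unique(grid)))
  stop("grid must be \"unique\", \"quantile:K\", or a numeric vector")
}

#' @export
print.percolation_profile <- function(x, ...) {
  cat(sprintf("<percolation_profile: %d thresholds in [%.4g, %.4g], t* = %.6g>\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$t_star))
  invisible(x)
}

#' Percolation threshold of a weighted network
#'
#' Convenience wrapper returning only `t_star` of [percolation_profile()]
#' with the default exact grid.
#'
#' @inheritParams percolation_profile
#' @return The percolation threshold (an observed edge weight).
#' @export
percolation_threshold <- function(network, grid = "unique",
                                  tstar_rule = "preserve") {
  percolation_profile(network, grid = grid, tstar_rule = tstar_rule)$t_star
}

#' Write a percolation profile as CSV
#'
#' Columns `threshold`, `giant_size`; `t_star` is recorded as a comment
#' line at the top.
#'
#' @param profile a `percolation_profile`.
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_star=%.15g", profile$t_star), con)
  utils::write.table(data.frame(threshold = profile$thresholds,
                                giant_size = profile$giant_sizes),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
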