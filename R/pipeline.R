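#' Simulation configuration
#'
#' Bundles everything needed to run the end-to-end validation pipeline:
#' benchmark generator parameters, cohort settings, replicate count,
#' methods, threshold grid and master seed.
#'
#' @param lfr an [lfr_params()] object.
#' @param n_subjects cohort size per replicate.
#' @param n_timepoints series length per node.
#' @param snr signal-to-noise ratio of the Rician noise.
#' @param baseline signal baseline.
#' @param n_replicates number of independent replicates.
#' @param methods character subset of `c("newman", "surprise", "infomap")`.
#' @param grid threshold grid spec (see [percolation_profile()]).
#' @param restarts restarts/trials per method call.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return A list of class `simulation_config` with a `fingerprint` string
#'   recording all settings.
#' @export
simulation_config <- function(lfr = lfr_params(),
                              n_subjects = 20, n_timepoints = 150,
                              snr = 35, baseline = 100, n_replicates = 5,
                              methods = c("newman", "surprise", "infomap"),
                              grid = "unique", restarts = 16, seed = 1) {
  stopifnot(n_replicates >= 1, length(methods) >= 1,
            all(methods %in% c("newman", "surprise", "infomap")))
  cfg <- list(lfr = lfr, n_subjects = as.integer(n_subjects),
              n_timepoints = as.integer(n_timepoints), snr = snr,
              baseline = baseline, n_replicates = as.integer(n_replicates),
              methods = methods, grid = grid,
              restarts = as.integer(restarts), seed = as.integer(seed))
  cfg$fingerprint <- paste(
    sprintf("lfr(N=%d,tau_d=%g,tau_c=%g,k=%g,maxk=%d,minc=%d,maxc=%d,mut=%g,muw=%g,beta=%g)",
            lfr$n_nodes, lfr$degree_exponent, lfr$community_exponent,
            lfr$avg_degree, lfr$max_degree, lfr$min_community,
            lfr$max_community, lfr$mixing_topology, lfr$mixing_weight,
            lfr$strength_exponent),
    sprintf("subjects=%d", cfg$n_subjects),
    sprintf("m=%d", cfg$n_timepoints), sprintf("snr=%g", snr),
    sprintf("baseline=%g", baseline),
    sprintf("replicates=%d", cfg$n_replicates),
    paste0("methods=", paste(methods, collapse = "+")),
    paste0("grid=", paste(grid, collapse = ",")),
    sprintf("restarts=%d", cfg$restarts), sprintf("seed=%d", cfg$seed),
    sep = ";")
  class(cfg) <- "simulation_config"
  cfg
}

#' Preset simulation configurations
#'
#' `"scaled"`: a reduced-size configuration (150-node benchmark, 10
#' subjects, 3 replicates, 40-point quantile grid, 4 restarts) sized for
#' routine validation runs. `"paper"`: the full-scale configuration
#' (600-node benchmark, 20/40/60-subject cohorts, 5 replicates, exact
#' grid).
#'
#' @param name `"scaled"` or `"paper"`.
#' @param ... overrides forwarded to [simulation_config()].
#' @export
sim_preset <- function(name = c("scaled", "paper"), ...) {
  name <- match.arg(name)
  defaults <- if (name == "scaled") {
    list(lfr = lfr_params(n_nodes = 150, min_community = 5,
                          max_community = 50),
         n_subjects = 10, n_replicates = 3, grid = "quantile:40",
         restarts = 4)
  } else {
    list(lfr = lfr_params(n_nodes = 600), n_subjects = 60,
         n_replicates = 5, snr = 70, grid = "unique", restarts = 16)
  }
  over <- list(...)
  do.call(simulation_config, utils::modifyList(defaults, over))
}

#' Threshold sweep of one community detection method
#'
#' For each threshold of the grid (plus the percolation threshold t*,
#' which is always included): sparsify the network, detect communities on
#' the non-isolated subgraph (nodes detached by thresholding are scored as
#' singleton communities), and evaluate NMI, sensitivity and specificity
#' against the planted partition. Thresholds whose graph is edgeless are
#' skipped with a warning.
#'
#' @param network a [weighted_network()].
#' @param planted planted partition covering the network's nodes.
#' @param method `"newman"`, `"surprise"` or `"infomap"`.
#' @param grid threshold grid spec (see [percolation_profile()]).
#' @param seed integer RNG seed.
#' @param restarts restarts/trials for the method.
#' @param replicate_id replicate tag recorded in the output.
#' @return A data frame (`sweep_result`) with columns `replicate`,
#'   `method`, `threshold`, `nmi`, `sensitivity`, `specificity`, `t_star`.
#' @export
threshold_sweep <- function(network, planted, method, grid = "unique",
                            seed = 1, restarts = 16, replicate_id = 1L) {
  stopifnot(inherits(network, "weighted_network"))
  if (length(planted) != network$n_nodes)
    stop("planted partition must cover the network's nodes")
  prof <- percolation_profile(network, grid = grid)
  thresholds <- sort(unique(c(0, prof$thresholds, prof$t_star)))
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    th <- thresholds[i]
    sub <- sparsify(network, th)
    if (nrow(sub$edges) == 0) {
      warning(sprintf("threshold %.4g leaves no edges; skipped", th))
      next
    }
    retrieved <- .detect_partition(sub, method, seed = derive_seed(seed, i),
                                  restarts = restarts)
    ev <- evaluate_partition(planted, retrieved)
    rows[[i]] <- data.frame(replicate = replicate_id, method = method,
                            threshold = th, nmi = ev$nmi,
                            sensitivity = ev$sensitivity,
                            specificity = ev$specificity,
                            t_star = prof$t_star)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

# Detect on the subgraph of non-isolated nodes; nodes detached by
# thresholding are scored as singleton communities.
.detect_partition <- function(network, method, seed, restarts) {
  n <- network$n_nodes
  connected <- which(node_degrees(network) > 0)
  if (length(connected) == n) {
    memb <- detect_communities(network, method, seed = seed,
                               restarts = restarts)
    return(as.integer(memb))
  }
  sub <- .induced_network(network, connected)
  sub_memb <- detect_communities(sub, method, seed = seed,
                                 restarts = restarts)
  memb <- integer(n)
  memb[connected] <- as.integer(sub_memb)
  rest <- which(memb == 0L)
  memb[rest] <- max(sub_memb) + seq_along(rest)
  memb
}

#' Run Simulation 1: community detection on raw benchmark networks
#'
#' Per replicate: generate a weighted LFR benchmark and run the threshold
#' sweep of every configured method directly on the benchmark weights (no
#' time-series stage). Mirrors the noiseless validation protocol.
#'
#' @param config a [simulation_config()].
#' @return A `sweep_result` data frame over all replicates and methods,
#'   with the config fingerprint attached as attribute `fingerprint`.
#' @export
run_simulation1 <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- list()
  for (rep_id in seq_len(config$n_replicates)) {
    lfr <- config$lfr
    lfr$seed <- derive_seed(config$seed, 100L + rep_id)
    bench <- generate_lfr(lfr)
    for (method in config$methods) {
      out[[length(out) + 1L]] <- threshold_sweep(
        bench$network, bench$membership, method, grid = config$grid,
        seed = derive_seed(config$seed, 200L + rep_id),
        restarts = config$restarts, replicate_id = rep_id)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "fingerprint") <- config$fingerprint
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Run Simulation 2: the full noisy multi-subject pipeline
#'
#' Per replicate: generate a weighted LFR benchmark, simulate a cohort of
#' noisy correlated time series from it, build subject Pearson matrices
#' and the Fisher-averaged group network (negative correlations dropped),
#' then run the threshold sweep of every configured method against the
#' planted partition.
#'
#' @inheritParams run_simulation1
#' @return A `sweep_result` data frame, as [run_simulation1()].
#' @export
run_simulation2 <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- list()
  for (rep_id in seq_len(config$n_replicates)) {
    lfr <- config$lfr
    lfr$seed <- derive_seed(config$seed, 100L + rep_id)
    bench <- generate_lfr(lfr)
    panel <- generate_cohort(bench$network, n_subjects = config$n_subjects,
                             n_timepoints = config$n_timepoints,
                             snr = config$snr, baseline = config$baseline,
                             seed = derive_seed(config$seed, 300L + rep_id))
    gnet <- suppressMessages(cohort_group_network(panel))
    for (method in config$methods) {
      out[[length(out) + 1L]] <- threshold_sweep(
        gnet, bench$membership, method, grid = config$grid,
        seed = derive_seed(config$seed, 200L + rep_id),
        restarts = config$restarts, replicate_id = rep_id)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "fingerprint") <- config$fingerprint
  class(res) <- c("sweep_result", "data.frame")
  res
}

#' Summarize a sweep: optimum thresholds, t* band, metrics at t*
#'
#' Per method: the argmax-NMI threshold per replicate, the percolation
#' band (min-max t* across replicates) and the NMI at t*, averaged across
#' replicates.
#'
#' @param results a `sweep_result` data frame.
#' @return A data frame with one row per method.
#' @export
summarize_sweep <- function(results) {
  stopifnot(nrow(results) > 0)
  do.call(rbind, lapply(split(results, results$method), function(d) {
    reps <- split(d, d$replicate)
    best_th <- vapply(reps, function(r) r$threshold[which.max(r$nmi)],
                      numeric(1))
    nmi_at_tstar <- vapply(reps, function(r)
      r$nmi[which.min(abs(r$threshold - r$t_star[1]))], numeric(1))
    data.frame(method = d$method[1],
               best_threshold = mean(best_th),
               t_star_min = min(d$t_star), t_star_max = max(d$t_star),
               nmi_at_t_star = mean(nmi_at_tstar),
               peak_nmi = mean(vapply(reps, function(r) max(r$nmi),
                                      numeric(1))))
  }))
}

#' Write sweep results and their summary as CSV files
#'
#' Writes `results.csv` (tidy per-threshold rows) and `summary.csv` (one
#' row per method, see [summarize_sweep()]) into `out_dir`. Output is
#' byte-stable for fixed inputs.
#'
#' @param results a non-empty `sweep_result` data frame.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir) {
  if (is.null(results) || nrow(results) == 0)
    stop("results must be non-empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(out_dir, "results.csv")
  sum_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(as.data.frame(results), res_path, row.names = FALSE)
  utils::write.csv(summarize_sweep(results), sum_path, row.names = FALSE)
  fp <- attr(results, "fingerprint")
  if (!is.null(fp))
    writeLines(fp, file.path(out_dir, "fingerprint.txt"))
  invisible(c(res_path, sum_path))
}
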