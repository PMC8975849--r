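# Perturbation protocols probing the robustness of k-clique organization:
# weight thresholding (keep only strong links, or only weak ones) and node
# removal (random versus lowest-degree), each followed by percolation
# profiling.

#' Filter edges by weight threshold
#'
#' `mode = "weak"` deletes every edge of weight strictly below `cutoff`
#' (the surviving subgraph holds the strong associations, threshold tau);
#' `mode = "strong"` deletes every edge of weight greater than or equal to
#' `cutoff` (the survivors are the weak-association subgraph, threshold
#' theta). At equal cutoff the two modes partition the edge set. The node
#' set is kept unchanged, so percolation fractions stay comparable.
#'
#' @param net Weighted simple undirected igraph.
#' @param mode `"weak"` or `"strong"` -- which side gets *removed*.
#' @param cutoff Threshold in \[0, 1\].
#' @return The filtered network (weights retained).
#' @export
threshold_filter <- function(net, mode = c("weak", "strong"), cutoff) {
  check_network(net, require_weights = TRUE)
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("`cutoff` must lie in [0, 1]", call. = FALSE)
  }
  w <- igraph::E(net)$weight
  drop <- if (mode == "weak") w < cutoff else w >= cutoff
  igraph::delete_edges(net, which(drop))
}

#' Remove a fraction of nodes
#'
#' Deletes floor(alpha * N) nodes and their incident edges. `mode =
#' "random"` draws them uniformly without replacement; `mode =
#' "lowest_degree"` takes the smallest-degree nodes, breaking degree ties
#' uniformly at random. Surviving isolated nodes stay in the graph, so
#' downstream percolation fractions are fractions of the perturbed node
#' set.
#'
#' @param net Simple undirected igraph.
#' @param mode `"random"` or `"lowest_degree"`.
#' @param alpha Fraction of nodes to remove, in \[0, 1\].
#' @param seed Optional RNG seed (used for the draw and for tie-breaking).
#' @return The perturbed network.
#' @export
remove_nodes <- function(net, mode = c("random", "lowest_degree"), alpha,
                         seed = NULL) {
  check_network(net)
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  n <- igraph::vcount(net)
  n_rm <- floor(alpha * n)
  if (n_rm == 0L) return(net)
  victims <- with_seed(seed, {
    if (mode == "random") {
      sample.int(n, n_rm)
    } else {
      deg <- igraph::degree(net)
      order(deg, sample.int(n))[seq_len(n_rm)]
    }
  })
  igraph::delete_vertices(net, victims)
}

#' Sweep a perturbation parameter and profile percolation
#'
#' Applies a grid of perturbations -- weight thresholds (`tau` strong-link
#' filter, `theta` weak-link filter) or node-removal fractions
#' (`alpha_random`, `alpha_degree`) -- and computes the k-clique
#' percolation profile after each. Stochastic modes are replicated over
#' `n_seeds` seeds derived deterministically from `master_seed`; the
#' deterministic threshold modes run once (seed column `NA`).
#'
#' @param net Simple undirected igraph (weighted for threshold modes).
#' @param mode One of `"tau"`, `"theta"`, `"alpha_random"`,
#'   `"alpha_degree"`.
#' @param values Ascending grid of parameter values.
#' @param k_max Largest clique size profiled (default 6).
#' @param n_seeds Replicates for stochastic modes (default 10).
#' @param master_seed Master seed from which replicate seeds derive.
#' @param max_cliques Guard limit on maximal-clique enumeration.
#' @return Object of class `perturbation_result`: list with `parameter`,
#'   `results` (long `data.frame`: `parameter`, `value`, `seed`, `k`,
#'   `f_cc`), `mean` (averaged over seeds) and `seeds`.
#' @export
perturbation_sweep <- function(net, mode = c("tau", "theta", "alpha_random",
                                             "alpha_degree"),
                               values, k_max = 6, n_seeds = 10,
                               master_seed = 1, max_cliques = 1e7) {
  mode <- match.arg(mode)
  stochastic <- mode %in% c("alpha_random", "alpha_degree")
  check_network(net, require_weights = !stochastic)
  if (length(values) == 0L || is.unsorted(values)) {
    stop("`values` must be a non-empty ascending grid", call. = FALSE)
  }
  seeds <- if (stochastic) {
    vapply(seq_len(n_seeds),
           function(i) derive_seed(master_seed, paste0(mode, "_rep", i)), 0L)
  } else NA_integer_
  rows <- list()
  for (v in values) {
    for (s in seeds) {
      pert <- switch(mode,
        tau = threshold_filter(net, "weak", v),
        theta = threshold_filter(net, "strong", v),
        alpha_random = remove_nodes(net, "random", v, seed = s),
        alpha_degree = remove_nodes(net, "lowest_degree", v, seed = s))
      prof <- percolation_profile(pert, k_max, max_cliques)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = mode, value = v, seed = s,
                   k = prof$k, f_cc = prof$f_cc)
    }
  }
  res <- do.call(rbind, rows)
  mean_df <- aggregate(f_cc ~ parameter + value + k, data = res, FUN = mean)
  mean_df <- mean_df[order(mean_df$value, mean_df$k), ]
  rownames(mean_df) <- NULL
  structure(list(parameter = mode, results = res, mean = mean_df,
                 seeds = seeds[!is.na(seeds)]),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("Perturbation sweep '%s': %d value(s), %d seed(s)\n",
              x$parameter, length(unique(x$results$value)),
              max(1L, length(x$seeds))))
  invisible(x)
}

#' Write a perturbation sweep as long-format TSV
#'
#' Columns `parameter`, `value`, `seed`, `k`, `f_cc`.
#'
#' @param result A `perturbation_result`.
#' @param path Output path.
#' @export
write_sweep <- function(result, path) {
  stopifnot(inherits(result, "perturbation_result"))
  write.table(result$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
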