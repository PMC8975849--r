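# k-clique percolation. A k-clique is a complete subgraph on k nodes; two
# k-cliques are adjacent when they share k-1 nodes; a k-clique percolation
# cluster (community) is the node union of a maximal set of k-cliques
# connected through chains of adjacent k-cliques. Communities are computed
# from maximal cliques: every k-clique lies in some maximal clique of size
# >= k, and two maximal cliques of size >= k carry mutually reachable
# k-cliques exactly when they are linked through maximal-clique overlaps of
# >= k-1 nodes. Weights play no role here: percolation is purely
# topological.

#' Enumerate all maximal cliques
#'
#' Lists every maximal clique of a simple undirected graph exactly once
#' (pivoted Bron-Kerbosch search, via igraph). Isolated vertices are
#' maximal cliques of size 1.
#'
#' @param net Simple undirected igraph.
#' @param max_cliques Guard limit on the number of maximal cliques;
#'   enumeration on pathologically dense graphs aborts with an error
#'   instead of exhausting memory. Default 1e7.
#' @return List of character vectors of node names, each sorted.
#' @export
enumerate_maximal_cliques <- function(net, max_cliques = 1e7) {
  check_network(net)
  if (igraph::vcount(net) == 0L) return(list())
  n_cl <- igraph::count_max_cliques(net)
  if (n_cl > max_cliques) {
    stop(sprintf("graph has %g maximal cliques, above the guard limit %g",
                 n_cl, max_cliques), call. = FALSE)
  }
  cl <- igraph::max_cliques(net)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
  lapply(cl, function(v) sort(nm[as.integer(v)]))
}

# Core: connected components of the >= (k-1)-overlap relation among
# maximal cliques of size >= k (union-find over shared (k-1)-subsets, see
# src/cpm.cpp). `cliques` is a list of integer vertex-id vectors. Returns
# a list of integer vertex-id vectors (community node unions), sorted by
# decreasing size.
cpm_components <- function(cliques, k, n_vertices) {
  sizes <- lengths(cliques)
  cliques <- cliques[sizes >= k]
  if (length(cliques) == 0L) return(list())
  comp <- .cpm_membership(cliques, as.integer(k), as.integer(n_vertices))
  groups <- split(seq_along(cliques), comp)
  out <- lapply(groups, function(ix) {
    sort(unique(unlist(cliques[ix], use.names = FALSE)))
  })
  out[order(lengths(out), decreasing = TRUE)]
}

#' k-clique communities of a network
#'
#' Partitions the k-cliques of the graph into percolation clusters (two
#' k-cliques in the same cluster iff linked by a chain of k-cliques each
#' sharing k-1 nodes with the next) and returns each cluster as the union
#' of its k-cliques' nodes. Distinct communities may overlap in fewer than
#' k-1 nodes, which is what makes the method suitable for semantic
#' networks where a word belongs to several communities.
#'
#' @param net Simple undirected igraph.
#' @param k Clique size, integer >= 2.
#' @param max_cliques Guard limit passed to the maximal-clique enumeration.
#' @return Object of class `kclique_communities`: list with elements `k`,
#'   `communities` (list of sorted character vectors, largest first) and
#'   `n_nodes`.
#' @export
k_clique_communities <- function(net, k, max_cliques = 1e7) {
  check_network(net)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    stop("`k` must be an integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  comms <- list()
  if (n > 0L && igraph::ecount(net) > 0L) {
    n_cl <- igraph::count_max_cliques(net, min = k)
    if (n_cl > max_cliques) {
      stop(sprintf("graph has %g maximal cliques of size >= %d, above the guard limit %g",
                   n_cl, k, max_cliques), call. = FALSE)
    }
    cl <- lapply(igraph::max_cliques(net, min = k), as.integer)
    comms <- lapply(cpm_components(cl, k, n), function(ix) nm[ix])
  }
  structure(list(k = k, communities = comms, n_nodes = n),
            class = "kclique_communities")
}

#' @export
print.kclique_communities <- function(x, ...) {
  cat(sprintf("%d-clique communities: %d (largest %d of %d nodes)\n",
              x$k, length(x$communities),
              if (length(x$communities)) length(x$communities[[1L]]) else 0L,
              x$n_nodes))
  invisible(x)
}

#' Percolation profile f_cc(k)
#'
#' For each k in 2..`k_max`, the fraction `f_cc` of nodes contained in the
#' largest k-clique percolation cluster (0 when the graph has no k-clique).
#' `f_union` additionally reports the fraction of nodes in *any* k-clique
#' community. Maximal cliques are enumerated once and reused across k.
#'
#' @param net Simple undirected igraph.
#' @param k_max Largest clique size to profile, integer >= 2.
#' @param max_cliques Guard limit on maximal-clique enumeration.
#' @return A `data.frame` of class `percolation_profile` with columns `k`,
#'   `f_cc`, `f_union`, `largest_community_size`, `n_communities`; the node
#'   count is kept in `attr(, "n_nodes")`.
#' @export
percolation_profile <- function(net, k_max = 8, max_cliques = 1e7) {
  check_network(net)
  if (!is.numeric(k_max) || k_max < 2) stop("`k_max` must be >= 2", call. = FALSE)
  k_max <- as.integer(k_max)
  n <- igraph::vcount(net)
  ks <- 2:k_max
  res <- data.frame(k = ks, f_cc = 0, f_union = 0,
                    largest_community_size = 0L, n_communities = 0L)
  if (n > 0L && igraph::ecount(net) > 0L) {
    n_cl <- igraph::count_max_cliques(net, min = 2)
    if (n_cl > max_cliques) {
      stop(sprintf("graph has %g maximal cliques, above the guard limit %g",
                   n_cl, max_cliques), call. = FALSE)
    }
    cl <- lapply(igraph::max_cliques(net, min = 2), as.integer)
    for (i in seq_along(ks)) {
      comms <- cpm_components(cl, ks[i], n)
      if (length(comms)) {
        res$largest_community_size[i] <- length(comms[[1L]])
        res$n_communities[i] <- length(comms)
        res$f_cc[i] <- length(comms[[1L]]) / n
        res$f_union[i] <- length(unique(unlist(comms, use.names = FALSE))) / n
      }
    }
  }
  attr(res, "n_nodes") <- n
  class(res) <- c("percolation_profile", "data.frame")
  res
}

#' Critical clique size k_c of a percolation profile
#'
#' The largest k whose largest k-clique community still covers at least
#' `min_fraction` of the nodes -- the operational "largest k for which
#' k-clique percolation occurs". Returns 1 when no profiled k qualifies.
#' The cutoff is a modelling choice (see the methods vignette); 0.01
#' treats a community spanning under 1 percent of the lexicon as
#' non-percolating.
#'
#' @param profile A `percolation_profile` (or data.frame with columns `k`,
#'   `f_cc`).
#' @param min_fraction Fraction of nodes in (0, 1] that the largest
#'   community must reach; default 0.01.
#' @return Integer k_c.
#' @export
critical_k <- function(profile, min_fraction = 0.01) {
  stopifnot(is.data.frame(profile), all(c("k", "f_cc") %in% names(profile)),
            nrow(profile) > 0L)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must lie in (0, 1]", call. = FALSE)
  }
  ok <- profile$k[profile$f_cc >= min_fraction]
  if (length(ok) == 0L) return(1L)
  as.integer(max(ok))
}

#' Analytic k-clique percolation threshold for Erdos-Renyi graphs
#'
#' The critical link probability above which a giant k-clique community
#' emerges in G(N, p): p_c(k) = 1 / [N (k - 1)]^(1 / (k - 1)). For k = 2
#' this is the classical giant-component threshold 1/N. Comparing a real
#' network's density with p_c(2) and p_c(3) tells whether its clique
#' structure could arise from random wiring alone.
#'
#' @param n_nodes Number of nodes N (>= 2).
#' @param k Clique size(s), integer(s) >= 2 (vectorized).
#' @return Numeric vector of critical probabilities.
#' @export
pc_threshold <- function(n_nodes, k) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2) {
    stop("`n_nodes` must be a single number >= 2", call. = FALSE)
  }
  if (!is.numeric(k) || any(k < 2) || any(k != round(k))) {
    stop("`k` must be integer(s) >= 2", call. = FALSE)
  }
  1 / (n_nodes * (k - 1))^(1 / (k - 1))
}

#' Write k-clique communities to a text file
#'
#' Plain-text format: a header line `k=<k>` followed by one community per
#' line, node ids whitespace-separated. With `format = "json"`, a JSON
#' object with fields `k`, `n_nodes` and `communities` (list of lists).
#'
#' @param comms A `kclique_communities` object.
#' @param path Output path.
#' @param format `"text"` (default) or `"json"`.
#' @export
write_communities <- function(comms, path, format = c("text", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(comms, "kclique_communities"))
  if (format == "text") {
    lines <- c(paste0("k=", comms$k),
               vapply(comms$communities, paste, "", collapse = " "))
    writeLines(lines, path)
  } else {
    jsonlite::write_json(list(k = comms$k, n_nodes = comms$n_nodes,
                              communities = comms$communities),
                         path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a percolation profile as TSV
#'
#' Columns `k`, `f_cc`, `largest_community_size`, `n_communities`.
#'
#' @param profile A `percolation_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "percolation_profile"))
  write.table(profile[c("k", "f_cc", "largest_community_size",
                        "n_communities")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
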