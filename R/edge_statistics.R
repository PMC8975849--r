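# Per-edge clique statistics. The edge clustering coefficient
#   C_ij = N_T(ij) / (min(k_i, k_j) - 1)
# is the number of triangles through an edge divided by the largest number
# possible given the smaller endpoint degree; like the nodal clustering
# coefficient it lies in [0, 1]. The edge clique number is the size of the
# largest clique containing the edge. In free-association data both
# statistics correlate with association strength, which the binned
# log-linear fit quantifies.

# Common-neighbor count for every edge, in igraph edge order.
edge_triangle_counts <- function(net) {
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  a2 <- a %*% a
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  as.numeric(a2[cbind(ends[, 1L], ends[, 2L])])
}

# Edge clustering for all edges, in igraph edge order.
edge_clustering_all <- function(net) {
  if (igraph::ecount(net) == 0L) return(numeric(0))
  nt <- edge_triangle_counts(net)
  deg <- igraph::degree(net)
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  denom <- unname(pmin(deg[ends[, 1L]], deg[ends[, 2L]]) - 1)
  ifelse(denom <= 0, 0, nt / denom)
}

# Resolve a length-2 node vector to an igraph edge id, erroring if absent.
resolve_edge <- function(net, edge) {
  stopifnot(length(edge) == 2L)
  eid <- tryCatch(igraph::get_edge_ids(net, as.character(edge), error = FALSE),
                  error = function(e) 0L)
  if (length(eid) != 1L || is.na(eid) || eid == 0L) {
    stop(sprintf("edge (%s, %s) is not in the network", edge[1L], edge[2L]),
         call. = FALSE)
  }
  eid
}

#' Edge clustering coefficient
#'
#' C_ij = N_T(ij) / (min(k_i, k_j) - 1) where N_T(ij) counts triangles
#' through the edge and k_i, k_j are the endpoint degrees. Defined as 0
#' when min(k_i, k_j) = 1 (a pendant edge can carry no triangle; the raw
#' formula would divide by zero).
#'
#' @param net Simple undirected igraph.
#' @param edge Length-2 vector of node names.
#' @return C_ij in [0, 1].
#' @export
edge_clustering <- function(net, edge) {
  check_network(net)
  eid <- resolve_edge(net, edge)
  ends <- igraph::ends(net, eid, names = TRUE)[1L, ]
  deg <- igraph::degree(net, ends)
  nt <- length(intersect(igraph::neighbors(net, ends[1L])$name,
                         igraph::neighbors(net, ends[2L])$name))
  denom <- min(deg) - 1
  if (denom <= 0) 0 else nt / denom
}

#' Edge clique number
#'
#' The size of the largest clique containing both endpoints of an edge;
#' always at least 2, and at least 3 exactly when the edge lies in a
#' triangle.
#'
#' @param net Simple undirected igraph.
#' @param edge Length-2 vector of node names.
#' @return Integer clique size >= 2.
#' @export
edge_clique_number <- function(net, edge) {
  check_network(net)
  eid <- resolve_edge(net, edge)
  ends <- igraph::ends(net, eid, names = TRUE)[1L, ]
  cn <- intersect(igraph::neighbors(net, ends[1L])$name,
                  igraph::neighbors(net, ends[2L])$name)
  if (length(cn) == 0L) return(2L)
  sub <- igraph::induced_subgraph(net, cn)
  2L + igraph::clique_num(sub)
}

# Edge clique numbers for all edges at once: scan maximal cliques and take,
# for every vertex pair inside a clique, the largest clique size seen.
edge_clique_numbers_all <- function(net, max_cliques = 1e7) {
  ne <- igraph::ecount(net)
  if (ne == 0L) return(integer(0))
  n <- igraph::vcount(net)
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  ekey <- (pmin(ends[, 1L], ends[, 2L]) - 1) * n + pmax(ends[, 1L], ends[, 2L])
  out <- rep.int(2L, ne)
  n_cl <- igraph::count_max_cliques(net, min = 3)
  if (n_cl > max_cliques) {
    stop(sprintf("graph has %g maximal cliques, above the guard limit %g",
                 n_cl, max_cliques), call. = FALSE)
  }
  cl <- igraph::max_cliques(net, min = 3)
  if (length(cl) == 0L) return(out)
  keys <- lapply(cl, function(v) {
    v <- sort(as.integer(v))
    pr <- combn(v, 2L)
    (pr[1L, ] - 1) * n + pr[2L, ]
  })
  sizes <- rep.int(lengths(cl), vapply(keys, length, 0L))
  keys <- unlist(keys, use.names = FALSE)
  best <- tapply(sizes, keys, max)
  hit <- match(ekey, as.numeric(names(best)))
  out[!is.na(hit)] <- as.integer(best[hit[!is.na(hit)]])
  out
}

#' Per-edge clique statistics table
#'
#' One row per edge: endpoints, weight (NA when the network is
#' unweighted), triangle count, edge clustering coefficient and edge
#' clique number.
#'
#' @param net Simple undirected igraph.
#' @param max_cliques Guard limit on maximal-clique enumeration.
#' @return `data.frame` with columns `source`, `target`, `weight`,
#'   `n_triangles`, `edge_clustering`, `clique_number`.
#' @export
edge_stats <- function(net, max_cliques = 1e7) {
  check_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  data.frame(
    source = if (nrow(el)) el[, 1L] else character(0),
    target = if (nrow(el)) el[, 2L] else character(0),
    weight = if (is_weighted_net(net)) igraph::E(net)$weight
             else rep(NA_real_, igraph::ecount(net)),
    n_triangles = as.integer(edge_triangle_counts(net)),
    edge_clustering = edge_clustering_all(net),
    clique_number = edge_clique_numbers_all(net, max_cliques),
    stringsAsFactors = FALSE)
}

#' Binned weight-clustering relation with log-linear fit
#'
#' Sorts edges by edge clustering coefficient (ties broken by the
#' lexicographic endpoint pair, so binning is deterministic), splits them
#' into `b` contiguous bins of near-equal size (any remainder goes to the
#' first bins), averages C_ij and w_ij within each bin, and fits the least
#' squares line log(<w>) = slope * <c> + intercept over the bin means.
#'
#' @param net Weighted simple undirected igraph with at least `b` edges.
#' @param b Number of bins (default 100).
#' @param log_base Base of the logarithm, 10 (default) or `exp(1)`.
#' @return Object of class `bin_fit`: list with `b`, `log_base`, `slope`,
#'   `intercept` and the bin table `bins` (`c_mean`, `w_mean`, `n_edges`).
#' @export
bin_and_fit <- function(net, b = 100, log_base = 10) {
  check_network(net, require_weights = TRUE)
  ne <- igraph::ecount(net)
  if (ne < b) {
    stop(sprintf("need at least b = %d edges, have %d", b, ne), call. = FALSE)
  }
  if (!log_base %in% c(10, exp(1))) {
    stop("`log_base` must be 10 or exp(1)", call. = FALSE)
  }
  cij <- edge_clustering_all(net)
  w <- igraph::E(net)$weight
  el <- igraph::as_edgelist(net, names = TRUE)
  a <- pmin(el[, 1L], el[, 2L]); bb <- pmax(el[, 1L], el[, 2L])
  ord <- order(cij, a, bb)
  sizes <- rep.int(ne %/% b, b)
  r <- ne %% b
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  bin <- rep.int(seq_len(b), sizes)
  c_mean <- as.numeric(tapply(cij[ord], bin, mean))
  w_mean <- as.numeric(tapply(w[ord], bin, mean))
  fit <- lm(log(w_mean, base = log_base) ~ c_mean)
  structure(list(b = b, log_base = log_base,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 bins = data.frame(c_mean = c_mean, w_mean = w_mean,
                                   n_edges = sizes)),
            class = "bin_fit")
}

#' @export
print.bin_fit <- function(x, ...) {
  base_lab <- if (x$log_base == 10) "log10" else "ln"
  cat(sprintf("Binned fit (%d bins): %s<w> = %.3f * <c> %+.3f\n",
              x$b, base_lab, x$slope, x$intercept))
  invisible(x)
}

#' Write a bin fit as JSON
#'
#' @param fit A `bin_fit`.
#' @param path Output path.
#' @export
write_bin_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "bin_fit"))
  jsonlite::write_json(list(b = fit$b, log_base = fit$log_base,
                            slope = fit$slope, intercept = fit$intercept,
                            bins = fit$bins),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Clique-number distribution of a weight class
#'
#' Restricts edges to a weight class (e.g. weak associations w <= 0.01 or
#' strong ones w > 0.1), and returns the normalized distribution of edge
#' clique numbers within the class plus the class's share of all edges.
#'
#' @param net Weighted simple undirected igraph.
#' @param weight_class Predicate: function of the weight vector returning
#'   a logical vector (e.g. `function(w) w <= 0.01`).
#' @param max_cliques Guard limit on maximal-clique enumeration.
#' @return List with `histogram` (named numeric: clique number ->
#'   fraction of class edges; empty with a warning when the class is
#'   empty) and `class_fraction` (share of all edges in the class).
#' @export
clique_number_distribution <- function(net, weight_class, max_cliques = 1e7) {
  check_network(net, require_weights = TRUE)
  stopifnot(is.function(weight_class))
  w <- igraph::E(net)$weight
  sel <- weight_class(w)
  stopifnot(is.logical(sel), length(sel) == length(w))
  frac <- if (length(w)) mean(sel) else 0
  if (!any(sel)) {
    warning("weight class matches no edges", call. = FALSE)
    return(list(histogram = setNames(numeric(0), character(0)),
                class_fraction = frac))
  }
  kn <- edge_clique_numbers_all(net, max_cliques)[sel]
  tab <- table(kn)
  list(histogram = setNames(as.numeric(tab) / sum(tab), names(tab)),
       class_fraction = frac)
}
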