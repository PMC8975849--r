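# Independent brute-force oracles for clique operations. These work from
# first principles (exhaustive subset checks, direct k-clique adjacency)
# and never call the package's clique machinery.

# All maximal cliques of a small graph (<= 25 nodes) by testing every
# vertex subset. Returns a sorted list of sorted name vectors.
oracle_maximal_cliques <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 25)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    s <- length(idx)
    if (sum(a[idx, idx, drop = FALSE]) != s * (s - 1)) next  # not a clique
    outside <- setdiff(seq_len(n), idx)
    if (s == 1 && length(outside) &&
        any(a[idx, outside, drop = FALSE] == 1)) next
    if (length(outside)) {
      ext <- colSums(a[idx, outside, drop = FALSE]) == s
      if (any(ext)) next                                     # extendable
    }
    out[[length(out) + 1L]] <- sort(nm[idx])
  }
  canonical_sets(out)
}

# All k-cliques of a small graph as vertex-index bitmasks.
oracle_k_cliques <- function(g, k) {
  n <- igraph::vcount(g)
  stopifnot(n <= 30)
  if (n < k) return(integer(0))
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  combs <- utils::combn(n, k)
  ok <- apply(combs, 2L, function(idx) {
    sum(a[idx, idx]) == k * (k - 1)
  })
  if (!any(ok)) return(integer(0))
  apply(combs[, ok, drop = FALSE], 2L, function(idx) {
    sum(bitwShiftL(1L, idx - 1L))
  })
}

popcount <- function(x) {
  cnt <- integer(length(x))
  while (any(x > 0L)) {
    cnt <- cnt + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  cnt
}

# Direct k-clique percolation: enumerate every k-clique, link pairs
# sharing k-1 vertices, take connected components, return node unions.
oracle_k_clique_communities <- function(g, k) {
  masks <- oracle_k_cliques(g, k)
  nc <- length(masks)
  if (nc == 0L) return(list())
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  cg <- igraph::make_empty_graph(nc, directed = FALSE)
  if (nc > 1L) {
    pairs <- utils::combn(nc, 2L)
    shared <- popcount(bitwAnd(masks[pairs[1L, ]], masks[pairs[2L, ]]))
    adj <- shared == k - 1L
    if (any(adj)) cg <- igraph::add_edges(cg, pairs[, adj, drop = FALSE])
  }
  comp <- igraph::components(cg)$membership
  comms <- lapply(split(seq_len(nc), comp), function(ix) {
    u <- Reduce(bitwOr, masks[ix])
    sort(nm[which(bitwAnd(u, bitwShiftL(1L, 0:29)) != 0L)])
  })
  canonical_sets(comms)
}

# Canonical form for a list of node sets: each sorted, list ordered
# lexicographically, so two lists compare with identical().
canonical_sets <- function(sets) {
  sets <- lapply(sets, sort)
  keys <- vapply(sets, paste, "", collapse = "\r")
  unname(sets[order(keys)])
}
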