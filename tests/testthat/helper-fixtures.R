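# Small graph fixtures, built in code at test time.

named_graph <- function(edges, isolated = character(0)) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

complete_graph <- function(n) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- paste0("p", seq_len(n))
  g
}

star_graph <- function(leaves) {
  named_graph(as.vector(rbind("hub", paste0("leaf", seq_len(leaves)))))
}

# Two triangles sharing exactly one node.
bowtie_graph <- function() {
  named_graph(c("a", "b", "b", "c", "c", "a",
                "c", "d", "d", "e", "e", "c"))
}

random_named_gnp <- function(n, p, seed) {
  g <- with_test_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Weighted toy network: 6 edges with assorted weights.
weighted_fixture <- function() {
  g <- named_graph(c("a", "b", "b", "c", "c", "a",
                     "c", "d", "d", "e", "e", "f"))
  igraph::E(g)$weight <- c(0.30, 0.05, 0.20, 0.08, 0.50, 0.01)
  g
}
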