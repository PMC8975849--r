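# Edge clustering coefficient, edge clique numbers, binned
# weight-clustering fits and clique-number distributions by weight class.

test_that("edge clustering is 1 on complete graphs and 0 on pendant edges", {
  expect_equal(edge_clustering(complete_graph(3), c("a", "b")), 1)
  expect_equal(edge_clustering(complete_graph(4), c("a", "c")), 1)
  # pendant edge: min degree 1, defined as 0
  expect_equal(edge_clustering(named_graph(c("a", "b")), c("a", "b")), 0)
  expect_error(edge_clustering(complete_graph(3), c("a", "z")),
               "not in the network")
})

test_that("edge clustering equals the common-neighbor oracle on all edges", {
  g <- random_named_gnp(20, 0.3, seed = 31)
  es <- edge_stats(g)
  deg <- igraph::degree(g)
  nbrs <- lapply(igraph::V(g)$name,
                 function(v) igraph::neighbors(g, v)$name)
  names(nbrs) <- igraph::V(g)$name
  for (i in seq_len(nrow(es))) {
    cn <- length(intersect(nbrs[[es$source[i]]], nbrs[[es$target[i]]]))
    md <- min(deg[es$source[i]], deg[es$target[i]])
    expected <- if (md <= 1) 0 else cn / (md - 1)
    expect_equal(es$edge_clustering[i], expected)
    expect_equal(es$n_triangles[i], cn)
    expect_equal(edge_clustering(g, c(es$source[i], es$target[i])), expected)
  }
  expect_true(all(es$edge_clustering >= 0 & es$edge_clustering <= 1))
})

test_that("edge clique number matches brute force on common neighborhoods", {
  expect_equal(edge_clique_number(named_graph(c("a", "b")), c("a", "b")), 2L)

  # K5 embedded in a sparse periphery
  g <- complete_graph(5)
  g <- igraph::add_vertices(g, 3, name = c("x", "y", "z"))
  g <- igraph::add_edges(g, c("a", "x", "x", "y", "y", "z"))
  expect_equal(edge_clique_number(g, c("b", "d")), 5L)
  expect_equal(edge_clique_number(g, c("x", "y")), 2L)

  gr <- random_named_gnp(15, 0.4, seed = 77)
  es <- edge_stats(gr)
  for (i in seq_len(nrow(es))) {
    u <- es$source[i]; v <- es$target[i]
    cn <- intersect(igraph::neighbors(gr, u)$name,
                    igraph::neighbors(gr, v)$name)
    expected <- if (length(cn) == 0L) 2L else {
      sub <- igraph::induced_subgraph(gr, cn)
      2L + max(lengths(oracle_maximal_cliques(sub)))
    }
    expect_equal(es$clique_number[i], expected)
    expect_equal(edge_clique_number(gr, c(u, v)), expected)
  }
  # an edge is in a triangle iff its clique number is at least 3
  expect_equal(es$clique_number >= 3L, es$n_triangles >= 1L)
})

test_that("bin_and_fit recovers an exact log-linear rule", {
  # one edge per bin: the bin mean is the edge itself, recovery is exact
  g <- grow_network(growth_params(n_target = 60, seed = 5))
  g <- assign_synthetic_weights(g, slope = 5.0, intercept = -4.4,
                                noise_sd = 0, log_base = 10)
  fit <- bin_and_fit(g, b = igraph::ecount(g), log_base = 10)
  expect_equal(fit$slope, 5.0, tolerance = 1e-9)
  expect_equal(fit$intercept, -4.4, tolerance = 1e-9)

  expect_error(bin_and_fit(igraph::delete_edge_attr(g, "weight"), b = 10),
               "weights")
  expect_error(bin_and_fit(weighted_fixture(), b = 100), "at least b")
})

test_that("bin_and_fit reproduces a hand-computed two-bin case", {
  # path a-b-c-d-e plus chord a-c: C values known per edge
  g <- named_graph(c("a", "b", "b", "c", "c", "d", "d", "e", "a", "c"))
  es <- edge_stats(g)
  w <- c(0.4, 0.2, 0.1, 0.05, 0.8)
  igraph::E(g)$weight <- w
  fit <- bin_and_fit(g, b = 2, log_base = 10)
  # hand binning: sort by (C, edge id); 5 edges -> bins of 3 and 2
  ord <- order(es$edge_clustering, pmin(es$source, es$target),
               pmax(es$source, es$target))
  cm <- c(mean(es$edge_clustering[ord[1:3]]),
          mean(es$edge_clustering[ord[4:5]]))
  wm <- c(mean(w[ord[1:3]]), mean(w[ord[4:5]]))
  slope <- (log10(wm[2]) - log10(wm[1])) / (cm[2] - cm[1])
  expect_equal(fit$bins$c_mean, cm)
  expect_equal(fit$bins$w_mean, wm)
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, log10(wm[1]) - slope * cm[1])
  expect_equal(fit$bins$n_edges, c(3L, 2L))
})

test_that("bin_and_fit is invariant to edge input order", {
  g <- grow_network(growth_params(n_target = 80, seed = 9))
  g <- assign_synthetic_weights(g, noise_sd = 0.2, seed = 2)
  fit1 <- bin_and_fit(g, b = 20)
  # rebuild the same network with permuted edge order
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  set.seed(4); perm <- sample.int(nrow(el))
  g2 <- igraph::graph_from_edgelist(el[perm, ], directed = FALSE)
  # look up each g2 edge's weight in g
  ids <- igraph::get_edge_ids(g, t(igraph::as_edgelist(g2)))
  igraph::E(g2)$weight <- w[ids]
  fit2 <- bin_and_fit(g2, b = 20)
  expect_equal(fit2$slope, fit1$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit1$intercept, tolerance = 1e-12)
})

test_that("clique-number distributions separate planted weight classes", {
  g <- complete_graph(3)
  igraph::E(g)$weight <- 0.5
  d <- clique_number_distribution(g, function(w) w > 0)
  expect_equal(d$histogram, c("3" = 1))
  expect_equal(d$class_fraction, 1)

  expect_warning(
    d0 <- clique_number_distribution(g, function(w) w > 0.9),
    "no edges")
  expect_length(d0$histogram, 0L)
  expect_equal(d0$class_fraction, 0)

  # strong K5 core, weak triangle-free periphery
  core <- complete_graph(5)
  igraph::E(core)$weight <- 0.5
  g2 <- igraph::add_vertices(core, 4, name = paste0("p", 1:4))
  g2 <- igraph::add_edges(g2, c("a", "p1", "p1", "p2", "p2", "p3",
                                "p3", "p4"),
                          attr = list(weight = rep(0.005, 4)))
  strong <- clique_number_distribution(g2, function(w) w > 0.1)
  weak <- clique_number_distribution(g2, function(w) w <= 0.01)
  expect_equal(strong$histogram, c("5" = 1))
  expect_equal(weak$histogram, c("2" = 1))
  expect_equal(strong$class_fraction, 10 / 14)
  expect_equal(weak$class_fraction, 4 / 14)
})
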