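# Maximal cliques, k-clique communities, percolation profiles and the
# analytic threshold, validated against exhaustive brute-force oracles.

test_that("maximal cliques match closed forms on canonical graphs", {
  k5 <- enumerate_maximal_cliques(complete_graph(5))
  expect_length(k5, 1L)
  expect_equal(k5[[1L]], letters[1:5])

  p3 <- enumerate_maximal_cliques(path_graph(3))
  expect_equal(canonical_sets(p3),
               canonical_sets(list(c("p1", "p2"), c("p2", "p3"))))

  expect_equal(enumerate_maximal_cliques(igraph::make_empty_graph(
    0, directed = FALSE)), list())
})

test_that("maximal cliques equal the exhaustive-subset oracle", {
  for (s in 1:30) {
    set.seed(2000 + s)
    n <- sample(5:12, 1)
    g <- random_named_gnp(n, runif(1, 0.2, 0.7), seed = 2000 + s)
    expect_equal(canonical_sets(enumerate_maximal_cliques(g)),
                 oracle_maximal_cliques(g),
                 info = paste("seed", 2000 + s))
  }
  # isolated vertices are size-1 maximal cliques
  g <- named_graph(c("a", "b"), isolated = "z")
  expect_equal(canonical_sets(enumerate_maximal_cliques(g)),
               canonical_sets(list(c("a", "b"), "z")))
})

test_that("the clique-count guard aborts instead of enumerating", {
  g <- random_named_gnp(12, 0.5, seed = 1)
  expect_error(enumerate_maximal_cliques(g, max_cliques = 2),
               "guard limit")
  expect_error(percolation_profile(random_named_gnp(12, 0.5, seed = 2),
                                   4, max_cliques = 1), "guard limit")
})

test_that("k-clique communities resolve canonical overlap cases", {
  # two triangles sharing one node: overlap 1 < k-1 = 2, so two communities
  comms <- k_clique_communities(bowtie_graph(), 3)
  expect_equal(canonical_sets(comms$communities),
               canonical_sets(list(c("a", "b", "c"), c("c", "d", "e"))))

  # complete graph: all k-cliques chain together
  k6 <- k_clique_communities(complete_graph(6), 4)
  expect_length(k6$communities, 1L)
  expect_equal(k6$communities[[1L]], letters[1:6])

  expect_error(k_clique_communities(complete_graph(4), 1), ">= 2")
})

test_that("k-clique communities equal direct k-clique-adjacency components", {
  for (s in 1:20) {
    set.seed(3000 + s)
    g <- random_named_gnp(sample(8:15, 1), 0.4, seed = 3000 + s)
    for (k in 3:4) {
      expect_equal(canonical_sets(k_clique_communities(g, k)$communities),
                   oracle_k_clique_communities(g, k),
                   info = paste("seed", 3000 + s, "k", k))
    }
  }
})

test_that("percolation profile matches closed forms and the oracle", {
  pr <- percolation_profile(complete_graph(6), 6)
  expect_equal(pr$f_cc, rep(1, 5))

  pr10 <- percolation_profile(path_graph(10), 3)
  expect_equal(pr10$f_cc[pr10$k == 2], 1)
  expect_equal(pr10$f_cc[pr10$k == 3], 0)

  for (s in 1:6) {
    g <- random_named_gnp(14, 0.35, seed = 4000 + s)
    pr <- percolation_profile(g, 5)
    for (k in 2:5) {
      oc <- oracle_k_clique_communities(g, k)
      f_expected <- if (length(oc)) max(lengths(oc)) / 14 else 0
      expect_equal(pr$f_cc[pr$k == k], f_expected,
                   info = paste("seed", 4000 + s, "k", k))
    }
  }
})

test_that("f_cc(2) is the largest connected component fraction", {
  g <- random_named_gnp(200, 0.012, seed = 99)
  pr <- percolation_profile(g, 3)
  comp <- igraph::components(g)
  expect_equal(pr$f_cc[pr$k == 2], max(comp$csize) / 200)
})

test_that("f_cc is monotone: non-increasing in k, non-decreasing in edges", {
  for (s in 1:5) {
    set.seed(5000 + s)
    g <- random_named_gnp(20, 0.3, seed = 5000 + s)
    pr <- percolation_profile(g, 6)
    expect_true(all(diff(pr$f_cc) <= 1e-12))
    # add one random missing edge: no f_cc may decrease
    missing <- which(as.matrix(igraph::as_adjacency_matrix(g)) == 0 &
                     upper.tri(diag(20)), arr.ind = TRUE)
    pick <- missing[sample.int(nrow(missing), 1), ]
    g2 <- igraph::add_edges(g, igraph::V(g)$name[pick])
    pr2 <- percolation_profile(g2, 6)
    expect_true(all(pr2$f_cc >= pr$f_cc - 1e-12))
  }
})

test_that("critical_k picks the largest percolating k", {
  prof <- data.frame(k = 2:7, f_cc = c(1, 0.9, 0.5, 0.2, 0.05, 0))
  expect_equal(critical_k(prof, 0.01), 6L)
  expect_equal(critical_k(data.frame(k = 2, f_cc = 0.004), 0.01), 1L)
  expect_error(critical_k(prof, 0), "0, 1")
  expect_error(critical_k(prof, 1.5), "0, 1")
})

test_that("pc_threshold implements the analytic formula", {
  expect_equal(pc_threshold(1234, 2), 1 / 1234)
  expect_equal(pc_threshold(5000, 4), 1 / (5000 * 3)^(1 / 3))
  expect_error(pc_threshold(1, 3), ">= 2")
  expect_error(pc_threshold(100, 1.5), "integer")
})

test_that("community and profile writers produce the documented formats", {
  comms <- k_clique_communities(bowtie_graph(), 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_communities(comms, f)
  lines <- readLines(f)
  expect_equal(lines[1L], "k=3")
  expect_length(lines, 3L)

  fj <- withr::local_tempfile(fileext = ".json")
  write_communities(comms, fj, format = "json")
  js <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(js$k, 3L)
  expect_length(js$communities, 2L)

  fp <- withr::local_tempfile(fileext = ".tsv")
  write_profile(percolation_profile(complete_graph(5), 4), fp)
  tab <- read.delim(fp)
  expect_equal(names(tab), c("k", "f_cc", "largest_community_size",
                             "n_communities"))
  expect_equal(nrow(tab), 3L)
})
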