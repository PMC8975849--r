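# Edge-list / association-table reading, symmetrization and summaries.

write_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_edge_list collapses duplicate pairs keeping the max weight", {
  f <- write_tmp(c("a\tb\t0.3", "b\ta\t0.1"))
  g <- read_edge_list(f)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 0.3)

  f2 <- write_tmp(c("# comment", "a\tb", "b\tc"))
  g2 <- read_edge_list(f2)
  expect_equal(igraph::vcount(g2), 3L)
  expect_equal(igraph::ecount(g2), 2L)
  expect_false(kcliquenet:::is_weighted_net(g2))
})

test_that("read_edge_list handles CSV, headers, and reports bad rows", {
  f <- write_tmp(c("source,target,weight", "a,b,0.5", "b,c,0.25"))
  g <- read_edge_list(f)
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))

  expect_error(read_edge_list(write_tmp(c("a\tb\t0.5", "c"))),
               "line 2")
  expect_error(read_edge_list(write_tmp(c("a\tb\t1.5"))), "weight")
  expect_error(read_edge_list(write_tmp(c("a\tb\t-0.2"))), "weight")
  expect_error(read_edge_list(write_tmp(c("a\tb\t0.5", "b\tc\tx"))),
               "non-numeric")
  expect_error(read_edge_list("no/such/file.tsv"), "not found")
})

test_that("random duplicated rows reduce to distinct unordered pairs", {
  set.seed(42)
  src <- sample(letters[1:8], 100, replace = TRUE)
  dst <- sample(letters[1:8], 100, replace = TRUE)
  keep <- src != dst
  src <- src[keep]; dst <- dst[keep]
  f <- write_tmp(paste(src, dst, sep = "\t"))
  g <- read_edge_list(f)
  expected <- length(unique(paste(pmin(src, dst), pmax(src, dst))))
  expect_equal(igraph::ecount(g), expected)
})

test_that("edge lists survive a write/read round trip", {
  g <- weighted_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  k1 <- kcliquenet:::edge_keys(igraph::as_edgelist(g)[, 1],
                               igraph::as_edgelist(g)[, 2])
  k2 <- kcliquenet:::edge_keys(igraph::as_edgelist(g2)[, 1],
                               igraph::as_edgelist(g2)[, 2])
  expect_setequal(k2, k1)
  expect_equal(igraph::E(g2)$weight[match(k1, k2)], igraph::E(g)$weight,
               tolerance = 1e-9)
})

test_that("symmetrize keeps the greater directed strength", {
  tab <- data.frame(cue = c("a", "b"), response = c("b", "a"),
                    strength = c(0.3, 0.1))
  g <- symmetrize(tab)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 0.3)

  g1 <- symmetrize(data.frame(cue = "a", response = "b", strength = 0.2))
  expect_equal(igraph::E(g1)$weight, 0.2)

  g0 <- symmetrize(data.frame(cue = character(0), response = character(0),
                              strength = numeric(0)))
  expect_equal(igraph::vcount(g0), 0L)
})

test_that("symmetrize matches a per-pair max oracle on random tables", {
  set.seed(7)
  words <- paste0("w", 1:12)
  cue <- sample(words, 50, replace = TRUE)
  resp <- sample(words, 50, replace = TRUE)
  keep <- !duplicated(paste(cue, resp, sep = "\r")) & cue != resp
  tab <- data.frame(cue = cue[keep], response = resp[keep],
                    strength = round(runif(sum(keep), 0.01, 0.15), 3))
  g <- suppressWarnings(symmetrize(tab))  # per-cue sums may top 1 by chance
  expect_lte(igraph::ecount(g), nrow(tab))
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    ab <- tab$strength[tab$cue == el[i, 1] & tab$response == el[i, 2]]
    ba <- tab$strength[tab$cue == el[i, 2] & tab$response == el[i, 1]]
    expect_equal(igraph::E(g)$weight[i], max(c(ab, ba)))
    expect_true(igraph::E(g)$weight[i] %in% tab$strength)
  }
})

test_that("association table validation enforces the invariants", {
  expect_error(validate_association_table(
    data.frame(cue = "a", response = "b", strength = 1.2)), "0, 1")
  expect_error(validate_association_table(
    data.frame(cue = c("a", "a"), response = c("b", "b"),
               strength = c(0.1, 0.2))), "repeated")
  expect_warning(validate_association_table(
    data.frame(cue = c("a", "a"), response = c("b", "c"),
               strength = c(0.7, 0.6))), "summing above 1")
  # probabilities out of a cue summing to exactly 1 are fine
  expect_silent(validate_association_table(
    data.frame(cue = c("a", "a"), response = c("b", "c"),
               strength = c(0.5, 0.5))))
})

test_that("network_summary matches closed forms on canonical graphs", {
  s <- network_summary(complete_graph(3))
  expect_equal(s$density, 1)
  expect_equal(s$transitivity, 1)
  expect_equal(s$avg_clustering, 1)

  s5 <- network_summary(star_graph(5))
  expect_equal(s5$transitivity, 0)
  expect_equal(s5$avg_clustering, 0)
  expect_equal(s5$density, 5 / choose(6, 2))

  expect_error(network_summary(named_graph(character(0), isolated = "x")),
               "at least 2")
})

test_that("summary invariants hold on random graphs", {
  for (s in 1:5) {
    g <- random_named_gnp(15, 0.4, seed = 100 + s)
    sm <- network_summary(g)
    expect_gte(sm$transitivity, 0); expect_lte(sm$transitivity, 1)
    expect_gte(sm$avg_clustering, 0); expect_lte(sm$avg_clustering, 1)
    expect_equal(sm$density,
                 igraph::ecount(g) / choose(igraph::vcount(g), 2))
  }
  sk <- network_summary(complete_graph(6))
  expect_equal(sk$transitivity, 1)
  expect_equal(sk$avg_clustering, 1)
})

test_that("summary JSON output carries the five reported fields", {
  f <- withr::local_tempfile(fileext = ".json")
  write_summary_json(network_summary(complete_graph(4)), f)
  js <- jsonlite::read_json(f)
  expect_named(js, c("n_nodes", "n_edges", "density", "transitivity",
                     "avg_clustering"))
  expect_equal(js$n_edges, 6L)
})
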