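# Synthetic networks: Erdos-Renyi baselines, a triangle
# preferential-attachment growth model for free-association-like clique
# structure, a weight generator emulating the empirical weight-clustering
# relation, and power-law degree-distribution fitting.

#' Erdos-Renyi random graph G(n, p)
#'
#' Each unordered node pair is an edge independently with probability `p`.
#' Serves both as the null model for the analytic percolation threshold
#' [pc_threshold()] and as the initial condition of [grow_network()].
#'
#' @param n Number of nodes (>= 1).
#' @param p Link probability in \[0, 1\].
#' @param seed Optional RNG seed.
#' @return Unweighted simple undirected igraph with nodes named
#'   `"1" .. "n"`.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Growth-model parameters
#'
#' Parameters of the triangle preferential-attachment model: at every step
#' a new word attaches to the 2`m` endpoints of `m` existing edges drawn
#' with probability proportional to the summed endpoint degrees (each
#' selection closes a triangle), then `c` random edges appear between old
#' words; growth starts from an Erdos-Renyi seed graph G(`l`, `p0`).
#' Defaults m = 4, c = 4, l = 20, p0 = 0.2 reproduce the sparse, highly
#' clustered regime where k-clique percolation survives up to k of 5-6.
#'
#' @param m Edges selected per step (>= 1); controls triangle formation
#'   and is the key parameter for k-clique percolation.
#' @param c Random old-pair edges per step (>= 0); controls the random
#'   "background" wiring.
#' @param l Initial node count (2 <= l <= n_target).
#' @param p0 Initial ER link probability in \[0, 1\].
#' @param n_target Final node count.
#' @param seed Optional RNG seed.
#' @param replace Sample the m edges with replacement instead of without
#'   (default `FALSE`).
#' @return List of class `growth_params`.
#' @export
growth_params <- function(m = 4, c = 4, l = 20, p0 = 0.2, n_target = 2000,
                          seed = NULL, replace = FALSE) {
  stopifnot(m >= 1, m == round(m), c >= 0, c == round(c),
            l >= 2, l == round(l), n_target >= l, n_target == round(n_target),
            p0 >= 0, p0 <= 1)
  structure(list(m = as.integer(m), c = as.integer(c), l = as.integer(l),
                 p0 = p0, n_target = as.integer(n_target), seed = seed,
                 replace = isTRUE(replace)),
            class = "growth_params")
}

#' Grow a triangle preferential-attachment network
#'
#' Simulates the growth model described in [growth_params()]: an
#' Erdos-Renyi seed graph G(l, p0), then one new node per step connected
#' to both endpoints of each of `m` existing edges chosen with probability
#' proportional to the sum of their endpoint degrees (degrees frozen at
#' the step start; duplicate endpoint links collapse, keeping the graph
#' simple), plus `c` uniformly random edges between non-adjacent old
#' nodes. Identical parameters and seed give an identical edge set.
#'
#' @param params A `growth_params` object.
#' @return Unweighted simple undirected igraph with `n_target` nodes named
#'   `"1" .. "n_target"` (node `"i"` was added at step i).
#' @export
grow_network <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  with_seed(params$seed, {
    g0 <- igraph::sample_gnp(params$l, params$p0)
    el <- igraph::as_edgelist(g0, names = FALSE)
    if (nrow(el) < params$m && params$n_target > params$l) {
      stop(sprintf("growth step for node %d: only %d edges available, need m = %d",
                   params$l + 1L, nrow(el), params$m), call. = FALSE)
    }
    res <- .grow_edges(as.integer(el[, 1L]), as.integer(el[, 2L]),
                       params$l, params$n_target, params$m, params$c,
                       params$replace)
    g <- igraph::make_empty_graph(params$n_target, directed = FALSE)
    g <- igraph::add_edges(g, rbind(res$src, res$dst))
    igraph::V(g)$name <- as.character(seq_len(params$n_target))
    g
  })
}

#' Assign synthetic weights from the weight-clustering relation
#'
#' Emulates the empirical log-linear dependence of association strength on
#' edge clustering: each edge gets
#' `w = base^(slope * C_ij + intercept + eps)`, `eps ~ N(0, noise_sd)`,
#' clipped into \[1e-6, 1\], with C_ij computed on the unweighted
#' topology. With the default slope 5.0 and intercept -4.4 (base 10) the
#' weights mimic free-association strengths: highly clustered edges carry
#' strong associations.
#'
#' @param net Simple undirected igraph (existing weights are overwritten).
#' @param slope,intercept Coefficients of the log-linear rule.
#' @param noise_sd Standard deviation of the Gaussian noise on the log
#'   scale (0 for the exact deterministic rule).
#' @param log_base Base of the rule's logarithm, 10 (default) or `exp(1)`.
#' @param seed Optional RNG seed.
#' @return The network with a `weight` edge attribute in (0, 1].
#' @export
assign_synthetic_weights <- function(net, slope = 5.0, intercept = -4.4,
                                     noise_sd = 0.2, log_base = 10,
                                     seed = NULL) {
  check_network(net)
  if (!log_base %in% c(10, exp(1))) {
    stop("`log_base` must be 10 or exp(1)", call. = FALSE)
  }
  cij <- edge_clustering_all(net)
  eps <- with_seed(seed, rnorm(length(cij), 0, noise_sd))
  w <- log_base^(slope * cij + intercept + eps)
  igraph::E(net)$weight <- pmin(pmax(w, 1e-6), 1)
  net
}

#' Fit a power-law exponent to the degree distribution
#'
#' Fits p(d) ~ d^(-gamma) to the degrees at or above `x_min`, either by
#' the continuous-approximation maximum-likelihood estimator
#' `gamma = 1 + n / sum(log(d / (x_min - 1/2)))` (method `"mle"`,
#' default), or by least squares of the log complementary cumulative
#' distribution against log degree, whose slope is 1 - gamma (method
#' `"tail_regression"`). The empirical CCDF P(D >= d) over all distinct
#' degrees is returned alongside for plotting.
#'
#' @param net Simple undirected igraph, or a numeric vector taken directly
#'   as the degree sequence.
#' @param method `"mle"` or `"tail_regression"`.
#' @param x_min Smallest degree included in the fit (>= 1).
#' @return Object of class `degree_fit`: list with `gamma`, `method`,
#'   `x_min`, `n_tail` and `ccdf` (`data.frame` of `degree`, `ccdf`).
#' @export
fit_degree_exponent <- function(net, method = c("mle", "tail_regression"),
                                x_min = 1) {
  method <- match.arg(method)
  stopifnot(is.numeric(x_min), length(x_min) == 1L, x_min >= 1)
  if (is.numeric(net)) {
    deg <- net
  } else {
    check_network(net)
    deg <- igraph::degree(net)
  }
  dpos <- sort(deg[deg >= 1])
  dv <- unique(dpos)
  nn <- length(dpos)
  ccdf <- data.frame(degree = dv,
                     ccdf = 1 - (match(dv, dpos) - 1) / nn)
  tail_d <- deg[deg >= x_min]
  if (length(unique(tail_d)) < 10L) {
    stop("degenerate degree sequence: fewer than 10 distinct degrees >= x_min",
         call. = FALSE)
  }
  if (method == "mle") {
    gamma <- 1 + length(tail_d) / sum(log(tail_d / (x_min - 0.5)))
  } else {
    pts <- ccdf[ccdf$degree >= x_min, ]
    fit <- lm(log(ccdf) ~ log(degree), data = pts)
    gamma <- abs(unname(coef(fit)[2L])) + 1
  }
  structure(list(gamma = gamma, method = method, x_min = x_min,
                 n_tail = length(tail_d), ccdf = ccdf),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("Power-law degree fit (%s, x_min = %g): gamma = %.3f (n_tail = %d)\n",
              x$method, x$x_min, x$gamma, x$n_tail))
  invisible(x)
}

#' Write a degree CCDF as TSV
#'
#' Columns `degree`, `ccdf`.
#'
#' @param fit A `degree_fit`.
#' @param path Output path.
#' @export
write_ccdf <- function(fit, path) {
  stopifnot(inherits(fit, "degree_fit"))
  write.table(fit$ccdf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
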