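# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed for a named stage, derived from a master seed.
# Stable across sessions (plain integer arithmetic, no hashing libraries);
# result is a valid 32-bit seed.
derive_seed <- function(master_seed, name) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  codes <- utf8ToInt(name)
  h <- 0
  for (co in codes) h <- (h * 131 + co) %% 2147483629
  as.integer((abs(master_seed) %% 2147483629 + h * 7919) %% 2147483629 + 1)
}

# Validate that `net` is a simple undirected igraph, optionally demanding
# weights; weights, when present, must lie in (0, 1].
check_network <- function(net, require_weights = FALSE) {
  if (!igraph::is_igraph(net)) {
    stop("`net` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop("`net` must be undirected", call. = FALSE)
  }
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    stop("`net` must be simple (no self-loops or multi-edges)", call. = FALSE)
  }
  has_w <- "weight" %in% igraph::edge_attr_names(net)
  if (require_weights && !has_w) {
    stop("network must carry edge weights for this operation", call. = FALSE)
  }
  if (has_w) {
    w <- igraph::E(net)$weight
    if (any(!is.finite(w)) || any(w <= 0) || any(w > 1)) {
      stop("edge weights must lie in (0, 1]", call. = FALSE)
    }
  }
  invisible(net)
}

is_weighted_net <- function(net) {
  "weight" %in% igraph::edge_attr_names(net)
}

# Canonical unordered edge keys "a|b" with a <= b lexicographically.
edge_keys <- function(from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  paste(a, b, sep = "\r")
}
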