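# Reading, validating, symmetrizing and summarizing weighted association
# networks. Networks are simple undirected igraph objects whose vertices are
# named by opaque strings (no case folding: "Dog" and "dog" stay distinct)
# and whose optional edge weights are association strengths in (0, 1].

#' Read a weighted edge list into a network
#'
#' Reads a two- or three-column delimited file (`source`, `target`,
#' optional `weight`) into a simple undirected [igraph][igraph::igraph]
#' graph. Lines starting with `#` and blank lines are ignored; an optional
#' header row is detected automatically. Duplicate undirected pairs are
#' collapsed keeping the maximum weight, mirroring the symmetrization rule
#' for bidirectional associations. Self-loop rows are dropped with a
#' warning.
#'
#' @param path Path to a TSV/CSV edge list.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param header `NA` (default) auto-detects a header row; `TRUE`/`FALSE`
#'   force the choice.
#' @return An undirected simple igraph; weighted iff the file has a third
#'   column, with weights in (0, 1].
#' @seealso [write_edge_list()], [symmetrize()]
#' @export
read_edge_list <- function(path, sep = NULL, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, trimws)
  ncols <- lengths(fields)
  bad <- which(ncols < 2L | ncols > 3L)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: expected 2 or 3 fields, got %d",
                 lineno[bad[1L]], ncols[bad[1L]]), call. = FALSE)
  }
  if (any(ncols != ncols[1L])) {
    bad <- which(ncols != ncols[1L])[1L]
    stop(sprintf("malformed row at line %d: inconsistent field count",
                 lineno[bad]), call. = FALSE)
  }
  weighted <- ncols[1L] == 3L
  if (is.na(header)) {
    f1 <- fields[[1L]]
    header <- identical(tolower(f1[1:2]), c("source", "target")) ||
      (weighted && is.na(suppressWarnings(as.numeric(f1[3L]))))
  }
  if (header) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (length(fields) == 0L) {
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
  }
  src <- vapply(fields, `[[`, "", 1L)
  dst <- vapply(fields, `[[`, "", 2L)
  if (any(src == "" | dst == "")) {
    bad <- which(src == "" | dst == "")[1L]
    stop(sprintf("malformed row at line %d: empty node id", lineno[bad]),
         call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    wtxt <- vapply(fields, `[[`, "", 3L)
    w <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1L]
      stop(sprintf("malformed row at line %d: non-numeric weight '%s'",
                   lineno[bad], wtxt[bad]), call. = FALSE)
    }
    if (any(w <= 0 | w > 1)) {
      bad <- which(w <= 0 | w > 1)[1L]
      stop(sprintf("invalid weight %g at line %d: weights must lie in (0, 1]",
                   w[bad], lineno[bad]), call. = FALSE)
    }
  }
  loops <- src == dst
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped", call. = FALSE)
    src <- src[!loops]; dst <- dst[!loops]
    if (weighted) w <- w[!loops]
  }
  build_undirected(src, dst, w)
}

# Collapse directed/duplicated pairs into a simple undirected igraph,
# keeping the maximum weight per unordered pair.
build_undirected <- function(src, dst, w = NULL) {
  nodes <- sort(unique(c(src, dst)))
  if (length(src) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::add_vertices(g, length(nodes), name = nodes))
  }
  key <- edge_keys(src, dst)
  if (is.null(w)) {
    uniq <- !duplicated(key)
    a <- pmin(src, dst)[uniq]
    b <- pmax(src, dst)[uniq]
    el <- cbind(a, b)
  } else {
    wmax <- tapply(w, key, max)
    parts <- strsplit(names(wmax), "\r", fixed = TRUE)
    el <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  if (!is.null(w)) igraph::E(g)$weight <- as.numeric(wmax)
  g
}

#' Write a network as an edge list
#'
#' Writes `source`, `target` (and `weight`, if present) as a delimited file
#' with a header row; a round trip through [read_edge_list()] reproduces
#' the node set, edge set and weights. Isolated vertices cannot be
#' expressed in an edge list and are silently lost.
#'
#' @param net Simple undirected igraph.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_edge_list <- function(net, path, sep = "\t") {
  check_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(source = el[, 1L], target = el[, 2L],
                   stringsAsFactors = FALSE)
  if (is_weighted_net(net)) {
    df$weight <- format(igraph::E(net)$weight, digits = 15, trim = TRUE,
                        scientific = FALSE)
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cue-response association table
#'
#' Reads a CSV with header `cue,response,strength` holding directed
#' free-association records: `strength` is the fraction of respondents who
#' produced `response` given `cue` (a conditional response probability in
#' (0, 1]). Repeated (cue, response) pairs are rejected; a cue whose
#' outgoing strengths sum to more than 1 (plus `tol`) draws a warning,
#' since probabilities out of a cue cannot exceed 1.
#'
#' @param path CSV path.
#' @param tol Tolerance on the per-cue strength sum (default 1e-6).
#' @return A `data.frame` with columns `cue`, `response`, `strength`.
#' @export
read_association_table <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = ",", header = TRUE, quote = "\"",
                   colClasses = c("character", "character", "numeric"),
                   comment.char = "#", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("cue", "response", "strength") %in% names(df))) {
    stop("association table needs columns cue,response,strength",
         call. = FALSE)
  }
  validate_association_table(df[c("cue", "response", "strength")], tol)
}

#' Validate an association table
#'
#' @param table `data.frame` with columns `cue`, `response`, `strength`.
#' @param tol Tolerance on per-cue strength sums.
#' @return The table, invisibly validated (errors on violated invariants,
#'   warns when a cue's strengths sum above 1 + `tol`).
#' @export
validate_association_table <- function(table, tol = 1e-6) {
  stopifnot(is.data.frame(table),
            all(c("cue", "response", "strength") %in% names(table)))
  s <- table$strength
  if (any(!is.finite(s)) || any(s <= 0) || any(s > 1)) {
    stop("association strengths must lie in (0, 1]", call. = FALSE)
  }
  key <- paste(table$cue, table$response, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- table[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("repeated (cue, response) pair: (%s, %s)",
                 dup$cue, dup$response), call. = FALSE)
  }
  sums <- tapply(s, table$cue, sum)
  over <- sums > 1 + tol
  if (any(over)) {
    warning(sum(over), " cue(s) have outgoing strengths summing above 1 ",
            "(max ", format(max(sums)), ")", call. = FALSE)
  }
  table
}

#' Symmetrize a directed association table into a weighted network
#'
#' Builds the undirected association network: every cue and response
#' becomes a node, every (cue, response) record an undirected edge, and a
#' bidirectional association keeps the greater of its two directed
#' strengths as the edge weight. Self-associations (cue equal to response)
#' are dropped with a warning so the result stays simple.
#'
#' @param table Association `data.frame` (see [read_association_table()]).
#' @return Weighted simple undirected igraph.
#' @export
symmetrize <- function(table) {
  table <- validate_association_table(table)
  if (nrow(table) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  loops <- table$cue == table$response
  if (any(loops)) {
    warning(sum(loops), " self-association(s) dropped", call. = FALSE)
    table <- table[!loops, , drop = FALSE]
  }
  nodes <- sort(unique(c(table$cue, table$response)))
  g <- build_undirected(table$cue, table$response, table$strength)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  g
}

#' Structural summary of a network
#'
#' Node and edge counts, density, global transitivity (3 x triangles /
#' connected triples) and the mean local clustering coefficient (nodes of
#' degree below 2 contribute 0). Transitivity and mean local clustering
#' answer subtly different questions -- the former weights high-degree
#' nodes by their triple counts -- so both are reported.
#'
#' @param net Simple undirected igraph with at least 2 nodes.
#' @return A list of class `network_summary` with elements `n_nodes`,
#'   `n_edges`, `density`, `transitivity`, `avg_clustering`.
#' @export
network_summary <- function(net) {
  check_network(net)
  n <- igraph::vcount(net)
  if (n < 2L) stop("network summary needs at least 2 nodes", call. = FALSE)
  e <- igraph::ecount(net)
  tr <- igraph::transitivity(net, type = "global")
  if (is.nan(tr)) tr <- 0
  cl <- igraph::transitivity(net, type = "localaverageundirected",
                             isolates = "zero")
  if (is.nan(cl)) cl <- 0
  structure(list(n_nodes = n, n_edges = e,
                 density = e / (n * (n - 1) / 2),
                 transitivity = tr, avg_clustering = cl),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  nodes: %d   edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  density: %.4g\n", x$density))
  cat(sprintf("  transitivity: %.4g   avg clustering: %.4g\n",
              x$transitivity, x$avg_clustering))
  invisible(x)
}

#' Write a network summary as JSON
#'
#' @param summary A `network_summary`.
#' @param path Output path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
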