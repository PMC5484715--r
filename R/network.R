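#' Construct a network from an edge table
#'
#' `sbd_network()` is the basic container used throughout the package: an
#' ordered node set and an ordered edge list, directed or undirected.  Nodes
#' and edges carry stable integer indices -- nodes in first-appearance order,
#' edges in input order -- and every downstream tie-break (driver
#' representatives, driven-row selection) refers to these indices.
#'
#' Self-loops and duplicate edges are rejected: switchboard dynamics routes
#' signals between *distinct* inbound and outbound edges of a node, and the
#' identical-or-orthogonal column structure of the line-graph matrix presumes
#' a simple graph.
#'
#' @param edges two-column matrix or data.frame of (tail, head) pairs; node
#'   identifiers may be character or integer.
#' @param directed logical; undirected edges are stored once.
#' @param nodes optional character vector fixing the node set (and its order);
#'   defaults to first appearance in `edges`.  Extra names give isolated
#'   nodes.
#' @param weights optional numeric edge weights, kept as metadata.
#' @return an object of class `sbd_network` with fields `nodes`, `edges`
#'   (M x 2 integer matrix of node indices), `directed`, `N`, `M`, `weights`.
#' @examples
#' net <- sbd_network(rbind(c("a", "b"), c("b", "c")), directed = TRUE)
#' net$N  # 3
#' @export
sbd_network <- function(edges, directed = TRUE, nodes = NULL, weights = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) < 2L) stop("edges must have two columns (tail, head)")
  tails <- as.character(edges[, 1])
  heads <- as.character(edges[, 2])
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(tails, heads)))
  } else {
    nodes <- as.character(nodes)
    extra <- setdiff(unique(c(tails, heads)), nodes)
    if (length(extra)) stop("edge references unknown node(s): ",
                            paste(extra, collapse = ", "))
  }
  ti <- match(tails, nodes)
  hi <- match(heads, nodes)
  if (any(ti == hi)) {
    bad <- which(ti == hi)[1]
    stop(sprintf("self-loop at node '%s' (edge %d) is not allowed",
                 tails[bad], bad))
  }
  key <- if (directed) paste(ti, hi) else paste(pmin(ti, hi), pmax(ti, hi))
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(sprintf("duplicate edge (%s, %s) at position %d",
                 tails[bad], heads[bad], bad))
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(ti)) stop("weights length must equal edge count")
  }
  structure(list(
    nodes = nodes,
    edges = cbind(tail = as.integer(ti), head = as.integer(hi)),
    directed = isTRUE(directed),
    N = length(nodes),
    M = length(ti),
    weights = weights
  ), class = "sbd_network")
}

#' @export
print.sbd_network <- function(x, ...) {
  cat(sprintf("<sbd_network> %s, N = %d nodes, M = %d edges\n",
              if (x$directed) "directed" else "undirected", x$N, x$M))
  invisible(x)
}

#' Read a network from an edge-list text file
#'
#' One edge per line, `tail<ws>head[<ws>weight]`; lines starting with `#`
#' (and blank lines) are ignored.  Node order is first appearance, edge order
#' is file order.
#'
#' @param path file path.
#' @param directed logical.
#' @return an [sbd_network].
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # optional `# node <name>` directives fix the node set and order
  # (written by write_edge_list to preserve isolated nodes)
  nd <- regmatches(lines, regexec("^\\s*#\\s*node\\s+(\\S+)\\s*$", lines))
  nodes <- vapply(nd[lengths(nd) == 2], `[`, character(1), 2)
  if (!length(nodes)) nodes <- NULL
  keep <- which(!grepl("^\\s*(#|$)", lines))
  tails <- character(0); heads <- character(0); w <- numeric(0)
  has_w <- FALSE
  for (i in keep) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 2L || length(tok) > 3L)
      stop(sprintf("line %d: expected 'tail head [weight]', got '%s'",
                   i, lines[i]))
    tails <- c(tails, tok[1]); heads <- c(heads, tok[2])
    if (length(tok) == 3L) {
      wi <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(wi)) stop(sprintf("line %d: non-numeric weight '%s'", i, tok[3]))
      has_w <- TRUE
      w <- c(w, wi)
    } else {
      w <- c(w, NA_real_)
    }
  }
  sbd_network(cbind(tails, heads), directed = directed, nodes = nodes,
              weights = if (has_w) w else NULL)
}

#' Write a network as an edge-list text file
#'
#' Inverse of [read_edge_list()]: round-trips node names, edge order and
#' weights exactly.
#'
#' @param net an [sbd_network].
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "sbd_network"))
  lines <- character(net$M)
  for (e in seq_len(net$M)) {
    lines[e] <- paste(net$nodes[net$edges[e, 1]], net$nodes[net$edges[e, 2]])
    if (!is.null(net$weights) && !is.na(net$weights[e]))
      lines[e] <- paste(lines[e], format(net$weights[e], digits = 17))
  }
  # `# node` directives pin the node set and its order, so isolated nodes
  # and first-appearance indexing survive a round-trip
  hdr <- c(sprintf("# directed=%s", net$directed),
           sprintf("# node %s", net$nodes))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a network from a GraphML file
#'
#' Node identifiers are taken from the GraphML `name`/id attributes and
#' coerced to the package's stable first-appearance index.
#'
#' @param path GraphML file path.
#' @param directed logical or `NA` to use the file's own directedness.
#' @return an [sbd_network].
#' @export
read_graphml <- function(path, directed = NA) {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.na(directed)) directed <- igraph::is_directed(g)
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  sbd_network(cbind(nm[el[, 1]], nm[el[, 2]]), directed = directed, nodes = nm)
}

#' In-, out- or total degrees of every node
#'
#' @param net an [sbd_network].
#' @return a data.frame with one row per node: `node`, and `k_in`, `k_out`
#'   (directed) or `k` (undirected).  Degree conservation holds:
#'   `sum(k_out) == sum(k_in) == M` and `sum(k) == 2 * M`.
#' @export
degree_profile <- function(net) {
  stopifnot(inherits(net, "sbd_network"))
  if (net$directed) {
    data.frame(node = net$nodes,
               k_in = tabulate(net$edges[, 2], nbins = net$N),
               k_out = tabulate(net$edges[, 1], nbins = net$N))
  } else {
    data.frame(node = net$nodes,
               k = tabulate(as.vector(net$edges), nbins = net$N))
  }
}

# internal: (k_in, k_out) for directed, (k, k) for undirected
.degrees <- function(net) {
  if (net$directed) {
    list(k_in = tabulate(net$edges[, 2], nbins = net$N),
         k_out = tabulate(net$edges[, 1], nbins = net$N))
  } else {
    k <- tabulate(as.vector(net$edges), nbins = net$N)
    list(k_in = k, k_out = k)
  }
}

#' Connected components of a network
#'
#' For directed networks components are *weak* components: this is the
#' convention under which the per-component driver correction (one driver for
#' each balanced component) matches the exact-controllability oracles on
#' cycles and disjoint unions.  Isolated nodes form singleton components with
#' `has_edges = FALSE`.
#'
#' @param net an [sbd_network].
#' @return a list of class `component_partition`: `membership` (component id
#'   per node), `n_components`, `members` (list of node-index vectors),
#'   `edge_count` and `has_edges` per component.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "sbd_network"))
  if (net$M == 0L) {
    g <- igraph::make_empty_graph(n = net$N, directed = net$directed)
  } else {
    g <- igraph::graph_from_edgelist(net$edges, directed = net$directed)
    g <- igraph::add_vertices(g, max(0L, net$N - igraph::vcount(g)))
  }
  comp <- igraph::components(g, mode = "weak")
  memb <- as.integer(comp$membership)
  nc <- comp$no
  ec <- tabulate(memb[net$edges[, 1]], nbins = nc)
  structure(list(
    membership = memb,
    n_components = nc,
    members = split(seq_len(net$N), memb),
    edge_count = ec,
    has_edges = ec > 0L
  ), class = "component_partition")
}
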