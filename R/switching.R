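# Switching matrices and the edge-level (line-graph) linear system.
#
# Directed networks: the state vector has one entry per edge (D = M).
# Undirected networks: each physical edge is split into two opposite arcs
# (D = 2M); edge e yields arc 2e-1 (low-index endpoint -> high) and arc 2e
# (the reverse).  Node v's switching matrix couples ALL inbound arc states at
# v to ALL outbound arc states at v, including the reverse arc of the same
# physical edge, so it is square k_v x k_v.

# internal: state/arc table.  Columns: tail, head, edge, rev (reverse arc id
# or NA for directed networks).
.arc_table <- function(net) {
  if (net$directed) {
    data.frame(tail = net$edges[, 1], head = net$edges[, 2],
               edge = seq_len(net$M), rev = NA_integer_)
  } else {
    if (net$M == 0L)
      return(data.frame(tail = integer(0), head = integer(0),
                        edge = integer(0), rev = integer(0)))
    lo <- pmin(net$edges[, 1], net$edges[, 2])
    hi <- pmax(net$edges[, 1], net$edges[, 2])
    n <- 2L * net$M
    tail <- integer(n); head <- integer(n)
    tail[seq(1L, n, by = 2L)] <- lo; head[seq(1L, n, by = 2L)] <- hi
    tail[seq(2L, n, by = 2L)] <- hi; head[seq(2L, n, by = 2L)] <- lo
    data.frame(tail = tail, head = head,
               edge = rep(seq_len(net$M), each = 2L),
               rev = as.integer(seq_len(n) + c(1L, -1L)))
  }
}

#' Build the per-node switching matrices of a network
#'
#' Node `v`'s switching matrix routes its inbound edge states to the
#' derivatives of its outbound edge states.  Its shape is out-degree x
#' in-degree (directed) or degree x degree (undirected); row order is
#' ascending outbound state index, column order ascending inbound state
#' index.  Three modes are supported:
#'
#' * `"structural"`: entries are free parameters; a seeded generic numeric
#'   realization (i.i.d. on \[0.5, 1.5)) is stored so that numeric oracles
#'   can run, and the realization is redrawn (at most 5 times) in the
#'   measure-zero event that its numeric rank falls below the pattern's
#'   structural rank.
#' * `"unweighted"`: every pattern entry equals 1.
#' * `"weighted"`: explicit values supplied through `values`; if omitted, a
#'   seeded random draw is used.
#'
#' @param net an [sbd_network].
#' @param mode a single mode or a per-node character vector (names or
#'   positional) from `c("structural", "unweighted", "weighted")`.
#' @param seed integer seed for the generic realizations.
#' @param pattern optional named list of logical matrices restricting the
#'   nonzero pattern of selected nodes; default is the complete pattern
#'   (every inbound edge can route to every outbound edge).
#' @param values optional named list of numeric matrices for
#'   `"weighted"`-mode nodes.
#' @return named list (by node name) of `switching_matrix` objects covering
#'   every node (nodes with zero in- or out-degree get an empty matrix).
#' @export
make_switching_matrices <- function(net, mode = "structural", seed = 1L,
                                    pattern = NULL, values = NULL) {
  stopifnot(inherits(net, "sbd_network"))
  modes <- c("structural", "unweighted", "weighted")
  if (length(mode) == 1L) mode <- rep(mode, net$N)
  if (length(mode) != net$N) stop("mode must be length 1 or N")
  if (!all(mode %in% modes))
    stop("unknown switching mode: ", paste(setdiff(mode, modes), collapse = ", "))
  arcs <- .arc_table(net)
  out_states <- split(seq_len(nrow(arcs)), factor(arcs$tail, seq_len(net$N)))
  in_states  <- split(seq_len(nrow(arcs)), factor(arcs$head, seq_len(net$N)))
  withr::with_seed(as.integer(seed), {
    S <- vector("list", net$N)
    for (v in seq_len(net$N)) {
      os <- out_states[[v]]; is <- in_states[[v]]
      kr <- length(os); kc <- length(is)
      pat <- matrix(TRUE, kr, kc)
      if (!is.null(pattern) && !is.null(pattern[[net$nodes[v]]])) {
        pv <- pattern[[net$nodes[v]]]
        if (!identical(dim(pv), dim(pat)))
          stop(sprintf("pattern for node '%s' must be %d x %d",
                       net$nodes[v], kr, kc))
        pat <- pv
      }
      val <- NULL
      if (kr > 0L && kc > 0L) {
        if (mode[v] == "unweighted") {
          val <- matrix(0, kr, kc); val[pat] <- 1
        } else if (mode[v] == "weighted" && !is.null(values) &&
                   !is.null(values[[net$nodes[v]]])) {
          val <- values[[net$nodes[v]]]
          if (!identical(dim(val), c(kr, kc)))
            stop(sprintf("values for node '%s' must be %d x %d",
                         net$nodes[v], kr, kc))
          if (any(val[!pat] != 0))
            stop(sprintf("values for node '%s' lie outside the pattern",
                         net$nodes[v]))
          if (any(val[pat] == 0))
            stop(sprintf("values for node '%s' are zero on the pattern",
                         net$nodes[v]))
        } else {
          srank <- .structural_rank(pat)
          for (try in seq_len(6L)) {
            if (try == 6L) stop("degenerate structural realization persisted")
            val <- matrix(0, kr, kc)
            val[pat] <- stats::runif(sum(pat), 0.5, 1.5)
            if (.numeric_rank(val) == srank) break
          }
        }
      } else {
        val <- matrix(numeric(0), kr, kc)
      }
      S[[v]] <- structure(list(
        node = v, node_name = net$nodes[v], mode = mode[v],
        k_out = kr, k_in = kc, pattern = pat, values = val,
        out_states = os, in_states = is
      ), class = "switching_matrix")
    }
  })
  names(S) <- net$nodes
  S
}

#' @export
print.switching_matrix <- function(x, ...) {
  cat(sprintf("<switching_matrix> node '%s', %d x %d, mode %s\n",
              x$node_name, x$k_out, x$k_in, x$mode))
  invisible(x)
}

#' Assemble the line-graph linear system
#'
#' Builds the edge-level system `dx/dt = (W - T) x + H u`: `W[i, j]` is
#' nonzero exactly when the head of state `j` is the tail of state `i`, and
#' its value is the corresponding switching-matrix entry; `T` is uniform
#' diagonal damping.
#'
#' @param net an [sbd_network].
#' @param S switching matrices from [make_switching_matrices()]; must cover
#'   every node with outbound states.
#' @param tau uniform damping scalar (>= 0).
#' @return a `line_graph_system`: fields `W` (dense D x D), `D`, `arcs`
#'   (state table), `tau`, `net`, `S`.
#' @export
assemble_line_graph <- function(net, S, tau = 0) {
  stopifnot(inherits(net, "sbd_network"))
  arcs <- .arc_table(net)
  D <- nrow(arcs)
  W <- matrix(0, D, D)
  for (v in seq_len(net$N)) {
    sv <- S[[net$nodes[v]]]
    has_out <- any(arcs$tail == v)
    if (is.null(sv)) {
      if (has_out) stop(sprintf("missing switching matrix for node '%s'",
                                net$nodes[v]))
      next
    }
    if (sv$k_out > 0L && sv$k_in > 0L)
      W[sv$out_states, sv$in_states] <- sv$values
  }
  stopifnot(length(tau) == 1L, tau >= 0)
  structure(list(W = W, D = D, arcs = arcs, tau = as.numeric(tau),
                 net = net, S = S),
            class = "line_graph_system")
}

#' @export
print.line_graph_system <- function(x, ...) {
  cat(sprintf("<line_graph_system> D = %d states, tau = %g, %d nonzeros\n",
              x$D, x$tau[1], sum(x$W != 0)))
  invisible(x)
}

#' Remove uniform damping from a line-graph system
#'
#' Identical diagonal damping has no effect on controllability, so it can be
#' dropped before any rank analysis.  Heterogeneous damping is outside that
#' guarantee and is refused.
#'
#' @param sys a `line_graph_system` (its `tau` may be a scalar or a
#'   length-D vector; the vector must be uniform).
#' @return the same system with `tau = 0`.
#' @export
strip_damping <- function(sys) {
  stopifnot(inherits(sys, "line_graph_system"))
  tau <- sys$tau
  if (length(tau) > 1L && length(unique(tau)) > 1L)
    stop("non-uniform damping is not supported; controllability invariance ",
         "is only guaranteed for identical damping terms")
  sys$tau <- 0
  sys
}

#' Dump the coupling matrix W as sparse text
#'
#' Writes a MatrixMarket-style coordinate listing (`row col value`, 1-based)
#' for external inspection.
#'
#' @param sys a `line_graph_system`.
#' @param path output path.
#' @export
write_w_sparse <- function(sys, path) {
  nz <- which(sys$W != 0, arr.ind = TRUE)
  lines <- c("%%MatrixMarket matrix coordinate real general",
             sprintf("%d %d %d", sys$D, sys$D, nrow(nz)),
             sprintf("%d %d %.17g", nz[, 1], nz[, 2], sys$W[nz]))
  writeLines(lines, path)
  invisible(path)
}
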