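# Controllability engine: minimum driven edges, unique driver set, node and
# edge categories.
#
# Over the D edge states (D = M directed, 2M undirected):
#   M_D = D - sum_v rank(S_v) + sum_c beta_c
# where beta_c = 1 when every switching matrix in component c is square with
# full rank (such a "balanced" component needs one driver even though no row
# of W is dependent there).  A node is a driver iff rank(S_v) < k_v^+, plus
# one representative per beta = 1 component.

#' Per-component balanced-and-full-rank flag
#'
#' @param members node indices of one connected component.
#' @param S switching-matrix list for the network.
#' @param has_edges does the component contain any edge?
#' @param tol numeric-rank tolerance.
#' @return 0 or 1.
#' @export
component_beta <- function(members, S, has_edges = TRUE, tol = 1e-10) {
  if (!has_edges) return(0L)
  for (v in members) {
    sv <- S[[v]]
    if (sv$k_out != sv$k_in || sv$k_out == 0L) return(0L)
    if (switching_rank(sv, tol) < sv$k_out) return(0L)
  }
  1L
}

#' Edge controllability of a network under given switching matrices
#'
#' Computes the minimum number of driven edge states `M_D`, the driver-node
#' set (unique up to the per-component representatives of balanced
#' components), the driven states, per-node ranks and per-component beta
#' flags.
#'
#' @param net an [sbd_network].
#' @param S switching matrices from [make_switching_matrices()].
#' @param tol numeric-rank tolerance.
#' @param row_policy tie-break for which dependent rows are labelled driven:
#'   `"first"` keeps the lowest-index independent rows (default).  The driver
#'   *node* set does not depend on this policy.
#' @return a `controllability_result` with fields `M_D`, `N_D`, `D`,
#'   `driven_states`, `driver_nodes` (indices), `driver_names`, `ranks`,
#'   `beta` (per component), `n_D = N_D / N`, `m_D = M_D / D`.
#' @export
edge_controllability <- function(net, S, tol = 1e-10,
                                 row_policy = c("first", "last")) {
  stopifnot(inherits(net, "sbd_network"))
  row_policy <- match.arg(row_policy)
  deg <- .degrees(net)
  ranks <- vapply(seq_len(net$N), function(v) switching_rank(S[[v]], tol),
                  integer(1))
  comp <- connected_components(net)
  beta <- vapply(seq_len(comp$n_components), function(c)
    component_beta(comp$members[[c]], S, comp$has_edges[c], tol), integer(1))
  D <- if (net$directed) net$M else 2L * net$M
  k_out_states <- deg$k_out  # outbound arc count per node (k_v undirected)
  M_D <- D - sum(ranks) + sum(beta)
  rank_drivers <- which(ranks < k_out_states)
  # one representative per balanced full-rank component: lowest node index
  # with outbound states, and its lowest-index outbound state
  reps <- integer(0); rep_states <- integer(0)
  for (c in which(beta == 1L)) {
    cand <- comp$members[[c]]
    cand <- cand[k_out_states[cand] > 0L]
    r <- min(cand)
    reps <- c(reps, r)
    rep_states <- c(rep_states, min(S[[r]]$out_states))
  }
  driven <- integer(0)
  for (v in rank_drivers) {
    dep <- .dependent_rows(S[[v]], row_policy, tol)
    driven <- c(driven, S[[v]]$out_states[dep])
  }
  driven <- sort(c(driven, rep_states))
  drivers <- sort(unique(c(rank_drivers, reps)))
  N_D <- length(rank_drivers) + sum(beta)
  structure(list(
    M_D = as.integer(M_D), N_D = as.integer(N_D), D = D,
    driven_states = driven,
    driver_nodes = drivers,
    driver_names = net$nodes[drivers],
    rank_driver_nodes = rank_drivers,
    beta_representatives = reps,
    ranks = ranks, beta = beta,
    n_D = N_D / net$N, m_D = M_D / D,
    directed = net$directed, N = net$N, M = net$M
  ), class = "controllability_result")
}

#' @export
print.controllability_result <- function(x, ...) {
  cat(sprintf(paste0("<controllability_result> M_D = %d of %d states ",
                     "(m_D = %.4f), N_D = %d of %d nodes (n_D = %.4f)\n"),
              x$M_D, x$D, x$m_D, x$N_D, x$N, x$n_D))
  cat(sprintf("  drivers: %s\n", paste(x$driver_names, collapse = ", ")))
  invisible(x)
}

#' Classify one node and its outgoing edges
#'
#' Nodes fall in three degree classes -- I: `k_in == k_out`, II:
#' `k_in > k_out`, III: `k_in < k_out` -- and a node is a driver exactly when
#' its switching matrix is not of full row rank; it then has
#' `k_out - rank(S_v)` driven outgoing edges, selected deterministically
#' (the first `rank` independent rows, in ascending state order, stay
#' non-essential).
#'
#' @param S_v a `switching_matrix`.
#' @param tol numeric-rank tolerance.
#' @return list with `degree_class`, `role` (`"driver"`/`"non-essential"`),
#'   `rank`, `n_driven`, `driven_states`, `edge_roles` (per outgoing state).
#' @export
classify_node <- function(S_v, tol = 1e-10) {
  stopifnot(inherits(S_v, "switching_matrix"))
  cls <- if (S_v$k_in == S_v$k_out) "I" else if (S_v$k_in > S_v$k_out) "II" else "III"
  if (S_v$k_out == 0L) {
    return(list(degree_class = cls, role = "non-essential", rank = 0L,
                n_driven = 0L, driven_states = integer(0),
                edge_roles = character(0)))
  }
  r <- switching_rank(S_v, tol)
  dep <- .dependent_rows(S_v, "first", tol)
  roles <- rep("non-essential", S_v$k_out)
  roles[dep] <- "driven"
  list(degree_class = cls,
       role = if (r < S_v$k_out) "driver" else "non-essential",
       rank = r,
       n_driven = S_v$k_out - r,
       driven_states = S_v$out_states[dep],
       edge_roles = stats::setNames(roles, S_v$out_states))
}
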