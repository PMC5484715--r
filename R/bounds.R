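# Degree-only controllability bounds and strong structural controllability.
#
# The upper bound (unweighted switching matrices) and lower bound
# (structural switching matrices) of both N_D and M_D are pure functions of
# the degree sequence and the component structure:
#
#   directed:   N_D^U = N(k+ > 1) + N(k- = 0, k+ = 1) + sum beta'
#               N_D^L = N(k- < k+)                    + sum beta''
#               M_D^U = M - N(k- > 0, k+ > 0)         + sum beta'
#               M_D^L = M - sum min(k-, k+)           + sum beta''
#   undirected (over the 2M arc states):
#               N_D^U = N(k > 1) + sum beta'     N_D^L = sum beta''
#               M_D^U = 2M - N(k > 0) + sum beta'  M_D^L = sum beta''
#
# beta'  = 1 iff the component only contains nodes with k+ = k- = 1
#          (directed cycle components; undirected single-edge components);
# beta'' = 1 iff the component is balanced, k+ = k- > 0 for every node
#          (every undirected component with edges qualifies).
#
# The undirected M_D formulas are stated over the arc-state dimension 2M --
# the only reading under which they agree with the engine and keep
# M - N(k>0) nonnegative on path graphs -- and m_D uses denominator 2M.

# per-component beta' and beta'' flags from degrees
.beta_flags <- function(net) {
  deg <- .degrees(net)
  comp <- connected_components(net)
  bp <- logical(comp$n_components); bpp <- logical(comp$n_components)
  for (c in seq_len(comp$n_components)) {
    if (!comp$has_edges[c]) next
    m <- comp$members[[c]]
    balanced <- all(deg$k_out[m] == deg$k_in[m] & deg$k_out[m] > 0L)
    bpp[c] <- balanced
    bp[c] <- balanced && all(deg$k_out[m] == 1L)
  }
  list(comp = comp, beta_prime = bp, beta_dprime = bpp)
}

#' Degree-only upper and lower controllability bounds
#'
#' Evaluates the closed-form bound formulas from the degree sequence and
#' component structure alone; equals [edge_controllability()] under
#' unweighted (upper) and structural (lower) switching matrices.
#'
#' @param net an [sbd_network].
#' @return a `bounds_result`: counts `N_D_upper`, `N_D_lower`, `M_D_upper`,
#'   `M_D_lower`, fractions `n_D_upper`, `n_D_lower`, `m_D_upper`,
#'   `m_D_lower` (m over M directed, 2M undirected), and the per-component
#'   `beta_prime` / `beta_dprime` flags.
#' @export
degree_bounds <- function(net) {
  stopifnot(inherits(net, "sbd_network"))
  deg <- .degrees(net)
  bf <- .beta_flags(net)
  sbp <- sum(bf$beta_prime); sbpp <- sum(bf$beta_dprime)
  if (net$directed) {
    D <- net$M
    NDU <- sum(deg$k_out > 1L) + sum(deg$k_in == 0L & deg$k_out == 1L) + sbp
    NDL <- sum(deg$k_in < deg$k_out) + sbpp
    MDU <- D - sum(deg$k_in > 0L & deg$k_out > 0L) + sbp
    MDL <- D - sum(pmin(deg$k_in, deg$k_out)) + sbpp
  } else {
    D <- 2L * net$M
    NDU <- sum(deg$k_out > 1L) + sbp
    NDL <- sbpp
    MDU <- D - sum(deg$k_out > 0L) + sbp
    MDL <- sbpp
  }
  structure(list(
    N_D_upper = as.integer(NDU), N_D_lower = as.integer(NDL),
    M_D_upper = as.integer(MDU), M_D_lower = as.integer(MDL),
    n_D_upper = NDU / net$N, n_D_lower = NDL / net$N,
    m_D_upper = if (D > 0) MDU / D else 0,
    m_D_lower = if (D > 0) MDL / D else 0,
    beta_prime = bf$beta_prime, beta_dprime = bf$beta_dprime,
    directed = net$directed, N = net$N, M = net$M, D = D
  ), class = "bounds_result")
}

#' @export
print.bounds_result <- function(x, ...) {
  cat(sprintf(paste0("<bounds_result> N_D in [%d, %d] (n_D [%.4f, %.4f]), ",
                     "M_D in [%d, %d] (m_D [%.4f, %.4f])\n"),
              x$N_D_lower, x$N_D_upper, x$n_D_lower, x$n_D_upper,
              x$M_D_lower, x$M_D_upper, x$m_D_lower, x$m_D_upper))
  invisible(x)
}

#' Strong structural controllability classification
#'
#' A node is strongly structurally controllable (SSC) when its category --
#' driver or non-essential, and its driven-edge count -- cannot change under
#' any re-weighting of its switching matrix: `k_out <= 1` or `k_in <= 1`
#' (directed), `k <= 1` (undirected).  All other nodes are weakly
#' structurally controllable (WSC).  A network whose nodes are all SSC has
#' coinciding upper and lower controllability bounds.
#'
#' @param net an [sbd_network].
#' @return an `ssc_report`: `labels` (per node, `"SSC"`/`"WSC"`), `N_ssc`,
#'   `n_ssc`, `fully_ssc`.
#' @export
ssc_classify <- function(net) {
  stopifnot(inherits(net, "sbd_network"))
  deg <- .degrees(net)
  ssc <- if (net$directed) deg$k_out <= 1L | deg$k_in <= 1L else deg$k_out <= 1L
  structure(list(
    labels = stats::setNames(ifelse(ssc, "SSC", "WSC"), net$nodes),
    N_ssc = as.integer(sum(ssc)),
    n_ssc = sum(ssc) / net$N,
    fully_ssc = all(ssc),
    N = net$N, directed = net$directed
  ), class = "ssc_report")
}

#' @export
print.ssc_report <- function(x, ...) {
  cat(sprintf("<ssc_report> N_ssc = %d of %d (n_ssc = %.4f)%s\n",
              x$N_ssc, x$N, x$n_ssc,
              if (x$fully_ssc) ", fully SSC" else ""))
  invisible(x)
}

#' Gap between the upper and lower controllability bounds
#'
#' A fully SSC network always has zero gap in both counts.  The converse
#' does not hold in general: in degenerate configurations (an undirected
#' 3-path, or two directed cycles sharing one node) a WSC node's driven edge
#' migrates between nodes as weights change without altering the network
#' totals, so the gap is zero although the network is not fully SSC.  The
#' exact equivalence lives at node level: a node is SSC iff its category is
#' the same under structural and unweighted switching matrices.
#'
#' @param net an [sbd_network].
#' @return list `N_gap`, `M_gap`, `zero_gap`.
#' @export
bound_gap <- function(net) {
  b <- degree_bounds(net)
  list(N_gap = b$N_D_upper - b$N_D_lower,
       M_gap = b$M_D_upper - b$M_D_lower,
       zero_gap = (b$N_D_upper == b$N_D_lower) && (b$M_D_upper == b$M_D_lower))
}
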