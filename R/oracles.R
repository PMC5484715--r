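# Independent verification oracles.  None of these feed the engine; they
# exist so every engine quantity can be cross-checked on realized numeric
# systems.

#' Numeric rank of the line-graph coupling matrix
#'
#' For any realized switchboard system, `rank(W)` must equal the sum of the
#' per-node switching-matrix ranks; this function computes the left side of
#' that identity independently of the engine.
#'
#' @param sys a `line_graph_system`.
#' @param tol relative tolerance.
#' @return integer rank of `W`.
#' @export
line_graph_rank_oracle <- function(sys, tol = 1e-10) {
  stopifnot(inherits(sys, "line_graph_system"))
  .numeric_rank(sys$W, tol)
}

# weak components of the state coupling graph (isolated states included)
.lg_components <- function(W) {
  D <- nrow(W)
  nz <- which(W != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(as.list(seq_len(D)))
  g <- igraph::graph_from_edgelist(nz[, c(2, 1), drop = FALSE],
                                   directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, D - igraph::vcount(g)))
  memb <- igraph::components(g, mode = "weak")$membership
  unname(split(seq_len(D), memb))
}

#' Minimum driven-state count via eigenvalue multiplicities
#'
#' Exact-controllability oracle: for each weak component of the line graph,
#' the minimum number of independent inputs equals the maximum geometric
#' multiplicity over that component's eigenvalues (at least one input per
#' component, since one signal cannot reach disconnected states).  The sum
#' over components must equal the engine's `M_D`, and the maximum is
#' expected at eigenvalue zero whenever the rank-deficiency term dominates.
#'
#' @param sys a `line_graph_system` with realized numeric `W`; `D <= 500`.
#' @param tol numeric-rank tolerance.
#' @param eig_tol absolute tolerance for clustering close eigenvalues.
#' @return integer: minimum number of driven states.
#' @export
exact_controllability_oracle <- function(sys, tol = 1e-10, eig_tol = 1e-8) {
  stopifnot(inherits(sys, "line_graph_system"))
  if (sys$D > 500L) stop("oracle capped at D <= 500")
  if (sys$D == 0L) return(0L)
  A <- sys$W - sys$tau[1] * diag(sys$D)  # damping shifts eigenvalues only
  total <- 0L
  for (idx in .lg_components(sys$W)) {
    Wc <- A[idx, idx, drop = FALSE]
    Dc <- length(idx)
    # candidate eigenvalues; 0 (shifted by the damping) is always included
    # because defective zero eigenvalues scatter numerically under eigen()
    ev <- c(-sys$tau[1] + 0i, eigen(Wc, only.values = TRUE)$values)
    # cluster eigenvalues within eig_tol (absolute) and test one per cluster
    reps <- c()
    for (l in ev) if (!length(reps) || min(Mod(reps - l)) > eig_tol)
      reps <- c(reps, l)
    mult <- vapply(reps, function(l)
      Dc - .numeric_rank(l * diag(Dc) - Wc, tol), numeric(1))
    total <- total + max(1L, max(mult))
  }
  as.integer(total)
}

#' Kalman rank certificate for a control configuration
#'
#' Places one input at every driven state of `result` and checks that the
#' controllability matrix `[B, WB, ..., W^(D-1) B]` has full numeric rank,
#' and (minimality spot-check) that removing any single input breaks it.
#' The rank is evaluated as the dimension of the controllable subspace,
#' grown as an orthonormal block-Krylov basis -- the same subspace the raw
#' controllability matrix spans, without its catastrophic conditioning.
#'
#' @param sys a `line_graph_system` with `D <= 60`.
#' @param result a `controllability_result` for the same system.
#' @param tol numeric-rank tolerance.
#' @return `TRUE` iff the configuration is controllable and minimal in the
#'   single-removal sense.
#' @export
kalman_certificate <- function(sys, result, tol = 1e-8) {
  stopifnot(inherits(sys, "line_graph_system"),
            inherits(result, "controllability_result"))
  if (sys$D > 60L) stop("certificate capped at D <= 60")
  drv <- result$driven_states
  if (length(drv) == 0L) return(sys$D == 0L)
  A <- sys$W - sys$tau[1] * diag(sys$D)
  full <- .kalman_rank(A, drv, tol) == sys$D
  if (!full) return(FALSE)
  for (i in seq_along(drv)) {
    if (length(drv) == 1L) {
      # free system: controllable only if D == 0
      if (sys$D == 0L) return(FALSE)
    } else if (.kalman_rank(A, drv[-i], tol) == sys$D) {
      return(FALSE)
    }
  }
  TRUE
}

# Kalman rank = dim span[B, AB, ..., A^(D-1)B], computed as the dimension of
# the controllable subspace via an orthonormalized block-Krylov basis (the
# raw controllability matrix is far too ill-conditioned for numeric rank
# beyond D ~ 20; the orthonormal recursion spans the same subspace exactly).
.kalman_rank <- function(A, input_states, tol = 1e-7) {
  D <- nrow(A)
  As <- A / max(svd(A, nu = 0, nv = 0)$d, 1)
  Q <- matrix(0, D, 0)
  frontier <- diag(1, D)[, input_states, drop = FALSE]
  while (ncol(frontier) > 0L && ncol(Q) < D) {
    added <- matrix(0, D, 0)
    for (j in seq_len(ncol(frontier))) {
      v <- frontier[, j]
      if (ncol(Q)) {
        v <- v - Q %*% crossprod(Q, v)
        v <- v - Q %*% crossprod(Q, v)  # second pass for stability
      }
      nv <- sqrt(sum(v^2))
      if (nv > tol) {
        v <- v / nv
        Q <- cbind(Q, v)
        added <- cbind(added, v)
      }
    }
    frontier <- if (ncol(added)) As %*% added else matrix(0, D, 0)
  }
  ncol(Q)
}
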