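# Rank primitives.  rank(S_v) is the framework's basic quantity: the number
# of driven outbound edges of node v is k_v^+ - rank(S_v).

# numeric rank via singular values; threshold tol * max(sv) * max(dim)
.numeric_rank <- function(A, tol = 1e-10) {
  if (length(A) == 0L || nrow(A) == 0L || ncol(A) == 0L) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (max(sv) == 0) return(0L)
  sum(sv > tol * max(sv) * max(dim(A)))
}

# generic (structural) rank of a zero/nonzero pattern = size of a maximum
# bipartite matching between rows and columns
.structural_rank <- function(pat) {
  if (length(pat) == 0L || nrow(pat) == 0L || ncol(pat) == 0L) return(0L)
  if (all(pat)) return(min(dim(pat)))
  nz <- which(pat, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(0L)
  nr <- nrow(pat)
  g <- igraph::graph_from_edgelist(cbind(nz[, 1], nr + nz[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nr + ncol(pat) - igraph::vcount(g)))
  types <- c(rep(FALSE, nr), rep(TRUE, ncol(pat)))
  igraph::max_bipartite_match(g, types = types)$matching_size
}

#' Rank of a switching matrix
#'
#' The rank is computed according to the matrix mode: structural matrices use
#' the generic (structural) rank of the nonzero pattern via maximum bipartite
#' matching (`min(k_out, k_in)` for the complete pattern); unweighted
#' matrices use the exact rank of the 0/1 matrix (1 for a complete nonempty
#' pattern); weighted matrices use the numeric rank with singular values
#' above `tol * max(sv) * max(dim)`.  A matrix with a zero dimension has
#' rank 0.
#'
#' @param S a `switching_matrix`.
#' @param tol relative tolerance for numeric rank.
#' @return integer rank.
#' @export
switching_rank <- function(S, tol = 1e-10) {
  stopifnot(inherits(S, "switching_matrix"))
  if (S$k_out == 0L || S$k_in == 0L) return(0L)
  switch(S$mode,
         structural = .structural_rank(S$pattern),
         unweighted = .numeric_rank(S$values * 1, tol),
         weighted   = .numeric_rank(S$values, tol))
}

# greedy selection of an independent row set, scanning rows in the given
# order; returns the kept (independent) row indices
.greedy_independent_rows <- function(mat, order = seq_len(nrow(mat)),
                                     tol = 1e-10) {
  kept <- integer(0)
  r <- 0L
  for (i in order) {
    cand <- mat[c(kept, i), , drop = FALSE]
    if (.numeric_rank(cand, tol) > r) {
      kept <- c(kept, i)
      r <- r + 1L
    }
  }
  sort(kept)
}

# dependent (driven) rows of a switching matrix under a deterministic
# tie-break: rows are scanned in ascending outbound-state order ("first",
# default) and the first rank(S) independent rows are non-essential; the
# reversed scan ("last") exists to assert policy-invariance of driver sets.
.dependent_rows <- function(S, policy = c("first", "last"), tol = 1e-10) {
  policy <- match.arg(policy)
  if (S$k_out == 0L) return(integer(0))
  if (S$k_in == 0L) return(seq_len(S$k_out))
  ord <- seq_len(S$k_out)
  if (policy == "last") ord <- rev(ord)
  kept <- .greedy_independent_rows(S$values, ord, tol)
  setdiff(seq_len(S$k_out), kept)
}
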