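# shared helpers: small random instances and deliberately rank-deficient
# weighted switching values

# random ER instance, directed or undirected, with at least one edge
rand_net <- function(seed, nmax = 20, kmax = 3, directed = NULL) {
  set.seed(seed)
  if (is.null(directed)) directed <- seed %% 2 == 0
  for (try in 1:20) {
    n <- sample(4:nmax, 1)
    net <- gen_er(n, runif(1, 0.5, min(kmax, n - 1)),
                  directed = directed, seed = seed + 1000L * try)
    if (net$M > 0) return(net)
  }
  stop("could not draw a non-empty network")
}

# weighted values: roughly half the nodes get a rank-1 outer product (all
# entries nonzero), the rest a generic matrix -- so weighted ranks sit
# strictly between the unweighted and structural extremes on busy nodes
rand_weighted_values <- function(net, seed) {
  set.seed(seed)
  deg <- degree_profile(net)
  kin <- if (net$directed) deg$k_in else deg$k
  kout <- if (net$directed) deg$k_out else deg$k
  vals <- list()
  for (v in seq_len(net$N)) {
    if (kout[v] == 0 || kin[v] == 0) next
    vals[[net$nodes[v]]] <-
      if (stats::runif(1) < 0.5)
        outer(stats::runif(kout[v], 0.5, 1.5), stats::runif(kin[v], 0.5, 1.5))
      else
        matrix(stats::runif(kout[v] * kin[v], 0.5, 1.5), kout[v], kin[v])
  }
  vals
}

# convenience: engine result for a network under a named mode
run_mode <- function(net, mode, seed = 1L, ...) {
  S <- make_switching_matrices(net, mode, seed = seed, ...)
  edge_controllability(net, S)
}
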