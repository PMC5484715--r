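test_that("degree-only bounds on canonical small networks", {
  chain <- gen_fixture("directed_path", 3)
  b <- degree_bounds(chain)
  expect_equal(c(b$N_D_upper, b$N_D_lower, b$M_D_upper, b$M_D_lower),
               c(1, 1, 1, 1))

  dyad <- gen_fixture("undirected_dyad")
  bd <- degree_bounds(dyad)
  # single undirected edge: one driver at both bounds (beta' = beta'' = 1)
  expect_equal(bd$N_D_upper, 1)
  expect_equal(bd$N_D_lower, 1)
  expect_equal(unname(bound_gap(dyad)$zero_gap), TRUE)

  # undirected lower node bound = number of components containing edges
  net <- gen_er(60, 1.2, directed = FALSE, seed = 9)
  comp <- connected_components(net)
  expect_equal(degree_bounds(net)$N_D_lower, sum(comp$has_edges))
})

test_that("degree bounds equal the engine at both extremes", {
  for (seed in 1:30) {
    net <- rand_net(seed, nmax = 25, kmax = 3.5)
    b <- degree_bounds(net)
    ru <- run_mode(net, "unweighted", seed = seed)
    rs <- run_mode(net, "structural", seed = seed)
    expect_equal(b$N_D_upper, ru$N_D, info = paste("seed", seed))
    expect_equal(b$M_D_upper, ru$M_D, info = paste("seed", seed))
    expect_equal(b$N_D_lower, rs$N_D, info = paste("seed", seed))
    expect_equal(b$M_D_lower, rs$M_D, info = paste("seed", seed))
    expect_true(b$N_D_lower <= b$N_D_upper)
    expect_true(b$M_D_lower <= b$M_D_upper)
  }
})

test_that("SSC labels follow the degree criterion", {
  net <- sbd_network(rbind(cbind(paste0("i", 1:5), "v"), c("v", "o")),
                     directed = TRUE)
  ssc <- ssc_classify(net)
  expect_equal(unname(ssc$labels["v"]), "SSC")  # k_in = 5, k_out = 1

  # k_in = k_out = 2 node is weakly structurally controllable
  net2 <- sbd_network(rbind(c("i1", "v"), c("i2", "v"),
                            c("v", "o1"), c("v", "o2")), directed = TRUE)
  expect_equal(unname(ssc_classify(net2)$labels["v"]), "WSC")

  chain <- gen_fixture("directed_path", 7)
  sc <- ssc_classify(chain)
  expect_true(sc$fully_ssc)
  expect_equal(sc$n_ssc, 1)
  expect_true(bound_gap(chain)$zero_gap)
})

test_that("fully SSC networks always have coinciding bounds", {
  nets <- c(
    lapply(c("fig1_toy", "out_star", "directed_path", "undirected_path",
             "undirected_dyad", "balanced_pair"),
           function(nm) gen_fixture(nm, n = 4)),
    lapply(1:20, rand_net))
  for (net in nets) {
    if (ssc_classify(net)$fully_ssc)
      expect_true(bound_gap(net)$zero_gap,
                  info = paste("N =", net$N, "M =", net$M))
  }
})

test_that("node-level SSC is equivalent to mode-invariant categories", {
  # the biconditional holds per node: a node's driver role and driven-edge
  # count agree between structural and unweighted modes exactly when the
  # node is SSC
  for (seed in 1:12) {
    net <- rand_net(seed)
    ssc <- ssc_classify(net)
    Ss <- make_switching_matrices(net, "structural", seed = seed)
    Su <- make_switching_matrices(net, "unweighted", seed = seed)
    for (v in seq_len(net$N)) {
      cs <- classify_node(Ss[[v]]); cu <- classify_node(Su[[v]])
      same <- cs$role == cu$role && cs$n_driven == cu$n_driven
      expect_equal(same, unname(ssc$labels[v]) == "SSC",
                   info = sprintf("seed %d node %d", seed, v))
    }
  }
})

test_that("a zero bound gap does not by itself imply full SSC", {
  # degenerate witness: undirected 3-path -- the WSC middle node's driven
  # edge migrates with the weights but the totals never move
  p3 <- gen_fixture("undirected_path", 3)
  expect_true(bound_gap(p3)$zero_gap)
  expect_false(ssc_classify(p3)$fully_ssc)
  # directed figure-eight: two cycles sharing one node
  f8 <- sbd_network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                          c("a", "d"), c("d", "e"), c("e", "a")),
                    directed = TRUE)
  expect_true(bound_gap(f8)$zero_gap)
  expect_false(ssc_classify(f8)$fully_ssc)
  # and the engine confirms both extremes coincide on these witnesses
  for (net in list(p3, f8)) {
    expect_equal(run_mode(net, "structural")$M_D,
                 run_mode(net, "unweighted")$M_D)
    expect_equal(run_mode(net, "structural")$N_D,
                 run_mode(net, "unweighted")$N_D)
  }
})

test_that("SSC node categories survive arbitrary re-weighting; WSC do not", {
  net <- rand_net(13, nmax = 12, kmax = 2.5, directed = TRUE)
  deg <- degree_profile(net)
  ssc <- ssc_classify(net)
  base_s <- make_switching_matrices(net, "structural", seed = 1)
  base_u <- make_switching_matrices(net, "unweighted", seed = 1)
  for (v in seq_len(net$N)) {
    if (deg$k_out[v] == 0 || deg$k_in[v] == 0) next
    ref <- classify_node(base_s[[v]])
    if (ssc$labels[v] == "SSC") {
      for (r in 1:50) {
        vals <- list()
        vals[[net$nodes[v]]] <- if (r %% 2 == 0)
          outer(runif(deg$k_out[v], 0.5, 1.5), runif(deg$k_in[v], 0.5, 1.5))
        else matrix(runif(deg$k_out[v] * deg$k_in[v], 0.1, 2),
                    deg$k_out[v], deg$k_in[v])
        Sv <- make_switching_matrices(net, "weighted", seed = r,
                                      values = vals)[[v]]
        got <- classify_node(Sv)
        expect_equal(got$role, ref$role)
        expect_equal(got$n_driven, ref$n_driven)
      }
    } else {
      # structural and unweighted categories must differ for WSC nodes
      cu <- classify_node(base_u[[v]])
      expect_true(ref$role != cu$role || ref$n_driven != cu$n_driven)
    }
  }
})
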