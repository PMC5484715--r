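test_that("every fixture reproduces its documented controllability", {
  fixtures <- list(
    gen_fixture("fig1_toy"),
    gen_fixture("directed_cycle", 4),
    gen_fixture("directed_cycle", 7),
    gen_fixture("out_star", 3),
    gen_fixture("directed_path", 5),
    gen_fixture("undirected_path", 3),
    gen_fixture("undirected_path", 6),
    gen_fixture("undirected_dyad"),
    gen_fixture("balanced_pair"))
  for (net in fixtures) {
    exp <- attr(net, "expected")
    for (mode in names(exp)) {
      res <- run_mode(net, mode, seed = 3)
      expect_equal(res$M_D, as.integer(exp[[mode]]$M_D), info = mode)
      expect_equal(res$N_D, as.integer(exp[[mode]]$N_D), info = mode)
    }
  }
})

test_that("toy network: structural drives only the in-degree-0 node's edge", {
  net <- gen_fixture("fig1_toy")
  res_s <- run_mode(net, "structural")
  res_u <- run_mode(net, "unweighted")
  # node d (no inbound edges, empty switching matrix) is always the driver
  # of its own outgoing edge
  d_state <- which(net$nodes[net$edges[, 1]] == "d")
  expect_equal(res_s$driven_states, d_state)
  expect_equal(res_s$driver_names, "d")
  # unweighted mode adds node a (out-degree 2, rank 1): one of a's two
  # outgoing edges becomes driven as well
  expect_setequal(res_u$driver_names, c("a", "d"))
  a_states <- which(net$nodes[net$edges[, 1]] == "a")
  extra <- setdiff(res_u$driven_states, d_state)
  expect_length(extra, 1)
  expect_true(extra %in% a_states)
})

test_that("out-star: hub with empty switching matrix drives all edges", {
  net <- gen_fixture("out_star", 3)
  res <- run_mode(net, "unweighted")
  expect_equal(res$M_D, 3)
  expect_equal(res$N_D, 1)
  expect_equal(res$driver_names, "hub")
  # the realized line-graph matrix is identically zero
  sys <- assemble_line_graph(net, make_switching_matrices(net, "unweighted"))
  expect_true(all(sys$W == 0))
  expect_equal(exact_controllability_oracle(sys), 3)
})

test_that("balanced components contribute one driver even at full rank", {
  cyc <- gen_fixture("directed_cycle", 4)
  for (mode in c("structural", "unweighted")) {
    S <- make_switching_matrices(cyc, mode, seed = 1)
    comp <- connected_components(cyc)
    expect_equal(component_beta(comp$members[[1]], S, comp$has_edges[1]), 1L)
    res <- edge_controllability(cyc, S)
    expect_equal(res$M_D, 1L)
    expect_equal(res$beta, 1L)
    # the representative is the deterministic lowest-index choice
    expect_equal(res$driver_nodes, 1L)
  }
  # isolated node: no edges, beta = 0
  iso <- sbd_network(rbind(c("a", "b")), directed = TRUE,
                     nodes = c("a", "b", "z"))
  S <- make_switching_matrices(iso, "structural")
  comp <- connected_components(iso)
  cz <- comp$membership[3]
  expect_equal(component_beta(comp$members[[cz]], S, comp$has_edges[cz]), 0L)
})

test_that("node categories follow the degree pattern and mode", {
  mk <- function(k_in, k_out, mode) {
    edges <- rbind(cbind(paste0("i", seq_len(k_in)), "v"),
                   cbind("v", paste0("o", seq_len(k_out))))
    net <- sbd_network(edges, directed = TRUE)
    classify_node(make_switching_matrices(net, mode, seed = 2)[["v"]])
  }
  # balanced node: structural full rank, unweighted rank 1
  c1 <- mk(2, 2, "structural")
  expect_equal(c1$degree_class, "I")
  expect_equal(c1$role, "non-essential")
  expect_equal(c1$n_driven, 0)
  c2 <- mk(2, 2, "unweighted")
  expect_equal(c2$role, "driver")
  expect_equal(c2$n_driven, 1)
  # convergent node (k_in > k_out)
  c3 <- mk(3, 2, "structural")
  expect_equal(c3$degree_class, "II")
  expect_equal(c3$role, "non-essential")
  c4 <- mk(3, 2, "unweighted")
  expect_equal(c4$n_driven, 1)
  # divergent node (k_in < k_out): driver under both, different counts
  c5 <- mk(2, 3, "structural")
  expect_equal(c5$degree_class, "III")
  expect_equal(c5$role, "driver")
  expect_equal(c5$n_driven, 1)
  c6 <- mk(2, 3, "unweighted")
  expect_equal(c6$n_driven, 2)
  expect_equal(unname(c6$edge_roles[c6$edge_roles == "driven"]),
               rep("driven", 2))
})

test_that("result invariants hold on random instances", {
  for (seed in 1:20) {
    net <- rand_net(seed)
    mode <- c("structural", "unweighted", "weighted")[1 + seed %% 3]
    vals <- if (mode == "weighted") rand_weighted_values(net, seed) else NULL
    S <- make_switching_matrices(net, mode, seed = seed, values = vals)
    res <- edge_controllability(net, S)
    D <- if (net$directed) net$M else 2L * net$M
    expect_equal(res$M_D, D - sum(res$ranks) + sum(res$beta))
    expect_equal(res$M_D, length(res$driven_states))
    # every driven state's tail node is a driver
    arcs_tail <- if (net$directed) net$edges[, 1] else {
      lo <- pmin(net$edges[, 1], net$edges[, 2])
      hi <- pmax(net$edges[, 1], net$edges[, 2])
      as.vector(rbind(lo, hi))
    }
    expect_true(all(arcs_tail[res$driven_states] %in% res$driver_nodes))
    expect_true(res$n_D >= 0 && res$n_D <= 1)
    expect_true(res$m_D >= 0 && res$m_D <= 1)
  }
})

test_that("the driver-node set is invariant to the row tie-break policy", {
  for (seed in 1:12) {
    net <- rand_net(seed)
    vals <- rand_weighted_values(net, seed)
    S <- make_switching_matrices(net, "weighted", seed = seed, values = vals)
    r1 <- edge_controllability(net, S, row_policy = "first")
    r2 <- edge_controllability(net, S, row_policy = "last")
    expect_identical(r1$driver_nodes, r2$driver_nodes)
    expect_identical(r1$M_D, r2$M_D)
    expect_identical(r1$N_D, r2$N_D)
    # only which rows are labelled driven may change, never how many per node
    expect_equal(length(r1$driven_states), length(r2$driven_states))
  }
})

test_that("structural <= weighted <= unweighted for M_D and N_D", {
  for (seed in 1:15) {
    net <- rand_net(seed)
    rs <- run_mode(net, "structural", seed = seed)
    ru <- run_mode(net, "unweighted", seed = seed)
    vals <- rand_weighted_values(net, seed)
    rw <- edge_controllability(
      net, make_switching_matrices(net, "weighted", seed = seed,
                                   values = vals))
    expect_true(rs$M_D <= rw$M_D && rw$M_D <= ru$M_D)
    expect_true(rs$N_D <= rw$N_D && rw$N_D <= ru$N_D)
  }
})
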