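# edgectrl

Edge controllability of complex networks under switchboard dynamics.

Many networked systems carry their dynamics on the **edges** rather than the
nodes: signals on the links of a regulatory circuit, packets on internet
connections, trains between stations.  In switchboard dynamics each node
`v` acts as a router: the states of its inbound edges drive the
time-derivatives of its outbound edge states through a **switching matrix**
`S_v` (of shape `k_v^+ x k_v^-` for a directed network, or `k_v x k_v` for an
undirected one after splitting every edge into two opposite arcs).  Written
over all edge states `x` the system is linear,

    dx/dt = (W - T) x + H u,

where `W` is the (transposed) adjacency matrix of the line graph — `W[i, j]`
is nonzero exactly when the head of edge `j` is the tail of edge `i` — `T` is
uniform damping and `H` places external inputs `u` at driver nodes.

`edgectrl` computes, for any directed or undirected network and any mix of
switching-matrix modes (structural = free parameters, unweighted = all ones,
weighted = explicit values):

* the minimum number of **driven edges** over the `D` edge states
  (`D = M` directed, `2M` undirected),

      M_D = D - sum_v rank(S_v) + sum_c beta_c,

  where `beta_c = 1` for components whose switching matrices are all square
  and full-rank (a balanced component needs one driver anyway);
* the unique **driver-node set** `{v : rank(S_v) < k_v^+}` plus one
  representative per balanced component, and `N_D`, `n_D = N_D / N`,
  `m_D = M_D / D`;
* degree-only **upper/lower controllability bounds** (attained by unweighted
  and structural matrices respectively) without computing any rank;
* the **strong structural controllability** classification
  (`SSC` iff `k^+ <= 1` or `k^- <= 1` directed, `k <= 1` undirected) and
  `n_ssc`;
* closed-form **ensemble predictions** of all four bound fractions for
  Erdos-Renyi (Poisson/Skellam and Bessel sums) and scale-free
  (Riemann-zeta sums) degree models;
* independent **verification oracles**: the line-graph rank identity
  `rank(W) = sum_v rank(S_v)`, an eigenvalue-multiplicity driver count, and a
  Kalman controllable-subspace certificate with a minimality spot-check.

## Worked example

The 4-node, 5-edge toy network has one node (`d`) with no inbound edges, so
its switching matrix is empty and its outgoing edge must always be driven.

```r
library(edgectrl)
net <- gen_fixture("fig1_toy")
res_s <- edge_controllability(net, make_switching_matrices(net, "structural"))
res_u <- edge_controllability(net, make_switching_matrices(net, "unweighted"))
res_s
#> <controllability_result> M_D = 1 of 5 states (m_D = 0.2000), N_D = 1 of 4 nodes (n_D = 0.2500)
#>   drivers: d
res_u
#> <controllability_result> M_D = 2 of 5 states (m_D = 0.4000), N_D = 2 of 4 nodes (n_D = 0.5000)
#>   drivers: a, d
degree_bounds(net)
#> <bounds_result> N_D in [1, 2] (n_D [0.2500, 0.5000]), M_D in [1, 2] (m_D [0.2000, 0.4000])
ssc_classify(net)
#> <ssc_report> N_ssc = 3 of 4 (n_ssc = 0.7500)
```

With structural (free-parameter) matrices only `d`'s edge is driven
(`M_D = 1`): that is the lower bound.  With unweighted matrices node `a`
(out-degree 2, rank-1 switching matrix) becomes a second driver (`M_D = 2`):
the upper bound.  The degree-only formulas reproduce both without touching a
single matrix, and `n_ssc = 0.75` says one node (`a`, with
`k^+ = k^- = 2`) can change category as the weights vary.

A command-line wrapper covering analyze/bounds/ssc/sweep/interpolate/generate
is installed at `inst/cli/edgectrl.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "edgectrl.R", package = "edgectrl"))')" \
    analyze mynet.txt --mode structural
```

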