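---
title: "Edge controllability under switchboard dynamics: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge controllability under switchboard dynamics: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgectrl)
```

## The model

Switchboard dynamics places the state variables on the edges of a network
$G(V, E)$.  Node $v$ routes the vector $y_v^-$ of its inbound edge states
into the derivatives of its outbound edge states,

$$\dot y_v^+ = S_v\, y_v^- - \tau \otimes y_v^+ + \sigma_v u_v,$$

through its switching matrix $S_v \in \mathbb{R}^{k_v^+ \times k_v^-}$.
Collecting all edge states into one vector $x$ gives the linear system
$\dot x = (W - T)x + Hu$, where $W$ is the transposed adjacency matrix of
the line graph $L(G)$: $w_{ij} \ne 0$ exactly when the head of edge $j$ is
the tail of edge $i$, and the value of every nonzero is the corresponding
entry of one switching matrix.

For an undirected network the signals travel both ways, so each physical
edge is split into two opposite arcs and the state dimension doubles:
$D = 2M$ instead of $D = M$.  Node $v$'s switching matrix is then square,
$k_v \times k_v$, and couples **all** inbound arcs at $v$ to **all**
outbound arcs at $v$ — including the reverse arc of the same physical edge,
since two arcs of one edge can be each other's input and output.  Arc
indexing is deterministic: edge $e$ (1-based) yields arc $2e-1$ from its
lower-index endpoint to the higher, and arc $2e$ for the reverse.

Three switching-matrix modes are supported.  *Structural* matrices carry
free nonzero parameters; their rank is the generic (structural) rank of the
pattern, computed by maximum bipartite matching, and a seeded numeric
realization drawn i.i.d. on $[0.5, 1.5)$ is stored so that the numeric
oracles can run.  The interval is bounded away from zero so no draw can
silently leave the pattern; on the measure-zero event that a realization's
numeric rank falls below the structural rank it is redrawn (at most five
times, then an error).  *Unweighted* matrices are all ones — the rank of a
complete nonempty pattern collapses to 1.  *Weighted* matrices take
explicit user values, with numeric rank thresholded at
$\text{tol}\cdot\sigma_{\max}\cdot\max(\dim)$, tol $=10^{-10}$ by default.

## The controllability engine

Because any two rows (columns) of $W$ are identical in pattern or have
disjoint support, the rank of $W$ decomposes node by node:
$\operatorname{rank}(W) = \sum_v \operatorname{rank}(S_v)$.  The package
treats this identity strictly as a *tested* property — the engine computes
per-node ranks, and an independent oracle (`line_graph_rank_oracle`)
verifies the assembled $W$ on every instance exercised by the test-suite.

The minimum number of driven edge states is

$$M_D = D - \sum_v \operatorname{rank}(S_v) + \sum_c \beta_c,$$

where $\beta_c = 1$ for a connected component whose switching matrices are
all square with full rank.  Such a balanced component has a full-rank $W$
block, but it still needs one external input because no input attached
elsewhere can reach it.  A node is a driver exactly when
$\operatorname{rank}(S_v) < k_v^+$; the driver set is therefore unique,
up to the one representative chosen in each $\beta = 1$ component.

Determinism replaces every "choose arbitrarily" in the procedure:

* **Driven rows.**  Rows of $S_v$ are scanned in ascending outbound-state
  order with greedy pivoted selection; the first
  $\operatorname{rank}(S_v)$ independent rows are non-essential, the rest
  driven.  The driver-node set is provably independent of this policy, and
  the tests re-run the engine under the reversed scan to assert it.
* **Balanced-component representative.**  The lowest node index with
  outbound states, and its lowest-index outbound state.

For directed networks "connected component" means *weak* component: that is
the convention under which $\sum_c \beta_c$ matches the
eigenvalue-multiplicity oracle on cycles and disjoint unions.

## Verification oracles

Two independent routes check every engine quantity on realized numeric
systems.  The *eigen-multiplicity oracle* decomposes the line graph into
weak components and takes, per component, the maximum geometric
multiplicity over its eigenvalues (at least one input per component).  The
candidate eigenvalue list always includes the damping-shifted zero
explicitly: defective zero eigenvalues of chain-like couplings scatter
numerically under `eigen()`, and without the explicit candidate the
multiplicity at zero is missed.  Eigenvalues are clustered with absolute
tolerance $10^{-8}$ before multiplicities are counted.  Note that the
per-component decomposition of $L(G)$ is compatible with the per-component
$\beta$ accounting on $G$: a balanced full-rank component of $G$ always has
a weakly connected line graph, while components of $G$ whose line graphs
split (for example a hub with no inbound edges) have their extra driven
states accounted for by rank deficiency rather than by $\beta$.

The *Kalman certificate* places one input column per driven state and
checks that the controllable subspace has full dimension, and that removing
any single input breaks it.  The subspace is grown as an orthonormal
block-Krylov basis rather than by ranking the raw controllability matrix
$[B, WB, \dots, W^{D-1}B]$, whose conditioning is hopeless beyond
$D \approx 20$; the orthonormal recursion spans exactly the same space.
Uniform damping only shifts the spectrum, so both oracles operate on
$W - \tau I$ and the tests assert $\tau$-invariance; heterogeneous damping
is refused rather than guessed, since the invariance argument does not
cover it.

## Degree-only bounds and strong structural controllability

Unweighted matrices minimize every $\operatorname{rank}(S_v)$ (to 1) and
structural matrices maximize it (to $\min(k_v^-, k_v^+)$), so the two modes
give the upper and lower bounds of both $M_D$ and $N_D$, and the bounds are
pure functions of the degree sequence:

| quantity | directed | undirected (over $2M$ arc states) |
|---|---|---|
| $N_D^U$ | $N_{(k^+>1)} + N_{(k^-=0,\,k^+=1)} + \sum\beta'$ | $N_{(k>1)} + \sum\beta'$ |
| $N_D^L$ | $N_{(k^-<k^+)} + \sum\beta''$ | $\sum\beta''$ |
| $M_D^U$ | $M - N_{(k^->0,\,k^+>0)} + \sum\beta'$ | $2M - N_{(k>0)} + \sum\beta'$ |
| $M_D^L$ | $M - \sum_v \min(k_v^-,k_v^+) + \sum\beta''$ | $\sum\beta''$ |

with $\beta' = 1$ for components containing only $k^+=k^-=1$ nodes
(directed cycles; undirected single-edge dyads) and $\beta'' = 1$ for
balanced components ($k^+ = k^- > 0$ everywhere; every undirected component
with edges).  The undirected edge formulas are stated over the $2M$ arc
states — the only reading that keeps $M - N_{(k>0)}$ nonnegative on a path
graph and makes the formulas coincide exactly with the engine; $m_D$
accordingly uses denominator $M$ (directed) or $2M$ (undirected).  The
equality of these formulas with the engine under the two extreme modes is
the central cross-module theorem, asserted exactly on hundreds of random
directed and undirected instances.

A node is **strongly structurally controllable** (SSC) when no re-weighting
of its switching matrix can change its category: $k^+ \le 1$ or
$k^- \le 1$ (directed), $k \le 1$ (undirected); all entries of a single row
or column being nonzero pins the rank at 1 regardless of values.  A fully
SSC network always has coinciding upper and lower bounds.  The converse is
*not* true at network level, which the test-suite documents with two
witnesses: the undirected 3-path and two directed cycles sharing a node.
In both, a WSC node's driven edge migrates between nodes as the weights
vary while the network totals $M_D$, $N_D$ never move.  The exact
equivalence holds per node — a node is SSC iff its role and driven-edge
count agree between the structural and unweighted extremes — and that
biconditional is what the tests assert.

## Ensemble analytics

For Erdos-Renyi ensembles with mean degree $\langle k\rangle$ the in- and
out-degrees are independent Poisson variables, giving closed forms for all
four bound fractions; the equal-degree probability is the Skellam mass
$e^{-2\langle k\rangle} I_0(2\langle k\rangle)$ and the expected one-sided
degree surplus is $\sum_{j\ge1} j\, e^{-2\langle k\rangle}
I_j(2\langle k\rangle)$, evaluated with scaled Bessel functions and
truncated when terms drop below $10^{-12}$ (or at index $10^5$).  The
non-monotonic bump in $m_D^U$ at small $\langle k\rangle$ is the
isolated-dyad correction $\sum\beta'$, visible in the sweep output as a
dedicated column.  Undirected lower bounds need the expected
components-per-node fraction $n_{CC}$; `estimate_ncc()` measures it on
seeded generated networks (default), or evaluates the subcritical
tree-component series $\sum_s s^{s-2}(\langle k\rangle
e^{-\langle k\rangle})^s / (\langle k\rangle\, s!)$, valid for
$\langle k\rangle < 1$.

Scale-free ensembles use the pure power law $P(k) = k^{-\gamma}/\zeta(\gamma)$,
$k \ge 1$ (cutoff $\kappa \to \infty$).  Two published identities for this
model are internally inconsistent with the degree model itself, so the
package evaluates the forms that follow from the model and cross-checks
them by brute-force pmf summation in the tests: the ensemble mean degree is
$\zeta(\gamma-1)/\zeta(\gamma)$ (not its reciprocal), and the equal-degree
probability in the lower node bound is $\zeta(2\gamma)/\zeta(\gamma)^2$.
The directed lower edge bound is the double series
$\sum_j j \sum_i i^{-\gamma}(i+j)^{-\gamma}$ normalized by
$\zeta(\gamma)\zeta(\gamma-1)$; the inner sum is evaluated through a
Hurwitz-zeta helper (Euler–Maclaurin, checked against an independent zeta
implementation in the tests) with an integral bound for the truncated tail.
The expected SSC fractions, $1-(1-e^{-\langle k\rangle}-\langle k\rangle
e^{-\langle k\rangle})^2$ (directed) and $(1+\langle k\rangle)
e^{-\langle k\rangle}$ (undirected), are derived from the same Poisson
degree model and accepted through simulation agreement.

## Synthetic networks

`gen_er()` draws every (ordered) pair independently with probability
$\langle k\rangle/(N-1)$, so the realized mean degree is within sampling
error of the target.  `gen_sf()` is a configuration model — Table-style
ensemble predictions assume a given degree distribution, so preferential
attachment would be the wrong generator — with degrees drawn from
$P(k) \propto k^{-\gamma} e^{-k/\kappa}$, $k \ge 1$, in/out sequences drawn
independently (zero in–out correlation by design), sums reconciled by
incrementing random entries of the smaller sequence, and self-loops and
multi-edges repaired by degree-preserving edge switches.  Both generators
are fully seeded: one seed per specification, reproducible edge lists.

What the generated data does *not* emulate: degree correlations,
clustering, community structure, and weighted empirical edge strengths.
Passing tests therefore demonstrate the combinatorial and spectral
machinery, and the ensemble formulas under their stated degree models —
not that any particular real network is well approximated by those models.
Real networks enter through `read_edge_list()`/`read_graphml()`; none are
bundled.

Self-loops and multi-edges are rejected at load: the switchboard routes
between distinct inbound and outbound edges, and the
identical-or-orthogonal column property of $W$ presumes a simple graph.

## Numerical choices and problem sizes

* numeric rank: singular values above $10^{-10}\,\sigma_{\max}\max(\dim)$;
* eigenvalue clustering in the multiplicity oracle: $10^{-8}$ absolute;
* Krylov basis acceptance threshold: $10^{-7}$ after normalization;
* series truncation: terms below $10^{-12}$ or $10^5$ terms;
* the eigen oracle is capped at $D \le 500$ and the Kalman certificate at
  $D \le 60$ — beyond that they stop being trustworthy oracles.

The test-suite exercises the rank identity and bound equivalence on 200
random networks each ($N \le 40$), the oracle cross-check on 100 realized
systems ($D \le 60$), interpolation monotonicity on 100 instances, and the
ensemble-versus-analytics comparison on directed and undirected ER networks
at $N = 10^4$, $\langle k\rangle \in \{1, 2, 4, 8\}$, 10 realizations per
point, with agreement required within 0.01.  The default sweep scale
(`run_sweep`) is $N = 2000$, $R = 10$, configurable upward.

## Known limitations

* Heterogeneous damping is refused, not analyzed.
* The SSC criterion is degree-based; no SSC test for one arbitrary *fixed*
  weighted matrix beyond it.
* No enumeration of alternative driven-edge configurations, no control
  signals $u(t)$, no time integration, no control-energy accounting.
* Finite-cutoff scale-free analytics are not provided; finite $\kappa$ is
  covered by simulation only.
* The interpolation experiment realizes intermediate controllability by
  mixing unweighted and structural nodes; arbitrary targets between the
  bounds may also be reachable through other weight choices not explored
  here.
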