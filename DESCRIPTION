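Package: edgectrl
Title: Edge Controllability of Complex Networks via Switchboard Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the controllability of dynamical processes
    that live on the edges of directed or undirected networks (switchboard
    dynamics).  Each node routes the signals on its inbound edges to the
    time-derivatives of its outbound edge signals through a switching
    matrix; the package computes the minimum number of driven edges and the
    unique driver-node set from the per-node switching-matrix ranks, the
    degree-only upper and lower controllability bounds attained by
    unweighted and structural (free-parameter) switching matrices, the
    strong-structural-controllability classification of nodes, and
    closed-form ensemble predictions for Erdos-Renyi and scale-free
    networks.  Independent line-graph rank, eigenvalue-multiplicity and
    Kalman-rank oracles are included for verification, together with seeded
    network generators and sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
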