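# Seeded synthetic networks: ER, configuration-model scale-free, and the
# small named fixtures used throughout the tests.

#' Generate an Erdos-Renyi random network
#'
#' Directed: every ordered pair of distinct nodes is an edge independently
#' with probability `kmean / (N - 1)`; undirected: every unordered pair with
#' the same probability, so the expected mean (total) degree is `kmean` in
#' both cases.
#'
#' @param N number of nodes (all retained, including isolated ones).
#' @param kmean target mean degree, `0 <= kmean <= N - 1`.
#' @param directed logical.
#' @param seed integer seed; the same spec always yields the same network.
#' @return an [sbd_network] with nodes named `"1" ... "N"`.
#' @export
gen_er <- function(N, kmean, directed = TRUE, seed = 1L) {
  stopifnot(N >= 1, kmean >= 0, kmean <= N - 1)
  p <- if (N > 1) kmean / (N - 1) else 0
  withr::with_seed(as.integer(seed), {
    npairs <- if (directed) N * (N - 1) else N * (N - 1) / 2
    m <- stats::rbinom(1, npairs, p)
    ti <- integer(0); hi <- integer(0)
    if (m > 0) {
      seen <- character(0)
      while (length(ti) < m) {
        need <- m - length(ti)
        a <- sample.int(N, 2L * need, replace = TRUE)
        b <- sample.int(N, 2L * need, replace = TRUE)
        ok <- a != b
        a <- a[ok]; b <- b[ok]
        if (!directed) {
          lo <- pmin(a, b); hi2 <- pmax(a, b)
          a <- lo; b <- hi2
        }
        key <- paste(a, b)
        new <- !(key %in% seen) & !duplicated(key)
        take <- which(new)[seq_len(min(need, sum(new)))]
        ti <- c(ti, a[take]); hi <- c(hi, b[take])
        seen <- c(seen, key[take])
      }
    }
    sbd_network(cbind(as.character(ti), as.character(hi)),
                directed = directed, nodes = as.character(seq_len(N)))
  })
}

# draw N degrees from P(k) propto k^-gamma exp(-k / kappa), k >= 1
.draw_powerlaw_degrees <- function(N, gamma, kappa, kmax) {
  k <- seq_len(kmax)
  logp <- -gamma * log(k) - if (is.finite(kappa)) k / kappa else 0
  p <- exp(logp - max(logp))
  sample(k, N, replace = TRUE, prob = p)
}

#' Generate a scale-free network via the configuration model
#'
#' Degrees are drawn i.i.d. from `P(k) propto k^-gamma exp(-k/kappa)`,
#' `k >= 1` (`kappa = Inf` gives the pure power law); directed in- and
#' out-sequences are drawn independently and reconciled to a common sum by
#' incrementing randomly chosen entries of the smaller sequence.  Stub
#' wiring uses the configuration model with self-loops and multi-edges
#' repaired by degree-preserving edge swaps.
#'
#' @param N number of nodes.
#' @param gamma power-law exponent, > 2.
#' @param kappa exponential cutoff (default `Inf`).
#' @param directed logical.
#' @param seed integer seed.
#' @return an [sbd_network].
#' @export
gen_sf <- function(N, gamma, kappa = Inf, directed = TRUE, seed = 1L) {
  stopifnot(N >= 2, gamma > 2)
  kmax <- max(2L, min(N - 1L, 100000L))
  withr::with_seed(as.integer(seed), {
    if (directed) {
      kout <- .draw_powerlaw_degrees(N, gamma, kappa, kmax)
      kin <- .draw_powerlaw_degrees(N, gamma, kappa, kmax)
      diff <- sum(kout) - sum(kin)
      while (diff != 0) {
        idx <- sample.int(N, abs(diff), replace = TRUE)
        add <- tabulate(idx, nbins = N)
        if (diff > 0) kin <- kin + add else kout <- kout + add
        diff <- sum(kout) - sum(kin)
      }
      g <- igraph::sample_degseq(out.deg = kout, in.deg = kin,
                                 method = "fast.heur.simple")
    } else {
      k <- .draw_powerlaw_degrees(N, gamma, kappa, kmax)
      if (sum(k) %% 2L == 1L) {
        i <- sample.int(N, 1)
        k[i] <- k[i] + 1L
      }
      g <- igraph::sample_degseq(k, method = "fast.heur.simple")
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    sbd_network(cbind(as.character(el[, 1]), as.character(el[, 2])),
                directed = directed, nodes = as.character(seq_len(N)))
  })
}

#' Named fixture networks
#'
#' Small networks with documented expected controllability results, used by
#' the test-suite and examples:
#'
#' * `"fig1_toy"`: directed, 4 nodes `a..d`, 5 edges; node `d` has no
#'   inbound edge, so its switching matrix is empty and its outgoing edge is
#'   always driven; with structural matrices that is the only driven edge
#'   (`M_D = 1`), with unweighted ones a second driven edge appears at the
#'   out-degree-2 node `a` (`M_D = 2`).
#' * `"directed_cycle"`: `n`-cycle, balanced, `M_D = N_D = 1` in all modes.
#' * `"out_star"`: hub with `n` leaves; the hub has no inbound edge, so all
#'   `n` outgoing edges are driven from the single driver.
#' * `"directed_path"`, `"undirected_path"`: chains of `n` nodes.
#' * `"undirected_dyad"`: one undirected edge.
#' * `"balanced_pair"`: two nodes with reciprocal directed edges.
#'
#' @param name fixture name (see above).
#' @param n size parameter where applicable.
#' @return an [sbd_network] with an `expected` attribute: per mode, the
#'   expected `M_D` and `N_D`.
#' @export
gen_fixture <- function(name = c("fig1_toy", "directed_cycle", "out_star",
                                 "directed_path", "undirected_path",
                                 "undirected_dyad", "balanced_pair"),
                        n = 3L) {
  name <- match.arg(name)
  exp2 <- function(ms, ns, mu, nu)
    list(structural = list(M_D = ms, N_D = ns),
         unweighted = list(M_D = mu, N_D = nu))
  net <- switch(name,
    fig1_toy = {
      e <- rbind(c("a", "b"),  # x1
                 c("a", "c"),  # x2
                 c("b", "a"),  # x3
                 c("c", "a"),  # x4
                 c("d", "b"))  # x5
      x <- sbd_network(e, directed = TRUE)
      attr(x, "expected") <- exp2(1L, 1L, 2L, 2L)
      x
    },
    directed_cycle = {
      stopifnot(n >= 2)
      v <- as.character(seq_len(n))
      x <- sbd_network(cbind(v, c(v[-1], v[1])), directed = TRUE)
      attr(x, "expected") <- exp2(1L, 1L, 1L, 1L)
      x
    },
    out_star = {
      stopifnot(n >= 1)
      x <- sbd_network(cbind("hub", paste0("leaf", seq_len(n))),
                       directed = TRUE)
      attr(x, "expected") <- exp2(n, 1L, n, 1L)
      x
    },
    directed_path = {
      stopifnot(n >= 2)
      v <- as.character(seq_len(n))
      x <- sbd_network(cbind(v[-n], v[-1]), directed = TRUE)
      attr(x, "expected") <- exp2(1L, 1L, 1L, 1L)
      x
    },
    undirected_path = {
      stopifnot(n >= 3)
      v <- as.character(seq_len(n))
      x <- sbd_network(cbind(v[-n], v[-1]), directed = FALSE)
      attr(x, "expected") <- exp2(1L, 1L, n - 2L, n - 2L)
      x
    },
    undirected_dyad = {
      x <- sbd_network(rbind(c("a", "b")), directed = FALSE)
      attr(x, "expected") <- exp2(1L, 1L, 1L, 1L)
      x
    },
    balanced_pair = {
      x <- sbd_network(rbind(c("a", "b"), c("b", "a")), directed = TRUE)
      attr(x, "expected") <- exp2(1L, 1L, 1L, 1L)
      x
    })
  net
}
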