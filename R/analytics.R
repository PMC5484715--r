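# Closed-form ensemble predictions for the controllability bounds.
#
# ER networks have independent Poisson in/out degrees with mean <k>; the
# equal-degree probability is the Skellam(0) mass e^{-2k} I_0(2k) and the
# expected one-sided surplus E[(k+ - k-)^+] is sum_j j e^{-2k} I_j(2k).
# Scale-free ensembles use the pure power law P(k) = k^{-gamma} / zeta(gamma)
# (k >= 1, cutoff kappa -> infinity), whose mean is zeta(gamma-1)/zeta(gamma)
# and whose equal-degree probability is zeta(2 gamma)/zeta(gamma)^2.  Both
# SF identities are evaluated from the degree model itself (and cross-checked
# by brute-force pmf summation in the tests) rather than transcribed.

.SERIES_TOL <- 1e-12
.SERIES_MAX <- 1e5

# Hurwitz zeta sum_{n>=0} (a+n)^{-s} for s > 1, via Euler-Maclaurin
.hurwitz_zeta <- function(s, a = 1) {
  stopifnot(s > 1, a > 0)
  K <- 12
  n <- 0:(K - 1)
  x <- a + K
  head <- sum((a + n)^(-s))
  tail <- x^(1 - s) / (s - 1) + x^(-s) / 2 +
    s * x^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * x^(-s - 3) / 720 +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) * x^(-s - 5) / 30240
  head + tail
}

.zeta <- function(s) .hurwitz_zeta(s, 1)

#' Analytic controllability bounds for Erdos-Renyi ensembles
#'
#' Closed-form large-N predictions of the four bound fractions as functions
#' of the mean degree, under Poisson degree statistics.  The undirected
#' formulas need the expected fraction of components per node `n_cc` (see
#' [estimate_ncc()]).
#'
#' @param kmean mean degree, >= 0 (directed: mean in-degree = mean
#'   out-degree).
#' @param directed logical.
#' @param n_cc components-per-node fraction, required when
#'   `directed = FALSE`.
#' @return named list `n_D_upper`, `n_D_lower`, `m_D_upper`, `m_D_lower`.
#' @export
er_bounds <- function(kmean, directed = TRUE, n_cc = NULL) {
  stopifnot(length(kmean) == 1L, kmean >= 0)
  k <- kmean
  if (directed) {
    nU <- 1 - (k + 1) * exp(-k) + k * exp(-2 * k)
    nL <- 0.5 * (1 - besselI(2 * k, 0, expon.scaled = TRUE))
    if (k > 0) {
      mU <- 1 - (1 - exp(-k))^2 / k
      j <- 1
      s <- 0
      repeat {
        term <- j * besselI(2 * k, j, expon.scaled = TRUE)
        s <- s + term
        if (term < .SERIES_TOL || j >= .SERIES_MAX) break
        j <- j + 1
      }
      mL <- s / k
    } else {
      mU <- 0; mL <- 0
    }
  } else {
    if (is.null(n_cc)) stop("undirected ER bounds require n_cc")
    nU <- 1 - (k + 1) * exp(-k) + (k / 2) * exp(-2 * k)
    nL <- n_cc - exp(-k)
    if (k > 0) {
      mU <- 1 - (1 - exp(-k)) / k + 0.5 * exp(-2 * k)
      mL <- (n_cc - exp(-k)) / k
    } else {
      mU <- 0; mL <- 0
    }
  }
  list(n_D_upper = nU, n_D_lower = max(0, nL),
       m_D_upper = mU, m_D_lower = max(0, mL))
}

#' Analytic controllability bounds for scale-free ensembles
#'
#' Pure power-law degree model `P(k) = k^-gamma / zeta(gamma)`, `k >= 1`
#' (infinite cutoff).  The directed lower edge bound is the normalized
#' double series `sum_j j sum_i i^-gamma (i+j)^-gamma`, evaluated with a
#' Hurwitz-zeta inner sum and an integral tail estimate.
#'
#' @param gamma power-law exponent, > 2.
#' @param directed logical.
#' @param n_cc components-per-node fraction, required for the undirected
#'   lower bounds.
#' @return named list `n_D_upper`, `n_D_lower`, `m_D_upper`, `m_D_lower`,
#'   plus `kmean` (the ensemble mean degree `zeta(gamma-1)/zeta(gamma)`).
#' @export
sf_bounds <- function(gamma, directed = TRUE, n_cc = NULL) {
  stopifnot(length(gamma) == 1L)
  if (gamma <= 2) stop("gamma must exceed 2 for a convergent mean degree")
  zg <- .zeta(gamma); zg1 <- .zeta(gamma - 1)
  kmean <- zg1 / zg
  if (directed) {
    nU <- 1 - 1 / zg
    nL <- 0.5 - .zeta(2 * gamma) / (2 * zg^2)
    mU <- 1 - zg / zg1
    # S = sum_i i^-gamma * sum_{s>i} (s - i) s^-gamma
    S <- 0; i <- 1
    repeat {
      term <- i^(-gamma) *
        (.hurwitz_zeta(gamma - 1, i + 1) - i * .hurwitz_zeta(gamma, i + 1))
      S <- S + term
      if ((term < .SERIES_TOL && i > 10) || i >= .SERIES_MAX) {
        # integral tail bound for the remaining i terms
        S <- S + term * i / max(1, 2 * gamma - 3)
        break
      }
      i <- i + 1
    }
    mL <- S / (zg * zg1)
  } else {
    if (is.null(n_cc)) stop("undirected SF bounds require n_cc")
    nU <- 1 - 1 / zg + 1 / (2 * zg * zg1)
    nL <- n_cc
    mU <- 1 - zg / zg1 + 1 / (2 * zg1^2)
    mL <- n_cc / kmean
  }
  list(n_D_upper = nU, n_D_lower = nL, m_D_upper = mU, m_D_lower = mL,
       kmean = kmean)
}

#' Expected fraction of strongly structurally controllable nodes
#'
#' Under Poisson degree statistics a node is WSC only when both its
#' in-degree and out-degree exceed 1 (directed) or its degree exceeds 1
#' (undirected), giving
#' `n_ssc = 1 - (1 - e^-k - k e^-k)^2` (directed, independent in/out) and
#' `n_ssc = (1 + k) e^-k` (undirected).
#'
#' @param kmean mean degree >= 0.
#' @param directed logical.
#' @return expected `n_ssc` fraction.
#' @export
expected_ssc_fraction <- function(kmean, directed = TRUE) {
  stopifnot(kmean >= 0)
  k <- kmean
  if (directed) 1 - (1 - exp(-k) - k * exp(-k))^2 else (1 + k) * exp(-k)
}

#' Expected components-per-node fraction of undirected ER networks
#'
#' `n_cc` is the expected number of connected components (isolated nodes
#' included) divided by N.  The default empirical method averages over
#' seeded generated networks; the series method uses the subcritical
#' tree-component series `sum_s s^(s-2) (k e^-k)^s / (k s!)`, valid for
#' `kmean < 1`.
#'
#' @param kmean mean degree >= 0.
#' @param method `"empirical"` or `"series"`.
#' @param N network size for the empirical method.
#' @param R realizations for the empirical method.
#' @param seed RNG seed for the empirical method.
#' @return estimated `n_cc` fraction.
#' @export
estimate_ncc <- function(kmean, method = c("empirical", "series"),
                         N = 10000L, R = 10L, seed = 1L) {
  stopifnot(kmean >= 0)
  method <- match.arg(method)
  if (kmean == 0) return(1)
  if (method == "series") {
    if (kmean >= 1)
      warning("tree-component series is only valid for kmean < 1")
    s <- 1:1000
    lterm <- (s - 2) * log(s) + s * (log(kmean) - kmean) - log(kmean) -
      lfactorial(s)
    return(sum(exp(lterm)))
  }
  vals <- vapply(seq_len(R), function(r) {
    net <- gen_er(N, kmean, directed = FALSE, seed = seed + r - 1L)
    connected_components(net)$n_components / N
  }, numeric(1))
  mean(vals)
}
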