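#' Monomolecular reaction networks
#'
#' A monomolecular network has reactions with at most one reactant and one
#' product, `A_i -> A_j` with rate `k_ji`; production and degradation are
#' encoded through a sink/source pseudo-species. Its kinetics
#' `dc/dt = K0 + K c` is solved exactly by eigen-decomposition of the rate
#' matrix.
#'
#' @param n Number of species.
#' @param edges Data frame with columns `from`, `to` (1-based species
#'   indices; 0 denotes the sink/source pseudo-species) and `k` (> 0).
#' @param c0 Initial concentrations (length `n`).
#' @return An object of class `mono_network`.
#' @examples
#' net <- mono_network(2, data.frame(from = 1, to = 2, k = 1), c0 = c(1, 0))
#' sol <- solve_monomolecular(net)
#' sol$evaluate(1)   # c_B(1) = 1 - exp(-1)
#' @export
mono_network <- function(n, edges, c0 = rep(0, n)) {
  stopifnot(n >= 1, is.data.frame(edges),
            all(c("from", "to", "k") %in% names(edges)),
            length(c0) == n, all(c0 >= 0))
  if (any(edges$k < 0) || any(!is.finite(edges$k)))
    stop("rate constants must be finite and nonnegative")
  if (any(edges$from > n | edges$to > n | edges$from < 0 | edges$to < 0))
    stop("edge endpoints out of range")
  structure(list(n = n, edges = edges, c0 = c0), class = "mono_network")
}

network_matrices <- function(net) {
  K <- matrix(0, net$n, net$n)
  K0 <- numeric(net$n)
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]; k <- net$edges$k[i]
    if (f == 0) {                       # production
      K0[t] <- K0[t] + k
    } else if (t == 0) {                # degradation
      K[f, f] <- K[f, f] - k
    } else {
      K[f, f] <- K[f, f] - k
      K[t, f] <- K[t, f] + k
    }
  }
  list(K = K, K0 = K0)
}

#' Exact eigen-solution of a monomolecular network
#'
#' Computes eigenvalues with left/right eigenvectors normalized to
#' biorthonormality, the steady state, and an `evaluate(t)` function
#' implementing `c(t) = c_s + sum_i r^i (l^i, c(0) - c_s) exp(lambda_i t)`.
#' Defective rate matrices (repeated eigenvalues without a full
#' eigenbasis) trigger a fallback to numerical propagation, with a
#' warning.
#'
#' @param net A `mono_network`.
#' @return List with `eigenvalues`, `right`, `left` (matrices of column
#'   vectors), `steady_state`, `evaluate`, and `method`
#'   (`"eigen"`/`"numeric"`).
#' @export
solve_monomolecular <- function(net) {
  stopifnot(inherits(net, "mono_network"))
  mats <- network_matrices(net)
  K <- mats$K; K0 <- mats$K0
  eg <- eigen(K)
  V <- eg$vectors
  defective <- abs(det(V)) < 1e-12 || !is.finite(rcond(V)) ||
    rcond(V) < 1e-12
  if (defective) {
    warning("rate matrix is defective or near-defective; ",
            "falling back to numerical propagation")
    evaluate <- function(t) {
      f <- function(tt, y, parms) list(K0 + K %*% y)
      out <- deSolve::lsoda(net$c0, c(0, sort(unique(t))), f,
                            rtol = 1e-10, atol = 1e-12)
      res <- out[match(t, out[, 1]), -1, drop = FALSE]
      if (length(t) == 1L) res <- drop(res)
      res
    }
    return(list(eigenvalues = eg$values, right = V, left = NULL,
                steady_state = NULL, evaluate = evaluate,
                method = "numeric"))
  }
  L <- solve(V)                         # rows are left eigenvectors
  # steady state: solve K cs = -K0 on the range; for closed systems
  # (singular K, zero K0) take the kernel mode scaled to the conserved
  # totals of c0
  lam <- eg$values
  zero <- abs(lam) < 1e-10 * max(abs(lam), 1)
  if (any(zero)) {
    if (any(abs(K0) > 0))
      stop("production fluxes with a singular rate matrix: ",
           "no finite steady state")
    cs <- numeric(net$n)
    for (i in which(zero)) {
      ri <- Re(V[, i]); li <- Re(L[i, ])
      cs <- cs + ri * sum(li * net$c0)
    }
  } else {
    cs <- as.numeric(solve(K, -K0))
  }
  evaluate <- function(t) {
    dev0 <- net$c0 - cs
    coef <- L %*% dev0
    res <- vapply(t, function(tt)
      Re(cs + as.numeric(V %*% (coef * exp(lam * tt)))), numeric(net$n))
    if (length(t) == 1L) drop(res) else t(res)
  }
  list(eigenvalues = lam, right = V, left = t(L),
       steady_state = Re(cs), evaluate = evaluate, method = "eigen")
}

#' Limiting-step analysis of an irreversible chain
#'
#' For a chain `A1 -> A2 -> ... -> An` with rates `k_1..k_{n-1}` and a
#' separated smallest constant `k_q`, the relaxation time is `1/k_q`; on
#' time scales beyond it the species `A_1..A_q` lump into a single pool
#' (left vector with ones on positions 1..q) that decays into `A_n`
#' (slow right eigenvector `e_q - e_n`), and the steady state holds all
#' mass at the chain end.
#'
#' @param k Rates `k_1..k_{n-1}` (> 0).
#' @param sep Required separation of the minimum (default 10); an
#'   ambiguity error lists near-ties when violated.
#' @return List with `tau`, `q` (limiting position),
#'   `lumped_left_vector`, `slow_right_vector`, `steady_state` (unit
#'   total).
#' @examples
#' chain_analysis(c(10, 0.1, 10))   # tau = 10, lump (1,1,0,0)
#' @export
chain_analysis <- function(k, sep = 10) {
  stopifnot(is.numeric(k), all(k > 0), length(k) >= 1)
  n <- length(k) + 1L
  q <- which.min(k)
  others <- k[-q]
  if (length(others) && min(others) < sep * k[q]) {
    ties <- which(k < sep * k[q] & seq_along(k) != q)
    stop("no separated limiting step: k[", q, "] = ", k[q],
         " is within a factor ", sep, " of k[",
         paste(ties, collapse = ", "), "]")
  }
  lump <- c(rep(1, q), rep(0, n - q))
  slow <- numeric(n); slow[q] <- 1; slow[n] <- -1
  ss <- c(rep(0, n - 1), 1)
  list(tau = 1 / k[q], q = q, lumped_left_vector = lump,
       slow_right_vector = slow, steady_state = ss)
}

#' Limiting-step analysis of an irreversible catalytic cycle
#'
#' For the cycle `A1 -> A2 -> ... -> An -> A1` with conserved total `b`:
#' the exact stationary rate is `w = b / sum(1/k_i)` with stationary
#' concentrations `c_i = w/k_i` (the harmonic-mean law). When one constant
#' `k_min` is much smaller than the rest, the cycle has a limiting step:
#' `w ~ k_min * b`, the zero-order steady state collects all mass at the
#' reactant of the slowest step, the nonzero eigenvalues approach the
#' negated non-limiting constants, and the relaxation time is set by the
#' second-slowest constant, `tau = 1/k_tau`. Without separation (e.g. all
#' `k_i` equal) the eigenvalues are complex — damped oscillations — and
#' the limiting-step approximation is refused (approximate fields `NA`,
#' `limiting = FALSE`).
#'
#' @param k Cycle rates `k_1..k_n` (> 0).
#' @param b Conserved total (> 0).
#' @param sep Separation factor required for the limiting-step outputs.
#' @return List with `w_exact`, `c_exact`, `eigen_exact`, and (when
#'   separated) `w_limiting`, `c_zero_order`, `eigen_approx`, `tau`,
#'   `k_tau`, plus logical `limiting` and `oscillatory`.
#' @examples
#' cycle_analysis(c(100, 10000, 1), b = 1)
#' @export
cycle_analysis <- function(k, b = 1, sep = 10) {
  stopifnot(is.numeric(k), all(k > 0), length(k) >= 2, b > 0)
  n <- length(k)
  w <- b / sum(1 / k)
  c_exact <- w / k
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    K[i, i] <- K[i, i] - k[i]
    K[j, i] <- K[j, i] + k[i]
  }
  lam <- eigen(K, only.values = TRUE)$values
  lam <- lam[order(abs(lam))]
  oscillatory <- any(abs(Im(lam)) > 1e-9 * max(abs(lam)))
  i_min <- which.min(k)
  others <- k[-i_min]
  separated <- min(others) >= sep * k[i_min]
  if (!separated) {
    return(list(w_exact = w, c_exact = c_exact, eigen_exact = lam,
                w_limiting = NA_real_, c_zero_order = NULL,
                eigen_approx = NULL, tau = NA_real_, k_tau = NA_real_,
                limiting = FALSE, oscillatory = oscillatory))
  }
  czero <- numeric(n); czero[i_min] <- b
  k_tau <- min(others)
  list(w_exact = w, c_exact = c_exact, eigen_exact = lam,
       w_limiting = k[i_min] * b, c_zero_order = czero,
       eigen_approx = -others, tau = 1 / k_tau, k_tau = k_tau,
       limiting = TRUE, oscillatory = oscillatory)
}

#' Quasi-steady-state and quasiequilibrium reductions of S + E <-> SE -> P
#'
#' The canonical enzyme mechanism with association/dissociation rates
#' `kappa_plus`, `kappa_minus` and catalytic rate `k2` under two classical
#' reductions:
#'
#' * QSS (`bE << bS`): the intermediates balance instantaneously, giving
#'   the Michaelis-Menten rate `k2*bE*cS/(cS + K_M)` with
#'   `K_M = (kappa_minus + k2)/kappa_plus`.
#' * QE (fast first equilibrium): the bound fraction solves the quadratic
#'   quasiequilibrium manifold equation in the slow variable
#'   `Cs = cS + cSE`, and the slow kinetics is `dCs/dt = -k2 cSE(Cs)`.
#'
#' @param bS,bE Total substrate and enzyme pools.
#' @param kappa_plus,kappa_minus Binding/unbinding rates.
#' @param k2 Catalytic rate.
#' @return List with `K_M`, `qss_rate(cS)`, `qe_cSE(Cs)`,
#'   `qe_reduced_ode(Cs)`, and `full_trajectory(times)` integrating the
#'   unreduced three-species system (cS, cE, cSE, cP) from free pools.
#' @export
qe_qss_demo <- function(bS, bE, kappa_plus, kappa_minus, k2) {
  stopifnot(bS > 0, bE > 0, kappa_plus > 0, kappa_minus >= 0, k2 > 0)
  if (bE >= bS / 10)
    warning("bE is not small against bS; the QSS reduction is not ",
            "expected to be accurate")
  K_M <- (kappa_minus + k2) / kappa_plus
  qss_rate <- function(cS) k2 * bE * cS / (cS + K_M)
  Keq <- kappa_plus / kappa_minus
  qe_cSE <- function(Cs) {
    # kappa_plus * cS * cE = kappa_minus * cSE on the manifold,
    # cS = Cs - cSE, cE = bE - cSE -> quadratic in cSE
    a <- kappa_plus
    bq <- -(kappa_plus * (Cs + bE) + kappa_minus)
    cq <- kappa_plus * Cs * bE
    (-bq - sqrt(bq^2 - 4 * a * cq)) / (2 * a)
  }
  qe_reduced_ode <- function(Cs) -k2 * qe_cSE(Cs)
  full_trajectory <- function(times) {
    f <- function(t, y, parms) {
      v_bind <- kappa_plus * y[1] * y[2] - kappa_minus * y[3]
      v_cat <- k2 * y[3]
      list(c(-v_bind, -v_bind + v_cat, v_bind - v_cat, v_cat))
    }
    out <- deSolve::lsoda(c(cS = bS, cE = bE, cSE = 0, cP = 0), times, f,
                          rtol = 1e-10, atol = 1e-12)
    as.data.frame(out)
  }
  list(K_M = K_M, qss_rate = qss_rate, qe_cSE = qe_cSE,
       qe_reduced_ode = qe_reduced_ode, full_trajectory = full_trajectory)
}
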