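#' Regime ratio beta of the non-linear model
#'
#' The critical parameter combination
#' `beta = k2 * [eIF4F]0 / (k4 * [60S]0)` compares the maximal initiation
#' flux (`k2*[eIF4F]0`, every initiation factor engaged and scanning) with
#' the maximal ribosome-recycling flux (`k4*[60S]0`, every 60S engaged in
#' elongation). `beta > 1` is the "efficient initiation" regime in which
#' subunit recycling limits protein synthesis; `beta < 1` is the
#' "inefficient initiation" regime in which initiation-factor recycling
#' limits it.
#'
#' @param p A `nonlinear_params` object.
#' @return Dimensionless ratio.
#' @examples
#' beta(nonlinear_params(2, 2, 5, 1))      # 0.48
#' beta(nonlinear_params(2, 2, 5, 0.1))    # 4.8
#' beta(nonlinear_params(2, 3, 50, 0.1))   # 7.2
#' @export
beta <- function(p) {
  stopifnot(inherits(p, "nonlinear_params"))
  p$k2 * p$total_eIF4F / (p$k4 * p$total_60S)
}

#' Classify the initiation regime
#'
#' @param p A `nonlinear_params` object.
#' @param boundary_band Half-width of the band around `beta = 1` flagged as
#'   near-degenerate (asymptotic formulas are not trusted there).
#' @return `"efficient"` or `"inefficient"`, with logical attribute
#'   `"boundary"` set when `|beta - 1| < boundary_band`.
#' @export
classify_regime <- function(p, boundary_band = 0.05) {
  b <- beta(p)
  structure(if (b > 1) "efficient" else "inefficient",
            boundary = abs(b - 1) < boundary_band)
}

# Steady-state species given the free-60S fraction x and the common flux
# w = k4*(1-x)*[60S]0.  Used both by the exact solver and by root
# admissibility checks.
steady_from_x <- function(x, p) {
  w <- p$k4 * (1 - x) * p$total_60S
  c60S <- x * p$total_60S
  cAUG <- if (x > 0) w / (p$k3 * c60S) else Inf
  c_mRNA40S <- w / p$k2
  c_eIF4F <- p$total_eIF4F - c_mRNA40S
  c40S <- if (c_eIF4F > 0) w / (p$k1 * c_eIF4F) else Inf
  c(c40S = c40S, c60S = c60S, c_eIF4F = c_eIF4F,
    c_mRNA40S = c_mRNA40S, cAUG = cAUG, c80S = (1 - x) * p$total_60S,
    w = w)
}

#' Exact steady state of the non-linear model
#'
#' At steady state all four fluxes are equal to a common rate `w`, and the
#' conservation laws close the system. Writing `x = [60S]s/[60S]0` gives
#' `w = k4*(1-x)*[60S]0` and every other species by back-substitution; the
#' 40S conservation law becomes a scalar equation in `x` on (0, 1], which
#' is solved by bracketed root finding ([stats::uniroot]) to high precision.
#' Candidate roots yielding negative `[eIF4F]s` or `[40S]s` are rejected.
#'
#' @param p A `nonlinear_params` object.
#' @param xtol Root-finding tolerance on `x`.
#' @return An object of class `steady_state` with elements `x` (free-60S
#'   fraction), `concentrations` (named vector), `prsynth` (steady protein
#'   synthesis rate), `regime`, and `source = "exact_rootfind"`.
#' @examples
#' ss <- steady_state_exact(nonlinear_params(2, 2, 5, 1))
#' ss$prsynth
#' @export
steady_state_exact <- function(p, xtol = 1e-12) {
  stopifnot(inherits(p, "nonlinear_params"))
  # residual of the 40S conservation law as a function of x; +Inf where the
  # back-substitution leaves the physical domain (so the root is bracketed
  # on the admissible side)
  fx <- function(x) {
    s <- steady_from_x(x, p)
    if (!is.finite(s[["c40S"]]) || s[["c_eIF4F"]] <= 0) return(Inf)
    s[["c40S"]] + s[["c_mRNA40S"]] + s[["cAUG"]] + s[["c80S"]] - p$total_40S
  }
  # The residual is monotone decreasing in x on the physical branch and
  # diverges to +Inf at the left edge of the admissible domain
  # (x_min = max(0, 1 - beta): below it [eIF4F]s <= 0); at x = 1 the flux
  # vanishes and the residual is -total_40S < 0.
  xmin <- max(0, 1 - beta(p))
  lo <- NA_real_
  for (eps in 10^seq(-14, -0.5, by = 0.5)) {
    cand <- xmin + (1 - xmin) * eps
    fc <- fx(cand)
    if (is.finite(fc) && fc > 0) { lo <- cand; flo <- fc; break }
  }
  hi <- 1
  if (!is.finite(lo))
    stop("no admissible steady state in (0, 1]: flux balance cannot close ",
         "the 40S conservation law for these parameters")
  root <- stats::uniroot(fx, c(lo, hi), tol = xtol)
  x <- root$root
  s <- steady_from_x(x, p)
  conc <- s[nonlinear_species]
  r <- nonlinear_rhs(conc, p)
  structure(list(x = x, concentrations = conc, prsynth = s[["w"]],
                 regime = as.character(classify_regime(p)),
                 source = "exact_rootfind",
                 flux_residual = max(abs(diff(r$fluxes))) /
                   max(r$fluxes, .Machine$double.eps)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s): x = %.6g, Prsynth = %.6g [%s]\n",
              x$regime, x$x, x$prsynth, x$source))
  print(signif(x$concentrations, 6))
  invisible(x)
}

#' Dimensionless coefficients of the steady-state cubic
#'
#' Neglecting terms of smaller order under the standard parameter ordering,
#' the flux-balance equation for the free-60S fraction `x` reduces to the
#' cubic (written in factored form)
#' `alpha*x*(1-x) + (1-x-delta)*x*(x+beta-1) + gamma*(1-x)*(x+beta-1) = 0`
#' with `alpha = k2/(k1*[60S]0)`, `beta = k2*[eIF4F]0/(k4*[60S]0)`,
#' `gamma = k4/(k3*[60S]0)`, `delta = [40S]0/[60S]0`. Under the ordering
#' assumptions `delta > 1` and `gamma << 1`, and `alpha << beta` whenever
#' `k1 >> k4/[eIF4F]0`; warnings are emitted when these fail.
#'
#' @param p A `nonlinear_params` object.
#' @return List with `alpha`, `beta`, `gamma`, `delta`, the expanded
#'   monomial coefficients (`x^3 + c2*x^2 + c1*x + c0`), and `params`.
#' @export
cubic_coeffs <- function(p) {
  stopifnot(inherits(p, "nonlinear_params"))
  a <- p$k2 / (p$k1 * p$total_60S)
  b <- beta(p)
  g <- p$k4 / (p$k3 * p$total_60S)
  d <- p$total_40S / p$total_60S
  if (d <= 1) warning("delta <= 1: 40S pool is not the largest; ",
                      "the reduced cubic may be inaccurate")
  if (g >= 0.1) warning("gamma is not small; the reduced cubic may be ",
                        "inaccurate")
  if (a >= b) warning("alpha >= beta (k1 <= k4/[eIF4F]0, weak-initiation ",
                      "regime); the reduced cubic may be inaccurate")
  # expand -(cubic) so the leading monomial is +x^3:
  # x^3 + (alpha+beta+gamma+delta-2) x^2
  #     - (alpha + (1-delta)(beta-1) + gamma(2-beta)) x - gamma(beta-1)
  list(alpha = a, beta = b, gamma = g, delta = d,
       c2 = a + b + g + d - 2,
       c1 = -(a + (1 - d) * (b - 1) + g * (2 - b)),
       c0 = -g * (b - 1),
       params = p)
}

#' Approximate roots of the steady-state cubic
#'
#' Returns the three candidate free-60S fractions: `x0`, close to zero
#' (dominant balance of the linear and constant terms, the efficient-regime
#' root), and `x1 >= x2` from the quadratic factor (the inefficient-regime
#' root and an always-negative companion). The admissible root is selected
#' by positivity of the back-substituted `[eIF4F]s` and `[40S]s` and by the
#' requirement `x` in (0, 1].
#'
#' @param p A `nonlinear_params` object.
#' @return List with `coeffs` (from [cubic_coeffs()]), `x0`, `x1`, `x2`,
#'   `admissible` (`"x0"` or `"x1"`), and `x` (the admissible value).
#'   If neither approximate root is admissible the exact solver is used as
#'   a fallback (with a warning) and `admissible = "exact"`.
#' @export
cubic_roots <- function(p) {
  cf <- cubic_coeffs(p)
  # x0 from the dominant balance c1*x + c0 = 0 of the full cubic
  x0 <- -cf$c0 / cf$c1
  # x1, x2 from the quadratic factor obtained by deflating x0:
  # x^2 + (c2 + x0) x + (c1 + x0*(c2 + x0))
  pq <- cf$c2 + x0
  qq <- cf$c1 + x0 * pq
  disc <- pq^2 - 4 * qq
  if (disc >= 0) {
    x1 <- (-pq + sqrt(disc)) / 2
    x2 <- (-pq - sqrt(disc)) / 2
  } else {
    x1 <- x2 <- NA_real_
  }
  admissible_x <- function(x) {
    if (!is.finite(x) || x <= 0 || x > 1) return(FALSE)
    s <- steady_from_x(x, p)
    is.finite(s[["c40S"]]) && s[["c_eIF4F"]] > 0 && s[["c40S"]] > 0 &&
      s[["c40S"]] <= p$total_40S
  }
  adm <- c(x0 = admissible_x(x0), x1 = admissible_x(x1))
  if (adm[["x1"]]) {
    choice <- "x1"; x <- x1
  } else if (adm[["x0"]]) {
    choice <- "x0"; x <- x0
  } else {
    warning("neither approximate cubic root is admissible; ",
            "falling back to the exact solver")
    x <- steady_state_exact(p)$x
    choice <- "exact"
  }
  list(coeffs = cf, x0 = x0, x1 = x1, x2 = x2,
       admissible = choice, x = x)
}

#' Approximate steady state from the cubic
#'
#' Convenience wrapper: back-substitutes the admissible cubic root into the
#' steady-state relations.
#'
#' @param p A `nonlinear_params` object.
#' @return A `steady_state` object with `source = "cubic_x0"`/`"cubic_x1"`.
#' @export
steady_state_cubic <- function(p) {
  r <- cubic_roots(p)
  if (r$admissible == "exact") return(steady_state_exact(p))
  s <- steady_from_x(r$x, p)
  structure(list(x = r$x, concentrations = s[nonlinear_species],
                 prsynth = s[["w"]],
                 regime = as.character(classify_regime(p)),
                 source = paste0("cubic_", r$admissible)),
            class = "steady_state")
}

#' Closed-form steady protein synthesis rate
#'
#' Under the ordering assumptions the steady rate is set by whichever
#' recycling flux is limiting:
#' `Prsynth_s ~ min(k2*[eIF4F]0, k4*[60S]0)` — initiation-factor recycling
#' in the inefficient regime (`beta < 1`), ribosomal-subunit recycling in
#' the efficient regime (`beta > 1`). The fastest constant `k3` never
#' appears: it is not a critical parameter in either scenario, and `k1`
#' enters only through its competition for eIF4F (neglected here).
#'
#' @param p A `nonlinear_params` object.
#' @return Steady protein synthesis rate (model units).
#' @export
steady_protein_rate <- function(p) {
  stopifnot(inherits(p, "nonlinear_params"))
  min(p$k2 * p$total_eIF4F, p$k4 * p$total_60S)
}

#' Polysome-size proxy
#'
#' The number of ribosomes engaged on mRNA (up to the implicit mRNA
#' concentration folded into the rate constants) is the bound-ribosome load
#' `[mRNA:40S]s + [AUG]s + [80S]s`. Because `k4` is the slowest constant the
#' load is dominated by `[80S]s = Prsynth_s/k4`, so the polysome proxy moves
#' monotonically with the steady protein synthesis rate under any
#' single-parameter inhibition that leaves `k4` fixed.
#'
#' @param p A `nonlinear_params` object.
#' @param ss Optional precomputed `steady_state` (exact solve by default).
#' @return Dimensionless bound-ribosome load.
#' @export
polysome_proxy <- function(p, ss = steady_state_exact(p)) {
  cc <- ss$concentrations
  unname(cc["c_mRNA40S"] + cc["cAUG"] + cc["c80S"])
}

#' Regime-flip thresholds for k4 and k2
#'
#' Solving `beta = 1` for one rate with the others fixed gives the
#' inhibition thresholds at which microRNA action on that step switches the
#' initiation scenario (and hence starts, or stops, affecting the steady
#' rate directly): `k4* = k2*[eIF4F]0/[60S]0` and
#' `k2* = k4*[60S]0/[eIF4F]0`.
#'
#' @param p A `nonlinear_params` object.
#' @return List with `k4_threshold` and `k2_threshold`.
#' @export
critical_thresholds <- function(p) {
  stopifnot(inherits(p, "nonlinear_params"))
  list(k4_threshold = p$k2 * p$total_eIF4F / p$total_60S,
       k2_threshold = p$k4 * p$total_60S / p$total_eIF4F)
}
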