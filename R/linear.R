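#' Closed-form analytics of the linear translation cycle
#'
#' When elongation is fast (`k3 >> k1, k2`) the three-species cycle
#' relaxes on two time scales: a fast elongation scale `~1/k3` on which
#' `[AUG]` equilibrates, and a slow initiation scale on which `[40S]` and
#' `[mRNA:40S]` exchange with relaxation time `1/(k1 + k2)`. The slow
#' subsystem has the closed-form solution
#' \deqn{[40S](t) = [40S]_0 (k_2 + k_1 e^{-(k_1+k_2)t})/(k_1+k_2)}
#' \deqn{[mRNA{:}40S](t) = [40S]_0 k_1 (1 - e^{-(k_1+k_2)t})/(k_1+k_2)}
#' with `[AUG] = k2*[mRNA:40S]/k3 * (1 - exp(-k3 t))`, so the protein
#' synthesis rate approaches
#' \deqn{Prsynth = [40S]_0\, k_1 k_2/(k_1+k_2), \qquad
#'       t_{rel} = 1/(k_1+k_2).}
#' Neither expression involves `k3`.
#'
#' @name linear_translation
NULL

#' Steady rate and relaxation time of the linear cycle
#'
#' @param p A `linear_params` object (expects `k3 >> k1, k2`).
#' @param sep Separation factor below which a warning flag is set.
#' @return List with `prsynth_ss`, `t_rel`, `slow_timescale`
#'   (`= 1/(k1+k2)`), `fast_timescale` (`= 1/k3`), and logical
#'   `separation_ok`.
#' @examples
#' linear_steady_and_relaxation(linear_params(1, 1, 1000))
#' @export
linear_steady_and_relaxation <- function(p, sep = 10) {
  stopifnot(inherits(p, "linear_params"))
  ok <- p$k3 >= sep * max(p$k1, p$k2)
  if (!ok)
    warning("k3 is not well separated from k1, k2 (factor < ", sep,
            "); the two-time-scale formulas degrade")
  list(prsynth_ss = p$total_40S * p$k1 * p$k2 / (p$k1 + p$k2),
       t_rel = 1 / (p$k1 + p$k2),
       slow_timescale = 1 / (p$k1 + p$k2),
       fast_timescale = 1 / p$k3,
       separation_ok = ok)
}

#' Closed-form approximate trajectory of the linear cycle
#'
#' Evaluates the two-time-scale approximation at the requested times for
#' the initial condition with all 40S free.
#'
#' @param p A `linear_params` object.
#' @param times Numeric vector of times (>= 0).
#' @param sep Separation factor for the validity warning flag.
#' @return A `trajectory` data.frame (with `separation_ok` attribute); no
#'   exception is raised when separation is poor — the approximation
#'   degrades gracefully.
#' @export
linear_analytic_trajectory <- function(p, times, sep = 10) {
  stopifnot(inherits(p, "linear_params"), all(times >= 0))
  ok <- p$k3 >= sep * max(p$k1, p$k2)
  ks <- p$k1 + p$k2
  e_slow <- exp(-ks * times)
  c40 <- p$total_40S * (p$k2 + p$k1 * e_slow) / ks
  m <- p$total_40S * p$k1 * (1 - e_slow) / ks
  aug <- (p$k2 / p$k3) * m * (1 - exp(-p$k3 * times))
  df <- data.frame(time = times, c40S = c40 - aug, c_mRNA40S = m,
                   cAUG = aug)
  df$w1 <- p$k1 * df$c40S
  df$w2 <- p$k2 * df$c_mRNA40S
  df$w3 <- p$k3 * df$cAUG
  df$prsynth <- df$w3
  out <- new_trajectory(df, p, species = linear_species)
  attr(out, "separation_ok") <- ok
  out
}

#' Exact eigen-solution of the linear cycle
#'
#' Dense eigen-decomposition of the 3x3 cycle rate matrix: the reference
#' implementation against which the two-time-scale formulas are checked.
#'
#' @param p A `linear_params` object.
#' @return List with `eigenvalues` (sorted by magnitude, including 0),
#'   `steady_state` (concentrations proportional to `1/k_i`, normalized to
#'   the conserved total), `prsynth_ss`, and `t_rel`
#'   (`1/|second-smallest nonzero eigenvalue... |`, i.e. the slow one).
#' @export
linear_eigen_solution <- function(p) {
  stopifnot(inherits(p, "linear_params"))
  K <- matrix(c(-p$k1,     0,  p$k3,
                 p$k1, -p$k2,     0,
                    0,  p$k2, -p$k3), 3, 3, byrow = TRUE)
  lam <- eigen(K, only.values = TRUE)$values
  lam <- lam[order(abs(lam))]
  cs <- c(1 / p$k1, 1 / p$k2, 1 / p$k3)
  cs <- cs / sum(cs) * p$total_40S
  names(cs) <- linear_species
  w <- p$total_40S / sum(1 / c(p$k1, p$k2, p$k3))
  list(eigenvalues = lam, steady_state = cs, prsynth_ss = w,
       t_rel = 1 / abs(Re(lam[2])))
}

#' MicroRNA inhibition scan of the linear model
#'
#' Scans the closed-form steady rate and relaxation time while one rate
#' constant is scaled by inhibition factors, for a chosen experimental
#' base setting (wild-type cap, `k1 = k2`, or A-cap, `k1 = k2/100`; see
#' [linear_setting()]).
#'
#' @param p Baseline `linear_params` (e.g. from [linear_setting()]).
#' @param mechanism `"k1"`, `"k2"` or `"k3"`.
#' @param setting Label carried into the result.
#' @param factors Inhibition factors in (0, 1], default 25 log-spaced
#'   values from 1 to 1e-4.
#' @return A `scan_result` data.frame with columns `mechanism`, `setting`,
#'   `factor`, `steady_rate`, `relaxation_time`.
#' @export
linear_mirna_scan <- function(p, mechanism = c("k1", "k2", "k3"),
                              setting = "unnamed",
                              factors = 10^seq(0, -4, length.out = 25)) {
  stopifnot(inherits(p, "linear_params"))
  mechanism <- match.arg(mechanism)
  if (any(factors <= 0) || any(factors > 1))
    stop("inhibition factors must lie in (0, 1]")
  factors <- sort(factors, decreasing = TRUE)
  rows <- lapply(factors, function(f) {
    pi <- p
    pi[[mechanism]] <- p[[mechanism]] * f
    an <- suppressWarnings(linear_steady_and_relaxation(pi))
    data.frame(mechanism = mechanism, setting = setting, factor = f,
               steady_rate = an$prsynth_ss, relaxation_time = an$t_rel)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("scan_result", "data.frame"), params = p)
}
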