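#' Parameters of the linear translation cycle
#'
#' The simplest representation of translation is a closed three-step cycle
#' over the small ribosomal subunit: free 40S binds the mRNA initiation site
#' (rate `k1`), scans to the start codon (rate `k2`), and completes
#' elongation/termination, releasing the 40S and one protein (rate `k3`).
#' All rates are first order; the total amount of 40S is conserved.
#'
#' @param k1 Initiation-complex assembly rate (1/time), > 0.
#' @param k2 Late (cap-independent) initiation rate (1/time), > 0.
#' @param k3 Combined elongation/termination rate (1/time), > 0.
#' @param total_40S Conserved total 40S pool (model concentration units), > 0.
#' @return An object of class `linear_params`.
#' @examples
#' p <- linear_params(k1 = 1, k2 = 1, k3 = 1000, total_40S = 100)
#' @export
linear_params <- function(k1, k2, k3, total_40S = 100) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3),
            is.numeric(total_40S))
  if (any(c(k1, k2, k3) <= 0)) stop("all rate constants must be > 0")
  if (total_40S <= 0) stop("total_40S must be > 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, total_40S = total_40S),
            class = "linear_params")
}

#' Parameters of the non-linear translation model with recycling
#'
#' The non-linear model tracks recycling of the initiation factor (lumped as
#' eIF4F) and of both ribosomal subunits through four irreversible
#' reactions: R1 `40S + eIF4F -> mRNA:40S` (rate `k1`, second order),
#' R2 `mRNA:40S -> AUG + eIF4F` (rate `k2`), R3 `AUG + 60S -> 80S`
#' (rate `k3`, second order), R4 `80S -> 40S + 60S` + protein (rate `k4`).
#' Three pools are conserved: total 40S, total 60S and total eIF4F.
#'
#' @param k1 Initiation-complex assembly rate (1/(conc*time)), > 0.
#' @param k2 Start-codon scanning/recognition rate (1/time), > 0.
#' @param k3 Ribosome assembly (60S joining) rate (1/(conc*time)), > 0.
#' @param k4 Elongation/termination + subunit recycling rate (1/time), > 0.
#' @param total_40S,total_60S,total_eIF4F Conserved totals, > 0.
#' @return An object of class `nonlinear_params`.
#' @examples
#' p <- nonlinear_params(k1 = 2, k2 = 2, k3 = 5, k4 = 1,
#'                       total_40S = 100, total_60S = 25, total_eIF4F = 6)
#' beta(p)   # 0.48, the inefficient-initiation regime
#' @export
nonlinear_params <- function(k1, k2, k3, k4,
                             total_40S = 100, total_60S = 25,
                             total_eIF4F = 6) {
  vals <- c(k1, k2, k3, k4, total_40S, total_60S, total_eIF4F)
  stopifnot(is.numeric(vals), length(vals) == 7L)
  if (any(c(k1, k2, k3, k4) <= 0)) stop("all rate constants must be > 0")
  if (any(c(total_40S, total_60S, total_eIF4F) <= 0))
    stop("all conserved totals must be > 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 total_40S = total_40S, total_60S = total_60S,
                 total_eIF4F = total_eIF4F),
            class = "nonlinear_params")
}

#' @export
print.linear_params <- function(x, ...) {
  cat("Linear translation cycle parameters\n")
  cat(sprintf("  k1 = %g, k2 = %g, k3 = %g; [40S]0 = %g\n",
              x$k1, x$k2, x$k3, x$total_40S))
  invisible(x)
}

#' @export
print.nonlinear_params <- function(x, ...) {
  cat("Non-linear translation model parameters\n")
  cat(sprintf("  k1 = %g, k2 = %g, k3 = %g, k4 = %g\n",
              x$k1, x$k2, x$k3, x$k4))
  cat(sprintf("  [40S]0 = %g, [60S]0 = %g, [eIF4F]0 = %g\n",
              x$total_40S, x$total_60S, x$total_eIF4F))
  cat(sprintf("  beta = %g (%s initiation)\n", beta(x), classify_regime(x)))
  invisible(x)
}

#' Does a parameter set satisfy the standard ordering assumptions?
#'
#' The analysis of the non-linear model assumes a separation of pools and
#' rates: the 40S pool is abundant (`total_40S >> total_eIF4F`,
#' `total_40S > total_60S > total_eIF4F`) and subunit recycling is the
#' slowest step (`k4` well below the pseudo-first-order rates of the other
#' reactions). "Much bigger/smaller" is interpreted as a difference of one
#' order of magnitude by default (`sep = 10`), configurable.
#'
#' @param p A `nonlinear_params` object.
#' @param sep Separation factor defining ">>" (default 10).
#' @return Logical; attribute `"checks"` holds the individual comparisons.
#' @export
ordering_satisfied <- function(p, sep = 10) {
  stopifnot(inherits(p, "nonlinear_params"))
  checks <- c(
    pool_40S_vs_eIF4F = p$total_40S >= sep * p$total_eIF4F,
    pool_40S_vs_60S   = p$total_40S > p$total_60S,
    pool_60S_vs_eIF4F = p$total_60S > p$total_eIF4F,
    k4_slowest        = p$k4 <= min(p$k1 * p$total_40S,
                                    p$k2,
                                    p$k3 * p$total_60S) / sep,
    k3_fast           = p$k3 * p$total_60S >= sep * p$k2
  )
  structure(all(checks), checks = checks)
}

#' State vectors
#'
#' Helper constructors for named nonnegative state vectors of the two
#' models. The default state puts every conserved pool in its free form,
#' which is the initial condition used throughout: translation is switched
#' on in a system where no complex has yet assembled.
#'
#' @param p Parameter object of the matching class.
#' @return Named numeric vector.
#' @export
initial_state <- function(p) UseMethod("initial_state")

#' @export
initial_state.linear_params <- function(p) {
  c(c40S = p$total_40S, c_mRNA40S = 0, cAUG = 0)
}

#' @export
initial_state.nonlinear_params <- function(p) {
  c(c40S = p$total_40S, c60S = p$total_60S, c_eIF4F = p$total_eIF4F,
    c_mRNA40S = 0, cAUG = 0, c80S = 0)
}

linear_species    <- c("c40S", "c_mRNA40S", "cAUG")
nonlinear_species <- c("c40S", "c60S", "c_eIF4F", "c_mRNA40S", "cAUG", "c80S")

check_state <- function(state, species, tol = 1e-9) {
  if (!all(species %in% names(state)))
    stop("state must contain components: ", paste(species, collapse = ", "))
  if (any(state[species] < -tol))
    stop("negative concentrations in state: ",
         paste(species[state[species] < -tol], collapse = ", "))
  pmax(state[species], 0)
}

#' Conservation-law residuals of a non-linear model state
#'
#' The vector field conserves three linear combinations exactly:
#' `[eIF4F] + [mRNA:40S]`, `[60S] + [80S]`, and
#' `[40S] + [mRNA:40S] + [AUG] + [80S]`.
#'
#' @param state Named state vector.
#' @param p `nonlinear_params`.
#' @return Named numeric vector of residuals (state minus totals).
#' @export
conservation_residuals <- function(state, p) {
  stopifnot(inherits(p, "nonlinear_params"))
  c(eIF4F = unname(state["c_eIF4F"] + state["c_mRNA40S"] - p$total_eIF4F),
    s60S  = unname(state["c60S"] + state["c80S"] - p$total_60S),
    s40S  = unname(state["c40S"] + state["c_mRNA40S"] + state["cAUG"] +
                     state["c80S"] - p$total_40S))
}
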