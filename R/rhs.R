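#' Right-hand side of the linear translation cycle
#'
#' Mass-action vector field of the closed three-step cycle. The three fluxes
#' are `w1 = k1*[40S]`, `w2 = k2*[mRNA:40S]`, `w3 = k3*[AUG]`; the sum of
#' the three derivatives is identically zero (closed cycle).
#'
#' @param state Named nonnegative vector with components `c40S`,
#'   `c_mRNA40S`, `cAUG`.
#' @param p A `linear_params` object.
#' @return List with `derivatives` (named vector), `fluxes` (`w1..w3`) and
#'   `prsynth` (protein synthesis rate, `w3`).
#' @export
linear_rhs <- function(state, p) {
  stopifnot(inherits(p, "linear_params"))
  s <- check_state(state, linear_species)
  w1 <- p$k1 * s[["c40S"]]
  w2 <- p$k2 * s[["c_mRNA40S"]]
  w3 <- p$k3 * s[["cAUG"]]
  list(derivatives = c(c40S = w3 - w1, c_mRNA40S = w1 - w2, cAUG = w2 - w3),
       fluxes = c(w1 = w1, w2 = w2, w3 = w3),
       prsynth = w3)
}

#' Right-hand side of the non-linear translation model
#'
#' Mass-action vector field of the four-reaction recycling model. Fluxes:
#' `w1 = k1*[40S]*[eIF4F]`, `w2 = k2*[mRNA:40S]`, `w3 = k3*[AUG]*[60S]`,
#' `w4 = k4*[80S]`. The three conservation laws hold as exact identities of
#' the vector field.
#'
#' The protein synthesis rate during transients is not uniquely pinned down
#' by the reaction scheme: one protein is completed per turn of the R3-R4
#' cycle, so both `k4*[80S]` (default) and `k3*[AUG]*[60S]` are sensible
#' definitions; they coincide at steady state.
#'
#' @param state Named nonnegative vector with components `c40S`, `c60S`,
#'   `c_eIF4F`, `c_mRNA40S`, `cAUG`, `c80S`.
#' @param p A `nonlinear_params` object.
#' @param prsynth_def Which flux defines `Prsynth(t)` out of steady state:
#'   `"k4"` (default, flux completing a protein) or `"k3"`.
#' @return List with `derivatives`, `fluxes` (`w1..w4`) and `prsynth`.
#' @export
nonlinear_rhs <- function(state, p, prsynth_def = c("k4", "k3")) {
  stopifnot(inherits(p, "nonlinear_params"))
  prsynth_def <- match.arg(prsynth_def)
  s <- check_state(state, nonlinear_species)
  w1 <- p$k1 * s[["c40S"]] * s[["c_eIF4F"]]
  w2 <- p$k2 * s[["c_mRNA40S"]]
  w3 <- p$k3 * s[["cAUG"]] * s[["c60S"]]
  w4 <- p$k4 * s[["c80S"]]
  d <- c(c40S      = w4 - w1,
         c60S      = w4 - w3,
         c_eIF4F   = w2 - w1,
         c_mRNA40S = w1 - w2,
         cAUG      = w2 - w3,
         c80S      = w3 - w4)
  list(derivatives = d,
       fluxes = c(w1 = w1, w2 = w2, w3 = w3, w4 = w4),
       prsynth = if (prsynth_def == "k4") w4 else w3)
}
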