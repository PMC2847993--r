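# Shared oracle helpers: independent reference computations used to check
# the closed-form/asymptotic implementations.

# random non-linear parameter sets satisfying the standard orderings
# (abundant 40S, intermediate 60S, scarce eIF4F, slow recycling)
random_ordered_params <- function(n, seed = 42, sep = 10) {
  set.seed(seed)
  replicate(n, simplify = FALSE, {
    E0 <- stats::runif(1, 2, 8)
    L <- E0 * stats::runif(1, 2, 6)
    R0 <- max(L * stats::runif(1, 2, 6), sep * E0)
    k2 <- stats::runif(1, 0.5, 5)
    k1 <- stats::runif(1, 0.5, 5)
    k3 <- stats::runif(1, 0.5, 5)
    k4 <- min(k1 * R0, k2, k3 * L) / (sep * stats::runif(1, 1, 10))
    nonlinear_params(k1, k2, k3, k4, R0, L, E0)
  })
}

# relative error of the glued solution against the numeric trajectory on
# log-spaced samples in a window, with 10% log-buffers at the edges and an
# absolute floor of 1% of the largest conserved pool
stage_window_error <- function(ps, traj, p, t_lo, t_hi, n = 40) {
  la <- log(t_lo); lb <- log(t_hi)
  tw <- exp(seq(la + 0.1 * (lb - la), lb - 0.1 * (lb - la),
                length.out = n))
  ana <- ps$evaluate(tw)
  sp <- c("c40S", "c60S", "c_eIF4F", "c_mRNA40S", "cAUG", "c80S")
  num <- sapply(sp, function(s) stats::approx(traj$time, traj[[s]],
                                              xout = tw)$y)
  floor <- 0.01 * max(p$total_40S, p$total_60S, p$total_eIF4F)
  rel <- abs(ana - num) / pmax(abs(num), floor)
  apply(rel, 2, max)
}

# steady state of a linear-model parameter set as a pseudo steady_state
# object usable by relaxation_time()
linear_ss_shim <- function(p) {
  list(concentrations = linear_eigen_solution(p)$steady_state)
}
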