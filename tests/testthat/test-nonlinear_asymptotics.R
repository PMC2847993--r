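test_that("stage 1: initial condition, plateaus and duration estimate", {
  p <- fixture("efficient")
  s1 <- stage1_solution(p)
  # t = 0 returns the all-free state exactly
  st0 <- s1$evaluate(0)[1, ]
  expect_equal(unname(st0), unname(initial_state(p)))
  # quasiequilibrium plateaus before t': eIF4F, mRNA:40S, AUG near the
  # numeric trajectory (within 20%) while 80S is still filling
  tr <- integrate_model(p, t_end = 4, n_out = 1200)
  tw <- exp(seq(log(5 / (p$k1 * p$total_40S)), log(0.8 * s1$t_prime),
                length.out = 15))
  ana <- s1$evaluate(tw)
  for (s in c("c_eIF4F", "c_mRNA40S", "cAUG")) {
    num <- stats::approx(tr$time, tr[[s]], xout = tw)$y
    expect_lt(max(abs(ana[, s] - num) / pmax(num, 0.06)), 0.20,
              label = s)
  }
  # t'' estimate within a factor 2 of the numeric ratio-10 crossing
  cr <- detect_crossings(tr)
  expect_lt(abs(log(s1$t_dprime / cr$t_dprime)), log(2))
  expect_lt(abs(log(s1$t_prime / cr$t_prime)), log(2))
  # refuses a non-all-free start and unseparated pools
  expect_error(stage1_solution(p, init = initial_state(p) * 0.5),
               "all-free")
  expect_error(stage1_solution(nonlinear_params(2, 2, 5, 0.1, 10, 25, 6)),
               "assumptions")
})

test_that("stage 2: QSS conservation and the closed-form descent", {
  p <- fixture("efficient")
  ps <- glue(p)
  s2 <- ps$stages[[2]]
  # A = [40S] + [AUG] is conserved along the reduced solution
  tw <- seq(s2$window[1], s2$window[2], length.out = 30)
  st <- s2$evaluate(tw)
  A <- st[, "c40S"] + st[, "cAUG"]
  # conservation up to the small 60S-transit correction at stage entry
  expect_lt(diff(range(A[-(1:5)])) / A[1], 0.02)
  expect_gt(s2$params$K2, 0)
  expect_true(all(diff(st[, "c40S"]) < 1e-9))      # monotone descent
  expect_gt(s2$params$c40S_s2, 0)
  # piecewise linear/exponential closed form vs direct numerical
  # integration of the reduced scalar ODE: max relative error <= 15%
  c40_0 <- st[1, "c40S"]; aug_0 <- st[1, "cAUG"]
  A0 <- c40_0 + aug_0
  scalar_rhs <- function(t, y, parms) {
    augv <- A0 - y
    drain <- p$k2 * p$total_eIF4F * p$k1 * y / (p$k2 + p$k1 * y)
    refill <- p$k4 * p$total_60S * p$k3 * augv / (p$k4 + p$k3 * augv)
    list(refill - drain)
  }
  tt <- seq(0, diff(s2$window), length.out = 200)
  num <- deSolve::lsoda(c(c40_0), tt, scalar_rhs, rtol = 1e-10,
                        atol = 1e-12)[, 2]
  cf <- stage2_closed_form(p, c40_0)
  expect_lt(max(abs(cf(tt) - num) / pmax(num, 0.5)), 0.15)
  # handoff checks
  bad <- initial_state(p)
  expect_error(stage2_solution(p, bad), "60S")
})

test_that("stage 3: terminal state, amplitude constant, relaxation time", {
  p <- fixture("efficient")
  ps <- glue(p)
  s3 <- ps$stages[[3]]
  ss <- steady_state_exact(p)
  term <- s3$evaluate(s3$window[1] + 50 * s3$relaxation_time)[1, ]
  expect_lt(max(abs(term - ss$concentrations) /
                  pmax(ss$concentrations, 1e-6)), 0.02)
  # B is determined by [40S]s and the handoff value, and the long-time
  # limit does not depend on the handoff transient
  expect_equal(s3$B, ss$concentrations[["c40S"]] - ps$stages[[2]]$c40_end)
  # band-entry time of the stage-3 solution within a factor 2 of the
  # numeric 10%-band time, both measured from t'''
  mr <- measure_relaxation(p, ss = ss)
  t_num <- mr$time - detect_crossings(mr$trajectory)$t_tprime
  tgrid <- s3$window[1] + seq(0, 10 * t_num, length.out = 800)
  ana <- s3$evaluate(tgrid)
  thr <- 0.10 * pmax(abs(ss$concentrations), 1e-4)
  outside <- abs(sweep(ana, 2, ss$concentrations, "-")) >
    matrix(thr, nrow(ana), 6, byrow = TRUE)
  t_ana <- tgrid[max(which(apply(outside, 1, any)))] - s3$window[1]
  expect_lt(abs(log(max(t_ana, 1e-12) / max(t_num, 1e-12))), log(2))
  expect_error(stage3_solution(p, initial_state(p)), "40S")
})

test_that("glued solution is continuous and tracks the numeric oracle", {
  lims <- c(efficient = 0.25, strong_separation = 0.15)
  for (nm in names(lims)) {
    p <- fixture(nm)
    ps <- glue(p)
    expect_equal(ps$route, "three_stage")
    tr3 <- ps$transitions
    # transition ordering for beta > 1
    expect_true(tr3$t_prime <= tr3$t_dprime)
    expect_true(tr3$t_dprime < tr3$t_tprime)
    # continuity of the gluing variable [40S] at the internal switches
    for (tsw in c(ps$t_a, tr3$t_tprime)) {
      lo <- ps$evaluate(tsw - 1e-9)[1, "c40S"]
      hi <- ps$evaluate(tsw + 1e-9)[1, "c40S"]
      expect_lt(abs(hi - lo) / lo, 1e-6)
    }
    # numeric crossings within a factor 2 of the analytic estimates
    t_end <- tr3$t_tprime + 20 * ps$stages[[3]]$relaxation_time
    tr <- integrate_model(p, t_end = t_end, n_out = 2500)
    cr <- detect_crossings(tr)
    for (f in c("t_prime", "t_dprime", "t_tprime"))
      expect_lt(abs(log(tr3[[f]] / cr[[f]])), log(2), label = f)
    # per-species tracking error in the buffered stage interiors
    err1 <- stage_window_error(ps, tr, p, 1e-3 / (p$k1 * p$total_40S),
                               tr3$t_dprime)
    err2 <- stage_window_error(ps, tr, p, tr3$t_dprime, tr3$t_tprime)
    err3 <- stage_window_error(ps, tr, p, tr3$t_tprime, t_end)
    expect_lt(max(err1, err2, err3), lims[[nm]], label = nm)
  }
})

test_that("below the regime boundary a single stage describes the process", {
  p <- fixture("default")           # beta = 0.48
  ps <- glue(p)
  expect_equal(ps$route, "single_stage")
  # the quasiequilibrium solution reproduces the numeric relaxation
  ss <- steady_state_exact(p)
  tr <- integrate_model(p, t_end = 30, n_out = 1500)
  tw <- exp(seq(log(0.02), log(25), length.out = 40))
  ana <- ps$evaluate(tw)
  sp <- colnames(ana)
  floor <- 0.01 * p$total_40S
  for (s in sp) {
    num <- stats::approx(tr$time, tr[[s]], xout = tw)$y
    expect_lt(max(abs(ana[, s] - num) / pmax(num, floor)), 0.25, label = s)
  }
  # terminal state close to the exact steady state
  term <- ps$evaluate(500)[1, ]
  expect_lt(max(abs(term - ss$concentrations) /
                  pmax(ss$concentrations, 1)), 0.05)
  # glue route agrees with the regime classifier on all fixtures
  for (nm in c("default", "efficient", "strong_separation",
               "efficient_scan")) {
    pp <- fixture(nm)
    route <- glue(pp)$route
    expect_equal(route == "three_stage",
                 as.character(classify_regime(pp)) == "efficient",
                 label = nm)
  }
})

test_that("glued-solution error is non-increasing as separation grows", {
  # sweep the time-scale separation (k3*pools vs k4) over two decades
  seps <- c(10, 100, 1000)
  errs <- vapply(seps, function(s) {
    p <- nonlinear_params(2, 2, 5, 2 / s, 100, 25, 6)   # beta = 6*s/25 > 1
    ps <- glue(p)
    t_end <- ps$transitions$t_tprime + 20 * ps$stages[[3]]$relaxation_time
    tr <- integrate_model(p, t_end = t_end, n_out = 2000)
    max(stage_window_error(ps, tr, p, ps$transitions$t_dprime,
                           ps$transitions$t_tprime),
        stage_window_error(ps, tr, p, ps$transitions$t_tprime, t_end))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0.02))   # non-increasing up to noise
})

test_that("weak-initiation regime is detected and described numerically", {
  p <- fixture("acap_default")            # k1 = 0.01
  ar <- acap_regime(p)
  expect_true(ar$acap)
  expect_true(ar$acap_strict)
  expect_equal(ar$route, "numeric")
  # steady rate decreases against the wild-type k1
  expect_lt(steady_state_exact(p)$prsynth,
            steady_state_exact(fixture("default"))$prsynth)
  # detection flag is a predicate on k1*[eIF4F]0 vs k4
  expect_false(acap_regime(fixture("efficient_scan"),
                           check_condition = FALSE)$acap)
  # trajectory inherits the conservation guarantees
  expect_lt(trajectory_conservation_error(ar$trajectory), 1e-6)
})
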