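test_that("beta takes the published worked values", {
  expect_equal(beta(nonlinear_params(2, 2, 5, 1, 100, 25, 6)), 0.48)
  expect_equal(beta(nonlinear_params(2, 2, 5, 0.1, 100, 25, 6)), 4.8)
  expect_equal(beta(nonlinear_params(2, 3, 50, 0.1, 100, 25, 6)), 7.2)
})

test_that("regime classification and the boundary flag", {
  expect_equal(as.character(classify_regime(fixture("default"))),
               "inefficient")
  expect_equal(as.character(classify_regime(fixture("efficient"))),
               "efficient")
  pb <- nonlinear_params(2, 2, 5, 0.48, 100, 25, 6)   # beta = 1 exactly
  expect_true(attr(classify_regime(pb), "boundary"))
  expect_false(attr(classify_regime(fixture("default")), "boundary"))
})

test_that("exact steady state matches long-horizon integration", {
  for (nm in fixture_names()) {
    p <- fixture(nm)
    ss <- steady_state_exact(p)
    tr <- integrate_model(p, t_end = 2000 / min(p$k4, 0.5), n_out = 250)
    term <- unlist(utils::tail(as.data.frame(tr)[names(ss$concentrations)],
                               1))
    expect_lt(max(abs(term - ss$concentrations) /
                    pmax(abs(ss$concentrations), 1e-12)), 1e-6,
              label = paste("terminal mismatch for", nm))
    # the steady state zeroes the vector field componentwise
    r <- nonlinear_rhs(ss$concentrations, p)
    expect_lt(max(abs(r$derivatives)) / max(r$fluxes), 1e-9)
    expect_lt(ss$flux_residual, 1e-10)
  }
})

test_that("no-initiation limit: vanishing eIF4F pool leaves pools free", {
  p <- nonlinear_params(2, 2, 5, 1, 100, 25, 1e-5)
  ss <- steady_state_exact(p)
  expect_gt(ss$x, 1 - 1e-4)
  expect_lt(ss$prsynth, 1e-3)
  expect_equal(unname(ss$concentrations["c40S"]), 100, tolerance = 1e-3)
})

test_that("cubic coefficients and roots behave as the asymptotics demand", {
  p <- fixture("default")
  cf <- cubic_coeffs(p)
  expect_equal(cf$beta, 0.48)
  expect_gt(cf$delta, 1)
  expect_lt(cf$gamma, 0.1)
  # the constant term of the monic cubic is -gamma*(1-beta)
  expect_equal(cf$c0, -cf$gamma * (cf$beta - 1))
  # admissible root close to the exact solver on all fixtures
  for (nm in fixture_names()) {
    pp <- fixture(nm)
    rs <- suppressWarnings(cubic_roots(pp))
    xe <- steady_state_exact(pp)$x
    expect_lt(abs(rs$x - xe) / xe, 0.10, label = nm)
  }
  # the efficient regime selects the small root x0
  expect_equal(suppressWarnings(cubic_roots(fixture("efficient")))$admissible,
               "x0")
  expect_equal(suppressWarnings(cubic_roots(fixture("default")))$admissible,
               "x1")
})

test_that("x2 is always negative and the physical steady state is unique", {
  params <- random_ordered_params(500, seed = 99)
  for (p in params) {
    rs <- suppressWarnings(cubic_roots(p))
    if (is.finite(rs$x2)) expect_lt(rs$x2, 0)
    # exactly one admissible root among x0, x1
    adm <- vapply(c(rs$x0, rs$x1), function(x) {
      if (!is.finite(x) || x <= 0 || x > 1) return(FALSE)
      w <- p$k4 * (1 - x) * p$total_60S
      e <- p$total_eIF4F - w / p$k2
      e > 0 && w / (p$k1 * e) > 0 && w / (p$k1 * e) <= p$total_40S
    }, logical(1))
    expect_equal(sum(adm), 1L)
  }
})

test_that("cubic root error shrinks as the parameter separation grows", {
  errs <- vapply(c(10, 100, 1000), function(s) {
    p <- nonlinear_params(2, 2, 5, 2 / s, 100, 25, 6)
    xe <- steady_state_exact(p)$x
    abs(suppressWarnings(cubic_roots(p))$x - xe) / xe
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("closed-form rate law: critical and non-critical parameters", {
  # inefficient regime: rate independent of k3 (vary x5)
  p <- fixture("default")
  r1 <- steady_state_exact(p)$prsynth
  p5 <- p; p5$k3 <- p$k3 * 5
  expect_lt(abs(steady_state_exact(p5)$prsynth - r1) / r1, 0.01)
  # efficient regime: rate ~ k4*[60S]0
  pe <- fixture("efficient")
  re <- steady_state_exact(pe)$prsynth
  expect_lt(abs(re - pe$k4 * pe$total_60S) / (pe$k4 * pe$total_60S), 0.25)
  expect_equal(steady_protein_rate(pe), pe$k4 * pe$total_60S)
  expect_equal(steady_protein_rate(p), p$k2 * p$total_eIF4F)
  # doubling the eIF4F pool in the efficient regime saturates
  pd <- pe; pd$total_eIF4F <- 2 * pe$total_eIF4F
  expect_lt(abs(steady_state_exact(pd)$prsynth - re) / re, 0.05)
  # k1 is never critical directly: a x10 increase moves the rate < 5% in
  # both regimes; a x10 decrease stays < 5% in the efficient regime and
  # < 10% in the inefficient one, where slower complex assembly starts to
  # sequester a visible share of the scarce eIF4F pool
  for (nm in c("default", "efficient")) {
    pp <- fixture(nm)
    r0 <- steady_state_exact(pp)$prsynth
    for (f in c(10, 0.1)) {
      pk <- pp; pk$k1 <- pp$k1 * f
      tol <- if (nm == "default" && f == 0.1) 0.10 else 0.05
      expect_lt(abs(steady_state_exact(pk)$prsynth - r0) / r0, tol,
                label = sprintf("%s k1 x%g", nm, f))
    }
  }
})

test_that("polysome proxy moves with the protein synthesis rate", {
  p <- fixture("default")
  factors <- 10^seq(0, -2, length.out = 8)
  for (mech in c("k2", "k4")) {
    rates <- proxies <- numeric(length(factors))
    for (i in seq_along(factors)) {
      pi <- p; pi[[mech]] <- p[[mech]] * factors[i]
      ss <- steady_state_exact(pi)
      rates[i] <- ss$prsynth
      proxies[i] <- polysome_proxy(pi, ss)
    }
    if (mech == "k2") {
      # k4 untouched: bound-ribosome load tracks the rate monotonically
      expect_true(all(diff(proxies[order(rates)]) >= -1e-9))
    } else {
      expect_true(all(is.finite(proxies)))
    }
  }
})

test_that("regime-flip thresholds follow from beta = 1", {
  p <- fixture("default")
  th <- critical_thresholds(p)
  expect_equal(th$k4_threshold, p$k2 * p$total_eIF4F / p$total_60S)
  expect_equal(th$k4_threshold, 0.48)
  expect_equal(th$k2_threshold, p$k4 * p$total_60S / p$total_eIF4F)
  # crossing the threshold flips the classifier
  pk <- p; pk$k4 <- th$k4_threshold * 1.01
  expect_equal(as.character(classify_regime(pk)), "inefficient")
  pk$k4 <- th$k4_threshold * 0.99
  expect_equal(as.character(classify_regime(pk)), "efficient")
})
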