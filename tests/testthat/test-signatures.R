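test_that("relaxation time: trivial cases and band nesting", {
  p <- fixture("default")
  ss <- steady_state_exact(p)
  tr <- integrate_model(p, init = ss$concentrations, t_end = 10)
  expect_equal(relaxation_time(tr, ss), 0)
  tr2 <- integrate_model(p, t_end = 60, n_out = 600)
  t10 <- relaxation_time(tr2, ss, band = 0.10)
  t05 <- relaxation_time(tr2, ss, band = 0.05)
  expect_gte(t05, t10)
  expect_gt(t10, 0)
  # an unsettled trajectory is reported, naming the species
  short <- integrate_model(p, t_end = 0.05, n_out = 50)
  expect_error(relaxation_time(short, ss), "settled")
})

test_that("strong late-step inhibition on an A-cap lengthens relaxation", {
  # linear model, A-cap cap structure, k2 inhibited x100: the numeric
  # relaxation time grows at least tenfold (the published "increases
  # drastically" cell)
  p <- linear_setting("acap")
  base <- integrate_model(p, t_end = 2000 / p$k2, n_out = 800)
  t_base <- relaxation_time(base, linear_ss_shim(p))
  pi <- p; pi$k2 <- p$k2 / 100
  inh <- integrate_model(pi, t_end = 4000 / pi$k2, n_out = 800)
  t_inh <- relaxation_time(inh, linear_ss_shim(pi))
  expect_gte(t_inh, 10 * t_base)
})

test_that("inhibition scans: baseline identity and published shapes", {
  p <- signature_setting("wt_inefficient")
  factors <- 10^seq(0, -3.2, by = -0.4)
  sc <- inhibition_scan(p, "k4", "wt_inefficient", factors)
  # factor = 1 row equals the unperturbed model outputs
  ss <- steady_state_exact(p)
  expect_equal(sc$steady_rate[sc$factor == 1], ss$prsynth)
  expect_equal(sc$relaxation_time[sc$factor == 1],
               measure_relaxation(p, ss = ss)$time)
  # k4 under inefficient initiation: flat until the regime-flip threshold,
  # then decreasing
  th <- critical_thresholds(p)$k4_threshold / p$k4
  pre <- sc[sc$factor > 2 * th, ]
  post <- sc[sc$factor < th / 2, ]
  expect_lt(max(abs(pre$steady_rate - ss$prsynth)) / ss$prsynth, 0.05)
  expect_true(all(diff(post$steady_rate) < 0))
  expect_error(inhibition_scan(p, "k4", factors = c(2, 1)), "factors")
})

test_that("classifier maps curve shapes to the published vocabulary", {
  # flat synthetic curves are no-change by construction
  flat <- structure(
    data.frame(mechanism = "k3", setting = "wt_inefficient",
               factor = 10^seq(0, -4, length.out = 12),
               steady_rate = 5 * (1 + 0.02 * sin(1:12)),
               relaxation_time = 2 * (1 + 0.02 * cos(1:12))),
    class = c("scan_result", "data.frame"),
    params = signature_setting("wt_inefficient"))
  cl <- classify_signature(flat)
  expect_equal(cl$rate_label, "no_change")
  expect_equal(cl$time_label, "no_change")
  # the canonical up-and-down and after-threshold cells
  p <- signature_setting("wt_inefficient")
  sc <- inhibition_scan(p, "k4", "wt_inefficient", 10^seq(0, -4, by = -0.1))
  cl4 <- classify_signature(sc)
  expect_equal(cl4$rate_label, "decreases_after_threshold")
  expect_equal(cl4$time_label, "goes_up_and_down")
  pe <- signature_setting("wt_efficient")
  sce <- inhibition_scan(pe, "k2", "wt_efficient", 10^seq(0, -4, by = -0.1))
  cle <- classify_signature(sce)
  expect_equal(cle$rate_label,
               "slightly_decreases_after_strong_inhibition")
  expect_equal(cle$time_label, "goes_up_and_down")
  # a scan narrower than 3 decades is refused
  expect_error(classify_signature(sc[sc$factor > 0.01, ]), "3 decades")
})

test_that("rate-curve breakpoints sit at the critical thresholds", {
  # wt_inefficient/k4 and wt_efficient/k2: the onset of the rate decline
  # (factor where the rate has dropped 25%) agrees with the beta = 1
  # threshold within 20%
  cases <- list(list(setting = "wt_inefficient", mech = "k4"),
                list(setting = "wt_efficient", mech = "k2"))
  for (cs in cases) {
    p <- signature_setting(cs$setting)
    th <- critical_thresholds(p)
    f_th <- if (cs$mech == "k4") th$k4_threshold / p$k4
            else th$k2_threshold / p$k2
    factors <- 10^seq(0, -2, by = -0.05)
    rates <- vapply(factors, function(f) {
      pi <- p; pi[[cs$mech]] <- p[[cs$mech]] * f
      steady_state_exact(pi)$prsynth
    }, numeric(1))
    base <- rates[1]
    f_break <- factors[which(rates < 0.75 * base)[1]]
    expect_lt(abs(log(f_break / f_th)), log(1.45),
              label = sprintf("%s/%s: breakpoint %.3g vs threshold %.3g",
                              cs$setting, cs$mech, f_break, f_th))
  }
})

test_that("mechanism lookup inverts the signature tables", {
  # A-cap linear context: unchanged rate + drastically longer relaxation
  # pins the late initiation step
  expect_equal(
    mechanism_lookup(list(acap = list(rate_label = "no_change",
                                      time_label = "increases_drastically")),
                     model = "linear"), "k2")
  # all-no-change is indistinguishable from no effect: k3 plus "none"
  obs <- list(wt_inefficient = list(rate_label = "no_change",
                                    time_label = "no_change"),
              wt_efficient = list(rate_label = "no_change",
                                  time_label = "no_change"),
              acap_inefficient = list(rate_label = "no_change",
                                      time_label = "no_change"),
              acap_efficient = list(rate_label = "no_change",
                                    time_label = "no_change"))
  expect_setequal(mechanism_lookup(obs, "nonlinear"), c("k3", "none"))
  # contradictory observations give the empty set
  contra <- list(wt_inefficient = list(rate_label = "decreases"),
                 wt_efficient = list(rate_label = "decreases"))
  expect_length(mechanism_lookup(contra, "nonlinear"), 0)
  expect_error(mechanism_lookup(list(wt = list(rate_label = "explodes")),
                                "linear"), "label")
  expect_error(mechanism_lookup(list(bogus = list(rate_label = "no_change")),
                                "nonlinear"), "setting")
})

test_that("the linear-model signature table is reproduced in full", {
  tab <- signature_table("linear")
  ref <- reference_signature_table("linear")
  m <- merge(tab, ref, by = c("setting", "mechanism"),
             suffixes = c("_got", "_ref"))
  expect_equal(m$rate_label_got, m$rate_label_ref)
  expect_equal(m$time_label_got, m$time_label_ref)
})
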