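test_that("transcription timescales invert the conductances", {
  m <- ref_model_fx()
  reg <- regulation_state(m, constant = 5000)
  expect_equal(unname(reg$tau_mu["A"]), 5000 / 379)
  # ratio law: tau_mu_CaT / tau_mu_A = g_A / g_CaT
  expect_equal(reg$tau_mu[["CaT"]] / reg$tau_mu[["A"]], 379 / 2.35,
               tolerance = 1e-12)
  # equal conductances give equal timescales (exact diagonal motion)
  meq <- neuron_model(setNames(rep(100, 8), channel_names()))
  req <- regulation_state(meq, constant = 5000)
  expect_true(all(req$tau_mu == 50))
  # a zero conductance means an infinite timescale: rejected
  g0 <- m$gbar; g0["H"] <- 0
  expect_error(regulation_state(with_gbar(m, g0)))
})

test_that("the closed loop holds the reference model at its own target", {
  tr <- integrate_closed_loop(ref_model_fx(), ref_reg_fx(),
                              t_total = 100000)
  expect_false(tr$diverged)
  drift <- max(abs(tr$g_final / ref_model_fx()$gbar - 1))
  expect_lt(drift, 0.02)
})

test_that("conductance motion follows the timescale-ratio direction law", {
  m <- ref_model_fx()
  reg <- ref_reg_fx()
  start <- with_gbar(m, m$gbar * 0.25)
  tr <- integrate_closed_loop(start, reg, t_total = 120000,
                              min_time = 120000)
  # window well past the translation transient, well before the fixed point
  dir <- function(i, j) {
    trajectory_direction(tr, i, j, from = 20000, to = 60000)$slope
  }
  for (pair in list(c("A", "CaT"), c("Kd", "NaV"), c("CaS", "KCa"))) {
    expected <- reg$tau_mu[[pair[1]]] / reg$tau_mu[[pair[2]]]
    expect_equal(dir(pair[1], pair[2]), expected, tolerance = 0.01)
  }
})

test_that("trajectories started on the reference ray stay on it", {
  m <- ref_model_fx()
  tr <- integrate_closed_loop(with_gbar(m, m$gbar * 0.3), ref_reg_fx(),
                              t_total = 150000)
  log <- tr$log[tr$log$t > 20000, ]
  for (ch in c("CaS", "Kd", "NaV", "KCa")) {
    ratio <- log[[ch]] / log[["A"]]
    ref_ratio <- m$gbar[[ch]] / m$gbar[["A"]]
    expect_true(all(abs(ratio / ref_ratio - 1) < 0.01))
  }
  # and the loop recovers the reference densities (diagonal recovery)
  expect_lt(max(abs(tr$g_final / m$gbar - 1)), 0.1)
})

test_that("open-loop co-regulation preserves density only when tuned", {
  m <- ref_model_fx()
  r_g <- 1e-6 * m$geometry$A # membrane production rate
  tuned <- tuned_open_loop_rates(m, r_g)
  tr <- integrate_open_loop(m, tuned, t_total = 500000)
  expect_equal(unname(tr$g_final), unname(m$gbar), tolerance = 1e-9)
  # a 5x mismatched growth rate dilutes density towards 1/5
  mis <- growth_params(k = 0, r_growth = 5 * r_g, r = tuned$r)
  tr2 <- integrate_open_loop(m, mis, t_total = 5e7)
  expect_equal(unname(tr2$g_final / m$gbar),
               rep(1 / 5, 8), tolerance = 0.05)
})
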