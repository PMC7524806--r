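test_that("gating steady states are bounded and time constants positive", {
  for (V in seq(-120, 60, by = 5)) {
    for (Ca in c(0.05, 1, 50, 500)) {
      g <- steady_state(V, Ca)
      expect_true(all(g$m_inf >= 0 & g$m_inf <= 1))
      expect_true(all(g$h_inf >= 0 & g$h_inf <= 1))
      expect_true(all(g$tau_m > 0))
      expect_true(all(g$tau_h > 0))
    }
  }
})

test_that("gating anchors match the published kinetics", {
  # NaV half-activation at -25.5 mV
  expect_equal(steady_state(-25.5, 1)$m_inf[["NaV"]], 0.5, tolerance = 1e-12)
  # sigmoid saturation at depolarised potentials
  expect_gt(steady_state(60, 1)$m_inf[["NaV"]], 0.99)
  # the leak carries no gates
  g <- steady_state(-37.2, 1)
  expect_identical(unname(g$m_inf["Leak"]), 1)
  expect_identical(unname(g$h_inf["Leak"]), 1)
  # KCa activation vanishes with calcium and is half-saturated at 3 uM
  expect_lt(steady_state(0, 1e-9)$m_inf[["KCa"]], 1e-9)
  v_part <- 1 / (1 + exp((0 + 28.3) / -12.6))
  expect_equal(steady_state(0, 3)$m_inf[["KCa"]], v_part / 2,
               tolerance = 1e-12)
})

test_that("calcium current density matches a term-by-term hand evaluation", {
  m <- reference_model()
  V <- -40; Ca <- 0.05
  # independent evaluation of the two calcium-current terms
  sig <- function(V, Vh, k) 1 / (1 + exp((V + Vh) / k))
  ECa <- 12.199 * log(3000 / Ca)
  cas <- 165 * sig(V, 33, -8.1)^3 * sig(V, 60, 6.2) * (V - ECa)
  cat_ <- 2.35 * sig(V, 27.1, -7.2)^3 * sig(V, 32.1, 5.5) * (V - ECa)
  expect_equal(total_calcium_current_density(m, V, Ca), cas + cat_,
               tolerance = 1e-12)
})

test_that("calcium current obeys the trivial limits", {
  m <- reference_model()
  g0 <- m$gbar; g0["CaS"] <- 0; g0["CaT"] <- 0
  m0 <- with_gbar(m, g0)
  expect_equal(total_calcium_current_density(m0, -30, 1), 0)
  expect_equal(total_calcium_current_density(m0, 10, 50), 0)
  # zero driving force exactly at the Nernst potential
  Ca <- 2.5
  expect_equal(total_calcium_current_density(m, nernst_ca(Ca), Ca), 0,
               tolerance = 1e-12)
})

test_that("non-finite inputs are rejected", {
  expect_error(steady_state(NaN, 1))
  expect_error(steady_state(-50, -1))
})
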