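test_that("a passive membrane relaxes monotonically to the leak reversal", {
  m <- neuron_model(c(Leak = 0.46))
  r <- simulate_neuron(m, t_total = 3000, burnin = 1000, record_stride = 20L)
  expect_false(r$diverged)
  expect_equal(tail(r$V, 1), -50, tolerance = 1e-3)
  # from -60 towards -50: non-decreasing
  expect_true(all(diff(r$V) >= -1e-9))
  # with no calcium current, calcium settles at its resting value
  expect_equal(tail(r$Ca, 1), 0.05, tolerance = 1e-6)
  expect_equal(mean_calcium(r), 0.05, tolerance = 1e-3)
})

test_that("dynamics are invariant under joint scaling of area and shell volume", {
  m1 <- reference_model()
  geom3 <- list(A = m1$geometry$A * 3, eta = m1$geometry$eta * 3)
  m3 <- reference_model(geometry = geom3)
  r1 <- simulate_neuron(m1, t_total = 6000, burnin = 1000, record_stride = 10L)
  r3 <- simulate_neuron(m3, t_total = 6000, burnin = 1000, record_stride = 10L)
  expect_equal(r1$V, r3$V, tolerance = 1e-12)
  expect_equal(r1$Ca, r3$Ca, tolerance = 1e-12)
})

test_that("the reference model bursts with a step-size-converged period", {
  m <- reference_model()
  r_coarse <- simulate_neuron(m, t_total = 15000, burnin = 5000)
  r_fine <- simulate_neuron(m, t_total = 15000, dt = 0.005, burnin = 5000,
                            record_stride = 10L)
  p_coarse <- trace_metrics(r_coarse)$burst_period
  p_fine <- trace_metrics(r_fine)$burst_period
  expect_true(is.finite(p_coarse) && is.finite(p_fine))
  expect_lt(abs(p_coarse / p_fine - 1), 0.02)
})

test_that("traces stay finite and gates bounded across the sampling hypercube", {
  m <- reference_model()
  set.seed(7)
  bad <- 0L
  for (k in 1:1000) {
    g <- runif(8) * 2 * m$gbar
    r <- simulate_neuron(with_gbar(m, g), t_total = 1200, burnin = 600,
                         record = FALSE)
    fs <- r$final_state
    ok <- !r$diverged && all(is.finite(fs)) &&
      all(fs[3:18] >= 0 & fs[3:18] <= 1) && # m and h gates bounded
      fs[2] > 0                             # calcium positive
    if (!ok) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("simulation is deterministic and the divergence guard works", {
  m <- reference_model()
  r1 <- simulate_neuron(m, t_total = 2000, burnin = 500)
  r2 <- simulate_neuron(m, t_total = 2000, burnin = 500)
  expect_identical(r1$V, r2$V)
  expect_error(simulate_neuron(m, t_total = 1000, burnin = 2000))
})
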