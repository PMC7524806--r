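make_result <- function(t, V, Ca = rep(1, length(t)), burnin = 0) {
  structure(list(t = t, V = V, Ca = Ca, mean_Ca = mean(Ca),
                 diverged = FALSE, dt = diff(t[1:2]), burnin = burnin,
                 t_end = max(t)),
            class = "sim_result")
}

test_that("spike detection counts threshold crossings once each", {
  t <- seq(0, 1000, by = 0.1)
  expect_length(detect_spikes(t, rep(-60, length(t))), 0)
  # five square pulses above threshold
  V <- rep(-60, length(t))
  for (s in seq(100, 900, by = 200)) V[t >= s & t < s + 2] <- 20
  expect_length(detect_spikes(t, V), 5)
})

test_that("burst metrics recover a constructed periodic burst train", {
  # 4 spikes at 10 ms ISI, burst every 1000 ms, 10 bursts
  spikes <- as.vector(outer(seq(0, 30, by = 10), seq(0, 9000, by = 1000), "+"))
  spikes <- sort(spikes)
  bm <- burst_metrics(spikes, duration = 10000)
  expect_equal(bm$burst_period, 1000)
  expect_equal(bm$n_spikes_per_burst, 4)
  expect_gte(bm$duty_cycle, 0.03)
  expect_lte(bm$duty_cycle, 0.04)
  expect_true(bm$regular)
})

test_that("spike trains without burst structure flag undefined metrics", {
  single <- seq(0, 5000, by = 500) # one spike every 500 ms
  bm <- burst_metrics(single, duration = 5000)
  expect_true(is.na(bm$burst_period))
  expect_false(bm$regular)
})

test_that("classification is exhaustive and follows the tolerance rules", {
  cfg <- classifier_config(target_period = 1000, target_duty = 0.3)
  base <- list(n_spikes = 100, burst_period = 1000, duty_cycle = 0.3,
               n_spikes_per_burst = 8, regular = TRUE, diverged = FALSE)
  expect_identical(classify(base, cfg), "canonical")
  # period within 5%, duty cycle off by 30%
  off <- base; off$burst_period <- 1050; off$duty_cycle <- 0.39
  expect_identical(classify(off, cfg), "other_bursting")
  silent <- base; silent$n_spikes <- 0
  expect_identical(classify(silent, cfg), "silent")
  tonic <- base; tonic$burst_period <- NA_real_
  tonic$n_spikes_per_burst <- NA_real_
  expect_identical(classify(tonic, cfg), "tonic_or_one_spike")
  one_spike <- base; one_spike$n_spikes_per_burst <- 1
  expect_identical(classify(one_spike, cfg), "tonic_or_one_spike")
  labels <- c(classify(base, cfg), classify(off, cfg), classify(silent, cfg),
              classify(tonic, cfg))
  expect_true(all(labels %in% c("canonical", "other_bursting",
                                "tonic_or_one_spike", "silent")))
})

test_that("the reference model classifies canonical against its own targets", {
  tg <- ref_targets_fx()
  expect_identical(tg$metrics$state_label, "other_bursting") # no targets yet
  r <- simulate_neuron(ref_model_fx(), t_total = 15000, burnin = 5000)
  expect_identical(trace_metrics(r, tg$cfg)$state_label, "canonical")
})

test_that("metrics are stable across disjoint analysis windows", {
  r <- simulate_neuron(ref_model_fx(), t_total = 45000, burnin = 5000)
  win <- function(from, to) {
    keep <- r$t >= from & r$t <= to
    make_result(r$t[keep], r$V[keep], r$Ca[keep], burnin = from)
  }
  m1 <- trace_metrics(win(5000, 25000))
  m2 <- trace_metrics(win(25000, 45000))
  expect_lt(abs(m1$burst_period / m2$burst_period - 1), 0.02)
  expect_lt(abs(m1$duty_cycle / m2$duty_cycle - 1), 0.02)
})
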