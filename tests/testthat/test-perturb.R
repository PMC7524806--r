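test_that("perturbation summaries match hand-computed values", {
  g0 <- c(10, 20)
  expect_equal(summarise_perturbation(g0, 2 * g0)$mu, 1)
  expect_equal(summarise_perturbation(g0, 2 * g0)$sigma, 0)
  expect_equal(summarise_perturbation(g0, g0)$mu, 0)
  expect_equal(summarise_perturbation(g0, g0)$sigma, 0)
  # relative changes (0.1, 0.3): mean 0.2, sd with N-1 = sqrt(0.02)
  s <- summarise_perturbation(g0, g0 * c(1.1, 1.3))
  expect_equal(s$mu, 0.2)
  expect_equal(s$sigma, sqrt(0.02))
  expect_error(summarise_perturbation(c(0, 1), c(1, 1)))
})

test_that("sampled perturbations realise the requested moments exactly", {
  m <- ref_model_fx()
  for (mu in c(-0.5, 0, 0.8)) {
    for (sg in c(0, 0.2, 0.6)) {
      ps <- sample_perturbations(m, mu, sg, n = 3, seed = 11)
      for (p in ps) {
        s <- summarise_perturbation(m$gbar, p$gbar)
        expect_equal(s$mu, mu, tolerance = 1e-10)
        expect_equal(s$sigma, sg, tolerance = 1e-10)
        expect_true(all(p$gbar >= 0))
      }
    }
  }
  # sigma = 0 is a pure scaling: a size-change-equivalent perturbation
  p0 <- sample_perturbations(m, 0.5, 0, n = 1, seed = 1)[[1]]
  expect_equal(unname(p0$gbar), unname(1.5 * m$gbar))
  # seeded reproducibility
  a <- sample_perturbations(m, 0.1, 0.4, n = 2, seed = 99)
  b <- sample_perturbations(m, 0.1, 0.4, n = 2, seed = 99)
  expect_identical(lapply(a, `[[`, "gbar"), lapply(b, `[[`, "gbar"))
})

test_that("infeasible perturbation requests error after the retry cap", {
  m <- ref_model_fx()
  expect_error(sample_perturbations(m, -2, 0, n = 1, seed = 1, max_tries = 5))
})

test_that("zero-dispersion perturbations of any mean recover the target period", {
  # sigma = 0 is a size-change equivalent: homeostasis restores the
  # phenotype no matter how large the mean shift
  m <- ref_model_fx()
  tg <- ref_targets_fx()
  reg <- ref_reg_fx()
  for (mu in c(-0.8, 1)) {
    p <- sample_perturbations(m, mu, 0, n = 1, seed = 1)[[1]]
    res <- recovery_experiment(p, reg, tg$cfg)
    expect_lt(abs(res$terminal_period / tg$period - 1), 0.1)
    expect_identical(res$state_label, "canonical")
  }
})
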