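small_db <- function() {
  fixture("small_db", {
    tg <- ref_targets_fx()
    cfg <- db_config(template = ref_model_fx(), n = 3,
                     target_period = tg$period, target_duty = tg$duty,
                     tol_period = 0.5, tol_duty = 0.5, max_draws = 400)
    generate_model_db(cfg, seed = 7)
  })
}

test_that("database generation is reproducible from its seed", {
  db1 <- small_db()
  tg <- ref_targets_fx()
  cfg <- db_config(template = ref_model_fx(), n = 3,
                   target_period = tg$period, target_duty = tg$duty,
                   tol_period = 0.5, tol_duty = 0.5, max_draws = 400)
  db2 <- generate_model_db(cfg, seed = 7)
  expect_identical(lapply(db1$models, `[[`, "gbar"),
                   lapply(db2$models, `[[`, "gbar"))
  expect_identical(db1$n_draws, db2$n_draws)
})

test_that("accepted records re-simulate as bursting within tolerance", {
  db <- small_db()
  expect_gte(length(db$models), 1)
  for (rec in db$models) {
    m <- with_gbar(db$template, rec$gbar)
    tm <- trace_metrics(simulate_neuron(m, t_total = 15000, burnin = 5000))
    expect_true(is.finite(tm$burst_period))
    expect_gte(tm$n_spikes_per_burst, 2)
    expect_lt(abs(tm$burst_period / rec$metrics$burst_period - 1), 0.01)
  }
})

test_that("a database round-trips through disk losslessly", {
  db <- small_db()
  dir <- withr::local_tempdir()
  save_model_db(db, dir)
  db2 <- load_model_db(dir, template = db$template)
  expect_identical(length(db2$models), length(db$models))
  for (k in seq_along(db$models)) {
    expect_equal(db2$models[[k]]$gbar, db$models[[k]]$gbar)
    expect_equal(db2$models[[k]]$mean_Ca, db$models[[k]]$mean_Ca)
  }
  expect_identical(db2$seed, db$seed)
  # schema versioning is enforced
  mf <- file.path(dir, "manifest.json")
  j <- jsonlite::read_json(mf)
  j$schema <- "something-else"
  jsonlite::write_json(j, mf, auto_unbox = TRUE)
  expect_error(load_model_db(dir, template = db$template), "schema")
})

test_that("an exhausted draw budget returns a partial database with a warning", {
  tg <- ref_targets_fx()
  cfg <- db_config(template = ref_model_fx(), n = 50,
                   target_period = tg$period, target_duty = tg$duty,
                   max_draws = 10)
  expect_warning(db <- generate_model_db(cfg, seed = 3), "budget")
  expect_lt(length(db$models), 50)
})
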