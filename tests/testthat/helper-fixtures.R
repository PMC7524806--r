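# Memoised fixtures shared across test files. Everything is generated in
# code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

ref_model_fx <- function() fixture("ref_model", reference_model())

# reference targets: burst period, duty cycle, calcium target (30 s window)
ref_targets_fx <- function() {
  fixture("ref_targets", reference_targets(ref_model_fx()))
}

ref_reg_fx <- function() {
  fixture("ref_reg", {
    tg <- ref_targets_fx()
    regulation_state(ref_model_fx(), Ca_target = tg$Ca_target)
  })
}

# seeded 30-model database + ray census, shared by the acceptance tests
acc_db_fx <- function() {
  fixture("acc_db", {
    tg <- ref_targets_fx()
    cfg <- db_config(template = ref_model_fx(),
                     target_period = tg$period, target_duty = tg$duty)
    generate_model_db(cfg, seed = 42)
  })
}

acc_census_fx <- function() fixture("acc_census", ray_census(acc_db_fx()))
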