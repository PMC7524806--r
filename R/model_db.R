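#' Database configuration
#'
#' Random model databases are drawn from a hypercube in the 8-dimensional
#' space of conductance densities and kept when their intrinsic dynamics
#' fall within tolerance of a target bursting behaviour.
#'
#' @param template A [neuron_model()] providing geometry, calcium handling
#'   and the hypercube centre; bounds default to `[0, 2] x` its
#'   conductances.
#' @param lower,upper Named per-channel hypercube bounds (uS/mm^2).
#' @param target_period,target_duty Target burst period (ms) and duty
#'   cycle. Defaults are computed from the template via
#'   [reference_targets()] when omitted.
#' @param tol_period,tol_duty Relative acceptance tolerances (default 20%).
#' @param n Requested number of accepted models.
#' @param t_total,burnin Evaluation simulation window, ms.
#' @param prescreen_t Total time of the cheap prescreen simulation, ms; a
#'   draw proceeds to full evaluation only if the prescreen shows spiking
#'   with burst-like interspike-interval structure. Set to 0 to disable.
#' @param max_draws Draw budget; generation stops (with a warning) when it
#'   is exhausted.
#' @return List of class `db_config`.
#' @export
db_config <- function(template = reference_model(),
                      lower = 0 * template$gbar,
                      upper = 2 * template$gbar,
                      target_period = NULL, target_duty = NULL,
                      tol_period = 0.2, tol_duty = 0.2,
                      n = 30, t_total = 15000, burnin = 5000,
                      prescreen_t = 6000, max_draws = 5000) {
  stopifnot(all(lower >= 0), all(upper >= lower), tol_period > 0,
            tol_duty > 0, n >= 1)
  if (is.null(target_period) || is.null(target_duty)) {
    tgt <- reference_targets(template)
    target_period <- tgt$period
    target_duty <- tgt$duty
  }
  structure(
    list(template = template, lower = lower, upper = upper,
         target_period = target_period, target_duty = target_duty,
         tol_period = tol_period, tol_duty = tol_duty,
         n = n, t_total = t_total, burnin = burnin,
         prescreen_t = prescreen_t, max_draws = max_draws),
    class = "db_config"
  )
}

#' Generate a database of similar bursting models
#'
#' Seeded rejection sampling: points are drawn uniformly from the
#' hypercube, simulated, and kept when they burst regularly with period and
#' duty cycle within the configured tolerances of the target. Each accepted
#' record stores its conductances, burst metrics, and its own mean calcium
#' (the record's regulation target).
#'
#' @param cfg A [db_config()].
#' @param seed RNG seed (integer); the database is fully reproducible from
#'   it.
#' @param progress Print progress every 50 draws.
#' @return List of class `model_db`: `models` (list of records with `gbar`,
#'   `metrics`, `mean_Ca`, `draw`), `template`, `cfg`, `seed`, `n_draws`,
#'   `acceptance` (accepted / draws).
#' @export
generate_model_db <- function(cfg = db_config(), seed = 1, progress = FALSE) {
  stopifnot(inherits(cfg, "db_config"))
  seed <- as.integer(seed)
  set.seed(seed)
  cls_cfg <- classifier_config(target_period = cfg$target_period,
                               target_duty = cfg$target_duty)
  accepted <- list()
  draw <- 0L
  while (length(accepted) < cfg$n && draw < cfg$max_draws) {
    draw <- draw + 1L
    g <- cfg$lower + runif(8) * (cfg$upper - cfg$lower)
    model <- with_gbar(cfg$template, g)
    if (cfg$prescreen_t > 0 && !prescreen_burster(model, cfg)) next
    res <- simulate_neuron(model, t_total = cfg$t_total,
                           burnin = cfg$burnin)
    if (isTRUE(res$diverged)) next
    m <- trace_metrics(res, cls_cfg)
    if (!accept_record(m, cfg)) next
    accepted[[length(accepted) + 1L]] <- list(
      gbar = model$gbar, metrics = m, mean_Ca = m$mean_Ca, draw = draw)
    if (progress) {
      message(sprintf("accepted %d/%d at draw %d",
                      length(accepted), cfg$n, draw))
    }
  }
  if (length(accepted) < cfg$n) {
    warning(sprintf("draw budget exhausted: %d of %d models accepted",
                    length(accepted), cfg$n))
  }
  structure(
    list(models = accepted, template = cfg$template, cfg = cfg,
         seed = seed, n_draws = draw,
         acceptance = length(accepted) / draw),
    class = "model_db"
  )
}

# cheap reject: short run must spike and show burst-like ISI structure
prescreen_burster <- function(model, cfg) {
  res <- simulate_neuron(model, t_total = cfg$prescreen_t,
                         burnin = cfg$prescreen_t / 3)
  if (isTRUE(res$diverged)) return(FALSE)
  post <- res$t > res$burnin
  spk <- detect_spikes(res$t[post], res$V[post])
  if (length(spk) < 6) return(FALSE)
  isi <- diff(spk)
  max(isi) > 3 * median(isi)
}

accept_record <- function(m, cfg) {
  is.finite(m$burst_period) && is.finite(m$duty_cycle) &&
    isTRUE(m$regular) && m$n_spikes_per_burst >= 2 &&
    abs(m$burst_period - cfg$target_period) <=
      cfg$tol_period * cfg$target_period &&
    abs(m$duty_cycle - cfg$target_duty) <= cfg$tol_duty * cfg$target_duty
}

#' Save a model database
#'
#' Writes a CSV of conductances and metrics plus a JSON manifest carrying
#' the seed, bounds, tolerances and schema version.
#'
#' @param db A `model_db`.
#' @param path Directory to write `models.csv` and `manifest.json` into.
#' @return The path, invisibly.
#' @export
save_model_db <- function(db, path) {
  stopifnot(inherits(db, "model_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(seq_along(db$models), function(k) {
    rec <- db$models[[k]]
    cbind(data.frame(model = k, draw = rec$draw),
          as.data.frame(as.list(rec$gbar)),
          metrics_row(rec$metrics))
  }))
  write.csv(tab, file.path(path, "models.csv"), row.names = FALSE)
  manifest <- list(
    schema = "calreg-db-1",
    seed = db$seed, n_draws = db$n_draws, acceptance = db$acceptance,
    n = length(db$models),
    lower = as.list(db$cfg$lower), upper = as.list(db$cfg$upper),
    target_period = db$cfg$target_period, target_duty = db$cfg$target_duty,
    tol_period = db$cfg$tol_period, tol_duty = db$cfg$tol_duty,
    t_total = db$cfg$t_total, burnin = db$cfg$burnin
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model database
#'
#' @param path Directory written by [save_model_db()].
#' @param template A [neuron_model()] supplying geometry and calcium
#'   parameters (must match the generating configuration).
#' @return A `model_db` (records carry the stored metrics table rather than
#'   full `trace_metrics` objects, plus `gbar` and `mean_Ca`).
#' @export
load_model_db <- function(path, template = reference_model()) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$schema, "calreg-db-1")) {
    stop("unrecognised database schema: ", manifest$schema)
  }
  tab <- read.csv(file.path(path, "models.csv"), stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(k) {
    row <- tab[k, ]
    list(gbar = setNames(as.numeric(row[channel_names()]), channel_names()),
         metrics = as.list(row[c("burst_period", "duty_cycle",
                                 "n_spikes_per_burst", "cv_period",
                                 "mean_Ca", "state_label")]),
         mean_Ca = row$mean_Ca, draw = row$draw)
  })
  structure(
    list(models = models, template = template,
         cfg = manifest, seed = manifest$seed, n_draws = manifest$n_draws,
         acceptance = manifest$acceptance),
    class = "model_db"
  )
}

#' @export
print.model_db <- function(x, ...) {
  cat(sprintf("<model_db> %d bursting models (seed %s, %d draws, %.1f%% accepted)\n",
              length(x$models), x$seed, x$n_draws, 100 * x$acceptance))
  invisible(x)
}
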