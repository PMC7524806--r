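#' Summarise a high-dimensional perturbation
#'
#' A perturbation from baseline conductances `g0` to `g` is summarised by
#' the mean and the standard deviation (with N - 1 in the denominator) of
#' the per-channel relative changes `(g - g0) / g0`. Pure size changes are
#' exactly the perturbations with zero standard deviation.
#'
#' @param g0 Baseline conductance densities (strictly positive).
#' @param g Perturbed conductance densities.
#' @return List of class `perturbation_summary`: `mu`, `sigma`,
#'   `relative` (per-channel changes).
#' @export
summarise_perturbation <- function(g0, g) {
  stopifnot(length(g0) == length(g), all(g0 > 0))
  rel <- (g - g0) / g0
  structure(
    list(mu = mean(rel), sigma = sd(rel), relative = rel),
    class = "perturbation_summary"
  )
}

#' Sample perturbations with exact moments
#'
#' Draws per-channel relative changes from a normal distribution and
#' re-standardises them so the realised mean and standard deviation match
#' the request exactly. Draws producing a negative conductance are
#' resampled (up to `max_tries`); a request whose dispersion persistently
#' forces negative conductances errors out.
#'
#' @param model Baseline [neuron_model()].
#' @param mu Target mean relative change.
#' @param sigma Target standard deviation of relative changes (>= 0).
#' @param n Number of perturbed models.
#' @param seed RNG seed.
#' @param max_tries Resampling cap per perturbation.
#' @return List of `neuron_model`s, each with attribute `"summary"` (its
#'   [summarise_perturbation()] against the baseline).
#' @export
sample_perturbations <- function(model, mu, sigma, n = 1, seed = 1,
                                 max_tries = 1000) {
  stopifnot(inherits(model, "neuron_model"), sigma >= 0, n >= 1,
            all(model$gbar > 0))
  set.seed(seed)
  nc <- length(model$gbar)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("could not sample a non-negative perturbation with mu = ",
             mu, ", sigma = ", sigma)
      }
      if (sigma == 0) {
        rel <- rep(mu, nc)
      } else {
        z <- rnorm(nc)
        z <- (z - mean(z)) / sd(z)     # exact re-standardisation
        rel <- mu + sigma * z
      }
      g <- model$gbar * (1 + rel)
      if (all(g >= 0)) break
    }
    m <- with_gbar(model, g)
    attr(m, "summary") <- summarise_perturbation(model$gbar, g)
    out[[k]] <- m
  }
  out
}

#' Recovery from a perturbation under homeostasis
#'
#' Runs the closed loop (no growth) from the perturbed conductances until
#' convergence, then classifies the terminal dynamics and reports the
#' terminal burst period.
#'
#' @param perturbed A perturbed [neuron_model()] (e.g. from
#'   [sample_perturbations()]).
#' @param reg A [regulation_state()] from the unperturbed reference.
#' @param cfg A [classifier_config()] with the reference targets.
#' @param t_max Maximum closed-loop time, ms.
#' @param t_total,burnin Classification window, ms.
#' @return List: `terminal_period` (ms, NA if not bursting),
#'   `terminal_duty`, `state_label`, `converged`, `g_final`.
#' @export
recovery_experiment <- function(perturbed, reg, cfg, t_max = 300000,
                                t_total = 15000, burnin = 5000) {
  tr <- integrate_closed_loop(perturbed, reg, t_total = t_max)
  if (tr$diverged) {
    return(list(terminal_period = NA_real_, terminal_duty = NA_real_,
                state_label = "nonconvergent", converged = FALSE,
                g_final = tr$g_final))
  }
  m <- trace_metrics(
    simulate_neuron(tr$model_final, t_total = t_total, burnin = burnin),
    cfg)
  list(terminal_period = m$burst_period, terminal_duty = m$duty_cycle,
       state_label = m$state_label, converged = tr$converged,
       g_final = tr$g_final)
}

#' Mean/variance perturbation-recovery sweep
#'
#' For each (mu, sigma) cell, samples `n_each` perturbations, runs the
#' recovery experiment, and tabulates terminal outcomes. The headline
#' property is that recovery failure tracks sigma (ratio-disrupting
#' perturbations), not mu (size-change-like perturbations).
#'
#' @param model Reference [neuron_model()].
#' @param reg,cfg Regulation state and classifier from the reference.
#' @param mu_grid,sigma_grid Sweep grids.
#' @param n_each Perturbations per cell.
#' @param seed Base RNG seed.
#' @param ... Passed to [recovery_experiment()].
#' @return Data.frame: mu, sigma, realised moments, terminal period/duty,
#'   state label, relative period error.
#' @export
perturbation_sweep <- function(model, reg, cfg,
                               mu_grid = c(-0.5, 0, 0.5, 1),
                               sigma_grid = c(0, 0.25, 0.5, 1),
                               n_each = 3, seed = 1, ...) {
  rows <- list()
  cell <- 0
  for (mu in mu_grid) for (sg in sigma_grid) {
    cell <- cell + 1
    ms <- tryCatch(
      sample_perturbations(model, mu, sg, n = n_each,
                           seed = seed + 7919L * cell),
      error = function(e) NULL)
    if (is.null(ms)) {
      # dispersion too large for the mean: no non-negative realisation
      rows[[length(rows) + 1]] <- data.frame(
        mu = mu, sigma = sg, mu_real = NA_real_, sigma_real = NA_real_,
        terminal_period = NA_real_, terminal_duty = NA_real_,
        state_label = "infeasible", period_error = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    for (m in ms) {
      res <- recovery_experiment(m, reg, cfg, ...)
      s <- attr(m, "summary")
      rows[[length(rows) + 1]] <- data.frame(
        mu = mu, sigma = sg, mu_real = s$mu, sigma_real = s$sigma,
        terminal_period = res$terminal_period,
        terminal_duty = res$terminal_duty,
        state_label = res$state_label,
        period_error = abs(res$terminal_period / cfg$target_period - 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
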