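#' Construct a single-compartment neuron model
#'
#' A point in the 8-dimensional space of maximal conductance densities,
#' together with cell geometry and calcium-handling parameters. Voltage
#' dynamics follow `Cm * dV/dt = -sum_i gbar_i m_i^p h_i^q (V - E_i)` and
#' intracellular calcium follows the thin-shell balance
#' `dCa/dt = -phi * i_Ca * A / (2 F eta) - (Ca - Ca_inf) / tau_Ca`.
#'
#' Because the voltage equation is written in densities, the dynamics are
#' independent of absolute size as long as the ratio `A / eta` is fixed
#' (the thin-shell assumption): growth only matters through dilution of
#' total conductance.
#'
#' @param gbar Named numeric vector of maximal conductance densities
#'   (uS/mm^2) for channels `A, CaS, CaT, H, Kd, Leak, NaV, KCa`. Missing
#'   names default to 0.
#' @param geometry List with `A` (membrane area, mm^2) and `eta` (thin-shell
#'   calcium volume, mm^3).
#' @param ca_params List with `phi` (dimensionless flux prefactor), `tau_Ca`
#'   (buffering timescale, ms), `Ca_inf` (resting calcium, uM) and `Ca_out`
#'   (extracellular calcium, uM, for the Nernst reversal).
#' @param Cm Specific membrane capacitance, nF/mm^2.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(gbar,
                         geometry = default_geometry(),
                         ca_params = default_ca_params(),
                         Cm = 10) {
  full <- stats::setNames(numeric(8), channel_names())
  if (is.null(names(gbar))) {
    stopifnot(length(gbar) == 8)
    full[] <- as.numeric(gbar)
  } else {
    stopifnot(all(names(gbar) %in% channel_names()))
    full[names(gbar)] <- as.numeric(gbar)
  }
  if (any(!is.finite(full)) || any(full < 0)) {
    stop("conductance densities must be finite and non-negative")
  }
  stopifnot(geometry$A > 0, geometry$eta > 0, Cm > 0,
            ca_params$phi > 0, ca_params$tau_Ca > 0,
            ca_params$Ca_inf > 0, ca_params$Ca_out > 0)
  structure(
    list(gbar = full, geometry = geometry, ca_params = ca_params, Cm = Cm),
    class = "neuron_model"
  )
}

#' Default cell geometry
#'
#' Membrane area of a compact stomatogastric-type soma and a thin calcium
#' shell roughly 1.1 um deep, chosen so the calcium flux prefactor matches
#' the published model lineage this package follows.
#'
#' @return List with `A` (mm^2) and `eta` (mm^3).
#' @export
default_geometry <- function() {
  list(A = 0.0628, eta = 0.0628 * 1.103e-3)
}

#' Default calcium handling parameters
#'
#' @return List with `phi` (dimensionless), `tau_Ca` (ms), `Ca_inf` (uM),
#'   `Ca_out` (uM).
#' @export
default_ca_params <- function() {
  list(phi = 0.2, tau_Ca = 200, Ca_inf = 0.05, Ca_out = 3000)
}

#' The reference bursting model
#'
#' The canonical burster all plane, basin and silent-state analyses are
#' anchored to, with maximal conductance densities (uS/mm^2):
#' gA = 379, gCaS = 165, gCaT = 2.35, gH = 0.72, gKCa = 297, gKd = 1713,
#' gLeak = 0.46, gNaV = 1370.
#'
#' @inheritParams neuron_model
#' @return A `neuron_model`.
#' @export
reference_model <- function(geometry = default_geometry(),
                            ca_params = default_ca_params(),
                            Cm = 10) {
  neuron_model(
    c(A = 379, CaS = 165, CaT = 2.35, H = 0.72,
      Kd = 1713, Leak = 0.46, NaV = 1370, KCa = 297),
    geometry = geometry, ca_params = ca_params, Cm = Cm
  )
}

#' Replace the conductance densities of a model
#'
#' @param model A [neuron_model()].
#' @param gbar New conductance-density vector (named or in canonical order).
#' @return A `neuron_model` with the same geometry/calcium parameters.
#' @export
with_gbar <- function(model, gbar) {
  neuron_model(gbar, geometry = model$geometry,
               ca_params = model$ca_params, Cm = model$Cm)
}

#' Simulate a neuron model
#'
#' Integrates the voltage, gating and calcium equations with the exponential
#' Euler method at a fixed time step. Gating variables are clipped to [0, 1]
#' after every step; integration aborts and flags divergence if |V| exceeds
#' 500 mV.
#'
#' @param model A [neuron_model()].
#' @param t_total Total simulated time, ms.
#' @param dt Time step, ms (default 0.05).
#' @param burnin Initial transient discarded from averages, ms.
#' @param init Initial state: `NULL` for the default (V = -60 mV,
#'   Ca = Ca_inf, gates at steady state), a length-2 vector `c(V, Ca)`
#'   (gates at steady state for that point), or a full state vector
#'   `c(V, Ca, m[8], h[8])`.
#' @param record If `TRUE` (default) return the V and Ca traces; the trace
#'   is recorded every `record_stride` steps.
#' @param record_stride Integer stride between recorded samples.
#' @return A `sim_result` list: `t`, `V`, `Ca` (traces), `mean_Ca` (time
#'   average of calcium after burn-in, at full dt resolution), `dt`,
#'   `burnin`, `diverged`, `t_end`, `final_state`.
#' @export
simulate_neuron <- function(model, t_total = 20000, dt = 0.05,
                            burnin = 5000, init = NULL,
                            record = TRUE, record_stride = 1L) {
  stopifnot(inherits(model, "neuron_model"), dt > 0, t_total > burnin)
  if (is.null(init)) init <- numeric(0)
  res <- .sim_neuron_cpp(
    model$gbar, model$Cm, model$geometry$A, model$geometry$eta,
    model$ca_params$phi, model$ca_params$tau_Ca, model$ca_params$Ca_inf,
    model$ca_params$Ca_out, dt, t_total, burnin, as.numeric(init),
    if (record) as.integer(record_stride) else 0L
  )
  res$dt <- dt
  res$burnin <- burnin
  class(res) <- "sim_result"
  res
}

#' Time-averaged intracellular calcium
#'
#' The long-run mean of the calcium trace after the burn-in window; for the
#' reference dynamics this average defines `Ca_target`, the set point of the
#' regulation system.
#'
#' @param x A `sim_result` from [simulate_neuron()], or a `neuron_model`
#'   (which is then simulated with the given arguments).
#' @param ... Passed to [simulate_neuron()] when `x` is a model.
#' @return Mean calcium, uM (`NA` if the simulation diverged).
#' @export
mean_calcium <- function(x, ...) {
  if (inherits(x, "neuron_model")) {
    x <- simulate_neuron(x, record = FALSE, ...)
  }
  stopifnot(inherits(x, "sim_result"))
  x$mean_Ca
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %.1f s simulated (dt = %g ms, burn-in %.1f s)%s\n",
    x$t_end / 1000, x$dt, x$burnin / 1000,
    if (isTRUE(x$diverged)) " [DIVERGED]" else ""
  ))
  cat(sprintf("  mean [Ca] after burn-in: %.3f uM\n", x$mean_Ca))
  invisible(x)
}

#' Export a simulation trace to CSV
#'
#' @param result A `sim_result` with recorded traces.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "sim_result"), length(result$t) > 0)
  utils::write.csv(
    data.frame(t = result$t, V = result$V, Ca = result$Ca),
    path, row.names = FALSE
  )
  invisible(path)
}
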