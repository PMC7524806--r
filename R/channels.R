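#' Channel complement of the model
#'
#' The model carries eight conductances of the crustacean stomatogastric
#' lineage: a transient potassium current (A), slow and transient calcium
#' currents (CaS, CaT), a hyperpolarisation-activated inward current (H), a
#' delayed-rectifier potassium current (Kd), a passive leak, a fast sodium
#' current (NaV), and a calcium-gated potassium current (KCa). Only CaS and
#' CaT flux calcium into the cell.
#'
#' @return Character vector of the eight channel names, in the canonical
#'   order used throughout the package.
#' @export
channel_names <- function() {
  c("A", "CaS", "CaT", "H", "Kd", "Leak", "NaV", "KCa")
}

#' Channel gating structure
#'
#' Static description of each channel: activation exponent `p`, inactivation
#' exponent `q`, fixed reversal potential `E` (mV; `NA` for the calcium
#' channels, whose reversal follows the Nernst potential of the instantaneous
#' calcium concentration), and whether the channel carries calcium.
#'
#' @return A data.frame with one row per channel.
#' @export
channel_specs <- function() {
  data.frame(
    name = channel_names(),
    p = c(3L, 3L, 3L, 1L, 4L, 0L, 3L, 4L),
    q = c(1L, 1L, 1L, 0L, 0L, 0L, 1L, 0L),
    E = c(-80, NA, NA, -20, -80, -50, 50, -80),
    carries_calcium = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Steady-state gating and time constants
#'
#' Evaluates the voltage (and, for KCa, calcium) dependent steady-state
#' activation/inactivation and their time constants for all eight channels.
#' Kinetics follow the published stomatogastric channel equations used by
#' this model family; KCa activation is scaled by `Ca / (Ca + 3 uM)`.
#'
#' @param V Membrane potential, mV (scalar).
#' @param Ca Intracellular calcium, uM (scalar, > 0).
#' @return A list with numeric vectors `m_inf`, `h_inf` (dimensionless, in
#'   [0, 1]) and `tau_m`, `tau_h` (ms), each named by channel. Channels
#'   without a gate report 1 for the steady state and 1 ms for the time
#'   constant (never used by the integrator).
#' @export
steady_state <- function(V, Ca) {
  stopifnot(is.finite(V), is.finite(Ca), Ca > 0)
  g <- .gating_cpp(V, Ca)
  lapply(g, function(x) stats::setNames(x, channel_names()))
}

#' Nernst reversal potential for calcium
#'
#' @param Ca Intracellular calcium, uM.
#' @param Ca_out Extracellular calcium, uM (default 3 mM).
#' @return Reversal potential, mV.
#' @export
nernst_ca <- function(Ca, Ca_out = 3000) {
  12.199 * log(Ca_out / Ca)
}

#' Steady-state membrane current densities
#'
#' Total and calcium-only current density (outward positive, nA/mm^2) with
#' every gate at its steady state for the given voltage and with intracellular
#' calcium frozen at `Ca` (which sets both KCa activation and the calcium
#' reversal potential). This is the right-hand side used by the analytical
#' silent-state solver.
#'
#' @param model A [neuron_model()].
#' @param V Membrane potential(s), mV; vectorised.
#' @param Ca Frozen intracellular calcium, uM.
#' @return A list with numeric vectors `i_total` and `i_ca` (nA/mm^2).
#' @export
steady_state_currents <- function(model, V, Ca) {
  stopifnot(all(is.finite(V)), is.finite(Ca), Ca > 0)
  .ss_currents_cpp(model$gbar, as.numeric(V), Ca, model$ca_params$Ca_out)
}

#' Total calcium current density at a given state
#'
#' Sum over the two calcium-carrying channels (CaS, CaT) of
#' `gbar * m^p * h^q * (V - E_Ca)`, with gates at steady state for
#' (`V`, `Ca`) and `E_Ca` from the Nernst potential at `Ca`.
#'
#' @inheritParams steady_state_currents
#' @return Calcium current density, nA/mm^2 (outward positive; influx is
#'   negative).
#' @export
total_calcium_current_density <- function(model, V, Ca) {
  steady_state_currents(model, V, Ca)$i_ca
}
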