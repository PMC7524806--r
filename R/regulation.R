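#' Regulation state: timescales and calcium target
#'
#' The master regulator senses the deviation of intracellular calcium from
#' `Ca_target` and transcribes mRNA for every channel:
#' `tau_mu_i * dmu_i/dt = Ca_target - Ca`, and conductance follows mRNA as
#' `tau_g * dg_i/dt = mu_i - g_i`. Transcription timescales are tied to the
#' model's own conductances, `tau_mu_i = constant / gbar_i`, which makes the
#' model's conductance ratios a fixed direction of the controller: for any
#' pair, `g_j / g_i = tau_mu_i / tau_mu_j`.
#'
#' @param model A [neuron_model()] whose conductances set the timescales.
#' @param constant Timescale constant, ms (default 5000).
#' @param tau_g Translation timescale, ms (default 5000).
#' @param Ca_target Calcium set point, uM (normally the model's own
#'   long-run mean calcium; may be set later).
#' @param regulate Character vector of regulated channels (default all 8;
#'   set to `setdiff(channel_names(), "Leak")` to exclude the leak).
#' @return List of class `regulation_state` with per-channel `tau_mu` (ms;
#'   `Inf` for unregulated channels, which then never move), `tau_g`,
#'   `Ca_target`.
#' @export
regulation_state <- function(model, constant = 5000, tau_g = 5000,
                             Ca_target = NA_real_,
                             regulate = channel_names()) {
  stopifnot(inherits(model, "neuron_model"), constant > 0, tau_g > 0,
            all(regulate %in% channel_names()))
  g <- model$gbar[regulate]
  if (any(g <= 0)) {
    stop("regulated channels must have strictly positive conductance ",
         "(zero conductance implies an infinite transcription timescale)")
  }
  tau_mu <- setNames(rep(Inf, 8), channel_names())
  tau_mu[regulate] <- constant / g
  structure(
    list(tau_mu = tau_mu, tau_g = tau_g, Ca_target = Ca_target,
         mu = model$gbar),
    class = "regulation_state"
  )
}

#' Growth parameters
#'
#' @param k Relative linear growth rate of membrane area and shell volume,
#'   per ms: `dA/dt = k * A0`, `deta/dt = k * eta0`, which conserves the
#'   thin-shell ratio A/eta exactly.
#' @param r_growth,r Open-loop effector rates: membrane production rate and
#'   per-channel conductance production rates (total uS per ms).
#' @return List of class `growth_params`.
#' @export
growth_params <- function(k = 0, r_growth = NULL, r = NULL) {
  stopifnot(k >= 0)
  structure(list(k = k, r_growth = r_growth, r = r), class = "growth_params")
}

#' The four growth rates used in the growth experiments
#'
#' @return Numeric vector of relative growth rates (per ms).
#' @export
growth_rates <- function() c(1e-7, 5e-6, 1e-6, 5e-5)

#' Integrate the closed-loop regulated neuron
#'
#' Co-integrates the membrane/calcium equations with the mRNA and
#' conductance dynamics (and, optionally, linear growth of `A` and `eta`).
#' mRNA and conductance state are in density units; growth enters as a
#' dilution term `-(dA/dt / A) g_i` on each density (new membrane dilutes
#' existing channels, and the calcium error then drives resynthesis). mRNA
#' and conductances are clipped at zero.
#'
#' @param model Starting [neuron_model()] (its `gbar` is the initial
#'   condition; timescales normally come from the reference model via
#'   [regulation_state()]).
#' @param reg A [regulation_state()] with `Ca_target` set.
#' @param growth A [growth_params()] (default: no growth).
#' @param t_total Maximum simulated time, ms.
#' @param dt Time step, ms.
#' @param log_every Logging stride for the trajectory, ms.
#' @param check_every Convergence check stride, ms.
#' @param tol_drift Convergence declared when the maximum relative change of
#'   any conductance density between checks falls below this (only with
#'   `k = 0`).
#' @param min_time Earliest time convergence may be declared, ms.
#' @return List of class `regulation_trajectory`: `log` (data.frame with t,
#'   per-channel densities, A, windowed mean Ca), `g_final` (densities),
#'   `A_final`, `eta_final`, `converged`, `diverged`, `t_end`, and
#'   `model_final` (a `neuron_model` at the terminal densities and size).
#' @export
integrate_closed_loop <- function(model, reg, growth = growth_params(),
                                  t_total = 300000, dt = 0.05,
                                  log_every = 250, check_every = 10000,
                                  tol_drift = 0.005, min_time = 50000) {
  stopifnot(inherits(model, "neuron_model"), inherits(reg, "regulation_state"),
            is.finite(reg$Ca_target))
  res <- .sim_closed_loop_cpp(
    model$gbar, reg$tau_mu, reg$tau_g, reg$Ca_target, growth$k,
    model$Cm, model$geometry$A, model$geometry$eta,
    model$ca_params$phi, model$ca_params$tau_Ca, model$ca_params$Ca_inf,
    model$ca_params$Ca_out, dt, t_total, log_every, check_every,
    tol_drift, min_time, numeric(0)
  )
  log <- as.data.frame(res$log)
  names(log) <- c("t", channel_names(), "A", "mean_Ca_window")
  out <- list(
    log = log,
    g_final = setNames(as.numeric(res$g_final), channel_names()),
    A_final = res$A_final, eta_final = res$eta_final,
    Ca_final = res$Ca_final,
    converged = isTRUE(res$converged), diverged = isTRUE(res$diverged),
    t_end = res$t_end,
    model_final = neuron_model(
      setNames(as.numeric(res$g_final), channel_names()),
      geometry = list(A = res$A_final, eta = res$eta_final),
      ca_params = model$ca_params, Cm = model$Cm
    )
  )
  class(out) <- "regulation_trajectory"
  out
}

#' Direction of conductance motion for a channel pair
#'
#' Over a trajectory window, the controller moves conductances in a fixed
#' direction: `Delta g_j / Delta g_i` approaches `tau_mu_i / tau_mu_j`.
#' This measures the realised slope from the trajectory log.
#'
#' @param traj A `regulation_trajectory`.
#' @param i,j Channel names.
#' @param from,to Window bounds, ms (defaults: from 10% to the end of the
#'   log, skipping the initial translation transient).
#' @return List with `slope` (realised Delta g_j / Delta g_i; compare with
#'   tau_mu_i / tau_mu_j from the regulation state) and `theta` (atan2 of
#'   the motion, radians).
#' @export
trajectory_direction <- function(traj, i, j, from = NULL, to = NULL) {
  log <- traj$log
  if (is.null(from)) from <- log$t[1] + 0.1 * diff(range(log$t))
  if (is.null(to)) to <- max(log$t)
  w <- log$t >= from & log$t <= to
  dgi <- log[[i]][w][sum(w)] - log[[i]][w][1]
  dgj <- log[[j]][w][sum(w)] - log[[j]][w][1]
  list(slope = dgj / dgi, theta = atan2(dgj, dgi))
}

#' Integrate the open-loop co-regulation scheme
#'
#' A constant effector drive `E = 1` produces total conductance at rates
#' `r_i` and membrane area at rate `r_growth`, with no calcium feedback:
#' `dG_i/dt = r_i`, `dA/dt = r_growth` (and `eta` in proportion). The
#' densities are available in closed form; no membrane integration is
#' needed until the terminal state is classified.
#'
#' @param model Starting [neuron_model()].
#' @param rates A [growth_params()] with `r_growth` (mm^2/ms) and `r`
#'   (named uS/ms per channel, or a single scale applied to the tuned
#'   ratios).
#' @param t_total Duration, ms.
#' @param n_log Number of logged points.
#' @return List of class `regulation_trajectory` (same shape as the closed
#'   loop, `converged = NA`).
#' @export
integrate_open_loop <- function(model, rates, t_total = 300000, n_log = 200) {
  stopifnot(inherits(model, "neuron_model"), !is.null(rates$r_growth),
            !is.null(rates$r))
  A0 <- model$geometry$A
  G0 <- model$gbar * A0
  r <- setNames(rep(0, 8), channel_names())
  r[names(rates$r)] <- rates$r
  tt <- seq(0, t_total, length.out = n_log)
  A_t <- A0 + rates$r_growth * tt
  dens <- sapply(channel_names(), function(ch) (G0[[ch]] + r[[ch]] * tt) / A_t)
  log <- data.frame(t = tt, dens, A = A_t,
                    mean_Ca_window = NA_real_, check.names = FALSE)
  gf <- setNames(as.numeric(dens[n_log, ]), channel_names())
  Af <- A_t[n_log]
  out <- list(
    log = log, g_final = gf, A_final = Af,
    eta_final = model$geometry$eta * Af / A0,
    converged = NA, diverged = FALSE, t_end = t_total,
    model_final = neuron_model(
      gf, geometry = list(A = Af, eta = model$geometry$eta * Af / A0),
      ca_params = model$ca_params, Cm = model$Cm
    )
  )
  class(out) <- "regulation_trajectory"
  out
}

#' Tuned open-loop production rates for a model
#'
#' Chooses per-channel rates so that at growth rate `r_growth` the density
#' of every channel is preserved exactly: `r_i = gbar_i * r_growth`.
#'
#' @param model A [neuron_model()].
#' @param r_growth Membrane production rate, mm^2/ms.
#' @return A [growth_params()].
#' @export
tuned_open_loop_rates <- function(model, r_growth) {
  growth_params(k = 0, r_growth = r_growth, r = model$gbar * r_growth)
}

#' Export a regulation trajectory to CSV
#'
#' @param traj A `regulation_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj$log, path, row.names = FALSE)
  invisible(path)
}
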