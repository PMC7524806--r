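#' Voltages quenching the calcium dynamics
#'
#' In a silent state pinned at the calcium target, the calcium balance
#' requires the steady window-current influx through CaS and CaT to equal
#' the buffering loss: `phi * i_Ca(V) * A / (2 F eta) =
#' -(Ca_target - Ca_inf) / tau_Ca`, with gates at steady state and the
#' calcium reversal evaluated at the target concentration. Roots are
#' searched in [-80, 0] mV on a 0.5 mV bracketing grid refined by Brent's
#' method. An empty result is meaningful: below a critical calcium-channel
#' density the required influx is unattainable and no trapped silent state
#' exists.
#'
#' @param model A [neuron_model()].
#' @param Ca_target Calcium target, uM.
#' @param Vrange Search interval, mV.
#' @param grid Pre-scan resolution, mV.
#' @param Ca_for_gates Calcium used for steady-state gating and the Nernst
#'   reversal: `"target"` (default) or `"resting"`.
#' @return Numeric vector of roots V_Ca (possibly empty), sorted.
#' @export
solve_V_Ca <- function(model, Ca_target, Vrange = c(-80, 0), grid = 0.5,
                       Ca_for_gates = c("target", "resting")) {
  Ca_for_gates <- match.arg(Ca_for_gates)
  Ca_gate <- if (Ca_for_gates == "target") Ca_target else model$ca_params$Ca_inf
  coef <- with(model, ca_params$phi * geometry$A /
                 (2 * 96485 * geometry$eta))
  need <- (Ca_target - model$ca_params$Ca_inf) / model$ca_params$tau_Ca
  f <- function(V) {
    -coef * steady_state_currents(model, V, Ca_gate)$i_ca - need
  }
  find_roots(f, Vrange, grid)
}

#' Voltages quenching the voltage dynamics
#'
#' Roots of the total steady-state membrane current
#' `sum_i gbar_i m_inf^p h_inf^q (V - E_i) = 0` in [-80, 0] mV, with
#' intracellular calcium frozen at `Ca` (sets KCa activation and the
#' calcium reversal).
#'
#' @param model A [neuron_model()].
#' @param Ca Frozen calcium, uM (normally the calcium target).
#' @param Vrange Search interval, mV.
#' @param grid Pre-scan resolution, mV.
#' @return Numeric vector of roots V_V (possibly empty), sorted.
#' @export
solve_V_V <- function(model, Ca, Vrange = c(-80, 0), grid = 0.5) {
  f <- function(V) steady_state_currents(model, V, Ca)$i_total
  find_roots(f, Vrange, grid)
}

# bracketing grid + Brent refinement
find_roots <- function(f, range, grid) {
  V <- seq(range[1], range[2], by = grid)
  y <- f(V)
  ok <- is.finite(y)
  V <- V[ok]; y <- y[ok]
  if (length(V) < 2) return(numeric(0))
  idx <- which(y[-1] * y[-length(y)] < 0)
  roots <- vapply(idx, function(k) {
    uniroot(function(v) f(v), c(V[k], V[k + 1]), tol = 1e-11)$root
  }, numeric(1))
  exact <- V[y == 0]
  sort(unique(c(roots, exact)))
}

#' Marginal stability of the voltage fixed point
#'
#' Numerical derivative of the steady-state membrane current at V; since
#' `dV/dt = -i_total / Cm`, a positive current slope means the voltage
#' fixed point is locally attracting in the frozen-gating reduction.
#'
#' @param model A [neuron_model()].
#' @param V Voltage, mV.
#' @param Ca Frozen calcium, uM.
#' @param h Finite-difference step, mV.
#' @return `d i_total / dV` (uS/mm^2 equivalent).
#' @export
marginal_stability <- function(model, V, Ca, h = 1e-4) {
  ss <- steady_state_currents(model, c(V - h, V + h), Ca)
  (ss$i_total[2] - ss$i_total[1]) / (2 * h)
}

#' Analytical silent set in a plane
#'
#' Locus of plane points where a calcium-quenching voltage and a
#' voltage-quenching voltage coincide (|V_V - V_Ca| below the matching
#' tolerance), i.e. where a fully quenched (silent) state consistent with
#' the calcium target exists. For each x on a grid, the signed mismatch of
#' the closest (V_V, V_Ca) pair is tracked along y and its zero crossings
#' are refined by bisection.
#'
#' @param plane A [plane_def()] (the calcium channels must all sit in one
#'   group; they do by default).
#' @param Ca_target Calcium target, uM.
#' @param resolution Number of grid points per axis.
#' @param tol Matching tolerance on |V_V - V_Ca|, mV.
#' @param Ca_for_gates Passed to [solve_V_Ca()].
#' @return Data.frame of class `silent_set`: `x`, `y`, `V_Ca`, `V_V`,
#'   `mismatch` (mV), `dIdV` (marginal stability of the voltage equation).
#'   Zero rows when no silent state exists in the plane.
#' @export
silent_set <- function(plane, Ca_target, resolution = 40, tol = 0.05,
                       Ca_for_gates = "target") {
  stopifnot(inherits(plane, "plane_def"))
  ca_in_y <- all(c("CaS", "CaT") %in% plane$group_y)
  ca_in_x <- all(c("CaS", "CaT") %in% plane$group_x)
  if (!ca_in_y && !ca_in_x) {
    stop("the calcium channels must lie in a single plane group")
  }
  # coordinate driving the calcium equation vs the free coordinate
  if (ca_in_y) {
    ca_seq <- seq(plane$ylim[1], plane$ylim[2], length.out = resolution)
    free_lim <- plane$xlim
  } else {
    ca_seq <- seq(plane$xlim[1], plane$xlim[2], length.out = resolution)
    free_lim <- plane$ylim
  }
  at <- function(ca, free) if (ca_in_y) c(free, ca) else c(ca, free)
  rows <- list()
  for (ca_coord in ca_seq) {
    g_ca <- plane_gbar(plane, at(ca_coord, free_lim[1])[1],
                       at(ca_coord, free_lim[1])[2])
    m_ca <- with_gbar(plane$model, g_ca)
    vca <- solve_V_Ca(m_ca, Ca_target, Ca_for_gates = Ca_for_gates)
    if (length(vca) == 0) next
    mismatch <- function(free) {
      xy <- at(ca_coord, free)
      m <- with_gbar(plane$model, plane_gbar(plane, xy[1], xy[2]))
      vv <- solve_V_V(m, Ca_target)
      if (length(vv) == 0) return(NA_real_)
      d <- outer(vv, vca, "-")
      d[which.min(abs(d))]
    }
    free_grid <- seq(free_lim[1], free_lim[2], length.out = resolution)
    dvals <- vapply(free_grid, mismatch, numeric(1))
    ok <- is.finite(dvals)
    fg <- free_grid[ok]; dv <- dvals[ok]
    if (length(fg) < 2) next
    idx <- which(dv[-1] * dv[-length(dv)] < 0)
    for (k in idx) {
      lo <- fg[k]; hi <- fg[k + 1]; dlo <- dv[k]
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        dmid <- mismatch(mid)
        if (!is.finite(dmid)) break
        if (sign(dmid) == sign(dlo)) { lo <- mid; dlo <- dmid }
        else hi <- mid
        if (abs(dmid) < tol / 4) break
      }
      free_star <- (lo + hi) / 2
      xy <- at(ca_coord, free_star)
      m <- with_gbar(plane$model, plane_gbar(plane, xy[1], xy[2]))
      vv <- solve_V_V(m, Ca_target)
      vca2 <- solve_V_Ca(m, Ca_target, Ca_for_gates = Ca_for_gates)
      if (length(vv) == 0 || length(vca2) == 0) next
      d <- outer(vv, vca2, "-")
      best <- which(abs(d) == min(abs(d)), arr.ind = TRUE)[1, ]
      if (abs(d[best[1], best[2]]) > tol) next
      rows[[length(rows) + 1]] <- data.frame(
        x = xy[1], y = xy[2],
        V_V = vv[best[1]], V_Ca = vca2[best[2]],
        mismatch = d[best[1], best[2]],
        dIdV = marginal_stability(m, vv[best[1]], Ca_target))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(x = numeric(0), y = numeric(0), V_V = numeric(0),
               V_Ca = numeric(0), mismatch = numeric(0), dIdV = numeric(0))
  }
  class(out) <- c("silent_set", class(out))
  out
}

#' Check a silent solution by direct simulation
#'
#' Initialises the full model (no regulation) at the candidate silent
#' state — V at the voltage root, gates at steady state, calcium at the
#' target — and integrates for `t_total`. The state is labelled stable if
#' the membrane potential stays within `band` mV of the fixed point and no
#' spikes occur.
#'
#' @param model A [neuron_model()] at the silent-set point.
#' @param V Fixed-point voltage, mV.
#' @param Ca_target Calcium target, uM.
#' @param t_total Simulation length, ms (default 20 s).
#' @param band Allowed excursion, mV.
#' @return `"stable"` or `"unstable"` (divergent runs are unstable).
#' @export
validate_branch_by_simulation <- function(model, V, Ca_target,
                                          t_total = 20000, band = 2) {
  r <- simulate_neuron(model, t_total = t_total, burnin = 0,
                       init = c(V, Ca_target))
  if (isTRUE(r$diverged)) return("unstable")
  spk <- detect_spikes(r$t, r$V)
  if (length(spk) == 0 && all(abs(r$V - V) <= band)) "stable" else "unstable"
}

#' Label the branches of a silent set
#'
#' Runs [validate_branch_by_simulation()] at every row of a silent set.
#'
#' @param sset A `silent_set`.
#' @param plane The [plane_def()] it was computed on.
#' @param Ca_target Calcium target, uM.
#' @param ... Passed to [validate_branch_by_simulation()].
#' @return The silent set with a `branch` column (`stable` / `unstable`).
#' @export
label_silent_branches <- function(sset, plane, Ca_target, ...) {
  branch <- vapply(seq_len(nrow(sset)), function(k) {
    m <- with_gbar(plane$model, plane_gbar(plane, sset$x[k], sset$y[k]))
    validate_branch_by_simulation(m, sset$V_V[k], Ca_target, ...)
  }, character(1))
  sset$branch <- branch
  sset
}
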