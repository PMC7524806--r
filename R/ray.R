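#' Scan mean calcium along the growth ray
#'
#' Uniform scaling of all conductance densities is the signature of a size
#' change, and the only direction the master regulator can move in. For each
#' scale factor `s` the model is simulated with `gbar * s` (geometry fixed)
#' and the time-averaged calcium recorded, normalised by the regulation
#' target.
#'
#' @param model A [neuron_model()].
#' @param Ca_target Calcium target for normalisation, uM (default: the
#'   model's own mean calcium at scale 1, computed with the same window).
#' @param scales Scale factors (default 30 log-spaced points in [0.05, 3],
#'   with 1 inserted).
#' @param t_total,burnin Simulation window per scale point, ms.
#' @param metrics Also record burst metrics at each scale (needs traces;
#'   slightly slower).
#' @param cfg Classifier configuration used when `metrics = TRUE`.
#' @return List of class `ray_scan`: `scales`, `mean_Ca`, `norm_Ca`
#'   (mean_Ca / Ca_target, NA where the simulation diverged), `Ca_target`,
#'   optionally `metrics` (data.frame), plus the window settings.
#' @export
scan_ray <- function(model, Ca_target = NULL,
                     scales = ray_scales(),
                     t_total = 15000, burnin = 5000,
                     metrics = FALSE, cfg = classifier_config()) {
  stopifnot(inherits(model, "neuron_model"), length(scales) >= 2)
  scales <- sort(unique(c(scales, 1)))
  sim1 <- function(s, rec) {
    simulate_neuron(with_gbar(model, model$gbar * s),
                    t_total = t_total, dt = 0.05, burnin = burnin,
                    record = rec)
  }
  if (is.null(Ca_target)) Ca_target <- sim1(1, FALSE)$mean_Ca
  mca <- numeric(length(scales))
  mrows <- vector("list", length(scales))
  for (k in seq_along(scales)) {
    r <- sim1(scales[k], metrics)
    mca[k] <- if (isTRUE(r$diverged)) NA_real_ else r$mean_Ca
    if (metrics) mrows[[k]] <- metrics_row(trace_metrics(r, cfg))
  }
  out <- list(scales = scales, mean_Ca = mca, norm_Ca = mca / Ca_target,
              Ca_target = Ca_target, t_total = t_total, burnin = burnin)
  if (metrics) out$metrics <- cbind(scale = scales, do.call(rbind, mrows))
  class(out) <- "ray_scan"
  out
}

#' Default scale grid for ray scans
#'
#' @param n Number of points.
#' @param lo,hi Range of scale factors.
#' @return Log-spaced scale factors.
#' @export
ray_scales <- function(n = 30, lo = 0.05, hi = 3) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Fixed points of the regulator along the ray
#'
#' Fixed points are crossings of the calcium target by the mean-calcium
#' curve; a crossing with positive slope is stable (the controller's
#' negative feedback restores the scale), one with negative slope unstable.
#' Excursions beyond the target smaller than `noise_floor` (relative to the
#' target) are treated as simulation jitter and suppressed before crossing
#' detection. Detected crossings are refined by bisection with fresh
#' simulations.
#'
#' @param scan A `ray_scan`.
#' @param model The model the scan was computed from (needed for
#'   refinement; omit to skip refinement).
#' @param noise_floor Relative excursion below which a target crossing is
#'   ignored (default 0.03).
#' @param refine Number of bisection refinement steps per crossing
#'   (0 = interval midpoint from the scan grid).
#' @return A data.frame with columns `scale`, `stable`, `norm_Ca_lo`,
#'   `norm_Ca_hi` (one row per fixed point, ordered by scale).
#' @export
find_fixed_points <- function(scan, model = NULL, noise_floor = 0.03,
                              refine = 4) {
  stopifnot(inherits(scan, "ray_scan"), length(scan$scales) >= 10)
  ok <- is.finite(scan$norm_Ca)
  s <- scan$scales[ok]
  y <- scan$norm_Ca[ok] - 1   # signed distance from target
  if (length(s) < 2) return(empty_fp())
  # suppress jitter: flatten excursions smaller than the noise floor
  y[abs(y) < noise_floor] <- 0
  sgn <- sign(y)
  # carry last non-zero sign through flattened stretches
  run <- sgn
  for (k in seq_along(run)[-1]) if (run[k] == 0) run[k] <- run[k - 1]
  cross <- which(run[-1] != run[-length(run)] & run[-1] != 0 &
                   run[-length(run)] != 0)
  if (length(cross) == 0) return(empty_fp())
  rows <- lapply(cross, function(k) {
    lo <- s[k]; hi <- s[k + 1]
    ylo <- y[k]; yhi <- y[k + 1]
    # stability from the direction of the grid-level sign change: an upward
    # crossing (calcium rising with scale) is restored by the negative
    # feedback, a downward one is not
    stable <- run[k + 1] > run[k]
    if (!is.null(model) && refine > 0) {
      rsgn <- sign(run[k])
      for (it in seq_len(refine)) {
        mid <- sqrt(lo * hi)
        ymid <- mean_calcium(with_gbar(model, model$gbar * mid),
                             t_total = scan$t_total,
                             burnin = scan$burnin) / scan$Ca_target - 1
        if (!is.finite(ymid)) break
        if (sign(ymid) == rsgn || ymid == 0) { lo <- mid; ylo <- ymid }
        else { hi <- mid; yhi <- ymid }
      }
    }
    data.frame(scale = sqrt(lo * hi), stable = stable,
               norm_Ca_lo = ylo + 1, norm_Ca_hi = yhi + 1)
  })
  do.call(rbind, rows)
}

empty_fp <- function() {
  data.frame(scale = numeric(0), stable = logical(0),
             norm_Ca_lo = numeric(0), norm_Ca_hi = numeric(0))
}

#' Fixed-point census over a model database
#'
#' For each database model: scan the ray, detect fixed points of its own
#' regulation target, and count the stable ones. The headline statistic is
#' the fraction of models with 1 or 2 stable fixed points.
#'
#' @param db A model database from [generate_model_db()].
#' @param scales Scale grid.
#' @param t_total,burnin Simulation window per scale point, ms.
#' @param refine Bisection refinement steps.
#' @param noise_floor Passed to [find_fixed_points()].
#' @param progress Print one line per model.
#' @return List of class `ray_census`: `per_model` (data.frame with model
#'   id, n stable/unstable fixed points), `fixed_points` (data.frame of all
#'   fixed points with model id), `fraction_1_or_2` (stable count in
#'   {1, 2}), `scans` (list of `ray_scan`).
#' @export
ray_census <- function(db, scales = ray_scales(), t_total = 15000,
                       burnin = 5000, refine = 4, noise_floor = 0.03,
                       progress = FALSE) {
  stopifnot(inherits(db, "model_db"))
  per <- vector("list", length(db$models))
  fps <- vector("list", length(db$models))
  scans <- vector("list", length(db$models))
  for (k in seq_along(db$models)) {
    rec <- db$models[[k]]
    model <- with_gbar(db$template, rec$gbar)
    scan <- scan_ray(model, Ca_target = rec$mean_Ca, scales = scales,
                     t_total = t_total, burnin = burnin)
    fp <- find_fixed_points(scan, model = model, refine = refine,
                            noise_floor = noise_floor)
    per[[k]] <- data.frame(model = k, n_stable = sum(fp$stable),
                           n_unstable = sum(!fp$stable))
    if (nrow(fp) > 0) fps[[k]] <- cbind(model = k, fp)
    scans[[k]] <- scan
    if (progress) {
      message(sprintf("model %d/%d: %d stable fixed point(s)",
                      k, length(db$models), sum(fp$stable)))
    }
  }
  per <- do.call(rbind, per)
  out <- list(per_model = per,
              fixed_points = if (length(fps)) do.call(rbind, fps) else NULL,
              fraction_1_or_2 = mean(per$n_stable %in% c(1L, 2L)),
              scans = scans)
  class(out) <- "ray_census"
  out
}

#' Voltage dynamics at the stable fixed points
#'
#' Simulates every database model at each of its stable fixed-point scales
#' and reports burst period and duty cycle normalised by that model's own
#' target metrics.
#'
#' @param db A model database.
#' @param census A `ray_census` over the same database.
#' @param t_total,burnin Simulation window, ms.
#' @param cfg Classifier configuration (targets are ignored; the
#'   normalisation uses each model's stored metrics).
#' @return List of class `compensation_table`: `table` (data.frame: model,
#'   scale, burst_period, duty_cycle, normalised versions, state label) and
#'   `fraction_within_20` (both normalised metrics in [0.8, 1.2]).
#' @export
compensation_outcomes <- function(db, census, t_total = 15000,
                                  burnin = 5000, cfg = classifier_config()) {
  stopifnot(inherits(db, "model_db"), inherits(census, "ray_census"))
  fp <- census$fixed_points
  fp <- fp[fp$stable, , drop = FALSE]
  rows <- lapply(seq_len(NROW(fp)), function(r) {
    k <- fp$model[r]
    rec <- db$models[[k]]
    model <- with_gbar(db$template, rec$gbar * fp$scale[r])
    m <- trace_metrics(simulate_neuron(model, t_total = t_total,
                                       burnin = burnin), cfg)
    data.frame(model = k, scale = fp$scale[r],
               burst_period = m$burst_period, duty_cycle = m$duty_cycle,
               norm_period = m$burst_period / rec$metrics$burst_period,
               norm_duty = m$duty_cycle / rec$metrics$duty_cycle,
               state_label = m$state_label, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  within <- if (is.null(tab)) NA_real_ else {
    mean(is.finite(tab$norm_period) & is.finite(tab$norm_duty) &
           abs(tab$norm_period - 1) <= 0.2 & abs(tab$norm_duty - 1) <= 0.2)
  }
  structure(list(table = tab, fraction_within_20 = within),
            class = "compensation_table")
}

#' @export
print.ray_scan <- function(x, ...) {
  cat(sprintf("<ray_scan> %d scales in [%.2g, %.2g]; Ca target %.3g uM\n",
              length(x$scales), min(x$scales), max(x$scales), x$Ca_target))
  invisible(x)
}

#' @export
print.ray_census <- function(x, ...) {
  cat(sprintf("<ray_census> %d models; %.0f%% with 1-2 stable fixed points\n",
              nrow(x$per_model), 100 * x$fraction_1_or_2))
  print(table(stable_fixed_points = x$per_model$n_stable))
  invisible(x)
}
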