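#' Classifier configuration
#'
#' Thresholds used to extract burst metrics from a voltage trace and to
#' classify dynamics into the four states. Dynamics whose burst period and
#' duty cycle are both within `canonical_tol` (default 10%) of the targets
#' are "canonical"; bursting outside that band is "other_bursting"; periodic
#' single-spike dynamics (tonic spiking / one-spike bursting) are merged
#' into "tonic_or_one_spike"; traces with no spikes are "silent".
#'
#' @param spike_threshold Spike detection threshold, mV.
#' @param burst_break_factor Interspike intervals longer than this multiple
#'   of the median ISI delimit bursts.
#' @param canonical_tol Relative tolerance on burst period and duty cycle
#'   for the canonical class.
#' @param target_period Target burst period, ms (reference model's).
#' @param target_duty Target duty cycle.
#' @param spike_width Nominal spike width, ms, added to the ISI span of a
#'   burst when computing its duration.
#' @param cv_max Maximum coefficient of variation of burst periods for the
#'   dynamics to count as regular bursting.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(spike_threshold = 0,
                              burst_break_factor = 3,
                              canonical_tol = 0.10,
                              target_period = NA_real_,
                              target_duty = NA_real_,
                              spike_width = 5,
                              cv_max = 0.2) {
  stopifnot(burst_break_factor > 1, canonical_tol > 0, spike_width >= 0)
  structure(
    list(spike_threshold = spike_threshold,
         burst_break_factor = burst_break_factor,
         canonical_tol = canonical_tol,
         target_period = target_period,
         target_duty = target_duty,
         spike_width = spike_width,
         cv_max = cv_max),
    class = "classifier_config"
  )
}

#' Detect spikes in a voltage trace
#'
#' One event per upward crossing of the threshold.
#'
#' @param t Time grid, ms.
#' @param V Voltage trace, mV.
#' @param threshold Crossing threshold, mV.
#' @return Numeric vector of spike times, ms.
#' @export
detect_spikes <- function(t, V, threshold = 0) {
  stopifnot(length(t) == length(V), all(is.finite(V)))
  if (length(V) < 2) return(numeric(0))
  idx <- which(V[-1] > threshold & V[-length(V)] <= threshold)
  t[idx + 1]
}

#' Burst metrics from a spike train
#'
#' Bursts are delimited where an interspike interval exceeds
#' `burst_break_factor` times the median ISI. The burst period is the mean
#' interval between burst starts, the duty cycle the mean burst duration
#' (first-to-last spike span plus the nominal spike width) divided by the
#' period. Metrics are `NA` (flagged, not zeroed) when fewer than two
#' complete bursts are available or when no burst structure exists.
#'
#' @param spike_times Spike times, ms.
#' @param duration Analysed trace duration, ms (used only for sanity).
#' @param cfg A [classifier_config()].
#' @return List: `burst_period` (ms), `duty_cycle`, `n_spikes_per_burst`
#'   (mean over complete bursts), `n_bursts`, `cv_period`, `regular`
#'   (logical: enough bursts and period CV below `cfg$cv_max`).
#' @export
burst_metrics <- function(spike_times, duration, cfg = classifier_config()) {
  und <- list(burst_period = NA_real_, duty_cycle = NA_real_,
              n_spikes_per_burst = NA_real_, n_bursts = 0L,
              cv_period = NA_real_, regular = FALSE)
  n <- length(spike_times)
  if (n < 4) return(und)
  isi <- diff(spike_times)
  med <- median(isi)
  breaks <- which(isi > cfg$burst_break_factor * med)
  if (length(breaks) == 0) {
    # no burst structure: uniform spiking
    return(und)
  }
  # burst start indices (first spike overall + spike after each break)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  nb <- length(starts)
  if (nb < 3) return(und) # need >= 2 complete inter-burst intervals
  start_times <- spike_times[starts]
  periods <- diff(start_times)
  sp_per_burst <- ends - starts + 1L
  # durations of complete bursts (all but possibly truncated last one)
  durs <- spike_times[ends] - spike_times[starts] + cfg$spike_width
  keep <- seq_len(nb - 1L)
  period <- mean(periods)
  duty <- mean(durs[keep]) / period
  cv <- sd(periods) / period
  list(burst_period = period,
       duty_cycle = duty,
       n_spikes_per_burst = mean(sp_per_burst[keep]),
       n_bursts = nb,
       cv_period = cv,
       regular = is.finite(cv) && cv <= cfg$cv_max)
}

#' Extract trace metrics from a simulation
#'
#' Runs spike detection and burst analysis on the post-burn-in window of a
#' `sim_result` and attaches the mean calcium and the state label.
#'
#' @param result A `sim_result` from [simulate_neuron()] with recorded traces.
#' @param cfg A [classifier_config()].
#' @return A list of class `trace_metrics`: `spike_times`, `burst_period`,
#'   `duty_cycle`, `n_spikes_per_burst`, `mean_Ca`, `state_label`, plus the
#'   auxiliary fields of [burst_metrics()].
#' @export
trace_metrics <- function(result, cfg = classifier_config()) {
  stopifnot(inherits(result, "sim_result"), length(result$t) > 0)
  post <- result$t > result$burnin
  tt <- result$t[post]
  spk <- detect_spikes(tt, result$V[post], cfg$spike_threshold)
  bm <- burst_metrics(spk, duration = diff(range(tt)), cfg = cfg)
  out <- c(list(spike_times = spk, n_spikes = length(spk),
                mean_Ca = result$mean_Ca,
                diverged = isTRUE(result$diverged)),
           bm)
  out$state_label <- classify(out, cfg)
  class(out) <- "trace_metrics"
  out
}

#' Classify dynamics into the four states
#'
#' Exhaustive, mutually exclusive labels:
#' `silent` (no spikes), `tonic_or_one_spike` (spiking without multi-spike
#' burst structure), `canonical` (regular bursting with period and duty
#' cycle within tolerance of the targets), `other_bursting` (all remaining
#' bursting dynamics).
#'
#' @param metrics A `trace_metrics` (or any list with fields `n_spikes`,
#'   `burst_period`, `duty_cycle`, `n_spikes_per_burst`, `regular`).
#' @param cfg A [classifier_config()] with targets set.
#' @return A single character label.
#' @export
classify <- function(metrics, cfg = classifier_config()) {
  if (isTRUE(metrics$diverged)) return("other_bursting")
  if (metrics$n_spikes == 0) return("silent")
  bursting <- is.finite(metrics$burst_period) &&
    is.finite(metrics$n_spikes_per_burst) && metrics$n_spikes_per_burst >= 2
  if (!bursting) return("tonic_or_one_spike")
  if (isTRUE(metrics$regular) &&
      is.finite(cfg$target_period) && is.finite(cfg$target_duty)) {
    ok_p <- abs(metrics$burst_period - cfg$target_period) <=
      cfg$canonical_tol * cfg$target_period
    ok_d <- abs(metrics$duty_cycle - cfg$target_duty) <=
      cfg$canonical_tol * cfg$target_duty
    if (ok_p && ok_d) return("canonical")
  }
  "other_bursting"
}

#' Reference targets for the classifier
#'
#' Simulates a model (normally the reference burster), extracts its burst
#' period, duty cycle and mean calcium, and returns a classifier
#' configuration with those targets plus the calcium target.
#'
#' @param model A [neuron_model()].
#' @param t_total,burnin Simulation window, ms.
#' @param ... Further arguments to [classifier_config()].
#' @return List with `cfg` (a `classifier_config`), `Ca_target` (uM),
#'   `period`, `duty`, and the full `metrics`.
#' @export
reference_targets <- function(model, t_total = 30000, burnin = 10000, ...) {
  res <- simulate_neuron(model, t_total = t_total, burnin = burnin)
  m <- trace_metrics(res, classifier_config(...))
  stopifnot(is.finite(m$burst_period), is.finite(m$duty_cycle))
  list(cfg = classifier_config(target_period = m$burst_period,
                               target_duty = m$duty_cycle, ...),
       Ca_target = m$mean_Ca,
       period = m$burst_period,
       duty = m$duty_cycle,
       metrics = m)
}

#' One-row summary of trace metrics
#'
#' @param metrics A `trace_metrics`.
#' @return A one-row data.frame suitable for rbinding into a metrics table.
#' @export
metrics_row <- function(metrics) {
  data.frame(
    n_spikes = metrics$n_spikes,
    burst_period = metrics$burst_period,
    duty_cycle = metrics$duty_cycle,
    n_spikes_per_burst = metrics$n_spikes_per_burst,
    cv_period = metrics$cv_period,
    mean_Ca = metrics$mean_Ca,
    state_label = metrics$state_label,
    stringsAsFactors = FALSE
  )
}
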