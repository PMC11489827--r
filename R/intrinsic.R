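#' Resting membrane potential from a zero-current recording
#'
#' RMP is the median of the recorded voltage in consecutive intervals of
#' `interval_s` (default 20 s); the median makes the estimate robust to
#' brief depolarizing events. Test-pulse epochs (from the sweep-set
#' metadata) are excised, together with a settle margin after each pulse,
#' before the medians are taken. The summary value is the mean of the
#' interval medians falling inside `stat_window` (a `c(start, end)` range
#' in seconds; default the whole recording).
#'
#' @param sweeps a [sweep_set()] with protocol `zero_current_test_pulse`
#' @param interval_s interval length for the medians, seconds
#' @param stat_window `c(start, end)` window (s) over which interval
#'   medians are averaged for the summary
#' @param settle_s extra time excised after each test pulse (s)
#' @return list with `timecourse` (data.frame `interval_start`,
#'   `rmp_mV`) and `summary` (mV)
#' @export
estimate_rmp <- function(sweeps, interval_s = 20, stat_window = NULL,
                         settle_s = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"),
            sweeps$protocol == "zero_current_test_pulse")
  sw <- sweeps$sweeps[[1]]
  total <- nrow(sw) / sweeps$sampling_rate
  if (interval_s > total) stop("interval longer than the recording")
  keep <- rep(TRUE, nrow(sw))
  ps <- sweeps$meta$pulse_starts
  pd <- sweeps$meta$pulse_dur_s %||% 0.5
  for (s in ps) keep[sw$t >= s & sw$t < s + pd + settle_s] <- FALSE
  edges <- seq(0, total + 1e-9, by = interval_s)
  n_int <- floor(total / interval_s + 1e-9)
  starts <- edges[seq_len(n_int)]
  rmp <- vapply(starts, function(s) {
    sel <- keep & sw$t >= s & sw$t < s + interval_s
    median(sw$Vm[sel])
  }, numeric(1))
  tc <- data.frame(interval_start = starts, rmp_mV = rmp)
  if (is.null(stat_window)) stat_window <- c(0, total)
  inwin <- starts >= stat_window[1] & (starts + interval_s) <= stat_window[2] + 1e-9
  list(timecourse = tc, summary = mean(rmp[inwin]))
}

#' Membrane resistance from hyperpolarizing test pulses
#'
#' For each test pulse, the steady-state voltage change is the mean over
#' `ss_window` (default the final 100 ms of the 500-ms pulse) minus the
#' mean over `baseline_window` (default the 100 ms immediately before
#' pulse onset); Rm = dV / I (mV / pA, reported in MOhm). A warning flag
#' is raised for pulses where the deflection at mid-pulse differs from
#' the steady-state deflection by more than 5 %, indicating that the
#' membrane had not settled.
#'
#' @param sweeps a [sweep_set()] with test-pulse metadata
#'   (`pulse_starts`, `pulse_dur_s`, `pulse_amp_pA`)
#' @param ss_window length (s) of the steady-state window at the pulse end
#' @param baseline_window length (s) of the pre-pulse baseline window
#' @return list with `per_pulse` (data.frame `pulse_start`, `rm_MOhm`,
#'   `steady`) and `rm_MOhm` (mean over pulses)
#' @export
estimate_rm <- function(sweeps, ss_window = 0.1, baseline_window = 0.1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  sw <- sweeps$sweeps[[1]]
  ps <- sweeps$meta$pulse_starts
  pd <- sweeps$meta$pulse_dur_s %||% 0.5
  amp <- sweeps$meta$pulse_amp_pA
  if (is.null(ps) || is.null(amp) || amp == 0) {
    stop("sweep set carries no non-zero test-pulse protocol", call. = FALSE)
  }
  res <- lapply(ps, function(s) {
    base <- mean(sw$Vm[sw$t >= s - baseline_window & sw$t < s])
    ss <- mean(sw$Vm[sw$t >= s + pd - ss_window & sw$t < s + pd])
    mid <- mean(sw$Vm[sw$t >= s + pd / 2 - ss_window / 2 &
                        sw$t < s + pd / 2 + ss_window / 2])
    dv <- ss - base
    steady <- abs((mid - base) - dv) <= 0.05 * abs(dv)
    c(rm = dv / amp * 1000, steady = steady) # mV/pA -> MOhm
  })
  per_pulse <- data.frame(pulse_start = ps,
                          rm_MOhm = vapply(res, `[[`, numeric(1), "rm"),
                          steady = as.logical(vapply(res, `[[`, numeric(1),
                                                     "steady")))
  if (any(!per_pulse$steady)) {
    warning("steady state not reached within the test pulse for ",
            sum(!per_pulse$steady), " pulse(s)")
  }
  list(per_pulse = per_pulse, rm_MOhm = mean(per_pulse$rm_MOhm))
}

#' Detect action-potential onsets by a smoothed dV/dt threshold
#'
#' The first derivative of Vm is computed as a central first difference
#' times the sampling rate, then smoothed with a second-order
#' Savitzky-Golay filter (default window 5 samples). Onsets are the time
#' points at which the smoothed derivative crosses `dvdt_threshold`
#' (default 20 V/s) from below; the crossing is inclusive (the first
#' sample at or above threshold triggers) and no re-trigger occurs until
#' the derivative has fallen back below threshold.
#'
#' @param sweep data.frame with columns `t` (s) and `Vm` (mV)
#' @param sampling_rate Hz; at least 10 kHz is recommended for a
#'   meaningful V/s resolution (a warning is issued below that)
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters
#' @param dvdt_threshold onset threshold, V/s
#' @return data.frame with one row per AP: `time` (s), `vm_at_onset` (mV)
#' @export
detect_aps <- function(sweep, sampling_rate, sg_window = 5, sg_order = 2,
                       dvdt_threshold = 20) {
  if (sampling_rate < 1e4) {
    warning("sampling rate below 10 kHz: dV/dt resolution is coarse")
  }
  v <- sweep$Vm
  n <- length(v)
  dvdt <- numeric(n)
  dvdt[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2 * sampling_rate / 1000 # V/s
  dvdt[1] <- dvdt[2]; dvdt[n] <- dvdt[n - 1]
  sm <- signal::sgolayfilt(dvdt, p = sg_order, n = sg_window)
  above <- sm >= dvdt_threshold
  runs <- true_runs(above)
  if (!nrow(runs)) {
    return(data.frame(time = numeric(0), vm_at_onset = numeric(0)))
  }
  data.frame(time = sweep$t[runs$start], vm_at_onset = v[runs$start])
}

#' Excitability metrics from a series of step-current sweeps
#'
#' From per-sweep AP tables: AP threshold is the Vm at the onset of the
#' first AP evoked at the lowest current amplitude that evoked any AP;
#' rheobase is that current amplitude; maximum mean rate is the largest
#' AP count per step divided by the step duration; maximum instantaneous
#' rate is the inverse of the minimum inter-spike interval. Metrics that
#' are undefined (no APs anywhere) are returned as `NA`, never 0.
#'
#' @param step_sweeps a [sweep_set()] with protocol `step_series`
#' @param ap_tables optional list of AP tables (one per sweep) from
#'   [detect_aps()]; computed internally when omitted
#' @param step_dur_s step duration (s); taken from the metadata by default
#' @return list: `rheobase_pA`, `ap_threshold_mV`, `max_mean_rate_hz`,
#'   `max_inst_rate_hz`, `ap_counts` (per step)
#' @export
excitability_metrics <- function(step_sweeps, ap_tables = NULL,
                                 step_dur_s = NULL) {
  stopifnot(inherits(step_sweeps, "sweep_set"),
            step_sweeps$protocol == "step_series")
  steps <- step_sweeps$meta$step_amplitudes_pA
  step_dur <- step_dur_s %||% step_sweeps$meta$step_dur_s %||% 0.5
  if (is.null(ap_tables)) {
    ap_tables <- lapply(step_sweeps$sweeps, detect_aps,
                        sampling_rate = step_sweeps$sampling_rate)
  }
  counts <- vapply(ap_tables, nrow, integer(1))
  if (all(counts == 0L)) {
    return(list(rheobase_pA = NA_real_, ap_threshold_mV = NA_real_,
                max_mean_rate_hz = NA_real_, max_inst_rate_hz = NA_real_,
                ap_counts = counts))
  }
  first <- which(counts > 0L)[1]
  isis <- unlist(lapply(ap_tables[counts >= 2L],
                        function(tb) diff(tb$time)))
  list(
    rheobase_pA = steps[first],
    ap_threshold_mV = ap_tables[[first]]$vm_at_onset[1],
    max_mean_rate_hz = max(counts) / step_dur,
    max_inst_rate_hz = if (length(isis)) 1 / min(isis) else NA_real_,
    ap_counts = counts
  )
}

#' Aggregate excitability metrics across repeated series
#'
#' Per-condition aggregation over the repetitions of the step protocol:
#' the mean of each metric across series, except rheobase, for which the
#' median is used. Undefined (`NA`) series values are excluded.
#'
#' @param series_metrics list of results from [excitability_metrics()]
#' @return named list of aggregated metrics
#' @export
aggregate_series <- function(series_metrics) {
  pull <- function(f) vapply(series_metrics, `[[`, numeric(1), f)
  list(
    rheobase_pA = median(pull("rheobase_pA"), na.rm = TRUE),
    ap_threshold_mV = mean(pull("ap_threshold_mV"), na.rm = TRUE),
    max_mean_rate_hz = mean(pull("max_mean_rate_hz"), na.rm = TRUE),
    max_inst_rate_hz = mean(pull("max_inst_rate_hz"), na.rm = TRUE)
  )
}
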