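#' Sweep set
#'
#' A list of current- or voltage-clamp sweeps sharing a sampling rate and
#' protocol. Each sweep is a data.frame with columns `t` (s), plus
#' `Vm` (mV) and `I` (pA) for current clamp or `I` (pA) for voltage clamp.
#'
#' @param sweeps list of sweep data.frames
#' @param sampling_rate Hz
#' @param protocol one of `"zero_current_test_pulse"`, `"step_series"`,
#'   `"paired_pulse"`, `"continuous"`
#' @param meta named list of protocol metadata (pulse/step tables,
#'   stimulus times, series index, condition label)
#' @return object of class `sweep_set`
#' @export
sweep_set <- function(sweeps, sampling_rate,
                      protocol = c("zero_current_test_pulse", "step_series",
                                   "paired_pulse", "continuous"),
                      meta = list()) {
  protocol <- match.arg(protocol)
  stopifnot(is.list(sweeps), sampling_rate > 0)
  structure(list(sweeps = sweeps, sampling_rate = sampling_rate,
                 protocol = protocol, meta = meta),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set: %d sweep(s), %g Hz, protocol %s>\n",
              length(x$sweeps), x$sampling_rate, x$protocol))
  invisible(x)
}

# Exact update of the single-compartment leaky membrane between samples:
# V[n+1] = Vinf + (V[n] - Vinf) * exp(-dt/tau), Vinf = E + I*R.
# R in MOhm, C in pF (tau = R*C in microseconds), I in pA, V in mV.
leaky_membrane_response <- function(I_pA, fs, R_MOhm, C_pF, E_rest_mV,
                                    V0 = E_rest_mV) {
  tau_s <- R_MOhm * C_pF * 1e-6
  a <- exp(-1 / (fs * tau_s))
  vinf <- E_rest_mV + I_pA * R_MOhm / 1000 # pA * MOhm = microvolt*1000 -> mV
  v <- numeric(length(I_pA))
  prev <- V0
  for (n in seq_along(I_pA)) {
    prev <- vinf[n] + (prev - vinf[n]) * a
    v[n] <- prev
  }
  v
}

# Action-potential waveform template added on top of Vm at threshold
# crossing: raised-cosine upstroke (amplitude_mV over rise_ms) and
# downstroke, total 2 ms by default. Peak dV/dt = amplitude*pi/(2*rise),
# ~98 V/s with the defaults, well above the 20 V/s detection criterion.
ap_template <- function(fs, amplitude_mV = 50, rise_ms = 0.8,
                        total_ms = 2) {
  n_rise <- max(2L, round(rise_ms / 1000 * fs))
  n_fall <- max(2L, round((total_ms - rise_ms) / 1000 * fs))
  up <- amplitude_mV * (1 - cos(pi * seq(0, 1, length.out = n_rise))) / 2
  down <- amplitude_mV * (1 + cos(pi * seq(0, 1, length.out = n_fall + 1))) / 2
  c(up, down[-1])
}

#' Generate synthetic current-clamp sweeps
#'
#' Membrane voltage follows a single-compartment leaky integrator with
#' exact per-sample exponential updates, so the step response matches the
#' closed-form RC solution to machine precision at zero noise. Two
#' protocols are available: a zero-current recording with hyperpolarizing
#' test pulses every 20 s (membrane-resistance estimation), and a series
#' of 500-ms depolarizing steps (excitability). Action potentials are
#' generated integrate-and-fire style: when the subthreshold voltage
#' crosses `threshold_mV` the AP waveform template is pasted in, the
#' voltage is reset, and integration resumes after a refractory period.
#'
#' @param config a [synthetic_config()] with `modality = "currentclamp"`.
#'   Recognized `params`: `R_MOhm` (default 500), `C_pF` (default 50),
#'   `E_rest_mV` (default -70), `noise_sd_mV` (default 0),
#'   `protocol` (`"zero_current_test_pulse"` or `"step_series"`),
#'   `pulse_amp_pA` (default -10), `pulse_dur_s` (0.5),
#'   `pulse_interval_s` (20), `step_amplitudes_pA` (default
#'   `seq(0, 120, 10)`), `step_dur_s` (0.5), `pre_s`/`post_s` (padding
#'   around each step, default 0.1), `threshold_mV` (-45),
#'   `reset_mV` (-60), `refractory_s` (0.005), `ap_amplitude_mV` (50)
#' @return list with `sweeps` (a [sweep_set()]) and `ground_truth`
#'   (membrane parameters and per-sweep AP times)
#' @export
gen_currentclamp <- function(config) {
  stopifnot(inherits(config, "synthetic_config"),
            config$modality == "currentclamp")
  p <- config$params
  R <- p$R_MOhm %||% 500
  C <- p$C_pF %||% 50
  E <- p$E_rest_mV %||% -70
  noise_sd <- p$noise_sd_mV %||% 0
  fs <- config$sampling_rate
  protocol <- p$protocol %||% "zero_current_test_pulse"
  tau_s <- R * C * 1e-6

  if (protocol == "zero_current_test_pulse") {
    pulse_amp <- p$pulse_amp_pA %||% -10
    pulse_dur <- p$pulse_dur_s %||% 0.5
    pulse_int <- p$pulse_interval_s %||% 20
    if (tau_s >= pulse_dur / 3) {
      warning("membrane tau >= pulse duration / 3: steady state not reached")
    }
    t <- seq(0, config$duration - 1 / fs, by = 1 / fs)
    I <- numeric(length(t))
    pulse_starts <- seq(pulse_int / 2, config$duration - pulse_dur,
                        by = pulse_int)
    for (s in pulse_starts) I[t >= s & t < s + pulse_dur] <- pulse_amp
    v <- leaky_membrane_response(I, fs, R, C, E)
    v <- v + with_seed(derive_seed(config$seed, 11L),
                       rnorm(length(v), sd = noise_sd))
    sw <- sweep_set(list(data.frame(t = t, Vm = v, I = I)), fs,
                    "zero_current_test_pulse",
                    meta = list(pulse_starts = pulse_starts,
                                pulse_dur_s = pulse_dur,
                                pulse_amp_pA = pulse_amp))
    return(list(sweeps = sw,
                ground_truth = list(R_MOhm = R, C_pF = C, E_rest_mV = E,
                                    ap_times = list(numeric(0)))))
  }

  # step series
  steps <- p$step_amplitudes_pA %||% seq(0, 120, by = 10)
  step_dur <- p$step_dur_s %||% 0.5
  pre <- p$pre_s %||% 0.1
  post <- p$post_s %||% 0.1
  thr <- p$threshold_mV %||% -45
  reset <- p$reset_mV %||% -60
  refr <- p$refractory_s %||% 0.005
  ap_amp <- p$ap_amplitude_mV %||% 50
  tmpl <- ap_template(fs, ap_amp)
  n_pre <- round(pre * fs); n_step <- round(step_dur * fs)
  n_post <- round(post * fs)
  t <- (seq_len(n_pre + n_step + n_post) - 1) / fs
  a <- exp(-1 / (fs * tau_s))
  sweeps <- vector("list", length(steps))
  ap_times <- vector("list", length(steps))
  noise <- with_seed(derive_seed(config$seed, 12L),
                     matrix(rnorm(length(t) * length(steps), sd = noise_sd),
                            nrow = length(t)))
  for (k in seq_along(steps)) {
    I <- c(numeric(n_pre), rep(steps[k], n_step), numeric(n_post))
    v <- numeric(length(t)); sub <- E; aps <- numeric(0)
    n_tmpl <- length(tmpl); n_refr <- round(refr * fs)
    n <- 1L
    while (n <= length(t)) {
      vinf <- E + I[n] * R / 1000
      sub <- vinf + (sub - vinf) * a
      if (sub >= thr) {
        # spike rides on the threshold voltage, then the membrane is held
        # at reset through the refractory period
        aps <- c(aps, t[n])
        idx <- n:min(n + n_tmpl - 1L, length(t))
        v[idx] <- thr + tmpl[seq_along(idx)]
        idx2 <- seq.int(n + n_tmpl,
                        min(n + n_tmpl + n_refr - 1L, length(t)))
        idx2 <- idx2[idx2 <= length(t) & idx2 >= 1L]
        v[idx2] <- reset
        sub <- reset
        n <- n + n_tmpl + n_refr
        next
      }
      v[n] <- sub
      n <- n + 1L
    }
    sweeps[[k]] <- data.frame(t = t, Vm = v + noise[, k], I = I)
    ap_times[[k]] <- aps
  }
  sw <- sweep_set(sweeps, fs, "step_series",
                  meta = list(step_amplitudes_pA = steps,
                              step_dur_s = step_dur, pre_s = pre))
  list(sweeps = sw,
       ground_truth = list(R_MOhm = R, C_pF = C, E_rest_mV = E,
                           threshold_mV = thr, ap_times = ap_times))
}

#' Generate synthetic voltage-clamp recordings (minis or evoked)
#'
#' Two modes. Miniature mode (`modality = "voltageclamp_mini"`): a
#' continuous holding-current trace containing Poisson-timed inward
#' bi-exponential mEPSC waveforms with lognormally distributed amplitudes
#' on Gaussian baseline noise. Evoked mode (`"voltageclamp_evoked"`):
#' trial-aligned sweeps of a 20-Hz paired-pulse protocol; each pulse is a
#' stimulus artifact followed, on success trials, by an inward EPSC of
#' fixed amplitude at monosynaptic latency. Failures are planted either as
#' an exact pattern (`n_failures` per pulse, positions drawn at random) or
#' as independent Bernoulli draws (`failure_prob`).
#'
#' @param config a [synthetic_config()]. Mini `params`: `rate` (min^-1,
#'   default 0.13), `amplitude_median_pA` (10), `amplitude_sdlog` (0.3),
#'   `rise_ms` (1.5), `decay_ms` (6), `noise_sd_pA` (2). Evoked `params`:
#'   `n_trials` (30), `success_amplitude_pA` (46.5), `failure_prob` or
#'   `n_failures` (per pulse), `noise_sd_pA` (0), `ipi_s` (0.05),
#'   `latency_s` (0.004), `rise_ms` (1), `decay_ms` (5),
#'   `artifact_amplitude_pA` (200), `sweep_dur_s` (0.3), `stim1_s` (0.05)
#' @return list with `sweeps` (a [sweep_set()]) and `ground_truth`. Mini
#'   ground truth: `event_times` (s), `event_amplitudes` (pA, magnitudes),
#'   `planted_rate`. Evoked ground truth: `failure_flags` (trials x 2
#'   logical matrix), `success_amplitude_pA`.
#' @export
gen_voltageclamp <- function(config) {
  stopifnot(inherits(config, "synthetic_config"),
            config$modality %in% c("voltageclamp_mini", "voltageclamp_evoked"))
  p <- config$params
  fs <- config$sampling_rate

  if (config$modality == "voltageclamp_mini") {
    rate <- p$rate %||% 0.13
    med <- p$amplitude_median_pA %||% 10
    sdlog <- p$amplitude_sdlog %||% 0.3
    rise <- p$rise_ms %||% 1.5
    decay <- p$decay_ms %||% 6
    noise_sd <- p$noise_sd_pA %||% 2
    dur <- config$duration
    tmpl <- biexp_template(fs, rise, decay)
    gt <- with_seed(derive_seed(config$seed, 21L), {
      n_ev <- rpois(1, rate / 60 * dur)
      list(times = sort(runif(n_ev, 0, dur * 0.999)),
           amps = stats::rlnorm(n_ev, log(med), sdlog))
    })
    n <- round(dur * fs)
    trace <- with_seed(derive_seed(config$seed, 22L),
                       rnorm(n, sd = noise_sd))
    for (k in seq_along(gt$times)) {
      i0 <- floor(gt$times[k] * fs) + 1L
      idx <- i0:min(n, i0 + length(tmpl) - 1L)
      trace[idx] <- trace[idx] - gt$amps[k] * tmpl[seq_along(idx)]
    }
    sw <- sweep_set(list(data.frame(t = (seq_len(n) - 1) / fs, I = trace)),
                    fs, "continuous")
    return(list(sweeps = sw,
                ground_truth = list(event_times = gt$times,
                                    event_amplitudes = gt$amps,
                                    planted_rate = rate)))
  }

  # evoked paired-pulse mode
  n_trials <- as.integer(p$n_trials %||% 30L)
  amp <- p$success_amplitude_pA %||% 46.5
  noise_sd <- p$noise_sd_pA %||% 0
  ipi <- p$ipi_s %||% 0.05
  latency <- p$latency_s %||% 0.004
  rise <- p$rise_ms %||% 1
  decay <- p$decay_ms %||% 5
  art_amp <- p$artifact_amplitude_pA %||% 200
  sweep_dur <- p$sweep_dur_s %||% 0.3
  stim1 <- p$stim1_s %||% 0.05
  fail <- with_seed(derive_seed(config$seed, 23L), {
    if (!is.null(p$n_failures)) {
      vapply(1:2, function(pulse) {
        f <- rep(FALSE, n_trials)
        f[sample.int(n_trials, min(p$n_failures, n_trials))] <- TRUE
        f
      }, logical(n_trials))
    } else {
      prob <- p$failure_prob %||% 0.25
      stop_if_not_prob(prob, "failure_prob")
      matrix(runif(n_trials * 2) < prob, ncol = 2)
    }
  })
  tmpl <- biexp_template(fs, rise, decay)
  art <- c(art_amp, -art_amp / 2, art_amp / 8) # 3-sample biphasic artifact
  n <- round(sweep_dur * fs)
  tt <- (seq_len(n) - 1) / fs
  stim_times <- c(stim1, stim1 + ipi)
  noise <- with_seed(derive_seed(config$seed, 24L),
                     matrix(rnorm(n * n_trials, sd = noise_sd), nrow = n))
  sweeps <- lapply(seq_len(n_trials), function(tr) {
    y <- noise[, tr]
    for (pulse in 1:2) {
      i_st <- round(stim_times[pulse] * fs) + 1L
      idx <- i_st:min(n, i_st + length(art) - 1L)
      y[idx] <- y[idx] + art[seq_along(idx)]
      if (!fail[tr, pulse]) {
        i_on <- round((stim_times[pulse] + latency) * fs) + 1L
        idx <- i_on:min(n, i_on + length(tmpl) - 1L)
        y[idx] <- y[idx] - amp * tmpl[seq_along(idx)]
      }
    }
    data.frame(t = tt, I = y)
  })
  sw <- sweep_set(sweeps, fs, "paired_pulse",
                  meta = list(stim_times = stim_times, n_trials = n_trials))
  list(sweeps = sw,
       ground_truth = list(failure_flags = fail,
                           success_amplitude_pA = amp))
}
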