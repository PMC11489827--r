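#' Preprocess an LFP trace: anti-alias, downsample, baseline-correct
#'
#' The source-rate trace is low-pass filtered (zero-phase Butterworth,
#' order 6, cutoff 0.8 x target Nyquist per decimation stage; decimation
#' factors > 10 are split into cascaded stages) and decimated to
#' `target_rate`, then baseline-corrected by subtracting a centered
#' rolling median (window `median_window` seconds), which removes DC and
#' slow drifts without distorting brief events. Artifact intervals are
#' set to `NA`.
#'
#' @param rec an [lfp_recording()] or a numeric vector
#' @param sampling_rate source rate (Hz, vector input only)
#' @param target_rate output rate (Hz), default 500; the source rate must
#'   be an integer multiple
#' @param median_window baseline median window (s), default 1
#' @param artifact_mask data.frame `start`/`end` (s), vector input only
#' @return list with `signal` (cleaned, at `target_rate`), `reference`
#'   (preprocessed the same way, when `rec` is an `lfp_recording`),
#'   `sampling_rate`
#' @export
preprocess_lfp <- function(rec, sampling_rate = NULL, target_rate = 500,
                           median_window = 1, artifact_mask = NULL) {
  if (inherits(rec, "lfp_recording")) {
    x <- rec$signal
    sampling_rate <- rec$sampling_rate
    artifact_mask <- rec$artifact_mask
    ref <- rec$noise_reference
  } else {
    x <- as.numeric(rec)
    ref <- NULL
  }
  stopifnot(!is.null(sampling_rate))
  if (target_rate > sampling_rate) {
    stop("target rate exceeds the source rate", call. = FALSE)
  }
  clean <- function(v) {
    v <- decimate_cascade(v, sampling_rate, target_rate)
    v - roll_median(v, round(median_window * target_rate))
  }
  if (length(x) / sampling_rate < 2 * median_window) {
    stop("recording shorter than twice the baseline window", call. = FALSE)
  }
  out <- clean(x)
  if (!is.null(artifact_mask) && nrow(artifact_mask)) {
    t_out <- (seq_along(out) - 1) / target_rate
    for (i in seq_len(nrow(artifact_mask))) {
      out[t_out >= artifact_mask$start[i] & t_out < artifact_mask$end[i]] <-
        NA_real_
    }
  }
  list(signal = out,
       reference = if (!is.null(ref)) clean(ref) else NULL,
       sampling_rate = target_rate)
}

# Cascaded anti-alias + decimate. Each stage: zero-phase order-6
# Butterworth at 0.8 x the post-stage Nyquist, then keep every q-th
# sample. Integer overall ratio required.
decimate_cascade <- function(x, fs_in, fs_out) {
  q_total <- fs_in / fs_out
  if (abs(q_total - round(q_total)) > 1e-9) {
    stop("source rate must be an integer multiple of the target rate")
  }
  q_total <- round(q_total)
  if (q_total == 1L) return(x)
  fs <- fs_in
  while (q_total > 1L) {
    q <- q_total
    if (q > 10L) {
      q <- max(which(q_total %% seq_len(10L) == 0L & seq_len(10L) > 1L))
    }
    bf <- signal::butter(6, 0.8 / q, type = "low")
    x <- filtfilt_padded(bf, x)
    x <- x[seq(1L, length(x), by = q)]
    q_total <- q_total / q
    fs <- fs / q
  }
  x
}

# Zero-phase filtering with odd-reflection end padding, so DC offsets and
# trends do not excite edge transients (signal::filtfilt starts from zero
# initial conditions).
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 1000L)
  head_pad <- 2 * x[1] - x[(np + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1L):(np + n)]
}

#' Noise-normalized bandpower timecourse
#'
#' Welch bandpower of the recording in consecutive non-overlapping
#' intervals, divided by the bandpower of the technical-noise reference
#' computed with the identical estimator and band. A ratio of 1 marks the
#' electrode noise floor. Intervals with more than half of their samples
#' masked return `NA`.
#'
#' @param signal cleaned signal at `fs` Hz (e.g. from [preprocess_lfp()])
#' @param reference cleaned technical-noise reference at `fs`
#' @param fs sampling rate (Hz)
#' @param band `c(f_lo, f_hi)` Hz, default `c(8, 40)`
#' @param interval_s interval length (s), default 300 (5 min)
#' @param win_s,overlap Welch parameters, default 6 s / 20 %
#' @return data.frame `interval_start` (s), `normalized_bandpower`
#' @export
bandpower_timecourse <- function(signal, reference, fs, band = c(8, 40),
                                 interval_s = 300, win_s = 6,
                                 overlap = 0.2) {
  stopifnot(length(reference) >= win_s * fs)
  ref_bp <- band_power(welch_psd(reference, fs, win_s, overlap), band)
  n_per <- round(interval_s * fs)
  n_int <- floor(length(signal) / n_per)
  starts <- (seq_len(n_int) - 1L) * n_per
  nbp <- vapply(starts, function(s) {
    seg <- signal[(s + 1L):(s + n_per)]
    if (mean(is.na(seg)) > 0.5) return(NA_real_)
    band_power(welch_psd(seg, fs, win_s, overlap), band) / ref_bp
  }, numeric(1))
  data.frame(interval_start = starts / fs, normalized_bandpower = nbp)
}

#' Detect early sharp waves (eSPWs)
#'
#' Dual criterion on the preprocessed (500 Hz, baseline-corrected) trace:
#' a candidate deflection must (a) exceed `amp_threshold` in magnitude
#' (polarity configurable; negative by default, as recorded below the
#' sharp-wave polarity reversal) and (b) coincide with an increase in
#' band power (default 15-30 Hz) of at least `band_z_min` robust
#' z-scores above its local baseline. The band power statistic is
#' matched to the event timescale: the signal is zero-phase band-pass
#' filtered and its rolling RMS envelope over `env_window_s` (default
#' 0.1 s, the typical sharp-wave width) is robust-z-scored against a
#' rolling median/MAD baseline over `local_baseline_s`. Candidates
#' closer than `refractory_s` are merged onto the larger deflection.
#'
#' @param signal preprocessed LFP at `fs` Hz
#' @param fs sampling rate (Hz), default 500
#' @param amp_threshold amplitude criterion (mV), default 0.05
#' @param polarity -1 for negative deflections (default), +1 for positive
#' @param band bandpower-increase band (Hz), default `c(15, 30)`
#' @param band_z_min robust z threshold for the band envelope, default 6
#'   (the separation valley between event-driven and pink-noise envelope
#'   excursions; see the methods vignette)
#' @param env_window_s rolling-RMS window for the band envelope (s)
#' @param local_baseline_s window for the local envelope baseline (s),
#'   default 10
#' @param refractory_s minimum event separation (s), default 0.2
#' @return data.frame `time` (s, deflection peak), `peak_amplitude` (mV,
#'   magnitude), `band_z`
#' @export
detect_espws <- function(signal, fs = 500, amp_threshold = 0.05,
                         polarity = -1, band = c(15, 30), band_z_min = 6,
                         env_window_s = 0.1, local_baseline_s = 10,
                         refractory_s = 0.2) {
  x <- ifelse(is.finite(signal), signal, 0)
  d <- polarity * signal # deflection of the configured polarity, positive
  d[is.na(d)] <- -Inf
  runs <- true_runs(d > amp_threshold)
  empty <- data.frame(time = numeric(0), peak_amplitude = numeric(0),
                      band_z = numeric(0))
  if (!nrow(runs)) return(empty)
  peak_idx <- mapply(function(s, e) s - 1L + which.max(d[s:e]),
                     runs$start, runs$end)
  amps <- d[peak_idx]
  # merge candidates within the refractory period, keeping the larger
  o <- order(peak_idx)
  peak_idx <- peak_idx[o]; amps <- amps[o]
  keep <- rep(TRUE, length(peak_idx)); last <- 1L
  for (k in seq_along(peak_idx)[-1]) {
    if ((peak_idx[k] - peak_idx[last]) / fs < refractory_s) {
      if (amps[k] > amps[last]) keep[last] <- FALSE else keep[k] <- FALSE
      if (keep[k]) last <- k
    } else last <- k
  }
  peak_idx <- peak_idx[keep]; amps <- amps[keep]

  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  env <- sqrt(roll_mean(bp^2, round(env_window_s * fs)))
  # baseline stats on a coarse grid (envelope is smooth at this scale),
  # interpolated back to full resolution
  cstep <- max(1L, round(0.05 * fs))
  ci <- seq(1L, length(env), by = cstep)
  k_loc <- max(3L, round(local_baseline_s / 0.05))
  base_c <- roll_median(env[ci], k_loc)
  mad_c <- roll_mad(env[ci], k_loc)
  base <- approx(ci, base_c, xout = seq_along(env), rule = 2)$y
  spread <- approx(ci, mad_c, xout = seq_along(env), rule = 2)$y
  z <- (env - base) / pmax(1.4826 * spread, .Machine$double.eps)
  half <- round(env_window_s * fs)
  zi <- vapply(peak_idx, function(i) {
    max(z[max(1L, i - half):min(length(z), i + half)])
  }, numeric(1))
  sel <- zi >= band_z_min
  data.frame(time = (peak_idx[sel] - 1L) / fs, peak_amplitude = amps[sel],
             band_z = zi[sel])
}

#' Detect oscillatory LFP bursts with an adaptive threshold
#'
#' The band power time series (default 4-15 Hz, from the multitaper
#' spectrogram at 0.2-s steps) is compared against an activity-dependent
#' threshold: the moving median of the power over `baseline_win` plus
#' `k` times its moving median absolute deviation over `mad_win` (raw
#' MAD, no normal-consistency factor). Maximal supra-threshold runs,
#' merged when separated by at most `merge_gap_s`, are candidate epochs.
#' Because the 1-s analysis window smears a burst's power over up to a
#' second of window positions, each epoch's boundaries are then refined
#' at signal resolution: the fine-scale band power (rolling mean of the
#' squared band-pass-filtered signal over `fine_window_s`) is compared
#' against the same interpolated threshold, and the refined
#' supra-threshold runs are kept iff they last at least `min_dur`
#' (default 600 ms, which rejects brief noise peaks).
#'
#' @param signal preprocessed LFP at `fs` Hz
#' @param fs sampling rate (Hz), default 500
#' @param band burst band (Hz), default `c(4, 15)`; a per-animal
#'   data-driven band can be passed instead
#' @param baseline_win moving-median window (s), default 120
#' @param mad_win moving-MAD window (s), default 360
#' @param k threshold factor on the MAD, default 5
#' @param min_dur minimum time above threshold (s), default 0.6
#' @param merge_gap_s maximum gap between merged runs (s), default 0.2
#' @param fine_window_s fine band-power averaging window (s), default 0.1
#' @return data.frame `start`, `end`, `duration` (s), `peak_power`
#' @export
detect_bursts <- function(signal, fs = 500, band = c(4, 15),
                          baseline_win = 120, mad_win = 360, k = 5,
                          min_dur = 0.6, merge_gap_s = 0.2,
                          fine_window_s = 0.1) {
  if (length(signal) / fs < mad_win) {
    stop("recording shorter than the MAD window", call. = FALSE)
  }
  x <- ifelse(is.na(signal), 0, signal)
  x <- x - mean(x)
  sg <- mt_spectrogram(x, fs, f_range = c(band[1], band[2]))
  p <- spectrogram_bandpower(sg, band)
  thr <- roll_median(p, round(baseline_win / sg$step)) +
    k * roll_mad(p, round(mad_win / sg$step))
  runs <- true_runs(p > thr)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), peak_power = numeric(0))
  if (!nrow(runs)) return(empty)
  # merge candidate epochs separated by <= merge_gap_s
  gap_bins <- floor(merge_gap_s / sg$step + 1e-9)
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L <= gap_bins) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else merged <- rbind(merged, runs[i, , drop = FALSE])
  }
  # fine-scale band power and the threshold interpolated to the time base
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  pfine <- roll_mean(filtfilt_padded(bf, x)^2, round(fine_window_s * fs))
  t_fine <- (seq_along(pfine) - 1) / fs
  thr_fine <- approx(sg$time, thr, xout = t_fine, rule = 2)$y
  ev <- empty
  for (i in seq_len(nrow(merged))) {
    lo <- max(sg$time[merged$start[i]] - 1, 0)
    hi <- min(sg$time[merged$end[i]] + 1, max(t_fine))
    idx <- which(t_fine >= lo & t_fine <= hi)
    fr <- true_runs(pfine[idx] > thr_fine[idx])
    if (!nrow(fr)) next
    # merge fine gaps as well, then gate on refined duration
    fm <- fr[1, , drop = FALSE]
    if (nrow(fr) > 1) {
      for (j in 2:nrow(fr)) {
        if ((fr$start[j] - fm$end[nrow(fm)] - 1L) / fs <= merge_gap_s) {
          fm$end[nrow(fm)] <- fr$end[j]
        } else fm <- rbind(fm, fr[j, , drop = FALSE])
      }
    }
    for (j in seq_len(nrow(fm))) {
      s0 <- t_fine[idx[fm$start[j]]]
      e0 <- t_fine[idx[fm$end[j]]]
      if (e0 - s0 >= min_dur) {
        ev <- rbind(ev, data.frame(
          start = s0, end = e0, duration = e0 - s0,
          peak_power = max(pfine[idx[fm$start[j]:fm$end[j]]])))
      }
    }
  }
  if (!nrow(ev)) return(empty)
  # epochs can overlap after extension; merge duplicates
  ev <- ev[order(ev$start), ]
  keep <- c(TRUE, diff(ev$start) > 1e-9)
  ev <- ev[keep, ]
  rownames(ev) <- NULL
  ev
}

#' Event occurrence rate in events per minute
#'
#' @param events data.frame of detected events (one row per event)
#' @param analyzed_duration mask-corrected duration in seconds
#' @return events per minute
#' @export
event_rate <- function(events, analyzed_duration) {
  if (analyzed_duration <= 0) stop("analyzed duration is zero")
  nrow(events) / analyzed_duration * 60
}
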