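# Current-clamp feature extraction: RMP, Rm, AP detection, excitability.

make_zero_current_sweep <- function(vm, fs = 10000, pulse_starts = numeric(0)) {
  n <- length(vm)
  sweep_set(list(data.frame(t = (0:(n - 1)) / fs, Vm = vm, I = 0)), fs,
            "zero_current_test_pulse",
            meta = list(pulse_starts = pulse_starts, pulse_dur_s = 0.5,
                        pulse_amp_pA = -10))
}

test_that("RMP medians are exact on constant voltage and robust to spikes", {
  fs <- 1000
  vm <- rep(-70, 60 * fs)
  r <- estimate_rmp(make_zero_current_sweep(vm, fs))
  expect_equal(r$timecourse$rmp_mV, rep(-70, 3))
  expect_equal(r$summary, -70)
  # 1% of samples contaminated by +40 mV spikes: median unmoved
  set.seed(1)
  vm2 <- vm
  vm2[sample(length(vm2), length(vm2) / 100)] <- 40
  r2 <- estimate_rmp(make_zero_current_sweep(vm2, fs))
  expect_equal(r2$summary, -70)
  expect_error(estimate_rmp(make_zero_current_sweep(rep(-70, 10 * fs), fs)),
               "interval")
})

test_that("summary RMP recovers a planted resting potential within 0.2 mV", {
  cfg <- synthetic_config("currentclamp", 600, 20000, seed = 1,
                          params = list(R_MOhm = 154.5, C_pF = 100,
                                        E_rest_mV = -61.3,
                                        noise_sd_mV = 0.5))
  g <- gen_currentclamp(cfg)
  r <- estimate_rmp(g$sweeps)
  expect_equal(r$summary, -61.3, tolerance = 0.2 / 61.3)
  expect_equal(nrow(r$timecourse), 30)
})

test_that("membrane resistance follows Ohm's law on analytic sweeps", {
  # hand-built pulse with -1.0 mV steady deflection at -10 pA: 100 MOhm
  fs <- 10000
  tt <- (0:(30 * fs - 1)) / fs
  vm <- rep(-70, length(tt))
  vm[tt >= 10 & tt < 10.5] <- -71
  sw <- make_zero_current_sweep(vm, fs, pulse_starts = 10)
  expect_equal(estimate_rm(sw)$rm_MOhm, 100)
  # invariance to a constant voltage offset
  sw_off <- sw; sw_off$sweeps[[1]]$Vm <- sw$sweeps[[1]]$Vm + 12.3
  expect_equal(estimate_rm(sw_off)$rm_MOhm, 100)
})

test_that("Rm estimation is exact on the RC model and warns off steady state", {
  fs <- 10000
  tt <- (0:(30 * fs - 1)) / fs
  vm <- rep(-70, length(tt))
  in_pulse <- tt >= 10 & tt < 10.5
  vm[in_pulse] <- rc_step_response(tt[in_pulse] - 10, 200, 100, -70, -10)
  vm[tt >= 10.5] <- -70 # instant recovery is fine for this check
  sw <- make_zero_current_sweep(vm, fs, pulse_starts = 10)
  expect_equal(estimate_rm(sw)$rm_MOhm, 200, tolerance = 0.01)
  # tau = 300 ms: mid-pulse deflection far from steady state
  vm2 <- rep(-70, length(tt))
  vm2[in_pulse] <- rc_step_response(tt[in_pulse] - 10, 3000, 100, -70, -10)
  vm2[tt >= 10.5] <- -70
  sw2 <- make_zero_current_sweep(vm2, fs, pulse_starts = 10)
  expect_warning(estimate_rm(sw2), "steady state")
})

test_that("Rm recovery over 50 noisy runs has median relative error < 2%", {
  errs <- vapply(1:50, function(s) {
    cfg <- synthetic_config("currentclamp", 25, 20000, seed = s,
                            params = list(R_MOhm = 500, C_pF = 50,
                                          E_rest_mV = -70,
                                          noise_sd_mV = 0.2))
    g <- gen_currentclamp(cfg)
    abs(estimate_rm(g$sweeps)$rm_MOhm - 500) / 500
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("AP detection obeys the inclusive 20 V/s boundary", {
  fs <- 20000
  ramp <- function(slope_v_per_s) {
    # 5 ms flat, 5 ms ramp at the requested dV/dt, 5 ms flat
    v <- c(rep(-70, 100), -70 + slope_v_per_s * 1000 * seq_len(100) / fs,
           rep(-70 + slope_v_per_s * 1000 * 100 / fs, 100))
    data.frame(t = (seq_along(v) - 1) / fs, Vm = v)
  }
  expect_equal(nrow(detect_aps(ramp(20), fs)), 1)
  # well below threshold even allowing for smoothing overshoot at corners
  expect_equal(nrow(detect_aps(ramp(17), fs)), 0)
  expect_equal(nrow(detect_aps(ramp(5), fs)), 0)
})

test_that("AP onsets match planted spike times and are offset invariant", {
  cfg <- synthetic_config("currentclamp", 1, 20000, seed = 1,
                          params = list(protocol = "step_series",
                                        noise_sd_mV = 0))
  g <- gen_currentclamp(cfg)
  tabs <- lapply(g$sweeps$sweeps, detect_aps, sampling_rate = 20000)
  expect_equal(vapply(tabs, nrow, integer(1)),
               lengths(g$ground_truth$ap_times))
  k <- which(lengths(g$ground_truth$ap_times) > 0)[1]
  expect_lt(max(abs(tabs[[k]]$time - g$ground_truth$ap_times[[k]])),
            2e-4)
  # invariance to voltage offset and time translation
  sw <- g$sweeps$sweeps[[k]]
  sw_off <- transform(sw, Vm = Vm + 17)
  expect_equal(nrow(detect_aps(sw_off, 20000)), nrow(tabs[[k]]))
  sw_sh <- transform(sw, t = t + 5)
  expect_equal(detect_aps(sw_sh, 20000)$time, tabs[[k]]$time + 5)
})

test_that("the extracted input-output curve reproduces the generator exactly", {
  cfg <- synthetic_config("currentclamp", 1, 20000, seed = 2,
                          params = list(protocol = "step_series",
                                        noise_sd_mV = 0))
  g <- gen_currentclamp(cfg)
  m <- excitability_metrics(g$sweeps)
  expect_equal(m$ap_counts, lengths(g$ground_truth$ap_times))
  expect_true(all(diff(m$ap_counts) >= 0)) # non-decreasing I/O curve
  expect_equal(m$ap_threshold_mV, g$ground_truth$threshold_mV,
               tolerance = 0.05)
  gt_counts <- lengths(g$ground_truth$ap_times)
  expect_equal(m$rheobase_pA,
               g$sweeps$meta$step_amplitudes_pA[which(gt_counts > 0)[1]])
})

test_that("excitability metrics implement the stated arithmetic", {
  tabs <- list(
    data.frame(time = numeric(0), vm_at_onset = numeric(0)),
    data.frame(time = c(0.15, 0.3, 0.45), vm_at_onset = c(-45, -44, -44)),
    data.frame(time = c(0.15, 0.17, 0.4), vm_at_onset = c(-45, -43, -44))
  )
  sw <- sweep_set(rep(list(data.frame(t = 0, Vm = -70, I = 0)), 3), 20000,
                  "step_series",
                  meta = list(step_amplitudes_pA = c(0, 10, 20),
                              step_dur_s = 0.5))
  m <- excitability_metrics(sw, tabs)
  expect_equal(m$max_mean_rate_hz, 6)     # 3 APs / 500 ms
  expect_equal(m$max_inst_rate_hz, 50)    # min ISI 20 ms
  expect_equal(m$rheobase_pA, 10)
  expect_equal(m$ap_threshold_mV, -45)
  # no APs anywhere: explicit missing values, never zero
  m0 <- excitability_metrics(sw, tabs[c(1, 1, 1)])
  expect_true(is.na(m0$rheobase_pA) && is.na(m0$max_mean_rate_hz))
})

test_that("series aggregation uses the mean except the median for rheobase", {
  series <- lapply(c(50, 60, 60), function(rb) {
    list(rheobase_pA = rb, ap_threshold_mV = -45 - rb / 100,
         max_mean_rate_hz = rb / 10, max_inst_rate_hz = rb / 5)
  })
  agg <- aggregate_series(series)
  expect_equal(agg$rheobase_pA, 60)
  expect_equal(agg$max_mean_rate_hz, mean(c(5, 6, 6)))
})
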