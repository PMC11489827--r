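# Miniature and evoked EPSC quantification.

test_that("mini detection is quiet on pure noise at a 5-SD threshold", {
  minutes <- 0; fp <- 0
  for (s in 1:4) {
    cfg <- synthetic_config("voltageclamp_mini", 600, 2000, seed = 200 + s,
                            params = list(rate = 0, noise_sd_pA = 2))
    g <- gen_voltageclamp(cfg)
    m <- detect_minis(g$sweeps, amp_threshold_pA = 10)
    fp <- fp + nrow(m$events); minutes <- minutes + 10
  }
  expect_lt(fp / minutes, 0.01 + 1e-9)
})

test_that("planted minis at SNR 8 are recovered with recall and precision >= 0.95", {
  cfg <- synthetic_config("voltageclamp_mini", 300, 2000, seed = 1,
                          params = list(rate = 30, amplitude_median_pA = 16,
                                        amplitude_sdlog = 0.1,
                                        noise_sd_pA = 2))
  g <- gen_voltageclamp(cfg)
  m <- detect_minis(g$sweeps, amp_threshold_pA = 10)
  gt <- g$ground_truth$event_times
  det <- m$events$time
  recall <- mean(vapply(gt, function(t) any(abs(det - t) < 0.01),
                        logical(1)))
  precision <- mean(vapply(det, function(t) any(abs(gt - t) < 0.01),
                           logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("mini event count is non-increasing in the amplitude threshold", {
  cfg <- synthetic_config("voltageclamp_mini", 300, 2000, seed = 2,
                          params = list(rate = 20, noise_sd_pA = 2))
  g <- gen_voltageclamp(cfg)
  counts <- vapply(c(4, 6, 8, 12), function(thr) {
    nrow(detect_minis(g$sweeps, amp_threshold_pA = thr)$events)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_minis(g$sweeps, amp_threshold_pA = -1), "> 0")
})

test_that("mini statistics implement the stated arithmetic", {
  ms <- list(events = data.frame(time = c(1, 2, 3),
                                 amplitude = c(10, 20, 30),
                                 area = c(1, 2, 3)),
             analyzed_duration = 1800)
  s <- mini_stats(ms)
  expect_equal(s$median_amplitude, 20)
  expect_equal(s$frequency, 0.1)
  empty <- list(events = data.frame(time = numeric(0),
                                    amplitude = numeric(0)),
                analyzed_duration = 1800)
  s0 <- mini_stats(empty)
  expect_equal(s0$frequency, 0)
  expect_null(s0$iei)
})

test_that("detected IEI distribution matches the generating exponential law", {
  cfg <- synthetic_config("voltageclamp_mini", 600, 2000, seed = 3,
                          params = list(rate = 60, amplitude_median_pA = 20,
                                        noise_sd_pA = 2))
  g <- gen_voltageclamp(cfg)
  m <- detect_minis(g$sweeps, amp_threshold_pA = 10)
  s <- mini_stats(m)
  expect_gt(length(s$iei), 400)
  ks <- suppressWarnings(ks.test(s$iei, "pexp", rate = 1))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("evoked classification is exact on noiseless planted patterns", {
  cfg <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 2,
                          params = list(n_trials = 100L, n_failures = 92L,
                                        success_amplitude_pA = 21.25,
                                        noise_sd_pA = 0))
  g <- gen_voltageclamp(cfg)
  oc <- classify_evoked(g$sweeps)
  fr <- failure_rate(oc)
  expect_equal(unname(fr["1"]), 0.92)
  expect_equal(unname(fr["1"] + mean(oc$outcome[oc$pulse == 1] == "success")),
               1)
  # all-zero responses: failure rate 100%
  cfg0 <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 1,
                           params = list(n_trials = 10L, n_failures = 10L,
                                         noise_sd_pA = 0))
  oc0 <- classify_evoked(gen_voltageclamp(cfg0)$sweeps)
  expect_equal(unname(failure_rate(oc0)), c(1, 1))
  expect_error(classify_evoked(g$sweeps, response_window_ms = c(1, 20)),
               "overlap")
})

test_that("Bernoulli failures at 25% are classified within 3 points at SNR 10", {
  hits <- 0; n <- 0; got_f <- 0; planted_f <- 0
  for (s in 1:10) {
    cfg <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 300 + s,
                            params = list(n_trials = 30L,
                                          failure_prob = 0.25,
                                          success_amplitude_pA = 40,
                                          noise_sd_pA = 4))
    g <- gen_voltageclamp(cfg)
    oc <- classify_evoked(g$sweeps)
    planted <- g$ground_truth$failure_flags
    got <- matrix(oc$outcome == "failure", ncol = 2, byrow = TRUE)
    hits <- hits + sum(got == planted); n <- n + length(planted)
    got_f <- got_f + sum(got[, 1]); planted_f <- planted_f + sum(planted[, 1])
  }
  # pooled classified rate within 3 points of the pooled planted rate
  expect_lt(abs(got_f - planted_f) / (n / 2), 0.03 + 1e-9)
  expect_gt(hits / n, 0.99) # per-trial agreement with the planted flags
})

test_that("failure-mean correction implements the stated subtraction", {
  oc <- data.frame(trial = 1:3, pulse = 1,
                   outcome = c("success", "failure", "failure"),
                   raw_amplitude = c(20, 2, 2))
  ca <- corrected_amplitudes(oc)
  expect_equal(ca$trials$corrected_amplitude, c(18, 0, 0))
  expect_equal(ca$summary$mean_failure, 2)
  # all failures: corrected amplitudes are ~0 and a warning-free path
  oc0 <- data.frame(trial = 1:3, pulse = 1, outcome = "failure",
                    raw_amplitude = c(1, 2, 3))
  expect_lt(mean(abs(corrected_amplitudes(oc0)$trials$corrected_amplitude)),
            1)
  # no failures at all: correction 0 with a warning
  oc1 <- data.frame(trial = 1:2, pulse = 1, outcome = "success",
                    raw_amplitude = c(10, 12))
  expect_warning(ca1 <- corrected_amplitudes(oc1), "no failure")
  expect_equal(ca1$summary$mean_corrected_all, 11)
})

test_that("corrected amplitudes are invariant to a constant baseline current", {
  cfg <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 5,
                          params = list(n_trials = 30L, n_failures = 8L,
                                        noise_sd_pA = 2))
  g <- gen_voltageclamp(cfg)
  oc1 <- classify_evoked(g$sweeps)
  sh <- g$sweeps
  sh$sweeps <- lapply(sh$sweeps, function(sw) { sw$I <- sw$I - 35; sw })
  oc2 <- classify_evoked(sh)
  expect_equal(corrected_amplitudes(oc2)$summary$mean_corrected_all,
               corrected_amplitudes(oc1)$summary$mean_corrected_all)
})

test_that("control-preset corrected eEPSC1 equals its closed-form expectation", {
  pr <- ca1_presets()$evoked_control_p2_5
  cfg <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 1,
                          params = list(n_trials = pr$n_trials,
                                        n_failures = pr$n_failures,
                                        success_amplitude_pA =
                                          pr$success_amplitude_pA,
                                        noise_sd_pA = 0))
  g <- gen_voltageclamp(cfg)
  ca <- corrected_amplitudes(classify_evoked(g$sweeps))
  expected <- (1 - pr$n_failures / pr$n_trials) * pr$success_amplitude_pA
  expect_equal(ca$summary$mean_corrected_all[1], expected,
               tolerance = 1e-9)
  expect_equal(expected, pr$mean_eepsc1_pA)
})

test_that("per-trial amplitudes are stable over a stationary evoked block", {
  cfg <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 6,
                          params = list(n_trials = 30L, n_failures = 8L,
                                        success_amplitude_pA = 40,
                                        noise_sd_pA = 4))
  g <- gen_voltageclamp(cfg)
  ca <- corrected_amplitudes(classify_evoked(g$sweeps))
  d <- ca$trials[ca$trials$pulse == 1, ]
  fit <- lm(corrected_amplitude ~ trial, data = d)
  ci <- confint(fit)["trial", ]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})
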