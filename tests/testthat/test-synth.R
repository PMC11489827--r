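# Synthetic-data generators: reproducibility, planted-event bookkeeping,
# and agreement of the membrane model with its closed form.

test_that("identical config and seed regenerate bit-identical data", {
  cfg <- synthetic_config("calcium", 30, 40, seed = 7,
                          params = list(n_cells = 5))
  a <- gen_calcium(cfg)
  b <- gen_calcium(cfg)
  expect_identical(a, b)
  cfg2 <- synthetic_config("calcium", 30, 40, seed = 8,
                           params = list(n_cells = 5))
  c <- gen_calcium(cfg2)
  expect_false(identical(a$ground_truth$cat_onsets,
                         c$ground_truth$cat_onsets))
})

test_that("all planted events lie inside the recording", {
  cfg <- synthetic_config("lfp", 120, 1000, seed = 3,
                          params = list(espw_rate = 6, burst_rate = 6,
                                        reference_duration = 30))
  g <- suppressWarnings(gen_lfp(cfg))
  gt <- g$ground_truth
  expect_true(all(gt$espw_times >= 0 & gt$espw_times < 120))
  expect_true(all(gt$burst_starts >= 0 & gt$burst_ends <= 122))
  cfg2 <- synthetic_config("calcium", 60, 40, seed = 3,
                           params = list(n_cells = 8, cell_rate = 6))
  g2 <- gen_calcium(cfg2)
  ons <- unlist(g2$ground_truth$cat_onsets)
  expect_true(all(ons >= 0 & ons < 60))
})

test_that("event-free generators produce pure noise with linear SD scaling", {
  base <- list(n_cells = 4, cell_rate = 0, gdp_rate = 0, noise_sd_dff = 0.05,
               drift_amplitude = 0)
  cfg1 <- synthetic_config("calcium", 60, 40, seed = 5, params = base)
  base$noise_sd_dff <- 0.10
  cfg2 <- synthetic_config("calcium", 60, 40, seed = 5, params = base)
  s1 <- sd(gen_calcium(cfg1)$traces$F[1, ])
  s2 <- sd(gen_calcium(cfg2)$traces$F[1, ])
  expect_equal(s2 / s1, 2, tolerance = 0.02)
  # zero noise, zero rates: constant traces and empty ground truth
  cfg0 <- synthetic_config("calcium", 30, 40, seed = 1,
                           params = list(n_cells = 10, cell_rate = 0,
                                         gdp_rate = 0, noise_sd_dff = 0))
  g0 <- gen_calcium(cfg0)
  expect_equal(max(apply(g0$traces$F, 1, sd)), 0)
  expect_equal(sum(lengths(g0$ground_truth$cat_onsets)), 0)
  expect_length(g0$ground_truth$gdp_times, 0)
})

test_that("planted Poisson counts fall in the 99% interval of rate x duration", {
  # network events at 2 min^-1 over 480 s: mean 16
  cfg <- synthetic_config("calcium", 480, 40, seed = 1,
                          params = list(n_cells = 20, cell_rate = 0,
                                        gdp_rate = 2,
                                        gdp_participation = 0.5))
  g <- gen_calcium(cfg)
  expect_gte(length(g$ground_truth$gdp_times), qpois(0.005, 16))
  expect_lte(length(g$ground_truth$gdp_times), qpois(0.995, 16))
  # sharp waves at 2.1 min^-1 over 30 min: mean 63
  cfgl <- synthetic_config("lfp", 1800, 500, seed = 1,
                           params = list(burst_rate = 0,
                                         reference_duration = 60))
  gl <- gen_lfp(cfgl)
  expect_gte(length(gl$ground_truth$espw_times), qpois(0.005, 63))
  expect_lte(length(gl$ground_truth$espw_times), qpois(0.995, 63))
  # minis at 0.13 min^-1 pooled over 10 x 60 min: mean 78
  tot <- sum(vapply(1:10, function(s) {
    cc <- synthetic_config("voltageclamp_mini", 3600, 200, seed = s,
                           params = list(rate = 0.13))
    length(gen_voltageclamp(cc)$ground_truth$event_times)
  }, numeric(1)))
  expect_gte(tot, qpois(0.005, 78))
  expect_lte(tot, qpois(0.995, 78))
})

test_that("membrane step response matches the closed-form RC solution", {
  cfg <- synthetic_config("currentclamp", 45, 20000, seed = 1,
                          params = list(R_MOhm = 154.5, C_pF = 100,
                                        E_rest_mV = -61.3, noise_sd_mV = 0))
  g <- gen_currentclamp(cfg)
  sw <- g$sweeps$sweeps[[1]]
  s0 <- g$sweeps$meta$pulse_starts[1]
  sel <- sw$t >= s0 & sw$t < s0 + 0.5
  t_rel <- sw$t[sel] - s0 + 1 / 20000 # exact update is evaluated at sample end
  pred <- rc_step_response(t_rel, 154.5, 100, -61.3, -10)
  rms <- sqrt(mean((sw$Vm[sel] - pred)^2))
  expect_lt(rms / abs(-1.545), 0.005)
  # deflection at pulse end within 1% of I*R = -1.545 mV
  defl <- mean(sw$Vm[sw$t >= s0 + 0.4 & sw$t < s0 + 0.5]) - (-61.3)
  expect_equal(defl, -1.545, tolerance = 0.01)
  # Ohm's law at R = 100 MOhm: steady-state deflection exactly -1.0 mV
  cfg2 <- synthetic_config("currentclamp", 45, 20000, seed = 1,
                           params = list(R_MOhm = 100, C_pF = 20,
                                         E_rest_mV = -70, noise_sd_mV = 0))
  g2 <- gen_currentclamp(cfg2)
  sw2 <- g2$sweeps$sweeps[[1]]
  s0 <- g2$sweeps$meta$pulse_starts[1]
  defl2 <- sw2$Vm[max(which(sw2$t < s0 + 0.5))] - (-70)
  expect_equal(defl2, -1, tolerance = 1e-6)
})

test_that("slow membranes trigger the steady-state warning", {
  cfg <- synthetic_config("currentclamp", 45, 10000, seed = 1,
                          params = list(R_MOhm = 2000, C_pF = 100,
                                        noise_sd_mV = 0))
  expect_warning(gen_currentclamp(cfg), "steady state")
})

test_that("subthreshold step series plants no action potentials", {
  cfg <- synthetic_config("currentclamp", 1, 20000, seed = 1,
                          params = list(protocol = "step_series",
                                        step_amplitudes_pA = seq(0, 40, 10),
                                        noise_sd_mV = 0))
  g <- gen_currentclamp(cfg)
  expect_equal(sum(lengths(g$ground_truth$ap_times)), 0)
})

test_that("evoked mode plants the exact requested failure pattern", {
  cfg <- synthetic_config("voltageclamp_evoked", 10, 20000, seed = 2,
                          params = list(n_trials = 100L, n_failures = 92L,
                                        noise_sd_pA = 0))
  g <- gen_voltageclamp(cfg)
  expect_equal(colSums(g$ground_truth$failure_flags), c(92, 92))
  expect_equal(nrow(g$ground_truth$failure_flags), 100L)
})

test_that("mini mode at rate 0 yields pure noise and empty ground truth", {
  cfg <- synthetic_config("voltageclamp_mini", 60, 2000, seed = 4,
                          params = list(rate = 0, noise_sd_pA = 2))
  g <- gen_voltageclamp(cfg)
  expect_length(g$ground_truth$event_times, 0)
  expect_equal(sd(g$sweeps$sweeps[[1]]$I), 2, tolerance = 0.05)
})

test_that("invalid generator parameters are rejected", {
  expect_error(gen_calcium(synthetic_config("calcium", 10, 40,
                                            params = list(n_cells = 0))),
               "n_cells")
  expect_error(gen_calcium(synthetic_config("calcium", 10, 40,
                                            params = list(gdp_participation = 1.5))),
               "participation")
  expect_error(gen_voltageclamp(synthetic_config("voltageclamp_evoked", 10,
                                                 2000,
                                                 params = list(failure_prob = 1.2))),
               "\\[0, 1\\]")
  expect_error(synthetic_config("calcium", -5, 40))
  expect_error(synthetic_config("calcium", 10, 40,
                                params = list(cell_rate = -1)),
               "rates")
  expect_error(gen_lfp(synthetic_config("lfp", 0.05, 1000,
                                        params = list(espw_width_ms = 100))),
               "longer than")
})
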