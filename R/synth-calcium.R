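#' Generate a synthetic somatic Ca2+ imaging dataset
#'
#' Emulates a population recording from an immature hippocampal network:
#' each cell fires spontaneous Ca2+ transients as an independent Poisson
#' process, and network co-activation epochs (GDP-like events) occur as a
#' separate Poisson process during which a random subset comprising at
#' least `gdp_participation` of all cells receives an additional transient
#' within a 500-ms span. Raw fluorescence is
#' `F(t) = F0_drift(t) * (1 + sum of transients) + noise`, where the
#' transients are instantaneous-rise, exponential-decay waveforms in dF/F
#' units and `F0_drift` is an optional slow multiplicative drift.
#'
#' @param config a [synthetic_config()] with `modality = "calcium"`.
#'   Recognized `params`: `n_cells` (default 20), `cell_rate` (min^-1,
#'   default 1.4), `gdp_rate` (min^-1, default 2), `gdp_participation`
#'   (fraction in (0, 1], default 0.5), `gdp_span_s` (default 0.5),
#'   `amplitude_dff` (default 0.5), `decay_s` (default 1),
#'   `noise_sd_dff` (default 0.05), `baseline_au` (default 100),
#'   `drift_amplitude` (relative, default 0), `drift_period_s` (default
#'   600)
#' @return list with `traces` (a [fluorescence_traces()]) and
#'   `ground_truth` (list: `cat_onsets` per cell in seconds, `gdp_times`,
#'   `planted_rates` in min^-1)
#' @export
gen_calcium <- function(config) {
  stopifnot(inherits(config, "synthetic_config"),
            config$modality == "calcium")
  p <- config$params
  n_cells <- as.integer(p$n_cells %||% 20L)
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  cell_rate <- p$cell_rate %||% 1.4
  gdp_rate <- p$gdp_rate %||% 2
  part <- p$gdp_participation %||% 0.5
  if (part <= 0 || part > 1) {
    stop("gdp_participation must lie in (0, 1]", call. = FALSE)
  }
  span <- p$gdp_span_s %||% 0.5
  amp <- p$amplitude_dff %||% 0.5
  decay <- p$decay_s %||% 1
  noise_sd <- p$noise_sd_dff %||% 0.05
  baseline <- p$baseline_au %||% 100
  drift_amp <- p$drift_amplitude %||% 0
  drift_period <- p$drift_period_s %||% 600

  dur <- config$duration
  fs <- config$sampling_rate
  times <- seq(0, dur - 1 / fs, by = 1 / fs)
  n_frames <- length(times)

  cell_onsets <- with_seed(derive_seed(config$seed, 1L), {
    lapply(seq_len(n_cells), function(i) {
      sort(runif(rpois(1, cell_rate / 60 * dur), 0, dur))
    })
  })
  gdp <- with_seed(derive_seed(config$seed, 2L), {
    gdp_times <- sort(runif(rpois(1, gdp_rate / 60 * dur), 0, dur - span))
    members <- lapply(gdp_times, function(t0) {
      k <- max(ceiling(part * n_cells), 1L)
      sample.int(n_cells, k)
    })
    jitter <- lapply(gdp_times, function(t0) runif(n_cells, 0, span))
    list(times = gdp_times, members = members, jitter = jitter)
  })
  onsets <- cell_onsets
  for (g in seq_along(gdp$times)) {
    for (cell in gdp$members[[g]]) {
      onsets[[cell]] <- sort(c(onsets[[cell]],
                               gdp$times[g] + gdp$jitter[[g]][cell]))
    }
  }

  drift <- 1 + drift_amp * sin(2 * pi * times / drift_period)
  F <- with_seed(derive_seed(config$seed, 3L), {
    t(vapply(seq_len(n_cells), function(i) {
      dff <- numeric(n_frames)
      for (on in onsets[[i]]) {
        idx <- which(times >= on)
        dff[idx] <- dff[idx] + amp * exp(-(times[idx] - on) / decay)
      }
      baseline * drift * (1 + dff) + rnorm(n_frames, sd = noise_sd * baseline)
    }, numeric(n_frames)))
  })

  list(
    traces = fluorescence_traces(F, times),
    ground_truth = list(
      cat_onsets = onsets,
      spontaneous_onsets = cell_onsets,
      gdp_times = gdp$times,
      planted_rates = c(cell_rate = cell_rate, gdp_rate = gdp_rate)
    )
  )
}
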