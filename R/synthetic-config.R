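#' Synthetic-dataset configuration
#'
#' A validated container describing one synthetic recording: which modality
#' to generate, its duration and sampling rate, the master seed, and a
#' nested block of modality-specific parameters (event rates in min^-1,
#' amplitudes in dF/F, pA or mV, template time constants in ms, noise SDs,
#' membrane R in MOhm and C in pF).
#'
#' The same config with the same seed always regenerates a bit-identical
#' dataset; different seeds give different planted event times.
#'
#' @param modality one of `"calcium"`, `"currentclamp"`,
#'   `"voltageclamp_mini"`, `"voltageclamp_evoked"`, `"lfp"`
#' @param duration recording duration in seconds (> 0)
#' @param sampling_rate sampling rate in Hz (> 0)
#' @param seed integer master seed
#' @param params named list of modality parameters; unset entries fall back
#'   to the modality defaults (see the generator documentation)
#' @return an object of class `synthetic_config`
#' @seealso [gen_calcium()], [gen_currentclamp()], [gen_voltageclamp()],
#'   [gen_lfp()], [read_config()]
#' @export
synthetic_config <- function(modality, duration, sampling_rate, seed = 1L,
                             params = list()) {
  modality <- match.arg(modality, c("calcium", "currentclamp",
                                    "voltageclamp_mini", "voltageclamp_evoked",
                                    "lfp"))
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0, is.numeric(seed), length(seed) == 1L)
  rates <- params[grepl("_rate$|^rate$", names(params))]
  if (length(rates) && any(unlist(rates) < 0)) {
    stop("all event rates must be >= 0", call. = FALSE)
  }
  structure(list(modality = modality, duration = duration,
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 params = params),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config: %s, %.1f s @ %g Hz, seed %d>\n",
              x$modality, x$duration, x$sampling_rate, x$seed))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a synthetic-dataset configuration from YAML or JSON
#'
#' The file must contain the fields `modality`, `duration`,
#' `sampling_rate`, and optionally `seed` and a nested `params` block.
#' A `schema_version` field, if present, must equal 1.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a [synthetic_config()]
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$schema_version) && cfg$schema_version != 1) {
    stop("unsupported config schema_version: ", cfg$schema_version)
  }
  synthetic_config(cfg$modality, cfg$duration, cfg$sampling_rate,
                   cfg$seed %||% 1L, cfg$params %||% list())
}

#' Reference presets for neonatal CA1 recordings
#'
#' Named parameter sets describing the control- and silenced-condition
#' recordings the synthetic generators emulate: spontaneous event rates,
#' paired-pulse failure structure, and passive membrane parameters typical
#' of CA1 pyramidal cells in the first postnatal weeks (plus the more
#' mature P29-31 cells used as a pharmacological positive control).
#'
#' The evoked presets plant an exact number of failures; their success
#' amplitudes are chosen so that the mean failure-corrected first-pulse
#' EPSC amplitude over all trials equals the preset `mean_eepsc1_pA`
#' analytically: mean = (1 - n_failures/n_trials) * success_amplitude.
#'
#' @return a nested named list of presets
#' @export
ca1_presets <- function() {
  list(
    calcium_control = list(
      cell_rate = 1.4,      # spontaneous CaT rate, min^-1
      gdp_rate = 2.0,       # network-event rate, min^-1
      gdp_participation = 0.5,
      duration = 480        # 8-min imaging block, s
    ),
    calcium_silenced = list(cell_rate = 0, gdp_rate = 0, duration = 480),
    mepsc_control = list(rate = 0.13),   # min^-1
    mepsc_silenced = list(rate = 0.05),  # min^-1
    evoked_control_p2_5 = list(
      n_trials = 30L,
      n_failures = 8L,                 # ~25 % failure rate
      success_amplitude_pA = 46.5,     # => mean corrected eEPSC1 = 34.1 pA
      mean_eepsc1_pA = 34.1
    ),
    evoked_silenced_p2_5 = list(
      n_trials = 100L,
      n_failures = 92L,                # 92 % failure rate
      success_amplitude_pA = 21.25,    # => mean corrected eEPSC1 = 1.7 pA
      mean_eepsc1_pA = 1.7
    ),
    membrane_pre_baclofen = list(R_MOhm = 154.5, E_rest_mV = -61.3),
    membrane_post_baclofen = list(R_MOhm = 85.8, E_rest_mV = -67.2),
    espw_control = list(rate = 2.1),   # min^-1, first postnatal week
    burst_control = list(rate = 4.0),  # min^-1, second postnatal week
    burst_silenced = list(rate = 2.0)
  )
}
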