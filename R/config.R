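#' Simulation configuration
#'
#' Collects every tunable of the network, the stimulation protocol and the
#' experiment variants, with defaults set to the reference focal-discharge
#' conditions: 20x20 grid of 320 excitatory + 80 inhibitory neurons, tonic
#' depolarizing current 2 to excitatory cells (the 4-AP surrogate), nine
#' 500 ms suprathreshold pulses (SimPs) to the centered 7x7 focus at 3 s
#' onset-to-onset intervals, 1 ms integration step, 600 s total duration.
#'
#' @param grid grid shape `c(rows, cols)`.
#' @param n_exc,n_inh numbers of excitatory / inhibitory neurons (must sum to
#'   the grid area).
#' @param focus_size side of the centered square stimulation focus.
#' @param exc_window,inh_window,astro_window side of the excitatory-input,
#'   inhibitory-input and astrocyte-territory squares.
#' @param dt integration step (ms); the membrane scheme requires 1.
#' @param duration_ms total simulated time (ms).
#' @param seed master RNG seed (placement, heterogeneity).
#' @param neuron_exc,neuron_inh [neuron_params()] for the two classes.
#' @param synapse a [synapse_params()]; `s_inh = 0.015` reproduces the
#'   strengthened-inhibition variant.
#' @param adaptation an [adaptation_params()].
#' @param adapt_exc_only if `TRUE`, the slow `b` depression applies to
#'   excitatory neurons only (default: all neurons).
#' @param tonic_current tonic current to excitatory neurons.
#' @param n_pulses,pulse_duration,pulse_interval,pulse_amplitude,first_pulse_onset
#'   stimulation protocol: number of SimPs, pulse length (ms), onset-to-onset
#'   interval (ms), injected current amplitude, onset of the first pulse (ms).
#'   The amplitude is a calibrated constant (see the package vignette): it
#'   makes stimulated neurons fire robustly (tens of Hz) during the pulse
#'   without guaranteeing a discharge in every run.
#' @param astro_enabled include the astrocyte feedback loop.
#' @param astro_params an [astrocyte_params()].
#' @param astro_block_region `"none"`, `"focus"` or `"outside"`: region whose
#'   astrocytes have Ca2+ clamped to zero (the BAPTA surrogate).
#' @param astro_feedback_mode `"nmda"` (glutamate onto NMDA conductances) or
#'   `"gabaa"` (GABA onto GABA-A conductances).
#' @param astro_gain conductance increment per unit released gliotransmitter
#'   per ms applied to each target neuron.
#' @param astro_input_gain scale on the per-spike Ca2+ increments.
#' @param astro_targets_exc_only restrict feedback targets to excitatory
#'   neurons in the territory (default: all neurons).
#' @param sd_frac relative SD of all heterogeneous parameter draws.
#' @param record_cadence sampling interval (ms) for continuous traces.
#' @param record_raster keep exact spike times (neuron, ms).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(grid = c(20, 20), n_exc = 320, n_inh = 80,
                       focus_size = 7, exc_window = 7, inh_window = 3,
                       astro_window = 3, dt = 1, duration_ms = 600000,
                       seed = 1,
                       neuron_exc = neuron_params("excitatory"),
                       neuron_inh = neuron_params("inhibitory"),
                       synapse = synapse_params(),
                       adaptation = adaptation_params(),
                       adapt_exc_only = FALSE,
                       tonic_current = 2,
                       n_pulses = 9, pulse_duration = 500,
                       pulse_interval = 3000, pulse_amplitude = 6,
                       first_pulse_onset = 1000,
                       astro_enabled = FALSE,
                       astro_params = astrocyte_params(),
                       astro_block_region = c("none", "focus", "outside"),
                       astro_feedback_mode = c("nmda", "gabaa"),
                       astro_gain = 0.015, astro_input_gain = 1,
                       astro_targets_exc_only = FALSE,
                       sd_frac = 0.01,
                       record_cadence = 10, record_raster = FALSE) {
  cfg <- list(
    grid = as.integer(grid), n_exc = as.integer(n_exc),
    n_inh = as.integer(n_inh), focus_size = as.integer(focus_size),
    exc_window = as.integer(exc_window), inh_window = as.integer(inh_window),
    astro_window = as.integer(astro_window), dt = dt,
    duration_ms = as.integer(duration_ms), seed = as.integer(seed),
    neuron_exc = neuron_exc, neuron_inh = neuron_inh, synapse = synapse,
    adaptation = adaptation, adapt_exc_only = isTRUE(adapt_exc_only),
    tonic_current = tonic_current,
    n_pulses = as.integer(n_pulses),
    pulse_duration = as.integer(pulse_duration),
    pulse_interval = as.integer(pulse_interval),
    pulse_amplitude = pulse_amplitude,
    first_pulse_onset = as.integer(first_pulse_onset),
    astro_enabled = isTRUE(astro_enabled), astro_params = astro_params,
    astro_block_region = match.arg(astro_block_region),
    astro_feedback_mode = match.arg(astro_feedback_mode),
    astro_gain = astro_gain, astro_input_gain = astro_input_gain,
    astro_targets_exc_only = isTRUE(astro_targets_exc_only),
    sd_frac = sd_frac,
    record_cadence = as.integer(record_cadence),
    record_raster = isTRUE(record_raster)
  )
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  if (cfg$dt != 1) stop("dt must be 1 ms (the membrane scheme is defined for the unit step)")
  if (cfg$n_exc + cfg$n_inh != prod(cfg$grid))
    stop("n_exc + n_inh must equal the grid area")
  if (cfg$pulse_duration >= cfg$pulse_interval)
    stop("pulse_duration must be shorter than pulse_interval")
  if (cfg$duration_ms < 1) stop("duration_ms must be positive")
  taus <- with(cfg$synapse, c(tau_ampa, tau_nmda, tau_gabaa, tau_gabab))
  if (any(taus <= 0)) stop("synaptic time constants must be positive")
  if (cfg$astro_gain < 0 || cfg$astro_input_gain < 0)
    stop("astrocyte gains must be nonnegative")
  invisible(cfg)
}

#' Read a simulation configuration from JSON
#'
#' Unknown keys are rejected; omitted keys keep the package defaults. Nested
#' parameter groups (`synapse`, `adaptation`, `astro_params`, `neuron_exc`,
#' `neuron_inh`) are given as JSON objects with the same field names as the
#' corresponding constructors.
#'
#' @param path path to a JSON file.
#' @return a validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  top <- names(formals(sim_config))
  unknown <- setdiff(names(raw), top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- raw
  for (grp in c("synapse", "adaptation", "astro_params",
                "neuron_exc", "neuron_inh")) {
    if (!is.null(raw[[grp]])) {
      ctor <- switch(grp, synapse = synapse_params,
                     adaptation = adaptation_params,
                     astro_params = astrocyte_params,
                     neuron_exc = function(...) neuron_params("excitatory", ...),
                     neuron_inh = function(...) neuron_params("inhibitory", ...))
      known <- setdiff(names(formals(ctor)), "...")
      bad <- setdiff(names(raw[[grp]]), c(known, "cell_class"))
      if (length(bad))
        stop("unknown keys in ", grp, ": ", paste(bad, collapse = ", "))
      args[[grp]] <- do.call(ctor, raw[[grp]][names(raw[[grp]]) != "cell_class"])
    }
  }
  do.call(sim_config, args)
}
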