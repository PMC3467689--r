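to_csr <- function(input_lists, weight_lists, n) {
  # invert per-post input lists into a pre -> posts CSR (0-based for C++)
  pre <- unlist(input_lists, use.names = FALSE)
  post <- rep(seq_along(input_lists), lengths(input_lists))
  w <- unlist(weight_lists, use.names = FALSE)
  o <- order(pre)
  pre <- pre[o]; post <- post[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(pre, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(post - 1L), w = as.numeric(w))
}

lists_to_csr <- function(lists, weights, n) {
  # flatten per-owner lists (astro patches/targets) directly, 0-based
  ptr <- c(0L, cumsum(lengths(lists)))
  list(ptr = as.integer(ptr),
       idx = as.integer(unlist(lists, use.names = FALSE) - 1L),
       w = as.numeric(unlist(weights, use.names = FALSE)))
}

#' Pulse onset times of the stimulation protocol
#'
#' @param config a [sim_config()].
#' @return integer vector of SimP onset times (ms, 0-based).
#' @export
pulse_onsets <- function(config) {
  config$first_pulse_onset +
    (seq_len(config$n_pulses) - 1L) * config$pulse_interval
}

#' Run a full network simulation
#'
#' Builds the network for `config$seed`, integrates the coupled
#' neuron-synapse-adaptation-astrocyte system over `config$duration_ms` at a
#' 1 ms step, applies the SimP protocol, and returns spike counts, sampled
#' continuous traces and (optionally) the exact spike raster. Runs are
#' deterministic given the config (all randomness is drawn at build time), and
#' variant flags (astrocytes on/off, blockade, feedback mode) do not perturb
#' the neuron-side draws, so paired-seed comparisons isolate the variant's
#' effect.
#'
#' @param config a [sim_config()].
#' @param network optionally a prebuilt [build_network()] result (must match
#'   the config's structural fields); rebuilt from `config$seed` otherwise.
#' @return list of class `"sim_result"`: `counts` (per-ms spike counts,
#'   columns `exc_focus`, `exc_out`, `inh_focus`, `inh_out`), `traces`
#'   (data.frame sampled every `record_cadence` ms: regional mean excitatory /
#'   inhibitory currents, mean `b`, regional mean astrocytic Ca2+ and
#'   glutamate, pulse flag), `raster` (data.frame `neuron`, `time_ms`,
#'   `cell_class`, or `NULL`), `pulse_onsets`, `network`, `config`.
#' @export
run_simulation <- function(config = sim_config(), network = NULL) {
  validate_config(config)
  if (is.null(network)) network <- build_network(config, config$seed)
  lay <- network$layout
  n <- lay$n
  sp <- config$synapse

  exc <- to_csr(network$conn$exc_inputs, network$conn$exc_w, n)
  inh <- to_csr(network$conn$inh_inputs, network$conn$inh_w, n)
  patch <- lists_to_csr(network$tiling$patch, network$tiling$sigma, n)
  targ <- lists_to_csr(network$tiling$targets,
                       lapply(network$tiling$targets, function(x) rep(1, length(x))),
                       n)

  blocked <- switch(config$astro_block_region,
                    none = rep(FALSE, n),
                    focus = lay$focus_mask,
                    outside = !lay$focus_mask)
  adapt_mask <- if (config$adapt_exc_only) lay$is_exc else rep(TRUE, n)

  tonic_i <- ifelse(lay$is_exc, config$tonic_current, 0)
  init <- rest_state(network$het$b, tonic_i)

  res <- engine_run(
    net = list(n = n, is_exc = lay$is_exc, focus = lay$focus_mask,
               exc_ptr = exc$ptr, exc_post = exc$idx, exc_w = exc$w,
               inh_ptr = inh$ptr, inh_post = inh$idx, inh_w = inh$w),
    neuron = list(v0 = init$v, u0 = init$u, a = network$het$a,
                  bs = network$het$b, c = network$het$c, d = network$het$d),
    syn = list(dec_ampa = exp(-1 / sp$tau_ampa),
               dec_nmda = exp(-1 / sp$tau_nmda),
               dec_gabaa = exp(-1 / sp$tau_gabaa),
               dec_gabab = exp(-1 / sp$tau_gabab),
               nmda_ratio = sp$nmda_ratio, gabab_ratio = sp$gabab_ratio,
               v_exc = sp$v_exc, v_inh = sp$v_inh),
    adapt = list(m = config$adaptation$m,
                 tauR_ms = config$adaptation$tau_R * 1000,
                 recovery = config$adaptation$recovery_rate,
                 mask = adapt_mask),
    astro = list(enabled = config$astro_enabled,
                 patch_ptr = patch$ptr, patch_idx = patch$idx,
                 patch_sigma = patch$w,
                 targ_ptr = targ$ptr, targ_idx = targ$idx,
                 alpha = network$tiling$alpha, beta = network$tiling$beta,
                 ca_th = config$astro_params$ca_th,
                 kappa = config$astro_params$kappa,
                 mu_s = config$astro_params$mu,
                 eta_s = config$astro_params$eta,
                 gain = config$astro_gain,
                 input_gain = config$astro_input_gain,
                 blocked = blocked,
                 mode_gabaa = config$astro_feedback_mode == "gabaa"),
    protocol = list(pulse_onset = pulse_onsets(config),
                    pulse_dur = config$pulse_duration,
                    amplitude = config$pulse_amplitude,
                    tonic = config$tonic_current),
    control = list(T = config$duration_ms, cadence = config$record_cadence,
                   record_raster = config$record_raster)
  )

  counts <- res$counts
  colnames(counts) <- c("exc_focus", "exc_out", "inh_focus", "inh_out")
  traces <- as.data.frame(res$traces)
  names(traces) <- c("time_ms", "I_exc_focus", "I_inh_focus", "I_exc_out",
                     "I_inh_out", "I_exc_all", "I_inh_all", "mean_b",
                     "ca_focus", "ca_out", "glu_focus", "glu_out", "pulse")
  raster <- NULL
  if (config$record_raster) {
    raster <- data.frame(neuron = res$raster_neuron,
                         time_ms = res$raster_time,
                         cell_class = lay$cell_class[res$raster_neuron])
  }
  structure(list(counts = counts, traces = traces, raster = raster,
                 pulse_onsets = pulse_onsets(config),
                 final_b = res$final_b, final_v = res$final_v,
                 final_u = res$final_u, final_R = res$final_R,
                 final_g = res$final_g,
                 mean_b_s = mean(network$het$b),
                 network = network, config = config),
            class = "sim_result")
}

#' Apply astrocytic feedback to synaptic conductances (reference)
#'
#' R-level reference for the feedback step performed inside the engine: each
#' astrocyte increments the NMDA (glutamate mode) or GABA-A (GABA mode)
#' conductance of every neuron in its territory by `gain * glu * dt`.
#'
#' @param synapses a [synapse_state()].
#' @param tiling the `tiling` element of a [build_network()] result.
#' @param glu per-astrocyte released-gliotransmitter values.
#' @param mode `"nmda"` or `"gabaa"`.
#' @param gain conductance increment per unit glu per ms.
#' @param dt time step (ms).
#' @return the incremented [synapse_state()].
#' @export
apply_astro_feedback <- function(synapses, tiling, glu,
                                 mode = c("nmda", "gabaa"), gain = 0.001,
                                 dt = 1) {
  mode <- match.arg(mode)
  field <- if (mode == "nmda") "g_nmda" else "g_gabaa"
  for (k in seq_along(glu)) {
    inc <- gain * glu[k] * dt
    if (inc > 0) {
      idx <- tiling$targets[[k]]
      synapses[[field]][idx] <- synapses[[field]][idx] + inc
    }
  }
  synapses
}

#' Run the Monte-Carlo variant suite
#'
#' Runs the seven experimental conditions on paired seeds: purely neuronal
#' network at baseline (`s_inh = 0.01`) and with strengthened inhibition
#' (`s_inh = 0.015`); astrocyte feedback on; astrocytes blocked at the focus;
#' astrocytes blocked outside the focus; inhibitory-only (GABA) astrocyte
#' feedback; and astrocyte feedback combined with strengthened inhibition.
#' Each run is summarized by its discharge outcome.
#'
#' @param base_config a [sim_config()] used as the template.
#' @param n_runs runs per condition.
#' @param seeds seed vector (length `n_runs`); the same seed is reused across
#'   conditions so neuron-side randomness is paired.
#' @param variants optional character vector to restrict the conditions.
#' @return data.frame with one row per run and condition: `variant`, `seed`,
#'   `generated`, `threshold` (onset SimP index, NA on failure),
#'   `duration_s`, `refractory_s`, `delay_s`.
#' @export
run_variant_suite <- function(base_config = sim_config(), n_runs = 20,
                              seeds = seq_len(n_runs),
                              variants = c("no_astro", "no_astro_inh15",
                                           "astro", "astro_block_focus",
                                           "astro_block_outside",
                                           "astro_gaba", "astro_inh15")) {
  stopifnot(length(seeds) == n_runs)
  mod <- list(
    no_astro = list(),
    no_astro_inh15 = list(s_inh = 0.015),
    astro = list(astro_enabled = TRUE),
    astro_block_focus = list(astro_enabled = TRUE,
                             astro_block_region = "focus"),
    astro_block_outside = list(astro_enabled = TRUE,
                               astro_block_region = "outside"),
    astro_gaba = list(astro_enabled = TRUE, astro_feedback_mode = "gabaa"),
    astro_inh15 = list(astro_enabled = TRUE, s_inh = 0.015)
  )
  rows <- list()
  for (vn in variants) {
    m <- mod[[vn]]
    for (s in seeds) {
      cfg <- base_config
      cfg$seed <- as.integer(s)
      if (!is.null(m$s_inh)) cfg$synapse$s_inh <- m$s_inh
      if (isTRUE(m$astro_enabled)) cfg$astro_enabled <- TRUE
      if (!is.null(m$astro_block_region))
        cfg$astro_block_region <- m$astro_block_region
      if (!is.null(m$astro_feedback_mode))
        cfg$astro_feedback_mode <- m$astro_feedback_mode
      out <- simulation_outcome(run_simulation(cfg))
      rows[[length(rows) + 1]] <- data.frame(
        variant = vn, seed = s, generated = out$generated,
        threshold = ifelse(out$generated, out$onset_pulse_index, NA),
        duration_s = ifelse(out$generated, out$duration_s, NA),
        refractory_s = out$refractory_s %||% NA,
        delay_s = out$propagation_delay_s %||% NA
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
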