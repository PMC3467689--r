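# Monte-Carlo ensembles shared across acceptance test blocks, computed once
# per test session. Threshold-only questions use 40 s runs (detection needs
# the nine pulses plus the 5 s sustained window); duration/refractory
# questions need the full post-discharge epoch (450 s).
.ens_cache <- new.env(parent = emptyenv())

ensemble <- function(name) {
  if (!is.null(.ens_cache[[name]])) return(.ens_cache[[name]])
  val <- switch(name,
    thr_baseline = mc_outcomes(seeds = 1:40, duration_ms = 40000),
    thr_inh15 = mc_outcomes(seeds = 1:40, duration_ms = 40000, s_inh = 0.015),
    full_default = mc_outcomes(seeds = 1:16, duration_ms = 450000),
    stop("unknown ensemble: ", name)
  )
  .ens_cache[[name]] <- val
  val
}

mc_outcomes <- function(seeds, duration_ms, s_inh = NULL, ...) {
  rows <- lapply(seeds, function(s) {
    cfg <- sim_config(duration_ms = duration_ms, seed = s, ...)
    if (!is.null(s_inh)) cfg$synapse$s_inh <- s_inh
    oc <- simulation_outcome(run_simulation(cfg))
    data.frame(seed = s, generated = oc$generated,
               threshold = ifelse(oc$generated, oc$onset_pulse_index, NA),
               duration_s = ifelse(oc$generated, oc$duration_s, NA),
               refractory_s = ifelse(is.null(oc$refractory_s), NA,
                                     oc$refractory_s),
               delay_s = ifelse(is.null(oc$propagation_delay_s), NA,
                                oc$propagation_delay_s),
               exc_hz = oc$exc_plateau_hz, inh_hz = oc$inh_plateau_hz)
  })
  do.call(rbind, rows)
}

# paired-seed variant thresholds (failures censored at n_pulses + 1)
variant_thresholds <- function(seeds, variant_args = list()) {
  vapply(seeds, function(s) {
    cfg <- do.call(sim_config,
                   c(list(duration_ms = 40000, seed = s), variant_args))
    oc <- simulation_outcome(run_simulation(cfg))
    if (oc$generated) oc$onset_pulse_index else cfg$n_pulses + 1
  }, numeric(1))
}
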