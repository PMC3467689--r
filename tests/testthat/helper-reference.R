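# R-loop replica of the compiled engine, built from the package's exported
# single-step functions, for cross-checking on small grids. Mirrors the
# engine's per-step order: decay -> deliver previous spikes -> astro feedback
# -> membrane step -> adaptation -> astrocytes (driven by this step's spikes).
reference_run <- function(config, network = build_network(config, config$seed)) {
  lay <- network$layout
  n <- lay$n
  sp <- config$synapse
  ap <- config$astro_params
  onsets <- pulse_onsets(config)
  T_ms <- config$duration_ms

  st <- rest_state(network$het$b,
                   ifelse(lay$is_exc, config$tonic_current, 0))
  syn <- synapse_state(n)
  adapt <- adaptation_state(n, b = network$het$b)
  ast <- astrocyte_state(n)
  blocked <- switch(config$astro_block_region,
                    none = rep(FALSE, n), focus = lay$focus_mask,
                    outside = !lay$focus_mask)
  adapt_mask <- if (config$adapt_exc_only) lay$is_exc else rep(TRUE, n)
  het_np <- list(a = network$het$a, b = adapt$b,
                 c = network$het$c, d = network$het$d)
  ad_par <- list(m = config$adaptation$m, tau_R = config$adaptation$tau_R,
                 recovery_rate = config$adaptation$recovery_rate,
                 b_s = network$het$b)
  as_par <- list(alpha = network$tiling$alpha, beta = network$tiling$beta,
                 ca_th = ap$ca_th, kappa = ap$kappa, mu = ap$mu, eta = ap$eta)

  counts <- matrix(0L, T_ms, 4,
                   dimnames = list(NULL, c("exc_focus", "exc_out",
                                           "inh_focus", "inh_out")))
  # out-edge lists (pre -> posts), delivered pre-by-pre in ascending order so
  # every accumulation chain matches the engine's bit for bit
  invert <- function(inputs, w) {
    pre <- unlist(inputs, use.names = FALSE)
    post <- rep(seq_along(inputs), lengths(inputs))
    wv <- unlist(w, use.names = FALSE)
    lev <- factor(pre, levels = seq_len(n))
    list(post = split(post, lev), w = split(wv, lev))
  }
  oe <- invert(network$conn$exc_inputs, network$conn$exc_w)
  oi <- invert(network$conn$inh_inputs, network$conn$inh_w)

  spiked_prev <- logical(n)
  b_dyn <- adapt$b
  for (t in 0:(T_ms - 1)) {
    syn <- decay_conductances(syn, sp, dt = 1)
    for (j in which(spiked_prev)) {
      if (lay$is_exc[j]) {
        po <- oe$post[[j]]; w <- oe$w[[j]]
        syn$g_ampa[po] <- syn$g_ampa[po] + w
        syn$g_nmda[po] <- syn$g_nmda[po] + w * sp$nmda_ratio
      } else {
        po <- oi$post[[j]]; w <- oi$w[[j]]
        syn$g_gabaa[po] <- syn$g_gabaa[po] + w
        syn$g_gabab[po] <- syn$g_gabab[po] + w * sp$gabab_ratio
      }
    }
    if (config$astro_enabled)
      syn <- apply_astro_feedback(syn, network$tiling, ast$glu,
                                  mode = config$astro_feedback_mode,
                                  gain = config$astro_gain, dt = 1)
    pulse_on <- any(t >= onsets & t < onsets + config$pulse_duration)
    I <- ifelse(lay$is_exc, config$tonic_current, 0) +
      ifelse(pulse_on & lay$focus_mask, config$pulse_amplitude, 0)
    het_np$b <- b_dyn
    st <- izhikevich_step(st, het_np, syn, sp, I_ext = I, dt = 1)
    adapt$b <- b_dyn
    adapt <- adaptation_step(adapt, st$spiked, ad_par, dt = 1)
    b_dyn <- ifelse(adapt_mask, adapt$b, b_dyn)
    if (config$astro_enabled) {
      input <- vapply(seq_len(n), function(k) {
        jj <- network$tiling$patch[[k]]
        sum(network$tiling$sigma[[k]][st$spiked[jj]])
      }, numeric(1)) * config$astro_input_gain
      ast <- calcium_step(ast, input, as_par, dt = 1)
      ast$ca[blocked] <- 0
      ast <- glutamate_step(ast, as_par, dt = 1)
    }
    if (any(st$spiked)) {
      col <- ifelse(lay$is_exc, 0L, 2L) + ifelse(lay$focus_mask, 1L, 2L)
      for (i in which(st$spiked)) counts[t + 1, col[i]] <- counts[t + 1, col[i]] + 1L
    }
    spiked_prev <- st$spiked
  }
  list(counts = counts, v = st$v, u = st$u, b = b_dyn,
       ca = ast$ca, glu = ast$glu)
}

# small-network config used by the engine-equivalence and property tests
small_config <- function(duration_ms = 2500, seed = 7, n_pulses = 3, ...) {
  sim_config(grid = c(6, 6), n_exc = 29, n_inh = 7, focus_size = 3,
             exc_window = 5, inh_window = 3, astro_window = 3,
             duration_ms = duration_ms, seed = seed,
             n_pulses = n_pulses, pulse_duration = 200, pulse_interval = 700,
             pulse_amplitude = 6, first_pulse_onset = 100, ...)
}
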