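#' Neuron state container
#'
#' Membrane voltage, recovery variable and current-step spike flags for a
#' population of `n` neurons. `rest_state()` places each neuron at the stable
#' fixed point of its membrane equation for a given holding current, i.e. the
#' more negative root of `0.04 v^2 + (5 - b) v + 140 + I = 0`, with `u = b v`.
#'
#' @param n number of neurons.
#' @param v,u initial values, recycled to length `n`.
#' @return list of class `"neuron_state"` with vectors `v`, `u`, `spiked`.
#' @export
neuron_state <- function(n, v = -70, u = -14) {
  structure(list(v = rep_len(v, n), u = rep_len(u, n),
                 spiked = logical(n)), class = "neuron_state")
}

#' @rdname neuron_state
#' @param b Izhikevich recovery coupling (vectorized).
#' @param I_ext holding current (vectorized).
#' @export
rest_state <- function(b, I_ext = 0) {
  disc <- (5 - b)^2 - 4 * 0.04 * (140 + I_ext)
  if (any(disc < 0))
    stop("no resting fixed point: holding current above the saddle-node")
  v <- (-(5 - b) - sqrt(disc)) / (2 * 0.04)
  n <- length(v)
  structure(list(v = v, u = b * v, spiked = logical(n)),
            class = "neuron_state")
}

#' Synaptic conductance state
#'
#' Per-neuron AMPA, NMDA, GABA-A and GABA-B conductances (dimensionless,
#' nonnegative).
#'
#' @param n number of neurons.
#' @return list of class `"synapse_state"` with four numeric vectors.
#' @export
synapse_state <- function(n) {
  z <- numeric(n)
  structure(list(g_ampa = z, g_nmda = z, g_gabaa = z, g_gabab = z),
            class = "synapse_state")
}

#' Voltage-dependent NMDA (magnesium-block) gating factor
#'
#' `x^2 / (1 + x^2)` with `x = (v + 80)/60`: zero at -80 mV, 0.5 at -20 mV,
#' approaching 1 with depolarization.
#'
#' @param v membrane voltage (mV), vectorized.
#' @return gating factor in `[0, 1)`.
#' @examples
#' nmda_gating(c(-80, -20))
#' @export
nmda_gating <- function(v) {
  x <- (v + 80) / 60
  x^2 / (1 + x^2)
}

#' Synaptic currents from conductances
#'
#' Every conductance multiplies its own driving force; the NMDA conductance is
#' additionally scaled by the magnesium-block gating factor. Currents are
#' depolarizing-positive: `I_exc >= 0` below the excitatory reversal and
#' `I_inh <= 0` above the inhibitory reversal.
#'
#' @param v membrane voltage (mV), vectorized.
#' @param synapses a [synapse_state()].
#' @param params a [synapse_params()].
#' @return list with vectors `I_exc` and `I_inh`.
#' @export
synaptic_current <- function(v, synapses, params = synapse_params()) {
  I_exc <- (synapses$g_ampa + synapses$g_nmda * nmda_gating(v)) *
    (params$v_exc - v)
  I_inh <- (synapses$g_gabaa + synapses$g_gabab) * (params$v_inh - v)
  list(I_exc = I_exc, I_inh = I_inh)
}

#' Exponential decay of synaptic conductances
#'
#' Each conductance is multiplied by `exp(-dt/tau)`. The exact exponential is
#' used rather than forward Euler because `tau_AMPA` equals the 1 ms
#' integration step, for which Euler decay degenerates to zero.
#'
#' @inheritParams synaptic_current
#' @param dt time step (ms).
#' @return the decayed [synapse_state()].
#' @export
decay_conductances <- function(synapses, params = synapse_params(), dt = 1) {
  stopifnot(dt > 0)
  synapses$g_ampa  <- synapses$g_ampa  * exp(-dt / params$tau_ampa)
  synapses$g_nmda  <- synapses$g_nmda  * exp(-dt / params$tau_nmda)
  synapses$g_gabaa <- synapses$g_gabaa * exp(-dt / params$tau_gabaa)
  synapses$g_gabab <- synapses$g_gabab * exp(-dt / params$tau_gabab)
  synapses
}

#' Instantaneous conductance increments from presynaptic spikes
#'
#' Adds the summed per-connection increments for the excitatory and inhibitory
#' inputs that fired this step. With the default uniform weights a single
#' excitatory spike adds `s_exc` to AMPA and `nmda_ratio * s_exc` to NMDA; an
#' inhibitory spike adds `s_inh` to GABA-A and `gabab_ratio * s_inh` to GABA-B.
#'
#' @inheritParams synaptic_current
#' @param exc_spike_count,inh_spike_count number of presynaptic excitatory /
#'   inhibitory inputs that fired (vectorized over postsynaptic neurons).
#' @param weights optional list with `s_exc`, `s_inh` per-connection increments
#'   overriding the means in `params` (same recycling rules).
#' @return the incremented [synapse_state()].
#' @export
deliver_spikes <- function(synapses, exc_spike_count, inh_spike_count,
                           params = synapse_params(), weights = NULL) {
  stopifnot(all(exc_spike_count >= 0), all(inh_spike_count >= 0))
  s_exc <- (weights$s_exc %||% params$s_exc)
  s_inh <- (weights$s_inh %||% params$s_inh)
  synapses$g_ampa  <- synapses$g_ampa  + exc_spike_count * s_exc
  synapses$g_nmda  <- synapses$g_nmda  + exc_spike_count * s_exc * params$nmda_ratio
  synapses$g_gabaa <- synapses$g_gabaa + inh_spike_count * s_inh
  synapses$g_gabab <- synapses$g_gabab + inh_spike_count * s_inh * params$gabab_ratio
  synapses
}

#' One membrane step of the Izhikevich neuron (implicit-conductance scheme)
#'
#' Advances `v` with the numerically stable update
#' `v(t+1) = (v + f(v, u) + g E + I) / (1 + g)` where
#' `f(v, u) = 0.04 v^2 + 5 v + 140 - u`, `g` is the total effective
#' conductance (NMDA scaled by its gating factor, evaluated at the pre-update
#' voltage), `E` the conductance-weighted mean reversal potential (so
#' `g E = sum_i g_i E_i`) and `I` the non-conductance current. The conductance
#' term is treated backward-Euler in `v`, which keeps the step stable under the
#' large synaptic conductances reached during a discharge. `u` is advanced by
#' forward Euler, `u <- u + a (b v - u)`, at the pre-update voltage. If the
#' updated `v` reaches the 50 mV cutoff the neuron is flagged as spiking and
#' reset (`v <- c`, `u <- u + d`), so the returned voltage is always below
#' cutoff. Defined for the unit step `dt = 1` ms.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()], or a list of vectors `a`, `b`, `c`, `d`
#'   for heterogeneous populations. `b` may be the dynamic adaptation value.
#' @param synapses a [synapse_state()].
#' @param syn_params a [synapse_params()].
#' @param I_ext external (non-conductance) current, vectorized.
#' @param dt time step; must be 1 ms.
#' @return the updated [neuron_state()].
#' @export
izhikevich_step <- function(state, params, synapses,
                            syn_params = synapse_params(), I_ext = 0,
                            dt = 1) {
  stopifnot(dt == 1)
  if (any(!is.finite(state$v)) || any(!is.finite(state$u)))
    stop("non-finite neuron state (v or u)")
  v <- state$v
  u <- state$u
  g_exc <- synapses$g_ampa + synapses$g_nmda * nmda_gating(v)
  g_inh <- synapses$g_gabaa + synapses$g_gabab
  g <- g_exc + g_inh
  gE <- g_exc * syn_params$v_exc + g_inh * syn_params$v_inh
  f <- 0.04 * v^2 + 5 * v + 140 - u
  v_new <- (v + f + gE + I_ext) / (1 + g)
  u_new <- u + params$a * (params$b * v - u)
  spiked <- v_new >= 50
  v_new[spiked] <- rep_len(params$c, length(v_new))[spiked]
  u_new[spiked] <- u_new[spiked] + rep_len(params$d, length(u_new))[spiked]
  structure(list(v = v_new, u = u_new, spiked = spiked),
            class = "neuron_state")
}

#' Adaptation (excitability) state
#'
#' Dynamic `b` and low-pass-filtered spike train `R` per neuron.
#'
#' @param n number of neurons.
#' @param b initial `b` values (recycled).
#' @return list of class `"adaptation_state"` with vectors `b` and `R`.
#' @export
adaptation_state <- function(n, b = 0.2) {
  structure(list(b = rep_len(b, n), R = numeric(n)),
            class = "adaptation_state")
}

#' One step of the slow excitability adaptation
#'
#' `R` decays exponentially with time constant `tau_R` (seconds) and gains
#' `1/tau_R` (per ms) at each spike, so that under sustained firing its steady
#' state equals the firing rate in spikes/ms. `b` then integrates
#' `db/dt = -m R + recovery_rate (b_s - b)` with time in seconds. The
#' quasi-steady value under sustained rate `r` (spikes/ms) is
#' `b_s - (m / recovery_rate) r`.
#'
#' @param adapt an [adaptation_state()].
#' @param spiked logical vector: which neurons spiked this step.
#' @param params an [adaptation_params()] (fields may be vectors).
#' @param dt time step (ms).
#' @return the updated [adaptation_state()].
#' @export
adaptation_step <- function(adapt, spiked, params = adaptation_params(),
                            dt = 1) {
  stopifnot(dt > 0)
  tau_ms <- params$tau_R * 1000
  R <- adapt$R * exp(-dt / tau_ms) + as.numeric(spiked) / tau_ms
  dt_s <- dt / 1000
  b <- adapt$b + dt_s * (-params$m * R +
                           params$recovery_rate * (params$b_s - adapt$b))
  structure(list(b = b, R = R), class = "adaptation_state")
}
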