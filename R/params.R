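#' Izhikevich neuron parameters
#'
#' Parameters of the two-variable quadratic integrate-and-fire ("Izhikevich")
#' neuron, `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`, with
#' reset `v <- c`, `u <- u + d` when `v` reaches the 50 mV spike cutoff.
#' Defaults give a regular-spiking cell for the excitatory class and a
#' fast-spiking cell for the inhibitory class.
#'
#' @param cell_class `"excitatory"` or `"inhibitory"`; selects the default
#'   `(a, b, c, d)` quadruple.
#' @param a recovery rate of `u` (1/ms scale).
#' @param b coupling of `u` to voltage; the resting value of the dynamic
#'   excitability variable (see [adaptation_params()]).
#' @param c reset voltage (mV).
#' @param d recovery increment applied at each spike.
#' @return A list of class `"neuron_params"`.
#' @examples
#' neuron_params("inhibitory")
#' @export
neuron_params <- function(cell_class = c("excitatory", "inhibitory"),
                          a = NULL, b = NULL, c = NULL, d = NULL) {
  cell_class <- match.arg(cell_class)
  def <- if (cell_class == "excitatory") {
    list(a = 0.02, b = 0.2, c = -65, d = 10)
  } else {
    list(a = 0.2, b = 0.26, c = -65, d = 0.5)
  }
  p <- list(
    a = a %||% def$a, b = b %||% def$b, c = c %||% def$c, d = d %||% def$d,
    cell_class = cell_class
  )
  stopifnot(p$c < 50)
  structure(p, class = "neuron_params")
}

#' Conductance-synapse parameters
#'
#' First-order kinetics `dg/dt = -g/tau` for AMPA, NMDA, GABA-A and GABA-B
#' conductances; a presynaptic spike increments the postsynaptic conductances
#' instantaneously. The long NMDA time constant (2 s) mimics the
#' low-magnesium condition under which focal discharges are evoked in slices.
#'
#' @param tau_ampa,tau_nmda,tau_gabaa,tau_gabab decay constants (ms).
#' @param s_exc AMPA conductance increment per presynaptic excitatory spike.
#' @param nmda_ratio NMDA/AMPA increment ratio (uniform across synapses).
#' @param s_inh GABA-A increment per presynaptic inhibitory spike.
#' @param gabab_ratio GABA-B/GABA-A increment ratio.
#' @param v_exc,v_inh excitatory/inhibitory reversal potentials (mV).
#' @return A list of class `"synapse_params"`.
#' @export
synapse_params <- function(tau_ampa = 1, tau_nmda = 2000, tau_gabaa = 6,
                           tau_gabab = 150, s_exc = 0.001, nmda_ratio = 2,
                           s_inh = 0.01, gabab_ratio = 0.3,
                           v_exc = 0, v_inh = -90) {
  stopifnot(tau_ampa > 0, tau_nmda > 0, tau_gabaa > 0, tau_gabab > 0,
            s_exc >= 0, s_inh >= 0, nmda_ratio >= 0, gabab_ratio >= 0)
  structure(list(
    tau_ampa = tau_ampa, tau_nmda = tau_nmda, tau_gabaa = tau_gabaa,
    tau_gabab = tau_gabab, s_exc = s_exc, nmda_ratio = nmda_ratio,
    s_inh = s_inh, gabab_ratio = gabab_ratio, v_exc = v_exc, v_inh = v_inh
  ), class = "synapse_params")
}

#' Slow excitability-adaptation parameters
#'
#' Activity-dependent depression of the Izhikevich `b` parameter,
#' `db/dt = -m R(t) + recovery_rate (b_s - b)` with `b` relaxation expressed
#' per second, where `R(t)` is the neuron's spike train low-pass filtered with
#' time constant `tau_R` (seconds) and normalized so that its steady state
#' equals the firing rate in spikes/ms. Sustained discharge depresses `b`,
#' which terminates the seizure-like event; the slow recovery of `b` produces
#' the postictal refractory period.
#'
#' @param m coupling between filtered spiking and `b`.
#' @param tau_R spike-train filter time constant (s).
#' @param recovery_rate relaxation rate of `b` toward `b_s` (1/s).
#' @param b_s resting value of `b` (per neuron; defaults to the cell's
#'   static Izhikevich `b`).
#' @return A list of class `"adaptation_params"`.
#' @export
adaptation_params <- function(m = 15, tau_R = 150, recovery_rate = 1,
                              b_s = 0.2) {
  stopifnot(m >= 0, tau_R > 0, recovery_rate > 0)
  structure(list(m = m, tau_R = tau_R, recovery_rate = recovery_rate,
                 b_s = b_s), class = "adaptation_params")
}

#' Astrocyte calcium and gliotransmission parameters
#'
#' Two-variable somatic Ca2+ dynamics driven by spikes of the excitatory
#' neurons in the astrocyte's territory,
#' `d[Ca]/dt = -phi + sum_j sigma_j delta(t - t_f)`,
#' `dphi/dt = alpha (beta [Ca] - phi)` (time in ms), plus thresholded,
#' adapting glutamate release:
#' `mu d[glu]/dt = -[glu] + ([Ca] - ca_th) - kappa lambda` when `[Ca] > ca_th`
#' (drive term absent otherwise) and `eta dlambda/dt = -lambda + [glu]`,
#' with `mu`, `eta` in seconds. `[Ca]` and `[glu]` are clamped nonnegative.
#' Concentrations are in nominal mM.
#'
#' @param alpha recovery coupling rate (1/ms).
#' @param beta Ca2+-to-recovery gain.
#' @param sigma mean per-input Ca2+ increment per presynaptic spike (mM).
#' @param ca_th release threshold (mM); see [derive_threshold()].
#' @param kappa release-adaptation gain.
#' @param mu glutamate time constant (s).
#' @param eta adaptation time constant (s).
#' @return A list of class `"astrocyte_params"`.
#' @export
astrocyte_params <- function(alpha = 0.001, beta = 0.01, sigma = 0.00083,
                             ca_th = 0.0018, kappa = 200, mu = 0.5, eta = 10) {
  stopifnot(alpha > 0, beta > 0, sigma > 0, ca_th > 0, kappa >= 0,
            mu > 0, eta > 0)
  structure(list(alpha = alpha, beta = beta, sigma = sigma, ca_th = ca_th,
                 kappa = kappa, mu = mu, eta = eta),
            class = "astrocyte_params")
}

#' Gliotransmitter release threshold from the per-synapse value
#'
#' The astrocyte-level Ca2+ threshold for release is the single-synapse
#' threshold multiplied by the number of neuronal inputs the astrocyte
#' integrates (the cells in its 3x3 territory).
#'
#' @param per_synapse_threshold single-synapse Ca2+ threshold (any
#'   concentration unit; the result is in the same unit).
#' @param n_inputs number of neuronal inputs.
#' @return `per_synapse_threshold * n_inputs`.
#' @examples
#' derive_threshold(2e-4, 9)  # 0.0018 mM
#' @export
derive_threshold <- function(per_synapse_threshold, n_inputs) {
  stopifnot(per_synapse_threshold > 0, n_inputs > 0)
  per_synapse_threshold * n_inputs
}

`%||%` <- function(x, y) if (is.null(x)) y else x
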