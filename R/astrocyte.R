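#' Astrocyte state container
#'
#' Ca2+ concentration, recovery variable, released-glutamate signal and
#' release-adaptation variable for `n` astrocytes. Only `ca` and `glu` are
#' clamped nonnegative; `phi` and `lam` are free.
#'
#' @param n number of astrocytes.
#' @return list of class `"astrocyte_state"` with vectors `ca`, `phi`,
#'   `glu`, `lam`.
#' @export
astrocyte_state <- function(n) {
  z <- numeric(n)
  structure(list(ca = z, phi = z, glu = z, lam = z),
            class = "astrocyte_state")
}

#' One step of astrocytic Ca2+ dynamics
#'
#' Euler step of `d[Ca]/dt = -phi + input`, `dphi/dt = alpha (beta [Ca] - phi)`
#' with time in ms; `spike_input` is the summed weighted delta input
#' (`sum_j sigma_j` over inputs that spiked this step). Under a constant
#' weighted input rate `rho` (per ms) the steady state is `ca = rho / beta`,
#' `phi = rho`. Ca2+ is clamped at zero.
#'
#' @param state an [astrocyte_state()].
#' @param spike_input nonnegative weighted spike input this step (vectorized).
#' @param params an [astrocyte_params()] (fields may be vectors).
#' @param dt time step (ms).
#' @return the updated [astrocyte_state()].
#' @export
calcium_step <- function(state, spike_input, params = astrocyte_params(),
                         dt = 1) {
  stopifnot(all(spike_input >= 0))
  ca <- state$ca - state$phi * dt + spike_input
  phi <- state$phi + params$alpha * (params$beta * state$ca - state$phi) * dt
  ca[ca < 0] <- 0
  structure(list(ca = ca, phi = phi, glu = state$glu, lam = state$lam),
            class = "astrocyte_state")
}

#' One step of thresholded, adapting glutamate release
#'
#' `mu d[glu]/dt = -[glu] + ([Ca] - ca_th) - kappa lambda` while `[Ca]`
#' exceeds the release threshold; below threshold the drive term is absent.
#' `eta dlambda/dt = -lambda + [glu]` always. `mu` and `eta` are in seconds;
#' the step integrates the per-second rates over `dt` ms. `[glu]` is clamped
#' at zero. A Ca2+ level held above threshold yields a transient release that
#' relaxes to the small fixed point `(ca - ca_th)/(1 + kappa)` — a single
#' dominant episode — while Ca2+ oscillating across the threshold produces
#' pulsatile release.
#'
#' @param state an [astrocyte_state()].
#' @param params an [astrocyte_params()] (fields may be vectors).
#' @param dt time step (ms).
#' @return the updated [astrocyte_state()].
#' @export
glutamate_step <- function(state, params = astrocyte_params(), dt = 1) {
  dt_s <- dt / 1000
  drive <- pmax(state$ca - params$ca_th, 0) * (state$ca > params$ca_th)
  glu <- state$glu + (dt_s / params$mu) *
    (-state$glu + drive - params$kappa * state$lam)
  lam <- state$lam + (dt_s / params$eta) * (-state$lam + state$glu)
  glu[glu < 0] <- 0
  structure(list(ca = state$ca, phi = state$phi, glu = glu, lam = lam),
            class = "astrocyte_state")
}

#' Single-astrocyte harness: response to Poisson spike-train input
#'
#' Drives one astrocyte with `n_inputs` independent Poisson spike trains of a
#' common rate, each with its own Ca2+ increment drawn from
#' `N(sigma, (sd_frac * sigma)^2)`, and integrates the Ca2+ and release
#' dynamics at 1 ms resolution.
#'
#' @param rate_hz firing rate of each input train (Hz).
#' @param n_inputs number of input trains (1 to 9).
#' @param duration_ms simulated time (ms).
#' @param seed RNG seed for the input trains and weight draws.
#' @param params an [astrocyte_params()].
#' @param sd_frac relative SD of the per-input weight draws.
#' @return list with vectors `time` (ms), `ca`, `glu`, and `summary`
#'   (`mean_ca`, `total_glu` = sum of glu over time in concentration·ms,
#'   `peak_ca`).
#' @export
run_astro_unit <- function(rate_hz, n_inputs, duration_ms = 60000, seed = 1,
                           params = astrocyte_params(), sd_frac = 0.01) {
  stopifnot(rate_hz >= 0, n_inputs >= 1, n_inputs <= 9, duration_ms >= 1)
  set.seed(seed)
  sigma_j <- rnorm(n_inputs, params$sigma, sd_frac * params$sigma)
  p_ms <- rate_hz / 1000
  steps <- as.integer(duration_ms)
  # per-step weighted input: sum over inputs of sigma_j * Bernoulli(p_ms)
  spikes <- matrix(stats::runif(steps * n_inputs) < p_ms, nrow = steps)
  input <- as.numeric(spikes %*% sigma_j)
  tr <- astro_unit_run(input, params$alpha, params$beta, params$ca_th,
                       params$kappa, params$mu, params$eta)
  list(time = seq_len(steps), ca = tr$ca, glu = tr$glu,
       summary = list(mean_ca = mean(tr$ca), total_glu = sum(tr$glu),
                      peak_ca = max(tr$ca)))
}

#' Rate-by-input sweep of the single-astrocyte harness
#'
#' @param rates vector of input rates (Hz).
#' @param n_inputs_grid vector of input counts.
#' @param duration_ms simulated time per cell (ms).
#' @param seed base seed; each grid cell uses a distinct derived seed.
#' @param params an [astrocyte_params()].
#' @return data.frame with columns `rate_hz`, `n_inputs`, `mean_ca`,
#'   `total_glu`, `peak_ca`.
#' @export
astro_unit_sweep <- function(rates, n_inputs_grid = 1:9, duration_ms = 60000,
                             seed = 1, params = astrocyte_params()) {
  grid <- expand.grid(rate_hz = rates, n_inputs = n_inputs_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- run_astro_unit(grid$rate_hz[i], grid$n_inputs[i], duration_ms,
                          seed = seed + i, params = params)
    cbind(grid[i, ], as.data.frame(out$summary))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
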