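#' Centered moving average with edge truncation
#'
#' @param x numeric vector.
#' @param window window length in samples.
#' @return smoothed vector of the same length.
#' @export
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  if (window == 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- window %/% 2
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + (window - half - 1L))
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Population firing rate from a spike raster
#'
#' Per-ms population mean firing rate in Hz, optionally smoothed with a
#' moving-average window (50 ms by default, the smoothing used for all
#' display-facing traces).
#'
#' @param raster data.frame with columns `neuron` and `time_ms` (0-based ms).
#' @param window_ms moving-average window (ms); 1 disables smoothing.
#' @param population_mask logical vector over neurons selecting the
#'   population (default: all neurons up to `n_neurons`).
#' @param n_neurons number of neurons in the population universe.
#' @param duration_ms trace length (ms).
#' @return numeric vector of length `duration_ms` (Hz).
#' @export
firing_rate <- function(raster, window_ms = 50, population_mask = NULL,
                        n_neurons, duration_ms) {
  stopifnot(window_ms >= 1)
  keep <- if (is.null(population_mask)) rep(TRUE, nrow(raster)) else
    population_mask[raster$neuron]
  n_pop <- if (is.null(population_mask)) n_neurons else sum(population_mask)
  counts <- tabulate(raster$time_ms[keep] + 1L, nbins = duration_ms)
  rate <- counts / n_pop * 1000
  moving_average(rate, window_ms)
}

#' Population rate traces of a simulation
#'
#' Builds per-ms firing-rate traces (Hz) for the whole network and for the
#' excitatory, inhibitory, focus and outside-focus populations from the
#' engine's per-ms spike counts.
#'
#' @param result a [run_simulation()] result.
#' @param window_ms moving-average window (ms); 1 disables smoothing.
#' @return data.frame with columns `time_ms`, `all_hz`, `exc_hz`, `inh_hz`,
#'   `focus_hz`, `outside_hz`.
#' @export
network_rates <- function(result, window_ms = 50) {
  cn <- result$counts
  lay <- result$network$layout
  n <- lay$n; ne <- sum(lay$is_exc); ni <- n - ne
  nf <- sum(lay$focus_mask); no <- n - nf
  sm <- function(x, n_pop) moving_average(x / n_pop * 1000, window_ms)
  data.frame(
    time_ms = seq_len(nrow(cn)) - 1L,
    all_hz = sm(rowSums(cn), n),
    exc_hz = sm(cn[, "exc_focus"] + cn[, "exc_out"], ne),
    inh_hz = sm(cn[, "inh_focus"] + cn[, "inh_out"], ni),
    focus_hz = sm(cn[, "exc_focus"] + cn[, "inh_focus"], nf),
    outside_hz = sm(cn[, "exc_out"] + cn[, "inh_out"], no)
  )
}

#' Detect a sustained ictal discharge in a rate trace
#'
#' A discharge is considered generated when the smoothed network rate stays
#' above `sustain_hz` (1 Hz) continuously for at least `sustain_s` beyond a
#' SimP offset; the threshold is the ordinal of that SimP. The discharge end
#' is the first time after onset at which the rate stays below `end_hz` for
#' at least `end_s`; the duration is measured from the onset SimP's start.
#'
#' @param rate_hz smoothed per-ms network rate (Hz).
#' @param protocol list with `onsets` (SimP onset times, ms 0-based) and
#'   `pulse_duration` (ms).
#' @param sustain_hz,sustain_s sustained-rate criterion.
#' @param end_hz,end_s back-to-zero criterion.
#' @return list of class `"id_outcome"`: `generated`, `onset_pulse_index`,
#'   `onset_time_ms`, `end_time_ms`, `duration_s` (0 when not generated).
#' @export
detect_id <- function(rate_hz, protocol, sustain_hz = 1, sustain_s = 5,
                      end_hz = 0.1, end_s = 1) {
  onsets <- protocol$onsets
  offs <- onsets + protocol$pulse_duration
  T_ms <- length(rate_hz)
  if (length(onsets) == 0)
    return(structure(list(generated = FALSE, onset_pulse_index = NA_integer_,
                          onset_time_ms = NA_real_, end_time_ms = NA_real_,
                          duration_s = 0), class = "id_outcome"))
  if (T_ms < max(offs) + sustain_s * 1000)
    stop("rate trace shorter than the protocol requires")
  above <- rate_hz > sustain_hz
  ca <- cumsum(above)
  span <- as.integer(sustain_s * 1000)
  onset_idx <- NA_integer_
  for (p in seq_along(onsets)) {
    i0 <- offs[p] + 1L              # 1-based index of offset time
    i1 <- i0 + span - 1L
    if (i1 <= T_ms && (ca[i1] - ca[i0 - 1L]) == span) {
      onset_idx <- p
      break
    }
  }
  if (is.na(onset_idx)) {
    return(structure(list(generated = FALSE, onset_pulse_index = NA_integer_,
                          onset_time_ms = NA_real_, end_time_ms = NA_real_,
                          duration_s = 0), class = "id_outcome"))
  }
  below <- rate_hz < end_hz
  cb <- c(0, cumsum(below))
  wend <- as.integer(end_s * 1000)
  start <- offs[onset_idx] + span   # search after the sustained window
  end_time <- NA_real_
  if (start + 1L <= T_ms - wend + 1L) {
    i_all <- (start + 1L):(T_ms - wend + 1L)
    hit <- i_all[cb[i_all + wend] - cb[i_all] == wend]
    if (length(hit)) end_time <- hit[1] - 1L
  }
  onset_time <- onsets[onset_idx]
  dur <- if (is.na(end_time)) NA_real_ else (end_time - onset_time) / 1000
  structure(list(generated = TRUE, onset_pulse_index = onset_idx,
                 onset_time_ms = onset_time, end_time_ms = end_time,
                 duration_s = dur), class = "id_outcome")
}

#' Postictal refractory period from the adaptation trace
#'
#' Time from discharge end until the population-mean excitability variable
#' `b` first recovers to 95\% of its resting value.
#'
#' @param b_trace population-mean `b` values.
#' @param times_ms sample times of `b_trace` (ms).
#' @param b_s resting (population-mean) value of `b`.
#' @param end_time_ms discharge end time (ms).
#' @param level recovery level (fraction of `b_s`).
#' @return list with `refractory_s` (NA when censored) and `censored`.
#' @export
postictal_refractory <- function(b_trace, times_ms, b_s, end_time_ms,
                                 level = 0.95) {
  after <- times_ms >= end_time_ms
  rec <- after & (b_trace >= level * b_s)
  if (!any(rec)) return(list(refractory_s = NA_real_, censored = TRUE))
  t_rec <- times_ms[which(rec)[1]]
  list(refractory_s = (t_rec - end_time_ms) / 1000, censored = FALSE)
}

#' Propagation delay from focus to surround
#'
#' Time at which the smoothed outside-focus population rate first enters a
#' sustained (>= `sustain_s`) epoch above the recruitment threshold, minus
#' the onset SimP's start time. The sustained-epoch requirement mirrors the
#' discharge-detection criterion, so transient spillover of pulse-evoked
#' activity across the focus border does not count as recruitment; with
#' `sustain_s = 0` the first instantaneous crossing is used instead.
#'
#' @param outside_rate_hz smoothed per-ms outside-focus rate (Hz).
#' @param onset_pulse_time_ms start time of the discharge-triggering SimP.
#' @param threshold_hz recruitment threshold (Hz).
#' @param sustain_s minimum dwell above threshold (s).
#' @return delay in seconds (NA when the surround is never recruited).
#' @export
propagation_delay <- function(outside_rate_hz, onset_pulse_time_ms,
                              threshold_hz = 1, sustain_s = 5) {
  t0 <- as.integer(onset_pulse_time_ms)
  x <- outside_rate_hz[-seq_len(t0)] > threshold_hz   # from t0 onward
  if (!any(x)) return(NA_real_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= sustain_s * 1000
  if (!any(ok)) return(NA_real_)
  (starts[which(ok)[1]] - 1L) / 1000
}

#' Excitation/inhibition balance traces
#'
#' Regional means of the summed excitatory (AMPA + NMDA) and inhibitory
#' (GABA-A + GABA-B) currents, from the sampled traces, smoothed with a
#' 50 ms moving average, together with the population rates.
#'
#' @param result a [run_simulation()] result.
#' @param smooth_ms smoothing window (ms).
#' @return data.frame with `time_ms`, `region`, `excitation`, `inhibition`.
#' @export
balance_traces <- function(result, smooth_ms = 50) {
  tr <- result$traces
  cad <- result$config$record_cadence
  w <- max(1L, as.integer(round(smooth_ms / cad)))
  mk <- function(region, e, i) data.frame(
    time_ms = tr$time_ms, region = region,
    excitation = moving_average(e, w), inhibition = moving_average(i, w))
  rbind(mk("focus", tr$I_exc_focus, tr$I_inh_focus),
        mk("outside", tr$I_exc_out, tr$I_inh_out),
        mk("all", tr$I_exc_all, tr$I_inh_all))
}

#' Excitation-inhibition plane density
#'
#' 2D histogram of (excitation, |inhibition|) points over a time window,
#' comparable across runs when given common breaks.
#'
#' @param balance a [balance_traces()] data.frame (single region).
#' @param t_max_ms upper end of the time window (e.g. through the seventh
#'   SimP).
#' @param nbins number of bins per axis.
#' @param breaks optional list with `x`, `y` break vectors.
#' @return list with `x`, `y` bin breaks and `density` matrix (normalized to
#'   sum to 1).
#' @export
ei_plane_density <- function(balance, t_max_ms = Inf, nbins = 40,
                             breaks = NULL) {
  pts <- balance[balance$time_ms <= t_max_ms, ]
  x <- pts$excitation; y <- abs(pts$inhibition)
  if (is.null(breaks)) {
    breaks <- list(x = seq(0, max(x) * 1.001 + 1e-12, length.out = nbins + 1),
                   y = seq(0, max(y) * 1.001 + 1e-12, length.out = nbins + 1))
  }
  ix <- pmin(pmax(findInterval(x, breaks$x, all.inside = TRUE), 1), nbins)
  iy <- pmin(pmax(findInterval(y, breaks$y, all.inside = TRUE), 1), nbins)
  d <- matrix(0, nbins, nbins)
  for (k in seq_along(ix)) d[ix[k], iy[k]] <- d[ix[k], iy[k]] + 1
  list(x = breaks$x, y = breaks$y, density = d / sum(d))
}

#' Average rate spectrogram across runs
#'
#' Short-time Fourier power of per-ms population-rate traces (1 kHz
#' sampling), averaged across runs. During a fully developed discharge the
#' spectrogram shows two bands: a low one at the excitatory and a high one at
#' the inhibitory population firing frequency.
#'
#' @param rate_traces list of per-ms rate vectors (equal lengths), unsmoothed.
#' @param window_s STFT window (s).
#' @param overlap fractional window overlap.
#' @return list with `f` (Hz), `t` (s) and `power` (freq x time, mean across
#'   runs).
#' @export
rate_spectrogram <- function(rate_traces, window_s = 1, overlap = 0.5) {
  if (!length(rate_traces)) stop("need at least one rate trace")
  if (is.numeric(rate_traces)) rate_traces <- list(rate_traces)
  fs <- 1000
  nwin <- as.integer(window_s * fs)
  nov <- as.integer(nwin * overlap)
  acc <- NULL
  for (x in rate_traces) {
    sg <- signal::specgram(x, n = nwin, Fs = fs, overlap = nov)
    p <- Mod(sg$S)^2
    acc <- if (is.null(acc)) p else acc + p
  }
  sg <- signal::specgram(rate_traces[[1]], n = nwin, Fs = fs, overlap = nov)
  list(f = sg$f, t = sg$t, power = acc / length(rate_traces))
}

#' Threshold statistics over a Monte-Carlo ensemble
#'
#' Histogram of onset SimP indices over successful runs, the failure
#' fraction (runs with no discharge after all SimPs), and a Poisson fit to
#' the threshold distribution of the successes: the maximum-likelihood mean
#' (sample mean) with standard error `sqrt(mean/n)`.
#'
#' @param outcomes data.frame with logical `generated` and integer
#'   `threshold` columns (one row per run), as produced by
#'   [run_variant_suite()] or assembled from [simulation_outcome()] calls.
#' @param n_pulses number of pulses (histogram support).
#' @return list with `histogram` (named vector over 1..n_pulses),
#'   `failure_fraction`, `n_runs`, `n_success`, `poisson_mean`, `poisson_se`
#'   (NA when there are no successes, with `degenerate = TRUE`).
#' @export
threshold_statistics <- function(outcomes, n_pulses = 9) {
  stopifnot(nrow(outcomes) >= 1)
  succ <- as.integer(
    outcomes$threshold[outcomes$generated & !is.na(outcomes$threshold)])
  hist <- tabulate(succ, nbins = n_pulses)
  names(hist) <- seq_len(n_pulses)
  n <- nrow(outcomes)
  if (!length(succ)) {
    return(list(histogram = hist, failure_fraction = 1, n_runs = n,
                n_success = 0, poisson_mean = NA_real_,
                poisson_se = NA_real_, degenerate = TRUE))
  }
  mu <- mean(succ)
  list(histogram = hist, failure_fraction = 1 - length(succ) / n,
       n_runs = n, n_success = length(succ), poisson_mean = mu,
       poisson_se = sqrt(mu / length(succ)), degenerate = FALSE)
}

#' Full outcome summary of one simulation
#'
#' Applies [detect_id()], [postictal_refractory()], [propagation_delay()] and
#' the plateau population rates to a simulation result.
#'
#' @param result a [run_simulation()] result.
#' @param window_ms smoothing window for the rate traces (ms).
#' @param ... criterion overrides passed to [detect_id()].
#' @return list: `generated`, `onset_pulse_index`, `onset_time_ms`,
#'   `end_time_ms`, `duration_s`, `refractory_s`, `refractory_censored`,
#'   `propagation_delay_s`, `exc_plateau_hz`, `inh_plateau_hz`.
#' @export
simulation_outcome <- function(result, window_ms = 50, ...) {
  rates <- network_rates(result, window_ms)
  proto <- list(onsets = result$pulse_onsets,
                pulse_duration = result$config$pulse_duration)
  id <- detect_id(rates$all_hz, proto, ...)
  out <- c(unclass(id), list(refractory_s = NA_real_,
                             refractory_censored = NA,
                             propagation_delay_s = NA_real_,
                             exc_plateau_hz = NA_real_,
                             inh_plateau_hz = NA_real_))
  if (id$generated) {
    if (!is.na(id$end_time_ms)) {
      ref <- postictal_refractory(result$traces$mean_b,
                                  result$traces$time_ms,
                                  result$mean_b_s, id$end_time_ms)
      out$refractory_s <- ref$refractory_s
      out$refractory_censored <- ref$censored
      rates_pop <- id_population_rates(result, id)
      out$exc_plateau_hz <- rates_pop["exc_hz"]
      out$inh_plateau_hz <- rates_pop["inh_hz"]
    }
    out$propagation_delay_s <- propagation_delay(rates$outside_hz,
                                                 id$onset_time_ms)
  }
  out
}

#' Mean per-neuron population rates during the discharge plateau
#'
#' Mean excitatory and inhibitory per-neuron firing rates during the fully
#' developed discharge, taken over a window centered on the peak of the
#' 1-s-smoothed network rate between discharge onset and end (the plateau),
#' so the slow build-up and the terminal decline do not dilute the estimate.
#'
#' @param result a [run_simulation()] result.
#' @param id an [detect_id()] outcome with `generated = TRUE`.
#' @param half_window_s half-width of the plateau window (s).
#' @return named vector `c(exc_hz, inh_hz)`.
#' @export
id_population_rates <- function(result, id, half_window_s = 5) {
  stopifnot(id$generated, !is.na(id$end_time_ms))
  lay <- result$network$layout
  cn <- result$counts
  t0 <- id$onset_time_ms + result$config$pulse_duration
  t1 <- id$end_time_ms
  all_sm <- moving_average(rowSums(cn), 1000)
  pk <- t0 + which.max(all_sm[(t0 + 1L):t1]) - 1L
  w0 <- max(t0, pk - half_window_s * 1000)
  w1 <- min(t1, pk + half_window_s * 1000)
  rows <- (w0 + 1L):w1          # counts row r is time r-1
  secs <- (w1 - w0) / 1000
  c(exc_hz = sum(cn[rows, "exc_focus"] + cn[rows, "exc_out"]) /
      sum(lay$is_exc) / secs,
    inh_hz = sum(cn[rows, "inh_focus"] + cn[rows, "inh_out"]) /
      sum(!lay$is_exc) / secs)
}
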