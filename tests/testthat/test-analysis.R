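proto <- list(onsets = seq(1000, 25000, by = 3000), pulse_duration = 500)

# synthetic rate trace: >1 Hz during every pulse, sustained from pulse k on
synth_rate <- function(T_ms, proto, sustained_from = NA, level = 8,
                       end_at = NA) {
  x <- numeric(T_ms)
  for (on in proto$onsets)
    x[(on + 1):(on + proto$pulse_duration)] <- level
  if (!is.na(sustained_from)) {
    from <- proto$onsets[sustained_from] + 1
    to <- if (is.na(end_at)) T_ms else end_at
    x[from:to] <- level
  }
  x
}

test_that("firing_rate converts rasters to Hz and smoothing conserves mass", {
  empty <- data.frame(neuron = integer(0), time_ms = integer(0))
  expect_equal(firing_rate(empty, 1, n_neurons = 10, duration_ms = 100),
               rep(0, 100))
  # every neuron fires once per 100 ms -> 10 Hz population mean
  ras <- expand.grid(neuron = 1:20, t0 = seq(0, 900, by = 100))
  ras$time_ms <- ras$t0 + as.integer(ras$neuron %% 97) %% 100
  r <- firing_rate(ras, window_ms = 1, n_neurons = 20, duration_ms = 1000)
  expect_equal(mean(r), 10)
  sm <- firing_rate(ras, window_ms = 50, n_neurons = 20, duration_ms = 1000)
  expect_equal(mean(sm), mean(r), tolerance = 0.02)  # integral conserved
  # population mask restricts the census
  mask <- rep(c(TRUE, FALSE), 10)
  rm <- firing_rate(ras, 1, population_mask = mask, n_neurons = 20,
                    duration_ms = 1000)
  expect_equal(mean(rm), 10)
  # interior mass conservation is exact for a compactly supported bump
  x <- numeric(1000); x[400:600] <- 3
  expect_equal(sum(moving_average(x, 50)), sum(x), tolerance = 1e-12)
})

test_that("detect_id finds the triggering pulse and the discharge end", {
  T_ms <- 120000
  # sustained from the 5th pulse for 60 s
  on5 <- proto$onsets[5]
  x <- synth_rate(T_ms, proto, sustained_from = 5, end_at = on5 + 60000)
  out <- detect_id(x, proto)
  expect_true(out$generated)
  expect_equal(out$onset_pulse_index, 5)
  expect_equal(out$onset_time_ms, on5)
  expect_equal(out$end_time_ms, on5 + 60000, tolerance = 2)
  expect_equal(out$duration_s, 60, tolerance = 0.01)
  # activity only during pulses: not a discharge
  out0 <- detect_id(synth_rate(T_ms, proto), proto)
  expect_false(out0$generated)
  expect_equal(out0$duration_s, 0)
  # all-zero trace
  expect_false(detect_id(numeric(T_ms), proto)$generated)
  # too-short trace errors
  expect_error(detect_id(numeric(5000), proto), "shorter")
})

test_that("detect_id threshold is monotone: stricter criterion never advances onset", {
  T_ms <- 120000
  set.seed(21)
  for (k in 1:8) {
    from <- sample(2:8, 1)
    lev <- runif(1, 1.5, 12)
    x <- synth_rate(T_ms, proto, sustained_from = from, level = lev,
                    end_at = proto$onsets[from] + 50000)
    lo <- detect_id(x, proto, sustain_hz = 1)
    hi <- detect_id(x, proto, sustain_hz = 2)
    if (hi$generated) {
      expect_true(lo$generated)
      expect_gte(hi$onset_pulse_index, lo$onset_pulse_index)
    }
    # idempotence: same input, same answer
    expect_identical(lo, detect_id(x, proto, sustain_hz = 1))
  }
})

test_that("postictal refractory matches the exponential crossing time", {
  b_s <- 0.2
  times <- seq(0, 500000, by = 10)
  end_t <- 80000
  Delta <- 0.12
  tau <- 60000
  b <- b_s - Delta * exp(-(pmax(times - end_t, 0)) / tau)
  out <- postictal_refractory(b, times, b_s, end_t)
  expect_false(out$censored)
  expect_equal(out$refractory_s, tau * log(Delta / (0.05 * b_s)) / 1000,
               tolerance = 0.01)
  # constant at b_s: zero
  expect_equal(postictal_refractory(rep(b_s, 100), 1:100 * 10, b_s, 200)$refractory_s, 0)
  # already within 5%: zero
  b2 <- b_s - 0.004 * exp(-(pmax(times - end_t, 0)) / tau)
  expect_equal(postictal_refractory(b2, times, b_s, end_t)$refractory_s, 0)
  # never recovering: censored
  out3 <- postictal_refractory(rep(0.5 * b_s, 100), 1:100 * 10, b_s, 200)
  expect_true(out3$censored)
})

test_that("propagation delay finds the sustained outside recruitment", {
  x <- numeric(60000)
  x[(13000 + 10000 + 1):60000] <- 5    # sustained from onset + 10 s
  expect_equal(propagation_delay(x, 13000), 10)
  # a transient pulse-locked excursion is ignored
  x[13501:13900] <- 5                  # times 13500-13899 ms
  expect_equal(propagation_delay(x, 13000), 10)
  # but counts with the instantaneous estimator
  expect_equal(propagation_delay(x, 13000, sustain_s = 0), 0.5)
  expect_true(is.na(propagation_delay(numeric(60000), 13000)))
  expect_gte(propagation_delay(x, 13000), 0)
})

test_that("balance traces average the recorded currents by region", {
  cfg <- small_config(duration_ms = 1000, seed = 2)
  res <- run_simulation(cfg)
  bal <- balance_traces(res, smooth_ms = res$config$record_cadence)  # no smoothing
  expect_setequal(unique(bal$region), c("focus", "outside", "all"))
  # all-region trace equals the census-weighted mean of focus and outside
  n_f <- sum(res$network$layout$focus_mask)
  n_o <- res$network$layout$n - n_f
  f <- bal[bal$region == "focus", ]
  o <- bal[bal$region == "outside", ]
  a <- bal[bal$region == "all", ]
  expect_equal(a$excitation, (f$excitation * n_f + o$excitation * n_o) / (n_f + n_o),
               tolerance = 1e-10)
  # hand-computed single-neuron current at a recorded step
  v <- -70; g_a <- 0.02; g_n <- 0.01
  expect_equal(synaptic_current(v, list(g_ampa = g_a, g_nmda = g_n,
                                        g_gabaa = 0, g_gabab = 0))$I_exc,
               (g_a + g_n * nmda_gating(v)) * 70)
  # zero-conductance network records zero currents
  cfg0 <- small_config(duration_ms = 300, seed = 2, n_pulses = 0)
  res0 <- run_simulation(cfg0)
  expect_true(all(res0$traces$I_exc_all == 0 & res0$traces$I_inh_all == 0))
})

test_that("ei plane density is a normalized histogram", {
  bal <- data.frame(time_ms = 1:1000, region = "focus",
                    excitation = runif(1000, 0, 3),
                    inhibition = -runif(1000, 0, 5))
  d <- ei_plane_density(bal, t_max_ms = 800, nbins = 10)
  expect_equal(sum(d$density), 1)
  expect_equal(dim(d$density), c(10, 10))
})

test_that("spectrogram recovers a pure oscillation and a constant", {
  t <- seq(0, 19.999, by = 0.001)
  x20 <- 10 + 5 * sin(2 * pi * 20 * t)
  sp <- rate_spectrogram(list(x20, x20))
  pw <- rowMeans(sp$power)
  f_ac <- sp$f[sp$f > 2]
  expect_equal(f_ac[which.max(pw[sp$f > 2])], 20, tolerance = 0.05)
  const <- rate_spectrogram(rep(4, 20000))
  pc <- rowMeans(const$power)
  expect_equal(const$f[which.max(pc)], 0)           # all power at DC
  expect_lt(max(pc[const$f > 1]) / pc[1], 1e-4)     # window leakage only
})

test_that("threshold statistics recover a known Poisson ensemble", {
  oc <- data.frame(generated = rep(TRUE, 5), threshold = rep(4, 5))
  st <- threshold_statistics(oc)
  expect_equal(st$poisson_mean, 4)
  expect_equal(st$failure_fraction, 0)
  expect_equal(unname(st$histogram[4]), 5)
  # 250 draws from Poisson(5): ML mean within 3 standard errors
  set.seed(17)
  draws <- rpois(250, 5)
  draws <- draws[draws >= 1 & draws <= 9]
  oc2 <- data.frame(generated = TRUE, threshold = draws)
  st2 <- threshold_statistics(oc2)
  expect_lt(abs(st2$poisson_mean - 5), 3 * st2$poisson_se)
  expect_equal(st2$poisson_se, sqrt(st2$poisson_mean / length(draws)))
  # failures counted separately, successes still fit
  oc3 <- rbind(oc2, data.frame(generated = FALSE, threshold = NA)[rep(1, 50), ])
  st3 <- threshold_statistics(oc3)
  expect_equal(st3$failure_fraction, 50 / (50 + length(draws)))
  expect_equal(st3$poisson_mean, st2$poisson_mean)
  # degenerate: no successes
  st4 <- threshold_statistics(data.frame(generated = FALSE, threshold = NA))
  expect_true(st4$degenerate)
  expect_true(is.na(st4$poisson_mean))
})
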