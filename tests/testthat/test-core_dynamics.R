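test_that("NMDA gating follows the magnesium-block curve", {
  expect_equal(nmda_gating(-80), 0)
  expect_equal(nmda_gating(-20), 0.5)
  expect_equal(nmda_gating(-70), (10 / 60)^2 / (1 + (10 / 60)^2),
               tolerance = 1e-12)
  # strictly increasing above -80 mV, bounded in [0, 1)
  v <- seq(-79, 60, by = 1)
  g <- nmda_gating(v)
  expect_true(all(diff(g) > 0))
  expect_true(all(g >= 0 & g < 1))
})

test_that("synaptic currents have the right sign and driving forces", {
  syn <- synapse_state(1)
  expect_equal(synaptic_current(-70, syn), list(I_exc = 0, I_inh = 0))
  syn$g_ampa <- 0.001
  expect_equal(synaptic_current(-70, syn)$I_exc, 0.001 * 70)
  syn <- synapse_state(1)
  syn$g_gabaa <- 0.01
  expect_equal(synaptic_current(-90, syn)$I_inh, 0)   # at reversal
  # depolarizing-positive convention across voltages
  syn <- synapse_state(1)
  syn$g_ampa <- 0.1; syn$g_nmda <- 0.2; syn$g_gabaa <- 0.1; syn$g_gabab <- 0.03
  for (v in c(-85, -70, -50)) {
    cur <- synaptic_current(v, syn)
    expect_gt(cur$I_exc, 0)
    expect_lt(cur$I_inh, 0)
  }
})

test_that("conductances decay by the exact exponential and stay nonnegative", {
  syn <- synapse_state(1)
  syn$g_ampa <- 1; syn$g_nmda <- 0.002
  out <- decay_conductances(syn, dt = 1)
  expect_equal(out$g_ampa, exp(-1), tolerance = 1e-12)
  out2000 <- syn
  for (i in 1:2000) out2000 <- decay_conductances(out2000, dt = 1)
  expect_equal(out2000$g_nmda, 0.002 * exp(-1), tolerance = 1e-9)
  expect_true(all(unlist(out2000[c("g_ampa", "g_nmda", "g_gabaa", "g_gabab")]) >= 0))
})

test_that("spike delivery adds the per-receptor increments", {
  syn <- synapse_state(1)
  expect_identical(deliver_spikes(syn, 0, 0), syn)
  one_e <- deliver_spikes(syn, 1, 0)
  expect_equal(one_e$g_ampa, 0.001)
  expect_equal(one_e$g_nmda, 0.002)
  one_i <- deliver_spikes(syn, 0, 1)
  expect_equal(one_i$g_gabaa, 0.01)
  expect_equal(one_i$g_gabab, 0.003)
})

test_that("membrane fixed points match the quadratic nullcline roots", {
  # 0.04 v^2 + (5 - b) v + 140 = 0 with b = 0.2 has roots -70 and -50
  st <- neuron_state(1, v = -70, u = -0.2 * 70)
  syn <- synapse_state(1)
  np <- neuron_params("excitatory")
  out <- izhikevich_step(st, np, syn, I_ext = 0)
  expect_equal(out$v, st$v, tolerance = 1e-12)
  expect_equal(out$u, st$u, tolerance = 1e-12)
  expect_false(out$spiked)
  # rest_state solves the same quadratic
  expect_equal(rest_state(0.2, 0)$v, -70, tolerance = 1e-12)
  roots <- polyroot(c(140, 5 - 0.2, 0.04))
  expect_equal(sort(Re(roots)), c(-70, -50), tolerance = 1e-9)
})

test_that("spike reset clamps voltage below cutoff and increments u", {
  st <- neuron_state(1, v = 49.5, u = 0)
  np <- neuron_params("excitatory")
  out <- izhikevich_step(st, np, synapse_state(1), I_ext = 0)
  expect_true(out$spiked)
  expect_equal(out$v, -65)
  u_before_reset <- 0 + np$a * (np$b * 49.5 - 0)
  expect_equal(out$u, u_before_reset + np$d)
  # reset invariant under strong drive
  st <- rest_state(0.2, 2)
  vmax <- -Inf
  for (i in 1:2000) {
    st <- izhikevich_step(st, np, synapse_state(1), I_ext = 30)
    vmax <- max(vmax, st$v)
  }
  expect_lt(vmax, 50)
})

test_that("neuron at rest stays silent over 1e5 steps, incl. tonic current", {
  np_e <- neuron_params("excitatory")
  np_i <- neuron_params("inhibitory")
  # both classes at once: I = (2, 0), rest at the holding current
  b <- c(np_e$b, np_i$b)
  I <- c(2, 0)
  st <- rest_state(b, I)
  params <- list(a = c(np_e$a, np_i$a), b = b,
                 c = c(np_e$c, np_i$c), d = c(np_e$d, np_i$d))
  syn <- synapse_state(2)
  spikes <- 0L
  for (i in 1:100000) {
    st <- izhikevich_step(st, params, syn, I_ext = I)
    spikes <- spikes + sum(st$spiked)
  }
  expect_identical(spikes, 0L)
  # tonic current 2 is below the excitatory saddle-node (positive discriminant)
  expect_gt((5 - 0.2)^2 - 4 * 0.04 * (140 + 2), 0)
})

test_that("non-finite state is rejected with a diagnostic", {
  st <- neuron_state(1, v = NaN, u = 0)
  expect_error(izhikevich_step(st, neuron_params(), synapse_state(1)),
               "non-finite")
})

test_that("adaptation filter matches its quasi-steady closed form", {
  ad <- adaptation_state(1, b = 0.2)
  p <- adaptation_params()
  out <- adaptation_step(ad, FALSE, p)
  expect_equal(out$b, ad$b)
  expect_equal(out$R, 0)
  # deterministic firing at r = 1/67 spikes/ms for T = 150 s (= one tau_R):
  # R approaches r * (1 - exp(-T/tau_R)); b tracks b_s - (m/rec) R
  r <- 1 / 67
  T_ms <- 150000
  ad <- adaptation_state(1, b = 0.2)
  for (i in 1:T_ms) ad <- adaptation_step(ad, i %% 67 == 0, p)
  expect_equal(ad$R, r * (1 - exp(-1)), tolerance = 0.03)
  expect_lt(abs(ad$b - (p$b_s - p$m / p$recovery_rate * ad$R)), 5e-3)
  # the quasi-steady value at a sustained 15 Hz is negative: strong
  # excitability loss during the discharge
  expect_lt(p$b_s - p$m / p$recovery_rate * 0.015, 0)
  # with no further spikes b recovers toward b_s: monotone once past the
  # brief relaxation onto the quasi-steady path (b chases b_s - (m/rec) R
  # while R decays)
  bb <- numeric(8000)
  for (i in 1:8000) { ad <- adaptation_step(ad, FALSE, p); bb[i] <- ad$b }
  expect_true(all(diff(bb[3000:8000]) >= -1e-12))
  expect_true(all(bb <= p$b_s))
  expect_gt(bb[8000], bb[1])
})

test_that("unitary PSPs are ~0.1 mV (EPSP) and ~0.5 mV (IPSP)", {
  psp <- function(exc) {
    st <- rest_state(0.2, 0)
    syn <- synapse_state(1)
    syn <- if (exc) deliver_spikes(syn, 1, 0) else deliver_spikes(syn, 0, 1)
    v0 <- st$v
    dev <- 0
    np <- neuron_params("excitatory")
    for (t in 1:500) {
      st <- izhikevich_step(st, np, syn, I_ext = 0)
      syn <- decay_conductances(syn)
      dev <- if (exc) max(dev, st$v - v0) else min(dev, st$v - v0)
    }
    dev
  }
  expect_gt(psp(TRUE), 0.05)
  expect_lt(psp(TRUE), 0.15)
  expect_lt(psp(FALSE), -0.25)
  expect_gt(psp(FALSE), -0.75)
})
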