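# ictalnet

Simulation of focal seizure-like ictal discharge (ID) generation in a
neuron–astrocyte network, for computational neuroscientists studying how
astrocytic gliotransmission shifts the excitation/inhibition balance at an
epileptogenic focus.

## The model

A 20×20 grid of Izhikevich neurons (320 regular-spiking excitatory, 80
fast-spiking inhibitory, randomly placed) with conductance-based synapses:

- membrane: `v' = 0.04 v² + 5 v + 140 − u + I`, `u' = a(bv − u)`, reset
  `v ← c`, `u ← u + d` at the 50 mV cutoff, integrated at 1 ms with the
  implicit-conductance update `v(t+1) = (v + f(v,u) + gE + I)/(1 + g)`,
  which stays stable under discharge-scale conductances;
- synapses: AMPA/NMDA/GABA_A/GABA_B with τ = 1/2000/6/150 ms, per-spike
  increments s_exc = 0.001 (NMDA 2×), s_inh = 0.01 (GABA_B 0.3×), NMDA
  gated by the magnesium-block factor `[(v+80)/60]²/(1+[(v+80)/60]²)`;
  excitatory inputs from the 7×7 neighborhood, inhibition from the 3×3;
- slow excitability depression `b' = −m R(t) + r(b_s − b)` (m = 15,
  τ_R = 150 s) that terminates the discharge and produces the postictal
  refractory period;
- one astrocyte per grid site, integrating local excitatory spiking into
  two-variable Ca²⁺ dynamics (`α = 0.001`, `β = 0.01`) with thresholded,
  adapting glutamate release above Ca²⁺ = 0.0018 mM, fed back onto the
  territory's neurons as NMDA (or, in a variant, GABA_A) conductance.

The stimulation protocol injects nine 500-ms depolarizing pulses (SimPs)
into the centered 7×7 focus; the ID threshold is the ordinal of the SimP
after which the 50-ms-smoothed network rate stays above 1 Hz. Variant
flags reproduce the study's comparisons: astrocytes on/off, regional
astrocyte blockade (BAPTA surrogate), inhibitory-only gliotransmission,
and strengthened inhibitory synapses. All parameters are heterogeneous
(1 % SD draws) and every run is exactly reproducible from its seed. The
time-stepped core is compiled (Rcpp) and verified bit-for-bit against a
pure-R reference loop.

See the vignette (`vignettes/focal-discharge-model.Rmd`) for the full
model description, the two calibrated protocol constants, numerical
choices and known limitations.

## A worked example

```r
library(ictalnet)

cfg <- sim_config(duration_ms = 120000, seed = 4)   # defaults: no astrocytes
res <- run_simulation(cfg)
simulation_outcome(res)
#> $generated           TRUE
#> $onset_pulse_index   3        # third SimP starts the sustained discharge
#> $duration_s          59.0     # about a minute of sustained firing
#> $propagation_delay_s 3.09     # surround recruited ~3 s after that SimP
#> $exc_plateau_hz      11.7     # per-neuron plateau rates
#> $inh_plateau_hz      32.4
```

The third pulse tips this network into a self-sustained discharge carried
by accumulated NMDA conductance; the discharge spreads from the focus,
holds for ~59 s, then collapses as the excitability variable `b` depresses.
Re-running with `astro_enabled = TRUE` lowers the threshold (here 3 → 2):
focal astrocytes sense the pulse-evoked spiking, cross their Ca²⁺ release
threshold and feed glutamate back onto the same neurons. Monte-Carlo
comparisons across the variant conditions:

```r
out <- run_variant_suite(sim_config(duration_ms = 40000), n_runs = 20)
threshold_statistics(out[out$variant == "no_astro", ])
```

A thin command-line front end is installed at `inst/cli/ictalnet`
(subcommands `simulate`, `astro-unit`, `sweep`, `analyze`).

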