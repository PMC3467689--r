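#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Full coupled neuron-astrocyte network integration at a 1 ms step.
//
// Per-step order (part of the reproducibility contract, mirrored by the R
// reference loop used in the tests):
//   1. exponential decay of all synaptic conductances
//   2. delivery of the previous step's spikes (one-step transmission delay)
//   3. astrocytic feedback drive (gain * glu * dt onto NMDA or GABA-A)
//   4. membrane update: implicit-conductance Izhikevich step + reset
//   5. slow excitability adaptation (R filter, dynamic b)
//   6. astrocyte Ca2+ and gliotransmitter update driven by this step's spikes
//
// The engine is deterministic: all random draws happen R-side at build time.

// [[Rcpp::export]]
List engine_run(List net, List neuron, List syn, List adapt, List astro,
                List protocol, List control) {
  const int n = as<int>(net["n"]);
  const LogicalVector is_exc = net["is_exc"];
  const LogicalVector focus = net["focus"];
  const IntegerVector exc_ptr = net["exc_ptr"];   // CSR pre -> posts (0-based)
  const IntegerVector exc_post = net["exc_post"];
  const NumericVector exc_w = net["exc_w"];
  const IntegerVector inh_ptr = net["inh_ptr"];
  const IntegerVector inh_post = net["inh_post"];
  const NumericVector inh_w = net["inh_w"];

  NumericVector v = clone(as<NumericVector>(neuron["v0"]));
  NumericVector u = clone(as<NumericVector>(neuron["u0"]));
  const NumericVector a = neuron["a"];
  const NumericVector bs = neuron["bs"];
  const NumericVector cr = neuron["c"];
  const NumericVector dr = neuron["d"];

  const double dec_ampa = as<double>(syn["dec_ampa"]);
  const double dec_nmda = as<double>(syn["dec_nmda"]);
  const double dec_gabaa = as<double>(syn["dec_gabaa"]);
  const double dec_gabab = as<double>(syn["dec_gabab"]);
  const double nmda_ratio = as<double>(syn["nmda_ratio"]);
  const double gabab_ratio = as<double>(syn["gabab_ratio"]);
  const double v_exc = as<double>(syn["v_exc"]);
  const double v_inh = as<double>(syn["v_inh"]);

  const double m_cpl = as<double>(adapt["m"]);
  const double tauR_ms = as<double>(adapt["tauR_ms"]);
  const double recovery = as<double>(adapt["recovery"]);   // 1/s
  const LogicalVector adapt_mask = adapt["mask"];
  const double decR = std::exp(-1.0 / tauR_ms);
  const double invR = 1.0 / tauR_ms;

  const bool astro_on = as<bool>(astro["enabled"]);
  const IntegerVector patch_ptr = astro["patch_ptr"];
  const IntegerVector patch_idx = astro["patch_idx"];
  const NumericVector patch_sigma = astro["patch_sigma"];
  const IntegerVector targ_ptr = astro["targ_ptr"];
  const IntegerVector targ_idx = astro["targ_idx"];
  const NumericVector alpha = astro["alpha"];
  const NumericVector beta = astro["beta"];
  const double ca_th = as<double>(astro["ca_th"]);
  const double kappa = as<double>(astro["kappa"]);
  const double mu_s = as<double>(astro["mu_s"]);
  const double eta_s = as<double>(astro["eta_s"]);
  const double gain = as<double>(astro["gain"]);
  const double input_gain = as<double>(astro["input_gain"]);
  const LogicalVector blocked = astro["blocked"];
  const bool mode_gabaa = as<bool>(astro["mode_gabaa"]);
  const int n_ast = astro_on ? n : 0;

  const IntegerVector pulse_onset = protocol["pulse_onset"]; // ms, 0-based
  const int pulse_dur = as<int>(protocol["pulse_dur"]);
  const double amp = as<double>(protocol["amplitude"]);
  const double tonic = as<double>(protocol["tonic"]);

  const int T = as<int>(control["T"]);
  const int cadence = as<int>(control["cadence"]);
  const bool rec_raster = as<bool>(control["record_raster"]);

  std::vector<char> pulse_active(T, 0);
  for (int p = 0; p < pulse_onset.size(); ++p) {
    int t0 = pulse_onset[p];
    for (int t = std::max(0, t0); t < std::min(T, t0 + pulse_dur); ++t)
      pulse_active[t] = 1;
  }

  std::vector<double> g_ampa(n, 0.0), g_nmda(n, 0.0),
      g_gabaa(n, 0.0), g_gabab(n, 0.0);
  std::vector<char> spiked_prev(n, 0), spiked_now(n, 0);
  std::vector<double> Rf(n, 0.0), b_dyn(bs.begin(), bs.end());
  std::vector<double> ca(n_ast, 0.0), phi(n_ast, 0.0),
      glu(n_ast, 0.0), lam(n_ast, 0.0);

  // region bookkeeping
  int n_focus = 0, n_out = 0, na_focus = 0, na_out = 0;
  for (int i = 0; i < n; ++i) (focus[i] ? n_focus : n_out)++;
  na_focus = n_focus; na_out = n_out;

  IntegerMatrix counts(T, 4);  // exc_focus, exc_out, inh_focus, inh_out
  const int nrec = (T + cadence - 1) / cadence;
  const int ntrc = 13;
  NumericMatrix traces(nrec, ntrc);
  std::vector<int> ras_n, ras_t;
  if (rec_raster) { ras_n.reserve(1 << 18); ras_t.reserve(1 << 18); }

  int irec = 0;
  for (int t = 0; t < T; ++t) {
    // 1. decay (flush subnormals to zero: slow exponential tails otherwise
    // stick at the smallest denormal and poison the FPU for the whole run)
    const double TINY = 2.3e-308;
    for (int i = 0; i < n; ++i) {
      g_ampa[i] *= dec_ampa;   if (g_ampa[i] < TINY) g_ampa[i] = 0.0;
      g_nmda[i] *= dec_nmda;   if (g_nmda[i] < TINY) g_nmda[i] = 0.0;
      g_gabaa[i] *= dec_gabaa; if (g_gabaa[i] < TINY) g_gabaa[i] = 0.0;
      g_gabab[i] *= dec_gabab; if (g_gabab[i] < TINY) g_gabab[i] = 0.0;
    }
    // 2. deliver previous step's spikes
    for (int j = 0; j < n; ++j) {
      if (!spiked_prev[j]) continue;
      if (is_exc[j]) {
        for (int k = exc_ptr[j]; k < exc_ptr[j + 1]; ++k) {
          g_ampa[exc_post[k]] += exc_w[k];
          g_nmda[exc_post[k]] += exc_w[k] * nmda_ratio;
        }
      } else {
        for (int k = inh_ptr[j]; k < inh_ptr[j + 1]; ++k) {
          g_gabaa[inh_post[k]] += inh_w[k];
          g_gabab[inh_post[k]] += inh_w[k] * gabab_ratio;
        }
      }
    }
    // 3. astrocytic feedback
    if (astro_on) {
      for (int k = 0; k < n_ast; ++k) {
        double inc = gain * glu[k];
        if (inc <= 0) continue;
        if (mode_gabaa) {
          for (int q = targ_ptr[k]; q < targ_ptr[k + 1]; ++q)
            g_gabaa[targ_idx[q]] += inc;
        } else {
          for (int q = targ_ptr[k]; q < targ_ptr[k + 1]; ++q)
            g_nmda[targ_idx[q]] += inc;
        }
      }
    }
    // 4. membrane update
    const bool active = pulse_active[t];
    const bool recording = (t % cadence == 0);
    double sIe_f = 0, sIi_f = 0, sIe_o = 0, sIi_o = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      double I = (is_exc[i] ? tonic : 0.0) + ((active && focus[i]) ? amp : 0.0);
      double x = (v[i] + 80.0) / 60.0;
      double gate = x * x / (1.0 + x * x);
      double ge = g_ampa[i] + g_nmda[i] * gate;
      double gi = g_gabaa[i] + g_gabab[i];
      double g = ge + gi;
      double gE = ge * v_exc + gi * v_inh;
      // 0.04*(v*v): grouped as in the R reference so the two integrators
      // agree bit for bit
      double f = 0.04 * (v[i] * v[i]) + 5.0 * v[i] + 140.0 - u[i];
      double vn = (v[i] + f + gE + I) / (1.0 + g);
      double un = u[i] + a[i] * (b_dyn[i] * v[i] - u[i]);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("non-finite neuron state at step %d (neuron %d)", t, i + 1);
      if (recording) {
        double Ie = ge * (v_exc - v[i]);
        double Ii = gi * (v_inh - v[i]);
        if (focus[i]) { sIe_f += Ie; sIi_f += Ii; }
        else { sIe_o += Ie; sIi_o += Ii; }
      }
      if (vn >= 50.0) {
        spiked_now[i] = 1;
        v[i] = cr[i];
        u[i] = un + dr[i];
        int col = (is_exc[i] ? 0 : 2) + (focus[i] ? 0 : 1);
        counts(t, col)++;
        if (rec_raster) { ras_n.push_back(i + 1); ras_t.push_back(t); }
      } else {
        spiked_now[i] = 0;
        v[i] = vn;
        u[i] = un;
      }
    }
    // 5. adaptation
    for (int i = 0; i < n; ++i) {
      Rf[i] = Rf[i] * decR + (spiked_now[i] ? invR : 0.0);
      if (Rf[i] < TINY) Rf[i] = 0.0;
      if (adapt_mask[i])
        b_dyn[i] += 0.001 * (-m_cpl * Rf[i] + recovery * (bs[i] - b_dyn[i]));
      if (recording) sb += b_dyn[i];
    }
    // 6. astrocytes (driven by this step's spikes)
    if (astro_on) {
      for (int k = 0; k < n_ast; ++k) {
        double input = 0.0;
        for (int q = patch_ptr[k]; q < patch_ptr[k + 1]; ++q)
          if (spiked_now[patch_idx[q]]) input += patch_sigma[q];
        input *= input_gain;
        double ca_new = ca[k] - phi[k] + input;           // dt = 1 ms
        phi[k] += alpha[k] * (beta[k] * ca[k] - phi[k]);
        if (ca_new < 0) ca_new = 0;
        if (blocked[k]) ca_new = 0;
        ca[k] = ca_new;
        double drive = (ca[k] > ca_th) ? (ca[k] - ca_th) : 0.0;
        double glu_new = glu[k] + (0.001 / mu_s) *
            (-glu[k] + drive - kappa * lam[k]);
        lam[k] += (0.001 / eta_s) * (-lam[k] + glu[k]);
        glu[k] = (glu_new < 0) ? 0.0 : glu_new;
        if (ca[k] < TINY) ca[k] = 0.0;
        if (glu[k] < TINY) glu[k] = 0.0;
        if (std::fabs(phi[k]) < TINY) phi[k] = 0.0;
        if (std::fabs(lam[k]) < TINY) lam[k] = 0.0;
      }
    }
    if (recording) {
      double ca_f = 0, ca_o = 0, gl_f = 0, gl_o = 0;
      if (astro_on) {
        for (int k = 0; k < n_ast; ++k) {
          if (focus[k]) { ca_f += ca[k]; gl_f += glu[k]; }
          else { ca_o += ca[k]; gl_o += glu[k]; }
        }
      }
      traces(irec, 0) = t;
      traces(irec, 1) = sIe_f / n_focus;
      traces(irec, 2) = sIi_f / n_focus;
      traces(irec, 3) = sIe_o / n_out;
      traces(irec, 4) = sIi_o / n_out;
      traces(irec, 5) = (sIe_f + sIe_o) / n;
      traces(irec, 6) = (sIi_f + sIi_o) / n;
      traces(irec, 7) = sb / n;
      traces(irec, 8) = astro_on ? ca_f / na_focus : 0.0;
      traces(irec, 9) = astro_on ? ca_o / na_out : 0.0;
      traces(irec, 10) = astro_on ? gl_f / na_focus : 0.0;
      traces(irec, 11) = astro_on ? gl_o / na_out : 0.0;
      traces(irec, 12) = active ? 1.0 : 0.0;
      ++irec;
    }
    std::swap(spiked_prev, spiked_now);
    std::fill(spiked_now.begin(), spiked_now.end(), 0);
  }

  List out = List::create(
      _["counts"] = counts,
      _["traces"] = traces,
      _["final_b"] = NumericVector(b_dyn.begin(), b_dyn.end()),
      _["final_v"] = v,
      _["final_u"] = u,
      _["final_R"] = NumericVector(Rf.begin(), Rf.end()),
      _["final_g"] = List::create(
          _["g_ampa"] = NumericVector(g_ampa.begin(), g_ampa.end()),
          _["g_nmda"] = NumericVector(g_nmda.begin(), g_nmda.end()),
          _["g_gabaa"] = NumericVector(g_gabaa.begin(), g_gabaa.end()),
          _["g_gabab"] = NumericVector(g_gabab.begin(), g_gabab.end())));
  if (rec_raster) {
    out["raster_neuron"] = IntegerVector(ras_n.begin(), ras_n.end());
    out["raster_time"] = IntegerVector(ras_t.begin(), ras_t.end());
  }
  return out;
}

// Single-astrocyte harness integration (Ca2+ / release dynamics only),
// used by the unit-model sweeps where an R-level loop would be slow.
// [[Rcpp::export]]
List astro_unit_run(NumericVector input, double alpha, double beta,
                    double ca_th, double kappa, double mu_s, double eta_s) {
  const int T = input.size();
  NumericVector ca_tr(T), glu_tr(T);
  double ca = 0, phi = 0, glu = 0, lam = 0;
  for (int t = 0; t < T; ++t) {
    double ca_new = ca - phi + input[t];
    phi += alpha * (beta * ca - phi);
    ca = (ca_new < 0) ? 0.0 : ca_new;
    double drive = (ca > ca_th) ? (ca - ca_th) : 0.0;
    double glu_new = glu + (0.001 / mu_s) * (-glu + drive - kappa * lam);
    lam += (0.001 / eta_s) * (-lam + glu);
    glu = (glu_new < 0) ? 0.0 : glu_new;
    ca_tr[t] = ca;
    glu_tr[t] = glu;
  }
  return List::create(_["ca"] = ca_tr, _["glu"] = glu_tr);
}
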