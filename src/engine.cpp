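// Fixed-step integrator for the multicompartment STN-GPe network.
//
// Voltage: backward Euler on the branched cable equation per cell (Hines
// elimination, compartments ordered parent-before-child), with ionic and
// synaptic conductances frozen at their start-of-step values so they enter
// the implicit solve linearly. Gates: staggered exponential-Euler updates
// from voltage-grid lookup tables built by the R reference implementations.
// Synapses: event-driven Tsodyks-Markram updates on spike arrival plus
// per-step exponential decays; the GABA-B G-protein cascade integrates with
// B-A held constant over the step. All randomness (initial voltages are
// drawn in R; here only the somatic noise current) comes from a
// Mersenne-Twister stream seeded from R, with Box-Muller normals for
// platform-independent reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

struct GateTable {
  int type;                 // 0 table, 1 instantaneous, 2 ca sKCa, 3 ca CaL, 4 wang_sd
  std::vector<double> xinf, taufac;           // type 0/1
  std::vector<double> xt;                     // interleaved [xinf, taufac]
  std::vector<double> as, bs, ad, bd;         // type 4 rate tables
  double p1 = 0, p2 = 0, p3 = 0, p4 = 0;      // type 2/3 params
  double cafac = 0;                           // 1 - exp(-dt/tau) for ca gates
};

struct VGrid {
  double v0, dv;
  int n;
  inline double look(const std::vector<double>& tab, double v) const {
    double u = (v - v0) / dv;
    if (u <= 0) return tab[0];
    if (u >= n - 1) return tab[n - 1];
    int i = (int)u;
    double f = u - i;
    return tab[i] * (1 - f) + tab[i + 1] * f;
  }
};

inline double skca_inf(double ca, double xmax, double th, double k) {
  double l = std::log10(ca * 1e3);
  return xmax / (1.0 + std::exp(-(l - th) / k));
}
inline double cal_inact_inf(double ca, double x0, double amp, double th,
                            double k) {
  return x0 + amp / (1.0 + std::exp((ca * 1e3 - th) / k));
}

struct RNG {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0;
  explicit RNG(uint64_t seed) : eng(seed) {}
  double unif() {  // in (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, List cfg) {
  // --- unpack configuration -------------------------------------------------
  const double dt = as<double>(cfg["dt"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const int rec_start = as<int>(cfg["record_start"]);
  const int rec_every = as<int>(cfg["record_every"]);
  const double spike_thresh = as<double>(cfg["spike_threshold"]);
  const int refrac_steps = as<int>(cfg["refrac_steps"]);
  const uint64_t seed = (uint64_t)as<double>(cfg["seed"]);

  // --- compartments ---------------------------------------------------------
  IntegerVector parent = net["parent"];        // 0-based, -1 root
  NumericVector cap = net["cap_nF"];
  NumericVector g_ax = net["g_ax_uS"];
  NumericVector g_leak = net["g_leak_uS"];
  NumericVector e_leak = net["e_leak"];
  IntegerVector comp_cell = net["comp_cell"];  // 0-based
  NumericVector ca_rest = net["ca_rest"];
  NumericVector ca_taufac = net["ca_taufac"];  // 1 - exp(-dt/tau_ca)
  NumericVector ca_tau = net["ca_tau"];
  NumericVector ca_flux = net["ca_flux"];      // mM/ms per nA
  NumericVector nernst_fac = net["nernst_fac"];  // mV; E = fac*log(ca_out/ca)
  NumericVector ca_out = net["ca_out"];
  NumericVector iclamp = net["iclamp"];
  const int ncomp = parent.size();

  // --- cells ----------------------------------------------------------------
  IntegerVector soma_comp = net["soma_comp"];  // 0-based
  NumericVector noise_sd = net["noise_sd"];
  NumericVector v_init = net["v_init"];
  const int ncell = soma_comp.size();

  // --- gate tables ----------------------------------------------------------
  List gspecs = net["gate_specs"];
  VGrid grid{as<double>(net["grid_v0"]), as<double>(net["grid_dv"]),
             as<int>(net["grid_n"])};
  const int nspec = gspecs.size();
  std::vector<GateTable> specs(nspec);
  for (int s = 0; s < nspec; ++s) {
    List g = gspecs[s];
    GateTable& G = specs[s];
    G.type = as<int>(g["type"]);
    if (G.type == 0 || G.type == 1) {
      G.xinf = as<std::vector<double>>(g["xinf"]);
      if (G.type == 0) {
        G.taufac = as<std::vector<double>>(g["taufac"]);
        G.xt.resize(2 * G.xinf.size());
        for (size_t j = 0; j < G.xinf.size(); ++j) {
          G.xt[2 * j] = G.xinf[j];
          G.xt[2 * j + 1] = G.taufac[j];
        }
      }
    } else if (G.type == 2 || G.type == 3) {
      NumericVector p = g["params"];
      G.p1 = p[0]; G.p2 = p[1]; G.p3 = p[2]; G.p4 = p[3];
      G.cafac = as<double>(g["cafac"]);
    } else if (G.type == 4) {
      G.as = as<std::vector<double>>(g["as"]);
      G.bs = as<std::vector<double>>(g["bs"]);
      G.ad = as<std::vector<double>>(g["ad"]);
      G.bd = as<std::vector<double>>(g["bd"]);
    }
  }

  // --- channel instances ----------------------------------------------------
  IntegerVector ch_comp = net["ch_comp"];
  NumericVector ch_g = net["ch_g_uS"];
  NumericVector ch_erev = net["ch_erev"];
  IntegerVector ch_use_ca_erev = net["ch_use_ca_erev"];
  IntegerVector ch_is_ca = net["ch_is_ca"];
  IntegerVector ch_ngates = net["ch_ngates"];
  IntegerMatrix ch_gspec = net["ch_gspec"];    // nchan x 3, -1 pad
  IntegerMatrix ch_gexp = net["ch_gexp"];
  const int nchan = ch_comp.size();

  // flat gate-state storage
  std::vector<int> g_off(nchan + 1, 0);
  for (int c = 0; c < nchan; ++c) g_off[c + 1] = g_off[c] + ch_ngates[c];
  const int ngate = g_off[nchan];
  std::vector<double> gx(ngate, 0.0), gd(ngate, 0.0);  // gd: companion d state
  // per-type gate instance lists for branch-free update loops
  std::vector<int> t0_gi, t0_comp, t0_spec;
  std::vector<int> t1_gi, t1_comp, t1_spec;
  std::vector<int> tc_gi, tc_comp, tc_spec;   // calcium-dependent (types 2/3)
  std::vector<int> t4_gi, t4_comp, t4_spec;
  for (int c = 0; c < nchan; ++c) {
    for (int k = 0; k < ch_ngates[c]; ++k) {
      int sid = ch_gspec(c, k), gi = g_off[c] + k, ic = ch_comp[c];
      switch (specs[sid].type) {
        case 0: t0_gi.push_back(gi); t0_comp.push_back(ic);
                t0_spec.push_back(sid); break;
        case 1: t1_gi.push_back(gi); t1_comp.push_back(ic);
                t1_spec.push_back(sid); break;
        case 2: case 3: tc_gi.push_back(gi); tc_comp.push_back(ic);
                tc_spec.push_back(sid); break;
        case 4: t4_gi.push_back(gi); t4_comp.push_back(ic);
                t4_spec.push_back(sid); break;
      }
    }
  }

  // --- synapses ---------------------------------------------------------------
  IntegerVector sy_comp = net["sy_comp"];
  IntegerVector sy_type = net["sy_type"];      // 0 AMPA 1 NMDA 2 GABAA 3 GABAB
  NumericVector sy_g = net["sy_g_uS"];
  NumericVector sy_erev = net["sy_erev"];
  NumericVector sy_afac = net["sy_afac"];
  NumericVector sy_bfac = net["sy_bfac"];
  NumericVector sy_rfac = net["sy_rfac"];
  NumericVector sy_ufac = net["sy_ufac"];
  NumericVector sy_U1 = net["sy_U1"];
  NumericVector sy_fpeak = net["sy_fpeak"];
  NumericVector sy_k4fac = net["sy_k4fac"];
  NumericVector sy_k3term = net["sy_k3term"];
  NumericVector sy_kd = net["sy_kd"];
  NumericVector sy_nhill = net["sy_nhill"];
  IntegerVector sy_delay = net["sy_delay_steps"];
  IntegerVector sy_source = net["sy_source"];  // 0-based global source
  IntegerVector sy_rec_slot = net["sy_rec_slot"];  // -1 none
  IntegerVector sy_rec_sign = net["sy_rec_sign"];  // +1 exc / -1 inh
  const int nsyn = sy_comp.size();

  std::vector<double> A(nsyn, 0), B(nsyn, 0), Rres(nsyn, 1), U(nsyn, 0),
      Gp(nsyn, 0);

  // source -> synapse CSR
  const int nsrc = as<int>(net["n_sources"]);
  std::vector<int> src_cnt(nsrc + 1, 0);
  for (int s = 0; s < nsyn; ++s) src_cnt[sy_source[s] + 1]++;
  for (int s = 0; s < nsrc; ++s) src_cnt[s + 1] += src_cnt[s];
  std::vector<int> src_syn(nsyn);
  {
    std::vector<int> fill(src_cnt.begin(), src_cnt.end() - 1);
    for (int s = 0; s < nsyn; ++s) src_syn[fill[sy_source[s]]++] = s;
  }

  // generator events (sorted by step)
  IntegerVector gev_step = net["gen_event_step"];
  IntegerVector gev_src = net["gen_event_source"];
  const int ngev = gev_step.size();

  // delay ring buffer
  int max_delay = 1;
  for (int s = 0; s < nsyn; ++s) max_delay = std::max(max_delay, (int)sy_delay[s]);
  const int ring = max_delay + 2;
  std::vector<std::vector<int>> bucket(ring);

  const int n_rec_slots = as<int>(net["n_rec_slots"]);

  // --- state ------------------------------------------------------------------
  std::vector<double> v(ncomp), ca(ncomp), eca(ncomp);
  for (int i = 0; i < ncomp; ++i) {
    v[i] = v_init[comp_cell[i]];
    ca[i] = ca_rest[i];
    eca[i] = nernst_fac[i] * std::log(ca_out[i] / ca[i]);
  }
  // initialize gates at steady state for v_init / resting calcium
  for (int c = 0; c < nchan; ++c) {
    double vc = v[ch_comp[c]];
    for (int k = 0; k < ch_ngates[c]; ++k) {
      const GateTable& G = specs[ch_gspec(c, k)];
      int gi = g_off[c] + k;
      switch (G.type) {
        case 0: case 1: gx[gi] = grid.look(G.xinf, vc); break;
        case 2: gx[gi] = skca_inf(ca[ch_comp[c]], G.p1, G.p2, G.p3); break;
        case 3: gx[gi] = cal_inact_inf(ca[ch_comp[c]], G.p1, G.p2, G.p3, G.p4);
                break;
        case 4: {
          double as_ = grid.look(G.as, vc), bs_ = grid.look(G.bs, vc);
          double ad_ = grid.look(G.ad, vc), bd_ = grid.look(G.bd, vc);
          double w = 1.0 / (1.0 + as_ / bs_ + bd_ / ad_);
          gx[gi] = (as_ / bs_) * w;
          gd[gi] = (bd_ / ad_) * w;
        } break;
      }
    }
  }

  // children-count for diagonal assembly handled implicitly by elimination.
  std::vector<double> diag(ncomp), rhs(ncomp);
  std::vector<int> vg_i(ncomp);
  std::vector<double> vg_f(ncomp);
  std::vector<int> last_spike(ncell, -1000000);
  std::vector<double> v_soma_prev(ncell);
  for (int c = 0; c < ncell; ++c) v_soma_prev[c] = v[soma_comp[c]];

  const int n_rec = (n_steps > rec_start)
      ? (n_steps - rec_start + rec_every - 1) / rec_every : 0;
  NumericMatrix v_rec(n_rec, ncell);
  NumericMatrix exc_rec(n_rec_slots > 0 ? n_rec : 0, n_rec_slots);
  NumericMatrix inh_rec(n_rec_slots > 0 ? n_rec : 0, n_rec_slots);
  NumericVector t_rec(n_rec);
  std::vector<std::vector<double>> spikes(ncell);
  std::vector<double> exc_now(n_rec_slots, 0), inh_now(n_rec_slots, 0);

  RNG rng(seed);
  int gev_ptr = 0;
  bool diverged = false;
  int div_comp = -1;
  int step_done = 0;

  for (int step = 0; step < n_steps; ++step) {
    // 1. deliver synaptic events due now
    std::vector<int>& due = bucket[step % ring];
    for (int idx : due) {
      U[idx] += sy_U1[idx] * (1.0 - U[idx]);
      double r = U[idx] * Rres[idx];
      Rres[idx] -= r;
      A[idx] += sy_fpeak[idx] * r;
      B[idx] += sy_fpeak[idx] * r;
    }
    due.clear();

    // 2. advance gates at the pre-solve voltage (staggered update),
    // one branch-homogeneous loop per kinetics type
    for (int i = 0; i < ncomp; ++i) {
      diag[i] = cap[i] / dt + g_leak[i];
      rhs[i] = cap[i] / dt * v[i] + g_leak[i] * e_leak[i] + iclamp[i];
      double u = (v[i] - grid.v0) / grid.dv;
      if (u < 0) u = 0;
      if (u > grid.n - 1.000001) u = grid.n - 1.000001;
      vg_i[i] = (int)u;
      vg_f[i] = u - vg_i[i];
    }
    for (size_t q = 0; q < t0_gi.size(); ++q) {
      const int ic = t0_comp[q];
      const double f = vg_f[ic];
      const double* t = &specs[t0_spec[q]].xt[2 * vg_i[ic]];
      double xinf = t[0] + (t[2] - t[0]) * f;
      double fac = t[1] + (t[3] - t[1]) * f;
      double& x = gx[t0_gi[q]];
      x = xinf + (x - xinf) * fac;
    }
    for (size_t q = 0; q < t1_gi.size(); ++q) {
      const int ic = t1_comp[q];
      const double* t = &specs[t1_spec[q]].xinf[vg_i[ic]];
      gx[t1_gi[q]] = t[0] + (t[1] - t[0]) * vg_f[ic];
    }
    for (size_t q = 0; q < tc_gi.size(); ++q) {
      const GateTable& G = specs[tc_spec[q]];
      double cc = ca[tc_comp[q]];
      double xinf = (G.type == 2) ? skca_inf(cc, G.p1, G.p2, G.p3)
                                  : cal_inact_inf(cc, G.p1, G.p2, G.p3, G.p4);
      double& x = gx[tc_gi[q]];
      x += (xinf - x) * G.cafac;
    }
    for (size_t q = 0; q < t4_gi.size(); ++q) {
      const GateTable& G = specs[t4_spec[q]];
      const int ic = t4_comp[q], i0 = vg_i[ic], gi = t4_gi[q];
      const double f = vg_f[ic];
      double as_ = G.as[i0] + (G.as[i0 + 1] - G.as[i0]) * f;
      double bs_ = G.bs[i0] + (G.bs[i0 + 1] - G.bs[i0]) * f;
      double ad_ = G.ad[i0] + (G.ad[i0 + 1] - G.ad[i0]) * f;
      double bd_ = G.bd[i0] + (G.bd[i0 + 1] - G.bd[i0]) * f;
      double x = gx[gi], d0 = gd[gi];
      double w = 1.0 - x - d0;
      x += dt * (as_ * w - bs_ * x);
      d0 += dt * (bd_ * w - ad_ * d0);
      if (x < 0) x = 0; else if (x > 1) x = 1;
      if (d0 < 0) d0 = 0; else if (d0 > 1) d0 = 1;
      gx[gi] = x; gd[gi] = d0;
    }
    // channel currents with the fresh gate values
    for (int c = 0; c < nchan; ++c) {
      const int ic = ch_comp[c];
      double open = 1.0;
      const int ng = ch_ngates[c];
      const double* xs = &gx[g_off[c]];
      for (int k = 0; k < ng; ++k) {
        double x = xs[k];
        int e = ch_gexp(c, k);
        if (e == 1) open *= x;
        else if (e == 2) open *= x * x;
        else if (e == 3) open *= x * x * x;
        else if (e == 4) { double x2 = x * x; open *= x2 * x2; }
      }
      double g = ch_g[c] * open;
      double e_rev = ch_use_ca_erev[c] ? eca[ic] : ch_erev[c];
      diag[ic] += g;
      rhs[ic] += g * e_rev;
      if (ch_is_ca[c]) {
        double i_nA = g * (v[ic] - e_rev);
        ca[ic] += (-i_nA * ca_flux[ic]) * ca_tau[ic] * ca_taufac[ic];
      }
    }
    // synapses (conductance frozen over the step)
    if (n_rec_slots > 0) {
      std::fill(exc_now.begin(), exc_now.end(), 0.0);
      std::fill(inh_now.begin(), inh_now.end(), 0.0);
    }
    for (int s = 0; s < nsyn; ++s) {
      double ba = B[s] - A[s];
      bool active = ba > 1e-12 || Gp[s] > 1e-9;
      if (active) {
        int ic = sy_comp[s];
        double g;
        if (sy_type[s] == 3) {           // GABA-B Hill gating
          double g2 = Gp[s] * Gp[s], gn = g2 * g2;
          double k2 = sy_kd[s] * sy_kd[s], kn = k2 * k2;
          if (sy_nhill[s] != 4.0) {
            gn = std::pow(Gp[s], sy_nhill[s]);
            kn = std::pow(sy_kd[s], sy_nhill[s]);
          }
          g = sy_g[s] * gn / (gn + kn);
        } else {
          g = sy_g[s] * ba;
          if (sy_type[s] == 1)           // NMDA magnesium block at current v
            g *= 1.0 / (1.0 + std::exp(-0.062 * v[ic]) / 3.57);
        }
        diag[ic] += g;
        rhs[ic] += g * sy_erev[s];
        if (sy_rec_slot[s] >= 0) {
          double cur = g * (v[ic] - sy_erev[s]);
          if (sy_rec_sign[s] > 0) exc_now[sy_rec_slot[s]] += cur;
          else inh_now[sy_rec_slot[s]] += cur;
        }
      }
      // state decay for the step (conductance above used pre-decay state)
      A[s] *= sy_afac[s];
      B[s] *= sy_bfac[s];
      Rres[s] = 1.0 + (Rres[s] - 1.0) * sy_rfac[s];
      U[s] *= sy_ufac[s];
      if (sy_type[s] == 3)
        Gp[s] = Gp[s] * sy_k4fac[s] + sy_k3term[s] * ba;
    }
    // somatic noise
    for (int c = 0; c < ncell; ++c)
      if (noise_sd[c] > 0) rhs[soma_comp[c]] += noise_sd[c] * rng.norm();

    // 3. Hines solve (parents precede children)
    for (int i = ncomp - 1; i > 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double gij = g_ax[i];
      diag[i] += gij;
      double f = gij / diag[i];
      diag[p] += gij - gij * f;
      rhs[p] += f * rhs[i];
    }
    if (parent[0] >= 0) stop("compartment ordering invalid");
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < ncomp; ++i) {
      int p = parent[i];
      v[i] = (p < 0) ? rhs[i] / diag[i]
                     : (rhs[i] + g_ax[i] * v[p]) / diag[i];
    }

    // divergence guard
    for (int i = 0; i < ncomp; ++i) {
      if (!(v[i] > -200.0 && v[i] < 200.0)) {
        diverged = true; div_comp = i;
        break;
      }
    }
    if (diverged) { step_done = step; break; }

    // 4. calcium relaxation toward rest (influx added in assembly above)
    for (int i = 0; i < ncomp; ++i) {
      if (ca_taufac[i] > 0) {
        ca[i] += (ca_rest[i] - ca[i]) * ca_taufac[i];
        if (ca[i] < 1e-9) ca[i] = 1e-9;
        eca[i] = nernst_fac[i] * std::log(ca_out[i] / ca[i]);
      }
    }

    // 7. spike detection at the soma, event scheduling
    for (int c = 0; c < ncell; ++c) {
      double vs = v[soma_comp[c]];
      bool crossing = vs >= spike_thresh && v_soma_prev[c] < spike_thresh;
      v_soma_prev[c] = vs;
      if (crossing && step - last_spike[c] > refrac_steps) {
        spikes[c].push_back(step * dt);
        last_spike[c] = step;
        for (int q = src_cnt[c]; q < src_cnt[c + 1]; ++q) {
          int sid = src_syn[q];
          bucket[(step + sy_delay[sid]) % ring].push_back(sid);
        }
      }
    }

    // generator events arriving at this step (presynaptic spike time = step)
    while (gev_ptr < ngev && gev_step[gev_ptr] == step) {
      int src = gev_src[gev_ptr];
      for (int q = src_cnt[src]; q < src_cnt[src + 1]; ++q) {
        int sid = src_syn[q];
        bucket[(step + sy_delay[sid]) % ring].push_back(sid);
      }
      ++gev_ptr;
    }
    while (gev_ptr < ngev && gev_step[gev_ptr] < step) ++gev_ptr;

    // 8. recording
    if (step >= rec_start && (step - rec_start) % rec_every == 0) {
      int row = (step - rec_start) / rec_every;
      t_rec[row] = step * dt;
      for (int c = 0; c < ncell; ++c) v_rec(row, c) = v[soma_comp[c]];
      for (int sl = 0; sl < n_rec_slots; ++sl) {
        exc_rec(row, sl) = exc_now[sl];
        inh_rec(row, sl) = inh_now[sl];
      }
    }
    step_done = step + 1;
  }

  List spk(ncell);
  for (int c = 0; c < ncell; ++c) spk[c] = wrap(spikes[c]);

  return List::create(
      _["spikes"] = spk, _["v_soma"] = v_rec, _["t_rec"] = t_rec,
      _["exc"] = exc_rec, _["inh"] = inh_rec,
      _["diverged"] = diverged, _["div_comp"] = div_comp + 1,
      _["div_cell"] = diverged ? comp_cell[div_comp] + 1 : NA_INTEGER,
      _["steps_done"] = step_done,
      _["v_final"] = NumericVector(v.begin(), v.end()),
      _["ca_final"] = NumericVector(ca.begin(), ca.end()));
}
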