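// Simplified conductance-based spiking layer.
//
// Single-compartment neurons with Na/K/leak currents (plus a slow K
// adaptation current and an NMDA-like conductance where enabled), dual
// exponential synapses with per-contact conduction + synaptic delays served
// from a time-bucket event queue, and ohmic gap junctions.  Fixed-step
// exponential-Euler integration.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

// cellpar rows = types, columns C, gNa, gK, gL, gKs, ENa, EK, EL;
// recpar rows = receptors (exc, inh, nmda), columns tau_rise, tau_decay, E_rev
// [[Rcpp::export]]
List simulate_network_cpp(IntegerVector type_id,
                          NumericMatrix cellpar,
                          IntegerVector pre, IntegerVector post,
                          NumericVector weight, IntegerVector receptor,
                          NumericVector delay,
                          NumericMatrix recpar,
                          IntegerVector gap_i, IntegerVector gap_j,
                          NumericVector gap_g,
                          IntegerVector stim_idx, NumericVector stim_on,
                          NumericVector stim_off, NumericVector stim_amp,
                          NumericVector nmda_tonic,
                          NumericVector v0, double dt, double duration) {
  int n = type_id.size();
  int nsyn = pre.size();
  int nrec = recpar.nrow();
  int nsteps = (int)std::ceil(duration / dt);

  // per-receptor kinetics and peak normalisation
  std::vector<double> ktr(nrec), ktd(nrec), Erev(nrec), norm(nrec);
  for (int r = 0; r < nrec; ++r) {
    double tr = recpar(r, 0), td = recpar(r, 1);
    ktr[r] = std::exp(-dt / tr);
    ktd[r] = std::exp(-dt / td);
    Erev[r] = recpar(r, 2);
    double tp = (td * tr / (td - tr)) * std::log(td / tr);
    norm[r] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  }

  // outgoing contacts in CSR form, ordered by presynaptic neuron
  std::vector<int> out_ptr(n + 1, 0);
  for (int k = 0; k < nsyn; ++k) out_ptr[pre[k]]++;
  for (int i = 0; i < n; ++i) out_ptr[i + 1] += out_ptr[i];
  std::vector<int> out_post(nsyn), out_rec(nsyn), out_dstep(nsyn);
  std::vector<double> out_w(nsyn);
  {
    std::vector<int> cur(n, 0);
    int max_d = 0;
    for (int k = 0; k < nsyn; ++k) {
      int p = pre[k] - 1;
      int slot = out_ptr[p] + cur[p]++;
      out_post[slot] = post[k] - 1;
      out_rec[slot] = receptor[k] - 1;
      out_w[slot] = weight[k];
      int ds = (int)std::ceil(delay[k] / dt);
      if (ds < 1) ds = 1;
      out_dstep[slot] = ds;
      if (ds > max_d) max_d = ds;
    }
    (void)max_d;
  }

  // event buckets: bucket[t] -> list of (post, receptor, weight)
  int max_delay_steps = 1;
  for (int k = 0; k < nsyn; ++k)
    if (out_dstep[k] > max_delay_steps) max_delay_steps = out_dstep[k];
  std::vector< std::vector<int> > ev_post(nsteps + max_delay_steps + 2);
  std::vector< std::vector<int> > ev_rec(nsteps + max_delay_steps + 2);
  std::vector< std::vector<double> > ev_w(nsteps + max_delay_steps + 2);

  // gap junction adjacency (symmetric; both directions supplied or expanded here)
  std::vector< std::vector< std::pair<int, double> > > gap(n);
  for (int k = 0; k < gap_i.size(); ++k) {
    gap[gap_i[k] - 1].push_back(std::make_pair(gap_j[k] - 1, gap_g[k]));
    gap[gap_j[k] - 1].push_back(std::make_pair(gap_i[k] - 1, gap_g[k]));
  }

  // state
  std::vector<double> V(n), m(n), h(n), nn(n), q(n);
  std::vector< std::vector<double> > sr(nrec, std::vector<double>(n, 0.0));
  std::vector< std::vector<double> > sd(nrec, std::vector<double>(n, 0.0));
  std::vector<bool> in_spike(n, false);
  for (int i = 0; i < n; ++i) {
    V[i] = v0[i];
    double v = V[i];
    double am = 0.32 * vtrap(v + 54.0, 4.0), bm = 0.28 * vtrap(-(v + 27.0), 5.0);
    double ah = 0.128 * std::exp(-(v + 50.0) / 18.0),
           bh = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
    double an = 0.032 * vtrap(v + 52.0, 5.0), bn = 0.5 * std::exp(-(v + 57.0) / 40.0);
    m[i] = am / (am + bm); h[i] = ah / (ah + bh); nn[i] = an / (an + bn);
    q[i] = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  }

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<double> Vprev(n);
  std::vector< std::vector<int> > stim_of(n);
  for (int k = 0; k < stim_idx.size(); ++k)
    stim_of[stim_idx[k] - 1].push_back(k);

  for (int stp = 0; stp < nsteps; ++stp) {
    double t = stp * dt;
    // deliver queued synaptic events
    {
      std::vector<int> &ep = ev_post[stp];
      std::vector<int> &er = ev_rec[stp];
      std::vector<double> &ew = ev_w[stp];
      for (size_t k = 0; k < ep.size(); ++k) {
        sr[er[k]][ep[k]] += ew[k] * norm[er[k]];
        sd[er[k]][ep[k]] += ew[k] * norm[er[k]];
      }
      ep.clear(); er.clear(); ew.clear();
    }
    for (int i = 0; i < n; ++i) Vprev[i] = V[i];

    for (int i = 0; i < n; ++i) {
      int ty = type_id[i] - 1;
      double C = cellpar(ty, 0), gNa = cellpar(ty, 1), gK = cellpar(ty, 2),
             gL = cellpar(ty, 3), gKs = cellpar(ty, 4), ENa = cellpar(ty, 5),
             EK = cellpar(ty, 6), EL = cellpar(ty, 7);
      double v = Vprev[i];

      // gating (exponential Euler on the linearised kinetics)
      double am = 0.32 * vtrap(v + 54.0, 4.0), bm = 0.28 * vtrap(-(v + 27.0), 5.0);
      double ah = 0.128 * std::exp(-(v + 50.0) / 18.0),
             bh = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
      double an = 0.032 * vtrap(v + 52.0, 5.0), bn = 0.5 * std::exp(-(v + 57.0) / 40.0);
      double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh), tn = 1.0 / (an + bn);
      m[i] += (am * tm - m[i]) * (1.0 - std::exp(-dt / tm));
      h[i] += (ah * th - h[i]) * (1.0 - std::exp(-dt / th));
      nn[i] += (an * tn - nn[i]) * (1.0 - std::exp(-dt / tn));
      double qinf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
      q[i] += (qinf - q[i]) * (1.0 - std::exp(-dt / 400.0));

      double gtot = gL + gNa * m[i] * m[i] * m[i] * h[i] + gK * nn[i] * nn[i] * nn[i] * nn[i]
                    + gKs * q[i];
      double gE = gL * EL + gNa * m[i] * m[i] * m[i] * h[i] * ENa
                  + (gK * nn[i] * nn[i] * nn[i] * nn[i] + gKs * q[i]) * EK;

      // synapses
      for (int r = 0; r < nrec; ++r) {
        double g = sd[r][i] - sr[r][i];
        if (g < 0) g = 0;
        if (r == 2) { // NMDA-like: sigmoidal voltage-dependent Mg block
          g *= 1.0 / (1.0 + 0.28 * std::exp(-0.062 * v));
        }
        gtot += g; gE += g * Erev[r];
      }
      if (nmda_tonic[i] > 0) {
        double g = nmda_tonic[i] / (1.0 + 0.28 * std::exp(-0.062 * v));
        gtot += g; gE += g * 0.0;
      }
      // gap junctions (neighbour voltage from previous step)
      for (size_t k = 0; k < gap[i].size(); ++k) {
        gtot += gap[i][k].second;
        gE += gap[i][k].second * Vprev[gap[i][k].first];
      }
      // stimulus current
      double I = 0.0;
      for (size_t kk = 0; kk < stim_of[i].size(); ++kk) {
        int k = stim_of[i][kk];
        if (t >= stim_on[k] && t < stim_off[k]) I += stim_amp[k];
      }

      double Vinf = (gE + I) / gtot;
      V[i] = Vinf + (v - Vinf) * std::exp(-dt * gtot / C);

      // synaptic state decay
      for (int r = 0; r < nrec; ++r) {
        sr[r][i] *= ktr[r];
        sd[r][i] *= ktd[r];
      }

      // threshold crossing
      if (!in_spike[i] && V[i] >= 0.0 && Vprev[i] < 0.0) {
        in_spike[i] = true;
        spike_id.push_back(i + 1);
        spike_t.push_back(t + dt);
        // queue outgoing events
        for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
          int slot = stp + out_dstep[k];
          ev_post[slot].push_back(out_post[k]);
          ev_rec[slot].push_back(out_rec[k]);
          ev_w[slot].push_back(out_w[k]);
        }
      } else if (in_spike[i] && V[i] < -10.0) {
        in_spike[i] = false;
      }
    }
  }
  return List::create(_["neuron"] = spike_id, _["t"] = spike_t);
}
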