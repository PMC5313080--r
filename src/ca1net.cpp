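#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Distance-binned connection sampling.
//
// Three steps, per presynaptic/postsynaptic type pair:
//   1. all pre-post distances in the XY plane;
//   2. the requested number of connections is split into radial distance
//      bins according to the Gaussian axonal bouton distribution (the quota
//      vector is computed in R and passed in);
//   3. candidate pairs are assigned to their bins and each bin's quota is
//      drawn uniformly without replacement.
// Bins whose quota exceeds their candidate count are exhausted and the
// deficit is reassigned to the nearest bins with spare candidates,
// alternating inward/outward. Selection uses a sequential scan with
// probability quota_remaining / candidates_remaining per candidate, which is
// exact uniform sampling without replacement in a single pass.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sample_connections(NumericVector pre_x, NumericVector pre_y,
                            NumericVector post_x, NumericVector post_y,
                            bool same_pop, double extent, double binw,
                            IntegerVector quota_in, int seed) {
  const int npre = pre_x.size(), npost = post_x.size();
  const int nbins = quota_in.size();
  const double ext2 = extent * extent;
  std::vector<long long> cand(nbins, 0);

  for (int i = 0; i < npre; ++i) {
    const double xi = pre_x[i], yi = pre_y[i];
    for (int j = 0; j < npost; ++j) {
      if (same_pop && i == j) continue;
      const double dx = xi - post_x[j], dy = yi - post_y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > ext2) continue;
      int b = (int)(std::sqrt(d2) / binw);
      if (b >= nbins) b = nbins - 1;
      cand[b]++;
    }
  }

  // shortfall reassignment: exhaust the bin, push the deficit to the
  // nearest non-exhausted bins (alternating inward/outward)
  std::vector<long long> quota(nbins);
  for (int b = 0; b < nbins; ++b) quota[b] = quota_in[b];
  for (int b = 0; b < nbins; ++b) {
    if (quota[b] <= cand[b]) continue;
    long long deficit = quota[b] - cand[b];
    quota[b] = cand[b];
    for (int off = 1; off < nbins && deficit > 0; ++off) {
      for (int s = -1; s <= 1 && deficit > 0; s += 2) {
        int nb = b + s * off;
        if (nb < 0 || nb >= nbins) continue;
        long long spare = cand[nb] - quota[nb];
        if (spare <= 0) continue;
        long long take = std::min(spare, deficit);
        quota[nb] += take;
        deficit -= take;
      }
    }
  }

  long long total = 0;
  for (int b = 0; b < nbins; ++b) total += quota[b];

  std::vector<int> out_pre, out_post;
  std::vector<double> out_d;
  out_pre.reserve(total); out_post.reserve(total); out_d.reserve(total);

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<long long> left(cand), need(quota);

  for (int i = 0; i < npre; ++i) {
    const double xi = pre_x[i], yi = pre_y[i];
    for (int j = 0; j < npost; ++j) {
      if (same_pop && i == j) continue;
      const double dx = xi - post_x[j], dy = yi - post_y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > ext2) continue;
      const double d = std::sqrt(d2);
      int b = (int)(d / binw);
      if (b >= nbins) b = nbins - 1;
      if (need[b] > 0 && unif(rng) * (double)left[b] < (double)need[b]) {
        out_pre.push_back(i + 1);
        out_post.push_back(j + 1);
        out_d.push_back(d);
        need[b]--;
      }
      left[b]--;
    }
  }

  return List::create(_["pre"] = wrap(out_pre), _["post"] = wrap(out_post),
                      _["dist"] = wrap(out_d),
                      _["quota"] = wrap(std::vector<double>(quota.begin(), quota.end())),
                      _["candidates"] = wrap(std::vector<double>(cand.begin(), cand.end())));
}

// ---------------------------------------------------------------------------
// Adaptive exponential integrate-and-fire, single neuron, arbitrary
// injected-current vector. Forward Euler with a clamped exponential term;
// spike cut at Vpeak, reset to Vreset, spike-triggered adaptation b with
// time constant tauw, absolute refractory period.
// params: EL, gL (nS), C (pF), VT, DeltaT, Vreset, Vpeak, tref (ms),
//         b (pA), tauw (ms)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_neuron(NumericVector params, NumericVector I, double dt,
                    double V0) {
  const double EL = params[0], gL = params[1], C = params[2], VT = params[3],
               DT = params[4], Vreset = params[5], Vpeak = params[6],
               tref = params[7], badapt = params[8], tauw = params[9];
  const int n = I.size();
  const int refsteps = (int)std::round(tref / dt);
  NumericVector V(n + 1);
  std::vector<double> spikes;
  V[0] = V0;
  double v = V0, w = 0.0;
  int ref = 0;
  for (int t = 0; t < n; ++t) {
    if (ref > 0) {
      ref--;
      v = Vreset;
    } else {
      double ex = (v - VT) / DT;
      if (ex > 16.0) ex = 16.0;
      double dv = (-gL * (v - EL) + gL * DT * std::exp(ex) - w + I[t]) / C;
      v += dt * dv;
      if (v >= Vpeak) {
        spikes.push_back((t + 1) * dt);
        v = Vreset;
        w += badapt;
        ref = refsteps;
      }
    }
    w += dt * (-w / tauw);
    V[t + 1] = v;
  }
  return List::create(_["V"] = V, _["spikes"] = wrap(spikes));
}

// ---------------------------------------------------------------------------
// Clock-driven network engine.
//
// Neurons: adaptive exponential integrate-and-fire (arrays per neuron).
// Synapses: conductance-based double exponentials, grouped into channels
// (tau_rise, tau_decay, E_rev). Per neuron and channel two state variables
// S1 (rise) and S2 (decay) decay exponentially (exact per step); an incoming
// event increments both by w * N where N normalizes the peak of
// (S2 - S1) to w. g = S2 - S1; I_syn = sum_c g_c (E_c - V).
// Events travel with per-edge integer-step delays through a ring buffer.
// ---------------------------------------------------------------------------

struct Delivery { int idx; double w; };

// [[Rcpp::export]]
List cpp_simulate(List neurons, List channels, List edges, List aff_edges,
                  IntegerVector aff_step, IntegerVector aff_unit,
                  NumericVector Iext, int nsteps, double dt,
                  IntegerVector vm_ids, int vm_every,
                  NumericVector lfp_w, int lfp_every) {
  NumericVector EL = neurons["EL"], gL = neurons["gL"], Cm = neurons["C"],
                VT = neurons["VT"], DT = neurons["DeltaT"],
                Vreset = neurons["Vreset"], Vpeak = neurons["Vpeak"],
                badapt = neurons["b"], tauw = neurons["tauw"];
  IntegerVector refsteps = neurons["refsteps"];
  const int n = EL.size();

  NumericVector tau1 = channels["tau1"], tau2 = channels["tau2"],
                erev = channels["erev"];
  const int nchan = tau1.size();
  std::vector<double> d1(nchan), d2(nchan), nrm(nchan);
  for (int c = 0; c < nchan; ++c) {
    d1[c] = std::exp(-dt / tau1[c]);
    d2[c] = std::exp(-dt / tau2[c]);
    double tp = tau1[c] * tau2[c] / (tau2[c] - tau1[c]) *
                std::log(tau2[c] / tau1[c]);
    nrm[c] = 1.0 / (std::exp(-tp / tau2[c]) - std::exp(-tp / tau1[c]));
  }

  IntegerVector e_ptr = edges["ptr"];   // length n+1, CSR over presynaptic id
  IntegerVector e_dst = edges["dst"], e_chan = edges["chan"],
                e_del = edges["delay"];
  NumericVector e_w = edges["w"];
  IntegerVector a_ptr = aff_edges["ptr"];
  IntegerVector a_dst = aff_edges["dst"], a_chan = aff_edges["chan"],
                a_del = aff_edges["delay"];
  NumericVector a_w = aff_edges["w"];

  int maxdel = 1;
  for (int k = 0; k < e_del.size(); ++k) if (e_del[k] > maxdel) maxdel = e_del[k];
  for (int k = 0; k < a_del.size(); ++k) if (a_del[k] > maxdel) maxdel = a_del[k];
  const int D = maxdel + 1;
  std::vector<std::vector<Delivery>> ring(D);

  std::vector<double> S1((size_t)nchan * n, 0.0), S2((size_t)nchan * n, 0.0);
  std::vector<double> V(n), W(n, 0.0), Isyn(n, 0.0);
  std::vector<int> ref(n, 0);
  for (int i = 0; i < n; ++i) V[i] = EL[i];

  std::vector<int> sp_id; std::vector<double> sp_t;
  std::vector<double> wsum_local(nchan, 0.0), wsum_aff(nchan, 0.0);

  const int nvm = vm_ids.size();
  const int nvmsamp = nvm > 0 ? nsteps / vm_every + 1 : 0;
  NumericMatrix vm_out(nvmsamp, nvm);
  if (nvm > 0)
    for (int k = 0; k < nvm; ++k) vm_out(0, k) = V[vm_ids[k] - 1];
  const bool do_lfp = lfp_w.size() == n;
  std::vector<double> lfp;
  if (do_lfp) lfp.reserve(nsteps / lfp_every + 1);

  size_t ap = 0; // pointer into afferent spike list (sorted by step)

  for (int t = 0; t < nsteps; ++t) {
    // afferent spikes occurring at this step: schedule their deliveries
    while (ap < (size_t)aff_step.size() && aff_step[ap] == t) {
      const int u = aff_unit[ap];
      for (int k = a_ptr[u]; k < a_ptr[u + 1]; ++k) {
        const int slot = (t + a_del[k]) % D;
        ring[slot].push_back({a_chan[k] * n + a_dst[k], a_w[k] * nrm[a_chan[k]]});
        wsum_aff[a_chan[k]] += a_w[k];
      }
      ap++;
    }
    // deliver events due now
    std::vector<Delivery> &slot = ring[t % D];
    for (const Delivery &dv : slot) { S1[dv.idx] += dv.w; S2[dv.idx] += dv.w; }
    slot.clear();
    // decay synaptic states, accumulate synaptic current
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    for (int c = 0; c < nchan; ++c) {
      double *s1 = &S1[(size_t)c * n], *s2 = &S2[(size_t)c * n];
      const double dd1 = d1[c], dd2 = d2[c], ee = erev[c];
      for (int i = 0; i < n; ++i) {
        s1[i] *= dd1; s2[i] *= dd2;
        Isyn[i] += (s2[i] - s1[i]) * (ee - V[i]);
      }
    }
    // membrane update
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0) { ref[i]--; V[i] = Vreset[i]; }
      else {
        double ex = (V[i] - VT[i]) / DT[i];
        if (ex > 16.0) ex = 16.0;
        double dv = (-gL[i] * (V[i] - EL[i]) + gL[i] * DT[i] * std::exp(ex)
                     - W[i] + Isyn[i] + Iext[i]) / Cm[i];
        V[i] += dt * dv;
        if (V[i] >= Vpeak[i]) {
          sp_id.push_back(i + 1);
          sp_t.push_back((t + 1) * dt);
          V[i] = Vreset[i];
          W[i] += badapt[i];
          ref[i] = refsteps[i];
          for (int k = e_ptr[i]; k < e_ptr[i + 1]; ++k) {
            if (e_w[k] == 0.0) continue;
            const int slot2 = (t + e_del[k]) % D;
            ring[slot2].push_back({e_chan[k] * n + e_dst[k],
                                   e_w[k] * nrm[e_chan[k]]});
            wsum_local[e_chan[k]] += e_w[k];
          }
        }
      }
      W[i] += dt * (-W[i] / tauw[i]);
      if (!std::isfinite(V[i]))
        stop("membrane potential diverged (cell %d at %.3f ms)", i + 1,
             (t + 1) * dt);
    }
    // recorders
    if (nvm > 0 && (t + 1) % vm_every == 0) {
      int row = (t + 1) / vm_every;
      if (row < nvmsamp)
        for (int k = 0; k < nvm; ++k) vm_out(row, k) = V[vm_ids[k] - 1];
    }
    if (do_lfp && (t + 1) % lfp_every == 0) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += lfp_w[i] * Isyn[i];
      lfp.push_back(acc);
    }
  }

  return List::create(_["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
                      _["vm"] = vm_out, _["lfp"] = wrap(lfp),
                      _["wsum_local"] = wrap(wsum_local),
                      _["wsum_aff"] = wrap(wsum_aff));
}
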