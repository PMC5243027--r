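// Spiking network core: conductance-based exponential integrate-and-fire
// neurons, aggregated exponential/bi-exponential synapse states, Bernoulli
// wiring, forward-Euler integration with a fixed step and whole-step
// conduction delays. All voltages mV, conductances nS, currents pA,
// capacitances nF, times ms.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PCG32: fast, seedable generator so a session's stochastic inputs are
// reproducible from a single integer seed independent of R's RNG state.
// ---------------------------------------------------------------------------
struct PCG32 {
  uint64_t state, inc;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t s) {
    uint64_t sm = s;
    state = splitmix64(sm);
    inc = splitmix64(sm) | 1ULL;
  }

  inline uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((~rot + 1u) & 31u));
  }

  inline double uniform() {  // in (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
};

static NumericVector rng_pack(const PCG32 &r) {
  NumericVector out(4);
  out[0] = (double)(uint32_t)(r.state >> 32);
  out[1] = (double)(uint32_t)(r.state & 0xFFFFFFFFULL);
  out[2] = (double)(uint32_t)(r.inc >> 32);
  out[3] = (double)(uint32_t)(r.inc & 0xFFFFFFFFULL);
  return out;
}

static void rng_unpack(PCG32 &r, const NumericVector &v) {
  r.state = ((uint64_t)(uint32_t)v[0] << 32) | (uint64_t)(uint32_t)v[1];
  r.inc = ((uint64_t)(uint32_t)v[2] << 32) | (uint64_t)(uint32_t)v[3];
}

// exp(x) via argument reduction + degree-7 polynomial; relative error
// ~5e-9 for |x| < 700, far below the Euler discretization error, and much
// faster than the libm call on generic builds.
static inline double fast_exp(double x) {
  const double LOG2E = 1.4426950408889634;
  const double LN2_HI = 0.6931471805599453;
  const double LN2_LO = 2.3190468138462996e-17;
  double t = x * LOG2E + 0.5;
  int ni = (int)t;
  if (t < ni) --ni;  // fast floor; |x| stays far below INT_MAX here
  double n = (double)ni;
  double r = x - n * LN2_HI;
  r -= n * LN2_LO;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040)))))));
  union { double d; uint64_t u; } sc;
  sc.u = (uint64_t)((int64_t)ni + 1023) << 52;
  return p * sc.d;
}

// Poisson sample by inversion; lambda is small (<~1) in all uses.
static inline int rpois_small(PCG32 &rng, double lambda, double exp_neg_lambda) {
  if (lambda <= 0.0) return 0;
  double u = rng.uniform();
  double p = exp_neg_lambda, cum = p;
  int k = 0;
  while (u > cum && k < 40) {
    ++k;
    p *= lambda / k;
    cum += p;
  }
  return k;
}

// ---------------------------------------------------------------------------
// Wiring. Neuron index space: [0, n_pyr) pyramidal (pools: [0, n_sel) left,
// [n_sel, 2 n_sel) right, rest non-selective), [n_pyr, n_pyr + n_int)
// interneurons (accumulator halves: first half left).
// ---------------------------------------------------------------------------

// architecture: 0 = attractor (common interneuron pool), 1 = accumulator
// (split halves exclusively wired to the matching selective pool).
// [[Rcpp::export]]
List cpp_wire_network(int n_pyr, int n_sel, int n_int, int architecture,
                      double p_pyr_recurrent, double p_int_recurrent,
                      double p_pyr_to_int, double p_int_to_pyr,
                      int seed) {
  const int n_total = n_pyr + n_int;
  PCG32 rng;
  rng.seed((uint64_t)(uint32_t)seed * 0x100000001ULL + 0xDA3E39CB94B95BDBULL);

  std::vector<std::vector<int>> targets(n_total);
  const int half = n_int / 2;

  auto pool_of = [&](int i) -> int {
    // 0 = left selective, 1 = right selective, 2 = non-selective
    if (i < n_sel) return 0;
    if (i < 2 * n_sel) return 1;
    return 2;
  };

  for (int j = 0; j < n_pyr; ++j) {
    int pj = pool_of(j);
    // pyramidal -> pyramidal: recurrent within a selective pool; the
    // non-selective pool exchanges connections with the whole pyramidal
    // population; never directly across the two selective pools
    for (int i = 0; i < n_pyr; ++i) {
      if (i == j) continue;
      int pi = pool_of(i);
      bool allowed = (pi == pj) || pi == 2 || pj == 2;
      if (allowed && rng.uniform() < p_pyr_recurrent) targets[j].push_back(i);
    }
    // pyramidal -> interneurons
    for (int k = 0; k < n_int; ++k) {
      bool allowed = true;
      if (architecture == 1 && pj != 2) {
        int hk = (k < half) ? 0 : 1;
        allowed = (hk == pj);
      }
      if (allowed && rng.uniform() < p_pyr_to_int) targets[j].push_back(n_pyr + k);
    }
  }

  for (int j = 0; j < n_int; ++j) {
    int hj = (j < half) ? 0 : 1;
    // interneuron -> interneuron (within the same half for the accumulator)
    for (int k = 0; k < n_int; ++k) {
      if (k == j) continue;
      bool allowed = true;
      if (architecture == 1) allowed = (((k < half) ? 0 : 1) == hj);
      if (allowed && rng.uniform() < p_int_recurrent) targets[n_pyr + j].push_back(n_pyr + k);
    }
    // interneuron -> pyramidal
    for (int i = 0; i < n_pyr; ++i) {
      int pi = pool_of(i);
      bool allowed = true;
      if (architecture == 1 && pi != 2) allowed = (pi == hj);
      if (allowed && rng.uniform() < p_int_to_pyr) targets[n_pyr + j].push_back(i);
    }
  }

  // CSR layout
  std::size_t n_edges = 0;
  for (auto &t : targets) n_edges += t.size();
  IntegerVector offsets(n_total + 1), flat((R_xlen_t)n_edges);
  std::size_t pos = 0;
  offsets[0] = 0;
  for (int j = 0; j < n_total; ++j) {
    for (int t : targets[j]) flat[pos++] = t;
    offsets[j + 1] = (int)pos;
  }

  return List::create(_["offsets"] = offsets, _["targets"] = flat,
                      _["n_pyr"] = n_pyr, _["n_sel"] = n_sel,
                      _["n_int"] = n_int, _["architecture"] = architecture);
}

// ---------------------------------------------------------------------------
// Session simulation
// ---------------------------------------------------------------------------

// params list fields (all per target class where relevant, [pyr, int]):
//   C, g_L, E_L, Delta_T, V_T, V_s, V_r (length-2 numerics),
//   ref_steps (length-2 int), G_ext, G_bg, G_rec, G_nmda, G_gaba (length-2),
//   tau_ampa, tau_gaba, tau_nmda_rise, tau_nmda_decay, Mg, E_gaba, dt,
//   delay_steps, saturating (0/1)
// [[Rcpp::export]]
List cpp_simulate_session(List net, List params,
                          NumericVector background_rate,  // Hz, [pyramidal, interneuron]
                          NumericVector task_rate_left,
                          NumericVector task_rate_right,
                          double I_stim_pyr, double I_stim_int,
                          IntegerVector trial_start_steps,
                          bool reinitialize,
                          int seed,
                          Nullable<List> init_state,
                          bool return_spikes,
                          Nullable<IntegerVector> ext_event_neuron,
                          Nullable<IntegerVector> ext_event_step) {
  const IntegerVector offsets = net["offsets"];
  const IntegerVector targets = net["targets"];
  const int n_pyr = net["n_pyr"], n_sel = net["n_sel"], n_int = net["n_int"];
  const int n_total = n_pyr + n_int;
  const int n_steps = task_rate_left.size();
  if (task_rate_right.size() != n_steps)
    stop("task rate vectors must have equal length");

  const NumericVector C = params["C"], g_L = params["g_L"], E_L = params["E_L"],
                      Delta_T = params["Delta_T"], V_T = params["V_T"],
                      V_s = params["V_s"], V_r = params["V_r"],
                      G_ext = params["G_ext"], G_bg = params["G_bg"],
                      G_rec = params["G_rec"], G_nmda = params["G_nmda"],
                      G_gaba = params["G_gaba"];
  const IntegerVector ref_steps = params["ref_steps"];
  const double tau_ampa = params["tau_ampa"], tau_gaba = params["tau_gaba"];
  const double tau_nr = params["tau_nmda_rise"], tau_nd = params["tau_nmda_decay"];
  const double Mg = params["Mg"], E_gaba = params["E_gaba"], dt = params["dt"];
  const double w_plus = params["w_plus"];  // within-pool recurrent potentiation
  const int delay_steps = params["delay_steps"];
  const bool saturating = as<int>(params["saturating"]) != 0;

  // hoist per-class parameters out of Rcpp proxies for the hot loop
  double pC[2], pgL[2], pEL[2], pDT[2], pVT[2], pVs[2], pVr[2];
  double pGext[2], pGbg[2], pGrec[2], pGnmda[2], pGgaba[2];
  int pref[2];
  for (int c2 = 0; c2 < 2; ++c2) {
    pC[c2] = C[c2]; pgL[c2] = g_L[c2]; pEL[c2] = E_L[c2]; pDT[c2] = Delta_T[c2];
    pVT[c2] = V_T[c2]; pVs[c2] = V_s[c2]; pVr[c2] = V_r[c2];
    pGext[c2] = G_ext[c2]; pGbg[c2] = G_bg[c2]; pGrec[c2] = G_rec[c2];
    pGnmda[c2] = G_nmda[c2]; pGgaba[c2] = G_gaba[c2]; pref[c2] = ref_steps[c2];
  }
  const int *off_p = offsets.begin();
  const int *tgt_p = targets.begin();
  int *cnt_p = nullptr;  // set after counts allocation

  const double d_ampa = std::exp(-dt / tau_ampa);
  const double d_gaba = std::exp(-dt / tau_gaba);
  const double d_nr = std::exp(-dt / tau_nr);
  const double d_nd = std::exp(-dt / tau_nd);
  const double nmda_norm = tau_nd / (tau_nd - tau_nr);
  const double mg_over = Mg / 3.57;

  // state
  std::vector<double> V(n_total), g_ext(n_total, 0.0), g_bg(n_total, 0.0),
      g_rec(n_total, 0.0), x_ns(n_total, 0.0), x_nf(n_total, 0.0),
      g_gaba(n_total, 0.0);
  std::vector<int> refr(n_total, 0);
  std::vector<std::vector<int>> delay_ring(std::max(delay_steps, 1));
  PCG32 rng;
  rng.seed((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 0x2545F4914F6CDD1DULL);
  int ring_pos = 0;

  for (int i = 0; i < n_total; ++i) V[i] = E_L[i < n_pyr ? 0 : 1];

  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector sV = st["V"], s1 = st["g_ext"], s2 = st["g_bg"],
                  s3 = st["g_rec"], s4 = st["x_nmda_slow"], s5 = st["x_nmda_fast"],
                  s6 = st["g_gaba"];
    IntegerVector sr = st["refractory_steps"];
    if (sV.size() != n_total) stop("state size does not match network size");
    for (int i = 0; i < n_total; ++i) {
      V[i] = sV[i]; g_ext[i] = s1[i]; g_bg[i] = s2[i]; g_rec[i] = s3[i];
      x_ns[i] = s4[i]; x_nf[i] = s5[i]; g_gaba[i] = s6[i]; refr[i] = sr[i];
    }
    List pend = st["pending_spikes"];
    for (int d = 0; d < (int)pend.size() && d < (int)delay_ring.size(); ++d) {
      IntegerVector ids = pend[d];
      delay_ring[d] = std::vector<int>(ids.begin(), ids.end());
    }
    NumericVector rs = st["rng_state"];
    rng_unpack(rng, rs);
  }

  // externally scheduled input events (deterministic test hook)
  std::vector<int> ev_neuron, ev_step;
  if (ext_event_neuron.isNotNull()) {
    IntegerVector en(ext_event_neuron), es(ext_event_step);
    if (en.size() != es.size()) stop("external event vectors must match");
    ev_neuron.assign(en.begin(), en.end());
    ev_step.assign(es.begin(), es.end());
  }
  std::size_t ev_ptr = 0;

  // outputs
  IntegerMatrix counts(n_steps, 4);  // left, right, non-selective, interneuron
  cnt_p = counts.begin();
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  double task_events_sel = 0.0;  // diagnostics: where task input landed
  double task_events_other = 0.0;

  std::vector<int> trial_starts(trial_start_steps.begin(), trial_start_steps.end());
  std::size_t next_trial = 0;

  std::vector<int> fired;
  fired.reserve(256);

  const double lam_bg_cls[2] = {background_rate[0] * dt / 1000.0,
                                background_rate[1] * dt / 1000.0};
  const double e_lam_bg_cls[2] = {std::exp(-lam_bg_cls[0]),
                                  std::exp(-lam_bg_cls[1])};
  const bool any_bg = lam_bg_cls[0] > 0.0 || lam_bg_cls[1] > 0.0;

  for (int s = 0; s < n_steps; ++s) {
    if (reinitialize && next_trial < trial_starts.size() && s == trial_starts[next_trial]) {
      for (int i = 0; i < n_total; ++i) {
        V[i] = E_L[i < n_pyr ? 0 : 1];
        g_ext[i] = g_bg[i] = g_rec[i] = x_ns[i] = x_nf[i] = g_gaba[i] = 0.0;
        refr[i] = 0;
      }
      for (auto &dr : delay_ring) dr.clear();
    }
    if (next_trial < trial_starts.size() && s == trial_starts[next_trial]) ++next_trial;

    // decay all synapse states
    for (int i = 0; i < n_total; ++i) {
      g_ext[i] *= d_ampa;
      g_bg[i] *= d_ampa;
      g_rec[i] *= d_ampa;
      x_ns[i] *= d_nd;
      x_nf[i] *= d_nr;
      g_gaba[i] *= d_gaba;
    }

    // deliver delayed recurrent spikes
    std::vector<int> &due = delay_ring[ring_pos];
    for (int pre : due) {
      const bool exc = pre < n_pyr;
      const bool pre_sel = pre < 2 * n_sel;
      const int pre_pool = pre < n_sel ? 0 : 1;
      for (int p = off_p[pre]; p < off_p[pre + 1]; ++p) {
        const int tgt = tgt_p[p];
        const int cls = tgt < n_pyr ? 0 : 1;
        if (exc) {
          // Hebbian-potentiated weights within a selective pool
          const double w = (pre_sel && tgt < 2 * n_sel &&
                            (tgt < n_sel ? 0 : 1) == pre_pool) ? w_plus : 1.0;
          if (saturating) {
            g_rec[tgt] = pGrec[cls] * w;
            x_ns[tgt] = w;
            x_nf[tgt] = w;
          } else {
            g_rec[tgt] += pGrec[cls] * w;
            x_ns[tgt] += w;
            x_nf[tgt] += w;
          }
        } else {
          if (saturating) g_gaba[tgt] = pGgaba[cls];
          else            g_gaba[tgt] += pGgaba[cls];
        }
      }
    }
    due.clear();

    // background Poisson input to every neuron
    if (any_bg) {
      for (int i = 0; i < n_total; ++i) {
        const int cls = i < n_pyr ? 0 : 1;
        int k = rpois_small(rng, lam_bg_cls[cls], e_lam_bg_cls[cls]);
        if (k) {
          if (saturating) g_bg[i] = pGbg[cls];
          else            g_bg[i] += k * pGbg[cls];
        }
      }
    }

    // task-related Poisson input to the selective pools only
    for (int pool = 0; pool < 2; ++pool) {
      const double rate = pool == 0 ? task_rate_left[s] : task_rate_right[s];
      if (rate <= 0.0) continue;
      const double lam = rate * dt / 1000.0;
      const double e_lam = fast_exp(-lam);
      const int lo = pool * n_sel, hi = lo + n_sel;
      for (int i = lo; i < hi; ++i) {
        int k = rpois_small(rng, lam, e_lam);
        if (k) {
          if (saturating) g_ext[i] = pGext[0];
          else            g_ext[i] += k * pGext[0];
          task_events_sel += k;
        }
      }
    }

    // externally scheduled events (delivered to the AMPA_ext state)
    while (ev_ptr < ev_step.size() && ev_step[ev_ptr] == s) {
      const int i = ev_neuron[ev_ptr];
      const int cls = i < n_pyr ? 0 : 1;
      if (saturating) g_ext[i] = pGext[cls];
      else            g_ext[i] += pGext[cls];
      if (i >= 2 * n_sel || i >= n_pyr) task_events_other += 1.0;
      else task_events_sel += 1.0;
      ++ev_ptr;
    }

    // membrane update
    fired.clear();
    for (int i = 0; i < n_total; ++i) {
      const int cls = i < n_pyr ? 0 : 1;
      if (refr[i] > 0) {
        --refr[i];
        V[i] = pVr[cls];  // clamped during the refractory period
        continue;
      }
      const double v = V[i];
      const double gate = 1.0 / (1.0 + mg_over * fast_exp(-0.062 * v));
      const double I_ampa = (g_ext[i] + g_bg[i] + g_rec[i]) * v;  // E = 0 mV
      const double I_nmda = pGnmda[cls] * nmda_norm * (x_ns[i] - x_nf[i]) * gate * v;
      const double I_gaba = g_gaba[i] * (v - E_gaba);
      const double I_total = I_ampa + I_nmda + I_gaba - (cls == 0 ? I_stim_pyr : I_stim_int);
      double arg = (v - pVT[cls]) / pDT[cls];
      if (arg > 20.0) arg = 20.0;  // spike is inevitable; avoid overflow
      const double dV = dt *
        (-pgL[cls] * (v - pEL[cls]) + pgL[cls] * pDT[cls] * fast_exp(arg) - I_total) /
        (pC[cls] * 1000.0);
      double v_new = v + dV;
      if (!std::isfinite(v_new))
        stop("numerical instability: neuron %d at t = %.2f ms", i + 1, s * dt);
      if (v_new >= pVs[cls]) {
        fired.push_back(i);
        v_new = pVr[cls];
        refr[i] = pref[cls];
      }
      V[i] = v_new;
    }

    // record spikes
    for (int id : fired) {
      int pop;
      if (id < n_sel) pop = 0;
      else if (id < 2 * n_sel) pop = 1;
      else if (id < n_pyr) pop = 2;
      else pop = 3;
      ++cnt_p[s + (R_xlen_t)n_steps * pop];
      if (return_spikes) {
        spike_id.push_back(id + 1);
        spike_t.push_back((s + 1) * dt);  // spikes register at the end of the step
      }
    }
    delay_ring[ring_pos].swap(fired);
    ring_pos = (ring_pos + 1) % delay_ring.size();
  }

  // pack final state; ring rotated so entry d holds spikes due in d+1 steps
  List pend((int)delay_ring.size());
  for (int d = 0; d < (int)delay_ring.size(); ++d) {
    const std::vector<int> &v = delay_ring[(ring_pos + d) % delay_ring.size()];
    pend[d] = IntegerVector(v.begin(), v.end());
  }
  List state = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["g_ext"] = NumericVector(g_ext.begin(), g_ext.end()),
      _["g_bg"] = NumericVector(g_bg.begin(), g_bg.end()),
      _["g_rec"] = NumericVector(g_rec.begin(), g_rec.end()),
      _["x_nmda_slow"] = NumericVector(x_ns.begin(), x_ns.end()),
      _["x_nmda_fast"] = NumericVector(x_nf.begin(), x_nf.end()),
      _["g_gaba"] = NumericVector(g_gaba.begin(), g_gaba.end()),
      _["refractory_steps"] = IntegerVector(refr.begin(), refr.end()),
      _["pending_spikes"] = pend,
      _["rng_state"] = rng_pack(rng));

  List out = List::create(
      _["counts"] = counts,
      _["state"] = state,
      _["task_events_selective"] = task_events_sel,
      _["task_events_other"] = task_events_other,
      _["n_steps"] = n_steps);
  if (return_spikes) {
    out["spike_neuron"] = IntegerVector(spike_id.begin(), spike_id.end());
    out["spike_time_ms"] = NumericVector(spike_t.begin(), spike_t.end());
  }
  return out;
}
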