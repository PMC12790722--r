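// Izhikevich-network integrator with delayed delivery and additive STDP.
//
// The network state handed in from R is one row per neuron: outgoing
// targets, integer-ms delays and weights.  Integration runs on a 1-ms
// event grid (configurable dt) with two half-steps of the membrane
// equation per step, a circular buffer for delayed synaptic delivery, and
// trace-based STDP: presynaptic traces are indexed at spike-arrival time,
// depression is applied on delivery after a postsynaptic spike, and
// excitatory weights are consolidated once per second with a damped
// eligibility derivative plus a small positive drift.
//
// Synapse tables are copied into flat row-major arrays so the per-spike
// loops stream through contiguous memory (the R matrices are column-major).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".izhi_simulate")]]
List izhi_simulate(int n_neurons,
                   int n_excitatory,
                   IntegerMatrix targets,      // N x M, 1-based neuron ids
                   IntegerMatrix delays,       // N x M, integer ms >= 1
                   NumericMatrix weights_in,   // N x M
                   double dt,                  // ms; must divide 1
                   double total_ms,            // warmup + scored, ms
                   double warmup_ms,
                   double input_current,       // amplitude of the per-ms drive
                   bool stdp_enabled,
                   double a_plus,
                   double a_minus,
                   double tau_ms,
                   double weight_cap,
                   double weight_drift,        // per-second additive drift
                   double sd_damping,          // per-second eligibility damping
                   NumericVector bias_current, // constant per-neuron drive
                   bool record_raster)
{
  const int N = n_neurons;
  const int M = targets.ncol();
  const int T = (int) std::lround(total_ms);
  const int warm = (int) std::lround(warmup_ms);
  const int steps_per_ms = std::max(1, (int) std::lround(1.0 / dt));

  // flat row-major copies of the synapse tables
  std::vector<int> tg((size_t) N * M), dl((size_t) N * M);
  std::vector<double> w((size_t) N * M);
  int max_delay = 1;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < M; ++j) {
      tg[(size_t) i * M + j] = targets(i, j) - 1;
      int d_ = delays(i, j);
      dl[(size_t) i * M + j] = d_;
      w[(size_t) i * M + j] = weights_in(i, j);
      if (d_ > max_delay) max_delay = d_;
    }
  const int D = max_delay;

  // neuron constants: regular spiking (excitatory), fast spiking (inhibitory)
  std::vector<double> a(N), d(N);
  const double b = 0.2, c = -65.0;
  for (int i = 0; i < N; ++i) {
    if (i < n_excitatory) { a[i] = 0.02; d[i] = 8.0; }
    else                  { a[i] = 0.10; d[i] = 2.0; }
  }

  // reverse index of excitatory synapses (flat, CSR-like) for STDP
  std::vector<int> in_off(N + 1, 0), in_pre, in_synidx;
  if (stdp_enabled) {
    std::vector<int> cnt(N, 0);
    for (int i = 0; i < n_excitatory; ++i)
      for (int j = 0; j < M; ++j) cnt[tg[(size_t) i * M + j]]++;
    for (int i = 0; i < N; ++i) in_off[i + 1] = in_off[i] + cnt[i];
    in_pre.resize(in_off[N]);
    in_synidx.resize(in_off[N]);
    std::vector<int> fill(N, 0);
    for (int i = 0; i < n_excitatory; ++i)
      for (int j = 0; j < M; ++j) {
        int t_ = tg[(size_t) i * M + j];
        int pos = in_off[t_] + fill[t_]++;
        in_pre[pos] = i;
        in_synidx[pos] = (int) ((size_t) i * M + j);
      }
  }

  std::vector<double> v(N, -65.0), u(N);
  for (int i = 0; i < N; ++i) u[i] = b * v[i];

  // delayed-input ring buffer, D + 1 slots
  std::vector<double> Ibuf((size_t) (D + 1) * N, 0.0);

  const double decay = std::exp(-1.0 / tau_ms);
  std::vector<double> decay_pow(D + 1);
  for (int k = 0; k <= D; ++k) decay_pow[k] = std::pow(decay, (double) k);

  // presynaptic trace indexed by arrival time within the current second
  const int LTP_W = 1001 + D;
  std::vector<double> LTP;
  std::vector<double> LTD(N, 0.0);
  std::vector<double> sd;                 // eligibility, exc synapses only
  if (stdp_enabled) {
    LTP.assign((size_t) N * LTP_W, 0.0);
    sd.assign((size_t) n_excitatory * M, 0.0);
  }

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  if (record_raster) { sp_neuron.reserve(1 << 20); sp_time.reserve(1 << 20); }
  std::vector<double> pop_counts(std::max(0, T - warm), 0.0);

  const bool has_bias = bias_current.size() == N;
  std::vector<int> fired;
  fired.reserve(N);

  RNGScope scope;

  for (int t = 0; t < T; ++t) {
    const int slot = t % (D + 1);
    double* I = &Ibuf[(size_t) slot * N];

    // external drive: one random neuron per ms, plus any constant bias
    if (input_current != 0.0) {
      int k = (int) std::floor(unif_rand() * N);
      if (k >= N) k = N - 1;
      I[k] += input_current;
    }
    if (has_bias)
      for (int i = 0; i < N; ++i) I[i] += bias_current[i];

    const int tmod = t % 1000;

    fired.clear();
    for (int i = 0; i < N; ++i) {
      double vi = v[i], ui = u[i];
      const double Ii = I[i];
      for (int s = 0; s < steps_per_ms; ++s) {
        vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
        vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
        ui += dt * a[i] * (b * vi - ui);
        if (vi >= 30.0) break;
      }
      if (!std::isfinite(vi) || !std::isfinite(ui))
        stop("membrane variable diverged (neuron %d, t = %d ms)", i + 1, t);
      if (vi >= 30.0) {
        v[i] = c;
        u[i] = ui + d[i];
        fired.push_back(i);
        if (t >= warm) {
          pop_counts[t - warm] += 1.0;
          if (record_raster) {
            sp_neuron.push_back(i + 1);
            sp_time.push_back((double) (t - warm));
          }
        }
      } else {
        v[i] = vi;
        u[i] = ui;
      }
    }
    for (int i = 0; i < N; ++i) I[i] = 0.0;

    for (size_t fk = 0; fk < fired.size(); ++fk) {
      const int fi = fired[fk];
      if (stdp_enabled) {
        LTP[(size_t) fi * LTP_W + tmod + D] = a_plus;
        LTD[fi] = a_minus;
        // potentiate incoming exc synapses whose spikes arrived just before
        for (int k = in_off[fi]; k < in_off[fi + 1]; ++k) {
          const int pre = in_pre[k];
          const int syn = in_synidx[k];
          sd[syn] += LTP[(size_t) pre * LTP_W + tmod + D - dl[syn]];
        }
      }
      // schedule delivery
      const bool exc = fi < n_excitatory;
      const size_t row = (size_t) fi * M;
      for (int j = 0; j < M; ++j) {
        const int tgt = tg[row + j];
        const int d_ = dl[row + j];
        int s2 = slot + d_;
        if (s2 > D) s2 -= (D + 1);
        Ibuf[(size_t) s2 * N + tgt] += w[row + j];
        if (stdp_enabled && exc) {
          // depression: presynaptic spike arriving after a recent
          // postsynaptic spike weakens the synapse at arrival time
          sd[row + j] -= LTD[tgt] * decay_pow[d_];
        }
      }
    }

    if (stdp_enabled) {
      // advance traces one ms
      for (int i = 0; i < N; ++i) {
        LTP[(size_t) i * LTP_W + tmod + D + 1] =
          decay * LTP[(size_t) i * LTP_W + tmod + D];
        LTD[i] *= decay;
      }
      if (tmod == 999) {
        for (int i = 0; i < N; ++i) {
          double* row = &LTP[(size_t) i * LTP_W];
          for (int j = 0; j <= D; ++j) row[j] = row[1000 + j];
          for (int j = D + 1; j < LTP_W; ++j) row[j] = 0.0;
        }
        for (size_t s = 0; s < sd.size(); ++s) {
          double w_ = w[s] + weight_drift + sd[s];
          if (w_ < 0.0) w_ = 0.0;
          if (w_ > weight_cap) w_ = weight_cap;
          w[s] = w_;
          sd[s] *= sd_damping;
        }
      }
    }

    if ((t & 1023) == 0) checkUserInterrupt();
  }

  NumericMatrix weights_out(N, M);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < M; ++j)
      weights_out(i, j) = w[(size_t) i * M + j];

  return List::create(_["neuron"] = wrap(sp_neuron),
                      _["time_ms"] = wrap(sp_time),
                      _["pop_counts"] = wrap(pop_counts),
                      _["weights"] = weights_out);
}
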