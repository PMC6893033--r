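#include <Rcpp.h>
#include <queue>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Deterministic RNG helpers. mt19937_64 output is standardized bit-exactly;
// the transforms below avoid implementation-defined std::*_distribution.
namespace {

struct Rng {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(int seed, uint32_t stream) {
    std::seed_seq seq{static_cast<uint32_t>(seed), stream, 0x9e3779b9u};
    eng.seed(seq);
  }
  double unif() { // in [0, 1)
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { // inter-event interval
    double u = unif();
    return -std::log1p(-u) / rate;
  }
  double norm() { // Box-Muller, cached
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

struct Csr {
  std::vector<int> ptr, col;
  std::vector<double> val;
  int nrow = 0;
};

Csr dense_to_csr(const NumericMatrix &m) {
  Csr c;
  c.nrow = m.nrow();
  c.ptr.assign(c.nrow + 1, 0);
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      if (m(i, j) != 0.0) c.ptr[i + 1]++;
  for (int i = 0; i < c.nrow; ++i) c.ptr[i + 1] += c.ptr[i];
  c.col.resize(c.ptr[c.nrow]);
  c.val.resize(c.ptr[c.nrow]);
  std::vector<int> pos(c.ptr.begin(), c.ptr.end() - 1);
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      if (m(i, j) != 0.0) { c.col[pos[i]] = j; c.val[pos[i]] = m(i, j); pos[i]++; }
  return c;
}

Csr triplet_to_csr(int nrow, const IntegerVector &ti, const IntegerVector &tj,
                   const NumericVector &tx) {
  Csr c;
  c.nrow = nrow;
  c.ptr.assign(nrow + 1, 0);
  int nnz = ti.size();
  for (int e = 0; e < nnz; ++e) c.ptr[ti[e] + 1]++;
  for (int i = 0; i < nrow; ++i) c.ptr[i + 1] += c.ptr[i];
  c.col.resize(nnz);
  c.val.resize(nnz);
  std::vector<int> pos(c.ptr.begin(), c.ptr.end() - 1);
  for (int e = 0; e < nnz; ++e) {
    int i = ti[e];
    c.col[pos[i]] = tj[e];
    c.val[pos[i]] = tx[e];
    pos[i]++;
  }
  return c;
}

inline double csr_dot_state(const Csr &c, int row, const std::vector<uint8_t> &s,
                            int offset) {
  double acc = 0.0;
  for (int e = c.ptr[row]; e < c.ptr[row + 1]; ++e)
    acc += c.val[e] * s[c.col[e] + offset];
  return acc;
}

// min-heap on (time, unit index); ties broken by lowest unit index
typedef std::pair<double, int> Event;

} // namespace

// Event-driven asynchronous simulation of a sampling network coupled to a
// noise backend. Unit indices: 0..M-1 sampling units, M..M+N-1 noise units.
//
// unit_kind: 0 intrinsic logistic (inverse temperature beta),
//            1 deterministic Heaviside + private Gaussian noise,
//            2 deterministic Heaviside + projected background input.
// noise_kind: 0 none, 1 shared pool (stochastic logistic, unconnected),
//             2 recurrent deterministic network (Heaviside).
// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix W, NumericVector b, double beta,
                        int unit_kind, double priv_mu, double priv_sigma,
                        NumericMatrix P, int noise_kind,
                        NumericVector noise_bias, double beta_pool,
                        IntegerVector A_i, IntegerVector A_j, NumericVector A_x,
                        double T, double tau, double T_warmup,
                        IntegerVector record_subset, bool record_noise_updates,
                        int seed, int snapshot_every, IntegerVector probe_targets,
                        bool accumulate_source_cov, int max_samples) {
  const int M = W.nrow();
  const int N = (noise_kind > 0) ? noise_bias.size() : 0;
  const int n_units = M + N;
  const int m_rec = record_subset.size();
  const int n_probe = probe_targets.size();
  if (n_units == 0) stop("no units to simulate");
  if (tau <= 0.0 || T <= 0.0) stop("tau and T must be positive");

  Rng rng_sched(seed, 1u), rng_update(seed, 2u), rng_noise(seed, 3u);

  Csr proj, adj;
  if (unit_kind == 2 && noise_kind > 0) proj = dense_to_csr(P);
  if (noise_kind == 2) adj = triplet_to_csr(N, A_i, A_j, A_x);

  // pool update probabilities are state-independent; precompute
  std::vector<double> pool_p(noise_kind == 1 ? N : 0);
  for (int k = 0; k < (int)pool_p.size(); ++k)
    pool_p[k] = 1.0 / (1.0 + std::exp(-beta_pool * noise_bias[k]));

  // initial states: independent fair coins at t = 0
  std::vector<uint8_t> s(n_units);
  for (int i = 0; i < n_units; ++i) s[i] = rng_update.unif() < 0.5 ? 1 : 0;

  const double rate = 1.0 / tau;
  std::priority_queue<Event, std::vector<Event>, std::greater<Event>> queue;
  for (int i = 0; i < n_units; ++i) queue.push(Event(rng_sched.expo(rate), i));

  std::vector<double> rec_times;
  std::vector<int> rec_states;
  if (max_samples > 0) {
    rec_times.reserve(max_samples);
    rec_states.reserve((size_t)max_samples * m_rec);
  }
  std::vector<double> probe_fields; // row-major, n_probe per snapshot
  std::vector<double> src_sum(N, 0.0);
  std::vector<double> src_cross; // upper triangle co-activation counts
  if (accumulate_source_cov && N > 0) src_cross.assign((size_t)N * N, 0.0);
  std::vector<int> active; // scratch for co-activation accumulation
  std::vector<double> update_counts(n_units, 0.0);
  long long n_rec = 0, n_snap = 0;

  while (!queue.empty()) {
    Event ev = queue.top();
    const double t = ev.first;
    const int u = ev.second;
    if (t > T) break;
    queue.pop();
    queue.push(Event(t + rng_sched.expo(rate), u));
    update_counts[u] += 1.0;

    if (u < M) { // sampling unit
      double h = b[u];
      for (int j = 0; j < M; ++j) h += W(u, j) * s[j];
      if (unit_kind == 0) {
        double p = 1.0 / (1.0 + std::exp(-beta * h));
        s[u] = rng_update.unif() < p ? 1 : 0;
      } else if (unit_kind == 1) {
        double xi = priv_mu + priv_sigma * rng_noise.norm();
        s[u] = (h + xi) >= 0.0 ? 1 : 0;
      } else {
        double pf = (noise_kind > 0) ? csr_dot_state(proj, u, s, M) : 0.0;
        s[u] = (h + pf) >= 0.0 ? 1 : 0;
      }
    } else { // noise unit
      int k = u - M;
      if (noise_kind == 1) {
        s[u] = rng_update.unif() < pool_p[k] ? 1 : 0;
      } else {
        double h = noise_bias[k] + csr_dot_state(adj, k, s, M);
        s[u] = h >= 0.0 ? 1 : 0;
      }
    }

    const bool rec_event = (u < M) || (record_noise_updates && u >= M);
    if (rec_event && t >= T_warmup) {
      ++n_rec;
      rec_times.push_back(t);
      for (int r = 0; r < m_rec; ++r) rec_states.push_back(s[record_subset[r]]);
      if (snapshot_every > 0 && (n_rec % snapshot_every) == 0 && N > 0) {
        ++n_snap;
        for (int pr = 0; pr < n_probe; ++pr)
          probe_fields.push_back(csr_dot_state(proj, probe_targets[pr], s, M));
        for (int k = 0; k < N; ++k) src_sum[k] += s[M + k];
        if (accumulate_source_cov) {
          active.clear();
          for (int k = 0; k < N; ++k)
            if (s[M + k]) active.push_back(k);
          for (size_t a = 0; a < active.size(); ++a)
            for (size_t bb = a; bb < active.size(); ++bb)
              src_cross[(size_t)active[a] * N + active[bb]] += 1.0;
        }
      }
      if (max_samples > 0 && n_rec >= max_samples) break;
    }
  }

  IntegerMatrix states(n_rec, m_rec);
  for (long long e = 0; e < n_rec; ++e)
    for (int r = 0; r < m_rec; ++r) states(e, r) = rec_states[(size_t)e * m_rec + r];

  NumericMatrix probes(n_snap, n_probe);
  for (long long e = 0; e < n_snap; ++e)
    for (int r = 0; r < n_probe; ++r) probes(e, r) = probe_fields[(size_t)e * n_probe + r];

  NumericVector src_mean(N);
  for (int k = 0; k < N; ++k) src_mean[k] = n_snap > 0 ? src_sum[k] / n_snap : NA_REAL;

  List out = List::create(
      _["times"] = NumericVector(rec_times.begin(), rec_times.end()),
      _["states"] = states, _["n_snapshots"] = (double)n_snap,
      _["probe_fields"] = probes, _["source_mean"] = src_mean,
      _["update_counts"] = NumericVector(update_counts.begin(), update_counts.end()),
      _["final_state"] = IntegerVector(s.begin(), s.end()));
  if (accumulate_source_cov && N > 0) {
    // unbiased sample covariance of source states over snapshots
    NumericMatrix cov(N, N);
    if (n_snap > 1) {
      for (int k = 0; k < N; ++k)
        for (int l = k; l < N; ++l) {
          double cross = src_cross[(size_t)k * N + l];
          double c = (cross - n_snap * src_mean[k] * src_mean[l]) / (n_snap - 1.0);
          cov(k, l) = c;
          cov(l, k) = c;
        }
    }
    out["source_cov"] = cov;
  }
  return out;
}

// Exact Boltzmann probabilities over all 2^M states by Gray-code enumeration.
// State code: unit 0 is the least-significant bit.
// [[Rcpp::export]]
NumericVector cpp_boltzmann_probs(NumericMatrix W, NumericVector b, double beta) {
  const int M = W.nrow();
  if (M < 1 || M > 30) stop("M out of range for enumeration");
  const size_t n_states = (size_t)1 << M;
  std::vector<double> logw(n_states);
  std::vector<double> f(M); // f_j = sum_i W(j, i) s_i for current state
  std::vector<uint8_t> s(M, 0);
  double x = 0.0; // beta * (1/2 sum w s s + sum b s); zero state -> 0
  logw[0] = 0.0;
  size_t code = 0;
  for (size_t g = 1; g < n_states; ++g) {
    // bit flipped between Gray codes g-1 and g
    int j = __builtin_ctzll(g);
    double d = s[j] ? -1.0 : 1.0;
    x += beta * d * (f[j] + b[j]);
    s[j] = !s[j];
    for (int i = 0; i < M; ++i) f[i] += d * W(i, j);
    code ^= (size_t)1 << j;
    logw[code] = x;
  }
  double mx = logw[0];
  for (size_t i = 1; i < n_states; ++i)
    if (logw[i] > mx) mx = logw[i];
  double z = 0.0;
  NumericVector probs(n_states);
  for (size_t i = 0; i < n_states; ++i) {
    probs[i] = std::exp(logw[i] - mx);
    z += probs[i];
  }
  for (size_t i = 0; i < n_states; ++i) probs[i] /= z;
  return probs;
}

// One asynchronous Gibbs sweep (each unit updated once, in the given order)
// applied independently to every row of the state matrix. Used for the
// negative phase of CD-1.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_sweep(NumericMatrix W, NumericVector b, double beta,
                              IntegerMatrix S, IntegerVector order, int seed) {
  const int M = W.nrow();
  const int n = S.nrow();
  IntegerMatrix out(clone(S));
  Rng rng(seed, 7u);
  for (int oi = 0; oi < order.size(); ++oi) {
    int u = order[oi];
    for (int r = 0; r < n; ++r) {
      double h = b[u];
      for (int j = 0; j < M; ++j) h += W(u, j) * out(r, j);
      double p = 1.0 / (1.0 + std::exp(-beta * h));
      out(r, u) = rng.unif() < p ? 1 : 0;
    }
  }
  return out;
}
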