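#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Self-contained counter-free PRNG so trajectories are bit-reproducible from
// an integer seed, independent of R's RNG state: xoshiro256++ seeded via
// splitmix64 (Blackman & Vigna).  Replicate r of an ensemble with master
// seed s uses the r-th output of the splitmix64 stream started at s, which
// gives deterministic, effectively independent substreams.

namespace {

struct SplitMix64 {
  uint64_t x;
  explicit SplitMix64(uint64_t seed) : x(seed) {}
  uint64_t next() {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    SplitMix64 sm(seed);
    for (int i = 0; i < 4; ++i) s[i] = sm.next();
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]; never 0 so log() is safe
  double unif() {
    return (static_cast<double>(next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

struct TelegraphParams {
  double r_on, r_off, k_m, g_m, k_p, g_p;
};

struct TelegraphState {
  int g;       // promoter: 0 = OFF, 1 = ON
  double m;    // mRNA copy number (integer-valued)
  double p;    // protein copy number (integer-valued)
};

// Advance the jump process from time t0, writing the state that holds at
// each requested sample time (piecewise-constant between reaction events;
// a sample coinciding exactly with an event records the post-event state).
// On return `st` holds the state at the final sample time.
void run_segment(const TelegraphParams &par, TelegraphState &st, double t0,
                 const NumericVector &times, Xoshiro256pp &rng,
                 IntegerVector *out_g, NumericVector *out_m,
                 NumericVector *out_p) {
  const R_xlen_t n = times.size();
  double t = t0;
  R_xlen_t k = 0;
  while (k < n) {
    const double a1 = st.g ? par.r_off : par.r_on;   // promoter flip
    const double a2 = par.k_m * st.g;                // transcription
    const double a3 = par.g_m * st.m;                // mRNA decay
    const double a4 = par.k_p * st.m;                // translation
    const double a5 = par.g_p * st.p;                // protein removal
    const double a0 = a1 + a2 + a3 + a4 + a5;
    double t_next;
    if (a0 > 0.0) {
      t_next = t - std::log(rng.unif()) / a0;
    } else {
      t_next = R_PosInf;  // absorbing: hold state forever
    }
    while (k < n && times[k] < t_next) {
      if (out_g) (*out_g)[k] = st.g;
      if (out_m) (*out_m)[k] = st.m;
      if (out_p) (*out_p)[k] = st.p;
      ++k;
    }
    if (k >= n) break;
    t = t_next;
    const double u = rng.unif() * a0;
    if (u < a1) {
      st.g = 1 - st.g;
    } else if (u < a1 + a2) {
      st.m += 1.0;
    } else if (u < a1 + a2 + a3) {
      st.m -= 1.0;
    } else if (u < a1 + a2 + a3 + a4) {
      st.p += 1.0;
    } else {
      st.p -= 1.0;
    }
  }
}

TelegraphParams make_params(double r_on, double r_off, double k_m, double g_m,
                            double k_p, double g_p) {
  TelegraphParams par;
  par.r_on = r_on; par.r_off = r_off;
  par.k_m = k_m;   par.g_m = g_m;
  par.k_p = k_p;   par.g_p = g_p;
  return par;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ssa_path(double r_on, double r_off, double k_m, double g_m,
                  double k_p, double g_p, int g0, double m0, double p0,
                  double t0, NumericVector times, double seed) {
  const TelegraphParams par = make_params(r_on, r_off, k_m, g_m, k_p, g_p);
  TelegraphState st;
  st.g = g0; st.m = m0; st.p = p0;
  Xoshiro256pp rng(static_cast<uint64_t>(seed));
  const R_xlen_t n = times.size();
  IntegerVector out_g(n);
  NumericVector out_m(n), out_p(n);
  run_segment(par, st, t0, times, rng, &out_g, &out_m, &out_p);
  return List::create(_["promoter"] = out_g, _["mrna"] = out_m,
                      _["protein"] = out_p,
                      _["final"] = NumericVector::create(st.g, st.m, st.p));
}

// Endpoint-only ensemble: n_reps independent replicates, each run to t_end,
// initial promoter state Bernoulli(p_on_init) with state-conditional initial
// means (rounded) for mRNA and protein.
// [[Rcpp::export]]
NumericMatrix cpp_ssa_ensemble(double r_on, double r_off, double k_m,
                               double g_m, double k_p, double g_p,
                               double t_end, int n_reps, double seed,
                               double p_on_init, double m_init_off,
                               double m_init_on, double p_init_off,
                               double p_init_on) {
  const TelegraphParams par = make_params(r_on, r_off, k_m, g_m, k_p, g_p);
  NumericMatrix out(n_reps, 3);
  SplitMix64 stream(static_cast<uint64_t>(seed));
  NumericVector times = NumericVector::create(t_end);
  for (int r = 0; r < n_reps; ++r) {
    Xoshiro256pp rng(stream.next());
    TelegraphState st;
    st.g = (rng.unif() <= p_on_init) ? 1 : 0;
    st.m = std::nearbyint(st.g ? m_init_on : m_init_off);
    st.p = std::nearbyint(st.g ? p_init_on : p_init_off);
    run_segment(par, st, 0.0, times, rng, nullptr, nullptr, nullptr);
    out(r, 0) = st.g;
    out(r, 1) = st.m;
    out(r, 2) = st.p;
  }
  colnames(out) = CharacterVector::create("promoter", "mrna", "protein");
  return out;
}
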