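#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Viterbi decoding of the context-sensitive repeat HMM.
//
// The explicit state space (one NR state; per period p: R(p), i insertion
// states, d deletion states, and a forced chain of p J-states per indel run
// length) is never materialized. J-chains are deterministic once entered, so
// the score of a chain entered at position t0 with look-back L is the DP
// value at entry plus a contiguous sum of relative-emission terms, obtained
// from per-look-back prefix sums. Deletion states are silent and are folded
// into the chain-entry transition penalty. The decode is observationally
// equivalent to running Viterbi over the explicit space (tested against a
// brute-force reference implementation).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Model {
  int k, mi, md;            // max period, max consecutive insert/delete
  double lambda, nu_in, nu_out, match, at, open, cont;
  double bg[4];
  double l_match[4];        // log(match / bg[c])    (current letter c)
  double l_mis[4];          // log((1-match)/(1-bg[lb])) (look-back letter lb)
  double l_n;               // log(1 - match): any N involved
  double l_nr_nr, l_r_nr, l_open, l_cont, l_exit;
  std::vector<double> l_nr_r;   // per period
  std::vector<double> l_r_self; // per period
  std::vector<int> dmax;        // usable deletion run per period
};

static Model make_model(List par) {
  Model m;
  m.k  = as<int>(par["k"]);
  m.mi = as<int>(par["max_insert"]);
  m.md = as<int>(par["max_delete"]);
  m.lambda = as<double>(par["lambda"]);
  m.nu_in  = as<double>(par["nu_in"]);
  m.nu_out = as<double>(par["nu_out"]);
  m.match  = as<double>(par["match_prob"]);
  m.at     = as<double>(par["at_richness"]);
  m.open   = as<double>(par["indel_open"]);
  m.cont   = as<double>(par["indel_extend"]);
  m.bg[0] = m.at / 2; m.bg[1] = (1 - m.at) / 2;
  m.bg[2] = (1 - m.at) / 2; m.bg[3] = m.at / 2;
  for (int c = 0; c < 4; ++c) {
    m.l_match[c] = std::log(m.match / m.bg[c]);
    m.l_mis[c]   = std::log((1 - m.match) / (1 - m.bg[c]));
  }
  m.l_n = std::log1p(-m.match);
  m.l_nr_nr = std::log(1 - m.nu_in);
  m.l_r_nr  = std::log(m.nu_out);
  m.l_open  = m.open > 0 ? std::log(m.open) : NEG_INF;
  m.l_cont  = m.cont > 0 ? std::log(m.cont) : NEG_INF;
  m.l_exit  = std::log1p(-m.cont);
  double gden = 0;
  for (int p = 1; p <= m.k; ++p) gden += std::pow(m.lambda, p);
  m.l_nr_r.resize(m.k + 1);
  m.l_r_self.resize(m.k + 1);
  m.dmax.resize(m.k + 1);
  for (int p = 1; p <= m.k; ++p) {
    double gp = std::pow(m.lambda, p) / gden;
    double in = m.nu_in * gp;
    m.l_nr_r[p] = in > 0 ? std::log(in) : NEG_INF;
    m.dmax[p] = std::min(m.md, p - 1);
    double open_i = m.mi >= 1 ? m.open : 0.0;
    double open_d = m.dmax[p] >= 1 ? m.open : 0.0;
    m.l_r_self[p] = std::log(1 - m.nu_out - open_i - open_d);
  }
  return m;
}

// log relative-emission of position t (1-based) under look-back L.
// Neutral (0) when the look-back reaches before the window start.
static inline double erel(const int *code, int n, int t, int L, const Model &m) {
  if (L <= 0 || t - L < 1) return 0.0;
  int cur = code[t - 1], lb = code[t - 1 - L];
  if (cur == 4 || lb == 4) return m.l_n;
  return (cur == lb) ? m.l_match[cur] : m.l_mis[lb];
}

// exit log-probability of an insertion run of length a (into its J-chain)
static inline double exit_i(const Model &m, int a) {
  return (a < m.mi) ? m.l_exit : 0.0;
}
static inline double exit_d(const Model &m, int j, int p) {
  return (j < m.dmax[p]) ? m.l_exit : 0.0;
}

// [[Rcpp::export(name = ".decode_core")]]
List decode_core(IntegerVector seq_codes, List par) {
  Model m = make_model(par);
  const int n = seq_codes.size();
  const int k = m.k, mi = m.mi;
  std::vector<int> code(n);
  for (int t = 0; t < n; ++t) code[t] = seq_codes[t] - 1; // 0..3, 4 = N

  if (n == 0) {
    return List::create(_["kind"] = IntegerVector(0),
                        _["period"] = IntegerVector(0),
                        _["run"] = IntegerVector(0),
                        _["look_back"] = IntegerVector(0),
                        _["del_before"] = IntegerVector(0),
                        _["score"] = 0.0);
  }

  const int Lmax = k + mi;
  // prefix sums of relative-emission terms per look-back: PF[L][t], t = 0..n
  std::vector<double> PF((size_t)(Lmax + 1) * (n + 1), 0.0);
  for (int L = 1; L <= Lmax; ++L) {
    double *row = &PF[(size_t)L * (n + 1)];
    row[0] = 0.0;
    for (int t = 1; t <= n; ++t) row[t] = row[t - 1] + erel(code.data(), n, t, L, m);
  }
  auto chain_sum = [&](int L, int t0, int t1) {
    const double *row = &PF[(size_t)L * (n + 1)];
    return row[t1] - row[t0];
  };

  // DP storage
  std::vector<double> Rv((size_t)(n + 1) * k, NEG_INF); // Rv[t*k + p-1]
  std::vector<double> NRv(n + 1, NEG_INF);
  std::vector<unsigned char> Rbp((size_t)(n + 1) * k, 0); // 0 self,1 NR,2 J
  std::vector<short> NRbp(n + 1, 0);                      // 0 NR, p from R(p)
  std::vector<signed char> Jprov((size_t)(n + 1) * k, 0); // +a ins, -j del
  std::vector<double> Jv_prev(k + 1, NEG_INF), Jv_cur(k + 1, NEG_INF);
  NRv[0] = 0.0;

  // I-state value: run of length a ending at DP index t (value excludes any
  // exit term). Derived from stored R values; I emissions are ratio-neutral.
  auto ival = [&](int p, int a, int t) {
    int t0 = t - a;
    if (t0 < 0) return NEG_INF;
    double v = Rv[(size_t)t0 * k + (p - 1)];
    if (v == NEG_INF) return NEG_INF;
    v += m.l_open;
    for (int s = 1; s < a; ++s) v += m.l_cont;
    return v;
  };

  for (int t = 1; t <= n; ++t) {
    // chains ending at t (entered at t0 = t - p)
    for (int p = 1; p <= k; ++p) {
      double best = NEG_INF;
      signed char prov = 0;
      int t0 = t - p;
      if (t0 >= 1) {
        for (int a = 1; a <= mi; ++a) {
          double v = ival(p, a, t0);
          if (v == NEG_INF) continue;
          v += exit_i(m, a) + chain_sum(p + a, t0, t);
          if (v > best) { best = v; prov = (signed char)a; }
        }
        double rv0 = Rv[(size_t)t0 * k + (p - 1)];
        if (rv0 != NEG_INF) {
          for (int j = 1; j <= m.dmax[p]; ++j) {
            double v = rv0 + m.l_open;
            for (int s = 1; s < j; ++s) v += m.l_cont;
            v += exit_d(m, j, p) + chain_sum(p - j, t0, t);
            if (v > best) { best = v; prov = (signed char)(-j); }
          }
        }
      }
      Jv_cur[p] = best;
      Jprov[(size_t)t * k + (p - 1)] = prov;
    }
    // R states
    for (int p = 1; p <= k; ++p) {
      double e = erel(code.data(), n, t, p, m);
      double best = NRv[t - 1] + m.l_nr_r[p] + e;
      unsigned char bp = 1;
      double c = Rv[(size_t)(t - 1) * k + (p - 1)] + m.l_r_self[p] + e;
      if (c > best) { best = c; bp = 0; }
      c = Jv_prev[p] + e; // J-chain end -> R with probability 1
      if (c > best) { best = c; bp = 2; }
      Rv[(size_t)t * k + (p - 1)] = best;
      Rbp[(size_t)t * k + (p - 1)] = bp;
    }
    // NR state (ratio-neutral emission)
    {
      double best = NRv[t - 1] + m.l_nr_nr;
      short bp = 0;
      for (int p = 1; p <= k; ++p) {
        double c = Rv[(size_t)(t - 1) * k + (p - 1)] + m.l_r_nr;
        if (c > best) { best = c; bp = (short)p; }
      }
      NRv[t] = best;
      NRbp[t] = bp;
    }
    std::swap(Jv_prev, Jv_cur);
  }

  // Choose the end state, in tie-break preference order:
  // NR, then R(p) by period, then I, then in-progress J-chains.
  struct End { int type, p, run, phase; }; // type 0 NR, 1 R, 2 I, 3 J
  double best = NRv[n];
  End end{0, 0, 0, 0};
  for (int p = 1; p <= k; ++p) {
    double v = Rv[(size_t)n * k + (p - 1)];
    if (v > best) { best = v; end = {1, p, 0, 0}; }
  }
  for (int p = 1; p <= k; ++p) {
    for (int a = 1; a <= mi; ++a) {
      double v = ival(p, a, n);
      if (v > best) { best = v; end = {2, p, a, 0}; }
    }
  }
  // chains completing exactly at n (path ends on the last J state)
  for (int p = 1; p <= k; ++p) {
    double v = Jv_prev[p]; // after the final swap: chains ending at n
    if (v > best) {
      best = v;
      end = {3, p, Jprov[(size_t)n * k + (p - 1)], p};
    }
  }
  for (int p = 1; p <= k; ++p) {
    for (int t0 = std::max(1, n - p + 1); t0 <= n - 1; ++t0) {
      int phase = n - t0; // chain position reached at n (1..p-1)
      for (int a = 1; a <= mi; ++a) {
        double v = ival(p, a, t0);
        if (v == NEG_INF) continue;
        v += exit_i(m, a) + chain_sum(p + a, t0, n);
        if (v > best) { best = v; end = {3, p, a, phase}; }
      }
      double rv0 = Rv[(size_t)t0 * k + (p - 1)];
      if (rv0 != NEG_INF) {
        for (int j = 1; j <= m.dmax[p]; ++j) {
          double v = rv0 + m.l_open;
          for (int s = 1; s < j; ++s) v += m.l_cont;
          v += exit_d(m, j, p) + chain_sum(p - j, t0, n);
          if (v > best) { best = v; end = {3, p, -j, phase}; }
        }
      }
    }
  }

  // traceback
  IntegerVector kind(n), period(n), run(n), look_back(n), del_before(n);
  int type = end.type, p = end.p, r = end.run, phase = end.phase;
  for (int t = n; t >= 1; --t) {
    // record label of position t
    if (type == 0) { kind[t-1] = 0; period[t-1] = 0; run[t-1] = 0; look_back[t-1] = 0; }
    else if (type == 1) { kind[t-1] = 1; period[t-1] = p; run[t-1] = 0; look_back[t-1] = p; }
    else if (type == 2) { kind[t-1] = 2; period[t-1] = p; run[t-1] = r; look_back[t-1] = 0; }
    else { kind[t-1] = 3; period[t-1] = p; run[t-1] = r;
           look_back[t-1] = r > 0 ? p + r : p + r; /* p - j */ }
    // step to predecessor state at t-1
    if (type == 0) {
      short bp = NRbp[t];
      if (bp == 0) { type = 0; } else { type = 1; p = bp; }
    } else if (type == 1) {
      unsigned char bp = Rbp[(size_t)t * k + (p - 1)];
      if (bp == 0) { type = 1; }
      else if (bp == 1) { type = 0; }
      else { r = Jprov[(size_t)(t - 1) * k + (p - 1)]; type = 3; phase = p; }
    } else if (type == 2) {
      if (r > 1) { type = 2; r = r - 1; } else { type = 1; }
    } else { // J
      if (phase > 1) { phase--; }
      else if (r > 0) { type = 2; /* I run of length r ended at t-1 */ }
      else { del_before[t-1] = -r; type = 1; }
    }
  }

  return List::create(_["kind"] = kind, _["period"] = period, _["run"] = run,
                      _["look_back"] = look_back,
                      _["del_before"] = del_before, _["score"] = best);
}

// Per-position path increments log T + log(E / E0) for an arbitrary label
// path (as produced by decode_core, or stitched across windows). Transitions
// absent from the model (possible only at window seams) are scored by
// routing through NR in zero steps: exit cost of the previous state plus the
// entry cost of the current one.
// [[Rcpp::export(name = ".path_terms")]]
NumericVector path_terms(IntegerVector seq_codes, IntegerVector kind,
                         IntegerVector period, IntegerVector run,
                         IntegerVector look_back, IntegerVector del_before,
                         List par) {
  Model m = make_model(par);
  const int n = seq_codes.size();
  std::vector<int> code(n);
  for (int t = 0; t < n; ++t) code[t] = seq_codes[t] - 1;
  NumericVector out(n);
  // previous state: start = NR
  int pk = 0, pp = 0, pr = 0;
  for (int t = 1; t <= n; ++t) {
    int ck = kind[t-1], cp = period[t-1], cr = run[t-1];
    double lt = NEG_INF;
    bool valid = true;
    if (ck == 0) {
      if (pk == 0) lt = m.l_nr_nr;
      else if (pk == 1) lt = m.l_r_nr;
      else valid = false;
    } else if (ck == 1) {
      if (pk == 1 && pp == cp) lt = m.l_r_self[cp];
      else if (pk == 0) lt = m.l_nr_r[cp];
      else if (pk == 3 && pp == cp) lt = 0.0; // chain end -> R
      else valid = false;
    } else if (ck == 2) {
      if (pk == 1 && pp == cp && cr == 1) lt = m.l_open;
      else if (pk == 2 && pp == cp && cr == pr + 1) lt = m.l_cont;
      else valid = false;
    } else { // J
      bool entry = (pk != 3) || pp != cp || pr != cr;
      if (!entry) lt = 0.0; // within chain
      else if (cr > 0 && pk == 2 && pp == cp && pr == cr) lt = exit_i(m, cr);
      else if (cr < 0 && pk == 1 && pp == cp) {
        int j = -cr;
        lt = m.l_open;
        for (int s = 1; s < j; ++s) lt += m.l_cont;
        lt += exit_d(m, j, cp);
      } else valid = false;
    }
    if (!valid) {
      // seam fallback: previous -> NR -> current
      double exit = (pk == 1) ? m.l_r_nr : (pk == 0 ? 0.0 : m.l_r_nr);
      double enter = (ck == 0) ? m.l_nr_nr : m.l_nr_r[std::max(cp, 1)];
      lt = exit + enter;
    }
    out[t-1] = lt + erel(code.data(), n, t, look_back[t-1], m);
    pk = ck; pp = cp; pr = cr;
  }
  return out;
}

// Sliding-window Jensen-Shannon divergence series used for repeat splitting.
// letters: 1..4 codes, 5 = N; idx: profile index 1..p, or 0 for letters
// (insertions) excluded from profiles. For each boundary b (w .. len - w,
// 1-based count of letters on the left), builds p x 4 frequency profiles
// from the w letters left of the boundary and the w letters right of it
// (pseudocount added to every cell before row normalization; N letters are
// excluded) and evaluates the halved symmetrized Kullback-Leibler sum.
// Returns a vector of length len with NA outside admissible boundaries.
// [[Rcpp::export(name = ".jsd_series")]]
NumericVector jsd_series(IntegerVector letters, IntegerVector idx, int p,
                         int w, double pseudo) {
  const int n = letters.size();
  NumericVector out(n, NA_REAL);
  if (2 * w > n || p < 1) return out;
  std::vector<double> L((size_t)p * 4), R((size_t)p * 4);
  for (int b = w; b <= n - w; ++b) {
    std::fill(L.begin(), L.end(), pseudo);
    std::fill(R.begin(), R.end(), pseudo);
    for (int s = b - w; s < b; ++s) {
      int c = letters[s] - 1, i = idx[s];
      if (i >= 1 && c < 4) L[(size_t)(i - 1) * 4 + c] += 1.0;
    }
    for (int s = b; s < b + w; ++s) {
      int c = letters[s] - 1, i = idx[s];
      if (i >= 1 && c < 4) R[(size_t)(i - 1) * 4 + c] += 1.0;
    }
    double jsd = 0.0;
    for (int i = 0; i < p; ++i) {
      double sl = 0, sr = 0;
      for (int c = 0; c < 4; ++c) { sl += L[(size_t)i*4+c]; sr += R[(size_t)i*4+c]; }
      for (int c = 0; c < 4; ++c) {
        double l = L[(size_t)i*4+c] / sl, r = R[(size_t)i*4+c] / sr;
        jsd += -0.5 * (l * std::log(r / l) + r * std::log(l / r));
      }
    }
    out[b - 1] = jsd; // boundary after letter b (1-based)
  }
  return out;
}
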