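#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bit-level primitives
//
// A regulatory region is a binary vector of length L; positions 0..L-2 are
// strength bits, position L-1 is the type bit.  Regions are stored with a
// stride so the same helpers serve single genomes (IntegerMatrix, stride n)
// and population arrays (dim n x L x N, stride n within an individual block).
// ---------------------------------------------------------------------------

static inline double interact_bits(const int* cis, const int* trans, int L,
                                   int cst, int tst) {
  if (cis[(size_t)(L - 1) * cst] == 0) return 0.0;  // cis gate closed
  int pc = 0;
  for (int l = 0; l < L - 1; ++l) pc += cis[(size_t)l * cst] & trans[(size_t)l * tst];
  double v = (double)pc / (double)L;
  return trans[(size_t)(L - 1) * tst] == 1 ? v : -v;
}

static void build_M(const int* cis, const int* trans, int n, int L, double* M) {
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      M[i + (size_t)n * j] = interact_bits(cis + i, trans + j, L, n, n);
}

// One synchronous update of the expression vector: a gene is expressed at
// t+1 iff its summed regulatory input at t is strictly positive.
static void step_state(const double* M, int n, const int* s, int* out) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j)
      if (s[j]) acc += M[i + (size_t)n * j];
    out[i] = acc > 0 ? 1 : 0;
  }
}

// ---------------------------------------------------------------------------
// Maturation: iterate to a fixed point (outcome 1), a cycle (2), or give up
// after step_cap steps without any state repeating (3, non-viable).
// ---------------------------------------------------------------------------

struct Matured {
  int outcome;                          // 1 fixed, 2 cycle, 3 non-viable
  int period;                           // 1 / k / 0
  int steps;
  double fit;                           // NA when no target supplied
  std::vector<int> repr;                // representative expression vector
  std::vector<std::vector<int> > cycle; // one full period (outcome 2, on demand)
};

static double fit_of(const int* e, const int* target, int n, double sigma2) {
  int d = 0;
  for (int i = 0; i < n; ++i)
    if (target[i] >= 0 && e[i] != target[i]) ++d;
  return std::exp(-std::sqrt((double)d) / sigma2);
}

// Packed-state fast path: for n <= 64 an expression vector fits one word, so
// visited-state bookkeeping needs no per-step allocation.  Larger networks
// fall back to string keys.

static inline uint64_t encode_state(const int* s, int n) {
  uint64_t w = 0;
  for (int i = 0; i < n; ++i) if (s[i]) w |= (uint64_t)1 << i;
  return w;
}

static inline void decode_state(uint64_t w, int n, int* s) {
  for (int i = 0; i < n; ++i) s[i] = (int)((w >> i) & 1);
}

static inline uint64_t step_packed(const double* M, int n, uint64_t w) {
  uint64_t out = 0;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j)
      if ((w >> j) & 1) acc += M[i + (size_t)n * j];
    if (acc > 0) out |= (uint64_t)1 << i;
  }
  return out;
}

static int fit_of_packed(uint64_t w, const int* target, int n) {
  int d = 0;
  for (int i = 0; i < n; ++i)
    if (target[i] >= 0 && (int)((w >> i) & 1) != target[i]) ++d;
  return d;
}

static Matured mature_packed(const double* M, int n, const int* init, int cap,
                             const int* target, double sigma2,
                             bool keep_cycle) {
  Matured r;
  r.outcome = 3; r.period = 0; r.steps = cap; r.fit = 0.0;
  std::vector<uint64_t> traj;
  traj.reserve(64);
  uint64_t cur = encode_state(init, n);
  traj.push_back(cur);
  std::unordered_map<uint64_t, int> seen;
  seen.emplace(cur, 0);
  for (int t = 1; t <= cap; ++t) {
    cur = step_packed(M, n, cur);
    traj.push_back(cur);
    std::unordered_map<uint64_t, int>::iterator it = seen.find(cur);
    if (it != seen.end()) {
      int t0 = it->second, per = t - t0;
      r.steps = t; r.period = per;
      r.repr.resize(n);
      if (per == 1) {
        r.outcome = 1;
        decode_state(cur, n, r.repr.data());
        r.fit = target ?
          std::exp(-std::sqrt((double)fit_of_packed(cur, target, n)) / sigma2) :
          NA_REAL;
      } else {
        r.outcome = 2;
        int bi = t0;
        if (target) {
          int worst = -1;
          for (int m = t0; m < t0 + per; ++m) {
            int d = fit_of_packed(traj[m], target, n);
            if (d > worst) { worst = d; bi = m; }
          }
          r.fit = std::exp(-std::sqrt((double)worst) / sigma2);
        } else {
          r.fit = NA_REAL;
        }
        decode_state(traj[bi], n, r.repr.data());
        if (keep_cycle) {
          r.cycle.resize(per, std::vector<int>(n));
          for (int m = 0; m < per; ++m)
            decode_state(traj[t0 + m], n, r.cycle[m].data());
        }
      }
      return r;
    }
    seen.emplace(cur, t);
  }
  r.repr.resize(n);
  decode_state(cur, n, r.repr.data());  // last state visited; fitness stays 0
  if (!target) r.fit = NA_REAL;
  return r;
}

static Matured mature_eval(const double* M, int n, const int* init, int cap,
                           const int* target, double sigma2, bool keep_cycle) {
  if (n <= 64) return mature_packed(M, n, init, cap, target, sigma2, keep_cycle);
  Matured r;
  r.outcome = 3; r.period = 0; r.steps = cap; r.fit = 0.0;
  std::vector<std::vector<int> > traj;
  traj.emplace_back(init, init + n);
  std::unordered_map<std::string, int> seen;
  {
    std::string k((size_t)n, '0');
    for (int i = 0; i < n; ++i) k[i] = (char)('0' + init[i]);
    seen.emplace(std::move(k), 0);
  }
  std::vector<int> cur(init, init + n), nxt(n);
  for (int t = 1; t <= cap; ++t) {
    step_state(M, n, cur.data(), nxt.data());
    cur.swap(nxt);
    traj.push_back(cur);
    std::string key((size_t)n, '0');
    for (int i = 0; i < n; ++i) key[i] = (char)('0' + cur[i]);
    std::unordered_map<std::string, int>::iterator it = seen.find(key);
    if (it != seen.end()) {
      int t0 = it->second, per = t - t0;
      r.steps = t; r.period = per;
      if (per == 1) {
        r.outcome = 1;
        r.repr = cur;
        r.fit = target ? fit_of(cur.data(), target, n, sigma2) : NA_REAL;
      } else {
        r.outcome = 2;
        int bi = t0;
        if (target) {
          double best = R_PosInf;
          for (int m = t0; m < t0 + per; ++m) {
            double f = fit_of(traj[m].data(), target, n, sigma2);
            if (f < best) { best = f; bi = m; }
          }
          r.fit = best;
        } else {
          r.fit = NA_REAL;
        }
        r.repr = traj[bi];
        if (keep_cycle)
          r.cycle.assign(traj.begin() + t0, traj.begin() + t0 + per);
      }
      return r;
    }
    seen.emplace(std::move(key), t);
  }
  r.repr = cur;  // last state visited; fitness stays 0
  if (!target) r.fit = NA_REAL;
  return r;
}

// Fitness-proportional parent draw from a cumulative-weight vector.
static int sample_cum(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  int k = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
  if (k >= (int)cum.size()) k = (int)cum.size() - 1;
  return k;
}

// ---------------------------------------------------------------------------
// Exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double interaction_cpp(IntegerVector cis, IntegerVector trans) {
  int L = cis.size();
  return interact_bits(cis.begin(), trans.begin(), L, 1, 1);
}

// [[Rcpp::export]]
NumericMatrix build_matrix_cpp(IntegerMatrix cis, IntegerMatrix trans) {
  int n = cis.nrow(), L = cis.ncol();
  NumericMatrix M(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      M(i, j) = interact_bits(cis.begin() + i, trans.begin() + j, L, n, n);
  return M;
}

// kind: 0 = cis (recompute row `gene`), 1 = trans (recompute column `gene`).
// `gene` is 0-based.
// [[Rcpp::export]]
NumericMatrix refresh_cpp(NumericMatrix M, IntegerMatrix cis, IntegerMatrix trans,
                          int gene, int kind) {
  int n = cis.nrow(), L = cis.ncol();
  NumericMatrix out = clone(M);
  if (kind == 0) {
    for (int j = 0; j < n; ++j)
      out(gene, j) = interact_bits(cis.begin() + gene, trans.begin() + j, L, n, n);
  } else {
    for (int i = 0; i < n; ++i)
      out(i, gene) = interact_bits(cis.begin() + i, trans.begin() + gene, L, n, n);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector step_cpp(NumericMatrix M, IntegerVector state) {
  int n = M.nrow();
  IntegerVector out(n);
  step_state(REAL(M), n, state.begin(), out.begin());
  return out;
}

// [[Rcpp::export]]
List mature_cpp(NumericMatrix M, IntegerVector init, int step_cap) {
  int n = M.nrow();
  Matured r = mature_eval(REAL(M), n, init.begin(), step_cap, (const int*)0, 1.0, true);
  IntegerMatrix cyc(r.outcome == 2 ? r.period : 0, n);
  if (r.outcome == 2)
    for (int m = 0; m < r.period; ++m)
      for (int i = 0; i < n; ++i) cyc(m, i) = r.cycle[m][i];
  return List::create(_["outcome"] = r.outcome, _["period"] = r.period,
                      _["steps"] = r.steps,
                      _["final"] = IntegerVector(r.repr.begin(), r.repr.end()),
                      _["cycle"] = cyc);
}

// target codes: -1 = free (neutral) gene, otherwise 0/1.
// [[Rcpp::export]]
double evaluate_cpp(NumericMatrix M, IntegerVector init, IntegerVector target,
                    double sigma2, int step_cap) {
  int n = M.nrow();
  Matured r = mature_eval(REAL(M), n, init.begin(), step_cap, target.begin(),
                          sigma2, false);
  return r.outcome == 3 ? 0.0 : r.fit;
}

// ---------------------------------------------------------------------------
// Population-level helpers.  Population bit arrays have dim (n, L, N):
// element (g, l, k) sits at g + n*l + n*L*k.  Interaction arrays have dim
// (n, n, N).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector build_pop_matrices_cpp(IntegerVector cis, IntegerVector trans,
                                     int n, int L, int N) {
  NumericVector M((R_xlen_t)n * n * N);
  size_t G = (size_t)n * L;
  for (int k = 0; k < N; ++k)
    build_M(cis.begin() + G * k, trans.begin() + G * k, n, L,
            REAL(M) + (size_t)n * n * k);
  return M;
}

// [[Rcpp::export]]
List mature_pop_cpp(NumericVector M, int n, int N, IntegerVector init,
                    int step_cap, IntegerVector target, double sigma2) {
  IntegerMatrix expr(n, N);
  NumericVector fit(N);
  IntegerVector outcome(N), steps(N), period(N);
  for (int k = 0; k < N; ++k) {
    Matured r = mature_eval(REAL(M) + (size_t)n * n * k, n, init.begin(),
                            step_cap, target.begin(), sigma2, false);
    for (int i = 0; i < n; ++i) expr(i, k) = r.repr[i];
    fit[k] = r.outcome == 3 ? 0.0 : r.fit;
    outcome[k] = r.outcome; steps[k] = r.steps; period[k] = r.period;
  }
  return List::create(_["expression"] = expr, _["fitness"] = fit,
                      _["outcome"] = outcome, _["steps"] = steps,
                      _["period"] = period);
}

// One Wright-Fisher generation: fitness-proportional parent draws, optional
// recombination (model 1 = cis-swapping, 2 = single breakpoint), Poisson
// bit-flip mutations with incremental matrix refresh, maturation, fitness.
// zero_policy: 0 = error when all fitnesses are zero, 1 = uniform fallback.
// [[Rcpp::export]]
List next_generation_cpp(IntegerVector cis, IntegerVector trans, NumericVector M,
                         NumericVector fitness, int n, int L, int N,
                         double mu, double tb_cis, double tb_trans,
                         IntegerVector target, double sigma2,
                         IntegerVector init_expr, int step_cap,
                         int recomb_model, double recomb_prob, int zero_policy) {
  const size_t G = (size_t)n * L;
  IntegerVector ncis((R_xlen_t)G * N), ntrans((R_xlen_t)G * N);
  NumericVector nM((R_xlen_t)n * n * N), nfit(N);
  IntegerMatrix nexpr(n, N);
  IntegerVector noutcome(N), nsteps(N), nperiod(N);

  std::vector<double> cum(N);
  double tot = 0.0;
  for (int k = 0; k < N; ++k) { tot += fitness[k]; cum[k] = tot; }
  bool uniform = false;
  if (!(tot > 0)) {
    if (zero_policy == 0)
      stop("all individuals have zero fitness; no parent can be selected");
    uniform = true;
    for (int k = 0; k < N; ++k) cum[k] = k + 1.0;
  }

  std::vector<double> childM((size_t)n * n);
  for (int k = 0; k < N; ++k) {
    int p1 = sample_cum(cum);
    const int* c1 = cis.begin() + G * p1;
    const int* t1 = trans.begin() + G * p1;
    int* cc = ncis.begin() + G * k;
    int* ct = ntrans.begin() + G * k;
    bool two = recomb_model > 0 && unif_rand() < recomb_prob;
    if (!two) {
      std::copy(c1, c1 + G, cc);
      std::copy(t1, t1 + G, ct);
      const double* pm = REAL(M) + (size_t)n * n * p1;
      std::copy(pm, pm + (size_t)n * n, childM.begin());
    } else {
      int p2 = sample_cum(cum);
      const int* c2 = cis.begin() + G * p2;
      const int* t2 = trans.begin() + G * p2;
      if (recomb_model == 1) {  // cis swapping: trans from p1, cis per-gene coin
        std::copy(t1, t1 + G, ct);
        for (int g = 0; g < n; ++g) {
          const int* src = unif_rand() < 0.5 ? c2 : c1;
          for (int l = 0; l < L; ++l) cc[g + (size_t)n * l] = src[g + (size_t)n * l];
        }
      } else {                  // breakpoint j in {1..n-1}
        int j = 1 + (int)(unif_rand() * (n - 1));
        if (j > n - 1) j = n - 1;
        for (int g = 0; g < n; ++g) {
          const int* sc = g < j ? c1 : c2;
          const int* st = g < j ? t1 : t2;
          for (int l = 0; l < L; ++l) {
            cc[g + (size_t)n * l] = sc[g + (size_t)n * l];
            ct[g + (size_t)n * l] = st[g + (size_t)n * l];
          }
        }
      }
      build_M(cc, ct, n, L, childM.data());
    }

    int nm = (int)R::rpois(mu);
    for (int m = 0; m < nm; ++m) {
      int reg = (int)(unif_rand() * (2 * n));
      if (reg >= 2 * n) reg = 2 * n - 1;
      int kind = reg / n;  // 0 = cis, 1 = trans
      int g = reg % n;
      int pos;
      if (unif_rand() < (kind == 0 ? tb_cis : tb_trans)) {
        pos = L - 1;
      } else {
        pos = (int)(unif_rand() * (L - 1));
        if (pos >= L - 1) pos = L - 2;
      }
      int* bits = kind == 0 ? cc : ct;
      bits[g + (size_t)n * pos] ^= 1;
      if (kind == 0) {
        for (int j2 = 0; j2 < n; ++j2)
          childM[g + (size_t)n * j2] = interact_bits(cc + g, ct + j2, L, n, n);
      } else {
        for (int i2 = 0; i2 < n; ++i2)
          childM[i2 + (size_t)n * g] = interact_bits(cc + i2, ct + g, L, n, n);
      }
    }

    Matured mr = mature_eval(childM.data(), n, init_expr.begin(), step_cap,
                             target.begin(), sigma2, false);
    std::copy(childM.begin(), childM.end(), REAL(nM) + (size_t)n * n * k);
    for (int i = 0; i < n; ++i) nexpr(i, k) = mr.repr[i];
    nfit[k] = mr.outcome == 3 ? 0.0 : mr.fit;
    noutcome[k] = mr.outcome; nsteps[k] = mr.steps; nperiod[k] = mr.period;
  }

  return List::create(_["cis"] = ncis, _["trans"] = ntrans, _["M"] = nM,
                      _["fitness"] = nfit, _["expression"] = nexpr,
                      _["outcome"] = noutcome, _["steps"] = nsteps,
                      _["period"] = nperiod, _["uniform_fallback"] = uniform);
}

// Clone every individual, hit each clone with exactly `m` uniformly placed
// bit flips (same placement law as the mutation model), refresh, mature.
// Inputs are untouched; outputs describe the branch population.
// [[Rcpp::export]]
List probe_branch_cpp(IntegerVector cis, IntegerVector trans, NumericVector M,
                      int n, int L, int N, int m, double tb_cis,
                      double tb_trans, IntegerVector init_expr, int step_cap,
                      IntegerVector target, double sigma2) {
  const size_t G = (size_t)n * L;
  NumericVector bM = clone(M);
  IntegerVector bcis = clone(cis), btrans = clone(trans);
  IntegerMatrix expr(n, N);
  NumericVector fit(N);
  IntegerVector outcome(N);
  for (int k = 0; k < N; ++k) {
    int* cc = bcis.begin() + G * k;
    int* ct = btrans.begin() + G * k;
    double* cm = REAL(bM) + (size_t)n * n * k;
    for (int e = 0; e < m; ++e) {
      int reg = (int)(unif_rand() * (2 * n));
      if (reg >= 2 * n) reg = 2 * n - 1;
      int kind = reg / n;
      int g = reg % n;
      int pos;
      if (unif_rand() < (kind == 0 ? tb_cis : tb_trans)) {
        pos = L - 1;
      } else {
        pos = (int)(unif_rand() * (L - 1));
        if (pos >= L - 1) pos = L - 2;
      }
      int* bits = kind == 0 ? cc : ct;
      bits[g + (size_t)n * pos] ^= 1;
      if (kind == 0) {
        for (int j2 = 0; j2 < n; ++j2)
          cm[g + (size_t)n * j2] = interact_bits(cc + g, ct + j2, L, n, n);
      } else {
        for (int i2 = 0; i2 < n; ++i2)
          cm[i2 + (size_t)n * g] = interact_bits(cc + i2, ct + g, L, n, n);
      }
    }
    Matured r = mature_eval(cm, n, init_expr.begin(), step_cap, target.begin(),
                            sigma2, false);
    for (int i = 0; i < n; ++i) expr(i, k) = r.repr[i];
    fit[k] = r.outcome == 3 ? 0.0 : r.fit;
    outcome[k] = r.outcome;
  }
  return List::create(_["cis"] = bcis, _["trans"] = btrans, _["M"] = bM,
                      _["expression"] = expr, _["fitness"] = fit,
                      _["outcome"] = outcome);
}

// Regulation-free baseline: gene states are the genotype; a mutation flips a
// gene state directly; no maturation.  Shares the parent-sampling helper.
// [[Rcpp::export]]
List grnless_generation_cpp(IntegerMatrix states, NumericVector fitness,
                            double mu, IntegerVector target, double sigma2,
                            int zero_policy) {
  int n = states.nrow(), N = states.ncol();
  std::vector<double> cum(N);
  double tot = 0.0;
  for (int k = 0; k < N; ++k) { tot += fitness[k]; cum[k] = tot; }
  if (!(tot > 0)) {
    if (zero_policy == 0)
      stop("all individuals have zero fitness; no parent can be selected");
    for (int k = 0; k < N; ++k) cum[k] = k + 1.0;
  }
  IntegerMatrix ns(n, N);
  NumericVector nf(N);
  for (int k = 0; k < N; ++k) {
    int p = sample_cum(cum);
    for (int i = 0; i < n; ++i) ns(i, k) = states(i, p);
    int nm = (int)R::rpois(mu);
    for (int m = 0; m < nm; ++m) {
      int g = (int)(unif_rand() * n);
      if (g >= n) g = n - 1;
      ns(g, k) ^= 1;
    }
    nf[k] = fit_of(&ns(0, k), target.begin(), n, sigma2);
  }
  return List::create(_["states"] = ns, _["fitness"] = nf);
}

// One '0'/'1' string per individual: per gene the cis bits then the trans bits.
// [[Rcpp::export]]
CharacterVector genome_keys_cpp(IntegerVector cis, IntegerVector trans,
                                int n, int L, int N) {
  const size_t G = (size_t)n * L;
  CharacterVector out(N);
  std::string buf((size_t)2 * n * L, '0');
  for (int k = 0; k < N; ++k) {
    const int* c = cis.begin() + G * k;
    const int* t = trans.begin() + G * k;
    size_t p = 0;
    for (int g = 0; g < n; ++g) {
      for (int l = 0; l < L; ++l) buf[p++] = (char)('0' + c[g + (size_t)n * l]);
      for (int l = 0; l < L; ++l) buf[p++] = (char)('0' + t[g + (size_t)n * l]);
    }
    out[k] = buf;
  }
  return out;
}
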