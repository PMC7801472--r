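// Compiled simulation core. Mirrors the pure-R reference round
// (run_round) draw-for-draw: identical RNG consumption order and
// identical floating-point accumulation (cumulative sums in long double,
// stored as double, matching R's cumsum), so compiled and reference
// trajectories are bit-identical under the same seed.
//
// Draw order per round:
//   partner selection, agents i = 1..N: u1 (error branch); u2 (uniform
//     index if u1 < eps, else weighted inverse-CDF walk over row i)
//   [payoffs and weight updates consume no draws]
//   imitation (average/total rule), agents i = 1..N: u (consider?); if
//     considering: u2 (error?); then u3 (random strategy if error, else
//     candidate walk — over the round's interaction partners by default,
//     over all other agents under the population-wide pool)
//   moran rule instead: u (reproducer walk or uniform), u2 (target),
//     u3 (error?), u4 (random strategy if error)
//
// Every weighted walk falls back to a uniform index (from the same
// deviate) when its total weight is zero: the random-mixing limit once
// all relevant links have decayed to floating-point zero in a
// payoff-free (all-spiteful) population.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// First index (0-based) with cum >= u * total; uniform fallback on a
// non-positive total.
static inline int walk_first(const std::vector<double>& cum, int m, double u) {
  const double total = cum[m - 1];
  if (!(total > 0)) {
    int k = (int)std::floor(u * m);
    return k > m - 1 ? m - 1 : k;
  }
  const double t = u * total;
  for (int k = 0; k < m; ++k)
    if (cum[k] >= t) return k;
  return m - 1;
}

// Map position k among "others of i" (0-based) back to an agent index.
static inline int unskip(int k, int i) { return k < i ? k : k + 1; }

static int choose_host(const NumericMatrix& w, int i, int n, double eps,
                       std::vector<double>& cum) {
  const double u1 = unif_rand();
  if (u1 < eps) {
    const double u2 = unif_rand();
    int k = (int)std::floor(u2 * (n - 1));
    if (k > n - 2) k = n - 2;
    return unskip(k, i);
  }
  const double u2 = unif_rand();
  long double acc = 0.0L;
  int m = 0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    acc += w(i, j);
    cum[m++] = (double)acc;
  }
  return unskip(walk_first(cum, n - 1, u2), i);
}

// Population-wide candidate walk (combined weights, all j != i).
static int choose_candidate_all(const NumericMatrix& w, int i, int n,
                                double u, std::vector<double>& cum) {
  long double acc = 0.0L;
  int m = 0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    acc += w(i, j) + w(j, i);
    cum[m++] = (double)acc;
  }
  return unskip(walk_first(cum, n - 1, u), i);
}

// Partner-pool candidate walk (combined weights over this round's
// deduplicated partner list).
static int choose_candidate_pool(const NumericMatrix& w, int i,
                                 const std::vector<int>& pool, double u,
                                 std::vector<double>& cum) {
  const int m = (int)pool.size();
  long double acc = 0.0L;
  for (int k = 0; k < m; ++k) {
    acc += w(i, pool[k]) + w(pool[k], i);
    cum[k] = (double)acc;
  }
  return pool[walk_first(cum, m, u)];
}

// rule: 0 = average_payoff, 1 = total_payoff, 2 = moran
// [[Rcpp::export]]
List run_rounds_cpp(NumericMatrix w_in, IntegerVector strat_in, int nrounds,
                    double b, double c, double eps, double delta,
                    double Rrate, double lam, double e, int rule,
                    bool discount_all, bool partner_pool) {
  NumericMatrix w = clone(w_in);
  IntegerVector s = clone(strat_in);
  const int n = w.nrow();
  if (n < 2) stop("need at least two agents");
  std::vector<int> visits(n), nint(n), splayed(n), news(n);
  std::vector<double> ptot(n), vpay(n), cum(n);
  std::vector<std::vector<int>> pools(n);
  std::vector<char> seen(n);
  const double keep = 1.0 - delta;

  for (int r = 0; r < nrounds; ++r) {
    for (int i = 0; i < n; ++i) splayed[i] = s[i];

    for (int i = 0; i < n; ++i)
      visits[i] = choose_host(w, i, n, eps, cum);

    for (int i = 0; i < n; ++i) { ptot[i] = 0.0; nint[i] = 0; }
    for (int i = 0; i < n; ++i) {
      const int j = visits[i];
      const double pv = 1.0 - c * s[i] - b * s[j];
      const double ph = 1.0 - c * s[j] - b * s[i];
      vpay[i] = pv;
      ptot[i] += pv; nint[i] += 1;
      ptot[j] += ph; nint[j] += 1;
    }

    // weights decayed past 1e-280 are flushed to exact zero: payoff-free
    // (all-spiteful) populations otherwise decay into subnormal doubles,
    // which cost 10-100x per operation and carry no usable signal
    if (discount_all) {
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
          if (i != j) {
            w(i, j) *= keep;
            if (w(i, j) < 1e-280) w(i, j) = 0.0;
          }
    } else {
      for (int i = 0; i < n; ++i) {
        w(i, visits[i]) *= keep;
        if (w(i, visits[i]) < 1e-280) w(i, visits[i]) = 0.0;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (vpay[i] < 0) stop("negative payoff cannot be reinforced");
      w(i, visits[i]) += Rrate * vpay[i];
    }

    if (rule == 2) {  // moran: one birth-death event
      std::vector<double> fitcum(n);
      long double acc = 0.0L;
      for (int i = 0; i < n; ++i) {
        acc += ptot[i] / nint[i];
        fitcum[i] = (double)acc;
      }
      const double u = unif_rand();
      const int rep = walk_first(fitcum, n, u);
      const double u2 = unif_rand();
      int k = (int)std::floor(u2 * (n - 1));
      if (k > n - 2) k = n - 2;
      const int target = unskip(k, rep);
      const double u3 = unif_rand();
      if (u3 < e) {
        const double u4 = unif_rand();
        s[target] = (u4 < 0.5) ? 0 : 1;
      } else {
        s[target] = s[rep];
      }
    } else {  // per-agent synchronous imitation
      if (partner_pool) {
        // canonical pool order: ascending visitor index, host inserted at
        // the owner's own turn; first-occurrence deduplication
        for (int i = 0; i < n; ++i) pools[i].clear();
        for (int i = 0; i < n; ++i) {
          pools[i].push_back(visits[i]);
          pools[visits[i]].push_back(i);
        }
        for (int i = 0; i < n; ++i) {
          for (int j = 0; j < n; ++j) seen[j] = 0;
          int m = 0;
          for (size_t k = 0; k < pools[i].size(); ++k) {
            const int p = pools[i][k];
            if (!seen[p]) { seen[p] = 1; pools[i][m++] = p; }
          }
          pools[i].resize(m);
        }
      }
      for (int i = 0; i < n; ++i) news[i] = s[i];
      for (int i = 0; i < n; ++i) {
        const double u = unif_rand();
        if (u >= lam) continue;
        const double u2 = unif_rand();
        if (u2 < e) {
          const double u3 = unif_rand();
          news[i] = (u3 < 0.5) ? 0 : 1;
        } else {
          const double u3 = unif_rand();
          const int j = partner_pool
            ? choose_candidate_pool(w, i, pools[i], u3, cum)
            : choose_candidate_all(w, i, n, u3, cum);
          const double vi = (rule == 1) ? ptot[i] : ptot[i] / nint[i];
          const double vj = (rule == 1) ? ptot[j] : ptot[j] / nint[j];
          if (vj > vi) news[i] = splayed[j];
        }
      }
      for (int i = 0; i < n; ++i) s[i] = news[i];
    }
  }

  IntegerVector visits_out(n), nint_out(n), splayed_out(n);
  NumericVector ptot_out(n);
  for (int i = 0; i < n; ++i) {
    visits_out[i] = visits[i] + 1;  // back to 1-based
    nint_out[i] = nint[i];
    splayed_out[i] = splayed[i];
    ptot_out[i] = ptot[i];
  }
  return List::create(_["w"] = w, _["strategies"] = s,
                      _["visits"] = visits_out,
                      _["payoff_total"] = ptot_out,
                      _["n_interactions"] = nint_out,
                      _["strategies_played"] = splayed_out);
}
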