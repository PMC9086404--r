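#include <Rcpp.h>
using namespace Rcpp;

// Trend discretization. For x_i != 0 the relative change (x_{i+1}-x_i)/|x_i|
// is compared against the threshold t (inclusive at +-t unless strict); for
// x_i == 0 the symbol is the sign of x_{i+1}.
static IntegerVector discretize_impl(const NumericVector& x, double t,
                                     bool strict) {
  int n = x.size();
  IntegerVector d(n - 1);
  for (int i = 0; i < n - 1; ++i) {
    if (x[i] == 0.0) {
      d[i] = (x[i + 1] > 0) - (x[i + 1] < 0);
    } else {
      double r = (x[i + 1] - x[i]) / std::fabs(x[i]);
      bool up = strict ? (r > t) : (r >= t);
      bool down = strict ? (r < -t) : (r <= -t);
      d[i] = up ? 1 : (down ? -1 : 0);
    }
  }
  return d;
}

// [[Rcpp::export]]
IntegerVector discretize_cpp(NumericVector x, double t, bool strict) {
  return discretize_impl(x, t, strict);
}

// Score-only local trend score: max over start offsets |o| <= D of the
// maximal (possibly empty) contiguous-window sum of dx[i] * dy[i + o].
static int lt_score_only(const IntegerVector& dx, const IntegerVector& dy,
                         int D) {
  int m = dx.size();
  long best = 0;
  for (int o = -D; o <= D; ++o) {
    int lo = std::max(0, -o), hi = std::min(m - 1, m - 1 - o);
    long S = 0, minS = 0;
    for (int q = lo; q <= hi; ++q) {
      S += (long)dx[q] * dy[q + o];
      if (S - minS > best) best = S - minS;
      if (S < minS) minS = S;
    }
  }
  return (int)best;
}

// Full dynamic program with alignment recovery. Ties among optimal windows
// resolve to the smallest start_x, then start_y, then length. Returned
// starts are 1-based; 0/0/0 encodes the empty alignment.
// [[Rcpp::export]]
List lt_score_cpp(IntegerVector dx, IntegerVector dy, int D) {
  int m = dx.size();
  long best = 0;
  int bi = 0, bj = 0, bk = 0;
  for (int o = -D; o <= D; ++o) {
    int lo = std::max(0, -o), hi = std::min(m - 1, m - 1 - o);
    if (lo > hi) continue;
    long S = 0, minS = 0;
    int minIdx = lo - 1;  // window start = minIdx + 1 (0-based element index)
    for (int q = lo; q <= hi; ++q) {
      S += (long)dx[q] * dy[q + o];
      long cand = S - minS;
      if (cand > 0) {
        int si = minIdx + 2;  // 1-based start in dx
        int sj = si + o;
        int k = q - minIdx;
        bool take = cand > best;
        if (!take && cand == best) {
          take = (si < bi) || (si == bi && (sj < bj || (sj == bj && k < bk)));
        }
        if (take) {
          best = cand;
          bi = si;
          bj = sj;
          bk = k;
        }
      }
      if (S < minS) {
        minS = S;
        minIdx = q;
      }
    }
  }
  return List::create(_["score"] = (int)best, _["start_x"] = bi,
                      _["start_y"] = bj, _["length"] = bk);
}

// Permutation null scores: shuffle the numeric values of y (R RNG),
// re-discretize, re-score against the fixed trend sequence dx.
// [[Rcpp::export]]
IntegerVector perm_scores_cpp(IntegerVector dx, NumericVector y, double t,
                              bool strict, int D, int n_perm) {
  IntegerVector out(n_perm);
  int n = y.size();
  for (int p = 0; p < n_perm; ++p) {
    NumericVector yp = Rcpp::sample(y, n, false);
    IntegerVector dyp = discretize_impl(yp, t, strict);
    out[p] = lt_score_only(dx, dyp, D);
  }
  return out;
}

// Permutation null scores, symbol variant: shuffle the trend symbols of y
// directly (R RNG) and re-score against dx.
// [[Rcpp::export]]
IntegerVector perm_scores_sym_cpp(IntegerVector dx, IntegerVector dy,
                                  int D, int n_perm) {
  IntegerVector out(n_perm);
  int m = dy.size();
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector dyp = Rcpp::sample(dy, m, false);
    out[p] = lt_score_only(dx, dyp, D);
  }
  return out;
}

// Simulate a stationary symmetric two-state trend chain on {-1, +1} with
// stay probability a, started from its stationary law (1/2, 1/2). R RNG.
// [[Rcpp::export]]
IntegerVector sim_chain2_cpp(int m, double a) {
  IntegerVector d(m);
  d[0] = unif_rand() < 0.5 ? 1 : -1;
  for (int i = 1; i < m; ++i) d[i] = unif_rand() < a ? d[i - 1] : -d[i - 1];
  return d;
}

// Simulate a stationary symmetric three-state trend chain on {-1, 0, +1}
// with stay probability b from +-1, flip probability c, and exit probability
// d from 0 to each of +-1; started from the stationary law.
// [[Rcpp::export]]
IntegerVector sim_chain3_cpp(int m, double b, double c, double d) {
  double phi1 = d / (1.0 - b - c + 2.0 * d);
  IntegerVector out(m);
  double u = unif_rand();
  out[0] = u < phi1 ? 1 : (u < 2 * phi1 ? -1 : 0);
  for (int i = 1; i < m; ++i) {
    double v = unif_rand();
    int prev = out[i - 1];
    if (prev == 0) {
      out[i] = v < d ? 1 : (v < 2 * d ? -1 : 0);
    } else {
      out[i] = v < b ? prev : (v < b + c ? -prev : 0);
    }
  }
  return out;
}
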