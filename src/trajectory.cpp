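#include <Rcpp.h>
using namespace Rcpp;

// Deterministic one-generation selection map: frequency after selection given
// frequency x before selection, genotype fitnesses (1, 1+s2, 1+s1).
static double fwd_map(double x, double s1, double s2) {
  double num = x * (1.0 + s1 * x + s2 * (1.0 - x));
  double den = 1.0 + s1 * x * x + 2.0 * s2 * x * (1.0 - x);
  return num / den;
}

// Inverse of fwd_map on [0,1]: closed-form quadratic for genic selection
// (s1 = 2 s2 > 0), monotone bisection otherwise.
static double sel_inverse(double y, double s1, double s2) {
  if (y <= 0.0) return 0.0;
  if (y >= 1.0) return 1.0;
  if (std::fabs(s1) < 1e-14 && std::fabs(s2) < 1e-14) return y;
  if (std::fabs(s1 - 2.0 * s2) < 1e-12 && s2 > 1e-14) {
    double sig = s2;
    double b = 1.0 + sig - 2.0 * sig * y;
    return (-b + std::sqrt(b * b + 4.0 * sig * y)) / (2.0 * sig);
  }
  double lo = 0.0, hi = 1.0;
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + hi);
    if (fwd_map(mid, s1, s2) < y) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double fwd_map_cpp(double x, double s1, double s2) { return fwd_map(x, s1, s2); }

// [[Rcpp::export]]
double sel_inverse_cpp(double y, double s1, double s2) {
  return sel_inverse(y, s1, s2);
}

// Backward Wright-Fisher trajectory sampler: from I0 copies at present,
// draw I_t ~ Binomial(2 N_t, Y'_{t-1}) until loss, Y' the pre-selection
// frequency whose post-selection frequency equals I_{t-1}/(2 N_{t-1}).
// [[Rcpp::export]]
List traj_sample_cpp(int I0, double s1, double s2, NumericVector N,
                     int tmax) {
  std::vector<int> I;
  I.reserve(1024);
  I.push_back(I0);
  double logPB = 0.0;
  int t = 0;
  while (I[t] > 0) {
    if (t >= tmax)
      return List::create(_["I"] = IntegerVector(I.begin(), I.end()),
                          _["logPB"] = logPB, _["status"] = "tmax");
    double twoNprev = 2.0 * N[t];
    double twoNcur = 2.0 * N[t + 1];
    double y = I[t] / twoNprev;
    double yp = sel_inverse(y, s1, s2);
    // quantile-transform draw: exactly one uniform per generation keeps
    // random streams aligned across runs (common random numbers)
    int draw = (int) R::qbinom(unif_rand(), std::floor(twoNcur + 0.5), yp,
                               1, 0);
    logPB += R::dbinom(draw, std::floor(twoNcur + 0.5), yp, 1);
    I.push_back(draw);
    ++t;
  }
  return List::create(_["I"] = IntegerVector(I.begin(), I.end()),
                      _["logPB"] = logPB, _["status"] = "ok");
}

// Forward log-probability of a path I[0..T] (I[T] = 0) under the
// Wright-Fisher model with selection: product over t = T..1 of
// Binomial(I_{t-1}; 2 N_{t-1}, X'_t); the t = T factor is 1 iff the path
// starts from a single founding copy.
// [[Rcpp::export]]
double traj_forward_logprob_cpp(IntegerVector I, double s1, double s2,
                                NumericVector N) {
  int T = I.size() - 1;
  if (I[T] != 0) stop("trajectory must end at loss (I_T = 0)");
  if (I[T - 1] != 1) return R_NegInf;
  double logPF = 0.0;
  for (int t = T - 1; t >= 1; --t) {
    double twoN = std::floor(2.0 * N[t] + 0.5);
    double xp = fwd_map(I[t] / twoN, s1, s2);
    double twoNprev = std::floor(2.0 * N[t - 1] + 0.5);
    logPF += R::dbinom(I[t - 1], twoNprev, xp, 1);
    if (!R_FINITE(logPF)) return R_NegInf;
  }
  return logPF;
}

// Forward Wright-Fisher simulation of R replicate paths from a single copy,
// returning the copy-number matrix (replicates x generations). Used by the
// sweep simulator and by forward-simulation oracle tests.
// [[Rcpp::export]]
IntegerMatrix wf_forward_batch_cpp(int R, double s1, double s2,
                                   NumericVector N, int horizon) {
  IntegerMatrix out(R, horizon + 1);
  for (int r = 0; r < R; ++r) {
    int cur = 1;
    out(r, 0) = cur;
    for (int t = 1; t <= horizon; ++t) {
      if (cur > 0) {
        double twoNprev = std::floor(2.0 * N[t - 1] + 0.5);
        double twoN = std::floor(2.0 * N[t] + 0.5);
        double xp = fwd_map(cur / twoNprev, s1, s2);
        cur = (int) R::rbinom(twoN, xp);
      }
      out(r, t) = cur;
    }
  }
  return out;
}
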