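#include <Rcpp.h>
using namespace Rcpp;

// Sequential importance sampler over genealogical histories of a coded
// sample configuration, conditional on one allele-frequency trajectory.
//
// State: distinct coded haplotypes (R1, R2, M...) with multiplicities.
// Events: coalescence within a type, mutation shift / merge, recombination
// moves that change one recombination coordinate (extensions past the
// current breakpoint, or shrinks that also shed mutation coordinates
// outside the new region). Per-step importance weight: hbar / (2 gamma).
//
// Recombination terms are aggregated per source type via prefix/suffix
// sums over the targets (the target distribution factorizes over sides);
// the per-generation survival columns are cached lazily and shared across
// the K paths of a batch, and the concrete target is sampled only when a
// recombination move is chosen.

struct Hap {
  int R1, R2;
  std::vector<int> M;
  bool operator==(const Hap &o) const {
    return R1 == o.R1 && R2 == o.R2 && M == o.M;
  }
};

struct Move {
  double w;      // term in hbar
  int kind;      // 0 coal, 1 shift, 2 merge, 3 recomb (target sampled later)
  int i;         // acting type index
  int j;         // partner type index (merge) or -1
};

class Engine {
public:
  // trajectory arrays indexed by generation v = 0 .. Tend (Tend = T - 1)
  NumericVector invI, X, Ct;
  int Tend;
  double theta, rho, N0, gTot;
  int mL, mR, j0;                 // j0 = mutant column (1-based)
  NumericVector gL, gR, bpL, bpR; // gL[a] = Morgans spanned by a SNPs left

  // lazy per-generation columns, per side with m SNPs:
  //   [0 .. m+1]        survival suffix SL(a), SL(m+1) = 0
  //   [m+2 .. 2m+3]     suffix sum of dL(a) * g(a)
  //   [2m+4 .. 3m+3]    prefix sum of bp(a) * dL(a),   a = 0 .. m-1
  //   [3m+4 .. 4m+3]    prefix sum of bp(a) * dL(a) * g(a)
  std::vector<std::vector<double>> cacheL, cacheR;
  // scratch buffers for target sampling (reused across events)
  std::vector<double> tw;
  std::vector<int> tside, tnewR, ntL, ntR;

  const std::vector<double> &colSide(int v, bool left) {
    std::vector<double> &c = left ? cacheL[v] : cacheR[v];
    if (c.empty()) {
      int m = left ? mL : mR;
      const NumericVector &g = left ? gL : gR;
      const NumericVector &bp = left ? bpL : bpR;
      c.resize(4 * m + 4);
      for (int a = 0; a <= m; ++a) c[a] = std::exp(-g[a] * Ct[v]);
      c[m + 1] = 0.0;
      c[2 * m + 3] = 0.0;
      for (int a = m; a >= 0; --a)
        c[m + 2 + a] = c[m + 3 + a] + (c[a] - c[a + 1]) * g[a];
      double pd = 0.0, pgd = 0.0;
      for (int a = 0; a < m; ++a) {
        double d = c[a] - c[a + 1];
        pd += bp[a] * d;
        pgd += bp[a] * d * g[a];
        c[2 * m + 4 + a] = pd;
        c[3 * m + 4 + a] = pgd;
      }
    }
    return c;
  }
  double beta(const Hap &h) const {
    return (gL[h.R1] + gR[h.R2]) / gTot;
  }
};

// does oM equal hM restricted to columns in [lo, hi] (order preserved)?
static bool matches_filtered(const std::vector<int> &hM,
                             const std::vector<int> &oM, int lo, int hi) {
  size_t q = 0;
  for (size_t i = 0; i < hM.size(); ++i) {
    int m = hM[i];
    if (m >= lo && m <= hi) {
      if (q >= oM.size() || oM[q] != m) return false;
      ++q;
    }
  }
  return q == oM.size();
}

// Aggregated recombination term of hbar for source type k: sum over all
// single-coordinate targets t (extensions at the current breakpoint
// interval, shrinks at the interval of the new, smaller coordinate) of
// beta_t * rho * (n_t + 1) * p(k -> t); raw weights r(interval) *
// P_[t](v) * X_v, p normalized over both directions and sides.
static double recomb_term(Engine &E, const std::vector<Hap> &types,
                          const std::vector<int> &mult, int k, int v) {
  const Hap &h = types[k];
  const std::vector<double> &cl = E.colSide(v, true);
  const std::vector<double> &cr = E.colSide(v, false);
  int oPdL = 2 * E.mL + 4, oPgdL = 3 * E.mL + 4;
  int oPdR = 2 * E.mR + 4, oPgdR = 3 * E.mR + 4;
  double dR_h = cr[h.R2] - cr[h.R2 + 1];
  double dL_h = cl[h.R1] - cl[h.R1 + 1];
  double fL = h.R1 < E.mL ? E.bpL[h.R1] * dR_h * E.X[v] : 0.0;
  double fR = h.R2 < E.mR ? E.bpR[h.R2] * dL_h * E.X[v] : 0.0;
  double sL = h.R1 > 0 ? dR_h * E.X[v] : 0.0;   // left shrinks
  double sR = h.R2 > 0 ? dL_h * E.X[v] : 0.0;   // right shrinks
  double psum = fL * cl[h.R1 + 1] + fR * cr[h.R2 + 1];
  if (sL > 0) psum += sL * cl[oPdL + h.R1 - 1];
  if (sR > 0) psum += sR * cr[oPdR + h.R2 - 1];
  if (!(psum > 0.0)) return 0.0;
  // baseline (n_t = 0): beta-weighted total of the raw weights
  double acc = 0.0;
  if (fL > 0)
    acc += fL * (cl[E.mL + 3 + h.R1] + E.gR[h.R2] * cl[h.R1 + 1]);
  if (fR > 0)
    acc += fR * (cr[E.mR + 3 + h.R2] + E.gL[h.R1] * cr[h.R2 + 1]);
  if (sL > 0)
    acc += sL * (cl[oPgdL + h.R1 - 1] + E.gR[h.R2] * cl[oPdL + h.R1 - 1]);
  if (sR > 0)
    acc += sR * (cr[oPgdR + h.R2 - 1] + E.gL[h.R1] * cr[oPdR + h.R2 - 1]);
  acc /= E.gTot;
  // add n_t * beta_t * raw_t for targets already present in the sample
  int d = (int) types.size();
  int lo = E.j0 - h.R1, hi = E.j0 + h.R2;
  for (int j = 0; j < d; ++j) {
    if (j == k) continue;
    const Hap &o = types[j];
    double raw = 0.0;
    if (o.R2 == h.R2 && o.R1 != h.R1) {
      if (o.R1 > h.R1) {
        if (fL > 0 && o.M == h.M) raw = fL * (cl[o.R1] - cl[o.R1 + 1]);
      } else if (sL > 0 &&
                 matches_filtered(h.M, o.M, E.j0 - o.R1, hi)) {
        raw = E.bpL[o.R1] * sL * (cl[o.R1] - cl[o.R1 + 1]);
      }
    } else if (o.R1 == h.R1 && o.R2 != h.R2) {
      if (o.R2 > h.R2) {
        if (fR > 0 && o.M == h.M) raw = fR * (cr[o.R2] - cr[o.R2 + 1]);
      } else if (sR > 0 &&
                 matches_filtered(h.M, o.M, lo, E.j0 + o.R2)) {
        raw = E.bpR[o.R2] * sR * (cr[o.R2] - cr[o.R2 + 1]);
      }
    }
    if (raw > 0)
      acc += mult[j] * ((E.gL[o.R1] + E.gR[o.R2]) / E.gTot) * raw;
  }
  return E.rho * acc / psum;
}

// smallest a in [aLo, aHi] with suffix[aLo] - suffix[a + 1] >= r
// (suffix non-increasing in a)
static int search_suffix(const double *suffix, int aLo, int aHi, double r) {
  double target = suffix[aLo] - r;
  int lo = aLo, hi = aHi;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (suffix[mid + 1] <= target) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// smallest a in [0, aHi] with prefix[a] >= r (prefix non-decreasing)
static int search_prefix(const double *prefix, int aHi, double r) {
  int lo = 0, hi = aHi;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (prefix[mid] >= r) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// Sample the concrete target for a chosen recombination move of type k,
// with probability proportional to beta_t * (n_t + 1) * raw_t. The base
// (n_t = 0) mass decomposes into eight components with closed-form
// prefix/suffix CDFs in the cached columns; targets already present in
// the sample contribute an O(d) correction list.
static void sample_recomb_target(Engine &E, const std::vector<Hap> &types,
                                 const std::vector<int> &mult, int k, int v,
                                 int &side, int &newR) {
  const Hap &h = types[k];
  const std::vector<double> &cl = E.colSide(v, true);
  const std::vector<double> &cr = E.colSide(v, false);
  const double *SdL = cl.data(), *SgdL = cl.data() + E.mL + 2;
  const double *PdL = cl.data() + 2 * E.mL + 4, *PgdL = cl.data() + 3 * E.mL + 4;
  const double *SdR = cr.data(), *SgdR = cr.data() + E.mR + 2;
  const double *PdR = cr.data() + 2 * E.mR + 4, *PgdR = cr.data() + 3 * E.mR + 4;
  int d = (int) types.size();
  double dR_h = cr[h.R2] - cr[h.R2 + 1];
  double dL_h = cl[h.R1] - cl[h.R1 + 1];
  double fL = h.R1 < E.mL ? E.bpL[h.R1] * dR_h * E.X[v] : 0.0;
  double fR = h.R2 < E.mR ? E.bpR[h.R2] * dL_h * E.X[v] : 0.0;
  double sL = h.R1 > 0 ? dR_h * E.X[v] : 0.0;
  double sR = h.R2 > 0 ? dL_h * E.X[v] : 0.0;
  // base-mass components (all divided by gTot implicitly; scale cancels)
  double m0 = fL > 0 ? fL * SgdL[h.R1 + 1] : 0.0;                // ext L, g
  double m1 = fL > 0 ? fL * E.gR[h.R2] * SdL[h.R1 + 1] : 0.0;    // ext L, c
  double m2 = fR > 0 ? fR * SgdR[h.R2 + 1] : 0.0;                // ext R, g
  double m3 = fR > 0 ? fR * E.gL[h.R1] * SdR[h.R2 + 1] : 0.0;    // ext R, c
  double m4 = sL > 0 ? sL * PgdL[h.R1 - 1] : 0.0;                // shr L, g
  double m5 = sL > 0 ? sL * E.gR[h.R2] * PdL[h.R1 - 1] : 0.0;    // shr L, c
  double m6 = sR > 0 ? sR * PgdR[h.R2 - 1] : 0.0;                // shr R, g
  double m7 = sR > 0 ? sR * E.gL[h.R1] * PdR[h.R2 - 1] : 0.0;    // shr R, c
  // extra mass n_t * beta_t * raw_t for targets already in the sample
  std::vector<double> &xw = E.tw;
  std::vector<int> &xs = E.tside, &xn = E.tnewR;
  xw.clear(); xs.clear(); xn.clear();
  int lo = E.j0 - h.R1, hi = E.j0 + h.R2;
  double extra = 0.0;
  for (int j = 0; j < d; ++j) {
    if (j == k) continue;
    const Hap &o = types[j];
    double raw = 0.0;
    if (o.R2 == h.R2 && o.R1 != h.R1) {
      if (o.R1 > h.R1) {
        if (fL > 0 && o.M == h.M) raw = fL * (cl[o.R1] - cl[o.R1 + 1]);
      } else if (sL > 0 && matches_filtered(h.M, o.M, E.j0 - o.R1, hi)) {
        raw = E.bpL[o.R1] * sL * (cl[o.R1] - cl[o.R1 + 1]);
      }
      if (raw > 0) {
        double xx = mult[j] * (E.gL[o.R1] + E.gR[o.R2]) * raw;
        xw.push_back(xx); xs.push_back(0); xn.push_back(o.R1);
        extra += xx;
      }
    } else if (o.R1 == h.R1 && o.R2 != h.R2) {
      if (o.R2 > h.R2) {
        if (fR > 0 && o.M == h.M) raw = fR * (cr[o.R2] - cr[o.R2 + 1]);
      } else if (sR > 0 && matches_filtered(h.M, o.M, lo, E.j0 + o.R2)) {
        raw = E.bpR[o.R2] * sR * (cr[o.R2] - cr[o.R2 + 1]);
      }
      if (raw > 0) {
        double xx = mult[j] * (E.gL[o.R1] + E.gR[o.R2]) * raw;
        xw.push_back(xx); xs.push_back(1); xn.push_back(o.R2);
        extra += xx;
      }
    }
  }
  double tot = m0 + m1 + m2 + m3 + m4 + m5 + m6 + m7 + extra;
  double u = unif_rand() * tot;
  if (u < m0) {
    side = 0; newR = search_suffix(SgdL, h.R1 + 1, E.mL, u / fL); return;
  }
  u -= m0;
  if (u < m1) {
    side = 0;
    newR = search_suffix(SdL, h.R1 + 1, E.mL, u / (fL * E.gR[h.R2]));
    return;
  }
  u -= m1;
  if (u < m2) {
    side = 1; newR = search_suffix(SgdR, h.R2 + 1, E.mR, u / fR); return;
  }
  u -= m2;
  if (u < m3) {
    side = 1;
    newR = search_suffix(SdR, h.R2 + 1, E.mR, u / (fR * E.gL[h.R1]));
    return;
  }
  u -= m3;
  if (u < m4) {
    side = 0; newR = search_prefix(PgdL, h.R1 - 1, u / sL); return;
  }
  u -= m4;
  if (u < m5) {
    side = 0; newR = search_prefix(PdL, h.R1 - 1, u / (sL * E.gR[h.R2]));
    return;
  }
  u -= m5;
  if (u < m6) {
    side = 1; newR = search_prefix(PgdR, h.R2 - 1, u / sR); return;
  }
  u -= m6;
  if (u < m7) {
    side = 1; newR = search_prefix(PdR, h.R2 - 1, u / (sR * E.gL[h.R1]));
    return;
  }
  u -= m7;
  for (size_t q = 0; q < xw.size(); ++q) {
    if (u < xw[q]) { side = xs[q]; newR = xn[q]; return; }
    u -= xw[q];
  }
  // numerical fallback: last extra target or the far extension
  if (!xw.empty()) { side = xs.back(); newR = xn.back(); return; }
  if (fL > 0) { side = 0; newR = E.mL; return; }
  side = 1; newR = E.mR;
}

// Enumerate the proposal terms of hbar (recombination aggregated per type).
static double enumerate_moves(Engine &E, const std::vector<Hap> &types,
                              const std::vector<int> &mult, int v,
                              std::vector<Move> &moves) {
  moves.clear();
  int d = (int) types.size();
  int n = 0;
  for (int k = 0; k < d; ++k) n += mult[k];
  double invLX = 2.0 * E.N0 * E.invI[v];
  double hbar = 0.0;
  for (int k = 0; k < d; ++k) {
    if (mult[k] >= 2) {
      double w = (double) n * (mult[k] - 1) * invLX;
      moves.push_back({w, 0, k, -1});
      hbar += w;
    }
  }
  if (E.theta > 0.0) {
    for (int k = 0; k < d; ++k) {
      if (mult[k] != 1 || types[k].M.empty()) continue;
      const Hap &h = types[k];
      int j = -1;
      for (int q = 0; q < d; ++q) {
        const Hap &o = types[q];
        if (q != k && o.R1 == h.R1 && o.R2 == h.R2 &&
            o.M.size() + 1 == h.M.size() &&
            std::equal(h.M.begin() + 1, h.M.end(), o.M.begin())) {
          j = q; break;
        }
      }
      if (j < 0) {
        double w = E.theta * E.beta(types[k]);
        moves.push_back({w, 1, k, -1});
        hbar += w;
      } else {
        double w = E.theta * (mult[j] + 1) * E.beta(types[j]);
        moves.push_back({w, 2, k, j});
        hbar += w;
      }
    }
  }
  if (E.rho > 0.0) {
    for (int k = 0; k < d; ++k) {
      double w = recomb_term(E, types, mult, k, v);
      if (w > 0.0) {
        moves.push_back({w, 3, k, -1});
        hbar += w;
      }
    }
  }
  return hbar;
}

static double gamma_rate(const Engine &E, const std::vector<Hap> &types,
                         const std::vector<int> &mult, int v) {
  int n = 0; double sumBeta = 0.0;
  for (size_t k = 0; k < types.size(); ++k) {
    n += mult[k];
    sumBeta += mult[k] * E.beta(types[k]);
  }
  double invLX = 2.0 * E.N0 * E.invI[v];
  return 0.5 * n * (n - 1) * invLX + 0.5 * (E.theta + E.rho) * sumBeta;
}

static void apply_move(Engine &E, std::vector<Hap> &types,
                       std::vector<int> &mult, const Move &mv, int v) {
  if (mv.kind == 0) {
    mult[mv.i] -= 1;
  } else if (mv.kind == 1) {
    types[mv.i].M.erase(types[mv.i].M.begin());
  } else if (mv.kind == 2) {
    int j = mv.j;
    mult[j] += 1;
    types.erase(types.begin() + mv.i);
    mult.erase(mult.begin() + mv.i);
  } else {
    int side, newR;
    sample_recomb_target(E, types, mult, mv.i, v, side, newR);
    Hap tgt = types[mv.i];
    if (side == 0) tgt.R1 = newR; else tgt.R2 = newR;
    if (!tgt.M.empty()) {
      int lo = E.j0 - tgt.R1, hi = E.j0 + tgt.R2;
      std::vector<int> keep;
      for (size_t q = 0; q < tgt.M.size(); ++q)
        if (tgt.M[q] >= lo && tgt.M[q] <= hi) keep.push_back(tgt.M[q]);
      tgt.M.swap(keep);
    }
    mult[mv.i] -= 1;
    int removed = mult[mv.i] == 0 ? mv.i : -1;
    int jt = -1;
    for (size_t q = 0; q < types.size(); ++q)
      if (types[q] == tgt) { jt = (int) q; break; }
    if (jt >= 0) mult[jt] += 1;
    else { types.push_back(tgt); mult.push_back(1); }
    if (removed >= 0) {
      types.erase(types.begin() + removed);
      mult.erase(mult.begin() + removed);
    }
  }
}

static Engine make_engine(NumericVector invI, NumericVector X,
                          NumericVector Ct, double theta, double rho,
                          double N0, int mL, int mR, int j0,
                          NumericVector gL, NumericVector gR,
                          NumericVector bpL, NumericVector bpR,
                          double gTot) {
  Engine E;
  E.invI = invI; E.X = X; E.Ct = Ct; E.Tend = invI.size() - 1;
  E.theta = theta; E.rho = rho; E.N0 = N0; E.gTot = gTot;
  E.mL = mL; E.mR = mR; E.j0 = j0;
  E.gL = gL; E.gR = gR; E.bpL = bpL; E.bpR = bpR;
  E.cacheL.assign(E.Tend + 1, std::vector<double>());
  E.cacheR.assign(E.Tend + 1, std::vector<double>());
  return E;
}

static std::vector<Hap> parse_types(List typesR) {
  std::vector<Hap> types;
  for (int k = 0; k < typesR.size(); ++k) {
    IntegerVector tv = typesR[k];
    Hap h; h.R1 = tv[0]; h.R2 = tv[1];
    for (int q = 2; q < tv.size(); ++q) h.M.push_back(tv[q]);
    types.push_back(h);
  }
  return types;
}

// statuses: 0 absorbed, 1 beyond trajectory, 2 dead end, 3 event-cap
// [[Rcpp::export]]
List genealogy_batch_cpp(List typesR, IntegerVector multR,
                         NumericVector invI, NumericVector X,
                         NumericVector Ct, double theta, double rho,
                         double N0, int mL, int mR, int j0,
                         NumericVector gL, NumericVector gR,
                         NumericVector bpL, NumericVector bpR,
                         double gTot, int K, int maxEvents) {
  Engine E = make_engine(invI, X, Ct, theta, rho, N0, mL, mR, j0, gL, gR,
                         bpL, bpR, gTot);
  std::vector<Hap> types0 = parse_types(typesR);
  std::vector<int> mult0(multR.begin(), multR.end());

  NumericVector logw(K);
  IntegerVector status(K), nev(K);
  std::vector<Move> moves;
  moves.reserve(64);

  for (int path = 0; path < K; ++path) {
    std::vector<Hap> types = types0;
    std::vector<int> mult = mult0;
    double lw = 0.0;
    int st = -1, events = 0, t = 0;
    while (true) {
      // absorbed at the founder singleton?
      if (types.size() == 1 && mult[0] == 1 && types[0].R1 == mL &&
          types[0].R2 == mR && types[0].M.empty()) { st = 0; break; }
      if (events >= maxEvents) { st = 3; break; }
      // waiting time: per-generation Bernoulli with hazard gamma / (2 N0)
      int n = 0; double sumBeta = 0.0;
      for (size_t k = 0; k < types.size(); ++k) {
        n += mult[k];
        sumBeta += mult[k] * E.beta(types[k]);
      }
      double hb = 0.5 * n * (n - 1);
      double hm = (theta + rho) * sumBeta / (4.0 * N0);
      int v = -1;
      if (hb == 0.0) {
        // single lineage: constant hazard, jump geometrically
        if (hm > 0.0 && t < E.Tend) {
          double hz = hm > 1.0 ? 1.0 : hm;
          int jump = 1 + (int) R::rgeom(hz);
          if (t + jump <= E.Tend) v = t + jump;
        }
      } else {
        for (int u = t + 1; u <= E.Tend; ++u) {
          double hz = hb * E.invI[u] + hm;
          if (hz > 1.0) hz = 1.0;
          if (unif_rand() < hz) { v = u; break; }
        }
      }
      if (v < 0) { st = 1; break; } // beyond the trajectory end
      double hbar = enumerate_moves(E, types, mult, v, moves);
      if (!(hbar > 0.0)) { st = 2; break; }
      double g = gamma_rate(E, types, mult, v);
      lw += std::log(hbar) - std::log(2.0 * g);
      double u = unif_rand() * hbar, acc = 0.0;
      size_t pick = moves.size() - 1;
      for (size_t q = 0; q < moves.size(); ++q) {
        acc += moves[q].w;
        if (u <= acc) { pick = q; break; }
      }
      apply_move(E, types, mult, moves[pick], v);
      ++events;
      t = v;
    }
    logw[path] = (st == 0) ? lw : R_NegInf;
    status[path] = st;
    nev[path] = events;
  }
  return List::create(_["logWeight"] = logw, _["status"] = status,
                      _["events"] = nev);
}

// Debug/cross-check: hbar and gamma for a configuration at generation v.
// [[Rcpp::export]]
List rates_debug_cpp(List typesR, IntegerVector multR, int v,
                     NumericVector invI, NumericVector X, NumericVector Ct,
                     double theta, double rho, double N0, int mL, int mR,
                     int j0, NumericVector gL, NumericVector gR,
                     NumericVector bpL, NumericVector bpR, double gTot) {
  Engine E = make_engine(invI, X, Ct, theta, rho, N0, mL, mR, j0, gL, gR,
                         bpL, bpR, gTot);
  std::vector<Hap> types = parse_types(typesR);
  std::vector<int> mult(multR.begin(), multR.end());
  std::vector<Move> moves;
  double hbar = enumerate_moves(E, types, mult, v, moves);
  double g = gamma_rate(E, types, mult, v);
  return List::create(_["hbar"] = hbar, _["gamma"] = g);
}
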