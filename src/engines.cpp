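// Compiled single-realisation engines for the tau-leap, SBS, SBS-DA and
// UBTL solvers.  These mirror the R reference implementations statement by
// statement (same arithmetic order, same RNG call order via R's RNG), so a
// run with the same seed is bit-identical to the R path; the R functions
// remain the documented reference and the test oracle.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int N, M;
  std::vector<int> orders;     // N x M column-major
  std::vector<double> nuEff;   // N x M column-major
  std::vector<double> c;
  std::vector<double> fact;    // factorial(m) per (i,j) entry handled inline
  int ord(int i, int j) const { return orders[i + (size_t)j * N]; }
  double nu(int i, int j) const { return nuEff[i + (size_t)j * N]; }
};

Model makeModel(const IntegerMatrix& orders, const NumericMatrix& nuEff,
                const NumericVector& c) {
  Model m;
  m.N = orders.nrow(); m.M = orders.ncol();
  m.orders.assign(orders.begin(), orders.end());
  m.nuEff.assign(nuEff.begin(), nuEff.end());
  m.c.assign(c.begin(), c.end());
  return m;
}

// mass-action propensities over real states; mirrors .makeEvaluators()$prop
void propEval(const Model& md, const double* x, double* a) {
  for (int j = 0; j < md.M; ++j) a[j] = md.c[j];
  for (int j = 0; j < md.M; ++j) {
    for (int i = 0; i < md.N; ++i) {
      int m = md.ord(i, j);
      if (m == 0) continue;
      double v = 1.0;
      for (int l = 0; l < m; ++l) v *= (x[i] - l);
      v /= R::gammafn(m + 1.0);
      a[j] *= v;
    }
  }
  for (int j = 0; j < md.M; ++j) if (a[j] < 0) a[j] = 0;
}

void driftEval(const Model& md, const double* x, double* d,
               std::vector<double>& scratch) {
  propEval(md, x, scratch.data());
  for (int i = 0; i < md.N; ++i) d[i] = 0.0;
  for (int j = 0; j < md.M; ++j)
    for (int i = 0; i < md.N; ++i) d[i] += md.nu(i, j) * scratch[j];
}

// modified midpoint stages; returns false when a stage leaves the
// admissible region (population states only).  `drift0` optionally
// supplies the shared start-state drift (one evaluation per step).
bool mmpStages(const Model& md, const double* x0, double tau, int nSub,
               std::vector<double>& stages, bool checkNonneg,
               const double* drift0 = nullptr) {
  int N = md.N;
  double h = tau / nSub;
  double slack = -R_PosInf;
  if (checkNonneg) {
    double mx = 0.0;
    for (int i = 0; i < N; ++i) mx = std::max(mx, std::fabs(x0[i]));
    slack = -1e-9 * (1 + mx);
  }
  stages.assign((size_t)(nSub + 1) * N, 0.0);
  std::vector<double> d(N), scr(md.M);
  std::vector<double> z0(x0, x0 + N), z1(N), z2(N);
  for (int i = 0; i < N; ++i) stages[i] = x0[i];
  if (drift0) for (int i = 0; i < N; ++i) d[i] = drift0[i];
  else driftEval(md, z0.data(), d.data(), scr);
  for (int i = 0; i < N; ++i) {
    z1[i] = z0[i] + h * d[i];
    if (!(z1[i] >= slack) || !std::isfinite(z1[i])) return false;
  }
  for (int i = 0; i < N; ++i) stages[(size_t)1 * N + i] = z1[i];
  for (int m = 1; m < nSub; ++m) {
    driftEval(md, z1.data(), d.data(), scr);
    for (int i = 0; i < N; ++i) {
      z2[i] = z0[i] + 2 * h * d[i];
      if (!(z2[i] >= slack) || !std::isfinite(z2[i])) return false;
    }
    for (int i = 0; i < N; ++i) stages[(size_t)(m + 1) * N + i] = z2[i];
    z0 = z1; z1 = z2;
  }
  return true;
}

// per-step propensity integral (composite trapezoid on raw stages);
// mirrors .propIntegral
bool propIntegral(const Model& md, const double* x, double tau, int nSub,
                  std::vector<double>& out, const double* drift0) {
  out.assign(md.M, 0.0);
  if (tau == 0) return true;
  std::vector<double> stages;
  if (!mmpStages(md, x, tau, nSub, stages, true, drift0)) return false;
  double h = tau / nSub;
  std::vector<double> a0(md.M), an(md.M), am(md.M);
  propEval(md, &stages[0], a0.data());
  propEval(md, &stages[(size_t)nSub * md.N], an.data());
  for (int j = 0; j < md.M; ++j) out[j] = 0.5 * (a0[j] + an[j]);
  for (int m = 1; m < nSub; ++m) {
    propEval(md, &stages[(size_t)m * md.N], am.data());
    for (int j = 0; j < md.M; ++j) out[j] += am[j];
  }
  for (int j = 0; j < md.M; ++j) {
    out[j] *= h;
    if (out[j] < 0) out[j] = 0;
  }
  return true;
}

// reaction-coupling matrix f[j][jp]; mirrors reactionCouplingMatrix()
void couplingMatrix(const Model& md, const double* x,
                    std::vector<double>& f) {
  int N = md.N, M = md.M;
  std::vector<double> dA((size_t)M * N, 0.0);   // dA[j + M*i]
  for (int j = 0; j < M; ++j) {
    for (int i = 0; i < N; ++i) {
      if (md.ord(i, j) == 0) continue;
      double g = md.c[j];
      for (int ip = 0; ip < N; ++ip) {
        int m = md.ord(ip, j);
        if (m == 0) continue;
        double v;
        if (ip == i) {
          v = 0.0;
          for (int l = 0; l < m; ++l) {
            double term = 1.0;
            for (int lp = 0; lp < m; ++lp)
              if (lp != l) term *= (x[ip] - lp);
            v += term;
          }
        } else {
          v = 1.0;
          for (int l = 0; l < m; ++l) v *= (x[ip] - l);
        }
        g *= v / R::gammafn(m + 1.0);
      }
      dA[j + (size_t)M * i] = g;
    }
  }
  f.assign((size_t)M * M, 0.0);                 // f[j + M*jp]
  for (int jp = 0; jp < M; ++jp)
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < M; ++j)
        f[j + (size_t)M * jp] += dA[j + (size_t)M * i] * md.nu(i, jp);
}

// frozen-coefficient moment integral, Gragg-smoothed endpoint; mirrors
// .momentIntegral (state is (mu, var), no admissibility check)
bool momentIntegral(const Model& md, const std::vector<double>& f,
                    const std::vector<double>& a, double tau, int nSub,
                    std::vector<double>& out) {
  int M = md.M;
  out.assign(2 * (size_t)M, 0.0);
  if (tau == 0) return true;
  double h = tau / nSub;
  auto rhs = [&](const std::vector<double>& y, std::vector<double>& d) {
    // matches the R reference: dmu = (f %*% mu) + a, then dvar
    for (int j = 0; j < M; ++j) d[j] = 0.0;
    for (int jp = 0; jp < M; ++jp)
      for (int j = 0; j < M; ++j)
        d[j] += f[j + (size_t)M * jp] * y[jp];
    for (int j = 0; j < M; ++j) d[j] += a[j];
    for (int j = 0; j < M; ++j)
      d[M + j] = 2 * f[j + (size_t)M * j] * y[M + j] + d[j];
  };
  int n2 = 2 * M;
  std::vector<double> z0(n2, 0.0), z1(n2), z2(n2), d(n2), zPrev(n2);
  rhs(z0, d);
  for (int i = 0; i < n2; ++i) z1[i] = z0[i] + h * d[i];
  for (int m = 1; m < nSub; ++m) {
    rhs(z1, d);
    for (int i = 0; i < n2; ++i) z2[i] = z0[i] + 2 * h * d[i];
    z0 = z1; z1 = z2;
  }
  rhs(z1, d);
  for (int i = 0; i < n2; ++i)
    out[i] = 0.5 * (z1[i] + z0[i] + h * d[i]);
  for (int i = 0; i < n2; ++i)
    if (!std::isfinite(out[i])) return false;
  return true;
}

// Neville table in h^2 with n_q substeps; mirrors nevilleExtend
struct Neville {
  std::vector<std::vector<double>> diag;  // diag[q-1][cc-1] length-L entries
  std::vector<int> nSub;
  int L;
  explicit Neville(int len) : L(len) {}
  void extend(const std::vector<double>& value, int n) {
    int q = (int)nSub.size() + 1;
    nSub.push_back(n);
    std::vector<double> row((size_t)q * L);
    for (int i = 0; i < L; ++i) row[i] = value[i];
    if (q > 1) {
      const std::vector<double>& prev = diag[q - 2];
      for (int cc = 2; cc <= q; ++cc) {
        double r = (double)nSub[q - 1] / nSub[q - cc];
        double denom = r * r - 1.0;
        for (int i = 0; i < L; ++i) {
          double cur = row[(size_t)(cc - 2) * L + i];
          double pv = prev[(size_t)(cc - 2) * L + i];
          row[(size_t)(cc - 1) * L + i] = cur + (cur - pv) / denom;
        }
      }
    }
    diag.push_back(std::move(row));
  }
  // top entry of column q (rows 1..q combined)
  const double* top(int q) const {
    return diag[q - 1].data() + (size_t)(q - 1) * L;
  }
  const double* second(int q) const {
    return diag[q - 1].data() + (size_t)(q - 2) * L;
  }
  // scaled column error over the first `lead` components
  double err(int q, int lead, double atol, double rtol) const {
    const double* t = top(q);
    const double* s = second(q);
    double num = 0.0, scale = 0.0;
    for (int i = 0; i < lead; ++i) num += (t[i] - s[i]) * (t[i] - s[i]);
    for (int i = 0; i < lead; ++i) scale += t[i] * t[i];
    return std::sqrt(num) / (atol + rtol * std::sqrt(scale));
  }
};

double candidateTau(double tau, double errK, int k, double s1, double s2,
                    double maxGrowth) {
  if (errK < 1e-300) return tau * s1 * maxGrowth;
  double e = 1.0 / (2 * (k - 1) + 1);
  return std::min(tau * s1 * std::pow(s2 / errK, e), tau * maxGrowth);
}

struct StepOut {
  std::vector<double> state;
  double tauUsed, tauNext;
  int kConv, kNext, rejections, work;
};

// one adaptive step; mirrors .adaptiveStep + sbsStep/sbsDaStep
// da = false: SBS (propensity integrals, Poisson update)
// da = true : SBS-DA (moment pairs, hybrid update)
bool adaptiveStep(const Model& md, const std::vector<double>& x, double tau,
                  double s1, double s2, double atol, double rtol, int kMax,
                  double maxGrowth, int kTarget /* 0 = first step */,
                  double floorTau, bool da, StepOut& outp) {
  int M = md.M;
  // zero-propensity shortcut
  {
    std::vector<double> a(M);
    propEval(md, x.data(), a.data());
    bool quiet = true;
    for (int j = 0; j < M; ++j) if (a[j] != 0) { quiet = false; break; }
    if (quiet) {
      outp.state = x; outp.tauUsed = tau; outp.tauNext = tau;
      outp.kConv = 1; outp.kNext = 2; outp.rejections = 0; outp.work = 0;
      return true;
    }
  }
  std::vector<double> fFroz, aFroz;
  if (da) {
    couplingMatrix(md, x.data(), fFroz);
    aFroz.assign(M, 0.0);
    propEval(md, x.data(), aFroz.data());
  }
  std::vector<double> drift0(md.N);
  if (!da) {
    std::vector<double> scr(md.M);
    driftEval(md, x.data(), drift0.data(), scr);
  }
  int rejections = 0, work = 1;   // the shared start-state evaluation
  int L = da ? 2 * M : M;
  std::vector<double> fc;
  for (;;) {
    int wLo, wHi;
    if (kTarget == 0) { wLo = 2; wHi = kMax; }
    else {
      wLo = std::max(2, kTarget - 1);
      wHi = std::min(kMax, kTarget + 1);
    }
    int qMax = wHi;
    Neville tab(L);
    std::vector<double> errs(qMax + 1, NA_REAL);
    int accepted = 0;
    bool failed = false;
    for (int q = 1; q <= qMax; ++q) {
      int nSub = 2 * q;
      bool ok = da ? momentIntegral(md, fFroz, aFroz, tau, nSub, fc)
                   : propIntegral(md, x.data(), tau, nSub, fc,
                                  drift0.data());
      if (!ok) { failed = true; break; }
      work += nSub;
      tab.extend(fc, nSub);
      if (q >= 2) {
        errs[q] = tab.err(q, M, atol, rtol);
        if (q >= wLo && q <= wHi && errs[q] <= 1) { accepted = q; break; }
      }
    }
    if (failed || accepted == 0) {
      tau /= 2; ++rejections;
      if (tau < floorTau) stop("SBS stepsize underflow (no convergence)");
      continue;
    }
    const double* extr = tab.top(accepted);
    // sample reaction counts (RNG order mirrors the R reference)
    std::vector<double> K(M);
    if (!da) {
      double mx = 1.0;
      for (int j = 0; j < M; ++j) mx = std::max(mx, std::fabs(extr[j]));
      for (int j = 0; j < M; ++j)
        if (extr[j] < -1e-8 * mx)
          stop("negative extrapolated Poisson parameter");
      for (int j = 0; j < M; ++j)
        K[j] = R::rpois(std::max(extr[j], 0.0));
    } else {
      // hybridSample: all Poisson draws first, then all Gaussian draws
      for (int j = 0; j < M; ++j) {
        double mu = std::max(extr[j], 0.0);
        if (mu < 10) K[j] = R::rpois(mu);
      }
      for (int j = 0; j < M; ++j) {
        double mu = std::max(extr[j], 0.0);
        if (mu >= 10) {
          double v = std::max(extr[M + j], 0.0);
          double z = R::rnorm(mu, std::sqrt(v));
          K[j] = std::max(std::floor(z + 0.5), 0.0);
        }
      }
    }
    std::vector<double> xNew(md.N);
    for (int i = 0; i < md.N; ++i) xNew[i] = x[i];
    for (int j = 0; j < M; ++j)
      for (int i = 0; i < md.N; ++i) xNew[i] += md.nu(i, j) * K[j];
    bool neg = false;
    for (int i = 0; i < md.N; ++i) if (xNew[i] < 0) { neg = true; break; }
    if (neg) {
      tau /= 2; ++rejections;
      if (tau < floorTau)
        stop("SBS stepsize underflow (negative populations)");
      continue;
    }
    // efficiency-optimal next column among the built columns (err known)
    double bestW = R_PosInf, bestTau = tau;
    int bestK = 2;
    int A = 3;
    for (int q = 2; q <= qMax; ++q) {
      A += 2 * q;
      if (!ISNAN(errs[q])) {
        double tc = candidateTau(tau, errs[q], q, s1, s2, maxGrowth);
        double W = A / tc;
        if (W < bestW) { bestW = W; bestTau = tc; bestK = q; }
      }
    }
    outp.state = std::move(xNew);
    outp.tauUsed = tau; outp.tauNext = bestTau;
    outp.kConv = accepted; outp.kNext = bestK;
    outp.rejections = rejections; outp.work = work;
    return true;
  }
}

}  // namespace

// [[Rcpp::export(name = ".sbs_cpp")]]
List sbs_cpp(IntegerMatrix orders, NumericMatrix nuEff, NumericVector c,
             NumericVector x0, double t0, double T, double s1, double s2,
             double atol, double rtol, int kMax, double tau0,
             double tau0Multiple, double maxGrowth, bool da,
             bool saveTraj) {
  Model md = makeModel(orders, nuEff, c);
  std::vector<double> x(x0.begin(), x0.end());
  double t = t0;
  std::vector<double> a(md.M);
  propEval(md, x.data(), a.data());
  double a0 = 0.0;
  for (int j = 0; j < md.M; ++j) a0 += a[j];
  double tau;
  if (R_finite(tau0)) tau = tau0;
  else if (a0 > 0) tau = tau0Multiple / a0;
  else tau = T - t0;
  int kTarget = 0;
  double floorTau = 1e-12 * (T - t0);

  std::vector<double> times, states, iT, iTau;
  std::vector<int> iK, iRej, iWork;
  times.push_back(t);
  for (int i = 0; i < md.N; ++i) states.push_back(x[i]);

  StepOut rec;
  while (t < T) {
    double tauTry = std::min(std::max(tau, floorTau), T - t);
    adaptiveStep(md, x, tauTry, s1, s2, atol, rtol, kMax, maxGrowth,
                 kTarget, floorTau, da, rec);
    if (rec.tauUsed < floorTau)
      stop("adaptive stepper stalled: stepsize underflow");
    x = rec.state;
    double tPrev = t;
    t = (T - t - rec.tauUsed < floorTau) ? T : t + rec.tauUsed;
    iT.push_back(tPrev); iTau.push_back(rec.tauUsed);
    iK.push_back(rec.kConv); iRej.push_back(rec.rejections);
    iWork.push_back(rec.work);
    tau = std::min(rec.tauNext, (T - t > 0) ? T - t : rec.tauNext);
    kTarget = rec.kNext;
    if (saveTraj) {
      times.push_back(t);
      for (int i = 0; i < md.N; ++i) states.push_back(x[i]);
    }
  }
  if (!saveTraj) {
    times.push_back(T);
    for (int i = 0; i < md.N; ++i) states.push_back(x[i]);
  }
  int nPts = (int)times.size();
  NumericMatrix S(nPts, md.N);
  for (int r = 0; r < nPts; ++r)
    for (int i = 0; i < md.N; ++i) S(r, i) = states[(size_t)r * md.N + i];
  return List::create(
    _["times"] = NumericVector(times.begin(), times.end()),
    _["states"] = S,
    _["t"] = NumericVector(iT.begin(), iT.end()),
    _["tau"] = NumericVector(iTau.begin(), iTau.end()),
    _["k"] = IntegerVector(iK.begin(), iK.end()),
    _["rejections"] = IntegerVector(iRej.begin(), iRej.end()),
    _["work"] = IntegerVector(iWork.begin(), iWork.end()));
}

// Cao-Gillespie-Petzold stepsize bound; mirrors tauSelect()
static double tauSelectCpp(const Model& md, const IntegerMatrix& orders,
                           const LogicalVector& fixed,
                           const std::vector<double>& x, double epsilon,
                           double tRemaining) {
  int N = md.N, M = md.M;
  std::vector<double> a(M);
  propEval(md, x.data(), a.data());
  bool quiet = true;
  for (int j = 0; j < M; ++j) if (a[j] != 0) { quiet = false; break; }
  if (quiet) return tRemaining;
  std::vector<double> mu(N, 0.0), sig2(N, 0.0);
  for (int j = 0; j < M; ++j)
    for (int i = 0; i < N; ++i) {
      mu[i] += md.nu(i, j) * a[j];
      sig2[i] += md.nu(i, j) * md.nu(i, j) * a[j];
    }
  double tau = R_PosInf;
  for (int i = 0; i < N; ++i) {
    if (fixed[i]) continue;
    int o = 0;
    for (int j = 0; j < M; ++j)
      if (orders(i, j) > 0) {
        int oTot = 0;
        for (int ii = 0; ii < N; ++ii) oTot += orders(ii, j);
        if (oTot > o) o = oTot;
      }
    if (o == 0) continue;
    int m = 0;
    for (int j = 0; j < M; ++j)
      if (orders(i, j) > 0) {
        int oTot = 0;
        for (int ii = 0; ii < N; ++ii) oTot += orders(ii, j);
        if (oTot == o && orders(i, j) > m) m = orders(i, j);
      }
    double xi = x[i], g;
    if (o == 1) g = 1;
    else if (o == 2) g = (m == 1) ? 2 : 2 + 1 / (xi - 1);
    else g = (m == 1) ? 3
             : (m == 2) ? 1.5 * (2 + 1 / (xi - 1))
                        : 3 + 1 / (xi - 1) + 2 / (xi - 2);
    double bound = std::max(epsilon * xi / g, 1.0);
    if (mu[i] != 0) tau = std::min(tau, bound / std::fabs(mu[i]));
    if (sig2[i] != 0) tau = std::min(tau, bound * bound / sig2[i]);
  }
  return std::min(tau, tRemaining);
}

// [[Rcpp::export(name = ".leap_cpp")]]
List leap_cpp(IntegerMatrix orders, NumericMatrix nuEff, NumericVector c,
              LogicalVector fixed, NumericVector x0, double t0, double T,
              double epsilon, bool ubtl, bool saveTraj) {
  Model md = makeModel(orders, nuEff, c);
  std::vector<double> x(x0.begin(), x0.end());
  double t = t0;
  double floorTau = 1e-12 * (T - t0);
  std::vector<double> times, states, iTau;
  times.push_back(t);
  for (int i = 0; i < md.N; ++i) states.push_back(x[i]);
  std::vector<double> a(md.M), K(md.M), xNew(md.N), fFroz, mom;

  while (t < T) {
    double tau = tauSelectCpp(md, orders, fixed, x, epsilon, T - t);
    if (ubtl) {
      couplingMatrix(md, x.data(), fFroz);
      propEval(md, x.data(), a.data());
    }
    for (;;) {
      if (!ubtl) {
        propEval(md, x.data(), a.data());
        for (int j = 0; j < md.M; ++j) K[j] = R::rpois(a[j] * tau);
      } else {
        Neville tab(2 * md.M);
        for (int nSub : {8, 16}) {
          if (!momentIntegral(md, fFroz, a, tau, nSub, mom))
            stop("modified midpoint failure in UBTL step");
          tab.extend(mom, nSub);
        }
        const double* extr = tab.top(2);
        for (int j = 0; j < md.M; ++j) {
          double mu = std::max(extr[j], 0.0);
          if (mu < 10) K[j] = R::rpois(mu);
        }
        for (int j = 0; j < md.M; ++j) {
          double mu = std::max(extr[j], 0.0);
          if (mu >= 10) {
            double v = std::max(extr[md.M + j], 0.0);
            double z = R::rnorm(mu, std::sqrt(v));
            K[j] = std::max(std::floor(z + 0.5), 0.0);
          }
        }
      }
      for (int i = 0; i < md.N; ++i) xNew[i] = x[i];
      for (int j = 0; j < md.M; ++j)
        for (int i = 0; i < md.N; ++i) xNew[i] += md.nu(i, j) * K[j];
      bool neg = false;
      for (int i = 0; i < md.N; ++i) if (xNew[i] < 0) { neg = true; break; }
      if (!neg) break;
      tau /= 2;
      if (tau < floorTau) stop("leap stepsize underflow");
    }
    for (int i = 0; i < md.N; ++i) x[i] = xNew[i];
    t = (T - t - tau < floorTau) ? T : t + tau;
    iTau.push_back(tau);
    if (saveTraj) {
      times.push_back(t);
      for (int i = 0; i < md.N; ++i) states.push_back(x[i]);
    }
  }
  if (!saveTraj) {
    times.push_back(T);
    for (int i = 0; i < md.N; ++i) states.push_back(x[i]);
  }
  int nPts = (int)times.size();
  NumericMatrix S(nPts, md.N);
  for (int r = 0; r < nPts; ++r)
    for (int i = 0; i < md.N; ++i) S(r, i) = states[(size_t)r * md.N + i];
  return List::create(
    _["times"] = NumericVector(times.begin(), times.end()),
    _["states"] = S,
    _["tau"] = NumericVector(iTau.begin(), iTau.end()));
}
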