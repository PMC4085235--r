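#include <Rcpp.h>
using namespace Rcpp;

// Exact Gillespie direct-method path generation.  Propensities use the
// distinct-combination mass-action convention: a_j = c_j * prod_i C(x_i, m_ij).
// Uses R's RNG so results are governed by set.seed().

static double propensity(const IntegerMatrix& orders, const NumericVector& c,
                         const std::vector<double>& x, int j) {
  double a = c[j];
  const int N = orders.nrow();
  for (int i = 0; i < N; ++i) {
    int m = orders(i, j);
    if (m == 0) continue;
    for (int l = 0; l < m; ++l) a *= (x[i] - l);
    if (m == 2) a /= 2.0;
    else if (m > 2) a /= R::gammafn(m + 1.0);
    if (a <= 0.0) return 0.0;
  }
  return a;
}

// [[Rcpp::export(name = ".ssa_cpp")]]
List ssa_cpp(IntegerMatrix orders, IntegerMatrix nuEff, NumericVector c,
             NumericVector x0, double t0, double tEnd,
             bool saveTraj, double maxEvents) {
  const int N = orders.nrow();
  const int M = orders.ncol();
  std::vector<double> x(x0.begin(), x0.end());
  double t = t0;

  std::vector<double> times;
  std::vector<double> states;   // row-major N per event
  if (saveTraj) {
    times.push_back(t);
    for (int i = 0; i < N; ++i) states.push_back(x[i]);
  }

  std::vector<double> a(M);
  double nEvents = 0.0;
  while (t < tEnd) {
    double a0 = 0.0;
    for (int j = 0; j < M; ++j) { a[j] = propensity(orders, c, x, j); a0 += a[j]; }
    if (a0 <= 0.0) break;                       // absorbing: freeze to tEnd
    double dt = R::rexp(1.0 / a0);
    if (t + dt > tEnd) { t = tEnd; break; }
    t += dt;
    double u = unif_rand() * a0;
    int jSel = M - 1;
    double acc = 0.0;
    for (int j = 0; j < M; ++j) { acc += a[j]; if (u <= acc) { jSel = j; break; } }
    for (int i = 0; i < N; ++i) x[i] += nuEff(i, jSel);
    if (saveTraj) {
      times.push_back(t);
      for (int i = 0; i < N; ++i) states.push_back(x[i]);
    }
    if (++nEvents >= maxEvents)
      stop("SSA event budget exceeded");
  }

  NumericVector xf(x.begin(), x.end());
  if (!saveTraj)
    return List::create(_["time"] = tEnd, _["state"] = xf);

  const int nPts = times.size();
  NumericMatrix S(nPts, N);
  for (int r = 0; r < nPts; ++r)
    for (int i = 0; i < N; ++i) S(r, i) = states[(size_t)r * N + i];
  // append the frozen final state at tEnd if the last event was before it
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = S, _["finalTime"] = tEnd,
                      _["finalState"] = xf);
}
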