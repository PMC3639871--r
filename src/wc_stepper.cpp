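// Delayed Wilson-Cowan network integrator: method of steps with classical
// RK4 and Catmull-Rom interpolation of the delayed excitatory history.
// Time unit is ms throughout; delays must exceed 2*dt.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigf(double s, double a, double th) {
  return 1.0 / (1.0 + std::exp(-a * (s - th))) - 1.0 / (1.0 + std::exp(a * th));
}

struct History {
  // ring buffer of E values on the dt grid, plus constant pre-history
  int n_osc, cap;
  double dt;
  std::vector<double> buf;      // cap x n_osc, row = grid index % cap
  std::vector<double> pre;      // constant history for t <= 0
  long filled;                  // highest grid index stored

  History(int n_osc_, int cap_, double dt_, const NumericVector& E0)
      : n_osc(n_osc_), cap(cap_), dt(dt_), buf((size_t)cap_ * n_osc_, 0.0),
        pre(E0.begin(), E0.end()), filled(-1) {}

  void push(long idx, const double* E) {
    double* row = &buf[(size_t)(idx % cap) * n_osc];
    for (int k = 0; k < n_osc; ++k) row[k] = E[k];
    filled = idx;
  }
  double at(long idx, int k) const {
    if (idx <= 0) return pre[k];
    if (idx > filled) idx = filled;  // clamped: only reachable within 2*dt of the head
    return buf[(size_t)(idx % cap) * n_osc + k];
  }
  // cubic Catmull-Rom interpolation at time tq (<= current time)
  double interp(double tq, int k) const {
    if (tq <= 0.0) return pre[k];
    double x = tq / dt;
    long j0 = (long)std::floor(x);
    double f = x - j0;
    if (f < 1e-12) return at(j0, k);
    double p0 = at(j0 - 1, k), p1 = at(j0, k), p2 = at(j0 + 1, k), p3 = at(j0 + 2, k);
    double a0 = -0.5 * p0 + 1.5 * p1 - 1.5 * p2 + 0.5 * p3;
    double a1 = p0 - 2.5 * p1 + 2.0 * p2 - 0.5 * p3;
    double a2 = -0.5 * p0 + 0.5 * p2;
    return ((a0 * f + a1) * f + a2) * f + p1;
  }
};

// [[Rcpp::export]]
List wc_integrate(NumericMatrix par,      // n_osc x 12 rows: alpha beta_e beta_i r a_e a_i th_e th_i w_ee w_ei w_ie w_ii
                  NumericVector P, NumericVector Q,
                  IntegerVector efrom,    // 0-based source oscillator
                  IntegerVector eto,      // 0-based target oscillator
                  NumericVector eweight,
                  NumericVector edelay,   // ms
                  double duration, double dt, double record_dt,
                  NumericVector E0, NumericVector I0) {
  const int n = par.nrow();
  const int ne = efrom.size();
  const long nsteps = (long)std::llround(duration / dt);
  const int rec_every = (int)std::llround(record_dt / dt);
  const long nrec = nsteps / rec_every + 1;

  double maxdel = 0.0;
  for (int e = 0; e < ne; ++e) {
    if (edelay[e] <= 2.0 * dt) stop("coupling delays must exceed 2*dt");
    if (edelay[e] > maxdel) maxdel = edelay[e];
  }
  int cap = (int)std::ceil(maxdel / dt) + 8;
  History hist(n, cap, dt, E0);

  std::vector<double> E(E0.begin(), E0.end()), I(I0.begin(), I0.end());
  std::vector<double> Ev(n), Iv(n), cpl(n);
  std::vector<double> k1E(n), k1I(n), k2E(n), k2I(n), k3E(n), k3I(n), k4E(n), k4I(n);

  NumericMatrix Erec(n, nrec), Irec(n, nrec);
  for (int k = 0; k < n; ++k) { Erec(k, 0) = E[k]; Irec(k, 0) = I[k]; }
  hist.push(0, E.data());

  // cache parameters and edges in plain arrays (row-per-oscillator layout)
  std::vector<double> pp(12 * n), Pv(P.begin(), P.end()), Qv(Q.begin(), Q.end());
  for (int k = 0; k < n; ++k)
    for (int c = 0; c < 12; ++c) pp[12 * k + c] = par(k, c);
  std::vector<int> ef(efrom.begin(), efrom.end()), et(eto.begin(), eto.end());
  std::vector<double> ew(eweight.begin(), eweight.end()),
      edl(edelay.begin(), edelay.end());

  auto deriv = [&](const std::vector<double>& Ecur, const std::vector<double>& Icur,
                   double t, std::vector<double>& dE, std::vector<double>& dI) {
    std::fill(cpl.begin(), cpl.end(), 0.0);
    for (int e = 0; e < ne; ++e)
      cpl[et[e]] += ew[e] * hist.interp(t - edl[e], ef[e]);
    for (int k = 0; k < n; ++k) {
      const double* q = &pp[12 * k];
      double sE = q[8] * Ecur[k] - q[10] * Icur[k] + cpl[k] + Pv[k];
      double sI = q[9] * Ecur[k] - q[11] * Icur[k] + Qv[k];
      dE[k] = -q[0] * Ecur[k] + q[1] * (1.0 - q[3] * Ecur[k]) * sigf(sE, q[4], q[6]);
      dI[k] = -q[0] * Icur[k] + q[2] * (1.0 - q[3] * Icur[k]) * sigf(sI, q[5], q[7]);
    }
  };

  long irec = 1;
  for (long i = 0; i < nsteps; ++i) {
    double t = i * dt;
    deriv(E, I, t, k1E, k1I);
    for (int k = 0; k < n; ++k) { Ev[k] = E[k] + 0.5 * dt * k1E[k]; Iv[k] = I[k] + 0.5 * dt * k1I[k]; }
    deriv(Ev, Iv, t + 0.5 * dt, k2E, k2I);
    for (int k = 0; k < n; ++k) { Ev[k] = E[k] + 0.5 * dt * k2E[k]; Iv[k] = I[k] + 0.5 * dt * k2I[k]; }
    deriv(Ev, Iv, t + 0.5 * dt, k3E, k3I);
    for (int k = 0; k < n; ++k) { Ev[k] = E[k] + dt * k3E[k]; Iv[k] = I[k] + dt * k3I[k]; }
    deriv(Ev, Iv, t + dt, k4E, k4I);
    for (int k = 0; k < n; ++k) {
      E[k] += dt / 6.0 * (k1E[k] + 2.0 * k2E[k] + 2.0 * k3E[k] + k4E[k]);
      I[k] += dt / 6.0 * (k1I[k] + 2.0 * k2I[k] + 2.0 * k3I[k] + k4I[k]);
    }
    hist.push(i + 1, E.data());
    if ((i + 1) % rec_every == 0 && irec < nrec) {
      for (int k = 0; k < n; ++k) { Erec(k, irec) = E[k]; Irec(k, irec) = I[k]; }
      ++irec;
    }
  }

  NumericVector times(nrec);
  for (long j = 0; j < nrec; ++j) times[j] = j * record_dt;
  return List::create(_["E"] = Erec, _["I"] = Irec, _["time_ms"] = times);
}

// Beta-gamma switching detector: literal latched three-condition rule on
// 1 ms band-power series. Backward differences; the first sample cannot
// trigger. Latch releases as soon as beta >= gamma.
// [[Rcpp::export]]
IntegerVector switching_indicator(NumericVector beta, NumericVector gamma) {
  const int n = beta.size();
  if (gamma.size() != n) stop("beta and gamma series must have equal length");
  IntegerVector ind(n);
  bool on = false;
  for (int t = 0; t < n; ++t) {
    if (on && beta[t] >= gamma[t]) on = false;
    if (!on && t > 0) {
      bool trig = (beta[t] - beta[t - 1] < 0.0) &&
                  (gamma[t] - gamma[t - 1] > 0.0) &&
                  (gamma[t] - beta[t] > 0.0);
      if (trig) on = true;
    }
    ind[t] = on ? 1 : 0;
  }
  return ind;
}
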