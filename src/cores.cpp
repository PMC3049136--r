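#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared helpers for the stochastic cores. All simulators draw from R's RNG
// so that set.seed() in R makes runs bit-reproducible.

static inline double propensity(const int r, const IntegerVector &x,
                                const IntegerMatrix &react,
                                const NumericVector &rates,
                                const LogicalVector &sigScaled,
                                const double level) {
  double a = rates[r];
  if (sigScaled[r]) a *= level;
  if (a <= 0.0) return 0.0;
  const int S = react.nrow();
  for (int s = 0; s < S; ++s) {
    int m = react(s, r);
    // mass-action combinatorics x(x-1).../ for multiplicity m (m is 0/1/2 here)
    for (int k = 0; k < m; ++k) a *= (double)(x[s] - k);
  }
  return a > 0.0 ? a : 0.0;
}

// Direct-method SSA over a piecewise-constant signal, recording the state at
// the requested times (left-hold). Signal segments: sigT[k] is the start of
// segment k with level sigLevel[k] (uM); sigT[0] <= t0. If sigSpecies >= 0 the
// signal is a molecular species whose *unbound* copy number is SET to
// sigLevelMol[k] at each segment start; otherwise flagged propensities are
// multiplied by the current level. The next-reaction time is re-drawn at every
// switch (exact by memorylessness).
// [[Rcpp::export]]
IntegerMatrix ssa_sample_cpp(IntegerVector x0, IntegerMatrix stoich,
                             IntegerMatrix react, NumericVector rates,
                             LogicalVector sigScaled, int sigSpecies,
                             NumericVector sigT, NumericVector sigLevel,
                             IntegerVector sigLevelMol, double t0,
                             NumericVector recordTimes) {
  const int S = stoich.nrow(), R = stoich.ncol();
  const int nT = recordTimes.size(), nSeg = sigT.size();
  IntegerVector x = clone(x0);
  IntegerMatrix out(nT, S);

  int seg = 0;
  while (seg + 1 < nSeg && sigT[seg + 1] <= t0) ++seg;
  if (sigSpecies >= 0) x[sigSpecies] = sigLevelMol[seg];

  double t = t0;
  int k = 0;
  const double tEnd = recordTimes[nT - 1];
  while (k < nT) {
    double level = sigLevel[seg];
    double tSwitch = (seg + 1 < nSeg) ? sigT[seg + 1] : R_PosInf;
    double a0 = 0.0;
    std::vector<double> a(R);
    for (int r = 0; r < R; ++r) {
      a[r] = propensity(r, x, react, rates, sigScaled, level);
      a0 += a[r];
    }
    double tau = (a0 > 0.0) ? R::exp_rand() / a0 : R_PosInf;
    double tNext = t + tau;
    if (tNext >= tSwitch && tSwitch <= tEnd) {
      while (k < nT && recordTimes[k] < tSwitch) {
        for (int s = 0; s < S; ++s) out(k, s) = x[s];
        ++k;
      }
      t = tSwitch;
      ++seg;
      if (sigSpecies >= 0) x[sigSpecies] = sigLevelMol[seg];
      continue;
    }
    while (k < nT && recordTimes[k] < tNext) {
      for (int s = 0; s < S; ++s) out(k, s) = x[s];
      ++k;
    }
    if (k >= nT) break;
    t = tNext;
    // choose reaction
    double u = unif_rand() * a0, c = 0.0;
    int r = R - 1;
    for (int j = 0; j < R; ++j) {
      c += a[j];
      if (u <= c) { r = j; break; }
    }
    for (int s = 0; s < S; ++s) {
      x[s] += stoich(s, r);
      if (x[s] < 0) stop("negative copy number: stoichiometry violated");
    }
  }
  return out;
}

// As above but recording every reaction event (and every signal switch), for
// event-level diagnostics. Returns times and the state *after* each event.
// [[Rcpp::export]]
List ssa_events_cpp(IntegerVector x0, IntegerMatrix stoich, IntegerMatrix react,
                    NumericVector rates, LogicalVector sigScaled,
                    int sigSpecies, NumericVector sigT, NumericVector sigLevel,
                    IntegerVector sigLevelMol, double t0, double tEnd,
                    int maxEvents) {
  const int S = stoich.nrow(), R = stoich.ncol();
  const int nSeg = sigT.size();
  IntegerVector x = clone(x0);

  std::vector<double> times;
  std::vector<int> states;
  times.reserve(1024);

  int seg = 0;
  while (seg + 1 < nSeg && sigT[seg + 1] <= t0) ++seg;
  if (sigSpecies >= 0) x[sigSpecies] = sigLevelMol[seg];

  double t = t0;
  times.push_back(t);
  for (int s = 0; s < S; ++s) states.push_back(x[s]);

  while (t < tEnd) {
    if ((int)times.size() > maxEvents)
      stop("event record exceeded max_events (%d); sample on a grid instead",
           maxEvents);
    double level = sigLevel[seg];
    double tSwitch = (seg + 1 < nSeg) ? sigT[seg + 1] : R_PosInf;
    double a0 = 0.0;
    std::vector<double> a(R);
    for (int r = 0; r < R; ++r) {
      a[r] = propensity(r, x, react, rates, sigScaled, level);
      a0 += a[r];
    }
    double tau = (a0 > 0.0) ? R::exp_rand() / a0 : R_PosInf;
    double tNext = t + tau;
    if (tNext >= tSwitch && tSwitch <= tEnd) {
      t = tSwitch;
      ++seg;
      if (sigSpecies >= 0) x[sigSpecies] = sigLevelMol[seg];
      times.push_back(t);
      for (int s = 0; s < S; ++s) states.push_back(x[s]);
      continue;
    }
    if (tNext > tEnd) break;
    t = tNext;
    double u = unif_rand() * a0, c = 0.0;
    int r = R - 1;
    for (int j = 0; j < R; ++j) {
      c += a[j];
      if (u <= c) { r = j; break; }
    }
    for (int s = 0; s < S; ++s) {
      x[s] += stoich(s, r);
      if (x[s] < 0) stop("negative copy number: stoichiometry violated");
    }
    times.push_back(t);
    for (int s = 0; s < S; ++s) states.push_back(x[s]);
  }

  const int n = times.size();
  NumericVector tOut(n);
  IntegerMatrix xOut(n, S);
  for (int i = 0; i < n; ++i) {
    tOut[i] = times[i];
    for (int s = 0; s < S; ++s) xOut(i, s) = states[i * S + s];
  }
  return List::create(_["times"] = tOut, _["counts"] = xOut);
}

// Chemical Langevin equation by Euler-Maruyama: one independent Wiener channel
// per reaction, diffusion amplitude sqrt(a_r(x)). Propensity arguments are
// clamped at zero for negative excursions. Records the state at recordTimes,
// stepping with dt and shortening the last substep to hit each record time
// and each signal switch exactly.
// [[Rcpp::export]]
NumericMatrix cle_cpp(NumericVector x0, IntegerMatrix stoich,
                      IntegerMatrix react, NumericVector rates,
                      LogicalVector sigScaled, int sigSpecies,
                      NumericVector sigT, NumericVector sigLevel,
                      IntegerVector sigLevelMol, double t0, double dt,
                      NumericVector recordTimes) {
  const int S = stoich.nrow(), R = stoich.ncol();
  const int nT = recordTimes.size(), nSeg = sigT.size();
  NumericVector x = clone(x0);
  NumericMatrix out(nT, S);

  int seg = 0;
  while (seg + 1 < nSeg && sigT[seg + 1] <= t0) ++seg;
  if (sigSpecies >= 0) x[sigSpecies] = (double)sigLevelMol[seg];

  double t = t0;
  std::vector<double> drift(S), noise(S);
  for (int k = 0; k < nT; ++k) {
    double tTarget = recordTimes[k];
    while (t < tTarget) {
      double tSwitch = (seg + 1 < nSeg) ? sigT[seg + 1] : R_PosInf;
      if (t >= tSwitch) {
        ++seg;
        if (sigSpecies >= 0) x[sigSpecies] = (double)sigLevelMol[seg];
        continue;
      }
      double h = std::min({dt, tTarget - t, tSwitch - t});
      double level = sigLevel[seg];
      std::fill(drift.begin(), drift.end(), 0.0);
      std::fill(noise.begin(), noise.end(), 0.0);
      for (int r = 0; r < R; ++r) {
        double a = rates[r];
        if (sigScaled[r]) a *= level;
        if (a < 0.0) a = 0.0;
        for (int s = 0; s < S; ++s) {
          int m = react(s, r);
          for (int kk = 0; kk < m; ++kk) {
            double v = x[s] - (double)kk;
            a *= (v > 0.0 ? v : 0.0);
          }
        }
        double dW = std::sqrt(a * h) * norm_rand();
        for (int s = 0; s < S; ++s) {
          if (stoich(s, r) != 0) {
            drift[s] += stoich(s, r) * a * h;
            noise[s] += stoich(s, r) * dW;
          }
        }
      }
      for (int s = 0; s < S; ++s) x[s] += drift[s] + noise[s];
      t += h;
    }
    for (int s = 0; s < S; ++s) out(k, s) = x[s];
  }
  return out;
}

// Action of the matrix exponential exp(t*Q) on a probability vector by
// uniformization: Q = lam*(P - I) with P = I + Q/lam substochastic
// (lam >= max |diag(Q)|), so exp(tQ)v = e^{-lam t} sum_k (lam t)^k/k! P^k v
// with all-nonnegative terms. Q is passed in compressed sparse column form.
// The time is split so lam*dt <= 256 per substep to keep Poisson weights in
// double range; the Poisson tail below tol is truncated.
// [[Rcpp::export]]
NumericVector expmv_unif_cpp(int n, IntegerVector qp, IntegerVector qi,
                             NumericVector qx, double lam, NumericVector v,
                             double tTotal, double tol) {
  if (tTotal <= 0.0) return clone(v);
  if (lam <= 0.0) return clone(v); // zero generator
  int m = (int)std::ceil(lam * tTotal / 256.0);
  if (m < 1) m = 1;
  double dt = tTotal / m;
  double tolSub = tol / m;

  std::vector<double> p(v.begin(), v.end());
  std::vector<double> b(n), qb(n);

  std::vector<double> acc(n);
  for (int step = 0; step < m; ++step) {
    const double a = lam * dt;
    const double ea = std::exp(-a);
    // weights are kept as a^k/k! (max ~ e^a/sqrt(2 pi a), in range for
    // a <= 256) and the factor e^{-a} is applied once at the end; starting
    // the recursion at e^{-a} itself drives every accumulator product into
    // subnormal range and is ~100x slower on x86
    double w = 1.0, cum = 1.0;
    std::copy(p.begin(), p.end(), b.begin());
    std::copy(p.begin(), p.end(), acc.begin());
    int kmax = (int)std::ceil(a + 12.0 * std::sqrt(a + 1.0) + 30.0);
    for (int k = 1; k <= kmax; ++k) {
      // b <- P b = b + (Q b)/lam
      std::fill(qb.begin(), qb.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        double bj = b[j];
        if (bj == 0.0) continue;
        for (int idx = qp[j]; idx < qp[j + 1]; ++idx)
          qb[qi[idx]] += qx[idx] * bj;
      }
      for (int i = 0; i < n; ++i) {
        b[i] += qb[i] / lam;
        if (b[i] < 1e-280) b[i] = 0.0; // floor round-off and subnormals
      }
      w *= a / k;
      cum += w;
      for (int i = 0; i < n; ++i) acc[i] += w * b[i];
      if (1.0 - ea * cum < tolSub) break;
    }
    for (int i = 0; i < n; ++i) {
      p[i] = ea * acc[i];
      if (p[i] < 1e-280) p[i] = 0.0;
    }
  }
  return NumericVector(p.begin(), p.end());
}
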