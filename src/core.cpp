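// Compiled core of the half-sarcomere simulation: axial force-balance
// solver (filament-wise tridiagonal Newton relaxation) and the integrated
// per-timestep loop (thermal forcing -> stochastic transitions -> force
// balance). Formulas mirror the R-level reference functions; a diagnostic
// export allows the test suite to cross-check the two implementations.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct XB {
  double kr, kth, rW, rS, thW, thS, kT;
};
struct RC {
  double tau, b0, A, C, D, G, H, dGw, dGs;
  bool r31shift;
};
struct SP {
  double kthick, l0thick, kthin, l0thin;
};
struct TI {
  double a, b;
};

XB asXB(const List& l) {
  XB p;
  p.kr = l["kr"]; p.kth = l["ktheta"]; p.rW = l["rW"]; p.rS = l["rS"];
  p.thW = l["thetaW"]; p.thS = l["thetaS"]; p.kT = l["kT"];
  return p;
}
RC asRC(const List& l) {
  RC r;
  r.tau = l["tau"]; r.b0 = l["baseline"]; r.A = l["A"]; r.C = l["C"];
  r.D = l["D"]; r.G = l["G"]; r.H = l["H"];
  r.dGw = l["dG_weak"]; r.dGs = l["dG_strong"];
  r.r31shift = l.containsElementNamed("r31_shifted") ?
      as<bool>(l["r31_shifted"]) : false;
  return r;
}
SP asSP(const List& l) {
  SP s;
  s.kthick = l["k_thick"]; s.l0thick = l["l0_thick"];
  s.kthin = l["k_thin"]; s.l0thin = l["l0_thin"];
  return s;
}
TI asTI(const List& l) {
  TI t;
  t.a = l["a"]; t.b = l["b"];
  return t;
}

inline double expCap(double x) { return std::exp(std::min(x, 700.0)); }

inline double stateEnergy(double r, double th, bool strong, const XB& p) {
  double r0 = strong ? p.rS : p.rW, t0 = strong ? p.thS : p.thW;
  double dr = r - r0, dt = th - t0;
  return 0.5 * p.kr * dr * dr + 0.5 * p.kth * dt * dt; // pN nm
}

// dU/d(dx) for a bound head; force on the thin node is -g, +g on the anchor
inline double gAxial(double dx, double am, bool strong, const XB& p) {
  double r = std::sqrt(dx * dx + am * am), th = std::atan2(am, dx);
  double r0 = strong ? p.rS : p.rW, t0 = strong ? p.thS : p.thW;
  return p.kr * (r - r0) * (dx / r) - p.kth * (th - t0) * (am / (r * r));
}

inline double titinAxial(double tipX, double hs, double radCC,
                         double rest, const TI& ti) {
  double dxa = hs - tipX;
  double L = std::sqrt(dxa * dxa + radCC * radCC);
  return ti.a * std::exp(ti.b * (L - rest)) * dxa / L;
}

// Thomas algorithm for J * delta = -R with J tridiagonal
// diag d[i], super/sub-diagonal off (constant +k per neighbour pair is NOT
// assumed: pass explicit off vectors)
void thomasSolve(std::vector<double>& d, std::vector<double>& off,
                 std::vector<double>& rhs, std::vector<double>& x) {
  int n = d.size();
  if (n == 1) { x[0] = rhs[0] / d[0]; return; }
  std::vector<double> cp(n), dp(n);
  cp[0] = off[0] / d[0];
  dp[0] = rhs[0] / d[0];
  for (int i = 1; i < n; ++i) {
    double m = d[i] - off[i - 1] * cp[i - 1];
    cp[i] = (i < n - 1) ? off[i] / m : 0.0;
    dp[i] = (rhs[i] - off[i - 1] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
}

struct Lattice {
  int nf, ng, nc, nn, nh;
  NumericMatrix thickX, thinX;     // nc x nf, nn x ng
  IntegerVector headState, boundSite, headThick, headCrown, headThin,
      headPhase, siteOcc;
  NumericVector headR, headTheta;
  double hs, am, radOffset /* thick+thin radius */, titinRest;
};

// accumulate crossbridge forces (+g on anchor, -g on site) and local
// stiffness |dg/ddx| into per-node arrays
void xbLoads(const Lattice& L, const XB& xb,
             NumericMatrix& fThick, NumericMatrix& kThick,
             NumericMatrix& fThin, NumericMatrix& kThin) {
  std::fill(fThick.begin(), fThick.end(), 0.0);
  std::fill(kThick.begin(), kThick.end(), 0.0);
  std::fill(fThin.begin(), fThin.end(), 0.0);
  std::fill(kThin.begin(), kThin.end(), 0.0);
  for (int i = 0; i < L.nh; ++i) {
    if (L.headState[i] <= 1) continue;
    int f = L.headThick[i] - 1, c = L.headCrown[i] - 1;
    int g = L.headThin[i] - 1, j = L.boundSite[i] - g * L.nn - 1;
    double dx = L.thinX(j, g) - L.thickX(c, f);
    bool strong = L.headState[i] == 3;
    double gax = gAxial(dx, L.am, strong, xb);
    const double h = 1e-4;
    double gp = (gAxial(dx + h, L.am, strong, xb) -
                 gAxial(dx - h, L.am, strong, xb)) / (2 * h);
    if (gp < 0) gp = 0; // keep Newton diagonal definite
    fThick(c, f) += gax;
    kThick(c, f) += gp;
    fThin(j, g) -= gax;
    kThin(j, g) += gp;
  }
}

double maxResidual(const Lattice& L, const SP& sp, const TI& ti,
                   const NumericMatrix& fThick, const NumericMatrix& fThin) {
  double worst = 0.0;
  for (int f = 0; f < L.nf; ++f) {
    for (int i = 0; i < L.nc; ++i) {
      double xm = (i == 0) ? 0.0 : L.thickX(i - 1, f);
      double R = -sp.kthick * (L.thickX(i, f) - xm - sp.l0thick);
      if (i < L.nc - 1)
        R += sp.kthick * (L.thickX(i + 1, f) - L.thickX(i, f) - sp.l0thick);
      else
        R += titinAxial(L.thickX(i, f), L.hs, L.am + L.radOffset,
                        L.titinRest, ti);
      R += fThick(i, f);
      worst = std::max(worst, std::fabs(R));
    }
  }
  for (int g = 0; g < L.ng; ++g) {
    for (int j = 0; j < L.nn; ++j) {
      double xz = (j == 0) ? L.hs : L.thinX(j - 1, g);
      double R = sp.kthin * (xz - L.thinX(j, g) - sp.l0thin);
      if (j < L.nn - 1)
        R -= sp.kthin * (L.thinX(j, g) - L.thinX(j + 1, g) - sp.l0thin);
      R += fThin(j, g);
      worst = std::max(worst, std::fabs(R));
    }
  }
  return worst;
}

double elasticEnergy(const Lattice& L, const SP& sp, const TI& ti,
                     const XB& xb) {
  double E = 0.0;
  for (int f = 0; f < L.nf; ++f) {
    for (int i = 0; i < L.nc; ++i) {
      double xm = (i == 0) ? 0.0 : L.thickX(i - 1, f);
      double s = L.thickX(i, f) - xm - sp.l0thick;
      E += 0.5 * sp.kthick * s * s;
    }
    double dxa = L.hs - L.thickX(L.nc - 1, f);
    double len = std::sqrt(dxa * dxa +
                           (L.am + L.radOffset) * (L.am + L.radOffset));
    double dL = len - L.titinRest;
    E += (ti.b > 0) ? (ti.a / ti.b) * (std::exp(ti.b * dL) - 1.0)
                    : ti.a * dL;
  }
  for (int g = 0; g < L.ng; ++g)
    for (int j = 0; j < L.nn; ++j) {
      double xz = (j == 0) ? L.hs : L.thinX(j - 1, g);
      double s = xz - L.thinX(j, g) - sp.l0thin;
      E += 0.5 * sp.kthin * s * s;
    }
  for (int i = 0; i < L.nh; ++i) {
    if (L.headState[i] <= 1) continue;
    int f = L.headThick[i] - 1, c = L.headCrown[i] - 1;
    int g = L.headThin[i] - 1, j = L.boundSite[i] - g * L.nn - 1;
    double dx = L.thinX(j, g) - L.thickX(c, f);
    double r = std::sqrt(dx * dx + L.am * L.am), th = std::atan2(L.am, dx);
    E += stateEnergy(r, th, L.headState[i] == 3, xb);
  }
  return E;
}

// one relaxation pass: solve every thick chain then every thin chain by a
// tridiagonal Newton step with crossbridge/titin loads linearised
void relaxPass(Lattice& L, const SP& sp, const TI& ti, const XB& xb,
               NumericMatrix& fThick, NumericMatrix& kThick,
               NumericMatrix& fThin, NumericMatrix& kThin) {
  const double h = 1e-4;
  xbLoads(L, xb, fThick, kThick, fThin, kThin);
  for (int f = 0; f < L.nf; ++f) {
    int n = L.nc;
    std::vector<double> d(n), off(n - 1, sp.kthick), rhs(n), delta(n);
    for (int i = 0; i < n; ++i) {
      double xm = (i == 0) ? 0.0 : L.thickX(i - 1, f);
      double R = -sp.kthick * (L.thickX(i, f) - xm - sp.l0thick);
      double diag = -sp.kthick - kThick(i, f);
      if (i < n - 1) {
        R += sp.kthick * (L.thickX(i + 1, f) - L.thickX(i, f) - sp.l0thick);
        diag -= sp.kthick;
      } else {
        double radCC = L.am + L.radOffset;
        R += titinAxial(L.thickX(i, f), L.hs, radCC, L.titinRest, ti);
        double dft = (titinAxial(L.thickX(i, f) + h, L.hs, radCC,
                                 L.titinRest, ti) -
                      titinAxial(L.thickX(i, f) - h, L.hs, radCC,
                                 L.titinRest, ti)) / (2 * h);
        if (dft < 0) diag += dft; // stabilising part only
      }
      R += fThick(i, f);
      d[i] = diag;
      rhs[i] = -R;
    }
    thomasSolve(d, off, rhs, delta);
    for (int i = 0; i < n; ++i) L.thickX(i, f) += delta[i];
  }
  xbLoads(L, xb, fThick, kThick, fThin, kThin);
  for (int g = 0; g < L.ng; ++g) {
    int n = L.nn;
    std::vector<double> d(n), off(n - 1, sp.kthin), rhs(n), delta(n);
    for (int j = 0; j < n; ++j) {
      double xz = (j == 0) ? L.hs : L.thinX(j - 1, g);
      double R = sp.kthin * (xz - L.thinX(j, g) - sp.l0thin);
      double diag = -sp.kthin - kThin(j, g);
      if (j < n - 1) {
        R -= sp.kthin * (L.thinX(j, g) - L.thinX(j + 1, g) - sp.l0thin);
        diag -= sp.kthin;
      }
      R += fThin(j, g);
      d[j] = diag;
      rhs[j] = -R;
    }
    thomasSolve(d, off, rhs, delta);
    for (int j = 0; j < n; ++j) L.thinX(j, g) += delta[j];
  }
}

// returns true on convergence; residual and optional energy trace out-params
bool solveEq(Lattice& L, const SP& sp, const TI& ti, const XB& xb,
             double tol, int maxIter, double& residual,
             std::vector<double>* energyTrace) {
  NumericMatrix fThick(L.nc, L.nf), kThick(L.nc, L.nf);
  NumericMatrix fThin(L.nn, L.ng), kThin(L.nn, L.ng);
  for (int it = 0; it < maxIter; ++it) {
    relaxPass(L, sp, ti, xb, fThick, kThick, fThin, kThin);
    if (energyTrace) energyTrace->push_back(elasticEnergy(L, sp, ti, xb));
    xbLoads(L, xb, fThick, kThick, fThin, kThin);
    residual = maxResidual(L, sp, ti, fThick, fThin);
    if (residual < tol) return true;
  }
  return false;
}

Lattice latticeFromR(NumericMatrix thickX, NumericMatrix thinX,
                     IntegerVector headState, IntegerVector boundSite,
                     IntegerVector headThick, IntegerVector headCrown,
                     IntegerVector headThin,
                     double hs, double am, double radCC, double titinRest) {
  Lattice L;
  L.thickX = clone(thickX);
  L.thinX = clone(thinX);
  L.headState = headState;
  L.boundSite = boundSite;
  L.headThick = headThick;
  L.headCrown = headCrown;
  L.headThin = headThin;
  L.nc = thickX.nrow(); L.nf = thickX.ncol();
  L.nn = thinX.nrow(); L.ng = thinX.ncol();
  L.nh = headState.size();
  L.hs = hs; L.am = am;
  L.radOffset = radCC - am;
  L.titinRest = titinRest;
  return L;
}

} // namespace

// [[Rcpp::export]]
List solve_eq_cpp(NumericMatrix thickX, NumericMatrix thinX,
                  IntegerVector headState, IntegerVector boundSite,
                  IntegerVector headThick, IntegerVector headCrown,
                  IntegerVector headThin,
                  double hs, double am, double radCC, double titinRest,
                  List springs, List titin, List xbL,
                  double tol, int maxIter, bool trace) {
  Lattice L = latticeFromR(thickX, thinX, headState, boundSite, headThick,
                           headCrown, headThin, hs, am, radCC, titinRest);
  SP sp = asSP(springs);
  TI ti = asTI(titin);
  XB xb = asXB(xbL);
  double residual = NA_REAL;
  std::vector<double> etr;
  bool ok = solveEq(L, sp, ti, xb, tol, maxIter, residual,
                    trace ? &etr : nullptr);
  int iters = trace ? (int)etr.size() : NA_INTEGER;
  return List::create(_["thickX"] = L.thickX, _["thinX"] = L.thinX,
                      _["converged"] = ok, _["residual"] = residual,
                      _["iterations"] = iters,
                      _["energy"] = trace ? wrap(etr) : R_NilValue);
}

// Cross-validation export: per-geometry energies, axial force gradient and
// bound-state rates, for comparison against the R reference implementation.
// [[Rcpp::export]]
DataFrame xb_diag_cpp(NumericVector dx, double am, List xbL, List rcL,
                      double AP) {
  XB xb = asXB(xbL);
  RC rc = asRC(rcL);
  int n = dx.size();
  NumericVector ew(n), es(n), gw(n), gs(n), r21(n), r23(n), r32(n), r31(n);
  for (int i = 0; i < n; ++i) {
    double r = std::sqrt(dx[i] * dx[i] + am * am), th = std::atan2(am, dx[i]);
    ew[i] = stateEnergy(r, th, false, xb);
    es[i] = stateEnergy(r, th, true, xb);
    gw[i] = gAxial(dx[i], am, false, xb);
    gs[i] = gAxial(dx[i], am, true, xb);
    double U1 = ew[i] / xb.kT - rc.dGw, U2 = es[i] / xb.kT - rc.dGs;
    double tipX = xb.rW * std::cos(xb.thW);
    double dW = std::fabs(tipX - dx[i]);
    double base = rc.tau * std::exp(-dW * dW) + rc.b0;
    r21[i] = base * expCap(U1);
    r23[i] = rc.A * (1.0 + std::tanh(rc.C + rc.D * (U1 - U2)));
    r32[i] = r23[i] * expCap(U2 - U1);
    r31[i] = std::max(0.0, rc.G * (rc.r31shift ? U2 : es[i] / xb.kT) + rc.H);
  }
  (void)AP;
  return DataFrame::create(_["ew"] = ew, _["es"] = es, _["gw"] = gw,
                           _["gs"] = gs, _["r21"] = r21, _["r23"] = r23,
                           _["r32"] = r32, _["r31"] = r31);
}

// Integrated protocol loop. drive vectors have one entry per step:
// hsV/amV are the length and AM spacing at the END of each step, apV the
// actin permissiveness during the step. Records are taken after the force
// balance of each step.
// [[Rcpp::export]]
List sim_core(NumericMatrix thickX, NumericMatrix thinX,
              IntegerVector headState0, NumericVector headR0,
              NumericVector headTheta0, IntegerVector boundSite0,
              IntegerVector siteOcc0,
              IntegerVector headThick, IntegerVector headCrown,
              IntegerVector headThin, IntegerVector headPhase,
              double hs0, double am0, double radOffset, double titinRest,
              List xbL, List rcL, List springs, List titin,
              double tol, int maxIter,
              NumericVector hsV, NumericVector amV, NumericVector apV,
              double dt) {
  XB xb = asXB(xbL);
  RC rc = asRC(rcL);
  SP sp = asSP(springs);
  TI ti = asTI(titin);
  Lattice L = latticeFromR(thickX, thinX, clone(headState0),
                           clone(boundSite0), headThick, headCrown, headThin,
                           hs0, am0, am0 + radOffset, titinRest);
  L.radOffset = radOffset;
  NumericVector headR = clone(headR0), headTheta = clone(headTheta0);
  IntegerVector siteOcc = clone(siteOcc0);
  IntegerVector& state = L.headState;
  IntegerVector& site = L.boundSite;

  int nsteps = hsV.size();
  NumericVector force(nsteps), fStrong(nsteps), fWeak(nsteps),
      titinF(nsteps);
  IntegerVector nWeak(nsteps), nStrong(nsteps);

  double sigR = std::sqrt(xb.kT / xb.kr), sigT = std::sqrt(xb.kT / xb.kth);
  double tipWx = xb.rW * std::cos(xb.thW);

  for (int t = 0; t < nsteps; ++t) {
    double AP = apV[t];
    // 1) thermal forcing of unbound heads
    for (int i = 0; i < L.nh; ++i) {
      if (state[i] != 1) continue;
      double r = R::rnorm(xb.rW, sigR);
      while (r <= 0) r = R::rnorm(xb.rW, sigR);
      headR[i] = r;
      headTheta[i] = R::rnorm(xb.thW, sigT);
    }
    // 2) stochastic transitions at the current geometry
    for (int i = 0; i < L.nh; ++i) {
      int f = headThick[i] - 1, c = headCrown[i] - 1;
      int g = headThin[i] - 1;
      double xa = L.thickX(c, f);
      if (state[i] == 1) {
        double tipX = xa + headR[i] * std::cos(headTheta[i]);
        // axially nearest eligible node (phase: j %% 3, 1-based j)
        int ph = headPhase[i];
        int jstart = (ph == 0) ? 3 : ph;
        int jbest = -1;
        double bestd = R_PosInf;
        for (int j = jstart; j <= L.nn; j += 3) {
          double dax = std::fabs(tipX - L.thinX(j - 1, g));
          if (dax <= bestd) { bestd = dax; jbest = j; }
        }
        if (jbest < 0) continue;
        int jsel = -1;
        double dsel = R_PosInf;
        for (int k = -1; k <= 1; ++k) {
          int j = jbest + 3 * k;
          if (j < 1 || j > L.nn) continue;
          if (siteOcc[g * L.nn + j - 1] != 0) continue;
          double d = std::fabs(tipX - L.thinX(j - 1, g));
          if (d <= dsel) { dsel = d; jsel = j; }
        }
        if (jsel < 0) continue;
        double p12 = 1.0 - std::exp(-AP * (rc.tau * std::exp(-dsel * dsel) +
                                           rc.b0) * dt);
        if (R::runif(0, 1) < p12) {
          state[i] = 2;
          site[i] = g * L.nn + jsel;
          siteOcc[site[i] - 1] = i + 1;
          double dxb = L.thinX(jsel - 1, g) - xa;
          headR[i] = std::sqrt(dxb * dxb + L.am * L.am);
          headTheta[i] = std::atan2(L.am, dxb);
        }
      } else {
        int j = site[i] - g * L.nn;
        double xs = L.thinX(j - 1, g);
        double dxb = xs - xa;
        double r = std::sqrt(dxb * dxb + L.am * L.am);
        double th = std::atan2(L.am, dxb);
        double ew = stateEnergy(r, th, false, xb) / xb.kT;
        double es = stateEnergy(r, th, true, xb) / xb.kT;
        double U1 = ew - rc.dGw, U2 = es - rc.dGs;
        double r23 = rc.A * (1.0 + std::tanh(rc.C + rc.D * (U1 - U2)));
        if (state[i] == 2) {
          double ddx = xa + tipWx - xs;
          double dW2 = ddx * ddx;
          double r21 = (rc.tau * std::exp(-dW2) + rc.b0) * expCap(U1);
          double tot = r21 + r23;
          if (tot > 0) {
            double ptot = 1.0 - std::exp(-tot * dt);
            double u = R::runif(0, 1);
            if (u < ptot * r21 / tot) {
              siteOcc[site[i] - 1] = 0;
              site[i] = 0;
              state[i] = 1;
              headR[i] = xb.rW; headTheta[i] = xb.thW;
            } else if (u < ptot) {
              state[i] = 3;
            }
          }
        } else {
          double r32 = r23 * expCap(U2 - U1);
          double r31 = std::max(0.0, rc.G * (rc.r31shift ? U2 : es) + rc.H);
          double tot = r32 + r31;
          if (tot > 0) {
            double ptot = 1.0 - std::exp(-tot * dt);
            double u = R::runif(0, 1);
            if (u < ptot * r32 / tot) {
              state[i] = 2;
            } else if (u < ptot) {
              siteOcc[site[i] - 1] = 0;
              site[i] = 0;
              state[i] = 1;
              headR[i] = xb.rW; headTheta[i] = xb.thW;
            }
          }
        }
      }
    }
    // 3) prescribed length and lattice-spacing update
    double delta = hsV[t] - L.hs;
    if (delta != 0.0)
      for (int g = 0; g < L.ng; ++g)
        for (int j = 0; j < L.nn; ++j) L.thinX(j, g) += delta;
    L.hs = hsV[t];
    L.am = amV[t];
    // 4) force balance
    double residual;
    if (!solveEq(L, sp, ti, xb, tol, maxIter, residual, nullptr))
      stop("equilibrium solver failed at step %d (residual %.3g pN)",
           t + 1, residual);
    // bound-head geometry and records
    double fS = 0, fW = 0;
    int nW = 0, nS = 0;
    for (int i = 0; i < L.nh; ++i) {
      if (state[i] <= 1) continue;
      int f = headThick[i] - 1, c = headCrown[i] - 1;
      int g = headThin[i] - 1, j = site[i] - g * L.nn;
      double dxb = L.thinX(j - 1, g) - L.thickX(c, f);
      headR[i] = std::sqrt(dxb * dxb + L.am * L.am);
      headTheta[i] = std::atan2(L.am, dxb);
      double gax = gAxial(dxb, L.am, state[i] == 3, xb);
      if (state[i] == 2) { fW += gax; ++nW; } else { fS += gax; ++nS; }
    }
    double fb = 0;
    for (int f = 0; f < L.nf; ++f)
      fb += sp.kthick * (L.thickX(0, f) - sp.l0thick);
    double tsum = 0;
    for (int f = 0; f < L.nf; ++f)
      tsum += titinAxial(L.thickX(L.nc - 1, f), L.hs, L.am + radOffset,
                         L.titinRest, ti);
    force[t] = fb;
    fStrong[t] = fS; fWeak[t] = fW;
    titinF[t] = tsum;
    nWeak[t] = nW; nStrong[t] = nS;
  }

  return List::create(
      _["force"] = force, _["fStrong"] = fStrong, _["fWeak"] = fWeak,
      _["titinF"] = titinF, _["nWeak"] = nWeak, _["nStrong"] = nStrong,
      _["thickX"] = L.thickX, _["thinX"] = L.thinX,
      _["headState"] = state, _["headR"] = headR,
      _["headTheta"] = headTheta, _["boundSite"] = site,
      _["siteOcc"] = siteOcc);
}
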