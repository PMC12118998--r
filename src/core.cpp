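// Numeric core of the slug simulator.
//
// Geometry conventions: each cell is an ellipsoid with orthonormal body frame
// R (columns = unit axis vectors a,b,c in world coordinates) and semi-axes s
// (um).  All forces are in g*um/s^2, drags in g/s, time in s.  The overdamped
// force balance M p' = F has scalar-times-identity 3x3 blocks, so the 3n x 3n
// system reduces to an n x n solve with three right-hand sides.
//
// Hot paths (pair collection, shape fits, per-axis relaxation) use fixed-size
// hand-rolled linear algebra; Armadillo is used only for the n x n drag solve
// and R interop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::cube;

static const double EPS_DIST = 1e-9;   // coincident-center tolerance (um)

// ---------------------------------------------------------------------------
// small dense solvers (Gaussian elimination with partial pivoting)
// ---------------------------------------------------------------------------

template <int N>
static bool solveN(double A[N][N], double b[N]) {
  int piv[N];
  for (int i = 0; i < N; ++i) piv[i] = i;
  for (int c = 0; c < N; ++c) {
    int p = c;
    double mx = std::fabs(A[c][c]);
    for (int r2 = c + 1; r2 < N; ++r2)
      if (std::fabs(A[r2][c]) > mx) { mx = std::fabs(A[r2][c]); p = r2; }
    if (mx < 1e-300) return false;
    if (p != c) {
      for (int k = 0; k < N; ++k) std::swap(A[c][k], A[p][k]);
      std::swap(b[c], b[p]);
    }
    double d = A[c][c];
    for (int r2 = c + 1; r2 < N; ++r2) {
      double f = A[r2][c] / d;
      if (f == 0.0) continue;
      for (int k = c; k < N; ++k) A[r2][k] -= f * A[c][k];
      b[r2] -= f * b[c];
    }
  }
  for (int c = N - 1; c >= 0; --c) {
    double s = b[c];
    for (int k = c + 1; k < N; ++k) s -= A[c][k] * b[k];
    b[c] = s / A[c][c];
  }
  return true;
}

// ---------------------------------------------------------------------------
// elementary geometry
// ---------------------------------------------------------------------------

static inline double supportRadius3(const double *s, const double *u) {
  double q = (u[0] / s[0]) * (u[0] / s[0]) + (u[1] / s[1]) * (u[1] / s[1]) +
             (u[2] / s[2]) * (u[2] / s[2]);
  return 1.0 / std::sqrt(q);
}

// area of the circle of intersection of two spheres (radii r1, r2, center
// distance D).  Deep containment (D <= |r1-r2|) has no intersection circle;
// near-coincident centers are capped at the smaller great circle.
static inline double lensArea(double r1, double r2, double D) {
  if (D >= r1 + r2) return 0.0;
  double mn = std::min(r1, r2);
  if (D <= EPS_DIST) return M_PI * mn * mn;
  if (D <= std::fabs(r1 - r2)) return 0.0;
  double x = (D * D - r2 * r2 + r1 * r1) / (2.0 * D);
  double h2 = r1 * r1 - x * x;
  if (h2 <= 0.0) return 0.0;
  return M_PI * h2;
}

// body-frame components of a world vector: u_body = R^T v
static inline void toBody(const double *R, const double *v, double *u) {
  u[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
  u[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
  u[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

struct PairRec {
  int i, j;
  double vhat[3];    // unit vector from center i to center j (world)
  double dist;       // center distance
  double di, dj;     // support distances along +/- vhat
  double d0;         // overlap distance, >= 0
};

// all pairs within interaction range (enlarged-adhesion reach or nucleus
// range); frames passed as raw column-major 3x3 blocks
static void collectPairs(const mat &P, const double *Aptr, const mat &S,
                         std::vector<PairRec> &out) {
  int n = P.n_rows;
  out.clear();
  for (int i = 0; i < n; ++i) {
    double smaxI =
        std::max(S(i, 0), std::max(S(i, 1), S(i, 2)));
    for (int j = i + 1; j < n; ++j) {
      double smaxJ = std::max(S(j, 0), std::max(S(j, 1), S(j, 2)));
      double v[3] = {P(j, 0) - P(i, 0), P(j, 1) - P(i, 1), P(j, 2) - P(i, 2)};
      double d2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
      double reach = 1.4 * (smaxI + smaxJ);
      if (d2 >= reach * reach && d2 >= 16.0) continue;
      double dist = std::sqrt(d2);
      double vhat[3];
      if (dist <= EPS_DIST) {
        // coincident centers: deep overlap along a random direction
        double ct = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
        double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
        vhat[0] = st * std::cos(ph); vhat[1] = ct; vhat[2] = st * std::sin(ph);
        dist = EPS_DIST;
      } else {
        vhat[0] = v[0] / dist; vhat[1] = v[1] / dist; vhat[2] = v[2] / dist;
      }
      double sI[3] = {S(i, 0), S(i, 1), S(i, 2)};
      double sJ[3] = {S(j, 0), S(j, 1), S(j, 2)};
      double ub[3], mvhat[3] = {-vhat[0], -vhat[1], -vhat[2]};
      toBody(Aptr + 9 * i, vhat, ub);
      double di = supportRadius3(sI, ub);
      toBody(Aptr + 9 * j, mvhat, ub);
      double dj = supportRadius3(sJ, ub);
      if (dist >= 1.4 * (di + dj) && dist >= 4.0) continue;
      PairRec r;
      r.i = i; r.j = j;
      r.vhat[0] = vhat[0]; r.vhat[1] = vhat[1]; r.vhat[2] = vhat[2];
      r.dist = dist; r.di = di; r.dj = dj;
      r.d0 = std::max(0.0, di + dj - dist);
      out.push_back(r);
    }
  }
}

// ---------------------------------------------------------------------------
// deformed-radius fitting
// ---------------------------------------------------------------------------
// Given m boundary target points (unit directions U (rows, body frame) and
// target center-to-boundary distances d), find semi-axes s such that the
// ellipsoid passes through the targets.  m = 1: volume-conserving,
// sum-of-axes-minimizing solve; m = 2: exact solve with the volume
// constraint; m >= 3: bounded least squares with a mild volume residual.

struct FitResult {
  double s[3];
  double residual;   // sum of squared point misfits (um^2), after clamping
  int m;             // number of targets
  bool converged;
};

static double pointMisfit(const double *s, const std::vector<double> &U,
                          const std::vector<double> &d) {
  double r = 0.0;
  for (size_t j = 0; j < d.size(); ++j) {
    double e = supportRadius3(s, &U[3 * j]) - d[j];
    r += e * e;
  }
  return r;
}

static inline void clampAxes(double *s, double lo, double hi) {
  for (int k = 0; k < 3; ++k) s[k] = std::min(hi, std::max(lo, s[k]));
}

// Levenberg-Marquardt on point residuals plus a volume residual of weight wV
static bool fitLM(double *s, const std::vector<double> &U,
                  const std::vector<double> &d, double V0, double wV,
                  int maxit) {
  int m = d.size();
  double lam = 1e-3;
  std::vector<double> r(m + 1), J(3 * (m + 1));
  for (int it = 0; it < maxit; ++it) {
    for (int j = 0; j < m; ++j) {
      const double *u = &U[3 * j];
      double sr = supportRadius3(s, u);
      r[j] = sr - d[j];
      double sr3 = sr * sr * sr;
      for (int k = 0; k < 3; ++k)
        J[3 * j + k] = sr3 * u[k] * u[k] / (s[k] * s[k] * s[k]);
    }
    double prod = s[0] * s[1] * s[2];
    r[m] = wV * (prod / V0 - 1.0);
    for (int k = 0; k < 3; ++k) J[3 * m + k] = wV * prod / (V0 * s[k]);
    double f0 = 0.0;
    for (int j = 0; j <= m; ++j) f0 += r[j] * r[j];
    double H[3][3] = {{0}}, g[3] = {0, 0, 0};
    for (int j = 0; j <= m; ++j)
      for (int a = 0; a < 3; ++a) {
        g[a] += J[3 * j + a] * r[j];
        for (int b = 0; b < 3; ++b) H[a][b] += J[3 * j + a] * J[3 * j + b];
      }
    bool improved = false;
    for (int tries = 0; tries < 12; ++tries) {
      double Hl[3][3], step[3];
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) Hl[a][b] = H[a][b];
        Hl[a][a] += lam * (H[a][a] + 1e-12);
        step[a] = -g[a];
      }
      if (!solveN<3>(Hl, step)) { lam *= 10.0; continue; }
      double sn[3];
      double stepNorm = 0.0;
      for (int k = 0; k < 3; ++k) {
        sn[k] = std::min(9.0, std::max(1.5, s[k] + step[k]));
        stepNorm += step[k] * step[k];
      }
      double f1 = 0.0;
      for (int j = 0; j < m; ++j) {
        double e = supportRadius3(sn, &U[3 * j]) - d[j];
        f1 += e * e;
      }
      double rv = wV * (sn[0] * sn[1] * sn[2] / V0 - 1.0);
      f1 += rv * rv;
      if (f1 <= f0) {
        s[0] = sn[0]; s[1] = sn[1]; s[2] = sn[2];
        if (stepNorm < 1e-22) return true;
        lam = std::max(1e-12, lam * 0.3);
        improved = true;
        break;
      }
      lam *= 10.0;
    }
    if (!improved) return true;  // stalled at a (local) minimum
  }
  return false;
}

// can any semi-axis vector within the iteration box meet the target?
static inline bool targetFeasible(const double *u, double d) {
  double lo3[3] = {1.5, 1.5, 1.5}, hi3[3] = {9.0, 9.0, 9.0};
  return d >= supportRadius3(lo3, u) - 1e-9 &&
         d <= supportRadius3(hi3, u) + 1e-9;
}

// single target: minimize a+b+c subject to support(s,u) = d and abc = V0,
// via damped Newton on the KKT system
static bool fitSingleKKT(double *s, const double *u, double d, double V0) {
  // least-squares init of the multipliers from stationarity at the start
  double l1, l2;
  {
    double C[3][2], CtC[2][2] = {{0, 0}, {0, 0}}, Ctb[2] = {0, 0};
    double prod = s[0] * s[1] * s[2];
    for (int k = 0; k < 3; ++k) {
      C[k][0] = -2.0 * u[k] * u[k] / (s[k] * s[k] * s[k]);
      C[k][1] = prod / s[k];
      for (int a = 0; a < 2; ++a) {
        Ctb[a] += C[k][a] * (-1.0);
        for (int b = 0; b < 2; ++b) CtC[a][b] += C[k][a] * C[k][b];
      }
    }
    double A2[2][2] = {{CtC[0][0], CtC[0][1]}, {CtC[1][0], CtC[1][1]}};
    double b2[2] = {Ctb[0], Ctb[1]};
    if (!solveN<2>(A2, b2)) { b2[0] = 0.0; b2[1] = 0.0; }
    l1 = b2[0]; l2 = b2[1];
  }
  double target = 1.0 / (d * d);
  double bestCv = std::numeric_limits<double>::infinity();
  int stagn = 0;
  for (int it = 0; it < 200; ++it) {
    double prod = s[0] * s[1] * s[2];
    double r[5], Jm[5][5] = {{0}};
    double g1 = -target;
    for (int k = 0; k < 3; ++k) {
      double uk2 = u[k] * u[k], sk = s[k];
      g1 += uk2 / (sk * sk);
      r[k] = 1.0 + l1 * (-2.0 * uk2 / (sk * sk * sk)) + l2 * (prod / sk);
      Jm[k][k] = 6.0 * l1 * uk2 / (sk * sk * sk * sk);
      for (int m2 = 0; m2 < 3; ++m2)
        if (m2 != k) Jm[k][m2] = l2 * prod / (sk * s[m2]);
      Jm[k][3] = -2.0 * uk2 / (sk * sk * sk);
      Jm[k][4] = prod / sk;
      Jm[3][k] = -2.0 * uk2 / (sk * sk * sk);
      Jm[4][k] = prod / sk;
    }
    r[3] = g1;
    r[4] = prod - V0;
    double cv = std::fabs(supportRadius3(s, u) - d) +
                std::fabs(prod - V0) / V0;
    if (cv < 1e-9 &&
        std::fabs(r[0]) + std::fabs(r[1]) + std::fabs(r[2]) < 1e-6)
      return true;
    if (cv < 0.9 * bestCv) { bestCv = cv; stagn = 0; }
    else if (++stagn > 10) return false;      // not converging; use fallback
    double rhs[5];
    for (int k = 0; k < 5; ++k) rhs[k] = -r[k];
    if (!solveN<5>(Jm, rhs)) return false;
    double mx = std::max(std::fabs(rhs[0]),
                         std::max(std::fabs(rhs[1]), std::fabs(rhs[2])));
    double damp = (mx > 0.5) ? 0.5 / mx : 1.0;
    for (int k = 0; k < 3; ++k)
      s[k] = std::min(9.0, std::max(1.5, s[k] + damp * rhs[k]));
    l1 += damp * rhs[3];
    l2 += damp * rhs[4];
  }
  return false;
}

// two targets: exact 3x3 Newton on the two support constraints + volume
static bool fitDoubleNewton(double *s, const std::vector<double> &U,
                            const std::vector<double> &d, double V0) {
  double bestCv = std::numeric_limits<double>::infinity();
  int stagn = 0;
  for (int it = 0; it < 200; ++it) {
    double r[3], Jm[3][3];
    for (int j = 0; j < 2; ++j) {
      const double *u = &U[3 * j];
      double g = -1.0 / (d[j] * d[j]);
      for (int k = 0; k < 3; ++k) {
        g += u[k] * u[k] / (s[k] * s[k]);
        Jm[j][k] = -2.0 * u[k] * u[k] / (s[k] * s[k] * s[k]);
      }
      r[j] = g;
    }
    double prod = s[0] * s[1] * s[2];
    r[2] = prod - V0;
    for (int k = 0; k < 3; ++k) Jm[2][k] = prod / s[k];
    double cv = std::fabs(supportRadius3(s, &U[0]) - d[0]) +
                std::fabs(supportRadius3(s, &U[3]) - d[1]) +
                std::fabs(prod - V0) / V0;
    if (cv < 1e-9) return true;
    if (cv < 0.9 * bestCv) { bestCv = cv; stagn = 0; }
    else if (++stagn > 10) return false;      // not converging; use fallback
    double rhs[3] = {-r[0], -r[1], -r[2]};
    if (!solveN<3>(Jm, rhs)) return false;
    double mx = std::max(std::fabs(rhs[0]),
                         std::max(std::fabs(rhs[1]), std::fabs(rhs[2])));
    double damp = (mx > 0.5) ? 0.5 / mx : 1.0;
    for (int k = 0; k < 3; ++k)
      s[k] = std::min(9.0, std::max(1.5, s[k] + damp * rhs[k]));
  }
  return false;
}

static FitResult fitRadii(const double *sCur, const std::vector<double> &U,
                          const std::vector<double> &d, const double *lo,
                          const double *hi, double V0,
                          const double *init = nullptr) {
  FitResult out;
  out.m = d.size();
  out.s[0] = sCur[0]; out.s[1] = sCur[1]; out.s[2] = sCur[2];
  out.converged = true;
  if (out.m == 0) { out.residual = 0.0; return out; }
  double s[3];
  for (int k = 0; k < 3; ++k) {
    s[k] = init ? init[k] : sCur[k];
    s[k] = std::min(9.0, std::max(1.5, s[k]));
  }
  bool ok = false;
  bool feasible = true;
  for (int j = 0; j < out.m; ++j)
    if (!targetFeasible(&U[3 * j], d[j])) { feasible = false; break; }
  if (out.m == 1) {
    ok = feasible && fitSingleKKT(s, &U[0], d[0], V0);
    if (!ok) {
      s[0] = sCur[0]; s[1] = sCur[1]; s[2] = sCur[2];
      ok = fitLM(s, U, d, V0, 10.0, 60);   // bound-clamped best fit
    }
  } else if (out.m == 2) {
    ok = feasible && fitDoubleNewton(s, U, d, V0);
    if (!ok) {
      s[0] = sCur[0]; s[1] = sCur[1]; s[2] = sCur[2];
      ok = fitLM(s, U, d, V0, 10.0, 60);
    }
  } else {
    ok = fitLM(s, U, d, V0, 1.0, 100);
  }
  if (!ok) {
    out.converged = false;              // keep previous shape
    out.residual = pointMisfit(sCur, U, d);
    return out;
  }
  for (int k = 0; k < 3; ++k)
    s[k] = std::min(hi[k], std::max(lo[k], s[k]));
  out.s[0] = s[0]; out.s[1] = s[1]; out.s[2] = s[2];
  out.residual = pointMisfit(s, U, d);
  return out;
}

// targets for one cell from its overlap records; the deep-overlap rule
// applies in the single-neighbour case
static void cellTargets(int ci, const std::vector<PairRec> &recs,
                        const std::vector<int> &recIdx, const double *Aptr,
                        std::vector<double> &U, std::vector<double> &d) {
  int m = recIdx.size();
  U.resize(3 * m);
  d.resize(m);
  for (int q = 0; q < m; ++q) {
    const PairRec &r = recs[recIdx[q]];
    bool first = (r.i == ci);
    double vh[3];
    if (first) {
      vh[0] = r.vhat[0]; vh[1] = r.vhat[1]; vh[2] = r.vhat[2];
    } else {
      vh[0] = -r.vhat[0]; vh[1] = -r.vhat[1]; vh[2] = -r.vhat[2];
    }
    double dSelf = first ? r.di : r.dj;
    double dOther = first ? r.dj : r.di;
    toBody(Aptr + 9 * ci, vh, &U[3 * q]);
    double dn;
    if (m == 1 && r.d0 >= r.dist)
      dn = r.dist - 0.7 * dOther;   // neighbour boundary beyond the center
    else
      dn = dSelf - 0.5 * r.d0;
    d[q] = std::max(0.5, dn);
  }
}

// ---------------------------------------------------------------------------
// standard-linear-solid axis dynamics
// ---------------------------------------------------------------------------
// u' = (kSer/mu * (f + lambda - kPar*u) + df/dt) / (kPar + kSer)
// with lambda coupling the three axes through d(abc)/dt = 0.

// continuous-time lambda: the affine solve of the volume-rate equation
static double solveLambda(const double *u, const double *f, const double *kPar,
                          const double *kSer, const double *muD,
                          const double *rest) {
  double num = 0.0, den = 0.0;
  for (int k = 0; k < 3; ++k) {
    double Bk = kSer[k] / (muD[k] * (kPar[k] + kSer[k]));
    double Ak = Bk * (f[k] - kPar[k] * u[k]);
    double w = 1.0;
    for (int m2 = 0; m2 < 3; ++m2)
      if (m2 != k) w *= (rest[m2] + u[m2]);
    num += w * Ak;
    den += w * Bk;
  }
  if (std::fabs(den) < 1e-300) return 0.0;
  return -num / den;
}

// exact exponential update of the affine ODE over dt at fixed f and lambda;
// E[k] = exp(-dt/tau_k) may be precomputed by the caller.  lambdaMode 1
// projects lambda so the discrete update conserves the product of the
// semi-axes, lambdaMode 0 forces lambda = 0.
static void stepAxesExp(const double *u, const double *f, const double *kPar,
                        const double *kSer, const double *muD,
                        const double *rest, double dt, int lambdaMode,
                        const double *Epre, double *un, double *lambdaOut) {
  double E[3], dU[3];
  for (int k = 0; k < 3; ++k) {
    if (Epre) {
      E[k] = Epre[k];
    } else {
      double tau = muD[k] * (kPar[k] + kSer[k]) / (kPar[k] * kSer[k]);
      E[k] = std::exp(-dt / tau);
    }
    dU[k] = (1.0 - E[k]) / kPar[k];
  }
  double lam = 0.0;
  if (lambdaMode == 1) {
    double Vtarget =
        (rest[0] + u[0]) * (rest[1] + u[1]) * (rest[2] + u[2]);
    lam = solveLambda(u, f, kPar, kSer, muD, rest);
    for (int it = 0; it < 60; ++it) {
      double x[3];
      for (int k = 0; k < 3; ++k) {
        double uInf = (f[k] + lam) / kPar[k];
        x[k] = rest[k] + uInf + (u[k] - uInf) * E[k];
      }
      double h = x[0] * x[1] * x[2] - Vtarget;
      if (std::fabs(h) < 1e-13 * std::fabs(Vtarget)) break;
      double hp = dU[0] * x[1] * x[2] + dU[1] * x[0] * x[2] +
                  dU[2] * x[0] * x[1];
      if (std::fabs(hp) < 1e-300) break;
      lam -= h / hp;
    }
  }
  for (int k = 0; k < 3; ++k) {
    double uInf = (f[k] + lam) / kPar[k];
    un[k] = uInf + (u[k] - uInf) * E[k];
  }
  if (lambdaOut) *lambdaOut = lam;
}

// ---------------------------------------------------------------------------
// parameters
// ---------------------------------------------------------------------------

struct Params {
  arma::vec kappa, cosPsi;       // per cell
  mat kPar, kSer, muD, rest;     // n x 3
  arma::vec V0;                  // per-cell conserved semi-axis product
  mat lo, hi;                    // per-cell per-axis shape bounds
  mat Erelax;                    // per-cell exp(-Delta/tau) per axis, where
                                 // Delta is the shape-lag interval
  double muF, muCell, rho, alpha;
  double boxW, boundR;
  double gammaRad, rotInc;
  int resampleEvery;
  double dt;
  int shapeEvery;                // steps per shape update (lag interval/dt)
  int integrator;                // 0 = euler, 1 = midpoint RK2
};

static Params unpackParams(const List &pl) {
  Params p;
  p.kappa = as<arma::vec>(pl["kappa"]);
  p.cosPsi = arma::cos(as<arma::vec>(pl["psi"]) * M_PI / 180.0);
  p.kPar = as<mat>(pl["kPar"]);
  p.kSer = as<mat>(pl["kSer"]);
  p.muD = as<mat>(pl["muDash"]);
  p.rest = as<mat>(pl["rest"]);
  p.V0 = p.rest.col(0) % p.rest.col(1) % p.rest.col(2);
  p.lo = p.rest - 1.0;
  p.hi = p.rest + 1.0;
  p.muF = as<double>(pl["muF"]);
  p.muCell = as<double>(pl["muCell"]);
  p.rho = as<double>(pl["rho"]);
  p.alpha = as<double>(pl["alpha"]);
  p.boxW = as<double>(pl["boxWidth"]);
  p.boundR = as<double>(pl["boundaryRadius"]);
  p.gammaRad = as<double>(pl["gamma"]) * M_PI / 180.0;
  p.rotInc = as<double>(pl["rotIncrement"]) * M_PI / 180.0;
  p.resampleEvery = as<int>(pl["resampleEvery"]);
  p.dt = as<double>(pl["dt"]);
  p.shapeEvery = as<int>(pl["shapeUpdateEvery"]);
  std::string integ = as<std::string>(pl["integrator"]);
  p.integrator = (integ == "euler") ? 0 : (integ == "rk2" ? 1 : 2);
  int n = p.rest.n_rows;
  double Delta = p.dt * p.shapeEvery;
  p.Erelax.set_size(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double tau = p.muD(i, k) * (p.kPar(i, k) + p.kSer(i, k)) /
                   (p.kPar(i, k) * p.kSer(i, k));
      p.Erelax(i, k) = std::exp(-Delta / tau);
    }
  return p;
}

static inline double boundary1d(double px, double rho, double r, double W) {
  if (px < 0.0) return r * rho;
  if (px < r) return rho * (r - px);
  if (px > W) return -r * rho;
  if (px > W - r) return rho * (W - r - px);
  return 0.0;
}

static inline double nucleusMag(double dist) {
  double dEff = std::max(dist, 0.5);  // cap prevents overflow at tiny gaps
  return 10.0 * (std::exp(3.0 * (1.0 / dEff - 0.25)) - 1.0);
}

// ---------------------------------------------------------------------------
// forces
// ---------------------------------------------------------------------------

struct ForceEval {
  mat Ftot;        // n x 3
  mat D;           // n x n scalar drag matrix
  // optional breakdown
  mat motive, motiveReact, adhesion, boundX, boundZ, overlap, overlapReact,
      nucleus;
  std::vector<PairRec> recs;
  mat Sfit;        // fitted semi-axes per cell (rows)
  arma::ivec fitOk;
  // scratch reused across evaluations
  std::vector<std::vector<int>> nbr;
  std::vector<double> Utg, dtg;
  mat warm;        // previous fitted semi-axes, used as optimizer start
};

static void computeForces(const mat &P, const double *Aptr, const mat &S,
                          const Params &par, bool breakdown, ForceEval &ev) {
  int n = P.n_rows;
  ev.Ftot.zeros(n, 3);
  if (breakdown) {
    ev.motive.zeros(n, 3); ev.motiveReact.zeros(n, 3);
    ev.adhesion.zeros(n, 3); ev.boundX.zeros(n, 3); ev.boundZ.zeros(n, 3);
    ev.overlap.zeros(n, 3); ev.overlapReact.zeros(n, 3);
    ev.nucleus.zeros(n, 3);
  }
  // motive forces: nearest cell center within the psi cone about the a-axis.
  // A center the cell has already engulfed (inside its own surface) is no
  // anchor for a pseudopod pull and is skipped.
  for (int i = 0; i < n; ++i) {
    if (par.kappa[i] <= 0.0) continue;
    int best = -1;
    double bestDist = std::numeric_limits<double>::infinity();
    const double *a = Aptr + 9 * i;  // first column of the frame
    double sI[3] = {S(i, 0), S(i, 1), S(i, 2)};
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double v[3] = {P(j, 0) - P(i, 0), P(j, 1) - P(i, 1), P(j, 2) - P(i, 2)};
      double dist = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
      if (dist <= EPS_DIST) continue;
      if ((a[0] * v[0] + a[1] * v[1] + a[2] * v[2]) / dist < par.cosPsi[i])
        continue;
      double vhat[3] = {v[0] / dist, v[1] / dist, v[2] / dist};
      double ub[3];
      toBody(Aptr + 9 * i, vhat, ub);
      if (dist <= supportRadius3(sI, ub)) continue;   // engulfed center
      if (dist < bestDist) { bestDist = dist; best = j; }
    }
    if (best < 0) continue;
    for (int k = 0; k < 3; ++k) {
      double fk = par.kappa[i] * (P(best, k) - P(i, k)) / bestDist;
      ev.Ftot(i, k) += fk;       // traction reaction propels the cell
      ev.Ftot(best, k) -= fk;    // pulled neighbour
      if (breakdown) {
        ev.motiveReact(i, k) += fk;
        ev.motive(best, k) -= fk;
      }
    }
  }
  // boundary forces (x and z; y unbounded)
  for (int i = 0; i < n; ++i) {
    double fx = boundary1d(P(i, 0), par.rho, par.boundR, par.boxW);
    double fz = boundary1d(P(i, 2), par.rho, par.boundR, par.boxW);
    ev.Ftot(i, 0) += fx;
    ev.Ftot(i, 2) += fz;
    if (breakdown) { ev.boundX(i, 0) = fx; ev.boundZ(i, 2) = fz; }
  }
  // pairwise records and per-cell shape fits
  collectPairs(P, Aptr, S, ev.recs);
  ev.nbr.assign(n, std::vector<int>());
  for (size_t q = 0; q < ev.recs.size(); ++q)
    if (ev.recs[q].d0 > 0.0) {
      ev.nbr[ev.recs[q].i].push_back(q);
      ev.nbr[ev.recs[q].j].push_back(q);
    }
  ev.Sfit = S;
  ev.fitOk.ones(n);
  if ((int)ev.warm.n_rows != n) ev.warm = S;
  mat axForce(n, 3, arma::fill::zeros);  // body-frame overlap axis forces
  for (int i = 0; i < n; ++i) {
    if (ev.nbr[i].empty()) { ev.warm.row(i) = S.row(i); continue; }
    cellTargets(i, ev.recs, ev.nbr[i], Aptr, ev.Utg, ev.dtg);
    double sCur[3] = {S(i, 0), S(i, 1), S(i, 2)};
    double wrm[3] = {ev.warm(i, 0), ev.warm(i, 1), ev.warm(i, 2)};
    double lo[3] = {par.lo(i, 0), par.lo(i, 1), par.lo(i, 2)};
    double hi[3] = {par.hi(i, 0), par.hi(i, 1), par.hi(i, 2)};
    FitResult fr = fitRadii(sCur, ev.Utg, ev.dtg, lo, hi, par.V0[i], wrm);
    for (int k = 0; k < 3; ++k) {
      ev.Sfit(i, k) = fr.s[k];
      ev.warm(i, k) = fr.s[k];
      axForce(i, k) =
          -(par.kPar(i, k) + par.kSer(i, k)) * (fr.s[k] - S(i, k));
    }
    ev.fitOk[i] = fr.converged ? 1 : 0;
  }
  // pair forces: adhesion, nucleus, overlap push + reaction
  for (const auto &r : ev.recs) {
    int i = r.i, j = r.j;
    // adhesion with enlarged radii (cells grab before touching)
    double dEi = 1.4 * r.di, dEj = 1.4 * r.dj;
    double sum = dEi + dEj;
    double d0E = std::max(0.0, sum - r.dist);
    if (d0E > 0.0 && d0E < 0.3 * sum) {
      double fmag;
      if (d0E <= 0.1 * sum) {
        fmag = par.alpha * lensArea(dEi, dEj, r.dist);
      } else {
        double zbar = lensArea(dEi, dEj, 0.9 * sum);
        double ramp = (0.3 * sum - d0E) / (0.2 * sum);
        fmag = par.alpha * ramp * ramp * zbar;
      }
      for (int k = 0; k < 3; ++k) {
        double fk = fmag * r.vhat[k];
        ev.Ftot(i, k) += fk;
        ev.Ftot(j, k) -= fk;
        if (breakdown) {
          ev.adhesion(i, k) += fk;
          ev.adhesion(j, k) -= fk;
        }
      }
    }
    // nucleus repulsion
    if (r.dist < 4.0) {
      double mag = nucleusMag(r.dist);
      for (int k = 0; k < 3; ++k) {
        double fk = mag * r.vhat[k];
        ev.Ftot(i, k) -= fk;
        ev.Ftot(j, k) += fk;
        if (breakdown) {
          ev.nucleus(i, k) -= fk;
          ev.nucleus(j, k) += fk;
        }
      }
    }
    // overlap (rheological) push from each cell's fitted deformation
    if (r.d0 > 0.0) {
      double mi = 0.0, mj = 0.0;
      const double *Ri = Aptr + 9 * i, *Rj = Aptr + 9 * j;
      for (int k = 0; k < 3; ++k) {
        double proji = Ri[3 * k] * r.vhat[0] + Ri[3 * k + 1] * r.vhat[1] +
                       Ri[3 * k + 2] * r.vhat[2];
        double projj = Rj[3 * k] * r.vhat[0] + Rj[3 * k + 1] * r.vhat[1] +
                       Rj[3 * k + 2] * r.vhat[2];
        mi += axForce(i, k) * std::fabs(proji);
        mj += axForce(j, k) * std::fabs(projj);
      }
      // rheological forces repel: a net pull (volume-conserving expansion
      // of axes oblique to this contact) transmits no force
      mi = std::max(0.0, mi);
      mj = std::max(0.0, mj);
      // i's deformation pushes j forward along vhat (reaction on i), and
      // symmetrically for j's deformation
      double msum = mi + mj;
      for (int k = 0; k < 3; ++k) {
        double fk = msum * r.vhat[k];
        ev.Ftot(j, k) += fk;
        ev.Ftot(i, k) -= fk;
        if (breakdown) {
          ev.overlap(j, k) += mi * r.vhat[k];
          ev.overlapReact(i, k) -= mi * r.vhat[k];
          ev.overlap(i, k) -= mj * r.vhat[k];
          ev.overlapReact(j, k) += mj * r.vhat[k];
        }
      }
    }
  }
  // drag matrix (scalar n x n; each 3x3 block is this scalar times I)
  ev.D.zeros(n, n);
  const double sphereArea = 4.0 * 25.0 * M_PI;
  for (const auto &r : ev.recs) {
    double chi = lensArea(r.di, r.dj, r.dist) / sphereArea;
    if (chi > 0.0) {
      ev.D(r.i, r.j) -= chi * par.muCell;
      ev.D(r.j, r.i) -= chi * par.muCell;
    }
  }
  for (int i = 0; i < n; ++i) {
    double chiSum = 0.0, offSum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      offSum += -ev.D(i, j);               // chi_ij * muCell
      chiSum += -ev.D(i, j) / par.muCell;  // chi_ij
    }
    double chi_ii = std::max(0.0, 1.0 - chiSum);
    ev.D(i, i) = chi_ii * par.muF + offSum + 1e-9 * par.muF;
  }
}

// ---------------------------------------------------------------------------
// orientation control
// ---------------------------------------------------------------------------

static void sampleCap(double gammaRad, double *d) {
  double u1 = unif_rand(), u2 = unif_rand();
  double ct = 1.0 - u1 * (1.0 - std::cos(gammaRad));
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double ph = 2.0 * M_PI * u2;
  d[0] = st * std::cos(ph); d[1] = ct; d[2] = st * std::sin(ph);
}

// rotate the triad (column-major 3x3) about (a x d) by at most inc towards
// d; anti-parallel flips front to back (handedness preserved)
static void rotateTriad(double *R, const double *d, double inc) {
  double a[3] = {R[0], R[1], R[2]};
  double c = a[0] * d[0] + a[1] * d[1] + a[2] * d[2];
  c = std::max(-1.0, std::min(1.0, c));
  double ang = std::acos(c);
  if (ang < 1e-12) return;
  if (ang > M_PI - 1e-9) {
    for (int k = 0; k < 6; ++k) R[k] = -R[k];   // flip a and b columns
    return;
  }
  double w[3] = {a[1] * d[2] - a[2] * d[1], a[2] * d[0] - a[0] * d[2],
                 a[0] * d[1] - a[1] * d[0]};
  double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (wn < 1e-15) return;
  for (int k = 0; k < 3; ++k) w[k] /= wn;
  double th = std::min(inc, ang);
  double ct = std::cos(th), st = std::sin(th), om = 1.0 - ct;
  // Rodrigues rotation matrix
  double Q[9];
  Q[0] = ct + w[0] * w[0] * om;
  Q[1] = w[1] * w[0] * om + w[2] * st;
  Q[2] = w[2] * w[0] * om - w[1] * st;
  Q[3] = w[0] * w[1] * om - w[2] * st;
  Q[4] = ct + w[1] * w[1] * om;
  Q[5] = w[2] * w[1] * om + w[0] * st;
  Q[6] = w[0] * w[2] * om + w[1] * st;
  Q[7] = w[1] * w[2] * om - w[0] * st;
  Q[8] = ct + w[2] * w[2] * om;
  double Rn[9];
  for (int col = 0; col < 3; ++col)
    for (int row = 0; row < 3; ++row)
      Rn[3 * col + row] = Q[row] * R[3 * col] + Q[row + 3] * R[3 * col + 1] +
                          Q[row + 6] * R[3 * col + 2];
  std::copy(Rn, Rn + 9, R);
}

static void reorthonormalize(double *R) {
  double na = std::sqrt(R[0] * R[0] + R[1] * R[1] + R[2] * R[2]);
  for (int k = 0; k < 3; ++k) R[k] /= na;
  double dot = R[0] * R[3] + R[1] * R[4] + R[2] * R[5];
  for (int k = 0; k < 3; ++k) R[3 + k] -= dot * R[k];
  double nb = std::sqrt(R[3] * R[3] + R[4] * R[4] + R[5] * R[5]);
  for (int k = 0; k < 3; ++k) R[3 + k] /= nb;
  R[6] = R[1] * R[5] - R[2] * R[4];
  R[7] = R[2] * R[3] - R[0] * R[5];
  R[8] = R[0] * R[4] - R[1] * R[3];
}

// ---------------------------------------------------------------------------
// time stepping
// ---------------------------------------------------------------------------

struct StepCounters {
  long clampEvents = 0;
  long fitFailures = 0;
};

struct Engine {
  ForceEval ev1, ev2;
  std::vector<PairRec> recs;
  std::vector<std::vector<int>> nbr;
  std::vector<double> Utg, dtg;
};

// one full step of the lagged-shape scheme
static void doStep(mat &P, double *Aptr, mat &S, mat &U, mat &Dstim,
                   const Params &par, long stepIdx, StepCounters &ctr,
                   Engine &eng) {
  int n = P.n_rows;
  // 1. stimulus resampling and incremental rotation
  for (int i = 0; i < n; ++i) {
    if (par.resampleEvery > 0 && stepIdx % par.resampleEvery == 0)
      sampleCap(par.gammaRad, Dstim.colptr(i));
    rotateTriad(Aptr + 9 * i, Dstim.colptr(i), par.rotInc);
    if (stepIdx % 256 == 0) reorthonormalize(Aptr + 9 * i);
  }
  // 2. positions: forces with shapes frozen at the step start
  if (par.integrator == 2) {
    // explicit Euler with local error control: substep so no cell moves
    // farther than maxDisp per force evaluation
    const double maxDisp = 0.1;                   // um
    double remaining = par.dt;
    int guard = 0;
    while (remaining > 1e-15 && ++guard <= 200) {
      computeForces(P, Aptr, S, par, false, eng.ev1);
      mat V = arma::solve(eng.ev1.D, eng.ev1.Ftot,
                          arma::solve_opts::likely_sympd);
      double vmax = arma::abs(V).max();
      double h = remaining;
      if (vmax * h > maxDisp) h = maxDisp / vmax;
      if (h < par.dt / 200) h = par.dt / 200;     // cost guard
      if (h > remaining) h = remaining;
      P += h * V;
      remaining -= h;
    }
  } else {
    computeForces(P, Aptr, S, par, false, eng.ev1);
    mat V1 = arma::solve(eng.ev1.D, eng.ev1.Ftot,
                         arma::solve_opts::likely_sympd);
    if (par.integrator == 1) {
      mat Pm = P + 0.5 * par.dt * V1;
      computeForces(Pm, Aptr, S, par, false, eng.ev2);
      mat V2 = arma::solve(eng.ev2.D, eng.ev2.Ftot,
                           arma::solve_opts::likely_sympd);
      P += par.dt * V2;
    } else {
      P += par.dt * V1;
    }
  }
  // 3. shapes, at the end of each lag interval: instantaneous deformation at
  //    the new positions, then zero-force relaxation to the current time
  if ((stepIdx + 1) % par.shapeEvery != 0) return;
  double Delta = par.dt * par.shapeEvery;
  collectPairs(P, Aptr, S, eng.recs);
  eng.nbr.assign(n, std::vector<int>());
  for (size_t q = 0; q < eng.recs.size(); ++q)
    if (eng.recs[q].d0 > 0.0) {
      eng.nbr[eng.recs[q].i].push_back(q);
      eng.nbr[eng.recs[q].j].push_back(q);
    }
  for (int i = 0; i < n; ++i) {
    if (!eng.nbr[i].empty()) {
      cellTargets(i, eng.recs, eng.nbr[i], Aptr, eng.Utg, eng.dtg);
      double sCur[3] = {S(i, 0), S(i, 1), S(i, 2)};
      double lo[3] = {par.lo(i, 0), par.lo(i, 1), par.lo(i, 2)};
      double hi[3] = {par.hi(i, 0), par.hi(i, 1), par.hi(i, 2)};
      FitResult fr = fitRadii(sCur, eng.Utg, eng.dtg, lo, hi, par.V0[i]);
      if (!fr.converged) ctr.fitFailures++;
      for (int k = 0; k < 3; ++k) U(i, k) = fr.s[k] - par.rest(i, k);
    }
    double zero[3] = {0, 0, 0};
    double uRow[3] = {U(i, 0), U(i, 1), U(i, 2)};
    double kp[3] = {par.kPar(i, 0), par.kPar(i, 1), par.kPar(i, 2)};
    double ks[3] = {par.kSer(i, 0), par.kSer(i, 1), par.kSer(i, 2)};
    double mu[3] = {par.muD(i, 0), par.muD(i, 1), par.muD(i, 2)};
    double rs[3] = {par.rest(i, 0), par.rest(i, 1), par.rest(i, 2)};
    double Ep[3] = {par.Erelax(i, 0), par.Erelax(i, 1), par.Erelax(i, 2)};
    double un[3];
    stepAxesExp(uRow, zero, kp, ks, mu, rs, Delta, 1, Ep, un, nullptr);
    for (int k = 0; k < 3; ++k) {
      double sk = rs[k] + un[k];
      if (sk < par.lo(i, k)) { sk = par.lo(i, k); ctr.clampEvents++; }
      if (sk > par.hi(i, k)) { sk = par.hi(i, k); ctr.clampEvents++; }
      S(i, k) = sk;
      U(i, k) = sk - rs[k];
    }
  }
}

static double relPosition(const mat &P, const LogicalVector &isPst) {
  double ymin = P.col(1).min(), ymax = P.col(1).max();
  double y0 = 0.0; int m = 0;
  for (int i = 0; i < (int)P.n_rows; ++i)
    if (isPst[i]) { y0 += P(i, 1); ++m; }
  if (m == 0 || ymax - ymin < 1e-12) return NA_REAL;
  return (y0 / m - ymin) / (ymax - ymin);
}

// ---------------------------------------------------------------------------
// exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_support_radius(NumericVector semiAxes, NumericVector direction) {
  double s[3] = {semiAxes[0], semiAxes[1], semiAxes[2]};
  double u[3] = {direction[0], direction[1], direction[2]};
  return supportRadius3(s, u);
}

// [[Rcpp::export]]
double cpp_lens_area(double r1, double r2, double dist) {
  return lensArea(r1, r2, dist);
}

// [[Rcpp::export]]
List cpp_overlap_record(NumericVector p1, NumericMatrix R1, NumericVector s1,
                        NumericVector p2, NumericMatrix R2, NumericVector s2) {
  double v[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double dist = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  double vhat[3];
  bool degenerate = false;
  if (dist <= EPS_DIST) {
    degenerate = true;
    double ct = 2.0 * unif_rand() - 1.0, ph = 2.0 * M_PI * unif_rand();
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    vhat[0] = st * std::cos(ph); vhat[1] = ct; vhat[2] = st * std::sin(ph);
    dist = EPS_DIST;
  } else {
    for (int k = 0; k < 3; ++k) vhat[k] = v[k] / dist;
  }
  double sa[3] = {s1[0], s1[1], s1[2]}, sb[3] = {s2[0], s2[1], s2[2]};
  double Ra[9], Rb[9];
  std::copy(R1.begin(), R1.end(), Ra);
  std::copy(R2.begin(), R2.end(), Rb);
  double ub[3], mv[3] = {-vhat[0], -vhat[1], -vhat[2]};
  toBody(Ra, vhat, ub);
  double di = supportRadius3(sa, ub);
  toBody(Rb, mv, ub);
  double dj = supportRadius3(sb, ub);
  double d0 = std::max(0.0, di + dj - dist);
  return List::create(
      _["vhat"] = NumericVector::create(vhat[0], vhat[1], vhat[2]),
      _["dist"] = dist, _["dI"] = di, _["dJ"] = dj, _["d0"] = d0,
      _["degenerate"] = degenerate);
}

// [[Rcpp::export]]
List cpp_fit_radii(NumericVector sCur, NumericMatrix dirs, NumericVector dNew,
                   NumericVector lo, NumericVector hi, double V0) {
  int m = dNew.size();
  std::vector<double> U(3 * m), d(m);
  for (int j = 0; j < m; ++j) {
    for (int k = 0; k < 3; ++k) U[3 * j + k] = dirs(j, k);
    d[j] = dNew[j];
  }
  double sc[3] = {sCur[0], sCur[1], sCur[2]};
  double lo3[3] = {lo[0], lo[1], lo[2]}, hi3[3] = {hi[0], hi[1], hi[2]};
  FitResult fr = fitRadii(sc, U, d, lo3, hi3, V0);
  std::string cs = fr.m == 0 ? "none"
                   : (fr.m == 1 ? "single" : (fr.m == 2 ? "double" : "multi"));
  return List::create(
      _["semiAxes"] = NumericVector::create(fr.s[0], fr.s[1], fr.s[2]),
      _["residual"] = fr.residual, _["case"] = cs,
      _["converged"] = fr.converged);
}

// [[Rcpp::export]]
double cpp_solve_lambda(NumericVector u, NumericVector f, NumericVector kPar,
                        NumericVector kSer, NumericVector muDash,
                        NumericVector rest) {
  return solveLambda(REAL(u), REAL(f), REAL(kPar), REAL(kSer), REAL(muDash),
                     REAL(rest));
}

// [[Rcpp::export]]
List cpp_step_axes(NumericVector u, NumericVector f, NumericVector kPar,
                   NumericVector kSer, NumericVector muDash,
                   NumericVector rest, double dt, int lambdaMode,
                   NumericVector fJump) {
  double uu[3];
  // instantaneous elastic jump from a force step (df/dt term)
  for (int k = 0; k < 3; ++k)
    uu[k] = u[k] + fJump[k] / (kPar[k] + kSer[k]);
  double un[3], lam = 0.0;
  stepAxesExp(uu, REAL(f), REAL(kPar), REAL(kSer), REAL(muDash), REAL(rest),
              dt, lambdaMode, nullptr, un, &lam);
  return List::create(_["u"] = NumericVector::create(un[0], un[1], un[2]),
                      _["lambda"] = lam);
}

// [[Rcpp::export]]
List cpp_assemble_forces(NumericMatrix positions, NumericVector axesFlat,
                         NumericMatrix semiAxes, List paramList) {
  mat P = as<mat>(positions);
  mat S = as<mat>(semiAxes);
  Params par = unpackParams(paramList);
  ForceEval ev;
  computeForces(P, REAL(axesFlat), S, par, true, ev);
  int nr = ev.recs.size();
  NumericMatrix recTab(nr, 6);
  for (int q = 0; q < nr; ++q) {
    recTab(q, 0) = ev.recs[q].i + 1;
    recTab(q, 1) = ev.recs[q].j + 1;
    recTab(q, 2) = ev.recs[q].dist;
    recTab(q, 3) = ev.recs[q].di;
    recTab(q, 4) = ev.recs[q].dj;
    recTab(q, 5) = ev.recs[q].d0;
  }
  colnames(recTab) =
      CharacterVector::create("i", "j", "dist", "dI", "dJ", "d0");
  return List::create(
      _["total"] = wrap(ev.Ftot), _["drag"] = wrap(ev.D),
      _["motive"] = wrap(ev.motive), _["motiveReaction"] = wrap(ev.motiveReact),
      _["adhesion"] = wrap(ev.adhesion), _["boundaryX"] = wrap(ev.boundX),
      _["boundaryZ"] = wrap(ev.boundZ), _["overlap"] = wrap(ev.overlap),
      _["overlapReaction"] = wrap(ev.overlapReact),
      _["nucleus"] = wrap(ev.nucleus), _["records"] = recTab,
      _["fitted"] = wrap(ev.Sfit));
}

// [[Rcpp::export]]
NumericVector cpp_boundary_force(NumericVector position, double rho,
                                 double boxWidth, double r) {
  NumericVector f(3);
  f[0] = boundary1d(position[0], rho, r, boxWidth);
  f[2] = boundary1d(position[2], rho, r, boxWidth);
  return f;
}

// [[Rcpp::export]]
double cpp_nucleus_magnitude(double dist) {
  if (dist >= 4.0) return 0.0;
  return nucleusMag(dist);
}

// [[Rcpp::export]]
NumericVector cpp_sample_direction(double gammaDeg) {
  double d[3];
  sampleCap(gammaDeg * M_PI / 180.0, d);
  return NumericVector::create(d[0], d[1], d[2]);
}

// [[Rcpp::export]]
NumericMatrix cpp_rotate_toward(NumericMatrix axes, NumericVector d,
                                double incrementDeg) {
  double R[9];
  std::copy(axes.begin(), axes.end(), R);
  double dn[3] = {d[0], d[1], d[2]};
  double nrm = std::sqrt(dn[0] * dn[0] + dn[1] * dn[1] + dn[2] * dn[2]);
  for (int k = 0; k < 3; ++k) dn[k] /= nrm;
  rotateTriad(R, dn, incrementDeg * M_PI / 180.0);
  NumericMatrix out(3, 3);
  std::copy(R, R + 9, out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix positions, NumericVector axesFlat,
             NumericMatrix semiAxes, NumericMatrix deformation,
             LogicalVector isPrestalk, List paramList, int nSteps,
             int stride, bool recordFrames) {
  int n = positions.nrow();
  mat P = as<mat>(positions);
  std::vector<double> A(REAL(axesFlat), REAL(axesFlat) + 9 * n);
  mat S = as<mat>(semiAxes);
  mat U = as<mat>(deformation);
  Params par = unpackParams(paramList);
  mat Dstim(3, n, arma::fill::zeros);
  Dstim.row(1).ones();
  StepCounters ctr;
  Engine eng;
  int nRec = nSteps / stride + 1;
  NumericVector times(nRec), relpos(nRec);
  cube framesP, framesS, framesA;
  if (recordFrames) {
    framesP.set_size(n, 3, nRec);
    framesS.set_size(n, 3, nRec);
    framesA.set_size(n, 3, nRec);  // a-axis only
  }
  int rec = 0;
  for (long stepIdx = 0; stepIdx <= nSteps; ++stepIdx) {
    if (stepIdx % stride == 0) {
      times[rec] = stepIdx * par.dt;
      relpos[rec] = relPosition(P, isPrestalk);
      if (recordFrames) {
        framesP.slice(rec) = P;
        framesS.slice(rec) = S;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k)
            framesA.slice(rec)(i, k) = A[9 * i + k];
      }
      ++rec;
    }
    if (stepIdx == nSteps) break;
    doStep(P, A.data(), S, U, Dstim, par, stepIdx, ctr, eng);
    if (!P.is_finite())
      stop("non-finite cell position at step %ld (t = %.3f s)", stepIdx + 1,
           (stepIdx + 1) * par.dt);
    if (stepIdx % 20000 == 0)
      Rcpp::checkUserInterrupt();
  }
  NumericVector axesOut(9 * n);
  std::copy(A.begin(), A.end(), axesOut.begin());
  List out = List::create(
      _["times"] = times, _["relpos"] = relpos, _["positions"] = wrap(P),
      _["axes"] = axesOut, _["semiAxes"] = wrap(S), _["deformation"] = wrap(U),
      _["clampEvents"] = (double)ctr.clampEvents,
      _["fitFailures"] = (double)ctr.fitFailures);
  if (recordFrames) {
    out["framePositions"] = wrap(framesP);
    out["frameSemiAxes"] = wrap(framesS);
    out["frameAAxis"] = wrap(framesA);
  }
  return out;
}
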