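// Fast paths for optimization-time inner loops: closed-form bSSFP steady
// state (3x3 affine fixed point per measurement) and the finite-difference
// Jacobian of a balanced transient train. The FD scheme mirrors the R-level
// jacobian contract exactly: central differences with relative step and
// absolute floor, analytic M0 (linearity) and phi0 (i * signal) columns.
#include <Rcpp.h>
#include <complex>
using namespace Rcpp;
typedef std::complex<double> cd;

static void solve3(const double A[3][3], const double b[3], double x[3]) {
  double a[3][4] = {{A[0][0], A[0][1], A[0][2], b[0]},
                    {A[1][0], A[1][1], A[1][2], b[1]},
                    {A[2][0], A[2][1], A[2][2], b[2]}};
  for (int c = 0; c < 3; ++c) {
    int piv = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(a[r][c]) > std::fabs(a[piv][c])) piv = r;
    if (piv != c)
      for (int j = c; j < 4; ++j) std::swap(a[c][j], a[piv][j]);
    for (int r = c + 1; r < 3; ++r) {
      const double f = a[r][c] / a[c][c];
      for (int j = c; j < 4; ++j) a[r][j] -= f * a[c][j];
    }
  }
  for (int r = 2; r >= 0; --r) {
    double s = a[r][3];
    for (int j = r + 1; j < 3; ++j) s -= a[r][j] * x[j];
    x[r] = s / a[r][r];
  }
}

static cd bssfp_one(double flip, double tr, double te, double dphi,
                    double T1, double T2, double M0, double phi0,
                    double omega0) {
  const double e1 = std::exp(-tr / T1), e2 = std::exp(-tr / T2);
  const double psi = 2.0 * M_PI * omega0 * tr / 1000.0 - dphi;
  const double ca = std::cos(flip), sa = std::sin(flip);
  const double cp = std::cos(psi), sp = std::sin(psi);
  // M = Rz(psi) diag(e2,e2,e1) Rx(flip)
  const double M[3][3] = {{cp * e2, -sp * e2 * ca, sp * e2 * sa},
                          {sp * e2, cp * e2 * ca, -cp * e2 * sa},
                          {0.0, e1 * sa, e1 * ca}};
  const double A[3][3] = {{1.0 - M[0][0], -M[0][1], -M[0][2]},
                          {-M[1][0], 1.0 - M[1][1], -M[1][2]},
                          {-M[2][0], -M[2][1], 1.0 - M[2][2]}};
  const double b[3] = {0.0, 0.0, M0 * (1.0 - e1)};
  double m[3];
  solve3(A, b, m);
  // post-pulse magnetization, then precession + decay to TE
  const double my = ca * m[1] - sa * m[2];
  const cd mxy(m[0], my);
  return mxy * std::polar(std::exp(-te / T2),
                          2.0 * M_PI * omega0 * te / 1000.0 + phi0);
}

// [[Rcpp::export]]
ComplexVector bssfp_signal_cpp(NumericVector flips, NumericVector trs,
                               NumericVector tes, NumericVector dphis,
                               double T1, double T2, double M0, double phi0,
                               double omega0) {
  const int n = flips.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    const cd v = bssfp_one(flips[i], trs[i], tes[i], dphis[i], T1, T2, M0,
                           phi0, omega0);
    out[i] = Rcomplex{v.real(), v.imag()};
  }
  return out;
}

// balanced train propagation (same dynamics as bloch_train_cpp), signals
// without the phi0 factor (applied by the caller)
static void bal_signals(const NumericVector &flips, const NumericVector &phases,
                        const NumericVector &trs, double te, double T1,
                        double T2, double M0, double omega0, double mx,
                        double my, double mz, std::vector<cd> &sig) {
  const int n = flips.size();
  const double E2te = std::exp(-te / T2);
  const double th_te = 2.0 * M_PI * omega0 * te / 1000.0;
  for (int i = 0; i < n; ++i) {
    const double a = flips[i], phi = phases[i];
    const double ca = std::cos(a), sa = std::sin(a);
    const double cp = std::cos(phi), sp = std::sin(phi);
    const double x1 = cp * mx + sp * my;
    const double y1 = -sp * mx + cp * my;
    const double y2 = ca * y1 - sa * mz;
    const double z2 = sa * y1 + ca * mz;
    mx = cp * x1 - sp * y2;
    my = sp * x1 + cp * y2;
    mz = z2;
    sig[i] = cd(mx, my) * std::polar(E2te, th_te) * std::polar(1.0, -phi);
    const double tr = trs[i];
    const double E1 = std::exp(-tr / T1), E2 = std::exp(-tr / T2);
    const double th = 2.0 * M_PI * omega0 * tr / 1000.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double nx = E2 * (ct * mx - st * my);
    const double ny = E2 * (st * mx + ct * my);
    mx = nx;
    my = ny;
    mz = mz * E1 + M0 * (1.0 - E1);
  }
}

// [[Rcpp::export]]
List bloch_balanced_jacobian_cpp(NumericVector flips, NumericVector phases,
                                 NumericVector trs, double te, double T1,
                                 double T2, double M0, double phi0,
                                 double omega0, NumericVector minit,
                                 double h_rel, double h_abs) {
  const int n = flips.size();
  std::vector<cd> s0(n), sp_(n), sm_(n), sM(n);
  bal_signals(flips, phases, trs, te, T1, T2, M0, omega0, minit[0], minit[1],
              minit[2], s0);
  ComplexMatrix J(n, 5);
  ComplexVector sig(n);
  const cd rot = std::polar(1.0, phi0);
  // central FD in T1, T2, omega0
  const double pars[3] = {T1, T2, omega0};
  for (int j = 0; j < 3; ++j) {
    const double h = std::max(std::fabs(pars[j]) * h_rel, h_abs);
    double T1p = T1, T2p = T2, w0p = omega0;
    double T1m = T1, T2m = T2, w0m = omega0;
    if (j == 0) { T1p += h; T1m -= h; }
    if (j == 1) { T2p += h; T2m -= h; }
    if (j == 2) { w0p += h; w0m -= h; }
    bal_signals(flips, phases, trs, te, T1p, T2p, M0, w0p, minit[0], minit[1],
                minit[2], sp_);
    bal_signals(flips, phases, trs, te, T1m, T2m, M0, w0m, minit[0], minit[1],
                minit[2], sm_);
    for (int i = 0; i < n; ++i) {
      const cd d = (sp_[i] - sm_[i]) / (2.0 * h) * rot;
      J(i, j) = Rcomplex{d.real(), d.imag()};
    }
  }
  // M0 column: the model is linear in M0 (thermal-proportional initial state)
  bal_signals(flips, phases, trs, te, T1, T2, 1.0, omega0, minit[0] / M0,
              minit[1] / M0, minit[2] / M0, sM);
  for (int i = 0; i < n; ++i) {
    const cd v = s0[i] * rot;
    sig[i] = Rcomplex{v.real(), v.imag()};
    const cd dm = sM[i] * rot;
    J(i, 2) = J(i, 2); // omega0 already set (column index 4 below)
    J(i, 3) = Rcomplex{dm.real(), dm.imag()};
    const cd dp = cd(0.0, 1.0) * v;
    J(i, 4) = Rcomplex{dp.real(), dp.imag()};
  }
  // reorder columns to (T1, T2, M0, phi0, omega0)
  ComplexMatrix Jo(n, 5);
  for (int i = 0; i < n; ++i) {
    Jo(i, 0) = J(i, 0);
    Jo(i, 1) = J(i, 1);
    Jo(i, 2) = J(i, 3);
    Jo(i, 3) = J(i, 4);
    Jo(i, 4) = J(i, 2);
  }
  return List::create(_["signal"] = sig, _["jacobian"] = Jo);
}
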