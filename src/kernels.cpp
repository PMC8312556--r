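// Spin-dynamics kernels: extended phase graph (EPG) propagation for gradient
// spoiled sequences and single-isochromat Bloch recursion for balanced ones.
// Angles arrive in radians, times in ms, off-resonance in Hz.
#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cd;

// EPG configuration states up to dephasing order K.
// Fm[k] stores conj(F(-k)), the usual convention, so Fm[0] == conj(Fp[0]).
struct EPGState3 {
  std::vector<cd> Fp, Fm, Z;
  explicit EPGState3(int K) : Fp(K + 1), Fm(K + 1), Z(K + 1) {}
  int K() const { return (int)Fp.size() - 1; }
};

// Instantaneous RF rotation by alpha about an axis at phase phi in the
// transverse plane (Weigel's mixing matrix for [F+_k, F-_k, Z_k]).
static void epg_rf(EPGState3 &s, double alpha, double phi) {
  const double ca2 = std::cos(alpha / 2.0), sa2 = std::sin(alpha / 2.0);
  const double sa = std::sin(alpha), ca = std::cos(alpha);
  const cd ei = std::polar(1.0, phi);
  const cd e2i = std::polar(1.0, 2.0 * phi);
  const cd t11 = cd(ca2 * ca2, 0.0);
  const cd t12 = e2i * (sa2 * sa2);
  const cd t13 = cd(0.0, -1.0) * ei * sa;
  const cd t21 = std::conj(e2i) * (sa2 * sa2);
  const cd t22 = cd(ca2 * ca2, 0.0);
  const cd t23 = cd(0.0, 1.0) * std::conj(ei) * sa;
  const cd t31 = cd(0.0, -0.5) * std::conj(ei) * sa;
  const cd t32 = cd(0.0, 0.5) * ei * sa;
  const cd t33 = cd(ca, 0.0);
  const int n = (int)s.Fp.size();
  for (int k = 0; k < n; ++k) {
    const cd fp = s.Fp[k], fm = s.Fm[k], z = s.Z[k];
    s.Fp[k] = t11 * fp + t12 * fm + t13 * z;
    s.Fm[k] = t21 * fp + t22 * fm + t23 * z;
    s.Z[k] = t31 * fp + t32 * fm + t33 * z;
  }
}

// Relaxation for t ms; longitudinal recovery (scaled by M0) enters Z_0 only.
static void epg_relax(EPGState3 &s, double t, double T1, double T2, double M0) {
  const double E1 = std::exp(-t / T1), E2 = std::exp(-t / T2);
  const int n = (int)s.Fp.size();
  for (int k = 0; k < n; ++k) {
    s.Fp[k] *= E2;
    s.Fm[k] *= E2;
    s.Z[k] *= E1;
  }
  s.Z[0] += M0 * (1.0 - E1);
}

// Ideal unit crusher gradient: F+ orders shift up, F- orders shift down.
static void epg_grad(EPGState3 &s) {
  const int K = s.K();
  for (int k = K; k >= 1; --k) s.Fp[k] = s.Fp[k - 1];
  for (int k = 0; k < K; ++k) s.Fm[k] = s.Fm[k + 1];
  s.Fm[K] = cd(0.0, 0.0);
  s.Fp[0] = std::conj(s.Fm[0]);
}

// One pulse train: per pulse do RF -> (optional) record F0 at TE ->
// relaxation over TR -> crusher shift.
static void epg_run_train(EPGState3 &s, const NumericVector &flips,
                          const NumericVector &phases, const NumericVector &trs,
                          double te, double T1, double T2, double M0,
                          ComplexVector *sig) {
  const int n = flips.size();
  const double E2te = std::exp(-te / T2);
  for (int i = 0; i < n; ++i) {
    epg_rf(s, flips[i], phases[i]);
    if (sig != nullptr) {
      const cd v = s.Fp[0] * E2te;
      (*sig)[i] = Rcomplex{v.real(), v.imag()};
    }
    epg_relax(s, trs[i], T1, T2, M0);
    epg_grad(s);
  }
}

static EPGState3 state_from_matrix(const ComplexMatrix &init) {
  const int K = init.ncol() - 1;
  EPGState3 s(K);
  for (int k = 0; k <= K; ++k) {
    s.Fp[k] = cd(init(0, k).r, init(0, k).i);
    s.Fm[k] = cd(init(1, k).r, init(1, k).i);
    s.Z[k] = cd(init(2, k).r, init(2, k).i);
  }
  return s;
}

static ComplexMatrix state_to_matrix(const EPGState3 &s) {
  const int K = s.K();
  ComplexMatrix out(3, K + 1);
  for (int k = 0; k <= K; ++k) {
    out(0, k) = Rcomplex{s.Fp[k].real(), s.Fp[k].imag()};
    out(1, k) = Rcomplex{s.Fm[k].real(), s.Fm[k].imag()};
    out(2, k) = Rcomplex{s.Z[k].real(), s.Z[k].imag()};
  }
  return out;
}

// [[Rcpp::export]]
List epg_train_cpp(NumericVector flips, NumericVector phases, NumericVector trs,
                   double te, double T1, double T2, double M0,
                   ComplexMatrix init, bool record) {
  EPGState3 s = state_from_matrix(init);
  ComplexVector sig(record ? flips.size() : 0);
  epg_run_train(s, flips, phases, trs, te, T1, T2, M0,
                record ? &sig : nullptr);
  double top = std::max(std::abs(s.Fp[s.K()]),
                        std::max(std::abs(s.Fm[s.K()]), std::abs(s.Z[s.K()])));
  return List::create(_["signal"] = sig, _["state"] = state_to_matrix(s),
                      _["top_energy"] = top);
}

// Real-ified state vector layout used by the affine cycle map:
// [Re Fp_0..K, Im Fp_0..K, Re Fm_0..K, Im Fm_0..K, Re Z_0..K, Im Z_0..K].
static void state_to_real(const EPGState3 &s, double *x) {
  const int L = s.K() + 1;
  for (int k = 0; k < L; ++k) {
    x[k] = s.Fp[k].real();
    x[L + k] = s.Fp[k].imag();
    x[2 * L + k] = s.Fm[k].real();
    x[3 * L + k] = s.Fm[k].imag();
    x[4 * L + k] = s.Z[k].real();
    x[5 * L + k] = s.Z[k].imag();
  }
}

static EPGState3 state_from_real(const double *x, int K) {
  EPGState3 s(K);
  const int L = K + 1;
  for (int k = 0; k < L; ++k) {
    s.Fp[k] = cd(x[k], x[L + k]);
    s.Fm[k] = cd(x[2 * L + k], x[3 * L + k]);
    s.Z[k] = cd(x[4 * L + k], x[5 * L + k]);
  }
  return s;
}

// Affine map m -> A m + b of one full train on the real-ified truncated EPG
// state (the map is only real-linear because the crusher re-imposes
// Fp_0 = conj(Fm_0)). Used for direct driven-equilibrium solves.
// [[Rcpp::export]]
List epg_cycle_map_cpp(NumericVector flips, NumericVector phases,
                       NumericVector trs, double te, double T1, double T2,
                       double M0, int K) {
  const int L = K + 1, D = 6 * L;
  NumericMatrix A(D, D);
  NumericVector b(D);
  {
    EPGState3 s(K); // zero state: propagation gives the affine offset
    epg_run_train(s, flips, phases, trs, te, T1, T2, M0, nullptr);
    state_to_real(s, b.begin());
  }
  std::vector<double> e(D, 0.0), out(D);
  for (int j = 0; j < D; ++j) {
    std::fill(e.begin(), e.end(), 0.0);
    e[j] = 1.0;
    EPGState3 s = state_from_real(e.data(), K);
    epg_run_train(s, flips, phases, trs, te, T1, T2, 0.0, nullptr);
    state_to_real(s, out.data());
    for (int i = 0; i < D; ++i) A(i, j) = out[i];
  }
  return List::create(_["A"] = A, _["b"] = b);
}

// Fixed-point iteration of the cycle map from thermal equilibrium; geometric
// convergence with rate exp(-T_cycle/T1) guarantees termination for T1 finite.
// [[Rcpp::export]]
List epg_fixed_point_iter_cpp(NumericVector flips, NumericVector phases,
                              NumericVector trs, double te, double T1,
                              double T2, double M0, int K, double tol,
                              int max_cycles) {
  EPGState3 s(K);
  s.Z[0] = cd(M0, 0.0);
  double resid = R_PosInf;
  int cyc = 0;
  std::vector<double> prev(6 * (K + 1)), cur(6 * (K + 1));
  state_to_real(s, prev.data());
  for (cyc = 0; cyc < max_cycles; ++cyc) {
    epg_run_train(s, flips, phases, trs, te, T1, T2, M0, nullptr);
    state_to_real(s, cur.data());
    resid = 0.0;
    for (size_t i = 0; i < cur.size(); ++i)
      resid = std::max(resid, std::abs(cur[i] - prev[i]));
    std::swap(prev, cur);
    if (resid <= tol) break;
  }
  double top = std::max(std::abs(s.Fp[K]),
                        std::max(std::abs(s.Fm[K]), std::abs(s.Z[K])));
  return List::create(_["state"] = state_to_matrix(s), _["residual"] = resid,
                      _["cycles"] = cyc + 1, _["top_energy"] = top);
}

// Single-isochromat Bloch recursion for balanced readouts. Right-handed
// rotations; the recorded signal is demodulated by the pulse phase and
// includes off-resonance precession and T2 decay to TE.
// [[Rcpp::export]]
List bloch_train_cpp(NumericVector flips, NumericVector phases,
                     NumericVector trs, double te, double T1, double T2,
                     double M0, double omega0, NumericVector minit,
                     bool record) {
  const int n = flips.size();
  double mx = minit[0], my = minit[1], mz = minit[2];
  ComplexVector sig(record ? n : 0);
  const double E2te = std::exp(-te / T2);
  const double th_te = 2.0 * M_PI * omega0 * te / 1000.0;
  for (int i = 0; i < n; ++i) {
    const double a = flips[i], phi = phases[i];
    // R = Rz(phi) Rx(a) Rz(-phi)
    const double ca = std::cos(a), sa = std::sin(a);
    const double cp = std::cos(phi), sp = std::sin(phi);
    // rotate into pulse frame
    double x1 = cp * mx + sp * my;
    double y1 = -sp * mx + cp * my;
    double z1 = mz;
    // rotate about x by a (right-handed: z -> -y for a = 90)
    double y2 = ca * y1 - sa * z1;
    double z2 = sa * y1 + ca * z1;
    // back to lab frame
    mx = cp * x1 - sp * y2;
    my = sp * x1 + cp * y2;
    mz = z2;
    if (record) {
      const cd mxy(mx, my);
      const cd v = mxy * std::polar(E2te, th_te) * std::polar(1.0, -phi);
      sig[i] = Rcomplex{v.real(), v.imag()};
    }
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
  return List::create(
      _["signal"] = sig,
      _["m"] = NumericVector::create(mx, my, mz));
}
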