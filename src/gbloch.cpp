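// Compiled core for the two-pool magnetization-transfer toolkit:
//  * super-Lorentzian Green's function (adaptive quadrature + lookup table)
//  * generalized-Bloch Volterra solver for semi-solid saturation during a
//    rectangular pulse (product integration, trapezoidal, Richardson)
//  * linearized semi-solid relaxation rate R2s,l (root matching at pulse end)
//  * precomputed (alpha, log TRF/T2s) grid of R2s,l * T2s with bicubic lookup
//  * 6x6 Bloch-McConnell generator, matrix-exponential propagators, and the
//    full hybrid-state cycle simulation (real path and complex-step path for
//    machine-precision signal derivatives)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
typedef std::complex<double> cxd;

static inline double re_of(double x) { return x; }
static inline double re_of(const cxd &x) { return x.real(); }

// ---------------------------------------------------------------------------
// super-Lorentzian lineshape Green's function
//   G(x) = int_0^1 exp(-x^2 (3 z^2 - 1)^2 / 8) dz,  x = tau / T2s
// ---------------------------------------------------------------------------

static inline double sl_integrand(double x, double z) {
  const double u = 3.0 * z * z - 1.0;
  return std::exp(-x * x * u * u / 8.0);
}

static double sl_simpson(double x, double a, double b, double fa, double fm,
                         double fb, double S, double tol, int depth) {
  const double m = 0.5 * (a + b);
  const double lm = 0.5 * (a + m), rm = 0.5 * (m + b);
  const double flm = sl_integrand(x, lm), frm = sl_integrand(x, rm);
  const double Sl = (m - a) / 6.0 * (fa + 4.0 * flm + fm);
  const double Sr = (b - m) / 6.0 * (fm + 4.0 * frm + fb);
  const double err = Sl + Sr - S;
  if (depth <= 0 || std::abs(err) < 15.0 * tol)
    return Sl + Sr + err / 15.0;
  return sl_simpson(x, a, m, fa, flm, fm, Sl, 0.5 * tol, depth - 1) +
         sl_simpson(x, m, b, fm, frm, fb, Sr, 0.5 * tol, depth - 1);
}

static double sl_quad(double x, double a, double b, double tol) {
  const double fa = sl_integrand(x, a), fb = sl_integrand(x, b);
  const double m = 0.5 * (a + b), fm = sl_integrand(x, m);
  const double S = (b - a) / 6.0 * (fa + 4.0 * fm + fb);
  return sl_simpson(x, a, b, fa, fm, fb, S, tol, 48);
}

// [[Rcpp::export]]
double green_superlorentzian_cpp(double x, double tol = 1e-12) {
  if (x == 0.0) return 1.0;
  // split at the stationary point z* = 1/sqrt(3) where the exponent vanishes;
  // the integrand develops a sharp peak there for large x
  const double zst = 1.0 / std::sqrt(3.0);
  return sl_quad(x, 0.0, zst, 0.5 * tol) + sl_quad(x, zst, 1.0, 0.5 * tol);
}

// [[Rcpp::export]]
arma::vec green_table_cpp(double xmax, double dx, double tol = 1e-11) {
  const int n = (int)std::ceil(xmax / dx) + 1;
  vec tab(n);
  for (int i = 0; i < n; ++i) tab[i] = green_superlorentzian_cpp(i * dx, tol);
  return tab;
}

// Keys / Catmull-Rom cubic through 4 points; t in [0,1] between p0 and p1.
template <typename T>
static inline T cubic4(double pm1, double p0, double p1, double p2, T t) {
  return p0 + 0.5 * t * ((p1 - pm1) +
         t * ((2.0 * pm1 - 5.0 * p0 + 4.0 * p1 - p2) +
         t * (3.0 * (p0 - p1) + p2 - pm1)));
}

template <typename T>
static inline T cubic4T(T pm1, T p0, T p1, T p2, T t) {
  return p0 + 0.5 * t * ((p1 - pm1) +
         t * ((2.0 * pm1 - 5.0 * p0 + 4.0 * p1 - p2) +
         t * (3.0 * (p0 - p1) + p2 - pm1)));
}

// G is an even function of x; mirror across 0 for the first cell. Beyond
// the table end the asymptotic ~1/x tail is used (never extrapolate the
// cubic).
template <typename T>
static T gtab_interp(const vec &tab, double dx, T x) {
  const int n = tab.n_elem;
  double xr = re_of(x);
  if (xr < 0.0) { x = -x; xr = -xr; }
  const double xend = (n - 1) * dx;
  if (xr >= xend) return tab[n - 1] * (xend / x);
  int i = (int)std::floor(xr / dx);
  if (i > n - 2) { i = n - 2; }
  T t = x * (1.0 / dx) - (double)i;
  const double pm1 = (i == 0) ? tab[1] : tab[i - 1];
  const double p2 = (i + 2 <= n - 1) ? tab[i + 2] : tab[n - 1];
  return cubic4<T>(pm1, tab[i], tab[i + 1], p2, t);
}

// ---------------------------------------------------------------------------
// generalized-Bloch Volterra equation, normalized time u = t / T2s:
//   dz/du = -kappa^2 int_0^u G(u - v) z(v) dv,  kappa = omega_y * T2s = alpha/r
// over u in [0, r], r = TRF / T2s.  Product integration with trapezoidal
// weights; implicit in the newest point (linear solve per step).
// ---------------------------------------------------------------------------

static double volterra_end(double alpha, double r, int n, const vec &gtab,
                           double gdx) {
  const double h = r / n;
  const double kap = alpha / r;
  const double kap2 = kap * kap;
  vec G(n + 1), z(n + 1), f(n + 1);
  for (int k = 0; k <= n; ++k) G[k] = gtab_interp<double>(gtab, gdx, k * h);
  z[0] = 1.0;
  f[0] = 0.0;
  const double denom = 1.0 + 0.25 * h * h * kap2 * G[0];
  for (int k = 0; k < n; ++k) {
    double s = 0.5 * G[k + 1] * z[0];
    const double *gp = G.memptr() + 1;   // G[k+1-j] for j=k..1
    const double *zp = z.memptr() + 1;   // z[j] for j=1..k
    double acc = 0.0;
    for (int j = 1; j <= k; ++j) acc += gp[k - j] * zp[j - 1];
    s += acc;
    const double Ipart = h * s;
    const double znew = (z[k] + 0.5 * h * (f[k] - kap2 * Ipart)) / denom;
    z[k + 1] = znew;
    f[k + 1] = -kap2 * (Ipart + 0.5 * h * G[0] * znew);
  }
  return z[n];
}

static int volterra_nsteps(double r) {
  int n = (int)std::ceil(24.0 * r);
  if (n < 512) n = 512;
  if (n > 2048) n = 2048;
  return n;
}

// [[Rcpp::export]]
double volterra_cpp(double alpha, double r, const arma::vec &gtab, double gdx,
                    int n = 0, bool richardson = true) {
  if (alpha == 0.0) return 1.0;
  if (n <= 0) n = volterra_nsteps(r);
  if (n % 2 != 0) ++n;
  const double zn = volterra_end(alpha, r, n, gtab, gdx);
  if (!richardson) return zn;
  const double zh = volterra_end(alpha, r, n / 2, gtab, gdx);
  return (4.0 * zn - zh) / 3.0;  // trapezoidal scheme is O(h^2)
}

// Linearized 2x2 semi-solid propagation in normalized time:
//   d/du (xs, zs) = [[-rho, kap], [-kap, 0]] (xs, zs),  rho = R2s,l * T2s
// closed-form matrix exponential; returns zs(r) from initial (0, 1).
// [[Rcpp::export]]
double lin_zs_end_cpp(double alpha, double r, double rho) {
  const double kap = alpha / r;
  const double m = -0.5 * rho;
  const double disc = m * m - kap * kap;
  // E22 = e^{m r} (cosh(q r) - m sinh(q r)/q); written overflow-stable
  if (disc > 0.0) {
    const double q = std::sqrt(disc);
    // both exponents are <= 0 (q < |m|), so no overflow
    return 0.5 * ((1.0 - m / q) * std::exp((m + q) * r) +
                  (1.0 + m / q) * std::exp((m - q) * r));
  }
  if (disc == 0.0) return std::exp(m * r) * (1.0 - m * r);
  const double w = std::sqrt(-disc);
  return std::exp(m * r) * (std::cos(w * r) - m * std::sin(w * r) / w);
}

// Root-find rho such that the linearized propagation reproduces zs_target.
// The map rho -> zs_lin(rho) is not monotonic for flip angles beyond ~pi
// (the damped rotation sweeps through a smaller effective angle), so the
// bracket is located by a log-spaced scan and the smallest root is taken
// (continuity with the undamped rotation at rho = 0).
// [[Rcpp::export]]
double linearize_rho_cpp(double alpha, double r, double zs_target,
                         double tol = 1e-12, double rho_max = 1e6,
                         bool best_approx = false) {
  double lo = 0.0;
  double flo = lin_zs_end_cpp(alpha, r, lo) - zs_target;
  if (std::abs(flo) < tol) return lo;
  const int nscan = 600;
  const double l0 = std::log(1e-4), l1 = std::log(rho_max);
  double hi = 0.0, fhi = flo;
  bool found = false;
  double best_rho = 0.0, best_f = std::abs(flo);
  for (int k = 0; k <= nscan; ++k) {
    const double rho = std::exp(l0 + (l1 - l0) * k / nscan);
    const double f = lin_zs_end_cpp(alpha, r, rho) - zs_target;
    if (!std::isfinite(f))
      Rcpp::stop("linearize_rho: non-finite propagation at rho=%g", rho);
    if (std::abs(f) < best_f) { best_f = std::abs(f); best_rho = rho; }
    if (flo * f <= 0.0) { hi = rho; fhi = f; found = true; break; }
    lo = rho; flo = f;
  }
  if (!found) {
    // beyond alpha ~ pi the damped rotation may be unable to reach the
    // generalized-Bloch end value at all; callers that tabulate the rate
    // accept the least-misfit rate instead (continuous at the boundary)
    if (best_approx) return best_rho;
    Rcpp::stop("linearize_rho: root not bracketed in [0, %g] "
               "(alpha=%g, r=%g, target=%g)", rho_max, alpha, r, zs_target);
  }
  for (int it = 0; it < 200 && (hi - lo) > tol * (1.0 + hi); ++it) {
    const double mid = 0.5 * (lo + hi);
    const double fm = lin_zs_end_cpp(alpha, r, mid) - zs_target;
    if (fm == 0.0) return mid;
    if (flo * fm <= 0.0) { hi = mid; fhi = fm; } else { lo = mid; flo = fm; }
  }
  return 0.5 * (lo + hi);
}

// alpha -> 0 limit of the matching rate: match the O(omega_y^2) terms,
//   int_0^r (r-u) G(u) du  =  (exp(-rho r) + rho r - 1) / rho^2
// [[Rcpp::export]]
double rho_smallalpha_cpp(const arma::vec &gtab, double gdx, double r) {
  const int n = 4096;
  const double h = r / n;
  double A = 0.0;
  for (int k = 0; k <= n; ++k) {
    const double w = (k == 0 || k == n) ? 0.5 : 1.0;
    A += w * (r - k * h) * gtab_interp<double>(gtab, gdx, k * h);
  }
  A *= h;
  // B(rho) decreasing from r^2/2 at rho=0 towards 0
  auto B = [r](double rho) {
    if (rho < 1e-12) return 0.5 * r * r * (1.0 - rho * r / 3.0);
    return (std::exp(-rho * r) + rho * r - 1.0) / (rho * rho);
  };
  double lo = 0.0, hi = 1.0;
  while (B(hi) > A && hi < 1e8) hi *= 2.0;
  for (int it = 0; it < 200 && (hi - lo) > 1e-13 * (1.0 + hi); ++it) {
    const double mid = 0.5 * (lo + hi);
    if (B(mid) > A) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
arma::mat r2sl_grid_cpp(const arma::vec &alpha_nodes,
                        const arma::vec &logr_nodes, const arma::vec &gtab,
                        double gdx) {
  mat V(alpha_nodes.n_elem, logr_nodes.n_elem);
  for (uword j = 0; j < logr_nodes.n_elem; ++j) {
    const double r = std::exp(logr_nodes[j]);
    for (uword i = 0; i < alpha_nodes.n_elem; ++i) {
      const double a = alpha_nodes[i];
      if (a == 0.0) {
        V(i, j) = rho_smallalpha_cpp(gtab, gdx, r);
      } else {
        const double zs = volterra_cpp(a, r, gtab, gdx, 0, true);
        V(i, j) = linearize_rho_cpp(a, r, zs, 1e-12, 1e6, a > 3.15);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return V;
}

// ---------------------------------------------------------------------------
// bicubic lookup on the uniform (alpha, log r) lattice, templated so that the
// complex-step derivative path differentiates the interpolant analytically
// ---------------------------------------------------------------------------

template <typename T>
static T grid2_interp(const mat &V, double a0, double da, double l0, double dl,
                      T a, T l) {
  const int na = V.n_rows, nl = V.n_cols;
  double ar = re_of(a), lr = re_of(l);
  // clamp to the lattice (derivative w.r.t. a clamped coordinate is dropped)
  if (ar < a0) { a = T(a0); ar = a0; }
  if (ar > a0 + da * (na - 1)) { a = T(a0 + da * (na - 1)); ar = re_of(a); }
  if (lr < l0) { l = T(l0); lr = l0; }
  if (lr > l0 + dl * (nl - 1)) { l = T(l0 + dl * (nl - 1)); lr = re_of(l); }
  int ia = (int)std::floor((ar - a0) / da);
  int il = (int)std::floor((lr - l0) / dl);
  if (ia > na - 2) ia = na - 2;
  if (il > nl - 2) il = nl - 2;
  if (ia < 0) ia = 0;
  if (il < 0) il = 0;
  T ta = (a - a0) * (1.0 / da) - (double)ia;
  T tl = (l - l0) * (1.0 / dl) - (double)il;
  auto ridx = [na](int k) { return std::min(std::max(k, 0), na - 1); };
  auto cidx = [nl](int k) { return std::min(std::max(k, 0), nl - 1); };
  T rows[4];
  for (int d = -1; d <= 2; ++d) {
    const int i = ridx(ia + d);
    rows[d + 1] = cubic4<T>(V(i, cidx(il - 1)), V(i, cidx(il)),
                            V(i, cidx(il + 1)), V(i, cidx(il + 2)), tl);
  }
  return cubic4T<T>(rows[0], rows[1], rows[2], rows[3], ta);
}

// [[Rcpp::export]]
double grid_lookup_cpp(const arma::mat &V, double a0, double da, double l0,
                       double dl, double alpha, double logr) {
  return grid2_interp<double>(V, a0, da, l0, dl, alpha, logr);
}

// ---------------------------------------------------------------------------
// Bloch-McConnell generator and hybrid-state cycle simulation
// state ordering: (xf, yf, zf, xs, zs, 1)
// ---------------------------------------------------------------------------

template <typename T>
struct ParsC {
  T m0s, R1f, R2f, Rx, R1s, T2s, wz, b1;
};

template <typename T>
static Mat<T> gen6(const ParsC<T> &p, T wy, T r2sl) {
  Mat<T> A(6, 6, fill::zeros);
  const T m0f = 1.0 - p.m0s;
  A(0, 0) = -p.R2f; A(0, 1) = -p.wz;  A(0, 2) = wy;
  A(1, 0) = p.wz;   A(1, 1) = -p.R2f;
  A(2, 0) = -wy;
  A(2, 2) = -(p.R1f + p.Rx * p.m0s);
  A(2, 4) = p.Rx * m0f;
  A(2, 5) = m0f * p.R1f;
  A(3, 3) = -r2sl;  A(3, 4) = wy;
  A(4, 2) = p.Rx * p.m0s;
  A(4, 3) = -wy;
  A(4, 4) = -(p.R1s + p.Rx * m0f);
  A(4, 5) = p.m0s * p.R1s;
  return A;
}

// [[Rcpp::export]]
arma::mat generator_cpp(double m0s, double R1f, double R2f, double Rx,
                        double R1s, double T2s, double wy, double wz,
                        double r2sl) {
  ParsC<double> p{m0s, R1f, R2f, Rx, R1s, T2s, wz, 1.0};
  return gen6<double>(p, wy, r2sl);
}

// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat &A) {
  if (!A.is_finite()) Rcpp::stop("expm: non-finite generator entries");
  return expmat(A);
}

struct TrainC {
  vec alpha, trf;
  double TR, trf_inv, cycle_time;
  bool inversion;
};

static TrainC train_from_list(const Rcpp::List &train) {
  TrainC t;
  t.alpha = Rcpp::as<vec>(train["alpha"]);
  t.trf = Rcpp::as<vec>(train["trf"]);
  t.TR = Rcpp::as<double>(train["tr"]);
  t.trf_inv = Rcpp::as<double>(train["trf_inv"]);
  t.cycle_time = Rcpp::as<double>(train["cycle_time"]);
  t.inversion = Rcpp::as<bool>(train["inversion"]);
  return t;
}

// Full cycle: inversion (pi pulse + crushers) -> N x [pulse, echo, free] ->
// trailing free interval.  Signal recorded at TR/2 after the pulse center,
// demodulated for the pi phase increment (sign alternation of omega_y).
template <typename T>
static void simulate_core(const ParsC<T> &p, const TrainC &tr, const mat &V,
                          double a0, double da, double l0, double dl,
                          Col<T> &xf, Col<T> &yf, Mat<T> &cycleM,
                          Col<T> &mper) {
  const int N = tr.alpha.n_elem;
  const T r2s_free = 1.0 / p.T2s;
  const Mat<T> Afree = gen6<T>(p, T(0.0), r2s_free);

  std::vector<Mat<T>> P(N), Fh(N);
  for (int n = 0; n < N; ++n) {
    const T aeff = p.b1 * tr.alpha[n];
    const double sgn = (n % 2 == 0) ? 1.0 : -1.0;
    const T wy = aeff * (sgn / tr.trf[n]);
    const T r = tr.trf[n] / p.T2s;
    const T rho = grid2_interp<T>(V, a0, da, l0, dl, aeff, std::log(r));
    const T r2sl = rho / p.T2s;
    P[n] = expmat(Mat<T>(gen6<T>(p, wy, r2sl) * tr.trf[n]));
    Fh[n] = expmat(Mat<T>(Afree * ((tr.TR - tr.trf[n]) * 0.5)));
  }

  // T2-selective rectangular inversion pulse followed by crusher gradients
  Mat<T> Pinv(6, 6, fill::eye);
  if (tr.inversion) {
    const T aeff_inv = p.b1 * datum::pi;
    const T wy_inv = aeff_inv / tr.trf_inv;
    const T r_inv = tr.trf_inv / p.T2s;
    const T rho_inv = grid2_interp<T>(V, a0, da, l0, dl, aeff_inv,
                                      std::log(r_inv));
    Pinv = expmat(Mat<T>(gen6<T>(p, wy_inv, rho_inv / p.T2s) * tr.trf_inv));
    Pinv.row(0).zeros();  // crushers spoil xf, yf, xs
    Pinv.row(1).zeros();
    Pinv.row(3).zeros();
  }

  double t_end = tr.cycle_time - N * tr.TR;
  if (t_end < 0.0) t_end = 0.0;
  const Mat<T> Fend = expmat(Mat<T>(Afree * t_end));

  Mat<T> M = Pinv;
  for (int n = 0; n < N; ++n) M = Fh[n] * (Fh[n] * (P[n] * M));
  M = Fend * M;
  cycleM = M;

  // periodic boundary condition: fixed point of the affine cycle map
  const Mat<T> A5 = M.submat(0, 0, 4, 4);
  const Col<T> b5 = M.submat(0, 5, 4, 5);
  Mat<T> I5(5, 5, fill::eye);
  const Col<T> m5 = solve(Mat<T>(I5 - A5), b5);
  mper.set_size(6);
  mper.subvec(0, 4) = m5;
  mper[5] = T(1.0);

  Col<T> m = Pinv * mper;
  xf.set_size(N);
  yf.set_size(N);
  for (int n = 0; n < N; ++n) {
    const double sgn = (n % 2 == 0) ? 1.0 : -1.0;
    m = P[n] * m;
    m = Fh[n] * m;
    xf[n] = m[0] * sgn;
    yf[n] = m[1] * sgn;
    m = Fh[n] * m;
  }
}

static ParsC<double> pars_from_list(const Rcpp::List &pars) {
  ParsC<double> p;
  p.m0s = Rcpp::as<double>(pars["m0s"]);
  p.R1f = Rcpp::as<double>(pars["R1f"]);
  p.R2f = Rcpp::as<double>(pars["R2f"]);
  p.Rx = Rcpp::as<double>(pars["Rx"]);
  p.R1s = Rcpp::as<double>(pars["R1s"]);
  p.T2s = Rcpp::as<double>(pars["T2s"]);
  p.wz = Rcpp::as<double>(pars["wz"]);
  p.b1 = Rcpp::as<double>(pars["b1"]);
  return p;
}

// [[Rcpp::export]]
Rcpp::List simulate_cpp(const Rcpp::List &pars, const Rcpp::List &train,
                        const arma::mat &V, double a0, double da, double l0,
                        double dl) {
  const ParsC<double> p = pars_from_list(pars);
  const TrainC tr = train_from_list(train);
  Col<double> xf, yf, mper;
  Mat<double> M;
  simulate_core<double>(p, tr, V, a0, da, l0, dl, xf, yf, M, mper);
  return Rcpp::List::create(Rcpp::Named("xf") = xf, Rcpp::Named("yf") = yf,
                            Rcpp::Named("cycle") = M,
                            Rcpp::Named("state") = mper);
}

// complex-step derivative: parameter `dpar` is perturbed by i*h; the
// imaginary parts of xf, yf divided by h are the exact derivatives of the
// (analytically continued) model.
// [[Rcpp::export]]
Rcpp::List simulate_cstep_cpp(const Rcpp::List &pars, const Rcpp::List &train,
                              const arma::mat &V, double a0, double da,
                              double l0, double dl, std::string dpar,
                              double h = 1e-200) {
  const ParsC<double> pr = pars_from_list(pars);
  ParsC<cxd> p{pr.m0s, pr.R1f, pr.R2f, pr.Rx, pr.R1s, pr.T2s, pr.wz, pr.b1};
  const cxd ih(0.0, h);
  if (dpar == "m0s") p.m0s += ih;
  else if (dpar == "R1f") p.R1f += ih;
  else if (dpar == "R2f") p.R2f += ih;
  else if (dpar == "Rx") p.Rx += ih;
  else if (dpar == "R1s") p.R1s += ih;
  else if (dpar == "T2s") p.T2s += ih;
  else if (dpar == "wz") p.wz += ih;
  else if (dpar == "b1") p.b1 += ih;
  else Rcpp::stop("unknown parameter '%s'", dpar.c_str());
  const TrainC tr = train_from_list(train);
  Col<cxd> xf, yf, mper;
  Mat<cxd> M;
  simulate_core<cxd>(p, tr, V, a0, da, l0, dl, xf, yf, M, mper);
  return Rcpp::List::create(Rcpp::Named("xf") = xf, Rcpp::Named("yf") = yf);
}
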