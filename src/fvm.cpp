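#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cell-centred finite-volume kernel for the winged-phase transport operator
// and the coupled forward-Euler update of both phases.
//
// Field layout: column-major nx x ny matrices, element (i, j) = cell with
// x-index i (0-based) and y-index j; cell centre at ((i+1/2)dx, (j+1/2)dy).
//
// Boundary-condition codes, side order {left (x=0), right (x=Lx),
// bottom (y=0), top (y=Ly)}: 0 = zero-gradient Neumann (no diffusive flux,
// advective outflow with the boundary-cell value, zero advective inflow),
// 1 = Dirichlet (ghost cell at distance dx/dy holding the fixed value,
// entering both the upwind advective and the central diffusive flux).

static inline double dface(double a, double b, bool harmonic) {
  if (harmonic) {
    double s = a + b;
    return s > 0.0 ? 2.0 * a * b / s : 0.0;
  }
  return 0.5 * (a + b);
}

// Net flux divergence of the Eq.-style flow term G = -v*M_upwind + D_f*dM/dn,
// out[c] = (G_east - G_west)/dx + (G_north - G_south)/dy, per second.
static void flux_div_core(const double* M, const double* vx, const double* vy,
                          const double* Dx, const double* Dy,
                          int nx, int ny, double dx, double dy,
                          const int* bc, const double* bcv, bool harmonic,
                          double* out) {
  const double invdx = 1.0 / dx, invdy = 1.0 / dy;
  const R_xlen_t n = (R_xlen_t)nx * ny;
  for (R_xlen_t k = 0; k < n; ++k) out[k] = 0.0;

  for (int j = 0; j < ny; ++j) {
    const int off = nx * j;
    {  // west boundary face of cell (0, j)
      const int c = off;
      const double vf = vx[c];
      double G;
      if (bc[0] == 1) {
        const double g = bcv[0];
        const double Mu = vf > 0 ? g : (vf < 0 ? M[c] : 0.5 * (g + M[c]));
        G = -vf * Mu + Dx[c] * (M[c] - g) * invdx;
      } else {
        G = (vf < 0) ? -vf * M[c] : 0.0;
      }
      out[c] -= G * invdx;
    }
    for (int i = 1; i < nx; ++i) {  // interior x-faces
      const int R = off + i, L = R - 1;
      const double vf = 0.5 * (vx[L] + vx[R]);
      const double Mu = vf > 0 ? M[L] : (vf < 0 ? M[R] : 0.5 * (M[L] + M[R]));
      const double Df = dface(Dx[L], Dx[R], harmonic);
      const double G = -vf * Mu + Df * (M[R] - M[L]) * invdx;
      out[L] += G * invdx;
      out[R] -= G * invdx;
    }
    {  // east boundary face of cell (nx-1, j)
      const int c = off + nx - 1;
      const double vf = vx[c];
      double G;
      if (bc[1] == 1) {
        const double g = bcv[1];
        const double Mu = vf > 0 ? M[c] : (vf < 0 ? g : 0.5 * (M[c] + g));
        G = -vf * Mu + Dx[c] * (g - M[c]) * invdx;
      } else {
        G = (vf > 0) ? -vf * M[c] : 0.0;
      }
      out[c] += G * invdx;
    }
  }

  for (int i = 0; i < nx; ++i) {
    {  // south boundary face of cell (i, 0)
      const int c = i;
      const double vf = vy[c];
      double G;
      if (bc[2] == 1) {
        const double g = bcv[2];
        const double Mu = vf > 0 ? g : (vf < 0 ? M[c] : 0.5 * (g + M[c]));
        G = -vf * Mu + Dy[c] * (M[c] - g) * invdy;
      } else {
        G = (vf < 0) ? -vf * M[c] : 0.0;
      }
      out[c] -= G * invdy;
    }
    for (int j = 1; j < ny; ++j) {  // interior y-faces
      const int T = i + nx * j, B = T - nx;
      const double vf = 0.5 * (vy[B] + vy[T]);
      const double Mu = vf > 0 ? M[B] : (vf < 0 ? M[T] : 0.5 * (M[B] + M[T]));
      const double Df = dface(Dy[B], Dy[T], harmonic);
      const double G = -vf * Mu + Df * (M[T] - M[B]) * invdy;
      out[B] += G * invdy;
      out[T] -= G * invdy;
    }
    {  // north boundary face of cell (i, ny-1)
      const int c = i + nx * (ny - 1);
      const double vf = vy[c];
      double G;
      if (bc[3] == 1) {
        const double g = bcv[3];
        const double Mu = vf > 0 ? M[c] : (vf < 0 ? g : 0.5 * (M[c] + g));
        G = -vf * Mu + Dy[c] * (g - M[c]) * invdy;
      } else {
        G = (vf > 0) ? -vf * M[c] : 0.0;
      }
      out[c] += G * invdy;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix fvm_flux_div_cpp(NumericMatrix M, NumericMatrix vx,
                               NumericMatrix vy, NumericMatrix Dx,
                               NumericMatrix Dy, double dx, double dy,
                               IntegerVector bc, NumericVector bcv,
                               bool harmonic) {
  const int nx = M.nrow(), ny = M.ncol();
  NumericMatrix out(nx, ny);
  flux_div_core(REAL(M), REAL(vx), REAL(vy), REAL(Dx), REAL(Dy), nx, ny, dx,
                dy, INTEGER(bc), REAL(bcv), harmonic, REAL(out));
  return out;
}

// Forward-Euler run of the coupled two-phase system.  Rate constants and the
// h fields arrive in day^-1 and are converted to s^-1 internally; dt is in
// seconds.  The aquatic phase has no transport terms.  Domain totals
// sum(psi*U)*dx*dy are recorded at step 0, every `record_every` steps and at
// the final step.  Aborts (ok = FALSE) on NaN or a negative value beyond
// -1e-10 * max(1, k1, k2).
// [[Rcpp::export]]
List fvm_run_cpp(NumericMatrix M0, NumericMatrix A0, NumericMatrix psi,
                 NumericMatrix vx, NumericMatrix vy, NumericMatrix Dx,
                 NumericMatrix Dy, NumericMatrix h1, NumericMatrix h2,
                 double gamma_, double r_, double k1, double k2, double mu1,
                 double mu2, double dx, double dy, IntegerVector bc,
                 NumericVector bcv, bool harmonic, double dt, int nsteps,
                 double t0, int record_every) {
  const int nx = M0.nrow(), ny = M0.ncol();
  const R_xlen_t n = (R_xlen_t)nx * ny;
  const double day = 86400.0;
  const double gs = gamma_ / day, rs = r_ / day, mu1s = mu1 / day,
               mu2s = mu2 / day;
  const double cellA = dx * dy;
  const double negtol = -1e-10 * std::max(1.0, std::max(k1, k2));

  std::vector<double> M(REAL(M0), REAL(M0) + n), Mn(n), A(REAL(A0), REAL(A0) + n),
      FD(n), dtpsi(n), h1s(n), h2s(n);
  const double* psip = REAL(psi);
  for (R_xlen_t c = 0; c < n; ++c) {
    dtpsi[c] = dt / psip[c];
    h1s[c] = REAL(h1)[c] / day;
    h2s[c] = REAL(h2)[c] / day;
  }

  std::vector<double> rec_t, rec_m, rec_a;
  rec_t.reserve(nsteps / std::max(1, record_every) + 3);
  rec_m.reserve(rec_t.capacity());
  rec_a.reserve(rec_t.capacity());
  double minM = R_PosInf, minA = R_PosInf;

  auto record = [&](double t) {
    double sm = 0.0, sa = 0.0;
    for (R_xlen_t c = 0; c < n; ++c) {
      sm += psip[c] * M[c];
      sa += psip[c] * A[c];
    }
    rec_t.push_back(t);
    rec_m.push_back(sm * cellA);
    rec_a.push_back(sa * cellA);
  };
  record(t0);

  bool ok = true;
  int fail_step = -1;
  for (int s = 1; s <= nsteps; ++s) {
    flux_div_core(M.data(), REAL(vx), REAL(vy), REAL(Dx), REAL(Dy), nx, ny,
                  dx, dy, INTEGER(bc), REAL(bcv), harmonic, FD.data());
    double mn = R_PosInf;
    for (R_xlen_t c = 0; c < n; ++c) {
      const double m = M[c], a = A[c];
      const double RM = gs * a * (1.0 - m / k1) - (mu1s + h1s[c]) * m;
      const double v = m + dtpsi[c] * (FD[c] + RM);
      Mn[c] = v;
      if (v < mn) mn = v;
    }
    double an = R_PosInf;
    for (R_xlen_t c = 0; c < n; ++c) {
      const double m = M[c], a = A[c];
      const double RA = rs * m * (1.0 - a / k2) - (mu2s + h2s[c] + gs) * a;
      const double v = a + dtpsi[c] * RA;
      A[c] = v;
      if (v < an) an = v;
    }
    M.swap(Mn);
    if (mn < minM) minM = mn;
    if (an < minA) minA = an;
    if (std::isnan(mn) || std::isnan(an) || mn < negtol || an < negtol) {
      ok = false;
      fail_step = s;
      record(t0 + s * dt);
      break;
    }
    if (s == nsteps || (record_every > 0 && s % record_every == 0))
      record(t0 + s * dt);
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Mout(nx, ny), Aout(nx, ny);
  std::copy(M.begin(), M.end(), REAL(Mout));
  std::copy(A.begin(), A.end(), REAL(Aout));
  return List::create(
      _["M"] = Mout, _["A"] = Aout, _["rec_t"] = wrap(rec_t),
      _["rec_winged"] = wrap(rec_m), _["rec_aquatic"] = wrap(rec_a),
      _["min_M"] = minM, _["min_A"] = minA, _["ok"] = ok,
      _["fail_step"] = fail_step);
}
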