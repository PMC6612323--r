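#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conservative finite-difference stepper for the nonlocal diffusion-taxis
// system on the periodic unit interval.
//
// State u is an n x N matrix (cells x populations).  Each step:
//   1. ubar_j = circular convolution of u_j with the top-hat weights w
//      (offsets -wm..wm).
//   2. Taxis flux at face k+1/2:  F = 0.5*(u_k + u_{k+1}) * V,
//      V = sum_j gamma_ij (ubar_j[k+1] - ubar_j[k]) / h.
//   3. Divergence (F_{k+1/2} - F_{k-1/2}) / h: telescopes, so the discrete
//      mass of every population is conserved to roundoff.
//   4. Diffusion: explicit centred second difference (scheme 0), or
//      backward-Euler via a periodic tridiagonal solve (scheme 1) with the
//      taxis term kept explicit.
//
// The homogeneous state is an exact fixed point of the explicit scheme:
// all face differences evaluate to exactly 0 in floating point.

static inline int wrap(int k, int n) {
  k %= n;
  return k < 0 ? k + n : k;
}

// Cyclic constant-coefficient tridiagonal solver (Sherman-Morrison around
// a standard Thomas factorisation).  Solves (I - alpha*Lap) x = r where
// Lap is the periodic second-difference matrix scaled by 1/h^2, i.e.
// diagonal b = 1 + 2*alpha, off-diagonal and corners a = -alpha.
struct CyclicTridiag {
  int n;
  double a;           // off-diagonal value
  double gamma0;      // Sherman-Morrison shift
  std::vector<double> denom;  // forward-elimination denominators
  std::vector<double> cp;     // forward-elimination multipliers
  std::vector<double> q;      // solve of modified system against corner vec
  double qfact_den;

  void init(int n_, double alpha) {
    n = n_;
    double b = 1.0 + 2.0 * alpha;
    a = -alpha;
    gamma0 = -b;
    std::vector<double> bb(n, b);
    bb[0] = b - gamma0;
    bb[n - 1] = b - a * a / gamma0;
    denom.assign(n, 0.0);
    cp.assign(n, 0.0);
    denom[0] = bb[0];
    cp[0] = a / bb[0];
    for (int i = 1; i < n; ++i) {
      denom[i] = bb[i] - a * cp[i - 1];
      cp[i] = a / denom[i];
    }
    // q = B^{-1} uvec with uvec = (gamma0, 0, ..., 0, a)
    std::vector<double> uvec(n, 0.0);
    uvec[0] = gamma0;
    uvec[n - 1] = a;
    q.assign(n, 0.0);
    solve_tridiag(uvec.data(), q.data());
    qfact_den = 1.0 + q[0] + (a / gamma0) * q[n - 1];
  }

  // Thomas solve of the (non-cyclic) modified system B x = r.
  void solve_tridiag(const double* r, double* x) const {
    x[0] = r[0] / denom[0];
    for (int i = 1; i < n; ++i)
      x[i] = (r[i] - a * x[i - 1]) / denom[i];
    for (int i = n - 2; i >= 0; --i)
      x[i] -= cp[i] * x[i + 1];
  }

  void solve(const double* r, double* x, double* work) const {
    solve_tridiag(r, work);
    double fact = (work[0] + (a / gamma0) * work[n - 1]) / qfact_den;
    for (int i = 0; i < n; ++i)
      x[i] = work[i] - fact * q[i];
  }
};

// [[Rcpp::export]]
List cpp_integrate(NumericMatrix u0, NumericVector d, NumericMatrix gamma,
                   NumericVector w, int wm, double tau, double h,
                   int nsteps, int scheme, double pos_tol) {
  const int n = u0.nrow();
  const int N = u0.ncol();
  if (d.size() != N || gamma.nrow() != N || gamma.ncol() != N)
    stop("inconsistent model dimensions");
  if ((int)w.size() != 2 * wm + 1)
    stop("weight vector must have length 2*wm + 1");

  NumericMatrix u = clone(u0);
  std::vector<double> ubar(n * N), V(n), F(n), unew(n), rhs(n), work(n);
  const double h2 = h * h;

  std::vector<CyclicTridiag> solvers;
  if (scheme == 1) {
    solvers.resize(N);
    for (int i = 0; i < N; ++i)
      solvers[i].init(n, tau * d[i] / h2);
  }

  int status = 0, fail_step = -1;
  double min_u = R_PosInf;

  for (int s = 0; s < nsteps; ++s) {
    // nonlocal averages
    for (int j = 0; j < N; ++j) {
      const double* uj = &u(0, j);
      double* bj = &ubar[(size_t)j * n];
      for (int k = 0; k < n; ++k) {
        double acc = 0.0;
        for (int t = -wm; t <= wm; ++t)
          acc += w[t + wm] * uj[wrap(k + t, n)];
        bj[k] = acc;
      }
    }
    double step_min = R_PosInf;
    for (int i = 0; i < N; ++i) {
      const double* ui = &u(0, i);
      // advective velocity at faces k+1/2, then flux
      for (int k = 0; k < n; ++k) {
        int kp = wrap(k + 1, n);
        double v = 0.0;
        for (int j = 0; j < N; ++j) {
          double g = gamma(i, j);
          if (j != i && g != 0.0) {
            const double* bj = &ubar[(size_t)j * n];
            v += g * (bj[kp] - bj[k]);
          }
        }
        v /= h;
        F[k] = 0.5 * (ui[k] + ui[kp]) * v;
      }
      if (scheme == 0) {
        for (int k = 0; k < n; ++k) {
          int kp = wrap(k + 1, n), km = wrap(k - 1, n);
          double lap = (ui[kp] - 2.0 * ui[k] + ui[km]) / h2;
          double div = (F[k] - F[km]) / h;
          unew[k] = ui[k] + tau * (d[i] * lap - div);
        }
      } else {
        double mass_rhs = 0.0;
        for (int k = 0; k < n; ++k) {
          int km = wrap(k - 1, n);
          rhs[k] = ui[k] - tau * (F[k] - F[km]) / h;
          mass_rhs += rhs[k];
        }
        solvers[i].solve(rhs.data(), unew.data(), work.data());
        // the exact implicit diffusion update conserves mass (the operator
        // has zero column sums); redistribute the O(eps) solver roundoff
        // uniformly so long runs do not accumulate a mass drift
        double mass_new = 0.0;
        for (int k = 0; k < n; ++k) mass_new += unew[k];
        double corr = (mass_rhs - mass_new) / n;
        for (int k = 0; k < n; ++k) unew[k] += corr;
      }
      for (int k = 0; k < n; ++k) {
        if (unew[k] < step_min) step_min = unew[k];
        u(k, i) = unew[k];
      }
    }
    if (step_min < min_u) min_u = step_min;
    if (step_min < -pos_tol) {
      status = 1;
      fail_step = s + 1;
      break;
    }
  }

  return List::create(_["u"] = u, _["status"] = status,
                      _["fail_step"] = fail_step, _["min_u"] = min_u);
}
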