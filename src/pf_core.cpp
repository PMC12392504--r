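// Compiled kernels for the phase-field cell model and streamline tracing.
//
// Grid convention: fields are nx-by-ny R matrices, column-major; element
// (i, j) sits at physical position (ox + i*dx, oy + j*dx) in micrometres
// (0-based i, j here).  All times are minutes.  Zero-flux (mirror) boundary
// conditions are used for spatial derivatives; the cell is kept away from
// the domain edge by the micropattern, so the boundary choice is not
// physically load-bearing.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline int idx(int i, int j, int nx) { return i + nx * j; }

// mirror index for zero-flux ghost nodes
inline int refl(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

void laplacian(const double* p, double* out, int nx, int ny, double dx) {
  const double inv = 1.0 / (dx * dx);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double c = p[idx(i, j, nx)];
      double s = p[idx(refl(i - 1, nx), j, nx)] + p[idx(refl(i + 1, nx), j, nx)] +
                 p[idx(i, refl(j - 1, ny), nx)] + p[idx(i, refl(j + 1, ny), nx)];
      out[idx(i, j, nx)] = (s - 4.0 * c) * inv;
    }
  }
}

void gradient(const double* p, double* gx, double* gy, int nx, int ny, double dx) {
  const double inv2 = 1.0 / (2.0 * dx);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      gx[idx(i, j, nx)] = (p[idx(refl(i + 1, nx), j, nx)] - p[idx(refl(i - 1, nx), j, nx)]) * inv2;
      gy[idx(i, j, nx)] = (p[idx(i, refl(j + 1, ny), nx)] - p[idx(i, refl(j - 1, ny), nx)]) * inv2;
    }
  }
}

double area_phi2(const double* p, int n, double dx) {
  double a = 0.0;
  for (int k = 0; k < n; ++k) a += p[k] * p[k];
  return a * dx * dx;
}

// phase-field perimeter functional: s = 6 k * Int phi^2(1-phi)^2 dr with
// k = 4 sqrt(2) / lambda; exact for the equilibrium logistic front.
double perimeter_integral(const double* p, int n, double dx, double lambda) {
  double a = 0.0;
  for (int k = 0; k < n; ++k) {
    double w = p[k] * (1.0 - p[k]);
    a += w * w;
  }
  const double kfront = 4.0 * std::sqrt(2.0) / lambda;
  return 6.0 * kfront * a * dx * dx;
}

// delta F_CH / delta phi = gamma [ (c0/lambda) * 2 phi(1-phi)(1-2phi) - lambda lap(phi) ]
void fd_ch(const double* p, const double* lap, double* out, int n,
           double gamma, double lambda, double c0) {
  const double pref = gamma * c0 / lambda;
  for (int k = 0; k < n; ++k) {
    double ph = p[k];
    out[k] = pref * 2.0 * ph * (1.0 - ph) * (1.0 - 2.0 * ph) - gamma * lambda * lap[k];
  }
}

struct Params {
  double gamma, lambda, c0, kappa, R0, eta, M, alpha;
  double mu_beta, sigma_beta, sigma_patch, s0;
  double tau_f, tau_chi, tau_s, tau, ell;
  bool no_filopodia;
};

Params unpack(const List& par) {
  Params q;
  q.gamma = par["gamma"]; q.lambda = par["lambda"]; q.c0 = par["c0"];
  q.kappa = par["kappa"]; q.R0 = par["R0"]; q.eta = par["eta"];
  q.M = par["M"]; q.alpha = par["alpha"];
  q.mu_beta = par["mu_beta"]; q.sigma_beta = par["sigma_beta"];
  q.sigma_patch = par["sigma_patch"]; q.s0 = par["s0"];
  q.tau_f = par["tau_f_min"]; q.tau_chi = par["tau_chi_min"];
  q.tau_s = par["tau_s"]; q.tau = par["tau"]; q.ell = par["ell"];
  q.no_filopodia = as<bool>(par["no_filopodia"]);
  return q;
}

// bilinear interpolation on the grid; 'fill' returned outside the domain
double interp(const double* p, int nx, int ny, double dx, double ox, double oy,
              double x, double y, double fill) {
  double fx = (x - ox) / dx, fy = (y - oy) / dx;
  if (fx < 0.0 || fy < 0.0 || fx > nx - 1.0 || fy > ny - 1.0) return fill;
  int i = (int)std::floor(fx); if (i > nx - 2) i = nx - 2;
  int j = (int)std::floor(fy); if (j > ny - 2) j = ny - 2;
  double tx = fx - i, ty = fy - j;
  double v00 = p[idx(i, j, nx)], v10 = p[idx(i + 1, j, nx)];
  double v01 = p[idx(i, j + 1, nx)], v11 = p[idx(i + 1, j + 1, nx)];
  return (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
         (1 - tx) * ty * v01 + tx * ty * v11;
}

// unordered phi = 1/2 edge crossings (marching-squares edge points)
void interface_points(const double* p, int nx, int ny, double dx, double ox, double oy,
                      std::vector<double>& xs, std::vector<double>& ys) {
  xs.clear(); ys.clear();
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double a = p[idx(i, j, nx)] - 0.5;
      if (i + 1 < nx) {
        double b = p[idx(i + 1, j, nx)] - 0.5;
        if (a * b < 0.0) {
          double t = a / (a - b);
          xs.push_back(ox + (i + t) * dx); ys.push_back(oy + j * dx);
        }
      }
      if (j + 1 < ny) {
        double b = p[idx(i, j + 1, nx)] - 0.5;
        if (a * b < 0.0) {
          double t = a / (a - b);
          xs.push_back(ox + i * dx); ys.push_back(oy + (j + t) * dx);
        }
      }
    }
  }
}

// one explicit Euler step of the coupled phi / P dynamics (no patch impulse)
void step_fields(double* phi, double* P, const double* chi,
                 double* lap, double* gx, double* gy, double* delta,
                 int nx, int ny, double dx, double dt,
                 const Params& q, bool freeze_shape,
                 double* area_out, double* perim_out) {
  const int n = nx * ny;
  const double A0 = M_PI * q.R0 * q.R0;
  laplacian(phi, lap, nx, ny, dx);
  gradient(phi, gx, gy, nx, ny, dx);
  double A = area_phi2(phi, n, dx);
  double s = perimeter_integral(phi, n, dx, q.lambda);
  *area_out = A; *perim_out = s;
  fd_ch(phi, lap, delta, n, q.gamma, q.lambda, q.c0);
  const double afac = -(4.0 * q.kappa / A0) * (1.0 - A / A0);
  const double floor_g = 1e-6 / dx;
  const double inv_eta = 1.0 / q.eta;
  const double inv_tau_chi = std::isfinite(q.tau_chi) ? 1.0 / q.tau_chi : 0.0;
  const double inv_tau = 1.0 / q.tau;
  double per_inh = 0.0;
  if (std::isfinite(q.s0) && s > q.s0)
    per_inh = (s / q.s0) * (s / q.s0) / q.tau_s;

  for (int k = 0; k < n; ++k) {
    double ph = phi[k];
    double d = delta[k] + afac * ph;
    if (!freeze_shape) {
      double gxx = gx[k], gyy = gy[k];
      double gn = std::sqrt(gxx * gxx + gyy * gyy);
      double w = ph * (1.0 - ph);
      double fm = q.alpha * P[k] * w * w * (1.0 - chi[k]);
      double nxh = 0.0, nyh = 0.0;
      if (gn > floor_g) { nxh = -gxx / gn; nyh = -gyy / gn; }
      double vx = (d * gxx + fm * nxh) * inv_eta;
      double vy = (d * gyy + fm * nyh) * inv_eta;
      phi[k] = ph + dt * (-(vx * gxx + vy * gyy) - q.M * d);
    }
    P[k] += dt * (-inv_tau_chi * chi[k] * ph - per_inh * ph - inv_tau * P[k]);
  }
}

void add_patch(double* P, const double* phi, int nx, int ny, double dx,
               double ox, double oy, double px, double py, double beta, double sigma) {
  const double cut = 4.0 * sigma;
  int i0 = std::max(0, (int)std::floor((px - cut - ox) / dx));
  int i1 = std::min(nx - 1, (int)std::ceil((px + cut - ox) / dx));
  int j0 = std::max(0, (int)std::floor((py - cut - oy) / dx));
  int j1 = std::min(ny - 1, (int)std::ceil((py + cut - oy) / dx));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int j = j0; j <= j1; ++j) {
    double y = oy + j * dx;
    for (int i = i0; i <= i1; ++i) {
      double x = ox + i * dx;
      double d2 = (x - px) * (x - px) + (y - py) * (y - py);
      int k = idx(i, j, nx);
      P[k] += beta * std::exp(-d2 * inv2s2) * phi[k];
    }
  }
}

// connected components of phi > 1/2 (4-neighbour flood fill); returns areas
std::vector<double> component_areas(const double* p, int nx, int ny, double dx) {
  const int n = nx * ny;
  std::vector<char> seen(n, 0);
  std::vector<double> areas;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || p[start] <= 0.5) continue;
    double cnt = 0.0;
    stack.push_back(start); seen[start] = 1;
    while (!stack.empty()) {
      int k = stack.back(); stack.pop_back();
      cnt += 1.0;
      int i = k % nx, j = k / nx;
      const int ii[4] = { i - 1, i + 1, i, i };
      const int jj[4] = { j, j, j - 1, j + 1 };
      for (int m = 0; m < 4; ++m) {
        if (ii[m] < 0 || ii[m] >= nx || jj[m] < 0 || jj[m] >= ny) continue;
        int kk = idx(ii[m], jj[m], nx);
        if (!seen[kk] && p[kk] > 0.5) { seen[kk] = 1; stack.push_back(kk); }
      }
    }
    areas.push_back(cnt * dx * dx);
  }
  return areas;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_laplacian(NumericMatrix phi, double dx) {
  int nx = phi.nrow(), ny = phi.ncol();
  NumericMatrix out(nx, ny);
  laplacian(phi.begin(), out.begin(), nx, ny, dx);
  return out;
}

// [[Rcpp::export]]
List cpp_gradient(NumericMatrix phi, double dx) {
  int nx = phi.nrow(), ny = phi.ncol();
  NumericMatrix gx(nx, ny), gy(nx, ny);
  gradient(phi.begin(), gx.begin(), gy.begin(), nx, ny, dx);
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

// [[Rcpp::export]]
NumericMatrix cpp_fd_ch(NumericMatrix phi, double dx, double gamma, double lambda, double c0) {
  int nx = phi.nrow(), ny = phi.ncol(), n = nx * ny;
  NumericMatrix lap(nx, ny), out(nx, ny);
  laplacian(phi.begin(), lap.begin(), nx, ny, dx);
  fd_ch(phi.begin(), lap.begin(), out.begin(), n, gamma, lambda, c0);
  return out;
}

// [[Rcpp::export]]
double cpp_area(NumericMatrix phi, double dx) {
  return area_phi2(phi.begin(), phi.nrow() * phi.ncol(), dx);
}

// [[Rcpp::export]]
double cpp_perimeter_integral(NumericMatrix phi, double dx, double lambda) {
  return perimeter_integral(phi.begin(), phi.nrow() * phi.ncol(), dx, lambda);
}

// [[Rcpp::export]]
NumericMatrix cpp_fd_area(NumericMatrix phi, double dx, double kappa, double R0) {
  int nx = phi.nrow(), ny = phi.ncol(), n = nx * ny;
  double A0 = M_PI * R0 * R0;
  double A = area_phi2(phi.begin(), n, dx);
  double fac = -(4.0 * kappa / A0) * (1.0 - A / A0);
  NumericMatrix out(nx, ny);
  for (int k = 0; k < n; ++k) out[k] = fac * phi[k];
  return out;
}

// [[Rcpp::export]]
List cpp_velocity(NumericMatrix phi, NumericMatrix P, NumericMatrix chi,
                  NumericMatrix delta, double dx, double alpha, double eta) {
  int nx = phi.nrow(), ny = phi.ncol(), n = nx * ny;
  NumericMatrix gx(nx, ny), gy(nx, ny), vx(nx, ny), vy(nx, ny);
  gradient(phi.begin(), gx.begin(), gy.begin(), nx, ny, dx);
  const double floor_g = 1e-6 / dx;
  for (int k = 0; k < n; ++k) {
    double ph = phi[k], w = ph * (1.0 - ph);
    double gn = std::sqrt(gx[k] * gx[k] + gy[k] * gy[k]);
    double fm = alpha * P[k] * w * w * (1.0 - chi[k]);
    double nxh = 0.0, nyh = 0.0;
    if (gn > floor_g) { nxh = -gx[k] / gn; nyh = -gy[k] / gn; }
    vx[k] = (delta[k] * gx[k] + fm * nxh) / eta;
    vy[k] = (delta[k] * gy[k] + fm * nyh) / eta;
  }
  return List::create(_["vx"] = vx, _["vy"] = vy);
}

// [[Rcpp::export]]
NumericMatrix cpp_interface_points(NumericMatrix phi, double dx, double ox, double oy) {
  std::vector<double> xs, ys;
  interface_points(phi.begin(), phi.nrow(), phi.ncol(), dx, ox, oy, xs, ys);
  NumericMatrix out(xs.size(), 2);
  for (size_t k = 0; k < xs.size(); ++k) { out(k, 0) = xs[k]; out(k, 1) = ys[k]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_patch(NumericMatrix P, NumericMatrix phi, double dx,
                              double ox, double oy, double px, double py,
                              double beta, double sigma) {
  NumericMatrix out = clone(P);
  add_patch(out.begin(), phi.begin(), P.nrow(), P.ncol(), dx, ox, oy, px, py, beta, sigma);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_component_areas(NumericMatrix phi, double dx) {
  std::vector<double> a = component_areas(phi.begin(), phi.nrow(), phi.ncol(), dx);
  return wrap(a);
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix phi, NumericMatrix P, NumericMatrix chi,
              double dx, double dt, List params, bool freeze_shape) {
  Params q = unpack(params);
  int nx = phi.nrow(), ny = phi.ncol();
  NumericMatrix phi2 = clone(phi), P2 = clone(P);
  std::vector<double> lap(nx * ny), gx(nx * ny), gy(nx * ny), delta(nx * ny);
  double A, s;
  step_fields(phi2.begin(), P2.begin(), chi.begin(), lap.data(), gx.data(),
              gy.data(), delta.data(), nx, ny, dx, dt, q, freeze_shape, &A, &s);
  return List::create(_["phi"] = phi2, _["P"] = P2, _["area"] = A, _["perimeter"] = s);
}

// Full simulation loop.  Uses R's RNG (seed it from R for reproducibility).
// [[Rcpp::export]]
List cpp_run(NumericMatrix phi0, NumericMatrix P0, NumericMatrix chi,
             double dx, double ox, double oy, List params, List control) {
  Params q = unpack(params);
  const int nx = phi0.nrow(), ny = phi0.ncol(), n = nx * ny;

  const double dt = control["dt"];
  const double duration = control["duration"];
  const double record_every = control["record_every"];
  const bool freeze_shape = as<bool>(control["freeze_shape"]);
  const bool log_patches = as<bool>(control["log_patches"]);
  const double fields_every = control["fields_every"];   // 0 = no snapshots
  const double rupture_frac = control["rupture_frac"];
  const double bbox_hx = control["bbox_hx"], bbox_hy = control["bbox_hy"];
  const double escape_margin = control["escape_margin"];

  NumericMatrix phi = clone(phi0), P = clone(P0);
  std::vector<double> lap(n), gx(n), gy(n), delta(n);
  std::vector<double> ifx, ify;

  const long nsteps = (long)std::llround(duration / dt);
  const long rec_stride = std::max(1L, (long)std::llround(record_every / dt));
  const long fld_stride = fields_every > 0
      ? std::max(1L, (long)std::llround(fields_every / dt)) : 0;

  std::vector<double> rec_t, rec_x, rec_y, rec_a, rec_s;
  std::vector<double> log_t, log_x, log_y, log_b, log_fb;
  List snap_phi, snap_P; std::vector<double> snap_t;

  bool ruptured = false, escaped = false, failed = false;
  double phi_min = 1e300, phi_max = -1e300;
  double A_last = area_phi2(phi.begin(), n, dx);
  double s_last = perimeter_integral(phi.begin(), n, dx, q.lambda);

  double t = 0.0;
  double next_fire = std::isfinite(q.tau_f) ? q.tau_f : R_PosInf;
  RNGScope rng;

  auto record = [&](double tt) {
    double m = 0.0, sx = 0.0, sy = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double ph = phi[idx(i, j, nx)];
        m += ph; sx += ph * (ox + i * dx); sy += ph * (oy + j * dx);
      }
    double xc = sx / m, yc = sy / m;
    rec_t.push_back(tt); rec_x.push_back(xc); rec_y.push_back(yc);
    rec_a.push_back(A_last); rec_s.push_back(s_last);
    if (!R_finite(xc) || !R_finite(A_last)) failed = true;
    if (std::fabs(xc) > bbox_hx + escape_margin || std::fabs(yc) > bbox_hy + escape_margin)
      escaped = true;
    std::vector<double> comps = component_areas(phi.begin(), nx, ny, dx);
    double thr = rupture_frac * M_PI * q.R0 * q.R0;
    int big = 0; for (double a : comps) if (a > thr) ++big;
    if (big > 1) ruptured = true;
    for (int k = 0; k < n; ++k) {
      if (phi[k] < phi_min) phi_min = phi[k];
      if (phi[k] > phi_max) phi_max = phi[k];
    }
  };

  record(0.0);
  if (fld_stride > 0) {
    snap_phi.push_back(clone(phi)); snap_P.push_back(clone(P)); snap_t.push_back(0.0);
  }

  for (long step = 1; step <= nsteps && !failed; ++step) {
    step_fields(phi.begin(), P.begin(), chi.begin(), lap.data(), gx.data(),
                gy.data(), delta.data(), nx, ny, dx, dt, q, freeze_shape,
                &A_last, &s_last);
    t = step * dt;

    // polarity patch impulses: once per tau_f of simulated time
    while (t >= next_fire - 1e-9) {
      interface_points(phi.begin(), nx, ny, dx, ox, oy, ifx, ify);
      size_t m = ifx.size();
      if (m > 0) {
        std::vector<double> w(m);
        double tot = 0.0;
        for (size_t k = 0; k < m; ++k) {
          double Pv = interp(P.begin(), nx, ny, dx, ox, oy, ifx[k], ify[k], 0.0);
          double wk = Pv > 0.0 ? Pv : 0.0;
          if (!q.no_filopodia) {
            // outward normal from -grad(phi)/|grad(phi)| at the contour point
            double gxx = 0.0, gyy = 0.0;
            {
              // central-difference gradient interpolated at the point
              double e = dx;
              double pxp = interp(phi.begin(), nx, ny, dx, ox, oy, ifx[k] + e, ify[k], 0.0);
              double pxm = interp(phi.begin(), nx, ny, dx, ox, oy, ifx[k] - e, ify[k], 0.0);
              double pyp = interp(phi.begin(), nx, ny, dx, ox, oy, ifx[k], ify[k] + e, 0.0);
              double pym = interp(phi.begin(), nx, ny, dx, ox, oy, ifx[k], ify[k] - e, 0.0);
              gxx = (pxp - pxm) / (2 * e); gyy = (pyp - pym) / (2 * e);
            }
            double gn = std::sqrt(gxx * gxx + gyy * gyy);
            double chi_probe = 1.0;
            if (gn > 1e-12) {
              double qx = ifx[k] - q.ell * gxx / gn;
              double qy = ify[k] - q.ell * gyy / gn;
              chi_probe = interp(chi.begin(), nx, ny, dx, ox, oy, qx, qy, 1.0);
            }
            wk *= (1.0 - chi_probe);
            if (wk < 0.0) wk = 0.0;
          }
          w[k] = wk; tot += wk;
        }
        size_t pick;
        bool fallback = tot <= 0.0;
        if (fallback) {
          pick = (size_t)std::floor(unif_rand() * m);
          if (pick >= m) pick = m - 1;
        } else {
          double u = unif_rand() * tot, c = 0.0;
          pick = m - 1;
          for (size_t k = 0; k < m; ++k) { c += w[k]; if (u <= c) { pick = k; break; } }
        }
        double beta = norm_rand() * q.sigma_beta + q.mu_beta;
        add_patch(P.begin(), phi.begin(), nx, ny, dx, ox, oy,
                  ifx[pick], ify[pick], beta, q.sigma_patch);
        if (log_patches) {
          log_t.push_back(next_fire); log_x.push_back(ifx[pick]);
          log_y.push_back(ify[pick]); log_b.push_back(beta);
          log_fb.push_back(fallback ? 1.0 : 0.0);
        }
      }
      next_fire += q.tau_f;
    }

    if (step % rec_stride == 0) record(t);
    if (fld_stride > 0 && step % fld_stride == 0) {
      snap_phi.push_back(clone(phi)); snap_P.push_back(clone(P)); snap_t.push_back(t);
    }
  }

  NumericMatrix patches(log_t.size(), 5);
  for (size_t k = 0; k < log_t.size(); ++k) {
    patches(k, 0) = log_t[k]; patches(k, 1) = log_x[k];
    patches(k, 2) = log_y[k]; patches(k, 3) = log_b[k];
    patches(k, 4) = log_fb[k];
  }

  List out = List::create(
    _["t"] = wrap(rec_t), _["x"] = wrap(rec_x), _["y"] = wrap(rec_y),
    _["area"] = wrap(rec_a), _["perimeter"] = wrap(rec_s),
    _["ruptured"] = ruptured, _["escaped"] = escaped, _["failed"] = failed,
    _["phi"] = phi, _["P"] = P, _["patches"] = patches,
    _["phi_min"] = phi_min, _["phi_max"] = phi_max);
  if (fld_stride > 0) {
    out["snap_phi"] = snap_phi; out["snap_P"] = snap_P; out["snap_t"] = wrap(snap_t);
  }
  return out;
}

// Streamline tracing on a binned drift field.  F is nxb-by-nvb at bin
// centres; non-finite entries are masked and treated as outside the
// populated region (interpolation never reads a masked bin).
// [[Rcpp::export]]
List cpp_streamlines(NumericMatrix F, NumericVector x_centers, NumericVector v_centers,
                     NumericMatrix seeds, double dt_s, double eps_v, double eps_F,
                     int max_steps, int keep_points) {
  const int nxb = F.nrow(), nvb = F.ncol();
  const double x0 = x_centers[0], v0 = v_centers[0];
  const double dxb = nxb > 1 ? x_centers[1] - x_centers[0] : 1.0;
  const double dvb = nvb > 1 ? v_centers[1] - v_centers[0] : 1.0;

  auto evalF = [&](double x, double v, bool* ok) -> double {
    double fx = (x - x0) / dxb, fv = (v - v0) / dvb;
    if (fx < 0.0 || fv < 0.0 || fx > nxb - 1.0 || fv > nvb - 1.0) { *ok = false; return 0.0; }
    int i = (int)std::floor(fx); if (i > nxb - 2) i = nxb - 2;
    int j = (int)std::floor(fv); if (j > nvb - 2) j = nvb - 2;
    double a = F(i, j), b = F(i + 1, j), c = F(i, j + 1), d = F(i + 1, j + 1);
    if (!R_finite(a) || !R_finite(b) || !R_finite(c) || !R_finite(d)) { *ok = false; return 0.0; }
    double tx = fx - i, tv = fv - j;
    *ok = true;
    return (1 - tx) * (1 - tv) * a + tx * (1 - tv) * b + (1 - tx) * tv * c + tx * tv * d;
  };

  const int ns = seeds.nrow();
  IntegerVector status(ns), used(ns);
  NumericVector xf(ns), vf(ns);
  List paths(ns);
  const int stride = std::max(1, max_steps / std::max(1, keep_points));

  for (int s = 0; s < ns; ++s) {
    double x = seeds(s, 0), v = seeds(s, 1);
    std::vector<double> px, pv;
    int st = 3; // 1 terminal, 2 escaped, 3 max-steps (cycling candidate)
    int k = 0;
    for (; k < max_steps; ++k) {
      bool ok;
      double Fv = evalF(x, v, &ok);
      if (!ok) { st = 2; break; }
      if (k % stride == 0) { px.push_back(x); pv.push_back(v); }
      if (std::fabs(v) < eps_v && std::fabs(Fv) < eps_F) { st = 1; break; }
      double xn = x + v * dt_s;
      double vn = v + Fv * dt_s;
      x = xn; v = vn;
    }
    px.push_back(x); pv.push_back(v);
    status[s] = st; used[s] = k; xf[s] = x; vf[s] = v;
    NumericMatrix pm(px.size(), 2);
    for (size_t m = 0; m < px.size(); ++m) { pm(m, 0) = px[m]; pm(m, 1) = pv[m]; }
    paths[s] = pm;
  }
  return List::create(_["status"] = status, _["steps"] = used,
                      _["x_end"] = xf, _["v_end"] = vf, _["paths"] = paths);
}
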