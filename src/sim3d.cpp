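// Compiled time-stepping core for the cylindrical 3D model: binary
// spherical retina on an azimuth-elevation grid, row-wise left-right edge
// detection, and the three coupled velocity equations.  Mirrors the R
// path (render_spherical_field -> spherical_functionals -> derivatives_3d
// -> step_swarm) cell for cell.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double wrap_angle(double a) {
  // floor-based modulo, identical to R's (a + pi) %% (2*pi) - pi
  double b = a + M_PI;
  double w = b - std::floor(b / (2.0 * M_PI)) * (2.0 * M_PI) - M_PI;
  if (w == -M_PI) w = M_PI;
  return w;
}

}  // namespace

// [[Rcpp::export]]
List sim3d_cpp(NumericMatrix state0, double gamma, double v0, double alpha0,
               double alpha1, double beta0, double beta1, double lambda0,
               double lambda1, double BL, double dt, int n_phi, int n_theta,
               int n_steps, IntegerVector record_at) {
  const int N = state0.nrow();
  std::vector<double> x(N), y(N), z(N), vpsi(N), psi(N), vz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = state0(i, 0);
    y[i] = state0(i, 1);
    z[i] = state0(i, 2);
    vpsi[i] = state0(i, 3);
    psi[i] = state0(i, 4);
    vz[i] = state0(i, 5);
  }

  // retina cell centers, symmetric about 0 (matches retina_grid() in R)
  const double dphi = 2.0 * M_PI / n_phi;
  const double dtheta = M_PI / n_theta;
  std::vector<double> phi(n_phi), theta(n_theta);
  std::vector<double> cp(n_phi), sp(n_phi), ct(n_theta), st(n_theta);
  for (int k = 0; k < n_phi; ++k) {
    phi[k] = ((k + 1) - (n_phi + 1) / 2.0) * dphi;
    cp[k] = std::cos(phi[k]);
    sp[k] = std::sin(phi[k]);
  }
  for (int l = 0; l < n_theta; ++l) {
    theta[l] = ((l + 1) - (n_theta + 1) / 2.0) * dtheta;
    ct[l] = std::cos(theta[l]);
    st[l] = std::sin(theta[l]);
  }
  // cell direction vectors, column-major [k + n_phi * l]
  const size_t ncell = static_cast<size_t>(n_phi) * n_theta;
  std::vector<double> Xd(ncell), Yd(ncell), Zd(ncell);
  for (int l = 0; l < n_theta; ++l)
    for (int k = 0; k < n_phi; ++k) {
      size_t idx = k + static_cast<size_t>(n_phi) * l;
      Xd[idx] = cp[k] * ct[l];
      Yd[idx] = sp[k] * ct[l];
      Zd[idx] = st[l];
    }

  const int nrec = record_at.size();
  NumericVector states(Dimension(nrec, N, 6));
  NumericVector min_dist(n_steps + 1);
  std::vector<double> dvp(N), dps(N), dvz(N);
  std::vector<char> occ(ncell);

  int rec_ptr = 0;
  auto record = [&](int step) {
    while (rec_ptr < nrec && record_at[rec_ptr] == step) {
      for (int i = 0; i < N; ++i) {
        states[rec_ptr + nrec * (i + N * 0)] = x[i];
        states[rec_ptr + nrec * (i + N * 1)] = y[i];
        states[rec_ptr + nrec * (i + N * 2)] = z[i];
        states[rec_ptr + nrec * (i + N * 3)] = vpsi[i];
        states[rec_ptr + nrec * (i + N * 4)] = psi[i];
        states[rec_ptr + nrec * (i + N * 5)] = vz[i];
      }
      ++rec_ptr;
    }
  };
  record(0);

  const double w_area = dphi * dtheta;

  for (int s = 0; s < n_steps; ++s) {
    double mind = R_PosInf;
    for (int i = 0; i < N; ++i) {
      std::fill(occ.begin(), occ.end(), 0);
      const double cpsi = std::cos(psi[i]), spsi = std::sin(psi[i]);
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < mind) mind = d;
        if (d == 0.0)
          stop("degenerate geometry: agents %d and %d coincide", i + 1,
               j + 1);
        double xp = cpsi * dx + spsi * dy;
        double yp = -spsi * dx + cpsi * dy;
        double n1 = xp / d, n2 = yp / d, n3 = dz / d;
        double sr = BL / (2.0 * d);
        if (sr > 1.0) sr = 1.0;
        double crho = std::cos(std::asin(sr));
        for (size_t c = 0; c < ncell; ++c) {
          if (occ[c]) continue;
          if (Xd[c] * n1 + Yd[c] * n2 + Zd[c] * n3 >= crho) occ[c] = 1;
        }
      }
      // area and row-wise edge functionals
      double Ac = 0, As = 0, Av = 0, Ec = 0, Es = 0, Ev = 0;
      for (int l = 0; l < n_theta; ++l) {
        const char* row = occ.data() + static_cast<size_t>(n_phi) * l;
        double rc = 0, rs = 0, rv = 0, ec = 0, es = 0;
        int ne = 0;
        for (int k = 0; k < n_phi; ++k) {
          if (row[k]) {
            rc += cp[k];
            rs += sp[k];
            rv += 1.0;
          }
          int prev = (k + n_phi - 1) % n_phi;
          if (row[k] != row[prev]) {
            double e = phi[k] - dphi / 2.0;
            ec += std::cos(e);
            es += std::sin(e);
            ++ne;
          }
        }
        Ac += rc * ct[l];
        As += rs * ct[l];
        Av += rv * st[l];
        Ec += ct[l] * dtheta * ec;
        Es += ct[l] * dtheta * es;
        Ev += st[l] * dtheta * ne;
      }
      Ac *= w_area;
      As *= w_area;
      Av *= w_area;
      dvp[i] = alpha0 * (-Ac + alpha1 * Ec) + gamma * (v0 - vpsi[i]);
      dps[i] = beta0 * (-As + beta1 * Es);
      dvz[i] = lambda0 * (-Av + lambda1 * Ev);
    }
    min_dist[s] = mind;
    for (int i = 0; i < N; ++i) {
      vpsi[i] += dt * dvp[i];
      psi[i] = wrap_angle(psi[i] + dt * dps[i]);
      vz[i] += dt * dvz[i];
      x[i] += dt * vpsi[i] * std::cos(psi[i]);
      y[i] += dt * vpsi[i] * std::sin(psi[i]);
      z[i] += dt * vz[i];
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(z[i]) || !std::isfinite(vpsi[i]) ||
          !std::isfinite(psi[i]) || !std::isfinite(vz[i]))
        stop("integration failure at step %d: non-finite state for agent %d",
             s + 1, i + 1);
    }
    if (s % 16 == 0) Rcpp::checkUserInterrupt();
    record(s + 1);
  }

  double mind = R_PosInf;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < mind) mind = d;
    }
  min_dist[n_steps] = mind;

  return List::create(_["states"] = states, _["min_dist"] = min_dist);
}
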