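// Compiled time-stepping core for the 2D vision-based model.  The math
// mirrors the R reference path (visual_field -> visual_accel/visual_turn ->
// step_swarm) exactly: per focal agent the retinal arcs of all neighbors
// are unioned with occlusion, the trigonometric area and edge functionals
// are evaluated in closed form (edges as a unit-weight Dirac comb, cut
// artifacts at +-pi excluded), and the swarm is advanced by synchronous
// explicit Euler.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double wrap_angle(double a) {
  // floor-based modulo, identical to R's (a + pi) %% (2*pi) - pi
  double b = a + M_PI;
  double w = b - std::floor(b / (2.0 * M_PI)) * (2.0 * M_PI) - M_PI;
  if (w == -M_PI) w = M_PI;  // retina convention (-pi, pi]
  return w;
}

struct Seg {
  double lo, hi;
};

// Visual functionals of agent i from the current swarm state; also folds
// the pairwise distances seen from i into min_d.
void functionals2d(int i, int N, const double* x, const double* y,
                   const double* psi, double BL, double& Acos, double& Asin,
                   double& Ecos, double& Esin, double& min_d,
                   std::vector<Seg>& segs) {
  segs.clear();
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    double dx = x[j] - x[i], dy = y[j] - y[i];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < min_d) min_d = d;
    if (d == 0.0)
      stop("degenerate geometry: agents %d and %d coincide", i + 1, j + 1);
    double bearing = wrap_angle(std::atan2(dy, dx) - psi[i]);
    double s = BL / (2.0 * d);
    if (s > 1.0) s = 1.0;
    double rho = std::asin(s);
    double lo = bearing - rho;
    double hi;
    if (lo < -M_PI) lo += 2.0 * M_PI;
    hi = lo + 2.0 * rho;
    if (hi > M_PI) {
      if (M_PI > lo) segs.push_back({lo, M_PI});
      double h2 = hi - 2.0 * M_PI;
      if (h2 > -M_PI) segs.push_back({-M_PI, h2});
    } else {
      segs.push_back({lo, hi});
    }
  }
  Acos = Asin = Ecos = Esin = 0.0;
  if (segs.empty()) return;
  std::sort(segs.begin(), segs.end(),
            [](const Seg& a, const Seg& b) { return a.lo < b.lo; });
  // merge overlapping/touching segments in place
  size_t m = 0;
  Seg cur = segs[0];
  for (size_t k = 1; k < segs.size(); ++k) {
    if (segs[k].lo <= cur.hi + 1e-12) {
      if (segs[k].hi > cur.hi) cur.hi = segs[k].hi;
    } else {
      segs[m++] = cur;
      cur = segs[k];
    }
  }
  segs[m++] = cur;
  segs.resize(m);
  for (size_t k = 0; k < m; ++k) {
    Acos += std::sin(segs[k].hi) - std::sin(segs[k].lo);
    Asin += std::cos(segs[k].lo) - std::cos(segs[k].hi);
  }
  const double tol = 1e-9;
  bool wrapc = segs[0].lo <= -M_PI + tol && segs[m - 1].hi >= M_PI - tol;
  for (size_t k = 0; k < m; ++k) {
    if (!(wrapc && k == 0)) {
      Ecos += std::cos(segs[k].lo);
      Esin += std::sin(segs[k].lo);
    }
    if (!(wrapc && k == m - 1)) {
      Ecos += std::cos(segs[k].hi);
      Esin += std::sin(segs[k].hi);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List sim2d_cpp(NumericMatrix state0, double gamma, double v0, double alpha0,
               double alpha1, double beta0, double beta1, double BL,
               double dt, int n_steps, IntegerVector record_at) {
  const int N = state0.nrow();
  std::vector<double> x(N), y(N), v(N), psi(N);
  for (int i = 0; i < N; ++i) {
    x[i] = state0(i, 0);
    y[i] = state0(i, 1);
    v[i] = state0(i, 2);
    psi[i] = state0(i, 3);
  }
  const int nrec = record_at.size();
  NumericVector states(Dimension(nrec, N, 4));
  NumericVector min_dist(n_steps + 1);
  std::vector<double> dv(N), dpsi(N);
  std::vector<Seg> segs;
  segs.reserve(2 * static_cast<size_t>(N));

  int rec_ptr = 0;
  auto record = [&](int step) {
    while (rec_ptr < nrec && record_at[rec_ptr] == step) {
      for (int i = 0; i < N; ++i) {
        states[rec_ptr + nrec * (i + N * 0)] = x[i];
        states[rec_ptr + nrec * (i + N * 1)] = y[i];
        states[rec_ptr + nrec * (i + N * 2)] = v[i];
        states[rec_ptr + nrec * (i + N * 3)] = psi[i];
      }
      ++rec_ptr;
    }
  };
  record(0);

  for (int s = 0; s < n_steps; ++s) {
    double mind = R_PosInf;
    for (int i = 0; i < N; ++i) {
      double Ac, As, Ec, Es;
      functionals2d(i, N, x.data(), y.data(), psi.data(), BL, Ac, As, Ec, Es,
                    mind, segs);
      dv[i] = gamma * (v0 - v[i]) + alpha0 * (-Ac + alpha1 * Ec);
      dpsi[i] = beta0 * (-As + beta1 * Es);
    }
    min_dist[s] = mind;
    for (int i = 0; i < N; ++i) {
      v[i] += dt * dv[i];
      psi[i] = wrap_angle(psi[i] + dt * dpsi[i]);
      x[i] += dt * v[i] * std::cos(psi[i]);
      y[i] += dt * v[i] * std::sin(psi[i]);
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
          !std::isfinite(v[i]) || !std::isfinite(psi[i]))
        stop("integration failure at step %d: non-finite state for agent %d",
             s + 1, i + 1);
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    record(s + 1);
  }

  double mind = R_PosInf;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < mind) mind = d;
    }
  min_dist[n_steps] = mind;

  return List::create(_["states"] = states, _["min_dist"] = min_dist);
}
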