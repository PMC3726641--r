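// Overdamped Langevin dynamics on analytic toy potentials with optional
// well-tempered metadynamics bias. The bias (and its analytic gradient,
// accumulated per deposited Gaussian - no finite differences) is cached on a
// dense grid, PLUMED sum_hills style, and linearly interpolated at the
// particle position; supported for 1- and 2-dimensional CV spaces.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct AxisPot {
  int form;      // 0 = double well, 1 = harmonic
  double p1, p2, p3;  // dw: barrier, center, halfsep; harm: k, center, -
  double energy(double s) const {
    if (form == 0) {
      double d = (s - p2) * (s - p2) - p3 * p3;
      return p1 * d * d / (p3 * p3 * p3 * p3);
    }
    double d = s - p2;
    return 0.5 * p1 * d * d;
  }
  double grad(double s) const {
    if (form == 0) {
      double d = (s - p2) * (s - p2) - p3 * p3;
      return 4.0 * p1 * d * (s - p2) / (p3 * p3 * p3 * p3);
    }
    return p1 * (s - p2);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_run_langevin")]]
List cpp_run_langevin(IntegerVector forms, NumericMatrix axis_params,
                      NumericVector x0, int n_steps, double dt,
                      double temperature, double diffusion,
                      double wall_limit, double wall_kappa,
                      bool biased, double w0, double sigma, int pace_steps,
                      double bias_factor,
                      NumericVector grid_lo, NumericVector grid_hi,
                      double grid_spacing, int stride) {
  const int d = forms.size();
  if (d < 1 || d > 3) stop("engine supports 1 to 3 dimensions");
  if (biased && d > 2)
    stop("biased runs are supported for 1- or 2-dimensional CV spaces only");
  const double kB = 0.0019872;
  const double kBT = kB * temperature;
  const double mobility = diffusion / kBT;           // Einstein relation
  const double noise_amp = std::sqrt(2.0 * diffusion * dt);
  const double kBdT = kB * (bias_factor - 1.0) * temperature;

  std::vector<AxisPot> pot(d);
  for (int k = 0; k < d; ++k) {
    pot[k].form = forms[k];
    pot[k].p1 = axis_params(k, 0);
    pot[k].p2 = axis_params(k, 1);
    pot[k].p3 = axis_params(k, 2);
  }

  // bias grids (V and its analytic per-axis gradient)
  std::vector<int> ng(d, 0);
  long grid_total = 1;
  for (int k = 0; k < d; ++k) {
    ng[k] = (int)std::floor((grid_hi[k] - grid_lo[k]) / grid_spacing) + 1;
    grid_total *= ng[k];
  }
  std::vector<double> V;
  std::vector<std::vector<double> > G(d);
  if (biased) {
    V.assign(grid_total, 0.0);
    for (int k = 0; k < d; ++k) G[k].assign(grid_total, 0.0);
  }
  const double sig2 = sigma * sigma;
  const int win = (int)std::ceil(8.0 * sigma / grid_spacing);

  std::vector<double> x(x0.begin(), x0.end());
  if ((int)x.size() != d) stop("x0 length must match dimensionality");

  int n_out = n_steps / stride + 1;
  NumericMatrix traj(n_out, d);
  NumericVector traj_t(n_out);
  int out_i = 0;

  int max_hills = biased ? n_steps / pace_steps + 1 : 0;
  NumericMatrix hill_center(std::max(max_hills, 1), d);
  NumericVector hill_height(std::max(max_hills, 1));
  NumericVector hill_time(std::max(max_hills, 1));
  int n_hills = 0;

  // linear interpolation of a grid array at point x (clamped)
  auto interp = [&](const std::vector<double>& A) -> double {
    if (d == 1) {
      double u = (x[0] - grid_lo[0]) / grid_spacing;
      int i0 = (int)std::floor(u);
      if (i0 < 0) { i0 = 0; u = 0; }
      if (i0 >= ng[0] - 1) { i0 = ng[0] - 2; u = i0 + 1; }
      double f = u - i0;
      return A[i0] * (1 - f) + A[i0 + 1] * f;
    }
    double u = (x[0] - grid_lo[0]) / grid_spacing;
    double v = (x[1] - grid_lo[1]) / grid_spacing;
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
    if (i0 < 0) { i0 = 0; u = 0; }
    if (j0 < 0) { j0 = 0; v = 0; }
    if (i0 >= ng[0] - 1) { i0 = ng[0] - 2; u = i0 + 1; }
    if (j0 >= ng[1] - 1) { j0 = ng[1] - 2; v = j0 + 1; }
    double fu = u - i0, fv = v - j0;
    long b = (long)j0 * ng[0] + i0;
    return A[b] * (1 - fu) * (1 - fv) + A[b + 1] * fu * (1 - fv) +
           A[b + ng[0]] * (1 - fu) * fv + A[b + ng[0] + 1] * fu * fv;
  };

  auto deposit_hill = [&](double t_now) {
    double Vs = interp(V);
    double w = w0 * std::exp(-Vs / kBdT);
    hill_time[n_hills] = t_now;
    for (int k = 0; k < d; ++k) hill_center(n_hills, k) = x[k];
    hill_height[n_hills] = w;
    ++n_hills;
    if (d == 1) {
      int c = (int)std::round((x[0] - grid_lo[0]) / grid_spacing);
      int i1 = std::max(0, c - win), i2 = std::min(ng[0] - 1, c + win);
      for (int i = i1; i <= i2; ++i) {
        double s = grid_lo[0] + i * grid_spacing;
        double dz = s - x[0];
        double g = w * std::exp(-dz * dz / (2 * sig2));
        V[i] += g;
        G[0][i] += -dz / sig2 * g;
      }
    } else {
      int c0 = (int)std::round((x[0] - grid_lo[0]) / grid_spacing);
      int c1 = (int)std::round((x[1] - grid_lo[1]) / grid_spacing);
      int i1 = std::max(0, c0 - win), i2 = std::min(ng[0] - 1, c0 + win);
      int j1 = std::max(0, c1 - win), j2 = std::min(ng[1] - 1, c1 + win);
      for (int j = j1; j <= j2; ++j) {
        double sy = grid_lo[1] + j * grid_spacing;
        double dy = sy - x[1];
        double gy = std::exp(-dy * dy / (2 * sig2));
        for (int i = i1; i <= i2; ++i) {
          double sx = grid_lo[0] + i * grid_spacing;
          double dx = sx - x[0];
          double g = w * std::exp(-dx * dx / (2 * sig2)) * gy;
          long b = (long)j * ng[0] + i;
          V[b] += g;
          G[0][b] += -dx / sig2 * g;
          G[1][b] += -dy / sig2 * g;
        }
      }
    }
  };

  RNGScope scope;
  for (int k = 0; k < d; ++k) traj(0, k) = x[k];
  traj_t[0] = 0.0;
  out_i = 1;

  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < d; ++k) {
      double F = pot[k].grad(x[k]);                    // dU/dx
      if (x[k] > wall_limit) F += 2.0 * wall_kappa * (x[k] - wall_limit);
      if (biased && n_hills > 0) F += interp(G[k]);    // analytic bias grad
      x[k] += -mobility * F * dt + noise_amp * R::norm_rand();
      if (!std::isfinite(x[k]) ||
          x[k] > grid_hi[k] + 10.0 || x[k] < grid_lo[k] - 10.0)
        stop("dynamics diverged at step %d (axis %d, x = %g); "
             "reduce dt or diffusion", step, k + 1, x[k]);
    }
    if (biased && step % pace_steps == 0) deposit_hill(step * dt);
    if (step % stride == 0 && out_i < n_out) {
      for (int k = 0; k < d; ++k) traj(out_i, k) = x[k];
      traj_t[out_i] = step * dt;
      ++out_i;
    }
  }

  List out = List::create(
      Named("times") = traj_t,
      Named("positions") = traj,
      Named("n_hills") = n_hills);
  if (biased && n_hills > 0) {
    out["hill_time"] = NumericVector(hill_time.begin(),
                                     hill_time.begin() + n_hills);
    NumericMatrix hc(n_hills, d);
    for (int i = 0; i < n_hills; ++i)
      for (int k = 0; k < d; ++k) hc(i, k) = hill_center(i, k);
    out["hill_center"] = hc;
    out["hill_height"] = NumericVector(hill_height.begin(),
                                       hill_height.begin() + n_hills);
  }
  return out;
}
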