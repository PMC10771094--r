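#include <Rcpp.h>
using namespace Rcpp;

// Ornstein-Uhlenbeck velocity flight simulator with reflecting cage walls.
//
// Velocity relaxes toward zero with time constant tau_s and is driven by
// Gaussian increments; during emission periods an additional drift
// (looked up from a precomputed acceleration profile over distance from the
// source) pushes the agent along +x away from the deterrent end. Positions
// and velocities reflect at the cage faces. Uses R's RNG so results are
// reproducible under set.seed().
//
// drift_idx: per-frame 1-based row into drift_tab, 0 = no drift.
// drift_tab: rows = treatments, cols = acceleration (m/s^2) sampled every
//            grid_dx meters of distance from the source, starting at 0.
// ud_dir:    +1 source at x = 0, -1 source at x = length.
// airborne:  frames where FALSE freeze the position (landed bat).
// [[Rcpp::export(name = ".sim_ou_flight")]]
List sim_ou_flight(int n_frames, double dt,
                   NumericVector box,
                   double tau_s, double sigma_c, double max_accel,
                   IntegerVector drift_idx, NumericMatrix drift_tab,
                   double grid_dx, int ud_dir,
                   LogicalVector airborne, NumericVector start) {
  const double L = box[0], W = box[1], H = box[2];
  NumericMatrix pos(n_frames, 3);
  const double sig_w = sigma_c * std::sqrt(2.0 / tau_s) * std::sqrt(dt);
  const int n_grid = drift_tab.ncol();
  double x = start[0], y = start[1], z = start[2];
  double vx = R::rnorm(0.0, sigma_c), vy = R::rnorm(0.0, sigma_c),
         vz = R::rnorm(0.0, sigma_c);

  for (int t = 0; t < n_frames; ++t) {
    if (airborne[t]) {
      double ax = 0.0;
      int row = drift_idx[t];
      if (row > 0) {
        double r = (ud_dir > 0) ? x : (L - x);
        int gi = (int)(r / grid_dx);
        if (gi < 0) gi = 0;
        if (gi >= n_grid) gi = n_grid - 1;
        double a = drift_tab(row - 1, gi);
        if (a > max_accel) a = max_accel;
        ax = (ud_dir > 0) ? a : -a;
      }
      vx += (-vx / tau_s + ax) * dt + sig_w * R::norm_rand();
      vy += (-vy / tau_s) * dt + sig_w * R::norm_rand();
      vz += (-vz / tau_s) * dt + sig_w * R::norm_rand();
      x += vx * dt; y += vy * dt; z += vz * dt;
      // reflecting boundaries (repeat in case of overshoot past both walls)
      for (int k = 0; k < 8; ++k) {
        bool moved = false;
        if (x < 0)  { x = -x;        vx = -vx; moved = true; }
        if (x > L)  { x = 2 * L - x; vx = -vx; moved = true; }
        if (y < 0)  { y = -y;        vy = -vy; moved = true; }
        if (y > W)  { y = 2 * W - y; vy = -vy; moved = true; }
        if (z < 0)  { z = -z;        vz = -vz; moved = true; }
        if (z > H)  { z = 2 * H - z; vz = -vz; moved = true; }
        if (!moved) break;
      }
    }
    pos(t, 0) = x; pos(t, 1) = y; pos(t, 2) = z;
  }
  return List::create(_["pos"] = pos);
}

// Per-row median and median absolute deviation of a pixels x frames matrix.
// [[Rcpp::export(name = ".row_median_mad")]]
List row_median_mad(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector med(nr), mad(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = m(i, j);
    std::nth_element(buf.begin(), buf.begin() + nc / 2, buf.end());
    double md = buf[nc / 2];
    if (nc % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + nc / 2 - 1,
                       buf.begin() + nc / 2);
      md = 0.5 * (md + buf[nc / 2 - 1]);
    }
    med[i] = md;
    for (int j = 0; j < nc; ++j) buf[j] = std::fabs(m(i, j) - md);
    std::nth_element(buf.begin(), buf.begin() + nc / 2, buf.end());
    double mm = buf[nc / 2];
    if (nc % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + nc / 2 - 1,
                       buf.begin() + nc / 2);
      mm = 0.5 * (mm + buf[nc / 2 - 1]);
    }
    mad[i] = mm;
  }
  return List::create(_["median"] = med, _["mad"] = mad);
}
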