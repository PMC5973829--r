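#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shared RT-bin assignment: bin of the step time t (seconds). The small
// epsilon keeps step times that land exactly on a bin edge (up to floating
// point noise) in the same bin as the R-side assignment of observed RTs.
static inline int rt_bin_index(double t, double rt_bin, int n_bins) {
  int b = (int)std::floor(t / rt_bin + 1e-9);
  if (b < 0) b = 0;
  if (b >= n_bins) b = n_bins - 1;
  return b;
}

// Joint (choice, RT-bin) probabilities of the collapsing-bound accumulator,
// by deterministic forward propagation of the per-step Gaussian transition
// kernel over a fixed RDV grid with absorbing bounds. One column per drift.
// [[Rcpp::export]]
List cpp_fpt_density(NumericVector drifts, double bound0, double decay,
                     double ndt, double noise_sd, double dt, double deadline,
                     double rt_bin, int n_grid, double span) {
  const int nd = drifts.size();
  const int n_bins = (int)std::ceil(deadline / rt_bin - 1e-9);
  const double h = 2.0 * span * bound0 / (n_grid - 1);
  if (bound0 < 3.0 * h)
    stop("RDV grid too coarse to resolve the bound (bound0 < 3 grid steps)");
  const int K = (int)std::floor((deadline - ndt) / dt + 1e-9);
  const int center = (n_grid - 1) / 2;

  // grid point values
  std::vector<double> x(n_grid);
  for (int i = 0; i < n_grid; ++i) x[i] = -span * bound0 + i * h;

  // Per-step absorption geometry.  Mass at grid point i represents a
  // uniform cell [x_i - h/2, x_i + h/2]; the fraction of each cell beyond
  // the bound is absorbed, so the likelihood varies continuously with the
  // bound parameters instead of jumping as the bound crosses grid points.
  // iu/il: first fully absorbed index on each side; fu/fl: absorbed
  // fraction of the straddling cell just inside.
  std::vector<int> iu(K + 1), il(K + 1);
  std::vector<double> fu(K + 1), fl(K + 1);
  const double x0 = x[0];
  for (int k = 1; k <= K; ++k) {
    double b = bound0 * std::exp(-decay * k * dt);
    double a = (b - x0 + 0.5 * h) / h;   // cells fully below +b
    int ifull = (int)std::ceil(a - 1e-12);
    if (ifull < 1) ifull = 1;
    if (ifull > n_grid) ifull = n_grid;
    iu[k] = ifull;
    fu[k] = (ifull > 0 && ifull <= n_grid) ? (ifull - a) : 0.0;
    if (fu[k] < 0) fu[k] = 0; if (fu[k] > 1) fu[k] = 1;
    double c = (-b - x0 - 0.5 * h) / h;  // cells fully above -b end here
    int lfull = (int)std::floor(c + 1e-12);
    if (lfull > n_grid - 2) lfull = n_grid - 2;
    if (lfull < -1) lfull = -1;
    il[k] = lfull;
    fl[k] = c - lfull;
    if (fl[k] < 0) fl[k] = 0; if (fl[k] > 1) fl[k] = 1;
  }

  NumericMatrix p_yes(n_bins, nd), p_no(n_bins, nd);
  NumericVector p_missed(nd);

  std::vector<double> p(n_grid), q(n_grid);
  for (int d = 0; d < nd; ++d) {
    const double v = drifts[d];
    // decompose the drift shift into an integer number of grid cells plus
    // a remainder, so the kernel band stays narrow for large drifts
    const int m = (int)std::lround(v / h);
    const double vf = v - m * h;
    const int J0 = (int)std::ceil((std::fabs(vf) + 5.0 * noise_sd) / h);
    const int jlo = m - J0, jhi = m + J0;    // nonzero kernel offsets
    std::vector<double> w(2 * J0 + 1);
    double prev = R::pnorm((-J0 * h - 0.5 * h - vf) / noise_sd, 0.0, 1.0, 1, 0);
    const double tail_lo = prev;
    for (int j = -J0; j <= J0; ++j) {
      double cur = R::pnorm((j * h + 0.5 * h - vf) / noise_sd, 0.0, 1.0, 1, 0);
      w[j + J0] = cur - prev;
      prev = cur;
    }
    w[0] += tail_lo;            // far tails land beyond the bound anyway
    w[2 * J0] += 1.0 - prev;

    std::fill(p.begin(), p.end(), 0.0);
    p[center] = 1.0;
    int lo = center, hi = center;        // current support of interior mass
    double yes_acc, no_acc, interior = 1.0;

    for (int k = 1; k <= K; ++k) {
      std::fill(q.begin(), q.end(), 0.0);
      int nlo = std::min(std::max(lo + jlo, 0), n_grid - 1);
      int nhi = std::max(std::min(hi + jhi, n_grid - 1), 0);
      for (int i = lo; i <= hi; ++i) {
        const double pi = p[i];
        if (pi <= 0.0) continue;
        int j0 = std::max(jlo, -i), j1 = std::min(jhi, n_grid - 1 - i);
        if (j0 > j1) {              // entire kernel lands off-grid
          if (i + jhi < 0) q[0] += pi; else q[n_grid - 1] += pi;
          continue;
        }
        // fold kernel mass that would leave the grid onto the edge points
        if (j0 > jlo) {
          double fold = 0.0;
          for (int j = jlo; j < j0; ++j) fold += w[j - jlo];
          q[0] += pi * fold;
        }
        if (j1 < jhi) {
          double fold = 0.0;
          for (int j = j1 + 1; j <= jhi; ++j) fold += w[j - jlo];
          q[n_grid - 1] += pi * fold;
        }
        const double *wj = &w[j0 - jlo];
        double *qd = &q[i + j0];
        for (int j = j0; j <= j1; ++j) *qd++ += pi * *wj++;
      }
      // absorb at the (possibly collapsed) bound, fractionally at the
      // straddling cells
      yes_acc = 0.0; no_acc = 0.0;
      for (int i = std::max(iu[k], 0); i <= n_grid - 1; ++i) {
        yes_acc += q[i]; q[i] = 0.0;
      }
      for (int i = 0; i <= std::min(il[k], n_grid - 1); ++i) {
        no_acc += q[i]; q[i] = 0.0;
      }
      if (iu[k] - 1 >= 0 && iu[k] - 1 <= n_grid - 1 && fu[k] > 0) {
        double frac = q[iu[k] - 1] * fu[k];
        yes_acc += frac; q[iu[k] - 1] -= frac;
      }
      if (il[k] + 1 >= 0 && il[k] + 1 <= n_grid - 1 && fl[k] > 0) {
        double frac = q[il[k] + 1] * fl[k];
        no_acc += frac; q[il[k] + 1] -= frac;
      }
      const double t = ndt + k * dt;
      const int b = rt_bin_index(t, rt_bin, n_bins);
      p_yes(b, d) += yes_acc;
      p_no(b, d) += no_acc;
      interior -= yes_acc + no_acc;

      lo = std::max(nlo, il[k] + 1); hi = std::min(nhi, iu[k] - 1);
      // trim vanishing tails of the interior support (mass dropped is
      // bounded by n_grid * K * 1e-16, far below the 1e-6 mass tolerance)
      while (lo < hi && q[lo] < 1e-16) ++lo;
      while (hi > lo && q[hi] < 1e-16) --hi;
      std::swap(p, q);
      if (interior < 1e-12 || lo > hi) { break; }
    }
    double rem = 0.0;
    for (int i = std::max(lo, 0); i <= std::min(hi, n_grid - 1); ++i) rem += p[i];
    p_missed[d] = rem;
  }

  return List::create(_["p_yes"] = p_yes, _["p_no"] = p_no,
                      _["p_missed"] = p_missed, _["n_bins"] = n_bins);
}

// Monte-Carlo simulation of the same discrete accumulator; one drift per
// trial. choice: 1 = yes, -1 = no, 0 = missed; rt = NA when missed.
// [[Rcpp::export]]
List cpp_simulate_trials(NumericVector drifts, double bound0, double decay,
                         double ndt, double noise_sd, double dt,
                         double deadline) {
  const int n = drifts.size();
  const int K = (int)std::floor((deadline - ndt) / dt + 1e-9);
  std::vector<double> bk(K + 1);
  for (int k = 1; k <= K; ++k) bk[k] = bound0 * std::exp(-decay * k * dt);
  IntegerVector choice(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    const double v = drifts[i];
    double rdv = 0.0;
    int ch = 0; double t = NA_REAL;
    for (int k = 1; k <= K; ++k) {
      rdv += v + noise_sd * norm_rand();
      if (rdv >= bk[k]) { ch = 1; t = ndt + k * dt; break; }
      if (rdv <= -bk[k]) { ch = -1; t = ndt + k * dt; break; }
    }
    choice[i] = ch; rt[i] = t;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

// Connected components of a 3-D logical array (6- or 26-connectivity).
// Returns integer labels (0 outside), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (size_t m = 0; m < off.size(); m += 3) {
        int tx = cx + off[m], ty = cy + off[m + 1], tz = cz + off[m + 2];
        if (tx < 0 || tx >= nx || ty < 0 || ty >= ny || tz < 0 || tz >= nz)
          continue;
        int t = tx + nx * (ty + ny * tz);
        if (mask[t] && lab[t] == 0) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
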