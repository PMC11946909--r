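#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sweep footprint f(x) = 1/d^2 * exp(kappa * cos(theta - alpha)) evaluated on
// an n x n grid of unit-spaced bin centres.  The cell containing the origin
// (d < dmin) is masked to zero: the 1/d^2 singularity is undefined there.
// [[Rcpp::export(name = ".footprintGrid")]]
NumericMatrix footprint_grid(int n, double cx, double cy, double alpha,
                             double kappa, double dmin = 0.5) {
  // rows index x, columns index y; f[i, j] is evaluated at the bin centre
  // x = i + 1, y = j + 1 (1-based grid coordinates).
  NumericMatrix f(n, n);
  const double ca = std::cos(alpha), sa = std::sin(alpha);
  for (int j = 0; j < n; ++j) {
    const double dy = (j + 1) - cy;
    for (int i = 0; i < n; ++i) {
      const double dx = (i + 1) - cx;
      const double d2 = dx * dx + dy * dy;
      if (d2 < dmin * dmin) { f(i, j) = 0.0; continue; }
      const double d = std::sqrt(d2);
      const double cth = (dx * ca + dy * sa) / d;
      f(i, j) = std::exp(kappa * cth) / d2;
    }
  }
  return f;
}

// Overlap curve O(alpha_k) = sum_x h(x)/d^2 * exp(kappa cos(theta_x - alpha_k))
// computed exactly (to Bessel-series truncation) via the Jacobi-Anger
// expansion: exp(kappa cos phi) = I0(kappa) + 2 sum_m Im(kappa) cos(m phi).
// `coefs` must be c(I0(kappa), 2*I1(kappa), ..., 2*IM(kappa)).
// [[Rcpp::export(name = ".overlapCurve")]]
NumericVector overlap_curve(NumericMatrix h, double cx, double cy,
                            NumericVector angles, NumericVector coefs,
                            double dmin = 0.5) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const int M = coefs.size() - 1;
  std::vector<double> A(M + 1, 0.0), B(M + 1, 0.0);
  for (int j = 0; j < n2; ++j) {
    const double dy = (j + 1) - cy;
    for (int i = 0; i < n1; ++i) {
      const double hx = h(i, j);
      if (hx == 0.0) continue;
      const double dx = (i + 1) - cx;
      const double d2 = dx * dx + dy * dy;
      if (d2 < dmin * dmin) continue;
      const double w = hx / d2;
      const double d = std::sqrt(d2);
      const double c = dx / d, s = dy / d; // e^{i theta}
      double cm = 1.0, sm = 0.0;           // e^{i m theta}, m = 0
      A[0] += w;
      for (int m = 1; m <= M; ++m) {
        const double cn = cm * c - sm * s;
        const double sn = sm * c + cm * s;
        cm = cn; sm = sn;
        A[m] += w * cm;
        B[m] += w * sm;
      }
    }
  }
  const int K = angles.size();
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    double o = coefs[0] * A[0];
    for (int m = 1; m <= M; ++m) {
      o += coefs[m] * (A[m] * std::cos(m * angles[k]) +
                       B[m] * std::sin(m * angles[k]));
    }
    out[k] = o;
  }
  return out;
}

// Add a footprint into the coverage trace in place (returns void; h modified).
// [[Rcpp::export(name = ".addFootprint")]]
void add_footprint(NumericMatrix h, double cx, double cy, double alpha,
                   double kappa, double dmin = 0.5, double gain = 1.0) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const double ca = std::cos(alpha), sa = std::sin(alpha);
  for (int j = 0; j < n2; ++j) {
    const double dy = (j + 1) - cy;
    for (int i = 0; i < n1; ++i) {
      const double dx = (i + 1) - cx;
      const double d2 = dx * dx + dy * dy;
      if (d2 < dmin * dmin) continue;
      const double d = std::sqrt(d2);
      const double cth = (dx * ca + dy * sa) / d;
      h(i, j) += gain * std::exp(kappa * cth) / d2;
    }
  }
}

// Gaussian-blob footprint for the multimodule agent variant: a round Gaussian
// of width sigma centred at distance len along direction alpha from (cx, cy).
// [[Rcpp::export(name = ".addGaussFootprint")]]
void add_gauss_footprint(NumericMatrix h, double cx, double cy, double alpha,
                         double len, double sigma, double gain = 1.0) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const double mx = cx + len * std::cos(alpha);
  const double my = cy + len * std::sin(alpha);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int j = 0; j < n2; ++j) {
    const double dy = (j + 1) - my;
    for (int i = 0; i < n1; ++i) {
      const double dx = (i + 1) - mx;
      h(i, j) += gain * std::exp(-(dx * dx + dy * dy) * inv2s2);
    }
  }
}

// Overlap of a Gaussian-blob footprint with the trace, for candidate angles.
// [[Rcpp::export(name = ".gaussOverlapCurve")]]
NumericVector gauss_overlap_curve(NumericMatrix h, double cx, double cy,
                                  NumericVector angles, double len,
                                  double sigma) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const int K = angles.size();
  NumericVector out(K);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // restrict to cells within 4 sigma of the blob centre for speed
  for (int k = 0; k < K; ++k) {
    const double mx = cx + len * std::cos(angles[k]);
    const double my = cy + len * std::sin(angles[k]);
    const int i0 = std::max(0, (int)std::floor(mx - 4 * sigma) - 1);
    const int i1 = std::min(n1 - 1, (int)std::ceil(mx + 4 * sigma));
    const int j0 = std::max(0, (int)std::floor(my - 4 * sigma) - 1);
    const int j1 = std::min(n2 - 1, (int)std::ceil(my + 4 * sigma));
    double o = 0.0;
    for (int j = j0; j <= j1; ++j) {
      const double dy = (j + 1) - my;
      for (int i = i0; i <= i1; ++i) {
        const double dx = (i + 1) - mx;
        o += h(i, j) * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
    out[k] = o;
  }
  return out;
}

// Full linear-path agent run in C++: the agent starts at (x0, y0), moves
// step_len bins per step along +x, places a 1/d^2 von Mises footprint each
// step, and from step 2 on chooses the direction minimising overlap with the
// accumulated trace.  Ties are broken by a uniform draw among minimal angles
// (R RNG).  Returns the chosen directions (radians).
// [[Rcpp::export(name = ".runLinearAgent")]]
NumericVector run_linear_agent(int n, int steps, double step_len, double x0,
                               double y0, double kappa, NumericVector angles,
                               NumericVector coefs, double first_dir,
                               double dmin = 0.5) {
  NumericMatrix h(n, n);
  NumericVector dirs(steps);
  double cx = x0, cy = y0;
  const int K = angles.size();
  for (int t = 0; t < steps; ++t) {
    double alpha;
    if (t == 0) {
      alpha = first_dir;
    } else {
      NumericVector o = overlap_curve(h, cx, cy, angles, coefs, dmin);
      double omin = o[0];
      for (int k = 1; k < K; ++k) if (o[k] < omin) omin = o[k];
      const double tol = 1e-10 * std::fabs(omin) + 1e-300;
      std::vector<int> mins;
      for (int k = 0; k < K; ++k) if (o[k] - omin <= tol) mins.push_back(k);
      int pick = 0;
      if (mins.size() > 1)
        pick = (int)std::floor(unif_rand() * mins.size());
      if (pick >= (int)mins.size()) pick = mins.size() - 1;
      alpha = angles[mins[pick]];
    }
    add_footprint(h, cx, cy, alpha, kappa, dmin, 1.0);
    dirs[t] = alpha;
    cx += step_len;
  }
  return dirs;
}

// Cell-averaged variants: within `rsub` bins of the footprint origin the
// integrand varies steeply (1/d^2 and the von Mises factor), so point
// sampling at cell centres leaves a strong square-lattice anisotropy that
// can dominate the overlap argmin.  Sub-sampling each nearby cell k x k and
// averaging approximates the cell integral and restores the rotational
// symmetry of the continuum field.  The origin cell itself stays masked
// (the 1/d^2 integral over it diverges).

// [[Rcpp::export(name = ".addFootprintAvg")]]
void add_footprint_avg(NumericMatrix h, double cx, double cy, double alpha,
                       double kappa, double dmin = 0.5, double gain = 1.0,
                       int rsub = 12, int k = 5) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const double ca = std::cos(alpha), sa = std::sin(alpha);
  const double r2sub = (double)rsub * rsub;
  for (int j = 0; j < n2; ++j) {
    const double dy = (j + 1) - cy;
    for (int i = 0; i < n1; ++i) {
      const double dx = (i + 1) - cx;
      const double d2 = dx * dx + dy * dy;
      if (d2 < dmin * dmin) continue;
      double val;
      if (d2 <= r2sub) {
        double acc = 0.0;
        for (int a = 0; a < k; ++a) {
          const double sx = dx + (a + 0.5) / k - 0.5;
          for (int b = 0; b < k; ++b) {
            const double sy = dy + (b + 0.5) / k - 0.5;
            const double sd2 = sx * sx + sy * sy;
            if (sd2 < 1e-12) continue;
            const double sd = std::sqrt(sd2);
            acc += std::exp(kappa * (sx * ca + sy * sa) / sd) / sd2;
          }
        }
        val = acc / (k * k);
      } else {
        const double d = std::sqrt(d2);
        val = std::exp(kappa * (dx * ca + dy * sa) / d) / d2;
      }
      h(i, j) += gain * val;
    }
  }
}

// Overlap curve with cell-averaged near field.  Far cells (d > rsub) use the
// Jacobi-Anger expansion as in overlap_curve; near cells are accumulated at
// sub-cell resolution into the same Fourier sums, which keeps the result a
// single series evaluation per candidate angle.
// [[Rcpp::export(name = ".overlapCurveAvg")]]
NumericVector overlap_curve_avg(NumericMatrix h, double cx, double cy,
                                NumericVector angles, NumericVector coefs,
                                double dmin = 0.5, int rsub = 12, int k = 5) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const int M = coefs.size() - 1;
  std::vector<double> A(M + 1, 0.0), B(M + 1, 0.0);
  const double r2sub = (double)rsub * rsub;
  const double invk2 = 1.0 / (double)(k * k);
  for (int j = 0; j < n2; ++j) {
    const double dy = (j + 1) - cy;
    for (int i = 0; i < n1; ++i) {
      const double hx = h(i, j);
      if (hx == 0.0) continue;
      const double dx = (i + 1) - cx;
      const double d2 = dx * dx + dy * dy;
      if (d2 < dmin * dmin) continue;
      if (d2 <= r2sub) {
        for (int a = 0; a < k; ++a) {
          const double sx = dx + (a + 0.5) / k - 0.5;
          for (int b = 0; b < k; ++b) {
            const double sy = dy + (b + 0.5) / k - 0.5;
            const double sd2 = sx * sx + sy * sy;
            if (sd2 < 1e-12) continue;
            const double w = hx * invk2 / sd2;
            const double sd = std::sqrt(sd2);
            const double c = sx / sd, s = sy / sd;
            double cm = 1.0, sm = 0.0;
            A[0] += w;
            for (int m = 1; m <= M; ++m) {
              const double cn = cm * c - sm * s;
              const double sn = sm * c + cm * s;
              cm = cn; sm = sn;
              A[m] += w * cm;
              B[m] += w * sm;
            }
          }
        }
      } else {
        const double w = hx / d2;
        const double d = std::sqrt(d2);
        const double c = dx / d, s = dy / d;
        double cm = 1.0, sm = 0.0;
        A[0] += w;
        for (int m = 1; m <= M; ++m) {
          const double cn = cm * c - sm * s;
          const double sn = sm * c + cm * s;
          cm = cn; sm = sn;
          A[m] += w * cm;
          B[m] += w * sm;
        }
      }
    }
  }
  const int K = angles.size();
  NumericVector out(K);
  for (int kk = 0; kk < K; ++kk) {
    double o = coefs[0] * A[0];
    for (int m = 1; m <= M; ++m) {
      o += coefs[m] * (A[m] * std::cos(m * angles[kk]) +
                       B[m] * std::sin(m * angles[kk]));
    }
    out[kk] = o;
  }
  return out;
}

// Fast overlap for the inner simulation loop: cells within `rnear` bins of
// the agent are summed exactly (with sub-cell averaging inside `rsub`);
// beyond that, 4x4 blocks of the trace are collapsed to their centroid.
// The far field carries ~1/d^3 of the overlap mass, so the block
// approximation perturbs the overlap curve by well under the 1-degree
// angle-grid resolution (verified against the exact kernel in tests).
static void accumulate_fourier(double w, double c, double s, int M,
                               std::vector<double> &A,
                               std::vector<double> &B) {
  double cm = 1.0, sm = 0.0;
  A[0] += w;
  for (int m = 1; m <= M; ++m) {
    const double cn = cm * c - sm * s;
    const double sn = sm * c + cm * s;
    cm = cn; sm = sn;
    A[m] += w * cm;
    B[m] += w * sm;
  }
}

static NumericVector overlap_curve_fast(const NumericMatrix &h,
                                        const NumericMatrix &hc, int blk,
                                        double cx, double cy,
                                        const NumericVector &angles,
                                        const NumericVector &coefs,
                                        double dmin, int rsub, int k,
                                        double rnear) {
  const int n1 = h.nrow(), n2 = h.ncol();
  const int M = coefs.size() - 1;
  std::vector<double> A(M + 1, 0.0), B(M + 1, 0.0);
  const double r2sub = (double)rsub * rsub;
  const double invk2 = 1.0 / (double)(k * k);
  const int i0 = std::max(0, (int)std::floor(cx - rnear) - 1);
  const int i1 = std::min(n1 - 1, (int)std::ceil(cx + rnear));
  const int j0 = std::max(0, (int)std::floor(cy - rnear) - 1);
  const int j1 = std::min(n2 - 1, (int)std::ceil(cy + rnear));
  for (int j = j0; j <= j1; ++j) {
    const double dy = (j + 1) - cy;
    for (int i = i0; i <= i1; ++i) {
      const double hx = h(i, j);
      if (hx == 0.0) continue;
      const double dx = (i + 1) - cx;
      const double d2 = dx * dx + dy * dy;
      if (d2 < dmin * dmin) continue;
      if (d2 <= r2sub) {
        for (int a = 0; a < k; ++a) {
          const double sx = dx + (a + 0.5) / k - 0.5;
          for (int b = 0; b < k; ++b) {
            const double sy = dy + (b + 0.5) / k - 0.5;
            const double sd2 = sx * sx + sy * sy;
            if (sd2 < 1e-12) continue;
            const double sd = std::sqrt(sd2);
            accumulate_fourier(hx * invk2 / sd2, sx / sd, sy / sd, M, A, B);
          }
        }
      } else {
        const double d = std::sqrt(d2);
        accumulate_fourier(hx / d2, dx / d, dy / d, M, A, B);
      }
    }
  }
  // far field from the blocked trace; blocks overlapping the near box are
  // handled per-cell above and subtracted here via the skip test
  const int nb1 = hc.nrow(), nb2 = hc.ncol();
  for (int bj = 0; bj < nb2; ++bj) {
    const double y0b = bj * blk + 1, y1b = bj * blk + blk;
    const double yc = 0.5 * (y0b + y1b);
    for (int bi = 0; bi < nb1; ++bi) {
      const double w = hc(bi, bj);
      if (w == 0.0) continue;
      const double x0b = bi * blk + 1, x1b = bi * blk + blk;
      // skip blocks intersecting the near box (already counted)
      if (x1b >= cx - rnear - 1 && x0b <= cx + rnear + 1 &&
          y1b >= cy - rnear - 1 && y0b <= cy + rnear + 1) continue;
      const double xc = 0.5 * (x0b + x1b);
      const double dx = xc - cx, dy = yc - cy;
      const double d2 = dx * dx + dy * dy;
      const double d = std::sqrt(d2);
      accumulate_fourier(w / d2, dx / d, dy / d, M, A, B);
    }
  }
  const int K = angles.size();
  NumericVector out(K);
  for (int kk = 0; kk < K; ++kk) {
    double o = coefs[0] * A[0];
    for (int m = 1; m <= M; ++m) {
      o += coefs[m] * (A[m] * std::cos(m * angles[kk]) +
                       B[m] * std::sin(m * angles[kk]));
    }
    out[kk] = o;
  }
  return out;
}

// Rebuild the blocked (4x4-summed) copy of the trace.
static void rebuild_coarse(const NumericMatrix &h, NumericMatrix &hc,
                           int blk) {
  const int n1 = h.nrow(), n2 = h.ncol();
  std::fill(hc.begin(), hc.end(), 0.0);
  for (int j = 0; j < n2; ++j) {
    const int bj = j / blk;
    for (int i = 0; i < n1; ++i) hc(i / blk, bj) += h(i, j);
  }
}

// Linear-path agent run with cell-averaged footprints (see above).
// [[Rcpp::export(name = ".runLinearAgentAvg")]]
NumericVector run_linear_agent_avg(int n, int steps, double step_len,
                                   double x0, double y0, double kappa,
                                   NumericVector angles, NumericVector coefs,
                                   double first_dir, double dmin = 0.5,
                                   int rsub = 12, int k = 5) {
  NumericMatrix h(n, n);
  const int blk = 4;
  NumericMatrix hc((n + blk - 1) / blk, (n + blk - 1) / blk);
  NumericVector dirs(steps);
  double cx = x0;
  const int K = angles.size();
  const double rnear = 48.0;
  for (int t = 0; t < steps; ++t) {
    double alpha;
    if (t == 0) {
      alpha = first_dir;
    } else {
      NumericVector o = overlap_curve_fast(h, hc, blk, cx, y0, angles,
                                           coefs, dmin, rsub, k, rnear);
      double omin = o[0];
      for (int kk = 1; kk < K; ++kk) if (o[kk] < omin) omin = o[kk];
      const double tol = 1e-10 * std::fabs(omin) + 1e-300;
      std::vector<int> mins;
      for (int kk = 0; kk < K; ++kk)
        if (o[kk] - omin <= tol) mins.push_back(kk);
      int pick = 0;
      if (mins.size() > 1)
        pick = (int)std::floor(unif_rand() * mins.size());
      if (pick >= (int)mins.size()) pick = (int)mins.size() - 1;
      alpha = angles[mins[pick]];
    }
    add_footprint_avg(h, cx, y0, alpha, kappa, dmin, 1.0, rsub, k);
    rebuild_coarse(h, hc, blk);
    dirs[t] = alpha;
    cx += step_len;
  }
  return dirs;
}

// Spike-train cross-correlogram: counts of (post - pre) lags in 1 ms bins
// over +/- window ms.  Both trains must be sorted ascending (seconds).
// [[Rcpp::export(name = ".ccgCounts")]]
IntegerVector ccg_counts(NumericVector pre, NumericVector post,
                         double bin_s = 0.001, double window_s = 0.050) {
  const int nb = (int)std::round(2.0 * window_s / bin_s); // e.g. 100 bins
  IntegerVector counts(nb + 1);                           // centred bins
  const int np = pre.size(), nq = post.size();
  int lo = 0;
  for (int i = 0; i < np; ++i) {
    const double t = pre[i];
    while (lo < nq && post[lo] < t - window_s - bin_s / 2) ++lo;
    for (int j = lo; j < nq; ++j) {
      const double lag = post[j] - t;
      if (lag > window_s + bin_s / 2) break;
      int b = (int)std::floor((lag + window_s + bin_s / 2) / bin_s);
      if (b >= 0 && b <= nb) counts[b]++;
    }
  }
  return counts;
}
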