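#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// minimum-image displacement on a periodic coordinate of given period
static inline double wrap_delta(double d, double period) {
  return d - period * std::round(d / period);
}

// grid spacing convention: periodic dims exclude the upper bound
// (nodes lo + i*(hi-lo)/r, i = 0..r-1), non-periodic dims include both ends
static inline double grid_spacing(double lo, double hi, int r, bool periodic) {
  return periodic ? (hi - lo) / r : (hi - lo) / (r - 1);
}

// Bias potential V(s) = sum_k h_k exp(-sum_j d_jk^2 / (2 s_jk^2)),
// evaluated on the full grid, one Gaussian evaluation per hill per node
// (separable per-dimension factors). Hills must arrive pre-sorted in the
// caller's canonical order; accumulation is plain double in that order.
// [[Rcpp::export]]
NumericVector cpp_sum_hills_exact(NumericMatrix centers, NumericMatrix widths,
                                  NumericVector heights, IntegerVector res,
                                  NumericVector lo, NumericVector hi,
                                  LogicalVector periodic) {
  const int n = centers.nrow(), d = centers.ncol();
  std::vector<double> sp(d);
  std::vector< std::vector<double> > nodes(d);
  R_xlen_t total = 1;
  for (int j = 0; j < d; ++j) {
    sp[j] = grid_spacing(lo[j], hi[j], res[j], periodic[j]);
    nodes[j].resize(res[j]);
    for (int i = 0; i < res[j]; ++i) nodes[j][i] = lo[j] + i * sp[j];
    total *= res[j];
  }
  NumericVector V(total);
  std::vector< std::vector<double> > g(d);
  for (int j = 0; j < d; ++j) g[j].resize(res[j]);

  for (int k = 0; k < n; ++k) {
    const double h = heights[k];
    for (int j = 0; j < d; ++j) {
      const double c = centers(k, j), s2 = 2.0 * widths(k, j) * widths(k, j);
      const double per = hi[j] - lo[j];
      for (int i = 0; i < res[j]; ++i) {
        double delta = nodes[j][i] - c;
        if (periodic[j]) delta = wrap_delta(delta, per);
        g[j][i] = std::exp(-delta * delta / s2);
      }
    }
    if (d == 1) {
      for (int i0 = 0; i0 < res[0]; ++i0) V[i0] += h * g[0][i0];
    } else if (d == 2) {
      R_xlen_t idx = 0;
      for (int i1 = 0; i1 < res[1]; ++i1) {
        const double hg1 = h * g[1][i1];
        for (int i0 = 0; i0 < res[0]; ++i0) V[idx++] += hg1 * g[0][i0];
      }
    } else {
      R_xlen_t idx = 0;
      for (int i2 = 0; i2 < res[2]; ++i2)
        for (int i1 = 0; i1 < res[1]; ++i1) {
          const double hg = h * g[1][i1] * g[2][i2];
          for (int i0 = 0; i0 < res[0]; ++i0) V[idx++] += hg * g[0][i0];
        }
    }
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return V;
}

// Fast path: one kernel per hill set, sampled on the grid spacing and
// truncated where the Gaussian exponent exceeds `cutoff`; each hill is
// stamped at the grid node nearest its center (periodic wrap-around).
// All hills of one CV must share a single width (checked by the caller).
// [[Rcpp::export]]
NumericVector cpp_sum_hills_fast(NumericMatrix centers, NumericVector sigma,
                                 NumericVector heights, IntegerVector res,
                                 NumericVector lo, NumericVector hi,
                                 LogicalVector periodic, double cutoff) {
  const int n = centers.nrow(), d = centers.ncol();
  std::vector<double> sp(d);
  std::vector<int> m(d), ksz(d);
  R_xlen_t total = 1;
  for (int j = 0; j < d; ++j) {
    sp[j] = grid_spacing(lo[j], hi[j], res[j], periodic[j]);
    m[j] = (int)std::floor(std::sqrt(2.0 * cutoff) * sigma[j] / sp[j]);
    if (m[j] > res[j]) m[j] = res[j];  // never wider than the grid itself
    ksz[j] = 2 * m[j] + 1;
    total *= res[j];
  }
  // per-dim exponent tables, then the (truncated) product kernel
  std::vector< std::vector<double> > e(d);
  for (int j = 0; j < d; ++j) {
    e[j].resize(ksz[j]);
    for (int o = -m[j]; o <= m[j]; ++o) {
      const double x = o * sp[j];
      e[j][o + m[j]] = x * x / (2.0 * sigma[j] * sigma[j]);
    }
  }
  R_xlen_t kn = 1;
  for (int j = 0; j < d; ++j) kn *= ksz[j];
  std::vector<double> kern(kn);
  {
    R_xlen_t idx = 0;
    if (d == 1) {
      for (int o0 = 0; o0 < ksz[0]; ++o0)
        kern[idx++] = (e[0][o0] <= cutoff) ? std::exp(-e[0][o0]) : 0.0;
    } else if (d == 2) {
      for (int o1 = 0; o1 < ksz[1]; ++o1)
        for (int o0 = 0; o0 < ksz[0]; ++o0) {
          const double et = e[0][o0] + e[1][o1];
          kern[idx++] = (et <= cutoff) ? std::exp(-et) : 0.0;
        }
    } else {
      for (int o2 = 0; o2 < ksz[2]; ++o2)
        for (int o1 = 0; o1 < ksz[1]; ++o1)
          for (int o0 = 0; o0 < ksz[0]; ++o0) {
            const double et = e[0][o0] + e[1][o1] + e[2][o2];
            kern[idx++] = (et <= cutoff) ? std::exp(-et) : 0.0;
          }
    }
  }

  NumericVector V(total);
  std::vector<int> base(d);
  // per-dim target index tables for the current hill (-1 = off-grid)
  std::vector< std::vector<int> > tgt(d);
  for (int j = 0; j < d; ++j) tgt[j].resize(ksz[j]);

  for (int k = 0; k < n; ++k) {
    const double h = heights[k];
    for (int j = 0; j < d; ++j) {
      long b = std::lround((centers(k, j) - lo[j]) / sp[j]);
      if (periodic[j]) {
        b %= res[j]; if (b < 0) b += res[j];
      } else {
        if (b < 0) b = 0;
        if (b > res[j] - 1) b = res[j] - 1;
      }
      base[j] = (int)b;
      for (int o = -m[j]; o <= m[j]; ++o) {
        long t = base[j] + o;
        if (periodic[j]) {
          t %= res[j]; if (t < 0) t += res[j];
        } else if (t < 0 || t > res[j] - 1) {
          t = -1;
        }
        tgt[j][o + m[j]] = (int)t;
      }
    }
    if (d == 1) {
      for (int o0 = 0; o0 < ksz[0]; ++o0) {
        const int t0 = tgt[0][o0];
        if (t0 >= 0) V[t0] += h * kern[o0];
      }
    } else if (d == 2) {
      R_xlen_t kidx = 0;
      for (int o1 = 0; o1 < ksz[1]; ++o1) {
        const int t1 = tgt[1][o1];
        if (t1 < 0) { kidx += ksz[0]; continue; }
        const R_xlen_t row = (R_xlen_t)t1 * res[0];
        for (int o0 = 0; o0 < ksz[0]; ++o0, ++kidx) {
          const int t0 = tgt[0][o0];
          if (t0 >= 0) V[row + t0] += h * kern[kidx];
        }
      }
    } else {
      R_xlen_t kidx = 0;
      for (int o2 = 0; o2 < ksz[2]; ++o2) {
        const int t2 = tgt[2][o2];
        for (int o1 = 0; o1 < ksz[1]; ++o1) {
          const int t1 = tgt[1][o1];
          if (t2 < 0 || t1 < 0) { kidx += ksz[0]; continue; }
          const R_xlen_t row = ((R_xlen_t)t2 * res[1] + t1) * res[0];
          for (int o0 = 0; o0 < ksz[0]; ++o0, ++kidx) {
            const int t0 = tgt[0][o0];
            if (t0 >= 0) V[row + t0] += h * kern[kidx];
          }
        }
      }
    }
    if (k % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return V;
}

// analytic model potentials: value and gradient
static inline double pot_U(int pot, const double* par, const double* s) {
  switch (pot) {
  case 1: { // tilted 1D double well: B(x^2-1)^2 + a x
    const double x = s[0];
    return par[0] * (x * x - 1.0) * (x * x - 1.0) + par[1] * x;
  }
  case 2: { // separable 2D four-well: B[(x^2-1)^2 + (y^2-1)^2]
    const double x = s[0], y = s[1];
    return par[0] * ((x * x - 1.0) * (x * x - 1.0) +
                     (y * y - 1.0) * (y * y - 1.0));
  }
  default: { // periodic cosine: A (1 - cos x)
    return par[0] * (1.0 - std::cos(s[0]));
  }
  }
}

static inline void pot_grad(int pot, const double* par, const double* s,
                            double* g) {
  switch (pot) {
  case 1:
    g[0] = 4.0 * par[0] * s[0] * (s[0] * s[0] - 1.0) + par[1];
    break;
  case 2:
    g[0] = 4.0 * par[0] * s[0] * (s[0] * s[0] - 1.0);
    g[1] = 4.0 * par[0] * s[1] * (s[1] * s[1] - 1.0);
    break;
  default:
    g[0] = par[0] * std::sin(s[0]);
    break;
  }
}

// Overdamped Langevin (Euler-Maruyama) on U(s) + V_bias(s,t) with periodic
// hill deposition. Heights returned for the HILLS file are pre-scaled by
// gamma/(gamma-1) for well-tempered runs, so that plain summation of the
// written heights reconstructs -F directly (the Plumed convention); the
// dynamics itself accumulates the raw deposited heights.
// [[Rcpp::export]]
List cpp_simulate(int pot, NumericVector par, int d, double kT, double dt,
                  int nsteps, int stride, double w0, NumericVector sigma,
                  double gamma, NumericVector s0, NumericVector lo,
                  NumericVector hi, LogicalVector periodic) {
  const int nh_max = nsteps / stride + 1;
  std::vector< std::vector<double> > hc(d);
  std::vector<double> hdep;          // raw deposited heights (drive dynamics)
  std::vector<double> hout, htime;   // written (pre-scaled) heights, times
  for (int j = 0; j < d; ++j) hc[j].reserve(nh_max);
  hdep.reserve(nh_max); hout.reserve(nh_max); htime.reserve(nh_max);

  NumericMatrix traj(nsteps, d);
  double s[3], gU[3], gV[3];
  for (int j = 0; j < d; ++j) s[j] = s0[j];
  const double noise = std::sqrt(2.0 * kT * dt);
  const bool wt = gamma > 1.0;
  const double wt_scale = wt ? gamma / (gamma - 1.0) : 1.0;

  for (int step = 1; step <= nsteps; ++step) {
    // bias gradient from accumulated hills
    for (int j = 0; j < d; ++j) gV[j] = 0.0;
    const size_t nh = hdep.size();
    for (size_t k = 0; k < nh; ++k) {
      double e = 0.0, del[3];
      for (int j = 0; j < d; ++j) {
        double dd = s[j] - hc[j][k];
        if (periodic[j]) dd = wrap_delta(dd, hi[j] - lo[j]);
        del[j] = dd;
        e += dd * dd / (2.0 * sigma[j] * sigma[j]);
      }
      if (e < 30.0) {
        const double gk = hdep[k] * std::exp(-e);
        for (int j = 0; j < d; ++j)
          gV[j] += -gk * del[j] / (sigma[j] * sigma[j]);
      }
    }
    pot_grad(pot, par.begin(), s, gU);
    for (int j = 0; j < d; ++j) {
      s[j] += -dt * (gU[j] + gV[j]) + noise * norm_rand();
      if (periodic[j]) {
        const double per = hi[j] - lo[j];
        s[j] = lo[j] + s[j] - lo[j] - per * std::floor((s[j] - lo[j]) / per);
      } else {
        const double mid = 0.5 * (lo[j] + hi[j]), half = 0.5 * (hi[j] - lo[j]);
        if (std::fabs(s[j] - mid) > 10.0 * half)
          stop("trajectory diverged at step %d (cv %d = %g)", step, j + 1, s[j]);
      }
    }
    for (int j = 0; j < d; ++j) traj(step - 1, j) = s[j];

    if (step % stride == 0) {
      // bias at the new position (for the well-tempered deposition rule)
      double Vh = 0.0;
      for (size_t k = 0; k < nh; ++k) {
        double e = 0.0;
        for (int j = 0; j < d; ++j) {
          double dd = s[j] - hc[j][k];
          if (periodic[j]) dd = wrap_delta(dd, hi[j] - lo[j]);
          e += dd * dd / (2.0 * sigma[j] * sigma[j]);
        }
        if (e < 30.0) Vh += hdep[k] * std::exp(-e);
      }
      const double h_dep = wt ? w0 * std::exp(-Vh / ((gamma - 1.0) * kT)) : w0;
      for (int j = 0; j < d; ++j) hc[j].push_back(s[j]);
      hdep.push_back(h_dep);
      hout.push_back(h_dep * wt_scale);
      htime.push_back(step * dt);
    }
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  const int nh = (int)hdep.size();
  NumericMatrix centers(nh, d);
  for (int k = 0; k < nh; ++k)
    for (int j = 0; j < d; ++j) centers(k, j) = hc[j][k];
  return List::create(_["times"] = NumericVector(htime.begin(), htime.end()),
                      _["centers"] = centers,
                      _["heights"] = NumericVector(hout.begin(), hout.end()),
                      _["trajectory"] = traj);
}
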