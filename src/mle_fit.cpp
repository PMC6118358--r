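// Maximum-likelihood localization of single emitters on an integrated
// Gaussian PSF with Poisson pixel noise. Per-parameter Newton-Raphson
// updates, Cramer-Rao lower bounds from the 4x4 Fisher information, and
// the likelihood-ratio deviance as goodness-of-fit statistic.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

const double SQRT2 = 1.4142135623730951;
const double SQRT_2PI = 2.5066282746310002;

// Ex(k) = 0.5 * [erf((k - p + .5)/(sqrt(2) s)) - erf((k - p - .5)/(sqrt(2) s))]
inline double int_gauss(double k, double p, double s) {
  return 0.5 * (std::erf((k - p + 0.5) / (SQRT2 * s)) -
                std::erf((k - p - 0.5) / (SQRT2 * s)));
}

inline double d_int_gauss(double k, double p, double s) {
  double zm = k - p - 0.5, zp = k - p + 0.5;
  return (std::exp(-zm * zm / (2 * s * s)) -
          std::exp(-zp * zp / (2 * s * s))) / (SQRT_2PI * s);
}

inline double d2_int_gauss(double k, double p, double s) {
  double zm = k - p - 0.5, zp = k - p + 0.5;
  return (zm * std::exp(-zm * zm / (2 * s * s)) -
          zp * std::exp(-zp * zp / (2 * s * s))) / (SQRT_2PI * s * s * s);
}

// invert a 4x4 symmetric positive-definite matrix in place (Gauss-Jordan
// with partial pivoting); returns false if singular
bool invert4(double a[4][4], double inv[4][4]) {
  double aug[4][8];
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      aug[i][j] = a[i][j];
      aug[i][j + 4] = (i == j) ? 1.0 : 0.0;
    }
  }
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    for (int r = c + 1; r < 4; ++r) {
      if (std::fabs(aug[r][c]) > std::fabs(aug[piv][c])) piv = r;
    }
    if (std::fabs(aug[piv][c]) < 1e-300) return false;
    if (piv != c) {
      for (int j = 0; j < 8; ++j) std::swap(aug[c][j], aug[piv][j]);
    }
    double d = aug[c][c];
    for (int j = 0; j < 8; ++j) aug[c][j] /= d;
    for (int r = 0; r < 4; ++r) {
      if (r == c) continue;
      double f = aug[r][c];
      if (f == 0.0) continue;
      for (int j = 0; j < 8; ++j) aug[r][j] -= f * aug[c][j];
    }
  }
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) inv[i][j] = aug[i][j + 4];
  }
  return true;
}

} // namespace

// rois: sz*sz*n array (photon units); returns n x 10 matrix with columns
// x, y, N, b, crlb_x, crlb_y, loglike, llr, ok, n_iter
// [[Rcpp::export(name = ".mle_fit_rois")]]
NumericMatrix mle_fit_rois(NumericVector rois, int sz, double sigma,
                           int max_iterations) {
  int npx = sz * sz;
  int n = rois.size() / npx;
  NumericMatrix out(n, 10);
  colnames(out) = CharacterVector::create(
      "x", "y", "photons", "background", "crlb_x", "crlb_y", "loglike",
      "llr", "ok", "n_iter");

  std::vector<double> ex(sz), ey(sz), dex(sz), dey(sz), d2ex(sz), d2ey(sz);

  for (int r = 0; r < n; ++r) {
    const double* d = &rois[(size_t)r * npx]; // column-major: d[i + sz*j]

    // init: b at min pixel, N at (sum - npx*min), position at COM
    double bmin = d[0], sum = 0.0;
    for (int i = 0; i < npx; ++i) {
      if (d[i] < bmin) bmin = d[i];
      sum += d[i];
    }
    double b = std::max(bmin, 0.01);
    double N = std::max(sum - npx * bmin, 1.0);
    double sx = 0.0, sy = 0.0, sw = 0.0;
    for (int j = 0; j < sz; ++j) {      // j = column = x
      for (int i = 0; i < sz; ++i) {    // i = row = y
        double w = std::max(d[i + sz * j] - bmin, 0.0);
        sx += w * j;
        sy += w * i;
        sw += w;
      }
    }
    double x = (sw > 0) ? sx / sw : (sz - 1) / 2.0;
    double y = (sw > 0) ? sy / sw : (sz - 1) / 2.0;

    int it = 0;
    for (; it < max_iterations; ++it) {
      for (int k = 0; k < sz; ++k) {
        ex[k] = int_gauss(k, x, sigma);
        ey[k] = int_gauss(k, y, sigma);
        dex[k] = d_int_gauss(k, x, sigma);
        dey[k] = d_int_gauss(k, y, sigma);
        d2ex[k] = d2_int_gauss(k, x, sigma);
        d2ey[k] = d2_int_gauss(k, y, sigma);
      }
      double g[4] = {0, 0, 0, 0};   // dLL/dtheta for x, y, N, b
      double h[4] = {0, 0, 0, 0};   // d2LL/dtheta2
      for (int j = 0; j < sz; ++j) {
        for (int i = 0; i < sz; ++i) {
          double mu = N * ex[j] * ey[i] + b;
          if (mu < 1e-12) mu = 1e-12;
          double dat = d[i + sz * j];
          double cf = dat / mu - 1.0;
          double cf2 = dat / (mu * mu);
          double dmu_x = N * dex[j] * ey[i];
          double dmu_y = N * ex[j] * dey[i];
          double dmu_N = ex[j] * ey[i];
          g[0] += cf * dmu_x;
          g[1] += cf * dmu_y;
          g[2] += cf * dmu_N;
          g[3] += cf;
          h[0] += cf * N * d2ex[j] * ey[i] - cf2 * dmu_x * dmu_x;
          h[1] += cf * N * ex[j] * d2ey[i] - cf2 * dmu_y * dmu_y;
          h[2] += -cf2 * dmu_N * dmu_N;
          h[3] += -cf2;
        }
      }
      // sequential per-parameter Newton updates; steps damped for position
      if (h[0] < 0) {
        double step = g[0] / h[0];
        if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
        x -= step;
      }
      if (h[1] < 0) {
        double step = g[1] / h[1];
        if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
        y -= step;
      }
      if (h[2] < 0) N = std::max(N - g[2] / h[2], 1e-6);
      if (h[3] < 0) b = std::max(b - g[3] / h[3], 1e-8);
    }

    bool ok = R_finite(x) && R_finite(y) && R_finite(N) && R_finite(b) &&
              x > -1.0 && x < sz && y > -1.0 && y < sz;

    // log-likelihood, deviance and Fisher information at the optimum
    for (int k = 0; k < sz; ++k) {
      ex[k] = int_gauss(k, x, sigma);
      ey[k] = int_gauss(k, y, sigma);
      dex[k] = d_int_gauss(k, x, sigma);
      dey[k] = d_int_gauss(k, y, sigma);
    }
    double ll = 0.0, llr = 0.0;
    double fisher[4][4] = {{0}};
    for (int j = 0; j < sz; ++j) {
      for (int i = 0; i < sz; ++i) {
        double mu = N * ex[j] * ey[i] + b;
        if (mu < 1e-12) mu = 1e-12;
        double dat = d[i + sz * j];
        ll += dat * std::log(mu) - mu - std::lgamma(dat + 1.0);
        llr += 2.0 * (mu - dat);
        if (dat > 0) llr += 2.0 * dat * std::log(dat / mu);
        double dmu[4] = {N * dex[j] * ey[i], N * ex[j] * dey[i],
                         ex[j] * ey[i], 1.0};
        for (int a = 0; a < 4; ++a) {
          for (int c = a; c < 4; ++c) {
            fisher[a][c] += dmu[a] * dmu[c] / mu;
          }
        }
      }
    }
    for (int a = 0; a < 4; ++a) {
      for (int c = 0; c < a; ++c) fisher[a][c] = fisher[c][a];
    }
    double inv[4][4];
    bool inv_ok = invert4(fisher, inv) && inv[0][0] > 0 && inv[1][1] > 0;

    out(r, 0) = x;
    out(r, 1) = y;
    out(r, 2) = N;
    out(r, 3) = b;
    out(r, 4) = inv_ok ? std::sqrt(inv[0][0]) : NA_REAL;
    out(r, 5) = inv_ok ? std::sqrt(inv[1][1]) : NA_REAL;
    out(r, 6) = ll;
    out(r, 7) = llr;
    out(r, 8) = (ok && inv_ok) ? 1.0 : 0.0;
    out(r, 9) = it;
  }
  return out;
}
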