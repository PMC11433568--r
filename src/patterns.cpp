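#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Coordinates within this distance of a grid point take that pixel's exact value.
static const double SNAP_TOL = 1e-6;

// Bilinear interpolation at (y, x), 0-based fractional coordinates.
// Coordinates are clamped to the grid, which for bilinear interpolation is
// equivalent to replicate-padding the image.
static inline double bilinear(const NumericMatrix &img, double y, double x) {
  const int M = img.nrow(), N = img.ncol();
  if (y < 0) y = 0;
  if (y > M - 1) y = M - 1;
  if (x < 0) x = 0;
  if (x > N - 1) x = N - 1;
  const double ry = std::round(y), rx = std::round(x);
  if (std::fabs(y - ry) < SNAP_TOL) y = ry;
  if (std::fabs(x - rx) < SNAP_TOL) x = rx;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (y0 > M - 1) y0 = M - 1;
  if (x0 > N - 1) x0 = N - 1;
  const int y1 = std::min(y0 + 1, M - 1), x1 = std::min(x0 + 1, N - 1);
  const double fy = y - y0, fx = x - x0;
  // lerp form: exact on constant images and when a fraction is 0
  const double v0 = img(y0, x0) + fx * (img(y0, x1) - img(y0, x0));
  const double v1 = img(y1, x0) + fx * (img(y1, x1) - img(y1, x0));
  return v0 + fy * (v1 - v0);
}

// Rotation-invariant uniform relabeling of an 8-bit pattern: patterns with at
// most two circular transitions get their popcount (0..8), the rest label 9.
static inline int riu2(const int bits[8]) {
  int U = std::abs(bits[7] - bits[0]);
  for (int n = 1; n < 8; ++n) U += std::abs(bits[n] - bits[n - 1]);
  if (U > 2) return 9;
  int c = 0;
  for (int n = 0; n < 8; ++n) c += bits[n];
  return c;
}

static inline double median_small(double *v, int n) {
  std::sort(v, v + n);
  return (n % 2 == 1) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Bilinear stencil for one sample offset: integer corner offsets plus the
// two interpolation fractions. Offsets are pixel-independent, so the
// stencil is precomputed once per scale.
struct Stencil {
  int oy, ox;
  double fy, fx;
};

static Stencil make_stencil(double dy, double dx) {
  double ry = std::round(dy), rx = std::round(dx);
  if (std::fabs(dy - ry) < SNAP_TOL) dy = ry;
  if (std::fabs(dx - rx) < SNAP_TOL) dx = rx;
  Stencil s;
  s.oy = (int)std::floor(dy);
  s.ox = (int)std::floor(dx);
  s.fy = dy - s.oy;
  s.fx = dx - s.ox;
  return s;
}

// Sample via a precomputed stencil at interior pixel base pointer; must only
// be called where base + 1 and base + M stay on the grid whenever the
// corresponding fraction is non-zero.
static inline double sample_stencil(const double *base, int M,
                                    const Stencil &t) {
  double v0 = base[0], v1 = v0;
  if (t.fx != 0) {
    v0 += t.fx * (base[(size_t)M] - base[0]);
  }
  if (t.fy != 0) {
    v1 = base[1];
    if (t.fx != 0) v1 += t.fx * (base[(size_t)M + 1] - base[1]);
    return v0 + t.fy * (v1 - v0);
  }
  return v0;
}

// [[Rcpp::export(name = ".pattern_maps_cpp")]]
List pattern_maps_cpp(NumericMatrix img, int r) {
  const int M = img.nrow(), N = img.ncol();
  if (r < 1) stop("scale r must be a positive integer");
  if (M < 2 * r + 1 || N < 2 * r + 1)
    stop("image too small for scale r = %d", r);

  const int P = 8 * r;
  std::vector<double> dy(P), dx(P);
  std::vector<Stencil> st(P);
  for (int n = 0; n < P; ++n) {
    const double th = 2.0 * M_PI * n / P;
    dy[n] = -r * std::sin(th);
    dx[n] = r * std::cos(th);
    st[n] = make_stencil(dy[n], dx[n]);
  }
  const double *im = img.begin();

  // Mean-absolute-local-difference image on the full grid (replicate-padded
  // sampling) so the ring threshold nu_r is defined over the whole valid region.
  // Interior pixels use the precomputed stencils; the border ring falls back
  // to the clamped sampler.
  NumericMatrix muld(M, N);
  for (int j = 0; j < N; ++j) {
    const bool jin = (j >= r && j < N - r);
    for (int i = 0; i < M; ++i) {
      const double pc = img(i, j);
      double s = 0.0;
      if (jin && i >= r && i < M - r) {
        for (int n = 0; n < P; ++n) {
          const Stencil &t = st[n];
          const double *base = im + (size_t)(j + t.ox) * M + (i + t.oy);
          s += std::fabs(sample_stencil(base, M, t) - pc);
        }
      } else {
        for (int n = 0; n < P; ++n)
          s += std::fabs(bilinear(img, i + dy[n], j + dx[n]) - pc);
      }
      muld(i, j) = s / P;
    }
  }

  IntegerMatrix mstrp(M, N), nrtxp(M, N), ritxp(M, N);
  std::fill(mstrp.begin(), mstrp.end(), -1);
  std::fill(nrtxp.begin(), nrtxp.end(), -1);
  std::fill(ritxp.begin(), ritxp.end(), -1);

  std::vector<double> smp(P), grp(r);
  int bits[8];

  for (int i = r; i < M - r; ++i) {
    for (int j = r; j < N - r; ++j) {
      const double pc = img(i, j);
      for (int n = 0; n < P; ++n) {
        const Stencil &t = st[n];
        const double *base = im + (size_t)(j + t.ox) * M + (i + t.oy);
        smp[n] = sample_stencil(base, M, t);
      }

      // MsTrP: median of each arc of r consecutive samples, sign vs center
      for (int k = 0; k < 8; ++k) {
        for (int t = 0; t < r; ++t) grp[t] = smp[r * k + t];
        bits[k] = (median_small(grp.data(), r) - pc >= 0.0) ? 1 : 0;
      }
      mstrp(i, j) = riu2(bits);

      // NrTxP: mean absolute difference per arc vs ring mean of muld
      double mldqp[8];
      for (int k = 0; k < 8; ++k) {
        double s = 0.0;
        for (int t = 0; t < r; ++t) s += std::fabs(smp[r * k + t] - pc);
        mldqp[k] = s / r;
      }
      double nu = 0.0, mu = 0.0;
      for (int y = j - r; y <= j + r; ++y) {
        nu += muld(i - r, y) + muld(i + r, y);
        mu += img(i - r, y) + img(i + r, y);
      }
      for (int x = i - r + 1; x <= i + r - 1; ++x) {
        nu += muld(x, j - r) + muld(x, j + r);
        mu += img(x, j - r) + img(x, j + r);
      }
      nu /= P;
      mu /= P;
      for (int k = 0; k < 8; ++k) bits[k] = (mldqp[k] - nu >= 0.0) ? 1 : 0;
      nrtxp(i, j) = riu2(bits);

      // RiTxP: center vs square-ring mean
      ritxp(i, j) = (pc - mu >= 0.0) ? 1 : 0;
    }
  }

  return List::create(_["mstrp"] = mstrp, _["nrtxp"] = nrtxp,
                      _["ritxp"] = ritxp);
}

// [[Rcpp::export(name = ".sample_circle_cpp")]]
NumericVector sample_circle_cpp(NumericMatrix img, int i, int j, int r,
                                bool clamp_border) {
  const int M = img.nrow(), N = img.ncol();
  const int i0 = i - 1, j0 = j - 1; // R is 1-based
  if (!clamp_border && (i0 < r || i0 >= M - r || j0 < r || j0 >= N - r))
    stop("center (%d, %d) is outside the valid region for scale r = %d", i, j,
         r);
  const int P = 8 * r;
  NumericVector out(P);
  for (int n = 0; n < P; ++n) {
    const double th = 2.0 * M_PI * n / P;
    out[n] = bilinear(img, i0 - r * std::sin(th), j0 + r * std::cos(th));
  }
  return out;
}
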