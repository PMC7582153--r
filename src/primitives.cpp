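#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, 2012),
// separable lower-envelope-of-parabolas, generalized to anisotropic spacing.
// Distances are physical (mm): the 1-D pass along axis k samples parabolas at
// positions i * spacing[k].
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, int n, double step) {
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    for (;;) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Distance (mm) from every voxel to the nearest TRUE voxel of `feature`.
// Voxels inside the feature get 0. If the feature is empty, all Inf.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector feature, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: true infinity makes the parabola-intersection
  // arithmetic produce NaN when two unreached parabolas meet
  const double INF = 1e15;
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = feature[i] ? 0.0 : INF;

  std::vector<double> line;
  // axis x
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      dt1d(line, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  // axis y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
      dt1d(line, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
    }
  // axis z
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(line, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = line[z];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing, sigma per axis in voxel units, kernel
// truncated at 3 sigma, edge-renormalized (kernel re-weighted near borders).
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double> &img, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma * sigma));
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
  std::vector<double> buf(len);

  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0) base = (R_xlen_t)b * nx * ny + (R_xlen_t)a * nx;
      else if (axis == 1) base = (R_xlen_t)b * nx * ny + a;
      else base = (R_xlen_t)b * nx + a;
      for (int i = 0; i < len; ++i) buf[i] = img[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double s = 0.0, w = 0.0;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          double kk = k[j - i + r];
          s += kk * buf[j];
          w += kk;
        }
        img[base + (R_xlen_t)i * stride] = s / w;
      }
    }
}

// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector img, IntegerVector dim,
                               NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(img.begin(), img.end());
  smooth_axis(buf, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(buf, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(buf, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(n);
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Resample a moving image onto a fixed grid through a displacement field.
// For fixed voxel index (i,j,k) the sampled physical point is
//   p = origin_f + idx * spacing_f + disp(i,j,k)   [mm, axis-aligned grids]
// mapped into moving voxel coordinates via origin_m / spacing_m.
// disp is an n x 3 matrix (mm) in fixed-grid voxel order; may be NULL for
// identity. Out-of-bounds samples take `fill`.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector warp_cpp(NumericVector moving, IntegerVector dim_m,
                       NumericVector spacing_m, NumericVector origin_m,
                       IntegerVector dim_f, NumericVector spacing_f,
                       NumericVector origin_f, Nullable<NumericMatrix> disp_,
                       bool nearest, double fill) {
  const int mx = dim_m[0], my = dim_m[1], mz = dim_m[2];
  const int fx = dim_f[0], fy = dim_f[1], fz = dim_f[2];
  const R_xlen_t nf = (R_xlen_t)fx * fy * fz;
  NumericVector out(nf);
  bool has_disp = disp_.isNotNull();
  NumericMatrix disp = has_disp ? NumericMatrix(disp_) : NumericMatrix(1, 3);

  R_xlen_t idx = 0;
  for (int k = 0; k < fz; ++k)
    for (int j = 0; j < fy; ++j)
      for (int i = 0; i < fx; ++i, ++idx) {
        double px = origin_f[0] + i * spacing_f[0];
        double py = origin_f[1] + j * spacing_f[1];
        double pz = origin_f[2] + k * spacing_f[2];
        if (has_disp) {
          px += disp(idx, 0);
          py += disp(idx, 1);
          pz += disp(idx, 2);
        }
        double vx = (px - origin_m[0]) / spacing_m[0];
        double vy = (py - origin_m[1]) / spacing_m[1];
        double vz = (pz - origin_m[2]) / spacing_m[2];
        if (nearest) {
          int xi = (int)std::lround(vx), yi = (int)std::lround(vy),
              zi = (int)std::lround(vz);
          if (xi < 0 || xi >= mx || yi < 0 || yi >= my || zi < 0 || zi >= mz)
            out[idx] = fill;
          else
            out[idx] = moving[(R_xlen_t)zi * mx * my + (R_xlen_t)yi * mx + xi];
        } else {
          int x0 = (int)std::floor(vx), y0 = (int)std::floor(vy),
              z0 = (int)std::floor(vz);
          double dx = vx - x0, dy = vy - y0, dz = vz - z0;
          double acc = 0.0;
          for (int c = 0; c < 8; ++c) {
            int xi = x0 + (c & 1), yi = y0 + ((c >> 1) & 1),
                zi = z0 + ((c >> 2) & 1);
            double w = ((c & 1) ? dx : 1 - dx) * (((c >> 1) & 1) ? dy : 1 - dy) *
                       (((c >> 2) & 1) ? dz : 1 - dz);
            double val;
            if (xi < 0 || xi >= mx || yi < 0 || yi >= my || zi < 0 || zi >= mz)
              val = fill;
            else
              val = moving[(R_xlen_t)zi * mx * my + (R_xlen_t)yi * mx + xi];
            acc += w * val;
          }
          out[idx] = acc;
        }
      }
  return out;
}
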