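#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 3D image kernels used by the proliferative-zone nucleus counter and the
// chromatin-variance projector. Arrays are R arrays with dim = c(ny, nx, nz)
// (column-major). Borders are handled by index clamping (replicate).

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".median_filter_3d")]]
NumericVector median_filter_3d(NumericVector img, int ry, int rx, int rz) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int ny = d[0], nx = d[1], nz = d[2];
  NumericVector out(img.size());
  out.attr("dim") = d;
  std::vector<double> win;
  win.reserve((2 * ry + 1) * (2 * rx + 1) * (2 * rz + 1));
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        win.clear();
        for (int dz = -rz; dz <= rz; ++dz) {
          int zz = clampi(z + dz, 0, nz - 1);
          for (int dx = -rx; dx <= rx; ++dx) {
            int xx = clampi(x + dx, 0, nx - 1);
            for (int dy = -ry; dy <= ry; ++dy) {
              int yy = clampi(y + dy, 0, ny - 1);
              win.push_back(img[yy + ny * (xx + (R_xlen_t)nx * zz)]);
            }
          }
        }
        size_t m = win.size() / 2;
        std::nth_element(win.begin(), win.begin() + m, win.end());
        double med = win[m];
        if (win.size() % 2 == 0) {
          std::nth_element(win.begin(), win.begin() + m - 1, win.begin() + m);
          med = 0.5 * (med + win[m - 1]);
        }
        out[y + ny * (x + (R_xlen_t)nx * z)] = med;
      }
    }
  }
  return out;
}

static void blur_axis(std::vector<double>& a, int ny, int nx, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  std::vector<double> tmp(a.size());
  const int n[3] = {ny, nx, nz};
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        int idx[3] = {y, x, z};
        for (int i = -r; i <= r; ++i) {
          int j[3] = {y, x, z};
          j[axis] = clampi(idx[axis] + i, 0, n[axis] - 1);
          acc += k[i + r] * a[j[0] + (R_xlen_t)ny * (j[1] + (R_xlen_t)nx * j[2])];
        }
        tmp[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)] = acc;
      }
    }
  }
  a.swap(tmp);
}

// [[Rcpp::export(name = ".gaussian_blur_3d")]]
NumericVector gaussian_blur_3d(NumericVector img, double sy, double sx,
                               double sz) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int ny = d[0], nx = d[1], nz = d[2];
  std::vector<double> a(img.begin(), img.end());
  blur_axis(a, ny, nx, nz, 0, sy);
  blur_axis(a, ny, nx, nz, 1, sx);
  blur_axis(a, ny, nx, nz, 2, sz);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}

// Local maxima strictly greater than all 26 neighbours and above threshold.
// Returns 1-based (y, x, z) coordinates.
// [[Rcpp::export(name = ".local_maxima_3d")]]
IntegerMatrix local_maxima_3d(NumericVector img, double threshold) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int ny = d[0], nx = d[1], nz = d[2];
  std::vector<int> ys, xs, zs;
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        double v = img[y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z)];
        if (!(v > threshold)) continue;
        bool ismax = true;
        for (int dz = -1; dz <= 1 && ismax; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dx = -1; dx <= 1 && ismax; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              if (dy == 0 && dx == 0 && dz == 0) continue;
              if (img[yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz)] >= v) {
                ismax = false;
                break;
              }
            }
          }
        }
        if (ismax) {
          ys.push_back(y + 1);
          xs.push_back(x + 1);
          zs.push_back(z + 1);
        }
      }
    }
  }
  IntegerMatrix out(ys.size(), 3);
  for (size_t i = 0; i < ys.size(); ++i) {
    out(i, 0) = ys[i];
    out(i, 1) = xs[i];
    out(i, 2) = zs[i];
  }
  colnames(out) = CharacterVector::create("y", "x", "z");
  return out;
}
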