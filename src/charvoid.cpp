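#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

// 3D connected-component labeling of a logical array stored in R's
// column-major order with dim = (nz, ny, nx). Connectivity is 6
// (face neighbours) or 26 (face+edge+corner). Labels are assigned in
// raster-scan order of the first voxel of each component, so they are
// deterministic for a given mask.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);

  std::vector<std::array<int,3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) > 1) continue;
        offs.push_back({{dz, dy, dx}});
      }

  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++cur;
    labels[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t j = stack.back();
      stack.pop_back();
      int z = (int)(j % nz);
      R_xlen_t r = j / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (size_t o = 0; o < offs.size(); ++o) {
        int zz = z + offs[o][0], yy = y + offs[o][1], xx = x + offs[o][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t k = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[k] && !labels[k]) {
          labels[k] = cur;
          stack.push_back(k);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Parallel-beam forward projection (discrete Radon transform) of one 2D
// slice. img is ny x nx; rays at angle theta integrate along direction
// (-sin t, cos t); the detector coordinate runs along (cos t, sin t).
// Output is n_angles x ndet with ndet = max(nx, ny); line sums are in
// pixel units (multiply by the pixel size for physical path lengths).
// [[Rcpp::export]]
NumericMatrix radon_cpp(NumericMatrix img, NumericVector angles) {
  const int ny = img.nrow(), nx = img.ncol();
  const int ndet = std::max(nx, ny);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (ndet - 1) / 2.0;
  const int ns = (int)std::ceil(std::sqrt((double)nx * nx + (double)ny * ny)) + 2;
  const double cs = (ns - 1) / 2.0;
  NumericMatrix out(angles.size(), ndet);
  for (int a = 0; a < angles.size(); ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int d = 0; d < ndet; ++d) {
      const double t = d - cdet;
      double acc = 0.0;
      for (int k = 0; k < ns; ++k) {
        const double u = k - cs;
        const double x = cx + t * c - u * s;
        const double y = cy + t * s + u * c;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
        const double fx = x - x0, fy = y - y0;
        const double v00 = (x0 >= 0     && y0 >= 0)     ? img(y0,     x0)     : 0.0;
        const double v01 = (x0 + 1 < nx && y0 >= 0)     ? img(y0,     x0 + 1) : 0.0;
        const double v10 = (x0 >= 0     && y0 + 1 < ny) ? img(y0 + 1, x0)     : 0.0;
        const double v11 = (x0 + 1 < nx && y0 + 1 < ny) ? img(y0 + 1, x0 + 1) : 0.0;
        acc += (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
      }
      out(a, d) = acc;
    }
  }
  return out;
}

// Back projection of one filtered sinogram (n_angles x ndet) onto an
// ny x nx grid, with linear interpolation along the detector and the
// standard pi/(2 * n_angles) quadrature weight for angles covering [0, pi).
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix fsino, NumericVector angles, int ny, int nx) {
  const int ndet = fsino.ncol();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cdet = (ndet - 1) / 2.0;
  NumericMatrix out(ny, nx);
  for (int a = 0; a < angles.size(); ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int xi = 0; xi < nx; ++xi) {
      const double xr = xi - cx;
      for (int yi = 0; yi < ny; ++yi) {
        const double t = xr * c + (yi - cy) * s + cdet;
        const int t0 = (int)std::floor(t);
        if (t0 < 0 || t0 >= ndet - 1) continue;
        const double f = t - t0;
        out(yi, xi) += (1 - f) * fsino(a, t0) + f * fsino(a, t0 + 1);
      }
    }
  }
  const double scale = M_PI / (2.0 * angles.size());
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] *= scale;
  return out;
}
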