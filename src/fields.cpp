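#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Separable 3D Gaussian convolution with truncated, renormalized kernels.
// sigma is given per axis in voxel units; sigma <= 0 skips that axis.
// Renormalizing at the edges keeps the filter mass 1 near boundaries, so
// simulated smooth fields keep (approximately) unit variance after the
// caller rescales; callers that need exact stationarity should pad.
// [[Rcpp::export(name = ".gaussian_smooth_3d")]]
NumericVector gaussian_smooth_3d(NumericVector x, IntegerVector dim,
                                 NumericVector sigma) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (sigma.size() != 3) stop("sigma must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != x.size()) stop("length(x) != prod(dim)");

  NumericVector cur = clone(x);
  const int n[3] = {nx, ny, nz};
  // strides for column-major 3D array
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int radius = (int)std::ceil(3.5 * s);
    if (radius < 1) radius = 1;
    std::vector<double> ker(2 * radius + 1);
    for (int k = -radius; k <= radius; ++k)
      ker[k + radius] = std::exp(-0.5 * (double)k * k / (s * s));

    NumericVector out(cur.size());
    const int na = n[ax];
    const R_xlen_t sa = stride[ax];
    // iterate over all lines along axis ax
    const int b1 = (ax == 0) ? n[1] : n[0];
    const int b2 = (ax == 2) ? n[1] : n[2];
    const R_xlen_t sb1 = (ax == 0) ? stride[1] : stride[0];
    const R_xlen_t sb2 = (ax == 2) ? stride[1] : stride[2];
    for (int j2 = 0; j2 < b2; ++j2) {
      for (int j1 = 0; j1 < b1; ++j1) {
        const R_xlen_t base = j1 * sb1 + j2 * sb2;
        for (int i = 0; i < na; ++i) {
          double acc = 0.0, wsum = 0.0;
          int klo = std::max(-radius, -i);
          int khi = std::min(radius, na - 1 - i);
          for (int k = klo; k <= khi; ++k) {
            double w = ker[k + radius];
            acc += w * cur[base + (R_xlen_t)(i + k) * sa];
            wsum += w;
          }
          out[base + (R_xlen_t)i * sa] = acc / wsum;
        }
      }
    }
    cur = out;
  }
  return cur;
}

// Connected-component labeling of a logical 3D mask under 26-connectivity
// (vertex adjacency). Returns integer labels (0 = background), components
// numbered 1..K in first-encounter (column-major scan) order.
// [[Rcpp::export(name = ".label_components_26")]]
IntegerVector label_components_26(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != mask.size()) stop("length(mask) != prod(dim)");

  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t v = 0; v < mask.size(); ++v) {
    if (mask[v] != TRUE || lab[v] != 0) continue;
    ++next;
    lab[v] = next;
    q.push(v);
    while (!q.empty()) {
      R_xlen_t u = q.front(); q.pop();
      int iz = (int)(u / sz);
      int iy = (int)((u - (R_xlen_t)iz * sz) / sy);
      int ix = (int)(u - (R_xlen_t)iz * sz - (R_xlen_t)iy * sy);
      for (int dz = -1; dz <= 1; ++dz) {
        int jz = iz + dz;
        if (jz < 0 || jz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int jy = iy + dy;
          if (jy < 0 || jy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int jx = ix + dx;
            if (jx < 0 || jx >= nx) continue;
            R_xlen_t w = jx * sx + (R_xlen_t)jy * sy + (R_xlen_t)jz * sz;
            if (mask[w] == TRUE && lab[w] == 0) {
              lab[w] = next;
              q.push(w);
            }
          }
        }
      }
    }
  }
  return lab;
}
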