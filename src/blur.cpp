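// Separable Gaussian smoothing of a 3D grid, replicate boundary handling.
// Kernel radius 4 sigma (per axis, in voxel units), normalised to unit sum.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static void convolve_axis(std::vector<double> &a, std::vector<double> &tmp,
                          const int dim[3], int axis,
                          const std::vector<double> &ker) {
  const int r = (int)(ker.size() / 2);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = dim[axis];
  const long stride = (axis == 0) ? 1L : (axis == 1 ? (long)nx : (long)nx * ny);
  // iterate over all lines along `axis`
  int odim[2];
  long ostride[2];
  int oi = 0;
  for (int ax = 0; ax < 3; ++ax) {
    if (ax == axis) continue;
    odim[oi] = dim[ax];
    ostride[oi] = (ax == 0) ? 1L : (ax == 1 ? (long)nx : (long)nx * ny);
    ++oi;
  }
  for (int u = 0; u < odim[1]; ++u) {
    for (int w = 0; w < odim[0]; ++w) {
      long base = u * ostride[1] + w * ostride[0];
      for (int p = 0; p < n; ++p) {
        double s = 0.0;
        for (int q = -r; q <= r; ++q) {
          int pp = p + q;
          if (pp < 0) pp = 0;
          else if (pp >= n) pp = n - 1;
          s += ker[q + r] * a[base + (long)pp * stride];
        }
        tmp[base + (long)p * stride] = s;
      }
    }
  }
  a.swap(tmp);
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector dimv = vol.attr("dim");
  if (dimv.size() != 3) stop("volume must be a 3D array");
  int dim[3] = {dimv[0], dimv[1], dimv[2]};
  long ntot = (long)dim[0] * dim[1] * dim[2];
  std::vector<double> a(REAL(vol), REAL(vol) + ntot), tmp(ntot);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int q = -r; q <= r; ++q) {
      ker[q + r] = std::exp(-0.5 * (q / s) * (q / s));
      sum += ker[q + r];
    }
    for (int q = 0; q < 2 * r + 1; ++q) ker[q] /= sum;
    convolve_axis(a, tmp, dim, axis, ker);
  }
  NumericVector out(ntot);
  std::copy(a.begin(), a.end(), REAL(out));
  out.attr("dim") = dimv;
  return out;
}
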