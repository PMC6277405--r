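#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable zero-padded Gaussian convolution of each (nu, nv) plane of a
// stack, with per-plane sigmas (in pixel units).  Kernels are normalized to
// unit sum, so the operator is exactly self-adjoint (symmetric kernel, zero
// padding) -- this is what the OSEM adjoint test relies on.

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma < 1e-6) return std::vector<double>(1, 1.0);
  int h = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * h + 1);
  double s = 0;
  for (int i = -h; i <= h; ++i) {
    k[i + h] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + h];
  }
  for (auto& x : k) x /= s;
  return k;
}

static void conv_plane(double* p, int nu, int nv,
                       const std::vector<double>& kx,
                       const std::vector<double>& ky,
                       std::vector<double>& tmp) {
  int hx = ((int)kx.size() - 1) / 2, hy = ((int)ky.size() - 1) / 2;
  // along u
  if (hx > 0) {
    for (int j = 0; j < nv; ++j) {
      double* row = p + (size_t)nu * j;
      for (int i = 0; i < nu; ++i) {
        double acc = 0;
        int lo = std::max(0, i - hx), hi = std::min(nu - 1, i + hx);
        for (int t = lo; t <= hi; ++t) acc += row[t] * kx[t - i + hx];
        tmp[i] = acc;
      }
      for (int i = 0; i < nu; ++i) row[i] = tmp[i];
    }
  }
  // along v
  if (hy > 0) {
    for (int i = 0; i < nu; ++i) {
      for (int j = 0; j < nv; ++j) {
        double acc = 0;
        int lo = std::max(0, j - hy), hi = std::min(nv - 1, j + hy);
        for (int t = lo; t <= hi; ++t)
          acc += p[i + (size_t)nu * t] * ky[t - j + hy];
        tmp[j] = acc;
      }
      for (int j = 0; j < nv; ++j) p[i + (size_t)nu * j] = tmp[j];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_stack(NumericVector arr, NumericVector sigx,
                              NumericVector sigy) {
  IntegerVector dim = arr.attr("dim");
  int nu = dim[0], nv = dim[1], nd = dim[2];
  NumericVector out = clone(arr);
  double* p = REAL(out);
  std::vector<double> tmp(std::max(nu, nv));
  for (int id = 0; id < nd; ++id) {
    std::vector<double> kx = gauss_kernel(sigx[id]);
    std::vector<double> ky = gauss_kernel(sigy[id]);
    conv_plane(p + (size_t)nu * nv * id, nu, nv, kx, ky, tmp);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss2d(NumericMatrix img, double sigx, double sigy) {
  NumericMatrix out = clone(img);
  std::vector<double> tmp(std::max(out.nrow(), out.ncol()));
  std::vector<double> kx = gauss_kernel(sigx), ky = gauss_kernel(sigy);
  conv_plane(REAL(out), out.nrow(), out.ncol(), kx, ky, tmp);
  return out;
}

// Sum a (nu,nv,nd) stack over depth into a (nu,nv) matrix.

// [[Rcpp::export]]
NumericMatrix cpp_plane_sum(NumericVector arr) {
  IntegerVector dim = arr.attr("dim");
  int nu = dim[0], nv = dim[1], nd = dim[2];
  NumericMatrix out(nu, nv);
  const double* p = REAL(arr);
  double* o = REAL(out);
  for (int id = 0; id < nd; ++id)
    for (size_t t = 0; t < (size_t)nu * nv; ++t)
      o[t] += p[t + (size_t)nu * nv * id];
  return out;
}

// Broadcast a (nu,nv) matrix to all nd planes (adjoint of cpp_plane_sum).

// [[Rcpp::export]]
NumericVector cpp_plane_bcast(NumericMatrix img, int nd) {
  int nu = img.nrow(), nv = img.ncol();
  NumericVector out(static_cast<R_xlen_t>(nu) * nv * nd);
  out.attr("dim") = IntegerVector::create(nu, nv, nd);
  double* o = REAL(out);
  const double* p = REAL(img);
  for (int id = 0; id < nd; ++id)
    for (size_t t = 0; t < (size_t)nu * nv; ++t)
      o[t + (size_t)nu * nv * id] = p[t];
  return out;
}
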