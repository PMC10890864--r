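// Hot kernels of the array engine: image-to-column gathering and its
// scatter-add adjoint. Geometry (index tables) is computed once in R and
// cached; these loops only move memory.
#include <Rcpp.h>
using namespace Rcpp;

// xp: (HpWp x C) padded image, column-major; idx: 1-based gather indices of
// length npix*koff (pixel index fastest). Returns (npix x koff*C) with the
// kernel offset fastest within the column blocks.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& xp, const IntegerVector& idx,
                         const int npix, const int koff) {
  const int C = xp.ncol();
  const int HpWp = xp.nrow();
  NumericMatrix out(npix, koff * C);
  const double* xpp = xp.begin();
  double* op = out.begin();
  const int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xpp + (R_xlen_t)c * HpWp;
    for (int o = 0; o < koff; ++o) {
      const int* icol = ip + (R_xlen_t)o * npix;
      double* ocol = op + ((R_xlen_t)c * koff + o) * npix;
      for (int p = 0; p < npix; ++p) ocol[p] = xc[icol[p] - 1];
    }
  }
  return out;
}

// Adjoint: scatter-add gcols (npix x koff*C) back into an (HpWp x C) array.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& gcols, const IntegerVector& idx,
                         const int HpWp, const int npix, const int koff) {
  const int C = gcols.ncol() / koff;
  NumericMatrix out(HpWp, C);
  const double* gp = gcols.begin();
  double* op = out.begin();
  const int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    double* oc = op + (R_xlen_t)c * HpWp;
    for (int o = 0; o < koff; ++o) {
      const int* icol = ip + (R_xlen_t)o * npix;
      const double* gcol = gp + ((R_xlen_t)c * koff + o) * npix;
      for (int p = 0; p < npix; ++p) oc[icol[p] - 1] += gcol[p];
    }
  }
  return out;
}
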