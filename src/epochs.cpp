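// Hot inner loops of the HEP pipeline: R-locked epoch gathering, per-epoch
// amplitude extrema, and accumulation of beat-locked templates into a
// signal vector.  All window arithmetic (seconds -> sample offsets) stays
// in R; these kernels only move samples.

#include <Rcpp.h>
using namespace Rcpp;

// Gather epochs around 0-based peak samples: rows = channel rows of `sig`
// (1-based), offsets = 0-based sample offsets relative to the peak sample.
// Peaks whose window would leave the signal must be filtered by the caller.
// Returns an array dim (nrows, noffs, npeaks).
// [[Rcpp::export]]
NumericVector gather_epochs(const NumericMatrix& sig,
                            const IntegerVector& peaks0,
                            const IntegerVector& offsets,
                            const IntegerVector& rows) {
  const int nch = rows.size(), ns = offsets.size(), ne = peaks0.size();
  const int nrow = sig.nrow();
  NumericVector out(static_cast<R_xlen_t>(nch) * ns * ne);
  double* o = REAL(out);
  const double* s = REAL(sig);
  for (int e = 0; e < ne; ++e) {
    const int p = peaks0[e];
    for (int k = 0; k < ns; ++k) {
      const R_xlen_t col = static_cast<R_xlen_t>(p + offsets[k]) * nrow;
      const R_xlen_t base = (static_cast<R_xlen_t>(e) * ns + k) * nch;
      for (int c = 0; c < nch; ++c)
        o[base + c] = s[col + (rows[c] - 1)];
    }
  }
  out.attr("dim") = IntegerVector::create(nch, ns, ne);
  return out;
}

// Per-(channel, epoch) max and min over samples of a (nch, ns, ne) array.
// [[Rcpp::export]]
List epoch_extremes(const NumericVector& arr) {
  IntegerVector d = arr.attr("dim");
  const int nch = d[0], ns = d[1], ne = d[2];
  NumericMatrix hi(nch, ne), lo(nch, ne);
  const double* a = REAL(arr);
  for (int e = 0; e < ne; ++e) {
    for (int c = 0; c < nch; ++c) {
      double h = a[(static_cast<R_xlen_t>(e) * ns) * nch + c], l = h;
      for (int k = 1; k < ns; ++k) {
        const double v = a[(static_cast<R_xlen_t>(e) * ns + k) * nch + c];
        if (v > h) h = v;
        if (v < l) l = v;
      }
      hi(c, e) = h;
      lo(c, e) = l;
    }
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// Sample-wise mean over the epochs listed in idx (1-based, repeats
// allowed) of a (nch, ns, ne) array; returns an nch x ns matrix.
// [[Rcpp::export]]
NumericMatrix mean_epochs(const NumericVector& arr, const IntegerVector& idx) {
  IntegerVector d = arr.attr("dim");
  const int nch = d[0], ns = d[1];
  const R_xlen_t plane = static_cast<R_xlen_t>(nch) * ns;
  NumericMatrix out(nch, ns);
  double* o = REAL(out);
  const double* a = REAL(arr);
  for (int k = 0; k < idx.size(); ++k) {
    const double* e = a + plane * (idx[k] - 1);
    for (R_xlen_t j = 0; j < plane; ++j) o[j] += e[j];
  }
  const double inv = 1.0 / idx.size();
  for (R_xlen_t j = 0; j < plane; ++j) o[j] *= inv;
  return out;
}

// Accumulate scale[k] * values over anchors[k] + offsets into a length-n
// vector (overlap-safe); anchors are 1-based sample indices, offsets
// 0-based relative shifts.  Out-of-range samples are silently clipped.
// [[Rcpp::export]]
NumericVector accumulate_template(const int n, const IntegerVector& offsets,
                                  const NumericVector& values,
                                  const IntegerVector& anchors,
                                  const NumericVector& scales) {
  NumericVector acc(n);
  const int ns = offsets.size();
  for (int k = 0; k < anchors.size(); ++k) {
    const double sc = scales[k];
    if (sc == 0.0) continue;
    const int a = anchors[k] - 1;
    for (int j = 0; j < ns; ++j) {
      const int i = a + offsets[j];
      if (i >= 0 && i < n) acc[i] += sc * values[j];
    }
  }
  return acc;
}
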