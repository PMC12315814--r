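#include <Rcpp.h>
using namespace Rcpp;

// Layouts: activations are (B, L, C) arrays in R's column-major order,
// index = b + B*(l + L*c). im2col matrices are (B*P) x (width*C) with
// row index b + B*p, column index j + width*c (P = L - width + 1).

// [[Rcpp::export]]
NumericMatrix im2col_c(NumericVector x, int B, int L, int C, int width) {
  int P = L - width + 1;
  NumericMatrix M(B * P, width * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < width; ++j) {
      double *dst = &M(0, j + width * c);
      const double *src = &x[0] + B * (j + L * c);
      std::copy(src, src + (size_t)B * P, dst);
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im_c(NumericMatrix dM, int B, int L, int C, int width) {
  int P = L - width + 1;
  NumericVector dx((size_t)B * L * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < width; ++j) {
      const double *src = &dM(0, j + width * c);
      double *dst = &dx[0] + B * (j + L * c);
      for (size_t i = 0; i < (size_t)B * P; ++i) dst[i] += src[i];
    }
  }
  dx.attr("dim") = IntegerVector::create(B, L, C);
  return dx;
}

// [[Rcpp::export]]
List maxpool_fwd_c(NumericVector x, int B, int L, int C, int width) {
  int P = L / width;
  NumericVector out((size_t)B * P * C);
  IntegerVector amax((size_t)B * P * C);
  for (int c = 0; c < C; ++c) {
    for (int p = 0; p < P; ++p) {
      const double *base = &x[0] + B * ((size_t)p * width + (size_t)L * c);
      double *o = &out[0] + B * ((size_t)p + (size_t)P * c);
      int *am = &amax[0] + B * ((size_t)p + (size_t)P * c);
      for (int b = 0; b < B; ++b) {
        double best = base[b];
        int arg = 0;
        for (int j = 1; j < width; ++j) {
          double v = base[b + (size_t)B * j];
          if (v > best) { best = v; arg = j; }
        }
        o[b] = best;
        am[b] = arg;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(B, P, C);
  amax.attr("dim") = IntegerVector::create(B, P, C);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_c(NumericVector d, IntegerVector amax,
                            int B, int L, int C, int width) {
  int P = L / width;
  NumericVector dx((size_t)B * L * C);
  for (int c = 0; c < C; ++c) {
    for (int p = 0; p < P; ++p) {
      const double *dd = &d[0] + B * ((size_t)p + (size_t)P * c);
      const int *am = &amax[0] + B * ((size_t)p + (size_t)P * c);
      double *base = &dx[0] + B * ((size_t)p * width + (size_t)L * c);
      for (int b = 0; b < B; ++b) {
        base[b + (size_t)B * am[b]] += dd[b];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(B, L, C);
  return dx;
}
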