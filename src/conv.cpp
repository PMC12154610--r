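#include <Rcpp.h>
using namespace Rcpp;

// 2-d convolution over [C, F, T] activations: "valid" along time,
// zero-padded "same" along frequency, stride 1, no bias.
// W has layout [Cout, Cin, nf, nt] (R column-major).

// [[Rcpp::export]]
NumericVector conv_vs_fwd_cpp(NumericVector x, IntegerVector xdim,
                              NumericVector W, IntegerVector wdim) {
  const int Cin = xdim[0], F = xdim[1], T = xdim[2];
  const int Cout = wdim[0], nf = wdim[2], nt = wdim[3];
  const int Tout = T - nt + 1, pad = (nf - 1) / 2;
  NumericVector y((size_t)Cout * F * Tout);
  const double* px = x.begin();
  const double* pw = W.begin();
  double* py = y.begin();
  for (int t = 0; t < Tout; ++t) {
    for (int dt = 0; dt < nt; ++dt) {
      for (int f = 0; f < F; ++f) {
        double* yc = py + (size_t)Cout * (f + (size_t)F * t);
        for (int df = 0; df < nf; ++df) {
          const int fi = f + df - pad;
          if (fi < 0 || fi >= F) continue;
          const double* xc = px + (size_t)Cin * (fi + (size_t)F * (t + dt));
          for (int cin = 0; cin < Cin; ++cin) {
            const double xv = xc[cin];
            if (xv == 0.0) continue;
            const double* wc =
                pw + (size_t)Cout * (cin + (size_t)Cin * (df + (size_t)nf * dt));
            for (int cout = 0; cout < Cout; ++cout) yc[cout] += wc[cout] * xv;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, F, Tout);
  return y;
}

// [[Rcpp::export]]
List conv_vs_bwd_cpp(NumericVector x, IntegerVector xdim,
                     NumericVector W, IntegerVector wdim,
                     NumericVector dy) {
  const int Cin = xdim[0], F = xdim[1], T = xdim[2];
  const int Cout = wdim[0], nf = wdim[2], nt = wdim[3];
  const int Tout = T - nt + 1, pad = (nf - 1) / 2;
  NumericVector dx((size_t)Cin * F * T);
  NumericVector dW((size_t)Cout * Cin * nf * nt);
  const double* px = x.begin();
  const double* pw = W.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  double* pdW = dW.begin();
  for (int t = 0; t < Tout; ++t) {
    for (int dt = 0; dt < nt; ++dt) {
      for (int f = 0; f < F; ++f) {
        const double* yc = pdy + (size_t)Cout * (f + (size_t)F * t);
        for (int df = 0; df < nf; ++df) {
          const int fi = f + df - pad;
          if (fi < 0 || fi >= F) continue;
          const size_t xoff = (size_t)Cin * (fi + (size_t)F * (t + dt));
          const double* xc = px + xoff;
          double* dxc = pdx + xoff;
          for (int cin = 0; cin < Cin; ++cin) {
            const size_t woff =
                (size_t)Cout * (cin + (size_t)Cin * (df + (size_t)nf * dt));
            const double* wc = pw + woff;
            double* dwc = pdW + woff;
            const double xv = xc[cin];
            double acc = 0.0;
            for (int cout = 0; cout < Cout; ++cout) {
              const double dyv = yc[cout];
              acc += wc[cout] * dyv;
              dwc[cout] += dyv * xv;
            }
            dxc[cin] += acc;
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(Cin, F, T);
  dW.attr("dim") = wdim;
  return List::create(Named("dx") = dx, Named("dW") = dW);
}
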