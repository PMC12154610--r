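#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zeroth-order modified Bessel function of the first kind, by power series.
// Converges quickly for the beta range used by Kaiser windows (< 40).
static double bessel_i0(double x) {
  double sum = 1.0, term = 1.0;
  const double x2 = x * x / 4.0;
  for (int k = 1; k < 400; ++k) {
    term *= x2 / ((double)k * (double)k);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  return sum;
}

//' Kaiser-windowed sinc resampling of multichannel signals.
//'
//' Rows of \code{x} are channels, columns are time samples. Output sample n
//' (0-based) interpolates the input at position n * fs_in / fs_out with a
//' zero-phase lowpass sinc kernel spanning \code{width} zero-crossings on
//' each side, tapered by a Kaiser window. Out-of-range input samples are
//' treated as zero.
//'
//' @noRd
// [[Rcpp::export]]
NumericMatrix resample_sinc_cpp(NumericMatrix x, double fs_in, double fs_out,
                                int width, double rolloff, double beta) {
  const int nch = x.nrow(), n_in = x.ncol();
  const double ratio = fs_out / fs_in;
  const int n_out = (int)std::lround(n_in * ratio);
  // cutoff in cycles per input sample (anti-aliasing for downsampling,
  // image rejection for upsampling)
  const double r = rolloff * 0.5 * std::min(fs_in, fs_out) / fs_in;
  const double L = width / (2.0 * r); // kernel half-span, input samples
  const double i0b = bessel_i0(beta);
  // Kaiser window lookup table over |d|/L in [0, 1] (linear interpolation;
  // the window is smooth, so 8192 points give ~1e-8 accuracy)
  const int NTAB = 8192;
  std::vector<double> wtab(NTAB + 1);
  for (int i = 0; i <= NTAB; ++i) {
    const double a = (double)i / NTAB;
    const double arg = 1.0 - a * a;
    wtab[i] = arg <= 0.0 ? 0.0 : bessel_i0(beta * std::sqrt(arg)) / i0b;
  }
  NumericMatrix y(nch, n_out);
  const double dec = fs_in / fs_out;
  const bool integer_ratio = std::fabs(dec - std::lround(dec)) < 1e-9;
  if (integer_ratio) {
    // integer decimation: every output sample shares one kernel phase,
    // so the windowed sinc is evaluated once
    const int span = (int)std::floor(L);
    std::vector<double> h(2 * span + 1);
    for (int k = -span; k <= span; ++k) {
      const double u = std::fabs((double)k) / L * NTAB;
      const int iu = (int)u;
      const double w = iu >= NTAB ? 0.0
                                  : wtab[iu] + (u - iu) * (wtab[iu + 1] - wtab[iu]);
      const double sx = 2.0 * r * k;
      const double s =
          (std::fabs(sx) < 1e-12) ? 1.0 : std::sin(M_PI * sx) / (M_PI * sx);
      h[k + span] = 2.0 * r * s * w;
    }
    const int step = (int)std::lround(dec);
    for (int n = 0; n < n_out; ++n) {
      const int p = n * step;
      const int m0 = std::max(0, p - span);
      const int m1 = std::min(n_in - 1, p + span);
      for (int c = 0; c < nch; ++c) {
        double acc = 0.0;
        for (int m = m0; m <= m1; ++m) acc += x(c, m) * h[m - p + span];
        y(c, n) = acc;
      }
    }
    return y;
  }
  for (int n = 0; n < n_out; ++n) {
    const double p = (double)n / ratio;
    const int m0 = std::max(0, (int)std::ceil(p - L));
    const int m1 = std::min(n_in - 1, (int)std::floor(p + L));
    for (int m = m0; m <= m1; ++m) {
      const double d = (double)m - p;
      const double u = std::fabs(d) / L * NTAB;
      const int iu = (int)u;
      const double w = iu >= NTAB ? 0.0
                                  : wtab[iu] + (u - iu) * (wtab[iu + 1] - wtab[iu]);
      const double sx = 2.0 * r * d;
      const double s =
          (std::fabs(sx) < 1e-12) ? 1.0 : std::sin(M_PI * sx) / (M_PI * sx);
      const double h = 2.0 * r * s * w;
      for (int c = 0; c < nch; ++c) y(c, n) += x(c, m) * h;
    }
  }
  return y;
}
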