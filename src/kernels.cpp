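#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Correlation of img with kernel k, "same" size, replicate (nearest-edge)
// padding. Kernel tap (ki, kj) reads the image at offset (ki - s/2, kj - s/2),
// so even-sided kernels have a half-pixel asymmetric support.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_replicate(NumericMatrix img, NumericMatrix k) {
  const int H = img.nrow(), W = img.ncol();
  const int sh = k.nrow(), sw = k.ncol();
  const int ch = sh / 2, cw = sw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int kj = 0; kj < sw; ++kj) {
        const int jj = clampi(j + kj - cw, 0, W - 1);
        for (int ki = 0; ki < sh; ++ki) {
          const int ii = clampi(i + ki - ch, 0, H - 1);
          acc += k(ki, kj) * img(ii, jj);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Five-way response classification: convolve with both kernels and label
// each pixel 0 = none, 1 = k0+, 2 = k0-, 3 = k90+, 4 = k90-.
// Ties between |r0| and |r90| go to k0.
// [[Rcpp::export]]
IntegerMatrix cpp_gabor_classify(NumericMatrix img, NumericMatrix k0,
                                 NumericMatrix k90, double eps) {
  const int H = img.nrow(), W = img.ncol();
  const int sh = k0.nrow(), sw = k0.ncol();
  const int ch = sh / 2, cw = sw / 2;
  IntegerMatrix lab(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double r0 = 0.0, r90 = 0.0;
      for (int kj = 0; kj < sw; ++kj) {
        const int jj = clampi(j + kj - cw, 0, W - 1);
        for (int ki = 0; ki < sh; ++ki) {
          const int ii = clampi(i + ki - ch, 0, H - 1);
          const double v = img(ii, jj);
          r0 += k0(ki, kj) * v;
          r90 += k90(ki, kj) * v;
        }
      }
      const double a0 = std::abs(r0), a90 = std::abs(r90);
      const double m = a0 > a90 ? a0 : a90;
      int l = 0;
      if (m >= eps && m > 0.0) {
        if (a0 >= a90) l = r0 > 0 ? 1 : 2;
        else           l = r90 > 0 ? 3 : 4;
      }
      lab(i, j) = l;
    }
  }
  return lab;
}

// One frame of adaptation dynamics. act is H x W x 4 (category-major last),
// labels is H x W with values 0..4. Stimulated categories decay by factor fd,
// all others recover toward 1 by factor fr. Returns the updated copy and the
// sum of all activations (for the trial summary).
// [[Rcpp::export]]
List cpp_adapt_update(NumericVector act, IntegerMatrix labels,
                      double fd, double fr) {
  IntegerVector dims = act.attr("dim");
  const int H = dims[0], W = dims[1];
  NumericVector out = clone(act);
  const int plane = H * W;
  double total = 0.0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int l = labels(i, j);
      const int base = j * H + i;
      for (int c = 0; c < 4; ++c) {
        double a = out[base + c * plane];
        if (l == c + 1) a *= fd;
        else            a = 1.0 - (1.0 - a) * fr;
        out[base + c * plane] = a;
        total += a;
      }
    }
  }
  out.attr("dim") = dims;
  return List::create(_["activation"] = out, _["total"] = total);
}
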