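#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3x3 "same" convolution with zero padding over a multi-channel grid.
// input: H x W x Cin array (column-major, R layout), kernels: 3 x 3 x Cin x Cout,
// bias: length Cout. Returns H x W x Cout. No activation, no pooling: the
// layer keeps full image resolution by construction.
// [[Rcpp::export]]
NumericVector conv3x3_same(NumericVector input, NumericVector kernels,
                           NumericVector bias, int H, int W, int Cin, int Cout) {
  NumericVector out(static_cast<R_xlen_t>(H) * W * Cout);
  const double* in = input.begin();
  const double* k = kernels.begin();
  double* o = out.begin();
  for (int co = 0; co < Cout; ++co) {
    const double b = bias[co];
    double* oc = o + static_cast<R_xlen_t>(H) * W * co;
    for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(H) * W; ++i) oc[i] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* ic = in + static_cast<R_xlen_t>(H) * W * ci;
      const double* kk = k + 9 * (ci + static_cast<R_xlen_t>(Cin) * co);
      for (int j = 0; j < 3; ++j) {
        for (int i = 0; i < 3; ++i) {
          const double w = kk[i + 3 * j];
          if (w == 0.0) continue;
          const int di = i - 1, dj = j - 1;
          const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
          const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
          for (int c = c0; c < c1; ++c) {
            const double* src = ic + static_cast<R_xlen_t>(H) * (c + dj) + di;
            double* dst = oc + static_cast<R_xlen_t>(H) * c;
            for (int r = r0; r < r1; ++r) dst[r] += w * src[r];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// Connected-component labeling of a binary matrix with 8-connectivity,
// two-pass union-find. Returns an integer matrix of labels (0 = background),
// labels are 1..n in raster (column-major) order of first occurrence root.
// [[Rcpp::export]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0) continue;
      // neighbours already visited in column-major order:
      // same column above, previous column (r-1, r, r+1)
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int t = 0; t < 4; ++t) {
        int rr = neigh[t][0], cc = neigh[t][1];
        if (rr < 0 || rr >= H || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        parent.push_back(next);
        best = next++;
      }
      lab(r, c) = best;
    }
  }
  // relabel roots consecutively in order of first appearance
  std::vector<int> remap(parent.size(), 0);
  int n = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find(l);
      if (remap[root] == 0) remap[root] = ++n;
      lab(r, c) = remap[root];
    }
  return lab;
}

// Bilinear resampling of a matrix to (Hout, Wout), pixel-centre aligned,
// edge-clamped. Used for intensity images.
// [[Rcpp::export]]
NumericMatrix resize_bilinear(NumericMatrix img, int Hout, int Wout) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(Hout, Wout);
  const double sr = static_cast<double>(H) / Hout;
  const double sc = static_cast<double>(W) / Wout;
  for (int c = 0; c < Wout; ++c) {
    double y = (c + 0.5) * sc - 0.5;
    int c0 = static_cast<int>(std::floor(y));
    double fc = y - c0;
    int c1 = std::min(std::max(c0 + 1, 0), W - 1);
    c0 = std::min(std::max(c0, 0), W - 1);
    for (int r = 0; r < Hout; ++r) {
      double x = (r + 0.5) * sr - 0.5;
      int r0 = static_cast<int>(std::floor(x));
      double fr = x - r0;
      int r1 = std::min(std::max(r0 + 1, 0), H - 1);
      r0 = std::min(std::max(r0, 0), H - 1);
      out(r, c) = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
                  fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
    }
  }
  return out;
}

// Nearest-neighbour resampling, for binary masks (keeps values in {0,1}).
// [[Rcpp::export]]
IntegerMatrix resize_nearest(IntegerMatrix img, int Hout, int Wout) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(Hout, Wout);
  const double sr = static_cast<double>(H) / Hout;
  const double sc = static_cast<double>(W) / Wout;
  for (int c = 0; c < Wout; ++c) {
    int cs = std::min(std::max(static_cast<int>(std::floor((c + 0.5) * sc)), 0), W - 1);
    for (int r = 0; r < Hout; ++r) {
      int rs = std::min(std::max(static_cast<int>(std::floor((r + 0.5) * sr)), 0), H - 1);
      out(r, c) = img(rs, cs);
    }
  }
  return out;
}
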