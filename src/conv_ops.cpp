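#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Patch extraction for convolution-as-matrix-multiply.
// x is an H x W x C array (column-major, as R stores it); the result has one
// column per output position (row-major over rows first, i.e. column index
// wo*Ho + ho) and kh*kw*C rows ordered exactly like as.vector() of a
// kh x kw x C filter array, so an F x (kh*kw*C) weight matrix applies directly.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int r0 = ho * stride - pad;
      const int c0 = wo * stride - pad;
      double* dst = &out(0, col);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int cc = c0 + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int r = r0 + ki;
            double v = 0.0;
            if (r >= 0 && r < H && cc >= 0 && cc < W)
              v = x[r + H * (cc + W * c)];
            dst[ki + kh * (kj + kw * c)] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch gradients back to image space.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x(H * W * C);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int r0 = ho * stride - pad;
      const int c0 = wo * stride - pad;
      const double* src = &cols(0, col);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int cc = c0 + kj;
          if (cc < 0 || cc >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int r = r0 + ki;
            if (r < 0 || r >= H) continue;
            x[r + H * (cc + W * c)] += src[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}

// Max pooling with recorded argmax (0-based linear index into the input
// array) so the backward pass routes gradients only to the winning pixel.

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int H, int W, int C, int p) {
  const int Ho = H / p, Wo = W / p;
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int kj = 0; kj < p; ++kj) {
          for (int ki = 0; ki < p; ++ki) {
            const int r = ho * p + ki, cc = wo * p + kj;
            const int i = r + H * (cc + W * c);
            if (x[i] > best) { best = x[i]; besti = i; }
          }
        }
        const int o = ho + Ho * (wo + Wo * c);
        out[o] = best;
        idx[o] = besti;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector idx,
                              int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (int i = 0; i < dout.size(); ++i) dx[idx[i]] += dout[i];
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// Connected-component labelling of a binary mask with selectable 4- or
// 8-connectivity (BFS flood fill). Labels are 1..n in scan order.

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int rr = q.front().first, cc = q.front().second;
        q.pop();
        for (int k = 0; k < nn; ++k) {
          const int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  }
  return lab;
}
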