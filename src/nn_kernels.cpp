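#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C), column-major: x[h + H*w + H*W*c].
// im2col rows are indexed r = ho + Ho*wo so that (Ho*Wo x Cout) matrix
// products reshape directly into (Ho, Wo, Cout) arrays; columns are indexed
// col = dh + k*dw + k*k*c, matching a (k, k, Cin, Cout) weight array
// flattened to a (k*k*Cin x Cout) matrix.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * dw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride - pad + dh;
            if (hsrc < 0 || hsrc >= H) continue;
            out(ho + Ho * wo, col) = x[hsrc + H * wsrc + H * W * c];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out(H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = dh + k * dw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * stride - pad + dh;
            if (hsrc < 0 || hsrc >= H) continue;
            out[hsrc + H * wsrc + H * W * c] += cols(ho + Ho * wo, col);
          }
        }
      }
    }
  }
  return out;
}

// Max pooling with same-padding support (pad with -inf). Returns the pooled
// map plus 1-based argmax linear indices into the input for the backward pass.
// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = R_NegInf;
        int besti = -1;
        for (int dw = 0; dw < k; ++dw) {
          int wsrc = wo * stride - pad + dw;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hsrc = ho * stride - pad + dh;
            if (hsrc < 0 || hsrc >= H) continue;
            int lin = hsrc + H * wsrc + H * W * c;
            if (x[lin] > best) { best = x[lin]; besti = lin; }
          }
        }
        int o = ho + Ho * wo + Ho * Wo * c;
        out[o] = best;
        idx[o] = besti + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector grad, IntegerVector idx,
                              int H, int W, int C) {
  NumericVector out(H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int i = 0; i < grad.size(); ++i) {
    if (idx[i] > 0) out[idx[i] - 1] += grad[i];
  }
  return out;
}

// ROI max pooling. rois is an n x 4 matrix of (x1, y1, x2, y2) in feature-map
// coordinates (continuous, 0-based, half-open). Output is (P, P, C, n); idx
// holds 1-based argmax linear indices into the feature map (0 = empty bin,
// which cannot occur because bins are clamped to cover at least one cell).
// [[Rcpp::export]]
List roipool_cpp(NumericVector feat, NumericMatrix rois, int P) {
  IntegerVector d = feat.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  int n = rois.nrow();
  NumericVector out(P * P * C * n);
  out.attr("dim") = IntegerVector::create(P, P, C, n);
  IntegerVector idx(P * P * C * n);
  for (int r = 0; r < n; ++r) {
    double x1 = rois(r, 0), y1 = rois(r, 1), x2 = rois(r, 2), y2 = rois(r, 3);
    if (x1 < 0) x1 = 0; if (y1 < 0) y1 = 0;
    if (x2 > W) x2 = W; if (y2 > H) y2 = H;
    double bw = (x2 - x1) / P, bh = (y2 - y1) / P;
    for (int py = 0; py < P; ++py) {
      int h0 = (int)std::floor(y1 + py * bh);
      int h1 = (int)std::ceil(y1 + (py + 1) * bh);
      if (h1 <= h0) h1 = h0 + 1;              // sub-cell proposal: use cell
      if (h0 < 0) h0 = 0; if (h1 > H) h1 = H;
      if (h0 >= H) h0 = H - 1;
      for (int px = 0; px < P; ++px) {
        int w0 = (int)std::floor(x1 + px * bw);
        int w1 = (int)std::ceil(x1 + (px + 1) * bw);
        if (w1 <= w0) w1 = w0 + 1;
        if (w0 < 0) w0 = 0; if (w1 > W) w1 = W;
        if (w0 >= W) w0 = W - 1;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int besti = -1;
          for (int w = w0; w < std::max(w1, w0 + 1); ++w)
            for (int h = h0; h < std::max(h1, h0 + 1); ++h) {
              int lin = h + H * w + H * W * c;
              if (feat[lin] > best) { best = feat[lin]; besti = lin; }
            }
          int o = py + P * px + P * P * c + P * P * C * r;
          out[o] = best;
          idx[o] = besti + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector roipool_bwd_cpp(NumericVector grad, IntegerVector idx,
                              int H, int W, int C) {
  NumericVector out(H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  for (int i = 0; i < grad.size(); ++i)
    if (idx[i] > 0) out[idx[i] - 1] += grad[i];
  return out;
}

// Pairwise IoU between two sets of corner boxes (x1, y1, x2, y2).
// [[Rcpp::export]]
NumericMatrix iou_matrix_cpp(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  NumericMatrix out(na, nb);
  for (int j = 0; j < nb; ++j) {
    double bx1 = b(j, 0), by1 = b(j, 1), bx2 = b(j, 2), by2 = b(j, 3);
    double barea = (bx2 - bx1) * (by2 - by1);
    for (int i = 0; i < na; ++i) {
      double ix1 = std::max(a(i, 0), bx1), iy1 = std::max(a(i, 1), by1);
      double ix2 = std::min(a(i, 2), bx2), iy2 = std::min(a(i, 3), by2);
      double iw = ix2 - ix1, ih = iy2 - iy1;
      double inter = (iw > 0 && ih > 0) ? iw * ih : 0.0;
      double aarea = (a(i, 2) - a(i, 0)) * (a(i, 3) - a(i, 1));
      out(i, j) = inter / (aarea + barea - inter);
    }
  }
  return out;
}
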