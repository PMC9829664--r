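#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// im2col for 2D arrays stored (H, W, C), kernel k x k, same padding, stride 1.
// Output: (H*W) x (k*k*C) matrix; column order (dh fastest, then dw, then c)
// matching matrix(w, k*k*C, Cout) flattening of a (k, k, C, Cout) weight array.
// [[Rcpp::export(name = ".im2col2d")]]
NumericMatrix im2col2d(NumericVector x, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  int n = H * W, kk = k * k * C;
  NumericMatrix out(n, kk);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = c * k * k + dw * k + dh;
        for (int j = 0; j < W; ++j) {
          int sj = j + dw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + dh - pad;
            if (si < 0 || si >= H) continue;
            out(j * H + i, col) = x[(size_t)si + (size_t)sj * H + (size_t)c * H * W];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col2d: scatter-add a (H*W) x (k*k*C) matrix back to (H, W, C).
// [[Rcpp::export(name = ".col2im2d")]]
NumericVector col2im2d(NumericMatrix cols, int H, int W, int C, int k) {
  int pad = (k - 1) / 2;
  NumericVector out(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int col = c * k * k + dw * k + dh;
        for (int j = 0; j < W; ++j) {
          int sj = j + dw - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + dh - pad;
            if (si < 0 || si >= H) continue;
            out[si + sj * H + c * H * W] += cols(j * H + i, col);
          }
        }
      }
    }
  }
  return out;
}

// im2col for 3D arrays stored (D1, D2, D3, C), cubic kernel k, same padding,
// stride 1. Output: (D1*D2*D3) x (k^3*C); column order (d1 fastest, d2, d3, c).
// [[Rcpp::export(name = ".im2col3d")]]
NumericMatrix im2col3d(NumericVector x, int A, int B, int D, int C, int k) {
  int pad = (k - 1) / 2;
  int n = A * B * D, kk = k * k * k * C;
  NumericMatrix out(n, kk);
  double *px = REAL(x);
  for (int c = 0; c < C; ++c) {
    for (int d3 = 0; d3 < k; ++d3) {
      for (int d2 = 0; d2 < k; ++d2) {
        for (int d1 = 0; d1 < k; ++d1) {
          int col = ((c * k + d3) * k + d2) * k + d1;
          for (int w = 0; w < D; ++w) {
            int sw = w + d3 - pad;
            if (sw < 0 || sw >= D) continue;
            for (int v = 0; v < B; ++v) {
              int sv = v + d2 - pad;
              if (sv < 0 || sv >= B) continue;
              double *src = px + (size_t)c * A * B * D + (size_t)sw * A * B + (size_t)sv * A;
              double *dst = &out(0, col) + (size_t)w * A * B + (size_t)v * A;
              int lo = std::max(0, pad - d1), hi = std::min(A, A + pad - d1);
              for (int u = lo; u < hi; ++u) dst[u] = src[u + d1 - pad];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3d.
// [[Rcpp::export(name = ".col2im3d")]]
NumericVector col2im3d(NumericMatrix cols, int A, int B, int D, int C, int k) {
  int pad = (k - 1) / 2;
  NumericVector out((size_t)A * B * D * C);
  double *po = REAL(out);
  for (int c = 0; c < C; ++c) {
    for (int d3 = 0; d3 < k; ++d3) {
      for (int d2 = 0; d2 < k; ++d2) {
        for (int d1 = 0; d1 < k; ++d1) {
          int col = ((c * k + d3) * k + d2) * k + d1;
          for (int w = 0; w < D; ++w) {
            int sw = w + d3 - pad;
            if (sw < 0 || sw >= D) continue;
            for (int v = 0; v < B; ++v) {
              int sv = v + d2 - pad;
              if (sv < 0 || sv >= B) continue;
              double *dst = po + (size_t)c * A * B * D + (size_t)sw * A * B + (size_t)sv * A;
              double *src = &cols(0, col) + (size_t)w * A * B + (size_t)v * A;
              int lo = std::max(0, pad - d1), hi = std::min(A, A + pad - d1);
              for (int u = lo; u < hi; ++u) dst[u + d1 - pad] += src[u];
            }
          }
        }
      }
    }
  }
  return out;
}

// Binary dilation of a logical 3D grid by an explicit set of integer offsets,
// clipped at the grid boundary (no wrap).
// [[Rcpp::export(name = ".dilate_offsets")]]
LogicalVector dilate_offsets(LogicalVector mask, IntegerVector dims,
                             IntegerMatrix offsets) {
  int A = dims[0], B = dims[1], D = dims[2];
  LogicalVector out((size_t)A * B * D);
  int noff = offsets.nrow();
  for (int w = 0; w < D; ++w)
    for (int v = 0; v < B; ++v)
      for (int u = 0; u < A; ++u) {
        size_t idx = (size_t)w * A * B + (size_t)v * A + u;
        if (!mask[idx]) continue;
        for (int o = 0; o < noff; ++o) {
          int uu = u + offsets(o, 0), vv = v + offsets(o, 1), ww = w + offsets(o, 2);
          if (uu < 0 || uu >= A || vv < 0 || vv >= B || ww < 0 || ww >= D) continue;
          out[(size_t)ww * A * B + (size_t)vv * A + uu] = true;
        }
      }
  return out;
}

// Connected-component labeling of a 3D logical grid (BFS flood fill).
// connectivity is 6, 18 or 26. Returns integer labels, 0 = background;
// label values are in discovery order (relabeled in R by size).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  int A = dims[0], B = dims[1], D = dims[2];
  size_t n = (size_t)A * B * D;
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> offs;
  for (int dw = -1; dw <= 1; ++dw)
    for (int dv = -1; dv <= 1; ++dv)
      for (int du = -1; du <= 1; ++du) {
        int m = std::abs(du) + std::abs(dv) + std::abs(dw);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({du, dv, dw});
      }
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int u = cur % A, v = (cur / A) % B, w = cur / ((size_t)A * B);
      for (auto &o : offs) {
        int uu = u + o[0], vv = v + o[1], ww = w + o[2];
        if (uu < 0 || uu >= A || vv < 0 || vv >= B || ww < 0 || ww >= D) continue;
        size_t t = (size_t)ww * A * B + (size_t)vv * A + uu;
        if (mask[t] && !lab[t]) { lab[t] = next; q.push(t); }
      }
    }
  }
  return lab;
}

// For each row of a (n x 3) point set, the Euclidean distance to the nearest
// row of b (m x 3). Brute force; surfaces at phantom scale are small.
// [[Rcpp::export(name = ".nn_min_dists")]]
NumericVector nn_min_dists(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
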