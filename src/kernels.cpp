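#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tensors are stored as (H*W*N) x C matrices: row index = n*H*W + col*H + row
// (0-based), i.e. samples stacked, column-major spatial layout within a sample.
// Channels are matrix columns. All sliding windows use symmetric (mirror,
// edge-excluded) reflection so feature rasters stay aligned with the input and
// horizontal/vertical flips commute with every operator.

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".shift_gather")]]
NumericMatrix shift_gather(const NumericMatrix& X, int H, int W, int N,
                           int dr, int dc) {
  const int C = X.ncol();
  NumericMatrix Y(X.nrow(), C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    for (int n = 0; n < N; ++n) {
      const int base = n * H * W;
      for (int col = 0; col < W; ++col) {
        const int sc = reflect_idx(col + dc, W);
        const double* xc = x + base + sc * H;
        double* yc = y + base + col * H;
        for (int row = 0; row < H; ++row)
          yc[row] = xc[reflect_idx(row + dr, H)];
      }
    }
  }
  return Y;
}

// Adjoint of shift_gather (scatter-add into the source positions).
// [[Rcpp::export(name = ".shift_scatter")]]
NumericMatrix shift_scatter(const NumericMatrix& G, int H, int W, int N,
                            int dr, int dc) {
  const int C = G.ncol();
  NumericMatrix Y(G.nrow(), C);
  for (int ch = 0; ch < C; ++ch) {
    const double* g = &G(0, ch);
    double* y = &Y(0, ch);
    for (int n = 0; n < N; ++n) {
      const int base = n * H * W;
      for (int col = 0; col < W; ++col) {
        const int sc = reflect_idx(col + dc, W);
        const double* gc = g + base + col * H;
        double* yc = y + base + sc * H;
        for (int row = 0; row < H; ++row)
          yc[reflect_idx(row + dr, H)] += gc[row];
      }
    }
  }
  return Y;
}

// Depthwise 3x3 cross-correlation, stride 1, reflect "same" padding.
// Wdw is 9 x C, kernel element k = 3*(dr+1) + (dc+1).
// [[Rcpp::export(name = ".dw_conv_fwd")]]
NumericMatrix dw_conv_fwd(const NumericMatrix& X, int H, int W, int N,
                          const NumericMatrix& Wdw) {
  const int C = X.ncol();
  NumericMatrix Y(X.nrow(), C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    for (int n = 0; n < N; ++n) {
      const int base = n * H * W;
      for (int col = 0; col < W; ++col) {
        double* yc = y + base + col * H;
        for (int kdr = -1; kdr <= 1; ++kdr) {
          for (int kdc = -1; kdc <= 1; ++kdc) {
            const double w = Wdw(3 * (kdr + 1) + (kdc + 1), ch);
            const double* xc = x + base + reflect_idx(col + kdc, W) * H;
            for (int row = 0; row < H; ++row)
              yc[row] += w * xc[reflect_idx(row + kdr, H)];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".dw_conv_bwd")]]
List dw_conv_bwd(const NumericMatrix& G, const NumericMatrix& X,
                 int H, int W, int N, const NumericMatrix& Wdw) {
  const int C = X.ncol();
  NumericMatrix dX(X.nrow(), C);
  NumericMatrix dW(9, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* g = &G(0, ch);
    const double* x = &X(0, ch);
    double* dx = &dX(0, ch);
    for (int n = 0; n < N; ++n) {
      const int base = n * H * W;
      for (int col = 0; col < W; ++col) {
        const double* gc = g + base + col * H;
        for (int kdr = -1; kdr <= 1; ++kdr) {
          for (int kdc = -1; kdc <= 1; ++kdc) {
            const int k = 3 * (kdr + 1) + (kdc + 1);
            const double w = Wdw(k, ch);
            const int sc = reflect_idx(col + kdc, W);
            const double* xc = x + base + sc * H;
            double* dxc = dx + base + sc * H;
            double acc = 0.0;
            for (int row = 0; row < H; ++row) {
              const int sr = reflect_idx(row + kdr, H);
              acc += gc[row] * xc[sr];
              dxc[sr] += w * gc[row];
            }
            dW(k, ch) += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dX, _["dw"] = dW);
}

// 2x2 max pooling, stride 2. Returns pooled values and the flat source row
// index (0-based) of each maximum for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol(), Ho = H / 2, Wo = W / 2;
  NumericMatrix Y(Ho * Wo * N, C);
  IntegerMatrix A(Ho * Wo * N, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = &X(0, ch);
    for (int n = 0; n < N; ++n) {
      const int bi = n * H * W, bo = n * Ho * Wo;
      for (int col = 0; col < Wo; ++col) {
        for (int row = 0; row < Ho; ++row) {
          int best = bi + (2 * col) * H + 2 * row;
          double bv = x[best];
          const int cand[3] = {bi + (2 * col) * H + 2 * row + 1,
                               bi + (2 * col + 1) * H + 2 * row,
                               bi + (2 * col + 1) * H + 2 * row + 1};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
          Y(bo + col * Ho + row, ch) = bv;
          A(bo + col * Ho + row, ch) = best;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["argmax"] = A);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericMatrix maxpool2_bwd(const NumericMatrix& G, const IntegerMatrix& A,
                           int H, int W, int N) {
  const int C = G.ncol();
  NumericMatrix dX(H * W * N, C);
  for (int ch = 0; ch < C; ++ch)
    for (int i = 0; i < G.nrow(); ++i)
      dX(A(i, ch), ch) += G(i, ch);
  return dX;
}

// Bilinear x2 upsampling (half-pixel centres: in = (out + 0.5)/2 - 0.5,
// clamped at the borders), plus its exact adjoint.
static void up2_axis(int n_in, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& w0) {
  const int n_out = 2 * n_in;
  i0.resize(n_out); i1.resize(n_out); w0.resize(n_out);
  for (int o = 0; o < n_out; ++o) {
    double p = (o + 0.5) / 2.0 - 0.5;
    int lo = (int)std::floor(p);
    double frac = p - lo;
    int hi = lo + 1;
    if (lo < 0) { lo = 0; hi = 0; frac = 0.0; }
    if (hi >= n_in) { hi = n_in - 1; lo = n_in - 1; frac = 0.0; }
    i0[o] = lo; i1[o] = hi; w0[o] = 1.0 - frac;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericMatrix upsample2_fwd(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol(), Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> wr, wc;
  up2_axis(H, r0, r1, wr); up2_axis(W, c0, c1, wc);
  NumericMatrix Y(Ho * Wo * N, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = &X(0, ch);
    double* y = &Y(0, ch);
    for (int n = 0; n < N; ++n) {
      const int bi = n * H * W, bo = n * Ho * Wo;
      for (int col = 0; col < Wo; ++col) {
        const double* xa = x + bi + c0[col] * H;
        const double* xb = x + bi + c1[col] * H;
        double* yc = y + bo + col * Ho;
        for (int row = 0; row < Ho; ++row) {
          const double a = wr[row] * xa[r0[row]] + (1 - wr[row]) * xa[r1[row]];
          const double b = wr[row] * xb[r0[row]] + (1 - wr[row]) * xb[r1[row]];
          yc[row] = wc[col] * a + (1 - wc[col]) * b;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericMatrix upsample2_bwd(const NumericMatrix& G, int H, int W, int N) {
  const int C = G.ncol(), Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1; std::vector<double> wr, wc;
  up2_axis(H, r0, r1, wr); up2_axis(W, c0, c1, wc);
  NumericMatrix dX(H * W * N, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* g = &G(0, ch);
    double* dx = &dX(0, ch);
    for (int n = 0; n < N; ++n) {
      const int bi = n * H * W, bo = n * Ho * Wo;
      for (int col = 0; col < Wo; ++col) {
        double* xa = dx + bi + c0[col] * H;
        double* xb = dx + bi + c1[col] * H;
        const double* gc = g + bo + col * Ho;
        for (int row = 0; row < Ho; ++row) {
          const double ga = wc[col] * gc[row], gb = (1 - wc[col]) * gc[row];
          xa[r0[row]] += wr[row] * ga; xa[r1[row]] += (1 - wr[row]) * ga;
          xb[r0[row]] += wr[row] * gb; xb[r1[row]] += (1 - wr[row]) * gb;
        }
      }
    }
  }
  return dX;
}

// Sliding-window GLCM texture features. `img` holds quantized gray levels in
// [0, levels); a w x w window (reflect padded) is centred on every pixel,
// symmetric co-occurrence counts are accumulated over all in-window pairs at
// the given offsets, normalized, and summarized. Output columns:
// homogeneity, mean, dissimilarity, entropy.
// [[Rcpp::export(name = ".glcm_map")]]
NumericMatrix glcm_map_cpp(const IntegerMatrix& img, int levels, int window,
                           const IntegerMatrix& offsets) {
  const int H = img.nrow(), W = img.ncol(), half = window / 2;
  const int n_off = offsets.nrow();
  NumericMatrix out(H * W, 4);
  std::vector<double> P(levels * levels);
  std::vector<int> win(window * window);
  for (int col = 0; col < W; ++col) {
    for (int row = 0; row < H; ++row) {
      for (int wc = 0; wc < window; ++wc)
        for (int wr = 0; wr < window; ++wr)
          win[wc * window + wr] =
            img(reflect_idx(row - half + wr, H), reflect_idx(col - half + wc, W));
      std::fill(P.begin(), P.end(), 0.0);
      double total = 0.0;
      for (int k = 0; k < n_off; ++k) {
        const int dr = offsets(k, 0), dc = offsets(k, 1);
        for (int wc = 0; wc < window; ++wc) {
          const int pc = wc + dc;
          if (pc < 0 || pc >= window) continue;
          for (int wr = 0; wr < window; ++wr) {
            const int pr = wr + dr;
            if (pr < 0 || pr >= window) continue;
            const int i = win[wc * window + wr], j = win[pc * window + pr];
            P[i * levels + j] += 1.0;
            P[j * levels + i] += 1.0;
            total += 2.0;
          }
        }
      }
      double hom = 0.0, mu = 0.0, dis = 0.0, ent = 0.0;
      if (total > 0) {
        for (int i = 0; i < levels; ++i) {
          double pmarg = 0.0;
          for (int j = 0; j < levels; ++j) {
            const double p = P[i * levels + j] / total;
            if (p > 0) {
              const int d = i > j ? i - j : j - i;
              hom += p / (1.0 + (double)d * d);
              dis += p * d;
              ent -= p * std::log(p);
              pmarg += p;
            }
          }
          mu += i * pmarg;
        }
      }
      const int o = col * H + row;
      out(o, 0) = hom; out(o, 1) = mu; out(o, 2) = dis; out(o, 3) = ent;
    }
  }
  return out;
}
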