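// Convolution and pooling kernels for the tensor engine.
//
// Tensors are R arrays with dim c(N, C, H, W); element (n, c, h, w)
// (0-based) sits at linear index n + N*(c + C*(h + H*w)).  Convolution is
// implemented as im2col followed by a GEMM, one sample and channel group at
// a time; the backward pass reuses the same patch matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline R_xlen_t idx4(R_xlen_t n, R_xlen_t c, R_xlen_t h, R_xlen_t w,
                            R_xlen_t N, R_xlen_t C, R_xlen_t H) {
  return n + N * (c + C * (h + H * w));
}

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the patch matrix (Cg*k*k x Ho*Wo) for sample n, channel group g.
// Row q = ci + Cg*(ki + k*kj); column l = ho + Ho*wo.
static void im2col(const double* x, arma::mat& col, R_xlen_t n, int g,
                   int N, int C, int H, int W, int Cg, int k, int stride,
                   int pad, int Ho, int Wo) {
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      for (int kj = 0; kj < k; ++kj) {
        const int wi = wo * stride - pad + kj;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < k; ++ki) {
          const int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          for (int ci = 0; ci < Cg; ++ci) {
            const int c = g * Cg + ci;
            col(ci + Cg * (ki + k * kj), l) = x[idx4(n, c, hi, wi, N, C, H)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector bias, int stride, int pad,
                                 int groups) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], Cg = wd[1], k = wd[2];
  if (wd[3] != k) stop("only square kernels are supported");
  if (C % groups != 0 || Cout % groups != 0)
    stop("groups must divide both channel counts");
  if (Cg != C / groups)
    stop("weight channel dimension does not match input channels per group");
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("output spatial dimensions would be empty");
  const int Cout_g = Cout / groups;
  const bool has_bias = bias.size() > 0;

  NumericVector y(static_cast<R_xlen_t>(N) * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);

  // weight matrices per group: (Cout_g x Cg*k*k)
  std::vector<arma::mat> Wm(groups, arma::mat(Cout_g, Cg * k * k));
  for (int g = 0; g < groups; ++g)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (int ci = 0; ci < Cg; ++ci)
          for (int co = 0; co < Cout_g; ++co)
            Wm[g](co, ci + Cg * (ki + k * kj)) =
                w[(g * Cout_g + co) +
                  static_cast<R_xlen_t>(Cout) * (ci + Cg * (ki + k * kj))];

  arma::mat col(Cg * k * k, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), col, n, g, N, C, H, W, Cg, k, stride, pad, Ho, Wo);
      arma::mat out = Wm[g] * col;  // (Cout_g x Ho*Wo)
      for (int l = 0; l < Ho * Wo; ++l) {
        const int ho = l % Ho, wo = l / Ho;
        for (int co = 0; co < Cout_g; ++co) {
          const int c = g * Cout_g + co;
          double v = out(co, l);
          if (has_bias) v += bias[c];
          y[idx4(n, c, ho, wo, N, Cout, Ho)] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], Cg = wd[1], k = wd[2];
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  const int Cout_g = Cout / groups;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);

  std::vector<arma::mat> Wm(groups, arma::mat(Cout_g, Cg * k * k));
  std::vector<arma::mat> Gw(groups, arma::mat(Cout_g, Cg * k * k,
                                              arma::fill::zeros));
  for (int g = 0; g < groups; ++g)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (int ci = 0; ci < Cg; ++ci)
          for (int co = 0; co < Cout_g; ++co)
            Wm[g](co, ci + Cg * (ki + k * kj)) =
                w[(g * Cout_g + co) +
                  static_cast<R_xlen_t>(Cout) * (ci + Cg * (ki + k * kj))];

  arma::mat col(Cg * k * k, Ho * Wo);
  arma::mat gmat(Cout_g, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), col, n, g, N, C, H, W, Cg, k, stride, pad, Ho, Wo);
      for (int l = 0; l < Ho * Wo; ++l) {
        const int ho = l % Ho, wo = l / Ho;
        for (int co = 0; co < Cout_g; ++co) {
          const int c = g * Cout_g + co;
          const double gv = gy[idx4(n, c, ho, wo, N, Cout, Ho)];
          gmat(co, l) = gv;
          if (has_bias) gb[c] += gv;
        }
      }
      Gw[g] += gmat * col.t();
      arma::mat gcol = Wm[g].t() * gmat;  // (Cg*k*k x Ho*Wo)
      // col2im: scatter-add patches back into gx
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int l = ho + Ho * wo;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              for (int ci = 0; ci < Cg; ++ci) {
                const int c = g * Cg + ci;
                gx[idx4(n, c, hi, wi, N, C, H)] +=
                    gcol(ci + Cg * (ki + k * kj), l);
              }
            }
          }
        }
      }
    }
  }
  for (int g = 0; g < groups; ++g)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki)
        for (int ci = 0; ci < Cg; ++ci)
          for (int co = 0; co < Cout_g; ++co)
            gw[(g * Cout_g + co) +
               static_cast<R_xlen_t>(Cout) * (ci + Cg * (ki + k * kj))] =
                Gw[g](co, ci + Cg * (ki + k * kj));

  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Ho = out_dim(H, k, stride, pad);
  const int Wo = out_dim(W, k, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("output spatial dimensions would be empty");

  NumericVector y(static_cast<R_xlen_t>(N) * C * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  IntegerVector argmax(y.size());  // 0-based linear index into x

  R_xlen_t o = 0;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t best_i = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const R_xlen_t i = idx4(n, c, hi, wi, N, C, H);
              if (x[i] > best) { best = x[i]; best_i = i; }
            }
          }
          // column-major order of (n, c, ho, wo) matches o's increment order
          o = idx4(n, c, ho, wo, N, C, Ho);
          y[o] = best;
          argmax[o] = static_cast<int>(best_i);
        }
  return List::create(_["y"] = y, _["argmax"] = argmax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector xdim, IntegerVector argmax,
                                   NumericVector gy) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] *
                   xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  return gx;
}
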