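// Minibatch convolution and pooling kernels for the desk-scale training
// engine. Arrays follow R's column-major layout with dimensions
// (H, W, C, N). Convolutions use im2col + GEMM (Armadillo); pooling is
// direct. All kernels are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int outSize(int W, int F, int P, int S) {
  return (W - F + 2 * P) / S + 1;
}

// im2col for one sample: returns (Fh*Fw*C) x (Ho*Wo)
static arma::mat im2col(const double* x, int H, int W, int C,
                        int fh, int fw, int stride, int ph, int pw,
                        int Ho, int Wo) {
  arma::mat col(fh * fw * C, (size_t)Ho * Wo);
  col.zeros();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t outIdx = (size_t)wo * Ho + ho;  // column index
      double* dst = col.colptr(outIdx);
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < fw; ++j) {
          int wi = wo * stride - pw + j;
          for (int i = 0; i < fh; ++i) {
            int hi = ho * stride - ph + i;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = x[(size_t)hi + (size_t)H * (wi + (size_t)W * c)];
            dst[i + fh * (j + fw * c)] = v;
          }
        }
      }
    }
  }
  return col;
}

static void col2im(const arma::mat& col, double* dx, int H, int W, int C,
                   int fh, int fw, int stride, int ph, int pw,
                   int Ho, int Wo) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t outIdx = (size_t)wo * Ho + ho;
      const double* src = col.colptr(outIdx);
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < fw; ++j) {
          int wi = wo * stride - pw + j;
          for (int i = 0; i < fh; ++i) {
            int hi = ho * stride - ph + i;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              dx[(size_t)hi + (size_t)H * (wi + (size_t)W * c)] +=
                src[i + fh * (j + fw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cppConvForward")]]
NumericVector cppConvForward(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int fh = wd[0], fw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch");
  int Ho = outSize(H, fh, ph, stride), Wo = outSize(W, fw, pw, stride);
  if (Ho < 1 || Wo < 1) stop("conv: non-positive output size");
  // weight matrix: (Fh*Fw*Cin) x Cout  (column-major reshape of w)
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)fh * fw * Cin, Cout,
               false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
                           fh, fw, stride, ph, pw, Ho, Wo);
    arma::mat out = Wm.t() * col;  // Cout x (Ho*Wo)
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c)
      for (size_t m = 0; m < (size_t)Ho * Wo; ++m)
        yp[m + (size_t)Ho * Wo * c] = out(c, m) + b[c];
  }
  return y;
}

// [[Rcpp::export(name = ".cppConvBackward")]]
List cppConvBackward(NumericVector x, NumericVector w, NumericVector dy,
                     int stride, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int fh = wd[0], fw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = outSize(H, fh, ph, stride), Wo = outSize(W, fw, pw, stride);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)fh * fw * Cin, Cout,
               false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dW((size_t)fh * fw * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * H * W * C, H, W, C,
                           fh, fw, stride, ph, pw, Ho, Wo);
    // dy for this sample as Cout x (Ho*Wo)
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    arma::mat dyM(Cout, (size_t)Ho * Wo);
    for (int c = 0; c < Cout; ++c)
      for (size_t m = 0; m < (size_t)Ho * Wo; ++m)
        dyM(c, m) = dyp[m + (size_t)Ho * Wo * c];
    dW += col * dyM.t();
    db += arma::sum(dyM, 1);
    arma::mat dcol = Wm * dyM;  // (Fh*Fw*Cin) x (Ho*Wo)
    col2im(dcol, dx.begin() + (size_t)n * H * W * C, H, W, C,
           fh, fw, stride, ph, pw, Ho, Wo);
  }
  NumericVector dWr((R_xlen_t)fh * fw * Cin * Cout);
  dWr.attr("dim") = IntegerVector::create(fh, fw, Cin, Cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// kind: 0 = max, 1 = average (window average over in-bounds cells)
// [[Rcpp::export(name = ".cppPoolForward")]]
List cppPoolForward(NumericVector x, int fh, int fw, int stride,
                    int ph, int pw, int kind) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = outSize(H, fh, ph, stride), Wo = outSize(W, fw, pw, stride);
  if (Ho < 1 || Wo < 1) stop("pool: non-positive output size");
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(kind == 0 ? y.size() : 0);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300, acc = 0.0;
          int cnt = 0; size_t bestIdx = 0;
          for (int j = 0; j < fw; ++j) {
            int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < fh; ++i) {
              int hi = ho * stride - ph + i;
              if (hi < 0 || hi >= H) continue;
              size_t idx = (size_t)hi + (size_t)H * (wi + (size_t)W * c);
              double v = xp[idx];
              if (v > best) { best = v; bestIdx = idx; }
              acc += v; ++cnt;
            }
          }
          size_t oIdx = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * c) +
                        (size_t)n * Ho * Wo * C;
          if (kind == 0) {
            y[oIdx] = best;
            arg[oIdx] = (int)((size_t)n * H * W * C + bestIdx);
          } else {
            y[oIdx] = cnt > 0 ? acc / cnt : 0.0;
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".cppMaxPoolBackward")]]
NumericVector cppMaxPoolBackward(NumericVector dy, IntegerVector arg,
                                 IntegerVector xdim) {
  size_t total = 1;
  for (int i = 0; i < xdim.size(); ++i) total *= (size_t)xdim[i];
  NumericVector dx((R_xlen_t)total);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[arg[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".cppAvgPoolBackward")]]
NumericVector cppAvgPoolBackward(NumericVector dy, IntegerVector xdim,
                                 int fh, int fw, int stride,
                                 int ph, int pw) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    double* dxp = dx.begin() + (size_t)n * H * W * C;
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * C;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int cnt = 0;
          for (int j = 0; j < fw; ++j) {
            int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < fh; ++i) {
              int hi = ho * stride - ph + i;
              if (hi >= 0 && hi < H) ++cnt;
            }
          }
          if (cnt == 0) continue;
          double g = dyp[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * c)] / cnt;
          for (int j = 0; j < fw; ++j) {
            int wi = wo * stride - pw + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < fh; ++i) {
              int hi = ho * stride - ph + i;
              if (hi >= 0 && hi < H)
                dxp[(size_t)hi + (size_t)H * (wi + (size_t)W * c)] += g;
            }
          }
        }
      }
    }
  }
  return dx;
}

// Batch normalization over (H, W, N) per channel. Training mode computes
// batch statistics and updated running averages; eval mode normalizes by
// the supplied running statistics.
// [[Rcpp::export(name = ".cppBNForward")]]
List cppBNForward(NumericVector x, NumericVector gamma, NumericVector beta,
                  NumericVector runMean, NumericVector runVar,
                  bool training, double momentum, double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = xd;
  NumericVector xhat((R_xlen_t)x.size());
  xhat.attr("dim") = xd;
  NumericVector invStd(C), newMean(C), newVar(C);
  for (int c = 0; c < C; ++c) {
    double mu, va;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xp = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      }
      double m = (double)plane * N;
      mu = s / m;
      va = s2 / m - mu * mu;
      if (va < 0) va = 0;
      newMean[c] = (1 - momentum) * runMean[c] + momentum * mu;
      newVar[c] = (1 - momentum) * runVar[c] + momentum * va;
    } else {
      mu = runMean[c];
      va = runVar[c];
      newMean[c] = runMean[c];
      newVar[c] = runVar[c];
    }
    double is = 1.0 / std::sqrt(va + eps);
    invStd[c] = is;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      size_t off = plane * (c + (size_t)C * n);
      const double* xp = x.begin() + off;
      double* yp = y.begin() + off;
      double* hp = xhat.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        double h = (xp[i] - mu) * is;
        hp[i] = h;
        yp[i] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invStd"] = invStd,
                      _["runMean"] = newMean, _["runVar"] = newVar);
}

// [[Rcpp::export(name = ".cppBNBackward")]]
List cppBNBackward(NumericVector xhat, NumericVector invStd,
                   NumericVector gamma, NumericVector dy, bool training) {
  IntegerVector xd = xhat.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  double m = (double)plane * N;
  NumericVector dx((R_xlen_t)xhat.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sDy = 0.0, sDyH = 0.0;
    for (int n = 0; n < N; ++n) {
      size_t off = plane * (c + (size_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        sDy += dp[i];
        sDyH += dp[i] * hp[i];
      }
    }
    dgamma[c] = sDyH;
    dbeta[c] = sDy;
    double g = gamma[c], is = invStd[c];
    double meanDy = sDy / m, meanDyH = sDyH / m;
    for (int n = 0; n < N; ++n) {
      size_t off = plane * (c + (size_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      double* xp = dx.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        double dxhat = dp[i] * g;
        xp[i] = training
          ? is * (dxhat - g * meanDy - hp[i] * g * meanDyH)
          : is * dxhat;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
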