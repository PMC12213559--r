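// Numeric kernels for the DSCnet blocks.
//
// All feature maps are (channels x time x batch) cubes; the singleton
// "height" axis of the (C x 1 x T) layout is implicit.  Every temporal
// convolution is zero-padded "same" with stride 1; pooling is the only
// operation that changes the time length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------------------
// grouped 1-D convolution
//
// x: (Cin x T x N), w: (Cout x Cin/groups x k), b: length Cout.
// Group g maps input rows [g*Cin/G, ...) to output rows [g*Cout/G, ...).
// Depthwise convolution is groups = Cin with Cout = Cin; pointwise mixing is
// k = 1 with groups = 1.

// Build the tap-shifted copy of x viewed as a (Cin x T*N) matrix: column
// (n*T + t) of the result holds x(:, t + s, n), zero outside the segment.
static void shiftedCopy(const mat& xall, mat& xs, const int T, const int N,
                        const int s) {
  xs.zeros();
  const int t0 = std::max(0, -s);
  const int t1 = std::min(T - 1, T - 1 - s);
  if (t0 > t1) return;
  for (int n = 0; n < N; ++n) {
    xs.cols(n * T + t0, n * T + t1) = xall.cols(n * T + t0 + s,
                                                n * T + t1 + s);
  }
}

// [[Rcpp::export]]
arma::cube conv1dForwardCpp(const arma::cube& x, const arma::cube& w,
                            const arma::vec& b, const int groups) {
  const int Cin = x.n_rows, T = x.n_cols, N = x.n_slices;
  const int Cout = w.n_rows, Cing = w.n_cols, k = w.n_slices;
  const int Coutg = Cout / groups;
  const int off = k / 2;
  cube y(Cout, T, N, fill::zeros);
  const mat xall(const_cast<double*>(x.memptr()), Cin, T * N, false, true);
  mat yall(y.memptr(), Cout, T * N, false, true);
  const bool depthwise = (groups == Cin && Cing == 1 && Cout == Cin);
  if (depthwise) {
    const double* xm = x.memptr();
    double* ym = y.memptr();
    for (int j = 0; j < k; ++j) {
      const int s = j - off;
      const int t0 = std::max(0, -s);
      const int t1 = std::min(T - 1, T - 1 - s);
      if (t0 > t1) continue;
      const double* wj = w.slice(j).memptr();
      for (int n = 0; n < N; ++n) {
        for (int t = t0; t <= t1; ++t) {
          double* yp = ym + (size_t)(n * T + t) * Cin;
          const double* xp = xm + (size_t)(n * T + t + s) * Cin;
          for (int c = 0; c < Cin; ++c) yp[c] += wj[c] * xp[c];
        }
      }
    }
  } else {
    mat xs;
    for (int j = 0; j < k; ++j) {
      const int s = j - off;
      const bool direct = (s == 0);
      if (!direct) {
        xs.set_size(Cin, T * N);
        shiftedCopy(xall, xs, T, N, s);
      }
      const mat& xj = direct ? xall : xs;
      if (groups == 1) {
        yall += w.slice(j) * xj;
      } else {
        for (int g = 0; g < groups; ++g) {
          yall.rows(g * Coutg, (g + 1) * Coutg - 1) +=
            w.slice(j).rows(g * Coutg, (g + 1) * Coutg - 1) *
            xj.rows(g * Cing, (g + 1) * Cing - 1);
        }
      }
    }
  }
  yall.each_col() += b;
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1dBackwardCpp(const arma::cube& x, const arma::cube& w,
                             const arma::cube& dy, const int groups) {
  const int Cin = x.n_rows, T = x.n_cols, N = x.n_slices;
  const int Cout = w.n_rows, Cing = w.n_cols, k = w.n_slices;
  const int Coutg = Cout / groups;
  const int off = k / 2;
  cube dx(Cin, T, N, fill::zeros);
  cube dw(Cout, Cing, k, fill::zeros);
  const mat xall(const_cast<double*>(x.memptr()), Cin, T * N, false, true);
  const mat dyall(const_cast<double*>(dy.memptr()), Cout, T * N, false,
                  true);
  mat dxall(dx.memptr(), Cin, T * N, false, true);
  vec db = sum(dyall, 1);
  const bool depthwise = (groups == Cin && Cing == 1 && Cout == Cin);
  if (depthwise) {
    const double* xm = x.memptr();
    const double* dym = dy.memptr();
    double* dxm = dx.memptr();
    for (int j = 0; j < k; ++j) {
      const int s = j - off;
      const int t0 = std::max(0, -s);
      const int t1 = std::min(T - 1, T - 1 - s);
      if (t0 > t1) continue;
      const double* wj = w.slice(j).memptr();
      double* dwj = dw.slice(j).memptr();
      for (int n = 0; n < N; ++n) {
        for (int t = t0; t <= t1; ++t) {
          const double* dyp = dym + (size_t)(n * T + t) * Cin;
          const double* xp = xm + (size_t)(n * T + t + s) * Cin;
          double* dxp = dxm + (size_t)(n * T + t + s) * Cin;
          for (int c = 0; c < Cin; ++c) {
            dwj[c] += dyp[c] * xp[c];
            dxp[c] += wj[c] * dyp[c];
          }
        }
      }
    }
  } else {
    mat xs;
    mat dxs(Cin, T * N);
    for (int j = 0; j < k; ++j) {
      const int s = j - off;
      const bool direct = (s == 0);
      if (!direct) {
        xs.set_size(Cin, T * N);
        shiftedCopy(xall, xs, T, N, s);
      }
      const mat& xj = direct ? xall : xs;
      if (groups == 1) {
        dw.slice(j) = dyall * xj.t();
        if (direct) {
          dxall += w.slice(j).t() * dyall;
          continue;
        }
        dxs = w.slice(j).t() * dyall;
      } else {
        if (!direct) dxs.zeros();
        for (int g = 0; g < groups; ++g) {
          dw.slice(j).rows(g * Coutg, (g + 1) * Coutg - 1) =
            dyall.rows(g * Coutg, (g + 1) * Coutg - 1) *
            xj.rows(g * Cing, (g + 1) * Cing - 1).t();
          if (direct) {
            dxall.rows(g * Cing, (g + 1) * Cing - 1) +=
              w.slice(j).rows(g * Coutg, (g + 1) * Coutg - 1).t() *
              dyall.rows(g * Coutg, (g + 1) * Coutg - 1);
          } else {
            dxs.rows(g * Cing, (g + 1) * Cing - 1) =
              w.slice(j).rows(g * Coutg, (g + 1) * Coutg - 1).t() *
              dyall.rows(g * Coutg, (g + 1) * Coutg - 1);
          }
        }
        if (direct) continue;
      }
      // scatter-add the shifted gradient back onto the input grid
      const int t0 = std::max(0, -s);
      const int t1 = std::min(T - 1, T - 1 - s);
      if (t0 > t1) continue;
      for (int n = 0; n < N; ++n) {
        dxall.cols(n * T + t0 + s, n * T + t1 + s) +=
          dxs.cols(n * T + t0, n * T + t1);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// ---------------------------------------------------------------------------
// temporal max pooling (non-overlapping windows of length p, remainder
// dropped); argmax recorded for the backward pass, first maximum wins.

// [[Rcpp::export]]
Rcpp::List maxpoolForwardCpp(const arma::cube& x, const int p) {
  const int C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const int To = T / p;
  cube y(C, To, N);
  icube idx(C, To, N);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < To; ++t) {
      for (int c = 0; c < C; ++c) {
        int best = t * p;
        double bv = x(c, best, n);
        for (int u = t * p + 1; u < (t + 1) * p; ++u) {
          if (x(c, u, n) > bv) { bv = x(c, u, n); best = u; }
        }
        y(c, t, n) = bv;
        idx(c, t, n) = best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpoolBackwardCpp(const arma::cube& dy, const arma::icube& idx,
                              const int tIn) {
  const int C = dy.n_rows, To = dy.n_cols, N = dy.n_slices;
  cube dx(C, tIn, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < To; ++t)
      for (int c = 0; c < C; ++c)
        dx(c, idx(c, t, n), n) += dy(c, t, n);
  return dx;
}

// ---------------------------------------------------------------------------
// nearest-neighbour temporal up-sampling by an integer factor p, clipped /
// edge-replicated to an arbitrary target length tOut.

// [[Rcpp::export]]
arma::cube upsampleForwardCpp(const arma::cube& x, const int p,
                              const int tOut) {
  const int C = x.n_rows, Tin = x.n_cols, N = x.n_slices;
  cube y(C, tOut, N);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < tOut; ++t) {
      int src = t / p; if (src >= Tin) src = Tin - 1;
      for (int c = 0; c < C; ++c) y(c, t, n) = x(c, src, n);
    }
  return y;
}

// [[Rcpp::export]]
arma::cube upsampleBackwardCpp(const arma::cube& dy, const int p,
                               const int tIn) {
  const int C = dy.n_rows, To = dy.n_cols, N = dy.n_slices;
  cube dx(C, tIn, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < To; ++t) {
      int src = t / p; if (src >= tIn) src = tIn - 1;
      for (int c = 0; c < C; ++c) dx(c, src, n) += dy(c, t, n);
    }
  return dx;
}

// ---------------------------------------------------------------------------
// CoT dynamic-context aggregation.
//
// a: (C*k x T x N) raw attention logits, row (c*k + j) holding the logit of
// neighbourhood tap j for channel c; v: (C x T x N) values.  Weights are
// softmax-normalized over the k taps; tap j reads v at time t + j - k/2
// (zero outside the segment).  Returns the aggregate y and the softmax
// probabilities for the backward pass.

// [[Rcpp::export]]
Rcpp::List cotAggForwardCpp(const arma::cube& a, const arma::cube& v,
                            const int k) {
  const int C = v.n_rows, T = v.n_cols, N = v.n_slices;
  const int off = k / 2;
  cube y(C, T, N, fill::zeros);
  cube p(C * k, T, N);
  std::vector<double> e(k);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c) {
        double mx = -datum::inf;
        for (int j = 0; j < k; ++j)
          mx = std::max(mx, a(c * k + j, t, n));
        double z = 0.0;
        for (int j = 0; j < k; ++j) {
          e[j] = std::exp(a(c * k + j, t, n) - mx);
          z += e[j];
        }
        double acc = 0.0;
        for (int j = 0; j < k; ++j) {
          const double pj = e[j] / z;
          p(c * k + j, t, n) = pj;
          const int u = t + j - off;
          if (u >= 0 && u < T) acc += pj * v(c, u, n);
        }
        y(c, t, n) = acc;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("p") = p);
}

// [[Rcpp::export]]
Rcpp::List cotAggBackwardCpp(const arma::cube& dy, const arma::cube& p,
                             const arma::cube& v, const arma::cube& y,
                             const int k) {
  const int C = v.n_rows, T = v.n_cols, N = v.n_slices;
  const int off = k / 2;
  cube da(C * k, T, N, fill::zeros);
  cube dv(C, T, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c) {
        const double g = dy(c, t, n);
        if (g == 0.0) continue;
        for (int j = 0; j < k; ++j) {
          const int u = t + j - off;
          const double pj = p(c * k + j, t, n);
          const double vj = (u >= 0 && u < T) ? v(c, u, n) : 0.0;
          if (u >= 0 && u < T) dv(c, u, n) += g * pj;
          da(c * k + j, t, n) = g * pj * (vj - y(c, t, n));
        }
      }
  return Rcpp::List::create(Rcpp::Named("da") = da, Rcpp::Named("dv") = dv);
}

// ---------------------------------------------------------------------------
// exact GELU x * Phi(x) and its derivative Phi(x) + x * phi(x)

// [[Rcpp::export]]
arma::cube geluCpp(const arma::cube& x) {
  cube y(size(x));
  const double is2 = 1.0 / std::sqrt(2.0);
  const double* xm = x.memptr();
  double* ym = y.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double v = xm[i];
    ym[i] = v * 0.5 * (1.0 + std::erf(v * is2));
  }
  return y;
}

// [[Rcpp::export]]
arma::cube geluGradCpp(const arma::cube& x) {
  cube y(size(x));
  const double is2 = 1.0 / std::sqrt(2.0);
  const double c = 1.0 / std::sqrt(2.0 * datum::pi);
  const double* xm = x.memptr();
  double* ym = y.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double v = xm[i];
    ym[i] = 0.5 * (1.0 + std::erf(v * is2)) + v * c * std::exp(-0.5 * v * v);
  }
  return y;
}

// ---------------------------------------------------------------------------
// batch normalization over (time x batch) per channel

// [[Rcpp::export]]
Rcpp::List bnForwardCpp(const arma::cube& x, const arma::vec& gamma,
                        const arma::vec& beta, const arma::vec& runMean,
                        const arma::vec& runVar, const bool training,
                        const double eps) {
  const int C = x.n_rows, T = x.n_cols, N = x.n_slices;
  const double M = double(T) * double(N);
  vec mu(C), var(C);
  if (training) {
    mu.zeros(); var.zeros();
    for (int n = 0; n < N; ++n) {
      mu += sum(x.slice(n), 1);
      var += sum(square(x.slice(n)), 1);
    }
    mu /= M;
    var = var / M - square(mu);
    var.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  } else {
    mu = runMean;
    var = runVar;
  }
  const vec invstd = 1.0 / sqrt(var + eps);
  cube xhat(C, T, N), y(C, T, N);
  for (int n = 0; n < N; ++n) {
    xhat.slice(n) = (x.slice(n).each_col() - mu).each_col() % invstd;
    y.slice(n) = (xhat.slice(n).each_col() % gamma).each_col() + beta;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("invstd") = invstd,
                            Rcpp::Named("mean") = mu, Rcpp::Named("var") = var);
}

// [[Rcpp::export]]
Rcpp::List bnBackwardCpp(const arma::cube& dy, const arma::cube& xhat,
                         const arma::vec& invstd, const arma::vec& gamma) {
  const int C = dy.n_rows, T = dy.n_cols, N = dy.n_slices;
  const double M = double(T) * double(N);
  vec sdy(C, fill::zeros), sdyx(C, fill::zeros);
  for (int n = 0; n < N; ++n) {
    sdy += sum(dy.slice(n), 1);
    sdyx += sum(dy.slice(n) % xhat.slice(n), 1);
  }
  cube dx(C, T, N);
  const vec a = gamma % invstd / M;
  for (int n = 0; n < N; ++n) {
    mat tmp = dy.slice(n) * M - xhat.slice(n).each_col() % sdyx;
    tmp.each_col() -= sdy;
    dx.slice(n) = tmp.each_col() % a;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = sdyx,
                            Rcpp::Named("dbeta") = sdy);
}
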