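// Dense compute kernels for the network layers. The surrounding layer
// logic, caching and autodiff orchestration live in R (nn-ops.R); these
// functions only carry the tight loops and BLAS calls. Activation tensors
// are (features, time, batch) cubes, matching R's column-major arrays.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---- 1-d convolution via im2col ------------------------------------------

// x: (Cin, L, B). Columns l*stride .. l*stride+kernel-1 of one slice are
// contiguous, so each im2col column is a single memcpy.
// [[Rcpp::export]]
List cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                  const arma::vec& b, int kernel, int stride,
                  bool keepCache) {
  const int cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int lout = (L - kernel) / stride + 1;
  arma::mat xc(cin * kernel, (size_t)lout * B);
  for (int bi = 0; bi < B; ++bi) {
    const double* xs = x.slice_memptr(bi);
    for (int l = 0; l < lout; ++l) {
      std::memcpy(xc.colptr((size_t)bi * lout + l),
                  xs + (size_t)l * stride * cin,
                  sizeof(double) * cin * kernel);
    }
  }
  arma::mat out = W * xc;
  out.each_col() += b;
  arma::cube outc(out.memptr(), W.n_rows, lout, B);
  if (keepCache) return List::create(_["out"] = outc, _["xc"] = xc);
  return List::create(_["out"] = outc);
}

// Weight/bias gradients only: convolution is the first layer, no input
// gradient needed.
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& dout, const arma::mat& xc) {
  arma::mat dm(const_cast<double*>(dout.memptr()), dout.n_rows,
               (size_t)dout.n_cols * dout.n_slices, false, true);
  arma::mat dW = dm * xc.t();
  arma::vec db = arma::sum(dm, 1);
  return List::create(_["dW"] = dW, _["db"] = db);
}

// ---- fused batch norm + LeakyReLU ----------------------------------------

// x: (F, N) with N pooling time and batch; per-row statistics, biased
// variance. LeakyReLU preserves sign, so the backward mask is recoverable
// from the sign of the output and needs no extra cache.
// [[Rcpp::export]]
List cpp_bn_leaky_fwd(const arma::mat& x, const arma::vec& g,
                      const arma::vec& b, const arma::vec& rm,
                      const arma::vec& rv, bool training, double momentum,
                      double eps, double slope) {
  const arma::uword F = x.n_rows, N = x.n_cols;
  if (training) {
    arma::vec sum(F, arma::fill::zeros), sumsq(F, arma::fill::zeros);
    const double* px = x.memptr();
    for (arma::uword j = 0; j < N; ++j) {
      const double* col = px + j * F;
      for (arma::uword f = 0; f < F; ++f) {
        sum[f] += col[f];
        sumsq[f] += col[f] * col[f];
      }
    }
    arma::vec mu = sum / N;
    arma::vec v = sumsq / N - mu % mu;
    v.transform([](double a) { return a > 0 ? a : 0; });
    arma::vec invstd = 1.0 / arma::sqrt(v + eps);
    arma::mat xhat(F, N), out(F, N);
    double* ph = xhat.memptr();
    double* po = out.memptr();
    for (arma::uword j = 0; j < N; ++j) {
      const double* col = px + j * F;
      double* hc = ph + j * F;
      double* oc = po + j * F;
      for (arma::uword f = 0; f < F; ++f) {
        const double h = (col[f] - mu[f]) * invstd[f];
        hc[f] = h;
        const double o = g[f] * h + b[f];
        oc[f] = o < 0 ? o * slope : o;
      }
    }
    return List::create(
      _["out"] = out, _["xhat"] = xhat, _["invstd"] = invstd,
      _["rm"] = (1 - momentum) * rm + momentum * mu,
      _["rv"] = (1 - momentum) * rv + momentum * v);
  }
  arma::vec scale = g / arma::sqrt(rv + eps);
  arma::mat out(F, N);
  const double* px = x.memptr();
  double* po = out.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* col = px + j * F;
    double* oc = po + j * F;
    for (arma::uword f = 0; f < F; ++f) {
      const double o = (col[f] - rm[f]) * scale[f] + b[f];
      oc[f] = o < 0 ? o * slope : o;
    }
  }
  return List::create(_["out"] = out);
}

// Backward of the fused block. With dpre the gradient at the BN output,
// sum(dxhat) = g * sum(dpre) and sum(dxhat * xhat) = g * sum(dpre * xhat),
// so only db and dg need accumulating.
// [[Rcpp::export]]
List cpp_bn_leaky_bwd(const arma::mat& dout, const arma::mat& out,
                      const arma::vec& g, const arma::mat& xhat,
                      const arma::vec& invstd, double slope) {
  const arma::uword F = dout.n_rows, N = dout.n_cols;
  arma::vec dg(F, arma::fill::zeros), db(F, arma::fill::zeros);
  const double* pd = dout.memptr();
  const double* po = out.memptr();
  const double* ph = xhat.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* dc = pd + j * F;
    const double* oc = po + j * F;
    const double* hc = ph + j * F;
    for (arma::uword f = 0; f < F; ++f) {
      const double dpre = oc[f] < 0 ? dc[f] * slope : dc[f];
      db[f] += dpre;
      dg[f] += dpre * hc[f];
    }
  }
  const double n = (double)N;
  arma::vec c0 = invstd % g;             // per-unit dpre coefficient
  arma::vec c1 = invstd % g % db / n;    // mean correction
  arma::vec c2 = invstd % g % dg / n;    // variance correction
  arma::mat dx(F, N);
  double* px = dx.memptr();
  for (arma::uword j = 0; j < N; ++j) {
    const double* dc = pd + j * F;
    const double* oc = po + j * F;
    const double* hc = ph + j * F;
    double* xc = px + j * F;
    for (arma::uword f = 0; f < F; ++f) {
      const double dpre = oc[f] < 0 ? dc[f] * slope : dc[f];
      xc[f] = c0[f] * dpre - c1[f] - hc[f] * c2[f];
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// ---- max pooling ----------------------------------------------------------

// Non-overlapping windows of width pool along the time axis, floor
// division; argmax kept for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x, int pool) {
  const int F = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int lout = L / pool;
  arma::cube out(F, lout, B);
  arma::ucube arg(F, lout, B);
  for (int bi = 0; bi < B; ++bi) {
    for (int lo = 0; lo < lout; ++lo) {
      const double* src = x.slice_memptr(bi) + (size_t)lo * pool * F;
      double* dst = out.slice_memptr(bi) + (size_t)lo * F;
      arma::uword* am = arg.slice_memptr(bi) + (size_t)lo * F;
      for (int f = 0; f < F; ++f) {
        double best = src[f];
        arma::uword bj = 0;
        for (int j = 1; j < pool; ++j) {
          const double cand = src[f + (size_t)j * F];
          if (cand > best) { best = cand; bj = j; }
        }
        dst[f] = best;
        am[f] = bj;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dout, const arma::ucube& arg,
                           int pool, int lin) {
  const int F = dout.n_rows, lout = dout.n_cols, B = dout.n_slices;
  arma::cube dx(F, lin, B, arma::fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    for (int lo = 0; lo < lout; ++lo) {
      const double* src = dout.slice_memptr(bi) + (size_t)lo * F;
      const arma::uword* am = arg.slice_memptr(bi) + (size_t)lo * F;
      double* dst = dx.slice_memptr(bi) + (size_t)lo * pool * F;
      for (int f = 0; f < F; ++f) dst[f + (size_t)am[f] * F] += src[f];
    }
  }
  return dx;
}

// ---- LSTM -----------------------------------------------------------------

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// Extract the (D, B) time-step matrix from a (D, T, B) cube.
static arma::mat step_of(const arma::cube& x, int t) {
  arma::mat out(x.n_rows, x.n_slices);
  for (arma::uword bi = 0; bi < x.n_slices; ++bi) {
    out.col(bi) = x.slice(bi).col(t);
  }
  return out;
}

static void set_step(arma::cube& x, int t, const arma::mat& v) {
  for (arma::uword bi = 0; bi < x.n_slices; ++bi) {
    x.slice(bi).col(t) = v.col(bi);
  }
}

// One direction over x (D, T, B); gate order i, f, g, o stacked in the rows
// of Wx/Wh/b. reverse = process the sequence from t = T-1 down.
// [[Rcpp::export]]
List cpp_lstm_fwd(const arma::cube& x, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b, bool reverse) {
  const int T = x.n_cols, B = x.n_slices;
  const int H = Wh.n_cols;
  arma::cube I(H, T, B), Fg(H, T, B), G(H, T, B), O(H, T, B), C(H, T, B),
      TC(H, T, B), Hs(H, T, B);
  arma::mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int k = 0; k < T; ++k) {
    const int t = reverse ? T - 1 - k : k;
    arma::mat z = Wx * step_of(x, t) + Wh * h;
    z.each_col() += b;
    arma::mat ig = sigm(z.rows(0, H - 1));
    arma::mat fg = sigm(z.rows(H, 2 * H - 1));
    arma::mat gg = arma::tanh(z.rows(2 * H, 3 * H - 1));
    arma::mat og = sigm(z.rows(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    arma::mat tc = arma::tanh(c);
    h = og % tc;
    set_step(I, t, ig); set_step(Fg, t, fg); set_step(G, t, gg);
    set_step(O, t, og); set_step(C, t, c); set_step(TC, t, tc);
    set_step(Hs, t, h);
  }
  return List::create(_["hs"] = Hs, _["I"] = I, _["Fg"] = Fg, _["G"] = G,
                      _["O"] = O, _["C"] = C, _["TC"] = TC);
}

// dhs: gradient into each h_t from the layers above.
// [[Rcpp::export]]
List cpp_lstm_bwd(const arma::cube& dhs, const arma::cube& x,
                  const arma::cube& Hs, const arma::cube& I,
                  const arma::cube& Fg, const arma::cube& G,
                  const arma::cube& O, const arma::cube& C,
                  const arma::cube& TC, const arma::mat& Wx,
                  const arma::mat& Wh, bool reverse) {
  const int D = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int H = Wh.n_cols;
  arma::mat dWx(4 * H, D, arma::fill::zeros);
  arma::mat dWh(4 * H, H, arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  arma::cube dx(D, T, B);
  arma::mat dh(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
  const arma::mat zero(H, B, arma::fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    const int t = reverse ? T - 1 - k : k;
    const int tprev = reverse ? t + 1 : t - 1;
    const bool first = (k == 0);
    dh += step_of(dhs, t);
    arma::mat og = step_of(O, t), tc = step_of(TC, t), ig = step_of(I, t),
              fg = step_of(Fg, t), gg = step_of(G, t);
    dc += dh % og % (1 - tc % tc);
    arma::mat cprev = first ? zero : step_of(C, tprev);
    arma::mat hprev = first ? zero : step_of(Hs, tprev);
    arma::mat dz(4 * H, B);
    dz.rows(0, H - 1) = dc % gg % ig % (1 - ig);
    dz.rows(H, 2 * H - 1) = dc % cprev % fg % (1 - fg);
    dz.rows(2 * H, 3 * H - 1) = dc % ig % (1 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = dh % tc % og % (1 - og);
    dWx += dz * step_of(x, t).t();
    dWh += dz * hprev.t();
    db += arma::sum(dz, 1);
    set_step(dx, t, Wx.t() * dz);
    dh = Wh.t() * dz;
    dc %= fg;
  }
  return List::create(_["dx"] = dx, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}

// ---- squeeze-and-excitation broadcast helpers ----------------------------

// out[f, t, b] = x[f, t, b] * s[f, b]
// [[Rcpp::export]]
arma::cube cpp_scale_channels(const arma::cube& x, const arma::mat& s) {
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  for (arma::uword bi = 0; bi < x.n_slices; ++bi) {
    out.slice(bi) = x.slice(bi).each_col() % s.col(bi);
  }
  return out;
}

// out[f, t, b] = x[f, t, b] + m[f, b]
// [[Rcpp::export]]
arma::cube cpp_add_channels(const arma::cube& x, const arma::mat& m) {
  arma::cube out(x.n_rows, x.n_cols, x.n_slices);
  for (arma::uword bi = 0; bi < x.n_slices; ++bi) {
    out.slice(bi) = x.slice(bi).each_col() + m.col(bi);
  }
  return out;
}

// Per-channel time average: z[f, b] = mean_t x[f, t, b]
// [[Rcpp::export]]
arma::mat cpp_time_mean(const arma::cube& x) {
  arma::mat z(x.n_rows, x.n_slices);
  for (arma::uword bi = 0; bi < x.n_slices; ++bi) {
    z.col(bi) = arma::mean(x.slice(bi), 1);
  }
  return z;
}
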