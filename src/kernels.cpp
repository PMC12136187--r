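// Neural-network engine. All trainable parameters of a network live in one
// flat vector `theta`; an integer layout table describes the layer stack.
// Activations in the convolution domain are [n * L, C] matrices with
// batch-fastest row order (row = i + pos * n, 0-based); the dense domain is
// the usual [n, d]. The two layouts share one linear order, so reshape and
// flatten are O(1). Convolution weights are [k * C_in, C_out] with row index
// c * k + j for kernel offset j within input channel c.
//
// Layout columns (see nn_build()):
//  0 kind (1 dense, 2 reshape, 3 flatten, 4 conv, 5 pool, 6 norm,
//          7 upsample, 8 activation)
//  1 activation code (0 relu, 1 lrelu, 2 tanh, 3 sigmoid, 4 linear)
//  2 in_len   3 in_ch   4 out_ch/units   5 kernel/size/factor   6 stride
//  7 pad   8 w offset   9 w length   10 b offset   11 b length
//  12 running-stats offset (norm)   13 out_len

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

enum Kind { DENSE = 1, RESHAPE, FLATTEN, CONV, POOL, NORM, UPSAMPLE, ACT };

struct Cache {
  mat a;   // dense: input x; conv: patches P; act: pre-activation x
  mat b;   // act: output y; norm: xhat; pool: argmax (as double)
  vec c;   // norm: invstd
};

static inline mat act_apply(const mat& x, int code) {
  switch (code) {
    case 0: { mat y = x; y.transform([](double v) { return v > 0 ? v : 0.0; }); return y; }
    case 1: { mat y = x; y.transform([](double v) { return v > 0 ? v : 0.2 * v; }); return y; }
    case 2: return arma::tanh(x);
    case 3: return 1.0 / (1.0 + arma::exp(-x));
    default: return x;
  }
}

static inline mat act_grad(const mat& g, const mat& x, const mat& y, int code) {
  switch (code) {
    case 0: return g % arma::conv_to<mat>::from(x > 0);
    case 1: { mat s = x; s.transform([](double v) { return v > 0 ? 1.0 : 0.2; }); return g % s; }
    case 2: return g % (1.0 - arma::square(y));
    case 3: return g % y % (1.0 - y);
    default: return g;
  }
}

// im2col patches: P [n*out_len, k*C] with column c*k + j
static mat im2col(const mat& x, int k, int stride, int pad, int n,
                  int in_len, int out_len) {
  const int C = x.n_cols;
  mat P(n * out_len, k * C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int j = 0; j < k; ++j) {
      double* dst = P.colptr(c * k + j);
      for (int o = 0; o < out_len; ++o) {
        const int pos = o * stride + j - pad;  // input position (0-based)
        double* d = dst + o * n;
        if (pos < 0 || pos >= in_len) {
          std::fill(d, d + n, 0.0);
        } else {
          const double* s = src + pos * n;
          std::copy(s, s + n, d);
        }
      }
    }
  }
  return P;
}

// scatter dP [n*out_len, k*C] back to the input layout [n*in_len, C]
static mat col2im(const mat& dP, int k, int stride, int pad, int n,
                  int in_len, int out_len) {
  const int C = dP.n_cols / k;
  mat dx(n * in_len, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* dst = dx.colptr(c);
    for (int j = 0; j < k; ++j) {
      const double* src = dP.colptr(c * k + j);
      for (int o = 0; o < out_len; ++o) {
        const int pos = o * stride + j - pad;
        if (pos < 0 || pos >= in_len) continue;
        double* d = dst + pos * n;
        const double* s = src + o * n;
        for (int i = 0; i < n; ++i) d[i] += s[i];
      }
    }
  }
  return dx;
}

static mat forward_pass(const vec& theta, const IntegerMatrix& layout,
                        vec& rstats, const mat& x0, bool training,
                        bool update_stats, std::vector<Cache>* caches) {
  mat cur = x0;
  const int nl = layout.nrow();
  for (int i = 0; i < nl; ++i) {
    const int kind = layout(i, 0);
    if (kind == DENSE) {
      const mat W(const_cast<double*>(theta.memptr()) + layout(i, 8),
                  layout(i, 2), layout(i, 4), false, true);
      const vec b(const_cast<double*>(theta.memptr()) + layout(i, 10),
                  layout(i, 11), false, true);
      if (caches) { Cache cc; cc.a = cur; (*caches)[i] = cc; }
      cur = cur * W;
      cur.each_row() += b.t();
    } else if (kind == RESHAPE) {
      cur.reshape(cur.n_rows * cur.n_cols / layout(i, 3), layout(i, 3));
    } else if (kind == FLATTEN) {
      const int n = cur.n_rows / layout(i, 2);
      cur.reshape(n, layout(i, 2) * layout(i, 3));
    } else if (kind == CONV) {
      const int n = cur.n_rows / layout(i, 2);
      const mat W(const_cast<double*>(theta.memptr()) + layout(i, 8),
                  layout(i, 5) * layout(i, 3), layout(i, 4), false, true);
      const vec b(const_cast<double*>(theta.memptr()) + layout(i, 10),
                  layout(i, 11), false, true);
      mat P = im2col(cur, layout(i, 5), layout(i, 6), layout(i, 7), n,
                     layout(i, 2), layout(i, 13));
      cur = P * W;
      cur.each_row() += b.t();
      if (caches) { Cache cc; cc.a = std::move(P); (*caches)[i] = cc; }
    } else if (kind == POOL) {
      const int n = cur.n_rows / layout(i, 2);
      const int size = layout(i, 5), stride = layout(i, 6);
      const int out_len = layout(i, 13), C = cur.n_cols;
      mat out(n * out_len, C), arg(n * out_len, C);
      for (int c = 0; c < C; ++c) {
        const double* src = cur.colptr(c);
        double* dst = out.colptr(c);
        double* am = arg.colptr(c);
        for (int o = 0; o < out_len; ++o) {
          for (int ii = 0; ii < n; ++ii) {
            double best = src[o * stride * n + ii];
            int bj = 0;
            for (int j = 1; j < size; ++j) {
              const double v = src[(o * stride + j) * n + ii];
              if (v > best) { best = v; bj = j; }
            }
            dst[o * n + ii] = best;
            am[o * n + ii] = bj;
          }
        }
      }
      if (caches) { Cache cc; cc.b = std::move(arg); (*caches)[i] = cc; }
      cur = out;
    } else if (kind == NORM) {
      const int C = layout(i, 3), soff = layout(i, 12);
      const vec gamma(const_cast<double*>(theta.memptr()) + layout(i, 8),
                      C, false, true);
      const vec beta(const_cast<double*>(theta.memptr()) + layout(i, 10),
                     C, false, true);
      const int m = cur.n_rows;
      arma::rowvec mu, va;
      bool batch_stats = training && m > 1;
      if (batch_stats) {
        mu = arma::mean(cur, 0);
        cur.each_row() -= mu;
        va = arma::sum(arma::square(cur), 0) / m;
        if (update_stats) {
          for (int c = 0; c < C; ++c) {
            rstats[soff + c] = BN_MOMENTUM * rstats[soff + c] +
              (1 - BN_MOMENTUM) * mu[c];
            rstats[soff + C + c] = BN_MOMENTUM * rstats[soff + C + c] +
              (1 - BN_MOMENTUM) * va[c];
          }
        }
      } else {
        mu = rstats.subvec(soff, soff + C - 1).t();
        va = rstats.subvec(soff + C, soff + 2 * C - 1).t();
        cur.each_row() -= mu;
      }
      arma::rowvec invstd = 1.0 / arma::sqrt(va + BN_EPS);
      cur.each_row() %= invstd;  // cur is now xhat
      if (caches) {
        Cache cc;
        cc.b = cur;
        cc.c = invstd.t();
        cc.a = mat(1, 1);
        cc.a(0, 0) = batch_stats ? 1.0 : 0.0;
        (*caches)[i] = cc;
      }
      cur.each_row() %= gamma.t();
      cur.each_row() += beta.t();
    } else if (kind == UPSAMPLE) {
      const int n = cur.n_rows / layout(i, 2);
      const int L = layout(i, 2), f = layout(i, 5), C = cur.n_cols;
      mat out(n * L * f, C);
      for (int c = 0; c < C; ++c) {
        const double* src = cur.colptr(c);
        double* dst = out.colptr(c);
        for (int l = 0; l < L; ++l)
          for (int t = 0; t < f; ++t)
            std::copy(src + l * n, src + (l + 1) * n, dst + (l * f + t) * n);
      }
      cur = out;
    } else if (kind == ACT) {
      mat y = act_apply(cur, layout(i, 1));
      if (caches) {
        Cache cc; cc.a = std::move(cur); cc.b = y; (*caches)[i] = cc;
      }
      cur = std::move(y);
    }
  }
  return cur;
}

// returns gradient wrt the input; fills gtheta at the layout offsets
static mat backward_pass(const vec& theta, const IntegerMatrix& layout,
                         const std::vector<Cache>& caches, mat grad,
                         vec& gtheta, bool param_grads = true) {
  for (int i = layout.nrow() - 1; i >= 0; --i) {
    const int kind = layout(i, 0);
    if (kind == DENSE) {
      const mat W(const_cast<double*>(theta.memptr()) + layout(i, 8),
                  layout(i, 2), layout(i, 4), false, true);
      if (param_grads) {
        mat dW = caches[i].a.t() * grad;
        std::copy(dW.begin(), dW.end(), gtheta.memptr() + layout(i, 8));
        arma::rowvec db = arma::sum(grad, 0);
        std::copy(db.begin(), db.end(), gtheta.memptr() + layout(i, 10));
      }
      grad = grad * W.t();
    } else if (kind == RESHAPE) {
      grad.reshape(grad.n_rows * grad.n_cols / (layout(i, 2) * layout(i, 3)),
                   layout(i, 2) * layout(i, 3));
    } else if (kind == FLATTEN) {
      grad.reshape(grad.n_rows * layout(i, 2), layout(i, 3));
    } else if (kind == CONV) {
      const int n = grad.n_rows / layout(i, 13);
      const mat W(const_cast<double*>(theta.memptr()) + layout(i, 8),
                  layout(i, 5) * layout(i, 3), layout(i, 4), false, true);
      if (param_grads) {
        mat dW = caches[i].a.t() * grad;
        std::copy(dW.begin(), dW.end(), gtheta.memptr() + layout(i, 8));
        arma::rowvec db = arma::sum(grad, 0);
        std::copy(db.begin(), db.end(), gtheta.memptr() + layout(i, 10));
      }
      mat dP = grad * W.t();
      grad = col2im(dP, layout(i, 5), layout(i, 6), layout(i, 7), n,
                    layout(i, 2), layout(i, 13));
    } else if (kind == POOL) {
      const int out_len = layout(i, 13);
      const int n = grad.n_rows / out_len;
      const int size = layout(i, 5), stride = layout(i, 6);
      const int C = grad.n_cols;
      const mat& arg = caches[i].b;
      mat dx(n * layout(i, 2), C, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        const double* g = grad.colptr(c);
        const double* am = arg.colptr(c);
        double* d = dx.colptr(c);
        for (int o = 0; o < out_len; ++o)
          for (int ii = 0; ii < n; ++ii)
            d[(o * stride + (int)am[o * n + ii]) * n + ii] += g[o * n + ii];
      }
      grad = dx;
    } else if (kind == NORM) {
      const int C = layout(i, 3);
      const vec gamma(const_cast<double*>(theta.memptr()) + layout(i, 8),
                      C, false, true);
      const mat& xhat = caches[i].b;
      const vec& invstd = caches[i].c;
      const bool batch_stats = caches[i].a(0, 0) > 0.5;
      const int m = grad.n_rows;
      arma::rowvec dgamma = arma::sum(grad % xhat, 0);
      arma::rowvec dbeta = arma::sum(grad, 0);
      if (param_grads) {
        std::copy(dgamma.begin(), dgamma.end(),
                  gtheta.memptr() + layout(i, 8));
        std::copy(dbeta.begin(), dbeta.end(),
                  gtheta.memptr() + layout(i, 10));
      }
      mat dxhat = grad.each_row() % gamma.t();
      if (batch_stats) {
        arma::rowvec s1 = arma::sum(dxhat, 0) / m;
        arma::rowvec s2 = arma::sum(dxhat % xhat, 0) / m;
        dxhat.each_row() -= s1;
        dxhat -= xhat.each_row() % s2;
      }
      dxhat.each_row() %= invstd.t();
      grad = std::move(dxhat);
    } else if (kind == UPSAMPLE) {
      const int f = layout(i, 5), L = layout(i, 2);
      const int n = grad.n_rows / (L * f);
      const int C = grad.n_cols;
      mat dx(n * L, C, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        const double* g = grad.colptr(c);
        double* d = dx.colptr(c);
        for (int l = 0; l < L; ++l)
          for (int t = 0; t < f; ++t) {
            const double* s = g + (l * f + t) * n;
            for (int ii = 0; ii < n; ++ii) d[l * n + ii] += s[ii];
          }
      }
      grad = dx;
    } else if (kind == ACT) {
      grad = act_grad(grad, caches[i].a, caches[i].b, layout(i, 1));
    }
  }
  return grad;
}

static void adam_inplace(vec& theta, const vec& g, vec& m, vec& v,
                         const vec& wmask, double lr, double l2, double c1,
                         double c2, double beta1, double beta2, double eps) {
  const int nn = theta.n_elem;
  for (int i = 0; i < nn; ++i) {
    const double gv = g[i] + l2 * wmask[i] * theta[i];
    m[i] = beta1 * m[i] + (1 - beta1) * gv;
    v[i] = beta2 * v[i] + (1 - beta2) * gv * gv;
    theta[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// row-wise softmax + cross-entropy against one-hot y; grad wrt logits
static double softmax_ce_grad(const mat& logits, const mat& y, mat& grad,
                              double* acc) {
  mat z = logits.each_col() - arma::max(logits, 1);
  mat e = arma::exp(z);
  mat p = e.each_col() / arma::sum(e, 1);
  double loss = -arma::accu(y % arma::log(p + 1e-12)) / logits.n_rows;
  grad = (p - y) / logits.n_rows;
  if (acc) {
    arma::uvec pred = p.col(0) >= 0.5;
    arma::uvec truth = y.col(0) >= 0.5;
    *acc = arma::mean(arma::conv_to<vec>::from(pred == truth));
  }
  return loss;
}

// ---- exported entry points ---------------------------------------------------

// [[Rcpp::export(name = ".nn_fwd")]]
List nn_fwd_cpp(const arma::vec& theta, const IntegerMatrix& layout,
                const arma::vec& rstats, const arma::mat& x, bool training,
                bool update_stats, bool want_caches) {
  vec rs = rstats;
  if (!want_caches) {
    mat out = forward_pass(theta, layout, rs, x, training, update_stats,
                           nullptr);
    return List::create(_["out"] = out, _["rstats"] = rs);
  }
  std::vector<Cache> caches(layout.nrow());
  mat out = forward_pass(theta, layout, rs, x, training, update_stats,
                         &caches);
  List cl(layout.nrow());
  for (int i = 0; i < layout.nrow(); ++i) {
    cl[i] = List::create(_["a"] = caches[i].a, _["b"] = caches[i].b,
                         _["c"] = caches[i].c);
  }
  return List::create(_["out"] = out, _["rstats"] = rs, _["caches"] = cl);
}

// [[Rcpp::export(name = ".nn_bwd")]]
List nn_bwd_cpp(const arma::vec& theta, const IntegerMatrix& layout,
                const List& caches, const arma::mat& grad) {
  std::vector<Cache> cc(layout.nrow());
  for (int i = 0; i < layout.nrow(); ++i) {
    List li = caches[i];
    cc[i].a = as<mat>(li["a"]);
    cc[i].b = as<mat>(li["b"]);
    cc[i].c = as<vec>(li["c"]);
  }
  vec gtheta(theta.n_elem, arma::fill::zeros);
  mat gin = backward_pass(theta, layout, cc, grad, gtheta);
  return List::create(_["gtheta"] = gtheta, _["grad_in"] = gin);
}

// [[Rcpp::export(name = ".nn_adam")]]
List nn_adam_cpp(const arma::vec& theta, const arma::vec& g,
                 const arma::vec& m, const arma::vec& v,
                 const arma::vec& wmask, double lr, double l2, double c1,
                 double c2, double beta1, double beta2, double eps) {
  vec th = theta, m2 = m, v2 = v;
  adam_inplace(th, g, m2, v2, wmask, lr, l2, c1, c2, beta1, beta2, eps);
  return List::create(_["theta"] = th, _["m"] = m2, _["v"] = v2);
}

// one fused classifier/discriminator update on a prepared batch
// [[Rcpp::export(name = ".nn_train_step")]]
List nn_train_step(const arma::vec& theta, const IntegerMatrix& layout,
                   const arma::vec& rstats, const arma::vec& m,
                   const arma::vec& v, const arma::vec& wmask,
                   const arma::mat& x, const arma::mat& y, double lr,
                   double l2, double c1, double c2) {
  vec th = theta, rs = rstats, m2 = m, v2 = v;
  std::vector<Cache> caches(layout.nrow());
  mat out = forward_pass(th, layout, rs, x, true, true, &caches);
  mat grad;
  double acc = 0;
  double loss = softmax_ce_grad(out, y, grad, &acc);
  vec gtheta(th.n_elem, arma::fill::zeros);
  backward_pass(th, layout, caches, grad, gtheta);
  adam_inplace(th, gtheta, m2, v2, wmask, lr, l2, c1, c2, 0.9, 0.999, 1e-8);
  return List::create(_["theta"] = th, _["m"] = m2, _["v"] = v2,
                      _["rstats"] = rs, _["loss"] = loss, _["acc"] = acc);
}

// one fused generator update through a frozen discriminator: z -> G ->
// (mask) -> (join condition) -> D -> cross-entropy against the real class
// [[Rcpp::export(name = ".nn_gen_step")]]
List nn_gen_step(const arma::vec& theta_g, const IntegerMatrix& layout_g,
                 const arma::vec& rstats_g, const arma::vec& m,
                 const arma::vec& v, const arma::vec& wmask_g,
                 const arma::vec& theta_d, const IntegerMatrix& layout_d,
                 const arma::vec& rstats_d, const arma::mat& z,
                 const arma::mat& cond, const arma::vec& mask,
                 const arma::vec& unmask, double lr, double l2, double c1,
                 double c2) {
  vec thg = theta_g, rsg = rstats_g, m2 = m, v2 = v;
  std::vector<Cache> gc(layout_g.nrow());
  mat fake = forward_pass(thg, layout_g, rsg, z, true, true, &gc);
  const bool masked = mask.n_elem == fake.n_cols;
  if (masked) {
    fake.each_row() %= unmask.t();
    fake.each_row() += mask.t();
  }
  mat xd = cond.n_cols > 0 ? arma::join_rows(fake, cond) : fake;
  vec rsd = rstats_d;  // frozen D: running stats not persisted
  std::vector<Cache> dc(layout_d.nrow());
  mat out = forward_pass(theta_d, layout_d, rsd, xd, true, false, &dc);
  mat y(out.n_rows, out.n_cols, arma::fill::zeros);
  y.col(0).ones();  // positive (real) labels on generated samples
  mat grad;
  double loss = softmax_ce_grad(out, y, grad, nullptr);
  vec gdummy;
  mat gin = backward_pass(theta_d, layout_d, dc, grad, gdummy, false);
  mat gfake = gin.cols(0, fake.n_cols - 1);
  if (masked) gfake.each_row() %= unmask.t();
  vec gtheta(thg.n_elem, arma::fill::zeros);
  backward_pass(thg, layout_g, gc, gfake, gtheta);
  adam_inplace(thg, gtheta, m2, v2, wmask_g, lr, l2, c1, c2, 0.9, 0.999,
               1e-8);
  return List::create(_["theta"] = thg, _["m"] = m2, _["v"] = v2,
                      _["rstats"] = rsg, _["loss"] = loss);
}
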