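// 1D convolutional autoencoder engine: forward/backward passes, Adam training
// loop with checkpointing, batched inference, and the ensemble fitness kernel.
// Feature maps are stored as (batch*len) x channels matrices; because every
// sample in a batch has the same (even) length, within-sample row parity equals
// global row parity, so pooling/upsampling are plain strided row indexing.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Spec {
  std::vector<int> filters;  // encoder ladder, last entry = bottleneck
  int kernel;                // odd, same padding
  bool skips;                // U-Net style encoder->decoder concatenation
  int input_len;
};

Spec parse_spec(const Rcpp::List& s) {
  Spec sp;
  Rcpp::IntegerVector f = s["encoder_filters"];
  sp.filters = std::vector<int>(f.begin(), f.end());
  sp.kernel = Rcpp::as<int>(s["kernel_size"]);
  sp.skips = Rcpp::as<bool>(s["skip_connections"]);
  sp.input_len = Rcpp::as<int>(s["input_len"]);
  if (sp.kernel % 2 != 1) Rcpp::stop("kernel_size must be odd");
  return sp;
}

void parse_weights(const Rcpp::List& wl, std::vector<mat>& W,
                   std::vector<rowvec>& b) {
  int n = wl.size();
  W.resize(n);
  b.resize(n);
  for (int i = 0; i < n; ++i) {
    Rcpp::List li = wl[i];
    W[i] = Rcpp::as<mat>(li["W"]);
    b[i] = Rcpp::as<rowvec>(li["b"]);
  }
}

Rcpp::List wrap_weights(const std::vector<mat>& W,
                        const std::vector<rowvec>& b) {
  Rcpp::List out(W.size());
  for (size_t i = 0; i < W.size(); ++i)
    out[i] = Rcpp::List::create(Rcpp::Named("W") = W[i],
                                Rcpp::Named("b") = b[i]);
  return out;
}

// zero-padded shifted copies; sample boundaries respected per block of `len` rows
mat im2col(const mat& X, int B, int len, int k) {
  int ch = X.n_cols, p = k / 2;
  mat Xc(X.n_rows, (size_t)k * ch, fill::zeros);
  for (int o = -p; o <= p; ++o) {
    int cb = (o + p) * ch;
    int u0 = std::max(0, -o), u1 = len - 1 - std::max(0, o);
    if (u1 < u0) continue;
    for (int bi = 0; bi < B; ++bi) {
      Xc.submat(bi * len + u0, cb, bi * len + u1, cb + ch - 1) =
          X.rows(bi * len + u0 + o, bi * len + u1 + o);
    }
  }
  return Xc;
}

mat col2im(const mat& dXc, int B, int len, int k, int ch) {
  int p = k / 2;
  mat dX(dXc.n_rows, ch, fill::zeros);
  for (int o = -p; o <= p; ++o) {
    int cb = (o + p) * ch;
    int u0 = std::max(0, -o), u1 = len - 1 - std::max(0, o);
    if (u1 < u0) continue;
    for (int bi = 0; bi < B; ++bi) {
      dX.rows(bi * len + u0 + o, bi * len + u1 + o) +=
          dXc.submat(bi * len + u0, cb, bi * len + u1, cb + ch - 1);
    }
  }
  return dX;
}

uvec stride2(int nrow, int start) {
  return regspace<uvec>(start, 2, nrow - 1);
}

mat maxpool2(const mat& X, umat& mask) {
  uvec ev = stride2(X.n_rows, 0), od = stride2(X.n_rows, 1);
  mat A = X.rows(ev), Bm = X.rows(od);
  mask = conv_to<umat>::from(A >= Bm);
  return max(A, Bm);
}

mat maxpool2_back(const mat& dY, const umat& mask) {
  mat dX(dY.n_rows * 2, dY.n_cols, fill::zeros);
  uvec ev = stride2(dX.n_rows, 0), od = stride2(dX.n_rows, 1);
  mat m = conv_to<mat>::from(mask);
  dX.rows(ev) = dY % m;
  dX.rows(od) = dY % (1.0 - m);
  return dX;
}

mat up2(const mat& X) {
  mat Y(X.n_rows * 2, X.n_cols);
  uvec ev = stride2(Y.n_rows, 0), od = stride2(Y.n_rows, 1);
  Y.rows(ev) = X;
  Y.rows(od) = X;
  return Y;
}

mat up2_back(const mat& dY) {
  uvec ev = stride2(dY.n_rows, 0), od = stride2(dY.n_rows, 1);
  return dY.rows(ev) + dY.rows(od);
}

inline void relu_inplace(mat& A) {
  A.transform([](double x) { return x > 0.0 ? x : 0.0; });
}

struct Ctx {
  std::vector<mat> conv_in;
  std::vector<mat> conv_out;  // post-activation
  std::vector<int> conv_len;
  std::vector<umat> pool_mask;
  std::vector<mat> skips;
};

// X0: (B*input_len) x 1 stacked single-channel input
mat forward(const Spec& sp, const std::vector<mat>& W,
            const std::vector<rowvec>& b, const mat& X0, int B, Ctx* ctx) {
  int L = (int)sp.filters.size();
  int len = sp.input_len;
  int li = 0;
  mat A = X0;
  std::vector<mat> skips(L - 1);
  for (int i = 0; i < L; ++i) {
    if (ctx) { ctx->conv_in.push_back(A); ctx->conv_len.push_back(len); }
    mat Xc = im2col(A, B, len, sp.kernel);
    A = Xc * W[li];
    A.each_row() += b[li];
    relu_inplace(A);
    if (ctx) ctx->conv_out.push_back(A);
    ++li;
    if (i < L - 1) {
      skips[i] = A;
      umat mask;
      A = maxpool2(A, mask);
      len /= 2;
      if (ctx) ctx->pool_mask.push_back(mask);
    }
  }
  for (int i = L - 2; i >= 0; --i) {
    A = up2(A);
    len *= 2;
    if (sp.skips) A = join_rows(A, skips[i]);
    if (ctx) { ctx->conv_in.push_back(A); ctx->conv_len.push_back(len); }
    mat Xc = im2col(A, B, len, sp.kernel);
    A = Xc * W[li];
    A.each_row() += b[li];
    relu_inplace(A);
    if (ctx) ctx->conv_out.push_back(A);
    ++li;
  }
  if (ctx) { ctx->conv_in.push_back(A); ctx->conv_len.push_back(len); }
  mat Xc = im2col(A, B, len, sp.kernel);
  A = Xc * W[li];
  A.each_row() += b[li];  // linear output head
  if (ctx) {
    ctx->conv_out.push_back(A);
    ctx->skips = skips;
  }
  return A;
}

void backward(const Spec& sp, const std::vector<mat>& W, Ctx& ctx,
              const mat& dOut, int B, std::vector<mat>& dW,
              std::vector<rowvec>& db) {
  int L = (int)sp.filters.size();
  int nlayers = 2 * L;
  dW.resize(nlayers);
  db.resize(nlayers);
  int li = nlayers - 1;
  mat dA = dOut;
  {  // linear output conv
    mat Xc = im2col(ctx.conv_in[li], B, ctx.conv_len[li], sp.kernel);
    dW[li] = Xc.t() * dA;
    db[li] = sum(dA, 0);
    dA = col2im(dA * W[li].t(), B, ctx.conv_len[li], sp.kernel,
                ctx.conv_in[li].n_cols);
  }
  std::vector<mat> skip_grad(L - 1);
  for (int i = 0; i <= L - 2; ++i) {  // decoder convs, level 0 upward
    int ld = nlayers - 2 - i;
    dA %= conv_to<mat>::from(ctx.conv_out[ld] > 0);
    mat Xc = im2col(ctx.conv_in[ld], B, ctx.conv_len[ld], sp.kernel);
    dW[ld] = Xc.t() * dA;
    db[ld] = sum(dA, 0);
    mat dIn = col2im(dA * W[ld].t(), B, ctx.conv_len[ld], sp.kernel,
                     ctx.conv_in[ld].n_cols);
    if (sp.skips) {
      int ch_up = sp.filters[i + 1];
      skip_grad[i] = dIn.cols(ch_up, dIn.n_cols - 1);
      dIn = dIn.cols(0, ch_up - 1);
    }
    dA = up2_back(dIn);
  }
  for (int i = L - 1; i >= 0; --i) {  // encoder convs
    if (i < L - 1) {
      dA = maxpool2_back(dA, ctx.pool_mask[i]);
      if (sp.skips) dA += skip_grad[i];
    }
    dA %= conv_to<mat>::from(ctx.conv_out[i] > 0);
    mat Xc = im2col(ctx.conv_in[i], B, ctx.conv_len[i], sp.kernel);
    dW[i] = Xc.t() * dA;
    db[i] = sum(dA, 0);
    if (i > 0)
      dA = col2im(dA * W[i].t(), B, ctx.conv_len[i], sp.kernel,
                  ctx.conv_in[i].n_cols);
  }
}

mat stack_rows(const mat& X, const uvec& sel, int len) {
  mat out(sel.n_elem * (size_t)len, 1);
  for (size_t bi = 0; bi < sel.n_elem; ++bi)
    out.submat(bi * len, 0, (bi + 1) * len - 1, 0) = X.row(sel[bi]).t();
  return out;
}

double eval_loss(const Spec& sp, const std::vector<mat>& W,
                 const std::vector<rowvec>& b, const mat& X, const mat& Y,
                 int chunk) {
  int n = X.n_rows, len = sp.input_len;
  double acc = 0.0;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    uvec sel = regspace<uvec>(s, e - 1);
    mat P = forward(sp, W, b, stack_rows(X, sel, len), e - s, nullptr);
    mat T = stack_rows(Y, sel, len);
    acc += accu(square(P - T));
  }
  return acc / ((double)n * len);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_dcae_train(Rcpp::List spec, Rcpp::List weights,
                          const arma::mat& Xtr, const arma::mat& Ytr,
                          const arma::mat& Xval, const arma::mat& Yval,
                          int epochs, int batch_size, double lr, double beta1,
                          double beta2, double eps, bool shuffle, int seed) {
  Spec sp = parse_spec(spec);
  std::vector<mat> W;
  std::vector<rowvec> b;
  parse_weights(weights, W, b);
  int n = Xtr.n_rows, len = sp.input_len;
  if (n < 1) Rcpp::stop("empty training set");
  bool has_val = Xval.n_rows > 0;

  std::vector<mat> mW(W.size()), vW(W.size());
  std::vector<rowvec> mb(b.size()), vb(b.size());
  for (size_t i = 0; i < W.size(); ++i) {
    mW[i].zeros(size(W[i]));
    vW[i].zeros(size(W[i]));
    mb[i].zeros(size(b[i]));
    vb[i].zeros(size(b[i]));
  }

  std::mt19937 rng((uint32_t)seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  mat history(epochs, 2);
  double best_val = datum::inf;
  int best_epoch = 0;
  std::vector<mat> bestW = W;
  std::vector<rowvec> bestb = b;
  long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) {  // explicit Fisher-Yates for cross-compiler determinism
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(rng() % (uint32_t)(i + 1));
        std::swap(idx[i], idx[j]);
      }
    }
    double ep_loss = 0.0;
    long ep_count = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size);
      int B = e - s;
      uvec sel(B);
      for (int i = 0; i < B; ++i) sel[i] = idx[s + i];
      mat X0 = stack_rows(Xtr, sel, len);
      mat T = stack_rows(Ytr, sel, len);
      Ctx ctx;
      mat P = forward(sp, W, b, X0, B, &ctx);
      mat diff = P - T;
      double loss = accu(square(diff)) / diff.n_elem;
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      ep_loss += loss * diff.n_elem;
      ep_count += diff.n_elem;
      mat dOut = (2.0 / diff.n_elem) * diff;
      std::vector<mat> dW;
      std::vector<rowvec> db;
      backward(sp, W, ctx, dOut, B, dW, db);
      ++step;
      double c1 = 1.0 - std::pow(beta1, (double)step);
      double c2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t i = 0; i < W.size(); ++i) {
        mW[i] = beta1 * mW[i] + (1.0 - beta1) * dW[i];
        vW[i] = beta2 * vW[i] + (1.0 - beta2) * square(dW[i]);
        W[i] -= lr * (mW[i] / c1) / (sqrt(vW[i] / c2) + eps);
        mb[i] = beta1 * mb[i] + (1.0 - beta1) * db[i];
        vb[i] = beta2 * vb[i] + (1.0 - beta2) * square(db[i]);
        b[i] -= lr * (mb[i] / c1) / (sqrt(vb[i] / c2) + eps);
      }
    }
    double tr_loss = ep_loss / ep_count;
    double val_loss =
        has_val ? eval_loss(sp, W, b, Xval, Yval, 64) : tr_loss;
    history(ep, 0) = tr_loss;
    history(ep, 1) = val_loss;
    if (val_loss < best_val) {
      best_val = val_loss;
      best_epoch = ep + 1;
      bestW = W;
      bestb = b;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = wrap_weights(bestW, bestb),
      Rcpp::Named("final_weights") = wrap_weights(W, b),
      Rcpp::Named("history") = history,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
arma::mat cpp_dcae_predict(Rcpp::List spec, Rcpp::List weights,
                           const arma::mat& X) {
  Spec sp = parse_spec(spec);
  std::vector<mat> W;
  std::vector<rowvec> b;
  parse_weights(weights, W, b);
  int n = X.n_rows, len = sp.input_len;
  if ((int)X.n_cols != len) Rcpp::stop("input windows must have %d samples", len);
  mat out(n, len);
  int chunk = 64;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    uvec sel = regspace<uvec>(s, e - 1);
    mat P = forward(sp, W, b, stack_rows(X, sel, len), e - s, nullptr);
    for (int bi = 0; bi < e - s; ++bi)
      out.row(s + bi) = P.submat(bi * len, 0, (bi + 1) * len - 1, 0).t();
  }
  return out;
}

// Average the selected members' predicted waveforms, extract per-window
// SBP (max) / DBP (min), return the mean of the two Pearson correlations.
// [[Rcpp::export]]
double cpp_ensemble_fitness(const arma::cube& stack, const arma::uvec& sel1,
                            const arma::vec& ref_sbp,
                            const arma::vec& ref_dbp) {
  if (sel1.n_elem == 0) return -1.0;
  mat avg = stack.slice(sel1[0] - 1);
  for (size_t i = 1; i < sel1.n_elem; ++i) avg += stack.slice(sel1[i] - 1);
  avg /= (double)sel1.n_elem;
  vec sbp = max(avg, 1), dbp = min(avg, 1);
  auto pr = [](const vec& x, const vec& y) -> double {
    vec xc = x - mean(x), yc = y - mean(y);
    double den = std::sqrt(dot(xc, xc) * dot(yc, yc));
    if (den <= 0.0) return datum::nan;
    return dot(xc, yc) / den;
  };
  double r1 = pr(ref_sbp, sbp), r2 = pr(ref_dbp, dbp);
  if (!std::isfinite(r1) || !std::isfinite(r2)) return -1.0;
  return 0.5 * (r1 + r2);
}
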