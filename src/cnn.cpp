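// Minimal CNN engine for the pose regressors: 3x3 convolutions (pad 1,
// configurable stride) via im2col + GEMM, per-channel batch normalization,
// ReLU, fully connected layers, weighted L2/L1 losses and Adam. The network
// layout (channels, strides, ReLU placement, FC widths) comes from R as a
// flat description, so the same engine runs both the coarse and the fine
// regressor at any input size.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

struct NetDesc {
  int in_size;                 // input image side (pixels), square
  std::vector<int> channels;   // output channels per conv layer
  std::vector<int> stride;     // stride per conv layer
  std::vector<int> relu;       // 1 if ReLU follows this conv's BN
  std::vector<int> fc;         // FC widths incl. final output dim
  std::vector<int> hw;         // spatial side after each conv layer
};

static NetDesc make_desc(const List &desc) {
  NetDesc d;
  d.in_size = as<int>(desc["input_size"]);
  d.channels = as<std::vector<int>>(desc["conv_channels"]);
  d.stride = as<std::vector<int>>(desc["conv_stride"]);
  d.relu = as<std::vector<int>>(desc["conv_relu"]);
  d.fc = as<std::vector<int>>(desc["fc_sizes"]);
  int hw = d.in_size;
  for (size_t l = 0; l < d.channels.size(); ++l) {
    hw = (hw + 2 - 3) / d.stride[l] + 1; // 3x3 kernel, pad 1
    d.hw.push_back(hw);
  }
  return d;
}

// Activations are (channels x B*P) with column index b*P + y*W + x.
static mat im2col(const mat &X, int W, int H, int B, int stride, int Wo, int Ho) {
  const int C = X.n_rows, P = W * H, Po = Wo * Ho;
  mat col(C * 9, (size_t)B * Po, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int yo = 0; yo < Ho; ++yo) {
      for (int xo = 0; xo < Wo; ++xo) {
        size_t ci = (size_t)b * Po + (size_t)yo * Wo + xo;
        double *dst = col.colptr(ci);
        for (int ky = 0; ky < 3; ++ky) {
          int yi = yo * stride - 1 + ky;
          if (yi < 0 || yi >= H) continue;
          for (int kx = 0; kx < 3; ++kx) {
            int xi = xo * stride - 1 + kx;
            if (xi < 0 || xi >= W) continue;
            const double *src = X.colptr((size_t)b * P + (size_t)yi * W + xi);
            for (int c = 0; c < C; ++c) dst[c * 9 + ky * 3 + kx] = src[c];
          }
        }
      }
    }
  }
  return col;
}

static mat col2im(const mat &dcol, int C, int W, int H, int B, int stride,
                  int Wo, int Ho) {
  const int P = W * H, Po = Wo * Ho;
  mat dX(C, (size_t)B * P, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int yo = 0; yo < Ho; ++yo) {
      for (int xo = 0; xo < Wo; ++xo) {
        size_t ci = (size_t)b * Po + (size_t)yo * Wo + xo;
        const double *src = dcol.colptr(ci);
        for (int ky = 0; ky < 3; ++ky) {
          int yi = yo * stride - 1 + ky;
          if (yi < 0 || yi >= H) continue;
          for (int kx = 0; kx < 3; ++kx) {
            int xi = xo * stride - 1 + kx;
            if (xi < 0 || xi >= W) continue;
            double *dst = dX.colptr((size_t)b * P + (size_t)yi * W + xi);
            for (int c = 0; c < C; ++c) dst[c] += src[c * 9 + ky * 3 + kx];
          }
        }
      }
    }
  }
  return dX;
}

struct Params {
  // per conv layer: W (Cout x Cin*9), gamma, beta, run_mean, run_var
  std::vector<mat> convW;
  std::vector<vec> gamma, beta, rmean, rvar;
  // per fc layer: W, b
  std::vector<mat> fcW;
  std::vector<vec> fcb;
};

static Params params_from_list(const List &pl, const NetDesc &d) {
  Params p;
  int k = 0;
  for (size_t l = 0; l < d.channels.size(); ++l) {
    p.convW.push_back(as<mat>(pl[k++]));
    p.gamma.push_back(as<vec>(pl[k++]));
    p.beta.push_back(as<vec>(pl[k++]));
    p.rmean.push_back(as<vec>(pl[k++]));
    p.rvar.push_back(as<vec>(pl[k++]));
  }
  for (size_t l = 0; l < d.fc.size(); ++l) {
    p.fcW.push_back(as<mat>(pl[k++]));
    p.fcb.push_back(as<vec>(pl[k++]));
  }
  return p;
}

static List params_to_list(const Params &p, const CharacterVector &names) {
  List out(names.size());
  int k = 0;
  for (size_t l = 0; l < p.convW.size(); ++l) {
    out[k++] = p.convW[l];
    out[k++] = p.gamma[l];
    out[k++] = p.beta[l];
    out[k++] = p.rmean[l];
    out[k++] = p.rvar[l];
  }
  for (size_t l = 0; l < p.fcW.size(); ++l) {
    out[k++] = p.fcW[l];
    out[k++] = p.fcb[l];
  }
  out.attr("names") = names;
  return out;
}

struct Cache {
  std::vector<mat> cols;    // im2col inputs per conv layer
  std::vector<mat> xhat;    // BN normalized pre-activations
  std::vector<vec> mu, var; // batch stats
  std::vector<mat> act;     // post-(BN,ReLU) activations per conv layer
  std::vector<mat> fcin;    // inputs to each FC layer
  mat flat;                 // flattened conv output (C*P x B)
};

// Forward pass over a batch held as (1 x B*P) input rows.
// train = true uses batch statistics and fills the cache.
static mat forward(const Params &p, NetDesc &d, const mat &input, int B,
                   bool train, Cache *cache, Params *running_update) {
  mat X = input;
  int W = d.in_size, H = d.in_size;
  for (size_t l = 0; l < d.channels.size(); ++l) {
    int Wo = d.hw[l], Ho = d.hw[l];
    mat col = im2col(X, W, H, B, d.stride[l], Wo, Ho);
    mat Z = p.convW[l] * col; // (Cout x B*Po)
    vec mu, va;
    if (train) {
      mu = arma::mean(Z, 1);
      va = arma::var(Z, 1 /*ML normalization*/, 1);
    } else {
      mu = p.rmean[l];
      va = p.rvar[l];
    }
    mat xhat = Z.each_col() - mu;
    vec inv_sd = 1.0 / arma::sqrt(va + BN_EPS);
    xhat.each_col() %= inv_sd;
    mat A = xhat.each_col() % p.gamma[l];
    A.each_col() += p.beta[l];
    if (d.relu[l]) A = arma::clamp(A, 0.0, arma::datum::inf);
    if (train && running_update) {
      running_update->rmean[l] = BN_MOMENTUM * running_update->rmean[l] + (1 - BN_MOMENTUM) * mu;
      running_update->rvar[l] = BN_MOMENTUM * running_update->rvar[l] + (1 - BN_MOMENTUM) * va;
    }
    if (cache) {
      cache->cols.push_back(std::move(col));
      cache->xhat.push_back(xhat);
      cache->mu.push_back(mu);
      cache->var.push_back(va);
      cache->act.push_back(A);
    }
    X = cache ? cache->act.back() : A;
    W = Wo; H = Ho;
  }
  // flatten: (C x B*P) -> (C*P x B)
  const int C = d.channels.back(), P = W * H;
  mat F(C * P, B);
  for (int b = 0; b < B; ++b) {
    F.col(b) = arma::vectorise(X.cols((size_t)b * P, (size_t)b * P + P - 1));
  }
  if (cache) cache->flat = F;
  mat Y = F;
  for (size_t l = 0; l < d.fc.size(); ++l) {
    if (cache) cache->fcin.push_back(Y);
    Y = p.fcW[l] * Y;
    Y.each_col() += p.fcb[l];
    if (l + 1 < d.fc.size()) Y = arma::clamp(Y, 0.0, arma::datum::inf);
  }
  return Y; // (out x B)
}

// loss_type 2: sum_k w_k (y-t)^2 ; loss_type 1: sum_k w_k |y-t| ; mean over batch
static double loss_and_grad(const mat &Y, const mat &T, const vec &w,
                            int loss_type, mat &G) {
  mat D = Y - T;
  const double B = Y.n_cols;
  double loss;
  if (loss_type == 2) {
    mat D2 = D % D;
    D2.each_col() %= w;
    loss = arma::accu(D2) / B;
    G = D;
    G.each_col() %= w;
    G *= 2.0 / B;
  } else {
    mat Da = arma::abs(D);
    Da.each_col() %= w;
    loss = arma::accu(Da) / B;
    G = arma::sign(D);
    G.each_col() %= w;
    G *= 1.0 / B;
  }
  return loss;
}

static void backward(const Params &p, NetDesc &d, const Cache &cache,
                     const mat &G0, int B, Params &grad) {
  // FC layers
  mat G = G0;
  for (int l = (int)d.fc.size() - 1; l >= 0; --l) {
    grad.fcW[l] = G * cache.fcin[l].t();
    grad.fcb[l] = arma::sum(G, 1);
    G = p.fcW[l].t() * G;
    if (l > 0) G %= arma::conv_to<mat>::from(cache.fcin[l] > 0);
  }
  // unflatten: (C*P x B) -> (C x B*P)
  const int C = d.channels.back(), P = d.hw.back() * d.hw.back();
  mat dX(C, (size_t)B * P);
  for (int b = 0; b < B; ++b) {
    dX.cols((size_t)b * P, (size_t)b * P + P - 1) =
        arma::reshape(G.col(b), C, P);
  }
  // conv layers
  for (int l = (int)d.channels.size() - 1; l >= 0; --l) {
    if (d.relu[l]) dX %= arma::conv_to<mat>::from(cache.act[l] > 0);
    // BN backward
    const mat &xhat = cache.xhat[l];
    const double n = xhat.n_cols;
    grad.gamma[l] = arma::sum(dX % xhat, 1);
    grad.beta[l] = arma::sum(dX, 1);
    vec inv_sd = 1.0 / arma::sqrt(cache.var[l] + BN_EPS);
    mat dZ = dX.each_col() % p.gamma[l];
    vec m1 = arma::sum(dZ, 1) / n;
    vec m2 = arma::sum(dZ % xhat, 1) / n;
    dZ.each_col() -= m1;
    dZ -= xhat.each_col() % m2;
    dZ.each_col() %= inv_sd;
    grad.convW[l] = dZ * cache.cols[l].t();
    mat dcol = p.convW[l].t() * dZ;
    int Win = (l == 0) ? d.in_size : d.hw[l - 1];
    int Cin = (l == 0) ? 1 : d.channels[l - 1];
    dX = col2im(dcol, Cin, Win, Win, B, d.stride[l], d.hw[l], d.hw[l]);
  }
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<mat *> &ps) {
    for (auto *p : ps) {
      m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<mat *> &ps, const std::vector<mat *> &gs, double lr) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*gs[i]);
      v[i] = b2 * v[i] + (1 - b2) * arma::square(*gs[i]);
      *ps[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

static std::vector<mat *> trainable(Params &p, std::vector<mat> &gholder) {
  (void)gholder;
  std::vector<mat *> out;
  for (size_t l = 0; l < p.convW.size(); ++l) out.push_back(&p.convW[l]);
  for (size_t l = 0; l < p.gamma.size(); ++l) {
    out.push_back(static_cast<mat *>(&p.gamma[l]));
    out.push_back(static_cast<mat *>(&p.beta[l]));
  }
  for (size_t l = 0; l < p.fcW.size(); ++l) {
    out.push_back(&p.fcW[l]);
    out.push_back(static_cast<mat *>(&p.fcb[l]));
  }
  return out;
}

// images: (H*W x N) column-per-image matrices (column-major pixel order
// matching the activation layout x + y*W).
static mat batch_input(const mat &images, const uvec &idx) {
  mat X(1, idx.n_elem * images.n_rows);
  for (size_t b = 0; b < idx.n_elem; ++b) {
    X.cols(b * images.n_rows, (b + 1) * images.n_rows - 1) =
        images.col(idx[b]).t();
  }
  return X;
}

// Re-estimate the BN statistics from data: forward in chunks (normalizing
// each chunk by its own statistics, as during training) while aggregating
// exact first and second moments of the pre-BN activations per layer, then
// store the aggregated mean / variance as the inference statistics.
// [[Rcpp::export(name = ".cnn_calibrate_bn_cpp")]]
List cnn_calibrate_bn_cpp(List params, List desc, const arma::mat &images,
                          int chunk = 256) {
  NetDesc d = make_desc(desc);
  Params p = params_from_list(params, d);
  const int N = images.n_cols;
  const size_t L = d.channels.size();
  std::vector<vec> s1(L), s2(L);
  std::vector<double> cnt(L, 0.0);
  for (size_t l = 0; l < L; ++l) {
    s1[l] = vec(d.channels[l], arma::fill::zeros);
    s2[l] = vec(d.channels[l], arma::fill::zeros);
  }
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = arma::regspace<uvec>(s, e - 1);
    mat X = batch_input(images, idx);
    Cache cache;
    forward(p, d, X, e - s, true, &cache, nullptr);
    for (size_t l = 0; l < L; ++l) {
      // recover raw pre-BN moments from the cached batch stats
      double n = cache.xhat[l].n_cols;
      s1[l] += n * cache.mu[l];
      s2[l] += n * (cache.var[l] + arma::square(cache.mu[l]));
      cnt[l] += n;
    }
  }
  for (size_t l = 0; l < L; ++l) {
    p.rmean[l] = s1[l] / cnt[l];
    p.rvar[l] = s2[l] / cnt[l] - arma::square(p.rmean[l]);
    p.rvar[l] = arma::clamp(p.rvar[l], 0.0, arma::datum::inf);
  }
  return params_to_list(p, params.attr("names"));
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(List params, List desc, const arma::mat &images,
                          int chunk = 256) {
  NetDesc d = make_desc(desc);
  Params p = params_from_list(params, d);
  const int N = images.n_cols;
  mat out;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = arma::regspace<uvec>(s, e - 1);
    mat X = batch_input(images, idx);
    mat Y = forward(p, d, X, e - s, false, nullptr, nullptr);
    out = out.n_cols ? arma::join_rows(out, Y) : Y;
  }
  return out;
}

// Loss under training-mode normalization (each chunk normalized by its own
// batch statistics); diagnostic for batch-norm behaviour.
// [[Rcpp::export(name = ".cnn_loss_batchmode_cpp")]]
double cnn_loss_batchmode_cpp(List params, List desc, const arma::mat &images,
                              const arma::mat &targets, const arma::vec &weights,
                              int loss_type, int chunk = 64) {
  NetDesc d = make_desc(desc);
  Params p = params_from_list(params, d);
  const int N = images.n_cols;
  double tot = 0.0;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    uvec idx = arma::regspace<uvec>(s, e - 1);
    mat X = batch_input(images, idx);
    Cache cache;
    mat Y = forward(p, d, X, e - s, true, &cache, nullptr);
    mat G;
    tot += (e - s) * loss_and_grad(Y, targets.cols(idx), weights, loss_type, G);
  }
  return tot / N;
}

// [[Rcpp::export(name = ".cnn_loss_cpp")]]
double cnn_loss_cpp(List params, List desc, const arma::mat &images,
                    const arma::mat &targets, const arma::vec &weights,
                    int loss_type) {
  mat Y = cnn_forward_cpp(params, desc, images);
  mat G;
  return loss_and_grad(Y, targets, weights, loss_type, G);
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(List params, List desc, const arma::mat &images,
                   const arma::mat &targets, const arma::mat &val_images,
                   const arma::mat &val_targets, const arma::vec &weights,
                   int loss_type, const arma::vec &lr_per_epoch,
                   int batch_size, int epochs, int batches_per_epoch,
                   bool verbose) {
  NetDesc d = make_desc(desc);
  Params p = params_from_list(params, d);
  Params best = p;
  Params grad = p; // same shapes
  const int N = images.n_cols;
  const bool has_val = val_images.n_cols > 0;

  std::vector<mat> dummy;
  std::vector<mat *> ps = trainable(p, dummy);
  Adam adam;
  adam.init(ps);

  NumericVector tr_hist(epochs), va_hist(epochs);
  double best_val = arma::datum::inf;

  for (int ep = 0; ep < epochs; ++ep) {
    const double lr = lr_per_epoch[std::min<arma::uword>(ep, lr_per_epoch.n_elem - 1)];
    double ep_loss = 0.0;
    for (int it = 0; it < batches_per_epoch; ++it) {
      IntegerVector draw = Rcpp::sample(N, std::min(batch_size, N), false);
      uvec idx(draw.size());
      for (int k = 0; k < draw.size(); ++k) idx[k] = draw[k] - 1;
      mat X = batch_input(images, idx);
      Cache cache;
      mat Y = forward(p, d, X, idx.n_elem, true, &cache, &p);
      mat T = targets.cols(idx);
      mat G;
      double loss = loss_and_grad(Y, T, weights, loss_type, G);
      if (!std::isfinite(loss)) stop("training diverged: non-finite loss at epoch %d", ep + 1);
      backward(p, d, cache, G, idx.n_elem, grad);
      std::vector<mat *> gs = trainable(grad, dummy);
      adam.step(ps, gs, lr);
      ep_loss += loss;
    }
    ep_loss /= batches_per_epoch;
    tr_hist[ep] = ep_loss;
    double vl = NA_REAL;
    if (has_val) {
      vl = cnn_loss_cpp(params_to_list(p, params.attr("names")), desc,
                        val_images, val_targets, weights, loss_type);
      if (vl < best_val) { best_val = vl; best = p; }
    } else {
      best = p;
    }
    va_hist[ep] = vl;
    if (verbose) Rprintf("epoch %3d  train %.5f  val %s\n", ep + 1, ep_loss,
                         has_val ? std::to_string(vl).c_str() : "-");
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["params"] = params_to_list(has_val ? best : p, params.attr("names")),
      _["final_params"] = params_to_list(p, params.attr("names")),
      _["train_loss"] = tr_hist, _["val_loss"] = va_hist,
      _["best_val"] = has_val ? best_val : NA_REAL);
}

// ---- incremental training session (online augmentation support) ----
// The R side owns the batch loop (so augmentation can happen in R with the
// same code the dataset builder uses); Adam state lives here.

struct Session {
  NetDesc d;
  Params p;
  Adam adam;
  CharacterVector names;
};

// [[Rcpp::export(name = ".cnn_session_new")]]
SEXP cnn_session_new(List params, List desc) {
  Session *s = new Session();
  s->d = make_desc(desc);
  s->p = params_from_list(params, s->d);
  s->names = params.attr("names");
  std::vector<mat> dummy;
  std::vector<mat *> ps = trainable(s->p, dummy);
  s->adam.init(ps);
  Rcpp::XPtr<Session> ptr(s, true);
  return ptr;
}

// images: (P x B) one column per image; targets: (out x B)
// [[Rcpp::export(name = ".cnn_session_step")]]
double cnn_session_step(SEXP sess, const arma::mat &images,
                        const arma::mat &targets, const arma::vec &weights,
                        int loss_type, double lr) {
  Rcpp::XPtr<Session> s(sess);
  const int B = images.n_cols;
  uvec idx = arma::regspace<uvec>(0, B - 1);
  mat X = batch_input(images, idx);
  Cache cache;
  mat Y = forward(s->p, s->d, X, B, true, &cache, &s->p);
  mat G;
  double loss = loss_and_grad(Y, targets, weights, loss_type, G);
  if (!std::isfinite(loss)) stop("training diverged: non-finite loss");
  Params grad = s->p;
  backward(s->p, s->d, cache, G, B, grad);
  std::vector<mat> dummy;
  std::vector<mat *> ps = trainable(s->p, dummy);
  std::vector<mat *> gs = trainable(grad, dummy);
  s->adam.step(ps, gs, lr);
  return loss;
}

// [[Rcpp::export(name = ".cnn_session_params")]]
List cnn_session_params(SEXP sess) {
  Rcpp::XPtr<Session> s(sess);
  return params_to_list(s->p, s->names);
}
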