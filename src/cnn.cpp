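// Minimal CNN engine: stacked valid-mode conv2d + LeakyReLU blocks, flatten,
// batch normalization, dense + dropout, dense + softmax, trained with Adam on
// categorical cross-entropy. Deterministic under a seed (own mt19937,
// single-threaded).
//
// Layer activations are stored batched: A_l is (C_l, N * P_l) where P_l =
// h_l * w_l and the spatial position index is pos = j * h + i (row fastest),
// so im2col reads and one GEMM per layer serve the whole minibatch.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvSpec {
  int f, kh, kw, sh, sw;   // filters, kernel, stride
  int in_c, ih, iw, oh, ow;
};

struct Params {
  std::vector<mat> convW;  // (F, C*kh*kw)
  std::vector<vec> convB;
  vec gamma, beta, run_mean, run_var;
  mat W1; vec b1;
  mat W2; vec b2;
};

struct Config {
  std::vector<ConvSpec> blocks;
  double slope;
  int dense_units;
  double dropout;
  double lr;
  int batch, epochs;
  int n_classes;
  double bn_eps = 1e-5;
  double bn_momentum = 0.9;
};

std::vector<ConvSpec> infer_shapes(const Rcpp::IntegerVector& filters,
                                   const Rcpp::IntegerMatrix& kernels,
                                   const Rcpp::IntegerMatrix& strides,
                                   int G, int K) {
  std::vector<ConvSpec> out;
  int h = G, w = K, c = 1;
  for (int b = 0; b < filters.size(); ++b) {
    ConvSpec s;
    s.f = filters[b];
    s.kh = kernels(b, 0); s.kw = kernels(b, 1);
    s.sh = strides(b, 0); s.sw = strides(b, 1);
    s.in_c = c; s.ih = h; s.iw = w;
    if (s.kh > h || s.kw > w) {
      Rcpp::stop("conv block %d: kernel (%d, %d) exceeds input shape (%d, %d)",
                 b + 1, s.kh, s.kw, h, w);
    }
    s.oh = (h - s.kh) / s.sh + 1;
    s.ow = (w - s.kw) / s.sw + 1;
    h = s.oh; w = s.ow; c = s.f;
    out.push_back(s);
  }
  return out;
}

// im2col over the whole batch: in (C, N*Pin) -> out (C*kh*kw, N*Pout)
void im2col_batch(const mat& in, const ConvSpec& s, int N, mat& out) {
  int Pin = s.ih * s.iw, Pout = s.oh * s.ow;
  out.set_size(s.in_c * s.kh * s.kw, (uword)N * Pout);
  for (int n = 0; n < N; ++n) {
    const uword in0 = (uword)n * Pin, out0 = (uword)n * Pout;
    for (int j = 0; j < s.ow; ++j) {
      for (int i = 0; i < s.oh; ++i) {
        const uword col = out0 + (uword)j * s.oh + i;
        uword r = 0;
        for (int c = 0; c < s.in_c; ++c)
          for (int kj = 0; kj < s.kw; ++kj)
            for (int ki = 0; ki < s.kh; ++ki)
              out(r++, col) = in(c, in0 + (uword)(j * s.sw + kj) * s.ih
                                        + (i * s.sh + ki));
      }
    }
  }
}

// scatter-add transpose of im2col_batch: cols (C*kh*kw, N*Pout) -> din (C, N*Pin)
void col2im_batch(const mat& cols, const ConvSpec& s, int N, mat& din) {
  int Pin = s.ih * s.iw, Pout = s.oh * s.ow;
  din.zeros(s.in_c, (uword)N * Pin);
  for (int n = 0; n < N; ++n) {
    const uword in0 = (uword)n * Pin, out0 = (uword)n * Pout;
    for (int j = 0; j < s.ow; ++j) {
      for (int i = 0; i < s.oh; ++i) {
        const uword col = out0 + (uword)j * s.oh + i;
        uword r = 0;
        for (int c = 0; c < s.in_c; ++c)
          for (int kj = 0; kj < s.kw; ++kj)
            for (int ki = 0; ki < s.kh; ++ki)
              din(c, in0 + (uword)(j * s.sw + kj) * s.ih + (i * s.sh + ki))
                += cols(r++, col);
      }
    }
  }
}

inline mat leaky(const mat& x, double slope) {
  return arma::max(x, slope * x);
}
inline void leaky_grad_inplace(mat& g, const mat& pre, double slope) {
  for (uword i = 0; i < pre.n_elem; ++i)
    if (pre(i) <= 0) g(i) *= slope;
}

struct BatchCache {
  std::vector<mat> xcol;  // per conv layer
  std::vector<mat> pre;
};

// Build A_0 (1, N*G*K) for the samples in `take` from the (m,1,G,K) array.
mat input_matrix(const Rcpp::NumericVector& feats, int m, int G, int K,
                 const std::vector<int>& take) {
  int N = take.size(), P = G * K;
  mat a0(1, (uword)N * P);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k)
      for (int g = 0; g < G; ++g)
        a0(0, (uword)n * P + (uword)k * G + g) =
          feats[take[n] + (std::size_t)m * (g + (std::size_t)G * k)];
  return a0;
}

// Forward through the conv stack; returns flattened features Xf (D, N).
mat conv_forward(const mat& a0, int N, const Config& cfg, const Params& p,
                 BatchCache* cache) {
  mat act = a0;
  mat xcol;
  for (size_t b = 0; b < cfg.blocks.size(); ++b) {
    const ConvSpec& s = cfg.blocks[b];
    im2col_batch(act, s, N, xcol);
    mat pre = p.convW[b] * xcol;
    pre.each_col() += p.convB[b];
    if (cache) { cache->xcol.push_back(xcol); cache->pre.push_back(pre); }
    act = leaky(pre, cfg.slope);
  }
  // flatten: sample n's vector = (pos varies fastest, then channel)
  const ConvSpec& last = cfg.blocks.back();
  int P = last.oh * last.ow, C = last.f;
  mat Xf(C * P, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < P; ++q)
        Xf((uword)c * P + q, n) = act(c, (uword)n * P + q);
  return Xf;
}

// Backward through the conv stack from dXf (D, N); accumulates dW/db.
void conv_backward(const mat& dXf, int N, const Config& cfg, const Params& p,
                   const BatchCache& cache,
                   std::vector<mat>& dW, std::vector<vec>& db) {
  int B = cfg.blocks.size();
  const ConvSpec& last = cfg.blocks[B - 1];
  int P = last.oh * last.ow, C = last.f;
  mat dact(C, (uword)N * P);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < P; ++q)
        dact(c, (uword)n * P + q) = dXf((uword)c * P + q, n);
  for (int b = B - 1; b >= 0; --b) {
    const ConvSpec& s = cfg.blocks[b];
    leaky_grad_inplace(dact, cache.pre[b], cfg.slope);  // dact -> dpre
    dW[b] = dact * cache.xcol[b].t();
    db[b] = sum(dact, 1);
    if (b > 0) {
      mat dcols = p.convW[b].t() * dact;
      col2im_batch(dcols, s, N, dact);
    }
  }
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mB, vB;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void add_mat(const mat& shape) {
    mW.push_back(zeros<mat>(shape.n_rows, shape.n_cols));
    vW.push_back(zeros<mat>(shape.n_rows, shape.n_cols));
  }
  void add_vec(const vec& shape) {
    mB.push_back(zeros<vec>(shape.n_elem));
    vB.push_back(zeros<vec>(shape.n_elem));
  }
  void step_mat(int i, mat& w, const mat& g, double lr) {
    mW[i] = b1 * mW[i] + (1 - b1) * g;
    vW[i] = b2 * vW[i] + (1 - b2) * (g % g);
    mat mh = mW[i] / (1 - std::pow(b1, t));
    mat vh = vW[i] / (1 - std::pow(b2, t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void step_vec(int i, vec& w, const vec& g, double lr) {
    mB[i] = b1 * mB[i] + (1 - b1) * g;
    vB[i] = b2 * vB[i] + (1 - b2) * (g % g);
    vec mh = mB[i] / (1 - std::pow(b1, t));
    vec vh = vB[i] / (1 - std::pow(b2, t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
};

mat softmax_cols(mat z) {
  for (uword j = 0; j < z.n_cols; ++j) {
    z.col(j) -= z.col(j).max();
    z.col(j) = exp(z.col(j));
    z.col(j) /= accu(z.col(j));
  }
  return z;
}

Params init_params(const Config& cfg, int D, std::mt19937& rng) {
  Params p;
  std::normal_distribution<double> N(0.0, 1.0);
  auto he_mat = [&](int rows, int cols, int fan_in) {
    mat w(rows, cols);
    double sd = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = N(rng) * sd;
    return w;
  };
  for (const ConvSpec& s : cfg.blocks) {
    int fan_in = s.in_c * s.kh * s.kw;
    p.convW.push_back(he_mat(s.f, fan_in, fan_in));
    p.convB.push_back(zeros<vec>(s.f));
  }
  p.gamma = ones<vec>(D);
  p.beta = zeros<vec>(D);
  p.run_mean = zeros<vec>(D);
  p.run_var = ones<vec>(D);
  p.W1 = he_mat(cfg.dense_units, D, D);
  p.b1 = zeros<vec>(cfg.dense_units);
  p.W2 = he_mat(cfg.n_classes, cfg.dense_units, cfg.dense_units);
  p.b2 = zeros<vec>(cfg.n_classes);
  return p;
}

Config read_config(const Rcpp::List& conf, int G, int K) {
  Config cfg;
  cfg.blocks = infer_shapes(conf["filters"], conf["kernels"], conf["strides"], G, K);
  cfg.slope = Rcpp::as<double>(conf["leaky_slope"]);
  cfg.dense_units = Rcpp::as<int>(conf["dense_units"]);
  cfg.dropout = Rcpp::as<double>(conf["dropout_rate"]);
  cfg.lr = Rcpp::as<double>(conf["learning_rate"]);
  cfg.batch = Rcpp::as<int>(conf["batch_size"]);
  cfg.epochs = Rcpp::as<int>(conf["epochs"]);
  cfg.n_classes = Rcpp::as<int>(conf["n_classes"]);
  return cfg;
}

Params read_params(const Rcpp::List& fit) {
  Params p;
  Rcpp::List cw = fit["conv_w"], cb = fit["conv_b"];
  for (int b = 0; b < cw.size(); ++b) {
    p.convW.push_back(Rcpp::as<mat>(cw[b]));
    p.convB.push_back(Rcpp::as<vec>(cb[b]));
  }
  p.gamma = Rcpp::as<vec>(fit["gamma"]);
  p.beta = Rcpp::as<vec>(fit["beta"]);
  p.run_mean = Rcpp::as<vec>(fit["run_mean"]);
  p.run_var = Rcpp::as<vec>(fit["run_var"]);
  p.W1 = Rcpp::as<mat>(fit["W1"]);
  p.b1 = Rcpp::as<vec>(fit["b1"]);
  p.W2 = Rcpp::as<mat>(fit["W2"]);
  p.b2 = Rcpp::as<vec>(fit["b2"]);
  return p;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::NumericVector features, Rcpp::IntegerVector labels,
                         Rcpp::List conf, int seed) {
  Rcpp::IntegerVector dims = features.attr("dim");
  int m = dims[0], G = dims[2], K = dims[3];
  Config cfg = read_config(conf, G, K);
  const ConvSpec& last = cfg.blocks.back();
  int D = last.oh * last.ow * last.f;

  std::mt19937 rng(seed);
  Params p = init_params(cfg, D, rng);

  Adam adam;
  for (const mat& w : p.convW) adam.add_mat(w);
  adam.add_mat(p.W1); adam.add_mat(p.W2);
  for (const vec& b : p.convB) adam.add_vec(b);
  adam.add_vec(p.b1); adam.add_vec(p.b2);
  adam.add_vec(p.gamma); adam.add_vec(p.beta);
  int nconv = p.convW.size();

  int batch = std::min(cfg.batch, m);
  double keep = 1.0 - cfg.dropout;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::vector<double> history;

  for (int epoch = 0; epoch < cfg.epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < m; start += batch) {
      int N = std::min(batch, m - start);
      std::vector<int> take(idx.begin() + start, idx.begin() + start + N);
      // forward: conv stack
      BatchCache cache;
      mat a0 = input_matrix(features, m, G, K, take);
      mat Xf = conv_forward(a0, N, cfg, p, &cache);
      // batch norm (training: batch statistics)
      vec mu = mean(Xf, 1);
      mat centered = Xf.each_col() - mu;
      vec var = mean(centered % centered, 1);
      vec inv_sd = 1.0 / sqrt(var + cfg.bn_eps);
      mat xhat = centered.each_col() % inv_sd;
      mat Y = xhat.each_col() % p.gamma;
      Y.each_col() += p.beta;
      p.run_mean = cfg.bn_momentum * p.run_mean + (1 - cfg.bn_momentum) * mu;
      p.run_var = cfg.bn_momentum * p.run_var + (1 - cfg.bn_momentum) * var;
      // dense 1 + LeakyReLU + dropout
      mat Z1 = p.W1 * Y;
      Z1.each_col() += p.b1;
      mat A1 = leaky(Z1, cfg.slope);
      mat mask(A1.n_rows, A1.n_cols, fill::ones);
      if (cfg.dropout > 0) {
        for (uword i = 0; i < mask.n_elem; ++i)
          mask(i) = (U(rng) < keep) ? 1.0 / keep : 0.0;
      }
      mat A1d = A1 % mask;
      // dense 2 + softmax + cross-entropy
      mat Z2 = p.W2 * A1d;
      Z2.each_col() += p.b2;
      mat P = softmax_cols(Z2);
      double loss = 0.0;
      for (int n = 0; n < N; ++n)
        loss -= std::log(std::max(P(labels[take[n]], n), 1e-12));
      loss /= N;
      epoch_loss += loss;
      ++n_batches;
      // backward
      mat dZ2 = P;
      for (int n = 0; n < N; ++n) dZ2(labels[take[n]], n) -= 1.0;
      dZ2 /= N;
      mat dW2 = dZ2 * A1d.t();
      vec db2 = sum(dZ2, 1);
      mat dA1 = (p.W2.t() * dZ2) % mask;
      leaky_grad_inplace(dA1, Z1, cfg.slope);  // dA1 -> dZ1
      mat dW1 = dA1 * Y.t();
      vec db1 = sum(dA1, 1);
      mat dY = p.W1.t() * dA1;
      // batch-norm backward
      vec dgamma = sum(dY % xhat, 1);
      vec dbeta = sum(dY, 1);
      mat dxhat = dY.each_col() % p.gamma;
      vec sum_dxhat = sum(dxhat, 1);
      vec sum_dxhat_xhat = sum(dxhat % xhat, 1);
      mat dXf = dxhat * (double)N;
      dXf.each_col() -= sum_dxhat;
      dXf -= xhat.each_col() % sum_dxhat_xhat;
      dXf.each_col() %= inv_sd / (double)N;
      // conv stack backward
      std::vector<mat> dWc(nconv);
      std::vector<vec> dbc(nconv);
      conv_backward(dXf, N, cfg, p, cache, dWc, dbc);
      // Adam update
      adam.t += 1;
      for (int b = 0; b < nconv; ++b) {
        adam.step_mat(b, p.convW[b], dWc[b], cfg.lr);
        adam.step_vec(b, p.convB[b], dbc[b], cfg.lr);
      }
      adam.step_mat(nconv, p.W1, dW1, cfg.lr);
      adam.step_mat(nconv + 1, p.W2, dW2, cfg.lr);
      adam.step_vec(nconv, p.b1, db1, cfg.lr);
      adam.step_vec(nconv + 1, p.b2, db2, cfg.lr);
      adam.step_vec(nconv + 2, p.gamma, dgamma, cfg.lr);
      adam.step_vec(nconv + 3, p.beta, dbeta, cfg.lr);
    }
    history.push_back(epoch_loss / n_batches);
  }

  Rcpp::List cw(nconv), cb(nconv);
  for (int b = 0; b < nconv; ++b) {
    cw[b] = Rcpp::wrap(p.convW[b]);
    cb[b] = Rcpp::wrap(p.convB[b]);
  }
  return Rcpp::List::create(
    Rcpp::Named("conv_w") = cw,
    Rcpp::Named("conv_b") = cb,
    Rcpp::Named("gamma") = p.gamma,
    Rcpp::Named("beta") = p.beta,
    Rcpp::Named("run_mean") = p.run_mean,
    Rcpp::Named("run_var") = p.run_var,
    Rcpp::Named("W1") = p.W1,
    Rcpp::Named("b1") = p.b1,
    Rcpp::Named("W2") = p.W2,
    Rcpp::Named("b2") = p.b2,
    Rcpp::Named("history") = history
  );
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_cnn_predict(Rcpp::List fit, Rcpp::NumericVector features,
                                    Rcpp::List conf) {
  Rcpp::IntegerVector dims = features.attr("dim");
  int m = dims[0], G = dims[2], K = dims[3];
  Config cfg = read_config(conf, G, K);
  Params p = read_params(fit);
  const ConvSpec& last = cfg.blocks.back();
  int D = last.oh * last.ow * last.f;
  if ((int)p.gamma.n_elem != D) {
    Rcpp::stop("feature shape (%d, %d) does not match the trained model (flatten dim %d vs %d)",
               G, K, D, (int)p.gamma.n_elem);
  }
  std::vector<int> take(m);
  for (int i = 0; i < m; ++i) take[i] = i;
  mat a0 = input_matrix(features, m, G, K, take);
  mat Xf = conv_forward(a0, m, cfg, p, nullptr);
  vec inv_sd = 1.0 / sqrt(p.run_var + cfg.bn_eps);
  mat Y = Xf.each_col() - p.run_mean;
  Y.each_col() %= inv_sd % p.gamma;
  Y.each_col() += p.beta;
  mat Z1 = p.W1 * Y;
  Z1.each_col() += p.b1;
  mat A1 = leaky(Z1, cfg.slope);
  mat Z2 = p.W2 * A1;
  Z2.each_col() += p.b2;
  mat P = softmax_cols(Z2);
  Rcpp::NumericMatrix out(m, cfg.n_classes);
  for (int s = 0; s < m; ++s)
    for (int c = 0; c < cfg.n_classes; ++c) out(s, c) = P(c, s);
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_cnn_shapes(Rcpp::IntegerVector filters,
                                   Rcpp::IntegerMatrix kernels,
                                   Rcpp::IntegerMatrix strides,
                                   int G, int K) {
  std::vector<ConvSpec> blocks = infer_shapes(filters, kernels, strides, G, K);
  Rcpp::IntegerMatrix out(blocks.size(), 3);
  for (size_t b = 0; b < blocks.size(); ++b) {
    out(b, 0) = blocks[b].oh;
    out(b, 1) = blocks[b].ow;
    out(b, 2) = blocks[b].f;
  }
  Rcpp::colnames(out) = Rcpp::CharacterVector::create("height", "width", "channels");
  return out;
}
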