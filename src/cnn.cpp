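// Embedding-initialised 1D convolutional network: forward pass, backprop and
// RMSprop training. Layout: token indices -> embedding lookup ->
// 3 x [conv(width 3, relu) -> maxpool(2) -> dropout] -> dense(relu) x2 ->
// dense(1, sigmoid). Convolutions use "valid" padding and are computed as
// im2col + GEMM over the whole minibatch.
//
// Activations for a batch of B samples with sequence length L and C channels
// are stored as a (B*L) x C matrix, sample-major (row b*L + t).
// All randomness (shuffling, dropout) draws from R's RNG, so training is
// reproducible under set.seed() and single-threaded by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double BCE_EPS = 1e-7;

struct Conv { arma::mat W; arma::rowvec b; };
struct Dense { arma::mat W; arma::rowvec b; };

struct Net {
  arma::mat E;                 // vocab x dim
  std::vector<Conv> conv;      // weight (k*C_in) x C_out
  std::vector<Dense> dense;    // last one has 1 output unit
  int kernel, pool;
};

Net unpack(const List& params) {
  Net net;
  net.E = as<arma::mat>(params["E"]);
  net.kernel = as<int>(params["kernel"]);
  net.pool = as<int>(params["pool"]);
  List cw = params["conv_W"], cb = params["conv_b"];
  for (int i = 0; i < cw.size(); ++i) {
    Conv c; c.W = as<arma::mat>(cw[i]); c.b = as<arma::rowvec>(cb[i]);
    net.conv.push_back(c);
  }
  List dw = params["dense_W"], db = params["dense_b"];
  for (int i = 0; i < dw.size(); ++i) {
    Dense d; d.W = as<arma::mat>(dw[i]); d.b = as<arma::rowvec>(db[i]);
    net.dense.push_back(d);
  }
  return net;
}

List pack(const Net& net) {
  List cw(net.conv.size()), cb(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i) { cw[i] = net.conv[i].W; cb[i] = net.conv[i].b; }
  List dw(net.dense.size()), db(net.dense.size());
  for (size_t i = 0; i < net.dense.size(); ++i) { dw[i] = net.dense[i].W; db[i] = net.dense[i].b; }
  return List::create(_["E"] = net.E, _["conv_W"] = cw, _["conv_b"] = cb,
                      _["dense_W"] = dw, _["dense_b"] = db,
                      _["kernel"] = net.kernel, _["pool"] = net.pool);
}

// im2col for kernel k: rows of `out` are sliding windows of `in` flattened.
// in: (B*L) x C, out: (B*(L-k+1)) x (k*C)
arma::mat im2col(const arma::mat& in, int B, int L, int k) {
  int Lo = L - k + 1, C = in.n_cols;
  arma::mat out(B * Lo, k * C);
  arma::uvec idx(B * Lo);
  for (int off = 0; off < k; ++off) {
    arma::uword p = 0;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Lo; ++t) idx(p++) = (arma::uword)(b * L + t + off);
    out.cols(off * C, off * C + C - 1) = in.rows(idx);
  }
  return out;
}

// scatter-add transpose of im2col
arma::mat col2im(const arma::mat& grad, int B, int L, int k) {
  int Lo = L - k + 1, C = grad.n_cols / k;
  arma::mat out(B * L, C, arma::fill::zeros);
  for (int off = 0; off < k; ++off) {
    const arma::mat part = grad.cols(off * C, off * C + C - 1);
    arma::uword p = 0;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < Lo; ++t) out.row(b * L + t + off) += part.row(p++);
  }
  return out;
}

// max pool over `pool` consecutive positions; records the winning offset
arma::mat maxpool(const arma::mat& in, int B, int L, int pool,
                  arma::umat& argmax) {
  int Lo = L / pool, C = in.n_cols;
  arma::mat out(B * Lo, C);
  argmax.set_size(B * Lo, C);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lo; ++t) {
      arma::uword ro = b * Lo + t, ri = b * L + t * pool;
      out.row(ro) = in.row(ri);
      argmax.row(ro).zeros();
      for (int j = 1; j < pool; ++j) {
        for (int c = 0; c < C; ++c) {
          if (in(ri + j, c) > out(ro, c)) { out(ro, c) = in(ri + j, c); argmax(ro, c) = j; }
        }
      }
    }
  }
  return out;
}

arma::mat maxpool_back(const arma::mat& grad, const arma::umat& argmax,
                       int B, int L, int pool) {
  int Lo = L / pool, C = grad.n_cols;
  arma::mat out(B * L, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Lo; ++t) {
      arma::uword ro = b * Lo + t, ri = b * L + t * pool;
      for (int c = 0; c < C; ++c) out(ri + argmax(ro, c), c) = grad(ro, c);
    }
  return out;
}

arma::mat dropout_mask(int n, int m, double rate) {
  arma::mat mask(n, m);
  double keep = 1.0 - rate;
  for (arma::uword i = 0; i < mask.n_elem; ++i)
    mask(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
  return mask;
}

struct Cache {
  arma::mat M;                        // embedded input (B*L0) x D
  std::vector<arma::mat> P;           // im2col inputs per conv layer
  std::vector<arma::mat> Z;           // conv pre-activations
  std::vector<arma::mat> A;           // conv relu outputs
  std::vector<arma::umat> AM;         // pool argmax
  std::vector<arma::mat> Pool;        // pooled (and possibly dropped) outputs
  std::vector<arma::mat> Mask;        // dropout masks (empty if not training)
  std::vector<int> lenC, lenP;        // conv / pooled lengths
  arma::mat Flat;                     // B x flat
  std::vector<arma::mat> Dz, Da;      // dense pre/post activations
  arma::vec yhat;
};

// forward pass; tokens are 0-based row indices into E
arma::vec forward(const Net& net, const arma::umat& tokens, bool training,
                  double dropout, Cache* cache) {
  int B = tokens.n_rows, L0 = tokens.n_cols, D = net.E.n_cols;
  arma::mat M(B * L0, D);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L0; ++t) M.row(b * L0 + t) = net.E.row(tokens(b, t));

  Cache local;
  Cache& c = cache ? *cache : local;
  c.M = M;
  c.P.clear(); c.Z.clear(); c.A.clear(); c.AM.clear(); c.Pool.clear();
  c.Mask.clear(); c.lenC.clear(); c.lenP.clear(); c.Dz.clear(); c.Da.clear();

  arma::mat cur = M;
  int len = L0;
  for (size_t l = 0; l < net.conv.size(); ++l) {
    arma::mat P = im2col(cur, B, len, net.kernel);
    int lenC = len - net.kernel + 1;
    arma::mat Z = P * net.conv[l].W;
    Z.each_row() += net.conv[l].b;
    arma::mat A = arma::clamp(Z, 0.0, arma::datum::inf);
    arma::umat am;
    int lenP = lenC / net.pool;
    arma::mat pooled = maxpool(A, B, lenC, net.pool, am);
    arma::mat mask;
    if (training && dropout > 0) {
      mask = dropout_mask(pooled.n_rows, pooled.n_cols, dropout);
      pooled %= mask;
    }
    c.P.push_back(P); c.Z.push_back(Z); c.A.push_back(A); c.AM.push_back(am);
    c.Pool.push_back(pooled); c.Mask.push_back(mask);
    c.lenC.push_back(lenC); c.lenP.push_back(lenP);
    cur = pooled; len = lenP;
  }

  // flatten: sample b -> concat of its `len` rows
  int C = cur.n_cols;
  arma::mat flat(B, len * C);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < len; ++t)
      flat(b, arma::span(t * C, t * C + C - 1)) = cur.row(b * len + t);
  c.Flat = flat;

  arma::mat a = flat;
  for (size_t l = 0; l < net.dense.size(); ++l) {
    arma::mat z = a * net.dense[l].W;
    z.each_row() += net.dense[l].b;
    c.Dz.push_back(z);
    if (l + 1 < net.dense.size()) {
      a = arma::clamp(z, 0.0, arma::datum::inf);
    } else {
      a = 1.0 / (1.0 + arma::exp(-z));
    }
    c.Da.push_back(a);
  }
  c.yhat = c.Da.back().col(0);
  return c.yhat;
}

struct Grads {
  arma::mat E;
  std::vector<arma::mat> cW; std::vector<arma::rowvec> cb;
  std::vector<arma::mat> dW; std::vector<arma::rowvec> db;
};

Grads backward(const Net& net, const Cache& c, const arma::umat& tokens,
               const arma::vec& y) {
  int B = tokens.n_rows, L0 = tokens.n_cols;
  Grads g;
  g.cW.resize(net.conv.size()); g.cb.resize(net.conv.size());
  g.dW.resize(net.dense.size()); g.db.resize(net.dense.size());

  // BCE + sigmoid: dL/dz = (yhat - y)/B
  arma::mat delta = (c.yhat - y) / (double)B;
  for (int l = (int)net.dense.size() - 1; l >= 0; --l) {
    const arma::mat& ain = (l == 0) ? c.Flat : c.Da[l - 1];
    g.dW[l] = ain.t() * delta;
    g.db[l] = arma::sum(delta, 0);
    if (l > 0) {
      delta = delta * net.dense[l].W.t();
      delta %= arma::conv_to<arma::mat>::from(c.Dz[l - 1] > 0);
    } else {
      delta = delta * net.dense[l].W.t();  // B x flat
    }
  }

  // un-flatten
  int nl = (int)net.conv.size();
  int lenP = c.lenP[nl - 1], C = c.Pool[nl - 1].n_cols;
  arma::mat dPool(B * lenP, C);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < lenP; ++t)
      dPool.row(b * lenP + t) = delta(b, arma::span(t * C, t * C + C - 1));

  arma::mat dcur = dPool;
  for (int l = nl - 1; l >= 0; --l) {
    if (!c.Mask[l].is_empty()) dcur %= c.Mask[l];
    arma::mat dA = maxpool_back(dcur, c.AM[l], B, c.lenC[l], net.pool);
    dA %= arma::conv_to<arma::mat>::from(c.Z[l] > 0);
    g.cW[l] = c.P[l].t() * dA;
    g.cb[l] = arma::sum(dA, 0);
    arma::mat dP = dA * net.conv[l].W.t();
    int lenIn = (l == 0) ? L0 : c.lenP[l - 1];
    dcur = col2im(dP, B, lenIn, net.kernel);
  }

  // dcur is now d(embedded input): accumulate per token row
  g.E.zeros(net.E.n_rows, net.E.n_cols);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L0; ++t) g.E.row(tokens(b, t)) += dcur.row(b * L0 + t);
  return g;
}

struct RMS {
  arma::mat E;
  std::vector<arma::mat> cW; std::vector<arma::rowvec> cb;
  std::vector<arma::mat> dW; std::vector<arma::rowvec> db;
  void init(const Net& n) {
    E.zeros(n.E.n_rows, n.E.n_cols);
    for (auto& c : n.conv) { cW.push_back(arma::zeros(c.W.n_rows, c.W.n_cols));
                             cb.push_back(arma::zeros<arma::rowvec>(c.b.n_elem)); }
    for (auto& d : n.dense) { dW.push_back(arma::zeros(d.W.n_rows, d.W.n_cols));
                              db.push_back(arma::zeros<arma::rowvec>(d.b.n_elem)); }
  }
};

template <class T>
void rms_step(T& w, T& cache, const T& grad, double lr, double rho, double eps) {
  cache = rho * cache + (1.0 - rho) * arma::square(grad);
  w -= lr * grad / (arma::sqrt(cache) + eps);
}

double bce(const arma::vec& y, const arma::vec& yhat) {
  arma::vec p = arma::clamp(yhat, BCE_EPS, 1.0 - BCE_EPS);
  return arma::mean(-(y % arma::log(p) + (1.0 - y) % arma::log(1.0 - p)));
}

arma::uvec r_permutation(int n) {
  arma::uvec perm = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm(i), perm(j));
  }
  return perm;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(IntegerMatrix tokens, NumericVector labels, List params,
                   int epochs, int batch_size, double lr, double rho,
                   double dropout, bool freeze_embedding) {
  Net net = unpack(params);
  int B = tokens.nrow();
  arma::umat tok(B, tokens.ncol());
  for (int i = 0; i < B; ++i)
    for (int j = 0; j < tokens.ncol(); ++j) tok(i, j) = tokens(i, j) - 1;
  arma::vec y = as<arma::vec>(labels);

  RMS rms; rms.init(net);
  double eps = 1e-7;
  arma::vec history(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    arma::uvec perm = r_permutation(B);
    double loss_sum = 0; int nb = 0;
    for (int start = 0; start < B; start += batch_size) {
      int end = std::min(start + batch_size, B) - 1;
      arma::uvec sel = perm.subvec(start, end);
      arma::umat tb = tok.rows(sel);
      arma::vec yb = y.elem(sel);
      Cache cache;
      arma::vec yhat = forward(net, tb, true, dropout, &cache);
      loss_sum += bce(yb, yhat); ++nb;
      Grads g = backward(net, cache, tb, yb);
      if (!freeze_embedding) rms_step(net.E, rms.E, g.E, lr, rho, eps);
      for (size_t l = 0; l < net.conv.size(); ++l) {
        rms_step(net.conv[l].W, rms.cW[l], g.cW[l], lr, rho, eps);
        rms_step(net.conv[l].b, rms.cb[l], g.cb[l], lr, rho, eps);
      }
      for (size_t l = 0; l < net.dense.size(); ++l) {
        rms_step(net.dense[l].W, rms.dW[l], g.dW[l], lr, rho, eps);
        rms_step(net.dense[l].b, rms.db[l], g.db[l], lr, rho, eps);
      }
    }
    history(ep) = loss_sum / nb;
    if ((ep & 7) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack(net),
                      _["history"] = NumericVector(history.begin(), history.end()));
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(IntegerMatrix tokens, List params, int batch_size) {
  Net net = unpack(params);
  int B = tokens.nrow();
  arma::umat tok(B, tokens.ncol());
  for (int i = 0; i < B; ++i)
    for (int j = 0; j < tokens.ncol(); ++j) tok(i, j) = tokens(i, j) - 1;
  NumericVector out(B);
  for (int start = 0; start < B; start += batch_size) {
    int end = std::min(start + batch_size, B) - 1;
    arma::umat tb = tok.rows(start, end);
    arma::vec yhat = forward(net, tb, false, 0.0, nullptr);
    for (int i = start; i <= end; ++i) out[i] = yhat(i - start);
  }
  return out;
}
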