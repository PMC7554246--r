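// Skip-gram with negative sampling over bigram token sequences.
// Center/context pairs are all ordered pairs within +/- window; tokens equal
// to pad_idx (any bigram containing X) are skipped as both centers and
// contexts. Noise distribution is unigram^0.75 over non-pad tokens.
// Learning rate decays linearly over all processed centers. Uses R's RNG
// throughout, so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 30) return 1.0;
  if (x < -30) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
arma::mat sgns_train_cpp(List seqs, int vocab_size, int pad_idx, int dim,
                         int window, int negative, int epochs, double lr,
                         double min_lr) {
  std::vector<std::vector<int>> corpus;
  corpus.reserve(seqs.size());
  arma::vec counts(vocab_size, arma::fill::zeros);
  long long n_centers = 0;
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector s = seqs[i];
    std::vector<int> v(s.size());
    for (int j = 0; j < s.size(); ++j) {
      v[j] = s[j] - 1;  // to 0-based
      counts(v[j]) += 1.0;
      if (v[j] != pad_idx - 1) ++n_centers;
    }
    corpus.push_back(std::move(v));
  }
  if (n_centers == 0) stop("corpus contains no usable (non-pad) tokens");

  // noise table: cumulative unigram^0.75 over non-pad tokens
  arma::vec noise = arma::pow(counts, 0.75);
  if (pad_idx >= 1) noise(pad_idx - 1) = 0.0;
  arma::vec cum = arma::cumsum(noise);
  double total = cum(vocab_size - 1);
  if (total <= 0) stop("degenerate noise distribution");

  int pad0 = pad_idx - 1;
  arma::mat Win(vocab_size, dim), Wout(vocab_size, dim, arma::fill::zeros);
  for (arma::uword i = 0; i < Win.n_elem; ++i)
    Win(i) = (unif_rand() - 0.5) / dim;
  Win.row(pad0).zeros();  // pad embedding stays at zero during pretraining

  const long long total_centers = (long long)epochs * n_centers;
  long long done = 0;
  arma::rowvec grad_in(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& seq : corpus) {
      int L = (int)seq.size();
      for (int i = 0; i < L; ++i) {
        int center = seq[i];
        if (center == pad0) continue;
        double alpha = lr + (min_lr - lr) * ((double)done / (double)total_centers);
        ++done;
        int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int ctx = seq[j];
          if (ctx == pad0) continue;
          grad_in.zeros();
          // positive pair
          {
            double score = sigmoid(arma::dot(Win.row(center), Wout.row(ctx)));
            double g = alpha * (1.0 - score);
            grad_in += g * Wout.row(ctx);
            Wout.row(ctx) += g * Win.row(center);
          }
          // negative samples
          for (int k = 0; k < negative; ++k) {
            double u = unif_rand() * total;
            int neg = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
            if (neg >= vocab_size) neg = vocab_size - 1;
            if (neg == ctx || neg == pad0) continue;
            double score = sigmoid(arma::dot(Win.row(center), Wout.row(neg)));
            double g = alpha * (0.0 - score);
            grad_in += g * Wout.row(neg);
            Wout.row(neg) += g * Win.row(center);
          }
          Win.row(center) += grad_in;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return Win;
}
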