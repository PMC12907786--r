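// Minibatch Adam trainer for the fully-connected networks (hot loop).
// Mirrors the R-level engine in R/nn.R: ReLU hidden layers, sigmoid or
// identity output, L1 loss, step learning-rate decay, optional Gaussian
// input noise on the leading columns (per-row SNR drawn uniformly in dB),
// lowest-validation-loss checkpointing. The R side owns weight
// initialization and the train/validation split so the data pipeline stays
// seeded from R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  bool sigmoid_out;
};

static arma::mat net_forward(const Net& net, const arma::mat& X,
                             std::vector<arma::mat>* cache) {
  arma::mat H = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    if (cache) (*cache)[l] = H;
    arma::mat Z = H * net.W[l];
    Z.each_row() += net.b[l];
    if (l + 1 < L) H = arma::clamp(Z, 0.0, arma::datum::inf);
    else if (net.sigmoid_out) H = 1.0 / (1.0 + arma::exp(-Z));
    else H = Z;
  }
  return H;
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(Rcpp::List W0, Rcpp::List b0, bool sigmoid_out,
                         const arma::mat& Xt, const arma::mat& Yt,
                         const arma::mat& Xv, const arma::mat& Yv,
                         int epochs, int batch, double lr0, int decay_every,
                         double lr_factor, int noise_cols,
                         double snr_lo, double snr_hi, int seed) {
  Net net;
  const int L = W0.size();
  net.sigmoid_out = sigmoid_out;
  for (int l = 0; l < L; ++l) {
    net.W.push_back(Rcpp::as<arma::mat>(W0[l]));
    net.b.push_back(Rcpp::as<arma::rowvec>(b0[l]));
  }
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  // shuffle order comes from R's RNG (seeded by the caller via set.seed)

  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(net.W[l])); vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(arma::size(net.b[l])); vb[l].zeros(arma::size(net.b[l]));
  }
  long t = 0;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  const arma::uword n = Xt.n_rows;

  // fixed noisy validation inputs (one draw, so epochs are comparable)
  arma::mat Xv_n = Xv;
  if (noise_cols > 0) {
    for (arma::uword i = 0; i < Xv_n.n_rows; ++i) {
      double snr = snr_lo + (snr_hi - snr_lo) * unif(rng);
      double sd = std::pow(10.0, -snr / 20.0);
      for (int j = 0; j < noise_cols; ++j) Xv_n(i, j) += sd * gauss(rng);
    }
  }

  Net best = net;
  double best_val = arma::datum::inf;
  arma::vec tr_hist(epochs), val_hist(epochs);
  std::vector<arma::mat> cache(L);

  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 * std::pow(lr_factor, ep / decay_every);
    arma::uvec ord = arma::randperm(n);
    double tl = 0; int nb = 0;
    for (arma::uword s = 0; s < n; s += batch) {
      arma::uword e = std::min<arma::uword>(s + batch, n) - 1;
      arma::uvec bi = ord.subvec(s, e);
      arma::mat Xb = Xt.rows(bi);
      if (noise_cols > 0) {
        for (arma::uword i = 0; i < Xb.n_rows; ++i) {
          double snr = snr_lo + (snr_hi - snr_lo) * unif(rng);
          double sd = std::pow(10.0, -snr / 20.0);
          for (int j = 0; j < noise_cols; ++j) Xb(i, j) += sd * gauss(rng);
        }
      }
      arma::mat Yb = Yt.rows(bi);
      arma::mat out = net_forward(net, Xb, &cache);
      arma::mat R = out - Yb;
      tl += arma::mean(arma::mean(arma::abs(R))); ++nb;
      arma::mat dZ = arma::sign(R) / double(R.n_elem);
      if (sigmoid_out) dZ %= out % (1.0 - out);
      ++t;
      double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = cache[l].t() * dZ;
        arma::rowvec gb = arma::sum(dZ, 0);
        if (l > 0) {
          arma::mat dH = dZ * net.W[l].t();
          dZ = dH % arma::conv_to<arma::mat>::from(cache[l] > 0);
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
        net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
        net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    arma::mat Vout = net_forward(net, Xv_n, nullptr);
    double vl = arma::mean(arma::mean(arma::abs(Vout - Yv)));
    if (!std::isfinite(vl))
      Rcpp::stop("training diverged (non-finite validation loss)");
    tr_hist(ep) = tl / nb; val_hist(ep) = vl;
    if (vl < best_val) { best_val = vl; best = net; }
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) { Wout[l] = best.W[l]; bout[l] = best.b[l]; }
  return Rcpp::List::create(Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
                            Rcpp::Named("train_loss") = tr_hist,
                            Rcpp::Named("val_loss_hist") = val_hist,
                            Rcpp::Named("val_loss") = best_val);
}

// Plain batched forward pass (prediction hot path).
// [[Rcpp::export]]
arma::mat mlp_forward_cpp(Rcpp::List W0, Rcpp::List b0, bool sigmoid_out,
                          const arma::mat& X) {
  Net net;
  net.sigmoid_out = sigmoid_out;
  for (int l = 0; l < W0.size(); ++l) {
    net.W.push_back(Rcpp::as<arma::mat>(W0[l]));
    net.b.push_back(Rcpp::as<arma::rowvec>(b0[l]));
  }
  return net_forward(net, X, nullptr);
}
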