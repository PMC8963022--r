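// Training loop for the single-hidden-layer ReLU network: minibatch Adam on
// the softmax cross-entropy loss with an L2 penalty. All randomness
// (initial weights, per-epoch shuffles) is generated on the R side from an
// rng_handle and passed in, so results are bit-reproducible under a seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export]]
List mlp_adam_train(const arma::mat& X, const arma::uvec& y_idx, int K,
                    arma::mat W1, arma::rowvec b1, arma::mat W2,
                    arma::rowvec b2, const arma::umat& orders,
                    double lr, double l2, int batch_size, double tol,
                    int patience) {
  const int n = X.n_rows;
  const int epochs = orders.n_cols;
  const int bs = std::min(batch_size, n);

  arma::mat Y(n, K, arma::fill::zeros);
  for (int i = 0; i < n; ++i) Y(i, y_idx(i) - 1) = 1.0;

  arma::mat mW1(arma::size(W1), arma::fill::zeros), vW1 = mW1;
  arma::mat mW2(arma::size(W2), arma::fill::zeros), vW2 = mW2;
  arma::rowvec mb1(arma::size(b1), arma::fill::zeros), vb1 = mb1;
  arma::rowvec mb2(arma::size(b2), arma::fill::zeros), vb2 = mb2;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t_step = 0;
  double best = arma::datum::inf;
  int stall = 0, epochs_run = 0;

  for (int e = 0; e < epochs; ++e) {
    const arma::uvec ord = orders.col(e) - 1;
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += bs) {
      const int stop = std::min(start + bs, n) - 1;
      const arma::uvec idx = ord.subvec(start, stop);
      const arma::mat Xb = X.rows(idx);
      const arma::mat Yb = Y.rows(idx);
      const int nb = Xb.n_rows;

      arma::mat Hpre = Xb * W1;
      Hpre.each_row() += b1;
      const arma::mat H = arma::clamp(Hpre, 0.0, arma::datum::inf);
      arma::mat logits = H * W2;
      logits.each_row() += b2;
      logits.each_col() -= arma::max(logits, 1);
      arma::mat P = arma::exp(logits);
      P.each_col() /= arma::sum(P, 1);

      const double ce = -arma::mean(arma::log(
          arma::clamp(arma::sum(P % Yb, 1), 1e-12, arma::datum::inf)));
      ep_loss += ce + 0.5 * l2 *
        (arma::accu(W1 % W1) + arma::accu(W2 % W2)) / nb;
      ++n_batches;

      const arma::mat dlogits = (P - Yb) / nb;
      const arma::mat gW2 = H.t() * dlogits + l2 * W2 / nb;
      const arma::rowvec gb2 = arma::sum(dlogits, 0);
      arma::mat dH = dlogits * W2.t();
      dH.elem(arma::find(Hpre <= 0)).zeros();
      const arma::mat gW1 = Xb.t() * dH + l2 * W1 / nb;
      const arma::rowvec gb1 = arma::sum(dH, 0);

      ++t_step;
      const double c1 = 1.0 - std::pow(beta1, (double)t_step);
      const double c2 = 1.0 - std::pow(beta2, (double)t_step);
      mW1 = beta1 * mW1 + (1 - beta1) * gW1;
      vW1 = beta2 * vW1 + (1 - beta2) * (gW1 % gW1);
      W1 -= lr * (mW1 / c1) / (arma::sqrt(vW1 / c2) + eps);
      mb1 = beta1 * mb1 + (1 - beta1) * gb1;
      vb1 = beta2 * vb1 + (1 - beta2) * (gb1 % gb1);
      b1 -= lr * (mb1 / c1) / (arma::sqrt(vb1 / c2) + eps);
      mW2 = beta1 * mW2 + (1 - beta1) * gW2;
      vW2 = beta2 * vW2 + (1 - beta2) * (gW2 % gW2);
      W2 -= lr * (mW2 / c1) / (arma::sqrt(vW2 / c2) + eps);
      mb2 = beta1 * mb2 + (1 - beta1) * gb2;
      vb2 = beta2 * vb2 + (1 - beta2) * (gb2 % gb2);
      b2 -= lr * (mb2 / c1) / (arma::sqrt(vb2 / c2) + eps);
    }
    ep_loss /= n_batches;
    epochs_run = e + 1;
    if (ep_loss < best - tol) {
      best = ep_loss;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2,
                      _["b2"] = b2, _["loss"] = best,
                      _["epochs_run"] = epochs_run);
}
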