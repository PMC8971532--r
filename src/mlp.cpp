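// Multilayer feed-forward network trained with minibatch Adam on an MAE
// loss. Written for single-CPU reproducibility: all randomness (weight
// initialization, epoch shuffling) comes from one std::mt19937 stream
// seeded by the caller, so a fixed seed gives bit-identical training runs.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat forward_all(const arma::mat& X,
                             const std::vector<arma::mat>& W,
                             const std::vector<arma::rowvec>& b) {
  arma::mat A = X;
  for (size_t l = 0; l < W.size(); ++l) {
    A = A * W[l];
    A.each_row() += b[l];
    if (l + 1 < W.size()) A = arma::clamp(A, 0.0, arma::datum::inf); // ReLU
  }
  return A;
}

// MAE per the training loss definition: sum over targets, mean over rows
static double mae_loss(const arma::mat& pred, const arma::mat& Y) {
  return arma::accu(arma::abs(pred - Y)) / pred.n_rows;
}

// fused Adam step: one pass over parameters, moments and gradient
template <typename T>
static inline void adam_core(T& w, T& m, T& v, const double* g, double lr,
                             double beta1, double beta2, double c1, double c2,
                             double eps) {
  double* wp = w.memptr();
  double* mp = m.memptr();
  double* vp = v.memptr();
  const arma::uword n = w.n_elem;
  for (arma::uword e = 0; e < n; ++e) {
    const double ge = g[e];
    mp[e] = beta1 * mp[e] + (1.0 - beta1) * ge;
    vp[e] = beta2 * vp[e] + (1.0 - beta2) * ge * ge;
    wp[e] -= lr * (mp[e] / c1) / (std::sqrt(vp[e] / c2) + eps);
  }
}

static inline void adam_update(arma::mat& w, arma::mat& m, arma::mat& v,
                               const double* g, double lr, double beta1,
                               double beta2, double c1, double c2,
                               double eps) {
  adam_core(w, m, v, g, lr, beta1, beta2, c1, c2, eps);
}

static inline void adam_update_row(arma::rowvec& w, arma::rowvec& m,
                                   arma::rowvec& v, const double* g,
                                   double lr, double beta1, double beta2,
                                   double c1, double c2, double eps) {
  adam_core(w, m, v, g, lr, beta1, beta2, c1, c2, eps);
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                   const arma::mat& Xval, const arma::mat& Yval,
                   const arma::ivec& hidden, double lr, int batch_size,
                   int epochs, int seed) {
  const arma::uword n = X.n_rows;
  std::vector<arma::uword> dims;
  dims.push_back(X.n_cols);
  for (arma::uword i = 0; i < hidden.n_elem; ++i) dims.push_back(hidden[i]);
  dims.push_back(Y.n_cols);
  const size_t L = dims.size() - 1;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<arma::mat> W(L), mW(L), vW(L), bestW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L), bestb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l].set_size(dims[l], dims[l + 1]);
    const double sd = std::sqrt(2.0 / dims[l]);      // He initialization
    for (arma::uword j = 0; j < W[l].n_elem; ++j) W[l](j) = sd * gauss(rng);
    b[l] = arma::rowvec(dims[l + 1], arma::fill::zeros);
    mW[l] = arma::mat(dims[l], dims[l + 1], arma::fill::zeros);
    vW[l] = mW[l];
    mb[l] = arma::rowvec(dims[l + 1], arma::fill::zeros);
    vb[l] = mb[l];
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  arma::vec train_hist(epochs), val_hist(epochs);
  double best_val = arma::datum::inf;
  int best_epoch = -1;

  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<arma::mat> A(L + 1), Z(L);
  std::vector<arma::mat> gW(L);
  std::vector<arma::rowvec> gb(L);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    arma::uword nb = 0;
    for (arma::uword start = 0; start < n; start += batch_size, ++nb) {
      const arma::uword stop = std::min<arma::uword>(start + batch_size, n) - 1;
      arma::uvec take(stop - start + 1);
      for (arma::uword i = 0; i <= stop - start; ++i) take[i] = idx[start + i];
      A[0] = X.rows(take);
      const arma::mat Yb = Y.rows(take);
      for (size_t l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l + 1 < L) ? arma::clamp(Z[l], 0.0, arma::datum::inf)
                               : Z[l];
      }
      const double bl = mae_loss(A[L], Yb);
      ep_loss += bl;
      // d(MAE)/d(pred): sign, averaged over the rows of the batch
      arma::mat delta = arma::sign(A[L] - Yb) / static_cast<double>(Yb.n_rows);
      for (size_t l = L; l-- > 0;) {
        gW[l] = A[l].t() * delta;
        gb[l] = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          // ReLU mask, fused single pass
          double* d = delta.memptr();
          const double* z = Z[l - 1].memptr();
          const arma::uword ne = delta.n_elem;
          for (arma::uword e = 0; e < ne; ++e)
            if (z[e] <= 0.0) d[e] = 0.0;
        }
      }
      ++step;
      const double c1 = 1.0 - std::pow(beta1, (double)step);
      const double c2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t l = 0; l < L; ++l) {
        adam_update(W[l], mW[l], vW[l], gW[l].memptr(), lr, beta1, beta2,
                    c1, c2, eps);
        adam_update_row(b[l], mb[l], vb[l], gb[l].memptr(), lr, beta1, beta2,
                        c1, c2, eps);
      }
    }
    train_hist[ep] = ep_loss / nb;
    const double vl = mae_loss(forward_all(Xval, W, b), Yval);
    val_hist[ep] = vl;
    if (!std::isfinite(vl) || !std::isfinite(train_hist[ep]))
      stop("non-finite loss at epoch %d", ep + 1);
    if (vl < best_val) {           // best-checkpoint early stopping
      best_val = vl;
      best_epoch = ep;
      bestW = W;
      bestb = b;
    }
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = wrap(bestW[l]);
    bout[l] = wrap(arma::vec(bestb[l].t()));
  }
  return List::create(_["weights"] = Wout, _["biases"] = bout,
                      _["train_loss"] = train_hist, _["val_loss"] = val_hist,
                      _["best_epoch"] = best_epoch + 1,
                      _["best_val_loss"] = best_val);
}
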