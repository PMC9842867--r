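// Full-batch Adam training of the consolidate-update graph convolutional
// coordinate regressor. Node features X and consolidated neighbor features
// C = P * X (P the row-normalized off-diagonal balanced adjacency) are fixed
// during training, so they are precomputed in R and passed in. Architecture:
//   X' = X W1^T + C W2^T          (graph layer, no bias)
//   H0 = ReLU(X')
//   H1..H3 = ReLU(H V^T + b)      (three hidden MLP layers)
//   Y  = H3 V4^T + b4             (linear 3-unit output: xyz per node)
// Loss: mean over masked pairs (i<j, CF>0) of (||y_i - y_j|| - d_ij)^2.
// The best-loss parameters seen during training are the returned model.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline arma::mat relu(const arma::mat& x) {
  return x % (x > 0);
}

struct AdamState {
  arma::mat m, v;
  explicit AdamState(const arma::mat& p)
      : m(arma::size(p), arma::fill::zeros),
        v(arma::size(p), arma::fill::zeros) {}
};

inline void adam_step(arma::mat& p, const arma::mat& g, AdamState& s,
                      double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  s.m = b1 * s.m + (1.0 - b1) * g;
  s.v = b2 * s.v + (1.0 - b2) * (g % g);
  arma::mat mhat = s.m / (1.0 - std::pow(b1, t));
  arma::mat vhat = s.v / (1.0 - std::pow(b2, t));
  p -= lr * mhat / (arma::sqrt(vhat) + eps);
}

arma::mat glorot(int rows, int cols, std::mt19937& rng) {
  double limit = std::sqrt(6.0 / (rows + cols));
  std::uniform_real_distribution<double> unif(-limit, limit);
  arma::mat w(rows, cols);
  for (int j = 0; j < cols; ++j)
    for (int i = 0; i < rows; ++i)
      w(i, j) = unif(rng);
  return w;
}

}  // namespace

// [[Rcpp::export]]
List train_gcnn_cpp(const arma::mat& X, const arma::mat& C,
                    const arma::umat& pairs, const arma::vec& d,
                    int h1, int h2, int h3,
                    double lr, double tol, int max_epochs,
                    unsigned int seed) {
  const int E = X.n_cols;
  const arma::uword M = pairs.n_rows;
  std::mt19937 rng(seed);

  arma::mat W1 = glorot(E, E, rng), W2 = glorot(E, E, rng);
  arma::mat V1 = glorot(h1, E, rng), V2 = glorot(h2, h1, rng);
  arma::mat V3 = glorot(h3, h2, rng), V4 = glorot(3, h3, rng);
  arma::mat b1(1, h1, arma::fill::zeros), b2(1, h2, arma::fill::zeros);
  arma::mat b3(1, h3, arma::fill::zeros), b4(1, 3, arma::fill::zeros);

  std::vector<arma::mat*> params = {&W1, &W2, &V1, &b1, &V2, &b2,
                                    &V3, &b3, &V4, &b4};
  std::vector<AdamState> adam;
  adam.reserve(params.size());
  for (auto* p : params) adam.emplace_back(*p);

  std::vector<arma::mat> best;
  for (auto* p : params) best.push_back(*p);
  double best_loss = arma::datum::inf;
  int best_epoch = 0;

  arma::vec loss_hist(max_epochs);
  bool converged = false;
  int epochs_run = 0;
  for (int ep = 1; ep <= max_epochs; ++ep) {
    // forward
    arma::mat Xp = X * W1.t() + C * W2.t();
    arma::mat H0 = relu(Xp);
    arma::mat Z1 = H0 * V1.t(); Z1.each_row() += b1;
    arma::mat H1 = relu(Z1);
    arma::mat Z2 = H1 * V2.t(); Z2.each_row() += b2;
    arma::mat H2 = relu(Z2);
    arma::mat Z3 = H2 * V3.t(); Z3.each_row() += b3;
    arma::mat H3 = relu(Z3);
    arma::mat Y = H3 * V4.t(); Y.each_row() += b4;
    if (!Y.is_finite()) {
      stop("non-finite coordinates during training (epoch %d): "
           "consider a lower learning rate", ep);
    }

    // pairwise-distance loss and its gradient wrt Y
    arma::mat GY(Y.n_rows, 3, arma::fill::zeros);
    double loss = 0.0;
    for (arma::uword m = 0; m < M; ++m) {
      const arma::uword i = pairs(m, 0), j = pairs(m, 1);
      arma::rowvec diff = Y.row(i) - Y.row(j);
      double dist = arma::norm(diff, 2);
      double r = dist - d(m);
      loss += r * r;
      if (dist > 1e-12) {
        arma::rowvec g = (2.0 * r / (static_cast<double>(M) * dist)) * diff;
        GY.row(i) += g;
        GY.row(j) -= g;
      }
    }
    loss /= static_cast<double>(M);
    loss_hist(ep - 1) = loss;
    epochs_run = ep;
    if (loss < best_loss) {
      best_loss = loss;
      best_epoch = ep;
      for (size_t k = 0; k < params.size(); ++k) best[k] = *params[k];
    }
    if (loss < tol) { converged = true; break; }

    // backward
    arma::mat dZ4 = GY;
    arma::mat gV4 = dZ4.t() * H3;
    arma::mat gb4 = arma::sum(dZ4, 0);
    arma::mat dZ3 = (dZ4 * V4) % (Z3 > 0);
    arma::mat gV3 = dZ3.t() * H2;
    arma::mat gb3 = arma::sum(dZ3, 0);
    arma::mat dZ2 = (dZ3 * V3) % (Z2 > 0);
    arma::mat gV2 = dZ2.t() * H1;
    arma::mat gb2 = arma::sum(dZ2, 0);
    arma::mat dZ1 = (dZ2 * V2) % (Z1 > 0);
    arma::mat gV1 = dZ1.t() * H0;
    arma::mat gb1 = arma::sum(dZ1, 0);
    arma::mat dXp = (dZ1 * V1) % (Xp > 0);
    arma::mat gW1 = dXp.t() * X;
    arma::mat gW2 = dXp.t() * C;

    std::vector<arma::mat*> grads = {&gW1, &gW2, &gV1, &gb1, &gV2, &gb2,
                                     &gV3, &gb3, &gV4, &gb4};
    double t = static_cast<double>(ep);
    for (size_t k = 0; k < params.size(); ++k) {
      adam_step(*params[k], *grads[k], adam[k], lr, t);
    }
  }

  return List::create(
      _["W1"] = best[0], _["W2"] = best[1],
      _["V1"] = best[2], _["b1"] = arma::vec(best[3].t()),
      _["V2"] = best[4], _["b2"] = arma::vec(best[5].t()),
      _["V3"] = best[6], _["b3"] = arma::vec(best[7].t()),
      _["V4"] = best[8], _["b4"] = arma::vec(best[9].t()),
      _["loss_history"] = loss_hist.head(epochs_run),
      _["final_loss"] = best_loss,
      _["best_epoch"] = best_epoch,
      _["epochs_run"] = epochs_run,
      _["converged"] = converged);
}
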