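// LINE-style node embedding: edge-sampling SGD with negative sampling.
// Edges are drawn with probability proportional to their weight (alias
// method); negative nodes are drawn from the weighted-degree^{3/4} noise
// distribution. Second-order proximity trains separate context vectors;
// first-order proximity (optional) uses the node vectors themselves as
// context. Single-threaded and fully determined by the seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  void build(const std::vector<double>& w) {
    const int n = static_cast<int>(w.size());
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double v : w) total += v;
    std::vector<double> scaled(n);
    for (int i = 0; i < n; ++i) scaled[i] = w[i] * n / total;
    std::vector<int> small, large;
    for (int i = n - 1; i >= 0; --i) {
      if (scaled[i] < 1.0) small.push_back(i); else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      if (scaled[l] < 1.0) small.push_back(l); else large.push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  int draw(std::mt19937& rng, std::uniform_real_distribution<double>& unif) const {
    const int n = static_cast<int>(prob.size());
    int k = std::min(n - 1, static_cast<int>(unif(rng) * n));
    return unif(rng) < prob[k] ? k : alias[k];
  }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List line_embed_cpp(const IntegerVector& edge_i, const IntegerVector& edge_j,
                    const NumericVector& edge_w, int n_nodes, int e_dim,
                    int epochs, int samples_per_epoch, int negative,
                    double rho0, int order, unsigned int seed) {
  const int n_edges = edge_i.size();
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // directed duplication: each undirected edge contributes both directions
  std::vector<int> src(2 * n_edges), dst(2 * n_edges);
  std::vector<double> ew(2 * n_edges);
  std::vector<double> wdeg(n_nodes, 0.0);
  for (int k = 0; k < n_edges; ++k) {
    src[2 * k] = edge_i[k];     dst[2 * k] = edge_j[k];     ew[2 * k] = edge_w[k];
    src[2 * k + 1] = edge_j[k]; dst[2 * k + 1] = edge_i[k]; ew[2 * k + 1] = edge_w[k];
    wdeg[edge_i[k]] += edge_w[k];
    wdeg[edge_j[k]] += edge_w[k];
  }
  AliasTable edge_tab;
  edge_tab.build(ew);
  std::vector<double> noise(n_nodes);
  for (int i = 0; i < n_nodes; ++i) {
    noise[i] = wdeg[i] > 0 ? std::pow(wdeg[i], 0.75) : 1e-12;
  }
  AliasTable node_tab;
  node_tab.build(noise);

  arma::mat u(n_nodes, e_dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < e_dim; ++k)
      u(i, k) = (unif(rng) - 0.5) / e_dim;
  arma::mat ctx(n_nodes, e_dim, arma::fill::zeros);
  arma::mat& context = (order == 1) ? u : ctx;

  const long total = static_cast<long>(epochs) * samples_per_epoch;
  arma::vec loss_hist(epochs, arma::fill::zeros);
  std::vector<double> err(e_dim);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_acc = 0.0;
    for (int s = 0; s < samples_per_epoch; ++s, ++step) {
      double rho = rho0 * (1.0 - static_cast<double>(step) / total);
      if (rho < rho0 * 1e-4) rho = rho0 * 1e-4;
      int e = edge_tab.draw(rng, unif);
      int vi = src[e], vj = dst[e];
      std::fill(err.begin(), err.end(), 0.0);
      for (int t = 0; t <= negative; ++t) {
        int target;
        double label;
        if (t == 0) { target = vj; label = 1.0; }
        else        { target = node_tab.draw(rng, unif); label = 0.0; }
        double f = 0.0;
        for (int k = 0; k < e_dim; ++k) f += u(vi, k) * context(target, k);
        double sg = sigmoid(f);
        double g = (label - sg) * rho;
        loss_acc += (label > 0.5) ? -std::log(std::max(sg, 1e-12))
                                  : -std::log(std::max(1.0 - sg, 1e-12));
        for (int k = 0; k < e_dim; ++k) {
          err[k] += g * context(target, k);
          context(target, k) += g * u(vi, k);
        }
      }
      for (int k = 0; k < e_dim; ++k) u(vi, k) += err[k];
    }
    loss_hist(ep) = loss_acc / samples_per_epoch;
  }

  return List::create(_["u"] = u,
                      _["context"] = (order == 1) ? u : ctx,
                      _["loss"] = loss_hist);
}
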