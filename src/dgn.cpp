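// Training engine for the edge-weighted GIN surrogate.
//
// The forward pass mirrors the R-level ops (embed_vertices, gin_layer,
// readout); here it is paired with exact reverse-mode gradients, an Adam
// optimizer on the mean-absolute-error loss, and patience-based early
// stopping on the validation MAE. All randomness (epoch shuffling) comes
// from one std::mt19937_64 seeded by the caller, so runs are reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Params {
  std::vector<arma::mat> W;   // W[0]: in_dim x K, W[l]: K x K
  std::vector<arma::rowvec> b;
  arma::vec eps;              // L-1 scalars
  double ws, wn;
  arma::vec wout;             // K * L

  Params zeros_like() const {
    Params g;
    g.W.reserve(W.size());
    g.b.reserve(b.size());
    for (const auto& w : W) g.W.push_back(arma::zeros<arma::mat>(w.n_rows, w.n_cols));
    for (const auto& bb : b) g.b.push_back(arma::zeros<arma::rowvec>(bb.n_elem));
    g.eps = arma::zeros<arma::vec>(eps.n_elem);
    g.ws = 0.0; g.wn = 0.0;
    g.wout = arma::zeros<arma::vec>(wout.n_elem);
    return g;
  }
};

struct Adam {
  Params m, v;
  double beta1 = 0.9, beta2 = 0.999, epshat = 1e-8, lr;
  long t = 0;

  Adam(const Params& p, double lr_) : m(p.zeros_like()), v(p.zeros_like()), lr(lr_) {}

  template <typename T>
  void upd(T& theta, T& mm, T& vv, const T& g) {
    mm = beta1 * mm + (1.0 - beta1) * g;
    vv = beta2 * vv + (1.0 - beta2) * (g % g);
    T mhat = mm / (1.0 - std::pow(beta1, (double)t));
    T vhat = vv / (1.0 - std::pow(beta2, (double)t));
    theta -= lr * mhat / (arma::sqrt(vhat) + epshat);
  }

  void upd_scalar(double& theta, double& mm, double& vv, double g) {
    mm = beta1 * mm + (1.0 - beta1) * g;
    vv = beta2 * vv + (1.0 - beta2) * g * g;
    double mhat = mm / (1.0 - std::pow(beta1, (double)t));
    double vhat = vv / (1.0 - std::pow(beta2, (double)t));
    theta -= lr * mhat / (std::sqrt(vhat) + epshat);
  }

  void step(Params& p, const Params& g) {
    ++t;
    for (size_t l = 0; l < p.W.size(); ++l) {
      upd(p.W[l], m.W[l], v.W[l], g.W[l]);
      upd(p.b[l], m.b[l], v.b[l], g.b[l]);
    }
    if (p.eps.n_elem) upd(p.eps, m.eps, v.eps, g.eps);
    upd_scalar(p.ws, m.ws, v.ws, g.ws);
    upd_scalar(p.wn, m.wn, v.wn, g.wn);
    upd(p.wout, m.wout, v.wout, g.wout);
  }
};

// forward through all layers; fills H (post-ReLU states) and P (layer inputs)
double forward_sample(const arma::mat& Xbase, const arma::sp_mat& A,
                      const arma::uvec& site, const Params& par, int L,
                      std::vector<arma::mat>& H, std::vector<arma::mat>& P,
                      arma::vec& svec) {
  arma::mat X = Xbase;
  for (arma::uword i = 0; i < site.n_elem; ++i) X(site[i], 9) = 1.0;
  const int K = par.W[0].n_cols;
  const arma::uword n = X.n_rows;

  P[0] = X;
  arma::mat Z = X * par.W[0];
  Z.each_row() += par.b[0];
  H[0] = arma::clamp(Z, 0.0, arma::datum::inf);
  for (int l = 1; l < L; ++l) {
    P[l] = (1.0 + par.eps[l - 1]) * H[l - 1] + A * H[l - 1];
    Z = P[l] * par.W[l];
    Z.each_row() += par.b[l];
    H[l] = arma::clamp(Z, 0.0, arma::datum::inf);
  }

  svec.set_size(n);
  svec.fill(par.wn);
  for (arma::uword i = 0; i < site.n_elem; ++i) svec[site[i]] = par.ws;

  double pred = 0.0;
  for (int l = 0; l < L; ++l) {
    const arma::vec wseg = par.wout.subvec(l * K, (l + 1) * K - 1);
    pred += arma::dot(svec, H[l] * wseg);
  }
  return pred;
}

void backward_sample(const arma::sp_mat& A, const arma::uvec& site,
                     const Params& par, int L, double dpred,
                     const std::vector<arma::mat>& H,
                     const std::vector<arma::mat>& P,
                     const arma::vec& svec, Params& grad) {
  const int K = par.W[0].n_cols;
  const arma::uword n = H[0].n_rows;

  arma::uvec is_site(n, arma::fill::zeros);
  for (arma::uword i = 0; i < site.n_elem; ++i) is_site[site[i]] = 1;

  // readout gradients
  std::vector<arma::mat> dH(L);
  double r_site = 0.0, r_non = 0.0;
  for (int l = 0; l < L; ++l) {
    const arma::vec wseg = par.wout.subvec(l * K, (l + 1) * K - 1);
    arma::vec rl = H[l] * wseg;            // per-vertex readout of layer l
    for (arma::uword vtx = 0; vtx < n; ++vtx) {
      if (is_site[vtx]) r_site += rl[vtx]; else r_non += rl[vtx];
    }
    grad.wout.subvec(l * K, (l + 1) * K - 1) += dpred * (H[l].t() * svec);
    dH[l] = dpred * (svec * wseg.t());     // n x K outer product
  }
  grad.ws += dpred * r_site;
  grad.wn += dpred * r_non;

  // backprop through convolutions
  for (int l = L - 1; l >= 1; --l) {
    arma::mat dZ = dH[l] % arma::conv_to<arma::mat>::from(H[l] > 0.0);
    grad.W[l] += P[l].t() * dZ;
    grad.b[l] += arma::sum(dZ, 0);
    arma::mat dP = dZ * par.W[l].t();
    grad.eps[l - 1] += arma::accu(dP % H[l - 1]);
    dH[l - 1] += (1.0 + par.eps[l - 1]) * dP + A * dP;  // A symmetric
  }
  arma::mat dZ0 = dH[0] % arma::conv_to<arma::mat>::from(H[0] > 0.0);
  grad.W[0] += P[0].t() * dZ0;
  grad.b[0] += arma::sum(dZ0, 0);
}

Params params_from_list(const List& weights) {
  Params p;
  List Wl = weights["W"], bl = weights["b"];
  for (int i = 0; i < Wl.size(); ++i) {
    p.W.push_back(as<arma::mat>(Wl[i]));
    p.b.push_back(as<arma::rowvec>(bl[i]));
  }
  p.eps = as<arma::vec>(weights["eps"]);
  p.ws = as<double>(weights["w_site"]);
  p.wn = as<double>(weights["w_nonsite"]);
  p.wout = as<arma::vec>(weights["w_out"]);
  return p;
}

List params_to_list(const Params& p) {
  List Wl(p.W.size()), bl(p.b.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    Wl[i] = wrap(p.W[i]);
    bl[i] = wrap(p.b[i]);
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["eps"] = wrap(p.eps),
                      _["w_site"] = p.ws, _["w_nonsite"] = p.wn,
                      _["w_out"] = wrap(p.wout));
}

arma::sp_mat build_adj(int n, const arma::imat& edges, const arma::vec& w) {
  arma::umat loc(2, 2 * edges.n_rows);
  arma::vec val(2 * edges.n_rows);
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    loc(0, 2 * e) = edges(e, 0); loc(1, 2 * e) = edges(e, 1);
    loc(0, 2 * e + 1) = edges(e, 1); loc(1, 2 * e + 1) = edges(e, 0);
    val[2 * e] = w[e]; val[2 * e + 1] = w[e];
  }
  return arma::sp_mat(loc, val, n, n);
}

std::vector<arma::uvec> sites_from_list(const List& site_list) {
  std::vector<arma::uvec> out;
  out.reserve(site_list.size());
  for (int i = 0; i < site_list.size(); ++i) {
    IntegerVector s = site_list[i];
    arma::uvec u(s.size());
    for (int j = 0; j < s.size(); ++j) u[j] = s[j];
    out.push_back(u);
  }
  return out;
}

double eval_mae(const arma::mat& Xbase, const arma::sp_mat& A,
                const std::vector<arma::uvec>& sites, const arma::vec& y,
                const arma::uvec& idx, const Params& par, int L,
                std::vector<arma::mat>& H, std::vector<arma::mat>& P) {
  double s = 0.0;
  arma::vec svec;
  for (arma::uword i = 0; i < idx.n_elem; ++i) {
    double pred = forward_sample(Xbase, A, sites[idx[i]], par, L, H, P, svec);
    s += std::abs(pred - y[idx[i]]);
  }
  return s / idx.n_elem;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_dgn_predict(const arma::mat& Xbase, const arma::imat& edges,
                              const arma::vec& edge_w, const List& site_list,
                              const List& weights, int L) {
  Params par = params_from_list(weights);
  arma::sp_mat A = build_adj(Xbase.n_rows, edges, edge_w);
  std::vector<arma::uvec> sites = sites_from_list(site_list);
  std::vector<arma::mat> H(L), P(L);
  arma::vec svec;
  NumericVector out(site_list.size());
  for (int i = 0; i < site_list.size(); ++i) {
    out[i] = forward_sample(Xbase, A, sites[i], par, L, H, P, svec);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dgn_train(const arma::mat& Xbase, const arma::imat& edges,
                   const arma::vec& edge_w, const List& site_list,
                   const arma::vec& y, const IntegerVector& train_idx,
                   const IntegerVector& val_idx, const List& init_weights,
                   int L, double lr, int batch_size, int max_epochs,
                   int patience, double seed) {
  Params par = params_from_list(init_weights);
  arma::sp_mat A = build_adj(Xbase.n_rows, edges, edge_w);
  std::vector<arma::uvec> sites = sites_from_list(site_list);
  Adam opt(par, lr);

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  arma::uvec va(val_idx.size());
  for (int i = 0; i < val_idx.size(); ++i) va[i] = val_idx[i];
  arma::uvec tr_eval(tr.size());
  for (size_t i = 0; i < tr.size(); ++i) tr_eval[i] = tr[i];

  std::mt19937_64 rng((unsigned long long)seed);
  std::vector<arma::mat> H(L), P(L);
  arma::vec svec;

  std::vector<double> train_log, val_log;
  double best_val = arma::datum::inf;
  int best_epoch = -1;
  Params best = par;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(tr.begin(), tr.end(), rng);
    for (size_t start = 0; start < tr.size(); start += batch_size) {
      size_t bend = std::min(start + (size_t)batch_size, tr.size());
      Params grad = par.zeros_like();
      double inv_b = 1.0 / (double)(bend - start);
      for (size_t i = start; i < bend; ++i) {
        int s = tr[i];
        double pred = forward_sample(Xbase, A, sites[s], par, L, H, P, svec);
        if (!std::isfinite(pred)) stop("non-finite prediction: training diverged");
        double diff = pred - y[s];
        double dpred = (diff > 0) ? inv_b : (diff < 0 ? -inv_b : 0.0);
        backward_sample(A, sites[s], par, L, dpred, H, P, svec, grad);
      }
      opt.step(par, grad);
    }
    double tr_mae = eval_mae(Xbase, A, sites, y, tr_eval, par, L, H, P);
    double va_mae = va.n_elem ? eval_mae(Xbase, A, sites, y, va, par, L, H, P)
                              : tr_mae;
    if (!std::isfinite(tr_mae) || !std::isfinite(va_mae)) {
      stop("non-finite loss at epoch %d: training diverged", epoch + 1);
    }
    train_log.push_back(tr_mae);
    val_log.push_back(va_mae);
    if (va_mae < best_val) {
      best_val = va_mae;
      best_epoch = epoch;
      best = par;
    }
    if (epoch - best_epoch >= patience) break;
  }

  return List::create(
      _["weights"] = params_to_list(best),
      _["final_weights"] = params_to_list(par),
      _["train_mae"] = wrap(train_log), _["val_mae"] = wrap(val_log),
      _["best_epoch"] = best_epoch + 1, _["best_val_mae"] = best_val,
      _["epochs_run"] = (int)train_log.size());
}
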