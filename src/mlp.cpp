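// Two-arm multilayer perceptron for drug response regression.
//
// The network embeds a cell-feature vector and a drug-fingerprint vector
// through separate stacks of affine+ReLU layers, concatenates the two
// embeddings, passes them through a ReLU head and a final linear unit, and
// is trained by minibatch Adam on mean-squared error with early stopping on
// a validation partition.  All randomness (weight initialization, minibatch
// order) comes from a caller-supplied integer seed through a private
// mt19937 stream, so identical calls are bit-identical.

#include <RcppArmadillo.h>
#include <algorithm>
#include <random>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct Net {
  // layer weights in order: cell arm, drug arm, head, output (last entry)
  std::vector<mat> W;
  std::vector<vec> b;
  int n_cell, n_drug, n_head;  // layer counts per section (output excluded)
};

Net net_from_list(const List& net_in) {
  Net net;
  net.n_cell = as<int>(net_in["n_cell"]);
  net.n_drug = as<int>(net_in["n_drug"]);
  net.n_head = as<int>(net_in["n_head"]);
  List Wl = net_in["W"], bl = net_in["b"];
  for (int i = 0; i < Wl.size(); ++i) {
    net.W.push_back(as<mat>(Wl[i]));
    net.b.push_back(as<vec>(bl[i]));
  }
  return net;
}

List net_to_list(const Net& net) {
  List Wl(net.W.size()), bl(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    Wl[i] = net.W[i];
    bl[i] = net.b[i];
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["n_cell"] = net.n_cell,
                      _["n_drug"] = net.n_drug, _["n_head"] = net.n_head);
}

inline void affine_relu(const mat& W, const vec& b, const mat& X, mat& out,
                        bool relu = true) {
  out = W * X;
  out.each_col() += b;
  if (relu)
    for (double* p = out.memptr(); p != out.memptr() + out.n_elem; ++p)
      if (*p < 0.0) *p = 0.0;
}

// activation workspace reused across minibatches
struct Workspace {
  std::vector<mat> act;   // post-activation of every layer (output last)
  std::vector<mat> delta; // gradients wrt pre-activations
  mat Z;                  // concatenated embeddings
  mat dZ;
};

// forward pass; activations stored in ws.act (n_layers + 1 entries,
// the last being the linear output row)
void forward(const Net& net, const mat& Xc, const mat& Xd, Workspace& ws) {
  int L = (int)net.W.size();
  ws.act.resize(L);
  const mat* in = &Xc;
  for (int i = 0; i < net.n_cell; ++i) {
    affine_relu(net.W[i], net.b[i], *in, ws.act[i]);
    in = &ws.act[i];
  }
  in = &Xd;
  for (int i = net.n_cell; i < net.n_cell + net.n_drug; ++i) {
    affine_relu(net.W[i], net.b[i], *in, ws.act[i]);
    in = &ws.act[i];
  }
  ws.Z = arma::join_cols(ws.act[net.n_cell - 1],
                         ws.act[net.n_cell + net.n_drug - 1]);
  in = &ws.Z;
  for (int i = net.n_cell + net.n_drug; i < L - 1; ++i) {
    affine_relu(net.W[i], net.b[i], *in, ws.act[i]);
    in = &ws.act[i];
  }
  affine_relu(net.W[L - 1], net.b[L - 1], *in, ws.act[L - 1], false);
}

// dz = back where act > 0, else 0
inline void relu_backward(const mat& back, const mat& act, mat& dz) {
  dz.set_size(back.n_rows, back.n_cols);
  const double* a = act.memptr();
  const double* b = back.memptr();
  double* o = dz.memptr();
  for (arma::uword i = 0; i < back.n_elem; ++i) o[i] = a[i] > 0 ? b[i] : 0.0;
}

struct Grads {
  std::vector<mat> W;
  std::vector<vec> b;
};

// backprop one minibatch; returns batch sum of squared errors
double backward(const Net& net, const mat& Xc, const mat& Xd, const vec& y,
                Workspace& ws, Grads& g) {
  int L = (int)net.W.size();
  const double n = (double)y.n_elem;
  vec resid = ws.act[L - 1].row(0).t() - y;
  double sse = arma::dot(resid, resid);

  ws.delta.resize(L);
  ws.delta[L - 1] = (2.0 / n) * resid.t();  // 1 x B

  int first_head = net.n_cell + net.n_drug;
  // head and output layers
  for (int i = L - 1; i > first_head; --i) {
    mat back = net.W[i].t() * ws.delta[i];
    relu_backward(back, ws.act[i - 1], ws.delta[i - 1]);
  }
  {  // gradient into the concatenation
    mat back = net.W[first_head].t() * ws.delta[first_head];
    int cw = net.W[net.n_cell - 1].n_rows;
    // split between the arms, applying each arm's final ReLU mask
    relu_backward(back.rows(0, cw - 1), ws.act[net.n_cell - 1],
                  ws.delta[net.n_cell - 1]);
    relu_backward(back.rows(cw, back.n_rows - 1),
                  ws.act[first_head - 1], ws.delta[first_head - 1]);
  }
  for (int i = net.n_cell - 1; i > 0; --i) {
    mat back = net.W[i].t() * ws.delta[i];
    relu_backward(back, ws.act[i - 1], ws.delta[i - 1]);
  }
  for (int i = first_head - 1; i > net.n_cell; --i) {
    mat back = net.W[i].t() * ws.delta[i];
    relu_backward(back, ws.act[i - 1], ws.delta[i - 1]);
  }

  auto input_of = [&](int i) -> const mat& {
    if (i == 0) return Xc;
    if (i == net.n_cell) return Xd;
    if (i == first_head) return ws.Z;
    return ws.act[i - 1];
  };
  for (int i = 0; i < L; ++i) {
    g.W[i] = ws.delta[i] * input_of(i).t();
    g.b[i] = arma::sum(ws.delta[i], 1);
  }
  return sse;
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Net& net) {
    for (size_t i = 0; i < net.W.size(); ++i) {
      mW.push_back(arma::zeros<mat>(net.W[i].n_rows, net.W[i].n_cols));
      vW.push_back(arma::zeros<mat>(net.W[i].n_rows, net.W[i].n_cols));
      mb.push_back(arma::zeros<vec>(net.b[i].n_elem));
      vb.push_back(arma::zeros<vec>(net.b[i].n_elem));
    }
  }
  inline void update(double* w, double* m, double* v, const double* g,
                     arma::uword n, double lr, double c1, double c2) {
    for (arma::uword k = 0; k < n; ++k) {
      m[k] = b1 * m[k] + (1 - b1) * g[k];
      v[k] = b2 * v[k] + (1 - b2) * g[k] * g[k];
      w[k] -= lr * (m[k] / c1) / (std::sqrt(v[k] / c2) + eps);
    }
  }
  void step(Net& net, const Grads& g, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < net.W.size(); ++i) {
      update(net.W[i].memptr(), mW[i].memptr(), vW[i].memptr(),
             g.W[i].memptr(), net.W[i].n_elem, lr, c1, c2);
      update(net.b[i].memptr(), mb[i].memptr(), vb[i].memptr(),
             g.b[i].memptr(), net.b[i].n_elem, lr, c1, c2);
    }
  }
};

double val_mse(const Net& net, const mat& Xc, const mat& Xd, const vec& y,
               Workspace& ws) {
  forward(net, Xc, Xd, ws);
  vec resid = ws.act[net.W.size() - 1].row(0).t() - y;
  return arma::dot(resid, resid) / y.n_elem;
}

}  // namespace

// [[Rcpp::export(name = ".mlp_init")]]
List mlp_init(int cell_in, int drug_in, IntegerVector cell_widths,
              IntegerVector drug_widths, IntegerVector head_widths, int seed) {
  Net net;
  net.n_cell = cell_widths.size();
  net.n_drug = drug_widths.size();
  net.n_head = head_widths.size();
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  auto add_layer = [&](int nin, int nout) {
    mat W(nout, nin);
    double sd = std::sqrt(2.0 / nin);  // He initialization for ReLU
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = sd * norm(rng);
    net.W.push_back(W);
    net.b.push_back(arma::zeros<vec>(nout));
  };
  int prev = cell_in;
  for (int w : cell_widths) { add_layer(prev, w); prev = w; }
  int cell_out = prev;
  prev = drug_in;
  for (int w : drug_widths) { add_layer(prev, w); prev = w; }
  int drug_out = prev;
  prev = cell_out + drug_out;
  for (int w : head_widths) { add_layer(prev, w); prev = w; }
  add_layer(prev, 1);
  return net_to_list(net);
}

// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train(List net_in, const arma::mat& Xc, const arma::mat& Xd,
               const arma::vec& y, const arma::mat& Xcv, const arma::mat& Xdv,
               const arma::vec& yv, double lr, int batch, int max_epochs,
               int patience, int seed, IntegerVector snapshot_epochs) {
  // X matrices arrive as samples x features; work feature-major
  mat Xct = Xc.t(), Xdt = Xd.t(), Xcvt = Xcv.t(), Xdvt = Xdv.t();
  Net net = net_from_list(net_in);
  Adam adam(net);
  Grads grads;
  grads.W.resize(net.W.size());
  grads.b.resize(net.b.size());
  Workspace ws, ws_val;
  std::mt19937 rng((unsigned)seed + 1u);

  const arma::uword n = y.n_elem;
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  std::set<int> snaps(snapshot_epochs.begin(), snapshot_epochs.end());
  List snapshots;
  std::vector<int> snapshot_at;

  Net best = net;
  double best_val = arma::datum::inf;
  int best_epoch = 0, stale = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_sse = 0.0;
    arma::uword done = 0;
    while (done < n) {
      arma::uword bend = std::min(done + (arma::uword)batch, n);
      arma::uvec idx(bend - done);
      for (arma::uword i = done; i < bend; ++i) idx[i - done] = order[i];
      mat xc = Xct.cols(idx), xd = Xdt.cols(idx);
      forward(net, xc, xd, ws);
      tr_sse += backward(net, xc, xd, y(idx), ws, grads);
      adam.step(net, grads, lr);
      done = bend;
    }
    double tr_loss = tr_sse / n;
    double val_loss = val_mse(net, Xcvt, Xdvt, yv, ws_val);
    if (!std::isfinite(tr_loss) || !std::isfinite(val_loss))
      stop("non-finite loss at epoch %d", epoch);
    tr_hist.push_back(tr_loss);
    val_hist.push_back(val_loss);
    epochs_run = epoch;
    if (snaps.count(epoch)) {
      snapshots.push_back(net_to_list(net));
      snapshot_at.push_back(epoch);
    }
    if (val_loss < best_val) {  // strict: ties keep the earlier epoch
      best_val = val_loss;
      best = net;
      best_epoch = epoch;
      stale = 0;
    } else if (++stale >= patience) {
      break;
    }
  }

  return List::create(
      _["net"] = net_to_list(best), _["best_epoch"] = best_epoch,
      _["train_loss"] = tr_hist, _["val_loss"] = val_hist,
      _["epochs_run"] = epochs_run, _["snapshots"] = snapshots,
      _["snapshot_epochs"] = wrap(snapshot_at));
}

// [[Rcpp::export(name = ".mlp_predict")]]
arma::vec mlp_predict(List net_in, const arma::mat& Xc, const arma::mat& Xd) {
  Net net = net_from_list(net_in);
  Workspace ws;
  forward(net, Xc.t(), Xd.t(), ws);
  return ws.act[net.W.size() - 1].row(0).t();
}

// [[Rcpp::export(name = ".mlp_drug_embed")]]
arma::mat mlp_drug_embed(List net_in, const arma::mat& Xd) {
  Net net = net_from_list(net_in);
  mat A = Xd.t(), out;
  for (int i = net.n_cell; i < net.n_cell + net.n_drug; ++i) {
    affine_relu(net.W[i], net.b[i], A, out);
    A = out;
  }
  return A.t();  // drugs x embedding width
}
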