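// Compiled cores: coupled-Bernoulli raster simulator and the multilayer
// LSTM next-step spike predictor (forward pass, truncated BPTT with focal
// loss, Adam updates, teacher-forced prediction). All randomness comes from
// R's RNG (simulator) or from pre-drawn R inputs (initial weights, window
// shuffles), so results are reproducible with set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------------------
// Simulator: p_j(t) = clip(base_j + sum_i W[i,j] * X[i, t - delay], 0, 1)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List sim_coupled_core(const arma::vec& base, const arma::mat& W,
                            int n_bins, int delay) {
  const int n = base.n_elem;
  Rcpp::IntegerMatrix X(n_bins, n);
  long clipped = 0;
  const bool coupled = any(vectorise(W) != 0.0);
  vec p(n);
  for (int t = 0; t < n_bins; ++t) {
    p = base;
    if (coupled && t >= delay) {
      for (int i = 0; i < n; ++i) {
        if (X(t - delay, i) == 1) p += W.row(i).t();
      }
    }
    for (int j = 0; j < n; ++j) {
      double pj = p(j);
      if (pj < 0.0) { pj = 0.0; ++clipped; }
      else if (pj > 1.0) { pj = 1.0; ++clipped; }
      X(t, j) = (R::unif_rand() < pj) ? 1 : 0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("X") = X,
                            Rcpp::Named("clipped") = (double)clipped);
}

// ---------------------------------------------------------------------------
// LSTM machinery
// ---------------------------------------------------------------------------

struct LSTMLayer {
  mat W;     // in_dim x 4H, gate order [i f g o]
  mat U;     // H x 4H
  rowvec b;  // 1 x 4H
};

struct Net {
  std::vector<LSTMLayer> layers;
  mat V;     // H x n_out
  rowvec c;  // 1 x n_out
  int hidden() const { return layers.back().U.n_rows; }
};

static Net unpack_net(const Rcpp::List& params) {
  Net net;
  Rcpp::List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    Rcpp::List lay = layers[l];
    LSTMLayer L;
    L.W = Rcpp::as<mat>(lay["W"]);
    L.U = Rcpp::as<mat>(lay["U"]);
    L.b = Rcpp::as<rowvec>(lay["b"]);
    net.layers.push_back(L);
  }
  net.V = Rcpp::as<mat>(params["V"]);
  net.c = Rcpp::as<rowvec>(params["c"]);
  return net;
}

static Rcpp::List pack_net(const Net& net) {
  Rcpp::List layers(net.layers.size());
  for (size_t l = 0; l < net.layers.size(); ++l) {
    layers[l] = Rcpp::List::create(
        Rcpp::Named("W") = net.layers[l].W,
        Rcpp::Named("U") = net.layers[l].U,
        Rcpp::Named("b") = net.layers[l].b);
  }
  return Rcpp::List::create(Rcpp::Named("layers") = layers,
                            Rcpp::Named("V") = net.V,
                            Rcpp::Named("c") = net.c);
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static const double P_EPS = 1e-7;  // probability clamp inside the loss

// focal loss per element, pi clamped to [P_EPS, 1 - P_EPS]
static inline double focal_elem(double pi, double y, double gamma) {
  double p = std::min(std::max(pi, P_EPS), 1.0 - P_EPS);
  if (y > 0.5) return -std::pow(1.0 - p, gamma) * std::log(p);
  return -std::pow(p, gamma) * std::log(1.0 - p);
}

// d(loss)/d(logit z) per element (unnormalised)
static inline double focal_dz(double pi, double y, double gamma) {
  double p = std::min(std::max(pi, P_EPS), 1.0 - P_EPS);
  if (y > 0.5)
    return gamma * p * std::pow(1.0 - p, gamma) * std::log(p)
         - std::pow(1.0 - p, gamma + 1.0);
  return -gamma * (1.0 - p) * std::pow(p, gamma) * std::log(1.0 - p)
       + std::pow(p, gamma + 1.0);
}

// Caches for one forward pass of a batch window
struct LayerCache {
  cube I, F, G, O, C, TC, H;  // each B x Hdim x T
};

// Forward pass; fills caches when `keep` is true. Returns mean focal loss.
// Xb, Yb: cubes B x n x T (inputs and next-step targets).
static double forward_batch(const Net& net, const cube& Xb, const cube& Yb,
                            double gamma, std::vector<LayerCache>& caches,
                            bool keep, cube* PI_out) {
  const int B = Xb.n_rows, T = Xb.n_slices;
  const int nL = net.layers.size();
  const int n_out = net.V.n_cols;
  std::vector<mat> h(nL), cc(nL);
  const int Hdim = net.hidden();
  for (int l = 0; l < nL; ++l) {
    h[l] = zeros<mat>(B, Hdim);
    cc[l] = zeros<mat>(B, Hdim);
  }
  if (keep) {
    caches.assign(nL, LayerCache());
    for (int l = 0; l < nL; ++l) {
      caches[l].I.set_size(B, Hdim, T); caches[l].F.set_size(B, Hdim, T);
      caches[l].G.set_size(B, Hdim, T); caches[l].O.set_size(B, Hdim, T);
      caches[l].C.set_size(B, Hdim, T); caches[l].TC.set_size(B, Hdim, T);
      caches[l].H.set_size(B, Hdim, T);
    }
  }
  double loss = 0.0;
  for (int t = 0; t < T; ++t) {
    mat xin = Xb.slice(t);
    for (int l = 0; l < nL; ++l) {
      const LSTMLayer& L = net.layers[l];
      mat A = xin * L.W + h[l] * L.U;
      A.each_row() += L.b;
      mat gi = sigmoid(A.cols(0, Hdim - 1));
      mat gf = sigmoid(A.cols(Hdim, 2 * Hdim - 1));
      mat gg = tanh(A.cols(2 * Hdim, 3 * Hdim - 1));
      mat go = sigmoid(A.cols(3 * Hdim, 4 * Hdim - 1));
      cc[l] = gf % cc[l] + gi % gg;
      mat tc = tanh(cc[l]);
      h[l] = go % tc;
      if (keep) {
        caches[l].I.slice(t) = gi; caches[l].F.slice(t) = gf;
        caches[l].G.slice(t) = gg; caches[l].O.slice(t) = go;
        caches[l].C.slice(t) = cc[l]; caches[l].TC.slice(t) = tc;
        caches[l].H.slice(t) = h[l];
      }
      xin = h[l];
    }
    mat Z = xin * net.V;
    Z.each_row() += net.c;
    mat PI = sigmoid(Z);
    if (PI_out) PI_out->slice(t) = PI;
    const mat& Y = Yb.slice(t);
    for (int bI = 0; bI < B; ++bI)
      for (int j = 0; j < n_out; ++j)
        loss += focal_elem(PI(bI, j), Y(bI, j), gamma);
  }
  return loss / ((double)B * T * n_out);
}

struct Grads {
  std::vector<LSTMLayer> layers;
  mat V;
  rowvec c;
};

static Grads zero_grads(const Net& net) {
  Grads g;
  for (auto& L : net.layers) {
    LSTMLayer z;
    z.W = zeros<mat>(L.W.n_rows, L.W.n_cols);
    z.U = zeros<mat>(L.U.n_rows, L.U.n_cols);
    z.b = zeros<rowvec>(L.b.n_elem);
    g.layers.push_back(z);
  }
  g.V = zeros<mat>(net.V.n_rows, net.V.n_cols);
  g.c = zeros<rowvec>(net.c.n_elem);
  return g;
}

// Forward + BPTT over one batch window; returns mean loss, fills grads.
static double backward_batch(const Net& net, const cube& Xb, const cube& Yb,
                             double gamma, Grads& g) {
  const int B = Xb.n_rows, T = Xb.n_slices;
  const int nL = net.layers.size();
  const int n_out = net.V.n_cols;
  const int Hdim = net.hidden();
  std::vector<LayerCache> caches;
  cube PI(B, n_out, T);
  double loss = forward_batch(net, Xb, Yb, gamma, caches, true, &PI);
  const double scale = 1.0 / ((double)B * T * n_out);

  std::vector<mat> dH_rec(nL, zeros<mat>(B, Hdim));
  std::vector<mat> dC_next(nL, zeros<mat>(B, Hdim));
  for (int t = T - 1; t >= 0; --t) {
    // output layer
    mat dZ(B, n_out);
    const mat& Y = Yb.slice(t);
    const mat& Pt = PI.slice(t);
    for (int bI = 0; bI < B; ++bI)
      for (int j = 0; j < n_out; ++j)
        dZ(bI, j) = scale * focal_dz(Pt(bI, j), Y(bI, j), gamma);
    const mat& Htop = caches[nL - 1].H.slice(t);
    g.V += Htop.t() * dZ;
    g.c += sum(dZ, 0);
    mat dFromAbove = dZ * net.V.t();  // gradient into top layer's h_t
    for (int l = nL - 1; l >= 0; --l) {
      const LSTMLayer& L = net.layers[l];
      LayerCache& ch = caches[l];
      mat dH = dFromAbove + dH_rec[l];
      const mat& gi = ch.I.slice(t); const mat& gf = ch.F.slice(t);
      const mat& gg = ch.G.slice(t); const mat& go = ch.O.slice(t);
      const mat& tc = ch.TC.slice(t);
      mat dC = dC_next[l] + dH % go % (1.0 - tc % tc);
      mat dAo = (dH % tc) % go % (1.0 - go);
      mat dAi = (dC % gg) % gi % (1.0 - gi);
      mat dAg = (dC % gi) % (1.0 - gg % gg);
      mat Cprev = (t > 0) ? ch.C.slice(t - 1) : zeros<mat>(B, Hdim);
      mat dAf = (dC % Cprev) % gf % (1.0 - gf);
      dC_next[l] = dC % gf;
      mat dA = join_rows(join_rows(dAi, dAf), join_rows(dAg, dAo));
      mat xin = (l == 0) ? Xb.slice(t) : caches[l - 1].H.slice(t);
      mat hprev = (t > 0) ? ch.H.slice(t - 1) : zeros<mat>(B, Hdim);
      g.layers[l].W += xin.t() * dA;
      g.layers[l].U += hprev.t() * dA;
      g.layers[l].b += sum(dA, 0);
      dH_rec[l] = dA * L.U.t();
      dFromAbove = dA * L.W.t();  // into layer below's h_t (or input)
    }
  }
  return loss;
}

struct AdamState {
  Grads m, v;
  long t = 0;
};

static void adam_update_mat(mat& p, const mat& g, mat& m, mat& v,
                            double lr_t, double b1, double b2, double eps) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr_t * m / (sqrt(v) + eps);
}

static void adam_update_row(rowvec& p, const rowvec& g, rowvec& m, rowvec& v,
                            double lr_t, double b1, double b2, double eps) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  p -= lr_t * m / (sqrt(v) + eps);
}

static double grad_sq_norm(const Grads& g) {
  double s = accu(g.V % g.V) + accu(g.c % g.c);
  for (auto& L : g.layers)
    s += accu(L.W % L.W) + accu(L.U % L.U) + accu(L.b % L.b);
  return s;
}

static void scale_grads(Grads& g, double f) {
  g.V *= f; g.c *= f;
  for (auto& L : g.layers) { L.W *= f; L.U *= f; L.b *= f; }
}

// Build input/target cubes for a set of window starts (0-based rows of X;
// inputs are rows s .. s+T-1, targets rows s+1 .. s+T).
static void fill_cubes(const mat& X, const ivec& starts, int T,
                       cube& Xb, cube& Yb) {
  const int B = starts.n_elem, n = X.n_cols;
  Xb.set_size(B, n, T);
  Yb.set_size(B, n, T);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t) {
      Xb.slice(t).row(b) = X.row(starts(b) + t);
      Yb.slice(t).row(b) = X.row(starts(b) + t + 1);
    }
  }
}

static double eval_windows(const Net& net, const mat& X, const ivec& starts,
                           int T, int batch, double gamma) {
  if (starts.n_elem == 0) return NA_REAL;
  double loss = 0.0;
  int done = 0;
  std::vector<LayerCache> caches;
  while (done < (int)starts.n_elem) {
    int bsz = std::min<int>(batch, starts.n_elem - done);
    ivec sub = starts.subvec(done, done + bsz - 1);
    cube Xb, Yb;
    fill_cubes(X, sub, T, Xb, Yb);
    loss += forward_batch(net, Xb, Yb, gamma, caches, false, nullptr) * bsz;
    done += bsz;
  }
  return loss / starts.n_elem;
}

// Mean focal loss over a set of windows; used for validation and testing.
// [[Rcpp::export]]
double lstm_loss_core(Rcpp::List params, const arma::mat& X,
                      const arma::ivec& starts, int window_len,
                      double gamma) {
  Net net = unpack_net(params);
  return eval_windows(net, X, starts, window_len, starts.n_elem, gamma);
}

// Gradients for one batch of windows (for gradient checking in tests).
// [[Rcpp::export]]
Rcpp::List lstm_grad_core(Rcpp::List params, const arma::mat& X,
                          const arma::ivec& starts, int window_len,
                          double gamma) {
  Net net = unpack_net(params);
  cube Xb, Yb;
  fill_cubes(X, starts, window_len, Xb, Yb);
  Grads g = zero_grads(net);
  double loss = backward_batch(net, Xb, Yb, gamma, g);
  Net gn;
  gn.layers = g.layers;
  gn.V = g.V;
  gn.c = g.c;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack_net(gn));
}

// [[Rcpp::export]]
Rcpp::List lstm_train_core(const arma::mat& X, Rcpp::List params,
                           const arma::imat& epoch_orders,
                           const arma::ivec& train_starts,
                           const arma::ivec& val_starts,
                           int window_len, int batch_size, double gamma,
                           double lr, double clip_norm) {
  Net net = unpack_net(params);
  const int epochs = epoch_orders.n_rows;
  const int n_train = train_starts.n_elem;
  AdamState st;
  st.m = zero_grads(net);
  st.v = zero_grads(net);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  vec train_trace(epochs), val_trace(epochs);

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    int n_seen = 0;
    for (int off = 0; off < n_train; off += batch_size) {
      int bsz = std::min(batch_size, n_train - off);
      ivec starts(bsz);
      for (int k = 0; k < bsz; ++k)
        starts(k) = train_starts(epoch_orders(e, off + k));
      cube Xb, Yb;
      fill_cubes(X, starts, window_len, Xb, Yb);
      Grads g = zero_grads(net);
      double loss = backward_batch(net, Xb, Yb, gamma, g);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d; lower the learning rate", e + 1);
      double nrm = std::sqrt(grad_sq_norm(g));
      if (clip_norm > 0 && nrm > clip_norm) scale_grads(g, clip_norm / nrm);
      st.t += 1;
      double lr_t = lr * std::sqrt(1.0 - std::pow(b2, (double)st.t)) /
                    (1.0 - std::pow(b1, (double)st.t));
      for (size_t l = 0; l < net.layers.size(); ++l) {
        adam_update_mat(net.layers[l].W, g.layers[l].W, st.m.layers[l].W,
                        st.v.layers[l].W, lr_t, b1, b2, eps);
        adam_update_mat(net.layers[l].U, g.layers[l].U, st.m.layers[l].U,
                        st.v.layers[l].U, lr_t, b1, b2, eps);
        adam_update_row(net.layers[l].b, g.layers[l].b, st.m.layers[l].b,
                        st.v.layers[l].b, lr_t, b1, b2, eps);
      }
      adam_update_mat(net.V, g.V, st.m.V, st.v.V, lr_t, b1, b2, eps);
      adam_update_row(net.c, g.c, st.m.c, st.v.c, lr_t, b1, b2, eps);
      epoch_loss += loss * bsz;
      n_seen += bsz;
      Rcpp::checkUserInterrupt();
    }
    train_trace(e) = epoch_loss / n_seen;
    val_trace(e) = eval_windows(net, X, val_starts, window_len, batch_size,
                                gamma);
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack_net(net),
                            Rcpp::Named("train_loss") = train_trace,
                            Rcpp::Named("val_loss") = val_trace);
}

// Teacher-forced one-step prediction over a full test sequence, hidden state
// carried across all bins. Output row k is the probability vector for test
// bin warmup + k (1-based), conditioned on the true bins before it.
// [[Rcpp::export]]
arma::mat lstm_predict_core(Rcpp::List params, const arma::mat& X,
                            int warmup) {
  Net net = unpack_net(params);
  const int T = X.n_rows;
  const int nL = net.layers.size();
  const int Hdim = net.hidden();
  const int n_out = net.V.n_cols;
  if (T < warmup + 1)
    Rcpp::stop("test raster too short: %d bins but warm-up needs %d + 1", T,
               warmup);
  std::vector<rowvec> h(nL, zeros<rowvec>(Hdim)), cc(nL, zeros<rowvec>(Hdim));
  mat out(T - warmup, n_out);
  for (int t = 0; t < T - 1; ++t) {
    rowvec xin = X.row(t);
    for (int l = 0; l < nL; ++l) {
      const LSTMLayer& L = net.layers[l];
      rowvec A = xin * L.W + h[l] * L.U + L.b;
      rowvec gi = 1.0 / (1.0 + exp(-A.subvec(0, Hdim - 1)));
      rowvec gf = 1.0 / (1.0 + exp(-A.subvec(Hdim, 2 * Hdim - 1)));
      rowvec gg = tanh(A.subvec(2 * Hdim, 3 * Hdim - 1));
      rowvec go = 1.0 / (1.0 + exp(-A.subvec(3 * Hdim, 4 * Hdim - 1)));
      cc[l] = gf % cc[l] + gi % gg;
      h[l] = go % tanh(cc[l]);
      xin = h[l];
    }
    int target = t + 1;  // 0-based bin being predicted
    if (target >= warmup) {
      rowvec Z = xin * net.V + net.c;
      out.row(target - warmup) = 1.0 / (1.0 + exp(-Z));
    }
    if (t % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
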