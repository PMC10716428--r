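// LSTM sequence classifier: single LSTM layer, ReLU dense stack with
// dropout, 2-node softmax output, weighted cross-entropy, Adam, early
// stopping on validation loss. Sequences are right-aligned (pre-padded)
// inside a (T x D x N) cube; a per-step mask freezes the recurrent state
// before each sample's first real time step. All randomness (weight
// initialisation, shuffling, dropout) is drawn from R's RNG so that
// set.seed() in R makes training fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uvec;
using arma::rowvec;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Net {
  int D, U, n_dense;
  std::vector<mat> P;  // Wx(4U x D), Wh(4U x U), b(1 x 4U),
                       // then per dense layer W(h x h_prev), b(1 x h),
                       // then Wout(2 x h_last), bout(1 x 2)
  std::vector<int> dense;
};

static mat r_uniform_mat(int r, int c, double s) {
  mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = (unif_rand() * 2.0 - 1.0) * s;
  return m;
}

static Net init_net(int D, int U, const std::vector<int>& dense) {
  Net net;
  net.D = D; net.U = U; net.dense = dense; net.n_dense = (int)dense.size();
  double sx = 1.0 / std::sqrt((double)D), sh = 1.0 / std::sqrt((double)U);
  net.P.push_back(r_uniform_mat(4 * U, D, sx));
  net.P.push_back(r_uniform_mat(4 * U, U, sh));
  mat b(1, 4 * U, arma::fill::zeros);
  b.cols(U, 2 * U - 1).fill(1.0);  // forget-gate bias
  net.P.push_back(b);
  int prev = U;
  for (int k = 0; k < net.n_dense; ++k) {
    net.P.push_back(r_uniform_mat(dense[k], prev, 1.0 / std::sqrt((double)prev)));
    net.P.push_back(mat(1, dense[k], arma::fill::zeros));
    prev = dense[k];
  }
  net.P.push_back(r_uniform_mat(2, prev, 1.0 / std::sqrt((double)prev)));
  net.P.push_back(mat(1, 2, arma::fill::zeros));
  return net;
}

// forward pass for a batch; returns class probabilities (B x 2).
// When caches is non-null, intermediate quantities are stored for BPTT.
struct Caches {
  cube Hs, I, F, G, O, C, Th, Xc;  // Hs: state before step t
  mat M;                            // mask (B x T)
  std::vector<mat> Zpre;            // dense post-relu pre-dropout
  std::vector<mat> Zin;             // inputs to each dense layer / output
  std::vector<mat> Drop;            // dropout masks (already scaled)
};

static mat forward(const Net& net, const cube& X, const arma::ivec& len,
                   const uvec& idx, bool train, double dropout,
                   Caches* cc) {
  const int T = X.n_rows, D = net.D, U = net.U;
  const int B = idx.n_elem;
  const mat& Wx = net.P[0];
  const mat& Wh = net.P[1];
  const rowvec b = net.P[2].row(0);

  mat H(B, U, arma::fill::zeros), C(B, U, arma::fill::zeros);
  if (cc) {
    cc->Hs.set_size(B, U, T); cc->I.set_size(B, U, T); cc->F.set_size(B, U, T);
    cc->G.set_size(B, U, T);  cc->O.set_size(B, U, T); cc->C.set_size(B, U, T);
    cc->Th.set_size(B, U, T); cc->Xc.set_size(B, D, T); cc->M.set_size(B, T);
  }
  mat Xt(B, D);
  arma::colvec mt(B);
  for (int t = 0; t < T; ++t) {
    for (int bi = 0; bi < B; ++bi) {
      const arma::uword s = idx[bi];
      for (int d = 0; d < D; ++d) Xt(bi, d) = X(t, d, s);
      mt(bi) = (t >= T - len[s]) ? 1.0 : 0.0;
    }
    mat A = Xt * Wx.t() + H * Wh.t();
    A.each_row() += b;
    mat gi = sigmoid(A.cols(0, U - 1));
    mat gf = sigmoid(A.cols(U, 2 * U - 1));
    mat gg = arma::tanh(A.cols(2 * U, 3 * U - 1));
    mat go = sigmoid(A.cols(3 * U, 4 * U - 1));
    mat Cn = gf % C + gi % gg;
    mat Tn = arma::tanh(Cn);
    mat Hn = go % Tn;
    if (cc) {
      cc->Hs.slice(t) = H; cc->I.slice(t) = gi; cc->F.slice(t) = gf;
      cc->G.slice(t) = gg; cc->O.slice(t) = go; cc->Xc.slice(t) = Xt;
      cc->M.col(t) = mt;
    }
    mat Cnew = Cn.each_col() % mt; mat Cold = C.each_col() % (1.0 - mt);
    C = Cnew + Cold;
    mat Hnew = Hn.each_col() % mt; mat Hold = H.each_col() % (1.0 - mt);
    H = Hnew + Hold;
    if (cc) { cc->C.slice(t) = C; cc->Th.slice(t) = arma::tanh(C); }
  }

  mat Z = H;
  if (cc) { cc->Zin.clear(); cc->Zpre.clear(); cc->Drop.clear(); }
  for (int k = 0; k < net.n_dense; ++k) {
    if (cc) cc->Zin.push_back(Z);
    mat A = Z * net.P[3 + 2 * k].t();
    A.each_row() += net.P[4 + 2 * k].row(0);
    mat R = arma::clamp(A, 0.0, arma::datum::inf);
    if (cc) cc->Zpre.push_back(R);
    if (train && dropout > 0) {
      mat Dm(R.n_rows, R.n_cols);
      const double keep = 1.0 - dropout;
      for (arma::uword i = 0; i < Dm.n_elem; ++i)
        Dm(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
      R %= Dm;
      if (cc) cc->Drop.push_back(Dm);
    } else if (cc) {
      cc->Drop.push_back(mat(R.n_rows, R.n_cols, arma::fill::ones));
    }
    Z = R;
  }
  if (cc) cc->Zin.push_back(Z);
  mat logits = Z * net.P[3 + 2 * net.n_dense].t();
  logits.each_row() += net.P[4 + 2 * net.n_dense].row(0);
  logits.each_col() -= arma::max(logits, 1);
  mat E = arma::exp(logits);
  return E.each_col() / arma::sum(E, 1);
}

static double weighted_ce(const mat& prob, const arma::ivec& y,
                          const uvec& idx, double case_weight) {
  double loss = 0, wsum = 0;
  for (arma::uword bi = 0; bi < idx.n_elem; ++bi) {
    const int yi = y[idx[bi]];
    const double w = (yi == 1) ? case_weight : 1.0;
    loss -= w * std::log(std::max(prob(bi, yi), 1e-12));
    wsum += w;
  }
  return loss / wsum;
}

static void backward(const Net& net, const Caches& cc, const mat& prob,
                     const arma::ivec& y, const uvec& idx,
                     double case_weight, std::vector<mat>& Gr) {
  const int T = cc.M.n_cols, U = net.U, B = idx.n_elem;
  for (size_t p = 0; p < net.P.size(); ++p)
    Gr[p] = mat(net.P[p].n_rows, net.P[p].n_cols, arma::fill::zeros);

  double wsum = 0;
  vec w(B);
  for (int bi = 0; bi < B; ++bi) {
    w(bi) = (y[idx[bi]] == 1) ? case_weight : 1.0;
    wsum += w(bi);
  }
  mat dlog = prob;
  for (int bi = 0; bi < B; ++bi) dlog(bi, y[idx[bi]]) -= 1.0;
  dlog.each_col() %= (w / wsum);

  const int oW = 3 + 2 * net.n_dense;
  Gr[oW] = dlog.t() * cc.Zin[net.n_dense];
  Gr[oW + 1] = arma::sum(dlog, 0);
  mat dZ = dlog * net.P[oW];

  for (int k = net.n_dense - 1; k >= 0; --k) {
    dZ %= cc.Drop[k];
    mat relu_grad = arma::conv_to<mat>::from(cc.Zpre[k] > 0);
    mat dA = dZ % relu_grad;
    Gr[3 + 2 * k] = dA.t() * cc.Zin[k];
    Gr[4 + 2 * k] = arma::sum(dA, 0);
    dZ = dA * net.P[3 + 2 * k];
  }

  mat dH = dZ, dC(B, U, arma::fill::zeros);
  const mat& Wh = net.P[1];
  for (int t = T - 1; t >= 0; --t) {
    const arma::colvec mt = cc.M.col(t);
    const mat& gi = cc.I.slice(t); const mat& gf = cc.F.slice(t);
    const mat& gg = cc.G.slice(t); const mat& go = cc.O.slice(t);
    const mat& Th = cc.Th.slice(t);
    mat cprev = (t > 0) ? cc.C.slice(t - 1) : mat(B, U, arma::fill::zeros);

    mat dO = dH % Th;
    mat dCt = dC + dH % go % (1.0 - Th % Th);
    mat dI = dCt % gg;
    mat dG = dCt % gi;
    mat dF = dCt % cprev;
    mat dCprev = dCt % gf;

    mat dA(B, 4 * U);
    dA.cols(0, U - 1)         = dI % gi % (1.0 - gi);
    dA.cols(U, 2 * U - 1)     = dF % gf % (1.0 - gf);
    dA.cols(2 * U, 3 * U - 1) = dG % (1.0 - gg % gg);
    dA.cols(3 * U, 4 * U - 1) = dO % go % (1.0 - go);
    dA.each_col() %= mt;

    Gr[0] += dA.t() * cc.Xc.slice(t);
    Gr[1] += dA.t() * cc.Hs.slice(t);
    Gr[2] += arma::sum(dA, 0);

    mat dHpass = dH.each_col() % (1.0 - mt);
    dH = dA * Wh + dHpass;
    mat dCpass = dC.each_col() % (1.0 - mt);
    dC = dCprev.each_col() % mt + dCpass;
  }
}

static List net_to_list(const Net& net) {
  List w(net.P.size());
  for (size_t i = 0; i < net.P.size(); ++i) w[i] = wrap(net.P[i]);
  return w;
}

static Net net_from_list(List w, int D, int U, const std::vector<int>& dense) {
  Net net;
  net.D = D; net.U = U; net.dense = dense; net.n_dense = (int)dense.size();
  for (int i = 0; i < w.size(); ++i) net.P.push_back(as<mat>(w[i]));
  return net;
}

// [[Rcpp::export]]
List lstm_train_cpp(const arma::cube& X, const arma::ivec& len,
                    const arma::ivec& y,
                    const arma::cube& Xv, const arma::ivec& lenv,
                    const arma::ivec& yv,
                    int units, const arma::ivec& dense_sizes,
                    double dropout, double case_weight,
                    int max_epochs, int patience, int batch_size,
                    double lr) {
  const int N = X.n_slices, D = X.n_cols;
  std::vector<int> dense(dense_sizes.begin(), dense_sizes.end());
  Net net = init_net(D, units, dense);
  const size_t NP = net.P.size();
  std::vector<mat> Gr(NP), M(NP), V(NP);
  for (size_t p = 0; p < NP; ++p) {
    M[p] = mat(net.P[p].n_rows, net.P[p].n_cols, arma::fill::zeros);
    V[p] = M[p];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  const bool has_val = Xv.n_slices > 0;
  double best_val = arma::datum::inf;
  std::vector<mat> best_P = net.P;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> train_hist, val_hist;

  std::vector<arma::uword> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // shuffle with R RNG (Fisher-Yates)
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double ep_loss = 0; int n_batches = 0;
    for (int s0 = 0; s0 < N; s0 += batch_size) {
      const int s1 = std::min(s0 + batch_size, N);
      uvec idx(s1 - s0);
      for (int i = s0; i < s1; ++i) idx[i - s0] = perm[i];
      Caches cc;
      mat prob = forward(net, X, len, idx, true, dropout, &cc);
      ep_loss += weighted_ce(prob, y, idx, case_weight);
      ++n_batches;
      backward(net, cc, prob, y, idx, case_weight, Gr);
      ++step;
      const double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                          (1.0 - std::pow(b1, (double)step));
      for (size_t p = 0; p < NP; ++p) {
        M[p] = b1 * M[p] + (1.0 - b1) * Gr[p];
        V[p] = b2 * V[p] + (1.0 - b2) * (Gr[p] % Gr[p]);
        net.P[p] -= corr * M[p] / (arma::sqrt(V[p]) + eps);
      }
    }
    train_hist.push_back(ep_loss / std::max(n_batches, 1));
    ++epochs_run;

    if (has_val) {
      double vloss = 0, vw = 0;
      const int NV = Xv.n_slices;
      for (int s0 = 0; s0 < NV; s0 += 256) {
        const int s1 = std::min(s0 + 256, NV);
        uvec idx(s1 - s0);
        for (int i = s0; i < s1; ++i) idx[i - s0] = i;
        mat prob = forward(net, Xv, lenv, idx, false, 0.0, nullptr);
        for (int i = s0; i < s1; ++i) {
          const double w = (yv[i] == 1) ? case_weight : 1.0;
          vloss -= w * std::log(std::max(prob(i - s0, yv[i]), 1e-12));
          vw += w;
        }
      }
      vloss /= vw;
      val_hist.push_back(vloss);
      if (vloss < best_val - 1e-6) {
        best_val = vloss; best_P = net.P; best_epoch = epochs_run; wait = 0;
      } else if (++wait >= patience) break;
    } else {
      best_P = net.P; best_epoch = epochs_run;
    }
  }
  net.P = best_P;
  return List::create(
    _["weights"] = net_to_list(net),
    _["best_val_loss"] = has_val ? best_val : NA_REAL,
    _["epochs_run"] = epochs_run,
    _["best_epoch"] = best_epoch,
    _["train_loss"] = train_hist,
    _["val_loss"] = val_hist);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(List weights, const arma::cube& X,
                           const arma::ivec& len, int units,
                           const arma::ivec& dense_sizes) {
  std::vector<int> dense(dense_sizes.begin(), dense_sizes.end());
  Net net = net_from_list(weights, X.n_cols, units, dense);
  const int N = X.n_slices;
  mat out(N, 2);
  for (int s0 = 0; s0 < N; s0 += 256) {
    const int s1 = std::min(s0 + 256, N);
    uvec idx(s1 - s0);
    for (int i = s0; i < s1; ++i) idx[i - s0] = i;
    out.rows(s0, s1 - 1) = forward(net, X, len, idx, false, 0.0, nullptr);
  }
  return out;
}
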