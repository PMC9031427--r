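// Convolution + BiLSTM + softmax sequence labeller.
//
// Architecture: name-internal feature rows (T x 5) pass through a
// width-w convolution with ReLU (CF filters); the output is
// concatenated with frozen per-token embeddings (T x ED, optional
// channel dropout during training) and fed to a bidirectional LSTM;
// a shared dense softmax maps each token's [h_fwd; h_bwd] to the five
// BIOES classes. Training is cross-entropy with Adam, gradients
// accumulated over a sentence mini-batch. All randomness comes from
// std::mt19937 seeds passed in from R, so runs are reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

enum PIdx { WC = 0, BC, WF, UF, BF, WB, UB, BB, WO, BO, NPARAM };
static const char* PNAMES[NPARAM] = {"Wc", "bc", "Wf", "Uf", "bf",
                                     "Wb", "Ub", "bb", "Wo", "bo"};

static std::vector<mat> listToParams(const List& l) {
  std::vector<mat> P(NPARAM);
  for (int i = 0; i < NPARAM; ++i)
    P[i] = as<mat>(l[PNAMES[i]]);
  return P;
}

static List paramsToList(const std::vector<mat>& P) {
  List l(NPARAM);
  CharacterVector nm(NPARAM);
  for (int i = 0; i < NPARAM; ++i) { l[i] = P[i]; nm[i] = PNAMES[i]; }
  l.attr("names") = nm;
  return l;
}

static mat glorot(int nr, int nc, std::mt19937& rng) {
  double r = std::sqrt(6.0 / (nr + nc));
  std::uniform_real_distribution<double> unif(-r, r);
  mat m(nr, nc);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = unif(rng);
  return m;
}

// [[Rcpp::export(name = ".nn_init")]]
List nn_init(int fdim, int conv_width, int conv_filters, int embed_dim,
             int hidden, int nclass, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  int D = conv_filters + embed_dim;
  std::vector<mat> P(NPARAM);
  P[WC] = glorot(conv_filters, conv_width * fdim, rng);
  P[BC] = mat(conv_filters, 1, arma::fill::zeros);
  P[WF] = glorot(4 * hidden, D, rng);
  P[UF] = glorot(4 * hidden, hidden, rng);
  P[BF] = mat(4 * hidden, 1, arma::fill::zeros);
  P[BF].rows(hidden, 2 * hidden - 1).fill(1.0);   // forget-gate bias
  P[WB] = glorot(4 * hidden, D, rng);
  P[UB] = glorot(4 * hidden, hidden, rng);
  P[BB] = mat(4 * hidden, 1, arma::fill::zeros);
  P[BB].rows(hidden, 2 * hidden - 1).fill(1.0);
  P[WO] = glorot(nclass, 2 * hidden, rng);
  P[BO] = mat(nclass, 1, arma::fill::zeros);
  return paramsToList(P);
}

// [[Rcpp::export(name = ".nn_adam_init")]]
List nn_adam_init(const List& params) {
  std::vector<mat> P = listToParams(params);
  std::vector<mat> M(NPARAM), V(NPARAM);
  for (int i = 0; i < NPARAM; ++i) {
    M[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
    V[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
  }
  return List::create(Named("m") = paramsToList(M),
                      Named("v") = paramsToList(V),
                      Named("t") = 0);
}

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LstmCache {
  mat i, f, g, o, c, h, tc;   // each H x T
};

// X is D x T; returns h (H x T) plus gate cache for backprop
static void lstmForward(const mat& W, const mat& U, const vec& b,
                        const mat& X, bool rev, LstmCache& cc) {
  int H = U.n_cols, T = X.n_cols;
  cc.i.set_size(H, T); cc.f.set_size(H, T); cc.g.set_size(H, T);
  cc.o.set_size(H, T); cc.c.set_size(H, T); cc.h.set_size(H, T);
  cc.tc.set_size(H, T);
  vec hprev(H, arma::fill::zeros), cprev(H, arma::fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = rev ? T - 1 - s : s;
    vec a = W * X.col(t) + U * hprev + b;
    vec ii = sigm(a.rows(0, H - 1));
    vec ff = sigm(a.rows(H, 2 * H - 1));
    vec gg = arma::tanh(a.rows(2 * H, 3 * H - 1));
    vec oo = sigm(a.rows(3 * H, 4 * H - 1));
    vec ct = ff % cprev + ii % gg;
    vec tct = arma::tanh(ct);
    vec ht = oo % tct;
    cc.i.col(t) = ii; cc.f.col(t) = ff; cc.g.col(t) = gg;
    cc.o.col(t) = oo; cc.c.col(t) = ct; cc.tc.col(t) = tct;
    cc.h.col(t) = ht;
    hprev = ht; cprev = ct;
  }
}

// dH is upstream dLoss/dh (H x T); accumulates dW,dU,db and adds into dX
static void lstmBackward(const mat& W, const mat& U, const LstmCache& cc,
                         const mat& X, const mat& dH, bool rev,
                         mat& dW, mat& dU, mat& db_, mat& dX) {
  int H = U.n_cols, T = X.n_cols;
  vec dhCarry(H, arma::fill::zeros), dc(H, arma::fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = rev ? T - 1 - s : s;
    int tPrev = rev ? t + 1 : t - 1;
    bool hasPrev = rev ? (t + 1 < T) : (t - 1 >= 0);
    vec cprev = hasPrev ? vec(cc.c.col(tPrev)) : vec(H, arma::fill::zeros);
    vec hprev = hasPrev ? vec(cc.h.col(tPrev)) : vec(H, arma::fill::zeros);
    vec dh = dH.col(t) + dhCarry;
    vec o = cc.o.col(t), tc = cc.tc.col(t), i = cc.i.col(t),
        f = cc.f.col(t), g = cc.g.col(t);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec di = dc % g;
    vec df = dc % cprev;
    vec dg = dc % i;
    vec da(4 * H);
    da.rows(0, H - 1)         = di % i % (1.0 - i);
    da.rows(H, 2 * H - 1)     = df % f % (1.0 - f);
    da.rows(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dW += da * X.col(t).t();
    dU += da * hprev.t();
    db_ += da;
    dX.col(t) += W.t() * da;
    dhCarry = U.t() * da;
    dc = dc % f;
  }
}

// Build conv output Z (CF x T) from features F (T x fdim); caches the
// pre-activation mask for backprop via zRaw.
static mat convForward(const mat& Wc, const vec& bc, const mat& Fts,
                       int cw, mat& zRaw) {
  int T = Fts.n_rows, fdim = Fts.n_cols, CF = Wc.n_rows;
  int hw = (cw - 1) / 2;
  mat win(cw * fdim, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int k = -hw; k <= hw; ++k) {
      int tt = t + k;
      if (tt < 0 || tt >= T) continue;
      win.col(t).rows((k + hw) * fdim, (k + hw + 1) * fdim - 1) =
        Fts.row(tt).t();
    }
  zRaw = Wc * win + arma::repmat(bc, 1, T);
  mat Z = zRaw;
  Z.elem(arma::find(Z < 0)).zeros();
  (void)CF;
  return Z;
}

static void convBackward(const mat& dZ, const mat& zRaw, const mat& Fts,
                         int cw, mat& dWc, mat& dbc) {
  int T = Fts.n_rows, fdim = Fts.n_cols;
  int hw = (cw - 1) / 2;
  mat dzr = dZ;
  dzr.elem(arma::find(zRaw <= 0)).zeros();
  mat win(cw * fdim, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int k = -hw; k <= hw; ++k) {
      int tt = t + k;
      if (tt < 0 || tt >= T) continue;
      win.col(t).rows((k + hw) * fdim, (k + hw + 1) * fdim - 1) =
        Fts.row(tt).t();
    }
  dWc += dzr * win.t();
  dbc += arma::sum(dzr, 1);
}

// full forward; returns probability matrix (nclass x T)
static mat forwardPass(const std::vector<mat>& P, const mat& Fts,
                       const mat& Emb, int cw, LstmCache& cf,
                       LstmCache& cb, mat& X, mat& zRaw) {
  mat Z = convForward(P[WC], P[BC].col(0), Fts, cw, zRaw);
  X = arma::join_cols(Z, Emb.t());            // D x T
  lstmForward(P[WF], P[UF], P[BF].col(0), X, false, cf);
  lstmForward(P[WB], P[UB], P[BB].col(0), X, true, cb);
  mat Hcat = arma::join_cols(cf.h, cb.h);     // 2H x T
  mat logits = P[WO] * Hcat + arma::repmat(P[BO], 1, X.n_cols);
  logits.each_row() -= arma::max(logits, 0);
  mat ex = arma::exp(logits);
  mat probs = ex;
  probs.each_row() /= arma::sum(ex, 0);
  return probs;
}

// [[Rcpp::export(name = ".nn_forward")]]
NumericMatrix nn_forward(const List& params, const NumericMatrix& feats,
                         const NumericMatrix& embs, int conv_width) {
  std::vector<mat> P = listToParams(params);
  mat Fts = as<mat>(feats), Emb = as<mat>(embs);
  LstmCache cf, cb; mat X, zRaw;
  mat probs = forwardPass(P, Fts, Emb, conv_width, cf, cb, X, zRaw);
  return wrap(mat(probs.t()));                // T x nclass
}

// [[Rcpp::export(name = ".nn_train_epoch")]]
List nn_train_epoch(const List& params, const List& adam,
                    const List& feats, const List& embs,
                    const List& labels, const IntegerVector& order,
                    double lr, int batch_size, double dropout,
                    int conv_width, int seed) {
  std::vector<mat> P = listToParams(params);
  std::vector<mat> M = listToParams(as<List>(adam["m"]));
  std::vector<mat> V = listToParams(as<List>(adam["v"]));
  int adamT = as<int>(adam["t"]);
  std::vector<mat> G(NPARAM);
  for (int i = 0; i < NPARAM; ++i)
    G[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double totalLoss = 0.0; int nTok = 0, inBatch = 0;
  int H = P[UF].n_cols;
  int CF = P[WC].n_rows;

  auto applyAdam = [&](int count) {
    if (count == 0) return;
    ++adamT;
    for (int i = 0; i < NPARAM; ++i) {
      mat g = G[i] / count;
      M[i] = b1 * M[i] + (1 - b1) * g;
      V[i] = b2 * V[i] + (1 - b2) * (g % g);
      mat mhat = M[i] / (1 - std::pow(b1, adamT));
      mat vhat = V[i] / (1 - std::pow(b2, adamT));
      P[i] -= lr * mhat / (arma::sqrt(vhat) + eps);
      G[i].zeros();
    }
  };

  for (int idx = 0; idx < order.size(); ++idx) {
    int s = order[idx] - 1;                  // R is 1-based
    mat Fts = as<mat>(feats[s]);
    mat Emb = as<mat>(embs[s]);
    IntegerVector y = labels[s];
    int T = Fts.n_rows;
    if (T == 0) continue;
    // channel (spatial) dropout on embedding columns, train time only
    if (dropout > 0.0) {
      for (arma::uword j = 0; j < Emb.n_cols; ++j)
        if (unif(rng) < dropout) Emb.col(j).zeros();
        else Emb.col(j) /= (1.0 - dropout);
    }
    LstmCache cf, cb; mat X, zRaw;
    mat probs = forwardPass(P, Fts, Emb, conv_width, cf, cb, X, zRaw);
    // cross-entropy loss and dLogits = probs - onehot
    mat dLogits = probs;
    for (int t = 0; t < T; ++t) {
      totalLoss += -std::log(std::max(probs(y[t], t), 1e-12));
      dLogits(y[t], t) -= 1.0;
    }
    nTok += T;
    dLogits /= T;                            // mean over tokens
    mat Hcat = arma::join_cols(cf.h, cb.h);
    G[WO] += dLogits * Hcat.t();
    G[BO] += arma::sum(dLogits, 1);
    mat dHcat = P[WO].t() * dLogits;         // 2H x T
    mat dX(X.n_rows, T, arma::fill::zeros);
    lstmBackward(P[WF], P[UF], cf, X, dHcat.rows(0, H - 1), false,
                 G[WF], G[UF], G[BF], dX);
    lstmBackward(P[WB], P[UB], cb, X, dHcat.rows(H, 2 * H - 1), true,
                 G[WB], G[UB], G[BB], dX);
    convBackward(dX.rows(0, CF - 1), zRaw, Fts, conv_width, G[WC], G[BC]);
    if (++inBatch == batch_size) { applyAdam(inBatch); inBatch = 0; }
  }
  applyAdam(inBatch);
  List adamOut = List::create(Named("m") = paramsToList(M),
                              Named("v") = paramsToList(V),
                              Named("t") = adamT);
  return List::create(Named("params") = paramsToList(P),
                      Named("adam") = adamOut,
                      Named("loss") = nTok ? totalLoss / nTok : NA_REAL);
}
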