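// Compiled learners: histogram-split decision-tree ensembles (Random
// Forest / Extra Trees), gradient boosting, a one-hidden-layer MLP and
// single-cell GRU/LSTM sequence classifiers trained with Adam.
//
// All randomness is drawn from R's RNG (unif_rand / norm_rand), so every
// fit is reproducible under set.seed() from R. Everything runs
// single-threaded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int runif_int(int n) {  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// ---------------------------------------------------------------------------
// Decision trees (flat-array representation)
// ---------------------------------------------------------------------------

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x <= thr goes left
  std::vector<int> left, right;
  std::vector<double> value;     // leaf prediction
};

static const int NBINS = 32;

// Gini impurity of a binary node given positive count and total.
static inline double gini(double pos, double n) {
  if (n <= 0) return 0.0;
  double p = pos / n;
  return 2.0 * p * (1.0 - p);
}

// Grow one classification tree. mode 0 = RF (best histogram split over
// mtry features), 1 = Extra Trees (one uniform-random threshold per
// sampled feature). `imp` accumulates impurity-decrease importances.
static int grow_cls(const arma::mat& X, const arma::ivec& y,
                    std::vector<int>& idx, int lo, int hi, int depth,
                    int max_depth, int min_split, int mtry, int mode,
                    TreeBuf& T, arma::vec& imp) {
  int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  int node = T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.value.push_back((double)pos / n);
  if (pos == 0 || pos == n || n < min_split || depth >= max_depth)
    return node;

  int p = X.n_cols;
  double parent = gini(pos, n);
  double best_gain = 1e-12;
  int best_f = -1; double best_thr = 0.0;

  for (int m = 0; m < mtry; ++m) {
    int f = runif_int(p);
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = lo; i < hi; ++i) {
      double v = X(idx[i], f);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    if (!(mx > mn)) continue;
    if (mode == 1) {                       // Extra Trees: random threshold
      double thr = mn + unif_rand() * (mx - mn);
      double nl = 0, pl = 0;
      for (int i = lo; i < hi; ++i) {
        if (X(idx[i], f) <= thr) { nl += 1; pl += y[idx[i]]; }
      }
      double nr = n - nl, pr = pos - pl;
      if (nl < 1 || nr < 1) continue;
      double gain = parent - (nl / n) * gini(pl, nl) - (nr / n) * gini(pr, nr);
      if (gain > best_gain) { best_gain = gain; best_f = f; best_thr = thr; }
    } else {                               // RF: histogram best split
      double cnt[NBINS], cpos[NBINS];
      std::fill(cnt, cnt + NBINS, 0.0);
      std::fill(cpos, cpos + NBINS, 0.0);
      double w = (mx - mn) / NBINS;
      for (int i = lo; i < hi; ++i) {
        int b = (int)((X(idx[i], f) - mn) / w);
        if (b >= NBINS) b = NBINS - 1;
        cnt[b] += 1; cpos[b] += y[idx[i]];
      }
      double nl = 0, pl = 0;
      for (int b = 0; b < NBINS - 1; ++b) {
        nl += cnt[b]; pl += cpos[b];
        double nr = n - nl, pr = pos - pl;
        if (nl < 1 || nr < 1) continue;
        double gain = parent - (nl / n) * gini(pl, nl) -
                      (nr / n) * gini(pr, nr);
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_thr = mn + w * (b + 1);
        }
      }
    }
  }
  if (best_f < 0) return node;
  // partition idx[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;
  imp[best_f] += best_gain * n;
  T.feature[node] = best_f; T.threshold[node] = best_thr;
  int l = grow_cls(X, y, idx, lo, mid, depth + 1, max_depth, min_split,
                   mtry, mode, T, imp);
  int r = grow_cls(X, y, idx, mid, hi, depth + 1, max_depth, min_split,
                   mtry, mode, T, imp);
  T.left[node] = l; T.right[node] = r;
  return node;
}

static List tree_to_list(const TreeBuf& T) {
  return List::create(_["feature"] = wrap(T.feature),
                      _["threshold"] = wrap(T.threshold),
                      _["left"] = wrap(T.left),
                      _["right"] = wrap(T.right),
                      _["value"] = wrap(T.value));
}

static double tree_predict(const IntegerVector& feature,
                           const NumericVector& threshold,
                           const IntegerVector& left,
                           const IntegerVector& right,
                           const NumericVector& value,
                           const arma::mat& X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return value[node];
}

// [[Rcpp::export]]
List cpp_train_forest(const arma::mat& X, const arma::ivec& y, int ntree,
                      int mtry, bool extra, int max_depth, int min_split) {
  int n = X.n_rows;
  arma::vec imp(X.n_cols, arma::fill::zeros);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    if (extra) {                    // Extra Trees: full sample, no bootstrap
      for (int i = 0; i < n; ++i) idx[i] = i;
    } else {                        // RF: bootstrap
      for (int i = 0; i < n; ++i) idx[i] = runif_int(n);
    }
    TreeBuf T;
    grow_cls(X, y, idx, 0, n, 0, max_depth, min_split, mtry,
             extra ? 1 : 0, T, imp);
    trees[t] = tree_to_list(T);
  }
  double s = arma::accu(imp);
  if (s > 0) imp /= s;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
arma::vec cpp_predict_forest(const List& model, const arma::mat& X) {
  List trees = model["trees"];
  int n = X.n_rows, nt = trees.size();
  arma::vec out(n, arma::fill::zeros);
  for (int t = 0; t < nt; ++t) {
    List T = trees[t];
    IntegerVector f = T["feature"], l = T["left"], r = T["right"];
    NumericVector thr = T["threshold"], v = T["value"];
    for (int i = 0; i < n; ++i) out[i] += tree_predict(f, thr, l, r, v, X, i);
  }
  return out / nt;
}

// ---------------------------------------------------------------------------
// Gradient boosting (logistic loss, shallow regression trees,
// Newton leaf updates)
// ---------------------------------------------------------------------------

// Grow one regression tree on gradients g with hessian h; histogram splits
// over all features; leaves store sum(g)/sum(h) (Newton step).
static int grow_reg(const arma::mat& X, const arma::vec& g,
                    const arma::vec& h, std::vector<int>& idx, int lo,
                    int hi, int depth, int max_depth, int min_split,
                    TreeBuf& T, arma::vec& imp) {
  int n = hi - lo;
  double sg = 0, sh = 0;
  for (int i = lo; i < hi; ++i) { sg += g[idx[i]]; sh += h[idx[i]]; }
  int node = T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.value.push_back(sh > 0 ? sg / sh : 0.0);
  if (n < min_split || depth >= max_depth) return node;

  int p = X.n_cols;
  double parent = sh > 0 ? sg * sg / sh : 0.0;
  double best_gain = 1e-12;
  int best_f = -1; double best_thr = 0.0;
  for (int f = 0; f < p; ++f) {
    double mn = R_PosInf, mx = R_NegInf;
    for (int i = lo; i < hi; ++i) {
      double v = X(idx[i], f);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    if (!(mx > mn)) continue;
    double bg[NBINS], bh[NBINS], bc[NBINS];
    std::fill(bg, bg + NBINS, 0.0);
    std::fill(bh, bh + NBINS, 0.0);
    std::fill(bc, bc + NBINS, 0.0);
    double w = (mx - mn) / NBINS;
    for (int i = lo; i < hi; ++i) {
      int b = (int)((X(idx[i], f) - mn) / w);
      if (b >= NBINS) b = NBINS - 1;
      bg[b] += g[idx[i]]; bh[b] += h[idx[i]]; bc[b] += 1;
    }
    double gl = 0, hl = 0, cl = 0;
    for (int b = 0; b < NBINS - 1; ++b) {
      gl += bg[b]; hl += bh[b]; cl += bc[b];
      double gr = sg - gl, hr = sh - hl, cr = n - cl;
      if (cl < 1 || cr < 1 || hl <= 0 || hr <= 0) continue;
      double gain = gl * gl / hl + gr * gr / hr - parent;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_thr = mn + w * (b + 1);
      }
    }
  }
  if (best_f < 0) return node;
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;
  imp[best_f] += best_gain;
  T.feature[node] = best_f; T.threshold[node] = best_thr;
  int l = grow_reg(X, g, h, idx, lo, mid, depth + 1, max_depth, min_split,
                   T, imp);
  int r = grow_reg(X, g, h, idx, mid, hi, depth + 1, max_depth, min_split,
                   T, imp);
  T.left[node] = l; T.right[node] = r;
  return node;
}

// [[Rcpp::export]]
List cpp_train_gbm(const arma::mat& X, const arma::ivec& y, int nrounds,
                   double learning_rate, int max_depth, int min_split) {
  int n = X.n_rows;
  double pbar = arma::accu(arma::conv_to<arma::vec>::from(y)) / n;
  pbar = std::min(1 - 1e-6, std::max(1e-6, pbar));
  double f0 = std::log(pbar / (1 - pbar));
  arma::vec F(n, arma::fill::value(f0));
  arma::vec imp(X.n_cols, arma::fill::zeros);
  List trees(nrounds);
  for (int t = 0; t < nrounds; ++t) {
    arma::vec p = 1.0 / (1.0 + arma::exp(-F));
    arma::vec g(n), h(n);
    for (int i = 0; i < n; ++i) {
      g[i] = y[i] - p[i];
      h[i] = std::max(1e-9, p[i] * (1.0 - p[i]));
    }
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    TreeBuf T;
    grow_reg(X, g, h, idx, 0, n, 0, max_depth, min_split, T, imp);
    trees[t] = tree_to_list(T);
    IntegerVector ff = wrap(T.feature), ll = wrap(T.left), rr = wrap(T.right);
    NumericVector tt = wrap(T.threshold), vv = wrap(T.value);
    for (int i = 0; i < n; ++i)
      F[i] += learning_rate * tree_predict(ff, tt, ll, rr, vv, X, i);
  }
  double s = arma::accu(imp);
  if (s > 0) imp /= s;
  return List::create(_["trees"] = trees, _["f0"] = f0,
                      _["learning_rate"] = learning_rate,
                      _["importance"] = imp);
}

// [[Rcpp::export]]
arma::vec cpp_predict_gbm(const List& model, const arma::mat& X) {
  List trees = model["trees"];
  double f0 = model["f0"], lr = model["learning_rate"];
  int n = X.n_rows, nt = trees.size();
  arma::vec F(n, arma::fill::value(f0));
  for (int t = 0; t < nt; ++t) {
    List T = trees[t];
    IntegerVector f = T["feature"], l = T["left"], r = T["right"];
    NumericVector thr = T["threshold"], v = T["value"];
    for (int i = 0; i < n; ++i)
      F[i] += lr * tree_predict(f, thr, l, r, v, X, i);
  }
  return 1.0 / (1.0 + arma::exp(-F));
}

// ---------------------------------------------------------------------------
// Adam helper
// ---------------------------------------------------------------------------

struct Adam {
  double lr, b1, b2, eps;
  long t;
  std::vector<arma::mat> m, v;
  Adam(double lr_) : lr(lr_), b1(0.9), b2(0.999), eps(1e-8), t(0) {}
  void init(const std::vector<arma::mat*>& params) {
    for (auto* p : params) {
      m.push_back(arma::mat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(arma::mat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<arma::mat*>& params,
            const std::vector<arma::mat*>& grads) {
    ++t;
    double c1 = 1 - std::pow(b1, (double)t);
    double c2 = 1 - std::pow(b2, (double)t);
    for (size_t k = 0; k < params.size(); ++k) {
      m[k] = b1 * m[k] + (1 - b1) * (*grads[k]);
      v[k] = b2 * v[k] + (1 - b2) * arma::square(*grads[k]);
      *params[k] -= lr * (m[k] / c1) / (arma::sqrt(v[k] / c2) + eps);
    }
  }
};

static arma::mat rand_mat(int r, int c, double scale) {
  arma::mat M(r, c);
  for (arma::uword i = 0; i < M.n_elem; ++i)
    M(i) = (unif_rand() * 2.0 - 1.0) * scale;
  return M;
}

// ---------------------------------------------------------------------------
// MLP: one hidden ReLU layer, sigmoid output, Adam, early stopping
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_train_mlp(const arma::mat& X, const arma::vec& y, int hidden,
                   int max_epochs, int batch, double lr, double val_frac,
                   int patience) {
  int n = X.n_rows, p = X.n_cols;
  // shuffled split into train/validation for early stopping
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[runif_int(i + 1)]);
  int nval = std::max(1, (int)(n * val_frac));
  if (nval >= n) nval = n / 5 + 1;
  int ntr = n - nval;
  arma::uvec tr(ntr), va(nval);
  for (int i = 0; i < ntr; ++i) tr[i] = perm[i];
  for (int i = 0; i < nval; ++i) va[i] = perm[ntr + i];
  arma::mat Xtr = X.rows(tr), Xva = X.rows(va);
  arma::vec ytr = y.elem(tr), yva = y.elem(va);

  double sc = std::sqrt(6.0 / (p + hidden));
  arma::mat W1 = rand_mat(p, hidden, sc), b1(1, hidden, arma::fill::zeros);
  arma::mat W2 = rand_mat(hidden, 1, std::sqrt(6.0 / (hidden + 1)));
  arma::mat b2(1, 1, arma::fill::zeros);
  std::vector<arma::mat*> params = {&W1, &b1, &W2, &b2};
  Adam opt(lr);
  opt.init(params);

  auto val_loss = [&]() {
    arma::mat H = Xva * W1;
    H.each_row() += b1;
    H.transform([](double z) { return z > 0 ? z : 0.0; });
    arma::vec o = 1.0 / (1.0 + arma::exp(-(H * W2 + b2(0, 0))));
    o = arma::clamp(o, 1e-9, 1 - 1e-9);
    return -arma::mean(yva % arma::log(o) + (1 - yva) % arma::log(1 - o));
  };

  double best = val_loss();
  arma::mat bW1 = W1, bb1 = b1, bW2 = W2, bb2 = b2;
  int bad = 0;
  std::vector<int> ord(ntr);
  for (int i = 0; i < ntr; ++i) ord[i] = i;
  for (int ep = 0; ep < max_epochs; ++ep) {
    for (int i = ntr - 1; i > 0; --i) std::swap(ord[i], ord[runif_int(i + 1)]);
    for (int s = 0; s < ntr; s += batch) {
      int e = std::min(ntr, s + batch);
      arma::uvec bi(e - s);
      for (int i = s; i < e; ++i) bi[i - s] = ord[i];
      arma::mat Xb = Xtr.rows(bi);
      arma::vec yb = ytr.elem(bi);
      int nb = Xb.n_rows;
      arma::mat Z = Xb * W1;
      Z.each_row() += b1;
      arma::mat H = Z;
      H.transform([](double z) { return z > 0 ? z : 0.0; });
      arma::vec o = 1.0 / (1.0 + arma::exp(-(H * W2 + b2(0, 0))));
      arma::vec d = (o - yb) / nb;                 // dL/dlogit
      arma::mat gW2 = H.t() * d;
      arma::mat gb2(1, 1); gb2(0, 0) = arma::accu(d);
      arma::mat dH = d * W2.t();
      dH.elem(arma::find(Z <= 0)).zeros();
      arma::mat gW1 = Xb.t() * dH;
      arma::mat gb1 = arma::sum(dH, 0);
      std::vector<arma::mat*> grads = {&gW1, &gb1, &gW2, &gb2};
      opt.step(params, grads);
    }
    double vl = val_loss();
    if (vl < best - 1e-6) {
      best = vl; bad = 0;
      bW1 = W1; bb1 = b1; bW2 = W2; bb2 = b2;
    } else if (++bad >= patience) break;
  }
  return List::create(_["W1"] = bW1, _["b1"] = bb1, _["W2"] = bW2,
                      _["b2"] = bb2);
}

// [[Rcpp::export]]
arma::vec cpp_predict_mlp(const List& model, const arma::mat& X) {
  arma::mat W1 = model["W1"], b1 = model["b1"], W2 = model["W2"],
            b2 = model["b2"];
  arma::mat H = X * W1;
  H.each_row() += arma::rowvec(b1.row(0));
  H.transform([](double z) { return z > 0 ? z : 0.0; });
  return 1.0 / (1.0 + arma::exp(-(H * W2 + b2(0, 0))));
}

// ---------------------------------------------------------------------------
// Single-cell GRU / LSTM with sigmoid head, BCE loss, Adam
// ---------------------------------------------------------------------------

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// X: cube (features, time, windows); y in {0,1}.
// cell: 0 = GRU, 1 = LSTM. Returns weights; training loss per epoch.
// [[Rcpp::export]]
List cpp_train_rnn(const arma::cube& X, const arma::vec& y, int cell,
                   int hidden, int epochs, int batch, double lr) {
  int F = X.n_rows, T = X.n_cols, N = X.n_slices;
  int G = (cell == 0) ? 3 : 4;                  // gates
  double sc = 1.0 / std::sqrt((double)hidden);
  arma::mat W = rand_mat(F, G * hidden, sc);    // input weights
  arma::mat U = rand_mat(hidden, G * hidden, sc);
  arma::mat b(1, G * hidden, arma::fill::zeros);
  arma::mat wo = rand_mat(hidden, 1, sc);
  arma::mat bo(1, 1, arma::fill::zeros);
  std::vector<arma::mat*> params = {&W, &U, &b, &wo, &bo};
  Adam opt(lr);
  opt.init(params);

  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  arma::vec epoch_loss(epochs, arma::fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = N - 1; i > 0; --i) std::swap(ord[i], ord[runif_int(i + 1)]);
    double tot_loss = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int e0 = std::min(N, s0 + batch);
      int nb = e0 - s0;
      // gather batch: Xt per step as nb x F
      std::vector<arma::mat> Xt(T);
      arma::vec yb(nb);
      for (int t = 0; t < T; ++t) Xt[t].set_size(nb, F);
      for (int i = 0; i < nb; ++i) {
        int w = ord[s0 + i];
        yb[i] = y[w];
        const arma::mat& sl = X.slice(w);      // F x T, columns contiguous
        for (int t = 0; t < T; ++t) {
          const double* src = sl.colptr(t);
          arma::mat& M = Xt[t];
          for (int f = 0; f < F; ++f) M(i, f) = src[f];
        }
      }
      // forward
      std::vector<arma::mat> Hs(T + 1), Cs, Za(T), Zb(T), Zc(T), Zd;
      Hs[0] = arma::mat(nb, hidden, arma::fill::zeros);
      if (cell == 1) {
        Cs.assign(T + 1, arma::mat());
        Cs[0] = arma::mat(nb, hidden, arma::fill::zeros);
        Zd.assign(T, arma::mat());
      }
      for (int t = 0; t < T; ++t) {
        arma::mat A = Xt[t] * W + Hs[t] * U;
        A.each_row() += b.row(0);
        if (cell == 0) {  // GRU: z, r, candidate (candidate uses r .* h)
          arma::mat z = sigm(A.cols(0, hidden - 1));
          arma::mat r = sigm(A.cols(hidden, 2 * hidden - 1));
          // recompute candidate pre-activation with gated state
          arma::mat Ah = Xt[t] * W.cols(2 * hidden, 3 * hidden - 1) +
                         (r % Hs[t]) * U.cols(2 * hidden, 3 * hidden - 1);
          Ah.each_row() += b.cols(2 * hidden, 3 * hidden - 1).row(0);
          arma::mat hh = arma::tanh(Ah);
          Hs[t + 1] = (1 - z) % Hs[t] + z % hh;
          Za[t] = z; Zb[t] = r; Zc[t] = hh;
        } else {          // LSTM: i, f, o, g
          arma::mat ig = sigm(A.cols(0, hidden - 1));
          arma::mat fg = sigm(A.cols(hidden, 2 * hidden - 1));
          arma::mat og = sigm(A.cols(2 * hidden, 3 * hidden - 1));
          arma::mat gg = arma::tanh(A.cols(3 * hidden, 4 * hidden - 1));
          Cs[t + 1] = fg % Cs[t] + ig % gg;
          Hs[t + 1] = og % arma::tanh(Cs[t + 1]);
          Za[t] = ig; Zb[t] = fg; Zc[t] = og; Zd[t] = gg;
        }
      }
      arma::vec o = arma::clamp(sigm(Hs[T] * wo + bo(0, 0)), 1e-9, 1 - 1e-9);
      tot_loss += -arma::accu(yb % arma::log(o) +
                              (1 - yb) % arma::log(1 - o));
      // backward
      arma::mat gW(F, G * hidden, arma::fill::zeros);
      arma::mat gU(hidden, G * hidden, arma::fill::zeros);
      arma::mat gb(1, G * hidden, arma::fill::zeros);
      arma::vec dlogit = (o - yb) / nb;
      arma::mat gwo = Hs[T].t() * dlogit;
      arma::mat gbo(1, 1); gbo(0, 0) = arma::accu(dlogit);
      arma::mat dH = dlogit * wo.t();
      arma::mat dC;
      if (cell == 1) dC = arma::mat(nb, hidden, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        if (cell == 0) {
          const arma::mat &z = Za[t], &r = Zb[t], &hh = Zc[t];
          arma::mat dz = dH % (hh - Hs[t]) % z % (1 - z);
          arma::mat dhh = dH % z % (1 - hh % hh);
          arma::mat Uh = U.cols(2 * hidden, 3 * hidden - 1);
          arma::mat drh = dhh * Uh.t();       // grad wrt (r % h)
          arma::mat dr = drh % Hs[t] % r % (1 - r);
          arma::mat Az(nb, 2 * hidden);
          Az.cols(0, hidden - 1) = dz;
          Az.cols(hidden, 2 * hidden - 1) = dr;
          gW.cols(0, 2 * hidden - 1) += Xt[t].t() * Az;
          gU.cols(0, 2 * hidden - 1) += Hs[t].t() * Az;
          gb.cols(0, 2 * hidden - 1) += arma::sum(Az, 0);
          gW.cols(2 * hidden, 3 * hidden - 1) += Xt[t].t() * dhh;
          gU.cols(2 * hidden, 3 * hidden - 1) += (Zb[t] % Hs[t]).t() * dhh;
          gb.cols(2 * hidden, 3 * hidden - 1) += arma::sum(dhh, 0);
          arma::mat dHprev = dH % (1 - z) + drh % r +
            dz * U.cols(0, hidden - 1).t() +
            dr * U.cols(hidden, 2 * hidden - 1).t();
          dH = dHprev;
        } else {
          const arma::mat &ig = Za[t], &fg = Zb[t], &og = Zc[t],
                          &gg = Zd[t];
          arma::mat tc = arma::tanh(Cs[t + 1]);
          arma::mat dc = dC + dH % og % (1 - tc % tc);
          arma::mat do_ = dH % tc % og % (1 - og);
          arma::mat di = dc % gg % ig % (1 - ig);
          arma::mat df = dc % Cs[t] % fg % (1 - fg);
          arma::mat dg = dc % ig % (1 - gg % gg);
          arma::mat A(nb, 4 * hidden);
          A.cols(0, hidden - 1) = di;
          A.cols(hidden, 2 * hidden - 1) = df;
          A.cols(2 * hidden, 3 * hidden - 1) = do_;
          A.cols(3 * hidden, 4 * hidden - 1) = dg;
          gW += Xt[t].t() * A;
          gU += Hs[t].t() * A;
          gb += arma::sum(A, 0);
          dH = A * U.t();
          dC = dc % fg;
        }
      }
      std::vector<arma::mat*> grads = {&gW, &gU, &gb, &gwo, &gbo};
      opt.step(params, grads);
    }
    epoch_loss[ep] = tot_loss / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["W"] = W, _["U"] = U, _["b"] = b, _["wo"] = wo,
                      _["bo"] = bo, _["cell"] = cell, _["hidden"] = hidden,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
arma::vec cpp_predict_rnn(const List& model, const arma::cube& X) {
  arma::mat W = model["W"], U = model["U"], b = model["b"], wo = model["wo"],
            bo = model["bo"];
  int cell = model["cell"], hidden = model["hidden"];
  int F = X.n_rows, T = X.n_cols, N = X.n_slices;
  arma::mat H(N, hidden, arma::fill::zeros), C;
  if (cell == 1) C = arma::mat(N, hidden, arma::fill::zeros);
  arma::mat Xt(N, F);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i)
      for (int f = 0; f < F; ++f) Xt(i, f) = X(f, t, i);
    arma::mat A = Xt * W + H * U;
    A.each_row() += b.row(0);
    if (cell == 0) {
      arma::mat z = sigm(A.cols(0, hidden - 1));
      arma::mat r = sigm(A.cols(hidden, 2 * hidden - 1));
      arma::mat Ah = Xt * W.cols(2 * hidden, 3 * hidden - 1) +
                     (r % H) * U.cols(2 * hidden, 3 * hidden - 1);
      Ah.each_row() += b.cols(2 * hidden, 3 * hidden - 1).row(0);
      arma::mat hh = arma::tanh(Ah);
      H = (1 - z) % H + z % hh;
    } else {
      arma::mat ig = sigm(A.cols(0, hidden - 1));
      arma::mat fg = sigm(A.cols(hidden, 2 * hidden - 1));
      arma::mat og = sigm(A.cols(2 * hidden, 3 * hidden - 1));
      arma::mat gg = arma::tanh(A.cols(3 * hidden, 4 * hidden - 1));
      C = fg % C + ig % gg;
      H = og % arma::tanh(C);
    }
  }
  return sigm(H * wo + bo(0, 0));
}
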