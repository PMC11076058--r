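// Batched forward/backward kernels for the recurrent backbone:
// two stacked GRU layers (gate order r, z, n; per-gate input and recurrent
// biases) followed by a per-timestep dense projection back to feature space,
// plus an optional 6-unit dense head applied to the temporal mean of the
// projection.
//
// Sequences in a batch are sorted by decreasing length and zero-padded to
// the longest clip; at each timestep only the columns of still-active
// sequences are touched, so padding costs nothing and padded positions are
// excluded from states, losses and temporal means. Sorting permutes only
// the within-batch column order, which leaves losses and gradients
// unchanged; per-clip outputs are un-permuted before returning.
//
// Gradients are exact analytic backprop through time; a finite-difference
// test on small layers guards the derivation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

namespace {

struct Params {
  mat W1, U1, W2, U2, Wd, Wh;
  vec b1i, b1h, b2i, b2h, bd, bh;
  bool has_head = false;
};

Params unpack(const List& p) {
  Params P;
  P.W1  = Rcpp::as<mat>(p["W1"]);
  P.U1  = Rcpp::as<mat>(p["U1"]);
  P.b1i = Rcpp::as<vec>(p["b1i"]);
  P.b1h = Rcpp::as<vec>(p["b1h"]);
  P.W2  = Rcpp::as<mat>(p["W2"]);
  P.U2  = Rcpp::as<mat>(p["U2"]);
  P.b2i = Rcpp::as<vec>(p["b2i"]);
  P.b2h = Rcpp::as<vec>(p["b2h"]);
  P.Wd  = Rcpp::as<mat>(p["Wd"]);
  P.bd  = Rcpp::as<vec>(p["bd"]);
  if (p.containsElementNamed("Wh")) {
    P.Wh = Rcpp::as<mat>(p["Wh"]);
    P.bh = Rcpp::as<vec>(p["bh"]);
    P.has_head = true;
  }
  return P;
}

// Batch layout shared by all kernels: clip b of the R-level list sits in
// column order[b] has no meaning here -- column j holds clip perm[j].
struct Batch {
  cube X;        // (F x B x Tmax), zero-padded, columns sorted by length desc
  uvec lens;     // sorted lengths
  uvec perm;     // perm[j] = original index of column j
  uvec active;   // active[t] = number of sequences with len > t
};

// Stack (T_i x F) clip matrices into the sorted padded layout. When `like`
// is non-null its permutation is reused (for input/target pairs).
Batch pad_clips(const List& xs, const Batch* like = nullptr) {
  const unsigned B = xs.size();
  std::vector<mat> tmp(B);
  uvec raw_lens(B);
  unsigned F = 0;
  for (unsigned b = 0; b < B; ++b) {
    tmp[b] = Rcpp::as<mat>(xs[b]).t();  // F x T_b
    raw_lens[b] = tmp[b].n_cols;
    F = tmp[b].n_rows;
  }
  Batch bt;
  bt.perm = like ? like->perm : stable_sort_index(raw_lens, "descend");
  bt.lens.set_size(B);
  for (unsigned j = 0; j < B; ++j) bt.lens[j] = raw_lens[bt.perm[j]];
  const unsigned Tmax = bt.lens[0];
  bt.active.set_size(Tmax);
  for (unsigned t = 0; t < Tmax; ++t) {
    unsigned nb = 0;
    while (nb < B && bt.lens[nb] > t) ++nb;
    bt.active[t] = nb;
  }
  bt.X.zeros(F, B, Tmax);
  for (unsigned j = 0; j < B; ++j) {
    const mat& m = tmp[bt.perm[j]];
    for (unsigned t = 0; t < bt.lens[j]; ++t) bt.X.slice(t).col(j) = m.col(t);
  }
  return bt;
}

struct LayerCache {
  cube H, R, Z, N, C;  // each (h x B x T)
};

void gru_forward(const mat& W, const mat& U, const vec& bi, const vec& bh_,
                 const cube& X, const Batch& bt, LayerCache& cc) {
  const unsigned d = X.n_rows, B = X.n_cols, T = X.n_slices;
  const unsigned h = U.n_cols;
  cc.H.zeros(h, B, T); cc.R.zeros(h, B, T); cc.Z.zeros(h, B, T);
  cc.N.zeros(h, B, T); cc.C.zeros(h, B, T);

  const mat Xm(const_cast<double*>(X.memptr()), d, B * T, false, true);
  mat G = W * Xm;          // (3h x B*T), input contributions for all t
  G.each_col() += bi;

  mat hprev(h, B, fill::zeros), rec;
  for (unsigned t = 0; t < T; ++t) {
    const unsigned nb = bt.active[t];
    if (nb == 0) break;
    rec = U * hprev.cols(0, nb - 1);
    rec.each_col() += bh_;
    const auto g = G.cols(t * B, t * B + nb - 1);
    mat& r = cc.R.slice(t);
    mat& z = cc.Z.slice(t);
    mat& c = cc.C.slice(t);
    mat& n = cc.N.slice(t);
    mat& ht = cc.H.slice(t);
    r.cols(0, nb - 1) =
        1.0 / (1.0 + exp(-(g.rows(0, h - 1) + rec.rows(0, h - 1))));
    z.cols(0, nb - 1) =
        1.0 / (1.0 + exp(-(g.rows(h, 2 * h - 1) + rec.rows(h, 2 * h - 1))));
    c.cols(0, nb - 1) = rec.rows(2 * h, 3 * h - 1);
    n.cols(0, nb - 1) = tanh(g.rows(2 * h, 3 * h - 1) +
                             r.cols(0, nb - 1) % c.cols(0, nb - 1));
    ht.cols(0, nb - 1) =
        (1.0 - z.cols(0, nb - 1)) % n.cols(0, nb - 1) +
        z.cols(0, nb - 1) % hprev.cols(0, nb - 1);
    hprev = ht;
  }
}

struct LayerGrads {
  mat dW, dU;
  vec dbi, dbh;
};

// Backward through one GRU layer. dHout holds dL/dh_t (padded cols zero).
void gru_backward(const mat& W, const mat& U, const cube& X,
                  const LayerCache& cc, const Batch& bt, const cube& dHout,
                  bool need_dx, LayerGrads& g, cube& dX) {
  const unsigned d = X.n_rows, B = X.n_cols, T = X.n_slices;
  const unsigned h = U.n_cols;
  cube DA(3 * h, B, T, fill::zeros);   // da_r, da_z, da_n stacked
  cube DAU(3 * h, B, T, fill::zeros);  // da_r, da_z, dc stacked
  if (need_dx) dX.zeros(d, B, T);

  mat dh(h, B, fill::zeros);
  const mat zeros_hB(h, B, fill::zeros);
  const mat Wt = W.t(), Ut = U.t();
  for (int t = T - 1; t >= 0; --t) {
    const unsigned nb = bt.active[t];
    if (nb == 0) continue;
    const unsigned j1 = nb - 1;
    dh.cols(0, j1) += dHout.slice(t).cols(0, j1);
    const mat& hprev_full = (t > 0) ? cc.H.slice(t - 1) : zeros_hB;
    const auto hprev = hprev_full.cols(0, j1);
    const auto r = cc.R.slice(t).cols(0, j1);
    const auto z = cc.Z.slice(t).cols(0, j1);
    const auto n = cc.N.slice(t).cols(0, j1);
    const auto c = cc.C.slice(t).cols(0, j1);
    const auto dha = dh.cols(0, j1);

    mat& da = DA.slice(t);
    mat& dau = DAU.slice(t);
    da.submat(h, 0, 2 * h - 1, j1) = (dha % (hprev - n)) % z % (1.0 - z);
    da.submat(2 * h, 0, 3 * h - 1, j1) = (dha % (1.0 - z)) % (1.0 - n % n);
    const auto dan = da.submat(2 * h, 0, 3 * h - 1, j1);
    da.submat(0, 0, h - 1, j1) = (dan % c) % r % (1.0 - r);
    dau.submat(0, 0, 2 * h - 1, j1) = da.submat(0, 0, 2 * h - 1, j1);
    dau.submat(2 * h, 0, 3 * h - 1, j1) = dan % r;

    if (need_dx) dX.slice(t).cols(0, j1) = Wt * da.cols(0, j1);
    const mat dh_new = dha % z + Ut * dau.cols(0, j1);
    dh.cols(0, j1) = dh_new;
  }

  // Weight gradients in two large GEMMs over all timesteps (padded
  // columns are zero and contribute nothing).
  const mat Xm(const_cast<double*>(X.memptr()), d, B * T, false, true);
  const mat DAm(DA.memptr(), 3 * h, B * T, false, true);
  const mat DAUm(DAU.memptr(), 3 * h, B * T, false, true);
  cube HP(h, B, T);
  HP.slice(0).zeros();
  for (unsigned t = 1; t < T; ++t) HP.slice(t) = cc.H.slice(t - 1);
  const mat HPm(HP.memptr(), h, B * T, false, true);

  g.dW = DAm * Xm.t();
  g.dU = DAUm * HPm.t();
  g.dbi = sum(DAm, 1);
  g.dbh = sum(DAUm, 1);
}

struct ForwardCache {
  Batch bt;
  LayerCache l1, l2;
  cube Y;          // dense projection output (Fout x B x T)
};

void backbone_forward(const Params& P, const List& xs, ForwardCache& fc) {
  fc.bt = pad_clips(xs);
  gru_forward(P.W1, P.U1, P.b1i, P.b1h, fc.bt.X, fc.bt, fc.l1);
  gru_forward(P.W2, P.U2, P.b2i, P.b2h, fc.l1.H, fc.bt, fc.l2);
  const unsigned B = fc.bt.X.n_cols, T = fc.bt.X.n_slices;
  const unsigned Fo = P.Wd.n_rows;
  const mat H2m(fc.l2.H.memptr(), P.Wd.n_cols, B * T, false, true);
  mat Ym = P.Wd * H2m;
  Ym.each_col() += P.bd;
  fc.Y = cube(Ym.memptr(), Fo, B, T);
  for (unsigned t = 0; t < T; ++t) {
    mat& ys = fc.Y.slice(t);
    for (unsigned j = fc.bt.active[t]; j < B; ++j) ys.col(j).zeros();
  }
}

// Shared tail of both training objectives: backprop dY through the dense
// projection and both GRU layers, returning the full backbone gradient list.
List backbone_backward(const Params& P, ForwardCache& fc, const cube& dY) {
  const unsigned B = fc.bt.X.n_cols, T = fc.bt.X.n_slices;
  const unsigned h2 = P.Wd.n_cols;
  const mat dYm(const_cast<double*>(dY.memptr()), P.Wd.n_rows, B * T, false,
                true);
  const mat H2m(fc.l2.H.memptr(), h2, B * T, false, true);
  mat dWd = dYm * H2m.t();
  vec dbd = sum(dYm, 1);
  mat dH2m = P.Wd.t() * dYm;
  cube dH2(dH2m.memptr(), h2, B, T);

  LayerGrads g2, g1;
  cube dH1;
  gru_backward(P.W2, P.U2, fc.l1.H, fc.l2, fc.bt, dH2, true, g2, dH1);
  cube dX_unused;
  gru_backward(P.W1, P.U1, fc.bt.X, fc.l1, fc.bt, dH1, false, g1, dX_unused);

  return List::create(
      Named("W1") = g1.dW, Named("U1") = g1.dU,
      Named("b1i") = g1.dbi, Named("b1h") = g1.dbh,
      Named("W2") = g2.dW, Named("U2") = g2.dU,
      Named("b2i") = g2.dbi, Named("b2h") = g2.dbh,
      Named("Wd") = dWd, Named("bd") = dbd);
}

mat pool_means(const ForwardCache& fc) {
  const unsigned Fo = fc.Y.n_rows, B = fc.Y.n_cols, T = fc.Y.n_slices;
  mat pooled(Fo, B, fill::zeros);
  for (unsigned t = 0; t < T; ++t) pooled += fc.Y.slice(t);
  for (unsigned j = 0; j < B; ++j) pooled.col(j) /= double(fc.bt.lens[j]);
  return pooled;
}

double recon_loss_and_delta(const ForwardCache& fc, const cube& Tgt,
                            bool loss_on_masked, const uvec& t0s,
                            const uvec& t1s, cube* dY) {
  const unsigned B = fc.bt.X.n_cols;
  double sse = 0.0, n_cells = 0.0;
  if (dY) dY->zeros(fc.Y.n_rows, B, fc.Y.n_slices);
  for (unsigned j = 0; j < B; ++j) {
    unsigned t0 = 0, t1 = fc.bt.lens[j];
    if (loss_on_masked) { t0 = t0s[j]; t1 = t1s[j]; }
    for (unsigned t = t0; t < t1; ++t) {
      vec diff = fc.Y.slice(t).col(j) - Tgt.slice(t).col(j);
      sse += dot(diff, diff);
      if (dY) dY->slice(t).col(j) = diff;
      n_cells += fc.Y.n_rows;
    }
  }
  if (dY) (*dY) *= 2.0 / n_cells;
  return sse / n_cells;
}

// Per-column mask bounds in the sorted layout (0-based, half-open).
void sorted_mask_bounds(const Batch& bt, const Rcpp::IntegerVector& mask_start,
                        const Rcpp::IntegerVector& mask_len, uvec& t0s,
                        uvec& t1s) {
  const unsigned B = bt.perm.n_elem;
  t0s.set_size(B);
  t1s.set_size(B);
  for (unsigned j = 0; j < B; ++j) {
    t0s[j] = (unsigned)(mask_start[bt.perm[j]] - 1);
    t1s[j] = t0s[j] + (unsigned)mask_len[bt.perm[j]];
  }
}

}  // namespace

// Reconstruction loss and gradients for one pretraining batch.
// xs_masked / xs_target: lists of (T_i x F) matrices. When loss_on_masked,
// only rows [mask_start_i, mask_start_i + mask_len_i) enter the loss
// (1-based starts); otherwise all valid timesteps do.
// [[Rcpp::export]]
List cpp_recon_grad(List params, List xs_masked, List xs_target,
                    bool loss_on_masked,
                    Rcpp::IntegerVector mask_start,
                    Rcpp::IntegerVector mask_len) {
  Params P = unpack(params);
  ForwardCache fc;
  backbone_forward(P, xs_masked, fc);
  Batch tgt = pad_clips(xs_target, &fc.bt);

  uvec t0s, t1s;
  sorted_mask_bounds(fc.bt, mask_start, mask_len, t0s, t1s);
  cube dY;
  const double loss =
      recon_loss_and_delta(fc, tgt.X, loss_on_masked, t0s, t1s, &dY);
  List grads = backbone_backward(P, fc, dY);
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// Emotion-regression loss and gradients for one batch of a jointly trained
// (unfrozen) model: MSE between head(mean_t backbone(x)) and 6-dim labels.
// y: (6 x B) matrix of true intensities, in the order of xs.
// [[Rcpp::export]]
List cpp_emotion_grad(List params, List xs, arma::mat y) {
  Params P = unpack(params);
  if (!P.has_head) Rcpp::stop("parameters lack an emotion head");
  ForwardCache fc;
  backbone_forward(P, xs, fc);
  const unsigned B = fc.bt.X.n_cols, T = fc.bt.X.n_slices;

  mat y_sorted = y.cols(fc.bt.perm);
  mat pooled = pool_means(fc);
  mat pred = P.Wh * pooled;
  pred.each_col() += P.bh;
  mat diff = pred - y_sorted;
  const double n_cells = double(diff.n_elem);
  const double loss = accu(diff % diff) / n_cells;

  mat dpred = diff * (2.0 / n_cells);
  mat dWh = dpred * pooled.t();
  vec dbh = sum(dpred, 1);
  mat dpooled = P.Wh.t() * dpred;
  cube dY(fc.Y.n_rows, B, T, fill::zeros);
  for (unsigned j = 0; j < B; ++j)
    for (unsigned t = 0; t < fc.bt.lens[j]; ++t)
      dY.slice(t).col(j) = dpooled.col(j) / double(fc.bt.lens[j]);

  List grads = backbone_backward(P, fc, dY);
  grads["Wh"] = dWh;
  grads["bh"] = dbh;
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// Forward pass only. Returns per-clip dense projections (T_i x F), the
// temporal-mean pooled features (B x F), and head predictions (B x 6) when
// the parameter list carries a head. Output order matches the input list.
// [[Rcpp::export]]
List cpp_forward(List params, List xs, bool return_sequences) {
  Params P = unpack(params);
  ForwardCache fc;
  backbone_forward(P, xs, fc);
  const unsigned B = fc.bt.X.n_cols;

  mat pooled = pool_means(fc);
  uvec inv(B);
  for (unsigned j = 0; j < B; ++j) inv[fc.bt.perm[j]] = j;

  List out;
  if (return_sequences) {
    List ys(B);
    for (unsigned b = 0; b < B; ++b) {
      const unsigned j = inv[b];
      mat Yb(fc.Y.n_rows, fc.bt.lens[j]);
      for (unsigned t = 0; t < fc.bt.lens[j]; ++t)
        Yb.col(t) = fc.Y.slice(t).col(j);
      ys[b] = Yb.t();  // back to (T x F)
    }
    out["sequences"] = ys;
  }
  out["pooled"] = mat(pooled.cols(inv)).t();
  if (P.has_head) {
    mat pred = P.Wh * pooled;
    pred.each_col() += P.bh;
    out["predictions"] = mat(pred.cols(inv)).t();
  }
  return out;
}

// Held-out reconstruction error without gradients (mean squared error over
// the same cells cpp_recon_grad would use).
// [[Rcpp::export]]
double cpp_recon_loss(List params, List xs_masked, List xs_target,
                      bool loss_on_masked,
                      Rcpp::IntegerVector mask_start,
                      Rcpp::IntegerVector mask_len) {
  Params P = unpack(params);
  ForwardCache fc;
  backbone_forward(P, xs_masked, fc);
  Batch tgt = pad_clips(xs_target, &fc.bt);
  uvec t0s, t1s;
  sorted_mask_bounds(fc.bt, mask_start, mask_len, t0s, t1s);
  return recon_loss_and_delta(fc, tgt.X, loss_on_masked, t0s, t1s, nullptr);
}
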