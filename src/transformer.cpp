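// BERT-style encoder for coded clinical sequences: summed input-embedding
// channels, multi-head self-attention layers with LayerNorm residual blocks,
// GELU feed-forward, and a linear masked-token prediction head.
// Forward + analytic backward over a batch of (short) sequences; gradients are
// accumulated unscaled together with the summed cross-entropy loss so the
// caller can normalise by the number of predicted positions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-12;

struct LNCache { mat xhat; vec inv_sd; };

static mat layernorm_fwd(const mat& X, const rowvec& g, const rowvec& b,
                         LNCache& c) {
  int T = X.n_rows, H = X.n_cols;
  mat Y(T, H);
  c.xhat.set_size(T, H);
  c.inv_sd.set_size(T);
  for (int t = 0; t < T; ++t) {
    rowvec x = X.row(t);
    double mu = arma::mean(x);
    double var = arma::mean(arma::square(x - mu));
    double is = 1.0 / std::sqrt(var + LN_EPS);
    rowvec xh = (x - mu) * is;
    c.xhat.row(t) = xh;
    c.inv_sd(t) = is;
    Y.row(t) = xh % g + b;
  }
  return Y;
}

static mat layernorm_bwd(const mat& dY, const LNCache& c, const rowvec& g,
                         mat& dg, mat& db) {
  int T = dY.n_rows, H = dY.n_cols;
  mat dX(T, H);
  dg += arma::sum(dY % c.xhat, 0);
  db += arma::sum(dY, 0);
  for (int t = 0; t < T; ++t) {
    rowvec dyg = dY.row(t) % g;
    double m1 = arma::mean(dyg);
    double m2 = arma::mean(dyg % c.xhat.row(t));
    dX.row(t) = c.inv_sd(t) * (dyg - m1 - c.xhat.row(t) * m2);
  }
  return dX;
}

static inline double gelu(double x) {
  return 0.5 * x * (1.0 + std::erf(x * M_SQRT1_2));
}
static inline double gelu_grad(double x) {
  double cdf = 0.5 * (1.0 + std::erf(x * M_SQRT1_2));
  double pdf = std::exp(-0.5 * x * x) / std::sqrt(2.0 * M_PI);
  return cdf + x * pdf;
}

struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

struct LayerCache {
  mat E_in, Q, K, V, Ccat, R1pre, H1, F1, G;
  std::vector<mat> A;   // per-head attention weights
  LNCache ln1, ln2;
};

static rowvec as_rowvec(SEXP s) {
  NumericVector v(s);
  rowvec r(v.size());
  for (int i = 0; i < v.size(); ++i) r(i) = v[i];
  return r;
}

// [[Rcpp::export]]
List bert_batch_cpp(List channel_ids, List labels, List params, int n_heads,
                    bool want_grads, int hidden_layer) {
  List r_tables = params["tables"];
  int n_ch = r_tables.size();
  std::vector<mat> tables(n_ch);
  for (int c = 0; c < n_ch; ++c) tables[c] = as<mat>(r_tables[c]);
  rowvec ln0_g = as_rowvec(params["ln0_g"]);
  rowvec ln0_b = as_rowvec(params["ln0_b"]);
  List r_layers = params["layers"];
  int L = r_layers.size();
  std::vector<LayerParams> layers(L);
  for (int l = 0; l < L; ++l) {
    List rl = r_layers[l];
    layers[l].Wq = as<mat>(rl["Wq"]); layers[l].Wk = as<mat>(rl["Wk"]);
    layers[l].Wv = as<mat>(rl["Wv"]); layers[l].Wo = as<mat>(rl["Wo"]);
    layers[l].W1 = as<mat>(rl["W1"]); layers[l].W2 = as<mat>(rl["W2"]);
    layers[l].bq = as_rowvec(rl["bq"]); layers[l].bk = as_rowvec(rl["bk"]);
    layers[l].bv = as_rowvec(rl["bv"]); layers[l].bo = as_rowvec(rl["bo"]);
    layers[l].b1 = as_rowvec(rl["b1"]); layers[l].b2 = as_rowvec(rl["b2"]);
    layers[l].ln1_g = as_rowvec(rl["ln1_g"]);
    layers[l].ln1_b = as_rowvec(rl["ln1_b"]);
    layers[l].ln2_g = as_rowvec(rl["ln2_g"]);
    layers[l].ln2_b = as_rowvec(rl["ln2_b"]);
  }
  mat Wout = as<mat>(params["Wout"]);
  rowvec bout = as_rowvec(params["bout"]);

  int H = tables[0].n_cols;
  int dh = H / n_heads;
  double scale = 1.0 / std::sqrt((double)dh);
  int Vtok = Wout.n_cols;

  // gradient accumulators
  std::vector<mat> g_tables;
  mat g_ln0_g, g_ln0_b, g_Wout, g_bout;
  std::vector<LayerParams> g_layers;
  if (want_grads) {
    g_tables.resize(n_ch);
    for (int c = 0; c < n_ch; ++c)
      g_tables[c] = arma::zeros<mat>(tables[c].n_rows, H);
    g_ln0_g = arma::zeros<mat>(1, H);
    g_ln0_b = arma::zeros<mat>(1, H);
    g_Wout = arma::zeros<mat>(H, Vtok);
    g_bout = arma::zeros<mat>(1, Vtok);
    g_layers.resize(L);
    for (int l = 0; l < L; ++l) {
      int I = layers[l].W1.n_cols;
      g_layers[l].Wq = arma::zeros<mat>(H, H);
      g_layers[l].Wk = arma::zeros<mat>(H, H);
      g_layers[l].Wv = arma::zeros<mat>(H, H);
      g_layers[l].Wo = arma::zeros<mat>(H, H);
      g_layers[l].W1 = arma::zeros<mat>(H, I);
      g_layers[l].W2 = arma::zeros<mat>(I, H);
      g_layers[l].bq = arma::zeros<rowvec>(H);
      g_layers[l].bk = arma::zeros<rowvec>(H);
      g_layers[l].bv = arma::zeros<rowvec>(H);
      g_layers[l].bo = arma::zeros<rowvec>(H);
      g_layers[l].b1 = arma::zeros<rowvec>(I);
      g_layers[l].b2 = arma::zeros<rowvec>(H);
      g_layers[l].ln1_g = arma::zeros<rowvec>(H);
      g_layers[l].ln1_b = arma::zeros<rowvec>(H);
      g_layers[l].ln2_g = arma::zeros<rowvec>(H);
      g_layers[l].ln2_b = arma::zeros<rowvec>(H);
    }
  }

  int B = channel_ids.size();
  double loss_sum = 0.0;
  int n_labels = 0, n_correct = 0;
  List hidden_out(hidden_layer >= 0 ? B : 0);

  for (int b = 0; b < B; ++b) {
    IntegerMatrix ids = channel_ids[b];   // n_ch x T, 0-based
    int T = ids.ncol();
    IntegerVector lab = labels.size() > b ? (IntegerVector)labels[b]
                                          : IntegerVector(T, -1);

    // --- embedding sum + LayerNorm
    mat X0 = arma::zeros<mat>(T, H);
    for (int c = 0; c < n_ch; ++c)
      for (int t = 0; t < T; ++t)
        X0.row(t) += tables[c].row(ids(c, t));
    LNCache ln0;
    mat E = layernorm_fwd(X0, ln0_g, ln0_b, ln0);
    if (hidden_layer == 0) hidden_out[b] = wrap(E);

    // --- encoder layers
    std::vector<LayerCache> caches(L);
    for (int l = 0; l < L; ++l) {
      LayerCache& cc = caches[l];
      const LayerParams& lp = layers[l];
      cc.E_in = E;
      cc.Q = E * lp.Wq; cc.Q.each_row() += lp.bq;
      cc.K = E * lp.Wk; cc.K.each_row() += lp.bk;
      cc.V = E * lp.Wv; cc.V.each_row() += lp.bv;
      cc.Ccat.set_size(T, H);
      cc.A.resize(n_heads);
      for (int h = 0; h < n_heads; ++h) {
        mat Qh = cc.Q.cols(h * dh, (h + 1) * dh - 1);
        mat Kh = cc.K.cols(h * dh, (h + 1) * dh - 1);
        mat Vh = cc.V.cols(h * dh, (h + 1) * dh - 1);
        mat S = Qh * Kh.t() * scale;
        mat A(T, T);
        for (int t = 0; t < T; ++t) {
          rowvec s = S.row(t);
          s -= s.max();
          rowvec e = arma::exp(s);
          A.row(t) = e / arma::accu(e);
        }
        cc.A[h] = A;
        cc.Ccat.cols(h * dh, (h + 1) * dh - 1) = A * Vh;
      }
      mat O = cc.Ccat * lp.Wo; O.each_row() += lp.bo;
      cc.R1pre = E + O;
      cc.H1 = layernorm_fwd(cc.R1pre, lp.ln1_g, lp.ln1_b, cc.ln1);
      cc.F1 = cc.H1 * lp.W1; cc.F1.each_row() += lp.b1;
      cc.G.set_size(arma::size(cc.F1));
      for (arma::uword i = 0; i < cc.F1.n_elem; ++i)
        cc.G(i) = gelu(cc.F1(i));
      mat F2 = cc.G * lp.W2; F2.each_row() += lp.b2;
      mat R2 = cc.H1 + F2;
      E = layernorm_fwd(R2, lp.ln2_g, lp.ln2_b, cc.ln2);
      if (hidden_layer == l + 1) hidden_out[b] = wrap(E);
    }

    // --- masked-token head on labelled positions
    mat dE = arma::zeros<mat>(T, H);
    bool any_label = false;
    for (int t = 0; t < T; ++t) {
      if (lab[t] < 0) continue;
      any_label = true;
      rowvec logits = E.row(t) * Wout + bout;
      double mx = logits.max();
      rowvec ex = arma::exp(logits - mx);
      double Z = arma::accu(ex);
      rowvec p = ex / Z;
      loss_sum += -(std::log(p(lab[t]) + 1e-30));
      n_labels++;
      if ((int)p.index_max() == lab[t]) n_correct++;
      if (want_grads) {
        rowvec dlog = p;
        dlog(lab[t]) -= 1.0;
        g_Wout += E.row(t).t() * dlog;
        g_bout += dlog;
        dE.row(t) += dlog * Wout.t();
      }
    }

    if (!want_grads || !any_label) continue;

    // --- backward through layers
    for (int l = L - 1; l >= 0; --l) {
      LayerCache& cc = caches[l];
      const LayerParams& lp = layers[l];
      LayerParams& gl = g_layers[l];
      mat dg2(1, H, arma::fill::zeros), db2ln(1, H, arma::fill::zeros);
      mat dR2 = layernorm_bwd(dE, cc.ln2, lp.ln2_g, dg2, db2ln);
      gl.ln2_g += dg2.row(0); gl.ln2_b += db2ln.row(0);
      mat dH1 = dR2;                 // residual branch
      mat dF2 = dR2;
      mat dG = dF2 * lp.W2.t();
      gl.W2 += cc.G.t() * dF2;
      gl.b2 += arma::sum(dF2, 0);
      mat dF1(arma::size(cc.F1));
      for (arma::uword i = 0; i < cc.F1.n_elem; ++i)
        dF1(i) = dG(i) * gelu_grad(cc.F1(i));
      dH1 += dF1 * lp.W1.t();
      gl.W1 += cc.H1.t() * dF1;
      gl.b1 += arma::sum(dF1, 0);
      mat dg1(1, H, arma::fill::zeros), db1ln(1, H, arma::fill::zeros);
      mat dR1 = layernorm_bwd(dH1, cc.ln1, lp.ln1_g, dg1, db1ln);
      gl.ln1_g += dg1.row(0); gl.ln1_b += db1ln.row(0);
      mat dE_in = dR1;               // residual branch
      mat dO = dR1;
      mat dCcat = dO * lp.Wo.t();
      gl.Wo += cc.Ccat.t() * dO;
      gl.bo += arma::sum(dO, 0);
      int T2 = dE.n_rows;
      mat dQ(T2, H), dK(T2, H), dV(T2, H);
      for (int h = 0; h < n_heads; ++h) {
        mat Qh = cc.Q.cols(h * dh, (h + 1) * dh - 1);
        mat Kh = cc.K.cols(h * dh, (h + 1) * dh - 1);
        mat Vh = cc.V.cols(h * dh, (h + 1) * dh - 1);
        mat dCh = dCcat.cols(h * dh, (h + 1) * dh - 1);
        const mat& A = cc.A[h];
        mat dA = dCh * Vh.t();
        mat dVh = A.t() * dCh;
        vec rs = arma::sum(dA % A, 1);
        mat dAc = dA;
        dAc.each_col() -= rs;
        mat dS = A % dAc;
        dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh * scale;
        dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh * scale;
        dV.cols(h * dh, (h + 1) * dh - 1) = dVh;
      }
      gl.Wq += cc.E_in.t() * dQ; gl.bq += arma::sum(dQ, 0);
      gl.Wk += cc.E_in.t() * dK; gl.bk += arma::sum(dK, 0);
      gl.Wv += cc.E_in.t() * dV; gl.bv += arma::sum(dV, 0);
      dE_in += dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
      dE = dE_in;
    }

    mat dg0(1, H, arma::fill::zeros), db0(1, H, arma::fill::zeros);
    mat dX0 = layernorm_bwd(dE, ln0, ln0_g, dg0, db0);
    g_ln0_g += dg0; g_ln0_b += db0;
    for (int c = 0; c < n_ch; ++c)
      for (int t = 0; t < (int)dX0.n_rows; ++t)
        g_tables[c].row(ids(c, t)) += dX0.row(t);
  }

  List out = List::create(_["loss_sum"] = loss_sum,
                          _["n_labels"] = n_labels,
                          _["n_correct"] = n_correct);
  if (hidden_layer >= 0) out["hidden"] = hidden_out;
  if (want_grads) {
    List gt(n_ch);
    for (int c = 0; c < n_ch; ++c) gt[c] = wrap(g_tables[c]);
    List gls(L);
    for (int l = 0; l < L; ++l) {
      gls[l] = List::create(
        _["Wq"] = g_layers[l].Wq, _["Wk"] = g_layers[l].Wk,
        _["Wv"] = g_layers[l].Wv, _["Wo"] = g_layers[l].Wo,
        _["bq"] = NumericVector(g_layers[l].bq.begin(), g_layers[l].bq.end()),
        _["bk"] = NumericVector(g_layers[l].bk.begin(), g_layers[l].bk.end()),
        _["bv"] = NumericVector(g_layers[l].bv.begin(), g_layers[l].bv.end()),
        _["bo"] = NumericVector(g_layers[l].bo.begin(), g_layers[l].bo.end()),
        _["W1"] = g_layers[l].W1, _["b1"] = NumericVector(g_layers[l].b1.begin(), g_layers[l].b1.end()),
        _["W2"] = g_layers[l].W2, _["b2"] = NumericVector(g_layers[l].b2.begin(), g_layers[l].b2.end()),
        _["ln1_g"] = NumericVector(g_layers[l].ln1_g.begin(), g_layers[l].ln1_g.end()),
        _["ln1_b"] = NumericVector(g_layers[l].ln1_b.begin(), g_layers[l].ln1_b.end()),
        _["ln2_g"] = NumericVector(g_layers[l].ln2_g.begin(), g_layers[l].ln2_g.end()),
        _["ln2_b"] = NumericVector(g_layers[l].ln2_b.begin(), g_layers[l].ln2_b.end()));
    }
    out["grads"] = List::create(
      _["tables"] = gt,
      _["ln0_g"] = NumericVector(g_ln0_g.begin(), g_ln0_g.end()),
      _["ln0_b"] = NumericVector(g_ln0_b.begin(), g_ln0_b.end()),
      _["layers"] = gls,
      _["Wout"] = g_Wout,
      _["bout"] = NumericVector(g_bout.begin(), g_bout.end()));
  }
  return out;
}
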