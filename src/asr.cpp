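// Attention-sum reader core: bidirectional GRU encoders, dot-product
// attention with softmax, pointer-sum loss, and exact backpropagation.
// Gate row layout in the 3H-row weight matrices: [0,H) reset, [H,2H)
// update, [2H,3H) candidate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::Named;

namespace {

struct GruCache {
  mat R, Z, N, Hs; // H x T, columns in processing order
};

inline vec sigmoid_vec(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// One GRU direction over the columns of X visited in `order`.
void gru_forward(const mat& X, const uvec& order, const mat& Wx,
                 const mat& Wh, const vec& b, const int H, GruCache& c) {
  const int T = order.n_elem;
  c.R.set_size(H, T); c.Z.set_size(H, T);
  c.N.set_size(H, T); c.Hs.set_size(H, T);
  vec h = zeros<vec>(H);
  for (int s = 0; s < T; ++s) {
    const vec x = X.col(order[s]);
    const vec pre = Wx * x + b; // 3H
    const vec r = sigmoid_vec(pre.subvec(0, H - 1) + Wh.rows(0, H - 1) * h);
    const vec z = sigmoid_vec(pre.subvec(H, 2 * H - 1) + Wh.rows(H, 2 * H - 1) * h);
    const vec n = tanh(pre.subvec(2 * H, 3 * H - 1) + Wh.rows(2 * H, 3 * H - 1) * (r % h));
    h = (1.0 - z) % n + z % h;
    c.R.col(s) = r; c.Z.col(s) = z; c.N.col(s) = n; c.Hs.col(s) = h;
  }
}

// Backprop through one direction. dHout: H x T gradient on the hidden
// state emitted at each processing step. Accumulates into dX (at the
// original column positions), dWx, dWh, db.
void gru_backward(const mat& X, const uvec& order, const mat& Wx,
                  const mat& Wh, const int H, const GruCache& c,
                  const mat& dHout, mat& dX, mat& dWx, mat& dWh, vec& db) {
  const int T = order.n_elem;
  vec dh_prev = zeros<vec>(H); // gradient flowing back from step s+1
  for (int s = T - 1; s >= 0; --s) {
    const vec dh = dHout.col(s) + dh_prev;
    const vec r = c.R.col(s), z = c.Z.col(s), n = c.N.col(s);
    const vec hprev = (s == 0) ? zeros<vec>(H) : vec(c.Hs.col(s - 1));
    const vec dn = dh % (1.0 - z);
    const vec dz = dh % (hprev - n);
    const vec dan = dn % (1.0 - n % n);
    const vec daz = dz % z % (1.0 - z);
    const vec drh = Wh.rows(2 * H, 3 * H - 1).t() * dan; // d(r % hprev)
    const vec dar = (drh % hprev) % r % (1.0 - r);
    const vec x = X.col(order[s]);
    dWx.rows(0, H - 1)         += dar * x.t();
    dWx.rows(H, 2 * H - 1)     += daz * x.t();
    dWx.rows(2 * H, 3 * H - 1) += dan * x.t();
    dWh.rows(0, H - 1)         += dar * hprev.t();
    dWh.rows(H, 2 * H - 1)     += daz * hprev.t();
    dWh.rows(2 * H, 3 * H - 1) += dan * (r % hprev).t();
    db.subvec(0, H - 1)         += dar;
    db.subvec(H, 2 * H - 1)     += daz;
    db.subvec(2 * H, 3 * H - 1) += dan;
    dX.col(order[s]) += Wx.rows(0, H - 1).t() * dar
                      + Wx.rows(H, 2 * H - 1).t() * daz
                      + Wx.rows(2 * H, 3 * H - 1).t() * dan;
    dh_prev = dh % z + Wh.rows(0, H - 1).t() * dar
                     + Wh.rows(H, 2 * H - 1).t() * daz + drh % r;
  }
}

uvec fwd_order(int T) { return regspace<uvec>(0, T - 1); }
uvec bwd_order(int T) { return regspace<uvec>(T - 1, 0); }

// Embed token/type indices (1-based) into a D x T input matrix.
mat embed(const IntegerVector& idx, const IntegerVector& tidx,
          const mat& Wword, const mat& Wtype, const bool useType) {
  const int T = idx.size();
  const int Dw = Wword.n_cols;
  const int Dt = useType ? Wtype.n_cols : 0;
  mat X(Dw + Dt, T);
  for (int t = 0; t < T; ++t) {
    X.submat(0, t, Dw - 1, t) = Wword.row(idx[t] - 1).t();
    if (useType)
      X.submat(Dw, t, Dw + Dt - 1, t) = Wtype.row(tidx[t] - 1).t();
  }
  return X;
}

vec softmax_stable(const vec& z) {
  const vec e = exp(z - z.max());
  return e / accu(e);
}

struct Params {
  mat cf_Wx, cf_Wh, cb_Wx, cb_Wh, qf_Wx, qf_Wh, qb_Wx, qb_Wh;
  vec cf_b, cb_b, qf_b, qb_b;
};

Params unpack(const List& w) {
  Params p;
  p.cf_Wx = Rcpp::as<mat>(w["cf_Wx"]); p.cf_Wh = Rcpp::as<mat>(w["cf_Wh"]);
  p.cb_Wx = Rcpp::as<mat>(w["cb_Wx"]); p.cb_Wh = Rcpp::as<mat>(w["cb_Wh"]);
  p.qf_Wx = Rcpp::as<mat>(w["qf_Wx"]); p.qf_Wh = Rcpp::as<mat>(w["qf_Wh"]);
  p.qb_Wx = Rcpp::as<mat>(w["qb_Wx"]); p.qb_Wh = Rcpp::as<mat>(w["qb_Wh"]);
  p.cf_b = Rcpp::as<vec>(w["cf_b"]); p.cb_b = Rcpp::as<vec>(w["cb_b"]);
  p.qf_b = Rcpp::as<vec>(w["qf_b"]); p.qb_b = Rcpp::as<vec>(w["qb_b"]);
  return p;
}

// Shared forward pass; caches returned through the out-parameters.
void asr_forward_core(const mat& Xd, const mat& Xq, const Params& p,
                      const int H, GruCache& ccf, GruCache& ccb,
                      GruCache& cqf, GruCache& cqb, mat& F, vec& g, vec& s) {
  const int Td = Xd.n_cols, Tq = Xq.n_cols;
  gru_forward(Xd, fwd_order(Td), p.cf_Wx, p.cf_Wh, p.cf_b, H, ccf);
  gru_forward(Xd, bwd_order(Td), p.cb_Wx, p.cb_Wh, p.cb_b, H, ccb);
  gru_forward(Xq, fwd_order(Tq), p.qf_Wx, p.qf_Wh, p.qf_b, H, cqf);
  gru_forward(Xq, bwd_order(Tq), p.qb_Wx, p.qb_Wh, p.qb_b, H, cqb);
  F.set_size(2 * H, Td);
  for (int t = 0; t < Td; ++t) {
    F.submat(0, t, H - 1, t) = ccf.Hs.col(t);
    F.submat(H, t, 2 * H - 1, t) = ccb.Hs.col(Td - 1 - t);
  }
  g.set_size(2 * H);
  g.subvec(0, H - 1) = cqf.Hs.col(Tq - 1);
  g.subvec(H, 2 * H - 1) = cqb.Hs.col(Tq - 1); // last processing step = position 0
  s = softmax_stable(F.t() * g);
}

} // namespace

// Bidirectional GRU over an already-embedded input, exposed for the
// encoder operations and their unit tests. Returns a 2H x T matrix whose
// column t stacks the forward state after reading 1..t over the backward
// state after reading T..t.
// [[Rcpp::export]]
arma::mat cpp_bigru(const arma::mat& X, const arma::mat& Wx_f,
                    const arma::mat& Wh_f, const arma::vec& b_f,
                    const arma::mat& Wx_b, const arma::mat& Wh_b,
                    const arma::vec& b_b, const int H) {
  const int T = X.n_cols;
  GruCache cf, cb;
  gru_forward(X, fwd_order(T), Wx_f, Wh_f, b_f, H, cf);
  gru_forward(X, bwd_order(T), Wx_b, Wh_b, b_b, H, cb);
  mat out(2 * H, T);
  for (int t = 0; t < T; ++t) {
    out.submat(0, t, H - 1, t) = cf.Hs.col(t);
    out.submat(H, t, 2 * H - 1, t) = cb.Hs.col(T - 1 - t);
  }
  return out;
}

// Single GRU step from a zero state, for hand-checked unit tests.
// [[Rcpp::export]]
arma::vec cpp_gru_step(const arma::vec& x, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::vec& b, const int H) {
  GruCache c;
  mat X(x.n_elem, 1); X.col(0) = x;
  gru_forward(X, fwd_order(1), Wx, Wh, b, H, c);
  return c.Hs.col(0);
}

// Full forward pass for one instance: returns the attention distribution
// s over document positions plus the encodings.
// [[Rcpp::export]]
List cpp_asr_instance(const IntegerVector& doc, const IntegerVector& dtype,
                      const IntegerVector& qry, const IntegerVector& qtype,
                      const arma::mat& Wword, const arma::mat& Wtype,
                      const List& params, const int H, const bool useType) {
  const Params p = unpack(params);
  const mat Xd = embed(doc, dtype, Wword, Wtype, useType);
  const mat Xq = embed(qry, qtype, Wword, Wtype, useType);
  GruCache ccf, ccb, cqf, cqb; mat F; vec g, s;
  asr_forward_core(Xd, Xq, p, H, ccf, ccb, cqf, cqb, F, g, s);
  return List::create(Named("s") = s, Named("f") = F, Named("g") = g);
}

// Loss and gradients over a batch. `anspos` holds 1-based document
// positions of the answer token for each instance. Returns the summed
// loss -log P(a|d,q) and gradient sums for every parameter.
// [[Rcpp::export]]
List cpp_asr_batch(const List& docs, const List& dtypes, const List& qrys,
                   const List& qtypes, const List& anspos,
                   const arma::mat& Wword, const arma::mat& Wtype,
                   const List& params, const int H, const bool useType) {
  const Params p = unpack(params);
  const int B = docs.size();
  const int Dw = Wword.n_cols;
  const int Dt = useType ? Wtype.n_cols : 0;

  mat dWword(Wword.n_rows, Dw, fill::zeros);
  mat dWtype(useType ? Wtype.n_rows : 1, std::max(Dt, 1), fill::zeros);
  mat d_cf_Wx(size(p.cf_Wx), fill::zeros), d_cf_Wh(size(p.cf_Wh), fill::zeros);
  mat d_cb_Wx(size(p.cb_Wx), fill::zeros), d_cb_Wh(size(p.cb_Wh), fill::zeros);
  mat d_qf_Wx(size(p.qf_Wx), fill::zeros), d_qf_Wh(size(p.qf_Wh), fill::zeros);
  mat d_qb_Wx(size(p.qb_Wx), fill::zeros), d_qb_Wh(size(p.qb_Wh), fill::zeros);
  vec d_cf_b(3 * H, fill::zeros), d_cb_b(3 * H, fill::zeros);
  vec d_qf_b(3 * H, fill::zeros), d_qb_b(3 * H, fill::zeros);

  double loss = 0.0;
  for (int bi = 0; bi < B; ++bi) {
    const IntegerVector doc = docs[bi], dtype = dtypes[bi];
    const IntegerVector qry = qrys[bi], qtype = qtypes[bi];
    const IntegerVector apos = anspos[bi];
    const int Td = doc.size(), Tq = qry.size();
    const mat Xd = embed(doc, dtype, Wword, Wtype, useType);
    const mat Xq = embed(qry, qtype, Wword, Wtype, useType);
    GruCache ccf, ccb, cqf, cqb; mat F; vec g, s;
    asr_forward_core(Xd, Xq, p, H, ccf, ccb, cqf, cqb, F, g, s);

    double P = 0.0;
    for (int k = 0; k < apos.size(); ++k) P += s(apos[k] - 1);
    const double Pc = std::max(P, 1e-300);
    loss += -std::log(Pc);

    // softmax + pointer-sum backward: dz_i = s_i (1 - [i in I]/P)
    vec dz = s;
    for (int k = 0; k < apos.size(); ++k)
      dz(apos[k] - 1) -= s(apos[k] - 1) / Pc;
    const vec dg = F * dz;
    mat dF = g * dz.t(); // 2H x Td

    // context encoders
    mat dXd(Xd.n_rows, Td, fill::zeros);
    mat dHf = dF.rows(0, H - 1); // processing order == position order
    gru_backward(Xd, fwd_order(Td), p.cf_Wx, p.cf_Wh, H, ccf, dHf,
                 dXd, d_cf_Wx, d_cf_Wh, d_cf_b);
    mat dHb(H, Td);
    for (int s2 = 0; s2 < Td; ++s2) // step s2 emits the state at position Td-1-s2
      dHb.col(s2) = dF.submat(H, Td - 1 - s2, 2 * H - 1, Td - 1 - s2);
    gru_backward(Xd, bwd_order(Td), p.cb_Wx, p.cb_Wh, H, ccb, dHb,
                 dXd, d_cb_Wx, d_cb_Wh, d_cb_b);

    // query encoders: only the final processing step receives gradient
    mat dXq(Xq.n_rows, Tq, fill::zeros);
    mat dHqf(H, Tq, fill::zeros), dHqb(H, Tq, fill::zeros);
    dHqf.col(Tq - 1) = dg.subvec(0, H - 1);
    dHqb.col(Tq - 1) = dg.subvec(H, 2 * H - 1);
    gru_backward(Xq, fwd_order(Tq), p.qf_Wx, p.qf_Wh, H, cqf, dHqf,
                 dXq, d_qf_Wx, d_qf_Wh, d_qf_b);
    gru_backward(Xq, bwd_order(Tq), p.qb_Wx, p.qb_Wh, H, cqb, dHqb,
                 dXq, d_qb_Wx, d_qb_Wh, d_qb_b);

    // scatter embedding gradients
    for (int t = 0; t < Td; ++t) {
      dWword.row(doc[t] - 1) += dXd.submat(0, t, Dw - 1, t).t();
      if (useType)
        dWtype.row(dtype[t] - 1) += dXd.submat(Dw, t, Dw + Dt - 1, t).t();
    }
    for (int t = 0; t < Tq; ++t) {
      dWword.row(qry[t] - 1) += dXq.submat(0, t, Dw - 1, t).t();
      if (useType)
        dWtype.row(qtype[t] - 1) += dXq.submat(Dw, t, Dw + Dt - 1, t).t();
    }
  }

  return List::create(
    Named("loss") = loss,
    Named("grads") = List::create(
      Named("Wword") = dWword, Named("Wtype") = dWtype,
      Named("cf_Wx") = d_cf_Wx, Named("cf_Wh") = d_cf_Wh, Named("cf_b") = d_cf_b,
      Named("cb_Wx") = d_cb_Wx, Named("cb_Wh") = d_cb_Wh, Named("cb_b") = d_cb_b,
      Named("qf_Wx") = d_qf_Wx, Named("qf_Wh") = d_qf_Wh, Named("qf_b") = d_qf_b,
      Named("qb_Wx") = d_qb_Wx, Named("qb_Wh") = d_qb_Wh, Named("qb_b") = d_qb_b));
}
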