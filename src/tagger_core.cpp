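#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Numerically safe log-sum-exp; returns -Inf for an all -Inf input so that
// transition masks propagate without producing NaN.
static inline double lse(const vec& v) {
  if (v.n_elem == 0) return -datum::inf;
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(accu(exp(v - m)));
}

// Linear-chain CRF over K real tags plus virtual START (index K) and
// STOP (index K+1) states.  E is T x K emissions; A is (K+2) x (K+2)
// transitions; label paths are 0-based.

// [[Rcpp::export]]
double cpp_crf_logZ(const arma::mat& E, const arma::mat& A) {
  const int T = E.n_rows, K = E.n_cols, S = K, P = K + 1;
  if (T == 0) return A(S, P);
  vec alpha(K);
  for (int k = 0; k < K; ++k) alpha(k) = A(S, k) + E(0, k);
  for (int t = 1; t < T; ++t) {
    vec na(K);
    for (int k = 0; k < K; ++k) {
      vec tmp = alpha + A.submat(0, k, K - 1, k);
      na(k) = lse(tmp) + E(t, k);
    }
    alpha = na;
  }
  vec fin = alpha + A.submat(0, P, K - 1, P);
  return lse(fin);
}

// [[Rcpp::export]]
double cpp_crf_score(const arma::mat& E, const arma::mat& A,
                     const arma::ivec& y) {
  const int T = E.n_rows, S = E.n_cols, P = S + 1;
  if (T == 0) return A(S, P);
  double sc = A(S, y(0)) + E(0, y(0));
  for (int t = 1; t < T; ++t) sc += A(y(t - 1), y(t)) + E(t, y(t));
  sc += A(y(T - 1), P);
  return sc;
}

// Log-likelihood of the gold path and gradients of the NEGATIVE
// log-likelihood w.r.t. emissions and transitions (forward-backward).
// [[Rcpp::export]]
List cpp_crf_grad(const arma::mat& E, const arma::mat& A,
                  const arma::ivec& y) {
  const int T = E.n_rows, K = E.n_cols, S = K, P = K + 1;
  if (T == 0)
    return List::create(_["loglik"] = 0.0, _["d_emissions"] = mat(0, K),
                        _["d_transitions"] = mat(K + 2, K + 2, fill::zeros));
  mat alpha(T, K), beta(T, K);
  for (int k = 0; k < K; ++k) alpha(0, k) = A(S, k) + E(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      vec tmp = alpha.row(t - 1).t() + A.submat(0, k, K - 1, k);
      alpha(t, k) = lse(tmp) + E(t, k);
    }
  for (int j = 0; j < K; ++j) beta(T - 1, j) = A(j, P);
  for (int t = T - 2; t >= 0; --t)
    for (int j = 0; j < K; ++j) {
      vec tmp(K);
      for (int k = 0; k < K; ++k)
        tmp(k) = A(j, k) + E(t + 1, k) + beta(t + 1, k);
      beta(t, j) = lse(tmp);
    }
  vec fin = alpha.row(T - 1).t() + A.submat(0, P, K - 1, P);
  const double logZ = lse(fin);
  const double loglik = cpp_crf_score(E, A, y) - logZ;

  // expected counts (marginals)
  mat dE(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double v = alpha(t, k) + beta(t, k) - logZ;
      dE(t, k) = std::isfinite(v) ? std::exp(v) : 0.0;
    }
  mat dA(K + 2, K + 2, fill::zeros);
  for (int k = 0; k < K; ++k) dA(S, k) += dE(0, k);
  for (int j = 0; j < K; ++j) dA(j, P) += dE(T - 1, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      if (!std::isfinite(alpha(t - 1, j))) continue;
      for (int k = 0; k < K; ++k) {
        double v = alpha(t - 1, j) + A(j, k) + E(t, k) + beta(t, k) - logZ;
        if (std::isfinite(v)) dA(j, k) += std::exp(v);
      }
    }
  // minus observed counts
  for (int t = 0; t < T; ++t) dE(t, y(t)) -= 1.0;
  dA(S, y(0)) -= 1.0;
  for (int t = 1; t < T; ++t) dA(y(t - 1), y(t)) -= 1.0;
  dA(y(T - 1), P) -= 1.0;
  return List::create(_["loglik"] = loglik, _["d_emissions"] = dE,
                      _["d_transitions"] = dA);
}

// Exact max-scoring path; ties broken toward the lowest tag index at every
// backtrack step (strict > keeps the first maximum).
// [[Rcpp::export]]
List cpp_crf_viterbi(const arma::mat& E, const arma::mat& A) {
  const int T = E.n_rows, K = E.n_cols, S = K, P = K + 1;
  if (T == 0)
    return List::create(_["path"] = IntegerVector(0), _["score"] = A(S, P));
  mat delta(T, K);
  imat psi(T, K, fill::zeros);
  for (int k = 0; k < K; ++k) delta(0, k) = A(S, k) + E(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = -datum::inf;
      int bj = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + A(j, k);
        if (v > best) { best = v; bj = j; }
      }
      delta(t, k) = best + E(t, k);
      psi(t, k) = bj;
    }
  double best = -datum::inf;
  int bk = 0;
  for (int k = 0; k < K; ++k) {
    double v = delta(T - 1, k) + A(k, P);
    if (v > best) { best = v; bk = k; }
  }
  IntegerVector path(T);
  int cur = bk;
  for (int t = T - 1; t >= 0; --t) { path[t] = cur; cur = psi(t, cur); }
  return List::create(_["path"] = path, _["score"] = best);
}

// ---------------------------------------------------------------------------
// Bidirectional LSTM encoder.  Gate order within the stacked 4H pre-activation
// is [input, forget, cell, output]; h_t = o * tanh(c_t), c_t = f*c_{t-1}+i*g.

static void lstm_fwd(const mat& X, const mat& Wx, const mat& Wh, const vec& b,
                     bool rev, mat& gi, mat& gf, mat& gg, mat& go, mat& cs,
                     mat& hs) {
  const int T = X.n_rows, H = Wh.n_cols;
  gi.set_size(T, H); gf.set_size(T, H); gg.set_size(T, H); go.set_size(T, H);
  cs.set_size(T, H); hs.set_size(T, H);
  vec hp(H, fill::zeros), cp(H, fill::zeros);
  for (int s = 0; s < T; ++s) {
    const int t = rev ? T - 1 - s : s;
    vec a = Wx * X.row(t).t() + Wh * hp + b;
    vec i = 1.0 / (1.0 + exp(-a.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-a.subvec(H, 2 * H - 1)));
    vec g = tanh(a.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-a.subvec(3 * H, 4 * H - 1)));
    vec c = f % cp + i % g;
    vec h = o % tanh(c);
    gi.row(t) = i.t(); gf.row(t) = f.t(); gg.row(t) = g.t(); go.row(t) = o.t();
    cs.row(t) = c.t(); hs.row(t) = h.t();
    hp = h; cp = c;
  }
}

static void lstm_bwd(const mat& X, const mat& Wx, const mat& Wh, const mat& gi,
                     const mat& gf, const mat& gg, const mat& go, const mat& cs,
                     const mat& hs, const mat& dH, bool rev, mat& dWx, mat& dWh,
                     vec& db, mat& dX, bool want_dx) {
  const int T = X.n_rows, H = Wh.n_cols;
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    const int t = rev ? T - 1 - s : s;
    vec dh = dH.row(t).t() + dh_next;
    vec c = cs.row(t).t();
    vec tc = tanh(c);
    vec i = gi.row(t).t(), f = gf.row(t).t(), g = gg.row(t).t(),
        o = go.row(t).t();
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec cprev(H, fill::zeros), hprev(H, fill::zeros);
    if (s > 0) {
      const int tp = rev ? T - s : s - 1;
      cprev = cs.row(tp).t();
      hprev = hs.row(tp).t();
    }
    vec da(4 * H);
    da.subvec(0, H - 1) = (dc % g) % i % (1.0 - i);
    da.subvec(H, 2 * H - 1) = (dc % cprev) % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    dWx += da * X.row(t);
    dWh += da * hprev.t();
    db += da;
    dh_next = Wh.t() * da;
    dc_next = dc % f;
    if (want_dx) dX.row(t) += (Wx.t() * da).t();
  }
}

// Eval-mode emissions: BiLSTM states concatenated and linearly projected.
// [[Rcpp::export]]
arma::mat cpp_bilstm_emissions(const arma::mat& X, const arma::mat& w_fx,
                               const arma::mat& w_fh, const arma::vec& b_f,
                               const arma::mat& w_bx, const arma::mat& w_bh,
                               const arma::vec& b_b, const arma::mat& w_p,
                               const arma::vec& b_p) {
  const int T = X.n_rows, K = w_p.n_rows;
  if (T == 0) return mat(0, K);
  mat fi, ff, fg, fo, fc, fh, bi, bfg, bg, bo, bc, bh;
  lstm_fwd(X, w_fx, w_fh, b_f, false, fi, ff, fg, fo, fc, fh);
  lstm_fwd(X, w_bx, w_bh, b_b, true, bi, bfg, bg, bo, bc, bh);
  mat E = join_rows(fh, bh) * w_p.t();
  E.each_row() += b_p.t();
  return E;
}

// Full training step for one sentence: forward pass, CRF negative
// log-likelihood, and analytic gradients for every parameter (and the
// input embeddings when want_dx, for fine-tuning).  dropmask, when non-empty,
// is a T x 2H inverted-dropout mask applied to the encoder output.
// [[Rcpp::export]]
List cpp_tagger_grad(const arma::mat& X, const arma::mat& w_fx,
                     const arma::mat& w_fh, const arma::vec& b_f,
                     const arma::mat& w_bx, const arma::mat& w_bh,
                     const arma::vec& b_b, const arma::mat& w_p,
                     const arma::vec& b_p, const arma::mat& A,
                     const arma::ivec& y, const arma::mat& dropmask,
                     bool want_dx) {
  const int T = X.n_rows, H = w_fh.n_cols;
  mat fi, ff, fg, fo, fc, fh, bi, bfg, bg, bo, bc, bh;
  lstm_fwd(X, w_fx, w_fh, b_f, false, fi, ff, fg, fo, fc, fh);
  lstm_fwd(X, w_bx, w_bh, b_b, true, bi, bfg, bg, bo, bc, bh);
  mat Hraw = join_rows(fh, bh);
  const bool masked = dropmask.n_rows == Hraw.n_rows && dropmask.n_cols == Hraw.n_cols;
  mat Hd = masked ? mat(Hraw % dropmask) : Hraw;
  mat E = Hd * w_p.t();
  E.each_row() += b_p.t();

  List cg = cpp_crf_grad(E, A, y);
  const double loss = -as<double>(cg["loglik"]);
  mat dE = as<mat>(cg["d_emissions"]);
  mat dA = as<mat>(cg["d_transitions"]);

  mat dWp = dE.t() * Hd;
  vec dbp = sum(dE, 0).t();
  mat dHd = dE * w_p;
  mat dHraw = masked ? mat(dHd % dropmask) : dHd;

  mat dWfx(size(w_fx), fill::zeros), dWfh(size(w_fh), fill::zeros);
  mat dWbx(size(w_bx), fill::zeros), dWbh(size(w_bh), fill::zeros);
  vec dbf(b_f.n_elem, fill::zeros), dbb(b_b.n_elem, fill::zeros);
  mat dX(T, X.n_cols, fill::zeros);
  lstm_bwd(X, w_fx, w_fh, fi, ff, fg, fo, fc, fh, dHraw.cols(0, H - 1), false,
           dWfx, dWfh, dbf, dX, want_dx);
  lstm_bwd(X, w_bx, w_bh, bi, bfg, bg, bo, bc, bh, dHraw.cols(H, 2 * H - 1),
           true, dWbx, dWbh, dbb, dX, want_dx);

  return List::create(
      _["loss"] = loss, _["emissions"] = E, _["w_fx"] = dWfx, _["w_fh"] = dWfh,
      _["b_f"] = dbf, _["w_bx"] = dWbx, _["w_bh"] = dWbh, _["b_b"] = dbb,
      _["w_p"] = dWp, _["b_p"] = dbp, _["trans"] = dA, _["d_x"] = dX);
}
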