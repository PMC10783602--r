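// Batched forward/backward pass of the multi-output EdgeConv network.
// This mirrors the R reference implementation (sg_forward / sg_backward);
// the two are cross-checked in the test suite. Only the training loop and
// batch inference use this engine; the exported single-graph operations
// keep the R path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat act_f(arma::mat x, int act) {
  if (act == 0) {
    double* p = x.memptr();
    for (arma::uword i = 0; i < x.n_elem; ++i) if (p[i] < 0) p[i] = 0;
  } else {
    double* p = x.memptr();
    for (arma::uword i = 0; i < x.n_elem; ++i) p[i] = std::tanh(p[i]);
  }
  return x;
}

// chain-rule product dY * f'(A), expressed through the cached output R
static arma::mat act_dmul(arma::mat dY, const arma::mat& R, int act) {
  double* o = dY.memptr();
  const double* r = R.memptr();
  if (act == 0) {
    for (arma::uword i = 0; i < dY.n_elem; ++i) if (r[i] <= 0) o[i] = 0;
  } else {
    for (arma::uword i = 0; i < dY.n_elem; ++i) o[i] *= 1.0 - r[i] * r[i];
  }
  return dY;
}

struct Layers {
  std::vector<arma::mat> W1, W2;
  std::vector<arma::rowvec> b1, b2;
};

static Layers unpack(const List& params) {
  Layers out;
  for (int i = 0; i < params.size(); ++i) {
    List p = params[i];
    out.W1.push_back(as<arma::mat>(p["W1"]));
    out.b1.push_back(arma::rowvec(as<arma::vec>(p["b1"]).t()));
    out.W2.push_back(as<arma::mat>(p["W2"]));
    out.b2.push_back(arma::rowvec(as<arma::vec>(p["b2"]).t()));
  }
  return out;
}

// column-major pointer loops: arma's row subviews are strided and slow at
// this shape (tens of thousands of short rows)
static arma::mat scatter_rows(const arma::mat& M, const arma::uvec& idx,
                              unsigned int n) {
  arma::mat out(n, M.n_cols, arma::fill::zeros);
  for (unsigned int c = 0; c < M.n_cols; ++c) {
    const double* m = M.colptr(c);
    double* o = out.colptr(c);
    for (unsigned int e = 0; e < idx.n_elem; ++e) o[idx[e]] += m[e];
  }
  return out;
}

static arma::mat gather_rows(const arma::mat& M, const arma::uvec& idx) {
  arma::mat out(idx.n_elem, M.n_cols);
  for (unsigned int c = 0; c < M.n_cols; ++c) {
    const double* m = M.colptr(c);
    double* o = out.colptr(c);
    for (unsigned int e = 0; e < idx.n_elem; ++e) o[e] = m[idx[e]];
  }
  return out;
}

// fused A = P[dst, ] + Q[src, ]
static arma::mat gather_sum(const arma::mat& P, const arma::mat& Q,
                            const arma::uvec& dst, const arma::uvec& src) {
  arma::mat out(dst.n_elem, P.n_cols);
  for (unsigned int c = 0; c < P.n_cols; ++c) {
    const double* p = P.colptr(c);
    const double* q = Q.colptr(c);
    double* o = out.colptr(c);
    for (unsigned int e = 0; e < dst.n_elem; ++e) o[e] = p[dst[e]] + q[src[e]];
  }
  return out;
}

// forward pass; fills caches when wanted
struct FwdState {
  std::vector<arma::mat> H;      // embeddings 0..L
  std::vector<arma::mat> Rlay;   // edge-level hidden activations per layer
  std::vector<arma::mat> Rhead;  // node-level hidden activations per head
  arma::mat S;                   // node scores
  arma::mat slide;               // per-graph scores
};

static FwdState forward(const arma::mat& X, const arma::uvec& src,
                        const arma::uvec& dst, const arma::uvec& gid,
                        unsigned int n_graphs, const Layers& lay,
                        const Layers& head, int act, unsigned int width,
                        bool cache) {
  FwdState st;
  unsigned int n = X.n_rows;
  unsigned int L = lay.W1.size();
  bool has_edges = dst.n_elem > 0;
  st.H.push_back(X);
  arma::vec deg(n, arma::fill::zeros);
  if (has_edges) {
    for (unsigned int e = 0; e < dst.n_elem; ++e) deg[dst[e]] += 1.0;
  }
  for (unsigned int l = 0; l < L; ++l) {
    if (!has_edges) {
      st.H.push_back(arma::mat(n, width, arma::fill::zeros));
      if (cache) st.Rlay.push_back(arma::mat());
      continue;
    }
    const arma::mat& H = st.H[l];
    unsigned int d_in = H.n_cols;
    arma::mat W1a = lay.W1[l].rows(0, d_in - 1);
    arma::mat W1b = lay.W1[l].rows(d_in, 2 * d_in - 1);
    arma::mat P = H * (W1a - W1b);
    arma::mat Q = H * W1b;
    Q.each_row() += lay.b1[l];
    arma::mat R = act_f(gather_sum(P, Q, dst, src), act);
    arma::mat Hn = scatter_rows(R * lay.W2[l], dst, n);
    Hn += deg * lay.b2[l];
    st.H.push_back(Hn);
    if (cache) st.Rlay.push_back(R);
  }
  unsigned int K = head.W2[0].n_cols;
  st.S.zeros(n, K);
  for (unsigned int l = 0; l <= L; ++l) {
    arma::mat A = st.H[l] * head.W1[l];
    A.each_row() += head.b1[l];
    arma::mat R = act_f(A, act);
    arma::mat Y = R * head.W2[l];
    Y.each_row() += head.b2[l];
    st.S += Y;
    if (cache) st.Rhead.push_back(R);
  }
  st.slide.zeros(n_graphs, K);
  for (unsigned int i = 0; i < n; ++i) st.slide.row(gid[i]) += st.S.row(i);
  return st;
}

// [[Rcpp::export(name = ".cpp_sg_forward")]]
List cpp_sg_forward(const arma::mat& X, const arma::uvec& src1,
                    const arma::uvec& dst1, const arma::uvec& gid1,
                    int n_graphs, const List& layers, const List& heads,
                    int act, int width) {
  Layers lay = unpack(layers);
  Layers head = unpack(heads);
  arma::uvec src = src1 - 1, dst = dst1 - 1, gid = gid1 - 1;
  FwdState st = forward(X, src, dst, gid, n_graphs, lay, head, act, width,
                        false);
  return List::create(_["node_scores"] = st.S, _["slide_scores"] = st.slide);
}

// [[Rcpp::export(name = ".cpp_sg_step")]]
List cpp_sg_step(const arma::mat& X, const arma::uvec& src1,
                 const arma::uvec& dst1, const arma::uvec& gid1,
                 int n_graphs, const List& layers, const List& heads,
                 int act, int width, const arma::mat& labels) {
  Layers lay = unpack(layers);
  Layers head = unpack(heads);
  arma::uvec src = src1 - 1, dst = dst1 - 1, gid = gid1 - 1;
  unsigned int n = X.n_rows;
  unsigned int L = lay.W1.size();
  FwdState st = forward(X, src, dst, gid, n_graphs, lay, head, act, width,
                        true);

  // pairwise hinge ranking loss and its gradient wrt slide scores
  unsigned int K = st.slide.n_cols;
  arma::mat G(n_graphs, K, arma::fill::zeros);
  double loss = 0.0;
  long n_pairs = 0;
  for (unsigned int k = 0; k < K; ++k) {
    std::vector<unsigned int> pos, neg;
    for (int i = 0; i < n_graphs; ++i) {
      double y = labels(i, k);
      if (ISNAN(y)) continue;
      if (y == 1.0) pos.push_back(i); else neg.push_back(i);
    }
    n_pairs += (long)pos.size() * neg.size();
    for (unsigned int a : pos) for (unsigned int b : neg) {
      double m = st.slide(a, k) - st.slide(b, k);
      if (m < 1.0) {
        loss += 1.0 - m;
        G(a, k) -= 1.0;
        G(b, k) += 1.0;
      }
    }
  }

  // backward
  arma::mat dS(n, K);
  for (unsigned int i = 0; i < n; ++i) dS.row(i) = G.row(gid[i]);
  std::vector<arma::mat> dH(L + 1);
  List gheads(L + 1), glayers(L);
  for (unsigned int l = 0; l <= L; ++l) {
    const arma::mat& R = st.Rhead[l];
    arma::mat dW2 = R.t() * dS;
    arma::rowvec db2 = arma::sum(dS, 0);
    arma::mat dA = act_dmul(dS * head.W2[l].t(), R, act);
    arma::mat dW1 = st.H[l].t() * dA;
    arma::rowvec db1 = arma::sum(dA, 0);
    dH[l] = dA * head.W1[l].t();
    gheads[l] = List::create(_["W1"] = dW1, _["b1"] = arma::vec(db1.t()),
                             _["W2"] = dW2, _["b2"] = arma::vec(db2.t()));
  }
  bool has_edges = dst.n_elem > 0;
  for (int l = L - 1; l >= 0; --l) {
    if (!has_edges) {
      glayers[l] = List::create(
        _["W1"] = arma::mat(arma::size(lay.W1[l]), arma::fill::zeros),
        _["b1"] = arma::vec(lay.b1[l].n_elem, arma::fill::zeros),
        _["W2"] = arma::mat(arma::size(lay.W2[l]), arma::fill::zeros),
        _["b2"] = arma::vec(lay.b2[l].n_elem, arma::fill::zeros));
      continue;
    }
    const arma::mat& Hprev = st.H[l];
    const arma::mat& R = st.Rlay[l];
    unsigned int d_in = Hprev.n_cols;
    arma::mat W1a = lay.W1[l].rows(0, d_in - 1);
    arma::mat W1b = lay.W1[l].rows(d_in, 2 * d_in - 1);
    arma::mat dM = gather_rows(dH[l + 1], dst);
    arma::mat dW2 = R.t() * dM;
    arma::rowvec db2 = arma::sum(dM, 0);
    arma::mat dA = act_dmul(dM * lay.W2[l].t(), R, act);
    arma::rowvec db1 = arma::sum(dA, 0);
    arma::mat Sdst = scatter_rows(dA, dst, n);
    arma::mat Ssrc = scatter_rows(dA, src, n);
    arma::mat dW1a = Hprev.t() * Sdst;
    arma::mat dW1src = Hprev.t() * Ssrc;
    arma::mat dW1 = arma::join_cols(dW1a, dW1src - dW1a);
    dH[l] += Sdst * (W1a - W1b).t() + Ssrc * W1b.t();
    glayers[l] = List::create(_["W1"] = dW1, _["b1"] = arma::vec(db1.t()),
                              _["W2"] = dW2, _["b2"] = arma::vec(db2.t()));
  }
  return List::create(
    _["loss"] = loss, _["n_pairs"] = (double)n_pairs,
    _["slide_scores"] = st.slide,
    _["grads"] = List::create(_["layers"] = glayers, _["heads"] = gheads));
}
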