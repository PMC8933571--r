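// Siamese multi-kernel 1-D CNN encoder: forward, backward and the fused
// classification/constraint head. Single-precision internally; the R side
// owns parameter storage (plain matrices/vectors) and the Adam updates.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

static inline int out_len(int T, int stride) { return (T + stride - 1) / stride; }

static inline int pad_left(int T, int D, int stride) {
  const int To = out_len(T, stride);
  const int pad = std::max((To - 1) * stride + D - T, 0);
  return pad / 2; // TensorFlow-style 'same': extra padding goes to the right
}

// Gather D columns (kernel support) per output position into a (C*D) x To
// matrix; out-of-range positions are zero (zero 'same' padding).
static void im2col(const fmat& X, int D, int stride, int pl, fmat& cols) {
  const int C = X.n_rows, T = X.n_cols, To = cols.n_cols;
  cols.zeros();
  for (int t = 0; t < To; ++t) {
    const int base = t * stride - pl;
    float* dst = cols.colptr(t);
    for (int j = 0; j < D; ++j) {
      const int c = base + j;
      if (c >= 0 && c < T)
        std::memcpy(dst + (std::size_t)j * C, X.colptr(c), C * sizeof(float));
    }
  }
}

static void col2im_add(const fmat& cols, int D, int stride, int pl, fmat& dX) {
  const int C = dX.n_rows, T = dX.n_cols;
  const int To = cols.n_cols;
  for (int t = 0; t < To; ++t) {
    const int base = t * stride - pl;
    const float* src = cols.colptr(t);
    for (int j = 0; j < D; ++j) {
      const int c = base + j;
      if (c >= 0 && c < T) {
        float* dst = dX.colptr(c);
        const float* s = src + (std::size_t)j * C;
        for (int i = 0; i < C; ++i) dst[i] += s[i];
      }
    }
  }
}

struct ConvLayer {
  fmat W;            // F x (C*D)
  fvec b, g, be;     // bias, BN scale, BN shift (length F)
  fvec rm, rv;       // BN running mean / var
  int D;
};

struct LayerCache {
  fcube xhat;        // normalized pre-scale activations
  fvec istd;         // 1/sqrt(var+eps) per filter
  fcube A;           // post-ReLU activations
};

struct Encoder {
  int M, F, stride, nblk;
  std::vector<ConvLayer> L1, L2;
};

struct BranchCache {
  std::vector<fcube> Xin;       // block inputs after dropout
  std::vector<LayerCache> c1, c2;
  std::vector<umat> amax;       // global-max-pool argmax per filter x record
};

struct BlockGrads {
  fmat dW1, dW2;
  fvec db1, dg1, dbe1, db2, dg2, dbe2;
};

// conv -> BN -> ReLU over a batch cube (C x T x B) -> (F x To x B)
static fcube conv_bn_relu_fwd(const fcube& X, ConvLayer& L, int stride,
                              bool training, LayerCache* cache,
                              bool update_running) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int F = L.W.n_rows;
  const int To = out_len(T, stride);
  const int pl = pad_left(T, L.D, stride);
  fcube Y(F, To, B);
  fmat cols(C * L.D, To);
  for (int s = 0; s < B; ++s) {
    im2col(X.slice(s), L.D, stride, pl, cols);
    Y.slice(s) = L.W * cols;
    Y.slice(s).each_col() += L.b;
  }
  const std::size_t N = (std::size_t)To * B;
  fmat Ym(Y.memptr(), F, N, false, true); // alias, in-place ops
  if (training) {
    fvec mu = mean(Ym, 1);
    Ym.each_col() -= mu;
    fvec var = mean(square(Ym), 1);
    fvec istd = 1.0f / sqrt(var + BN_EPS);
    Ym.each_col() %= istd;
    if (cache) { cache->xhat = Y; cache->istd = istd; }
    if (update_running) {
      L.rm = (1.0f - BN_MOMENTUM) * L.rm + BN_MOMENTUM * mu;
      L.rv = (1.0f - BN_MOMENTUM) * L.rv + BN_MOMENTUM * var;
    }
  } else {
    fvec istd = 1.0f / sqrt(L.rv + BN_EPS);
    Ym.each_col() -= L.rm;
    Ym.each_col() %= istd;
  }
  Ym.each_col() %= L.g;
  Ym.each_col() += L.be;
  Ym.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (cache) cache->A = Y;
  return Y;
}

// Backward through ReLU -> BN -> conv. dA is the gradient w.r.t. post-ReLU
// output and is consumed as scratch. Gradients are ACCUMULATED into the
// provided containers (Siamese branches share parameters). dX may be null
// when the upstream input needs no gradient (raw data).
static void conv_bn_relu_bwd(fcube& dA, const fcube& X, const ConvLayer& L,
                             int stride, const LayerCache& cc,
                             fmat& dW, fvec& db, fvec& dg, fvec& dbe,
                             fcube* dX) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int F = L.W.n_rows;
  const int To = dA.n_cols;
  const int pl = pad_left(T, L.D, stride);
  const std::size_t N = (std::size_t)To * B;
  fmat dAm(dA.memptr(), F, N, false, true);
  const fmat Am(const_cast<float*>(cc.A.memptr()), F, N, false, true);
  const fmat xh(const_cast<float*>(cc.xhat.memptr()), F, N, false, true);
  // ReLU
  dAm.elem(find(Am <= 0.0f)).zeros();
  // BN scale/shift
  dg += sum(dAm % xh, 1);
  dbe += sum(dAm, 1);
  dAm.each_col() %= L.g; // now d xhat
  // BN normalize backward: dz = istd/N * (N*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
  fvec s1 = sum(dAm, 1);
  fvec s2 = sum(dAm % xh, 1);
  dAm *= (float)N;
  dAm.each_col() -= s1;
  {
    fmat tmp = xh;
    tmp.each_col() %= s2;
    dAm -= tmp;
  }
  {
    fvec sc = cc.istd / (float)N;
    dAm.each_col() %= sc;
  }
  // conv backward
  fmat cols(C * L.D, To), dcols;
  for (int s = 0; s < B; ++s) {
    im2col(X.slice(s), L.D, stride, pl, cols);
    dW += dA.slice(s) * cols.t();
    db += sum(dA.slice(s), 1);
    if (dX) {
      dcols = L.W.t() * dA.slice(s);
      col2im_add(dcols, L.D, stride, pl, dX->slice(s));
    }
  }
}

static fvec as_fvec(SEXP x) { return conv_to<fvec>::from(Rcpp::as<vec>(x)); }
static fmat as_fmat(SEXP x) { return conv_to<fmat>::from(Rcpp::as<mat>(x)); }

static Encoder parse_encoder(List params, List structure) {
  Encoder E;
  E.M = Rcpp::as<int>(structure["M"]);
  E.F = Rcpp::as<int>(structure["n_filters"]);
  E.stride = Rcpp::as<int>(structure["stride"]);
  Rcpp::IntegerVector kernels = structure["kernels"];
  E.nblk = kernels.size();
  List blocks = params["blocks"];
  for (int b = 0; b < E.nblk; ++b) {
    List blk = blocks[b];
    ConvLayer l1, l2;
    l1.W = as_fmat(blk["W1"]); l1.b = as_fvec(blk["b1"]);
    l1.g = as_fvec(blk["g1"]); l1.be = as_fvec(blk["be1"]);
    l1.rm = as_fvec(blk["rm1"]); l1.rv = as_fvec(blk["rv1"]);
    l1.D = kernels[b];
    l2.W = as_fmat(blk["W2"]); l2.b = as_fvec(blk["b2"]);
    l2.g = as_fvec(blk["g2"]); l2.be = as_fvec(blk["be2"]);
    l2.rm = as_fvec(blk["rm2"]); l2.rv = as_fvec(blk["rv2"]);
    l2.D = kernels[b];
    E.L1.push_back(std::move(l1));
    E.L2.push_back(std::move(l2));
  }
  return E;
}

static fmat encoder_fwd(const fcube& X0, Encoder& E, bool training,
                        double dropout, std::mt19937& rng, BranchCache* bc,
                        bool update_running) {
  const int B = X0.n_slices;
  fmat feat(E.F * E.nblk, B);
  for (int b = 0; b < E.nblk; ++b) {
    fcube Xin = X0;
    if (training && dropout > 0.0) {
      std::bernoulli_distribution keep(1.0 - dropout);
      const float scale = 1.0f / (1.0f - (float)dropout);
      for (auto& v : Xin) v = keep(rng) ? v * scale : 0.0f;
    }
    LayerCache c1l, c2l;
    fcube A1 = conv_bn_relu_fwd(Xin, E.L1[b], E.stride, training,
                                training && bc ? &c1l : nullptr, update_running);
    fcube A2 = conv_bn_relu_fwd(A1, E.L2[b], E.stride, training,
                                training && bc ? &c2l : nullptr, update_running);
    umat amax(E.F, B);
    for (int s = 0; s < B; ++s) {
      for (int f = 0; f < E.F; ++f) {
        uword idx;
        const float m = A2.slice(s).row(f).max(idx);
        feat(b * E.F + f, s) = m;
        amax(f, s) = idx;
      }
    }
    if (bc) {
      bc->Xin.push_back(std::move(Xin));
      bc->c1.push_back(std::move(c1l));
      bc->c2.push_back(std::move(c2l));
      bc->amax.push_back(std::move(amax));
    }
  }
  return feat;
}

static void encoder_bwd(const fmat& dFeat, Encoder& E, BranchCache& bc,
                        std::vector<BlockGrads>& G) {
  for (int b = 0; b < E.nblk; ++b) {
    const fcube& A2 = bc.c2[b].A;
    const int To2 = A2.n_cols, B = A2.n_slices;
    fcube dA2(E.F, To2, B, fill::zeros);
    for (int s = 0; s < B; ++s)
      for (int f = 0; f < E.F; ++f)
        dA2(f, bc.amax[b](f, s), s) += dFeat(b * E.F + f, s);
    const fcube& A1 = bc.c1[b].A;
    fcube dA1(A1.n_rows, A1.n_cols, A1.n_slices, fill::zeros);
    conv_bn_relu_bwd(dA2, A1, E.L2[b], E.stride, bc.c2[b],
                     G[b].dW2, G[b].db2, G[b].dg2, G[b].dbe2, &dA1);
    conv_bn_relu_bwd(dA1, bc.Xin[b], E.L1[b], E.stride, bc.c1[b],
                     G[b].dW1, G[b].db1, G[b].dg1, G[b].dbe1, nullptr);
  }
}

static inline double sigmoid_d(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// -log(sigmoid(x)), numerically stable
static inline double nls(double x) {
  return x > 0.0 ? std::log1p(std::exp(-x)) : -x + std::log1p(std::exp(x));
}

// Encode a batch of segments. In training mode batch statistics are used for
// BN and dropout is applied (seeded); running statistics are never modified.
// [[Rcpp::export]]
arma::mat cpp_encode(const arma::cube& X, List params, List structure,
                     bool training, double dropout, int seed) {
  Encoder E = parse_encoder(params, structure);
  fcube Xf = conv_to<fcube>::from(X);
  std::mt19937 rng((unsigned)seed);
  BranchCache bc;
  fmat feat = encoder_fwd(Xf, E, training, dropout, rng,
                          training ? &bc : nullptr, false);
  return conv_to<mat>::from(feat);
}

// One training step on a mini-batch: Siamese forward on alarm (and, when the
// discriminative constraint is on, baseline) segments, fused classification
// head, combined loss and full gradient. Returns gradients, updated BN
// running statistics, loss components and per-record probabilities.
// [[Rcpp::export]]
List cpp_siamese_step(const arma::cube& xA_, const arma::cube& xR_,
                      const arma::ivec& alarm_idx, const arma::vec& rule,
                      const arma::vec& y, List params, List structure,
                      double w, double pos_weight, double dropout, int seed,
                      bool use_constraint, bool use_alarm, bool use_rule) {
  Encoder E = parse_encoder(params, structure);
  const int B = xA_.n_slices;
  const int Sa = Rcpp::as<int>(structure["Sa"]);
  const int Sr = Rcpp::as<int>(structure["Sr"]);
  fmat Wa, WrOuter;
  fvec Wr, Wc;
  if (use_alarm) Wa = as_fmat(params["Wa"]);
  if (use_rule) Wr = as_fvec(params["Wr"]);
  Wc = as_fvec(params["Wc"]);
  const double bc_bias = Rcpp::as<double>(params["bc"]);

  fcube xA = conv_to<fcube>::from(xA_);
  std::mt19937 rng((unsigned)seed);
  BranchCache bcA, bcR;
  fmat featA = encoder_fwd(xA, E, true, dropout, rng, &bcA, true);
  fmat featR;
  if (use_constraint) {
    fcube xR = conv_to<fcube>::from(xR_);
    featR = encoder_fwd(xR, E, true, dropout, rng, &bcR, true);
  }
  const int Se = featA.n_rows;
  const int K = Se + (use_alarm ? Sa : 0) + (use_rule ? Sr : 0);
  if ((int)Wc.n_elem != K)
    Rcpp::stop("classifier weight length %d does not match fused size %d",
               (int)Wc.n_elem, K);

  // fused head forward
  fmat concat(K, B);
  concat.rows(0, Se - 1) = featA;
  int off = Se;
  if (use_alarm) {
    for (int i = 0; i < B; ++i)
      concat.col(i).subvec(off, off + Sa - 1) = Wa.row(alarm_idx[i] - 1).t();
    off += Sa;
  }
  if (use_rule) {
    for (int i = 0; i < B; ++i)
      concat.col(i).subvec(off, off + Sr - 1) = (float)rule[i] * Wr;
  }
  vec z(B), O(B), dz(B);
  double loss_bce = 0.0;
  for (int i = 0; i < B; ++i) {
    z[i] = dot(Wc, concat.col(i)) + bc_bias;
    O[i] = sigmoid_d(z[i]);
    if (y[i] > 0.5) {
      loss_bce += pos_weight * nls(z[i]);
      dz[i] = pos_weight * (O[i] - 1.0) / B;
    } else {
      loss_bce += nls(-z[i]);
      dz[i] = O[i] / B;
    }
  }
  loss_bce /= B;

  // head backward
  fvec dWc(K, fill::zeros);
  double dbc = 0.0;
  fmat dconcat(K, B);
  for (int i = 0; i < B; ++i) {
    dWc += (float)dz[i] * concat.col(i);
    dbc += dz[i];
    dconcat.col(i) = (float)dz[i] * Wc;
  }
  fmat dfA = dconcat.rows(0, Se - 1);
  fmat dWa;
  fvec dWr;
  off = Se;
  if (use_alarm) {
    dWa.zeros(Wa.n_rows, Wa.n_cols);
    for (int i = 0; i < B; ++i)
      dWa.row(alarm_idx[i] - 1) += dconcat.col(i).subvec(off, off + Sa - 1).t();
    off += Sa;
  }
  if (use_rule) {
    dWr.zeros(Sr);
    for (int i = 0; i < B; ++i)
      dWr += (float)rule[i] * dconcat.col(i).subvec(off, off + Sr - 1);
  }

  // discriminative constraint
  double loss_con = 0.0;
  fmat dfR;
  if (use_constraint) {
    int n1 = 0, n2 = 0;
    for (int i = 0; i < B; ++i) (y[i] > 0.5 ? n2 : n1)++;
    dfR.zeros(Se, B);
    for (int i = 0; i < B; ++i) {
      const double d = dot(conv_to<vec>::from(featA.col(i)),
                           conv_to<vec>::from(featR.col(i)));
      double coeff;
      if (y[i] > 0.5) { // true alarm: push apart
        loss_con += nls(-d) / n2;
        coeff = w * sigmoid_d(d) / n2;
      } else {          // false alarm: pull together
        loss_con += nls(d) / n1;
        coeff = w * (sigmoid_d(d) - 1.0) / n1;
      }
      dfA.col(i) += (float)coeff * featR.col(i);
      dfR.col(i) += (float)coeff * featA.col(i);
    }
  }

  // encoder backward, gradients accumulated across the two shared branches
  std::vector<BlockGrads> G(E.nblk);
  for (int b = 0; b < E.nblk; ++b) {
    G[b].dW1.zeros(E.L1[b].W.n_rows, E.L1[b].W.n_cols);
    G[b].dW2.zeros(E.L2[b].W.n_rows, E.L2[b].W.n_cols);
    G[b].db1.zeros(E.F); G[b].dg1.zeros(E.F); G[b].dbe1.zeros(E.F);
    G[b].db2.zeros(E.F); G[b].dg2.zeros(E.F); G[b].dbe2.zeros(E.F);
  }
  encoder_bwd(dfA, E, bcA, G);
  if (use_constraint) encoder_bwd(dfR, E, bcR, G);

  List gblocks(E.nblk);
  for (int b = 0; b < E.nblk; ++b) {
    gblocks[b] = List::create(
      Named("W1") = conv_to<mat>::from(G[b].dW1),
      Named("b1") = conv_to<vec>::from(G[b].db1),
      Named("g1") = conv_to<vec>::from(G[b].dg1),
      Named("be1") = conv_to<vec>::from(G[b].dbe1),
      Named("W2") = conv_to<mat>::from(G[b].dW2),
      Named("b2") = conv_to<vec>::from(G[b].db2),
      Named("g2") = conv_to<vec>::from(G[b].dg2),
      Named("be2") = conv_to<vec>::from(G[b].dbe2));
  }
  List running(E.nblk);
  for (int b = 0; b < E.nblk; ++b) {
    running[b] = List::create(
      Named("rm1") = conv_to<vec>::from(E.L1[b].rm),
      Named("rv1") = conv_to<vec>::from(E.L1[b].rv),
      Named("rm2") = conv_to<vec>::from(E.L2[b].rm),
      Named("rv2") = conv_to<vec>::from(E.L2[b].rv));
  }
  List grads = List::create(
    Named("blocks") = gblocks,
    Named("Wc") = conv_to<vec>::from(dWc),
    Named("bc") = dbc);
  if (use_alarm) grads["Wa"] = conv_to<mat>::from(dWa);
  if (use_rule) grads["Wr"] = conv_to<vec>::from(dWr);

  return List::create(
    Named("grads") = grads,
    Named("running") = running,
    Named("loss_bce") = loss_bce,
    Named("loss_constraint") = loss_con,
    Named("loss_total") = loss_bce + w * loss_con,
    Named("probs") = O);
}
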