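// Three-branch 1D-CNN + attention regressor for binding affinity.
//
// Layout conventions:
//  - a batch of B sequences of length L with C channels is a (B*L) x C
//    matrix, rows grouped per sample (sample b owns rows [b*L, (b+1)*L)).
//  - convolutions are bias-free with 'same' zero padding, so an all-zero
//    (padding) input region stays exactly zero through conv+ReLU; this is
//    what makes cropping trailing padding an exact operation.
//  - all RNG (shuffling, dropout) goes through R's RNG so that set.seed()
//    on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::umat;
using arma::uword;
using arma::vec;

// ---------------------------------------------------------------- weights

struct Net {
  mat emb_pocket;  // 42 x E   (row 0 = pad, frozen at zero)
  mat emb_smiles;  // 65 x E   (row 0 = pad, frozen at zero)
  mat Wproj;       // 58 x E   (bias-free projection of residue features)
  mat pkW1, pkW2, pkW3;  // pocket branch conv kernels, (k*Cin) x Cout
  mat prW1, prW2, prW3;  // protein branch
  mat smW1, smW2, smW3;  // SMILES branch
  mat att;               // 1 x 6: wq bq wk bk wv bv
  mat Wf1, bf1, Wf2, bf2, Wo, bo;

  std::vector<mat*> params() {
    return {&emb_pocket, &emb_smiles, &Wproj, &pkW1, &pkW2, &pkW3,
            &prW1, &prW2, &prW3, &smW1, &smW2, &smW3, &att,
            &Wf1, &bf1, &Wf2, &bf2, &Wo, &bo};
  }
};

static const char* kParamNames[] = {
    "emb_pocket", "emb_smiles", "Wproj", "pkW1", "pkW2", "pkW3",
    "prW1", "prW2", "prW3", "smW1", "smW2", "smW3", "att",
    "Wf1", "bf1", "Wf2", "bf2", "Wo", "bo"};

static Net net_from_list(const List& w) {
  Net n;
  std::vector<mat*> p = n.params();
  for (size_t i = 0; i < p.size(); ++i) {
    *p[i] = as<mat>(w[kParamNames[i]]);
  }
  return n;
}

static List net_to_list(Net& n) {
  List out;
  std::vector<mat*> p = n.params();
  for (size_t i = 0; i < p.size(); ++i) out[kParamNames[i]] = *p[i];
  return out;
}

static Net net_zeros_like(Net& n) {
  Net z = n;
  for (mat* m : z.params()) m->zeros();
  return z;
}

// ------------------------------------------------------------ primitives

// im2col for 'same' zero-padded 1D convolution over per-sample blocks
static mat im2col(const mat& X, int B, int L, int k) {
  const int C = X.n_cols;
  const int padL = (k - 1) / 2;
  mat out(size_t(B) * L, size_t(k) * C, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int s = j - padL;
    const int t0 = std::max(0, -s);
    const int t1 = L - 1 - std::max(0, s);
    if (t1 < t0) continue;
    for (int b = 0; b < B; ++b) {
      out.submat(size_t(b) * L + t0, size_t(j) * C,
                 size_t(b) * L + t1, size_t(j) * C + C - 1) =
          X.rows(size_t(b) * L + t0 + s, size_t(b) * L + t1 + s);
    }
  }
  return out;
}

// adjoint of im2col: scatter-add column blocks back onto input rows
static mat col2im(const mat& dXcol, int B, int L, int k, int C) {
  const int padL = (k - 1) / 2;
  mat dX(size_t(B) * L, C, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int s = j - padL;
    const int t0 = std::max(0, -s);
    const int t1 = L - 1 - std::max(0, s);
    if (t1 < t0) continue;
    for (int b = 0; b < B; ++b) {
      dX.rows(size_t(b) * L + t0 + s, size_t(b) * L + t1 + s) +=
          dXcol.submat(size_t(b) * L + t0, size_t(j) * C,
                       size_t(b) * L + t1, size_t(j) * C + C - 1);
    }
  }
  return dX;
}

// max pool, width 2 stride 2 (odd tail dropped); mask records the argmax
static mat maxpool2(const mat& X, int B, int L, int& Lo, umat& mask) {
  Lo = L / 2;
  const int C = X.n_cols;
  mat out(size_t(B) * Lo, C);
  mask.set_size(size_t(B) * Lo, C);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lo; ++t) {
      const size_t r0 = size_t(b) * L + 2 * t, ro = size_t(b) * Lo + t;
      for (int c = 0; c < C; ++c) {
        const double a = X(r0, c), d = X(r0 + 1, c);
        out(ro, c) = a >= d ? a : d;
        mask(ro, c) = a >= d ? 0 : 1;
      }
    }
  }
  return out;
}

static mat maxpool2_back(const mat& dY, const umat& mask, int B, int L) {
  const int Lo = L / 2, C = dY.n_cols;
  mat dX(size_t(B) * L, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < Lo; ++t) {
      const size_t r0 = size_t(b) * L + 2 * t, ro = size_t(b) * Lo + t;
      for (int c = 0; c < C; ++c) dX(r0 + mask(ro, c), c) = dY(ro, c);
    }
  }
  return dX;
}

static mat globalmax(const mat& X, int B, int L, umat& idx) {
  const int C = X.n_cols;
  mat out(B, C);
  idx.set_size(B, C);
  for (int b = 0; b < B; ++b) {
    const mat sub = X.rows(size_t(b) * L, size_t(b) * L + L - 1);
    for (int c = 0; c < C; ++c) {
      uword w;
      out(b, c) = sub.col(c).max(w);
      idx(b, c) = w;
    }
  }
  return out;
}

static mat globalmax_back(const mat& dY, const umat& idx, int B, int L) {
  const int C = dY.n_cols;
  mat dX(size_t(B) * L, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) dX(size_t(b) * L + idx(b, c), c) = dY(b, c);
  return dX;
}

// ------------------------------------------------------------ branches

struct BranchCache {
  mat X0, Xc1, C1, P1, Xc2, C2, P2, Xc3, C3, G;
  umat m1, m2, gidx;
  int L0, L1, L2;
};

// conv -> pool -> conv -> pool -> conv -> global max ; output B x 128
static mat branch_forward(const mat& E, int B, int L, const mat& W1,
                          const mat& W2, const mat& W3, int k1, int k2,
                          int k3, BranchCache* cache) {
  BranchCache tmp;
  BranchCache& c = cache ? *cache : tmp;
  c.L0 = L;
  c.Xc1 = im2col(E, B, L, k1);
  c.C1 = c.Xc1 * W1;
  c.C1.transform([](double v) { return v > 0 ? v : 0.0; });
  c.P1 = maxpool2(c.C1, B, L, c.L1, c.m1);
  c.Xc2 = im2col(c.P1, B, c.L1, k2);
  c.C2 = c.Xc2 * W2;
  c.C2.transform([](double v) { return v > 0 ? v : 0.0; });
  c.P2 = maxpool2(c.C2, B, c.L1, c.L2, c.m2);
  c.Xc3 = im2col(c.P2, B, c.L2, k3);
  c.C3 = c.Xc3 * W3;
  c.C3.transform([](double v) { return v > 0 ? v : 0.0; });
  c.G = globalmax(c.C3, B, c.L2, c.gidx);
  if (cache) cache->X0 = E;
  return c.G;
}

// returns gradient wrt the embedded input; accumulates dW1..3
static mat branch_backward(const mat& dG, int B, const BranchCache& c,
                           const mat& W1, const mat& W2, const mat& W3,
                           int k1, int k2, int k3, mat& dW1, mat& dW2,
                           mat& dW3) {
  mat dC3 = globalmax_back(dG, c.gidx, B, c.L2);
  dC3 %= arma::conv_to<mat>::from(c.C3 > 0);
  dW3 += c.Xc3.t() * dC3;
  mat dP2 = col2im(dC3 * W3.t(), B, c.L2, k3, W2.n_cols);
  mat dC2 = maxpool2_back(dP2, c.m2, B, c.L1);
  dC2 %= arma::conv_to<mat>::from(c.C2 > 0);
  dW2 += c.Xc2.t() * dC2;
  mat dP1 = col2im(dC2 * W2.t(), B, c.L1, k2, W1.n_cols);
  mat dC1 = maxpool2_back(dP1, c.m1, B, c.L0);
  dC1 %= arma::conv_to<mat>::from(c.C1 > 0);
  dW1 += c.Xc1.t() * dC1;
  return col2im(dC1 * W1.t(), B, c.L0, k1, c.X0.n_cols);
}

// ------------------------------------------------------------ attention

// scaled dot-product attention over the 384-vector: each feature is a
// token, Q/K/V are scalar affine projections of the token, d_k = 1
struct AttCache {
  mat X;                    // B x D input
  std::vector<mat> A;       // per-sample D x D softmax weights
};

static mat attention_forward(const mat& X, const mat& att, AttCache* cache,
                             bool residual = false) {
  const double wq = att(0, 0), bq = att(0, 1), wk = att(0, 2), bk = att(0, 3),
               wv = att(0, 4), bv = att(0, 5);
  const int B = X.n_rows, D = X.n_cols;
  mat out(B, D);
  if (cache) {
    cache->X = X;
    cache->A.assign(B, mat());
  }
  for (int b = 0; b < B; ++b) {
    vec x = X.row(b).t();
    vec q = wq * x + bq, k = wk * x + bk, v = wv * x + bv;
    mat S = q * k.t();  // / sqrt(d_k) with d_k = 1
    S.each_col() -= arma::max(S, 1);
    mat A = arma::exp(S);
    A.each_col() /= arma::sum(A, 1);
    out.row(b) = (A * v).t();
    if (residual) out.row(b) += X.row(b);
    if (cache) cache->A[b] = std::move(A);
  }
  return out;
}

static mat attention_backward(const mat& dO, const AttCache& c,
                              const mat& att, mat& datt,
                              bool residual = false) {
  const double wq = att(0, 0), wk = att(0, 2), wv = att(0, 4);
  const int B = c.X.n_rows, D = c.X.n_cols;
  mat dX(B, D, arma::fill::zeros);
  double dwq = 0, dbq = 0, dwk = 0, dbk = 0, dwv = 0, dbv = 0;
  for (int b = 0; b < B; ++b) {
    vec x = c.X.row(b).t();
    vec q = wq * x + att(0, 1), k = wk * x + att(0, 3),
        v = wv * x + att(0, 5);
    const mat& A = c.A[b];
    vec dout = dO.row(b).t();
    vec dv = A.t() * dout;
    dwv += arma::dot(dv, x);
    dbv += arma::accu(dv);
    vec dx = wv * dv;
    mat dA = dout * v.t();
    vec rs = arma::sum(dA % A, 1);
    mat dS = A % dA;              // dS_ij = A_ij*(dA_ij - sum_j' dA_ij' A_ij')
    mat Ars = A;
    Ars.each_col() %= rs;
    dS -= Ars;
    vec dq = dS * k;
    vec dk = dS.t() * q;
    dwq += arma::dot(dq, x);
    dbq += arma::accu(dq);
    dwk += arma::dot(dk, x);
    dbk += arma::accu(dk);
    dx += wq * dq + wk * dk;
    if (residual) dx += dout;
    dX.row(b) = dx.t();
  }
  datt(0, 0) += dwq;
  datt(0, 1) += dbq;
  datt(0, 2) += dwk;
  datt(0, 3) += dbk;
  datt(0, 4) += dwv;
  datt(0, 5) += dbv;
  return dX;
}

// ------------------------------------------------------------ full model

struct Batch {
  arma::imat pocket;  // B x Lp integer codes (0 = pad)
  mat protein;        // (B*Lr) x 58
  arma::imat smiles;  // B x Ls
  vec y;
  arma::ivec len_pocket, len_protein, len_smiles;  // per-sample content
  int Lp, Lr, Ls;
  int B() const { return pocket.n_rows; }
};

// crop length: multiple of 4, >= 8, content + margin for the rightward
// spread of the same-padded conv stack (mirrors crop_lengths() in R)
static int crop_len(int content, int cap) {
  int L = ((content + 32 + 3) / 4) * 4;
  if (L < 8) L = 8;
  return std::min(L, cap);
}

struct Kernels {
  int pk1, pk2, pk3, sm1, sm2, sm3;
  bool att_residual;
  bool att_skip;  // diagnostic: bypass the attention layer entirely
};

struct FwdCache {
  mat Ep, Er, Es;
  BranchCache bp, br, bs;
  AttCache att;
  mat X384, O, H1pre, H1, D1, H2pre, H2, D2;
};

static mat embed_codes(const arma::imat& codes, const mat& emb, int B, int L) {
  mat E(size_t(B) * L, emb.n_cols, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < L; ++t) {
      const int code = codes(b, t);
      if (code > 0) E.row(size_t(b) * L + t) = emb.row(code);
    }
  return E;
}

static vec model_forward(Net& n, const Batch& d, const Kernels& ks,
                         double dropout, bool training, FwdCache* c) {
  const int B = d.B();
  FwdCache tmp;
  FwdCache& f = c ? *c : tmp;
  f.Ep = embed_codes(d.pocket, n.emb_pocket, B, d.Lp);
  f.Er = d.protein * n.Wproj;
  f.Es = embed_codes(d.smiles, n.emb_smiles, B, d.Ls);
  mat Gp = branch_forward(f.Ep, B, d.Lp, n.pkW1, n.pkW2, n.pkW3, ks.pk1,
                          ks.pk2, ks.pk3, c ? &f.bp : nullptr);
  mat Gr = branch_forward(f.Er, B, d.Lr, n.prW1, n.prW2, n.prW3, ks.pk1,
                          ks.pk2, ks.pk3, c ? &f.br : nullptr);
  mat Gs = branch_forward(f.Es, B, d.Ls, n.smW1, n.smW2, n.smW3, ks.sm1,
                          ks.sm2, ks.sm3, c ? &f.bs : nullptr);
  f.X384 = arma::join_rows(Gp, Gr, Gs);
  f.O = ks.att_skip ? f.X384
                    : attention_forward(f.X384, n.att, c ? &f.att : nullptr,
                                        ks.att_residual);
  f.H1pre = f.O * n.Wf1;
  f.H1pre.each_row() += n.bf1.row(0);
  f.H1 = f.H1pre;
  f.H1.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && dropout > 0) {
    f.D1.set_size(f.H1.n_rows, f.H1.n_cols);
    const double keep = 1.0 - dropout;
    for (uword i = 0; i < f.D1.n_elem; ++i)
      f.D1(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    f.H1 %= f.D1;
  }
  f.H2pre = f.H1 * n.Wf2;
  f.H2pre.each_row() += n.bf2.row(0);
  f.H2 = f.H2pre;
  f.H2.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && dropout > 0) {
    f.D2.set_size(f.H2.n_rows, f.H2.n_cols);
    const double keep = 1.0 - dropout;
    for (uword i = 0; i < f.D2.n_elem; ++i)
      f.D2(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    f.H2 %= f.D2;
  }
  return f.H2 * n.Wo.col(0) + n.bo(0, 0);
}

static double logcosh_mean(const vec& e) {
  vec a = arma::abs(e);
  return arma::mean(a + arma::log1p(arma::exp(-2.0 * a)) - std::log(2.0));
}

static void model_backward(Net& n, Net& g, const Batch& d, const Kernels& ks,
                           double dropout, FwdCache& f, const vec& yhat) {
  const int B = d.B();
  vec e = yhat - d.y;
  vec dyhat = arma::tanh(e) / double(B);  // d/de mean(log cosh e)
  g.Wo += f.H2.t() * dyhat;
  g.bo(0, 0) += arma::accu(dyhat);
  mat dH2 = dyhat * n.Wo.col(0).t();
  if (dropout > 0 && f.D2.n_elem) dH2 %= f.D2;
  dH2 %= arma::conv_to<mat>::from(f.H2pre > 0);
  g.Wf2 += f.H1.t() * dH2;
  g.bf2.row(0) += arma::sum(dH2, 0);
  mat dH1 = dH2 * n.Wf2.t();
  if (dropout > 0 && f.D1.n_elem) dH1 %= f.D1;
  dH1 %= arma::conv_to<mat>::from(f.H1pre > 0);
  g.Wf1 += f.O.t() * dH1;
  g.bf1.row(0) += arma::sum(dH1, 0);
  mat dO = dH1 * n.Wf1.t();
  mat dX384 = ks.att_skip
                  ? dO
                  : attention_backward(dO, f.att, n.att, g.att, ks.att_residual);
  const int E = n.emb_pocket.n_cols;
  mat dGp = dX384.cols(0, E - 1);
  mat dGr = dX384.cols(E, 2 * E - 1);
  mat dGs = dX384.cols(2 * E, 3 * E - 1);
  mat dEp = branch_backward(dGp, B, f.bp, n.pkW1, n.pkW2, n.pkW3, ks.pk1,
                            ks.pk2, ks.pk3, g.pkW1, g.pkW2, g.pkW3);
  mat dEr = branch_backward(dGr, B, f.br, n.prW1, n.prW2, n.prW3, ks.pk1,
                            ks.pk2, ks.pk3, g.prW1, g.prW2, g.prW3);
  mat dEs = branch_backward(dGs, B, f.bs, n.smW1, n.smW2, n.smW3, ks.sm1,
                            ks.sm2, ks.sm3, g.smW1, g.smW2, g.smW3);
  // embedding gradients: scatter-add per code, pad row stays zero
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < d.Lp; ++t) {
      const int code = d.pocket(b, t);
      if (code > 0) g.emb_pocket.row(code) += dEp.row(size_t(b) * d.Lp + t);
    }
    for (int t = 0; t < d.Ls; ++t) {
      const int code = d.smiles(b, t);
      if (code > 0) g.emb_smiles.row(code) += dEs.row(size_t(b) * d.Ls + t);
    }
  }
  g.Wproj += d.protein.t() * dEr;
}

// ------------------------------------------------------------ data glue

static Batch batch_from_list(const List& data) {
  Batch d;
  d.pocket = as<arma::imat>(data["pocket"]);
  d.protein = as<mat>(data["protein"]);
  d.smiles = as<arma::imat>(data["smiles"]);
  d.y = data.containsElementNamed("y") ? as<vec>(data["y"])
                                       : vec(d.pocket.n_rows, arma::fill::zeros);
  d.Lp = d.pocket.n_cols;
  d.Ls = d.smiles.n_cols;
  d.Lr = d.protein.n_rows / d.pocket.n_rows;
  const int N = d.pocket.n_rows;
  d.len_pocket.set_size(N);
  d.len_protein.set_size(N);
  d.len_smiles.set_size(N);
  for (int i = 0; i < N; ++i) {
    int lp = 0, ls = 0, lr = 0;
    for (int t = 0; t < d.Lp; ++t)
      if (d.pocket(i, t) != 0) lp = t + 1;
    for (int t = 0; t < d.Ls; ++t)
      if (d.smiles(i, t) != 0) ls = t + 1;
    for (int t = 0; t < d.Lr; ++t)
      if (arma::any(d.protein.row(size_t(i) * d.Lr + t) != 0)) lr = t + 1;
    d.len_pocket(i) = lp;
    d.len_protein(i) = lr;
    d.len_smiles(i) = ls;
  }
  return d;
}

static Batch batch_subset(const Batch& d, const arma::uvec& idx) {
  Batch s;
  // crop each block to the batch's own content (exact: see crop_len)
  int cp = 0, cr = 0, cs = 0;
  for (uword i = 0; i < idx.n_elem; ++i) {
    cp = std::max(cp, int(d.len_pocket(idx(i))));
    cr = std::max(cr, int(d.len_protein(idx(i))));
    cs = std::max(cs, int(d.len_smiles(idx(i))));
  }
  s.Lp = crop_len(cp, d.Lp);
  s.Lr = crop_len(cr, d.Lr);
  s.Ls = crop_len(cs, d.Ls);
  s.pocket = d.pocket.submat(arma::conv_to<arma::uvec>::from(idx),
                             arma::regspace<arma::uvec>(0, s.Lp - 1));
  s.smiles = d.smiles.submat(arma::conv_to<arma::uvec>::from(idx),
                             arma::regspace<arma::uvec>(0, s.Ls - 1));
  s.y = d.y(idx);
  s.len_pocket = d.len_pocket(idx);
  s.len_protein = d.len_protein(idx);
  s.len_smiles = d.len_smiles(idx);
  s.protein.set_size(idx.n_elem * s.Lr, d.protein.n_cols);
  for (uword i = 0; i < idx.n_elem; ++i)
    s.protein.rows(i * s.Lr, (i + 1) * s.Lr - 1) =
        d.protein.rows(idx(i) * d.Lr, idx(i) * d.Lr + s.Lr - 1);
  return s;
}

static Kernels kernels_from_cfg(const List& cfg) {
  IntegerVector kp = cfg["kernel_protein_pocket"], ksm = cfg["kernel_smiles"];
  Kernels ks;
  ks.pk1 = kp[0];
  ks.pk2 = kp[1];
  ks.pk3 = kp[2];
  ks.sm1 = ksm[0];
  ks.sm2 = ksm[1];
  ks.sm3 = ksm[2];
  ks.att_residual = cfg.containsElementNamed("attention_residual")
                        ? as<bool>(cfg["attention_residual"])
                        : false;
  ks.att_skip = cfg.containsElementNamed("attention_skip")
                    ? as<bool>(cfg["attention_skip"])
                    : false;
  return ks;
}

static vec predict_chunked(Net& n, const Batch& d, const Kernels& ks) {
  const int N = d.B();
  const int maxL = std::max(d.Lp, std::max(d.Lr, d.Ls));
  const int chunk = std::max(1, 16384 / maxL);
  vec out(N);
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    arma::uvec idx = arma::regspace<arma::uvec>(s, e - 1);
    Batch sub = batch_subset(d, idx);
    out.subvec(s, e - 1) = model_forward(n, sub, ks, 0.0, false, nullptr);
  }
  return out;
}

// ------------------------------------------------------------ exports

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = "cpp_predict")]]
NumericVector cpp_predict(List weights, List data, List cfg) {
  Net n = net_from_list(weights);
  Batch d = batch_from_list(data);
  Kernels ks = kernels_from_cfg(cfg);
  vec out = predict_chunked(n, d, ks);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export(name = "cpp_loss")]]
double cpp_loss(List weights, List data, List cfg) {
  Net n = net_from_list(weights);
  Batch d = batch_from_list(data);
  Kernels ks = kernels_from_cfg(cfg);
  vec yhat = predict_chunked(n, d, ks);
  return logcosh_mean(yhat - d.y);
}

// [[Rcpp::export(name = "cpp_train")]]
List cpp_train(List weights, List train, List val, List cfg) {
  Net n = net_from_list(weights);
  Batch tr = batch_from_list(train);
  Batch va = batch_from_list(val);
  Kernels ks = kernels_from_cfg(cfg);
  const int epochs = as<int>(cfg["epochs"]);
  const int batch = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["lr"]);
  const double dropout = as<double>(cfg["dropout"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  Net g = net_zeros_like(n), m1 = net_zeros_like(n), m2 = net_zeros_like(n);
  std::vector<mat*> pn = n.params(), pg = g.params(), pm = m1.params(),
                    pv = m2.params();
  const int N = tr.B();
  long step = 0;
  double best = R_PosInf;
  int best_epoch = -1;
  Net bestnet = n;
  NumericVector hist_tr(epochs), hist_va(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    arma::uvec ord = arma::regspace<arma::uvec>(0, N - 1);
    for (int i = N - 1; i > 0; --i) {
      int j = int(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    double ep_loss = 0;
    int nb = 0;
    for (int s = 0; s < N; s += batch, ++nb) {
      const int e = std::min(N, s + batch);
      Batch bd = batch_subset(tr, ord.subvec(s, e - 1));
      FwdCache f;
      vec yhat = model_forward(n, bd, ks, dropout, true, &f);
      ep_loss += logcosh_mean(yhat - bd.y);
      for (mat* gm : pg) gm->zeros();
      model_backward(n, g, bd, ks, dropout, f, yhat);
      ++step;
      const double corr =
          lr * std::sqrt(1.0 - std::pow(b2, step)) / (1.0 - std::pow(b1, step));
      for (size_t i = 0; i < pn.size(); ++i) {
        *pm[i] = b1 * (*pm[i]) + (1 - b1) * (*pg[i]);
        *pv[i] = b2 * (*pv[i]) + (1 - b2) * arma::square(*pg[i]);
        *pn[i] -= corr * (*pm[i]) / (arma::sqrt(*pv[i]) + eps);
      }
      // keep the pad embedding rows frozen at zero
      n.emb_pocket.row(0).zeros();
      n.emb_smiles.row(0).zeros();
    }
    vec vhat = predict_chunked(n, va, ks);
    const double vloss = logcosh_mean(vhat - va.y);
    hist_tr[ep] = ep_loss / std::max(nb, 1);
    hist_va[ep] = vloss;
    if (vloss < best) {
      best = vloss;
      best_epoch = ep + 1;
      bestnet = n;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(bestnet),
                      _["final_weights"] = net_to_list(n),
                      _["train_loss"] = hist_tr, _["val_loss"] = hist_va,
                      _["best_epoch"] = best_epoch,
                      _["best_val_loss"] = best);
}

// single CNN branch on one embedded sequence (L x E) -> 128-vector
// [[Rcpp::export(name = "cpp_cnn_branch")]]
NumericVector cpp_cnn_branch(NumericMatrix seq, List Ws, IntegerVector kernels) {
  mat E = as<mat>(seq);
  mat W1 = as<mat>(Ws[0]), W2 = as<mat>(Ws[1]), W3 = as<mat>(Ws[2]);
  if (E.n_rows < 4)
    stop("sequence shorter than the conv/pool stack can contract (need >= 4)");
  mat G = branch_forward(E, 1, E.n_rows, W1, W2, W3, kernels[0], kernels[1],
                         kernels[2], nullptr);
  vec out = G.row(0).t();
  return NumericVector(out.begin(), out.end());
}

// attention layer as used inside the model (scalar token projections)
// [[Rcpp::export(name = "cpp_model_attention")]]
NumericMatrix cpp_model_attention(NumericMatrix X, NumericVector att) {
  mat A(1, 6);
  for (int i = 0; i < 6; ++i) A(0, i) = att[i];
  return wrap(attention_forward(as<mat>(X), A, nullptr));
}

// finite-difference-checkable loss+gradient for one batch (test hook)
// [[Rcpp::export(name = "cpp_loss_grad")]]
List cpp_loss_grad(List weights, List data, List cfg) {
  Net n = net_from_list(weights);
  Batch d = batch_from_list(data);
  Kernels ks = kernels_from_cfg(cfg);
  Net g = net_zeros_like(n);
  FwdCache f;
  vec yhat = model_forward(n, d, ks, 0.0, true, &f);
  model_backward(n, g, d, ks, 0.0, f, yhat);
  return List::create(_["loss"] = logcosh_mean(yhat - d.y),
                      _["grad"] = net_to_list(g));
}
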