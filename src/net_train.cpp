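// Compiled training loop for the compact convolutional PRP classifier.
// Mirrors the R reference implementation (R/nnet.R) operation for
// operation: Toeplitz/block-diagonal matmul convolutions, ELU, average
// pooling, inverted dropout, Adam with max-norm on the spatial filters,
// and checkpointing at the lowest validation loss. All randomness
// (shuffling, dropout) is drawn from R's RNG so results are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int E, Tn, K, F1, D, C1, F2, K1, K2, T1, T2, Pflat;
};

struct Consts {
  uvec fill1, grp1;           // single-filter Toeplitz fill / kernel taps
  uvec fill1s, ends1;         // sorted gather for the kernel gradient
  uvec s2_lin;                // Sstack[(d,f), e] scatter of the S cube
  uvec m_fill, m_val, m_fills;
  uvec m_ends;
  mat pool1, pool2;
};

struct Params {
  mat W1;    // K1 x F1
  cube S;    // D x E x F1
  vec b1;    // C1
  mat W3;    // K2 x C1
  mat W4;    // C1 x F2
  vec b4;    // F2
  mat W5;    // Pflat x K
  vec b5;    // K
};

inline mat elu(const mat& z) {
  mat out = z;
  out.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  return out;
}

inline mat elu_grad(const mat& z) {
  mat out = z;
  out.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); });
  return out;
}

// (B*E, T) -> (E, B*T)
mat perm_M0_to_Xmat(const mat& M0, int B, int E, int T) {
  mat X(E, B * T);
  for (int t = 0; t < T; ++t) {
    const double* src = M0.colptr(t);
    double* dst = X.colptr(t * B);
    for (int e = 0; e < E; ++e)
      for (int b = 0; b < B; ++b)
        dst[(size_t)b * E + e] = src[b + e * B];
  }
  return X;
}

// (E, B*T) -> (B*E, T)
mat perm_Xmat_to_M0(const mat& X, int B, int E, int T) {
  mat M0(B * E, T);
  for (int t = 0; t < T; ++t) {
    double* dst = M0.colptr(t);
    const double* src = X.colptr(t * B);
    for (int e = 0; e < E; ++e)
      for (int b = 0; b < B; ++b)
        dst[b + e * B] = src[(size_t)b * E + e];
  }
  return M0;
}

// (C1, B*T) -> (B*C1, T), rows ordered (b, c)
mat perm_U_to_Um(const mat& U, int B, int C1, int T) {
  mat Um(B * C1, T);
  for (int t = 0; t < T; ++t) {
    const double* src = U.colptr(t * B);
    double* dst = Um.colptr(t);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < C1; ++c)
        dst[b + c * B] = src[(size_t)b * C1 + c];
  }
  return Um;
}

// (B*C1, T) -> (C1, B*T)
mat perm_Um_to_U(const mat& dUm, int B, int C1, int T) {
  mat dU(C1, B * T);
  for (int t = 0; t < T; ++t) {
    const double* src = dUm.colptr(t);
    double* dst = dU.colptr(t * B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < C1; ++c)
        dst[(size_t)b * C1 + c] = src[b + c * B];
  }
  return dU;
}

// (B, C1*T1) -> (B*T1, C1)
mat perm_Z4_to_M4(const mat& Z4, int B, int C1, int T1) {
  mat M4(B * T1, C1);
  for (int c = 0; c < C1; ++c) {
    double* dst = M4.colptr(c);
    for (int t = 0; t < T1; ++t) {
      const double* src = Z4.colptr(c + t * C1);
      for (int b = 0; b < B; ++b) dst[b + t * B] = src[b];
    }
  }
  return M4;
}

// (B*T1, C1) -> (B, C1*T1)
mat perm_M4_to_Z4(const mat& dM4, int B, int C1, int T1) {
  mat dZ4(B, C1 * T1);
  for (int c = 0; c < C1; ++c) {
    const double* src = dM4.colptr(c);
    for (int t = 0; t < T1; ++t) {
      double* dst = dZ4.colptr(c + t * C1);
      for (int b = 0; b < B; ++b) dst[b] = src[b + t * B];
    }
  }
  return dZ4;
}

// (B*T1, F2) -> (B*F2, T1)
mat perm_A5_to_P2in(const mat& A5, int B, int T1, int F2) {
  mat P(B * F2, T1);
  for (int f = 0; f < F2; ++f) {
    const double* src = A5.colptr(f);
    for (int t = 0; t < T1; ++t) {
      double* dst = P.colptr(t);
      for (int b = 0; b < B; ++b) dst[b + f * B] = src[b + t * B];
    }
  }
  return P;
}

// (B*F2, T1) -> (B*T1, F2)
mat perm_P2in_to_A5(const mat& dP, int B, int T1, int F2) {
  mat dA5(B * T1, F2);
  for (int f = 0; f < F2; ++f) {
    double* dst = dA5.colptr(f);
    for (int t = 0; t < T1; ++t) {
      const double* src = dP.colptr(t);
      for (int b = 0; b < B; ++b) dst[b + t * B] = src[b + f * B];
    }
  }
  return dA5;
}

struct Cache {
  mat Xmat, Um, Sstack, ZbM, P1, A4, Mbig, M4, Z5, Xf;
  std::vector<mat> Toep;   // per-temporal-filter T x T convolution matrix
  mat m1, m2;              // dropout masks (empty when disabled)
  mat logits, probs;
  int B;
};

void forward(const Params& p, const Consts& cs, const Dims& d,
             const mat& M0, bool use_masks, const mat& m1, const mat& m2,
             Cache& c) {
  // The depthwise spatial filtering is applied before the temporal
  // convolution (both are linear and the temporal kernel is shared
  // across electrodes, so the order is mathematically irrelevant);
  // this cuts the arithmetic roughly in half relative to the naive
  // order used by the R reference implementation.
  int B = M0.n_rows / d.E;
  c.B = B;
  c.Xmat = perm_M0_to_Xmat(M0, B, d.E, d.Tn);
  c.Sstack.zeros(d.C1, d.E);
  c.Sstack.elem(cs.s2_lin) = vec(p.S.memptr(), p.S.n_elem);
  mat U = c.Sstack * c.Xmat;                  // C1 x (B*T)
  c.Um = perm_U_to_Um(U, B, d.C1, d.Tn);      // (B*C1) x T, rows (b, c)
  c.Toep.assign(d.F1, mat());
  c.ZbM.set_size(B * d.C1, d.Tn);
  for (int f = 0; f < d.F1; ++f) {
    c.Toep[f].zeros(d.Tn, d.Tn);
    c.Toep[f].elem(cs.fill1) = vec(p.W1.colptr(f), d.K1).elem(cs.grp1);
    int r0 = f * d.D * B, r1 = (f + 1) * d.D * B - 1;
    c.ZbM.rows(r0, r1) = c.Um.rows(r0, r1) * c.Toep[f];
  }
  for (int cc = 0; cc < d.C1; ++cc)
    c.ZbM.rows(cc * B, (cc + 1) * B - 1) += p.b1[cc];
  mat A3 = elu(c.ZbM);
  c.P1 = A3 * cs.pool1;
  if (use_masks) c.P1 %= m1;
  c.A4 = mat(c.P1.memptr(), B, d.C1 * d.T1);  // pure reshape
  c.Mbig.zeros(d.C1 * d.T1, d.C1 * d.T1);
  c.Mbig.elem(cs.m_fill) = vec(p.W3.memptr(), p.W3.n_elem).elem(cs.m_val);
  mat Z4 = c.A4 * c.Mbig;
  c.M4 = perm_Z4_to_M4(Z4, B, d.C1, d.T1);
  c.Z5 = c.M4 * p.W4;
  c.Z5.each_row() += p.b4.t();
  mat A5 = elu(c.Z5);
  mat P2in = perm_A5_to_P2in(A5, B, d.T1, d.F2);
  mat P2 = P2in * cs.pool2;
  if (use_masks) P2 %= m2;
  c.Xf = mat(P2.memptr(), B, d.Pflat);        // pure reshape
  c.logits = c.Xf * p.W5;
  c.logits.each_row() += p.b5.t();
  mat sh = c.logits.each_col() - max(c.logits, 1);
  mat ex = exp(sh);
  c.probs = ex.each_col() / sum(ex, 1);
  if (use_masks) { c.m1 = m1; c.m2 = m2; }
}

vec grouped_sums(const mat& G, const uvec& fill_sorted, const uvec& ends) {
  vec vals = G.elem(fill_sorted);
  vec cs = cumsum(vals);
  vec out(ends.n_elem);
  uword prev = 0;
  for (uword i = 0; i < ends.n_elem; ++i) {
    out[i] = cs[ends[i] - 1] - (i == 0 ? 0.0 : cs[ends[i - 1] - 1]);
    prev = ends[i];
  }
  (void)prev;
  return out;
}

void backward(const Params& p, const Consts& cs, const Dims& d,
              const Cache& c, const mat& dlogits, Params& g) {
  int B = c.B;
  bool use_masks = c.m1.n_elem > 0;
  g.W5 = c.Xf.t() * dlogits;
  g.b5 = sum(dlogits, 0).t();
  mat dXf = dlogits * p.W5.t();
  mat dP2 = mat(dXf.memptr(), B * d.F2, d.T2);
  if (use_masks) dP2 %= c.m2;
  mat dP2in = dP2 * cs.pool2.t();
  mat dA5 = perm_P2in_to_A5(dP2in, B, d.T1, d.F2);
  mat dZ5 = dA5 % elu_grad(c.Z5);
  g.b4 = sum(dZ5, 0).t();
  g.W4 = c.M4.t() * dZ5;
  mat dM4 = dZ5 * p.W4.t();
  mat dZ4 = perm_M4_to_Z4(dM4, B, d.C1, d.T1);
  mat dA4 = dZ4 * c.Mbig.t();
  mat G3 = c.A4.t() * dZ4;
  g.W3 = mat(grouped_sums(G3, cs.m_fills, cs.m_ends).memptr(),
             d.K2, d.C1);
  mat dP1 = mat(dA4.memptr(), B * d.C1, d.T1);
  if (use_masks) dP1 %= c.m1;
  mat dA3 = dP1 * cs.pool1.t();
  mat dZb = dA3 % elu_grad(c.ZbM);
  // bias gradient per channel (rows of dZb are ordered (b, c))
  g.b1.set_size(d.C1);
  for (int cc = 0; cc < d.C1; ++cc)
    g.b1[cc] = accu(dZb.rows(cc * B, (cc + 1) * B - 1));
  // depthwise temporal convolution: kernel gradients and input grad
  mat dUm(B * d.C1, d.Tn);
  g.W1.set_size(d.K1, d.F1);
  for (int f = 0; f < d.F1; ++f) {
    int r0 = f * d.D * B, r1 = (f + 1) * d.D * B - 1;
    dUm.rows(r0, r1) = dZb.rows(r0, r1) * c.Toep[f].t();
    mat Gf = c.Um.rows(r0, r1).t() * dZb.rows(r0, r1);  // T x T
    g.W1.col(f) = grouped_sums(Gf, cs.fill1s, cs.ends1);
  }
  mat dU = perm_Um_to_U(dUm, B, d.C1, d.Tn);
  mat dSstack = dU * c.Xmat.t();              // C1 x E
  vec sflat = dSstack.elem(cs.s2_lin);
  g.S = cube(sflat.memptr(), d.D, d.E, d.F1);
}

void adam_update(Params& p, const Params& g, Params& m, Params& v,
                 int t, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  auto upd = [&](mat& pm, const mat& gm, mat& mm, mat& vm) {
    mm = b1 * mm + (1 - b1) * gm;
    vm = b2 * vm + (1 - b2) * square(gm);
    pm -= lr * (mm / c1) / (sqrt(vm / c2) + eps);
  };
  auto updv = [&](vec& pm, const vec& gm, vec& mm, vec& vm) {
    mm = b1 * mm + (1 - b1) * gm;
    vm = b2 * vm + (1 - b2) * square(gm);
    pm -= lr * (mm / c1) / (sqrt(vm / c2) + eps);
  };
  upd(p.W1, g.W1, m.W1, v.W1);
  { // cube S
    mat ps(p.S.memptr(), p.S.n_elem, 1, false, true);
    mat gs(const_cast<double*>(g.S.memptr()), g.S.n_elem, 1, false, true);
    mat ms(m.S.memptr(), m.S.n_elem, 1, false, true);
    mat vs(v.S.memptr(), v.S.n_elem, 1, false, true);
    upd(ps, gs, ms, vs);
  }
  updv(p.b1, g.b1, m.b1, v.b1);
  upd(p.W3, g.W3, m.W3, v.W3);
  upd(p.W4, g.W4, m.W4, v.W4);
  updv(p.b4, g.b4, m.b4, v.b4);
  upd(p.W5, g.W5, m.W5, v.W5);
  updv(p.b5, g.b5, m.b5, v.b5);
  // max-norm on the depthwise spatial filters
  for (uword f = 0; f < p.S.n_slices; ++f)
    for (uword dd = 0; dd < p.S.n_rows; ++dd) {
      rowvec r = p.S.slice(f).row(dd);
      double nrm = norm(r, 2);
      if (nrm > 1.0) p.S.slice(f).row(dd) = r / nrm;
    }
}

double xent(const mat& probs, const ivec& y) {
  double s = 0;
  for (uword i = 0; i < y.n_elem; ++i)
    s += -std::log(std::max(probs(i, y[i] - 1), 1e-12));
  return s / y.n_elem;
}

Params params_from_list(const Rcpp::List& pl) {
  Params p;
  p.W1 = Rcpp::as<mat>(pl["W1"]);
  p.S = Rcpp::as<cube>(pl["S"]);
  p.b1 = Rcpp::as<vec>(pl["b1"]);
  p.W3 = Rcpp::as<mat>(pl["W3"]);
  p.W4 = Rcpp::as<mat>(pl["W4"]);
  p.b4 = Rcpp::as<vec>(pl["b4"]);
  p.W5 = Rcpp::as<mat>(pl["W5"]);
  p.b5 = Rcpp::as<vec>(pl["b5"]);
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = p.W1, Rcpp::Named("S") = p.S,
    Rcpp::Named("b1") = p.b1, Rcpp::Named("W3") = p.W3,
    Rcpp::Named("W4") = p.W4, Rcpp::Named("b4") = p.b4,
    Rcpp::Named("W5") = p.W5, Rcpp::Named("b5") = p.b5);
}

Params zeros_like(const Params& p) {
  Params z;
  z.W1 = zeros<mat>(size(p.W1));
  z.S = zeros<cube>(size(p.S));
  z.b1 = zeros<vec>(size(p.b1));
  z.W3 = zeros<mat>(size(p.W3));
  z.W4 = zeros<mat>(size(p.W4));
  z.b4 = zeros<vec>(size(p.b4));
  z.W5 = zeros<mat>(size(p.W5));
  z.b5 = zeros<vec>(size(p.b5));
  return z;
}

Dims dims_from_list(const Rcpp::List& dl) {
  Dims d;
  d.E = dl["E"]; d.Tn = dl["Tn"]; d.K = dl["K"]; d.F1 = dl["F1"];
  d.D = dl["D"]; d.C1 = dl["C1"]; d.F2 = dl["F2"]; d.K1 = dl["K1"];
  d.K2 = dl["K2"]; d.T1 = dl["T1"]; d.T2 = dl["T2"]; d.Pflat = dl["Pflat"];
  return d;
}

Consts consts_from_model(const Rcpp::List& model) {
  Consts cs;
  Rcpp::List tm1s = model["tm1s"];
  cs.fill1 = Rcpp::as<uvec>(tm1s["fill"]) - 1;
  cs.grp1 = Rcpp::as<uvec>(tm1s["grp"]) - 1;
  cs.fill1s = Rcpp::as<uvec>(tm1s["fill_sorted"]) - 1;
  cs.ends1 = Rcpp::as<uvec>(tm1s["grp_ends"]);
  cs.s2_lin = Rcpp::as<uvec>(model["s2_lin"]) - 1;
  cs.m_fill = Rcpp::as<uvec>(model["m_fill"]) - 1;
  cs.m_val = Rcpp::as<uvec>(model["m_val"]) - 1;
  cs.m_fills = Rcpp::as<uvec>(model["m_fill_sorted"]) - 1;
  cs.m_ends = Rcpp::as<uvec>(model["m_ends"]);
  cs.pool1 = Rcpp::as<mat>(model["pool1"]);
  cs.pool2 = Rcpp::as<mat>(model["pool2"]);
  return cs;
}

} // namespace

// Single forward pass (no dropout); returns logits and probabilities.
// Used for prediction and for cross-checking the R reference path.
// [[Rcpp::export(name = ".cpp_net_forward")]]
Rcpp::List cpp_net_forward(const Rcpp::List& model,
                           const Rcpp::NumericVector& X) {
  Rcpp::List pl = model["params"];
  Params p = params_from_list(pl);
  Dims d = dims_from_list(model["dims"]);
  Consts cs = consts_from_model(model);
  Rcpp::IntegerVector dm = X.attr("dim");
  int B = dm[0];
  mat M0(const_cast<double*>(X.begin()), B * d.E, d.Tn, false, true);
  Cache c;
  forward(p, cs, d, M0, false, mat(), mat(), c);
  return Rcpp::List::create(Rcpp::Named("logits") = c.logits,
                            Rcpp::Named("probs") = c.probs);
}

// Full training loop with Adam, lr decay, dropout, patience-based early
// stopping and checkpointing at the lowest validation loss.
// [[Rcpp::export(name = ".cpp_net_train")]]
Rcpp::List cpp_net_train(const Rcpp::List& model,
                         const Rcpp::NumericVector& Xtr,
                         const Rcpp::IntegerVector& ytr,
                         const Rcpp::NumericVector& Xval,
                         const Rcpp::IntegerVector& yval,
                         double lr0, double lr_decay, int decay_every,
                         int max_epochs, int batch_size, double dropout,
                         double patience, int min_epochs) {
  Rcpp::List pl = model["params"];
  Params p = params_from_list(pl);
  Dims d = dims_from_list(model["dims"]);
  Consts cs = consts_from_model(model);

  Rcpp::IntegerVector dmt = Xtr.attr("dim");
  int n = dmt[0];
  mat M0tr(const_cast<double*>(Xtr.begin()), n * d.E, d.Tn, false, true);
  Rcpp::IntegerVector dmv = Xval.attr("dim");
  int nv = dmv[0];
  mat M0val(const_cast<double*>(Xval.begin()), nv * d.E, d.Tn, false, true);
  ivec ytr_a = Rcpp::as<ivec>(ytr);
  ivec yval_a = Rcpp::as<ivec>(yval);

  Params m = zeros_like(p), v = zeros_like(p), g = zeros_like(p);
  Params best = p;
  double best_loss = datum::inf;
  int best_epoch = 0, since_best = 0, t_adam = 0;

  Rcpp::RNGScope rng;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  Cache c;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    double lr = lr0 * std::pow(lr_decay, (epoch - 1) / decay_every);
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      int B = std::min(batch_size, n - b0);
      mat M0b(B * d.E, d.Tn);
      ivec yb(B);
      for (int i = 0; i < B; ++i) {
        int src = ord[b0 + i];
        yb[i] = ytr_a[src];
        for (int e = 0; e < d.E; ++e)
          M0b.row(i + e * B) = M0tr.row(src + e * n);
      }
      mat m1, m2;
      bool use_masks = dropout > 0;
      if (use_masks) {
        m1.set_size(B * d.C1, d.T1);
        m2.set_size(B * d.F2, d.T2);
        for (uword i = 0; i < m1.n_elem; ++i)
          m1[i] = (unif_rand() >= dropout) / (1.0 - dropout);
        for (uword i = 0; i < m2.n_elem; ++i)
          m2[i] = (unif_rand() >= dropout) / (1.0 - dropout);
      }
      forward(p, cs, d, M0b, use_masks, m1, m2, c);
      mat dlog = c.probs;
      for (int i = 0; i < B; ++i) dlog(i, yb[i] - 1) -= 1.0;
      dlog /= B;
      backward(p, cs, d, c, dlog, g);
      ++t_adam;
      adam_update(p, g, m, v, t_adam, lr);
    }
    Cache cv_;
    forward(p, cs, d, M0val, false, mat(), mat(), cv_);
    double vloss = xent(cv_.probs, yval_a);
    if (vloss < best_loss) {
      best_loss = vloss;
      best = p;
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best >= patience && epoch >= min_epochs) {
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(best),
                            Rcpp::Named("val_loss") = best_loss,
                            Rcpp::Named("best_epoch") = best_epoch);
}
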