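// Feature-guided 1-D CNN: conv/BN/LeakyReLU/pool stack, FC head, tanh fusion
// layer, mean-squared-error loss, full backpropagation and Adam updates.
// Layout conventions:
//  - activations between layers are matrices of shape (B*L) x D with row
//    index r = b*L + t (sample b, time t); convolution uses 'same' zero
//    padding via im2col, kernels stored as (kl*Din) x Dout matrices with row
//    index u*Din + din (tap u, input channel din);
//  - max pooling takes non-overlapping pairs (2i-1, 2i), flooring odd tails;
//  - batch normalisation uses biased batch statistics while training and
//    running statistics (momentum 0.1) at inference;
//  - LeakyReLU slopes are learnable, one scalar per layer;
//  - batch-norm normalisation, activation and pooling are fused per-column
//    loops over raw memory: these passes are bandwidth-bound and dominate
//    the runtime if written as separate whole-matrix expressions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::as;

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;

// 'same' padding split: left pad floor((kl-1)/2), remainder on the right.
static inline int padLeft(int kl) { return (kl - 1) / 2; }

struct NetConfig {
  int nc;
  std::vector<int> filters, kernels;
  int inputLen, fc1, outDim, pDim;
  double lr, beta1, beta2, eps;
  bool freezeWl;
};

static NetConfig readConfig(const List& cfg) {
  NetConfig c;
  Rcpp::IntegerVector f = cfg["convFilters"], k = cfg["convKernels"];
  c.filters.assign(f.begin(), f.end());
  c.kernels.assign(k.begin(), k.end());
  c.nc = (int)c.filters.size();
  c.inputLen = as<int>(cfg["inputLen"]);
  c.fc1 = as<int>(cfg["fc1"]);
  c.outDim = as<int>(cfg["outDim"]);
  c.pDim = as<int>(cfg["pDim"]);
  c.lr = as<double>(cfg["learningRate"]);
  c.beta1 = as<double>(cfg["beta1"]);
  c.beta2 = as<double>(cfg["beta2"]);
  c.eps = as<double>(cfg["epsilon"]);
  c.freezeWl = cfg.containsElementNamed("freezeWl") ?
    as<bool>(cfg["freezeWl"]) : false;
  return c;
}

struct Net {
  NetConfig cfg;
  // parameters (biases/slopes kept as 1 x k matrices for a uniform registry)
  std::vector<mat> Wc, bc, gam, bet, slope;
  std::vector<mat> rmean, rvar;  // running BN stats, not trained
  mat W1, b1, slopeFc, W2, b2, wl, wp;
  // Adam state
  std::vector<mat> mMom, vMom;
  double tStep;
  // geometry
  std::vector<int> Lin, Lp;
  int flatDim;
  // forward caches
  std::vector<mat> M, Z, Xhat, V, Apool;
  std::vector<rowvec> muC, invstdC;
  mat F0, H1pre, H1, Lfeat, Pc;
  vec u, yhat;
  int B;
  // gradients
  std::vector<mat> dWc, dbc, dgam, dbet, dslope;
  mat dW1, db1, dslopeFc, dW2, db2, dwl, dwp;

  void geometry() {
    Lin.resize(cfg.nc); Lp.resize(cfg.nc);
    int L = cfg.inputLen;
    for (int i = 0; i < cfg.nc; ++i) {
      if (L < 2) Rcpp::stop("layer %d input length %d is too short to pool",
                            i + 1, L);
      Lin[i] = L;
      Lp[i] = L / 2;
      L = Lp[i];
    }
    flatDim = Lp[cfg.nc - 1] * cfg.filters[cfg.nc - 1];
  }

  void fromParams(const List& params) {
    List w = params["weights"];
    List bn = params["bn"];
    List adam = params["adam"];
    Wc.clear(); bc.clear(); gam.clear(); bet.clear(); slope.clear();
    rmean.clear(); rvar.clear();
    for (int i = 0; i < cfg.nc; ++i) {
      std::string s = std::to_string(i + 1);
      Wc.push_back(as<mat>(w["Wconv" + s]));
      bc.push_back(as<mat>(w["bconv" + s]));
      gam.push_back(as<mat>(w["gamma" + s]));
      bet.push_back(as<mat>(w["beta" + s]));
      slope.push_back(as<mat>(w["slope" + s]));
      rmean.push_back(as<mat>(bn["rmean" + s]));
      rvar.push_back(as<mat>(bn["rvar" + s]));
    }
    W1 = as<mat>(w["W1"]); b1 = as<mat>(w["b1"]);
    slopeFc = as<mat>(w["slopeFc"]);
    W2 = as<mat>(w["W2"]); b2 = as<mat>(w["b2"]);
    wl = as<mat>(w["wl"]);
    if (cfg.pDim > 0) wp = as<mat>(w["wp"]); else wp.set_size(0, 1);
    List m = adam["m"], v = adam["v"];
    mMom.clear(); vMom.clear();
    for (int i = 0; i < m.size(); ++i) {
      mMom.push_back(as<mat>(m[i]));
      vMom.push_back(as<mat>(v[i]));
    }
    tStep = as<double>(adam["t"]);
  }

  std::vector<mat*> registry() {
    std::vector<mat*> r;
    for (int i = 0; i < cfg.nc; ++i) {
      r.push_back(&Wc[i]); r.push_back(&bc[i]);
      r.push_back(&gam[i]); r.push_back(&bet[i]); r.push_back(&slope[i]);
    }
    r.push_back(&W1); r.push_back(&b1); r.push_back(&slopeFc);
    r.push_back(&W2); r.push_back(&b2); r.push_back(&wl);
    if (cfg.pDim > 0) r.push_back(&wp);
    return r;
  }
  std::vector<mat*> gradRegistry() {
    std::vector<mat*> r;
    for (int i = 0; i < cfg.nc; ++i) {
      r.push_back(&dWc[i]); r.push_back(&dbc[i]);
      r.push_back(&dgam[i]); r.push_back(&dbet[i]); r.push_back(&dslope[i]);
    }
    r.push_back(&dW1); r.push_back(&db1); r.push_back(&dslopeFc);
    r.push_back(&dW2); r.push_back(&db2); r.push_back(&dwl);
    if (cfg.pDim > 0) r.push_back(&dwp);
    return r;
  }

  List toParams(const Rcpp::CharacterVector& weightNames) {
    List w, bn;
    for (int i = 0; i < cfg.nc; ++i) {
      std::string s = std::to_string(i + 1);
      w["Wconv" + s] = Wc[i]; w["bconv" + s] = bc[i];
      w["gamma" + s] = gam[i]; w["beta" + s] = bet[i];
      w["slope" + s] = slope[i];
      bn["rmean" + s] = rmean[i]; bn["rvar" + s] = rvar[i];
    }
    w["W1"] = W1; w["b1"] = b1; w["slopeFc"] = slopeFc;
    w["W2"] = W2; w["b2"] = b2; w["wl"] = wl;
    if (cfg.pDim > 0) w["wp"] = wp;
    List m, v;
    std::vector<mat*> reg = registry();
    for (size_t i = 0; i < reg.size(); ++i) {
      std::string nm = as<std::string>(weightNames[i]);
      m[nm] = mMom[i]; v[nm] = vMom[i];
    }
    List adam = List::create(Named("m") = m, Named("v") = v,
                             Named("t") = tStep);
    return List::create(Named("weights") = w, Named("bn") = bn,
                        Named("adam") = adam);
  }

  void allocCaches() {
    M.assign(cfg.nc, mat()); Z.assign(cfg.nc, mat());
    Xhat.assign(cfg.nc, mat()); V.assign(cfg.nc, mat());
    Apool.assign(cfg.nc, mat());
    muC.assign(cfg.nc, rowvec()); invstdC.assign(cfg.nc, rowvec());
    dWc.assign(cfg.nc, mat()); dbc.assign(cfg.nc, mat());
    dgam.assign(cfg.nc, mat()); dbet.assign(cfg.nc, mat());
    dslope.assign(cfg.nc, mat());
  }

  // im2col from activation A ((B*L) x Din); per (tap, channel) the copy is
  // one contiguous column segment per sample.
  void im2col(int i, const mat& A, int L, int Din) {
    int kl = cfg.kernels[i];
    int pl = padLeft(kl);
    M[i].set_size(B * L, kl * Din);
    for (int uu = 0; uu < kl; ++uu) {
      int shift = uu - pl;
      int tlo = std::max(0, -shift), thi = std::min(L - 1, L - 1 - shift);
      for (int dn = 0; dn < Din; ++dn) {
        double* dst = M[i].colptr(uu * Din + dn);
        const double* src = A.colptr(dn);
        for (int b = 0; b < B; ++b) {
          double* d = dst + b * L;
          const double* s = src + b * L + shift;
          for (int t = 0; t < tlo; ++t) d[t] = 0.0;
          for (int t = tlo; t <= thi; ++t) d[t] = s[t];
          for (int t = thi + 1; t < L; ++t) d[t] = 0.0;
        }
      }
    }
  }

  void col2im(int i, const mat& dM, mat& dA, int L, int Din) {
    int kl = cfg.kernels[i];
    int pl = padLeft(kl);
    dA.zeros(B * L, Din);
    for (int uu = 0; uu < kl; ++uu) {
      int shift = uu - pl;
      int tlo = std::max(0, -shift), thi = std::min(L - 1, L - 1 - shift);
      if (tlo > thi) continue;
      for (int dn = 0; dn < Din; ++dn) {
        const double* src = dM.colptr(uu * Din + dn);
        double* dst = dA.colptr(dn);
        for (int b = 0; b < B; ++b) {
          const double* s = src + b * L;
          double* d = dst + b * L + shift;
          for (int t = tlo; t <= thi; ++t) d[t] += s[t];
        }
      }
    }
  }

  // Xbt: inputLen x B (one window per column); P: B x pDim
  double forward(const mat& Xbt, const mat& P, const vec* yPtr,
                 bool training) {
    B = Xbt.n_cols;
    Pc = P;
    // the (B*inputLen) x 1 layer-0 activation is Xbt's memory verbatim
    mat A(const_cast<double*>(Xbt.memptr()), B * cfg.inputLen, 1, false);
    int Din = 1;
    for (int i = 0; i < cfg.nc; ++i) {
      int L = Lin[i], Dout = cfg.filters[i];
      im2col(i, (i == 0) ? A : Apool[i - 1], L, Din);
      Z[i] = M[i] * Wc[i];
      int n = B * L;
      Xhat[i].set_size(n, Dout);
      V[i].set_size(n, Dout);
      muC[i].set_size(Dout); invstdC[i].set_size(Dout);
      double a = slope[i](0, 0);
      int Lpool = Lp[i];
      Apool[i].set_size(B * Lpool, Dout);
      for (int j = 0; j < Dout; ++j) {
        double* z = Z[i].colptr(j);
        double bias = bc[i](0, j);
        double mu, varb;
        if (training) {
          double s = 0, ss = 0;
          for (int r = 0; r < n; ++r) { z[r] += bias; s += z[r]; }
          mu = s / n;
          for (int r = 0; r < n; ++r) {
            double d = z[r] - mu; ss += d * d;
          }
          varb = ss / n;
          rmean[i](0, j) = (1.0 - BN_MOM) * rmean[i](0, j) + BN_MOM * mu;
          rvar[i](0, j) = (1.0 - BN_MOM) * rvar[i](0, j) + BN_MOM * varb;
        } else {
          for (int r = 0; r < n; ++r) z[r] += bias;
          mu = rmean[i](0, j);
          varb = rvar[i](0, j);
        }
        double is = 1.0 / std::sqrt(varb + BN_EPS);
        muC[i](j) = mu; invstdC[i](j) = is;
        double g = gam[i](0, j), be = bet[i](0, j);
        double* xh = Xhat[i].colptr(j);
        double* vv = V[i].colptr(j);
        for (int r = 0; r < n; ++r) {
          double x = (z[r] - mu) * is;
          xh[r] = x;
          double v = g * x + be;
          vv[r] = v;
        }
        // fused LeakyReLU + pairwise max pool over the activated values;
        // V keeps the pre-activation for the backward pass
        double* ap = Apool[i].colptr(j);
        for (int b = 0; b < B; ++b) {
          const double* vb = vv + b * L;
          double* apb = ap + b * Lpool;
          for (int ii = 0; ii < Lpool; ++ii) {
            double v1 = vb[2 * ii], v2 = vb[2 * ii + 1];
            double y1 = (v1 > 0) ? v1 : a * v1;
            double y2 = (v2 > 0) ? v2 : a * v2;
            apb[ii] = (y1 >= y2) ? y1 : y2;
          }
        }
      }
      Din = Dout;
    }
    // flatten: F0(b, d*Lp + ii) = Apool(b*Lp + ii, d)
    int Lpool = Lp[cfg.nc - 1], Dlast = cfg.filters[cfg.nc - 1];
    const mat& Alast = Apool[cfg.nc - 1];
    F0.set_size(B, flatDim);
    for (int d = 0; d < Dlast; ++d) {
      const double* src = Alast.colptr(d);
      for (int ii = 0; ii < Lpool; ++ii) {
        double* dst = F0.colptr(d * Lpool + ii);
        for (int b = 0; b < B; ++b) dst[b] = src[b * Lpool + ii];
      }
    }
    H1pre = F0 * W1;
    H1pre.each_row() += b1.row(0);
    double af = slopeFc(0, 0);
    H1.set_size(B, cfg.fc1);
    {
      const double* p = H1pre.memptr();
      double* q = H1.memptr();
      uword nEl = H1pre.n_elem;
      for (uword k = 0; k < nEl; ++k) q[k] = p[k] > 0 ? p[k] : af * p[k];
    }
    Lfeat = H1 * W2;
    Lfeat.each_row() += b2.row(0);
    u = Lfeat * wl;
    if (cfg.pDim > 0) u += Pc * wp;
    yhat = tanh(u);
    if (yPtr == nullptr) return 0.0;
    return accu(square(*yPtr - yhat)) / (double)B;
  }

  void backward(const vec& y) {
    vec du = (2.0 / (double)B) * (yhat - y) % (1.0 - square(yhat));
    dwl = Lfeat.t() * du;
    if (cfg.pDim > 0) dwp = Pc.t() * du;
    mat dL;
    if (cfg.freezeWl) {
      dwl.zeros();
      dL.zeros(B, cfg.outDim);
    } else {
      dL = du * wl.t();
    }
    dW2 = H1.t() * dL;
    db2 = sum(dL, 0);
    mat dH1 = dL * W2.t();
    double af = slopeFc(0, 0);
    mat dH1pre(B, cfg.fc1);
    double sFc = 0;
    {
      const double* p = H1pre.memptr();
      const double* g = dH1.memptr();
      double* q = dH1pre.memptr();
      uword nEl = dH1pre.n_elem;
      for (uword k = 0; k < nEl; ++k) {
        if (p[k] > 0) q[k] = g[k];
        else { q[k] = af * g[k]; sFc += g[k] * p[k]; }
      }
    }
    dslopeFc.set_size(1, 1);
    dslopeFc(0, 0) = sFc;
    dW1 = F0.t() * dH1pre;
    db1 = sum(dH1pre, 0);
    mat dF0 = dH1pre * W1.t();
    // unflatten
    int Lpool = Lp[cfg.nc - 1], Dlast = cfg.filters[cfg.nc - 1];
    mat dA(B * Lpool, Dlast);
    for (int d = 0; d < Dlast; ++d) {
      double* dst = dA.colptr(d);
      for (int ii = 0; ii < Lpool; ++ii) {
        const double* src = dF0.colptr(d * Lpool + ii);
        for (int b = 0; b < B; ++b) dst[b * Lpool + ii] = src[b];
      }
    }
    for (int i = cfg.nc - 1; i >= 0; --i) {
      int L = Lin[i], Dout = cfg.filters[i];
      int Lpool_i = Lp[i];
      double a = slope[i](0, 0);
      double n = (double)(B * L);
      mat dZ(B * L, Dout);
      dgam[i].set_size(1, Dout); dbet[i].set_size(1, Dout);
      dslope[i].set_size(1, 1);
      double sSlope = 0;
      for (int j = 0; j < Dout; ++j) {
        // fused pool + LeakyReLU backward: route the pooled gradient to the
        // pair's argmax (on the pre-activation V), through the activation
        const double* vv = V[i].colptr(j);
        const double* gpool = dA.colptr(j);
        const double* xh = Xhat[i].colptr(j);
        double* dz = dZ.colptr(j);
        double g = gam[i](0, j);
        double s1 = 0, s2 = 0, dgj = 0, dbj = 0;
        std::fill(dz, dz + B * L, 0.0);
        // first pass: dV routed sparsely; accumulate BN sums (dz holds dXhat)
        for (int b = 0; b < B; ++b) {
          const double* vb = vv + b * L;
          const double* gb = gpool + b * Lpool_i;
          double* dzb = dz + b * L;
          for (int ii = 0; ii < Lpool_i; ++ii) {
            double v1 = vb[2 * ii], v2 = vb[2 * ii + 1];
            double y1 = (v1 > 0) ? v1 : a * v1;
            double y2 = (v2 > 0) ? v2 : a * v2;
            int r = (y1 >= y2) ? 2 * ii : 2 * ii + 1;
            double vr = vb[r];
            double dv = (vr > 0) ? gb[ii] : a * gb[ii];
            if (vr <= 0) sSlope += gb[ii] * vr;
            double xhr = xh[b * L + r];
            dgj += dv * xhr;
            dbj += dv;
            double dxh = dv * g;
            dzb[r] = dxh;
            s1 += dxh;
            s2 += dxh * xhr;
          }
        }
        dgam[i](0, j) = dgj;
        dbet[i](0, j) = dbj;
        double is = invstdC[i](j);
        double c1 = s1 / n, c2 = s2 / n;
        for (int r = 0; r < B * L; ++r) {
          dz[r] = is * (dz[r] - c1 - xh[r] * c2);
        }
      }
      dslope[i](0, 0) = sSlope;
      dWc[i] = M[i].t() * dZ;
      dbc[i] = sum(dZ, 0);
      if (i > 0) {
        mat dM = dZ * Wc[i].t();
        int Din = cfg.filters[i - 1];
        col2im(i, dM, dA, L, Din);
      }
    }
  }

  void adamStep() {
    tStep += 1.0;
    std::vector<mat*> w = registry();
    std::vector<mat*> g = gradRegistry();
    double bc1 = 1.0 - std::pow(cfg.beta1, tStep);
    double bc2 = 1.0 - std::pow(cfg.beta2, tStep);
    for (size_t i = 0; i < w.size(); ++i) {
      double* wm = w[i]->memptr();
      const double* gm = g[i]->memptr();
      double* m = mMom[i].memptr();
      double* v = vMom[i].memptr();
      uword nEl = w[i]->n_elem;
      for (uword k = 0; k < nEl; ++k) {
        m[k] = cfg.beta1 * m[k] + (1.0 - cfg.beta1) * gm[k];
        v[k] = cfg.beta2 * v[k] + (1.0 - cfg.beta2) * gm[k] * gm[k];
        wm[k] -= cfg.lr * (m[k] / bc1) /
          (std::sqrt(v[k] / bc2) + cfg.eps);
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_train(const arma::mat& X, const arma::mat& P, const arma::vec& y,
               List params, List config, const Rcpp::IntegerMatrix& orders,
               int batchSize, Rcpp::CharacterVector weightNames) {
  Net net;
  net.cfg = readConfig(config);
  net.geometry();
  net.fromParams(params);
  net.allocCaches();
  int N = X.n_rows;
  mat Xt = X.t();  // contiguous per-window columns for cheap gathering
  mat Pt = P.t();
  int epochs = orders.nrow();
  vec lossHist(epochs, fill::zeros);
  mat Xbt(X.n_cols, batchSize);
  mat Pbt(P.n_cols, batchSize);
  for (int e = 0; e < epochs; ++e) {
    double sumLoss = 0.0;
    for (int start = 0; start < N; start += batchSize) {
      int stop = std::min(start + batchSize, N) - 1;
      int Bsz = stop - start + 1;
      if ((int)Xbt.n_cols != Bsz) {
        Xbt.set_size(X.n_cols, Bsz);
        Pbt.set_size(P.n_cols, Bsz);
      }
      vec yb(Bsz);
      for (int k = 0; k < Bsz; ++k) {
        int idx = orders(e, start + k);
        Xbt.col(k) = Xt.col(idx);
        if (P.n_cols > 0) Pbt.col(k) = Pt.col(idx);
        yb(k) = y(idx);
      }
      double loss = net.forward(Xbt, Pbt.t(), &yb, true);
      net.backward(yb);
      net.adamStep();
      sumLoss += loss * Bsz;
    }
    lossHist(e) = sumLoss / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("params") = net.toParams(weightNames),
                      Named("lossHistory") = lossHist);
}

// [[Rcpp::export]]
List cpp_predict(const arma::mat& X, const arma::mat& P, List params,
                 List config) {
  Net net;
  net.cfg = readConfig(config);
  net.geometry();
  net.fromParams(params);
  net.allocCaches();
  int N = X.n_rows;
  int chunk = 512;
  mat l(N, net.cfg.outDim);
  vec yhat(N);
  for (int start = 0; start < N; start += chunk) {
    int stop = std::min(start + chunk, N) - 1;
    mat Xbt = X.rows(start, stop).t();
    mat Pb = P.n_cols > 0 ? mat(P.rows(start, stop)) : mat(Xbt.n_cols, 0);
    net.forward(Xbt, Pb, nullptr, false);
    l.rows(start, stop) = net.Lfeat;
    yhat.subvec(start, stop) = net.yhat;
  }
  return List::create(Named("l") = l, Named("yhat") = yhat);
}

// Loss and analytic gradients for one batch (training-mode batch statistics,
// running-stat side effects discarded) -- supports finite-difference checks.
// [[Rcpp::export]]
List cpp_loss_grads(const arma::mat& X, const arma::mat& P,
                    const arma::vec& y, List params, List config,
                    Rcpp::CharacterVector weightNames, bool gradients) {
  Net net;
  net.cfg = readConfig(config);
  net.geometry();
  net.fromParams(params);
  net.allocCaches();
  mat Xbt = X.t();
  double loss = net.forward(Xbt, P, &y, true);
  if (!gradients) return List::create(Named("loss") = loss);
  net.backward(y);
  std::vector<mat*> g = net.gradRegistry();
  List grads;
  for (size_t i = 0; i < g.size(); ++i) {
    grads[as<std::string>(weightNames[i])] = *g[i];
  }
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// One bias-corrected Adam step on a single tensor; the same arithmetic the
// training loop applies. `tPrev` is the step counter before this update.
// [[Rcpp::export]]
List cpp_adam_step(const arma::mat& w, const arma::mat& g, const arma::mat& m,
                   const arma::mat& v, double tPrev, double lr, double beta1,
                   double beta2, double eps) {
  double t = tPrev + 1.0;
  mat m2 = beta1 * m + (1.0 - beta1) * g;
  mat v2 = beta2 * v + (1.0 - beta2) * square(g);
  mat w2 = w - lr * (m2 / (1.0 - std::pow(beta1, t))) /
    (sqrt(v2 / (1.0 - std::pow(beta2, t))) + eps);
  return List::create(Named("weight") = w2, Named("m") = m2, Named("v") = v2,
                      Named("t") = t);
}

// Single-sample 'same'-padded 1-D convolution (no BN/activation); x is
// L x Din, W is (kl*Din) x Dout with row index tap*Din + channel.
// [[Rcpp::export]]
arma::mat cpp_conv1d_same(const arma::mat& x, const arma::mat& W,
                          const arma::rowvec& bias, int kl) {
  int L = x.n_rows, Din = x.n_cols, Dout = W.n_cols;
  if ((int)W.n_rows != kl * Din)
    Rcpp::stop("kernel matrix must have kl*Din rows");
  if (kl > L) Rcpp::stop("kernel longer than the input");
  int pl = padLeft(kl);
  mat M(L, kl * Din, fill::zeros);
  for (int uu = 0; uu < kl; ++uu) {
    int shift = uu - pl;
    int tlo = std::max(0, -shift), thi = std::min(L - 1, L - 1 - shift);
    if (tlo > thi) continue;
    for (int dn = 0; dn < Din; ++dn) {
      M.submat(tlo, uu * Din + dn, thi, uu * Din + dn) =
        x.submat(tlo + shift, dn, thi + shift, dn);
    }
  }
  mat out = M * W;
  out.each_row() += bias;
  return out;
}

// Pairwise (non-overlapping) max pooling along rows; odd tail dropped.
// [[Rcpp::export]]
arma::mat cpp_maxpool_pairs(const arma::mat& y) {
  int L = y.n_rows, D = y.n_cols;
  if (L < 2) Rcpp::stop("pooling needs at least two rows");
  int Lp = L / 2;
  mat out(Lp, D);
  for (int i = 0; i < Lp; ++i) {
    for (int j = 0; j < D; ++j) {
      out(i, j) = std::max(y(2 * i, j), y(2 * i + 1, j));
    }
  }
  return out;
}
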