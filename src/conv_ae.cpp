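// 1-D convolutional autoencoder: same-padding convolutions via im2col GEMM,
// factor-4 max pooling / step-repetition upsampling, ReLU hidden units and a
// sigmoid output layer, trained with Adam on the mean-absolute-error loss.
// Single precision throughout, as is conventional for such models.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Arch {
  int k = 5, p = 4, L = 256, d = 16;
  std::vector<int> encF, decF;  // conv output feature counts
  std::vector<int> encT;        // encoder conv input lengths
  std::vector<int> decT;        // decoder conv input lengths
};

Arch makeArch(int d) {
  Arch a;
  a.d = d;
  auto mx = [&](int v) { return std::max(v, d); };
  a.encF = {mx(64), mx(32), mx(16), d};
  a.decF = {mx(16), mx(16), mx(32), mx(64), 1};
  a.encT = {256, 64, 16, 4};
  a.decT = {1, 4, 16, 64, 256};
  return a;
}

// input cube (C, T, N) -> patch matrix (C*k, T*N); zero padding at borders
fmat im2col(const fcube& X, int k) {
  const int C = X.n_rows, T = X.n_cols, N = X.n_slices, pad = k / 2;
  fmat col(C * k, (uword)T * N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int kk = 0; kk < k; ++kk) {
      const int off = kk - pad;
      const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
      if (t1 <= t0) continue;
      col.submat(kk * C, (uword)n * T + t0,
                 kk * C + C - 1, (uword)n * T + t1 - 1) =
          X.slice(n).cols(t0 + off, t1 + off - 1);
    }
  return col;
}

fcube col2im(const fmat& dcol, int C, int T, int N, int k) {
  const int pad = k / 2;
  fcube dX(C, T, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int kk = 0; kk < k; ++kk) {
      const int off = kk - pad;
      const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
      if (t1 <= t0) continue;
      dX.slice(n).cols(t0 + off, t1 + off - 1) +=
          dcol.submat(kk * C, (uword)n * T + t0,
                      kk * C + C - 1, (uword)n * T + t1 - 1);
    }
  return dX;
}

fcube matToCube(const fmat& Y, int C, int T, int N) {
  return fcube(const_cast<float*>(Y.memptr()), C, T, N, true);
}

fmat cubeToMat(const fcube& X) {
  return fmat(const_cast<float*>(X.memptr()), X.n_rows,
              (uword)X.n_cols * X.n_slices, true);
}

void maxPool(const fcube& X, int p, fcube& Y, ucube& mask) {
  const int C = X.n_rows, T = X.n_cols, N = X.n_slices, To = T / p;
  Y.set_size(C, To, N);
  mask.set_size(C, To, N);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < To; ++t)
      for (int c = 0; c < C; ++c) {
        float best = X(c, t * p, n);
        uword bj = 0;
        for (int j = 1; j < p; ++j) {
          const float v = X(c, t * p + j, n);
          if (v > best) { best = v; bj = j; }
        }
        Y(c, t, n) = best;
        mask(c, t, n) = bj;
      }
}

fcube maxPoolBack(const fcube& dY, const ucube& mask, int p) {
  const int C = dY.n_rows, To = dY.n_cols, N = dY.n_slices;
  fcube dX(C, To * p, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < To; ++t)
      for (int c = 0; c < C; ++c)
        dX(c, t * p + mask(c, t, n), n) = dY(c, t, n);
  return dX;
}

fcube upsample(const fcube& X, int p) {
  const int C = X.n_rows, T = X.n_cols, N = X.n_slices;
  fcube Y(C, T * p, N);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < p; ++j)
        Y.slice(n).col(t * p + j) = X.slice(n).col(t);
  return Y;
}

fcube upsampleBack(const fcube& dY, int p) {
  const int C = dY.n_rows, T = dY.n_cols / p, N = dY.n_slices;
  fcube dX(C, T, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < p; ++j)
        dX.slice(n).col(t) += dY.slice(n).col(t * p + j);
  return dX;
}

struct Params {
  std::vector<fmat> W;  // (Cout, Cin*k)
  std::vector<fvec> b;
};

Params fromR(const Rcpp::List& weights) {
  Params P;
  for (int i = 0; i < weights.size(); ++i) {
    Rcpp::List layer = weights[i];
    P.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(layer["W"])));
    P.b.push_back(conv_to<fvec>::from(Rcpp::as<vec>(layer["b"])));
  }
  return P;
}

Rcpp::List toR(const Params& P) {
  Rcpp::List out(P.W.size());
  for (size_t i = 0; i < P.W.size(); ++i)
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(P.W[i]),
        Rcpp::Named("b") = conv_to<vec>::from(P.b[i]));
  return out;
}

struct Cache {
  std::vector<fmat> cols;    // im2col of each conv input (9)
  std::vector<fcube> acts;   // post-activation conv outputs (9)
  std::vector<ucube> masks;  // encoder pool argmax (4)
};

// forward pass over a batch; X is (L, N) in [0, 1]
void forwardPass(const Params& P, const Arch& a, const fmat& X,
                 fmat& code, fmat& recon, Cache* cache) {
  const int N = X.n_cols;
  fcube A = matToCube(X, 1, a.L, N);
  for (int l = 0; l < 4; ++l) {
    fmat col = im2col(A, a.k);
    fmat Z = P.W[l] * col;
    Z.each_col() += P.b[l];
    Z.clamp(0.0f, std::numeric_limits<float>::infinity());  // ReLU
    fcube Zc = matToCube(Z, a.encF[l], a.encT[l], N);
    fcube pooled; ucube mask;
    maxPool(Zc, a.p, pooled, mask);
    if (cache) {
      cache->cols.push_back(std::move(col));
      cache->acts.push_back(std::move(Zc));
      cache->masks.push_back(std::move(mask));
    }
    A = std::move(pooled);
  }
  code = cubeToMat(A);  // (d, N)
  for (int l = 0; l < 5; ++l) {
    fmat col = im2col(A, a.k);
    fmat Z = P.W[4 + l] * col;
    Z.each_col() += P.b[4 + l];
    if (l < 4)
      Z.clamp(0.0f, std::numeric_limits<float>::infinity());
    else
      Z = 1.0f / (1.0f + exp(-Z));  // sigmoid output layer
    fcube Zc = matToCube(Z, a.decF[l], a.decT[l], N);
    if (cache) {
      cache->cols.push_back(std::move(col));
      cache->acts.push_back(Zc);
    }
    A = (l < 4) ? upsample(Zc, a.p) : std::move(Zc);
  }
  // final activation is (1, L, N); its memory layout matches an (L, N) matrix
  recon = fmat(const_cast<float*>(A.memptr()), a.L, N, true);
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
};

// backward pass for the MAE loss; returns batch MAE
float backwardPass(const Params& P, const Arch& a, const fmat& X,
                   const Cache& cache, const fmat& recon, Grads& g) {
  const int N = X.n_cols;
  const float scale = 1.0f / ((float)a.L * N);
  const fmat diff = recon - X;
  const float mae = accu(abs(diff)) / ((float)a.L * N);
  fmat dRecon = conv_to<fmat>::from(sign(diff)) * scale;
  fcube dA = matToCube(dRecon, 1, a.L, N);

  // decoder, last layer (sigmoid) back to first
  for (int l = 4; l >= 0; --l) {
    const int idx = 4 + l;
    if (l < 4) dA = upsampleBack(dA, a.p);
    const fcube& act = cache.acts[idx];
    fcube dZ(size(act));
    if (l == 4)
      dZ = dA % act % (1.0f - act);
    else
      dZ = dA % conv_to<fcube>::from(act > 0.0f);
    fmat dZm = cubeToMat(dZ);
    g.dW[idx] = dZm * cache.cols[idx].t();
    g.db[idx] = sum(dZm, 1);
    fmat dcol = P.W[idx].t() * dZm;
    dA = col2im(dcol, (l == 0) ? a.d : a.decF[l - 1], a.decT[l], N, a.k);
  }

  // encoder, last layer back to input
  for (int l = 3; l >= 0; --l) {
    dA = maxPoolBack(dA, cache.masks[l], a.p);
    const fcube& act = cache.acts[l];
    fcube dZ = dA % conv_to<fcube>::from(act > 0.0f);
    fmat dZm = cubeToMat(dZ);
    g.dW[l] = dZm * cache.cols[l].t();
    g.db[l] = sum(dZm, 1);
    if (l > 0) {
      fmat dcol = P.W[l].t() * dZm;
      dA = col2im(dcol, a.encF[l - 1], a.encT[l], N, a.k);
    }
  }
  return mae;
}

float datasetMAE(const Params& P, const Arch& a, const fmat& X,
                 int chunk = 512) {
  double total = 0.0;
  const int N = X.n_cols;
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    fmat code, recon;
    forwardPass(P, a, X.cols(s, e - 1), code, recon, nullptr);
    total += (double)accu(abs(recon - X.cols(s, e - 1)));
  }
  return (float)(total / ((double)a.L * N));
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_ae_forward(Rcpp::List weights, arma::mat X, int latentDim,
                          int chunk = 512) {
  const Arch a = makeArch(latentDim);
  if ((int)X.n_rows != a.L)
    Rcpp::stop("segments must have %d samples, got %d", a.L, (int)X.n_rows);
  const Params P = fromR(weights);
  const fmat Xf = conv_to<fmat>::from(X);
  const int N = Xf.n_cols;
  mat codeAll(latentDim, N), reconAll(a.L, N);
  for (int s = 0; s < N; s += chunk) {
    const int e = std::min(N, s + chunk);
    fmat code, recon;
    forwardPass(P, a, Xf.cols(s, e - 1), code, recon, nullptr);
    codeAll.cols(s, e - 1) = conv_to<mat>::from(code);
    reconAll.cols(s, e - 1) = conv_to<mat>::from(recon);
  }
  return Rcpp::List::create(Rcpp::Named("code") = codeAll,
                            Rcpp::Named("recon") = reconAll);
}

// [[Rcpp::export]]
Rcpp::List cpp_ae_train(Rcpp::List weights, arma::mat Xtrain, arma::mat Xval,
                        int latentDim, int epochs, int batchSize, double lr,
                        int seed) {
  const Arch a = makeArch(latentDim);
  if ((int)Xtrain.n_rows != a.L)
    Rcpp::stop("segments must have %d samples", a.L);
  Params P = fromR(weights);
  const fmat Xf = conv_to<fmat>::from(Xtrain);
  const fmat Xv = conv_to<fmat>::from(Xval);
  const int N = Xf.n_cols, nLayer = (int)P.W.size();

  // Adam state
  std::vector<fmat> mW(nLayer), vW(nLayer);
  std::vector<fvec> mb(nLayer), vb(nLayer);
  for (int i = 0; i < nLayer; ++i) {
    mW[i].zeros(size(P.W[i])); vW[i].zeros(size(P.W[i]));
    mb[i].zeros(size(P.b[i])); vb[i].zeros(size(P.b[i]));
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f, eta = (float)lr;
  long step = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> trainMAE(epochs), valMAE(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epochLoss = 0.0; long seen = 0;
    for (int s = 0; s < N; s += batchSize) {
      const int e = std::min(N, s + batchSize);
      fmat Xb(a.L, e - s);
      for (int j = s; j < e; ++j) Xb.col(j - s) = Xf.col(order[j]);
      Cache cache;
      fmat code, recon;
      forwardPass(P, a, Xb, code, recon, &cache);
      Grads g;
      g.dW.resize(nLayer); g.db.resize(nLayer);
      const float mae = backwardPass(P, a, Xb, cache, recon, g);
      epochLoss += (double)mae * (e - s); seen += e - s;
      ++step;
      const float c1 = 1.0f - std::pow(b1, (float)step);
      const float c2 = 1.0f - std::pow(b2, (float)step);
      for (int i = 0; i < nLayer; ++i) {
        mW[i] = b1 * mW[i] + (1 - b1) * g.dW[i];
        vW[i] = b2 * vW[i] + (1 - b2) * square(g.dW[i]);
        P.W[i] -= eta * (mW[i] / c1) / (sqrt(vW[i] / c2) + eps);
        mb[i] = b1 * mb[i] + (1 - b1) * g.db[i];
        vb[i] = b2 * vb[i] + (1 - b2) * square(g.db[i]);
        P.b[i] -= eta * (mb[i] / c1) / (sqrt(vb[i] / c2) + eps);
      }
    }
    trainMAE[ep] = epochLoss / seen;
    valMAE[ep] = Xv.n_cols ? (double)datasetMAE(P, a, Xv) : NA_REAL;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = toR(P),
      Rcpp::Named("trainMAE") = trainMAE,
      Rcpp::Named("valMAE") = valMAE);
}
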