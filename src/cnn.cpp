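// Multi-branch 1D CNN for windowed IMU signals.
//
// Three identical-topology branches (accelerometer, gyroscope, magnetometer):
//   conv(128 filters, k=5) -> ReLU -> conv(128, k=3) -> ReLU -> maxpool(2/2)
//   -> conv(64, k=5) -> ReLU -> conv(64, k=3) -> ReLU -> maxpool(2/2)
//   -> flatten
// concatenated, then dense(128) -> ReLU -> dropout(0.2) -> dense(128) -> ReLU
// -> dense(4) -> softmax, trained with Adam on categorical cross-entropy and
// early stopping on validation loss with best-weight restoration.
//
// Convolutions use valid padding and are evaluated as im2col + sgemm, single
// precision throughout; weights cross the R boundary as double matrices.

#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#define CHARNET_HAVE_MXCSR 1
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Converged networks produce gradients deep in the subnormal float range,
// where x86 arithmetic is orders of magnitude slower; flush-to-zero /
// denormals-are-zero mode during network computation avoids that (the
// values are far below any meaningful precision here). Restores the FP
// environment on scope exit.
struct FlushDenormalsGuard {
#ifdef CHARNET_HAVE_MXCSR
  unsigned int saved;
  FlushDenormalsGuard() : saved(_mm_getcsr()) {
    _mm_setcsr(saved | 0x8040); // FTZ (bit 15) | DAZ (bit 6)
  }
  ~FlushDenormalsGuard() { _mm_setcsr(saved); }
#endif
};

struct ConvCache {
  fmat Acol;   // (k*Cin) x (Tout*B)
  fcube Y;     // post-ReLU output (Cout, Tout, B)
};

struct PoolCache {
  Cube<unsigned char> arg; // which element of each pair was the max
  uword Tin;
};

// im2col with column order (sample-major, then output position):
// column index = b*Tout + t; rows ordered (tap kk, channel ci) = kk*Cin + ci
fcube conv_forward(const fcube& X, const fmat& W, const fvec& b, uword k,
                   ConvCache& cache, bool relu = true) {
  const uword Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword Tout = T - k + 1;
  cache.Acol.set_size(k * Cin, Tout * B);
  for (uword bb = 0; bb < B; ++bb) {
    const fmat& S = X.slice(bb);
    for (uword t = 0; t < Tout; ++t) {
      float* dst = cache.Acol.colptr(bb * Tout + t);
      for (uword kk = 0; kk < k; ++kk)
        std::memcpy(dst + kk * Cin, S.colptr(t + kk), Cin * sizeof(float));
    }
  }
  fmat Ym = W * cache.Acol;
  Ym.each_col() += b;
  if (relu) Ym.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fcube Y(Ym.memptr(), W.n_rows, Tout, B); // copies; layout matches
  cache.Y = Y;
  return Y;
}

// Applies the ReLU mask (from the cached post-activation output) to dY in
// place, then backprops through the affine map. The input gradient is
// skipped for the first layer of a branch (nothing consumes it).
fcube conv_backward(const fcube& X, const fmat& W, uword k,
                    const ConvCache& cache, fcube& dY,
                    fmat& gW, fvec& gb, bool need_dx = true) {
  const uword Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, Tout = T - k + 1;
  // ReLU gradient, in place
  {
    const float* y = cache.Y.memptr();
    float* d = dY.memptr();
    const uword n = dY.n_elem;
    for (uword i = 0; i < n; ++i) if (y[i] <= 0.0f) d[i] = 0.0f;
  }
  fmat dYm(dY.memptr(), Cout, Tout * B, false, true);
  gW = dYm * cache.Acol.t();
  gb = sum(dYm, 1);
  if (!need_dx) return fcube();
  fmat dA = W.t() * dYm; // (k*Cin) x (Tout*B)
  fcube dX(Cin, T, B, fill::zeros);
  for (uword bb = 0; bb < B; ++bb) {
    fmat& D = dX.slice(bb);
    for (uword t = 0; t < Tout; ++t) {
      const float* src = dA.colptr(bb * Tout + t);
      for (uword kk = 0; kk < k; ++kk) {
        float* dst = D.colptr(t + kk);
        const float* s2 = src + kk * Cin;
        for (uword ci = 0; ci < Cin; ++ci) dst[ci] += s2[ci];
      }
    }
  }
  return dX;
}

fcube pool_forward(const fcube& X, PoolCache& cache) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword To = T / 2; // valid pooling drops a trailing odd sample
  cache.arg.set_size(C, To, B);
  cache.Tin = T;
  fcube Y(C, To, B);
  for (uword bb = 0; bb < B; ++bb)
    for (uword t = 0; t < To; ++t)
      for (uword c = 0; c < C; ++c) {
        const float a = X(c, 2 * t, bb), d = X(c, 2 * t + 1, bb);
        if (a >= d) { Y(c, t, bb) = a; cache.arg(c, t, bb) = 0; }
        else        { Y(c, t, bb) = d; cache.arg(c, t, bb) = 1; }
      }
  return Y;
}

fcube pool_backward(const fcube& dY, const PoolCache& cache) {
  const uword C = dY.n_rows, To = dY.n_cols, B = dY.n_slices;
  fcube dX(C, cache.Tin, B, fill::zeros);
  for (uword bb = 0; bb < B; ++bb)
    for (uword t = 0; t < To; ++t)
      for (uword c = 0; c < C; ++c)
        dX(c, 2 * t + cache.arg(c, t, bb), bb) = dY(c, t, bb);
  return dX;
}

struct Params {
  std::vector<fmat> W;  // 12 conv (branch-major) + 3 dense
  std::vector<fvec> b;
  static const uword kernel[4];
};
const uword Params::kernel[4] = {5, 3, 5, 3};

Params from_r(const Rcpp::List& weights) {
  Params p;
  if (weights.size() != 30) Rcpp::stop("expected 30 weight entries");
  for (int i = 0; i < 15; ++i) {
    p.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(weights[2 * i])));
    p.b.push_back(conv_to<fvec>::from(Rcpp::as<vec>(weights[2 * i + 1])));
  }
  return p;
}

Rcpp::List to_r(const Params& p, Rcpp::CharacterVector names) {
  Rcpp::List out(30);
  for (int i = 0; i < 15; ++i) {
    out[2 * i] = Rcpp::wrap(conv_to<mat>::from(p.W[i]));
    out[2 * i + 1] = Rcpp::wrap(conv_to<vec>::from(p.b[i]));
  }
  out.attr("names") = names;
  return out;
}

// R array (Nw, Wl, Nc) -> fcube (Nc, Wl, Nw)
fcube r_array_to_cube(const Rcpp::NumericVector& a) {
  Rcpp::IntegerVector d = a.attr("dim");
  const uword Nw = d[0], Wl = d[1], Nc = d[2];
  fcube X(Nc, Wl, Nw);
  const double* src = a.begin();
  for (uword c = 0; c < Nc; ++c)
    for (uword t = 0; t < Wl; ++t) {
      const double* col = src + t * Nw + c * Nw * Wl;
      for (uword i = 0; i < Nw; ++i)
        X(c, t, i) = static_cast<float>(col[i]);
    }
  return X;
}

fcube gather(const fcube& X, const std::vector<uword>& idx, uword from, uword n) {
  fcube out(X.n_rows, X.n_cols, n);
  for (uword j = 0; j < n; ++j) out.slice(j) = X.slice(idx[from + j]);
  return out;
}

struct ForwardCache {
  ConvCache conv[12];
  PoolCache pool[6];
  fcube branch_in[3];
  fmat Hcat, H1, H1d, H2, P;
  fmat drop_mask;
};

// forward pass over one batch; if train, applies dropout with given rng
fmat net_forward(const Params& p, const fcube Xb[3], ForwardCache& fc,
                 bool train, double dropout, std::mt19937* rng) {
  const uword B = Xb[0].n_slices;
  std::vector<fmat> flat(3);
  for (int br = 0; br < 3; ++br) {
    fc.branch_in[br] = Xb[br];
    fcube h = conv_forward(Xb[br], p.W[br * 4 + 0], p.b[br * 4 + 0], 5,
                           fc.conv[br * 4 + 0]);
    h = conv_forward(h, p.W[br * 4 + 1], p.b[br * 4 + 1], 3, fc.conv[br * 4 + 1]);
    h = pool_forward(h, fc.pool[br * 2 + 0]);
    h = conv_forward(h, p.W[br * 4 + 2], p.b[br * 4 + 2], 5, fc.conv[br * 4 + 2]);
    h = conv_forward(h, p.W[br * 4 + 3], p.b[br * 4 + 3], 3, fc.conv[br * 4 + 3]);
    h = pool_forward(h, fc.pool[br * 2 + 1]);
    flat[br] = fmat(h.memptr(), h.n_rows * h.n_cols, B); // copy, col-major
  }
  fc.Hcat = join_cols(flat[0], join_cols(flat[1], flat[2])); // 5184 x B
  fc.H1 = p.W[12] * fc.Hcat;
  fc.H1.each_col() += p.b[12];
  fc.H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (train && dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    fc.drop_mask.set_size(fc.H1.n_rows, fc.H1.n_cols);
    const float keep = 1.0f - static_cast<float>(dropout);
    for (uword i = 0; i < fc.drop_mask.n_elem; ++i)
      fc.drop_mask(i) = (U(*rng) < keep) ? 1.0f / keep : 0.0f;
    fc.H1d = fc.H1 % fc.drop_mask;
  } else {
    fc.H1d = fc.H1;
  }
  fc.H2 = p.W[13] * fc.H1d;
  fc.H2.each_col() += p.b[13];
  fc.H2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat Z = p.W[14] * fc.H2;
  Z.each_col() += p.b[14];
  Z.each_row() -= max(Z, 0);
  fmat P = exp(Z);
  frowvec s = sum(P, 0);
  P.each_row() /= s;
  fc.P = P;
  return P;
}

void net_backward(const Params& p, const ForwardCache& fc,
                  const uvec& y, Params& g) {
  const uword B = fc.P.n_cols;
  fmat dZ = fc.P;
  for (uword i = 0; i < B; ++i) dZ(y(i), i) -= 1.0f;
  dZ /= static_cast<float>(B);
  g.W[14] = dZ * fc.H2.t();
  g.b[14] = sum(dZ, 1);
  fmat dH2 = p.W[14].t() * dZ;
  for (uword i = 0; i < dH2.n_elem; ++i) if (fc.H2(i) <= 0.0f) dH2(i) = 0.0f;
  g.W[13] = dH2 * fc.H1d.t();
  g.b[13] = sum(dH2, 1);
  fmat dH1 = p.W[13].t() * dH2;
  if (fc.drop_mask.n_elem > 0) dH1 %= fc.drop_mask;
  for (uword i = 0; i < dH1.n_elem; ++i) if (fc.H1(i) <= 0.0f) dH1(i) = 0.0f;
  g.W[12] = dH1 * fc.Hcat.t();
  g.b[12] = sum(dH1, 1);
  fmat dHcat = p.W[12].t() * dH1; // 5184 x B
  const uword per = dHcat.n_rows / 3;
  for (int br = 0; br < 3; ++br) {
    fmat dflat = dHcat.rows(br * per, (br + 1) * per - 1);
    const PoolCache& p2 = fc.pool[br * 2 + 1];
    const uword C4 = 64, T4 = dflat.n_rows / C4;
    fcube dh(dflat.memptr(), C4, T4, B); // copies
    dh = pool_backward(dh, p2);
    // conv4 (k=3): input was conv3's output
    const ConvCache& c3 = fc.conv[br * 4 + 2];
    const ConvCache& c4 = fc.conv[br * 4 + 3];
    fcube d3 = conv_backward(c3.Y, p.W[br * 4 + 3], 3, c4, dh,
                             g.W[br * 4 + 3], g.b[br * 4 + 3]);
    // conv3's input is pool1's output; rebuild it from conv2's cached output
    // and the stored argmax rather than caching it separately
    const ConvCache& c2 = fc.conv[br * 4 + 1];
    const PoolCache& p1 = fc.pool[br * 2 + 0];
    fcube pool1(c2.Y.n_rows, c2.Y.n_cols / 2, B);
    for (uword bb = 0; bb < B; ++bb)
      for (uword t = 0; t < pool1.n_cols; ++t)
        for (uword c = 0; c < pool1.n_rows; ++c)
          pool1(c, t, bb) = c2.Y(c, 2 * t + p1.arg(c, t, bb), bb);
    fcube d2p = conv_backward(pool1, p.W[br * 4 + 2], 5, c3, d3,
                              g.W[br * 4 + 2], g.b[br * 4 + 2]);
    fcube d2 = pool_backward(d2p, p1);
    const ConvCache& c1 = fc.conv[br * 4 + 0];
    fcube d1 = conv_backward(c1.Y, p.W[br * 4 + 1], 3, c2, d2,
                             g.W[br * 4 + 1], g.b[br * 4 + 1]);
    conv_backward(fc.branch_in[br], p.W[br * 4 + 0], 5, c1, d1,
                  g.W[br * 4 + 0], g.b[br * 4 + 0], /*need_dx=*/false);
  }
}

struct AdamState {
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  long t = 0;
  void init(const Params& p) {
    for (size_t i = 0; i < p.W.size(); ++i) {
      mW.push_back(fmat(size(p.W[i]), fill::zeros));
      vW.push_back(fmat(size(p.W[i]), fill::zeros));
      mb.push_back(fvec(size(p.b[i]), fill::zeros));
      vb.push_back(fvec(size(p.b[i]), fill::zeros));
    }
  }
  void step(Params& p, const Params& g, float lr) {
    ++t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    const float c1 = 1.0f - std::pow(b1, static_cast<float>(t));
    const float c2 = 1.0f - std::pow(b2, static_cast<float>(t));
    for (size_t i = 0; i < p.W.size(); ++i) {
      mW[i] = b1 * mW[i] + (1 - b1) * g.W[i];
      vW[i] = b2 * vW[i] + (1 - b2) * square(g.W[i]);
      p.W[i] -= lr * (mW[i] / c1) / (sqrt(vW[i] / c2) + eps);
      mb[i] = b1 * mb[i] + (1 - b1) * g.b[i];
      vb[i] = b2 * vb[i] + (1 - b2) * square(g.b[i]);
      p.b[i] -= lr * (mb[i] / c1) / (sqrt(vb[i] / c2) + eps);
    }
  }
};

// evaluate loss/accuracy over a full set in chunks, no dropout
void evaluate_set(const Params& p, const fcube X[3], const uvec& y,
                  uword chunk, double& loss, double& acc) {
  const uword N = y.n_elem;
  double ll = 0.0; uword correct = 0;
  ForwardCache fc;
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  for (uword at = 0; at < N; at += chunk) {
    const uword n = std::min(chunk, N - at);
    fcube Xb[3] = {gather(X[0], idx, at, n), gather(X[1], idx, at, n),
                   gather(X[2], idx, at, n)};
    fmat P = net_forward(p, Xb, fc, false, 0.0, nullptr);
    for (uword j = 0; j < n; ++j) {
      ll += -std::log(std::max(1e-12f, P(y(at + j), j)));
      if (P.col(j).index_max() == y(at + j)) ++correct;
    }
  }
  loss = ll / N;
  acc = static_cast<double>(correct) / N;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights,
                         Rcpp::NumericVector acc, Rcpp::NumericVector gyro,
                         Rcpp::NumericVector mag, Rcpp::IntegerVector y,
                         Rcpp::NumericVector vacc, Rcpp::NumericVector vgyro,
                         Rcpp::NumericVector vmag, Rcpp::IntegerVector vy,
                         int epochs, int batch_size, double lr, int patience,
                         double dropout, int seed) {
  FlushDenormalsGuard ftz;
  Params p = from_r(weights);
  fcube X[3] = {r_array_to_cube(acc), r_array_to_cube(gyro),
                r_array_to_cube(mag)};
  fcube XV[3] = {r_array_to_cube(vacc), r_array_to_cube(vgyro),
                 r_array_to_cube(vmag)};
  const uword N = y.size();
  uvec yt(N); for (uword i = 0; i < N; ++i) yt(i) = y[i];
  uvec yv(vy.size()); for (int i = 0; i < vy.size(); ++i) yv(i) = vy[i];

  AdamState adam; adam.init(p);
  Params g = p; // shapes
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  double best_val = std::numeric_limits<double>::infinity();
  Params best = p;
  int best_epoch = 0, wait = 0, stopped = epochs;
  ForwardCache fc;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0.0; uword tr_correct = 0; uword n_seen = 0;
    // drop-last batching: a trailing partial minibatch is skipped (that
    // epoch's shuffle already rotates which windows sit there), keeping
    // every batch - and every layer workspace - the same size
    const uword stop = (N >= static_cast<uword>(batch_size))
      ? N - (N % batch_size) : N;
    for (uword at = 0; at < stop; at += batch_size) {
      const uword n = std::min<uword>(batch_size, N - at);
      fcube Xb[3] = {gather(X[0], order, at, n), gather(X[1], order, at, n),
                     gather(X[2], order, at, n)};
      uvec yb(n);
      for (uword j = 0; j < n; ++j) yb(j) = yt(order[at + j]);
      fmat P = net_forward(p, Xb, fc, true, dropout, &rng);
      for (uword j = 0; j < n; ++j) {
        tr_loss += -std::log(std::max(1e-12f, P(yb(j), j)));
        if (P.col(j).index_max() == yb(j)) ++tr_correct;
      }
      net_backward(p, fc, yb, g);
      adam.step(p, g, static_cast<float>(lr));
      n_seen += n;
    }
    double vl, va;
    evaluate_set(p, XV, yv, 256, vl, va);
    h_tl.push_back(tr_loss / n_seen);
    h_ta.push_back(static_cast<double>(tr_correct) / n_seen);
    h_vl.push_back(vl);
    h_va.push_back(va);
    if (vl < best_val - 1e-9) {
      best_val = vl; best = p; best_epoch = ep; wait = 0;
    } else {
      ++wait;
      if (wait >= patience) { stopped = ep; break; }
    }
    stopped = ep;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = to_r(best, weights.attr("names")),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq(1, static_cast<int>(h_tl.size())),
      Rcpp::Named("train_loss") = h_tl, Rcpp::Named("train_acc") = h_ta,
      Rcpp::Named("val_loss") = h_vl, Rcpp::Named("val_acc") = h_va),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("stopped_epoch") = stopped,
    Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List weights, Rcpp::NumericVector acc,
                          Rcpp::NumericVector gyro, Rcpp::NumericVector mag,
                          int chunk = 256) {
  FlushDenormalsGuard ftz;
  Params p = from_r(weights);
  fcube X[3] = {r_array_to_cube(acc), r_array_to_cube(gyro),
                r_array_to_cube(mag)};
  const uword N = X[0].n_slices;
  mat out(N, 4);
  ForwardCache fc;
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;
  for (uword at = 0; at < N; at += chunk) {
    const uword n = std::min<uword>(chunk, N - at);
    fcube Xb[3] = {gather(X[0], idx, at, n), gather(X[1], idx, at, n),
                   gather(X[2], idx, at, n)};
    fmat P = net_forward(p, Xb, fc, false, 0.0, nullptr);
    for (uword j = 0; j < n; ++j)
      for (uword k = 0; k < 4; ++k)
        out(at + j, k) = P(k, j);
  }
  return out;
}

// per-branch temporal trace for a given Nc, as actually computed by the
// forward machinery (one zero sample pushed through one branch)
// [[Rcpp::export]]
Rcpp::IntegerMatrix cnn_branch_trace_cpp(Rcpp::List weights, int Nc) {
  Params p = from_r(weights);
  fcube x(Nc, 128, 1, fill::zeros);
  ConvCache cc; PoolCache pc;
  std::vector<std::array<int, 2>> shapes;
  shapes.push_back({static_cast<int>(x.n_rows), static_cast<int>(x.n_cols)});
  fcube h = conv_forward(x, p.W[0], p.b[0], 5, cc);
  shapes.push_back({static_cast<int>(h.n_rows), static_cast<int>(h.n_cols)});
  h = conv_forward(h, p.W[1], p.b[1], 3, cc);
  shapes.push_back({static_cast<int>(h.n_rows), static_cast<int>(h.n_cols)});
  h = pool_forward(h, pc);
  shapes.push_back({static_cast<int>(h.n_rows), static_cast<int>(h.n_cols)});
  h = conv_forward(h, p.W[2], p.b[2], 5, cc);
  shapes.push_back({static_cast<int>(h.n_rows), static_cast<int>(h.n_cols)});
  h = conv_forward(h, p.W[3], p.b[3], 3, cc);
  shapes.push_back({static_cast<int>(h.n_rows), static_cast<int>(h.n_cols)});
  h = pool_forward(h, pc);
  shapes.push_back({static_cast<int>(h.n_rows), static_cast<int>(h.n_cols)});
  Rcpp::IntegerMatrix out(shapes.size(), 2);
  for (size_t i = 0; i < shapes.size(); ++i) {
    out(i, 0) = shapes[i][0];
    out(i, 1) = shapes[i][1];
  }
  colnames(out) = Rcpp::CharacterVector::create("channels", "time");
  return out;
}

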