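// Compact 3-D convolutional regressor: optional average-pool stem, then
// conv(3x3x3, same padding) -> ReLU -> maxpool(2) blocks, global average
// pooling and a linear head; MSE loss, Adam updates.  Convolutions run as
// im2col + BLAS GEMM through Armadillo.  All randomness (weight init,
// epoch shuffling, augmentation angles) comes from one mt19937_64 stream
// so training is reproducible bit-for-bit on a given platform.
#include <RcppArmadillo.h>
#include <random>
#include "sampling.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct BlockGeom {
  int side_in, side_out, Vin, Vout, cin, cout;
  std::vector<int> nb;    // Vin x 27 neighbour source index, -1 = zero pad
  std::vector<int> child; // Vout x 8 pooled child indices
};

void build_geom(std::vector<BlockGeom> &G, int side0,
                const IntegerVector &channels) {
  int side = side0, cin = 1;
  for (int b = 0; b < channels.size(); ++b) {
    BlockGeom g;
    g.side_in = side;
    g.side_out = side / 2;
    g.Vin = side * side * side;
    g.Vout = g.side_out * g.side_out * g.side_out;
    g.cin = cin;
    g.cout = channels[b];
    g.nb.resize((size_t)g.Vin * 27);
    int d = side;
    for (int i3 = 0; i3 < d; ++i3)
      for (int i2 = 0; i2 < d; ++i2)
        for (int i1 = 0; i1 < d; ++i1) {
          int v = i1 + d * (i2 + d * i3);
          int o = 0;
          for (int o3 = -1; o3 <= 1; ++o3)
            for (int o2 = -1; o2 <= 1; ++o2)
              for (int o1 = -1; o1 <= 1; ++o1, ++o) {
                int j1 = i1 + o1, j2 = i2 + o2, j3 = i3 + o3;
                g.nb[(size_t)v * 27 + o] =
                    (j1 < 0 || j1 >= d || j2 < 0 || j2 >= d || j3 < 0 || j3 >= d)
                        ? -1
                        : j1 + d * (j2 + d * j3);
              }
        }
    g.child.resize((size_t)g.Vout * 8);
    int h = g.side_out;
    for (int u3 = 0; u3 < h; ++u3)
      for (int u2 = 0; u2 < h; ++u2)
        for (int u1 = 0; u1 < h; ++u1) {
          int u = u1 + h * (u2 + h * u3);
          int k = 0;
          for (int c3 = 0; c3 <= 1; ++c3)
            for (int c2 = 0; c2 <= 1; ++c2)
              for (int c1 = 0; c1 <= 1; ++c1, ++k)
                g.child[(size_t)u * 8 + k] =
                    (2 * u1 + c1) + d * ((2 * u2 + c2) + d * (2 * u3 + c3));
        }
    side = g.side_out;
    cin = g.cout;
    G.push_back(std::move(g));
  }
}

struct Params {
  std::vector<arma::mat> W;  // (27*cin) x cout per block
  std::vector<arma::rowvec> bias;
  arma::vec wd;
  double bd;
};

struct Adam {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::rowvec> mb, vb;
  arma::vec mwd, vwd;
  double mbd, vbd;
  long t;
};

void init_params(Params &P, const std::vector<BlockGeom> &G,
                 std::mt19937_64 &rng) {
  std::normal_distribution<double> norm(0.0, 1.0);
  P.W.resize(G.size());
  P.bias.resize(G.size());
  for (size_t b = 0; b < G.size(); ++b) {
    int fan = 27 * G[b].cin;
    double sd = std::sqrt(2.0 / fan);
    P.W[b].set_size(fan, G[b].cout);
    for (arma::uword j = 0; j < P.W[b].n_cols; ++j)
      for (arma::uword i = 0; i < P.W[b].n_rows; ++i)
        P.W[b](i, j) = sd * norm(rng);
    P.bias[b] = arma::rowvec(G[b].cout, arma::fill::zeros);
  }
  int cl = G.back().cout;
  P.wd.set_size(cl);
  double sd = std::sqrt(1.0 / cl);
  for (int i = 0; i < cl; ++i) P.wd(i) = sd * norm(rng);
  P.bd = 0.0;
}

void init_adam(Adam &A, const Params &P) {
  A.mW.resize(P.W.size());
  A.vW.resize(P.W.size());
  A.mb.resize(P.W.size());
  A.vb.resize(P.W.size());
  for (size_t b = 0; b < P.W.size(); ++b) {
    A.mW[b] = arma::zeros<arma::mat>(P.W[b].n_rows, P.W[b].n_cols);
    A.vW[b] = A.mW[b];
    A.mb[b] = arma::zeros<arma::rowvec>(P.bias[b].n_elem);
    A.vb[b] = A.mb[b];
  }
  A.mwd = arma::zeros<arma::vec>(P.wd.n_elem);
  A.vwd = A.mwd;
  A.mbd = A.vbd = 0.0;
  A.t = 0;
}

inline void adam_mat(arma::mat &w, const arma::mat &g, arma::mat &m,
                     arma::mat &v, double lr, double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * arma::square(g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}

// stem average pooling: raw cube (side^3, column-major) -> rows of A0
void stem_pool(const double *cube, int S, int stem, arma::mat &A0, int row0) {
  int s0 = S / stem;
  double inv = 1.0 / (stem * stem * stem);
  for (int i3 = 0; i3 < s0; ++i3)
    for (int i2 = 0; i2 < s0; ++i2)
      for (int i1 = 0; i1 < s0; ++i1) {
        double acc = 0.0;
        for (int c3 = 0; c3 < stem; ++c3)
          for (int c2 = 0; c2 < stem; ++c2)
            for (int c1 = 0; c1 < stem; ++c1)
              acc += cube[(stem * i1 + c1) +
                          (std::int64_t)S * ((stem * i2 + c2) +
                                             (std::int64_t)S * (stem * i3 + c3))];
        A0(row0 + i1 + s0 * (i2 + s0 * i3), 0) = acc * inv;
      }
}

void im2col(const arma::mat &A, const BlockGeom &g, int N, arma::mat &K) {
  // A: (N*Vin) x cin ; K: (N*Vin) x (27*cin)
  for (int o = 0; o < 27; ++o)
    for (int c = 0; c < g.cin; ++c) {
      double *dst = K.colptr(o * g.cin + c);
      const double *srcc = A.colptr(c);
      for (int n = 0; n < N; ++n) {
        const int base = n * g.Vin;
        for (int v = 0; v < g.Vin; ++v) {
          int s = g.nb[(size_t)v * 27 + o];
          dst[base + v] = (s < 0) ? 0.0 : srcc[base + s];
        }
      }
    }
}

void col2im(const arma::mat &dK, const BlockGeom &g, int N, arma::mat &dA) {
  dA.zeros(N * g.Vin, g.cin);
  for (int o = 0; o < 27; ++o)
    for (int c = 0; c < g.cin; ++c) {
      const double *src = dK.colptr(o * g.cin + c);
      double *dstc = dA.colptr(c);
      for (int n = 0; n < N; ++n) {
        const int base = n * g.Vin;
        for (int v = 0; v < g.Vin; ++v) {
          int s = g.nb[(size_t)v * 27 + o];
          if (s >= 0) dstc[base + s] += src[base + v];
        }
      }
    }
}

struct Cache {
  std::vector<arma::mat> K;     // im2col inputs per block
  std::vector<arma::mat> Y;     // post-ReLU conv outputs
  std::vector<arma::Mat<int>> amax; // argmax row (into Y) per pooled entry
  std::vector<arma::mat> A;     // pooled activations (A[0] = stem output)
  arma::mat F;                  // GAP features N x c_last
};

arma::vec forward(const Params &P, const std::vector<BlockGeom> &G, int N,
                  Cache &C, bool keep) {
  size_t B = G.size();
  if (C.K.size() != B) {
    C.K.resize(B);
    C.Y.resize(B);
    C.amax.resize(B);
    C.A.resize(B + 1);
  }
  for (size_t b = 0; b < B; ++b) {
    const BlockGeom &g = G[b];
    C.K[b].set_size(N * g.Vin, 27 * g.cin);
    im2col(C.A[b], g, N, C.K[b]);
    C.Y[b] = C.K[b] * P.W[b];
    C.Y[b].each_row() += P.bias[b];
    C.Y[b].transform([](double x) { return x > 0.0 ? x : 0.0; });
    // max pool 2
    arma::mat Ao(N * g.Vout, g.cout);
    arma::Mat<int> am;
    if (keep) am.set_size(N * g.Vout, g.cout);
    for (int ch = 0; ch < g.cout; ++ch) {
      const double *y = C.Y[b].colptr(ch);
      double *a = Ao.colptr(ch);
      for (int n = 0; n < N; ++n) {
        int bi = n * g.Vin, bo = n * g.Vout;
        for (int u = 0; u < g.Vout; ++u) {
          const int *kid = &g.child[(size_t)u * 8];
          int best = bi + kid[0];
          double mv = y[best];
          for (int k = 1; k < 8; ++k) {
            double cv = y[bi + kid[k]];
            if (cv > mv) { mv = cv; best = bi + kid[k]; }
          }
          a[bo + u] = mv;
          if (keep) am(bo + u, ch) = best;
        }
      }
    }
    C.A[b + 1] = std::move(Ao);
    if (keep) C.amax[b] = std::move(am);
  }
  // global average pool
  const BlockGeom &gl = G.back();
  C.F.set_size(N, gl.cout);
  for (int ch = 0; ch < gl.cout; ++ch) {
    const double *a = C.A[B].colptr(ch);
    for (int n = 0; n < N; ++n) {
      double acc = 0.0;
      for (int u = 0; u < gl.Vout; ++u) acc += a[n * gl.Vout + u];
      C.F(n, ch) = acc / gl.Vout;
    }
  }
  return C.F * P.wd + P.bd;
}

void backward(Params &P, Adam &Ad, const std::vector<BlockGeom> &G, int N,
              Cache &C, const arma::vec &dy, double lr) {
  size_t B = G.size();
  Ad.t += 1;
  double bc1 = 1.0 - std::pow(0.9, (double)Ad.t);
  double bc2 = 1.0 - std::pow(0.999, (double)Ad.t);
  arma::vec gwd = C.F.t() * dy;
  double gbd = arma::accu(dy);
  arma::mat dF = dy * P.wd.t(); // N x c_last
  // GAP backward
  const BlockGeom &gl = G.back();
  arma::mat dA(N * gl.Vout, gl.cout);
  for (int ch = 0; ch < gl.cout; ++ch) {
    double *d = dA.colptr(ch);
    for (int n = 0; n < N; ++n) {
      double val = dF(n, ch) / gl.Vout;
      for (int u = 0; u < gl.Vout; ++u) d[n * gl.Vout + u] = val;
    }
  }
  for (int b = (int)B - 1; b >= 0; --b) {
    const BlockGeom &g = G[b];
    // pool backward into dY
    arma::mat dY(N * g.Vin, g.cout, arma::fill::zeros);
    for (int ch = 0; ch < g.cout; ++ch) {
      double *dYc = dY.colptr(ch);
      const double *dAc = dA.colptr(ch);
      const int *am = C.amax[b].colptr(ch);
      for (int r = 0; r < N * g.Vout; ++r) dYc[am[r]] += dAc[r];
    }
    // ReLU mask (Y stored post-ReLU: zero entries get zero gradient)
    dY %= arma::conv_to<arma::mat>::from(C.Y[b] > 0.0);
    arma::mat gW = C.K[b].t() * dY;
    arma::rowvec gb = arma::sum(dY, 0);
    if (b > 0) {
      arma::mat dK = dY * P.W[b].t();
      col2im(dK, g, N, dA); // gradient wrt this block's input activation
    }
    adam_mat(P.W[b], gW, Ad.mW[b], Ad.vW[b], lr, bc1, bc2);
    arma::mat biasm(P.bias[b]), gbm(gb), mbm(Ad.mb[b]), vbm(Ad.vb[b]);
    adam_mat(biasm, gbm, mbm, vbm, lr, bc1, bc2);
    P.bias[b] = biasm.row(0);
    Ad.mb[b] = mbm.row(0);
    Ad.vb[b] = vbm.row(0);
  }
  arma::mat wdm(P.wd), gwdm(gwd), mwdm(Ad.mwd), vwdm(Ad.vwd);
  adam_mat(wdm, gwdm, mwdm, vwdm, lr, bc1, bc2);
  P.wd = wdm.col(0);
  Ad.mwd = mwdm.col(0);
  Ad.vwd = vwdm.col(0);
  Ad.mbd = 0.9 * Ad.mbd + 0.1 * gbd;
  Ad.vbd = 0.999 * Ad.vbd + 0.001 * gbd * gbd;
  P.bd -= lr * (Ad.mbd / bc1) / (std::sqrt(Ad.vbd / bc2) + 1e-8);
}

List params_to_list(const Params &P) {
  List W(P.W.size()), bias(P.W.size());
  for (size_t b = 0; b < P.W.size(); ++b) {
    W[b] = wrap(P.W[b]);
    bias[b] = wrap(arma::vec(P.bias[b].t()));
  }
  return List::create(_["W"] = W, _["bias"] = bias, _["wd"] = wrap(P.wd),
                      _["bd"] = P.bd);
}

void params_from_list(Params &P, List L) {
  List W = L["W"], bias = L["bias"];
  P.W.resize(W.size());
  P.bias.resize(W.size());
  for (int b = 0; b < W.size(); ++b) {
    P.W[b] = as<arma::mat>(W[b]);
    arma::vec bv = as<arma::vec>(bias[b]);
    P.bias[b] = bv.t();
  }
  P.wd = as<arma::vec>(L["wd"]);
  P.bd = as<double>(L["bd"]);
}

} // namespace

// [[Rcpp::export(name = ".cpp_cnn_train")]]
List cpp_cnn_train(NumericVector cubes, NumericVector targets,
                   IntegerVector train_idx, IntegerVector val_idx,
                   IntegerVector channels, int stem, int epochs, int batch,
                   double lr, int naug, double amin, double amax, int seed) {
  IntegerVector dim = cubes.attr("dim");
  int S = dim[0];
  if (dim[1] != S || dim[2] != S) stop("cubes must be cubic");
  std::int64_t V = (std::int64_t)S * S * S;
  if (S % stem != 0) stop("cube side not divisible by stem pooling factor");
  int side0 = S / stem;
  for (int b = 0; b < channels.size(); ++b) {
    if (side0 % 2 != 0)
      stop("cube side too small for %d conv blocks", (int)channels.size());
    side0 /= 2;
  }
  std::vector<BlockGeom> G;
  build_geom(G, S / stem, channels);
  std::mt19937_64 rng((std::uint64_t)seed);
  Params P;
  init_params(P, G, rng);
  Adam Ad;
  init_adam(Ad, P);
  std::uniform_real_distribution<double> unif(amin, amax);
  const double *cb = cubes.begin();
  int ntr = train_idx.size();
  int items = naug > 0 ? ntr * naug : ntr;
  std::vector<int> order(items);
  std::vector<double> rot((size_t)V);
  Cache C;
  NumericVector epoch_loss(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < items; ++i) order[i] = train_idx[i % ntr];
    std::shuffle(order.begin(), order.end(), rng);
    double lsum = 0.0;
    long lcnt = 0;
    for (int start = 0; start < items; start += batch) {
      int N = std::min(batch, items - start);
      arma::mat A0(N * G[0].Vin, 1);
      arma::vec t(N);
      for (int k = 0; k < N; ++k) {
        int s = order[start + k];
        t(k) = targets[s];
        const double *src = cb + (std::int64_t)s * V;
        if (naug > 0) {
          double a1 = unif(rng), a2 = unif(rng), a3 = unif(rng);
          ipet::rotate_array(src, rot.data(), S, S, S, a1, a2, a3);
          stem_pool(rot.data(), S, stem, A0, k * G[0].Vin);
        } else {
          stem_pool(src, S, stem, A0, k * G[0].Vin);
        }
      }
      C.A.resize(G.size() + 1);
      C.A[0] = std::move(A0);
      arma::vec yhat = forward(P, G, N, C, true);
      arma::vec resid = yhat - t;
      double loss = arma::dot(resid, resid) / N;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
      lsum += loss * N;
      lcnt += N;
      backward(P, Ad, G, N, C, resid * (2.0 / N), lr);
    }
    epoch_loss[ep] = lsum / lcnt;
    Rcpp::checkUserInterrupt();
  }
  // validation predictions (no augmentation)
  int nval = val_idx.size();
  NumericVector vp(nval);
  for (int start = 0; start < nval; start += batch) {
    int N = std::min(batch, nval - start);
    arma::mat A0(N * G[0].Vin, 1);
    for (int k = 0; k < N; ++k)
      stem_pool(cb + (std::int64_t)val_idx[start + k] * V, S, stem, A0,
                k * G[0].Vin);
    Cache Cv;
    Cv.A.resize(G.size() + 1);
    Cv.A[0] = std::move(A0);
    arma::vec yhat = forward(P, G, N, Cv, true);
    for (int k = 0; k < N; ++k) vp[start + k] = yhat(k);
  }
  return List::create(_["weights"] = params_to_list(P), _["val_pred"] = vp,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
NumericVector cpp_cnn_predict(List weights, NumericVector cubes,
                              IntegerVector channels, int stem) {
  IntegerVector dim = cubes.attr("dim");
  int S = dim[0];
  int n = dim.size() == 4 ? dim[3] : 1;
  std::int64_t V = (std::int64_t)S * S * S;
  std::vector<BlockGeom> G;
  build_geom(G, S / stem, channels);
  Params P;
  params_from_list(P, weights);
  const double *cb = cubes.begin();
  NumericVector out(n);
  int batch = 16;
  for (int start = 0; start < n; start += batch) {
    int N = std::min(batch, n - start);
    arma::mat A0(N * G[0].Vin, 1);
    for (int k = 0; k < N; ++k)
      stem_pool(cb + (std::int64_t)(start + k) * V, S, stem, A0, k * G[0].Vin);
    Cache C;
    C.A.resize(G.size() + 1);
    C.A[0] = std::move(A0);
    arma::vec yhat = forward(P, G, N, C, true);
    for (int k = 0; k < N; ++k) out[start + k] = yhat(k);
  }
  return out;
}
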