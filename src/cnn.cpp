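// Compact convolutional classifier used for amyloid-pathology tile
// classification and stride-based sliding-window heatmap inference.
//
// Architecture (fixed by the pipeline, parameterized by channel widths):
// N conv blocks [3x3 conv, pad 1, ReLU, 2x2 max pool] followed by dense
// layers (ReLU) and a final dense layer with K sigmoid outputs
// (independent per-class probabilities, multilabel).
//
// Convolutions are computed as GEMM on transposed im2col matrices:
// activations are stored as (H*W x C) matrices so every channel is a
// contiguous column block (cache-friendly for both im2col and pooling).
// All internal arithmetic is single precision (standard for CNNs; the
// per-window working set then stays cache-resident during sliding-window
// inference). Training runs mini-batch Adam on mean binary
// cross-entropy; shuffling orders and initial weights come from the R
// side so determinism is governed by R's RNG alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct Net {
  std::vector<fmat> cw;  // conv weights, each (Cout x Cin*9)
  std::vector<fvec> cb;  // conv biases
  std::vector<fmat> dw;  // dense weights
  std::vector<fvec> db;  // dense biases
};

static Net net_from_list(const List& params) {
  Net net;
  List cw = params["conv_w"], cb = params["conv_b"];
  List dw = params["dense_w"], db = params["dense_b"];
  for (int i = 0; i < cw.size(); ++i) {
    net.cw.push_back(conv_to<fmat>::from(as<mat>(cw[i])));
    net.cb.push_back(conv_to<fvec>::from(as<vec>(cb[i])));
  }
  for (int i = 0; i < dw.size(); ++i) {
    net.dw.push_back(conv_to<fmat>::from(as<mat>(dw[i])));
    net.db.push_back(conv_to<fvec>::from(as<vec>(db[i])));
  }
  return net;
}

static List net_to_list(const Net& net) {
  List cw(net.cw.size()), cb(net.cb.size());
  List dw(net.dw.size()), db(net.db.size());
  for (size_t i = 0; i < net.cw.size(); ++i) {
    cw[i] = conv_to<mat>::from(net.cw[i]);
    cb[i] = conv_to<vec>::from(net.cb[i]);
  }
  for (size_t i = 0; i < net.dw.size(); ++i) {
    dw[i] = conv_to<mat>::from(net.dw[i]);
    db[i] = conv_to<vec>::from(net.db[i]);
  }
  return List::create(_["conv_w"] = cw, _["conv_b"] = cb,
                      _["dense_w"] = dw, _["dense_b"] = db);
}

// transposed im2col for a 3x3 kernel, zero padding 1: (H*W) x (9*C).
// Column c*9 + (dx+1)*3 + (dy+1) holds channel c shifted by (dy, dx).
static fmat im2colT(const fmat& A, int H, int W) {
  const int C = A.n_cols;
  fmat K(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const fmat ch(const_cast<float*>(A.colptr(c)), H, W, false, true);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int idx = c * 9 + (dx + 1) * 3 + (dy + 1);
        fmat sh(K.colptr(idx), H, W, false, true);
        const int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
        const int c0 = std::max(0, -dx), c1 = W - 1 - std::max(0, dx);
        if (r0 <= r1 && c0 <= c1)
          sh.submat(r0, c0, r1, c1) =
            ch.submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx);
      }
    }
  }
  return K;
}

// adjoint of im2colT: scatter-add a (H*W x 9*C) gradient back to (H*W x C)
static fmat col2imT(const fmat& G, int H, int W, int C) {
  fmat dA(H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat acc(dA.colptr(c), H, W, false, true);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int idx = c * 9 + (dx + 1) * 3 + (dy + 1);
        const fmat g(const_cast<float*>(G.colptr(idx)), H, W, false, true);
        const int r0 = std::max(0, -dy), r1 = H - 1 - std::max(0, dy);
        const int c0 = std::max(0, -dx), c1 = W - 1 - std::max(0, dx);
        if (r0 <= r1 && c0 <= c1)
          acc.submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx) +=
            g.submat(r0, c0, r1, c1);
      }
    }
  }
  return dA;
}

// 2x2 max pooling on (H*W x C) activations; records argmax offsets
static fmat maxpool2(const fmat& A, int H, int W, umat& arg) {
  const int H2 = H / 2, W2 = W / 2, C = A.n_cols;
  fmat out(H2 * W2, C);
  arg.set_size(H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    uword* am = arg.colptr(c);
    for (int w = 0; w < W2; ++w) {
      const float* col0 = src + (2 * w) * H;
      const float* col1 = src + (2 * w + 1) * H;
      for (int h = 0; h < H2; ++h) {
        const float v[4] = { col0[2 * h], col0[2 * h + 1],
                             col1[2 * h], col1[2 * h + 1] };
        int a = 0;
        for (int k = 1; k < 4; ++k) if (v[k] > v[a]) a = k;
        dst[h + H2 * w] = v[a];
        am[h + H2 * w] = a;
      }
    }
  }
  return out;
}

static fmat unpool2(const fmat& G, int H2, int W2, const umat& arg) {
  const int H = 2 * H2, W = 2 * W2, C = G.n_cols;
  fmat out(H * W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* g = G.colptr(c);
    const uword* am = arg.colptr(c);
    float* dst = out.colptr(c);
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const uword a = am[h + H2 * w];
        const int hh = 2 * h + (int)(a & 1u);
        const int ww = 2 * w + (int)(a >> 1);
        dst[hh + H * ww] = g[h + H2 * w];
      }
  }
  return out;
}

static inline void relu_inplace(fmat& Z) {
  float* p = Z.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

static fvec sigmoid_vec(const fvec& z) {
  return 1.0f / (1.0f + exp(-clamp(z, -30.0f, 30.0f)));
}

// forward pass, inference only (no caches)
static fvec forward_probs(const Net& net, fmat A, int H, int W) {
  for (size_t l = 0; l < net.cw.size(); ++l) {
    fmat K = im2colT(A, H, W);
    fmat Z = K * net.cw[l].t();
    Z.each_row() += net.cb[l].t();
    relu_inplace(Z);
    umat arg;
    A = maxpool2(Z, H, W, arg);
    H /= 2; W /= 2;
  }
  fvec h = vectorise(A);
  for (size_t l = 0; l + 1 < net.dw.size(); ++l) {
    h = net.dw[l] * h + net.db[l];
    h.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  }
  return sigmoid_vec(net.dw.back() * h + net.db.back());
}

struct Cache {
  std::vector<fmat> K;     // im2colT of each conv input
  std::vector<fmat> Z;     // post-ReLU conv activations (H*W x Cout)
  std::vector<umat> arg;   // pool argmax
  std::vector<int> H, W;   // conv input dims
  std::vector<fvec> dh;    // dense-layer inputs (incl. flattened conv out)
  fvec probs;
};

static fvec forward_train(const Net& net, fmat A, int H, int W, Cache& cc) {
  const size_t nl = net.cw.size();
  cc.K.resize(nl); cc.Z.resize(nl); cc.arg.resize(nl);
  cc.H.resize(nl); cc.W.resize(nl);
  for (size_t l = 0; l < nl; ++l) {
    cc.H[l] = H; cc.W[l] = W;
    cc.K[l] = im2colT(A, H, W);
    fmat Z = cc.K[l] * net.cw[l].t();
    Z.each_row() += net.cb[l].t();
    relu_inplace(Z);
    cc.Z[l] = Z;
    A = maxpool2(Z, H, W, cc.arg[l]);
    H /= 2; W /= 2;
  }
  cc.dh.clear();
  fvec h = vectorise(A);
  for (size_t l = 0; l + 1 < net.dw.size(); ++l) {
    cc.dh.push_back(h);
    h = net.dw[l] * h + net.db[l];
    h.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  }
  cc.dh.push_back(h);
  cc.probs = sigmoid_vec(net.dw.back() * h + net.db.back());
  return cc.probs;
}

// backward pass for one sample; accumulates gradients into gnet
static void backward(const Net& net, const Cache& cc, const fvec& y,
                     float scale, Net& gnet) {
  // d(mean BCE)/dlogit = (p - y) / n_classes
  fvec delta = (cc.probs - y) * (scale / (float)y.n_elem);
  const size_t nd = net.dw.size();
  for (size_t l = nd; l-- > 0;) {
    gnet.dw[l] += delta * cc.dh[l].t();
    gnet.db[l] += delta;
    if (l == 0) { delta = net.dw[l].t() * delta; break; }
    fvec prev = net.dw[l].t() * delta;
    delta = prev % conv_to<fvec>::from(cc.dh[l] > 0);
  }
  const size_t nl = net.cw.size();
  const int H2 = cc.H[nl - 1] / 2, W2 = cc.W[nl - 1] / 2;
  const int Cn = net.cw[nl - 1].n_rows;
  fmat g(delta.memptr(), H2 * W2, Cn);  // grad wrt final pooled output
  for (size_t l = nl; l-- > 0;) {
    fmat dZ = unpool2(g, cc.H[l] / 2, cc.W[l] / 2, cc.arg[l]);
    {
      const float* z = cc.Z[l].memptr();
      float* p = dZ.memptr();
      for (uword i = 0; i < dZ.n_elem; ++i) if (z[i] <= 0.0f) p[i] = 0.0f;
    }
    gnet.cw[l] += dZ.t() * cc.K[l];
    gnet.cb[l] += sum(dZ, 0).t();
    if (l > 0) {
      fmat dK = dZ * net.cw[l];
      g = col2imT(dK, cc.H[l], cc.W[l], net.cw[l - 1].n_rows);
    }
  }
}

// decode a raw tile (H*W*C bytes, R array layout, 0..255) to (H*W x C)
static fmat raw_to_mat(const RawVector& r, int HW, int C) {
  fmat x(HW, C);
  const unsigned char* p = RAW(r);
  float* q = x.memptr();
  const std::size_t n = (std::size_t)HW * C;
  for (std::size_t i = 0; i < n; ++i) q[i] = p[i] / 255.0f - 0.5f;  // centered inputs
  return x;
}

static Net zeros_like(const Net& net) {
  Net g;
  for (auto& m : net.cw) g.cw.push_back(fmat(size(m), fill::zeros));
  for (auto& v : net.cb) g.cb.push_back(fvec(size(v), fill::zeros));
  for (auto& m : net.dw) g.dw.push_back(fmat(size(m), fill::zeros));
  for (auto& v : net.db) g.db.push_back(fvec(size(v), fill::zeros));
  return g;
}

struct Adam {
  Net m, v;
  float b1, b2, eps;
  long t = 0;
  Adam(const Net& net, float b1_, float b2_, float eps_)
    : m(zeros_like(net)), v(zeros_like(net)), b1(b1_), b2(b2_), eps(eps_) {}
  template <typename T>
  void upd1(T& w, T& mm, T& vv, const T& g, float lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    const float c1 = 1 - std::pow(b1, (float)t);
    const float c2 = 1 - std::pow(b2, (float)t);
    w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
  }
  void step(Net& net, const Net& g, float lr) {
    ++t;
    for (size_t i = 0; i < net.cw.size(); ++i) {
      upd1(net.cw[i], m.cw[i], v.cw[i], g.cw[i], lr);
      upd1(net.cb[i], m.cb[i], v.cb[i], g.cb[i], lr);
    }
    for (size_t i = 0; i < net.dw.size(); ++i) {
      upd1(net.dw[i], m.dw[i], v.dw[i], g.dw[i], lr);
      upd1(net.db[i], m.db[i], v.db[i], g.db[i], lr);
    }
  }
};

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
NumericMatrix cpp_cnn_predict(List params, List tiles, int tile_size,
                              int channels) {
  Net net = net_from_list(params);
  const int n = tiles.size();
  NumericMatrix out(n, net.dw.back().n_rows);
  for (int i = 0; i < n; ++i) {
    fmat x = raw_to_mat(as<RawVector>(tiles[i]), tile_size * tile_size,
                        channels);
    fvec p = forward_probs(net, x, tile_size, tile_size);
    for (uword k = 0; k < p.n_elem; ++k) out(i, k) = p(k);
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_cnn_train")]]
List cpp_cnn_train(List params, List tiles, NumericMatrix labels,
                   int tile_size, int channels, int epochs, int batch_size,
                   double lr, double beta1, double beta2, double eps,
                   IntegerMatrix order) {
  Net net = net_from_list(params);
  Adam adam(net, (float)beta1, (float)beta2, (float)eps);
  const int n = tiles.size();
  const fmat Y = conv_to<fmat>::from(as<mat>(labels));
  std::vector<double> epoch_loss;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int b1 = std::min(b0 + batch_size, n);
      Net g = zeros_like(net);
      for (int i = b0; i < b1; ++i) {
        const int idx = order(i, ep) - 1;
        fmat x = raw_to_mat(as<RawVector>(tiles[idx]),
                            tile_size * tile_size, channels);
        Cache cc;
        fvec p = forward_train(net, x, tile_size, tile_size, cc);
        fvec y = Y.row(idx).t();
        p = clamp(p, 1e-7f, 1.0f - 1e-7f);
        loss_sum += as_scalar(mean(-(y % log(p) +
                                     (1.0f - y) % log(1.0f - p))));
        backward(net, cc, y, 1.0f / (b1 - b0), g);
      }
      adam.step(net, g, (float)lr);
      Rcpp::checkUserInterrupt();
    }
    epoch_loss.push_back(loss_sum / n);
  }
  return List::create(_["params"] = net_to_list(net),
                      _["loss"] = wrap(epoch_loss));
}

// Sliding-window heatmap: window top-left (i*stride, j*stride) in 0-based
// slide pixels maps to heatmap pixel (i, j). Windows whose tissue
// coverage is below min_tissue_frac are skipped (left at zero).
// [[Rcpp::export(name = ".cpp_sliding_window")]]
NumericVector cpp_sliding_window(List params, NumericVector image,
                                 IntegerMatrix tissue, int stride,
                                 int window, double min_tissue_frac) {
  Net net = net_from_list(params);
  IntegerVector dims = image.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  const double* img = image.begin();
  const int hh = (H - window) / stride + 1;
  const int hw = (W - window) / stride + 1;
  const int K = net.dw.back().n_rows;
  const bool use_mask = tissue.nrow() == H && tissue.ncol() == W &&
    min_tissue_frac > 0.0;
  mat sat;  // integral image of the tissue mask
  if (use_mask) {
    mat tm(H, W);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) tm(i, j) = tissue(i, j) != 0;
    sat = cumsum(cumsum(tm, 0), 1);
  }
  const double area = (double)window * window;
  NumericVector out(hh * hw * K);
  out.attr("dim") = IntegerVector::create(hh, hw, K);
  fmat win(window * window, C);
  for (int j = 0; j < hw; ++j) {
    for (int i = 0; i < hh; ++i) {
      const int r0 = i * stride, c0 = j * stride;
      const int r1 = r0 + window - 1, c1 = c0 + window - 1;
      if (use_mask) {
        double s = sat(r1, c1);
        if (r0 > 0) s -= sat(r0 - 1, c1);
        if (c0 > 0) s -= sat(r1, c0 - 1);
        if (r0 > 0 && c0 > 0) s += sat(r0 - 1, c0 - 1);
        if (s / area < min_tissue_frac) continue;
      }
      for (int c = 0; c < C; ++c) {
        float* dst = win.colptr(c);
        const double* base = img + (std::size_t)c * H * W;
        for (int w = 0; w < window; ++w) {
          const double* src = base + (std::size_t)(c0 + w) * H + r0;
          float* d = dst + w * window;
          for (int h = 0; h < window; ++h) d[h] = (float)src[h] - 0.5f;
        }
      }
      fvec p = forward_probs(net, win, window, window);
      for (int k = 0; k < K; ++k) out[i + hh * j + hh * hw * k] = p(k);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
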