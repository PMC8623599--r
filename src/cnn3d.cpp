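// 3D convolutional network core: im2col + single-precision GEMM forward and
// backward passes, and the SGD-with-momentum training loop. Tensors use the
// layout value[t + T*(h + H*(w + W*c))], i.e. a column-major R array with
// dim (T, H, W, C). Convolutions use "same" zero padding p = (k - 1) / 2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvSpec {
  int kt, kh, kw, st, sh, sw, cin, cout;
};

struct Dims { int T, H, W, C; };

static inline int out_len(int n, int k, int s) {
  int p = (k - 1) / 2;
  return (n + 2 * p - k) / s + 1;
}

static Dims out_dims(const Dims& d, const ConvSpec& cs) {
  Dims o;
  o.T = out_len(d.T, cs.kt, cs.st);
  o.H = out_len(d.H, cs.kh, cs.sh);
  o.W = out_len(d.W, cs.kw, cs.sw);
  o.C = cs.cout;
  return o;
}

// Gather the padded input patches into col (rows = To*Ho*Wo output positions,
// cols = kt*kh*kw*Cin). Row index = to + To*(ho + Ho*wo); column index =
// dt + kt*(dh + kh*(dw + kw*c)) — matching the weight matrix layout.
static void im2col(const arma::fvec& x, const Dims& d, const ConvSpec& cs,
                   const Dims& o, arma::fmat& col) {
  const int pt = (cs.kt - 1) / 2, ph = (cs.kh - 1) / 2, pw = (cs.kw - 1) / 2;
  const arma::uword rows = (arma::uword)o.T * o.H * o.W;
  col.zeros(rows, (arma::uword)cs.kt * cs.kh * cs.kw * d.C);
  const float* xp = x.memptr();
  for (int c = 0; c < d.C; ++c) {
    for (int dw = 0; dw < cs.kw; ++dw)
      for (int dh = 0; dh < cs.kh; ++dh)
        for (int dt = 0; dt < cs.kt; ++dt) {
          const arma::uword j = dt + cs.kt * (dh + cs.kh * (dw + (arma::uword)cs.kw * c));
          float* colj = col.colptr(j);
          for (int wo = 0; wo < o.W; ++wo) {
            const int wi = wo * cs.sw - pw + dw;
            if (wi < 0 || wi >= d.W) continue;
            for (int ho = 0; ho < o.H; ++ho) {
              const int hi = ho * cs.sh - ph + dh;
              if (hi < 0 || hi >= d.H) continue;
              const float* src = xp + (arma::uword)d.T * (hi + (arma::uword)d.H * (wi + (arma::uword)d.W * c));
              float* dst = colj + (arma::uword)(wo * o.H + ho) * o.T;
              for (int to = 0; to < o.T; ++to) {
                const int ti = to * cs.st - pt + dt;
                if (ti >= 0 && ti < d.T) dst[to] = src[ti];
              }
            }
          }
        }
  }
}

// Scatter-add transpose of im2col: accumulate dcol back into dx.
static void col2im(const arma::fmat& dcol, const Dims& d, const ConvSpec& cs,
                   const Dims& o, arma::fvec& dx) {
  const int pt = (cs.kt - 1) / 2, ph = (cs.kh - 1) / 2, pw = (cs.kw - 1) / 2;
  dx.zeros((arma::uword)d.T * d.H * d.W * d.C);
  float* xp = dx.memptr();
  for (int c = 0; c < d.C; ++c) {
    for (int dw = 0; dw < cs.kw; ++dw)
      for (int dh = 0; dh < cs.kh; ++dh)
        for (int dt = 0; dt < cs.kt; ++dt) {
          const arma::uword j = dt + cs.kt * (dh + cs.kh * (dw + (arma::uword)cs.kw * c));
          const float* colj = dcol.colptr(j);
          for (int wo = 0; wo < o.W; ++wo) {
            const int wi = wo * cs.sw - pw + dw;
            if (wi < 0 || wi >= d.W) continue;
            for (int ho = 0; ho < o.H; ++ho) {
              const int hi = ho * cs.sh - ph + dh;
              if (hi < 0 || hi >= d.H) continue;
              float* dst = xp + (arma::uword)d.T * (hi + (arma::uword)d.H * (wi + (arma::uword)d.W * c));
              const float* src = colj + (arma::uword)(wo * o.H + ho) * o.T;
              for (int to = 0; to < o.T; ++to) {
                const int ti = to * cs.st - pt + dt;
                if (ti >= 0 && ti < d.T) dst[ti] += src[to];
              }
            }
          }
        }
  }
}

static inline arma::fmat swish(const arma::fmat& z) {
  return z % (1.0f / (1.0f + arma::exp(-z)));
}

static inline arma::fmat swish_grad(const arma::fmat& z) {
  arma::fmat s = 1.0f / (1.0f + arma::exp(-z));
  return s % (1.0f + z % (1.0f - s));
}

struct Network {
  std::vector<ConvSpec> specs;
  std::vector<Dims> dims;        // dims[0] = input, dims[l+1] = after conv l
  std::vector<arma::fmat> convW; // (k*cin) x cout
  std::vector<arma::fvec> convB;
  std::vector<arma::fmat> denseW; // in x out
  std::vector<arma::fvec> denseB;
};

static Network build_network(List arch, IntegerVector input_dim,
                             List conv_w, List conv_b,
                             List dense_w, List dense_b) {
  Network net;
  Dims d = { input_dim[0], input_dim[1], input_dim[2], input_dim[3] };
  net.dims.push_back(d);
  IntegerMatrix am = arch["conv"];
  for (int l = 0; l < am.nrow(); ++l) {
    ConvSpec cs = { am(l, 0), am(l, 1), am(l, 2), am(l, 3), am(l, 4), am(l, 5),
                    am(l, 6), am(l, 7) };
    net.specs.push_back(cs);
    net.dims.push_back(out_dims(net.dims.back(), cs));
    NumericMatrix W = conv_w[l];
    NumericVector b = conv_b[l];
    net.convW.push_back(arma::conv_to<arma::fmat>::from(
        arma::mat(W.begin(), W.nrow(), W.ncol(), false)));
    net.convB.push_back(arma::conv_to<arma::fvec>::from(
        arma::vec(b.begin(), b.size(), false)));
  }
  for (int l = 0; l < dense_w.size(); ++l) {
    NumericMatrix W = dense_w[l];
    NumericVector b = dense_b[l];
    net.denseW.push_back(arma::conv_to<arma::fmat>::from(
        arma::mat(W.begin(), W.nrow(), W.ncol(), false)));
    net.denseB.push_back(arma::conv_to<arma::fvec>::from(
        arma::vec(b.begin(), b.size(), false)));
  }
  return net;
}

struct Cache {
  std::vector<arma::fmat> cols;   // im2col per conv layer
  std::vector<arma::fmat> convZ;  // pre-activation per conv layer
  arma::fvec gap;                 // pooled features
  std::vector<arma::fvec> denseZ; // pre-activations
  std::vector<arma::fvec> denseA; // post-activations (input to next layer)
  float p;
};

// Input centering: tensors arrive in [0, 1]; the network consumes 2x - 1.
static float forward(const Network& net, const arma::fvec& x0, Cache* cache) {
  arma::fvec act = 2.0f * x0 - 1.0f;
  Cache local;
  Cache& cc = cache ? *cache : local;
  cc.cols.clear(); cc.convZ.clear(); cc.denseZ.clear(); cc.denseA.clear();
  arma::fmat A;
  for (size_t l = 0; l < net.specs.size(); ++l) {
    const Dims& din = net.dims[l];
    const Dims& dout = net.dims[l + 1];
    arma::fmat col;
    im2col(act, din, net.specs[l], dout, col);
    arma::fmat Z = col * net.convW[l];
    Z.each_row() += net.convB[l].t();
    A = swish(Z);
    if (cache) { cc.cols.push_back(std::move(col)); cc.convZ.push_back(std::move(Z)); }
    act = arma::vectorise(A);
  }
  const Dims& dl = net.dims.back();
  const arma::uword rows = (arma::uword)dl.T * dl.H * dl.W;
  arma::fmat Afin(act.memptr(), rows, dl.C, false);
  arma::fvec f = arma::mean(Afin, 0).t();
  cc.gap = f;
  arma::fvec h = f;
  const size_t nd = net.denseW.size();
  float p = 0.5f;
  for (size_t l = 0; l < nd; ++l) {
    arma::fvec z = net.denseW[l].t() * h + net.denseB[l];
    cc.denseZ.push_back(z);
    if (l + 1 < nd) {
      h = z % (1.0f / (1.0f + arma::exp(-z)));
      cc.denseA.push_back(h);
    } else {
      p = 1.0f / (1.0f + std::exp(-z[0]));
    }
  }
  cc.p = p;
  return p;
}

struct Grads {
  std::vector<arma::fmat> convW;
  std::vector<arma::fvec> convB;
  std::vector<arma::fmat> denseW;
  std::vector<arma::fvec> denseB;
  void init(const Network& net) {
    convW.clear(); convB.clear(); denseW.clear(); denseB.clear();
    for (size_t l = 0; l < net.convW.size(); ++l) {
      convW.push_back(arma::fmat(arma::size(net.convW[l]), arma::fill::zeros));
      convB.push_back(arma::fvec(net.convB[l].n_elem, arma::fill::zeros));
    }
    for (size_t l = 0; l < net.denseW.size(); ++l) {
      denseW.push_back(arma::fmat(arma::size(net.denseW[l]), arma::fill::zeros));
      denseB.push_back(arma::fvec(net.denseB[l].n_elem, arma::fill::zeros));
    }
  }
};

// Accumulate the gradient of BCE(p, y) into g. Returns the loss.
static float backward(const Network& net, const arma::fvec& x0, float y,
                      Grads& g) {
  Cache cc;
  float p = forward(net, x0, &cc);
  const float eps = 1e-7f;
  float pc = std::min(std::max(p, eps), 1.0f - eps);
  float loss = -(y * std::log(pc) + (1.0f - y) * std::log(1.0f - pc));

  const size_t nd = net.denseW.size();
  // dz for sigmoid + BCE head
  arma::fvec dz(1);
  dz[0] = p - y;
  arma::fvec dh;
  for (int l = (int)nd - 1; l >= 0; --l) {
    const arma::fvec& hin = (l == 0) ? cc.gap : cc.denseA[l - 1];
    g.denseW[l] += hin * dz.t();
    g.denseB[l] += dz;
    if (l > 0) {
      dh = net.denseW[l] * dz;
      const arma::fvec& z = cc.denseZ[l - 1];
      arma::fvec s = 1.0f / (1.0f + arma::exp(-z));
      dz = dh % (s % (1.0f + z % (1.0f - s)));
    }
  }
  arma::fvec dgap = net.denseW[0] * ((nd > 1) ? dz : arma::fvec{ (float)(p - y) });
  // note: for nd == 1 dz already equals p - y

  const Dims& dl = net.dims.back();
  const arma::uword rows = (arma::uword)dl.T * dl.H * dl.W;
  arma::fmat dA(rows, dl.C);
  for (int c = 0; c < dl.C; ++c) dA.col(c).fill(dgap[c] / (float)rows);

  for (int l = (int)net.specs.size() - 1; l >= 0; --l) {
    arma::fmat dZ = dA % swish_grad(cc.convZ[l]);
    g.convW[l] += cc.cols[l].t() * dZ;
    g.convB[l] += arma::sum(dZ, 0).t();
    if (l > 0) {
      arma::fmat dcol = dZ * net.convW[l].t();
      arma::fvec dx;
      col2im(dcol, net.dims[l], net.specs[l], net.dims[l + 1], dx);
      // reshape dx into the activation matrix of the previous layer
      const Dims& dp = net.dims[l];
      const arma::uword prows = (arma::uword)dp.T * dp.H * dp.W;
      dA = arma::fmat(dx.memptr(), prows, dp.C);
    }
  }
  return loss;
}

static std::vector<arma::fvec> convert_inputs(List x) {
  std::vector<arma::fvec> xs;
  xs.reserve(x.size());
  for (int i = 0; i < x.size(); ++i) {
    NumericVector xi = x[i];
    xs.push_back(arma::conv_to<arma::fvec>::from(
        arma::vec(xi.begin(), xi.size(), false)));
  }
  return xs;
}

// [[Rcpp::export]]
List cnn3d_train_cpp(List arch, IntegerVector input_dim,
                     List conv_w, List conv_b, List dense_w, List dense_b,
                     List x, NumericVector y, NumericVector lr_epoch,
                     IntegerMatrix order, int batch_size, double momentum) {
  Network net = build_network(arch, input_dim, conv_w, conv_b, dense_w, dense_b);
  std::vector<arma::fvec> xs = convert_inputs(x);
  const int n = xs.size();
  const int epochs = lr_epoch.size();

  Grads vel; vel.init(net);   // momentum buffers
  Grads g;
  NumericVector loss_log(epochs);

  for (int e = 0; e < epochs; ++e) {
    const float lr = (float)lr_epoch[e];
    double epoch_loss = 0.0;
    int done = 0;
    while (done < n) {
      const int bs = std::min(batch_size, n - done);
      g.init(net);
      float bloss = 0.0f;
      for (int k = 0; k < bs; ++k) {
        const int idx = order(e, done + k);   // 0-based sample index
        bloss += backward(net, xs[idx], (float)y[idx], g);
      }
      epoch_loss += bloss;
      const float inv = 1.0f / (float)bs;
      for (size_t l = 0; l < net.convW.size(); ++l) {
        vel.convW[l] = (float)momentum * vel.convW[l] - lr * inv * g.convW[l];
        net.convW[l] += vel.convW[l];
        vel.convB[l] = (float)momentum * vel.convB[l] - lr * inv * g.convB[l];
        net.convB[l] += vel.convB[l];
      }
      for (size_t l = 0; l < net.denseW.size(); ++l) {
        vel.denseW[l] = (float)momentum * vel.denseW[l] - lr * inv * g.denseW[l];
        net.denseW[l] += vel.denseW[l];
        vel.denseB[l] = (float)momentum * vel.denseB[l] - lr * inv * g.denseB[l];
        net.denseB[l] += vel.denseB[l];
      }
      done += bs;
    }
    loss_log[e] = epoch_loss / n;
    Rcpp::checkUserInterrupt();
  }

  List out_cw(net.convW.size()), out_cb(net.convB.size());
  for (size_t l = 0; l < net.convW.size(); ++l) {
    out_cw[l] = wrap(arma::conv_to<arma::mat>::from(net.convW[l]));
    out_cb[l] = wrap(arma::conv_to<arma::vec>::from(net.convB[l]));
  }
  List out_dw(net.denseW.size()), out_db(net.denseB.size());
  for (size_t l = 0; l < net.denseW.size(); ++l) {
    out_dw[l] = wrap(arma::conv_to<arma::mat>::from(net.denseW[l]));
    out_db[l] = wrap(arma::conv_to<arma::vec>::from(net.denseB[l]));
  }
  return List::create(_["conv_w"] = out_cw, _["conv_b"] = out_cb,
                      _["dense_w"] = out_dw, _["dense_b"] = out_db,
                      _["loss"] = loss_log);
}

// [[Rcpp::export]]
NumericVector cnn3d_predict_cpp(List arch, IntegerVector input_dim,
                                List conv_w, List conv_b,
                                List dense_w, List dense_b, List x) {
  Network net = build_network(arch, input_dim, conv_w, conv_b, dense_w, dense_b);
  std::vector<arma::fvec> xs = convert_inputs(x);
  NumericVector out(xs.size());
  for (size_t i = 0; i < xs.size(); ++i)
    out[i] = forward(net, xs[i], nullptr);
  return out;
}

// Single 3D convolution layer (double precision, optional swish), exposed so
// tests can compare against a direct R implementation.
// [[Rcpp::export]]
NumericVector conv3d_layer_cpp(NumericVector x, IntegerVector dims,
                               NumericMatrix W, NumericVector b,
                               IntegerVector kernel, IntegerVector stride,
                               bool activate) {
  Dims d = { dims[0], dims[1], dims[2], dims[3] };
  ConvSpec cs = { kernel[0], kernel[1], kernel[2],
                  stride[0], stride[1], stride[2],
                  d.C, (int)W.ncol() };
  Dims o = out_dims(d, cs);
  arma::fvec xf = arma::conv_to<arma::fvec>::from(
      arma::vec(x.begin(), x.size(), false));
  arma::fmat col;
  im2col(xf, d, cs, o, col);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(
      arma::mat(W.begin(), W.nrow(), W.ncol(), false));
  arma::fmat Z = col * Wf;
  arma::fvec bf = arma::conv_to<arma::fvec>::from(
      arma::vec(b.begin(), b.size(), false));
  Z.each_row() += bf.t();
  if (activate) Z = swish(Z);
  NumericVector out = wrap(arma::conv_to<arma::vec>::from(arma::vectorise(Z)));
  out.attr("dim") = IntegerVector::create(o.T, o.H, o.W, o.C);
  return out;
}
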