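// Compact CPU neural-network engine: 3x3 'same' convolutions via im2col +
// BLAS GEMM, batch normalization, 2x2 max pooling, nearest-neighbour
// upsampling, U-Net encoder/decoder with skip connections, a VGG16-style
// regression backbone with a global max+mean pooling head, and the Adamax
// optimizer. Double precision throughout; all randomness comes from a
// per-network mt19937 so runs are reproducible on a single thread.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::XPtr;

typedef std::vector<cube> Batch;

// ---------- im2col / col2im for 3x3 same-padding convolution ----------
//
// Layout: cols is (H*W) x (9*C) so that every shifted image occupies one
// contiguous column, and a cube's memory doubles as an (H*W) x C matrix —
// all copies and GEMM operands stay cache-friendly and several reshapes
// become zero-copy views.

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out((size_t)H * W, 9 * C);
  int r = 0;
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        mat sh(out.colptr(r), H, W, false, true);  // view into column r
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        const int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        if (r1 > r0 && c1 > c0)
          sh.submat(r0, c0, r1 - 1, c1 - 1) =
            s.submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
        // zero only the padded strips (at most one row and one column)
        if (r0 > 0) sh.row(0).zeros();
        if (r1 < H) sh.row(H - 1).zeros();
        if (c0 > 0) sh.col(0).zeros();
        if (c1 < W) sh.col(W - 1).zeros();
        ++r;
      }
    }
  }
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  int r = 0;
  for (int c = 0; c < C; ++c) {
    mat& d = dx.slice(c);
    for (int dxo = -1; dxo <= 1; ++dxo) {
      for (int dyo = -1; dyo <= 1; ++dyo) {
        const mat sh(const_cast<double*>(cols.colptr(r)), H, W, false, true);
        const int r0 = std::max(0, -dyo), r1 = std::min(H, H - dyo);
        const int c0 = std::max(0, -dxo), c1 = std::min(W, W - dxo);
        if (r1 > r0 && c1 > c0)
          d.submat(r0 + dyo, c0 + dxo, r1 - 1 + dyo, c1 - 1 + dxo) +=
            sh.submat(r0, c0, r1 - 1, c1 - 1);
        ++r;
      }
    }
  }
  return dx;
}

// zero-copy view of a cube as an (H*W) x C matrix
static mat cube_as_mat(const cube& x) {
  return mat(const_cast<double*>(x.memptr()),
             (size_t)x.n_rows * x.n_cols, x.n_slices, false, true);
}

// ---------- parameter containers ----------

struct Param {  // conv (W: cout x 9cin) or dense (W: out x in)
  mat W; vec b;
  mat gW; vec gb;
  mat mW, uW; vec mb, ub;
  void init(int rows, int cols, int bias_len, double sd, std::mt19937& rng) {
    std::normal_distribution<double> N(0.0, sd);
    W.set_size(rows, cols);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = N(rng);
    b.zeros(bias_len);
    gW.zeros(rows, cols); gb.zeros(bias_len);
    mW.zeros(rows, cols); uW.zeros(rows, cols);
    mb.zeros(bias_len); ub.zeros(bias_len);
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
};

struct BNParam {
  vec g, b, gg, gb, mg, ug, mb_, ub_, rmean, rvar, mu, var;
  void init(int C) {
    g.ones(C); b.zeros(C);
    gg.zeros(C); gb.zeros(C);
    mg.zeros(C); ug.zeros(C); mb_.zeros(C); ub_.zeros(C);
    rmean.zeros(C); rvar.ones(C);
    mu.zeros(C); var.ones(C);
  }
  void zero_grad() { gg.zeros(); gb.zeros(); }
};

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

// Adamax update for one parameter tensor
static void adamax_mat(mat& W, const mat& g, mat& m, mat& u,
                       double lr, double b1, double b2, double eps, int t) {
  m = b1 * m + (1.0 - b1) * g;
  u = arma::max(b2 * u, arma::abs(g));
  W -= (lr / (1.0 - std::pow(b1, t))) * (m / (u + eps));
}
static void adamax_vec(vec& W, const vec& g, vec& m, vec& u,
                       double lr, double b1, double b2, double eps, int t) {
  m = b1 * m + (1.0 - b1) * g;
  u = arma::max(b2 * u, arma::abs(g));
  W -= (lr / (1.0 - std::pow(b1, t))) * (m / (u + eps));
}

// ---------- layer primitives over a batch ----------

// conv weights are stored (9*cin) x cout; 1x1 conv weights cin x cout
static void conv3_fwd(const Batch& xs, const Param& p, Batch& out) {
  out.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    mat cols = im2col3(xs[i]);
    out[i].set_size(xs[i].n_rows, xs[i].n_cols, p.W.n_cols);
    mat Y = cube_as_mat(out[i]);
    Y = cols * p.W;
    Y.each_row() += p.b.t();
  }
}

static void conv3_bwd(const Batch& xs, Param& p, const Batch& dys, Batch& dxs) {
  dxs.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    mat cols = im2col3(xs[i]);
    mat dY = cube_as_mat(dys[i]);
    p.gW += cols.t() * dY;
    p.gb += sum(dY, 0).t();
    mat dcols = dY * p.W.t();
    dxs[i] = col2im3(dcols, xs[i].n_rows, xs[i].n_cols, xs[i].n_slices);
  }
}

static void conv1_fwd(const Batch& xs, const Param& p, Batch& out) {
  out.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    mat X = cube_as_mat(xs[i]);
    out[i].set_size(xs[i].n_rows, xs[i].n_cols, p.W.n_cols);
    mat Y = cube_as_mat(out[i]);
    Y = X * p.W;
    Y.each_row() += p.b.t();
  }
}

static void conv1_bwd(const Batch& xs, Param& p, const Batch& dys, Batch& dxs) {
  dxs.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    mat X = cube_as_mat(xs[i]);
    mat dY = cube_as_mat(dys[i]);
    p.gW += X.t() * dY;
    p.gb += sum(dY, 0).t();
    dxs[i].set_size(xs[i].n_rows, xs[i].n_cols, p.W.n_rows);
    mat dX = cube_as_mat(dxs[i]);
    dX = dY * p.W.t();
  }
}

// batchnorm forward over batch (training mode); caches mu/var in bn
static void bn_fwd_train(const Batch& xs, BNParam& bn, Batch& out) {
  const int C = xs[0].n_slices;
  const double N = (double)xs.size() * xs[0].n_rows * xs[0].n_cols;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (size_t i = 0; i < xs.size(); ++i) {
      s += accu(xs[i].slice(c));
      s2 += accu(square(xs[i].slice(c)));
    }
    bn.mu(c) = s / N;
    bn.var(c) = s2 / N - bn.mu(c) * bn.mu(c);
    if (bn.var(c) < 0) bn.var(c) = 0;
  }
  bn.rmean = BN_MOMENTUM * bn.rmean + (1 - BN_MOMENTUM) * bn.mu;
  bn.rvar = BN_MOMENTUM * bn.rvar + (1 - BN_MOMENTUM) * bn.var;
  out.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    out[i].set_size(size(xs[i]));
    for (int c = 0; c < C; ++c) {
      const double sd = std::sqrt(bn.var(c) + BN_EPS);
      out[i].slice(c) = bn.g(c) * (xs[i].slice(c) - bn.mu(c)) / sd + bn.b(c);
    }
  }
}

static void bn_fwd_infer(const cube& x, const BNParam& bn, cube& out) {
  out.set_size(size(x));
  for (uword c = 0; c < x.n_slices; ++c) {
    const double sd = std::sqrt(bn.rvar(c) + BN_EPS);
    out.slice(c) = bn.g(c) * (x.slice(c) - bn.rmean(c)) / sd + bn.b(c);
  }
}

static void bn_bwd(const Batch& xs, BNParam& bn, const Batch& dys, Batch& dxs) {
  const int C = xs[0].n_slices;
  const double N = (double)xs.size() * xs[0].n_rows * xs[0].n_cols;
  dxs.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) dxs[i].set_size(size(xs[i]));
  for (int c = 0; c < C; ++c) {
    const double sd = std::sqrt(bn.var(c) + BN_EPS);
    double sum_dy = 0, sum_dy_xhat = 0;
    for (size_t i = 0; i < xs.size(); ++i) {
      const mat xhat = (xs[i].slice(c) - bn.mu(c)) / sd;
      sum_dy += accu(dys[i].slice(c));
      sum_dy_xhat += accu(dys[i].slice(c) % xhat);
    }
    bn.gg(c) += sum_dy_xhat;
    bn.gb(c) += sum_dy;
    for (size_t i = 0; i < xs.size(); ++i) {
      const mat xhat = (xs[i].slice(c) - bn.mu(c)) / sd;
      dxs[i].slice(c) = (bn.g(c) / sd) *
        (dys[i].slice(c) - sum_dy / N - xhat * (sum_dy_xhat / N));
    }
  }
}

static void relu_fwd(Batch& xs) {
  for (auto& x : xs) x.transform([](double v) { return v > 0 ? v : 0.0; });
}
static void relu_bwd(const Batch& act, Batch& dys) {  // act = post-relu output
  for (size_t i = 0; i < act.size(); ++i) {
    const double* a = act[i].memptr();
    double* d = dys[i].memptr();
    for (uword j = 0; j < act[i].n_elem; ++j)
      if (a[j] <= 0) d[j] = 0;
  }
}

// 2x2 max pooling with floor semantics; idx stores linear index into input slice
static void pool2_fwd(const Batch& xs, Batch& out, std::vector<ucube>& idx) {
  out.resize(xs.size());
  idx.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    const int H = xs[i].n_rows / 2, W = xs[i].n_cols / 2, C = xs[i].n_slices;
    out[i].set_size(H, W, C);
    idx[i].set_size(H, W, C);
    for (int c = 0; c < C; ++c) {
      const mat& s = xs[i].slice(c);
      for (int x = 0; x < W; ++x) {
        for (int y = 0; y < H; ++y) {
          double best = s(2 * y, 2 * x);
          uword bi = (uword)(2 * x) * s.n_rows + 2 * y;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy) {
              const double v = s(2 * y + dy, 2 * x + dx);
              if (v > best) {
                best = v;
                bi = (uword)(2 * x + dx) * s.n_rows + (2 * y + dy);
              }
            }
          out[i](y, x, c) = best;
          idx[i](y, x, c) = bi;
        }
      }
    }
  }
}

static void pool2_bwd(const Batch& xs, const std::vector<ucube>& idx,
                      const Batch& dys, Batch& dxs) {
  dxs.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    dxs[i].zeros(size(xs[i]));
    const int H = dys[i].n_rows, W = dys[i].n_cols, C = dys[i].n_slices;
    for (int c = 0; c < C; ++c) {
      mat& d = dxs[i].slice(c);
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y)
          d(idx[i](y, x, c)) += dys[i](y, x, c);
    }
  }
}

static void up2_fwd(const Batch& xs, Batch& out) {
  out.resize(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) {
    const int H = xs[i].n_rows, W = xs[i].n_cols, C = xs[i].n_slices;
    out[i].set_size(2 * H, 2 * W, C);
    for (int c = 0; c < C; ++c)
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y) {
          const double v = xs[i](y, x, c);
          out[i](2 * y, 2 * x, c) = v;
          out[i](2 * y + 1, 2 * x, c) = v;
          out[i](2 * y, 2 * x + 1, c) = v;
          out[i](2 * y + 1, 2 * x + 1, c) = v;
        }
  }
}

static void up2_bwd(const Batch& dys, Batch& dxs) {
  dxs.resize(dys.size());
  for (size_t i = 0; i < dys.size(); ++i) {
    const int H = dys[i].n_rows / 2, W = dys[i].n_cols / 2, C = dys[i].n_slices;
    dxs[i].set_size(H, W, C);
    for (int c = 0; c < C; ++c)
      for (int x = 0; x < W; ++x)
        for (int y = 0; y < H; ++y)
          dxs[i](y, x, c) = dys[i](2 * y, 2 * x, c) + dys[i](2 * y + 1, 2 * x, c) +
                            dys[i](2 * y, 2 * x + 1, c) + dys[i](2 * y + 1, 2 * x + 1, c);
  }
}

static void concat_fwd(const Batch& a, const Batch& b, Batch& out) {
  out.resize(a.size());
  for (size_t i = 0; i < a.size(); ++i) out[i] = join_slices(a[i], b[i]);
}
static void concat_bwd(const Batch& dys, int ca, Batch& da, Batch& db) {
  da.resize(dys.size());
  db.resize(dys.size());
  for (size_t i = 0; i < dys.size(); ++i) {
    da[i] = dys[i].slices(0, ca - 1);
    db[i] = dys[i].slices(ca, dys[i].n_slices - 1);
  }
}

// ---------- U-Net ----------

class UNet {
 public:
  std::vector<int> widths;  // encoder widths; bottleneck = 2 * last
  int cin, nout;            // nout == 1 -> sigmoid/BCE, else softmax/CE
  std::vector<Param> convs; // enc (2/level), bottleneck (2), dec (2/level), out (1x1)
  std::vector<BNParam> bns; // one per conv except output
  std::mt19937 rng;
  int t = 0;

  UNet(const std::vector<int>& w, int cin_, int nout_, unsigned seed)
      : widths(w), cin(cin_), nout(nout_), rng(seed) {
    const int L = widths.size();
    int prev = cin;
    auto add_conv = [&](int cout, int k) {  // k = kernel elements per input ch
      Param p;
      p.init(k * prev, cout, cout, std::sqrt(2.0 / (k * prev)), rng);
      convs.push_back(p);
      BNParam b; b.init(cout); bns.push_back(b);
      prev = cout;
    };
    for (int i = 0; i < L; ++i) { add_conv(widths[i], 9); add_conv(widths[i], 9); }
    const int bw = 2 * widths[L - 1];
    add_conv(bw, 9); add_conv(bw, 9);
    for (int i = L - 1; i >= 0; --i) {
      prev = prev + widths[i];  // upsampled + skip
      add_conv(widths[i], 9); add_conv(widths[i], 9);
    }
    Param out;
    out.init(prev, nout, nout, std::sqrt(2.0 / prev), rng);
    convs.push_back(out);
  }

  size_t n_params() const {
    size_t n = 0;
    for (const auto& p : convs) n += p.W.n_elem + p.b.n_elem;
    for (const auto& b : bns) n += b.g.n_elem + b.b.n_elem;
    return n;
  }

  // forward for training: caches everything needed for backward
  struct Tape {
    std::vector<Batch> conv_in;   // input to each conv (pre-im2col)
    std::vector<Batch> conv_out;  // conv output (pre-BN)
    std::vector<Batch> act;       // post BN+relu
    std::vector<Batch> pool_in;   // per level
    std::vector<std::vector<ucube>> pool_idx;
    std::vector<Batch> skips;
    Batch logits;                 // output conv result
    Batch probs;
  };

  void forward_train(const Batch& xs, Tape& tp) {
    const int L = widths.size();
    tp.conv_in.resize(convs.size());
    tp.conv_out.resize(convs.size());
    tp.act.resize(convs.size());
    tp.pool_in.resize(L);
    tp.pool_idx.resize(L);
    tp.skips.resize(L);
    Batch cur = xs;
    int k = 0;
    auto block = [&](int k0) {  // two conv+bn+relu starting at conv k0
      for (int j = 0; j < 2; ++j) {
        tp.conv_in[k0 + j] = cur;
        conv3_fwd(cur, convs[k0 + j], tp.conv_out[k0 + j]);
        bn_fwd_train(tp.conv_out[k0 + j], bns[k0 + j], cur);
        relu_fwd(cur);
        tp.act[k0 + j] = cur;
      }
    };
    for (int i = 0; i < L; ++i) {
      block(k);
      k += 2;
      tp.skips[i] = cur;
      tp.pool_in[i] = cur;
      Batch pooled;
      pool2_fwd(cur, pooled, tp.pool_idx[i]);
      cur = pooled;
    }
    block(k); k += 2;  // bottleneck
    for (int i = L - 1; i >= 0; --i) {
      Batch up;
      up2_fwd(cur, up);
      Batch cat;
      concat_fwd(up, tp.skips[i], cat);
      cur = cat;
      block(k); k += 2;
    }
    const int ko = convs.size() - 1;
    tp.conv_in[ko] = cur;
    conv1_fwd(cur, convs[ko], tp.logits);
    tp.probs.resize(tp.logits.size());
    for (size_t i = 0; i < tp.logits.size(); ++i) tp.probs[i] = softmax_or_sigmoid(tp.logits[i]);
  }

  cube softmax_or_sigmoid(const cube& z) const {
    cube p(size(z));
    if (nout == 1) {
      p.slice(0) = 1.0 / (1.0 + exp(-z.slice(0)));
      return p;
    }
    mat mx = z.slice(0);
    for (int c = 1; c < nout; ++c) mx = arma::max(mx, z.slice(c));
    mat den(z.n_rows, z.n_cols, fill::zeros);
    for (int c = 0; c < nout; ++c) {
      p.slice(c) = exp(z.slice(c) - mx);
      den += p.slice(c);
    }
    for (int c = 0; c < nout; ++c) p.slice(c) /= den;
    return p;
  }

  // ys: class index matrices (0..nout-1) for softmax, 0/1 matrices for sigmoid
  double loss_and_backward(const Batch& xs, const std::vector<imat>& ys, bool do_update,
                           double lr, double b1, double b2, double eps) {
    Tape tp;
    forward_train(xs, tp);
    const int B = xs.size();
    const double npix = (double)xs[0].n_rows * xs[0].n_cols;
    double loss = 0;
    Batch dlogits(B);
    for (int i = 0; i < B; ++i) {
      dlogits[i].set_size(size(tp.logits[i]));
      if (nout == 1) {
        const mat& p = tp.probs[i].slice(0);
        for (uword j = 0; j < p.n_elem; ++j) {
          const double y = ys[i](j), pv = std::min(std::max(p(j), 1e-12), 1.0 - 1e-12);
          loss += -(y * std::log(pv) + (1 - y) * std::log(1 - pv));
        }
        dlogits[i].slice(0) = (p - conv_to<mat>::from(ys[i])) / (npix * B);
      } else {
        for (int c = 0; c < nout; ++c) dlogits[i].slice(c) = tp.probs[i].slice(c);
        for (uword j = 0; j < ys[i].n_elem; ++j) {
          const int y = ys[i](j);
          const double pv = std::min(std::max(tp.probs[i].slice(y)(j), 1e-12), 1.0);
          loss += -std::log(pv);
          dlogits[i].slice(y)(j) -= 1.0;
        }
        for (int c = 0; c < nout; ++c) dlogits[i].slice(c) /= (npix * B);
      }
    }
    loss /= npix * B;

    for (auto& p : convs) p.zero_grad();
    for (auto& b : bns) b.zero_grad();

    const int L = widths.size();
    const int ko = convs.size() - 1;
    Batch d;
    conv1_bwd(tp.conv_in[ko], convs[ko], dlogits, d);
    int k = ko - 1;  // walk convs backwards
    auto block_bwd = [&](int k1) {  // backward through convs k1-1, k1 (two conv+bn+relu)
      for (int j = 0; j < 2; ++j) {
        const int kk = k1 - j;
        relu_bwd(tp.act[kk], d);
        Batch dbn;
        bn_bwd(tp.conv_out[kk], bns[kk], d, dbn);
        Batch dx;
        conv3_bwd(tp.conv_in[kk], convs[kk], dbn, dx);
        d = dx;
      }
    };
    for (int i = 0; i < L; ++i) {  // decoder blocks, shallowest was last
      block_bwd(k); k -= 2;
      Batch dup, dskip;
      concat_bwd(d, d[0].n_slices - widths[i], dup, dskip);
      Batch ddown;
      up2_bwd(dup, ddown);
      d = ddown;
      // stash skip gradient to add after pooling backward at level i
      skip_grad[i] = dskip;
    }
    block_bwd(k); k -= 2;  // bottleneck
    for (int i = L - 1; i >= 0; --i) {
      Batch dpool;
      pool2_bwd(tp.pool_in[i], tp.pool_idx[i], d, dpool);
      for (size_t s = 0; s < dpool.size(); ++s) dpool[s] += skip_grad[i][s];
      d = dpool;
      block_bwd(k); k -= 2;
    }

    if (do_update) {
      ++t;
      for (auto& p : convs) {
        adamax_mat(p.W, p.gW, p.mW, p.uW, lr, b1, b2, eps, t);
        adamax_vec(p.b, p.gb, p.mb, p.ub, lr, b1, b2, eps, t);
      }
      for (auto& b : bns) {
        adamax_vec(b.g, b.gg, b.mg, b.ug, lr, b1, b2, eps, t);
        adamax_vec(b.b, b.gb, b.mb_, b.ub_, lr, b1, b2, eps, t);
      }
    }
    return loss;
  }

  std::map<int, Batch> skip_grad;

  cube predict(const cube& x) {
    const int L = widths.size();
    Batch cur(1, x);
    std::vector<Batch> skips(L);
    int k = 0;
    auto block = [&](int k0) {
      for (int j = 0; j < 2; ++j) {
        Batch z;
        conv3_fwd(cur, convs[k0 + j], z);
        cube o;
        bn_fwd_infer(z[0], bns[k0 + j], o);
        o.transform([](double v) { return v > 0 ? v : 0.0; });
        cur[0] = o;
      }
    };
    for (int i = 0; i < L; ++i) {
      block(k); k += 2;
      skips[i] = cur;
      Batch pooled;
      std::vector<ucube> idx;
      pool2_fwd(cur, pooled, idx);
      cur = pooled;
    }
    block(k); k += 2;
    for (int i = L - 1; i >= 0; --i) {
      Batch up;
      up2_fwd(cur, up);
      Batch cat;
      concat_fwd(up, skips[i], cat);
      cur = cat;
      block(k); k += 2;
    }
    Batch logits;
    conv1_fwd(cur, convs.back(), logits);
    return softmax_or_sigmoid(logits[0]);
  }
};

// ---------- VGG16-style regressor ----------

class VGG {
 public:
  std::vector<int> plan;  // conv widths; 0 marks a 2x2 max pool
  int cin, hidden;
  std::vector<Param> convs;
  Param fc1, fc2;
  std::mt19937 rng;
  int t = 0;

  VGG(const std::vector<int>& plan_, int cin_, int hidden_, unsigned seed)
      : plan(plan_), cin(cin_), hidden(hidden_), rng(seed) {
    int prev = cin, last = cin;
    for (int w : plan) {
      if (w == 0) continue;
      Param p;
      p.init(9 * prev, w, w, std::sqrt(2.0 / (9 * prev)), rng);
      convs.push_back(p);
      prev = w;
      last = w;
    }
    feat_ch = last;
    fc1.init(hidden, 2 * feat_ch, hidden, std::sqrt(2.0 / (2.0 * feat_ch)), rng);
    fc2.init(1, hidden, 1, std::sqrt(1.0 / hidden), rng);
  }
  int feat_ch;

  size_t n_params() const {
    size_t n = fc1.W.n_elem + fc1.b.n_elem + fc2.W.n_elem + fc2.b.n_elem;
    for (const auto& p : convs) n += p.W.n_elem + p.b.n_elem;
    return n;
  }

  struct Tape {
    std::vector<Batch> conv_in;   // input to each conv
    std::vector<Batch> act;       // post relu (conv output activated in place)
    std::vector<Batch> pool_in;
    std::vector<std::vector<ucube>> pool_idx;
    Batch feat;                   // final feature map
    std::vector<vec> pooled;      // 2*feat_ch
    std::vector<uvec> max_idx;    // argmax per channel
    std::vector<vec> h1, h1_relu, drop1, drop2;
    std::vector<double> z2, yhat;
  };

  // forward through conv stack only (shared by train/predict)
  void conv_forward(const Batch& xs, Tape& tp) {
    const int npool = std::count(plan.begin(), plan.end(), 0);
    tp.conv_in.resize(convs.size());
    tp.act.resize(convs.size());
    tp.pool_in.resize(npool);
    tp.pool_idx.resize(npool);
    Batch cur = xs;
    int k = 0, pi = 0;
    for (int w : plan) {
      if (w == 0) {
        tp.pool_in[pi] = cur;
        Batch pooled;
        pool2_fwd(cur, pooled, tp.pool_idx[pi]);
        cur = pooled;
        ++pi;
      } else {
        tp.conv_in[k] = cur;
        Batch z;
        conv3_fwd(cur, convs[k], z);
        relu_fwd(z);
        tp.act[k] = z;
        cur = z;
        ++k;
      }
    }
    tp.feat = cur;
  }

  void head_forward(Tape& tp, double dropout, bool train) {
    const size_t B = tp.feat.size();
    tp.pooled.resize(B); tp.max_idx.resize(B);
    tp.h1.resize(B); tp.h1_relu.resize(B);
    tp.drop1.resize(B); tp.drop2.resize(B);
    tp.z2.resize(B); tp.yhat.resize(B);
    std::uniform_real_distribution<double> U(0.0, 1.0);
    for (size_t i = 0; i < B; ++i) {
      const cube& f = tp.feat[i];
      vec pool(2 * feat_ch);
      uvec mi(feat_ch);
      for (int c = 0; c < feat_ch; ++c) {
        pool(c) = f.slice(c).max();
        mi(c) = f.slice(c).index_max();
        pool(feat_ch + c) = accu(f.slice(c)) / f.slice(c).n_elem;
      }
      tp.max_idx[i] = mi;
      vec d1(2 * feat_ch, fill::ones);
      if (train && dropout > 0)
        for (uword j = 0; j < d1.n_elem; ++j)
          d1(j) = (U(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      tp.drop1[i] = d1;
      tp.pooled[i] = pool;
      vec z1 = fc1.W * (pool % d1) + fc1.b;
      tp.h1[i] = z1;
      vec h = z1;
      h.transform([](double v) { return v > 0 ? v : 0.0; });
      tp.h1_relu[i] = h;
      vec d2(hidden, fill::ones);
      if (train && dropout > 0)
        for (uword j = 0; j < d2.n_elem; ++j)
          d2(j) = (U(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      tp.drop2[i] = d2;
      const double z2 = as_scalar(fc2.W * (h % d2)) + fc2.b(0);
      tp.z2[i] = z2;
      tp.yhat[i] = 1.0 / (1.0 + std::exp(-z2));
    }
  }

  // loss_kind: 0 = MSE, 1 = MAE
  double loss_and_backward(const Batch& xs, const std::vector<double>& ys,
                           int loss_kind, bool freeze_backbone, double dropout,
                           bool do_update, double lr, double b1, double b2, double eps) {
    Tape tp;
    conv_forward(xs, tp);
    head_forward(tp, dropout, true);
    const int B = xs.size();
    double loss = 0;
    std::vector<double> dy(B);
    for (int i = 0; i < B; ++i) {
      const double e = tp.yhat[i] - ys[i];
      if (loss_kind == 0) { loss += e * e; dy[i] = 2.0 * e / B; }
      else { loss += std::abs(e); dy[i] = (e > 0 ? 1.0 : (e < 0 ? -1.0 : 0.0)) / B; }
    }
    loss /= B;

    for (auto& p : convs) p.zero_grad();
    fc1.zero_grad(); fc2.zero_grad();

    Batch dfeat(B);
    for (int i = 0; i < B; ++i) {
      const double dz2 = dy[i] * tp.yhat[i] * (1.0 - tp.yhat[i]);
      const vec hd = tp.h1_relu[i] % tp.drop2[i];
      fc2.gW += dz2 * hd.t();
      fc2.gb(0) += dz2;
      vec dh = (fc2.W.t() * dz2) % tp.drop2[i];
      for (int j = 0; j < hidden; ++j) if (tp.h1[i](j) <= 0) dh(j) = 0;
      const vec pd = tp.pooled[i] % tp.drop1[i];
      fc1.gW += dh * pd.t();
      fc1.gb += dh;
      if (!freeze_backbone) {
        vec dpool = (fc1.W.t() * dh) % tp.drop1[i];
        const cube& f = tp.feat[i];
        dfeat[i].zeros(size(f));
        const double ne = (double)f.n_rows * f.n_cols;
        for (int c = 0; c < feat_ch; ++c) {
          dfeat[i].slice(c).fill(dpool(feat_ch + c) / ne);
          dfeat[i].slice(c)(tp.max_idx[i](c)) += dpool(c);
        }
      }
    }

    if (!freeze_backbone) {
      // walk conv stack backwards
      Batch d = dfeat;
      int k = convs.size() - 1;
      int pi = tp.pool_in.size() - 1;
      for (int ip = plan.size() - 1; ip >= 0; --ip) {
        if (plan[ip] == 0) {
          Batch dx;
          pool2_bwd(tp.pool_in[pi], tp.pool_idx[pi], d, dx);
          d = dx;
          --pi;
        } else {
          relu_bwd(tp.act[k], d);
          Batch dx;
          conv3_bwd(tp.conv_in[k], convs[k], d, dx);
          d = dx;
          --k;
        }
      }
    }

    if (do_update) {
      ++t;
      if (!freeze_backbone)
        for (auto& p : convs) {
          adamax_mat(p.W, p.gW, p.mW, p.uW, lr, b1, b2, eps, t);
          adamax_vec(p.b, p.gb, p.mb, p.ub, lr, b1, b2, eps, t);
        }
      adamax_mat(fc1.W, fc1.gW, fc1.mW, fc1.uW, lr, b1, b2, eps, t);
      adamax_vec(fc1.b, fc1.gb, fc1.mb, fc1.ub, lr, b1, b2, eps, t);
      adamax_mat(fc2.W, fc2.gW, fc2.mW, fc2.uW, lr, b1, b2, eps, t);
      adamax_vec(fc2.b, fc2.gb, fc2.mb, fc2.ub, lr, b1, b2, eps, t);
    }
    return loss;
  }

  double predict(const cube& x) {
    Tape tp;
    Batch xs(1, x);
    conv_forward(xs, tp);
    head_forward(tp, 0.0, false);
    return tp.yhat[0];
  }

  // head-only training step on precomputed pooled feature vectors
  double train_head(const std::vector<vec>& pooled, const std::vector<double>& ys,
                    int loss_kind, double dropout, double lr, double b1,
                    double b2, double eps) {
    const int B = pooled.size();
    fc1.zero_grad(); fc2.zero_grad();
    std::uniform_real_distribution<double> U(0.0, 1.0);
    double loss = 0;
    for (int i = 0; i < B; ++i) {
      vec d1(pooled[i].n_elem, fill::ones), d2(hidden, fill::ones);
      if (dropout > 0) {
        for (uword j = 0; j < d1.n_elem; ++j)
          d1(j) = (U(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
        for (uword j = 0; j < d2.n_elem; ++j)
          d2(j) = (U(rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
      }
      const vec pd = pooled[i] % d1;
      vec z1 = fc1.W * pd + fc1.b;
      vec h = z1;
      h.transform([](double v) { return v > 0 ? v : 0.0; });
      const vec hd = h % d2;
      const double z2 = as_scalar(fc2.W * hd) + fc2.b(0);
      const double yhat = 1.0 / (1.0 + std::exp(-z2));
      const double e = yhat - ys[i];
      double dy;
      if (loss_kind == 0) { loss += e * e; dy = 2.0 * e / B; }
      else { loss += std::abs(e); dy = (e > 0 ? 1.0 : (e < 0 ? -1.0 : 0.0)) / B; }
      const double dz2 = dy * yhat * (1.0 - yhat);
      fc2.gW += dz2 * hd.t();
      fc2.gb(0) += dz2;
      vec dh = (fc2.W.t() * dz2) % d2;
      for (int j = 0; j < hidden; ++j) if (z1(j) <= 0) dh(j) = 0;
      fc1.gW += dh * pd.t();
      fc1.gb += dh;
    }
    ++t;
    adamax_mat(fc1.W, fc1.gW, fc1.mW, fc1.uW, lr, b1, b2, eps, t);
    adamax_vec(fc1.b, fc1.gb, fc1.mb, fc1.ub, lr, b1, b2, eps, t);
    adamax_mat(fc2.W, fc2.gW, fc2.mW, fc2.uW, lr, b1, b2, eps, t);
    adamax_vec(fc2.b, fc2.gb, fc2.mb, fc2.ub, lr, b1, b2, eps, t);
    return loss / B;
  }
};

// ---------- R conversions ----------

static cube r2cube(SEXP a) {
  Rcpp::NumericVector v(a);
  Rcpp::IntegerVector d = v.attr("dim");
  cube out;
  if (d.size() == 2) {
    out.set_size(d[0], d[1], 1);
    std::copy(v.begin(), v.end(), out.memptr());
  } else {
    out.set_size(d[0], d[1], d[2]);
    std::copy(v.begin(), v.end(), out.memptr());
  }
  return out;
}

static Rcpp::NumericVector cube2r(const cube& x) {
  Rcpp::NumericVector out(x.n_elem);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static Batch list2batch(List xs) {
  Batch b(xs.size());
  for (int i = 0; i < xs.size(); ++i) b[i] = r2cube(xs[i]);
  return b;
}

static std::vector<imat> list2labels(List ys) {
  std::vector<imat> out(ys.size());
  for (int i = 0; i < ys.size(); ++i) {
    Rcpp::IntegerMatrix m(ys[i]);
    imat mm(m.nrow(), m.ncol());
    for (int j = 0; j < m.nrow() * m.ncol(); ++j) mm(j) = m[j];
    out[i] = mm;
  }
  return out;
}

static List params_to_list(const std::vector<Param>& ps) {
  List out(ps.size());
  for (size_t i = 0; i < ps.size(); ++i)
    out[i] = List::create(Rcpp::Named("W") = ps[i].W, Rcpp::Named("b") = ps[i].b);
  return out;
}
static void list_to_params(List l, std::vector<Param>& ps) {
  for (size_t i = 0; i < ps.size(); ++i) {
    List li = l[i];
    ps[i].W = Rcpp::as<mat>(li["W"]);
    ps[i].b = Rcpp::as<vec>(li["b"]);
  }
}

// ---------- exported U-Net API ----------

// [[Rcpp::export]]
SEXP nn_unet_create(Rcpp::IntegerVector widths, int in_ch, int n_out, int seed) {
  std::vector<int> w(widths.begin(), widths.end());
  XPtr<UNet> p(new UNet(w, in_ch, n_out, (unsigned)seed), true);
  return p;
}

// [[Rcpp::export]]
double nn_unet_nparams(SEXP ptr) {
  XPtr<UNet> p(ptr);
  return (double)p->n_params();
}

// [[Rcpp::export]]
double nn_unet_train_batch(SEXP ptr, List xs, List ys, double lr,
                           double beta1, double beta2, double eps) {
  XPtr<UNet> p(ptr);
  Batch xb = list2batch(xs);
  std::vector<imat> yb = list2labels(ys);
  return p->loss_and_backward(xb, yb, true, lr, beta1, beta2, eps);
}

// [[Rcpp::export]]
List nn_unet_grads(SEXP ptr, List xs, List ys) {
  XPtr<UNet> p(ptr);
  Batch xb = list2batch(xs);
  std::vector<imat> yb = list2labels(ys);
  const double loss = p->loss_and_backward(xb, yb, false, 0, 0.9, 0.999, 1e-7);
  List g(p->convs.size());
  for (size_t i = 0; i < p->convs.size(); ++i)
    g[i] = List::create(Rcpp::Named("W") = p->convs[i].gW, Rcpp::Named("b") = p->convs[i].gb);
  List gbn(p->bns.size());
  for (size_t i = 0; i < p->bns.size(); ++i)
    gbn[i] = List::create(Rcpp::Named("g") = p->bns[i].gg, Rcpp::Named("b") = p->bns[i].gb);
  return List::create(Rcpp::Named("loss") = loss, Rcpp::Named("conv") = g,
                      Rcpp::Named("bn") = gbn);
}

// [[Rcpp::export]]
double nn_unet_batch_loss(SEXP ptr, List xs, List ys) {
  XPtr<UNet> p(ptr);
  Batch xb = list2batch(xs);
  std::vector<imat> yb = list2labels(ys);
  return p->loss_and_backward(xb, yb, false, 0, 0.9, 0.999, 1e-7);
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_unet_predict(SEXP ptr, SEXP x) {
  XPtr<UNet> p(ptr);
  return cube2r(p->predict(r2cube(x)));
}

// [[Rcpp::export]]
List nn_unet_get_weights(SEXP ptr) {
  XPtr<UNet> p(ptr);
  List bn(p->bns.size());
  for (size_t i = 0; i < p->bns.size(); ++i)
    bn[i] = List::create(Rcpp::Named("g") = p->bns[i].g, Rcpp::Named("b") = p->bns[i].b,
                         Rcpp::Named("rmean") = p->bns[i].rmean,
                         Rcpp::Named("rvar") = p->bns[i].rvar);
  return List::create(Rcpp::Named("conv") = params_to_list(p->convs),
                      Rcpp::Named("bn") = bn,
                      Rcpp::Named("widths") = Rcpp::wrap(p->widths),
                      Rcpp::Named("in_ch") = p->cin, Rcpp::Named("n_out") = p->nout);
}

// [[Rcpp::export]]
void nn_unet_set_weights(SEXP ptr, List w) {
  XPtr<UNet> p(ptr);
  list_to_params(w["conv"], p->convs);
  List bn = w["bn"];
  for (size_t i = 0; i < p->bns.size(); ++i) {
    List bi = bn[i];
    p->bns[i].g = Rcpp::as<vec>(bi["g"]);
    p->bns[i].b = Rcpp::as<vec>(bi["b"]);
    p->bns[i].rmean = Rcpp::as<vec>(bi["rmean"]);
    p->bns[i].rvar = Rcpp::as<vec>(bi["rvar"]);
  }
}

// ---------- exported VGG API ----------

// [[Rcpp::export]]
SEXP nn_vgg_create(Rcpp::IntegerVector plan, int in_ch, int hidden, int seed) {
  std::vector<int> w(plan.begin(), plan.end());
  XPtr<VGG> p(new VGG(w, in_ch, hidden, (unsigned)seed), true);
  return p;
}

// [[Rcpp::export]]
double nn_vgg_nparams(SEXP ptr) {
  XPtr<VGG> p(ptr);
  return (double)p->n_params();
}

// [[Rcpp::export]]
int nn_vgg_feature_width(SEXP ptr) {
  XPtr<VGG> p(ptr);
  return 2 * p->feat_ch;
}

// [[Rcpp::export]]
double nn_vgg_train_batch(SEXP ptr, List xs, Rcpp::NumericVector ys, double lr,
                          double beta1, double beta2, double eps, int loss_kind,
                          bool freeze_backbone, double dropout) {
  XPtr<VGG> p(ptr);
  Batch xb = list2batch(xs);
  std::vector<double> yb(ys.begin(), ys.end());
  return p->loss_and_backward(xb, yb, loss_kind, freeze_backbone, dropout, true,
                              lr, beta1, beta2, eps);
}

// [[Rcpp::export]]
List nn_vgg_grads(SEXP ptr, List xs, Rcpp::NumericVector ys, int loss_kind,
                  bool freeze_backbone) {
  XPtr<VGG> p(ptr);
  Batch xb = list2batch(xs);
  std::vector<double> yb(ys.begin(), ys.end());
  const double loss = p->loss_and_backward(xb, yb, loss_kind, freeze_backbone, 0.0,
                                           false, 0, 0.9, 0.999, 1e-7);
  List g(p->convs.size());
  for (size_t i = 0; i < p->convs.size(); ++i)
    g[i] = List::create(Rcpp::Named("W") = p->convs[i].gW, Rcpp::Named("b") = p->convs[i].gb);
  return List::create(Rcpp::Named("loss") = loss, Rcpp::Named("conv") = g,
                      Rcpp::Named("fc1") = List::create(Rcpp::Named("W") = p->fc1.gW,
                                                        Rcpp::Named("b") = p->fc1.gb),
                      Rcpp::Named("fc2") = List::create(Rcpp::Named("W") = p->fc2.gW,
                                                        Rcpp::Named("b") = p->fc2.gb));
}

// [[Rcpp::export]]
double nn_vgg_batch_loss(SEXP ptr, List xs, Rcpp::NumericVector ys, int loss_kind) {
  XPtr<VGG> p(ptr);
  Batch xb = list2batch(xs);
  std::vector<double> yb(ys.begin(), ys.end());
  return p->loss_and_backward(xb, yb, loss_kind, true, 0.0, false, 0, 0.9, 0.999, 1e-7);
}

// [[Rcpp::export]]
double nn_vgg_train_head(SEXP ptr, Rcpp::NumericMatrix feats,
                         Rcpp::NumericVector ys, double lr, double beta1,
                         double beta2, double eps, int loss_kind,
                         double dropout) {
  XPtr<VGG> p(ptr);
  std::vector<vec> pooled(feats.nrow());
  for (int i = 0; i < feats.nrow(); ++i) {
    vec v(feats.ncol());
    for (int j = 0; j < feats.ncol(); ++j) v(j) = feats(i, j);
    pooled[i] = v;
  }
  std::vector<double> yb(ys.begin(), ys.end());
  return p->train_head(pooled, yb, loss_kind, dropout, lr, beta1, beta2, eps);
}

// [[Rcpp::export]]
Rcpp::NumericVector nn_vgg_features(SEXP ptr, SEXP x) {
  XPtr<VGG> p(ptr);
  VGG::Tape tp;
  Batch xs(1, r2cube(x));
  p->conv_forward(xs, tp);
  const cube& f = tp.feat[0];
  Rcpp::NumericVector out(2 * p->feat_ch);
  for (int c = 0; c < p->feat_ch; ++c) {
    out[c] = f.slice(c).max();
    out[p->feat_ch + c] = accu(f.slice(c)) / f.slice(c).n_elem;
  }
  return out;
}

// [[Rcpp::export]]
double nn_vgg_predict(SEXP ptr, SEXP x) {
  XPtr<VGG> p(ptr);
  return p->predict(r2cube(x));
}

// [[Rcpp::export]]
List nn_vgg_get_weights(SEXP ptr) {
  XPtr<VGG> p(ptr);
  return List::create(
      Rcpp::Named("conv") = params_to_list(p->convs),
      Rcpp::Named("fc1") = List::create(Rcpp::Named("W") = p->fc1.W, Rcpp::Named("b") = p->fc1.b),
      Rcpp::Named("fc2") = List::create(Rcpp::Named("W") = p->fc2.W, Rcpp::Named("b") = p->fc2.b),
      Rcpp::Named("plan") = Rcpp::wrap(p->plan), Rcpp::Named("in_ch") = p->cin,
      Rcpp::Named("hidden") = p->hidden);
}

// [[Rcpp::export]]
void nn_vgg_set_weights(SEXP ptr, List w) {
  XPtr<VGG> p(ptr);
  list_to_params(w["conv"], p->convs);
  List f1 = w["fc1"], f2 = w["fc2"];
  p->fc1.W = Rcpp::as<mat>(f1["W"]);
  p->fc1.b = Rcpp::as<vec>(f1["b"]);
  p->fc2.W = Rcpp::as<mat>(f2["W"]);
  p->fc2.b = Rcpp::as<vec>(f2["b"]);
}
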