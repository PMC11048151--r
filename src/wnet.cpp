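// 1-D dual-U-Net ("WNet") sequence-to-sequence engine with an optional
// bidirectional-LSTM bottleneck, written directly on Armadillo (single
// precision, BLAS gemm via im2col).  Activations are stored as
// (channels x batch*length) matrices in sample-major column order: the
// column index of sample b, position t is b*L + t.  All randomness
// (weight init, dropout, batch shuffling) flows from integer seeds so two
// runs with equal seeds are bit-identical.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::uvec;

static const float ADAM_B1 = 0.9f, ADAM_B2 = 0.999f, ADAM_EPS = 1e-8f;

struct Param {
  fmat W, G, M, V;
  std::string name;
  void init(int r, int c, const std::string& nm) {
    W.zeros(r, c); G.zeros(r, c); M.zeros(r, c); V.zeros(r, c); name = nm;
  }
  size_t size() const { return W.n_elem; }
};

// With sample-major column layout, the k taps of one convolution window are
// k consecutive columns of the padded activation, i.e. one contiguous block
// of Cin*k floats.  im2col and its transpose therefore reduce to one
// memcpy (or fused add) per output position.
struct Conv1d {
  int Cin, Cout, k, stride, pad;
  Param W, b;  // W: (Cout, Cin*k)
  fmat col;
  int B = 0, Lin = 0, Lout = 0, Lpad = 0;

  void build(int cin, int cout, int kk, int ss, int pp, std::mt19937& rng,
             float init_scale, const std::string& nm) {
    Cin = cin; Cout = cout; k = kk; stride = ss; pad = pp;
    W.init(Cout, Cin * k, nm + ".weight");
    b.init(Cout, 1, nm + ".bias");
    std::normal_distribution<float> nd(0.f, init_scale);
    for (auto& w : W.W) w = nd(rng);
  }

  fmat forward(const fmat& X, int Bn, int Lin_) {
    B = Bn; Lin = Lin_;
    Lpad = Lin + 2 * pad;
    Lout = (Lpad - k) / stride + 1;
    fmat Xpad(Cin, static_cast<size_t>(B) * Lpad, arma::fill::zeros);
    {
      float* xp = Xpad.memptr();
      const float* xs = X.memptr();
      const size_t row_in = static_cast<size_t>(Cin) * Lin;
      const size_t row_pad = static_cast<size_t>(Cin) * Lpad;
      for (int bb = 0; bb < B; ++bb)
        std::memcpy(xp + bb * row_pad + static_cast<size_t>(pad) * Cin,
                    xs + bb * row_in, sizeof(float) * row_in);
    }
    col.set_size(static_cast<size_t>(Cin) * k, static_cast<size_t>(B) * Lout);
    {
      const float* xp = Xpad.memptr();
      float* cp = col.memptr();
      const size_t blk = static_cast<size_t>(Cin) * k;
      size_t w = 0;
      for (int bb = 0; bb < B; ++bb)
        for (int o = 0; o < Lout; ++o, ++w)
          std::memcpy(cp + w * blk,
                      xp + (static_cast<size_t>(bb) * Lpad +
                            static_cast<size_t>(o) * stride) * Cin,
                      sizeof(float) * blk);
    }
    fmat Y = W.W * col;
    Y.each_col() += b.W.col(0);
    return Y;
  }

  fmat backward(const fmat& dY) {
    b.G += arma::sum(dY, 1);
    W.G += dY * col.t();
    fmat dcol = W.W.t() * dY;
    fmat dXpad(Cin, static_cast<size_t>(B) * Lpad, arma::fill::zeros);
    {
      const float* cp = dcol.memptr();
      float* xp = dXpad.memptr();
      const size_t blk = static_cast<size_t>(Cin) * k;
      size_t w = 0;
      for (int bb = 0; bb < B; ++bb)
        for (int o = 0; o < Lout; ++o, ++w) {
          float* dst = xp + (static_cast<size_t>(bb) * Lpad +
                             static_cast<size_t>(o) * stride) * Cin;
          const float* src = cp + w * blk;
          for (size_t i = 0; i < blk; ++i) dst[i] += src[i];
        }
    }
    fmat dX(Cin, static_cast<size_t>(B) * Lin);
    {
      const float* xp = dXpad.memptr();
      float* xd = dX.memptr();
      const size_t row_in = static_cast<size_t>(Cin) * Lin;
      const size_t row_pad = static_cast<size_t>(Cin) * Lpad;
      for (int bb = 0; bb < B; ++bb)
        std::memcpy(xd + bb * row_in,
                    xp + bb * row_pad + static_cast<size_t>(pad) * Cin,
                    sizeof(float) * row_in);
    }
    return dX;
  }
};

struct ConvT1d {
  int Cin, Cout, k, stride, pad;
  Param W, b;  // W: (Cout*k, Cin)
  fmat Xc;
  int B = 0, Lin = 0, Lout = 0, Lfull = 0;

  void build(int cin, int cout, int kk, int ss, int pp, std::mt19937& rng,
             float init_scale, const std::string& nm) {
    Cin = cin; Cout = cout; k = kk; stride = ss; pad = pp;
    W.init(Cout * k, Cin, nm + ".weight");
    b.init(Cout, 1, nm + ".bias");
    std::normal_distribution<float> nd(0.f, init_scale);
    for (auto& w : W.W) w = nd(rng);
  }

  fmat forward(const fmat& X, int Bn, int Lin_) {
    B = Bn; Lin = Lin_;
    Lfull = stride * (Lin - 1) + k;
    Lout = Lfull - 2 * pad;
    Xc = X;
    fmat Z = W.W * X;  // (Cout*k, B*Lin)
    fmat Yfull(Cout, static_cast<size_t>(B) * Lfull, arma::fill::zeros);
    {
      const float* zp = Z.memptr();
      float* yp = Yfull.memptr();
      const size_t blk = static_cast<size_t>(Cout) * k;
      size_t w = 0;
      for (int bb = 0; bb < B; ++bb)
        for (int i = 0; i < Lin; ++i, ++w) {
          float* dst = yp + (static_cast<size_t>(bb) * Lfull +
                             static_cast<size_t>(i) * stride) * Cout;
          const float* src = zp + w * blk;
          for (size_t j = 0; j < blk; ++j) dst[j] += src[j];
        }
    }
    fmat Y(Cout, static_cast<size_t>(B) * Lout);
    {
      const float* yp = Yfull.memptr();
      float* yd = Y.memptr();
      const size_t row_out = static_cast<size_t>(Cout) * Lout;
      const size_t row_full = static_cast<size_t>(Cout) * Lfull;
      for (int bb = 0; bb < B; ++bb)
        std::memcpy(yd + bb * row_out,
                    yp + bb * row_full + static_cast<size_t>(pad) * Cout,
                    sizeof(float) * row_out);
    }
    Y.each_col() += b.W.col(0);
    return Y;
  }

  fmat backward(const fmat& dY) {
    b.G += arma::sum(dY, 1);
    fmat dYfull(Cout, static_cast<size_t>(B) * Lfull, arma::fill::zeros);
    {
      const float* yp = dY.memptr();
      float* yd = dYfull.memptr();
      const size_t row_out = static_cast<size_t>(Cout) * Lout;
      const size_t row_full = static_cast<size_t>(Cout) * Lfull;
      for (int bb = 0; bb < B; ++bb)
        std::memcpy(yd + bb * row_full + static_cast<size_t>(pad) * Cout,
                    yp + bb * row_out, sizeof(float) * row_out);
    }
    fmat dZ(static_cast<size_t>(Cout) * k, static_cast<size_t>(B) * Lin);
    {
      const float* yp = dYfull.memptr();
      float* zp = dZ.memptr();
      const size_t blk = static_cast<size_t>(Cout) * k;
      size_t w = 0;
      for (int bb = 0; bb < B; ++bb)
        for (int i = 0; i < Lin; ++i, ++w)
          std::memcpy(zp + w * blk,
                      yp + (static_cast<size_t>(bb) * Lfull +
                            static_cast<size_t>(i) * stride) * Cout,
                      sizeof(float) * blk);
    }
    W.G += dZ * Xc.t();
    return W.W.t() * dZ;
  }
};

struct BatchNorm1d {
  int C;
  Param g, be;
  fvec rmean, rvar;  // running stats (buffers, not trained)
  float mom = 0.1f, eps = 1e-5f;
  fmat xhat;
  fvec inv_std;
  float N = 0;

  void build(int c, const std::string& nm) {
    C = c;
    g.init(C, 1, nm + ".gamma"); g.W.ones();
    be.init(C, 1, nm + ".beta");
    rmean.zeros(C); rvar.ones(C);
  }

  fmat forward(const fmat& X, bool training) {
    if (training) {
      N = static_cast<float>(X.n_cols);
      fvec mu = arma::mean(X, 1);
      fmat cen = X.each_col() - mu;
      fvec var = arma::mean(arma::square(cen), 1);
      inv_std = 1.0f / arma::sqrt(var + eps);
      xhat = cen.each_col() % inv_std;
      rmean = (1 - mom) * rmean + mom * mu;
      float corr = N > 1 ? N / (N - 1) : 1.f;
      rvar = (1 - mom) * rvar + mom * var * corr;
      fmat Y = xhat.each_col() % g.W.col(0);
      Y.each_col() += be.W.col(0);
      return Y;
    }
    fvec is = 1.0f / arma::sqrt(rvar + eps);
    fmat Y = (X.each_col() - rmean).each_col() % (is % g.W.col(0));
    Y.each_col() += be.W.col(0);
    return Y;
  }

  fmat backward(const fmat& dY) {
    g.G += arma::sum(dY % xhat, 1);
    be.G += arma::sum(dY, 1);
    fmat dxhat = dY.each_col() % g.W.col(0);
    fvec s1 = arma::sum(dxhat, 1) / N;
    fvec s2 = arma::sum(dxhat % xhat, 1) / N;
    fmat dX = dxhat;
    dX.each_col() -= s1;
    dX -= xhat.each_col() % s2;
    dX.each_col() %= inv_std;
    return dX;
  }
};

struct ReLU {
  fmat mask;  // 1 where the input was positive
  fmat forward(fmat X) {
    mask.set_size(X.n_rows, X.n_cols);
    float* m = mask.memptr();
    float* x = X.memptr();
    for (size_t i = 0; i < X.n_elem; ++i) {
      if (x[i] > 0) { m[i] = 1.f; } else { m[i] = 0.f; x[i] = 0.f; }
    }
    return X;
  }
  fmat backward(fmat dY) { dY %= mask; return dY; }
};

struct Dropout {
  float p;
  fmat mask;
  bool active = false;
  fmat forward(const fmat& X, bool training, std::mt19937& rng) {
    active = training && p > 0;
    if (!active) return X;
    std::uniform_real_distribution<float> ud(0.f, 1.f);
    mask.set_size(X.n_rows, X.n_cols);
    const float scale = 1.0f / (1.0f - p);
    for (auto& m : mask) m = (ud(rng) >= p) ? scale : 0.f;
    return X % mask;
  }
  fmat backward(const fmat& dY) { return active ? fmat(dY % mask) : dY; }
};

// Single bidirectional LSTM over the bottleneck time axis.  Input/output
// (C x B*T) sample-major; hidden size H = C/2 per direction, outputs
// concatenated (forward direction rows [0,H), backward rows [H,2H)).
struct BiLSTM {
  int C, H;
  Param Wx[2], Wh[2], b[2];  // per direction: (4H x C), (4H x H), (4H x 1)
  int B = 0, T = 0;
  std::vector<fmat> gi[2], gf[2], gg[2], go[2], cc[2], tc[2], hp[2];
  fmat Xc;
  std::vector<uvec> tidx;

  void build(int c, std::mt19937& rng, const std::string& nm) {
    C = c; H = c / 2;
    const char* dn[2] = {".fwd", ".bwd"};
    float s = 1.0f / std::sqrt(static_cast<float>(H));
    std::uniform_real_distribution<float> ud(-s, s);
    for (int d = 0; d < 2; ++d) {
      Wx[d].init(4 * H, C, nm + dn[d] + ".weight_ih");
      Wh[d].init(4 * H, H, nm + dn[d] + ".weight_hh");
      b[d].init(4 * H, 1, nm + dn[d] + ".bias");
      for (auto& w : Wx[d].W) w = ud(rng);
      for (auto& w : Wh[d].W) w = ud(rng);
    }
  }

  static fmat sig(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

  fmat forward(const fmat& X, int Bn, int Tn) {
    B = Bn; T = Tn; Xc = X;
    tidx.assign(T, uvec());
    for (int t = 0; t < T; ++t) {
      uvec ix(B);
      for (int bb = 0; bb < B; ++bb) ix[bb] = static_cast<size_t>(bb) * T + t;
      tidx[t] = ix;
    }
    fmat Y(C, X.n_cols, arma::fill::zeros);
    for (int d = 0; d < 2; ++d) {
      gi[d].assign(T, fmat()); gf[d].assign(T, fmat()); gg[d].assign(T, fmat());
      go[d].assign(T, fmat()); cc[d].assign(T, fmat()); tc[d].assign(T, fmat());
      hp[d].assign(T, fmat());
      fmat Yd(H, X.n_cols, arma::fill::zeros);
      fmat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
      for (int step = 0; step < T; ++step) {
        int t = (d == 0) ? step : (T - 1 - step);
        hp[d][t] = h;
        fmat Xt = Xc.cols(tidx[t]);
        fmat G = Wx[d].W * Xt + Wh[d].W * h;
        G.each_col() += b[d].W.col(0);
        fmat i = sig(G.rows(0, H - 1));
        fmat f = sig(G.rows(H, 2 * H - 1));
        fmat gg_ = arma::tanh(G.rows(2 * H, 3 * H - 1));
        fmat o = sig(G.rows(3 * H, 4 * H - 1));
        fmat cnew = f % c + i % gg_;
        fmat tcn = arma::tanh(cnew);
        h = o % tcn;
        gi[d][t] = i; gf[d][t] = f; gg[d][t] = gg_; go[d][t] = o;
        cc[d][t] = c;  // c_{t-1}
        tc[d][t] = tcn;
        c = cnew;
        Yd.cols(tidx[t]) = h;
      }
      Y.rows(static_cast<size_t>(d) * H, static_cast<size_t>(d + 1) * H - 1) = Yd;
    }
    return Y;
  }

  fmat backward(const fmat& dY) {
    fmat dX(C, Xc.n_cols, arma::fill::zeros);
    for (int d = 0; d < 2; ++d) {
      fmat dYd = dY.rows(static_cast<size_t>(d) * H, static_cast<size_t>(d + 1) * H - 1);
      fmat dh(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
      for (int step = T - 1; step >= 0; --step) {
        int t = (d == 0) ? step : (T - 1 - step);
        dh += dYd.cols(tidx[t]);
        fmat d_o = dh % tc[d][t];
        dc += dh % go[d][t] % (1.0f - arma::square(tc[d][t]));
        fmat d_i = dc % gg[d][t];
        fmat d_g = dc % gi[d][t];
        fmat d_f = dc % cc[d][t];
        fmat dc_prev = dc % gf[d][t];
        fmat dG(4 * H, B);
        dG.rows(0, H - 1) = d_i % gi[d][t] % (1.0f - gi[d][t]);
        dG.rows(H, 2 * H - 1) = d_f % gf[d][t] % (1.0f - gf[d][t]);
        dG.rows(2 * H, 3 * H - 1) = d_g % (1.0f - arma::square(gg[d][t]));
        dG.rows(3 * H, 4 * H - 1) = d_o % go[d][t] % (1.0f - go[d][t]);
        Wx[d].G += dG * Xc.cols(tidx[t]).t();
        Wh[d].G += dG * hp[d][t].t();
        b[d].G += arma::sum(dG, 1);
        dX.cols(tidx[t]) += Wx[d].W.t() * dG;
        dh = Wh[d].W.t() * dG;
        dc = dc_prev;
      }
    }
    return dX;
  }
};

struct UBlock {
  int levels, Cin, F;
  std::vector<Conv1d> down;
  std::vector<BatchNorm1d> dbn;
  std::vector<ReLU> drelu;
  std::vector<ConvT1d> up;
  std::vector<BatchNorm1d> ubn;
  std::vector<ReLU> urelu;
  Dropout drop;
  bool has_lstm = false;
  BiLSTM lstm;
  std::vector<fmat> enc;     // post-ReLU encoder outputs
  std::vector<fmat> dskip;   // grads flowing back through skips
  std::vector<int> Ldown;
  int B = 0;

  int down_out(int l) const { return F << l; }                 // l = 0..levels-1
  int up_out(int l) const { return l < levels - 1 ? (F << (levels - 2 - l)) : F; }
  int up_in(int l) const { return l == 0 ? down_out(levels - 1) : 2 * up_out(l - 1); }

  void build(int cin, int f, int lev, int k, int stride, float dropout_p,
             bool with_lstm, std::mt19937& rng, const std::string& nm) {
    Cin = cin; F = f; levels = lev;
    down.resize(levels); dbn.resize(levels); drelu.resize(levels);
    up.resize(levels); ubn.resize(levels); urelu.resize(levels);
    drop.p = dropout_p;
    for (int l = 0; l < levels; ++l) {
      int ci = (l == 0) ? Cin : down_out(l - 1);
      int co = down_out(l);
      down[l].build(ci, co, k, stride, 1, rng,
                    std::sqrt(2.0f / (ci * k)), nm + ".down" + std::to_string(l + 1));
      dbn[l].build(co, nm + ".down" + std::to_string(l + 1) + ".bn");
    }
    for (int l = 0; l < levels; ++l) {
      int ci = up_in(l), co = up_out(l);
      up[l].build(ci, co, k, stride, 1, rng,
                  std::sqrt(2.0f / (ci * k)), nm + ".up" + std::to_string(l + 1));
      ubn[l].build(co, nm + ".up" + std::to_string(l + 1) + ".bn");
    }
    has_lstm = with_lstm;
    if (has_lstm) lstm.build(down_out(levels - 1), rng, nm + ".bilstm");
  }

  fmat forward(const fmat& X, int Bn, int Lin, bool training, std::mt19937& rng) {
    B = Bn;
    enc.assign(levels, fmat());
    Ldown.assign(levels + 1, 0);
    Ldown[0] = Lin;
    fmat cur = X;
    for (int l = 0; l < levels; ++l) {
      cur = down[l].forward(cur, B, Ldown[l]);
      Ldown[l + 1] = down[l].Lout;
      cur = dbn[l].forward(cur, training);
      cur = drelu[l].forward(cur);
      enc[l] = cur;
    }
    if (has_lstm) cur = lstm.forward(cur, B, Ldown[levels]);
    cur = drop.forward(cur, training, rng);
    for (int l = 0; l < levels; ++l) {
      cur = up[l].forward(cur, B, Ldown[levels - l]);
      cur = ubn[l].forward(cur, training);
      cur = urelu[l].forward(cur);
      if (l < levels - 1) cur = arma::join_cols(cur, enc[levels - 2 - l]);
    }
    return cur;
  }

  fmat backward(const fmat& dY) {
    dskip.assign(levels, fmat());
    fmat d = dY;
    for (int l = levels - 1; l >= 0; --l) {
      if (l < levels - 1) {
        int co = up_out(l);
        fmat dtop = d.rows(0, co - 1);
        dskip[levels - 2 - l] = d.rows(co, d.n_rows - 1);
        d = dtop;
      }
      d = urelu[l].backward(d);
      d = ubn[l].backward(d);
      d = up[l].backward(d);
    }
    d = drop.backward(d);
    if (has_lstm) d = lstm.backward(d);
    for (int l = levels - 1; l >= 0; --l) {
      if (l < levels - 1) d += dskip[l];
      d = drelu[l].backward(d);
      d = dbn[l].backward(d);
      d = down[l].backward(d);
    }
    return d;
  }
};

struct WNet {
  int in_len, levels, F, k, stride;
  float dropout_p;
  bool bilstm;
  int Lpad, pad_left, pad_right;
  UBlock U1, U2;
  Conv1d final_conv;
  fmat tanh_out;
  int B = 0;
  std::mt19937 rng;       // dropout stream during training
  long adam_t = 0;
  std::vector<Param*> params;
  std::vector<BatchNorm1d*> bns;

  WNet(const std::string& variant, int in_len_, int levels_, int base,
       int k_, int stride_, float drop_p, int seed) {
    in_len = in_len_; levels = levels_; F = base; k = k_; stride = stride_;
    dropout_p = drop_p;
    bilstm = (variant == "wnet_bilstm");
    int block = 1 << levels;
    Lpad = ((in_len + block - 1) / block) * block;
    pad_left = (Lpad - in_len) / 2;
    pad_right = Lpad - in_len - pad_left;
    std::mt19937 init_rng(static_cast<unsigned>(seed));
    U1.build(1, F, levels, k, stride, dropout_p, false, init_rng, "u1");
    U2.build(F, F, levels, k, stride, dropout_p, bilstm, init_rng, "u2");
    final_conv.build(F, 1, 1, 1, 0, init_rng, std::sqrt(1.0f / F), "final");
    rng.seed(static_cast<unsigned>(seed) + 101u);
    collect();
  }

  void collect() {
    params.clear(); bns.clear();
    auto addU = [&](UBlock& u) {
      for (int l = 0; l < u.levels; ++l) {
        params.push_back(&u.down[l].W); params.push_back(&u.down[l].b);
        params.push_back(&u.dbn[l].g); params.push_back(&u.dbn[l].be);
        bns.push_back(&u.dbn[l]);
      }
      if (u.has_lstm) {
        for (int d = 0; d < 2; ++d) {
          params.push_back(&u.lstm.Wx[d]); params.push_back(&u.lstm.Wh[d]);
          params.push_back(&u.lstm.b[d]);
        }
      }
      for (int l = 0; l < u.levels; ++l) {
        params.push_back(&u.up[l].W); params.push_back(&u.up[l].b);
        params.push_back(&u.ubn[l].g); params.push_back(&u.ubn[l].be);
        bns.push_back(&u.ubn[l]);
      }
    };
    addU(U1); addU(U2);
    params.push_back(&final_conv.W); params.push_back(&final_conv.b);
  }

  fmat pad_in(const fmat& X, int Bn) const {
    fmat Y(1, static_cast<size_t>(Bn) * Lpad, arma::fill::zeros);
    for (int bb = 0; bb < Bn; ++bb)
      Y.cols(static_cast<size_t>(bb) * Lpad + pad_left,
             static_cast<size_t>(bb) * Lpad + pad_left + in_len - 1) =
          X.cols(static_cast<size_t>(bb) * in_len,
                 static_cast<size_t>(bb + 1) * in_len - 1);
    return Y;
  }

  fmat crop_out(const fmat& X, int Bn) const {
    fmat Y(X.n_rows, static_cast<size_t>(Bn) * in_len);
    for (int bb = 0; bb < Bn; ++bb)
      Y.cols(static_cast<size_t>(bb) * in_len, static_cast<size_t>(bb + 1) * in_len - 1) =
          X.cols(static_cast<size_t>(bb) * Lpad + pad_left,
                 static_cast<size_t>(bb) * Lpad + pad_left + in_len - 1);
    return Y;
  }

  // X: (1, B*in_len) -> (1, B*in_len)
  fmat forward(const fmat& X, int Bn, bool training) {
    B = Bn;
    fmat cur = pad_in(X, B);
    cur = U1.forward(cur, B, Lpad, training, rng);
    cur = U2.forward(cur, B, Lpad, training, rng);
    cur = final_conv.forward(cur, B, Lpad);
    tanh_out = arma::tanh(cur);
    return crop_out(tanh_out, B);
  }

  void backward(const fmat& dOut) {
    fmat d(1, static_cast<size_t>(B) * Lpad, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb)
      d.cols(static_cast<size_t>(bb) * Lpad + pad_left,
             static_cast<size_t>(bb) * Lpad + pad_left + in_len - 1) =
          dOut.cols(static_cast<size_t>(bb) * in_len,
                    static_cast<size_t>(bb + 1) * in_len - 1);
    d = d % (1.0f - arma::square(tanh_out));
    d = final_conv.backward(d);
    d = U2.backward(d);
    U1.backward(d);
  }

  void zero_grads() { for (auto* p : params) p->G.zeros(); }

  void adam_step(float lr) {
    ++adam_t;
    const float c1 = 1.0f - std::pow(ADAM_B1, static_cast<float>(adam_t));
    const float c2 = 1.0f - std::pow(ADAM_B2, static_cast<float>(adam_t));
    for (auto* p : params) {
      p->M = ADAM_B1 * p->M + (1.0f - ADAM_B1) * p->G;
      p->V = ADAM_B2 * p->V + (1.0f - ADAM_B2) * arma::square(p->G);
      p->W -= lr * (p->M / c1) / (arma::sqrt(p->V / c2) + ADAM_EPS);
    }
  }

  size_t n_params() const {
    size_t n = 0;
    for (auto* p : params) n += p->size();
    return n;
  }

  std::vector<fmat> snapshot() const {
    std::vector<fmat> s;
    for (auto* p : params) s.push_back(p->W);
    for (auto* b : bns) { s.push_back(fmat(b->rmean)); s.push_back(fmat(b->rvar)); }
    return s;
  }

  void restore(const std::vector<fmat>& s) {
    size_t i = 0;
    for (auto* p : params) p->W = s[i++];
    for (auto* b : bns) { b->rmean = s[i++].col(0); b->rvar = s[i++].col(0); }
  }
};

static fmat as_fmat(const Rcpp::NumericMatrix& X) {
  fmat F(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      F(i, j) = static_cast<float>(X(i, j));
  return F;
}

// reshape (L x B) sample columns into the engine's (1, B*L) layout
static fmat as_row(const fmat& X) {
  fmat Y(const_cast<float*>(X.memptr()), 1, X.n_elem, true, true);
  return Y;
}

// [[Rcpp::export(name = ".wnet_create")]]
SEXP wnet_create_cpp(std::string variant, int in_len, int levels, int base,
                     int kernel, int stride, double dropout, int seed) {
  Rcpp::XPtr<WNet> p(new WNet(variant, in_len, levels, base, kernel, stride,
                              static_cast<float>(dropout), seed), true);
  return p;
}

// [[Rcpp::export(name = ".wnet_nparams")]]
double wnet_nparams_cpp(SEXP ptr) {
  Rcpp::XPtr<WNet> m(ptr);
  return static_cast<double>(m->n_params());
}

// [[Rcpp::export(name = ".wnet_forward")]]
Rcpp::NumericMatrix wnet_forward_cpp(SEXP ptr, Rcpp::NumericMatrix X,
                                     bool training = false, int batch = 256) {
  Rcpp::XPtr<WNet> m(ptr);
  const int L = X.nrow(), N = X.ncol();
  if (L != m->in_len) Rcpp::stop("input length %d != model in_len %d", L, m->in_len);
  fmat Xf = as_fmat(X);
  Rcpp::NumericMatrix out(L, N);
  for (int s = 0; s < N; s += batch) {
    int e = std::min(N, s + batch);
    fmat Xb = Xf.cols(s, e - 1);
    fmat Y = m->forward(as_row(Xb), e - s, training);
    for (int j = s; j < e; ++j)
      for (int i = 0; i < L; ++i)
        out(i, j) = static_cast<double>(Y(0, static_cast<size_t>(j - s) * L + i));
  }
  return out;
}

// Mean squared error over included samples and its gradient scale.
// [[Rcpp::export(name = ".wnet_train")]]
Rcpp::List wnet_train_cpp(SEXP ptr,
                          Rcpp::NumericMatrix X, Rcpp::NumericMatrix Y,
                          Rcpp::LogicalMatrix M,
                          Rcpp::NumericMatrix Xv, Rcpp::NumericMatrix Yv,
                          int epochs, int batch,
                          double lr0, double decay_factor, int decay_step,
                          int seed, bool masked_loss) {
  Rcpp::XPtr<WNet> m(ptr);
  const int L = X.nrow();
  const int N = X.ncol(), Nv = Xv.ncol();
  if (N < 1) Rcpp::stop("empty training set");
  if (Nv < 1) Rcpp::stop("empty validation set");
  if (Y.nrow() != L || Yv.nrow() != L || Y.ncol() != N || Yv.ncol() != Nv)
    Rcpp::stop("input/target shape mismatch");
  fmat Xf = as_fmat(X), Yf = as_fmat(Y), Xvf = as_fmat(Xv), Yvf = as_fmat(Yv);
  fmat Mf(L, N);
  bool any_masked = false;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < L; ++i) {
      Mf(i, j) = M(i, j) ? 1.0f : 0.0f;
      if (!M(i, j)) any_masked = true;
    }
  if (masked_loss && any_masked) {
    double tot = arma::accu(Mf);
    if (tot == 0) Rcpp::stop("masked_loss with all-false mask");
  }

  std::mt19937 shuffler(static_cast<unsigned>(seed));
  m->rng.seed(static_cast<unsigned>(seed) + 101u);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  std::vector<double> tr_hist, val_hist, lr_hist;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1;
  std::vector<fmat> best_state;

  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 * std::pow(decay_factor, ep / decay_step);
    lr_hist.push_back(lr);
    std::shuffle(idx.begin(), idx.end(), shuffler);
    double sse = 0, cnt = 0;
    for (int s = 0; s < N; s += batch) {
      int e = std::min(N, s + batch);
      int Bn = e - s;
      uvec cols(Bn);
      for (int i = 0; i < Bn; ++i) cols[i] = idx[s + i];
      fmat Xb = Xf.cols(cols), Yb = Yf.cols(cols);
      fmat Yhat = m->forward(as_row(Xb), Bn, true);
      fmat res = Yhat - as_row(Yb);
      double l;
      if (masked_loss) {
        fmat Mb = Mf.cols(cols);
        res = res % as_row(Mb);
        l = arma::accu(as_row(Mb));
        if (l == 0) continue;
      } else {
        l = static_cast<double>(res.n_elem);
      }
      double batch_sse = arma::accu(arma::square(res));
      sse += batch_sse; cnt += l;
      fmat dOut = res * static_cast<float>(2.0 / l);
      m->zero_grads();
      m->backward(dOut);
      m->adam_step(static_cast<float>(lr));
    }
    double tr_loss = sse / cnt;
    if (!std::isfinite(tr_loss))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    tr_hist.push_back(tr_loss);

    // validation (eval mode, unmasked: validation targets carry no gaps)
    double vsse = 0, vcnt = 0;
    for (int s = 0; s < Nv; s += 256) {
      int e = std::min(Nv, s + 256);
      fmat Xb = Xvf.cols(s, e - 1);
      fmat Yhat = m->forward(as_row(Xb), e - s, false);
      fmat res = Yhat - as_row(fmat(Yvf.cols(s, e - 1)));
      vsse += arma::accu(arma::square(res));
      vcnt += res.n_elem;
    }
    double val_loss = vsse / vcnt;
    if (!std::isfinite(val_loss))
      Rcpp::stop("non-finite validation loss at epoch %d", ep + 1);
    val_hist.push_back(val_loss);
    if (val_loss < best_val) {
      best_val = val_loss;
      best_epoch = ep + 1;
      best_state = m->snapshot();
    }
    Rcpp::checkUserInterrupt();
  }
  if (!best_state.empty()) m->restore(best_state);
  return Rcpp::List::create(
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("lr") = lr_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}

// Loss and analytic parameter gradients for one batch (training-mode
// forward, no optimizer step).  Used by the gradient-correctness tests.
// [[Rcpp::export(name = ".wnet_loss_grad")]]
Rcpp::List wnet_loss_grad_cpp(SEXP ptr, Rcpp::NumericMatrix X,
                              Rcpp::NumericMatrix Y, int seed) {
  Rcpp::XPtr<WNet> m(ptr);
  const int L = X.nrow(), N = X.ncol();
  if (L != m->in_len) Rcpp::stop("input length mismatch");
  m->rng.seed(static_cast<unsigned>(seed));
  fmat Xf = as_fmat(X), Yf = as_fmat(Y);
  fmat Yhat = m->forward(as_row(Xf), N, true);
  fmat res = Yhat - as_row(Yf);
  double l = static_cast<double>(res.n_elem);
  double loss = arma::accu(arma::square(res)) / l;
  m->zero_grads();
  fmat dOut = res * static_cast<float>(2.0 / l);
  m->backward(dOut);
  Rcpp::List grads(m->params.size());
  Rcpp::CharacterVector nm(m->params.size());
  for (size_t i = 0; i < m->params.size(); ++i) {
    const fmat& G = m->params[i]->G;
    Rcpp::NumericVector v(G.n_elem);
    for (size_t j = 0; j < G.n_elem; ++j) v[j] = G[j];
    grads[i] = v;
    nm[i] = m->params[i]->name;
  }
  grads.attr("names") = nm;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// [[Rcpp::export(name = ".wnet_tensors")]]
Rcpp::List wnet_tensors_cpp(SEXP ptr) {
  Rcpp::XPtr<WNet> m(ptr);
  Rcpp::List out(m->params.size());
  Rcpp::CharacterVector nm(m->params.size());
  for (size_t i = 0; i < m->params.size(); ++i) {
    const fmat& W = m->params[i]->W;
    Rcpp::NumericVector v(W.n_elem);
    for (size_t j = 0; j < W.n_elem; ++j) v[j] = W[j];
    out[i] = v;
    nm[i] = m->params[i]->name;
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export(name = ".wnet_get_state")]]
Rcpp::NumericVector wnet_get_state_cpp(SEXP ptr) {
  Rcpp::XPtr<WNet> m(ptr);
  std::vector<fmat> s = m->snapshot();
  size_t n = 0;
  for (auto& f : s) n += f.n_elem;
  Rcpp::NumericVector out(n);
  size_t k = 0;
  for (auto& f : s)
    for (size_t j = 0; j < f.n_elem; ++j) out[k++] = f[j];
  return out;
}

// [[Rcpp::export(name = ".wnet_set_state")]]
void wnet_set_state_cpp(SEXP ptr, Rcpp::NumericVector state) {
  Rcpp::XPtr<WNet> m(ptr);
  std::vector<fmat> s = m->snapshot();  // template for shapes
  size_t n = 0;
  for (auto& f : s) n += f.n_elem;
  if (static_cast<size_t>(state.size()) != n)
    Rcpp::stop("state length %d does not match model (%d)", state.size(), (int)n);
  size_t k = 0;
  for (auto& f : s)
    for (size_t j = 0; j < f.n_elem; ++j) f[j] = static_cast<float>(state[k++]);
  m->restore(s);
}
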