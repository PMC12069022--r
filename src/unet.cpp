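// Tiny 3D U-Net primitives for CPU training at phantom scale.
//
// Tensors are (n_voxels x channels) float matrices; voxel linear order is
// R's column-major array order (first grid axis fastest).  Convolutions are
// 3x3x3, zero-padded, implemented as 27 shifted GEMMs so BLAS does the work
// instead of an im2col buffer (which would not fit memory at 64^3 x 24ch).

#include <RcppArmadillo.h>
#include <cfloat>
#include <cstring>
#include <vector>
#include <queue>

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uword;

struct Dim3 {
  int n1, n2, n3;
  long n() const { return (long)n1 * n2 * n3; }
};

static Dim3 as_dim3(const IntegerVector& dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  Dim3 d;
  d.n1 = dims[0]; d.n2 = dims[1]; d.n3 = dims[2];
  return d;
}

// ---- padded shift machinery -------------------------------------------------

static fmat pad1(const fmat& X, const Dim3& d) {
  const int p1 = d.n1 + 2, p2 = d.n2 + 2, p3 = d.n3 + 2;
  fmat P((long)p1 * p2 * p3, X.n_cols, arma::fill::zeros);
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = P.colptr(c);
    for (int k = 0; k < d.n3; ++k)
      for (int j = 0; j < d.n2; ++j) {
        const float* s = src + (long)d.n1 * (j + (long)d.n2 * k);
        float* t = dst + 1 + (long)p1 * ((j + 1) + (long)p2 * (k + 1));
        std::memcpy(t, s, sizeof(float) * d.n1);
      }
  }
  return P;
}

// S(v, c) = P(v + shift, c); shift 0 extracts the interior (un-pad)
static void gather(const fmat& P, const Dim3& d, int s1, int s2, int s3, fmat& S) {
  const int p1 = d.n1 + 2, p2 = d.n2 + 2;
  for (uword c = 0; c < P.n_cols; ++c) {
    const float* src = P.colptr(c);
    float* dst = S.colptr(c);
    for (int k = 0; k < d.n3; ++k)
      for (int j = 0; j < d.n2; ++j) {
        const float* s = src + (1 + s1) + (long)p1 * ((j + 1 + s2) + (long)p2 * (k + 1 + s3));
        float* t = dst + (long)d.n1 * (j + (long)d.n2 * k);
        std::memcpy(t, s, sizeof(float) * d.n1);
      }
  }
}

// ---- conv 3x3x3 -------------------------------------------------------------

// W is (27*Cin x Cout); row index = offset + 27*cin, offset = o1 + 3*o2 + 9*o3
// with shifts o-1 in {-1,0,1} per axis (cross-correlation convention).
static fmat conv3_fwd(const fmat& X, const Dim3& d, const fmat& W, const frowvec& b) {
  const int Cin = X.n_cols, Cout = W.n_cols;
  fmat P = pad1(X, d);
  fmat Y(d.n(), Cout, arma::fill::zeros);
  fmat S(d.n(), Cin);
  fmat Wo(Cin, Cout);
  for (int off = 0; off < 27; ++off) {
    const int s1 = off % 3 - 1, s2 = (off / 3) % 3 - 1, s3 = off / 9 - 1;
    gather(P, d, s1, s2, s3, S);
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co) Wo(ci, co) = W(off + 27 * ci, co);
    Y += S * Wo;
  }
  Y.each_row() += b;
  return Y;
}

// dX(v) = sum_o dY(v - o) W_o^T, expressed as gathers from padded dY so the
// reduction runs inside GEMM instead of an elementwise scatter loop.
static fmat conv3_bwd(const fmat& X, const Dim3& d, const fmat& W, const fmat& dY,
                      fmat& dW, frowvec& db, bool need_dx = true) {
  const int Cin = X.n_cols, Cout = W.n_cols;
  fmat P = pad1(X, d);
  fmat dYp;
  if (need_dx) dYp = pad1(dY, d);
  fmat S(d.n(), Cin);
  fmat Sdy;
  if (need_dx) Sdy.set_size(d.n(), Cout);
  fmat Wo(Cin, Cout);
  fmat dX;
  if (need_dx) dX.zeros(d.n(), Cin);
  dW.zeros(27 * Cin, Cout);
  db = arma::sum(dY, 0);
  for (int off = 0; off < 27; ++off) {
    const int s1 = off % 3 - 1, s2 = (off / 3) % 3 - 1, s3 = off / 9 - 1;
    gather(P, d, s1, s2, s3, S);
    fmat dWo = S.t() * dY;
    for (int ci = 0; ci < Cin; ++ci)
      for (int co = 0; co < Cout; ++co) {
        dW(off + 27 * ci, co) = dWo(ci, co);
        Wo(ci, co) = W(off + 27 * ci, co);
      }
    if (need_dx) {
      gather(dYp, d, -s1, -s2, -s3, Sdy);
      dX += Sdy * Wo.t();
    }
  }
  return dX;
}

// ---- pooling / upsampling ---------------------------------------------------

static fmat maxpool2(const fmat& X, const Dim3& d, Dim3& dout, arma::umat& idx) {
  dout.n1 = d.n1 / 2; dout.n2 = d.n2 / 2; dout.n3 = d.n3 / 2;
  idx.set_size(dout.n(), X.n_cols);
  fmat Y(dout.n(), X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    uword* id = idx.colptr(c);
    long vo = 0;
    for (int k = 0; k < dout.n3; ++k)
      for (int j = 0; j < dout.n2; ++j)
        for (int i = 0; i < dout.n1; ++i, ++vo) {
          float best = -FLT_MAX;
          long bi = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const long v = (2 * i + di) +
                  (long)d.n1 * ((2 * j + dj) + (long)d.n2 * (2 * k + dk));
                if (src[v] > best) { best = src[v]; bi = v; }
              }
          dst[vo] = best;
          id[vo] = (uword)bi;
        }
  }
  return Y;
}

static fmat maxpool2_bwd(const fmat& dY, const arma::umat& idx, long nin) {
  fmat dX(nin, dY.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    float* dx = dX.colptr(c);
    const float* dy = dY.colptr(c);
    const uword* id = idx.colptr(c);
    for (long v = 0; v < (long)dY.n_rows; ++v) dx[id[v]] += dy[v];
  }
  return dX;
}

static fmat up2(const fmat& X, const Dim3& d, Dim3& dout) {
  dout.n1 = 2 * d.n1; dout.n2 = 2 * d.n2; dout.n3 = 2 * d.n3;
  fmat Y(dout.n(), X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = Y.colptr(c);
    long vo = 0;
    for (int k = 0; k < dout.n3; ++k)
      for (int j = 0; j < dout.n2; ++j)
        for (int i = 0; i < dout.n1; ++i, ++vo)
          dst[vo] = src[(i / 2) + (long)d.n1 * ((j / 2) + (long)d.n2 * (k / 2))];
  }
  return Y;
}

static fmat up2_bwd(const fmat& dY, const Dim3& dout, const Dim3& din) {
  fmat dX(din.n(), dY.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const float* dy = dY.colptr(c);
    float* dx = dX.colptr(c);
    long vo = 0;
    for (int k = 0; k < dout.n3; ++k)
      for (int j = 0; j < dout.n2; ++j)
        for (int i = 0; i < dout.n1; ++i, ++vo)
          dx[(i / 2) + (long)din.n1 * ((j / 2) + (long)din.n2 * (k / 2))] += dy[vo];
  }
  return dX;
}

// ---- parameter plumbing -----------------------------------------------------

static fmat get_W(const List& params, const std::string& name) {
  NumericVector a = params[name];
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 5) stop("weight %s must be a 5-d array", name.c_str());
  const int Cin = dm[3], Cout = dm[4];
  fmat W(27 * Cin, Cout);
  const double* p = a.begin();
  const long n = 27L * Cin * Cout;
  for (long t = 0; t < n; ++t) W.memptr()[t] = (float)p[t];
  return W;
}

static frowvec get_b(const List& params, const std::string& name) {
  NumericVector a = params[name];
  frowvec b(a.size());
  for (int i = 0; i < a.size(); ++i) b[i] = (float)a[i];
  return b;
}

static NumericVector W_to_r(const fmat& dW, int Cin, int Cout) {
  NumericVector out(27L * Cin * Cout);
  for (long t = 0; t < (long)dW.n_elem; ++t) out[t] = dW.memptr()[t];
  out.attr("dim") = IntegerVector::create(3, 3, 3, Cin, Cout);
  return out;
}

static NumericVector b_to_r(const frowvec& db) {
  NumericVector out(db.n_elem);
  for (uword i = 0; i < db.n_elem; ++i) out[i] = db[i];
  return out;
}

static fmat relu(const fmat& X) { return arma::clamp(X, 0.0f, FLT_MAX); }

// zero dY where the stored post-activation was zero
static fmat relu_bwd(const fmat& dY, const fmat& act) {
  fmat out = dY;
  out.elem(arma::find(act <= 0.0f)).zeros();
  return out;
}

// ---- U-Net forward/backward -------------------------------------------------
//
// Each block conv is 3x3x3 conv -> instance norm (learned gamma/beta) ->
// ReLU.  Instance normalization is what makes a tiny U-Net converge in the
// few hundred optimizer steps a CPU budget allows, and removes per-sample
// intensity-scale effects (residual bias field) that a raw conv stack is
// slow to learn away.

struct ConvCache {
  fmat in;        // conv input
  fmat xhat;      // normalized pre-activation
  frowvec sd;     // per-channel sqrt(var + eps)
  fmat a;         // post-ReLU activation
};

struct UNetCache {
  std::vector<ConvCache> enc1, enc2;   // per level
  std::vector<Dim3> enc_dim;
  std::vector<arma::umat> pool_idx;
  ConvCache bott1, bott2;
  Dim3 bott_dim;
  std::vector<ConvCache> dec1, dec2;   // indexed by level (0 = finest)
  fmat out_in;
  fmat p;
};

static const float IN_EPS = 1e-5f;

// conv -> instance norm -> relu
static fmat conv_in_relu(const List& params, const std::string& name,
                         const fmat& X, const Dim3& d, ConvCache* C) {
  fmat Z = conv3_fwd(X, d, get_W(params, name + "_W"), get_b(params, name + "_b"));
  frowvec mu = arma::mean(Z, 0);
  frowvec sd = arma::sqrt(arma::var(Z, 1, 0) + IN_EPS);
  Z.each_row() -= mu;
  Z.each_row() /= sd;
  fmat xhat = Z;                       // keep normalized copy
  frowvec g = get_b(params, name + "_g");
  frowvec n = get_b(params, name + "_n");
  Z.each_row() %= g;
  Z.each_row() += n;
  fmat A = relu(Z);
  if (C) { C->in = X; C->xhat = xhat; C->sd = sd; C->a = A; }
  return A;
}

// backward through relu -> instance norm -> conv; fills grads, returns dX
static fmat conv_in_relu_bwd(const List& params, const std::string& name,
                             const ConvCache& C, const Dim3& d, const fmat& dA,
                             List& grads, bool need_dx) {
  fmat dY = relu_bwd(dA, C.a);
  frowvec g = get_b(params, name + "_g");
  frowvec dn = arma::sum(dY, 0);
  frowvec dg = arma::sum(dY % C.xhat, 0);
  fmat dxhat = dY;
  dxhat.each_row() %= g;
  const float n_vox = (float)C.xhat.n_rows;
  frowvec m1 = arma::sum(dxhat, 0) / n_vox;
  frowvec m2 = arma::sum(dxhat % C.xhat, 0) / n_vox;
  fmat dZ = dxhat;
  dZ.each_row() -= m1;
  dZ -= C.xhat.each_row() % m2;
  dZ.each_row() /= C.sd;
  fmat dW; frowvec db;
  fmat dX = conv3_bwd(C.in, d, get_W(params, name + "_W"), dZ, dW, db, need_dx);
  const int Cin = C.in.n_cols, Cout = C.a.n_cols;
  grads[name + "_W"] = W_to_r(dW, Cin, Cout);
  grads[name + "_b"] = b_to_r(db);
  grads[name + "_g"] = b_to_r(dg);
  grads[name + "_n"] = b_to_r(dn);
  return dX;
}

static fmat unet_forward(const List& params, const fmat& x0, const Dim3& d0,
                         int depth, UNetCache* C) {
  fmat x = x0;
  Dim3 d = d0;
  std::vector<fmat> skip(depth);
  std::vector<Dim3> sdim(depth);
  if (C) {
    C->enc1.resize(depth); C->enc2.resize(depth);
    C->enc_dim.resize(depth); C->pool_idx.resize(depth);
    C->dec1.resize(depth); C->dec2.resize(depth);
  }
  for (int l = 0; l < depth; ++l) {
    if (d.n1 % 2 || d.n2 % 2 || d.n3 % 2)
      stop("grid not divisible by 2^depth");
    const std::string pre = "enc" + std::to_string(l);
    fmat a1 = conv_in_relu(params, pre + "_c1", x, d, C ? &C->enc1[l] : nullptr);
    fmat a2 = conv_in_relu(params, pre + "_c2", a1, d, C ? &C->enc2[l] : nullptr);
    if (C) C->enc_dim[l] = d;
    skip[l] = a2;
    sdim[l] = d;
    Dim3 dn;
    arma::umat idx;
    x = maxpool2(a2, d, dn, idx);
    if (C) C->pool_idx[l] = idx;
    d = dn;
  }
  {
    fmat a1 = conv_in_relu(params, "bott_c1", x, d, C ? &C->bott1 : nullptr);
    fmat a2 = conv_in_relu(params, "bott_c2", a1, d, C ? &C->bott2 : nullptr);
    if (C) C->bott_dim = d;
    x = a2;
  }
  for (int l = depth - 1; l >= 0; --l) {
    Dim3 du;
    fmat xu = up2(x, d, du);
    d = sdim[l];
    fmat xc = arma::join_rows(xu, skip[l]);
    const std::string pre = "dec" + std::to_string(l);
    fmat a1 = conv_in_relu(params, pre + "_c1", xc, d, C ? &C->dec1[l] : nullptr);
    fmat a2 = conv_in_relu(params, pre + "_c2", a1, d, C ? &C->dec2[l] : nullptr);
    x = a2;
  }
  // 1x1x1 output conv + sigmoid
  NumericVector wr = params["out_W"];
  fmat Wout(wr.size(), 1);
  for (int i = 0; i < wr.size(); ++i) Wout(i, 0) = (float)wr[i];
  const float bout = (float)as<double>(params["out_b"]);
  if (C) C->out_in = x;
  fmat logits = x * Wout;
  logits += bout;
  fmat p = 1.0f / (1.0f + arma::exp(-logits));
  if (C) C->p = p;
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(List params, NumericVector x, IntegerVector dims, int depth) {
  Dim3 d = as_dim3(dims);
  fmat x0(d.n(), 1);
  for (long i = 0; i < d.n(); ++i) x0(i, 0) = (float)x[i];
  fmat p = unet_forward(params, x0, d, depth, nullptr);
  NumericVector out(d.n());
  for (long i = 0; i < d.n(); ++i) out[i] = p(i, 0);
  out.attr("dim") = dims;
  return out;
}

// Soft-Dice + weighted-BCE loss and full gradient.
// [[Rcpp::export]]
List cpp_unet_grad(List params, NumericVector x, IntegerVector dims, NumericVector y,
                   int depth, double pos_weight = -1.0, double bce_scale = 1.0,
                   int dice_denom = 1) {
  Dim3 d0 = as_dim3(dims);
  const long n = d0.n();
  if (y.size() != n) stop("target size mismatch");
  fmat x0(n, 1), yv(n, 1);
  for (long i = 0; i < n; ++i) { x0(i, 0) = (float)x[i]; yv(i, 0) = (float)y[i]; }

  UNetCache C;
  unet_forward(params, x0, d0, depth, &C);
  const fmat& p = C.p;

  // soft-Dice (linear or squared denominator)
  const double eps = 1.0;
  double num = 2.0 * arma::dot(p, yv) + eps;
  double den = (dice_denom == 2)
    ? (double)(arma::dot(p, p) + arma::dot(yv, yv)) + eps
    : (double)(arma::accu(p) + arma::accu(yv)) + eps;
  const double dice_loss = 1.0 - num / den;
  // positive-class-weighted BCE (see R docs): without a foreground weight
  // the ~0.3% foreground is drowned by the background term early on
  const double sy = arma::accu(yv);
  const float w = (pos_weight > 0) ? (float)pos_weight
                                   : (float)((n - sy) / std::max(sy, 1.0));
  fmat pc = arma::clamp(p, 1e-7f, 1.0f - 1e-7f);
  const double bce = -bce_scale * arma::accu(w * (yv % arma::log(pc)) +
                                 (1.0f - yv) % arma::log(1.0f - pc)) / n;
  if (!std::isfinite(dice_loss) || !std::isfinite(bce)) {
    return List::create(_["loss"] = NA_REAL, _["dice"] = dice_loss, _["bce"] = bce,
                        _["grads"] = R_NilValue);
  }

  fmat ddice_dp;
  if (dice_denom == 2)
    ddice_dp = 2.0f * (float)(num / (den * den)) * p - 2.0f * yv / (float)den;
  else
    ddice_dp = (float)(num / (den * den)) - 2.0f * yv / (float)den;
  fmat dlogit = (float)bce_scale *
    ((1.0f - yv) % p - w * (yv % (1.0f - p))) / (float)n +
    ddice_dp % (p % (1.0f - p));

  List grads;
  // output conv
  NumericVector wr = params["out_W"];
  fmat Wout(wr.size(), 1);
  for (int i = 0; i < wr.size(); ++i) Wout(i, 0) = (float)wr[i];
  fmat dWout = C.out_in.t() * dlogit;
  NumericVector dWout_r(dWout.n_rows);
  for (uword i = 0; i < dWout.n_rows; ++i) dWout_r[i] = dWout(i, 0);
  grads["out_W"] = dWout_r;
  grads["out_b"] = (double)arma::accu(dlogit);
  fmat dx = dlogit * Wout.t();

  // decoder (backwards: finest level first)
  std::vector<fmat> dskip(depth);
  Dim3 d;
  for (int l = 0; l < depth; ++l) {
    const std::string pre = "dec" + std::to_string(l);
    d = C.enc_dim[l];
    fmat da1 = conv_in_relu_bwd(params, pre + "_c2", C.dec2[l], d, dx, grads, true);
    fmat dc = conv_in_relu_bwd(params, pre + "_c1", C.dec1[l], d, da1, grads, true);
    const int cup = C.dec1[l].in.n_cols - C.enc2[l].a.n_cols;
    fmat dxu = dc.cols(0, cup - 1);
    dskip[l] = dc.cols(cup, dc.n_cols - 1);
    Dim3 dlo;
    dlo.n1 = d.n1 / 2; dlo.n2 = d.n2 / 2; dlo.n3 = d.n3 / 2;
    dx = up2_bwd(dxu, d, dlo);
  }

  // bottleneck
  {
    fmat da1 = conv_in_relu_bwd(params, "bott_c2", C.bott2, C.bott_dim, dx, grads, true);
    dx = conv_in_relu_bwd(params, "bott_c1", C.bott1, C.bott_dim, da1, grads, true);
  }

  // encoder levels, deepest first
  for (int l = depth - 1; l >= 0; --l) {
    const std::string pre = "enc" + std::to_string(l);
    d = C.enc_dim[l];
    fmat da2 = maxpool2_bwd(dx, C.pool_idx[l], d.n());
    da2 += dskip[l];
    fmat da1 = conv_in_relu_bwd(params, pre + "_c2", C.enc2[l], d, da2, grads, true);
    dx = conv_in_relu_bwd(params, pre + "_c1", C.enc1[l], d, da1, grads, l > 0);
  }

  return List::create(_["loss"] = dice_loss + bce, _["dice"] = dice_loss,
                      _["bce"] = bce, _["grads"] = grads);
}

// ---- small 3-D image utilities ---------------------------------------------

// 6-connected component labelling; 0 = background, components numbered from 1
// in decreasing voxel-count order.
// [[Rcpp::export]]
IntegerVector cpp_label3(IntegerVector mask, IntegerVector dims) {
  Dim3 d = as_dim3(dims);
  const long n = d.n();
  if (mask.size() != n) stop("mask size mismatch");
  IntegerVector lab(n, 0);
  std::vector<long> stack;
  std::vector<long> sizes;
  int next = 0;
  for (long v0 = 0; v0 < n; ++v0) {
    if (mask[v0] == 0 || lab[v0] != 0) continue;
    ++next;
    long sz = 0;
    stack.push_back(v0);
    lab[v0] = next;
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      ++sz;
      const int i = v % d.n1;
      const long r = v / d.n1;
      const int j = r % d.n2;
      const int k = r / d.n2;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
        const long w = ii + (long)d.n1 * (jj + (long)d.n2 * kk);
        if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> ord(next);
  for (int i = 0; i < next; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> newlab(next + 1, 0);
  for (int r = 0; r < next; ++r) newlab[ord[r] + 1] = r + 1;
  for (long v = 0; v < n; ++v) if (lab[v]) lab[v] = newlab[lab[v]];
  lab.attr("dim") = dims;
  return lab;
}

// Separable Gaussian smoothing, truncated at 3 sigma, border-renormalized
// so constants are preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector x, IntegerVector dims, double sigma) {
  Dim3 d = as_dim3(dims);
  const long n = d.n();
  if (x.size() != n) stop("size mismatch");
  if (sigma <= 0) { NumericVector out = clone(x); out.attr("dim") = dims; return out; }
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; ++t) ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  std::vector<double> a(x.begin(), x.end()), b(n);
  const int nn[3] = {d.n1, d.n2, d.n3};
  const long str[3] = {1, (long)d.n1, (long)d.n1 * d.n2};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = nn[ax];
    const long s = str[ax];
    const long nlines = n / len;
    for (long line = 0; line < nlines; ++line) {
      // base index of this line
      long rem = line, base = 0;
      for (int o = 0; o < 3; ++o) {
        if (o == ax) continue;
        const long idx = rem % nn[o];
        rem /= nn[o];
        base += idx * str[o];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0, wsum = 0;
        const int lo = std::max(-r, -i), hi = std::min(r, len - 1 - i);
        for (int t = lo; t <= hi; ++t) {
          acc += ker[t + r] * a[base + (long)(i + t) * s];
          wsum += ker[t + r];
        }
        b[base + (long)i * s] = acc / wsum;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Euclidean ball dilation of a binary mask.
// [[Rcpp::export]]
IntegerVector cpp_dilate3(IntegerVector mask, IntegerVector dims, int radius) {
  Dim3 d = as_dim3(dims);
  const long n = d.n();
  if (mask.size() != n) stop("size mismatch");
  std::vector<std::array<int, 3>> offs;
  for (int dk = -radius; dk <= radius; ++dk)
    for (int dj = -radius; dj <= radius; ++dj)
      for (int di = -radius; di <= radius; ++di)
        if (di * di + dj * dj + dk * dk <= radius * radius)
          offs.push_back({di, dj, dk});
  IntegerVector out(n, 0);
  for (long v = 0; v < n; ++v) {
    if (mask[v] == 0) continue;
    const int i = v % d.n1;
    const long r2 = v / d.n1;
    const int j = r2 % d.n2;
    const int k = r2 / d.n2;
    for (const auto& o : offs) {
      const int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d.n1 || jj >= d.n2 || kk >= d.n3) continue;
      out[ii + (long)d.n1 * (jj + (long)d.n2 * kk)] = 1;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Block mean / block max downsampling by integer factor (dims divisible).
// [[Rcpp::export]]
NumericVector cpp_downsample_mean(NumericVector x, IntegerVector dims, int f) {
  Dim3 d = as_dim3(dims);
  if (d.n1 % f || d.n2 % f || d.n3 % f) stop("dims not divisible by factor");
  Dim3 o = {d.n1 / f, d.n2 / f, d.n3 / f};
  NumericVector out(o.n());
  const double inv = 1.0 / ((double)f * f * f);
  for (int k = 0; k < o.n3; ++k)
    for (int j = 0; j < o.n2; ++j)
      for (int i = 0; i < o.n1; ++i) {
        double acc = 0;
        for (int dk = 0; dk < f; ++dk)
          for (int dj = 0; dj < f; ++dj)
            for (int di = 0; di < f; ++di)
              acc += x[(f * i + di) + (long)d.n1 * ((f * j + dj) + (long)d.n2 * (f * k + dk))];
        out[i + (long)o.n1 * (j + (long)o.n2 * k)] = acc * inv;
      }
  out.attr("dim") = IntegerVector::create(o.n1, o.n2, o.n3);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_downsample_max(IntegerVector x, IntegerVector dims, int f) {
  Dim3 d = as_dim3(dims);
  if (d.n1 % f || d.n2 % f || d.n3 % f) stop("dims not divisible by factor");
  Dim3 o = {d.n1 / f, d.n2 / f, d.n3 / f};
  IntegerVector out(o.n());
  for (int k = 0; k < o.n3; ++k)
    for (int j = 0; j < o.n2; ++j)
      for (int i = 0; i < o.n1; ++i) {
        int m = 0;
        for (int dk = 0; dk < f && !m; ++dk)
          for (int dj = 0; dj < f && !m; ++dj)
            for (int di = 0; di < f; ++di)
              if (x[(f * i + di) + (long)d.n1 * ((f * j + dj) + (long)d.n2 * (f * k + dk))]) {
                m = 1; break;
              }
        out[i + (long)o.n1 * (j + (long)o.n2 * k)] = m;
      }
  out.attr("dim") = IntegerVector::create(o.n1, o.n2, o.n3);
  return out;
}
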