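// Convolutional engine for the leaf tracer, vein grower and U-Net baseline.
//
// Activations are stored as (C x H*W*B) matrices: each column is the channel
// vector of one pixel, columns grouped per sample, spatial index p = r + c*H
// (column-major, matching R matrices). Blocks follow the shared encoder
// design: three zero-padded 3x3 convolutions with batch normalization and
// LeakyReLU, a residual connection from the first activation to the third
// pre-activation, and 2x2 max pooling between blocks. The U-Net decoder
// mirrors the encoder with 2x2 transposed convolutions and concatenated
// skip connections. Training uses Adam with early stopping on a held-out
// validation split.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
// The engine runs in single precision: the networks are small, the task is
// classification/regression at pixel scale, and fp32 roughly doubles GEMM
// and memory throughput on one CPU core.
using mat = arma::fmat;
using vec = arma::fvec;
using arma::umat;

static const double LRELU_SLOPE = 0.1;
static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;
static const double P_CLAMP = 1e-7;

// ---------------------------------------------------------------------------
// basic ops

// im2col for 3x3 zero-padded convolution. A: (C, HW*B) -> P: (9C, HW*B).
// The (dr, dc) shift is a contiguous column shift of dc*H + dr within each
// sample, so each kernel offset is one big block copy per sample followed by
// zeroing the rows that crossed the vertical image edge.
static void im2col3(const mat& A, int H, int W, int B, mat& P) {
  const int C = A.n_rows, HW = H * W;
  P.set_size(9 * C, (size_t)HW * B);
  for (int q = 0; q < 9; ++q) {
    const int dr = q % 3 - 1, dc = q / 3 - 1;
    const int s = dc * H + dr;  // column shift inside a sample
    const int dst_lo = std::max(0, -s), dst_hi = std::min(HW, HW - s);
    const int r_lo = std::max(0, -dr), r_hi = std::min(H, H - dr);
    for (int b = 0; b < B; ++b) {
      size_t base = (size_t)b * HW;
      // edge columns outside the horizontal shift range
      if (dst_lo > 0)
        P.submat(q * C, base, q * C + C - 1, base + dst_lo - 1).zeros();
      if (dst_hi < HW)
        P.submat(q * C, base + dst_hi, q * C + C - 1, base + HW - 1).zeros();
      if (dst_hi > dst_lo) {
        P.submat(q * C, base + dst_lo, q * C + C - 1, base + dst_hi - 1) =
            A.cols(base + dst_lo + s, base + dst_hi + s - 1);
      }
      // zero rows that wrapped across the vertical edge
      if (dr != 0) {
        for (int c = 0; c < W; ++c) {
          size_t col0 = base + (size_t)c * H;
          if (r_lo > 0) {
            size_t a0 = std::max(col0, base + (size_t)dst_lo);
            size_t a1 = std::min(col0 + r_lo, base + (size_t)dst_hi);
            if (a1 > a0)
              P.submat(q * C, a0, q * C + C - 1, a1 - 1).zeros();
          }
          if (r_hi < H) {
            size_t a0 = std::max(col0 + r_hi, base + (size_t)dst_lo);
            size_t a1 = std::min(col0 + H, base + (size_t)dst_hi);
            if (a1 > a0)
              P.submat(q * C, a0, q * C + C - 1, a1 - 1).zeros();
          }
        }
      }
    }
  }
}

// col2im: accumulate dP (9C, HW*B) back into dA (C, HW*B). Invalid entries
// of dP (those reading zero padding) are zeroed first so the accumulation
// can run as one shifted block add per kernel offset and sample.
static void col2im3(mat& dP, int H, int W, int B, mat& dA) {
  const int C = dA.n_rows, HW = H * W;
  for (int q = 0; q < 9; ++q) {
    const int dr = q % 3 - 1, dc = q / 3 - 1;
    const int s = dc * H + dr;
    const int dst_lo = std::max(0, -s), dst_hi = std::min(HW, HW - s);
    const int r_lo = std::max(0, -dr), r_hi = std::min(H, H - dr);
    for (int b = 0; b < B; ++b) {
      size_t base = (size_t)b * HW;
      if (dst_lo > 0)
        dP.submat(q * C, base, q * C + C - 1, base + dst_lo - 1).zeros();
      if (dst_hi < HW)
        dP.submat(q * C, base + dst_hi, q * C + C - 1, base + HW - 1).zeros();
      if (dr != 0) {
        for (int c = 0; c < W; ++c) {
          size_t col0 = base + (size_t)c * H;
          if (r_lo > 0) {
            size_t a0 = std::max(col0, base + (size_t)dst_lo);
            size_t a1 = std::min(col0 + r_lo, base + (size_t)dst_hi);
            if (a1 > a0)
              dP.submat(q * C, a0, q * C + C - 1, a1 - 1).zeros();
          }
          if (r_hi < H) {
            size_t a0 = std::max(col0 + r_hi, base + (size_t)dst_lo);
            size_t a1 = std::min(col0 + H, base + (size_t)dst_hi);
            if (a1 > a0)
              dP.submat(q * C, a0, q * C + C - 1, a1 - 1).zeros();
          }
        }
      }
      if (dst_hi > dst_lo) {
        dA.cols(base + dst_lo + s, base + dst_hi + s - 1) +=
            dP.submat(q * C, base + dst_lo, q * C + C - 1, base + dst_hi - 1);
      }
    }
  }
}

struct BNCache { mat xhat; vec istd; };

// Batch norm across all columns, per channel row.
static mat bn_forward(const mat& X, const vec& gamma, const vec& beta,
                      vec& rmean, vec& rvar, bool train, BNCache& cache) {
  const int C = X.n_rows;
  const double M = (double)X.n_cols;
  mat Y(X.n_rows, X.n_cols);
  if (train) {
    vec mu = arma::mean(X, 1);
    vec va(C);
    for (int r = 0; r < C; ++r) {
      const arma::frowvec d = X.row(r) - mu(r);
      va(r) = arma::dot(d, d) / M;
    }
    cache.istd = 1.0 / arma::sqrt(va + BN_EPS);
    cache.xhat.set_size(X.n_rows, X.n_cols);
    for (int r = 0; r < C; ++r) {
      cache.xhat.row(r) = (X.row(r) - mu(r)) * cache.istd(r);
      Y.row(r) = gamma(r) * cache.xhat.row(r) + beta(r);
    }
    rmean = (1.0 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu;
    rvar = (1.0 - BN_MOMENTUM) * rvar + BN_MOMENTUM * va;
  } else {
    for (int r = 0; r < C; ++r) {
      double istd = 1.0 / std::sqrt(rvar(r) + BN_EPS);
      Y.row(r) = gamma(r) * (X.row(r) - rmean(r)) * istd + beta(r);
    }
  }
  return Y;
}

static mat bn_backward(const mat& dY, const vec& gamma, const BNCache& cache,
                       vec& dgamma, vec& dbeta) {
  const int C = dY.n_rows;
  const double M = (double)dY.n_cols;
  mat dX(dY.n_rows, dY.n_cols);
  dgamma.set_size(C); dbeta.set_size(C);
  for (int r = 0; r < C; ++r) {
    dgamma(r) = arma::dot(dY.row(r), cache.xhat.row(r));
    dbeta(r) = arma::accu(dY.row(r));
    dX.row(r) = (gamma(r) * cache.istd(r) / M) *
                (M * dY.row(r) - dbeta(r) - cache.xhat.row(r) * dgamma(r));
  }
  return dX;
}

static mat lrelu(const mat& Z) {
  mat A = Z;
  A.transform([](double v) { return v > 0 ? v : LRELU_SLOPE * v; });
  return A;
}

static mat lrelu_back(const mat& dA, const mat& Z) {
  mat dZ = dA;
  const float* z = Z.memptr();
  float* d = dZ.memptr();
  for (size_t i = 0; i < Z.n_elem; ++i)
    if (z[i] <= 0) d[i] *= LRELU_SLOPE;
  return dZ;
}

// 2x2 max pooling; argmax stores the source column index per (row, out col).
static mat pool_forward(const mat& A, int H, int W, int B, umat& arg) {
  const int C = A.n_rows, Ho = H / 2, Wo = W / 2;
  const int HW = H * W, HWo = Ho * Wo;
  mat Y(C, (size_t)HWo * B);
  arg.set_size(C, (size_t)HWo * B);
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        size_t oc = (size_t)b * HWo + (size_t)co * Ho + ro;
        size_t s[4];
        s[0] = (size_t)b * HW + (size_t)(2 * co) * H + 2 * ro;
        s[1] = s[0] + 1;
        s[2] = s[0] + H;
        s[3] = s[2] + 1;
        for (int r = 0; r < C; ++r) {
          double best = A(r, s[0]); size_t bi = s[0];
          for (int k = 1; k < 4; ++k)
            if (A(r, s[k]) > best) { best = A(r, s[k]); bi = s[k]; }
          Y(r, oc) = best;
          arg(r, oc) = bi;
        }
      }
    }
  }
  return Y;
}

static mat pool_backward(const mat& dY, const umat& arg, int C, size_t in_cols) {
  mat dA(C, in_cols, arma::fill::zeros);
  for (size_t oc = 0; oc < dY.n_cols; ++oc)
    for (int r = 0; r < C; ++r)
      dA(r, arg(r, oc)) += dY(r, oc);
  return dA;
}

// ---------------------------------------------------------------------------
// parameter bookkeeping

struct Params {
  std::vector<mat> W;   // weights/biases in architecture order
  std::vector<vec> rmean, rvar;  // BN running stats in BN order
};

static Params params_from_r(const List& p, const List& run) {
  Params out;
  for (R_xlen_t i = 0; i < p.size(); ++i)
    out.W.push_back(as<mat>(p[i]));
  List rm = run["mean"], rv = run["var"];
  for (R_xlen_t i = 0; i < rm.size(); ++i) {
    out.rmean.push_back(as<vec>(rm[i]));
    out.rvar.push_back(as<vec>(rv[i]));
  }
  return out;
}

static List params_to_r(const Params& p) {
  List w(p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i) w[i] = p.W[i];
  List rm(p.rmean.size()), rv(p.rvar.size());
  for (size_t i = 0; i < p.rmean.size(); ++i) { rm[i] = p.rmean[i]; rv[i] = p.rvar[i]; }
  return List::create(_["params"] = w,
                      _["running"] = List::create(_["mean"] = rm, _["var"] = rv));
}

struct Arch {
  std::string type;   // "encoder" or "unet"
  int in_ch, tile, out_dim;
  std::string head;   // "linear", "softmax9", "sigmoid_map"
  std::vector<int> widths;
};

static Arch arch_from_r(const List& a) {
  Arch out;
  out.type = as<std::string>(a["type"]);
  out.in_ch = as<int>(a["in_ch"]);
  out.tile = as<int>(a["tile"]);
  out.out_dim = a.containsElementNamed("out_dim") ? as<int>(a["out_dim"]) : 1;
  out.head = as<std::string>(a["head"]);
  IntegerVector w = a["widths"];
  for (int i = 0; i < w.size(); ++i) out.widths.push_back(w[i]);
  return out;
}

// caches for one forward pass
struct BlockCache {
  mat x0, yA, a1, yB, a2, s;  // stored activations
  BNCache bnA, bnB, bnC;
  umat poolArg;
  int H, W;          // input spatial dims of the block
  bool pooled;
};

struct NetCache {
  std::vector<BlockCache> blocks;        // encoder blocks (and unet decoder blocks appended)
  std::vector<mat> skips;                // unet: pre-pool activations
  std::vector<mat> dec_in;               // unet: tconv inputs, concat halves
  mat fc_in;                             // encoder: flattened input to fc
  mat out_pre;                           // pre-head outputs (logits)
  int B;
};

// one encoder-style block. pi = index of first param; bi = index of first BN.
// Advances pi by 12 and bi by 3.
static mat block_forward(const Params& P, std::vector<vec>& rmean, std::vector<vec>& rvar,
                         const mat& X, int H, int W, int B, bool train,
                         bool pool, int& pi, int& bi, BlockCache& cb) {
  cb.H = H; cb.W = W; cb.pooled = pool;
  cb.x0 = X;
  mat Pcol;
  im2col3(X, H, W, B, Pcol);
  mat zA = P.W[pi] * Pcol; zA.each_col() += vec(P.W[pi + 1].col(0));
  cb.yA = bn_forward(zA, vec(P.W[pi + 2].col(0)), vec(P.W[pi + 3].col(0)),
                     rmean[bi], rvar[bi], train, cb.bnA);
  cb.a1 = lrelu(cb.yA);
  im2col3(cb.a1, H, W, B, Pcol);
  mat zB = P.W[pi + 4] * Pcol; zB.each_col() += vec(P.W[pi + 5].col(0));
  cb.yB = bn_forward(zB, vec(P.W[pi + 6].col(0)), vec(P.W[pi + 7].col(0)),
                     rmean[bi + 1], rvar[bi + 1], train, cb.bnB);
  cb.a2 = lrelu(cb.yB);
  im2col3(cb.a2, H, W, B, Pcol);
  mat zC = P.W[pi + 8] * Pcol; zC.each_col() += vec(P.W[pi + 9].col(0));
  mat yC = bn_forward(zC, vec(P.W[pi + 10].col(0)), vec(P.W[pi + 11].col(0)),
                      rmean[bi + 2], rvar[bi + 2], train, cb.bnC);
  cb.s = yC + cb.a1;  // residual within block
  mat a3 = lrelu(cb.s);
  pi += 12; bi += 3;
  if (pool) return pool_forward(a3, H, W, B, cb.poolArg);
  return a3;
}

// backward through one block. pi/bi point at the block's first param on entry
// (call with the same indices used in forward). Returns gradient wrt block input.
static mat block_backward(const Params& P, const BlockCache& cb, const mat& dOut_in,
                          int B, int pi, std::vector<mat>& G) {
  const int H = cb.H, W = cb.W;
  const int C = P.W[pi].n_rows;  // block width
  mat dA3;
  if (cb.pooled) {
    dA3 = pool_backward(dOut_in, cb.poolArg, C, (size_t)H * W * B);
  } else {
    dA3 = dOut_in;
  }
  mat dS = lrelu_back(dA3, cb.s);
  // conv C
  vec dg, db;
  mat dzC = bn_backward(dS, vec(P.W[pi + 10].col(0)), cb.bnC, dg, db);
  G[pi + 10] += mat(dg); G[pi + 11] += mat(db);
  mat Pcol;
  im2col3(cb.a2, H, W, B, Pcol);
  G[pi + 8] += dzC * Pcol.t();
  G[pi + 9] += mat(arma::sum(dzC, 1));
  mat dPcol = P.W[pi + 8].t() * dzC;
  mat dA2(C, dS.n_cols, arma::fill::zeros);
  col2im3(dPcol, H, W, B, dA2);
  // conv B
  mat dyB = lrelu_back(dA2, cb.yB);
  mat dzB = bn_backward(dyB, vec(P.W[pi + 6].col(0)), cb.bnB, dg, db);
  G[pi + 6] += mat(dg); G[pi + 7] += mat(db);
  im2col3(cb.a1, H, W, B, Pcol);
  G[pi + 4] += dzB * Pcol.t();
  G[pi + 5] += mat(arma::sum(dzB, 1));
  dPcol = P.W[pi + 4].t() * dzB;
  mat dA1(C, dS.n_cols, arma::fill::zeros);
  col2im3(dPcol, H, W, B, dA1);
  dA1 += dS;  // residual branch
  // conv A
  mat dyA = lrelu_back(dA1, cb.yA);
  mat dzA = bn_backward(dyA, vec(P.W[pi + 2].col(0)), cb.bnA, dg, db);
  G[pi + 2] += mat(dg); G[pi + 3] += mat(db);
  im2col3(cb.x0, H, W, B, Pcol);
  G[pi] += dzA * Pcol.t();
  G[pi + 1] += mat(arma::sum(dzA, 1));
  dPcol = P.W[pi].t() * dzA;
  mat dX(cb.x0.n_rows, cb.x0.n_cols, arma::fill::zeros);
  col2im3(dPcol, H, W, B, dX);
  return dX;
}

// ---------------------------------------------------------------------------
// encoder network (tracer / grower)

static mat encoder_forward(const Arch& A, Params& P, const mat& X0, int B,
                           bool train, NetCache& cache) {
  int H = A.tile, W = A.tile;
  const int nb = A.widths.size();
  cache.blocks.assign(nb, BlockCache());
  cache.B = B;
  mat cur = X0;
  int pi = 0, bi = 0;
  for (int b = 0; b < nb; ++b) {
    bool pool = (b < nb - 1);
    cur = block_forward(P, P.rmean, P.rvar, cur, H, W, B, train, pool, pi, bi,
                        cache.blocks[b]);
    if (pool) { H /= 2; W /= 2; }
  }
  // fully connected head over the remaining H x W x C map
  const int C = A.widths[nb - 1], HW = H * W;
  cache.fc_in.set_size((size_t)C * HW, B);
  for (int b = 0; b < B; ++b)
    cache.fc_in.col(b) = arma::vectorise(cur.cols((size_t)b * HW, (size_t)b * HW + HW - 1));
  mat out = P.W[pi] * cache.fc_in;
  out.each_col() += vec(P.W[pi + 1].col(0));
  cache.out_pre = out;
  return out;
}

static void encoder_backward(const Arch& A, const Params& P, const NetCache& cache,
                             const mat& dOut, std::vector<mat>& G) {
  const int nb = A.widths.size();
  const int B = cache.B;
  int H = A.tile, W = A.tile;
  // param index of fc layer
  int pi_fc = 12 * nb;
  G[pi_fc] += dOut * cache.fc_in.t();
  G[pi_fc + 1] += mat(arma::sum(dOut, 1));
  mat dFc = P.W[pi_fc].t() * dOut;  // (C*HW, B)
  for (int b = 0; b < nb - 1; ++b) { H /= 2; W /= 2; }
  const int C = A.widths[nb - 1], HW = H * W;
  mat dCur(C, (size_t)HW * B);
  for (int b = 0; b < B; ++b)
    dCur.cols((size_t)b * HW, (size_t)b * HW + HW - 1) =
        arma::reshape(dFc.col(b), C, HW);
  for (int b = nb - 1; b >= 0; --b)
    dCur = block_backward(P, cache.blocks[b], dCur, B, 12 * b, G);
}

// ---------------------------------------------------------------------------
// U-Net

// params: encoder blocks (12 each), then per decoder stage: Wt, bt + block
// (12), then final 1x1 conv W, b. BN order: encoder BNs then decoder BNs.
static mat unet_forward(const Arch& A, Params& P, const mat& X0, int B,
                        bool train, NetCache& cache) {
  const int nb = A.widths.size();
  int H = A.tile, W = A.tile;
  cache.B = B;
  cache.blocks.assign(2 * nb - 1, BlockCache());
  cache.skips.assign(nb - 1, mat());
  cache.dec_in.assign(2 * (nb - 1), mat());
  mat cur = X0;
  int pi = 0, bi = 0;
  // encoder (save pre-pool activations as skips)
  for (int b = 0; b < nb; ++b) {
    bool pool = (b < nb - 1);
    // need the pre-pool activation: run block without pooling, save, then pool
    cur = block_forward(P, P.rmean, P.rvar, cur, H, W, B, train, false, pi, bi,
                        cache.blocks[b]);
    if (pool) {
      cache.skips[b] = cur;
      cache.blocks[b].pooled = true;  // mark for backward
      cur = pool_forward(cur, H, W, B, cache.blocks[b].poolArg);
      H /= 2; W /= 2;
    }
  }
  // decoder
  for (int s = nb - 2; s >= 0; --s) {
    const int Cout = A.widths[s];
    int di = 2 * (nb - 2 - s);
    cache.dec_in[di] = cur;  // tconv input
    // transposed conv 2x2 stride 2: Wt (4*Cout, Cin)
    mat Y4 = P.W[pi] * cur;
    const int HW = H * W, Ho = 2 * H, Wo = 2 * W, HWo = Ho * Wo;
    mat up(Cout, (size_t)HWo * B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r) {
          size_t src = (size_t)b * HW + (size_t)c * H + r;
          for (int q = 0; q < 4; ++q) {
            int dr = q % 2, dc = q / 2;
            size_t dst = (size_t)b * HWo + (size_t)(2 * c + dc) * Ho + (2 * r + dr);
            for (int ch = 0; ch < Cout; ++ch)
              up(ch, dst) = Y4(q * Cout + ch, src);
          }
        }
    up.each_col() += vec(P.W[pi + 1].col(0));
    pi += 2;
    H = Ho; W = Wo;
    // concat skip on top
    cache.dec_in[di + 1] = up;
    mat cat = arma::join_cols(cache.skips[s], up);
    cur = block_forward(P, P.rmean, P.rvar, cat, H, W, B, train, false, pi, bi,
                        cache.blocks[nb + (nb - 2 - s)]);
  }
  // final 1x1 conv + store logits
  mat out = P.W[pi] * cur;
  out.each_col() += vec(P.W[pi + 1].col(0));
  cache.out_pre = out;  // (1, HW*B)
  return out;
}

static void unet_backward(const Arch& A, const Params& P, NetCache& cache,
                          const mat& dLogit, std::vector<mat>& G) {
  const int nb = A.widths.size();
  const int B = cache.B;
  // recover spatial dims at full resolution
  int pi_final = 12 * nb + (nb - 1) * 14;  // 12/block encoder + (2+12)/decoder stage
  // final conv
  // input to final conv = a3 of last decoder block = lrelu(s)
  const BlockCache& lastb = cache.blocks[2 * nb - 2];
  mat a3 = lrelu(lastb.s);
  G[pi_final] += dLogit * a3.t();
  G[pi_final + 1] += mat(arma::sum(dLogit, 1));
  mat dCur = P.W[pi_final].t() * dLogit;
  int H = A.tile, W = A.tile;
  // decoder backward (stages in reverse of forward: forward went s = nb-2 .. 0,
  // backward goes s = 0 .. nb-2)
  for (int s = 0; s <= nb - 2; ++s) {
    int di = 2 * (nb - 2 - s);
    int stage_pi = 12 * nb + (nb - 2 - s) * 14;  // start of this stage's params
    int blk = nb + (nb - 2 - s);
    // block backward (input was concat)
    mat dCat = block_backward(P, cache.blocks[blk], dCur, B, stage_pi + 2, G);
    const int Cs = A.widths[s];
    mat dSkip = dCat.rows(0, Cs - 1);
    mat dUp = dCat.rows(Cs, dCat.n_rows - 1);
    // tconv backward
    const int Ho = cache.blocks[blk].H, Wo = cache.blocks[blk].W;
    const int Hi = Ho / 2, Wi = Wo / 2;
    const int HWo = Ho * Wo, HWi = Hi * Wi;
    G[stage_pi + 1] += mat(arma::sum(dUp, 1));
    mat dY4(4 * Cs, (size_t)HWi * B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < Wi; ++c)
        for (int r = 0; r < Hi; ++r) {
          size_t src = (size_t)b * HWi + (size_t)c * Hi + r;
          for (int q = 0; q < 4; ++q) {
            int dr = q % 2, dc = q / 2;
            size_t dst = (size_t)b * HWo + (size_t)(2 * c + dc) * Ho + (2 * r + dr);
            for (int ch = 0; ch < Cs; ++ch)
              dY4(q * Cs + ch, src) = dUp(ch, dst);
          }
        }
    G[stage_pi] += dY4 * cache.dec_in[di].t();
    mat dIn = P.W[stage_pi].t() * dY4;
    // propagate into encoder skip + deeper decoder path
    // deeper path continues with dIn; skip grad handled when we reach encoder
    // store skip grad by adding into a buffer: reuse cache.skips as grad store
    cache.skips[s] = dSkip;  // overwrite activation with its gradient
    dCur = dIn;
  }
  // encoder backward
  for (int b = nb - 1; b >= 0; --b) {
    if (b < nb - 1) {
      // dCur is gradient at pooled output; un-pool then add skip gradient
      const int C = A.widths[b];
      mat dPre = pool_backward(dCur, cache.blocks[b].poolArg,
                               C, (size_t)cache.blocks[b].H * cache.blocks[b].W * B);
      dPre += cache.skips[b];
      cache.blocks[b].pooled = false;  // block_backward must not un-pool again
      dCur = block_backward(P, cache.blocks[b], dPre, B, 12 * b, G);
    } else {
      dCur = block_backward(P, cache.blocks[b], dCur, B, 12 * b, G);
    }
  }
}

// ---------------------------------------------------------------------------
// heads and losses

struct LossCfg {
  std::string mode;  // "wmse", "focal", "bce"
  vec weights;       // wmse
  double alpha, gamma;
};

static LossCfg loss_from_r(const List& l) {
  LossCfg out;
  out.mode = as<std::string>(l["mode"]);
  if (l.containsElementNamed("weights") && !Rf_isNull(l["weights"]))
    out.weights = as<vec>(l["weights"]);
  out.alpha = l.containsElementNamed("alpha") ? as<double>(l["alpha"]) : 0.25;
  out.gamma = l.containsElementNamed("gamma") ? as<double>(l["gamma"]) : 2.0;
  return out;
}

static inline double clampp(double p) {
  return std::min(1.0 - P_CLAMP, std::max(P_CLAMP, p));
}

// focal loss value and d/dp for one pixel
static inline void focal_point(double p, double y, double alpha, double gamma,
                               double& L, double& dLdp) {
  p = clampp(p);
  if (y > 0.5) {
    double om = 1.0 - p;
    double lg = std::log(p);
    L = -alpha * std::pow(om, gamma) * lg;
    dLdp = -alpha * (-gamma * (gamma > 0 ? std::pow(om, gamma - 1.0) : 0.0) * lg +
                     std::pow(om, gamma) / p);
    if (gamma == 0.0) dLdp = -alpha / p;
  } else {
    double lg = std::log(1.0 - p);
    L = -(1.0 - alpha) * std::pow(p, gamma) * lg;
    dLdp = -(1.0 - alpha) * (gamma * (gamma > 0 ? std::pow(p, gamma - 1.0) : 0.0) * lg -
                             std::pow(p, gamma) / (1.0 - p));
    if (gamma == 0.0) dLdp = (1.0 - alpha) / (1.0 - p);
  }
}

static inline void bce_point(double p, double y, double& L, double& dLdp) {
  p = clampp(p);
  if (y > 0.5) { L = -std::log(p); dLdp = -1.0 / p; }
  else { L = -std::log(1.0 - p); dLdp = 1.0 / (1.0 - p); }
}

// loss + gradient wrt pre-head outputs. Y layout depends on head.
// Returns loss; fills dOut (same shape as logits).
static double head_loss(const Arch& A, const LossCfg& L, const mat& logits,
                        const mat& Y, const mat& validM, mat& dOut) {
  dOut.zeros(logits.n_rows, logits.n_cols);
  double total = 0.0;
  if (A.head == "linear") {
    // weighted MSE over displacement pairs; Y (2N, B)
    const int N = logits.n_rows / 2;
    const int B = logits.n_cols;
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < N; ++i) {
        double w = L.weights(i);
        double d1 = logits(i, b) - Y(i, b);
        double d2 = logits(N + i, b) - Y(N + i, b);
        total += w * (d1 * d1 + d2 * d2) / N;
        dOut(i, b) = 2.0 * w * d1 / (N * B);
        dOut(N + i, b) = 2.0 * w * d2 / (N * B);
      }
    }
    return total / B;
  }
  if (A.head == "softmax9") {
    // logits (18, B): rows 0..8 vein, 9..17 background; Y (9, B) in {0,1}
    const int B = logits.n_cols;
    const double M = 9.0 * B;
    for (int b = 0; b < B; ++b) {
      for (int k = 0; k < 9; ++k) {
        double zv = logits(k, b), zb = logits(9 + k, b);
        double p = 1.0 / (1.0 + std::exp(zb - zv));
        double l, dldp;
        if (L.mode == "focal") focal_point(p, Y(k, b), L.alpha, L.gamma, l, dldp);
        else bce_point(p, Y(k, b), l, dldp);
        total += l;
        double pc = clampp(p);
        double dz = dldp * pc * (1.0 - pc) / M;
        dOut(k, b) += dz;
        dOut(9 + k, b) -= dz;
      }
    }
    return total / M;
  }
  // sigmoid_map: logits (1, HW*B); Y flattened to match; validM same shape
  const size_t n = logits.n_cols;
  double nvalid = 0.0;
  std::vector<double> dl(n);
  for (size_t i = 0; i < n; ++i) {
    if (validM.n_elem == n && validM(0, i) < 0.5) { dl[i] = 0.0; continue; }
    double p = 1.0 / (1.0 + std::exp(-logits(0, i)));
    double l, dldp;
    if (L.mode == "focal") focal_point(p, Y(0, i), L.alpha, L.gamma, l, dldp);
    else bce_point(p, Y(0, i), l, dldp);
    total += l;
    double pc = clampp(p);
    dl[i] = dldp * pc * (1.0 - pc);
    nvalid += 1.0;
  }
  if (nvalid == 0) return 0.0;
  for (size_t i = 0; i < n; ++i) dOut(0, i) = dl[i] / nvalid;
  return total / nvalid;
}

// ---------------------------------------------------------------------------
// data conversion: R array (S, S, C, n) -> (C, S*S*n) matrix

static mat tiles_to_mat(const NumericVector& X) {
  IntegerVector d = X.attr("dim");
  const int S = d[0], C = d[2], n = d[3];
  const size_t SS = (size_t)S * S;
  mat A(C, SS * n);
  const double* src = X.begin();
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < C; ++c) {
      const double* col = src + s * SS * C + (size_t)c * SS;
      for (size_t p = 0; p < SS; ++p)
        A(c, (size_t)s * SS + p) = (float)col[p];
    }
  }
  return A;
}

static mat forward_any(const Arch& A, Params& P, const mat& X0, int B,
                       bool train, NetCache& cache) {
  if (A.type == "unet") return unet_forward(A, P, X0, B, train, cache);
  return encoder_forward(A, P, X0, B, train, cache);
}

static void backward_any(const Arch& A, const Params& P, NetCache& cache,
                         const mat& dOut, std::vector<mat>& G) {
  if (A.type == "unet") unet_backward(A, P, cache, dOut, G);
  else encoder_backward(A, P, cache, dOut, G);
}

// head transform for inference outputs
static mat head_apply(const Arch& A, const mat& logits) {
  if (A.head == "linear") return logits;
  if (A.head == "softmax9") {
    mat p(9, logits.n_cols);
    for (size_t b = 0; b < logits.n_cols; ++b)
      for (int k = 0; k < 9; ++k)
        p(k, b) = 1.0 / (1.0 + std::exp(logits(9 + k, b) - logits(k, b)));
    return p;
  }
  mat p = logits;
  p.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
  return p;
}

// ---------------------------------------------------------------------------
// exported: forward pass (eval mode)

// [[Rcpp::export]]
NumericMatrix cpp_forward(const List& arch, const List& params_r, const List& running_r,
                          const NumericVector& X, int batch) {
  Arch A = arch_from_r(arch);
  Params P = params_from_r(params_r, running_r);
  IntegerVector d = X.attr("dim");
  const int S = d[0], n = d[3];
  const size_t SS = (size_t)S * S;
  mat Xall = tiles_to_mat(X);
  int out_rows, out_cols_per;
  if (A.head == "linear") { out_rows = A.out_dim; out_cols_per = 1; }
  else if (A.head == "softmax9") { out_rows = 9; out_cols_per = 1; }
  else { out_rows = (int)SS; out_cols_per = 1; }
  NumericMatrix out(out_rows, n);
  NetCache cache;
  for (int start = 0; start < n; start += batch) {
    int B = std::min(batch, n - start);
    mat Xb = Xall.cols(start * SS, (size_t)(start + B) * SS - 1);
    mat logits = forward_any(A, P, Xb, B, false, cache);
    mat vals = head_apply(A, logits);
    if (A.head == "sigmoid_map") {
      for (int b = 0; b < B; ++b)
        for (size_t i = 0; i < SS; ++i)
          out(i, start + b) = vals(0, (size_t)b * SS + i);
    } else {
      for (int b = 0; b < B; ++b)
        for (int i = 0; i < out_rows; ++i)
          out(i, start + b) = vals(i, b);
    }
  }
  return out;
}

// exported: loss and gradients on a batch (for gradient checking)
// [[Rcpp::export]]
List cpp_loss_grads(const List& arch, const List& params_r, const List& running_r,
                    const NumericVector& X, const NumericMatrix& Y,
                    Nullable<NumericMatrix> valid, const List& loss_cfg, bool train) {
  Arch A = arch_from_r(arch);
  Params P = params_from_r(params_r, running_r);
  LossCfg L = loss_from_r(loss_cfg);
  IntegerVector d = X.attr("dim");
  const int S = d[0], n = d[3];
  const size_t SS = (size_t)S * S;
  mat Xall = tiles_to_mat(X);
  NetCache cache;
  mat logits = forward_any(A, P, Xall, n, train, cache);
  mat Ym = as<mat>(Y);
  mat Yuse, Vuse;
  if (A.head == "sigmoid_map") {
    Yuse.set_size(1, SS * n);
    for (int b = 0; b < n; ++b)
      for (size_t i = 0; i < SS; ++i)
        Yuse(0, (size_t)b * SS + i) = Ym(i, b);
    if (valid.isNotNull()) {
      mat Vm = as<mat>(valid.get());
      Vuse.set_size(1, SS * n);
      for (int b = 0; b < n; ++b)
        for (size_t i = 0; i < SS; ++i)
          Vuse(0, (size_t)b * SS + i) = Vm(i, b);
    }
  } else {
    Yuse = Ym;
  }
  mat dOut;
  double loss = head_loss(A, L, logits, Yuse, Vuse, dOut);
  std::vector<mat> G(P.W.size());
  for (size_t i = 0; i < P.W.size(); ++i) G[i].zeros(P.W[i].n_rows, P.W[i].n_cols);
  backward_any(A, P, cache, dOut, G);
  List Gr(G.size());
  for (size_t i = 0; i < G.size(); ++i) Gr[i] = G[i];
  return List::create(_["loss"] = loss, _["grads"] = Gr);
}

// Per-epoch augmentation for displacement-regression tiles (linear head):
// centre-fixed horizontal flip (negates the column displacements), integer
// translation (shifts the displacement targets exactly), and channel
// jitter on the RGB channels. The overlay channel (index 3) keeps value 0
// outside the support; RGB fills with white. Applied to one sample's
// columns of Xb in place.
static void augment_linear_sample(mat& Xb, mat& Yb, int b, int S, int C,
                                  int jitter, double color, bool allow_flip,
                                  std::mt19937& rng) {
  std::uniform_int_distribution<int> Uj(-jitter, jitter);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  const bool flip = allow_flip && U01(rng) < 0.5;
  const int tr = jitter > 0 ? Uj(rng) : 0;
  const int tc = jitter > 0 ? Uj(rng) : 0;
  const int ctr = S / 2;  // 0-based centre index
  const size_t SS = (size_t)S * S;
  if (flip || tr != 0 || tc != 0) {
    mat src = Xb.cols((size_t)b * SS, (size_t)(b + 1) * SS - 1);
    for (int cdst = 0; cdst < S; ++cdst) {
      int c0 = cdst - tc;
      int csrc = flip ? (2 * ctr - c0) : c0;
      for (int rdst = 0; rdst < S; ++rdst) {
        int rsrc = rdst - tr;
        size_t dst = (size_t)b * SS + (size_t)cdst * S + rdst;
        if (rsrc < 0 || rsrc >= S || csrc < 0 || csrc >= S) {
          for (int ch = 0; ch < C; ++ch)
            Xb(ch, dst) = (ch == 3) ? 0.0f : 1.0f;
        } else {
          size_t s = (size_t)csrc * S + rsrc;
          for (int ch = 0; ch < C; ++ch) Xb(ch, dst) = src(ch, s);
        }
      }
    }
    const int N = Yb.n_rows / 2;
    for (int i = 0; i < N; ++i) {
      Yb(i, b) += tr;
      Yb(N + i, b) = (flip ? -Yb(N + i, b) : Yb(N + i, b)) + tc;
    }
  }
  if (color > 0) {
    std::uniform_real_distribution<double> Us(1.0 - color, 1.0 + color);
    std::uniform_real_distribution<double> Uh(-color / 2, color / 2);
    double shift = Uh(rng);
    for (int ch = 0; ch < std::min(C, 3); ++ch) {
      double sc = Us(rng);
      for (size_t p = 0; p < SS; ++p) {
        float v = Xb(ch, (size_t)b * SS + p) * sc + shift;
        Xb(ch, (size_t)b * SS + p) = std::min(1.0f, std::max(0.0f, v));
      }
    }
  }
}

// ---------------------------------------------------------------------------
// exported: full training loop with Adam and early stopping

// [[Rcpp::export]]
List cpp_train(const List& arch, const List& params_r, const List& running_r,
               const NumericVector& X, const NumericMatrix& Y,
               const NumericVector& Xval, const NumericMatrix& Yval,
               Nullable<NumericMatrix> validTr, Nullable<NumericMatrix> validVa,
               const List& loss_cfg, const List& opts) {
  Arch A = arch_from_r(arch);
  Params P = params_from_r(params_r, running_r);
  LossCfg L = loss_from_r(loss_cfg);
  const int epochs = as<int>(opts["epochs"]);
  const int batch = as<int>(opts["batch"]);
  const int patience = as<int>(opts["patience"]);
  double lr = as<double>(opts["lr"]);
  // optional step decay: multiply lr by decay_factor at each listed epoch
  std::vector<int> decay_at;
  double decay_factor = 1.0;
  if (opts.containsElementNamed("decay_at") && !Rf_isNull(opts["decay_at"])) {
    IntegerVector da = opts["decay_at"];
    for (int i = 0; i < da.size(); ++i) decay_at.push_back(da[i]);
    decay_factor = as<double>(opts["decay_factor"]);
  }
  // per-epoch tile augmentation (displacement-regression head only)
  int aug_jitter = 0;
  double aug_color = 0.0;
  bool aug_flip = false;
  if (opts.containsElementNamed("aug") && !Rf_isNull(opts["aug"])) {
    List aug = opts["aug"];
    aug_jitter = as<int>(aug["jitter"]);
    aug_color = as<double>(aug["color"]);
    aug_flip = as<bool>(aug["flip"]);
  }
  const unsigned seed = (unsigned)as<int>(opts["seed"]);
  const bool verbose = opts.containsElementNamed("verbose") ? as<bool>(opts["verbose"]) : false;

  IntegerVector d = X.attr("dim");
  const int S = d[0], n = d[3];
  const size_t SS = (size_t)S * S;
  IntegerVector dv = Xval.attr("dim");
  const int nval = dv[3];

  mat Xall = tiles_to_mat(X);
  mat Xv = tiles_to_mat(Xval);
  mat Ym = as<mat>(Y);
  mat Yv = as<mat>(Yval);
  mat Vtr, Vva;
  if (validTr.isNotNull()) Vtr = as<mat>(validTr.get());
  if (validVa.isNotNull()) Vva = as<mat>(validVa.get());

  // Adam state
  std::vector<mat> M(P.W.size()), V(P.W.size()), G(P.W.size());
  for (size_t i = 0; i < P.W.size(); ++i) {
    M[i].zeros(P.W[i].n_rows, P.W[i].n_cols);
    V[i].zeros(P.W[i].n_rows, P.W[i].n_cols);
    G[i].zeros(P.W[i].n_rows, P.W[i].n_cols);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::mt19937 rng(seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Params best = P;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0;
  std::vector<double> hist_tr, hist_va;

  NetCache cache;
  auto eval_val = [&](Params& Pc) {
    double tot = 0.0; long cnt = 0;
    for (int start = 0; start < nval; start += batch) {
      int B = std::min(batch, nval - start);
      mat Xb = Xv.cols((size_t)start * SS, (size_t)(start + B) * SS - 1);
      mat logits = forward_any(A, Pc, Xb, B, false, cache);
      mat Yb, Vb;
      if (A.head == "sigmoid_map") {
        Yb.set_size(1, SS * B);
        for (int b = 0; b < B; ++b)
          for (size_t i = 0; i < SS; ++i)
            Yb(0, (size_t)b * SS + i) = Yv(i, start + b);
        if (Vva.n_elem) {
          Vb.set_size(1, SS * B);
          for (int b = 0; b < B; ++b)
            for (size_t i = 0; i < SS; ++i)
              Vb(0, (size_t)b * SS + i) = Vva(i, start + b);
        }
      } else {
        Yb = Yv.cols(start, start + B - 1);
      }
      mat dOut;
      tot += head_loss(A, L, logits, Yb, Vb, dOut) * B;
      cnt += B;
    }
    return tot / cnt;
  };

  int epoch = 0;
  for (epoch = 1; epoch <= epochs; ++epoch) {
    for (int de : decay_at) if (de == epoch) lr *= decay_factor;
    // deterministic Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> U(0, i);
      std::swap(order[i], order[U(rng)]);
    }
    double tr_tot = 0.0; long tr_cnt = 0;
    for (int start = 0; start < n; start += batch) {
      int B = std::min(batch, n - start);
      mat Xb(Xall.n_rows, SS * B);
      mat Yb, Vb;
      if (A.head == "sigmoid_map") { Yb.set_size(1, SS * B); if (Vtr.n_elem) Vb.set_size(1, SS * B); }
      else Yb.set_size(Ym.n_rows, B);
      for (int b = 0; b < B; ++b) {
        int s = order[start + b];
        Xb.cols((size_t)b * SS, (size_t)(b + 1) * SS - 1) =
            Xall.cols((size_t)s * SS, (size_t)(s + 1) * SS - 1);
        if (A.head == "sigmoid_map") {
          for (size_t i = 0; i < SS; ++i) Yb(0, (size_t)b * SS + i) = Ym(i, s);
          if (Vtr.n_elem)
            for (size_t i = 0; i < SS; ++i) Vb(0, (size_t)b * SS + i) = Vtr(i, s);
        } else {
          Yb.col(b) = Ym.col(s);
        }
      }
      if (A.head == "linear" && (aug_flip || aug_jitter > 0 || aug_color > 0)) {
        for (int b = 0; b < B; ++b)
          augment_linear_sample(Xb, Yb, b, S, Xall.n_rows, aug_jitter,
                                aug_color, aug_flip, rng);
      }
      mat logits = forward_any(A, P, Xb, B, true, cache);
      mat dOut;
      double loss = head_loss(A, L, logits, Yb, Vb, dOut);
      tr_tot += loss * B; tr_cnt += B;
      for (size_t i = 0; i < G.size(); ++i) G[i].zeros();
      backward_any(A, P, cache, dOut, G);
      ++step;
      double bc1 = 1.0 - std::pow(b1, (double)step);
      double bc2 = 1.0 - std::pow(b2, (double)step);
      for (size_t i = 0; i < P.W.size(); ++i) {
        M[i] = b1 * M[i] + (1.0 - b1) * G[i];
        V[i] = b2 * V[i] + (1.0 - b2) * arma::square(G[i]);
        P.W[i] -= lr * (M[i] / bc1) / (arma::sqrt(V[i] / bc2) + eps);
      }
    }
    double va = eval_val(P);
    hist_tr.push_back(tr_tot / tr_cnt);
    hist_va.push_back(va);
    if (verbose) Rcpp::Rcout << "epoch " << epoch << " train " << tr_tot / tr_cnt
                             << " val " << va << "\n";
    if (va < best_val - 1e-9) {
      best_val = va; best = P; best_epoch = epoch; bad = 0;
    } else {
      if (++bad >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  List pr = params_to_r(best);
  return List::create(
      _["params"] = pr["params"], _["running"] = pr["running"],
      _["best_epoch"] = best_epoch, _["best_val"] = best_val,
      _["epochs_run"] = std::min(epoch, epochs),
      _["history"] = DataFrame::create(
          _["epoch"] = seq_len(hist_tr.size()),
          _["train_loss"] = hist_tr, _["val_loss"] = hist_va));
}
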