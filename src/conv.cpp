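// The two convolution + ReLU + max-pool stages that compress the
// cross-layer node-embedding plane of each neighboring subgraph into the
// graph-level vector g.
//
// Both stages run fused in one call and the (large) activation caches stay
// on the C++ side behind an external pointer, so only the input plane, the
// flattened output and the parameter gradients ever cross the R boundary.
//
// Layout conventions (shared with the R side):
//  * a batch of B images with C channels is a cube (h, w, B*C) whose slice
//    index is b*C + c (channel fastest);
//  * kernels are a (kh*kw*C) x F matrix; patch element (c, dx, dy) sits at
//    row c*kh*kw + dx*kh + dy (dy fastest), matching im2col below;
//  * for one batch item the F conv planes occupy F consecutive cube slices,
//    which equals the column-major (oh*ow) x F gemm output, so results are
//    written in place;
//  * the flattened graph vector of item b is the contiguous memory of its
//    F2 pooled slices, so the (flat x B) output is an alias of the pooled
//    cube;
//  * pooling argmax stores the linear index y + oh*x inside the conv plane.
// Valid convolution only (no padding), pool blocks truncate at the edge.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct StageSpec {
  int C, kh, kw, ph, pw, F;
};

struct ConvCache {
  arma::cube X1, Oc1, P1, Oc2, P2;
  arma::icube Am1, Am2;
};

static StageSpec read_spec(const arma::mat& K, const IntegerVector& s, int C) {
  StageSpec sp;
  sp.C = C;
  sp.kh = s[0]; sp.kw = s[1]; sp.ph = s[2]; sp.pw = s[3];
  sp.F = K.n_cols;
  return sp;
}

static void im2col(const arma::cube& X, int b, const StageSpec& sp,
                   arma::mat& A) {
  const int h = X.n_rows, w = X.n_cols;
  const int oh = h - sp.kh + 1, ow = w - sp.kw + 1;
  for (int c = 0; c < sp.C; ++c) {
    const double* S = X.slice_memptr(b * sp.C + c);
    for (int dx = 0; dx < sp.kw; ++dx) {
      for (int dy = 0; dy < sp.kh; ++dy) {
        double* dst = A.colptr(c * sp.kh * sp.kw + dx * sp.kh + dy);
        for (int x = 0; x < ow; ++x) {
          const double* src = S + (x + dx) * h + dy;
          std::copy(src, src + oh, dst + x * oh);
        }
      }
    }
  }
}

// conv + ReLU + max-pool for all batch items of one stage.
static void stage_forward(const arma::cube& X, const arma::mat& K,
                          const arma::vec& bias, const StageSpec& sp,
                          arma::cube& Oc, arma::icube& Am, arma::cube& Op) {
  const int h = X.n_rows, w = X.n_cols;
  const int B = X.n_slices / sp.C;
  const int oh = h - sp.kh + 1, ow = w - sp.kw + 1;
  const int oh2 = oh / sp.ph, ow2 = ow / sp.pw;
  if (oh < 1 || ow < 1 || oh2 < 1 || ow2 < 1)
    stop("convolution input (%d x %d) smaller than kernel/pool extent", h, w);
  Oc.set_size(oh, ow, B * sp.F);
  Op.set_size(oh2, ow2, B * sp.F);
  Am.set_size(oh2, ow2, B * sp.F);
  arma::mat A(oh * ow, sp.kh * sp.kw * sp.C);
  for (int b = 0; b < B; ++b) {
    im2col(X, b, sp, A);
    arma::mat O(Oc.slice_memptr(b * sp.F), oh * ow, sp.F, false, true);
    O = A * K;
    O.each_row() += bias.t();
    O.transform([](double v) { return v > 0 ? v : 0.0; });
    for (int f = 0; f < sp.F; ++f) {
      const double* Of = Oc.slice_memptr(b * sp.F + f);
      double* Pp = Op.slice_memptr(b * sp.F + f);
      int* Pa = Am.slice_memptr(b * sp.F + f);
      for (int x2 = 0; x2 < ow2; ++x2) {
        for (int y2 = 0; y2 < oh2; ++y2) {
          double best = -1.0;  // post-ReLU values are >= 0
          int bi = 0;
          for (int dx = 0; dx < sp.pw; ++dx) {
            const double* col = Of + (x2 * sp.pw + dx) * oh + y2 * sp.ph;
            for (int dy = 0; dy < sp.ph; ++dy) {
              if (col[dy] > best) {
                best = col[dy];
                bi = y2 * sp.ph + dy + (x2 * sp.pw + dx) * oh;
              }
            }
          }
          Pp[y2 + x2 * oh2] = best;
          Pa[y2 + x2 * oh2] = bi;
        }
      }
    }
  }
}

// Gradient of one stage. dOp is the gradient at the pooled output; returns
// the gradient at the stage input through dX, and accumulates dK / dbias.
static void stage_backward(const arma::cube& X, const arma::cube& Oc,
                           const arma::icube& Am, const arma::cube& dOp,
                           const arma::mat& K, const StageSpec& sp,
                           arma::cube& dX, arma::mat& dK, arma::vec& db) {
  const int h = X.n_rows, w = X.n_cols;
  const int B = X.n_slices / sp.C;
  const int oh = h - sp.kh + 1, ow = w - sp.kw + 1;
  const int oh2 = dOp.n_rows, ow2 = dOp.n_cols;
  dX.zeros(h, w, B * sp.C);
  dK.zeros(K.n_rows, K.n_cols);
  db.zeros(sp.F);
  arma::mat A(oh * ow, sp.kh * sp.kw * sp.C);
  arma::mat G(oh * ow, sp.F);
  for (int b = 0; b < B; ++b) {
    G.zeros();
    for (int f = 0; f < sp.F; ++f) {
      const double* Of = Oc.slice_memptr(b * sp.F + f);
      const double* dP = dOp.slice_memptr(b * sp.F + f);
      const int* Pa = Am.slice_memptr(b * sp.F + f);
      double* Gf = G.colptr(f);
      const int n2 = oh2 * ow2;
      for (int t = 0; t < n2; ++t) {
        const int idx = Pa[t];
        // ReLU gate: the winning conv value is 0 only when the whole pool
        // block was clipped, in which case no gradient flows.
        if (Of[idx] > 0) Gf[idx] += dP[t];
      }
    }
    im2col(X, b, sp, A);
    dK += A.t() * G;
    db += arma::sum(G, 0).t();
    arma::mat dA = G * K.t();
    double* dS0 = dX.slice_memptr(b * sp.C);
    for (int c = 0; c < sp.C; ++c) {
      double* dS = dS0 + (size_t)c * h * w;
      for (int dx = 0; dx < sp.kw; ++dx) {
        for (int dy = 0; dy < sp.kh; ++dy) {
          const double* src = dA.colptr(c * sp.kh * sp.kw + dx * sp.kh + dy);
          for (int x = 0; x < ow; ++x) {
            double* dst = dS + (x + dx) * h + dy;
            const double* s = src + x * oh;
            for (int y = 0; y < oh; ++y) dst[y] += s[y];
          }
        }
      }
    }
  }
}

// Both stages forward. spec1/spec2 = c(kh, kw, ph, pw). Returns the
// flattened graph vectors as a (flat x B) matrix; with keep_cache the
// activations are retained for conv_stages_backward.
// [[Rcpp::export]]
List conv_stages_forward(const arma::cube& H,
                         const arma::mat& K1, const arma::vec& bias1,
                         const IntegerVector& spec1,
                         const arma::mat& K2, const arma::vec& bias2,
                         const IntegerVector& spec2,
                         bool keep_cache) {
  StageSpec s1 = read_spec(K1, spec1, 1);
  StageSpec s2 = read_spec(K2, spec2, s1.F);
  const int B = H.n_slices;
  Rcpp::XPtr<ConvCache> cache(new ConvCache());
  cache->X1 = H;
  stage_forward(cache->X1, K1, bias1, s1, cache->Oc1, cache->Am1, cache->P1);
  stage_forward(cache->P1, K2, bias2, s2, cache->Oc2, cache->Am2, cache->P2);
  const int flat = cache->P2.n_rows * cache->P2.n_cols * s2.F;
  arma::mat Gt(cache->P2.memptr(), flat, B);  // copies into the return value
  if (!keep_cache) {
    return List::create(_["Gt"] = Gt, _["cache"] = R_NilValue);
  }
  return List::create(_["Gt"] = Gt, _["cache"] = cache);
}

// Both stages backward from the gradient at the flattened output.
// [[Rcpp::export]]
List conv_stages_backward(SEXP cache_, const arma::mat& dGt,
                          const arma::mat& K1, const IntegerVector& spec1,
                          const arma::mat& K2, const IntegerVector& spec2) {
  Rcpp::XPtr<ConvCache> cache(cache_);
  StageSpec s1 = read_spec(K1, spec1, 1);
  StageSpec s2 = read_spec(K2, spec2, s1.F);
  const arma::cube& P2 = cache->P2;
  arma::cube dP2(const_cast<double*>(dGt.memptr()),
                 P2.n_rows, P2.n_cols, P2.n_slices, false, true);
  arma::cube dP1, dH;
  arma::mat dK1, dK2;
  arma::vec db1, db2;
  stage_backward(cache->P1, cache->Oc2, cache->Am2, dP2, K2, s2,
                 dP1, dK2, db2);
  stage_backward(cache->X1, cache->Oc1, cache->Am1, dP1, K1, s1,
                 dH, dK1, db1);
  return List::create(_["dH"] = dH,
                      _["dK1"] = dK1, _["dbias1"] = db1,
                      _["dK2"] = dK2, _["dbias2"] = db2);
}
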