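// Width-scalable VGG-style 3D convolutional network, single precision.
//
// Convolutions are 3x3x3 with same-padding. Spatial activations are kept
// in a transposed, halo-padded layout: an (Vp * (B + 2)) x C matrix whose
// row index is slab * Vp + padded_voxel, with one guard slab at each end
// and all non-interior rows held at zero. In this layout im2col is 27 * C
// contiguous memcpys, each convolution is one tall-skinny sgemm (with the
// output written straight into the padded buffer via the LDC stride), and
// the col2im transpose is 27 * C vectorized accumulation loops — no
// per-voxel gather anywhere. Spills across slab boundaries only ever
// touch halo rows, which are re-zeroed, and the guard slabs keep shifted
// reads in bounds.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb,
            const float* beta, float* c, const int* ldc);
}

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

static const float BN_EPS = 1e-5f;

// geometry of one spatial stage (shared by the layers operating on it)
struct Stage {
  int dims[3] = {0, 0, 0};
  int pdims[3] = {0, 0, 0};
  int V = 0, Vp = 0;
  std::vector<int> interior;  // padded index of each interior voxel
  std::vector<int> halo;      // padded indices that are not interior
  int delta[27];              // padded linear offset of each 3x3x3 tap
};

static Stage make_stage(const std::vector<int>& d) {
  Stage s;
  for (int i = 0; i < 3; ++i) { s.dims[i] = d[i]; s.pdims[i] = d[i] + 2; }
  s.V = d[0] * d[1] * d[2];
  s.Vp = s.pdims[0] * s.pdims[1] * s.pdims[2];
  std::vector<char> is_int(s.Vp, 0);
  s.interior.reserve(s.V);
  for (int iz = 0; iz < d[2]; ++iz)
    for (int iy = 0; iy < d[1]; ++iy)
      for (int ix = 0; ix < d[0]; ++ix) {
        const int vp = (ix + 1) +
          s.pdims[0] * ((iy + 1) + s.pdims[1] * (iz + 1));
        s.interior.push_back(vp);
        is_int[vp] = 1;
      }
  for (int vp = 0; vp < s.Vp; ++vp)
    if (!is_int[vp]) s.halo.push_back(vp);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o)
        s.delta[o] = dx + s.pdims[0] * (dy + s.pdims[1] * dz);
  return s;
}

struct PoolGeom {
  std::vector<std::array<int, 8>> src;  // padded input indices per out voxel
  std::vector<int> cnt;
  std::vector<int> dims_out;
};

static PoolGeom make_pool_geom(const Stage& in, int stride) {
  PoolGeom g;
  auto odim = [stride](int n) { return stride == 2 ? (n + 1) / 2 : n; };
  const int ox = odim(in.dims[0]), oy = odim(in.dims[1]),
    oz = odim(in.dims[2]);
  g.dims_out = {ox, oy, oz};
  g.src.resize((size_t)ox * oy * oz);
  g.cnt.assign((size_t)ox * oy * oz, 0);
  for (int iz = 0; iz < oz; ++iz)
    for (int iy = 0; iy < oy; ++iy)
      for (int ix = 0; ix < ox; ++ix) {
        const int vo = ix + ox * (iy + oy * iz);
        const int bx = stride == 2 ? 2 * ix : ix;
        const int by = stride == 2 ? 2 * iy : iy;
        const int bz = stride == 2 ? 2 * iz : iz;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int jx = bx + dx, jy = by + dy, jz = bz + dz;
              if (jx < in.dims[0] && jy < in.dims[1] && jz < in.dims[2])
                g.src[vo][g.cnt[vo]++] = (jx + 1) +
                  in.pdims[0] * ((jy + 1) + in.pdims[1] * (jz + 1));
            }
      }
  return g;
}

struct Layer {
  std::string type;
  int cin = 0, cout = 0, din = 0, dout = 0;
  float drop_rate = 0.f;
  int stride = 2;
  Stage stage;                   // conv/pool/bn/relu input stage
  Stage stage_out;               // pool output stage
  PoolGeom pool;
  fmat Wt; fvec b;               // conv/fc weights, Wt is (fan_in x fan_out)
  fvec gamma, beta, rmean, rvar; // bn
  // per-batch caches
  fmat out;                      // forward output (persistent buffer)
  fmat dbuf;                     // gradient wrt input (persistent)
  fmat xhat; fvec istd;          // bn
  std::vector<int> amax;         // pool argmax (absolute row in input)
  fmat mask;                     // relu / dropout mask
  int lastB = -1;
  bool compact = false;          // small-volume conv: interior-only gemms
  fmat Pc, dYc;                  // compact fiber-layout scratch
  // Adam state
  fmat mW, vW; fvec mb, vb, mg, vg, mbt, vbt;
};

static std::vector<int> as_dims(SEXP s) {
  IntegerVector iv(s);
  return {iv[0], iv[1], iv[2]};
}

static fvec to_fvec(SEXP s) {
  NumericVector v(s);
  return arma::conv_to<fvec>::from(arma::vec(v.begin(), v.size(), false));
}

static std::vector<Layer> parse_layers(List layers) {
  std::vector<Layer> net;
  for (int i = 0; i < layers.size(); ++i) {
    List sp = layers[i];
    Layer L;
    L.type = as<std::string>(sp["type"]);
    if (L.type == "conv") {
      L.cin = as<int>(sp["cin"]); L.cout = as<int>(sp["cout"]);
      L.stage = make_stage(as_dims(sp["dims"]));
      NumericMatrix W = sp["W"];  // (cout x cin*27), R-side convention
      fmat Wf = arma::conv_to<fmat>::from(
        arma::mat(W.begin(), W.nrow(), W.ncol(), false));
      L.Wt = Wf.t();
      L.b = to_fvec(sp["b"]);
      L.mW.zeros(L.Wt.n_rows, L.Wt.n_cols);
      L.vW.zeros(L.Wt.n_rows, L.Wt.n_cols);
      L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
      // at tiny volumes the halo dominates the slab; gather the interior
      // into a compact patch matrix instead of streaming padded slabs
      L.compact = L.stage.V <= 100;
    } else if (L.type == "bn") {
      L.gamma = to_fvec(sp["gamma"]); L.beta = to_fvec(sp["beta"]);
      L.rmean = to_fvec(sp["running_mean"]);
      L.rvar = to_fvec(sp["running_var"]);
      L.mg.zeros(L.gamma.n_elem); L.vg.zeros(L.gamma.n_elem);
      L.mbt.zeros(L.beta.n_elem); L.vbt.zeros(L.beta.n_elem);
    } else if (L.type == "pool") {
      L.stage = make_stage(as_dims(sp["dims"]));
      L.stride = as<int>(sp["stride"]);
      L.pool = make_pool_geom(L.stage, L.stride);
      L.stage_out = make_stage(L.pool.dims_out);
    } else if (L.type == "fc") {
      L.din = as<int>(sp["din"]); L.dout = as<int>(sp["dout"]);
      NumericMatrix W = sp["W"];
      fmat Wf = arma::conv_to<fmat>::from(
        arma::mat(W.begin(), W.nrow(), W.ncol(), false));
      L.Wt = Wf.t();
      L.b = to_fvec(sp["b"]);
      L.mW.zeros(L.Wt.n_rows, L.Wt.n_cols);
      L.vW.zeros(L.Wt.n_rows, L.Wt.n_cols);
      L.mb.zeros(L.b.n_elem); L.vb.zeros(L.b.n_elem);
    } else if (L.type == "dropout") {
      L.drop_rate = as<float>(sp["rate"]);
    } else if (L.type != "relu" && L.type != "flatten") {
      stop("unknown layer type: " + L.type);
    }
    net.push_back(std::move(L));
  }
  // bn/relu before a conv act on that conv's input stage; flatten takes
  // the stage of the nearest preceding pool/conv output
  for (size_t i = 0; i < net.size(); ++i) {
    if (net[i].type == "flatten") {
      for (int j = (int)i - 1; j >= 0; --j) {
        if (net[j].type == "pool") { net[i].stage = net[j].stage_out; break; }
        if (net[j].type == "conv") { net[i].stage = net[j].stage; break; }
      }
    } else if (net[i].type == "bn" ||
               (net[i].type == "relu" && net[i].stage.V == 0)) {
      for (size_t j = i + 1; j < net.size(); ++j) {
        if (net[j].type == "conv") { net[i].stage = net[j].stage; break; }
        if (net[j].type == "flatten" || net[j].type == "fc") break;
      }
      if (net[i].stage.V == 0) {
        // no conv follows (post-activation placement): inherit the stage
        // of the nearest preceding spatial layer
        for (int j = (int)i - 1; j >= 0; --j) {
          if (net[j].type == "pool") { net[i].stage = net[j].stage_out; break; }
          if (net[j].type == "conv") { net[i].stage = net[j].stage; break; }
        }
      }
    }
  }
  return net;
}

// zero every non-interior row of the active region (halo + guard slabs)
static void zero_noninterior(fmat& A, const Stage& s, int B) {
  const int Vp = s.Vp;
  for (arma::uword c = 0; c < A.n_cols; ++c) {
    float* col = A.colptr(c);
    std::memset(col, 0, sizeof(float) * Vp);
    std::memset(col + (size_t)Vp * (B + 1), 0, sizeof(float) * Vp);
    for (int b = 0; b < B; ++b) {
      float* slab = col + (size_t)Vp * (1 + b);
      for (int h : s.halo) slab[h] = 0.f;
    }
  }
}

static void ensure_buf(fmat& M, size_t rows, size_t cols, int lastB, int B) {
  if (M.n_rows != rows || M.n_cols != cols) M.zeros(rows, cols);
  else if (lastB != B) M.zeros();
}

struct RNG {
  std::mt19937 gen;
  std::uniform_real_distribution<float> unif{0.f, 1.f};
  explicit RNG(unsigned seed) : gen(seed) {}
  float runif() { return unif(gen); }
  int rint(int n) { return (int)(gen() % (unsigned)n); }
};

// scratch space shared across layers (currently none needed; kept for
// future buffers)
struct Workspace {};

// row-chunk size for the per-tap convolution gemms: small enough that a
// chunk of activations plus gradients stays in the L2 cache across taps
static const size_t CONV_CHUNK = 32768;

// ---- vectorized kernels for the single-channel input convolution ------
// With one input channel the per-tap BLAS calls are rank-1 updates whose
// packing overhead dominates; these chunked kernels stream the input once
// per tap from cache. Dispatched at runtime on AVX2+FMA support.

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define SDFC_HAVE_TARGET 1
__attribute__((target("avx2,fma")))
#endif
static void conv1_fwd_kernel(const float* A, float* Y, const float* Wt,
                             const int* delta, size_t VpB, size_t ldy,
                             int cout) {
  for (size_t j0 = 0; j0 < VpB; j0 += CONV_CHUNK) {
    const size_t ch = std::min(CONV_CHUNK, VpB - j0);
    for (int o = 0; o < 27; ++o) {
      const float* a = A + delta[o] + j0;
      for (int co = 0; co < cout; ++co) {
        const float w = Wt[o + 27 * co];
        float* y = Y + (size_t)co * ldy + j0;
        if (o == 0)
          for (size_t j = 0; j < ch; ++j) y[j] = w * a[j];
        else
          for (size_t j = 0; j < ch; ++j) y[j] += w * a[j];
      }
    }
  }
}

#ifdef SDFC_HAVE_TARGET
__attribute__((target("avx2,fma")))
#endif
static void conv1_dw_kernel(const float* A, const float* D, float* dW,
                            const int* delta, size_t VpB, size_t ldd,
                            int cout) {
  for (int i = 0; i < 27 * cout; ++i) dW[i] = 0.f;
  for (size_t j0 = 0; j0 < VpB; j0 += CONV_CHUNK) {
    const size_t ch = std::min(CONV_CHUNK, VpB - j0);
    for (int o = 0; o < 27; ++o) {
      const float* a = A + delta[o] + j0;
      for (int co = 0; co < cout; ++co) {
        const float* d = D + (size_t)co * ldd + j0;
        float accv[16] = {0};
        size_t j = 0;
        for (; j + 16 <= ch; j += 16)
          for (int u = 0; u < 16; ++u) accv[u] += a[j + u] * d[j + u];
        float acc = 0;
        for (int u = 0; u < 16; ++u) acc += accv[u];
        for (; j < ch; ++j) acc += a[j] * d[j];
        dW[o + 27 * co] += acc;
      }
    }
  }
}

static bool cpu_has_avx2() {
#if defined(SDFC_HAVE_TARGET)
  static int ok = -1;
  if (ok < 0)
    ok = __builtin_cpu_supports("avx2") && __builtin_cpu_supports("fma");
  return ok == 1;
#else
  return true;  // kernels compiled with baseline flags
#endif
}

// gather the interior of a padded activation into fiber layout:
// P(o*cin + c, b*V + v) = A(slab_b + interior[v] + delta[o], c)
static void gather_patches(const fmat& A, fmat& P, const Stage& s, int cin,
                           int B) {
  const int V = s.V;
  P.set_size((size_t)cin * 27, (size_t)V * B);
  for (int b = 0; b < B; ++b) {
    const size_t slab = (size_t)s.Vp * (1 + b);
    for (int v = 0; v < V; ++v) {
      float* pc = P.colptr((size_t)b * V + v);
      const int base = s.interior[v];
      for (int o = 0; o < 27; ++o) {
        const size_t r = slab + base + s.delta[o];
        for (int c = 0; c < cin; ++c)
          pc[(size_t)o * cin + c] = A(r, c);
      }
    }
  }
}

// gather interior columns only: Y(c, b*V + v) = A(slab_b + interior[v], c)
static void gather_interior(const fmat& A, fmat& Y, const Stage& s, int C,
                            int B) {
  const int V = s.V;
  Y.set_size(C, (size_t)V * B);
  for (int b = 0; b < B; ++b) {
    const size_t slab = (size_t)s.Vp * (1 + b);
    for (int v = 0; v < V; ++v) {
      float* yc = Y.colptr((size_t)b * V + v);
      const size_t r = slab + s.interior[v];
      for (int c = 0; c < C; ++c) yc[c] = A(r, c);
    }
  }
}

// ---------------------------------------------------------------- forward

// scatter a (V x B) sample block into the padded transposed layout
static void load_input(const fmat& Xcols, fmat& A0, const Stage& s, int B,
                       int lastB) {
  ensure_buf(A0, (size_t)s.Vp * (B + 2), 1, lastB, B);
  float* col = A0.colptr(0);
  for (int b = 0; b < B; ++b) {
    float* slab = col + (size_t)s.Vp * (1 + b);
    const float* x = Xcols.colptr(b);
    for (int v = 0; v < s.V; ++v) slab[s.interior[v]] = x[v];
  }
}

static fmat* forward(std::vector<Layer>& net, fmat& A0, int B, bool train,
                     RNG& rng, Workspace& ws) {
  fmat* A = &A0;
  for (auto& L : net) {
    if (L.type == "conv") {
      const Stage& s = L.stage;
      const size_t VpB = (size_t)s.Vp * B;
      const size_t stride = (size_t)s.Vp * (B + 2);
      const int K = L.cin * 27;
      ensure_buf(L.out, stride, L.cout, L.lastB, B);
      if (L.cin == 1 && cpu_has_avx2()) {
        conv1_fwd_kernel(A->memptr() + s.Vp, L.out.memptr() + s.Vp,
                         L.Wt.memptr(), s.delta, VpB, stride, L.cout);
        for (int c = 0; c < L.cout; ++c) {
          float* y = L.out.colptr(c) + s.Vp;
          const float bc = L.b[c];
          for (size_t j = 0; j < VpB; ++j) y[j] += bc;
        }
        zero_noninterior(L.out, s, B);
        L.lastB = B;
        A = &L.out;
        continue;
      }
      if (L.compact) {
        gather_patches(*A, L.Pc, s, L.cin, B);
        fmat Yc = L.Wt.t() * L.Pc;       // (cout x V*B)
        Yc.each_col() += L.b;
        for (int b = 0; b < B; ++b) {
          const size_t slab = (size_t)s.Vp * (1 + b);
          for (int v = 0; v < s.V; ++v) {
            const float* yc = Yc.colptr((size_t)b * s.V + v);
            const size_t r = slab + s.interior[v];
            for (int c = 0; c < L.cout; ++c) L.out(r, c) = yc[c];
          }
        }
        L.lastB = B;
        A = &L.out;
        continue;
      }
      // Y_interior += A_shifted x W_o per tap, in row chunks small enough
      // that each activation chunk stays cached across the 27 taps
      for (size_t j0 = 0; j0 < VpB; j0 += CONV_CHUNK) {
        const int ch = (int)std::min(CONV_CHUNK, VpB - j0);
        for (int o = 0; o < 27; ++o)
          sgemm('N', 'N', ch, L.cout, L.cin, 1.f,
                A->memptr() + s.Vp + s.delta[o] + j0, (int)(A->n_rows),
                L.Wt.memptr() + (size_t)o * L.cin, K,
                o == 0 ? 0.f : 1.f, L.out.memptr() + s.Vp + j0,
                (int)stride);
      }
      for (int c = 0; c < L.cout; ++c) {
        float* y = L.out.colptr(c) + s.Vp;
        const float bc = L.b[c];
        for (size_t j = 0; j < VpB; ++j) y[j] += bc;
      }
      zero_noninterior(L.out, s, B);
      L.lastB = B;
      A = &L.out;
    } else if (L.type == "bn") {
      const Stage& s = L.stage;
      const size_t VpB = (size_t)s.Vp * B;
      const size_t stride = (size_t)s.Vp * (B + 2);
      const float n = (float)((size_t)s.V * B);
      const int C = A->n_cols;
      ensure_buf(L.out, stride, C, L.lastB, B);
      if (L.xhat.n_rows != stride || (int)L.xhat.n_cols != C)
        L.xhat.zeros(stride, C);
      L.istd.set_size(C);
      for (int c = 0; c < C; ++c) {
        const float* x = A->colptr(c) + s.Vp;
        float mu, istd;
        if (train) {
          double sum = 0, sq = 0;
          for (size_t j = 0; j < VpB; ++j) {
            sum += x[j];
            sq += (double)x[j] * x[j];
          }
          mu = (float)(sum / n);
          float va = (float)(sq / n) - mu * mu;
          if (va < 0) va = 0;
          L.rmean[c] = 0.9f * L.rmean[c] + 0.1f * mu;
          L.rvar[c] = 0.9f * L.rvar[c] +
            0.1f * va * (n / std::max(n - 1.f, 1.f));
          istd = 1.0f / std::sqrt(va + BN_EPS);
          L.istd[c] = istd;
        } else {
          mu = L.rmean[c];
          istd = 1.0f / std::sqrt(L.rvar[c] + BN_EPS);
        }
        const float ga = L.gamma[c], be = L.beta[c];
        float* xh = L.xhat.colptr(c) + s.Vp;
        float* y = L.out.colptr(c) + s.Vp;
        if (train) {
          for (size_t j = 0; j < VpB; ++j) {
            const float z = (x[j] - mu) * istd;
            xh[j] = z;
            y[j] = ga * z + be;
          }
        } else {
          for (size_t j = 0; j < VpB; ++j)
            y[j] = ga * (x[j] - mu) * istd + be;
        }
      }
      zero_noninterior(L.out, s, B);
      if (train) zero_noninterior(L.xhat, s, B);
      L.lastB = B;
      A = &L.out;
    } else if (L.type == "relu") {
      // applied in place: the clamped values, not the pre-activation, are
      // what the next layer needs, and the mask suffices for backward
      L.mask.set_size(A->n_rows, A->n_cols);
      float* y = A->memptr();
      float* m = L.mask.memptr();
      const size_t nel = A->n_elem;
      for (size_t j = 0; j < nel; ++j) {
        if (y[j] > 0.f) m[j] = 1.f; else { m[j] = 0.f; y[j] = 0.f; }
      }
    } else if (L.type == "pool") {
      const Stage& si = L.stage;
      const Stage& so = L.stage_out;
      const int C = A->n_cols, Vo = so.V;
      ensure_buf(L.out, (size_t)so.Vp * (B + 2), C, L.lastB, B);
      L.amax.assign((size_t)Vo * B * C, 0);
      for (int c = 0; c < C; ++c) {
        const float* xc = A->colptr(c);
        float* yc = L.out.colptr(c);
        int* am = L.amax.data() + (size_t)c * Vo * B;
        for (int b = 0; b < B; ++b) {
          const size_t ib = (size_t)si.Vp * (1 + b);
          const size_t ob = (size_t)so.Vp * (1 + b);
          for (int vo = 0; vo < Vo; ++vo) {
            const auto& srcs = L.pool.src[vo];
            const int cnt = L.pool.cnt[vo];
            size_t best_r = ib + srcs[0];
            float best = xc[best_r];
            for (int t = 1; t < cnt; ++t) {
              const size_t r = ib + srcs[t];
              if (xc[r] > best) { best = xc[r]; best_r = r; }
            }
            yc[ob + so.interior[vo]] = best;
            am[(size_t)b * Vo + vo] = (int)best_r;
          }
        }
      }
      L.lastB = B;
      A = &L.out;
    } else if (L.type == "flatten") {
      const Stage& s = L.stage;
      const int C = A->n_cols, V = s.V;
      L.out.set_size((size_t)C * V, B);
      for (int c = 0; c < C; ++c) {
        const float* xc = A->colptr(c);
        for (int b = 0; b < B; ++b) {
          float* f = L.out.colptr(b) + (size_t)c * V;
          const float* slab = xc + (size_t)s.Vp * (1 + b);
          for (int v = 0; v < V; ++v) f[v] = slab[s.interior[v]];
        }
      }
      A = &L.out;
    } else if (L.type == "fc") {
      L.out.set_size(L.dout, B);
      sgemm('T', 'N', L.dout, B, L.din, 1.f, L.Wt.memptr(), L.din,
            A->memptr(), L.din, 0.f, L.out.memptr(), L.dout);
      L.out.each_col() += L.b;
      A = &L.out;
    } else if (L.type == "dropout") {
      if (train && L.drop_rate > 0.f) {
        const float keep = 1.f - L.drop_rate;
        L.mask.set_size(A->n_rows, A->n_cols);
        L.out.set_size(A->n_rows, A->n_cols);
        const float* x = A->memptr();
        float* m = L.mask.memptr();
        float* y = L.out.memptr();
        for (size_t j = 0; j < L.out.n_elem; ++j) {
          m[j] = rng.runif() < keep ? 1.f / keep : 0.f;
          y[j] = x[j] * m[j];
        }
        A = &L.out;
      } else {
        L.mask.set_size(0, 0);  // marks the layer as inactive this pass
      }
    }
  }
  return A;
}

// --------------------------------------------------------------- backward

struct Grads {
  fmat dW; fvec db, dgamma, dbeta;
};

// the input each layer saw during the last forward pass
static fmat* layer_input(std::vector<Layer>& net, int i, fmat& A0) {
  for (int j = i - 1; j >= 0; --j) {
    if (net[j].type == "relu") continue;  // in-place
    if (net[j].type == "dropout" && net[j].mask.n_elem == 0) continue;
    return &net[j].out;
  }
  return &A0;
}

static void backprop(std::vector<Layer>& net, fmat& A0, fmat dTop, int B,
                     std::vector<Grads>& grads, Workspace& ws) {
  fmat* dA = &dTop;
  for (int i = (int)net.size() - 1; i >= 0; --i) {
    Layer& L = net[i];
    Grads& G = grads[i];
    if (L.type == "conv") {
      const Stage& s = L.stage;
      const size_t VpB = (size_t)s.Vp * B;
      const size_t stride = (size_t)s.Vp * (B + 2);
      const int K = L.cin * 27;
      zero_noninterior(*dA, s, B);
      fmat* in = layer_input(net, i, A0);
      if (i == 0 && L.cin == 1 && cpu_has_avx2()) {
        G.dW.set_size(K, L.cout);
        conv1_dw_kernel(in->memptr() + s.Vp, dA->memptr() + s.Vp,
                        G.dW.memptr(), s.delta, VpB, stride, L.cout);
        G.db.set_size(L.cout);
        for (int c = 0; c < L.cout; ++c) {
          const float* d = dA->colptr(c) + s.Vp;
          double acc = 0;
          for (size_t j = 0; j < VpB; ++j) acc += d[j];
          G.db[c] = (float)acc;
        }
        continue;  // first layer: no input gradient needed
      }
      if (L.compact) {
        gather_interior(*dA, L.dYc, s, L.cout, B);
        gather_patches(*in, L.Pc, s, L.cin, B);
        G.dW = L.Pc * L.dYc.t();         // (cin*27 x cout), Wt convention
        G.db = arma::sum(L.dYc, 1);
        if (i == 0) continue;
        fmat dPc = L.Wt * L.dYc;         // (cin*27 x V*B)
        if (L.dbuf.n_rows != stride || (int)L.dbuf.n_cols != L.cin)
          L.dbuf.set_size(stride, L.cin);
        L.dbuf.zeros();
        for (int b = 0; b < B; ++b) {
          const size_t slab = (size_t)s.Vp * (1 + b);
          for (int v = 0; v < s.V; ++v) {
            const float* pc = dPc.colptr((size_t)b * s.V + v);
            const int base = s.interior[v];
            for (int o = 0; o < 27; ++o) {
              const size_t r = slab + base + s.delta[o];
              for (int c = 0; c < L.cin; ++c)
                L.dbuf(r, c) += pc[(size_t)o * L.cin + c];
            }
          }
        }
        dA = &L.dbuf;
        continue;
      }
      G.dW.set_size(K, L.cout);  // transposed convention, like Wt
      for (size_t j0 = 0; j0 < VpB; j0 += CONV_CHUNK) {
        const int ch = (int)std::min(CONV_CHUNK, VpB - j0);
        for (int o = 0; o < 27; ++o)
          sgemm('T', 'N', L.cin, L.cout, ch, 1.f,
                in->memptr() + s.Vp + s.delta[o] + j0, (int)(in->n_rows),
                dA->memptr() + s.Vp + j0, (int)stride,
                j0 == 0 ? 0.f : 1.f, G.dW.memptr() + (size_t)o * L.cin, K);
      }
      G.db.set_size(L.cout);
      for (int c = 0; c < L.cout; ++c) {
        const float* d = dA->colptr(c) + s.Vp;
        double acc = 0;
        for (size_t j = 0; j < VpB; ++j) acc += d[j];
        G.db[c] = (float)acc;
      }
      if (i == 0) continue;  // no gradient needed wrt the network input
      if (L.dbuf.n_rows != stride || (int)L.dbuf.n_cols != L.cin)
        L.dbuf.set_size(stride, L.cin);
      L.dbuf.zeros();
      // dIn_shifted += dY x W_o^T per tap, chunked as in the forward pass
      for (size_t j0 = 0; j0 < VpB; j0 += CONV_CHUNK) {
        const int ch = (int)std::min(CONV_CHUNK, VpB - j0);
        for (int o = 0; o < 27; ++o)
          sgemm('N', 'T', ch, L.cin, L.cout, 1.f,
                dA->memptr() + s.Vp + j0, (int)stride,
                L.Wt.memptr() + (size_t)o * L.cin, K,
                1.f, L.dbuf.memptr() + s.Vp + s.delta[o] + j0,
                (int)(L.dbuf.n_rows));
      }
      dA = &L.dbuf;
    } else if (L.type == "bn") {
      const Stage& s = L.stage;
      const size_t VpB = (size_t)s.Vp * B;
      const size_t stride = (size_t)s.Vp * (B + 2);
      const float n = (float)((size_t)s.V * B);
      const int C = dA->n_cols;
      zero_noninterior(*dA, s, B);
      G.dgamma.set_size(C); G.dbeta.set_size(C);
      if (L.dbuf.n_rows != stride || (int)L.dbuf.n_cols != C)
        L.dbuf.zeros(stride, C);
      for (int c = 0; c < C; ++c) {
        const float* d = dA->colptr(c) + s.Vp;
        const float* xh = L.xhat.colptr(c) + s.Vp;
        double sdx = 0, sdxx = 0;
        for (size_t j = 0; j < VpB; ++j) {
          sdx += d[j];
          sdxx += (double)d[j] * xh[j];
        }
        G.dbeta[c] = (float)sdx;
        G.dgamma[c] = (float)sdxx;
        const float ga = L.gamma[c], istd = L.istd[c];
        const float sum_dx = (float)sdx * ga, sum_dxx = (float)sdxx * ga;
        float* dz = L.dbuf.colptr(c) + s.Vp;
        const float k = istd / n;
        for (size_t j = 0; j < VpB; ++j)
          dz[j] = k * (n * ga * d[j] - sum_dx - xh[j] * sum_dxx);
      }
      dA = &L.dbuf;
    } else if (L.type == "relu") {
      L.dbuf = (*dA) % L.mask;
      dA = &L.dbuf;
    } else if (L.type == "pool") {
      const Stage& si = L.stage;
      const Stage& so = L.stage_out;
      const int C = dA->n_cols, Vo = so.V;
      const size_t istride = (size_t)si.Vp * (B + 2);
      if (L.dbuf.n_rows != istride || (int)L.dbuf.n_cols != C)
        L.dbuf.set_size(istride, C);
      L.dbuf.zeros();
      for (int c = 0; c < C; ++c) {
        const float* dc = dA->colptr(c);
        float* di = L.dbuf.colptr(c);
        const int* am = L.amax.data() + (size_t)c * Vo * B;
        for (int b = 0; b < B; ++b) {
          const size_t ob = (size_t)so.Vp * (1 + b);
          for (int vo = 0; vo < Vo; ++vo)
            di[am[(size_t)b * Vo + vo]] += dc[ob + so.interior[vo]];
        }
      }
      dA = &L.dbuf;
    } else if (L.type == "flatten") {
      const Stage& s = L.stage;
      const int C = (int)(dA->n_rows / s.V), V = s.V;
      const size_t stride = (size_t)s.Vp * (B + 2);
      if (L.dbuf.n_rows != stride || (int)L.dbuf.n_cols != C)
        L.dbuf.set_size(stride, C);
      L.dbuf.zeros();
      for (int c = 0; c < C; ++c) {
        float* xc = L.dbuf.colptr(c);
        for (int b = 0; b < B; ++b) {
          const float* f = dA->colptr(b) + (size_t)c * V;
          float* slab = xc + (size_t)s.Vp * (1 + b);
          for (int v = 0; v < V; ++v) slab[s.interior[v]] = f[v];
        }
      }
      dA = &L.dbuf;
    } else if (L.type == "fc") {
      fmat* in = layer_input(net, i, A0);
      G.dW.set_size(L.din, L.dout);  // transposed convention
      sgemm('N', 'T', L.din, L.dout, B, 1.f, in->memptr(), L.din,
            dA->memptr(), L.dout, 0.f, G.dW.memptr(), L.din);
      G.db = arma::sum(*dA, 1);
      L.dbuf.set_size(L.din, B);
      sgemm('N', 'N', L.din, B, L.dout, 1.f, L.Wt.memptr(), L.din,
            dA->memptr(), L.dout, 0.f, L.dbuf.memptr(), L.din);
      dA = &L.dbuf;
    } else if (L.type == "dropout") {
      if (L.mask.n_elem == dA->n_elem) {
        L.dbuf = (*dA) % L.mask;
        dA = &L.dbuf;
      }
    }
  }
}

// ------------------------------------------------------------------ adam

static void adam_step(fmat& W, fmat& m, fmat& v, const fmat& g, float lr,
                      float eps, int t) {
  const float b1 = 0.9f, b2 = 0.999f;
  m = b1 * m + (1.f - b1) * g;
  v = b2 * v + (1.f - b2) * (g % g);
  const float c1 = 1.f - std::pow(b1, (float)t);
  const float c2 = 1.f - std::pow(b2, (float)t);
  W -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

static void adam_step_v(fvec& W, fvec& m, fvec& v, const fvec& g, float lr,
                        float eps, int t) {
  const float b1 = 0.9f, b2 = 0.999f;
  m = b1 * m + (1.f - b1) * g;
  v = b2 * v + (1.f - b2) * (g % g);
  const float c1 = 1.f - std::pow(b1, (float)t);
  const float c2 = 1.f - std::pow(b2, (float)t);
  W -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

// softmax cross-entropy; fills dLogits, returns (loss_sum, n_correct)
static std::pair<double, int> softmax_xent(const fmat& logits,
                                           const std::vector<int>& y,
                                           fmat& dLogits, fmat& probs) {
  const int B = logits.n_cols, K = logits.n_rows;
  probs.set_size(K, B);
  dLogits.set_size(K, B);
  double loss = 0.0; int correct = 0;
  for (int b = 0; b < B; ++b) {
    const float mx = logits.col(b).max();
    fvec e = arma::exp(logits.col(b) - mx);
    const float sm = arma::accu(e);
    fvec p = e / sm;
    probs.col(b) = p;
    loss += -std::log(std::max(p[y[b]], 1e-12f));
    dLogits.col(b) = p;
    dLogits(y[b], b) -= 1.f;
    if ((int)p.index_max() == y[b]) ++correct;
  }
  dLogits /= (float)B;
  return {loss, correct};
}

static fmat to_fmat(NumericMatrix X) {
  arma::mat Xd(X.begin(), X.nrow(), X.ncol(), false);
  return arma::conv_to<fmat>::from(Xd);
}

static void write_back(List layers, const std::vector<Layer>& net) {
  for (int i = 0; i < layers.size(); ++i) {
    List sp = layers[i];
    const Layer& L = net[i];
    if (L.type == "conv" || L.type == "fc") {
      fmat W = L.Wt.t();
      NumericMatrix Wout(W.n_rows, W.n_cols);
      std::copy(W.begin(), W.end(), Wout.begin());
      NumericVector b(L.b.n_elem);
      std::copy(L.b.begin(), L.b.end(), b.begin());
      sp["W"] = Wout; sp["b"] = b;
    } else if (L.type == "bn") {
      auto out = [](const fvec& v) {
        NumericVector o(v.n_elem);
        std::copy(v.begin(), v.end(), o.begin());
        return o;
      };
      sp["gamma"] = out(L.gamma); sp["beta"] = out(L.beta);
      sp["running_mean"] = out(L.rmean); sp["running_var"] = out(L.rvar);
    }
    layers[i] = sp;
  }
}

static const Stage& input_stage(const std::vector<Layer>& net) {
  for (const auto& L : net)
    if (L.type == "conv") return L.stage;
  stop("network has no convolution layer");
}

static fmat predict_probs(std::vector<Layer>& net, const fmat& X,
                          const std::vector<int>& idx, int batch, RNG& rng,
                          Workspace& ws, fmat& A0, int& lastB0) {
  const int n = (int)idx.size();
  int K = 2;
  for (int i = (int)net.size() - 1; i >= 0; --i)
    if (net[i].type == "fc") { K = net[i].dout; break; }
  const Stage& s0 = input_stage(net);
  fmat probs(K, n);
  int done = 0;
  while (done < n) {
    const int B = std::min(batch, n - done);
    fmat Xb(X.n_rows, B);
    for (int b = 0; b < B; ++b) Xb.col(b) = X.col(idx[done + b]);
    load_input(Xb, A0, s0, B, lastB0);
    lastB0 = B;
    fmat* logits = forward(net, A0, B, false, rng, ws);
    for (int b = 0; b < B; ++b) {
      const float mx = logits->col(b).max();
      fvec e = arma::exp(logits->col(b) - mx);
      probs.col(done + b) = e / arma::accu(e);
    }
    done += B;
  }
  return probs;
}

// [[Rcpp::export]]
List cnn_train_cpp(List layers, NumericMatrix X, IntegerVector y,
                   IntegerVector train_idx, IntegerVector val_idx,
                   List hyper) {
  std::vector<Layer> net = parse_layers(layers);
  const fmat Xf = to_fmat(X);
  const int epochs = as<int>(hyper["epochs"]);
  const int batch = as<int>(hyper["batch"]);
  const float lr0 = as<float>(hyper["lr0"]);
  const int half = as<int>(hyper["lr_half_period"]);
  const float eps = as<float>(hyper["adam_epsilon"]);
  RNG rng(as<unsigned>(hyper["seed"]));
  Workspace ws;
  const Stage& s0 = input_stage(net);
  fmat A0;
  int lastB0 = -1;

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  for (auto& i : tr) --i;
  for (auto& i : va) --i;
  std::vector<int> yy(y.begin(), y.end());

  std::vector<Grads> grads(net.size());
  NumericVector ep_loss(epochs), ep_acc(epochs), ep_vloss(epochs),
    ep_vacc(epochs), ep_lr(epochs);
  int t_adam = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    const float lr = lr0 * std::pow(0.5f, (float)(ep / half));
    for (int i = (int)tr.size() - 1; i > 0; --i)
      std::swap(tr[i], tr[rng.rint(i + 1)]);
    double loss_sum = 0; int correct = 0, seen = 0;
    for (size_t off = 0; off < tr.size(); off += batch) {
      const int B = std::min<size_t>(batch, tr.size() - off);
      fmat Xb(Xf.n_rows, B);
      std::vector<int> yb(B);
      for (int b = 0; b < B; ++b) {
        Xb.col(b) = Xf.col(tr[off + b]);
        yb[b] = yy[tr[off + b]];
      }
      load_input(Xb, A0, s0, B, lastB0);
      lastB0 = B;
      fmat* logits = forward(net, A0, B, true, rng, ws);
      fmat dLogits, probs;
      auto res = softmax_xent(*logits, yb, dLogits, probs);
      if (!std::isfinite(res.first))
        stop("non-finite training loss at epoch %d (lr %g)", ep + 1, lr);
      loss_sum += res.first; correct += res.second; seen += B;
      backprop(net, A0, dLogits, B, grads, ws);
      ++t_adam;
      for (size_t li = 0; li < net.size(); ++li) {
        Layer& L = net[li];
        Grads& G = grads[li];
        if (L.type == "conv" || L.type == "fc") {
          adam_step(L.Wt, L.mW, L.vW, G.dW, lr, eps, t_adam);
          adam_step_v(L.b, L.mb, L.vb, G.db, lr, eps, t_adam);
        } else if (L.type == "bn") {
          adam_step_v(L.gamma, L.mg, L.vg, G.dgamma, lr, eps, t_adam);
          adam_step_v(L.beta, L.mbt, L.vbt, G.dbeta, lr, eps, t_adam);
        }
      }
    }
    ep_loss[ep] = loss_sum / seen;
    ep_acc[ep] = (double)correct / seen;
    ep_lr[ep] = lr;
    if (!va.empty()) {
      fmat vp = predict_probs(net, Xf, va, batch, rng, ws, A0, lastB0);
      double vloss = 0; int vcorrect = 0;
      for (size_t b = 0; b < va.size(); ++b) {
        vloss += -std::log(std::max(vp(yy[va[b]], b), 1e-12f));
        if ((int)vp.col(b).index_max() == yy[va[b]]) ++vcorrect;
      }
      ep_vloss[ep] = vloss / va.size();
      ep_vacc[ep] = (double)vcorrect / va.size();
    } else {
      ep_vloss[ep] = NA_REAL; ep_vacc[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  List out_layers = clone(layers);
  write_back(out_layers, net);
  DataFrame log = DataFrame::create(
    _["epoch"] = seq_len(epochs), _["lr"] = ep_lr,
    _["train_loss"] = ep_loss, _["train_acc"] = ep_acc,
    _["val_loss"] = ep_vloss, _["val_acc"] = ep_vacc);
  return List::create(_["layers"] = out_layers, _["log"] = log);
}

// training-mode loss and parameter gradients on one batch (no update);
// used by the finite-difference gradient checks in the test suite
// [[Rcpp::export]]
List cnn_loss_grad_cpp(List layers, NumericMatrix X, IntegerVector y,
                       int seed = 0) {
  std::vector<Layer> net = parse_layers(layers);
  const fmat Xf = to_fmat(X);
  const int B = X.ncol();
  RNG rng((unsigned)seed);
  Workspace ws;
  const Stage& s0 = input_stage(net);
  fmat A0;
  load_input(Xf, A0, s0, B, -1);
  fmat* logits = forward(net, A0, B, true, rng, ws);
  std::vector<int> yy(y.begin(), y.end());
  fmat dLogits, probs;
  auto res = softmax_xent(*logits, yy, dLogits, probs);
  std::vector<Grads> grads(net.size());
  backprop(net, A0, dLogits, B, grads, ws);
  List gout;
  for (size_t i = 0; i < net.size(); ++i) {
    const Layer& L = net[i];
    if (L.type == "conv" || L.type == "fc") {
      fmat dW = grads[i].dW.t();  // back to the R-side convention
      NumericMatrix W(dW.n_rows, dW.n_cols);
      std::copy(dW.begin(), dW.end(), W.begin());
      NumericVector db(grads[i].db.n_elem);
      std::copy(grads[i].db.begin(), grads[i].db.end(), db.begin());
      gout.push_back(List::create(_["dW"] = W, _["db"] = db));
    } else if (L.type == "bn") {
      NumericVector dg(grads[i].dgamma.n_elem), dbt(grads[i].dbeta.n_elem);
      std::copy(grads[i].dgamma.begin(), grads[i].dgamma.end(), dg.begin());
      std::copy(grads[i].dbeta.begin(), grads[i].dbeta.end(), dbt.begin());
      gout.push_back(List::create(_["dgamma"] = dg, _["dbeta"] = dbt));
    } else {
      gout.push_back(R_NilValue);
    }
  }
  return List::create(_["loss"] = res.first / B, _["grads"] = gout,
                      _["probs"] = NumericMatrix(probs.n_rows, probs.n_cols,
                                                 probs.begin()));
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List layers, NumericMatrix X, int batch = 32) {
  std::vector<Layer> net = parse_layers(layers);
  const fmat Xf = to_fmat(X);
  std::vector<int> idx(X.ncol());
  for (int i = 0; i < X.ncol(); ++i) idx[i] = i;
  RNG rng(0);
  Workspace ws;
  fmat A0;
  int lastB0 = -1;
  fmat p = predict_probs(net, Xf, idx, batch, rng, ws, A0, lastB0);
  NumericMatrix out(p.n_rows, p.n_cols);
  std::copy(p.begin(), p.end(), out.begin());
  return out;
}
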