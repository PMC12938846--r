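// Numerical kernels: im2col-style convolutions, bilinear/trilinear sampling,
// and ray-integral radiograph rendering.  Array layouts follow R's
// column-major convention throughout:
//   2D feature maps  : dim c(h, w, C)   -> idx = y + h*x + h*w*c
//   3D volumes       : dim c(n1,n2,n3,C)-> idx = a + n1*b + n1*n2*c + n1*n2*n3*ch
// Pixel coordinates are 0-based with centers at integers, (x = column,
// y = row).

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#ifdef __GLIBC__
#include <malloc.h>
#endif
using namespace Rcpp;

// Training allocates and frees hundreds of MB of tape buffers per step; by
// default glibc serves those via mmap and returns them to the OS on free,
// which makes every step re-fault its pages (very slow under sandboxed
// kernels).  Raising the mmap/trim thresholds keeps the arena warm.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

// ---------------------------------------------------------------------------
// 2D im2col / col2im (3x3 same padding by default, arbitrary odd k)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector x, int h, int w, int cin, int k) {
  int p = k / 2;
  int n = h * w;
  NumericMatrix out(n, cin * k * k);
  for (int c = 0; c < cin; ++c) {
    const double *xc = x.begin() + (R_xlen_t)h * w * c;
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        int col = c * k * k + ky * k + kx;
        double *oc = &out(0, col);
        for (int xx = 0; xx < w; ++xx) {
          int sx = xx + kx - p;
          if (sx < 0 || sx >= w) continue;
          int ylo = std::max(0, p - ky);
          int yhi = std::min(h, h + p - ky);
          for (int yy = ylo; yy < yhi; ++yy) {
            int sy = yy + ky - p;
            oc[yy + (R_xlen_t)h * xx] = xc[sy + (R_xlen_t)h * sx];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix cols, int h, int w, int cin, int k) {
  int p = k / 2;
  NumericVector gx((R_xlen_t)h * w * cin);
  for (int c = 0; c < cin; ++c) {
    double *xc = gx.begin() + (R_xlen_t)h * w * c;
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        int col = c * k * k + ky * k + kx;
        const double *oc = &cols(0, col);
        for (int xx = 0; xx < w; ++xx) {
          int sx = xx + kx - p;
          if (sx < 0 || sx >= w) continue;
          int ylo = std::max(0, p - ky);
          int yhi = std::min(h, h + p - ky);
          for (int yy = ylo; yy < yhi; ++yy) {
            int sy = yy + ky - p;
            xc[sy + (R_xlen_t)h * sx] += oc[yy + (R_xlen_t)h * xx];
          }
        }
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// 3D convolution, k = 3, same zero padding, slab-wise im2col to bound memory
// ---------------------------------------------------------------------------

static void im2col3d_slab(const double *x, int n1, int n2, int n3, int cin,
                          int z0, int z1, arma::mat &cols) {
  // cols: (n1*n2*(z1-z0)) x (cin*27); column layout ch*27 + (dc+1)*9 + (db+1)*3 + (da+1).
  // Writes every entry (zeros for out-of-range taps), so the buffer need
  // not be pre-zeroed and can be reused across slabs.
  int nz = z1 - z0;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int ch = 0; ch < cin; ++ch) {
    const double *xc = x + plane * n3 * ch;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int db = -1; db <= 1; ++db) {
        for (int da = -1; da <= 1; ++da) {
          int col = ch * 27 + (dc + 1) * 9 + (db + 1) * 3 + (da + 1);
          double *o = cols.colptr(col);
          for (int z = 0; z < nz; ++z) {
            int sc = z + z0 + dc;
            if (sc < 0 || sc >= n3) {
              std::fill(o + plane * z, o + plane * (z + 1), 0.0);
              continue;
            }
            for (int b = 0; b < n2; ++b) {
              int sb = b + db;
              double *dst = o + plane * z + (R_xlen_t)n1 * b;
              if (sb < 0 || sb >= n2) {
                std::fill(dst, dst + n1, 0.0);
                continue;
              }
              int alo = std::max(0, -da), ahi = std::min(n1, n1 - da);
              const double *src = xc + plane * sc + (R_xlen_t)n1 * sb;
              for (int a = 0; a < alo; ++a) dst[a] = 0.0;
              for (int a = alo; a < ahi; ++a) dst[a] = src[a + da];
              for (int a = ahi; a < n1; ++a) dst[a] = 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im3d_slab(const arma::mat &cols, int n1, int n2, int n3,
                          int cin, int z0, int z1, double *gx) {
  int nz = z1 - z0;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int ch = 0; ch < cin; ++ch) {
    double *xc = gx + plane * n3 * ch;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int db = -1; db <= 1; ++db) {
        for (int da = -1; da <= 1; ++da) {
          int col = ch * 27 + (dc + 1) * 9 + (db + 1) * 3 + (da + 1);
          const double *o = cols.colptr(col);
          for (int z = 0; z < nz; ++z) {
            int sc = z + z0 + dc;
            if (sc < 0 || sc >= n3) continue;
            for (int b = 0; b < n2; ++b) {
              int sb = b + db;
              if (sb < 0 || sb >= n2) continue;
              int alo = std::max(0, -da), ahi = std::min(n1, n1 - da);
              double *dst = xc + plane * sc + (R_xlen_t)n1 * sb;
              const double *src = o + plane * z + (R_xlen_t)n1 * b;
              for (int a = alo; a < ahi; ++a) dst[a + da] += src[a];
            }
          }
        }
      }
    }
  }
}

// Shift-GEMM 3x3x3 convolution: copy the volume once into a zero-padded
// buffer; each of the 27 kernel taps then corresponds to a constant row
// offset in the padded flat index, so the whole tap reduces to one BLAS
// dgemm on a pointer-offset view with leading dimension = padded size.
// Interior voxels only ever read in-bounds (zero) padding, so results are
// exact; junk accumulated at padded border rows is never read back.

static void pad_volume(const double *x, int n1, int n2, int n3, int C,
                       double *xp, int m1, int m2, int m3, int p) {
  R_xlen_t npad = (R_xlen_t)m1 * m2 * m3, nvox = (R_xlen_t)n1 * n2 * n3;
  std::fill(xp, xp + npad * C, 0.0);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < n3; ++c)
      for (int b = 0; b < n2; ++b)
        std::copy(x + nvox * ch + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c),
                  x + nvox * ch + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c) + n1,
                  xp + npad * ch + p + (R_xlen_t)m1 * (b + p) +
                    (R_xlen_t)m1 * m2 * (c + p));
}

static void unpad_volume(const double *xp, int m1, int m2, int m3, int C,
                         double *x, int n1, int n2, int n3, int p) {
  R_xlen_t npad = (R_xlen_t)m1 * m2 * m3, nvox = (R_xlen_t)n1 * n2 * n3;
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < n3; ++c)
      for (int b = 0; b < n2; ++b) {
        const double *src = xp + npad * ch + p + (R_xlen_t)m1 * (b + p) +
          (R_xlen_t)m1 * m2 * (c + p);
        double *dst = x + nvox * ch + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c);
        std::copy(src, src + n1, dst);
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims, int cin,
                            NumericMatrix W, NumericVector bias, int dil = 1) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int m1 = n1 + 2 * dil, m2 = n2 + 2 * dil, m3 = n3 + 2 * dil;
  int cout = W.ncol();
  R_xlen_t nvox = (R_xlen_t)n1 * n2 * n3, npad = (R_xlen_t)m1 * m2 * m3;
  std::vector<double> xp(npad * cin), z(npad * cout, 0.0);
  pad_volume(x.begin(), n1, n2, n3, cin, xp.data(), m1, m2, m3, dil);
  const double one = 1.0;
  int ldx = (int)npad;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        int tap = (dc + 1) * 9 + (db + 1) * 3 + (da + 1);
        long delta = (long)dil * (da + (long)m1 * db + (long)m1 * m2 * dc);
        int L = (int)(npad - std::labs(delta));
        // gather W_tap as a cin x cout block (rows tap, tap+27, ...)
        std::vector<double> wt((size_t)cin * cout);
        for (int co = 0; co < cout; ++co)
          for (int ci = 0; ci < cin; ++ci)
            wt[(size_t)cin * co + ci] = W(ci * 27 + tap, co);
        const double *A = xp.data() + std::max(delta, 0L);
        double *C = z.data() + std::max(-delta, 0L);
        F77_CALL(dgemm)("N", "N", &L, &cout, &cin, &one, A, &ldx,
                        wt.data(), &cin, &one, C, &ldx FCONE FCONE);
      }
  NumericVector y(nvox * cout);
  unpad_volume(z.data(), m1, m2, m3, cout, y.begin(), n1, n2, n3, dil);
  for (int co = 0; co < cout; ++co) {
    double *yc = y.begin() + nvox * co, bc = bias[co];
    for (R_xlen_t i = 0; i < nvox; ++i) yc[i] += bc;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims, int cin,
                   NumericMatrix W, NumericVector gy, int dil = 1) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int m1 = n1 + 2 * dil, m2 = n2 + 2 * dil, m3 = n3 + 2 * dil;
  int cout = W.ncol();
  R_xlen_t nvox = (R_xlen_t)n1 * n2 * n3, npad = (R_xlen_t)m1 * m2 * m3;
  std::vector<double> xp(npad * cin), gp(npad * cout), gxp(npad * cin, 0.0);
  pad_volume(x.begin(), n1, n2, n3, cin, xp.data(), m1, m2, m3, dil);
  pad_volume(gy.begin(), n1, n2, n3, cout, gp.data(), m1, m2, m3, dil);
  NumericMatrix gW(W.nrow(), cout);
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) {
    const double *gc = gy.begin() + nvox * co;
    double s = 0;
    for (R_xlen_t i = 0; i < nvox; ++i) s += gc[i];
    gb[co] = s;
  }
  const double one = 1.0, zero = 0.0;
  int ldx = (int)npad;
  std::vector<double> wt((size_t)cin * cout), gwt((size_t)cin * cout);
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        int tap = (dc + 1) * 9 + (db + 1) * 3 + (da + 1);
        long delta = (long)dil * (da + (long)m1 * db + (long)m1 * m2 * dc);
        int L = (int)(npad - std::labs(delta));
        const double *A = xp.data() + std::max(delta, 0L);     // x view
        const double *G = gp.data() + std::max(-delta, 0L);    // gy view
        // gW_tap = A^T G  (cin x cout)
        F77_CALL(dgemm)("T", "N", &cin, &cout, &L, &one, A, &ldx,
                        G, &ldx, &zero, gwt.data(), &cin FCONE FCONE);
        for (int co = 0; co < cout; ++co)
          for (int ci = 0; ci < cin; ++ci)
            gW(ci * 27 + tap, co) += gwt[(size_t)cin * co + ci];
        // gx view += G W_tap^T
        for (int co = 0; co < cout; ++co)
          for (int ci = 0; ci < cin; ++ci)
            wt[(size_t)cin * co + ci] = W(ci * 27 + tap, co);
        double *GX = gxp.data() + std::max(delta, 0L);
        F77_CALL(dgemm)("N", "T", &L, &cin, &cout, &one, G, &ldx,
                        wt.data(), &cin, &one, GX, &ldx FCONE FCONE);
      }
  NumericVector gx(nvox * cin);
  unpad_volume(gxp.data(), m1, m2, m3, cin, gx.begin(), n1, n2, n3, dil);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Bilinear sampling of a (h, w, C) map at continuous pixel locations
// ---------------------------------------------------------------------------

// Decode sampling locations once into 4 tap indices + weights, then gather
// channel-by-channel so each image plane stays cache-resident.
struct BilinTaps {
  std::vector<R_xlen_t> idx;  // 4 per point, -1 for out-of-image taps
  std::vector<double> wt;     // 4 per point
};

static void bilin_decode(const NumericMatrix &uv, int h, int w, BilinTaps &t) {
  int n = uv.nrow();
  t.idx.assign((size_t)4 * n, -1);
  t.wt.assign((size_t)4 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    double x = uv(i, 0), y = uv(i, 1);
    if (!R_finite(x) || !R_finite(y)) continue;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double fx = x - x0, fy = y - y0;
    int k = 0;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx, ++k) {
        int xx = x0 + dx;
        if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
        double wv = wy * (dx ? fx : 1.0 - fx);
        if (wv == 0.0) continue;
        t.idx[(size_t)4 * i + k] = yy + (R_xlen_t)h * xx;
        t.wt[(size_t)4 * i + k] = wv;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bilin_fw(NumericVector img, int h, int w, int C,
                           NumericMatrix uv) {
  int n = uv.nrow();
  NumericMatrix out(n, C);
  BilinTaps t;
  bilin_decode(uv, h, w, t);
  R_xlen_t plane = (R_xlen_t)h * w;
  for (int c = 0; c < C; ++c) {
    const double *pc = img.begin() + plane * c;
    double *oc = &out(0, c);
    for (int i = 0; i < n; ++i) {
      const R_xlen_t *id = &t.idx[(size_t)4 * i];
      const double *wv = &t.wt[(size_t)4 * i];
      double acc = 0.0;
      for (int k = 0; k < 4; ++k)
        if (id[k] >= 0) acc += wv[k] * pc[id[k]];
      oc[i] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bilin_bw(int h, int w, int C, NumericMatrix uv,
                           NumericMatrix gy) {
  int n = uv.nrow();
  NumericVector gimg((R_xlen_t)h * w * C);
  BilinTaps t;
  bilin_decode(uv, h, w, t);
  R_xlen_t plane = (R_xlen_t)h * w;
  for (int c = 0; c < C; ++c) {
    double *pc = gimg.begin() + plane * c;
    const double *gc = &gy(0, c);
    for (int i = 0; i < n; ++i) {
      const R_xlen_t *id = &t.idx[(size_t)4 * i];
      const double *wv = &t.wt[(size_t)4 * i];
      for (int k = 0; k < 4; ++k)
        if (id[k] >= 0) pc[id[k]] += wv[k] * gc[i];
    }
  }
  return gimg;
}

// ---------------------------------------------------------------------------
// Trilinear sampling of a scalar volume at world points (used by the pose
// resampler); volume has isotropic/anisotropic spacing, origin at the center
// of voxel (0,0,0).
// ---------------------------------------------------------------------------

static inline double trilerp(const double *vol, int n1, int n2, int n3,
                             double a, double b, double c) {
  if (a < -1 || b < -1 || c < -1 || a > n1 || b > n2 || c > n3) return 0.0;
  int a0 = (int)std::floor(a), b0 = (int)std::floor(b), c0 = (int)std::floor(c);
  double fa = a - a0, fb = b - b0, fc = c - c0;
  double out = 0.0;
  for (int dc = 0; dc <= 1; ++dc) {
    int cc = c0 + dc;
    if (cc < 0 || cc >= n3) continue;
    double wc = dc ? fc : 1.0 - fc;
    for (int db = 0; db <= 1; ++db) {
      int bb = b0 + db;
      if (bb < 0 || bb >= n2) continue;
      double wb = wc * (db ? fb : 1.0 - fb);
      for (int da = 0; da <= 1; ++da) {
        int aa = a0 + da;
        if (aa < 0 || aa >= n1) continue;
        double wt = wb * (da ? fa : 1.0 - fa);
        if (wt != 0.0)
          out += wt * vol[aa + (R_xlen_t)n1 * bb + (R_xlen_t)n1 * n2 * cc];
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trilerp(NumericVector vol, IntegerVector dims,
                          NumericVector origin, NumericVector spacing,
                          NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a = (pts(i, 0) - origin[0]) / spacing[0];
    double b = (pts(i, 1) - origin[1]) / spacing[1];
    double c = (pts(i, 2) - origin[2]) / spacing[2];
    out[i] = trilerp(vol.begin(), dims[0], dims[1], dims[2], a, b, c);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Ray-integral radiograph rendering: for each pixel, integrate attenuation
// along the ray src + t * dir with a fixed world-space step, clipped to the
// volume bounding box.  Linear in attenuation (no normalization here).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_drr(NumericVector vol, IntegerVector dims,
                      NumericVector origin, NumericVector spacing,
                      NumericVector src, NumericMatrix dirs, double step) {
  int n = dirs.nrow();
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(n);
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = origin[k] - 0.5 * spacing[k];
    hi[k] = origin[k] + spacing[k] * (dims[k] - 0.5);
  }
  for (int i = 0; i < n; ++i) {
    double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (nrm <= 0) { out[i] = NA_REAL; continue; }
    for (int k = 0; k < 3; ++k) d[k] /= nrm;
    double t0 = 0.0, t1 = R_PosInf;
    bool miss = false;
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(d[k]) < 1e-12) {
        if (src[k] < lo[k] || src[k] > hi[k]) { miss = true; break; }
      } else {
        double ta = (lo[k] - src[k]) / d[k];
        double tb = (hi[k] - src[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    if (miss || t1 <= t0) { out[i] = 0.0; continue; }
    double acc = 0.0;
    for (double t = t0 + 0.5 * step; t < t1; t += step) {
      double a = (src[0] + t * d[0] - origin[0]) / spacing[0];
      double b = (src[1] + t * d[1] - origin[1]) / spacing[1];
      double c = (src[2] + t * d[2] - origin[2]) / spacing[2];
      acc += trilerp(vol.begin(), n1, n2, n3, a, b, c);
    }
    out[i] = acc * step;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused per-slot voxel softmax + soft-argmax over an (nvox, N) logit stack.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_softargmax_slots(NumericVector logits, R_xlen_t nvox, int N,
                          NumericMatrix centers, double temp) {
  NumericMatrix coords(N, 3), P(nvox, N);
  for (int n = 0; n < N; ++n) {
    const double *v = logits.begin() + nvox * n;
    double m = v[0];
    for (R_xlen_t i = 1; i < nvox; ++i) if (v[i] > m) m = v[i];
    double s = 0;
    double *p = &P(0, n);
    for (R_xlen_t i = 0; i < nvox; ++i) { p[i] = std::exp((v[i] - m) / temp); s += p[i]; }
    double cx = 0, cy = 0, cz = 0;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      p[i] /= s;
      cx += p[i] * centers(i, 0);
      cy += p[i] * centers(i, 1);
      cz += p[i] * centers(i, 2);
    }
    coords(n, 0) = cx; coords(n, 1) = cy; coords(n, 2) = cz;
  }
  return List::create(_["coords"] = coords, _["P"] = P);
}

// [[Rcpp::export]]
NumericVector cpp_softargmax_slots_bw(NumericMatrix P, NumericMatrix centers,
                                      NumericMatrix coords,
                                      NumericMatrix gcoords, double temp) {
  R_xlen_t nvox = P.nrow();
  int N = P.ncol();
  NumericVector gx(nvox * N);
  for (int n = 0; n < N; ++n) {
    const double *p = &P(0, n);
    double g0 = gcoords(n, 0), g1 = gcoords(n, 1), g2 = gcoords(n, 2);
    double dot = coords(n, 0) * g0 + coords(n, 1) * g1 + coords(n, 2) * g2;
    double *o = gx.begin() + nvox * n;
    for (R_xlen_t i = 0; i < nvox; ++i)
      o[i] = p[i] * (centers(i, 0) * g0 + centers(i, 1) * g1 +
                     centers(i, 2) * g2 - dot) / temp;
  }
  return gx;
}

// ---------------------------------------------------------------------------
// 2D max pooling with stride = window (used by the context module), plus
// argmax bookkeeping for the backward pass.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int h, int w, int C, int f) {
  int ho = h / f, wo = w / f;
  NumericVector y((R_xlen_t)ho * wo * C);
  IntegerVector idx((R_xlen_t)ho * wo * C);  // 1-based flat index into x
  for (int c = 0; c < C; ++c) {
    const double *xc = x.begin() + (R_xlen_t)h * w * c;
    double *yc = y.begin() + (R_xlen_t)ho * wo * c;
    int *ic = idx.begin() + (R_xlen_t)ho * wo * c;
    for (int xo = 0; xo < wo; ++xo) {
      for (int yo = 0; yo < ho; ++yo) {
        double best = R_NegInf;
        R_xlen_t barg = 0;
        for (int dx = 0; dx < f; ++dx) {
          for (int dy = 0; dy < f; ++dy) {
            R_xlen_t src = (R_xlen_t)(yo * f + dy) + (R_xlen_t)h * (xo * f + dx);
            if (xc[src] > best) { best = xc[src]; barg = src; }
          }
        }
        yc[yo + (R_xlen_t)ho * xo] = best;
        ic[yo + (R_xlen_t)ho * xo] = (int)(barg + (R_xlen_t)h * w * c) + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}
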