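// Convolution kernels: im2col + GEMM (BLAS) with output-z slab chunking to
// bound the col-buffer memory.
#include <RcppArmadillo.h>
#include <queue>
#include <limits>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &a, int d[4]) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() == 3) { d[0]=dm[0]; d[1]=dm[1]; d[2]=dm[2]; d[3]=1; }
  else { d[0]=dm[0]; d[1]=dm[1]; d[2]=dm[2]; d[3]=dm[3]; }
}

static inline int conv_out(int n, int k, int s, int p) {
  return (n + 2*p - k) / s + 1;
}

// fill col (N_slab x K) for output rows oz in [oz0, oz0+nz); K = kx*ky*kz*ci
static void im2col_slab(const double *xp, const int X, const int Y, const int Z,
                        const int ci_n, const int kx, const int ky, const int kz,
                        const int sx, const int sy, const int sz,
                        const int px, const int py, const int pz,
                        const int Xo, const int Yo,
                        const int oz0, const int nz, double *col) {
  const R_xlen_t Ns = (R_xlen_t)Xo * Yo * nz;
  R_xlen_t k = 0;
  for (int ci = 0; ci < ci_n; ++ci) {
    const double *xci = xp + ((R_xlen_t)ci) * X * Y * Z;
    for (int dz = 0; dz < kz; ++dz)
    for (int dy = 0; dy < ky; ++dy)
    for (int dx = 0; dx < kx; ++dx, ++k) {
      double *ck = col + k * Ns;
      R_xlen_t n = 0;
      for (int ozr = 0; ozr < nz; ++ozr) {
        int iz = (oz0 + ozr) * sz - pz + dz;
        bool z_ok = (iz >= 0 && iz < Z);
        for (int oy = 0; oy < Yo; ++oy) {
          int iy = oy * sy - py + dy;
          if (!z_ok || iy < 0 || iy >= Y) {
            for (int ox = 0; ox < Xo; ++ox) ck[n++] = 0.0;
            continue;
          }
          const double *xrow = xci + X * ((R_xlen_t)iy + (R_xlen_t)Y * iz);
          for (int ox = 0; ox < Xo; ++ox) {
            int ix = ox * sx - px + dx;
            ck[n++] = (ix >= 0 && ix < X) ? xrow[ix] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add t(col)-shaped gradient back to gx
static void col2im_add_slab(const double *col, const int X, const int Y, const int Z,
                            const int ci_n, const int kx, const int ky, const int kz,
                            const int sx, const int sy, const int sz,
                            const int px, const int py, const int pz,
                            const int Xo, const int Yo,
                            const int oz0, const int nz, double *gxp) {
  const R_xlen_t Ns = (R_xlen_t)Xo * Yo * nz;
  R_xlen_t k = 0;
  for (int ci = 0; ci < ci_n; ++ci) {
    double *xci = gxp + ((R_xlen_t)ci) * X * Y * Z;
    for (int dz = 0; dz < kz; ++dz)
    for (int dy = 0; dy < ky; ++dy)
    for (int dx = 0; dx < kx; ++dx, ++k) {
      const double *ck = col + k * Ns;
      R_xlen_t n = 0;
      for (int ozr = 0; ozr < nz; ++ozr) {
        int iz = (oz0 + ozr) * sz - pz + dz;
        bool z_ok = (iz >= 0 && iz < Z);
        for (int oy = 0; oy < Yo; ++oy) {
          int iy = oy * sy - py + dy;
          if (!z_ok || iy < 0 || iy >= Y) { n += Xo; continue; }
          double *xrow = xci + X * ((R_xlen_t)iy + (R_xlen_t)Y * iz);
          for (int ox = 0; ox < Xo; ++ox) {
            int ix = ox * sx - px + dx;
            if (ix >= 0 && ix < X) xrow[ix] += ck[n];
            ++n;
          }
        }
      }
    }
  }
}

static int slab_size(R_xlen_t plane, R_xlen_t K) {
  // keep the col buffer near 8M doubles (~64 MB)
  R_xlen_t per = plane * K;
  int nz = (int)std::max((R_xlen_t)1, (R_xlen_t)(8000000 / std::max(per, (R_xlen_t)1)));
  return nz;
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       IntegerVector stride, IntegerVector pad) {
  int xd[4]; get_dims4(x, xd);
  IntegerVector wd = w.attr("dim");
  const int kx = wd[0], ky = wd[1], kz = wd[2], ci_n = wd[3], co_n = wd[4];
  const int X = xd[0], Y = xd[1], Z = xd[2];
  if (xd[3] != ci_n) stop("channel mismatch in conv_fwd");
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const int Xo = conv_out(X, kx, sx, px), Yo = conv_out(Y, ky, sy, py),
            Zo = conv_out(Z, kz, sz, pz);
  const R_xlen_t K = (R_xlen_t)kx * ky * kz * ci_n;
  NumericVector y(((R_xlen_t)Xo) * Yo * Zo * co_n);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, co_n);
  arma::mat Wm(w.begin(), K, co_n, false, true);
  const int nzb = slab_size((R_xlen_t)Xo * Yo, K);
  arma::mat col((R_xlen_t)Xo * Yo * std::min(nzb, Zo), K);
  for (int oz0 = 0; oz0 < Zo; oz0 += nzb) {
    int nz = std::min(nzb, Zo - oz0);
    R_xlen_t Ns = (R_xlen_t)Xo * Yo * nz;
    if ((R_xlen_t)col.n_rows != Ns) col.set_size(Ns, K);
    im2col_slab(x.begin(), X, Y, Z, ci_n, kx, ky, kz, sx, sy, sz,
                px, py, pz, Xo, Yo, oz0, nz, col.memptr());
    arma::mat ys = col * Wm;  // Ns x co
    double *yp = y.begin();
    for (int co = 0; co < co_n; ++co) {
      double *dst = yp + ((R_xlen_t)co) * Xo * Yo * Zo + (R_xlen_t)oz0 * Xo * Yo;
      const double *src = ys.colptr(co);
      double bc = b[co];
      for (R_xlen_t i = 0; i < Ns; ++i) dst[i] = src[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv_bwd_x")]]
NumericVector conv_bwd_x(NumericVector gy, NumericVector w,
                         IntegerVector stride, IntegerVector pad,
                         IntegerVector xdim) {
  int gd[4]; get_dims4(gy, gd);
  IntegerVector wd = w.attr("dim");
  const int kx = wd[0], ky = wd[1], kz = wd[2], ci_n = wd[3], co_n = wd[4];
  const int Xo = gd[0], Yo = gd[1], Zo = gd[2];
  if (gd[3] != co_n) stop("channel mismatch in conv_bwd_x");
  const int X = xdim[0], Y = xdim[1], Z = xdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const R_xlen_t K = (R_xlen_t)kx * ky * kz * ci_n;
  NumericVector gx(((R_xlen_t)X) * Y * Z * ci_n);
  gx.attr("dim") = IntegerVector::create(X, Y, Z, ci_n);
  arma::mat Wm(w.begin(), K, co_n, false, true);
  const int nzb = slab_size((R_xlen_t)Xo * Yo, K);
  for (int oz0 = 0; oz0 < Zo; oz0 += nzb) {
    int nz = std::min(nzb, Zo - oz0);
    R_xlen_t Ns = (R_xlen_t)Xo * Yo * nz;
    arma::mat gys(Ns, co_n);
    const double *gp = gy.begin();
    for (int co = 0; co < co_n; ++co) {
      const double *src = gp + ((R_xlen_t)co) * Xo * Yo * Zo + (R_xlen_t)oz0 * Xo * Yo;
      std::copy(src, src + Ns, gys.colptr(co));
    }
    arma::mat gcol = gys * Wm.t();  // Ns x K
    col2im_add_slab(gcol.memptr(), X, Y, Z, ci_n, kx, ky, kz, sx, sy, sz,
                    px, py, pz, Xo, Yo, oz0, nz, gx.begin());
  }
  return gx;
}

// [[Rcpp::export(name = ".conv_bwd_w")]]
List conv_bwd_w(NumericVector x, NumericVector gy, IntegerVector kdim,
                IntegerVector stride, IntegerVector pad) {
  int xd[4], gd[4]; get_dims4(x, xd); get_dims4(gy, gd);
  const int X = xd[0], Y = xd[1], Z = xd[2], ci_n = xd[3];
  const int Xo = gd[0], Yo = gd[1], Zo = gd[2], co_n = gd[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int px = pad[0], py = pad[1], pz = pad[2];
  const R_xlen_t K = (R_xlen_t)kx * ky * kz * ci_n;
  NumericVector gw(K * co_n);
  gw.attr("dim") = IntegerVector::create(kx, ky, kz, ci_n, co_n);
  NumericVector gb(co_n);
  arma::mat GW(gw.begin(), K, co_n, false, true);
  const int nzb = slab_size((R_xlen_t)Xo * Yo, K);
  arma::mat col((R_xlen_t)Xo * Yo * std::min(nzb, Zo), K);
  for (int oz0 = 0; oz0 < Zo; oz0 += nzb) {
    int nz = std::min(nzb, Zo - oz0);
    R_xlen_t Ns = (R_xlen_t)Xo * Yo * nz;
    if ((R_xlen_t)col.n_rows != Ns) col.set_size(Ns, K);
    im2col_slab(x.begin(), X, Y, Z, ci_n, kx, ky, kz, sx, sy, sz,
                px, py, pz, Xo, Yo, oz0, nz, col.memptr());
    arma::mat gys(Ns, co_n);
    const double *gp = gy.begin();
    for (int co = 0; co < co_n; ++co) {
      const double *src = gp + ((R_xlen_t)co) * Xo * Yo * Zo + (R_xlen_t)oz0 * Xo * Yo;
      std::copy(src, src + Ns, gys.colptr(co));
      double s = 0; for (R_xlen_t i = 0; i < Ns; ++i) s += src[i];
      gb[co] += s;
    }
    GW += col.t() * gys;
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
//      anisotropic spacing; distance to the nearest voxel with mask != 0 ----

static void edt_1d(std::vector<double> &f, std::vector<double> &d, double h, int n) {
  std::vector<int> v(n); std::vector<double> z(n + 1);
  int k = 0; v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq*qq) - (f[v[k]] + vv*vv)) / (2*qq - 2*vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k+1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k+1] < qq) ++k;
    double diff = qq - (double)v[k] * h;
    d[q] = diff*diff + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(IntegerVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  const double INF = 1e30;
  NumericVector d(((R_xlen_t)X) * Y * Z);
  d.attr("dim") = dm;
  double *dp = d.begin(); const int *mp = mask.begin();
  for (R_xlen_t i = 0; i < d.size(); ++i) dp[i] = (mp[i] != 0) ? 0.0 : INF;

  std::vector<double> f(std::max(std::max(X, Y), Z)), o(std::max(std::max(X, Y), Z));
  // axis 1 (x)
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) {
    double *col = dp + X * ((R_xlen_t)y + (R_xlen_t)Y * z);
    for (int x = 0; x < X; ++x) f[x] = col[x];
    edt_1d(f, o, spacing[0], X);
    for (int x = 0; x < X; ++x) col[x] = o[x];
  }
  // axis 2 (y)
  for (int z = 0; z < Z; ++z) for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) f[y] = dp[x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)];
    edt_1d(f, o, spacing[1], Y);
    for (int y = 0; y < Y; ++y) dp[x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)] = o[y];
  }
  // axis 3 (z)
  for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    for (int z = 0; z < Z; ++z) f[z] = dp[x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)];
    edt_1d(f, o, spacing[2], Z);
    for (int z = 0; z < Z; ++z) dp[x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)] = o[z];
  }
  return d;
}

// ---- Dijkstra over foreground voxels (26-connectivity) ----
// edge cost = euclidean step length * penalty; with a depth map supplied,
// penalty = 1 / (mid_depth + eps)^power which pulls paths to the medial axis.

// [[Rcpp::export(name = ".voxel_dijkstra")]]
List voxel_dijkstra(IntegerVector mask, NumericVector spacing,
                    IntegerVector sources, NumericVector depth,
                    double eps, double power) {
  IntegerVector dm = mask.attr("dim");
  const int X = dm[0], Y = dm[1], Z = dm[2];
  const R_xlen_t n = ((R_xlen_t)X) * Y * Z;
  const int *mp = mask.begin();
  const double *dep = depth.size() == n ? depth.begin() : nullptr;
  NumericVector dist(n); IntegerVector parent(n);
  double *dd = dist.begin(); int *par = parent.begin();
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) { dd[i] = INF; par[i] = -1; }

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    R_xlen_t v = sources[s]; // 0-based linear index
    if (v < 0 || v >= n || mp[v] == 0) stop("source outside foreground");
    dd[v] = 0.0; pq.push(QE(0.0, v));
  }
  // neighbor offsets
  int off[26][3]; int no = 0;
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx) {
    if (dx == 0 && dy == 0 && dz == 0) continue;
    off[no][0] = dx; off[no][1] = dy; off[no][2] = dz; ++no;
  }
  double sp0 = spacing[0], sp1 = spacing[1], sp2 = spacing[2];
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dd[u]) continue;
    int ux = (int)(u % X), uy = (int)((u / X) % Y), uz = (int)(u / ((R_xlen_t)X * Y));
    for (int t = 0; t < 26; ++t) {
      int vx = ux + off[t][0], vy = uy + off[t][1], vz = uz + off[t][2];
      if (vx < 0 || vx >= X || vy < 0 || vy >= Y || vz < 0 || vz >= Z) continue;
      R_xlen_t v = vx + X * ((R_xlen_t)vy + (R_xlen_t)Y * vz);
      if (mp[v] == 0) continue;
      double lx = off[t][0] * sp0, ly = off[t][1] * sp1, lz = off[t][2] * sp2;
      double len = std::sqrt(lx*lx + ly*ly + lz*lz);
      double w = len;
      if (dep) {
        double mid = 0.5 * (dep[u] + dep[v]);
        w = len / std::pow(mid + eps, power);
      }
      if (dd[u] + w < dd[v]) {
        dd[v] = dd[u] + w; par[v] = (int)u;
        pq.push(QE(dd[v], v));
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}
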