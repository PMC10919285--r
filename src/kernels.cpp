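#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2D convolution (same padding, odd kernels, optional dilation) via im2col.
// Tensor layout everywhere: column-major R arrays (H, W, C, B).
// ---------------------------------------------------------------------------

static void im2col(const double* xp, int H, int W, int Cin,
                   int kh, int kw, int dil, arma::mat& col) {
  const int ph = dil * (kh - 1) / 2, pw = dil * (kw - 1) / 2;
  col.zeros();
  for (int c = 0; c < Cin; ++c)
    for (int j = 0; j < kw; ++j)
      for (int i = 0; i < kh; ++i) {
        const int colidx = i + kh * (j + kw * c);
        const int di = i * dil - ph, dj = j * dil - pw;
        double* cp = col.colptr(colidx);
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj;
          if (sw < 0 || sw >= W) continue;
          const double* src = xp + (size_t)c * H * W + (size_t)sw * H;
          double* dst = cp + (size_t)w * H;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int h = lo; h < hi; ++h) dst[h] = src[h + di];
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector y((size_t)H * W * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat col(H * W, kh * kw * Cin);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + (size_t)bb * H * W * Cin, H, W, Cin, kh, kw, dilation, col);
    arma::mat Y(y.begin() + (size_t)bb * H * W * Cout, H * W, Cout, false, true);
    Y = col * Wm;
    for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int ph = dilation * (kh - 1) / 2, pw = dilation * (kw - 1) / 2;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector dx((size_t)H * W * Cin * B);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector dw((size_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat col(H * W, kh * kw * Cin);
  for (int bb = 0; bb < B; ++bb) {
    im2col(x.begin() + (size_t)bb * H * W * Cin, H, W, Cin, kh, kw, dilation, col);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)bb * H * W * Cout,
                 H * W, Cout, false);
    dWm += col.t() * dY;
    for (int o = 0; o < Cout; ++o) db[o] += arma::accu(dY.col(o));
    arma::mat dcol = dY * Wm.t();
    double* dxp = dx.begin() + (size_t)bb * H * W * Cin;
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const int colidx = i + kh * (j + kw * c);
          const int di = i * dilation - ph, dj = j * dilation - pw;
          const double* cp = dcol.colptr(colidx);
          for (int w2 = 0; w2 < W; ++w2) {
            const int sw = w2 + dj;
            if (sw < 0 || sw >= W) continue;
            double* dst = dxp + (size_t)c * H * W + (size_t)sw * H;
            const double* src = cp + (size_t)w2 * H;
            const int lo = std::max(0, -di), hi = std::min(H, H - di);
            for (int h = lo; h < hi; ++h) dst[h + di] += src[h];
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (stride 2); input H, W must be even.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx((size_t)Ho * Wo * C * B);  // flat index into input plane
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const double* pl = xp + (size_t)cb * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const int h0 = 2 * h, w0 = 2 * w;
        int best = h0 + H * w0;
        double bv = pl[best];
        const int cand[3] = {h0 + 1 + H * w0, h0 + H * (w0 + 1), h0 + 1 + H * (w0 + 1)};
        for (int t = 0; t < 3; ++t)
          if (pl[cand[t]] > bv) { bv = pl[cand[t]]; best = cand[t]; }
        const size_t o = (size_t)cb * Ho * Wo + (size_t)w * Ho + h;
        yp[o] = bv;
        ip[o] = best;
      }
  }
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    double* pl = dxp + (size_t)cb * H * W;
    const size_t base = (size_t)cb * Ho * Wo;
    for (size_t o = 0; o < (size_t)Ho * Wo; ++o) pl[ip[base + o]] += dyp[base + o];
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing, 3D. Returns distances in mm to the nearest site.
// ---------------------------------------------------------------------------

static const double DT_BIG = 1e15;

static void dt1d(const double* f, double* d, int* v, double* z, int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG;
  z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector sites, NumericVector spacing) {
  IntegerVector sd = sites.attr("dim");
  const int nx = sd[0], ny = sd[1], nz = sd[2];
  NumericVector out((size_t)nx * ny * nz);
  out.attr("dim") = sd;
  double* D = out.begin();
  for (size_t i = 0; i < (size_t)nx * ny * nz; ++i)
    D[i] = sites[i] ? 0.0 : DT_BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* col = D + (size_t)k * nx * ny + (size_t)j * nx;
      dt1d(col, d.data(), v.data(), z.data(), nx, spacing[0] * spacing[0]);
      std::copy(d.begin(), d.begin() + nx, col);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[(size_t)k * nx * ny + (size_t)j * nx + i];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, spacing[1] * spacing[1]);
      for (int j = 0; j < ny; ++j) D[(size_t)k * nx * ny + (size_t)j * nx + i] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[(size_t)k * nx * ny + (size_t)j * nx + i];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, spacing[2] * spacing[2]);
      for (int k = 0; k < nz; ++k) D[(size_t)k * nx * ny + (size_t)j * nx + i] = d[k];
    }
  for (size_t i = 0; i < (size_t)nx * ny * nz; ++i) D[i] = std::sqrt(D[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear / nearest-neighbour resampling under a dense displacement field.
// disp has dims (nx, ny, nz, 3), displacement in voxel units (0-based math).
// Images are clamped at the edge; labels fall to 0 outside the domain.
// ---------------------------------------------------------------------------

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double trilerp(const double* vol, int nx, int ny, int nz,
                             double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  const int x0 = std::min((int)std::floor(x), nx - 2 < 0 ? 0 : nx - 2);
  const int y0 = std::min((int)std::floor(y), ny - 2 < 0 ? 0 : ny - 2);
  const int z0 = std::min((int)std::floor(z), nz - 2 < 0 ? 0 : nz - 2);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
            z1 = std::min(z0 + 1, nz - 1);
  auto at = [&](int i, int j, int k) {
    return vol[(size_t)k * nx * ny + (size_t)j * nx + i];
  };
  const double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  const double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  const double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  const double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(NumericVector vol, NumericVector disp) {
  IntegerVector vd = vol.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int K = vd.size() == 4 ? vd[3] : 1;
  const size_t V = (size_t)nx * ny * nz;
  NumericVector out(V * K);
  out.attr("dim") = vd;
  const double* dp = disp.begin();
  for (int c = 0; c < K; ++c) {
    const double* vp = vol.begin() + (size_t)c * V;
    double* op = out.begin() + (size_t)c * V;
    size_t o = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++o) {
          const double x = i + dp[o], y = j + dp[V + o], z = k + dp[2 * V + o];
          op[o] = trilerp(vp, nx, ny, nz, x, y, z);
        }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_warp_nn(IntegerVector lab, NumericVector disp) {
  IntegerVector vd = lab.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const size_t V = (size_t)nx * ny * nz;
  IntegerVector out(V);
  out.attr("dim") = vd;
  const double* dp = disp.begin();
  const int* lp = lab.begin();
  int* op = out.begin();
  size_t o = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++o) {
        const long xi = std::lround(i + dp[o]);
        const long yi = std::lround(j + dp[V + o]);
        const long zi = std::lround(k + dp[2 * V + o]);
        if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
          op[o] = 0;
        else
          op[o] = lp[(size_t)zi * nx * ny + (size_t)yi * nx + xi];
      }
  return out;
}

// ---------------------------------------------------------------------------
// Nodal displacement grid <-> dense field (trilinear in node-index space).
// Node a sits at voxel coordinate a * ns (0-based); grid has gx,gy,gz nodes.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_field_from_nodes(NumericVector nodes, IntegerVector dims,
                                   double ns) {
  IntegerVector nd = nodes.attr("dim");
  const int gx = nd[0], gy = nd[1], gz = nd[2];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t V = (size_t)nx * ny * nz, G = (size_t)gx * gy * gz;
  NumericVector out(V * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  for (int d = 0; d < 3; ++d) {
    const double* np = nodes.begin() + d * G;
    double* op = out.begin() + d * V;
    size_t o = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++o)
          op[o] = trilerp(np, gx, gy, gz, i / ns, j / ns, k / ns);
  }
  return out;
}

// Adjoint of cpp_field_from_nodes: scatter a dense 3-field onto the node grid.
// [[Rcpp::export]]
NumericVector cpp_scatter_to_nodes(NumericVector dense, IntegerVector gdims,
                                   double ns) {
  IntegerVector dd = dense.attr("dim");
  const int nx = dd[0], ny = dd[1], nz = dd[2];
  const int gx = gdims[0], gy = gdims[1], gz = gdims[2];
  const size_t V = (size_t)nx * ny * nz, G = (size_t)gx * gy * gz;
  NumericVector out(G * 3);
  out.attr("dim") = IntegerVector::create(gx, gy, gz, 3);
  for (int d = 0; d < 3; ++d) {
    const double* dp = dense.begin() + d * V;
    double* op = out.begin() + d * G;
    size_t o = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++o) {
          double tx = clampd(i / ns, 0.0, gx - 1.0);
          double ty = clampd(j / ns, 0.0, gy - 1.0);
          double tz = clampd(k / ns, 0.0, gz - 1.0);
          const int x0 = std::min((int)std::floor(tx), std::max(gx - 2, 0));
          const int y0 = std::min((int)std::floor(ty), std::max(gy - 2, 0));
          const int z0 = std::min((int)std::floor(tz), std::max(gz - 2, 0));
          const double fx = tx - x0, fy = ty - y0, fz = tz - z0;
          const int x1 = std::min(x0 + 1, gx - 1), y1 = std::min(y0 + 1, gy - 1),
                    z1 = std::min(z0 + 1, gz - 1);
          const double v = dp[o];
          auto acc = [&](int i2, int j2, int k2, double w) {
            op[(size_t)k2 * gx * gy + (size_t)j2 * gx + i2] += w * v;
          };
          acc(x0, y0, z0, (1 - fx) * (1 - fy) * (1 - fz));
          acc(x1, y0, z0, fx * (1 - fy) * (1 - fz));
          acc(x0, y1, z0, (1 - fx) * fy * (1 - fz));
          acc(x1, y1, z0, fx * fy * (1 - fz));
          acc(x0, y0, z1, (1 - fx) * (1 - fy) * fz);
          acc(x1, y0, z1, fx * (1 - fy) * fz);
          acc(x0, y1, z1, (1 - fx) * fy * fz);
          acc(x1, y1, z1, fx * fy * fz);
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Registration data term: mean squared residual between the warped reference
// channel stack and the target stack, and its gradient with respect to the
// dense displacement (exact derivative of trilinear interpolation).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_reg_obj(NumericVector ref, NumericVector tgt, NumericVector disp) {
  IntegerVector vd = ref.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int K = vd.size() == 4 ? vd[3] : 1;
  const size_t V = (size_t)nx * ny * nz;
  const double* dp = disp.begin();
  const double* rb = ref.begin();
  const double* tb = tgt.begin();
  double ssd = 0.0;
  size_t o = 0;
  // voxel-outer loop so the interpolation stencil is computed once and
  // shared across all K channels
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++o) {
        double x = clampd(i + dp[o], 0.0, nx - 1.0);
        double y = clampd(j + dp[V + o], 0.0, ny - 1.0);
        double z = clampd(k + dp[2 * V + o], 0.0, nz - 1.0);
        const int x0 = std::min((int)std::floor(x), std::max(nx - 2, 0));
        const int y0 = std::min((int)std::floor(y), std::max(ny - 2, 0));
        const int z0 = std::min((int)std::floor(z), std::max(nz - 2, 0));
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                  z1 = std::min(z0 + 1, nz - 1);
        const size_t b000 = (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
        const size_t b100 = (size_t)z0 * nx * ny + (size_t)y0 * nx + x1;
        const size_t b010 = (size_t)z0 * nx * ny + (size_t)y1 * nx + x0;
        const size_t b110 = (size_t)z0 * nx * ny + (size_t)y1 * nx + x1;
        const size_t b001 = (size_t)z1 * nx * ny + (size_t)y0 * nx + x0;
        const size_t b101 = (size_t)z1 * nx * ny + (size_t)y0 * nx + x1;
        const size_t b011 = (size_t)z1 * nx * ny + (size_t)y1 * nx + x0;
        const size_t b111 = (size_t)z1 * nx * ny + (size_t)y1 * nx + x1;
        const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
        const double w100 = fx * (1 - fy) * (1 - fz);
        const double w010 = (1 - fx) * fy * (1 - fz);
        const double w110 = fx * fy * (1 - fz);
        const double w001 = (1 - fx) * (1 - fy) * fz;
        const double w101 = fx * (1 - fy) * fz;
        const double w011 = (1 - fx) * fy * fz;
        const double w111 = fx * fy * fz;
        for (int c = 0; c < K; ++c) {
          const double* rp = rb + (size_t)c * V;
          const double w = rp[b000] * w000 + rp[b100] * w100 +
                           rp[b010] * w010 + rp[b110] * w110 +
                           rp[b001] * w001 + rp[b101] * w101 +
                           rp[b011] * w011 + rp[b111] * w111;
          const double r = w - tb[(size_t)c * V + o];
          ssd += r * r;
        }
      }
  return ssd / ((double)V * K);
}

// [[Rcpp::export]]
List cpp_reg_obj_grad(NumericVector ref, NumericVector tgt, NumericVector disp) {
  IntegerVector vd = ref.attr("dim");
  const int nx = vd[0], ny = vd[1], nz = vd[2];
  const int K = vd.size() == 4 ? vd[3] : 1;
  const size_t V = (size_t)nx * ny * nz;
  const double* dp = disp.begin();
  NumericVector grad(V * 3);
  grad.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  double* gp = grad.begin();
  double ssd = 0.0;
  const double scale = 2.0 / ((double)V * K);
  const double* rb = ref.begin();
  const double* tb = tgt.begin();
  size_t o = 0;
  // voxel-outer loop: the stencil, weights and clamp flags are shared by
  // all K channels; gradients accumulate across channels per voxel
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++o) {
        double x = i + dp[o], y = j + dp[V + o], z = k + dp[2 * V + o];
        const bool inx = x > 0.0 && x < nx - 1.0;
        const bool iny = y > 0.0 && y < ny - 1.0;
        const bool inz = z > 0.0 && z < nz - 1.0;
        x = clampd(x, 0.0, nx - 1.0);
        y = clampd(y, 0.0, ny - 1.0);
        z = clampd(z, 0.0, nz - 1.0);
        const int x0 = std::min((int)std::floor(x), std::max(nx - 2, 0));
        const int y0 = std::min((int)std::floor(y), std::max(ny - 2, 0));
        const int z0 = std::min((int)std::floor(z), std::max(nz - 2, 0));
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                  z1 = std::min(z0 + 1, nz - 1);
        const size_t b000 = (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
        const size_t dx = (size_t)(x1 - x0);
        const size_t dy = (size_t)(y1 - y0) * nx;
        const size_t dz = (size_t)(z1 - z0) * nx * ny;
        double gx = 0.0, gy = 0.0, gz = 0.0;
        for (int c = 0; c < K; ++c) {
          const double* rp = rb + (size_t)c * V + b000;
          const double v000 = rp[0], v100 = rp[dx];
          const double v010 = rp[dy], v110 = rp[dx + dy];
          const double v001 = rp[dz], v101 = rp[dx + dz];
          const double v011 = rp[dy + dz], v111 = rp[dx + dy + dz];
          const double c00 = v000 * (1 - fx) + v100 * fx;
          const double c10 = v010 * (1 - fx) + v110 * fx;
          const double c01 = v001 * (1 - fx) + v101 * fx;
          const double c11 = v011 * (1 - fx) + v111 * fx;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          const double w = c0 * (1 - fz) + c1 * fz;
          const double r = w - tb[(size_t)c * V + o];
          ssd += r * r;
          const double dwdx =
              ((v100 - v000) * (1 - fy) + (v110 - v010) * fy) * (1 - fz) +
              ((v101 - v001) * (1 - fy) + (v111 - v011) * fy) * fz;
          const double dwdy = (c10 - c00) * (1 - fz) + (c11 - c01) * fz;
          const double dwdz = c1 - c0;
          gx += r * dwdx;
          gy += r * dwdy;
          gz += r * dwdz;
        }
        if (inx) gp[o] = scale * gx;
        if (iny) gp[V + o] = scale * gy;
        if (inz) gp[2 * V + o] = scale * gz;
      }
  return List::create(_["value"] = ssd / ((double)V * K), _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// Parzen (isotropic Gaussian kernel) entropy estimate of a particle set and
// its gradient with respect to the particle positions.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_parzen_entropy(NumericMatrix pts, double sigma) {
  const int m = pts.nrow();
  const double s2 = sigma * sigma;
  const double logZ = std::log((double)(m - 1)) + 1.5 * std::log(2.0 * M_PI * s2);
  std::vector<double> S(m, 0.0);
  arma::mat K(m, m, arma::fill::zeros);
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        const double t = pts(i, d) - pts(j, d);
        d2 += t * t;
      }
      const double kij = std::exp(-d2 / (2.0 * s2));
      K(i, j) = kij;
      K(j, i) = kij;
      S[i] += kij;
      S[j] += kij;
    }
  const double tiny = 1e-300;
  double H = 0.0;
  for (int i = 0; i < m; ++i) H += std::log(std::max(S[i], tiny));
  H = -(H / m) + logZ;
  NumericMatrix grad(m, 3);
  for (int i = 0; i < m; ++i) {
    const double Si = std::max(S[i], tiny);
    for (int j = 0; j < m; ++j) {
      if (j == i || K(i, j) == 0.0) continue;
      const double Sj = std::max(S[j], tiny);
      const double w = (1.0 / Si + 1.0 / Sj) * K(i, j) / ((double)m * s2);
      for (int d = 0; d < 3; ++d) grad(i, d) += w * (pts(i, d) - pts(j, d));
    }
  }
  return List::create(_["H"] = H, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// Binned k-nearest-neighbour search (exact) for 3D point sets.
// Returns 1-based indices into cand and distances, both (nq x k).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix cand, int k) {
  const int nq = query.nrow(), nc = cand.nrow();
  k = std::min(k, nc);
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) {
    mn[d] = R_PosInf;
    mx[d] = R_NegInf;
    for (int i = 0; i < nc; ++i) {
      mn[d] = std::min(mn[d], cand(i, d));
      mx[d] = std::max(mx[d], cand(i, d));
    }
  }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(mx[d] - mn[d], 1e-9);
  double bs = std::cbrt(vol / std::max(nc, 1)) * 2.0;
  bs = std::max(bs, 1e-6);
  int nb[3];
  for (int d = 0; d < 3; ++d)
    nb[d] = std::max(1, (int)std::floor((mx[d] - mn[d]) / bs) + 1);
  auto binof = [&](double x, int d) {
    int b = (int)std::floor((x - mn[d]) / bs);
    return std::min(std::max(b, 0), nb[d] - 1);
  };
  std::vector<std::vector<int>> bins((size_t)nb[0] * nb[1] * nb[2]);
  for (int i = 0; i < nc; ++i) {
    const int bx = binof(cand(i, 0), 0), by = binof(cand(i, 1), 1),
              bz = binof(cand(i, 2), 2);
    bins[(size_t)bz * nb[0] * nb[1] + (size_t)by * nb[0] + bx].push_back(i);
  }
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  const int rmax = std::max(nb[0], std::max(nb[1], nb[2]));
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    const int qbx = binof(qx, 0), qby = binof(qy, 1), qbz = binof(qz, 2);
    int found = 0;
    for (int t = 0; t < k; ++t) bd[t] = R_PosInf;
    for (int R = 0; R <= rmax; ++R) {
      // stop once the kth best cannot be beaten by points in shell R
      if (found >= k && bd[k - 1] <= (R - 1) * bs) break;
      bool any = false;
      for (int dz = -R; dz <= R; ++dz) {
        const int bz = qbz + dz;
        if (bz < 0 || bz >= nb[2]) continue;
        for (int dy = -R; dy <= R; ++dy) {
          const int by = qby + dy;
          if (by < 0 || by >= nb[1]) continue;
          for (int dx = -R; dx <= R; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != R)
              continue;
            const int bx = qbx + dx;
            if (bx < 0 || bx >= nb[0]) continue;
            any = true;
            const std::vector<int>& cell =
                bins[(size_t)bz * nb[0] * nb[1] + (size_t)by * nb[0] + bx];
            for (size_t t = 0; t < cell.size(); ++t) {
              const int ci = cell[t];
              const double ddx = cand(ci, 0) - qx, ddy = cand(ci, 1) - qy,
                           ddz = cand(ci, 2) - qz;
              const double dd = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              if (dd < bd[k - 1]) {
                int p = k - 1;
                while (p > 0 && bd[p - 1] > dd) {
                  bd[p] = bd[p - 1];
                  bi[p] = bi[p - 1];
                  --p;
                }
                bd[p] = dd;
                bi[p] = ci;
                if (found < k) ++found;
              }
            }
          }
        }
      }
      if (!any && found >= k) break;
    }
    for (int t = 0; t < k; ++t) {
      idx(q, t) = bi[t] + 1;
      dist(q, t) = bd[t];
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Signed distance of every voxel centre to an oriented particle surface:
// distance-weighted mean over the k nearest particles of the projection of
// the offset onto the particle normal.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_signed_distance_grid(NumericMatrix pts, NumericMatrix normals,
                                       IntegerVector dims, NumericVector spacing,
                                       int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t V = (size_t)nx * ny * nz;
  NumericMatrix q(V, 3);
  size_t o = 0;
  for (int kk = 0; kk < nz; ++kk)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++o) {
        q(o, 0) = (i + 0.5) * spacing[0];
        q(o, 1) = (j + 0.5) * spacing[1];
        q(o, 2) = (kk + 0.5) * spacing[2];
      }
  List knn = cpp_knn(q, pts, k);
  IntegerMatrix idx = knn["idx"];
  NumericMatrix dist = knn["dist"];
  const int kk2 = idx.ncol();
  NumericVector sd(V);
  sd.attr("dim") = dims;
  for (size_t v = 0; v < V; ++v) {
    double wsum = 0.0, acc = 0.0;
    for (int t = 0; t < kk2; ++t) {
      const int pi = idx(v, t) - 1;
      const double w = 1.0 / (dist(v, t) + 1e-6);
      double dotp = 0.0;
      for (int d = 0; d < 3; ++d)
        dotp += (q(v, d) - pts(pi, d)) * normals(pi, d);
      acc += w * dotp;
      wsum += w;
    }
    sd[v] = acc / wsum;
  }
  return sd;
}

// ---------------------------------------------------------------------------
// Generalised winding number of an oriented point cloud on a voxel grid:
// w(q) = (1/4pi) * sum_i a_i * n_i . (p_i - q) / |p_i - q|^3.
// Converges to ~1 inside a closed surface and ~0 outside; robust to sparse
// sampling and to thin / moderately concave shapes where nearest-normal
// sign estimates fail.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_winding_grid(NumericMatrix pts, NumericMatrix normals,
                               NumericVector areas, IntegerVector dims,
                               NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t V = (size_t)nx * ny * nz;
  const int m = pts.nrow();
  NumericVector out(V);
  out.attr("dim") = dims;
  const double inv4pi = 1.0 / (4.0 * M_PI);
  // pre-scale normals by area weights
  std::vector<double> anx(m), any_(m), anz(m), px(m), py(m), pz(m);
  for (int i = 0; i < m; ++i) {
    anx[i] = areas[i] * normals(i, 0);
    any_[i] = areas[i] * normals(i, 1);
    anz[i] = areas[i] * normals(i, 2);
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
  }
  size_t o = 0;
  for (int k = 0; k < nz; ++k) {
    const double qz = (k + 0.5) * spacing[2];
    for (int j = 0; j < ny; ++j) {
      const double qy = (j + 0.5) * spacing[1];
      for (int i = 0; i < nx; ++i, ++o) {
        const double qx = (i + 0.5) * spacing[0];
        double acc = 0.0;
        for (int t = 0; t < m; ++t) {
          const double dx = px[t] - qx, dy = py[t] - qy, dz = pz[t] - qz;
          const double r2 = dx * dx + dy * dy + dz * dz + 1e-12;
          const double inv_r3 = 1.0 / (r2 * std::sqrt(r2));
          acc += (anx[t] * dx + any_[t] * dy + anz[t] * dz) * inv_r3;
        }
        out[o] = acc * inv4pi;
      }
    }
  }
  return out;
}
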