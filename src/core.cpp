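// Numerical core: physical-space resampling, masked NCC, separable Gaussian
// smoothing, anisotropic squared Euclidean distance transform, connected
// components, slice-wise hole filling, surface extraction and the
// bidirectional local distance. All grids are axis-aligned; the physical
// position of 0-based index (i,j,k) is origin + (i,j,k)*spacing and arrays are
// R column-major with dim = (nx, ny, nz).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static inline double trilerp(const double *v, int nx, int ny, int nz,
                             double ux, double uy, double uz, bool &ok) {
  if (ux < 0 || uy < 0 || uz < 0 ||
      ux > nx - 1.0 || uy > ny - 1.0 || uz > nz - 1.0) { ok = false; return 0.0; }
  ok = true;
  int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy), k0 = (int)std::floor(uz);
  if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
  if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
  double fx = ux - i0, fy = uy - j0, fz = uz - k0;
  size_t sxy = (size_t)nx * ny;
  const double *p = v + i0 + (size_t)nx * j0 + sxy * k0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[sxy] * (1 - fx) + p[sxy + 1] * fx;
  double c11 = p[sxy + nx] * (1 - fx) + p[sxy + nx + 1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
}

static inline double nearest(const double *v, int nx, int ny, int nz,
                             double ux, double uy, double uz, bool &ok) {
  long i = (long)std::lround(ux), j = (long)std::lround(uy), k = (long)std::lround(uz);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) { ok = false; return 0.0; }
  ok = true;
  return v[i + (size_t)nx * j + (size_t)nx * ny * k];
}

// Map target voxel centers through p' = R (p - c) + c + t into source physical
// space and interpolate. interp: 0 = linear, 1 = nearest.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericVector sspacing, NumericVector sorigin,
                           IntegerVector tdim, NumericVector tspacing,
                           NumericVector torigin, NumericVector Rmat,
                           NumericVector tvec, NumericVector cvec,
                           int interp, double fill) {
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  NumericVector out((size_t)tnx * tny * tnz);
  const double *sv = src.begin();
  const double *R = Rmat.begin();
  double ox = sorigin[0], oy = sorigin[1], oz = sorigin[2];
  double sx = sspacing[0], sy = sspacing[1], sz = sspacing[2];
  size_t idx = 0;
  for (int k = 0; k < tnz; ++k) {
    double pz0 = torigin[2] + k * tspacing[2] - cvec[2];
    for (int j = 0; j < tny; ++j) {
      double py0 = torigin[1] + j * tspacing[1] - cvec[1];
      for (int i = 0; i < tnx; ++i, ++idx) {
        double px0 = torigin[0] + i * tspacing[0] - cvec[0];
        double qx = R[0] * px0 + R[3] * py0 + R[6] * pz0 + cvec[0] + tvec[0];
        double qy = R[1] * px0 + R[4] * py0 + R[7] * pz0 + cvec[1] + tvec[1];
        double qz = R[2] * px0 + R[5] * py0 + R[8] * pz0 + cvec[2] + tvec[2];
        double ux = (qx - ox) / sx, uy = (qy - oy) / sy, uz = (qz - oz) / sz;
        bool ok;
        double val = (interp == 0) ? trilerp(sv, snx, sny, snz, ux, uy, uz, ok)
                                   : nearest(sv, snx, sny, snz, ux, uy, uz, ok);
        out[idx] = ok ? val : fill;
      }
    }
  }
  out.attr("dim") = tdim;
  return out;
}

// Accumulate NCC sums over fixed-grid voxels with fixed_mask = 1 whose mapped
// point lies inside the moving support and (nearest-sampled) moving_mask = 1.
// Returns c(n, sum_f, sum_m, sum_ff, sum_mm, sum_fm).
// [[Rcpp::export]]
NumericVector cpp_ncc_sums(NumericVector fixedv, NumericVector fmask,
                           IntegerVector fdim, NumericVector fspacing,
                           NumericVector forigin, NumericVector movingv,
                           NumericVector mmask, IntegerVector mdim,
                           NumericVector mspacing, NumericVector morigin,
                           NumericVector Rmat, NumericVector tvec,
                           NumericVector cvec) {
  int fnx = fdim[0], fny = fdim[1], fnz = fdim[2];
  int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  const double *fv = fixedv.begin(), *fm = fmask.begin();
  const double *mv = movingv.begin();
  const double *mm = (mmask.size() > 1) ? mmask.begin() : nullptr;
  const double *R = Rmat.begin();
  double n = 0, sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  size_t idx = 0;
  for (int k = 0; k < fnz; ++k) {
    double pz0 = forigin[2] + k * fspacing[2] - cvec[2];
    for (int j = 0; j < fny; ++j) {
      double py0 = forigin[1] + j * fspacing[1] - cvec[1];
      for (int i = 0; i < fnx; ++i, ++idx) {
        if (fm[idx] == 0) continue;
        double px0 = forigin[0] + i * fspacing[0] - cvec[0];
        double qx = R[0] * px0 + R[3] * py0 + R[6] * pz0 + cvec[0] + tvec[0];
        double qy = R[1] * px0 + R[4] * py0 + R[7] * pz0 + cvec[1] + tvec[1];
        double qz = R[2] * px0 + R[5] * py0 + R[8] * pz0 + cvec[2] + tvec[2];
        double ux = (qx - morigin[0]) / mspacing[0];
        double uy = (qy - morigin[1]) / mspacing[1];
        double uz = (qz - morigin[2]) / mspacing[2];
        bool ok;
        double val = trilerp(mv, mnx, mny, mnz, ux, uy, uz, ok);
        if (!ok) continue;
        if (mm) {
          bool ok2;
          double mval = nearest(mm, mnx, mny, mnz, ux, uy, uz, ok2);
          if (!ok2 || mval == 0) continue;
        }
        double f = fv[idx];
        n += 1; sf += f; sm += val;
        sff += f * f; smm += val * val; sfm += f * val;
      }
    }
  }
  return NumericVector::create(n, sf, sm, sff, smm, sfm);
}

// NCC sums plus the accumulators for the analytic metric derivative.
// For every sample i with fixed value f_i and interpolated moving value m_i
// at y_i = R (x_i - c) + c + t, accumulate for each parameter p:
//   G1_p = sum f_i dm_i/dp,  G2_p = sum m_i dm_i/dp,  G3_p = sum dm_i/dp,
// where dm_i/dp = grad M(y_i) . dy_i/dp; grad M by central differences of
// trilinear samples one voxel apart, dy/dt = e_t and dy/dr_k = J_k (x - c)
// with J_k the derivative of Rz Ry Rx in the k-th angle. Returns
// c(n, sf, sm, sff, smm, sfm, G1[6], G2[6], G3[6]).
// [[Rcpp::export]]
NumericVector cpp_ncc_grad_sums(NumericVector fixedv, NumericVector fmask,
                                IntegerVector fdim, NumericVector fspacing,
                                NumericVector forigin, NumericVector movingv,
                                NumericVector mmask, IntegerVector mdim,
                                NumericVector mspacing, NumericVector morigin,
                                NumericVector Rmat, NumericVector tvec,
                                NumericVector cvec, NumericVector Jx,
                                NumericVector Jy, NumericVector Jz) {
  int fnx = fdim[0], fny = fdim[1], fnz = fdim[2];
  int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  const double *fv = fixedv.begin(), *fm = fmask.begin();
  const double *mv = movingv.begin();
  const double *mm = (mmask.size() > 1) ? mmask.begin() : nullptr;
  const double *R = Rmat.begin();
  const double *J[3] = {Jx.begin(), Jy.begin(), Jz.begin()};
  double n = 0, sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  double G1[6] = {0}, G2[6] = {0}, G3[6] = {0};
  size_t idx = 0;
  for (int k = 0; k < fnz; ++k) {
    double pz0 = forigin[2] + k * fspacing[2] - cvec[2];
    for (int j = 0; j < fny; ++j) {
      double py0 = forigin[1] + j * fspacing[1] - cvec[1];
      for (int i = 0; i < fnx; ++i, ++idx) {
        if (fm[idx] == 0) continue;
        double px0 = forigin[0] + i * fspacing[0] - cvec[0];
        double qx = R[0] * px0 + R[3] * py0 + R[6] * pz0 + cvec[0] + tvec[0];
        double qy = R[1] * px0 + R[4] * py0 + R[7] * pz0 + cvec[1] + tvec[1];
        double qz = R[2] * px0 + R[5] * py0 + R[8] * pz0 + cvec[2] + tvec[2];
        double ux = (qx - morigin[0]) / mspacing[0];
        double uy = (qy - morigin[1]) / mspacing[1];
        double uz = (qz - morigin[2]) / mspacing[2];
        bool ok;
        double val = trilerp(mv, mnx, mny, mnz, ux, uy, uz, ok);
        if (!ok) continue;
        if (mm) {
          bool ok2;
          double mval = nearest(mm, mnx, mny, mnz, ux, uy, uz, ok2);
          if (!ok2 || mval == 0) continue;
        }
        double f = fv[idx];
        n += 1; sf += f; sm += val;
        sff += f * f; smm += val * val; sfm += f * val;
        // moving-image gradient (physical units/mm), central differences one
        // voxel apart; out-of-support probes contribute zero along that axis
        double gphys[3] = {0, 0, 0};
        for (int ax = 0; ax < 3; ++ax) {
          double up[3] = {ux, uy, uz}, dn[3] = {ux, uy, uz};
          up[ax] += 1.0; dn[ax] -= 1.0;
          bool okp, okn;
          double vp = trilerp(mv, mnx, mny, mnz, up[0], up[1], up[2], okp);
          double vn = trilerp(mv, mnx, mny, mnz, dn[0], dn[1], dn[2], okn);
          if (okp && okn) gphys[ax] = (vp - vn) / (2.0 * mspacing[ax]);
        }
        // dm/dp: translations then rotations
        double dmdp[6];
        dmdp[3] = gphys[0]; dmdp[4] = gphys[1]; dmdp[5] = gphys[2];
        for (int r = 0; r < 3; ++r) {
          const double *Jr = J[r];
          double dx = Jr[0] * px0 + Jr[3] * py0 + Jr[6] * pz0;
          double dy = Jr[1] * px0 + Jr[4] * py0 + Jr[7] * pz0;
          double dz = Jr[2] * px0 + Jr[5] * py0 + Jr[8] * pz0;
          dmdp[r] = gphys[0] * dx + gphys[1] * dy + gphys[2] * dz;
        }
        for (int p = 0; p < 6; ++p) {
          G1[p] += f * dmdp[p];
          G2[p] += val * dmdp[p];
          G3[p] += dmdp[p];
        }
      }
    }
  }
  NumericVector out(24);
  out[0] = n; out[1] = sf; out[2] = sm; out[3] = sff; out[4] = smm; out[5] = sfm;
  for (int p = 0; p < 6; ++p) {
    out[6 + p] = G1[p]; out[12 + p] = G2[p]; out[18 + p] = G3[p];
  }
  return out;
}

static void gauss1d(std::vector<double> &line, const std::vector<double> &ker) {
  int n = (int)line.size(), r = (int)ker.size() / 2;
  std::vector<double> out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int t = -r; t <= r; ++t) {
      int s = i + t;
      if (s < 0) s = 0; else if (s >= n) s = n - 1;  // replicate boundary
      acc += line[s] * ker[t + r];
    }
    out[i] = acc;
  }
  line.swap(out);
}

// Separable Gaussian smoothing; sigma per axis in voxel units, truncated 3*sigma.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  int nvec[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += ker[t + r]; }
    for (auto &w : ker) w /= tot;
    int n = nvec[ax];
    size_t st = stride[ax];
    int na = nvec[(ax + 1) % 3], nb = nvec[(ax + 2) % 3];
    size_t sta = stride[(ax + 1) % 3], stb = stride[(ax + 2) % 3];
    std::vector<double> line(n);
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        size_t base = sta * a + stb * b;
        for (int i = 0; i < n; ++i) line[i] = out[base + st * i];
        gauss1d(line, ker);
        for (int i = 0; i < n; ++i) out[base + st * i] = line[i];
      }
  }
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform with sample weight w
// (physical spacing): f over grid positions i*w.
static void dt1d(std::vector<double> &f, double w) {
  int n = (int)f.size();
  std::vector<int> v(n); std::vector<double> z(n + 1), d(n);
  int k = 0; v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w * (q - p));
      if (s <= z[k]) { k--; } else break;
    }
    k++; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < w * q) k++;
    double dq = w * q - w * v[k];
    d[q] = dq * dq + f[v[k]];
  }
  f.swap(d);
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// voxel center with mask = 1. Exact on anisotropic grids.
// [[Rcpp::export]]
NumericVector cpp_sqedt(NumericVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nt = (size_t)nx * ny * nz;
  // large finite stand-in for +inf: keeps the envelope arithmetic finite and
  // exceeds any squared distance a real grid can produce
  const double INF = 1e15;
  NumericVector out(nt);
  for (size_t i = 0; i < nt; ++i) out[i] = (mask[i] != 0) ? 0.0 : INF;
  int nvec[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int n = nvec[ax];
    size_t st = stride[ax];
    int na = nvec[(ax + 1) % 3], nb = nvec[(ax + 2) % 3];
    size_t sta = stride[(ax + 1) % 3], stb = stride[(ax + 2) % 3];
    std::vector<double> line(n);
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        size_t base = sta * a + stb * b;
        bool any = false;
        for (int i = 0; i < n; ++i) { line[i] = out[base + st * i]; if (line[i] < INF) any = true; }
        if (!any) continue;
        dt1d(line, spacing[ax]);
        for (int i = 0; i < n; ++i) out[base + st * i] = line[i];
      }
  }
  out.attr("dim") = dim;
  return out;
}

// Largest 6-connected component of a binary volume.
// [[Rcpp::export]]
NumericVector cpp_largest_component(NumericVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nt = (size_t)nx * ny * nz;
  std::vector<int> label(nt, 0);
  int best_label = 0; size_t best_size = 0; int cur = 0;
  std::vector<size_t> queue;
  for (size_t s = 0; s < nt; ++s) {
    if (mask[s] == 0 || label[s] != 0) continue;
    cur++;
    size_t size = 0;
    queue.clear(); queue.push_back(s); label[s] = cur;
    while (!queue.empty()) {
      size_t v = queue.back(); queue.pop_back(); size++;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((size_t)nx * ny));
      const int di[6] = {1, -1, 0, 0, 0, 0}, dj[6] = {0, 0, 1, -1, 0, 0}, dk[6] = {0, 0, 0, 0, 1, -1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t w = ii + (size_t)nx * jj + (size_t)nx * ny * kk;
        if (mask[w] != 0 && label[w] == 0) { label[w] = cur; queue.push_back(w); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  NumericVector out(nt);
  for (size_t s = 0; s < nt; ++s) out[s] = (label[s] == best_label && best_label > 0) ? 1.0 : 0.0;
  out.attr("dim") = dim;
  return out;
}

// Fill holes slice-by-slice along z: background 4-connected to the slice
// border stays background, enclosed background becomes foreground.
// [[Rcpp::export]]
NumericVector cpp_fill_holes_slicewise(NumericVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(mask);
  std::vector<char> outside((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    size_t base = (size_t)nx * ny * k;
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    for (int i = 0; i < nx; ++i) {
      if (mask[base + i] == 0) { outside[i] = 1; stack.push_back(i); }
      size_t top = (size_t)nx * (ny - 1) + i;
      if (mask[base + top] == 0 && !outside[top]) { outside[top] = 1; stack.push_back((int)top); }
    }
    for (int j = 0; j < ny; ++j) {
      size_t l = (size_t)nx * j, r = l + nx - 1;
      if (mask[base + l] == 0 && !outside[l]) { outside[l] = 1; stack.push_back((int)l); }
      if (mask[base + r] == 0 && !outside[r]) { outside[r] = 1; stack.push_back((int)r); }
    }
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int i = v % nx, j = v / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        size_t w = ii + (size_t)nx * jj;
        if (mask[base + w] == 0 && !outside[w]) { outside[w] = 1; stack.push_back((int)w); }
      }
    }
    for (size_t w = 0; w < (size_t)nx * ny; ++w)
      if (mask[base + w] == 0 && !outside[w]) out[base + w] = 1.0;
  }
  out.attr("dim") = dim;
  return out;
}

// 0-based (i,j,k) indices of mask voxels with >= 1 six-connected background
// neighbor (out of bounds counts as background), ordered lexicographically by
// (i, j, k).
// [[Rcpp::export]]
IntegerMatrix cpp_surface_indices(NumericVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> is, js, ks;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        size_t v = i + (size_t)nx * j + (size_t)nx * ny * k;
        if (mask[v] == 0) continue;
        bool surf = false;
        const int di[6] = {1, -1, 0, 0, 0, 0}, dj[6] = {0, 0, 1, -1, 0, 0}, dk[6] = {0, 0, 0, 0, 1, -1};
        for (int t = 0; t < 6 && !surf; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) { surf = true; break; }
          if (mask[ii + (size_t)nx * jj + (size_t)nx * ny * kk] == 0) surf = true;
        }
        if (surf) { is.push_back(i); js.push_back(j); ks.push_back(k); }
      }
  IntegerMatrix out((int)is.size(), 3);
  for (int r = 0; r < (int)is.size(); ++r) { out(r, 0) = is[r]; out(r, 1) = js[r]; out(r, 2) = ks[r]; }
  return out;
}

// Bidirectional local distance per reference point: forward nearest distance
// to the target set, maxed with the largest distance of target points whose
// nearest reference point (ties -> lowest index) is this one.
// [[Rcpp::export]]
NumericVector cpp_bld(NumericMatrix ref, NumericMatrix tgt) {
  int nr = ref.nrow(), ntg = tgt.nrow();
  NumericVector bld(nr);
  std::vector<double> fwd(nr);
  for (int a = 0; a < nr; ++a) {
    double best = std::numeric_limits<double>::infinity();
    double ax = ref(a, 0), ay = ref(a, 1), az = ref(a, 2);
    for (int b = 0; b < ntg; ++b) {
      double dx = ax - tgt(b, 0), dy = ay - tgt(b, 1), dz = az - tgt(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    fwd[a] = std::sqrt(best);
    bld[a] = fwd[a];
  }
  for (int b = 0; b < ntg; ++b) {
    double best = std::numeric_limits<double>::infinity();
    int arg = 0;
    double bx = tgt(b, 0), by = tgt(b, 1), bz = tgt(b, 2);
    for (int a = 0; a < nr; ++a) {
      double dx = bx - ref(a, 0), dy = by - ref(a, 1), dz = bz - ref(a, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = a; }   // strict < keeps lowest index on ties
    }
    double d = std::sqrt(best);
    if (d > bld[arg]) bld[arg] = d;
  }
  return bld;
}
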