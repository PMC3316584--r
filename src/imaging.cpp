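// Voxel-level kernels: Gaussian bead rendering, subvolume SSD tracking with
// tri-linear interpolation, 3D connected-component labelling, and
// point-in-tetrahedron lookup on a uniform grid.
//
// Conventions: arrays are R arrays indexed [ix, iy, iz] (x fastest); the
// center of voxel (i, j, k) (0-based) sits at origin + (i + 0.5) * spacing.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>

using namespace Rcpp;

namespace {

inline double vox(const double* v, const int* d, int i, int j, int k) {
  return v[(size_t)i + (size_t)d[0] * ((size_t)j + (size_t)d[1] * (size_t)k)];
}

// tri-linear interpolation at continuous voxel-center coordinates; returns
// false when the sample point leaves the grid
inline bool trilinear(const double* v, const int* d, double x, double y,
                      double z, double& out) {
  if (x < 0.0 || y < 0.0 || z < 0.0 || x > d[0] - 1.0 || y > d[1] - 1.0 ||
      z > d[2] - 1.0)
    return false;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > d[0] - 2) i0 = d[0] - 2;
  if (j0 > d[1] - 2) j0 = d[1] - 2;
  if (k0 > d[2] - 2) k0 = d[2] - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const double c000 = vox(v, d, i0, j0, k0), c100 = vox(v, d, i0 + 1, j0, k0);
  const double c010 = vox(v, d, i0, j0 + 1, k0),
               c110 = vox(v, d, i0 + 1, j0 + 1, k0);
  const double c001 = vox(v, d, i0, j0, k0 + 1),
               c101 = vox(v, d, i0 + 1, j0, k0 + 1);
  const double c011 = vox(v, d, i0, j0 + 1, k0 + 1),
               c111 = vox(v, d, i0 + 1, j0 + 1, k0 + 1);
  const double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
  const double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
  const double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
  out = c0 + fz * (c1 - c0);
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_render")]]
NumericVector cpp_render(NumericMatrix positions, NumericVector intensity,
                         IntegerVector dims, NumericVector spacing,
                         NumericVector origin, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = REAL(out);
  const double cut = 4.0;  // truncate blobs at 4 sigma
  for (int b = 0; b < positions.nrow(); ++b) {
    // bead position in voxel-center coordinates
    const double pcx = (positions(b, 0) - origin[0]) / spacing[0] - 0.5;
    const double pcy = (positions(b, 1) - origin[1]) / spacing[1] - 0.5;
    const double pcz = (positions(b, 2) - origin[2]) / spacing[2] - 0.5;
    const double sx = sigma[0] / spacing[0], sy = sigma[1] / spacing[1],
                 sz = sigma[2] / spacing[2];
    const int i0 = std::max(0, (int)std::ceil(pcx - cut * sx));
    const int i1 = std::min(nx - 1, (int)std::floor(pcx + cut * sx));
    const int j0 = std::max(0, (int)std::ceil(pcy - cut * sy));
    const int j1 = std::min(ny - 1, (int)std::floor(pcy + cut * sy));
    const int k0 = std::max(0, (int)std::ceil(pcz - cut * sz));
    const int k1 = std::min(nz - 1, (int)std::floor(pcz + cut * sz));
    const double amp = intensity[b % intensity.size()];
    for (int k = k0; k <= k1; ++k) {
      const double gz = (k - pcz) / sz;
      for (int j = j0; j <= j1; ++j) {
        const double gy = (j - pcy) / sy;
        for (int i = i0; i <= i1; ++i) {
          const double gx = (i - pcx) / sx;
          o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] +=
              amp * std::exp(-0.5 * (gx * gx + gy * gy + gz * gz));
        }
      }
    }
  }
  return out;
}

// separable Gaussian smoothing with reflected boundaries (sigma in voxels)
// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector voxels, IntegerVector dims,
                          NumericVector sigma_vox) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<double> buf(REAL(voxels), REAL(voxels) + voxels.size());
  std::vector<double> tmp(buf.size());
  const size_t stride[3] = {1, (size_t)d[0], (size_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma_vox[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int i = -r; i <= r; ++i) ksum += (k[i + r] = std::exp(-0.5 * i * i / (s * s)));
    for (double& v : k) v /= ksum;
    const int n = d[ax];
    const int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    for (int j2 = 0; j2 < d[o2]; ++j2)
      for (int j1 = 0; j1 < d[o1]; ++j1) {
        const size_t base = stride[o1] * j1 + stride[o2] * j2;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;           // reflect
            if (ii >= n) ii = 2 * n - ii - 1;
            acc += k[t + r] * buf[base + stride[ax] * ii];
          }
          tmp[base + stride[ax] * i] = acc;
        }
      }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// [[Rcpp::export(name = ".cpp_track")]]
List cpp_track(NumericVector refvox, IntegerVector refdim, NumericVector tarvox,
               IntegerVector tardim, NumericMatrix positions,
               NumericVector spacing, NumericVector ref_origin,
               NumericVector tar_origin, NumericVector subvol,
               double search_radius) {
  const int nb = positions.nrow();
  const double* rv = REAL(refvox);
  const double* tv = REAL(tarvox);
  int rd[3] = {refdim[0], refdim[1], refdim[2]};
  int td[3] = {tardim[0], tardim[1], tardim[2]};
  NumericMatrix disp(nb, 3);
  NumericVector residual(nb);
  LogicalVector lost(nb);

  int half[3], srch[3];
  for (int k = 0; k < 3; ++k) {
    half[k] = std::max(1, (int)std::lround((subvol[k] / spacing[k] - 1.0) / 2.0));
    srch[k] = std::max(1, (int)std::ceil(search_radius / spacing[k]));
  }
  const int wn = (2 * half[0] + 1) * (2 * half[1] + 1) * (2 * half[2] + 1);
  std::vector<double> rwin(wn);

  for (int b = 0; b < nb; ++b) {
    // reference window around the nearest voxel to the bead
    int c[3];
    bool ok = true;
    for (int k = 0; k < 3; ++k) {
      const double pc =
          (positions(b, k) - ref_origin[k]) / spacing[k] - 0.5;
      c[k] = (int)std::lround(pc);
      if (c[k] - half[k] < 0 || c[k] + half[k] > rd[k] - 1) ok = false;
    }
    if (!ok) {
      lost[b] = true;
      disp(b, 0) = disp(b, 1) = disp(b, 2) = NA_REAL;
      residual[b] = NA_REAL;
      continue;
    }
    // offset between the two stacks' voxel grids, in target voxel-center coords
    double goff[3];
    for (int k = 0; k < 3; ++k)
      goff[k] = (ref_origin[k] - tar_origin[k]) / spacing[k];

    // SSD of mean-subtracted windows at shift s (target voxel units). The
    // shift is split symmetrically -- reference sampled at -s/2, target at
    // +s/2 -- so both windows see the same tri-linear smoothing at the
    // optimum and the sub-voxel interpolation bias cancels.
    std::vector<double> twin(wn);
    auto ssd = [&](const double* s, double& out) -> bool {
      double tmean = 0.0, rmean = 0.0;
      int idx = 0;
      for (int dk = -half[2]; dk <= half[2]; ++dk)
        for (int dj = -half[1]; dj <= half[1]; ++dj)
          for (int di = -half[0]; di <= half[0]; ++di) {
            double rval, tval;
            if (!trilinear(rv, rd, c[0] + di - 0.5 * s[0],
                           c[1] + dj - 0.5 * s[1], c[2] + dk - 0.5 * s[2],
                           rval))
              return false;
            if (!trilinear(tv, td, c[0] + di + goff[0] + 0.5 * s[0],
                           c[1] + dj + goff[1] + 0.5 * s[1],
                           c[2] + dk + goff[2] + 0.5 * s[2], tval))
              return false;
            rwin[idx] = rval;
            twin[idx++] = tval;
            rmean += rval;
            tmean += tval;
          }
      rmean /= wn;
      tmean /= wn;
      double acc = 0.0;
      for (int i = 0; i < wn; ++i) {
        const double dv = (rwin[i] - rmean) - (twin[i] - tmean);
        acc += dv * dv;
      }
      out = acc;
      return true;
    };

    // coarse integer-voxel grid search
    double best[3] = {0, 0, 0}, bestval = R_PosInf;
    bool on_edge = false;
    for (int sk = -srch[2]; sk <= srch[2]; ++sk)
      for (int sj = -srch[1]; sj <= srch[1]; ++sj)
        for (int si = -srch[0]; si <= srch[0]; ++si) {
          const double s[3] = {(double)si, (double)sj, (double)sk};
          double val;
          if (!ssd(s, val)) continue;
          if (val < bestval) {
            bestval = val;
            best[0] = si;
            best[1] = sj;
            best[2] = sk;
            on_edge = (std::abs(si) == srch[0] || std::abs(sj) == srch[1] ||
                       std::abs(sk) == srch[2]);
          }
        }
    if (!R_FINITE(bestval) || on_edge) {
      lost[b] = true;
      disp(b, 0) = disp(b, 1) = disp(b, 2) = NA_REAL;
      residual[b] = R_FINITE(bestval) ? bestval : NA_REAL;
      continue;
    }

    // sub-voxel refinement: pattern search with successive step halving
    double step = 0.5;
    for (int it = 0; it < 60 && step > 1e-6; ++it) {
      bool moved = false;
      for (int sk = -1; sk <= 1; ++sk)
        for (int sj = -1; sj <= 1; ++sj)
          for (int si = -1; si <= 1; ++si) {
            if (!si && !sj && !sk) continue;
            const double s[3] = {best[0] + step * si, best[1] + step * sj,
                                 best[2] + step * sk};
            double val;
            if (ssd(s, val) && val < bestval) {
              bestval = val;
              best[0] = s[0];
              best[1] = s[1];
              best[2] = s[2];
              moved = true;
            }
          }
      if (!moved) step *= 0.5;
    }

    for (int k = 0; k < 3; ++k) disp(b, k) = best[k] * spacing[k];
    residual[b] = bestval;
    lost[b] = false;
  }
  return List::create(_["displacements"] = disp, _["residuals"] = residual,
                      _["lost"] = lost);
}

// [[Rcpp::export(name = ".cpp_label3d")]]
List cpp_label3d(NumericVector voxels, IntegerVector dims, double threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(voxels);
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int nlab = 0;
  std::vector<double> wsum, wx, wy, wz, peak;
  std::vector<int> count;
  std::vector<size_t> stack;

  for (size_t start = 0; start < n; ++start) {
    if (label[start] || v[start] <= threshold) continue;
    ++nlab;
    wsum.push_back(0.0); wx.push_back(0.0); wy.push_back(0.0);
    wz.push_back(0.0); peak.push_back(0.0); count.push_back(0);
    stack.clear();
    stack.push_back(start);
    label[start] = nlab;
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % nx), j = (int)((cur / nx) % ny),
                k = (int)(cur / ((size_t)nx * ny));
      const double w = v[cur];
      wsum[nlab - 1] += w;
      wx[nlab - 1] += w * i;
      wy[nlab - 1] += w * j;
      wz[nlab - 1] += w * k;
      peak[nlab - 1] = std::max(peak[nlab - 1], w);
      ++count[nlab - 1];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            const size_t q = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
            if (!label[q] && v[q] > threshold) {
              label[q] = nlab;
              stack.push_back(q);
            }
          }
    }
  }
  NumericMatrix centroid(nlab, 3);
  NumericVector total(nlab), peakint(nlab);
  IntegerVector nvox(nlab);
  for (int l = 0; l < nlab; ++l) {
    centroid(l, 0) = wx[l] / wsum[l];
    centroid(l, 1) = wy[l] / wsum[l];
    centroid(l, 2) = wz[l] / wsum[l];
    total[l] = wsum[l];
    peakint[l] = peak[l];
    nvox[l] = count[l];
  }
  return List::create(_["centroid_vox"] = centroid, _["total_intensity"] = total,
                      _["peak_intensity"] = peakint, _["n_voxels"] = nvox);
}

// [[Rcpp::export(name = ".cpp_point_in_tets")]]
IntegerVector cpp_point_in_tets(NumericMatrix queries, NumericMatrix nodes,
                                IntegerMatrix elements, double cell_size) {
  const int m = elements.nrow(), nq = queries.nrow();
  // bounding box of the mesh
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = R_PosInf;
    hi[k] = R_NegInf;
  }
  for (int i = 0; i < nodes.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], nodes(i, k));
      hi[k] = std::max(hi[k], nodes(i, k));
    }
  int gd[3];
  for (int k = 0; k < 3; ++k)
    gd[k] = std::max(1, (int)std::ceil((hi[k] - lo[k]) / cell_size));
  auto cellof = [&](double x, int k) {
    int c = (int)std::floor((x - lo[k]) / cell_size);
    return std::min(std::max(c, 0), gd[k] - 1);
  };
  std::vector<std::vector<int>> bins((size_t)gd[0] * gd[1] * gd[2]);
  for (int e = 0; e < m; ++e) {
    double elo[3] = {R_PosInf, R_PosInf, R_PosInf},
           ehi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 4; ++j) {
      const int nidx = elements(e, j) - 1;
      for (int k = 0; k < 3; ++k) {
        elo[k] = std::min(elo[k], nodes(nidx, k));
        ehi[k] = std::max(ehi[k], nodes(nidx, k));
      }
    }
    for (int ck = cellof(elo[2], 2); ck <= cellof(ehi[2], 2); ++ck)
      for (int cj = cellof(elo[1], 1); cj <= cellof(ehi[1], 1); ++cj)
        for (int ci = cellof(elo[0], 0); ci <= cellof(ehi[0], 0); ++ci)
          bins[(size_t)ci + (size_t)gd[0] * ((size_t)cj + (size_t)gd[1] * ck)]
              .push_back(e);
  }

  IntegerVector out(nq, NA_INTEGER);
  const double tol = -1e-9;
  for (int q = 0; q < nq; ++q) {
    const double p[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    if (p[0] < lo[0] || p[1] < lo[1] || p[2] < lo[2] || p[0] > hi[0] ||
        p[1] > hi[1] || p[2] > hi[2])
      continue;
    const size_t cell = (size_t)cellof(p[0], 0) +
                        (size_t)gd[0] * ((size_t)cellof(p[1], 1) +
                                         (size_t)gd[1] * cellof(p[2], 2));
    for (int e : bins[cell]) {
      const int a = elements(e, 0) - 1, bI = elements(e, 1) - 1,
                cI = elements(e, 2) - 1, dI = elements(e, 3) - 1;
      double M[3][3], rhs[3];
      for (int k = 0; k < 3; ++k) {
        M[k][0] = nodes(bI, k) - nodes(a, k);
        M[k][1] = nodes(cI, k) - nodes(a, k);
        M[k][2] = nodes(dI, k) - nodes(a, k);
        rhs[k] = p[k] - nodes(a, k);
      }
      const double det =
          M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
          M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
          M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
      if (det == 0.0) continue;
      const double b0 = (rhs[0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
                         M[0][1] * (rhs[1] * M[2][2] - M[1][2] * rhs[2]) +
                         M[0][2] * (rhs[1] * M[2][1] - M[1][1] * rhs[2])) /
                        det;
      const double b1 = (M[0][0] * (rhs[1] * M[2][2] - M[1][2] * rhs[2]) -
                         rhs[0] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
                         M[0][2] * (M[1][0] * rhs[2] - rhs[1] * M[2][0])) /
                        det;
      const double b2 = (M[0][0] * (M[1][1] * rhs[2] - rhs[1] * M[2][1]) -
                         M[0][1] * (M[1][0] * rhs[2] - rhs[1] * M[2][0]) +
                         rhs[0] * (M[1][0] * M[2][1] - M[1][1] * M[2][0])) /
                        det;
      if (b0 >= tol && b1 >= tol && b2 >= tol && 1.0 - b0 - b1 - b2 >= tol) {
        out[q] = e + 1;
        break;
      }
    }
  }
  return out;
}
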