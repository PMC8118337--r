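// Geometry hot paths: surface sampling, Gaussian splatting, trilinear
// interpolation, 3D connected components / hole filling, ray casting and
// isosurface extraction. All voxel coordinates are 0-based voxel-center
// units (center of voxel i at coordinate i); linear index ix + nx*(iy+ny*iz).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quasi-uniform point samples on a triangle soup. Each triangle is split
// into n^2 congruent subtriangles with n chosen so subtriangle edges are
// below `spacing`; one sample per subtriangle centroid, weighted by its area.
// [[Rcpp::export]]
List cpp_sample_triangles(NumericMatrix V, IntegerMatrix F, double spacing) {
  const int nf = F.nrow();
  std::vector<double> px, py, pz, pw;
  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    const double ax = V(a,0), ay = V(a,1), az = V(a,2);
    const double ux = V(b,0)-ax, uy = V(b,1)-ay, uz = V(b,2)-az;
    const double vx = V(c,0)-ax, vy = V(c,1)-ay, vz = V(c,2)-az;
    const double e1 = std::sqrt(ux*ux+uy*uy+uz*uz);
    const double e2 = std::sqrt(vx*vx+vy*vy+vz*vz);
    const double wx = vx-ux, wy = vy-uy, wz = vz-uz;
    const double e3 = std::sqrt(wx*wx+wy*wy+wz*wz);
    const double emax = std::max(e1, std::max(e2, e3));
    const double cxp = uy*vz-uz*vy, cyp = uz*vx-ux*vz, czp = ux*vy-uy*vx;
    const double area = 0.5*std::sqrt(cxp*cxp+cyp*cyp+czp*czp);
    if (area <= 0) continue;
    int n = (int)std::ceil(emax / spacing);
    if (n < 1) n = 1;
    const double w = area / (double)(n*n);
    const double inv = 1.0/(double)n;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n - i; ++j) {
        // upright subtriangle centroid
        double s = (i + 1.0/3.0)*inv, t = (j + 1.0/3.0)*inv;
        px.push_back(ax + s*ux + t*vx);
        py.push_back(ay + s*uy + t*vy);
        pz.push_back(az + s*uz + t*vz);
        pw.push_back(w);
        if (j < n - i - 1) { // inverted subtriangle centroid
          s = (i + 2.0/3.0)*inv; t = (j + 2.0/3.0)*inv;
          px.push_back(ax + s*ux + t*vx);
          py.push_back(ay + s*uy + t*vy);
          pz.push_back(az + s*uz + t*vz);
          pw.push_back(w);
        }
      }
    }
  }
  const int m = (int)px.size();
  NumericMatrix P(m, 3);
  NumericVector W(m);
  for (int i = 0; i < m; ++i) {
    P(i,0) = px[i]; P(i,1) = py[i]; P(i,2) = pz[i]; W[i] = pw[i];
  }
  return List::create(_["points"] = P, _["weights"] = W);
}

// Accumulate anisotropic Gaussian splats of weighted points into a volume.
// Points in voxel-center units; sigma per axis in voxel units.
// [[Rcpp::export]]
NumericVector cpp_splat(NumericMatrix pts, NumericVector wts,
                        IntegerVector dims, NumericVector sigma_vox,
                        double truncate = 3.0) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double sx = sigma_vox[0], sy = sigma_vox[1], sz = sigma_vox[2];
  const int rx = (int)std::ceil(truncate * sx);
  const int ry = (int)std::ceil(truncate * sy);
  const int rz = (int)std::ceil(truncate * sz);
  if (2 * rx + 1 > 64 || 2 * ry + 1 > 64 || 2 * rz + 1 > 64)
    stop("splat kernel too wide (sigma too large for the grid)");
  const int np = pts.nrow();
  for (int p = 0; p < np; ++p) {
    const double x = pts(p,0), y = pts(p,1), z = pts(p,2), w = wts[p];
    const int x0 = std::max(0, (int)std::ceil(x - rx));
    const int x1 = std::min(nx - 1, (int)std::floor(x + rx));
    const int y0 = std::max(0, (int)std::ceil(y - ry));
    const int y1 = std::min(ny - 1, (int)std::floor(y + ry));
    const int z0 = std::max(0, (int)std::ceil(z - rz));
    const int z1 = std::min(nz - 1, (int)std::floor(z + rz));
    // separable kernel: one exp per axis offset instead of per voxel
    double ex[64], ey[64], ez[64];
    for (int i = x0; i <= x1; ++i) {
      const double d = (i - x) / sx;
      ex[i - x0] = std::exp(-0.5 * d * d);
    }
    for (int j = y0; j <= y1; ++j) {
      const double d = (j - y) / sy;
      ey[j - y0] = std::exp(-0.5 * d * d);
    }
    for (int k = z0; k <= z1; ++k) {
      const double d = (k - z) / sz;
      ez[k - z0] = std::exp(-0.5 * d * d);
    }
    for (int k = z0; k <= z1; ++k) {
      const double wz = w * ez[k - z0];
      for (int j = y0; j <= y1; ++j) {
        const double wyz = wz * ey[j - y0];
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = x0; i <= x1; ++i)
          vol[base + i] += wyz * ex[i - x0];
      }
    }
  }
  return vol;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = pts(p,0), y = pts(p,1), z = pts(p,2);
    const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
              k0 = (int)std::floor(z);
    double acc = 0.0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    for (int dk = 0; dk <= 1; ++dk) {
      const int k = k0 + dk;
      if (k < 0 || k >= nz) continue;
      const double wk = dk ? fz : 1.0 - fz;
      for (int dj = 0; dj <= 1; ++dj) {
        const int j = j0 + dj;
        if (j < 0 || j >= ny) continue;
        const double wj = dj ? fy : 1.0 - fy;
        for (int di = 0; di <= 1; ++di) {
          const int i = i0 + di;
          if (i < 0 || i >= nx) continue;
          const double wi = di ? fx : 1.0 - fx;
          acc += wi * wj * wk * vol[(R_xlen_t)i + nx*(j + (R_xlen_t)ny*k)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// 6-connected components of a binary volume; labels 1..K by decreasing size
// would cost a sort, so labels are arbitrary and sizes are returned.
// [[Rcpp::export]]
List cpp_label_components(IntegerVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  std::vector<double> sizes;
  std::vector<R_xlen_t> stack;
  int lab = 0;
  const int dx[6] = {1,-1,0,0,0,0};
  const int dy[6] = {0,0,1,-1,0,0};
  const int dz[6] = {0,0,0,0,1,-1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!vol[s] || labels[s]) continue;
    ++lab;
    double sz = 0;
    stack.push_back(s);
    labels[s] = lab;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      ++sz;
      const int i = (int)(cur % nx);
      const int j = (int)((cur / nx) % ny);
      const int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        const int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t q = (R_xlen_t)ii + nx*(jj + (R_xlen_t)ny*kk);
        if (vol[q] && !labels[q]) { labels[q] = lab; stack.push_back(q); }
      }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = labels, _["sizes"] = wrap(sizes));
}

// Fill interior cavities: background voxels not reachable from the volume
// border (6-connectivity) become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx-1 && j != 0 && j != ny-1 && k != 0 && k != nz-1)
          continue;
        const R_xlen_t q = (R_xlen_t)i + nx*(j + (R_xlen_t)ny*k);
        if (!vol[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
      }
  const int dx[6] = {1,-1,0,0,0,0};
  const int dy[6] = {0,0,1,-1,0,0};
  const int dz[6] = {0,0,0,0,1,-1};
  while (!stack.empty()) {
    const R_xlen_t cur = stack.back();
    stack.pop_back();
    const int i = (int)(cur % nx);
    const int j = (int)((cur / nx) % ny);
    const int k = (int)(cur / ((R_xlen_t)nx * ny));
    for (int d = 0; d < 6; ++d) {
      const int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      const R_xlen_t q = (R_xlen_t)ii + nx*(jj + (R_xlen_t)ny*kk);
      if (!vol[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  IntegerVector out(n);
  for (R_xlen_t q = 0; q < n; ++q) out[q] = (vol[q] || !outside[q]) ? 1 : 0;
  return out;
}

// Taubin lambda/mu smoothing iterations over a fixed edge list.
// [[Rcpp::export]]
NumericMatrix cpp_taubin(NumericMatrix V, IntegerVector ei,
                         IntegerVector ej, int iterations, double lambda,
                         double mu) {
  const int n = V.nrow(), ne = ei.size();
  NumericMatrix out(clone(V));
  std::vector<double> acc((size_t)n * 3);
  std::vector<int> deg(n, 0);
  for (int e = 0; e < ne; ++e) ++deg[ei[e] - 1];
  const double fac[2] = {lambda, mu};
  for (int it = 0; it < iterations; ++it) {
    for (int step = 0; step < 2; ++step) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int e = 0; e < ne; ++e) {
        const int a = ei[e] - 1, b = ej[e] - 1;
        acc[3*a]   += out(b, 0);
        acc[3*a+1] += out(b, 1);
        acc[3*a+2] += out(b, 2);
      }
      for (int v = 0; v < n; ++v) {
        if (!deg[v]) continue;
        for (int k = 0; k < 3; ++k)
          out(v, k) += fac[step] * (acc[3*v+k] / deg[v] - out(v, k));
      }
    }
  }
  return out;
}

// Exact solid voxelization by z-column parity: for every lateral voxel
// column, intersect the vertical line with the mesh and mark voxels whose
// centers lie inside an odd number of crossings. Voxel center i maps to
// physical coordinate (i - ctr) * pitch per axis.
// [[Rcpp::export]]
IntegerVector cpp_voxelize_solid_grid(NumericMatrix V, IntegerMatrix F,
                                      int n, double pitch, double ctr) {
  IntegerVector out((R_xlen_t)n * n * n);
  const int nf = F.nrow();
  std::vector<double> zs;
  for (int iy = 0; iy < n; ++iy) {
    const double y = (iy - ctr) * pitch;
    for (int ix = 0; ix < n; ++ix) {
      // tiny lateral offset avoids rays through vertices/edges
      const double x = (ix - ctr) * pitch + 1e-7 * pitch;
      zs.clear();
      for (int f = 0; f < nf; ++f) {
        const int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
        const double ax = V(a,0)-x, ay = V(a,1)-y;
        const double bx = V(b,0)-x, by = V(b,1)-y;
        const double cx = V(c,0)-x, cy = V(c,1)-y;
        // 2D barycentric test of (0,0) against the projected triangle
        const double d = (by-cy)*(ax-cx) + (cx-bx)*(ay-cy);
        if (std::fabs(d) < 1e-15) continue;
        const double u = ((by-cy)*(-cx) + (cx-bx)*(-cy)) / d;
        const double v = ((cy-ay)*(-cx) + (ax-cx)*(-cy)) / d;
        if (u < 0 || v < 0 || u + v > 1) continue;
        zs.push_back(u*V(a,2) + v*V(b,2) + (1-u-v)*V(c,2));
      }
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      for (size_t k = 0; k + 1 < zs.size(); k += 2) {
        int k0 = (int)std::ceil(zs[k] / pitch + ctr);
        int k1 = (int)std::floor(zs[k+1] / pitch + ctr);
        if (k0 < 0) k0 = 0;
        if (k1 > n - 1) k1 = n - 1;
        for (int kz = k0; kz <= k1; ++kz)
          out[(R_xlen_t)ix + n*(iy + (R_xlen_t)n*kz)] = 1;
      }
    }
  }
  return out;
}

static inline bool moller_trumbore(const double *orig, const double *dir,
                                   const double *a, const double *b,
                                   const double *c, double &t) {
  const double eps = 1e-12;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i]-a[i]; e2[i] = c[i]-a[i]; }
  pv[0] = dir[1]*e2[2]-dir[2]*e2[1];
  pv[1] = dir[2]*e2[0]-dir[0]*e2[2];
  pv[2] = dir[0]*e2[1]-dir[1]*e2[0];
  const double det = e1[0]*pv[0]+e1[1]*pv[1]+e1[2]*pv[2];
  if (std::fabs(det) < eps) return false;
  const double inv = 1.0/det;
  for (int i = 0; i < 3; ++i) tv[i] = orig[i]-a[i];
  const double u = (tv[0]*pv[0]+tv[1]*pv[1]+tv[2]*pv[2])*inv;
  if (u < -1e-9 || u > 1.0+1e-9) return false;
  qv[0] = tv[1]*e1[2]-tv[2]*e1[1];
  qv[1] = tv[2]*e1[0]-tv[0]*e1[2];
  qv[2] = tv[0]*e1[1]-tv[1]*e1[0];
  const double v = (dir[0]*qv[0]+dir[1]*qv[1]+dir[2]*qv[2])*inv;
  if (v < -1e-9 || u + v > 1.0+1e-9) return false;
  t = (e2[0]*qv[0]+e2[1]*qv[1]+e2[2]*qv[2])*inv;
  return true;
}

// Farthest positive intersection with the mesh along each direction from the
// origin; 0 when a direction misses the mesh entirely.
// [[Rcpp::export]]
NumericVector cpp_ray_radial(NumericMatrix V, IntegerMatrix F,
                             NumericMatrix dirs) {
  const int nd = dirs.nrow(), nf = F.nrow();
  NumericVector out(nd);
  std::vector<double> vx(V.nrow()*3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3*i+j] = V(i,j);
  const double orig[3] = {0.0, 0.0, 0.0};
  for (int d = 0; d < nd; ++d) {
    const double dir[3] = {dirs(d,0), dirs(d,1), dirs(d,2)};
    double best = 0.0, t;
    for (int f = 0; f < nf; ++f) {
      const double *a = &vx[3*(F(f,0)-1)];
      const double *b = &vx[3*(F(f,1)-1)];
      const double *c = &vx[3*(F(f,2)-1)];
      if (moller_trumbore(orig, dir, a, b, c, t) && t > best) best = t;
    }
    out[d] = best;
  }
  return out;
}

// All intersection parameters t of one ray with the mesh (test oracle).
// [[Rcpp::export]]
NumericVector cpp_ray_hits(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, NumericVector dir) {
  std::vector<double> ts;
  const int nf = F.nrow();
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double d[3] = {dir[0], dir[1], dir[2]};
  double t;
  for (int f = 0; f < nf; ++f) {
    double a[3], b[3], c[3];
    for (int j = 0; j < 3; ++j) {
      a[j] = V(F(f,0)-1, j); b[j] = V(F(f,1)-1, j); c[j] = V(F(f,2)-1, j);
    }
    if (moller_trumbore(o, d, a, b, c, t)) ts.push_back(t);
  }
  return wrap(ts);
}

// Isosurface extraction by marching over the Freudenthal 6-tetrahedra
// decomposition of each grid cube (marching-cubes family; watertight by
// construction because the face diagonals are translation invariant).
// Vertices lie on grid edges, deduplicated by edge key; triangles are
// oriented with outward normals (inside = value >= level).
// [[Rcpp::export]]
List cpp_march_tets(NumericVector vol, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int tets[6][4] = {
    {0, 4, 6, 7}, {0, 4, 5, 7}, {0, 2, 6, 7},
    {0, 2, 3, 7}, {0, 1, 5, 7}, {0, 1, 3, 7}
  }; // corner ids: bit0 = x, bit1 = y, bit2 = z
  std::unordered_map<long long, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  auto corner_index = [&](int i, int j, int k, int c) -> R_xlen_t {
    return (R_xlen_t)(i + (c & 1)) +
           (R_xlen_t)nx * ((j + ((c >> 1) & 1)) +
           (R_xlen_t)ny * (k + ((c >> 2) & 1)));
  };
  auto edge_point = [&](R_xlen_t g0, R_xlen_t g1) -> int {
    if (g0 > g1) std::swap(g0, g1);
    const long long key = (long long)g0 * (long long)N + (long long)g1;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    const double v0 = vol[g0], v1 = vol[g1];
    double t = (level - v0) / (v1 - v0);
    if (t < 0) t = 0; if (t > 1) t = 1;
    const int i0 = (int)(g0 % nx), j0 = (int)((g0 / nx) % ny),
              k0 = (int)(g0 / ((R_xlen_t)nx * ny));
    const int i1 = (int)(g1 % nx), j1 = (int)((g1 / nx) % ny),
              k1 = (int)(g1 / ((R_xlen_t)nx * ny));
    vx.push_back(i0 + t * (i1 - i0));
    vy.push_back(j0 + t * (j1 - j0));
    vz.push_back(k0 + t * (k1 - k0));
    const int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const double *inward) {
    // orient so the normal points away from the inside of the surface
    const double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
    const double wx = vx[c]-vx[a], wy = vy[c]-vy[a], wz = vz[c]-vz[a];
    const double nxv = uy*wz-uz*wy, nyv = uz*wx-ux*wz, nzv = ux*wy-uy*wx;
    const double cx = (vx[a]+vx[b]+vx[c])/3.0 - inward[0];
    const double cy = (vy[a]+vy[b]+vy[c])/3.0 - inward[1];
    const double cz = (vz[a]+vz[b]+vz[c])/3.0 - inward[2];
    if (nxv*cx + nyv*cy + nzv*cz >= 0) {
      tri.push_back(a); tri.push_back(b); tri.push_back(c);
    } else {
      tri.push_back(a); tri.push_back(c); tri.push_back(b);
    }
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        R_xlen_t g[8];
        double val[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          g[c] = corner_index(i, j, k, c);
          val[c] = vol[g[c]];
          (val[c] >= level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int tt = 0; tt < 6; ++tt) {
          const int *T = tets[tt];
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (val[T[c]] >= level) inside[nin++] = c;
          if (nin == 0 || nin == 4) continue;
          // centroid of the inside corners, for orientation
          double cen[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c) {
            const R_xlen_t gi = g[T[inside[c]]];
            cen[0] += (double)(gi % nx);
            cen[1] += (double)((gi / nx) % ny);
            cen[2] += (double)(gi / ((R_xlen_t)nx * ny));
          }
          for (int c = 0; c < 3; ++c) cen[c] /= nin;
          if (nin == 1 || nin == 3) {
            // one vertex on its own side: single triangle
            int apex = -1;
            for (int c = 0; c < 4; ++c) {
              const bool in = val[T[c]] >= level;
              if ((nin == 1 && in) || (nin == 3 && !in)) apex = c;
            }
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) e[m++] = edge_point(g[T[apex]], g[T[c]]);
            emit(e[0], e[1], e[2], cen);
          } else {
            // 2-2 split: quad across the four mixed edges
            int in0 = -1, in1 = -1, out0 = -1, out1 = -1;
            for (int c = 0; c < 4; ++c) {
              if (val[T[c]] >= level) { if (in0 < 0) in0 = c; else in1 = c; }
              else { if (out0 < 0) out0 = c; else out1 = c; }
            }
            const int p00 = edge_point(g[T[in0]], g[T[out0]]);
            const int p01 = edge_point(g[T[in0]], g[T[out1]]);
            const int p10 = edge_point(g[T[in1]], g[T[out0]]);
            const int p11 = edge_point(g[T[in1]], g[T[out1]]);
            emit(p00, p01, p11, cen);
            emit(p00, p11, p10, cen);
          }
        }
      }
  const int nv = (int)vx.size();
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vout(i,0) = vx[i]; Vout(i,1) = vy[i]; Vout(i,2) = vz[i];
  }
  IntegerMatrix Fout((int)tri.size() / 3, 3);
  for (int f = 0; f < Fout.nrow(); ++f) {
    Fout(f,0) = tri[3*f] + 1; Fout(f,1) = tri[3*f+1] + 1;
    Fout(f,2) = tri[3*f+2] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
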