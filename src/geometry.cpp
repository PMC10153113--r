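// Low-level volumetric and mesh primitives.
// All volumes use R array layout: dim (nx, ny, nz), element (i,j,k) at
// linear index i + nx*(j + ny*k) (0-based here; R callers are 1-based).
#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <vector>
#include <unordered_map>
#include <queue>
#include <set>
#include <array>
#include <limits>
using namespace Rcpp;

static inline size_t idx3(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), used per-axis.
static void dt1d(const double* f, double* d, int n, std::vector<int>& v,
                 std::vector<double>& z) {
  v.resize(n); z.resize(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (voxels) from every voxel to the nearest foreground voxel.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector fg, int nx, int ny, int nz) {
  const double INF = 1e30;
  NumericVector out(fg.size());
  std::vector<double> buf((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < fg.size(); ++i) buf[i] = fg[i] ? 0.0 : INF;
  std::vector<int> v; std::vector<double> z;
  std::vector<double> f(std::max(nx, std::max(ny, nz))),
                      d(std::max(nx, std::max(ny, nz)));
  // x pass
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) f[i] = buf[idx3(i, j, k, nx, ny)];
    dt1d(f.data(), d.data(), nx, v, z);
    for (int i = 0; i < nx; ++i) buf[idx3(i, j, k, nx, ny)] = d[i];
  }
  // y pass
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) f[j] = buf[idx3(i, j, k, nx, ny)];
    dt1d(f.data(), d.data(), ny, v, z);
    for (int j = 0; j < ny; ++j) buf[idx3(i, j, k, nx, ny)] = d[j];
  }
  // z pass
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < nz; ++k) f[k] = buf[idx3(i, j, k, nx, ny)];
    dt1d(f.data(), d.data(), nz, v, z);
    for (int k = 0; k < nz; ++k) buf[idx3(i, j, k, nx, ny)] = d[k];
  }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(buf[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with reflecting boundaries.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, int nx, int ny, int nz,
                          double sigma) {
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += ker[t + r];
  }
  for (double& kk : ker) kk /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  // x
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t)
        acc += ker[t + r] * a[idx3(reflect(i + t, nx), j, k, nx, ny)];
      b[idx3(i, j, k, nx, ny)] = acc;
    }
  a.swap(b);
  // y
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double acc = 0;
      for (int t = -r; t <= r; ++t)
        acc += ker[t + r] * a[idx3(i, reflect(j + t, ny), k, nx, ny)];
      b[idx3(i, j, k, nx, ny)] = acc;
    }
  a.swap(b);
  // z
  if (nz > 1) {
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t)
          acc += ker[t + r] * a[idx3(i, j, reflect(k + t, nz), nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// 6-connected component labelling of a binary volume.
// [[Rcpp::export]]
IntegerVector cpp_cc3d(LogicalVector fg, int nx, int ny, int nz) {
  IntegerVector lab(fg.size(), 0);
  int cur = 0;
  std::vector<size_t> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < fg.size(); ++s) {
    if (!fg[s] || lab[s]) continue;
    ++cur;
    stack.clear(); stack.push_back((size_t)s); lab[s] = cur;
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((size_t)nx * ny));
      for (int t = 0; t < 6; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t q = idx3(ii, jj, kk, nx, ny);
        if (fg[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Mask of voxels connected to the grid border through background (6-conn).
// [[Rcpp::export]]
LogicalVector cpp_outside_mask(LogicalVector fg, int nx, int ny, int nz) {
  LogicalVector out(fg.size(), false);
  std::vector<size_t> stack;
  auto push = [&](int i, int j, int k) {
    size_t q = idx3(i, j, k, nx, ny);
    if (!fg[q] && !out[q]) { out[q] = true; stack.push_back(q); }
  };
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    push(i, j, 0); push(i, j, nz - 1);
  }
  for (int k = 0; k < nz; ++k) for (int i = 0; i < nx; ++i) {
    push(i, 0, k); push(i, ny - 1, k);
  }
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) {
    push(0, j, k); push(nx - 1, j, k);
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    size_t p = stack.back(); stack.pop_back();
    int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((size_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      push(ii, jj, kk);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra isosurfacing. Grid coordinates are 0-based voxel
// indices; the R caller shifts to its 1-based convention. Vertices are
// deduplicated per lattice edge, so the mesh is watertight by construction.
struct EdgeKeyHash {
  size_t operator()(const std::pair<size_t, size_t>& p) const {
    return std::hash<size_t>()(p.first * 1000003u ^ p.second);
  }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, int nx, int ny, int nz, double iso) {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<std::pair<size_t, size_t>, int, EdgeKeyHash> edgeMap;
  const int off[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                         {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                          {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  auto gid = [&](int i, int j, int k) { return idx3(i, j, k, nx, ny); };
  auto edgeVertex = [&](size_t ga, size_t gb, double sa, double sb,
                        double ax, double ay, double az,
                        double bx, double by, double bz) -> int {
    std::pair<size_t, size_t> key = ga < gb ? std::make_pair(ga, gb)
                                            : std::make_pair(gb, ga);
    auto it = edgeMap.find(key);
    if (it != edgeMap.end()) return it->second;
    double t = sa / (sa - sb);
    if (t < 1e-6) t = 1e-6;
    if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    int id = (int)vx.size() - 1;
    edgeMap[key] = id;
    return id;
  };
  double cs[8]; size_t cg[8]; double cx[8], cy[8], cz[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          cg[c] = gid(ii, jj, kk);
          double s = vol[cg[c]] - iso;
          if (s == 0.0) s = 1e-12;  // nudge to avoid degenerate cuts
          cs[c] = s;
          cx[c] = ii; cy[c] = jj; cz[c] = kk;
          if (s > 0) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int corn[4] = {a, b, c, d};
          int inside[4], outside[4]; int ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) {
            if (cs[corn[q]] > 0) inside[ni++] = corn[q];
            else outside[no++] = corn[q];
          }
          if (ni == 0 || ni == 4) continue;
          auto ev = [&](int A, int B) {
            return edgeVertex(cg[A], cg[B], cs[A], cs[B],
                              cx[A], cy[A], cz[A], cx[B], cy[B], cz[B]);
          };
          auto emit = [&](int p1, int p2, int p3,
                          double inx, double iny, double inz) {
            // orient so the normal points away from the inside centroid
            double ux = vx[p2] - vx[p1], uy = vy[p2] - vy[p1], uz = vz[p2] - vz[p1];
            double wx = vx[p3] - vx[p1], wy = vy[p3] - vy[p1], wz = vz[p3] - vz[p1];
            double nxx = uy * wz - uz * wy, nyy = uz * wx - ux * wz,
                   nzz = ux * wy - uy * wx;
            double gx = (vx[p1] + vx[p2] + vx[p3]) / 3.0 - inx;
            double gy = (vy[p1] + vy[p2] + vy[p3]) / 3.0 - iny;
            double gz = (vz[p1] + vz[p2] + vz[p3]) / 3.0 - inz;
            if (nxx * gx + nyy * gy + nzz * gz < 0) std::swap(p2, p3);
            tri.push_back(p1); tri.push_back(p2); tri.push_back(p3);
          };
          if (ni == 1) {
            int A = inside[0];
            emit(ev(A, outside[0]), ev(A, outside[1]), ev(A, outside[2]),
                 cx[A], cy[A], cz[A]);
          } else if (ni == 3) {
            int A = outside[0];
            double inx = (cx[inside[0]] + cx[inside[1]] + cx[inside[2]]) / 3.0;
            double iny = (cy[inside[0]] + cy[inside[1]] + cy[inside[2]]) / 3.0;
            double inz = (cz[inside[0]] + cz[inside[1]] + cz[inside[2]]) / 3.0;
            emit(ev(inside[0], A), ev(inside[1], A), ev(inside[2], A),
                 inx, iny, inz);
          } else {  // 2-2
            int A = inside[0], B = inside[1], C = outside[0], D = outside[1];
            int pAC = ev(A, C), pAD = ev(A, D), pBC = ev(B, C), pBD = ev(B, D);
            double inx = 0.5 * (cx[A] + cx[B]), iny = 0.5 * (cy[A] + cy[B]),
                   inz = 0.5 * (cz[A] + cz[B]);
            emit(pAC, pAD, pBD, inx, iny, inz);
            emit(pAC, pBD, pBC, inx, iny, inz);
          }
        }
      }
  int nV = (int)vx.size();
  NumericMatrix V(nV, 3);
  for (int i = 0; i < nV; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  int nF = (int)tri.size() / 3;
  IntegerMatrix F(nF, 3);
  for (int f = 0; f < nF; ++f) {
    F(f, 0) = tri[3 * f]; F(f, 1) = tri[3 * f + 1]; F(f, 2) = tri[3 * f + 2];
  }
  return List::create(_["V"] = V, _["F"] = F);
}

// ---------------------------------------------------------------------------
// Closest point on triangle (Ericson, Real-Time Collision Detection).
static void closestPtTri(const double* p, const double* a, const double* b,
                         const double* c, double* out, double* bary) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; bary[0]=1;bary[1]=0;bary[2]=0; return; }
  double bp[3]; for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; bary[0]=0;bary[1]=1;bary[2]=0; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    bary[0]=1-v;bary[1]=v;bary[2]=0; return;
  }
  double cp[3]; for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; bary[0]=0;bary[1]=0;bary[2]=1; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    bary[0]=1-w;bary[1]=0;bary[2]=w; return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    bary[0]=0;bary[1]=1-w;bary[2]=w; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
  bary[0]=1-v-w;bary[1]=v;bary[2]=w;
}

// Nearest triangle query with a uniform-grid spatial index ("AABB tree
// equivalent" per the contract). Returns 1-based face index, barycentric
// weights, distance and foot point for each query point.
// [[Rcpp::export]]
List cpp_closest_triangle(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int nF = F.nrow(), nP = P.nrow();
  // bounding box
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf; hi[d] = R_NegInf;
    for (int i = 0; i < V.nrow(); ++i) {
      lo[d] = std::min(lo[d], V(i, d)); hi[d] = std::max(hi[d], V(i, d));
    }
    double pad = 1e-9 + 1e-6 * (hi[d] - lo[d]); lo[d] -= pad; hi[d] += pad;
  }
  double ext[3] = {hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2]};
  double vol = std::max(ext[0]*ext[1]*ext[2], 1e-30);
  double h = std::cbrt(vol / std::max(nF, 1));
  if (h <= 0) h = 1.0;
  int ncell[3];
  for (int d = 0; d < 3; ++d)
    ncell[d] = std::max(1, std::min(256, (int)std::ceil(ext[d] / h)));
  double cw[3];
  for (int d = 0; d < 3; ++d) cw[d] = ext[d] / ncell[d];
  size_t ntot = (size_t)ncell[0]*ncell[1]*ncell[2];
  std::vector<std::vector<int> > bins(ntot);
  auto cellOf = [&](double x, int d) {
    int c = (int)((x - lo[d]) / cw[d]);
    return std::max(0, std::min(ncell[d]-1, c));
  };
  for (int f = 0; f < nF; ++f) {
    double flo[3], fhi[3];
    for (int d = 0; d < 3; ++d) {
      double x0 = V(F(f,0)-1,d), x1 = V(F(f,1)-1,d), x2 = V(F(f,2)-1,d);
      flo[d] = std::min(x0, std::min(x1, x2));
      fhi[d] = std::max(x0, std::max(x1, x2));
    }
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) { c0[d] = cellOf(flo[d], d); c1[d] = cellOf(fhi[d], d); }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          bins[idx3(i, j, k, ncell[0], ncell[1])].push_back(f);
  }
  std::vector<int> stamp(nF, -1);
  IntegerVector faceOut(nP);
  NumericMatrix baryOut(nP, 3), footOut(nP, 3);
  NumericVector distOut(nP);
  double minw = std::min(cw[0], std::min(cw[1], cw[2]));
  int maxR = ncell[0] + ncell[1] + ncell[2] + 2;
  for (int q = 0; q < nP; ++q) {
    double p[3] = {P(q,0), P(q,1), P(q,2)};
    int ci = cellOf(p[0],0), cj = cellOf(p[1],1), ck = cellOf(p[2],2);
    double best = R_PosInf; int bestF = -1; double bestB[3] = {0,0,0}, bestPt[3] = {0,0,0};
    for (int r = 0; r <= maxR; ++r) {
      if (bestF >= 0 && (double)(r - 1) * minw > best) break;
      bool any = false;
      int i0 = std::max(0, ci - r), i1 = std::min(ncell[0]-1, ci + r);
      int j0 = std::max(0, cj - r), j1 = std::min(ncell[1]-1, cj + r);
      int k0 = std::max(0, ck - r), k1 = std::min(ncell[2]-1, ck + r);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            int rr = std::max(std::abs(i-ci), std::max(std::abs(j-cj), std::abs(k-ck)));
            if (rr != r) continue;  // shell only
            any = true;
            const std::vector<int>& lst = bins[idx3(i, j, k, ncell[0], ncell[1])];
            for (size_t t = 0; t < lst.size(); ++t) {
              int f = lst[t];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              int v0 = F(f,0) - 1, v1 = F(f,1) - 1, v2 = F(f,2) - 1;
              double a[3] = {V(v0,0), V(v0,1), V(v0,2)};
              double b[3] = {V(v1,0), V(v1,1), V(v1,2)};
              double c[3] = {V(v2,0), V(v2,1), V(v2,2)};
              double pt[3], bc[3];
              closestPtTri(p, a, b, c, pt, bc);
              double dd = 0;
              for (int d = 0; d < 3; ++d) dd += (pt[d]-p[d])*(pt[d]-p[d]);
              dd = std::sqrt(dd);
              if (dd < best || (dd == best && f < bestF)) {
                best = dd; bestF = f;
                for (int d = 0; d < 3; ++d) { bestB[d] = bc[d]; bestPt[d] = pt[d]; }
              }
            }
          }
      if (!any && bestF >= 0) break;
    }
    faceOut[q] = bestF + 1;
    distOut[q] = best;
    for (int d = 0; d < 3; ++d) { baryOut(q,d) = bestB[d]; footOut(q,d) = bestPt[d]; }
  }
  return List::create(_["face"] = faceOut, _["bary"] = baryOut,
                      _["dist"] = distOut, _["point"] = footOut);
}

// ---------------------------------------------------------------------------
// Trilinear sampling of a volume at fractional 1-based coordinates.
// Out-of-range points get `fill`; the count is returned.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, int nx, int ny, int nz,
                   NumericMatrix P, double fill) {
  int n = P.nrow();
  NumericVector out(n);
  int nOut = 0;
  for (int q = 0; q < n; ++q) {
    double x = P(q,0) - 1.0, y = P(q,1) - 1.0, z = P(q,2) - 1.0;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1 ||
        ISNAN(x) || ISNAN(y) || ISNAN(z)) {
      out[q] = fill; ++nOut; continue;
    }
    int i0 = std::min((int)std::floor(x), nx - 2 < 0 ? 0 : nx - 2);
    int j0 = std::min((int)std::floor(y), ny - 2 < 0 ? 0 : ny - 2);
    int k0 = std::min((int)std::floor(z), nz - 2 < 0 ? 0 : nz - 2);
    if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = vol[idx3(i0,j0,k0,nx,ny)], c100 = vol[idx3(i1,j0,k0,nx,ny)];
    double c010 = vol[idx3(i0,j1,k0,nx,ny)], c110 = vol[idx3(i1,j1,k0,nx,ny)];
    double c001 = vol[idx3(i0,j0,k1,nx,ny)], c101 = vol[idx3(i1,j0,k1,nx,ny)];
    double c011 = vol[idx3(i0,j1,k1,nx,ny)], c111 = vol[idx3(i1,j1,k1,nx,ny)];
    double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
    out[q] = c0 + fz * (c1 - c0);
  }
  return List::create(_["values"] = out, _["n_outside"] = nOut);
}

// ---------------------------------------------------------------------------
// Union-find connected components of a graph over n nodes (1-based edges).
// [[Rcpp::export]]
IntegerVector cpp_graph_components(int n, IntegerMatrix edges) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = find(edges(e, 0) - 1), b = find(edges(e, 1) - 1);
    if (a != b) parent[a] = b;
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++cur; lab[i] = cur; }
    else lab[i] = it->second;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Topology-preserving mesh decimation by shortest-edge collapse with the
// link condition. Faces are 1-based; returns a compacted 1-based mesh.
// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int targetV) {
  int nv = Vin.nrow(), nf = Fin.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i]=Vin(i,0); Y[i]=Vin(i,1); Z[i]=Vin(i,2); }
  std::vector<std::array<int,3> > faces(nf);
  std::vector<bool> faceAlive(nf, true), vertAlive(nv, true);
  std::vector<std::set<int> > vFaces(nv), vNbr(nv);
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) faces[f][c] = Fin(f, c) - 1;
    for (int c = 0; c < 3; ++c) {
      vFaces[faces[f][c]].insert(f);
      vNbr[faces[f][c]].insert(faces[f][(c+1)%3]);
      vNbr[faces[f][c]].insert(faces[f][(c+2)%3]);
    }
  }
  auto elen2 = [&](int a, int b) {
    double dx=X[a]-X[b], dy=Y[a]-Y[b], dz=Z[a]-Z[b];
    return dx*dx+dy*dy+dz*dz;
  };
  typedef std::pair<double, std::pair<int,int> > QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;
  for (int a = 0; a < nv; ++a)
    for (int b : vNbr[a]) if (b > a) heap.push({elen2(a,b), {a,b}});
  int alive = nv;
  std::vector<int> common;
  while (alive > targetV && !heap.empty()) {
    QE top = heap.top(); heap.pop();
    int a = top.second.first, b = top.second.second;
    if (!vertAlive[a] || !vertAlive[b]) continue;
    if (!vNbr[a].count(b)) continue;
    double cur = elen2(a, b);
    if (top.first < cur * (1.0 - 1e-12)) { heap.push({cur, {a,b}}); continue; }
    // link condition: common neighbors must be exactly the two opposites
    common.clear();
    for (int x : vNbr[a]) if (x != b && vNbr[b].count(x)) common.push_back(x);
    std::vector<int> shared;  // faces containing both a and b
    for (int f : vFaces[a]) if (faceAlive[f] && vFaces[b].count(f)) shared.push_back(f);
    if (shared.size() != 2 || common.size() != 2) continue;
    // avoid collapsing a tetrahedron-like pocket into a duplicate face
    bool dupRisk = false;
    for (int f : vFaces[a]) {
      if (!faceAlive[f]) continue;
      bool hasB = false; int o[2]; int no = 0;
      for (int c = 0; c < 3; ++c) {
        int v = faces[f][c];
        if (v == b) hasB = true;
        else if (v != a && no < 2) o[no++] = v;
      }
      if (hasB || no != 2) continue;
      // would become (b, o0, o1): does that face already exist?
      for (int g : vFaces[b]) {
        if (!faceAlive[g] || g == f) continue;
        int cnt = 0;
        for (int c = 0; c < 3; ++c)
          if (faces[g][c] == o[0] || faces[g][c] == o[1] || faces[g][c] == b) ++cnt;
        if (cnt == 3) { dupRisk = true; break; }
      }
      if (dupRisk) break;
    }
    if (dupRisk) continue;
    // collapse a -> b at the midpoint
    X[b] = 0.5*(X[a]+X[b]); Y[b] = 0.5*(Y[a]+Y[b]); Z[b] = 0.5*(Z[a]+Z[b]);
    for (int f : shared) {
      faceAlive[f] = false;
      for (int c = 0; c < 3; ++c) {
        vFaces[faces[f][c]].erase(f);
      }
    }
    std::vector<int> af(vFaces[a].begin(), vFaces[a].end());
    for (int f : af) {
      if (!faceAlive[f]) continue;
      for (int c = 0; c < 3; ++c) if (faces[f][c] == a) faces[f][c] = b;
      vFaces[a].erase(f); vFaces[b].insert(f);
    }
    for (int x : vNbr[a]) {
      if (x == b) continue;
      vNbr[x].erase(a); vNbr[x].insert(b); vNbr[b].insert(x);
    }
    vNbr[b].erase(a);
    vNbr[a].clear(); vFaces[a].clear();
    vertAlive[a] = false; --alive;
    for (int x : vNbr[b]) heap.push({elen2(b,x), {std::min(b,x), std::max(b,x)}});
  }
  // compact
  std::vector<int> remap(nv, 0);
  int nvOut = 0;
  for (int i = 0; i < nv; ++i) if (vertAlive[i]) remap[i] = nvOut++;
  NumericMatrix Vout(nvOut, 3);
  for (int i = 0; i < nv; ++i) if (vertAlive[i]) {
    Vout(remap[i],0)=X[i]; Vout(remap[i],1)=Y[i]; Vout(remap[i],2)=Z[i];
  }
  int nfOut = 0;
  for (int f = 0; f < nf; ++f) if (faceAlive[f]) ++nfOut;
  IntegerMatrix Fout(nfOut, 3);
  int r = 0;
  for (int f = 0; f < nf; ++f) if (faceAlive[f]) {
    for (int c = 0; c < 3; ++c) Fout(r, c) = remap[faces[f][c]] + 1;
    ++r;
  }
  return List::create(_["V"] = Vout, _["F"] = Fout);
}
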