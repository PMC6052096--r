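// Compiled core: trilinear sampling, gradients, scanline mesh voxelization,
// surface-sampled texture features, node-wise free-form registration sweeps,
// and the per-sampling-vertex local fusion-weight sweeps.
//
// Conventions: voxel indices are 0-based; continuous voxel coordinates place
// voxel centers at integers; "mm" positions relate to voxel coordinates via
// an axis-aligned mapping x_mm = origin + spacing * idx (validated in R).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// ---------------------------------------------------------------- utilities

struct Grid {
  const double* v;
  int nx, ny, nz;
  inline size_t lin(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
  }
  inline double at(int i, int j, int k) const { return v[lin(i, j, k)]; }
  inline bool in(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
};

// Trilinear interpolation at continuous voxel coordinate; outside the
// voxel-center hull [0, n-1]^3 the fill value is returned.
static double trilin(const Grid& g, double x, double y, double z, double fill) {
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= g.nx - 1.0 && y <= g.ny - 1.0 && z <= g.nz - 1.0))
    return fill;
  int i0 = (int)std::floor(x); if (i0 == g.nx - 1) i0--;
  int j0 = (int)std::floor(y); if (j0 == g.ny - 1) j0--;
  int k0 = (int)std::floor(z); if (k0 == g.nz - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c000 = g.at(i0, j0, k0),     c100 = g.at(i0 + 1, j0, k0);
  double c010 = g.at(i0, j0 + 1, k0), c110 = g.at(i0 + 1, j0 + 1, k0);
  double c001 = g.at(i0, j0, k0 + 1), c101 = g.at(i0 + 1, j0, k0 + 1);
  double c011 = g.at(i0, j0 + 1, k0 + 1), c111 = g.at(i0 + 1, j0 + 1, k0 + 1);
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts, double fill) {
  Grid g{vol.begin(), dim[0], dim[1], dim[2]};
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = trilin(g, pts(i, 0), pts(i, 1), pts(i, 2), fill);
  return out;
}

// Gradient magnitude by central differences (one-sided at borders), mm^-1.
// [[Rcpp::export]]
NumericVector cpp_gradmag(NumericVector vol, IntegerVector dim,
                          NumericVector spacing) {
  Grid g{vol.begin(), dim[0], dim[1], dim[2]};
  NumericVector out(vol.size());
  for (int k = 0; k < g.nz; k++)
    for (int j = 0; j < g.ny; j++)
      for (int i = 0; i < g.nx; i++) {
        int il = std::max(i - 1, 0), ih = std::min(i + 1, g.nx - 1);
        int jl = std::max(j - 1, 0), jh = std::min(j + 1, g.ny - 1);
        int kl = std::max(k - 1, 0), kh = std::min(k + 1, g.nz - 1);
        double gx = (g.at(ih, j, k) - g.at(il, j, k)) / ((ih - il) * spacing[0]);
        double gy = (g.at(i, jh, k) - g.at(i, jl, k)) / ((jh - jl) * spacing[1]);
        double gz = (g.at(i, j, kh) - g.at(i, j, kl)) / ((kh - kl) * spacing[2]);
        out[g.lin(i, j, k)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

// ------------------------------------------------------------- voxelization

// Scanline parity voxelizer along the x axis, in continuous voxel coords.
// Ray origins are jittered by a tiny fixed offset so rays never hit mesh
// edges/vertices exactly (deterministic).
static const double EPSY = 4.9e-7, EPSZ = 8.63e-7;

struct ScanMesh {
  const double* vx; const double* vy; const double* vz; // vertex coords (vox)
  int nv;
  const int* f0; const int* f1; const int* f2;          // faces, 0-based
  int nf;
};

// All x-crossings of the +x ray through (y, z); appended to xs.
static void line_crossings(const ScanMesh& m, double y, double z,
                           std::vector<double>& xs) {
  xs.clear();
  for (int f = 0; f < m.nf; f++) {
    int a = m.f0[f], b = m.f1[f], c = m.f2[f];
    double ay = m.vy[a] - y, az = m.vz[a] - z;
    double by = m.vy[b] - y, bz = m.vz[b] - z;
    double cy = m.vy[c] - y, cz = m.vz[c] - z;
    // 2D barycentric in (y,z) projection
    double d = (by - ay) * (cz - az) - (cy - ay) * (bz - az);
    if (d == 0.0) continue;
    double w1 = (-ay * (cz - az) + az * (cy - ay)) / d;   // weight of b
    double w2 = (ay * (bz - az) - az * (by - ay)) / d;    // weight of c
    double w0 = 1.0 - w1 - w2;
    if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
    xs.push_back(w0 * m.vx[a] + w1 * m.vx[b] + w2 * m.vx[c]);
  }
  std::sort(xs.begin(), xs.end());
}

// Set/clear `bit` in mask along one x-line according to crossing parity.
static void fill_line(int* mask, const Grid& dims, int j, int k, int bit,
                      const std::vector<double>& xs) {
  size_t base = dims.lin(0, j, k);
  for (int i = 0; i < dims.nx; i++) mask[base + i] &= ~bit;
  size_t npair = xs.size() / 2;
  for (size_t p = 0; p < npair; p++) {
    double a = xs[2 * p], b = xs[2 * p + 1];
    int lo = (int)std::ceil(a);  if ((double)lo == a) lo++;
    int hi = (int)std::floor(b); if ((double)hi == b) hi--;
    lo = std::max(lo, 0); hi = std::min(hi, dims.nx - 1);
    for (int i = lo; i <= hi; i++) mask[base + i] |= bit;
  }
}

static void scan_mesh(const ScanMesh& m, int* mask, const Grid& dims, int bit,
                      int jlo, int jhi, int klo, int khi) {
  std::vector<double> xs;
  for (int k = klo; k <= khi; k++)
    for (int j = jlo; j <= jhi; j++) {
      line_crossings(m, j + EPSY, k + EPSZ, xs);
      fill_line(mask, dims, j, k, bit, xs);
    }
}

// Voxel centers strictly inside the mesh -> bit set. verts in voxel coords.
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector dim, int bit,
                           Nullable<IntegerVector> mask_ = R_NilValue) {
  int nv = verts.nrow(), nf = faces.nrow();
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; i++) { vx[i] = verts(i,0); vy[i] = verts(i,1); vz[i] = verts(i,2); }
  std::vector<int> f0(nf), f1(nf), f2(nf);
  for (int f = 0; f < nf; f++) { f0[f] = faces(f,0); f1[f] = faces(f,1); f2[f] = faces(f,2); }
  ScanMesh m{vx.data(), vy.data(), vz.data(), nv, f0.data(), f1.data(), f2.data(), nf};
  IntegerVector mask = mask_.isNull()
    ? IntegerVector((R_xlen_t)dim[0] * dim[1] * dim[2])
    : IntegerVector(mask_.get());
  Grid dims{nullptr, dim[0], dim[1], dim[2]};
  double ylo = *std::min_element(vy.begin(), vy.end());
  double yhi = *std::max_element(vy.begin(), vy.end());
  double zlo = *std::min_element(vz.begin(), vz.end());
  double zhi = *std::max_element(vz.begin(), vz.end());
  int jlo = std::max((int)std::floor(ylo), 0), jhi = std::min((int)std::ceil(yhi), dims.ny - 1);
  int klo = std::max((int)std::floor(zlo), 0), khi = std::min((int)std::ceil(zhi), dims.nz - 1);
  scan_mesh(m, mask.begin(), dims, bit, jlo, jhi, klo, khi);
  return mask;
}

// Min unsigned distance from each point to any triangle of the mesh (coords
// shared between points and vertices; typically mm).
static double point_tri_dist2(double px, double py, double pz,
                              const double* A, const double* B, const double* C) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
  double ac[3] = {C[0]-A[0], C[1]-A[1], C[2]-A[2]};
  double ap[3] = {px-A[0], py-A[1], pz-A[2]};
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double qx, qy, qz;
  if (d1 <= 0 && d2 <= 0) { qx=A[0]; qy=A[1]; qz=A[2]; }
  else {
    double bp[3] = {px-B[0], py-B[1], pz-B[2]};
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { qx=B[0]; qy=B[1]; qz=B[2]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        qx=A[0]+v*ab[0]; qy=A[1]+v*ab[1]; qz=A[2]+v*ab[2];
      } else {
        double cp[3] = {px-C[0], py-C[1], pz-C[2]};
        double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
        double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
        if (d6 >= 0 && d5 <= d6) { qx=C[0]; qy=C[1]; qz=C[2]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double w = d2 / (d2 - d6);
            qx=A[0]+w*ac[0]; qy=A[1]+w*ac[1]; qz=A[2]+w*ac[2];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              qx=B[0]+w*(C[0]-B[0]); qy=B[1]+w*(C[1]-B[1]); qz=B[2]+w*(C[2]-B[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              qx=A[0]+ab[0]*v+ac[0]*w; qy=A[1]+ab[1]*v+ac[1]*w; qz=A[2]+ab[2]*v+ac[2]*w;
            }
          }
        }
      }
    }
  }
  double dx=px-qx, dy=py-qy, dz=pz-qz;
  return dx*dx+dy*dy+dz*dz;
}

// [[Rcpp::export]]
NumericVector cpp_mesh_dist(NumericMatrix pts, NumericMatrix verts,
                            IntegerMatrix faces) {
  int n = pts.nrow(), nf = faces.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int f = 0; f < nf; f++) {
      double A[3] = {verts(faces(f,0),0), verts(faces(f,0),1), verts(faces(f,0),2)};
      double B[3] = {verts(faces(f,1),0), verts(faces(f,1),1), verts(faces(f,1),2)};
      double C[3] = {verts(faces(f,2),0), verts(faces(f,2),1), verts(faces(f,2),2)};
      double d2 = point_tri_dist2(pts(i,0), pts(i,1), pts(i,2), A, B, C);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ------------------------------------------------------------ features

struct FeatCtx {
  Grid vol, grad, bits;      // bits carries int mask reinterpreted via ibits
  const int* ibits;
  NumericVector spacing;
  double fill;
  // per radius: integer offsets and radius in mm
  std::vector<std::vector<std::array<int,3>>> offs;
  std::vector<double> radii;
};

static const double SD_FLOOR = 1e-6;

// Compute the 9 features (NI/RI/IG x 3 radii) at one continuous voxel-coord
// position for a structure identified by `bit`. feats must hold 9 doubles.
static bool features_at(const FeatCtx& cx, double px, double py, double pz,
                        int bit, double* feats) {
  bool flagged = false;
  int n0x = (int)std::llround(px), n0y = (int)std::llround(py),
      n0z = (int)std::llround(pz);
  double sx = cx.spacing[0], sy = cx.spacing[1], sz = cx.spacing[2];
  for (size_t r = 0; r < cx.radii.size(); r++) {
    double rr = cx.radii[r], rr2 = rr * rr;
    double sIR = 0, sIR2 = 0, sOR = 0, sG = 0;
    int nIR = 0, nOR = 0, nG = 0;
    for (const auto& o : cx.offs[r]) {
      int i = n0x + o[0], j = n0y + o[1], k = n0z + o[2];
      double dx = (i - px) * sx, dy = (j - py) * sy, dz = (k - pz) * sz;
      if (dx * dx + dy * dy + dz * dz > rr2) continue;
      double val, gval; bool inside;
      if (cx.vol.in(i, j, k)) {
        size_t li = cx.vol.lin(i, j, k);
        val = cx.vol.v[li];
        gval = cx.grad.v[li];
        inside = (cx.ibits[li] & bit) != 0;
      } else { val = cx.fill; gval = 0.0; inside = false; }
      if (inside) { sIR += val; sIR2 += val * val; nIR++; }
      else        { sOR += val; nOR++; }
      sG += gval; nG++;
    }
    if (nIR == 0 || nOR == 0) {
      feats[r] = 0.0; feats[3 + r] = 0.0; flagged = true;
    } else {
      double muIR = sIR / nIR;
      double varIR = sIR2 / nIR - muIR * muIR;
      if (varIR < 0) varIR = 0;
      double sdIR = std::sqrt(varIR);
      feats[r] = muIR / std::max(sdIR, SD_FLOOR);
      double muOR = sOR / nOR;
      double den = muOR + muIR;
      if (std::fabs(den) < 1e-6) { feats[3 + r] = 0.0; flagged = true; }
      else feats[3 + r] = 2.0 * (muOR - muIR) / den;
    }
    feats[6 + r] = nG > 0 ? sG / nG : 0.0;
  }
  return flagged;
}

static FeatCtx make_ctx(NumericVector vol, NumericVector grad, IntegerVector dim,
                        NumericVector spacing, IntegerVector bits,
                        List offsets, NumericVector radii, double fill) {
  FeatCtx cx;
  cx.vol = Grid{vol.begin(), dim[0], dim[1], dim[2]};
  cx.grad = Grid{grad.begin(), dim[0], dim[1], dim[2]};
  cx.bits = cx.vol;
  cx.ibits = bits.begin();
  cx.spacing = spacing;
  cx.fill = fill;
  for (int r = 0; r < offsets.size(); r++) {
    IntegerMatrix om = offsets[r];
    std::vector<std::array<int,3>> v(om.nrow());
    for (int i = 0; i < om.nrow(); i++) v[i] = {om(i,0), om(i,1), om(i,2)};
    cx.offs.push_back(std::move(v));
    cx.radii.push_back(radii[r]);
  }
  return cx;
}

// verts in voxel coords; vert_bit = structure bit (1/2/4) per vertex.
// [[Rcpp::export]]
NumericMatrix cpp_features(NumericVector vol, NumericVector grad,
                           IntegerVector dim, NumericVector spacing,
                           IntegerVector inside_bits, NumericMatrix verts,
                           IntegerVector vert_bit, List offsets,
                           NumericVector radii, double fill) {
  FeatCtx cx = make_ctx(vol, grad, dim, spacing, inside_bits, offsets, radii, fill);
  int V = verts.nrow();
  NumericMatrix out(V, 9);
  LogicalVector flg(V);
  double f[9];
  for (int v = 0; v < V; v++) {
    flg[v] = features_at(cx, verts(v,0), verts(v,1), verts(v,2), vert_bit[v], f);
    for (int c = 0; c < 9; c++) out(v, c) = f[c];
  }
  out.attr("flagged") = flg;
  return out;
}

// ------------------------------------------------------------ Nelder-Mead

// Minimal deterministic Nelder-Mead (minimization). Returns best point.
static std::vector<double> nelder_mead(
    std::function<double(const double*)> fn, std::vector<double> x0,
    double step, int maxit, double ftol, double* fbest_out) {
  int n = (int)x0.size();
  std::vector<std::vector<double>> S(n + 1, x0);
  std::vector<double> fv(n + 1);
  for (int i = 0; i < n; i++) S[i + 1][i] += step;
  for (int i = 0; i <= n; i++) fv[i] = fn(S[i].data());
  int nev = n + 1;
  std::vector<double> xr(n), xe(n), xc(n), cen(n);
  while (nev < maxit) {
    // order
    std::vector<int> ord(n + 1);
    for (int i = 0; i <= n; i++) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b){ return fv[a] < fv[b]; });
    std::vector<std::vector<double>> S2(n + 1); std::vector<double> f2(n + 1);
    for (int i = 0; i <= n; i++) { S2[i] = S[ord[i]]; f2[i] = fv[ord[i]]; }
    S = S2; fv = f2;
    if (std::fabs(fv[n] - fv[0]) <= ftol * (std::fabs(fv[0]) + ftol)) break;
    for (int d = 0; d < n; d++) {
      cen[d] = 0;
      for (int i = 0; i < n; i++) cen[d] += S[i][d];
      cen[d] /= n;
    }
    for (int d = 0; d < n; d++) xr[d] = cen[d] + (cen[d] - S[n][d]);
    double fr = fn(xr.data()); nev++;
    if (fr < fv[0]) {
      for (int d = 0; d < n; d++) xe[d] = cen[d] + 2.0 * (cen[d] - S[n][d]);
      double fe = fn(xe.data()); nev++;
      if (fe < fr) { S[n] = xe; fv[n] = fe; } else { S[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      S[n] = xr; fv[n] = fr;
    } else {
      bool outside = fr < fv[n];
      if (outside)
        for (int d = 0; d < n; d++) xc[d] = cen[d] + 0.5 * (xr[d] - cen[d]);
      else
        for (int d = 0; d < n; d++) xc[d] = cen[d] + 0.5 * (S[n][d] - cen[d]);
      double fc = fn(xc.data()); nev++;
      if (fc < std::min(fr, fv[n])) { S[n] = xc; fv[n] = fc; }
      else { // shrink
        for (int i = 1; i <= n; i++) {
          for (int d = 0; d < n; d++) S[i][d] = S[0][d] + 0.5 * (S[i][d] - S[0][d]);
          fv[i] = fn(S[i].data()); nev++;
        }
      }
    }
  }
  int ib = 0;
  for (int i = 1; i <= n; i++) if (fv[i] < fv[ib]) ib = i;
  if (fbest_out) *fbest_out = fv[ib];
  return S[ib];
}

// ------------------------------------------------------------ registration

struct Corr { double sx = 0, sxx = 0, sy = 0, syy = 0, sxy = 0; long n = 0; };
static double corr_of(const Corr& c) {
  if (c.n < 2) return 0.0;
  double vx = c.n * c.sxx - c.sx * c.sx;
  double vy = c.n * c.syy - c.sy * c.sy;
  if (vx <= 0 || vy <= 0) return 0.0;
  return (c.n * c.sxy - c.sx * c.sy) / std::sqrt(vx * vy);
}

// Tangent-plane RI at a test-space position (mm) with a given outward normal.
static double plane_ri(const Grid& test, NumericVector spacing,
                       NumericVector origin,
                       const std::vector<std::array<int,3>>& offs, double radius,
                       double px, double py, double pz,
                       double nxn, double nyn, double nzn, double fill) {
  double vx = (px - origin[0]) / spacing[0];
  double vy = (py - origin[1]) / spacing[1];
  double vz = (pz - origin[2]) / spacing[2];
  int n0x = (int)std::llround(vx), n0y = (int)std::llround(vy),
      n0z = (int)std::llround(vz);
  double rr2 = radius * radius;
  double sIR = 0, sOR = 0; int nIR = 0, nOR = 0;
  for (const auto& o : offs) {
    int i = n0x + o[0], j = n0y + o[1], k = n0z + o[2];
    double dx = (i - vx) * spacing[0], dy = (j - vy) * spacing[1],
           dz = (k - vz) * spacing[2];
    if (dx * dx + dy * dy + dz * dz > rr2) continue;
    double val = test.in(i, j, k) ? test.v[test.lin(i, j, k)] : fill;
    double side = dx * nxn + dy * nyn + dz * nzn;
    if (side < 0) { sIR += val; nIR++; } else { sOR += val; nOR++; }
  }
  if (nIR == 0 || nOR == 0) return 0.0;
  double muIR = sIR / nIR, muOR = sOR / nOR, den = muOR + muIR;
  if (std::fabs(den) < 1e-6) return 0.0;
  return 2.0 * (muOR - muIR) / den;
}

// Tangent-plane RI at arbitrary world-mm positions (exported for the
// template-side registration features and for tests).
// [[Rcpp::export]]
NumericVector cpp_plane_ri(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix pts, NumericMatrix normals,
                           IntegerMatrix offsets, double radius, double fill) {
  Grid g{vol.begin(), dim[0], dim[1], dim[2]};
  std::vector<std::array<int,3>> offs(offsets.nrow());
  for (int i = 0; i < offsets.nrow(); i++)
    offs[i] = {offsets(i,0), offsets(i,1), offsets(i,2)};
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = plane_ri(g, spacing, origin, offs, radius, pts(i,0), pts(i,1),
                      pts(i,2), normals(i,0), normals(i,1), normals(i,2), fill);
  return out;
}

// RI at arbitrary world-mm positions with IR/OR split by an inside-bit
// indicator volume (the voxelized surface interior).
// [[Rcpp::export]]
NumericVector cpp_indicator_ri(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix pts, IntegerVector bits,
                               IntegerVector vbit, IntegerMatrix offsets,
                               double radius, double fill) {
  Grid g{vol.begin(), dim[0], dim[1], dim[2]};
  int n = pts.nrow();
  NumericVector out(n);
  double rr2 = radius * radius;
  for (int p = 0; p < n; p++) {
    double vx = (pts(p,0) - origin[0]) / spacing[0];
    double vy = (pts(p,1) - origin[1]) / spacing[1];
    double vz = (pts(p,2) - origin[2]) / spacing[2];
    int n0x = (int)std::llround(vx), n0y = (int)std::llround(vy),
        n0z = (int)std::llround(vz);
    double sIR = 0, sOR = 0; int nIR = 0, nOR = 0;
    for (int t = 0; t < offsets.nrow(); t++) {
      int i = n0x + offsets(t,0), j = n0y + offsets(t,1), k = n0z + offsets(t,2);
      double dx = (i - vx) * spacing[0], dy = (j - vy) * spacing[1],
             dz = (k - vz) * spacing[2];
      if (dx * dx + dy * dy + dz * dz > rr2) continue;
      double val; bool inside;
      if (g.in(i, j, k)) {
        size_t li = g.lin(i, j, k);
        val = g.v[li];
        inside = (bits[li] & vbit[p]) != 0;
      } else { val = fill; inside = false; }
      if (inside) { sIR += val; nIR++; } else { sOR += val; nOR++; }
    }
    if (nIR == 0 || nOR == 0) { out[p] = 0.0; continue; }
    double muIR = sIR / nIR, muOR = sOR / nOR, den = muOR + muIR;
    out[p] = std::fabs(den) < 1e-6 ? 0.0 : 2.0 * (muOR - muIR) / den;
  }
  return out;
}

// One resolution level of the hybrid free-form registration.
// Lattice nodes carry incremental displacements (mm) of the backward map;
// prev_* carry the frozen displacement of coarser levels.
// [[Rcpp::export]]
List cpp_register_level(NumericVector tmpl, NumericVector test,
                        IntegerVector dim, NumericVector spacing,
                        NumericVector origin, IntegerVector mask_idx,
                        NumericMatrix prev_disp_vol, NumericMatrix lat_init,
                        IntegerVector lat_dim, NumericVector lat_origin,
                        double lat_spacing, double cap, double lambda,
                        double w_surf, NumericMatrix sverts,
                        List sfaces, IntegerVector svstruct,
                        NumericMatrix prev_disp_surf, NumericVector F_T,
                        IntegerMatrix ri_offsets,
                        double ri_radius, int nm_maxit, int sweeps, double tol,
                        int refresh_moves, double fill) {
  Grid gt{tmpl.begin(), dim[0], dim[1], dim[2]};
  Grid gi{test.begin(), dim[0], dim[1], dim[2]};
  int lnx = lat_dim[0], lny = lat_dim[1], lnz = lat_dim[2];
  int L = lnx * lny * lnz;
  std::vector<double> lat(3 * (size_t)L);
  for (int i = 0; i < L; i++)
    for (int c = 0; c < 3; c++) lat[3 * (size_t)i + c] = lat_init(i, c);
  auto lidx = [&](int i, int j, int k) { return i + lnx * (j + lny * k); };

  int M = mask_idx.size();
  std::vector<double> xm(3 * (size_t)M);   // world mm of masked voxels
  std::vector<double> tv(M);               // test values
  for (int q = 0; q < M; q++) {
    int lin = mask_idx[q];
    int i = lin % dim[0], j = (lin / dim[0]) % dim[1], k = lin / (dim[0] * dim[1]);
    xm[3*(size_t)q]   = origin[0] + spacing[0] * i;
    xm[3*(size_t)q+1] = origin[1] + spacing[1] * j;
    xm[3*(size_t)q+2] = origin[2] + spacing[2] * k;
    tv[q] = test[lin];
  }

  // trilinear lattice weights at a world point for this level's lattice
  struct LW { int nodes[8]; double w[8]; int cnt; };
  auto lat_w = [&](double x0, double x1, double x2) {
    LW r; r.cnt = 0;
    double u = (x0 - lat_origin[0]) / lat_spacing;
    double v = (x1 - lat_origin[1]) / lat_spacing;
    double s = (x2 - lat_origin[2]) / lat_spacing;
    u = std::min(std::max(u, 0.0), lnx - 1.0);
    v = std::min(std::max(v, 0.0), lny - 1.0);
    s = std::min(std::max(s, 0.0), lnz - 1.0);
    int i0 = std::max(0, std::min((int)std::floor(u), lnx - 2));
    int j0 = std::max(0, std::min((int)std::floor(v), lny - 2));
    int k0 = std::max(0, std::min((int)std::floor(s), lnz - 2));
    double fu = u - i0, fv = v - j0, fs = s - k0;
    for (int dk = 0; dk < 2; dk++)
      for (int dj = 0; dj < 2; dj++)
        for (int di = 0; di < 2; di++) {
          double ww = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) * (dk ? fs : 1 - fs);
          r.nodes[r.cnt] = lidx(i0 + di, j0 + dj, k0 + dk);
          r.w[r.cnt] = ww;
          r.cnt++;
        }
    return r;
  };

  // precompute lattice weights per masked voxel and per surface vertex
  std::vector<LW> vox_lw(M);
  for (int q = 0; q < M; q++)
    vox_lw[q] = lat_w(xm[3*(size_t)q], xm[3*(size_t)q+1], xm[3*(size_t)q+2]);
  int Vr = sverts.nrow();
  std::vector<LW> srf_lw(Vr);
  for (int v = 0; v < Vr; v++)
    srf_lw[v] = lat_w(sverts(v,0), sverts(v,1), sverts(v,2));

  // node -> support voxel / surface vertex lists: exactly the points whose
  // trilinear lattice weight for the node is non-zero (the node's support;
  // points farther away are not displaced by a node move).
  std::vector<std::vector<int>> node_vox(L), node_srf(L);
  for (int q = 0; q < M; q++)
    for (int t = 0; t < vox_lw[q].cnt; t++)
      if (vox_lw[q].w[t] > 0) node_vox[vox_lw[q].nodes[t]].push_back(q);
  for (int v = 0; v < Vr; v++)
    for (int t = 0; t < srf_lw[v].cnt; t++)
      if (srf_lw[v].w[t] > 0) node_srf[srf_lw[v].nodes[t]].push_back(v);

  std::vector<std::array<int,3>> ri_offs(ri_offsets.nrow());
  for (int i = 0; i < ri_offsets.nrow(); i++)
    ri_offs[i] = {ri_offsets(i,0), ri_offsets(i,1), ri_offsets(i,2)};

  // current per-voxel displacement of THIS level (mm)
  auto level_disp_vox = [&](int q, int c) {
    double d = 0;
    for (int t = 0; t < vox_lw[q].cnt; t++)
      d += vox_lw[q].w[t] * lat[3*(size_t)vox_lw[q].nodes[t] + c];
    return d;
  };
  auto level_disp_srf = [&](int v, int c) {
    double d = 0;
    for (int t = 0; t < srf_lw[v].cnt; t++)
      d += srf_lw[v].w[t] * lat[3*(size_t)srf_lw[v].nodes[t] + c];
    return d;
  };

  std::vector<double> W(M);          // warped template values at masked voxels
  std::vector<double> FS(Vr);        // estimated RI on deformed surface
  auto warp_value = [&](int q, double dx, double dy, double dz) {
    double yx = xm[3*(size_t)q]   + prev_disp_vol(q,0) + dx;
    double yy = xm[3*(size_t)q+1] + prev_disp_vol(q,1) + dy;
    double yz = xm[3*(size_t)q+2] + prev_disp_vol(q,2) + dz;
    return trilin(gt, (yx - origin[0]) / spacing[0],
                      (yy - origin[1]) / spacing[1],
                      (yz - origin[2]) / spacing[2], fill);
  };

  // Inside/outside indicator of the deformed registration surface, frozen
  // between sweeps: IR/OR of the RI feature are defined by the surface
  // interior, re-voxelized at every refresh (per-sweep feature refresh).
  std::vector<int> sbits((size_t)dim[0] * dim[1] * dim[2], 0);
  auto voxelize_surf = [&]() {
    std::fill(sbits.begin(), sbits.end(), 0);
    Grid dims{nullptr, dim[0], dim[1], dim[2]};
    for (int s = 0; s < sfaces.size(); s++) {
      IntegerMatrix fm = sfaces[s];
      int bitv = 1 << s;
      std::vector<int> vids;
      for (int v = 0; v < Vr; v++) if (svstruct[v] == bitv) vids.push_back(v);
      std::vector<double> vx(Vr), vy(Vr), vz(Vr); // global indexing
      double ylo = 1e30, yhi = -1e30, zlo = 1e30, zhi = -1e30;
      for (int v : vids) {
        double d0 = 0, d1 = 0, d2 = 0;
        for (int t = 0; t < srf_lw[v].cnt; t++) {
          int nd = srf_lw[v].nodes[t];
          d0 += srf_lw[v].w[t] * lat[3*(size_t)nd];
          d1 += srf_lw[v].w[t] * lat[3*(size_t)nd+1];
          d2 += srf_lw[v].w[t] * lat[3*(size_t)nd+2];
        }
        vx[v] = (sverts(v,0) - prev_disp_surf(v,0) - d0 - origin[0]) / spacing[0];
        vy[v] = (sverts(v,1) - prev_disp_surf(v,1) - d1 - origin[1]) / spacing[1];
        vz[v] = (sverts(v,2) - prev_disp_surf(v,2) - d2 - origin[2]) / spacing[2];
        ylo = std::min(ylo, vy[v]); yhi = std::max(yhi, vy[v]);
        zlo = std::min(zlo, vz[v]); zhi = std::max(zhi, vz[v]);
      }
      int nf = fm.nrow();
      std::vector<int> f0(nf), f1(nf), f2(nf);
      for (int f = 0; f < nf; f++) { f0[f]=fm(f,0); f1[f]=fm(f,1); f2[f]=fm(f,2); }
      ScanMesh m{vx.data(), vy.data(), vz.data(), Vr,
                 f0.data(), f1.data(), f2.data(), nf};
      int jlo = std::max((int)std::floor(ylo), 0);
      int jhi = std::min((int)std::ceil(yhi), dims.ny - 1);
      int klo = std::max((int)std::floor(zlo), 0);
      int khi = std::min((int)std::ceil(zhi), dims.nz - 1);
      scan_mesh(m, sbits.data(), dims, bitv, jlo, jhi, klo, khi);
    }
  };

  auto surf_ri = [&](int v, double dx, double dy, double dz) {
    // forward-map approximation: deformed position = anchor - total disp
    double px = sverts(v,0) - (prev_disp_surf(v,0) + dx);
    double py = sverts(v,1) - (prev_disp_surf(v,1) + dy);
    double pz = sverts(v,2) - (prev_disp_surf(v,2) + dz);
    double vx = (px - origin[0]) / spacing[0];
    double vy = (py - origin[1]) / spacing[1];
    double vz = (pz - origin[2]) / spacing[2];
    int n0x = (int)std::llround(vx), n0y = (int)std::llround(vy),
        n0z = (int)std::llround(vz);
    int bitv = svstruct[v];
    double rr2 = ri_radius * ri_radius;
    double sIR = 0, sOR = 0; int nIR = 0, nOR = 0;
    for (const auto& o : ri_offs) {
      int i = n0x + o[0], j = n0y + o[1], k = n0z + o[2];
      double ddx = (i - vx) * spacing[0], ddy = (j - vy) * spacing[1],
             ddz = (k - vz) * spacing[2];
      if (ddx * ddx + ddy * ddy + ddz * ddz > rr2) continue;
      double val; bool inside;
      if (gi.in(i, j, k)) {
        size_t li = gi.lin(i, j, k);
        val = gi.v[li];
        inside = (sbits[li] & bitv) != 0;
      } else { val = fill; inside = false; }
      if (inside) { sIR += val; nIR++; } else { sOR += val; nOR++; }
    }
    if (nIR == 0 || nOR == 0) return 0.0;
    double muIR = sIR / nIR, muOR = sOR / nOR, den = muOR + muIR;
    if (std::fabs(den) < 1e-6) return 0.0;
    return 2.0 * (muOR - muIR) / den;
  };

  Corr cvol;
  Corr csrf[3];  // per-structure accumulators, pooled in surf_score()
  auto sidx = [](int bit) { return bit == 1 ? 0 : (bit == 2 ? 1 : 2); };
  auto surf_score = [&]() {
    Corr pooled;
    for (int s = 0; s < 3; s++) {
      pooled.sx += csrf[s].sx; pooled.sxx += csrf[s].sxx;
      pooled.sy += csrf[s].sy; pooled.syy += csrf[s].syy;
      pooled.sxy += csrf[s].sxy; pooled.n += csrf[s].n;
    }
    return corr_of(pooled);
  };
  double smooth_total = 0;
  auto lap_sq = [&](int i, int j, int k) {
    double s = 0;
    for (int c = 0; c < 3; c++) {
      double l = 0;
      int id = lidx(i,j,k);
      if (i > 0)       l += lat[3*(size_t)lidx(i-1,j,k)+c] - lat[3*(size_t)id+c];
      if (i < lnx - 1) l += lat[3*(size_t)lidx(i+1,j,k)+c] - lat[3*(size_t)id+c];
      if (j > 0)       l += lat[3*(size_t)lidx(i,j-1,k)+c] - lat[3*(size_t)id+c];
      if (j < lny - 1) l += lat[3*(size_t)lidx(i,j+1,k)+c] - lat[3*(size_t)id+c];
      if (k > 0)       l += lat[3*(size_t)lidx(i,j,k-1)+c] - lat[3*(size_t)id+c];
      if (k < lnz - 1) l += lat[3*(size_t)lidx(i,j,k+1)+c] - lat[3*(size_t)id+c];
      s += l * l;
    }
    return s;
  };
  auto refresh = [&]() {
    cvol = Corr();
    for (int s = 0; s < 3; s++) csrf[s] = Corr();
    for (int q = 0; q < M; q++) {
      W[q] = warp_value(q, level_disp_vox(q,0), level_disp_vox(q,1), level_disp_vox(q,2));
      cvol.sx += W[q]; cvol.sxx += W[q]*W[q]; cvol.sy += tv[q];
      cvol.syy += tv[q]*tv[q]; cvol.sxy += W[q]*tv[q]; cvol.n++;
    }
    if (w_surf != 0 && Vr > 1) voxelize_surf();
    for (int v = 0; v < Vr; v++) {
      FS[v] = surf_ri(v, level_disp_srf(v,0), level_disp_srf(v,1), level_disp_srf(v,2));
      Corr& c = csrf[sidx(svstruct[v])];
      c.sx += FS[v]; c.sxx += FS[v]*FS[v]; c.sy += F_T[v];
      c.syy += F_T[v]*F_T[v]; c.sxy += FS[v]*F_T[v]; c.n++;
    }
    smooth_total = 0;
    for (int k = 0; k < lnz; k++)
      for (int j = 0; j < lny; j++)
        for (int i = 0; i < lnx; i++) smooth_total += lap_sq(i, j, k);
  };
  auto objective = [&]() {
    double o = corr_of(cvol) - lambda * smooth_total / L;
    if (w_surf != 0 && Vr > 1) o += w_surf * surf_score();
    return o;
  };

  refresh();
  double obj = objective();
  double obj_initial = obj;
  std::vector<double> trace;
  trace.push_back(obj);

  std::vector<double> Wc, FSc; // candidate scratch
  int accepted_since_refresh = 0;
  for (int sw = 0; sw < sweeps; sw++) {
    double obj_sweep_start = obj;
    for (int k = 0; k < lnz; k++)
      for (int j = 0; j < lny; j++)
        for (int i = 0; i < lnx; i++) {
          int id = lidx(i, j, k);
          const std::vector<int>& qs = node_vox[id];
          if (qs.empty()) continue;
          static const std::vector<int> empty_vec;
          const std::vector<int>& vss = (w_surf != 0) ? node_srf[id] : empty_vec;
          double cur[3] = {lat[3*(size_t)id], lat[3*(size_t)id+1], lat[3*(size_t)id+2]};
          Wc.resize(qs.size()); FSc.resize(vss.size());
          // cache per-point displacement excluding node id, and id's weight
          std::vector<double> vb(4 * qs.size()), sb(4 * vss.size());
          for (size_t t = 0; t < qs.size(); t++) {
            int q = qs[t];
            double d0 = 0, d1 = 0, d2 = 0, wn = 0;
            for (int u = 0; u < vox_lw[q].cnt; u++) {
              int nd = vox_lw[q].nodes[u];
              double wgt = vox_lw[q].w[u];
              if (nd == id) { wn += wgt; continue; }
              d0 += wgt * lat[3*(size_t)nd];
              d1 += wgt * lat[3*(size_t)nd+1];
              d2 += wgt * lat[3*(size_t)nd+2];
            }
            vb[4*t] = d0; vb[4*t+1] = d1; vb[4*t+2] = d2; vb[4*t+3] = wn;
          }
          for (size_t t = 0; t < vss.size(); t++) {
            int v = vss[t];
            double d0 = 0, d1 = 0, d2 = 0, wn = 0;
            for (int u = 0; u < srf_lw[v].cnt; u++) {
              int nd = srf_lw[v].nodes[u];
              double wgt = srf_lw[v].w[u];
              if (nd == id) { wn += wgt; continue; }
              d0 += wgt * lat[3*(size_t)nd];
              d1 += wgt * lat[3*(size_t)nd+1];
              d2 += wgt * lat[3*(size_t)nd+2];
            }
            sb[4*t] = d0; sb[4*t+1] = d1; sb[4*t+2] = d2; sb[4*t+3] = wn;
          }
          auto eval = [&](const double* p_in) {
            double p[3] = {p_in[0], p_in[1], p_in[2]};
            double nrm = std::sqrt(p[0]*p[0] + p[1]*p[1] + p[2]*p[2]);
            if (nrm > cap) { for (int c = 0; c < 3; c++) p[c] *= cap / nrm; }
            Corr cv = cvol;
            Corr cs[3] = {csrf[0], csrf[1], csrf[2]};
            for (size_t t = 0; t < qs.size(); t++) {
              int q = qs[t];
              double wn = vb[4*t+3];
              double wv = warp_value(q, vb[4*t] + wn * p[0],
                                     vb[4*t+1] + wn * p[1],
                                     vb[4*t+2] + wn * p[2]);
              Wc[t] = wv;
              cv.sx += wv - W[q];
              cv.sxx += wv*wv - W[q]*W[q];
              cv.sxy += (wv - W[q]) * tv[q];
            }
            for (size_t t = 0; t < vss.size(); t++) {
              int v = vss[t];
              double wn = sb[4*t+3];
              double fs = surf_ri(v, sb[4*t] + wn * p[0],
                                  sb[4*t+1] + wn * p[1],
                                  sb[4*t+2] + wn * p[2]);
              FSc[t] = fs;
              Corr& c = cs[sidx(svstruct[v])];
              c.sx += fs - FS[v];
              c.sxx += fs*fs - FS[v]*FS[v];
              c.sxy += (fs - FS[v]) * F_T[v];
            }
            // smoothness: recompute laplacians of node and neighbours
            double old_local = lap_sq(i, j, k);
            if (i > 0) old_local += lap_sq(i-1, j, k);
            if (i < lnx-1) old_local += lap_sq(i+1, j, k);
            if (j > 0) old_local += lap_sq(i, j-1, k);
            if (j < lny-1) old_local += lap_sq(i, j+1, k);
            if (k > 0) old_local += lap_sq(i, j, k-1);
            if (k < lnz-1) old_local += lap_sq(i, j, k+1);
            double save[3] = {lat[3*(size_t)id], lat[3*(size_t)id+1], lat[3*(size_t)id+2]};
            lat[3*(size_t)id] = p[0]; lat[3*(size_t)id+1] = p[1]; lat[3*(size_t)id+2] = p[2];
            double new_local = lap_sq(i, j, k);
            if (i > 0) new_local += lap_sq(i-1, j, k);
            if (i < lnx-1) new_local += lap_sq(i+1, j, k);
            if (j > 0) new_local += lap_sq(i, j-1, k);
            if (j < lny-1) new_local += lap_sq(i, j+1, k);
            if (k > 0) new_local += lap_sq(i, j, k-1);
            if (k < lnz-1) new_local += lap_sq(i, j, k+1);
            lat[3*(size_t)id] = save[0]; lat[3*(size_t)id+1] = save[1]; lat[3*(size_t)id+2] = save[2];
            double sm = smooth_total - old_local + new_local;
            double o = corr_of(cv) - lambda * sm / L;
            if (w_surf != 0 && Vr > 1) {
              Corr pooled;
              for (int s = 0; s < 3; s++) {
                pooled.sx += cs[s].sx; pooled.sxx += cs[s].sxx;
                pooled.sy += cs[s].sy; pooled.syy += cs[s].syy;
                pooled.sxy += cs[s].sxy; pooled.n += cs[s].n;
              }
              o += w_surf * corr_of(pooled);
            }
            return -o; // minimized
          };
          double fbest;
          std::vector<double> x0(cur, cur + 3);
          std::vector<double> best =
            nelder_mead(eval, x0, 0.25 * lat_spacing, nm_maxit, 1e-7, &fbest);
          if (-fbest > obj + 1e-12) {
            // commit: project onto cap, then re-evaluate to refresh caches
            double nrm = std::sqrt(best[0]*best[0] + best[1]*best[1] + best[2]*best[2]);
            if (nrm > cap) for (int c = 0; c < 3; c++) best[c] *= cap / nrm;
            eval(best.data()); // fills Wc, FSc for the committed point
            // update smoothness total
            double old_local = lap_sq(i, j, k);
            if (i > 0) old_local += lap_sq(i-1, j, k);
            if (i < lnx-1) old_local += lap_sq(i+1, j, k);
            if (j > 0) old_local += lap_sq(i, j-1, k);
            if (j < lny-1) old_local += lap_sq(i, j+1, k);
            if (k > 0) old_local += lap_sq(i, j, k-1);
            if (k < lnz-1) old_local += lap_sq(i, j, k+1);
            for (int c = 0; c < 3; c++) lat[3*(size_t)id + c] = best[c];
            double new_local = lap_sq(i, j, k);
            if (i > 0) new_local += lap_sq(i-1, j, k);
            if (i < lnx-1) new_local += lap_sq(i+1, j, k);
            if (j > 0) new_local += lap_sq(i, j-1, k);
            if (j < lny-1) new_local += lap_sq(i, j+1, k);
            if (k > 0) new_local += lap_sq(i, j, k-1);
            if (k < lnz-1) new_local += lap_sq(i, j, k+1);
            smooth_total += new_local - old_local;
            for (size_t t = 0; t < qs.size(); t++) {
              int q = qs[t];
              double wv = Wc[t];
              cvol.sx += wv - W[q]; cvol.sxx += wv*wv - W[q]*W[q];
              cvol.sxy += (wv - W[q]) * tv[q];
              W[q] = wv;
            }
            for (size_t t = 0; t < vss.size(); t++) {
              int v = vss[t];
              double fs = FSc[t];
              Corr& c = csrf[sidx(svstruct[v])];
              c.sx += fs - FS[v]; c.sxx += fs*fs - FS[v]*FS[v];
              c.sxy += (fs - FS[v]) * F_T[v];
              FS[v] = fs;
            }
            obj = objective();
            // periodic surface-feature refresh: bounds the staleness of the
            // frozen boundary indicator within a sweep
            if (w_surf != 0 && refresh_moves > 0 &&
                ++accepted_since_refresh >= refresh_moves) {
              refresh();
              obj = objective();
              accepted_since_refresh = 0;
            }
          }
        }
    refresh(); // per-sweep feature refresh + numerical hygiene
    obj = objective();
    trace.push_back(obj);
    if (obj - obj_sweep_start < tol) break;
  }

  NumericMatrix lat_out(L, 3);
  for (int i = 0; i < L; i++)
    for (int c = 0; c < 3; c++) lat_out(i, c) = lat[3*(size_t)i + c];
  return List::create(_["lattice"] = lat_out,
                      _["objective"] = obj,
                      _["objective_initial"] = obj_initial,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// --------------------------------------------------- local fusion weights

// One coarse-to-fine level sweep: per sampling vertex, Nelder-Mead on the
// n_b-simplex (squared-softmax reparameterization) of the locally restricted
// feature-match objective. Positions, the inside-bit indicator and features
// are maintained incrementally.
// [[Rcpp::export]]
List cpp_local_sweep(NumericVector test, NumericVector grad, IntegerVector dim,
                     NumericVector spacing, NumericVector origin,
                     NumericVector Xs,      // V x 3 x nb (mm)
                     NumericVector Ftrue,   // V x 9 x nb
                     NumericMatrix w0,      // m_total x nb
                     IntegerVector part,    // V, 0-based sampling-vertex id
                     IntegerVector vstruct, // V, 1..3
                     List faces_list, IntegerVector voffset,
                     List feat_offsets, NumericVector radii,
                     int nm_maxit, double fill) {
  IntegerVector xdim = Xs.attr("dim");
  int V = xdim[0], nb = xdim[2];
  int m_total = w0.nrow();
  int nstruct = faces_list.size();
  Grid dims{nullptr, dim[0], dim[1], dim[2]};

  // current positions: from each vertex's partition weight vector
  std::vector<double> P(3 * (size_t)V);
  auto xs_at = [&](int v, int c, int j) {
    return Xs[(size_t)v + (size_t)V * c + (size_t)V * 3 * j];
  };
  auto ft_at = [&](int v, int c, int j) {
    return Ftrue[(size_t)v + (size_t)V * c + (size_t)V * 9 * j];
  };
  NumericMatrix w = clone(w0);
  for (int v = 0; v < V; v++) {
    int s = part[v];
    for (int c = 0; c < 3; c++) {
      double acc = 0;
      for (int j = 0; j < nb; j++) acc += w(s, j) * xs_at(v, c, j);
      P[3*(size_t)v + c] = acc;
    }
  }

  // per-structure scan meshes over current P (voxel coords derived on the fly)
  std::vector<std::vector<int>> sf0(nstruct), sf1(nstruct), sf2(nstruct);
  std::vector<int> nvs(nstruct), off(nstruct);
  for (int s = 0; s < nstruct; s++) {
    IntegerMatrix fm = faces_list[s];
    int nf = fm.nrow();
    sf0[s].resize(nf); sf1[s].resize(nf); sf2[s].resize(nf);
    for (int f = 0; f < nf; f++) {
      sf0[s][f] = fm(f,0); sf1[s][f] = fm(f,1); sf2[s][f] = fm(f,2);
    }
    off[s] = voffset[s];
  }
  // per-structure vertex counts from offsets
  for (int s = 0; s < nstruct; s++)
    nvs[s] = (s + 1 < nstruct ? voffset[s+1] : V) - voffset[s];

  // voxel-coordinate accessors for structure s, local vertex index lv
  std::vector<std::vector<double>> VX(nstruct), VY(nstruct), VZ(nstruct);
  auto sync_struct_coords = [&](int s) {
    VX[s].resize(nvs[s]); VY[s].resize(nvs[s]); VZ[s].resize(nvs[s]);
    for (int lv = 0; lv < nvs[s]; lv++) {
      int v = off[s] + lv;
      VX[s][lv] = (P[3*(size_t)v]   - origin[0]) / spacing[0];
      VY[s][lv] = (P[3*(size_t)v+1] - origin[1]) / spacing[1];
      VZ[s][lv] = (P[3*(size_t)v+2] - origin[2]) / spacing[2];
    }
  };
  auto update_vert_coord = [&](int v) {
    int s = vstruct[v] - 1; int lv = v - off[s];
    VX[s][lv] = (P[3*(size_t)v]   - origin[0]) / spacing[0];
    VY[s][lv] = (P[3*(size_t)v+1] - origin[1]) / spacing[1];
    VZ[s][lv] = (P[3*(size_t)v+2] - origin[2]) / spacing[2];
  };
  for (int s = 0; s < nstruct; s++) sync_struct_coords(s);

  IntegerVector bits((R_xlen_t)dim[0] * dim[1] * dim[2]);

  // Per-line face buckets: for each (y,z) scanline, the faces whose (y,z)
  // bbox covers it. Updated incrementally as partition vertices move, so a
  // rescan only tests locally relevant faces.
  std::vector<std::vector<std::vector<int>>> line_faces(nstruct);
  auto face_line_range = [&](int s, int f, int& jlo, int& jhi, int& klo,
                             int& khi) {
    int a = sf0[s][f], b = sf1[s][f], c = sf2[s][f];
    double ylo = std::min({VY[s][a], VY[s][b], VY[s][c]});
    double yhi = std::max({VY[s][a], VY[s][b], VY[s][c]});
    double zlo = std::min({VZ[s][a], VZ[s][b], VZ[s][c]});
    double zhi = std::max({VZ[s][a], VZ[s][b], VZ[s][c]});
    jlo = std::max((int)std::floor(ylo), 0);
    jhi = std::min((int)std::ceil(yhi), dims.ny - 1);
    klo = std::max((int)std::floor(zlo), 0);
    khi = std::min((int)std::ceil(zhi), dims.nz - 1);
  };
  auto bucket_add = [&](int s, int f) {
    int jlo, jhi, klo, khi;
    face_line_range(s, f, jlo, jhi, klo, khi);
    for (int k = klo; k <= khi; k++)
      for (int j = jlo; j <= jhi; j++)
        line_faces[s][j + dims.ny * k].push_back(f);
  };
  auto bucket_remove = [&](int s, int f) {
    int jlo, jhi, klo, khi;
    face_line_range(s, f, jlo, jhi, klo, khi);
    for (int k = klo; k <= khi; k++)
      for (int j = jlo; j <= jhi; j++) {
        auto& b = line_faces[s][j + dims.ny * k];
        for (size_t t = 0; t < b.size(); t++)
          if (b[t] == f) { b[t] = b.back(); b.pop_back(); break; }
      }
  };
  for (int s = 0; s < nstruct; s++) {
    line_faces[s].assign((size_t)dims.ny * dims.nz, {});
    for (size_t f = 0; f < sf0[s].size(); f++) bucket_add(s, (int)f);
  }

  std::vector<double> xs_buf;
  auto rescan_line = [&](int s, int j, int k) {
    const auto& cand = line_faces[s][j + dims.ny * k];
    double y = j + EPSY, z = k + EPSZ;
    xs_buf.clear();
    for (int f : cand) {
      int a = sf0[s][f], b = sf1[s][f], c = sf2[s][f];
      double ay = VY[s][a] - y, az = VZ[s][a] - z;
      double by = VY[s][b] - y, bz = VZ[s][b] - z;
      double cy = VY[s][c] - y, cz = VZ[s][c] - z;
      double d = (by - ay) * (cz - az) - (cy - ay) * (bz - az);
      if (d == 0.0) continue;
      double w1 = (-ay * (cz - az) + az * (cy - ay)) / d;
      double w2 = (ay * (bz - az) - az * (by - ay)) / d;
      double w0 = 1.0 - w1 - w2;
      if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
      xs_buf.push_back(w0 * VX[s][a] + w1 * VX[s][b] + w2 * VX[s][c]);
    }
    std::sort(xs_buf.begin(), xs_buf.end());
    fill_line(bits.begin(), dims, j, k, 1 << s, xs_buf);
  };
  auto rescan = [&](int s, int jlo, int jhi, int klo, int khi) {
    jlo = std::max(jlo, 0); jhi = std::min(jhi, dims.ny - 1);
    klo = std::max(klo, 0); khi = std::min(khi, dims.nz - 1);
    for (int k = klo; k <= khi; k++)
      for (int j = jlo; j <= jhi; j++) rescan_line(s, j, k);
  };
  for (int s = 0; s < nstruct; s++) {
    double ylo = *std::min_element(VY[s].begin(), VY[s].end());
    double yhi = *std::max_element(VY[s].begin(), VY[s].end());
    double zlo = *std::min_element(VZ[s].begin(), VZ[s].end());
    double zhi = *std::max_element(VZ[s].begin(), VZ[s].end());
    rescan(s, (int)std::floor(ylo), (int)std::ceil(yhi),
              (int)std::floor(zlo), (int)std::ceil(zhi));
  }

  FeatCtx cx = make_ctx(test, grad, dim, spacing, bits, feat_offsets, radii, fill);
  cx.ibits = bits.begin();

  // partitions: sampling vertex -> member vertices; incident faces
  std::vector<std::vector<int>> members(m_total);
  for (int v = 0; v < V; v++) members[part[v]].push_back(v);
  // vertex -> incident faces (per structure local face ids)
  std::vector<std::vector<std::vector<int>>> vfaces(nstruct);
  for (int s = 0; s < nstruct; s++) {
    vfaces[s].assign(nvs[s], {});
    for (size_t f = 0; f < sf0[s].size(); f++) {
      vfaces[s][sf0[s][f]].push_back((int)f);
      vfaces[s][sf1[s][f]].push_back((int)f);
      vfaces[s][sf2[s][f]].push_back((int)f);
    }
  }

  double fbuf[9];
  int accepted = 0;
  double total_gain = 0;
  for (int sidx = 0; sidx < m_total; sidx++) {
    const std::vector<int>& mem = members[sidx];
    if (mem.empty()) continue;
    int s = vstruct[mem[0]] - 1;
    int bit = 1 << s;
    // incident face set (unique)
    std::vector<int> ifaces;
    for (int v : mem)
      for (int f : vfaces[s][v - off[s]]) ifaces.push_back(f);
    std::sort(ifaces.begin(), ifaces.end());
    ifaces.erase(std::unique(ifaces.begin(), ifaces.end()), ifaces.end());

    auto apply_w = [&](const double* wv) {
      int jlo = dims.ny, jhi = -1, klo = dims.nz, khi = -1;
      auto grow = [&](int f) {
        int a, b, c2, d;
        face_line_range(s, f, a, b, c2, d);
        jlo = std::min(jlo, a); jhi = std::max(jhi, b);
        klo = std::min(klo, c2); khi = std::max(khi, d);
      };
      for (int f : ifaces) { grow(f); bucket_remove(s, f); }
      for (int v : mem) {
        for (int c = 0; c < 3; c++) {
          double acc = 0;
          for (int j = 0; j < nb; j++) acc += wv[j] * xs_at(v, c, j);
          P[3*(size_t)v + c] = acc;
        }
        update_vert_coord(v);
      }
      for (int f : ifaces) { bucket_add(s, f); grow(f); }
      rescan(s, jlo, jhi, klo, khi);
    };

    auto local_obj = [&](const double* wv) {
      double o = 0;
      for (int v : mem) {
        double vx = (P[3*(size_t)v]   - origin[0]) / spacing[0];
        double vy = (P[3*(size_t)v+1] - origin[1]) / spacing[1];
        double vz = (P[3*(size_t)v+2] - origin[2]) / spacing[2];
        features_at(cx, vx, vy, vz, bit, fbuf);
        for (int c = 0; c < 9; c++) {
          double mu = 0;
          for (int j = 0; j < nb; j++) mu += wv[j] * ft_at(v, c, j);
          double var = 0;
          for (int j = 0; j < nb; j++) {
            double d = ft_at(v, c, j) - mu;
            var += wv[j] * d * d;
          }
          double sd = std::max(std::sqrt(std::max(var, 0.0)), SD_FLOOR);
          o -= std::fabs(mu - fbuf[c]) / sd;
        }
      }
      return o;
    };

    std::vector<double> wcur(nb), wtmp(nb);
    for (int j = 0; j < nb; j++) wcur[j] = w(sidx, j);
    double f0 = local_obj(wcur.data()); // state already at wcur
    auto eval_u = [&](const double* u) {
      double ss = 0;
      for (int j = 0; j < nb; j++) ss += u[j] * u[j];
      if (ss < 1e-12) { for (int j = 0; j < nb; j++) wtmp[j] = 1.0 / nb; }
      else for (int j = 0; j < nb; j++) wtmp[j] = u[j] * u[j] / ss;
      apply_w(wtmp.data());
      return -local_obj(wtmp.data());
    };
    std::vector<double> u0(nb);
    for (int j = 0; j < nb; j++) u0[j] = std::sqrt(std::max(wcur[j], 0.0));
    double fbest;
    std::vector<double> ub = nelder_mead(eval_u, u0, 0.1, nm_maxit, 1e-8, &fbest);
    if (-fbest > f0 + 1e-12) {
      double ss = 0;
      for (int j = 0; j < nb; j++) ss += ub[j] * ub[j];
      for (int j = 0; j < nb; j++)
        w(sidx, j) = ss < 1e-12 ? 1.0 / nb : ub[j] * ub[j] / ss;
      accepted++;
      total_gain += (-fbest) - f0;
      for (int j = 0; j < nb; j++) wcur[j] = w(sidx, j);
    }
    apply_w(wcur.data()); // restore/commit state for this partition
  }

  return List::create(_["weights"] = w, _["accepted"] = accepted,
                      _["gain"] = total_gain);
}
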