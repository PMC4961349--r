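#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a 6-tetrahedron cube
// decomposition. All cubes share the same decomposition (main diagonal
// v0-v6), so face diagonals agree between neighbouring cubes and closed
// level sets yield watertight meshes. Vertices are returned in 0-based
// fractional voxel coordinates; the caller applies the affine.

static inline std::uint64_t edge_key(std::uint64_t a, std::uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vol);
  auto lin = [&](int i, int j, int k) -> std::uint64_t {
    return (std::uint64_t)i + (std::uint64_t)nx *
           ((std::uint64_t)j + (std::uint64_t)ny * (std::uint64_t)k);
  };
  // cube corner offsets, bit order (dx, dy, dz)
  static const int off[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing the v0-v6 diagonal
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  std::unordered_map<std::uint64_t, int> edge_vert;
  std::vector<double> verts;   // x,y,z triples (voxel coords)
  std::vector<int> faces;      // 0-based vertex indices

  double cpos[8][3], cval[8];
  std::uint64_t cid[8];

  auto edge_point = [&](int a, int b) -> int {
    std::uint64_t key = edge_key(cid[a], cid[b]);
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double va = cval[a], vb = cval[b];
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    int id = (int)(verts.size() / 3);
    for (int d = 0; d < 3; ++d)
      verts.push_back(cpos[a][d] + t * (cpos[b][d] - cpos[a][d]));
    edge_vert.emplace(key, id);
    return id;
  };

  // emit triangle oriented so its normal points from inside (>= iso) toward
  // outside, using the tet's inside/outside centroids as reference
  auto emit = [&](int e0, int e1, int e2,
                  const double ci[3], const double co[3]) {
    const double *a = &verts[3 * e0], *b = &verts[3 * e1],
                 *c = &verts[3 * e2];
    double u[3], w[3], n[3], r[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = b[d] - a[d]; w[d] = c[d] - a[d]; r[d] = co[d] - ci[d];
    }
    n[0] = u[1]*w[2] - u[2]*w[1];
    n[1] = u[2]*w[0] - u[0]*w[2];
    n[2] = u[0]*w[1] - u[1]*w[0];
    double dp = n[0]*r[0] + n[1]*r[1] + n[2]*r[2];
    if (dp >= 0) { faces.push_back(e0); faces.push_back(e1);
                   faces.push_back(e2); }
    else         { faces.push_back(e0); faces.push_back(e2);
                   faces.push_back(e1); }
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          cid[c] = lin(ii, jj, kk);
          cval[c] = v[cid[c]];
          cpos[c][0] = ii; cpos[c][1] = jj; cpos[c][2] = kk;
          (cval[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int tc[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int inside[4], nin = 0, outside[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[tc[c]] > iso) inside[nin++] = tc[c];
            else outside[nout++] = tc[c];
          }
          if (nin == 0 || nin == 4) continue;
          double ci[3] = {0,0,0}, co[3] = {0,0,0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) ci[d] += cpos[inside[c]][d] / nin;
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) co[d] += cpos[outside[c]][d] / nout;
          if (nin == 1) {
            int e0 = edge_point(inside[0], outside[0]);
            int e1 = edge_point(inside[0], outside[1]);
            int e2 = edge_point(inside[0], outside[2]);
            emit(e0, e1, e2, ci, co);
          } else if (nin == 3) {
            int e0 = edge_point(outside[0], inside[0]);
            int e1 = edge_point(outside[0], inside[1]);
            int e2 = edge_point(outside[0], inside[2]);
            emit(e0, e1, e2, ci, co);
          } else { // 2 in, 2 out: quad split into two triangles
            int e00 = edge_point(inside[0], outside[0]);
            int e01 = edge_point(inside[0], outside[1]);
            int e11 = edge_point(inside[1], outside[1]);
            int e10 = edge_point(inside[1], outside[0]);
            emit(e00, e01, e11, ci, co);
            emit(e00, e11, e10, ci, co);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int p = 0; p < nv; ++p)
    for (int d = 0; d < 3; ++d) V(p, d) = verts[3 * p + d];
  for (int f = 0; f < nf; ++f)
    for (int d = 0; d < 3; ++d) F(f, d) = faces[3 * f + d] + 1; // 1-based
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Moller-Trumbore ray casting: for each ray, nearest intersection with any
// triangle at ray parameter t in (eps, max_t]. Returns t (NA if no hit).

// [[Rcpp::export(name = ".cast_rays")]]
NumericVector cast_rays(NumericMatrix origins, NumericMatrix dirs,
                        NumericMatrix V, IntegerMatrix F, double max_t) {
  const int nr = origins.nrow(), nf = F.nrow();
  const double eps = 1e-9;
  NumericVector out(nr, NA_REAL);
  std::vector<double> e1(3 * nf), e2(3 * nf), v0(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      v0[3*f+d] = V(a, d);
      e1[3*f+d] = V(b, d) - V(a, d);
      e2[3*f+d] = V(c, d) - V(a, d);
    }
  }
  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r,0), origins(r,1), origins(r,2)};
    double dvec[3] = {dirs(r,0), dirs(r,1), dirs(r,2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const double *E1 = &e1[3*f], *E2 = &e2[3*f], *P0 = &v0[3*f];
      double p[3] = {dvec[1]*E2[2] - dvec[2]*E2[1],
                     dvec[2]*E2[0] - dvec[0]*E2[2],
                     dvec[0]*E2[1] - dvec[1]*E2[0]};
      double det = E1[0]*p[0] + E1[1]*p[1] + E1[2]*p[2];
      if (det > -eps && det < eps) continue;
      double inv = 1.0 / det;
      double tv[3] = {o[0]-P0[0], o[1]-P0[1], o[2]-P0[2]};
      double u = (tv[0]*p[0] + tv[1]*p[1] + tv[2]*p[2]) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double q[3] = {tv[1]*E1[2] - tv[2]*E1[1],
                     tv[2]*E1[0] - tv[0]*E1[2],
                     tv[0]*E1[1] - tv[1]*E1[0]};
      double w = (dvec[0]*q[0] + dvec[1]*q[1] + dvec[2]*q[2]) * inv;
      if (w < 0.0 || u + w > 1.0) continue;
      double t = (E2[0]*q[0] + E2[1]*q[1] + E2[2]*q[2]) * inv;
      if (t > eps && t <= max_t && t < best) best = t;
    }
    if (R_finite(best)) out[r] = best;
  }
  return out;
}
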