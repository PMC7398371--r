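#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Low-level geometry kernels shared by the whole pipeline: ray casting
// against triangle soups (contact queries, inside tests), unsigned
// point-to-mesh distance (inscribed-sphere radius), and marching
// tetrahedra (implicit-surface phantom generation).  All coordinates mm.

static const double RAY_EPS = 1e-12;

// Moller-Trumbore; returns t >= 0 of the hit along dir, or -1.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b,
                             const double *c) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int i = 0; i < 3; ++i) {
    e1[i] = b[i] - a[i];
    e2[i] = c[i] - a[i];
  }
  pv[0] = d[1] * e2[2] - d[2] * e2[1];
  pv[1] = d[2] * e2[0] - d[0] * e2[2];
  pv[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < RAY_EPS) return -1.0;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) tv[i] = o[i] - a[i];
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < -1e-10 || u > 1.0 + 1e-10) return -1.0;
  qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
  qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
  qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-10 || u + v > 1.0 + 1e-10) return -1.0;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return t;
}

// First-hit distance along each ray; Inf when the ray escapes.
// [[Rcpp::export]]
NumericVector cpp_ray_first_hit(NumericMatrix origins, NumericMatrix dirs,
                                NumericMatrix V, IntegerMatrix F) {
  int nr = origins.nrow(), nf = F.nrow();
  NumericVector out(nr, R_PosInf);
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  std::vector<int> fi(nf * 3);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) fi[3 * f + j] = 3 * (F(f, j) - 1);
  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    double d[3] = {dirs(r, 0), dirs(r, 1), dirs(r, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double t = ray_tri(o, d, &vx[fi[3 * f]], &vx[fi[3 * f + 1]],
                         &vx[fi[3 * f + 2]]);
      if (t > 1e-9 && t < best) best = t;
    }
    out[r] = best;
  }
  return out;
}

// Number of forward crossings per ray (parity inside test).
// [[Rcpp::export]]
IntegerVector cpp_ray_hit_count(NumericMatrix origins, NumericVector dir,
                                NumericMatrix V, IntegerMatrix F) {
  int nr = origins.nrow(), nf = F.nrow();
  IntegerVector out(nr);
  double d[3] = {dir[0], dir[1], dir[2]};
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  std::vector<int> fi(nf * 3);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) fi[3 * f + j] = 3 * (F(f, j) - 1);
  for (int r = 0; r < nr; ++r) {
    double o[3] = {origins(r, 0), origins(r, 1), origins(r, 2)};
    int cnt = 0;
    for (int f = 0; f < nf; ++f) {
      double t = ray_tri(o, d, &vx[fi[3 * f]], &vx[fi[3 * f + 1]],
                         &vx[fi[3 * f + 2]]);
      if (t > 1e-9) ++cnt;
    }
    out[r] = cnt;
  }
  return out;
}

// Closest distance from a point to one triangle (Ericson, RTCD 5.1.5).
static inline double point_tri_dist2(const double *p, const double *a,
                                     const double *b, const double *c) {
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0)
    return ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3)
    return bp[0] * bp[0] + bp[1] * bp[1] + bp[2] * bp[2];
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double s2 = 0.0;
    for (int i = 0; i < 3; ++i) {
      double q = ap[i] - v * ab[i];
      s2 += q * q;
    }
    return s2;
  }
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6)
    return cp[0] * cp[0] + cp[1] * cp[1] + cp[2] * cp[2];
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double s2 = 0.0;
    for (int i = 0; i < 3; ++i) {
      double q = ap[i] - w * ac[i];
      s2 += q * q;
    }
    return s2;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double s2 = 0.0;
    for (int i = 0; i < 3; ++i) {
      double q = bp[i] - w * (c[i] - b[i]);
      s2 += q * q;
    }
    return s2;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double s2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    double q = ap[i] - v * ab[i] - w * ac[i];
    s2 += q * q;
  }
  return s2;
}

// Unsigned minimum distance from each point to the mesh surface.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int j = 0; j < 3; ++j) vx[3 * i + j] = V(i, j);
  std::vector<int> fi(nf * 3);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) fi[3 * f + j] = 3 * (F(f, j) - 1);
  for (int r = 0; r < np; ++r) {
    double p[3] = {P(r, 0), P(r, 1), P(r, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = point_tri_dist2(p, &vx[fi[3 * f]], &vx[fi[3 * f + 1]],
                                  &vx[fi[3 * f + 2]]);
      if (d2 < best) best = d2;
    }
    out[r] = std::sqrt(best);
  }
  return out;
}

// --- marching tetrahedra ---------------------------------------------------
// Kuhn 6-tet decomposition of each grid cube around the (+x,+y,+z) main
// diagonal; the decomposition is face-to-face compatible across cubes, so
// edge-keyed vertex sharing yields a watertight, consistently oriented
// surface of the region {field < iso}.  Triangles are oriented outward
// (normal toward increasing field).

struct MTState {
  std::map<std::pair<int, int>, int> edge_vertex;
  std::vector<double> vx;
  std::vector<int> tri;
};

static int edge_point(MTState &st, int ia, int ib, const double *pa,
                      const double *pb, double fa, double fb, double iso) {
  std::pair<int, int> key = ia < ib ? std::make_pair(ia, ib)
                                    : std::make_pair(ib, ia);
  std::map<std::pair<int, int>, int>::iterator it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)(st.vx.size() / 3);
  for (int i = 0; i < 3; ++i) st.vx.push_back(pa[i] + t * (pb[i] - pa[i]));
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState &st, int v1, int v2, int v3, const double *ref_in,
                     const double *ref_out) {
  // orient so the normal points from the inside centroid toward outside
  const double *p1 = &st.vx[3 * v1];
  const double *p2 = &st.vx[3 * v2];
  const double *p3 = &st.vx[3 * v3];
  double e1[3], e2[3], n[3], d[3];
  for (int i = 0; i < 3; ++i) {
    e1[i] = p2[i] - p1[i];
    e2[i] = p3[i] - p1[i];
    d[i] = ref_out[i] - ref_in[i];
  }
  n[0] = e1[1] * e2[2] - e1[2] * e2[1];
  n[1] = e1[2] * e2[0] - e1[0] * e2[2];
  n[2] = e1[0] * e2[1] - e1[1] * e2[0];
  if (n[0] * d[0] + n[1] * d[1] + n[2] * d[2] >= 0.0) {
    st.tri.push_back(v1);
    st.tri.push_back(v2);
    st.tri.push_back(v3);
  } else {
    st.tri.push_back(v1);
    st.tri.push_back(v3);
    st.tri.push_back(v2);
  }
}

static void do_tet(MTState &st, const int idx[4], const double pts[4][3],
                   const double f[4], double iso) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) {
    in[i] = f[i] < iso;
    if (in[i]) ++nin;
  }
  if (nin == 0 || nin == 4) return;
  int ins[4], outs[4];
  int a = 0, b = 0;
  for (int i = 0; i < 4; ++i) {
    if (in[i]) ins[a++] = i;
    else outs[b++] = i;
  }
  double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
  for (int i = 0; i < a; ++i)
    for (int j = 0; j < 3; ++j) cin[j] += pts[ins[i]][j] / a;
  for (int i = 0; i < b; ++i)
    for (int j = 0; j < 3; ++j) cout[j] += pts[outs[i]][j] / b;
  if (nin == 1) {
    int A = ins[0];
    int v1 = edge_point(st, idx[A], idx[outs[0]], pts[A], pts[outs[0]], f[A],
                        f[outs[0]], iso);
    int v2 = edge_point(st, idx[A], idx[outs[1]], pts[A], pts[outs[1]], f[A],
                        f[outs[1]], iso);
    int v3 = edge_point(st, idx[A], idx[outs[2]], pts[A], pts[outs[2]], f[A],
                        f[outs[2]], iso);
    emit_tri(st, v1, v2, v3, cin, cout);
  } else if (nin == 3) {
    int D = outs[0];
    int v1 = edge_point(st, idx[D], idx[ins[0]], pts[D], pts[ins[0]], f[D],
                        f[ins[0]], iso);
    int v2 = edge_point(st, idx[D], idx[ins[1]], pts[D], pts[ins[1]], f[D],
                        f[ins[1]], iso);
    int v3 = edge_point(st, idx[D], idx[ins[2]], pts[D], pts[ins[2]], f[D],
                        f[ins[2]], iso);
    emit_tri(st, v1, v2, v3, cin, cout);
  } else {
    int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
    int vac = edge_point(st, idx[A], idx[C], pts[A], pts[C], f[A], f[C], iso);
    int vad = edge_point(st, idx[A], idx[D], pts[A], pts[D], f[A], f[D], iso);
    int vbd = edge_point(st, idx[B], idx[D], pts[B], pts[D], f[B], f[D], iso);
    int vbc = edge_point(st, idx[B], idx[C], pts[B], pts[C], f[B], f[C], iso);
    emit_tri(st, vac, vad, vbd, cin, cout);
    emit_tri(st, vac, vbd, vbc, cin, cout);
  }
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, NumericVector xs,
                             NumericVector ys, NumericVector zs, double iso) {
  int nx = xs.size(), ny = ys.size(), nz = zs.size();
  if ((double)nx * ny * nz != (double)field.size())
    stop("field length does not match grid dimensions");
  MTState st;
  // cube corner offsets in (i,j,k)
  static const int co[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // Kuhn decomposition around diagonal corner0 - corner6
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        int gid[8];
        double pts[8][3], fv[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          gid[c] = ii + nx * (jj + ny * kk);
          pts[c][0] = xs[ii];
          pts[c][1] = ys[jj];
          pts[c][2] = zs[kk];
          fv[c] = field[gid[c]];
          if (fv[c] < iso) any_in = true;
          else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4];
          double tp[4][3], tf[4];
          for (int v = 0; v < 4; ++v) {
            int c = tets[t][v];
            idx[v] = gid[c];
            tf[v] = fv[c];
            for (int q = 0; q < 3; ++q) tp[v][q] = pts[c][q];
          }
          do_tet(st, idx, tp, tf, iso);
        }
      }
    }
  }
  int nv = (int)(st.vx.size() / 3), nf = (int)(st.tri.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) V(i, j) = st.vx[3 * i + j];
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = st.tri[3 * i + j] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Minimum distance from each query point to a set of 2D segments, with
// periodic wrap in y (unrolled-cylinder raster helper).
// [[Rcpp::export]]
NumericVector cpp_min_dist_segments_2d(NumericMatrix P, NumericMatrix S,
                                       double wrap_y) {
  // S columns: x1 y1 x2 y2
  int np = P.nrow(), ns = S.nrow();
  NumericVector out(np, R_PosInf);
  double shifts[3] = {-wrap_y, 0.0, wrap_y};
  for (int s = 0; s < ns; ++s) {
    double x1 = S(s, 0), y1 = S(s, 1), x2 = S(s, 2), y2 = S(s, 3);
    double dx = x2 - x1, dy = y2 - y1;
    double L2 = dx * dx + dy * dy;
    for (int p = 0; p < np; ++p) {
      double px = P(p, 0);
      for (int w = 0; w < 3; ++w) {
        double py = P(p, 1) + shifts[w];
        double t = L2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / L2 : 0.0;
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
        double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
        double d2 = qx * qx + qy * qy;
        if (d2 < out[p]) out[p] = d2;
      }
    }
  }
  for (int p = 0; p < np; ++p) out[p] = std::sqrt(out[p]);
  return out;
}
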