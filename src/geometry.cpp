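#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>
#include <algorithm>

using namespace Rcpp;

// Signed distance from query points to a closed simple polygon.
// Sign convention: positive inside (even-odd rule), negative outside,
// zero on the boundary. Polygon is implicitly closed (last->first edge).
// [[Rcpp::export]]
NumericVector cpp_polygon_sdf(NumericVector qx, NumericVector qy,
                              NumericVector vx, NumericVector vy) {
  const int nq = qx.size();
  const int nv = vx.size();
  if (nv < 3) stop("polygon needs at least 3 vertices");
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double x = qx[i], y = qy[i];
    double d2 = R_PosInf;
    bool inside = false;
    for (int j = 0, k = nv - 1; j < nv; k = j++) {
      const double ax = vx[k], ay = vy[k];
      const double bx = vx[j], by = vy[j];
      const double ex = bx - ax, ey = by - ay;
      const double wx = x - ax, wy = y - ay;
      const double L2 = ex * ex + ey * ey;
      double t = 0.0;
      if (L2 > 0.0) {
        t = (wx * ex + wy * ey) / L2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double dx = wx - t * ex, dy = wy - t * ey;
      const double dd = dx * dx + dy * dy;
      if (dd < d2) d2 = dd;
      if (((ay > y) != (by > y)) &&
          (x < ax + (bx - ax) * (y - ay) / (by - ay)))
        inside = !inside;
    }
    const double d = std::sqrt(d2);
    // boundary ties (d == 0) report 0 regardless of the parity test
    out[i] = inside ? d : -d;
  }
  return out;
}

namespace {

struct MeshAccum {
  std::unordered_map<uint64_t, int> edge_vertex; // grid-edge key -> vertex index
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  int edge_point(uint64_t a, uint64_t b,
                 double ax, double ay, double az, double fa,
                 double bx, double by, double bz, double fb) {
    uint64_t lo = a < b ? a : b, hi = a < b ? b : a;
    uint64_t key = (lo << 24) ^ hi; // node ids < 2^24 by construction
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    // interpolate deterministically from the lower node id
    double px, py, pz;
    if (a > b) { std::swap(ax, bx); std::swap(ay, by); std::swap(az, bz); std::swap(fa, fb); }
    const double t = fa / (fa - fb);
    px = ax + t * (bx - ax);
    py = ay + t * (by - ay);
    pz = az + t * (bz - az);
    int idx = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vertex.emplace(key, idx);
    return idx;
  }

  // emit triangle oriented so its normal points away from the inside
  // reference point (outward for a positive-inside field)
  void tri(int i0, int i1, int i2, double rx, double ry, double rz) {
    if (i0 == i1 || i1 == i2 || i0 == i2) return;
    const double ax = vx[i0], ay = vy[i0], az = vz[i0];
    const double ux = vx[i1] - ax, uy = vy[i1] - ay, uz = vz[i1] - az;
    const double wx = vx[i2] - ax, wy = vy[i2] - ay, wz = vz[i2] - az;
    const double nx = uy * wz - uz * wy;
    const double ny = uz * wx - ux * wz;
    const double nz = ux * wy - uy * wx;
    const double cx = (ax + vx[i1] + vx[i2]) / 3.0 - rx;
    const double cy = (ay + vy[i1] + vy[i2]) / 3.0 - ry;
    const double cz = (az + vz[i1] + vz[i2]) / 3.0 - rz;
    if (nx * cx + ny * cy + nz * cz < 0.0) std::swap(i1, i2);
    f0.push_back(i0); f1.push_back(i1); f2.push_back(i2);
  }
};

} // namespace

// Marching tetrahedra over a regular grid using the Kuhn 6-tetrahedron cube
// decomposition (translation-invariant, hence face-compatible between
// neighbouring cubes -> watertight surface). Values > 0 are inside; exact
// zeros are nudged outside (deterministic tie-break). Vertices are deduped
// exactly by grid-edge key so every surface edge has degree 2.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, IntegerVector dims,
                       NumericVector origin, double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((double)nx * ny * nz > 16000000.0) stop("grid too large");
  std::vector<double> F(values.begin(), values.end());
  for (auto &v : F) if (v == 0.0) v = -1e-12;

  // Kuhn tets: permutations of axis insertion order from corner (0,0,0)
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
  };

  MeshAccum M;
  const uint64_t NX = (uint64_t)nx, NXY = (uint64_t)nx * ny;
  auto nid = [&](int ix, int iy, int iz) -> uint64_t {
    return (uint64_t)ix + NX * iy + NXY * iz;
  };

  int corner[4][3];
  for (int iz = 0; iz + 1 < nz; ++iz)
    for (int iy = 0; iy + 1 < ny; ++iy)
      for (int ix = 0; ix + 1 < nx; ++ix) {
        // quick reject: all 8 corners same sign
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          double v = F[nid(ix + (c & 1), iy + ((c >> 1) & 1), iz + ((c >> 2) & 1))];
          (v > 0.0 ? anyin : anyout) = true;
        }
        if (!(anyin && anyout)) continue;
        for (int tp = 0; tp < 6; ++tp) {
          corner[0][0] = 0; corner[0][1] = 0; corner[0][2] = 0;
          for (int s = 1; s < 4; ++s) {
            corner[s][0] = corner[s-1][0];
            corner[s][1] = corner[s-1][1];
            corner[s][2] = corner[s-1][2];
            corner[s][perms[tp][s-1]] = 1;
          }
          uint64_t id[4]; double px[4], py[4], pz[4], fv[4]; bool in[4];
          int n_in = 0;
          for (int s = 0; s < 4; ++s) {
            const int cx = ix + corner[s][0], cy = iy + corner[s][1], cz = iz + corner[s][2];
            id[s] = nid(cx, cy, cz);
            px[s] = origin[0] + cx * spacing;
            py[s] = origin[1] + cy * spacing;
            pz[s] = origin[2] + cz * spacing;
            fv[s] = F[id[s]];
            in[s] = fv[s] > 0.0;
            if (in[s]) ++n_in;
          }
          if (n_in == 0 || n_in == 4) continue;
          int A[4], B[4]; int na = 0, nb = 0;
          for (int s = 0; s < 4; ++s) (in[s] ? A[na++] : B[nb++]) = s;
          auto ep = [&](int a, int b) {
            return M.edge_point(id[a], id[b], px[a], py[a], pz[a], fv[a],
                                px[b], py[b], pz[b], fv[b]);
          };
          if (n_in == 1) {
            const int a = A[0];
            M.tri(ep(a, B[0]), ep(a, B[1]), ep(a, B[2]), px[a], py[a], pz[a]);
          } else if (n_in == 3) {
            const int b = B[0];
            M.tri(ep(A[0], b), ep(A[1], b), ep(A[2], b), px[A[0]], py[A[0]], pz[A[0]]);
          } else { // 2 in, 2 out: quad split into two triangles
            const int a0 = A[0], a1 = A[1], b0 = B[0], b1 = B[1];
            const int q0 = ep(a0, b0), q1 = ep(a0, b1), q2 = ep(a1, b1), q3 = ep(a1, b0);
            M.tri(q0, q1, q2, px[a0], py[a0], pz[a0]);
            M.tri(q0, q2, q3, px[a0], py[a0], pz[a0]);
          }
        }
      }

  const int nvert = (int)M.vx.size();
  const int nf = (int)M.f0.size();
  NumericMatrix V(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    V(i, 0) = M.vx[i]; V(i, 1) = M.vy[i]; V(i, 2) = M.vz[i];
  }
  IntegerMatrix Fc(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fc(i, 0) = M.f0[i] + 1; Fc(i, 1) = M.f1[i] + 1; Fc(i, 2) = M.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}

// Connected components of a triangle mesh via union-find on shared vertices.
// Returns a component label per face (1-based, largest component = 1).
// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix faces, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const int nf = faces.nrow();
  for (int i = 0; i < nf; ++i) {
    int a = find(faces(i, 0) - 1), b = find(faces(i, 1) - 1), c = find(faces(i, 2) - 1);
    parent[b] = a; parent[find(c)] = find(a);
  }
  std::unordered_map<int, int> relabel;
  std::vector<int> count;
  IntegerVector lab(nf);
  for (int i = 0; i < nf; ++i) {
    int r = find(faces(i, 0) - 1);
    auto it = relabel.find(r);
    int l;
    if (it == relabel.end()) {
      l = (int)count.size();
      relabel.emplace(r, l);
      count.push_back(0);
    } else l = it->second;
    ++count[l];
    lab[i] = l;
  }
  // rank labels by face count, largest first
  std::vector<int> order(count.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(), [&](int a, int b) { return count[a] > count[b]; });
  std::vector<int> rank(count.size());
  for (size_t i = 0; i < order.size(); ++i) rank[order[i]] = (int)i + 1;
  for (int i = 0; i < nf; ++i) lab[i] = rank[lab[i]];
  return lab;
}

// Evaluate a triharmonic (r^3) RBF with linear polynomial tail at query
// points: F(p) = sum_i w_i |p - c_i|^3 + a0 + a1 x + a2 y + a3 z
// [[Rcpp::export]]
NumericVector cpp_rbf_eval(NumericMatrix pts, NumericMatrix centers,
                           NumericVector w, NumericVector poly) {
  const int n = pts.nrow(), m = centers.nrow();
  NumericVector out(n);
  std::vector<double> cx(m), cy(m), cz(m), wv(m);
  for (int j = 0; j < m; ++j) {
    cx[j] = centers(j, 0); cy[j] = centers(j, 1); cz[j] = centers(j, 2);
    wv[j] = w[j];
  }
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    double acc = poly[0] + poly[1] * x + poly[2] * y + poly[3] * z;
    for (int j = 0; j < m; ++j) {
      const double dx = x - cx[j], dy = y - cy[j], dz = z - cz[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      acc += wv[j] * r2 * std::sqrt(r2);
    }
    out[i] = acc;
  }
  return out;
}
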