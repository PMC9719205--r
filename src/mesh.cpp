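#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a rectilinear grid.
// Each cell is split into the 6 Kuhn tetrahedra sharing the 0-7 main
// diagonal; the decomposition is conforming across neighbouring cells, so
// a closed level set yields a watertight triangle mesh. Vertices lie at
// linearly interpolated iso crossings on tetrahedron edges and are welded
// through a (grid node, grid node) edge key.

// corner bit order: bit0 -> +x, bit1 -> +y, bit2 -> +z
static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct MeshAccum {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> vlab;
  std::vector<int> f0, f1, f2;
};

static inline int edgeVertex(MeshAccum &M, int64_t na, int64_t nb,
                             const double *val, const int *lab,
                             const double *px, const double *py,
                             const double *pz, double iso) {
  if (na > nb) std::swap(na, nb);
  uint64_t key = (uint64_t)na * 2000000011ULL + (uint64_t)nb;
  auto it = M.edge_vertex.find(key);
  if (it != M.edge_vertex.end()) return it->second;
  double va = val[na], vb = val[nb];
  double t = (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int id = (int)M.vx.size();
  M.vx.push_back(px[na] + t * (px[nb] - px[na]));
  M.vy.push_back(py[na] + t * (py[nb] - py[na]));
  M.vz.push_back(pz[na] + t * (pz[nb] - pz[na]));
  M.vlab.push_back(va >= iso ? lab[na] : lab[nb]);
  M.edge_vertex[key] = id;
  return id;
}

static inline void addTri(MeshAccum &M, int a, int b, int c,
                          double gx, double gy, double gz) {
  // orient so the normal points away from the inside-corner centroid g
  double ax = M.vx[a], ay = M.vy[a], az = M.vz[a];
  double ux = M.vx[b] - ax, uy = M.vy[b] - ay, uz = M.vz[b] - az;
  double wx = M.vx[c] - ax, wy = M.vy[c] - ay, wz = M.vz[c] - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double cx = (ax + M.vx[b] + M.vx[c]) / 3.0 - gx;
  double cy = (ay + M.vy[b] + M.vy[c]) / 3.0 - gy;
  double cz = (az + M.vz[b] + M.vz[c]) / 3.0 - gz;
  if (nx * cx + ny * cy + nz * cz < 0.0) std::swap(b, c);
  M.f0.push_back(a + 1);
  M.f1.push_back(b + 1);
  M.f2.push_back(c + 1);
}

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dims, NumericVector spacing,
                NumericVector origin, double iso, IntegerVector labels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *val = vol.begin();
  const int *lab = labels.begin();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // node coordinate lookup tables (per axis, combined on the fly)
  MeshAccum M;
  std::vector<double> px((size_t)nx * ny * nz), py(px.size()), pz(px.size());
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        px[idx] = ox + i * sx;
        py[idx] = oy + j * sy;
        pz[idx] = oz + k * sz;
      }

  int64_t corner[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          corner[c] = (int64_t)ci + (int64_t)nx * (cj + (int64_t)ny * ck);
        }
        // quick reject: all corners on one side
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          if (val[corner[c]] >= iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;

        for (int t = 0; t < 6; ++t) {
          int64_t n[4];
          bool in[4];
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            n[c] = corner[TET[t][c]];
            in[c] = val[n[c]] >= iso;
            if (in[c]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // centroid of inside corners for orientation
          double gx = 0, gy = 0, gz = 0;
          for (int c = 0; c < 4; ++c)
            if (in[c]) { gx += px[n[c]]; gy += py[n[c]]; gz += pz[n[c]]; }
          gx /= nin; gy /= nin; gz /= nin;

          if (nin == 1 || nin == 3) {
            // the lone vertex (inside if nin==1, outside if nin==3)
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (nin == 1)) lone = c;
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != lone)
                e[m++] = edgeVertex(M, n[lone], n[c], val, lab,
                                    px.data(), py.data(), pz.data(), iso);
            addTri(M, e[0], e[1], e[2], gx, gy, gz);
          } else { // nin == 2
            int a = -1, b = -1, c1 = -1, c2 = -1;
            for (int c = 0; c < 4; ++c) {
              if (in[c]) { if (a < 0) a = c; else b = c; }
              else { if (c1 < 0) c1 = c; else c2 = c; }
            }
            int eac1 = edgeVertex(M, n[a], n[c1], val, lab, px.data(), py.data(), pz.data(), iso);
            int eac2 = edgeVertex(M, n[a], n[c2], val, lab, px.data(), py.data(), pz.data(), iso);
            int ebc2 = edgeVertex(M, n[b], n[c2], val, lab, px.data(), py.data(), pz.data(), iso);
            int ebc1 = edgeVertex(M, n[b], n[c1], val, lab, px.data(), py.data(), pz.data(), iso);
            addTri(M, eac1, eac2, ebc2, gx, gy, gz);
            addTri(M, eac1, ebc2, ebc1, gx, gy, gz);
          }
        }
      }
    }
  }

  int nv = (int)M.vx.size(), nf = (int)M.f0.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = M.vx[v];
    verts(v, 1) = M.vy[v];
    verts(v, 2) = M.vz[v];
  }
  IntegerMatrix faces(nf, 3);
  for (int f = 0; f < nf; ++f) {
    faces(f, 0) = M.f0[f];
    faces(f, 1) = M.f1[f];
    faces(f, 2) = M.f2[f];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces,
                      _["vertexLabel"] = IntegerVector(M.vlab.begin(), M.vlab.end()));
}

// Brute-force nearest neighbour: for each query row, index of the closest
// reference row and the distance. Adequate for the subsampled point sets
// used in ICP (a few thousand points a side).
// [[Rcpp::export(name = ".nn_brute")]]
List nn_brute(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int r = 0; r < nr; ++r) {
    rx[r] = ref(r, 0); ry[r] = ref(r, 1); rz[r] = ref(r, 2);
  }
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int r = 0; r < nr; ++r) {
      const double dx = rx[r] - qx, dy = ry[r] - qy, dz = rz[r] - qz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = r; }
    }
    idx[q] = bi + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Uniform-grid exact nearest neighbour: same result as brute force but
// O(1) expected per query for surface-like reference clouds. Used by ICP
// so the full fixed vertex set can serve as the correspondence target.
// [[Rcpp::export(name = ".nn_grid")]]
List nn_grid(NumericMatrix query, NumericMatrix ref, double cell) {
  const int nq = query.nrow(), nr = ref.nrow();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int r = 0; r < nr; ++r)
    for (int a = 0; a < 3; ++a) {
      if (ref(r, a) < lo[a]) lo[a] = ref(r, a);
      if (ref(r, a) > hi[a]) hi[a] = ref(r, a);
    }
  int dim[3];
  for (int a = 0; a < 3; ++a) {
    dim[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cell) + 1);
  }
  const size_t ncell = (size_t)dim[0] * dim[1] * dim[2];
  std::vector<int> count(ncell + 1, 0);
  std::vector<int> cidx(nr);
  for (int r = 0; r < nr; ++r) {
    int c[3];
    for (int a = 0; a < 3; ++a) {
      c[a] = (int)((ref(r, a) - lo[a]) / cell);
      if (c[a] >= dim[a]) c[a] = dim[a] - 1;
      if (c[a] < 0) c[a] = 0;
    }
    cidx[r] = c[0] + dim[0] * (c[1] + dim[1] * c[2]);
    ++count[cidx[r] + 1];
  }
  for (size_t i = 1; i <= ncell; ++i) count[i] += count[i - 1];
  std::vector<int> bucket(nr);
  {
    std::vector<int> cur(count.begin(), count.end() - 1);
    for (int r = 0; r < nr; ++r) bucket[cur[cidx[r]]++] = r;
  }
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int qc[3];
    qc[0] = (int)std::floor((qx - lo[0]) / cell);
    qc[1] = (int)std::floor((qy - lo[1]) / cell);
    qc[2] = (int)std::floor((qz - lo[2]) / cell);
    double best = R_PosInf;
    int bi = -1;
    const int ringMax = dim[0] + dim[1] + dim[2] + 3;
    for (int ring = 0; ring < ringMax; ++ring) {
      // all closer points found once every cell within ring-1 is scanned
      if (bi >= 0) {
        double safe = (ring - 1) * cell;
        if (safe > 0 && best <= safe * safe) break;
      }
      bool any = false;
      for (int dzc = -ring; dzc <= ring; ++dzc) {
        int kz = qc[2] + dzc;
        if (kz < 0 || kz >= dim[2]) continue;
        for (int dyc = -ring; dyc <= ring; ++dyc) {
          int ky = qc[1] + dyc;
          if (ky < 0 || ky >= dim[1]) continue;
          for (int dxc = -ring; dxc <= ring; ++dxc) {
            // only the shell of the cube, inner cells already scanned
            if (std::max(std::abs(dxc), std::max(std::abs(dyc),
                                                 std::abs(dzc))) != ring)
              continue;
            int kx = qc[0] + dxc;
            if (kx < 0 || kx >= dim[0]) continue;
            any = true;
            size_t cc = (size_t)kx + dim[0] * ((size_t)ky + dim[1] * kz);
            for (int p = count[cc]; p < count[cc + 1]; ++p) {
              int r = bucket[p];
              const double ddx = ref(r, 0) - qx, ddy = ref(r, 1) - qy,
                ddz = ref(r, 2) - qz;
              const double d = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d < best) { best = d; bi = r; }
            }
          }
        }
      }
      if (!any && bi >= 0) break;
    }
    idx[q] = bi + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
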