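// Isosurface extraction by marching tetrahedra on the Kuhn (6-tetrahedra)
// subdivision of each grid cell.  The subdivision uses the same main
// diagonal in every cell, so face diagonals agree between neighbouring
// cells and the extracted surface is watertight wherever the level set
// stays inside the grid.  Each surface vertex lies on a tetrahedron edge
// whose endpoints are grid samples bracketing the iso value
// (value < iso on one side, >= iso on the other) and is placed by linear
// interpolation; shared edges are deduplicated so the mesh is indexed.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// corner bit layout: bit0 = +x, bit1 = +y, bit2 = +z
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

struct EdgeKeyHash {
  std::size_t operator()(const uint64_t &k) const {
    return std::hash<uint64_t>()(k);
  }
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector vol, double iso, NumericVector spacing,
                       NumericVector origin) {
  IntegerVector dim = vol.attr("dim");
  if (dim.size() != 3) stop("volume must be a 3D array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("volume needs >= 2 voxels per axis");
  const double *v = REAL(vol);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const uint64_t nnode = (uint64_t)nx * ny * nz;

  std::vector<double> verts;
  std::vector<int> tris;
  std::unordered_map<uint64_t, int, EdgeKeyHash> edge_vertex;
  edge_vertex.reserve(1 << 16);

  // returns 0-based vertex id for the crossing on grid-node pair (na, nb)
  // canonical endpoint order (smaller node id first) keeps interpolation
  // bit-identical between the tetrahedra sharing the edge
  double va_, vb_;
  auto edge_point = [&](uint64_t na, uint64_t nb) -> int {
    if (na > nb) std::swap(na, nb);
    uint64_t key = na * nnode + nb;
    std::unordered_map<uint64_t, int, EdgeKeyHash>::iterator it =
        edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    va_ = v[na];
    vb_ = v[nb];
    double t = (iso - va_) / (vb_ - va_);
    int ia = (int)(na % nx), ja = (int)((na / nx) % ny), ka = (int)(na / ((uint64_t)nx * ny));
    int ib = (int)(nb % nx), jb = (int)((nb / nx) % ny), kb = (int)(nb / ((uint64_t)nx * ny));
    double px = ox + sx * (ia + t * (ib - ia));
    double py = oy + sy * (ja + t * (jb - ja));
    double pz = oz + sz * (ka + t * (kb - ka));
    int id = (int)(verts.size() / 3);
    verts.push_back(px);
    verts.push_back(py);
    verts.push_back(pz);
    edge_vertex[key] = id;
    return id;
  };

  uint64_t node[8];
  double val[8];
  bool inside[8];

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          node[c] = (uint64_t)ii + (uint64_t)nx * (jj + (uint64_t)ny * kk);
          val[c] = v[node[c]];
          inside[c] = val[c] < iso;
        }
        // skip cells with no crossing
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) (inside[c] ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int *tc = TETS[t];
          int nin = 0, nout = 0;
          int cin[4], cout[4];
          for (int c = 0; c < 4; ++c) {
            if (inside[tc[c]]) cin[nin++] = tc[c];
            else cout[nout++] = tc[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? cin[0] : cout[0];
            const int *others = (nin == 1) ? cout : cin;
            int e0 = edge_point(node[apex], node[others[0]]);
            int e1 = edge_point(node[apex], node[others[1]]);
            int e2 = edge_point(node[apex], node[others[2]]);
            tris.push_back(e0);
            tris.push_back(e1);
            tris.push_back(e2);
          } else {
            // two in, two out: quad cycle e(i0,o0), e(i0,o1), e(i1,o1), e(i1,o0)
            int q0 = edge_point(node[cin[0]], node[cout[0]]);
            int q1 = edge_point(node[cin[0]], node[cout[1]]);
            int q2 = edge_point(node[cin[1]], node[cout[1]]);
            int q3 = edge_point(node[cin[1]], node[cout[0]]);
            tris.push_back(q0);
            tris.push_back(q1);
            tris.push_back(q2);
            tris.push_back(q0);
            tris.push_back(q2);
            tris.push_back(q3);
          }
        }
      }
    }
  }

  int nvert = (int)(verts.size() / 3);
  int ntri = (int)(tris.size() / 3);
  NumericMatrix V(nvert, 3);
  for (int p = 0; p < nvert; ++p) {
    V(p, 0) = verts[3 * p];
    V(p, 1) = verts[3 * p + 1];
    V(p, 2) = verts[3 * p + 2];
  }
  IntegerMatrix F(ntri, 3);
  for (int p = 0; p < ntri; ++p) {
    F(p, 0) = tris[3 * p] + 1;
    F(p, 1) = tris[3 * p + 1] + 1;
    F(p, 2) = tris[3 * p + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
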