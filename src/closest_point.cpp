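// Exact closest-point-on-mesh queries.
//
// Distances are point-to-triangle (interior / edge / vertex), accelerated by
// an axis-aligned bounding-box hierarchy with exact leaf tests and
// best-first pruning, so results are identical to an exhaustive scan over
// all triangles.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest point on triangle (a,b,c) to p; Voronoi-region case analysis.
static void closest_pt_tri(const double p[3], const double a[3],
                           const double b[3], const double c[3],
                           double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
    return;
  }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    for (int i = 0; i < 3; ++i) out[i] = b[i];
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    for (int i = 0; i < 3; ++i) out[i] = c[i];
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double dist2(const double a[3], const double b[3]) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    double d = a[i] - b[i];
    s += d * d;
  }
  return s;
}

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;   // children, -1 for leaf
  int start, count;  // triangle range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;          // triangle indices, leaf-contiguous
  const double *V;                 // 3 x nv column-major? stored row access below
  const int *Ftri;                 // 3 * nt (0-based vertex ids)
  int nv, nt;
  std::vector<double> cent;        // 3 * nt centroids

  void tri_vertex(int t, int k, double out[3]) const {
    int vi = Ftri[3 * t + k];
    out[0] = V[vi];
    out[1] = V[vi + nv];
    out[2] = V[vi + 2 * nv];
  }

  int build(int start, int count) {
    BVHNode nd;
    for (int i = 0; i < 3; ++i) {
      nd.bmin[i] = R_PosInf;
      nd.bmax[i] = R_NegInf;
    }
    for (int j = start; j < start + count; ++j) {
      int t = order[j];
      double v[3];
      for (int k = 0; k < 3; ++k) {
        tri_vertex(t, k, v);
        for (int i = 0; i < 3; ++i) {
          if (v[i] < nd.bmin[i]) nd.bmin[i] = v[i];
          if (v[i] > nd.bmax[i]) nd.bmax[i] = v[i];
        }
      }
    }
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) {
      nodes[idx].left = nodes[idx].right = -1;
      nodes[idx].start = start;
      nodes[idx].count = count;
      return idx;
    }
    // split on the longest centroid axis at the median
    double cmin[3] = {R_PosInf, R_PosInf, R_PosInf};
    double cmax[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = start; j < start + count; ++j) {
      int t = order[j];
      for (int i = 0; i < 3; ++i) {
        double c = cent[3 * t + i];
        if (c < cmin[i]) cmin[i] = c;
        if (c > cmax[i]) cmax[i] = c;
      }
    }
    int axis = 0;
    double ext = cmax[0] - cmin[0];
    for (int i = 1; i < 3; ++i)
      if (cmax[i] - cmin[i] > ext) {
        ext = cmax[i] - cmin[i];
        axis = i;
      }
    int mid = start + count / 2;
    if (ext <= 0.0) {
      // all centroids coincide: arbitrary halves
    } else {
      const std::vector<double> &ce = cent;
      std::nth_element(order.begin() + start, order.begin() + mid,
                       order.begin() + start + count,
                       [axis, &ce](int a, int b) {
                         return ce[3 * a + axis] < ce[3 * b + axis];
                       });
    }
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[idx].left = l;
    nodes[idx].right = r;
    nodes[idx].start = start;
    nodes[idx].count = count;
    return idx;
  }

  void init(const double *V_, const int *F_, int nv_, int nt_) {
    V = V_;
    Ftri = F_;
    nv = nv_;
    nt = nt_;
    cent.resize(3 * (size_t)nt);
    order.resize(nt);
    for (int t = 0; t < nt; ++t) {
      order[t] = t;
      double v[3], c[3] = {0, 0, 0};
      for (int k = 0; k < 3; ++k) {
        tri_vertex(t, k, v);
        for (int i = 0; i < 3; ++i) c[i] += v[i];
      }
      for (int i = 0; i < 3; ++i) cent[3 * t + i] = c[i] / 3.0;
    }
    nodes.reserve(2 * (size_t)nt);
    build(0, nt);
  }

  static double box_dist2(const BVHNode &nd, const double p[3]) {
    double s = 0.0;
    for (int i = 0; i < 3; ++i) {
      double d = 0.0;
      if (p[i] < nd.bmin[i]) d = nd.bmin[i] - p[i];
      else if (p[i] > nd.bmax[i]) d = p[i] - nd.bmax[i];
      s += d * d;
    }
    return s;
  }

  // nearest triangle to p; returns best squared distance, fills cp and tri
  double query(const double p[3], double cp[3], int &tri) const {
    double best = R_PosInf;
    tri = -1;
    std::vector<std::pair<double, int> > stack;
    stack.reserve(64);
    stack.push_back(std::make_pair(box_dist2(nodes[0], p), 0));
    double a[3], b[3], c[3], q[3];
    while (!stack.empty()) {
      std::pair<double, int> top = stack.back();
      stack.pop_back();
      if (top.first >= best) continue;
      const BVHNode &nd = nodes[top.second];
      if (nd.left < 0) {
        for (int j = nd.start; j < nd.start + nd.count; ++j) {
          int t = order[j];
          tri_vertex(t, 0, a);
          tri_vertex(t, 1, b);
          tri_vertex(t, 2, c);
          closest_pt_tri(p, a, b, c, q);
          double d2q = dist2(p, q);
          if (d2q < best) {
            best = d2q;
            tri = t;
            cp[0] = q[0];
            cp[1] = q[1];
            cp[2] = q[2];
          }
        }
      } else {
        double dl = box_dist2(nodes[nd.left], p);
        double dr = box_dist2(nodes[nd.right], p);
        // push farther first so the nearer child is processed next
        if (dl < dr) {
          if (dr < best) stack.push_back(std::make_pair(dr, nd.right));
          if (dl < best) stack.push_back(std::make_pair(dl, nd.left));
        } else {
          if (dl < best) stack.push_back(std::make_pair(dl, nd.left));
          if (dr < best) stack.push_back(std::make_pair(dr, nd.right));
        }
      }
    }
    return best;
  }
};

// Owns copies of the mesh arrays so an index can outlive the R matrices
// it was built from.
struct MeshBVH {
  std::vector<double> V;  // column-major, nv x 3
  std::vector<int> Ftri;  // 3 * nt, 0-based
  int nv, nt;
  BVH bvh;
};

static MeshBVH *make_mesh_bvh(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nt = F.nrow();
  if (nt < 1) stop("reference mesh has no faces");
  MeshBVH *m = new MeshBVH();
  m->nv = nv;
  m->nt = nt;
  m->V.assign(REAL(V), REAL(V) + 3 * (size_t)nv);
  m->Ftri.resize(3 * (size_t)nt);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) {
      int vi = F(t, k) - 1;
      if (vi < 0 || vi >= nv) {
        delete m;
        stop("face index out of range");
      }
      m->Ftri[3 * t + k] = vi;
    }
  m->bvh.init(m->V.data(), m->Ftri.data(), nv, nt);
  return m;
}

static List query_mesh_bvh(const MeshBVH *m, NumericMatrix query) {
  int nq = query.nrow();
  NumericVector dist(nq);
  NumericMatrix cp(nq, 3);
  IntegerVector tri(nq);
  double p[3], q[3];
  for (int i = 0; i < nq; ++i) {
    p[0] = query(i, 0);
    p[1] = query(i, 1);
    p[2] = query(i, 2);
    int t;
    double d2b = m->bvh.query(p, q, t);
    dist[i] = std::sqrt(d2b);
    tri[i] = t + 1;
    cp(i, 0) = q[0];
    cp(i, 1) = q[1];
    cp(i, 2) = q[2];
  }
  return List::create(_["distance"] = dist, _["point"] = cp,
                      _["triangle"] = tri);
}

// [[Rcpp::export(name = ".cpp_bvh_build")]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshBVH> xp(make_mesh_bvh(V, F), true);
  return xp;
}

// [[Rcpp::export(name = ".cpp_bvh_query")]]
List cpp_bvh_query(SEXP xp_, NumericMatrix query) {
  XPtr<MeshBVH> xp(xp_);
  if (!xp) stop("stale mesh index");
  return query_mesh_bvh(xp.get(), query);
}

// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix query, NumericMatrix V,
                        IntegerMatrix F, bool brute = false) {
  int nq = query.nrow(), nv = V.nrow(), nt = F.nrow();
  if (nt < 1) stop("reference mesh has no faces");
  std::vector<int> Ftri(3 * (size_t)nt);
  for (int t = 0; t < nt; ++t)
    for (int k = 0; k < 3; ++k) {
      int vi = F(t, k) - 1;
      if (vi < 0 || vi >= nv) stop("face index out of range");
      Ftri[3 * t + k] = vi;
    }
  NumericVector dist(nq);
  NumericMatrix cp(nq, 3);
  IntegerVector tri(nq);

  if (brute) {
    double p[3], a[3], b[3], c[3], q[3];
    for (int i = 0; i < nq; ++i) {
      p[0] = query(i, 0);
      p[1] = query(i, 1);
      p[2] = query(i, 2);
      double best = R_PosInf;
      int bt = -1;
      double bq[3] = {0, 0, 0};
      for (int t = 0; t < nt; ++t) {
        for (int k = 0; k < 3; ++k) {
          int vi = Ftri[3 * t + k];
          double *dst = (k == 0) ? a : (k == 1 ? b : c);
          dst[0] = V(vi, 0);
          dst[1] = V(vi, 1);
          dst[2] = V(vi, 2);
        }
        closest_pt_tri(p, a, b, c, q);
        double d2q = dist2(p, q);
        if (d2q < best) {
          best = d2q;
          bt = t;
          bq[0] = q[0];
          bq[1] = q[1];
          bq[2] = q[2];
        }
      }
      dist[i] = std::sqrt(best);
      tri[i] = bt + 1;
      cp(i, 0) = bq[0];
      cp(i, 1) = bq[1];
      cp(i, 2) = bq[2];
    }
  } else {
    BVH bvh;
    bvh.init(REAL(V), Ftri.data(), nv, nt);
    double p[3], q[3];
    for (int i = 0; i < nq; ++i) {
      p[0] = query(i, 0);
      p[1] = query(i, 1);
      p[2] = query(i, 2);
      int t;
      double d2b = bvh.query(p, q, t);
      dist[i] = std::sqrt(d2b);
      tri[i] = t + 1;
      cp(i, 0) = q[0];
      cp(i, 1) = q[1];
      cp(i, 2) = q[2];
    }
  }
  return List::create(_["distance"] = dist, _["point"] = cp,
                      _["triangle"] = tri);
}
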