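#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

// Exact 3-d kd-tree (median split on widest axis, bucketed leaves, per-node
// bounding boxes for pruning). Used for all nearest-neighbour queries:
// distance fields between clouds, and per-voxel-centre distance fields for
// the confusion-matrix sweep. Exactness matters: evaluation metrics must be
// reproducible bit-for-bit.

namespace {

struct Node {
  int lo, hi;        // point range [lo, hi) in perm
  int axis;          // split axis, -1 for leaf
  int left, right;
  double bb_min[3], bb_max[3];
};

class KDTree3 {
public:
  std::vector<double> pts;   // row-major x,y,z
  std::vector<int> perm;
  std::vector<Node> nodes;
  static const int LEAF = 16;

  explicit KDTree3(const Rcpp::NumericMatrix& m) {
    const int n = m.nrow();
    pts.resize(3 * (size_t)n);
    perm.resize(n);
    for (int i = 0; i < n; ++i) {
      pts[3 * (size_t)i]     = m(i, 0);
      pts[3 * (size_t)i + 1] = m(i, 1);
      pts[3 * (size_t)i + 2] = m(i, 2);
      perm[i] = i;
    }
    if (n > 0) {
      nodes.reserve(2 * (size_t)n / LEAF + 8);
      build(0, n);
    }
  }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1; nd.axis = -1;
    for (int a = 0; a < 3; ++a) {
      nd.bb_min[a] = std::numeric_limits<double>::infinity();
      nd.bb_max[a] = -nd.bb_min[a];
    }
    for (int k = lo; k < hi; ++k) {
      const double* p = &pts[3 * (size_t)perm[k]];
      for (int a = 0; a < 3; ++a) {
        if (p[a] < nd.bb_min[a]) nd.bb_min[a] = p[a];
        if (p[a] > nd.bb_max[a]) nd.bb_max[a] = p[a];
      }
    }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= LEAF) return id;
    int ax = 0;
    double ext = nd.bb_max[0] - nd.bb_min[0];
    for (int a = 1; a < 3; ++a)
      if (nd.bb_max[a] - nd.bb_min[a] > ext) { ext = nd.bb_max[a] - nd.bb_min[a]; ax = a; }
    if (!(ext > 0.0)) return id;  // all points coincide: keep as leaf
    int mid = lo + (hi - lo) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) {
                       return pts[3 * (size_t)a + ax] < pts[3 * (size_t)b + ax];
                     });
    nodes[id].axis = ax;
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  static double bbox_dist2(const Node& nd, const double q[3]) {
    double d2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = 0.0;
      if (q[a] < nd.bb_min[a]) d = nd.bb_min[a] - q[a];
      else if (q[a] > nd.bb_max[a]) d = q[a] - nd.bb_max[a];
      d2 += d * d;
    }
    return d2;
  }

  void query(const double q[3], int node, double& best2, int& bi) const {
    const Node& nd = nodes[node];
    if (bbox_dist2(nd, q) >= best2) return;
    if (nd.axis < 0) {
      for (int k = nd.lo; k < nd.hi; ++k) {
        const int i = perm[k];
        const double* p = &pts[3 * (size_t)i];
        const double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best2) { best2 = d2; bi = i; }
      }
      return;
    }
    const int l = nd.left, r = nd.right;
    const double dl = bbox_dist2(nodes[l], q);
    const double dr = bbox_dist2(nodes[r], q);
    if (dl <= dr) {
      query(q, l, best2, bi);
      if (dr < best2) query(q, r, best2, bi);
    } else {
      query(q, r, best2, bi);
      if (dl < best2) query(q, l, best2, bi);
    }
  }

  // Nearest neighbour, optionally warm-started with a candidate index whose
  // distance bounds the search (exactness is unaffected: the true nearest
  // neighbour is never farther than any candidate).
  void nn(const double q[3], double& dist, int& idx, int seed_idx = -1) const {
    double best2 = std::numeric_limits<double>::infinity();
    int bi = -1;
    if (seed_idx >= 0) {
      const double* p = &pts[3 * (size_t)seed_idx];
      const double dx = q[0] - p[0], dy = q[1] - p[1], dz = q[2] - p[2];
      best2 = dx * dx + dy * dy + dz * dz;
      bi = seed_idx;
    }
    query(q, 0, best2, bi);
    dist = std::sqrt(best2);
    idx = bi;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_nn(Rcpp::NumericMatrix query, Rcpp::NumericMatrix target) {
  const int n = query.nrow();
  Rcpp::NumericVector dist(n);
  Rcpp::IntegerVector idx(n);
  if (target.nrow() == 0) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(idx.begin(), idx.end(), NA_INTEGER);
    return Rcpp::List::create(Rcpp::Named("dist") = dist, Rcpp::Named("idx") = idx);
  }
  KDTree3 tree(target);
  for (int i = 0; i < n; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    double d; int j;
    tree.nn(q, d, j);
    dist[i] = d;
    idx[i] = j + 1;  // 1-based for R
  }
  return Rcpp::List::create(Rcpp::Named("dist") = dist, Rcpp::Named("idx") = idx);
}

// Nearest-neighbour distance from every voxel centre of a regular grid to a
// point set. Grid: dims[0] x dims[1] x dims[2] voxels of edge `voxel`, lowest
// corner at `origin`; centre of voxel (ix,iy,iz) (0-based) is
// origin + (i + 0.5) * voxel. Linear index runs x fastest (R array order).
// Each query is warm-started with the previous voxel's neighbour: adjacent
// centres are one edge apart, so that candidate tightly bounds the search
// without affecting exactness.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_voxel_nn(Rcpp::NumericMatrix target,
                                 Rcpp::NumericVector origin,
                                 double voxel,
                                 Rcpp::IntegerVector dims) {
  const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t total = nx * ny * nz;
  Rcpp::NumericVector out(total);
  if (target.nrow() == 0) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  KDTree3 tree(target);
  std::vector<int> above((size_t)nx, -1);  // neighbour indices from the row below
  R_xlen_t k = 0;
  int prev = -1;
  for (R_xlen_t iz = 0; iz < nz; ++iz) {
    const double z = origin[2] + (iz + 0.5) * voxel;
    for (R_xlen_t iy = 0; iy < ny; ++iy) {
      const double y = origin[1] + (iy + 0.5) * voxel;
      for (R_xlen_t ix = 0; ix < nx; ++ix, ++k) {
        double q[3] = { origin[0] + (ix + 0.5) * voxel, y, z };
        // warm start with the better of the previous voxel's neighbour and
        // the one from the adjacent row (both are valid upper bounds)
        int seed = prev;
        const int ab = above[(size_t)ix];
        if (ab >= 0) {
          if (seed < 0) {
            seed = ab;
          } else {
            const double* pa = &tree.pts[3 * (size_t)ab];
            const double* ps = &tree.pts[3 * (size_t)seed];
            const double da = (q[0]-pa[0])*(q[0]-pa[0]) + (q[1]-pa[1])*(q[1]-pa[1]) +
                              (q[2]-pa[2])*(q[2]-pa[2]);
            const double ds = (q[0]-ps[0])*(q[0]-ps[0]) + (q[1]-ps[1])*(q[1]-ps[1]) +
                              (q[2]-ps[2])*(q[2]-ps[2]);
            if (da < ds) seed = ab;
          }
        }
        double d; int j;
        tree.nn(q, d, j, seed);
        out[k] = d;
        prev = j;
        above[(size_t)ix] = j;
      }
    }
  }
  return out;
}

// For every voxel centre, whether any target point lies within `radius`.
// Same grid conventions as cpp_voxel_nn. Equivalent to cpp_voxel_nn(...) <=
// radius but far cheaper: the search is bounded at `radius` from the start,
// so empty space prunes at the root.
// [[Rcpp::export]]
Rcpp::LogicalVector cpp_voxel_within(Rcpp::NumericMatrix target,
                                     Rcpp::NumericVector origin,
                                     double voxel,
                                     Rcpp::IntegerVector dims,
                                     double radius) {
  const R_xlen_t nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t total = nx * ny * nz;
  Rcpp::LogicalVector out(total);
  if (target.nrow() == 0) {
    std::fill(out.begin(), out.end(), FALSE);
    return out;
  }
  KDTree3 tree(target);
  const double r2 = radius * radius;
  // nextafter: keep points at exactly `radius` inside the <= comparison
  const double bound2 = std::nextafter(r2, std::numeric_limits<double>::infinity());
  R_xlen_t k = 0;
  for (R_xlen_t iz = 0; iz < nz; ++iz) {
    const double z = origin[2] + (iz + 0.5) * voxel;
    for (R_xlen_t iy = 0; iy < ny; ++iy) {
      const double y = origin[1] + (iy + 0.5) * voxel;
      for (R_xlen_t ix = 0; ix < nx; ++ix, ++k) {
        double q[3] = { origin[0] + (ix + 0.5) * voxel, y, z };
        double best2 = bound2;
        int bi = -1;
        tree.query(q, 0, best2, bi);
        out[k] = (bi >= 0 && best2 <= r2);
      }
    }
  }
  return out;
}
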