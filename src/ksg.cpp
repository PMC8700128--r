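// k-nearest-neighbour machinery for the Kraskov-Stogbauer-Grassberger (KSG)
// estimators of mutual information and conditional mutual information.
// All distances are in the maximum (Chebyshev) norm, as in KSG type 1.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Static kd-tree over points stored column-major (R matrix layout).
// Splits on the dimension of largest extent; leaves hold <= 16 points.
class KDTree {
public:
  KDTree(const double* pts, int n, int d) : pts_(pts), n_(n), d_(d) {
    idx_.resize(n);
    for (int i = 0; i < n; ++i) idx_[i] = i;
    nodes_.reserve(2 * n / LEAF + 4);
    if (n > 0) build(0, n);
  }

  // k nearest neighbours of point q (self included if present in the tree);
  // returns the distances in ascending order in out (length k).
  void knn(const double* q, int k, std::vector<double>& heap) const {
    heap.clear();
    knn_rec(0, q, k, heap);
    std::sort_heap(heap.begin(), heap.end());
  }

  // number of points with max-norm distance to q strictly below eps
  int count_within(const double* q, double eps) const {
    if (nodes_.empty()) return 0;
    return count_rec(0, q, eps);
  }

  // indices (ascending by distance) of the k nearest neighbours of the
  // in-tree point `self`, excluding self
  void knn_idx(int self, int k, std::vector<int>& out) const {
    std::vector<std::pair<double, int> > heap;
    std::vector<double> q(d_);
    for (int j = 0; j < d_; ++j) q[j] = coord(self, j);
    knn_idx_rec(0, q.data(), self, k, heap);
    std::sort_heap(heap.begin(), heap.end());
    out.clear();
    for (size_t i = 0; i < heap.size(); ++i) out.push_back(heap[i].second);
  }

private:
  static const int LEAF = 16;
  struct Node {
    int lo, hi;        // range in idx_
    int left, right;   // children (-1 for leaf)
    std::vector<double> bmin, bmax;
  };
  const double* pts_;
  int n_, d_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;

  double coord(int i, int j) const { return pts_[i + (size_t)n_ * j]; }

  int build(int lo, int hi) {
    int id = (int)nodes_.size();
    nodes_.push_back(Node());
    Node& nd = nodes_[id];
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1;
    nd.bmin.assign(d_, R_PosInf);
    nd.bmax.assign(d_, R_NegInf);
    for (int t = lo; t < hi; ++t) {
      int i = idx_[t];
      for (int j = 0; j < d_; ++j) {
        double v = coord(i, j);
        if (v < nd.bmin[j]) nd.bmin[j] = v;
        if (v > nd.bmax[j]) nd.bmax[j] = v;
      }
    }
    if (hi - lo > LEAF) {
      int dim = 0; double ext = -1.0;
      for (int j = 0; j < d_; ++j) {
        double e = nd.bmax[j] - nd.bmin[j];
        if (e > ext) { ext = e; dim = j; }
      }
      int mid = (lo + hi) / 2;
      const double* p = pts_; int n = n_;
      std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                       [p, n, dim](int a, int b) {
                         return p[a + (size_t)n * dim] < p[b + (size_t)n * dim];
                       });
      int l = build(lo, mid);
      int r = build(mid, hi);
      nodes_[id].left = l;  // re-index: vector may have been reallocated
      nodes_[id].right = r;
    }
    return id;
  }

  double box_dist(const Node& nd, const double* q) const {
    double d = 0.0;
    for (int j = 0; j < d_; ++j) {
      double lo = nd.bmin[j] - q[j], hi = q[j] - nd.bmax[j];
      double a = lo > hi ? lo : hi;
      if (a > d) d = a;
    }
    return d;
  }
  double box_maxdist(const Node& nd, const double* q) const {
    double d = 0.0;
    for (int j = 0; j < d_; ++j) {
      double a = std::max(std::fabs(q[j] - nd.bmin[j]), std::fabs(q[j] - nd.bmax[j]));
      if (a > d) d = a;
    }
    return d;
  }
  double pt_dist(int i, const double* q) const {
    double d = 0.0;
    for (int j = 0; j < d_; ++j) {
      double a = std::fabs(coord(i, j) - q[j]);
      if (a > d) d = a;
    }
    return d;
  }

  void knn_rec(int id, const double* q, int k, std::vector<double>& heap) const {
    const Node& nd = nodes_[id];
    if ((int)heap.size() == k && box_dist(nd, q) >= heap.front()) return;
    if (nd.left < 0) {
      for (int t = nd.lo; t < nd.hi; ++t) {
        double d = pt_dist(idx_[t], q);
        if ((int)heap.size() < k) {
          heap.push_back(d); std::push_heap(heap.begin(), heap.end());
        } else if (d < heap.front()) {
          std::pop_heap(heap.begin(), heap.end()); heap.back() = d;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double dl = box_dist(nodes_[nd.left], q), dr = box_dist(nodes_[nd.right], q);
    if (dl < dr) { knn_rec(nd.left, q, k, heap); knn_rec(nd.right, q, k, heap); }
    else         { knn_rec(nd.right, q, k, heap); knn_rec(nd.left, q, k, heap); }
  }

  void knn_idx_rec(int id, const double* q, int self, int k,
                   std::vector<std::pair<double, int> >& heap) const {
    const Node& nd = nodes_[id];
    if ((int)heap.size() == k && box_dist(nd, q) >= heap.front().first) return;
    if (nd.left < 0) {
      for (int t = nd.lo; t < nd.hi; ++t) {
        int i = idx_[t];
        if (i == self) continue;
        double d = pt_dist(i, q);
        std::pair<double, int> e(d, i);
        if ((int)heap.size() < k) {
          heap.push_back(e); std::push_heap(heap.begin(), heap.end());
        } else if (e < heap.front()) {
          std::pop_heap(heap.begin(), heap.end()); heap.back() = e;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double dl = box_dist(nodes_[nd.left], q), dr = box_dist(nodes_[nd.right], q);
    if (dl < dr) { knn_idx_rec(nd.left, q, self, k, heap); knn_idx_rec(nd.right, q, self, k, heap); }
    else         { knn_idx_rec(nd.right, q, self, k, heap); knn_idx_rec(nd.left, q, self, k, heap); }
  }

  int count_rec(int id, const double* q, double eps) const {
    const Node& nd = nodes_[id];
    if (box_dist(nd, q) >= eps) return 0;
    if (box_maxdist(nd, q) < eps) return nd.hi - nd.lo;
    if (nd.left < 0) {
      int c = 0;
      for (int t = nd.lo; t < nd.hi; ++t)
        if (pt_dist(idx_[t], q) < eps) ++c;
      return c;
    }
    return count_rec(nd.left, q, eps) + count_rec(nd.right, q, eps);
  }
};

// gather row i of matrix m (n x d) into buf
inline void get_row(const NumericMatrix& m, int i, std::vector<double>& buf) {
  int d = m.ncol(), n = m.nrow();
  buf.resize(d);
  const double* p = m.begin();
  for (int j = 0; j < d; ++j) buf[j] = p[i + (size_t)n * j];
}

NumericMatrix cbind_mats(const NumericMatrix& a, const NumericMatrix& b) {
  int n = a.nrow(), da = a.ncol(), db = b.ncol();
  NumericMatrix out(n, da + db);
  std::copy(a.begin(), a.end(), out.begin());
  std::copy(b.begin(), b.end(), out.begin() + (size_t)n * da);
  return out;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
double ksg_cmi_cpp(NumericMatrix x, NumericMatrix y, NumericMatrix z, int k) {
  int n = x.nrow();
  if (y.nrow() != n || (z.ncol() > 0 && z.nrow() != n))
    stop("ksg_cmi_cpp: row mismatch");
  if (n <= 2 * k) stop("ksg_cmi_cpp: need n > 2k");
  bool cond = z.ncol() > 0;

  NumericMatrix xz = cond ? cbind_mats(x, z) : x;
  NumericMatrix yz = cond ? cbind_mats(y, z) : y;
  NumericMatrix joint = cbind_mats(xz, y);

  KDTree tj(joint.begin(), n, joint.ncol());
  KDTree txz(xz.begin(), n, xz.ncol());
  KDTree tyz(yz.begin(), n, yz.ncol());
  KDTree* tz = cond ? new KDTree(z.begin(), n, z.ncol()) : 0;

  std::vector<double> q, heap;
  double acc = 0.0;
  const double tol = 1e-12;
  for (int i = 0; i < n; ++i) {
    get_row(joint, i, q);
    tj.knn(q.data(), k + 1, heap);   // self is included at distance 0
    double eps = heap[k];
    std::vector<double> qi(q);
    // counts (strictly inside eps, excluding the point itself)
    int nxz = txz.count_within(qi.data(), eps - tol) - 1;
    std::vector<double> qy(q.begin() + xz.ncol(), q.end());
    std::vector<double> qyz(qy);
    if (cond)
      qyz.insert(qyz.end(), qi.begin() + x.ncol(), qi.begin() + xz.ncol());
    int nyz = tyz.count_within(qyz.data(), eps - tol) - 1;
    if (nxz < 0) nxz = 0;
    if (nyz < 0) nyz = 0;
    if (cond) {
      std::vector<double> qz(qi.begin() + x.ncol(), qi.begin() + xz.ncol());
      int nz = tz->count_within(qz.data(), eps - tol) - 1;
      if (nz < 0) nz = 0;
      acc += R::digamma(nxz + 1.0) + R::digamma(nyz + 1.0) - R::digamma(nz + 1.0);
    } else {
      acc += R::digamma(nxz + 1.0) + R::digamma(nyz + 1.0);
    }
  }
  if (tz) delete tz;
  double out = R::digamma((double)k) - acc / n;
  if (!cond) out += R::digamma((double)n);
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix knn_indices_cpp(NumericMatrix z, int k) {
  int n = z.nrow();
  if (k >= n) stop("knn_indices_cpp: k must be < n");
  KDTree tz(z.begin(), n, z.ncol());
  IntegerMatrix out(n, k);
  std::vector<double> q;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    get_row(z, i, q);
    tz.knn_idx(i, k, nb);
    for (int j = 0; j < k; ++j) out(i, j) = nb[j] + 1; // 1-based for R
  }
  return out;
}
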