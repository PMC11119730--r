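#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Exact kd-tree over the rows of a numeric matrix. Supports k-nearest-neighbor
// queries and range counting under the Euclidean (p = 2) and maximum
// (Chebyshev, p = Inf) norms. Self-exclusion is by row index: when the query
// set is the reference set itself, query i never matches reference i.
//
// Euclidean distances are compared in squared form internally and square-rooted
// once on output; Chebyshev distances are compared directly.

namespace {

struct Node {
  int left, right;   // child node ids, -1 for leaf
  int dim;           // split dimension
  double val;        // split value
  int start, end;    // index range [start, end) into perm (leaves only)
};

class KDTree {
public:
  KDTree(const NumericMatrix& pts, bool chebyshev)
    : pts_(pts), cheb_(chebyshev), n_(pts.nrow()), d_(pts.ncol()) {
    perm_.resize(n_);
    for (int i = 0; i < n_; ++i) perm_[i] = i;
    nodes_.reserve(2 * n_ / kLeafSize + 4);
    if (n_ > 0) build(0, n_, 0);
  }

  // distances from q to its k nearest reference points, sorted ascending;
  // `exclude` is a reference row index to skip (-1 for none)
  void knn(const double* q, int k, int exclude, std::vector<double>& out) const {
    std::priority_queue<double> heap;  // max-heap of current best distances
    search(0, q, k, exclude, heap);
    out.resize(heap.size());
    for (int i = static_cast<int>(heap.size()) - 1; i >= 0; --i) {
      out[i] = heap.top();
      heap.pop();
    }
    if (!cheb_)
      for (double& v : out) v = std::sqrt(v);
  }

  // number of reference points with dist(q, x) < r (strict) or <= r,
  // excluding row `exclude`
  int count(const double* q, double r, bool strict, int exclude) const {
    double rcmp = cheb_ ? r : r * r;
    return countRec(0, q, r, rcmp, strict, exclude);
  }

private:
  static const int kLeafSize = 16;
  const NumericMatrix& pts_;
  bool cheb_;
  int n_, d_;
  std::vector<int> perm_;
  std::vector<Node> nodes_;

  double coord(int row, int col) const { return pts_(row, col); }

  double dist(const double* q, int row) const {
    if (cheb_) {
      double m = 0.0;
      for (int j = 0; j < d_; ++j)
        m = std::max(m, std::fabs(q[j] - coord(row, j)));
      return m;
    }
    double s = 0.0;
    for (int j = 0; j < d_; ++j) {
      double w = q[j] - coord(row, j);
      s += w * w;
    }
    return s;  // squared
  }

  int build(int start, int end, int depth) {
    int id = static_cast<int>(nodes_.size());
    nodes_.push_back(Node());
    Node nd;
    nd.start = start;
    nd.end = end;
    if (end - start <= kLeafSize) {
      nd.left = nd.right = -1;
      nd.dim = -1;
      nd.val = 0.0;
      nodes_[id] = nd;
      return id;
    }
    // split on the dimension of largest spread for robustness
    int dim = 0;
    double best = -1.0;
    for (int j = 0; j < d_; ++j) {
      double lo = coord(perm_[start], j), hi = lo;
      for (int i = start + 1; i < end; ++i) {
        double v = coord(perm_[i], j);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > best) { best = hi - lo; dim = j; }
    }
    int mid = start + (end - start) / 2;
    std::nth_element(perm_.begin() + start, perm_.begin() + mid,
                     perm_.begin() + end,
                     [&](int a, int b) { return coord(a, dim) < coord(b, dim); });
    nd.dim = dim;
    nd.val = coord(perm_[mid], dim);
    nodes_[id] = nd;  // placeholder before recursion (vector may grow)
    int left = build(start, mid, depth + 1);
    int right = build(mid, end, depth + 1);
    nodes_[id].left = left;
    nodes_[id].right = right;
    return id;
  }

  void search(int id, const double* q, int k, int exclude,
              std::priority_queue<double>& heap) const {
    const Node& nd = nodes_[id];
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.end; ++i) {
        int row = perm_[i];
        if (row == exclude) continue;
        double dv = dist(q, row);
        if (static_cast<int>(heap.size()) < k) {
          heap.push(dv);
        } else if (dv < heap.top()) {
          heap.pop();
          heap.push(dv);
        }
      }
      return;
    }
    double delta = q[nd.dim] - nd.val;
    int nearer = delta <= 0 ? nd.left : nd.right;
    int farther = delta <= 0 ? nd.right : nd.left;
    search(nearer, q, k, exclude, heap);
    // distance from q to the splitting plane lower-bounds both norms
    double plane = std::fabs(delta);
    double bound = cheb_ ? plane : plane * plane;
    if (static_cast<int>(heap.size()) < k || bound <= heap.top())
      search(farther, q, k, exclude, heap);
  }

  int countRec(int id, const double* q, double r, double rcmp, bool strict,
               int exclude) const {
    const Node& nd = nodes_[id];
    if (nd.left < 0) {
      int c = 0;
      for (int i = nd.start; i < nd.end; ++i) {
        int row = perm_[i];
        if (row == exclude) continue;
        double dv = dist(q, row);
        if (strict ? (dv < rcmp) : (dv <= rcmp)) ++c;
      }
      return c;
    }
    double delta = q[nd.dim] - nd.val;
    int c = 0;
    // left subtree holds coords <= val, right holds coords >= val
    if (delta - r <= 0) c += countRec(nd.left, q, r, rcmp, strict, exclude);
    if (delta + r >= 0) c += countRec(nd.right, q, r, rcmp, strict, exclude);
    return c;
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_knn_dist(NumericMatrix reference, NumericMatrix query, int k,
                           bool chebyshev, bool self_excluded) {
  int nq = query.nrow(), d = query.ncol();
  if (reference.ncol() != d) stop("dimension mismatch between query and reference");
  int avail = self_excluded ? reference.nrow() - 1 : reference.nrow();
  if (k < 1 || k > avail) stop("k out of range for the reference set");
  KDTree tree(reference, chebyshev);
  NumericMatrix out(nq, k);
  std::vector<double> buf, qrow(d);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < d; ++j) qrow[j] = query(i, j);
    tree.knn(qrow.data(), k, self_excluded ? i : -1, buf);
    for (int j = 0; j < k; ++j) out(i, j) = buf[j];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericMatrix reference, NumericMatrix query,
                               NumericVector radius, bool chebyshev,
                               bool self_excluded, bool strict) {
  int nq = query.nrow(), d = query.ncol();
  if (reference.ncol() != d) stop("dimension mismatch between query and reference");
  if (radius.size() != nq) stop("one radius per query point is required");
  KDTree tree(reference, chebyshev);
  IntegerVector out(nq);
  std::vector<double> qrow(d);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < d; ++j) qrow[j] = query(i, j);
    out[i] = tree.count(qrow.data(), radius[i], strict,
                        self_excluded ? i : -1);
  }
  return out;
}
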