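// Dynamic 1-D range-min-query on an AVL tree with subtree-minimum
// pointers, and the colinear anchor-chaining DP that uses it: an exact
// search under the full gap cost inside a small window combined with an
// RMQ-accelerated search under a linear gap cost over the large window.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

struct AvlTree {
  // node arrays; -1 = null
  std::vector<double> key;      // y
  std::vector<long long> id;    // insertion id, breaks key ties
  std::vector<double> val;      // s
  std::vector<int> left, right, height, minp; // minp: node with min s in subtree
  std::vector<int> freelist;
  int root = -1;
  long long next_id = 0;
  int n = 0;

  int node_new(double k, long long i, double v) {
    int t;
    if (!freelist.empty()) { t = freelist.back(); freelist.pop_back(); }
    else {
      t = (int)key.size();
      key.push_back(0); id.push_back(0); val.push_back(0);
      left.push_back(-1); right.push_back(-1);
      height.push_back(1); minp.push_back(t);
    }
    key[t] = k; id[t] = i; val[t] = v;
    left[t] = right[t] = -1; height[t] = 1; minp[t] = t;
    return t;
  }
  int h(int t) const { return t < 0 ? 0 : height[t]; }
  void pull(int t) {
    height[t] = 1 + std::max(h(left[t]), h(right[t]));
    int m = t;
    if (left[t] >= 0 && val[minp[left[t]]] < val[m]) m = minp[left[t]];
    if (right[t] >= 0 && val[minp[right[t]]] < val[m]) m = minp[right[t]];
    minp[t] = m;
  }
  bool less(double k1, long long i1, double k2, long long i2) const {
    return k1 < k2 || (k1 == k2 && i1 < i2);
  }
  int rot_right(int t) {
    int l = left[t];
    left[t] = right[l]; right[l] = t;
    pull(t); pull(l);
    return l;
  }
  int rot_left(int t) {
    int r = right[t];
    right[t] = left[r]; left[r] = t;
    pull(t); pull(r);
    return r;
  }
  int balance(int t) {
    pull(t);
    int bf = h(left[t]) - h(right[t]);
    if (bf > 1) {
      if (h(left[left[t]]) < h(right[left[t]])) left[t] = rot_left(left[t]);
      t = rot_right(t);
    } else if (bf < -1) {
      if (h(right[right[t]]) < h(left[right[t]])) right[t] = rot_right(right[t]);
      t = rot_left(t);
    }
    return t;
  }
  int insert_rec(int t, int nd) {
    if (t < 0) return nd;
    if (less(key[nd], id[nd], key[t], id[t]))
      left[t] = insert_rec(left[t], nd);
    else
      right[t] = insert_rec(right[t], nd);
    return balance(t);
  }
  long long insert(double k, double v) {
    long long i = next_id++;
    root = insert_rec(root, node_new(k, i, v));
    ++n;
    return i;
  }
  int min_node(int t) const { while (left[t] >= 0) t = left[t]; return t; }
  int erase_rec(int t, double k, long long i, bool &found) {
    if (t < 0) return t;
    if (less(k, i, key[t], id[t])) left[t] = erase_rec(left[t], k, i, found);
    else if (less(key[t], id[t], k, i)) right[t] = erase_rec(right[t], k, i, found);
    else {
      found = true;
      if (left[t] < 0 || right[t] < 0) {
        int child = left[t] >= 0 ? left[t] : right[t];
        freelist.push_back(t);
        return child < 0 ? -1 : balance(child);
      }
      int s = min_node(right[t]);
      // move successor's payload into t, then delete successor
      key[t] = key[s]; id[t] = id[s]; val[t] = val[s];
      bool f2 = false;
      right[t] = erase_rec(right[t], key[s], id[s], f2);
    }
    return balance(t);
  }
  bool erase(double k, long long i) {
    bool found = false;
    root = erase_rec(root, k, i, found);
    if (found) --n;
    return found;
  }
  // leftmost (first-inserted) node with key == k, or -1
  int find_key(double k) const {
    int t = root, hit = -1;
    while (t >= 0) {
      if (key[t] < k) t = right[t];
      else {
        if (key[t] == k) hit = t;
        t = left[t];
      }
    }
    return hit;
  }
  // min val among keys >= a (b unbounded); returns node index or -1
  int query_ge(int t, double a) const {
    if (t < 0) return -1;
    if (key[t] < a) return query_ge(right[t], a);
    int best = t;
    if (right[t] >= 0 && val[minp[right[t]]] < val[best]) best = minp[right[t]];
    int lb = query_ge(left[t], a);
    if (lb >= 0 && val[lb] < val[best]) best = lb;
    return best;
  }
  int query_le(int t, double b) const {
    if (t < 0) return -1;
    if (key[t] > b) return query_le(left[t], b);
    int best = t;
    if (left[t] >= 0 && val[minp[left[t]]] < val[best]) best = minp[left[t]];
    int rb = query_le(right[t], b);
    if (rb >= 0 && val[rb] < val[best]) best = rb;
    return best;
  }
  // min val among a <= key <= b; node index or -1
  int query(double a, double b) const {
    int t = root;
    while (t >= 0) {
      if (key[t] < a) { t = right[t]; continue; }
      if (key[t] > b) { t = left[t]; continue; }
      break;
    }
    if (t < 0) return -1;
    int best = t;
    int lb = query_ge(left[t], a);
    if (lb >= 0 && val[lb] < val[best]) best = lb;
    int rb = query_le(right[t], b);
    if (rb >= 0 && val[rb] < val[best]) best = rb;
    return best;
  }
};

// ---- R-facing RMQ tree ----

// [[Rcpp::export(name = ".rmq_new")]]
SEXP rmq_new() {
  XPtr<AvlTree> p(new AvlTree(), true);
  return p;
}

// [[Rcpp::export(name = ".rmq_insert")]]
double rmq_insert_cpp(SEXP ptr, double y, double s) {
  XPtr<AvlTree> p(ptr);
  return (double)p->insert(y, s);
}

// [[Rcpp::export(name = ".rmq_delete")]]
bool rmq_delete_cpp(SEXP ptr, double y) {
  XPtr<AvlTree> p(ptr);
  int t = p->find_key(y);
  if (t < 0) return false;
  return p->erase(p->key[t], p->id[t]);
}

// [[Rcpp::export(name = ".rmq_query")]]
double rmq_query_cpp(SEXP ptr, double a, double b) {
  XPtr<AvlTree> p(ptr);
  int t = p->query(a, b);
  return t < 0 ? NA_REAL : p->val[t];
}

// [[Rcpp::export(name = ".rmq_size")]]
int rmq_size_cpp(SEXP ptr) {
  XPtr<AvlTree> p(ptr);
  return p->n;
}

// [[Rcpp::export(name = ".rmq_height")]]
int rmq_height_cpp(SEXP ptr) {
  XPtr<AvlTree> p(ptr);
  return p->root < 0 ? 0 : p->height[p->root];
}

// ---- chaining DP ----

static inline double full_beta(double g, double dmin, double G,
                               double c1, double c2) {
  if (g > G) return R_PosInf;
  if (g == 0) return 0.0;
  return c1 * g + c2 * dmin + std::log2(g);
}

// Combined chaining DP over anchors sorted by (x, y), one segment/strand
// run. Exact search under the full gap cost within the G' window, plus an
// RMQ candidate optimal under the linear cost c1*(dx+dy) within the G
// window; the better of the two, rescored under the full cost, becomes
// the predecessor. Returns f (score ending at i) and prev (1-based; 0 =
// chain start).
// [[Rcpp::export(name = ".chain_dp")]]
List chain_dp_cpp(NumericVector x, NumericVector y, NumericVector w,
                  double G, double Gp, double c1, double c2,
                  bool use_rmq = true) {
  int n = x.size();
  NumericVector f(n), fp(n);
  IntegerVector prev(n);
  std::vector<double> hp(n);          // h'(j) for the linear-cost DP
  std::vector<long long> node_id(n, -1);
  AvlTree tree;
  int ins = 0, del = 0;
  for (int i = 0; i < n; ++i) {
    // maintain RMQ window {j : x_i - G <= x_j <= x_i - w_i}
    if (use_rmq) {
      while (ins < i && x[ins] <= x[i] - w[i]) {
        node_id[ins] = tree.insert(y[ins], -hp[ins]);
        ++ins;
      }
      while (del < ins && x[del] < x[i] - G) {
        tree.erase(y[del], node_id[del]);
        ++del;
      }
    }
    double best = w[i], bestg = -1.0;
    int bestj = -1;
    // exact search in the G' window under the full cost
    for (int j = i - 1; j >= 0; --j) {
      if (x[i] - x[j] > Gp) break;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx <= 0 || dy <= 0 || dy > Gp) continue;
      double g = std::fabs(dy - dx);
      double dmin = std::min(dx, dy);
      double beta = full_beta(g, dmin, G, c1, c2);
      if (!R_finite(beta)) continue;
      double alpha = std::min(dmin, w[i]);
      double sc = f[j] + alpha - beta;
      if (sc > best || (sc == best && bestj >= 0 && g < bestg)) {
        best = sc; bestj = j; bestg = g;
      }
    }
    // linear-cost DP value and RMQ candidate
    double fpi = 0.0;
    if (use_rmq) {
      int t = tree.query(y[i] - G, y[i] - w[i]);
      if (t >= 0) {
        double cand = -tree.val[t] - c1 * (x[i] + y[i]);
        if (cand > fpi) fpi = cand;
        int j = (int)tree.id[t];
        // rescore the RMQ winner under the full cost
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx > 0 && dy > 0) {
          double g = std::fabs(dy - dx);
          double dmin = std::min(dx, dy);
          double beta = full_beta(g, dmin, G, c1, c2);
          if (R_finite(beta)) {
            double sc = f[j] + std::min(dmin, w[i]) - beta;
            if (sc > best) { best = sc; bestj = j; bestg = g; }
          }
        }
      }
    }
    f[i] = best;
    fp[i] = fpi;
    hp[i] = fpi + w[i] + c1 * (x[i] + y[i]);
    prev[i] = bestj + 1;  // 1-based for R; 0 = none
  }
  return List::create(_["f"] = f, _["prev"] = prev, _["fprime"] = fp);
}
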