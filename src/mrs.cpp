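// Multiresolution region-merging segmentation.
//
// Bottom-up pairwise merging from an initial partition (single pixels or a
// finer segmentation level).  Merge cost
//   f = (1 - shape_w) * dh_color + shape_w * dh_shape
//   dh_color = sum_b w_b * (n_m s_m,b - n_1 s_1,b - n_2 s_2,b)
//   dh_shape = cmpct_w * dh_cmpct + (1 - cmpct_w) * dh_smooth
// with compactness l/sqrt(n) and smoothness l/(bounding-box perimeter),
// each object-size weighted.  A merge executes only if f < scale^2, and
// only for mutually best-fitting pairs; the scan order is deterministic
// (ascending object id, survivor = smaller id) so runs are reproducible
// without a seed.  Objects are 4-connected; 0-labelled (masked) pixels
// belong to no object.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Obj {
  bool active = false;
  double n = 0;
  std::vector<double> sum, sumsq;
  double perim = 0;
  int rmin = 0, rmax = -1, cmin = 0, cmax = -1;
  std::vector<int> nbr;          // neighbour object ids
  std::vector<double> shared;    // shared boundary length per neighbour
  bool best_valid = false;
  int best_id = -1;
  double best_f = 0;
};

inline double sigma(const Obj& o, int b) {
  double m = o.sum[b] / o.n;
  double v = o.sumsq[b] / o.n - m * m;
  return v > 0 ? std::sqrt(v) : 0.0;
}

inline double h_cmpct(double l, double n) { return l / std::sqrt(n); }
inline double bbox_perim(int rmin, int rmax, int cmin, int cmax) {
  return 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
}

double merge_cost(const Obj& a, const Obj& b, double shared,
                  const std::vector<double>& w,
                  double shape_w, double cmpct_w) {
  const int L = (int)w.size();
  double nm = a.n + b.n;
  double dcolor = 0;
  for (int k = 0; k < L; ++k) {
    double s = a.sum[k] + b.sum[k], ss = a.sumsq[k] + b.sumsq[k];
    double m = s / nm, v = ss / nm - m * m;
    double sm = v > 0 ? std::sqrt(v) : 0.0;
    dcolor += w[k] * (nm * sm - a.n * sigma(a, k) - b.n * sigma(b, k));
  }
  if (shape_w == 0) return dcolor;
  double lm = a.perim + b.perim - 2.0 * shared;
  double d_cmp = nm * h_cmpct(lm, nm)
    - a.n * h_cmpct(a.perim, a.n) - b.n * h_cmpct(b.perim, b.n);
  int rmin = std::min(a.rmin, b.rmin), rmax = std::max(a.rmax, b.rmax);
  int cmin = std::min(a.cmin, b.cmin), cmax = std::max(a.cmax, b.cmax);
  double d_smo = nm * lm / bbox_perim(rmin, rmax, cmin, cmax)
    - a.n * a.perim / bbox_perim(a.rmin, a.rmax, a.cmin, a.cmax)
    - b.n * b.perim / bbox_perim(b.rmin, b.rmax, b.cmin, b.cmax);
  double dshape = cmpct_w * d_cmp + (1 - cmpct_w) * d_smo;
  return (1 - shape_w) * dcolor + shape_w * dshape;
}

inline int nbr_index(const Obj& o, int id) {
  for (size_t k = 0; k < o.nbr.size(); ++k)
    if (o.nbr[k] == id) return (int)k;
  return -1;
}

inline void nbr_remove(Obj& o, int id) {
  int k = nbr_index(o, id);
  if (k >= 0) {
    o.nbr[k] = o.nbr.back(); o.nbr.pop_back();
    o.shared[k] = o.shared.back(); o.shared.pop_back();
  }
}

inline void nbr_add(Obj& o, int id, double s) {
  int k = nbr_index(o, id);
  if (k >= 0) o.shared[k] += s;
  else { o.nbr.push_back(id); o.shared.push_back(s); }
}

} // namespace

// [[Rcpp::export(name = ".mrs_segment_cpp")]]
IntegerMatrix mrs_segment_cpp(List layers, NumericVector weights,
                              double scale, double shape_w, double cmpct_w,
                              IntegerMatrix init) {
  const int nr = init.nrow(), nc = init.ncol();
  const int L = layers.size();
  std::vector<const double*> lay(L);
  for (int k = 0; k < L; ++k) {
    NumericMatrix m = layers[k];
    if (m.nrow() != nr || m.ncol() != nc)
      stop("layer %d does not match the init grid", k + 1);
    lay[k] = REAL(m);
  }
  std::vector<double> w(weights.begin(), weights.end());
  if ((int)w.size() != L) stop("one weight per layer required");
  if (scale <= 0) stop("scale must be positive");
  const double thr = scale * scale;

  int maxlab = 0;
  for (int i = 0; i < nr * nc; ++i)
    if (init[i] > maxlab) maxlab = init[i];
  std::vector<Obj> obj(maxlab + 1);

  // accumulate per-object stats
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = init[r + (size_t)c * nr];
      if (id <= 0) continue;
      Obj& o = obj[id];
      if (!o.active) {
        o.active = true;
        o.sum.assign(L, 0.0); o.sumsq.assign(L, 0.0);
        o.rmin = r; o.rmax = r; o.cmin = c; o.cmax = c;
      }
      o.n += 1;
      o.rmin = std::min(o.rmin, r); o.rmax = std::max(o.rmax, r);
      o.cmin = std::min(o.cmin, c); o.cmax = std::max(o.cmax, c);
      for (int k = 0; k < L; ++k) {
        double v = lay[k][r + (size_t)c * nr];
        if (ISNAN(v)) stop("NA layer value inside an unmasked pixel");
        o.sum[k] += v; o.sumsq[k] += v * v;
      }
    }
  }

  // perimeter and adjacency (4-neighbourhood, shared boundary lengths)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = init[r + (size_t)c * nr];
      if (id <= 0) continue;
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        int id2 = (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc)
          ? 0 : init[r2 + (size_t)c2 * nr];
        if (id2 != id) {
          obj[id].perim += 1;
          // count each shared edge once (from the smaller id, right/down)
          if (id2 > 0 && id < id2 && (d == 1 || d == 3)) {
            nbr_add(obj[id], id2, 1.0);
            nbr_add(obj[id2], id, 1.0);
          }
        }
      }
    }
  }

  std::vector<int> parent(maxlab + 1);
  for (int i = 0; i <= maxlab; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  auto compute_best = [&](int i) {
    Obj& o = obj[i];
    o.best_id = -1; o.best_f = R_PosInf;
    for (size_t k = 0; k < o.nbr.size(); ++k) {
      int j = o.nbr[k];
      double f = merge_cost(o, obj[j], o.shared[k], w, shape_w, cmpct_w);
      if (f < o.best_f || (f == o.best_f && j < o.best_id)) {
        o.best_f = f; o.best_id = j;
      }
    }
    o.best_valid = true;
  };

  bool changed = true;
  while (changed) {
    changed = false;
    for (int i = 1; i <= maxlab; ++i) {
      if (!obj[i].active) continue;
      if (!obj[i].best_valid) compute_best(i);
      int j = obj[i].best_id;
      if (j < 0 || obj[i].best_f >= thr) continue;
      if (!obj[j].best_valid) compute_best(j);
      if (obj[j].best_id != i) continue;       // not mutually best
      // merge: survivor = smaller id
      int a = std::min(i, j), b = std::max(i, j);
      Obj& A = obj[a]; Obj& B = obj[b];
      double sAB = A.shared[nbr_index(A, b)];
      for (int k = 0; k < L; ++k) {
        A.sum[k] += B.sum[k]; A.sumsq[k] += B.sumsq[k];
      }
      A.perim = A.perim + B.perim - 2.0 * sAB;
      A.n += B.n;
      A.rmin = std::min(A.rmin, B.rmin); A.rmax = std::max(A.rmax, B.rmax);
      A.cmin = std::min(A.cmin, B.cmin); A.cmax = std::max(A.cmax, B.cmax);
      nbr_remove(A, b);
      for (size_t k = 0; k < B.nbr.size(); ++k) {
        int t = B.nbr[k];
        if (t == a) continue;
        nbr_remove(obj[t], b);
        nbr_add(obj[t], a, B.shared[k]);
        nbr_add(A, t, B.shared[k]);
        obj[t].best_valid = false;
      }
      B.active = false;
      B.nbr.clear(); B.shared.clear();
      parent[b] = a;
      A.best_valid = false;
      for (size_t k = 0; k < A.nbr.size(); ++k)
        obj[A.nbr[k]].best_valid = false;
      changed = true;
    }
  }

  // relabel contiguously in order of first occurrence (column-major)
  std::vector<int> newlab(maxlab + 1, 0);
  int next = 0;
  IntegerMatrix out(nr, nc);
  for (size_t i = 0; i < (size_t)nr * nc; ++i) {
    int id = init[i];
    if (id <= 0) { out[i] = 0; continue; }
    int root = find(id);
    if (newlab[root] == 0) newlab[root] = ++next;
    out[i] = newlab[root];
  }
  return out;
}

// Mean within-object standard deviation, averaged over layers — the
// local-variance statistic scanned over candidate scales.
// [[Rcpp::export(name = ".object_lv_cpp")]]
double object_lv_cpp(List layers, IntegerMatrix labels) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const int L = layers.size();
  int maxlab = 0;
  for (size_t i = 0; i < (size_t)nr * nc; ++i)
    if (labels[i] > maxlab) maxlab = labels[i];
  if (maxlab == 0) return NA_REAL;
  double total = 0;
  for (int k = 0; k < L; ++k) {
    NumericMatrix m = layers[k];
    std::vector<double> n(maxlab + 1, 0), s(maxlab + 1, 0),
      ss(maxlab + 1, 0);
    for (size_t i = 0; i < (size_t)nr * nc; ++i) {
      int id = labels[i];
      if (id <= 0) continue;
      double v = m[i];
      n[id] += 1; s[id] += v; ss[id] += v * v;
    }
    double acc = 0; int cnt = 0;
    for (int id = 1; id <= maxlab; ++id) {
      if (n[id] == 0) continue;
      double mu = s[id] / n[id], var = ss[id] / n[id] - mu * mu;
      acc += var > 0 ? std::sqrt(var) : 0.0;
      ++cnt;
    }
    total += acc / cnt;
  }
  return total / L;
}

// Bulk all-direction GLCM entropy, one value per object: min-max
// quantization per object, symmetric co-occurrence over the four
// distance-1 offsets, pairs restricted to within-object pixels.
// [[Rcpp::export(name = ".glcm_entropy_by_object_cpp")]]
NumericVector glcm_entropy_by_object_cpp(NumericMatrix layer,
                                         IntegerMatrix labels,
                                         int levels) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int maxlab = 0;
  for (size_t i = 0; i < (size_t)nr * nc; ++i)
    if (labels[i] > maxlab) maxlab = labels[i];
  std::vector<double> vmin(maxlab + 1, R_PosInf),
    vmax(maxlab + 1, R_NegInf);
  for (size_t i = 0; i < (size_t)nr * nc; ++i) {
    int id = labels[i];
    if (id <= 0) continue;
    double v = layer[i];
    if (v < vmin[id]) vmin[id] = v;
    if (v > vmax[id]) vmax[id] = v;
  }
  // quantized values
  std::vector<int> q((size_t)nr * nc, -1);
  for (size_t i = 0; i < (size_t)nr * nc; ++i) {
    int id = labels[i];
    if (id <= 0) continue;
    double lo = vmin[id], hi = vmax[id];
    int g = (hi > lo)
      ? std::min(levels - 1, (int)std::floor((layer[i] - lo) / (hi - lo)
                                             * levels))
      : 0;
    q[i] = g;
  }
  std::unordered_map<uint64_t, double> counts;
  std::vector<double> totals(maxlab + 1, 0.0);
  const int dr[4] = {0, -1, -1, -1}, dc[4] = {1, 1, 0, -1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = labels[r + (size_t)c * nr];
      if (id <= 0) continue;
      int a = q[r + (size_t)c * nr];
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (labels[r2 + (size_t)c2 * nr] != id) continue;
        int b = q[r2 + (size_t)c2 * nr];
        uint64_t k1 = ((uint64_t)id << 16) | ((uint64_t)a << 8) | b;
        uint64_t k2 = ((uint64_t)id << 16) | ((uint64_t)b << 8) | a;
        counts[k1] += 1; counts[k2] += 1;
        totals[id] += 2;
      }
    }
  }
  NumericVector ent(maxlab);
  for (auto& kv : counts) {
    int id = (int)(kv.first >> 16);
    double p = kv.second / totals[id];
    ent[id - 1] -= p * std::log(p);
  }
  return ent;
}

// Partition/connectivity audit: labels must be contiguous 1..K over
// unmasked pixels and every object 4-connected.  Returns true or throws.
// [[Rcpp::export(name = ".check_partition_cpp")]]
bool check_partition_cpp(IntegerMatrix labels) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int maxlab = 0;
  for (size_t i = 0; i < (size_t)nr * nc; ++i) {
    if (labels[i] < 0) stop("negative label");
    if (labels[i] > maxlab) maxlab = labels[i];
  }
  std::vector<double> count(maxlab + 1, 0), seen(maxlab + 1, 0);
  std::vector<int> seed(maxlab + 1, -1);
  for (size_t i = 0; i < (size_t)nr * nc; ++i) {
    int id = labels[i];
    if (id == 0) continue;
    count[id] += 1;
    if (seed[id] < 0) seed[id] = (int)i;
  }
  for (int id = 1; id <= maxlab; ++id)
    if (count[id] == 0) stop("labels are not contiguous 1..n");
  std::vector<char> visited((size_t)nr * nc, 0);
  std::vector<int> stack;
  for (int id = 1; id <= maxlab; ++id) {
    stack.clear();
    stack.push_back(seed[id]);
    visited[seed[id]] = 1;
    double n = 0;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      n += 1;
      int r = p % nr, c = p / nr;
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int r2 = r + dr[d], c2 = c + dc[d];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int q = r2 + c2 * nr;
        if (!visited[q] && labels[q] == id) {
          visited[q] = 1;
          stack.push_back(q);
        }
      }
    }
    if (n != count[id]) stop("object %d is not 4-connected", id);
  }
  return true;
}
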