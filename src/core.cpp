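#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Disjoint-set forest with union by size and path compression.
struct DSF {
  std::vector<int> parent;
  std::vector<int> size;
  DSF(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int root = x;
    while (parent[root] != root) root = parent[root];
    while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
    return root;
  }
  int join(int a, int b) {
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
    return a;
  }
};

struct Edge {
  double w;
  int p, q; // column-major pixel indices, p < q
};

static void build_edges(const NumericMatrix &img, int connectivity,
                        std::vector<Edge> &edges) {
  const int H = img.nrow(), W = img.ncol();
  edges.clear();
  edges.reserve((size_t)2 * H * W * (connectivity == 8 ? 2 : 1));
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int p = c * H + r;
      if (r + 1 < H) { // down
        int q = p + 1;
        edges.push_back({std::fabs(img(r, c) - img(r + 1, c)), p, q});
      }
      if (c + 1 < W) { // right
        int q = p + H;
        edges.push_back({std::fabs(img(r, c) - img(r, c + 1)), p, q});
      }
      if (connectivity == 8) {
        if (r + 1 < H && c + 1 < W) { // down-right
          int q = p + H + 1;
          edges.push_back({std::fabs(img(r, c) - img(r + 1, c + 1)), p, q});
        }
        if (r > 0 && c + 1 < W) { // up-right
          int q = p + H - 1;
          edges.push_back({std::fabs(img(r, c) - img(r - 1, c + 1)), p, q});
        }
      }
    }
  }
  // deterministic order: nondecreasing weight, ties by first then second endpoint
  std::sort(edges.begin(), edges.end(), [](const Edge &a, const Edge &b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.p != b.p) return a.p < b.p;
    return a.q < b.q;
  });
}

// Graph-based still-segmentation (Felzenszwalb-Huttenlocher merge rule):
// components c1, c2 merge when the between-region difference (current edge
// weight, edges processed in nondecreasing order) does not exceed
// min(Int(c1) + k/|c1|, Int(c2) + k/|c2|), Int being the largest merge
// weight inside the component. A post-pass merges every region smaller
// than min_size with its lowest-weight-edge neighbour.
// [[Rcpp::export]]
IntegerMatrix fh_segment_cpp(NumericMatrix img, double k, int min_size,
                             int connectivity) {
  const int H = img.nrow(), W = img.ncol();
  const int n = H * W;
  std::vector<Edge> edges;
  build_edges(img, connectivity, edges);

  DSF dsf(n);
  std::vector<double> intdiff(n, 0.0); // Int(c), indexed by root
  for (const Edge &e : edges) {
    int a = dsf.find(e.p), b = dsf.find(e.q);
    if (a == b) continue;
    double ta = intdiff[a] + k / dsf.size[a];
    double tb = intdiff[b] + k / dsf.size[b];
    if (e.w <= std::min(ta, tb)) {
      int root = dsf.join(a, b);
      intdiff[root] = e.w; // edges ascending: new internal max is e.w
    }
  }
  if (min_size > 1) {
    for (const Edge &e : edges) {
      int a = dsf.find(e.p), b = dsf.find(e.q);
      if (a == b) continue;
      if (dsf.size[a] < min_size || dsf.size[b] < min_size) dsf.join(a, b);
    }
  }
  // renumber 1..K by first occurrence in column-major order
  IntegerMatrix labels(H, W);
  std::vector<int> lab(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int root = dsf.find(i);
    if (lab[root] == 0) lab[root] = ++next;
    labels[i] = lab[root];
  }
  labels.attr("n_regions") = next;
  return labels;
}

static inline int mirror_index(int i, int n) {
  // reflect about the edge pixel without repeating it: -1 -> 1, n -> n-2
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Per-pixel Shannon entropy (bits) of the windowed intensity histogram.
// Odd windows are centred; even windows take one extra row/column towards
// the bottom-right. Values are assumed in [0, 1] and binned uniformly.
// [[Rcpp::export]]
NumericMatrix local_entropy_cpp(NumericMatrix x, int window, int bins) {
  const int H = x.nrow(), W = x.ncol();
  const int lo = -(window - 1) / 2;      // odd: -(w-1)/2; even: -(w/2 - 1)
  const int hi = window / 2;             // odd: (w-1)/2;  even: w/2
  NumericMatrix out(H, W);
  std::vector<int> hist(bins);
  std::vector<int> binned((size_t)H * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double v = x(r, c);
      int b = (int)(v * bins);
      if (b < 0) b = 0;
      if (b >= bins) b = bins - 1;
      binned[(size_t)c * H + r] = b;
    }
  const double total = (double)window * window;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int dc = lo; dc <= hi; ++dc) {
        int cc = mirror_index(c + dc, W);
        for (int dr = lo; dr <= hi; ++dr) {
          int rr = mirror_index(r + dr, H);
          ++hist[binned[(size_t)cc * H + rr]];
        }
      }
      double hsum = 0.0;
      for (int b = 0; b < bins; ++b) {
        if (hist[b] > 0) {
          double p = hist[b] / total;
          hsum -= p * std::log2(p);
        }
      }
      out(r, c) = hsum;
    }
  }
  return out;
}

// Connected-component labelling of a binary mask; components numbered
// 1..K by first occurrence in column-major order, background stays 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int n = H * W;
  DSF dsf(n);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int p = c * H + r;
      if (r + 1 < H && mask(r + 1, c)) dsf.join(dsf.find(p), dsf.find(p + 1));
      if (c + 1 < W && mask(r, c + 1)) dsf.join(dsf.find(p), dsf.find(p + H));
      if (connectivity == 8) {
        if (r + 1 < H && c + 1 < W && mask(r + 1, c + 1))
          dsf.join(dsf.find(p), dsf.find(p + H + 1));
        if (r > 0 && c + 1 < W && mask(r - 1, c + 1))
          dsf.join(dsf.find(p), dsf.find(p + H - 1));
      }
    }
  }
  IntegerMatrix labels(H, W);
  std::vector<int> lab(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = i % H, c = i / H;
    if (!mask(r, c)) { labels[i] = 0; continue; }
    int root = dsf.find(i);
    if (lab[root] == 0) lab[root] = ++next;
    labels[i] = lab[root];
  }
  labels.attr("n_components") = next;
  return labels;
}
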