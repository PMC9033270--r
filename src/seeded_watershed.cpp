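#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Priority-flood seeded watershed. Pixels are flooded in order of increasing
// height (ties broken by insertion order, which is deterministic: seeds are
// pushed in label order and neighbours in scan order), constrained to `mask`.
// Each pixel is labelled when first reached; the flooding level carried along
// a path is the running maximum of heights, so two basins meet on the lowest
// saddle between their seeds.

struct Node {
  double h;
  unsigned long long order;
  int idx;
  int label;
};

struct NodeCmp {
  bool operator()(const Node &a, const Node &b) const {
    if (a.h != b.h) return a.h > b.h;   // lower flooding level first
    return a.order > b.order;           // then FIFO
  }
};

// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix height, LogicalMatrix mask,
                                   IntegerMatrix seeds) {
  const int nr = height.nrow(), nc = height.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("mask and height must share dimensions");
  IntegerMatrix labels(nr, nc);
  std::priority_queue<Node, std::vector<Node>, NodeCmp> pq;
  unsigned long long order = 0;

  const int ns = seeds.nrow();
  for (int s = 0; s < ns; ++s) {
    const int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed outside image bounds");
    const int idx = c * nr + r;
    if (mask[idx] && labels[idx] == 0) {
      labels[idx] = s + 1;
      pq.push(Node{height[idx], order++, idx, s + 1});
    }
  }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    const Node nd = pq.top();
    pq.pop();
    const int r = nd.idx % nr, c = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int j = cc * nr + rr;
      if (!mask[j] || labels[j] != 0) continue;
      labels[j] = nd.label;
      pq.push(Node{std::max(height[j], nd.h), order++, j, nd.label});
    }
  }
  return labels;
}
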