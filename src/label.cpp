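#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a binary mask (column-major logical
// matrix) with 4- or 8-connectivity. Two-pass union-find; labels are
// renumbered 1..n in order of first (column-major) appearance.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 0;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously visited neighbours in column-major order
      int best = 0;
      int neigh[4];
      int nn = 0;
      if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0 && mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
      if (connectivity == 8) {
        if (i > 0 && j > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (i < nr - 1 && j > 0 && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < nn; ++k) unite(parent, best, neigh[k]);
      }
    }
  }

  // second pass: resolve and renumber in order of first appearance
  std::vector<int> renum(next + 1, 0);
  int n_out = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!lab(i, j)) continue;
      int r = find_root(parent, lab(i, j));
      if (!renum[r]) renum[r] = ++n_out;
      lab(i, j) = renum[r];
    }
  }
  return lab;
}
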