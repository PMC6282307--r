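#include <Rcpp.h>
using namespace Rcpp;

// Exact minimization of the LCA duplication-loss cost over all 2^m
// assignments of ambiguous gene leaves to host (MUL-tree) leaf copies.
// Node ids are the 1-based ids of the R phylo edge matrices.  Assignments
// are enumerated in lexicographic order (first ambiguous leaf = most
// significant bit, A=0 < B=1); the first strict minimum wins, so the
// returned assignment is the lexicographically smallest optimum.
//
// Loss counting is on the host tree induced by the images of the sampled
// leaves: a host node counts toward path lengths only if at least two of
// its child subtrees contain images ("branching" nodes).

// [[Rcpp::export]]
List cpp_min_assignment(IntegerMatrix gkids, IntegerVector gpo, int gntips,
                        IntegerVector img_fixed, IntegerVector amb,
                        IntegerVector optA, IntegerVector optB,
                        IntegerVector hparent, IntegerMatrix hkids,
                        IntegerVector hpo, IntegerVector hdepth, int hntips,
                        double cost_dup, double cost_loss) {
  const int gn = gkids.nrow();
  const int hn = hparent.size();
  const int m = amb.size();
  if (m > 25) stop("too many ambiguous leaves");
  const long n_assign = 1L << m;

  std::vector<int> img(gn + 1), cnt(hn + 1), idepth(hn + 1);
  std::vector<char> branching(hn + 1);
  std::vector<int> leaf_img(gntips + 1);

  double best_cost = -1.0;
  int bestD = 0, bestL = 0;
  std::vector<int> best_bits(m, 0);

  for (long a = 0; a < n_assign; ++a) {
    // leaf images for this assignment
    for (int i = 1; i <= gntips; ++i) leaf_img[i] = img_fixed[i - 1];
    for (int j = 0; j < m; ++j) {
      const int bit = (int)((a >> (m - 1 - j)) & 1L);
      leaf_img[amb[j]] = bit ? optB[j] : optA[j];
    }
    // induced-subtree bookkeeping on the host
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 1; i <= gntips; ++i) cnt[leaf_img[i]]++;
    for (int k = 0; k < hn; ++k) {
      const int v = hpo[k];
      if (v > hntips) {
        const int c1 = hkids(v - 1, 0), c2 = hkids(v - 1, 1);
        cnt[v] += cnt[c1] + cnt[c2];
        branching[v] = (cnt[c1] > 0 && cnt[c2] > 0);
      } else {
        branching[v] = 0;
      }
    }
    for (int k = hn - 1; k >= 0; --k) {
      const int v = hpo[k];
      const int p = hparent[v - 1];
      idepth[v] = (p == 0) ? 0 : idepth[p] + (branching[p] ? 1 : 0);
    }
    // LCA mapping and event counts over the gene tree
    int D = 0, L = 0;
    for (int k = 0; k < gn; ++k) {
      const int g = gpo[k];
      if (g <= gntips) { img[g] = leaf_img[g]; continue; }
      const int c1 = gkids(g - 1, 0), c2 = gkids(g - 1, 1);
      int x = img[c1], y = img[c2];
      while (x != y) {
        if (hdepth[x - 1] >= hdepth[y - 1]) x = hparent[x - 1];
        else y = hparent[y - 1];
      }
      img[g] = x;
      const bool dup = (x == img[c1]) || (x == img[c2]);
      if (dup) ++D;
      L += (idepth[img[c1]] - idepth[x]) - (dup ? 0 : 1);
      L += (idepth[img[c2]] - idepth[x]) - (dup ? 0 : 1);
    }
    const double cost = cost_dup * D + cost_loss * L;
    if (best_cost < 0.0 || cost < best_cost) {
      best_cost = cost;
      bestD = D; bestL = L;
      for (int j = 0; j < m; ++j)
        best_bits[j] = (int)((a >> (m - 1 - j)) & 1L);
    }
  }
  return List::create(_["bits"] = IntegerVector(best_bits.begin(),
                                                best_bits.end()),
                      _["D"] = bestD, _["L"] = bestL,
                      _["cost"] = best_cost);
}
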