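#include <Rcpp.h>
using namespace Rcpp;

// Fenwick (binary indexed) tree over prediction ranks, storing weights.
struct Fenwick {
  std::vector<double> t;
  int n;
  Fenwick(int n_) : t(n_ + 1, 0.0), n(n_) {}
  void add(int i, double w) {
    for (; i <= n; i += i & (-i)) t[i] += w;
  }
  double prefix(int i) const {  // sum of ranks 1..i
    double s = 0.0;
    for (; i > 0; i -= i & (-i)) s += t[i];
    return s;
  }
};

// Weighted pairwise concordance for right-censored data.
//
// Inputs must be sorted by decreasing time. A pair (i, j) is comparable when
// the earlier time belongs to an event; it is concordant when that member
// has the higher predicted risk; prediction ties count 1/2. Pair weight is
// the product of the member weights; pairs with tied times are not
// comparable. Returns (concordant, discordant, tied, comparable) weights.
// [[Rcpp::export(name = ".concordance_counts")]]
NumericVector concordance_counts(IntegerVector rank, NumericVector time,
                                 LogicalVector event, NumericVector w,
                                 int n_ranks) {
  int n = rank.size();
  Fenwick tree(n_ranks);
  double conc = 0.0, disc = 0.0, tied = 0.0, comp = 0.0, in_tree = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && time[j] == time[i]) ++j;  // block of tied times
    for (int k = i; k < j; ++k) {             // query events against later times
      if (!event[k] || in_tree <= 0.0) continue;
      double below = tree.prefix(rank[k] - 1);
      double at = tree.prefix(rank[k]) - below;
      double above = in_tree - below - at;
      conc += w[k] * below;   // later-time member has lower predicted risk
      disc += w[k] * above;
      tied += w[k] * at;
      comp += w[k] * in_tree;
    }
    for (int k = i; k < j; ++k) {             // then insert the whole block
      tree.add(rank[k], w[k]);
      in_tree += w[k];
    }
    i = j;
  }
  return NumericVector::create(conc, disc, tied, comp);
}
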