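#include <Rcpp.h>
using namespace Rcpp;

// Permutation kernels for the Monte-Carlo tests. Both use R's RNG so that
// set.seed() in R controls the draws.

// Null sums for the spacer-position test: for each permutation, draw for
// cassette i a random k[i]-subset of serials 1..n[i] (without replacement)
// and return the total of all drawn serials across cassettes.
// [[Rcpp::export]]
NumericVector perm_position_sums(IntegerVector n, IntegerVector k, int nperm) {
  int m = n.size();
  int nmax = 0;
  for (int i = 0; i < m; ++i) {
    if (k[i] < 0 || k[i] > n[i]) stop("invalid flagged count");
    if (n[i] > nmax) nmax = n[i];
  }
  std::vector<int> pool(nmax);
  NumericVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    double total = 0.0;
    for (int i = 0; i < m; ++i) {
      int ni = n[i], ki = k[i];
      for (int j = 0; j < ni; ++j) pool[j] = j + 1;
      // partial Fisher-Yates: first ki entries become the sample
      for (int j = 0; j < ki; ++j) {
        int r = j + (int)(unif_rand() * (ni - j));
        if (r >= ni) r = ni - 1;
        std::swap(pool[j], pool[r]);
        total += pool[j];
      }
    }
    out[p] = total;
  }
  return out;
}

// Null counts for the cassette-shuffle sharing test: labels[i] is the
// individual owning cassette i. seq_groups holds, for every spacer sequence
// occurring in >= 2 cassettes, the (1-based) indices of those cassettes.
// Each permutation shuffles the label vector (preserving per-individual
// cassette counts) and counts sequences seen in >= 2 distinct individuals.
// [[Rcpp::export]]
IntegerVector perm_shared_counts(IntegerVector labels, List seq_groups, int nperm) {
  int nc = labels.size();
  int ng = seq_groups.size();
  std::vector<int> lab(nc);
  IntegerVector out(nperm);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < nc; ++i) lab[i] = labels[i];
    for (int i = nc - 1; i > 0; --i) {
      int r = (int)(unif_rand() * (i + 1));
      if (r > i) r = i;
      std::swap(lab[i], lab[r]);
    }
    int shared = 0;
    for (int g = 0; g < ng; ++g) {
      IntegerVector idx = seq_groups[g];
      int first = lab[idx[0] - 1];
      for (int j = 1; j < idx.size(); ++j) {
        if (lab[idx[j] - 1] != first) { ++shared; break; }
      }
    }
    out[p] = shared;
  }
  return out;
}
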