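#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Nearest-taxon turnover engines. Null models shuffle taxon labels on the
// cophenetic matrix; a permutation row maps taxon slot -> shuffled slot.
// Row 0 of `perms` is conventionally the identity (the observed value).

// beta-MNTD between sample pairs under label permutations.
// D: K x K cophenetic matrix; comm_idx: per-sample 0-based indices of taxa
// present; comm_w: matching weights (relative abundances, or 1/S for the
// unweighted variant); pairs: n_pairs x 2 (0-based sample indices);
// perms: n_perm x K permutations of 0..K-1.
// Returns n_pairs x n_perm.
// [[Rcpp::export]]
NumericMatrix bmntd_perm_engine(const NumericMatrix& D, const List& comm_idx,
                                const List& comm_w, const IntegerMatrix& pairs,
                                const IntegerMatrix& perms) {
  const int np = pairs.nrow(), nr = perms.nrow(), ns = comm_idx.size();
  NumericMatrix out(np, nr);
  std::vector<std::vector<int> > idx(ns);
  std::vector<std::vector<double> > w(ns);
  for (int s = 0; s < ns; ++s) {
    idx[s] = as<std::vector<int> >(comm_idx[s]);
    w[s] = as<std::vector<double> >(comm_w[s]);
  }
  const double* dp = REAL(D);
  const int K = D.nrow();
  std::vector<int> pr(K);
  for (int r = 0; r < nr; ++r) {
    for (int k = 0; k < K; ++k) pr[k] = perms(r, k);
    for (int p = 0; p < np; ++p) {
      const std::vector<int>& a = idx[pairs(p, 0)];
      const std::vector<int>& b = idx[pairs(p, 1)];
      const std::vector<double>& wa = w[pairs(p, 0)];
      const std::vector<double>& wb = w[pairs(p, 1)];
      const size_t na = a.size(), nb = b.size();
      double s1 = 0.0, s2 = 0.0;
      // one pass per direction; columns of D are contiguous in memory
      for (size_t i = 0; i < na; ++i) {
        const double* col = dp + (size_t)pr[a[i]] * K;
        double mn = std::numeric_limits<double>::infinity();
        for (size_t j = 0; j < nb; ++j) {
          const double d = col[pr[b[j]]];
          if (d < mn) mn = d;
        }
        s1 += wa[i] * mn;
      }
      for (size_t j = 0; j < nb; ++j) {
        const double* col = dp + (size_t)pr[b[j]] * K;
        double mn = std::numeric_limits<double>::infinity();
        for (size_t i = 0; i < na; ++i) {
          const double d = col[pr[a[i]]];
          if (d < mn) mn = d;
        }
        s2 += wb[j] * mn;
      }
      out(p, r) = 0.5 * (s1 + s2);
    }
  }
  return out;
}

// Within-sample MNTD under label permutations: for each sample, the
// (weighted) mean over present taxa of the distance to the nearest other
// present taxon. Returns n_samples x n_perm.
// [[Rcpp::export]]
NumericMatrix mntd_perm_engine(const NumericMatrix& D, const List& comm_idx,
                               const List& comm_w, const IntegerMatrix& perms) {
  const int ns = comm_idx.size(), nr = perms.nrow();
  NumericMatrix out(ns, nr);
  std::vector<std::vector<int> > idx(ns);
  std::vector<std::vector<double> > w(ns);
  for (int s = 0; s < ns; ++s) {
    idx[s] = as<std::vector<int> >(comm_idx[s]);
    w[s] = as<std::vector<double> >(comm_w[s]);
  }
  const double* dp = REAL(D);
  const int K = D.nrow();
  std::vector<int> pr(K);
  for (int r = 0; r < nr; ++r) {
    for (int k = 0; k < K; ++k) pr[k] = perms(r, k);
    for (int s = 0; s < ns; ++s) {
      const std::vector<int>& a = idx[s];
      const std::vector<double>& wa = w[s];
      const size_t na = a.size();
      if (na < 2) { out(s, r) = NA_REAL; continue; }
      double acc = 0.0;
      for (size_t i = 0; i < na; ++i) {
        const double* col = dp + (size_t)pr[a[i]] * K;
        double mn = std::numeric_limits<double>::infinity();
        for (size_t j = 0; j < na; ++j) {
          if (j == i) continue;
          const double d = col[pr[a[j]]];
          if (d < mn) mn = d;
        }
        acc += wa[i] * mn;
      }
      out(s, r) = acc;
    }
  }
  return out;
}
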