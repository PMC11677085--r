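#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance between all sample
// pairs. D is the taxon x taxon patristic distance matrix, W the taxon x
// sample weight matrix (relative abundances, or 1/richness for the
// unweighted variant; zero marks absence). perm optionally remaps taxon
// indices into D (1-based), which implements the tip-label shuffle null
// without copying D.
//
// bMNTD(k,m) = 0.5 * ( sum_i W(i,k) * min_{j in m} D(i,j)
//                    + sum_j W(j,m) * min_{i in k} D(j,i) )
// Conspecifics count: a taxon present in both samples has nearest distance 0.

// [[Rcpp::export(name = ".bmntd_kernel")]]
NumericMatrix bmntd_kernel(const NumericMatrix& D, const NumericMatrix& W,
                           Nullable<IntegerVector> perm = R_NilValue) {
  const int n_taxa = D.nrow();
  const int n_samp = W.ncol();
  if (W.nrow() != n_taxa) stop("dimension mismatch between D and W");

  std::vector<int> map(n_taxa);
  if (perm.isNotNull()) {
    IntegerVector p(perm);
    if (p.size() != n_taxa) stop("perm length mismatch");
    for (int i = 0; i < n_taxa; ++i) map[i] = p[i] - 1;
  } else {
    for (int i = 0; i < n_taxa; ++i) map[i] = i;
  }

  std::vector< std::vector<int> > present(n_samp);
  for (int s = 0; s < n_samp; ++s)
    for (int i = 0; i < n_taxa; ++i)
      if (W(i, s) > 0.0) present[s].push_back(i);

  // M(i, s): distance from taxon i to its nearest taxon in sample s
  NumericMatrix M(n_taxa, n_samp);
  for (int s = 0; s < n_samp; ++s) {
    const std::vector<int>& pr = present[s];
    for (int i = 0; i < n_taxa; ++i) {
      const int di = map[i];
      double mn = R_PosInf;
      for (size_t u = 0; u < pr.size(); ++u) {
        const double d = D(di, map[pr[u]]);
        if (d < mn) mn = d;
      }
      M(i, s) = mn;
    }
  }

  NumericMatrix half(n_samp, n_samp);
  for (int k = 0; k < n_samp; ++k) {
    const std::vector<int>& pr = present[k];
    for (int m = 0; m < n_samp; ++m) {
      double acc = 0.0;
      for (size_t u = 0; u < pr.size(); ++u) acc += W(pr[u], k) * M(pr[u], m);
      half(k, m) = acc;
    }
  }

  NumericMatrix out(n_samp, n_samp);
  for (int k = 0; k < n_samp; ++k)
    for (int m = 0; m < n_samp; ++m)
      out(k, m) = 0.5 * (half(k, m) + half(m, k));
  return out;
}
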