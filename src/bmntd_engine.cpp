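#include <Rcpp.h>
using namespace Rcpp;

// beta-MNTD for one sample pair under one taxon relabelling.
// D: full patristic matrix over the taxon universe (0-based indices).
// pa/pb: indices of taxa present in the two samples; wa/wb their weights
// (within-sample relative abundances, or 1/richness when unweighted).
// perm: taxon relabelling (perm[i] is the tip whose distances taxon i takes).
static double bmntd_one(const NumericMatrix& D,
                        const IntegerVector& pa, const NumericVector& wa,
                        const IntegerVector& pb, const NumericVector& wb,
                        const IntegerVector& perm) {
  const int na = pa.size(), nb = pb.size();
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    const int ti = perm[pa[i]];
    double mn = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double d = D(ti, perm[pb[j]]);
      if (d < mn) mn = d;
    }
    acc += wa[i] * mn;
  }
  for (int j = 0; j < nb; ++j) {
    const int tj = perm[pb[j]];
    double mn = R_PosInf;
    for (int i = 0; i < na; ++i) {
      const double d = D(tj, perm[pa[i]]);
      if (d < mn) mn = d;
    }
    acc += wb[j] * mn;
  }
  return 0.5 * acc;
}

// Observed and null beta-MNTD for a set of sample pairs.
// perms is n_taxa x n_null, 0-based; each column one global tip shuffle
// shared by every pair.  Returns a list with `obs` (length n_pairs) and
// `null` (n_pairs x n_null).
// [[Rcpp::export(name = ".bmntd_engine")]]
List bmntd_engine(NumericMatrix D, List pres, List wts,
                  IntegerMatrix pairs, IntegerMatrix perms) {
  const int n_pairs = pairs.nrow();
  const int n_null = perms.ncol();
  const int n_taxa = D.nrow();

  std::vector<IntegerVector> P(pres.size());
  std::vector<NumericVector> W(wts.size());
  for (int s = 0; s < pres.size(); ++s) {
    P[s] = as<IntegerVector>(pres[s]);
    W[s] = as<NumericVector>(wts[s]);
  }

  IntegerVector ident(n_taxa);
  for (int i = 0; i < n_taxa; ++i) ident[i] = i;

  NumericVector obs(n_pairs);
  NumericMatrix nul(n_pairs, n_null);
  for (int p = 0; p < n_pairs; ++p) {
    const int a = pairs(p, 0), b = pairs(p, 1);
    obs[p] = bmntd_one(D, P[a], W[a], P[b], W[b], ident);
  }
  for (int r = 0; r < n_null; ++r) {
    IntegerVector perm = perms(_, r);
    for (int p = 0; p < n_pairs; ++p) {
      const int a = pairs(p, 0), b = pairs(p, 1);
      nul(p, r) = bmntd_one(D, P[a], W[a], P[b], W[b], perm);
    }
  }
  return List::create(_["obs"] = obs, _["null"] = nul);
}
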