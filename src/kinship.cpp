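#include <Rcpp.h>
using namespace Rcpp;

// Tabular-method numerator relationship matrix.  sire/dam are 1-based
// indices into a topologically sorted pedigree, 0 = unknown parent.
// [[Rcpp::export(name = ".tabular_A")]]
NumericMatrix tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  if (n > 12000) stop("pedigree too large for dense tabular A (n > 12000)");
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree is not topologically sorted at row %d", i + 1);
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = A(j, i) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// Inbreeding coefficients by the ancestor-tracing recursion
// (Meuwissen & Luo style): a_ii = sum_j L_j^2 D_j over ancestors j,
// F_i = a_ii - 1, with D_j the Mendelian-sampling variance of j given its
// parents' inbreeding.
// [[Rcpp::export(name = ".inbreeding_recursive")]]
NumericVector inbreeding_recursive(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i)
      stop("pedigree is not topologically sorted at row %d", i + 1);
    if (s >= 0 && d >= 0)
      D[i] = 0.5 - 0.25 * (F[s] + F[d]);
    else if (s >= 0)
      D[i] = 0.75 - 0.25 * F[s];
    else if (d >= 0)
      D[i] = 0.75 - 0.25 * F[d];
    else
      D[i] = 1.0;
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    double aii = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      aii += L[j] * L[j] * D[j];
      int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) L[sj] += 0.5 * L[j];
      if (dj >= 0) L[dj] += 0.5 * L[j];
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Gene dropping: offspring gametes from parental haplotype pairs with
// per-interval recombination.  hap is (2*n_parents) x m (0/1), rows 2k,2k+1
// belong to parent k (0-based).  rf[j] is the recombination fraction
// between markers j and j+1 (rf = 0.5 at chromosome boundaries).
// parent[i] gives the 0-based parent index of gamete i.
// [[Rcpp::export(name = ".drop_gametes")]]
IntegerMatrix drop_gametes(IntegerMatrix hap, IntegerVector parent,
                           NumericVector rf) {
  int m = hap.ncol(), ng = parent.size();
  if (rf.size() != m - 1) stop("rf must have m - 1 entries");
  IntegerMatrix out(ng, m);
  for (int g = 0; g < ng; ++g) {
    int p = parent[g];
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    for (int j = 0; j < m; ++j) {
      out(g, j) = hap(2 * p + cur, j);
      if (j < m - 1 && unif_rand() < rf[j]) cur = 1 - cur;
    }
  }
  return out;
}
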