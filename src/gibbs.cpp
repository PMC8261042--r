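// Gibbs sampler for the multi-trait (breed-as-trait) single-step animal
// model.  Fixed-effect and permanent-environment equations are sampled
// single-site; each animal's T-vector of additive effects is sampled
// jointly from its multivariate-normal full conditional (one pass over the
// animal's H-inverse column), which mixes the genetic covariance far
// better than scalar updates.  The genetic covariance matrix is drawn from
// its inverse-Wishart full conditional, permanent-environment and residual
// variances from scaled inverse chi-square full conditionals.  All
// randomness comes from R's RNG so set.seed() governs the chain.
//
// Equation layout (0-based): fixed effects [0, n_fix); additive effects
// animal-major, eq = n_fix + a*T + t; then permanent-environment levels.
// The data cross-product C0 = W'W is unweighted; each equation belongs to
// exactly one trait (block-diagonal multi-trait design), so its data part
// is rescaled by the current 1/sigma2_e(trait) on the fly.  Records hit a
// single animal, so C0 carries no animal-animal or cross-trait terms
// within the additive block.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#define TMAX 8

static arma::mat inv_wishart_draw(const arma::mat &S, double df, int &jitters) {
  // Sigma ~ IW(df, S): draw W ~ Wishart(df, S^-1) by Bartlett, invert.
  int t = S.n_rows;
  arma::mat Ssum = S;
  for (int attempt = 0; attempt < 50; ++attempt) {
    arma::mat Sinv, Linv, draw;
    bool ok = arma::inv_sympd(Sinv, Ssum) && arma::chol(Linv, Sinv, "lower");
    if (ok) {
      arma::mat A(t, t, arma::fill::zeros);
      for (int i = 0; i < t; ++i) {
        A(i, i) = std::sqrt(R::rchisq(df - i));
        for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
      }
      arma::mat LA = Linv * A;
      arma::mat W = LA * LA.t();
      if (arma::inv_sympd(draw, W)) return draw;
    }
    Ssum.diag() += 1e-8 * arma::trace(Ssum) / t + 1e-12;
    ++jitters;
  }
  stop("inverse-Wishart draw failed repeatedly (scale not SPD)");
}

// Cholesky (lower) of P (T x T), then draw x ~ N(P^-1 r, P^-1) in place.
static inline void mvn_precision_draw(double *P, double *r, double *out,
                                      int T) {
  double L[TMAX * TMAX];
  for (int j = 0; j < T; ++j) {
    double d = P[j * T + j];
    for (int k = 0; k < j; ++k) d -= L[j * T + k] * L[j * T + k];
    if (d <= 0) stop("non-positive-definite conditional precision");
    L[j * T + j] = std::sqrt(d);
    for (int i = j + 1; i < T; ++i) {
      double v = P[i * T + j];
      for (int k = 0; k < j; ++k) v -= L[i * T + k] * L[j * T + k];
      L[i * T + j] = v / L[j * T + j];
    }
  }
  double w[TMAX];
  for (int i = 0; i < T; ++i) { // forward solve L w = r
    double v = r[i];
    for (int k = 0; k < i; ++k) v -= L[i * T + k] * w[k];
    w[i] = v / L[i * T + i];
  }
  for (int i = 0; i < T; ++i) w[i] += norm_rand();
  for (int i = T - 1; i >= 0; --i) { // back solve L' x = w + z
    double v = w[i];
    for (int k = i + 1; k < T; ++k) v -= L[k * T + i] * out[k];
    out[i] = v / L[i * T + i];
  }
}

// [[Rcpp::export(name = ".gibbs_mme")]]
List gibbs_mme(S4 C0, NumericVector rhs0, S4 W, NumericVector y,
               IntegerVector rec_trait, S4 Hinv, int n_fix, int T,
               int n_anim, IntegerVector eq_trait, IntegerVector eq_type,
               NumericMatrix S0, double nu0, NumericVector nu_e,
               NumericVector s2e0, NumericVector nu_p, NumericVector s2p0,
               int n_cycles, int burnin, int thin, NumericMatrix Sigma_start,
               NumericVector s2e_start, NumericVector s2p_start) {
  if (T > TMAX) stop("at most %d traits supported", TMAX);
  const IntegerVector Cp = C0.slot("p"), Ci = C0.slot("i");
  const NumericVector Cx = C0.slot("x");
  const IntegerVector Wp = W.slot("p"), Wi = W.slot("i");
  const NumericVector Wx = W.slot("x");
  const IntegerVector Hp = Hinv.slot("p"), Hi = Hinv.slot("i");
  const NumericVector Hx = Hinv.slot("x");
  const int neq = rhs0.size(), nrec = y.size();

  arma::mat Sigma = as<arma::mat>(Sigma_start);
  arma::vec s2e = as<arma::vec>(s2e_start);
  arma::vec s2p = as<arma::vec>(s2p_start);
  std::vector<double> x(neq, 0.0);

  arma::ivec nrec_t(T, arma::fill::zeros);
  for (int r = 0; r < nrec; ++r) nrec_t[rec_trait[r]]++;
  std::vector<std::vector<int> > pe_eqs(T);
  for (int i = 0; i < neq; ++i)
    if (eq_type[i] == 2) pe_eqs[eq_trait[i]].push_back(i);

  int n_store = (n_cycles - burnin) / thin;
  int npar_sig = T * (T + 1) / 2;
  arma::mat store(n_store, npar_sig + T + T, arma::fill::zeros);
  arma::vec xmean(neq, arma::fill::zeros);
  arma::mat B(n_anim, T); // workspace for Hinv * U
  int stored = 0, jitters = 0;
  double sig[TMAX * TMAX], se_inv[TMAX], P[TMAX * TMAX], r[TMAX], ua[TMAX];

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    arma::mat Sigma_inv = arma::inv_sympd(Sigma);
    for (int a = 0; a < T; ++a)
      for (int b = 0; b < T; ++b) sig[a * T + b] = Sigma_inv(a, b);
    for (int t = 0; t < T; ++t) se_inv[t] = 1.0 / s2e[t];

    // --- fixed-effect equations (single site) ---
    for (int i = 0; i < n_fix; ++i) {
      double w = se_inv[eq_trait[i]];
      double num = rhs0[i] * w, diag = 0.0;
      for (int k = Cp[i]; k < Cp[i + 1]; ++k) {
        int j = Ci[k];
        double v = Cx[k] * w;
        if (j == i) diag += v; else num -= v * x[j];
      }
      x[i] = num / diag + norm_rand() / std::sqrt(diag);
    }

    // --- additive effects, one joint T-draw per animal ---
    for (int a = 0; a < T * TMAX; ++a) P[a] = 0.0;
    for (int a = 0; a < n_anim; ++a) {
      double haa = 0.0;
      for (int t = 0; t < T; ++t) {
        int i = n_fix + a * T + t;
        double w = se_inv[t];
        double num = rhs0[i] * w, dd = 0.0;
        for (int k = Cp[i]; k < Cp[i + 1]; ++k) {
          int j = Ci[k];
          if (j == i) dd += Cx[k] * w; else num -= Cx[k] * w * x[j];
        }
        r[t] = num;
        for (int s = 0; s < T; ++s) P[t * T + s] = 0.0;
        P[t * T + t] = dd;
      }
      const double *xadd = &x[n_fix];
      for (int k = Hp[a]; k < Hp[a + 1]; ++k) {
        int b = Hi[k];
        double h = Hx[k];
        if (b == a) { haa = h; continue; }
        const double *xb = xadd + b * T;
        for (int t = 0; t < T; ++t) {
          double acc = 0.0;
          for (int s = 0; s < T; ++s) acc += sig[t * T + s] * xb[s];
          r[t] -= h * acc;
        }
      }
      for (int t = 0; t < T; ++t)
        for (int s = 0; s < T; ++s) P[t * T + s] += haa * sig[t * T + s];
      mvn_precision_draw(P, r, ua, T);
      for (int t = 0; t < T; ++t) x[n_fix + a * T + t] = ua[t];
    }

    // --- permanent-environment equations (single site) ---
    for (int t = 0; t < T; ++t) {
      double pinv = (s2p[t] > 0) ? 1.0 / s2p[t] : 0.0;
      for (size_t q = 0; q < pe_eqs[t].size(); ++q) {
        int i = pe_eqs[t][q];
        double w = se_inv[t];
        double num = rhs0[i] * w, diag = pinv;
        for (int k = Cp[i]; k < Cp[i + 1]; ++k) {
          int j = Ci[k];
          double v = Cx[k] * w;
          if (j == i) diag += v; else num -= v * x[j];
        }
        x[i] = num / diag + norm_rand() / std::sqrt(diag);
      }
    }

    // --- genetic covariance: IW(nu0 + n_anim, S0 + U' Hinv U) ---
    for (int a = 0; a < n_anim; ++a) {
      double acc[TMAX];
      for (int t = 0; t < T; ++t) acc[t] = 0.0;
      for (int k = Hp[a]; k < Hp[a + 1]; ++k) {
        int b = Hi[k];
        double h = Hx[k];
        const double *xb = &x[n_fix + b * T];
        for (int t = 0; t < T; ++t) acc[t] += h * xb[t];
      }
      for (int t = 0; t < T; ++t) B(a, t) = acc[t];
    }
    arma::mat Su(T, T, arma::fill::zeros);
    for (int a = 0; a < n_anim; ++a) {
      const double *xa = &x[n_fix + a * T];
      for (int t = 0; t < T; ++t)
        for (int s = 0; s <= t; ++s) Su(t, s) += xa[t] * B(a, s);
    }
    Su = arma::symmatl(Su);
    Su = 0.5 * (Su + Su.t()) + as<arma::mat>(S0);
    Sigma = inv_wishart_draw(Su, nu0 + n_anim, jitters);

    // --- residual variances ---
    std::vector<double> e(y.begin(), y.end());
    for (int j = 0; j < neq; ++j) {
      double xj = x[j];
      if (xj == 0.0) continue;
      for (int k = Wp[j]; k < Wp[j + 1]; ++k) e[Wi[k]] -= Wx[k] * xj;
    }
    arma::vec sse(T, arma::fill::zeros);
    for (int rr = 0; rr < nrec; ++rr) sse[rec_trait[rr]] += e[rr] * e[rr];
    for (int t = 0; t < T; ++t)
      s2e[t] = (nu_e[t] * s2e0[t] + sse[t]) / R::rchisq(nu_e[t] + nrec_t[t]);

    // --- permanent-environment variances ---
    for (int t = 0; t < T; ++t) {
      size_t np = pe_eqs[t].size();
      if (np == 0) continue;
      double ssp = 0.0;
      for (size_t k = 0; k < np; ++k) {
        double v = x[pe_eqs[t][k]];
        ssp += v * v;
      }
      s2p[t] = (nu_p[t] * s2p0[t] + ssp) / R::rchisq(nu_p[t] + (double)np);
    }

    if (cyc > burnin && (cyc - burnin) % thin == 0 && stored < n_store) {
      int c = 0;
      for (int j = 0; j < T; ++j)
        for (int i = 0; i <= j; ++i) store(stored, c++) = Sigma(i, j);
      for (int t = 0; t < T; ++t) store(stored, c++) = s2p[t];
      for (int t = 0; t < T; ++t) store(stored, c++) = s2e[t];
      for (int i = 0; i < neq; ++i) xmean[i] += x[i];
      ++stored;
    }
  }
  if (stored > 0) xmean /= stored;
  return List::create(_["draws"] = store, _["x_mean"] = xmean,
                      _["jitters"] = jitters, _["n_stored"] = stored);
}
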