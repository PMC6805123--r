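#include <Rcpp.h>
using namespace Rcpp;

// Integrated N-mixture likelihood machinery.
//
// A cell's likelihood is sum_{N=0}^{Nmax} NegBin(N | lambda_j, phi) *
// prod_{i in cell} Poisson(y_i | N * gamma_i * d_i). Because the Poisson
// log-terms are linear in (y_i, gamma_i d_i), the product over sites collapses
// to three per-cell sufficient statistics:
//   ysum_j = sum y_i,   gdsum_j = sum gamma_i d_i,
//   csum_j = sum [ y_i log(gamma_i d_i) - lgamma(y_i + 1) ]
// so each N costs O(1) regardless of the number of cameras in the cell.
// Everything is computed in log space with a log-sum-exp reduction.

// log pmf of NegBin with mean `lam`, dispersion `phi` (variance lam + lam^2/phi)
// [[Rcpp::export]]
NumericVector negbin_logpmf_cpp(IntegerVector N, double lam, double phi) {
  if (lam <= 0 || phi <= 0) stop("lam and phi must be positive");
  int n = N.size();
  NumericVector out(n);
  double lp = std::log(phi) - std::log(phi + lam);   // log(phi/(phi+lam))
  double lq = std::log(lam) - std::log(phi + lam);   // log(lam/(phi+lam))
  for (int k = 0; k < n; k++) {
    int Nk = N[k];
    if (Nk < 0) { out[k] = R_NegInf; continue; }
    out[k] = R::lgammafn(Nk + phi) - R::lgammafn(phi) - R::lgammafn(Nk + 1.0)
           + phi * lp + Nk * lq;
  }
  return out;
}

// Per-cell integrated log-likelihood from cell-level sufficient statistics.
// Cells without cameras (nsites == 0) contribute exactly 0.
static NumericVector cells_loglik(const NumericVector& loglam, double phi, int Nmax,
                                  const NumericVector& ysum, const NumericVector& gdsum,
                                  const NumericVector& csum, const IntegerVector& nsites) {
  int G = loglam.size();
  NumericVector out(G);
  // dispersion-only part of the NegBin log pmf, shared across cells
  std::vector<double> lgtab(Nmax + 1), logN(Nmax + 1);
  for (int N = 0; N <= Nmax; N++) {
    lgtab[N] = R::lgammafn(N + phi) - R::lgammafn(phi) - R::lgammafn(N + 1.0);
    logN[N] = (N > 0) ? std::log((double) N) : R_NegInf;
  }
  for (int j = 0; j < G; j++) {
    if (nsites[j] == 0) { out[j] = 0.0; continue; }
    double lam = std::exp(loglam[j]);
    double lp = std::log(phi) - std::log(phi + lam);
    double lq = loglam[j] - std::log(phi + lam);
    // online log-sum-exp; the summand is log-concave in N, so once terms are
    // falling and sit far below the running max the tail is negligible
    double m = R_NegInf, s = 0.0, prev = R_PosInf;
    if (ysum[j] <= 0.0) {  // N = 0 is admissible only when every count is zero
      m = lgtab[0] + phi * lp + csum[j];
      s = 1.0;
      prev = m;
    }
    for (int N = 1; N <= Nmax; N++) {
      double t = lgtab[N] + phi * lp + N * lq
               + ysum[j] * logN[N] - N * gdsum[j] + csum[j];
      if (t > m) {
        s = s * std::exp(m - t) + 1.0;
        m = t;
      } else {
        s += std::exp(t - m);
        if (t < prev && t < m - 45.0) break;
      }
      prev = t;
    }
    out[j] = m + std::log(s);
  }
  return out;
}

// Integrated log-likelihood per cell from site-level data.
// site_cell0: 0-based cell index of each site; gd = gamma_i * d_i.
// [[Rcpp::export]]
NumericVector nmix_loglik_cells_cpp(NumericVector loglam, double phi, int Nmax,
                                    NumericVector y, NumericVector gd,
                                    IntegerVector site_cell0) {
  int G = loglam.size(), S = y.size();
  if (gd.size() != S || site_cell0.size() != S) stop("site vectors differ in length");
  NumericVector ysum(G), gdsum(G), csum(G);
  IntegerVector nsites(G);
  for (int i = 0; i < S; i++) {
    int j = site_cell0[i];
    if (j < 0 || j >= G) stop("site refers to a cell outside the grid");
    if (y[i] < 0) stop("negative count");
    ysum[j] += y[i];
    gdsum[j] += gd[i];
    csum[j] += y[i] * std::log(gd[i]) - R::lgammafn(y[i] + 1.0);
    nsites[j] += 1;
  }
  return cells_loglik(loglam, phi, Nmax, ysum, gdsum, csum, nsites);
}

// Total integrated log-likelihood (sum over cells).
// [[Rcpp::export]]
double nmix_loglik_cpp(NumericVector loglam, double phi, int Nmax,
                       NumericVector y, NumericVector gd,
                       IntegerVector site_cell0) {
  NumericVector cl = nmix_loglik_cells_cpp(loglam, phi, Nmax, y, gd, site_cell0);
  double s = 0.0;
  for (double v : cl) s += v;
  return s;
}

// One full sweep of component-wise random-walk Metropolis updates of the site
// errors eps_i. Only the site's own cell likelihood changes, so each update
// recomputes a single cell. Uses R's RNG (seed-reproducible from R).
// lin = X_gamma %*% beta_gamma (site linear predictor without eps);
// logd = log effort; cell_ptr/cell_site: CSR layout of sites grouped by cell.
// [[Rcpp::export]]
List eps_sweep_cpp(NumericVector eps, NumericVector step_sd,
                   NumericVector y, NumericVector ylg, NumericVector lin,
                   NumericVector logd, IntegerVector site_cell0,
                   IntegerVector cell_ptr, IntegerVector cell_site,
                   NumericVector loglam, double phi, double sigma, int Nmax) {
  RNGScope scope;
  int S = eps.size();
  NumericVector eps_new = clone(eps);
  IntegerVector accepted(S);
  int G = loglam.size();
  std::vector<double> lgtab(Nmax + 1), logN(Nmax + 1);
  for (int N = 0; N <= Nmax; N++) {
    lgtab[N] = R::lgammafn(N + phi) - R::lgammafn(phi) - R::lgammafn(N + 1.0);
    logN[N] = (N > 0) ? std::log((double) N) : R_NegInf;
  }
  double inv2s2 = (sigma > 0) ? 1.0 / (2.0 * sigma * sigma) : R_PosInf;

  // cell log-likelihood with current eps_new, one cell at a time
  auto cell_ll = [&](int j) {
    double ysum = 0, gdsum = 0, csum = 0;
    for (int p = cell_ptr[j]; p < cell_ptr[j + 1]; p++) {
      int i = cell_site[p];
      double lgd = lin[i] + eps_new[i] + logd[i];
      ysum += y[i];
      gdsum += std::exp(lgd);
      csum += y[i] * lgd - ylg[i];
    }
    double lam = std::exp(loglam[j]);
    double lp = std::log(phi) - std::log(phi + lam);
    double lq = loglam[j] - std::log(phi + lam);
    double m = R_NegInf, s = 0.0, prev = R_PosInf;
    if (ysum <= 0.0) { m = lgtab[0] + phi * lp + csum; s = 1.0; prev = m; }
    for (int N = 1; N <= Nmax; N++) {
      double t = lgtab[N] + phi * lp + N * lq + ysum * logN[N] - N * gdsum + csum;
      if (t > m) { s = s * std::exp(m - t) + 1.0; m = t; }
      else { s += std::exp(t - m); if (t < prev && t < m - 45.0) break; }
      prev = t;
    }
    return m + std::log(s);
  };

  std::vector<double> cur_ll(G, NA_REAL);
  for (int i = 0; i < S; i++) {
    int j = site_cell0[i];
    if (!R_FINITE(cur_ll[j]) || ISNA(cur_ll[j])) cur_ll[j] = cell_ll(j);
    double old_e = eps_new[i];
    double cur = cur_ll[j];
    double prop = old_e + step_sd[i] * norm_rand();
    eps_new[i] = prop;
    double new_ll = cell_ll(j);
    double lr = new_ll - cur - (prop * prop - old_e * old_e) * inv2s2;
    if (std::log(unif_rand()) < lr) {
      accepted[i] = 1;
      cur_ll[j] = new_ll;
    } else {
      eps_new[i] = old_e;
    }
  }
  return List::create(_["eps"] = eps_new, _["accepted"] = accepted);
}
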