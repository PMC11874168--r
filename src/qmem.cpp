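#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// check (pinball) loss rho_tau(u) = u * (tau - 1[u < 0])
static inline double rho_tau(double u, double tau) {
  return u * (tau - (u < 0.0 ? 1.0 : 0.0));
}

// log(Phi(hi) - Phi(lo)) for hi >= lo, computed in whichever tail is stable
static double log_phi_diff(double hi, double lo) {
  if (hi <= lo) return R_NegInf;
  if (hi + lo < 0.0) {
    double lh = ::Rf_pnorm5(hi, 0.0, 1.0, 1, 1);
    double ll = ::Rf_pnorm5(lo, 0.0, 1.0, 1, 1);
    double d = ll - lh;
    return lh + (d < -36.0 ? 0.0 : log1p(-std::exp(d)));
  }
  double lh = ::Rf_pnorm5(lo, 0.0, 1.0, 0, 1); // upper tail of lo
  double ll = ::Rf_pnorm5(hi, 0.0, 1.0, 0, 1);
  double d = ll - lh;
  return lh + (d < -36.0 ? 0.0 : log1p(-std::exp(d)));
}

// Exact log of int prod_i ALD(r_i - b; sigma, tau) * N(b; 0, sb^2) db for
// one cluster. The summed check loss is piecewise linear in b with kinks
// at the sorted residuals, so each piece integrates in closed form:
//   int_L^U exp(A + S b) phi(b; 0, sb) db
//     = exp(A + S^2 sb^2 / 2) * [Phi((U - S sb^2)/sb) - Phi((L - S sb^2)/sb)]
static double cluster_exact(std::vector<double>& r, double sigma,
                            double sb, double tau) {
  const int nj = (int)r.size();
  std::sort(r.begin(), r.end());
  double T = 0.0;
  for (int i = 0; i < nj; ++i) T += r[i];

  double mx = R_NegInf;
  std::vector<double> logI(nj + 1);
  double P = 0.0; // prefix sum of sorted residuals below the piece
  for (int k = 0; k <= nj; ++k) {
    if (k > 0) P += r[k - 1];
    double A = (-tau * (T - P) + (1.0 - tau) * P) / sigma;
    double S = (tau * (nj - k) - k * (1.0 - tau)) / sigma;
    double shift = S * sb; // = S*sb^2 / sb, argument shift in z units
    double zlo = (k == 0) ? R_NegInf : r[k - 1] / sb - shift;
    double zhi = (k == nj) ? R_PosInf : r[k] / sb - shift;
    logI[k] = A + 0.5 * S * S * sb * sb + log_phi_diff(zhi, zlo);
    if (logI[k] > mx) mx = logI[k];
  }
  double s = 0.0;
  for (int k = 0; k <= nj; ++k) s += std::exp(logI[k] - mx);
  return mx + std::log(s) + nj * std::log(tau * (1.0 - tau) / sigma);
}

// Unnormalized log integrand for one cluster (adaptive-quadrature route)
static double h_cluster(double b, const double* r, int nj, double sigma,
                        double tau, double sigma_b, double log_ald_const,
                        double log_prior_const) {
  double s = nj * log_ald_const;
  for (int i = 0; i < nj; ++i) {
    s -= rho_tau((r[i] - b) / sigma, tau);
  }
  s += log_prior_const - 0.5 * (b * b) / (sigma_b * sigma_b);
  return s;
}

// d h / d b (defined a.e.; step-decreasing in b, so the root is unique)
static double dh_cluster(double b, const double* r, int nj, double sigma,
                         double tau, double sigma_b) {
  double s = 0.0;
  for (int i = 0; i < nj; ++i) {
    s += (r[i] - b < 0.0) ? (tau - 1.0) : tau;
  }
  return s / sigma - b / (sigma_b * sigma_b);
}

static double cluster_agh(const double* rj, int nj, double sigma, double sb,
                          double tau, const NumericVector& gh_nodes,
                          const NumericVector& gh_log_weights) {
  const int Q = gh_nodes.size();
  const double log_ald_const = std::log(tau * (1.0 - tau) / sigma);
  const double log_prior_const =
      -0.5 * std::log(2.0 * M_PI) - std::log(sb);

  // bracket + bisect the unique mode of the concave integrand
  double lo = 0.0, hi = 0.0;
  for (int i = 0; i < nj; ++i) {
    if (rj[i] < lo) lo = rj[i];
    if (rj[i] > hi) hi = rj[i];
  }
  lo -= sigma + sb;
  hi += sigma + sb;
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (dh_cluster(mid, rj, nj, sigma, tau, sb) > 0.0) lo = mid;
    else hi = mid;
  }
  double mode = 0.5 * (lo + hi);

  // curvature by finite difference, floored at the prior curvature
  double delta = sb / 8.0;
  double h0 = h_cluster(mode, rj, nj, sigma, tau, sb, log_ald_const,
                        log_prior_const);
  double hp = h_cluster(mode + delta, rj, nj, sigma, tau, sb, log_ald_const,
                        log_prior_const);
  double hm = h_cluster(mode - delta, rj, nj, sigma, tau, sb, log_ald_const,
                        log_prior_const);
  double curv = -(hp + hm - 2.0 * h0) / (delta * delta);
  double floor_curv = 1.0 / (sb * sb);
  if (!(curv > floor_curv)) curv = floor_curv;
  double scale = 1.0 / std::sqrt(curv);

  // adaptive GH: integral ~ sqrt(2) s sum_q w_q e^{x_q^2} f(mode + sqrt2 s x_q)
  double mx = R_NegInf;
  const double sq2s = M_SQRT2 * scale;
  std::vector<double> logterm(Q);
  for (int q = 0; q < Q; ++q) {
    double x = gh_nodes[q];
    logterm[q] = gh_log_weights[q] + x * x +
        h_cluster(mode + sq2s * x, rj, nj, sigma, tau, sb, log_ald_const,
                  log_prior_const);
    if (logterm[q] > mx) mx = logterm[q];
  }
  double s = 0.0;
  for (int q = 0; q < Q; ++q) s += std::exp(logterm[q] - mx);
  return mx + std::log(s) + std::log(sq2s);
}

// Marginal log-likelihood of the linear quantile mixed model with a
// Gaussian cluster random intercept. method 0 = exact piecewise closed
// form (default engine route), 1 = adaptive Gauss-Hermite quadrature.
// Observations must be sorted by cluster; cl_start is 0-based.
// [[Rcpp::export]]
double qmem_marginal_loglik_cpp(NumericVector r, IntegerVector cl_start,
                                IntegerVector cl_len, double sigma,
                                double sigma_b, double tau, int method,
                                NumericVector gh_nodes,
                                NumericVector gh_log_weights) {
  const int J = cl_start.size();
  double total = 0.0;

  if (sigma_b < 1e-12) { // degenerate mixing: independent ALD terms
    const double log_ald_const = std::log(tau * (1.0 - tau) / sigma);
    for (int i = 0; i < r.size(); ++i) {
      total += log_ald_const - rho_tau(r[i] / sigma, tau);
    }
    return total;
  }

  for (int j = 0; j < J; ++j) {
    if (method == 0) {
      std::vector<double> rj(&r[cl_start[j]], &r[cl_start[j]] + cl_len[j]);
      total += cluster_exact(rj, sigma, sigma_b, tau);
    } else {
      total += cluster_agh(&r[cl_start[j]], cl_len[j], sigma, sigma_b, tau,
                           gh_nodes, gh_log_weights);
    }
  }
  return total;
}
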