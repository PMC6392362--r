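#include <Rcpp.h>
using namespace Rcpp;

// Two-state (unavailable/available) forward pass along the stops of one
// route-year, conditional on the route being occupied and on one detection
// class.  Missing stops (NA) contribute emission 1 while the availability
// chain still advances; trailing NAs therefore marginalize out exactly.
static double stop_forward_core(const int* y, int S,
                                double th0, double th, double thp,
                                const double* p) {
  double fu, fa; // joint prob of observations so far and {unavail, avail}
  {
    double eu = 1.0, ea = 1.0;
    if (y[0] != NA_INTEGER) {
      eu = (y[0] == 1) ? 0.0 : 1.0;
      ea = (y[0] == 1) ? p[0] : 1.0 - p[0];
    }
    fu = (1.0 - th0) * eu;
    fa = th0 * ea;
  }
  for (int s = 1; s < S; s++) {
    double eu = 1.0, ea = 1.0;
    if (y[s] != NA_INTEGER) {
      eu = (y[s] == 1) ? 0.0 : 1.0;
      ea = (y[s] == 1) ? p[s] : 1.0 - p[s];
    }
    double nu = (fu * (1.0 - th) + fa * (1.0 - thp)) * eu;
    double na = (fu * th + fa * thp) * ea;
    fu = nu;
    fa = na;
  }
  return fu + fa;
}

// Emission for one year given occupancy state z and one detection class.
static double year_emission_core(const int* y, int S, int z,
                                 double th0, double th, double thp,
                                 const double* p) {
  if (z == 0) {
    for (int s = 0; s < S; s++)
      if (y[s] == 1) return 0.0;
    return 1.0;
  }
  return stop_forward_core(y, S, th0, th, thp, p);
}

// Likelihood of one route's full history for one detection class:
// two-state forward over years (unoccupied/occupied).
static double route_class_lik(const int* y, int S, int T,
                              double psi, double th0, double th, double thp,
                              const double* gamma, const double* eps,
                              const double* p) {
  double e0 = year_emission_core(y, S, 0, th0, th, thp, p);
  double e1 = year_emission_core(y, S, 1, th0, th, thp, p);
  double f0 = (1.0 - psi) * e0;
  double f1 = psi * e1;
  for (int t = 1; t < T; t++) {
    const int* yt = y + (size_t)t * S;
    const double* pt = p + (size_t)t * S;
    e0 = year_emission_core(yt, S, 0, th0, th, thp, pt);
    e1 = year_emission_core(yt, S, 1, th0, th, thp, pt);
    double g = gamma[t - 1], e = eps[t - 1];
    double n0 = (f0 * (1.0 - g) + f1 * e) * e0;
    double n1 = (f0 * g + f1 * (1.0 - e)) * e1;
    f0 = n0;
    f1 = n1;
  }
  return f0 + f1;
}

// [[Rcpp::export]]
double cpp_stop_forward(IntegerVector y, double theta0, double theta,
                        double theta_prime, NumericVector p) {
  return stop_forward_core(y.begin(), y.size(), theta0, theta, theta_prime,
                           p.begin());
}

// [[Rcpp::export]]
double cpp_route_likelihood(IntegerMatrix obs,
                            double psi, double theta0, double theta,
                            double theta_prime,
                            NumericVector gamma, NumericVector eps,
                            NumericMatrix p1, NumericMatrix p2,
                            double pi_mix) {
  int S = obs.nrow(), T = obs.ncol();
  double l1 = route_class_lik(obs.begin(), S, T, psi, theta0, theta,
                              theta_prime, gamma.begin(), eps.begin(),
                              p1.begin());
  double l2 = route_class_lik(obs.begin(), S, T, psi, theta0, theta,
                              theta_prime, gamma.begin(), eps.begin(),
                              p2.begin());
  return pi_mix * l1 + (1.0 - pi_mix) * l2;
}

// Dataset-level -2 log likelihood.  obs is an S x T x R integer array,
// p1/p2 are S x T matrices shared by all routes (detection structure is
// year + stop only), psi/theta/theta_prime are per-route, gamma/eps are
// R x (T-1) matrices.  Returns +Inf if any route has likelihood <= 0.
// [[Rcpp::export]]
double cpp_dataset_neg2ll(IntegerVector obs, int S, int T, int R,
                          NumericVector psi, NumericVector theta0,
                          NumericVector theta, NumericVector theta_prime,
                          NumericMatrix gamma,
                          NumericMatrix eps,
                          NumericMatrix p1, NumericMatrix p2,
                          double pi_mix) {
  double acc = 0.0;
  std::vector<double> g(T > 1 ? T - 1 : 0), e(T > 1 ? T - 1 : 0);
  for (int r = 0; r < R; r++) {
    const int* yr = obs.begin() + (size_t)r * S * T;
    for (int t = 0; t + 1 < T; t++) {
      g[t] = gamma(r, t);
      e[t] = eps(r, t);
    }
    double l1 = route_class_lik(yr, S, T, psi[r], theta0[r], theta[r],
                                theta_prime[r], g.data(), e.data(),
                                p1.begin());
    double l2 = route_class_lik(yr, S, T, psi[r], theta0[r], theta[r],
                                theta_prime[r], g.data(), e.data(),
                                p2.begin());
    double l = pi_mix * l1 + (1.0 - pi_mix) * l2;
    if (!(l > 0.0)) return R_PosInf;
    acc += std::log(l);
  }
  return -2.0 * acc;
}

// Per-year emission probabilities for one route and one detection class:
// returns a T x 2 matrix with columns Pr(y_t | z=0), Pr(y_t | z=1).
// Used by the goodness-of-fit forward filter.
// [[Rcpp::export]]
NumericMatrix cpp_year_emissions(IntegerMatrix obs,
                                 double theta0, double theta,
                                 double theta_prime,
                                 NumericMatrix p) {
  int S = obs.nrow(), T = obs.ncol();
  NumericMatrix out(T, 2);
  for (int t = 0; t < T; t++) {
    const int* yt = obs.begin() + (size_t)t * S;
    const double* pt = p.begin() + (size_t)t * S;
    out(t, 0) = year_emission_core(yt, S, 0, theta0, theta, theta_prime, pt);
    out(t, 1) = year_emission_core(yt, S, 1, theta0, theta, theta_prime, pt);
  }
  return out;
}
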