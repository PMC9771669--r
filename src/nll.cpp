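#include <Rcpp.h>
using namespace Rcpp;

// Fast path for the optimizer: unpack the log-parameter vector, run the
// mean/variance recursion over the time-by-age lattice, and accumulate the
// negative weighted Gaussian log-likelihood from per-cell sufficient
// statistics (w = sum of weights, m = sum w*x, s = sum w*x^2).
//
// Layout of `par` (all logs): r_b | e_first_age (n_t) | v_first_age (n_t) |
// e_first_time (n_a-1) | v_first_time (n_a-1) | mu_linf (n_int*n_groups,
// column-major) | sigma2_linf2 (same shape).
//
// group_mode: 0 = single group, 1 = by age, 2 = by cohort mean length.
// Boundaries define lower-closed, upper-open classes.

static inline int group_index(double x, const NumericVector& boundaries) {
  int g = 0;
  for (int b = 0; b < boundaries.size(); ++b) {
    if (x >= boundaries[b]) ++g; else break;
  }
  return g;
}

// [[Rcpp::export]]
double cpp_vb_nll(NumericVector par, int n_t, int n_a, int a_min,
                  bool varying, int n_groups, int group_mode,
                  NumericVector boundaries, bool non_shrink,
                  NumericMatrix w, NumericMatrix m, NumericMatrix s,
                  double var_floor) {
  const int n_int = varying ? (n_t - 1) : 1;
  const int k = 1 + 2 * n_t + 2 * (n_a - 1) + 2 * n_int * n_groups;
  if (par.size() != k) stop("packed vector has wrong length");

  int i = 0;
  const double r_b = std::exp(par[i++]);
  std::vector<double> E(n_t * n_a), V(n_t * n_a);
  // column-major like R matrices: cell (t, a) at t + a * n_t
  for (int t = 0; t < n_t; ++t) E[t] = std::exp(par[i + t]);
  i += n_t;
  for (int t = 0; t < n_t; ++t) V[t] = std::exp(par[i + t]);
  i += n_t;
  for (int a = 1; a < n_a; ++a) E[a * n_t] = std::exp(par[i + a - 1]);
  i += n_a - 1;
  for (int a = 1; a < n_a; ++a) V[a * n_t] = std::exp(par[i + a - 1]);
  i += n_a - 1;
  const int mu_off = i, s2_off = i + n_int * n_groups;

  const double alpha = std::exp(-r_b);
  const double alpha2 = alpha * alpha;
  const double vgain = (1.0 - alpha2) / (2.0 * r_b);

  for (int t = 0; t < n_t - 1; ++t) {
    const int row = varying ? t : 0;
    for (int a = 0; a < n_a - 1; ++a) {
      int g = 0;
      if (group_mode == 1) g = group_index((double)(a_min + a), boundaries);
      else if (group_mode == 2) g = group_index(E[t + a * n_t], boundaries);
      const double mu = std::exp(par[mu_off + row + g * n_int]);
      const double s2 = std::exp(par[s2_off + row + g * n_int]);
      double e_next = E[t + a * n_t] * alpha + mu * (1.0 - alpha);
      if (non_shrink && e_next < E[t + a * n_t]) e_next = E[t + a * n_t];
      E[(t + 1) + (a + 1) * n_t] = e_next;
      V[(t + 1) + (a + 1) * n_t] = V[t + a * n_t] * alpha2 + s2 * vgain;
    }
  }

  const double log2pi = std::log(2.0 * M_PI);
  double nll = 0.0;
  for (int a = 0; a < n_a; ++a) {
    for (int t = 0; t < n_t; ++t) {
      const double wc = w(t, a);
      if (wc <= 0.0 && m(t, a) == 0.0 && s(t, a) == 0.0) continue;
      double v = V[t + a * n_t];
      if (v < var_floor) v = var_floor;
      const double e = E[t + a * n_t];
      nll += 0.5 * wc * (log2pi + std::log(v)) +
             0.5 * (s(t, a) - 2.0 * e * m(t, a) + wc * e * e) / v;
    }
  }
  return nll;
}
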