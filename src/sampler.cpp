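#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs chain for BayesCpi, replicating the R reference
// conditionals (R/sampler-core.R) draw for draw on the shared R RNG stream.
//
// variant 1: residual updating, rhs_j = X_j'e + cj a_j         (O(n)/marker)
// variant 2: crossproduct form from X'y and X'X rows           (O(p)/marker)
//
// The maintained quantity (residual e, or s = X'X a) is audited against a
// fresh recomputation every audit_every iterations; disagreement beyond
// 1e-6 aborts.

static inline double inclusion_prob(double log_lr, double pi) {
  if (pi <= 0.0) return 1.0;
  if (pi >= 1.0) return 0.0;
  double x = log_lr + std::log((1.0 - pi) / pi);
  // plogis
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double ex = std::exp(x);
  return ex / (1.0 + ex);
}

// [[Rcpp::export]]
List cpp_bayescpi_chain(const NumericMatrix& X, const NumericVector& y,
                        int variant, int n_iter, int thin,
                        double nu_e, double S2_e, double nu_a, double S2_a,
                        bool estimate_pi, bool estimate_variances,
                        double mu0, NumericVector a0, double pi0,
                        double sigma2_a0, double sigma2_e0,
                        int audit_every) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (a0.size() != p) stop("length(a0) != ncol(X)");
  if (thin < 1) stop("thin must be >= 1");

  std::vector<double> a(a0.begin(), a0.end());
  std::vector<int> delta(p, 1);
  for (int j = 0; j < p; ++j) delta[j] = (a[j] != 0.0) ? 1 : 0;
  double mu = mu0, pi = pi0, s2a = sigma2_a0, s2e = sigma2_e0;

  // fixed precomputations
  std::vector<double> cj(p), Xty(p), Xt1(p);
  double sum_y = 0.0, yty = 0.0;
  for (int i = 0; i < n; ++i) { sum_y += y[i]; yty += y[i] * y[i]; }
  for (int j = 0; j < p; ++j) {
    double css = 0.0, cty = 0.0, c1 = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = X(i, j);
      css += x * x; cty += x * y[i]; c1 += x;
    }
    if (css <= 0.0) stop("monomorphic marker (zero column sum of squares)");
    cj[j] = css; Xty[j] = cty; Xt1[j] = c1;
  }

  NumericMatrix XtX;
  std::vector<double> e, s;
  if (variant == 1) {
    e.assign(n, 0.0);
    for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
    for (int j = 0; j < p; ++j)
      if (a[j] != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * a[j];
  } else if (variant == 2) {
    XtX = NumericMatrix(p, p);
    for (int j = 0; j < p; ++j)
      for (int k = j; k < p; ++k) {
        double v = 0.0;
        for (int i = 0; i < n; ++i) v += X(i, j) * X(i, k);
        XtX(j, k) = v; XtX(k, j) = v;
      }
    s.assign(p, 0.0);
    for (int j = 0; j < p; ++j) {
      double v = 0.0;
      for (int k = 0; k < p; ++k) v += XtX(j, k) * a[k];
      s[j] = v;
    }
  } else stop("variant must be 1 or 2");

  const int n_thin = n_iter / thin + 1;
  NumericMatrix scalars(n_iter + 1, 5);
  NumericMatrix a_thin(n_thin, p);
  IntegerMatrix delta_thin(n_thin, p);
  IntegerVector thin_iters(n_thin);
  NumericVector a_mean(p);
  double op_count = 0.0;

  int m0 = 0; for (int j = 0; j < p; ++j) m0 += delta[j];
  scalars(0, 0) = mu; scalars(0, 1) = pi; scalars(0, 2) = s2a;
  scalars(0, 3) = s2e; scalars(0, 4) = m0;
  for (int j = 0; j < p; ++j) { a_thin(0, j) = a[j]; delta_thin(0, j) = delta[j]; }
  thin_iters[0] = 0;
  int thin_row = 1;

  RNGScope scope;
  for (int t = 1; t <= n_iter; ++t) {
    // --- general mean (flat prior) ---
    double rbar;
    if (variant == 1) {
      double se = 0.0;
      for (int i = 0; i < n; ++i) se += e[i];
      rbar = se / n + mu;
    } else {
      double d1 = 0.0;
      for (int j = 0; j < p; ++j) d1 += Xt1[j] * a[j];
      rbar = (sum_y - d1) / n;
    }
    double mu_new = R::rnorm(rbar, std::sqrt(s2e / n));
    if (variant == 1) {
      double dmu = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= dmu;
    }
    mu = mu_new;
    op_count += n;

    // --- single-site sweep, ascending marker order ---
    const double lambda = s2e / s2a;
    for (int j = 0; j < p; ++j) {
      double rhs;
      if (variant == 1) {
        double d = 0.0;
        for (int i = 0; i < n; ++i) d += X(i, j) * e[i];
        rhs = d + cj[j] * a[j];
        op_count += n;
      } else {
        rhs = Xty[j] - Xt1[j] * mu - s[j] + cj[j] * a[j];
        op_count += p;
      }
      double v = cj[j] * s2a + s2e;
      double log_lr = -0.5 * std::log(v / s2e) +
        rhs * rhs * s2a / (2.0 * s2e * v);
      double p1 = inclusion_prob(log_lr, pi);
      double u = unif_rand();
      double a_new;
      int d_new;
      if (u < p1) {
        double denom = cj[j] + lambda;
        a_new = R::rnorm(rhs / denom, std::sqrt(s2e / denom));
        d_new = 1;
      } else {
        a_new = 0.0; d_new = 0;
      }
      double da = a_new - a[j];
      if (da != 0.0) {
        if (variant == 1) {
          for (int i = 0; i < n; ++i) e[i] -= X(i, j) * da;
          op_count += n;
        } else {
          for (int k = 0; k < p; ++k) s[k] += XtX(k, j) * da;
          op_count += p;
        }
      }
      a[j] = a_new; delta[j] = d_new;
    }

    // --- variance components and pi ---
    int m = 0; double ssa = 0.0;
    for (int j = 0; j < p; ++j) { m += delta[j]; ssa += a[j] * a[j]; }
    if (estimate_variances) {
      s2a = (nu_a * S2_a + ssa) / R::rchisq(nu_a + m);
      double ee;
      if (variant == 1) {
        ee = 0.0;
        for (int i = 0; i < n; ++i) ee += e[i] * e[i];
      } else {
        double as = 0.0, aty = 0.0, a1 = 0.0;
        for (int j = 0; j < p; ++j) {
          as += a[j] * s[j]; aty += a[j] * Xty[j]; a1 += a[j] * Xt1[j];
        }
        ee = yty + n * mu * mu + as - 2.0 * mu * sum_y - 2.0 * aty +
          2.0 * mu * a1;
        if (ee < 0.0) ee = 0.0;
      }
      s2e = (nu_e * S2_e + ee) / R::rchisq(nu_e + n);
    }
    if (estimate_pi) pi = R::rbeta(p - m + 1.0, m + 1.0);

    if (!std::isfinite(s2a) || !std::isfinite(s2e) || !std::isfinite(mu))
      stop("sampler diverged (non-finite state) at iteration %d", t);

    // --- periodic audit of the maintained quantity ---
    if (audit_every > 0 && t % audit_every == 0) {
      if (variant == 1) {
        double worst = 0.0;
        std::vector<double> ef(n);
        for (int i = 0; i < n; ++i) ef[i] = y[i] - mu;
        for (int j = 0; j < p; ++j)
          if (a[j] != 0.0)
            for (int i = 0; i < n; ++i) ef[i] -= X(i, j) * a[j];
        for (int i = 0; i < n; ++i)
          worst = std::max(worst, std::fabs(ef[i] - e[i]));
        if (worst > 1e-6)
          stop("residual audit failed at iteration %d (max drift %g)",
               t, worst);
        e.swap(ef);
      } else {
        double worst = 0.0;
        std::vector<double> sf(p, 0.0);
        for (int k = 0; k < p; ++k)
          if (a[k] != 0.0)
            for (int j = 0; j < p; ++j) sf[j] += XtX(j, k) * a[k];
        for (int j = 0; j < p; ++j)
          worst = std::max(worst, std::fabs(sf[j] - s[j]));
        if (worst > 1e-6)
          stop("crossproduct audit failed at iteration %d (max drift %g)",
               t, worst);
        s.swap(sf);
      }
    }

    // --- record ---
    scalars(t, 0) = mu; scalars(t, 1) = pi; scalars(t, 2) = s2a;
    scalars(t, 3) = s2e; scalars(t, 4) = m;
    for (int j = 0; j < p; ++j)
      a_mean[j] += (a[j] - a_mean[j]) / t;
    if (t % thin == 0) {
      for (int j = 0; j < p; ++j) {
        a_thin(thin_row, j) = a[j];
        delta_thin(thin_row, j) = delta[j];
      }
      thin_iters[thin_row] = t;
      ++thin_row;
    }
    if (t % 256 == 0) checkUserInterrupt();
  }
  if (n_iter == 0)
    for (int j = 0; j < p; ++j) a_mean[j] = a[j];

  return List::create(
    _["scalars"] = scalars, _["a_thin"] = a_thin,
    _["delta_thin"] = delta_thin, _["thin_iters"] = thin_iters,
    _["a_mean"] = a_mean, _["op_count"] = op_count);
}
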