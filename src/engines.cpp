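// Gibbs and EM engines for the four-component SNP-effect mixture model.
// Residuals are maintained incrementally; matrices arrive as R memory and
// are wrapped without copying. All randomness goes through R's RNG so that
// set.seed() on the R side controls every draw.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const int NCLASS = 4;

// log-sum-exp class draw; logw may contain -inf for zero-probability classes
static inline int draw_class(const double *logw) {
  double mx = logw[0];
  for (int k = 1; k < NCLASS; ++k) if (logw[k] > mx) mx = logw[k];
  double w[NCLASS], tot = 0.0;
  for (int k = 0; k < NCLASS; ++k) {
    w[k] = std::exp(logw[k] - mx);
    tot += w[k];
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < NCLASS; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return NCLASS - 1;
}

// class log-likelihoods of the partial-residual statistic r with the SNP
// effect integrated out: r ~ N(0, l^2 sigma_k^2 + l sigma_e^2)
static inline void class_loglik(double r, double l, const double *gamma,
                                double sigma_g2, double sigma_e2,
                                double *out) {
  for (int k = 0; k < NCLASS; ++k) {
    double vk = l * l * gamma[k] * sigma_g2 + l * sigma_e2;
    out[k] = -0.5 * std::log(vk) - 0.5 * r * r / vk;
  }
}

// [[Rcpp::export(name = ".cpp_gibbs_chain")]]
List cpp_gibbs_chain(NumericMatrix Zs_r, NumericVector y_r,
                     Nullable<NumericMatrix> X_r,
                     Nullable<NumericMatrix> Pbeta_r,
                     NumericVector einv_r, NumericVector gamma_r,
                     double sigma_g2, double sigma_a2,
                     Nullable<NumericMatrix> Tv_r,
                     Nullable<NumericVector> lamv_r,
                     NumericVector alpha_r,
                     int niter, int burnin,
                     NumericVector g0, NumericVector pr0,
                     NumericVector beta0, NumericVector v0,
                     double sigma_e2, double nu0, double S0,
                     bool exclusion, int exclude_at,
                     double exclude_threshold,
                     int g_sample_thin) {
  const int n = Zs_r.nrow(), m = Zs_r.ncol();
  arma::mat Z(Zs_r.begin(), n, m, false, true);
  arma::vec y(y_r.begin(), n, false, true);
  arma::vec einv(einv_r.begin(), n, false, true);
  const double *gamma = gamma_r.begin();

  bool have_X = X_r.isNotNull();
  arma::mat X, Pbeta;
  if (have_X) {
    NumericMatrix Xm(X_r.get()), Pm(Pbeta_r.get());
    X = arma::mat(Xm.begin(), Xm.nrow(), Xm.ncol());
    Pbeta = arma::mat(Pm.begin(), Pm.nrow(), Pm.ncol());
  }
  bool have_v = sigma_a2 > 0.0 && Tv_r.isNotNull();
  arma::mat Tv;
  arma::vec lamv;
  if (have_v) {
    NumericMatrix Tm(Tv_r.get());
    Tv = arma::mat(Tm.begin(), Tm.nrow(), Tm.ncol());
    lamv = as<arma::vec>(lamv_r.get());
  }

  // weighted genotype columns and per-SNP information l_i = Z_i' E^-1 Z_i
  arma::mat Zei = Z.each_col() % einv;
  arma::vec l(m);
  for (int i = 0; i < m; ++i) l(i) = arma::dot(Zei.col(i), Z.col(i));

  arma::vec g(g0.begin(), m);
  arma::vec pr(pr0.begin(), NCLASS);
  arma::vec beta = have_X ? arma::vec(beta0.begin(), beta0.size())
                          : arma::vec();
  arma::vec v(v0.begin(), n);
  arma::ivec cls(m, arma::fill::zeros);

  arma::vec e = y - Z * g - v;
  if (have_X) e -= X * beta;

  arma::vec g_sum(m, arma::fill::zeros), v_sum(n, arma::fill::zeros);
  arma::vec pr_sum(NCLASS, arma::fill::zeros);
  arma::vec beta_sum(have_X ? beta.n_elem : 1, arma::fill::zeros);
  arma::mat P(m, NCLASS, arma::fill::zeros);
  double se2_sum = 0.0;
  int nsamp = 0, drift_events = 0;

  std::vector<int> count1(m, 0);        // class-1 tallies for exclusion rule
  std::vector<bool> excluded(m, false);
  arma::vec run_p1(m, arma::fill::zeros);

  int nstore = 0;
  if (g_sample_thin > 0)
    nstore = (niter - burnin + g_sample_thin - 1) / g_sample_thin;
  arma::mat g_samples(nstore > 0 ? nstore : 1, nstore > 0 ? m : 1,
                      arma::fill::zeros);
  int istore = 0;

  arma::mat pr_trace(niter, NCLASS, arma::fill::zeros);
  arma::vec se2_trace(niter, arma::fill::zeros);

  double logw[NCLASS];
  arma::ivec counts(NCLASS);

  for (int it = 1; it <= niter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();

    // fixed effects: weighted least squares on the partial residual
    if (have_X) {
      arma::vec xb = X * beta;
      arma::vec beta_new = Pbeta * (e + xb);
      e += xb - X * beta_new;
      beta = beta_new;
    }

    // SNP sweep
    counts.zeros();
    for (int i = 0; i < m; ++i) {
      if (excluded[i]) { cls(i) = 0; counts(0)++; continue; }
      double gi = g(i);
      double r = arma::dot(Zei.col(i), e) + l(i) * gi;
      class_loglik(r, l(i), gamma, sigma_g2, sigma_e2, logw);
      for (int k = 0; k < NCLASS; ++k)
        logw[k] += (pr(k) > 0.0) ? std::log(pr(k)) : -1e300;
      int k = draw_class(logw);
      double g_new;
      if (k == 0) {
        g_new = 0.0;
      } else {
        double denom = l(i) + sigma_e2 / (gamma[k] * sigma_g2);
        g_new = r / denom + std::sqrt(sigma_e2 / denom) * norm_rand();
      }
      if (g_new != gi) e -= Z.col(i) * (g_new - gi);
      g(i) = g_new;
      cls(i) = k;
      counts(k)++;
      if (exclusion && it <= exclude_at && k == 0) count1[i]++;
    }

    // exclusion rule: freeze persistent zero-class SNPs
    if (exclusion && it == exclude_at) {
      for (int i = 0; i < m; ++i) {
        run_p1(i) = (double)count1[i] / (double)exclude_at;
        if (run_p1(i) > exclude_threshold) {
          excluded[i] = true;
          if (g(i) != 0.0) { e += Z.col(i) * g(i); g(i) = 0.0; }
          cls(i) = 0;
        }
      }
    }

    // mixture proportions: Dirichlet(alpha + counts)
    {
      double tot = 0.0;
      for (int k = 0; k < NCLASS; ++k) {
        pr(k) = R::rgamma(alpha_r[k] + counts(k), 1.0);
        tot += pr(k);
      }
      pr /= tot;
    }

    // polygenic values: exact multivariate-normal full conditional via the
    // precomputed whitening transform Tv, eigenvalues lamv
    if (have_v) {
      arma::vec rv = e + v;
      arma::vec b = (einv % rv) / sigma_e2;
      arma::vec tb = Tv.t() * b;
      arma::vec d = lamv / sigma_a2 + 1.0 / sigma_e2;
      arma::vec zdraw(tb.n_elem);
      for (arma::uword j = 0; j < zdraw.n_elem; ++j) zdraw(j) = norm_rand();
      arma::vec v_new = Tv * (tb / d + zdraw / arma::sqrt(d));
      e += v - v_new;
      v = v_new;
    }

    // residual variance: scaled inverse chi-square
    {
      double ss = S0 + arma::dot(e % einv, e);
      double df = nu0 + (double)n;
      if (ss <= 0.0) stop("non-positive residual sum of squares");
      sigma_e2 = ss / R::rchisq(df);
    }

    pr_trace.row(it - 1) = pr.t();
    se2_trace(it - 1) = sigma_e2;

    // periodic residual resync guards against numerical drift
    if (it % 512 == 0 || it == niter) {
      arma::vec e_true = y - Z * g - v;
      if (have_X) e_true -= X * beta;
      if (arma::norm(e - e_true, 2) > 1e-6) drift_events++;
      e = e_true;
    }

    if (it > burnin) {
      g_sum += g;
      pr_sum += pr;
      v_sum += v;
      if (have_X) beta_sum += beta;
      se2_sum += sigma_e2;
      for (int i = 0; i < m; ++i) P(i, cls(i)) += 1.0;
      if (g_sample_thin > 0 && ((it - burnin - 1) % g_sample_thin == 0) &&
          istore < nstore) {
        g_samples.row(istore++) = g.t();
      }
      nsamp++;
    }
  }

  double ns = (double)std::max(nsamp, 1);
  g_sum /= ns; pr_sum /= ns; v_sum /= ns;
  List out = List::create(
    _["g_mean"] = NumericVector(g_sum.begin(), g_sum.end()),
    _["P"] = wrap(arma::mat(P / ns)),
    _["pr_mean"] = NumericVector(pr_sum.begin(), pr_sum.end()),
    _["v_mean"] = NumericVector(v_sum.begin(), v_sum.end()),
    _["beta_mean"] = have_X ? wrap(arma::vec(beta_sum / ns)) : R_NilValue,
    _["sigma_e2_mean"] = se2_sum / ns,
    _["n_samples"] = nsamp,
    _["excluded"] = LogicalVector(excluded.begin(), excluded.end()),
    _["run_p1"] = NumericVector(run_p1.begin(), run_p1.end()),
    _["drift_events"] = drift_events,
    _["pr_trace"] = wrap(pr_trace),
    _["sigma_e2_trace"] = NumericVector(se2_trace.begin(), se2_trace.end()),
    _["state"] = List::create(
      _["g"] = NumericVector(g.begin(), g.end()),
      _["class_of"] = IntegerVector(cls.begin(), cls.end()),
      _["pr"] = NumericVector(pr.begin(), pr.end()),
      _["beta"] = have_X ? wrap(arma::vec(beta)) : R_NilValue,
      _["v"] = NumericVector(v.begin(), v.end()),
      _["sigma_e2"] = sigma_e2));
  if (g_sample_thin > 0) out["g_samples"] = wrap(g_samples);
  return out;
}

// One EM pass over all SNPs: E-step responsibilities with the PEV-inflated
// effective precision, posterior-mean M-step, incremental residual update.
// [[Rcpp::export(name = ".cpp_em_sweep")]]
List cpp_em_sweep(NumericMatrix Zs_r, NumericMatrix Zei_r,
                  NumericVector e_r, NumericVector g_r,
                  NumericVector l_r, NumericVector pev_corr_r,
                  NumericVector pr_r, NumericVector gamma_r,
                  double sigma_g2, double sigma_e2) {
  const int n = Zs_r.nrow(), m = Zs_r.ncol();
  arma::mat Z(Zs_r.begin(), n, m, false, true);
  arma::mat Zei(Zei_r.begin(), n, m, false, true);
  arma::vec e(e_r.begin(), n);      // copies: caller keeps its state
  arma::vec g(g_r.begin(), m);
  const double *gamma = gamma_r.begin();
  arma::vec pr(pr_r.begin(), NCLASS);
  arma::mat P(m, NCLASS);
  arma::vec varg(m);                 // per-SNP posterior variance of g
  double free_energy_terms = 0.0;    // prior + entropy parts of the objective
  const double LOG2PI = 1.8378770664093453;
  double logw[NCLASS];

  for (int i = 0; i < m; ++i) {
    double gi = g(i);
    double li = l_r[i];
    double r = arma::dot(Zei.col(i), e) + li * gi;
    // the PEV term enters as additive noise variance in the statistic r:
    // Var(Z_i'E^-1(u - u_hat)) = pev_corr_i, so tau replaces l sigma_e^2
    double tau = li * sigma_e2 + pev_corr_r[i];
    double mx = -1e300;
    for (int k = 0; k < NCLASS; ++k) {
      double vk = li * li * gamma[k] * sigma_g2 + tau;
      logw[k] = -0.5 * std::log(vk) - 0.5 * r * r / vk;
      logw[k] += (pr(k) > 0.0) ? std::log(pr(k)) : -1e300;
      if (logw[k] > mx) mx = logw[k];
    }
    double tot = 0.0, w[NCLASS];
    for (int k = 0; k < NCLASS; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
    double g_new = 0.0, e2 = 0.0;
    for (int k = 0; k < NCLASS; ++k) {
      w[k] /= tot;
      P(i, k) = w[k];
      if (w[k] <= 0.0) continue;
      double fi = -std::log(w[k]);   // entropy part; log Pr_k added in R

      if (k > 0) {
        double sk2 = gamma[k] * sigma_g2;
        double vk = 1.0 / (li * li / tau + 1.0 / sk2);
        double mk = r * li / tau * vk;
        g_new += w[k] * mk;
        e2 += w[k] * (vk + mk * mk);
        // Gaussian prior expectation + Gaussian entropy of q(g | class k)
        fi += -0.5 * (LOG2PI + std::log(sk2)) - (vk + mk * mk) / (2.0 * sk2)
              + 0.5 * (LOG2PI + 1.0 + std::log(vk));
      }
      free_energy_terms += w[k] * fi;
    }
    varg(i) = std::max(e2 - g_new * g_new, 0.0);
    if (!std::isfinite(g_new)) stop("non-finite EM update at SNP %d", i + 1);
    if (g_new != gi) e -= Z.col(i) * (g_new - gi);
    g(i) = g_new;
  }
  return List::create(_["g"] = NumericVector(g.begin(), g.end()),
                      _["e"] = NumericVector(e.begin(), e.end()),
                      _["P"] = wrap(P),
                      _["varg"] = NumericVector(varg.begin(), varg.end()),
                      _["free_energy_terms"] = free_energy_terms);
}
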