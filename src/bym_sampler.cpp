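// Metropolis-within-Gibbs sampler for the BYM spatial logistic model.
//
// Likelihood is evaluated on binomial cells (area x cycle x age sufficient
// statistics of the individual Bernoulli outcomes):
//   logit p_cell = X beta + u[area] + v[area]
// with an intrinsic CAR (pairwise-difference) prior on u, iid normal prior
// on v, normal priors on the fixed effects, and either conjugate gamma
// hyperpriors on the precisions (Gibbs update) or uniform hyperpriors on the
// standard deviations (Metropolis on log sd). u is recentred to sum to zero
// every sweep with a compensating intercept shift (X column 0 must be 1).
//
// All randomness goes through R's RNG, so set.seed() in R makes runs exact.

#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

static inline double mp_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// binomial log-likelihood of one cell (no combinatorial constant)
static inline double cell_ll(double y, double m, double eta) {
  return y * eta - m * mp_log1pexp(eta);
}

// [[Rcpp::export(name = ".bym_chain")]]
List bym_chain(NumericMatrix X, NumericVector y, NumericVector m,
               IntegerVector area,            // 0-based cell -> area
               IntegerVector adj_idx, IntegerVector adj_off,   // neighbours
               IntegerVector cell_idx, IntegerVector cell_off, // cells/area
               int n_comp,
               int n_burn, int n_keep, int thin,
               int prior_family,               // 0 gamma_precision, 1 uniform_sd
               double gamma_shape, double gamma_rate, double unif_upper,
               double fe_sd,
               bool fixed_scales, double sigma_u_fix, double sigma_v_fix,
               NumericVector beta_init, double sigma_init,
               bool adapt) {
  const int n_cells = X.nrow(), p = X.ncol();
  const int n_areas = adj_off.size() - 1;

  // nonzero rows of each design column (fixed-effect updates touch only
  // cells where the column is nonzero)
  std::vector<std::vector<int>> xnz(p);
  for (int k = 0; k < p; ++k)
    for (int c = 0; c < n_cells; ++c)
      if (X(c, k) != 0.0) xnz[k].push_back(c);

  NumericVector beta = clone(beta_init);
  std::vector<double> u(n_areas, 0.0), v(n_areas, 0.0);
  double sigma_u = fixed_scales ? sigma_u_fix : sigma_init;
  double sigma_v = fixed_scales ? sigma_v_fix : sigma_init;

  // linear predictor per cell
  std::vector<double> eta(n_cells, 0.0);
  for (int c = 0; c < n_cells; ++c) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += X(c, k) * beta[k];
    eta[c] = e;
  }
  // cached per-cell log-likelihood at the current eta (kept in lock-step
  // with every eta change; halves the exp() work and makes the per-draw
  // deviance a running sum)
  std::vector<double> ll(n_cells), prop_ll(n_cells);
  for (int c = 0; c < n_cells; ++c) ll[c] = cell_ll(y[c], m[c], eta[c]);

  // adaptive proposal scales
  std::vector<double> s_beta(p, 0.1), s_u(n_areas, 0.3), s_v(n_areas, 0.3),
      s_w(n_areas, 0.3);
  double s_lsu = 0.3, s_lsv = 0.3, s_a = 0.3, s_ncu = 0.3, s_ncv = 0.3;
  double s_joint = 1.0;
  std::vector<double> mu_b(p, 0.0), db(p, 0.0);
  std::vector<std::vector<double>> cov_b(p, std::vector<double>(p, 0.0));
  std::vector<std::vector<double>> Lc(p, std::vector<double>(p, 0.0));
  int cov_n = 0;
  bool have_chol = false;
  std::vector<double> acc_beta(p, 0.0), acc_u(n_areas, 0.0),
      acc_v(n_areas, 0.0);

  const int n_save = n_keep / thin;
  NumericMatrix draws(n_save, p + 2 * n_areas + 2);
  NumericVector deviance(n_save);
  int save_at = 0;

  const int n_iter = n_burn + n_keep;
  for (int it = 0; it < n_iter; ++it) {
    const double gam = adapt && it < n_burn
                           ? std::pow((double)it + 1.0, -0.6)
                           : 0.0;
    const double tau_u = 1.0 / (sigma_u * sigma_u);
    const double tau_v = 1.0 / (sigma_v * sigma_v);

    // ---- fixed effects: random-walk Metropolis, one at a time ----
    for (int k = 0; k < p; ++k) {
      const double delta = s_beta[k] * R::norm_rand();
      double dll = 0.0;
      for (int ci : xnz[k]) {
        prop_ll[ci] = cell_ll(y[ci], m[ci], eta[ci] + X(ci, k) * delta);
        dll += prop_ll[ci] - ll[ci];
      }
      const double b0 = beta[k], b1 = beta[k] + delta;
      dll += (b0 * b0 - b1 * b1) / (2.0 * fe_sd * fe_sd);
      int acc = 0;
      if (std::log(R::unif_rand()) < dll) {
        beta[k] = b1;
        for (int ci : xnz[k]) {
          eta[ci] += X(ci, k) * delta;
          ll[ci] = prop_ll[ci];
        }
        acc = 1;
      }
      if (gam > 0.0) s_beta[k] *= std::exp(gam * (acc - 0.44));
      else acc_beta[k] += acc;
    }

    // ---- joint adaptive-Metropolis move on the fixed-effect block ----
    // single-site walks mix slowly when coefficients are correlated in the
    // posterior (intercept with income, cycles with each other); a blocked
    // proposal with the covariance learned during burn-in fixes that
    if (it >= 200) {
      // refresh the Cholesky factor of the running covariance occasionally
      if (it % 50 == 0 || !have_chol) {
        for (int a2 = 0; a2 < p; ++a2)
          for (int b2 = 0; b2 < p; ++b2)
            Lc[a2][b2] = cov_b[a2][b2] / std::max(1, cov_n - 1);
        for (int a2 = 0; a2 < p; ++a2) Lc[a2][a2] += 1e-8;
        bool ok = true;
        for (int a2 = 0; a2 < p && ok; ++a2) {
          for (int b2 = 0; b2 <= a2 && ok; ++b2) {
            double sum = Lc[a2][b2];
            for (int k2 = 0; k2 < b2; ++k2) sum -= Lc[a2][k2] * Lc[b2][k2];
            if (a2 == b2) {
              if (sum <= 0.0) ok = false;
              else Lc[a2][a2] = std::sqrt(sum);
            } else {
              Lc[a2][b2] = sum / Lc[b2][b2];
            }
          }
        }
        have_chol = ok;
      }
      if (have_chol) {
        std::vector<double> z(p), delta(p, 0.0);
        for (int k = 0; k < p; ++k) z[k] = R::norm_rand();
        const double fac = s_joint * 2.38 / std::sqrt((double)p);
        for (int a2 = 0; a2 < p; ++a2) {
          double d = 0.0;
          for (int b2 = 0; b2 <= a2; ++b2) d += Lc[a2][b2] * z[b2];
          delta[a2] = fac * d;
        }
        double dll = 0.0;
        std::vector<double> xde(n_cells, 0.0);
        for (int k = 0; k < p; ++k)
          if (delta[k] != 0.0)
            for (int ci : xnz[k]) xde[ci] += X(ci, k) * delta[k];
        for (int c = 0; c < n_cells; ++c)
          if (xde[c] != 0.0) {
            prop_ll[c] = cell_ll(y[c], m[c], eta[c] + xde[c]);
            dll += prop_ll[c] - ll[c];
          }
        for (int k = 0; k < p; ++k) {
          const double b0 = beta[k], b1 = beta[k] + delta[k];
          dll += (b0 * b0 - b1 * b1) / (2.0 * fe_sd * fe_sd);
        }
        int acc = 0;
        if (std::log(R::unif_rand()) < dll) {
          for (int k = 0; k < p; ++k) beta[k] += delta[k];
          for (int c = 0; c < n_cells; ++c)
            if (xde[c] != 0.0) {
              eta[c] += xde[c];
              ll[c] = prop_ll[c];
            }
          acc = 1;
        }
        if (gam > 0.0) s_joint *= std::exp(gam * (acc - 0.234));
      }
    }
    // accumulate running mean / covariance of beta during burn-in
    if (it < n_burn) {
      ++cov_n;
      for (int k = 0; k < p; ++k) db[k] = beta[k] - mu_b[k];
      for (int k = 0; k < p; ++k) mu_b[k] += db[k] / cov_n;
      for (int a2 = 0; a2 < p; ++a2)
        for (int b2 = 0; b2 < p; ++b2)
          cov_b[a2][b2] += db[a2] * (beta[b2] - mu_b[b2]);
    }

    // ---- spatial effects u ----
    for (int j = 0; j < n_areas; ++j) {
      const double delta = s_u[j] * R::norm_rand();
      const double u1 = u[j] + delta;
      double dll = 0.0;
      for (int t = cell_off[j]; t < cell_off[j + 1]; ++t) {
        const int ci = cell_idx[t];
        prop_ll[ci] = cell_ll(y[ci], m[ci], eta[ci] + delta);
        dll += prop_ll[ci] - ll[ci];
      }
      double dq = 0.0;  // change in sum of squared pairwise differences
      for (int t = adj_off[j]; t < adj_off[j + 1]; ++t) {
        const double uk = u[adj_idx[t]];
        dq += (u1 - uk) * (u1 - uk) - (u[j] - uk) * (u[j] - uk);
      }
      dll -= 0.5 * tau_u * dq;
      int acc = 0;
      if (std::log(R::unif_rand()) < dll) {
        u[j] = u1;
        for (int t = cell_off[j]; t < cell_off[j + 1]; ++t) {
          eta[cell_idx[t]] += delta;
          ll[cell_idx[t]] = prop_ll[cell_idx[t]];
        }
        acc = 1;
      }
      if (gam > 0.0) s_u[j] *= std::exp(gam * (acc - 0.44));
      else acc_u[j] += acc;
    }

    // recentre u (sum-to-zero) and compensate through the intercept;
    // eta is unchanged because the shift cancels
    double ubar = 0.0;
    for (int j = 0; j < n_areas; ++j) ubar += u[j];
    ubar /= n_areas;
    for (int j = 0; j < n_areas; ++j) u[j] -= ubar;
    beta[0] += ubar;

    // ---- unstructured effects v ----
    for (int j = 0; j < n_areas; ++j) {
      const double delta = s_v[j] * R::norm_rand();
      const double v1 = v[j] + delta;
      double dll = 0.0;
      for (int t = cell_off[j]; t < cell_off[j + 1]; ++t) {
        const int ci = cell_idx[t];
        prop_ll[ci] = cell_ll(y[ci], m[ci], eta[ci] + delta);
        dll += prop_ll[ci] - ll[ci];
      }
      dll += 0.5 * tau_v * (v[j] * v[j] - v1 * v1);
      int acc = 0;
      if (std::log(R::unif_rand()) < dll) {
        v[j] = v1;
        for (int t = cell_off[j]; t < cell_off[j + 1]; ++t) {
          eta[cell_idx[t]] += delta;
          ll[cell_idx[t]] = prop_ll[cell_idx[t]];
        }
        acc = 1;
      }
      if (gam > 0.0) s_v[j] *= std::exp(gam * (acc - 0.44));
      else acc_v[j] += acc;
    }

    // ---- rebalance the spatial/unstructured split ----
    // moving mass between u_j and v_j leaves u_j + v_j (hence the
    // likelihood) unchanged but mixes the weakly identified split that
    // drives sigma_u and sigma_v
    for (int j = 0; j < n_areas; ++j) {
      const double d = s_w[j] * R::norm_rand();
      const double u1 = u[j] + d, v1 = v[j] - d;
      double dq = 0.0;
      for (int t = adj_off[j]; t < adj_off[j + 1]; ++t) {
        const double uk = u[adj_idx[t]];
        dq += (u1 - uk) * (u1 - uk) - (u[j] - uk) * (u[j] - uk);
      }
      const double dll = -0.5 * tau_u * dq +
                         0.5 * tau_v * (v[j] * v[j] - v1 * v1);
      int acc = 0;
      if (std::log(R::unif_rand()) < dll) {
        u[j] = u1;
        v[j] = v1;
        acc = 1;
      }
      if (gam > 0.0) s_w[j] *= std::exp(gam * (acc - 0.44));
    }
    {
      double ubar2 = 0.0;
      for (int j = 0; j < n_areas; ++j) ubar2 += u[j];
      ubar2 /= n_areas;
      for (int j = 0; j < n_areas; ++j) u[j] -= ubar2;
      beta[0] += ubar2;
    }

    // ---- global split move: u' = a u, v' = v + (1 - a) u ----
    // keeps every u_j + v_j (and the sum-to-zero constraint) intact while
    // trading overall mass between the spatial and iid components; the
    // scaling family needs the Jacobian a^(n-1) on the constrained space
    {
      const double a = std::exp(s_a * R::norm_rand());
      double ss_u0 = 0.0;
      for (int j = 0; j < n_areas; ++j)
        for (int t = adj_off[j]; t < adj_off[j + 1]; ++t) {
          const int k = adj_idx[t];
          if (k > j) {
            const double dd = u[j] - u[k];
            ss_u0 += dd * dd;
          }
        }
      double dv2 = 0.0;
      for (int j = 0; j < n_areas; ++j) {
        const double v1 = v[j] + (1.0 - a) * u[j];
        dv2 += v1 * v1 - v[j] * v[j];
      }
      const double lacc = -0.5 * tau_u * (a * a - 1.0) * ss_u0 -
                          0.5 * tau_v * dv2 +
                          (n_areas - 1.0) * std::log(a);
      int acc = 0;
      if (std::log(R::unif_rand()) < lacc) {
        for (int j = 0; j < n_areas; ++j) {
          v[j] += (1.0 - a) * u[j];
          u[j] *= a;
        }
        acc = 1;
      }
      if (gam > 0.0) s_a *= std::exp(gam * (acc - 0.44));
    }

    // ---- scale parameters ----
    if (!fixed_scales) {
      double ss_u = 0.0;  // sum over unique pairs of (u_i - u_j)^2
      for (int j = 0; j < n_areas; ++j)
        for (int t = adj_off[j]; t < adj_off[j + 1]; ++t) {
          const int k = adj_idx[t];
          if (k > j) {
            const double d = u[j] - u[k];
            ss_u += d * d;
          }
        }
      double ss_v = 0.0;
      for (int j = 0; j < n_areas; ++j) ss_v += v[j] * v[j];

      if (prior_family == 0) {  // conjugate gamma on the precisions
        const double tu = R::rgamma(gamma_shape + 0.5 * (n_areas - n_comp),
                                    1.0 / (gamma_rate + 0.5 * ss_u));
        const double tv = R::rgamma(gamma_shape + 0.5 * n_areas,
                                    1.0 / (gamma_rate + 0.5 * ss_v));
        sigma_u = 1.0 / std::sqrt(tu);
        sigma_v = 1.0 / std::sqrt(tv);
      } else {  // uniform(0, upper) on sd: Metropolis on log sd
        {
          const double ls1 = std::log(sigma_u) + s_lsu * R::norm_rand();
          const double s1 = std::exp(ls1);
          int acc = 0;
          if (s1 < unif_upper) {
            // log target in sigma + log-Jacobian of the log transform
            const double lt0 = -(n_areas - n_comp) * std::log(sigma_u) -
                               0.5 * ss_u / (sigma_u * sigma_u) +
                               std::log(sigma_u);
            const double lt1 = -(n_areas - n_comp) * std::log(s1) -
                               0.5 * ss_u / (s1 * s1) + std::log(s1);
            if (std::log(R::unif_rand()) < lt1 - lt0) { sigma_u = s1; acc = 1; }
          }
          if (gam > 0.0) s_lsu *= std::exp(gam * (acc - 0.44));
        }
        {
          const double ls1 = std::log(sigma_v) + s_lsv * R::norm_rand();
          const double s1 = std::exp(ls1);
          int acc = 0;
          if (s1 < unif_upper) {
            const double lt0 = -((double)n_areas) * std::log(sigma_v) -
                               0.5 * ss_v / (sigma_v * sigma_v) +
                               std::log(sigma_v);
            const double lt1 = -((double)n_areas) * std::log(s1) -
                               0.5 * ss_v / (s1 * s1) + std::log(s1);
            if (std::log(R::unif_rand()) < lt1 - lt0) { sigma_v = s1; acc = 1; }
          }
          if (gam > 0.0) s_lsv *= std::exp(gam * (acc - 0.44));
        }
      }
    }

    // ---- non-centred rescaling of each random-effect block ----
    // jointly scaling the effects and their sd (u' = r u, tau' = tau / r^2)
    // steps straight across the funnel that makes the scales slow-mixing in
    // the centred parametrization; acceptance ratios follow from the
    // change of variables on the constrained space
    if (!fixed_scales) {
      {  // v block
        const double r = std::exp(s_ncv * R::norm_rand());
        const double sv1 = sigma_v * r;
        bool ok = prior_family == 0 || sv1 < unif_upper;
        int acc = 0;
        if (ok) {
          double dll = 0.0;
          for (int c = 0; c < n_cells; ++c) {
            prop_ll[c] = cell_ll(y[c], m[c], eta[c] + (r - 1.0) * v[area[c]]);
            dll += prop_ll[c] - ll[c];
          }
          const double tv = 1.0 / (sigma_v * sigma_v);
          const double lacc =
              prior_family == 0
                  ? dll - 2.0 * gamma_shape * std::log(r) -
                        gamma_rate * tv * (1.0 / (r * r) - 1.0)
                  : dll + std::log(r);
          if (std::log(R::unif_rand()) < lacc) {
            for (int c = 0; c < n_cells; ++c) {
              eta[c] += (r - 1.0) * v[area[c]];
              ll[c] = prop_ll[c];
            }
            for (int j = 0; j < n_areas; ++j) v[j] *= r;
            sigma_v = sv1;
            acc = 1;
          }
        }
        if (gam > 0.0) s_ncv *= std::exp(gam * (acc - 0.44));
      }
      if (n_comp == 1) {  // u block (connected graph case)
        const double r = std::exp(s_ncu * R::norm_rand());
        const double su1 = sigma_u * r;
        bool ok = prior_family == 0 || su1 < unif_upper;
        int acc = 0;
        if (ok) {
          double dll = 0.0;
          for (int c = 0; c < n_cells; ++c) {
            prop_ll[c] = cell_ll(y[c], m[c], eta[c] + (r - 1.0) * u[area[c]]);
            dll += prop_ll[c] - ll[c];
          }
          const double tu = 1.0 / (sigma_u * sigma_u);
          const double lacc =
              prior_family == 0
                  ? dll - 2.0 * gamma_shape * std::log(r) -
                        gamma_rate * tu * (1.0 / (r * r) - 1.0)
                  : dll + std::log(r);
          if (std::log(R::unif_rand()) < lacc) {
            for (int c = 0; c < n_cells; ++c) {
              eta[c] += (r - 1.0) * u[area[c]];
              ll[c] = prop_ll[c];
            }
            for (int j = 0; j < n_areas; ++j) u[j] *= r;
            sigma_u = su1;
            acc = 1;
          }
        }
        if (gam > 0.0) s_ncu *= std::exp(gam * (acc - 0.44));
      }
    }

    if (!std::isfinite(beta[0]) || !std::isfinite(sigma_u)) {
      stop("Sampler diverged (non-finite state) at iteration %d", it + 1);
    }

    // ---- save ----
    if (it >= n_burn && ((it - n_burn + 1) % thin == 0)) {
      for (int k = 0; k < p; ++k) draws(save_at, k) = beta[k];
      for (int j = 0; j < n_areas; ++j) draws(save_at, p + j) = u[j];
      for (int j = 0; j < n_areas; ++j) draws(save_at, p + n_areas + j) = v[j];
      draws(save_at, p + 2 * n_areas) = sigma_u;
      draws(save_at, p + 2 * n_areas + 1) = sigma_v;
      double dev = 0.0;
      for (int c = 0; c < n_cells; ++c) dev += ll[c];
      deviance[save_at] = -2.0 * dev;
      ++save_at;
    }
  }

  const double post_iter = (double)n_keep;
  double am = 0.0;
  for (int k = 0; k < p; ++k) am += acc_beta[k];
  return List::create(
      _["draws"] = draws, _["deviance"] = deviance,
      _["accept_beta"] = am / (p * post_iter),
      _["accept_u"] =
          std::accumulate(acc_u.begin(), acc_u.end(), 0.0) /
          (n_areas * post_iter),
      _["accept_v"] =
          std::accumulate(acc_v.begin(), acc_v.end(), 0.0) /
          (n_areas * post_iter));
}
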