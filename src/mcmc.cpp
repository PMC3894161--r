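// Metropolis sampler core for the phylogenetic Gaussian process model.
//
// The chain alternates many prior-preserving updates of the latent log-rate
// vector (underrelaxed proposals r' = sqrt(1 - eps^2) r + eps L z, which
// leave the GP prior invariant so the acceptance ratio is the likelihood
// ratio alone) with a single log-scale random-walk update of the kernel
// hyperparameters per iteration.  All randomness comes from R's RNG, so
// chains are reproducible from set.seed().
//
// Performance notes (the sampler is the package's hot loop): the per-
// iteration block of prior perturbations L Z is computed as one
// matrix-matrix product; the kernel matrix is evaluated on the lower
// triangle only; the likelihood table is held G x N so a site's two
// bracketing grid values share a cache line.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat cov_matrix(const arma::mat& D, double ell, double sigma,
                            int kernel, double jitter) {
  const double s2 = sigma * sigma;
  const arma::uword n = D.n_rows;
  arma::mat K(n, n);
  if (kernel == 0) {                       // Matern 1.5
    const double c = std::sqrt(3.0) / ell;
    for (arma::uword j = 0; j < n; ++j)
      for (arma::uword i = j; i < n; ++i) {
        const double x = c * D(i, j);
        K(i, j) = s2 * (1.0 + x) * std::exp(-x);
      }
  } else if (kernel == 1) {                // Matern 2.5
    const double c = std::sqrt(5.0) / ell;
    for (arma::uword j = 0; j < n; ++j)
      for (arma::uword i = j; i < n; ++i) {
        const double x = c * D(i, j);
        K(i, j) = s2 * (1.0 + x + x * x / 3.0) * std::exp(-x);
      }
  } else {                                 // squared exponential
    const double c = 1.0 / ell;
    for (arma::uword j = 0; j < n; ++j)
      for (arma::uword i = j; i < n; ++i) {
        const double x = c * D(i, j);
        K(i, j) = s2 * std::exp(-0.5 * x * x);
      }
  }
  K = arma::symmatl(K);
  K.diag() += jitter;
  return K;
}

// [[Rcpp::export(name = ".cov_matrix_cpp")]]
arma::mat cov_matrix_cpp(const arma::mat& D, double ell, double sigma,
                         int kernel, double jitter) {
  return cov_matrix(D, ell, sigma, kernel, jitter);
}

// linear interpolation of cached per-site log-likelihoods, on the rate
// scale; tab is G x N (one column per site)
static double interp_total(const arma::vec& r, const arma::mat& tab,
                           double rate_min, double rate_max, double step) {
  const int G = tab.n_rows, N = tab.n_cols;
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    const double* col = tab.colptr(i);
    const double rho = std::exp(r[i]);
    if (rho <= rate_min) {
      tot += col[0];
    } else if (rho >= rate_max) {
      tot += col[G - 1];
    } else {
      double u = (rho - rate_min) / step;
      int k = (int)u;
      if (k > G - 2) k = G - 2;
      const double w = u - k;
      tot += (1.0 - w) * col[k] + w * col[k + 1];
    }
  }
  return tot;
}

// N(0, K) log density via the lower Cholesky factor (constant included)
static double gp_logdens(const arma::vec& r, const arma::mat& L) {
  arma::vec y = arma::solve(arma::trimatl(L), r);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  return -0.5 * arma::dot(y, y) - 0.5 * logdet -
         0.5 * r.n_elem * std::log(2.0 * M_PI);
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(const arma::mat& D, const arma::mat& tab,
                   double rate_min, double rate_max, double step,
                   int kernel, double jitter,
                   double scale_l, double scale_s,
                   int n_iter, int rate_updates, int thin, int burn_iter,
                   double epsilon, double hyper_step,
                   double ell0, double sigma0, const arma::vec& r0,
                   double target_acc, bool adapt, bool fix_hyper) {
  const int N = r0.n_elem;
  double ell = ell0, sigma = sigma0;

  arma::mat K = cov_matrix(D, ell, sigma, kernel, jitter);
  arma::mat L;
  if (!arma::chol(L, K, "lower"))
    stop("Cholesky factorization failed at the initial hyperparameters");

  arma::vec r = r0;
  double ll = interp_total(r, tab, rate_min, rate_max, step);
  if (!std::isfinite(ll))
    stop("non-finite log-likelihood at the initial state");

  const int n_trace = n_iter / thin;
  const int n_keep = n_iter / thin - burn_iter / thin;
  arma::mat r_draws(std::max(n_keep, 0), N);
  arma::vec ell_trace(n_trace), sigma_trace(n_trace), ll_trace(n_trace);
  arma::ivec trace_iter(n_trace);

  long rate_prop_post = 0, rate_acc_post = 0;
  long hyper_prop_post = 0, hyper_acc_post = 0;
  long rate_prop_win = 0, rate_acc_win = 0;
  long hyper_prop_win = 0, hyper_acc_win = 0;
  int chol_failures = 0;
  int idx_trace = 0, idx_keep = 0;

  const double inv_sl = 1.0 / scale_l, inv_ss = 1.0 / scale_s;
  arma::mat Z(N, rate_updates), E(N, rate_updates);
  arma::vec rp(N);

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool post_burn = iter > burn_iter;

    // -- latent log-rate updates (prior-preserving) --
    // the whole iteration's prior perturbations in one matrix product
    double* zp = Z.memptr();
    for (int i = 0; i < N * rate_updates; ++i) zp[i] = R::norm_rand();
    E = L * Z;
    const double keep = std::sqrt(1.0 - epsilon * epsilon);
    for (int u = 0; u < rate_updates; ++u) {
      rp = keep * r + epsilon * E.col(u);
      const double llp = interp_total(rp, tab, rate_min, rate_max, step);
      ++rate_prop_win;
      if (post_burn) ++rate_prop_post;
      if (std::log(R::unif_rand()) < llp - ll) {
        r = rp;
        ll = llp;
        ++rate_acc_win;
        if (post_burn) ++rate_acc_post;
      }
    }

    // -- hyperparameter update, log-scale random walk --
    if (!fix_hyper) {
      const double le = std::log(ell), ls = std::log(sigma);
      const double lep = le + hyper_step * R::norm_rand();
      const double lsp = ls + hyper_step * R::norm_rand();
      const double ellp = std::exp(lep), sigmap = std::exp(lsp);
      ++hyper_prop_win;
      if (post_burn) ++hyper_prop_post;
      arma::mat Lp;
      arma::mat Kp = cov_matrix(D, ellp, sigmap, kernel, jitter);
      if (!arma::chol(Lp, Kp, "lower")) {
        ++chol_failures;            // proposal rejected
      } else {
        // prior density of the CURRENT r under the proposed covariance,
        // exponential hyperpriors, and the log-scale Jacobian
        const double lp_prop = gp_logdens(r, Lp) - ellp * inv_sl -
                               sigmap * inv_ss + lep + lsp;
        const double lp_cur = gp_logdens(r, L) - ell * inv_sl -
                              sigma * inv_ss + le + ls;
        if (std::log(R::unif_rand()) < lp_prop - lp_cur) {
          ell = ellp;
          sigma = sigmap;
          L = Lp;
          ++hyper_acc_win;
          if (post_burn) ++hyper_acc_post;
        }
      }
    }

    // -- Robbins-Monro tuning toward the target acceptance, burn-in only --
    if (adapt && !post_burn) {
      if (iter % 25 == 0 && rate_prop_win > 0) {
        const double acc = (double)rate_acc_win / rate_prop_win;
        epsilon *= std::exp(acc - target_acc);
        if (epsilon > 1.0) epsilon = 1.0;
        if (epsilon < 1e-3) epsilon = 1e-3;
        rate_prop_win = rate_acc_win = 0;
      }
      if (!fix_hyper && iter % 50 == 0 && hyper_prop_win > 0) {
        const double acc = (double)hyper_acc_win / hyper_prop_win;
        hyper_step *= std::exp(2.0 * (acc - target_acc));
        if (hyper_step > 5.0) hyper_step = 5.0;
        if (hyper_step < 1e-3) hyper_step = 1e-3;
        hyper_prop_win = hyper_acc_win = 0;
      }
    }

    // -- thinned recording --
    if (iter % thin == 0) {
      ell_trace[idx_trace] = ell;
      sigma_trace[idx_trace] = sigma;
      ll_trace[idx_trace] = ll;
      trace_iter[idx_trace] = iter;
      ++idx_trace;
      if (post_burn && idx_keep < (int)r_draws.n_rows) {
        r_draws.row(idx_keep) = r.t();
        ++idx_keep;
      }
    }
  }

  return List::create(
    _["r_draws"] = r_draws,
    _["ell_trace"] = ell_trace,
    _["sigma_trace"] = sigma_trace,
    _["loglik_trace"] = ll_trace,
    _["trace_iter"] = trace_iter,
    _["n_burn_trace"] = burn_iter / thin,
    _["rate_proposed"] = (double)rate_prop_post,
    _["rate_accepted"] = (double)rate_acc_post,
    _["hyper_proposed"] = (double)hyper_prop_post,
    _["hyper_accepted"] = (double)hyper_acc_post,
    _["chol_failures"] = chol_failures,
    _["epsilon"] = epsilon,
    _["hyper_step"] = hyper_step);
}
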