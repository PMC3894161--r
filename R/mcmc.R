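#' Prior-preserving proposal for the log-rate vector
#'
#' Neal's underrelaxed Gaussian proposal
#' \deqn{r' = \sqrt{1 - \epsilon^2}\, r + \epsilon L z,}
#' with `z` a vector of independent standard normals and `L` the lower
#' Cholesky factor of the prior covariance.  If `r` is distributed according
#' to the zero-mean GP prior, so is `r'`, for every `epsilon`; the
#' Metropolis acceptance ratio for this move therefore reduces to the
#' likelihood ratio alone.  `epsilon = 0` is the identity, `epsilon = 1` a
#' fresh prior draw.
#'
#' @param r current log-rate vector.
#' @param L lower Cholesky factor of the prior covariance (or a
#'   [build_covariance()] object).
#' @param epsilon step size in (0, 1].
#' @return The proposed vector.
#' @export
propose_rates <- function(r, L, epsilon) {
  if (inherits(L, "gp_covariance")) L <- L$L
  if (epsilon < 0 || epsilon > 1) stop("'epsilon' must be in [0, 1]")
  sqrt(1 - epsilon^2) * r + epsilon * drop(L %*% rnorm(length(r)))
}

#' Single Metropolis updates (reference implementation)
#'
#' One update of the latent rates (`rate_update_step`) or of the
#' hyperparameter pair (`hyper_update_step`), operating on a plain state
#' list.  These R-level steps define the algorithm that the compiled
#' sampler in [phylogp()] runs; they are exported for inspection, testing
#' and small problems.
#'
#' A state is a list with elements `r`, `loglik` (total interpolated
#' log-likelihood of `r`), `cov` (a [build_covariance()]), and acceptance
#' tallies `rate_accepted`, `rate_proposed`, `hyper_accepted`,
#' `hyper_proposed`.
#'
#' @param state the current state list.
#' @param cache a [build_loglik_cache()].
#' @param epsilon rate-proposal step in (0, 1].
#' @return The updated state.
#' @export
rate_update_step <- function(state, cache, epsilon) {
  N <- length(state$r)
  rp <- propose_rates(state$r, state$cov$L, epsilon)
  llp <- sum(interp_site_loglik(cache, seq_len(N), rp))
  state$rate_proposed <- state$rate_proposed + 1L
  if (log(runif(1)) < llp - state$loglik) {
    state$r <- rp
    state$loglik <- llp
    state$rate_accepted <- state$rate_accepted + 1L
  }
  state
}

#' @rdname rate_update_step
#' @param D distance matrix the covariance is built on.
#' @param scale_l,scale_s exponential hyperprior means.
#' @param hyper_step standard deviation of the bivariate Gaussian step on
#'   `(log ell, log sigma)`.
#' @export
hyper_update_step <- function(state, D, scale_l = 100, scale_s = 10,
                              hyper_step = 0.4) {
  cov <- state$cov
  lep <- log(cov$ell) + hyper_step * rnorm(1)
  lsp <- log(cov$sigma) + hyper_step * rnorm(1)
  state$hyper_proposed <- state$hyper_proposed + 1L
  covp <- tryCatch(
    build_covariance(D, exp(lep), exp(lsp), cov$kernel, cov$jitter),
    error = function(e) {
      warning("Cholesky failed for proposed hyperparameters; proposal rejected")
      NULL
    })
  if (is.null(covp)) return(state)
  # GP density of the current r, exponential priors, log-scale Jacobian
  lp_prop <- gp_log_density(state$r, covp) +
    log_hyper_prior(covp$ell, covp$sigma, scale_l, scale_s) + lep + lsp
  lp_cur <- gp_log_density(state$r, cov) +
    log_hyper_prior(cov$ell, cov$sigma, scale_l, scale_s) +
    log(cov$ell) + log(cov$sigma)
  if (log(runif(1)) < lp_prop - lp_cur) {
    state$cov <- covp
    state$hyper_accepted <- state$hyper_accepted + 1L
  }
  state
}

kernel_id <- function(kernel) {
  match(kernel, c("matern15", "matern25", "sqexp")) - 1L
}

#' Run one MCMC chain
#'
#' Low-level driver behind [phylogp()]: executes the update schedule (many
#' latent-rate updates, then one hyperparameter update, per iteration) with
#' adaptive step-size tuning during burn-in, thinning, and post-burn-in
#' recording.  Randomness comes from R's RNG.
#'
#' @param cache a [build_loglik_cache()].
#' @param D N x N Calpha distance matrix.
#' @param kernel covariance family.
#' @param n_iter total iterations.
#' @param burn_in fraction of iterations discarded as burn-in, in (0, 1).
#' @param thin record every `thin`-th iteration.
#' @param rate_updates latent-rate updates per iteration (default 50).
#' @param epsilon,hyper_step initial proposal step sizes (tuned during
#'   burn-in toward `target_acc`, then frozen).
#' @param jitter covariance diagonal jitter.
#' @param scale_l,scale_s exponential hyperprior means.
#' @param init_ell,init_sigma initial hyperparameter values.
#' @param target_acc target acceptance rate for tuning.
#' @param adapt tune step sizes during burn-in?
#' @param fix_hyper if `TRUE`, keep `(init_ell, init_sigma)` fixed (no
#'   hyperparameter updates).
#' @return A `gp_chain` list: post-burn-in thinned `r_draws`, full thinned
#'   hyperparameter traces, acceptance statistics and tuned step sizes.
#' @export
run_chain <- function(cache, D, kernel = c("matern15", "matern25", "sqexp"),
                      n_iter = 20000, burn_in = 0.5, thin = 10,
                      rate_updates = 50, epsilon = 0.3, hyper_step = 0.4,
                      jitter = 1e-6, scale_l = 100, scale_s = 10,
                      init_ell = NULL, init_sigma = 1, target_acc = 0.25,
                      adapt = TRUE, fix_hyper = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(cache, "loglik_cache"))
  D <- as.matrix(D)
  N <- cache$n_sites
  if (nrow(D) != N)
    stop("distance matrix dimension (", nrow(D),
         ") does not match the number of sites (", N, ")")
  if (n_iter < thin) stop("'n_iter' must be at least 'thin'")
  if (burn_in <= 0 || burn_in >= 1) stop("'burn_in' must be in (0, 1)")
  if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must be in (0, 1]")
  if (is.null(init_ell)) init_ell <- 2 * mean_nn_distance(D)
  burn_iter <- floor(n_iter * burn_in)

  cov0 <- build_covariance(D, init_ell, init_sigma, kernel, jitter)
  r0 <- drop(cov0$L %*% rnorm(N))

  res <- .run_chain_cpp(D, t(cache$table), cache$rate_min, cache$rate_max,
                        cache$step, kernel_id(kernel), jitter,
                        scale_l, scale_s,
                        as.integer(n_iter), as.integer(rate_updates),
                        as.integer(thin), as.integer(burn_iter),
                        epsilon, hyper_step, init_ell, init_sigma, r0,
                        target_acc, adapt, fix_hyper)
  if (res$chol_failures > 0)
    warning(res$chol_failures,
            " hyperparameter proposal(s) rejected on Cholesky failure")
  res$n_iter <- n_iter
  res$burn_iter <- burn_iter
  res$thin <- thin
  res$kernel <- kernel
  res$rate_rate <- res$rate_accepted / max(res$rate_proposed, 1)
  res$hyper_rate <- res$hyper_accepted / max(res$hyper_proposed, 1)
  class(res) <- "gp_chain"
  res
}

mean_nn_distance <- function(D) {
  if (nrow(D) < 2) return(1)
  mean(apply(D + diag(Inf, nrow(D)), 1, min))
}

#' @export
print.gp_chain <- function(x, ...) {
  cat("MCMC chain: ", x$n_iter, " iterations (burn-in ", x$burn_iter,
      ", thin ", x$thin, "), ", nrow(x$r_draws), " recorded draws\n", sep = "")
  cat(sprintf("  post-burn-in acceptance: rates %.3f, hyperparameters %.3f\n",
              x$rate_rate, x$hyper_rate))
  invisible(x)
}
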