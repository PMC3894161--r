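#' Discretized Gamma distribution of rates across sites
#'
#' Equal-probability discretization of a Gamma distribution with mean 1
#' (shape = rate = `alpha`): category boundaries are the `k/C` quantiles and
#' each category's representative rate is the mean of the Gamma within its
#' bin, then the mean of the discretized distribution is renormalized to 1.
#'
#' @param alpha Gamma shape parameter, > 0.
#' @param n_categories number of rate categories (>= 1).
#' @return An object of class `gamma_rates`: list with `alpha`, `rates`,
#'   `probs` (uniform) and `n_categories`.
#' @export
discretize_gamma <- function(alpha, n_categories = 16) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  stopifnot(n_categories >= 1)
  C <- as.integer(n_categories)
  q <- qgamma(seq(0, 1, length.out = C + 1L), shape = alpha, rate = alpha)
  # mean of Gamma(alpha, alpha) within each bin: incomplete-gamma identity
  pg <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- C * diff(pg)
  rates <- rates / mean(rates)   # kill residual float error; mean exactly 1
  structure(list(alpha = alpha, rates = rates, probs = rep(1 / C, C),
                 n_categories = C),
            class = "gamma_rates")
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat("Discrete Gamma rates: alpha = ", format(x$alpha), ", ",
      x$n_categories, " categories, mean ", format(sum(x$probs * x$rates)),
      "\n", sep = "")
  invisible(x)
}

#' i.i.d. discrete-Gamma site-rate estimation (empirical Bayes)
#'
#' The comparator model: site rates are independent draws from a mean-1
#' discrete Gamma distribution.  The shape `alpha` is fitted by maximizing
#' the marginal likelihood \eqn{\sum_i \log \sum_c (1/C) L_i(r_c)} by 1-D
#' bounded optimization, and each site's estimate is its empirical-Bayes
#' posterior mean rate \eqn{\sum_c r_c w_{ic}} with \eqn{w_{ic} \propto
#' L_i(r_c)}.  This is a reimplementation of the model class behind
#' Rate4Site-style conservation scoring, not a port of that program.
#'
#' @param alignment an [aa_alignment()].
#' @param tree an [ape::phylo] tree matching the alignment.
#' @param model a [substitution_model()]; default JTT.
#' @param n_categories number of Gamma categories (default 16).
#' @param cache optional precomputed [build_loglik_cache()]; built on the
#'   fly otherwise.
#' @param alpha_bounds search interval for the shape parameter.
#' @return An object of class `iid_rates`: list with per-site posterior mean
#'   `rates`, fitted `alpha`, `logLik` and the discretization.
#' @export
fit_iid_rates <- function(alignment, tree, model = jtt_model(),
                          n_categories = 16, cache = NULL,
                          alpha_bounds = c(0.02, 100)) {
  if (is.null(cache)) cache <- build_loglik_cache(alignment, tree, model)
  N <- cache$n_sites

  site_ll_matrix <- function(alpha) {
    dg <- discretize_gamma(alpha, n_categories)
    matrix(vapply(dg$rates, function(rc)
      interp_site_loglik(cache, seq_len(N), rep(log(rc), N)),
      numeric(N)), nrow = N)            # N x C
  }
  marginal_ll <- function(alpha) {
    ll <- site_ll_matrix(alpha)
    m <- apply(ll, 1L, max)
    sum(m + log(rowMeans(exp(ll - m))))
  }
  opt <- optimize(marginal_ll, interval = alpha_bounds, maximum = TRUE,
                  tol = 1e-4)
  alpha <- opt$maximum
  # boundary report: snap to the bound when the optimum sits against it
  if (alpha > alpha_bounds[2] * 0.999) alpha <- alpha_bounds[2]
  if (alpha < alpha_bounds[1] * 1.001) alpha <- alpha_bounds[1]

  dg <- discretize_gamma(alpha, n_categories)
  ll <- site_ll_matrix(alpha)
  m <- apply(ll, 1L, max)
  w <- exp(ll - m)
  w <- w / rowSums(w)
  structure(list(rates = drop(w %*% dg$rates), alpha = alpha,
                 logLik = opt$objective, gamma = dg,
                 n_categories = n_categories),
            class = "iid_rates")
}

#' @export
print.iid_rates <- function(x, ...) {
  cat("i.i.d. discrete-Gamma rate fit: ", length(x$rates), " sites, alpha = ",
      format(x$alpha, digits = 4), " (", x$n_categories,
      " categories), logLik = ", format(x$logLik, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
coef.iid_rates <- function(object, ...) c(alpha = object$alpha)

#' @export
fitted.iid_rates <- function(object, ...) object$rates
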