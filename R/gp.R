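#' Spatial covariance kernels for log substitution rates
#'
#' Stationary kernels on Calpha--Calpha Euclidean distance.  The default,
#' Matern 1.5, is the roughest of the three and suits proteins whose
#' functional patches may be small; Matern 2.5 and the squared exponential
#' give progressively smoother latent rate fields.  A fixed jitter is added
#' on the diagonal (`same_site = TRUE`) to keep the Cholesky factorization
#' stable.
#'
#' The forms, with distance `d`, characteristic length `ell` and signal
#' standard deviation `sigma`:
#' \deqn{matern15: \sigma^2 (1 + \sqrt{3} d/\ell) e^{-\sqrt{3} d/\ell}}
#' \deqn{matern25: \sigma^2 (1 + \sqrt{5} d/\ell + 5 d^2/(3\ell^2)) e^{-\sqrt{5} d/\ell}}
#' \deqn{sqexp:    \sigma^2 e^{-d^2/(2\ell^2)}}
#'
#' @param d distance(s) in Angstroms, >= 0; vectorized.
#' @param ell characteristic length scale (Angstroms), > 0.
#' @param sigma signal standard deviation (unitless), > 0.
#' @param kernel one of `"matern15"`, `"matern25"`, `"sqexp"`.
#' @param jitter diagonal noise, added where `same_site` is `TRUE`.
#' @param same_site logical, is this a diagonal (i == j) entry; recycled.
#' @return Covariance value(s).
#' @export
kernel_value <- function(d, ell, sigma, kernel = c("matern15", "matern25", "sqexp"),
                         jitter = 1e-6, same_site = FALSE) {
  kernel <- match.arg(kernel)
  if (any(d < 0)) stop("distances must be non-negative")
  stopifnot(ell > 0, sigma > 0, jitter >= 0)
  x <- d / ell
  k <- switch(kernel,
    matern15 = sigma^2 * (1 + sqrt(3) * x) * exp(-sqrt(3) * x),
    matern25 = sigma^2 * (1 + sqrt(5) * x + 5 * x^2 / 3) * exp(-sqrt(5) * x),
    sqexp    = sigma^2 * exp(-x^2 / 2))
  k + jitter * rep_len(as.numeric(same_site), length(k))
}

#' Build the GP covariance matrix and its Cholesky factor
#'
#' @param D symmetric matrix of pairwise Calpha distances (Angstroms).
#' @inheritParams kernel_value
#' @return An object of class `gp_covariance`: list with `K`, the lower
#'   Cholesky factor `L`, `logdet` (log determinant of `K`) and the
#'   parameters used.
#' @export
build_covariance <- function(D, ell, sigma,
                             kernel = c("matern15", "matern25", "sqexp"),
                             jitter = 1e-6) {
  kernel <- match.arg(kernel)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0))
    stop("'D' must be a symmetric distance matrix with a zero diagonal")
  n <- nrow(D)
  K <- kernel_value(D, ell, sigma, kernel, jitter = 0)
  dim(K) <- c(n, n)
  K <- (K + t(K)) / 2
  diag(K) <- diag(K) + jitter
  L <- tryCatch(t(chol(K)), error = function(e)
    stop("Cholesky factorization failed (ell = ", format(ell), ", sigma = ",
         format(sigma), ", jitter = ", format(jitter), "): ",
         conditionMessage(e)))
  structure(list(K = K, L = L, logdet = 2 * sum(log(diag(L))),
                 ell = ell, sigma = sigma, kernel = kernel, jitter = jitter),
            class = "gp_covariance")
}

#' @export
print.gp_covariance <- function(x, ...) {
  cat("GP covariance (", x$kernel, "): ", nrow(x$K), " sites, ell = ",
      format(x$ell), " A, sigma = ", format(x$sigma), "\n", sep = "")
  invisible(x)
}

#' Multivariate normal log-density of a log-rate vector under the GP prior
#'
#' Computed through the stored Cholesky factor; no explicit inverse or
#' determinant is formed.
#'
#' @param r numeric vector of log rates.
#' @param cov a [build_covariance()] object of matching dimension.
#' @return The log prior density.
#' @export
gp_log_density <- function(r, cov) {
  stopifnot(inherits(cov, "gp_covariance"))
  n <- nrow(cov$K)
  if (length(r) != n)
    stop("length of 'r' (", length(r), ") does not match covariance dimension (",
         n, ")")
  y <- forwardsolve(cov$L, r)
  -0.5 * sum(y^2) - 0.5 * cov$logdet - n / 2 * log(2 * pi)
}

#' Exponential hyperpriors on the GP hyperparameters
#'
#' Independent exponential priors on the characteristic length `ell` and the
#' signal standard deviation `sigma`, parameterized by their means
#' (`scale_l`, `scale_s`).  Large scales give weakly informative priors.
#' Non-positive arguments return `-Inf` (an impossible state), not an error.
#'
#' @param ell,sigma hyperparameter values.
#' @param scale_l prior mean of `ell` in Angstroms (default 100).
#' @param scale_s prior mean of `sigma` (default 10).
#' @return Joint log prior density.
#' @export
log_hyper_prior <- function(ell, sigma, scale_l = 100, scale_s = 10) {
  stopifnot(scale_l > 0, scale_s > 0)
  if (!is.finite(ell) || !is.finite(sigma) || ell <= 0 || sigma <= 0)
    return(-Inf)
  dexp(ell, rate = 1 / scale_l, log = TRUE) +
    dexp(sigma, rate = 1 / scale_s, log = TRUE)
}
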