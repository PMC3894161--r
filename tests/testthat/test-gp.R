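test_that("kernels evaluate to their closed forms", {
  # (1 + sqrt(3)) exp(-sqrt(3)), evaluated to 30 digits with arbitrary
  # precision arithmetic and frozen here
  expect_equal(kernel_value(1, ell = 1, sigma = 1, "matern15", jitter = 0),
               0.483357724596507650595075082258, tolerance = 1e-15)
  expect_equal(kernel_value(0, 3, 2, "matern15", jitter = 1e-4, same_site = TRUE),
               4 + 1e-4)
  for (k in c("matern15", "matern25", "sqexp")) {
    expect_equal(kernel_value(0, 7, 1.5, k, jitter = 0), 1.5^2)
    expect_lt(kernel_value(50 * 7, 7, 1.5, k, jitter = 0), 1e-12 * 1.5^2)
  }
  expect_error(kernel_value(-1, 1, 1), "non-negative")
})

test_that("kernels are monotone in distance and in length scale", {
  d <- seq(0, 60, by = 0.5)
  set.seed(1)
  for (k in c("matern15", "matern25", "sqexp")) {
    for (i in 1:3) {
      ell <- runif(1, 1, 30); sigma <- runif(1, 0.2, 3)
      v <- kernel_value(d, ell, sigma, k, jitter = 0)
      expect_true(all(diff(v) < 0))
      # larger length scale, stronger correlation at fixed d > 0
      expect_true(all(kernel_value(d[-1], ell * 2, sigma, k, jitter = 0) > v[-1]))
    }
  }
})

test_that("covariance matrices are PD with jitter and match limiting cases", {
  # near-zero length scale: no spatial correlation
  D <- pairwise_distances(make_2d_grid(3, 3, spacing = 5))
  cv <- build_covariance(D, ell = 1e-6, sigma = 1.3, jitter = 1e-6)
  expect_equal(cv$K, (1.3^2 + 1e-6) * diag(9), tolerance = 1e-10)
  # coincident points: off-diagonal sigma^2, still PD
  D0 <- matrix(0, 2, 2)
  cv0 <- build_covariance(D0, ell = 5, sigma = 2, jitter = 1e-6)
  expect_equal(cv0$K[1, 2], 4)
  expect_equal(cv0$K[1, 1], 4 + 1e-6)
  expect_equal(cv0$L %*% t(cv0$L), cv0$K, tolerance = 1e-8)
  # random 30-site cloud: smallest eigenvalue >= jitter (dense eigensolver)
  set.seed(9)
  Dr <- pairwise_distances(matrix(runif(90, 0, 40), 30, 3))
  cvr <- build_covariance(Dr, ell = 12, sigma = 1.7, jitter = 1e-6)
  expect_gte(min(eigen(cvr$K, symmetric = TRUE, only.values = TRUE)$values),
             1e-6 - 1e-10)
  expect_error(build_covariance(matrix(c(0, 1, 2, 0), 2, 2), 1, 1), "symmetric")
})

test_that("compiled and R kernel matrices agree", {
  set.seed(4)
  D <- pairwise_distances(matrix(runif(60, 0, 30), 20, 3))
  for (kid in 0:2) {
    kn <- c("matern15", "matern25", "sqexp")[kid + 1]
    expect_equal(phylogp:::.cov_matrix_cpp(D, 8.5, 1.4, kid, 1e-6),
                 build_covariance(D, 8.5, 1.4, kn, 1e-6)$K, tolerance = 1e-12)
  }
})

test_that("gp_log_density matches explicit inverse/determinant computation", {
  set.seed(11)
  D <- pairwise_distances(matrix(runif(15, 0, 20), 5, 3))
  cv <- build_covariance(D, ell = 9, sigma = 1.2, jitter = 1e-6)
  r <- rnorm(5)
  oracle <- -0.5 * drop(t(r) %*% solve(cv$K) %*% r) -
    0.5 * log(det(cv$K)) - 2.5 * log(2 * pi)
  expect_equal(gp_log_density(r, cv), oracle, tolerance = 1e-9)
  # r = 0: quadratic form vanishes
  expect_equal(gp_log_density(rep(0, 5), cv),
               -0.5 * log(det(cv$K)) - 2.5 * log(2 * pi), tolerance = 1e-9)
  # N = 1 reduces to the univariate normal density
  cv1 <- build_covariance(matrix(0, 1, 1), ell = 5, sigma = 0.8, jitter = 0)
  expect_equal(gp_log_density(0.33, cv1),
               stats::dnorm(0.33, 0, 0.8, log = TRUE), tolerance = 1e-12)
  expect_error(gp_log_density(rnorm(4), cv), "match")
})

test_that("exponential hyperpriors have the stated closed form and integrate to 1", {
  expect_equal(log_hyper_prior(100, 10, scale_l = 100, scale_s = 10),
               log(exp(-1) / 100) + log(exp(-1) / 10), tolerance = 1e-12)
  # joint density at 0+ approaches the product of the modes, 1/(scale_l scale_s)
  expect_equal(exp(log_hyper_prior(1e-12, 1e-12, 100, 10)),
               1 / (100 * 10), tolerance = 1e-9)
  expect_identical(log_hyper_prior(-1, 1), -Inf)
  expect_identical(log_hyper_prior(1, 0), -Inf)
  marg <- stats::integrate(function(x) exp(dexp(x, 1 / 100, log = TRUE)),
                           0, Inf)$value
  expect_equal(marg, 1, tolerance = 1e-6)
})

test_that("prior draws reproduce the expected mean log-density (Monte Carlo)", {
  set.seed(21)
  D <- pairwise_distances(matrix(runif(30, 0, 25), 10, 3))
  cv <- build_covariance(D, ell = 10, sigma = 1, jitter = 1e-6)
  n <- 1e4
  ld <- replicate(n, gp_log_density(drop(cv$L %*% rnorm(10)), cv))
  # E[log p(r)] = -N/2 log(2 pi) - 1/2 log|K| - N/2
  expected <- -5 * log(2 * pi) - 0.5 * cv$logdet - 5
  expect_lt(abs(mean(ld) - expected), 3 * sd(ld) / sqrt(n))
})

test_that("Matern 2.5 sample paths are smoother than Matern 1.5", {
  set.seed(31)
  x <- seq(0, 20, by = 0.4)
  D <- abs(outer(x, x, "-"))
  msd <- sapply(c("matern15", "matern25"), function(k) {
    cv <- build_covariance(D, ell = 8, sigma = 1, kernel = k, jitter = 1e-9)
    mean(replicate(200, mean(diff(drop(cv$L %*% rnorm(length(x))))^2)))
  })
  expect_lt(msd["matern25"], msd["matern15"])
})
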