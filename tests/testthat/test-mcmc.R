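test_that("the underrelaxed proposal has the stated limiting cases", {
  set.seed(5)
  D <- pairwise_distances(matrix(runif(15, 0, 20), 5, 3))
  cv <- build_covariance(D, ell = 8, sigma = 1, jitter = 1e-6)
  r <- rnorm(5)
  expect_identical(propose_rates(r, cv, 0), r)
  # epsilon = 1: a fresh prior draw, L z, independent of r
  set.seed(77); z <- rnorm(5)
  set.seed(77)
  expect_equal(propose_rates(r, cv, 1), drop(cv$L %*% z), tolerance = 1e-12)
  expect_error(propose_rates(r, cv, 1.2), "epsilon")
})

test_that("the proposal leaves the GP prior invariant (empirical covariance)", {
  set.seed(6)
  D <- pairwise_distances(matrix(runif(15, 0, 12), 5, 3))
  cv <- build_covariance(D, ell = 6, sigma = 1, jitter = 1e-6)
  n <- 1e4
  eps <- 0.4
  r <- t(cv$L %*% matrix(rnorm(5 * n), 5))        # r ~ N(0, K)
  rp <- t(apply(r, 1, function(x) propose_rates(x, cv, eps)))
  emp <- crossprod(rp) / n
  expect_lt(max(abs(emp - cv$K)), 4 * max(cv$K) / sqrt(n) * 3)
  expect_lt(max(abs(colMeans(rp))), 0.05)
})

test_that("rate updates always accept when the likelihood is flat", {
  m <- jtt_model()
  tree <- simulation_tree()
  gaps <- aa_alignment(matrix("-", 4, 6, dimnames = list(tree$tip.label, NULL)))
  cache <- build_loglik_cache(gaps, tree, m, grid_size = 20)
  D <- pairwise_distances(make_2d_grid(2, 3))
  cv <- build_covariance(D, 8, 1)
  st <- list(r = drop(cv$L %*% rnorm(6)), cov = cv,
             rate_proposed = 0L, rate_accepted = 0L,
             hyper_proposed = 0L, hyper_accepted = 0L)
  st$loglik <- sum(interp_site_loglik(cache, 1:6, st$r))
  set.seed(8)
  for (i in 1:1000) st <- rate_update_step(st, cache, 0.5)
  expect_identical(st$rate_accepted, 1000L)
  expect_identical(st$rate_proposed, 1000L)

  # epsilon -> 0 is a null move: always accepted even with data
  aln <- tiny_alignment()
  cache2 <- build_loglik_cache(aln, tree, m, grid_size = 20)
  cv2 <- build_covariance(pairwise_distances(make_2d_grid(1, 5)), 8, 1)
  st2 <- list(r = rnorm(5, 0, 0.1), cov = cv2,
              rate_proposed = 0L, rate_accepted = 0L,
              hyper_proposed = 0L, hyper_accepted = 0L)
  st2$loglik <- sum(interp_site_loglik(cache2, 1:5, st2$r))
  for (i in 1:200) st2 <- rate_update_step(st2, cache2, 1e-8)
  expect_identical(st2$rate_accepted, 200L)
})

test_that("a zero-width hyperparameter proposal is always accepted", {
  D <- pairwise_distances(make_2d_grid(2, 2))
  cv <- build_covariance(D, 8, 1)
  st <- list(r = rnorm(4, 0, 0.5), cov = cv, loglik = 0,
             rate_proposed = 0L, rate_accepted = 0L,
             hyper_proposed = 0L, hyper_accepted = 0L)
  set.seed(10)
  for (i in 1:50) st <- hyper_update_step(st, D, hyper_step = 0)
  expect_identical(st$hyper_accepted, 50L)
  expect_equal(st$cov$ell, 8)
  expect_equal(st$cov$sigma, 1)
})

test_that("chain bookkeeping: draw counts, determinism, acceptance tallies", {
  m <- jtt_model()
  tree <- simulation_tree()
  d <- sim_dataset(12, rows = 2, cols = 3, block = 1)
  cache <- build_loglik_cache(d$aln, tree, m, grid_size = 100)
  D <- pairwise_distances(d$grid)
  set.seed(1)
  ch <- run_chain(cache, D, n_iter = 100, burn_in = 0.5, thin = 10,
                  rate_updates = 5)
  expect_identical(nrow(ch$r_draws), 5L)           # floor(50 / 10)
  expect_identical(length(ch$ell_trace), 10L)
  expect_lte(ch$rate_accepted, ch$rate_proposed)
  expect_identical(ch$rate_proposed, 5 * 50)       # post-burn-in proposals
  expect_identical(ch$hyper_proposed, 50)
  set.seed(1)
  ch2 <- run_chain(cache, D, n_iter = 100, burn_in = 0.5, thin = 10,
                   rate_updates = 5)
  expect_identical(ch$r_draws, ch2$r_draws)        # bit-identical given seed
  expect_identical(ch$ell_trace, ch2$ell_trace)
  set.seed(2)
  ch3 <- run_chain(cache, D, n_iter = 100, burn_in = 0.5, thin = 10,
                   rate_updates = 5)
  expect_false(identical(ch$r_draws, ch3$r_draws))
})

test_that("summaries pool chains, are order-invariant, and match closed forms", {
  # hand-built fit objects exercise the summary path in isolation
  fake_chain <- function(r_draws, ell, sigma) {
    list(r_draws = r_draws, ell_trace = ell, sigma_trace = sigma,
         trace_iter = seq(20, by = 10, length.out = length(ell)),
         burn_iter = 10, rate_rate = 0.25, hyper_rate = 0.25)
  }
  fake_fit <- function(chains, N) {
    structure(list(chains = chains, N = N, columns = seq_len(N),
                   coords = NULL, kernel = "matern15", n_iter = 100,
                   burn_in = 0.1, thin = 10, taxa = c("a", "b")),
              class = "phylogp")
  }
  # all draws identical: mean rate = exp(r), zero-width intervals
  r <- matrix(rep(c(-0.5, 0.2), each = 4), 4, 2)
  s1 <- summary(fake_fit(list(fake_chain(r, rep(7, 4), rep(1, 4))), 2))
  expect_equal(s1$rates$mean_rate, exp(c(-0.5, 0.2)))
  expect_equal(s1$rates$lower, s1$rates$upper)
  expect_equal(s1$ell_median, 7)

  # two chains with swapped draw order give identical summaries
  set.seed(3)
  A <- matrix(rnorm(20), 10, 2)
  B <- A[10:1, ]
  f1 <- fake_fit(list(fake_chain(A, 1:10, 1:10),
                      fake_chain(B, 10:1, 10:1)), 2)
  f2 <- fake_fit(list(fake_chain(B, 10:1, 10:1),
                      fake_chain(A, 1:10, 1:10)), 2)
  expect_equal(summary(f1)$rates, summary(f2)$rates)
  expect_equal(summary(f1)$ell_median, summary(f2)$ell_median)

  # draws from a known lognormal: mean rate within 3 MC standard errors
  set.seed(4)
  n <- 4000
  draws <- matrix(rnorm(n, meanlog <- 0.3, 0.4), n, 1)
  s3 <- summary(fake_fit(list(fake_chain(draws, rep(1, n), rep(1, n))), 1))
  true_mean <- exp(0.3 + 0.4^2 / 2)
  mc_se <- sd(exp(draws)) / sqrt(n)
  expect_lt(abs(s3$rates$mean_rate - true_mean), 3 * mc_se)
})

test_that("fits are reproducible end-to-end given a seed", {
  d <- sim_dataset(33, rows = 3, cols = 3, block = 3)
  f1 <- phylogp(d$aln, simulation_tree(), d$grid, chains = 2, n_iter = 200,
                grid_size = 50, seed = 99)
  f2 <- phylogp(d$aln, simulation_tree(), d$grid, chains = 2, n_iter = 200,
                grid_size = 50, seed = 99)
  expect_identical(fitted(f1), fitted(f2))
  expect_identical(coef(f1), coef(f2))
})
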