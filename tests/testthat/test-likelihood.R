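test_that("two-taxon pruning matches the single-internal-node summation", {
  m <- jtt_model()
  tree <- read_newick(text = "(A:0.13,B:0.41);")
  for (pair in list(c("A", "A"), c("R", "W"), c("C", "C"))) {
    for (rate in c(0.2, 1, 3.7)) {
      col <- setNames(pair, c("A", "B"))
      direct <- log(sum(m$freqs *
                          transition_matrix(m, 0.13 * rate)[, match(pair[1], phylogp:::AA_ALPHABET)] *
                          transition_matrix(m, 0.41 * rate)[, match(pair[2], phylogp:::AA_ALPHABET)]))
      expect_equal(site_log_likelihood(col, tree, m, rate), direct,
                   tolerance = 1e-10)
    }
  }
})

test_that("four-taxon pruning matches brute-force enumeration of internal states", {
  m <- jtt_model()
  tree <- simulation_tree()
  cols <- list(c(t1 = "A", t2 = "A", t3 = "A", t4 = "A"),
               c(t1 = "A", t2 = "R", t3 = "N", t4 = "D"),
               c(t1 = "W", t2 = "W", t3 = "-", t4 = "F"),
               c(t1 = "K", t2 = "X", t3 = "K", t4 = "E"))
  for (col in cols) {
    for (rate in c(0.5, 1.6)) {
      expect_equal(site_log_likelihood(col, tree, m, rate),
                   brute_force_site_loglik(col, tree, m, rate),
                   tolerance = 1e-8)
    }
  }
})

test_that("gaps are missing data and all-gap columns give exactly zero", {
  m <- jtt_model()
  tree <- simulation_tree()
  gap <- c(t1 = "-", t2 = "-", t3 = "X", t4 = "-")
  expect_identical(site_log_likelihood(gap, tree, m, 0.7), 0)
  expect_error(site_log_likelihood(gap, tree, m, 0), "positive")
  expect_error(site_log_likelihood(gap, tree, m, -1), "positive")
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  m <- jtt_model()
  aln <- tiny_alignment()
  tree <- simulation_tree()
  ll <- vapply(seq_len(ncol(aln)), function(i)
    site_log_likelihood(aln[, i], tree, m, 1.3), numeric(1))
  for (og in c("t1", "t3")) {
    rerooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
    ll2 <- vapply(seq_len(ncol(aln)), function(i)
      site_log_likelihood(aln[, i], rerooted, m, 1.3), numeric(1))
    expect_equal(ll2, ll, tolerance = 1e-9)
  }
})

test_that("total likelihood agrees with phangorn's pruning implementation", {
  # independent cross-check of the whole likelihood path under JTT
  m <- jtt_model()
  tree <- simulation_tree()
  d <- sim_dataset(42, rows = 4, cols = 5, block = 1)
  ours <- sum(vapply(seq_len(ncol(d$aln)), function(i)
    site_log_likelihood(d$aln[, i], tree, m, 1), numeric(1)))
  phy <- phangorn::phyDat(unclass(d$aln), type = "AA")
  fit <- phangorn::pml(tree, phy, model = "JTT")
  expect_equal(ours, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("the cache grid is uniform and exact at grid points", {
  m <- jtt_model()
  tree <- simulation_tree()
  aln <- tiny_alignment()
  cache <- build_loglik_cache(aln, tree, m, grid_size = 50, rate_max = 20,
                              rate_min = 0.005)
  expect_equal(dim(cache$table), c(5L, 50L))
  sp <- diff(cache$rate_grid)
  expect_equal(sp, rep(sp[1], 49), tolerance = 1e-12)
  # default grid spacing equals rate_min itself
  expect_equal((20 - 0.005) / 3999, 0.005, tolerance = 1e-6)
  for (g in c(1L, 17L, 50L))
    expect_equal(cache$table[2, g],
                 site_log_likelihood(aln[, 2], tree, m, cache$rate_grid[g]),
                 tolerance = 1e-12)
  # single-column alignment gives a 1 x G table
  c1 <- build_loglik_cache(aln[, 1, drop = FALSE], tree, m, grid_size = 10)
  expect_equal(dim(c1$table), c(1L, 10L))
  expect_error(build_loglik_cache(aln, tree, m, rate_min = 0), "positive")
})

test_that("interpolation is exact at nodes, linear between, clamped outside", {
  m <- jtt_model()
  tree <- simulation_tree()
  aln <- tiny_alignment()
  cache <- build_loglik_cache(aln, tree, m, grid_size = 100)
  g <- cache$rate_grid
  expect_equal(interp_site_loglik(cache, 3, log(g[40])), cache$table[3, 40])
  mid <- (g[40] + g[41]) / 2
  expect_equal(interp_site_loglik(cache, 3, log(mid)),
               (cache$table[3, 40] + cache$table[3, 41]) / 2, tolerance = 1e-12)
  expect_equal(interp_site_loglik(cache, 1, log(50)), cache$table[1, 100])
  expect_equal(interp_site_loglik(cache, 1, log(1e-9)), cache$table[1, 1])
})

test_that("default-grid interpolation error is small across the working range", {
  m <- jtt_model()
  tree <- simulation_tree()
  set.seed(3)
  field <- rep(1, 8)
  aln <- simulate_alignment(tree, m, field)
  cache <- build_loglik_cache(aln, tree, m)  # default 4000-point grid
  # log-likelihoods curve like k log(rate) near zero, so the uniform rate
  # grid is least accurate just above its floor: require < 0.01 log units
  # over [0.05, 19] and < 0.05 down to 0.01
  rates <- exp(runif(60, log(0.05), log(19)))
  sites <- sample.int(8, 60, replace = TRUE)
  exact <- mapply(function(s, r) site_log_likelihood(aln[, s], tree, m, r),
                  sites, rates)
  approx <- interp_site_loglik(cache, sites, log(rates))
  expect_lt(max(abs(exact - approx)), 0.01)

  low <- exp(runif(40, log(0.01), log(0.05)))
  sl <- sample.int(8, 40, replace = TRUE)
  exact_low <- mapply(function(s, r) site_log_likelihood(aln[, s], tree, m, r),
                      sl, low)
  approx_low <- interp_site_loglik(cache, sl, log(low))
  expect_lt(max(abs(exact_low - approx_low)), 0.05)
})
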