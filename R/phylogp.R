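#' Fit the phylogenetic Gaussian process rate model
#'
#' Bayesian inference of spatially correlated site-specific amino-acid
#' substitution rates.  The log rates follow a zero-mean Gaussian process
#' over the structure's pairwise Calpha distances; the data enter through
#' the standard pruning likelihood on a fixed tree under the JTT model,
#' cached on a rate grid and interpolated.  Posterior sampling uses a
#' Metropolis scheme with prior-preserving latent updates (many per
#' iteration) and log-scale hyperparameter updates (one per iteration),
#' with step sizes tuned during burn-in toward a 0.25 acceptance rate.
#'
#' By default two independent chains are run and pooled after burn-in.
#'
#' @param alignment an [aa_alignment()] (or a path, read via
#'   [read_alignment()]).
#' @param tree an [ape::phylo] tree with branch lengths whose tips match the
#'   alignment taxa (or a path, read via [read_newick()]).
#' @param structure a [structure_coords()] with one point per alignment
#'   column (e.g. from [make_2d_grid()] or [map_structure_to_alignment()]),
#'   or directly an N x N distance matrix.  If the structure carries an
#'   alignment-column mapping, unmapped columns are dropped from the model.
#' @param model a [substitution_model()]; default JTT.
#' @param kernel covariance family: `"matern15"` (default), `"matern25"` or
#'   `"sqexp"`.
#' @param chains number of independent chains (default 2).
#' @param n_iter iterations per chain (default 20000).
#' @param burn_in fraction discarded as burn-in (default 0.5).
#' @param thin record every `thin`-th iteration (default 10).
#' @param rate_updates latent-rate updates per iteration (default 50).
#' @param epsilon,hyper_step initial proposal steps, tuned during burn-in.
#' @param jitter covariance diagonal jitter (default 1e-6).
#' @param prior_scale_l,prior_scale_s exponential hyperprior means for the
#'   characteristic length (Angstroms) and signal standard deviation.
#' @param grid_size,rate_max,rate_min likelihood cache grid (defaults 4000
#'   points up to rate 20).
#' @param init_ell initial characteristic length; default twice the mean
#'   nearest-neighbor Calpha distance.
#' @param init_sigma initial signal standard deviation.
#' @param fix_hyper fix the hyperparameters at their initial values instead
#'   of sampling them.
#' @param seed optional RNG seed; with the same seed the fit is fully
#'   reproducible.
#' @param cache optional precomputed [build_loglik_cache()] (must match the
#'   modeled columns).
#' @param verbose print per-chain progress.
#' @return An object of class `phylogp` with [summary.phylogp()],
#'   [coef.phylogp()], [fitted.phylogp()] and [plot.phylogp()] methods.
#' @examples
#' \donttest{
#' set.seed(1)
#' grid <- make_2d_grid(4, 4)
#' field <- block_rate_field(grid, block = 2)
#' aln <- simulate_alignment(simulation_tree(), jtt_model(), field)
#' fit <- phylogp(aln, simulation_tree(), grid, chains = 1, n_iter = 500,
#'                grid_size = 200, seed = 1)
#' summary(fit)
#' }
#' @export
phylogp <- function(alignment, tree, structure, model = jtt_model(),
                    kernel = c("matern15", "matern25", "sqexp"),
                    chains = 2, n_iter = 20000, burn_in = 0.5, thin = 10,
                    rate_updates = 50, epsilon = 0.3, hyper_step = 0.4,
                    jitter = 1e-6, prior_scale_l = 100, prior_scale_s = 10,
                    grid_size = 4000, rate_max = 20,
                    rate_min = rate_max / grid_size,
                    init_ell = NULL, init_sigma = 1, fix_hyper = FALSE,
                    seed = NULL, cache = NULL, verbose = FALSE) {
  cl <- match.call()
  kernel <- match.arg(kernel)
  if (is.character(alignment) && !is.matrix(alignment))
    alignment <- read_alignment(alignment)
  if (!inherits(alignment, "aa_alignment")) alignment <- aa_alignment(alignment)
  if (is.character(tree)) tree <- read_newick(tree)

  columns <- seq_len(ncol(alignment))
  if (inherits(structure, "structure_coords")) {
    if (!is.null(structure$column)) columns <- structure$column
    D <- pairwise_distances(structure)
    coords <- structure
  } else {
    D <- as.matrix(structure)
    coords <- NULL
  }
  if (length(columns) != nrow(D))
    stop("structure has ", nrow(D), " sites but ", length(columns),
         " alignment columns are modeled")
  aln_used <- alignment[, columns, drop = FALSE]

  if (!is.null(seed)) set.seed(seed)
  if (is.null(cache))
    cache <- build_loglik_cache(aln_used, tree, model, grid_size = grid_size,
                                rate_max = rate_max, rate_min = rate_min)
  else if (cache$n_sites != nrow(D))
    stop("supplied cache does not match the number of modeled sites")

  chain_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (verbose) message("chain ", ch, "/", chains, " ...")
    chain_list[[ch]] <- run_chain(
      cache, D, kernel = kernel, n_iter = n_iter, burn_in = burn_in,
      thin = thin, rate_updates = rate_updates, epsilon = epsilon,
      hyper_step = hyper_step, jitter = jitter, scale_l = prior_scale_l,
      scale_s = prior_scale_s, init_ell = init_ell, init_sigma = init_sigma,
      fix_hyper = fix_hyper)
  }

  structure(list(chains = chain_list, call = cl, N = nrow(D),
                 columns = columns, coords = coords, kernel = kernel,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 prior_scale_l = prior_scale_l, prior_scale_s = prior_scale_s,
                 taxa = rownames(alignment), seed = seed),
            class = "phylogp")
}

# pooled post-burn-in draws across chains
pooled_draws <- function(object) {
  post <- lapply(object$chains, function(ch) {
    keep <- ch$trace_iter > ch$burn_iter
    list(r = ch$r_draws,
         ell = ch$ell_trace[keep],
         sigma = ch$sigma_trace[keep])
  })
  list(r = do.call(rbind, lapply(post, `[[`, "r")),
       ell = unlist(lapply(post, `[[`, "ell")),
       sigma = unlist(lapply(post, `[[`, "sigma")))
}

#' @export
print.phylogp <- function(x, ...) {
  cat("Phylogenetic Gaussian process rate model\n")
  cat("  ", x$N, " sites, ", length(x$taxa), " taxa, kernel ", x$kernel,
      "\n", sep = "")
  cat("  ", length(x$chains), " chain(s) x ", x$n_iter,
      " iterations (burn-in ", format(x$burn_in), ", thin ", x$thin, ")\n",
      sep = "")
  p <- pooled_draws(x)
  cat(sprintf("  posterior median ell = %.2f A, sigma = %.3f\n",
              median(p$ell), median(p$sigma)))
  invisible(x)
}

#' Posterior summaries for a phylogp fit
#'
#' Per-site posterior mean substitution rates (the mean of `exp(r)` over the
#' pooled post-burn-in draws) with equal-tailed credible intervals, and the
#' posterior medians of the hyperparameters.
#'
#' @param object a [phylogp()] fit.
#' @param prob credible-interval coverage (default 0.95).
#' @param ... unused.
#' @return An object of class `summary.phylogp`: list with `rates` (a
#'   data.frame: site, alignment column, mean rate, interval), `ell_median`,
#'   `sigma_median`, per-chain hyperparameter medians and acceptance rates.
#' @export
summary.phylogp <- function(object, prob = 0.95, ...) {
  p <- pooled_draws(object)
  if (nrow(p$r) == 0) stop("no post-burn-in draws to summarize")
  rates <- exp(p$r)
  a <- (1 - prob) / 2
  qs <- apply(rates, 2, quantile, probs = c(a, 1 - a))
  out <- list(
    rates = data.frame(site = seq_len(object$N),
                       column = object$columns,
                       mean_rate = colMeans(rates),
                       lower = qs[1, ], upper = qs[2, ]),
    ell_median = median(p$ell),
    sigma_median = median(p$sigma),
    ell_by_chain = vapply(object$chains, function(ch)
      median(ch$ell_trace[ch$trace_iter > ch$burn_iter]), numeric(1)),
    acceptance = data.frame(
      update = c("rates", "hyperparameters"),
      rate = c(mean(vapply(object$chains, `[[`, numeric(1), "rate_rate")),
               mean(vapply(object$chains, `[[`, numeric(1), "hyper_rate")))),
    n_draws = nrow(p$r), prob = prob)
  class(out) <- "summary.phylogp"
  out
}

#' @export
print.summary.phylogp <- function(x, ...) {
  cat("Posterior summary (", x$n_draws, " pooled draws)\n", sep = "")
  cat(sprintf("  median characteristic length ell: %.2f A  (per chain: %s)\n",
              x$ell_median, paste(sprintf("%.2f", x$ell_by_chain),
                                  collapse = ", ")))
  cat(sprintf("  median signal standard deviation sigma: %.3f\n",
              x$sigma_median))
  cat(sprintf("  acceptance rates: rates %.3f, hyperparameters %.3f\n",
              x$acceptance$rate[1], x$acceptance$rate[2]))
  cat("  site rates (first rows):\n")
  print(head(x$rates, 5), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname summary.phylogp
#' @export
coef.phylogp <- function(object, ...) {
  p <- pooled_draws(object)
  c(length_scale = median(p$ell), signal_sd = median(p$sigma))
}

#' @rdname summary.phylogp
#' @export
fitted.phylogp <- function(object, ...) {
  p <- pooled_draws(object)
  colMeans(exp(p$r))
}

#' Trace and rate-field plots for a phylogp fit
#'
#' `type = "trace"` draws the thinned hyperparameter traces per chain;
#' `type = "rates"` shows the posterior mean rates, as a heatmap when the
#' structure is a 2D lattice and as a site profile otherwise.
#'
#' @param x a [phylogp()] fit.
#' @param type `"trace"` or `"rates"`.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.phylogp <- function(x, type = c("trace", "rates"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    old <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(par(old))
    ell <- vapply(x$chains, `[[`, numeric(length(x$chains[[1]]$ell_trace)),
                  "ell_trace")
    sig <- vapply(x$chains, `[[`, numeric(length(x$chains[[1]]$sigma_trace)),
                  "sigma_trace")
    it <- x$chains[[1]]$trace_iter
    matplot(it, ell, type = "l", lty = 1, xlab = "iteration",
            ylab = "ell (A)", main = "characteristic length", ...)
    abline(v = x$chains[[1]]$burn_iter, lty = 3)
    matplot(it, sig, type = "l", lty = 1, xlab = "iteration",
            ylab = "sigma", main = "signal standard deviation", ...)
    abline(v = x$chains[[1]]$burn_iter, lty = 3)
  } else {
    r <- fitted(x)
    g <- if (!is.null(x$coords)) attr(x$coords, "grid") else NULL
    if (!is.null(g)) {
      z <- matrix(r, nrow = g["cols"], ncol = g["rows"])
      image(z, col = hcl.colors(64, "viridis"), axes = FALSE,
            main = "posterior mean substitution rate", ...)
    } else {
      plot(r, type = "h", xlab = "site", ylab = "posterior mean rate", ...)
    }
  }
  invisible(x)
}
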