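#' @title Per-site phylogenetic likelihood by the pruning algorithm
#'
#' @description
#' The likelihood of one alignment column given the tree, the substitution
#' model and a site-specific rate multiplier.  Branch lengths are scaled by
#' the rate before transition matrices are computed.  Gaps (`-`) and unknown
#' residues (`X`) are treated as missing data: their partial likelihood is 1
#' for every state, so an all-gap column has log-likelihood exactly 0.
#'
#' @param column a character vector of residues, named by taxon (or in the
#'   order of the tree's tip labels).
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param model a [substitution_model()].
#' @param rate substitution-rate multiplier, > 0.
#' @return The log-likelihood (a single finite number, <= 0).
#' @export
site_log_likelihood <- function(column, tree, model, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number")
  if (is.null(names(column))) {
    if (length(column) != length(tree$tip.label))
      stop("column length does not match number of tree tips")
    names(column) <- tree$tip.label
  }
  aln <- aa_alignment(matrix(column, ncol = 1,
                             dimnames = list(names(column), NULL)))
  tidx <- tree_index(tree, rownames(aln))
  drop(prune_loglik(encode_alignment(aln), tidx, model, rate))
}

# Post-order traversal bookkeeping for a tree whose tips match the
# alignment's taxa.  Works for rooted or unrooted (basal multifurcation)
# trees; reversibility makes the root placement irrelevant.
tree_index <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!setequal(tree$tip.label, taxa))
    stop("tree tip labels do not match alignment taxa\n  tree: ",
         paste(sort(tree$tip.label), collapse = ","), "\n  alignment: ",
         paste(sort(taxa), collapse = ","))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(edge = tr$edge,
       elen = tr$edge.length,
       ntip = ntip,
       nnode = tr$Nnode,
       root = ntip + 1L,
       tip_row = match(tr$tip.label, taxa))
}

# Pruning log-likelihood for all sites at once at a single rate.
# states: integer matrix (taxa x sites), NA = missing.  Returns a vector of
# per-site log-likelihoods.  Per-node rescaling guards against underflow.
prune_loglik <- function(states, tidx, model, rate) {
  N <- ncol(states)
  partial <- vector("list", tidx$ntip + tidx$nnode)
  logscale <- numeric(N)
  edge <- tidx$edge
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1L]
    child <- edge[k, 2L]
    P <- transition_matrix(model, tidx$elen[k] * rate)
    if (child <= tidx$ntip) {
      st <- states[tidx$tip_row[child], ]
      C <- matrix(1, N, 20)
      ok <- which(!is.na(st))
      if (length(ok)) C[ok, ] <- t(P)[st[ok], , drop = FALSE]
    } else {
      pc <- partial[[child]]
      s <- rowSums(pc)
      pc <- pc / s
      logscale <- logscale + log(s)
      C <- pc %*% t(P)
    }
    partial[[parent]] <- if (is.null(partial[[parent]])) C else partial[[parent]] * C
  }
  out <- drop(log(partial[[tidx$root]] %*% model$freqs)) + logscale
  # all-missing columns carry no data: exactly zero, not accumulated roundoff
  out[colSums(!is.na(states)) == 0L] <- 0
  out
}

#' Cached per-site log-likelihoods on a rate grid
#'
#' Evaluates every site's log-likelihood at `grid_size` evenly spaced
#' substitution rates (default 4000 points from `rate_max / grid_size` up to
#' `rate_max` = 20) so that the MCMC sampler can replace pruning with linear
#' interpolation.  Duplicate site patterns are collapsed before evaluation
#' and re-expanded, which the caller never sees.
#'
#' @param alignment an [aa_alignment()].
#' @param tree an [ape::phylo] tree whose tips match the alignment taxa.
#' @param model a [substitution_model()]; defaults to JTT.
#' @param grid_size number of grid points (>= 2).
#' @param rate_max largest cached rate.
#' @param rate_min smallest cached rate; the default `rate_max / grid_size`
#'   gives a grid spacing equal to `rate_min` itself.
#' @return An object of class `loglik_cache`: list with `rate_grid` (length
#'   G), `table` (N x G matrix of log-likelihoods), and the grid parameters.
#' @export
build_loglik_cache <- function(alignment, tree, model = jtt_model(),
                               grid_size = 4000, rate_max = 20,
                               rate_min = rate_max / grid_size) {
  stopifnot(inherits(alignment, "aa_alignment"))
  if (grid_size < 2) stop("'grid_size' must be at least 2")
  if (!is.finite(rate_min) || rate_min <= 0)
    stop("'rate_min' must be positive")
  if (rate_min >= rate_max) stop("'rate_min' must be smaller than 'rate_max'")
  tidx <- tree_index(tree, rownames(alignment))
  states <- encode_alignment(alignment)
  grid <- seq(rate_min, rate_max, length.out = grid_size)

  key <- apply(states, 2L, paste, collapse = ",")
  upat <- !duplicated(key)
  map <- match(key, key[upat])
  ustates <- states[, upat, drop = FALSE]

  tab_u <- matrix(0, ncol(ustates), grid_size)
  for (g in seq_len(grid_size))
    tab_u[, g] <- prune_loglik(ustates, tidx, model, grid[g])
  structure(list(rate_grid = grid,
                 table = tab_u[map, , drop = FALSE],
                 rate_min = rate_min, rate_max = rate_max,
                 step = grid[2] - grid[1],
                 n_sites = ncol(alignment),
                 grid_size = grid_size),
            class = "loglik_cache")
}

#' @export
print.loglik_cache <- function(x, ...) {
  cat("Site log-likelihood cache: ", x$n_sites, " sites x ", x$grid_size,
      " rates in [", format(x$rate_min), ", ", format(x$rate_max), "]\n", sep = "")
  invisible(x)
}

#' Interpolated site log-likelihood
#'
#' Approximates the log-likelihood of a site at an arbitrary log rate from
#' the cache: the rate `exp(log_rate)` is located between the two nearest
#' cached rates and the cached log-likelihoods are interpolated linearly in
#' the rate.  Rates outside the cached range use the value at the closest
#' grid boundary.
#'
#' @param cache a [build_loglik_cache()] object.
#' @param site site index (1-based), recycled against `log_rate`.
#' @param log_rate log substitution rate(s).
#' @return Interpolated log-likelihood(s).
#' @export
interp_site_loglik <- function(cache, site, log_rate) {
  stopifnot(inherits(cache, "loglik_cache"))
  n <- max(length(site), length(log_rate))
  site <- rep_len(as.integer(site), n)
  rho <- exp(rep_len(log_rate, n))
  G <- cache$grid_size
  out <- numeric(n)
  lo <- rho <= cache$rate_min
  hi <- rho >= cache$rate_max
  out[lo] <- cache$table[cbind(site[lo], 1L)]
  out[hi] <- cache$table[cbind(site[hi], G)]
  mid <- !(lo | hi)
  if (any(mid)) {
    u <- (rho[mid] - cache$rate_min) / cache$step
    k <- pmin(floor(u), G - 2) + 1L
    w <- u - (k - 1L)
    s <- site[mid]
    out[mid] <- (1 - w) * cache$table[cbind(s, k)] +
      w * cache$table[cbind(s, k + 1L)]
  }
  out
}
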