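#' Block-structured ground-truth rate fields
#'
#' Divides a rectangular lattice into non-overlapping `block` x `block`
#' squares and assigns the `low` and `high` substitution rates to the blocks
#' in a checkerboard pattern, starting with `low` in the top-left block.
#' Sites at the low rate are flagged as functional.  With the default rates
#' 0.2 and 1.8 and an even number of blocks the mean site rate is exactly 1.
#'
#' @param grid a [make_2d_grid()] structure.
#' @param block block edge length in sites; must divide both grid dimensions.
#' @param low,high the two substitution rates.
#' @return An object of class `rate_field`: list with `rates`,
#'   `functional_mask` (`TRUE` = slow/functional) and the `coords`.
#' @examples
#' f <- block_rate_field(make_2d_grid(20, 20), block = 10)
#' mean(f$rates)  # 1
#' @export
block_rate_field <- function(grid, block, low = 0.2, high = 1.8) {
  g <- attr(grid, "grid")
  if (is.null(g)) stop("'grid' must come from make_2d_grid()")
  stopifnot(low > 0, high > 0, block >= 1)
  rows <- g["rows"]; cols <- g["cols"]
  if (rows %% block != 0 || cols %% block != 0)
    stop("block size ", block, " does not divide the ", rows, "x", cols, " grid")
  ri <- rep(seq_len(rows), each = cols)
  ci <- rep(seq_len(cols), times = rows)
  parity <- ((ri - 1) %/% block + (ci - 1) %/% block) %% 2
  rates <- ifelse(parity == 0, low, high)
  structure(list(rates = rates, functional_mask = rates == min(low, high),
                 coords = grid),
            class = "rate_field")
}

#' @export
print.rate_field <- function(x, ...) {
  cat("Rate field: ", length(x$rates), " sites, rates {",
      paste(sort(unique(x$rates)), collapse = ", "), "}, ",
      sum(x$functional_mask), " functional\n", sep = "")
  invisible(x)
}

#' Simulate an alignment under site-specific rates
#'
#' Sites evolve independently: the root state is drawn from the model's
#' equilibrium frequencies and each branch applies the transition matrix at
#' branch length times the site's rate.  No indels are generated, matching
#' the likelihood's assumptions exactly.  Uses R's RNG; call `set.seed()`
#' for reproducibility.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param model a [substitution_model()].
#' @param rates a [block_rate_field()] or a positive numeric vector, one
#'   rate per site.
#' @param keep_states if `TRUE`, simulate by explicit jump (Gillespie)
#'   sampling along each branch — distributionally identical to the default
#'   transition-matrix sampling — and attach the full node state matrix
#'   (attribute `"node_states"`, rows indexed by ape node number), the
#'   tree's edge matrix (attribute `"edge"`) and the per-site count of
#'   actual substitution events (attribute `"n_events"`).
#' @return An [aa_alignment()] with one row per tip.
#' @export
simulate_alignment <- function(tree, model, rates, keep_states = FALSE) {
  if (inherits(rates, "rate_field")) rates <- rates$rates
  stopifnot(is.numeric(rates), all(is.finite(rates)), all(rates > 0))
  N <- length(rates)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  states <- matrix(NA_integer_, nnode, N)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, N, replace = TRUE, prob = model$freqs)
  n_events <- integer(N)

  if (keep_states) {
    # jump-chain simulation: exponential waiting times at the state's exit
    # rate, so every substitution event is observed and countable
    exit <- -diag(model$Q)
    jump <- model$Q / exit
    diag(jump) <- 0
    for (k in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
      blen <- tr$edge.length[k]
      for (i in seq_len(N)) {
        a <- states[parent, i]
        t <- blen * rates[i]
        repeat {
          w <- stats::rexp(1, rate = exit[a])
          if (w >= t) break
          t <- t - w
          a <- sample.int(20L, 1L, prob = jump[a, ])
          n_events[i] <- n_events[i] + 1L
        }
        states[child, i] <- a
      }
    }
  } else {
    ugroup <- match(rates, unique(rates))
    urates <- unique(rates)
    for (k in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
      for (u in seq_along(urates)) {
        idx <- which(ugroup == u)
        P <- transition_matrix(model, tr$edge.length[k] * urates[u])
        ps <- states[parent, idx]
        for (a in unique(ps)) {
          j <- idx[ps == a]
          states[child, j] <- sample.int(20L, length(j), replace = TRUE,
                                         prob = P[a, ])
        }
      }
    }
  }
  m <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]], ntip, N,
              dimnames = list(tr$tip.label, NULL))
  out <- aa_alignment(m)
  if (keep_states) {
    attr(out, "node_states") <- states
    attr(out, "edge") <- tr$edge
    attr(out, "n_events") <- n_events
  }
  out
}

#' Randomly permute alignment columns
#'
#' Destroys any spatial arrangement of site-specific rates relative to the
#' structure while preserving the multiset of columns; used as a negative
#' control for spatial correlation.  Uses R's RNG.
#'
#' @param alignment an [aa_alignment()] with at least 1 column.
#' @return The permuted [aa_alignment()]; the permutation used is attached
#'   as attribute `"perm"`.
#' @export
shuffle_columns <- function(alignment) {
  stopifnot(inherits(alignment, "aa_alignment"))
  N <- ncol(alignment)
  perm <- if (N > 1L) sample.int(N) else 1L
  out <- alignment[, perm, drop = FALSE]
  attr(out, "perm") <- perm
  out
}
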