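# Independent oracles and small fixtures shared across test files.
# Oracles deliberately avoid the package's own fast paths: brute-force
# enumeration, explicit inverses, quadrature.

# Brute-force site likelihood: sum over every assignment of states to the
# internal nodes, using transition probabilities directly.  Works for any
# tree small enough to enumerate (<= 2-3 internal nodes).
brute_force_site_loglik <- function(column, tree, model, rate) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  internal <- ntip + seq_len(nnode)
  obs <- match(toupper(column[tr$tip.label]), phylogp:::AA_ALPHABET)
  combos <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  total <- 0
  for (ci in seq_len(nrow(combos))) {
    assign_state <- function(node) {
      if (node <= ntip) obs[node] else combos[ci, node - ntip]
    }
    p <- model$freqs[assign_state(ntip + 1L)]  # root prior
    for (k in seq_len(nrow(tr$edge))) {
      a <- assign_state(tr$edge[k, 1L])
      b <- assign_state(tr$edge[k, 2L])
      P <- transition_matrix(model, tr$edge.length[k] * rate)
      p <- p * if (is.na(b)) 1 else P[a, b]
    }
    total <- total + p
  }
  log(total)
}

# Dense-grid quadrature posterior for the log rate of a single site (or two
# independent quantities via product); used against fixed-hyperparameter MCMC.
quadrature_posterior_1d <- function(cache, site, prior_sd, grid) {
  loglik <- interp_site_loglik(cache, rep(site, length(grid)), grid)
  logpost <- loglik + stats::dnorm(grid, 0, prior_sd, log = TRUE)
  w <- exp(logpost - max(logpost))
  w / sum(w)
}

# A tiny fixed alignment on the canonical 4-taxon tree
tiny_alignment <- function() {
  aa_alignment(list(t1 = "ARNDC", t2 = "ARNDV", t3 = "ARNEC", t4 = "GRNDC"))
}

# Deterministic simulated dataset on an r x c lattice
sim_dataset <- function(seed, rows = 10, cols = 10, block = 5,
                        low = 0.2, high = 1.8) {
  set.seed(seed)
  grid <- make_2d_grid(rows, cols)
  field <- block_rate_field(grid, block = block, low = low, high = high)
  aln <- simulate_alignment(simulation_tree(), jtt_model(), field)
  list(grid = grid, field = field, aln = aln)
}

# Minimal three-residue PDB fixture (two chains, one altloc pair)
write_pdb_fixture <- function(path) {
  writeLines(c(
    "HEADER    SYNTHETIC TEST STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      4  CA AVAL A   3       7.000   8.000   9.000  0.50  0.00           C",
    "ATOM      5  CA BVAL A   3       7.500   8.500   9.500  0.50  0.00           C",
    "ATOM      6  CA  LEU B   1      10.000  11.000  12.000  1.00  0.00           C",
    "TER",
    "END"), path)
  path
}
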