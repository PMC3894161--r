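# phylogp

Bayesian inference of **spatially correlated site-specific substitution
rates** in proteins with known tertiary structure.

Functionally important residues evolve slowly, and they cluster into
patches in the folded protein (active sites, binding interfaces). Classic
conservation estimators such as the discrete-Gamma/Rate4Site family treat
per-site rates as i.i.d. across alignment columns and so cannot use that
clustering. `phylogp` places a zero-mean **Gaussian process prior on the
log substitution rates** over the structure's pairwise C&alpha; distances:

```
p(r | X, T)  ∝  [ Π_i L_i(exp(r_i)) ] · N(r; 0, K(D))
K_ij = k(d_ij) + δ·[i = j],    k(d) = σ² (1 + √3 d/ℓ) e^(−√3 d/ℓ)   (Matérn 1.5)
```

where `L_i` is the Felsenstein pruning likelihood of column `i` under the
JTT model on a fixed tree, `ℓ` (Å) is the characteristic length of spatial
rate correlation and `σ` the marginal spread of log rates. Both
hyperparameters get exponential priors and are **learned from the data** —
no sliding-window size to choose. Posterior sampling uses Metropolis
updates with prior-preserving latent proposals (`r' = √(1−ε²) r + ε L z`)
interleaved 50:1 with log-scale hyperparameter moves, adaptive tuning
toward 0.25 acceptance during burn-in, and two pooled chains.

The package also includes everything needed to benchmark the model: a
sequence simulator with block-structured rate fields on 2D lattice toy
structures, an i.i.d. discrete-Gamma empirical-Bayes baseline
(a reimplementation of that model class, not a wrapper), and ROC/log-loss
evaluation utilities.

## Worked example

Simulate the benchmark toy protein — a 10×10 lattice at 5 Å spacing with a
checkerboard of slow (0.2) and fast (1.8) 5×5 blocks, four taxa on a tree
of total length 1 — then fit the GP model and the i.i.d. baseline:

```r
library(phylogp)
tree  <- simulation_tree()
grid  <- make_2d_grid(10, 10)                 # 100-residue toy structure
field <- block_rate_field(grid, block = 5)    # checkerboard of 0.2 / 1.8
set.seed(1)
aln <- simulate_alignment(tree, jtt_model(), field)

fit <- phylogp(aln, tree, grid, seed = 1)     # 2 chains x 20000 iterations
summary(fit)
```

```
Posterior summary (2000 pooled draws)
  median characteristic length ell: 36.20 A  (per chain: 38.92, 32.90)
  median signal standard deviation sigma: 1.624
  acceptance rates: rates 0.245, hyperparameters 0.193
  site rates (first rows):
 site column mean_rate  lower upper
    1      1     0.291 0.0428 0.851
    2      2     0.300 0.0585 0.755
    3      3     0.357 0.0880 0.848
    4      4     0.466 0.1315 1.061
    5      5     0.675 0.2293 1.461
```

The recovered length scale (~36 Å) reflects the 25 Å blocks plus the
kernel's reach; per-site mean rates for the first column of the lattice
step up from the slow block toward the fast one. Compare against the
i.i.d. baseline:

```r
baseline <- fit_iid_rates(aln, tree)          # discrete-Gamma empirical Bayes
log_rate_loss(field, fitted(fit))             # 0.72
log_rate_loss(field, fitted(baseline))        # 1.093
roc_curve(field$functional_mask, fitted(fit))$auc       # 0.9396
roc_curve(field$functional_mask, fitted(baseline))$auc  # 0.847
```

The GP halves-ish the squared log-rate error and improves the AUC for
detecting the slow (functional) sites — the spatial prior is doing the
work, since both models share the same likelihood machinery.

For real data, build the structure side from a PDB file:

```r
aln <- read_alignment("family.fasta")
sc  <- read_pdb_ca("structure.pdb", chain = "A")
sc  <- map_structure_to_alignment(sc, aln, ref_taxon = "human")
fit <- phylogp(aln, read_newick("family.nwk"), sc, seed = 1)
top_k_conserved(fitted(fit), 20)              # candidate functional patch
```

A command-line front end with `simulate` / `infer` / `baseline` /
`evaluate` subcommands is installed at `inst/scripts/phylogp`.

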