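---
title: "Methods: a phylogenetic Gaussian process model for site-specific substitution rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a phylogenetic Gaussian process model for site-specific substitution rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Functionally important residues are under stronger purifying selection and
therefore accumulate amino-acid replacements more slowly than the rest of a
protein. Classic conservation estimators treat the per-site substitution
rate as independent and identically distributed across alignment columns,
which ignores a strong biological regularity: functional sites cluster into
patches in the folded structure (active sites, binding interfaces). This
package models that clustering directly.

Let $X$ be a protein alignment with $N$ columns, $T$ a fixed phylogenetic
tree with branch lengths in expected substitutions per site, and $D$ the
$N \times N$ matrix of Euclidean distances (in angstroms) between the
C$\alpha$ atoms of the residues of one structure in the family. Writing
$r_i$ for the *log* substitution rate of site $i$, the posterior is

$$ p(r \mid X, T) \propto \Big[ \prod_{i=1}^N L_i(e^{r_i}) \Big] \, p(r), $$

where $L_i(\rho)$ is the standard pruning likelihood of column $i$ with all
branch lengths scaled by $\rho$, and the prior $p(r)$ is a zero-mean
Gaussian process over the structure,

$$ r \sim \mathcal{N}(0, K(D)), \qquad
   K_{ij} = k(d_{ij}) + \delta\,[i = j]. $$

The default covariance is Matérn 1.5,
$k(d) = \sigma^2 (1 + \sqrt{3} d/\ell) e^{-\sqrt{3} d/\ell}$, with
Matérn 2.5 and the squared exponential available; the three differ only in
the smoothness they impose on the latent rate field, and Matérn 1.5 — the
roughest — is the default precisely so that small functional patches and
sharp rate boundaries are not smoothed away. The hyperparameters have
direct interpretations: the characteristic length $\ell$ (Å) is the
distance over which log rates stay correlated, and the signal standard
deviation $\sigma$ (unitless) is the marginal spread of log rates at a
single site. Both get independent exponential priors and are estimated
from the data; this is the model's central advantage over sliding-window
smoothing, where the window size must be guessed.

Model assumptions worth stating explicitly: the tree (topology and branch
lengths) is fixed; the substitution process is JTT at every site, rescaled
per site by $e^{r_i}$; rates are constant over the tree (no heterotachy);
gaps and unknown residues are missing data; sites are conditionally
independent given $r$; and the structure of a single family member stands
in for all of them.

## The likelihood and its cached approximation

`site_log_likelihood()` implements Felsenstein pruning over the 20
amino-acid states, with transition matrices from the eigendecomposition of
the reversible JTT generator (normalized to one expected substitution per
unit branch length at equilibrium; the numerical table ships in
`inst/extdata/jtt.dat`). Per-node rescaling keeps partial likelihoods away
from underflow, all-gap columns contribute exactly zero, and the
likelihood is invariant to root placement (tested via re-rooting).

The sampler evaluates site likelihoods millions of times, so
`build_loglik_cache()` precomputes each site's log-likelihood on a uniform
grid of substitution rates — by default 4000 points from 0.005 to 20 —
and `interp_site_loglik()` interpolates linearly *in the rate* between
the two bracketing grid points, clamping to the boundary value outside the
grid. Identical site patterns are collapsed before the grid evaluation.
Two numerical consequences are documented deliberately:

* the lower grid bound (0.005, i.e. `rate_max / grid_size`) is a design
  choice; it is configurable;
* because log-likelihoods behave like $k \log \rho$ as $\rho \to 0$ (for a
  column implying $k$ substitutions), linear interpolation is least
  accurate just above the grid floor. Measured on random four-taxon
  columns, the error is below 0.01 log units for rates in $[0.05, 19]$ and
  below 0.05 down to rate 0.01. For the rate ranges that matter in
  practice (roughly 0.1–10) the approximation is far more accurate.

## Posterior sampling

Both parameter blocks use Metropolis updates (implemented in compiled code;
`rate_update_step()`/`hyper_update_step()` are the exported single-step
reference forms):

* **Latent log rates.** The proposal is Neal's underrelaxed form
  $r' = \sqrt{1-\epsilon^2}\, r + \epsilon L z$, with $L$ the lower
  Cholesky factor of $K$ and $z$ standard normal. This proposal leaves the
  GP prior exactly invariant — a property the test suite verifies
  empirically rather than assumes — so the acceptance ratio reduces to the
  likelihood ratio alone. $\epsilon \in (0,1]$ trades off step size
  against acceptance.
* **Hyperparameters.** $(\log \ell, \log \sigma)$ take a bivariate
  Gaussian random-walk step. Because the exponential priors are on the
  natural scale, the acceptance ratio includes the log-scale
  change-of-variables term $\ell' \sigma' / (\ell \sigma)$ explicitly. A
  proposal whose covariance fails to factorize (numerically non-PD) counts
  as a rejection.

Each iteration performs 50 latent updates and one hyperparameter update —
the hyperparameter move costs a fresh $O(N^3)$ Cholesky factorization while
a latent move costs $O(N^2)$, so the 50:1 schedule balances the two — and
every 10th iteration is recorded. During burn-in only, $\epsilon$ and the
hyperparameter step are adapted multiplicatively (Robbins–Monro style,
every 25 and 50 iterations respectively) toward an acceptance rate of
0.25, then frozen so the recorded phase is a valid fixed-kernel chain.
Two independent chains are run and pooled after burn-in by default.

Defaults that were genuinely open and how they were fixed:

* `n_iter = 20000`, `burn_in = 0.5`: comfortable for the 400-site toy
  problems; the package's own benchmark runs use 5000 iterations per chain
  (with 2 chains and 5 replicates per condition), which keeps a full
  two-configuration comparison within minutes on one core while leaving the
  qualitative results unchanged.
* `jitter = 1e-6`: small enough not to perturb the kernel, large enough to
  keep the Cholesky stable at $\ell \to 0$ or coincident coordinates.
* Exponential hyperpriors are parameterized by their **means**:
  `prior_scale_l = 100` Å and `prior_scale_s = 10`. These are weakly
  informative over realistic protein dimensions (a protein domain spans
  tens of angstroms; log-rate spreads beyond ~3 are extreme). The
  alternative reading — exponential *rate* parameters set large — would
  give a sharply informative prior concentrated at zero and is rejected on
  that ground; sensitivity to the scales is low in the simulation regime
  because 400 sites carry much more information than the prior.
* Initialization: $\ell_0$ = twice the mean nearest-neighbor C$\alpha$
  distance, $\sigma_0 = 1$, and $r$ drawn from the prior — starting
  hyperparameters at a data-independent but geometry-aware point avoids
  degenerate covariances at step one.
* Per-site point estimates are posterior means of $e^{r_i}$ (mean rate,
  not exponentiated mean log rate); the credible intervals are
  equal-tailed quantiles of $e^{r_i}$.

## The synthetic data generator

`simulation_tree()`, `make_2d_grid()`, `block_rate_field()` and
`simulate_alignment()` reproduce the benchmark conditions this model is
evaluated under: four taxa related by a balanced quartet with every branch
0.2 expected substitutions per site (total tree length 1, so the average
site sees a single substitution — deliberately information-poor), a 20×20
planar lattice with 5 Å spacing standing in for a tertiary structure, and
a checkerboard of 10×10 (configuration 1) or 5×5 (configuration 2) blocks
alternating between rates 0.2 and 1.8, so the mean rate is exactly 1 and
the slow sites form spatial patches. Sites evolve independently given
their rates; the root state is drawn from JTT equilibrium. With
`keep_states = TRUE` the simulator switches to jump-chain (Gillespie)
sampling — distributionally identical — so actual substitution events can
be counted. `shuffle_columns()` permutes alignment columns to destroy the
spatial arrangement while preserving the data, the negative control for
spatial correlation.

What the generator does *not* emulate: indels (alignments are gapless and
ungapped), alignment error, heterotachy, among-site compositional
heterogeneity, 3D protein geometry (the lattice is planar), and tree
uncertainty. Passing tests on these simulations therefore demonstrate
correctness of the inference machinery and the model's behavior when its
assumptions hold — not robustness to real-data violations of them.

## The i.i.d. baseline and evaluation

`fit_iid_rates()` is a reimplementation of the model class behind
Rate4Site-style conservation scoring, not a port: site rates i.i.d. from a
mean-one discrete Gamma (16 equal-probability categories by default, finer
than the common 4 to make the comparator as strong as practical; category
rates are within-bin means), shape $\alpha$ fitted by bounded 1-D
maximization of the marginal likelihood, per-site estimates by
empirical-Bayes posterior mean. One boundary behavior is worth knowing:
for an alignment of *only* invariant columns the marginal likelihood
increases as $\alpha \to 0$ (piling Gamma mass near rate zero fits
all-conserved data best under the mean-1 constraint), so $\alpha$ is
reported at the lower search bound there, with flat low rates.

`log_rate_loss()` is the mean squared difference of log rates — the log
scale emphasizes exactly the low-rate region where conservation signal
lives. `roc_curve()` ranks sites by estimated rate ascending (low rate =
predicted functional); ties move along diagonal segments so the
trapezoidal AUC equals the tie-corrected Mann–Whitney statistic.
`top_k_conserved()` breaks rate ties toward the smaller site index,
deterministically. `compare_methods()` pairs the two estimators replicate
by replicate: per-replicate losses and AUCs, a paired Wilcoxon signed-rank
test on the losses, and a pooled ROC by vertical averaging on a fixed
false-positive-rate grid.

## Degenerate inputs and tie-breaks

Single-site structures are legal (the GP degenerates to a univariate
normal); zero-length branches are legal; all-gap columns are legal at
every rate; non-positive rates are domain errors; non-positive
hyperparameters have prior density $-\infty$ (rejected states, not
exceptions); a structure mapping excludes alignment columns where the
reference taxon is gapped rather than imputing coordinates, and reports
them; multi-model PDB files use the first model, alternate locations other
than the first are dropped, and residues without a C$\alpha$ are skipped
with a warning.

## Known limitations

The $O(N^3)$ Cholesky per hyperparameter update bounds practical alignment
sizes at a few thousand mapped sites. The model shares information only
through spatial proximity — a lone conserved site surrounded by variable
ones is pulled toward its neighbors, which is the intended bias but a bias
nonetheless (visible as the GP's slightly conservative rate range).
Column-shuffled data are handled gracefully (the posterior length scale
collapses toward zero and the model approaches the i.i.d. limit), but on
truly uncorrelated data the absolute rate estimates can be worse than the
i.i.d. baseline's even while site *rankings* remain comparable. No
heterotachy, no mixture over substitution models, no mean function linking
rates to local structural covariates (e.g. solvent accessibility), and no
tree estimation.
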