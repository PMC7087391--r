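---
title: "Methods: orthogonal data augmentation for parallel BayesCpi sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthogonal data augmentation for parallel BayesCpi sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Model

Phenotypes of $n$ genotyped individuals are modeled with the general mean
as the only fixed effect,

$$ \mathbf{y} = \mathbf{1}\mu + \mathbf{X}\mathbf{a} + \mathbf{e}, $$

where $\mathbf{X}$ is the $n \times p$ matrix of 0/1/2 allele counts,
centered column-wise before analysis, and
$\mathbf{e} \mid \sigma^2_e \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e)$.
The BayesCpi prior makes each marker effect a mixture of a point mass at
zero (with probability $\pi$, the *null-effect* probability) and
$N(0, \sigma^2_a)$ with a variance common to all loci.  Priors are flat on
$\mu$, uniform on $\pi$, and scaled inverse chi-square
$\nu S^2 \chi^{-2}_\nu$ on both variances.

### Single-site sampler

The conventional Gibbs sampler updates, per iteration, $\mu$; then each
$(\delta_j, a_j)$ in ascending marker order; then
$(\sigma^2_a, \sigma^2_e, \pi)$.  The indicator is drawn from its
conditional with the effect integrated out, via the log likelihood ratio

$$ \ell_j = -\tfrac12 \log\frac{c_j\sigma^2_a + \sigma^2_e}{\sigma^2_e}
   + \frac{r_j^2 \sigma^2_a}{2\sigma^2_e (c_j\sigma^2_a + \sigma^2_e)},
   \qquad
   \Pr(\delta_j = 1 \mid \cdot) =
   \frac{(1-\pi) e^{\ell_j}}{(1-\pi) e^{\ell_j} + \pi}, $$

with $c_j = \mathbf{X}_j'\mathbf{X}_j$ and $r_j$ the right-hand side
adjusted for all other effects; an included effect is then
$N(r_j/(c_j + \sigma^2_e/\sigma^2_a),\ \sigma^2_e/(c_j +
\sigma^2_e/\sigma^2_a))$.  A unit test checks this inclusion probability
against direct quadrature of the two marginal likelihoods.  The
conjugate variance updates are, with $m = \sum_j \delta_j$:
$\sigma^2_a \sim (\nu_a S^2_a + \sum_{\delta_j=1} a_j^2)/\chi^2_{\nu_a+m}$,
$\sigma^2_e \sim (\nu_e S^2_e + \mathbf{e}'\mathbf{e})/\chi^2_{\nu_e+n}$,
and $\pi \sim \mathrm{Beta}(p-m+1,\ m+1)$.

Two computational variants of the sweep are provided because their costs
differ, not their output: variant I maintains the residual vector
($O(np)$ time per iteration, $O(np)$ space), variant II works from
$\mathbf{X}'\mathbf{y}$ and $\mathbf{X}'\mathbf{X}$ ($O(p^2)$ time,
$O(p^2)$ space).  Both consume the random-number stream identically, so a
test can require the two chains to match draw for draw; the maintained
quantity (residual or crossproduct) is audited against a fresh
recomputation every 1000 iterations with a $10^{-6}$ tolerance.

### Orthogonal data augmentation

The serial bottleneck is the dependence of $r_j$ on the other effects.
With $\mathbf{W}_o = [\mathbf{1}\ \mathbf{X}]$, we append a square matrix
$\mathbf{W}_a = [\tilde{\mathbf{J}}\ \tilde{\mathbf{X}}]$ of $p+1$
synthetic rows such that

$$ \mathbf{W}_a'\mathbf{W}_a = \mathbf{I}d - \mathbf{W}_o'\mathbf{W}_o, $$

making the Gram matrix of the stacked design exactly $\mathbf{I}d$.  We
take $d$ as the largest eigenvalue of $\mathbf{W}_o'\mathbf{W}_o$ plus a
jitter of 0.001: at $d = \lambda_{\max}$ exactly, the matrix to factor is
singular in the top eigendirection and the Cholesky factorization becomes
numerically unstable.  The factorization route is Cholesky with a
symmetric-eigendecomposition fallback that clamps eigenvalues in
$[-10^{-8} d, 0)$ to zero; both routes give the same Gram matrix (only
$\mathbf{W}_a'\mathbf{W}_a$ matters — the posterior is invariant to which
root is used — and we fix $\mathbf{W}_a$ to the upper-triangular factor
for reproducibility).  `orthogonality_defect()` reports
$\max_{i \ne j} |(\mathbf{W}_c'\mathbf{W}_c)_{ij}|/d$; every constructed
augmentation must stay below $10^{-6}$.

### BayesXII

The phenotypes attached to the synthetic rows are unobserved; the sampler
alternates

1. $(\mu, \mathbf{a}, \boldsymbol\delta) \mid \tilde{\mathbf{y}}, \cdot$ —
   all coordinates independent, since each conditional uses only
   $r_j = \mathbf{X}_j'\mathbf{y} + \tilde{\mathbf{X}}_j'\tilde{\mathbf{y}}$
   and the common precision $d + \sigma^2_e/\sigma^2_a$; the indicator
   uses the same likelihood ratio as above with $d$ in place of $c_j$
   (the natural extension — only the non-null conditional is standard —
   validated by the posterior-equivalence tests);
2. $\tilde{\mathbf{y}} \mid \cdot \sim
   N(\tilde{\mathbf{J}}\mu + \tilde{\mathbf{X}}\mathbf{a},
   \mathbf{I}\sigma^2_e)$, element-wise independent;
3. the variance updates, where the residual variance conditions on both
   residual blocks of the joint model:
   $\sigma^2_e \sim (\nu_e S^2_e + \mathbf{e}'\mathbf{e} +
   \tilde{\mathbf{e}}'\tilde{\mathbf{e}})/\chi^2_{\nu_e + n + p + 1}$.
   $\sigma^2_a$ and $\pi$ depend only on $(\mathbf{a},
   \boldsymbol\delta)$ and keep their single-site updates.  The degrees of
   freedom $\nu_e + n + p + 1$ count both observed and augmented
   residuals; a test verifies the update distribution against direct
   scaled-inverse-chi-square sampling (Kolmogorov–Smirnov at $10^4$
   draws).

$\tilde{\mathbf{y}}$ is initialized at its conditional mean
$\tilde{\mathbf{J}}\mu_0 + \tilde{\mathbf{X}}\mathbf{a}_0$.

Integrating $\tilde{\mathbf{y}}$ out of the augmented model returns the
original posterior, so BayesXII and the single-site sampler target the
same distribution — the package's central claim, tested two ways: both
samplers reproduce the closed-form conjugate-normal posterior when $\pi$
is fixed at 0 and the variances are fixed, and on simulated data the two
samplers' posterior-mean test-set breeding values correlate above 0.99.

### Reproducible parallelism

"Parallel" is implemented as a testable contract rather than a wall-clock
claim.  Per iteration, one $(u_j, z_j)$ pair is pre-drawn per marker in
fixed marker order before any work is scheduled, and the crossproducts
$\tilde{\mathbf{X}}_j'\tilde{\mathbf{y}}$ are evaluated over fixed-width
(64-column) marker tiles.  Workers only change which process evaluates a
tile, never the arithmetic or the randomness, so any worker count yields
bit-identical chains — asserted by a test comparing `workers = 1` against
`workers = 4`.  (Evaluating the same columns inside differently shaped
matrix products is *not* bit-stable across optimized BLAS kernels, which
is why the tiling is fixed rather than derived from the worker count.)
The worker map uses `parallel::mclapply`; a single-process vectorized
path is the reference implementation.

### Grouped augmentation

For high-density panels the $p \times p$ augmentation is too large to
store or factor, so markers are partitioned (default: contiguous blocks)
and each group's columns are orthogonalized separately with their own
$d_i$.  Columns in different groups remain correlated, so groups are
processed sequentially with a residual-style right-hand side across
groups, while all effects within a group are drawn simultaneously.  The
grouped augmentation has no intercept row: $\mu$ keeps its single-site
update and the residual-variance degrees of freedom become
$\nu_e + n + p$.  Agreement with the single-site sampler is tested the
same way as for the full augmentation.  How the partition is chosen can
affect convergence; the package makes the block size a parameter and does
not optimize it.

## Data simulator

The simulator emulates a livestock genomic-prediction design: founder
haplotypes are drawn site-independently with per-locus allele frequencies
from Uniform(0.05, 0.95); linkage disequilibrium then accrues through
generations of constant-size random mating (drift), followed by one
expansion generation that produces the analysis cohort.  Meiosis uses
Poisson($L$) crossovers per chromosome with uniform positions, no
interference and no mutation; each offspring draws two distinct parents
uniformly.  The default genome is 10 chromosomes of 1 Morgan with evenly
spaced loci; defaults elsewhere are 100 founders, 100 generations, 5% of
retained loci as QTL, genetic variance scaled to exactly 1.0 in the
expansion generation (population-variance convention, denominator $n$),
and heritability 0.3.  Monomorphic loci are removed rather than kept as
zero columns because the single-site conditional divides by
$\mathbf{X}_j'\mathbf{X}_j$.  The train/test split re-applies the filter
with training-set frequencies and centers both sets with training means.

What the simulator does *not* emulate: real linkage maps, mutation,
selection, population structure or pedigree, phasing error, and the
site-frequency spectrum of real SNP arrays.  Passing tests therefore show
correctness of the samplers on data with realistic LD structure and a
sparse additive architecture — not performance on any particular real
population.

Starting values follow the dispersed-start convention for multi-chain
diagnostics: marker effects are drawn $N(0, \sigma^2_a)$ with
$\sigma^2_a = \sigma^2_g / ((1-\pi)\sum_i 2p_i(1-p_i))$, the variance
that spreads an assumed genetic variance over the expected non-null
markers.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nu_e`, `nu_a` | 4 | prior d.f. of the variance components |
| `S2_a` | from the starting-value formula | prior scale, marker-effect variance |
| `S2_e` | `var(y) * (1 - h2_guess)`, `h2_guess = 0.5` | prior scale, residual variance |
| `pi_init` | 0.5 | initial null-effect probability |
| `jitter` | 0.001 | added to $\lambda_{\max}$ for numerical stability |
| `thin` | 10 | thinning of stored effect samples |
| burn-in | 20% of the chain | discarded before posterior summaries |
| group size | 1000 | grouped-augmentation block width |

The hyperparameter defaults follow the conventions of the
genomic-prediction software ecosystem this model family comes from; the
burn-in fraction is configurable everywhere it is used.

## Experiment sizes and numerical choices

The package's own validation experiments are intentionally small: the agreement
experiment uses 500 training / 200 testing individuals with a 200-marker
panel (five single-site chains of 10,000 iterations; one BayesXII chain
of 50,000 — the parallel sampler needs several-fold more iterations, which
is the expected price of the $d$-shrinkage), and the convergence-vs-$n$
experiment uses a 1000-marker panel with $n \in \{200, 1000, 5000\}$ and
20 generations of mating.  "Iterations to agreement" is operationalized
as the first 100-iteration checkpoint at which the running-mean effects
give test-set EBVs correlating at least 0.99 with a converged single-site
reference, capped at 20,000 iterations (a censored run records the cap;
the comparison across $n$ is on rank averages, which the cap cannot
distort upward).  Convergence is declared when the PSRF of
$\sigma^2_a$ across five dispersed-start chains falls below 1.1; the
PSRF is floored at 1 so it reads as inflation over perfect mixing.
Pearson correlation is used for accuracy and agreement throughout, and
"adjusted phenotype" means subtraction of the posterior-mean general
mean — the model's only fixed effect.

Degenerate inputs are errors, not warnings: monomorphic markers inside a
sampler, non-PSD augmentation targets beyond the $10^{-8} d$ tolerance
(the message names the offending eigenvalue and suggests a larger
jitter), heritability outside $(0,1)$, and augmentations whose stored
fingerprint does not match the genotype matrix they are applied to.

## Known limitations

* Only the BayesCpi prior is implemented; other mixture priors would slot
  into the same likelihood-ratio structure but are out of scope.
* The general mean is the only fixed effect.
* The parallel backend is process-level on one machine; distributed
  (message-passing) execution is out of scope.
* The full augmentation stores a $(p+1) \times (p+1)$ matrix; beyond a
  few thousand markers the grouped variant is the practical route.
* The simulator's founder haplotypes are site-independent; short-range LD
  is entirely drift-generated and weaker than on real arrays at equal map
  length.

## Example

```{r example}
library(bayesxii)
cfg <- sim_config(n_founders = 100, n_generations = 20, p_loci = 200,
                  n_final = 700, n_train = 500, n_test = 200, seed = 42)
ds <- simulate_dataset(cfg)
G <- ds$train$geno; y <- ds$train$trait$y
traces <- run_chains(G, y, n_iter = 10000, thin = 10, n_chains = 5,
                     master_seed = 42)
diagnostics_report(traces, ds$test$geno$X, ds$test$trait$y)
aug <- build_oda(G)
tx <- run_chain_xii(G, y, aug, n_iter = 50000, thin = 25, seed = 43)
method_agreement(traces[[1]], tx, ds$test$geno$X)
```
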