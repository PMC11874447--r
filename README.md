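# tismod

Sparse Bayesian spatial factorization of spatially resolved transcriptomics
(SRT) data into **tissue modules**: latent expression components consisting
of a smooth spatial activity map over the profiled locations plus the
sparse set of genes driving it.  Tissue modules are the natural unit for
tissue-centric analysis — anatomical layers, tumour niches, stromal
compartments — because they are found unsupervised from spatial
co-expression rather than from cell-type references, may overlap in space
and in genes, and come with per-gene membership probabilities.

The package is aimed at anyone analysing spot- or bead-level SRT matrices
(ST/Visium-style arrays, Slide-seq/Stereo-seq-style bead data) who wants
interpretable spatial components with explicit sparsity, plus the
simulation and evaluation machinery to validate such decompositions.

## Model

For a normalized spots-by-genes matrix $Y \in \mathbb R^{S\times L}$ with
spot coordinates:

$$Y_{sl} \sim \mathcal N\Big(\textstyle\sum_{c=1}^{C} P_{sc} G_{cl},\
\lambda_s^{-1}\Big)$$

* $P_{\cdot c}$ — spatial map of module $c$, with Gaussian-process prior
  $\mathrm{MVN}(0, \sigma_c^{-1}\Sigma^{(c)})$,
  $\Sigma^{(c)}_{ss'} = \exp(-\tfrac12 d(s,s')^2 r_c)$ (squared-exponential
  kernel on Euclidean distance); the decay rate $r_c = 1/l_c^2$ is selected
  per module from a data-driven grid.
* $G_{cl} = \omega_{cl} s_{cl}$ — spike-and-slab loadings:
  $\omega_{cl}\sim\mathcal N(0,\beta_c^{-1})$,
  $s_{cl}\sim\mathrm{Bernoulli}(\psi_{cl}\phi_{cl})$ with Beta/Bernoulli
  hyperpriors.  Gene $l$ belongs to module $c$ when the posterior inclusion
  probability $E_Q(s_{cl}) > 0.5$.
* Inference is mean-field coordinate-ascent variational Bayes with a
  provably non-decreasing ELBO; surplus modules shrink to zero loading
  vectors and are flagged inactive, so the module count self-selects.

Fitted loadings can be held fixed to re-infer maps on another section of
the same tissue (`transfer()` / `predict(fit, newdata = ...)`).

## Worked example

```r
library(tismod)

# a 10x10 grid, 200 genes, one planted disk pattern carried by 40 genes
sim <- simulate_scenario(1, n_genes = 200, grid_size = 10, set_size = 40,
                         seed = 3)
fit <- tismod(sim$profile, C = 3, seed = 3)
fit
#> Tissue-module factorization: 100 spots x 200 genes, C = 3
#>   active modules: 1 of 3; converged after 12 rounds (ELBO -15677.55)

mask <- sim$truth$pattern_fields[[1]]
sapply(1:3, function(c) auroc_aupr(fit$maps[, c], mask)$auroc)
#> [1] 1.0000000 0.4671489 0.6088005

table(planted = lengths(sim$truth$memberships) > 0,
      member = gene_membership(fit)[1, ])
#>        member
#> planted FALSE TRUE
#>   FALSE   158    2
#>   TRUE      0   40
```

Module 1 recovers the planted pattern exactly (AUROC 1.0; the other two
modules are inactive noise and carry no member genes), and its membership
call finds all 40 planted genes with 2 false positives (FDR 0.048).
Downstream helpers: `summary(fit)` tabulates per-module gene counts and
length scales, `top_genes()` extracts ranked marker lists, `scale_map()`
prepares maps for display, `compare_modules()` tests gene-set overlap
between modules, and `align_to_domains()` / `best_threshold_ari()` /
`fdr_power_curve()` score fits against annotated domains.

For real data, start from `read_expression()` (dense TSV/CSV with
ST-style `"<x>x<y>"` spot names or a coordinate sidecar, or matrix-market
triplets), then `filter_profile()`, `normalize_profile()` and
`select_hvgs()` — or `preprocess_profile()` for the whole chain.  A thin
command-line wrapper with `simulate` / `preprocess` / `fit` / `transfer` /
`evaluate` subcommands is installed at
`system.file("cli", "tismod", package = "tismod")`.

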