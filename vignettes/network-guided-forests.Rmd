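---
title: "Network-guided random forests: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided random forests: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrf)
```

## The model

`netrf` grows classification forests whose trees are biased toward genes a
gene network says are interesting. The bias enters in exactly one place: the
distribution from which the `mtry` candidate splitting variables are drawn
at each tree node. Everything else — bootstrap resampling, Gini split
search, growth to purity, majority-vote aggregation, out-of-bag (OOB)
permutation importance — is the ordinary CART random forest, and with a
uniform sampling prior the implementation *is* the standard random forest
(the two code paths are tested to produce node-identical trees at a fixed
seed).

The sampling prior π\* is the equilibrium of a random walk with restart on
the network,

$$\pi_{t+1} = (1-r)\,A^\top \pi_t + r\,\pi_0,$$

with `A` the row-normalized 0/1 adjacency, `r` the restart probability and
π\_0 a restart distribution carrying external evidence. At `r = 1` the walk
never moves and π\* = π\_0; at `r = 0` it forgets π\_0 and settles on the
degree-proportional stationary law. In between, π\* blends three things:
degree, the evidence in π\_0, and network proximity to genes with evidence.

Six prior-construction strategies are built in and form the comparison set
of the evaluation harness:

| method | prior |
|---|---|
| Oracle | uniform over the (known) disease genes only |
| StandardRF | uniform over all genes |
| MarginalP | ∝ −log p (Welch two-sample t-test per gene) |
| Topology | ∝ degree |
| NetworkP | walk equilibrium, π\_0 ∝ −log p, r = 0.3 |
| NetworkQ | as NetworkP with Benjamini–Hochberg adjusted p |

Two readings of the construction were genuinely open and are resolved here
as follows.

* *Normalization of −log p.* The weights are normalized to sum to one (L1)
  rather than to unit Euclidean length, because π\_0 must be a probability
  distribution for the walk iteration to conserve mass. NetworkQ uses the
  identical transform on adjusted p-values.
* *The t-test.* Welch's unequal-variance form, the safer default for
  expression data; genes constant across all samples get p = 1 (no
  evidence) and p-values are floored at 1e-300 so −log p stays finite.
  When *every* (adjusted) p-value is 1 — routine for NetworkQ under a
  global null, where BH adjustment saturates — the restart distribution
  falls back to uniform with a message, rather than failing the fit.

## Numerical choices in the walk

* **Convergence.** L1 tolerance 1e-10 with at most 1000 iterations;
  convergence is geometric at rate (1 − r), so 1000 is ample for r ≥ 0.1.
  Non-convergence returns the last iterate with a classed warning.
* **Dangling genes.** A zero-degree gene has no outgoing transition and
  would leak walker mass. Its mass is redirected to the restart
  distribution at every step (a self-restart), keeping each iterate a
  proper distribution, so isolated genes still end up with restart-derived
  weight and weighted sampling stays well defined.
* **r = 0.** Power iteration can oscillate on bipartite graphs, so the
  restart-free case returns the degree law directly — it is the stationary
  distribution of the simple walk on any connected graph regardless of
  periodicity. Disconnected networks need no special casing for r > 0:
  the restart ties components together through π\_0.

## The forest

* **Weighted sampling without replacement** is by successive draws
  proportional to the remaining weights, renormalizing after each draw.
  The exact scheme is not canonical in the literature; this one matches
  the plain reading of "sampled according to π\*" and is exposed directly
  (`sample_candidates()`) so its empirical marginal frequencies can be, and
  are, tested against the prior.
* **Ties.** Split ties break deterministically (lowest gene index, then
  lowest threshold); prediction ties break to class 0; importance ties
  rank by gene order. All three are arbitrary, and fixed so that equal
  (data, config, seed) gives bit-identical results.
* **Thresholds** sit at midpoints of consecutive distinct sorted values
  within the node (standard CART).
* **mtry** defaults to ⌈√k⌉ where k is the number of genes with *positive*
  prior weight — for StandardRF that is the usual ⌈√p⌉, and for Oracle it
  reproduces a standard forest fit on the disease genes alone. A candidate
  that admits no impurity-reducing split simply yields none; candidates
  are not redrawn, so a node may become a leaf early.
* **Importance** is the unnormalized mean over trees (with non-empty OOB
  sets) of the OOB accuracy drop after permuting a gene within the tree's
  OOB samples; genes a tree never uses contribute exact zeros, so
  never-used genes score 0.

## Gene selection

`recursive_elimination()` drops the lowest-ranked ⌊0.10 k⌋ genes per round
(at least one, so small panels still shrink), stops when the next drop
would undershoot `min_genes`, and truncates to exactly `min_genes` by the
final ranking. Two under-determined points:

* Marginal p-values are computed once on the full data and renormalized
  over the retained genes — a gene's two-sample test does not change when
  other genes are dropped. Network priors *are* recomputed each round on
  the induced subnetwork, since degree and diffusion do change.
* The predictive model after selection is a standard uniform-prior forest
  on the selected genes, mirroring the Oracle benchmark's construction.

## What the simulator emulates — and what it does not

`simulate_network()` partitions genes into modules with sizes uniform on
[8, 50] (so the first quartile, which sets the default disease-module size,
lands in the 12–20 gene range typical of curated disease modules), wires
each module by preferential attachment, and joins each module's hub to an
earlier module's hub chosen with probability proportional to module size.
This yields one connected component, heavy-tailed degrees with dominant
hubs, and clear module structure — the features the evaluation depends on.
It is *not* a fit to any real interactome: clustering coefficients, degree
correlations and edge densities of curated PPI networks are not calibrated.

`simulate_expression()` draws from a Gaussian graphical model whose
precision matrix is nonzero exactly on the network edges (entries ±[0.1,
0.3], symmetrically rescaled until strictly diagonally dominant, hence
positive definite) and maps each gene through a Gaussian copula to a
negative-binomial marginal with mean log-uniform in [20, 2000] and
dispersion uniform in [0.1, 0.6] — bulk-RNA-seq-like counts whose rank
dependence follows the network. Library-size variation, batch effects and
zero inflation are deliberately absent, and the marginals are generic
rather than calibrated to a reference cohort. Passing tests therefore show
the *methodological* behaviour (who finds modules, who selects hubs
spuriously), not performance on any particular real dataset.

Phenotypes follow a logistic model: log-odds = Σ over disease genes of
β\_i X\_i with standardized expression and zero intercept, so cases and
controls are balanced on average. Scenarios: `Null` (no disease genes),
`RanEqu` (random genes, equal effects β), `ModEqu`/`ModTopo` (one module;
equal effects, or effects π\*\_i · β · |M| from a within-module walk with
restart mass on a randomly chosen *main* gene), and `TwoModEqu`/`TwoModTopo`
(two disjoint modules). Connectivity-based effects always sum to β·|M| per
module, so β stays the average effect size. The restart probability for the
effect-size walk is not pinned down by the phenotype model itself; it is
fixed at 0.3, the same value the NetworkP/NetworkQ methods use. The
disease configuration (module choice, main gene) is drawn once per
scenario run and held fixed across replications, like the network, so
selection counts refer to a fixed truth.

## Evaluation design

`run_scenario()` holds one network fixed, redraws expression and phenotype
per replication, splits samples equally into train and test halves, and
scores each method by (1) mean test misclassification of a standard forest
refit on the selected genes, (2) mean sensitivity — the selected fraction
of true disease genes — and (3) per-gene selection counts across
replications. Selection is top-|D| by importance *within the method's
feature set* (genes of positive prior weight): the Oracle's feature set is
the disease-gene set itself, which is what makes its sensitivity 1 by
construction and its accuracy the benchmark. Under `Null` there is no |D|;
the recorded selection size defaults to 15 genes, the midpoint of the
12–20 module-size band. Failed replications are excluded with a warning,
never silently.

Default problem sizes are desk scale — p = 200 genes, n = 400 samples,
200 trees, 10 replications — chosen so a full scenario comparison runs in
about a minute on one core; the full-scale design (p = 1000 or 3000,
n = 2000, 1000 trees, 100 replications) is reached by changing arguments,
not code.

## Known limitations

* Binary phenotypes only; no survival or quantitative endpoints.
* Unweighted, undirected networks; edge confidence scores are not used.
* The weighted-draw scheme is one defensible reading of "sampling
  according to π\*"; alternatives (e.g. Efraimidis–Spirakis keys) would
  change tree-level randomness though not the marginal single-draw law.
* Hub bias is a *feature* of topology-weighted priors that the null
  scenario exposes as spurious selection; the package measures it
  (`plot_selection_degree()`) but does not correct for it.
* At the desk scale the sensitivity differences between the
  evidence-using methods are within one or two standard errors;
  full-scale runs are needed for sharp method rankings.
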