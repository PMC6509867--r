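---
title: "Stage-specific gene selection and pathway evolution networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific gene selection and pathway evolution networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagewise)
```

## The problem

Tumours progress through pathological T stages (t1--t4), and the genes that
drive each stage need not be the same. Given paired gene-expression and DNA
methylation profiles for the same patients, a clinical table with a
`pathology_t_stage` entry per sample, a protein--protein interaction (PPI)
network and a pathway gene-set collection, `stagewise` identifies a gene set
per stage, condenses each into a connected functional module on the PPI
network, and summarizes how stage-enriched pathways overlap one another --
a pathway-level view of disease progression.

The pipeline has four statistical steps, each exposed as ordinary functions
and orchestrated by `run_pipeline()`.

## Step 1: stage-specific gene selection

For each stage $t$ the clinical labels are binarized one-vs-rest into
$Y_t \in \{0,1\}^m$. Expression and methylation features are concatenated
into a standardized design matrix $X$ (two columns per gene), and we solve

$$\hat\beta(\lambda) \;=\; \arg\min_\beta\; \frac{1}{m}\lVert Y_t - X\beta\rVert_2^2
 \;+\; \lambda\left( a\lVert\beta\rVert_1 + (1-a)\lVert\beta\rVert_2^2 \right)$$

along a log-spaced grid of `n_models` overall penalty strengths $\lambda$,
from $\lambda_{\max}$ (the smallest value at which
$\max_j |\tfrac{2}{m} x_j^\top y| \le \lambda a$ forces $\hat\beta = 0$)
down to `lambda_min_ratio` $\times\ \lambda_{\max}$. The response is kept
as the squared-error regression on the binary labels rather than a logistic
model: the selection signal of interest is the ordering in which features
enter the path, for which the least-squares path is standard and fast.

Each grid point is one "model". A gene counts as selected in a model when
any of its feature columns (expression *or* methylation -- the union, never
the sum) has $|\hat\beta_j| >$ `coef_threshold`; genes selected in at least
`cutoff` of the `n_models` models form the stage's gene set. This
selection-frequency rule is what makes the output stable: a gene must stay
active across a wide span of penalty strengths, not merely appear once near
the unpenalized end.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha_mix` | 0.5 | lasso/ridge mixing $a$; at 0.5 the two penalty coefficients are equal at every grid point |
| `n_models` | 50 | path points (models) per stage |
| `cutoff` | 20 | minimum selections out of `n_models` |
| `coef_threshold` | $10^{-8}$ | numerically-nonzero cut on $|\hat\beta|$ |
| `lambda_min_ratio` | $10^{-2}$ | path floor as a fraction of $\lambda_{\max}$ |
| `tol` | $10^{-7}$ | coordinate-descent sweep tolerance (max coefficient change) |

The path floor deserves a note. With more features than samples the
least-squares path saturates as $\lambda \to 0$: near the floor nearly
every model contains $\sim m$ active features, so counting selections over
those models is uninformative and background genes flood past any cutoff.
We therefore default to $10^{-2}$, the conventional floor for the
$n > m$ regime (it is, for instance, what `glmnet` defaults to when
`nobs < nvars`); $10^{-3}$ remains one config entry away for tall data.

### Solver

The objective is minimized by cyclic coordinate descent (C++ via Rcpp) with
warm starts down the grid and an active-set inner loop: full sweeps
alternate with passes over the currently nonzero set, and the grid point is
converged when a full sweep moves no coefficient by more than `tol`. The
coordinate update is the closed-form soft-threshold step; with
`alpha_mix` $< 1$ the ridge term makes each subproblem strictly convex, so
the iteration is monotone in the objective. The tests verify the solutions
against an independent accelerated proximal-gradient (FISTA) minimizer, a
1-D grid-search oracle, and the closed-form ridge solution in the
vanishing-lasso limit.

Degenerate inputs are refused loudly: constant labels raise an error, and a
label vector orthogonal to every column yields the all-zero path (the grid
collapses to machine-epsilon penalties and the warm start never moves).
$\lambda_{\max}$ is inflated by one part in $10^9$ so the first grid point
is exactly zero despite floating-point rounding of the subgradient bound.

## Step 2: giant-component modules

Selected genes are often scattered across the interactome, so each stage's
set is expanded with its direct (first-hop) PPI neighbours, the full
subgraph induced by seeds plus neighbours is taken from the background
network, and only the giant connected component is kept as the stage
module. Members are annotated by role -- `detected` (seed) versus
`neighbor` -- and, across stages, with pairwise overlap tags such as
`2-3N` (stage-2 detected gene also present as a stage-3 neighbour) or
`3N-4N` (neighbour in both), lower stage always written first.

Size ties between components are broken deterministically: first by the
number of detected seeds a component contains, then by the
lexicographically smallest sorted node list. Components of size one are
permitted; an empty subnetwork yields an empty module with a warning
rather than an error, so a stage with no selected genes does not abort a
run.

## Step 3: pathway enrichment

Each module's genes are tested against every pathway by the upper-tail
hypergeometric probability $P(K \ge k)$, with Benjamini--Hochberg
correction across the pathways reported for that stage and a default
significance threshold of $q \le 0.05$. Pathways sharing no gene with the
module are not reported. The test universe is the set of genes that are
both annotated in the collection and measured in the omics layers -- the
conservative common default, and configurable.

## Step 4: the pathway evolution network

Significant pathways across all stages are pooled into one network: a
pathway significant in several stages remains a single node carrying its
stage set. Two pathways are connected when their full annotated gene sets
share at least one gene, with edge weight

$$W \;=\; \frac{k^2}{p\,q},$$

where $k$ is the shared-gene count and $p, q$ the two pathway sizes. $W$
is symmetric, lies in $[0,1]$, equals 1 exactly for identical sets and 0
exactly for disjoint ones; it is the natural product of the two containment
fractions $k/p$ and $k/q$. Edge weights always use the full annotated
sets, not the enriched-overlap subsets. Connected components of this
network are the operational definition of pathway "groups"; reading each
group's stage composition gives the progression story.

## The synthetic-data generator

`synth_config()` / `write_synth_inputs()` generate the five inputs with the
statistical structure the pipeline assumes, plus a `truth.json` ground
truth for parameter-recovery testing:

* **Omics**: background entries i.i.d. $N(0, \sigma^2)$ on a z-score-like
  scale for both layers (the pipeline standardizes columns anyway, so
  marginal shape is not load-bearing). Each stage plants
  `signal_genes_per_stage` genes whose mean shifts by
  $+\texttt{effect\_size}\,\sigma$ in expression and
  $-\texttt{effect\_size}\,\sigma$ in methylation in that stage's samples
  -- the canonical anti-correlated promoter-methylation/expression
  relation, which also exercises the union rule of gene-level counting.
* **PPI**: Erdős--Rényi background at `ppi_mean_degree`, plus a star over
  each stage's planted genes so they are mutually reachable within two
  hops -- the structure the giant-component step is designed to exploit.
  Component structure, not the degree law, is what that step consumes, so
  a scale-free background is deliberately not simulated.
* **Pathways**: per stage, `signal_pathways_per_stage` sets seeded with at
  least 50% of that stage's planted genes; each gets a size-matched random
  decoy. The lead signal pathways of consecutive stages share
  `shared_chain_genes` members drawn from the planted genes of the two
  flanking stages, so the shared members are disease genes the pipeline
  can actually observe in both stages' modules -- this plants a detectable
  cross-stage chain in the overlap network.

Defaults (200 samples in four equal stages, 500 genes, 10 planted genes
per stage, effect size 2, noise 1, mean degree 4, 40 pathways of 10--20
genes) are chosen so that the planted signal is strong but the background
is dense enough for false selection to be possible; they are the study
conditions under which the end-to-end recovery properties in the test
suite are stated. Everything is a deterministic function of the
configuration seed.

What the generator does **not** emulate: batch effects, copy-number
contamination, probe-level methylation structure (an optional locus map in
`read_omics()` covers multi-gene CpG sharing), unbalanced stage prevalence
(configurable but uniform by default), correlated background genes, and
scale-free interactome topology. Passing recovery tests on this generator
therefore shows the machinery is correct and well-calibrated for clean
planted signal; it does not certify performance on real tumour cohorts.

## Recovery metrics

In the end-to-end checks, *recall* is strict per stage: the fraction of
stage-$t$ planted genes in the stage-$t$ selected set. *Precision* is
measured against the union of all planted genes. The reason is structural:
with one-vs-rest labels, a gene planted for stage $s$ is genuinely
informative for every other stage's contrast (it is elevated in part of
the "rest" class, giving it a real negative association with $Y_t$), so a
correct selector will pick some cross-stage planted genes, and the
meaningful false positives are the background genes. Module coverage --
the fraction of selected planted genes retained by the giant component --
is reported separately.

## Ingestion rules

Features with any missing value are dropped. Methylation loci mapping to
several genes are shared equally (value divided by the gene count), and a
gene's value is the mean of its received contributions -- order-independent
and on the original scale. Substage suffixes (`t2a`, `T2b`) normalize to
their major stage; stages outside t1--t4 after normalization are an error
naming the offending samples. Columns are z-scored because the elastic-net
penalty is scale-sensitive; constant columns are dropped with a warning.
Samples are aligned by intersecting the identifiers present in expression,
methylation and the staged clinical rows.

## Known limitations

* The least-squares-on-binary-labels objective is a selection device, not
  a calibrated classifier; its coefficients should not be interpreted as
  effect sizes.
* The number of "models" is a path length, so cutoff/`n_models` is the
  real stability dial; resampling-based stability selection would be a
  natural extension and is intentionally out of scope.
* Enrichment is a plain hypergeometric test; it ignores gene-length,
  expression-level and annotation biases that dedicated enrichment tools
  model.
* Pathway groups are connected components; with dense annotation overlap
  a single giant group can swallow the structure, in which case the
  `min_w` edge filter is the intended remedy.
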