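---
title: "Sparse multiblock discriminant analysis: model, algorithm and design notes"
author: "multiblockDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse multiblock discriminant analysis: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiblockDA)
```

## The model

A multiblock dataset is a collection of $J$ feature matrices
$X_1, \dots, X_J$ ($N$ samples $\times$ $P_j$ features, columns centered)
measured on one common sample set. In the genomic layout the blocks are
SNP, CNV, DNA methylation, gene expression, and a single-column class
block holding the case/control labels coded $\pm 1$. Each block is
summarized by a latent score $v_j = X_j \alpha_j$, and the fit maximizes
the weighted sum of squared covariances between the scores of linked
blocks,

$$
\max_{\alpha_1,\dots,\alpha_J} \;
\sum_{j \ne k} d_{jk}\,
\bigl(\alpha_j^\top \chi_j^\top \chi_k \alpha_k\bigr)^2
\quad \text{s.t.} \quad
\lVert \chi_j \alpha_j \rVert^2 = N,\;
\text{elastic-net sparsity on } \alpha_j ,
$$

where $\chi_j = X_j$ for feature blocks and
$\chi_5 = X_5 + b \odot m$ for the class block (below). The binary linkage
matrix $C$ declares which pairs contribute; the weight matrix $D$
generalizes it. In the default genomic graph the three upstream blocks each
link to gene expression and gene expression links to the class block, with
the expression–class pair weighted 3: the class block has one column, so
without up-weighting its covariance term would be negligible against the
block–block terms. With binary weights and no slack
(`sgccaMode = TRUE`) the objective is exactly the sparse generalized
canonical correlation model, which the package keeps as a built-in
ablation.

**Assumptions.** Blocks share the sample set and ordering; labels are
binary with both classes present; features are approximately continuous
(the optimizer only uses inner products, but heavily discrete blocks
weaken the covariance signal); missing values are handled upstream.

## Slack variables: the discriminant ingredient

The class margin is enlarged with the slack device of discriminative
least-squares regression. Each sample carries a nonnegative slack $m_i$,
updated once per sweep as

$$
m = \max\bigl(b \odot (v_{\mathrm{GE}} - v_{\mathrm{class}}),\, 0\bigr),
\qquad
\chi_5 = X_5 + b \odot m ,
$$

with $b_i = \pm 1$ the class direction of sample $i$. A sample whose
gene-expression score already overshoots its class target in its own
class's direction pushes the target further out: the margin can only
grow, and $b \odot (\chi_5 - X_5) = m \ge 0$ guarantees a slack never
reverses a label. The slack-augmented $\chi_5$ is used in *every*
covariance term, so the class-side pull propagates to the upstream blocks
through the gene-expression score. With $m \equiv 0$ and $D = C$ the
discriminant fit is algebraically the plain model — the package's test
suite asserts the two code paths produce identical loadings in that case.

Two presentation choices in the source derivation deserve a note. First,
the derivation's slack update subtracts the class-side quantity
$\upsilon_5$; read as the *inner component* of the class block that
quantity is $3\,\mathrm{cov}(v_5, v_4)\, v_4$, of order $N$, and the slack
would swamp the $\pm 1$ labels. We read it as the class block's *latent
score* $v_5$ (the two symbols are typographically near-identical), which
keeps the slack on the scale of the scores and reproduces the original
least-squares regression formulation exactly. Second, the
gene-expression loading is updated against its full inner component
$\upsilon_4$ — in which the class/slack target already enters through the
weighted expression–class term — rather than against a class-only target;
a class-only target would ignore the three upstream blocks in the update
and forfeit the ascent property of the cyclic iteration.

## The optimizer

Each rank (component) is fit by a cyclic Wold iteration:

1. **Initialization.** Loadings start from seeded standard-normal draws,
   normalized. The whole fit is bit-reproducible from `seed`.
2. **Dense warm start.** Sweeps with $\lambda = 0$ until the objective
   change falls below `tol` (or `warmMaxIter` sweeps), converging to the
   dominant multiblock covariance structure. This is initialization, not
   model fitting: cross-validating $\lambda$ against a random-direction
   target would be meaningless.
3. **Shrinkage selection.** Per block, $\lambda_j$ is chosen once per rank
   by K-fold cross-validation (default $K = 5$) of the soft-thresholded
   regression of the warm inner component $\upsilon_j$ on the block:
   inner products on training folds are rescaled to the full-sample scale,
   the loading's overall scale is refit by least squares, and the held-out
   entries of $\upsilon_j$ are predicted; the $\lambda$ with minimal mean
   held-out squared error wins, ties broken toward the larger (sparser)
   value. The automatic grid holds 20 log-spaced candidates from 0 to
   0.95 of $\max_i \lvert \chi_j(i)^\top \upsilon_j \rvert$; because the
   grid never reaches the maximum itself, shrinkage can never annihilate a
   block's strongest feature (in particular the one-column class block
   always survives). `cvEverySweep = TRUE` re-selects every sweep instead;
   it is off by default because a moving penalty breaks the within-rank
   monotonicity of the objective.
4. **Sparse sweeps.** Blocks update in the order upstream blocks, class
   block, gene-expression block last (so the discriminant block sees fresh
   neighbor scores): inner component, univariate soft-threshold,
   normalization to $\lVert \chi_j \alpha_j \rVert^2 = N$; each sweep ends
   with the slack update. Because the inner component of a single-neighbor
   block is a covariance-scaled copy of its neighbor's score, an absolute
   threshold would inherit that prefactor's drift between sweeps; the
   selected $\lambda_j$ is therefore rescaled each sweep by the ratio of
   the current to the selection-time target norm, keeping the selected
   sparsity level rather than an absolute cut.
5. **Stopping.** The rank stops when the relative objective change drops
   below `tol` (default $10^{-6}$), when `maxIter` sweeps are reached, or
   when a sweep fails to increase the objective — in that case the sweep
   is rolled back and the previous iterate kept (ascent-only acceptance,
   the same safeguard line-search optimizers use). The recorded objective
   trace is consequently non-decreasing, which the tests assert on seeded
   fits.
6. **Deflation and further ranks.** Each feature block is residualized
   against its own score, $X_j \leftarrow X_j - v_j (v_j^\top
   v_j)^{-1} v_j^\top X_j$, and the next rank is fit on the residuals. The
   class block is *not* deflated: projecting a one-column $\pm 1$ block
   out of its own span would erase all class information from later ranks.
   Extraction stops early when a rank returns all-zero loadings.

**Degenerate inputs.** An all-zero loading cannot be normalized and is
returned as-is with a `degenerate` flag; an annihilating user-supplied
$\lambda$ grid yields a zero-rank result rather than an error; a loading
that dies during later sweeps rolls back to the last accepted iterate;
scores that are numerically zero relative to their block are not used for
deflation (their normalized projector would be noise). Constant columns
are centered to zero and retained with a warning so feature indices stay
aligned with ground-truth masks.

**Normalization conventions.** The score-norm contract
$\lVert \chi \alpha \rVert^2 = N$ is the package default; the `"unit"`
option ($\lVert \chi\alpha \rVert = 1$) differs by the constant
$\sqrt{N}$, cancels in covariance *rankings*, and is provided for
compatibility with the unit-variance convention some derivations use.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `nRanks` | 3 | components extracted; the simulated signal subspace is low-dimensional and selection is a union over ranks, so a handful of ranks recovers the support without accumulating false positives |
| `maxIter` | 100 | cap on sparse sweeps per rank (dimensionless) |
| `tol` | 1e-6 | relative objective-change convergence threshold |
| `cvFolds` | 5 | K of the shrinkage cross-validation |
| `lambdaGrid` | `"auto"` | 20 log-spaced candidates, 0 to 0.95·max inner product |
| `discriminant` | `TRUE` | slack machinery on the expression–class pair |
| `sgccaMode` | `FALSE` | binary weights, slack off (ablation) |
| `warmMaxIter` | 25 | cap on dense warm-start sweeps |
| `classWeight` (graph) | 3 | up-weighting of the expression–class covariance |

## What the generator emulates — and what it does not

`simulateMultiblock()` reproduces an abstract benchmark, not genomic data.
Three upstream blocks (100/200/300 features) are built from four column
generators: mean-shifted normals (the ten signal features per block, means
2.4/−2.6, 3/4, 5/−3), a Bernoulli-indicator-plus-noise generator
(threshold 0.6), AR(1)-correlated multivariate normals (lag-1 correlation
0.8–0.9, the multicollinear nuisance), and variance-scaled normals. The
gene-expression block is $X_4 = \sum_j X_j B_j + \Xi$ with standard-normal
noise $\Xi$ and 50 columns; each $B_j$ is nonzero only in its leading
$10 \times 10$ corner, so exactly ten features of every block — including
the response block — carry signal. Reading the signal restriction
uniformly across blocks is deliberate: with coefficients dense across
response columns, every response feature is signal-bearing and a
ten-feature ground truth for that block would be unreachable by any
method. Nonzero coefficients are drawn uniformly from $[0.5, 1.5]$ with
random sign, per replication.

Class labels are Bernoulli draws with probability
$\pi = \operatorname{logit}^{-1}\bigl((X_4 - \bar X_4) B_4\bigr)$, where
$B_4$ is supported on the response block's ten signal columns. The linear
predictor is centered: the upstream generators have large nonzero means
whose weighted sum would otherwise saturate $\pi$ at the same value for
every sample and systematically produce single-class cohorts. Centering is
an implicit intercept and keeps the classes near balance; an (unlikely)
single-class draw is redrawn from subsequent RNG values and recorded.

The generator does **not** emulate SNP allele coding, copy-number
segmentation, methylation beta distributions, linkage disequilibrium
beyond AR(1), batch effects, or label noise. Passing the replication
study therefore demonstrates that the optimizer recovers planted sparse
cross-block structure at realistic dimensions and noise — not that it
will perform identically on real multi-omic cohorts.

## The replication study

`runStudy()` repeats, per replication: simulate (N = 500), prepare, fit
each method on identical data, select features ($|\alpha| > 0$ in any
rank), and score against the truth masks. TPR, PPV and ACCU are computed
from confusion counts pooled over the three upstream blocks (600 features,
30 true). Pooling stops at the upstream blocks because the classical
two-block comparator in this benchmark treats gene expression as the
response side and cannot select its features; restricting the confusion
matrix keeps the score comparable across methods.
`scoreSelection()` pools all four feature blocks (650 features, 40 true)
when called directly, and both poolings are available. A replication whose
fit fails is recorded, excluded from the summary, and warned about —
never silently dropped. The study reports mean, sample standard deviation
and standard error over replications; `scripts/acceptance.R` runs the
50-replication version for both methods from one master seed (replication
$r$ uses seed $\mathrm{master} + r$, so any replication is reproducible in
isolation). At these sizes one replication fits both methods in under a
second; the full study takes well under a minute on one CPU.

## Known limitations

* Binary classes only; the multi-class extension of the slack device is
  out of scope.
* No missing-value handling; imputation is upstream.
* The constraint-form sparsity parameters are not exposed; only the
  Lagrangian $\lambda$ form that the soft-thresholding solves.
* The covariance objective with a moving penalty is not guaranteed
  monotone; the ascent-only acceptance rule trades a possibly earlier
  stop for a monotone trace. In practice the dense warm start carries the
  optimization and the sparse phase stabilizes within a few sweeps.
* λ cross-validation is once per rank by default; data whose covariance
  structure changes drastically across sweeps may prefer
  `cvEverySweep = TRUE` at the cost of the monotone trace.
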