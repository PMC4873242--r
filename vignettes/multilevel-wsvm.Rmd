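---
title: "Multilevel weighted SVMs: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel weighted SVMs: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlwsvm)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The classification model

The base learner is the soft-margin SVM with RBF kernel
$k(x,z)=\exp(-\gamma\|x-z\|^2)$. For imbalanced problems the package uses
its cost-sensitive form, in which positive-class (minority, label $+1$) and
negative-class slack variables carry separate penalties $C^+$ and $C^-$:

$$\min_{w,b,\xi}\ \tfrac12\|w\|^2
  + C^+\!\!\sum_{i:y_i=+1}\!\xi_i + C^-\!\!\sum_{j:y_j=-1}\!\xi_j,
\qquad y_i(w^\top\phi(x_i)+b)\ge 1-\xi_i,\ \ \xi_i\ge 0 .$$

With $C^+=C^-$ this is the standard SVM, and the package's tests assert
that equivalence numerically. The dual quadratic program is delegated to
libsvm (through `e1071`); the package re-derives the decision function from
the returned dual coefficients and fixes its orientation so that positive
decision values always mean the minority class. The dual-feasibility
invariants ($|\alpha_i|\le C_{y_i}$, $\sum_i \alpha_i y_i=0$, margin
condition on free support vectors) are asserted against an independent
quadratic-programming solve (`kernlab::ipop`) in the test suite rather than
trusted.

**Class weights.** The inverse-size rule resolves a base penalty $C$ into
$C^+ = C\,l/(2n^+)$ and $C^- = C\,l/(2n^-)$ ($l$ = training size). This
keeps the total penalty mass of the two classes equal, so the majority
class cannot dominate the objective merely by being large. Only
proportionality to inverse class size is essential; the $l/2$ scaling is a
normalization choice that makes the balanced case reduce to the uniform
penalty exactly, which is also what the tests exploit.

## Multilevel training

Exact kernel-SVM training with model selection is quadratic-to-cubic in the
sample count, which is what the hierarchy removes.

**Coarsening.** Each class is coarsened on its own k-nearest-neighbor graph
(k = 10; Euclidean distances on standardized features, matching the RBF
geometry). One step selects a greedy maximal independent set — a dominating
set of the class, so every point is either kept or adjacent to a kept point
— and, while fewer than a fraction $Q = 0.5$ of the class is selected,
keeps adding maximal independent sets of the remainder. The last sweep may
overshoot $Q$; that is accepted rather than trimmed, because trimming would
break the domination property. Recursion stops when a level's total size
is at most 500 points (one joint bound over both classes), or when no class
can shrink. A class at or below 250 points (half the bound) is carried
unchanged while the other continues; this is what drives the coarsest level
toward balance even at a 98:2 input skew. Level graphs are rebuilt on the
selected points at every level — selection-based coarsening keeps levels as
nested subsets, so rebuilding preserves exact k-NN semantics and the stored
graphs are reused during refinement.

**Coarsest solve and the uniform-design search.** The coarsest level is
trained directly, with hyperparameters chosen by a nested uniform design:
9 design points over $C\in[0.01,100]$, $\gamma\in[0.005,3.000078]$ mapped
on the $\log_2$ scale, then 5 points on a half-width window recentered on
the stage-1 optimum and clipped (by shifting, to preserve width) into the
initial range. The committed lattices are $U_9$ with level pattern
(1,5),(2,9),(3,3),(4,7),(5,1),(6,6),(7,2),(8,8),(9,4) at grid fractions
$(2i-1)/18$, and $U_5$ with pattern (1,2),(2,5),(3,3),(4,1),(5,4) at
fractions $(2i-1)/10$. The $U_5$ center run (3,3) is mapped exactly onto
the stage-1 optimum and not retrained, so a full search evaluates
$9+5-1=13$ distinct combinations — the fixed budget the design exists to
enforce. Published uniform-design tables differ between sources; any fixed
space-filling pattern with these run counts serves, but the tables are
committed in code so results are reproducible. Candidates are scored by
mean G-mean over stratified 5-fold validation with shared folds; a fold
whose prediction degenerates to one class scores 0. Ties prefer smaller
$C$, then smaller $\gamma$ — the smoother model.

**Refinement.** From the coarsest level upward, the inherited support
vectors are expanded with up to 5 of their nearest same-class neighbors
from the stored level graph (neighbor lists are per class, so the expansion
never crosses classes). If the resulting training set has fewer than
$Q_{dt} = 500$ points, the uniform-design search is re-run warm-started at
the inherited $(C,\gamma)$ — warm starts restrict stage 1 to a half-width
window around the center, on the reasoning that the coarse optimum is
already in the right region — and one model is trained. Otherwise
$(C,\gamma)$ are inherited verbatim and the set is clustered per class with
k-means into $K = \max(2, \lfloor n/Q_{dt}\rfloor)$ clusters total,
apportioned to classes by size (at least one each); every cluster is paired
with the nearest $\lceil 0.10\,K_{\mathrm{opp}}\rceil$ opposite-class
clusters by centroid distance, one weighted SVM is trained per pair, and
the union of the pair models' support vectors moves up. $Q_{dt}$ is set
equal to the coarsest bound: both thresholds answer the same question
("small enough to solve directly?") and no second value is justified.

Three design points were genuinely open and are resolved as follows.
*Prediction after a clustered finest level*: the refinement returns a
support set and parameters but no single decision function, so the package
trains one consolidating weighted SVM on the returned support set with the
final $(C,\gamma)$ — the minimal completion that yields a predictor for
unseen points. *Neighbor-list symmetrization*: the coarsening needs an
undirected graph; the union of directed k-NN edges is used (an edge exists
if either endpoint lists the other), the more inclusive convention, which
can only improve domination coverage. *Datasets at or below the coarsest
bound*: the framework collapses to one uniform-design search plus one
weighted SVM, and the test suite asserts this path is identical to calling
those two functions directly with the same seed.

## Missing values: regularized EM

Imputation treats the features as jointly Gaussian and alternates between
(a) re-estimating the mean and covariance of the completed data and (b)
replacing each missingness pattern's missing block with the prediction of
a ridge regression of those features on the pattern's observed features.
The ridge penalty of every regression is chosen by generalized
cross-validation over the log grid $10^{-4},\dots,10^2$ (13 points):
regularization controls the variance of imputations exactly where the
observed information is weak. Iterations start from mean imputation (the
standard regularized-EM start) and stop when the largest relative change
of the imputed values drops below $10^{-4}$ or after 50 iterations —
conventional values; on the package's fixtures convergence takes about 10
iterations and the change criterion decreases monotonically after the
first step, which a test asserts with a small numerical slack. Observed
cells are never modified, a feature observed nowhere is an error, and a
non-converged run returns its last iterate with a warning rather than
failing.

Held-out data are completed by a single frozen conditional-mean pass,
$\hat x_m = \mu_m + (x_o-\mu_o)(\Sigma_{oo}+\lambda I)^{-1}\Sigma_{om}$,
using the training-fold $\mu$, $\Sigma$ and the median of the fitted
ridge penalties (rescaled to the covariance scale) — no statistic of the
held-out fold enters, and a test compares fold-wise against whole-data
imputation parameters to detect leakage.

The mean-imputation baseline is included because it is the limit of the
regularized scheme under infinite shrinkage; the package's property test
requires the EM imputer to beat it in median RMSE on equicorrelated
Gaussian data ($\rho = 0.9$, d = 10, n = 500, 20% missing, 10 seeds).

## Evaluation protocol

Performance is reported as sensitivity, specificity, G-mean
$\sqrt{SN\cdot SP}$ and accuracy from the $\pm1$ confusion matrix. An
empty rate denominator reports 0 with a degeneracy flag — a deliberate
convention that makes degenerate predictors lose the model selection.
Cross-validation uses stratified outer folds (10 by default; plain random
folds would starve the minority class at high skew), fits the normalizer
and the imputer on each training fold only, and averages per-fold metrics
(pooling over all held-out predictions is available by flag, since both
conventions exist in practice). Whole-data standardization before
splitting — the common benchmark preprocessing — is available as
`normalize_global`, but fold-local is the default because it is the
statistically safe choice.

## Synthetic data: what it does and does not show

The generator produces the two classical Gaussian-mixture benchmark
geometries — two unit-covariance classes at opposite means
$\pm(s/2)/\sqrt{d}\cdot\mathbf 1$ (separation $s = 4$ reproduces the
classical twonorm construction with means at $2/\sqrt d$), and a
variance-4 class around a unit-covariance class (ringnorm-like) — plus
multi-blob layouts for one-against-all tests, with configurable imbalance,
equicorrelation and separation. Missingness is injected MCAR with an
*exact* masked-cell count ($\lfloor r_{mv}\,n\,d\rceil$ cells drawn without
replacement) rather than per-cell Bernoulli, so tests can assert counts
deterministically; rows are never fully masked. A Monte-Carlo test checks
that the mask is independent of the labels.

Passing on this data shows that the machinery — coarsening contracts,
budget of the search, weighting benefit, imputation benefit — behaves as
designed under known Gaussian geometry. It does not show robustness to the
pathologies of real clinical tables: informative (MAR/NMAR) missingness,
heavy-tailed or categorical features, label noise, or covariate shift.
The imputer in particular is derived under joint Gaussianity and MCAR.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design: the
coarsening contract is checked on 10,000 points (k = 10, the scale at which
the hierarchy is exercised over several levels), the search budget on 500,
the refinement-vs-direct comparison on 1,200-point fixtures over 5 seeds
(agreement within 0.05 G-mean), the benchmark-regime check on the 7,400 ×
20 twonorm geometry (held-out G-mean ≥ 0.95 with the full pipeline), and
the statistical comparisons over 10 seeds each. Exact k-NN is used up to
10,000 points; above that a random-projection-tree forest with one
neighbor-of-neighbor refinement sweep provides approximate neighbors (the
tests require recall ≥ 0.9 against brute force, and the forest equals exact
search when its leaves are made exhaustive). Ties in neighbor distance
break by index; standard deviations are sample (n−1) and floored at
$10^{-12}$, so constant features standardize to 0; support-vector
membership uses $|\alpha| > 10^{-8}$; sign ties in prediction go to the
minority class. All randomness — generators, fold assignment, greedy
orders, k-means starts — derives from explicit seeds, and identical seeds
reproduce identical models end to end.

## Known limitations

The hierarchy assumes Euclidean neighborhood structure is informative; on
purely categorical or very high-dimensional sparse data the k-NN graphs,
and hence the coarsening, degrade. The clustered refinement branch trains
independent pair models whose support-vector union can exceed what a joint
solve would select. One-against-all multiclass trains per-class binary
models without calibrating their decision scales. The imputer's Gaussian
conditional means are linear; strongly nonlinear feature dependence is not
captured.
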