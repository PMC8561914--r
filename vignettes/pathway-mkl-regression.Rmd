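---
title: "Pathway-based multiple kernel learning for tumour volume regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based multiple kernel learning for tumour volume regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Predicting a continuous clinical outcome — here the volume of a primary
tumour at diagnosis — from bulk gene expression is usually done with models
that consume all genes at once (random forests, support vector regression on
the full expression vector). Such models can predict well, but because
expression features are strongly correlated, the genes they lean on change
from one train/test split to the next, and they say little about *which
biological processes* drive the outcome.

`prognosit` instead gives every pathway (gene set) its own kernel and learns
the predictor together with a sparse convex combination of those kernels.
For a cohort of $N$ tumours with expression profiles $x_i$ and responses
$y_i$, the base learner is $\varepsilon$-insensitive support vector
regression: residuals inside a tube of half-width $\varepsilon$ are free,
residuals outside it are penalized linearly with weight $C$, and the
function norm is regularized. Its dual is a quadratic program in the $2N$
coefficients $(\alpha^+, \alpha^-)$,

$$
\min\;
-\sum_i y_i(\alpha_i^+-\alpha_i^-)
+\varepsilon\sum_i(\alpha_i^++\alpha_i^-)
+\tfrac12\sum_{ij}(\alpha_i^+-\alpha_i^-)(\alpha_j^+-\alpha_j^-)
K_{ij},
$$

subject to $0\le\alpha_i^\pm\le C$ and $\sum_i(\alpha_i^+-\alpha_i^-)=0$.
Since samples enter only through the kernel $K$, the model extends to
multiple kernels by substituting $K_\eta=\sum_{m=1}^P \eta_m K_m$, with one
Gaussian kernel $K_m$ per gene set, computed on the set's expression
sub-matrix. The weights $\eta$ live on the unit simplex
($\eta_m\ge 0$, $\sum_m\eta_m=1$), whose $\ell_1$ geometry drives most
weights to zero — the surviving sets are the model's pathway selection.

Training alternates two exactly solvable steps, starting from uniform
weights $\eta_m = 1/P$:

1. solve the SVR dual at the current $K_\eta$;
2. update the weights multiplicatively,
   $\eta_m' \propto \eta_m\sqrt{\alpha^\top K_m\alpha}$
   (with $\alpha=\alpha^+-\alpha^-$), renormalizing to the simplex.

The update is the exact minimizer of the group-lasso form of the
regularizer at fixed coefficients, so each half-step cannot increase the
nested objective: the primal value decreases monotonically. Equivalently,
the recorded *dual* value (a negated primal at each solve) increases
monotonically; the per-iteration trace kept by `prognosit_fit()` lets the
test suite verify this. The nested problem is not jointly convex, so only a
stationary point is guaranteed; in practice the loop converges in tens of
iterations, and we run at most 200 with an early stop when the
$\ell_1$ change of $\eta$ falls below $10^{-6}$. The reported solution is
re-solved once at the final weights so coefficients and weights are
mutually optimal. A final weight above 0.01 marks a set as selected.

## Kernels and tunable parameters

* **Kernel width** $\sigma_m$: the mean Euclidean distance over all
  unordered pairs of *training* samples on the set's standardized
  sub-matrix (self-pairs excluded; ordered vs unordered makes no
  difference to the mean). Widths are computed once per training set and
  reused for test-time cross-kernels, so test data never influence the
  model. A degenerate all-identical sub-matrix would give $\sigma=0$; the
  stack builder substitutes 1 with a warning, which makes that kernel the
  all-ones matrix — harmless inside a convex combination. Kernels carry no
  further normalization beyond the Gaussian's intrinsic unit diagonal.
* **Regularization** $C>0$: tuned over $\{10^{-3},\dots,10^{3}\}$ (7
  values).
* **Tube-width multiplier** $\in\{0, 0.25, \dots, 2\}$ (9 values): the
  tuned quantity is the multiplier, and
  $\varepsilon = \text{multiplier}\times\mathrm{sd}(y_\text{train})$ is
  recomputed from the *current* training responses in every fold and
  replication.
* **Iterations**: 200 maximum, early stop as above.
* **Selection threshold**: 0.01 on the final weights.

The evaluation protocol (`run_replications()`): per replication, an 80/20
train/test split; features standardized to zero mean and unit sample
standard deviation using *training* statistics only; responses (volumes,
the product of three recorded tumour dimensions, with non-positive or
missing values discarded upstream) cube-rooted so the target lives on the
scale of a single dimension; hyperparameters chosen by 4-fold
cross-validation on the training part; the model refitted on the full
training part and scored on the held-out part with
$\mathrm{NRMSE}=\sqrt{\|y-\hat y\|^2 / \|y-\bar y\|^2}$, for which the mean
predictor scores exactly 1. Grid ties break towards the smallest $C$, then
the smallest multiplier — the most regularized of the tied models.

## Numerical choices

The dual QP's Hessian $[[K,-K],[-K,K]]$ is always rank-deficient, and
Gaussian kernels with mean-distance widths are themselves often
near-singular, which is numerically hostile territory for dense
factorization-based solvers. `solve_svr_dual()` therefore runs a chain of
back ends — `quadprog` (dense active set, with a $10^{-8}$ ridge; a
$10^{-10}$ ridge proved measurably less accurate), `kernlab::ipop`
(interior point), an equality-constrained linear solve for the
$\varepsilon=0$ case (valid whenever the box does not bind; its ridge
shrinks with $C$ because the primal multiplies residuals by $C$), and a
sequential-minimal-optimization solver written for this package
(second-order working-set selection, exact piecewise-quadratic line search
across the $\varepsilon$-term kinks, warm-started from the previous MKL
iteration) — and accepts the first candidate that passes verification:
box/equality feasibility of the raw iterate and a primal–dual gap below
$10^{-6}\max(1,|\text{primal}|)$, with the gap measured against the best
primal completion of the returned coefficients. Returned pairs are
canonicalized through $\beta=\alpha^+-\alpha^-$,
$\alpha^\pm=\max(\pm\beta,0)$, which never worsens the objective and makes
complementarity exact. The SMO stopping tolerance scales like $1/(NC)$
because the duality gap is bounded by roughly the violation times $2NC$.

The intercept is recovered from the KKT conditions: free support vectors
pin it exactly and are averaged; failing those, the midpoint of the
feasible interval implied by the box-active constraints is used (for the
all-zero solution this is the midpoint of
$[\max y_i - \varepsilon,\ \min y_i + \varepsilon]$). The paper-side
literature rarely states this rule; it is this package's choice.

Other floors and tie-breaks: weight entries below $10^{-12}$ snap to exact
0 (zeros are absorbing under the multiplicative update, so this only
accelerates the inevitable); quadratic forms that round off slightly
negative are clamped to 0 before the square root; an all-zero $\alpha$
(tube covers the data) makes the weight update degenerate, so the loop
keeps the current weights, returns the constant model and warns.
Zero-variance training features standardize to exactly 0 for any input.
Gene symbols match expression columns by exact, case-sensitive string
equality — alias resolution would silently change the partitions. Genes in
no set are unused by the MKL model (the all-features SVR baseline still
sees them); sets matching no column are flagged and dropped before kernel
construction.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws expression with standard normal marginals and
exchangeable within-set correlation 0.5 (one latent factor per set, no
between-set correlation), mimicking the strong co-expression within
pathways while keeping set identity crisp. The response signal is a sum of
Gaussian radial bumps — one per informative set, centred at a random point
of that set's expression space with squared length-scale equal to the set
size — deliberately the kind of smooth nonlinearity a Gaussian kernel
represents, so that recovery failures indicate method defects rather than
model mismatch. Gaussian noise with standard deviation half the signal's
is added, and the result is shifted positive and cubed into "volumes", so
the pipeline's cube-root transform recovers a well-scaled target exactly
(up to the affine shift, to which NRMSE is invariant). The reference
conditions are 150 samples, 600 genes in 20 sets of 30, sets 1 and 2
informative. `generate_paired()` adds a tumour/normal mode: normal tissue
is a baseline draw, tumour tissue adds a per-gene shift on chosen genes
plus independent noise.

What passing tests on these cohorts do **not** show: robustness to
count-distributed (negative binomial) expression, library-size and batch
effects, heavy-tailed or heteroscedastic clinical noise, pathway
collections whose sets overlap heavily or mismatch the expression panel,
and cohort sizes in the hundreds with tens of thousands of genes. The
synthetic study is a correctness harness, not a biological benchmark.

## Differential analysis

The tumour-versus-normal step runs a two-sided Wilcoxon signed-rank test
per gene on paired tissues, via `stats::wilcox.test`: zero differences are
dropped (Wilcoxon's original treatment), the exact null distribution is
used up to 25 nonzero pairs when there are no ties, and the normal
approximation with continuity correction otherwise. Significance is called
at raw $p<0.05$ to mirror the protocol; Benjamini–Hochberg adjustment is
available behind a flag. Direction is the sign of the median paired
difference.

## Problem sizes used by the shipped tests and acceptance script

The test suite exercises the full pipeline at the reference conditions
(150 x 600, 10 seeds) and uses smaller cohorts (tens of samples, tens of
genes) for unit-level properties; the solver-oracle comparison runs on
random instances with up to 16 samples, where the independent
projected-gradient oracle converges quickly. The acceptance script runs 10
replications of the protocol on the reference cohort, with the pathway-MKL
model at the mid-grid hyperparameters ($C=1$, multiplier $0.5$) and the
SVR baseline cross-validated over a reduced $3\times3$ grid; these sizes
are the package's choice of a desk-scale study and are stated here so the
reported numbers are reproducible as printed.

## Known limitations

* The alternating scheme finds a stationary point of a nonconvex nested
  problem; different kernel orderings or degenerate ties could reach
  different fixed points (not observed under the shipped conditions).
* Selection frequencies are threshold-dependent; 0.01 follows the
  protocol, and no stability selection or inference on the frequencies is
  attempted.
* The Wilcoxon step tests genes marginally, with no correction by default.
* The random-forest baseline of the original comparison is out of scope;
  `compare_algorithms()` provides the paired two-sided t-test used to
  compare per-replication scores of any two algorithms run on the same
  splits.
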