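# prognosit

Pathway-based multiple kernel learning (MKL) for predicting tumour volume
from gene expression, with supervised pathway selection.

## What problem this solves, and for whom

Models that predict a clinical outcome from all ~20 000 expression features
at once (random forests, single-kernel support vector regression) can
predict adequately but, because expression is highly correlated, they lean
on different gene subsets in every train/test split and reveal little about
the biology. For computational biologists who want the prediction *and* the
mechanism, `prognosit` assigns each pathway (gene set, e.g. an MSigDB
Hallmark or PID collection in GMT format) its own Gaussian kernel and
learns an ε-insensitive support vector regression model jointly with a
sparse convex combination of those kernels. The handful of pathways with
non-negligible weight constitute the model's explanation.

## The model

Base learner: ε-SVR. With kernel matrix K, its dual is

    min  -Σᵢ yᵢ(αᵢ⁺-αᵢ⁻) + ε Σᵢ(αᵢ⁺+αᵢ⁻) + ½ ΣᵢΣⱼ (αᵢ⁺-αᵢ⁻)(αⱼ⁺-αⱼ⁻) K(xᵢ,xⱼ)
    s.t. Σᵢ(αᵢ⁺-αᵢ⁻) = 0,   0 ≤ αᵢ± ≤ C

MKL extension: K is replaced by K_η = Σₘ ηₘ Kₘ, one Gaussian kernel per
gene set (width σₘ = mean pairwise training distance on that set's
sub-matrix), with η on the unit simplex (ηₘ ≥ 0, Σₘ ηₘ = 1). Training
alternates the dual QP at fixed η with the multiplicative update

    ηₘ ← ηₘ √(αᵀKₘα) / Σₒ ηₒ √(αᵀKₒα),   α = α⁺ - α⁻

starting from ηₘ = 1/P, for up to 200 iterations. The ℓ₁ geometry of the
simplex makes the final η sparse; sets with ηₘ > 0.01 are "selected".
Evaluation uses replicated 80/20 splits, training-statistics
standardization, cube-rooted volumes, a 4-fold cross-validated grid over
C ∈ {10⁻³..10³} and tube multiplier ∈ {0, 0.25, …, 2}
(ε = multiplier × sd of the current training responses), and
NRMSE = √(‖y-ŷ‖² / ‖y-ȳ‖²), where 1 means "no better than the mean".

## Worked example

```r
library(prognosit)

# synthetic cohort: 150 samples, 600 genes in 20 sets, sets 1-2 drive a
# nonlinear response
cohort <- generate_cohort(synthetic_spec(seed = 11))
y <- cube_root(cohort$volumes)
partition <- map_to_features(cohort$sets, colnames(cohort$expression))

split <- make_split(length(y), seed = 11)           # 120 train / 30 test
std <- fit_standardizer(cohort$expression[split$train, ])
x_tr <- apply_standardizer(std, cohort$expression[split$train, ])
x_te <- apply_standardizer(std, cohort$expression[split$test, ])

stack <- build_kernel_stack(x_tr, partition)        # 20 Gaussian kernels
fit <- prognosit_fit(stack, y[split$train], C = 1,
                     epsilon = 0.5 * sd(y[split$train]))
fit
#> Pathway-MKL SVR model: 20 kernels, 7 selected (weight > 0.01)
#>   iterations: 173 (converged)
#>   top weights: SET02=0.506, SET01=0.303, SET06=0.060, SET07=0.052, SET09=0.030

nrmse(y[split$test], predict(fit, x_te))
#> [1] 0.5288104
```

The two planted informative sets carry the two largest kernel weights, the
remaining mass is spread thinly over a few background sets, and the test
NRMSE of ≈0.53 is far below the mean predictor's 1.0. On a cohort with no
informative sets the same pipeline returns NRMSE ≈ 1 — the model honestly
reports that there is nothing to learn.

The full protocol (`run_replications()`), pathway selection frequencies
(`selection_frequencies()`) and the paired tumour-vs-normal Wilcoxon table
(`paired_wilcoxon()`) follow the same API; `inst/cli/prognosit` exposes
`simulate`, `run` and `wilcoxon` subcommands over YAML configs for shell
use.

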